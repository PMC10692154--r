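# Human-readable naming of unique assemblies.
#
# Rule precedence (first hit wins):
#   1. curated override (md5 keyed)
#   2. Complex Portal exact match      -> portal recommended name
#   3. Complex Portal extended match   -> portal name(s) + extras
#   4. ribosome detection              -> subunit-based ribosome name
#   5. common GO cellular-component    -> GO term name
#   6. single UniProt accession        -> UniProt recommended name
#      (alone, or with generic extras: antibody/peptide/DNA/RNA)
#   7. all-unmapped protein assemblies -> antibody / entity names
#   8. Rfam-only nucleic assemblies    -> Rfam family (entity) names
#   9. unmapped nucleic assemblies     -> "DNA" / "RNA" / "DNA/RNA hybrid"
#  10. otherwise unnamed
#
# The curated list exists to repair automation, so it overrides
# everything; GO sits below the portal because portal names are curated
# per complex while GO terms describe whole families of complexes.

NAMING_CATEGORIES <- c(
  "uniprot", "unmapped_protein", "nucleic_generic", "complex_portal",
  "ribosome", "antibody", "entity_common_name", "go", "curated", "rfam",
  "unnamed"
)

#' Default naming configuration
#'
#' Tunables of the naming decision tree:
#' \describe{
#'   \item{rrna_families}{Rfam families recognised as rRNA, split by
#'     ribosomal subunit. Small subunit: RF00177 (bacterial SSU), RF01959
#'     (archaeal SSU), RF01960 (eukaryotic SSU). Large subunit: RF02541
#'     (bacterial LSU), RF02540 (archaeal LSU), RF02543 (eukaryotic LSU),
#'     RF00001 (5S) and RF00002 (5.8S).}
#'   \item{eukaryotic_rrna}{Families implying a eukaryotic-style ribosome
#'     (40 S / 60 S / 80 S naming).}
#'   \item{trna_families}{tRNA families (RF00005, RF01852).}
#'   \item{ribosomal_protein_patterns}{Case-insensitive regexes matched
#'     against UniProt and entity names to recognise ribosomal proteins.}
#'   \item{ssu_protein_patterns, lsu_protein_patterns}{Used to infer the
#'     subunit when no rRNA is mapped to Rfam.}
#'   \item{go_allowlist}{GO cellular-component ids eligible for naming —
#'     terms describing a complex or molecular machine, never a location
#'     like "cytoplasm".}
#'   \item{peptide_max_length}{Longest unmapped chain called a peptide
#'     (residues).}
#'   \item{eukaryotic_taxa}{Taxonomy ids treated as eukaryotic when rRNA
#'     gives no kingdom signal.}
#' }
#'
#' @return A named list.
#' @export
default_naming_config <- function() {
  list(
    rrna_families = list(
      SSU = c("RF00177", "RF01959", "RF01960"),
      LSU = c("RF02541", "RF02540", "RF02543", "RF00001", "RF00002")
    ),
    eukaryotic_rrna = c("RF01960", "RF02543", "RF00002"),
    trna_families = c("RF00005", "RF01852"),
    ribosomal_protein_patterns = c("ribosomal protein", "\\bribosome\\b"),
    ssu_protein_patterns = c("\\b30S\\b", "\\b40S\\b", "small subunit"),
    lsu_protein_patterns = c("\\b50S\\b", "\\b60S\\b", "large subunit"),
    go_allowlist = c(
      "GO:0000786", # nucleosome
      "GO:0005665", # RNA polymerase II, core
      "GO:0016591", # RNA polymerase II, holoenzyme
      "GO:0000502", # proteasome complex
      "GO:0005839", # proteasome core complex
      "GO:0009522", # photosystem I
      "GO:0009523", # photosystem II
      "GO:0005833", # haemoglobin complex
      "GO:0033178", # proton-transporting ATP synthase, catalytic core
      "GO:0045259" # proton-transporting ATP synthase complex
    ),
    peptide_max_length = 19L,
    eukaryotic_taxa = integer(0),
    relaxed_portal_stoich = FALSE,
    relation_mode = "strict"
  )
}

matches_any <- function(x, patterns) {
  x <- x[!is.na(x)]
  if (length(x) == 0) {
    return(FALSE)
  }
  any(vapply(
    patterns,
    function(p) any(grepl(p, x, ignore.case = TRUE, perl = TRUE)),
    logical(1)
  ))
}

#' Detect ribosomal assemblies
#'
#' Two ordered detection routes. Primary: at least one RNA component maps
#' to a configured rRNA Rfam family and at least one protein looks
#' ribosomal (name pattern match). Fallback, used only when no rRNA
#' mapping exists at all: the assembly has both unmapped RNA and
#' ribosomal proteins. Subunits come from the rRNA families present, or —
#' on the fallback route — from subunit hints in the protein names
#' (defaulting to a full ribosome when the names carry no hint).
#'
#' @param components Merged component tibble of one unique assembly.
#' @param config Naming configuration ([default_naming_config()]).
#' @return A list of class `ribosome_call`: `is_ribosome`, `subunits`
#'   (subset of `c("SSU", "LSU")`), `has_trna`, `has_other_rna`,
#'   `kingdom_style`, `route`.
#' @export
detect_ribosome <- function(components, config = default_naming_config()) {
  rna <- components[components$polymer_type == "RNA", ]
  rrna_all <- unlist(config$rrna_families, use.names = FALSE)
  mapped_rrna <- rna$rfam[!is.na(rna$rfam) & rna$rfam %in% rrna_all]
  prot_names <- c(
    components$uniprot_name[components$polymer_type == "protein"],
    components$entity_name[components$polymer_type == "protein"]
  )
  has_ribo_protein <- matches_any(prot_names, config$ribosomal_protein_patterns)
  has_unmapped_rna <- any(is.na(rna$rfam))
  any_rfam_rna <- any(!is.na(rna$rfam))

  route <- NA_character_
  if (length(mapped_rrna) > 0 && has_ribo_protein) {
    route <- "rfam"
  } else if (!any_rfam_rna && has_unmapped_rna && has_ribo_protein) {
    route <- "fallback"
  }
  is_ribosome <- !is.na(route)

  subunits <- character(0)
  if (is_ribosome) {
    if (route == "rfam") {
      if (any(mapped_rrna %in% config$rrna_families$SSU)) subunits <- c(subunits, "SSU")
      if (any(mapped_rrna %in% config$rrna_families$LSU)) subunits <- c(subunits, "LSU")
    } else {
      if (matches_any(prot_names, config$ssu_protein_patterns)) subunits <- c(subunits, "SSU")
      if (matches_any(prot_names, config$lsu_protein_patterns)) subunits <- c(subunits, "LSU")
      if (length(subunits) == 0) subunits <- c("SSU", "LSU")
    }
  }

  has_trna <- any(!is.na(rna$rfam) & rna$rfam %in% config$trna_families)
  other_rna <- !is.na(rna$polymer_type) &
    (is.na(rna$rfam) | !(rna$rfam %in% c(rrna_all, config$trna_families)))
  has_other_rna <- is_ribosome && any(other_rna)

  kingdom_style <- if (length(mapped_rrna) > 0) {
    if (any(mapped_rrna %in% config$eukaryotic_rrna)) {
      "eukaryotic-style"
    } else {
      "prokaryotic-style"
    }
  } else if (any(components$taxonomy_id %in% config$eukaryotic_taxa)) {
    "eukaryotic-style"
  } else {
    "unknown"
  }

  structure(
    list(
      is_ribosome = is_ribosome, subunits = subunits, has_trna = has_trna,
      has_other_rna = has_other_rna, kingdom_style = kingdom_style,
      route = route
    ),
    class = "ribosome_call"
  )
}

#' Name a ribosomal assembly
#'
#' `"30 S ribosomal subunit"` / `"50 S ribosomal subunit"` for single
#' subunits (`40 S`/`60 S` in eukaryotic style), `"70 S ribosome"`
#' (`"80 S ribosome"`) when both subunits are present; `" and tRNA"` is
#' appended when tRNA is bound and `" and RNA"` when any other RNA is.
#' Unknown kingdom style names prokaryotic-style.
#'
#' @param call A `ribosome_call` from [detect_ribosome()].
#' @return The ribosome name string.
#' @export
ribosome_name <- function(call) {
  if (!isTRUE(call$is_ribosome)) {
    stop("ribosome_name() called on a non-ribosome assembly", call. = FALSE)
  }
  euk <- identical(call$kingdom_style, "eukaryotic-style")
  base <- if (all(c("SSU", "LSU") %in% call$subunits)) {
    if (euk) "80 S ribosome" else "70 S ribosome"
  } else if ("SSU" %in% call$subunits) {
    if (euk) "40 S ribosomal subunit" else "30 S ribosomal subunit"
  } else {
    if (euk) "60 S ribosomal subunit" else "50 S ribosomal subunit"
  }
  if (call$has_trna) base <- paste0(base, " and tRNA")
  if (call$has_other_rna) base <- paste0(base, " and RNA")
  base
}

#' Archive-wide GO annotation counts
#'
#' Number of components annotated with each GO cellular-component id,
#' over the whole snapshot. Used as the specificity measure when several
#' shared terms qualify: fewer annotated components means a more specific
#' term.
#'
#' @param snapshot An `assembly_snapshot` tibble.
#' @return Named integer vector: GO id -> component count.
#' @export
go_term_counts <- function(snapshot) {
  ids <- unlist(lapply(snapshot$go_cc, function(x) names(parse_go_cc(x))))
  if (length(ids) == 0) {
    return(stats::setNames(integer(0), character(0)))
  }
  tab <- table(ids)
  stats::setNames(as.integer(tab), names(tab))
}

#' Name from a common GO cellular-component term
#'
#' Returns the name of a GO CC term carried by every component of the
#' assembly, restricted to the configured allow-list of
#' complex-describing terms. When several terms qualify, the most
#' specific wins (fewest annotated components archive-wide per
#' `term_counts`; ties break alphabetically by term name). NULL if any
#' component lacks a shared term.
#'
#' @param components Merged component tibble.
#' @param config Naming configuration.
#' @param term_counts Optional counts from [go_term_counts()].
#' @return A list with `go_id` and `name`, or NULL.
#' @export
common_go_name <- function(components, config = default_naming_config(),
                           term_counts = NULL) {
  go_sets <- lapply(components$go_cc, parse_go_cc)
  if (any(vapply(go_sets, length, integer(1)) == 0)) {
    return(NULL)
  }
  common <- Reduce(intersect, lapply(go_sets, names))
  common <- intersect(common, config$go_allowlist)
  if (length(common) == 0) {
    return(NULL)
  }
  name_of <- function(id) {
    for (s in go_sets) if (id %in% names(s)) return(unname(s[[id]]))
  }
  names <- vapply(common, name_of, character(1))
  counts <- if (!is.null(term_counts)) {
    ifelse(is.na(term_counts[common]), Inf, term_counts[common])
  } else {
    rep(Inf, length(common))
  }
  ord <- order(counts, names, method = "radix")
  list(go_id = common[ord[1]], name = unname(names[ord[1]]))
}

# display order for generic extras appended to a UniProt name:
# antibodies (alphabetically), then peptides, DNA, RNA, hybrids
generic_extra_names <- function(extras) {
  ab <- sort(unique(extras$display_name[extras$category == "antibody"]),
    method = "radix"
  )
  rest <- c(
    if (any(extras$category == "peptide")) "peptide",
    if (any(extras$category == "DNA")) "DNA",
    if (any(extras$category == "RNA")) "RNA",
    if (any(extras$display_name == "DNA/RNA hybrid")) "DNA/RNA hybrid"
  )
  c(ab, rest)
}

#' Name a single unique assembly
#'
#' Applies the naming decision tree (see the module header) to one unique
#' composition. Unnamed is a valid outcome, never an error.
#'
#' @param unique_row One row of the `uniques` tibble, as a list (e.g.
#'   `as.list(uniques[i, ])`).
#' @param portal_match A `portal_match` for this composition, or NULL.
#' @param curated Named character vector md5 -> curated name (may be
#'   empty).
#' @param config Naming configuration.
#' @param catalog Portal catalogue (for recommended names); required when
#'   `portal_match` is not NULL.
#' @param term_counts Archive-wide GO counts ([go_term_counts()]).
#' @return A list of class `name_result`: `name` (NA when unnamed),
#'   `category`, `evidence` (character vector of source records).
#' @export
name_assembly <- function(unique_row, portal_match = NULL,
                          curated = character(0),
                          config = default_naming_config(),
                          catalog = NULL, term_counts = NULL) {
  comp <- unique_row$components[[1]]
  md5 <- unique_row$md5[[1]]
  result <- function(name, category, evidence) {
    structure(
      list(name = name, category = category, evidence = evidence),
      class = "name_result"
    )
  }

  # 1. curated override
  if (md5 %in% names(curated)) {
    return(result(unname(curated[[md5]]), "curated", paste0("curated:", md5)))
  }

  # 2-3. Complex Portal
  if (!is.null(portal_match)) {
    portal_names <- vapply(portal_match$complex_acs, function(ac) {
      hit <- which(catalog$complex_ac == ac)
      if (length(hit) == 0) ac else catalog$recommended_name[[hit[1]]]
    }, character(1))
    base <- paste(portal_names, collapse = ", ")
    extras <- portal_match$extra_components
    name <- if (nrow(extras) > 0) {
      paste(c(base, unique(extras$display_name)), collapse = " and ")
    } else {
      base
    }
    return(result(
      name, "complex_portal",
      paste0("complex_portal:", portal_match$complex_acs)
    ))
  }

  # 4. ribosome
  call <- detect_ribosome(comp, config)
  if (call$is_ribosome) {
    return(result(
      ribosome_name(call), "ribosome",
      paste0("ribosome_rule:", call$route)
    ))
  }

  # 5. common GO cellular-component term
  go <- common_go_name(comp, config, term_counts)
  if (!is.null(go)) {
    return(result(go$name, "go", paste0("go:", go$go_id)))
  }

  prot <- comp[comp$polymer_type == "protein", ]
  nonprot <- comp[comp$polymer_type != "protein", ]
  mapped_accs <- unique(prot$uniprot[prot$mapped])

  # 6. single UniProt accession, alone or with generic extras
  if (length(mapped_accs) == 1) {
    uname <- prot$uniprot_name[prot$mapped][1]
    if (is.na(uname)) uname <- prot$entity_name[prot$mapped][1]
    others <- dplyr::bind_rows(prot[!prot$mapped, ], nonprot)
    if (nrow(others) == 0) {
      return(result(uname, "uniprot", paste0("uniprot:", mapped_accs)))
    }
    extras <- extras_tibble(others, config$peptide_max_length)
    if (all(extras$category %in% c("antibody", "peptide", "DNA", "RNA") |
      extras$display_name == "DNA/RNA hybrid")) {
      name <- paste(
        paste(c(uname, generic_extra_names(extras)), collapse = ", "),
        "complex"
      )
      return(result(name, "uniprot", paste0("uniprot:", mapped_accs)))
    }
    return(result(NA_character_, "unnamed", character(0)))
  }

  # 7. all-unmapped protein assemblies: antibody and/or entity names
  if (nrow(nonprot) == 0 && nrow(prot) > 0 && length(mapped_accs) == 0) {
    all_antibody <- all(prot$is_antibody %in% TRUE)
    names <- prot$entity_name
    if (all(!is.na(names)) && length(names) > 0) {
      display <- sort(unique(names), method = "radix")
      if (all_antibody) {
        return(result(
          paste(display, collapse = " and "), "antibody",
          paste0("antibody_entity:", prot$entry_id[1], "/", prot$entity_id)
        ))
      }
      if (nrow(prot) == 1) {
        return(result(
          display, "unmapped_protein",
          paste0("entity:", prot$entry_id[1], "/", prot$entity_id[1])
        ))
      }
      return(result(
        paste(display, collapse = " and "), "entity_common_name",
        paste0("entity:", prot$entry_id[1], "/", prot$entity_id)
      ))
    }
    return(result(NA_character_, "unnamed", character(0)))
  }

  # 8-9. nucleic-acid-only assemblies
  if (nrow(prot) == 0 && nrow(nonprot) > 0) {
    if (all(nonprot$mapped)) {
      names <- unique(nonprot$entity_name)
      if (all(!is.na(names))) {
        return(result(
          paste(sort(names, method = "radix"), collapse = " and "), "rfam",
          paste0("rfam:", unique(nonprot$rfam))
        ))
      }
    }
    types <- unique(nonprot$polymer_type)
    name <- if (identical(types, "DNA")) {
      "DNA"
    } else if (identical(types, "RNA")) {
      "RNA"
    } else {
      "DNA/RNA hybrid"
    }
    return(result(name, "nucleic_generic", "nucleic_type_rule"))
  }

  # 10. unnamed
  result(NA_character_, "unnamed", character(0))
}

#' @export
print.name_result <- function(x, ...) {
  cat("[", x$category, "] ", if (is.na(x$name)) "<unnamed>" else x$name, "\n",
    sep = ""
  )
  invisible(x)
}

#' Name every unique assembly
#'
#' @param uniques The `uniques` tibble from [group_unique()].
#' @param matches Portal matches from [match_all_portal()] (or NULL).
#' @param curated Curated-name vector (md5 -> name).
#' @param config Naming configuration.
#' @param catalog Portal catalogue.
#' @param term_counts GO counts from [go_term_counts()].
#' @return `uniques` with columns `name`, `category` and list-column
#'   `evidence` appended.
#' @export
name_uniques <- function(uniques, matches = NULL, curated = character(0),
                         config = default_naming_config(), catalog = NULL,
                         term_counts = NULL) {
  results <- lapply(seq_len(nrow(uniques)), function(i) {
    name_assembly(
      as.list(uniques[i, ]),
      portal_match = if (!is.null(matches)) matches[[uniques$md5[[i]]]],
      curated = curated, config = config, catalog = catalog,
      term_counts = term_counts
    )
  })
  uniques$name <- vapply(results, `[[`, character(1), "name")
  uniques$category <- vapply(results, `[[`, character(1), "category")
  uniques$evidence <- lapply(results, `[[`, "evidence")
  uniques
}

#' Naming category breakdown
#'
#' @param named_uniques Output of [name_uniques()].
#' @return A list with `by_category` (tibble: category, n_unique,
#'   n_entries — annotated member entries), `n_unique`, `n_named` and
#'   `named_fraction`.
#' @export
naming_statistics <- function(named_uniques) {
  n_entries <- vapply(
    named_uniques$members,
    function(m) length(unique(m$entry_id)), integer(1)
  )
  by_category <- tibble::tibble(
    category = named_uniques$category, n_entries = n_entries
  ) |>
    dplyr::count(.data$category, wt = NULL, name = "n_unique") |>
    dplyr::left_join(
      tibble::tibble(category = named_uniques$category, n_entries = n_entries) |>
        dplyr::group_by(.data$category) |>
        dplyr::summarise(n_entries = sum(.data$n_entries), .groups = "drop"),
      by = "category"
    ) |>
    dplyr::arrange(dplyr::desc(.data$n_unique), .data$category)
  n_named <- sum(named_uniques$category != "unnamed")
  list(
    by_category = by_category,
    n_unique = nrow(named_uniques),
    n_named = n_named,
    named_fraction = if (nrow(named_uniques) > 0) {
      n_named / nrow(named_uniques)
    } else {
      NA_real_
    }
  )
}
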