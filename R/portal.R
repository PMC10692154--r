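# Matching unique compositions to Complex Portal definitions.
#
# Three match kinds:
#   exact             the UniProt multiset (with stoichiometry) of the
#                     assembly equals a portal complex's participants and
#                     the assembly has no other components
#   exact_plus_extras one portal complex's participants are contained in
#                     the assembly; the leftover components are
#                     categorised (protein/DNA/RNA/antibody/peptide/
#                     unmapped)
#   multi_portal      two or more portal complexes with disjoint
#                     participant coverage are contained in the assembly
#                     (greedy largest-coverage-first cover, ties to the
#                     lowest accession)

#' Mapped UniProt multiset of an assembly
#' @param components Merged component tibble (from [merge_components()]).
#' @return Named integer vector accession -> copies.
#' @keywords internal
mapped_protein_multiset <- function(components) {
  prot <- components[components$polymer_type == "protein" & components$mapped, ]
  stats::setNames(as.integer(prot$copies), prot$uniprot)
}

#' Categorise a component for extras reporting and naming
#'
#' Categories: `protein` (UniProt-mapped), `antibody`, `peptide`
#' (unmapped protein shorter than `peptide_max_length` residues, when a
#' length is available), `DNA`, `RNA`, `unmapped` (anything else:
#' unmapped proteins of unknown or full length, DNA/RNA hybrids).
#'
#' @param components Merged component tibble rows.
#' @param peptide_max_length Longest chain still called a peptide.
#' @return Character vector of categories, one per row.
#' @export
categorize_component <- function(components, peptide_max_length = 19L) {
  dplyr::case_when(
    components$is_antibody %in% TRUE & !components$mapped ~ "antibody",
    components$polymer_type == "protein" & components$mapped ~ "protein",
    components$polymer_type == "protein" &
      !is.na(components$seq_length) &
      components$seq_length <= peptide_max_length ~ "peptide",
    components$polymer_type == "DNA" ~ "DNA",
    components$polymer_type == "RNA" ~ "RNA",
    TRUE ~ "unmapped"
  )
}

extras_tibble <- function(components, peptide_max_length = 19L) {
  if (nrow(components) == 0) {
    return(tibble::tibble(
      label = character(), category = character(), display_name = character()
    ))
  }
  category <- categorize_component(components, peptide_max_length)
  display <- dplyr::case_when(
    category == "protein" ~ dplyr::coalesce(
      components$uniprot_name, components$entity_name, "protein"
    ),
    category == "antibody" ~ dplyr::coalesce(components$entity_name, "antibody"),
    category == "peptide" ~ "peptide",
    category == "DNA" ~ "DNA",
    category == "RNA" ~ "RNA",
    components$polymer_type == "DNA/RNA" ~ "DNA/RNA hybrid",
    TRUE ~ dplyr::coalesce(components$entity_name, "protein")
  )
  tibble::tibble(
    label = components$label, category = category, display_name = display
  )
}

multiset_contains <- function(big, small, relaxed = FALSE) {
  if (!all(names(small) %in% names(big))) {
    return(FALSE)
  }
  shared <- big[names(small)]
  if (relaxed) all(small <= shared) else all(small == shared)
}

#' Exact Complex Portal match
#'
#' @param components Merged component tibble of a unique assembly.
#' @param catalog Portal catalogue from [read_portal_catalog()].
#' @return A `portal_match` list (`kind = "exact"`) or NULL. Among equal
#'   portal entries the lowest accession wins.
#' @export
match_exact <- function(components, catalog) {
  if (nrow(catalog) == 0 || nrow(components) == 0) {
    return(NULL)
  }
  if (!all(components$polymer_type == "protein" & components$mapped)) {
    return(NULL)
  }
  assembly <- mapped_protein_multiset(components)
  hits <- vapply(catalog$participants, function(p) {
    length(p) == length(assembly) && multiset_contains(assembly, p)
  }, logical(1))
  if (!any(hits)) {
    return(NULL)
  }
  acs <- sort(catalog$complex_ac[hits], method = "radix")
  new_portal_match("exact", acs[1], extras_tibble(components[0, ]))
}

#' Extended Complex Portal match
#'
#' Called when no exact match exists. Finds portal complexes wholly
#' contained in the assembly's mapped-protein multiset (equal
#' stoichiometry on shared participants unless `relaxed_stoich`), covering
#' greedily by largest participant coverage first. Leftover components
#' are categorised; if two or more portal complexes are covered the match
#' kind is `multi_portal`.
#'
#' @param components Merged component tibble of a unique assembly.
#' @param catalog Portal catalogue.
#' @param relaxed_stoich Allow lower stoichiometry in the portal
#'   definition than in the assembly?
#' @param peptide_max_length Passed to [categorize_component()].
#' @return A `portal_match` list or NULL.
#' @export
match_extended <- function(components, catalog, relaxed_stoich = FALSE,
                           peptide_max_length = 19L) {
  if (nrow(catalog) == 0 || nrow(components) == 0) {
    return(NULL)
  }
  remaining <- mapped_protein_multiset(components)
  chosen <- character(0)
  covered <- character(0)
  repeat {
    fits <- vapply(catalog$participants, function(p) {
      length(p) > 0 && multiset_contains(remaining, p, relaxed = relaxed_stoich)
    }, logical(1))
    fits[catalog$complex_ac %in% chosen] <- FALSE
    if (!any(fits)) {
      break
    }
    coverage <- vapply(catalog$participants, function(p) sum(p), integer(1))
    coverage[!fits] <- -1L
    best <- which(coverage == max(coverage))
    best <- best[order(catalog$complex_ac[best], method = "radix")][1]
    p <- catalog$participants[[best]]
    chosen <- c(chosen, catalog$complex_ac[[best]])
    covered <- c(covered, names(p))
    if (relaxed_stoich) {
      remaining[names(p)] <- remaining[names(p)] - p
      remaining <- remaining[remaining > 0]
    } else {
      remaining <- remaining[setdiff(names(remaining), names(p))]
    }
  }
  if (length(chosen) == 0) {
    return(NULL)
  }
  leftover <- components[!(components$polymer_type == "protein" &
    components$mapped &
    components$uniprot %in% covered), ]
  extras <- extras_tibble(leftover, peptide_max_length)
  if (length(chosen) == 1 && nrow(extras) == 0) {
    # full coverage by one complex: this is an exact match after all
    # (only reachable when the caller skipped match_exact)
    return(new_portal_match("exact", chosen, extras))
  }
  kind <- if (length(chosen) >= 2) "multi_portal" else "exact_plus_extras"
  new_portal_match(kind, chosen, extras)
}

new_portal_match <- function(kind, complex_acs, extra_components) {
  structure(
    list(
      kind = kind, complex_acs = complex_acs,
      extra_components = extra_components
    ),
    class = "portal_match"
  )
}

#' @export
print.portal_match <- function(x, ...) {
  cat(
    "portal match [", x$kind, "]: ",
    paste(x$complex_acs, collapse = " + "), "\n",
    sep = ""
  )
  if (nrow(x$extra_components) > 0) {
    cat(
      "  extras:",
      paste0(
        x$extra_components$label, " (", x$extra_components$category, ")",
        collapse = ", "
      ),
      "\n"
    )
  }
  invisible(x)
}

#' Match a unique assembly against the Complex Portal
#'
#' Tries [match_exact()] first, then [match_extended()]; an extended match
#' never fires when an exact one exists.
#'
#' @inheritParams match_extended
#' @return A `portal_match` or NULL.
#' @export
match_portal <- function(components, catalog, relaxed_stoich = FALSE,
                         peptide_max_length = 19L) {
  match_exact(components, catalog) %||%
    match_extended(components, catalog,
      relaxed_stoich = relaxed_stoich,
      peptide_max_length = peptide_max_length
    )
}

#' Match every unique assembly against the Complex Portal
#'
#' @param uniques The `uniques` tibble from [group_unique()].
#' @param catalog Portal catalogue.
#' @param relaxed_stoich,peptide_max_length Passed through.
#' @return A list of `portal_match`/NULL, parallel to `uniques` rows and
#'   named by md5.
#' @export
match_all_portal <- function(uniques, catalog, relaxed_stoich = FALSE,
                             peptide_max_length = 19L) {
  matches <- lapply(uniques$components, function(comp) {
    match_portal(comp, catalog,
      relaxed_stoich = relaxed_stoich,
      peptide_max_length = peptide_max_length
    )
  })
  names(matches) <- uniques$md5
  matches
}

#' Export the portal mapping file
#'
#' One row per matched unique assembly, ordered by accession; written
#' atomically (temp file, then rename) so a failed export never leaves a
#' partial file.
#'
#' @param uniques The `uniques` tibble.
#' @param matches Output of [match_all_portal()].
#' @param path Output TSV path.
#' @return The mapping tibble, invisibly.
#' @export
export_mapping <- function(uniques, matches, path) {
  rows <- lapply(seq_len(nrow(uniques)), function(i) {
    m <- matches[[uniques$md5[[i]]]]
    if (is.null(m)) {
      return(NULL)
    }
    tibble::tibble(
      accession = uniques$accession[[i]],
      md5 = uniques$md5[[i]],
      complex_acs = paste(m$complex_acs, collapse = "|"),
      kind = m$kind,
      extras = paste(
        paste0(m$extra_components$label, ":", m$extra_components$category),
        collapse = "|"
      )
    )
  })
  mapping <- dplyr::bind_rows(rows)
  if (nrow(mapping) == 0) {
    mapping <- tibble::tibble(
      accession = character(), md5 = character(), complex_acs = character(),
      kind = character(), extras = character()
    )
  }
  mapping <- dplyr::arrange(mapping, .data$accession)
  tmp <- paste0(path, ".tmp")
  ok <- FALSE
  tryCatch(
    {
      readr::write_tsv(mapping, tmp, na = "", progress = FALSE)
      file.rename(tmp, path)
      ok <- TRUE
    },
    finally = if (!ok && file.exists(tmp)) unlink(tmp)
  )
  invisible(mapping)
}
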