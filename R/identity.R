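# Canonical composition labels, composition strings and md5 digests,
# preferred-assembly selection and grouping of assemblies into unique
# compositions.
#
# The label grammar, per component type:
#   protein mapped to UniProt   <accession>_<stoichiometry>
#   RNA mapped to Rfam          <accession>_<stoichiometry>
#   antibody (unmapped)         antibody_<entry>_<entity>_<stoichiometry>
#   protein (unmapped)          protein_<entry>_<entity>_<stoichiometry>
#   RNA (unmapped)              RNA_<entry>_<entity>_<stoichiometry>
#   DNA                         DNA_<entry>_<entity>_<stoichiometry>
#   DNA/RNA hybrid              DNA/RNA_<entry>_<entity>_<stoichiometry>
#
# The "identity" of a component is its label without the stoichiometry
# suffix; two components with the same identity are the same molecule and
# their copy numbers are summed before labelling.

is_chimeric <- function(uniprot) {
  !is.na(uniprot) & grepl(";", uniprot, fixed = TRUE)
}

#' Component identity token
#'
#' The label base without the stoichiometry suffix: the mapped accession
#' for UniProt/Rfam components, or `<type>_<entry>_<entity>` for unmapped
#' ones. Components with equal identity are copies of the same molecule.
#'
#' @param components Component rows (snapshot columns).
#' @return Character vector of identity tokens.
#' @export
component_identity <- function(components) {
  with(components, {
    mapped_protein <- polymer_type == "protein" & !is.na(uniprot)
    mapped_rna <- polymer_type == "RNA" & !is.na(rfam)
    antibody <- polymer_type == "protein" & is_antibody %in% TRUE & is.na(uniprot)
    dplyr::case_when(
      mapped_protein ~ uniprot,
      mapped_rna ~ rfam,
      antibody ~ paste0("antibody_", entry_id, "_", entity_id),
      polymer_type == "protein" ~ paste0("protein_", entry_id, "_", entity_id),
      polymer_type == "RNA" ~ paste0("RNA_", entry_id, "_", entity_id),
      polymer_type == "DNA" ~ paste0("DNA_", entry_id, "_", entity_id),
      polymer_type == "DNA/RNA" ~ paste0("DNA/RNA_", entry_id, "_", entity_id)
    )
  })
}

component_is_mapped <- function(components) {
  (components$polymer_type == "protein" & !is.na(components$uniprot)) |
    (components$polymer_type == "RNA" & !is.na(components$rfam))
}

#' Generate composition labels for components
#'
#' Applies the label grammar to each component row. A component mapped to
#' an external accession is labelled `<accession>_<stoichiometry>`; an
#' unmapped component is labelled by its type, entry and entity so that it
#' only ever matches itself. A flagged antibody with a UniProt mapping is
#' labelled by the accession (the mapping is the stronger evidence).
#'
#' @param components Component rows (snapshot columns).
#' @return Character vector of labels, one per row.
#' @export
component_label <- function(components) {
  if (any(is_chimeric(components$uniprot))) {
    bad <- components[is_chimeric(components$uniprot), ]
    stop(
      "cannot label chimeric component(s): ",
      paste0(bad$entry_id, "/", bad$entity_id, collapse = ", "),
      " (entities mapping to >1 UniProt accession are excluded from",
      " unique-assembly identification)",
      call. = FALSE
    )
  }
  paste0(component_identity(components), "_", components$copies)
}

#' Merge components of an assembly by identity
#'
#' Components split across deposition entities but mapped to the same
#' accession are the same molecule; their copy numbers are summed before
#' labelling. Unmapped identities embed entry and entity, so they never
#' merge. The result carries one row per identity with descriptive fields
#' taken from the first contributing entity.
#'
#' @param components Component rows of one assembly.
#' @return A tibble with one row per component identity, including
#'   `identity`, `label`, `mapped` and summed `copies`.
#' @export
merge_components <- function(components) {
  components <- tibble::as_tibble(components)
  components$identity <- component_identity(components)
  components$mapped <- component_is_mapped(components)
  merged <- components |>
    dplyr::group_by(.data$identity) |>
    dplyr::summarise(
      entry_id = dplyr::first(.data$entry_id),
      entity_id = dplyr::first(.data$entity_id),
      polymer_type = dplyr::first(.data$polymer_type),
      uniprot = dplyr::first(.data$uniprot),
      rfam = dplyr::first(.data$rfam),
      is_antibody = any(.data$is_antibody %in% TRUE),
      entity_name = dplyr::first(.data$entity_name),
      uniprot_name = dplyr::first(.data$uniprot_name),
      go_cc = dplyr::first(.data$go_cc),
      taxonomy_id = dplyr::first(.data$taxonomy_id),
      copies = sum(.data$copies),
      mapped = dplyr::first(.data$mapped),
      seq_length = dplyr::first(.data$seq_length),
      n_entities = dplyr::n(),
      .groups = "drop"
    )
  merged$label <- paste0(merged$identity, "_", merged$copies)
  merged
}

#' Canonical composition key of an assembly
#'
#' Merges components by identity, orders labels canonically (mapped
#' accession labels first, then unmapped labels, each block in bytewise
#' lexicographic order), joins them with `","` (no whitespace) into the
#' composition string, and takes its md5 digest. The key depends only on
#' the component multiset, never on input order.
#'
#' @param components Component rows of one assembly.
#' @return A list of class `composition_key` with `labels`,
#'   `composition_string` and `md5_hex`.
#' @export
canonical_key <- function(components) {
  elig <- eligibility(components)
  if (!elig$eligible) {
    stop("assembly is not eligible: ", elig$reason, call. = FALSE)
  }
  merged <- merge_components(components)
  ord <- order(!merged$mapped, merged$label, method = "radix")
  labels <- merged$label[ord]
  composition_string <- paste(labels, collapse = ",")
  structure(
    list(
      labels = labels,
      composition_string = composition_string,
      md5_hex = digest::digest(composition_string, algo = "md5", serialize = FALSE)
    ),
    class = "composition_key"
  )
}

#' @export
print.composition_key <- function(x, ...) {
  cat("composition:", x$composition_string, "\n")
  cat("md5:        ", x$md5_hex, "\n")
  invisible(x)
}

#' Eligibility of an assembly for unique-composition identification
#'
#' Assemblies containing chimeric chains — a single polymer entity mapped
#' to more than one UniProt accession — are excluded from identification.
#'
#' @param components Component rows of one assembly.
#' @return A list with `eligible` (logical) and `reason` (NA when
#'   eligible; names the offending entity otherwise).
#' @export
eligibility <- function(components) {
  chim <- is_chimeric(components$uniprot)
  if (any(chim)) {
    bad <- components[chim, ]
    list(
      eligible = FALSE,
      reason = paste0(
        "chimeric entity ", paste0(bad$entry_id, "/", bad$entity_id,
          collapse = ", "
        ),
        " maps to multiple UniProt accessions"
      )
    )
  } else {
    list(eligible = TRUE, reason = NA_character_)
  }
}

#' Select the preferred assembly of an entry
#'
#' The preferred assembly is the smallest assembly (fewest polymer chains,
#' i.e. lowest total copy count) containing all polymeric entities of the
#' entry; ties break to the lowest assembly_id. If no assembly contains
#' every entity, the assembly covering the most entities wins (same
#' tie-breaks).
#'
#' @param entry_components Snapshot rows of a single entry (all its
#'   assemblies).
#' @return The selected `assembly_id` (integer scalar).
#' @export
select_preferred_assembly <- function(entry_components) {
  if (nrow(entry_components) == 0) {
    stop("select_preferred_assembly() needs at least one assembly", call. = FALSE)
  }
  if (length(unique(entry_components$entry_id)) != 1) {
    stop("select_preferred_assembly() expects a single entry", call. = FALSE)
  }
  all_entities <- unique(entry_components$entity_id)
  per_assembly <- entry_components |>
    dplyr::group_by(.data$assembly_id) |>
    dplyr::summarise(
      n_entities = dplyr::n_distinct(.data$entity_id),
      n_chains = sum(.data$copies),
      .groups = "drop"
    )
  per_assembly$complete <- per_assembly$n_entities == length(all_entities)
  candidates <- if (any(per_assembly$complete)) {
    per_assembly[per_assembly$complete, ]
  } else {
    per_assembly[per_assembly$n_entities == max(per_assembly$n_entities), ]
  }
  candidates <- candidates[order(candidates$n_chains, candidates$assembly_id), ]
  candidates$assembly_id[[1]]
}

#' Preferred assembly of every entry in a snapshot
#'
#' @param snapshot An `assembly_snapshot` tibble.
#' @return A tibble with `entry_id` and the preferred `assembly_id`.
#' @export
select_preferred <- function(snapshot) {
  snapshot |>
    dplyr::group_by(.data$entry_id) |>
    dplyr::group_modify(function(df, key) {
      df$entry_id <- key$entry_id
      tibble::tibble(assembly_id = select_preferred_assembly(df))
    }) |>
    dplyr::ungroup()
}

#' Group preferred, eligible assemblies into unique compositions
#'
#' Runs identification over a snapshot: selects each entry's preferred
#' assembly, drops assemblies containing chimeric chains, computes the
#' canonical composition key of each survivor, groups equal keys into one
#' unique assembly, and (when a registry is supplied) assigns persistent
#' accessions. New compositions are assigned in lexicographic order of
#' their composition strings, so accession minting is independent of
#' snapshot row order.
#'
#' @param snapshot An `assembly_snapshot` tibble.
#' @param registry A `cpx_registry` (or NULL to skip accession assignment).
#' @param preferred_only Identify only each entry's preferred assembly
#'   (the default, matching archive practice)? With `FALSE` every eligible
#'   assembly is identified.
#' @return A list with `uniques` (tibble, one row per unique composition:
#'   accession, md5, composition string, labels, merged component table,
#'   members, composition class flags) and the updated `registry`.
#' @export
group_unique <- function(snapshot, registry = NULL, preferred_only = TRUE) {
  work <- tibble::as_tibble(snapshot)
  if (preferred_only && nrow(work) > 0) {
    pref <- select_preferred(work)
    work <- dplyr::semi_join(work, pref, by = c("entry_id", "assembly_id"))
  }
  if (nrow(work) == 0) {
    uniques <- empty_uniques()
    return(list(uniques = uniques, registry = registry))
  }

  per_assembly <- work |>
    dplyr::group_by(.data$entry_id, .data$assembly_id) |>
    dplyr::group_split()
  keys <- vector("list", length(per_assembly))
  keep <- logical(length(per_assembly))
  for (i in seq_along(per_assembly)) {
    comp <- per_assembly[[i]]
    if (eligibility(comp)$eligible) {
      keys[[i]] <- canonical_key(comp)
      keep[i] <- TRUE
    }
  }
  per_assembly <- per_assembly[keep]
  keys <- keys[keep]
  if (length(per_assembly) == 0) {
    return(list(uniques = empty_uniques(), registry = registry))
  }

  md5 <- vapply(keys, `[[`, character(1), "md5_hex")
  comp_string <- vapply(keys, `[[`, character(1), "composition_string")
  groups <- split(seq_along(per_assembly), md5)
  # canonical, order-independent output ordering
  first_of <- vapply(groups, `[`, integer(1), 1)
  ord <- order(comp_string[first_of], method = "radix")
  groups <- groups[ord]

  rows <- lapply(groups, function(idx) {
    comp <- merge_components(per_assembly[[idx[1]]])
    members <- tibble::tibble(
      entry_id = vapply(per_assembly[idx], function(a) a$entry_id[[1]], character(1)),
      assembly_id = vapply(per_assembly[idx], function(a) a$assembly_id[[1]], integer(1))
    )
    members <- members[order(members$entry_id, members$assembly_id), ]
    has_protein <- any(comp$polymer_type == "protein")
    has_nucleic <- any(comp$polymer_type != "protein")
    n_mem <- nrow(members)
    tibble::tibble(
      md5 = md5[idx[1]],
      composition_string = comp_string[idx[1]],
      labels = list(keys[[idx[1]]]$labels),
      components = list(comp),
      members = list(members),
      n_members = n_mem,
      n_components = nrow(comp),
      n_chains = sum(comp$copies),
      protein_only = has_protein && !has_nucleic,
      nucleic_only = !has_protein,
      quaternary = if (nrow(comp) > 1) {
        "heteromeric"
      } else if (comp$copies[[1]] > 1) "homomeric" else "monomeric",
      all_mapped = all(comp$mapped),
      any_mapped = any(comp$mapped),
      taxonomy_ids = list(sort(unique(comp$taxonomy_id[!is.na(comp$taxonomy_id)])))
    )
  })
  uniques <- dplyr::bind_rows(rows)

  if (!is.null(registry)) {
    assigned <- assign_identifiers(registry, uniques$md5)
    uniques$accession <- assigned$accessions
    registry <- assigned$registry
  } else {
    uniques$accession <- NA_character_
  }
  uniques <- uniques[, c("accession", setdiff(names(uniques), "accession"))]
  list(uniques = uniques, registry = registry)
}

empty_uniques <- function() {
  tibble::tibble(
    accession = character(),
    md5 = character(),
    composition_string = character(),
    labels = list(),
    components = list(),
    members = list(),
    n_members = integer(),
    n_components = integer(),
    n_chains = integer(),
    protein_only = logical(),
    nucleic_only = logical(),
    quaternary = character(),
    all_mapped = logical(),
    any_mapped = logical(),
    taxonomy_ids = list()
  )
}

#' Composition statistics over unique assemblies
#'
#' Archive-level breakdown of unique compositions: protein-only versus
#' protein/nucleic-acid versus nucleic-acid-only, quaternary class, and
#' UniProt mapping coverage.
#'
#' @param uniques The `uniques` tibble from [group_unique()].
#' @return A named list of counts.
#' @export
composition_statistics <- function(uniques) {
  list(
    n_unique = nrow(uniques),
    protein_only = sum(uniques$protein_only),
    protein_nucleic = sum(!uniques$protein_only & !uniques$nucleic_only),
    nucleic_only = sum(uniques$nucleic_only),
    monomeric = sum(uniques$quaternary == "monomeric"),
    homomeric = sum(uniques$quaternary == "homomeric"),
    heteromeric = sum(uniques$quaternary == "heteromeric"),
    any_component_mapped = sum(uniques$any_mapped),
    all_components_mapped = sum(uniques$all_mapped)
  )
}

#' Stoichiometry variability of homomeric compositions
#'
#' For every accession observed as a single-component mapped assembly
#' (monomeric or homomeric), counts how many distinct stoichiometries the
#' archive holds. Accessions with more than one stoichiometry flag either
#' genuine biological variability or annotation problems.
#'
#' @param uniques The `uniques` tibble from [group_unique()].
#' @return A tibble: `accession_mapped` (UniProt accession),
#'   `protein_name`, `n_stoichiometries`, `stoichiometries`.
#' @export
stoichiometry_variability <- function(uniques) {
  single <- uniques[uniques$n_components == 1 & uniques$all_mapped &
    uniques$protein_only, ]
  if (nrow(single) == 0) {
    return(tibble::tibble(
      accession_mapped = character(), protein_name = character(),
      n_stoichiometries = integer(), stoichiometries = character()
    ))
  }
  rows <- lapply(seq_len(nrow(single)), function(i) {
    comp <- single$components[[i]]
    tibble::tibble(
      accession_mapped = comp$uniprot[[1]],
      protein_name = comp$uniprot_name[[1]],
      stoich = comp$copies[[1]]
    )
  })
  dplyr::bind_rows(rows) |>
    dplyr::group_by(.data$accession_mapped) |>
    dplyr::summarise(
      protein_name = dplyr::first(.data$protein_name),
      n_stoichiometries = dplyr::n_distinct(.data$stoich),
      stoichiometries = paste(sort(unique(.data$stoich)), collapse = ","),
      .groups = "drop"
    ) |>
    dplyr::arrange(dplyr::desc(.data$n_stoichiometries), .data$accession_mapped)
}
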