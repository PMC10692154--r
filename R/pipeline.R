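# End-to-end weekly-release-style orchestration:
# identify -> relate -> portal-map -> name -> symmetry -> stats.
#
# Outputs are written to temporary files and renamed into place, so a
# failed run never leaves partial outputs; identical inputs plus an
# unchanged registry produce byte-identical outputs, and the registry is
# only ever appended to.

#' Run the full assembly-standardisation pipeline
#'
#' @param snapshot An `assembly_snapshot` tibble or a snapshot TSV path.
#' @param portal_catalog A catalogue tibble, a catalogue TSV path, or
#'   NULL to skip Complex Portal matching.
#' @param curated A named character vector (md5 -> name), a curated-list
#'   TSV path, or NULL.
#' @param registry_path Path of the persistent identifier registry. When
#'   the file exists it is loaded and extended append-only; when it does
#'   not, a fresh registry starting at serial 100001 is created there.
#'   NULL runs with an in-memory registry.
#' @param out_dir Output directory (created if needed), receiving
#'   `unique_assemblies.tsv`, `relations.tsv`, `portal_mapping.tsv`,
#'   `names.tsv`, `symmetry_report.tsv` and `stats.json`. NULL skips
#'   writing.
#' @param config Naming configuration ([default_naming_config()]); its
#'   `relation_mode` and `relaxed_portal_stoich` entries set the
#'   relation and portal-matching modes.
#' @return Invisibly, a list with `uniques` (named), `relations`,
#'   `matches`, `mapping`, `symmetry`, `consistency`, `stats` and
#'   `registry`.
#' @export
run_pipeline <- function(snapshot, portal_catalog = NULL, curated = NULL,
                         registry_path = NULL, out_dir = NULL,
                         config = default_naming_config()) {
  if (is.character(snapshot)) {
    snapshot <- read_snapshot(snapshot)
  } else {
    report <- validate_snapshot(snapshot)
    if (nrow(report$errors) > 0) {
      stop("snapshot validation failed; see validate_snapshot()", call. = FALSE)
    }
  }
  if (is.character(portal_catalog)) {
    portal_catalog <- read_portal_catalog(portal_catalog)
  }
  if (is.character(curated) && length(curated) == 1 && is.null(names(curated))) {
    curated <- read_curated_names(curated)
  }
  if (is.null(curated)) curated <- character(0)

  registry <- if (!is.null(registry_path) && file.exists(registry_path)) {
    load_registry(registry_path)
  } else {
    new_registry()
  }

  gu <- group_unique(snapshot, registry)
  uniques <- gu$uniques
  registry <- gu$registry

  relations <- build_relation_graph(uniques, mode = config$relation_mode)

  matches <- if (!is.null(portal_catalog)) {
    match_all_portal(uniques, portal_catalog,
      relaxed_stoich = isTRUE(config$relaxed_portal_stoich),
      peptide_max_length = config$peptide_max_length
    )
  } else {
    stats::setNames(
      vector("list", nrow(uniques)),
      uniques$md5
    )
  }

  term_counts <- go_term_counts(snapshot)
  named <- name_uniques(uniques,
    matches = matches, curated = curated,
    config = config, catalog = portal_catalog, term_counts = term_counts
  )

  freq <- symmetry_frequency(snapshot)
  consistency <- consistency_by_composition(uniques, snapshot)

  rel_counts <- relation_counts(relations, uniques)
  naming_stats <- naming_statistics(named)
  stats <- list(
    composition = composition_statistics(uniques),
    naming = c(
      list(
        n_named = naming_stats$n_named,
        named_fraction = naming_stats$named_fraction
      ),
      list(by_category = naming_stats$by_category)
    ),
    portal = list(
      n_matched = sum(!vapply(matches, is.null, logical(1))),
      n_exact = sum(vapply(
        matches, function(m) !is.null(m) && m$kind == "exact", logical(1)
      )),
      n_exact_plus_extras = sum(vapply(
        matches, function(m) !is.null(m) && m$kind == "exact_plus_extras",
        logical(1)
      )),
      n_multi_portal = sum(vapply(
        matches, function(m) !is.null(m) && m$kind == "multi_portal", logical(1)
      ))
    ),
    relations = list(
      n_edges = nrow(relations),
      n_sub_assemblies = sum(rel_counts$is_sub),
      n_super_assemblies = sum(rel_counts$is_super)
    ),
    symmetry = list(
      n_labelled = freq$n_labelled,
      n_symmetric = freq$n_symmetric,
      families = freq$families,
      n_compositions_assessed = consistency$n_assessed,
      n_compositions_inconsistent = consistency$n_inconsistent,
      fraction_inconsistent = consistency$fraction_inconsistent,
      n_assemblies_assessed = consistency$n_assemblies_assessed,
      n_assemblies_inconsistent = consistency$n_assemblies_inconsistent
    )
  )

  mapping <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_atomic <- function(tbl, file) {
      path <- file.path(out_dir, file)
      tmp <- paste0(path, ".tmp")
      readr::write_tsv(tbl, tmp, na = "", progress = FALSE)
      file.rename(tmp, path)
    }
    write_atomic(uniques_table(named), "unique_assemblies.tsv")
    write_atomic(
      relations[, c("sub_accession", "super_accession", "added_components")],
      "relations.tsv"
    )
    mapping <- export_mapping(
      uniques, matches, file.path(out_dir, "portal_mapping.tsv")
    )
    write_atomic(names_table(named), "names.tsv")
    write_atomic(consistency$by_composition, "symmetry_report.tsv")
    stats_path <- file.path(out_dir, "stats.json")
    tmp <- paste0(stats_path, ".tmp")
    jsonlite::write_json(stats, tmp,
      auto_unbox = TRUE, pretty = TRUE,
      digits = 10, dataframe = "rows", na = "null"
    )
    file.rename(tmp, stats_path)
  } else {
    mapping <- export_mapping(uniques, matches, tempfile(fileext = ".tsv"))
  }
  if (!is.null(registry_path)) {
    save_registry(registry, registry_path)
  }

  invisible(list(
    uniques = named, relations = relations, matches = matches,
    mapping = mapping, symmetry = freq, consistency = consistency,
    stats = stats, registry = registry
  ))
}

#' Flat output table of unique assemblies
#' @param uniques The (named) `uniques` tibble.
#' @return A plain tibble ready for TSV export.
#' @export
uniques_table <- function(uniques) {
  tibble::tibble(
    accession = uniques$accession,
    md5 = uniques$md5,
    composition_string = uniques$composition_string,
    n_members = uniques$n_members,
    members = vapply(uniques$members, function(m) {
      paste(paste0(m$entry_id, "_", m$assembly_id), collapse = "|")
    }, character(1)),
    protein_only = uniques$protein_only,
    nucleic_only = uniques$nucleic_only,
    quaternary = uniques$quaternary,
    all_mapped = uniques$all_mapped,
    any_mapped = uniques$any_mapped
  )
}

names_table <- function(named) {
  tibble::tibble(
    accession = named$accession,
    name = named$name,
    category = named$category,
    evidence = vapply(
      named$evidence, function(e) paste(e, collapse = "|"), character(1)
    )
  )
}

#' Incremental update against an existing registry
#'
#' Convenience wrapper around [run_pipeline()] making the persistence
#' contract explicit: compositions seen in earlier runs keep their
#' accessions, only novel compositions mint new ones, and removing
#' entries from the snapshot never deletes an assignment.
#'
#' @inheritParams run_pipeline
#' @return See [run_pipeline()].
#' @export
incremental_update <- function(snapshot, registry_path,
                               portal_catalog = NULL, curated = NULL,
                               out_dir = NULL,
                               config = default_naming_config()) {
  if (!file.exists(registry_path)) {
    stop("incremental update requires an existing registry: ", registry_path,
      call. = FALSE
    )
  }
  run_pipeline(snapshot,
    portal_catalog = portal_catalog, curated = curated,
    registry_path = registry_path, out_dir = out_dir, config = config
  )
}
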