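# Point-group symmetry analysis over unique compositions. Symmetry
# detection itself (e.g. AnAnaS run on coordinates) is an input: each
# assembly may carry a Schoenflies label in the snapshot's `symmetry`
# column. Labels are normalised to uppercase; "asymmetric" and "C1" are
# the same label. Missing labels are excluded, never treated as
# asymmetric.

#' Normalise a point-group label
#'
#' @param label Character vector of raw labels.
#' @return Uppercase Schoenflies strings; `asymmetric`/`C1` -> `"C1"`;
#'   NA stays NA.
#' @export
normalize_symmetry_label <- function(label) {
  out <- toupper(trimws(label))
  out[out %in% c("ASYMMETRIC", "C1")] <- "C1"
  out
}

symmetry_family <- function(label) {
  dplyr::case_when(
    is.na(label) ~ NA_character_,
    label == "C1" ~ "asymmetric",
    grepl("^C\\d+$", label) ~ "cyclic",
    grepl("^D\\d+$", label) ~ "dihedral",
    label == "T" ~ "tetrahedral",
    label == "O" ~ "octahedral",
    label == "I" ~ "icosahedral",
    TRUE ~ "other"
  )
}

#' Per-assembly symmetry labels of a snapshot
#'
#' One row per (entry, assembly) with its normalised label (the first
#' non-missing label among the assembly's component rows; the label is an
#' assembly-level property repeated per row in the flat file).
#'
#' @param snapshot An `assembly_snapshot` tibble.
#' @return A tibble: entry_id, assembly_id, symmetry.
#' @export
assembly_symmetry_labels <- function(snapshot) {
  tibble::as_tibble(snapshot) |>
    dplyr::group_by(.data$entry_id, .data$assembly_id) |>
    dplyr::summarise(
      symmetry = {
        lab <- .data$symmetry[!is.na(.data$symmetry)]
        if (length(lab) > 0) normalize_symmetry_label(lab[[1]]) else NA_character_
      },
      .groups = "drop"
    )
}

#' Frequency of point-group symmetries
#'
#' Histogram over the symmetry labels of labelled assemblies plus
#' family-level totals. Family fractions are reported among symmetric
#' assemblies (asymmetric/C1 excluded), the convention used when stating
#' that cyclic and dihedral groups dominate the archive.
#'
#' @param snapshot An `assembly_snapshot` tibble (assemblies without a
#'   label are skipped).
#' @return A list with `histogram` (label, family, n), `families`
#'   (family, n, fraction_symmetric), `n_labelled`, `n_symmetric`.
#' @export
symmetry_frequency <- function(snapshot) {
  labels <- assembly_symmetry_labels(snapshot)
  labels <- labels[!is.na(labels$symmetry), ]
  labels$family <- symmetry_family(labels$symmetry)
  if (any(labels$family == "other")) {
    warning(
      "unparseable point-group label(s) counted as 'other': ",
      paste(unique(labels$symmetry[labels$family == "other"]), collapse = ", "),
      call. = FALSE
    )
  }
  histogram <- labels |>
    dplyr::count(.data$symmetry, .data$family, name = "n") |>
    dplyr::arrange(dplyr::desc(.data$n), .data$symmetry)
  n_symmetric <- sum(labels$family != "asymmetric")
  families <- labels |>
    dplyr::count(.data$family, name = "n") |>
    dplyr::mutate(
      fraction_symmetric = ifelse(
        .data$family == "asymmetric" | n_symmetric == 0,
        NA_real_, .data$n / n_symmetric
      )
    ) |>
    dplyr::arrange(dplyr::desc(.data$n))
  list(
    histogram = histogram, families = families,
    n_labelled = nrow(labels), n_symmetric = n_symmetric
  )
}

#' Symmetry consistency across members of each unique composition
#'
#' A composition is assessed when at least two of its member assemblies
#' carry a symmetry label; it is consistent iff all non-missing labels
#' agree (after normalisation). Unlabelled members never change the
#' status. Totals are reported both by composition and by member
#' assembly.
#'
#' @param uniques The `uniques` tibble from [group_unique()].
#' @param snapshot The snapshot the groups came from (source of labels).
#' @return A list of class `consistency_report`: `by_composition`
#'   (md5, accession, n_members, n_labelled, labels, label_histogram,
#'   is_consistent), `n_assessed`, `n_inconsistent`,
#'   `fraction_inconsistent`, and the member-assembly countings
#'   `n_assemblies_assessed` / `n_assemblies_inconsistent`.
#' @export
consistency_by_composition <- function(uniques, snapshot) {
  labels <- assembly_symmetry_labels(snapshot)
  rows <- lapply(seq_len(nrow(uniques)), function(i) {
    members <- uniques$members[[i]]
    mem <- dplyr::left_join(members, labels, by = c("entry_id", "assembly_id"))
    lab <- mem$symmetry[!is.na(mem$symmetry)]
    tibble::tibble(
      md5 = uniques$md5[[i]],
      accession = uniques$accession[[i]],
      n_members = nrow(members),
      n_labelled = length(lab),
      labels = paste(lab, collapse = "|"),
      label_histogram = paste(
        names(table(lab)), as.integer(table(lab)),
        sep = ":", collapse = "|"
      ),
      is_consistent = if (length(lab) >= 2) length(unique(lab)) == 1 else NA
    )
  })
  by_composition <- dplyr::bind_rows(rows)
  if (nrow(by_composition) == 0) {
    by_composition <- tibble::tibble(
      md5 = character(), accession = character(), n_members = integer(),
      n_labelled = integer(), labels = character(),
      label_histogram = character(), is_consistent = logical()
    )
  }
  assessed <- by_composition[!is.na(by_composition$is_consistent), ]
  n_assessed <- nrow(assessed)
  n_inconsistent <- sum(!assessed$is_consistent)
  structure(
    list(
      by_composition = by_composition,
      n_assessed = n_assessed,
      n_inconsistent = n_inconsistent,
      fraction_inconsistent = if (n_assessed > 0) {
        n_inconsistent / n_assessed
      } else {
        NA_real_
      },
      n_assemblies_assessed = sum(assessed$n_labelled),
      n_assemblies_inconsistent = sum(assessed$n_labelled[!assessed$is_consistent])
    ),
    class = "consistency_report"
  )
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(
    "symmetry consistency: ", x$n_inconsistent, " of ", x$n_assessed,
    " assessed compositions inconsistent",
    if (x$n_assessed > 0) {
      sprintf(" (%.1f%%)", 100 * x$fraction_inconsistent)
    } else {
      ""
    },
    "\n",
    sep = ""
  )
  invisible(x)
}
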