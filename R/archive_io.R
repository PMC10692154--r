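# Reading, validating and writing archive snapshots and the auxiliary
# inputs of the pipeline (Complex Portal catalogues, curated-name lists).
#
# A snapshot is a tidy component table: one row per polymer component of
# one assembly of one entry. Assemblies are identified by (entry_id,
# assembly_id); components within an assembly by entity_id.

#' Snapshot column schema
#'
#' Mandatory and optional columns of the archive-snapshot TSV. `symmetry`
#' (a point-group label per assembly, repeated on each of its component
#' rows) and `seq_length` (polymer sequence length, used only to tell
#' peptides from proteins) are optional.
#'
#' @return A list with character vectors `mandatory` and `optional`.
#' @export
snapshot_schema <- function() {
  list(
    mandatory = c(
      "entry_id", "assembly_id", "entity_id", "polymer_type", "uniprot",
      "rfam", "is_antibody", "entity_name", "uniprot_name", "go_cc",
      "taxonomy_id", "copies"
    ),
    optional = c("symmetry", "seq_length")
  )
}

#' Polymer types recognised in snapshots
#' @keywords internal
POLYMER_TYPES <- c("protein", "DNA", "RNA", "DNA/RNA")

snapshot_col_types <- function() {
  readr::cols(
    entry_id = readr::col_character(),
    assembly_id = readr::col_integer(),
    entity_id = readr::col_integer(),
    polymer_type = readr::col_character(),
    uniprot = readr::col_character(),
    rfam = readr::col_character(),
    is_antibody = readr::col_logical(),
    entity_name = readr::col_character(),
    uniprot_name = readr::col_character(),
    go_cc = readr::col_character(),
    taxonomy_id = readr::col_integer(),
    copies = readr::col_integer(),
    symmetry = readr::col_character(),
    seq_length = readr::col_integer()
  )
}

#' Build a snapshot component table
#'
#' Low-level constructor used by the fixture generator and tests. Fills in
#' optional columns, fixes column order and attaches the
#' `assembly_snapshot` class.
#'
#' @param rows A data frame with (a subset of) the snapshot columns.
#' @return A tibble of class `assembly_snapshot`.
#' @export
as_snapshot <- function(rows) {
  schema <- snapshot_schema()
  rows <- tibble::as_tibble(rows)
  missing <- setdiff(schema$mandatory, names(rows))
  if (length(missing) > 0) {
    stop("snapshot schema error: missing mandatory column(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  for (col in schema$optional) {
    if (!col %in% names(rows)) {
      rows[[col]] <- if (col == "seq_length") NA_integer_ else NA_character_
    }
  }
  rows <- rows[, c(schema$mandatory, schema$optional)]
  rows$entry_id <- as.character(rows$entry_id)
  rows$assembly_id <- as.integer(rows$assembly_id)
  rows$entity_id <- as.integer(rows$entity_id)
  rows$copies <- as.integer(rows$copies)
  rows$is_antibody <- as.logical(rows$is_antibody)
  rows$taxonomy_id <- as.integer(rows$taxonomy_id)
  rows$seq_length <- as.integer(rows$seq_length)
  class(rows) <- c("assembly_snapshot", class(tibble::tibble()))
  rows
}

#' Read an archive snapshot
#'
#' Reads the tab-separated snapshot format (UTF-8, fixed header; see
#' [snapshot_schema()]) into a tidy component table. Row order is
#' preserved. With `validate = TRUE` (the default) the snapshot is checked
#' against the field invariants and reading fails with a message listing
#' every violation.
#'
#' @param path Path to a snapshot TSV.
#' @param validate Reject snapshots with invariant violations?
#' @return A tibble of class `assembly_snapshot`, one row per polymer
#'   component of each assembly.
#' @export
read_snapshot <- function(path, validate = TRUE) {
  if (!file.exists(path)) {
    stop("snapshot file does not exist: ", path, call. = FALSE)
  }
  header <- names(suppressMessages(
    readr::read_tsv(path, n_max = 0, col_types = readr::cols(.default = "c"))
  ))
  missing <- setdiff(snapshot_schema()$mandatory, header)
  if (length(missing) > 0) {
    stop("snapshot schema error: missing mandatory column(s): ",
      paste(missing, collapse = ", "),
      call. = FALSE
    )
  }
  raw <- suppressMessages(readr::read_tsv(
    path,
    col_types = snapshot_col_types(), na = c(""), progress = FALSE
  ))
  snapshot <- as_snapshot(raw)
  if (validate) {
    report <- validate_snapshot(snapshot)
    if (nrow(report$errors) > 0) {
      stop(
        "snapshot validation failed with ", nrow(report$errors),
        " error(s):\n",
        paste(
          utils::head(
            paste0("  [", report$errors$locator, "] ", report$errors$rule),
            20
          ),
          collapse = "\n"
        ),
        call. = FALSE
      )
    }
  }
  snapshot
}

#' Write an archive snapshot
#'
#' Inverse of [read_snapshot()]: snapshots written here and read back
#' compare equal, and canonical-form files round-trip byte-identically.
#'
#' @param snapshot An `assembly_snapshot` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_snapshot <- function(snapshot, path) {
  readr::write_tsv(snapshot, path, na = "", progress = FALSE)
  invisible(path)
}

#' Validate an archive snapshot
#'
#' Checks every field invariant of the component table and returns a
#' report rather than failing: `errors` lists hard violations (a snapshot
#' with any is rejected by the downstream modules), `warnings` lists
#' recoverable oddities.
#'
#' @param snapshot An `assembly_snapshot` tibble (parsed, not yet trusted).
#' @return A list of class `validation_report` with tibbles `errors` and
#'   `warnings`, each with columns `locator` and `rule`.
#' @export
validate_snapshot <- function(snapshot) {
  loc <- paste0(
    "row ", seq_len(nrow(snapshot)), " (", snapshot$entry_id, "/",
    snapshot$assembly_id, "/", snapshot$entity_id, ")"
  )
  errors <- list()
  warnings <- list()
  flag <- function(bad, rule) {
    bad <- which(bad %in% TRUE)
    if (length(bad) > 0) tibble::tibble(locator = loc[bad], rule = rule)
  }

  errors$entry <- flag(
    !grepl("^[a-z0-9]{4}$", snapshot$entry_id),
    "entry_id must be a 4-character lowercase PDB code"
  )
  errors$assembly <- flag(
    is.na(snapshot$assembly_id) | snapshot$assembly_id < 1,
    "assembly_id must be a positive integer"
  )
  errors$entity <- flag(
    is.na(snapshot$entity_id) | snapshot$entity_id < 1,
    "entity_id must be a positive integer"
  )
  errors$type <- flag(
    !snapshot$polymer_type %in% POLYMER_TYPES,
    paste0("polymer_type must be one of ", paste(POLYMER_TYPES, collapse = ", "))
  )
  errors$copies <- flag(
    is.na(snapshot$copies) | snapshot$copies < 1,
    "copies must be >= 1"
  )
  errors$rfam_type <- flag(
    !is.na(snapshot$rfam) & !snapshot$polymer_type %in% c("RNA", "DNA/RNA"),
    "rfam_accession only permitted for RNA or DNA/RNA components"
  )
  errors$rfam_format <- flag(
    !is.na(snapshot$rfam) & !grepl("^RF\\d{5}$", snapshot$rfam),
    "rfam accession must match RF\\d{5}"
  )
  errors$uniprot_type <- flag(
    (!is.na(snapshot$uniprot) | !is.na(snapshot$uniprot_name)) &
      snapshot$polymer_type != "protein",
    "uniprot fields only permitted for protein components"
  )
  errors$antibody <- flag(
    snapshot$is_antibody %in% TRUE & snapshot$polymer_type != "protein",
    "is_antibody implies polymer_type = protein"
  )
  bad_go <- !is.na(snapshot$go_cc) &
    !vapply(strsplit(snapshot$go_cc, "|", fixed = TRUE), function(parts) {
      all(grepl("^GO:\\d{7}=.+$", parts))
    }, logical(1))
  errors$go <- flag(bad_go, "go_cc must be pipe-separated GO:NNNNNNN=name pairs")

  # one row per entity within an assembly
  key <- paste(snapshot$entry_id, snapshot$assembly_id, snapshot$entity_id)
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  errors$dup <- flag(dup, "duplicate (entry_id, assembly_id, entity_id) record")

  warnings$symmetry <- flag(
    !is.na(snapshot$symmetry) &
      !grepl("^([CcDd]\\d+|[TOI]|asymmetric)$", snapshot$symmetry),
    "unrecognised point-group label (will be counted as 'other')"
  )

  report <- list(
    errors = dplyr::bind_rows(errors) %||% tibble::tibble(
      locator = character(), rule = character()
    ),
    warnings = dplyr::bind_rows(warnings) %||% tibble::tibble(
      locator = character(), rule = character()
    )
  )
  if (nrow(report$errors) == 0) {
    report$errors <- tibble::tibble(locator = character(), rule = character())
  }
  if (nrow(report$warnings) == 0) {
    report$warnings <- tibble::tibble(locator = character(), rule = character())
  }
  structure(report, class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(
    "snapshot validation report: ", nrow(x$errors), " error(s), ",
    nrow(x$warnings), " warning(s)\n",
    sep = ""
  )
  if (nrow(x$errors) > 0) {
    cat(paste0("  E [", x$errors$locator, "] ", x$errors$rule, "\n"), sep = "")
  }
  if (nrow(x$warnings) > 0) {
    cat(paste0("  W [", x$warnings$locator, "] ", x$warnings$rule, "\n"), sep = "")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# Complex Portal catalogue

#' Read a Complex Portal catalogue
#'
#' Accepts either the package's three-column layout (`complex_ac`,
#' `recommended_name`, `participants`) or the public "complextab" dialect
#' (`#Complex ac`, `Recommended name`, `Identifiers (and stoichiometry) of
#' molecules in complex`; extra columns are ignored). Participants are
#' `accession(stoichiometry)` tokens separated by `|`. Participants whose
#' accession is clearly not a protein accession (CPX cross-references,
#' RNAcentral URS ids, ChEBI small molecules) are dropped with a warning;
#' the retained complex is flagged `partial_definition`.
#'
#' @param path Path to a catalogue TSV.
#' @return A tibble with columns `complex_ac`, `recommended_name`,
#'   `participants` (list of named integer vectors: accession ->
#'   stoichiometry) and `partial_definition`.
#' @export
read_portal_catalog <- function(path) {
  if (!file.exists(path)) {
    stop("portal catalogue does not exist: ", path, call. = FALSE)
  }
  raw <- suppressMessages(readr::read_tsv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    na = c(""), progress = FALSE
  ))
  pick <- function(simple, complextab) {
    if (simple %in% names(raw)) {
      raw[[simple]]
    } else if (complextab %in% names(raw)) {
      raw[[complextab]]
    } else {
      stop("portal catalogue is missing column '", simple, "'", call. = FALSE)
    }
  }
  ac <- pick("complex_ac", "#Complex ac")
  name <- pick("recommended_name", "Recommended name")
  tokens <- pick(
    "participants",
    "Identifiers (and stoichiometry) of molecules in complex"
  )

  parsed <- vector("list", length(ac))
  partial <- logical(length(ac))
  for (i in seq_along(ac)) {
    parts <- strsplit(tokens[[i]], "|", fixed = TRUE)[[1]]
    parts <- trimws(parts)
    m <- regmatches(parts, regexec("^([^()]+)\\((\\d+)\\)$", parts))
    bad <- vapply(m, length, integer(1)) == 0
    if (any(bad)) {
      stop(
        "portal catalogue parse error at line ", i + 1, ": malformed ",
        "participant token '", parts[which(bad)[1]], "'",
        call. = FALSE
      )
    }
    acc <- vapply(m, `[`, character(1), 2)
    stoich <- as.integer(vapply(m, `[`, character(1), 3))
    if (any(stoich < 1)) {
      stop(
        "portal catalogue parse error at line ", i + 1,
        ": participant stoichiometry must be >= 1",
        call. = FALSE
      )
    }
    non_protein <- grepl("^(CPX-|URS|CHEBI:|EBI-)", acc) | grepl("[:_]", acc)
    if (any(non_protein)) {
      warning(
        "dropping non-protein participant(s) of ", ac[[i]], ": ",
        paste(acc[non_protein], collapse = ", "),
        call. = FALSE
      )
      partial[i] <- TRUE
      acc <- acc[!non_protein]
      stoich <- stoich[!non_protein]
    }
    participants <- tapply(stoich, acc, sum)
    participants <- stats::setNames(as.integer(participants), names(participants))
    parsed[[i]] <- participants[order(names(participants), method = "radix")]
  }
  keep <- vapply(parsed, length, integer(1)) > 0
  if (any(!keep)) {
    warning(
      "dropping portal complex(es) with no protein participants: ",
      paste(ac[!keep], collapse = ", "),
      call. = FALSE
    )
  }
  tibble::tibble(
    complex_ac = ac[keep],
    recommended_name = name[keep],
    participants = parsed[keep],
    partial_definition = partial[keep]
  )
}

#' Write a Complex Portal catalogue in the package's three-column layout
#'
#' @param catalog A catalogue tibble as returned by [read_portal_catalog()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_portal_catalog <- function(catalog, path) {
  tokens <- vapply(catalog$participants, function(p) {
    paste0(names(p), "(", p, ")", collapse = "|")
  }, character(1))
  readr::write_tsv(
    tibble::tibble(
      complex_ac = catalog$complex_ac,
      recommended_name = catalog$recommended_name,
      participants = tokens
    ),
    path,
    na = "", progress = FALSE
  )
  invisible(path)
}

# ---------------------------------------------------------------------------
# Curated names

#' Read a curated-name list
#'
#' Two-column TSV mapping a composition md5 digest to a curator-approved
#' assembly name.
#'
#' @param path Path to the TSV.
#' @return A named character vector (md5 -> name).
#' @export
read_curated_names <- function(path) {
  if (!file.exists(path)) {
    stop("curated-name list does not exist: ", path, call. = FALSE)
  }
  raw <- suppressMessages(readr::read_tsv(
    path,
    col_types = readr::cols(
      md5 = readr::col_character(), name = readr::col_character()
    ),
    na = c(""), progress = FALSE
  ))
  if (!all(c("md5", "name") %in% names(raw))) {
    stop("curated-name list must have columns 'md5' and 'name'", call. = FALSE)
  }
  if (any(is.na(raw$name) | raw$name == "")) {
    stop("curated-name list contains empty names", call. = FALSE)
  }
  if (any(!grepl("^[0-9a-f]{32}$", raw$md5))) {
    stop("curated-name list contains malformed md5 keys", call. = FALSE)
  }
  if (anyDuplicated(raw$md5)) {
    stop("curated-name list contains duplicate md5 keys", call. = FALSE)
  }
  stats::setNames(raw$name, raw$md5)
}

#' Write a curated-name list
#'
#' @param curated A named character vector (md5 -> name).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curated_names <- function(curated, path) {
  readr::write_tsv(
    tibble::tibble(md5 = names(curated), name = unname(curated)),
    path,
    na = "", progress = FALSE
  )
  invisible(path)
}

# ---------------------------------------------------------------------------
# GO annotation helpers

#' Parse a `go_cc` cell into ids and names
#'
#' @param x A `go_cc` string (`GO:NNNNNNN=name` pairs joined by `|`) or NA.
#' @return A named character vector: GO id -> term name (empty if NA).
#' @export
parse_go_cc <- function(x) {
  if (is.na(x) || x == "") {
    return(stats::setNames(character(0), character(0)))
  }
  parts <- strsplit(x, "|", fixed = TRUE)[[1]]
  ids <- sub("=.*$", "", parts)
  names <- sub("^[^=]*=", "", parts)
  stats::setNames(names, ids)
}

format_go_cc <- function(ids, names) {
  if (length(ids) == 0) {
    return(NA_character_)
  }
  paste0(ids, "=", names, collapse = "|")
}
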