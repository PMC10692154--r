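# Persistent identifier registry: an append-only map from composition md5
# digests to PDB-CPX accessions. Once assigned, a pairing never changes.

#' Create an empty identifier registry
#'
#' @param next_serial First serial to mint (accessions are
#'   `PDB-CPX-<serial>`, unpadded decimal, strictly increasing).
#' @return A `cpx_registry` object.
#' @export
new_registry <- function(next_serial = 100001L) {
  next_serial <- as.integer(next_serial)
  if (is.na(next_serial) || next_serial < 1) {
    stop("next_serial must be a positive integer", call. = FALSE)
  }
  structure(
    list(assignments = character(0), next_serial = next_serial),
    class = "cpx_registry"
  )
}

#' @export
print.cpx_registry <- function(x, ...) {
  cat(
    "identifier registry: ", length(x$assignments), " assignment(s), ",
    "next serial ", x$next_serial, "\n",
    sep = ""
  )
  invisible(x)
}

#' Assign (or look up) the persistent accession of a composition
#'
#' Idempotent: a known md5 returns its stored accession and leaves the
#' registry untouched; an unseen md5 mints `PDB-CPX-<next_serial>` and
#' advances the serial. Assignments are never changed or removed.
#'
#' @param registry A `cpx_registry`.
#' @param md5 A 32-character composition digest.
#' @return A list with `accession` and the (possibly updated) `registry`.
#' @export
assign_identifier <- function(registry, md5) {
  stopifnot(inherits(registry, "cpx_registry"))
  if (!grepl("^[0-9a-f]{32}$", md5)) {
    stop("md5 must be a 32-character lowercase hex digest", call. = FALSE)
  }
  existing <- registry$assignments[md5]
  if (!is.na(existing)) {
    return(list(accession = unname(existing), registry = registry))
  }
  accession <- paste0("PDB-CPX-", registry$next_serial)
  registry$assignments[md5] <- accession
  registry$next_serial <- registry$next_serial + 1L
  list(accession = accession, registry = registry)
}

#' Vectorised identifier assignment
#'
#' Assigns accessions for the digests in the order given (callers that
#' need order-independence, like [group_unique()], sort their digests
#' canonically first).
#'
#' @param registry A `cpx_registry`.
#' @param md5s Character vector of digests (duplicates allowed).
#' @return A list with `accessions` (parallel to `md5s`) and the updated
#'   `registry`.
#' @export
assign_identifiers <- function(registry, md5s) {
  accessions <- character(length(md5s))
  for (i in seq_along(md5s)) {
    res <- assign_identifier(registry, md5s[[i]])
    accessions[[i]] <- res$accession
    registry <- res$registry
  }
  list(accessions = accessions, registry = registry)
}

#' Load an identifier registry
#'
#' Reads the two-column TSV (md5, accession) plus its JSON sidecar holding
#' the next serial. The file is checked for integrity: duplicate digests
#' or duplicate accessions abort the load (no assignment may ever be
#' rewritten).
#'
#' @param path Registry TSV path.
#' @return A `cpx_registry`.
#' @export
load_registry <- function(path) {
  if (!file.exists(path)) {
    stop("registry file does not exist: ", path, call. = FALSE)
  }
  raw <- suppressMessages(readr::read_tsv(
    path,
    col_types = readr::cols(
      md5 = readr::col_character(), accession = readr::col_character()
    ),
    na = c(""), progress = FALSE
  ))
  if (anyDuplicated(raw$md5) || anyDuplicated(raw$accession)) {
    stop(
      "registry integrity error: duplicate md5 or accession in ", path,
      call. = FALSE
    )
  }
  if (any(!grepl("^PDB-CPX-\\d+$", raw$accession))) {
    stop("registry integrity error: malformed accession in ", path, call. = FALSE)
  }
  serials <- as.integer(sub("^PDB-CPX-", "", raw$accession))
  sidecar <- paste0(path, ".meta.json")
  next_serial <- if (file.exists(sidecar)) {
    as.integer(jsonlite::read_json(sidecar)$next_serial)
  } else if (nrow(raw) > 0) {
    max(serials) + 1L
  } else {
    100001L
  }
  if (nrow(raw) > 0 && next_serial <= max(serials)) {
    stop("registry integrity error: next_serial overlaps existing accessions",
      call. = FALSE
    )
  }
  registry <- new_registry(next_serial)
  registry$assignments <- stats::setNames(raw$accession, raw$md5)
  registry
}

#' Save an identifier registry
#'
#' Writes assignments in serial order plus the JSON sidecar. The on-disk
#' file is append-only: if `path` already exists, every existing pair must
#' still be present unchanged in the registry being saved, otherwise the
#' save aborts with an integrity error.
#'
#' @param registry A `cpx_registry`.
#' @param path Registry TSV path.
#' @return `path`, invisibly.
#' @export
save_registry <- function(registry, path) {
  stopifnot(inherits(registry, "cpx_registry"))
  if (file.exists(path)) {
    old <- load_registry(path)
    current <- registry$assignments[names(old$assignments)]
    if (any(is.na(current)) || any(current != old$assignments)) {
      stop(
        "registry integrity error: refusing to drop or rewrite existing ",
        "assignments in ", path,
        call. = FALSE
      )
    }
  }
  serials <- as.integer(sub("^PDB-CPX-", "", unname(registry$assignments)))
  ord <- order(serials)
  tmp <- paste0(path, ".tmp")
  readr::write_tsv(
    tibble::tibble(
      md5 = names(registry$assignments)[ord],
      accession = unname(registry$assignments)[ord]
    ),
    tmp,
    na = "", progress = FALSE
  )
  file.rename(tmp, path)
  jsonlite::write_json(
    list(next_serial = registry$next_serial),
    paste0(path, ".meta.json"),
    auto_unbox = TRUE
  )
  invisible(path)
}
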