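# Sub-assembly / super-assembly detection among unique compositions.
#
# A composition a is a sub-assembly of b when a's component identities are
# a strict subset of b's. In strict mode (the default) every shared
# identity must have equal stoichiometry in a and b; in relaxed mode a's
# stoichiometry may be lower. Unmapped components compare by their full
# identity token, so they only ever match themselves.

#' Stoichiometry vector of a unique assembly
#'
#' @param x A row of the `uniques` tibble (as a list), a merged component
#'   tibble, or an already-named integer vector.
#' @return Named integer vector: component identity -> copies.
#' @export
as_stoichiometry <- function(x) {
  if (is.numeric(x) && !is.null(names(x))) {
    return(stats::setNames(as.integer(x), names(x)))
  }
  comp <- if (is.data.frame(x)) x else x$components[[1]]
  stats::setNames(as.integer(comp$copies), comp$identity)
}

#' Is `a` a sub-assembly of `b`?
#'
#' @param a,b Unique assemblies (rows of the `uniques` tibble, merged
#'   component tables, or named stoichiometry vectors).
#' @param mode `"strict"` (shared identities need equal stoichiometry) or
#'   `"relaxed"` (stoichiometry of `a` may be lower).
#' @return TRUE iff `a`'s identity set is a strict subset of `b`'s and the
#'   stoichiometry rule of `mode` holds on every shared identity.
#' @export
is_subassembly <- function(a, b, mode = c("strict", "relaxed")) {
  mode <- match.arg(mode)
  sa <- as_stoichiometry(a)
  sb <- as_stoichiometry(b)
  ids_a <- names(sa)
  ids_b <- names(sb)
  if (!all(ids_a %in% ids_b) || length(ids_a) >= length(ids_b)) {
    return(FALSE)
  }
  shared <- sb[ids_a]
  if (mode == "strict") all(sa == shared) else all(sa <= shared)
}

#' Build the sub-/super-assembly relation graph
#'
#' Evaluates [is_subassembly()] over all ordered pairs of unique
#' compositions and returns the direct relation edges. Storage is the full
#' relation (not its transitive reduction); [transitive_reduction()] gives
#' the reduced view.
#'
#' @param uniques The `uniques` tibble from [group_unique()].
#' @param mode Passed to [is_subassembly()].
#' @return A tibble of class `relation_graph`: `sub_accession`,
#'   `super_accession`, `sub_md5`, `super_md5`, `added_components`
#'   (labels present in the super- but not the sub-assembly, `|`-joined).
#' @export
build_relation_graph <- function(uniques, mode = c("strict", "relaxed")) {
  mode <- match.arg(mode)
  n <- nrow(uniques)
  stoich <- lapply(seq_len(n), function(i) as_stoichiometry(as.list(uniques[i, ])))
  edges <- list()
  k <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && is_subassembly(stoich[[i]], stoich[[j]], mode)) {
        added <- setdiff(uniques$labels[[j]], uniques$labels[[i]])
        k <- k + 1
        edges[[k]] <- tibble::tibble(
          sub_accession = uniques$accession[[i]],
          super_accession = uniques$accession[[j]],
          sub_md5 = uniques$md5[[i]],
          super_md5 = uniques$md5[[j]],
          added_components = paste(sort(added), collapse = "|")
        )
      }
    }
  }
  graph <- if (k > 0) {
    dplyr::arrange(dplyr::bind_rows(edges), .data$sub_md5, .data$super_md5)
  } else {
    tibble::tibble(
      sub_accession = character(), super_accession = character(),
      sub_md5 = character(), super_md5 = character(),
      added_components = character()
    )
  }
  class(graph) <- c("relation_graph", class(graph))
  graph
}

#' Per-composition relation counts
#'
#' @param graph A `relation_graph`.
#' @param uniques The `uniques` tibble the graph was built from.
#' @return A tibble: `md5`, `accession`, `n_super_assemblies` (number of
#'   compositions containing this one), `n_sub_assemblies` (number of
#'   compositions contained in this one), and logical `is_sub`/`is_super`.
#' @export
relation_counts <- function(graph, uniques) {
  n_super <- table(factor(graph$sub_md5, levels = uniques$md5))
  n_sub <- table(factor(graph$super_md5, levels = uniques$md5))
  tibble::tibble(
    md5 = uniques$md5,
    accession = uniques$accession,
    n_super_assemblies = as.integer(n_super),
    n_sub_assemblies = as.integer(n_sub),
    is_sub = as.integer(n_super) > 0,
    is_super = as.integer(n_sub) > 0
  )
}

#' Transitive reduction of a relation graph
#'
#' Removes every edge implied by two shorter ones, leaving only covering
#' relations. A view over the stored graph, not a replacement for it.
#'
#' @param graph A `relation_graph`.
#' @return The reduced `relation_graph`.
#' @export
transitive_reduction <- function(graph) {
  if (nrow(graph) == 0) {
    return(graph)
  }
  edge_set <- paste(graph$sub_md5, graph$super_md5)
  redundant <- logical(nrow(graph))
  for (e in seq_len(nrow(graph))) {
    a <- graph$sub_md5[[e]]
    b <- graph$super_md5[[e]]
    mids <- graph$super_md5[graph$sub_md5 == a & graph$super_md5 != b]
    if (any(paste(mids, b) %in% edge_set)) {
      redundant[e] <- TRUE
    }
  }
  out <- graph[!redundant, ]
  class(out) <- class(graph)
  out
}
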