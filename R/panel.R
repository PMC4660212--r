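## Testbed (cell-line panel) selection as maximum coverage: pick a fixed
## number of lines so that as many genes as possible are expressed in at
## least one selected line. Greedy solver with an exact exhaustive oracle.

#' Number of genes covered by a panel of cell lines
#'
#' @param presence a `presence_matrix` or logical gene x line matrix
#'   (unresolved cells count as absent).
#' @param panel character vector of line identifiers.
#' @return count of genes present in at least one panel line.
#' @export
coverage <- function(presence, panel) {
  m <- presence_calls(presence, unresolved_as = FALSE)
  unknown <- setdiff(panel, colnames(m))
  if (length(unknown))
    stop("unknown cell lines: ", paste(unknown, collapse = ", "), call. = FALSE)
  if (length(panel) == 0) return(0L)
  sum(rowSums(m[, panel, drop = FALSE]) > 0)
}

new_panel_selection <- function(selected, presence_m, gains, solver) {
  covered <- if (length(selected))
    rownames(presence_m)[rowSums(presence_m[, selected, drop = FALSE]) > 0]
  else character()
  structure(list(selected = selected, covered = covered,
                 coverage = length(covered), marginal_gains = gains,
                 n_genes = nrow(presence_m), solver = solver),
            class = "panel_selection")
}

#' @export
print.panel_selection <- function(x, ...) {
  cat(sprintf("Panel of %d lines (%s solver): %d / %d genes covered\n",
              length(x$selected), x$solver, x$coverage, x$n_genes))
  cat("  lines:", paste(x$selected, collapse = ", "), "\n")
  if (length(x$marginal_gains))
    cat("  marginal gains:", paste(x$marginal_gains, collapse = ", "), "\n")
  invisible(x)
}

#' Greedy maximum-coverage panel selection
#'
#' Repeatedly adds the cell line covering the most genes not yet covered.
#' Ties are broken lexicographically by line identifier for reproducibility.
#' The classical guarantee applies: greedy coverage is at least
#' (1 - 1/e) of the optimum.
#'
#' @param presence a `presence_matrix` or logical gene x line matrix.
#' @param panel_size number of lines to select; if it exceeds the number of
#'   candidates, all lines are selected with a warning.
#' @return a `panel_selection` with the lines in selection order and the
#'   per-step marginal coverage gains (non-increasing).
#' @export
select_panel_greedy <- function(presence, panel_size) {
  m <- presence_calls(presence, unresolved_as = FALSE)
  if (panel_size < 1) stop("panel_size must be >= 1", call. = FALSE)
  if (panel_size > ncol(m)) {
    warning("panel_size exceeds number of candidate lines; selecting all")
    panel_size <- ncol(m)
  }
  lines <- colnames(m) %||% line_ids(ncol(m))
  colnames(m) <- lines
  m <- m[, order(lines), drop = FALSE]  # lexicographic tie-break via column order
  selected <- character()
  gains <- integer()
  uncovered <- rep(TRUE, nrow(m))
  for (step in seq_len(panel_size)) {
    gain <- colSums(m & uncovered)
    gain[selected] <- -1L
    best <- names(gain)[which.max(gain)]  # first max = lexicographically smallest
    selected <- c(selected, best)
    gains <- c(gains, as.integer(max(gain)))
    uncovered <- uncovered & !m[, best]
  }
  new_panel_selection(selected, m, gains, "greedy")
}

#' Exact maximum-coverage panel selection by exhaustive enumeration
#'
#' Enumerates all panels of the requested size and returns one with maximal
#' coverage; among ties, the lexicographically smallest line set. Intended
#' as an oracle for the greedy solver and for study-scale instances (19
#' candidate lines choose 11 is 75,582 subsets).
#'
#' @param presence a `presence_matrix` or logical gene x line matrix.
#' @param panel_size number of lines to select.
#' @param max_subsets refuse instances with more than this many candidate
#'   subsets (default 1e6).
#' @return a `panel_selection`.
#' @export
select_panel_exact <- function(presence, panel_size, max_subsets = 1e6) {
  m <- presence_calls(presence, unresolved_as = FALSE)
  if (panel_size < 1) stop("panel_size must be >= 1", call. = FALSE)
  if (panel_size > ncol(m)) {
    warning("panel_size exceeds number of candidate lines; selecting all")
    panel_size <- ncol(m)
  }
  lines <- colnames(m) %||% line_ids(ncol(m))
  colnames(m) <- lines
  m <- m[, order(lines), drop = FALSE]
  n_subsets <- choose(ncol(m), panel_size)
  if (n_subsets > max_subsets)
    stop(sprintf(paste("instance has %.3g candidate subsets (cap %.3g);",
                       "use select_panel_greedy()"), n_subsets, max_subsets),
         call. = FALSE)
  subsets <- utils::combn(ncol(m), panel_size)  # columns in lexicographic order
  ## coverage of every subset at once: (genes x lines) %*% (lines x subsets)
  indicator <- matrix(0, ncol(m), ncol(subsets))
  indicator[cbind(as.vector(subsets), rep(seq_len(ncol(subsets)), each = panel_size))] <- 1
  cov <- colSums((m %*% indicator) > 0)
  best <- which.max(cov)  # first max = lexicographically smallest subset
  selected <- colnames(m)[subsets[, best]]
  new_panel_selection(selected, m, integer(), "exact")
}
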