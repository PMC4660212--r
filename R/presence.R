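## Expression presence calling: NanoString-style counts with qPCR rescue of
## ambiguous probes, plus comparative 2^-ddCt relative expression.

#' Call gene presence from counts with qPCR rescue
#'
#' A probe is *ambiguous* when its counts fall below `count_threshold` in
#' every cell line; such probes are re-evaluated by qPCR and a cell is called
#' present when Ct < `ct_threshold` cycles. Unambiguous probes are called
#' per line by the count threshold alone. Ambiguous cells lacking a qPCR
#' record are flagged unresolved (`NA`), never silently absent.
#'
#' @param counts non-negative gene x line count matrix with unique dimnames.
#' @param qpcr data.frame with columns gene, cell_line, Ct, undetected (a
#'   record with `undetected = TRUE` or missing Ct counts as not expressed).
#'   May be empty or NULL when no probe is ambiguous.
#' @param count_threshold counts at or above which a cell is present
#'   (default 1000).
#' @param ct_threshold Ct strictly below which a qPCR cell is present
#'   (default 35 cycles).
#' @param probe_map optional named list expanding a probe to the gene family
#'   it measures (probe name -> character vector of genes); rows are
#'   duplicated for each member. Default: probe = gene.
#' @return a `presence_matrix`: logical gene x line matrix (`NA` =
#'   unresolved) with a per-cell provenance attribute taking values
#'   "count_call", "qpcr_call" or "unresolved".
#' @export
call_presence <- function(counts, qpcr = NULL, count_threshold = 1000,
                          ct_threshold = 35, probe_map = NULL) {
  if (!is.matrix(counts) || !is.numeric(counts) || length(counts) == 0)
    stop("counts must be a non-empty numeric matrix", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene rownames and cell-line colnames", call. = FALSE)
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    stop("gene and cell-line identifiers must be unique", call. = FALSE)
  if (!is.null(qpcr) && nrow(qpcr)) {
    unknown <- setdiff(unique(qpcr$gene), rownames(counts))
    if (length(unknown))
      stop("qPCR records for genes not in the count matrix: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }

  ambiguous <- rowSums(counts >= count_threshold) == 0
  present <- counts >= count_threshold
  provenance <- matrix("count_call", nrow(counts), ncol(counts),
                       dimnames = dimnames(counts))
  for (g in rownames(counts)[ambiguous]) {
    for (line in colnames(counts)) {
      rec <- if (!is.null(qpcr) && nrow(qpcr))
        qpcr[qpcr$gene == g & qpcr$cell_line == line, , drop = FALSE]
      else qpcr
      if (is.null(rec) || nrow(rec) == 0) {
        present[g, line] <- NA
        provenance[g, line] <- "unresolved"
      } else {
        rec <- rec[1, ]
        detected <- !isTRUE(rec$undetected) && is.finite(rec$Ct)
        present[g, line] <- detected && rec$Ct < ct_threshold
        provenance[g, line] <- "qpcr_call"
      }
    }
  }
  as_presence_matrix(present, provenance = provenance, probe_map = probe_map)
}

#' Construct a presence matrix
#'
#' @param present logical gene x line matrix (NA = unresolved).
#' @param provenance optional character matrix of per-cell call provenance.
#' @param probe_map optional probe -> gene-family expansion applied to rows.
#' @return an object of class `presence_matrix`.
#' @export
as_presence_matrix <- function(present, provenance = NULL, probe_map = NULL) {
  stopifnot(is.matrix(present), is.logical(present))
  if (is.null(provenance))
    provenance <- matrix(ifelse(is.na(present), "unresolved", "count_call"),
                         nrow(present), ncol(present), dimnames = dimnames(present))
  if (!is.null(probe_map)) {
    expansion <- lapply(rownames(present), function(p) probe_map[[p]] %||% p)
    idx <- rep(seq_len(nrow(present)), lengths(expansion))
    present <- present[idx, , drop = FALSE]
    provenance <- provenance[idx, , drop = FALSE]
    rownames(present) <- rownames(provenance) <- unlist(expansion)
  }
  structure(list(present = present, provenance = provenance),
            class = "presence_matrix")
}

#' Extract the logical call matrix from a presence object
#'
#' @param x a `presence_matrix` (a plain logical matrix passes through).
#' @param unresolved_as value substituted for unresolved (`NA`) cells; use
#'   `NA` to keep them.
#' @return a logical gene x line matrix.
#' @export
presence_calls <- function(x, unresolved_as = NA) {
  m <- if (inherits(x, "presence_matrix")) x$present else x
  stopifnot(is.matrix(m), is.logical(m))
  if (!is.na(unresolved_as)) m[is.na(m)] <- unresolved_as
  m
}

#' @export
print.presence_matrix <- function(x, ...) {
  m <- x$present
  cat(sprintf("Presence calls: %d genes x %d cell lines\n", nrow(m), ncol(m)))
  cat(sprintf("  present %d | absent %d | unresolved %d\n",
              sum(m, na.rm = TRUE), sum(!m, na.rm = TRUE), sum(is.na(m))))
  tab <- table(x$provenance)
  cat("  provenance:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Relative expression by the comparative 2^-ddCt method
#'
#' Computes `2^-[(Ct_tgt,treated - Ct_ref,treated) - (Ct_tgt,control -
#' Ct_ref,control)]`, the fold change of the target gene in the treated
#' sample relative to the control sample, each normalized to a reference
#' gene measured in the same sample. Vectorized over its arguments.
#'
#' @param ct_target_treated,ct_reference_treated Ct values (cycles) in the
#'   treated sample.
#' @param ct_target_control,ct_reference_control Ct values in the control.
#' @return dimensionless fold change(s).
#' @export
relative_expression <- function(ct_target_treated, ct_reference_treated,
                                ct_target_control, ct_reference_control) {
  cts <- cbind(ct_target_treated, ct_reference_treated,
               ct_target_control, ct_reference_control)
  if (any(!is.finite(cts)))
    stop("all Ct values must be finite", call. = FALSE)
  ddct <- (ct_target_treated - ct_reference_treated) -
    (ct_target_control - ct_reference_control)
  2^(-ddct)
}

#' Summarize panel coverage of a presence matrix
#'
#' @param presence a `presence_matrix` or logical matrix; unresolved cells
#'   count as absent.
#' @param k report the fraction of genes present in more than `k` lines
#'   (default 2).
#' @return list with `line_counts` (per-gene number of expressing lines),
#'   `n_lines`, `fraction_in_all` and `fraction_in_more_than_k`.
#' @export
coverage_summary <- function(presence, k = 2) {
  m <- presence_calls(presence, unresolved_as = FALSE)
  if (length(m) == 0) stop("presence matrix is empty", call. = FALSE)
  line_counts <- rowSums(m)
  list(line_counts = line_counts,
       n_lines = ncol(m),
       fraction_in_all = mean(line_counts == ncol(m)),
       fraction_in_more_than_k = mean(line_counts > k),
       k = k)
}
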