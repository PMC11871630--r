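#' Build the order matching-statistics matrix
#'
#' Stacks the per-genome MS vectors of one pivot contig into a matrix and
#' sorts every column independently in descending order. Row `i` of the
#' result holds the i-th largest match length at each pivot position; the
#' originating genome is discarded. Each row of the sorted matrix again
#' satisfies the sawtooth property, so MEM extraction applies row-wise
#' ("order-MEMs"): containment of a k-mer in an order-i MEM certifies
#' presence in at least i non-pivot genomes.
#'
#' @param ms_rows Matrix with one row per non-pivot genome and one column
#'   per pivot position, or a list of equal-length MS vectors.
#' @return Integer matrix of the same shape with descending columns.
#' @export
build_order_matrix <- function(ms_rows) {
  if (is.list(ms_rows)) {
    lens <- lengths(ms_rows)
    if (length(unique(lens)) > 1L) {
      stop("all MS rows must have the same length (got ",
           paste(unique(lens), collapse = ", "), ")")
    }
    ms_rows <- do.call(rbind, ms_rows)
  }
  stopifnot(is.matrix(ms_rows))
  storage.mode(ms_rows) <- "integer"
  if (nrow(ms_rows) == 1L) return(ms_rows)
  om <- apply(ms_rows, 2L, sort.int, decreasing = TRUE, method = "radix")
  dimnames(om) <- NULL
  om
}

#' Extract order-overlap records from an order matrix
#'
#' Applies [ms_to_mems()] and [mems_to_overlaps()] to every row of the
#' order matrix, labelling records with the row's order (1 = shallowest).
#'
#' @param om Order matrix from [build_order_matrix()].
#' @param contig Pivot contig name for the records.
#' @return `data.frame` with columns `contig`, `start`, `end`, `label`
#'   (order), `is_gap`, sorted by (contig, start, end, label).
#' @export
extract_order_overlaps <- function(om, contig = "chr1") {
  stopifnot(is.matrix(om))
  recs <- lapply(seq_len(nrow(om)), function(i) {
    ms <- om[i, ]
    ov <- mems_to_overlaps(ms_to_mems(ms, contig), ms, contig)
    if (nrow(ov)) ov$label <- i
    else ov$label <- integer(0)
    ov
  })
  out <- do.call(rbind, recs)
  out <- out[order(out$contig, out$start, out$end, out$label), , drop = FALSE]
  rownames(out) <- NULL
  out[c("contig", "start", "end", "label", "is_gap")]
}

#' Conservation-count thresholds for quantile sampling
#'
#' For a pangenome of `t` genomes (pivot included) and a set of quantiles,
#' the retained conservation counts are `floor(q * t)`, de-duplicated and
#' ascending. A count threshold `c` maps to order row `c - 1` of the order
#' matrix (the pivot itself contributes the `+1`). With deciles and
#' `t = 89` this yields 8, 17, 26, ..., 89. Thresholds that floor to 0 are
#' dropped with a warning.
#'
#' @param t Total number of genomes including the pivot.
#' @param quantiles Fractions in `(0, 1]`; deciles by default.
#' @return Integer vector of strictly increasing conservation counts.
#' @export
quantile_thresholds <- function(t, quantiles = seq(0.1, 1, by = 0.1)) {
  if (t < 2L) stop("t must be at least 2")
  if (any(quantiles <= 0) || any(quantiles > 1)) {
    stop("quantiles must lie in (0, 1]")
  }
  th <- as.integer(floor(quantiles * t))
  if (any(th == 0L)) {
    warning("dropping quantile(s) ",
            paste(quantiles[th == 0L], collapse = ", "),
            ": threshold floors to 0 for t = ", t)
    th <- th[th != 0L]
  }
  sort(unique(th))
}

#' Quantile-sampling scheme
#'
#' @inheritParams quantile_thresholds
#' @return List of class `panmem_quantile_scheme` with fields `t`,
#'   `quantiles`, `thresholds`.
#' @export
quantile_scheme <- function(t, quantiles = seq(0.1, 1, by = 0.1)) {
  structure(list(t = as.integer(t), quantiles = quantiles,
                 thresholds = quantile_thresholds(t, quantiles)),
            class = "panmem_quantile_scheme")
}

#' Subsample order-overlap records to quantile thresholds
#'
#' Keeps only records whose order equals a retained row
#' (`threshold - 1`, including that row's gap records) and relabels each
#' with the conservation count it certifies (the threshold itself).
#' Unsampled rows are discarded; queries on the result floor exact
#' conservation counts to the retained threshold set. Threshold 1 (pivot
#' only) needs no order row: it is the query-time default.
#'
#' @param records Order-overlap `data.frame` (labels are orders).
#' @param scheme A `panmem_quantile_scheme`.
#' @return Records restricted to sampled rows, labels = thresholds.
#' @export
apply_quantile_sampling <- function(records, scheme) {
  stopifnot(inherits(scheme, "panmem_quantile_scheme"))
  orders <- scheme$thresholds - 1L
  orders <- orders[orders >= 1L]
  out <- records[records$label %in% orders, , drop = FALSE]
  out$label <- out$label + 1L
  rownames(out) <- NULL
  out
}

#' Drop long overlap records to shrink an index
#'
#' A k-mer marks itself absent only by spanning an overlap record with
#' overhang on both sides, which requires the record to be no longer than
#' `k - 2`. Discarding non-gap records longer than `l` therefore leaves
#' every query with `k <= l + 2` unchanged. Gap records are always kept
#' (any intersecting k-mer is absent regardless of k).
#'
#' @param records Overlap `data.frame`.
#' @param l Maximum retained non-gap record length (`end - start`);
#'   `l >= 0`, `Inf` for no filtering.
#' @return Filtered records.
#' @export
apply_length_filter <- function(records, l) {
  if (length(l) != 1L || is.na(l) || l < 0) stop("l must be a single value >= 0")
  keep <- records$is_gap | (records$end - records$start) <= l
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}
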