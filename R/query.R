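resolve_index <- function(index) {
  if (inherits(index, "panmem_index")) return(index)
  if (is.character(index) && length(index) == 1L) return(open_index(index))
  stop("index must be a panmem_index or a file path")
}

# Common query-argument validation. Returns the k-mer start positions
# (0-based pivot coordinates) enumerated by the query: x in
# [region$start, region$end - k], i.e. only k-mers fully inside the region.
check_query_args <- function(meta, region, k) {
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("k must be a positive integer")
  validate_region(region, meta$contig_lengths)
  if (region$end - region$start < k) {
    stop("k = ", k, " exceeds region length ", region$end - region$start)
  }
  if (!is.na(meta$filter_l) && k > meta$filter_l + 2) {
    stop("index was length-filtered at l = ", meta$filter_l,
         "; the maximum supported k is ", meta$filter_l + 2,
         " (requested k = ", k, ")")
  }
  region$start:(region$end - k)
}

# Absence vector for one label's records over the query's k-mer starts.
# A k-mer starting at x (0-based) is absent iff
#   - some non-gap record [s, e) satisfies x < s and x + k > e
#     (the k-mer spans the overlap with overhang on both sides), i.e.
#     x in [e - k + 1, s - 1]; or
#   - some gap record [s, e) intersects [x, x + k), i.e. x in [s - k + 1, e - 1].
# Ranges are accumulated with a difference array, so the cost is
# O(records + positions) per label.
absent_over_positions <- function(records, x0, xn, k) {
  L <- xn - x0 + 1
  if (nrow(records) == 0L) return(rep(FALSE, L))
  lo <- ifelse(records$is_gap, records$start - k + 1, records$end - k + 1)
  hi <- ifelse(records$is_gap, records$end - 1, records$start - 1)
  lo <- pmax(lo, x0)
  hi <- pmin(hi, xn)
  keep <- lo <= hi
  if (!any(keep)) return(rep(FALSE, L))
  add <- tabulate(lo[keep] - x0 + 1, nbins = L)
  rem <- tabulate(hi[keep] - x0 + 2, nbins = L + 1L)
  cumsum(add - rem[seq_len(L)]) > 0L
}

#' k-mer membership query
#'
#' For every genome of the pangenome and every k-mer fully inside the
#' region (starts `x` in `[start, end - k]`, pivot coordinates), reports
#' whether the pivot k-mer occurs in that genome. The answer is computed
#' from overlap records alone: a k-mer is absent from genome `n` iff it
#' spans one of that genome's overlap records with overhang on both sides,
#' or intersects one of its gap records; otherwise it is present. Runtime
#' is O(t * region length) given the fetched records. Valid for any `k`
#' from the same index.
#'
#' @param index A `panmem_index` or index file path (mode `"membership"`).
#' @param region A `panmem_region` on the pivot.
#' @param k K-mer length; for a length-filtered index `k <= l + 2`.
#' @return Logical matrix with one row per genome (row 1, the pivot, is
#'   all `TRUE`) and one column per k-mer start; row names are genome
#'   names, and the 0-based starts are in `attr(, "positions")`.
#' @export
membership_query <- function(index, region, k) {
  index <- resolve_index(index)
  meta <- index$meta
  if (meta$mode != "membership") {
    stop("membership_query requires a membership-mode index (got '",
         meta$mode, "')")
  }
  xs <- check_query_args(meta, region, k)
  rec <- read_region(index, region)
  out <- matrix(TRUE, nrow = meta$t, ncol = length(xs),
                dimnames = list(meta$genomes, NULL))
  for (n in 2:meta$t) {
    rn <- rec[rec$label == n, , drop = FALSE]
    out[n, ] <- !absent_over_positions(rn, xs[1L], xs[length(xs)], k)
  }
  attr(out, "positions") <- xs
  attr(out, "k") <- as.integer(k)
  out
}

#' k-mer conservation query
#'
#' For every k-mer fully inside the region, counts the number of genomes
#' (pivot included, so values are in `[1, t]`) containing it. Evaluated on
#' order-overlap records: the count at `x` is `1 + i*` where `i*` is the
#' deepest order whose records certify containment. Because order-i MEMs
#' nest (containment at order i+1 implies containment at order i), orders
#' are examined from the deepest down and evaluation stops as soon as all
#' positions are resolved; `early_stop = FALSE` forces the exhaustive
#' sweep over every order (identical answers, used for validation).
#'
#' @param index A `panmem_index` or path (mode `"conservation"`).
#' @inheritParams membership_query
#' @param early_stop Stop examining shallower orders once every position
#'   is resolved.
#' @return Integer vector of conservation counts, one per k-mer start;
#'   starts in `attr(, "positions")`.
#' @export
conservation_query <- function(index, region, k, early_stop = TRUE) {
  index <- resolve_index(index)
  meta <- index$meta
  if (meta$mode != "conservation") {
    stop("conservation_query requires a conservation-mode index (got '",
         meta$mode, "')")
  }
  xs <- check_query_args(meta, region, k)
  rec <- read_region(index, region)
  res <- rep(1L, length(xs))
  unresolved <- rep(TRUE, length(xs))
  for (i in seq(meta$t - 1L, 1L)) {
    if (early_stop && !any(unresolved)) break
    ri <- rec[rec$label == i, , drop = FALSE]
    present <- !absent_over_positions(ri, xs[1L], xs[length(xs)], k)
    hit <- unresolved & present
    res[hit] <- i + 1L
    unresolved <- unresolved & !present
  }
  attr(res, "positions") <- xs
  attr(res, "k") <- as.integer(k)
  res
}

#' Quantile (e.g. decile) conservation query
#'
#' On a quantile-sampled index, returns for each k-mer the largest
#' retained conservation-count threshold that its order row certifies —
#' the exact conservation count floored onto the threshold set. K-mers
#' certified by no retained row report 1 (the pivot itself).
#'
#' @param index A `panmem_index` or path (mode `"quantile"`).
#' @inheritParams membership_query
#' @return Integer vector of threshold values (plus 1 for uncertified
#'   positions); starts in `attr(, "positions")`.
#' @export
quantile_conservation_query <- function(index, region, k) {
  index <- resolve_index(index)
  meta <- index$meta
  if (meta$mode != "quantile") {
    stop("quantile_conservation_query requires a quantile-mode index (got '",
         meta$mode, "')")
  }
  xs <- check_query_args(meta, region, k)
  rec <- read_region(index, region)
  res <- rep(1L, length(xs))
  unresolved <- rep(TRUE, length(xs))
  for (th in sort(meta$thresholds[meta$thresholds > 1L], decreasing = TRUE)) {
    if (!any(unresolved)) break
    ri <- rec[rec$label == th, , drop = FALSE]
    present <- !absent_over_positions(ri, xs[1L], xs[length(xs)], k)
    hit <- unresolved & present
    res[hit] <- th
    unresolved <- unresolved & !present
  }
  attr(res, "positions") <- xs
  attr(res, "k") <- as.integer(k)
  res
}

# Test-only reference path: membership by direct MEM containment.
# A k-mer starting at x is present iff some MEM [s, e) satisfies
# s <= x and x + k <= e. Kept independent of the overlap-record route so
# the two can be checked against each other.
membership_by_mem_containment <- function(mems, region, k, contig_length) {
  x0 <- region$start
  xn <- region$end - k
  L <- xn - x0 + 1
  if (nrow(mems) == 0L) return(rep(FALSE, L))
  mm <- mems[mems$contig == region$contig, , drop = FALSE]
  lo <- pmax(mm$start, x0)
  hi <- pmin(mm$end - k, xn)
  keep <- lo <= hi
  if (!any(keep)) return(rep(FALSE, L))
  delta <- integer(L)
  add <- tabulate(lo[keep] - x0 + 1, nbins = L)
  rem <- tabulate(pmin(hi[keep] - x0 + 2, L + 1L), nbins = L + 1L)
  cumsum(add - rem[seq_len(L)]) > 0L
}

#' Bin conservation values for visualization
#'
#' Maps each conservation value to the proportion `value / t` of genomes
#' and aggregates positions into `bin_count` equal-width proportion bins
#' over consecutive windows, yielding the stacked-histogram data used to
#' plot conservation across a locus. Proportions within a window sum to 1.
#'
#' @param cons Integer conservation vector (from [conservation_query()] or
#'   [quantile_conservation_query()]).
#' @param t Total number of genomes including the pivot.
#' @param bin_count Number of equal-width proportion bins (`>= 1`).
#' @param window Window size in positions; defaults to one window spanning
#'   the whole vector.
#' @return Numeric matrix, one row per window and one column per bin
#'   (lowest proportion bin first); each row sums to 1. Window starts
#'   (0-based offsets into `cons`) are in `attr(, "window_start")`.
#' @export
bin_conservation <- function(cons, t, bin_count, window = length(cons)) {
  if (bin_count < 1L) stop("bin_count must be at least 1")
  if (window < 1L) stop("window must be at least 1")
  if (any(cons < 1L) || any(cons > t)) {
    stop("conservation values must lie in [1, t]")
  }
  bin <- pmin(ceiling(cons / t * bin_count), bin_count)
  win <- (seq_along(cons) - 1L) %/% window
  counts <- table(factor(win), factor(bin, levels = seq_len(bin_count)))
  prop <- counts / rowSums(counts)
  out <- matrix(as.numeric(prop), nrow = nrow(prop),
                dimnames = list(NULL, paste0("bin", seq_len(bin_count))))
  attr(out, "window_start") <- unique(win) * window
  out
}

#' Write a membership result as TSV
#'
#' One row per k-mer start (0-based pivot position), one column per
#' genome, values 0/1.
#'
#' @param result Matrix from [membership_query()].
#' @param path Output path or connection (`""` for stdout).
#' @return `path`, invisibly.
#' @export
write_membership_tsv <- function(result, path) {
  df <- data.frame(position = attr(result, "positions"),
                   t(result) + 0L, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a conservation vector as BedGraph
#'
#' Runs of equal values are merged into single BedGraph intervals
#' (contig, 0-based half-open start/end, value), ready for genome
#' browsers.
#'
#' @param cons Vector from [conservation_query()] (carries its positions).
#' @param contig Pivot contig of the query region.
#' @param path Output path or connection (`""` for stdout).
#' @return `path`, invisibly.
#' @export
write_conservation_bedgraph <- function(cons, contig, path) {
  xs <- attr(cons, "positions")
  r <- rle(as.integer(cons))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  lines <- paste(contig, xs[1L] + starts, xs[1L] + ends, r$values, sep = "\t")
  writeLines(lines, path)
  invisible(path)
}
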