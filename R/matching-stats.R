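#' Exact matching statistics of a pivot contig against a target genome
#'
#' `MS[j]` is the length of the longest suffix of the pivot prefix
#' `P[1..j]` occurring anywhere in the target text, where the target text
#' is the concatenation of every target contig and its reverse complement,
#' each terminated by a unique non-nucleotide separator so that matches can
#' never cross contig or strand boundaries. Computed exactly with a suffix
#' automaton over the target text (linear construction, one automaton step
#' per pivot character), so the whole computation is O(target + pivot)
#' up to the alphabet factor.
#'
#' Successive values satisfy the sawtooth property
#' `MS[j] - MS[j-1] <= 1`: extending the prefix by one character can grow
#' the longest matching suffix by at most one.
#'
#' @param pivot_seq Pivot contig sequence (single string over A/C/G/T/N),
#'   or a [genome()] whose first contig is used.
#' @param target Target [genome()].
#' @return Integer vector `MS[1..m]`, `m = nchar(pivot_seq)`.
#' @export
compute_matching_statistics <- function(pivot_seq, target) {
  if (inherits(pivot_seq, "panmem_genome")) {
    pivot_seq <- pivot_seq$sequences[[1L]]
  }
  stopifnot(is.character(pivot_seq), length(pivot_seq) == 1L)
  if (!nzchar(pivot_seq)) stop("pivot contig is empty")
  stopifnot(inherits(target, "panmem_genome"))
  seqs <- unname(target$sequences)
  if (sum(nchar(seqs)) == 0L) stop("target genome is empty")
  .ms_stream_cpp(pivot_seq, c(seqs, reverse_complement(seqs)))
}

is_sawtooth <- function(ms) {
  length(ms) > 0L && all(ms >= 0L) && ms[1L] <= 1L &&
    (length(ms) == 1L || all(diff(ms) <= 1L))
}

assert_sawtooth <- function(ms) {
  if (!is_sawtooth(ms)) {
    stop("matching-statistics vector violates the sawtooth property ",
         "(MS[j] - MS[j-1] <= 1, MS[1] <= 1, MS >= 0); upstream bug")
  }
  invisible(ms)
}

#' Extract MEM intervals from a matching-statistics vector
#'
#' MEMs correspond one-to-one with peaks of the MS landscape: positions `j`
#' with `MS[j] >= MS[j+1]`, plus the final position. A peak of length
#' `MS[j] = L >= 1` yields the 0-based half-open pivot interval
#' `[j - L, j)`. Zero-valued peaks carry no match and are excluded; the
#' positions they cover surface instead as gap records in
#' [mems_to_overlaps()].
#'
#' @param ms Integer MS vector (validated against the sawtooth property).
#' @param contig Pivot contig name attached to the output intervals.
#' @return `data.frame` with columns `contig`, `start`, `end`, sorted by
#'   `start` (strictly increasing starts and ends).
#' @export
ms_to_mems <- function(ms, contig = "chr1") {
  ms <- as.integer(ms)
  assert_sawtooth(ms)
  m <- length(ms)
  peak <- c(ms[-m] >= ms[-1L], TRUE)
  j <- which(peak & ms >= 1L)
  data.frame(contig = rep(contig, length(j)),
             start = j - ms[j], end = j,
             stringsAsFactors = FALSE)
}

#' Derive overlap and gap records from consecutive MEMs
#'
#' For each consecutive MEM pair `[a, b)`, `[c, d)` the shared interval
#' `[c, b)` is emitted: a proper overlap when `c < b`, and a point record
#' with equal start and end when the MEMs adjoin (`c == b`). A k-mer that
#' spans such a record with overhang on both sides is contained in neither
#' MEM of the pair, hence absent from the target. Additionally, every
#' maximal run of `MS = 0` columns becomes a gap record (`is_gap = TRUE`)
#' covering its 0-based positions: no MEM covers them, so any k-mer merely
#' intersecting a gap is absent. A single MEM with no zero columns yields
#' no records at all.
#'
#' @param mems MEM `data.frame` from [ms_to_mems()], sorted by start.
#' @param ms The MS vector the MEMs were derived from (locates zero runs).
#' @param contig Contig name used when `mems` is empty (all-zero MS).
#' @return `data.frame` with columns `contig`, `start`, `end`, `is_gap`.
#' @export
mems_to_overlaps <- function(mems, ms, contig = "chr1") {
  ms <- as.integer(ms)
  if (nrow(mems)) contig <- mems$contig[1L]
  if (nrow(mems) > 1L) {
    if (is.unsorted(mems$start, strictly = TRUE)) {
      stop("MEMs must be sorted by strictly increasing start")
    }
    b <- mems$end[-nrow(mems)]
    cc <- mems$start[-1L]
    keep <- cc <= b  # c > b pairs are zero-MS runs, covered by gap records
    over <- data.frame(contig = rep(contig, sum(keep)),
                       start = cc[keep], end = b[keep],
                       is_gap = rep(FALSE, sum(keep)),
                       stringsAsFactors = FALSE)
  } else {
    over <- data.frame(contig = character(0), start = integer(0),
                       end = integer(0), is_gap = logical(0),
                       stringsAsFactors = FALSE)
  }
  r <- rle(ms == 0L)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths  # 0-based starts of each run
  zero <- which(r$values)
  if (length(zero)) {
    gaps <- data.frame(contig = rep(contig, length(zero)),
                       start = starts[zero], end = ends[zero],
                       is_gap = rep(TRUE, length(zero)),
                       stringsAsFactors = FALSE)
    over <- rbind(over, gaps)
    over <- over[order(over$start, over$end), , drop = FALSE]
    rownames(over) <- NULL
  }
  over
}

#' Reconstruct a matching-statistics vector from its MEMs
#'
#' Inverse of [ms_to_mems()] via
#' `MS[j] = max(0, max over MEMs [s, e) with s < j <= e of (j - s))`;
#' positions covered by no MEM get 0. Together with the peak mapping this
#' is an exact round trip, which the test suite exercises.
#'
#' @param mems MEM `data.frame` from [ms_to_mems()].
#' @param m Pivot contig length.
#' @return Integer vector `MS[1..m]`.
#' @export
reconstruct_ms <- function(mems, m) {
  ms <- integer(m)
  for (i in seq_len(nrow(mems))) {
    j <- (mems$start[i] + 1L):mems$end[i]
    ms[j] <- pmax(ms[j], j - mems$start[i])
  }
  ms
}
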