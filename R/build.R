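# Compute the full record set and metadata for an index, without writing.
# Pairwise pivot-vs-genome MS computations are independent of one another;
# the final canonical sort makes the record set schedule-independent.
build_records <- function(pivot, genomes, mode, quantiles = seq(0.1, 1, 0.1),
                          filter_l = NULL) {
  stopifnot(inherits(pivot, "panmem_genome"))
  if (length(genomes) < 1L) stop("need at least one non-pivot genome")
  all_names <- c(pivot$name, vapply(genomes, `[[`, "", "name"))
  if (anyDuplicated(all_names)) {
    stop("duplicate genome names: ",
         paste(unique(all_names[duplicated(all_names)]), collapse = ", "))
  }
  t <- length(genomes) + 1L
  contig_lengths <- vapply(pivot$sequences, nchar, 0)

  per_contig <- lapply(names(pivot$sequences), function(cn) {
    pv <- pivot$sequences[[cn]]
    ms_rows <- lapply(genomes, function(g) compute_matching_statistics(pv, g))
    if (mode == "membership") {
      recs <- lapply(seq_along(ms_rows), function(i) {
        ms <- ms_rows[[i]]
        ov <- mems_to_overlaps(ms_to_mems(ms, cn), ms, cn)
        ov$label <- if (nrow(ov)) i + 1L else integer(0)  # genome ids 2..t
        ov
      })
      do.call(rbind, recs)
    } else {
      om <- build_order_matrix(ms_rows)
      extract_order_overlaps(om, cn)
    }
  })
  records <- do.call(rbind, per_contig)
  records <- records[c("contig", "start", "end", "label", "is_gap")]

  thresholds <- NULL
  if (mode == "quantile") {
    scheme <- quantile_scheme(t, quantiles)
    records <- apply_quantile_sampling(records, scheme)
    thresholds <- scheme$thresholds
  }
  if (!is.null(filter_l) && is.finite(filter_l)) {
    records <- apply_length_filter(records, filter_l)
  }
  records <- sort_records(records, names(contig_lengths))
  meta <- index_metadata(pivot$name, all_names, mode, contig_lengths,
                         filter_l = if (is.null(filter_l)) NA else filter_l,
                         thresholds = thresholds)
  list(records = records, meta = meta)
}

#' Build a pangenome index end to end
#'
#' Reads the pivot and the other genomes, computes matching statistics of
#' every pivot contig against each genome (and its reverse complement),
#' derives overlap records in the requested mode, optionally applies
#' quantile sampling and interval-length filtering, and writes the
#' columnar index.
#'
#' Modes: `"membership"` stores per-genome overlap records labelled by
#' genome id (2..t); `"conservation"` stores order-overlap records
#' labelled by order (1..t-1); `"quantile"` additionally subsamples
#' order rows to the requested quantile thresholds.
#'
#' @param pivot Pivot [genome()] or FASTA path.
#' @param genomes List of non-pivot [genome()] objects or FASTA paths
#'   (ids 2..t follow this order).
#' @param path Output index path.
#' @param mode `"membership"`, `"conservation"` or `"quantile"`.
#' @param quantiles Quantile fractions for `"quantile"` mode.
#' @param filter_l Optional maximum retained overlap length; the
#'   resulting index supports only `k <= filter_l + 2` but is exact there.
#' @param chunk_bytes Row-group size passed to [write_index()].
#' @return The embedded `panmem_meta`, invisibly.
#' @export
build_index <- function(pivot, genomes, path,
                        mode = c("membership", "conservation", "quantile"),
                        quantiles = seq(0.1, 1, by = 0.1),
                        filter_l = NULL, chunk_bytes = 5e8) {
  mode <- match.arg(mode)
  if (is.character(pivot)) pivot <- read_fasta(pivot, genome_id = 1L)
  genomes <- lapply(seq_along(genomes), function(i) {
    g <- genomes[[i]]
    if (is.character(g)) read_fasta(g, genome_id = i + 1L) else g
  })
  built <- build_records(pivot, genomes, mode, quantiles, filter_l)
  write_index(built$records, built$meta, path, chunk_bytes)
  invisible(built$meta)
}
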