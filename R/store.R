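INDEX_FORMAT_VERSION <- "1"
# rough bytes per encoded record, used to turn chunk_bytes into a row-group
# row count before compression
BYTES_PER_RECORD <- 21

#' Index metadata
#'
#' Describes an index file: the pivot, the genome collection, the
#' annotation mode, and any lossy/filtering settings. Embedded verbatim in
#' the Parquet footer so an index file is self-describing.
#'
#' @param pivot Pivot genome name.
#' @param genomes Character vector of all genome names, pivot first.
#' @param mode One of `"membership"` (labels are genome ids 2..t),
#'   `"conservation"` (labels are orders 1..t-1) or `"quantile"` (labels
#'   are retained conservation-count thresholds).
#' @param contig_lengths Named vector of pivot contig lengths.
#' @param filter_l Maximum retained overlap length, or `NA` if unfiltered.
#' @param thresholds Integer thresholds for quantile mode, else `NULL`.
#' @return List of class `panmem_meta`.
#' @export
index_metadata <- function(pivot, genomes, mode, contig_lengths,
                           filter_l = NA, thresholds = NULL) {
  mode <- match.arg(mode, c("membership", "conservation", "quantile"))
  if (mode == "quantile" && is.null(thresholds)) {
    stop("quantile mode requires thresholds")
  }
  structure(
    list(version = INDEX_FORMAT_VERSION,
         pivot = pivot,
         genomes = as.character(genomes),
         t = length(genomes),
         mode = mode,
         contig_lengths = stats::setNames(as.numeric(contig_lengths),
                                          names(contig_lengths)),
         filter_l = if (is.null(filter_l) || is.infinite(filter_l)) NA_real_ else as.numeric(filter_l),
         thresholds = if (is.null(thresholds)) NULL else as.integer(thresholds)),
    class = "panmem_meta"
  )
}

# Canonical record order: (contig in pivot order, start, end, label).
# Keeps start/end columns non-decreasing within contig blocks, which is
# what makes the columnar encoding compress well.
sort_records <- function(records, contig_levels = NULL) {
  if (is.null(contig_levels)) contig_levels <- unique(records$contig)
  ci <- match(records$contig, contig_levels)
  out <- records[order(ci, records$start, records$end, records$label), ,
                 drop = FALSE]
  rownames(out) <- NULL
  out
}

records_sorted <- function(records, contig_levels) {
  ci <- match(records$contig, contig_levels)
  all(order(ci, records$start, records$end, records$label) ==
        seq_len(nrow(records)))
}

#' Write overlap records as a columnar-compressed index file
#'
#' Records are stored column-major in a Parquet file, every column
#' compressed with the ZSTD codec, in row groups of roughly `chunk_bytes`
#' raw bytes. Metadata is embedded in the file footer under `panmem.*`
#' keys, so any Parquet reader can inspect the index.
#'
#' @param records `data.frame` with columns `contig`, `start`, `end`,
#'   `label`, `is_gap`, already in canonical (contig, start, end, label)
#'   order.
#' @param meta A `panmem_meta`.
#' @param path Output path (written atomically via a temporary file).
#' @param chunk_bytes Approximate raw bytes per row group; the default
#'   0.5 GB suits genome-scale indexes, tests use small values.
#' @return `path`, invisibly.
#' @export
write_index <- function(records, meta, path, chunk_bytes = 5e8) {
  stopifnot(inherits(meta, "panmem_meta"))
  required <- c("contig", "start", "end", "label", "is_gap")
  if (!all(required %in% names(records))) {
    stop("records must have columns ", paste(required, collapse = ", "))
  }
  contig_levels <- names(meta$contig_lengths)
  if (nrow(records) && !records_sorted(records, contig_levels)) {
    stop("records must be sorted by (contig, start, end, label)")
  }
  df <- data.frame(
    contig = factor(records$contig, levels = contig_levels),
    start = as.numeric(records$start),
    end = as.numeric(records$end),
    label = as.integer(records$label),
    is_gap = as.logical(records$is_gap)
  )
  tbl <- arrow::arrow_table(
    df,
    schema = arrow::schema(
      contig = arrow::dictionary(arrow::int32(), arrow::utf8()),
      start = arrow::int64(), end = arrow::int64(),
      label = arrow::int32(), is_gap = arrow::bool()
    )
  )
  tbl$metadata$panmem.version <- meta$version
  tbl$metadata$panmem.mode <- meta$mode
  tbl$metadata$panmem.pivot <- meta$pivot
  tbl$metadata$panmem.genomes <- jsonlite::toJSON(meta$genomes)
  tbl$metadata$panmem.t <- as.character(meta$t)
  tbl$metadata$panmem.filter_l <- as.character(meta$filter_l)
  tbl$metadata$panmem.thresholds <-
    if (is.null(meta$thresholds)) "null" else jsonlite::toJSON(meta$thresholds)
  tbl$metadata$panmem.contigs <-
    jsonlite::toJSON(as.list(meta$contig_lengths), auto_unbox = TRUE)

  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".parquet.tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  arrow::write_parquet(tbl, tmp, compression = "zstd",
                       chunk_size = max(1L, as.integer(chunk_bytes %/% BYTES_PER_RECORD)))
  if (!file.rename(tmp, path)) stop("failed to move index into place: ", path)
  invisible(path)
}

#' Read index metadata from a Parquet footer
#'
#' @param path Index file path.
#' @return A `panmem_meta`.
#' @export
read_index_metadata <- function(path) {
  if (!file.exists(path)) stop("index file not found: ", path)
  md <- tryCatch(
    arrow::ParquetFileReader$create(path)$GetSchema()$metadata,
    error = function(e) stop("cannot read index footer of '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (is.null(md$panmem.version)) {
    stop("'", path, "' has no index metadata in its footer")
  }
  contigs <- unlist(jsonlite::fromJSON(md$panmem.contigs))
  th <- jsonlite::fromJSON(md$panmem.thresholds)
  index_metadata(
    pivot = md$panmem.pivot,
    genomes = jsonlite::fromJSON(md$panmem.genomes),
    mode = md$panmem.mode,
    contig_lengths = contigs,
    filter_l = if (identical(md$panmem.filter_l, "NA")) NA_real_ else
      as.numeric(md$panmem.filter_l),
    thresholds = if (is.null(th)) NULL else as.integer(th)
  )
}

#' Open an index file
#'
#' Reads the footer metadata only; record pages are decoded lazily by
#' queries through [read_region()].
#'
#' @param path Index file path.
#' @return Object of class `panmem_index` with fields `path` and `meta`.
#' @export
open_index <- function(path) {
  structure(list(path = path, meta = read_index_metadata(path)),
            class = "panmem_index")
}

#' @export
print.panmem_index <- function(x, ...) {
  m <- x$meta
  cat("<panmem_index> ", x$path, "\n", sep = "")
  cat("  mode: ", m$mode, ", t = ", m$t, ", pivot = ", m$pivot, "\n", sep = "")
  cat("  contigs: ", paste0(names(m$contig_lengths), " (",
                            m$contig_lengths, " bp)", collapse = ", "),
      "\n", sep = "")
  if (!is.na(m$filter_l)) {
    cat("  length-filtered at l = ", m$filter_l,
        " (supports k <= ", m$filter_l + 2, ")\n", sep = "")
  }
  if (!is.null(m$thresholds)) {
    cat("  thresholds: ", paste(m$thresholds, collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Read the records intersecting a region
#'
#' Returns exactly the records `r` on the region's contig with
#' `r.start <= region.start < r.end` or
#' `region.start < r.start < region.end` — the intersection predicate the
#' queries rely on. The predicate is pushed down to the Parquet scan, so
#' row groups whose column statistics cannot match are skipped without
#' decompression.
#'
#' @param path Index file path (or a `panmem_index`).
#' @param region A `panmem_region`.
#' @return Record `data.frame` in canonical order.
#' @export
read_region <- function(path, region) {
  if (inherits(path, "panmem_index")) path <- path$path
  if (!file.exists(path)) stop("index file not found: ", path)
  stopifnot(inherits(region, "panmem_region"))
  qc <- region$contig
  qs <- region$start
  qe <- region$end
  ds <- arrow::open_dataset(path)
  out <- dplyr::collect(dplyr::filter(
    ds,
    contig == qc,
    (start <= qs & end > qs) | (start > qs & start < qe)
  ))
  out <- as.data.frame(out)
  out$contig <- as.character(out$contig)
  out$start <- as.numeric(out$start)
  out$end <- as.numeric(out$end)
  sort_records(out)
}

#' Read every record of an index
#'
#' @param path Index file path (or a `panmem_index`).
#' @return Record `data.frame` in canonical order.
#' @export
read_index_records <- function(path) {
  if (inherits(path, "panmem_index")) path <- path$path
  meta <- read_index_metadata(path)
  out <- as.data.frame(arrow::read_parquet(path))
  out$contig <- as.character(out$contig)
  out$start <- as.numeric(out$start)
  out$end <- as.numeric(out$end)
  sort_records(out, names(meta$contig_lengths))
}

#' Export an index as a plain-text BED file
#'
#' Four tab-delimited columns (contig, 0-based half-open start/end, label);
#' gap records carry a distinguishing fifth column `gap`. Point records
#' (adjoining MEMs) have equal start and end.
#'
#' @param path_index Index file path.
#' @param path_bed Output BED path.
#' @return `path_bed`, invisibly.
#' @export
export_bed <- function(path_index, path_bed) {
  rec <- read_index_records(path_index)
  lines <- paste(rec$contig, format(rec$start, scientific = FALSE, trim = TRUE),
                 format(rec$end, scientific = FALSE, trim = TRUE),
                 rec$label, sep = "\t")
  lines[rec$is_gap] <- paste0(lines[rec$is_gap], "\tgap")
  writeLines(lines, path_bed)
  invisible(path_bed)
}

#' Import records from a BED file written by [export_bed()]
#'
#' @param path_bed BED path.
#' @return Record `data.frame` (`contig`, `start`, `end`, `label`,
#'   `is_gap`).
#' @export
import_bed <- function(path_bed) {
  lines <- readLines(path_bed)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (length(lines) && any(nf < 4L)) {
    stop("malformed BED line: ", lines[which(nf < 4L)[1L]])
  }
  data.frame(
    contig = vapply(parts, `[`, "", 1L),
    start = as.numeric(vapply(parts, `[`, "", 2L)),
    end = as.numeric(vapply(parts, `[`, "", 3L)),
    label = as.integer(vapply(parts, `[`, "", 4L)),
    is_gap = nf >= 5L,
    stringsAsFactors = FALSE
  )
}
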