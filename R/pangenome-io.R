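DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Construct a genome object
#'
#' A genome is an ordered collection of named contigs over the uppercase
#' alphabet A, C, G, T, N. Genome 1 of a pangenome is the pivot: the genome
#' whose coordinates anchor the index and from which all query k-mers are
#' drawn.
#'
#' @param name Genome name (single string).
#' @param sequences Named character vector of contig sequences; names are
#'   contig names and must be unique.
#' @param genome_id Small positive integer identifier; 1 denotes the pivot.
#' @param ambiguous How to treat characters outside A/C/G/T/N after
#'   uppercasing: `"error"` rejects them, `"N"` coerces them to N.
#' @return An object of class `panmem_genome` with fields `name`,
#'   `sequences` and `genome_id`.
#' @export
genome <- function(name, sequences, genome_id = NA_integer_,
                   ambiguous = c("error", "N")) {
  ambiguous <- match.arg(ambiguous)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop("genome name must be a non-empty string")
  }
  if (!is.character(sequences) || length(sequences) == 0L) {
    stop("sequences must be a non-empty character vector")
  }
  cn <- names(sequences)
  if (is.null(cn) || any(!nzchar(cn))) {
    stop("every contig must be named")
  }
  if (anyDuplicated(cn)) {
    stop("contig names must be unique within a genome: ",
         paste(unique(cn[duplicated(cn)]), collapse = ", "))
  }
  sequences <- toupper(sequences)
  if (any(nchar(sequences) == 0L)) {
    stop("contig sequences must be non-empty (offending contig: ",
         cn[which(nchar(sequences) == 0L)[1L]], ")")
  }
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad)) {
    if (ambiguous == "error") {
      stop("contig '", cn[which(bad)[1L]],
           "' contains characters outside {A,C,G,T,N}; ",
           "use ambiguous = \"N\" to coerce them")
    }
    sequences[bad] <- gsub("[^ACGTN]", "N", sequences[bad])
  }
  structure(
    list(name = name, sequences = sequences,
         genome_id = as.integer(genome_id)),
    class = "panmem_genome"
  )
}

#' @export
print.panmem_genome <- function(x, ...) {
  cat("<panmem_genome> ", x$name,
      if (!is.na(x$genome_id)) paste0(" (id ", x$genome_id,
                                      if (x$genome_id == 1L) ", pivot", ")")
      else "",
      "\n", sep = "")
  cat("  contigs: ", length(x$sequences), " (",
      format(sum(nchar(x$sequences)), big.mark = ","), " bp)\n", sep = "")
  invisible(x)
}

#' Read a genome from a FASTA file
#'
#' Multi-record FASTA (plain or gzip-compressed) is read into one contig per
#' record, preserving record order. Sequences are uppercased and validated
#' against the A/C/G/T/N alphabet.
#'
#' @param path Path to a FASTA file (`.gz` allowed).
#' @param name Genome name; defaults to the file name without extension.
#' @inheritParams genome
#' @return A `panmem_genome`.
#' @export
read_fasta <- function(path, name = NULL, genome_id = NA_integer_,
                       ambiguous = c("error", "N")) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  ss <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("failed to parse FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(ss) == 0L) stop("FASTA file contains no records: ", path)
  seqs <- as.character(ss)
  # FASTA headers may carry descriptions after the record id
  names(seqs) <- sub("\\s.*$", "", names(ss))
  if (is.null(name)) {
    name <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(path),
                ignore.case = TRUE)
  }
  genome(name, seqs, genome_id = genome_id, ambiguous = ambiguous)
}

#' Write a genome to a FASTA file
#'
#' @param g A `panmem_genome`.
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @param width Line width for wrapped sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(g, path, width = 70L) {
  stopifnot(inherits(g, "panmem_genome"))
  ss <- Biostrings::DNAStringSet(g$sequences)
  Biostrings::writeXStringSet(ss, path, width = width,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Reverse complement of DNA sequences
#'
#' Watson-Crick complement, reversed; N is its own complement. Vectorised
#' over its argument.
#'
#' @param seq Character vector of sequences over A/C/G/T/N (case-insensitive).
#' @return Character vector of reverse-complemented sequences.
#' @export
reverse_complement <- function(seq) {
  if (!is.character(seq)) stop("seq must be a character vector")
  up <- toupper(seq)
  if (any(grepl("[^ACGTN]", up))) {
    stop("sequence contains characters outside {A,C,G,T,N}")
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(up)))
}

#' Construct a query region on the pivot
#'
#' Regions are 0-based, half-open intervals `[start, end)` on a pivot
#' contig, matching BED conventions.
#'
#' @param contig Contig name on the pivot genome.
#' @param start,end 0-based half-open coordinates, `0 <= start < end`.
#' @return An object of class `panmem_region`.
#' @export
query_region <- function(contig, start, end) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (!is.character(contig) || length(contig) != 1L || !nzchar(contig)) {
    stop("contig must be a non-empty string")
  }
  if (is.na(start) || is.na(end) || start < 0 || start >= end) {
    stop("invalid region: require 0 <= start < end (got [", start, ", ",
         end, "))")
  }
  structure(list(contig = contig, start = start, end = end),
            class = "panmem_region")
}

#' @export
print.panmem_region <- function(x, ...) {
  cat("<panmem_region> ", x$contig, ":", x$start, "-", x$end,
      " (0-based, half-open)\n", sep = "")
  invisible(x)
}

#' Parse a region string and validate it against the pivot
#'
#' @param text Region string `"contig:start-end"` with 0-based half-open
#'   coordinates.
#' @param contig_lengths Either a `panmem_genome` (the pivot) or a named
#'   numeric vector of contig lengths to validate against.
#' @return A `panmem_region`.
#' @export
parse_region <- function(text, contig_lengths) {
  m <- regmatches(text, regexec("^(.+):([0-9]+)-([0-9]+)$", text))[[1L]]
  if (length(m) != 4L) {
    stop("malformed region '", text, "': expected contig:start-end")
  }
  r <- query_region(m[2L], as.numeric(m[3L]), as.numeric(m[4L]))
  validate_region(r, contig_lengths)
}

# Validate a region against pivot contig lengths (genome or named vector).
validate_region <- function(region, contig_lengths) {
  stopifnot(inherits(region, "panmem_region"))
  if (inherits(contig_lengths, "panmem_genome")) {
    contig_lengths <- vapply(contig_lengths$sequences, nchar, 0)
  }
  if (!region$contig %in% names(contig_lengths)) {
    stop("unknown pivot contig '", region$contig, "' (have: ",
         paste(names(contig_lengths), collapse = ", "), ")")
  }
  len <- contig_lengths[[region$contig]]
  if (region$end > len) {
    stop("region [", region$start, ", ", region$end, ") exceeds contig '",
         region$contig, "' length ", len)
  }
  region
}
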