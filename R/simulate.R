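#' Configuration for a synthetic pangenome
#'
#' Describes a small pangenome consisting of a uniform-random pivot and
#' `t - 1` independently mutated copies. Mutations are per-base
#' substitutions (uniform among the three alternatives), geometric-length
#' insertions and deletions (p = 0.5, capped at 50 bp), and optional
#' inversions: non-overlapping 100-1000 bp segments replaced by their
#' reverse complement. All randomness flows from the single seed.
#'
#' @param seed Integer seed; the generator is fully deterministic given it.
#' @param t Number of genomes including the pivot (`t >= 2`).
#' @param pivot_length Total pivot length in bp (`>= 100`), split evenly
#'   across `contig_count` contigs.
#' @param contig_count Number of pivot contigs.
#' @param substitution_rate,insertion_rate,deletion_rate Per-base event
#'   probabilities in `[0, 1)`.
#' @param inversion_count Number of reverse-complemented segments per
#'   mutated genome.
#' @return A validated list of class `panmem_sim_config`.
#' @export
simulation_config <- function(seed, t = 5L, pivot_length = 10000L,
                              contig_count = 1L,
                              substitution_rate = 0.01,
                              insertion_rate = 0.001,
                              deletion_rate = 0.001,
                              inversion_count = 1L) {
  rates <- c(substitution_rate, insertion_rate, deletion_rate)
  if (any(rates < 0) || any(rates >= 1)) stop("rates must lie in [0, 1)")
  if (t < 2L) stop("t must be at least 2 (pivot plus one other genome)")
  if (pivot_length < 100L) stop("pivot_length must be at least 100 bp")
  if (contig_count < 1L || contig_count > pivot_length %/% 100L) {
    stop("contig_count must be >= 1 and leave every contig >= 100 bp")
  }
  if (inversion_count < 0L) stop("inversion_count must be non-negative")
  structure(
    list(seed = as.integer(seed), t = as.integer(t),
         pivot_length = as.integer(pivot_length),
         contig_count = as.integer(contig_count),
         substitution_rate = substitution_rate,
         insertion_rate = insertion_rate,
         deletion_rate = deletion_rate,
         inversion_count = as.integer(inversion_count)),
    class = "panmem_sim_config"
  )
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Mutate one contig sequence: substitutions, then insertions, then
# deletions, then inversions. Everything is vectorised; indel lengths are
# 1 + geometric(0.5), capped at 50 bp.
mutate_sequence <- function(seq, cfg) {
  x <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(x)
  bases <- c("A", "C", "G", "T")

  sub_at <- which(stats::runif(n) < cfg$substitution_rate & x != "N")
  if (length(sub_at)) {
    cur <- match(x[sub_at], bases)
    x[sub_at] <- bases[((cur - 1L + sample.int(3L, length(sub_at),
                                               replace = TRUE)) %% 4L) + 1L]
  }

  ins_at <- which(stats::runif(n) < cfg$insertion_rate)
  if (length(ins_at)) {
    lens <- pmin(stats::rgeom(length(ins_at), 0.5) + 1L, 50L)
    ins <- vapply(lens, random_dna, "")
    x[ins_at] <- paste0(ins, x[ins_at])
  }

  del_at <- which(stats::runif(n) < cfg$deletion_rate)
  if (length(del_at)) {
    lens <- pmin(stats::rgeom(length(del_at), 0.5) + 1L, 50L)
    drop <- unique(unlist(Map(function(s, l) s:min(s + l - 1L, n),
                              del_at, lens)))
    x <- x[-drop]
  }

  out <- paste(x, collapse = "")

  if (cfg$inversion_count > 0L) {
    m <- nchar(out)
    taken <- integer(0)
    for (i in seq_len(cfg$inversion_count)) {
      len <- sample(100:1000, 1L)
      if (m <= len + 1L) next
      # a few attempts at a segment not overlapping earlier inversions
      for (try in 1:20) {
        s <- sample.int(m - len, 1L)
        if (!any(s:(s + len - 1L) %in% taken)) {
          segment <- substring(out, s, s + len - 1L)
          out <- paste0(substring(out, 1L, s - 1L),
                        reverse_complement(segment),
                        substring(out, s + len, m))
          taken <- c(taken, s:(s + len - 1L))
          break
        }
      }
    }
  }
  out
}

#' Simulate a synthetic pangenome
#'
#' Genome 1 is the uniform-random pivot; genomes 2..t are independent
#' mutated copies of it (see [simulation_config()] for the mutation model).
#' The output is byte-identical for identical configurations.
#'
#' @param cfg A `panmem_sim_config`.
#' @return List of `t` [genome()] objects; element 1 is the pivot
#'   (genome_id 1).
#' @export
simulate_pangenome <- function(cfg) {
  stopifnot(inherits(cfg, "panmem_sim_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(cfg$seed)

  lens <- rep(cfg$pivot_length %/% cfg$contig_count, cfg$contig_count)
  lens[1L] <- lens[1L] + cfg$pivot_length %% cfg$contig_count
  pivot_seqs <- vapply(lens, random_dna, "")
  names(pivot_seqs) <- paste0("chr", seq_along(pivot_seqs))

  out <- vector("list", cfg$t)
  out[[1L]] <- genome("g1", pivot_seqs, genome_id = 1L)
  for (i in 2:cfg$t) {
    seqs <- vapply(pivot_seqs, mutate_sequence, "", cfg = cfg)
    names(seqs) <- names(pivot_seqs)
    out[[i]] <- genome(paste0("g", i), seqs, genome_id = as.integer(i))
  }
  out
}

#' Write a simulated pangenome to FASTA files plus a JSON manifest
#'
#' @param genomes List of [genome()] objects (element 1 = pivot).
#' @param dir Output directory (created if missing).
#' @param cfg Optional `panmem_sim_config` recorded in the manifest.
#' @return Character vector of FASTA paths (pivot first), invisibly.
#' @export
write_pangenome <- function(genomes, dir, cfg = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(vapply(genomes, `[[`, "", "name"), ".fa"))
  for (i in seq_along(genomes)) write_fasta(genomes[[i]], paths[i])
  manifest <- list(
    genomes = vapply(genomes, `[[`, "", "name"),
    files = basename(paths),
    pivot = genomes[[1L]]$name
  )
  if (!is.null(cfg)) manifest$config <- unclass(cfg)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(paths)
}

# All k-mers of a target genome (both strands, per contig so matches never
# span contig or strand boundaries), as a character vector.
target_kmer_set <- function(target, k) {
  seqs <- c(unname(target$sequences), reverse_complement(target$sequences))
  seqs <- seqs[nchar(seqs) >= k]
  unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    substring(s, 1:(n - k + 1L), k:n)
  }), use.names = FALSE)
}

#' Brute-force k-mer presence oracle
#'
#' Reference implementation of the membership definition: pivot k-mer
#' number x of the region is present iff it occurs verbatim in any target
#' contig or its reverse complement (N matches only N; matches never span
#' contigs or strands). Used as ground truth in tests; takes no shortcuts
#' through the index machinery.
#'
#' @param pivot,target [genome()] objects.
#' @param region A `panmem_region` on the pivot.
#' @param k K-mer length, `1 <= k <= region length`.
#' @return Logical vector of length `end - start - k + 1`.
#' @export
oracle_kmer_presence <- function(pivot, target, region, k) {
  validate_region(region, pivot)
  k <- as.integer(k)
  if (k < 1L) stop("k must be at least 1")
  if (region$end - region$start < k) {
    stop("k = ", k, " exceeds region length ", region$end - region$start)
  }
  seq <- pivot$sequences[[region$contig]]
  starts <- (region$start + 1L):(region$end - k + 1L)  # 1-based
  kmers <- substring(seq, starts, starts + k - 1L)
  kmers %in% target_kmer_set(target, k)
}

#' Brute-force conservation oracle
#'
#' Per k-mer start, `1` (the pivot always contains its own k-mers) plus the
#' number of non-pivot genomes whose [oracle_kmer_presence()] is true.
#'
#' @param pivot The pivot [genome()].
#' @param genomes List of non-pivot [genome()] objects.
#' @inheritParams oracle_kmer_presence
#' @return Integer vector with values in `[1, 1 + length(genomes)]`.
#' @export
oracle_conservation <- function(pivot, genomes, region, k) {
  pres <- vapply(genomes, oracle_kmer_presence, logical(region$end - region$start - k + 1),
                 pivot = pivot, region = region, k = k)
  if (is.null(dim(pres))) pres <- matrix(pres, nrow = 1L)
  as.integer(1L + rowSums(pres))
}
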