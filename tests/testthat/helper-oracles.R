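# Brute-force oracles and shared fixtures. Oracles deliberately avoid the
# package's index machinery so agreement tests are two independent routes.

rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# Matching statistics straight from the definition: for each prefix end j,
# grow the suffix length while naive substring search still finds it in
# some target contig or reverse complement. (Occurrence is monotone in
# suffix length, so the first failure stops the scan.)
brute_ms <- function(pivot, target_genome) {
  texts <- c(unname(target_genome$sequences),
             reverse_complement(target_genome$sequences))
  m <- nchar(pivot)
  ms <- integer(m)
  for (j in seq_len(m)) {
    l <- 0L
    while (l < j) {
      cand <- substr(pivot, j - l, j)
      hit <- any(vapply(texts, function(tx) grepl(cand, tx, fixed = TRUE),
                        logical(1)))
      if (!hit) break
      l <- l + 1L
    }
    ms[j] <- l
  }
  ms
}

# The store's intersection predicate applied naively to a full record set.
full_scan_region <- function(records, region) {
  qs <- region$start
  qe <- region$end
  keep <- records$contig == region$contig &
    ((records$start <= qs & qs < records$end) |
       (qs < records$start & records$start < qe))
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

make_fixture <- function(seed, t = 3, pivot_length = 2000, contig_count = 1,
                         substitution_rate = 0.02, insertion_rate = 0.001,
                         deletion_rate = 0.001, inversion_count = 1) {
  cfg <- simulation_config(seed, t = t, pivot_length = pivot_length,
                           contig_count = contig_count,
                           substitution_rate = substitution_rate,
                           insertion_rate = insertion_rate,
                           deletion_rate = deletion_rate,
                           inversion_count = inversion_count)
  list(cfg = cfg, genomes = simulate_pangenome(cfg))
}

# ---- suite of seeded pangenomes shared by the acceptance tests ----------
# 20 configurations spanning t in {2,3,5,10}, pivots of 5-20 kb over 1-3
# contigs, substitution rates 0.5-5%, indels on, one inversion each.
suite_configs <- function() {
  data.frame(
    seed = 9000 + 1:20,
    t = rep(c(2L, 3L, 5L, 10L), 5),
    pivot_length = rep(c(5000L, 8000L, 12000L, 16000L, 20000L), each = 4),
    contig_count = rep_len(c(1L, 2L, 3L, 1L, 2L), 20),
    substitution_rate = rep_len(c(0.005, 0.01, 0.02, 0.05), 20)
  )
}

.suite_cache <- new.env(parent = emptyenv())

# Builds (once per test run) every suite pangenome plus its membership,
# conservation and quantile indexes, and keeps the per-contig MS rows for
# invariant checks.
suite_fixtures <- function() {
  if (!is.null(.suite_cache$fixtures)) return(.suite_cache$fixtures)
  cfgs <- suite_configs()
  dir <- file.path(tempdir(), "panmem-suite")
  dir.create(dir, showWarnings = FALSE)
  fixtures <- lapply(seq_len(nrow(cfgs)), function(i) {
    row <- cfgs[i, ]
    fx <- make_fixture(row$seed, t = row$t, pivot_length = row$pivot_length,
                       contig_count = row$contig_count,
                       substitution_rate = row$substitution_rate)
    pivot <- fx$genomes[[1L]]
    targets <- fx$genomes[-1L]
    ms_rows <- lapply(names(pivot$sequences), function(cn) {
      do.call(rbind, lapply(targets, function(g) {
        compute_matching_statistics(pivot$sequences[[cn]], g)
      }))
    })
    names(ms_rows) <- names(pivot$sequences)
    paths <- file.path(dir, sprintf("fx%02d-%s.parquet", i,
                                    c("mem", "cons", "quant")))
    build_index(pivot, targets, paths[1L], mode = "membership",
                chunk_bytes = 1e5)
    build_index(pivot, targets, paths[2L], mode = "conservation",
                chunk_bytes = 1e5)
    suppressWarnings(
      build_index(pivot, targets, paths[3L], mode = "quantile",
                  chunk_bytes = 1e5)
    )
    list(cfg = fx$cfg, genomes = fx$genomes, ms_rows = ms_rows,
         idx_membership = paths[1L], idx_conservation = paths[2L],
         idx_quantile = paths[3L])
  })
  .suite_cache$fixtures <- fixtures
  fixtures
}

whole_contig_regions <- function(pivot) {
  lapply(names(pivot$sequences), function(cn) {
    query_region(cn, 0, nchar(pivot$sequences[[cn]]))
  })
}
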