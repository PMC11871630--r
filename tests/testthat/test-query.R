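# Build the three index modes for one fixture into a per-call directory.
build_all_modes <- function(fx) {
  dir <- tempfile("panmem-idx")
  dir.create(dir)
  paths <- file.path(dir, c("m.parquet", "c.parquet", "q.parquet"))
  build_index(fx$genomes[[1]], fx$genomes[-1], paths[1], mode = "membership")
  build_index(fx$genomes[[1]], fx$genomes[-1], paths[2], mode = "conservation")
  suppressWarnings(
    build_index(fx$genomes[[1]], fx$genomes[-1], paths[3], mode = "quantile")
  )
  list(membership = paths[1], conservation = paths[2], quantile = paths[3])
}

test_that("identical genomes are fully present and fully conserved at any k", {
  cfg <- simulation_config(601, t = 4, pivot_length = 500,
                           substitution_rate = 0, insertion_rate = 0,
                           deletion_rate = 0, inversion_count = 0)
  fx <- list(genomes = simulate_pangenome(cfg))
  idx <- build_all_modes(fx)
  reg <- query_region("chr1", 0, 500)
  for (k in c(1, 13, 100, 500)) {
    expect_true(all(membership_query(idx$membership, reg, k)))
    expect_true(all(conservation_query(idx$conservation, reg, k) == 4L))
  }
  expect_true(all(quantile_conservation_query(idx$quantile, reg, 31) == 4L))
})

test_that("a point overlap record marks exactly the spanning k-mers absent", {
  meta <- index_metadata("g1", c("g1", "g2"), "membership", c(chr1 = 30))
  recs <- data.frame(contig = "chr1", start = 10, end = 10, label = 2L,
                     is_gap = FALSE)
  p <- withr::local_tempfile(fileext = ".parquet")
  write_index(recs, meta, p)
  k <- 5L
  res <- membership_query(p, query_region("chr1", 0, 30), k)
  xs <- attr(res, "positions")
  # absent iff x < 10 and x + k > 10, i.e. x in [6, 9]
  expect_identical(unname(res["g2", ]), !(xs >= 6 & xs <= 9))
  expect_true(all(res["g1", ]))  # the pivot row is always true
})

test_that("membership and conservation agree with the oracles on fixtures", {
  for (seed in c(611, 612)) {
    fx <- make_fixture(seed, t = 5, pivot_length = 2500, contig_count = 2,
                       substitution_rate = 0.02)
    idx <- build_all_modes(fx)
    pivot <- fx$genomes[[1]]
    reg <- query_region("chr2", 100, 1100)
    for (k in c(7, 21, 64)) {
      mem <- membership_query(idx$membership, reg, k)
      for (n in 2:5) {
        expect_identical(unname(mem[n, ]),
                         oracle_kmer_presence(pivot, fx$genomes[[n]], reg, k))
      }
      cons <- conservation_query(idx$conservation, reg, k)
      expect_identical(as.integer(cons),
                       oracle_conservation(pivot, fx$genomes[-1], reg, k))
    }
  }
})

test_that("with one non-pivot genome, conservation is 1 + membership", {
  fx <- make_fixture(613, t = 2, pivot_length = 1500)
  idx <- build_all_modes(fx)
  reg <- query_region("chr1", 0, 1500)
  mem <- membership_query(idx$membership, reg, 11)
  cons <- conservation_query(idx$conservation, reg, 11)
  expect_identical(as.integer(cons), 1L + as.integer(mem[2, ]))
})

test_that("early-stopped and exhaustive conservation agree; counts drop with k", {
  fx <- make_fixture(614, t = 6, pivot_length = 2000, substitution_rate = 0.03)
  idx <- build_all_modes(fx)
  reg <- query_region("chr1", 0, 2000)
  for (k in c(5, 17, 41)) {
    fast <- conservation_query(idx$conservation, reg, k, early_stop = TRUE)
    slow <- conservation_query(idx$conservation, reg, k, early_stop = FALSE)
    expect_identical(as.integer(fast), as.integer(slow))
  }
  c15 <- conservation_query(idx$conservation, reg, 15)
  c16 <- conservation_query(idx$conservation, reg, 16)
  expect_true(all(c16 <= c15[seq_along(c16)]))
})

test_that("quantile queries floor exact conservation onto the thresholds", {
  fx <- make_fixture(615, t = 10, pivot_length = 2000, substitution_rate = 0.04)
  idx <- build_all_modes(fx)
  reg <- query_region("chr1", 0, 2000)
  th <- quantile_thresholds(10)
  for (k in c(9, 31)) {
    exact <- conservation_query(idx$conservation, reg, k)
    quant <- quantile_conservation_query(idx$quantile, reg, k)
    floor_exact <- vapply(as.integer(exact),
                          function(v) max(c(1L, th[th <= v])), 1L)
    expect_identical(as.integer(quant), floor_exact)
  }
})

test_that("mode mismatches and invalid k are rejected", {
  fx <- make_fixture(616, t = 3, pivot_length = 600)
  idx <- build_all_modes(fx)
  reg <- query_region("chr1", 0, 100)
  expect_error(membership_query(idx$conservation, reg, 5), "membership-mode")
  expect_error(conservation_query(idx$membership, reg, 5), "conservation-mode")
  expect_error(quantile_conservation_query(idx$membership, reg, 5),
               "quantile-mode")
  expect_error(membership_query(idx$membership, reg, 101), "exceeds region")
  expect_error(membership_query(idx$membership, reg, 0), "positive")
  expect_error(membership_query(idx$membership,
                                query_region("chrX", 0, 10), 5), "unknown")
})

test_that("length-filtered indexes answer identically up to k = l + 2", {
  fx <- make_fixture(617, t = 4, pivot_length = 3000, substitution_rate = 0.02)
  dir <- withr::local_tempdir()
  unf <- file.path(dir, "u.parquet")
  fil <- file.path(dir, "f.parquet")
  build_index(fx$genomes[[1]], fx$genomes[-1], unf, mode = "conservation")
  build_index(fx$genomes[[1]], fx$genomes[-1], fil, mode = "conservation",
              filter_l = 10)
  expect_lte(nrow(read_index_records(fil)), nrow(read_index_records(unf)))
  reg <- query_region("chr1", 0, 3000)
  for (k in c(3, 7, 12)) {
    expect_identical(as.integer(conservation_query(fil, reg, k)),
                     as.integer(conservation_query(unf, reg, k)))
  }
  expect_error(conservation_query(fil, reg, 13), "maximum supported k is 12")
})

test_that("binned conservation proportions are a normalized histogram", {
  expect_error(bin_conservation(c(1L, 2L), 4, 0), "at least 1")
  # fully conserved vector: all mass in the top bin
  bc <- bin_conservation(rep(5L, 40), 5, 10)
  expect_identical(dim(bc), c(1L, 10L))
  expect_equal(unname(bc[1, 10]), 1)
  # windowed proportions sum to 1 and match a naive recount
  set.seed(620)
  cons <- sample(1:8, 350, replace = TRUE)
  bc <- bin_conservation(cons, 8, 4, window = 100)
  expect_equal(unname(rowSums(bc)), rep(1, 4))
  naive <- table(factor(pmin(ceiling(cons[1:100] / 8 * 4), 4), levels = 1:4))
  expect_equal(unname(bc[1, ]), unname(as.numeric(naive) / 100))
})

test_that("query results export as TSV and BedGraph", {
  fx <- make_fixture(618, t = 3, pivot_length = 600)
  idx <- build_all_modes(fx)
  reg <- query_region("chr1", 50, 250)
  mem <- membership_query(idx$membership, reg, 15)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_membership_tsv(mem, tsv)
  tab <- utils::read.delim(tsv, check.names = FALSE)
  expect_identical(nrow(tab), ncol(mem))
  expect_identical(tab$position, attr(mem, "positions"))
  expect_identical(as.logical(tab$g2), unname(mem["g2", ]))

  cons <- conservation_query(idx$conservation, reg, 15)
  bg <- withr::local_tempfile(fileext = ".bedgraph")
  write_conservation_bedgraph(cons, "chr1", bg)
  rows <- read.table(bg, sep = "\t")
  expect_identical(rows$V2[1], 50L)                      # first k-mer start
  expect_identical(rows$V3[nrow(rows)], 50L + length(cons))
  # expanding the runs reproduces the vector
  expanded <- rep(rows$V4, rows$V3 - rows$V2)
  expect_identical(expanded, as.integer(cons))
})
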