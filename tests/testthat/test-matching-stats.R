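test_that("matching statistics handle identity, disjoint and strand cases", {
  expect_identical(compute_matching_statistics("ACGT", genome("t", c(c1 = "ACGT"))),
                   1:4)
  expect_identical(compute_matching_statistics("AAAA", genome("t", c(c1 = "CCCC"))),
                   rep(0L, 4))
  # pivot equals the reverse complement of the target
  expect_identical(compute_matching_statistics("ACCT", genome("t", c(c1 = "AGGT"))),
                   1:4)
  expect_error(compute_matching_statistics("", genome("t", c(c1 = "ACGT"))),
               "empty")
})

test_that("suffix-automaton matching statistics equal the brute-force definition", {
  set.seed(301)
  for (i in 1:12) {
    m <- sample(20:120, 1)
    n <- sample(30:180, 1)
    pv <- rand_seq(m)
    tg <- genome("t", c(c1 = rand_seq(n)))
    expect_identical(compute_matching_statistics(pv, tg), brute_ms(pv, tg))
  }
  # multi-contig target: matches must not bridge contigs
  pv <- "ACGTACGT"
  tg <- genome("t", c(c1 = "ACGT", c2 = "TACG"))
  expect_identical(compute_matching_statistics(pv, tg), brute_ms(pv, tg))
  # N is a literal character
  pv <- "ACNNACGT"
  tg <- genome("t", c(c1 = "GGACNNAC"))
  expect_identical(compute_matching_statistics(pv, tg), brute_ms(pv, tg))
})

test_that("matches never span the strand boundary of one contig", {
  # contig "AACC": rc is "GGTT"; "CCGG" occurs in neither strand alone but
  # would appear if the two were naively concatenated
  ms <- compute_matching_statistics("CCGG", genome("t", c(c1 = "AACC")))
  expect_identical(ms, brute_ms("CCGG", genome("t", c(c1 = "AACC"))))
  expect_lt(max(ms), 3L)
})

test_that("MEMs are the peaks of the sawtooth landscape", {
  expect_identical(ms_to_mems(c(1, 2, 3, 4))[, c("start", "end")],
                   data.frame(start = 0L, end = 4L))
  expect_identical(ms_to_mems(c(1, 2, 2, 1))[, c("start", "end")],
                   data.frame(start = c(0L, 1L, 3L), end = c(2L, 3L, 4L)))
  # zero peaks are excluded; position 1 is covered by no MEM
  expect_identical(ms_to_mems(c(1, 0, 1))[, c("start", "end")],
                   data.frame(start = c(0L, 2L), end = c(1L, 3L)))
  expect_error(ms_to_mems(c(1, 3, 2)), "sawtooth")
  expect_error(ms_to_mems(c(2, 2)), "sawtooth")  # MS[1] > 1 impossible
})

test_that("overlap records capture consecutive-MEM overlaps, points and gaps", {
  ov <- mems_to_overlaps(ms_to_mems(c(1, 2, 2, 1)), c(1, 2, 2, 1))
  expect_identical(ov[, c("start", "end", "is_gap")],
                   data.frame(start = c(1L, 3L), end = c(2L, 3L),
                              is_gap = c(FALSE, FALSE)))

  # adjoining MEMs produce a point record with equal start and end
  ms <- c(1, 2, 3, 1, 2)
  mems <- ms_to_mems(ms)
  expect_identical(mems$start, c(0L, 3L))
  ov <- mems_to_overlaps(mems, ms)
  expect_identical(ov$start, ov$end)
  expect_identical(ov$start, 3L)

  # a zero-MS run becomes a gap record over its 0-based positions
  ov <- mems_to_overlaps(ms_to_mems(c(1, 0, 1)), c(1, 0, 1))
  expect_identical(ov, data.frame(contig = "chr1", start = 1L, end = 2L,
                                  is_gap = TRUE))
  # leading and trailing zero runs are gaps too
  ov <- mems_to_overlaps(ms_to_mems(c(0, 0, 1, 0)), c(0, 0, 1, 0))
  expect_identical(ov[ov$is_gap, c("start", "end")],
                   data.frame(start = c(0L, 3L), end = c(2L, 4L)))

  # a single MEM with no zero columns yields nothing
  expect_identical(nrow(mems_to_overlaps(ms_to_mems(c(1, 2)), c(1, 2))), 0L)
  bad <- data.frame(contig = "chr1", start = c(3L, 0L), end = c(5L, 2L))
  expect_error(mems_to_overlaps(bad, c(1, 2)), "sorted")
})

test_that("MS vectors round-trip through MEM extraction", {
  set.seed(302)
  for (i in 1:10) {
    pv <- rand_seq(150)
    tg <- genome("t", c(c1 = rand_seq(sample(60:200, 1))))
    ms <- compute_matching_statistics(pv, tg)
    expect_identical(reconstruct_ms(ms_to_mems(ms), length(ms)), ms)
  }
  # vectors with zero runs round-trip as well
  ms <- c(0L, 1L, 2L, 0L, 0L, 1L, 1L)
  expect_identical(reconstruct_ms(ms_to_mems(ms), 7L), ms)
})
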