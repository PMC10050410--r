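sizes <- c(chr1 = 100000L, chr2 = 100000L)

test_that("summit extension gives fixed 501-bp half-open windows", {
  pk <- extend_summits(
    tibble::tibble(chrom = "chr1", summit = 10000L, score = 5),
    chrom_sizes = sizes
  )
  expect_equal(pk$start, 9750L)
  expect_equal(pk$end, 10251L)
  expect_equal(pk$end - pk$start, 501L)

  # boundary-exact summit is not clipped
  pk0 <- extend_summits(tibble::tibble(chrom = "chr1", summit = 250L, score = 1),
                        chrom_sizes = sizes)
  expect_equal(c(pk0$start, pk0$end), c(0L, 501L))
  expect_false(pk0$clipped)

  # exhaustive width audit over random summits
  set.seed(1)
  s <- tibble::tibble(chrom = "chr1",
                      summit = sample(300:99000, 1000), score = 1)
  ext <- extend_summits(s, chrom_sizes = sizes)
  expect_true(all(ext$end - ext$start == 501L))

  # off-chromosome summit errors; near-boundary summit is clipped+flagged
  expect_error(extend_summits(tibble::tibble(chrom = "chr1", summit = 100001L,
                                             score = 1), chrom_sizes = sizes))
  clip <- extend_summits(tibble::tibble(chrom = "chr1", summit = 100L, score = 1),
                         chrom_sizes = sizes)
  expect_true(clip$clipped)
})

test_that("blacklist filtering uses >=1 bp half-open overlap", {
  pk <- tibble::tibble(chrom = "chr1", start = 100L, end = 601L, score = 1)
  expect_identical(filter_blacklist(pk, pk[0, 1:3]), pk)
  # 1-bp overlap removes the peak
  bl <- tibble::tibble(chrom = "chr1", start = 600L, end = 700L)
  expect_equal(nrow(filter_blacklist(pk, bl)), 0L)
  # exactly adjacent (half-open) does not
  bl2 <- tibble::tibble(chrom = "chr1", start = 601L, end = 700L)
  expect_equal(nrow(filter_blacklist(pk, bl2)), 1L)
})

test_that("iterative overlap removal follows the greedy rule", {
  # two overlapping peaks: keep the higher score
  two <- tibble::tibble(chrom = "chr1", start = c(0L, 100L), end = c(501L, 601L),
                        score = c(10, 5))
  expect_equal(iterative_overlap_removal(two)$score, 10)

  # chain A[0,501) s=5, B[400,901) s=3, C[800,1301) s=4 -> {A, C}
  chain <- tibble::tibble(chrom = "chr1",
                          start = c(0L, 400L, 800L), end = c(501L, 901L, 1301L),
                          score = c(5, 3, 4))
  kept <- iterative_overlap_removal(chain)
  expect_equal(kept$score, c(5, 4))

  # non-overlapping input is the identity
  sep <- tibble::tibble(chrom = "chr1", start = c(0L, 1000L), end = c(501L, 1501L),
                        score = c(1, 2))
  expect_equal(iterative_overlap_removal(sep)$start, sep$start)

  # idempotence
  expect_equal(iterative_overlap_removal(kept), kept)
})

test_that("overlap removal is order invariant and matches the quadratic oracle", {
  set.seed(7)
  for (rep in 1:25) {
    pk <- random_peaks(40)
    got <- iterative_overlap_removal(pk)
    want <- oracle_greedy(pk)
    expect_equal(got$start, want$start)
    expect_equal(got$score, want$score)
    # permuting input order changes nothing
    perm <- pk[sample.int(nrow(pk)), , drop = FALSE]
    got2 <- iterative_overlap_removal(perm)
    expect_equal(got2$start, got$start)
  }
})

test_that("score-per-million normalizes within sample to 1e6", {
  one <- tibble::tibble(chrom = "chr1", start = 0L, end = 501L, score = 17,
                        sample_id = "s1")
  expect_equal(score_per_million(one)$spm, 1e6)

  pk <- tibble::tibble(chrom = "chr1", start = c(0, 1000, 2000), end = c(501, 1501, 2501),
                       score = c(2, 3, 5), sample_id = "s1")
  expect_equal(score_per_million(pk)$spm, c(2e5, 3e5, 5e5))

  set.seed(3)
  pk2 <- random_peaks(30)
  pk2$sample_id <- sample(c("a", "b"), 30, replace = TRUE)
  spm <- score_per_million(pk2)
  sums <- tapply(spm$spm, spm$sample_id, sum)
  expect_equal(as.vector(sums), rep(1e6, 2))

  pk2$score <- 0
  expect_error(score_per_million(pk2), "non-positive")
})

test_that("cross-sample merge enforces SPM, support and chromosome filters", {
  mk <- function(start, score, sample, chrom = "chr1") {
    score_per_million(tibble::tibble(
      chrom = chrom, start = as.integer(start), end = as.integer(start + 501L),
      summit = as.integer(start + 250L), score = score, sample_id = sample,
      clipped = FALSE
    ))
  }
  # same peak in 2 samples -> retained with support 2
  m <- merge_across_samples(list(mk(1000, 6, "s1"), mk(1000, 7, "s2")))
  expect_equal(nrow(m), 1L)
  expect_equal(m$support, 2L)

  # single-sample peak dropped regardless of spm
  m2 <- merge_across_samples(list(mk(1000, 100, "s1"), mk(9000, 50, "s2")))
  expect_equal(nrow(m2), 0L)

  # chrY excluded
  y1 <- rbind(mk(1000, 5, "s1"), mk(5000, 5, "s1", chrom = "chrY"))
  y2 <- rbind(mk(1000, 5, "s2"), mk(5000, 5, "s2", chrom = "chrY"))
  y1$spm <- 5e5; y2$spm <- 5e5  # keep both above min_spm
  my <- merge_across_samples(list(y1, y2))
  expect_false(any(my$chrom == "chrY"))

  expect_error(merge_across_samples(list(mk(1, 1, "s1"))), "at least 2")
})

test_that("support never increases when a sample is removed", {
  set.seed(11)
  mk_sample <- function(s) {
    pk <- random_peaks(60, width_range = c(100, 100))
    pk$sample_id <- s
    pk$clipped <- FALSE
    score_per_million(iterative_overlap_removal(pk))
  }
  sets <- lapply(c("s1", "s2", "s3"), mk_sample)
  full <- merge_across_samples(sets, min_spm = 0, min_support = 1)
  reduced <- merge_across_samples(sets[1:2], min_spm = 0, min_support = 1)
  shared <- intersect(peak_ids(full), peak_ids(reduced))
  f <- full$support[match(shared, peak_ids(full))]
  r <- reduced$support[match(shared, peak_ids(reduced))]
  expect_true(all(r <= f))
})
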