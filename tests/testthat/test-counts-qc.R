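test_that("Tn5 correction shifts fragment ends by +4 / -5", {
  ins <- correct_insertions(tibble::tibble(chrom = "chr1", start = 1000L,
                                           end = 1200L, sample_id = "s1"))
  expect_setequal(ins$position, c(1004L, 1195L))

  # minimal width 10 -> two insertions one bp apart
  ins10 <- correct_insertions(tibble::tibble(chrom = "chr1", start = 0L,
                                             end = 10L, sample_id = "s1"))
  expect_equal(sort(ins10$position), c(4L, 5L))

  # width <= 9 skipped with a warning
  expect_warning(
    short <- correct_insertions(tibble::tibble(chrom = "chr1",
                                               start = c(0L, 0L), end = c(9L, 50L),
                                               sample_id = "s1")),
    "width <= 9"
  )
  expect_equal(nrow(short), 2L)

  # random fragments match the per-fragment arithmetic
  set.seed(5)
  fr <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 500, TRUE),
                       start = sample.int(10000, 500),
                       sample_id = "s1")
  fr$end <- fr$start + sample(10:300, 500, TRUE)
  got <- correct_insertions(fr)
  expect_equal(sort(got$position), sort(c(fr$start + 4L, fr$end - 5L)))
})

test_that("insertion counting respects half-open peak bounds", {
  pk <- tibble::tibble(chrom = "chr1", start = 100L, end = 601L,
                       peak_id = "chr1:100-601")
  # at start counted, at end not
  ins <- tibble::tibble(chrom = "chr1", position = c(100L, 600L, 601L),
                        sample_id = "s1")
  m <- count_insertions(ins, pk)
  expect_equal(unname(m$values[1, 1]), 2L)

  # no insertions -> zero matrix with the right shape
  m0 <- count_insertions(ins[0, ], pk, sample_ids = c("s1", "s2"))
  expect_equal(dim(m0$values), c(1L, 2L))
  expect_true(all(m0$values == 0))

  # random instance equals the quadratic scan oracle
  set.seed(9)
  peaks <- random_peaks(25, width_range = c(100, 100))
  peaks <- iterative_overlap_removal(peaks)
  peaks$peak_id <- sprintf("p%02d", seq_len(nrow(peaks)))
  ins2 <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 800, TRUE),
                         position = sample.int(6000, 800, replace = TRUE),
                         sample_id = sample(c("a", "b", "c"), 800, TRUE))
  got <- count_insertions(ins2, peaks, sample_ids = c("a", "b", "c"))
  want <- oracle_count(ins2, peaks, c("a", "b", "c"))
  expect_equal(unname(got$values), unname(want))
})

test_that("insertions are conserved between matrix and off-peak space", {
  set.seed(13)
  peaks <- random_peaks(15, width_range = c(200, 200))
  peaks <- iterative_overlap_removal(peaks)
  fr <- tibble::tibble(chrom = sample(c("chr1", "chr2"), 400, TRUE),
                       start = sample.int(5000, 400, replace = TRUE),
                       sample_id = "s1")
  fr$end <- fr$start + sample(20:400, 400, TRUE)
  ins <- correct_insertions(fr)
  m <- count_insertions(ins, peaks)
  in_peak <- sum(m$values)
  off <- sum(oracle_count(ins, peaks, "s1") == 0) # not used for the identity
  expect_equal(in_peak + (nrow(ins) - in_peak), 2L * nrow(fr))
  # and in-peak total matches the oracle
  expect_equal(in_peak, sum(oracle_count(ins, peaks, "s1")))
})

test_that("normalization applies adjusted-prior log-CPM then quantile averaging", {
  x <- matrix(c(0L, 5L, 20L, 100L,
                3L, 7L, 15L, 80L,
                1L, 9L, 30L, 60L), nrow = 4,
              dimnames = list(paste0("r", 1:4), paste0("s", 1:3)))
  am <- accessibility_matrix(x)
  got <- normalize_matrix(am, prior_count = 5)

  # spreadsheet-style oracle: both stages by the stated formulas
  L <- colSums(x)
  p <- 5 * L / mean(L)
  lc <- log2(sweep(sweep(x, 2, p, "+"), 2, L + 2 * p, "/") * 1e6)
  qn <- lc
  means <- rowMeans(apply(lc, 2, sort))
  for (j in 1:3) {
    r <- rank(lc[, j], ties.method = "average")
    qn[, j] <- approx(seq_len(nrow(x)), means, xout = r)$y
  }
  expect_equal(unname(got$values), unname(qn), tolerance = 1e-8)

  # identical columns: quantile stage is the identity
  same <- matrix(rep(c(2L, 8L, 40L, 9L), 3), nrow = 4,
                 dimnames = list(paste0("r", 1:4), paste0("s", 1:3)))
  am2 <- accessibility_matrix(same)
  lc2 <- edgeR::cpm(same, log = TRUE, prior.count = 5)
  got2 <- normalize_matrix(am2)
  expect_equal(unname(got2$values), unname(lc2), tolerance = 1e-10)

  # column order statistics identical after normalization (ties-free
  # columns; tied counts are averaged and only match approximately)
  set.seed(21)
  rnd <- accessibility_matrix(
    matrix(c(sample.int(500, 40), sample.int(500, 40), sample.int(500, 40),
             sample.int(500, 40), sample.int(500, 40)), nrow = 40,
           dimnames = list(NULL, paste0("s", 1:5)))
  )
  nm <- normalize_matrix(rnd)
  sorted <- apply(nm$values, 2, sort)
  expect_true(all(abs(sorted - sorted[, 1]) < 1e-10))
})

test_that("TSS enrichment self-normalizes and matches a loop oracle", {
  set.seed(31)
  genome_len <- 1000000L
  tss <- tibble::tibble(chrom = "chr1",
                        position = seq(50000L, 950000L, by = 4500L),
                        strand = sample(c("+", "-"), 201, TRUE))
  # uniform insertions -> score ~ 1
  ins_u <- tibble::tibble(chrom = "chr1",
                          position = sample.int(genome_len, 3e5, replace = TRUE),
                          sample_id = "u")
  sc_u <- tss_enrichment(ins_u, tss)
  expect_lt(abs(sc_u$tss_enrichment - 1), 0.1)

  # concentrated insertions: score equals an explicit-loop recomputation
  ins_c <- tibble::tibble(
    chrom = "chr1",
    position = c(rep(tss$position, 40L) + sample(-30:30, 201 * 40, TRUE),
                 sample.int(genome_len, 20000L, replace = TRUE)),
    sample_id = "c"
  )
  sc_c <- tss_enrichment(ins_c, tss)
  prof <- numeric(4001)
  for (i in seq_len(nrow(tss))) {
    d <- ins_c$position - tss$position[i]
    if (tss$strand[i] == "-") d <- -d
    d <- d[abs(d) <= 2000]
    prof <- prof + tabulate(d + 2001L, 4001L)
  }
  flank <- mean(prof[abs(-2000:2000) >= 1900])
  norm <- prof / flank
  sm <- sapply(seq_along(norm), function(i) {
    mean(norm[max(1, i - 25):min(4001, i + 25)])
  })
  expect_equal(sc_c$tss_enrichment, max(sm[abs(-2000:2000) <= 50]),
               tolerance = 1e-10)
  expect_true(sc_c$pass)  # >= 5 threshold

  # invariance to uniform background scaling: doubling all insertions
  ins_d <- dplyr::bind_rows(ins_c, ins_c)
  sc_d <- tss_enrichment(ins_d, tss)
  expect_equal(sc_d$tss_enrichment, sc_c$tss_enrichment, tolerance = 1e-8)
})

test_that("fragment length histogram and nucleosome-free selection", {
  fr <- tibble::tibble(chrom = "chr1", start = 0L,
                       end = c(100L, 100L, 200L), sample_id = "s")
  h <- fragment_length_histogram(fr)
  expect_equal(h$count[h$length == 100], 2L)
  expect_equal(h$count[h$length == 200], 1L)

  expect_equal(nrow(fragment_length_histogram(fr[0, ])), 0L)

  # pooling above max_len
  fr2 <- tibble::tibble(chrom = "chr1", start = 0L, end = c(50L, 1500L, 2000L),
                        sample_id = "s")
  h2 <- fragment_length_histogram(fr2, max_len = 1000)
  expect_equal(h2$count[h2$length == 1000], 2L)

  # strict < 100 bound
  fr3 <- tibble::tibble(chrom = "chr1", start = 0L,
                        end = c(50L, 99L, 100L, 150L), sample_id = "s")
  nf <- select_nucleosome_free(fr3)
  expect_equal(nf$end, c(50L, 99L))
  expect_equal(nrow(select_nucleosome_free(
    tibble::tibble(chrom = "chr1", start = 0L, end = c(100L, 120L),
                   sample_id = "s"))), 0L)

  # random widths: retained count equals brute force
  set.seed(2)
  fr4 <- tibble::tibble(chrom = "chr1", start = 0L,
                        end = sample(10:400, 500, TRUE), sample_id = "s")
  expect_equal(nrow(select_nucleosome_free(fr4)), sum(fr4$end < 100))
})

test_that("synthetic fragment mixture shows modes near both component means", {
  co <- tiny_cohort(seed = 3)
  h <- fragment_length_histogram(co$fragments)
  # local mode within +/- 15 bp of each mixture mean
  near <- function(center) {
    sub <- h[abs(h$length - center) <= 15, ]
    max(sub$count)
  }
  far <- h$count[h$length > 300 & h$length < 400]
  expect_gt(near(60), max(far, 0))
  expect_gt(near(200), max(far, 0))
})
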