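mk_peaks <- function(summits, chrom = "chr1") {
  tibble::tibble(
    chrom = chrom, start = summits - 250L, end = summits + 251L,
    summit = as.integer(summits),
    peak_id = sprintf("%s:%d-%d", chrom, summits - 250L, summits + 251L)
  )
}

test_that("promoter classification is inclusive at the 1-kb boundary", {
  tss <- tibble::tibble(chrom = "chr1", position = 10000L, strand = "+",
                        gene_name = "G1")
  ann <- annotate_peaks(mk_peaks(c(10000L, 11000L, 11001L, 50000L)), tss)
  expect_equal(ann$class, c("promoter", "promoter", "distal", "distal"))
  expect_equal(ann$tss_distance[1], 0)
  expect_equal(ann$tss_distance[2], 1000)

  # strand-aware sign: a peak downstream of a minus-strand TSS has
  # negative distance flipped
  tss_m <- tibble::tibble(chrom = "chr1", position = 10000L, strand = "-",
                          gene_name = "G1")
  ann_m <- annotate_peaks(mk_peaks(10500L), tss_m)
  expect_equal(ann_m$tss_distance, -500)

  expect_error(annotate_peaks(mk_peaks(1000L), tss[0, ]), "empty TSS")
})

test_that("nearest-TSS assignment matches a brute-force oracle", {
  set.seed(17)
  tss <- tibble::tibble(
    chrom = sample(c("chr1", "chr2"), 50, TRUE),
    position = sample.int(200000, 50),
    strand = sample(c("+", "-"), 50, TRUE),
    gene_name = sprintf("G%02d", 1:50)
  )
  summits <- sample(500:199500, 300)
  pk <- mk_peaks(summits, chrom = sample(c("chr1", "chr2"), 300, TRUE))
  ann <- annotate_peaks(pk, tss)
  for (i in sample(300, 40)) {
    cand <- tss[tss$chrom == pk$chrom[i], ]
    d <- abs(pk$summit[i] - cand$position)
    expect_equal(abs(ann$tss_distance[i]), min(d))
    expect_equal(ann$class[i], ifelse(min(d) <= 1000, "promoter", "distal"))
  }
  # partition property
  expect_equal(sum(ann$class == "promoter") + sum(ann$class == "distal"),
               nrow(pk))
})

test_that("reference-set overlap flags and distal cancer CRE set algebra", {
  pk <- mk_peaks(c(1000L, 5000L, 9000L))
  refs <- list(
    fibroblast = tibble::tibble(chrom = "chr1", start = 900L, end = 950L),
    tcell = tibble::tibble(chrom = "chr1", start = c(900L, 4900L),
                           end = c(950L, 4950L))
  )
  ov <- overlap_reference_sets(pk, refs)
  expect_true(ov$fibroblast[1] && ov$tcell[1])
  expect_true(!ov$fibroblast[2] && ov$tcell[2])
  expect_false(ov$any_tme[3])

  # disjoint refs -> all flags empty
  far <- list(x = tibble::tibble(chrom = "chr2", start = 1L, end = 100L))
  expect_false(any(suppressWarnings(overlap_reference_sets(pk, far))$any_tme))

  tss <- tibble::tibble(chrom = "chr1", position = 1000L, strand = "+",
                        gene_name = "G")
  ann <- annotate_peaks(pk, tss)
  dc <- derive_distal_cancer_cres(ann, ov)
  # peak1 is promoter, peak2 overlaps tcell -> only peak3 remains
  expect_equal(dc$peak_id, pk$peak_id[3])

  # random instances satisfy the set identity
  set.seed(23)
  for (rep in 1:10) {
    pk2 <- mk_peaks(sample(seq(500L, 99000L, by = 600L), 60))
    refs2 <- list(a = random_peaks(10)[, 1:3], b = random_peaks(10)[, 1:3])
    ov2 <- overlap_reference_sets(pk2, refs2)
    ann2 <- annotate_peaks(pk2, tss)
    dc2 <- derive_distal_cancer_cres(ann2, ov2)
    n_distal <- sum(ann2$class == "distal")
    n_distal_tme <- sum(ann2$class == "distal" & ov2$any_tme)
    expect_equal(nrow(dc2), n_distal - n_distal_tme)
  }
})

test_that("deconvolution score averages flagged rows per sample", {
  vals <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 3,
                 dimnames = list(c("p1", "p2", "p3"), c("s1", "s2")))
  norm <- accessibility_matrix(vals, state = "logcpm_quantile")
  ov <- tibble::tibble(peak_id = c("p1", "p2", "p3"),
                       tcell = c(TRUE, TRUE, FALSE),
                       bcell = c(FALSE, FALSE, TRUE))
  sc <- deconvolution_score(norm, ov, "tcell")
  expect_equal(sc$score, c(s1 = 1.5, s2 = 4.5))
  # single flagged peak -> that row
  sc_b <- deconvolution_score(norm, ov, "bcell")
  expect_equal(unname(sc_b$score), c(3, 6))
  ov$bcell <- FALSE
  expect_error(deconvolution_score(norm, ov, "bcell"), "bcell")
})

test_that("rank-sum test: exact enumeration, symmetry, null uniformity", {
  # {1,2,3} vs {4,5,6}: exact two-sided p = 0.1 (2 of 20 labelings as extreme)
  r <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$p_value, 0.1)
  expect_equal(r$statistic, 0)

  # identical groups -> p = 1
  expect_equal(rank_sum_test(c(5, 5, 5), c(5, 5, 5))$p_value, 1)

  # symmetry
  set.seed(3)
  a <- rnorm(12); b <- rnorm(15)
  expect_equal(rank_sum_test(a, b)$p_value, rank_sum_test(b, a)$p_value)

  # oracle comparison: exact (small) and tie-corrected normal (large/ties)
  for (rep in 1:20) {
    a2 <- round(rnorm(sample(3:7, 1)), 2)
    b2 <- round(rnorm(sample(3:7, 1)), 2)
    got <- rank_sum_test(a2, b2)$p_value
    want <- if (anyDuplicated(c(a2, b2))) oracle_ranksum_normal(a2, b2)
            else oracle_ranksum_exact(a2, b2)
    expect_equal(got, want, tolerance = 1e-8)
  }
  a3 <- round(rnorm(30), 1); b3 <- round(rnorm(25), 1)
  expect_equal(rank_sum_test(a3, b3)$p_value, oracle_ranksum_normal(a3, b3),
               tolerance = 1e-8)

  # null calibration of the large-sample path
  set.seed(19)
  ps <- replicate(2000, rank_sum_test(rnorm(30), rnorm(30))$p_value)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("interval-overlap Fisher test matches hypergeometric enumeration", {
  # build a universe whose 2x2 table is [[3,1],[1,3]]
  universe <- tibble::tibble(chrom = "chr1",
                             start = seq(0L, 7000L, by = 1000L))
  universe$end <- universe$start + 500L
  in_a <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  in_b <- c(TRUE, TRUE, TRUE, FALSE, TRUE, FALSE, FALSE, FALSE)
  set_a <- universe[in_a, ]
  set_b <- universe[in_b, ]
  ft <- overlap_fisher(set_a, set_b, universe)
  expect_equal(unname(c(ft$n11, ft$n10, ft$n01, ft$n00)), c(3, 1, 1, 3))
  expect_equal(ft$p_value, 34 / 70, tolerance = 1e-10)
  expect_equal(ft$p_value, oracle_fisher_p(3, 1, 1, 3), tolerance = 1e-10)

  # perfectly concordant 10/10 split
  u2 <- tibble::tibble(chrom = "chr1", start = seq(0L, 19000L, by = 1000L))
  u2$end <- u2$start + 500L
  f2 <- overlap_fisher(u2[1:10, ], u2[1:10, ], u2)
  expect_equal(f2$p_value, 2 / choose(20, 10), tolerance = 1e-10)

  expect_error(overlap_fisher(u2[1:2, ], u2[3:4, ], u2[0, ]), "empty universe")
})
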