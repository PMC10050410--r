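test_pfm <- function() {
  # sharp 8-mer so the 1e-4 per-position threshold is attainable
  chromstrat:::consensus_pfm("ACGTACGT", conc = 0.97)
}

test_that("PWM threshold equals the exact null score distribution tail", {
  m <- motif_model("test", test_pfm())
  # brute force: enumerate all 4^8 windows under the uniform background
  w <- m$width
  combos <- as.matrix(expand.grid(rep(list(1:4), w)))
  scores <- numeric(nrow(combos))
  for (k in seq_len(w)) scores <- scores + m$pwm[combos[, k], k]
  scores_d <- round(scores * 100) / 100
  p_ge <- mean(scores_d >= m$score_threshold)
  expect_lte(p_ge, 1e-4)
  expect_gt(p_ge, 0)  # some windows do reach the threshold
  # minimality over achievable scores: admitting the next-lower achievable
  # score pushes the tail above the target
  next_lower <- max(scores_d[scores_d < m$score_threshold])
  expect_gt(mean(scores_d >= next_lower), 1e-4)
})

test_that("PWM scanning finds consensus hits with strand symmetry", {
  # non-palindromic consensus ACGTACGA
  m <- motif_model("test", chromstrat:::consensus_pfm("ACGTACGA", conc = 0.97))
  seqs <- c(hit = "ACGTACGAGG", none = "TTTTTTTTTT")
  h <- scan_pwm(seqs, m)
  expect_equal(h$seq_name, "hit")
  expect_equal(h$position, 0L)
  expect_equal(h$strand, "+")

  # reverse-complemented consensus: minus-strand hit at the mirrored position
  rc <- c(rc = "GGGGTCGTACGT")  # revcomp(ACGTACGA) at positions 4..11
  h_rc <- scan_pwm(rc, m)
  expect_equal(h_rc$strand, "-")
  expect_equal(h_rc$position, 4L)

  # sequence shorter than the motif: no hits, no error
  expect_equal(nrow(scan_pwm(c(s = "ACG"), m)), 0L)

  # N bases block matches
  expect_equal(nrow(scan_pwm(c(s = "ACGNACGAG"), m)), 0L)
})

test_that("scanning equals an exhaustive per-window rescoring oracle", {
  set.seed(61)
  m <- motif_model("test", test_pfm())
  seqs <- chromstrat:::random_seq(200, 40, 0.5)
  names(seqs) <- sprintf("s%03d", 1:200)
  got <- scan_pwm(seqs, m, threshold = 4)

  comp <- c(A = "T", C = "G", G = "C", T = "A")
  oracle <- list()
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[i], "")[[1]]
    for (j in 1:(40 - m$width + 1)) {
      win <- chars[j:(j + m$width - 1)]
      sc_p <- sum(m$pwm[cbind(match(win, c("A", "C", "G", "T")), 1:m$width)])
      rc <- rev(unname(comp[win]))
      sc_m <- sum(m$pwm[cbind(match(rc, c("A", "C", "G", "T")), 1:m$width)])
      if (sc_p >= 4) oracle[[length(oracle) + 1]] <-
          data.frame(seq_name = names(seqs)[i], position = j - 1L, strand = "+",
                     score = sc_p)
      if (sc_m >= 4) oracle[[length(oracle) + 1]] <-
          data.frame(seq_name = names(seqs)[i], position = j - 1L, strand = "-",
                     score = sc_m)
    }
  }
  want <- do.call(rbind, oracle)
  want <- want[order(want$seq_name, want$position, want$strand), ]
  got_o <- got[order(got$seq_name, got$position, got$strand), ]
  expect_equal(got_o$seq_name, want$seq_name)
  expect_equal(got_o$position, want$position)
  expect_equal(got_o$strand, want$strand)
  expect_equal(got_o$score, want$score, tolerance = 1e-10)

  # global reverse complement mirrors positions and flips strands
  rc_seqs <- vapply(seqs, chromstrat:::revcomp_chr, "")
  names(rc_seqs) <- names(seqs)
  h_rc <- scan_pwm(rc_seqs, m, threshold = 4)
  key <- function(h, L = 40) paste(h$seq_name,
                                   ifelse(h$strand == "+", "-", "+"),
                                   L - m$width - h$position)
  expect_setequal(key(got), paste(h_rc$seq_name, h_rc$strand, h_rc$position))
})

test_that("GC content counts non-N bases", {
  expect_equal(gc_content(c("AATT", "GCGC", "GCAT")), c(0, 1, 0.5))
  expect_equal(gc_content("GCNN"), 1)
  expect_true(is.na(gc_content("NNNN")))
  set.seed(3)
  seqs <- chromstrat:::random_seq(50, 120, 0.45)
  want <- vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    sum(ch %in% c("G", "C")) / length(ch)
  }, 0)
  expect_equal(unname(gc_content(seqs)), unname(want))
})

test_that("background peaks are matched, seeded and handle degeneracy", {
  set.seed(70)
  n <- 1500
  gc <- runif(n, 0.25, 0.65)
  acc <- rgamma(n, 5, 1)
  bg <- background_peaks(gc, acc, n_bg = 50, seed = 9)
  expect_equal(dim(bg), c(n, 50L))
  # matching quality: median |own GC - mean background GC| small
  dev <- abs(gc - rowMeans(matrix(gc[bg], nrow = n)))
  expect_lt(median(dev), 0.05)
  # deterministic under seed
  bg2 <- background_peaks(gc, acc, n_bg = 50, seed = 9)
  expect_identical(bg, bg2)
  # degenerate features: uniform sampling with warning
  expect_warning(background_peaks(rep(0.5, 300), rep(1, 300), n_bg = 10),
                 "identical")
})

test_that("motif deviations vanish under proportional columns and scale invariance", {
  set.seed(75)
  n <- 400
  base <- rpois(n, 40) + 1L
  vals <- cbind(s1 = base, s2 = 3L * base, s3 = 2L * base)
  rownames(vals) <- sprintf("p%03d", 1:n)
  am <- accessibility_matrix(vals)
  matches <- matrix(FALSE, n, 2, dimnames = list(rownames(vals), c("m1", "m2")))
  matches[sample(n, 60), 1] <- TRUE
  matches[sample(n, 80), 2] <- TRUE
  bg <- background_peaks(runif(n), rowMeans(vals), n_bg = 20, seed = 2)
  dev <- motif_deviations(am, matches, bg)
  expect_true(all(abs(dev$raw_dev) < 1e-10))

  # multiplying all counts by a constant leaves deviations unchanged
  am10 <- accessibility_matrix(vals * 10L)
  dev10 <- motif_deviations(am10, matches, bg)
  r <- dev$raw_dev
  expect_equal(dev10$raw_dev, r, tolerance = 1e-10)
})

test_that("deviation z-scores are calibrated on exchangeable null counts", {
  set.seed(80)
  n <- 2000; ns <- 12
  am <- generate_null_counts(n, ns, dispersion = 0.15, mu = 40, seed = 31)
  matches <- matrix(FALSE, n, 8,
                    dimnames = list(rownames(am$values), paste0("m", 1:8)))
  for (j in 1:8) matches[sample(n, 150), j] <- TRUE
  bg <- background_peaks(runif(n), rowMeans(am$values), n_bg = 50, seed = 3)
  z <- motif_deviations(am, matches, bg)$z
  expect_lt(abs(mean(z)), 0.1)
  expect_gt(sd(z), 0.8)
  expect_lt(sd(z), 1.2)
})

test_that("GC-matched enrichment equals the direct hypergeometric tail", {
  set.seed(85)
  n <- 600
  gc <- runif(n, 0.3, 0.6)
  target <- seq_len(n) <= 60
  matches <- matrix(runif(n * 2) < 0.1, n, 2,
                    dimnames = list(NULL, c("mA", "mB")))
  matches[target, "mA"] <- runif(60) < 0.6
  enr <- motif_enrichment(matches, target, gc, seed = 4)
  expect_equal(enr$motif[1], "mA")
  row <- enr[enr$motif == "mA", ]
  want <- phyper(row$target_hits - 1,
                 m = row$target_hits + row$bg_hits,
                 n = (row$n_target + row$n_bg) - (row$target_hits + row$bg_hits),
                 k = row$n_target, lower.tail = FALSE)
  expect_equal(row$p_value, want, tolerance = 1e-12)
  expect_error(motif_enrichment(matches, rep(TRUE, n), gc), "nonempty")
})

test_that("planted-motif sequences drive the enrichment test as designed", {
  m <- motif_model("test", test_pfm())
  # full vs zero planting at a permissive threshold
  gs <- generate_motif_sequences(m, 40, 40, 1, 0, length = 60, seed = 5)
  mm <- motif_matches(gs$target, list(m), threshold = 2)
  expect_true(all(mm[, 1]))

  # 0.8 vs 0.1 planting: hypergeometric enrichment p < 1e-10
  gs2 <- generate_motif_sequences(m, 100, 1000, 0.8, 0.1, length = 120, seed = 6)
  all_seq <- c(gs2$target, gs2$background)
  mm2 <- motif_matches(all_seq, list(m))
  target <- c(rep(TRUE, 100), rep(FALSE, 1000))
  enr <- motif_enrichment(mm2, target, gc_content(all_seq), seed = 7)
  expect_lt(enr$p_value[1], 1e-10)

  expect_error(generate_motif_sequences(m, 5, 5, 1, 0, length = 3),
               "motif width")
})

test_that("motif score t-test matches the textbook formula", {
  r <- motif_score_test(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_value, 1)

  set.seed(90)
  a <- rnorm(10); b <- rnorm(12, 1)
  got <- motif_score_test(a, b)
  sp <- sqrt(((10 - 1) * var(a) + (12 - 1) * var(b)) / 20)
  t_want <- (mean(a) - mean(b)) / (sp * sqrt(1 / 10 + 1 / 12))
  expect_equal(got$statistic, t_want, tolerance = 1e-10)
  expect_equal(got$p_value, 2 * pt(-abs(t_want), df = 20), tolerance = 1e-10)

  sep <- motif_score_test(c(0, 0, 0, 0) + rnorm(4, sd = 1e-3),
                          c(1, 1, 1, 1) + rnorm(4, sd = 1e-3))
  expect_lt(sep$p_value, 1e-4)
  expect_error(motif_score_test(rep(1, 3), rep(1, 4)), "pooled variance")
})
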