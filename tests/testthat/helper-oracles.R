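# Independent brute-force oracles used to cross-check the implementations.
# These deliberately use naive loops / direct formulas, never the package's
# own code paths.

overlaps_pair <- function(c1, s1, e1, c2, s2, e2) {
  c1 == c2 & s1 < e2 & s2 < e1
}

# quadratic greedy: repeatedly take the best-ranked remaining peak and
# drop everything overlapping it
oracle_greedy <- function(peaks, rank_col = "score") {
  kept <- peaks[0, ]
  remaining <- peaks
  while (nrow(remaining)) {
    ord <- order(-remaining[[rank_col]], remaining$chrom, remaining$start,
                 remaining$end, method = "radix")
    best <- remaining[ord[1], , drop = FALSE]
    kept <- rbind(kept, best)
    hit <- overlaps_pair(remaining$chrom, remaining$start, remaining$end,
                         best$chrom, best$start, best$end)
    remaining <- remaining[!hit, , drop = FALSE]
  }
  kept[order(kept$chrom, kept$start, kept$end, method = "radix"), , drop = FALSE]
}

# all-pairs overlap filter
oracle_filter <- function(peaks, blacklist) {
  keep <- vapply(seq_len(nrow(peaks)), function(i) {
    !any(overlaps_pair(peaks$chrom[i], peaks$start[i], peaks$end[i],
                       blacklist$chrom, blacklist$start, blacklist$end))
  }, TRUE)
  peaks[keep, , drop = FALSE]
}

# per-cell scan of insertions into peaks
oracle_count <- function(insertions, peaks, sample_ids) {
  m <- matrix(0L, nrow = nrow(peaks), ncol = length(sample_ids),
              dimnames = list(NULL, sample_ids))
  for (i in seq_len(nrow(peaks))) {
    inside <- insertions$chrom == peaks$chrom[i] &
      insertions$position >= peaks$start[i] &
      insertions$position < peaks$end[i]
    if (any(inside)) {
      t <- table(factor(insertions$sample_id[inside], levels = sample_ids))
      m[i, ] <- as.integer(t)
    }
  }
  m
}

# direct BH step-up formula
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (i in rev(seq_len(m))) {
    running <- min(running, p[ord[i]] * m / i)
    adj[ord[i]] <- min(running, 1)
  }
  adj
}

# textbook product-limit estimator: S at each distinct event time
oracle_km <- function(time, event) {
  ev_times <- sort(unique(time[event == 1]))
  s <- 1
  out <- data.frame(time = ev_times, surv = NA_real_)
  for (k in seq_along(ev_times)) {
    t <- ev_times[k]
    n_risk <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n_risk)
    out$surv[k] <- s
  }
  out
}

# two-group log-rank O-E / V by explicit accumulation over event times
oracle_logrank <- function(time, event, group) {
  groups <- sort(unique(group))
  stopifnot(length(groups) == 2)
  o_minus_e <- 0
  v <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == groups[1])
    d <- sum(time == t & event == 1)
    d1 <- sum(time == t & event == 1 & group == groups[1])
    o_minus_e <- o_minus_e + (d1 - d * n1 / n)
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  chisq <- o_minus_e^2 / v
  list(chisq = chisq, p = pchisq(chisq, df = 1, lower.tail = FALSE))
}

# two-sided Fisher p by hypergeometric enumeration over all tables with
# the observed margins
oracle_fisher_p <- function(n11, n10, n01, n00) {
  r1 <- n11 + n10
  c1 <- n11 + n01
  n <- n11 + n10 + n01 + n00
  ks <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(ks, c1, n - c1, r1)
  obs <- dhyper(n11, c1, n - c1, r1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# exact two-sided rank-sum p by enumeration of all group labelings
oracle_ranksum_exact <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  combs <- utils::combn(n, na)
  u_all <- apply(combs, 2, function(idx) sum(r[idx]) - na * (na + 1) / 2)
  mu <- na * (n - na) / 2
  min(1, mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-9))
}

# tie-corrected normal-approximation rank-sum p (no continuity correction)
oracle_ranksum_normal <- function(a, b) {
  na <- length(a); nb <- length(b); n <- na + nb
  r <- rank(c(a, b))
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  ties <- table(c(a, b))
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- na * nb / 12 * ((n + 1) - tie_term)
  z <- (u - na * nb / 2) / sqrt(sigma2)
  2 * pnorm(-abs(z))
}

# random fixture builders ----------------------------------------------------

random_peaks <- function(n, chroms = c("chr1", "chr2"), max_pos = 5000,
                         width_range = c(50, 400)) {
  start <- sample.int(max_pos, n, replace = TRUE)
  width <- sample(width_range[1]:width_range[2], n, replace = TRUE)
  tibble::tibble(
    chrom = sample(chroms, n, replace = TRUE),
    start = start,
    end = start + width,
    score = round(runif(n, 0, 100), 2)
  )
}

tiny_cohort <- function(seed = 42, ...) {
  generate_cohort(cohort_config(
    n_samples_per_group = 3, genome_length = 3e5, n_chroms = 2,
    n_true_regions = 150, fragments_per_sample = 30000,
    n_validation = 80, n_high_validation = 10, seed = seed, ...
  ))
}
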