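DNA_BASES <- c("A", "C", "G", "T")

#' Motif model from a position frequency matrix
#'
#' Converts base counts to a log-odds position weight matrix against a
#' background base composition (with a pseudocount), and computes the
#' default hit threshold: the smallest log-odds score whose probability
#' under the background model is at most `pval` per position, obtained by
#' dynamic programming over the discretized PWM score distribution.
#'
#' @param name motif name.
#' @param pfm 4 x width count matrix (rows A, C, G, T).
#' @param background background base frequencies (A, C, G, T).
#' @param pseudocount added (spread by background) to each column before
#'   the log-odds.
#' @param pval per-position null hit probability defining the default
#'   score threshold.
#' @return a `motif_model` list: `name`, `pfm`, `pwm` (log2 odds),
#'   `width`, `score_threshold`, `background`.
#' @export
motif_model <- function(name, pfm, background = rep(0.25, 4),
                        pseudocount = 1, pval = 1e-4) {
  stopifnot(is.matrix(pfm), nrow(pfm) == 4)
  if (any(pfm < 0)) abort("PFM counts must be nonnegative")
  if (ncol(pfm) < 4) abort("motif width must be >= 4")
  rownames(pfm) <- DNA_BASES
  background <- background / sum(background)
  prob <- sweep(pfm + pseudocount * background,
                2, colSums(pfm) + pseudocount, "/")
  pwm <- log2(prob / background)
  structure(
    list(name = name, pfm = pfm, pwm = pwm, width = ncol(pfm),
         score_threshold = pwm_score_threshold(pwm, background, pval),
         background = background),
    class = "motif_model"
  )
}

#' @export
print.motif_model <- function(x, ...) {
  cat(sprintf("<motif_model> %s: width %d, threshold %.2f bits\n",
              x$name, x$width, x$score_threshold))
  invisible(x)
}

#' PWM score threshold from the background score distribution
#'
#' Exact distribution of the PWM score of a random background window,
#' computed by dynamic programming over positions on a discretized score
#' grid; the threshold is the smallest score `s` with
#' `P(score >= s) <= pval`.
#'
#' @param pwm log-odds matrix (4 x width).
#' @param background base frequencies.
#' @param pval target per-position null hit probability.
#' @param precision score discretization (grid steps per unit).
#' @return the threshold score.
#' @export
pwm_score_threshold <- function(pwm, background, pval = 1e-4, precision = 100) {
  s_int <- round(pwm * precision)
  # distribution over partial integer scores; cur_v[i] = P(score == cur_lo + i - 1)
  cur_v <- 1
  cur_lo <- 0L
  for (k in seq_len(ncol(pwm))) {
    step_lo <- min(s_int[, k])
    step_hi <- max(s_int[, k])
    new_lo <- cur_lo + step_lo
    new_v <- numeric(length(cur_v) + (step_hi - step_lo))
    for (b in 1:4) {
      off <- s_int[b, k] - step_lo
      idx <- seq_along(cur_v) + off
      new_v[idx] <- new_v[idx] + background[b] * cur_v
    }
    cur_v <- new_v
    cur_lo <- new_lo
  }
  tail_p <- rev(cumsum(rev(cur_v)))
  ok <- which(tail_p <= pval)
  if (!length(ok)) return((cur_lo + length(cur_v) - 1) / precision)
  (cur_lo + ok[1] - 1) / precision
}

# encode sequences (character or DNAStringSet) into an n x maxL integer
# matrix (A=1 C=2 G=3 T=4, everything else / padding = 5), padding ragged
# ends
encode_sequences <- function(sequences) {
  if (methods::is(sequences, "XStringSet")) sequences <- as.character(sequences)
  n <- length(sequences)
  L <- nchar(sequences)
  maxL <- max(L)
  padded <- ifelse(L < maxL,
                   paste0(sequences, strrep("N", maxL - L)),
                   sequences)
  m <- matrix(match(unlist(strsplit(toupper(padded), "", fixed = TRUE)),
                    DNA_BASES),
              nrow = n, ncol = maxL, byrow = TRUE)
  m[is.na(m)] <- 5L
  list(enc = m, lengths = L)
}

scan_encoded <- function(enc, lengths, W, threshold, strand) {
  n <- nrow(enc)
  maxL <- ncol(enc)
  w <- ncol(W)
  if (maxL < w) {
    return(tibble(seq_index = integer(), position = integer(),
                  strand = character(), score = numeric()))
  }
  # sentinel 5th base (N / padding) scores -Inf-like, so such windows
  # can never reach a finite threshold
  Wvec <- as.vector(rbind(W, -1e9))  # column-major: W[b, k] at (k-1)*5 + b
  proto <- tibble(seq_index = integer(), position = integer(),
                  strand = character(), score = numeric())
  out <- vector("list", maxL - w + 1)
  for (j in seq_len(maxL - w + 1)) {
    score <- Wvec[enc[, j]]
    for (k in 2:w) {
      score <- score + Wvec[(k - 1L) * 5L + enc[, j + k - 1]]
    }
    hit <- score >= threshold & (j + w - 1) <= lengths
    if (any(hit)) {
      out[[j]] <- tibble(seq_index = which(hit), position = j - 1L,
                         strand = strand, score = score[hit])
    }
  }
  bind_rows(proto, out)
}

#' Scan sequences with a PWM
#'
#' Scores every window of every sequence on both strands with the motif's
#' log-odds matrix; a hit is a window scoring at least the threshold.
#' Positions are 0-based window starts in plus-strand coordinates;
#' windows containing non-ACGT bases never match. Sequences shorter than
#' the motif yield no hits (no error).
#'
#' @param sequences a `DNAStringSet` or named character vector.
#' @param motif a [motif_model()].
#' @param threshold log-odds cutoff; defaults to the motif's
#'   `score_threshold`.
#' @return tibble with `seq_name`, `position`, `strand` (`"+"`/`"-"`),
#'   `score`.
#' @export
scan_pwm <- function(sequences, motif, threshold = NULL) {
  stopifnot(inherits(motif, "motif_model"))
  threshold <- threshold %||% motif$score_threshold
  names_in <- names(sequences) %||% as.character(seq_along(sequences))
  e <- encode_sequences(sequences)
  W <- motif$pwm
  # reverse complement of the PWM: complement bases, reverse positions
  W_rc <- W[4:1, ncol(W):1, drop = FALSE]
  hits <- bind_rows(
    scan_encoded(e$enc, e$lengths, W, threshold, "+"),
    scan_encoded(e$enc, e$lengths, W_rc, threshold, "-")
  )
  hits <- hits[order(hits$seq_index, hits$position, hits$strand,
                     method = "radix"), , drop = FALSE]
  tibble(seq_name = names_in[hits$seq_index],
         position = hits$position, strand = hits$strand, score = hits$score)
}

#' Motif match matrix over peak sequences
#'
#' @param sequences peak sequences (`DNAStringSet` or character), one per
#'   peak, names = peak ids.
#' @param motifs list of [motif_model()] objects.
#' @param threshold optional shared log-odds cutoff.
#' @return logical peaks x motifs matrix: `TRUE` where the peak carries
#'   >= 1 hit.
#' @export
motif_matches <- function(sequences, motifs, threshold = NULL) {
  ids <- names(sequences) %||% as.character(seq_along(sequences))
  m <- matrix(FALSE, nrow = length(sequences), ncol = length(motifs),
              dimnames = list(ids, vapply(motifs, `[[`, "", "name")))
  e <- encode_sequences(sequences)  # encode once, scan every motif on it
  for (j in seq_along(motifs)) {
    mt <- motifs[[j]]
    thr <- threshold %||% mt$score_threshold
    W <- mt$pwm
    W_rc <- W[4:1, ncol(W):1, drop = FALSE]
    h <- bind_rows(scan_encoded(e$enc, e$lengths, W, thr, "+"),
                   scan_encoded(e$enc, e$lengths, W_rc, thr, "-"))
    if (nrow(h)) m[unique(h$seq_index), j] <- TRUE
  }
  m
}

#' GC fraction of sequences
#'
#' (G + C) / (number of non-N bases); sequences with no called bases give
#' `NA`.
#'
#' @param sequences a `DNAStringSet` or character vector.
#' @return numeric vector of GC fractions.
#' @export
gc_content <- function(sequences) {
  if (!methods::is(sequences, "DNAStringSet")) {
    sequences <- Biostrings::DNAStringSet(sequences)
  }
  af <- Biostrings::alphabetFrequency(sequences, baseOnly = TRUE)
  called <- rowSums(af[, DNA_BASES, drop = FALSE])
  out <- unname((af[, "C"] + af[, "G"]) / called)
  out[called == 0] <- NA_real_
  names(out) <- names(sequences)
  out
}

#' Extract peak sequences from a genome
#'
#' @param peaks peak tibble (`chrom`, `start`, `end`, 0-based half-open).
#' @param genome a `DNAStringSet` of chromosome sequences.
#' @return a `DNAStringSet` named by peak id.
#' @export
get_peak_sequences <- function(peaks, genome) {
  lens <- setNames(Biostrings::width(genome), names(genome))
  if (any(!peaks$chrom %in% names(genome)) ||
      any(peaks$start < 0) || any(peaks$end > lens[peaks$chrom])) {
    abort("peak outside the genome")
  }
  seqs <- vector("list", length(genome))
  names(seqs) <- names(genome)
  out <- Biostrings::DNAStringSet(rep("", nrow(peaks)))
  for (chr in unique(peaks$chrom)) {
    i <- which(peaks$chrom == chr)
    out[i] <- Biostrings::extractAt(
      genome[[chr]],
      IRanges::IRanges(start = peaks$start[i] + 1L, end = peaks$end[i])
    )
  }
  names(out) <- col_or(peaks, "peak_id", peak_ids(peaks))
  out
}

#' Background peaks matched on GC and mean accessibility
#'
#' For each peak, samples `n_bg` peaks (with replacement) from its
#' neighbourhood in the standardized (GC, mean accessibility) plane,
#' with Gaussian-kernel weights over the standardized Euclidean distance.
#' Used to background-correct motif deviations for sequence-composition
#' and abundance bias. Deterministic under `seed`.
#'
#' @param gc per-peak GC fraction.
#' @param mean_access per-peak mean accessibility (e.g. row means of the
#'   raw counts).
#' @param n_bg background peaks sampled per peak.
#' @param bandwidth Gaussian kernel bandwidth in standardized units.
#' @param seed RNG seed.
#' @return integer peaks x `n_bg` matrix of peak indices.
#' @export
background_peaks <- function(gc, mean_access, n_bg = 50, bandwidth = 0.1,
                             seed = 1) {
  n <- length(gc)
  if (n < n_bg) abort("need at least n_bg peaks")
  stopifnot(length(mean_access) == n)
  zstd <- function(x) {
    s <- sd(x)
    if (!is.finite(s) || s == 0) rep(0, length(x)) else (x - mean(x)) / s
  }
  gz <- zstd(gc)
  az <- zstd(mean_access)
  degenerate <- all(gz == 0) && all(az == 0)
  if (degenerate) warn("all peaks have identical features; uniform background sampling")
  with_seed(seed, {
    out <- matrix(0L, nrow = n, ncol = n_bg)
    chunk <- 1000L
    for (from in seq(1L, n, by = chunk)) {
      to <- min(from + chunk - 1L, n)
      if (degenerate) {
        out[from:to, ] <- matrix(sample.int(n, (to - from + 1L) * n_bg, replace = TRUE),
                                 ncol = n_bg)
        next
      }
      d2 <- outer(gz[from:to], gz, "-")^2 + outer(az[from:to], az, "-")^2
      wts <- exp(-d2 / (2 * bandwidth^2))
      for (i in seq_len(to - from + 1L)) {
        w <- wts[i, ]
        if (sum(w) <= 0) w <- rep(1, n)
        out[from + i - 1L, ] <- sample.int(n, n_bg, replace = TRUE, prob = w)
      }
    }
    out
  })
}

#' Motif deviation z-scores (motif scores)
#'
#' For motif m and sample j, the expected in-motif count under a
#' no-bias model is `E_mj = (sum of matched peaks' row totals / grand
#' total) * column total_j`; the raw deviation is `(X_mj - E_mj) / E_mj`
#' with `X_mj` the observed in-motif count. Each of the `n_bg` background
#' sets substitutes every matched peak with its GC/accessibility-matched
#' sampled peak, and the motif score is the background-corrected z:
#' `z = (raw_dev - mean(bg raw_dev)) / sd(bg raw_dev)`.
#'
#' @param raw a raw `accessibility_matrix`.
#' @param matches logical peaks x motifs matrix ([motif_matches()]);
#'   rows must align with the matrix regions.
#' @param background peaks x n_bg index matrix ([background_peaks()]).
#' @return a `motif_deviations` object: `raw_dev` and `z` (motifs x
#'   samples matrices).
#' @export
motif_deviations <- function(raw, matches, background) {
  stopifnot(inherits(raw, "accessibility_matrix"))
  values <- raw$values
  if (nrow(matches) != nrow(values)) abort("matches and counts must share the peak index")
  storage.mode(matches) <- "double"
  row_tot <- rowSums(values)
  col_tot <- colSums(values)
  grand <- sum(row_tot)
  dev_of <- function(idx_values, idx_rowtot) {
    X <- crossprod(matches, idx_values)
    E <- (crossprod(matches, idx_rowtot) / grand) %*% t(col_tot)
    (X - E) / E
  }
  raw_dev <- dev_of(values, row_tot)
  if (any(!is.finite(raw_dev))) {
    warn("motifs with zero expected counts flagged as missing (NA)")
    raw_dev[!is.finite(raw_dev)] <- NA_real_
  }
  n_bg <- ncol(background)
  acc <- matrix(0, nrow = ncol(matches), ncol = ncol(values))
  acc2 <- acc
  for (b in seq_len(n_bg)) {
    idx <- background[, b]
    dev_b <- dev_of(values[idx, , drop = FALSE], row_tot[idx])
    acc <- acc + dev_b
    acc2 <- acc2 + dev_b^2
  }
  bg_mean <- acc / n_bg
  bg_sd <- sqrt(pmax(acc2 / n_bg - bg_mean^2, 0) * n_bg / (n_bg - 1))
  z <- (raw_dev - bg_mean) / bg_sd
  dimnames(raw_dev) <- dimnames(z) <- list(colnames(matches), colnames(values))
  structure(list(raw_dev = raw_dev, z = z, n_bg = n_bg),
            class = "motif_deviations")
}

#' @export
print.motif_deviations <- function(x, ...) {
  cat(sprintf("<motif_deviations> %d motifs x %d samples (%d background sets)\n",
              nrow(x$z), ncol(x$z), x$n_bg))
  invisible(x)
}

#' Tidy motif deviations into long form
#'
#' @param x a `motif_deviations` object.
#' @param ... unused.
#' @return tibble with `motif`, `sample_id`, `raw_dev`, `z`.
#' @exportS3Method generics::tidy
tidy.motif_deviations <- function(x, ...) {
  tibble(
    motif = rep(rownames(x$z), times = ncol(x$z)),
    sample_id = rep(colnames(x$z), each = nrow(x$z)),
    raw_dev = as.vector(x$raw_dev),
    z = as.vector(x$z)
  )
}

#' GC-matched hypergeometric motif enrichment
#'
#' Tests whether motif-carrying peaks are over-represented in a target
#' peak set against a background of non-target peaks resampled to match
#' the target's GC-bin histogram; the p-value is the hypergeometric upper
#' tail of motif-carrying counts in the pooled (target + matched
#' background) peaks. Motifs are ranked by p-value.
#'
#' @param matches logical peaks x motifs matrix.
#' @param target logical per peak (the tested set).
#' @param gc per-peak GC fraction.
#' @param n_gc_bins number of GC bins for matching.
#' @param bg_ratio matched-background size as a multiple of the target
#'   size.
#' @param seed RNG seed for the background resampling.
#' @return tibble with `motif`, `n_target`, `target_hits`, `n_bg`,
#'   `bg_hits`, `p_value`, sorted ascending by p.
#' @export
motif_enrichment <- function(matches, target, gc, n_gc_bins = 10,
                             bg_ratio = 10, seed = 1) {
  if (!any(target) || all(target)) abort("target and background must both be nonempty")
  breaks <- unique(quantile(gc, probs = seq(0, 1, length.out = n_gc_bins + 1),
                            na.rm = TRUE))
  bin <- cut(gc, breaks = breaks, include.lowest = TRUE, labels = FALSE)
  bg_pool <- which(!target)
  bg_idx <- with_seed(seed, {
    idx <- integer(0)
    for (bb in sort(unique(bin[target]))) {
      want <- sum(target & bin == bb, na.rm = TRUE) * bg_ratio
      pool <- bg_pool[bin[bg_pool] == bb & !is.na(bin[bg_pool])]
      shift <- 1L
      while (!length(pool) && shift <= n_gc_bins) {
        # empty background bin: merge with neighbouring bins
        warn(sprintf("empty background GC bin %d merged with neighbours", bb))
        pool <- bg_pool[!is.na(bin[bg_pool]) & abs(bin[bg_pool] - bb) <= shift]
        shift <- shift + 1L
      }
      idx <- c(idx, sample(pool, want, replace = TRUE))
    }
    idx
  })
  n_t <- sum(target)
  n_b <- length(bg_idx)
  res <- lapply(colnames(matches), function(m) {
    k_t <- sum(matches[target, m])
    k_b <- sum(matches[bg_idx, m])
    p <- phyper(k_t - 1, m = k_t + k_b, n = (n_t + n_b) - (k_t + k_b),
                k = n_t, lower.tail = FALSE)
    tibble(motif = m, n_target = n_t, target_hits = k_t,
           n_bg = n_b, bg_hits = k_b, p_value = p)
  })
  out <- bind_rows(res)
  out[order(out$p_value, out$motif), , drop = FALSE]
}

#' Two-sample Student's t test of motif scores
#'
#' Pooled-variance two-sided t comparison of per-sample motif deviation
#' z-scores between two tumour groups.
#'
#' @param z_group_a,z_group_b numeric vectors (each >= 2 values).
#' @return tibble with `statistic` (t) and `p_value`.
#' @export
motif_score_test <- function(z_group_a, z_group_b) {
  if (length(z_group_a) < 2 || length(z_group_b) < 2) {
    abort("each group needs at least 2 values")
  }
  pooled_var <- (sum((z_group_a - mean(z_group_a))^2) +
                   sum((z_group_b - mean(z_group_b))^2)) /
    (length(z_group_a) + length(z_group_b) - 2)
  if (pooled_var == 0) abort("zero pooled variance; t statistic undefined")
  res <- t.test(z_group_a, z_group_b, var.equal = TRUE)
  tibble(statistic = unname(res$statistic), p_value = res$p.value)
}
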