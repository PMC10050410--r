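#' Quality-control parameters
#'
#' Windows and thresholds of the library QC statistics: the TSS profile is
#' built over +/- `tss_window` bp of each strand-corrected TSS, normalized
#' by the mean of the `flank_band` bins, smoothed with a centred
#' `smooth_window`-bp rolling mean, and scored as the maximum within
#' +/- `center_band` bp; libraries pass at `tss_min`. Fragments shorter
#' than `nfr_max_len` bp (strict) are nucleosome-free.
#'
#' @param tss_window half-width of the TSS profile, bp.
#' @param flank_band distance band (bp) used as background, inclusive.
#' @param smooth_window rolling-mean width, bp (odd).
#' @param center_band half-width of the scored centre, bp.
#' @param tss_min minimum passing TSS enrichment score.
#' @param nfr_max_len strict upper bound of nucleosome-free fragment
#'   length, bp.
#' @return a list of validated parameters.
#' @export
qc_params <- function(tss_window = 2000, flank_band = c(1900, 2000),
                      smooth_window = 51, center_band = 50,
                      tss_min = 5, nfr_max_len = 100) {
  if (smooth_window %% 2 != 1) stop_config("smooth_window", "must be odd")
  if (flank_band[2] > tss_window) stop_config("flank_band", "must lie within tss_window")
  list(tss_window = tss_window, flank_band = flank_band,
       smooth_window = smooth_window, center_band = center_band,
       tss_min = tss_min, nfr_max_len = nfr_max_len)
}

# truncated centred rolling mean (window shrinks at the profile edges)
rolling_mean_truncated <- function(x, window) {
  half <- (window - 1) / 2
  n <- length(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

#' TSS enrichment score per sample
#'
#' For every insertion within +/- `tss_window` bp of a TSS the signed,
#' strand-corrected distance is binned at single-base resolution and
#' summed over all TSSs. The profile is normalized by the mean of the
#' flank bins (|d| in `flank_band`), smoothed with a truncated centred
#' rolling mean, and the score is the maximum smoothed enrichment within
#' +/- `center_band` bp of the TSS. A flat (uniform) insertion profile
#' scores ~1; well-enriched ATAC libraries score >= `tss_min`.
#'
#' @param insertions insertion tibble (`chrom`, `position`, `sample_id`).
#' @param tss_catalog tibble with `chrom`, `position`, `strand`.
#' @param params see [qc_params()].
#' @return tibble with `sample_id`, `tss_enrichment`, `pass` (score >=
#'   `tss_min`); the per-sample smoothed profiles are attached as
#'   attribute `"profile"` (distance x sample matrix) for plotting.
#' @export
tss_enrichment <- function(insertions, tss_catalog, params = qc_params()) {
  if (!nrow(tss_catalog)) abort("empty TSS catalog")
  if (!nrow(insertions)) abort("no insertions supplied")
  w <- params$tss_window
  tss_gr <- GenomicRanges::GRanges(
    tss_catalog$chrom,
    IRanges::IRanges(start = pmax(tss_catalog$position + 1L - w, 1L),
                     end = tss_catalog$position + 1L + w)
  )
  ins_gr <- positions_to_gr(insertions$chrom, insertions$position)
  h <- GenomicRanges::findOverlaps(ins_gr, tss_gr)
  qi <- S4Vectors::queryHits(h)
  si <- S4Vectors::subjectHits(h)
  d <- insertions$position[qi] - tss_catalog$position[si]
  flip <- tss_catalog$strand[si] == "-"
  d[flip] <- -d[flip]
  ok <- abs(d) <= w
  d <- d[ok]
  samp <- insertions$sample_id[qi][ok]

  samples <- sort(unique(insertions$sample_id))
  bins <- seq(-w, w)
  flank_idx <- which(abs(bins) >= params$flank_band[1] & abs(bins) <= params$flank_band[2])
  center_idx <- which(abs(bins) <= params$center_band)

  profiles <- matrix(0, nrow = length(bins), ncol = length(samples),
                     dimnames = list(bins, samples))
  scores <- numeric(length(samples))
  for (k in seq_along(samples)) {
    prof <- tabulate(d[samp == samples[k]] + w + 1L, nbins = length(bins))
    flank <- mean(prof[flank_idx])
    if (flank <= 0) {
      abort(sprintf("TSS enrichment undefined for sample %s: zero flank signal",
                    samples[k]))
    }
    sm <- rolling_mean_truncated(prof / flank, params$smooth_window)
    profiles[, k] <- sm
    scores[k] <- max(sm[center_idx])
  }
  out <- tibble(sample_id = samples, tss_enrichment = scores,
                pass = scores >= params$tss_min)
  attr(out, "profile") <- profiles
  out
}

#' Fragment length histogram
#'
#' Exact counts per integer fragment length; lengths above `max_len` are
#' pooled into the top bin (flagged `pooled`). The histogram of an ATAC
#' library shows the sub-nucleosomal peak and the mono-nucleosome bump
#' (nucleosomal periodicity).
#'
#' @param fragments fragment tibble.
#' @param max_len pooling bound, bp.
#' @return tibble with `length`, `count`, `pooled`, one row per observed
#'   length; empty input gives an empty tibble.
#' @export
fragment_length_histogram <- function(fragments, max_len = 1000) {
  if (!nrow(fragments)) {
    return(tibble(length = integer(), count = integer(), pooled = logical()))
  }
  width <- fragments$end - fragments$start
  pooled <- width > max_len
  width <- pmin(width, max_len)
  tab <- table(width)
  tibble(
    length = as.integer(names(tab)),
    count = as.integer(tab),
    pooled = as.integer(names(tab)) == max_len & any(pooled)
  )
}

#' Select nucleosome-free fragments
#'
#' Retains fragments strictly shorter than `max_len` bp (default 100),
#' presumed to span open DNA between nucleosomes. The harmonization and
#' counting pipeline can be re-run on this subset (nucleosome-free
#' re-analysis).
#'
#' @param fragments fragment tibble.
#' @param max_len strict length bound, bp.
#' @return the retained fragments.
#' @export
select_nucleosome_free <- function(fragments, max_len = 100) {
  fragments[(fragments$end - fragments$start) < max_len, , drop = FALSE]
}
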