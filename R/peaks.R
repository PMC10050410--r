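#' Extend summit calls to fixed-width peaks
#'
#' Each summit is extended by `half_width` bp on both sides, giving
#' fixed-width peaks of `2 * half_width + 1` bp (501 bp at the default),
#' in 0-based half-open coordinates: `[summit - half_width, summit +
#' half_width + 1)`. Peaks that would run off a chromosome end are clipped
#' and flagged (`clipped = TRUE`); clipped peaks are later excluded from
#' the merged cross-sample set so the fixed-width invariant holds there.
#'
#' @param summits tibble with `chrom`, `summit` (0-based bp), `score`, and
#'   optionally `sample_id`.
#' @param half_width extension on each side of the summit, bp.
#' @param chrom_sizes named vector of chromosome lengths (bp). Summits
#'   outside their chromosome are an error.
#' @return a peak tibble: `chrom`, `start`, `end`, `summit`, `score`,
#'   `sample_id`, `clipped`, sorted by coordinate.
#' @export
extend_summits <- function(summits, half_width = 250, chrom_sizes) {
  stopifnot(all(c("chrom", "summit", "score") %in% names(summits)))
  sizes <- chrom_sizes[summits$chrom]
  if (any(is.na(sizes))) {
    abort(sprintf("summit on unknown chromosome: %s",
                  paste(unique(summits$chrom[is.na(sizes)]), collapse = ", ")))
  }
  if (any(summits$summit < 0 | summits$summit >= sizes)) {
    abort("summit position outside chromosome bounds")
  }
  start <- summits$summit - half_width
  end <- summits$summit + half_width + 1L
  clipped <- start < 0L | end > sizes
  out <- tibble(
    chrom = summits$chrom,
    start = as.integer(pmax(start, 0L)),
    end = as.integer(pmin(end, sizes)),
    summit = as.integer(summits$summit),
    score = as.numeric(summits$score),
    sample_id = col_or(summits, "sample_id", rep(NA_character_, nrow(summits))),
    clipped = clipped
  )
  out[radix_order(out$chrom, out$start, out$end), , drop = FALSE]
}

#' Remove peaks overlapping a blacklist
#'
#' Drops every peak sharing at least 1 bp with any blacklist interval
#' (half-open semantics). An empty blacklist is the identity.
#'
#' @param peaks peak tibble (`chrom`, `start`, `end`, ...).
#' @param blacklist interval tibble (`chrom`, `start`, `end`).
#' @return the retained peaks.
#' @export
filter_blacklist <- function(peaks, blacklist) {
  if (is.null(blacklist) || nrow(blacklist) == 0) return(peaks)
  hits <- GenomicRanges::countOverlaps(
    intervals_to_gr(peaks), intervals_to_gr(blacklist)
  )
  peaks[hits == 0L, , drop = FALSE]
}

#' Iterative overlap removal
#'
#' The greedy fixed-width peak selection rule: repeatedly keep the
#' highest-ranked remaining peak and discard every peak overlapping it
#' (>= 1 shared bp), until no peaks remain. Equivalently, peaks are
#' processed in rank order and kept iff they do not overlap an
#' already-kept peak. Ties in the ranking value are broken by
#' (chrom, start, end), which makes the result deterministic and
#' independent of input order.
#'
#' The implementation iterates a vectorized "local winner" rule: a peak is
#' kept when its priority is the best among all remaining peaks it
#' overlaps; peaks overlapping a winner are then removed and the rule is
#' reapplied to the remainder. This fixed point equals the greedy result.
#'
#' @param peaks peak tibble.
#' @param rank_by column used as ranking value: `"score"` (within-sample
#'   pass) or `"spm"` (cross-sample pass). Higher is better.
#' @return the mutually non-overlapping kept peaks, sorted by coordinate.
#' @export
iterative_overlap_removal <- function(peaks, rank_by = c("score", "spm")) {
  rank_by <- match.arg(rank_by)
  if (!rank_by %in% names(peaks)) {
    abort(sprintf("ranking column '%s' missing from peaks", rank_by))
  }
  n <- nrow(peaks)
  if (n <= 1) return(peaks)
  # priority 1 = best; deterministic tie-break on coordinates
  prio <- integer(n)
  prio[radix_order(-peaks[[rank_by]], peaks$chrom, peaks$start, peaks$end)] <- seq_len(n)

  gr <- intervals_to_gr(peaks)
  remaining <- seq_len(n)
  keep <- logical(n)
  while (length(remaining)) {
    sub <- gr[remaining]
    h <- GenomicRanges::findOverlaps(sub, sub)
    q <- S4Vectors::queryHits(h)
    s <- S4Vectors::subjectHits(h)
    # best (minimum) priority among each peak's overlap neighbourhood
    # (self-hits guarantee every peak appears as a query)
    prio_rem <- prio[remaining]
    best <- tapply(prio_rem[s], q, min)
    best <- unname(best[as.character(seq_along(remaining))])
    winners_local <- which(prio_rem == best)
    winners <- remaining[winners_local]
    keep[winners] <- TRUE
    # drop winners and everything overlapping them
    dead_local <- unique(q[s %in% winners_local])
    remaining <- remaining[-unique(c(winners_local, dead_local))]
  }
  out <- peaks[keep, , drop = FALSE]
  out[radix_order(out$chrom, out$start, out$end), , drop = FALSE]
}

#' Score-per-million normalization of peak scores
#'
#' Each peak's caller score is divided by the sum of all peak scores in
#' its sample divided by one million:
#' `spm_i = score_i / (sum_j score_j / 1e6)`, so SPM values sum to 1e6
#' within a sample and are comparable across samples of different depth.
#'
#' @param peaks peak tibble with `score` and (optionally) `sample_id`;
#'   normalization is per sample when `sample_id` is present.
#' @return peaks with an added/overwritten `spm` column.
#' @export
score_per_million <- function(peaks) {
  grp <- col_or(peaks, "sample_id", rep("sample", nrow(peaks)))
  totals <- tapply(peaks$score, grp, sum)
  if (any(totals <= 0)) {
    abort("score-per-million undefined: a sample has non-positive total score")
  }
  peaks$spm <- peaks$score / (totals[grp] / 1e6)
  peaks$spm <- as.numeric(peaks$spm)
  peaks
}

#' Merge per-sample peak sets into a reproducible fixed-width CRE set
#'
#' Pools the per-sample non-overlapping peak sets, repeats iterative
#' overlap removal across samples ranked by score-per-million, then keeps
#' peaks with `spm >= min_spm` that are supported by at least
#' `min_support` distinct samples (a peak's own source sample counts;
#' support is counted against the pre-merge per-sample sets). Clipped
#' (boundary-truncated) peaks and peaks on excluded chromosomes are
#' dropped.
#'
#' @param sample_sets list of per-sample peak tibbles, each already
#'   within-sample non-overlapping with `spm` assigned.
#' @param min_spm minimum score-per-million of a retained peak.
#' @param min_support minimum number of distinct supporting samples.
#' @param exclude_chroms chromosomes removed outright (the sex chromosome
#'   Y by default, matching the reproducible-set construction).
#' @return merged peak tibble with `support` and `peak_id` columns.
#' @export
merge_across_samples <- function(sample_sets, min_spm = 5, min_support = 2,
                                 exclude_chroms = "chrY") {
  if (length(sample_sets) < 2) {
    abort("merging requires at least 2 sample peak sets")
  }
  pooled <- bind_rows(sample_sets)
  if (!"spm" %in% names(pooled)) abort("sample sets must carry 'spm' (run score_per_million())")
  if ("clipped" %in% names(pooled)) pooled <- pooled[!pooled$clipped, , drop = FALSE]
  pooled <- pooled[!pooled$chrom %in% exclude_chroms, , drop = FALSE]
  merged <- iterative_overlap_removal(pooled, rank_by = "spm")

  # support: distinct pre-merge samples whose peaks overlap the survivor
  gr <- intervals_to_gr(merged)
  support <- integer(nrow(merged))
  for (s in sample_sets) {
    s <- s[!s$chrom %in% exclude_chroms, , drop = FALSE]
    if (!nrow(s)) next
    support <- support +
      (GenomicRanges::countOverlaps(gr, intervals_to_gr(s)) > 0L)
  }
  merged$support <- support
  merged <- merged[merged$spm >= min_spm & merged$support >= min_support, , drop = FALSE]
  merged$sample_id <- "merged"
  merged$peak_id <- peak_ids(merged)
  merged
}
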