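#' Annotate peaks as promoter or distal
#'
#' Measures the signed, strand-aware distance from each peak summit to the
#' nearest TSS (positive = downstream of the TSS in its reading
#' direction) and classifies peaks within +/- `promoter_dist` bp
#' (inclusive) as promoters; everything else is distal.
#'
#' @param peaks merged peak tibble with `summit` and `peak_id`.
#' @param tss tibble with `chrom`, `position`, `strand`, `gene_name`.
#' @param promoter_dist promoter window half-width, bp (inclusive).
#' @return annotation tibble: `peak_id`, `chrom`, `start`, `end`,
#'   `summit`, `class` (`"promoter"`/`"distal"`), `tss_distance` (signed
#'   bp; `NA` when the chromosome has no TSS), `nearest_gene`.
#' @export
annotate_peaks <- function(peaks, tss, promoter_dist = 1000) {
  if (!nrow(tss)) abort("empty TSS catalog")
  ids <- col_or(peaks, "peak_id", peak_ids(peaks))
  dist <- rep(NA_real_, nrow(peaks))
  gene <- rep(NA_character_, nrow(peaks))
  for (chr in unique(peaks$chrom)) {
    pk_i <- which(peaks$chrom == chr)
    ts <- tss[tss$chrom == chr, , drop = FALSE]
    if (!nrow(ts)) next
    ord <- radix_order(ts$position)
    ts <- ts[ord, , drop = FALSE]
    pos <- ts$position
    s <- peaks$summit[pk_i]
    # nearest sorted TSS via binary placement
    right <- findInterval(s, pos) + 1L
    left <- right - 1L
    dl <- ifelse(left >= 1, abs(s - pos[pmax(left, 1L)]), Inf)
    dr <- ifelse(right <= length(pos), abs(s - pos[pmin(right, length(pos))]), Inf)
    use_left <- dl <= dr  # tie -> lower-coordinate TSS, deterministic
    idx <- ifelse(use_left, left, right)
    signed <- s - pos[idx]
    signed[ts$strand[idx] == "-"] <- -signed[ts$strand[idx] == "-"]
    dist[pk_i] <- signed
    gene[pk_i] <- ts$gene_name[idx]
  }
  tibble(
    peak_id = ids,
    chrom = peaks$chrom, start = peaks$start, end = peaks$end,
    summit = peaks$summit,
    class = ifelse(!is.na(dist) & abs(dist) <= promoter_dist, "promoter", "distal"),
    tss_distance = dist,
    nearest_gene = gene
  )
}

#' Overlap peaks with reference CRE sets
#'
#' Flags each peak that shares >= 1 bp with any interval of each named
#' reference set (e.g. TME cell-type-specific CREs from single-cell
#' ATAC).
#'
#' @param peaks merged peak tibble.
#' @param refs named list of interval tibbles (`chrom`, `start`, `end`),
#'   one per cell type.
#' @return tibble with `peak_id`, one logical column per reference set,
#'   and `any_tme` (overlap with any set).
#' @export
overlap_reference_sets <- function(peaks, refs) {
  ids <- col_or(peaks, "peak_id", peak_ids(peaks))
  gr <- intervals_to_gr(peaks)
  out <- tibble(peak_id = ids)
  for (name in names(refs)) {
    out[[name]] <- GenomicRanges::countOverlaps(gr, intervals_to_gr(refs[[name]])) > 0L
  }
  flag_cols <- setdiff(names(out), "peak_id")
  out$any_tme <- if (length(flag_cols)) {
    Reduce(`|`, out[flag_cols])
  } else rep(FALSE, nrow(out))
  out
}

#' Derive distal cancer CREs
#'
#' The tumour-intrinsic regulatory repertoire: peaks that are neither
#' promoters (within the TSS window) nor overlapping any TME-specific
#' reference CRE.
#'
#' @param annotation output of [annotate_peaks()].
#' @param overlaps output of [overlap_reference_sets()] (same peaks).
#' @return the retained subset of `annotation`, with `is_distal_cancer =
#'   TRUE`.
#' @export
derive_distal_cancer_cres <- function(annotation, overlaps) {
  joined <- left_join(annotation, overlaps[, c("peak_id", "any_tme")], by = "peak_id")
  out <- joined[joined$class == "distal" & !joined$any_tme, , drop = FALSE]
  out$is_distal_cancer <- TRUE
  out
}

#' TME deconvolution score
#'
#' Per sample, the mean normalized accessibility over the peaks
#' overlapping one reference cell-type CRE set — an estimate of that cell
#' type's infiltration/activity in the bulk tumour.
#'
#' @param norm a normalized `accessibility_matrix`.
#' @param overlaps output of [overlap_reference_sets()].
#' @param set_name which reference set to score.
#' @return tibble with `sample_id`, `set`, `score`.
#' @export
deconvolution_score <- function(norm, overlaps, set_name) {
  stopifnot(inherits(norm, "accessibility_matrix"))
  if (!set_name %in% names(overlaps)) {
    abort(sprintf("unknown reference set '%s'", set_name))
  }
  flagged <- overlaps$peak_id[overlaps[[set_name]]]
  rows <- intersect(rownames(norm$values), flagged)
  if (!length(rows)) {
    abort(sprintf("no peaks overlap reference set '%s'", set_name))
  }
  vals <- norm$values[rows, , drop = FALSE]
  tibble(sample_id = colnames(vals), set = set_name, score = colMeans(vals))
}

#' Wilcoxon rank-sum test
#'
#' Two-sided Mann-Whitney U comparison of two groups; exact enumeration
#' when both groups have <= 8 observations and no ties, otherwise the
#' tie-corrected normal approximation (without continuity correction).
#'
#' @param values_a,values_b numeric vectors (each nonempty).
#' @return tibble with `statistic` (U for the first group) and `p_value`.
#' @export
rank_sum_test <- function(values_a, values_b) {
  if (!length(values_a) || !length(values_b)) abort("both groups must be nonempty")
  pooled <- c(values_a, values_b)
  if (length(unique(pooled)) == 1) {
    # fully tied data carry no ordering information
    return(tibble(statistic = length(values_a) * length(values_b) / 2,
                  p_value = 1))
  }
  no_ties <- !anyDuplicated(pooled)
  exact <- length(values_a) <= 8 && length(values_b) <= 8 && no_ties
  res <- suppressWarnings(
    wilcox.test(values_a, values_b, exact = exact, correct = FALSE)
  )
  tibble(statistic = unname(res$statistic), p_value = res$p.value)
}

#' Fisher's exact test of interval-set overlap
#'
#' Cross-tabulates the universe intervals by (overlaps set A) x
#' (overlaps set B) and applies the two-sided hypergeometric exact test —
#' the interval analogue of a bedtools-style overlap significance test.
#' The universe is normally the merged peak set.
#'
#' @param set_a,set_b interval tibbles.
#' @param universe interval tibble covering the tested space.
#' @return tibble with the 2x2 table cells (`n11` overlaps both ...
#'   `n00` overlaps neither), `odds_ratio` and `p_value`.
#' @export
overlap_fisher <- function(set_a, set_b, universe) {
  if (!nrow(universe)) abort("empty universe")
  gr_u <- intervals_to_gr(universe)
  in_a <- GenomicRanges::countOverlaps(gr_u, intervals_to_gr(set_a)) > 0L
  in_b <- GenomicRanges::countOverlaps(gr_u, intervals_to_gr(set_b)) > 0L
  tab <- table(factor(in_a, c(TRUE, FALSE)), factor(in_b, c(TRUE, FALSE)))
  ft <- fisher.test(tab, alternative = "two.sided")
  tibble(
    n11 = tab[1, 1], n10 = tab[1, 2], n01 = tab[2, 1], n00 = tab[2, 2],
    odds_ratio = unname(ft$estimate), p_value = ft$p.value
  )
}
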