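#' Accessibility matrix container
#'
#' A light S3 wrapper around a regions x samples matrix of Tn5 insertion
#' counts (or normalized values), carrying per-sample library sizes and
#' the normalization state (`"raw"`, `"logcpm"` or `"logcpm_quantile"`).
#'
#' @param values numeric matrix, regions in rows (rownames = region ids),
#'   samples in columns.
#' @param lib_sizes per-sample totals; defaults to column sums.
#' @param state normalization state.
#' @return an `accessibility_matrix` object.
#' @export
accessibility_matrix <- function(values,
                                 lib_sizes = colSums(values),
                                 state = c("raw", "logcpm", "logcpm_quantile")) {
  state <- match.arg(state)
  if (state == "raw" && (any(values < 0) || any(values != floor(values)))) {
    abort("raw accessibility values must be nonnegative integers")
  }
  structure(
    list(values = values, lib_sizes = lib_sizes, state = state),
    class = "accessibility_matrix"
  )
}

#' @export
print.accessibility_matrix <- function(x, ...) {
  cat(sprintf("<accessibility_matrix> %d regions x %d samples [%s]\n",
              nrow(x$values), ncol(x$values), x$state))
  invisible(x)
}

#' @export
dim.accessibility_matrix <- function(x) dim(x$values)

#' Tidy an accessibility matrix into long form
#'
#' @param x an `accessibility_matrix`.
#' @param ... unused.
#' @return tibble with `region`, `sample_id`, `value`.
#' @exportS3Method generics::tidy
tidy.accessibility_matrix <- function(x, ...) {
  tibble(
    region = rep(rownames(x$values), times = ncol(x$values)),
    sample_id = rep(colnames(x$values), each = nrow(x$values)),
    value = as.vector(x$values)
  )
}

#' @exportS3Method generics::glance
glance.accessibility_matrix <- function(x, ...) {
  tibble(
    n_regions = nrow(x$values), n_samples = ncol(x$values),
    state = x$state,
    median_lib_size = stats::median(x$lib_sizes)
  )
}

#' Tn5 offset correction of fragment ends
#'
#' Converts paired-end ATAC fragments to single-base transposition events.
#' The Tn5 dimer inserts with a 9-bp duplication, so read starts are
#' shifted +4 bp on the plus strand and -5 bp on the minus strand; for a
#' fragment `[start, end)` the left end behaves as a plus-strand read
#' start and the right end as a minus-strand one, giving insertions at
#' `start + 4` and `end - 5`. Fragments of width <= 9 bp (whose corrected
#' ends would cross) are skipped with a warning.
#'
#' @param fragments tibble with `chrom`, `start`, `end` (0-based
#'   half-open) and `sample_id`.
#' @return insertion tibble: `chrom`, `position` (0-based), `sample_id`;
#'   two rows per retained fragment.
#' @export
correct_insertions <- function(fragments) {
  width <- fragments$end - fragments$start
  if (any(width <= 0)) abort("fragments must satisfy end > start")
  short <- width <= 9L
  if (any(short)) {
    warn(sprintf("skipping %d fragments of width <= 9 bp (corrected ends would cross)",
                 sum(short)))
    fragments <- fragments[!short, , drop = FALSE]
  }
  tibble(
    chrom = rep(fragments$chrom, 2L),
    position = c(fragments$start + 4L, fragments$end - 5L),
    sample_id = rep(fragments$sample_id, 2L)
  )
}

#' Count Tn5 insertions in peaks
#'
#' Cell (i, j) is the number of sample-j insertion events with position in
#' `[start_i, end_i)` of peak i (half-open). Library sizes are the column
#' sums over peaks (in-peak insertions).
#'
#' @param insertions insertion tibble from [correct_insertions()].
#' @param peaks non-overlapping merged peak tibble with `peak_id`.
#' @param sample_ids optional vector fixing the sample (column) order.
#' @return a raw `accessibility_matrix`.
#' @export
count_insertions <- function(insertions, peaks, sample_ids = NULL) {
  ids <- col_or(peaks, "peak_id", peak_ids(peaks))
  sample_ids <- sample_ids %||% sort(unique(insertions$sample_id))
  gr_pk <- intervals_to_gr(peaks)
  gr_in <- positions_to_gr(insertions$chrom, insertions$position)
  h <- GenomicRanges::findOverlaps(gr_in, gr_pk)
  tab <- table(
    factor(S4Vectors::subjectHits(h), levels = seq_len(nrow(peaks))),
    factor(insertions$sample_id[S4Vectors::queryHits(h)], levels = sample_ids)
  )
  values <- matrix(as.integer(tab), nrow = nrow(peaks),
                   dimnames = list(ids, sample_ids))
  accessibility_matrix(values, state = "raw")
}

#' Log-CPM and quantile normalization of a counts matrix
#'
#' Stage 1 computes log2 counts-per-million with a library-size-adjusted
#' prior: with `p_j = prior_count * L_j / mean(L)`,
#' `value = log2((x + p_j) / (L_j + 2 p_j) * 1e6)` (the `cpm(log = TRUE,
#' prior.count = 5)` convention). Stage 2 quantile-normalizes across
#' samples: each column's order statistics are replaced by the
#' across-column mean of order statistics, preserving ranks and averaging
#' ties, so afterwards every column has an identical sorted-value vector.
#'
#' @param raw a raw `accessibility_matrix`.
#' @param prior_count prior count before the log (default 5).
#' @return an `accessibility_matrix` in state `"logcpm_quantile"`.
#' @export
normalize_matrix <- function(raw, prior_count = 5) {
  stopifnot(inherits(raw, "accessibility_matrix"))
  if (raw$state != "raw") abort("normalize_matrix() expects a raw counts matrix")
  if (any(raw$lib_sizes <= 0)) abort("zero library size; cannot normalize")
  lc <- edgeR::cpm(raw$values, lib.size = raw$lib_sizes,
                   log = TRUE, prior.count = prior_count)
  qn <- limma::normalizeQuantiles(lc, ties = TRUE)
  dimnames(qn) <- dimnames(raw$values)
  accessibility_matrix(qn, lib_sizes = raw$lib_sizes, state = "logcpm_quantile")
}
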