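#' @importFrom rlang abort warn inform %||%
#' @importFrom dplyr mutate filter select arrange group_by ungroup summarise
#'   bind_rows left_join n across all_of row_number desc
#' @importFrom tibble tibble as_tibble
#' @importFrom stats rnorm rpois rexp rnbinom runif rbinom median var sd
#'   p.adjust fisher.test wilcox.test t.test phyper pchisq hclust cutree
#'   dist kmeans prcomp quantile model.matrix setNames complete.cases
#' @importFrom utils head tail
NULL

# internal: deterministic radix order, independent of locale
radix_order <- function(...) order(..., method = "radix")

# column accessor safe for tibbles (where `$` on a missing column warns)
col_or <- function(df, name, default) {
  if (name %in% names(df)) df[[name]] else default
}

stop_config <- function(field, msg) {
  abort(sprintf("invalid configuration: field '%s' %s", field, msg),
        class = "chromstrat_config_error")
}

check_count <- function(x, field, min = 1) {
  if (length(x) != 1 || !is.finite(x) || x < min || x != floor(x)) {
    stop_config(field, sprintf("must be a single integer >= %s", min))
  }
  as.integer(x)
}

check_fraction <- function(x, field, lo = 0, hi = 1) {
  if (length(x) != 1 || !is.finite(x) || x < lo || x > hi) {
    stop_config(field, sprintf("must be in [%s, %s]", lo, hi))
  }
  as.numeric(x)
}

# row medians / variances without an extra matrix-stats dependency;
# variance uses the n-1 denominator
row_medians <- function(x) apply(x, 1L, stats::median)

row_vars <- function(x) {
  n <- ncol(x)
  if (n < 2) abort("row variance undefined for fewer than 2 samples")
  m <- rowMeans(x)
  rowSums((x - m)^2) / (n - 1)
}

# run code under a temporary RNG state seeded with `seed`, restoring
# the caller's stream afterwards
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# derive independent per-artifact sub-seeds from one master seed, so that
# adding a stream never perturbs earlier ones
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items;
#' 1 means identical partitions, 0 is the expected value under random
#' labelings. Used to compare recovered tumour clusters with planted
#' group labels.
#'
#' @param a,b label vectors of equal length (any atomic type).
#' @return a single number in \[-1, 1\].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

# half-open [start, end) interval tibbles -> GRanges (1-based closed inside)
intervals_to_gr <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1L, end = x$end)
  )
}

positions_to_gr <- function(chrom, position) {
  GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = position + 1L, width = 1L)
  )
}

peak_ids <- function(peaks) {
  sprintf("%s:%d-%d", peaks$chrom, peaks$start, peaks$end)
}
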