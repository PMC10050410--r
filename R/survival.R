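#' Surrogate marker score
#'
#' Per gene of the marker set, expression is standardized across samples
#' (z-score); a sample's score is the mean of the standardized values
#' over the set. Cohort scores therefore average to ~0 and a high score
#' flags samples whose marker expression is jointly elevated. Genes
#' absent from the matrix are reported and skipped; a raw-mean mode is
#' available via `standardize = FALSE`.
#'
#' @param expression genes x samples numeric matrix (log scale).
#' @param gene_set character vector of marker gene names.
#' @param standardize z-score each gene before averaging (default TRUE).
#' @return tibble with `sample_id`, `score`.
#' @export
marker_score <- function(expression, gene_set, standardize = TRUE) {
  present <- intersect(gene_set, rownames(expression))
  missing <- setdiff(gene_set, rownames(expression))
  if (!length(present)) {
    abort(sprintf("no marker genes found in the expression matrix; missing: %s",
                  paste(missing, collapse = ", ")))
  }
  if (length(missing)) {
    inform(sprintf("skipping %d marker genes absent from the matrix: %s",
                   length(missing), paste(missing, collapse = ", ")))
  }
  m <- expression[present, , drop = FALSE]
  if (standardize) {
    m <- t(scale(t(m)))
  }
  tibble(sample_id = colnames(expression), score = unname(colMeans(m)))
}

#' Split samples at a score cutoff
#'
#' `high` iff score strictly exceeds `cutoff`; a score exactly at the
#' cutoff is `low`.
#'
#' @param scores tibble from [marker_score()] (or a numeric vector).
#' @param cutoff threshold (default 0.4).
#' @return tibble with `sample_id`, `score`, `group` (`"high"`/`"low"`);
#'   group sizes attached as attribute `"counts"`.
#' @export
split_by_cutoff <- function(scores, cutoff = 0.4) {
  if (is.numeric(scores)) {
    scores <- tibble(sample_id = names(scores) %||%
                       as.character(seq_along(scores)),
                     score = unname(scores))
  }
  if (any(!is.finite(scores$score))) abort("scores must be finite")
  scores$group <- factor(ifelse(scores$score > cutoff, "high", "low"),
                         levels = c("low", "high"))
  attr(scores, "counts") <- table(scores$group)
  scores
}

#' Kaplan-Meier product-limit estimate
#'
#' At each distinct event time t, survival updates as
#' `S <- S * (1 - d_t / n_t)` with `d_t` events among `n_t` at risk;
#' censored subjects leave the risk set after their own time (they count
#' as at risk at a tied event time).
#'
#' @param table survival tibble: `sample`, `time` (> 0), `event` (0/1)
#'   and optionally `group`.
#' @param group optional vector overriding/providing the grouping.
#' @return a `km_fit` object wrapping the fitted survival curves.
#' @export
km_estimate <- function(table, group = NULL) {
  if (any(table$time <= 0)) abort("follow-up times must be positive")
  if (!all(table$event %in% c(0, 1))) abort("event must be 0/1")
  if (!nrow(table)) abort("empty survival table")
  existing <- if ("group" %in% names(table)) table$group else rep("all", nrow(table))
  table$group <- group %||% existing
  fit <- survival::survfit(survival::Surv(time, event) ~ group, data = table)
  structure(list(fit = fit, data = as_tibble(table)), class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  print(x$fit)
  invisible(x)
}

#' Tidy a Kaplan-Meier fit
#'
#' @param x a `km_fit`.
#' @param ... unused.
#' @return tibble: `group`, `time`, `n_risk`, `n_event`, `n_censor`,
#'   `surv` (step-function values at the distinct observed times).
#' @exportS3Method generics::tidy
tidy.km_fit <- function(x, ...) {
  f <- x$fit
  grp <- if (is.null(f$strata)) {
    rep(unique(x$data$group)[1], length(f$time))
  } else {
    rep(sub("^group=", "", names(f$strata)), f$strata)
  }
  tibble(group = grp, time = f$time, n_risk = f$n.risk,
         n_event = f$n.event, n_censor = f$n.censor, surv = f$surv)
}

#' @exportS3Method generics::glance
glance.km_fit <- function(x, ...) {
  s <- summary(x$fit)$table
  if (is.null(dim(s))) s <- t(as.matrix(s))
  tibble(
    group = sub("^group=", "", rownames(s) %||% "all"),
    n = s[, "records"], events = s[, "events"],
    median_survival = s[, "median"]
  )
}

#' Log-rank test
#'
#' Observed-minus-expected events per group accumulated over the pooled
#' distinct event times, with hypergeometric variance; the statistic is
#' chi-squared with (groups - 1) degrees of freedom.
#'
#' @param table survival tibble with `time`, `event`, `group`.
#' @return tibble with `statistic`, `df`, `p_value`.
#' @export
logrank_test <- function(table) {
  if (length(unique(table$group)) < 2) abort("log-rank needs >= 2 groups")
  if (sum(table$event) < 1) abort("log-rank undefined with no events")
  sd_ <- survival::survdiff(survival::Surv(time, event) ~ group, data = table)
  df <- length(sd_$n) - 1
  tibble(statistic = sd_$chisq, df = df,
         p_value = pchisq(sd_$chisq, df = df, lower.tail = FALSE))
}
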