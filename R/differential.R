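#' TMM normalization factors
#'
#' Trimmed mean of M-values scaling factors relative to a reference
#' sample (the one whose 75th-percentile count fraction is closest to the
#' cohort mean), with 30% log-ratio trimming and 5% abundance trimming
#' and a precision-weighted mean; factors are scaled so their product is
#' 1. Together with the library sizes these give the effective library
#' sizes used by the negative-binomial model.
#'
#' @param raw a raw `accessibility_matrix`.
#' @param trim_m log-ratio trim fraction.
#' @param trim_a abundance trim fraction.
#' @return named numeric vector of per-sample factors.
#' @export
tmm_factors <- function(raw, trim_m = 0.3, trim_a = 0.05) {
  stopifnot(inherits(raw, "accessibility_matrix"))
  if (any(colSums(raw$values) == 0)) abort("a sample has all-zero counts")
  f <- edgeR::calcNormFactors(raw$values, lib.size = raw$lib_sizes,
                              method = "TMM",
                              logratioTrim = trim_m, sumTrim = trim_a)
  setNames(f, colnames(raw$values))
}

#' Negative-binomial quasi-likelihood differential test
#'
#' Per region, a negative-binomial log-linear model with offsets
#' `log(lib_size * factor)` is fitted to the two groups; dispersions are
#' estimated with empirical-Bayes shrinkage toward an abundance trend
#' (robust), quasi-dispersions are squeezed toward their own trend, and
#' the group effect is tested with a quasi-likelihood F statistic (the
#' edgeR glmQLFit/glmQLFTest scheme). Fold changes are reported as
#' `log2fc` of the second group level over the first.
#'
#' @param raw a raw `accessibility_matrix`.
#' @param groups 2-level factor (or coercible) over samples; each level
#'   needs >= 2 samples.
#' @param factors optional TMM factors from [tmm_factors()]; computed
#'   when missing.
#' @return tibble (one row per region): `region`, `log2fc`, `stat`
#'   (QL F), `p_value`, `fdr` (BH), `dispersion` (tagwise NB),
#'   `ql_dispersion` (squeezed quasi-dispersion).
#' @export
fit_nb_ql <- function(raw, groups, factors = NULL) {
  stopifnot(inherits(raw, "accessibility_matrix"))
  groups <- factor(groups)
  if (nlevels(groups) != 2) abort("groups must have exactly 2 levels")
  if (any(table(groups) < 2)) abort("each group needs at least 2 samples")
  if (length(groups) != ncol(raw$values)) abort("groups length must match sample count")
  factors <- factors %||% tmm_factors(raw)
  y <- edgeR::DGEList(counts = raw$values, lib.size = raw$lib_sizes,
                      norm.factors = unname(factors), group = groups)
  design <- model.matrix(~groups)
  y <- edgeR::estimateDisp(y, design = design, robust = TRUE)
  fit <- edgeR::glmQLFit(y, design = design, legacy = TRUE)
  test <- edgeR::glmQLFTest(fit, coef = 2)
  tt <- test$table
  tibble(
    region = rownames(raw$values),
    log2fc = tt$logFC,
    stat = tt$F,
    p_value = tt$PValue,
    fdr = bh_fdr(tt$PValue),
    dispersion = y$tagwise.dispersion,
    ql_dispersion = fit$s2.post
  )
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: `adj_i = min_{j >= rank(i)} p_(j) * m / j`,
#' capped at 1.
#'
#' @param p vector of p-values in \[0, 1\].
#' @return adjusted vector, same order as the input.
#' @export
bh_fdr <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  p.adjust(p, method = "BH")
}

#' Call differentially accessible regions / expressed genes
#'
#' Strict thresholds, as conventionally printed: `up` iff
#' `log2fc > lfc_cut` and `fdr < fdr_cut`; `down` symmetric; otherwise
#' `ns`. A boundary value (`log2fc` exactly equal to the cutoff) is not
#' called.
#'
#' @param result tibble from [fit_nb_ql()] (needs `log2fc`, `fdr`).
#' @param lfc_cut absolute log2 fold-change cutoff (strict).
#' @param fdr_cut FDR cutoff (strict).
#' @return `result` with an added `call` column (`up`/`down`/`ns`);
#'   per-direction counts are attached as attribute `"counts"`.
#' @export
call_differential <- function(result, lfc_cut = 1, fdr_cut = 0.01) {
  call <- rep("ns", nrow(result))
  call[result$log2fc > lfc_cut & result$fdr < fdr_cut] <- "up"
  call[result$log2fc < -lfc_cut & result$fdr < fdr_cut] <- "down"
  result$call <- call
  attr(result, "counts") <- tibble(
    up = sum(call == "up"), down = sum(call == "down"), ns = sum(call == "ns")
  )
  result
}

#' Differential expression on a log-scale expression matrix
#'
#' Moderated t-tests (limma lmFit/eBayes) between two groups of a
#' continuous (log-scale) expression matrix, with BH-adjusted p-values —
#' used for surrogate-marker discovery from the cohort's expression data.
#'
#' @param expression genes x samples numeric matrix (log scale).
#' @param groups 2-level factor over samples.
#' @return tibble: `gene`, `log2fc` (second level over first), `stat`
#'   (moderated t), `p_value`, `fdr`.
#' @export
fit_limma <- function(expression, groups) {
  groups <- factor(groups)
  if (nlevels(groups) != 2) abort("groups must have exactly 2 levels")
  design <- model.matrix(~groups)
  fit <- limma::eBayes(limma::lmFit(expression, design))
  tt <- limma::topTable(fit, coef = 2, number = Inf, sort.by = "none")
  tibble(
    gene = rownames(expression),
    log2fc = tt$logFC,
    stat = tt$t,
    p_value = tt$P.Value,
    fdr = tt$adj.P.Val
  )
}
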