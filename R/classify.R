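#' Common accessible CREs
#'
#' Regions accessible at a similar level in essentially every tumour:
#' row median >= `min_median` and sample row variance (n-1 denominator)
#' <= `max_var` on the normalized scale. Both bounds are inclusive.
#'
#' @param norm a normalized `accessibility_matrix`.
#' @param min_median minimum row median (normalized units).
#' @param max_var maximum row variance.
#' @return character vector of retained region ids.
#' @export
common_accessible_cres <- function(norm, min_median = 3, max_var = 0.5) {
  stopifnot(inherits(norm, "accessibility_matrix"))
  if (ncol(norm$values) < 2) abort("variance undefined with fewer than 2 samples")
  med <- row_medians(norm$values)
  v <- row_vars(norm$values)
  rownames(norm$values)[med >= min_median & v <= max_var]
}

#' Top variable CREs
#'
#' Regions ranked by descending row variance after removing `exclude`;
#' the top `min(n, available)` are returned. Variance ties are broken by
#' region id (input order), keeping the selection deterministic.
#'
#' @param norm a normalized `accessibility_matrix`.
#' @param n number of regions to keep (default 50,000).
#' @param exclude region ids removed before ranking (e.g. the common
#'   CREs).
#' @return character vector of region ids, most variable first.
#' @export
top_variable_cres <- function(norm, n = 50000, exclude = NULL) {
  stopifnot(inherits(norm, "accessibility_matrix"))
  vals <- norm$values
  if (!is.null(exclude)) vals <- vals[!rownames(vals) %in% exclude, , drop = FALSE]
  if (!nrow(vals)) abort("no regions left after exclusion")
  v <- row_vars(vals)
  ord <- order(-v, seq_along(v), method = "radix")
  rownames(vals)[ord[seq_len(min(n, length(ord)))]]
}

#' Hierarchical clustering of tumours
#'
#' Agglomerative Ward clustering (ward.D2 on Euclidean distances between
#' sample vectors of the supplied regions), cut into `k` groups. Cluster
#' labels are `CA-A`, `CA-B`, ... in order of first appearance along the
#' sample ordering; the raw merge history is kept for inspection.
#'
#' @param norm a normalized `accessibility_matrix` (typically restricted
#'   to the top variable distal cancer CREs).
#' @param regions optional region ids to restrict to.
#' @param k number of tumour clusters (default 3).
#' @param metric distance metric (Euclidean, the conventional partner of
#'   ward.D2).
#' @return a `ca_clusters` object: `labels` tibble (`sample_id`,
#'   `cluster`), the `hclust` tree, and the parameters.
#' @export
cluster_tumours <- function(norm, regions = NULL, k = 3, metric = "euclidean") {
  stopifnot(inherits(norm, "accessibility_matrix"))
  vals <- norm$values
  if (!is.null(regions)) vals <- vals[rownames(vals) %in% regions, , drop = FALSE]
  if (k > ncol(vals)) abort("k exceeds the number of samples")
  d <- dist(t(vals), method = metric)
  tree <- hclust(d, method = "ward.D2")
  raw <- cutree(tree, k = k)
  # relabel in order of first appearance -> CA-A, CA-B, ...
  lab_map <- setNames(paste0("CA-", LETTERS[seq_along(unique(raw))]), unique(raw))
  labels <- tibble(sample_id = colnames(vals), cluster = unname(lab_map[as.character(raw)]))
  structure(
    list(labels = labels, tree = tree,
         params = list(k = k, metric = metric, linkage = "ward.D2",
                       n_regions = nrow(vals))),
    class = "ca_clusters"
  )
}

#' @export
print.ca_clusters <- function(x, ...) {
  sizes <- table(x$labels$cluster)
  cat(sprintf("<ca_clusters> k = %d on %d regions; sizes: %s\n",
              x$params$k, x$params$n_regions,
              paste(sprintf("%s=%d", names(sizes), sizes), collapse = ", ")))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ca_clusters <- function(x, ...) x$labels

#' @exportS3Method generics::glance
glance.ca_clusters <- function(x, ...) {
  tibble(
    k = x$params$k,
    n_samples = nrow(x$labels),
    n_regions = x$params$n_regions,
    max_merge_height = max(x$tree$height)
  )
}

#' k-means CRE modules
#'
#' Partitions (typically the top variable, non-common) CREs into `k`
#' modules by Lloyd-style k-means on their normalized accessibility
#' profiles, best of `n_init` seeded restarts by within-cluster sum of
#' squares.
#'
#' @param norm a normalized `accessibility_matrix`.
#' @param regions optional region ids to restrict to.
#' @param k number of modules (default 5).
#' @param iter_max maximum iterations per restart (default 100).
#' @param n_init random restarts (default 10).
#' @param seed RNG seed; results are reproducible given the seed.
#' @return tibble with `region`, `module` (1..k), plus the total and
#'   within-cluster sum of squares as attributes `"totss"`/`"wcss"`.
#' @export
kmeans_modules <- function(norm, regions = NULL, k = 5, iter_max = 100,
                           n_init = 10, seed = 1) {
  stopifnot(inherits(norm, "accessibility_matrix"))
  vals <- norm$values
  if (!is.null(regions)) vals <- vals[rownames(vals) %in% regions, , drop = FALSE]
  if (k > nrow(vals)) abort("k exceeds the number of regions")
  km <- with_seed(seed, kmeans(vals, centers = k, iter.max = iter_max, nstart = n_init))
  out <- tibble(region = rownames(vals), module = unname(km$cluster))
  attr(out, "totss") <- km$totss
  attr(out, "wcss") <- km$tot.withinss
  out
}

#' PCA embedding of samples
#'
#' Centred principal component analysis of the sample vectors (via
#' singular value decomposition). Component signs are fixed by the
#' convention that each component's largest-magnitude loading is
#' positive, making the embedding deterministic.
#'
#' @param norm a normalized `accessibility_matrix`.
#' @param regions optional region ids to restrict to.
#' @param n_components number of components returned.
#' @return list with `scores` (tibble: `sample_id`, `PC1`, ...),
#'   `explained_variance` (per component) and `total_variance`.
#' @export
pca_embed <- function(norm, regions = NULL, n_components = 2) {
  stopifnot(inherits(norm, "accessibility_matrix"))
  vals <- norm$values
  if (!is.null(regions)) vals <- vals[rownames(vals) %in% regions, , drop = FALSE]
  if (ncol(vals) < 2) abort("need at least 2 samples")
  pc <- prcomp(t(vals), center = TRUE, scale. = FALSE)
  n_components <- min(n_components, ncol(pc$x))
  rot <- pc$rotation[, seq_len(n_components), drop = FALSE]
  scores <- pc$x[, seq_len(n_components), drop = FALSE]
  for (j in seq_len(n_components)) {
    if (rot[which.max(abs(rot[, j])), j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  list(
    scores = as_tibble(cbind(tibble(sample_id = colnames(vals)), as.data.frame(scores))),
    explained_variance = pc$sdev[seq_len(n_components)]^2,
    total_variance = sum(pc$sdev^2)
  )
}
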