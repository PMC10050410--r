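#' @import ggplot2
NULL

#' Plot a fragment length histogram
#'
#' The sub-nucleosomal peak and the mono-nucleosome bump of an ATAC
#' library.
#'
#' @param hist tibble from [fragment_length_histogram()].
#' @return a ggplot.
#' @export
plot_fragment_lengths <- function(hist) {
  ggplot(hist, aes(x = .data$length, y = .data$count)) +
    geom_col(width = 1, fill = "grey30") +
    labs(x = "fragment length (bp)", y = "fragments") +
    theme_minimal()
}

#' Plot TSS enrichment profiles
#'
#' Smoothed, flank-normalized insertion profiles around the TSS, one
#' line per sample.
#'
#' @param tss_scores tibble from [tss_enrichment()] (carries the profile
#'   attribute).
#' @return a ggplot.
#' @export
plot_tss_profile <- function(tss_scores) {
  prof <- attr(tss_scores, "profile")
  if (is.null(prof)) abort("no profile attribute; rerun tss_enrichment()")
  df <- tibble(
    distance = rep(as.integer(rownames(prof)), times = ncol(prof)),
    enrichment = as.vector(prof),
    sample_id = rep(colnames(prof), each = nrow(prof))
  )
  ggplot(df, aes(x = .data$distance, y = .data$enrichment,
                 group = .data$sample_id)) +
    geom_line(alpha = 0.4) +
    labs(x = "distance from TSS (bp)", y = "normalized insertion enrichment") +
    theme_minimal()
}

#' Volcano plot of a differential result
#'
#' @param result tibble from [fit_nb_ql()]/[fit_limma()] after
#'   [call_differential()].
#' @return a ggplot.
#' @export
plot_volcano <- function(result) {
  ggplot(result, aes(x = .data$log2fc, y = -log10(.data$fdr),
                     colour = .data$call)) +
    geom_point(size = 0.6, alpha = 0.6) +
    scale_colour_manual(values = c(up = "firebrick", down = "steelblue",
                                   ns = "grey70")) +
    labs(x = "log2 fold change", y = "-log10 FDR", colour = NULL) +
    theme_minimal()
}

#' Dot plot of marker scores with the survival cutoff
#'
#' @param scores tibble from [split_by_cutoff()].
#' @param cutoff the cutoff used (drawn as a dashed line).
#' @return a ggplot.
#' @export
plot_marker_scores <- function(scores, cutoff = 0.4) {
  df <- scores[order(scores$score), , drop = FALSE]
  df$rank <- seq_len(nrow(df))
  ggplot(df, aes(x = .data$rank, y = .data$score, colour = .data$group)) +
    geom_point(size = 0.8) +
    geom_hline(yintercept = cutoff, linetype = "dashed", colour = "red") +
    labs(x = "samples (ranked)", y = "marker score", colour = NULL) +
    theme_minimal()
}

#' Kaplan-Meier curves
#'
#' @param object a `km_fit`.
#' @param ... unused.
#' @return a ggplot of the survival step functions per group.
#' @exportS3Method ggplot2::autoplot
autoplot.km_fit <- function(object, ...) {
  df <- tidy(object)
  start <- df[!duplicated(df$group), , drop = FALSE]
  start$time <- 0
  start$surv <- 1
  df <- bind_rows(start, df)
  ggplot(df, aes(x = .data$time, y = .data$surv, colour = .data$group)) +
    geom_step() +
    coord_cartesian(ylim = c(0, 1)) +
    labs(x = "time", y = "survival probability", colour = NULL) +
    theme_minimal()
}

#' Motif score boxplots by group
#'
#' @param object a `motif_deviations` result.
#' @param groups tibble with `sample_id` and a grouping column
#'   (`cluster` or `group`).
#' @param motifs motif names to show (default all).
#' @param ... unused.
#' @return a ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.motif_deviations <- function(object, groups = NULL, motifs = NULL, ...) {
  df <- tidy(object)
  if (!is.null(motifs)) df <- df[df$motif %in% motifs, , drop = FALSE]
  if (!is.null(groups)) {
    gcol <- setdiff(names(groups), "sample_id")[1]
    df <- left_join(df, groups, by = "sample_id")
    df$grp <- df[[gcol]]
  } else {
    df$grp <- "all"
  }
  ggplot(df, aes(x = .data$grp, y = .data$z, fill = .data$grp)) +
    geom_boxplot(outlier.size = 0.5) +
    facet_wrap(~motif) +
    labs(x = NULL, y = "motif deviation z-score", fill = NULL) +
    theme_minimal()
}

#' Dendrogram of the tumour clustering
#'
#' @param object a `ca_clusters` result.
#' @param ... unused.
#' @return a ggplot of the Ward merge tree.
#' @exportS3Method ggplot2::autoplot
autoplot.ca_clusters <- function(object, ...) {
  tree <- object$tree
  n <- length(tree$order)
  # leaf x positions in dendrogram order
  leaf_x <- numeric(n)
  leaf_x[tree$order] <- seq_len(n)
  node_x <- numeric(nrow(tree$merge))
  node_y <- tree$height
  seg <- vector("list", nrow(tree$merge))
  pos <- function(id) if (id < 0) c(leaf_x[-id], 0) else c(node_x[id], node_y[id])
  for (i in seq_len(nrow(tree$merge))) {
    a <- pos(tree$merge[i, 1])
    b <- pos(tree$merge[i, 2])
    node_x[i] <- (a[1] + b[1]) / 2
    seg[[i]] <- tibble(
      x = c(a[1], a[1], b[1]),
      xend = c(a[1], b[1], b[1]),
      y = c(a[2], node_y[i], node_y[i]),
      yend = c(node_y[i], node_y[i], b[2])
    )
  }
  segs <- bind_rows(seg)
  labels_df <- tibble(x = leaf_x, y = -0.02 * max(node_y),
                      label = tree$labels %||% as.character(seq_len(n)))
  ggplot() +
    geom_segment(data = segs, aes(x = .data$x, xend = .data$xend,
                                  y = .data$y, yend = .data$yend)) +
    geom_text(data = labels_df, aes(x = .data$x, y = .data$y,
                                    label = .data$label),
              angle = 90, hjust = 1, size = 2.5) +
    labs(x = NULL, y = "merge height (ward.D2)") +
    theme_minimal() +
    theme(axis.text.x = element_blank())
}
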