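# Hyperparameter grid selection and model-comparison statistics.

#' Default per-layer L1 penalty grids
#'
#' The cross-validated penalty sets used with deep-network layers: a fine
#' grid for the earliest layer and one or two values per deeper layer.
#'
#' @return Named list of numeric lambda grids by layer.
#' @export
lambda_grid <- function() {
  list(
    conv1 = c(0.33, 1, 3),
    layer1.0 = 3,
    layer2.0 = c(3, 6),
    layer3.0 = c(3, 9),
    layer4.0 = c(6, 12)
  )
}

#' Select the best configuration per core from a results table
#'
#' Averages validation scores over seeds for each (core, layer, scale,
#' lambda) configuration and returns the configuration maximizing the
#' validation score for each core. Ties are broken by smallest lambda, then
#' earliest layer. Test scores are meant to be reported only for the
#' selected configurations.
#'
#' @param results data frame with columns `core`, `layer`, `scale`,
#'   `lambda`, `seed`, `val_score` (larger is better).
#' @return Data frame with one row per core: the selected configuration and
#'   its seed-averaged validation score.
#' @export
grid_select <- function(results) {
  req <- c("core", "layer", "scale", "lambda", "seed", "val_score")
  if (!is.data.frame(results) || nrow(results) == 0) {
    stop("`results` must be a non-empty data frame")
  }
  if (!all(req %in% names(results))) {
    stop("`results` needs columns: ", paste(req, collapse = ", "))
  }
  agg <- stats::aggregate(val_score ~ core + layer + scale + lambda,
                          data = results, FUN = mean)
  layer_rank <- function(l) match(l, unique(results$layer[order(results$layer)]))
  out <- do.call(rbind, lapply(split(agg, agg$core), function(g) {
    g <- g[order(-g$val_score, g$lambda, layer_rank(g$layer)), , drop = FALSE]
    g[1, , drop = FALSE]
  }))
  rownames(out) <- NULL
  out
}

#' Pairwise cluster contrasts with Holm-Bonferroni correction
#'
#' For every pair of task clusters, a paired Wilcoxon signed-rank test on
#' per-neuron cluster-mean scores (the same neurons under each cluster),
#' with Holm-Bonferroni correction across all pairwise comparisons.
#'
#' @param scores `neurons x clusters` matrix (or data frame) of per-neuron
#'   cluster-mean scores; column names label the clusters.
#' @param exact passed to [stats::wilcox.test()].
#' @return Data frame with one row per cluster pair: `group1`, `group2`,
#'   the signed-rank statistic `V`, raw `p`, and Holm-adjusted `p_adj`.
#' @export
cluster_contrasts <- function(scores, exact = NULL) {
  scores <- as.matrix(scores)
  if (is.null(colnames(scores))) {
    colnames(scores) <- paste0("G", seq_len(ncol(scores)))
  }
  if (ncol(scores) < 2) stop("need at least two clusters")
  if (anyNA(scores)) stop("paired design requires complete scores")
  prs <- utils::combn(ncol(scores), 2)
  res <- data.frame(
    group1 = colnames(scores)[prs[1, ]],
    group2 = colnames(scores)[prs[2, ]],
    V = NA_real_, p = NA_real_
  )
  for (k in seq_len(ncol(prs))) {
    wt <- stats::wilcox.test(scores[, prs[1, k]], scores[, prs[2, k]],
                             paired = TRUE, exact = exact)
    res$V[k] <- unname(wt$statistic)
    res$p[k] <- wt$p.value
  }
  res$p_adj <- stats::p.adjust(res$p, method = "holm")
  res
}

#' Specialization index of an area
#'
#' Variance across task models of the normalized performance. The default
#' normalization subtracts the untrained-baseline score and divides by the
#' mean increment (`increment`); the plain mean-normalized variant
#' (`mean`) divides raw scores by their mean. The baseline never enters the
#' variance set, and the index is invariant to a common positive rescaling
#' of the (baseline-subtracted) scores.
#'
#' @param scores per-task-model mean scores (>= 3, excluding the baseline).
#' @param baseline untrained-baseline score (required for `increment`).
#' @param normalize `"increment"` or `"mean"`.
#' @param fisher_z apply Fisher's z-transform (`atanh`) to scores and
#'   baseline first; appropriate when scores are correlations.
#' @return A list with `index` (the variance), `normalized` (the normalized
#'   scores) and the settings.
#' @export
specialization_index <- function(scores, baseline = NULL,
                                 normalize = c("increment", "mean"),
                                 fisher_z = FALSE) {
  normalize <- match.arg(normalize)
  if (length(scores) < 3) stop("need at least 3 task-model scores")
  if (fisher_z) {
    scores <- atanh(scores)
    if (!is.null(baseline)) baseline <- atanh(baseline)
  }
  v <- switch(normalize,
    increment = {
      if (is.null(baseline)) stop("`baseline` required for increment normalization")
      inc <- scores - baseline
      inc / mean(inc)
    },
    mean = scores / mean(scores)
  )
  list(index = stats::var(v), normalized = v, normalize = normalize,
       fisher_z = fisher_z)
}

#' Compare specialization between two areas
#'
#' Tests equality of variances of normalized task-model performance between
#' two areas, reporting Bartlett's test and Levene's test side by side
#' (both appear in practice; neither is privileged). Correlation scores are
#' Fisher z-transformed by default before normalization.
#'
#' @param scores1,scores2 per-task-model scores of the two areas.
#' @param baseline1,baseline2 untrained-baseline scores.
#' @param normalize,fisher_z as in [specialization_index()].
#' @return Data frame with rows `bartlett` and `levene`: statistic and p
#'   value, plus the two specialization indices as attributes.
#' @export
specialization_test <- function(scores1, scores2, baseline1 = NULL,
                                baseline2 = NULL,
                                normalize = c("increment", "mean"),
                                fisher_z = TRUE) {
  normalize <- match.arg(normalize)
  s1 <- specialization_index(scores1, baseline1, normalize, fisher_z)
  s2 <- specialization_index(scores2, baseline2, normalize, fisher_z)
  y <- c(s1$normalized, s2$normalized)
  g <- factor(rep(c("area1", "area2"), c(length(s1$normalized),
                                         length(s2$normalized))))
  bt <- stats::bartlett.test(y, g)
  lv <- car::leveneTest(y ~ g)
  out <- data.frame(
    test = c("bartlett", "levene"),
    statistic = c(unname(bt$statistic), lv$`F value`[1]),
    p = c(bt$p.value, lv$`Pr(>F)`[1])
  )
  attr(out, "index1") <- s1$index
  attr(out, "index2") <- s2$index
  out
}
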