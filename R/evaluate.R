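# Reliability and performance estimators. All variances use unbiased
# estimators and are computed on repeated-trial test responses.

as_counts_array <- function(counts) {
  if (is.matrix(counts)) counts <- array(counts, c(dim(counts), 1L))
  stopifnot(is.array(counts), length(dim(counts)) == 3L)
  counts
}

#' Observation-noise variance per neuron
#'
#' The unbiased variance of responses across repeats of the same image,
#' averaged over images: the part of response variability a perfect model
#' cannot explain.
#'
#' @param counts `images x repeats` matrix (one neuron) or
#'   `images x repeats x neurons` array; at least 2 repeats.
#' @return Numeric vector of per-neuron noise variances.
#' @examples
#' noise_variance(rbind(c(0, 2)))  # one image, repeats {0, 2} -> 2
#' @export
noise_variance <- function(counts) {
  counts <- as_counts_array(counts)
  if (dim(counts)[2] < 2) {
    stop("noise variance is undefined with a single repeat per image")
  }
  apply(counts, 3, function(m) mean(apply(m, 1, stats::var)))
}

#' Explainable variance per neuron
#'
#' Total variance of all single-trial responses minus the observation-noise
#' variance is the explainable (stimulus-driven) variance; its ratio to the
#' total variance is the EV used to filter unreliable neurons. EV can be
#' negative for pure-noise neurons.
#'
#' @param counts `images x repeats (x neurons)` test counts, >= 2 repeats.
#' @return A data frame with columns `var_total`, `var_noise`, `var_exp`,
#'   `ev` (one row per neuron). Zero total variance yields `NA` EV with a
#'   warning.
#' @export
explainable_variance <- function(counts) {
  counts <- as_counts_array(counts)
  vn <- noise_variance(counts)
  vt <- apply(counts, 3, function(m) stats::var(as.vector(m)))
  ev <- (vt - vn) / vt
  if (any(vt == 0)) {
    warning("zero total variance for some neurons; EV undefined (NA)")
    ev[vt == 0] <- NA_real_
  }
  data.frame(var_total = vt, var_noise = vn, var_exp = vt - vn, ev = ev)
}

#' Filter neurons by explainable-variance ratio
#'
#' Removes neurons whose EV falls strictly below the threshold (default
#' 0.15); a neuron exactly at the threshold is retained. `NA` EVs are
#' removed.
#'
#' @param ev numeric vector of EV values.
#' @param threshold reliability cutoff.
#' @return Integer indices of retained neurons.
#' @export
filter_reliable <- function(ev, threshold = 0.15) {
  which(!is.na(ev) & ev >= threshold)
}

#' Fraction of explainable variance explained (FEVE)
#'
#' Residual variance is the average squared single-trial residual (predicted
#' rate vs observed count, averaged over repeats within an image, then over
#' images) corrected by the observation-noise variance; FEVE is one minus
#' its ratio to the explainable variance. FEVE <= 1, with equality iff the
#' noise-corrected residual variance is zero. Neurons with non-positive
#' explainable variance get `NA` with a warning and are excluded from the
#' population mean.
#'
#' @param predictions `images x neurons` matrix of predicted rates, aligned
#'   to the test images.
#' @param counts `images x repeats (x neurons)` test counts.
#' @return A list with per-neuron `feve`, `var_res`, and the population
#'   `mean` over neurons with defined FEVE.
#' @export
feve <- function(predictions, counts) {
  counts <- as_counts_array(counts)
  predictions <- cbind(predictions)
  stopifnot(nrow(predictions) == dim(counts)[1],
            ncol(predictions) == dim(counts)[3])
  rel <- explainable_variance(counts)
  n_neurons <- dim(counts)[3]
  var_res <- numeric(n_neurons)
  for (n in seq_len(n_neurons)) {
    # counts[, , n] is images x repeats; broadcast predictions across repeats
    sq <- (counts[, , n] - matrix(predictions[, n], dim(counts)[1],
                                  dim(counts)[2]))^2
    var_res[n] <- mean(rowMeans(sq)) - rel$var_noise[n]
  }
  fv <- 1 - var_res / rel$var_exp
  bad <- rel$var_exp <= 0 | is.na(rel$ev)
  if (any(bad)) {
    warning(sprintf("FEVE undefined for %d neuron(s) with non-positive explainable variance",
                    sum(bad)))
    fv[bad] <- NA_real_
  }
  list(feve = fv, var_res = var_res, mean = mean(fv, na.rm = TRUE))
}

#' Test-set correlation per neuron
#'
#' Pearson correlation between model predictions and the repeat-averaged
#' response, the standard published performance measure; aggregated as the
#' mean over neurons.
#'
#' @param predictions `images x neurons` matrix.
#' @param counts `images x repeats (x neurons)` test counts (>= 3 images).
#' @return A list with per-neuron `correlation` and the population `mean`
#'   over neurons with defined correlations (zero-variance predictions give
#'   `NA` with a warning).
#' @export
mean_test_correlation <- function(predictions, counts) {
  counts <- as_counts_array(counts)
  predictions <- cbind(predictions)
  if (dim(counts)[1] < 3) stop("need at least 3 test images")
  stopifnot(nrow(predictions) == dim(counts)[1],
            ncol(predictions) == dim(counts)[3])
  mean_resp <- apply(counts, c(1, 3), mean)
  rs <- vapply(seq_len(ncol(predictions)), function(n) {
    if (stats::sd(predictions[, n]) == 0 || stats::sd(mean_resp[, n]) == 0) {
      return(NA_real_)
    }
    stats::cor(predictions[, n], mean_resp[, n])
  }, numeric(1))
  if (anyNA(rs)) {
    warning(sprintf("correlation undefined for %d neuron(s) with zero-variance predictions or responses",
                    sum(is.na(rs))))
  }
  list(correlation = rs, mean = mean(rs, na.rm = TRUE))
}

#' Selectivity (sparseness) index
#'
#' For each neuron, the fraction of images whose mean response exceeds each
#' of `n_thresholds` evenly spaced thresholds between the minimum and
#' maximum response is computed; `A` is the area under that curve over
#' normalized thresholds (rectangle rule), and `SI = 1 - 2A`. SI approaches
#' 0 for uniformly distributed responses and 1 for very sparse neurons, and
#' is invariant to positive affine rescaling of the responses.
#'
#' @param responses numeric vector of per-image mean responses (one neuron)
#'   or an `images x neurons` matrix.
#' @param n_thresholds number of threshold bins (default 100).
#' @return A data frame with columns `A` and `SI` (one row per neuron).
#'   Constant responses give `NA` with a warning.
#' @export
selectivity_index <- function(responses, n_thresholds = 100) {
  responses <- cbind(responses)
  out <- t(apply(responses, 2, function(r) {
    lo <- min(r); hi <- max(r)
    if (hi == lo) return(c(NA_real_, NA_real_))
    th <- seq(lo, hi, length.out = n_thresholds)
    frac <- vapply(th, function(t) mean(r > t), numeric(1))
    A <- mean(frac)
    c(A, 1 - 2 * A)
  }))
  out <- data.frame(A = out[, 1], SI = out[, 2])
  if (anyNA(out$A)) warning("constant responses: selectivity index undefined (NA)")
  out
}

#' Evaluate a fitted encoding model on repeated-trial test data
#'
#' Computes per-neuron reliability (EV), test correlation, FEVE and
#' selectivity, applies the EV reliability filter for the population
#' summary, and returns everything as a `model_score`.
#'
#' @param model a fitted `spike_encoder`.
#' @param dataset an `area_dataset` with test counts.
#' @param ev_threshold reliability cutoff for the population summary.
#' @return An object of class `model_score`: a list with the per-neuron
#'   data frame `neurons`, the retained indices, and `summary` (mean test
#'   correlation and mean FEVE over retained neurons).
#' @export
evaluate <- function(model, dataset, ev_threshold = 0.15) {
  stopifnot(inherits(model, "spike_encoder"), inherits(dataset, "area_dataset"))
  counts <- dataset_test_counts(dataset)
  pred <- predict(model, dataset)
  rel <- explainable_variance(counts)
  ctab <- suppressWarnings(mean_test_correlation(pred, counts))
  ftab <- suppressWarnings(feve(pred, counts))
  mean_resp <- apply(counts, c(1, 3), mean)
  stab <- suppressWarnings(selectivity_index(mean_resp))
  keep <- filter_reliable(rel$ev, ev_threshold)
  tab <- data.frame(
    neuron = seq_len(dim(counts)[3]),
    session = model$neurons$session,
    ev = rel$ev, test_corr = ctab$correlation, feve = ftab$feve,
    si = stab$SI, retained = seq_len(dim(counts)[3]) %in% keep
  )
  structure(
    list(
      neurons = tab, retained = keep, ev_threshold = ev_threshold,
      summary = list(
        n_retained = length(keep),
        mean_test_corr = mean(tab$test_corr[keep], na.rm = TRUE),
        mean_feve = mean(tab$feve[keep], na.rm = TRUE),
        mean_ev = mean(tab$ev[keep]),
        mean_si = mean(tab$si[keep], na.rm = TRUE)
      )
    ),
    class = "model_score"
  )
}

#' @export
print.model_score <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "<model_score> %d/%d neurons retained (EV >= %.2f)\n  mean test correlation %.3f | mean FEVE %.3f | mean EV %.3f | mean SI %.3f\n",
    s$n_retained, nrow(x$neurons), x$ev_threshold, s$mean_test_corr,
    s$mean_feve, s$mean_ev, s$mean_si
  ))
  invisible(x)
}
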