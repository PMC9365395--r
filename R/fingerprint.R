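#' Event-based amplitude histogram
#'
#' One amplitude per burst; bin heights are normalized to the total number of
#' bursts, so fractions sum to one. Amplitudes pooled from several recordings
#' are simply concatenated before binning.
#'
#' @param burst_amplitudes Burst amplitudes in pA (one value per burst).
#' @param bin_width Bin width in pA.
#' @return Object of class `ebah`: list with `breaks`, `fraction`, `mids`,
#'   `n_bursts`.
#' @export
ebah <- function(burst_amplitudes, bin_width = 0.5) {
  stopifnot(length(burst_amplitudes) > 0, bin_width > 0)
  lo <- floor(min(burst_amplitudes) / bin_width) * bin_width
  hi <- ceiling(max(burst_amplitudes) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  if (breaks[length(breaks)] < hi) breaks <- c(breaks, hi)
  counts <- as.vector(table(cut(burst_amplitudes, breaks,
                                include.lowest = TRUE)))
  structure(list(breaks = breaks,
                 fraction = counts / length(burst_amplitudes),
                 mids = (breaks[-1] + breaks[-length(breaks)]) / 2,
                 n_bursts = length(burst_amplitudes)),
            class = "ebah")
}

#' @export
plot.ebah <- function(x, ...) {
  graphics::plot(x$mids, x$fraction, type = "h", lwd = 3,
                 xlab = "burst amplitude (pA)", ylab = "fraction of bursts",
                 ...)
  invisible(x)
}

#' Fit Gaussian amplitude classes to burst amplitudes
#'
#' Fits equal-variance Gaussian mixtures with 1 to `max_classes` components
#' and selects the class count by BIC. Channels assembled from a random mix
#' of high- and low-conductance subunits produce one amplitude class per
#' distinct subunit composition, so the class count carries the subunit
#' stoichiometry (see [infer_subunit_count()]).
#'
#' @param burst_amplitudes Burst amplitudes in pA (>= 10 bursts).
#' @param max_classes Largest class count considered (default 8).
#' @param seed Seed for the k-means initializations (deterministic given the
#'   seed).
#' @return Object of class `amplitude_class_model`: `classes` (`data.frame`
#'   with `mean`, `sd`, `weight`, means increasing), `n_classes`, `bic`
#'   (named vector over class counts), `n_bursts`.
#' @details Each candidate class count is initialized from k-means (which
#'   separates well-spaced amplitude classes reliably) and polished by the
#'   equal-variance Gaussian-mixture EM of \pkg{mclust}; the class count
#'   maximizing BIC is selected.
#' @importFrom mclust me meE bic unmap
#' @export
fit_amplitude_classes <- function(burst_amplitudes, max_classes = 8,
                                  seed = 1) {
  stopifnot(length(burst_amplitudes) >= 10)
  x <- as.numeric(burst_amplitudes)
  n <- length(x)
  set.seed(seed)
  max_classes <- min(max_classes, length(unique(x)))
  fits <- vector("list", max_classes)
  bics <- rep(NA_real_, max_classes)
  for (k in seq_len(max_classes)) {
    inits <- if (k == 1) list(rep(1L, n)) else {
      ctr <- seq(min(x), max(x), length.out = k)
      list(stats::kmeans(x, centers = k, nstart = 10, iter.max = 50)$cluster,
           # equally spaced centers catch rare extreme classes that k-means
           # sacrifices to split dense ones
           apply(abs(outer(x, ctr, "-")), 1, which.min))
    }
    fit <- NULL
    for (cl in inits) {
      if (length(unique(cl)) < k) next
      cand <- tryCatch(
        mclust::me(modelName = "E", data = x, z = mclust::unmap(cl)),
        error = function(e) NULL)
      if (is.null(cand) || is.na(cand$loglik)) next
      if (is.null(fit) || cand$loglik > fit$loglik) fit <- cand
    }
    if (is.null(fit)) {
      warning("amplitude mixture EM failed for k = ", k, "; skipped")
      next
    }
    fits[[k]] <- fit
    bics[k] <- mclust::bic(modelName = "E", loglik = fit$loglik,
                           n = n, d = 1, G = k)
  }
  if (all(is.na(bics))) stop("amplitude mixture fit failed for every k")
  kbest <- which.max(bics)
  fit <- fits[[kbest]]
  ord <- order(fit$parameters$mean)
  classes <- data.frame(mean = as.numeric(fit$parameters$mean[ord]),
                        sd = rep(sqrt(fit$parameters$variance$sigmasq),
                                 length.out = kbest)[ord],
                        weight = as.numeric(fit$parameters$pro[ord]))
  structure(list(classes = classes, n_classes = as.integer(kbest),
                 bic = stats::setNames(bics, seq_len(max_classes)),
                 n_bursts = n),
            class = "amplitude_class_model")
}

#' @export
print.amplitude_class_model <- function(x, ...) {
  cat("Amplitude class model: ", x$n_classes, " classes from ", x$n_bursts,
      " bursts\n", sep = "")
  print(signif(x$classes, 4), row.names = FALSE)
  invisible(x)
}

#' Infer subunit count from amplitude classes
#'
#' With `n + 1` amplitude classes whose extreme class means match the pure
#' low-conductance and pure high-conductance channel amplitudes, the channel
#' contains `n` exchangeable subunits. The inference is refused when the
#' extreme classes do not anchor to the endpoint amplitudes (class count
#' alone is ambiguous when extreme classes are rare), and an equal-step
#' diagnostic reports how evenly successive class means are spaced.
#'
#' @param model An [fit_amplitude_classes()] result.
#' @param endpoint_amplitudes Length-2 numeric: the all-LC and all-HC channel
#'   amplitudes in pA (from pure-population recordings).
#' @param tol Relative endpoint mismatch tolerated (default 0.2).
#' @return List: `n_subunits` (= classes - 1), `endpoint_match` (relative
#'   deviations), `step` (mean amplitude increment per HC subunit),
#'   `max_step_deviation` (largest deviation of a successive difference from
#'   the mean step, pA), `plausible` (`FALSE` for degenerate class counts).
#' @export
infer_subunit_count <- function(model, endpoint_amplitudes, tol = 0.2) {
  stopifnot(inherits(model, "amplitude_class_model"),
            length(endpoint_amplitudes) == 2)
  lo <- min(endpoint_amplitudes); hi <- max(endpoint_amplitudes)
  m <- model$classes$mean
  dev <- c(low = abs(m[1] - lo) / lo, high = abs(m[length(m)] - hi) / hi)
  if (any(dev > tol))
    stop("extreme amplitude classes do not match the endpoint amplitudes ",
         "(relative deviations ", paste(signif(dev, 3), collapse = ", "),
         "); subunit count cannot be inferred")
  n_sub <- model$n_classes - 1L
  steps <- diff(m)
  step <- if (length(steps)) mean(steps) else NA_real_
  list(n_subunits = n_sub,
       endpoint_match = dev,
       step = step,
       max_step_deviation = if (length(steps)) max(abs(steps - step)) else 0,
       plausible = n_sub >= 2)
}

#' Regression of class means on HC-subunit count
#'
#' Least-squares line through (presumed HC count, class mean amplitude). An
#' approximately linear relation with equal steps is the signature of
#' independent, roughly equal per-subunit contributions to conductance.
#'
#' @param model An [fit_amplitude_classes()] result with at least 3 classes.
#' @return List with `slope` (pA per HC subunit), `intercept` (pA, the all-LC
#'   amplitude), `residual_sd` (pA).
#' @export
class_mean_regression <- function(model) {
  stopifnot(inherits(model, "amplitude_class_model"))
  if (model$n_classes < 3) stop("need at least 3 classes for a regression")
  k <- seq_len(model$n_classes) - 1
  fit <- stats::lm(model$classes$mean ~ k)
  res <- stats::residuals(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       residual_sd = if (length(res) > 2) stats::sd(res) else 0)
}
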