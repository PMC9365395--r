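#' Log-binned dwell-duration histogram
#'
#' Standard display for single-channel dwell distributions: logarithmically
#' spaced bins, optionally with a square-root ordinate (display only; counts
#' are conserved either way).
#'
#' @param dwells Positive dwell durations in seconds.
#' @param bins_per_decade Bins per decade of time (default 10; cosmetic).
#' @param sqrt_ordinate Plot with a square-root count axis.
#' @param class Optional class label (`"shut"`/`"open"`) carried for display.
#' @return Object of class `dwell_histogram`: list with `breaks` (seconds),
#'   `counts`, `mids`, `n`, `sqrt_ordinate`, `class`.
#' @export
log_bin_histogram <- function(dwells, bins_per_decade = 10,
                              sqrt_ordinate = TRUE, class = NA_character_) {
  if (!length(dwells)) stop("no dwells")
  if (any(dwells <= 0)) stop("dwell durations must be positive")
  lo <- floor(log10(min(dwells)) * bins_per_decade) / bins_per_decade
  hi <- ceiling(log10(max(dwells)) * bins_per_decade) / bins_per_decade
  if (hi <= lo) hi <- lo + 1 / bins_per_decade
  breaks <- 10^seq(lo, hi, by = 1 / bins_per_decade)
  counts <- as.vector(table(cut(dwells, breaks, include.lowest = TRUE)))
  structure(list(breaks = breaks, counts = counts,
                 mids = sqrt(breaks[-1] * breaks[-length(breaks)]),
                 n = length(dwells), sqrt_ordinate = sqrt_ordinate,
                 class = class),
            class = "dwell_histogram")
}

#' @export
plot.dwell_histogram <- function(x, fit = NULL, main = NULL, ...) {
  y <- x$counts
  if (x$sqrt_ordinate) y <- sqrt(y)
  graphics::plot(x$mids * 1e3, y, type = "s", log = "x",
                 xlab = "duration (ms)",
                 ylab = if (x$sqrt_ordinate) "sqrt(count)" else "count",
                 main = main %||% paste(x$class, "dwells"), ...)
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "exp_mixture_fit"))
    tt <- exp(seq(log(min(x$breaks)), log(max(x$breaks)), length.out = 400))
    # expected counts per log bin: n * f(t) * t * ln(10)/bins_per_decade
    binw <- diff(log(x$breaks[1:2]))
    dens <- predict(fit, tt) * tt * binw * x$n
    graphics::lines(tt * 1e3, if (x$sqrt_ordinate) sqrt(dens) else dens,
                    col = 2)
    for (k in seq_len(nrow(fit$components))) {
      ck <- fit$components[k, ]
      dk <- ck$area / ck$tau * exp(-(tt - fit$dead_time) / ck$tau) * tt * binw * x$n
      graphics::lines(tt * 1e3, if (x$sqrt_ordinate) sqrt(dk) else dk,
                      col = 4, lty = 2)
    }
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit an exponential mixture to dwell durations
#'
#' Maximum-likelihood fit of a mixture of exponentials to raw (unbinned)
#' dwells, left-truncated at the dead time: for dwells `t >= dead_time` the
#' model density is `sum_j area_j / tau_j * exp(-(t - dead_time)/tau_j)`.
#' Areas are on the scale of detected (apparent) events. Fitting is by EM
#' with multiple deterministic seeded starts.
#'
#' @param dwells Dwell durations in seconds, all `>= dead_time`.
#' @param n_components Number of exponential components (k >= 1).
#' @param dead_time Left-truncation point in seconds (default 0).
#' @param n_starts Number of EM starts (first from quantile-spread taus, the
#'   rest jittered).
#' @param seed Seed for the jittered starts.
#' @param max_iter,tol EM iteration cap and log-likelihood convergence
#'   tolerance.
#' @return Object of class `exp_mixture_fit`: `components` (`data.frame`
#'   with `area`, `tau` sorted by `tau`), `loglik`, `n`, `dead_time`,
#'   `converged`.
#' @export
fit_exp_mixture <- function(dwells, n_components, dead_time = 0,
                            n_starts = 5, seed = 1, max_iter = 1000,
                            tol = 1e-9) {
  stopifnot(n_components >= 1, length(dwells) >= n_components)
  if (any(dwells < dead_time - 1e-12))
    stop("all dwells must be >= dead_time")
  x <- pmax(dwells - dead_time, 0)
  n <- length(x)
  k <- n_components
  if (k == 1) { # closed form: tau-hat is the mean of the shifted dwells
    tau <- max(mean(x), 1e-12)
    ll <- sum(-log(tau) - x / tau)
    return(structure(list(components = data.frame(area = 1, tau = tau),
                          loglik = ll, n = n, dead_time = dead_time,
                          converged = TRUE),
                     class = "exp_mixture_fit"))
  }
  # nested start: the (k-1)-component fit with its dominant component
  # duplicated (density unchanged, so the start log-likelihood equals the
  # smaller fit's) keeps the likelihood non-decreasing in k
  sub <- fit_exp_mixture(dwells, k - 1L, dead_time, n_starts, seed,
                         max_iter, tol)
  j <- which.max(sub$components$area)
  nested <- list(w = c(replace(sub$components$area, j,
                               sub$components$area[j] / 2),
                       sub$components$area[j] / 2),
                 tau = c(sub$components$tau, sub$components$tau[j]))
  set.seed(seed)
  qs <- stats::quantile(x[x > 0], probs = seq(0.15, 0.95, length.out = k))
  starts <- list(nested,
                 list(w = rep(1 / k, k), tau = pmax(as.numeric(qs), 1e-12)))
  for (s in seq_len(max(0, n_starts - 1))) {
    starts[[s + 2]] <- list(w = rep(1 / k, k),
                            tau = pmax(as.numeric(qs) *
                                         exp(stats::rnorm(k, 0, 0.7)), 1e-12))
  }
  best <- NULL
  for (st in starts) {
    fit <- .em_exp_mixture(x, st$w, st$tau, max_iter, tol)
    if (is.null(best) || fit$loglik > best$loglik) best <- fit
  }
  ord <- order(best$tau)
  structure(list(components = data.frame(area = best$w[ord],
                                         tau = best$tau[ord]),
                 loglik = best$loglik, n = n, dead_time = dead_time,
                 converged = best$converged),
            class = "exp_mixture_fit")
}

.em_exp_mixture <- function(x, w, tau, max_iter, tol) {
  n <- length(x)
  ll_old <- -Inf
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    lg <- outer(x, -1 / tau) + rep(log(w / tau), each = n)
    mx <- do.call(pmax, as.data.frame(lg))
    p <- exp(lg - mx)
    rs <- rowSums(p)
    ll <- sum(log(rs) + mx)
    r <- p / rs
    nk <- colSums(r)
    w <- pmax(nk / n, 1e-12)
    w <- w / sum(w)
    tau <- pmax(colSums(r * x) / pmax(nk, 1e-300), 1e-12)
    if (is.finite(ll) && abs(ll - ll_old) < tol * (abs(ll) + 1)) {
      converged <- TRUE
      ll_old <- ll
      break
    }
    ll_old <- ll
  }
  list(w = w, tau = tau, loglik = ll_old, converged = converged)
}

#' @export
predict.exp_mixture_fit <- function(object, t, ...) {
  x <- t - object$dead_time
  out <- numeric(length(x))
  ok <- x >= 0
  for (k in seq_len(nrow(object$components))) {
    ck <- object$components[k, ]
    out[ok] <- out[ok] + ck$area / ck$tau * exp(-x[ok] / ck$tau)
  }
  out
}

#' @export
print.exp_mixture_fit <- function(x, ...) {
  cat("Exponential mixture fit (", nrow(x$components), " components, n = ",
      x$n, ", logL = ", signif(x$loglik, 8), ")\n", sep = "")
  comp <- x$components
  comp$tau_ms <- comp$tau * 1e3
  print(comp, row.names = FALSE)
  invisible(x)
}

#' Select the number of exponential components
#'
#' Starting from one component, an extra component is accepted while the
#' likelihood-ratio statistic `2 * (logL_{k+1} - logL_k)` exceeds
#' `lrt_threshold` (default 10, the conventional single-channel criterion),
#' up to `max_components`.
#'
#' @inheritParams fit_exp_mixture
#' @param max_components Largest k considered.
#' @param lrt_threshold Acceptance threshold for `2 * delta logL`.
#' @return The selected component count (integer); the per-k fits are
#'   attached as attribute `fits`.
#' @export
select_component_count <- function(dwells, max_components = 4, dead_time = 0,
                                   lrt_threshold = 10, n_starts = 5,
                                   seed = 1) {
  stopifnot(max_components >= 1)
  fits <- list(fit_exp_mixture(dwells, 1, dead_time, n_starts, seed))
  k <- 1L
  while (k < max_components) {
    cand <- fit_exp_mixture(dwells, k + 1L, dead_time, n_starts, seed)
    fits[[k + 1L]] <- cand
    if (2 * (cand$loglik - fits[[k]]$loglik) <= lrt_threshold) break
    k <- k + 1L
  }
  structure(k, fits = fits)
}
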