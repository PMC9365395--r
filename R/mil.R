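#' Missed-event-corrected dwell kernels
#'
#' First-order missed-event correction for aggregated Markov likelihoods:
#' sojourns in the opposite conductance class shorter than the dead time are
#' unobserved, so the within-class sub-generators are corrected to
#' `Q~_aa = Q_aa + Q_af (I - exp(Q_ff td)) (-Q_ff)^-1 Q_fa`
#' and a dwell of apparent duration `t` in class `a` followed by a detected
#' transition to class `b` contributes
#' `exp(Q~_aa (t - td)) Q_ab exp(Q_bb td)`
#' (the trailing factor is the probability that the next dwell survives the
#' dead time, which makes the two-state apparent-dwell density integrate
#' exactly to one). At `td = 0` the kernels reduce to the ideal ones.
#'
#' @param g A [build_generator()] result.
#' @param dead_time Dead time in seconds (>= 0).
#' @param warn Warn when the dead time is long relative to the shortest
#'   state lifetime (the correction regime is then questionable). Disabled
#'   inside likelihood optimization, where extreme trial rates are routine.
#' @return List with corrected sub-generators (`qc_shut`, `qc_open`), cross
#'   factors (`cross_so`, `cross_os`), steady-state class entry vectors
#'   (`phi_shut`, `phi_open`), state index sets and `dead_time`.
#' @export
corrected_kernels <- function(g, dead_time, warn = TRUE) {
  stopifnot(inherits(g, "generator_matrix"), dead_time >= 0)
  s <- .class_idx(g, "shut"); o <- .class_idx(g, "open")
  q <- g$q
  qss <- q[s, s, drop = FALSE]; qoo <- q[o, o, drop = FALSE]
  qso <- q[s, o, drop = FALSE]; qos <- q[o, s, drop = FALSE]
  if (dead_time > 0) {
    mean_dwells <- c(-1 / diag(qss), -1 / diag(qoo))
    if (warn && dead_time >= min(mean_dwells) * 10)
      warning("dead time is large relative to the shortest state lifetime; ",
              "first-order missed-event correction may be inaccurate")
    eo <- .expm(qoo * dead_time); es <- .expm(qss * dead_time)
    ns <- length(s); no <- length(o)
    # tol = 0: badly scaled (but invertible) sub-generators arise routinely
    # at extreme trial rates during optimization
    qc_shut <- qss + qso %*% (diag(no) - eo) %*% solve(-qoo, tol = 0) %*% qos
    qc_open <- qoo + qos %*% (diag(ns) - es) %*% solve(-qss, tol = 0) %*% qso
    cross_so <- qso %*% eo
    cross_os <- qos %*% es
  } else {
    qc_shut <- qss; qc_open <- qoo
    cross_so <- qso; cross_os <- qos
  }
  pi <- equilibrium_occupancy(g)
  phi_s <- as.numeric(pi[o] %*% qos); phi_s <- phi_s / sum(phi_s)
  phi_o <- as.numeric(pi[s] %*% qso); phi_o <- phi_o / sum(phi_o)
  list(qc_shut = qc_shut, qc_open = qc_open,
       cross_so = cross_so, cross_os = cross_os,
       phi_shut = phi_s, phi_open = phi_o,
       shut_idx = s, open_idx = o, dead_time = dead_time)
}

#' Apparent dwell-time density under the missed-event correction
#'
#' Density of detected (apparent) dwells of a class, `t >= dead_time`, from
#' the corrected kernels. At `dead_time = 0` this equals
#' [ideal_dwell_density()].
#'
#' @inheritParams corrected_kernels
#' @param cls `"shut"` or `"open"`.
#' @param t Times in seconds.
#' @return Density values (s^-1); zero below the dead time.
#' @export
apparent_dwell_density <- function(g, cls = c("shut", "open"), t,
                                   dead_time) {
  cls <- match.arg(cls)
  k <- corrected_kernels(g, dead_time)
  if (cls == "shut") {
    qa <- k$qc_shut; cr <- k$cross_so; phi <- k$phi_shut
  } else {
    qa <- k$qc_open; cr <- k$cross_os; phi <- k$phi_open
  }
  ones <- rep(1, ncol(cr))
  vapply(t, function(ti) {
    if (ti < dead_time) return(0)
    as.numeric(phi %*% .expm(qa * (ti - dead_time)) %*% cr %*% ones)
  }, numeric(1))
}

# normalize one recording's data into dwell sequences for the likelihood:
# a burst_set contributes one sequence per burst, an event_list one sequence
.dwell_sequences <- function(data) {
  if (inherits(data, "burst_set")) {
    lapply(data$bursts, function(b) list(cls = as.integer(b$class == "open"),
                                         dur = b$duration))
  } else if (inherits(data, "event_list")) {
    list(list(cls = as.integer(data$class == "open"), dur = data$duration))
  } else stop("recording data must be an event_list or burst_set")
}

#' Define a missed-event likelihood fitting problem
#'
#' @param scheme A [kinetic_scheme()].
#' @param recordings List of recordings; each is a list with `events` (an
#'   [event_list()] or [burst_set()][define_bursts()], already dead-time
#'   conditioned) and optionally `concentrations` (named uM vector for that
#'   recording). A bare `event_list`/`burst_set` is also accepted.
#' @param dead_time Dead time in seconds shared by all recordings.
#' @param fixed Named numeric vector of rate symbols held constant.
#' @param start Named numeric vector of start values for free symbols
#'   (defaults to the scheme's current rates).
#' @return Object of class `fit_problem`.
#' @export
fit_problem <- function(scheme, recordings, dead_time = 0, fixed = NULL,
                        start = NULL) {
  stopifnot(inherits(scheme, "kinetic_scheme"), dead_time >= 0)
  if (inherits(recordings, c("event_list", "burst_set")))
    recordings <- list(list(events = recordings))
  recordings <- lapply(recordings, function(r) {
    if (inherits(r, c("event_list", "burst_set"))) r <- list(events = r)
    if (is.null(r$concentrations))
      r$concentrations <- attr(r$events, "meta")$concentrations %||%
        (if (inherits(r$events, "burst_set")) r$events$meta$concentrations)
    r
  })
  syms <- scheme$transitions$symbol
  if (!is.null(fixed)) {
    bad <- setdiff(names(fixed), syms)
    if (length(bad)) stop("unknown fixed symbols: ", paste(bad, collapse = ", "))
  }
  rates <- scheme_rates(scheme)
  if (!is.null(start)) rates[names(start)] <- start
  if (!is.null(fixed)) rates[names(fixed)] <- fixed
  structure(list(scheme = scheme, recordings = recordings,
                 dead_time = dead_time,
                 fixed = fixed, start = rates,
                 free_symbols = setdiff(syms, names(fixed))),
            class = "fit_problem")
}

#' Sequence log-likelihood of dwell data under a scheme
#'
#' Sums, over recordings and bursts, the forward log-likelihood
#' `log(phi prod_i exp(Q~_aa (t_i - td)) Q_ab exp(Q_bb td) 1)` with the
#' missed-event-corrected kernels of [corrected_kernels()]. The start vector
#' of each dwell sequence is the steady-state entry vector of its first
#' dwell's class. Ligand-dependent rates are rebuilt per recording from that
#' recording's concentrations.
#'
#' @param problem A [fit_problem()].
#' @param rates Named rates to evaluate at (defaults to the problem's start
#'   values; must cover all scheme symbols).
#' @return Log-likelihood (scalar). Non-finite likelihoods return a large
#'   negative value.
#' @export
sequence_loglik <- function(problem, rates = NULL) {
  stopifnot(inherits(problem, "fit_problem"))
  full <- problem$start
  if (!is.null(rates)) full[names(rates)] <- rates
  scheme <- set_scheme_rates(problem$scheme, full)
  td <- problem$dead_time
  total <- 0
  for (rec in problem$recordings) {
    g <- build_generator(scheme, rec$concentrations)
    # degenerate trial rates (e.g. at box bounds) can make the correction
    # terms singular; treat such points as likelihood floor
    k <- tryCatch(corrected_kernels(g, td, warn = FALSE),
                  error = function(e) NULL)
    if (is.null(k)) return(-1e15)
    seqs <- .dwell_sequences(rec$events)
    seqs <- seqs[vapply(seqs, function(s) length(s$cls) > 0, logical(1))]
    if (!length(seqs)) next
    cls <- unlist(lapply(seqs, `[[`, "cls"))
    dur <- unlist(lapply(seqs, `[[`, "dur")) - td
    if (any(dur < -1e-12))
      stop("dwell shorter than the dead time; condition the data with ",
           "impose_dead_time() first")
    dur <- pmax(dur, 0)
    len <- vapply(seqs, function(s) length(s$cls), integer(1))
    ptr <- c(0L, cumsum(len))[seq_along(len)]
    total <- total + forward_loglik_cpp(
      k$qc_shut, k$qc_open, k$cross_so, k$cross_os,
      k$phi_shut, k$phi_open,
      as.integer(cls), as.numeric(dur), as.integer(ptr), as.integer(len))
  }
  total
}

#' Missed-event-corrected maximum-likelihood fit of rate constants
#'
#' Global fit of a kinetic scheme to dwell sequences from one or more
#' recordings (which may be at different ligand concentrations but share the
#' same rate constants). Free rates are optimized on the log scale with box
#' bounds; fixed rates are honored exactly. Standard errors come from the
#' inverse observed information (numerical Hessian in log-rate space, delta
#' method back to natural units).
#'
#' @param problem A [fit_problem()].
#' @param n_starts Number of optimizer starts (start 1 from the problem's
#'   start values, the rest log-jittered; deterministic given `seed`).
#' @param seed Seed for the jittered starts.
#' @param lower,upper Box bounds for rates, s^-1 (applied on the log scale).
#' @param compute_se Compute standard errors (skipped for speed if `FALSE`).
#' @return Object of class `fit_result`: `estimates` (`data.frame` with
#'   `symbol`, `value`, `se`, `fixed`), `loglik`, `converged`, `n_dwells`,
#'   `derived` (equilibrium constants from the fitted rates), `problem`
#'   settings echo.
#' @seealso [constrained_refit()], [sequence_loglik()]
#' @export
mil_fit <- function(problem, n_starts = 1, seed = 1,
                    lower = 1e-2, upper = 1e7, compute_se = TRUE) {
  stopifnot(inherits(problem, "fit_problem"))
  free <- problem$free_symbols
  if (!length(free)) { # nothing to optimize: evaluate at the fixed values
    ll <- sequence_loglik(problem)
    return(.fit_result(problem, problem$start, ll, TRUE, NULL))
  }
  start <- problem$start[free]
  if (any(start <= 0)) stop("start values must be positive")
  obj <- function(lp) {
    r <- stats::setNames(exp(lp), free)
    -sequence_loglik(problem, r)
  }
  set.seed(seed)
  starts <- list(log(start))
  for (s in seq_len(max(0, n_starts - 1)))
    starts[[s + 1]] <- log(start) + stats::rnorm(length(free), 0, 0.5)
  best <- NULL
  for (st in starts) {
    opt <- stats::optim(st, obj, method = "L-BFGS-B",
                        lower = log(lower), upper = log(upper),
                        control = list(maxit = 500, factr = 1e4))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  est <- stats::setNames(exp(best$par), free)
  full <- problem$start
  full[free] <- est
  se <- NULL
  if (compute_se) {
    h <- try(stats::optimHess(best$par, obj), silent = TRUE)
    if (!inherits(h, "try-error")) {
      cov <- try(solve(h), silent = TRUE)
      if (!inherits(cov, "try-error") && all(diag(cov) > 0)) {
        se <- est * sqrt(diag(cov)) # delta method from log scale
        names(se) <- free
      }
    }
    if (is.null(se))
      warning("information matrix singular or not positive definite; ",
              "standard errors unavailable")
  }
  .fit_result(problem, full, -best$value, best$convergence == 0, se)
}

.fit_result <- function(problem, rates, loglik, converged, se) {
  syms <- problem$scheme$transitions$symbol
  est <- data.frame(symbol = syms,
                    value = as.numeric(rates[syms]),
                    se = if (is.null(se)) NA_real_ else
                      as.numeric(se[syms]),
                    fixed = syms %in% names(problem$fixed))
  n_dwells <- sum(vapply(problem$recordings, function(r) {
    sum(vapply(.dwell_sequences(r$events), function(s) length(s$cls),
               integer(1)))
  }, integer(1)))
  derived <- tryCatch(derived_constants(stats::setNames(est$value, est$symbol)),
                      error = function(e) numeric(0))
  structure(list(estimates = est, loglik = loglik, converged = converged,
                 n_dwells = n_dwells, derived = derived,
                 dead_time = problem$dead_time, fixed = problem$fixed,
                 scheme_name = problem$scheme$name),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("MIL fit of scheme '", x$scheme_name, "': logL = ",
      sprintf("%.3f", x$loglik), " on ", x$n_dwells, " dwells (dead time ",
      signif(x$dead_time * 1e6, 4), " us)",
      if (!x$converged) " [NOT CONVERGED]", "\n", sep = "")
  est <- x$estimates
  est$value <- signif(est$value, 5)
  est$se <- signif(est$se, 3)
  print(est, row.names = FALSE)
  if (length(x$derived)) {
    cat("Derived equilibrium constants:\n")
    print(signif(x$derived, 4))
  }
  invisible(x)
}

#' Refit with constraints and report both fits
#'
#' Re-fits a problem with additional rate constants held at given values —
#' the standard check that constraining the core scheme to independently
#' determined rates leaves the remaining estimates (e.g. blocking rates)
#' essentially unchanged.
#'
#' @param problem A [fit_problem()].
#' @param constrain Named numeric vector of symbols to hold constant.
#' @param free_fit An existing unconstrained [mil_fit()] result to compare
#'   against, or `NULL` to fit it here.
#' @param ... Passed to [mil_fit()].
#' @return List of class `fit_comparison` with elements `free` and
#'   `constrained` (both `fit_result`).
#' @export
constrained_refit <- function(problem, constrain, free_fit = NULL, ...) {
  stopifnot(inherits(problem, "fit_problem"))
  if (is.null(free_fit)) free_fit <- mil_fit(problem, ...)
  cons_problem <- fit_problem(problem$scheme, problem$recordings,
                              dead_time = problem$dead_time,
                              fixed = c(problem$fixed, constrain),
                              start = problem$start)
  cons_fit <- mil_fit(cons_problem, ...)
  structure(list(free = free_fit, constrained = cons_fit),
            class = "fit_comparison")
}

#' @export
print.fit_comparison <- function(x, ...) {
  cat("-- free fit --\n"); print(x$free)
  cat("-- constrained fit --\n"); print(x$constrained)
  invisible(x)
}
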