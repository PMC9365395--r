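#' Idealize a current trace by half-amplitude threshold crossing
#'
#' Transitions are placed where the trace crosses the 50% level between
#' baseline and open amplitude, with linear interpolation between samples.
#' The partial segments before the first and after the last crossing are
#' incompletely observed and are discarded, so the returned list starts and
#' ends at a detected transition.
#'
#' @param trace List with `t` (seconds) and `current` (pA), as returned by
#'   [simulate_trace()], or a numeric current vector with `sample_rate` given.
#' @param open_amplitude,baseline Open-channel and baseline current levels
#'   (pA); must differ. Polarity is handled automatically.
#' @param sample_rate Hz; required when `trace` is a bare numeric vector.
#' @param meta Metadata for the returned [event_list()].
#' @return An [event_list()] of alternating dwells; empty (with a warning) if
#'   the trace never crosses the threshold.
#' @export
idealize_trace <- function(trace, open_amplitude, baseline = 0,
                           sample_rate = NULL, meta = list()) {
  if (is.numeric(trace)) {
    if (is.null(sample_rate)) stop("sample_rate required for a bare vector")
    trace <- list(t = (seq_along(trace) - 0.5) / sample_rate, current = trace)
  }
  if (open_amplitude == baseline) stop("open_amplitude must differ from baseline")
  x <- (trace$current - baseline) / (open_amplitude - baseline) # open level -> 1
  thr <- 0.5
  above <- x > thr
  flips <- which(diff(above) != 0L)
  if (!length(flips)) {
    warning("trace never crosses the half-amplitude threshold; empty event list")
    return(event_list(character(0), numeric(0), meta = meta))
  }
  # interpolated crossing times
  tc <- trace$t[flips] + (thr - x[flips]) / (x[flips + 1L] - x[flips]) *
    (trace$t[flips + 1L] - trace$t[flips])
  if (length(tc) < 2) {
    warning("only one threshold crossing; empty event list")
    return(event_list(character(0), numeric(0), meta = meta))
  }
  dur <- diff(tc)
  # dwell after an upward crossing is open
  cls <- ifelse(above[flips + 1L], "open", "shut")[-length(tc)]
  event_list(cls, dur, meta = meta)
}

# merge consecutive same-class events (conditioning for raw input files)
normalize_events <- function(events) {
  if (!nrow(events)) return(events)
  r <- rle(events$class)
  if (all(r$lengths == 1L)) return(events)
  idx <- rep.int(seq_along(r$lengths), r$lengths)
  dur <- as.numeric(tapply(events$duration, idx, sum))
  amp <- as.numeric(tapply(events$amplitude, idx,
                           function(a) mean(a, na.rm = TRUE)))
  event_list(r$values, dur, ifelse(is.nan(amp), NA_real_, amp),
             meta = attr(events, "meta"))
}

#' Correct brief dwell durations for filter risetime
#'
#' Half-amplitude threshold detection through a Gaussian filter shortens the
#' apparent duration of events comparable to the filter risetime
#' (Tr = 0.3321/fc, 10-90%). This inverts the filter's width transfer
#' relation: for each observed width the true rectangular-pulse duration that
#' would produce it is recovered numerically. Events much longer than the
#' risetime (over about 3 Tr) are practically unchanged.
#'
#' @param events An [event_list()] of apparent dwells.
#' @param filter_fc Filter cutoff in Hz (> 0). `Inf` is the identity.
#' @return The event list with corrected durations.
#' @export
correct_risetime <- function(events, filter_fc) {
  stopifnot(inherits(events, "event_list"), filter_fc > 0)
  if (!nrow(events) || is.infinite(filter_fc)) return(events)
  tr <- 0.3321 / filter_fc
  sigma <- tr / 2.5631
  short <- events$duration < 5 * tr
  if (!any(short)) return(events)
  d <- events$duration
  d[short] <- vapply(d[short], .invert_apparent_width, numeric(1), sigma = sigma)
  out <- event_list(events$class, d, events$amplitude,
                    meta = attr(events, "meta"))
  out
}

# observed half-amplitude width of a rectangular pulse of true duration d
# after a Gaussian filter with impulse-response SD sigma; 0 if the filtered
# peak stays below half amplitude
.apparent_width <- function(d, sigma) {
  peak <- 2 * stats::pnorm(d / (2 * sigma)) - 1
  if (peak <= 0.5) return(0)
  g <- function(x) stats::pnorm((x + d / 2) / sigma) -
    stats::pnorm((x - d / 2) / sigma) - 0.5
  2 * stats::uniroot(g, c(0, d / 2 + 8 * sigma), tol = sigma * 1e-9)$root
}

.invert_apparent_width <- function(w, sigma) {
  d_min <- 2 * sigma * stats::qnorm(0.75)
  h <- function(d) .apparent_width(d, sigma) - w
  lo <- d_min * (1 + 1e-9)
  if (h(lo) >= 0) return(lo)
  hi <- w + 6 * sigma
  stats::uniroot(h, c(lo, hi), tol = sigma * 1e-9)$root
}

#' Impose a dead time on an event list
#'
#' Emulates the finite time resolution of event detection: every dwell
#' shorter than `dead_time` is treated as undetected and its duration is
#' folded into the merge of its two neighbours (which share a class). The
#' output strictly alternates, contains no dwell shorter than `dead_time`,
#' conserves total duration up to dropped boundary events, and the operation
#' is idempotent. Undetectable events at the very start or end of the record
#' have no two neighbours to merge and are dropped.
#'
#' @param events An [event_list()] (alternating).
#' @param dead_time Dead time in seconds (>= 0).
#' @return The censored [event_list()]; its metadata records `dead_time`.
#' @export
impose_dead_time <- function(events, dead_time) {
  stopifnot(inherits(events, "event_list"), dead_time >= 0)
  meta <- attr(events, "meta")
  meta$dead_time <- dead_time
  if (!nrow(events) || dead_time == 0) {
    attr(events, "meta") <- meta
    return(events)
  }
  events <- normalize_events(events)
  cls <- events$class; dur <- events$duration
  n <- length(dur)
  out_cls <- character(n); out_dur <- numeric(n)
  m <- 0L
  pending <- 0
  last_missed_cls <- ""; last_missed_dur <- 0
  i <- 1L
  # skip undetectable leading events
  while (i <= n && dur[i] < dead_time) i <- i + 1L
  while (i <= n) {
    if (dur[i] < dead_time) {
      pending <- pending + dur[i] # missed: accrues to the last kept dwell
      last_missed_cls <- cls[i]; last_missed_dur <- dur[i]
    } else {
      # a run of missed events is recursively absorbed by the dwell before it
      if (pending > 0 && m > 0L) {
        out_dur[m] <- out_dur[m] + pending
      }
      pending <- 0
      if (m > 0L && cls[i] == out_cls[m]) {
        out_dur[m] <- out_dur[m] + dur[i]
      } else {
        m <- m + 1L
        out_cls[m] <- cls[i]
        out_dur[m] <- dur[i]
      }
    }
    i <- i + 1L
  }
  if (pending > 0 && m > 0L) {
    # trailing run of missed events: absorbed by the final dwell, except a
    # last unpaired opposite-class event, which is an unmergeable boundary
    if (last_missed_cls != out_cls[m]) pending <- pending - last_missed_dur
    out_dur[m] <- out_dur[m] + pending
  }
  if (m == 0L) {
    warning("dead time removed every event")
    return(event_list(character(0), numeric(0), meta = meta))
  }
  event_list(out_cls[seq_len(m)], out_dur[seq_len(m)], meta = meta)
}

#' Critical closed duration from adjacent exponential components
#'
#' The critical closed duration separating intra-burst from inter-burst
#' closings is the time at which the probability-density contributions of the
#' two flanking shut components are equal:
#' `a1/tau1 exp(-t/tau1) = a2/tau2 exp(-t/tau2)`, i.e.
#' `t = log(a1 tau2 / (a2 tau1)) / (1/tau1 - 1/tau2)`.
#'
#' @param components `data.frame` with columns `area` and `tau` (seconds),
#'   e.g. from [fit_exp_mixture()] or [ideal_dwell_components()]; sorted by
#'   increasing `tau` internally.
#' @param split Index of the slowest intra-burst component; the intersection
#'   is computed between components `split` and `split + 1`. Defaults to the
#'   penultimate component, i.e. the intersection of the two slowest.
#' @return The critical closed duration in seconds (between the two taus).
#' @examples
#' comp <- data.frame(area = c(0.7, 0.3), tau = c(6e-5, 0.5))
#' determine_tau_crit(comp) # ~0.593 ms
#' @export
determine_tau_crit <- function(components, split = nrow(components) - 1L) {
  stopifnot(is.data.frame(components), nrow(components) >= 2,
            all(c("area", "tau") %in% names(components)))
  components <- components[order(components$tau), , drop = FALSE]
  if (split < 1 || split >= nrow(components)) stop("invalid split index")
  a1 <- components$area[split];      tau1 <- components$tau[split]
  a2 <- components$area[split + 1L]; tau2 <- components$tau[split + 1L]
  if (tau1 >= tau2) stop("components must have distinct taus (tau1 < tau2)")
  tc <- log(a1 * tau2 / (a2 * tau1)) / (1 / tau1 - 1 / tau2)
  if (!is.finite(tc) || tc <= 0)
    stop("no positive intersection for these components")
  tc
}

#' Partition an event list into bursts
#'
#' Shut dwells longer than `tau_crit` separate bursts attributable to
#' different activation epochs and are excluded from within-burst data.
#' Bursts are trimmed to start and end with an opening; bursts with fewer
#' than three events are omitted. Per burst, the open probability is open
#' time over total burst duration, and the amplitude is the mean open level
#' minus the mean shut level (when amplitudes are available).
#'
#' @param events An [event_list()].
#' @param tau_crit Critical closed duration in seconds; `Inf` puts all events
#'   in one burst.
#' @return Object of class `burst_set`: list with `bursts` (list of
#'   [event_list()] fragments), `summary` (`data.frame` with `n_events`,
#'   `duration`, `p_open`, `amplitude`), `tau_crit`, and counts of dropped
#'   fragments.
#' @export
define_bursts <- function(events, tau_crit) {
  stopifnot(inherits(events, "event_list"), tau_crit > 0)
  meta <- attr(events, "meta")
  sep <- events$class == "shut" & events$duration > tau_crit
  grp <- cumsum(sep)
  keep <- !sep
  frags <- split(as.data.frame(events)[keep, , drop = FALSE], grp[keep])
  bursts <- list(); dropped <- 0L
  for (f in frags) {
    op <- which(f$class == "open")
    if (!length(op)) { dropped <- dropped + 1L; next }
    f <- f[min(op):max(op), , drop = FALSE] # bursts start and end open
    if (nrow(f) < 3) { dropped <- dropped + 1L; next }
    bursts[[length(bursts) + 1L]] <-
      event_list(f$class, f$duration, f$amplitude, meta = meta)
  }
  summ <- do.call(rbind, lapply(bursts, function(b) {
    open <- b$class == "open"
    amp <- if (all(is.na(b$amplitude))) NA_real_ else {
      op_amp <- mean(b$amplitude[open], na.rm = TRUE)
      sh_amp <- mean(b$amplitude[!open], na.rm = TRUE)
      if (is.nan(sh_amp)) op_amp else op_amp - sh_amp
    }
    data.frame(n_events = nrow(b), duration = sum(b$duration),
               p_open = sum(b$duration[open]) / sum(b$duration),
               amplitude = amp)
  }))
  if (is.null(summ))
    summ <- data.frame(n_events = integer(0), duration = numeric(0),
                       p_open = numeric(0), amplitude = numeric(0))
  structure(list(bursts = bursts, summary = summ, tau_crit = tau_crit,
                 n_dropped_short = dropped, meta = meta),
            class = "burst_set")
}

#' @export
print.burst_set <- function(x, ...) {
  cat("Burst set: ", length(x$bursts), " bursts (tau_crit = ",
      signif(x$tau_crit * 1e3, 4), " ms, ", x$n_dropped_short,
      " fragments with < 3 events dropped)\n", sep = "")
  if (nrow(x$summary))
    cat("  mean P_open ", signif(mean(x$summary$p_open), 4),
        ", mean openings/burst ",
        signif(mean((x$summary$n_events + 1) / 2), 4), "\n", sep = "")
  invisible(x)
}

#' Filter bursts by open probability
#'
#' Two-pass cleanup of the per-burst open-probability distribution, used to
#' exclude bursts contaminated by overlapping channels or modal shifts:
#' first gross outliers are removed (median +/- `k_mad` * MAD), then a
#' Gaussian is fit to the survivors and bursts within `n_sigma` standard
#' deviations of the mean are retained.
#'
#' @param burst_set A [define_bursts()] result.
#' @param k_mad MAD multiplier for the outlier pass (default 5).
#' @param n_sigma Gaussian retention half-width in SDs (default 2).
#' @return The filtered `burst_set`; attribute `filter_log` records how many
#'   bursts each pass removed. Fewer than 5 bursts passes through unchanged
#'   with a warning.
#' @export
filter_bursts_by_popen <- function(burst_set, k_mad = 5, n_sigma = 2) {
  stopifnot(inherits(burst_set, "burst_set"))
  p <- burst_set$summary$p_open
  if (length(p) < 5) {
    warning("fewer than 5 bursts; P_open filter skipped")
    attr(burst_set, "filter_log") <- c(outlier = 0L, gaussian = 0L)
    return(burst_set)
  }
  med <- stats::median(p); madv <- stats::mad(p)
  keep1 <- if (madv > 0) abs(p - med) <= k_mad * madv else rep(TRUE, length(p))
  mu <- mean(p[keep1]); sdv <- stats::sd(p[keep1])
  keep2 <- keep1 & (if (isTRUE(sdv > 0)) abs(p - mu) <= n_sigma * sdv
                    else rep(TRUE, length(p)))
  out <- burst_set
  out$bursts <- burst_set$bursts[keep2]
  out$summary <- burst_set$summary[keep2, , drop = FALSE]
  rownames(out$summary) <- NULL
  attr(out, "filter_log") <- c(outlier = sum(!keep1),
                               gaussian = sum(keep1 & !keep2))
  out
}
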