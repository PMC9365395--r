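#' Event list constructor
#'
#' An event list is the idealized record of one recording: an ordered sequence
#' of dwells, each with a conductance class (`"shut"`/`"open"`), a duration in
#' seconds and an optional amplitude in pA, plus recording metadata.
#'
#' @param class Character vector of `"shut"`/`"open"` (or 0/1).
#' @param duration Numeric vector of dwell durations in seconds (> 0).
#' @param amplitude Optional numeric vector of per-event amplitudes (pA).
#' @param meta List of metadata: `id`, `concentrations` (named uM vector),
#'   `filter_fc` (Hz), `dead_time` (s), `voltage` (mV). Missing entries are
#'   filled with `NA`.
#' @return `data.frame` of class `event_list` with attribute `meta`.
#' @export
event_list <- function(class, duration, amplitude = NULL, meta = list()) {
  if (is.numeric(class)) class <- ifelse(class > 0, "open", "shut")
  class <- as.character(class)
  stopifnot(all(class %in% c("shut", "open")), length(class) == length(duration))
  if (any(!is.finite(duration)) || any(duration <= 0))
    stop("durations must be positive and finite")
  if (is.null(amplitude)) amplitude <- rep(NA_real_, length(class))
  df <- data.frame(class = class, duration = as.numeric(duration),
                   amplitude = as.numeric(amplitude))
  defaults <- list(id = NA_character_, concentrations = NULL,
                   filter_fc = NA_real_, dead_time = NA_real_,
                   voltage = NA_real_)
  meta <- utils::modifyList(defaults, meta)
  structure(df, meta = meta, class = c("event_list", "data.frame"))
}

#' @export
print.event_list <- function(x, ...) {
  m <- attr(x, "meta")
  cat("Event list '", m$id, "': ", nrow(x), " events, ",
      signif(sum(x$duration), 4), " s total (",
      sum(x$class == "open"), " open)\n", sep = "")
  utils::str(utils::head(as.data.frame(x)))
  invisible(x)
}

event_meta <- function(x) attr(x, "meta")

#' Simulate a state path of a gating scheme
#'
#' Exact stochastic simulation of the continuous-time Markov chain: sojourn
#' times are exponential with rate `-q_ii`, successors drawn proportionally to
#' `q_ij`, and the start state is drawn from the equilibrium occupancy (the
#' recordings being emulated are steady-state patches). Simulation stops once
#' the path contains `n_events` aggregated dwells (class runs).
#'
#' @param scheme A [kinetic_scheme()].
#' @param n_events Number of aggregated (class-level) events to generate.
#' @param concentrations Named ligand concentrations in uM.
#' @param seed Integer seed (mandatory: simulated data must be reproducible).
#' @param start `"equilibrium"` (default) or a state name.
#' @return `data.frame` with columns `state`, `class`, `sojourn` (seconds).
#' @export
simulate_state_path <- function(scheme, n_events, concentrations = NULL,
                                seed, start = "equilibrium") {
  stopifnot(inherits(scheme, "kinetic_scheme"), n_events >= 1)
  if (missing(seed)) stop("`seed` is mandatory")
  g <- build_generator(scheme, concentrations)
  q <- g$q
  n <- nrow(q)
  exit <- -diag(q)
  if (any(exit <= 0)) stop("absorbing state in scheme: ",
                           g$states[which(exit <= 0)[1]])
  p <- q / exit
  diag(p) <- 0
  cum <- t(apply(p, 1, cumsum))
  cls_num <- as.integer(g$classes == "open")

  set.seed(seed)
  s0 <- if (identical(start, "equilibrium")) {
    sample.int(n, 1, prob = equilibrium_occupancy(g))
  } else match(start, g$states)
  if (is.na(s0)) stop("unknown start state")

  chunk <- max(1024L, min(n_events * 2L, 2^18))
  states <- integer(0); sojourns <- numeric(0)
  cur <- s0; events <- 1L; last_cls <- cls_num[cur]
  repeat {
    u_next <- stats::runif(chunk)
    u_exp <- stats::rexp(chunk)
    st_chunk <- integer(chunk); so_chunk <- numeric(chunk)
    used <- 0L
    for (i in seq_len(chunk)) {
      st_chunk[i] <- cur
      so_chunk[i] <- u_exp[i] / exit[cur]
      used <- i
      nxt <- findInterval(u_next[i], cum[cur, ]) + 1L
      if (cls_num[nxt] != last_cls) {
        events <- events + 1L
        last_cls <- cls_num[nxt]
      }
      cur <- nxt
      if (events > n_events) break
    }
    states <- c(states, st_chunk[seq_len(used)])
    sojourns <- c(sojourns, so_chunk[seq_len(used)])
    if (events > n_events) break
  }
  data.frame(state = g$states[states],
             class = c("shut", "open")[cls_num[states] + 1L],
             sojourn = sojourns)
}

#' Aggregate a state path into an event list
#'
#' Merges consecutive sojourns of the same conductance class; the result
#' strictly alternates shut/open and conserves total duration.
#'
#' @param path Result of [simulate_state_path()].
#' @param meta Metadata list passed to [event_list()].
#' @return An [event_list()].
#' @export
aggregate_to_events <- function(path, meta = list()) {
  stopifnot(nrow(path) >= 1)
  r <- rle(path$class)
  idx <- rep.int(seq_along(r$lengths), r$lengths)
  dur <- as.numeric(tapply(path$sojourn, idx, sum))
  event_list(r$values, dur, meta = meta)
}

#' Simulate an event list from a scheme
#'
#' Convenience wrapper: [simulate_state_path()] then [aggregate_to_events()].
#' The ideal event list has no dead-time censoring; apply
#' [impose_dead_time()] to emulate limited recording bandwidth.
#'
#' @inheritParams simulate_state_path
#' @param id Recording identifier stored in the metadata.
#' @return An [event_list()] (ideal, i.e. uncensored).
#' @export
simulate_events <- function(scheme, n_events, concentrations = NULL, seed,
                            id = paste0(scheme$name, "-sim", seed)) {
  path <- simulate_state_path(scheme, n_events, concentrations, seed = seed)
  aggregate_to_events(path, meta = list(id = id,
                                        concentrations = concentrations))
}

#' Simulate a sampled current trace from an event list
#'
#' Renders the idealized rectangular current (shut = `baseline_pA`, open =
#' `open_pA` or the per-event amplitude), applies a Gaussian filter of cutoff
#' `filter_fc` (the standard stand-in for the recording chain's Bessel
#' filter; its 10-90% risetime is 0.3321/fc), and adds white Gaussian noise.
#'
#' @param events An [event_list()].
#' @param sample_rate Sampling rate in Hz.
#' @param filter_fc Filter cutoff in Hz, or `NULL` for no filtering. Must not
#'   exceed the Nyquist frequency.
#' @param noise_sd Noise standard deviation in pA.
#' @param open_pA,baseline_pA Class amplitudes in pA (per-event amplitudes in
#'   `events` take precedence for open dwells).
#' @param seed Integer seed for the noise (mandatory when `noise_sd > 0`).
#' @return List with `t` (seconds) and `current` (pA).
#' @export
simulate_trace <- function(events, sample_rate, filter_fc = NULL,
                           noise_sd = 0, open_pA = 16, baseline_pA = 0,
                           seed = NULL) {
  stopifnot(inherits(events, "event_list"))
  if (!is.null(filter_fc) && filter_fc > sample_rate / 2)
    stop("filter_fc exceeds the Nyquist frequency")
  if (noise_sd > 0 && is.null(seed)) stop("`seed` is mandatory when noise_sd > 0")
  amp <- ifelse(events$class == "open",
                ifelse(is.na(events$amplitude), open_pA, events$amplitude),
                baseline_pA)
  edges <- cumsum(events$duration)
  n <- ceiling(edges[length(edges)] * sample_rate)
  tt <- (seq_len(n) - 0.5) / sample_rate
  idx <- findInterval(tt, c(0, edges), rightmost.closed = TRUE)
  ideal <- amp[pmin(pmax(idx, 1L), length(amp))]
  out <- ideal
  if (!is.null(filter_fc)) {
    sigma <- 0.3321 / (2.5631 * filter_fc) * sample_rate # samples
    half <- ceiling(4 * sigma)
    k <- stats::dnorm(seq(-half, half), sd = sigma)
    k <- k / sum(k)
    padded <- c(rep(ideal[1], half), ideal, rep(ideal[length(ideal)], half))
    out <- stats::convolve(padded, rev(k), type = "filter")
  }
  if (noise_sd > 0) {
    set.seed(seed)
    out <- out + stats::rnorm(length(out), sd = noise_sd)
  }
  list(t = tt, current = out)
}

#' Simulate fingerprinting burst amplitudes from binomial pentamer assembly
#'
#' Emulates co-expression of high-conductance (HC) and low-conductance (LC)
#' subunit variants: each channel draws its HC-subunit count from
#' `Binomial(n_subunits, p_hc)`, contributes amplitude linearly in that count
#' between the all-LC and all-HC endpoints, and each measured burst amplitude
#' adds Gaussian within-class jitter.
#'
#' @param n_bursts Number of bursts.
#' @param p_hc Probability that a subunit slot is HC.
#' @param amp_lc,amp_hc All-LC and all-HC channel amplitudes in pA
#'   (`amp_hc > amp_lc > 0`).
#' @param class_sd Within-class amplitude SD in pA.
#' @param n_subunits Subunits per channel (default 5, a pentamer).
#' @param seed Integer seed (mandatory).
#' @return `data.frame` with `amplitude` (pA) and the hidden ground-truth
#'   `hc_count` per burst.
#' @export
simulate_fingerprint_bursts <- function(n_bursts, p_hc, amp_lc = 1.5,
                                        amp_hc = 16, class_sd = 0.3,
                                        n_subunits = 5, seed) {
  stopifnot(p_hc >= 0, p_hc <= 1, amp_hc > amp_lc, amp_lc > 0, n_subunits >= 2)
  if (missing(seed)) stop("`seed` is mandatory")
  set.seed(seed)
  k <- stats::rbinom(n_bursts, n_subunits, p_hc)
  mu <- amp_lc + k * (amp_hc - amp_lc) / n_subunits
  data.frame(amplitude = stats::rnorm(n_bursts, mu, class_sd), hc_count = k)
}
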