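#' Extend a scheme with an open-channel blocked state
#'
#' Adds a non-conducting blocked state reached from an open state, with a
#' concentration-dependent association rate `k_plus_B` (uM^-1 s^-1, ligand =
#' `blocker`) and dissociation rate `k_minus_B` (s^-1). The blocked state is
#' non-conducting and therefore belongs to the shut class: blockages appear
#' as brief closings. Extending twice with different blockers (or suffixes)
#' yields distinct blocked states.
#'
#' @param core A [kinetic_scheme()].
#' @param blocker Ligand name whose concentration drives the block (e.g.
#'   `"ACh"`, `"QX222"`).
#' @param from_open_state Name of the open state that is blocked.
#' @param k_plus_B Association rate constant, uM^-1 s^-1.
#' @param k_minus_B Dissociation rate constant, s^-1.
#' @param suffix Symbol suffix distinguishing multiple blockers (e.g.
#'   `"_QX"`); default empty.
#' @param name Name of the extended scheme.
#' @return The extended [kinetic_scheme()].
#' @examples
#' s2 <- extend_with_block(scheme_preset("S1"), "ACh", "Op", 170, 62000)
#' @export
extend_with_block <- function(core, blocker, from_open_state, k_plus_B,
                              k_minus_B, suffix = "",
                              name = paste0(core$name, "+block")) {
  stopifnot(inherits(core, "kinetic_scheme"))
  i <- match(from_open_state, core$states$state)
  if (is.na(i)) stop("unknown state: ", from_open_state)
  if (core$states$class[i] != "open")
    stop("'", from_open_state, "' is not an open state")
  bstate <- paste0(from_open_state, "B", suffix)
  if (bstate %in% core$states$state)
    stop("blocked state ", bstate, " already exists; use a different suffix")
  states <- rbind(core$states,
                  data.frame(state = bstate, class = "shut",
                             role = "open-blocked"))
  transitions <- rbind(
    core$transitions,
    data.frame(from = c(from_open_state, bstate),
               to = c(bstate, from_open_state),
               symbol = paste0(c("k_plus_B", "k_minus_B"), suffix),
               value = c(k_plus_B, k_minus_B),
               ligand = c(blocker, NA)))
  kinetic_scheme(name, states, transitions)
}

#' Fit an open-channel block concentration series
#'
#' Global missed-event-corrected fit of a core scheme extended with one
#' blocked state, across recordings spanning a range of blocker
#' concentrations (the blocker association rate is scaled by each
#' recording's concentration). Both the constrained fit (core rates held at
#' supplied values, only the blocking rates estimated) and the free fit (all
#' rates estimated) are returned, mirroring the standard check that the two
#' give nearly identical blocking kinetics.
#'
#' @param scheme The block-extended [kinetic_scheme()] (e.g. from
#'   [extend_with_block()] or `scheme_preset("S2")`).
#' @param recordings As in [fit_problem()]: list of recordings with
#'   dead-time-conditioned events and per-recording `concentrations`
#'   covering the blocker.
#' @param dead_time Dead time in seconds.
#' @param core_rates Named vector of core-scheme rates to hold constant in
#'   the constrained fit (default: the scheme's current core values).
#' @param block_symbols Character vector of the blocking-rate symbols
#'   (default: all `k_plus_B*`/`k_minus_B*` symbols in the scheme).
#' @param fit_free Also run the unconstrained fit (default `TRUE`).
#' @param ... Passed to [mil_fit()].
#' @return A `fit_comparison` (elements `constrained` and `free`; `free` is
#'   `NULL` when `fit_free = FALSE`). The derived constants of each fit
#'   include the block dissociation constant `K_B` in uM.
#' @export
fit_block_series <- function(scheme, recordings, dead_time,
                             core_rates = NULL, block_symbols = NULL,
                             fit_free = TRUE, ...) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  syms <- scheme$transitions$symbol
  if (is.null(block_symbols))
    block_symbols <- grep("^k_(plus|minus)_B", syms, value = TRUE)
  if (!length(block_symbols)) stop("scheme has no blocking-rate symbols")
  core_syms <- setdiff(syms, block_symbols)
  if (is.null(core_rates))
    core_rates <- scheme_rates(scheme)[core_syms]
  if (!length(recordings)) stop("empty recording list")
  cons_problem <- fit_problem(scheme, recordings, dead_time,
                              fixed = core_rates)
  constrained <- mil_fit(cons_problem, ...)
  free <- NULL
  if (fit_free) {
    start <- scheme_rates(scheme)
    start[names(core_rates)] <- core_rates
    bsym <- constrained$estimates
    start[block_symbols] <-
      bsym$value[match(block_symbols, bsym$symbol)] # warm start from constrained
    free_problem <- fit_problem(scheme, recordings, dead_time, start = start)
    free <- mil_fit(free_problem, ...)
  }
  structure(list(constrained = constrained, free = free),
            class = "fit_comparison")
}

#' Concentration-dependence signatures of open-channel block
#'
#' Summarizes, per blocker concentration, the empirical hallmarks of
#' open-channel block: mean apparent open duration (decreasing with
#' concentration) and the frequency of closings per second of open time
#' (increasing roughly linearly, slope ~ the blocker association rate).
#'
#' @param recordings As in [fit_problem()]; each recording's concentration of
#'   `blocker` is read from its metadata/`concentrations`.
#' @param blocker Ligand name to tabulate against.
#' @return `data.frame` with one row per concentration: `conc_uM`,
#'   `mean_open_s`, `closings_per_open_s`, `n_open`. Attribute
#'   `block_rate_slope` holds the least-squares slope of closing frequency
#'   versus concentration (s^-1 uM^-1).
#' @export
block_signatures <- function(recordings, blocker) {
  if (inherits(recordings, c("event_list", "burst_set")))
    recordings <- list(list(events = recordings))
  rows <- lapply(recordings, function(r) {
    if (inherits(r, c("event_list", "burst_set"))) r <- list(events = r)
    ev <- r$events
    conc <- r$concentrations %||% attr(ev, "meta")$concentrations %||%
      ev$meta$concentrations
    cu <- if (is.null(conc) || !blocker %in% names(conc)) 0
          else as.numeric(conc[blocker])
    seqs <- .dwell_sequences(ev)
    cls <- unlist(lapply(seqs, `[[`, "cls"))
    dur <- unlist(lapply(seqs, `[[`, "dur"))
    open <- cls == 1L
    # closings that interrupt open time: shut dwells with an opening on
    # both sides within a sequence
    n_interrupt <- sum(vapply(seqs, function(s) {
      if (length(s$cls) < 3) return(0L)
      inner <- s$cls[2:(length(s$cls) - 1L)]
      sum(inner == 0L)
    }, integer(1)))
    data.frame(conc_uM = cu, open_time = sum(dur[open]),
               n_open = sum(open), n_interrupt = n_interrupt)
  })
  d <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(d, d$conc_uM), function(x) {
    data.frame(conc_uM = x$conc_uM[1],
               mean_open_s = sum(x$open_time) / sum(x$n_open),
               closings_per_open_s = sum(x$n_interrupt) / sum(x$open_time),
               n_open = sum(x$n_open))
  }))
  agg <- agg[order(agg$conc_uM), , drop = FALSE]
  rownames(agg) <- NULL
  slope <- if (nrow(agg) >= 2)
    stats::coef(stats::lm(closings_per_open_s ~ conc_uM, data = agg))[2]
  else NA_real_
  attr(agg, "block_rate_slope") <- unname(slope)
  agg
}
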