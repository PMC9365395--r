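#' Run an end-to-end analysis pipeline
#'
#' Orchestrates the package's three analyses, plus simulation, behind one
#' deterministic entry point:
#'
#' * `"simulate"`: generate event lists from a scheme and (optionally) write
#'   them as event files.
#' * `"spontaneous"`: condition event lists (dead time), fit shut-dwell
#'   exponential components, derive the critical closed duration from the
#'   intersection of the two slowest components, define and filter bursts,
#'   and globally fit the scheme by missed-event-corrected maximum
#'   likelihood on the full dwell sequences.
#' * `"block"`: global concentration-series fit of a block-extended scheme,
#'   constrained and free.
#' * `"fingerprint"`: event-based amplitude histogram, Gaussian amplitude
#'   classes, subunit-count inference and class-mean regression. Recordings
#'   for fingerprinting are assumed preprocessed at 1 kHz bandwidth with a
#'   uniform 2 ms critical closed duration.
#'
#' @param pipeline One of `"simulate"`, `"spontaneous"`, `"block"`,
#'   `"fingerprint"`.
#' @param scheme A [kinetic_scheme()] or preset name (for scheme-based
#'   pipelines).
#' @param recordings For `"spontaneous"`/`"block"`: list of recordings
#'   ([fit_problem()] form) or paths to event files. For `"fingerprint"`:
#'   numeric burst amplitudes (pA) or a `data.frame` with an `amplitude`
#'   column.
#' @param dead_time Dead time in seconds (default 18.83e-6).
#' @param tau_crit `"auto"` (intersection rule) or a fixed value in seconds;
#'   the fingerprint pipeline default is 2 ms.
#' @param endpoint_amplitudes For `"fingerprint"`: all-LC and all-HC
#'   amplitudes (pA) anchoring the subunit-count inference.
#' @param seed Integer seed recorded in (and governing) every stochastic
#'   step.
#' @param n_events,n_recordings,concentrations For `"simulate"`.
#' @param out_dir Optional directory; when given, tables and a provenance
#'   JSON (seed, settings, filter counts) are written there.
#' @param ... Passed to the stage fitters.
#' @return A list with the stage results and a `provenance` record.
#' @export
run_pipeline <- function(pipeline = c("spontaneous", "block", "fingerprint",
                                      "simulate"),
                         scheme = NULL, recordings = NULL,
                         dead_time = 18.83e-6, tau_crit = "auto",
                         endpoint_amplitudes = NULL, seed = 1,
                         n_events = 10000, n_recordings = 3,
                         concentrations = NULL, out_dir = NULL, ...) {
  pipeline <- match.arg(pipeline)
  if (is.character(scheme) && length(scheme) == 1)
    scheme <- scheme_preset(scheme)
  prov <- list(pipeline = pipeline, seed = seed, dead_time = dead_time,
               tau_crit_policy = tau_crit,
               scheme = if (!is.null(scheme)) scheme$name,
               package_version = as.character(utils::packageVersion("sckinetics")))
  out <- switch(pipeline,
    simulate = {
      sims <- lapply(seq_len(n_recordings), function(i)
        simulate_events(scheme, n_events, concentrations, seed = seed + i - 1L,
                        id = sprintf("%s-rec%02d-seed%d", scheme$name, i,
                                     seed + i - 1L)))
      list(events = sims)
    },
    spontaneous = {
      recs <- .load_recordings(recordings)
      cond <- lapply(recs, function(r) {
        r$events <- impose_dead_time(r$events, dead_time)
        r
      })
      shut <- unlist(lapply(cond, function(r)
        r$events$duration[r$events$class == "shut"]))
      ncomp <- select_component_count(shut, max_components = 4,
                                      dead_time = dead_time, seed = seed)
      mix <- attr(ncomp, "fits")[[as.integer(ncomp)]]
      tc <- if (identical(tau_crit, "auto"))
        determine_tau_crit(mix$components) else tau_crit
      bursts <- lapply(cond, function(r)
        filter_bursts_by_popen(define_bursts(r$events, tc)))
      problem <- fit_problem(scheme, cond, dead_time = dead_time)
      fit <- mil_fit(problem, seed = seed, ...)
      prov$tau_crit_s <- tc
      prov$n_shut_components <- as.integer(ncomp)
      prov$burst_filter <- lapply(bursts, attr, "filter_log")
      list(shut_mixture = mix, tau_crit = tc, bursts = bursts, fit = fit,
           burst_popen = unlist(lapply(bursts, function(b) b$summary$p_open)))
    },
    block = {
      recs <- .load_recordings(recordings)
      cond <- lapply(recs, function(r) {
        r$events <- impose_dead_time(r$events, dead_time)
        r
      })
      fits <- fit_block_series(scheme, cond, dead_time, seed = seed, ...)
      list(fits = fits,
           signatures = block_signatures(cond,
                                         blocker = .main_blocker(scheme)))
    },
    fingerprint = {
      amps <- if (is.data.frame(recordings)) recordings$amplitude
              else as.numeric(recordings)
      tc <- if (identical(tau_crit, "auto")) 2e-3 else tau_crit
      prov$tau_crit_s <- tc
      model <- fit_amplitude_classes(amps, seed = seed)
      inference <- if (!is.null(endpoint_amplitudes))
        infer_subunit_count(model, endpoint_amplitudes) else NULL
      reg <- if (model$n_classes >= 3) class_mean_regression(model) else NULL
      list(histogram = ebah(amps), classes = model,
           subunits = inference, regression = reg)
    })
  out$provenance <- prov
  if (!is.null(out_dir)) .write_pipeline_outputs(out, pipeline, out_dir)
  out
}

.main_blocker <- function(scheme) {
  lig <- scheme$transitions$ligand[grepl("^k_plus_B",
                                         scheme$transitions$symbol)]
  lig <- lig[!is.na(lig)]
  if (length(lig)) lig[1] else scheme$transitions$ligand[
    !is.na(scheme$transitions$ligand)][1]
}

.load_recordings <- function(recordings) {
  if (inherits(recordings, c("event_list", "burst_set")))
    recordings <- list(recordings)
  lapply(recordings, function(r) {
    if (is.character(r)) r <- read_events(r)
    if (inherits(r, c("event_list", "burst_set"))) r <- list(events = r)
    if (is.null(r$concentrations))
      r$concentrations <- attr(r$events, "meta")$concentrations
    r
  })
}

.write_pipeline_outputs <- function(out, pipeline, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(out$provenance,
                       file.path(out_dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  if (pipeline == "simulate")
    for (ev in out$events)
      write_events(ev, file.path(out_dir,
                                 paste0(attr(ev, "meta")$id, ".events.tsv")))
  if (!is.null(out$fit))
    utils::write.table(out$fit$estimates,
                       file.path(out_dir, "rate_estimates.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  if (!is.null(out$fits)) {
    utils::write.table(out$fits$constrained$estimates,
                       file.path(out_dir, "rates_constrained.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(out$fits$free))
      utils::write.table(out$fits$free$estimates,
                         file.path(out_dir, "rates_free.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
  }
  if (!is.null(out$classes))
    utils::write.table(out$classes$classes,
                       file.path(out_dir, "amplitude_classes.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(out_dir)
}
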