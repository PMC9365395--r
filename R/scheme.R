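#' Construct a kinetic scheme
#'
#' A kinetic scheme is an aggregated continuous-time Markov model of channel
#' gating: a set of named states, each belonging to one conductance class
#' (`"shut"` or `"open"`), connected by first-order transitions. A transition
#' whose rate is ligand-dependent (units uM^-1 s^-1) names the ligand whose
#' concentration (in uM) multiplies the rate when the generator matrix is
#' built. Non-conducting blocked states belong to the shut class: blockages
#' appear as closings in a record.
#'
#' @param name Label for the scheme (e.g. `"S1"` or a user-defined name).
#' @param states `data.frame` with columns `state` (character, unique),
#'   `class` (`"shut"` or `"open"`) and optionally `role` (free annotation,
#'   e.g. `"primed-closed"`, `"open-blocked"`).
#' @param transitions `data.frame` with columns `from`, `to`, `symbol`
#'   (rate-constant name), `value` (non-negative; s^-1, or uM^-1 s^-1 when
#'   `ligand` is set) and optionally `ligand` (character or `NA`).
#'
#' @return An object of class `kinetic_scheme`.
#'
#' @details Rate-constant symbols follow a fixed grammar so that derived
#' equilibrium constants can be computed automatically (see
#' [derived_constants()]): priming steps `k_plus<n>_prime` / `k_minus<n>_prime`,
#' gating steps `beta_<n>` / `alpha_<n>`, agonist binding `k_plus_<n>` /
#' `k_minus_<n>`, and open-channel block `k_plus_B*` / `k_minus_B*` (an
#' optional suffix distinguishes blockers, e.g. `k_plus_B_QX`).
#'
#' @examples
#' sch <- kinetic_scheme(
#'   "two-state",
#'   states = data.frame(state = c("C", "O"), class = c("shut", "open")),
#'   transitions = data.frame(
#'     from = c("C", "O"), to = c("O", "C"),
#'     symbol = c("beta_1", "alpha_1"), value = c(100, 200)
#'   )
#' )
#' print(sch)
#' @export
kinetic_scheme <- function(name, states, transitions) {
  stopifnot(is.data.frame(states), is.data.frame(transitions))
  if (!all(c("state", "class") %in% names(states)))
    stop("`states` needs columns 'state' and 'class'")
  if (!all(c("from", "to", "symbol", "value") %in% names(transitions)))
    stop("`transitions` needs columns 'from', 'to', 'symbol', 'value'")
  states$state <- as.character(states$state)
  states$class <- as.character(states$class)
  if (!all(states$class %in% c("shut", "open")))
    stop("state class must be 'shut' or 'open'")
  if (anyDuplicated(states$state))
    stop("duplicate state names: ",
         paste(unique(states$state[duplicated(states$state)]), collapse = ", "))
  if (is.null(states$role)) states$role <- states$class
  if (is.null(transitions$ligand)) transitions$ligand <- NA_character_
  transitions$ligand <- as.character(transitions$ligand)
  transitions$from <- as.character(transitions$from)
  transitions$to <- as.character(transitions$to)
  transitions$symbol <- as.character(transitions$symbol)

  bad <- setdiff(c(transitions$from, transitions$to), states$state)
  if (length(bad))
    stop("transitions reference unknown states: ", paste(bad, collapse = ", "))
  if (any(transitions$value < 0)) stop("rate values must be non-negative")
  if (any(transitions$from == transitions$to)) stop("self-transitions not allowed")
  key <- paste(transitions$from, transitions$to)
  if (anyDuplicated(key))
    stop("duplicate transition: ", key[duplicated(key)][1])
  if (!any(states$class == "shut") || !any(states$class == "open"))
    stop("scheme needs at least one shut and one open state")

  sch <- structure(
    list(name = name,
         states = states[, c("state", "class", "role")],
         transitions = transitions[, c("from", "to", "symbol", "value", "ligand")]),
    class = "kinetic_scheme")
  unreach <- .unreachable_states(sch)
  if (length(unreach))
    stop("transition graph is not strongly connected; unreachable states: ",
         paste(unreach, collapse = ", "))
  sch
}

# states not mutually reachable from state 1 along positive-rate edges
.unreachable_states <- function(scheme) {
  st <- scheme$states$state
  n <- length(st)
  adj <- matrix(FALSE, n, n, dimnames = list(st, st))
  tr <- scheme$transitions[scheme$transitions$value > 0, ]
  adj[cbind(tr$from, tr$to)] <- TRUE
  reach <- function(a) {
    seen <- logical(n); seen[1] <- TRUE
    repeat {
      new <- (seen %*% a > 0) & !seen
      if (!any(new)) break
      seen <- seen | as.vector(new)
    }
    seen
  }
  fwd <- reach(adj); bwd <- reach(t(adj))
  st[!(fwd & bwd)]
}

#' @export
print.kinetic_scheme <- function(x, ...) {
  cat("Kinetic scheme '", x$name, "': ", nrow(x$states), " states (",
      sum(x$states$class == "shut"), " shut, ",
      sum(x$states$class == "open"), " open), ",
      nrow(x$transitions), " transitions\n", sep = "")
  for (i in seq_len(nrow(x$transitions))) {
    tr <- x$transitions[i, ]
    unit <- if (is.na(tr$ligand)) "s-1" else paste0("uM-1 s-1 x [", tr$ligand, "]")
    cat(sprintf("  %-6s -> %-6s  %-16s %12g %s\n",
                tr$from, tr$to, tr$symbol, tr$value, unit))
  }
  invisible(x)
}

#' Named rate constants of a scheme
#'
#' @param scheme A [kinetic_scheme()].
#' @return Named numeric vector of rate-constant values, one per symbol.
#' @export
scheme_rates <- function(scheme) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  stats::setNames(scheme$transitions$value, scheme$transitions$symbol)
}

#' Replace rate constants in a scheme
#'
#' @param scheme A [kinetic_scheme()].
#' @param rates Named numeric vector; names must be existing symbols.
#' @return The scheme with the named rate values replaced.
#' @export
set_scheme_rates <- function(scheme, rates) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  bad <- setdiff(names(rates), scheme$transitions$symbol)
  if (length(bad)) stop("unknown rate symbols: ", paste(bad, collapse = ", "))
  i <- match(scheme$transitions$symbol, names(rates))
  hit <- !is.na(i)
  scheme$transitions$value[hit] <- as.numeric(rates[i[hit]])
  if (any(scheme$transitions$value < 0)) stop("rate values must be non-negative")
  scheme
}

.s1_core <- function(name, kp1p, km1p, b1, a1) {
  kinetic_scheme(
    name,
    states = data.frame(
      state = c("C", "Cp", "Op"),
      class = c("shut", "shut", "open"),
      role  = c("closed", "primed-closed", "open-primed")),
    transitions = data.frame(
      from   = c("C",  "Cp", "Cp", "Op"),
      to     = c("Cp", "C",  "Op", "Cp"),
      symbol = c("k_plus1_prime", "k_minus1_prime", "beta_1", "alpha_1"),
      value  = c(kp1p, km1p, b1, a1)))
}

#' Built-in kinetic scheme presets
#'
#' Returns one of the named gating schemes for ancestral-beta-subunit
#' homopentamers and the wild-type adult muscle AChR, preloaded with the
#' globally fitted single-channel rate constants:
#'
#' * `"S1"`: linear priming scheme C - C' - O' for spontaneously opening
#'   homopentamers (agonist-free rates).
#' * `"S2"`: S1 plus one open-blocked state reached from O'; `blocker` selects
#'   the acetylcholine or QX-222 rate set, `constrained` selects the variant
#'   in which the core C-C'-O' rates were held at the agonist-free values.
#' * `"S3"`: wild-type activation scheme R - AR - A2R with openings from the
#'   mono- and diliganded closed states and ACh open-channel self-block of the
#'   diliganded open state.
#' * `"S4"`: S3 plus a QX-222 blocked state off the diliganded open state
#'   (`ach_uM` 10 or 30 selects the rate set fitted at that fixed ACh
#'   concentration).
#' * `"S5"`: multi-priming chain C - C' - C'' - C''' with an open state
#'   attached to each primed closed state.
#'
#' @param name One of `"S1"`, `"S2"`, `"S3"`, `"S4"`, `"S5"`.
#' @param blocker For `"S2"`: `"ACh"` or `"QX222"`.
#' @param constrained For `"S2"`: use the constrained-core rate set.
#' @param ach_uM For `"S4"`: the fixed ACh concentration (10 or 30 uM) whose
#'   QX-222 rate set to load.
#' @return A [kinetic_scheme()].
#' @examples
#' scheme_preset("S1")
#' scheme_preset("S2", blocker = "QX222")
#' @export
scheme_preset <- function(name = c("S1", "S2", "S3", "S4", "S5"),
                          blocker = c("ACh", "QX222"),
                          constrained = FALSE, ach_uM = 10) {
  name <- match.arg(name)
  blocker <- match.arg(blocker)
  switch(name,
    S1 = .s1_core("S1", 3900, 7600, 10000, 310),
    S2 = {
      if (constrained) {
        core <- .s1_core("S2", 3900, 7600, 10000, 310)
        bl <- if (blocker == "ACh") c(170, 60800) else c(95, 1400)
      } else if (blocker == "ACh") {
        core <- .s1_core("S2", 3500, 5400, 8000, 330)
        bl <- c(170, 62000)
      } else {
        core <- .s1_core("S2", 4000, 8000, 10500, 320)
        bl <- c(95, 1400)
      }
      extend_with_block(core, blocker = blocker, from_open_state = "Op",
                        k_plus_B = bl[1], k_minus_B = bl[2], name = "S2")
    },
    S3 = .wt_scheme(FALSE, ach_uM = NA),
    S4 = .wt_scheme(TRUE, ach_uM = ach_uM),
    S5 = kinetic_scheme(
      "S5",
      states = data.frame(
        state = c("C", "Cp", "Cpp", "Cppp", "Op", "Opp", "Oppp"),
        class = c("shut", "shut", "shut", "shut", "open", "open", "open"),
        role  = c("closed", "singly-primed", "doubly-primed", "triply-primed",
                  "open-1", "open-2", "open-3")),
      transitions = data.frame(
        from   = c("C", "Cp", "Cp", "Cpp", "Cpp", "Cppp",
                   "Cp", "Op", "Cpp", "Opp", "Cppp", "Oppp"),
        to     = c("Cp", "C", "Cpp", "Cp", "Cppp", "Cpp",
                   "Op", "Cp", "Opp", "Cpp", "Oppp", "Cppp"),
        symbol = c("k_plus1_prime", "k_minus1_prime",
                   "k_plus2_prime", "k_minus2_prime",
                   "k_plus3_prime", "k_minus3_prime",
                   "beta_1", "alpha_1", "beta_2", "alpha_2",
                   "beta_3", "alpha_3"),
        value  = c(2000, 2500, 13650, 14800, 2000, 5000,
                   11500, 17000, 175000, 6800, 40000, 500))))
}

.wt_scheme <- function(with_qx, ach_uM) {
  qx <- if (isTRUE(with_qx)) {
    if (!ach_uM %in% c(10, 30)) stop("S4 preset is defined for ach_uM = 10 or 30")
    if (ach_uM == 10) c(100, 845) else c(110, 845)
  }
  states <- data.frame(
    state = c("R", "AR", "A2R", "ARs", "A2Rs", "A2RsB_ACh"),
    class = c("shut", "shut", "shut", "open", "open", "shut"),
    role  = c("closed", "monoliganded-closed", "diliganded-closed",
              "monoliganded-open", "diliganded-open", "open-blocked"))
  transitions <- data.frame(
    from   = c("R", "AR", "AR", "A2R", "AR", "ARs", "A2R", "A2Rs",
               "A2Rs", "A2RsB_ACh"),
    to     = c("AR", "R", "A2R", "AR", "ARs", "AR", "A2Rs", "A2R",
               "A2RsB_ACh", "A2Rs"),
    symbol = c("k_plus_1", "k_minus_1", "k_plus_2", "k_minus_2",
               "beta_1", "alpha_1", "beta_2", "alpha_2",
               "k_plus_B_ACh", "k_minus_B_ACh"),
    value  = c(650, 14400, 325, 26500, 33, 8750, 14000, 1000, 215, 110000),
    ligand = c("ACh", NA, "ACh", NA, NA, NA, NA, NA, "ACh", NA))
  sch <- kinetic_scheme(if (isTRUE(with_qx)) "S4" else "S3", states, transitions)
  if (isTRUE(with_qx))
    sch <- extend_with_block(sch, blocker = "QX222", from_open_state = "A2Rs",
                             k_plus_B = qx[1], k_minus_B = qx[2], name = "S4",
                             suffix = "_QX")
  sch
}

#' Read or write a scheme as structured text
#'
#' Schemes are serialized as JSON with `name`, `states` and `transitions`
#' entries, mirroring the in-memory representation.
#'
#' @param path File path.
#' @param scheme A [kinetic_scheme()] (for writing).
#' @return `read_scheme()` returns a [kinetic_scheme()]; `write_scheme()`
#'   returns `path` invisibly.
#' @export
read_scheme <- function(path) {
  x <- jsonlite::fromJSON(path)
  kinetic_scheme(x$name, x$states, x$transitions)
}

#' @rdname read_scheme
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  jsonlite::write_json(unclass(scheme), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}
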