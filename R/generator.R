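#' Build the generator (Q) matrix of a scheme
#'
#' Resolves a kinetic scheme into its generator matrix at given ligand
#' concentrations. Off-diagonal entries are transition rates in s^-1
#' (ligand-dependent rates, in uM^-1 s^-1, are multiplied by the ligand
#' concentration in uM); diagonal entries are negative row sums, so every row
#' sums to zero.
#'
#' @param scheme A [kinetic_scheme()].
#' @param concentrations Named numeric vector of ligand concentrations in uM
#'   (e.g. `c(ACh = 30)`). Every ligand referenced by the scheme must be
#'   present; a missing ligand is a configuration error.
#' @return An object of class `generator_matrix`: list with elements `q`
#'   (square matrix, s^-1), `states`, `classes` (character vector aligned with
#'   the state order), `concentrations` and `scheme_name`.
#' @examples
#' g <- build_generator(scheme_preset("S1"))
#' rowSums(g$q) # all zero
#' @export
build_generator <- function(scheme, concentrations = NULL) {
  stopifnot(inherits(scheme, "kinetic_scheme"))
  st <- scheme$states$state
  n <- length(st)
  q <- matrix(0, n, n, dimnames = list(st, st))
  tr <- scheme$transitions
  need <- unique(tr$ligand[!is.na(tr$ligand)])
  missing_lig <- setdiff(need, names(concentrations))
  if (length(missing_lig))
    stop("no concentration supplied for ligand(s): ",
         paste(missing_lig, collapse = ", "))
  rate <- tr$value
  dep <- !is.na(tr$ligand)
  rate[dep] <- rate[dep] * as.numeric(concentrations[tr$ligand[dep]])
  q[cbind(tr$from, tr$to)] <- rate
  diag(q) <- 0
  diag(q) <- -rowSums(q)
  structure(list(q = q, states = st,
                 classes = stats::setNames(scheme$states$class, st),
                 concentrations = concentrations,
                 scheme_name = scheme$name),
            class = "generator_matrix")
}

.class_idx <- function(g, cls) which(g$classes == cls)

#' Equilibrium state occupancies
#'
#' Solves pi Q = 0, sum(pi) = 1 for the stationary distribution of the gating
#' chain.
#'
#' @param g A [build_generator()] result.
#' @return Named probability vector over states.
#' @export
equilibrium_occupancy <- function(g) {
  stopifnot(inherits(g, "generator_matrix"))
  n <- nrow(g$q)
  a <- rbind(t(g$q), rep(1, n))
  b <- c(rep(0, n), 1)
  pi <- qr.solve(a, b)
  if (any(!is.finite(pi)))
    stop("equilibrium solve failed (singular or ill-conditioned generator)")
  pi <- pmax(pi, 0)
  stats::setNames(pi / sum(pi), g$states)
}

# steady-state entry vector into class `cls`: flux from the other class,
# normalized. Row vector over the states of `cls`.
.entry_vector <- function(g, cls) {
  a <- .class_idx(g, cls)
  f <- setdiff(seq_along(g$states), a)
  pi <- equilibrium_occupancy(g)
  phi <- as.numeric(pi[f] %*% g$q[f, a, drop = FALSE])
  s <- sum(phi)
  if (s <= 0) stop("no flux into class '", cls, "'")
  phi / s
}

#' Exponential components of an ideal dwell-time density
#'
#' Spectral decomposition of the within-class sub-generator. For a class with
#' distinct eigenvalues the ideal dwell-time density is a mixture of
#' exponentials with time constants -1/eigenvalue and areas given by the
#' spectral expansion under the steady-state class-entry vector.
#'
#' @param g A [build_generator()] result.
#' @param cls `"shut"` or `"open"`.
#' @return `data.frame` with columns `tau` (seconds, increasing) and `area`
#'   (summing to 1), or `NULL` if the sub-generator is defective
#'   (non-diagonalizable) and no decomposition exists.
#' @export
ideal_dwell_components <- function(g, cls = c("shut", "open")) {
  cls <- match.arg(cls)
  a <- .class_idx(g, cls)
  if (!length(a)) stop("class '", cls, "' is empty")
  qaa <- g$q[a, a, drop = FALSE]
  phi <- .entry_vector(g, cls)
  e <- eigen(qaa)
  if (max(abs(Im(e$values))) > 1e-9 * max(abs(e$values)))
    return(NULL)
  v <- Re(e$vectors); lam <- Re(e$values)
  if (rcond(v) < 1e-10) return(NULL) # defective (or nearly): no decomposition
  if (any(lam >= 0)) stop("within-class sub-generator has non-negative eigenvalue")
  w <- solve(v)
  # f(t) = sum_k b_k exp(lam_k t); area_k = phi %*% A_k %*% 1
  areas <- vapply(seq_along(lam), function(k) {
    sum((phi %*% (v[, k, drop = FALSE] %*% w[k, , drop = FALSE])))
  }, numeric(1))
  out <- data.frame(tau = -1 / lam, area = areas)
  out <- out[order(out$tau), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Ideal (no dead time) dwell-time density
#'
#' Density of the sojourn time in a conductance class for the ideal record:
#' `phi exp(Q_cc t) (-Q_cc) 1`, with `phi` the steady-state class-entry
#' vector. Evaluated by the spectral decomposition when the sub-generator is
#' diagonalizable, otherwise by matrix exponentials.
#'
#' @inheritParams ideal_dwell_components
#' @param t Vector of times (seconds, >= 0).
#' @return Numeric vector of density values (s^-1).
#' @export
ideal_dwell_density <- function(g, cls = c("shut", "open"), t) {
  cls <- match.arg(cls)
  stopifnot(all(t >= 0))
  comp <- ideal_dwell_components(g, cls)
  if (!is.null(comp)) {
    sapply(t, function(ti) sum(comp$area / comp$tau * exp(-ti / comp$tau)))
  } else {
    a <- .class_idx(g, cls)
    qaa <- g$q[a, a, drop = FALSE]
    phi <- .entry_vector(g, cls)
    u <- -qaa %*% rep(1, length(a))
    vapply(t, function(ti) as.numeric(phi %*% .expm(qaa * ti) %*% u), numeric(1))
  }
}

#' Mean ideal class dwell
#'
#' Closed form `-phi Q_cc^-1 1` for the mean sojourn in a class.
#'
#' @inheritParams ideal_dwell_components
#' @return Mean dwell in seconds.
#' @export
mean_dwell <- function(g, cls = c("shut", "open")) {
  cls <- match.arg(cls)
  a <- .class_idx(g, cls)
  qaa <- g$q[a, a, drop = FALSE]
  phi <- .entry_vector(g, cls)
  -sum(phi %*% solve(qaa))
}

# small dense matrix exponential (scaling and squaring on top of a Pade-free
# Taylor series is overkill here; series with scaling is ample for the
# well-scaled sub-generators that arise)
.expm <- function(m) {
  n <- nrow(m)
  nrm <- max(abs(m))
  if (nrm == 0) return(diag(n))
  s <- max(0L, ceiling(log2(nrm)))
  a <- m / 2^s
  out <- diag(n); term <- diag(n)
  for (k in 1:24) {
    term <- term %*% a / k
    out <- out + term
    if (max(abs(term)) < 1e-17) break
  }
  for (i in seq_len(s)) out <- out %*% out
  out
}

#' Derived equilibrium constants
#'
#' Computes the equilibrium constants conventionally reported alongside
#' single-channel rate estimates: priming equilibria `K_prime_n =
#' k_plus<n>_prime / k_minus<n>_prime` (dimensionless), gating equilibria
#' `Theta_n = beta_n / alpha_n` (dimensionless), apparent dissociation
#' constants `K_n = k_minus_<n> / k_plus_<n>` (uM) and block dissociation
#' constants `K_B = k_minus_B / k_plus_B` (uM).
#'
#' @param rates Named numeric vector of rate constants, or a
#'   [kinetic_scheme()] whose rates are used.
#' @return Named numeric vector of derived constants. Ratios are only emitted
#'   when both members of a pair are present; a pair with a missing partner or
#'   a zero denominator is an error.
#' @examples
#' derived_constants(c(beta_1 = 10000, alpha_1 = 310)) # Theta_1 = 32.26
#' @export
derived_constants <- function(rates) {
  if (inherits(rates, "kinetic_scheme")) rates <- scheme_rates(rates)
  stopifnot(is.numeric(rates), !is.null(names(rates)))
  out <- numeric(0)
  take <- function(sym) {
    if (!sym %in% names(rates)) stop("missing rate symbol: ", sym)
    v <- unname(rates[sym])
    if (v <= 0) stop("rate symbol ", sym, " must be positive")
    v
  }
  for (sym in names(rates)) {
    if (grepl("^k_plus([0-9]+)_prime$", sym)) {
      n <- sub("^k_plus([0-9]+)_prime$", "\\1", sym)
      out[paste0("K_prime_", n)] <- take(sym) / take(paste0("k_minus", n, "_prime"))
    } else if (grepl("^beta_([0-9]+)$", sym)) {
      n <- sub("^beta_", "", sym)
      out[paste0("Theta_", n)] <- take(sym) / take(paste0("alpha_", n))
    } else if (grepl("^k_plus_([0-9]+)$", sym)) {
      n <- sub("^k_plus_", "", sym)
      out[paste0("K_", n)] <- take(paste0("k_minus_", n)) / take(sym)
    } else if (grepl("^k_plus_B", sym)) {
      suf <- sub("^k_plus_B", "", sym)
      out[paste0("K_B", suf)] <- take(paste0("k_minus_B", suf)) / take(sym)
    }
  }
  out
}
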