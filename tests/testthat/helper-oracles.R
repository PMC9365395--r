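# Independent reference implementations used to cross-check the package's
# numerics. These deliberately share no code with the package internals:
# matrix exponentials come from Matrix::expm and the algorithms are written
# in their most literal (brute-force) form.

# dense aggregated-Markov log-likelihood at zero dead time:
# phi * prod_i [ expm(Q_aa t_i) Q_ab ] * 1, with phi the steady-state
# entry vector of the first dwell's class
oracle_loglik <- function(scheme, sequences, concentrations = NULL) {
  g <- build_generator(scheme, concentrations)
  q <- g$q
  cls <- g$classes
  pi <- oracle_equilibrium(q)
  total <- 0
  for (s in sequences) {
    a <- which(cls == s$cls[1])
    f <- which(cls != s$cls[1])
    phi <- pi[f] %*% q[f, a, drop = FALSE]
    v <- phi / sum(phi)
    logscale <- 0
    for (i in seq_along(s$cls)) {
      a <- which(cls == s$cls[i])
      b <- setdiff(seq_along(cls), a)
      prop <- as.matrix(Matrix::expm(Matrix::Matrix(q[a, a, drop = FALSE] *
                                                      s$dur[i])))
      v <- v %*% prop %*% q[a, b, drop = FALSE]
      sc <- sum(v)
      logscale <- logscale + log(sc)
      v <- v / sc
    }
    total <- total + logscale
  }
  total
}

# stationary distribution via eigenvector of t(Q) for eigenvalue 0
oracle_equilibrium <- function(q) {
  e <- eigen(t(q))
  k <- which.min(abs(e$values))
  v <- Re(e$vectors[, k])
  v / sum(v)
}

# literal recursive-merge dead-time imposition: repeatedly find the first
# undetectable event and merge it with its neighbours (or drop it at a
# boundary), until stable
oracle_dead_time <- function(cls, dur, td) {
  repeat {
    i <- which(dur < td)
    if (!length(i)) break
    i <- i[1]
    if (i == 1 || i == length(dur)) {
      cls <- cls[-i]; dur <- dur[-i]
    } else {
      dur[i - 1] <- dur[i - 1] + dur[i] + dur[i + 1]
      cls <- cls[-c(i, i + 1)]
      dur <- dur[-c(i, i + 1)]
    }
    if (!length(dur)) break
  }
  # merge any remaining same-class neighbours
  j <- 1
  while (j < length(dur)) {
    if (length(cls) > j && cls[j] == cls[j + 1]) {
      dur[j] <- dur[j] + dur[j + 1]
      cls <- cls[-(j + 1)]; dur <- dur[-(j + 1)]
    } else j <- j + 1
  }
  list(cls = cls, dur = dur)
}

# random alternating event list for property tests
random_event_list <- function(n, seed) {
  set.seed(seed)
  start <- sample(c("shut", "open"), 1)
  cls <- rep(c("shut", "open"), length.out = n)
  if (start == "open") cls <- rev(cls)
  event_list(cls, rexp(n, rate = 1e4))
}

# random irreducible linear (chain) scheme with one open end state
random_chain_scheme <- function(n_shut, seed) {
  set.seed(seed)
  states <- data.frame(
    state = c(paste0("S", seq_len(n_shut)), "O"),
    class = c(rep("shut", n_shut), "open"))
  from <- c(states$state[-nrow(states)], states$state[-1])
  to <- c(states$state[-1], states$state[-nrow(states)])
  kinetic_scheme("chain",
                 states,
                 data.frame(from = from, to = to,
                            symbol = paste0("r", seq_along(from)),
                            value = 10^runif(length(from), 2, 4)))
}

td_detect <- 18.83e-6

sim_conditioned <- function(scheme, n_events, seed, concentrations = NULL,
                            td = td_detect) {
  impose_dead_time(
    simulate_events(scheme, n_events, concentrations, seed = seed), td)
}
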