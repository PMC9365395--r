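test_that("sequence likelihood reduces to the closed form on a toy burst", {
  ts <- kinetic_scheme("toy",
    data.frame(state = c("C", "O"), class = c("shut", "open")),
    data.frame(from = c("C", "O"), to = c("O", "C"),
               symbol = c("beta_1", "alpha_1"), value = c(100, 200)))
  ev <- event_list(c("shut", "open"), c(0.010, 0.005))
  p <- fit_problem(ts, ev, dead_time = 0)
  expect_equal(sequence_loglik(p), log(100) - 1 + log(200) - 1,
               tolerance = 1e-12)
})

test_that("likelihood at zero dead time matches the dense expm oracle", {
  skip_if_not_installed("Matrix")
  for (s in 1:4) {
    sch <- random_chain_scheme(2, seed = s)
    ev <- simulate_events(sch, 60, seed = s + 50)
    p <- fit_problem(sch, ev, dead_time = 0)
    got <- sequence_loglik(p)
    ref <- oracle_loglik(sch, list(list(cls = ev$class, dur = ev$duration)))
    expect_equal(got, ref, tolerance = 1e-8)
  }
})

test_that("corrected kernels reduce to ideal at zero dead time", {
  g <- build_generator(scheme_preset("S1"))
  tt <- c(1e-4, 1e-3, 5e-3)
  expect_equal(apparent_dwell_density(g, "open", tt, dead_time = 0),
               ideal_dwell_density(g, "open", tt), tolerance = 1e-10)
  expect_equal(apparent_dwell_density(g, "shut", tt, dead_time = 0),
               ideal_dwell_density(g, "shut", tt), tolerance = 1e-10)
})

test_that("two-state apparent open dwells stay exponential with reduced rate", {
  beta <- 5000; alpha <- 800; td <- 5e-5
  ts <- kinetic_scheme("toy",
    data.frame(state = c("C", "O"), class = c("shut", "open")),
    data.frame(from = c("C", "O"), to = c("O", "C"),
               symbol = c("beta_1", "alpha_1"), value = c(beta, alpha)))
  g <- build_generator(ts)
  k <- corrected_kernels(g, td)
  # closing rate reduced by the probability a closure escapes detection
  expect_equal(as.numeric(k$qc_open), -alpha * exp(-beta * td),
               tolerance = 1e-12)
  # apparent density is normalized and matches Monte-Carlo apparent dwells
  nrm <- integrate(function(t) apparent_dwell_density(g, "open", t, td),
                   td, Inf, rel.tol = 1e-9)$value
  expect_equal(nrm, 1, tolerance = 1e-6)
  ev <- sim_conditioned(ts, 20000, seed = 88, td = td)
  open <- ev$duration[ev$class == "open"]
  rate_hat <- 1 / (mean(open) - td)
  expect_equal(rate_hat, alpha * exp(-beta * td), tolerance = 0.05)
  ks <- suppressWarnings(
    ks.test(open - td, "pexp", rate = alpha * exp(-beta * td)))
  expect_gt(ks$p.value, 0.01)
})

test_that("missed brief shuttings lengthen apparent openings", {
  s1 <- scheme_preset("S1")
  ev <- sim_conditioned(s1, 20000, seed = 23)
  open <- ev$duration[ev$class == "open"]
  expect_gt(mean(open), 1 / 310) # ideal open lifetime is 1/alpha_1
})

test_that("likelihood prefers the generating parameters over distorted ones", {
  s1 <- scheme_preset("S1")
  recs <- list(list(events = sim_conditioned(s1, 8000, seed = 41)))
  p <- fit_problem(s1, recs, dead_time = td_detect)
  ll_truth <- sequence_loglik(p)
  ll_bad <- sequence_loglik(p, c(alpha_1 = 620))
  expect_gt(ll_truth, ll_bad)
})

test_that("fixing every parameter makes the fit a no-op", {
  s1 <- scheme_preset("S1")
  truth <- scheme_rates(s1)
  recs <- list(list(events = sim_conditioned(s1, 2000, seed = 43)))
  p <- fit_problem(s1, recs, dead_time = td_detect, fixed = truth)
  fit <- mil_fit(p)
  expect_equal(setNames(fit$estimates$value, fit$estimates$symbol),
               truth[fit$estimates$symbol])
  expect_equal(fit$loglik, sequence_loglik(p))
  expect_true(all(fit$estimates$fixed))
})

test_that("rates are recovered within 3 SE on a single moderate recording", {
  s1 <- scheme_preset("S1")
  truth <- scheme_rates(s1)
  recs <- list(list(events = sim_conditioned(s1, 8000, seed = 47)))
  p <- fit_problem(s1, recs, dead_time = td_detect,
                   start = truth * c(1.6, 0.7, 0.8, 1.4))
  fit <- mil_fit(p)
  expect_true(fit$converged)
  est <- setNames(fit$estimates$value, fit$estimates$symbol)
  se <- setNames(fit$estimates$se, fit$estimates$symbol)
  expect_true(all(is.finite(se) & se > 0))
  z <- abs(est - truth[names(est)]) / se
  expect_true(all(z < 3))
})

test_that("duplicating the dataset leaves estimates put and shrinks SEs by sqrt(2)", {
  s1 <- scheme_preset("S1")
  truth <- scheme_rates(s1)
  rec <- list(events = sim_conditioned(s1, 4000, seed = 53))
  p1 <- fit_problem(s1, list(rec), dead_time = td_detect,
                    start = truth * c(1.3, 0.8, 0.9, 1.2))
  f1 <- mil_fit(p1)
  p2 <- fit_problem(s1, list(rec, rec), dead_time = td_detect,
                    start = truth * c(1.3, 0.8, 0.9, 1.2))
  f2 <- mil_fit(p2)
  expect_equal(f2$estimates$value, f1$estimates$value, tolerance = 1e-3)
  expect_equal(f2$estimates$se / f1$estimates$se,
               rep(1 / sqrt(2), 4), tolerance = 0.05)
  expect_equal(f2$loglik, 2 * f1$loglik, tolerance = 1e-6)
})

test_that("likelihood is invariant to state reordering and burst splitting", {
  s1 <- scheme_preset("S1")
  ev <- sim_conditioned(s1, 3000, seed = 59)
  p <- fit_problem(s1, ev, dead_time = td_detect)
  ll <- sequence_loglik(p)
  s1r <- s1
  s1r$states <- s1$states[c(2, 3, 1), ]
  pr <- fit_problem(s1r, ev, dead_time = td_detect)
  expect_equal(sequence_loglik(pr), ll, tolerance = 1e-9)
  # two recordings split at a class boundary give the same total only up to
  # the second start vector; check the burst-structured route instead:
  # feeding the same dwells as one sequence or as a burst_set of that one
  # sequence must agree exactly
  bs <- list(bursts = list(ev), tau_crit = Inf, summary = NULL,
             meta = attr(ev, "meta"))
  class(bs) <- "burst_set"
  pb <- fit_problem(s1, list(list(events = bs)), dead_time = td_detect)
  expect_equal(sequence_loglik(pb), ll, tolerance = 1e-12)
})

test_that("constraining to the free optimum reproduces its likelihood", {
  s1 <- scheme_preset("S1")
  truth <- scheme_rates(s1)
  recs <- list(list(events = sim_conditioned(s1, 3000, seed = 61)))
  p <- fit_problem(s1, recs, dead_time = td_detect)
  free <- mil_fit(p, compute_se = FALSE)
  opt <- setNames(free$estimates$value, free$estimates$symbol)
  cmp <- constrained_refit(p, constrain = opt, free_fit = free)
  expect_equal(cmp$constrained$loglik, cmp$free$loglik, tolerance = 1e-8)
})
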