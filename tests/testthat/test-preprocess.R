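test_that("half-amplitude idealization recovers rectangular events", {
  ev <- event_list(c("shut", "open", "shut"), c(1e-3, 1e-3, 1e-3))
  tr <- simulate_trace(ev, sample_rate = 1e6, open_pA = 16)
  id <- idealize_trace(tr, 16)
  expect_equal(nrow(id), 1)
  expect_equal(as.character(id$class), "open")
  expect_equal(id$duration, 1e-3, tolerance = 2e-6) # within one sample
  # inverted polarity with swapped levels gives identical events
  tr_inv <- tr; tr_inv$current <- -tr_inv$current
  id_inv <- idealize_trace(tr_inv, open_amplitude = -16, baseline = 0)
  expect_equal(id_inv$duration, id$duration)
  flat <- list(t = tr$t, current = rep(0, length(tr$t)))
  expect_warning(id0 <- idealize_trace(flat, 16), "never crosses")
  expect_equal(nrow(id0), 0)
})

test_that("idealization round-trips a simulated recording at low noise", {
  s1 <- scheme_preset("S1")
  ev <- simulate_events(s1, 300, seed = 5)
  fc <- 2e4
  tr <- simulate_trace(ev, 1e6, filter_fc = fc, noise_sd = 0.5, open_pA = 16,
                       seed = 6)
  id <- impose_dead_time(idealize_trace(tr, 16), 18.83e-6)
  risetime <- 0.3321 / fc
  # long dwells (> 10x risetime) survive in comparable numbers; brief
  # closings near the filter resolution split or merge flanking openings
  # either way, so only rough count agreement is expected
  n_in <- sum(ev$class == "open" & ev$duration > 10 * risetime)
  n_out <- sum(id$class == "open" & id$duration > 10 * risetime)
  expect_equal(n_out, n_in, tolerance = 0.25)
  expect_equal(sum(id$duration[id$class == "open"]),
               sum(ev$duration[ev$class == "open"]), tolerance = 0.1)
})

test_that("risetime correction is asymptotically exact and monotone", {
  fc <- 1e4
  risetime <- 0.3321 / fc
  long <- event_list("open", 10 * risetime)
  expect_equal(correct_risetime(long, fc)$duration, 10 * risetime,
               tolerance = 0.01)
  expect_identical(correct_risetime(long, Inf)$duration, long$duration)
  # shorter apparent dwells receive larger upward corrections, checked
  # against a numerical convolution oracle on a duration grid
  grid <- risetime * c(0.5, 0.8, 1.2, 2, 3)
  corr <- correct_risetime(event_list(rep("open", 5), grid), fc)$duration
  uplift <- corr - grid
  expect_true(all(diff(uplift) <= 1e-9))
  expect_true(all(corr >= grid - 1e-12))
  # oracle: filter a pulse of the corrected duration, measure its apparent
  # width back, and compare with what we started from
  for (i in c(2, 4)) {
    d_true <- corr[i]
    pulse <- event_list(c("shut", "open", "shut"), c(5e-3, d_true, 5e-3))
    tr <- simulate_trace(pulse, 1e7, filter_fc = fc, open_pA = 16)
    w <- idealize_trace(tr, 16)$duration
    expect_equal(w, grid[i], tolerance = 0.02)
  }
})

test_that("dead-time imposition matches the recursive-merge oracle", {
  ev <- event_list(c("open", "shut", "open"), c(1e-3, 10e-6, 2e-3))
  out <- impose_dead_time(ev, 18.83e-6)
  expect_equal(nrow(out), 1)
  expect_equal(out$duration, 3.01e-3)
  # all long events: identity
  ev2 <- event_list(c("open", "shut", "open"), c(1e-3, 1e-3, 2e-3))
  expect_equal(impose_dead_time(ev2, 18.83e-6)$duration, ev2$duration)
  for (s in 1:150) {
    evr <- random_event_list(sample(2:40, 1), seed = s)
    td <- runif(1, 0, 3e-4)
    got <- suppressWarnings(impose_dead_time(evr, td))
    ref <- oracle_dead_time(as.character(evr$class), evr$duration, td)
    expect_equal(as.character(got$class), ref$cls)
    expect_equal(got$duration, ref$dur)
    # idempotence and conservation (up to dropped boundary events)
    again <- suppressWarnings(impose_dead_time(got, td))
    expect_equal(again$duration, got$duration)
    if (nrow(got)) expect_true(min(got$duration) >= td)
    expect_lte(sum(got$duration), sum(evr$duration) + 1e-12)
  }
})

test_that("critical closed duration solves the component intersection", {
  comp <- data.frame(area = c(0.7, 0.3), tau = c(6e-5, 0.5))
  tc <- determine_tau_crit(comp)
  expect_equal(tc, 0.5926e-3, tolerance = 1e-3)
  # numeric root of the stated intersection equation
  f <- function(t) comp$area[1] / comp$tau[1] * exp(-t / comp$tau[1]) -
    comp$area[2] / comp$tau[2] * exp(-t / comp$tau[2])
  tc_num <- uniroot(f, c(comp$tau[1], comp$tau[2]), tol = 1e-12)$root
  expect_equal(tc, tc_num, tolerance = 1e-9)
  expect_gt(tc, comp$tau[1]); expect_lt(tc, comp$tau[2])
  # equal areas, tau2 = e * tau1 reduces to the closed form exactly:
  # t = (1 + log(e)) adjusted -> log(tau2/tau1)/(1/tau1 - 1/tau2)
  t1 <- 1e-4; t2 <- exp(1) * t1
  tc2 <- determine_tau_crit(data.frame(area = c(0.5, 0.5), tau = c(t1, t2)))
  expect_equal(tc2, log(t2 / t1) / (1 / t1 - 1 / t2), tolerance = 1e-12)
  # scaling both areas leaves the intersection unchanged
  tc3 <- determine_tau_crit(data.frame(area = comp$area * 7, tau = comp$tau))
  expect_equal(tc3, tc)
  expect_error(determine_tau_crit(data.frame(area = c(1, 1),
                                             tau = c(2e-3, 2e-3))),
               "distinct")
})

test_that("burst definition splits on long closings and screens short bursts", {
  cls <- c("open", "shut", "open", "shut", "open", "shut", "open")
  dur <- c(3e-3, 2e-3, 3e-3, 10e-3, 1e-3, 1e-3, 2e-3)
  bs <- define_bursts(event_list(cls, dur), tau_crit = 5e-3)
  expect_equal(length(bs$bursts), 2)
  expect_equal(bs$summary$n_events, c(3, 3))
  # P_open arithmetic
  b <- define_bursts(event_list(c("open", "shut", "open"),
                                c(3e-3, 0.06e-3, 3e-3)), 1e-3)
  expect_equal(b$summary$p_open, 6 / 6.06, tolerance = 1e-9)
  # infinite tau_crit: one burst containing everything
  all_one <- define_bursts(event_list(cls, dur), Inf)
  expect_equal(length(all_one$bursts), 1)
  expect_equal(all_one$summary$n_events, 7)
})

test_that("P_open filtering removes constructed outliers and keeps a subset", {
  s1 <- scheme_preset("S1")
  ev <- sim_conditioned(s1, 8000, seed = 31)
  mix <- fit_exp_mixture(ev$duration[ev$class == "shut"], 2,
                         dead_time = td_detect, seed = 1)
  bs <- define_bursts(ev, determine_tau_crit(mix$components))
  kept <- filter_bursts_by_popen(bs)
  # homogeneous bursts: most survive; the P_open distribution is skewed
  # against its ceiling at 1, so the 2-sigma pass trims somewhat more than
  # the Gaussian 4.6%
  expect_gte(length(kept$bursts), 0.85 * length(bs$bursts))
  expect_true(all(kept$summary$p_open %in% bs$summary$p_open))
  # a grossly aberrant burst among high-P_open bursts is removed
  fake <- event_list(c("open", "shut", "open"), c(1e-5, 0.098, 1e-5))
  bs2 <- bs
  bs2$bursts <- c(bs2$bursts, list(fake))
  bs2$summary <- rbind(bs2$summary,
                       data.frame(n_events = 3, duration = 0.09802,
                                  p_open = 2e-5 / 0.09802,
                                  amplitude = NA_real_))
  kept2 <- filter_bursts_by_popen(bs2)
  expect_false(min(bs2$summary$p_open) %in% kept2$summary$p_open)
  tiny <- bs
  tiny$bursts <- bs$bursts[1:3]
  tiny$summary <- bs$summary[1:3, ]
  expect_warning(filter_bursts_by_popen(tiny), "fewer than 5")
})
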