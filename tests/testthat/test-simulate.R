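test_that("simulation is deterministic given the seed and requires one", {
  s1 <- scheme_preset("S1")
  a <- simulate_events(s1, 500, seed = 42)
  b <- simulate_events(s1, 500, seed = 42)
  expect_identical(a$duration, b$duration)
  expect_identical(a$class, b$class)
  expect_error(simulate_state_path(s1, 10), "seed")
})

test_that("sojourn statistics match the generator", {
  s1 <- scheme_preset("S1")
  ev <- simulate_events(s1, 20000, seed = 7)
  open <- ev$duration[ev$class == "open"]
  # single open state: dwell mean 1/alpha within 3 SE
  expect_lt(abs(mean(open) - 1 / 310), 3 * sd(open) / sqrt(length(open)))
  # open-class time fraction matches equilibrium occupancy
  pi <- equilibrium_occupancy(build_generator(s1))
  frac <- sum(open) / sum(ev$duration)
  expect_equal(frac, unname(pi["Op"]), tolerance = 0.02)
})

test_that("simulated dwell distributions agree with the ideal density", {
  s1 <- scheme_preset("S1")
  g <- build_generator(s1)
  ev <- simulate_events(s1, 10000, seed = 3)
  shut <- ev$duration[ev$class == "shut"]
  comp <- ideal_dwell_components(g, "shut")
  cdf <- function(t) sum(comp$area) -
    sapply(t, function(ti) sum(comp$area * exp(-ti / comp$tau)))
  ks <- suppressWarnings(ks.test(shut, cdf))
  expect_gt(ks$p.value, 0.01)
})

test_that("aggregation merges same-class sojourns and conserves time", {
  path <- data.frame(state = c("C", "Cp", "Op"),
                     class = c("shut", "shut", "open"),
                     sojourn = c(1e-3, 2e-3, 3e-3))
  ev <- aggregate_to_events(path)
  expect_equal(as.character(ev$class), c("shut", "open"))
  expect_equal(ev$duration, c(3e-3, 3e-3))
  ev1 <- aggregate_to_events(path[1, ])
  expect_equal(nrow(ev1), 1)
  for (s in 1:10) {
    set.seed(s)
    n <- sample(5:50, 1)
    p <- data.frame(state = "x",
                    class = sample(c("shut", "open"), n, replace = TRUE),
                    sojourn = rexp(n, 1000))
    evs <- aggregate_to_events(p)
    expect_equal(sum(evs$duration), sum(p$sojourn), tolerance = 1e-12)
    expect_true(all(evs$class[-1] != evs$class[-nrow(evs)]))
  }
})

test_that("mean openings per burst match the geometric reopening probability", {
  # from the primed-closed state the channel reopens with probability
  # beta_1/(beta_1 + k_minus1_prime), so one activation episode (everything
  # between visits to the resting closed state) carries a geometric number
  # of openings of mean 1/(1 - 10000/17600) ~ 2.32
  s1 <- scheme_preset("S1")
  path <- simulate_state_path(s1, 30000, seed = 12)
  n_open <- sum(path$state == "Op")
  visits_c <- which(path$state == "C")
  # episodes between C visits that contain at least one opening
  episode <- findInterval(which(path$state == "Op"), visits_c)
  n_bursts <- length(unique(episode))
  expect_equal(n_open / n_bursts, 1 / (1 - 10000 / 17600), tolerance = 0.05)
})

test_that("trace synthesis has the Gaussian-filter risetime and clean limits", {
  ev <- event_list(c("shut", "open", "shut"), c(1e-3, 1e-3, 1e-3))
  tr <- simulate_trace(ev, sample_rate = 1e6, open_pA = 16)
  expect_setequal(unique(tr$current), c(0, 16))
  # filtered step crosses half amplitude at the ideal transition and rises
  # 10-90% in 0.3321/fc
  fc <- 1e4
  tr2 <- simulate_trace(ev, 1e6, filter_fc = fc, open_pA = 16)
  i50 <- min(which(tr2$current > 8))
  expect_lt(abs(tr2$t[i50] - 1e-3), 2e-6) # within two samples
  i10 <- min(which(tr2$current > 1.6)); i90 <- min(which(tr2$current > 14.4))
  expect_equal((i90 - i10) * 1e-6, 0.3321 / fc, tolerance = 0.05)
  expect_error(simulate_trace(ev, 1e4, filter_fc = 6e3), "Nyquist")
})

test_that("fingerprint bursts follow binomial assembly with linear amplitudes", {
  fp <- simulate_fingerprint_bursts(20000, 0.5, amp_lc = 1.5, amp_hc = 16,
                                    class_sd = 0.3, seed = 9)
  # class means interpolate linearly: 1.5, 4.4, ..., 16.0 (step 2.9)
  mu <- as.numeric(tapply(fp$amplitude, fp$hc_count, mean))
  expect_equal(mu, seq(1.5, 16, by = 2.9), tolerance = 0.01)
  # class frequencies converge to the binomial pmf
  obs <- tabulate(fp$hc_count + 1, nbins = 6)
  gof <- chisq.test(obs, p = dbinom(0:5, 5, 0.5))
  expect_gt(gof$p.value, 0.01)
  # degenerate mixture
  fp1 <- simulate_fingerprint_bursts(2000, 1, seed = 2)
  expect_equal(mean(fp1$amplitude), 16, tolerance = 0.05)
  expect_true(all(fp1$hc_count == 5))
})
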