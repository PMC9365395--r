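test_that("generator matrix realizes the spontaneous priming scheme", {
  g <- build_generator(scheme_preset("S1"))
  expect_equal(g$q["C", "Cp"], 3900)
  expect_equal(g$q["Cp", "C"], 7600)
  expect_equal(g$q["Cp", "Op"], 10000)
  expect_equal(g$q["Op", "Cp"], 310)
  expect_equal(diag(g$q), c(C = -3900, Cp = -17600, Op = -310))
  expect_equal(unname(rowSums(g$q)), rep(0, 3))
})

test_that("ligand-dependent rates scale with concentration", {
  s2 <- scheme_preset("S2", blocker = "ACh")
  g <- build_generator(s2, c(ACh = 30))
  expect_equal(g$q["Op", "OpB"], 170 * 30)
  expect_error(build_generator(s2), "ACh")
})

test_that("generator rows sum to zero with non-negative off-diagonals for random schemes", {
  for (s in 1:20) {
    sch <- random_chain_scheme(sample(1:3, 1), seed = s)
    conc <- NULL
    g <- build_generator(sch, conc)
    expect_lt(max(abs(rowSums(g$q))), 1e-9 * max(abs(g$q)))
    off <- g$q; diag(off) <- 0
    expect_gte(min(off), 0)
  }
})

test_that("scheme validation rejects malformed inputs", {
  st <- data.frame(state = c("C", "O"), class = c("shut", "open"))
  tr <- data.frame(from = "C", to = "O", symbol = "b", value = 10)
  expect_error(kinetic_scheme("x", st, tr), "strongly connected")
  tr2 <- rbind(tr, data.frame(from = "O", to = "C", symbol = "a", value = -1))
  expect_error(kinetic_scheme("x", st, tr2), "non-negative")
  tr3 <- data.frame(from = c("C", "C", "O"), to = c("O", "O", "C"),
                    symbol = c("b", "b2", "a"), value = c(1, 2, 3))
  expect_error(kinetic_scheme("x", st, tr3), "duplicate transition")
})

test_that("equilibrium occupancy solves pi Q = 0 and matches detailed balance", {
  # symmetric two-state scheme splits occupancy evenly
  ts <- kinetic_scheme("sym",
    data.frame(state = c("C", "O"), class = c("shut", "open")),
    data.frame(from = c("C", "O"), to = c("O", "C"),
               symbol = c("beta_1", "alpha_1"), value = c(500, 500)))
  expect_equal(unname(equilibrium_occupancy(build_generator(ts))),
               c(0.5, 0.5))

  g <- build_generator(scheme_preset("S1"))
  pi <- equilibrium_occupancy(g)
  expect_lt(max(abs(pi %*% g$q)), 1e-9)
  # detailed-balance chain product: 1 : k+/k- : (k+/k-)(beta/alpha)
  w <- c(1, 3900 / 7600, (3900 / 7600) * (10000 / 310))
  expect_equal(unname(pi), w / sum(w), tolerance = 1e-9)
  expect_equal(unname(pi["Op"]), 0.916, tolerance = 1e-3)

  # permuting the state order permutes pi identically
  s1p <- scheme_preset("S1")
  perm <- c(3, 1, 2)
  s1p$states <- s1p$states[perm, ]
  pi2 <- equilibrium_occupancy(build_generator(s1p))
  expect_equal(pi2[names(pi)], pi, tolerance = 1e-9)
})

test_that("ideal dwell components give the spectral mixture", {
  g <- build_generator(scheme_preset("S1"))
  op <- ideal_dwell_components(g, "open")
  expect_equal(nrow(op), 1)
  expect_equal(op$tau, 1 / 310, tolerance = 1e-12)
  sh <- ideal_dwell_components(g, "shut")
  # 2x2 closed form: eigenvalues -2000 and -19500 s^-1
  expect_equal(sort(1 / sh$tau), c(2000, 19500), tolerance = 1e-9)
  expect_equal(sum(sh$area), 1, tolerance = 1e-9)
  # density integrates to 1 and its mean matches the closed form
  dens_int <- integrate(function(t) ideal_dwell_density(g, "shut", t),
                        0, Inf, rel.tol = 1e-9)$value
  expect_equal(dens_int, 1, tolerance = 1e-6)
  mean_quad <- integrate(function(t) t * ideal_dwell_density(g, "shut", t),
                         0, Inf, rel.tol = 1e-10)$value
  expect_equal(mean_quad, mean_dwell(g, "shut"), tolerance = 1e-6)
})

test_that("component count equals class size for distinct eigenvalues", {
  for (s in 21:25) {
    sch <- random_chain_scheme(3, seed = s)
    g <- build_generator(sch)
    comp <- ideal_dwell_components(g, "shut")
    if (is.null(comp)) next # defective sub-generator: decomposition absent
    expect_equal(nrow(comp), 3)
    expect_equal(sum(comp$area), 1, tolerance = 1e-9)
  }
})

test_that("derived equilibrium constants follow the footnote definitions", {
  d <- derived_constants(c(beta_1 = 10000, alpha_1 = 310))
  expect_equal(round(unname(d["Theta_1"]), 2), 32.26)
  d2 <- derived_constants(c(k_plus_B = 95, k_minus_B = 1400))
  expect_equal(round(unname(d2["K_B"]), 2), 14.74)
  d3 <- derived_constants(c(beta_2 = 7, alpha_2 = 7))
  expect_equal(unname(d3["Theta_2"]), 1)
  expect_error(derived_constants(c(beta_1 = 10)), "alpha_1")
  expect_error(derived_constants(c(beta_1 = 10, alpha_1 = 0)), "positive")
  # binding constants are dissociation ratios (k_minus / k_plus)
  d4 <- derived_constants(c(k_plus_1 = 650, k_minus_1 = 14400))
  expect_equal(unname(d4["K_1"]), 14400 / 650)
})

test_that("schemes round trip through the config file format", {
  path <- tempfile(fileext = ".json")
  s2 <- scheme_preset("S2", blocker = "QX222")
  write_scheme(s2, path)
  back <- read_scheme(path)
  expect_equal(back$states, s2$states)
  expect_equal(back$transitions, s2$transitions)
})
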