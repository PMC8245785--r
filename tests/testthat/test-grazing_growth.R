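test_that("growth rate matches the exponential closed form", {
  expect_equal(growth_rate(100, 100, 1), 0)
  expect_equal(growth_rate(100, 200, 1), log(2))
  # synthetic exponential trajectory recovers the injected rate
  expect_equal(growth_rate(175, 175 * exp(0.35 * 2), 2), 0.35)
  # antisymmetry and scale invariance
  set.seed(11)
  for (i in 1:20) {
    n0 <- runif(1, 10, 1e4); n1 <- runif(1, 10, 1e4)
    t <- runif(1, 0.5, 3); s <- runif(1, 0.1, 10)
    expect_equal(growth_rate(n0, n1, t), -growth_rate(n1, n0, t))
    expect_equal(growth_rate(s * n0, s * n1, t), growth_rate(n0, n1, t))
  }
  expect_true(is.na(growth_rate(0, 100, 1)))
})

test_that("logarithmic mean density behaves like a time average", {
  expect_equal(frost_mean_density(1000, 1000), 1000)
  expect_equal(frost_mean_density(1000, 2000), 1000 / log(2))
  expect_equal(frost_mean_density(2000, 1000), 1000 / log(2))
  set.seed(12)
  for (i in 1:25) {
    a <- runif(1, 1, 1e5); b <- runif(1, 1, 1e5)
    lm <- frost_mean_density(a, b)
    expect_gte(lm, min(a, b) * (1 - 1e-12))
    expect_lte(lm, max(a, b) * (1 + 1e-12))
    # equals the time average of the exponential path a -> b over [0, 1]
    quad <- stats::integrate(function(u) a * (b / a)^u, 0, 1)$value
    expect_equal(lm, quad, tolerance = 1e-6)
  }
})

test_that("grazing coefficient subtracts control growth", {
  # prey growing exactly at the control rate implies no grazing
  expect_equal(grazing_coefficient(0.5, 1e4, 1e4 * exp(0.5), 1), 0)
  expect_equal(grazing_coefficient(0.5, 1e4, 1e4 * exp(-0.2), 1), 0.7)
  # prey beating the control gives negative g
  expect_lt(grazing_coefficient(0.2, 1e4, 1e4 * exp(0.5), 1), 0)
})

test_that("clearance/ingestion recovers a constant-clearance forward model", {
  # fine-step simulation of the classic grazing model: the estimator must
  # recover the true clearance and mean per-grazer ingestion within 1%
  k <- 0.6; Fstar <- 1e-3
  for (case in list(c(C0 = 1e4, N0 = 100, mu = 0.4),
                    c(C0 = 5e4, N0 = 150, mu = 0.2))) {
    orc <- frost_oracle(case["C0"], case["N0"], k, Fstar, case["mu"],
                        t_end = 1)
    iv <- data.frame(culture_id = "X", treatment_id = "T", t0 = 0, t1 = 1,
                     N0 = unname(case["N0"]), N1 = unname(orc$N1),
                     C0 = unname(case["C0"]), C1 = unname(orc$C1),
                     k_control = k)
    est <- clearance_ingestion(iv)
    expect_equal(est$F, Fstar, tolerance = 0.01)
    expect_equal(est$I, unname(orc$I_mean), tolerance = 0.01)
    expect_equal(est$flags, "")
  }
})

test_that("zero grazing, negative grazing and depletion are handled", {
  iv <- data.frame(culture_id = "X", treatment_id = "T", t0 = 0, t1 = 1,
                   N0 = 100, N1 = 120,
                   C0 = 1e4, C1 = 1e4 * exp(0.5), k_control = 0.5)
  est <- clearance_ingestion(iv)
  expect_equal(est$F, 0)
  expect_equal(est$I, 0)
  # prey above control growth: flagged, I clamped under the default policy
  iv$C1 <- 1e4 * exp(0.8)
  est <- clearance_ingestion(iv)
  expect_match(est$flags, "negative_grazing")
  expect_equal(est$I, 0)
  expect_lt(est$g, 0)
  est2 <- clearance_ingestion(iv, negative_grazing_policy = "keep_negative")
  expect_lt(est2$I, 0)
  # depleted prey: detection-limit substitution, flagged
  iv$C1 <- 0
  est3 <- clearance_ingestion(iv, detection_limit = 0.5)
  expect_match(est3$flags, "depleted_prey")
  expect_true(is.finite(est3$I) && est3$I > 0)
})

test_that("growth rate from Poisson counting at 200+ individuals is tight", {
  # two endpoints counted to >= 200 individuals, mu*t = 1.4
  set.seed(99)
  mu <- 0.7; t <- 2; v0 <- 2.5; v1 <- 2.5 / exp(mu * t)
  n_reps <- 1000
  N0_true <- 100; N1_true <- N0_true * exp(mu * t)
  err <- replicate(n_reps, {
    n0 <- rpois(1, N0_true * v0 * exp(mu * t))   # ~ 1000 counted
    n1 <- rpois(1, N1_true * v0)
    abs(growth_rate(n0 / (v0 * exp(mu * t)), n1 / v0, t) - mu) / mu
  })
  expect_lt(median(err), 0.05)
})

test_that("interval builder honours dilution cycles and sampling gaps", {
  mk <- function(culture, day, species, density, phase)
    data.frame(culture_id = culture, treatment_id = "T", day = day,
               species = species, density = density,
               n_counted = NA_real_, volume_counted = NA_real_,
               phase = phase, stringsAsFactors = FALSE)
  # acclimation: 5 sampling days (0..4) with daily dilution -> 4 intervals
  acc <- do.call(rbind, lapply(0:3, function(d) rbind(
    mk("A", d, "ciliate", 15, "post_dilution"),
    mk("A", d + 1, "ciliate", 25, "pre_dilution"),
    mk("A", d, "prey", 1e4, "post_dilution"),
    mk("A", d + 1, "prey", 8e3, "pre_dilution"))))
  acc <- acc[order(acc$culture_id, acc$species, acc$day), ]
  iv <- build_intervals(acc)
  expect_equal(nrow(iv), 4)
  expect_equal(iv$t1 - iv$t0, rep(1, 4))
  expect_equal(iv$N0, rep(15, 4))
  expect_equal(iv$N1, rep(25, 4))
  # starvation: sampling on days 2, 5, 7, 9 -> (2,5), (5,7), (7,9)
  st <- do.call(rbind, lapply(c(2, 5, 7, 9), function(d)
    mk("B", d, "ciliate", 100 * exp(-0.3 * d), "none")))
  iv2 <- build_intervals(st)
  expect_equal(iv2$t0, c(2, 5, 7))
  expect_equal(iv2$t1, c(5, 7, 9))
  expect_true(all(is.na(iv2$k_control)))
  # control matched over the same window, using its own dilution phases
  ctrl <- rbind(mk("C", 2, "prey", 1e4, "post_dilution"),
                mk("C", 5, "prey", 1e4 * exp(0.4 * 3), "pre_dilution"))
  iv3 <- build_intervals(st, ctrl)
  expect_equal(iv3$k_control[1], 0.4)
  expect_true(is.na(iv3$k_control[2]))
})
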