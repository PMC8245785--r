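test_that("chloroplast pool decays exponentially without prey", {
  p <- sim_params(seed = 1, noise = "none")
  for (irr in c(10, 40, 120)) {
    st <- kleptoCarbon:::new_state(C = 0, N = 50, Q = 60, c = p$c_init)
    st <- kleptoCarbon:::advance(st, p, irr, 2)
    lambda <- p$d0 + p$d1 * irr
    expect_equal(st$Q, 60 * exp(-lambda * 2), tolerance = 0.01)
    expect_equal(st$C, 0)
  }
  # photosynthesis vanishes in the dark whatever the chl pool
  dark <- kleptoCarbon:::model_rates(
    kleptoCarbon:::new_state(C = 0, N = 50, Q = 80, c = p$c_init), p, 0)
  expect_equal(dark$P, 0)
})

test_that("chl half-life is strictly decreasing in irradiance", {
  p <- sim_params(seed = 1, noise = "none")
  hl <- log(2) / (p$d0 + p$d1 * c(5, 10, 40, 80, 120, 200))
  expect_true(all(diff(hl) < 0))
})

test_that("starved cultures only lose cells once prey are gone", {
  p <- sim_params(seed = 4, noise = "none")
  sim <- run_starvation(p, irradiances = 40, days = 9)
  tr <- sim$trajectories
  one <- tr[tr$culture_id == tr$culture_id[1], ]
  one <- one[order(one$day), ]
  post <- one[one$C < 0.5, ]            # after depletion
  expect_gt(nrow(post), 1)
  expect_true(all(diff(post$N) < 0))    # monotone decline, no divisions
})

test_that("the dilution operator halves prey with ciliates, then tops up", {
  st <- kleptoCarbon:::new_state(C = 3e4, N = 30, Q = 60, c = 7000)
  d <- kleptoCarbon:::dilute(st, 15, 4e4)
  expect_equal(d$N, 15)
  # prey halved to 1.5e4, then topped back to the 4e4 target
  expect_equal(d$C, 4e4)
  d2 <- kleptoCarbon:::dilute(
    kleptoCarbon:::new_state(C = 9e4, N = 30, Q = 60, c = 7000), 15, 4e4)
  expect_equal(d2$C, 4.5e4)             # no removal beyond dilution
  expect_warning(
    kleptoCarbon:::dilute(
      kleptoCarbon:::new_state(C = 3e4, N = 8, Q = 60, c = 7000), 15, 4e4),
    "below target")
})

test_that("the acclimation design yields 27 sample-bottle series", {
  p <- sim_params(seed = 6, noise = "none")
  sim <- run_acclimation(p)
  reps <- unique(sim$counts$culture_id[grepl("_r[0-9]$",
                                             sim$counts$culture_id)])
  expect_equal(length(reps), 27)
  expect_equal(nrow(sim$treatments), 9)
  # every replicate contributes 3 dilution-cycle intervals to the ledger
  per <- table(sim$truth$culture_id[sim$truth$culture_id %in% reps])
  expect_true(all(per == 3))
})

test_that("identical parameters give identical outputs", {
  a <- run_acclimation(sim_params(seed = 42), irradiances = 40,
                       prey_targets = c(5e3, 4e4), days = 4)
  b <- run_acclimation(sim_params(seed = 42), irradiances = 40,
                       prey_targets = c(5e3, 4e4), days = 4)
  for (f in c("counts", "control_counts", "scint", "fluor", "dims",
              "truth"))
    expect_identical(a[[f]], b[[f]], info = f)
  c2 <- run_acclimation(sim_params(seed = 43), irradiances = 40,
                        prey_targets = c(5e3, 4e4), days = 4)
  expect_false(identical(a$scint$dpm, c2$scint$dpm))
})

test_that("prey carbon removed equals carbon offered to the grazer", {
  p <- sim_params(seed = 8, noise = "none")
  sim <- run_acclimation(p, irradiances = c(10, 120))
  with(sim$truth, expect_equal(offered_carbon,
                               p$prey_carbon * removed_cells))
})

test_that("generated files pass all schema validators", {
  dir <- withr::local_tempdir()
  p <- sim_params(seed = 9)
  run_acclimation(p, irradiances = 40, out_dir = dir)
  expect_silent(read_counts(file.path(dir, "counts.csv")))
  expect_silent(read_counts(file.path(dir, "controls.csv")))
  expect_silent(read_scintillation(file.path(dir, "scint.csv")))
  expect_silent(read_fluorometry(file.path(dir, "fluor.csv")))
  expect_silent(read_dimensions(file.path(dir, "dims.csv")))
  expect_silent(read_treatments(file.path(dir, "treatments.csv")))
})

test_that("dark vials are independent of the true photosynthetic rate", {
  p_lo <- sim_params(seed = 10, alpha = 0.05)
  p_hi <- sim_params(seed = 10, alpha = 1.5)
  lo <- run_acclimation(p_lo, irradiances = 40, prey_targets = 1e4)
  hi <- run_acclimation(p_hi, irradiances = 40, prey_targets = 1e4)
  dl <- lo$scint$dpm[lo$scint$vial == "dark"]
  dh <- hi$scint$dpm[hi$scint$vial == "dark"]
  expect_identical(dl, dh)
  expect_false(identical(lo$scint$dpm[lo$scint$vial == "light"],
                         hi$scint$dpm[hi$scint$vial == "light"]))
})

test_that("Poisson counting at expectation 200 gives ~7% relative spread", {
  set.seed(55)
  # density 100 cells/mL in one 2 mL well: 200 individuals expected
  reps <- replicate(4000, kleptoCarbon:::count_sample(
    100, 2, 1, 200, exact = FALSE))
  expect_true(all(reps[2, ] == 2))
  dens <- reps[3, ]
  expect_equal(sd(dens) / mean(dens), 1 / sqrt(200), tolerance = 0.05)
})

test_that("halving the integration step leaves trajectories unchanged", {
  p1 <- sim_params(seed = 1, noise = "none")
  p2 <- sim_params(seed = 1, noise = "none", dt = 0.005)
  s1 <- run_acclimation(p1, irradiances = 40, prey_targets = 4e4)
  s2 <- run_acclimation(p2, irradiances = 40, prey_targets = 4e4)
  expect_equal(s1$truth$I, s2$truth$I, tolerance = 0.01)
  expect_equal(s1$truth$mu_y, s2$truth$mu_y, tolerance = 0.02)
  expect_equal(s1$truth$P_daily, s2$truth$P_daily, tolerance = 0.01)
})
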