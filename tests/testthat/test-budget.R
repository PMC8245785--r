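test_that("budget components are the documented linear conversions", {
  tr <- default_treatment()
  expect_equal(ingested_carbon(100, tr), 1000)
  expect_equal(ingested_carbon(0, tr), 0)
  tr12 <- default_treatment(prey_carbon = 12)
  expect_equal(ingested_carbon(5, tr12), 60)
  expect_equal(carbon_specific_growth(0.3, 2000), 600)
  expect_equal(carbon_specific_growth(0, 2000), 0)
  expect_equal(carbon_specific_growth(-0.2, 1000), -200)
})

test_that("gge allows values above 1 and is undefined at zero ingestion", {
  expect_equal(gge(600, 1000), 0.6)
  expect_equal(gge(1000, 1000), 1)
  expect_equal(gge(1100, 1000), 1.1)   # not clamped
  expect_true(is.na(gge(600, 0)))
  # invariant to a common rescaling of carbon units
  set.seed(21)
  for (i in 1:10) {
    m <- runif(1, 10, 5000); ci <- runif(1, 10, 5000)
    s <- runif(1, 0.1, 100)
    expect_equal(gge(s * m, s * ci), gge(m, ci))
  }
})

test_that("partition percentages are complementary and handle limits", {
  expect_equal(partition(500, 500)$photo_pct, 50)
  expect_equal(unlist(partition(0, 800)), c(photo_pct = 0, ingest_pct = 100))
  expect_equal(unlist(partition(800, 0)), c(photo_pct = 100, ingest_pct = 0))
  expect_true(all(is.na(partition(0, 0))))
  set.seed(22)
  p <- runif(50, 0, 1e3); ci <- runif(50, 0, 1e3)
  pp <- partition(p, ci)
  expect_equal(pp$photo_pct + pp$ingest_pct, rep(100, 50))
  expect_true(all(pp$photo_pct >= 0 & pp$photo_pct <= 100))
})

test_that("assembled records propagate missingness instead of zeros", {
  p <- sim_params(seed = 2, noise = "none")
  sim <- run_acclimation(p, irradiances = 40, prey_targets = 1e4)
  iv <- clearance_ingestion(build_intervals(sim$counts,
                                            sim$control_counts))
  # without scintillation data: GGE computable, partitioning undefined
  rec <- assemble_rates(iv, uptake = NULL,
                        fluor = chl_per_cell(
                          sim$fluor[sim$fluor$n_cells > 0, ]),
                        dims = sim$dims, treatments = sim$treatments)
  reps <- grepl("_r[0-9]$", rec$culture_id)
  expect_true(all(is.na(rec$P_daily)))
  expect_true(all(is.na(rec$photo_pct)))
  expect_true(all(is.finite(rec$GGE[reps])))
  # complete inputs: fully populated replicate records
  full <- assemble_rates(iv, uptake_hourly(pair_scintillation(sim$scint)),
                         chl_per_cell(sim$fluor[sim$fluor$n_cells > 0, ]),
                         sim$dims, sim$treatments)
  for (f in c("mu_y", "I", "P_daily", "chl_cell", "P_chl", "Bv", "C_y",
              "mu_yC", "C_I", "GGE", "photo_pct"))
    expect_true(all(is.finite(full[[f]][reps])), info = f)
  expect_true(all(full$photo_pct >= 0 & full$photo_pct <= 100,
                  na.rm = TRUE))
})

test_that("a starved interval yields zero ingested carbon and full photo share", {
  iv <- data.frame(culture_id = "X", treatment_id = "T1", t0 = 2, t1 = 5,
                   N0 = 100, N1 = 40, C0 = 1000, C1 = 1000,
                   k_control = 0, flags = "")
  iv <- clearance_ingestion(iv)  # g = 0 -> I = 0
  up <- uptake_hourly(scint_pair(culture_id = "X", day = 5))
  rec <- assemble_rates(iv, up, NULL, NULL,
                        treatment_table(default_treatment()))
  expect_equal(rec$C_I, 0)
  expect_true(is.na(rec$GGE))
  expect_equal(rec$photo_pct, 100)
})

test_that("summaries report mean, sample SD and group sizes", {
  rec <- data.frame(
    culture_id = sprintf("c%d", 1:6),
    treatment_id = rep(c("A", "B"), each = 3),
    t0 = 2, t1 = 3,
    mu_y = c(1, 2, 3, 5, 5, 5), stringsAsFactors = FALSE)
  s <- summarize_rates(rec, fields = "mu_y")
  expect_equal(nrow(s), 2)
  a <- s[s$treatment_id == "A", ]
  expect_equal(a$mean, 2)
  expect_equal(a$std, 1)
  expect_equal(a$n, 3)
  expect_equal(s$std[s$treatment_id == "B"], 0)
  # 3x3 treatment x day grid -> 9 groups
  grid <- expand.grid(treatment_id = c("A", "B", "C"), t1 = c(3, 4, 5))
  grid$culture_id <- sprintf("c%d", seq_len(nrow(grid)))
  grid$t0 <- grid$t1 - 1
  grid$mu_y <- 1
  expect_equal(nrow(summarize_rates(grid, fields = "mu_y")), 9)
})

test_that("conflicting duplicate point measurements are an error", {
  iv <- data.frame(culture_id = "X", treatment_id = "T1", t0 = 2, t1 = 3,
                   N0 = 100, N1 = 110, C0 = 1e4, C1 = 9e3,
                   k_control = 0.1, flags = "")
  iv <- clearance_ingestion(iv)
  fl <- data.frame(culture_id = c("X", "X"), day = 3, n_cells = 20,
                   reading = c(1300, 900), volume_filtered = NA_real_)
  expect_error(
    assemble_rates(iv, NULL, chl_per_cell(fl), NULL,
                   treatment_table(default_treatment())),
    "conflicting duplicate")
})
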