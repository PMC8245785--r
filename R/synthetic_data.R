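#' Parameters of the kleptoplast mixotroph simulator
#'
#' Bundles the mechanistic model parameters, the measurement-noise model and
#' a random seed. The default preset targets the observable ranges typical
#' of a kleptoplastidic oligotrich ciliate feeding on a cryptophyte: ~60-70
#' pg chl-a cell-1 when well fed, daily inorganic carbon uptake of order
#' 1e2-1e3 pg C cell-1 d-1, ingestion approaching ~900 prey cell-1 d-1 at
#' bloom prey densities, and survival of roughly a week after prey
#' depletion at intermediate irradiance.
#'
#' Model structure (per culture; densities are continuous, all noise lives
#' in the observation layer):
#' * prey: `dC/dt = mu_x(Irr) C - I(C) N`, with light-limited growth
#'   `mu_x = mu_max_x (1 - exp(-Irr/Ik_x))` and Monod ingestion
#'   `I(C) = I_max C / (K + C)`.
#' * chloroplast pool (per-cell chl-a, pg): `dQ/dt =
#'   chl_retention * q_prey * I(C) - (d0 + d1 Irr) Q`; only a fraction of
#'   ingested prey chl is sequestered (the rest is digested), and the pool
#'   decays faster under stronger light.
#' * photosynthesis per cell (pg C d-1):
#'   `P = PBmax (1 - exp(-alpha Irr / PBmax)) exp(-beta_inhib Irr) * Q exp(-k_s Q)`
#'   — a saturating P-I response with a high-light photoinhibition factor
#'   (the pool cannot be photoprotected by its host) and package-effect
#'   self-shading in chl.
#' * ciliate carbon balance (per-cell carbon `c`, pg): `net =
#'   a_assim (prey_carbon I(C) + P) - R_maint`; a positive balance first
#'   refills `c` and, once `c` reaches the division threshold `c_div`,
#'   drives division at rate `net / c`; a negative balance drains `c`
#'   (floored at `c_floor`) and drives mortality at rate
#'   `m0 * min(1, -net / R_maint)`.
#'
#' @param seed integer random seed.
#' @param ... overrides of any default parameter listed below.
#' @param noise `"default"` or `"none"` (all measurement noise off; counts
#'   report exact densities).
#'
#' @section Defaults:
#' `mu_max_x = 0.7` d-1, `Ik_x = 30`; `I_max = 3500` prey grazer-1 d-1,
#' `K = 1.2e5` cells mL-1 (a near-linear functional response over the
#' experimental prey range); `q_prey = 0.28` pg chl per prey cell,
#' `chl_retention = 0.05`; `d0 = 0.1` d-1, `d1 = 0.003` d-1 per umol
#' photons m-2 s-1; `alpha = 0.3`, `PBmax = 25` pg C (pg chl)-1 d-1,
#' `beta_inhib = 0.012`, `k_s = 0.004` per pg chl; `a_assim = 0.6`,
#' `R_maint = 180` pg C cell-1 d-1, `m0 = 0.7` d-1; `c_init = 7000`,
#' `c_div = 8000`, `c_floor = 2500` pg C cell-1; `chl_init = 65` pg;
#' `prey_carbon = 10` pg C, `carbon_per_volume = 0.19` pg C um-3,
#' `light_hours = 14`; `dt = 0.01` d. Measurement layer: Poisson counting
#' (2 mL wells, up to 12, targeting >= 200 ciliates; 0.1 mL cytometry
#' volumes for prey), `sa_per_ml = 2.22e6` DPM mL-1 medium activity,
#' `dic = 24` ug C mL-1, `dark_dpm = 80` DPM vial-total dark background,
#' `dpm_cv = 0.05`, `fluor_cv = 0.08`, `dim_cv = 0.05` (lognormal /
#' normal coefficients of variation), `aspect = 1.6` cell length:width.
#'
#' @return A list of class `kc_sim_params`.
#' @export
sim_params <- function(seed = 1L, ..., noise = c("default", "none")) {
  noise <- match.arg(noise)
  p <- list(
    # prey and grazing
    mu_max_x = 0.7, Ik_x = 30, I_max = 3500, K = 1.2e5,
    # chloroplast pool
    q_prey = 0.28, chl_retention = 0.05, d0 = 0.1, d1 = 0.003,
    chl_init = 65,
    # photosynthesis
    alpha = 0.3, PBmax = 25, beta_inhib = 0.012, k_s = 0.004,
    # ciliate carbon balance
    a_assim = 0.6, R_maint = 180, m0 = 0.7,
    c_init = 7000, c_div = 8000, c_floor = 2500,
    # conversion constants in force
    prey_carbon = 10, carbon_per_volume = 0.19, light_hours = 14,
    # integration
    dt = 0.01,
    # measurement layer
    sa_per_ml = 2.22e6, sa_volume = 0.1, counted_volume = 1.9,
    vial_volume = 2.0, incubation_h = 3, picked_cells = 20L, dic = 24,
    dark_dpm = 80, dpm_cv = 0.05, fluor_cv = 0.08, dim_cv = 0.05,
    n_dims = 10L, aspect = 1.6, fluor_volume = 5,
    seed = as.integer(seed)
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(p))
  if (length(unknown) > 0L)
    stop("sim_params: unknown parameter(s): ",
         paste(unknown, collapse = ", "))
  p[names(over)] <- over
  if (noise == "none") {
    p$dpm_cv <- 0; p$fluor_cv <- 0; p$dim_cv <- 0
    p$noise <- "none"
  } else p$noise <- "default"
  pos <- c("mu_max_x", "Ik_x", "I_max", "K", "q_prey", "d0", "PBmax",
           "c_init", "c_div", "dt", "sa_per_ml", "dic")
  for (f in pos) if (!is.finite(p[[f]]) || p[[f]] <= 0)
    stop("sim_params: ", f, " must be > 0")
  if (p$a_assim <= 0 || p$a_assim > 1)
    stop("sim_params: a_assim must be in (0, 1]")
  class(p) <- "kc_sim_params"
  p
}

# instantaneous model rates at a state
model_rates <- function(state, p, irr) {
  mu_x <- p$mu_max_x * (1 - exp(-irr / p$Ik_x))
  ing <- p$I_max * state$C / (p$K + state$C)
  pb <- p$PBmax * (1 - exp(-p$alpha * irr / p$PBmax)) *
    exp(-p$beta_inhib * irr)
  P <- pb * state$Q * exp(-p$k_s * state$Q)
  net <- p$a_assim * (p$prey_carbon * ing + P) - p$R_maint
  mu_y <- if (net > 0 && state$c >= p$c_div) net / state$c else 0
  mort <- if (net < 0) p$m0 * min(1, -net / p$R_maint) else 0
  list(mu_x = mu_x, ing = ing, P = P, net = net, mu_y = mu_y, mort = mort)
}

#' One Euler step of the kleptoplast model
#'
#' Advances a culture state by `dt` days under the model documented in
#' [sim_params()]. All state variables are floored at zero (per-cell carbon
#' at `c_floor`); a non-finite state aborts with a diagnostic.
#'
#' @param state list with `C` (prey, cells mL-1), `N` (ciliates, cells
#'   mL-1), `Q` (chl-a, pg cell-1), `c` (carbon, pg cell-1), `time` (d), and
#'   accumulators `cum_I` (prey eaten grazer-1), `cum_removed` (prey cells
#'   mL-1), `cum_offered` (pg C mL-1).
#' @param params a [sim_params()] object.
#' @param irradiance umol photons m-2 s-1.
#' @param dt step, days (> 0).
#' @return The updated state list.
#' @export
sim_step <- function(state, params, irradiance, dt = params$dt) {
  stopifnot(dt > 0)
  r <- model_rates(state, params, irradiance)
  eaten <- r$ing * state$N * dt           # prey cells mL-1 removed
  s <- state
  s$C <- max(0, state$C + (r$mu_x * state$C) * dt - eaten)
  s$N <- max(0, state$N + (r$mu_y - r$mort) * state$N * dt)
  s$Q <- max(0, state$Q +
               (params$chl_retention * params$q_prey * r$ing -
                  (params$d0 + params$d1 * irradiance) * state$Q) * dt)
  dc <- if (r$mu_y > 0) 0 else r$net * dt
  s$c <- min(params$c_div, max(params$c_floor, state$c + dc))
  s$time <- state$time + dt
  s$cum_I <- state$cum_I + r$ing * dt
  s$cum_removed <- state$cum_removed + eaten
  s$cum_offered <- state$cum_offered + params$prey_carbon * eaten
  if (any(!is.finite(unlist(s[c("C", "N", "Q", "c")]))))
    stop("sim_step: non-finite state at t = ", state$time,
         " (C=", state$C, ", N=", state$N, ", Q=", state$Q,
         ", c=", state$c, ")")
  s
}

new_state <- function(C, N, Q, c) {
  list(C = C, N = N, Q = Q, c = c, time = 0,
       cum_I = 0, cum_removed = 0, cum_offered = 0)
}

# advance a state to absolute time `to` with fixed Euler steps
advance <- function(state, params, irr, to) {
  while (state$time < to - 1e-9) {
    dt <- min(params$dt, to - state$time)
    state <- sim_step(state, params, irr, dt)
  }
  state
}

snapshot <- function(state, culture_id, treatment_id, day, phase) {
  data.frame(culture_id = culture_id, treatment_id = treatment_id,
             day = day, phase = phase, C = state$C, N = state$N,
             Q = state$Q, c = state$c, cum_I = state$cum_I,
             cum_removed = state$cum_removed,
             cum_offered = state$cum_offered, stringsAsFactors = FALSE)
}

# ---- experiment designs -----------------------------------------------------

#' Simulate the starvation experiment
#'
#' Emulates the prey-depletion design: a well-fed culture at ~175 ciliates
#' mL-1 receives a saturating prey pulse (3.25e4 cells mL-1) at day 0, is
#' split into triplicates, and is then followed without further prey
#' additions; sampling on days 2, 5, 7, 9 and every 2 days thereafter until
#' `days` or until the ciliate density drops below 5 cells mL-1. Prey
#' monocultures run in parallel as growth controls, diluted on each
#' sampling day back to the prey density of the mixed cultures (phase
#' labels mark the pre-/post-dilution control rows). Triplicates share the
#' deterministic trajectory and differ only in measurement noise.
#'
#' @param params a [sim_params()] object.
#' @param irradiances umol photons m-2 s-1 (default `c(10, 40, 120)`).
#' @param days experiment horizon, days (default 13).
#' @param out_dir optional directory; when given, the observation tables
#'   and the truth ledger are also written as the CSV files documented in
#'   [io_formats] (plus `controls.csv` and `truth.csv`).
#' @return A list with `counts`, `control_counts`, `scint`, `fluor`,
#'   `dims`, `treatments` (observation data.frames), `truth` (ground-truth
#'   ledger per culture x interval), and `trajectories` (sampled true
#'   states).
#' @export
run_starvation <- function(params = sim_params(),
                           irradiances = c(10, 40, 120), days = 13,
                           out_dir = NULL) {
  set.seed(params$seed)
  sample_days <- sort(unique(c(2, 5, 7, 9, seq(9, days, by = 2), days)))
  sample_days <- sample_days[sample_days <= days]
  traj <- list(); ctrl <- list(); trt <- list()
  for (irr in irradiances) {
    tid <- sprintf("I%g_starve", irr)
    trt[[tid]] <- treatment(tid, irr, 0, params$light_hours,
                            params$prey_carbon, params$carbon_per_volume)
    st <- new_state(C = 3.25e4, N = 175, Q = params$chl_init,
                    c = params$c_init)
    cst <- new_state(C = 3.25e4, N = 0, Q = 0, c = params$c_floor)
    ctrl_id <- sprintf("CTRL_%s", tid)
    ctrl_on <- TRUE
    for (cu in sprintf("%s_r%d", tid, 1:3))
      traj[[length(traj) + 1L]] <- snapshot(st, cu, tid, 0, "none")
    ctrl[[length(ctrl) + 1L]] <-
      snapshot(cst, ctrl_id, tid, 0, "post_dilution")
    for (d in sample_days) {
      st <- advance(st, params, irr, d)
      cst <- advance(cst, params, irr, d)
      for (cu in sprintf("%s_r%d", tid, 1:3))
        traj[[length(traj) + 1L]] <- snapshot(st, cu, tid, d, "none")
      if (ctrl_on) {
        ctrl[[length(ctrl) + 1L]] <-
          snapshot(cst, ctrl_id, tid, d, "pre_dilution")
        # dilute the monoculture back to the mixed culture's prey density;
        # monocultures stop once the mixed cultures hold no measurable prey
        if (st$C >= 0.5) {
          cst$C <- st$C
          ctrl[[length(ctrl) + 1L]] <-
            snapshot(cst, ctrl_id, tid, d, "post_dilution")
        } else ctrl_on <- FALSE
      }
      if (st$N < 5) break
    }
  }
  finish_run(do.call(rbind, traj), do.call(rbind, ctrl),
             do.call(treatment_table, unname(trt)), params, out_dir)
}

#' Simulate the prey-acclimation experiment
#'
#' Emulates the daily-dilution design: for each irradiance x prey-density
#' treatment a source culture is held at 15 ciliates mL-1 and its target
#' prey density by a daily dilution operator (scale both populations by the
#' factor restoring the ciliate target, then add prey back up to the prey
#' target; if the ciliate density is below target no concentration is
#' possible and only prey are added). Days 1-2 acclimate the source
#' culture; at the end of day 2 it is split into triplicates which are
#' sampled daily, pre- and post-dilution, through day `days` (default 5).
#' Scintillation, fluorometry and dimension subsamples are taken on the
#' sampling days after day 2 (at the pre-dilution time). Prey monocultures
#' at each treatment serve as growth controls, diluted daily back to
#' target.
#'
#' @param params a [sim_params()] object.
#' @param irradiances umol photons m-2 s-1 (default `c(10, 40, 120)`).
#' @param prey_targets prey densities, cells mL-1 (default
#'   `c(5e3, 1e4, 4e4)`).
#' @param days experiment length, days (default 5).
#' @inheritParams run_starvation
#' @return As [run_starvation()].
#' @export
run_acclimation <- function(params = sim_params(),
                            irradiances = c(10, 40, 120),
                            prey_targets = c(5e3, 1e4, 4e4), days = 5,
                            out_dir = NULL) {
  set.seed(params$seed)
  stopifnot(all(prey_targets > 0), days >= 3)
  traj <- list(); ctrl <- list(); trt <- list()
  for (irr in irradiances) for (tgt in prey_targets) {
    tid <- sprintf("I%g_P%g", irr, tgt)
    trt[[tid]] <- treatment(tid, irr, tgt, params$light_hours,
                            params$prey_carbon, params$carbon_per_volume)
    reps <- sprintf("%s_r%d", tid, 1:3)
    st <- new_state(C = tgt, N = 15, Q = params$chl_init, c = params$c_init)
    cst <- new_state(C = tgt, N = 0, Q = 0, c = params$c_floor)
    ctrl_id <- sprintf("CTRL_%s", tid)
    ctrl[[length(ctrl) + 1L]] <-
      snapshot(cst, ctrl_id, tid, 0, "post_dilution")
    for (d in seq_len(days)) {
      st <- advance(st, params, irr, d)
      cst <- advance(cst, params, irr, d)
      who <- if (d <= 2) tid else reps
      for (cu in who)
        traj[[length(traj) + 1L]] <- snapshot(st, cu, tid, d, "pre_dilution")
      ctrl[[length(ctrl) + 1L]] <-
        snapshot(cst, ctrl_id, tid, d, "pre_dilution")
      if (d < days) {
        st <- dilute(st, 15, tgt)
        cst$C <- tgt
        who <- if (d < 2) tid else reps
        for (cu in who)
          traj[[length(traj) + 1L]] <-
            snapshot(st, cu, tid, d, "post_dilution")
        ctrl[[length(ctrl) + 1L]] <-
          snapshot(cst, ctrl_id, tid, d, "post_dilution")
      }
    }
  }
  finish_run(do.call(rbind, traj), do.call(rbind, ctrl),
             do.call(treatment_table, unname(trt)), params, out_dir)
}

# the daily dilution operator of the acclimation protocol
dilute <- function(state, N_target, C_target) {
  f <- if (state$N >= N_target * (1 - 1e-9)) N_target / state$N else {
    warning("dilute: ciliate density ", signif(state$N, 4),
            " below target ", N_target, "; prey addition only")
    1
  }
  state$N <- state$N * f
  state$C <- max(state$C * f, C_target)
  state
}

# ---- observation layer ------------------------------------------------------

lnorm_noise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

# Poisson count of one sample; returns c(n, volume, density)
count_sample <- function(density, well_volume, max_wells, target, exact) {
  expected_one <- density * well_volume
  wells <- if (expected_one <= 0) 1
  else min(max_wells, max(1, ceiling(target / expected_one)))
  vol <- wells * well_volume
  if (exact) return(c(NA_real_, NA_real_, density))
  n <- stats::rpois(1, density * vol)
  c(n, vol, n / vol)
}

#' Generate observation tables from a true trajectory
#'
#' The forward measurement models: ciliate counts are Poisson draws over 2
#' mL wells repeated until ~200 individuals are expected (up to 12 wells);
#' prey counts are Poisson over cytometry volumes; light-vial DPM are
#' generated by inverting the uptake equation from the true photosynthetic
#' rate on top of a dark-vial background, with lognormal counting error;
#' fluorometry readings are `picked_cells * Q` (or bulk `C * volume *
#' q_prey` for prey) with lognormal error; cell dimensions are drawn around
#' the true biovolume (prolate spheroid at the configured aspect ratio)
#' with normal error on each axis. With `noise = "none"` every reading is
#' the exact forward value and counts report true densities, so pipeline
#' inversion reproduces the truth to float tolerance.
#'
#' @param trajectory a snapshot `data.frame` (internal format of the run
#'   functions).
#' @param params a [sim_params()] object.
#' @param rate_days days on which scintillation / fluorometry / dimension
#'   subsamples are taken.
#' @param species `"ciliate"` or `"prey"`-only (controls).
#' @return A list of observation `data.frame`s (`counts`, `scint`, `fluor`,
#'   `dims`).
#' @keywords internal
observe_trajectory <- function(trajectory, params, rate_days,
                               species = "ciliate") {
  exact <- params$noise == "none"
  counts <- list(); scint <- list(); fluor <- list(); dims <- list()
  for (i in seq_len(nrow(trajectory))) {
    row <- trajectory[i, ]
    if (species == "ciliate") {
      cs <- count_sample(row$N, 2, 12, 200, exact)
      counts[[length(counts) + 1L]] <- data.frame(
        culture_id = row$culture_id, treatment_id = row$treatment_id,
        day = row$day, species = "ciliate", density = cs[3],
        n_counted = cs[1], volume_counted = cs[2], phase = row$phase,
        stringsAsFactors = FALSE)
    }
    ps <- count_sample(row$C, 0.1, 10, 300, exact)
    counts[[length(counts) + 1L]] <- data.frame(
      culture_id = row$culture_id, treatment_id = row$treatment_id,
      day = row$day, species = "prey", density = ps[3],
      n_counted = ps[1], volume_counted = ps[2], phase = row$phase,
      stringsAsFactors = FALSE)

    is_rate_day <- any(abs(row$day - rate_days) < 1e-9) &&
      row$phase %in% c("pre_dilution", "none") && row$day > 0
    if (!is_rate_day) next
    if (species == "ciliate") {
      # scintillation pair: forward model of the uptake equation
      p_true <- row$c_P / params$light_hours   # pg C cell-1 h-1 in light
      d_net <- p_true * params$picked_cells * params$sa_per_ml *
        params$vial_volume * params$incubation_h / (params$dic * 1e6)
      scale <- params$counted_volume / params$vial_volume
      noise2 <- lnorm_noise(2, params$dpm_cv)
      scint[[length(scint) + 1L]] <- data.frame(
        culture_id = rep(row$culture_id, 2), day = rep(row$day, 2),
        vial = c("light", "dark"),
        dpm = c((params$dark_dpm + d_net) * scale * noise2[1],
                params$dark_dpm * scale * noise2[2]),
        n_cells = params$picked_cells, incubation_h = params$incubation_h,
        sa_dpm = params$sa_per_ml * params$sa_volume *
          lnorm_noise(1, if (exact) 0 else params$dpm_cv / 2),
        sa_volume = params$sa_volume,
        counted_volume = params$counted_volume,
        vial_volume = params$vial_volume, dic = params$dic,
        stringsAsFactors = FALSE)
      fluor[[length(fluor) + 1L]] <- data.frame(
        culture_id = row$culture_id, day = row$day,
        n_cells = params$picked_cells,
        reading = params$picked_cells * row$Q *
          lnorm_noise(1, params$fluor_cv),
        volume_filtered = NA_real_, stringsAsFactors = FALSE)
      bv <- row$c / params$carbon_per_volume
      w_true <- (6 * bv / (pi * params$aspect))^(1 / 3)
      nd <- params$n_dims
      werr <- 1 + stats::rnorm(nd, 0, params$dim_cv)
      lerr <- 1 + stats::rnorm(nd, 0, params$dim_cv)
      dims[[length(dims) + 1L]] <- data.frame(
        culture_id = rep(row$culture_id, nd), day = rep(row$day, nd),
        length = params$aspect * w_true * pmax(lerr, 0.5),
        width = w_true * pmax(werr, 0.5),
        shape = "ellipsoid", stringsAsFactors = FALSE)
    } else {
      # bulk prey chl sample from the control monoculture
      fluor[[length(fluor) + 1L]] <- data.frame(
        culture_id = row$culture_id, day = row$day, n_cells = 0L,
        reading = row$C * params$fluor_volume * params$q_prey *
          lnorm_noise(1, params$fluor_cv),
        volume_filtered = params$fluor_volume, stringsAsFactors = FALSE)
    }
  }
  list(counts = if (length(counts)) do.call(rbind, counts),
       scint = if (length(scint)) do.call(rbind, scint),
       fluor = if (length(fluor)) do.call(rbind, fluor),
       dims = if (length(dims)) do.call(rbind, dims))
}

# attach true photosynthetic rate, build the observation files and the
# ground-truth ledger, optionally write everything to out_dir
finish_run <- function(traj, ctrl, treatments, params, out_dir) {
  # true per-cell photosynthesis at each snapshot
  pb_irr <- function(irr) params$PBmax *
    (1 - exp(-params$alpha * irr / params$PBmax)) *
    exp(-params$beta_inhib * irr)
  irr_of <- treatments$irradiance[match(traj$treatment_id,
                                        treatments$treatment_id)]
  traj$c_P <- pb_irr(irr_of) * traj$Q * exp(-params$k_s * traj$Q)

  rate_days <- sort(unique(traj$day[traj$day > 0]))
  if (any(traj$phase == "pre_dilution"))  # acclimation: rate days are 3..5
    rate_days <- rate_days[rate_days > 2]

  obs <- observe_trajectory(traj, params, rate_days, "ciliate")
  cobs <- observe_trajectory(ctrl, params, rate_days, "prey")

  truth <- truth_ledger(traj, treatments, params)
  out <- list(counts = obs$counts, control_counts = cobs$counts,
              scint = obs$scint, fluor = obs$fluor, dims = obs$dims,
              treatments = treatments, truth = truth,
              trajectories = traj)
  if (!is.null(out_dir)) write_sim(out, out_dir)
  out
}

# ground truth per culture x interval, mirroring the pipeline's records
truth_ledger <- function(traj, treatments, params) {
  rows <- list()
  for (cu in unique(traj$culture_id)) {
    one <- traj[traj$culture_id == cu, , drop = FALSE]
    tid <- one$treatment_id[1]
    irr <- treatments$irradiance[treatments$treatment_id == tid]
    mu_x <- params$mu_max_x * (1 - exp(-irr / params$Ik_x))
    dilcyc <- any(one$phase == "pre_dilution")
    if (dilcyc) {
      starts <- one[one$phase == "post_dilution", , drop = FALSE]
      ends <- one[one$phase == "pre_dilution", , drop = FALSE]
      pairs <- lapply(seq_len(nrow(starts)), function(j) {
        nxt <- which(ends$day > starts$day[j] + 1e-9)
        if (length(nxt) == 0L) return(NULL)
        list(s = starts[j, ], e = ends[nxt[1], ])
      })
      pairs <- Filter(Negate(is.null), pairs)
    } else {
      one <- one[order(one$day), , drop = FALSE]
      pairs <- if (nrow(one) >= 2L)
        lapply(seq_len(nrow(one) - 1L),
               function(j) list(s = one[j, ], e = one[j + 1L, ])) else list()
    }
    for (pr in pairs) {
      t <- pr$e$day - pr$s$day
      I_true <- (pr$e$cum_I - pr$s$cum_I) / t
      mu_y <- if (pr$s$N > 0 && pr$e$N > 0) log(pr$e$N / pr$s$N) / t
      else NA_real_
      C_y <- pr$e$c
      C_I <- params$prey_carbon * I_true
      P <- pr$e$c_P
      rows[[length(rows) + 1L]] <- data.frame(
        culture_id = cu, treatment_id = tid, t0 = pr$s$day, t1 = pr$e$day,
        mu_y = mu_y, mu_x = mu_x, I = I_true, P_daily = P,
        chl_cell = pr$e$Q, Bv = pr$e$c / params$carbon_per_volume,
        C_y = C_y, mu_yC = mu_y * C_y, C_I = C_I,
        GGE = if (C_I > 0) mu_y * C_y / C_I else NA_real_,
        photo_pct = if (P + max(C_I, 0) > 0)
          100 * P / (P + max(C_I, 0)) else NA_real_,
        removed_cells = pr$e$cum_removed - pr$s$cum_removed,
        offered_carbon = pr$e$cum_offered - pr$s$cum_offered,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Write a simulated experiment to CSV files
#'
#' Emits `counts.csv` (mixed cultures), `controls.csv` (prey monocultures),
#' `scint.csv`, `fluor.csv`, `dims.csv`, `treatments.csv` and `truth.csv`
#' into `dir`.
#'
#' @param sim a list as returned by [run_starvation()] /
#'   [run_acclimation()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(df, name) utils::write.csv(
    df, file.path(dir, name), row.names = FALSE, quote = FALSE, na = "")
  wr(sim$counts, "counts.csv")
  wr(sim$control_counts, "controls.csv")
  wr(sim$scint, "scint.csv")
  wr(sim$fluor, "fluor.csv")
  wr(sim$dims, "dims.csv")
  wr(as.data.frame(sim$treatments), "treatments.csv")
  wr(sim$truth, "truth.csv")
  invisible(dir)
}
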