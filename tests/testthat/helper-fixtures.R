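# Small in-code fixtures shared across test files.

default_treatment <- function(id = "T1", irradiance = 40,
                              prey_target = 4e4, ...) {
  treatment(id, irradiance, prey_target, ...)
}

write_fixture <- function(lines, name) {
  path <- file.path(withr::local_tempdir(.local_envir = parent.frame()),
                    name)
  writeLines(lines, path)
  path
}

counts_fixture <- function() {
  c("culture_id,treatment_id,day,species,density,n_counted,volume_counted,phase",
    "A,T1,0,ciliate,100,200,2,none",
    "A,T1,0,prey,40000,400,0.01,none",
    "A,T1,1,ciliate,150,300,2,none")
}

scint_fixture <- function() {
  c("culture_id,day,vial,dpm,n_cells,incubation_h,sa_dpm,sa_volume,counted_volume,vial_volume,dic",
    "A,3,light,1200,20,3,222000,0.1,1.9,2,24",
    "A,3,dark,80,20,3,222000,0.1,1.9,2,24")
}

# one (or, with vector overrides, many) scintillation pairs as a data.frame
scint_pair <- function(...) {
  base <- list(
    culture_id = "A", day = 3, dpm_light = 1200, dpm_dark = 80,
    n_cells = 20L, incubation_h = 3, sa_dpm = 222000, sa_volume = 0.1,
    counted_volume = 1.9, vial_volume = 2, dic = 24)
  base <- utils::modifyList(base, list(...))
  do.call(data.frame, c(base, stringsAsFactors = FALSE))
}

# deterministic forward grazing model: prey grow at k and are removed at
# constant per-capita clearance Fstar by grazers growing at mu; used as the
# independent oracle for the clearance/ingestion estimator
frost_oracle <- function(C0, N0, k, Fstar, mu, t_end, dt = 0.001) {
  C <- C0; N <- N0; eaten_per_grazer <- 0; t <- 0
  steps <- round(t_end / dt)
  for (i in seq_len(steps)) {
    ing <- Fstar * C                 # prey grazer-1 d-1
    C <- C + (k * C - ing * N) * dt
    eaten_per_grazer <- eaten_per_grazer + ing * dt
    N <- N * (1 + mu * dt)
    t <- t + dt
  }
  list(C1 = C, N1 = N, I_mean = eaten_per_grazer / t_end)
}
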