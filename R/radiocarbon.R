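#' Specific activity of the incubation medium
#'
#' The tracer activity per millilitre of medium, measured on a small
#' subsample (100 uL by default) drawn from the incubated vial before
#' acidification: `SA_v = sa_dpm / sa_volume`.
#'
#' @param sa_dpm activity of the subsample, DPM (> 0). Vectorised.
#' @param sa_volume subsample volume, mL (> 0).
#' @return Specific activity, DPM mL-1.
#' @export
specific_activity <- function(sa_dpm, sa_volume) {
  if (any(!is.finite(sa_dpm) | sa_dpm <= 0))
    stop("specific_activity: sa_dpm must be > 0")
  if (any(!is.finite(sa_volume) | sa_volume <= 0))
    stop("specific_activity: sa_volume must be > 0 (mL)")
  sa_dpm / sa_volume
}

#' Hourly cellular inorganic carbon uptake from a light/dark vial pair
#'
#' The single-cell 14C method: picked cells are incubated with NaH14CO3 in a
#' light and a dark vial; the light-minus-dark labelled carbon, scaled by
#' the medium's dissolved inorganic carbon and specific activity, gives the
#' carbon fixed per cell per hour:
#'
#' `p = ((Dl* - Dd*) / N) * C_m * 1e6 / (SA_v * vial_volume * t)`
#'
#' where `Dl*`, `Dd*` are vial-total DPM, `N` the number of picked cells,
#' `C_m` the dissolved inorganic carbon (ug C mL-1), `SA_v` the per-mL
#' specific activity ([specific_activity()]), `t` the incubation time in
#' hours, and `1e6` converts ug to pg. Because a subsample is removed for
#' the specific-activity measurement before acidification, the counted DPM
#' cover only `counted_volume` of the `vial_volume` of medium; the measured
#' values are scaled to vial totals by `vial_volume / counted_volume`
#' (2.0/1.9 by default). Setting `counted_volume = vial_volume` in the input
#' recovers a no-correction mode.
#'
#' A dark reading above the light reading yields a negative rate; under the
#' default policy `"keep_negative"` it is retained (and flagged by the
#' caller) — clamping silently would bias low-rate treatments upward —
#' while `"clamp_zero"` truncates at 0.
#'
#' @param pairs a paired scintillation `data.frame` as returned by
#'   [read_scintillation()].
#' @param negative_uptake_policy `"keep_negative"` (default) or
#'   `"clamp_zero"`.
#' @return `pairs` with columns `p_hourly` (pg C cell-1 h-1) and `flags`
#'   appended; negative light-minus-dark differences are flagged
#'   `negative_uptake`.
#' @export
uptake_hourly <- function(pairs,
                          negative_uptake_policy =
                            c("keep_negative", "clamp_zero")) {
  negative_uptake_policy <- match.arg(negative_uptake_policy)
  vc <- pairs$vial_volume / pairs$counted_volume
  d_net <- (pairs$dpm_light - pairs$dpm_dark) * vc
  sa_v <- specific_activity(pairs$sa_dpm, pairs$sa_volume)
  p <- (d_net / pairs$n_cells) * pairs$dic * 1e6 /
    (sa_v * pairs$vial_volume * pairs$incubation_h)
  out <- pairs
  if (is.null(out$flags)) out$flags <- ""
  out$flags <- add_flag(out$flags, is.finite(p) & p < 0, "negative_uptake")
  if (negative_uptake_policy == "clamp_zero") p <- pmax(p, 0)
  out$p_hourly <- p
  out
}

#' Daily from hourly carbon uptake
#'
#' Daily carbon incorporation is the hourly rate times the duration of the
#' daily light period: `P = light_hours * p` (default 14 h).
#'
#' @param p_hourly hourly uptake, pg C cell-1 h-1. Vectorised.
#' @param treatment a [treatment()] row supplying `light_hours`.
#' @return Daily uptake, pg C cell-1 d-1.
#' @export
uptake_daily <- function(p_hourly, treatment) {
  treatment$light_hours * p_hourly
}

#' Per-cell chlorophyll-a content
#'
#' For picked-cell samples (`n_cells > 0`, 20 cells by default) per-cell
#' chl-a is `reading / n_cells`. For bulk filter samples (`n_cells = 0`) a
#' paired cell density is required and per-cell chl-a is
#' `reading / (density * volume_filtered)`.
#'
#' @param samples a fluorometry `data.frame` ([read_fluorometry()]).
#' @param density cell density, cells mL-1, required (recycled) for bulk
#'   rows; ignored for picked-cell rows.
#' @return `samples` with a `chl_cell` column (pg chl-a cell-1) appended.
#' @export
chl_per_cell <- function(samples, density = NULL) {
  picked <- samples$n_cells > 0
  out <- samples
  out$chl_cell <- NA_real_
  out$chl_cell[picked] <- samples$reading[picked] / samples$n_cells[picked]
  if (any(!picked)) {
    if (is.null(density))
      stop("chl_per_cell: bulk samples (n_cells = 0) need a paired density")
    density <- rep_len(density, nrow(samples))
    cells <- density[!picked] * samples$volume_filtered[!picked]
    if (any(!is.finite(cells) | cells <= 0))
      stop("chl_per_cell: bulk sample with non-positive cell total")
    out$chl_cell[!picked] <- samples$reading[!picked] / cells
  }
  out
}

#' Chlorophyll-specific carbon uptake
#'
#' `P_daily / chl`, the carbon fixed per unit chl-a per day — a proxy for
#' how efficiently the sequestered chloroplasts are operating.
#'
#' @param P_daily daily cellular uptake, pg C cell-1 d-1. Vectorised.
#' @param chl per-cell chl-a, pg cell-1.
#' @return pg C (pg chl-a)-1 d-1; `NA` where `chl` is not positive.
#' @export
chl_specific_uptake <- function(P_daily, chl) {
  ifelse(is.finite(chl) & chl > 0, P_daily / chl, NA_real_)
}
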