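#' Exponential growth (or mortality) rate
#'
#' `mu = (ln N1 - ln N0) / t`, assuming exponential change over the
#' interval. Negative values are valid and denote net mortality. A
#' non-positive density makes the rate undefined and returns `NA` (the
#' caller decides how to flag it) rather than raising.
#'
#' @param N0,N1 densities at the start and end of the interval, cells mL-1.
#' @param t interval length, days (> 0). Vectorised.
#' @return Rate, d-1; `NA` where a density is non-positive.
#' @examples
#' growth_rate(100, 200, 1)  # ln 2
#' @export
growth_rate <- function(N0, N1, t) {
  if (any(!is.finite(t) | t <= 0)) stop("growth_rate: t must be > 0 (days)")
  out <- ifelse(is.finite(N0) & is.finite(N1) & N0 > 0 & N1 > 0,
                (log(N1) - log(N0)) / t, NA_real_)
  out
}

#' Logarithmic mean density over an interval
#'
#' `(X1 - X0) / ln(X1 / X0)`, the time average of an exponentially changing
#' population — the mean density a grazer actually experienced over the
#' interval. This is the grazer-averaging refinement of the classic
#' clearance-rate calculation. The limit `X1 -> X0` returns `X0`; the result
#' always lies between `min(X0, X1)` and `max(X0, X1)`.
#'
#' @param X0,X1 densities at the interval endpoints, cells mL-1 (> 0).
#'   Vectorised.
#' @return Mean density, cells mL-1; `NA` where an input is non-positive.
#' @export
frost_mean_density <- function(X0, X1) {
  ok <- is.finite(X0) & is.finite(X1) & X0 > 0 & X1 > 0
  # relative tolerance for the equal-endpoint limit
  near <- ok & abs(X1 - X0) <= 1e-12 * pmax(X0, X1)
  out <- rep(NA_real_, length(ok))
  out[near] <- X0[near]
  gen <- ok & !near
  out[gen] <- (X1[gen] - X0[gen]) / (log(X1[gen]) - log(X0[gen]))
  out
}

#' Grazing coefficient
#'
#' The exponential prey-loss rate attributable to grazing:
#' `g = k_control - (ln C1 - ln C0) / t`, where `k_control` is the prey
#' growth rate measured in the paired grazer-free monoculture over the same
#' interval. `g` may come out negative (prey in the grazed culture outgrew
#' the control); such values are retained for the caller to flag.
#'
#' @param k_control prey growth rate in the control monoculture, d-1.
#' @param C0,C1 prey densities in the grazed culture at the interval
#'   endpoints, cells mL-1 (> 0).
#' @param t interval length, days (> 0). Vectorised.
#' @return Grazing coefficient, d-1; `NA` where a density is non-positive or
#'   `k_control` is missing.
#' @export
grazing_coefficient <- function(k_control, C0, C1, t) {
  if (any(!is.finite(t) | t <= 0))
    stop("grazing_coefficient: t must be > 0 (days)")
  ifelse(is.finite(k_control) & is.finite(C0) & is.finite(C1) &
           C0 > 0 & C1 > 0,
         k_control - (log(C1) - log(C0)) / t, NA_real_)
}

# append a flag token to a comma-separated flag string
add_flag <- function(flags, where, token) {
  flags[where] <- ifelse(flags[where] == "", token,
                         paste(flags[where], token, sep = ","))
  flags
}

#' Clearance and ingestion rates for a set of intervals
#'
#' Implements the batch-culture grazing-rate calculation: the grazing
#' coefficient `g` is the control prey growth rate minus the net prey rate
#' in the grazed culture; the clearance rate is `F = g / Nbar` with `Nbar`
#' the logarithmic mean grazer density over the interval (the
#' grazer-averaging modification); the ingestion rate is `I = F * Cbar` with
#' `Cbar` the logarithmic mean prey density.
#'
#' Prey depleted below detection by the end of an interval (`C1 = 0`, as
#' happens within 24 h in the low prey-density treatments) is substituted by
#' `detection_limit` and the record flagged `depleted_prey`; the log
#' formulas require positivity, and the flag keeps the substitution
#' auditable. Negative `g` (prey outgrew its control) is flagged
#' `negative_grazing`; under the default policy `"flag_zero"` the ingestion
#' rate is reported as 0 while the raw `g` is kept, under `"keep_negative"`
#' `F` and `I` keep their (negative) values.
#'
#' @param intervals a `data.frame` as built by [build_intervals()], with
#'   columns `culture_id, treatment_id, t0, t1, N0, N1, C0, C1, k_control`
#'   (and optionally `flags`).
#' @param detection_limit substitution density for depleted prey, cells mL-1
#'   (default 0.5, one cell per largest counted volume).
#' @param negative_grazing_policy `"flag_zero"` (default) or
#'   `"keep_negative"`.
#' @return `intervals` with columns `mu_y` (grazer growth, d-1), `g`, `F`
#'   (mL grazer-1 d-1), `I` (prey grazer-1 d-1) and `flags` appended.
#' @export
clearance_ingestion <- function(intervals, detection_limit = 0.5,
                                negative_grazing_policy =
                                  c("flag_zero", "keep_negative")) {
  negative_grazing_policy <- match.arg(negative_grazing_policy)
  iv <- intervals
  if (is.null(iv$flags)) iv$flags <- ""
  stopifnot(all(iv$t1 > iv$t0))
  t <- iv$t1 - iv$t0

  C1 <- iv$C1
  depleted <- is.finite(C1) & C1 < detection_limit & is.finite(iv$C0) &
    iv$C0 > 0
  C1[depleted] <- detection_limit
  iv$flags <- add_flag(iv$flags, depleted, "depleted_prey")

  iv$mu_y <- growth_rate(iv$N0, iv$N1, t)
  iv$flags <- add_flag(iv$flags, is.na(iv$mu_y), "undefined_growth")

  no_control <- !is.finite(iv$k_control)
  iv$flags <- add_flag(iv$flags, no_control &
                         is.finite(iv$C0) & iv$C0 > 0, "missing_control")

  iv$g <- grazing_coefficient(iv$k_control, iv$C0, C1, t)
  Nbar <- frost_mean_density(iv$N0, iv$N1)
  Cbar <- frost_mean_density(iv$C0, C1)
  iv$F <- iv$g / Nbar
  iv$I <- iv$F * Cbar

  neg <- is.finite(iv$g) & iv$g < 0
  iv$flags <- add_flag(iv$flags, neg, "negative_grazing")
  if (negative_grazing_policy == "flag_zero") {
    iv$F[neg] <- 0
    iv$I[neg] <- 0
  }
  iv
}

#' Build analysis intervals from count observations
#'
#' Turns per-culture count time series into the intervals over which rates
#' are computed, and attaches the prey control growth rate `k_control` from
#' the paired grazer-free monoculture over the same window.
#'
#' Two protocols are recognised. Under the daily-dilution (acclimation)
#' protocol, counts carry `post_dilution` / `pre_dilution` phase labels and
#' each interval runs from the post-dilution observation on one sampling day
#' to the pre-dilution observation on the next, so growth is measured within
#' a dilution cycle and needs no dilution correction. Without phase labels
#' (starvation protocol), consecutive sampling days form the intervals.
#' Controls are matched on `treatment_id` and are assumed to follow the same
#' phase convention; with several control cultures per treatment their
#' growth rates are averaged.
#'
#' @param counts a counts `data.frame` ([read_counts()]) for the mixed
#'   (grazed) cultures; must contain `ciliate` rows, `prey` rows optional
#'   per day.
#' @param controls a counts `data.frame` for prey monocultures (species
#'   `"prey"`), or `NULL` (then `k_control` is `NA` everywhere and ingestion
#'   is skipped downstream).
#' @param mode `"auto"` (default: dilution cycles when phase labels are
#'   present), `"dilution_cycle"`, or `"consecutive_samples"`.
#' @return A `data.frame` with one row per culture x interval: `culture_id,
#'   treatment_id, t0, t1, N0, N1, C0, C1, k_control, flags`.
#' @export
build_intervals <- function(counts, controls = NULL,
                            mode = c("auto", "dilution_cycle",
                                     "consecutive_samples")) {
  mode <- match.arg(mode)
  has_phase <- any(counts$phase %in% c("pre_dilution", "post_dilution"))
  if (mode == "auto")
    mode <- if (has_phase) "dilution_cycle" else "consecutive_samples"
  if (mode == "dilution_cycle" && !has_phase)
    stop("build_intervals: dilution_cycle mode requires phase labels")

  # density lookup for one culture's species at (day, phase)
  pick <- function(df, sp, day, phase) {
    rows <- df[df$species == sp & abs(df$day - day) < 1e-9, , drop = FALSE]
    # disambiguate pre-/post-dilution duplicates whenever labels are present
    if (nrow(rows) > 1L && any(rows$phase == phase))
      rows <- rows[rows$phase == phase, , drop = FALSE]
    if (nrow(rows) == 0L) return(NA_real_)
    mean(rows$density)
  }

  control_k <- function(treatment_id, t0, t1) {
    if (is.null(controls)) return(NA_real_)
    cc <- controls[controls$treatment_id == treatment_id &
                     controls$species == "prey", , drop = FALSE]
    if (nrow(cc) == 0L) return(NA_real_)
    ks <- vapply(split(cc, cc$culture_id), function(one) {
      c0 <- pick(one, "prey", t0, "post_dilution")
      c1 <- pick(one, "prey", t1, "pre_dilution")
      growth_rate(c0, c1, t1 - t0)
    }, numeric(1))
    if (all(is.na(ks))) NA_real_ else mean(ks, na.rm = TRUE)
  }

  out <- list()
  for (cu in unique(counts$culture_id)) {
    one <- counts[counts$culture_id == cu, , drop = FALSE]
    tid <- one$treatment_id[1]
    cil <- one[one$species == "ciliate", , drop = FALSE]
    days <- sort(unique(cil$day))
    if (mode == "dilution_cycle") {
      starts <- sort(unique(cil$day[cil$phase == "post_dilution"]))
      ends <- sort(unique(cil$day[cil$phase == "pre_dilution"]))
      pairs <- lapply(starts, function(d) {
        nxt <- ends[ends > d + 1e-9]
        if (length(nxt) == 0L) return(NULL)
        c(d, nxt[1])
      })
      pairs <- Filter(Negate(is.null), pairs)
    } else {
      pairs <- if (length(days) >= 2L)
        lapply(seq_len(length(days) - 1L),
               function(i) c(days[i], days[i + 1L])) else list()
    }
    for (p in pairs) {
      t0 <- p[1]; t1 <- p[2]
      out[[length(out) + 1L]] <- data.frame(
        culture_id = cu, treatment_id = tid, t0 = t0, t1 = t1,
        N0 = pick(one, "ciliate", t0, "post_dilution"),
        N1 = pick(one, "ciliate", t1, "pre_dilution"),
        C0 = pick(one, "prey", t0, "post_dilution"),
        C1 = pick(one, "prey", t1, "pre_dilution"),
        k_control = control_k(tid, t0, t1),
        flags = "", stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L)
    return(data.frame(culture_id = character(), treatment_id = character(),
                      t0 = numeric(), t1 = numeric(), N0 = numeric(),
                      N1 = numeric(), C0 = numeric(), C1 = numeric(),
                      k_control = numeric(), flags = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}
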