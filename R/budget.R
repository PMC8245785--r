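#' Ingested carbon
#'
#' Daily carbon intake from phagotrophy: `C_I = I * prey_carbon`, with the
#' default 10 pg C per ingested prey cell.
#'
#' @param I ingestion rate, prey grazer-1 d-1 (>= 0). Vectorised.
#' @param treatment a [treatment()] row supplying `prey_carbon`.
#' @return Ingested carbon, pg C cell-1 d-1.
#' @export
ingested_carbon <- function(I, treatment) {
  treatment$prey_carbon * I
}

#' Carbon-specific growth rate
#'
#' `mu_yC = mu_y * C_y`, the growth rate expressed as new biomass carbon
#' per cell per day; its sign follows `mu_y` (negative over mortality
#' intervals).
#'
#' @param mu_y growth rate, d-1. Vectorised.
#' @param C_y cell carbon content, pg C cell-1 (> 0).
#' @return pg C cell-1 d-1.
#' @export
carbon_specific_growth <- function(mu_y, C_y) {
  mu_y * C_y
}

#' Gross growth efficiency
#'
#' `GGE = mu_yC / C_I`: the fraction of ingested carbon converted into new
#' grazer biomass. Values above 1 are legal and are never clamped — a
#' kleptoplastidic grazer supplements ingestion with photosynthesis, and
#' efficiencies up to ~1.1 are observed. `C_I = 0` makes the ratio
#' undefined (`NA`), not zero or infinite.
#'
#' @param mu_yC carbon-specific growth, pg C cell-1 d-1. Vectorised.
#' @param C_I ingested carbon, pg C cell-1 d-1.
#' @return Dimensionless efficiency; `NA` where `C_I` is not positive.
#' @export
gge <- function(mu_yC, C_I) {
  ifelse(is.finite(C_I) & C_I > 0, mu_yC / C_I, NA_real_)
}

#' Partition acquired carbon between photosynthesis and ingestion
#'
#' The two inputs to the carbon budget are inorganic uptake `P` and
#' ingested carbon `C_I`; their percentage shares are
#' `photo_pct = 100 * P / (P + C_I)` and `ingest_pct = 100 - photo_pct`.
#' Both must be non-negative and not both zero, otherwise the shares are
#' undefined (`NA`).
#'
#' @param P_daily daily inorganic uptake, pg C cell-1 d-1 (>= 0).
#'   Vectorised.
#' @param C_I ingested carbon, pg C cell-1 d-1 (>= 0).
#' @return A `data.frame` with columns `photo_pct` and `ingest_pct`, summing
#'   to 100 wherever defined.
#' @export
partition <- function(P_daily, C_I) {
  ok <- is.finite(P_daily) & is.finite(C_I) & P_daily >= 0 & C_I >= 0 &
    (P_daily + C_I) > 0
  photo <- ifelse(ok, 100 * P_daily / (P_daily + C_I), NA_real_)
  data.frame(photo_pct = photo, ingest_pct = 100 - photo)
}

# single value per culture x sampling day, or error on conflicting duplicates
lookup_day <- function(df, value_col, culture, day, label) {
  rows <- which(df$culture_id == culture & abs(df$day - day) < 1e-9)
  if (length(rows) == 0L) return(NA_real_)
  vals <- df[[value_col]][rows]
  if (length(vals) > 1L && any(abs(vals - vals[1]) > 1e-9))
    stop("assemble_rates: conflicting duplicate ", label, " for ",
         culture, " day ", day)
  vals[1]
}

#' Assemble the carbon budget per culture x interval
#'
#' Joins the grazing/growth interval rates with per-sampling-day uptake,
#' chlorophyll, and biovolume measurements, and derives the budget
#' quantities: `C_y` (cell carbon), `mu_yC`, `C_I`, `GGE`, and the percent
#' partitioning of acquired carbon. Point measurements (scintillation,
#' fluorometry) are attached to the interval ending on their sampling day;
#' biovolume is averaged over all dimension rows with `t0 < day <= t1`.
#' Missing components leave dependent fields `NA` rather than zero, and all
#' flags are propagated into a comma-separated `flags` column.
#'
#' @param intervals output of [clearance_ingestion()] (columns `mu_y, g, F,
#'   I, flags`, plus the interval keys).
#' @param uptake output of [uptake_hourly()] or `NULL`.
#' @param fluor output of [chl_per_cell()] (ciliate picked-cell rows) or
#'   `NULL`.
#' @param dims a dimensions `data.frame` ([read_dimensions()]) or `NULL`.
#' @param treatments a treatment table ([treatment_table()] or
#'   [read_treatments()]).
#' @return A rate-record `data.frame` with the columns documented in
#'   [io_formats] (`rates.csv`), one row per culture x interval.
#' @export
assemble_rates <- function(intervals, uptake = NULL, fluor = NULL,
                           dims = NULL, treatments) {
  n <- nrow(intervals)
  rec <- data.frame(
    culture_id = intervals$culture_id,
    treatment_id = intervals$treatment_id,
    t0 = as.numeric(intervals$t0), t1 = as.numeric(intervals$t1),
    mu_y = intervals$mu_y, mu_x = intervals$k_control,
    g = intervals$g, F = intervals$F, I = intervals$I,
    P_daily = NA_real_, chl_cell = NA_real_, P_chl = NA_real_,
    Bv = NA_real_, C_y = NA_real_, mu_yC = NA_real_, C_I = NA_real_,
    GGE = NA_real_, photo_pct = NA_real_,
    flags = if (is.null(intervals$flags)) rep("", n) else intervals$flags,
    stringsAsFactors = FALSE
  )
  for (i in seq_len(n)) {
    tr <- treatment_row(treatments, rec$treatment_id[i])
    cu <- rec$culture_id[i]
    if (!is.null(uptake)) {
      p <- lookup_day(uptake, "p_hourly", cu, rec$t1[i], "scintillation")
      rec$P_daily[i] <- uptake_daily(p, tr)
      if (is.finite(p) && p < 0)
        rec$flags[i] <- paste0(rec$flags[i],
                               if (nzchar(rec$flags[i])) ",",
                               "negative_uptake")
    }
    if (!is.null(fluor))
      rec$chl_cell[i] <- lookup_day(fluor, "chl_cell", cu, rec$t1[i],
                                    "fluorometry")
    rec$P_chl[i] <- chl_specific_uptake(rec$P_daily[i], rec$chl_cell[i])
    if (!is.null(dims)) {
      dd <- dims[dims$culture_id == cu & dims$day > rec$t0[i] + 1e-9 &
                   dims$day <= rec$t1[i] + 1e-9, , drop = FALSE]
      if (nrow(dd) > 0L)
        rec$Bv[i] <- mean(biovolume(dd$length, dd$width, dd$shape))
    }
    if (is.finite(rec$Bv[i])) rec$C_y[i] <- ciliate_carbon(rec$Bv[i], tr)
    rec$mu_yC[i] <- carbon_specific_growth(rec$mu_y[i], rec$C_y[i])
    if (is.finite(rec$I[i])) rec$C_I[i] <- ingested_carbon(rec$I[i], tr)
    rec$GGE[i] <- gge(rec$mu_yC[i], rec$C_I[i])
    pp <- partition(rec$P_daily[i],
                    if (is.finite(rec$C_I[i])) max(rec$C_I[i], 0)
                    else NA_real_)
    rec$photo_pct[i] <- pp$photo_pct
  }
  rec
}

#' Summarise rate records by treatment and sampling day
#'
#' Group means with sample standard deviations (n - 1 denominator) and
#' group sizes, in long format — the form in which treatment x day results
#' are reported graphically as means +/- STD.
#'
#' @param records a rate-record `data.frame` ([assemble_rates()]).
#' @param fields character vector of numeric record columns to summarise
#'   (default: all rate and budget fields).
#' @return A long `data.frame`: `treatment_id, day, field, mean, std, n`
#'   (`day` is the interval's sampling day `t1`; `n` counts non-missing
#'   values).
#' @export
summarize_rates <- function(records,
                            fields = c("mu_y", "mu_x", "g", "F", "I",
                                       "P_daily", "chl_cell", "P_chl", "Bv",
                                       "C_y", "mu_yC", "C_I", "GGE",
                                       "photo_pct")) {
  stopifnot(nrow(records) > 0L)
  key <- interaction(records$treatment_id, records$t1, drop = TRUE)
  out <- list()
  for (k in levels(key)) {
    sub <- records[key == k, , drop = FALSE]
    for (f in fields) {
      v <- sub[[f]]
      v <- v[is.finite(v)]
      out[[length(out) + 1L]] <- data.frame(
        treatment_id = sub$treatment_id[1], day = sub$t1[1], field = f,
        mean = if (length(v)) mean(v) else NA_real_,
        std = if (length(v) > 1L) stats::sd(v) else NA_real_,
        n = length(v), stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}
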