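#' @name io_formats
#' @title Tabular formats of the carbon-budget pipeline
#'
#' @description
#' All interchange is plain CSV (RFC 4180, UTF-8, "." decimal). The pipeline
#' reads five input tables and writes one output table:
#'
#' * `counts.csv` — `culture_id,treatment_id,day,species,density,n_counted,volume_counted,phase`
#'   with `species` in `{ciliate, prey}` and `phase` in
#'   `{pre_dilution, post_dilution, none}`. Densities are cells mL-1.
#' * `scint.csv` — `culture_id,day,vial,dpm,n_cells,incubation_h,sa_dpm,sa_volume,counted_volume,vial_volume,dic`
#'   with one row per vial (`vial` in `{light, dark}`); rows are paired on
#'   `(culture_id, day)` on read. An unpaired vial is a hard error: silently
#'   dropping a dark control would bias every uptake rate computed from the
#'   light vial.
#' * `fluor.csv` — `culture_id,day,n_cells,reading,volume_filtered`;
#'   `n_cells = 0` marks a bulk filter sample (prey), otherwise `reading` is
#'   total chl-a (pg) over `n_cells` picked cells.
#' * `dims.csv` — `culture_id,day,length,width,shape` with `shape` in
#'   `{sphere, ellipsoid}`; rows with `length < width` are swapped with a
#'   warning (transcription-order slips are common; the shape math requires
#'   `length >= width`).
#' * `treatments.csv` — the columns of [treatment()].
#' * `rates.csv` — one row per culture x interval, columns exactly as
#'   produced by [assemble_rates()]; written at full double precision so a
#'   write/read round trip is bit-identical.
#'
#' Every reader is total on its documented schema: a valid file never
#' raises, and every rejection message names the offending row number and
#' field.
NULL

# ---- generic helpers --------------------------------------------------------

read_csv_checked <- function(path, required, label) {
  if (!file.exists(path)) stop(label, ": file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L)
    stop(label, ": missing required column(s): ",
         paste(missing, collapse = ", "))
  df
}

# Accumulate row-numbered validation failures and raise once.
fail_rows <- function(problems, label) {
  if (length(problems) > 0L)
    stop(label, ": ", length(problems), " invalid row(s):\n  ",
         paste(problems, collapse = "\n  "))
  invisible(NULL)
}

chk <- function(ok, row, field, msg) {
  bad <- which(!(ok %in% TRUE))
  if (length(bad) == 0L) return(character(0))
  sprintf("row %d: %s: %s", row[bad], field, msg)
}

# ---- counts -----------------------------------------------------------------

#' Read a cell-count table
#'
#' Reads and validates density observations of ciliates and prey. When both
#' counting-effort fields are present the reported density must agree with
#' `n_counted / volume_counted` up to rounding of the reported value; within
#' one culture, days must be non-decreasing per species.
#'
#' @param path path to a `counts.csv` file (see [io_formats]).
#' @return A validated `data.frame` with the schema columns; `phase` defaults
#'   to `"none"` where empty.
#' @export
read_counts <- function(path) {
  df <- read_csv_checked(
    path,
    c("culture_id", "treatment_id", "day", "species", "density"),
    "read_counts"
  )
  if (!"n_counted" %in% names(df)) df$n_counted <- NA_real_
  if (!"volume_counted" %in% names(df)) df$volume_counted <- NA_real_
  if (!"phase" %in% names(df)) df$phase <- "none"
  df$phase[is.na(df$phase) | df$phase == ""] <- "none"
  for (cn in c("day", "density", "n_counted", "volume_counted"))
    df[[cn]] <- as.numeric(df[[cn]])
  r <- seq_len(nrow(df))
  probs <- c(
    chk(is.finite(df$day) & df$day >= 0, r, "day", "must be >= 0"),
    chk(df$species %in% c("ciliate", "prey"), r, "species",
        "must be 'ciliate' or 'prey'"),
    chk(is.finite(df$density) & df$density >= 0, r, "density",
        "must be a number >= 0"),
    chk(is.na(df$n_counted) |
          (df$n_counted >= 0 & df$n_counted == round(df$n_counted)),
        r, "n_counted", "must be a non-negative integer"),
    chk(is.na(df$volume_counted) | df$volume_counted > 0, r,
        "volume_counted", "must be > 0 (mL)"),
    chk(df$phase %in% c("pre_dilution", "post_dilution", "none"), r,
        "phase", "must be pre_dilution, post_dilution or none")
  )
  # density consistency with counting effort, up to rounding of the report
  both <- !is.na(df$n_counted) & !is.na(df$volume_counted) &
    df$volume_counted > 0
  implied <- df$n_counted / df$volume_counted
  ok <- !both | abs(df$density - implied) <= 0.5 + 1e-9 * pmax(implied, 1)
  probs <- c(probs, chk(ok, r, "density",
                        "inconsistent with n_counted / volume_counted"))
  fail_rows(probs, "read_counts")
  # days non-decreasing per culture x species
  key <- interaction(df$culture_id, df$species, drop = TRUE)
  for (k in levels(key)) {
    d <- df$day[key == k]
    if (is.unsorted(d))
      stop("read_counts: days not non-decreasing within culture/species ", k)
  }
  df
}

# ---- scintillation ----------------------------------------------------------

#' Read and pair light/dark scintillation vials
#'
#' Each 14C incubation produces two vials, one incubated in the experimental
#' light and one wrapped dark. The file carries one row per vial; this reader
#' pairs them on `(culture_id, day)` and returns one row per pair with
#' `dpm_light` and `dpm_dark` columns. A light row with no dark partner (or
#' vice versa) is an error naming the unpaired key. Incubation metadata
#' (`n_cells`, volumes, `dic`, `incubation_h`) must agree within a pair; the
#' specific-activity subsample (`sa_dpm`) is taken from the light vial, whose
#' medium is the one the uptake computation normalises against.
#'
#' @param path path to a `scint.csv` file (see [io_formats]).
#' @return A `data.frame` with columns `culture_id, day, dpm_light, dpm_dark,
#'   n_cells, incubation_h, sa_dpm, sa_volume, counted_volume, vial_volume,
#'   dic`.
#' @export
read_scintillation <- function(path) {
  df <- read_csv_checked(
    path,
    c("culture_id", "day", "vial", "dpm", "n_cells", "incubation_h",
      "sa_dpm", "sa_volume", "counted_volume", "vial_volume", "dic"),
    "read_scintillation"
  )
  r <- seq_len(nrow(df))
  probs <- c(
    chk(df$vial %in% c("light", "dark"), r, "vial",
        "must be 'light' or 'dark'"),
    chk(is.finite(df$dpm) & df$dpm >= 0, r, "dpm", "must be >= 0"),
    chk(is.finite(df$n_cells) & df$n_cells > 0 &
          df$n_cells == round(df$n_cells), r, "n_cells",
        "must be a positive integer"),
    chk(is.finite(df$incubation_h) & df$incubation_h > 0, r,
        "incubation_h", "must be > 0 (h)"),
    chk(is.finite(df$sa_dpm) & df$sa_dpm > 0, r, "sa_dpm", "must be > 0"),
    chk(is.finite(df$dic) & df$dic > 0, r, "dic",
        "must be > 0 (ug C mL-1)"),
    chk(is.finite(df$sa_volume) & df$sa_volume > 0 &
          df$sa_volume <= df$vial_volume, r, "sa_volume",
        "must satisfy 0 < sa_volume <= vial_volume"),
    chk(is.finite(df$counted_volume) & df$counted_volume > 0 &
          df$counted_volume <= df$vial_volume, r, "counted_volume",
        "must satisfy 0 < counted_volume <= vial_volume")
  )
  fail_rows(probs, "read_scintillation")
  pair_scintillation(df)
}

#' Pair long-format light/dark vial rows
#'
#' The pairing step of [read_scintillation()], usable directly on an
#' in-memory long table (one row per vial) such as the one the simulator
#' emits.
#'
#' @param df a `data.frame` in the long `scint.csv` schema.
#' @return One row per `(culture_id, day)` pair; see [read_scintillation()].
#' @export
pair_scintillation <- function(df) {
  light <- df[df$vial == "light", ]
  dark <- df[df$vial == "dark", ]
  lk <- paste(light$culture_id, light$day, sep = "@")
  dk <- paste(dark$culture_id, dark$day, sep = "@")
  if (anyDuplicated(lk) || anyDuplicated(dk))
    stop("read_scintillation: duplicate vial for key ",
         c(lk[duplicated(lk)], dk[duplicated(dk)])[1])
  unpaired <- c(setdiff(lk, dk), setdiff(dk, lk))
  if (length(unpaired) > 0L)
    stop("read_scintillation: unpaired vial(s) for key(s): ",
         paste(unpaired, collapse = ", "))
  m <- match(lk, dk)
  meta <- c("n_cells", "incubation_h", "counted_volume", "vial_volume", "dic")
  for (f in meta) {
    bad <- which(abs(light[[f]] - dark[[f]][m]) > 1e-9)
    if (length(bad) > 0L)
      stop("read_scintillation: light/dark metadata mismatch in '", f,
           "' for key ", lk[bad[1]])
  }
  data.frame(
    culture_id = light$culture_id, day = light$day,
    dpm_light = light$dpm, dpm_dark = dark$dpm[m],
    n_cells = light$n_cells, incubation_h = light$incubation_h,
    sa_dpm = light$sa_dpm, sa_volume = light$sa_volume,
    counted_volume = light$counted_volume, vial_volume = light$vial_volume,
    dic = light$dic, stringsAsFactors = FALSE
  )
}

# ---- fluorometry ------------------------------------------------------------

#' Read a fluorometry table
#'
#' @param path path to a `fluor.csv` file (see [io_formats]). `n_cells = 0`
#'   marks a bulk filter sample and then `volume_filtered` must be present.
#' @return A validated `data.frame`.
#' @export
read_fluorometry <- function(path) {
  df <- read_csv_checked(path, c("culture_id", "day", "n_cells", "reading"),
                         "read_fluorometry")
  if (!"volume_filtered" %in% names(df)) df$volume_filtered <- NA_real_
  r <- seq_len(nrow(df))
  probs <- c(
    chk(is.finite(df$day) & df$day >= 0, r, "day", "must be >= 0"),
    chk(is.finite(df$n_cells) & df$n_cells >= 0 &
          df$n_cells == round(df$n_cells), r, "n_cells",
        "must be a non-negative integer"),
    chk(is.finite(df$reading) & df$reading >= 0, r, "reading",
        "must be >= 0 (pg chl-a)"),
    chk(df$n_cells > 0 |
          (!is.na(df$volume_filtered) & df$volume_filtered > 0),
        r, "volume_filtered",
        "required (> 0 mL) when n_cells = 0 (bulk sample)")
  )
  fail_rows(probs, "read_fluorometry")
  df
}

# ---- cell dimensions --------------------------------------------------------

#' Read a cell-dimension table
#'
#' Rows with `length < width` are swapped (with a warning naming the rows):
#' the biovolume formulas require the rotation axis first, and reversed
#' transcription is far more likely than a genuinely oblate cell.
#'
#' @param path path to a `dims.csv` file (see [io_formats]).
#' @return A validated `data.frame` with `length >= width` everywhere.
#' @export
read_dimensions <- function(path) {
  df <- read_csv_checked(path,
                         c("culture_id", "day", "length", "width", "shape"),
                         "read_dimensions")
  r <- seq_len(nrow(df))
  probs <- c(
    chk(is.finite(df$day) & df$day >= 0, r, "day", "must be >= 0"),
    chk(is.finite(df$length) & df$length > 0, r, "length",
        "must be > 0 (um)"),
    chk(is.finite(df$width) & df$width > 0, r, "width", "must be > 0 (um)"),
    chk(df$shape %in% c("sphere", "ellipsoid"), r, "shape",
        "must be 'sphere' or 'ellipsoid'")
  )
  fail_rows(probs, "read_dimensions")
  swap <- which(df$length < df$width)
  if (length(swap) > 0L) {
    warning("read_dimensions: length < width in row(s) ",
            paste(swap, collapse = ", "), "; axes swapped")
    tmp <- df$length[swap]
    df$length[swap] <- df$width[swap]
    df$width[swap] <- tmp
  }
  df
}

# ---- treatments -------------------------------------------------------------

#' Read a treatment table
#'
#' @param path path to a `treatments.csv` file (see [io_formats]).
#' @return A `kc_treatment` data.frame, one row per treatment.
#' @export
read_treatments <- function(path) {
  df <- read_csv_checked(
    path, c("treatment_id", "irradiance", "prey_target"), "read_treatments"
  )
  if (!"light_hours" %in% names(df)) df$light_hours <- 14
  if (!"prey_carbon" %in% names(df)) df$prey_carbon <- 10
  if (!"carbon_per_volume" %in% names(df)) df$carbon_per_volume <- 0.19
  rows <- lapply(seq_len(nrow(df)), function(i) {
    tryCatch(
      treatment(df$treatment_id[i], df$irradiance[i], df$prey_target[i],
                df$light_hours[i], df$prey_carbon[i],
                df$carbon_per_volume[i]),
      error = function(e) stop("read_treatments: row ", i, ": ",
                               conditionMessage(e), call. = FALSE)
    )
  })
  do.call(treatment_table, rows)
}

# ---- rates ------------------------------------------------------------------

rate_columns <- function() {
  c("culture_id", "treatment_id", "t0", "t1", "mu_y", "mu_x", "g", "F", "I",
    "P_daily", "chl_cell", "P_chl", "Bv", "C_y", "mu_yC", "C_I", "GGE",
    "photo_pct", "flags")
}

#' Write derived rates to CSV
#'
#' Writes one row per culture x interval in the documented column order at
#' full double precision (`%.17g`), so that [read_rates()] reproduces every
#' numeric value bit-identically. An empty record set yields a header-only
#' file.
#'
#' @param records a rate-record `data.frame` as produced by
#'   [assemble_rates()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_rates <- function(records, path) {
  cols <- rate_columns()
  missing <- setdiff(cols, names(records))
  if (length(missing) > 0L)
    stop("write_rates: records missing column(s): ",
         paste(missing, collapse = ", "))
  records <- records[, cols, drop = FALSE]
  fmt_num <- function(x) {
    out <- vapply(x, function(v) {
      if (is.na(v)) "" else sprintf("%.17g", v)
    }, character(1))
    out
  }
  cells <- lapply(cols, function(cn) {
    v <- records[[cn]]
    if (is.numeric(v)) fmt_num(v) else ifelse(is.na(v), "", as.character(v))
  })
  lines <- c(paste(cols, collapse = ","),
             if (nrow(records) > 0L) do.call(paste, c(cells, sep = ",")))
  writeLines(lines, path)
  invisible(path)
}

#' Read a rates CSV written by [write_rates()]
#'
#' @param path path to a `rates.csv` file.
#' @return A rate-record `data.frame` with the documented columns.
#' @export
read_rates <- function(path) {
  df <- read_csv_checked(path, rate_columns(), "read_rates")
  num <- setdiff(rate_columns(), c("culture_id", "treatment_id", "flags"))
  for (cn in num) {
    v <- df[[cn]]
    if (is.character(v)) v[v == ""] <- NA_character_
    df[[cn]] <- as.numeric(v)
  }
  df$flags <- ifelse(is.na(df$flags), "", as.character(df$flags))
  df
}
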