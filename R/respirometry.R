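# Bimodal (air + water) intermittent stopped-flow respirometry:
# raw two-phase optode logs -> per-fish MO2AIR, MO2WATER, RMR, SMR, %MO2AIR.

# Ideal-gas constant in L kPa mmol^-1 K^-1
.R_GAS <- 8.31446e-3

#' Respirometer chamber geometry
#'
#' Describes one bimodal respirometer: a sealed chamber of fixed total volume
#' split into an air phase projecting above the water surface and an effective
#' water phase. The effective water volume subtracts both the air phase and
#' the fish's body volume (mass / assumed body density of 1.0 kg/L); whether
#' the body volume is subtracted is flagged in the returned metadata.
#'
#' @param fish_mass fish wet mass in kg.
#' @param total_volume total chamber volume in litres.
#' @param air_volume calibrated air-phase volume in litres (see
#'   [calibrate_air_volume()]).
#' @param temperature water temperature in degrees Celsius; values outside the
#'   20--32 band for tropical freshwater work are rejected.
#' @param barometric_pressure ambient pressure in kPa.
#' @param fish_density assumed body density in kg/L used to convert mass to
#'   displaced volume.
#' @return An object of class `respirometer_geometry`: a list with
#'   `total_volume`, `air_volume`, `water_volume_effective`, `fish_mass`,
#'   `temperature`, `barometric_pressure` and `fish_volume_subtracted = TRUE`.
#' @examples
#' geom <- respirometer_geometry(fish_mass = 0.064)
#' geom$water_volume_effective  # 2.5 - 0.2 - 0.064
#' @export
respirometer_geometry <- function(fish_mass,
                                  total_volume = 2.5,
                                  air_volume = 0.2,
                                  temperature = 26.5,
                                  barometric_pressure = 101.325,
                                  fish_density = 1.0) {
  stopifnot(is.numeric(fish_mass), length(fish_mass) == 1L, fish_mass > 0)
  if (temperature < 20 || temperature > 32) {
    stop("temperature ", temperature, " degC outside the expected 20-32 band")
  }
  fish_volume <- fish_mass / fish_density
  water <- total_volume - air_volume - fish_volume
  if (air_volume <= 0 || water <= 0 || total_volume <= 0) {
    stop("volumes must be positive; got water_volume_effective = ", water)
  }
  structure(
    list(
      total_volume = total_volume,
      air_volume = air_volume,
      water_volume_effective = water,
      fish_mass = fish_mass,
      temperature = temperature,
      barometric_pressure = barometric_pressure,
      fish_volume_subtracted = TRUE
    ),
    class = "respirometer_geometry"
  )
}

#' @export
print.respirometer_geometry <- function(x, ...) {
  cat("Bimodal respirometer geometry\n")
  cat(sprintf("  total %.3f L = air %.3f L + water (effective) %.3f L + fish %.3f L\n",
              x$total_volume, x$air_volume, x$water_volume_effective,
              x$total_volume - x$air_volume - x$water_volume_effective))
  cat(sprintf("  fish mass %.4f kg, %.1f degC, %.1f kPa\n",
              x$fish_mass, x$temperature, x$barometric_pressure))
  invisible(x)
}

#' Saturation water vapour pressure (kPa)
#'
#' Buck (1981) fit for water vapour pressure over liquid water.
#'
#' @param temperature degrees Celsius.
#' @return vapour pressure in kPa.
#' @export
water_vapour_pressure <- function(temperature) {
  0.61121 * exp((18.678 - temperature / 234.5) *
                  (temperature / (257.14 + temperature)))
}

#' Oxygen solubility of air-equilibrated fresh water
#'
#' Concentration of dissolved oxygen at 100% air saturation, from the
#' Garcia & Gordon (1992) combined fit to the Benson & Krause data at
#' salinity 0, with a barometric correction for the dry-gas fraction
#' (P - pH2O) relative to one standard atmosphere.
#'
#' @param temperature water temperature, degrees Celsius.
#' @param barometric_pressure ambient pressure, kPa.
#' @return solubility in mmol O2 per litre at 100% air saturation.
#' @examples
#' o2_solubility(26.5)  # ~0.25 mmol/L
#' @export
o2_solubility <- function(temperature, barometric_pressure = 101.325) {
  stopifnot(temperature > 0, temperature < 40, barometric_pressure > 0)
  a <- c(5.80871, 3.20291, 4.17887, 5.10006, -9.86643e-2, 3.80369)
  ts <- log((298.15 - temperature) / (273.15 + temperature))
  umol_kg <- exp(sum(a * ts^(0:5)))
  pw <- water_vapour_pressure(temperature)
  corr <- (barometric_pressure - pw) / (101.325 - pw)
  # fresh water density ~0.997 kg/L at these temperatures
  umol_kg * corr * 0.997 / 1000
}

#' Partial pressure of O2 in air-saturated conditions (kPa)
#'
#' @param temperature degrees Celsius.
#' @param barometric_pressure kPa.
#' @return PO2 of water-vapour-saturated air, kPa.
#' @export
po2_air_saturation <- function(temperature, barometric_pressure = 101.325) {
  0.2095 * (barometric_pressure - water_vapour_pressure(temperature))
}

#' Convert between kPa and % air saturation
#'
#' Explicit oxygen unit converters. `kpa_to_pct_sat()` expresses an oxygen
#' partial pressure relative to the PO2 of air-saturated conditions at the
#' trial temperature and pressure; `pct_sat_to_kpa()` is its inverse.
#'
#' @param value oxygen reading(s).
#' @param temperature degrees Celsius.
#' @param barometric_pressure kPa.
#' @return converted value(s).
#' @export
kpa_to_pct_sat <- function(value, temperature, barometric_pressure = 101.325) {
  100 * value / po2_air_saturation(temperature, barometric_pressure)
}

#' @rdname kpa_to_pct_sat
#' @export
pct_sat_to_kpa <- function(value, temperature, barometric_pressure = 101.325) {
  value / 100 * po2_air_saturation(temperature, barometric_pressure)
}

#' Calibrate air-phase volume from a nitrogen bolus
#'
#' The air-phase volume of a sealed bimodal respirometer is derived from the
#' drop in O2 partial pressure caused by injecting a bolus of 100% N2 into
#' the sealed air space. Under well-mixed isobaric venting the post-bolus
#' partial pressure is `p_after = p_before * V / (V + bolus)`, which inverts
#' to `V = bolus * p_after / (p_before - p_after)`.
#'
#' Vectors describe replicate boluses; the replicate estimates are averaged.
#'
#' @param bolus_volume injected N2 volume(s), mL.
#' @param p_before O2 partial pressure(s) before injection, kPa.
#' @param p_after O2 partial pressure(s) after mixing, kPa.
#' @return estimated air-phase volume in mL (mean over replicates).
#' @examples
#' calibrate_air_volume(50, 20, 16)  # 200 mL
#' @export
calibrate_air_volume <- function(bolus_volume, p_before, p_after) {
  if (any(bolus_volume <= 0) || any(p_before <= 0) || any(p_after <= 0)) {
    stop("bolus_volume, p_before and p_after must all be positive")
  }
  if (any(p_after >= p_before)) {
    stop("no dilution detected: p_after must be below p_before")
  }
  mean(bolus_volume * p_after / (p_before - p_after))
}

#' Segment an optode trace into closed-phase measurement windows
#'
#' The stopped-flow cycle alternates a closed period (both phases sealed, O2
#' declines) with a flush period. Each returned window covers the closed
#' period of one cycle minus the first `settle_skip` seconds, which are
#' discarded as a mixing/settling artefact.
#'
#' @param trace an optode log `data.frame` with at least a `time_s` column,
#'   or a numeric vector of sample times in seconds.
#' @param closed_duration seconds the chamber is sealed per cycle.
#' @param flush_duration seconds of flushing per cycle.
#' @param settle_skip seconds discarded at the start of each closed phase.
#' @return `data.frame` with columns `cycle_index`, `t_start`, `t_end`
#'   (seconds, relative to the trace's first sample time). Zero rows, with a
#'   warning, if the trace spans less than one full cycle.
#' @examples
#' segment_cycles(seq(0, 61200, by = 5))  # 68 windows over 17 hr
#' @export
segment_cycles <- function(trace, closed_duration = 600, flush_duration = 300,
                           settle_skip = 60) {
  times <- if (is.data.frame(trace)) trace$time_s else as.numeric(trace)
  stopifnot(length(times) > 0, closed_duration > 0, flush_duration > 0,
            settle_skip >= 0, settle_skip < closed_duration)
  period <- closed_duration + flush_duration
  t0 <- min(times)
  span <- max(times) - t0
  n <- floor(span / period)
  if (n < 1) {
    warning("trace spans ", span, " s, less than one full ", period,
            "-s cycle; no windows")
    return(data.frame(cycle_index = integer(0), t_start = numeric(0),
                      t_end = numeric(0)))
  }
  k <- seq_len(n) - 1L
  data.frame(
    cycle_index = k + 1L,
    t_start = t0 + k * period + settle_skip,
    t_end = t0 + k * period + closed_duration
  )
}

#' Ordinary least-squares O2 slope over a closed-phase window
#'
#' Fits value ~ time by OLS and reports the slope per hour together with the
#' coefficient of determination. No quality filtering is applied here.
#'
#' @param time_s sample times in seconds.
#' @param value oxygen readings (any single unit).
#' @return list with `slope` (units per hour) and `r2`.
#' @export
fit_slope <- function(time_s, value) {
  n <- length(time_s)
  if (n < 3 || length(value) != n) {
    stop("insufficient data: need >= 3 paired samples, got ", n)
  }
  th <- time_s / 3600
  sxx <- sum((th - mean(th))^2)
  if (sxx == 0) stop("degenerate window: all sample times identical")
  syy <- sum((value - mean(value))^2)
  if (syy == 0) return(list(slope = 0, r2 = 0))
  sxy <- sum((th - mean(th)) * (value - mean(value)))
  slope <- sxy / sxx
  list(slope = slope, r2 = sxy^2 / (sxx * syy))
}

#' Oxygen uptake from the air phase
#'
#' Converts the decline in air-phase O2 partial pressure during a closed
#' period into a mass-specific uptake rate via the ideal gas law:
#' `MO2AIR = (-slope * V_air) / (R * T_K) / mass` with R in
#' L kPa mmol^-1 K^-1.
#'
#' @param slope_air air-phase O2 slope, kPa per hour (negative = decline).
#' @param geom a [respirometer_geometry()].
#' @param positive_tol positive slopes larger than this (kPa/hr) are flagged
#'   as an O2 increase in the closed phase.
#' @return uptake in mmol O2 kg^-1 hr^-1 (never negative), with attribute
#'   `flagged` TRUE where the slope rose beyond `positive_tol`.
#' @export
mo2_air <- function(slope_air, geom, positive_tol = 0.1) {
  stopifnot(inherits(geom, "respirometer_geometry"))
  flagged <- slope_air > positive_tol
  up <- pmax(0, -slope_air) * geom$air_volume /
    (.R_GAS * (geom$temperature + 273.15)) / geom$fish_mass
  attr(up, "flagged") <- flagged
  up
}

#' Oxygen uptake from the water phase
#'
#' Converts the decline in water-phase O2 (% air saturation) during a closed
#' period into a mass-specific uptake rate using the O2 solubility of
#' air-equilibrated fresh water at the trial temperature and pressure.
#'
#' @param slope_water water-phase slope, % air saturation per hour.
#' @param geom a [respirometer_geometry()].
#' @param solubility mmol O2 per litre at 100% air saturation; computed from
#'   `geom` via [o2_solubility()] when NULL.
#' @param positive_tol flagging threshold, %sat per hour.
#' @return uptake in mmol O2 kg^-1 hr^-1, attribute `flagged` as [mo2_air()].
#' @export
mo2_water <- function(slope_water, geom, solubility = NULL,
                      positive_tol = 0.5) {
  stopifnot(inherits(geom, "respirometer_geometry"))
  if (is.null(solubility)) {
    solubility <- o2_solubility(geom$temperature, geom$barometric_pressure)
  }
  stopifnot(solubility > 0)
  flagged <- slope_water > positive_tol
  up <- pmax(0, -slope_water) / 100 * solubility *
    geom$water_volume_effective / geom$fish_mass
  attr(up, "flagged") <- flagged
  up
}

#' Standard metabolic rate by the quantile method
#'
#' SMR is estimated as a low quantile of the repeated routine metabolic rate
#' measures, on the premise that a proportion q of RMR measures fall below
#' true SMR through temporal variability and measurement error. Linear
#' interpolation between order statistics is used (the default convention of
#' common statistical software, `quantile(type = 7)`).
#'
#' @param rmr_series per-cycle RMR values, mmol O2 kg^-1 hr^-1.
#' @param q quantile in (0, 0.5); default 0.12.
#' @return SMR estimate, with attributes `q` and `interpolation = "linear"`.
#' @export
smr_quantile <- function(rmr_series, q = 0.12) {
  if (length(rmr_series) == 0) stop("empty RMR series")
  stopifnot(q > 0, q < 0.5)
  if (length(rmr_series) < 20) {
    warning("only ", length(rmr_series),
            " RMR measures; quantile SMR is unstable below ~20")
  }
  out <- unname(stats::quantile(rmr_series, probs = q, type = 7, names = FALSE))
  attr(out, "q") <- q
  attr(out, "interpolation") <- "linear"
  out
}

#' Percentage of total oxygen uptake obtained from air
#'
#' Aggregated over the measurement interval:
#' `100 * sum(MO2AIR) / sum(MO2AIR + MO2WATER)`.
#'
#' @param cycles `data.frame` with columns `mo2_air` and `mo2_water`
#'   (one row per cycle), or a list/profile containing such a table.
#' @return percentage in \\[0, 100\\].
#' @export
pct_air <- function(cycles) {
  if (inherits(cycles, "metabolic_profile")) cycles <- cycles$cycles
  stopifnot(is.data.frame(cycles), nrow(cycles) >= 1,
            all(c("mo2_air", "mo2_water") %in% names(cycles)))
  tot <- sum(cycles$mo2_air) + sum(cycles$mo2_water)
  if (tot <= 0) stop("total oxygen uptake is zero; %MO2AIR undefined")
  100 * sum(cycles$mo2_air) / tot
}

#' Full metabolic profile of one fish from a two-phase optode trace
#'
#' Runs the respirometry pipeline for a single chamber: segments the trace
#' into closed-phase windows, fits the O2 decline in each phase per cycle,
#' converts slopes to uptake rates, and summarises routine metabolic rate
#' (mean of per-cycle RMR), standard metabolic rate (quantile method) and
#' the percentage of uptake obtained from air.
#'
#' @param trace optode log `data.frame` for one chamber with columns
#'   `time_s`, `phase` ("air"/"water"), `unit` ("kPa"/"pct_sat") and `value`.
#' @param geom a [respirometer_geometry()].
#' @param q SMR quantile.
#' @param settle_skip seconds of each closed phase discarded as mixing lag.
#' @param closed_duration,flush_duration cycle schedule, seconds.
#' @param solubility water O2 solubility override (mmol/L at 100% sat).
#' @param window_hours optional length-2 vector: keep only cycles whose
#'   closed phase starts within \\[h1, h2\\] hours of the trace start.
#' @param r2_min optional minimum r2; cycles below it in either phase are
#'   dropped and counted (no rejection filter by default).
#' @param fish_id identifier carried into the output.
#' @return object of class `metabolic_profile`: per-cycle table (`cycles`),
#'   `rmr`, `smr`, `pct_air`, `q`, `n_cycles`, `n_rejected` and metadata.
#' @export
metabolic_profile <- function(trace, geom, q = 0.12, settle_skip = 60,
                              closed_duration = 600, flush_duration = 300,
                              solubility = NULL, window_hours = NULL,
                              r2_min = NULL, fish_id = NULL) {
  stopifnot(is.data.frame(trace),
            all(c("time_s", "phase", "value") %in% names(trace)),
            inherits(geom, "respirometer_geometry"))
  if (is.null(solubility)) {
    solubility <- o2_solubility(geom$temperature, geom$barometric_pressure)
  }
  if (is.null(fish_id)) {
    fish_id <- if ("chamber_id" %in% names(trace)) {
      as.character(trace$chamber_id[1])
    } else "fish"
  }
  win <- segment_cycles(trace, closed_duration, flush_duration, settle_skip)
  if (nrow(win) == 0) stop("trace too short for a single cycle")
  t0 <- min(trace$time_s)
  if (!is.null(window_hours)) {
    h <- (win$t_start - settle_skip - t0) / 3600
    win <- win[h >= window_hours[1] & h < window_hours[2], , drop = FALSE]
    if (nrow(win) == 0) stop("no cycles inside the analysis window")
  }

  air <- trace[trace$phase == "air", , drop = FALSE]
  wat <- trace[trace$phase == "water", , drop = FALSE]
  if (!is.null(air$unit) && any(air$unit == "pct_sat")) {
    i <- air$unit == "pct_sat"
    air$value[i] <- pct_sat_to_kpa(air$value[i], geom$temperature,
                                   geom$barometric_pressure)
  }
  if (!is.null(wat$unit) && any(wat$unit == "kPa")) {
    i <- wat$unit == "kPa"
    wat$value[i] <- kpa_to_pct_sat(wat$value[i], geom$temperature,
                                   geom$barometric_pressure)
  }

  one <- function(df, a, b) {
    s <- df$time_s >= a & df$time_s <= b
    if (sum(s) < 3) return(c(NA_real_, NA_real_))
    f <- fit_slope(df$time_s[s], df$value[s])
    c(f$slope, f$r2)
  }
  m <- t(vapply(seq_len(nrow(win)), function(i) {
    c(one(air, win$t_start[i], win$t_end[i]),
      one(wat, win$t_start[i], win$t_end[i]))
  }, numeric(4)))
  cyc <- data.frame(
    cycle_index = win$cycle_index,
    slope_air = m[, 1], r2_air = m[, 2],
    slope_water = m[, 3], r2_water = m[, 4]
  )
  cyc <- cyc[stats::complete.cases(cyc[, c("slope_air", "slope_water")]), ,
             drop = FALSE]
  ua <- mo2_air(cyc$slope_air, geom)
  uw <- mo2_water(cyc$slope_water, geom, solubility)
  cyc$mo2_air <- as.numeric(ua)
  cyc$mo2_water <- as.numeric(uw)
  cyc$rmr_cycle <- cyc$mo2_air + cyc$mo2_water
  cyc$flagged <- attr(ua, "flagged") | attr(uw, "flagged")

  n_rejected <- 0L
  if (!is.null(r2_min)) {
    keep <- cyc$r2_air >= r2_min & cyc$r2_water >= r2_min
    n_rejected <- sum(!keep)
    cyc <- cyc[keep, , drop = FALSE]
  }
  if (nrow(cyc) == 0) stop("no usable cycles after filtering")

  structure(
    list(
      fish_id = fish_id,
      cycles = cyc,
      rmr = mean(cyc$rmr_cycle),
      smr = as.numeric(smr_quantile(cyc$rmr_cycle, q)),
      pct_air = pct_air(cyc),
      q = q,
      n_cycles = nrow(cyc),
      n_rejected = n_rejected,
      meta = list(
        settle_skip = settle_skip,
        quantile_interpolation = "linear",
        solubility_mmol_per_l = solubility,
        fish_volume_subtracted = geom$fish_volume_subtracted,
        r2_min = r2_min
      )
    ),
    class = "metabolic_profile"
  )
}

#' @export
print.metabolic_profile <- function(x, ...) {
  cat("Metabolic profile:", x$fish_id, "\n")
  cat(sprintf("  cycles: %d (rejected: %d)\n", x$n_cycles, x$n_rejected))
  cat(sprintf("  RMR  %.3f mmol O2/kg/hr\n", x$rmr))
  cat(sprintf("  SMR  %.3f mmol O2/kg/hr (quantile q = %.2f)\n", x$smr, x$q))
  cat(sprintf("  %%MO2AIR %.1f%%\n", x$pct_air))
  invisible(x)
}

#' @export
summary.metabolic_profile <- function(object, ...) {
  out <- data.frame(
    fish_id = object$fish_id,
    mass = NA_real_,
    rmr = object$rmr,
    smr = object$smr,
    pct_air = object$pct_air,
    n_cycles = object$n_cycles,
    stringsAsFactors = FALSE
  )
  out
}

#' Read / write delimited optode logs
#'
#' One row per optode sample: `time_s, chamber_id, phase, unit, value`.
#' Tab-separated with a header.
#'
#' @param path file path.
#' @return `read_optode_log()`: the log `data.frame`.
#' @export
read_optode_log <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("time_s", "chamber_id", "phase", "unit", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("optode log missing columns: ",
                         paste(miss, collapse = ", "))
  df[order(df$chamber_id, df$phase, df$time_s), need]
}

#' @rdname read_optode_log
#' @param log optode log `data.frame`.
#' @export
write_optode_log <- function(log, path) {
  utils::write.table(log, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Batch respirometry: one trait row per fish
#'
#' Applies [metabolic_profile()] to every chamber in a multi-chamber optode
#' log and returns a tidy per-fish trait table plus the combined per-cycle
#' companion table.
#'
#' @param log optode log covering one or more chambers.
#' @param geometries named list of [respirometer_geometry()], keyed by
#'   chamber id (the chamber id doubles as the fish id).
#' @param ... passed on to [metabolic_profile()].
#' @return list with `traits` (fish_id, mass, rmr, smr, pct_air, n_cycles)
#'   and `cycles` (per-cycle rows for every fish).
#' @export
respirometry_batch <- function(log, geometries, ...) {
  ids <- unique(as.character(log$chamber_id))
  miss <- setdiff(ids, names(geometries))
  if (length(miss)) stop("no geometry for chamber(s): ",
                         paste(miss, collapse = ", "))
  profs <- lapply(ids, function(id) {
    metabolic_profile(log[log$chamber_id == id, , drop = FALSE],
                      geometries[[id]], fish_id = id, ...)
  })
  traits <- do.call(rbind, lapply(profs, function(p) {
    data.frame(fish_id = p$fish_id,
               mass = geometries[[p$fish_id]]$fish_mass,
               rmr = p$rmr, smr = p$smr, pct_air = p$pct_air,
               n_cycles = p$n_cycles, stringsAsFactors = FALSE)
  }))
  cycles <- do.call(rbind, lapply(profs, function(p) {
    cbind(fish_id = p$fish_id, p$cycles, stringsAsFactors = FALSE)
  }))
  list(traits = traits, cycles = cycles, profiles = profs)
}
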