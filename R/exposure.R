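#' Constituent specification for exposure modeling
#'
#' Bundles the per-constituent inputs the intake model needs: the EVP
#' emission factor (ug exhaled per mg e-liquid consumed), the cigarette
#' sidestream emission (ug per cigarette, `NA` when no data exist), the
#' saturation mass concentration governing vapor/particle partitioning
#' (`NA` = fully volatile), the 8-h occupational exposure limit used as the
#' reference scale, and whether the exhaled-breath level was below the MDL.
#'
#' @param name Constituent name.
#' @param emission_factor ug per mg e-liquid consumed; must be 0 when
#'   `below_mdl` is `TRUE`.
#' @param sidestream_emission ug per cigarette, or `NA`.
#' @param saturation ug/m^3, or `NA` for fully volatile.
#' @param exposure_limit 8-h limit concentration (ug/m^3), or `NA`.
#' @param below_mdl Logical: exhaled level below the detection limit.
#' @return An object of class `constituent`.
#' @export
constituent <- function(name, emission_factor, sidestream_emission = NA_real_,
                        saturation = NA_real_, exposure_limit = NA_real_,
                        below_mdl = FALSE) {
  if (!is.finite(emission_factor) || emission_factor < 0)
    stop("`emission_factor` must be >= 0")
  if (isTRUE(below_mdl) && emission_factor != 0)
    stop("a below-MDL constituent must have emission_factor 0")
  for (v in c(sidestream_emission, saturation, exposure_limit))
    if (!is.na(v) && v < 0) stop("emissions, saturation and limits must be >= 0")
  structure(list(name = name, emission_factor = emission_factor,
                 sidestream_emission = sidestream_emission,
                 saturation = saturation, exposure_limit = exposure_limit,
                 below_mdl = isTRUE(below_mdl)),
            class = "constituent")
}

#' Default constituent registry
#'
#' EVP emission factors for the modeled product and cigarette sidestream
#' emissions (Kentucky reference 1R4F), with 8-h occupational limit
#' concentrations: nicotine 500, glycerin and propylene glycol 10,000,
#' formaldehyde 920, acetaldehyde 360,000 and acrolein 250 ug/m^3.
#' Acetaldehyde and acrolein were below the MDL in all exhaled-breath
#' collections, so their EVP emission factors are exactly 0. All EVP
#' constituents are treated as fully volatile by default (no saturation
#' concentration), consistent with their high volatility relative to smoke
#' particles.
#'
#' @param include_menthol Include menthol (which has no sidestream value and
#'   no reference limit). Default `FALSE`, matching the six-constituent
#'   intake table.
#' @return A named list of [constituent()] objects.
#' @export
default_constituents <- function(include_menthol = FALSE) {
  specs <- list(
    constituent("nicotine", 4.22, sidestream_emission = 5600,
                exposure_limit = 500),
    constituent("propylene_glycol", 83.86, exposure_limit = 10000),
    constituent("glycerin", 162.12, exposure_limit = 10000),
    constituent("formaldehyde", 0.0083, sidestream_emission = 700,
                exposure_limit = 920),
    constituent("acetaldehyde", 0, sidestream_emission = 4200,
                exposure_limit = 360000, below_mdl = TRUE),
    constituent("acrolein", 0, sidestream_emission = 1300,
                exposure_limit = 250, below_mdl = TRUE)
  )
  if (include_menthol)
    specs <- append(specs, list(constituent("menthol", 0.53)), after = 3)
  stats::setNames(specs, vapply(specs, `[[`, "", "name"))
}

#' Define an exposure scenario
#'
#' A bounded indoor space shared by product users and non-users for a fixed
#' duration.
#'
#' @param name Scenario label.
#' @param volume Space volume (m^3), positive.
#' @param ach Air-change rate (1/h), nonnegative.
#' @param duration Exposure duration (h), positive.
#' @param n_users Number of active users, at most `n_occupants`; 0 gives a
#'   source-free space with zero intakes.
#' @param n_occupants Total occupants (users + non-users).
#' @param source_kind `"evp"` or `"cigarette"`.
#' @return An object of class `scenario`.
#' @export
scenario <- function(name, volume, ach, duration, n_users, n_occupants,
                     source_kind = c("evp", "cigarette")) {
  source_kind <- match.arg(source_kind)
  if (!is.finite(volume) || volume <= 0) stop("`volume` must be positive")
  if (!is.finite(ach) || ach < 0) stop("`ach` must be >= 0")
  if (!is.finite(duration) || duration <= 0) stop("`duration` must be positive")
  if (n_users < 0 || n_users > n_occupants)
    stop("need 0 <= n_users <= n_occupants")
  structure(list(name = name, volume = volume, ach = ach, duration = duration,
                 n_users = n_users, n_occupants = n_occupants,
                 source_kind = source_kind),
            class = "scenario")
}

#' Default exposure scenarios
#'
#' The four modeled spaces: a car with closed windows, the same car with a
#' 3-inch window gap, a meeting room, and a restaurant. Published scenario
#' air-change rates are not available; the shipped values are
#' reconstructions obtained with [calibrate_ach()] so that the nicotine
#' intake in each space matches the reported intake table, and should be
#' read as plausible high-ventilation settings rather than measurements.
#'
#' @param source_kind `"evp"` or `"cigarette"` for all four scenarios.
#' @return A named list of [scenario()] objects.
#' @export
default_scenarios <- function(source_kind = c("evp", "cigarette")) {
  source_kind <- match.arg(source_kind)
  specs <- list(
    scenario("car_closed", volume = 3.17, ach = 25.06, duration = 1,
             n_users = 2, n_occupants = 4, source_kind = source_kind),
    scenario("car_open", volume = 3.17, ach = 52.48, duration = 1,
             n_users = 2, n_occupants = 4, source_kind = source_kind),
    scenario("meeting_room", volume = 81, ach = 1.637, duration = 4,
             n_users = 3, n_occupants = 15, source_kind = source_kind),
    scenario("restaurant", volume = 270, ach = 4.881, duration = 2,
             n_users = 15, n_occupants = 100, source_kind = source_kind)
  )
  stats::setNames(specs, vapply(specs, `[[`, "", "name"))
}

#' Usage and breathing assumptions
#'
#' `usage_model()` holds the consumption assumptions converting per-mg or
#' per-cigarette emissions into source rates: average daily e-liquid
#' consumption spread over the waking hours of use, and a cigarette pace of
#' one per hour. `breathing_model()` holds the non-user ventilation
#' assumptions; the defaults (500 mL tidal volume at 12 breaths/min) give a
#' minute ventilation of 0.36 m^3/h.
#'
#' @param evp_daily_consumption_mg Daily e-liquid consumption (mg/day).
#' @param evp_use_hours Hours of EVP use per day.
#' @param cigarettes_per_hour Cigarettes smoked per user per hour.
#' @param cigarette_use_hours Hours of smoking per day.
#' @return An object of class `usage_model` or `breathing_model`.
#' @export
usage_model <- function(evp_daily_consumption_mg = 902, evp_use_hours = 16,
                        cigarettes_per_hour = 1, cigarette_use_hours = 16) {
  vals <- c(evp_daily_consumption_mg, evp_use_hours, cigarettes_per_hour,
            cigarette_use_hours)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all usage parameters must be positive")
  structure(list(evp_daily_consumption_mg = evp_daily_consumption_mg,
                 evp_use_hours = evp_use_hours,
                 cigarettes_per_hour = cigarettes_per_hour,
                 cigarette_use_hours = cigarette_use_hours),
            class = "usage_model")
}

#' @rdname usage_model
#' @param tidal_volume_ml Tidal volume (mL).
#' @param breaths_per_min Breathing rate (breaths/min).
#' @export
breathing_model <- function(tidal_volume_ml = 500, breaths_per_min = 12) {
  if (tidal_volume_ml <= 0 || breaths_per_min <= 0)
    stop("breathing parameters must be positive")
  structure(list(tidal_volume_ml = tidal_volume_ml,
                 breaths_per_min = breaths_per_min),
            class = "breathing_model")
}

#' Minute ventilation in m^3/h
#' @param breathing A [breathing_model()].
#' @return Volume of air breathed per hour (m^3/h); 0.36 with the defaults.
#' @export
minute_ventilation <- function(breathing = breathing_model()) {
  breathing$tidal_volume_ml * breathing$breaths_per_min * 60 / 1e6
}

#' Constituent source rate for a scenario
#'
#' EVP sources emit `n_users x (daily consumption / hours of use) x emission
#' factor`; cigarette sources emit `n_users x cigarettes per hour x
#' sidestream emission`. A below-MDL constituent contributes a zero EVP
#' source; a cigarette scenario for a constituent with no sidestream data
#' returns `NA` (not available).
#'
#' @param constituent A [constituent()].
#' @param scen A [scenario()].
#' @param usage A [usage_model()].
#' @return Emission rate into the space (ug/h), or `NA_real_`.
#' @export
source_rate <- function(constituent, scen, usage = usage_model()) {
  if (scen$source_kind == "evp") {
    per_user <- usage$evp_daily_consumption_mg / usage$evp_use_hours
    scen$n_users * per_user * constituent$emission_factor
  } else {
    if (is.na(constituent$sidestream_emission)) return(NA_real_)
    scen$n_users * usage$cigarettes_per_hour * constituent$sidestream_emission
  }
}

#' Non-user intake from a time-averaged concentration
#'
#' Intake = average concentration x exposure duration x minute ventilation,
#' assuming 100% absorption of inhaled constituents. With the default
#' breathing model the ventilation factor is 0.36 m^3/h.
#'
#' @param average_concentration ug/m^3, nonnegative.
#' @param duration Exposure duration (h), positive.
#' @param breathing A [breathing_model()].
#' @return Intake (ug).
#' @export
#'
#' @examples
#' intake(500, 8)  # 1440 ug
intake <- function(average_concentration, duration,
                   breathing = breathing_model()) {
  if (any(average_concentration < 0)) stop("concentration must be >= 0")
  if (any(duration <= 0)) stop("`duration` must be positive")
  average_concentration * duration * minute_ventilation(breathing)
}

#' Reference intake at an 8-h exposure limit
#'
#' The intake a non-user would accumulate breathing air at the limit
#' concentration for a full 8-h shift: `limit x 8 h x minute ventilation`
#' (limit x 2.88 m^3 with the default breathing model). Reported values are
#' rounded to the nearest microgram; full precision is in `intake_full`.
#'
#' @param exposure_limit Limit concentration (ug/m^3), or `NA`.
#' @param breathing A [breathing_model()].
#' @param hours Reference shift length (h). Default 8.
#' @return A list with `intake` (rounded, ug), `intake_full`, and `status`
#'   (`"computed"` or `"NA"`).
#' @export
#'
#' @examples
#' limit_reference_intake(250)$intake  # 720 ug for acrolein
limit_reference_intake <- function(exposure_limit,
                                   breathing = breathing_model(), hours = 8) {
  if (is.na(exposure_limit))
    return(list(intake = NA_real_, intake_full = NA_real_, status = "NA"))
  if (exposure_limit <= 0) stop("`exposure_limit` must be positive")
  full <- exposure_limit * hours * minute_ventilation(breathing)
  list(intake = round(full), intake_full = full, status = "computed")
}

#' Run one exposure scenario over a constituent registry
#'
#' For each constituent, builds the continuous source, simulates the
#' well-mixed space from zero initial concentration, time-averages the
#' trajectory, and converts to non-user intake and the 8-h limit reference
#' intake. Below-MDL constituents propagate intake exactly 0 with status
#' `BELOW_MDL`; constituents without a cigarette sidestream value propagate
#' `NA` in cigarette scenarios.
#'
#' @param scen A [scenario()].
#' @param constituents Named list of [constituent()] objects.
#' @param usage A [usage_model()].
#' @param breathing A [breathing_model()].
#' @param timestep Simulation grid spacing (h). Default `duration/1000`.
#' @return A data.frame of class `intake_result` with columns `constituent`,
#'   `scenario`, `source_kind`, `duration_h`, `avg_concentration_ug_m3`,
#'   `intake_ug`, `limit_intake_ug`, `status`.
#' @export
run_scenario <- function(scen, constituents = default_constituents(),
                         usage = usage_model(), breathing = breathing_model(),
                         timestep = scen$duration / 1000) {
  rows <- lapply(constituents, function(cs) {
    lim <- limit_reference_intake(cs$exposure_limit, breathing)
    rate <- source_rate(cs, scen, usage)
    if (scen$source_kind == "evp" && cs$below_mdl) {
      status <- "BELOW_MDL"; avg <- 0; dose <- 0
    } else if (is.na(rate)) {
      status <- "NA"; avg <- NA_real_; dose <- NA_real_
    } else if (rate == 0) {
      status <- "computed"; avg <- 0; dose <- 0
    } else {
      tr <- simulate_box(scen$volume, scen$ach, continuous_source(rate),
                         scen$duration, timestep = timestep)
      avg <- average_concentration(tr)
      dose <- intake(avg, scen$duration, breathing)
      status <- "computed"
    }
    data.frame(constituent = cs$name, scenario = scen$name,
               source_kind = scen$source_kind, duration_h = scen$duration,
               avg_concentration_ug_m3 = avg, intake_ug = dose,
               limit_intake_ug = lim$intake, status = status,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, make.row.names = FALSE))
  class(out) <- c("intake_result", "data.frame")
  out
}

#' Cigarette-to-EVP fold difference
#'
#' Ratio of the cigarette-derived to the EVP-derived value (intake or source
#' rate) for the same constituent. Under the linear box model this equals
#' the per-user source-rate ratio and does not depend on the space volume,
#' ventilation, duration or number of users. An EVP value of exactly 0
#' (below-MDL constituent) yields `Inf` — an "infinite-fold" reduction.
#'
#' @param cig_value Cigarette-source value (ug or ug/h), nonnegative.
#' @param evp_value EVP-source value on the same scale, nonnegative.
#' @return Dimensionless fold difference.
#' @export
fold_difference <- function(cig_value, evp_value) {
  if (any(is.na(cig_value)) || any(is.na(evp_value)))
    stop("fold difference needs both values")
  if (any(cig_value < 0) || any(evp_value < 0)) stop("values must be >= 0")
  ifelse(evp_value == 0, Inf, cig_value / evp_value)
}

#' Per-user source-rate fold difference for a constituent
#'
#' @param cs A [constituent()] with both emission values.
#' @param usage A [usage_model()].
#' @return Fold difference of per-user cigarette vs EVP source rates.
#' @export
source_fold_difference <- function(cs, usage = usage_model()) {
  if (is.na(cs$sidestream_emission))
    stop("no sidestream emission for ", cs$name)
  cig <- usage$cigarettes_per_hour * cs$sidestream_emission
  evp <- (usage$evp_daily_consumption_mg / usage$evp_use_hours) *
    cs$emission_factor
  fold_difference(cig, evp)
}

#' Calibrate the air-change rate to a target average concentration
#'
#' Solves for the ventilation rate at which the transient time-averaged
#' concentration of a constituent over the scenario duration equals a
#' target. The average is computed through the same simulation and
#' trapezoidal-averaging path as [run_scenario()], and is strictly
#' decreasing in the air-change rate, so a bracketed root find converges; a
#' target at or above the zero-ventilation average `S T / (2V)` is
#' infeasible and raises an error stating the achievable range.
#'
#' @param scen A [scenario()] whose `ach` is ignored.
#' @param cs A [constituent()].
#' @param target_average Target time-averaged concentration (ug/m^3).
#' @param usage A [usage_model()].
#' @param tol Relative tolerance on the recovered rate. Default 1e-6.
#' @param timestep Simulation grid spacing (h).
#' @return Calibrated air-change rate (1/h).
#' @export
calibrate_ach <- function(scen, cs, target_average, usage = usage_model(),
                          tol = 1e-6, timestep = scen$duration / 1000) {
  if (!is.finite(target_average) || target_average <= 0)
    stop("`target_average` must be positive")
  rate <- source_rate(cs, scen, usage)
  if (is.na(rate) || rate <= 0)
    stop("scenario has no positive source for ", cs$name)
  avg_at <- function(l) {
    tr <- simulate_box(scen$volume, l, continuous_source(rate),
                       scen$duration, timestep = timestep)
    average_concentration(tr)
  }
  upper_avg <- rate * scen$duration / (2 * scen$volume)  # ach -> 0 limit
  if (target_average >= upper_avg)
    stop("target unreachable: achievable averages are below ",
         signif(upper_avg, 6), " ug/m^3 (zero-ventilation limit)")
  lo <- 1e-9
  hi <- 1
  while (avg_at(hi) > target_average && hi < 1e6) hi <- hi * 4
  if (hi >= 1e6) stop("target unreachable within the ventilation search range")
  r <- stats::uniroot(function(l) avg_at(l) - target_average, c(lo, hi),
                      tol = tol * max(1, hi))
  r$root
}
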