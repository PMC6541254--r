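#' Sensor-adoption economics: sampling plan, cash flow, NPV
#'
#' The appraisal compares the yearly cost of the destructive ripening
#' protocol (grape destroyed, sampling labor, laboratory anthocyanin
#' assays) with the cost of running the optical sensor over the same
#' protocol.  The yearly saving is the net cash flow; discounting it over
#' the sensor lifetime against the purchase price and periodic
#' maintenance gives the net present value (NPV).
#'
#' @name sensor-economics
NULL

#' Sampling plan for a season
#'
#' Defaults follow the standard protocol: each cultivar is sampled on 6
#' dates with 5 ripening samples per date, plus a harvest assessment of
#' 3 bunches on each of 4 vines (12 bunches) per cultivar.
#'
#' @param n_cultivars number of (red) cultivars monitored.
#' @param n_dates ripening sampling dates per season.
#' @param samples_per_date_per_cultivar ripening samples per date and
#'   cultivar.
#' @param vines_per_cultivar,bunches_per_vine harvest protocol.
#' @param t_ripening_min minutes to collect one destructive ripening
#'   sample.
#' @param t_harvest_min minutes to collect one harvest bunch.
#' @param t_mx_min minutes per optical measurement point.
#' @return a `grapemx_plan` list.
#' @export
sampling_plan <- function(n_cultivars,
                          n_dates = 6L,
                          samples_per_date_per_cultivar = 5L,
                          vines_per_cultivar = 4L,
                          bunches_per_vine = 3L,
                          t_ripening_min = 11,
                          t_harvest_min = 4.5,
                          t_mx_min = 5) {
  for (nm in c("n_cultivars", "n_dates", "samples_per_date_per_cultivar",
               "vines_per_cultivar", "bunches_per_vine")) {
    if (!is_count(get(nm))) {
      stop_grapemx("grapemx_config_error",
                   sprintf("`%s` must be a non-negative integer", nm))
    }
  }
  assert_number(t_ripening_min, "t_ripening_min", lower = 0)
  assert_number(t_harvest_min, "t_harvest_min", lower = 0)
  assert_number(t_mx_min, "t_mx_min", lower = 0)
  structure(list(
    n_cultivars = as.integer(n_cultivars),
    n_dates = as.integer(n_dates),
    samples_per_date_per_cultivar = as.integer(samples_per_date_per_cultivar),
    vines_per_cultivar = as.integer(vines_per_cultivar),
    bunches_per_vine = as.integer(bunches_per_vine),
    t_ripening_min = t_ripening_min,
    t_harvest_min = t_harvest_min,
    t_mx_min = t_mx_min), class = "grapemx_plan")
}

#' Cost parameters for the appraisal
#'
#' Defaults are the published reference values: ripening-sample weight
#' 0.05--0.2 kg, harvest-bunch weight 0.1--0.4 kg, wholesale grape price
#' 0.45--0.60 EUR/kg, labor 8 EUR/h, anthocyanin assay 20 EUR/sample
#' (the 5 EUR/sample sugar assay is recorded but excluded from savings:
#' a refractometer is assumed owned either way), sensor purchase
#' 13,900 EUR, maintenance 1,000 EUR every 3 years, discount rate 2%.
#'
#' @param sample_weight_kg,bunch_weight_kg,grape_price_eur_kg two-element
#'   `c(lower, upper)` ranges.
#' @param labor_eur_h labor cost, EUR per hour.
#' @param anth_lab_eur_sample laboratory anthocyanin assay, EUR/sample.
#' @param tss_lab_eur_sample laboratory sugar assay, EUR/sample (not part
#'   of the saving).
#' @param purchase_eur sensor purchase price.
#' @param maintenance_eur,maintenance_interval_y maintenance charge and
#'   its period in years.
#' @param discount_rate annual discount rate (> -1).
#' @return a `grapemx_costs` list.
#' @export
cost_parameters <- function(sample_weight_kg = c(0.05, 0.2),
                            bunch_weight_kg = c(0.1, 0.4),
                            grape_price_eur_kg = c(0.45, 0.60),
                            labor_eur_h = 8,
                            anth_lab_eur_sample = 20,
                            tss_lab_eur_sample = 5,
                            purchase_eur = 13900,
                            maintenance_eur = 1000,
                            maintenance_interval_y = 3L,
                            discount_rate = 0.02) {
  for (nm in c("sample_weight_kg", "bunch_weight_kg", "grape_price_eur_kg")) {
    rng <- get(nm)
    if (length(rng) != 2L || any(!is.finite(rng)) || rng[1L] > rng[2L] ||
          rng[1L] < 0) {
      stop_grapemx("grapemx_config_error",
                   sprintf("`%s` must be a non-negative range c(lower, upper)",
                           nm))
    }
  }
  assert_number(labor_eur_h, "labor_eur_h", lower = 0)
  assert_number(anth_lab_eur_sample, "anth_lab_eur_sample", lower = 0)
  assert_number(tss_lab_eur_sample, "tss_lab_eur_sample", lower = 0)
  assert_number(purchase_eur, "purchase_eur", lower = 0)
  assert_number(maintenance_eur, "maintenance_eur", lower = 0)
  if (!is_count(maintenance_interval_y) || maintenance_interval_y < 1) {
    stop_grapemx("grapemx_config_error",
                 "`maintenance_interval_y` must be a positive integer")
  }
  assert_number(discount_rate, "discount_rate", lower = -1,
                strict_lower = TRUE)
  structure(list(
    sample_weight_kg = as.numeric(sample_weight_kg),
    bunch_weight_kg = as.numeric(bunch_weight_kg),
    grape_price_eur_kg = as.numeric(grape_price_eur_kg),
    labor_eur_h = labor_eur_h,
    anth_lab_eur_sample = anth_lab_eur_sample,
    tss_lab_eur_sample = tss_lab_eur_sample,
    purchase_eur = purchase_eur,
    maintenance_eur = maintenance_eur,
    maintenance_interval_y = as.integer(maintenance_interval_y),
    discount_rate = discount_rate), class = "grapemx_costs")
}

#' Farm presets
#'
#' `"two-hectare"`: an average-sized Italian vineyard; destructive
#' sampling takes 11 min (ripening) and 4.5 min (harvest bunch), optical
#' points 5 min.  `"mossi"`: a 30-hectare estate growing 6 red cultivars;
#' 20 and 9 min destructive, 9.5 min optical.
#'
#' @param preset `"two-hectare"` or `"mossi"`.
#' @param n_cultivars overrides the preset's cultivar count
#'   (defaults: two-hectare 3, mossi 6).
#' @return a `grapemx_plan`.
#' @export
farm_preset <- function(preset = c("two-hectare", "mossi"),
                        n_cultivars = NULL) {
  if (!is.character(preset) || !preset[1L] %in% c("two-hectare", "mossi")) {
    stop_grapemx("grapemx_config_error",
                 sprintf("unknown farm preset `%s`", preset[1L]))
  }
  preset <- preset[1L]
  switch(preset,
    "two-hectare" = sampling_plan(n_cultivars = n_cultivars %||% 3L,
                                  t_ripening_min = 11, t_harvest_min = 4.5,
                                  t_mx_min = 5),
    "mossi" = sampling_plan(n_cultivars = n_cultivars %||% 6L,
                            t_ripening_min = 20, t_harvest_min = 9,
                            t_mx_min = 9.5))
}

#' Yearly sample counts implied by a plan
#'
#' @param plan a `grapemx_plan`.
#' @return list with `ripening_samples` (dates x samples x cultivars),
#'   `harvest_bunches` (vines x bunches x cultivars),
#'   `total_anth_samples` (their sum, each an anthocyanin assay) and
#'   `per_date_samples`.
#' @export
sample_counts <- function(plan) {
  stopifnot(inherits(plan, "grapemx_plan"))
  ripening <- plan$n_dates * plan$samples_per_date_per_cultivar *
    plan$n_cultivars
  harvest <- plan$vines_per_cultivar * plan$bunches_per_vine *
    plan$n_cultivars
  list(ripening_samples = ripening,
       harvest_bunches = harvest,
       total_anth_samples = ripening + harvest,
       per_date_samples = plan$samples_per_date_per_cultivar *
         plan$n_cultivars)
}

scenario_value <- function(range, scenario) {
  switch(scenario,
         lower = range[1L],
         upper = range[2L],
         average = mean(range))
}

#' Annual net cash flow from adopting the sensor
#'
#' Three saving components make up the yearly cash flow:
#' * grape value no longer destroyed:
#'   `ripening * w_sample * price + bunches * w_bunch * price`, with
#'   weight and price taken at the chosen bound of their ranges;
#' * labor saved: destructive collection time minus one optical point per
#'   replaced sample, at the hourly rate;
#' * laboratory assays avoided: one anthocyanin assay per sample/bunch.
#'
#' @param plan a `grapemx_plan`.
#' @param costs a `grapemx_costs`.
#' @param scenario which bound of the weight/price ranges to use:
#'   `"lower"`, `"upper"` or `"average"`.
#' @return list with `total` (EUR/year) and components `grape_value`,
#'   `labor_saving`, `lab_saving`.
#' @export
annual_net_cash_flow <- function(plan, costs,
                                 scenario = c("average", "lower", "upper")) {
  stopifnot(inherits(plan, "grapemx_plan"), inherits(costs, "grapemx_costs"))
  scenario <- match.arg(scenario)
  cnt <- sample_counts(plan)
  w_sample <- scenario_value(costs$sample_weight_kg, scenario)
  w_bunch <- scenario_value(costs$bunch_weight_kg, scenario)
  price <- scenario_value(costs$grape_price_eur_kg, scenario)

  grape_value <- (cnt$ripening_samples * w_sample +
                    cnt$harvest_bunches * w_bunch) * price
  destructive_min <- cnt$ripening_samples * plan$t_ripening_min +
    cnt$harvest_bunches * plan$t_harvest_min
  optical_min <- cnt$total_anth_samples * plan$t_mx_min
  labor_saving <- (destructive_min - optical_min) * costs$labor_eur_h / 60
  lab_saving <- cnt$total_anth_samples * costs$anth_lab_eur_sample

  list(total = grape_value + labor_saving + lab_saving,
       grape_value = grape_value,
       labor_saving = labor_saving,
       lab_saving = lab_saving,
       scenario = scenario)
}

maintenance_years <- function(lifetime, interval) {
  ys <- seq_len(lifetime)
  ys[ys %% interval == 0L]
}

#' Net present value of the sensor over its lifetime
#'
#' `NPV = -I - sum_m M / (1+r)^m + sum_t C_t / (1+r)^t` with purchase
#' price `I`, maintenance charge `M` falling at the end of every
#' `maintenance_interval_y`-th year of ownership (years `m`), constant
#' annual cash flow `C_t = cash_flow`, and discount rate `r`.  Cash flows
#' occur at end of year; exponents are integers.
#'
#' @param cash_flow annual net cash flow, EUR/year (see
#'   [annual_net_cash_flow()]), or the list that function returns.
#' @param lifetime sensor lifetime `T` in whole years (>= 1).
#' @param costs a `grapemx_costs`.
#' @param scenario label stored on the result.
#' @return a `grapemx_npv` list: `npv_eur`, `lifetime_y`, `cash_flows`
#'   (per-year vector), `scenario`, and `NULL` `mc_summary`.
#' @export
npv <- function(cash_flow, lifetime, costs, scenario = "average") {
  stopifnot(inherits(costs, "grapemx_costs"))
  if (is.list(cash_flow)) cash_flow <- cash_flow$total
  if (!is_count(lifetime) || lifetime < 1) {
    stop_grapemx("grapemx_invalid_lifetime",
                 "`lifetime` must be an integer number of years >= 1")
  }
  lifetime <- as.integer(lifetime)
  r <- costs$discount_rate
  ts <- seq_len(lifetime)
  disc_flows <- cash_flow / (1 + r)^ts
  m_years <- maintenance_years(lifetime, costs$maintenance_interval_y)
  disc_maint <- sum(costs$maintenance_eur / (1 + r)^m_years)
  structure(list(
    npv_eur = -costs$purchase_eur - disc_maint + sum(disc_flows),
    lifetime_y = lifetime,
    cash_flows = rep(cash_flow, lifetime),
    discounted_maintenance = disc_maint,
    scenario = scenario,
    mc_summary = NULL), class = "grapemx_npv")
}

#' @export
print.grapemx_npv <- function(x, ...) {
  cat(sprintf("<NPV: %.2f EUR over %d y (%s scenario)>\n",
              x$npv_eur, x$lifetime_y, x$scenario))
  if (!is.null(x$mc_summary)) {
    s <- x$mc_summary
    cat(sprintf("  Monte Carlo: mean %.2f, sd %.2f, n = %d, t = %.2f, seed = %s\n",
                s$mean, s$sd, s$n_draws, s$t_statistic, format(s$seed)))
  }
  invisible(x)
}

#' Smallest lifetime with positive NPV
#'
#' @inheritParams annual_net_cash_flow
#' @param max_lifetime search bound in years.
#' @return the smallest integer `T <= max_lifetime` with `NPV(T) > 0`, or
#'   `NA_integer_` if none.
#' @export
breakeven_lifetime <- function(plan, costs,
                               scenario = c("average", "lower", "upper"),
                               max_lifetime = 50L) {
  scenario <- match.arg(scenario)
  if (!is_count(max_lifetime) || max_lifetime < 1) {
    stop_grapemx("grapemx_invalid_lifetime",
                 "`max_lifetime` must be a positive integer")
  }
  cf <- annual_net_cash_flow(plan, costs, scenario)
  for (t in seq_len(max_lifetime)) {
    if (npv(cf, t, costs, scenario)$npv_eur > 0) return(as.integer(t))
  }
  NA_integer_
}

#' Monte Carlo NPV under labor-cost and sampling-time uncertainty
#'
#' Labor rate and the three sampling times are uncertain in practice
#' (slope, plot layout, weather).  Each draw samples them from uniform
#' distributions centered on their nominal values with relative
#' half-width `rel_half_width`, rebuilds the cash flow and recomputes the
#' NPV.  Grape weight and price stay at the chosen scenario bound.  With
#' zero half-widths every draw collapses onto the deterministic NPV.
#'
#' @inheritParams annual_net_cash_flow
#' @param lifetime sensor lifetime in years.
#' @param rel_half_width relative half-width of the uniform
#'   distributions (default 0.2, i.e. +/-20%); must be in `[0, 1]`.
#' @param n_draws number of draws (default 1000).
#' @param seed integer RNG seed recorded in the result.
#' @return a `grapemx_npv` whose `npv_eur` is the Monte Carlo mean and
#'   whose `mc_summary` holds `mean`, `sd`, `n_draws`, `t_statistic`
#'   (one-sample vs 0) and `seed`.
#' @export
monte_carlo_npv <- function(plan, costs,
                            scenario = c("average", "lower", "upper"),
                            lifetime = 7L, rel_half_width = 0.2,
                            n_draws = 1000L, seed = 1L) {
  scenario <- match.arg(scenario)
  if (!is.numeric(rel_half_width) || length(rel_half_width) != 1L ||
        !is.finite(rel_half_width) || rel_half_width < 0 ||
        rel_half_width > 1) {
    stop_grapemx("grapemx_invalid_distribution",
                 "`rel_half_width` must lie in [0, 1]")
  }
  if (!is_count(n_draws) || n_draws < 1) {
    stop_grapemx("grapemx_config_error", "`n_draws` must be a positive integer")
  }
  deterministic <- npv(annual_net_cash_flow(plan, costs, scenario),
                       lifetime, costs, scenario)
  if (rel_half_width == 0) {
    npvs <- rep(deterministic$npv_eur, n_draws)
  } else {
    old_seed <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                           globalenv()), add = TRUE)
    set.seed(seed)
    draw <- function(nominal) {
      if (nominal == 0) return(rep(0, n_draws))
      stats::runif(n_draws, nominal * (1 - rel_half_width),
                   nominal * (1 + rel_half_width))
    }
    labor <- draw(costs$labor_eur_h)
    t_rip <- draw(plan$t_ripening_min)
    t_har <- draw(plan$t_harvest_min)
    t_mx <- draw(plan$t_mx_min)
    npvs <- vapply(seq_len(n_draws), function(i) {
      plan_i <- plan
      plan_i$t_ripening_min <- t_rip[i]
      plan_i$t_harvest_min <- t_har[i]
      plan_i$t_mx_min <- t_mx[i]
      costs_i <- costs
      costs_i$labor_eur_h <- labor[i]
      npv(annual_net_cash_flow(plan_i, costs_i, scenario),
          lifetime, costs_i, scenario)$npv_eur
    }, numeric(1))
  }
  m <- mean(npvs)
  s <- stats::sd(npvs)
  out <- deterministic
  out$npv_eur <- m
  out$mc_summary <- list(
    mean = m, sd = s, n_draws = as.integer(n_draws),
    t_statistic = if (s > 0) m / (s / sqrt(n_draws)) else Inf * sign(m),
    seed = as.integer(seed),
    deterministic_npv = deterministic$npv_eur)
  out
}

#' Sensitivity of the appraisal to sampling time
#'
#' Two stress tests: (a) scale all three sampling times (with and
#' without the sensor) by a common factor `k`; (b) equalize the optical
#' time with the destructive times at a single value `tau`, removing the
#' labor saving entirely.  For each setting the NPV at `lifetime` years
#' and the breakeven lifetime are reported.
#'
#' @inheritParams annual_net_cash_flow
#' @param scale_grid common multipliers `k` (>= 0).
#' @param equalized_time_grid common sampling times `tau` in minutes
#'   (>= 0, conventionally up to 30).
#' @param lifetime lifetime at which NPV is reported.
#' @param max_lifetime breakeven search bound.
#' @return a data frame with columns `setting` (`"scale"` or
#'   `"equalized"`), `value` (`k` or `tau`), `npv_eur`, `breakeven_y`.
#' @export
sensitivity_sampling_time <- function(plan, costs,
                                      scenario = c("average", "lower",
                                                   "upper"),
                                      scale_grid = c(0.5, 1, 2),
                                      equalized_time_grid = seq(5, 30, by = 5),
                                      lifetime = 7L, max_lifetime = 50L) {
  scenario <- match.arg(scenario)
  if (length(scale_grid) == 0L || length(equalized_time_grid) == 0L ||
        any(scale_grid < 0) || any(equalized_time_grid < 0)) {
    stop_grapemx("grapemx_config_error",
                 "grids must be non-empty and non-negative")
  }
  eval_plan <- function(p, setting, value) {
    data.frame(
      setting = setting, value = value,
      npv_eur = npv(annual_net_cash_flow(p, costs, scenario), lifetime,
                    costs, scenario)$npv_eur,
      breakeven_y = breakeven_lifetime(p, costs, scenario, max_lifetime),
      stringsAsFactors = FALSE)
  }
  rows <- lapply(scale_grid, function(k) {
    p <- plan
    p$t_ripening_min <- plan$t_ripening_min * k
    p$t_harvest_min <- plan$t_harvest_min * k
    p$t_mx_min <- plan$t_mx_min * k
    eval_plan(p, "scale", k)
  })
  rows <- c(rows, lapply(equalized_time_grid, function(tau) {
    p <- plan
    p$t_ripening_min <- tau
    p$t_harvest_min <- tau
    p$t_mx_min <- tau
    eval_plan(p, "equalized", tau)
  }))
  do.call(rbind, rows)
}

#' Scenario grid report: NPV and breakeven per cost scenario
#'
#' @inheritParams annual_net_cash_flow
#' @param lifetime lifetime at which NPV is reported.
#' @param max_lifetime breakeven search bound.
#' @return data frame with one row per scenario (`lower`, `upper`,
#'   `average`): annual cash flow, NPV at `lifetime`, breakeven.
#' @export
npv_report <- function(plan, costs, lifetime = 7L, max_lifetime = 50L) {
  do.call(rbind, lapply(c("lower", "upper", "average"), function(sc) {
    cf <- annual_net_cash_flow(plan, costs, sc)
    data.frame(
      scenario = sc,
      cash_flow_eur_y = cf$total,
      npv_eur = npv(cf, lifetime, costs, sc)$npv_eur,
      lifetime_y = as.integer(lifetime),
      breakeven_y = breakeven_lifetime(plan, costs, sc, max_lifetime),
      stringsAsFactors = FALSE)
  }))
}
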