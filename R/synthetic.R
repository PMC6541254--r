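#' Published calibration anchors
#'
#' The calibration equations published for the five-cultivar field study,
#' as `grapemx_calibration` objects (coefficients, coefficient of
#' determination and sample size as printed).  Orientation follows the
#' package contract: `x` is the fluorescence index for the
#' anthocyanin-index models (`anth_ferari*`), the chemistry value for the
#' forward models (`anth_rg*`: x = anthocyanin; `sfr_tss`: x = TSS;
#' `flav_uv`: x = flavonols), and the north-east-side reading for the
#' cluster-side relations (`side`).
#'
#' Two published captions carry typographic defects that are resolved
#' here: the Ortrugo sugar model omits the "x" after its slope (read as
#' slope -0.0205), and the berry-basis Barbera anthocyanin quartic is
#' stored with a positive linear term (+1.2373), the only sign choice
#' that reproduces the described curve shape (index peak at 0.5--1.0
#' mg/g, decline toward zero by 1.5--2.2 mg/g).
#'
#' @return a nested named list of `grapemx_calibration` objects:
#'   `anth_ferari`, `anth_ferari_skin`, `anth_rg`, `anth_rg_skin`
#'   (per red/pink cultivar), `sfr_tss` (per cultivar), `flav_uv`
#'   (`pooled`, `barbera`, `ervi`) and `side` (per index).
#' @export
printed_calibration_models <- function() {
  lin <- function(slope, intercept, x, y, r2, n, domain = NULL) {
    new_calibration_model("linear", c(slope, intercept), x, y, r2, n,
                          domain = domain)
  }
  quad <- function(coefs, x, y, r2, n) {
    new_calibration_model("polynomial", coefs, x, y, r2, n, degree = 2L)
  }
  quart <- function(coefs, x, y, r2, n) {
    new_calibration_model("polynomial", coefs, x, y, r2, n, degree = 4L)
  }
  sig <- function(a, b, c, x, y, r2, n) {
    new_calibration_model("sigmoid", c(a, b, c), x, y, r2, n)
  }
  tss_dom <- list(variable = "tss", lower = 10, upper = Inf)
  list(
    anth_ferari = list(
      malvasia_r = lin(3.7167, -0.1982, "ferari", "anth_berry", 0.84, 27),
      barbera = sig(1.55, 4.005, 5.261, "ferari", "anth_berry", 0.99, 27),
      ervi = sig(1.47, 4.132, 5.906, "ferari", "anth_berry", 0.97, 27)),
    anth_ferari_skin = list(
      malvasia_r = lin(0.313, -0.1403, "ferari", "anth_skin", 0.64, 27),
      barbera = sig(1.533, 4.690, 0.635, "ferari", "anth_skin", 0.99, 27),
      ervi = sig(1.471, 11.064, 1.088, "ferari", "anth_skin", 0.98, 27)),
    anth_rg = list(
      malvasia_r = lin(2.6675, -0.0891, "anth_berry", "anth_rg", 0.82, 27),
      barbera = quart(c(-0.102, 0.7315, -1.6365, 1.2373, -0.102),
                      "anth_berry", "anth_rg", 0.85, 27),
      ervi = quart(c(-0.0081, 0.2422, -0.8925, 0.9441, -0.1142),
                   "anth_berry", "anth_rg", 0.91, 27)),
    anth_rg_skin = list(
      malvasia_r = lin(0.2527, -0.0893, "anth_skin", "anth_rg", 0.79, 27),
      barbera = quart(c(-3e-05, 0.0018, -0.0319, 0.1946, -0.1191),
                      "anth_skin", "anth_rg", 0.94, 27),
      ervi = quart(c(-4e-06, 4e-04, -0.0106, 0.1057, -0.1238),
                   "anth_skin", "anth_rg", 0.91, 27)),
    sfr_tss = list(
      ortrugo = lin(-0.0205, 0.8906, "tss", "sfr_r", 0.71, 12, tss_dom),
      malvasia_ca = lin(-0.0096, 0.7476, "tss", "sfr_r", 0.50, 12, tss_dom),
      malvasia_r = lin(-0.0144, 0.8405, "tss", "sfr_r", 0.68, 21, tss_dom),
      barbera = lin(-0.063, 0.7375, "tss", "sfr_r", 0.04, 21, tss_dom),
      ervi = lin(-0.0112, 0.8398, "tss", "sfr_r", 0.37, 21, tss_dom)),
    flav_uv = list(
      pooled = quad(c(-0.1105, 0.7613, 0.628),
                    "flavonols_skin", "flav_uv", 0.35, 41),
      barbera = quad(c(-0.1331, 0.5898, 1.589),
                     "flavonols_skin", "flav_uv", 0.66, 9),
      ervi = quad(c(-0.0886, 0.2592, 2.5412),
                  "flavonols_skin", "flav_uv", 0.64, 9)),
    side = list(
      anth_rg = lin(0.8537, 0.0014, "anth_rg_ne", "anth_rg_sw", 0.94, 27),
      ferari = lin(0.9131, 0.0026, "ferari_ne", "ferari_sw", 0.97, 27),
      flav_uv = lin(0.951, 0.0433, "flav_uv_ne", "flav_uv_sw", 0.95, 41),
      sfr_r = lin(0.7180, 0.1372, "sfr_r_ne", "sfr_r_sw", 0.75, 41)))
}

#' Cultivar profiles for the synthetic season
#'
#' A profile anchors the seasonal trajectory generator: harvest values of
#' the ripening variables (sugar, acidity, pH, malate, anthocyanins,
#' flavonols, phenols, berry mass, skin-to-berry ratio), the onset
#' values, logistic shape parameters, and which published calibration
#' equations drive channel synthesis.
#'
#' @param name cultivar label.
#' @param color `"white"`, `"pink"` or `"red"` (whites have
#'   `anth_max_berry = 0`).
#' @param tss_onset,tss_harvest degrees Brix at veraison onset and
#'   harvest (`tss_onset < tss_harvest`).
#' @param ta_initial,ta_harvest titratable acidity, g/L tartaric
#'   equivalents.
#' @param ph_initial,ph_harvest must pH.
#' @param malic_initial,malic_harvest malic acid, g/L.
#' @param anth_max_berry harvest total anthocyanins, mg/g fresh berry.
#' @param flavonols_harvest total flavonols, mg/g dry skin.
#' @param phenols_harvest total phenolics, mg/g fresh berry.
#' @param berry_mass_harvest g per berry.
#' @param skin_pct_harvest skin-to-berry fresh-mass ratio at harvest, %.
#' @param doy_onset,doy_harvest day-of-year window of the simulated
#'   season.
#' @param midpoint_doy,rate logistic midpoint (DOY) and steepness shared
#'   by the rising variables; acid decay mirrors them.
#' @param anth_midpoint_doy,anth_rate logistic parameters of pigment
#'   accumulation.
#' @param calib_anth,calib_sfr,calib_flav keys into
#'   [printed_calibration_models()] selecting the channel-synthesis
#'   models (`calib_sfr = NA` draws the sugar ratio from the
#'   pre-threshold variability band instead, used where no sugar model
#'   was significant).
#' @param channel_sigma multiplicative log-normal channel noise (sdlog).
#' @param chem_sd named additive-noise standard deviations for the
#'   chemistry variables.
#' @return a `grapemx_profile` list.
#' @export
cultivar_profile <- function(name, color = c("red", "white", "pink"),
                             tss_onset = 5, tss_harvest = 24,
                             ta_initial = 28, ta_harvest = 6,
                             ph_initial = 2.6, ph_harvest = 3.1,
                             malic_initial = 12, malic_harvest = 0.8,
                             anth_max_berry = 0, flavonols_harvest = 1.5,
                             phenols_harvest = 2.5,
                             berry_mass_harvest = 1.7,
                             skin_pct_harvest = 9.5,
                             doy_onset = 190, doy_harvest = 249,
                             midpoint_doy = 210, rate = 0.25,
                             anth_midpoint_doy = 215, anth_rate = 0.2,
                             calib_anth = "malvasia_r",
                             calib_sfr = name, calib_flav = "pooled",
                             channel_sigma = 0.03,
                             chem_sd = NULL) {
  color <- match.arg(color)
  if (tss_onset >= tss_harvest) {
    stop_grapemx("grapemx_config_error", "`tss_onset` must be < `tss_harvest`")
  }
  if (anth_max_berry < 0) {
    stop_grapemx("grapemx_config_error", "`anth_max_berry` must be >= 0")
  }
  if (skin_pct_harvest <= 0 || skin_pct_harvest >= 100) {
    stop_grapemx("grapemx_config_error",
                 "`skin_pct_harvest` must lie in (0, 100)")
  }
  default_sd <- list(tss = 0.4, ta = 0.3, ph = 0.03, malic = 0.15,
                     anth = 0.05, flavonols = 0.08, phenols = 0.1,
                     berry_mass = 0.05, skin_pct = 0.25)
  chem_sd <- utils::modifyList(default_sd, chem_sd %||% list())
  structure(list(
    name = name, color = color,
    tss_onset = tss_onset, tss_harvest = tss_harvest,
    ta_initial = ta_initial, ta_harvest = ta_harvest,
    ph_initial = ph_initial, ph_harvest = ph_harvest,
    malic_initial = malic_initial, malic_harvest = malic_harvest,
    anth_max_berry = anth_max_berry,
    flavonols_harvest = flavonols_harvest,
    phenols_harvest = phenols_harvest,
    berry_mass_harvest = berry_mass_harvest,
    skin_pct_harvest = skin_pct_harvest,
    doy_onset = doy_onset, doy_harvest = doy_harvest,
    midpoint_doy = midpoint_doy, rate = rate,
    anth_midpoint_doy = anth_midpoint_doy, anth_rate = anth_rate,
    calib_anth = calib_anth, calib_sfr = calib_sfr,
    calib_flav = calib_flav,
    channel_sigma = channel_sigma, chem_sd = chem_sd),
    class = "grapemx_profile")
}

#' Five preset cultivar profiles
#'
#' Anchored to the published harvest table of the five-cultivar study:
#' two whites (Ortrugo-like 22.3 Brix, Malvasia C.a.-like 19.9), one pink
#' (Malvasia R.-like, 0.20 mg/g anthocyanins) and two reds (Barbera-like
#' 1.68 mg/g, Ervi-like 1.91 mg/g).  Whites were picked earlier
#' (DOY 233) than the colored cultivars (DOY 249).  No sugar model was
#' significant for the Barbera-like profile, so its fluorescence ratio is
#' drawn from the pre-threshold variability band.
#'
#' @return named list of `grapemx_profile` objects: `ortrugo`,
#'   `malvasia_ca`, `malvasia_r`, `barbera`, `ervi`.
#' @export
cultivar_presets <- function() {
  list(
    ortrugo = cultivar_profile(
      "ortrugo", "white", tss_harvest = 22.3, ta_harvest = 4.96,
      ph_harvest = 3.14, malic_harvest = 0.23, anth_max_berry = 0,
      flavonols_harvest = 1.35, phenols_harvest = 1.93,
      berry_mass_harvest = 1.81, skin_pct_harvest = 8.96,
      doy_harvest = 233),
    malvasia_ca = cultivar_profile(
      "malvasia_ca", "white", tss_harvest = 19.9, ta_harvest = 6.38,
      ph_harvest = 2.95, malic_harvest = 0.57, anth_max_berry = 0,
      flavonols_harvest = 1.19, phenols_harvest = 2.50,
      berry_mass_harvest = 1.69, skin_pct_harvest = 8.70,
      doy_harvest = 233),
    malvasia_r = cultivar_profile(
      "malvasia_r", "pink", tss_harvest = 22.9, ta_harvest = 6.04,
      ph_harvest = 3.17, malic_harvest = 0.86, anth_max_berry = 0.20,
      flavonols_harvest = 0.68, phenols_harvest = 2.23,
      berry_mass_harvest = 1.95, skin_pct_harvest = 9.08,
      calib_anth = "malvasia_r"),
    barbera = cultivar_profile(
      "barbera", "red", tss_harvest = 27.2, ta_harvest = 9.21,
      ph_harvest = 3.07, malic_harvest = 0.88, anth_max_berry = 1.68,
      flavonols_harvest = 2.11, phenols_harvest = 2.89,
      berry_mass_harvest = 1.62, skin_pct_harvest = 9.82,
      calib_anth = "barbera", calib_sfr = NA_character_,
      calib_flav = "barbera"),
    ervi = cultivar_profile(
      "ervi", "red", tss_harvest = 26.7, ta_harvest = 6.67,
      ph_harvest = 3.19, malic_harvest = 1.11, anth_max_berry = 1.91,
      flavonols_harvest = 2.84, phenols_harvest = 3.78,
      berry_mass_harvest = 1.47, skin_pct_harvest = 9.35,
      calib_anth = "ervi", calib_flav = "ervi"))
}

logistic_curve <- function(doy, lower, upper, midpoint, rate) {
  lower + (upper - lower) / (1 + exp(-rate * (doy - midpoint)))
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  }
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())),
          add = TRUE)
  set.seed(seed)
  expr
}

#' Simulate a season of destructive ripening samples
#'
#' Each ripening variable follows a single logistic trajectory between
#' its onset and harvest anchors (acids and malate decay, the rest rise);
#' the skin-to-berry ratio drifts linearly to its harvest anchor within
#' 8--13%.  Skin-basis anthocyanins are derived from the berry-basis
#' value through the ratio, so the two bases stay exactly consistent.
#' Replicates add Gaussian noise; the same seed reproduces the same
#' table.
#'
#' @param profile a `grapemx_profile`.
#' @param dates ascending day-of-year vector (default: 9 dates from
#'   onset to harvest, giving 27 samples at 3 replicates, the sample
#'   size of the published per-cultivar fits).
#' @param n_replicates replicate samples per date.
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @param noise_scale multiplier on the profile's chemistry noise
#'   standard deviations (0 gives the noiseless trajectory).
#' @return a data frame of ripening samples: `cultivar`, `doy`,
#'   `replicate`, `tss`, `ta`, `ph`, `malic`, `anth_berry`, `anth_skin`,
#'   `phenols_berry`, `flavonols_skin`, `berry_mass`,
#'   `skin_to_berry_pct`.
#' @export
simulate_season <- function(profile, dates = NULL, n_replicates = 3L,
                            seed = NULL, noise_scale = 1) {
  stopifnot(inherits(profile, "grapemx_profile"))
  if (is.null(dates)) {
    dates <- round(seq(profile$doy_onset, profile$doy_harvest, length.out = 9))
  }
  if (length(dates) == 0L) {
    return(empty_season_frame())
  }
  if (is.unsorted(dates)) {
    stop_grapemx("grapemx_config_error", "`dates` must be ascending")
  }
  if (!is_count(n_replicates) || n_replicates < 1) {
    stop_grapemx("grapemx_config_error",
                 "`n_replicates` must be a positive integer")
  }
  p <- profile
  doy <- rep(dates, each = n_replicates)
  replicate <- rep(seq_len(n_replicates), times = length(dates))
  rise <- function(lo, hi) logistic_curve(doy, lo, hi, p$midpoint_doy, p$rate)
  base <- data.frame(
    cultivar = p$name, doy = as.integer(doy), replicate = replicate,
    tss = rise(p$tss_onset, p$tss_harvest),
    ta = logistic_curve(doy, p$ta_harvest, p$ta_initial,
                        p$midpoint_doy, -p$rate),
    ph = rise(p$ph_initial, p$ph_harvest),
    malic = logistic_curve(doy, p$malic_harvest, p$malic_initial,
                           p$midpoint_doy, -p$rate),
    anth_berry = logistic_curve(doy, 0, p$anth_max_berry,
                                p$anth_midpoint_doy, p$anth_rate),
    phenols_berry = rise(p$phenols_harvest * 0.5, p$phenols_harvest),
    flavonols_skin = rise(p$flavonols_harvest * 0.3, p$flavonols_harvest),
    berry_mass = rise(p$berry_mass_harvest * 0.45, p$berry_mass_harvest),
    stringsAsFactors = FALSE)
  # linear skin-ratio drift ending at the harvest anchor, kept in 8-13%
  span <- max(p$doy_harvest - p$doy_onset, 1)
  frac <- (doy - p$doy_onset) / span
  skin_start <- min(13, p$skin_pct_harvest + 2.5)
  base$skin_to_berry_pct <- pmin(13, pmax(8,
    skin_start + (p$skin_pct_harvest - skin_start) * frac))

  out <- with_seed(seed, {
    if (noise_scale > 0) {
      sd <- p$chem_sd
      jiggle <- function(v, s) pmax(v + stats::rnorm(length(v),
                                                     0, s * noise_scale), 0)
      base$tss <- jiggle(base$tss, sd$tss)
      base$ta <- jiggle(base$ta, sd$ta)
      base$ph <- jiggle(base$ph, sd$ph)
      base$malic <- jiggle(base$malic, sd$malic)
      base$anth_berry <- if (p$anth_max_berry > 0) {
        jiggle(base$anth_berry, sd$anth)
      } else {
        base$anth_berry
      }
      base$phenols_berry <- jiggle(base$phenols_berry, sd$phenols)
      base$flavonols_skin <- jiggle(base$flavonols_skin, sd$flavonols)
      base$berry_mass <- jiggle(base$berry_mass, sd$berry_mass)
      base$skin_to_berry_pct <- pmin(13, pmax(8,
        base$skin_to_berry_pct + stats::rnorm(nrow(base), 0,
                                              sd$skin_pct * noise_scale)))
    }
    base
  })
  out$anth_skin <- convert_anth_basis(out$anth_berry, out$skin_to_berry_pct)
  out[, c("cultivar", "doy", "replicate", "tss", "ta", "ph", "malic",
          "anth_berry", "anth_skin", "phenols_berry", "flavonols_skin",
          "berry_mass", "skin_to_berry_pct")]
}

empty_season_frame <- function() {
  data.frame(cultivar = character(), doy = integer(), replicate = integer(),
             tss = numeric(), ta = numeric(), ph = numeric(),
             malic = numeric(), anth_berry = numeric(),
             anth_skin = numeric(), phenols_berry = numeric(),
             flavonols_skin = numeric(), berry_mass = numeric(),
             skin_to_berry_pct = numeric(), stringsAsFactors = FALSE)
}

#' Synthesize fluorescence channels from ripening chemistry
#'
#' Inverts the published calibration equations: the anthocyanin index
#' FERARI is obtained by inverting the profile's anthocyanin model at the
#' sample's concentration (values at or above 99% of a sigmoid asymptote
#' are clipped there, with a warning); the red/green anthocyanin index
#' and the flavonol index are the forward model values; the simple
#' fluorescence ratio comes from the sugar model above the
#' `tss_threshold` and is drawn uniformly from the pre-threshold
#' variability band (0.5--1.1) below it, or always for profiles without a
#' significant sugar model.  The four indices determine the four
#' channels, which then receive multiplicative log-normal noise.
#'
#' At zero noise, recomputing indices from the returned channels
#' reproduces the model-implied index values to within numerical
#' round-off.
#'
#' @param samples ripening-sample data frame (see [simulate_season()]).
#' @param profile the `grapemx_profile` the samples came from.
#' @param models calibration set, default [printed_calibration_models()].
#' @param seed integer seed, or `NULL`.
#' @param channel_sigma sdlog of the log-normal channel noise (default
#'   from the profile; 0 disables noise).
#' @param tss_threshold sugar-model validity threshold, degrees Brix.
#' @return a fluorescence record data frame (`cultivar`, `doy`,
#'   `replicate`, `cluster_side`, four channels).
#' @export
synthesize_fluorescence <- function(samples, profile,
                                    models = printed_calibration_models(),
                                    seed = NULL, channel_sigma = NULL,
                                    tss_threshold = 10) {
  stopifnot(inherits(profile, "grapemx_profile"))
  channel_sigma <- channel_sigma %||% profile$channel_sigma
  n <- nrow(samples)
  if (n == 0L) {
    return(fluorescence_record(numeric(), numeric(), numeric(), numeric()))
  }
  anth_model <- models$anth_ferari[[profile$calib_anth]]
  if (is.null(anth_model)) {
    stop_grapemx("grapemx_config_error",
                 sprintf("no anthocyanin model `%s`", profile$calib_anth))
  }
  flav_model <- models$flav_uv[[profile$calib_flav]] %||%
    models$flav_uv$pooled

  anth <- samples$anth_berry
  if (anth_model$family == "sigmoid") {
    cap <- 0.99 * anth_model$coefficients[1L]
    n_clip <- sum(anth >= cap)
    if (n_clip > 0L) {
      warning(sprintf(
        "%d anthocyanin value(s) at or above the sigmoid asymptote were clipped to %.4g mg/g",
        n_clip, cap), call. = FALSE)
    }
    # below the model's sensitivity floor, the index sits at its zero
    # baseline: clip to the sigmoid value at index 0
    floor_y <- predict(anth_model, 0)
    anth <- pmin(pmax(anth, floor_y), cap)
  }
  ferari <- invert_calibration(anth_model, anth)
  # the red/green index model covers the full concentration range; it is
  # evaluated at the unclipped value
  anth_rg_model <- models$anth_rg[[profile$calib_anth]]
  anth_rg <- predict(anth_rg_model, samples$anth_berry)
  flav_uv <- predict(flav_model, samples$flavonols_skin)

  with_seed(seed, {
    sfr <- stats::runif(n, 0.5, 1.1)  # pre-threshold variability band
    sfr_key <- profile$calib_sfr
    if (!is.na(sfr_key)) {
      sfr_model <- models$sfr_tss[[sfr_key]]
      if (is.null(sfr_model)) {
        stop_grapemx("grapemx_config_error",
                     sprintf("no sugar model `%s`", sfr_key))
      }
      in_dom <- samples$tss >= tss_threshold
      sfr[in_dom] <- pmax(predict(sfr_model, samples$tss[in_dom]), 0.05)
    }
    idx <- data.frame(
      cultivar = samples$cultivar, doy = as.integer(samples$doy),
      replicate = samples$replicate, cluster_side = "unspecified",
      ferari = ferari, anth_rg = anth_rg, flav_uv = flav_uv, sfr_r = sfr,
      stringsAsFactors = FALSE)
    rec <- channels_from_indices(idx)
    if (channel_sigma > 0) {
      for (ch in CHANNEL_COLS) {
        rec[[ch]] <- rec[[ch]] * stats::rlnorm(n, 0, channel_sigma)
      }
    }
    rec[, c("cultivar", "doy", "replicate", "cluster_side", CHANNEL_COLS)]
  })
}

#' Pair readings across opposite cluster sides
#'
#' Treats the input records as north-east-side readings, maps each index
#' through its published side-concordance relation (plus optional
#' Gaussian index noise) to build the matching south-west reading, and
#' back-converts to channels.
#'
#' @param records fluorescence record data frame.
#' @param side_models named list of linear `grapemx_calibration` for
#'   `anth_rg`, `ferari`, `flav_uv`, `sfr_r` (default: the published
#'   relations).
#' @param noise_sd additive Gaussian noise on the mapped index values.
#' @param seed integer seed, or `NULL`.
#' @return a data frame with both sides (`cluster_side` `"NE"`/`"SW"`)
#'   and a shared `pair_id`.
#' @export
simulate_cluster_sides <- function(records,
                                   side_models =
                                     printed_calibration_models()$side,
                                   noise_sd = 0, seed = NULL) {
  needed <- c("anth_rg", "ferari", "flav_uv", "sfr_r")
  missing_rel <- setdiff(needed, names(side_models))
  if (length(missing_rel)) {
    stop_grapemx("grapemx_config_error",
                 paste("missing side relation(s):",
                       paste(missing_rel, collapse = ", ")))
  }
  slopes <- vapply(side_models[needed],
                   function(m) m$coefficients[1L], numeric(1))
  if (any(slopes <= 0)) {
    stop_grapemx("grapemx_config_error",
                 "side-relation slopes must be positive")
  }
  ne <- compute_indices(records)
  ne$pair_id <- seq_len(nrow(ne))
  ne$cluster_side <- "NE"
  with_seed(seed, {
    sw <- ne
    sw$cluster_side <- "SW"
    for (ix in needed) {
      m <- side_models[[ix]]
      mapped <- predict(m, ne[[ix]])
      if (noise_sd > 0) {
        mapped <- mapped + stats::rnorm(nrow(ne), 0, noise_sd)
      }
      sw[[ix]] <- mapped
    }
    sw$sfr_r <- pmax(sw$sfr_r, 1e-6)
    sw <- channels_from_indices(sw)
    sw <- compute_indices(sw)  # refresh flav after channel rebuild
    rbind(ne, sw[, names(ne)])
  })
}
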