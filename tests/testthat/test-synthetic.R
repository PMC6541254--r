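presets <- cultivar_presets()
models <- printed_calibration_models()

test_that("season simulation is seed-deterministic and anchored at harvest", {
  a <- simulate_season(presets$barbera, seed = 31L)
  b <- simulate_season(presets$barbera, seed = 31L)
  expect_identical(a, b)
  c2 <- simulate_season(presets$barbera, seed = 32L)
  expect_false(identical(a, c2))

  final <- a[a$doy == max(a$doy), ]
  expect_equal(mean(final$tss), 27.2, tolerance = 0.5)
  expect_equal(nrow(a), 27)  # 9 dates x 3 replicates
  expect_equal(nrow(simulate_season(presets$barbera, dates = integer())), 0)
})

test_that("white profiles accumulate no anthocyanin, reds rise toward their maximum", {
  w <- simulate_season(presets$ortrugo, seed = 1L, noise_scale = 0)
  expect_true(all(w$anth_berry == 0))
  expect_true(all(w$anth_skin == 0))
  r <- simulate_season(presets$ervi, seed = 1L, noise_scale = 0)
  expect_equal(max(r$anth_berry), 1.91, tolerance = 0.05)
})

test_that("zero-noise trajectories are monotone and both anthocyanin bases stay consistent", {
  for (nm in c("barbera", "malvasia_r")) {
    s <- simulate_season(presets[[nm]], n_replicates = 1L, noise_scale = 0)
    expect_true(all(diff(s$tss) >= 0))
    expect_true(all(diff(s$anth_berry) >= 0))
    expect_true(all(diff(s$ta) <= 0))
    expect_true(all(diff(s$malic) <= 0))
  }
  s <- simulate_season(presets$barbera, seed = 8L)  # with noise
  expect_equal(s$anth_skin * s$skin_to_berry_pct / 100, s$anth_berry,
               tolerance = 1e-12)
  pos <- s$anth_berry > 0
  expect_lt(max(abs(s$anth_skin[pos] / s$anth_berry[pos] -
                      100 / s$skin_to_berry_pct[pos])), 1e-9)
  expect_true(all(s$skin_to_berry_pct >= 8 & s$skin_to_berry_pct <= 13))
})

test_that("channel synthesis inverts the printed models exactly at zero noise", {
  # anthocyanin 0.5 mg/g through the red sigmoid: closed-form index value
  s <- simulate_season(presets$barbera, n_replicates = 1L, noise_scale = 0)
  s <- s[1, ]
  s$anth_berry <- 0.5
  s$tss <- 20
  rec <- synthesize_fluorescence(s, presets$barbera, seed = 3L,
                                 channel_sigma = 0)
  idx <- compute_indices(rec)
  expect_equal(idx$ferari, 0.62024, tolerance = 1e-4)
  expect_equal(rec$frf_r, 10^(-0.62024), tolerance = 1e-4)

  # white profile at 20 Brix: sugar model gives the fluorescence ratio directly
  w <- simulate_season(presets$ortrugo, n_replicates = 1L, noise_scale = 0)
  w <- w[1, ]
  w$tss <- 20
  recw <- synthesize_fluorescence(w, presets$ortrugo, seed = 3L,
                                  channel_sigma = 0)
  expect_equal(compute_indices(recw)$sfr_r, -0.0205 * 20 + 0.8906,
               tolerance = 1e-9)
})

test_that("index round-trip through channels is exact and channels stay positive", {
  for (nm in names(presets)) {
    s <- simulate_season(presets[[nm]], seed = 21L)
    rec <- suppressWarnings(
      synthesize_fluorescence(s, presets[[nm]], seed = 22L))
    ch <- as.matrix(rec[, c("frf_r", "frf_g", "frf_uv", "rf_r")])
    expect_true(all(ch > 0), label = paste(nm, "channels positive"))
  }
  # zero noise: model-implied indices are reproduced to round-off
  s <- simulate_season(presets$ervi, seed = 5L, noise_scale = 0)
  keep <- in_sigmoid_range(models$anth_ferari$ervi, s$anth_berry)
  rec <- suppressWarnings(
    synthesize_fluorescence(s, presets$ervi, seed = 6L, channel_sigma = 0))
  idx <- compute_indices(rec)
  expect_equal(idx$ferari[keep],
               invert_calibration(models$anth_ferari$ervi,
                                  s$anth_berry[keep]),
               tolerance = 1e-9)
  expect_equal(idx$anth_rg[keep],
               predict(models$anth_rg$ervi, s$anth_berry[keep]),
               tolerance = 1e-9)
  expect_equal(idx$flav_uv,
               predict(models$flav_uv$ervi, s$flavonols_skin),
               tolerance = 1e-9)
})

test_that("anthocyanin above the sigmoid asymptote is clipped with a warning, never an error", {
  s <- simulate_season(presets$barbera, n_replicates = 1L, noise_scale = 0)
  expect_warning(
    synthesize_fluorescence(s, presets$barbera, seed = 9L),
    regexp = "clipped")
  s_low <- s[s$anth_berry < 1.5, ]
  expect_silent(suppressMessages(
    synthesize_fluorescence(s_low, presets$barbera, seed = 9L)))
})

test_that("full chain at zero noise recovers the generating models' coefficients", {
  for (nm in c("barbera", "ervi", "malvasia_r")) {
    p <- presets[[nm]]
    anth_m <- models$anth_ferari[[p$calib_anth]]
    s <- simulate_season(p, seed = 41L, noise_scale = 0)
    rec <- suppressWarnings(
      synthesize_fluorescence(s, p, seed = 42L, channel_sigma = 0))
    idx <- compute_indices(rec)
    in_range <- in_sigmoid_range(anth_m, s$anth_berry)
    fit_anth <- if (anth_m$family == "sigmoid") {
      fit_sigmoid(idx$ferari[in_range], s$anth_berry[in_range])
    } else {
      fit_linear(idx$ferari[in_range], s$anth_berry[in_range])
    }
    expect_equal(fit_anth$coefficients, anth_m$coefficients,
                 tolerance = 1e-4, label = paste(nm, "anthocyanin model"))

    rg_m <- models$anth_rg[[p$calib_anth]]
    fit_rg <- if (rg_m$family == "linear") {
      fit_linear(s$anth_berry, idx$anth_rg)
    } else {
      fit_polynomial(s$anth_berry, idx$anth_rg, 4)
    }
    expect_equal(fit_rg$coefficients, rg_m$coefficients, tolerance = 1e-4,
                 label = paste(nm, "red/green anthocyanin model"))

    flav_m <- models$flav_uv[[p$calib_flav]]
    fit_fl <- fit_polynomial(s$flavonols_skin, idx$flav_uv, 2)
    expect_equal(fit_fl$coefficients, flav_m$coefficients, tolerance = 1e-4,
                 label = paste(nm, "flavonol model"))

    if (!is.na(p$calib_sfr)) {
      sfr_m <- models$sfr_tss[[p$calib_sfr]]
      dom <- s$tss >= 10
      fit_s <- fit_linear(s$tss[dom], idx$sfr_r[dom])
      expect_equal(fit_s$coefficients, sfr_m$coefficients, tolerance = 1e-4,
                   label = paste(nm, "sugar model"))
    }
  }
})

test_that("cluster-side pairing is deterministic and recovers the printed side relations", {
  s <- simulate_season(presets$ervi, seed = 51L, noise_scale = 0)
  rec <- suppressWarnings(
    synthesize_fluorescence(s, presets$ervi, seed = 52L, channel_sigma = 0))
  a <- simulate_cluster_sides(rec, seed = 53L)
  b <- simulate_cluster_sides(rec, seed = 53L)
  expect_identical(a, b)

  identity_rel <- lapply(
    stats::setNames(nm = c("anth_rg", "ferari", "flav_uv", "sfr_r")),
    function(ix) fit_linear(c(0, 0.5, 1), c(0, 0.5, 1), ix, ix))
  same <- simulate_cluster_sides(rec, side_models = identity_rel)
  ne <- same[same$cluster_side == "NE", ]
  sw <- same[same$cluster_side == "SW", ]
  expect_equal(sw$ferari, ne$ferari, tolerance = 1e-12)
  expect_equal(sw$sfr_r, ne$sfr_r, tolerance = 1e-12)

  pair <- simulate_cluster_sides(rec, seed = 54L)
  ne <- pair[pair$cluster_side == "NE", ]
  sw <- pair[pair$cluster_side == "SW", ]
  sc <- side_concordance(sw$ferari, ne$ferari, "ferari")
  expect_equal(sc$model$coefficients, c(0.9131, 0.0026), tolerance = 1e-6)
  sc2 <- side_concordance(sw$anth_rg, ne$anth_rg, "anth_rg")
  expect_equal(sc2$model$coefficients, c(0.8537, 0.0014), tolerance = 1e-6)

  expect_error(simulate_cluster_sides(rec, side_models = identity_rel[1:2]),
               class = "grapemx_config_error")
})

test_that("profile constructor enforces its physiological invariants", {
  expect_error(cultivar_profile("x", tss_onset = 30, tss_harvest = 20),
               class = "grapemx_config_error")
  expect_error(cultivar_profile("x", anth_max_berry = -1),
               class = "grapemx_config_error")
  expect_error(cultivar_profile("x", skin_pct_harvest = 0),
               class = "grapemx_config_error")
})
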