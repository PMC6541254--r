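models <- printed_calibration_models()

test_that("linear fit recovers an exact line and flags degenerate input", {
  fit <- fit_linear(c(0, 1, 2), c(1, 3, 5))
  expect_equal(fit$coefficients, c(2, 1))
  expect_equal(fit$r2, 1)
  expect_equal(fit$n, 3L)
  expect_error(fit_linear(c(1, 1, 1), c(1, 2, 3)),
               class = "grapemx_degenerate_fit")
  expect_error(fit_linear(1:2, 1:2), class = "grapemx_degenerate_fit")
  expect_error(fit_linear(1:3, 1:4), class = "grapemx_pairing_error")
})

test_that("polynomial fit recovers an exact quartic and checks point counts", {
  x <- c(-2, -1, 0, 1, 2, 3)
  fit <- fit_polynomial(x, x^4, degree = 4)
  expect_equal(fit$coefficients, c(1, 0, 0, 0, 0), tolerance = 1e-9)
  expect_equal(fit$r2, 1)
  expect_error(fit_polynomial(1:4, (1:4)^4, degree = 4),
               class = "grapemx_degenerate_fit")
  expect_error(fit_polynomial(c(1, 1, 2, 2, 3, 3), 1:6, degree = 4),
               class = "grapemx_degenerate_fit")
})

test_that("every printed calibration model is recovered from zero-noise data", {
  cases <- list(
    list(m = models$anth_ferari$malvasia_r, x = seq(0.05, 0.12, length.out = 27),
         fit = function(d) fit_linear(d$x, d$y)),
    list(m = models$anth_ferari$barbera, x = seq(0, 1.2, length.out = 27),
         fit = function(d) fit_sigmoid(d$x, d$y)),
    list(m = models$anth_ferari$ervi, x = seq(0, 1.2, length.out = 27),
         fit = function(d) fit_sigmoid(d$x, d$y)),
    list(m = models$anth_ferari_skin$barbera, x = seq(0, 16, length.out = 27),
         fit = function(d) fit_sigmoid(d$x, d$y)),
    list(m = models$anth_rg$malvasia_r, x = seq(0, 0.2, length.out = 27),
         fit = function(d) fit_linear(d$x, d$y)),
    list(m = models$anth_rg$barbera, x = seq(0, 1.7, length.out = 27),
         fit = function(d) fit_polynomial(d$x, d$y, 4)),
    list(m = models$anth_rg$ervi, x = seq(0, 1.9, length.out = 27),
         fit = function(d) fit_polynomial(d$x, d$y, 4)),
    list(m = models$sfr_tss$ortrugo, x = seq(10, 22.3, length.out = 12),
         fit = function(d) fit_linear(d$x, d$y)),
    list(m = models$sfr_tss$barbera, x = seq(10, 27.2, length.out = 21),
         fit = function(d) fit_linear(d$x, d$y)),
    list(m = models$flav_uv$pooled, x = seq(0.5, 3, length.out = 41),
         fit = function(d) fit_polynomial(d$x, d$y, 2)),
    list(m = models$side$ferari, x = seq(0, 1.5, length.out = 27),
         fit = function(d) fit_linear(d$x, d$y)),
    list(m = models$side$sfr_r, x = seq(0.3, 1.1, length.out = 41),
         fit = function(d) fit_linear(d$x, d$y)))
  for (case in cases) {
    d <- model_curve(case$m, case$x)
    fit <- case$fit(d)
    expect_equal(fit$coefficients, case$m$coefficients,
                 tolerance = 1e-4,
                 label = sprintf("%s %s->%s coefficients", case$m$family,
                                 case$m$x_name, case$m$y_name))
    expect_gt(fit$r2, 1 - 1e-9)
  }
})

test_that("sigmoid fitter beats or matches a brute-force grid search on noisy data", {
  m <- models$anth_ferari$ervi
  set.seed(11)
  x <- seq(0, 1.2, length.out = 27)
  y <- pmax(predict(m, x) + rnorm(27, 0, 0.05), 0)
  fit <- fit_sigmoid(x, y)
  oracle <- grid_search_sigmoid(x, y, a_range = c(0.5, 3),
                                b_range = c(1, 8), c_range = c(1, 12))
  sse_fit <- sum((y - predict(fit, x))^2)
  expect_lte(sse_fit, oracle$sse + 1e-8)
  expect_equal(fit$coefficients[1], oracle$a, tolerance = 0.1)
})

test_that("sigmoid fitting rejects degenerate data and reports failures", {
  expect_error(fit_sigmoid(1:10, rep(2, 10)),
               class = "grapemx_degenerate_fit")
  expect_error(fit_sigmoid(1:4, c(0, 1, 2, 3)),
               class = "grapemx_degenerate_fit")
  expect_error(fit_sigmoid(1:10, c(rep(0, 9), -1)),
               class = "grapemx_degenerate_fit")
})

test_that("predict and invert are mutually inverse on the valid domain", {
  sig <- models$anth_ferari$barbera
  expect_equal(invert_calibration(sig, 0.5),
               (4.005 - log(1.55 / 0.5 - 1)) / 5.261)
  expect_equal(invert_calibration(sig, 0.5), 0.62024, tolerance = 1e-4)
  lin <- fit_linear(c(0, 1, 2), c(1, 3, 5))
  expect_equal(invert_calibration(lin, 5), 2)
  for (x0 in seq(0.05, 1.4, length.out = 17)) {
    expect_equal(invert_calibration(sig, predict(sig, x0)), x0,
                 tolerance = 1e-9)
    expect_equal(invert_calibration(lin, predict(lin, x0)), x0,
                 tolerance = 1e-9)
  }
  expect_error(invert_calibration(sig, 1.6), class = "grapemx_out_of_range")
  expect_error(invert_calibration(sig, 0), class = "grapemx_out_of_range")
  expect_error(invert_calibration(models$anth_rg$barbera, 0.1),
               class = "grapemx_unsupported_family")
})

test_that("sigmoid predictions are increasing in x (c > 0) and bounded by the asymptote", {
  m <- models$anth_ferari$barbera
  x <- seq(-1, 5, length.out = 200)
  y <- predict(m, x)
  expect_true(all(diff(y) > 0))
  expect_true(all(y > 0 & y < m$coefficients[1]))
})

test_that("the sugar-domain filter keeps exactly the samples at or above threshold", {
  s <- data.frame(tss = c(4.5, 9.2, 10, 22.3), id = 1:4)
  kept <- filter_tss_domain(s, 10)
  expect_equal(kept$id, c(3, 4))
  expect_equal(filter_tss_domain(s, 0)$id, 1:4)
  expect_equal(nrow(filter_tss_domain(s[0, ], 10)), 0)
})

test_that("anthocyanin basis conversion divides by the skin fraction and round-trips", {
  expect_equal(convert_anth_basis(1.0, 10), 10.0)
  # red-cultivar harvest: 1.68 mg/g berry at a 9.82% skin ratio
  expect_equal(convert_anth_basis(1.68, 9.82), 17.1, tolerance = 0.005)
  expect_equal(
    convert_anth_basis_to_berry(convert_anth_basis(1.23, 9.5), 9.5), 1.23)
  expect_error(convert_anth_basis(1, 0), class = "grapemx_invalid_ratio")
  expect_error(convert_anth_basis(1, -5), class = "grapemx_invalid_ratio")
  # ordering preserved at fixed ratio
  a <- sort(runif(10))
  expect_true(all(diff(convert_anth_basis(a, 9.82)) > 0))
})

test_that("side concordance reports identity for equal sides and recovers the printed relation", {
  v <- seq(0.1, 1.5, length.out = 10)
  sc <- side_concordance(v, v)
  expect_equal(sc$model$coefficients, c(1, 0), tolerance = 1e-10)
  expect_equal(sc$model$r2, 1)
  expect_equal(sc$mean_abs_deviation, 0)

  ne <- seq(0, 1.5, length.out = 27)
  sw <- predict(models$side$ferari, ne)
  sc2 <- side_concordance(sw, ne, "ferari")
  expect_equal(sc2$model$coefficients, c(0.9131, 0.0026), tolerance = 1e-6)
  expect_error(side_concordance(1:3, 1:4), class = "grapemx_pairing_error")
  expect_error(side_concordance(1:2, 1:2), class = "grapemx_degenerate_fit")
})

test_that("model selection prefers the best r2 with a parsimony tie-break", {
  x <- seq(0, 2, length.out = 20)
  exact_line <- 2 * x + 1
  pick <- select_model(x, exact_line, candidates = c("linear", "polynomial"),
                       degree = 4)
  expect_identical(pick$family, "linear")

  sig <- models$anth_ferari$barbera
  d <- model_curve(sig, seq(0, 1.2, length.out = 27))
  pick2 <- select_model(d$x, d$y, candidates = c("linear", "sigmoid"))
  expect_identical(pick2$family, "sigmoid")
  # independent check: the sigmoid SSE really is smaller than the line's
  lin <- fit_linear(d$x, d$y)
  expect_lt(sum((d$y - predict(pick2, d$x))^2),
            sum((d$y - predict(lin, d$x))^2))
  expect_error(select_model(x, exact_line, candidates = character()),
               class = "grapemx_selection_failure")
})

test_that("calibration models serialize to a flat table and JSON faithfully", {
  m <- models$anth_ferari$barbera
  tab <- calibration_table(list(m, models$sfr_tss$ortrugo))
  expect_equal(nrow(tab), 2)
  expect_equal(tab$family, c("sigmoid", "linear"))
  expect_equal(tab$domain_lower[2], 10)
  path <- tempfile(fileext = ".json")
  write_calibration_json(m, path)
  back <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  expect_equal(back$coefficients[[1]], m$coefficients)
  expect_equal(back$family[[1]], "sigmoid")
})
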