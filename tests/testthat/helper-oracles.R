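# Independent oracles kept deliberately dumb: brute-force or literal
# spreadsheet-style arithmetic, never calling the code paths they check.

# Coarse grid search over (a, b, c) minimizing SSE of
# y = a / (1 + exp(b - c x)), refined once on a finer local grid.
grid_search_sigmoid <- function(x, y, a_range, b_range, c_range,
                                n_grid = 15L, refine = 2L) {
  sse <- function(a, b, c) sum((y - a / (1 + exp(b - c * x)))^2)
  best <- NULL
  for (pass in seq_len(refine + 1L)) {
    grid <- expand.grid(a = seq(a_range[1], a_range[2], length.out = n_grid),
                        b = seq(b_range[1], b_range[2], length.out = n_grid),
                        c = seq(c_range[1], c_range[2], length.out = n_grid))
    vals <- mapply(sse, grid$a, grid$b, grid$c)
    best <- grid[which.min(vals), ]
    shrink <- function(center, range) {
      w <- (range[2] - range[1]) / n_grid
      c(center - 2 * w, center + 2 * w)
    }
    a_range <- shrink(best$a, a_range)
    b_range <- shrink(best$b, b_range)
    c_range <- shrink(best$c, c_range)
  }
  list(a = best$a, b = best$b, c = best$c,
       sse = sse(best$a, best$b, best$c))
}

# Literal line-by-line re-derivation of the yearly saving for the default
# cost model (ranges at their midpoints): no shared code with the package.
spreadsheet_cash_flow_avg <- function(n_cultivars, t_rip, t_harv, t_mx) {
  ripening <- 6 * 5 * n_cultivars
  bunches <- 4 * 3 * n_cultivars
  price <- (0.45 + 0.60) / 2
  grape <- ripening * (0.05 + 0.2) / 2 * price +
    bunches * (0.1 + 0.4) / 2 * price
  labor <- ((ripening * t_rip + bunches * t_harv) -
              (ripening + bunches) * t_mx) * 8 / 60
  lab <- (ripening + bunches) * 20
  grape + labor + lab
}

# Discounted-sum NPV written out longhand (maintenance every 3rd year of
# ownership, end-of-year cash flows).
spreadsheet_npv <- function(cash_flow, lifetime, purchase = 13900,
                            maintenance = 1000, interval = 3, r = 0.02) {
  total <- -purchase
  for (t in seq_len(lifetime)) {
    total <- total + cash_flow / (1 + r)^t
    if (t %% interval == 0) total <- total - maintenance / (1 + r)^t
  }
  total
}

# Zero-noise data from a stored calibration model, for recovery tests.
model_curve <- function(model, x) {
  data.frame(x = x, y = predict(model, x))
}

expect_calibration_close <- function(fit, expected_coefs, tol = 1e-4) {
  expect_equal(fit$coefficients, expected_coefs, tolerance = tol)
}

# Chemistry values a sigmoid calibration can represent without clipping:
# above the index-zero baseline, below 99% of the asymptote.
in_sigmoid_range <- function(model, y) {
  if (model$family != "sigmoid") return(rep(TRUE, length(y)))
  y > predict(model, 0) & y < 0.99 * model$coefficients[1]
}
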