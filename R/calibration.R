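#' Calibration models linking fluorescence indices to wet chemistry
#'
#' A calibration model is one fitted index-vs-chemistry relationship.
#' Three families cover the published curve shapes:
#' * `linear`      y = p1 x + p2
#' * `polynomial`  y = p1 x^d + ... + p(d+1)  (descending powers)
#' * `sigmoid`     y = a / (1 + exp(b - c x))
#'
#' Coefficients are stored in that order; `domain` optionally records an
#' inclusive validity window on the predictor or on an auxiliary variable
#' (e.g. the total-soluble-solids threshold below which the sugar model
#' does not apply).
#'
#' @name calibration-models
NULL

new_calibration_model <- function(family, coefficients, x_name, y_name,
                                  r2, n, degree = NULL, domain = NULL) {
  family <- match.arg(family, c("linear", "polynomial", "sigmoid"))
  if (family == "sigmoid" && coefficients[[1L]] <= 0) {
    stop_grapemx("grapemx_fit_failure",
                 "sigmoid asymptote `a` must be positive")
  }
  structure(
    list(family = family,
         degree = if (family == "polynomial") as.integer(degree)
                  else if (family == "linear") 1L else NULL,
         coefficients = as.numeric(coefficients),
         x_name = x_name, y_name = y_name,
         domain = domain,
         r2 = min(max(r2, 0), 1), n = as.integer(n)),
    class = "grapemx_calibration")
}

#' @export
print.grapemx_calibration <- function(x, ...) {
  eq <- switch(x$family,
    linear = sprintf("%s = %.6g * %s + %.6g",
                     x$y_name, x$coefficients[1], x$x_name, x$coefficients[2]),
    polynomial = paste0(x$y_name, " = ", poly_text(x$coefficients, x$x_name)),
    sigmoid = sprintf("%s = %.6g / (1 + exp(%.6g - %.6g * %s))",
                      x$y_name, x$coefficients[1], x$coefficients[2],
                      x$coefficients[3], x$x_name))
  cat(sprintf("<calibration: %s>\n  %s\n  R^2 = %.4f, n = %d\n",
              x$family, eq, x$r2, x$n))
  if (!is.null(x$domain)) {
    cat(sprintf("  domain: %s in [%s, %s]\n",
                x$domain$variable %||% x$x_name,
                format(x$domain$lower %||% -Inf),
                format(x$domain$upper %||% Inf)))
  }
  invisible(x)
}

poly_text <- function(coef, xn) {
  d <- length(coef) - 1L
  paste(sprintf("%.6g*%s^%d", coef, xn, d:0), collapse = " + ")
}

r_squared <- function(y, fitted) {
  sst <- sum((y - mean(y))^2)
  sse <- sum((y - fitted)^2)
  if (sst <= 0) return(if (sse <= 0) 1 else 0)
  1 - sse / sst
}

check_xy <- function(x, y, min_n = 3L) {
  if (length(x) != length(y)) {
    stop_grapemx("grapemx_pairing_error",
                 sprintf("x and y must be paired (lengths %d and %d)",
                         length(x), length(y)))
  }
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < min_n) {
    stop_grapemx("grapemx_degenerate_fit",
                 sprintf("need at least %d finite points, got %d",
                         min_n, length(x)))
  }
  list(x = x, y = y)
}

#' Fit a straight-line calibration by ordinary least squares
#'
#' @param x,y paired numeric vectors (at least 3 finite points; `x` must
#'   vary).
#' @param x_name,y_name labels stored on the model.
#' @param domain optional list `(variable, lower, upper)` recording the
#'   validity window of the fit.
#' @return a `grapemx_calibration` object with coefficients
#'   `(slope, intercept)`.
#' @export
fit_linear <- function(x, y, x_name = "x", y_name = "y", domain = NULL) {
  d <- check_xy(x, y, min_n = 3L)
  if (stats::var(d$x) == 0) {
    stop_grapemx("grapemx_degenerate_fit", "x has zero variance")
  }
  fit <- stats::lm(y ~ x, data = d)
  cf <- unname(stats::coef(fit))  # (intercept, slope)
  new_calibration_model("linear", c(cf[2L], cf[1L]), x_name, y_name,
                        r2 = r_squared(d$y, stats::fitted(fit)),
                        n = length(d$x), domain = domain)
}

#' Fit a polynomial calibration of caller-chosen degree
#'
#' @inheritParams fit_linear
#' @param degree polynomial degree (2 for the flavonol quadratic, 4 for
#'   the anthocyanin quartics); needs `degree + 2` points and
#'   `degree + 1` distinct x values.
#' @return a `grapemx_calibration` with coefficients in descending powers.
#' @export
fit_polynomial <- function(x, y, degree, x_name = "x", y_name = "y",
                           domain = NULL) {
  if (!is_count(degree) || degree < 1) {
    stop_grapemx("grapemx_config_error", "`degree` must be a positive integer")
  }
  degree <- as.integer(degree)
  d <- check_xy(x, y, min_n = degree + 2L)
  if (length(unique(d$x)) < degree + 1L) {
    stop_grapemx("grapemx_degenerate_fit",
                 sprintf("need at least %d distinct x values for degree %d",
                         degree + 1L, degree))
  }
  fit <- stats::lm(y ~ stats::poly(x, degree, raw = TRUE), data = d)
  cf <- unname(stats::coef(fit))          # intercept, x, x^2, ...
  new_calibration_model("polynomial", rev(cf), x_name, y_name,
                        r2 = r_squared(d$y, stats::fitted(fit)),
                        n = length(d$x), degree = degree, domain = domain)
}

#' Fit a three-parameter sigmoid calibration
#'
#' Fits `y = a / (1 + exp(b - c x))` by nonlinear least squares
#' (Levenberg--Marquardt).  Starting values follow a logit
#' linearization: `a0 = 1.05 * max(y)`, then a straight line through
#' `log(y / (a0 - y))` on the interior points gives `c0` (slope) and
#' `b0` (minus the intercept).  Up to 10 restarts with jittered `a0`
#' precede a classed fit-failure error carrying the last residual norm.
#'
#' @inheritParams fit_linear
#' @param init optional named starting values `c(a=, b=, c=)` overriding
#'   the self-starting rule.
#' @return a `grapemx_calibration` with coefficients `(a, b, c)`.
#' @export
fit_sigmoid <- function(x, y, init = NULL, x_name = "x", y_name = "y",
                        domain = NULL) {
  d <- check_xy(x, y, min_n = 5L)
  if (any(d$y < 0)) {
    stop_grapemx("grapemx_degenerate_fit",
                 "sigmoid fitting requires non-negative y")
  }
  if (max(d$y) - min(d$y) <= 0) {
    stop_grapemx("grapemx_degenerate_fit", "y shows no spread")
  }
  # deterministic jitter ladder, so identical data always fit identically
  jitter_a <- c(1, 0.85, 1.25, 0.7, 1.6, 0.55, 2, 0.4, 3, 0.3)
  last_err <- NULL
  last_rnorm <- NA_real_
  for (j in jitter_a) {
    start <- if (!is.null(init)) as.list(init) else sigmoid_start(d$x, d$y, j)
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ a / (1 + exp(b - c * x)), data = d, start = start,
        lower = c(a = .Machine$double.eps, b = -Inf, c = -Inf),
        control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-10)),
      error = function(e) e)
    if (!inherits(fit, "error")) {
      cf <- stats::coef(fit)
      return(new_calibration_model(
        "sigmoid", c(cf[["a"]], cf[["b"]], cf[["c"]]), x_name, y_name,
        r2 = r_squared(d$y, stats::fitted(fit)),
        n = length(d$x), domain = domain))
    }
    last_err <- fit
    if (!is.null(init)) break  # explicit start: a single attempt
  }
  stop_grapemx("grapemx_fit_failure",
               paste("sigmoid fit did not converge:",
                     conditionMessage(last_err)),
               residual_norm = last_rnorm)
}

sigmoid_start <- function(x, y, a_jitter = 1) {
  a0 <- 1.05 * max(y) * a_jitter
  inner <- y > 0.02 * a0 & y < 0.98 * a0
  if (sum(inner) >= 2L) {
    z <- log(y[inner] / (a0 - y[inner]))
    cf <- stats::coef(stats::lm(z ~ x[inner]))
    c0 <- unname(cf[2L]); b0 <- -unname(cf[1L])
    if (!is.finite(c0) || c0 == 0) c0 <- 1
  } else {
    c0 <- 1
    b0 <- c0 * stats::median(x)
  }
  list(a = a0, b = b0, c = c0)
}

#' Evaluate a calibration model
#'
#' @param object a `grapemx_calibration`.
#' @param x numeric predictor values.
#' @param ... unused.
#' @return fitted values.
#' @export
predict.grapemx_calibration <- function(object, x, ...) {
  cf <- object$coefficients
  switch(object$family,
    linear = cf[1L] * x + cf[2L],
    polynomial = {
      d <- object$degree
      vapply(x, function(xi) sum(cf * xi^(d:0)), numeric(1))
    },
    sigmoid = cf[1L] / (1 + exp(cf[2L] - cf[3L] * x)))
}

#' Invert a monotone calibration model
#'
#' Solves `predict(model, x) == y` in closed form for the linear
#' (nonzero slope) and sigmoid families; a sigmoid requires
#' `0 < y < a`.  Polynomials are not invertible in general and raise an
#' unsupported-family error.
#'
#' @param model a `grapemx_calibration`.
#' @param y response value(s) inside the model's open range.
#' @return the unique predictor value(s).
#' @export
invert_calibration <- function(model, y) {
  cf <- model$coefficients
  switch(model$family,
    linear = {
      if (cf[1L] == 0) {
        stop_grapemx("grapemx_degenerate_fit",
                     "cannot invert a zero-slope linear model")
      }
      (y - cf[2L]) / cf[1L]
    },
    polynomial = stop_grapemx(
      "grapemx_unsupported_family",
      "polynomial calibrations are not invertible; use linear or sigmoid"),
    sigmoid = {
      a <- cf[1L]
      if (any(y <= 0 | y >= a)) {
        stop_grapemx("grapemx_out_of_range",
                     sprintf("sigmoid inversion needs 0 < y < a = %.6g", a))
      }
      (cf[2L] - log(a / y - 1)) / cf[3L]
    })
}

#' Restrict ripening samples to the reliable sugar-model domain
#'
#' The simple fluorescence ratio tracks total soluble solids only once
#' chlorophyll breakdown is underway; below about 10 degrees Brix the
#' relation is unstable.  Keeps samples with `tss >= threshold`, in input
#' order.
#'
#' @param samples data frame with a `tss` column (degrees Brix).
#' @param threshold inclusive lower bound, default 10.
#' @return the retained rows.
#' @export
filter_tss_domain <- function(samples, threshold = 10) {
  assert_number(threshold, "threshold", lower = 0)
  if (!"tss" %in% names(samples)) {
    stop_grapemx("grapemx_data_error", "samples need a `tss` column")
  }
  samples[!is.na(samples$tss) & samples$tss >= threshold, , drop = FALSE]
}

#' Convert anthocyanin concentration between berry and skin mass bases
#'
#' Anthocyanins sit in the skin, so concentration per gram of fresh skin
#' equals concentration per gram of whole berry divided by the
#' skin-to-berry fresh-mass fraction.
#'
#' @param anth_berry mg per g fresh berry mass.
#' @param skin_to_berry_pct skin mass as a percentage of berry mass,
#'   in (0, 100].
#' @return mg per g fresh skin mass.
#' @export
convert_anth_basis <- function(anth_berry, skin_to_berry_pct) {
  if (any(!is.finite(skin_to_berry_pct) | skin_to_berry_pct <= 0 |
            skin_to_berry_pct > 100)) {
    stop_grapemx("grapemx_invalid_ratio",
                 "`skin_to_berry_pct` must lie in (0, 100]")
  }
  anth_berry / (skin_to_berry_pct / 100)
}

#' @rdname convert_anth_basis
#' @param anth_skin mg per g fresh skin mass.
#' @export
convert_anth_basis_to_berry <- function(anth_skin, skin_to_berry_pct) {
  if (any(!is.finite(skin_to_berry_pct) | skin_to_berry_pct <= 0 |
            skin_to_berry_pct > 100)) {
    stop_grapemx("grapemx_invalid_ratio",
                 "`skin_to_berry_pct` must lie in (0, 100]")
  }
  anth_skin * (skin_to_berry_pct / 100)
}

#' Concordance of readings on opposite cluster sides
#'
#' Readings taken on the south-west and north-east faces of the same
#' cluster should agree; this regresses the SW series on the NE series
#' and reports, alongside the linear model, the mean absolute deviation
#' from the 1:1 line.
#'
#' @param sw,ne equal-length paired index vectors (n >= 3).
#' @param index_name label for the compared index.
#' @return a list with elements `model` (a linear `grapemx_calibration`,
#'   SW on NE) and `mean_abs_deviation`.
#' @export
side_concordance <- function(sw, ne, index_name = "index") {
  if (length(sw) != length(ne)) {
    stop_grapemx("grapemx_pairing_error",
                 sprintf("side vectors must pair up (lengths %d and %d)",
                         length(sw), length(ne)))
  }
  model <- fit_linear(ne, sw,
                      x_name = paste0(index_name, "_NE"),
                      y_name = paste0(index_name, "_SW"))
  list(model = model, mean_abs_deviation = mean(abs(sw - ne)))
}

#' Choose the best-fitting calibration family
#'
#' Fits each requested family and returns the one with the highest
#' coefficient of determination; exact ties go to the family with the
#' fewest coefficients.  Candidates whose preconditions the data violate
#' are skipped.
#'
#' @inheritParams fit_linear
#' @param candidates character subset of
#'   `c("linear", "polynomial", "sigmoid")`.
#' @param degree degree used for the polynomial candidate.
#' @return the winning `grapemx_calibration`.
#' @export
select_model <- function(x, y, candidates = c("linear", "sigmoid"),
                         degree = 4L, x_name = "x", y_name = "y") {
  if (length(candidates) == 0L) {
    stop_grapemx("grapemx_selection_failure", "no candidate families given")
  }
  candidates <- match.arg(candidates, c("linear", "polynomial", "sigmoid"),
                          several.ok = TRUE)
  fits <- list()
  for (fam in candidates) {
    fit <- tryCatch(
      switch(fam,
             linear = fit_linear(x, y, x_name, y_name),
             polynomial = fit_polynomial(x, y, degree, x_name, y_name),
             sigmoid = fit_sigmoid(x, y, x_name = x_name, y_name = y_name)),
      grapemx_error = function(e) NULL)
    if (!is.null(fit)) fits[[fam]] <- fit
  }
  if (length(fits) == 0L) {
    stop_grapemx("grapemx_selection_failure",
                 "every candidate family failed to fit")
  }
  r2 <- vapply(fits, `[[`, numeric(1), "r2")
  npar <- vapply(fits, function(f) length(f$coefficients), numeric(1))
  # highest r2; within 1e-12, fewest parameters
  best <- order(-round(r2, 12), npar)[1L]
  fits[[best]]
}

#' Serialize calibration models
#'
#' @param models a `grapemx_calibration` or list of them.
#' @return a data frame with one row per model (`coefficients` packed as
#'   a `;`-separated string in the CSV-friendly form).
#' @export
calibration_table <- function(models) {
  if (inherits(models, "grapemx_calibration")) models <- list(models)
  do.call(rbind, lapply(models, function(m) {
    data.frame(
      family = m$family,
      degree = m$degree %||% NA_integer_,
      coefficients = paste(format(m$coefficients, digits = 15),
                           collapse = ";"),
      x_name = m$x_name, y_name = m$y_name,
      domain_variable = m$domain$variable %||% NA_character_,
      domain_lower = m$domain$lower %||% NA_real_,
      domain_upper = m$domain$upper %||% NA_real_,
      r2 = m$r2, n = m$n,
      stringsAsFactors = FALSE)
  }))
}

#' @rdname calibration_table
#' @param path file to write JSON to.
#' @export
write_calibration_json <- function(models, path) {
  if (inherits(models, "grapemx_calibration")) models <- list(models)
  payload <- lapply(models, function(m) {
    list(family = m$family, degree = m$degree,
         coefficients = m$coefficients,
         x_name = m$x_name, y_name = m$y_name,
         domain = m$domain, r2 = m$r2, n = m$n)
  })
  atomic_write(path, function(tmp) {
    jsonlite::write_json(payload, tmp, auto_unbox = TRUE, digits = NA,
                         null = "null")
  })
  invisible(path)
}
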