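#' Fluorescence records and Multiplex-style ripening indices
#'
#' A fluorescence record holds one optical reading of a grape cluster:
#' far-red fluorescence under red, green and UV excitation (`frf_r`,
#' `frf_g`, `frf_uv`), red fluorescence under red excitation (`rf_r`),
#' plus `cultivar`, `doy` (day of year) and `cluster_side` metadata.
#' Records are plain data frames, one row per reading.
#'
#' @name fluorescence-records
NULL

CHANNEL_COLS <- c("frf_r", "frf_g", "frf_uv", "rf_r")
INDEX_COLS   <- c("sfr_r", "flav", "flav_uv", "anth_rg", "ferari")
CLUSTER_SIDES <- c("SW", "NE", "unspecified")

#' Build a table of fluorescence records
#'
#' @param frf_r,frf_g,frf_uv far-red fluorescence under red, green and UV
#'   excitation (relative units, strictly positive).
#' @param rf_r red fluorescence under red excitation (strictly positive).
#' @param cultivar cultivar label, recycled to the number of readings.
#' @param doy integer day of year (1--366), recycled.
#' @param cluster_side one of `"SW"`, `"NE"`, `"unspecified"`, recycled.
#' @return a data frame with one row per reading.
#' @export
fluorescence_record <- function(frf_r, frf_g, frf_uv, rf_r,
                                cultivar = "unknown", doy = 1L,
                                cluster_side = "unspecified") {
  n <- length(frf_r)
  rec <- data.frame(
    cultivar = rep_len(as.character(cultivar), n),
    doy = rep_len(as.integer(doy), n),
    cluster_side = rep_len(as.character(cluster_side), n),
    frf_r = as.numeric(frf_r), frf_g = as.numeric(frf_g),
    frf_uv = as.numeric(frf_uv), rf_r = as.numeric(rf_r),
    stringsAsFactors = FALSE
  )
  validate_fluorescence(rec)
  rec
}

validate_fluorescence <- function(rec, require_positive = TRUE) {
  missing_cols <- setdiff(CHANNEL_COLS, names(rec))
  if (length(missing_cols)) {
    stop_grapemx("grapemx_data_error",
                 paste("missing fluorescence channel column(s):",
                       paste(missing_cols, collapse = ", ")))
  }
  if (require_positive) {
    for (ch in CHANNEL_COLS) {
      bad <- !is.finite(rec[[ch]]) | rec[[ch]] <= 0
      if (any(bad)) {
        stop_grapemx(
          "grapemx_invalid_signal",
          sprintf("channel `%s` must be strictly positive (%d offending reading%s, first at row %d)",
                  ch, sum(bad), if (sum(bad) > 1L) "s" else "", which(bad)[1L]),
          channel = ch, rows = which(bad))
      }
    }
  }
  if ("doy" %in% names(rec) &&
      any(!is.na(rec$doy) & (rec$doy < 1L | rec$doy > 366L))) {
    stop_grapemx("grapemx_data_error", "`doy` must lie in 1..366")
  }
  if ("cluster_side" %in% names(rec) &&
      !all(rec$cluster_side %in% CLUSTER_SIDES)) {
    stop_grapemx("grapemx_data_error",
                 "`cluster_side` must be one of SW, NE, unspecified")
  }
  invisible(rec)
}

#' Offset-correct and standard-normalize raw fluorescence channels
#'
#' Raw sensor signals carry a residual electronic offset and are expressed
#' relative to a fluorescence standard.  Each channel is replaced by
#' `(raw - offset) / standard`; metadata columns are untouched.  With the
#' default zero offsets and unit standards this is the identity, matching
#' data exported already corrected.
#'
#' @param rec fluorescence record table (see [fluorescence_record()]).
#' @param offsets,standard numeric, either a single value applied to every
#'   channel or a vector named by channel (`frf_r`, `frf_g`, `frf_uv`,
#'   `rf_r`).  `standard` must be strictly positive.
#' @return the record table with corrected channels.
#' @export
normalize_signals <- function(rec, offsets = 0, standard = 1) {
  validate_fluorescence(rec, require_positive = FALSE)
  offsets <- expand_per_channel(offsets, "offsets")
  standard <- expand_per_channel(standard, "standard")
  if (any(standard <= 0)) {
    stop_grapemx("grapemx_config_error",
                 "`standard` reference values must be strictly positive")
  }
  for (ch in CHANNEL_COLS) {
    rec[[ch]] <- (rec[[ch]] - offsets[[ch]]) / standard[[ch]]
  }
  validate_fluorescence(rec)  # non-positive corrected channel -> error
  rec
}

expand_per_channel <- function(x, name) {
  if (length(x) == 1L && is.null(names(x))) {
    x <- stats::setNames(rep(as.numeric(x), 4L), CHANNEL_COLS)
  }
  if (!all(CHANNEL_COLS %in% names(x))) {
    stop_grapemx("grapemx_config_error",
                 sprintf("`%s` must be a scalar or named per channel (%s)",
                         name, paste(CHANNEL_COLS, collapse = ", ")))
  }
  as.list(x[CHANNEL_COLS])
}

#' Compute the five fluorescence ripening indices
#'
#' From normalized channels, derives (decimal logs throughout):
#' * `anth_rg = log10(frf_r / frf_g)` -- anthocyanin index, red vs green
#'   excitation;
#' * `ferari  = log10(1 / frf_r)` -- single-signal anthocyanin index;
#' * `flav    = log10(frf_r / frf_uv)` -- flavonol index;
#' * `flav_uv = log10(1 / frf_uv)` -- UV-screening flavonol index;
#' * `sfr_r   = frf_r / rf_r` -- simple fluorescence ratio, a chlorophyll
#'   breakdown (sugar-loading) proxy.
#'
#' By construction `flav + ferari == flav_uv` exactly; the three log
#' indices other than `anth_rg` change when all channels are rescaled by a
#' common factor, while `anth_rg` (a channel ratio) does not.
#'
#' @param rec fluorescence record table with strictly positive channels.
#' @return the input with the five index columns appended.
#' @export
compute_indices <- function(rec) {
  validate_fluorescence(rec)
  rec$anth_rg <- log10(rec$frf_r / rec$frf_g)
  rec$ferari  <- log10(1 / rec$frf_r)
  rec$flav    <- log10(rec$frf_r / rec$frf_uv)
  rec$flav_uv <- log10(1 / rec$frf_uv)
  rec$sfr_r   <- rec$frf_r / rec$rf_r
  rec
}

#' Reconstruct fluorescence channels from index values
#'
#' Inverse of [compute_indices()]: given `ferari`, `anth_rg`, `flav_uv`
#' and `sfr_r` (which determine all four channels uniquely), rebuilds
#' `frf_r`, `frf_g`, `frf_uv` and `rf_r`.
#'
#' @param idx data frame with columns `ferari`, `anth_rg`, `flav_uv`,
#'   `sfr_r` plus any metadata.
#' @return a fluorescence record table.
#' @export
channels_from_indices <- function(idx) {
  needed <- c("ferari", "anth_rg", "flav_uv", "sfr_r")
  if (!all(needed %in% names(idx))) {
    stop_grapemx("grapemx_data_error",
                 paste("need index columns:", paste(needed, collapse = ", ")))
  }
  if (any(idx$sfr_r <= 0)) {
    stop_grapemx("grapemx_invalid_signal",
                 "`sfr_r` must be strictly positive to reconstruct rf_r",
                 channel = "rf_r")
  }
  idx$frf_r  <- 10^(-idx$ferari)
  idx$frf_g  <- idx$frf_r * 10^(-idx$anth_rg)
  idx$frf_uv <- 10^(-idx$flav_uv)
  idx$rf_r   <- idx$frf_r / idx$sfr_r
  validate_fluorescence(idx)
  idx
}
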