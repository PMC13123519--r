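# Serialization: CSV for variance series (header `u,v_hat`, full float
# precision) and JSON for fit / detection / benchmark records.

#' Read a variance series from CSV
#'
#' Expects a header `u,v_hat` and two numeric columns; u must be strictly
#' monotone (the sweep direction is inferred) and all variances strictly
#' positive. Offending rows are named in error messages.
#'
#' @param path File path.
#' @return A [variance_series()].
#' @export
read_variance_series <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!identical(names(d)[1:2], c("u", "v_hat")))
    stop("expected header 'u,v_hat', got '", paste(names(d), collapse = ","), "'")
  if (!is.numeric(d$u) || !is.numeric(d$v_hat) || anyNA(d$u) || anyNA(d$v_hat)) {
    bad <- which(is.na(suppressWarnings(as.numeric(d$u))) |
                   is.na(suppressWarnings(as.numeric(d$v_hat))))
    stop("malformed numeric values at row(s): ", paste(bad, collapse = ", "))
  }
  if (nrow(d) >= 2L) {
    dd <- diff(d$u)
    if (any(dd == 0))
      stop("duplicate u value at row(s): ",
           paste(which(dd == 0) + 1L, collapse = ", "))
    if (!(all(dd > 0) || all(dd < 0)))
      stop("u values are not monotone")
  }
  if (any(d$v_hat <= 0))
    stop("non-positive v_hat at row(s): ",
         paste(which(d$v_hat <= 0), collapse = ", "))
  variance_series(d$u, d$v_hat)
}

#' Write a variance series to CSV
#'
#' Writes the two-column `u,v_hat` format at full double precision (so that a
#' write/read round trip is the identity), with an optional JSON metadata
#' sidecar (model, direction, truncation, tipping point).
#'
#' @param series A [variance_series()].
#' @param path Output CSV path.
#' @param meta_path Optional path for the JSON sidecar.
#' @export
write_variance_series <- function(series, path, meta_path = NULL) {
  stopifnot(inherits(series, "variance_series"))
  lines <- c("u,v_hat",
             sprintf("%.17g,%.17g", series$u, series$v_hat))
  writeLines(lines, path)
  if (!is.null(meta_path)) {
    meta <- list(schema = "tipmoc/variance_series/1", model = series$model,
                 direction = series$direction,
                 truncated_by_tipping = series$truncated_by_tipping,
                 tipping_u = series$tipping_u, n = length(series$u))
    jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                         na = "null", null = "null", pretty = TRUE)
  }
  invisible(path)
}

# Flatten one of the package's result objects into a plain, JSON-friendly
# list with a schema tag and a fixed key order.
.as_record <- function(x) {
  if (inherits(x, "power_law_fit"))
    return(c(list(schema = "tipmoc/power_law_fit/1"),
             x[c("a", "u_c_hat", "gamma", "b", "rss", "rho", "n_points",
                 "direction")]))
  if (inherits(x, "linear_fit"))
    return(c(list(schema = "tipmoc/linear_fit/1"),
             x[c("alpha", "beta", "rss", "n_points")]))
  if (inherits(x, "fit_comparison"))
    return(list(schema = "tipmoc/fit_comparison/1",
                a = x$power$a, u_c_hat = x$power$u_c_hat,
                gamma = x$power$gamma, b = x$power$b, rss = x$power$rss,
                rho = x$power$rho, n_points = x$n_points,
                aicc_power = x$aicc_power, aicc_linear = x$aicc_linear,
                delta_aicc = x$delta_aicc))
  if (inherits(x, "detection_result"))
    return(list(schema = "tipmoc/detection_result/1",
                detected = x$detected, u_det = x$u_det, u_c_hat = x$u_c_hat,
                gamma_hat = x$gamma_hat, rho = x$rho,
                stop_reason = x$stop_reason,
                detection_index = x$detection_index,
                ell0 = x$ell0, threshold = x$threshold,
                consecutive = x$consecutive,
                delta_aicc_trace = x$delta_aicc_trace))
  if (inherits(x, "benchmark_summary"))
    return(list(schema = "tipmoc/benchmark_summary/1",
                model_name = x$model_name, scenario = x$scenario,
                n_runs = x$n_runs, tau_mean = x$tau_mean, tau_sd = x$tau_sd,
                pct_detected = x$pct_detected, u_c_true = x$u_c_true,
                u_c_hat_mean = x$u_c_hat_mean, u_c_hat_sd = x$u_c_hat_sd,
                band = x$band, pct_in_band = x$pct_in_band,
                corr_udet_uchat = x$corr_udet_uchat))
  if (is.list(x)) return(x)
  stop("do not know how to serialize an object of class ",
       paste(class(x), collapse = "/"))
}

#' Write a result record as JSON
#'
#' Serializes fit, detection or benchmark objects (or any plain list) to JSON
#' with a schema tag, deterministic key order, `null` for missing optional
#' fields, and full numeric precision. Values that are infinite are written
#' as the strings `"Inf"`/`"-Inf"` (JSON has no infinities).
#'
#' @param record The object to write.
#' @param path Output path.
#' @export
write_results <- function(record, path) {
  rec <- .as_record(record)
  rec <- rapply(rec, function(v) {
    if (is.numeric(v)) {
      v[is.infinite(v)] <- NA  # JSON has no Inf; trace entries become null
      v
    } else v
  }, how = "replace")
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA, na = "null",
                       null = "null", pretty = TRUE, dataframe = "columns")
  invisible(path)
}

#' Benchmark summary as a one-row data frame
#'
#' The tabular shape used for multi-scenario result tables.
#'
#' @param x A `benchmark_summary`.
#' @param ... Unused.
#' @return One-row data frame.
#' @export
as.data.frame.benchmark_summary <- function(x, ...) {
  data.frame(model = x$model_name, scenario = x$scenario, n_runs = x$n_runs,
             tau_mean = x$tau_mean, tau_sd = x$tau_sd,
             pct_detected = x$pct_detected, u_c_true = x$u_c_true,
             u_c_hat_mean = x$u_c_hat_mean, u_c_hat_sd = x$u_c_hat_sd,
             band_lo = x$band[1], band_hi = x$band[2],
             pct_in_band = x$pct_in_band, corr = x$corr_udet_uchat,
             stringsAsFactors = FALSE)
}
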