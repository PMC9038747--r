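#' Goodness-of-fit criteria
#'
#' Computes the five statistics used throughout the package to compare
#' observed (`w`) and predicted (`z`) values:
#' \itemize{
#'   \item `r2` — squared Pearson correlation;
#'   \item `rmse` — root-mean-square error;
#'   \item `si` — scatter index, `RMSE / mean(w)`;
#'   \item `delta_pct` — summed absolute error relative to the summed
#'     observations, in percent;
#'   \item `nse` — Nash-Sutcliffe-style efficiency
#'     `1 - sum((w - z)^2) / sum((w - zbar)^2)`. The default
#'     `"as-printed"` mode normalizes by deviations of the *observations from
#'     the predicted mean* (`zbar`), the variant used in the reference
#'     workflow; mode `"standard"` uses the conventional observed mean.
#' }
#'
#' @param observed Numeric vector of observations `w` (length >= 2, not
#'   constant).
#' @param predicted Numeric vector of predictions `z`, same length.
#' @param nse_mode `"as-printed"` (default) or `"standard"`.
#' @return An object of class `metrics_report`: list with `r2`, `rmse`, `si`,
#'   `delta_pct`, `nse`, `n` and `nse_mode`.
#' @examples
#' compute_metrics(c(1, 2, 3), c(1, 2, 4))
#' @export
compute_metrics <- function(observed, predicted,
                            nse_mode = c("as-printed", "standard")) {
  nse_mode <- match.arg(nse_mode)
  w <- as.numeric(observed)
  z <- as.numeric(predicted)
  if (length(w) != length(z)) stop("`observed` and `predicted` sizes disagree")
  if (length(w) < 2L) stop("need at least 2 samples")
  if (stats::sd(w) == 0) stop("`observed` must not be constant")
  rmse <- sqrt(mean((w - z)^2))
  r2 <- if (stats::sd(z) == 0) 1 - as.numeric(rmse > 0) else
    stats::cor(w, z)^2
  ref <- if (nse_mode == "as-printed") mean(z) else mean(w)
  denom <- sum((w - ref)^2)
  nse <- if (denom == 0) ifelse(rmse == 0, 1, -Inf) else
    1 - sum((w - z)^2) / denom
  structure(list(
    r2 = r2,
    rmse = rmse,
    si = rmse / mean(w),
    delta_pct = sum(abs(z - w)) / sum(w) * 100,
    nse = nse,
    n = length(w),
    nse_mode = nse_mode
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "n = %d | R2 %.4f | RMSE %.5g | SI %.5g | delta %.4g%% | NSE %.4f (%s)\n",
    x$n, x$r2, x$rmse, x$si, x$delta_pct, x$nse, x$nse_mode))
  invisible(x)
}

#' Fraction of predictions within relative-error thresholds
#'
#' For each threshold `t` (percent), the fraction of samples whose relative
#' error `|z - w| / |w| * 100` is below `t`. Samples with a zero observed
#' value are excluded with a warning. Fractions are non-decreasing in the
#' threshold.
#'
#' @param observed,predicted Equal-length numeric vectors.
#' @param thresholds Numeric vector of percent thresholds (default
#'   `c(1, 2, 5, 10)`).
#' @return Data frame with columns `threshold_pct` and `fraction`.
#' @export
error_distribution <- function(observed, predicted,
                               thresholds = c(1, 2, 5, 10)) {
  w <- as.numeric(observed)
  z <- as.numeric(predicted)
  if (length(w) != length(z)) stop("`observed` and `predicted` sizes disagree")
  zero <- w == 0
  if (any(zero)) {
    warning(sum(zero), " sample(s) with observed value 0 excluded")
    w <- w[!zero]
    z <- z[!zero]
  }
  if (!length(w)) stop("no usable samples")
  rel <- abs(z - w) / abs(w) * 100
  data.frame(
    threshold_pct = as.numeric(thresholds),
    fraction = vapply(thresholds, function(t) mean(rel < t), numeric(1))
  )
}

#' Reference input combinations
#'
#' The six candidate input sets considered for yield/WUE estimation, named
#' `w1`..`w6`, over seasonal water consumption (`Ir`), rainfall (`P_e`),
#' relative humidity (`RH_avg`), temperature (`T_emp`) and sunshine hours
#' (`S_sh`).
#'
#' @return Named list of character vectors.
#' @examples
#' standard_combos()$w2
#' @export
standard_combos <- function() {
  list(
    w1 = c("Ir", "P_e", "RH_avg", "T_emp", "S_sh"),
    w2 = c("Ir", "P_e", "RH_avg", "S_sh"),
    w3 = c("Ir", "P_e", "T_emp", "S_sh"),
    w4 = c("Ir", "P_e", "RH_avg", "T_emp"),
    w5 = c("Ir", "T_emp", "RH_avg", "S_sh"),
    w6 = c("T_emp", "P_e", "S_sh")
  )
}

#' Evaluate candidate input combinations
#'
#' Trains one hybrid model per input combination on the *same* data split and
#' optimizer seed, reports the five criteria on the train and test partitions
#' for each, and flags the best combination by test RMSE (ties broken by
#' higher test R-squared, then declaration order).
#'
#' @param table Data frame with all candidate input columns and the target.
#' @param combos Named list of character vectors (default
#'   [standard_combos()]).
#' @param target Target column name.
#' @param config A [trainer_config()] applied identically to every combo.
#' @return An object of class `combo_report`: list with `report` (one data
#'   frame row per combo and split), `best` (name of the winning combo) and
#'   `fits` (the `so_anfis_fit` objects, named by combo).
#' @export
evaluate_combos <- function(table, combos = standard_combos(), target,
                            config = trainer_config()) {
  if (!length(combos)) stop("`combos` must be non-empty")
  if (is.null(names(combos)) || any(!nzchar(names(combos)))) {
    stop("`combos` must be a named list")
  }
  fits <- lapply(combos, function(inputs) {
    train_so_anfis(table, inputs, target, config)
  })
  row_of <- function(name, split, mr) {
    data.frame(combo = name, split = split, r2 = mr$r2, rmse = mr$rmse,
               si = mr$si, delta_pct = mr$delta_pct, nse = mr$nse,
               stringsAsFactors = FALSE)
  }
  report <- do.call(rbind, unlist(lapply(names(fits), function(nm) {
    list(row_of(nm, "train", fits[[nm]]$train_metrics),
         row_of(nm, "test", fits[[nm]]$test_metrics))
  }), recursive = FALSE))
  rownames(report) <- NULL
  test_rmse <- vapply(fits, function(f) f$test_metrics$rmse, numeric(1))
  test_r2 <- vapply(fits, function(f) f$test_metrics$r2, numeric(1))
  ord <- order(test_rmse, -test_r2, seq_along(fits))
  structure(list(report = report, best = names(fits)[ord[1L]], fits = fits),
            class = "combo_report")
}

#' @export
print.combo_report <- function(x, ...) {
  cat("Input-combination evaluation (best by test RMSE: ", x$best, ")\n",
      sep = "")
  print(x$report, digits = 4)
  invisible(x)
}

#' Write a combination report to CSV
#'
#' @param x A `combo_report`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_combo_report <- function(x, path) {
  stopifnot(inherits(x, "combo_report"))
  utils::write.csv(x$report, path, row.names = FALSE)
  invisible(path)
}
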