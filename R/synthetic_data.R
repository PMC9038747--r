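FEATURE_NAMES <- c("Ir", "T_emp", "RH_avg", "S_sh", "P_e")

default_feature_ranges <- function() {
  # Ir range anchors to the observed seasonal water-consumption extremes;
  # the climate ranges are plausible mid-latitude growing-season values.
  list(
    Ir = c(3950, 4945.2),    # m3/ha
    T_emp = c(12, 34),       # degrees C
    RH_avg = c(30, 75),      # percent
    S_sh = c(6, 14),         # sunshine hours
    P_e = c(0, 60)           # mm
  )
}

#' Synthetic feature-table specification
#'
#' Describes how to emulate a field feature table: independent uniform
#' features within configurable ranges, a planted Takagi-Sugeno surface
#' producing the target, and Gaussian noise expressed as a fraction of the
#' clean target range. An optional correlation matrix (Gaussian copula)
#' induces dependence between features; it defaults to off because the
#' emulated records report no covariance structure.
#'
#' @param n_samples Number of rows (default 120, the emulated study size).
#' @param ranges Named list of `c(min, max)` ranges for `Ir`, `T_emp`,
#'   `RH_avg`, `S_sh`, `P_e`; unnamed entries fall back to the defaults.
#' @param true_model The planted `anfis_model` generating targets (default
#'   [default_planted_model()]).
#' @param noise_sd Noise standard deviation as a fraction of the clean target
#'   range (default 0.02).
#' @param correlation Optional feature correlation matrix (5 x 5) for the
#'   Gaussian copula; `NULL` (default) keeps features independent.
#' @param seed Optional integer seed.
#' @return An object of class `generator_spec`.
#' @export
generator_spec <- function(n_samples = 120L, ranges = list(),
                           true_model = default_planted_model(),
                           noise_sd = 0.02, correlation = NULL, seed = NULL) {
  n_samples <- as.integer(n_samples)
  if (is.na(n_samples) || n_samples < 0L) stop("`n_samples` must be >= 0")
  if (!is.numeric(noise_sd) || noise_sd < 0) stop("`noise_sd` must be >= 0")
  full <- default_feature_ranges()
  for (nm in names(ranges)) {
    if (!nm %in% FEATURE_NAMES) stop("unknown feature: ", nm)
    r <- as.numeric(ranges[[nm]])
    if (length(r) != 2L || !all(is.finite(r)) || r[1L] > r[2L]) {
      stop("range for ", nm, " must be a finite c(min, max)")
    }
    full[[nm]] <- r
  }
  if (!is.null(correlation)) {
    correlation <- as.matrix(correlation)
    if (!all(dim(correlation) == length(FEATURE_NAMES)) ||
        any(abs(correlation - t(correlation)) > 1e-12)) {
      stop("`correlation` must be a symmetric 5 x 5 matrix")
    }
  }
  stopifnot(inherits(true_model, "anfis_model"))
  structure(list(n_samples = n_samples, ranges = full,
                 true_model = true_model, noise_sd = as.numeric(noise_sd),
                 correlation = correlation,
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "generator_spec")
}

#' Default planted fuzzy surface
#'
#' A three-rule Takagi-Sugeno model over `Ir`, `P_e`, `RH_avg` and `S_sh`
#' (the four-input combination without temperature) producing a yield-like
#' target around 30,000 kg/ha. Consequent slopes are scaled by the inverse
#' feature range so every input contributes a comparable share of the target
#' variance, giving combination-recovery tests a planted ground truth.
#'
#' @param target_name Label for the generated response (default `"yield"`).
#' @return An `anfis_model` with solved (hand-set) consequents.
#' @export
default_planted_model <- function(target_name = "yield") {
  ranges <- default_feature_ranges()
  inputs <- c("Ir", "P_e", "RH_avg", "S_sh")
  lo <- vapply(ranges[inputs], `[`, numeric(1), 1L)
  hi <- vapply(ranges[inputs], `[`, numeric(1), 2L)
  rng <- hi - lo
  mid <- (lo + hi) / 2
  at <- function(q) lo + q * rng
  centers <- rbind(at(0.25), at(0.55), at(0.80))
  sigmas <- rbind(0.30 * rng, 0.25 * rng, 0.30 * rng)
  # per-rule slope magnitudes in kg/ha across one full feature range
  gain <- rbind(
    c(3200, -2100, 1600, 2600),
    c(2400, 1800, -2200, -1500),
    c(-2800, 1200, 2000, 3000)
  )
  slopes <- sweep(gain, 2L, rng, `/`)
  base <- c(28000, 30500, 33000)
  intercepts <- base - as.numeric(slopes %*% mid)
  anfis_model(centers, sigmas, consequents = cbind(slopes, intercepts),
              input_names = inputs, target_name = target_name)
}

#' Generate the feature columns
#'
#' Draws every feature independently and uniformly within its configured
#' range (or through a Gaussian copula when a correlation matrix is set),
#' seeded for reproducibility. Targets are left unset.
#'
#' @param spec A [generator_spec()].
#' @return Data frame with a `row_id` column and the five feature columns.
#' @export
generate_features <- function(spec) {
  stopifnot(inherits(spec, "generator_spec"))
  n <- spec$n_samples
  draw <- function() {
    m <- length(FEATURE_NAMES)
    u <- if (is.null(spec$correlation)) {
      matrix(stats::runif(n * m), n, m)
    } else {
      z <- matrix(stats::rnorm(n * m), n, m) %*% chol(spec$correlation)
      stats::pnorm(z)
    }
    out <- data.frame(row_id = seq_len(n))
    for (j in seq_along(FEATURE_NAMES)) {
      r <- spec$ranges[[FEATURE_NAMES[j]]]
      out[[FEATURE_NAMES[j]]] <-
        r[1L] + (if (n) u[, j] else numeric(0)) * (r[2L] - r[1L])
    }
    out
  }
  with_local_seed(spec$seed, draw())
}

#' Attach planted-surface targets
#'
#' Evaluates the planted model on the feature rows and adds zero-mean
#' Gaussian noise with standard deviation `noise_sd` times the clean target
#' range. The planted model is attached as attribute `true_model` for
#' recovery tests.
#'
#' @param table Feature table from [generate_features()].
#' @param spec The same [generator_spec()].
#' @return The table with the target column appended.
#' @export
generate_targets <- function(table, spec) {
  stopifnot(inherits(spec, "generator_spec"))
  model <- spec$true_model
  missing <- setdiff(model$input_names, names(table))
  if (length(missing)) {
    stop("table lacks planted-model input(s): ",
         paste(missing, collapse = ", "))
  }
  clean <- if (nrow(table)) anfis_infer(model, table) else numeric(0)
  spread <- if (length(clean) > 1L) diff(range(clean)) else 0
  noise <- if (spec$noise_sd > 0 && spread > 0 && nrow(table)) {
    with_local_seed(if (is.null(spec$seed)) NULL else spec$seed + 1L,
                    stats::rnorm(nrow(table), 0, spec$noise_sd * spread))
  } else {
    numeric(nrow(table))
  }
  table[[model$target_name]] <- clean + noise
  attr(table, "true_model") <- model
  table
}

#' @describeIn generate_features Convenience wrapper: features plus targets
#'   in one call.
#' @export
generate_table <- function(spec) {
  generate_targets(generate_features(spec), spec)
}

#' Load a packaged fixture table
#'
#' The package ships the printed treatment tables used for the headline
#' comparisons: per-event irrigation characteristics (`"table4_events"`:
#' inlet flow, cut-off time, applied and net depths, application efficiency
#' for the BI/NSI/TSFI treatments over four irrigation events), per-treatment
#' yield and WUE summaries (`"table5_summary"`), and the candidate input
#' combinations (`"table7_combos"`, returned as a named list of character
#' vectors).
#'
#' @param name One of `"table4_events"`, `"table5_summary"`,
#'   `"table7_combos"`.
#' @return A data frame, or a named list for `"table7_combos"`.
#' @examples
#' load_fixture("table5_summary")
#' @export
load_fixture <- function(name) {
  choices <- c("table4_events", "table5_summary", "table7_combos")
  if (!is.character(name) || length(name) != 1L || !name %in% choices) {
    stop("unknown fixture; expected one of: ",
         paste(choices, collapse = ", "))
  }
  path <- system.file("extdata", paste0(name, ".csv"), package = "soanfis",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (name == "table7_combos") {
    combos <- strsplit(df$inputs, ";", fixed = TRUE)
    names(combos) <- df$combo
    return(combos)
  }
  df
}

#' Read a feature table from CSV
#'
#' Expects a comma-separated, header-first, `.`-decimal file containing at
#' least the five feature columns (`Ir`, `T_emp`, `RH_avg`, `S_sh`, `P_e`);
#' any further columns (target, metadata) are preserved as-is. Non-numeric
#' cells in a feature or target column are reported with their row and
#' column.
#'
#' @param path CSV path.
#' @param target Optional target column name that must also be present.
#' @return A data frame.
#' @export
read_feature_table <- function(path, target = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c(FEATURE_NAMES, target)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  for (col in required) {
    v <- df[[col]]
    if (!is.numeric(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad)) {
        stop(sprintf("non-numeric value in column '%s', row %d: '%s'",
                     col, bad[1L], v[bad[1L]]))
      }
      df[[col]] <- num
    }
  }
  df
}

#' Write a feature table to CSV
#'
#' Numeric columns are written as decimal text with 12 significant digits so
#' a write/read round trip preserves values to that precision; column order
#' and row order are stable and unknown columns survive.
#'
#' @param table A data frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  out <- table
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      out[[col]] <- formatC(out[[col]], digits = 12, format = "g")
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
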