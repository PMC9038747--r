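#' Hybrid trainer configuration
#'
#' Bundles the optimizer settings with the fuzzy-model hyperparameters and the
#' train/test protocol: a single seeded random 80/20 split, fuzzy-c-means
#' premise initialization, and Seasons Optimization over the premise vector
#' with the training RMSE (negated) as strength.
#'
#' @param so An [so_config()]; defaults to the reference settings
#'   (population 50, 3000 evaluations).
#' @param n_rules Number of fuzzy rules (default 3).
#' @param ridge Ridge penalty for the consequent solve (default 1e-8).
#' @param test_fraction Held-out fraction in `(0, 1)` (default 0.20).
#' @param split_seed Seed for the random partition (default: derived from the
#'   optimizer seed when present).
#' @param fuzzifier,fcm_max_iter Fuzzy c-means settings for initialization.
#' @return An object of class `trainer_config`.
#' @export
trainer_config <- function(so = so_config(), n_rules = 3L, ridge = 1e-8,
                           test_fraction = 0.20, split_seed = NULL,
                           fuzzifier = 2, fcm_max_iter = 300L) {
  stopifnot(inherits(so, "so_config"))
  n_rules <- as.integer(n_rules)
  if (is.na(n_rules) || n_rules < 1L) stop("`n_rules` must be >= 1")
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1) {
    stop("`test_fraction` must lie strictly between 0 and 1")
  }
  if (is.null(split_seed) && !is.null(so$seed)) split_seed <- so$seed + 1L
  structure(list(so = so, n_rules = n_rules, ridge = as.numeric(ridge),
                 test_fraction = as.numeric(test_fraction),
                 split_seed = if (is.null(split_seed)) NULL else
                   as.integer(split_seed),
                 fuzzifier = fuzzifier,
                 fcm_max_iter = as.integer(fcm_max_iter)),
            class = "trainer_config")
}

#' Encode a model's premise parameters as a search vector
#'
#' Flattens all `(c_ij, sigma_ij)` into a vector of length `D = 2 n m` in
#' fixed rule-major order — for each rule, all `m` centers then all `m`
#' widths. Search bounds come from the training features: each center may
#' roam the observed `[min_j, max_j]`, each width `[1%, 100%]` of the feature
#' range (so width lower bounds are strictly positive).
#'
#' @param model An `anfis_model` supplying the premises and the layout.
#' @param X Training feature matrix or data frame (used only for the bounds).
#' @return A list with `vector` (length `2 n m`) and `bounds`
#'   (an [so_bounds()]).
#' @export
encode_premises <- function(model, X) {
  stopifnot(inherits(model, "anfis_model"))
  X <- model_matrix_inputs(model, X)
  if (nrow(X) < 1L) stop("empty training data")
  k <- n_rules(model)
  m <- n_inputs(model)
  vec <- as.numeric(t(cbind(model$centers, model$sigmas)))
  lo_f <- apply(X, 2L, min)
  hi_f <- apply(X, 2L, max)
  rng <- pmax(hi_f - lo_f, 1e-8)
  lower <- rep(c(lo_f, 0.01 * rng), times = k)
  upper <- rep(c(hi_f, rng), times = k)
  list(vector = vec, bounds = so_bounds(lower, upper))
}

#' Decode a premise search vector into a model
#'
#' Inverse of [encode_premises()]: rebuilds the centers and widths from the
#' rule-major layout of the template model. Consequents are left unset (they
#' are re-solved per candidate during training).
#'
#' @param vector Numeric vector of length `2 n m`.
#' @param template An `anfis_model` defining `n`, `m` and the labels.
#' @return An `anfis_model` with new premises and `NULL` consequents.
#' @export
decode_premises <- function(vector, template) {
  stopifnot(inherits(template, "anfis_model"))
  k <- n_rules(template)
  m <- n_inputs(template)
  if (length(vector) != 2L * k * m) {
    stop("premise vector must have length ", 2L * k * m)
  }
  per_rule <- matrix(vector, nrow = k, ncol = 2L * m, byrow = TRUE)
  centers <- per_rule[, seq_len(m), drop = FALSE]
  sigmas <- per_rule[, m + seq_len(m), drop = FALSE]
  if (any(sigmas <= 0)) stop("decoded membership widths must be positive")
  anfis_model(centers, sigmas, consequents = NULL,
              input_names = template$input_names,
              target_name = template$target_name)
}

#' Strength of a premise candidate
#'
#' Decodes the premises, solves the consequents on the training data by ridge
#' least squares, and returns the *negated* training RMSE so that the
#' maximizing optimizer minimizes the error. Each invocation is one fitness
#' evaluation.
#'
#' @param vector Premise search vector (see [encode_premises()]).
#' @param X_train,y_train Training features and response.
#' @param template Template `anfis_model` fixing the layout.
#' @param ridge Ridge penalty for the consequent solve.
#' @return `-RMSE` on the training data (a scalar, `<= 0`).
#' @export
training_strength <- function(vector, X_train, y_train, template,
                              ridge = 1e-8) {
  make_training_strength(X_train, y_train, template, ridge)(vector)
}

#' @describeIn training_strength Factory returning a fast closure over
#'   pre-validated training matrices, suitable as `strength_fn` for
#'   [so_optimize()].
#' @export
make_training_strength <- function(X_train, y_train, template,
                                   ridge = 1e-8) {
  stopifnot(inherits(template, "anfis_model"))
  X <- model_matrix_inputs(template, X_train)
  y <- as.numeric(y_train)
  if (nrow(X) != length(y)) stop("`X_train` and `y_train` sizes disagree")
  k <- n_rules(template)
  m <- n_inputs(template)
  p <- m + 1L
  Xc <- cbind(X, 1)
  n <- nrow(X)
  d_len <- 2L * k * m
  col_w <- rep(seq_len(k), each = p)
  col_x <- rep(seq_len(p), times = k)
  ridge_eye <- ridge * diag(k * p)
  function(vector) {
    if (length(vector) != d_len) stop("premise vector must have length ", d_len)
    per_rule <- matrix(vector, nrow = k, ncol = 2L * m, byrow = TRUE)
    centers <- per_rule[, seq_len(m), drop = FALSE]
    sigmas <- per_rule[, m + seq_len(m), drop = FALSE]
    mu <- matrix(1, n, k)
    for (i in seq_len(k)) {
      z <- sweep(X, 2L, centers[i, ], `-`)
      z <- sweep(z, 2L, sigmas[i, ], `/`)
      mu[, i] <- exp(-0.5 * rowSums(z * z))
    }
    tot <- rowSums(mu)
    bad <- which(tot < 1e-300)
    if (length(bad)) {
      d2 <- matrix(0, length(bad), k)
      for (i in seq_len(k)) {
        z <- sweep(X[bad, , drop = FALSE], 2L, centers[i, ], `-`)
        z <- sweep(z, 2L, sigmas[i, ], `/`)
        d2[, i] <- rowSums(z * z)
      }
      mu[bad, ] <- 0
      mu[cbind(bad, max.col(-d2, ties.method = "first"))] <- 1
      tot[bad] <- 1
    }
    W <- mu / tot
    Phi <- W[, col_w, drop = FALSE] * Xc[, col_x, drop = FALSE]
    beta <- tryCatch(
      solve(crossprod(Phi) + ridge_eye, crossprod(Phi, y)),
      error = function(e) NULL
    )
    if (is.null(beta)) return(-Inf)
    resid <- y - drop(Phi %*% beta)
    -sqrt(mean(resid^2))
  }
}

#' Random train/test split
#'
#' Seeded uniform partition without replacement into `ceiling((1 - f) n)`
#' training rows and the remaining `floor(f n)` test rows; disjoint and
#' exhaustive.
#'
#' @param table A data frame (at least 5 rows).
#' @param test_fraction Held-out fraction (default 0.20).
#' @param seed Optional seed; the global RNG state is preserved.
#' @return A list with data frames `train`, `test` and the integer row
#'   indices `train_idx`, `test_idx`.
#' @export
split_train_test <- function(table, test_fraction = 0.20, seed = NULL) {
  n <- nrow(table)
  if (is.null(n) || n < 5L) stop("need at least 5 rows to split")
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("`test_fraction` must lie strictly between 0 and 1")
  }
  n_train <- ceiling((1 - test_fraction) * n)
  idx <- with_local_seed(seed, sample.int(n, n_train))
  train_idx <- sort(idx)
  test_idx <- setdiff(seq_len(n), train_idx)
  list(train = table[train_idx, , drop = FALSE],
       test = table[test_idx, , drop = FALSE],
       train_idx = train_idx, test_idx = test_idx)
}

#' Train a fuzzy model with the hybrid optimizer
#'
#' The full hybrid loop: restrict the table to the requested input
#' combination, split it once into train/test, initialize the premises by
#' fuzzy c-means (the resulting premise vector is injected into the initial
#' forest so the metaheuristic starts no worse than the deterministic
#' initializer), run Seasons Optimization over the premise vector with
#' negated training RMSE as strength, decode the best vector, re-solve the
#' consequents on the training rows, and score both partitions.
#'
#' @param table Data frame holding the input columns and the target column.
#' @param inputs Character vector of input column names, or a combo from
#'   [standard_combos()].
#' @param target Name of the target column.
#' @param config A [trainer_config()].
#' @return An object of class `so_anfis_fit`: list with `model`
#'   (`anfis_model`), `train_metrics`, `test_metrics` (see
#'   [compute_metrics()]), `so_trace` (per-generation best train RMSE),
#'   `fe_used`, `init_train_rmse` (fuzzy-c-means baseline), and the split row
#'   indices `train_idx`/`test_idx`.
#' @examples
#' \donttest{
#' spec <- generator_spec(n_samples = 80, seed = 1)
#' tab <- generate_table(spec)
#' cfg <- trainer_config(so = so_config(population_size = 10, fe_budget = 120,
#'                                      seed = 1))
#' fit <- train_so_anfis(tab, standard_combos()$w2, "yield", cfg)
#' fit$test_metrics$r2
#' }
#' @export
train_so_anfis <- function(table, inputs, target, config = trainer_config()) {
  stopifnot(inherits(config, "trainer_config"))
  inputs <- as.character(inputs)
  missing <- setdiff(c(inputs, target), names(table))
  if (length(missing)) {
    stop("missing column(s): ", paste(missing, collapse = ", "))
  }
  if (config$so$fe_budget < config$so$population_size) {
    stop("fitness budget smaller than the population size")
  }
  split <- split_train_test(table, config$test_fraction, config$split_seed)
  X_train <- as.matrix(split$train[inputs])
  y_train <- as.numeric(split$train[[target]])
  X_test <- as.matrix(split$test[inputs])
  y_test <- as.numeric(split$test[[target]])

  fcm_seed <- if (is.null(config$so$seed)) NULL else config$so$seed + 2L
  init <- anfis_init_fcm(X_train, y_train, k = config$n_rules,
                         fuzzifier = config$fuzzifier,
                         max_iter = config$fcm_max_iter, seed = fcm_seed,
                         input_names = inputs, target_name = target,
                         ridge = config$ridge)
  enc <- encode_premises(init, X_train)
  start <- pmin(pmax(enc$vector, enc$bounds$lower), enc$bounds$upper)
  strength <- make_training_strength(X_train, y_train, init,
                                     ridge = config$ridge)
  res <- so_optimize(strength, enc$bounds, config$so,
                     seeds = matrix(start, nrow = 1L))
  model <- decode_premises(res$best_position, init)
  model <- solve_consequents(model, X_train, y_train, ridge = config$ridge)

  trace <- res$trace
  trace$best_train_rmse <- -trace$best_strength
  structure(list(
    model = model,
    train_metrics = compute_metrics(y_train, anfis_infer(model, X_train)),
    test_metrics = compute_metrics(y_test, anfis_infer(model, X_test)),
    so_trace = trace,
    fe_used = res$fe_used,
    init_train_rmse = -strength(start),
    inputs = inputs,
    target = target,
    train_idx = split$train_idx,
    test_idx = split$test_idx
  ), class = "so_anfis_fit")
}

#' @export
print.so_anfis_fit <- function(x, ...) {
  cat("SO-trained Takagi-Sugeno model\n")
  cat("  inputs :", paste(x$inputs, collapse = ", "), "\n")
  cat("  target :", x$target, "\n")
  cat(sprintf("  train  : RMSE %.5g, R2 %.4f\n",
              x$train_metrics$rmse, x$train_metrics$r2))
  cat(sprintf("  test   : RMSE %.5g, R2 %.4f\n",
              x$test_metrics$rmse, x$test_metrics$r2))
  cat(sprintf("  evaluations: %d\n", x$fe_used))
  invisible(x)
}
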