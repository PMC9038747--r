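#' Construct a first-order Takagi-Sugeno fuzzy model
#'
#' A model is `n` rules over `m` inputs. Rule `i` reads "if `x_1` is
#' Gaussian(`c_i1`, `sigma_i1`) and ... and `x_m` is Gaussian(`c_im`,
#' `sigma_im`) then `y_i = s_i1 x_1 + ... + s_im x_m + s_i0`". Predictions are
#' the firing-strength-weighted average of the rule outputs.
#'
#' @param centers Numeric `n x m` matrix of membership centers `c_ij`.
#' @param sigmas Numeric `n x m` matrix of membership widths `sigma_ij`
#'   (all strictly positive).
#' @param consequents Optional `n x (m + 1)` matrix: `m` slopes followed by an
#'   intercept per rule. May be `NULL` until solved.
#' @param input_names Character vector of the `m` input labels.
#' @param target_name Label of the response (default `"target"`).
#' @return An object of class `anfis_model`.
#' @examples
#' anfis_model(centers = matrix(0, 1, 2), sigmas = matrix(1, 1, 2),
#'             consequents = matrix(c(1, -1, 0), 1, 3),
#'             input_names = c("a", "b"))
#' @export
anfis_model <- function(centers, sigmas, consequents = NULL,
                        input_names = NULL, target_name = "target") {
  centers <- as.matrix(centers)
  sigmas <- as.matrix(sigmas)
  if (!all(dim(centers) == dim(sigmas))) {
    stop("`centers` and `sigmas` must have identical dimensions")
  }
  if (nrow(centers) < 1L) stop("a model needs at least one rule")
  if (any(!is.finite(sigmas)) || any(sigmas <= 0)) {
    stop("all membership widths must be positive and finite")
  }
  m <- ncol(centers)
  if (is.null(input_names)) input_names <- paste0("x", seq_len(m))
  if (length(input_names) != m) {
    stop("`input_names` must have one label per input column")
  }
  if (!is.null(consequents)) {
    consequents <- as.matrix(consequents)
    if (nrow(consequents) != nrow(centers) || ncol(consequents) != m + 1L) {
      stop("`consequents` must be an n x (m + 1) matrix (slopes, intercept)")
    }
  }
  structure(list(centers = centers, sigmas = sigmas,
                 consequents = consequents,
                 input_names = as.character(input_names),
                 target_name = as.character(target_name)),
            class = "anfis_model")
}

n_rules <- function(model) nrow(model$centers)
n_inputs <- function(model) ncol(model$centers)

#' Gaussian membership degree
#'
#' `exp(-1/2 ((x - c) / sigma)^2)`: equals 1 exactly at the center and decays
#' strictly with `|x - c|`. Vectorized over `x`.
#'
#' @param x Numeric vector of input values.
#' @param c Center of the membership function.
#' @param sigma Width (standard deviation), strictly positive.
#' @return Membership degrees in `(0, 1]`.
#' @examples
#' gaussian_membership(c(0, 1), c = 0, sigma = 1)
#' @export
gaussian_membership <- function(x, c, sigma) {
  if (!is.numeric(sigma) || any(sigma <= 0)) stop("`sigma` must be positive")
  exp(-0.5 * ((x - c) / sigma)^2)
}

#' Firing strength of one rule
#'
#' The product of the per-input Gaussian membership degrees,
#' `mu_i = prod_j q_ij(x_j)`.
#'
#' @param x Numeric input vector of length `m`.
#' @param centers,sigmas Numeric vectors of length `m`: the rule's premise
#'   parameters.
#' @return A non-negative scalar firing strength.
#' @export
rule_firing <- function(x, centers, sigmas) {
  if (length(x) != length(centers) || length(centers) != length(sigmas)) {
    stop("`x`, `centers` and `sigmas` must share the same length")
  }
  prod(gaussian_membership(x, centers, sigmas))
}

## Internal: n_samples x n_rules matrix of raw firing strengths. X is a
## numeric matrix with columns in model input order.
firing_matrix <- function(model, X) {
  n <- nrow(X)
  k <- n_rules(model)
  mu <- matrix(1, n, k)
  for (i in seq_len(k)) {
    z <- sweep(X, 2L, model$centers[i, ], `-`)
    z <- sweep(z, 2L, model$sigmas[i, ], `/`)
    mu[, i] <- exp(-0.5 * rowSums(z * z))
  }
  mu
}

## Internal: normalized firing weights with the degenerate-firing fallback —
## rows whose total firing underflows are hard-assigned to the rule with the
## nearest sigma-scaled center (SO explores extreme premises, so this happens).
normalized_firing <- function(model, X, floor = 1e-300) {
  mu <- firing_matrix(model, X)
  tot <- rowSums(mu)
  bad <- which(tot < floor)
  if (length(bad)) {
    k <- n_rules(model)
    d2 <- matrix(0, length(bad), k)
    for (i in seq_len(k)) {
      z <- sweep(X[bad, , drop = FALSE], 2L, model$centers[i, ], `-`)
      z <- sweep(z, 2L, model$sigmas[i, ], `/`)
      d2[, i] <- rowSums(z * z)
    }
    mu[bad, ] <- 0
    mu[cbind(bad, max.col(-d2, ties.method = "first"))] <- 1
    tot[bad] <- 1
  }
  mu / tot
}

## Internal: coerce newdata (data.frame or matrix) to the model's input
## columns, in order.
model_matrix_inputs <- function(model, newdata) {
  if (is.data.frame(newdata)) {
    missing <- setdiff(model$input_names, names(newdata))
    if (length(missing)) {
      stop("missing input column(s): ", paste(missing, collapse = ", "))
    }
    newdata <- as.matrix(newdata[model$input_names])
  } else {
    newdata <- as.matrix(newdata)
    if (ncol(newdata) != n_inputs(model)) {
      stop("`newdata` must have ", n_inputs(model), " columns")
    }
  }
  storage.mode(newdata) <- "double"
  newdata
}

#' Evaluate a Takagi-Sugeno model
#'
#' Computes `f(x) = sum_i mu_i f_i / sum_i mu_i` with `f_i` the rule's linear
#' consequent. When the total firing underflows (below 1e-300) the output of
#' the rule with the nearest width-scaled center is used instead.
#'
#' @param model A fitted [anfis_model()] (consequents present).
#' @param newdata Data frame containing the model's input columns, or a
#'   numeric matrix/vector in input order.
#' @return Numeric vector of predictions.
#' @export
anfis_infer <- function(model, newdata) {
  stopifnot(inherits(model, "anfis_model"))
  if (is.null(model$consequents)) {
    stop("model has no consequent parameters; call solve_consequents() first")
  }
  if (is.numeric(newdata) && is.null(dim(newdata))) {
    newdata <- matrix(newdata, nrow = 1L)
  }
  X <- model_matrix_inputs(model, newdata)
  W <- normalized_firing(model, X)
  fo <- cbind(X, 1) %*% t(model$consequents)  # n x k rule outputs
  rowSums(W * fo)
}

#' @rdname anfis_infer
#' @param object An `anfis_model`.
#' @param ... Unused.
#' @export
predict.anfis_model <- function(object, newdata, ...) {
  anfis_infer(object, newdata)
}

#' Fuzzy c-means clustering
#'
#' Standard fuzzy c-means: soft memberships `u_ik` (rows sum to one) and
#' centers are alternated until the largest center shift drops below `tol`.
#' Samples coinciding with a center are hard-assigned. The fuzzified
#' within-cluster objective is non-increasing across iterations.
#'
#' @param X Numeric matrix (`n_samples x m`) or data frame of features.
#' @param k Number of clusters, `1 <= k <= n_samples`.
#' @param fuzzifier Fuzziness exponent `> 1` (default 2).
#' @param tol Convergence tolerance on the center shift (default 1e-6).
#' @param max_iter Iteration cap (default 300).
#' @param seed Optional seed for the random membership initialization; the
#'   global RNG state is preserved.
#' @return A list with `centers` (`k x m`), `memberships` (`n_samples x k`),
#'   `objective` (per-iteration trace) and `iterations`.
#' @export
fcm_cluster <- function(X, k, fuzzifier = 2, tol = 1e-6, max_iter = 300L,
                        seed = NULL) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  n <- nrow(X)
  k <- as.integer(k)
  if (k < 1L) stop("`k` must be at least 1")
  if (n < k) stop("need at least `k` samples")
  if (fuzzifier <= 1) stop("`fuzzifier` must exceed 1")
  run <- function() {
    u <- matrix(stats::runif(n * k), n, k)
    u <- u / rowSums(u)
    centers <- matrix(0, k, ncol(X))
    obj <- numeric(0)
    it <- 0L
    repeat {
      it <- it + 1L
      um <- u^fuzzifier
      new_centers <- (t(um) %*% X) / colSums(um)
      d2 <- matrix(0, n, k)
      for (i in seq_len(k)) {
        d2[, i] <- rowSums(sweep(X, 2L, new_centers[i, ], `-`)^2)
      }
      obj <- c(obj, sum(um * d2))
      zero <- d2 < 1e-300
      any_zero <- rowSums(zero) > 0
      expo <- 1 / (fuzzifier - 1)
      inv <- d2^(-expo)
      u <- inv / rowSums(inv)
      hard <- any_zero | !is.finite(rowSums(u))
      if (any(hard)) {
        u[hard, ] <- 0
        u[cbind(which(hard), max.col(-d2[hard, , drop = FALSE],
                                     ties.method = "first"))] <- 1
      }
      shift <- max(abs(new_centers - centers))
      centers <- new_centers
      if (shift < tol || it >= max_iter) break
    }
    list(centers = centers, memberships = u, objective = obj, iterations = it)
  }
  with_local_seed(seed, run())
}

#' Initialize a fuzzy model from fuzzy c-means clusters
#'
#' Places one rule per cluster: centers at the cluster centers, widths at the
#' membership-weighted standard deviation of each feature around its center,
#' floored at 1% of the feature range so degenerate clusters stay usable.
#' Consequents are then solved by [solve_consequents()].
#'
#' @inheritParams fcm_cluster
#' @param y Numeric response vector, one value per row of `X`.
#' @param input_names,target_name Labels for the resulting model; input names
#'   default to `colnames(X)`.
#' @param ridge Ridge penalty passed to [solve_consequents()].
#' @return A fitted `anfis_model` with `k` rules.
#' @export
anfis_init_fcm <- function(X, y, k, fuzzifier = 2, tol = 1e-6,
                           max_iter = 300L, seed = NULL,
                           input_names = NULL, target_name = "target",
                           ridge = 1e-8) {
  X <- as.matrix(X)
  if (is.null(input_names)) {
    input_names <- colnames(X)
    if (is.null(input_names)) input_names <- paste0("x", seq_len(ncol(X)))
  }
  fit <- fcm_cluster(X, k, fuzzifier = fuzzifier, tol = tol,
                     max_iter = max_iter, seed = seed)
  um <- fit$memberships^fuzzifier
  rng <- apply(X, 2L, function(col) diff(range(col)))
  floor_sigma <- pmax(0.01 * rng, 1e-8)
  sigmas <- matrix(0, k, ncol(X))
  for (i in seq_len(k)) {
    dev2 <- sweep(X, 2L, fit$centers[i, ], `-`)^2
    sigmas[i, ] <- sqrt(colSums(um[, i] * dev2) / sum(um[, i]))
  }
  sigmas <- pmax(sigmas, matrix(floor_sigma, k, ncol(X), byrow = TRUE))
  model <- anfis_model(fit$centers, sigmas, input_names = input_names,
                       target_name = target_name)
  solve_consequents(model, X, y, ridge = ridge)
}

#' Solve the linear consequent parameters
#'
#' With premises fixed, every sample contributes its normalized firing weights
#' times `[x, 1]` per rule to one global design matrix; the stacked consequent
#' vector is the ridge-regularized least-squares solution. The normalization
#' couples rules, so the fit is global rather than per-rule. Premises are
#' unchanged.
#'
#' @param model An `anfis_model` (premises set; consequents overwritten).
#' @param X Feature matrix or data frame with the model's input columns.
#' @param y Numeric response.
#' @param ridge Small non-negative ridge penalty (default 1e-8) guaranteeing a
#'   finite solution even with fewer samples than parameters.
#' @return The model with `consequents` filled in.
#' @export
solve_consequents <- function(model, X, y, ridge = 1e-8) {
  stopifnot(inherits(model, "anfis_model"))
  X <- model_matrix_inputs(model, X)
  y <- as.numeric(y)
  if (nrow(X) != length(y)) stop("`X` and `y` sizes disagree")
  if (length(y) < 1L) stop("need at least one sample")
  k <- n_rules(model)
  m <- n_inputs(model)
  W <- normalized_firing(model, X)
  Xc <- cbind(X, 1)
  p <- m + 1L
  # Phi[, (i-1)*p + j] = W[, i] * Xc[, j]
  Phi <- W[, rep(seq_len(k), each = p), drop = FALSE] *
    Xc[, rep(seq_len(p), times = k), drop = FALSE]
  A <- crossprod(Phi) + ridge * diag(k * p)
  b <- crossprod(Phi, y)
  beta <- solve(A, b)
  model$consequents <- matrix(beta, nrow = k, ncol = p, byrow = TRUE)
  model
}

#' Serialize a fuzzy model to JSON
#'
#' Writes input/target labels, per-rule premise parameters and consequents.
#' The round trip through [anfis_from_json()] is bit-exact.
#'
#' @param model An `anfis_model`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return `path` (invisibly) when writing to a file, otherwise a JSON string.
#' @export
anfis_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "anfis_model"))
  doc <- list(
    input_names = model$input_names,
    target_name = model$target_name,
    rules = lapply(seq_len(n_rules(model)), function(i) {
      list(centers = model$centers[i, ],
           sigmas = model$sigmas[i, ],
           consequents = if (is.null(model$consequents)) NULL else
             model$consequents[i, ])
    })
  )
  # 17 significant digits: lossless text round trip for IEEE doubles
  js <- jsonlite::toJSON(doc, digits = I(17), auto_unbox = TRUE,
                         null = "null")
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}

#' Deserialize a fuzzy model from JSON
#'
#' @param source A file path or a JSON string produced by [anfis_to_json()].
#' @return An `anfis_model`.
#' @export
anfis_from_json <- function(source) {
  doc <- jsonlite::fromJSON(source, simplifyVector = FALSE)
  rules <- doc$rules
  if (is.null(rules) || !length(rules)) stop("JSON document contains no rules")
  centers <- do.call(rbind, lapply(rules, function(r) as.numeric(r$centers)))
  sigmas <- do.call(rbind, lapply(rules, function(r) as.numeric(r$sigmas)))
  cons <- if (is.null(rules[[1L]]$consequents)) NULL else
    do.call(rbind, lapply(rules, function(r) as.numeric(r$consequents)))
  anfis_model(centers, sigmas, consequents = cons,
              input_names = unlist(doc$input_names),
              target_name = doc$target_name)
}

#' @export
print.anfis_model <- function(x, ...) {
  cat(sprintf("Takagi-Sugeno fuzzy model: %d rule(s), %d input(s)\n",
              n_rules(x), n_inputs(x)))
  cat("  inputs :", paste(x$input_names, collapse = ", "), "\n")
  cat("  target :", x$target_name, "\n")
  cat("  consequents:", if (is.null(x$consequents)) "unset" else "solved",
      "\n")
  invisible(x)
}
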