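#' Bounds of the search space
#'
#' A pair of equal-length numeric vectors delimiting a box-constrained search
#' domain. Every candidate position produced by the optimizer is kept inside
#' `[lower, upper]` component-wise.
#'
#' @param lower Numeric vector of lower limits (one per dimension).
#' @param upper Numeric vector of upper limits, same length as `lower`.
#' @return An object of class `so_bounds` with elements `lower`, `upper` and
#'   `d` (the dimension).
#' @examples
#' so_bounds(c(0, 0), c(1, 1))
#' @export
so_bounds <- function(lower, upper) {
  lower <- as.numeric(lower)
  upper <- as.numeric(upper)
  if (length(lower) != length(upper) || length(lower) < 1L) {
    stop("`lower` and `upper` must be non-empty vectors of equal length")
  }
  if (!all(is.finite(lower)) || !all(is.finite(upper))) {
    stop("bounds must be finite")
  }
  if (any(lower > upper)) {
    stop("every lower bound must not exceed its upper bound")
  }
  structure(list(lower = lower, upper = upper, d = length(lower)),
            class = "so_bounds")
}

#' Seasons Optimization configuration
#'
#' Collects the tunable parameters of the Seasons Optimization (SO)
#' metaheuristic: a population ("forest") of candidate solutions ("trees") is
#' evolved through four seasonal operators per generation — renew (spring,
#' random immigrants from last autumn's seeds), competition (summer, local
#' crowding-damped growth and cored-tree replacement), seeding (autumn,
#' elitist component-resampling offspring) and resistance (winter, culling of
#' the weakest and restoration of the population capacity).
#'
#' @param population_size Number of trees `N` kept in the forest (default 50).
#' @param fe_budget Total number of strength-function evaluations allowed,
#'   counting initialization (default 3000).
#' @param renew_rate Renew rate `p_r` in `[0, 1]`: fraction of last autumn's
#'   seed count re-sown as random seedlings each spring.
#' @param competition_rate Competition rate `p_c` in `(0, 1]`: fraction of the
#'   population treated as "cored" (strongest) trees in summer.
#' @param seeding_rate Seeding rate `p_s` in `[0, 1]`: fraction of the
#'   population that produces offspring in autumn.
#' @param resistance_rate Winter removal rate `p_w`; the printed update rule
#'   reduces algebraically to `p_s`, which is the default (`NULL`). Supply a
#'   value to decouple the two rates.
#' @param asymmetry Asymmetry index `gamma` in `[0, 1]`: discount applied to
#'   the crowding pressure exerted by a weaker neighbor.
#' @param growth_scale Scale `g > 0` of the Gaussian growth perturbation used
#'   in the competition phase, as a fraction of the bound width per dimension
#'   (default 0.01).
#' @param literal_growth Logical; if `TRUE` the competition update divides the
#'   whole perturbed position by `Lambda + 1` (the origin-dependent printed
#'   form) instead of damping only the increment. Default `FALSE`.
#' @param seed Optional integer seed making a run reproducible. All randomness
#'   in an optimizer run flows from this one seed; the caller's RNG state is
#'   left untouched.
#' @return An object of class `so_config`.
#' @examples
#' so_config(population_size = 20, fe_budget = 400, seed = 1)
#' @export
so_config <- function(population_size = 50L,
                      fe_budget = 3000L,
                      renew_rate = 0.4,
                      competition_rate = 0.3,
                      seeding_rate = 0.3,
                      resistance_rate = NULL,
                      asymmetry = 0.5,
                      growth_scale = 0.01,
                      literal_growth = FALSE,
                      seed = NULL) {
  population_size <- as.integer(population_size)
  fe_budget <- as.integer(fe_budget)
  if (is.na(population_size) || population_size < 2L) {
    stop("`population_size` must be an integer >= 2")
  }
  if (is.na(fe_budget) || fe_budget < population_size) {
    stop("`fe_budget` must be at least `population_size`")
  }
  chk01 <- function(x, name, lo_open = FALSE) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
        x < 0 || x > 1 || (lo_open && x == 0)) {
      stop(sprintf("`%s` must be a single value in %s", name,
                   if (lo_open) "(0, 1]" else "[0, 1]"))
    }
    as.numeric(x)
  }
  renew_rate <- chk01(renew_rate, "renew_rate")
  competition_rate <- chk01(competition_rate, "competition_rate", lo_open = TRUE)
  seeding_rate <- chk01(seeding_rate, "seeding_rate")
  asymmetry <- chk01(asymmetry, "asymmetry")
  if (!is.null(resistance_rate)) {
    resistance_rate <- chk01(resistance_rate, "resistance_rate")
  }
  if (!is.numeric(growth_scale) || growth_scale <= 0) {
    stop("`growth_scale` must be positive")
  }
  structure(list(
    population_size = population_size,
    fe_budget = fe_budget,
    renew_rate = renew_rate,
    competition_rate = competition_rate,
    seeding_rate = seeding_rate,
    resistance_rate = resistance_rate,
    asymmetry = asymmetry,
    growth_scale = as.numeric(growth_scale),
    literal_growth = isTRUE(literal_growth),
    seed = if (is.null(seed)) NULL else as.integer(seed)
  ), class = "so_config")
}

#' Read an SO configuration from a YAML or JSON mapping
#'
#' The file must contain a flat mapping whose keys are (a subset of) the
#' argument names of [so_config()]. YAML support requires the `yaml` package;
#' `.json` files are read with `jsonlite`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `so_config`.
#' @export
so_config_from_file <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the `yaml` package; use JSON instead")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  }
  if (!is.list(raw)) stop("config file must contain a mapping")
  known <- names(formals(so_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop("unknown SO config fields: ", paste(unknown, collapse = ", "))
  }
  do.call(so_config, raw)
}

## Internal: strength-function evaluator with an invocation counter and a hard
## budget. Non-finite strengths are demoted to -Inf with a warning so a broken
## candidate can never become the incumbent.
so_evaluator <- function(strength_fn, budget = Inf) {
  count <- 0L
  ev <- function(position) {
    count <<- count + 1L
    s <- strength_fn(position)
    if (!is.numeric(s) || length(s) != 1L || !is.finite(s)) {
      warning("strength function returned a non-finite value; ",
              "candidate assigned worst-possible strength", call. = FALSE)
      s <- -Inf
    }
    as.numeric(s)
  }
  list(
    eval = ev,
    eval_rows = function(mat) apply(mat, 1L, ev),
    used = function() count,
    left = function() max(0, budget - count)
  )
}

clamp_rows <- function(mat, bounds) {
  lo <- matrix(bounds$lower, nrow(mat), bounds$d, byrow = TRUE)
  hi <- matrix(bounds$upper, nrow(mat), bounds$d, byrow = TRUE)
  pmin(pmax(mat, lo), hi)
}

uniform_positions <- function(n, bounds) {
  d <- bounds$d
  r <- matrix(stats::runif(n * d), n, d)
  sweep(sweep(r, 2L, bounds$upper - bounds$lower, `*`), 2L,
        bounds$lower, `+`)
}

new_forest <- function(positions, strengths, A = 0L, y = 0L) {
  ib <- which.max(strengths)
  structure(list(
    positions = positions,
    strengths = strengths,
    A = as.integer(A),
    y = as.integer(y),
    best_position = positions[ib, , drop = TRUE],
    best_strength = strengths[ib]
  ), class = "so_forest")
}

update_best <- function(forest) {
  ib <- which.max(forest$strengths)
  if (length(ib) && forest$strengths[ib] >= forest$best_strength) {
    forest$best_strength <- forest$strengths[ib]
    forest$best_position <- forest$positions[ib, , drop = TRUE]
  }
  forest
}

#' Initialize the forest
#'
#' Draws `N` trees uniformly within the bounds (`t_ij = l_j + r_ij (u_j -
#' l_j)`, `r_ij ~ U(0,1)`) and evaluates each with the strength function
#' (consuming `N` evaluations). Seed count `A` and the generation counter `y`
#' start at zero.
#'
#' @param bounds An [so_bounds()].
#' @param config An [so_config()].
#' @param strength_fn Function mapping a position vector to a finite scalar;
#'   larger is stronger. The optimizer maximizes, so minimizers should supply
#'   the negated objective.
#' @param seeds Optional numeric matrix (rows are positions) injected verbatim
#'   into the initial forest in place of the first random trees, e.g. a
#'   deterministic warm start. Rows are clamped to the bounds.
#' @return An object of class `so_forest` with fields `positions` (N x D
#'   matrix), `strengths`, seed count `A`, generation `y`, and the incumbent
#'   `best_position`/`best_strength`.
#' @export
so_init_forest <- function(bounds, config, strength_fn, seeds = NULL) {
  stopifnot(inherits(bounds, "so_bounds"), inherits(config, "so_config"))
  n <- config$population_size
  pos <- uniform_positions(n, bounds)
  if (!is.null(seeds)) {
    seeds <- matrix(as.numeric(seeds), ncol = bounds$d)
    k <- min(nrow(seeds), n)
    pos[seq_len(k), ] <- clamp_rows(seeds[seq_len(k), , drop = FALSE], bounds)
  }
  ev <- if (is.list(strength_fn)) strength_fn else so_evaluator(strength_fn)
  s <- ev$eval_rows(pos)
  new_forest(pos, s)
}

#' Normalized strength of every tree
#'
#' Computes `tau_i = (S_i - min(S)) / |sum(S)|` — the minimum-shifted strength
#' over the *un-shifted* strength total. For the positive strengths the
#' seasonal model assumes this is exactly the printed allocation rule; taking
#' the total in absolute value extends it to negated-objective strengths
#' (e.g. `-RMSE`), where a signed denominator would zero out the whole
#' competition phase. When the denominator is zero all `tau_i` are zero.
#' `tau` remains scale-dependent by construction.
#'
#' @param forest An `so_forest` with all trees evaluated.
#' @return Numeric vector `tau`, one value per tree.
#' @export
so_normalized_strength <- function(forest) {
  s <- forest$strengths
  if (length(s) == 0L) stop("empty forest")
  denom <- sum(s)
  if (denom == 0 || !is.finite(denom)) return(rep(0, length(s)))
  # |sum|: identical to the printed rule for positive strengths, and keeps
  # the allocation non-negative for negated-objective (e.g. -RMSE) strengths
  tau <- (s - min(s)) / abs(denom)
  tau[!is.finite(tau)] <- 0  # guards -Inf-strength (failed) candidates
  tau
}

#' Renew phase (spring)
#'
#' If the forest is past its first generation (`y > 0`), sows
#' `ceiling(p_r * A)` seedlings at uniform-random positions within the bounds
#' (`A` being the number of seeds produced last autumn), evaluates them, and
#' appends them to the forest. A no-op at `y = 0` or when `A = 0`.
#'
#' @inheritParams so_init_forest
#' @param forest An `so_forest`.
#' @return The enlarged (or unchanged) forest.
#' @export
so_renew <- function(forest, bounds, config, strength_fn) {
  if (forest$y == 0L || forest$A == 0L || config$renew_rate == 0) {
    return(forest)
  }
  ev <- if (is.list(strength_fn)) strength_fn else so_evaluator(strength_fn)
  n_new <- min(ceiling(config$renew_rate * forest$A), ev$left())
  if (n_new <= 0L) return(forest)
  pos <- uniform_positions(n_new, bounds)
  s <- ev$eval_rows(pos)
  forest$positions <- rbind(forest$positions, pos)
  forest$strengths <- c(forest$strengths, s)
  update_best(forest)
}

## Internal: crowding index Lambda_j for tree j against the other zone members.
## S_k * Delta^-2 * lambda, with a distance floor guarding coincident trees and
## the asymmetry discount 1 - gamma applied to weaker neighbors.
crowding_index <- function(j, zone, positions, strengths, gamma,
                           dist_floor = 1e-12) {
  others <- setdiff(zone, j)
  if (!length(others)) return(0)
  dj <- positions[j, ]
  lam <- 0
  for (k in others) {
    delta <- sqrt(sum((dj - positions[k, ])^2))
    delta <- max(delta, dist_floor)
    w <- if (strengths[k] >= strengths[j]) 1 else 1 - gamma
    lam <- lam + strengths[k] * delta^-2 * w
  }
  lam
}

#' Competition phase (summer)
#'
#' The `N_c = ceiling(p_c * N)` strongest trees become *cored* trees. Each
#' cored tree claims `Z_i = ceiling(tau_i * (N - N_c))` of its nearest
#' (Euclidean) non-cored trees as neighbors (clamped at zero, drawn without
#' replacement, strongest cored tree first). Every neighbor receives a
#' Gaussian growth step damped by its crowding index
#' `Lambda_j = sum_k S_k Delta_jk^-2 lambda_jk` — by default
#' `T_j <- T_j + theta / (Lambda_j + 1)` with `theta ~ N(0, (g (u - l))^2)`
#' per dimension — is clamped to the bounds and re-evaluated. Finally the
#' cored tree is replaced by its strongest neighbor when that neighbor is at
#' least as strong (ties replace).
#'
#' @inheritParams so_renew
#' @return The forest after competition (same number of trees).
#' @export
so_competition <- function(forest, bounds, config, strength_fn) {
  ev <- if (is.list(strength_fn)) strength_fn else so_evaluator(strength_fn)
  n_cap <- config$population_size
  n_cur <- nrow(forest$positions)
  n_c <- min(ceiling(config$competition_rate * n_cap), n_cur)
  n_g <- n_cap - n_c
  if (n_c < 1L || n_g < 1L) return(forest)
  tau <- so_normalized_strength(forest)
  ord <- order(forest$strengths, decreasing = TRUE)
  cored <- ord[seq_len(n_c)]
  pool <- setdiff(ord, cored)
  sd_theta <- config$growth_scale * (bounds$upper - bounds$lower)
  s_snapshot <- forest$strengths
  for (i in cored) {
    if (!length(pool)) break
    z_i <- max(0L, ceiling(tau[i] * n_g))
    z_i <- min(z_i, length(pool))
    if (z_i < 1L) next
    d2 <- colSums((t(forest$positions[pool, , drop = FALSE]) -
                     forest$positions[i, ])^2)
    nb <- pool[order(d2)[seq_len(z_i)]]
    pool <- setdiff(pool, nb)
    zone <- c(i, nb)
    for (j in nb) {
      if (ev$left() < 1) next
      lam <- crowding_index(j, zone, forest$positions, s_snapshot,
                            config$asymmetry)
      theta <- stats::rnorm(bounds$d, 0, sd_theta)
      damp <- abs(lam) + 1  # |Lambda|: a true damping for negative strengths
      newpos <- if (config$literal_growth) {
        (forest$positions[j, ] + theta) / damp
      } else {
        forest$positions[j, ] + theta / damp
      }
      newpos <- pmin(pmax(newpos, bounds$lower), bounds$upper)
      forest$positions[j, ] <- newpos
      forest$strengths[j] <- ev$eval(newpos)
    }
    sb <- nb[which.max(forest$strengths[nb])]
    if (forest$strengths[i] <= forest$strengths[sb]) {
      forest$positions[i, ] <- forest$positions[sb, ]
      forest$strengths[i] <- forest$strengths[sb]
    }
  }
  update_best(forest)
}

#' Seeding phase (autumn)
#'
#' The `ceiling(p_s * N)` fittest trees each produce one offspring: a copy in
#' which `m` randomly chosen components (`m` uniform in `1..D-1`; `m = 1` when
#' `D = 1`) are perturbed by `l * r` with `l` drawn from `{-1, +1}` and `r`
#' uniform in `[l_j, u_j]`, then clamped to the bounds. Offspring are
#' evaluated and appended; the forest's seed count `A` is set to the number of
#' offspring actually produced (consumed by next spring's renew).
#'
#' @inheritParams so_renew
#' @return The forest with offspring appended and `A` updated.
#' @export
so_seeding <- function(forest, bounds, config, strength_fn) {
  ev <- if (is.list(strength_fn)) strength_fn else so_evaluator(strength_fn)
  n_cap <- config$population_size
  n_seed <- ceiling(config$seeding_rate * n_cap)
  if (n_seed < 1L) {
    forest$A <- 0L
    return(forest)
  }
  n_seed <- min(n_seed, nrow(forest$positions), ev$left())
  if (n_seed < 1L) {
    forest$A <- 0L
    return(forest)
  }
  d <- bounds$d
  parents <- order(forest$strengths, decreasing = TRUE)[seq_len(n_seed)]
  kids <- matrix(NA_real_, n_seed, d)
  for (idx in seq_len(n_seed)) {
    kid <- forest$positions[parents[idx], ]
    m <- if (d == 1L) 1L else sample.int(d - 1L, 1L)
    comp <- sample.int(d, m)
    ell <- sample(c(-1, 1), m, replace = TRUE)
    r <- stats::runif(m, bounds$lower[comp], bounds$upper[comp])
    kid[comp] <- kid[comp] + ell * r
    kids[idx, ] <- pmin(pmax(kid, bounds$lower), bounds$upper)
  }
  s <- ev$eval_rows(kids)
  forest$positions <- rbind(forest$positions, kids)
  forest$strengths <- c(forest$strengths, s)
  forest$A <- n_seed
  update_best(forest)
}

#' Resistance phase (winter)
#'
#' Removes the `ceiling(p_w * N)` weakest trees (`p_w` defaults to the
#' seeding rate, to which the printed removal rate reduces algebraically),
#' then trims back to capacity `N` keeping the strongest, and increments the
#' generation counter. The cull never takes the forest below capacity (or
#' below one tree), so the population is exactly `N` after every winter even
#' when a budget-truncated cycle recruited fewer trees than usual.
#'
#' @inheritParams so_renew
#' @return The forest at capacity, one generation older.
#' @export
so_resistance <- function(forest, config) {
  n_cap <- config$population_size
  p_w <- if (is.null(config$resistance_rate)) config$seeding_rate else
    config$resistance_rate
  n_cur <- nrow(forest$positions)
  # removal is capped so the forest never drops below capacity (or below a
  # single tree): on a budget-truncated final cycle with no recruits the
  # winter cull shrinks accordingly
  n_remove <- min(ceiling(p_w * n_cap), max(0L, n_cur - n_cap), n_cur - 1L)
  keep <- order(forest$strengths, decreasing = TRUE)
  if (n_remove > 0L) keep <- keep[seq_len(n_cur - n_remove)]
  keep <- keep[seq_len(min(length(keep), n_cap))]
  keep <- sort(keep)  # stable row order for reproducibility
  forest$positions <- forest$positions[keep, , drop = FALSE]
  forest$strengths <- forest$strengths[keep]
  forest$y <- forest$y + 1L
  update_best(forest)
}

#' Run the Seasons Optimization algorithm
#'
#' Initializes a forest and cycles renew, competition, seeding and resistance
#' until the evaluation budget is exhausted, returning the strongest candidate
#' ever evaluated together with a per-generation trace. The run is fully
#' reproducible given `config$seed`, and the caller's global RNG state is
#' preserved.
#'
#' @inheritParams so_init_forest
#' @return An object of class `so_result`: a list with `best_position`,
#'   `best_strength`, `fe_used`, the final `forest`, and `trace` — a data
#'   frame with columns `generation`, `best_strength`, `fe_used`.
#' @examples
#' sphere <- function(x) -sum(x^2)
#' res <- so_optimize(sphere, so_bounds(c(-5, -5), c(5, 5)),
#'                    so_config(population_size = 10, fe_budget = 200,
#'                              seed = 1))
#' res$best_strength
#' @export
so_optimize <- function(strength_fn, bounds, config, seeds = NULL) {
  stopifnot(inherits(bounds, "so_bounds"), inherits(config, "so_config"))
  run <- function() {
    ev <- so_evaluator(strength_fn, budget = config$fe_budget)
    forest <- so_init_forest(bounds, config, ev, seeds = seeds)
    trace <- list(data.frame(generation = 0L,
                             best_strength = forest$best_strength,
                             fe_used = ev$used()))
    while (ev$left() > 0) {
      fe_before <- ev$used()
      forest <- so_renew(forest, bounds, config, ev)
      forest <- so_competition(forest, bounds, config, ev)
      forest <- so_seeding(forest, bounds, config, ev)
      forest <- so_resistance(forest, config)
      trace[[length(trace) + 1L]] <-
        data.frame(generation = forest$y,
                   best_strength = forest$best_strength,
                   fe_used = ev$used())
      if (ev$used() == fe_before) break  # nothing evaluable: avoid spinning
    }
    structure(list(
      best_position = forest$best_position,
      best_strength = forest$best_strength,
      fe_used = ev$used(),
      forest = forest,
      trace = do.call(rbind, trace)
    ), class = "so_result")
  }
  with_local_seed(config$seed, run())
}

## Internal: evaluate `expr` under a locally seeded RNG without disturbing the
## caller's .Random.seed. seed = NULL just uses (and advances) the ambient RNG.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Write an optimizer trace to CSV
#'
#' @param result An `so_result` from [so_optimize()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_so_trace <- function(result, path) {
  stopifnot(inherits(result, "so_result"))
  utils::write.csv(result$trace, path, row.names = FALSE)
  invisible(path)
}

#' @export
print.so_result <- function(x, ...) {
  cat("Seasons Optimization result\n")
  cat(sprintf("  dimensions     : %d\n", length(x$best_position)))
  cat(sprintf("  best strength  : %.6g\n", x$best_strength))
  cat(sprintf("  evaluations    : %d\n", x$fe_used))
  cat(sprintf("  generations    : %d\n", max(x$trace$generation)))
  invisible(x)
}
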