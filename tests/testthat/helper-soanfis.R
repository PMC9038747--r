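# Shared test utilities: instrumented strength functions, tiny deterministic
# models, and a uniform random-search oracle for optimizer comparisons.

counting_strength <- function(fn) {
  count <- 0L
  f <- function(x) {
    count <<- count + 1L
    fn(x)
  }
  attr(f, "count") <- function() count
  f
}

sphere_strength <- function(x) -sum(x^2)

random_search_best <- function(fn, bounds, n) {
  pos <- sapply(seq_along(bounds$lower), function(j) {
    stats::runif(n, bounds$lower[j], bounds$upper[j])
  })
  max(apply(matrix(pos, nrow = n), 1L, fn))
}

# A small two-input, two-rule TSK model with known parameters.
tiny_tsk_model <- function() {
  anfis_model(
    centers = rbind(c(0, 0), c(2, 2)),
    sigmas = rbind(c(1, 1.5), c(1.2, 0.8)),
    consequents = rbind(c(1.0, -0.5, 2.0), c(-0.3, 0.8, -1.0)),
    input_names = c("a", "b")
  )
}

tiny_feature_grid <- function(n = 40, seed = 42) {
  set.seed(seed)
  data.frame(a = runif(n, -2, 4), b = runif(n, -2, 4))
}
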