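# shared fixtures built in code

# Erdos-Renyi style directed loop-free web
random_web <- function(n, p = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  adj <- matrix(rbinom(n * n, 1, p), n, n)
  diag(adj) <- 0L
  foodweb(adj)
}

# every change-statistic-capable statistic at lambda = 2
full_catalogue_spec <- function(lambda = 2) {
  do.call(model_spec, c(as.list(foodwebERGM:::CATALOGUE$name),
                        list(lambda = lambda)))
}

fast_settings <- function(n, sample_size = 500L, seed = 1L) {
  sampler_settings(n, burn_in = 20 * n^2, thinning = 4 * n^2,
                   sample_size = sample_size, seed = seed)
}
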