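test_that("the arc-only model reproduces Bernoulli densities", {
  spec <- model_spec("arc")
  n <- 5
  dyads <- n * (n - 1)
  for (target in c(0.5, 0.2)) {
    theta <- log(target / (1 - target))
    ens <- sample_networks(spec, theta, n = n,
                           settings = fast_settings(n, 1000, seed = 31))
    dens <- ens$statistics[, "arc"] / dyads
    mcse <- sd(dens) / sqrt(length(dens))
    expect_lt(abs(mean(dens) - target), 3 * mcse + 0.01)
  }
})

test_that("a long n=3 chain matches exact ERGM probabilities", {
  spec <- model_spec("arc", "reciprocity")
  theta <- c(-0.5, 0.8)
  probs <- foodwebERGM:::enumerate_probabilities(
    3, foodwebERGM:::as_stat_list(spec), theta)
  ens <- sample_networks(spec, theta, n = 3,
                         settings = sampler_settings(3, burn_in = 1000,
                                                     thinning = 20,
                                                     sample_size = 50000,
                                                     seed = 9),
                         keep_networks = TRUE)
  dyads <- which(!diag(3))
  code <- vapply(ens$networks, function(w) {
    sum(w$adjacency[dyads] * 2^(seq_along(dyads) - 1))
  }, numeric(1))
  emp <- tabulate(code + 1, nbins = 64) / length(code)
  tv <- 0.5 * sum(abs(emp - probs))
  expect_lt(tv, 0.02)
})

test_that("sampling is deterministic given the seed", {
  spec <- model_spec("arc", "generalist")
  s <- fast_settings(8, 50, seed = 77)
  a <- sample_networks(spec, c(-1, 0.3), n = 8, settings = s)
  b <- sample_networks(spec, c(-1, 0.3), n = 8, settings = s)
  expect_identical(a$statistics, b$statistics)
  s2 <- s; s2$seed <- 78L
  c <- sample_networks(spec, c(-1, 0.3), n = 8, settings = s2)
  expect_false(identical(a$statistics, c$statistics))
})

test_that("retained statistics agree with recomputation on the networks", {
  spec <- model_spec("arc", "generalist", "omnivory")
  ens <- sample_networks(spec, c(-1.5, 0.4, 0.2), n = 10,
                         settings = fast_settings(10, 20, seed = 5),
                         keep_networks = TRUE)
  for (k in c(1, 10, 20)) {
    expect_equal(ens$statistics[k, ],
                 compute_statistics(ens$networks[[k]], spec))
  }
})

test_that("acceptance rate is interior for finite nonzero theta", {
  ens <- sample_networks(model_spec("arc"), -1.5, n = 8,
                         settings = fast_settings(8, 100, seed = 3))
  expect_gt(ens$acceptance_rate, 0)
  expect_lt(ens$acceptance_rate, 1)
})

test_that("degenerate drift raises a warning and is flagged", {
  # strong positive arc force pins density at 1
  expect_warning(
    ens <- sample_networks(model_spec("arc"), 8, n = 6,
                           settings = fast_settings(6, 100, seed = 2)),
    "degenerate"
  )
  expect_true(ens$degenerate)
})

test_that("invalid sampler inputs are refused", {
  expect_error(sample_networks(model_spec("arc"), NaN, n = 5,
                               settings = fast_settings(5, 10)), "finite")
  expect_error(sample_networks(model_spec("arc"), c(1, 2), n = 5,
                               settings = fast_settings(5, 10)), "length")
})

test_that("conditional log-odds equal theta dot change statistics", {
  spec <- model_spec("arc", "generalist", "tri_trophic")
  web <- random_web(8, 0.3, seed = 12)
  # zero parameters: zero log-odds everywhere
  expect_equal(conditional_logodds(web, spec, c(0, 0, 0), 1, 2), 0)
  # arc-only at -1: every dyad scores -1
  expect_equal(conditional_logodds(web, model_spec("arc"), -1, 3, 5), -1)
  set.seed(21)
  for (k in 1:10) {
    i <- sample(8, 1); j <- sample(setdiff(1:8, i), 1)
    theta <- rnorm(3)
    expect_equal(conditional_logodds(web, spec, theta, i, j),
                 sum(theta * change_statistics(web, spec, i, j)))
  }
})
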