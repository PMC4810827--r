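test_that("exact enumeration MLE recovers closed forms on n = 3", {
  # 3 of 6 arcs present: theta = logit(1/2) = 0
  web <- foodweb_from_edges(c("A", "B", "C"), c("B", "C", "A"))
  th <- exact_fit_small(web, model_spec("arc"))
  expect_equal(as.numeric(th), 0, tolerance = 1e-7)

  # 2 of 6 arcs: logit(1/3)
  web <- fixture_web("chain3")
  th <- exact_fit_small(web, model_spec("arc"))
  expect_equal(as.numeric(th), log(1 / 2), tolerance = 1e-7)
  expect_lt(attr(th, "gradient_norm"), 1e-6)
})

test_that("exact MLE agrees with an independent optimizer", {
  # a mutual dyad plus one extra arc: (arcs, reciprocity) = (3, 1), the only
  # point strictly inside the n = 3 convex hull (a lone mutual dyad sits on
  # the face R = L/2, where the MLE diverges)
  web <- foodweb_from_edges(c("A", "B", "C"), c("B", "A", "A"))
  spec <- model_spec("arc", "reciprocity")
  th <- exact_fit_small(web, spec)
  sl <- foodwebERGM:::as_stat_list(spec)
  Z <- foodwebERGM:::enumerate_statistics(3, sl)
  zobs <- compute_statistics(web, spec)
  negll <- function(theta) {
    eta <- drop(Z %*% theta)
    -(sum(theta * zobs) - (max(eta) + log(sum(exp(eta - max(eta))))))
  }
  opt <- optim(c(0, 0), negll, method = "BFGS",
               control = list(reltol = 1e-14))
  expect_equal(as.numeric(th), opt$par, tolerance = 1e-4)
})

test_that("boundary statistics cap and warn instead of diverging", {
  adj <- matrix(1L, 3, 3); diag(adj) <- 0L
  full <- foodweb(adj)
  expect_warning(th <- exact_fit_small(full, model_spec("arc")), "boundary")
  expect_equal(as.numeric(th), 20)
  expect_error(exact_fit_small(random_web(5, 0.3, seed = 1),
                               model_spec("arc")), "n <= 4")
})

test_that("arc-only MCMC fit recovers logit(density)", {
  web <- fixture_web("baltic_like_30")
  fit <- fit_ergm(web, model_spec("arc"),
                  settings = sampler_settings(30, seed = 14))
  target <- log(web_density(web) / (1 - web_density(web)))
  expect_true(fit$converged)
  expect_lt(abs(unname(fit$theta) - target), 0.02)
})

test_that("MCMC MLE matches the enumeration oracle on n = 3", {
  web <- foodweb_from_edges(c("A", "B", "B"), c("B", "C", "A"))
  spec <- model_spec("arc", "reciprocity")
  exact <- exact_fit_small(web, spec)
  fit <- fit_ergm(web, spec,
                  settings = sampler_settings(3, burn_in = 2000,
                                              thinning = 200, seed = 5),
                  rm = rm_settings(phase3_samples = 20000,
                                   t_threshold = 0.02, max_restarts = 10))
  expect_equal(as.numeric(fit$theta), as.numeric(exact), tolerance = 0.05)
})

test_that("a converged fit satisfies the moment condition", {
  web <- fixture_web("baltic_like_30")
  spec <- model_spec("arc", "generalist")
  fit <- fit_ergm(web, spec, settings = sampler_settings(30, seed = 8))
  expect_true(fit$converged)
  expect_true(all(abs(fit$convergence_t) <= 0.1))
  # significance flags recompute from the reported numbers
  expect_equal(unname(fit$significant),
               unname(abs(fit$theta) >= 2 * fit$standard_errors))
  expect_true(all(fit$standard_errors > 0))
})

test_that("non-convergence is reported, not thrown", {
  web <- fixture_web("baltic_like_30")
  fit <- fit_ergm(web, model_spec("arc", "generalist"),
                  settings = sampler_settings(30, burn_in = 100,
                                              thinning = 50, seed = 3),
                  rm = rm_settings(subphase_lengths = c(1, 1), gain0 = 0.01,
                                   phase1_samples = 10, phase3_samples = 50,
                                   t_threshold = 1e-4, max_restarts = 0))
  expect_s3_class(fit, "ergm_fit")
  expect_false(fit$converged)
})

test_that("degenerate observed densities are refused", {
  expect_error(fit_ergm(foodweb(matrix(0L, 4, 4)), model_spec("arc")),
               "density")
})

test_that("candidate ranking prefers the generating specification", {
  spec_small <- model_spec("arc")
  spec_true <- model_spec("arc", "generalist")
  webs <- simulate_study(c(-3.2, 1.2), spec_true, n = 20, replicates = 1,
                         seed = 61)
  cmp <- compare_model_specs(webs[[1]], list(spec_small, spec_true),
                             settings = sampler_settings(20, seed = 17),
                             gof_settings = fast_settings(20, 300, seed = 18))
  expect_equal(nrow(cmp$table), 2)
  expect_equal(cmp$table$rank, 1:2)
  expect_true(all(c(1, 2) %in% cmp$table$candidate))
  # single candidate: trivially rank 1
  cmp1 <- compare_model_specs(webs[[1]], list(spec_small),
                              settings = sampler_settings(20, seed = 17),
                              gof_settings = fast_settings(20, 200, seed = 18))
  expect_equal(cmp1$table$rank, 1)
})

test_that("fit serialization and the combined table follow the flags", {
  web <- fixture_web("baltic_like_30")
  fit <- fit_ergm(web, model_spec("arc", "generalist"),
                  settings = sampler_settings(30, seed = 8))
  path <- withr::local_tempfile(fileext = ".json")
  write_fit_json(fit, path)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(unlist(back$theta), unclass(fit$theta), tolerance = 1e-12)
  tab <- fits_to_table(list(w1 = fit))
  starred <- grepl("\\*$", tab$w1)
  expect_equal(starred, unname(fit$significant))
})
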