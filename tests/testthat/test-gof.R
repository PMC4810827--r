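test_that("the default suite has 32 uniquely named statistics covering the model", {
  suite <- default_gof_suite()
  expect_length(suite, 32)
  nms <- vapply(suite, `[[`, "", "name")
  expect_equal(anyDuplicated(nms), 0L)
  model <- foodweb_model_spec(exploitative = TRUE)
  expect_true(all(vapply(model$configurations, `[[`, "", "name") %in% nms))
})

test_that("GoF t-ratios separate a misspecified model", {
  # the niche-model web is strongly hierarchical/transitive; an arc-only
  # (density-matched Bernoulli) model cannot reproduce its triangles
  web <- fixture_web("baltic_like_30")
  fit <- fit_ergm(web, model_spec("arc"),
                  settings = sampler_settings(30, seed = 42))
  rep <- goodness_of_fit(web, fit,
                         settings = sampler_settings(30, sample_size = 400,
                                                     seed = 43))
  tab <- rep$table
  # the modelled arc statistic is matched ...
  expect_lt(abs(tab$t[tab$statistic == "arc"]), 0.15)
  # ... but triangle-family statistics are not reproduced
  expect_gt(abs(tab$t[tab$statistic == "omnivory"]), 2)
  expect_gt(abs(tab$t[tab$statistic == "transitive_triangle"]), 2)
  expect_false(isTRUE(rep$pass))
})

test_that("GoF reports are reproducible bit for bit under a fixed seed", {
  web <- random_web(10, 0.3, seed = 9)
  fit <- fit_ergm(web, model_spec("arc"),
                  settings = sampler_settings(10, seed = 10))
  a <- goodness_of_fit(web, fit, settings = fast_settings(10, 150, seed = 4))
  b <- goodness_of_fit(web, fit, settings = fast_settings(10, 150, seed = 4))
  expect_identical(a$table, b$table)
})

test_that("an ensemble of one yields undefined t-ratios, not errors", {
  web <- random_web(8, 0.3, seed = 6)
  fit <- fit_ergm(web, model_spec("arc"),
                  settings = sampler_settings(8, seed = 11))
  rep <- goodness_of_fit(web, fit,
                         settings = sampler_settings(8, sample_size = 1,
                                                     seed = 2))
  expect_true(all(is.na(rep$table$t)))
  expect_true(is.na(rep$pass))
})

test_that("non-converged fits trigger a warning in GoF", {
  web <- fixture_web("baltic_like_30")
  fit <- fit_ergm(web, model_spec("arc"),
                  settings = sampler_settings(30, burn_in = 50, thinning = 20,
                                              seed = 3),
                  rm = rm_settings(subphase_lengths = c(1, 1),
                                   phase1_samples = 10, phase3_samples = 30,
                                   t_threshold = 1e-5, max_restarts = 0))
  expect_false(fit$converged)
  expect_warning(goodness_of_fit(web, fit,
                                 settings = fast_settings(30, 30, seed = 1)),
                 "converge")
})

test_that("modelled GoF t-ratios track the fit's convergence t-ratios", {
  web <- fixture_web("baltic_like_30")
  spec <- model_spec("arc", "generalist")
  fit <- fit_ergm(web, spec, settings = sampler_settings(30, seed = 19))
  rep <- goodness_of_fit(web, fit,
                         settings = sampler_settings(30, sample_size = 500,
                                                     seed = 20))
  tab <- rep$table
  for (nm in c("arc", "generalist")) {
    # same moment condition, opposite sign convention, independent ensemble
    expect_lt(abs(tab$t[tab$statistic == nm] + fit$convergence_t[[nm]]), 0.2)
  }
})
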