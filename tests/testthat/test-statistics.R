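test_that("hand-evaluated statistics on canonical webs are exact", {
  chain <- fixture_web("chain3")
  z <- compute_statistics(chain, c("arc", "tri_trophic", "omnivory",
                                   "apparent_competition",
                                   "exploitative_competition"), lambda = 2)
  expect_equal(unname(z), c(2, 1, 0, 0, 0))

  star <- fixture_web("pred_star4")  # a,b,c -> P
  z <- compute_statistics(star, c("generalist", "highly_predated",
                                  "apparent_competition"), lambda = 2)
  # alternating in-star: 4 * ((1/2)^3 + 3/2 - 1) = 2.5 = S2 - S3/2 = 3 - 0.5
  expect_equal(unname(z), c(2.5, 0, 3))

  fan <- fixture_web("prey_fan4")  # R -> x,y,z
  z <- compute_statistics(fan, c("generalist", "highly_predated",
                                 "exploitative_competition"), lambda = 2)
  expect_equal(unname(z), c(0, 2.5, 3))

  omn <- fixture_web("omnivory3")
  z <- compute_statistics(omn, c("omnivory", "transitive_triangle",
                                 "keystone"), lambda = 2)
  # one transitive triangle; keystone: B has in 1, out 1 -> g(1)^2 = 1
  expect_equal(unname(z), c(1, 1, 1))
})

test_that("all statistics vanish on the empty web and ignore labelling", {
  empty <- foodweb(matrix(0L, 6, 6))
  spec <- full_catalogue_spec()
  expect_true(all(compute_statistics(empty, spec) == 0))

  web <- random_web(9, 0.35, seed = 3)
  perm <- sample(9)
  relab <- foodweb(web$adjacency[perm, perm])
  expect_equal(compute_statistics(relab, spec), compute_statistics(web, spec))
})

test_that("alternating statistics approach raw counts as lambda grows", {
  web <- random_web(10, 0.4, seed = 8)
  big <- compute_statistics(web, c("generalist", "highly_predated"),
                            lambda = 1e6)
  raw <- compute_statistics(web, c("in_2_star", "out_2_star"))
  expect_equal(unname(big), unname(raw), tolerance = 1e-3)
})

test_that("g_lambda is increasing and concave in the count", {
  d <- 0:10
  g <- g_lambda(d, 2)
  expect_true(all(diff(g) > 0))
  expect_true(all(diff(diff(g)) < 0))
})

test_that("change statistics equal brute-force differences exactly", {
  spec <- full_catalogue_spec()
  set.seed(99)
  for (case in 1:100) {
    web <- random_web(10, runif(1, 0.1, 0.5))
    i <- sample(10, 1)
    j <- sample(setdiff(1:10, i), 1)
    with_arc <- web$adjacency; with_arc[i, j] <- 1L
    without <- web$adjacency; without[i, j] <- 0L
    brute <- compute_statistics(foodweb(with_arc), spec) -
      compute_statistics(foodweb(without), spec)
    delta <- change_statistics(web, spec, i, j)
    expect_equal(delta, brute, tolerance = 1e-9)
  }
})

test_that("change statistics on the empty web reduce to the arc term", {
  empty <- foodweb(matrix(0L, 5, 5))
  spec <- full_catalogue_spec()
  d <- change_statistics(empty, spec, 2, 4)
  expect_equal(unname(d["arc"]), 1)
  # a lone arc creates no stars, paths or triangles
  expect_true(all(d[setdiff(names(d), "arc")] == 0))
})

test_that("toggling the omnivory shortcut on a chain scores g(1)", {
  web <- fixture_web("chain3")
  d <- change_statistics(web, model_spec("arc", "omnivory"), "A", "C")
  expect_equal(unname(d), c(1, g_lambda(1, 2)))
  expect_error(change_statistics(web, model_spec("arc"), "A", "A"), "self-loop")
})

test_that("the statistic catalogue is validated at construction", {
  expect_error(config_stat("no_such_statistic"), "unknown")
  expect_error(config_stat("generalist", lambda = 0.5), "lambda")
  expect_error(model_spec("generalist"), "arc")
  expect_error(model_spec("arc", "arc"), "duplicate")
  # lambda pinned to 1 for non-alternating statistics
  expect_equal(config_stat("arc", lambda = 5)$lambda, 1)
  # GoF-only statistics cannot enter a fitted model
  expect_error(model_spec("arc", "triad_021C"), "cannot be modelled")
})

test_that("model specifications round-trip through YAML", {
  spec <- foodweb_model_spec(lambda = 3)
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(lapply(spec$configurations, function(s) {
    list(name = s$name, lambda = s$lambda)
  }), path)
  back <- read_model_spec(path)
  expect_equal(back, spec)
})
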