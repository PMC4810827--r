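test_that("percentage changes use |theta_before| as baseline", {
  cmp <- compare_fits(c(arc = -1, x = 2.0), c(arc = -1, x = 2.0))
  expect_equal(cmp$table$pct_change[cmp$table$configuration == "x"], 0)
  expect_false(any(cmp$table$sign_flip))

  cmp <- compare_fits(c(arc = -1, x = 0.5), c(arc = -1, x = -0.5))
  row <- cmp$table[cmp$table$configuration == "x", ]
  expect_equal(row$pct_change, -200)
  expect_true(row$sign_flip)

  cmp <- compare_fits(c(arc = -1, x = 0), c(arc = -1, x = 1))
  expect_true(is.na(cmp$table$pct_change[cmp$table$configuration == "x"]))
})

test_that("the coastal tri-trophic decline reproduces the published ~20%", {
  before <- baltic_estimates("coast_1980s")
  after <- baltic_estimates("coast_2000s")
  cmp <- compare_fits(before, after)
  tri <- cmp$table[cmp$table$configuration == "tri_trophic", ]
  expect_equal(tri$pct_change, 100 * (-0.4182 + 0.3501) / 0.3501,
               tolerance = 1e-12)
  expect_equal(tri$pct_change, -19.45, tolerance = 0.01)
  # exploitative competition exists only in the later model: kept, not dropped
  expect_true("exploitative_competition" %in% cmp$unshared$configuration)
  expect_equal(cmp$unshared$present_in[
    cmp$unshared$configuration == "exploitative_competition"], "after")
})

test_that("swapping periods rebaselines the percentage change", {
  fwd <- compare_fits(c(arc = -1, x = -0.35), c(arc = -1, x = -0.42))
  rev <- compare_fits(c(arc = -1, x = -0.42), c(arc = -1, x = -0.35))
  xf <- fwd$table[fwd$table$configuration == "x", ]
  xr <- rev$table[rev$table$configuration == "x", ]
  expect_equal(sign(xf$pct_change), -sign(xr$pct_change))
  # recomputed against the new baseline, not just negated
  expect_equal(xr$pct_change, 100 * (-0.35 + 0.42) / 0.42)
})

test_that("fits from different systems are refused unless forced", {
  mk <- function(region) {
    structure(list(theta = c(arc = -1), standard_errors = c(arc = 0.1),
                   significant = c(arc = TRUE),
                   web_metadata = list(region = region)),
              class = "ergm_fit")
  }
  expect_error(compare_fits(mk("offshore"), mk("coastal")), "separately")
  cmp <- compare_fits(mk("offshore"), mk("coastal"), allow_cross_system = TRUE)
  expect_equal(nrow(cmp$table), 1)
  expect_error(compare_fits(c(a = 1), c(b = 2)), "share")
})

test_that("comparison tables serialize with one-sided rows padded", {
  cmp <- compare_fits(baltic_estimates("coast_1980s"),
                      baltic_estimates("coast_2000s"))
  path <- withr::local_tempfile(fileext = ".csv")
  write_comparison_csv(cmp, path)
  tab <- read.csv(path)
  expect_true("exploitative_competition" %in% tab$configuration)
  row <- tab[tab$configuration == "exploitative_competition", ]
  expect_true(is.na(row$theta_before) && !is.na(row$theta_after))
})
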