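test_that("EM marginal likelihood matches a brute-force quadrature oracle", {
  set.seed(41)
  dat <- make_rasch_data(10, b = c(-1, -0.2, 0.4, 1.1))
  fit <- fit_rasch_mml(dat$x)
  b_hat <- fit$difficulties
  oracle <- rasch_loglik_naive(dat$x, b_hat, fit$nodes, fit$weights)
  expect_equal(fit$deviance, -2 * oracle, tolerance = 1e-9)
})

test_that("the EM ascends the marginal likelihood monotonically", {
  set.seed(42)
  dat <- make_rasch_data(200, b = c(-1.5, 0, 0.8, 2))
  fit <- fit_rasch_mml(dat$x)
  expect_true(fit$converged)
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
})

test_that("mirror-image items get mirror-image difficulties", {
  set.seed(43)
  dat <- make_rasch_data(3000, b = c(-0.9, 0.9))
  # force item 2's correct rate to equal item 1's incorrect rate exactly
  x <- dat$x
  x[, 2] <- 1L - x[, 1]
  fit <- fit_rasch_mml(x)
  expect_equal(unname(fit$difficulties[1]), -unname(fit$difficulties[2]),
               tolerance = 1e-4)
})

test_that("difficulty recovery improves with sample size", {
  b_true <- seq(-2, 2, length.out = 10)
  rmse <- sapply(c(300, 5000), function(n) {
    dat <- make_rasch_data(n, b_true, seed = n)
    fit <- fit_rasch_mml(dat$x)
    sqrt(mean((fit$difficulties - b_true)^2))
  })
  expect_lt(rmse[2], rmse[1])
  expect_lt(rmse[2], 0.1)
})

test_that("items with a single observed category are excluded loudly", {
  set.seed(44)
  dat <- make_rasch_data(60, b = c(-0.5, 0.5, 0))
  x <- cbind(dat$x, all1 = 1L)
  expect_warning(fit <- fit_rasch_mml(x), "single observed response category")
  expect_true(is.na(fit$difficulties["all1"]))
  expect_equal(sum(!is.na(fit$difficulties)), 3)
})

test_that("MAP theta matches a fine-grid argmax and stays finite", {
  set.seed(45)
  b <- c(-1.2, -0.3, 0.5, 1.4)
  dat <- make_rasch_data(30, b)
  theta <- map_theta(dat$x, b)
  grid_theta <- map_theta_grid(dat$x, b)
  expect_equal(unname(theta), unname(grid_theta), tolerance = 2e-3)

  x_extreme <- rbind(rep(1L, 4), rep(0L, 4))
  th_ext <- map_theta(x_extreme, b)
  expect_true(all(is.finite(th_ext)))
  expect_gt(th_ext[1], 0)
  expect_lt(th_ext[2], 0)

  # symmetric difficulties + balanced half-correct pattern: theta near zero
  th_bal <- map_theta(matrix(c(1L, 1L, 0L, 0L), 1), c(-1, 1, -1, 1))
  expect_equal(unname(th_bal), 0, tolerance = 1e-6)
})

test_that("MAP-based mastery is strict at zero and monotone in raw score", {
  expect_equal(rasch_mastery(c(0.31, 0, -2.1)), c(1L, 0L, 0L))
  set.seed(46)
  b <- runif(8, -2, 2)
  patterns <- matrix(rbinom(8 * 40, 1, 0.5), 40, 8)
  theta <- map_theta(patterns, b)
  raw <- rowSums(patterns)
  # Rasch sufficiency: theta (hence mastery) ordered by raw score
  ord <- order(raw)
  expect_true(all(diff(theta[ord][!duplicated(sort(raw))]) >= -1e-8))
  expect_true(all(tapply(theta, raw, function(v) max(v) - min(v)) < 1e-6))
})

test_that("outfit is nonnegative, near 1 under fit, and flags noise items", {
  set.seed(47)
  b <- seq(-1.5, 1.5, length.out = 12)
  dat <- make_rasch_data(2500, b)
  fit <- fit_rasch_mml(dat$x)
  theta <- map_theta(dat$x, fit$difficulties)
  tab <- rasch_outfit(dat$x, theta, fit$difficulties)
  expect_true(all(tab$outfit >= 0))
  expect_true(all(!tab$flagged))

  # an item answered by coin flip, evaluated across a wide ability span,
  # accumulates huge standardized residuals at the extremes
  set.seed(48)
  theta_wide <- seq(-3.5, 3.5, length.out = 2000)
  p_wide <- plogis(outer(theta_wide, b, "-"))
  x_wide <- matrix(rbinom(length(p_wide), 1, p_wide), 2000)
  x_wide <- cbind(x_wide, noise = rbinom(2000, 1, 0.5))
  tab_wide <- rasch_outfit(x_wide, theta_wide, c(b, 0))
  expect_gt(tab_wide$outfit[13], 1.4)
  expect_true(tab_wide$flagged[13])
  expect_true(all(!tab_wide$flagged[1:12]))

  # a reversed item (success probability decreasing in ability) is flagged
  # even through the full fit-then-score pipeline
  x_rev <- cbind(dat$x, rev = rbinom(2500, 1, plogis(-dat$theta)))
  fit_rev <- fit_rasch_mml(x_rev)
  theta_rev <- map_theta(x_rev, fit_rev$difficulties)
  tab_rev <- rasch_outfit(x_rev, theta_rev, fit_rev$difficulties)
  expect_gt(tab_rev$outfit[13], 1.4)
  expect_true(tab_rev$flagged[13])

  expect_error(rasch_outfit(dat$x, theta[-1], fit$difficulties),
               "dimension mismatch")
})

test_that("fit artifacts serialize to CSV and JSON and recompute", {
  tmp <- withr::local_tempdir()
  set.seed(48)
  dat <- make_rasch_data(150, b = c(-1, 0, 1))
  fit <- fit_rasch_mml(dat$x)
  theta <- map_theta(dat$x, fit$difficulties)
  tab <- write_rasch_fit(fit, rasch_outfit(dat$x, theta, fit$difficulties),
                         csv_path = file.path(tmp, "items.csv"),
                         json_path = file.path(tmp, "fit.json"))
  back <- read.csv(file.path(tmp, "items.csv"))
  expect_equal(back$difficulty, unname(fit$difficulties), tolerance = 1e-12)
  meta <- jsonlite::read_json(file.path(tmp, "fit.json"))
  expect_equal(meta$deviance,
               -2 * rasch_marginal_loglik(dat$x, fit$difficulties),
               tolerance = 1e-9)
})
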