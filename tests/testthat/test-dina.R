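test_that("the conjunctive eta rule and DINA response function are exact", {
  expect_equal(dina_eta(c(1, 1, 0), c(1, 1, 0)), 1L)
  expect_equal(dina_eta(c(1, 0), c(1, 1)), 0L)
  expect_equal(dina_eta(c(0, 0), c(0, 0)), 1L)  # empty product
  expect_error(dina_eta(c(1, 2), c(1, 0)), "binary")
  expect_error(dina_eta(c(1), c(1, 0)), "equal length")

  expect_equal(dina_irf(1, g = 0.2, s = 0.1), 0.9)
  expect_equal(dina_irf(0, g = 0.2, s = 0.1), 0.2)
  expect_equal(dina_irf(c(0, 1), g = 0, s = 0), c(0, 1))
  expect_error(dina_irf(1, g = -0.1, s = 0.2), "\\[0, 1\\]")
})

test_that("the profile space enumerates all classes in a stable order", {
  a <- profile_space(3)
  expect_equal(dim(a), c(8L, 3L))
  expect_equal(unname(a[1, ]), c(0L, 0L, 0L))
  expect_equal(unname(a[2, ]), c(0L, 0L, 1L))  # last attribute fastest
  expect_equal(unname(a[8, ]), c(1L, 1L, 1L))
  expect_equal(nrow(unique(a)), 8L)
  expect_error(profile_space(17), "k <= 16")
})

test_that("EM deviance matches the brute-force latent-class oracle", {
  q <- build_simple_q(c(2, 2))
  dat <- make_dina_data(20, q, g = rep(0.2, 4), s = rep(0.15, 4), seed = 51)
  fit <- fit_dina_em(dat$x, q)
  oracle <- dina_loglik_naive(dat$x, q, fit$guess, fit$slip,
                              fit$class_weights, fit$alpha)
  expect_equal(fit$deviance, -2 * oracle, tolerance = 1e-9)
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
  expect_equal(sum(fit$class_weights), 1, tolerance = 1e-10)
})

test_that("guess and slip are recovered on simulated DINA data", {
  q <- build_simple_q(c(5, 5, 5, 5))
  err <- sapply(c(500, 2000), function(n) {
    dat <- make_dina_data(n, q, g = rep(0.2, 20), s = rep(0.2, 20), seed = n)
    fit <- fit_dina_em(dat$x, q)
    mean(c(abs(fit$guess - 0.2), abs(fit$slip - 0.2)))
  })
  expect_lt(err[2], 0.05)
  expect_lt(err[2], err[1] + 0.01)  # error shrinks (up to MC noise) with n
})

test_that("class-conditional success is coherent with mastery labels", {
  q <- build_simple_q(c(3, 3))
  dat <- make_dina_data(800, q, g = rep(0.25, 6), s = rep(0.2, 6), seed = 52)
  fit <- fit_dina_em(dat$x, q)
  expect_true(all(fit$guess < 1 - fit$slip))
  expect_true(all(fit$guess > 0 & fit$guess < 1))
  expect_true(all(fit$slip > 0 & fit$slip < 1))
})

test_that("posteriors normalize, concentrate when noiseless, and marginalize", {
  q <- build_simple_q(c(2, 2))
  dat <- make_dina_data(40, q, g = rep(0.2, 4), s = rep(0.2, 4), seed = 53)
  fit <- fit_dina_em(dat$x, q)
  post <- dina_posteriors(dat$x, fit)
  expect_equal(unname(rowSums(post$posterior)), rep(1, 40), tolerance = 1e-10)
  expect_equal(post$marginal_mastery,
               post$posterior %*% fit$alpha, tolerance = 1e-12)
  expect_true(all(post$marginal_mastery >= 0 & post$marginal_mastery <= 1))

  # near-noiseless parameters: a pattern matching a profile's ideal response
  # puts almost all posterior mass on that profile
  fit0 <- fit
  fit0$guess[] <- 0.001; fit0$slip[] <- 0.001
  fit0$class_weights <- rep(0.25, 4)
  x_ideal <- matrix(c(1L, 1L, 0L, 0L), 1)  # masters attribute 1 only
  p0 <- dina_posteriors(x_ideal, fit0)
  target <- which(rownames(fit$alpha) == "10")
  expect_gt(p0$posterior[1, target], 0.99)
  expect_equal(unname(p0$map_profile[1, ]), c(1L, 0L))
})

test_that("MAP ties break deterministically toward the lowest class", {
  q <- build_simple_q(c(1, 1))
  fit <- suppressWarnings(fit_dina_em(
    make_dina_data(30, q, g = c(0.3, 0.3), s = c(0.3, 0.3), seed = 54)$x, q))
  fit$guess[] <- 0.5; fit$slip[] <- 0.5  # posteriors equal across classes
  fit$class_weights <- rep(0.25, 4)
  expect_warning(p <- dina_posteriors(matrix(c(1L, 0L), 1), fit), "tied")
  expect_equal(p$map_class, 1L)
})

test_that("item RMSEA is nonnegative, small under fit, large under misfit", {
  q <- build_simple_q(c(4, 4))
  dat <- make_dina_data(2500, q, g = rep(0.2, 8), s = rep(0.2, 8), seed = 55)
  fit <- fit_dina_em(dat$x, q)
  tab <- dina_item_rmsea(dat$x, fit)
  expect_true(all(tab$rmsea >= 0))
  expect_true(all(!tab$flagged))

  # plant an item listed on attribute 1 but actually driven by attribute 2:
  # no single guess/slip pair can match its class-conditional success rates
  x_bad <- dat$x
  set.seed(56)
  x_bad[, 1] <- rbinom(2500, 1, ifelse(dat$alpha[, 2] == 1, 0.9, 0.1))
  fit_bad <- suppressWarnings(fit_dina_em(x_bad, q))
  tab_bad <- suppressMessages(dina_item_rmsea(x_bad, fit_bad))
  expect_gt(tab_bad$rmsea[1], 0.08)
  expect_true(tab_bad$flagged[1])
})

test_that("structural guards reject bad Q-matrices and oversized K", {
  q <- build_simple_q(c(2, 2))
  x <- make_dina_data(20, q, g = rep(0.2, 4), s = rep(0.2, 4), seed = 57)$x
  q_zero <- q; q_zero[1, ] <- 0L
  expect_error(fit_dina_em(x, q_zero), "no attribute")
  expect_error(fit_dina_em(x, q[1:3, ]), "not TRUE")
})

test_that("DINA artifacts serialize and the deviance recomputes post hoc", {
  tmp <- withr::local_tempdir()
  q <- build_simple_q(c(2, 3))
  dat <- make_dina_data(120, q, g = rep(0.2, 5), s = rep(0.2, 5), seed = 58)
  fit <- fit_dina_em(dat$x, q)
  post <- dina_posteriors(dat$x, fit)
  write_dina_fit(fit, dina_item_rmsea(dat$x, fit, post), post,
                 item_csv = file.path(tmp, "items.csv"),
                 person_csv = file.path(tmp, "persons.csv"),
                 json_path = file.path(tmp, "fit.json"))
  items <- read.csv(file.path(tmp, "items.csv"))
  expect_equal(items$guess, unname(fit$guess), tolerance = 1e-12)
  persons <- read.csv(file.path(tmp, "persons.csv"))
  expect_equal(nrow(persons), 120)
  meta <- jsonlite::read_json(file.path(tmp, "fit.json"))
  expect_equal(meta$deviance,
               -2 * dina_marginal_loglik(dat$x, q, items$guess, items$slip,
                                         fit$class_weights),
               tolerance = 1e-9)
})
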