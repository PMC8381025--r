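#' Enumerate the latent attribute profile space
#'
#' All 2^K binary mastery profiles in a fixed lexicographic order (profile 1
#' is all-zero; the last attribute varies fastest), so class indices are
#' stable across fits and runs.
#'
#' @param k Number of attributes.
#' @param attribute_names Optional attribute labels.
#' @return 2^K x K binary matrix of profiles.
#' @export
profile_space <- function(k, attribute_names = NULL) {
  stopifnot(k >= 1, k <= 16)
  # binary counting 0 .. 2^K - 1 with attribute 1 as the leading digit
  idx <- 0:(2^k - 1)
  alpha <- sapply(k:1, function(bit) (idx %/% 2^(bit - 1)) %% 2)
  alpha <- matrix(as.integer(alpha), ncol = k)
  colnames(alpha) <- attribute_names %||% paste0("A", seq_len(k))
  rownames(alpha) <- apply(alpha, 1, paste, collapse = "")
  alpha
}

#' Ideal-response indicator of the conjunctive ("and"-gate) rule
#'
#' `eta = prod_k alpha_k ^ q_k`: 1 exactly when every attribute the item
#' requires is mastered. The empty product (an all-zero Q-row) is 1 by
#' convention, though simple-structure inputs never produce one.
#'
#' @param alpha Binary mastery profile.
#' @param q_row Binary Q-matrix row of the same length.
#' @return 0 or 1.
#' @export
dina_eta <- function(alpha, q_row) {
  if (length(alpha) != length(q_row)) {
    stop("alpha and q_row must have equal length", call. = FALSE)
  }
  if (!all(alpha %in% c(0, 1)) || !all(q_row %in% c(0, 1))) {
    stop("alpha and q_row must be binary", call. = FALSE)
  }
  as.integer(all(alpha[q_row == 1] == 1))
}

# classes x items eta matrix
eta_matrix <- function(alpha, q) {
  e <- matrix(0L, nrow(alpha), nrow(q))
  for (i in seq_len(nrow(q))) {
    req <- which(q[i, ] == 1)
    e[, i] <- as.integer(rowSums(alpha[, req, drop = FALSE]) == length(req))
  }
  dimnames(e) <- list(rownames(alpha), rownames(q))
  e
}

#' DINA item response function
#'
#' Success probability `1 - s` for examinees who master all required
#' attributes (`eta = 1`) and `g` otherwise.
#'
#' @param eta Ideal-response indicator (0/1, vectorised).
#' @param g Guess parameter in [0, 1].
#' @param s Slip parameter in [0, 1].
#' @return Success probability.
#' @export
dina_irf <- function(eta, g, s) {
  if (any(g < 0 | g > 1) || any(s < 0 | s > 1)) {
    stop("guess and slip parameters must lie in [0, 1]", call. = FALSE)
  }
  g^(1 - eta) * (1 - s)^eta
}

#' Fit the DINA model by EM over the full latent class space
#'
#' Marginal maximum likelihood with a saturated structural model: the 2^K
#' class mixing weights are free (up to summing to 1) and estimated jointly
#' with the per-item guess and slip parameters. The E-step computes each
#' person's posterior over all classes in log space (stable for long tests);
#' the M-step updates guess/slip by closed-form expected-count ratios and
#' the weights by posterior means. Guess and slip are clipped to
#' [1e-4, 1 - 1e-4]; the monotonicity condition g < 1 - s is checked and
#' warned about but not imposed.
#'
#' @param responses Persons x items binary matrix.
#' @param q Q-matrix (any structure; every row must load >= 1 attribute;
#'   K <= 16 so the 2^K enumeration stays tractable).
#' @param tol Convergence tolerance on the largest parameter change.
#' @param max_iter Maximum EM iterations.
#' @param init_g,init_s Starting values.
#' @return An object of class `dina_fit`: `guess`, `slip` (named), `alpha`
#'   (profile space), `class_weights`, `deviance`, `loglik_trace`,
#'   `iterations`, `converged`, `q`.
#' @export
fit_dina_em <- function(responses, q, tol = 1e-5, max_iter = 1000L,
                        init_g = 0.2, init_s = 0.2) {
  x <- check_responses(responses)
  q <- validate_qmatrix(q)
  stopifnot(ncol(x) == nrow(q))
  k <- ncol(q)
  if (k > 16) stop("K = ", k, " attributes: 2^K class enumeration refused ",
                   "above K = 16", call. = FALSE)
  alpha <- profile_space(k, colnames(q))
  e_ci <- eta_matrix(alpha, q)                      # classes x items
  n <- nrow(x); j <- ncol(x); n_class <- nrow(alpha)

  g <- rep(init_g, j); s <- rep(init_s, j)
  pi_c <- rep(1 / n_class, n_class)
  lo <- 1e-4; hi <- 1 - 1e-4
  loglik_trace <- numeric(0)
  converged <- FALSE

  for (iter in seq_len(max_iter)) {
    p_ci <- t(g^(1 - t(e_ci)) * (1 - s)^t(e_ci))    # classes x items
    # E-step in log space
    ll_jc <- x %*% t(log(p_ci)) + (1 - x) %*% t(log1p(-p_ci))  # persons x classes
    ll_jc <- sweep(ll_jc, 2, log(pi_c), "+")
    mx <- apply(ll_jc, 1, max)
    w <- exp(ll_jc - mx)
    rs <- rowSums(w)
    loglik <- sum(mx + log(rs))
    loglik_trace <- c(loglik_trace, loglik)
    post <- w / rs                                   # persons x classes

    # M-step
    mass1 <- post %*% e_ci                           # persons x items: P(eta=1 | x_j)
    n1 <- colSums(mass1)                             # expected masters per item
    r1 <- colSums(x * mass1)                         # expected correct among masters
    n0 <- n - n1
    r0 <- colSums(x) - r1
    g_new <- pmin(pmax(r0 / n0, lo), hi)
    s_new <- pmin(pmax(1 - r1 / n1, lo), hi)
    pi_new <- colMeans(post)

    change <- max(abs(g_new - g), abs(s_new - s), abs(pi_new - pi_c))
    g <- g_new; s <- s_new; pi_c <- pi_new
    if (change < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning(sprintf(
      "DINA EM did not converge in %d iterations (last max change = %.2e); loglik trace tail: %s",
      max_iter, change,
      paste(sprintf("%.4f", utils::tail(loglik_trace, 3)), collapse = ", ")),
      call. = FALSE)
  }
  if (any(g >= 1 - s)) {
    warning("monotonicity g < 1 - s violated for item(s): ",
            paste(colnames(x)[g >= 1 - s], collapse = ", "), call. = FALSE)
  }

  names(g) <- names(s) <- colnames(x)
  deviance <- -2 * dina_marginal_loglik(x, q, g, s, pi_c)

  structure(
    list(guess = g, slip = s, alpha = alpha, class_weights = pi_c,
         deviance = deviance, loglik_trace = loglik_trace,
         iterations = length(loglik_trace), converged = converged, q = q,
         settings = list(tol = tol, max_iter = max_iter,
                         init_g = init_g, init_s = init_s)),
    class = "dina_fit")
}

#' Marginal log-likelihood of a DINA parameterisation
#'
#' Direct evaluation of `sum_j log sum_c pi_c prod_i P(x_ij | alpha_c)`,
#' used for the reported deviance and post-hoc recomputation from saved
#' parameters.
#'
#' @param responses Persons x items binary matrix.
#' @param q Q-matrix.
#' @param g,s Guess and slip vectors.
#' @param class_weights Mixing proportions over the 2^K profiles in
#'   [profile_space()] order.
#' @return Log marginal likelihood (a scalar).
#' @export
dina_marginal_loglik <- function(responses, q, g, s, class_weights) {
  x <- check_responses(responses)
  q <- validate_qmatrix(q)
  alpha <- profile_space(ncol(q), colnames(q))
  e_ci <- eta_matrix(alpha, q)
  p_ci <- t(g^(1 - t(e_ci)) * (1 - s)^t(e_ci))
  ll_jc <- x %*% t(log(p_ci)) + (1 - x) %*% t(log1p(-p_ci))
  ll_jc <- sweep(ll_jc, 2, log(class_weights), "+")
  mx <- apply(ll_jc, 1, max)
  sum(mx + log(rowSums(exp(ll_jc - mx))))
}

#' @export
print.dina_fit <- function(x, ...) {
  cat(sprintf(
    "DINA fit: %d items, %d attributes (%d classes), deviance %.2f, %d EM iterations%s\n",
    length(x$guess), ncol(x$alpha), nrow(x$alpha), x$deviance, x$iterations,
    if (x$converged) "" else " (NOT converged)"))
  cat(sprintf("  guess in [%.3f, %.3f], slip in [%.3f, %.3f]\n",
              min(x$guess), max(x$guess), min(x$slip), max(x$slip)))
  invisible(x)
}

#' Posterior classification under a fitted DINA model
#'
#' Computes each examinee's posterior over the 2^K profiles, the maximum a
#' posteriori profile (ties broken toward the lowest class index, with a
#' warning), and the per-attribute marginal mastery probability (the
#' posterior mass of the profiles mastering that attribute).
#'
#' @param responses Persons x items binary matrix.
#' @param fit A `dina_fit`.
#' @return List with `posterior` (persons x classes, rows summing to 1),
#'   `map_class` (class index), `map_profile` (persons x attributes binary),
#'   `marginal_mastery` (persons x attributes probabilities).
#' @export
dina_posteriors <- function(responses, fit) {
  stopifnot(inherits(fit, "dina_fit"))
  x <- check_responses(responses)
  stopifnot(ncol(x) == length(fit$guess))
  e_ci <- eta_matrix(fit$alpha, fit$q)
  p_ci <- t(fit$guess^(1 - t(e_ci)) * (1 - fit$slip)^t(e_ci))
  ll_jc <- x %*% t(log(p_ci)) + (1 - x) %*% t(log1p(-p_ci))
  ll_jc <- sweep(ll_jc, 2, log(fit$class_weights), "+")
  mx <- apply(ll_jc, 1, max)
  w <- exp(ll_jc - mx)
  post <- w / rowSums(w)

  map_class <- max.col(post, ties.method = "first")
  row_max <- post[cbind(seq_len(nrow(post)), map_class)]
  n_at_max <- rowSums(abs(post - row_max) < 1e-12)
  if (any(n_at_max > 1)) {
    warning(sum(n_at_max > 1), " examinee(s) with tied posterior maxima; ",
            "ties broken toward the lowest class index", call. = FALSE)
  }
  map_profile <- fit$alpha[map_class, , drop = FALSE]
  rownames(map_profile) <- rownames(x)
  marginal <- post %*% fit$alpha
  dimnames(marginal) <- list(rownames(x), colnames(fit$alpha))
  dimnames(post) <- list(rownames(x), rownames(fit$alpha))
  list(posterior = post, map_class = map_class,
       map_profile = map_profile, marginal_mastery = marginal)
}

#' Item-level RMSEA fit index for the DINA model
#'
#' For each item, the root mean square (over latent classes, weighted by the
#' estimated class proportions) difference between the model-implied success
#' probability and the posterior-weighted observed proportion correct in the
#' class: `RMSEA_i = sqrt(sum_c pi_c (P_i(alpha_c) - Ptilde_ic)^2)`, with
#' `Ptilde_ic = sum_j post_jc x_ij / sum_j post_jc`. Classes with essentially
#' no posterior mass are skipped with their weight renormalised over the
#' remaining classes. Items above the cut (0.08 by convention) are flagged.
#'
#' @param responses Persons x items binary matrix.
#' @param fit A `dina_fit`.
#' @param posteriors Optional precomputed [dina_posteriors()] output.
#' @param cutoff Flag threshold.
#' @param empty_tol Posterior-mass threshold below which a class is skipped.
#' @return Data frame with columns `item`, `rmsea`, `flagged`.
#' @export
dina_item_rmsea <- function(responses, fit, posteriors = NULL,
                            cutoff = 0.08, empty_tol = 1e-8) {
  x <- check_responses(responses)
  if (is.null(posteriors)) posteriors <- dina_posteriors(x, fit)
  post <- posteriors$posterior
  e_ci <- eta_matrix(fit$alpha, fit$q)
  p_ci <- t(fit$guess^(1 - t(e_ci)) * (1 - fit$slip)^t(e_ci))  # classes x items

  class_mass <- colSums(post)
  keep <- class_mass > empty_tol
  if (!all(keep)) {
    message(sum(!keep), " empty latent class(es) skipped in RMSEA ",
            "with weight renormalisation")
  }
  obs <- t(crossprod(post[, keep, drop = FALSE], x) /
             class_mass[keep])                       # items x kept classes
  w <- fit$class_weights[keep]
  w <- w / sum(w)
  diff2 <- (t(p_ci[keep, , drop = FALSE]) - obs)^2   # items x kept classes
  rmsea <- sqrt(as.vector(diff2 %*% w))
  data.frame(item = colnames(x) %||% seq_len(ncol(x)),
             rmsea = rmsea,
             flagged = rmsea > cutoff,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Serialize a DINA fit
#'
#' Writes the item table (id, guess, slip, RMSEA, flag) and the person table
#' (MAP profile bits, per-attribute marginal probabilities) as CSV, and a
#' JSON summary (deviance, iterations, settings).
#'
#' @param fit A `dina_fit`.
#' @param rmsea_table Optional [dina_item_rmsea()] output to merge.
#' @param posteriors Optional [dina_posteriors()] output for the person table.
#' @param item_csv,person_csv,json_path Output paths (`NULL` skips).
#' @return Invisibly, the item table.
#' @export
write_dina_fit <- function(fit, rmsea_table = NULL, posteriors = NULL,
                           item_csv = NULL, person_csv = NULL,
                           json_path = NULL) {
  tab <- data.frame(item = names(fit$guess), guess = unname(fit$guess),
                    slip = unname(fit$slip), stringsAsFactors = FALSE)
  if (!is.null(rmsea_table)) tab <- merge(tab, rmsea_table, by = "item", sort = FALSE)
  if (!is.null(item_csv)) utils::write.csv(tab, item_csv, row.names = FALSE, quote = FALSE)
  if (!is.null(person_csv) && !is.null(posteriors)) {
    ids <- rownames(posteriors$map_profile) %||%
      paste0("person", seq_len(nrow(posteriors$map_profile)))
    pt <- data.frame(person = ids,
                     posteriors$map_profile,
                     check.names = FALSE, stringsAsFactors = FALSE)
    mm <- posteriors$marginal_mastery
    colnames(mm) <- paste0("p_", colnames(mm))
    pt <- cbind(pt, mm)
    utils::write.csv(pt, person_csv, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(model = "dina", deviance = fit$deviance,
           iterations = fit$iterations, converged = fit$converged,
           settings = fit$settings),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(tab)
}
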