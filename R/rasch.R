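#' Fit a unidimensional Rasch model by marginal maximum likelihood
#'
#' Item difficulties are estimated by an EM algorithm that integrates the
#' person parameter over a standard-normal population density, discretised
#' on a fixed grid of 61 equally spaced quadrature nodes on [-6, 6] with
#' renormalised normal weights. The latent scale is identified by fixing the
#' population at N(0, 1) and leaving the difficulties unconstrained, which
#' makes a mastery cut at theta = 0 the population median. Items observed in
#' only one response category carry no information about their difficulty
#' under this parameterisation and are excluded with a warning; their
#' difficulty is reported as `NA`.
#'
#' The E-step computes each person's posterior over the quadrature nodes;
#' the M-step solves the per-item score equation by safeguarded Newton
#' iterations on the expected complete-data log-likelihood. Convergence is
#' declared when the largest difficulty change falls below `tol`.
#'
#' @param responses Persons x items binary matrix (complete).
#' @param n_quad Number of quadrature nodes.
#' @param quad_range Endpoints of the node grid.
#' @param tol Convergence tolerance on max |change in b|.
#' @param max_iter Maximum EM iterations.
#' @return An object of class `rasch_fit`: `difficulties` (named, `NA` for
#'   excluded items), `deviance` (-2 x log marginal likelihood over the
#'   included items), `loglik_trace`, `iterations`, `converged`,
#'   `excluded_items`, plus the quadrature `nodes` and `weights` used.
#' @export
fit_rasch_mml <- function(responses, n_quad = 61L, quad_range = c(-6, 6),
                          tol = 1e-5, max_iter = 1000L) {
  x_all <- check_responses(responses)
  if (ncol(x_all) < 2) stop("need at least 2 items", call. = FALSE)

  p_obs <- colMeans(x_all)
  degenerate <- p_obs == 0 | p_obs == 1
  if (any(degenerate)) {
    warning("excluding item(s) with a single observed response category: ",
            paste(colnames(x_all)[degenerate], collapse = ", "), call. = FALSE)
  }
  x <- x_all[, !degenerate, drop = FALSE]
  if (ncol(x) < 2) stop("fewer than 2 informative items remain", call. = FALSE)

  nodes <- seq(quad_range[1], quad_range[2], length.out = n_quad)
  weights <- stats::dnorm(nodes)
  weights <- weights / sum(weights)

  # start at the logit of the observed proportion correct
  b <- -stats::qlogis(colMeans(x))
  n <- nrow(x)
  j <- ncol(x)
  loglik_trace <- numeric(0)
  converged <- FALSE

  for (iter in seq_len(max_iter)) {
    # E-step: person x node posterior
    p <- stats::plogis(outer(-b, nodes, "+"))        # items x nodes: P(theta_t - b_i)
    log_p <- log(p); log_q <- log1p(-p)
    ll_jt <- x %*% log_p + (1 - x) %*% log_q          # persons x nodes
    ll_jt <- sweep(ll_jt, 2, log(weights), "+")
    mx <- apply(ll_jt, 1, max)
    w_jt <- exp(ll_jt - mx)
    row_sums <- rowSums(w_jt)
    loglik <- sum(mx + log(row_sums))
    loglik_trace <- c(loglik_trace, loglik)
    f_jt <- w_jt / row_sums

    nt <- colSums(f_jt)                               # expected persons per node
    r_it <- crossprod(x, f_jt)                        # items x nodes expected correct

    # M-step: per-item Newton on sum_t [r_it - n_t P(theta_t - b_i)] = 0
    b_new <- b
    for (i in seq_len(j)) {
      bi <- b[i]
      for (step in 1:50) {
        p_t <- stats::plogis(nodes - bi)
        score <- sum(nt * p_t) - sum(r_it[i, ])
        info <- sum(nt * p_t * (1 - p_t))
        delta <- score / info
        delta <- max(min(delta, 2), -2)               # step safeguard
        bi <- bi + delta
        if (abs(delta) < 1e-10) break
      }
      b_new[i] <- bi
    }

    change <- max(abs(b_new - b))
    b <- b_new
    if (change < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning(sprintf(
      "Rasch EM did not converge in %d iterations (last max |db| = %.2e)",
      max_iter, change), call. = FALSE)
  }

  # deviance at the final parameters
  deviance <- -2 * rasch_marginal_loglik(x, b, nodes, weights)

  difficulties <- rep(NA_real_, ncol(x_all))
  names(difficulties) <- colnames(x_all)
  difficulties[!degenerate] <- b

  structure(
    list(difficulties = difficulties,
         deviance = deviance,
         loglik_trace = loglik_trace,
         iterations = length(loglik_trace),
         converged = converged,
         excluded_items = colnames(x_all)[degenerate],
         nodes = nodes, weights = weights,
         settings = list(n_quad = n_quad, quad_range = quad_range,
                         tol = tol, max_iter = max_iter)),
    class = "rasch_fit")
}

#' Marginal log-likelihood of a Rasch model on a quadrature grid
#'
#' Direct evaluation of `sum_j log sum_t w_t prod_i P_it^x (1-P_it)^(1-x)`,
#' used for the reported deviance and for post-hoc recomputation from saved
#' parameters.
#'
#' @param responses Persons x items binary matrix.
#' @param difficulties Item difficulties.
#' @param nodes,weights Quadrature nodes and (normalised) weights.
#' @return The log marginal likelihood (a scalar).
#' @export
rasch_marginal_loglik <- function(responses, difficulties,
                                  nodes = seq(-6, 6, length.out = 61),
                                  weights = NULL) {
  x <- check_responses(responses)
  stopifnot(ncol(x) == length(difficulties))
  if (is.null(weights)) {
    weights <- stats::dnorm(nodes)
    weights <- weights / sum(weights)
  }
  p <- stats::plogis(outer(-difficulties, nodes, "+"))
  ll_jt <- x %*% log(p) + (1 - x) %*% log1p(-p)
  ll_jt <- sweep(ll_jt, 2, log(weights), "+")
  mx <- apply(ll_jt, 1, max)
  sum(mx + log(rowSums(exp(ll_jt - mx))))
}

#' @export
print.rasch_fit <- function(x, ...) {
  cat(sprintf(
    "Rasch fit: %d items (%d excluded), deviance %.2f, %d EM iterations%s\n",
    length(x$difficulties), length(x$excluded_items), x$deviance,
    x$iterations, if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Maximum a posteriori person scoring
#'
#' For each examinee the posterior mode of theta under the Rasch likelihood
#' and a standard-normal prior. The log-posterior is strictly concave, so a
#' Newton iteration with step-halving against the posterior value converges
#' for every response pattern, including all-correct and all-incorrect
#' patterns, which the proper prior keeps finite.
#'
#' @param responses Persons x items binary matrix.
#' @param difficulties Item difficulties (finite; `NA` items are dropped).
#' @param tol Convergence tolerance in logits.
#' @return Named numeric vector of MAP theta estimates.
#' @export
map_theta <- function(responses, difficulties, tol = 1e-6) {
  x <- check_responses(responses)
  stopifnot(ncol(x) == length(difficulties))
  keep <- !is.na(difficulties)
  x <- x[, keep, drop = FALSE]
  b <- difficulties[keep]
  if (any(!is.finite(b))) stop("difficulties must be finite", call. = FALSE)

  log_post <- function(theta) {
    p <- stats::plogis(outer(theta, b, "-"))
    rowSums(x * log(p) + (1 - x) * log1p(-p)) - theta^2 / 2
  }

  theta <- rep(0, nrow(x))
  lp <- log_post(theta)
  for (iter in 1:100) {
    p <- stats::plogis(outer(theta, b, "-"))
    grad <- rowSums(x - p) - theta
    hess <- -rowSums(p * (1 - p)) - 1
    step <- -grad / hess
    # step-halving safeguard on the posterior value
    new_theta <- theta + step
    new_lp <- log_post(new_theta)
    bad <- new_lp < lp - 1e-12
    halvings <- 0
    while (any(bad) && halvings < 40) {
      step[bad] <- step[bad] / 2
      new_theta <- theta + step
      new_lp <- log_post(new_theta)
      bad <- new_lp < lp - 1e-12
      halvings <- halvings + 1
    }
    moved <- max(abs(new_theta - theta))
    theta <- new_theta
    lp <- new_lp
    if (moved < tol) break
  }
  names(theta) <- rownames(x)
  theta
}

#' Rasch mastery rule
#'
#' Master when the scored theta strictly exceeds the cut (default 0, the
#' population median under the N(0, 1) identification).
#'
#' @param theta Per-person theta estimates.
#' @param cut Logit cut.
#' @return Integer 0/1 vector.
#' @export
rasch_mastery <- function(theta, cut = 0) {
  (theta > cut) * 1L
}

#' Outfit item-fit statistic
#'
#' The unweighted mean-square standardised residual
#' `outfit_i = mean_j (X_ij - P_ij)^2 / (P_ij (1 - P_ij))`, with expectation
#' 1 under model fit. Values outside the acceptance band (0.6 to 1.4 by
#' convention) are flagged.
#'
#' @param responses Persons x items binary matrix.
#' @param theta Per-person ability estimates.
#' @param difficulties Per-item difficulties.
#' @param band Acceptable outfit range.
#' @return Data frame with columns `item`, `outfit`, `flagged`.
#' @export
rasch_outfit <- function(responses, theta, difficulties,
                         band = c(0.6, 1.4)) {
  x <- check_responses(responses)
  if (length(theta) != nrow(x) || length(difficulties) != ncol(x)) {
    stop("dimension mismatch between responses, theta and difficulties",
         call. = FALSE)
  }
  p <- stats::plogis(outer(theta, difficulties, "-"))
  deg <- !is.na(p) & (p <= 0 | p >= 1)
  if (any(deg)) {
    warning("degenerate response probabilities excluded from outfit",
            call. = FALSE)
    p[deg] <- NA
  }
  z2 <- (x - p)^2 / (p * (1 - p))
  outfit <- colMeans(z2, na.rm = TRUE)
  data.frame(item = colnames(x) %||% seq_len(ncol(x)),
             outfit = unname(outfit),
             flagged = unname(outfit < band[1] | outfit > band[2]),
             row.names = NULL, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a Rasch fit
#'
#' Writes the item table (id, difficulty, outfit, flag) as CSV and a JSON
#' summary (deviance, iterations, settings).
#'
#' @param fit A `rasch_fit`.
#' @param outfit_table Optional output of [rasch_outfit()] to merge in.
#' @param csv_path,json_path Output paths (either may be `NULL` to skip).
#' @return Invisibly, the item table written.
#' @export
write_rasch_fit <- function(fit, outfit_table = NULL,
                            csv_path = NULL, json_path = NULL) {
  tab <- data.frame(item = names(fit$difficulties),
                    difficulty = unname(fit$difficulties),
                    stringsAsFactors = FALSE)
  if (!is.null(outfit_table)) tab <- merge(tab, outfit_table, by = "item", sort = FALSE)
  if (!is.null(csv_path)) utils::write.csv(tab, csv_path, row.names = FALSE, quote = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(model = "rasch", deviance = fit$deviance,
           iterations = fit$iterations, converged = fit$converged,
           excluded_items = fit$excluded_items, settings = fit$settings),
      json_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(tab)
}
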