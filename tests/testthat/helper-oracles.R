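# Independent brute-force oracles and tiny data builders used across tests.
# These deliberately use naive loops (no shared code with the package
# internals beyond the exported API under test).

# direct quadrature evaluation of the Rasch marginal log-likelihood
rasch_loglik_naive <- function(x, b, nodes, weights) {
  b <- unname(b); weights <- unname(weights); dimnames(x) <- NULL
  total <- 0
  for (j in seq_len(nrow(x))) {
    marg <- 0
    for (t in seq_along(nodes)) {
      lik <- 1
      for (i in seq_len(ncol(x))) {
        p <- 1 / (1 + exp(-(nodes[t] - b[i])))
        lik <- lik * ifelse(x[j, i] == 1, p, 1 - p)
      }
      marg <- marg + weights[t] * lik
    }
    total <- total + log(marg)
  }
  total
}

# direct evaluation of the DINA marginal log-likelihood over all 2^K classes
dina_loglik_naive <- function(x, q, g, s, pi_c, alpha) {
  g <- unname(g); s <- unname(s); pi_c <- unname(pi_c)
  dimnames(x) <- NULL; dimnames(q) <- NULL; dimnames(alpha) <- NULL
  total <- 0
  for (j in seq_len(nrow(x))) {
    marg <- 0
    for (c in seq_len(nrow(alpha))) {
      lik <- pi_c[c]
      for (i in seq_len(ncol(x))) {
        eta <- as.integer(all(alpha[c, q[i, ] == 1] == 1))
        p <- if (eta == 1) 1 - s[i] else g[i]
        lik <- lik * ifelse(x[j, i] == 1, p, 1 - p)
      }
      marg <- marg + lik
    }
    total <- total + log(marg)
  }
  total
}

# fine-grid argmax of the Rasch log-posterior, per person
map_theta_grid <- function(x, b, grid = seq(-6, 6, by = 0.001)) {
  apply(x, 1, function(resp) {
    lp <- vapply(grid, function(th) {
      p <- 1 / (1 + exp(-(th - b)))
      sum(resp * log(p) + (1 - resp) * log(1 - p)) - th^2 / 2
    }, numeric(1))
    grid[which.max(lp)]
  })
}

# direct per-attribute agreement count
accuracy_naive <- function(true, observed) {
  vapply(seq_len(ncol(true)), function(k) {
    hits <- 0
    for (j in seq_len(nrow(true))) {
      if (true[j, k] == observed[j, k]) hits <- hits + 1
    }
    hits / nrow(true)
  }, numeric(1))
}

# small Rasch dataset with known difficulties
make_rasch_data <- function(n, b, seed = 1) {
  set.seed(seed)
  theta <- rnorm(n)
  p <- plogis(outer(theta, b, "-"))
  x <- matrix(rbinom(length(p), 1, p), nrow = n)
  colnames(x) <- paste0("item", seq_along(b))
  list(x = x, theta = theta, b = b)
}

# small DINA dataset with known guess/slip and profile weights
make_dina_data <- function(n, q, g, s, pi_c = NULL, seed = 1) {
  set.seed(seed)
  k <- ncol(q)
  alpha_space <- dcmastery::profile_space(k)
  if (is.null(pi_c)) pi_c <- rep(1 / nrow(alpha_space), nrow(alpha_space))
  cls <- sample(nrow(alpha_space), n, replace = TRUE, prob = pi_c)
  alpha <- alpha_space[cls, , drop = FALSE]
  x <- matrix(0L, n, nrow(q))
  for (i in seq_len(nrow(q))) {
    req <- which(q[i, ] == 1)
    eta <- as.integer(rowSums(alpha[, req, drop = FALSE]) == length(req))
    p <- ifelse(eta == 1, 1 - s[i], g[i])
    x[, i] <- rbinom(n, 1, p)
  }
  colnames(x) <- paste0("item", seq_len(nrow(q)))
  list(x = x, alpha = alpha, cls = cls, g = g, s = s, pi_c = pi_c)
}
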