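#' Define one cell of the simulation design
#'
#' A condition bundles everything needed to replicate one accuracy-study
#' cell: the number of examinees per form, the strand sizes (one test form
#' always carries all strands simultaneously), the common inter-attribute
#' correlation of the ability distribution, the uniform difficulty range,
#' the number of replicate forms, and the master seed. Defaults are the
#' study design: 1,000 examinees, strands of 5/10/15/20 items, difficulties
#' uniform on [-3, 3], 50 forms.
#'
#' @param n_persons Examinees per form.
#' @param strand_sizes Items per content strand.
#' @param rho Common pairwise correlation of the latent abilities, in [0, 1).
#' @param difficulty_low,difficulty_high Uniform difficulty range (logits).
#' @param n_forms Number of replicate test forms.
#' @param seed Master seed; each form draws from a deterministic substream.
#' @return An object of class `sim_condition`.
#' @export
sim_condition <- function(n_persons = 1000L,
                          strand_sizes = c(5L, 10L, 15L, 20L),
                          rho = 0,
                          difficulty_low = -3,
                          difficulty_high = 3,
                          n_forms = 50L,
                          seed = 1L) {
  stopifnot(n_persons >= 1, length(strand_sizes) >= 1, all(strand_sizes >= 1),
            n_forms >= 1, is.finite(rho))
  k <- length(strand_sizes)
  if (rho < 0 || rho >= 1 || (k > 1 && rho <= -1 / (k - 1))) {
    stop("rho = ", rho, " does not give a positive-definite ",
         "compound-symmetric correlation matrix for K = ", k, call. = FALSE)
  }
  if (difficulty_low >= difficulty_high) {
    stop("difficulty_low must be strictly below difficulty_high", call. = FALSE)
  }
  structure(
    list(n_persons = as.integer(n_persons),
         strand_sizes = as.integer(strand_sizes),
         rho = rho,
         difficulty_low = difficulty_low,
         difficulty_high = difficulty_high,
         n_forms = as.integer(n_forms),
         seed = as.integer(seed)),
    class = "sim_condition")
}

#' @export
print.sim_condition <- function(x, ...) {
  cat(sprintf(
    "Simulation condition: %d persons, strands [%s], rho = %.2f,\n  difficulties U(%g, %g), %d forms, seed %d\n",
    x$n_persons, paste(x$strand_sizes, collapse = ", "), x$rho,
    x$difficulty_low, x$difficulty_high, x$n_forms, x$seed))
  invisible(x)
}

#' Deterministic per-form substream seed
#'
#' Forms are reproducible in isolation: form f of a study with master seed s
#' always uses the same derived seed, kept within the 32-bit integer range.
#'
#' @param seed Master seed.
#' @param form Form index (1-based).
#' @return An integer seed.
#' @export
form_seed <- function(seed, form) {
  as.integer((as.double(seed) * 48271 + as.double(form) * 104729) %% 2147483647)
}

#' Draw item difficulties uniformly on a logit range
#'
#' @param n_items Number of items.
#' @param low,high Range endpoints in logits; `low < high`.
#' @return Numeric vector of difficulties.
#' @export
draw_difficulties <- function(n_items, low = -3, high = 3) {
  if (low >= high) stop("low must be strictly below high", call. = FALSE)
  stats::runif(n_items, low, high)
}

#' Draw correlated latent abilities
#'
#' Abilities are multivariate normal with zero mean, unit variances, and a
#' common pairwise correlation `rho` (compound symmetry), the structure used
#' for the inter-attribute correlation factor of the accuracy study.
#'
#' @param n_persons Number of examinees.
#' @param n_attributes Number of content strands K.
#' @param rho Common pairwise correlation.
#' @return `n_persons` x `n_attributes` matrix of abilities (logit scale).
#' @export
draw_abilities <- function(n_persons, n_attributes, rho = 0) {
  k <- as.integer(n_attributes)
  if (k < 1) stop("n_attributes must be >= 1", call. = FALSE)
  if (rho >= 1 || (k > 1 && rho <= -1 / (k - 1))) {
    stop("rho = ", rho, " is not positive definite for K = ", k, call. = FALSE)
  }
  sigma <- matrix(rho, k, k)
  diag(sigma) <- 1
  th <- MASS::mvrnorm(n_persons, mu = rep(0, k), Sigma = sigma)
  th <- matrix(th, nrow = n_persons, ncol = k)
  colnames(th) <- paste0("A", seq_len(k))
  th
}

#' Simulate binary responses under the simple-structure MIRT model
#'
#' Each item i measures the single attribute k(i) given by its Q-matrix row
#' with unit slope, so the success probability is
#' `plogis(theta[j, k(i)] - b[i])` and responses are independent Bernoulli
#' draws given abilities. The generator is defined for simple-structure
#' Q-matrices only.
#'
#' @param abilities Persons x attributes ability matrix.
#' @param difficulties Per-item difficulties (logits).
#' @param q Simple-structure Q-matrix with `length(difficulties)` rows.
#' @return Persons x items binary matrix.
#' @export
simulate_responses <- function(abilities, difficulties, q) {
  if (!is_simple_structure(q)) {
    stop("response generator is defined for simple-structure Q-matrices only",
         call. = FALSE)
  }
  abilities <- as.matrix(abilities)
  stopifnot(nrow(q) == length(difficulties), ncol(q) == ncol(abilities))
  k_of_item <- item_attribute(q)
  eta <- abilities[, k_of_item, drop = FALSE]
  p <- stats::plogis(sweep(eta, 2, difficulties, "-"))
  x <- matrix(stats::rbinom(length(p), 1L, p), nrow = nrow(p))
  dimnames(x) <- list(paste0("person", seq_len(nrow(x))), rownames(q))
  x
}

#' True mastery from latent abilities
#'
#' An examinee truly masters attribute k when the latent ability exceeds
#' zero strictly — the population median, symmetric with the Rasch
#' estimated-mastery rule. Ties at exactly 0 are non-mastery.
#'
#' @param abilities Persons x attributes ability matrix.
#' @param cut Mastery cut on the logit scale (default 0).
#' @return Persons x attributes binary mastery matrix.
#' @export
true_mastery <- function(abilities, cut = 0) {
  m <- (as.matrix(abilities) > cut) * 1L
  dimnames(m) <- dimnames(as.matrix(abilities))
  m
}

#' Generate one complete test form
#'
#' Draws difficulties, abilities and responses for one form of a condition,
#' using that form's deterministic substream seed.
#'
#' @param condition A [sim_condition()].
#' @param form Form index (used to derive the substream seed).
#' @return A list of class `generated_form` with elements `q`,
#'   `difficulties`, `abilities`, `responses`, `true_mastery`, `seed`.
#' @export
simulate_form <- function(condition, form = 1L) {
  stopifnot(inherits(condition, "sim_condition"))
  set.seed(form_seed(condition$seed, form))
  q <- build_simple_q(condition$strand_sizes)
  b <- draw_difficulties(nrow(q), condition$difficulty_low,
                         condition$difficulty_high)
  names(b) <- rownames(q)
  th <- draw_abilities(condition$n_persons, ncol(q), condition$rho)
  x <- simulate_responses(th, b, q)
  structure(
    list(q = q, difficulties = b, abilities = th, responses = x,
         true_mastery = true_mastery(th), seed = form_seed(condition$seed, form)),
    class = "generated_form")
}

#' Synthetic licensing-examination-shaped dataset
#'
#' Generates a dataset with the shape of a large medical licensing
#' examination: by default 3,265 examinees, 360 items across 8 content
#' strands of 45/45/45/25/154/20/20/6 items, simple-structure Q-matrix,
#' abilities compound-symmetric multivariate normal, difficulties uniform on
#' [-3, 3]. The real examination data are not public; this generator is a
#' synthetic stand-in that reproduces the dimensions, not the data.
#'
#' @param n_persons Number of examinees.
#' @param strand_sizes Items per content strand.
#' @param rho Common inter-attribute correlation. Real strand scores on such
#'   examinations are strongly related; 0.7 is used as the realistic default.
#' @param seed Seed.
#' @return A `generated_form` list (see [simulate_form()]).
#' @export
simulate_kmle_like <- function(n_persons = 3265L,
                               strand_sizes = c(45L, 45L, 45L, 25L, 154L, 20L, 20L, 6L),
                               rho = 0.7,
                               seed = 1L) {
  cond <- sim_condition(n_persons = n_persons, strand_sizes = strand_sizes,
                        rho = rho, n_forms = 1L, seed = seed)
  form <- simulate_form(cond, 1L)
  colnames(form$q) <- paste0("C", seq_along(strand_sizes))
  colnames(form$abilities) <- colnames(form$q)
  colnames(form$true_mastery) <- colnames(form$q)
  form
}
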