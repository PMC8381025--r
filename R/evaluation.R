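#' Classification accuracy against true mastery
#'
#' For each attribute, the 2x2 contingency table between true and observed
#' mastery and the proportion on its diagonal: the share of examinees whose
#' true and observed mastery states agree.
#'
#' @param true,observed Persons x attributes binary mastery matrices of the
#'   same dimensions.
#' @return List with `tables` (one 2x2 table per attribute) and `accuracy`
#'   (named numeric vector in [0, 1]).
#' @export
classification_accuracy <- function(true, observed) {
  true <- as.matrix(true); observed <- as.matrix(observed)
  if (!all(dim(true) == dim(observed))) {
    stop("true and observed mastery matrices must have equal dimensions",
         call. = FALSE)
  }
  n <- nrow(true)
  k <- ncol(true)
  labels <- colnames(true) %||% paste0("A", seq_len(k))
  tables <- vector("list", k)
  acc <- numeric(k)
  for (j in seq_len(k)) {
    tab <- table(factor(true[, j], levels = 0:1),
                 factor(observed[, j], levels = 0:1),
                 dnn = c("true", "observed"))
    tables[[j]] <- tab
    acc[j] <- (tab[1, 1] + tab[2, 2]) / n
  }
  names(tables) <- names(acc) <- labels
  list(tables = tables, accuracy = acc)
}

#' Classification consistency between two engines
#'
#' Per-attribute proportion of examinees classified identically by two
#' models. Symmetric in its arguments.
#'
#' @param m_a,m_b Persons x attributes binary mastery matrices.
#' @return Named numeric vector of exact-match proportions.
#' @export
classification_consistency <- function(m_a, m_b) {
  m_a <- as.matrix(m_a); m_b <- as.matrix(m_b)
  if (!all(dim(m_a) == dim(m_b))) {
    stop("mastery matrices must have equal dimensions", call. = FALSE)
  }
  out <- colMeans(m_a == m_b)
  names(out) <- colnames(m_a) %||% paste0("A", seq_len(ncol(m_a)))
  out
}

#' Per-attribute Pearson correlations between two score matrices
#'
#' @param s_a,s_b Persons x attributes numeric matrices.
#' @return Named numeric vector of correlations.
#' @export
score_correlations <- function(s_a, s_b) {
  s_a <- as.matrix(s_a); s_b <- as.matrix(s_b)
  if (!all(dim(s_a) == dim(s_b))) {
    stop("score matrices must have equal dimensions", call. = FALSE)
  }
  labels <- colnames(s_a) %||% paste0("A", seq_len(ncol(s_a)))
  va <- apply(s_a, 2, stats::var); vb <- apply(s_b, 2, stats::var)
  if (any(va == 0) || any(vb == 0)) {
    stop("zero-variance score column(s): ",
         paste(labels[va == 0 | vb == 0], collapse = ", "), call. = FALSE)
  }
  out <- vapply(seq_len(ncol(s_a)),
                function(j) stats::cor(s_a[, j], s_b[, j]), numeric(1))
  names(out) <- labels
  out
}

#' Classify one generated form with all three engines
#'
#' Runs the full classification battery on one form: CTT percent-correct
#' subscores with the strictly-above-half rule, a Rasch model fitted per
#' strand (MML items, MAP persons, master iff theta > 0), and a single DINA
#' model fitted jointly over all items (EM over the 2^K classes, MAP
#' profile). Returns the three mastery matrices and the three person-score
#' matrices.
#'
#' @param form A `generated_form` (or any list with `responses` and `q`).
#' @param ctt_cut CTT proportion-correct cut (strictly above; default 0.5).
#' @param theta_cut Rasch mastery cut in logits (strictly above; default 0).
#' @return List with `mastery` (list of persons x attributes matrices named
#'   ctt/rasch/dina), `scores` (ctt subscores, rasch MAP thetas, dina
#'   marginal mastery probabilities), and the underlying `fits`.
#' @export
classify_form <- function(form, ctt_cut = 0.5, theta_cut = 0) {
  x <- form$responses
  q <- validate_qmatrix(form$q, require_simple = TRUE)
  k <- ncol(q)
  strand_of <- item_attribute(q)
  labels <- colnames(q)

  sub <- ctt_subscores(x, q)
  ctt_m <- threshold_mastery(sub, cut = ctt_cut, strict = TRUE)

  theta <- matrix(NA_real_, nrow(x), k, dimnames = list(rownames(x), labels))
  rasch_fits <- vector("list", k)
  names(rasch_fits) <- labels
  for (a in seq_len(k)) {
    items <- which(strand_of == a)
    fit <- fit_rasch_mml(x[, items, drop = FALSE])
    theta[, a] <- map_theta(x[, items, drop = FALSE], fit$difficulties)
    rasch_fits[[a]] <- fit
  }
  rasch_m <- apply(theta, 2, rasch_mastery, cut = theta_cut)
  dimnames(rasch_m) <- dimnames(theta)

  dina_fit <- fit_dina_em(x, q)
  post <- dina_posteriors(x, dina_fit)
  dina_m <- post$map_profile

  list(mastery = list(ctt = ctt_m, rasch = rasch_m, dina = dina_m),
       scores = list(ctt = sub, rasch = theta,
                     dina = post$marginal_mastery),
       fits = list(rasch = rasch_fits, dina = dina_fit,
                   dina_posteriors = post))
}

#' Run one accuracy-study condition
#'
#' Replicates `n_forms` test forms under a condition, classifies each form
#' with the three engines, computes per-strand classification accuracy
#' against the simulated true mastery, and averages over forms. A form
#' whose fits fail is recorded in `failures`, never dropped silently.
#'
#' @param condition A [sim_condition()].
#' @param progress Print a dot per completed form.
#' @return An object of class `condition_result`: `condition`, `mean_accuracy`
#'   and `sd_accuracy` (model x strand matrices), `per_form` (long data
#'   frame: form, model, strand, strand_size, accuracy), `failures`.
#' @export
run_condition <- function(condition, progress = FALSE) {
  stopifnot(inherits(condition, "sim_condition"))
  models <- c("ctt", "rasch", "dina")
  k <- length(condition$strand_sizes)
  rows <- list()
  failures <- list()
  for (f in seq_len(condition$n_forms)) {
    res <- tryCatch({
      form <- simulate_form(condition, f)
      cls <- classify_form(form)
      lapply(models, function(m) {
        classification_accuracy(form$true_mastery, cls$mastery[[m]])$accuracy
      })
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures[[length(failures) + 1]] <-
        data.frame(form = f, message = conditionMessage(res))
      next
    }
    names(res) <- models
    for (m in models) {
      rows[[length(rows) + 1]] <- data.frame(
        form = f, model = m, strand = seq_len(k),
        strand_size = condition$strand_sizes,
        accuracy = unname(res[[m]]), stringsAsFactors = FALSE)
    }
    if (progress) cat(".")
  }
  if (progress) cat("\n")
  per_form <- do.call(rbind, rows)
  agg <- function(fun) {
    m <- matrix(NA_real_, length(models), k,
                dimnames = list(models, paste0(condition$strand_sizes, "items")))
    for (mo in models) for (st in seq_len(k)) {
      v <- per_form$accuracy[per_form$model == mo & per_form$strand == st]
      m[mo, st] <- fun(v)
    }
    m
  }
  structure(
    list(condition = condition,
         mean_accuracy = agg(mean),
         sd_accuracy = agg(stats::sd),
         per_form = per_form,
         failures = if (length(failures)) do.call(rbind, failures) else NULL),
    class = "condition_result")
}

#' @export
print.condition_result <- function(x, ...) {
  cat(sprintf("Accuracy over %d forms at rho = %.2f:\n",
              x$condition$n_forms, x$condition$rho))
  print(round(x$mean_accuracy, 3))
  if (!is.null(x$failures)) {
    cat(nrow(x$failures), "form(s) failed\n")
  }
  invisible(x)
}
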