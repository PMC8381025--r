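#' Run the full simulation accuracy study
#'
#' Sweeps the inter-attribute correlation grid, running [run_condition()]
#' once per rho, and optionally writes the results: a tidy long CSV
#' (condition, rho, strand size, model, mean accuracy, across-form SD,
#' number of forms), a wide pivot with one row per strand-size x model and
#' one column per rho (the accuracy-table layout), and a JSON run log
#' capturing the seed and every setting. Two runs with the same
#' configuration and seed produce byte-identical files.
#'
#' @param config A list (or path to a YAML file) with fields `rhos`,
#'   `strand_sizes`, `n_persons`, `n_forms`, `seed`, and optional
#'   `difficulty_low`/`difficulty_high`. Missing fields default to the study
#'   design: rhos 0/0.3/0.5/0.7/0.9, strands 5/10/15/20, 1,000 persons,
#'   50 forms, difficulties U(-3, 3).
#' @param out_dir Output directory (created if needed); `NULL` writes nothing.
#' @param progress Print progress dots.
#' @return List with `results` (one `condition_result` per rho), `long`
#'   (tidy data frame), `pivot` (wide data frame).
#' @export
run_simulation_study <- function(config = list(), out_dir = NULL,
                                 progress = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  defaults <- list(rhos = c(0, 0.3, 0.5, 0.7, 0.9),
                   strand_sizes = c(5L, 10L, 15L, 20L),
                   n_persons = 1000L, n_forms = 50L, seed = 1L,
                   difficulty_low = -3, difficulty_high = 3)
  cfg <- utils::modifyList(defaults, config)
  if (length(cfg$rhos) == 0) stop("empty rho grid", call. = FALSE)
  # validate the whole grid before any computation
  conds <- lapply(cfg$rhos, function(r) {
    sim_condition(n_persons = cfg$n_persons, strand_sizes = cfg$strand_sizes,
                  rho = r, difficulty_low = cfg$difficulty_low,
                  difficulty_high = cfg$difficulty_high,
                  n_forms = cfg$n_forms,
                  seed = form_seed(cfg$seed, match(r, cfg$rhos) * 1000L))
  })

  results <- lapply(conds, run_condition, progress = progress)
  names(results) <- paste0("rho", cfg$rhos)

  long <- do.call(rbind, lapply(seq_along(results), function(i) {
    r <- results[[i]]
    k <- length(cfg$strand_sizes)
    data.frame(condition = names(results)[i], rho = cfg$rhos[i],
               strand = rep(seq_len(k), each = 3),
               strand_size = rep(cfg$strand_sizes, each = 3),
               model = rep(rownames(r$mean_accuracy), k),
               mean_accuracy = as.vector(r$mean_accuracy),
               sd = as.vector(r$sd_accuracy),
               n_forms = cfg$n_forms, stringsAsFactors = FALSE)
  }))

  pivot <- stats::reshape(
    long[, c("strand", "strand_size", "model", "rho", "mean_accuracy")],
    idvar = c("strand", "strand_size", "model"), timevar = "rho",
    direction = "wide")
  names(pivot) <- sub("^mean_accuracy\\.", "rho_", names(pivot))
  pivot <- pivot[order(pivot$strand, pivot$model), ]
  rownames(pivot) <- NULL

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(long, file.path(out_dir, "accuracy_long.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(pivot, file.path(out_dir, "accuracy_table.csv"),
                     row.names = FALSE, quote = FALSE)
    fails <- do.call(rbind, lapply(results, function(r) r$failures))
    jsonlite::write_json(
      list(mode = "simulate", settings = cfg,
           n_failed_forms = if (is.null(fails)) 0L else nrow(fails),
           package_version = as.character(utils::packageVersion("dcmastery")),
           r_version = paste(R.version$major, R.version$minor, sep = ".")),
      file.path(out_dir, "run_log.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  list(results = results, long = long, pivot = pivot)
}

#' Analyse a response matrix with all three mastery engines
#'
#' The real-data pipeline: given a binary persons x items response matrix
#' and a simple-structure Q-matrix (as R matrices or paths to CSV files in
#' the package dialect), fits the per-strand Rasch models and the joint DINA
#' model, computes CTT subscores, and reports per-model deviances, item-fit
#' flags (outfit for Rasch, item RMSEA for DINA) counted per content domain,
#' pairwise mastery consistency (CTT-Rasch, CTT-DINA, Rasch-DINA) per
#' domain, and pairwise person-score correlations using the CTT proportion
#' correct, the Rasch MAP theta, and the DINA per-attribute marginal mastery
#' probability. No unidimensionality screening is performed; a note to that
#' effect goes in the run log.
#'
#' @param responses Matrix or CSV path.
#' @param qmatrix Matrix or CSV path.
#' @param ctt_cut CTT mastery cut (strictly above; default 0.5).
#' @param theta_cut Rasch mastery cut (strictly above; default 0).
#' @param out_dir Output directory for report CSVs, fit artifacts and the
#'   run log; `NULL` writes nothing.
#' @return An `analysis_report` list: `deviance`, `item_tables` (per model),
#'   `flag_counts`, `consistency`, `correlations` (all per domain),
#'   `mastery`, `scores`, `fits`.
#' @export
run_analysis <- function(responses, qmatrix, ctt_cut = 0.5, theta_cut = 0,
                         out_dir = NULL) {
  if (is.character(responses)) responses <- read_binary_matrix(responses)
  if (is.character(qmatrix)) qmatrix <- read_binary_matrix(qmatrix)
  x <- check_responses(responses)
  q <- validate_qmatrix(qmatrix, require_simple = TRUE)
  if (ncol(x) != nrow(q)) {
    stop("responses have ", ncol(x), " items but the Q-matrix has ",
         nrow(q), " rows", call. = FALSE)
  }
  domains <- colnames(q) %||% paste0("C", seq_len(ncol(q)))
  colnames(q) <- domains
  strand_of <- item_attribute(q)

  cls <- classify_form(list(responses = x, q = q),
                       ctt_cut = ctt_cut, theta_cut = theta_cut)

  rasch_dev <- sum(vapply(cls$fits$rasch, function(f) f$deviance, numeric(1)))
  dina_dev <- cls$fits$dina$deviance

  # item-fit tables
  outfit_tabs <- lapply(seq_along(domains), function(a) {
    items <- which(strand_of == a)
    fit <- cls$fits$rasch[[a]]
    tab <- rasch_outfit(x[, items, drop = FALSE],
                        cls$scores$rasch[, a], fit$difficulties)
    tab$domain <- domains[a]
    tab
  })
  outfit_tab <- do.call(rbind, outfit_tabs)
  rmsea_tab <- dina_item_rmsea(x, cls$fits$dina,
                               posteriors = cls$fits$dina_posteriors)
  rmsea_tab$domain <- domains[strand_of]

  flag_counts <- data.frame(
    domain = domains,
    n_items = as.vector(table(factor(strand_of, levels = seq_along(domains)))),
    rasch_flagged = vapply(domains, function(d)
      sum(outfit_tab$flagged[outfit_tab$domain == d], na.rm = TRUE), integer(1)),
    dina_flagged = vapply(domains, function(d)
      sum(rmsea_tab$flagged[rmsea_tab$domain == d]), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)

  m <- cls$mastery
  consistency <- data.frame(
    domain = domains,
    ctt_rasch = unname(classification_consistency(m$ctt, m$rasch)),
    ctt_dina = unname(classification_consistency(m$ctt, m$dina)),
    rasch_dina = unname(classification_consistency(m$rasch, m$dina)),
    stringsAsFactors = FALSE)

  s <- cls$scores
  correlations <- data.frame(
    domain = domains,
    ctt_rasch = unname(score_correlations(s$ctt, s$rasch)),
    ctt_dina = unname(score_correlations(s$ctt, s$dina)),
    rasch_dina = unname(score_correlations(s$rasch, s$dina)),
    stringsAsFactors = FALSE)

  report <- structure(
    list(deviance = c(rasch = rasch_dev, dina = dina_dev),
         item_tables = list(rasch = outfit_tab, dina = rmsea_tab),
         flag_counts = flag_counts,
         consistency = consistency,
         correlations = correlations,
         mastery = m, scores = s, fits = cls$fits,
         settings = list(ctt_cut = ctt_cut, theta_cut = theta_cut)),
    class = "analysis_report")

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(flag_counts, file.path(out_dir, "flag_counts.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(consistency, file.path(out_dir, "consistency.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(correlations, file.path(out_dir, "correlations.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(outfit_tab, file.path(out_dir, "rasch_items.csv"),
                     row.names = FALSE, quote = FALSE)
    write_dina_fit(cls$fits$dina, rmsea_table = rmsea_tab,
                   posteriors = cls$fits$dina_posteriors,
                   item_csv = file.path(out_dir, "dina_items.csv"),
                   person_csv = file.path(out_dir, "dina_persons.csv"))
    jsonlite::write_json(
      list(mode = "analyze",
           deviance = list(rasch = rasch_dev, dina = dina_dev),
           settings = report$settings,
           note = "no unidimensionality screening performed",
           package_version = as.character(utils::packageVersion("dcmastery")),
           r_version = paste(R.version$major, R.version$minor, sep = ".")),
      file.path(out_dir, "run_log.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Mastery analysis report\n")
  cat(sprintf("  deviance: Rasch %.1f (sum over strands), DINA %.1f\n",
              x$deviance["rasch"], x$deviance["dina"]))
  cat("  flagged items per domain:\n")
  print(x$flag_counts, row.names = FALSE)
  cat("  pairwise mastery consistency:\n")
  print(round_df(x$consistency, 3), row.names = FALSE)
  cat("  pairwise score correlations:\n")
  print(round_df(x$correlations, 3), row.names = FALSE)
  invisible(x)
}

round_df <- function(df, digits) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], round, digits = digits)
  df
}
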