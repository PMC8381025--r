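#' Classical-test-theory strand subscores
#'
#' The CTT subscore for examinee j on attribute k is the proportion correct
#' among the items whose Q-matrix row loads attribute k.
#'
#' @param responses Persons x items binary matrix.
#' @param q Simple-structure Q-matrix (items x attributes).
#' @return Persons x attributes matrix of proportions in [0, 1].
#' @export
ctt_subscores <- function(responses, q) {
  q <- validate_qmatrix(q, require_simple = TRUE)
  responses <- check_responses(responses)
  stopifnot(ncol(responses) == nrow(q))
  n_per_strand <- colSums(q)
  if (any(n_per_strand == 0)) {
    stop("attribute(s) ", paste(which(n_per_strand == 0), collapse = ", "),
         " have no items", call. = FALSE)
  }
  s <- responses %*% q
  s <- sweep(s, 2, n_per_strand, "/")
  dimnames(s) <- list(rownames(responses), colnames(q))
  s
}

#' Threshold a score matrix into mastery
#'
#' The percent-correct rule classifies an examinee as a master of a strand
#' when the strand score is strictly above the cut ("above 50%"): a score of
#' exactly the cut is non-mastery.
#'
#' @param scores Persons x attributes numeric matrix.
#' @param cut Mastery cut (default 0.5, i.e. above half correct).
#' @param strict Use strict inequality (default `TRUE`).
#' @return Binary mastery matrix of the same shape.
#' @export
threshold_mastery <- function(scores, cut = 0.5, strict = TRUE) {
  scores <- as.matrix(scores)
  m <- if (strict) (scores > cut) * 1L else (scores >= cut) * 1L
  dimnames(m) <- dimnames(scores)
  m
}

# shared response-matrix guard: binary, complete, integer storage
check_responses <- function(responses) {
  responses <- as.matrix(responses)
  if (anyNA(responses)) {
    bad <- which(is.na(responses), arr.ind = TRUE)[1, ]
    stop("missing response at row ", bad[1], ", column ", bad[2],
         "; complete data required", call. = FALSE)
  }
  ok <- matrix(responses %in% c(0, 1), nrow = nrow(responses))
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)[1, ]
    stop("non-binary response at row ", bad[1], ", column ", bad[2],
         call. = FALSE)
  }
  storage.mode(responses) <- "integer"
  responses
}
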