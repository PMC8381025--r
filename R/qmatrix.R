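#' Build a simple-structure Q-matrix from strand sizes
#'
#' Constructs the items-by-attributes incidence matrix for a test whose items
#' are grouped into content strands, each item measuring exactly one
#' attribute (simple structure). Items are ordered strand by strand, so
#' `strand_sizes = c(5, 10, 15, 20)` yields a 50 x 4 block matrix whose
#' first five rows load attribute 1, the next ten attribute 2, and so on.
#'
#' @param strand_sizes Integer vector of items per strand; all must be >= 1.
#' @param attribute_names Optional character vector of attribute labels;
#'   defaults to `"A1"`, `"A2"`, ...
#' @return An integer matrix with one row per item and one column per
#'   attribute, row names `"item1"`, ..., every row summing to exactly 1.
#' @examples
#' q <- build_simple_q(c(2, 3))
#' rowSums(q)
#' @export
build_simple_q <- function(strand_sizes, attribute_names = NULL) {
  if (length(strand_sizes) == 0) {
    stop("`strand_sizes` must contain at least one strand", call. = FALSE)
  }
  strand_sizes <- as.integer(strand_sizes)
  if (anyNA(strand_sizes) || any(strand_sizes < 1)) {
    stop("all strand sizes must be positive integers", call. = FALSE)
  }
  k <- length(strand_sizes)
  if (is.null(attribute_names)) attribute_names <- paste0("A", seq_len(k))
  stopifnot(length(attribute_names) == k)
  n_items <- sum(strand_sizes)
  q <- matrix(0L, nrow = n_items, ncol = k,
              dimnames = list(paste0("item", seq_len(n_items)), attribute_names))
  q[cbind(seq_len(n_items), rep(seq_len(k), strand_sizes))] <- 1L
  q
}

#' Validate a Q-matrix
#'
#' Checks that a Q-matrix is binary, has no empty item rows, and (optionally)
#' is simple structure. Used as the entry guard by every fitting routine.
#'
#' @param q Items-by-attributes matrix.
#' @param require_simple If `TRUE`, every row must sum to exactly 1.
#' @return The validated matrix, invisibly, in integer storage.
#' @export
validate_qmatrix <- function(q, require_simple = FALSE) {
  q <- as.matrix(q)
  if (!all(q %in% c(0, 1))) {
    stop("Q-matrix entries must be 0 or 1", call. = FALSE)
  }
  storage.mode(q) <- "integer"
  rs <- rowSums(q)
  if (any(rs == 0)) {
    stop("Q-matrix rows ", paste(which(rs == 0), collapse = ", "),
         " load no attribute", call. = FALSE)
  }
  if (require_simple && any(rs != 1)) {
    stop("Q-matrix is not simple structure: rows ",
         paste(which(rs != 1), collapse = ", "),
         " load more than one attribute", call. = FALSE)
  }
  invisible(q)
}

#' @rdname validate_qmatrix
#' @export
is_simple_structure <- function(q) {
  q <- as.matrix(q)
  all(q %in% c(0, 1)) && all(rowSums(q) == 1)
}

#' For a simple-structure Q-matrix, the attribute index of each item.
#' @param q Simple-structure Q-matrix.
#' @return Integer vector of length `nrow(q)`.
#' @export
item_attribute <- function(q) {
  q <- validate_qmatrix(q, require_simple = TRUE)
  max.col(q, ties.method = "first")
}

#' Read / write matrices in the package CSV dialect
#'
#' All tabular artifacts use one dialect: the first column holds row IDs,
#' the header holds column IDs, values are written without quoting.
#' `read_binary_matrix` additionally enforces strictly binary, complete
#' entries and reports the coordinates of any offending cell.
#'
#' @param path File path.
#' @param x Matrix to write.
#' @param id_name Name for the ID column in the header.
#' @return `read_*` return a matrix with dimnames; writers return `path`
#'   invisibly.
#' @export
read_binary_matrix <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  bad <- which(is.na(m) | !(m %in% c(0, 1)), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop("non-binary or missing cells at (row, column): ",
         paste(sprintf("(%s, %s)", rownames(m)[bad[, 1]],
                       colnames(m)[bad[, 2]]), collapse = "; "),
         call. = FALSE)
  }
  storage.mode(m) <- "integer"
  m
}

#' @rdname read_binary_matrix
#' @export
write_matrix_csv <- function(x, path, id_name = "id") {
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- seq_len(nrow(x))
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_name
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname read_binary_matrix
#' @export
read_matrix_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- as.character(df[[1]])
  m
}
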