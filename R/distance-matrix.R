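#' Labeled distance matrices
#'
#' A `dist_matrix` is a square, symmetric, nonnegative matrix with a zero
#' diagonal and unique labels. It is the shared currency of the beta-diversity,
#' cooccurrence, competition, and phylogenetic stages.
#'
#' @param values square numeric matrix (symmetric, zero diagonal, entries
#'   >= 0).
#' @param labels optional character labels; defaults to `rownames(values)`.
#' @param tol symmetry tolerance.
#' @return a `dist_matrix` (a validated matrix).
#' @export
dist_matrix <- function(values, labels = rownames(values), tol = 1e-8) {
  values <- as.matrix(values)
  if (nrow(values) != ncol(values))
    stop("distance matrix must be square", call. = FALSE)
  if (is.null(labels)) labels <- paste0("x", seq_len(nrow(values)))
  if (length(labels) != nrow(values) || anyDuplicated(labels))
    stop("labels must be unique and match the matrix dimension",
         call. = FALSE)
  if (any(values < -tol)) stop("negative distances", call. = FALSE)
  if (max(abs(values - t(values))) > tol)
    stop("matrix is not symmetric", call. = FALSE)
  if (any(abs(diag(values)) > tol))
    stop("nonzero diagonal", call. = FALSE)
  values <- (values + t(values)) / 2
  values[values < 0] <- 0
  diag(values) <- 0
  dimnames(values) <- list(labels, labels)
  structure(values, class = c("dist_matrix", "matrix", "array"))
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat(sprintf("dist_matrix: %d x %d, range [%.4g, %.4g]\n", nrow(x), ncol(x),
              min(x), max(x[upper.tri(x)])))
  invisible(x)
}

#' @rdname dist_matrix
#' @param x object to coerce (`matrix` or [stats::dist]).
#' @export
as_dist_matrix <- function(x, labels = NULL) {
  if (inherits(x, "dist_matrix")) return(x)
  if (inherits(x, "dist")) x <- as.matrix(x)
  dist_matrix(x, labels = if (is.null(labels)) rownames(x) else labels)
}

#' Extract the upper-triangle vector of a distance matrix
#' @param d a `dist_matrix` or square matrix.
#' @keywords internal
upper_vec <- function(d) d[upper.tri(d)]

#' Write / read a distance matrix as square labeled TSV
#' @param d a `dist_matrix`.
#' @param path file path.
#' @param digits significant digits written.
#' @export
write_dist_matrix <- function(d, path, digits = 6) {
  m <- signif(unclass(d), digits)
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dist_matrix
#' @export
read_dist_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  dist_matrix(m, tol = 1e-5)
}

#' Align several distance matrices to shared labels
#' @param ... `dist_matrix` objects.
#' @return a list of matrices restricted and reordered to the common labels.
#' @keywords internal
align_dist_matrices <- function(...) {
  ms <- list(...)
  common <- Reduce(intersect, lapply(ms, rownames))
  if (length(common) < 3)
    stop("fewer than 3 shared labels across matrices", call. = FALSE)
  lapply(ms, function(m) dist_matrix(unclass(m)[common, common]))
}
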