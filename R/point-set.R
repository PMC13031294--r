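#' Point set container
#'
#' A `point_set` bundles an n x d numeric matrix of feature coordinates with
#' an optional length-n integer label vector (ground-truth class or cluster
#' id). Row order is stable: every operation in the package that selects or
#' transforms points refers back to rows of the original matrix by 1-based
#' index.
#'
#' @param points Numeric matrix (n x d) of finite coordinates; a data frame
#'   or vector is coerced.
#' @param labels Optional integer-like vector of length n.
#' @return An object of class `point_set` with elements `points` and
#'   `labels` (`NULL` when absent).
#' @examples
#' ps <- point_set(matrix(rnorm(20), ncol = 2), labels = rep(1:2, each = 5))
#' ps
#' @export
point_set <- function(points, labels = NULL) {
  if (is.data.frame(points)) points <- as.matrix(points)
  if (!is.matrix(points)) points <- matrix(points, ncol = 1L)
  storage.mode(points) <- "double"
  if (nrow(points) < 1L || ncol(points) < 1L) {
    stop_invalid("`points` must have at least one row and one column")
  }
  if (!all(is.finite(points))) {
    stop_invalid("`points` must contain only finite values")
  }
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != nrow(points)) {
      stop_invalid("`labels` must have length nrow(points)")
    }
    if (anyNA(labels)) stop_invalid("`labels` must not contain NA")
  }
  structure(list(points = points, labels = labels), class = "point_set")
}

#' @export
print.point_set <- function(x, ...) {
  cat(sprintf("point_set: %d points in %d dimensions", nrow(x$points), ncol(x$points)))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat(sprintf("; %d labelled classes (%s)", length(tab),
                paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  }
  cat("\n")
  invisible(x)
}

#' @export
as.data.frame.point_set <- function(x, ...) {
  df <- as.data.frame(x$points)
  names(df) <- paste0("f", seq_len(ncol(x$points)))
  if (!is.null(x$labels)) df$label <- x$labels
  df
}

#' Number of points in a point set
#' @param x A `point_set`.
#' @return Integer point count.
#' @export
n_points <- function(x) {
  stopifnot(inherits(x, "point_set"))
  nrow(x$points)
}
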