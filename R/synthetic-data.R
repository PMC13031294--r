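# Seeded generators for the three benchmark geometries used throughout the
# package: interleaved half-moons (non-convex clusters), concentric rings
# (nested non-overlapping clusters) and partially overlapping isotropic
# Gaussian mixtures. Every generator returns ground-truth labels so cluster
# recovery can be scored with the adjusted Rand index.

# Split n into length(w) integer counts proportional to w, exactly summing
# to n (largest-remainder apportionment).
largest_remainder_counts <- function(n, w) {
  w <- w / sum(w)
  raw <- n * w
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(short)]
    counts[extra] <- counts[extra] + 1
  }
  as.integer(counts)
}

#' Two interleaved moons
#'
#' Generates `n` points split as evenly as possible between two interleaved
#' unit-radius half-circle arcs (the classic "two moons" benchmark for
#' non-convex cluster recovery), with isotropic Gaussian coordinate noise.
#' The first arc is the upper half of the unit circle; the second is a
#' reflected arc offset by (1, -0.5) so the two interleave.
#'
#' @param n Total number of points (>= 2).
#' @param noise_sd Standard deviation of the Gaussian noise added to each
#'   coordinate (>= 0; default 0.1).
#' @param seed Integer RNG seed.
#' @return A [point_set] with labels 1 (first arc) and 2 (second arc).
#' @examples
#' moons <- make_two_moons(200, noise_sd = 0.05, seed = 1)
#' plot(moons$points, col = moons$labels, asp = 1)
#' @export
make_two_moons <- function(n, noise_sd = 0.1, seed = 1L) {
  n <- check_count(n, "n", min = 2L)
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0) {
    stop_invalid("`noise_sd` must be a single non-negative number")
  }
  n1 <- n %/% 2L + n %% 2L
  n2 <- n - n1
  with_seed(seed, {
    t1 <- seq(0, pi, length.out = n1)
    t2 <- seq(0, pi, length.out = max(n2, 1L))[seq_len(n2)]
    pts <- rbind(
      cbind(cos(t1), sin(t1)),
      cbind(1 - cos(t2), 0.5 - sin(t2))
    )
    if (noise_sd > 0) {
      pts <- pts + matrix(stats::rnorm(length(pts), sd = noise_sd), ncol = 2L)
    }
    point_set(pts, labels = rep(c(1L, 2L), c(n1, n2)))
  })
}

#' Concentric rings
#'
#' Generates points on concentric circles centred at the origin, one class
#' per ring, with angles drawn uniformly and Gaussian noise applied to the
#' radius only. Points are apportioned evenly across rings.
#'
#' @param n Total number of points.
#' @param radii Numeric vector of >= 2 distinct positive radii
#'   (default `c(1, 3)`).
#' @param noise_sd Radial noise standard deviation (default 0.05). A warning
#'   is issued when the smallest radial gap is not comfortably larger than
#'   the noise scale (gap <= 4 * noise_sd), since rings may then overlap.
#' @param seed Integer RNG seed.
#' @return A [point_set] with labels 1..length(radii), ordered by `radii`.
#' @export
make_concentric_rings <- function(n, radii = c(1, 3), noise_sd = 0.05, seed = 1L) {
  n <- check_count(n, "n", min = 2L)
  radii <- as.numeric(radii)
  if (length(unique(radii)) < 2L || any(radii <= 0)) {
    stop_invalid("`radii` must contain at least 2 distinct positive radii")
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0) {
    stop_invalid("`noise_sd` must be a single non-negative number")
  }
  gap <- min(diff(sort(radii)))
  if (noise_sd > 0 && gap <= 4 * noise_sd) {
    warning(sprintf(
      "smallest radial gap (%.3g) is <= 4 * noise_sd (%.3g); rings may overlap radially",
      gap, 4 * noise_sd), call. = FALSE)
  }
  counts <- largest_remainder_counts(n, rep(1, length(radii)))
  with_seed(seed, {
    pts <- matrix(0, nrow = n, ncol = 2L)
    labels <- integer(n)
    at <- 0L
    for (i in seq_along(radii)) {
      ni <- counts[i]
      if (ni == 0L) next
      theta <- stats::runif(ni, 0, 2 * pi)
      r <- radii[i] + if (noise_sd > 0) stats::rnorm(ni, sd = noise_sd) else 0
      idx <- at + seq_len(ni)
      pts[idx, ] <- cbind(r * cos(theta), r * sin(theta))
      labels[idx] <- i
      at <- at + ni
    }
    point_set(pts, labels = labels)
  })
}

#' Isotropic Gaussian mixture
#'
#' Generates points from a mixture of isotropic Gaussian components
#' (covariance `sd_i^2 I`), labelled by component. Per-component sample
#' counts are the largest-remainder rounding of `n * weights`, so counts
#' always sum exactly to `n`. The default places three unit-sd components
#' at pairwise mean separation 5.5 sd: component tails overlap at the
#' point level (the hardest of the three benchmark geometries), while the
#' per-class centroid clouds produced by k-means compression remain
#' separated — the operating regime the hybrid algorithm is designed for.
#'
#' @param n Total number of points.
#' @param means Numeric matrix (one component mean per row) or list of
#'   equal-length numeric vectors.
#' @param sds Positive numeric vector, one per component (recycled if
#'   length 1).
#' @param weights Optional non-negative mixing weights summing to 1
#'   (default uniform).
#' @param seed Integer RNG seed.
#' @return A [point_set] with labels 1..k (component index).
#' @export
make_gaussian_mixture <- function(n,
                                  means = rbind(c(0, 0), c(5.5, 0), c(2.75, 4.763)),
                                  sds = 1,
                                  weights = NULL,
                                  seed = 1L) {
  n <- check_count(n, "n", min = 1L)
  if (is.list(means)) {
    lens <- lengths(means)
    if (length(unique(lens)) != 1L) stop_invalid("all `means` must have equal length")
    means <- do.call(rbind, means)
  }
  means <- as.matrix(means)
  k <- nrow(means)
  if (k < 1L) stop_invalid("at least one component mean required")
  sds <- as.numeric(sds)
  if (length(sds) == 1L) sds <- rep(sds, k)
  if (length(sds) != k) stop_invalid("`sds` must have one entry per component")
  if (any(!is.finite(sds)) || any(sds < 0)) stop_invalid("`sds` must be non-negative and finite")
  if (is.null(weights)) {
    weights <- rep(1 / k, k)
  } else {
    weights <- as.numeric(weights)
    if (length(weights) != k) stop_invalid("`weights` must have one entry per component")
    if (any(weights < 0) || abs(sum(weights) - 1) > 1e-8) {
      stop_invalid("`weights` must be non-negative and sum to 1")
    }
  }
  counts <- largest_remainder_counts(n, weights)
  d <- ncol(means)
  with_seed(seed, {
    pts <- matrix(0, nrow = n, ncol = d)
    labels <- integer(n)
    at <- 0L
    for (i in seq_len(k)) {
      ni <- counts[i]
      if (ni == 0L) next
      idx <- at + seq_len(ni)
      noise <- if (sds[i] > 0) matrix(stats::rnorm(ni * d, sd = sds[i]), ncol = d) else 0
      pts[idx, ] <- matrix(means[i, ], nrow = ni, ncol = d, byrow = TRUE) + noise
      labels[idx] <- i
      at <- at + ni
    }
    point_set(pts, labels = labels)
  })
}
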