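# Evaluation metrics as pure functions: classification accuracy from the
# confusion counts, the adjusted Rand index from the contingency table,
# and the efficiency ratios (data reduction, speedup, support-vector
# reduction, carbon-emission arithmetic).

#' Classification accuracy from confusion counts
#'
#' The fraction of correctly classified instances,
#' (TP + TN) / (TP + TN + FP + FN).
#'
#' @param tp,tn,fp,fn Non-negative counts; their sum must be >= 1.
#' @return Accuracy in \[0, 1\].
#' @export
accuracy <- function(tp, tn, fp, fn) {
  counts <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop_invalid("confusion counts must be non-negative")
  }
  total <- sum(counts)
  if (total < 1) stop_invalid("at least one instance is required (all counts zero)")
  (tp + tn) / total
}

#' Adjusted Rand index
#'
#' Chance-corrected agreement between two partitions of the same items,
#' computed from the contingency table: the pair-counting Rand index minus
#' its expectation under random labelling with fixed marginals, divided by
#' the maximum minus that expectation. Invariant to relabelling of either
#' argument and symmetric; 1 for identical partitions, about 0 for
#' unrelated ones, negative when agreement is below chance.
#'
#' Noise labels are treated as an ordinary extra cluster by default; with
#' `drop_noise = TRUE` rows where either vector equals `noise_label` are
#' removed first.
#'
#' @param a,b Label vectors of equal length >= 2 (any atomic type).
#' @param drop_noise Drop items labelled `noise_label` in either vector
#'   before computing (default `FALSE`).
#' @param noise_label The label regarded as noise (default 0, the
#'   package's DBSCAN convention).
#' @return ARI in \[-1, 1\].
#' @examples
#' adjusted_rand_index(c(1, 1, 2, 2), c(2, 2, 1, 1))  # 1
#' adjusted_rand_index(c(1, 1, 2, 2), c(1, 2, 1, 2))  # -0.5
#' @export
adjusted_rand_index <- function(a, b, drop_noise = FALSE, noise_label = 0L) {
  if (length(a) != length(b)) {
    stop_invalid("`a` and `b` must have equal length")
  }
  if (drop_noise) {
    keep <- a != noise_label & b != noise_label
    a <- a[keep]
    b <- b[keep]
  }
  n <- length(a)
  if (n < 2L) stop_invalid("at least 2 items are required")

  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  index <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  expected <- sum_a * sum_b / choose2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) {
    # both partitions trivial (all-one-cluster or all-singletons): identical
    return(1)
  }
  (index - expected) / (max_index - expected)
}

#' Data reduction ratio
#'
#' Fraction of retained data points after reduction, N' / N.
#'
#' @param n_reduced Retained count (1 <= n_reduced <= n_original).
#' @param n_original Original count (>= 1).
#' @return Ratio in (0, 1\].
#' @examples
#' reduction_ratio(100, 3000)  # 0.0333...
#' @export
reduction_ratio <- function(n_reduced, n_original) {
  if (!is.finite(n_original) || n_original < 1) {
    stop_invalid("`n_original` must be >= 1")
  }
  if (!is.finite(n_reduced) || n_reduced < 1 || n_reduced > n_original) {
    stop_invalid("`n_reduced` must satisfy 1 <= n_reduced <= n_original")
  }
  n_reduced / n_original
}

#' Training speedup factor
#'
#' Ratio of the execution time on the full data to the time after
#' reduction, T_original / T_reduced.
#'
#' @param t_original,t_reduced Positive times (seconds).
#' @return Speedup (> 0; > 1 means the reduced run is faster).
#' @export
speedup <- function(t_original, t_reduced) {
  if (!is.finite(t_original) || t_original <= 0 ||
      !is.finite(t_reduced) || t_reduced <= 0) {
    stop_invalid("times must be positive")
  }
  t_original / t_reduced
}

#' Support-vector reduction ratio
#'
#' Support vectors of the model trained on the reduced set divided by
#' those of the full-data model.
#'
#' @param svs_reduced,svs_full Positive support-vector counts.
#' @return Ratio (> 0).
#' @export
sv_reduction_ratio <- function(svs_reduced, svs_full) {
  if (!is.finite(svs_reduced) || svs_reduced < 1 ||
      !is.finite(svs_full) || svs_full < 1) {
    stop_invalid("support-vector counts must be >= 1")
  }
  svs_reduced / svs_full
}

#' Carbon emissions from energy use
#'
#' Grams of CO2-equivalent for a given energy consumption and regional
#' carbon intensity: energy (kWh) times intensity (gCO2/kWh). The energy
#' figure itself must come from an external meter; only the conversion is
#' performed here.
#'
#' @param energy_kwh Energy consumed, kWh (>= 0).
#' @param intensity_g_per_kwh Carbon intensity, gCO2/kWh (>= 0).
#' @return Emissions in grams CO2-eq.
#' @export
carbon_emissions <- function(energy_kwh, intensity_g_per_kwh) {
  if (!is.finite(energy_kwh) || energy_kwh < 0 ||
      !is.finite(intensity_g_per_kwh) || intensity_g_per_kwh < 0) {
    stop_invalid("energy and intensity must be non-negative")
  }
  energy_kwh * intensity_g_per_kwh
}
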