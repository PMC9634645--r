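# Moran's I under inverse-distance weights, permutation tests, Bonferroni
# screening, distance-binned correlograms and residual spatial checks.

#' Inverse-distance spatial weight matrix
#'
#' `w_ij = 1/d_ij` for `i != j` (distances floored at `d_floor` for
#' near-coincident plants), zero diagonal, then row-standardized by default
#' so each row sums to one.
#'
#' @param coords two-column matrix or data.frame of planar coordinates in
#'   meters (>= 3 points).
#' @param d_floor minimum distance (m) substituted for coincident points.
#' @param row_standardize divide each row by its sum (default `TRUE`).
#' @return n x n weight matrix.
#' @export
inverse_distance_weights <- function(coords, d_floor = 0.1,
                                     row_standardize = TRUE) {
  coords <- as.matrix(coords)
  if (nrow(coords) < 3) stop("need at least 3 points")
  d <- as.matrix(dist(coords))
  if (all(d[upper.tri(d)] == 0)) stop("all points are coincident")
  w <- 1 / pmax(d, d_floor)
  diag(w) <- 0
  if (row_standardize) {
    rs <- rowSums(w)
    w <- w / ifelse(rs > 0, rs, 1)
  }
  w
}

#' Sanity-check a spatial weight matrix
#'
#' Errors unless the matrix is square with a zero diagonal and non-negative
#' entries; used by the validation suite and available for fault injection.
#'
#' @param W candidate weight matrix.
#' @return `TRUE` invisibly if valid.
#' @export
check_weights <- function(W) {
  if (!is.matrix(W) || nrow(W) != ncol(W)) stop("weights must be square")
  if (any(diag(W) != 0)) stop("weight matrix has a non-zero diagonal")
  if (any(W < 0)) stop("negative spatial weight")
  invisible(TRUE)
}

#' Moran's I spatial autocorrelation statistic
#'
#' \deqn{I = \frac{n}{S_0} \frac{\sum_{ij} w_{ij} z_i z_j}{\sum_i z_i^2}}
#' with `z` the centered values and `S0` the sum of all weights. Positive
#' values indicate spatial clustering of similar values; the null
#' expectation is `-1/(n-1)`.
#'
#' @param values numeric vector (non-zero variance).
#' @param W weight matrix from [inverse_distance_weights()] (or any
#'   zero-diagonal non-negative matrix of matching dimension).
#' @return Moran's I (numeric scalar).
#' @export
morans_i <- function(values, W) {
  n <- length(values)
  if (nrow(W) != n) stop("values length must match weight matrix dimension")
  z <- values - mean(values)
  denom <- sum(z^2)
  if (denom == 0) stop("zero variance: Moran's I undefined")
  (n / sum(W)) * as.numeric(t(z) %*% W %*% z) / denom
}

#' Permutation test for Moran's I
#'
#' Randomizes values over locations `n_perm` times; for the one-sided
#' (clustering) alternative `p = (1 + #\{I_perm >= I_obs\})/(n_perm + 1)`,
#' so the minimum attainable p-value is `1/(n_perm + 1)`. The two-sided
#' alternative doubles the smaller tail (capped at 1).
#'
#' @inheritParams morans_i
#' @param n_perm number of permutations (default 999).
#' @param seed optional integer seed for reproducible permutations.
#' @param alternative `"greater"` (clustering, default) or `"two_sided"`.
#' @return object of class `moran_result`: `I`, `expected_I`, `p_perm`,
#'   `n_perm`, `alternative`.
#' @export
moran_permutation_test <- function(values, W, n_perm = 999, seed = NULL,
                                   alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  obs <- morans_i(values, W)
  n <- length(values)
  perm <- with_seed(seed, vapply(seq_len(n_perm), function(i) {
    morans_i(sample(values), W)
  }, numeric(1)))
  p_gr <- (1 + sum(perm >= obs)) / (n_perm + 1)
  p_le <- (1 + sum(perm <= obs)) / (n_perm + 1)
  p <- switch(alternative,
              greater = p_gr,
              two_sided = min(1, 2 * min(p_gr, p_le)))
  structure(list(I = obs, expected_I = -1 / (n - 1), p_perm = p,
                 n_perm = n_perm, alternative = alternative),
            class = "moran_result")
}

#' @export
print.moran_result <- function(x, ...) {
  cat(sprintf("Moran's I = %.4f (E[I] = %.4f), permutation p = %.4g (%d perms, %s)\n",
              x$I, x$expected_I, x$p_perm, x$n_perm, x$alternative))
  invisible(x)
}

#' Bonferroni-adjusted significance threshold
#'
#' @param alpha family-wise error rate.
#' @param m number of tests (>= 1).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (m < 1) stop("m must be >= 1")
  alpha / m
}

#' Distance-binned spatial correlogram with permutation envelope
#'
#' Moran-type autocorrelation per distance class (binary weights restricted
#' to pairs whose separation falls in the class, not row-standardized), with
#' a pointwise permutation envelope.
#'
#' @param values numeric vector (`n >= 10`).
#' @param coords planar coordinates, meters.
#' @param n_bins number of equal-width distance classes.
#' @param n_perm permutations for the envelope (default 199).
#' @param seed optional seed.
#' @param probs envelope quantiles (default 95% pointwise).
#' @return data.frame with `bin`, `d_lo`, `d_hi`, `n_pairs`, `I` (NA for an
#'   empty class), `lower`, `upper`.
#' @export
binned_correlogram <- function(values, coords, n_bins = 6, n_perm = 199,
                               seed = NULL, probs = c(0.025, 0.975)) {
  n <- length(values)
  if (n < 10) stop("need at least 10 points")
  d <- as.matrix(dist(as.matrix(coords)))
  breaks <- seq(0, max(d), length.out = n_bins + 1)
  breaks[1] <- -1e-9  # include the smallest positive distances
  Ws <- lapply(seq_len(n_bins), function(b) {
    w <- (d > breaks[b] & d <= breaks[b + 1]) * 1
    diag(w) <- 0
    w
  })
  n_pairs <- vapply(Ws, function(w) sum(w) / 2, numeric(1))
  stat <- function(v) vapply(seq_len(n_bins), function(b) {
    if (n_pairs[b] == 0) NA_real_ else morans_i(v, Ws[[b]])
  }, numeric(1))
  obs <- stat(values)
  perm <- with_seed(seed, t(vapply(seq_len(n_perm), function(i) {
    stat(sample(values))
  }, numeric(n_bins))))
  env <- apply(perm, 2, quantile, probs = probs, na.rm = TRUE)
  data.frame(bin = seq_len(n_bins),
             d_lo = pmax(breaks[-length(breaks)], 0), d_hi = breaks[-1],
             n_pairs = n_pairs, I = obs,
             lower = env[1, ], upper = env[2, ])
}

#' Spatial autocorrelation check on model residuals
#'
#' Two-sided Moran permutation test of residuals under inverse-distance
#' weights; used to verify the hurdle models' assumption that dye transfer
#' patterns are not driven by plant spatial arrangement.
#'
#' @param residuals numeric residual vector (e.g. randomized-quantile
#'   residuals from [hurdle_residuals()]).
#' @param coords planar coordinates of the corresponding observations.
#' @param n_perm,seed passed to [moran_permutation_test()].
#' @param d_floor passed to [inverse_distance_weights()].
#' @return `moran_result`.
#' @export
residual_spatial_check <- function(residuals, coords, n_perm = 999,
                                   seed = NULL, d_floor = 0.1) {
  W <- inverse_distance_weights(coords, d_floor = d_floor)
  moran_permutation_test(residuals, W, n_perm = n_perm, seed = seed,
                         alternative = "two_sided")
}
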