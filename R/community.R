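# Community-level comparisons between ecotypes: correlation-matrix PCA and
# PERMANOVA on seed-predator abundances, Mann-Whitney U tests on camera
# visitation, chi-square tests on germination and chlorosis.

community_counts <- function(comm) {
  taxa <- community_taxa(comm)
  m <- as.matrix(comm[, taxa, drop = FALSE])
  rownames(m) <- paste(comm$population_id, comm$year, sep = "_")
  m
}

#' Correlation-matrix PCA of a community abundance table
#'
#' Standardizes each taxon column to zero mean and unit variance and
#' eigendecomposes the correlation matrix (so rare and abundant taxa weigh
#' equally). Axis signs are normalized so that each axis's largest-loading
#' variable loads positively. Variable-axis associations are the Pearson
#' correlations between each raw abundance column and the axis scores.
#'
#' @param comm community table (see [validate_community()]) or a plain
#'   numeric matrix of abundances.
#' @return object of class `pca_result`: `eigenvalues`,
#'   `proportion_variance`, `scores`, `loadings`,
#'   `variable_axis_correlations` (signed; take `abs()` for magnitudes).
#' @export
pca_correlation <- function(comm) {
  m <- if (is.data.frame(comm) && "population_id" %in% names(comm))
    community_counts(validate_community(comm)) else as.matrix(comm)
  if (nrow(m) < 3) stop("need at least 3 rows")
  vars <- apply(m, 2, var)
  if (any(vars == 0))
    stop("zero-variance column: ", paste(colnames(m)[vars == 0], collapse = ", "))
  pc <- prcomp(m, center = TRUE, scale. = TRUE)
  # sign convention: largest-|loading| variable positive on each axis
  flip <- apply(pc$rotation, 2, function(v) sign(v[which.max(abs(v))]))
  flip[flip == 0] <- 1
  rot <- sweep(pc$rotation, 2, flip, "*")
  scores <- sweep(pc$x, 2, flip, "*")
  ev <- pc$sdev^2
  structure(list(
    eigenvalues = ev,
    proportion_variance = ev / sum(ev),
    scores = scores,
    loadings = rot,
    variable_axis_correlations = cor(m, scores)
  ), class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("Correlation-matrix PCA\n")
  pv <- round(100 * x$proportion_variance, 1)
  cat("  % variance per axis:", paste(pv, collapse = ", "), "\n")
  cat(sprintf("  PC1+PC2: %.1f%%\n", pv[1] + pv[2]))
  invisible(x)
}

#' Bray-Curtis dissimilarity between two count vectors
#'
#' \eqn{d = \sum_i |a_i - b_i| / \sum_i (a_i + b_i)}, in `[0, 1]`.
#'
#' @param a,b non-negative numeric vectors of equal length, not both
#'   all-zero.
#' @return dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  if (any(a < 0) || any(b < 0)) stop("counts must be non-negative")
  tot <- sum(a + b)
  if (tot == 0) stop("both vectors are all-zero: Bray-Curtis undefined")
  sum(abs(a - b)) / tot
}

#' PERMANOVA on a community abundance table
#'
#' Permutational multivariate ANOVA on pairwise Bray-Curtis (default) or
#' Euclidean distances, with sequential (Type-I) partitioning of the terms
#' in the order given and p-values from row permutations. The partitioning
#' is delegated to [vegan::adonis2()].
#'
#' @param comm community table with `ecotype` and `year` metadata columns
#'   (or a plain matrix, in which case `factors` must be supplied).
#' @param factors character vector of term names, fitted sequentially in
#'   this order (default `c("ecotype", "year")`), or a data.frame of
#'   factors when `comm` is a plain matrix.
#' @param distance `"bray"` (default) or `"euclidean"`.
#' @param n_perm number of permutations (default 999).
#' @param seed optional seed for reproducible permutations.
#' @return object of class `permanova_result`: data.frame `table` with per-
#'   term `df`, `sum_of_squares`, `pseudo_F`, `p_perm`, plus residual and
#'   total rows; attributes `n_perm`, `distance`.
#' @export
permanova <- function(comm, factors = c("ecotype", "year"),
                      distance = c("bray", "euclidean"),
                      n_perm = 999, seed = NULL) {
  distance <- match.arg(distance)
  if (is.data.frame(factors)) {
    meta <- factors
    m <- as.matrix(comm)
  } else {
    comm <- validate_community(comm)
    meta <- comm[, factors, drop = FALSE]
    m <- community_counts(comm)
  }
  meta[] <- lapply(meta, factor)
  if (any(vapply(meta, nlevels, 0L) < 2))
    stop("each factor needs at least 2 levels")
  if (distance == "bray" && any(rowSums(m) == 0))
    stop("all-zero row: Bray-Curtis undefined")
  f <- reformulate(names(meta), response = quote(m))
  fit <- with_seed(seed,
    vegan::adonis2(f, data = meta, method = distance,
                   permutations = n_perm, by = "terms"))
  tab <- data.frame(
    term = rownames(fit),
    df = fit$Df,
    sum_of_squares = fit$SumOfSqs,
    pseudo_F = fit$F,
    p_perm = fit$`Pr(>F)`,
    stringsAsFactors = FALSE
  )
  rownames(tab) <- NULL
  structure(list(table = tab, n_perm = n_perm, distance = distance),
            class = "permanova_result")
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("PERMANOVA (%s distance, %d permutations, sequential SS)\n",
              x$distance, x$n_perm))
  print(format(x$table, digits = 4), row.names = FALSE)
  invisible(x)
}

#' Mann-Whitney U test (tie-corrected normal approximation)
#'
#' Midranks the pooled sample; `U_first = R_first - n1(n1+1)/2` for the
#' group given first, `U_other = n1 n2 - U_first`. The two-sided p-value
#' uses the tie-corrected normal approximation with continuity correction
#' (the convention of the standard R implementation).
#'
#' @param first,second numeric vectors (the statistic is reported for
#'   `first`).
#' @param correct apply the continuity correction (default `TRUE`).
#' @return object of class `u_test`: `U_first`, `U_other`, `p_two_sided`,
#'   `n1`, `n2`.
#' @export
mann_whitney_u <- function(first, second, correct = TRUE) {
  n1 <- length(first); n2 <- length(second)
  if (n1 < 1 || n2 < 1) stop("both groups need at least one observation")
  pooled <- c(first, second)
  rk <- rank(pooled)
  U1 <- sum(rk[seq_len(n1)]) - n1 * (n1 + 1) / 2
  U2 <- n1 * n2 - U1
  N <- n1 + n2
  ties <- table(pooled)
  sigma2 <- (n1 * n2 / 12) * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  p <- if (sigma2 == 0) 1 else {
    z <- U1 - n1 * n2 / 2
    if (correct) z <- sign(z) * max(abs(z) - 0.5, 0)
    2 * pnorm(-abs(z) / sqrt(sigma2))
  }
  structure(list(U_first = U1, U_other = U2, p_two_sided = min(p, 1),
                 n1 = n1, n2 = n2),
            class = "u_test")
}

#' @export
print.u_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %.1f (complement %.1f; n1 = %d, n2 = %d), two-sided p = %.4g\n",
              x$U_first, x$U_other, x$n1, x$n2, x$p_two_sided))
  invisible(x)
}

#' Chi-square comparison of two proportions
#'
#' Pearson chi-square on the 2x2 success/failure table, df = 1, without
#' Yates continuity correction by default.
#'
#' @param successes length-2 integer vector of successes per group.
#' @param totals length-2 integer vector of group totals (> 0).
#' @param correct apply Yates continuity correction (default `FALSE`).
#' @return object of class `chisq_result`: `statistic`, `df`, `p_value`.
#' @export
chisq_two_proportions <- function(successes, totals, correct = FALSE) {
  if (length(successes) != 2 || length(totals) != 2)
    stop("supply successes and totals for exactly two groups")
  if (any(totals <= 0)) stop("totals must be > 0")
  tab <- rbind(successes, totals - successes)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected == 0)) stop("expected cell count of zero")
  res <- suppressWarnings(chisq.test(tab, correct = correct))
  structure(list(statistic = unname(res$statistic), df = unname(res$parameter),
                 p_value = res$p.value),
            class = "chisq_result")
}

#' @export
print.chisq_result <- function(x, ...) {
  cat(sprintf("Chi-square = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Ecotype comparison of camera-derived visitation
#'
#' Runs the four standard Mann-Whitney comparisons between ecotypes on a
#' camera table: recording duration, flowers filmed, moths observed per
#' hour, and flowers visited per hour. The statistic is reported for the
#' silicicolous (`Si`) group.
#'
#' @param cam validated camera table.
#' @return data.frame with one row per comparison: `variable`, `U_si`,
#'   `p_two_sided`.
#' @export
compare_visitation <- function(cam) {
  cam <- validate_camera(cam)
  si <- cam[cam$ecotype == "Si", ]
  ca <- cam[cam$ecotype == "Ca", ]
  vars <- c(duration_h = "duration_h", n_flowers_filmed = "n_flowers_filmed",
            moths_per_h = "moths_per_h", visits_per_h = "visits_per_h")
  rows <- lapply(names(vars), function(v) {
    u <- mann_whitney_u(si[[vars[[v]]]], ca[[vars[[v]]]])
    data.frame(variable = v, U_si = u$U_first, p_two_sided = u$p_two_sided,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Ecotype comparison of germination and chlorosis
#'
#' Pools populations within ecotype and runs two chi-square tests: the
#' germinated fraction of plated seeds, and the (fully or partially)
#' chlorotic fraction of germinated seedlings — chlorosis being the
#' diagnostic of inter-ecotype hybrid seedlings.
#'
#' @param germ validated germination table.
#' @param correct passed to [chisq_two_proportions()].
#' @return data.frame with rows `germination` and `chlorosis`.
#' @export
compare_germination <- function(germ, correct = FALSE) {
  germ <- validate_germination(germ)
  agg <- aggregate(germ[, c("n_seeds_plated", "n_germinated", "n_chlorotic",
                            "n_partially_chlorotic")],
                   by = list(ecotype = germ$ecotype), FUN = sum)
  agg <- agg[match(c("Ca", "Si"), agg$ecotype), ]
  g <- chisq_two_proportions(agg$n_germinated, agg$n_seeds_plated, correct)
  chl <- agg$n_chlorotic + agg$n_partially_chlorotic
  c2 <- chisq_two_proportions(chl, agg$n_germinated, correct)
  data.frame(test = c("germination", "chlorosis"),
             statistic = c(g$statistic, c2$statistic),
             df = c(g$df, c2$df),
             p_value = c(g$p_value, c2$p_value),
             stringsAsFactors = FALSE)
}
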