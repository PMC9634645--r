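# Hurdle count regression by maximum likelihood: a logit model for crossing
# the hurdle (any dye at all) and a zero-truncated Poisson or
# negative-binomial model for the positive counts, with an offset for
# sampling effort. The two components share no parameters, so the joint
# likelihood separates and each part is maximized on its own.

log1pexp <- function(x) ifelse(x > 30, x, log1p(exp(x)))

build_design <- function(terms, data) {
  f <- if (length(terms)) reformulate(terms) else ~1
  model.matrix(f, data = data)
}

# Standardize continuous (non-dummy) columns for optimizer stability and
# return the affine map A with b_original = A %*% b_scaled (and
# V_original = A V A').
standardize_design <- function(X) {
  p <- ncol(X)
  A <- diag(p)
  Xs <- X
  icpt <- match("(Intercept)", colnames(X))
  for (j in seq_len(p)) {
    if (!is.na(icpt) && j == icpt) next
    v <- X[, j]
    if (length(unique(v)) <= 2) next
    m <- mean(v); s <- sd(v)
    if (!is.finite(s) || s == 0) next
    Xs[, j] <- (v - m) / s
    A[j, j] <- 1 / s
    if (!is.na(icpt)) A[icpt, j] <- -m / s
  }
  list(X = Xs, A = A)
}

nll_zero <- function(g, X, ind) {
  eta <- drop(X %*% g)
  -(sum(eta[ind]) - sum(log1pexp(eta)))
}

grad_zero <- function(g, X, ind) {
  p <- plogis(drop(X %*% g))
  -drop(t(X) %*% (ind - p))
}

# log P(Y = 0) under the untruncated count distribution
log_p0 <- function(mu, family, size) {
  if (family == "poisson") -mu else size * (log(size) - log(size + mu))
}

nll_count <- function(par, X, y, off, family) {
  k <- ncol(X)
  b <- par[seq_len(k)]
  mu <- exp(drop(X %*% b) + off)
  if (family == "poisson") {
    ll <- dpois(y, mu, log = TRUE) - log1p(-exp(pmin(-mu, -1e-12)))
  } else {
    size <- exp(par[k + 1])
    lp0 <- log_p0(mu, "negbin", size)
    ll <- dnbinom(y, size = size, mu = mu, log = TRUE) -
      log1p(-exp(pmin(lp0, -1e-12)))
  }
  if (!all(is.finite(ll))) return(1e10)
  -sum(ll)
}

optim_restarts <- function(par0, fn, gr = NULL, seed = NULL, n_restart = 3, ...) {
  try_one <- function(p0) {
    tryCatch(optim(p0, fn, gr = gr, method = "BFGS",
                   control = list(maxit = 1000, reltol = 1e-12),
                   hessian = TRUE, ...),
             error = function(e) NULL)
  }
  res <- try_one(par0)
  jitters <- with_seed(seed, lapply(seq_len(n_restart), function(i) {
    par0 + rnorm(length(par0), sd = 0.5)
  }))
  for (p0 in jitters) {
    if (!is.null(res) && res$convergence == 0) break
    cand <- try_one(p0)
    if (!is.null(cand) &&
        (is.null(res) || cand$value < res$value)) res <- cand
  }
  res
}

safe_vcov <- function(hess) {
  v <- tryCatch(solve(hess), error = function(e) NULL)
  if (is.null(v) || any(!is.finite(diag(v))) || any(diag(v) < 0)) return(NULL)
  v
}

#' Fit a hurdle count regression by maximum likelihood
#'
#' Maximizes \deqn{\sum_{y_i=0} \log(1-p_i) + \sum_{y_i>0}\left[\log p_i +
#' \log f_{trunc}(y_i;\mu_i,k)\right]} where `logit(p_i)` is the zero-part
#' linear predictor, `log(mu_i)` the count-part linear predictor plus the
#' offset, and `f_trunc` the zero-truncated Poisson or negative-binomial
#' mass. Standard errors come from the observed information; continuous
#' predictors are standardized internally and coefficients reported on the
#' original scale.
#'
#' @param data data.frame of observations (e.g. a transfer table).
#' @param zero_terms,count_terms character vectors of model terms for the
#'   two components (interactions as `"a:b"`); an intercept is always
#'   included.
#' @param response name of the count response column (default `sum_count`).
#' @param offset optional column name; its log enters the count component
#'   only (the zero component models presence/absence per individual).
#' @param family `"negbin"` (default; dye counts are overdispersed) or
#'   `"poisson"`.
#' @param seed optional seed for the jittered optimizer restarts.
#' @return object of class `hurdle_fit` with elements `coefficients` (tidy
#'   data.frame: component, term, estimate, se, z, p), `zero_coefs`,
#'   `count_coefs`, `loglik`, `loglik_zero`, `loglik_count`, `family`,
#'   `nb_size`, `converged`, `message`, `n_obs`, and fitted internals used
#'   by [hurdle_residuals()] and [likelihood_ratio_test()].
#' @export
fit_hurdle <- function(data, zero_terms, count_terms,
                       response = "sum_count", offset = NULL,
                       family = c("negbin", "poisson"), seed = NULL) {
  family <- match.arg(family)
  y <- round(as.numeric(data[[response]]))
  off <- if (is.null(offset)) rep(0, length(y)) else log(as.numeric(data[[offset]]))
  X0 <- build_design(zero_terms, data)
  X1 <- build_design(count_terms, data)
  ok <- complete.cases(y, off, X0, X1)
  y <- y[ok]; off <- off[ok]
  X0 <- X0[ok, , drop = FALSE]; X1 <- X1[ok, , drop = FALSE]
  n <- length(y)
  if (n < 10) warning("fewer than 10 observations; hurdle fit will be unstable")
  if (all(y == 0)) stop("response is all zeros: nothing to model")
  if (all(y > 0)) stop("no zeros: hurdle unidentified")
  ind <- y > 0

  msg <- character(0)

  # --- zero component: Bernoulli/logit ML ---
  s0 <- standardize_design(X0)
  g0 <- rep(0, ncol(X0))
  icpt <- match("(Intercept)", colnames(X0))
  if (!is.na(icpt)) g0[icpt] <- qlogis(mean(ind))
  rz <- optim_restarts(g0, nll_zero, gr = grad_zero, seed = seed,
                       X = s0$X, ind = ind)
  conv_zero <- !is.null(rz) && rz$convergence == 0
  if (is.null(rz)) stop("zero-component optimization failed")
  if (max(abs(rz$par)) > 15) {
    conv_zero <- FALSE
    msg <- c(msg, "possible complete separation in the zero component")
  }
  zero_b <- drop(s0$A %*% rz$par)
  Vz <- safe_vcov(rz$hessian)
  zero_se <- if (is.null(Vz)) rep(NA_real_, length(zero_b)) else
    sqrt(diag(s0$A %*% Vz %*% t(s0$A)))
  names(zero_b) <- names(zero_se) <- colnames(X0)
  ll_zero <- -rz$value

  # --- count component: zero-truncated Poisson/NB ML on positives ---
  yp <- y[ind]; Xp <- X1[ind, , drop = FALSE]; op <- off[ind]
  s1 <- standardize_design(Xp)
  k1 <- ncol(Xp)
  b0 <- rep(0, k1)
  icpt1 <- match("(Intercept)", colnames(Xp))
  if (!is.na(icpt1)) b0[icpt1] <- log(mean(yp)) - mean(op)
  if (family == "negbin") {
    m <- mean(yp); v <- var(yp)
    size0 <- if (is.finite(v) && v > m) m^2 / (v - m) else 1
    b0 <- c(b0, log(min(max(size0, 0.05), 50)))
  }
  rc <- optim_restarts(b0, nll_count, seed = if (is.null(seed)) NULL else seed + 1,
                       X = s1$X, y = yp, off = op, family = family)
  if (is.null(rc)) stop("count-component optimization failed")
  conv_count <- rc$convergence == 0
  count_bs <- rc$par[seq_len(k1)]
  count_b <- drop(s1$A %*% count_bs)
  Vc <- safe_vcov(rc$hessian)
  nb_size <- NA_real_; nb_size_se <- NA_real_
  if (family == "negbin") {
    nb_size <- exp(rc$par[k1 + 1])
    if (!is.null(Vc)) nb_size_se <- nb_size * sqrt(Vc[k1 + 1, k1 + 1])
  }
  count_se <- if (is.null(Vc)) rep(NA_real_, k1) else
    sqrt(diag(s1$A %*% Vc[seq_len(k1), seq_len(k1), drop = FALSE] %*% t(s1$A)))
  names(count_b) <- names(count_se) <- colnames(Xp)
  ll_count <- -rc$value

  coefs <- rbind(
    data.frame(component = "zero", term = names(zero_b), estimate = zero_b,
               se = zero_se, stringsAsFactors = FALSE),
    data.frame(component = "count", term = names(count_b), estimate = count_b,
               se = count_se, stringsAsFactors = FALSE))
  coefs$z <- coefs$estimate / coefs$se
  coefs$p <- 2 * pnorm(-abs(coefs$z))
  rownames(coefs) <- NULL

  fitted_p <- plogis(drop(X0 %*% zero_b))
  fitted_mu <- exp(drop(X1 %*% count_b) + off)

  structure(list(
    coefficients = coefs,
    zero_coefs = zero_b, zero_se = zero_se,
    count_coefs = count_b, count_se = count_se,
    loglik = ll_zero + ll_count,
    loglik_zero = ll_zero, loglik_count = ll_count,
    family = family, nb_size = nb_size, nb_size_se = nb_size_se,
    converged = conv_zero && conv_count,
    message = paste(msg, collapse = "; "),
    n_obs = n, y = y, offset = off,
    fitted_p = fitted_p, fitted_mu = fitted_mu,
    zero_terms = zero_terms, count_terms = count_terms,
    obs_index = which(ok)
  ), class = "hurdle_fit")
}

#' @export
print.hurdle_fit <- function(x, ...) {
  cat(sprintf("Hurdle model (%s counts), n = %d, logLik = %.3f%s\n",
              x$family, x$n_obs, x$loglik,
              if (!x$converged) " [NOT CONVERGED]" else ""))
  if (nzchar(x$message)) cat("  note: ", x$message, "\n", sep = "")
  if (x$family == "negbin")
    cat(sprintf("  NB size (dispersion) = %.3f\n", x$nb_size))
  print(format(x$coefficients, digits = 4), row.names = FALSE)
  invisible(x)
}

#' @export
logLik.hurdle_fit <- function(object, ...) {
  p <- nrow(object$coefficients) + (object$family == "negbin")
  structure(object$loglik, df = p, nobs = object$n_obs, class = "logLik")
}

#' Likelihood-ratio test between nested hurdle fits
#'
#' @param full,reduced `hurdle_fit` objects on the same data, with the
#'   reduced model's terms a subset of the full model's in each component.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
likelihood_ratio_test <- function(full, reduced) {
  if (full$n_obs != reduced$n_obs || !identical(full$y, reduced$y))
    stop("models were not fitted to the same data")
  if (full$family != reduced$family) stop("models use different count families")
  nested <- all(names(reduced$zero_coefs) %in% names(full$zero_coefs)) &&
    all(names(reduced$count_coefs) %in% names(full$count_coefs))
  if (!nested) stop("models are not nested")
  df <- (length(full$zero_coefs) + length(full$count_coefs)) -
    (length(reduced$zero_coefs) + length(reduced$count_coefs))
  if (df <= 0) df <- max(df, 0L)
  stat <- 2 * (full$loglik - reduced$loglik)
  if (stat < 0 && stat > -1e-6) stat <- 0
  if (stat < 0) stop("negative LR statistic: full fit did not converge")
  p <- if (df == 0) 1 else pchisq(stat, df, lower.tail = FALSE)
  list(statistic = stat, df = df, p_value = p)
}

#' Randomized-quantile residuals of a hurdle fit
#'
#' Uniformizes each observation through the fitted hurdle CDF with a random
#' draw between the CDF just below and at the observed count, then maps to
#' the normal scale. Correct specification yields iid standard-normal
#' residuals, suitable for the spatial check in
#' [residual_spatial_check()].
#'
#' @param fit `hurdle_fit`.
#' @param seed optional seed for the uniform jitter.
#' @return numeric vector of residuals, one per observation.
#' @export
hurdle_residuals <- function(fit, seed = NULL) {
  p <- fit$fitted_p
  mu <- fit$fitted_mu
  y <- fit$y
  cdf_count <- function(q) {
    if (fit$family == "poisson") ppois(q, mu) else
      pnbinom(q, size = fit$nb_size, mu = mu)
  }
  p0 <- exp(log_p0(mu, fit$family, fit$nb_size))
  # truncated count CDF at y (vectorized); F_hurdle(y) for y >= 0
  Fh <- function(q) {
    ft <- pmax((cdf_count(q) - p0) / (1 - p0), 0)
    ifelse(q < 0, 0, (1 - p) + p * ft)
  }
  lo <- Fh(y - 1)
  hi <- Fh(y)
  lo[y == 0] <- 0
  u <- with_seed(seed, runif(length(y), lo, hi))
  qnorm(pmin(pmax(u, 1e-12), 1 - 1e-12))
}

#' @importFrom stats ppois pnbinom
NULL

#' Run one of the three dye-transfer hurdle analyses
#'
#' The three standard contrasts on a transfer table: (1)
#' `"intrapop_differences"` — do within-population transfer patterns differ
#' among populations (population as the nominal predictor); (2)
#' `"intra_vs_inter_ecotypic"` — do interpopulation transfers differ between
#' populations of the same versus different ecotypes; (3)
#' `"directionality"` — restricted to inter-ecotypic records, is there a
#' preferred direction of flow (Ca to Si versus Si to Ca). All models use
#' distance to dye source, estimated total flowers, the nominal factor and
#' its interaction with distance in both components, with log sampled
#' flowers as the count-component offset.
#'
#' @param transfers transfer table from [build_transfer_table()].
#' @param which one of `"intrapop_differences"`,
#'   `"intra_vs_inter_ecotypic"`, `"directionality"`.
#' @param family count family, `"negbin"` or `"poisson"`.
#' @param exclude optional character vector of `recipient_id`s to drop
#'   before fitting (explicit outlier list; never automatic).
#' @param coords optional data.frame (`recipient_id`, `x`, `y`) enabling the
#'   residual spatial autocorrelation check.
#' @param n_perm,seed control the residual permutation test and optimizer
#'   restarts.
#' @return list with `fit` (`hurdle_fit`), `coefficients` (tidy table),
#'   `n_excluded`, and `residual_moran` (`moran_result` or `NULL`).
#' @export
run_transfer_analyses <- function(transfers,
                                  which = c("intrapop_differences",
                                            "intra_vs_inter_ecotypic",
                                            "directionality"),
                                  family = c("negbin", "poisson"),
                                  exclude = NULL, coords = NULL,
                                  n_perm = 999, seed = NULL) {
  which <- match.arg(which)
  family <- match.arg(family)
  d <- switch(which,
    intrapop_differences = {
      d <- transfers[transfers$transfer_class == "intrapopulation", ]
      d$type <- factor(d$recipient_population)
      d
    },
    intra_vs_inter_ecotypic = {
      d <- transfers[transfers$transfer_class %in%
                       c("intra_ecotypic", "inter_ecotypic"), ]
      d$type <- factor(d$transfer_class,
                       levels = c("intra_ecotypic", "inter_ecotypic"))
      d
    },
    directionality = {
      d <- transfers[transfers$transfer_class == "inter_ecotypic", ]
      if (nrow(d) == 0)
        stop("directionality analysis requires inter-ecotypic transfers")
      d$type <- factor(d$direction)
      d
    })
  n_before <- nrow(d)
  if (!is.null(exclude)) d <- d[!d$recipient_id %in% exclude, ]
  n_excluded <- n_before - nrow(d)
  if (which == "directionality" && nrow(d) == 0)
    stop("directionality analysis requires inter-ecotypic transfers")

  terms <- c("r", "total_flowers_est", "type", "r:type")
  if (nlevels(droplevels(d$type)) < 2) terms <- c("r", "total_flowers_est")
  fit <- fit_hurdle(d, zero_terms = terms, count_terms = terms,
                    offset = "n_flowers_sampled", family = family,
                    seed = seed)
  moran <- NULL
  if (!is.null(coords)) {
    used <- d[fit$obs_index, ]
    xy <- coords[match(used$recipient_id, coords$recipient_id), c("x", "y")]
    res <- hurdle_residuals(fit, seed = seed)
    moran <- residual_spatial_check(res, xy, n_perm = n_perm, seed = seed)
  }
  list(fit = fit, coefficients = fit$coefficients,
       n_excluded = n_excluded, residual_moran = moran)
}
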