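test_that("zero component equals an independent logistic-regression oracle", {
  d <- simulate_hurdle_data(400, seed = 31)
  fit <- fit_hurdle(d, zero_terms = c("r", "type"),
                    count_terms = "r", offset = "n_flowers_sampled")
  oracle <- glm(I(sum_count > 0) ~ r + type, data = d, family = binomial)
  expect_equal(unname(fit$zero_coefs), unname(coef(oracle)), tolerance = 1e-4)
  expect_equal(unname(fit$zero_se),
               unname(sqrt(diag(vcov(oracle)))), tolerance = 1e-3)
  expect_equal(fit$loglik_zero, as.numeric(logLik(oracle)), tolerance = 1e-8)
})

test_that("hurdle log-likelihood separates into its two parts", {
  d <- simulate_hurdle_data(200, seed = 32)
  fit <- fit_hurdle(d, "r", "r", offset = "n_flowers_sampled")
  expect_equal(fit$loglik, fit$loglik_zero + fit$loglik_count)
  expect_true(is.finite(fit$loglik))
  expect_true(fit$converged)
  # single-replicate recovery sanity at the generating coefficients
  expect_lt(abs(fit$count_coefs[["r"]] - (-0.005)),
            3 * fit$count_se[["r"]])
})

test_that("degenerate responses are rejected", {
  d <- simulate_hurdle_data(50, seed = 33)
  d0 <- d; d0$sum_count <- 0
  expect_error(fit_hurdle(d0, "r", "r"), "all zeros")
  d1 <- d; d1$sum_count <- d1$sum_count + 1
  expect_error(fit_hurdle(d1, "r", "r"), "no zeros")
})

test_that("Poisson fit is the large-dispersion limit of the NB fit", {
  d <- simulate_hurdle_data(500, family = "poisson", seed = 34)
  fp <- fit_hurdle(d, "r", "r", offset = "n_flowers_sampled",
                   family = "poisson")
  fn <- fit_hurdle(d, "r", "r", offset = "n_flowers_sampled",
                   family = "negbin")
  # equidispersed data drives the NB size large and the coefficients together
  expect_gt(fn$nb_size, 20)
  expect_equal(unname(fp$count_coefs), unname(fn$count_coefs),
               tolerance = 0.02)
})

test_that("likelihood-ratio test: identity, nesting, null calibration", {
  d <- simulate_hurdle_data(200, seed = 35)
  full <- fit_hurdle(d, c("r", "type"), c("r", "type"),
                     offset = "n_flowers_sampled")
  same <- fit_hurdle(d, c("r", "type"), c("r", "type"),
                     offset = "n_flowers_sampled")
  lr0 <- likelihood_ratio_test(full, same)
  expect_equal(lr0$statistic, 0, tolerance = 1e-6)
  expect_equal(lr0$p_value, 1)
  red <- fit_hurdle(d, "r", "r", offset = "n_flowers_sampled")
  lr <- likelihood_ratio_test(full, red)
  expect_gte(lr$statistic, 0)
  expect_equal(lr$df, 2)
  expect_error(likelihood_ratio_test(red, full), "not nested|negative")
  other <- fit_hurdle(simulate_hurdle_data(150, seed = 36), "r", "r")
  expect_error(likelihood_ratio_test(full, other), "same data")

  # dropping a truly-null term: LR p-values should be uniform
  ps <- vapply(1:150, function(i) {
    dd <- simulate_hurdle_data(150, family = "poisson", seed = 1000 + i)
    f <- fit_hurdle(dd, c("r", "type"), c("r", "type"),
                    offset = "n_flowers_sampled", family = "poisson")
    r <- fit_hurdle(dd, "r", "r", offset = "n_flowers_sampled",
                    family = "poisson")
    likelihood_ratio_test(f, r)$p_value
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("randomized-quantile residuals are near-normal under the model", {
  d <- simulate_hurdle_data(400, seed = 37)
  fit <- fit_hurdle(d, "r", "r", offset = "n_flowers_sampled")
  res <- hurdle_residuals(fit, seed = 1)
  expect_length(res, fit$n_obs)
  expect_gt(shapiro.test(res)$p.value, 0.001)
  expect_identical(res, hurdle_residuals(fit, seed = 1))
})

test_that("the three transfer analyses filter, relabel and exclude correctly", {
  cfg <- sim_config(seed = 8, centers = cbind(c(0, 150, 320, 470),
                                              c(0, 60, -40, 30)),
                    radii = rep(40, 4), alpha = 80)
  plants <- simulate_landscape(cfg)
  dye <- simulate_dye_deposition(plants, cfg)
  tt <- build_transfer_table(plants, dye, simulated_source_map(cfg))

  a1 <- run_transfer_analyses(tt, "intrapop_differences", seed = 1)
  expect_s3_class(a1$fit, "hurdle_fit")
  expect_true(any(grepl("^type", a1$coefficients$term)))

  intra <- tt[tt$transfer_class == "intrapopulation", ]
  drop_id <- intra$recipient_id[which(intra$sum_count > 0)[1]]
  a1x <- run_transfer_analyses(tt, "intrapop_differences",
                               exclude = drop_id, seed = 1)
  # within the intrapopulation subset each recipient contributes one row
  expect_equal(a1$fit$n_obs - a1x$fit$n_obs, 1L)

  coords <- plants[plants$role == "recipient", c("plant_id", "x", "y")]
  names(coords)[1] <- "recipient_id"
  a2 <- run_transfer_analyses(tt, "intra_vs_inter_ecotypic",
                              coords = coords, n_perm = 99, seed = 1)
  expect_s3_class(a2$residual_moran, "moran_result")

  only_intra <- tt[tt$transfer_class != "inter_ecotypic", ]
  expect_error(run_transfer_analyses(only_intra, "directionality"),
               "requires inter-ecotypic")
})

test_that("a count-part transfer-type effect is detected when present", {
  detect <- vapply(1:40, function(i) {
    d <- simulate_hurdle_data(
      150,
      zero_coefs = c("(Intercept)" = 0.3, r = -0.005),
      count_coefs = c("(Intercept)" = 1.5, r = -0.004, typeB = 0.7),
      nb_size = 1.5, seed = 2000 + i)
    f <- fit_hurdle(d, c("r", "type"), c("r", "type"),
                    offset = "n_flowers_sampled")
    co <- f$coefficients
    co$p[co$component == "count" & co$term == "typeB"] <= 0.05
  }, logical(1))
  expect_gte(mean(detect), 0.8)
})

test_that("a null transfer-type effect is rarely declared", {
  false_pos <- vapply(1:40, function(i) {
    d <- simulate_hurdle_data(
      150,
      zero_coefs = c("(Intercept)" = 0.3, r = -0.005),
      count_coefs = c("(Intercept)" = 1.5, r = -0.004),
      nb_size = 1.5, seed = 3000 + i)
    f <- fit_hurdle(d, c("r", "type"), c("r", "type"),
                    offset = "n_flowers_sampled")
    co <- f$coefficients
    co$p[co$component == "count" & co$term == "typeB"] <= 0.05
  }, logical(1))
  expect_lte(mean(false_pos), 0.2)
})
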