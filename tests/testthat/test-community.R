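test_that("correlation PCA matches an eigen oracle and its invariants", {
  set.seed(41)
  # two perfectly correlated columns, three independent ones
  z <- rnorm(40)
  m <- cbind(a = z, b = 2 * z + 3, c = rnorm(40), d = rnorm(40), e = rnorm(40))
  p <- pca_correlation(m)
  # eigen oracle on the correlation matrix
  ev <- eigen(cor(m))$values
  expect_equal(p$eigenvalues, ev)
  expect_equal(sum(p$eigenvalues), 5)            # trace of the correlation matrix
  expect_equal(sum(p$proportion_variance), 1)
  expect_true(all(diff(p$eigenvalues) <= 1e-12))
  # the correlated pair loads together on one axis with eigenvalue ~2
  expect_equal(max(ev), 2, tolerance = 0.35)

  # independent columns, large n: proportions ~ 1/5 each
  m2 <- matrix(rnorm(5 * 4000), ncol = 5)
  p2 <- pca_correlation(m2)
  expect_true(all(abs(p2$proportion_variance - 0.2) < 0.03))

  m3 <- m; m3[, 2] <- 1
  colnames(m3)[2] <- "flat"
  expect_error(pca_correlation(m3), "zero-variance column: flat")
})

test_that("Bray-Curtis dissimilarity formula", {
  expect_equal(bray_curtis(c(3, 1, 2), c(3, 1, 2)), 0)
  expect_equal(bray_curtis(c(5, 0, 0), c(0, 2, 1)), 1)
  expect_equal(bray_curtis(c(7, 0, 0, 0, 0), c(2, 0, 0, 0, 0)), 5 / 9)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "all-zero")
  expect_error(bray_curtis(c(-1, 2), c(1, 2)), "non-negative")
  # agrees with vegan's implementation on random counts
  set.seed(42)
  a <- rpois(6, 5); b <- rpois(6, 5)
  expect_equal(bray_curtis(a, b),
               as.numeric(vegan::vegdist(rbind(a, b), method = "bray")))
})

test_that("PERMANOVA partitions SS sequentially and is seed-deterministic", {
  cfg <- sim_config(seed = 43)
  comm <- simulate_predator_communities(cfg)
  r1 <- permanova(comm, n_perm = 199, seed = 7)
  r2 <- permanova(comm, n_perm = 199, seed = 7)
  expect_identical(r1$table, r2$table)
  tab <- r1$table
  total <- tab$sum_of_squares[tab$term == "Total"]
  expect_equal(sum(tab$sum_of_squares[tab$term != "Total"]), total)
  expect_gte(min(tab$p_perm, na.rm = TRUE), 1 / 200)

  # total SS invariant to row order
  perm <- sample(nrow(comm))
  r3 <- permanova(comm[perm, ], n_perm = 49, seed = 7)
  expect_equal(r3$table$sum_of_squares[r3$table$term == "Total"], total)

  bad <- comm
  bad[1, community_taxa_names(bad)] <- 0
  expect_error(permanova(bad), "all-zero row")
})

test_that("separated groups reach the minimum attainable p-value", {
  m <- rbind(matrix(rep(c(300, 0, 0, 10, 20), 6), nrow = 6, byrow = TRUE),
             matrix(rep(c(0, 250, 120, 0, 0), 6), nrow = 6, byrow = TRUE))
  meta <- data.frame(group = rep(c("x", "y"), each = 6))
  # tiny within-group jitter so rows are distinct and no permutation ties
  set.seed(44)
  m <- m + matrix(rpois(60, 1), nrow = 12)
  r <- permanova(m, factors = meta, n_perm = 999, seed = 1)
  expect_equal(r$table$p_perm[1], 1 / 1000)
})

test_that("PERMANOVA p-values are roughly uniform under the null", {
  ps <- vapply(1:100, function(i) {
    # abundant null communities so all-zero rows are rare
    cfg <- sim_config(predator_si_shift = rep(0, 5),
                      predator_baseline_log = log(c(6, 3, 3, 2, 2)),
                      seed = 5000 + i)
    comm <- simulate_predator_communities(cfg)
    if (any(rowSums(comm[, community_taxa_names(comm)]) == 0)) return(NA_real_)
    permanova(comm, n_perm = 199, seed = i)$table$p_perm[1]
  }, numeric(1))
  ps <- ps[!is.na(ps)]
  expect_gt(length(ps), 60)
  expect_gt(suppressWarnings(ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("Mann-Whitney U matches brute-force pair counting", {
  u <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(u$U_first, 0)
  expect_equal(u$U_other, 9)

  set.seed(45)
  for (rep in 1:10) {
    a <- sample(1:6, 7, replace = TRUE)
    b <- sample(1:6, 5, replace = TRUE)
    brute <- sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
    u <- mann_whitney_u(a, b)
    expect_equal(u$U_first, brute)
    expect_equal(u$U_first + u$U_other, 35)
    # p agrees with the standard implementation's normal approximation
    w <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
    expect_equal(u$p_two_sided, w$p.value, tolerance = 1e-10)
    # invariance under a strictly monotone transform
    u2 <- mann_whitney_u(exp(a), exp(b))
    expect_equal(u2$U_first, u$U_first)
  }
})

test_that("chi-square two-proportion test matches the Pearson formula", {
  expect_equal(chisq_two_proportions(c(30, 30), c(60, 60))$statistic, 0)
  r <- chisq_two_proportions(c(50, 80), c(100, 100))
  # closed-form Pearson statistic N(ad - bc)^2 / ((a+b)(c+d)(a+c)(b+d))
  # for the 2x2 table [[50, 80], [50, 20]]
  expect_equal(r$statistic,
               200 * (50 * 20 - 80 * 50)^2 / (130 * 70 * 100 * 100))
  expect_equal(r$df, 1)
  r2 <- chisq_two_proportions(c(80, 50), c(100, 100))
  expect_equal(r2$statistic, r$statistic)
  expect_error(chisq_two_proportions(c(0, 0), c(5, 5)), "zero")
})

test_that("germination comparison pools populations within ecotype", {
  germ <- data.frame(
    population_id = c("a", "b", "c", "d"),
    ecotype = c("Ca", "Ca", "Si", "Si"),
    n_seeds_plated = c(100, 100, 100, 100),
    n_germinated = c(60, 70, 90, 85),
    n_chlorotic = c(1, 0, 2, 1),
    n_partially_chlorotic = c(0, 1, 1, 0))
  res <- compare_germination(germ)
  oracle <- suppressWarnings(
    chisq.test(rbind(c(130, 70), c(175, 25)), correct = FALSE))
  expect_equal(res$statistic[res$test == "germination"],
               unname(oracle$statistic))
  expect_equal(res$df, c(1, 1))
})
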