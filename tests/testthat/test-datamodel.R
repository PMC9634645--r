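test_that("tables round-trip through CSV unchanged", {
  plants <- make_plants()
  dye <- make_dye()
  p1 <- withr::local_tempfile(fileext = ".csv")
  p2 <- withr::local_tempfile(fileext = ".csv")
  write_table(plants, p1)
  write_table(dye, p2)
  expect_equal(read_plant_table(p1), plants)
  expect_equal(read_dye_table(p2), dye)

  cfg <- sim_config(seed = 3)
  comm <- simulate_predator_communities(cfg)
  cam <- simulate_visitation(cfg)
  germ <- simulate_germination(cfg)
  for (tab in list(comm, cam, germ)) {
    p <- withr::local_tempfile(fileext = ".csv")
    write_table(tab, p)
    reader <- if ("n_seeds_plated" %in% names(tab)) read_germination_table
      else if ("duration_h" %in% names(tab)) read_camera_table
      else read_community_table
    expect_equal(reader(p), tab)
  }
})

test_that("validators name the offending row", {
  dye <- make_dye()
  dye$particle_count[4] <- -1
  expect_error(validate_dye(dye), "row 4")
  plants <- make_plants()
  plants$x[2] <- NA
  expect_error(validate_plants(plants), "non-finite.*row 2")
  expect_error(validate_dye(make_dye()[, -3]), "missing required column")
})

test_that("empty dye file is a valid empty observation set", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines("plant_id,flower_id,dye_color,particle_count", p)
  d <- read_dye_table(p)
  expect_equal(nrow(d), 0)
  tt <- build_transfer_table(make_plants(), d, make_source_map())
  expect_true(all(tt$sum_count == 0))
})

test_that("pairwise distances are Euclidean, symmetric, zero on identity", {
  a <- list(x = 0, y = 0); b <- list(x = 3, y = 4)
  expect_equal(pairwise_distance(a, b), 5)
  expect_equal(pairwise_distance(b, a), 5)
  expect_equal(pairwise_distance(a, a), 0)
  expect_error(pairwise_distance(list(x = NA, y = 0), b), "non-finite")

  set.seed(42)
  pts <- data.frame(plant_id = paste0("p", 1:10),
                    x = runif(10, 0, 100), y = runif(10, 0, 100))
  D <- distance_matrix(pts)
  brute <- matrix(0, 10, 10)
  for (i in 1:10) for (j in 1:10)
    brute[i, j] <- sqrt((pts$x[i] - pts$x[j])^2 + (pts$y[i] - pts$y[j])^2)
  expect_equal(unname(D), brute)
})

test_that("total flower estimate is inflorescences times mean open flowers", {
  expect_equal(estimate_total_flowers(10, c(2, 2, 2, 2, 2)), 20)
  expect_equal(estimate_total_flowers(4, c(1, 3)), 8)
  expect_error(estimate_total_flowers(4, integer(0)), "no open-flower counts")
  set.seed(7)
  for (i in 1:20) {
    k <- sample(1:5, 1)
    v <- sample(0:9, k, replace = TRUE)
    n <- sample(1:30, 1)
    expect_equal(estimate_total_flowers(n, v), n * sum(v) / length(v))
  }
})

test_that("transfer table arithmetic and zero-filling are correct", {
  tt <- build_transfer_table(make_plants(), make_dye(), make_source_map())
  # one record per recipient x color
  expect_equal(nrow(tt), 5 * 2)
  a1b <- tt[tt$recipient_id == "A1" & tt$dye_color == "blue", ]
  expect_equal(a1b$sum_count, 3)                   # 2 + 1 (zero-count row ignored)
  expect_equal(a1b$mean_count_per_flower, 3 / 7)
  expect_equal(a1b$n_flowers_positive, 2)
  expect_equal(a1b$r, 5)                           # (3,4) from source at origin
  expect_equal(a1b$total_flowers_est, 20)
  # all-zero recipient still yields a record per color
  a3 <- tt[tt$recipient_id == "A3", ]
  expect_equal(nrow(a3), 2)
  expect_true(all(a3$sum_count == 0))
  # invariant: sum = mean x flowers sampled
  expect_true(all(abs(tt$sum_count -
                        tt$mean_count_per_flower * tt$n_flowers_sampled) < 1e-9))
  expect_error(
    build_transfer_table(make_plants(), make_dye(),
                         data.frame(dye_color = "blue",
                                    source_population = "PopA")),
    "no source mapping")
})

test_that("transfer classes and directions match a brute-force labeling", {
  cfg <- sim_config(seed = 5)
  plants <- simulate_landscape(cfg)
  dye <- simulate_dye_deposition(plants, cfg)
  tt <- build_transfer_table(plants, dye, simulated_source_map(cfg))
  eco <- setNames(plants$ecotype[!duplicated(plants$population_id)],
                  plants$population_id[!duplicated(plants$population_id)])
  for (i in seq_len(nrow(tt))) {
    se <- eco[[tt$source_population[i]]]
    re <- eco[[tt$recipient_population[i]]]
    want <- if (tt$source_population[i] == tt$recipient_population[i])
      "intrapopulation" else if (se == re) "intra_ecotypic" else "inter_ecotypic"
    expect_identical(tt$transfer_class[i], want)
    expect_identical(tt$direction[i], paste0(se, "To", re))
  }
})

test_that("transfer summary counts individuals and flowers with dye", {
  tt <- build_transfer_table(make_plants(), make_dye(), make_source_map())
  s <- transfer_summary(tt)
  aa <- s[s$source_population == "PopA" & s$recipient_population == "PopA", ]
  expect_equal(aa$pct_individuals_with_dye, 100 * 2 / 3)  # A1, A2 of 3
  expect_equal(aa$mean_pct_flowers_with_dye,
               mean(c(2 / 7, 1 / 5, 0)) * 100)
  # all-zero source-recipient pair: 0 +- 0
  bb <- s[s$source_population == "PopB" & s$recipient_population == "PopA", ]
  expect_equal(bb$pct_individuals_with_dye, 100 / 3)  # pink on A1
  zz <- s[s$source_population == "PopA" & s$recipient_population == "PopB", ]
  expect_equal(zz$mean_pct_flowers_with_dye, 100 / 7 / 2)
  # invariance to row order of the dye file
  tt2 <- build_transfer_table(make_plants(), make_dye()[c(6, 3, 1, 5, 2, 4), ],
                              make_source_map())
  expect_equal(transfer_summary(tt2), s)
})

test_that("summary flower percentages agree with a known hit probability", {
  # 200 recipients x 7 flowers, per-flower hit probability 0.3
  set.seed(9)
  n <- 200; nf <- 7; p <- 0.3
  hits <- rbinom(n, nf, p)
  tt <- data.frame(source_population = "S", recipient_population = "R",
                   sum_count = hits, n_flowers_positive = hits,
                   n_flowers_sampled = nf)
  s <- transfer_summary(tt)
  se <- sqrt(p * (1 - p) / nf) / sqrt(n) * 100
  expect_lt(abs(s$mean_pct_flowers_with_dye - 30), 3 * se)
})
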