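# Synthetic-data generator with known ground truth: kernel-driven dye
# deposition with excess zeros and overdispersion, ecotype-structured
# seed-predator communities, visitation-rate samples and germination counts.
# Defaults emulate the field conditions of a parapatric two-ecotype system:
# two populations of each ecotype per landscape, 0.7-5 km apart, 26-51
# recipients per population with usually 7 sampled flowers each.

#' Simulation configuration
#'
#' Bundles every ground-truth parameter of the synthetic landscape and
#' sampling design. Defaults describe the emulated field system; tests
#' recover the kernel and hurdle parameters set here.
#'
#' @param n_populations number of populations.
#' @param ecotypes ecotype label per population (`"Ca"`/`"Si"`).
#' @param centers two-column matrix of population centers (m); default four
#'   populations 0.7-5 km apart.
#' @param radii population disc radius per population (m).
#' @param plants_per_population recipient individuals per population.
#' @param alpha,beta ground-truth kernel extent (m) and shape.
#' @param intensity_c expected particles per flower at the reference
#'   distance (`r_ref`, default 1 m) from the source.
#' @param pi0 structural zero probability per flower (pollinator never
#'   arrived), in `[0, 1]`.
#' @param nb_size negative-binomial size (overdispersion; smaller = more
#'   overdispersed).
#' @param r_ref reference distance (m) at which the kernel is normalized so
#'   `intensity_c` is interpretable as "particles per flower near the
#'   source".
#' @param mean_inflorescences,mean_open_flowers Poisson means (shifted by 1)
#'   for inflorescence and per-inflorescence open-flower counts.
#' @param flowers_sampled flowers collected per recipient.
#' @param taxa taxon-group names of the predator community.
#' @param predator_baseline_log per-taxon baseline log mean abundance
#'   (calcicolous level).
#' @param predator_si_shift per-taxon log-mean shift on the silicicolous
#'   ecotype.
#' @param predator_nb_size negative-binomial size of predator counts.
#' @param years years sampled for predator communities.
#' @param visit_rate,moth_rate per-ecotype named rates (events/h) of flower
#'   visits and moth appearances.
#' @param cameras_per_ecotype named counts of camera-nights.
#' @param p_germ named per-ecotype germination probabilities.
#' @param p_chlorotic,p_partial probabilities that a germinated seedling is
#'   chlorotic / partially chlorotic (hybrid indicators).
#' @param seeds_per_population seeds plated per population.
#' @param placement recipient placement within each population disc:
#'   `"distance_stratified"` (default) draws the distance from the source
#'   group uniformly between 2 m and the disc radius, emulating the field
#'   protocol of sampling recipients so as to cover a wide range of
#'   distances; `"area_uniform"` scatters recipients uniformly over the
#'   disc area.
#' @param seed integer RNG seed expanded into per-stage streams.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_populations = 4,
                       ecotypes = c("Ca", "Si", "Si", "Ca"),
                       centers = NULL,
                       radii = rep(40, n_populations),
                       plants_per_population = rep(40, n_populations),
                       alpha = 30, beta = 0.8,
                       intensity_c = 25, pi0 = 0.4, nb_size = 0.6,
                       r_ref = 1,
                       mean_inflorescences = 4, mean_open_flowers = 3,
                       flowers_sampled = 7,
                       taxa = c("Noctuidae", "Coleophora", "Coleoptera",
                                "Diptera_Delia", "gall"),
                       predator_baseline_log =
                         log(c(4, 0.3, 0.5, 0.2, 0.1)),
                       predator_si_shift = c(0.7, 2, 1.5, 2.5, 2.5),
                       predator_nb_size = 0.8,
                       years = c(2019, 2020),
                       visit_rate = c(Ca = 0.98, Si = 1.83),
                       moth_rate = c(Ca = 0.49, Si = 0.85),
                       cameras_per_ecotype = c(Ca = 6, Si = 7),
                       p_germ = c(Ca = 0.7, Si = 0.9),
                       p_chlorotic = 0.02, p_partial = 0.01,
                       seeds_per_population = 150,
                       placement = c("distance_stratified", "area_uniform"),
                       seed = 1) {
  placement <- match.arg(placement)
  if (is.null(centers))
    centers <- cbind(c(0, 900, 2600, 4000), c(0, 600, -300, 800))[
      seq_len(n_populations), , drop = FALSE]
  stopifnot(alpha > 0, beta > 0, pi0 >= 0, pi0 <= 1, nb_size > 0,
            length(ecotypes) == n_populations,
            nrow(centers) == n_populations)
  cfg <- list(n_populations = n_populations, ecotypes = ecotypes,
              centers = centers, radii = radii,
              plants_per_population = plants_per_population,
              alpha = alpha, beta = beta, intensity_c = intensity_c,
              pi0 = pi0, nb_size = nb_size, r_ref = r_ref,
              mean_inflorescences = mean_inflorescences,
              mean_open_flowers = mean_open_flowers,
              flowers_sampled = flowers_sampled,
              taxa = taxa, predator_baseline_log = predator_baseline_log,
              predator_si_shift = predator_si_shift,
              predator_nb_size = predator_nb_size, years = years,
              visit_rate = visit_rate, moth_rate = moth_rate,
              cameras_per_ecotype = cameras_per_ecotype,
              p_germ = p_germ, p_chlorotic = p_chlorotic,
              p_partial = p_partial,
              seeds_per_population = seeds_per_population,
              placement = placement, seed = seed)
  class(cfg) <- "sim_config"
  cfg
}

pop_names <- function(cfg) {
  paste0("P", seq_len(cfg$n_populations), "_", cfg$ecotypes)
}

#' Simulate a plant landscape
#'
#' Scatters recipient plants uniformly within each population disc and
#' places one source group (a single source record at the disc center,
#' mirroring a tight ~0.5 m2 group of dye-marked plants) per population.
#' Warns when population discs overlap.
#'
#' @param cfg [sim_config()].
#' @return validated plant table.
#' @export
simulate_landscape <- function(cfg) {
  with_seed(stage_seed(cfg$seed, "landscape"), {
    pops <- pop_names(cfg)
    ctr_d <- as.matrix(dist(cfg$centers))
    min_gap <- outer(cfg$radii, cfg$radii, "+")
    if (any(ctr_d[upper.tri(ctr_d)] < min_gap[upper.tri(min_gap)]))
      warning("population discs overlap")
    rows <- lapply(seq_len(cfg$n_populations), function(i) {
      n <- cfg$plants_per_population[i]
      th <- runif(n, 0, 2 * pi)
      rr <- if (cfg$placement == "distance_stratified")
        runif(n, min(2, cfg$radii[i] / 2), cfg$radii[i])
      else cfg$radii[i] * sqrt(runif(n))
      n_infl <- 1 + rpois(n, cfg$mean_inflorescences)
      open <- vapply(seq_len(n), function(j) {
        paste(1 + rpois(5, cfg$mean_open_flowers), collapse = ";")
      }, character(1))
      rec <- data.frame(
        plant_id = sprintf("%s_r%02d", pops[i], seq_len(n)),
        population_id = pops[i], ecotype = cfg$ecotypes[i],
        x = cfg$centers[i, 1] + rr * cos(th),
        y = cfg$centers[i, 2] + rr * sin(th),
        role = "recipient",
        n_inflorescences = n_infl, open_flowers = open,
        n_flowers_sampled = cfg$flowers_sampled,
        stringsAsFactors = FALSE)
      src <- data.frame(
        plant_id = paste0(pops[i], "_src"),
        population_id = pops[i], ecotype = cfg$ecotypes[i],
        x = cfg$centers[i, 1], y = cfg$centers[i, 2], role = "source",
        n_inflorescences = 1, open_flowers = "",
        n_flowers_sampled = 0, stringsAsFactors = FALSE)
      rbind(src, rec)
    })
    validate_plants(do.call(rbind, rows))
  })
}

#' Dye-color to source-population map of a simulated landscape
#'
#' One distinct color per population, recycling the four field colors.
#'
#' @param cfg [sim_config()].
#' @return data.frame with `dye_color`, `source_population`.
#' @export
simulated_source_map <- function(cfg) {
  if (cfg$n_populations > length(DYE_COLORS))
    stop("at most ", length(DYE_COLORS), " populations: one color each")
  data.frame(dye_color = DYE_COLORS[seq_len(cfg$n_populations)],
             source_population = pop_names(cfg),
             stringsAsFactors = FALSE)
}

#' Simulate kernel-driven dye deposition
#'
#' For each recipient flower at distance `r` from a dye source, the particle
#' count is a structural zero with probability `pi0` (the pollinator never
#' arrived) and otherwise negative-binomial with mean
#' `mu(r) = c * f(alpha, beta; r) / f(alpha, beta; r_ref)` and size
#' `nb_size`, independent across flowers. Only positive counts produce
#' observation rows (sampled flowers absent from the table are zero-count by
#' protocol).
#'
#' @param plants plant table from [simulate_landscape()].
#' @param cfg [sim_config()].
#' @return validated dye-observation table.
#' @export
simulate_dye_deposition <- function(plants, cfg) {
  smap <- simulated_source_map(cfg)
  with_seed(stage_seed(cfg$seed, "deposition"), {
    f_ref <- kernel_density(cfg$alpha, cfg$beta, cfg$r_ref)
    rec <- plants[plants$role == "recipient", ]
    out <- list()
    for (i in seq_len(nrow(smap))) {
      src <- plants[plants$role == "source" &
                    plants$population_id == smap$source_population[i], ]
      r <- sqrt((rec$x - mean(src$x))^2 + (rec$y - mean(src$y))^2)
      mu <- cfg$intensity_c * kernel_density(cfg$alpha, cfg$beta, r) / f_ref
      for (j in seq_len(nrow(rec))) {
        nf <- rec$n_flowers_sampled[j]
        arrived <- runif(nf) >= cfg$pi0
        counts <- ifelse(arrived,
                         rnbinom(nf, size = cfg$nb_size, mu = mu[j]), 0L)
        pos <- which(counts > 0)
        if (length(pos))
          out[[length(out) + 1]] <- data.frame(
            plant_id = rec$plant_id[j],
            flower_id = sprintf("f%02d", pos),
            dye_color = smap$dye_color[i],
            particle_count = counts[pos],
            stringsAsFactors = FALSE)
      }
    }
    if (length(out) == 0)
      return(validate_dye(data.frame(plant_id = character(0),
                                     flower_id = character(0),
                                     dye_color = character(0),
                                     particle_count = integer(0))))
    validate_dye(do.call(rbind, out))
  })
}

#' Simulate hurdle-structured transfer data with known coefficients
#'
#' Direct generator for the hurdle-regression recovery and power
#' experiments: draws distances and a binary transfer type, then the zero
#' part (logit) and, conditional on crossing, a zero-truncated count (by
#' rejection from the untruncated family).
#'
#' @param n observations.
#' @param zero_coefs,count_coefs named numeric vectors over
#'   `(Intercept)`, `r`, and optionally `typeB` and `r:typeB`.
#' @param family `"negbin"` or `"poisson"`.
#' @param nb_size NB size parameter.
#' @param r_range distance range (m), drawn uniformly.
#' @param n_flowers offset variable (flowers sampled), recycled to `n`.
#' @param seed RNG seed.
#' @return data.frame with `r`, `type`, `total_flowers_est`,
#'   `n_flowers_sampled`, `sum_count`.
#' @export
simulate_hurdle_data <- function(n,
                                 zero_coefs = c("(Intercept)" = -0.5, r = -0.01),
                                 count_coefs = c("(Intercept)" = 2, r = -0.005),
                                 family = c("negbin", "poisson"),
                                 nb_size = 1.5,
                                 r_range = c(2, 300), n_flowers = 7,
                                 seed = 1) {
  family <- match.arg(family)
  with_seed(seed, {
    d <- data.frame(r = runif(n, r_range[1], r_range[2]),
                    type = factor(sample(c("A", "B"), n, replace = TRUE)),
                    total_flowers_est = 1 + rpois(n, 20),
                    n_flowers_sampled = rep_len(n_flowers, n))
    terms_of <- function(coefs) {
      X <- model.matrix(~ r * type, data = d)
      keep <- intersect(names(coefs), colnames(X))
      drop(X[, keep, drop = FALSE] %*% coefs[keep])
    }
    p <- plogis(terms_of(zero_coefs))
    mu <- exp(terms_of(count_coefs) + log(d$n_flowers_sampled))
    cross <- runif(n) < p
    draw_pos <- function(mu_i) {
      for (it in 1:1000) {
        v <- if (family == "poisson") rpois(1, mu_i)
        else rnbinom(1, size = nb_size, mu = mu_i)
        if (v > 0) return(v)
      }
      1L
    }
    d$sum_count <- ifelse(cross, vapply(mu, draw_pos, numeric(1)), 0)
    d
  })
}

#' Simulate seed-predator communities
#'
#' Per population-year row, taxon counts are negative-binomial with
#' `log(mean) = baseline + ecotype shift` (shift applied on the
#' silicicolous ecotype).
#'
#' @param cfg [sim_config()].
#' @return validated community table.
#' @export
simulate_predator_communities <- function(cfg) {
  with_seed(stage_seed(cfg$seed, "predators"), {
    pops <- pop_names(cfg)
    grid <- expand.grid(pop = seq_len(cfg$n_populations), year = cfg$years)
    counts <- t(vapply(seq_len(nrow(grid)), function(i) {
      shift <- if (cfg$ecotypes[grid$pop[i]] == "Si") cfg$predator_si_shift
               else rep(0, length(cfg$taxa))
      mu <- exp(cfg$predator_baseline_log + shift)
      rnbinom(length(mu), size = cfg$predator_nb_size, mu = mu)
    }, numeric(length(cfg$taxa))))
    colnames(counts) <- cfg$taxa
    comm <- data.frame(population_id = pops[grid$pop],
                       ecotype = cfg$ecotypes[grid$pop],
                       year = grid$year, stringsAsFactors = FALSE)
    validate_community(cbind(comm, as.data.frame(counts)))
  })
}

#' Simulate camera visitation records
#'
#' Poisson visit and moth counts over uniformly drawn exposure durations,
#' with per-ecotype rates.
#'
#' @param cfg [sim_config()].
#' @return validated camera table.
#' @export
simulate_visitation <- function(cfg) {
  with_seed(stage_seed(cfg$seed, "visitation"), {
    rows <- lapply(names(cfg$cameras_per_ecotype), function(eco) {
      k <- cfg$cameras_per_ecotype[[eco]]
      pops <- pop_names(cfg)[cfg$ecotypes == eco]
      dur <- round(runif(k, 2, 8), 2)
      visits <- rpois(k, cfg$visit_rate[[eco]] * dur)
      moths <- rpois(k, cfg$moth_rate[[eco]] * dur)
      data.frame(population_id = sample(pops, k, replace = TRUE),
                 ecotype = eco,
                 date = sprintf("2020-05-%02d", seq_len(k)),
                 duration_h = dur,
                 n_flowers_filmed = rpois(k, 50),
                 n_flowers_visited = visits, n_moths = moths,
                 visits_per_h = round(visits / dur, 2),
                 moths_per_h = round(moths / dur, 2),
                 stringsAsFactors = FALSE)
    })
    validate_camera(do.call(rbind, rows))
  })
}

#' Simulate a germination experiment
#'
#' Binomial germination per population with per-ecotype probability;
#' binomial chlorotic and partially chlorotic counts among the germinated.
#'
#' @param cfg [sim_config()].
#' @return validated germination table.
#' @export
simulate_germination <- function(cfg) {
  with_seed(stage_seed(cfg$seed, "germination"), {
    pops <- pop_names(cfg)
    n <- cfg$seeds_per_population
    germ <- rbinom(cfg$n_populations, n, cfg$p_germ[cfg$ecotypes])
    chl <- rbinom(cfg$n_populations, germ, cfg$p_chlorotic)
    part <- rbinom(cfg$n_populations, germ - chl, cfg$p_partial)
    validate_germination(data.frame(
      population_id = pops, ecotype = cfg$ecotypes,
      n_seeds_plated = n, n_germinated = germ,
      n_chlorotic = chl, n_partially_chlorotic = part,
      stringsAsFactors = FALSE))
  })
}

#' Write a full simulated dataset to disk
#'
#' Generates all five tables plus a ground-truth JSON sidecar recording the
#' configuration, so downstream recovery experiments can compare estimates
#' with the generating parameters.
#'
#' @param cfg [sim_config()].
#' @param dir output directory (created if needed).
#' @return named list of written file paths, invisibly; also returns the
#'   generated tables in the `tables` attribute.
#' @export
write_simulated_dataset <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  plants <- simulate_landscape(cfg)
  tables <- list(
    plants = plants,
    dye = simulate_dye_deposition(plants, cfg),
    community = simulate_predator_communities(cfg),
    camera = simulate_visitation(cfg),
    germination = simulate_germination(cfg)
  )
  paths <- lapply(names(tables), function(nm) {
    p <- file.path(dir, paste0(nm, ".csv"))
    write_table(tables[[nm]], p)
    p
  })
  names(paths) <- names(tables)
  truth <- unclass(cfg)
  truth$centers <- apply(cfg$centers, 1, function(v) v, simplify = FALSE)
  sidecar <- file.path(dir, "ground_truth.json")
  jsonlite::write_json(truth, sidecar, auto_unbox = TRUE, digits = NA)
  paths$ground_truth <- sidecar
  out <- paths
  attr(out, "tables") <- tables
  invisible(out)
}
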