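# Small deterministic fixtures shared across tests.

make_plants <- function() {
  data.frame(
    plant_id = c("A_src", "A1", "A2", "A3", "B_src", "B1", "B2"),
    population_id = c("PopA", "PopA", "PopA", "PopA", "PopB", "PopB", "PopB"),
    ecotype = c("Ca", "Ca", "Ca", "Ca", "Si", "Si", "Si"),
    x = c(0, 3, 0, 10, 500, 504, 510),
    y = c(0, 4, 10, 0, 0, 3, 0),
    role = c("source", "recipient", "recipient", "recipient",
             "source", "recipient", "recipient"),
    n_inflorescences = c(1, 10, 4, 5, 1, 2, 3),
    open_flowers = c("", "2;2;2;2;2", "1;3", "2;4;3", "", "5", "1;1;1"),
    n_flowers_sampled = c(0, 7, 5, 7, 0, 7, 7),
    stringsAsFactors = FALSE
  )
}

make_dye <- function() {
  data.frame(
    plant_id = c("A1", "A1", "A1", "A2", "B1", "A1"),
    flower_id = c("f3", "f5", "f1", "f1", "f2", "f1"),
    dye_color = c("blue", "blue", "blue", "blue", "blue", "pink"),
    particle_count = c(2, 1, 0, 4, 6, 3),
    stringsAsFactors = FALSE
  )
}

make_source_map <- function() {
  data.frame(dye_color = c("blue", "pink"),
             source_population = c("PopA", "PopB"),
             stringsAsFactors = FALSE)
}

# single-population transfer fixture for kernel fitting
make_kernel_transfers <- function(alpha = 30, beta = 0.8, n = 300,
                                  seed = 1, pi0 = 0.4, nb_size = 0.6) {
  cfg <- sim_config(n_populations = 1, ecotypes = "Si",
                    centers = matrix(c(0, 0), 1), radii = 200,
                    plants_per_population = n, alpha = alpha, beta = beta,
                    pi0 = pi0, nb_size = nb_size, seed = seed)
  plants <- simulate_landscape(cfg)
  dye <- simulate_dye_deposition(plants, cfg)
  build_transfer_table(plants, dye, simulated_source_map(cfg))
}
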