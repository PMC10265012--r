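# Small in-code fixtures shared across test files.

toy_hosts <- function(ids, species, group = "fish", ecosystem = "vent",
                      length_mm = NA_real_) {
  tibble::tibble(host_individual_id = ids, host_species = species,
                 host_group = group, ecosystem = ecosystem,
                 host_length_mm = length_mm)
}

toy_ann <- function(ids, taxon = "Trematoda", life_cycle = "ILC",
                    life_stage = "adult", redundancy = NA_character_) {
  tibble::tibble(morphogroup_id = ids, parasite_taxon = taxon,
                 life_cycle = life_cycle, life_stage = life_stage,
                 redundancy_group = redundancy)
}

toy_obs <- function(host, mg, count = 1L) {
  tibble::tibble(host_individual_id = host, morphogroup_id = mg,
                 count = as.integer(count))
}

# a host-species summary table built directly (bypasses dissection data)
toy_summaries <- function(n_per_cell = 2, ecosystems = c("vent", "atoll", "kelp"),
                          groups = "fish", chao2 = NULL, lengths = NULL,
                          seed = 1) {
  withr::with_seed(seed, {
    g <- expand.grid(ecosystem = ecosystems, host_group = groups,
                     i = seq_len(n_per_cell), stringsAsFactors = FALSE)
    n <- nrow(g)
    tibble::tibble(
      host_species = sprintf("sp%02d", seq_len(n)),
      host_group = g$host_group, ecosystem = g$ecosystem,
      n_individuals = 10L,
      chao2_estimate = if (is.null(chao2)) stats::runif(n, 0, 10) else chao2,
      mean_length = if (is.null(lengths)) stats::rlnorm(n, 4, 0.3) else lengths)
  })
}
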