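test_that("simulated datasets validate and are reproducible from the seed", {
  cfg <- compact_sim_config()
  d1 <- simulate_dataset(cfg, seed = 42)
  d2 <- simulate_dataset(cfg, seed = 42)
  expect_identical(d1$hosts, d2$hosts)
  expect_identical(d1$observations, d2$observations)
  expect_identical(d1$annotations, d2$annotations)
  expect_equal(nrow(validate_dissection(d1)), 0)
  expect_equal(nrow(validate_dissection(simulate_dataset(sim_config(), seed = 1))), 0)
  d3 <- simulate_dataset(cfg, seed = 43)
  expect_false(identical(d1$observations, d3$observations))
})

test_that("zero detection probability yields zero observations", {
  cfg <- compact_sim_config()
  cfg$detection_prob <- 0
  d <- simulate_dataset(cfg, seed = 1)
  expect_equal(nrow(d$observations), 0)
  expect_gt(nrow(d$hosts), 0)
})

test_that("realized prevalence matches the configured detection probability", {
  hosts <- tibble::tibble(ecosystem = "vent", host_group = "fish",
                          n_species = 1L, n_individuals = 1000L)
  pool <- tibble::tibble(parasite_taxon = "Copepoda", life_cycle = "DLC",
                         life_stage = "adult", n_morphogroups = 1L)
  cfg <- sim_config(ecosystems = "vent", hosts = hosts, pool = pool,
                    detection_prob = 0.3, specificity_breadth = 1L,
                    effect = 0, redundancy_clusters = 0L)
  d <- simulate_dataset(cfg, seed = 9)
  prev <- nrow(d$observations) / 1000
  bounds <- stats::qbinom(c(0.005, 0.995), 1000, 0.3) / 1000
  expect_gte(prev, bounds[1])
  expect_lte(prev, bounds[2])
})

test_that("invalid configurations are rejected with the offending field named", {
  expect_error(sim_config(detection_prob = 1.3), regexp = "detection_prob",
               class = "paradiv_config_error")
  expect_error(sim_config(effect = -1), regexp = "effect",
               class = "paradiv_config_error")
  bad_pool <- default_parasite_pool()
  bad_pool$life_cycle[bad_pool$life_stage == "metacercaria"] <- "DLC"
  expect_error(sim_config(pool = bad_pool), regexp = "pool",
               class = "paradiv_config_error")
})

test_that("null_scenario makes ecosystems exchangeable up to labels", {
  cfg <- null_scenario(sim_config())
  expect_equal(cfg$effect, 0)
  per_eco <- split(cfg$hosts[c("host_group", "n_species", "n_individuals")],
                   cfg$hosts$ecosystem)
  for (tab in per_eco[-1]) {
    expect_equal(as.data.frame(tab), as.data.frame(per_eco[[1]]),
                 ignore_attr = TRUE)
  }
  # zero-effect ordered scenario coincides with the null's effect
  expect_equal(ordered_effect_scenario(sim_config(), 0)$effect, 0)
  expect_equal(ecosystem_multipliers(c("a", "b", "c"), 0), rep(1, 3))
})

test_that("the ordered effect produces the configured richness ordering", {
  cfg <- ordered_effect_scenario(compact_sim_config(), 0.8)
  means <- colMeans(t(vapply(1:40, function(i) {
    d <- simulate_dataset(cfg, seed = 2000 + i)
    s <- host_species_summaries(d)
    tapply(s$chao2_estimate, s$ecosystem, mean)[c("vent", "atoll", "kelp")]
  }, numeric(3))))
  expect_lt(means["vent"], means["atoll"])
  expect_lt(means["atoll"], means["kelp"])
})

test_that("host-level aggregation and length linkage still produce valid data", {
  cfg <- compact_sim_config()
  cfg$aggregation <- 0.5
  cfg$length_richness_coef <- 0.5
  d <- simulate_dataset(cfg, seed = 77)
  expect_equal(nrow(validate_dissection(d)), 0)
})

test_that("packaged fixtures reproduce their construction targets", {
  v <- fixture_vent_composition()
  counts <- dplyr::count(v$annotations, parasite_taxon, life_stage)
  want <- tibble::tribble(
    ~parasite_taxon,  ~life_stage,       ~n,
    "Acanthocephala", "adult",            2L,
    "Copepoda",       "adult",            1L,
    "Nematoda",       "adult",            1L,
    "Nematoda",       "larval_nematode",  1L,
    "Rhizocephala",   "adult",            1L,
    "Trematoda",      "adult",            7L,
    "Trematoda",      "metacercaria",     7L,
    "Trematoda",      "sporocyst",        1L)
  expect_equal(dplyr::arrange(counts, parasite_taxon, life_stage), want)
  # every morphogroup is actually observed in a host
  expect_setequal(unique(v$observations$morphogroup_id),
                  v$annotations$morphogroup_id)
  # survives the inclusion protocol unchanged
  h <- apply_inclusion_filters(v)
  expect_equal(nrow(h$hosts), nrow(v$hosts))

  d <- fixture_table1_shape()
  margins <- d$hosts |>
    dplyr::distinct(ecosystem, host_group, host_species) |>
    dplyr::count(ecosystem)
  expect_equal(margins$n[match(c("kelp", "atoll", "vent"), margins$ecosystem)],
               c(28L, 44L, 28L))
  ind <- dplyr::count(d$hosts, ecosystem)
  expect_equal(ind$n[match(c("kelp", "atoll", "vent"), ind$ecosystem)],
               c(678L, 2637L, 2134L))
})
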