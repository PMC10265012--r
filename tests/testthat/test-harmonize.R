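make_counts_dataset <- function(counts) {
  hosts <- purrr::imap_dfr(counts, function(n, sp) {
    toy_hosts(sprintf("%s_i%02d", sp, seq_len(n)), sp)
  })
  dissection_data(hosts)
}

test_that("the minimum-sample-size filter keeps only host species with enough individuals", {
  d <- make_counts_dataset(c(A = 12, B = 9, C = 10))
  out <- apply_inclusion_filters(d, filter_spec(min_individuals = 10))
  expect_setequal(unique(out$hosts$host_species), c("A", "C"))
  # the filter counts dissected individuals, infected or not
  expect_equal(nrow(out$hosts), 22)
})

test_that("inclusion filtering is an idempotent, monotone contraction that logs provenance", {
  d <- simulate_dataset(compact_sim_config(), seed = 3)
  spec <- filter_spec()
  once <- apply_inclusion_filters(d, spec)
  twice <- apply_inclusion_filters(once, spec)
  expect_equal(once$hosts, twice$hosts)
  expect_equal(once$observations, twice$observations)
  expect_lte(nrow(once$hosts), nrow(d$hosts))
  expect_lte(nrow(once$observations), nrow(d$observations))
  expect_lte(nrow(once$annotations), nrow(d$annotations))
  expect_gt(length(once$provenance), length(d$provenance))
  expect_gt(length(twice$provenance), length(once$provenance))
})

test_that("morphogroups outside the focal parasite taxa are removed", {
  hosts <- toy_hosts(sprintf("h%02d", 1:10), "spA")
  ann <- dplyr::bind_rows(
    toy_ann("mg_trem"),
    toy_ann("mg_nemertean", taxon = "Nemertea"))  # non-focal symbiont
  obs <- dplyr::bind_rows(toy_obs("h01", "mg_trem"), toy_obs("h02", "mg_nemertean"))
  d <- dissection_data(hosts, obs, ann)
  out <- apply_inclusion_filters(d, filter_spec())
  expect_false("mg_nemertean" %in% out$annotations$morphogroup_id)
  expect_false("mg_nemertean" %in% out$observations$morphogroup_id)
  expect_true("mg_trem" %in% out$annotations$morphogroup_id)
})

test_that("filters that remove everything raise an explicit empty-result error", {
  d <- make_counts_dataset(c(A = 5))
  expect_error(apply_inclusion_filters(d, filter_spec(min_individuals = 10)),
               class = "paradiv_empty_error")
})

test_that("partitioning splits fish from invertebrates and conserves records", {
  d <- simulate_dataset(sim_config(), seed = 5)
  parts <- partition_hosts(d)
  expect_setequal(unique(parts$fish$hosts$host_group), "fish")
  expect_setequal(unique(parts$invertebrate$hosts$host_group),
                  c("crustacean", "mollusk", "polychaete"))
  expect_equal(nrow(parts$fish$hosts) + nrow(parts$invertebrate$hosts),
               nrow(d$hosts))
  expect_setequal(c(parts$fish$hosts$host_individual_id,
                    parts$invertebrate$hosts$host_individual_id),
                  d$hosts$host_individual_id)
  # vent column of the default structure: 2 fish species, 26 invertebrate
  vent_fish <- dplyr::filter(parts$fish$hosts, ecosystem == "vent")
  vent_inv <- dplyr::filter(parts$invertebrate$hosts, ecosystem == "vent")
  expect_equal(dplyr::n_distinct(vent_fish$host_species), 2)
  expect_equal(dplyr::n_distinct(vent_inv$host_species), 26)

  all_fish <- make_counts_dataset(c(A = 3))
  expect_equal(nrow(partition_hosts(all_fish)$invertebrate$hosts), 0)
})

test_that("redundant life stages are reduced to one morphogroup, preferring the adult", {
  hosts <- toy_hosts(c("h1", "h2"), c("spA", "spB"))
  ann <- toy_ann(c("trem_adult", "trem_meta"),
                 life_stage = c("adult", "metacercaria"),
                 redundancy = "trem_X")
  obs <- dplyr::bind_rows(toy_obs("h1", "trem_adult"), toy_obs("h2", "trem_meta"))
  out <- drop_redundant_stages(dissection_data(hosts, obs, ann))
  expect_equal(out$annotations$morphogroup_id, "trem_adult")
  expect_equal(out$observations$morphogroup_id, "trem_adult")

  # no shared redundancy groups: identity apart from provenance
  d2 <- dissection_data(hosts, obs,
                        toy_ann(c("trem_adult", "trem_meta"),
                                life_stage = c("adult", "metacercaria")))
  out2 <- drop_redundant_stages(d2)
  expect_equal(out2$annotations, d2$annotations)
  expect_equal(out2$observations, d2$observations)

  # three larval stages sharing a group, no adult: lexicographically first kept
  ann3 <- toy_ann(c("meta_c", "meta_a", "meta_b"),
                  life_stage = "metacercaria", redundancy = "grp")
  obs3 <- toy_obs(c("h1", "h1", "h2"), c("meta_c", "meta_a", "meta_b"))
  out3 <- drop_redundant_stages(dissection_data(hosts, obs3, ann3))
  expect_equal(out3$annotations$morphogroup_id, "meta_a")
})

test_that("redundancy removal only considers morphogroups present in the partition", {
  # the adult stage sits in fish; within the invertebrate partition the
  # metacercaria has no redundant partner and must be kept
  hosts <- toy_hosts(c("f1", "c1"), c("fishA", "crabA"),
                     group = c("fish", "crustacean"))
  ann <- toy_ann(c("trem_adult", "trem_meta"),
                 life_stage = c("adult", "metacercaria"), redundancy = "trem_X")
  obs <- dplyr::bind_rows(toy_obs("f1", "trem_adult"), toy_obs("c1", "trem_meta"))
  parts <- partition_hosts(dissection_data(hosts, obs, ann))
  inv <- drop_redundant_stages(parts$invertebrate)
  expect_true("trem_meta" %in% inv$observations$morphogroup_id)
})
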