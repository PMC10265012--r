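test_that("incidence matrices are binary with uninfected hosts as all-zero rows", {
  hosts <- toy_hosts(c("h1", "h2", "h3"), c("spA", "spA", "spB"))
  obs <- dplyr::bind_rows(toy_obs("h1", "P1", 5), toy_obs("h1", "P1", 1))
  d <- dissection_data(hosts, obs, toy_ann("P1"))
  m <- build_incidence(d, "host_individual")
  expect_equal(m$m, 3)
  expect_equal(unname(m$incidence[, "P1"]), c(1L, 0L, 0L))  # binary, not 6

  # species level: a morphogroup in both species has incidence frequency 2
  obs2 <- dplyr::bind_rows(toy_obs("h1", "P1"), toy_obs("h3", "P1"),
                           toy_obs("h2", "P2"))
  d2 <- dissection_data(hosts, obs2, toy_ann(c("P1", "P2")))
  ms <- build_incidence(d2, "host_species")
  expect_equal(ms$m, 2)
  expect_equal(sum(ms$incidence[, "P1"]), 2)
  expect_equal(sum(ms$incidence[, "P2"]), 1)

  expect_error(build_incidence(dissection_data(toy_hosts(character(), character()))),
               class = "paradiv_empty_error")
})

test_that("chao2 matches the closed-form estimator in both variants", {
  # S_obs = 5, Q1 = 2, Q2 = 1 on a constructed 4-unit matrix
  inc <- rbind(c(1, 1, 1, 1, 0),
               c(1, 1, 1, 0, 1),
               c(1, 1, 0, 0, 0),
               c(1, 0, 0, 0, 0))
  est_c <- chao2(inc, "classic")
  expect_equal(est_c[c("s_obs", "q1", "q2")],
               tibble::tibble(s_obs = 5L, q1 = 2L, q2 = 1L))
  expect_equal(est_c$estimate, 5 + 4 / 2)                   # 7.0
  expect_equal(chao2(inc, "bias_corrected")$estimate, 5 + 2 * 1 / (2 * 2))  # 5.5

  # every morphogroup in >= 3 units: estimator reduces to S_obs
  inc2 <- matrix(1, nrow = 3, ncol = 4)
  expect_equal(chao2(inc2, "classic")$estimate, 4)

  # classic falls back to the bias-corrected term when Q2 = 0
  inc3 <- rbind(c(1, 1, 0), c(0, 1, 0), c(0, 1, 1))  # q1 = 2, q2 = 0, s = 3
  expect_equal(chao2(inc3, "classic")$estimate, 3 + 2 * 1 / 2)
  # small-sample factor on request
  expect_equal(chao2(inc3, "classic", small_sample = TRUE)$estimate,
               3 + (2 / 3) * 2 * 1 / 2)

  # zero morphogroups: richness 0, not an error
  expect_equal(chao2(matrix(0L, 4, 0))$estimate, 0)
  expect_gte(chao2(inc)$estimate, est_c$s_obs)
})

test_that("chao2 agrees with vegan's incidence-based Chao estimator", {
  withr::with_seed(7, {
    for (i in 1:10) {
      m <- matrix(rbinom(8 * 12, 1, 0.25), nrow = 8)
      if (!any(colSums(m) > 0)) next
      ours <- chao2(m, "classic", small_sample = TRUE)$estimate
      ref <- vegan::specpool(m)$chao
      expect_equal(ours, ref, tolerance = 1e-9)
    }
  })
})

test_that("per-host-species summaries compose the chao2 kernel correctly", {
  d <- simulate_dataset(compact_sim_config(), seed = 21)
  s <- host_species_summaries(d)
  expect_equal(nrow(s), dplyr::n_distinct(d$hosts$host_species))
  for (sp in sample(s$host_species, 5)) {
    sub <- d
    sub$hosts <- dplyr::filter(d$hosts, host_species == sp)
    sub$observations <- dplyr::semi_join(d$observations, sub$hosts,
                                         by = "host_individual_id")
    direct <- chao2(build_incidence(sub, "host_individual"))
    row <- s[s$host_species == sp, ]
    expect_equal(row$chao2_estimate, direct$estimate)
    expect_equal(row$s_obs, direct$s_obs)
    expect_equal(row$n_individuals, direct$m)
  }
  # uninfected species have estimate 0; all-singleton species exceed s_obs
  hosts <- toy_hosts(sprintf("h%02d", 1:10), "clean")
  expect_equal(host_species_summaries(dissection_data(hosts))$chao2_estimate, 0)
  obs <- toy_obs(c("h01", "h02"), c("P1", "P2"))
  d2 <- dissection_data(hosts, obs, toy_ann(c("P1", "P2")))
  s2 <- host_species_summaries(d2)
  expect_gt(s2$chao2_estimate, s2$s_obs)
})

test_that("the accumulation curve reproduces exhaustive subset enumeration", {
  # h = (1, 2, 4) over H = 4 host species, worked by hand
  inc <- rbind(c(1, 1, 1), c(0, 1, 1), c(0, 0, 1), c(0, 0, 1))
  curve <- accumulation_curve(inc)
  expect_equal(curve$expected[1], 7 / 4)
  expect_equal(curve$expected[2], 14 / 6)
  expect_equal(curve$expected[4], 3)  # full sample recovers all morphogroups
  expect_equal(accumulation_oracle(inc, 2), 14 / 6)
  expect_error(accumulation_curve(inc, k = 5), class = "paradiv_argument_error")
  expect_error(accumulation_oracle(matrix(1, 60, 2), 30),
               class = "paradiv_argument_error")  # enumeration guard

  withr::with_seed(11, {
    for (i in 1:20) {
      m <- matrix(rbinom(6 * 5, 1, 0.4), nrow = 6)
      if (!any(colSums(m) > 0)) next
      curve <- accumulation_curve(m)
      oracle <- vapply(1:6, function(k) accumulation_oracle(m, k), numeric(1))
      expect_equal(curve$expected, oracle, tolerance = 1e-9)
      # concavity: second differences non-positive
      if (nrow(m) >= 3) {
        d2 <- diff(curve$expected, differences = 2)
        expect_true(all(d2 <= 1e-9))
      }
      # independent reference implementation
      ref <- vegan::specaccum(m, method = "exact")$richness
      expect_equal(curve$expected, ref, tolerance = 1e-9)
    }
  })
})

test_that("accumulation handles large host counts via log-safe binomials", {
  withr::with_seed(3, {
    m <- matrix(rbinom(2000 * 30, 1, 0.02), nrow = 2000)
    curve <- accumulation_curve(m, k = c(1, 10, 100, 1000, 2000))
    expect_true(all(is.finite(curve$expected)))
    expect_true(all(diff(curve$expected) >= -1e-9))
    expect_equal(curve$expected[5], sum(colSums(m) > 0))
  })
})

test_that("Monte-Carlo variance is attached, labelled, and seed-stable", {
  inc <- rbind(c(1, 1, 0), c(0, 1, 1), c(1, 0, 0), c(0, 1, 0))
  c1 <- accumulation_curve(inc, mc_variance = TRUE, seed = 5)
  c2 <- accumulation_curve(inc, mc_variance = TRUE, seed = 5)
  expect_identical(c1$variance, c2$variance)
  expect_identical(attr(c1, "variance_method"), "monte_carlo")
  expect_equal(c1$variance[4], 0)  # full sample has no sampling variance
})

test_that("chao2 reduces bias relative to observed richness on synthetic species", {
  # 500 replicate species, 50 individuals, 20 true morphogroups, sparse detection
  withr::with_seed(99, {
    s_true <- 20; n <- 50; p <- 0.03
    est <- t(vapply(1:500, function(i) {
      m <- matrix(rbinom(n * s_true, 1, p), nrow = n)
      c(obs = sum(colSums(m) > 0), chao = chao2(m)$estimate)
    }, numeric(2)))
    bias_obs <- abs(mean(est[, "obs"]) - s_true)
    bias_chao <- abs(mean(est[, "chao"]) - s_true)
    expect_lt(bias_chao, bias_obs)
  })
})
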