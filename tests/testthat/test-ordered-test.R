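test_that("midrank averages ties and always sums to n(n+1)/2", {
  expect_equal(midrank(c(3.2, 1.1, 9.9)), c(2, 1, 3))
  expect_equal(midrank(c(5, 5, 7)), c(1.5, 1.5, 3))
  expect_error(midrank(numeric()), class = "paradiv_argument_error")
  withr::with_seed(1, {
    for (i in 1:100) {
      n <- sample(2:40, 1)
      x <- sample(c(stats::rnorm(n - 2), 0, 0))  # guaranteed tie
      expect_equal(sum(midrank(x)), n * (n + 1) / 2)
    }
  })
})

test_that("degenerate fits behave as expected", {
  # response ranks equal to the scores, one group, constant covariate: R^2 = 1
  s <- toy_summaries(lengths = 100)
  s$chao2_estimate <- unname(ordered_scores()[s$ecosystem]) * 2
  fit <- fit_rank_ancova(s)
  expect_equal(fit$r_squared, 1)
  expect_gt(fit$t_obs, 0)

  # constant response: zero slope and zero R^2
  s2 <- toy_summaries(chao2 = 5, lengths = 100)
  fit2 <- fit_rank_ancova(s2)
  expect_equal(fit2$t_obs, 0)
  expect_equal(fit2$r_squared, 0)
  pt2 <- permutation_test(s2, b = 99, seed = 1)
  expect_equal(pt2$p_value, 1)

  # single ecosystem: the ordered score is inestimable
  s3 <- toy_summaries(ecosystems = "vent")
  expect_error(fit_rank_ancova(s3), class = "paradiv_estimation_error")
})

test_that("the fit matches an independent normal-equations solve", {
  s <- toy_summaries(n_per_cell = 2, groups = c("fish", "mollusk"), seed = 42)
  fit <- fit_rank_ancova(s)
  # independent solve of the normal equations on the same model
  y <- rank(s$chao2_estimate)
  X <- cbind(1, s$host_group == "mollusk", rank(s$mean_length),
             ordered_scores()[s$ecosystem])
  beta <- solve(t(X) %*% X, t(X) %*% y)
  expect_equal(fit$t_obs, beta[4], tolerance = 1e-10)
  r2 <- 1 - sum((y - X %*% beta)^2) / sum((y - mean(y))^2)
  expect_equal(fit$r_squared, r2, tolerance = 1e-10)
  expect_lte(fit$r_squared_reduced, fit$r_squared)
  # tidy/glance accessors
  expect_true(all(c("term", "estimate") %in% names(tidy(fit))))
  expect_equal(glance(fit)$t_obs, fit$t_obs)
})

test_that("t_obs is invariant to the host-group reference cell", {
  s <- toy_summaries(n_per_cell = 2, groups = c("fish", "mollusk"), seed = 8)
  fit1 <- fit_rank_ancova(s)
  # relabel groups so the alphabetical reference flips
  s2 <- dplyr::mutate(s, host_group = ifelse(host_group == "fish", "zfish", "afish"))
  fit2 <- fit_rank_ancova(s2)
  expect_equal(fit1$t_obs, fit2$t_obs, tolerance = 1e-10)
  expect_equal(fit1$r_squared, fit2$r_squared, tolerance = 1e-10)
})

test_that("Monte-Carlo p matches exhaustive enumeration on the 6-species toy", {
  # one host group, three ecosystems x two species: 6!/(2!2!2!) = 90 distinct
  # label assignments, enumerated directly with nested combinations
  s <- toy_summaries(n_per_cell = 2, seed = 31)
  fit <- fit_rank_ancova(s)
  y <- rank(s$chao2_estimate)
  X <- cbind(1, rank(s$mean_length))
  qx <- qr(X)
  y_res <- qr.resid(qx, y)
  coef_for <- function(labels) {
    sc <- qr.resid(qx, unname(ordered_scores()[labels]))
    sum(y_res * sc) / sum(sc^2)
  }
  t_all <- c()
  for (v in asplit(combn(1:6, 2), 2)) {
    rest <- setdiff(1:6, v)
    for (a in asplit(combn(rest, 2), 2)) {
      labels <- character(6)
      labels[v] <- "vent"; labels[a] <- "atoll"
      labels[setdiff(rest, a)] <- "kelp"
      t_all <- c(t_all, coef_for(labels))
    }
  }
  expect_length(t_all, 90)
  p_exact <- mean(t_all >= fit$t_obs - 1e-12)
  pt <- permutation_test(s, b = 10000, seed = 2)
  expect_equal(pt$t_obs, fit$t_obs, tolerance = 1e-12)
  expect_lt(abs(pt$p_value - p_exact), 0.02)
})

test_that("the permutation null is deterministic given the seed and respects strata", {
  # stratum 'b' species all share one ecosystem: any cross-stratum mixing
  # would produce t* values outside the within-stratum enumeration
  s <- dplyr::bind_rows(
    toy_summaries(n_per_cell = 1, groups = "fish", seed = 5),
    dplyr::mutate(toy_summaries(n_per_cell = 3, groups = "mollusk",
                                ecosystems = "vent", seed = 6),
                  host_species = paste0("m", host_species)))
  pt1 <- permutation_test(s, b = 300, seed = 9)
  pt2 <- permutation_test(s, b = 300, seed = 9)
  expect_identical(pt1$null_distribution, pt2$null_distribution)

  # enumerate every within-stratum assignment: 3! = 6 for the fish stratum,
  # the mollusk stratum is fixed
  y <- rank(s$chao2_estimate)
  X <- cbind(1, s$host_group == "mollusk", rank(s$mean_length))
  qx <- qr(X); y_res <- qr.resid(qx, y)
  fish_idx <- which(s$host_group == "fish")
  base_sc <- unname(ordered_scores()[s$ecosystem])
  t_set <- apply(rbind(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2), c(3,2,1)),
                 1, function(perm) {
    sc <- base_sc
    sc[fish_idx] <- sc[fish_idx][perm]
    scr <- qr.resid(qx, sc)
    sum(y_res * scr) / sum(scr^2)
  })
  expect_true(all(vapply(pt1$null_distribution, function(t) {
    min(abs(t - t_set)) < 1e-9
  }, logical(1))))

  # p is never 0 and never above 1
  expect_gte(pt1$p_value, 1 / (pt1$b + 1))
  expect_lte(pt1$p_value, 1)
})

test_that("the test is one-sided in the hypothesized direction", {
  s <- toy_summaries(n_per_cell = 6, seed = 13)
  s$chao2_estimate <- unname(ordered_scores()[s$ecosystem]) * 3 +
    withr::with_seed(14, stats::rnorm(nrow(s), 0, 0.5))
  p_fwd <- permutation_test(s, b = 499, seed = 3)$p_value
  p_rev <- permutation_test(s, scores = ordered_scores(c("kelp", "atoll", "vent")),
                            b = 499, seed = 3)$p_value
  expect_lt(p_fwd, 0.05)
  expect_gt(p_rev, 0.5)
})

test_that("species without a length covariate are excluded with a warning", {
  s <- toy_summaries(n_per_cell = 2, seed = 4)
  s$mean_length[1] <- NA
  expect_warning(fit1 <- fit_rank_ancova(s), "without mean_length")
  expect_equal(fit1$n, nrow(s) - 1)
  # with covariate = "none" nothing is dropped
  fit2 <- fit_rank_ancova(s, covariate = "none")
  expect_equal(fit2$n, nrow(s))
})
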