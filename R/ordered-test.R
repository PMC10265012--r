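# Ordered ecosystem hypothesis test: a nonparametric rank ANCOVA whose
# ecosystem term is an ordered score, with significance from a stratified
# permutation null (ecosystem labels shuffled among host species within each
# host group).

#' Midranks
#'
#' Ranks with ties replaced by their average (midranks) — the rank transform
#' underlying the rank ANCOVA. The rank sum is always `n (n + 1) / 2`.
#'
#' @param x Numeric vector.
#' @return Numeric vector of midranks.
#' @export
#' @examples
#' midrank(c(5, 5, 7))
midrank <- function(x) {
  if (!length(x)) abort("midrank of an empty vector", class = "paradiv_argument_error")
  rank(x, ties.method = "average")
}

#' Ordered ecosystem scores
#'
#' Encodes an ordered alternative hypothesis as equally spaced integer scores:
#' ecosystems listed from hypothesized lowest to hypothesized highest richness
#' receive scores 1, 2, .... Under the island-biogeography expectation that
#' richness is lowest in the most isolated, most disturbed habitat, the
#' default ordering is `vent < atoll < kelp`. Any strictly monotone named
#' numeric vector is accepted wherever scores are needed.
#'
#' @param ordering Character vector of ecosystem labels from hypothesized
#'   lowest to highest richness.
#' @return Named integer vector of scores.
#' @export
#' @examples
#' ordered_scores(c("vent", "atoll", "kelp"))
ordered_scores <- function(ordering = c("vent", "atoll", "kelp")) {
  if (anyDuplicated(ordering)) {
    abort("ecosystem ordering contains duplicates", class = "paradiv_config_error")
  }
  setNames(seq_along(ordering), ordering)
}

# Response, fixed design block, and score column for the rank model.
# Ecosystem enters only through the ordered score; host group enters as
# reference-cell dummies (alphabetically first level as reference), the
# covariate as the midrank of mean host species length.
rank_ancova_design <- function(summaries, scores,
                               covariate = c("rank_length", "none")) {
  covariate <- match.arg(covariate)
  s <- tibble::as_tibble(summaries)
  need <- c("host_species", "host_group", "ecosystem", "chao2_estimate")
  miss <- setdiff(need, names(s))
  if (length(miss)) {
    abort(paste0("summaries are missing column(s): ", paste(miss, collapse = ", ")),
          class = "paradiv_format_error")
  }
  bad_eco <- setdiff(unique(s$ecosystem), names(scores))
  if (length(bad_eco)) {
    abort(paste0("no ordered score for ecosystem(s): ",
                 paste(bad_eco, collapse = ", ")),
          class = "paradiv_config_error")
  }
  if (covariate == "rank_length") {
    drop <- is.na(s$mean_length)
    if (any(drop)) {
      warn(paste0("excluding ", sum(drop),
                  " host species without mean_length from the rank ANCOVA"))
      s <- s[!drop, , drop = FALSE]
    }
  }
  if (dplyr::n_distinct(s$ecosystem) < 2) {
    abort("rank ANCOVA needs >= 2 ecosystems; the ordered score is constant",
          class = "paradiv_estimation_error")
  }
  y <- midrank(s$chao2_estimate)
  groups <- sort(unique(s$host_group))
  X <- matrix(1, nrow = nrow(s), ncol = 1, dimnames = list(NULL, "(Intercept)"))
  if (length(groups) > 1) {
    for (g in groups[-1]) {
      X <- cbind(X, as.numeric(s$host_group == g))
      colnames(X)[ncol(X)] <- paste0("host_group", g)
    }
  }
  if (covariate == "rank_length") {
    X <- cbind(X, rank_length = midrank(s$mean_length))
  }
  list(y = y, X = X, score = unname(scores[s$ecosystem]),
       host_group = s$host_group, ecosystem = s$ecosystem,
       summaries = s, covariate = covariate)
}

ls_fit <- function(X, y) {
  qx <- qr(X)
  coefs <- qr.coef(qx, y)        # NA for aliased columns, original order
  res <- qr.resid(qx, y)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(res^2) / sst else 0
  list(coefficients = setNames(as.numeric(coefs), colnames(X)),
       residuals = res, r_squared = r2, rank = qx$rank)
}

#' Fit the rank ANCOVA for the ordered ecosystem hypothesis
#'
#' Least-squares fit of the midrank of the per-host-species Chao2 richness
#' estimate on host-group indicator contrasts, the midrank of mean host
#' species length, and an ordered ecosystem score. The coefficient on the
#' score (`t_obs`) is the ordered-effect statistic: positive when richness
#' increases along the hypothesized ordering. Its permutation distribution is
#' produced by [permutation_test()]; the least-squares fit itself carries no
#' distributional claim.
#'
#' @param summaries A tibble from [host_species_summaries()] (or any tibble
#'   with `host_species`, `host_group`, `ecosystem`, `chao2_estimate`, and
#'   `mean_length` when the covariate is used).
#' @param scores Named numeric vector of ordered ecosystem scores, see
#'   [ordered_scores()].
#' @param covariate `"rank_length"` (default) to adjust for the midrank of
#'   mean host species length, or `"none"`. Species without a length are
#'   excluded with a warning — imputing one would inject an untestable
#'   assumption.
#' @return A `rank_ancova` object with `t_obs`, `r_squared` (full model),
#'   `r_squared_reduced` (model without the ordered score), `coefficients`,
#'   `residuals` and `n`. Has [tidy()] and [glance()] methods.
#' @export
fit_rank_ancova <- function(summaries, scores = ordered_scores(),
                            covariate = c("rank_length", "none")) {
  d <- rank_ancova_design(summaries, scores, covariate)
  Xf <- cbind(d$X, ordered_score = d$score)
  full <- ls_fit(Xf, d$y)
  if (is.na(full$coefficients["ordered_score"])) {
    abort(paste0("singular rank-ANCOVA design: the ordered ecosystem score ",
                 "is collinear with the other terms (e.g. only one ecosystem ",
                 "per host group)"),
          class = "paradiv_estimation_error")
  }
  reduced <- ls_fit(d$X, d$y)
  structure(list(t_obs = unname(full$coefficients["ordered_score"]),
                 r_squared = full$r_squared,
                 r_squared_reduced = reduced$r_squared,
                 coefficients = full$coefficients,
                 residuals = full$residuals,
                 n = length(d$y), scores = scores, covariate = d$covariate),
            class = "rank_ancova")
}

#' @export
print.rank_ancova <- function(x, ...) {
  cat("<rank_ancova>\n")
  cat(sprintf("  n = %d host species; covariate = %s\n", x$n, x$covariate))
  cat(sprintf("  ordered-effect coefficient t_obs = %.4f\n", x$t_obs))
  cat(sprintf("  R^2 (full) = %.3f; R^2 (without ordered score) = %.3f\n",
              x$r_squared, x$r_squared_reduced))
  invisible(x)
}

#' @method tidy rank_ancova
#' @export
tidy.rank_ancova <- function(x, ...) {
  tibble::tibble(term = names(x$coefficients),
                 estimate = unname(x$coefficients))
}

#' @method glance rank_ancova
#' @export
glance.rank_ancova <- function(x, ...) {
  tibble::tibble(t_obs = x$t_obs, r_squared = x$r_squared,
                 r_squared_reduced = x$r_squared_reduced, n = x$n)
}

#' Stratified permutation test of the ordered ecosystem hypothesis
#'
#' Assesses the ordered-effect statistic of [fit_rank_ancova()] against a
#' null built by randomizing the assignment of host species to ecosystems
#' *within host groups*: each permutation shuffles the ecosystem labels among
#' the species of a host group, preserving the per-group multiset of labels,
#' then refits the model. The one-sided p-value uses the add-one estimator
#' `p = (1 + #\{t* >= t_obs\}) / (b + 1)`, which can never be exactly zero and
#' counts ties as exceedances.
#'
#' @inheritParams fit_rank_ancova
#' @param b Number of randomizations (default 9999).
#' @param seed Integer seed; the null distribution is bit-reproducible given
#'   the seed.
#' @param stratified If `TRUE` (default) labels are permuted within host
#'   groups; `FALSE` permutes across the whole table (sensitivity analysis).
#' @return A `rank_ancova_perm` object: `t_obs`, `r_squared`,
#'   `r_squared_reduced`, `p_value`, `b`, `seed`, `null_distribution`, and
#'   `strata` (per-host-group ecosystem label counts). Has [tidy()] and
#'   [glance()] methods.
#' @export
permutation_test <- function(summaries, scores = ordered_scores(),
                             b = 9999L, seed = 1L,
                             covariate = c("rank_length", "none"),
                             stratified = TRUE) {
  b <- as.integer(b)
  if (is.na(b) || b < 1L) abort("b must be >= 1", class = "paradiv_argument_error")
  d <- rank_ancova_design(summaries, scores, covariate)
  strata <- if (stratified) d$host_group else rep("all", length(d$y))
  permutable <- tapply(d$ecosystem, strata, dplyr::n_distinct)
  if (!any(permutable > 1)) {
    abort("no stratum contains more than one ecosystem; nothing to permute",
          class = "paradiv_estimation_error")
  }
  Xf <- cbind(d$X, ordered_score = d$score)
  full <- ls_fit(Xf, d$y)
  reduced <- ls_fit(d$X, d$y)
  if (is.na(full$coefficients["ordered_score"])) {
    abort("singular rank-ANCOVA design: the ordered score is collinear with the other terms",
          class = "paradiv_estimation_error")
  }
  t_obs <- unname(full$coefficients["ordered_score"])

  # Frisch-Waugh: with the non-score design block fixed across permutations,
  # the score coefficient is <resid(y), resid(score)> / ||resid(score)||^2
  # with residuals taken against that fixed block.
  qx <- qr(d$X)
  y_res <- qr.resid(qx, d$y)
  fwl_coef <- function(sc) {
    sc_res <- qr.resid(qx, sc)
    den <- sum(sc_res^2)
    if (den <= 1e-12 * sum(sc^2)) 0 else sum(y_res * sc_res) / den
  }
  idx_by_stratum <- split(seq_along(d$y), strata)
  score0 <- d$score
  local_rng(seed)
  t_null <- vapply(seq_len(b), function(i) {
    sc <- score0
    for (idx in idx_by_stratum) {
      if (length(idx) > 1) sc[idx] <- sc[idx][sample.int(length(idx))]
    }
    fwl_coef(sc)
  }, numeric(1))
  # ties (within floating-point noise of t_obs) count as exceedances
  tol <- 1e-9 * (1 + abs(t_obs))
  p <- (1 + sum(t_null >= t_obs - tol)) / (b + 1)

  strata_tbl <- tibble::as_tibble(d$summaries) |>
    dplyr::count(.data$host_group, .data$ecosystem, name = "n_species")
  structure(list(t_obs = t_obs, r_squared = full$r_squared,
                 r_squared_reduced = reduced$r_squared,
                 p_value = p, b = b, seed = as.integer(seed),
                 null_distribution = t_null, strata = strata_tbl,
                 scores = scores, covariate = d$covariate,
                 stratified = stratified, n = length(d$y)),
            class = "rank_ancova_perm")
}

#' @export
print.rank_ancova_perm <- function(x, ...) {
  cat("<rank_ancova_perm>\n")
  cat(sprintf("  n = %d host species; b = %d randomizations (seed %d)\n",
              x$n, x$b, x$seed))
  cat(sprintf("  t_obs = %.4f; R^2 = %.3f; one-sided p = %.4g\n",
              x$t_obs, x$r_squared, x$p_value))
  invisible(x)
}

#' @method tidy rank_ancova_perm
#' @export
tidy.rank_ancova_perm <- function(x, ...) {
  tibble::tibble(term = "ordered_score", estimate = x$t_obs,
                 p.value = x$p_value, b = x$b)
}

#' @method glance rank_ancova_perm
#' @export
glance.rank_ancova_perm <- function(x, ...) {
  tibble::tibble(t_obs = x$t_obs, r_squared = x$r_squared,
                 r_squared_reduced = x$r_squared_reduced,
                 p_value = x$p_value, b = x$b, seed = x$seed, n = x$n)
}
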