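# Incidence-based richness: binary incidence matrices, the Chao2 estimator of
# richness within host species, and analytic sample-based accumulation curves
# across host species.

#' Build a binary incidence matrix
#'
#' Converts a dissection dataset into the presence/absence structure all
#' richness estimation runs on: sampling units (host individuals, or host
#' species) by morphogroups, entry 1 iff the morphogroup was detected at
#' least once in the unit. Counts are deliberately discarded — the estimators
#' are incidence-based. Units with no observations (dissected but uninfected
#' hosts) appear as all-zero rows; they carry information through the number
#' of sampling units `m`.
#'
#' @param x A `dissection_data` object with at least one host record.
#' @param level `"host_individual"` (the unit for within-host-species Chao2)
#'   or `"host_species"` (the unit for across-species accumulation curves).
#' @return An `incidence_matrix`: a list with the binary `incidence` matrix
#'   (units in rows), `sampling_unit_ids`, `morphogroup_ids`, `m` (number of
#'   units) and `level`.
#' @export
build_incidence <- function(x, level = c("host_individual", "host_species")) {
  stopifnot(inherits(x, "dissection_data"))
  level <- match.arg(level)
  if (!nrow(x$hosts)) {
    abort("cannot build an incidence matrix from an empty dataset",
          class = "paradiv_empty_error")
  }
  unit_of <- if (level == "host_individual") {
    setNames(x$hosts$host_individual_id, x$hosts$host_individual_id)
  } else {
    setNames(x$hosts$host_species, x$hosts$host_individual_id)
  }
  units <- sort(unique(unname(unit_of)))
  mgs <- sort(unique(x$observations$morphogroup_id))
  inc <- matrix(0L, nrow = length(units), ncol = length(mgs),
                dimnames = list(units, mgs))
  if (nrow(x$observations)) {
    pairs <- unique(data.frame(unit = unname(unit_of[x$observations$host_individual_id]),
                               mg = x$observations$morphogroup_id))
    inc[cbind(pairs$unit, pairs$mg)] <- 1L
  }
  structure(list(incidence = inc, sampling_unit_ids = units,
                 morphogroup_ids = mgs, m = length(units), level = level),
            class = "incidence_matrix")
}

#' @export
print.incidence_matrix <- function(x, ...) {
  cat(sprintf("<incidence_matrix> %d %s unit(s) x %d morphogroup(s)\n",
              x$m, x$level, length(x$morphogroup_ids)))
  invisible(x)
}

#' Chao2 incidence-based richness estimate
#'
#' Estimates true richness from the incidence frequencies of rarely detected
#' species: with `S_obs` observed morphogroups, `Q1` detected in exactly one
#' sampling unit and `Q2` in exactly two, the classic form is
#' `S_obs + Q1^2 / (2 Q2)` and the bias-corrected form
#' `S_obs + Q1 (Q1 - 1) / (2 (Q2 + 1))`. When `Q2 = 0` the classic form falls
#' back to the bias-corrected term (the standard Chao convention); when
#' `Q1 = 0` both reduce to `S_obs`. A matrix with zero morphogroups yields a
#' valid estimate of 0 — an uninfected host species has richness 0.
#'
#' @param x An `incidence_matrix` (from [build_incidence()]), or a bare
#'   binary matrix with sampling units in rows.
#' @param variant `"bias_corrected"` (default) or `"classic"`.
#' @param small_sample If `TRUE`, multiply the correction term by
#'   `(m - 1) / m`. Off by default.
#' @return A one-row tibble: `s_obs`, `q1`, `q2`, `estimate`, `variant`, `m`.
#' @export
#' @examples
#' m <- matrix(c(1, 0, 0,   1, 1, 0,   1, 1, 1), nrow = 3, byrow = TRUE)
#' chao2(m, variant = "classic")
chao2 <- function(x, variant = c("bias_corrected", "classic"),
                  small_sample = FALSE) {
  variant <- match.arg(variant)
  inc <- if (inherits(x, "incidence_matrix")) x$incidence else as.matrix(x)
  if (!all(inc %in% c(0L, 1L))) {
    abort("incidence entries must be 0/1", class = "paradiv_format_error")
  }
  m <- nrow(inc)
  if (m < 1L) abort("need at least one sampling unit", class = "paradiv_empty_error")
  freq <- colSums(inc)
  freq <- freq[freq > 0]
  chao2_from_freq(length(freq), sum(freq == 1), sum(freq == 2),
                  m = m, variant = variant, small_sample = small_sample)
}

# Shared kernel so per-species summaries can run on aggregated frequencies
# without materializing one matrix per species.
chao2_from_freq <- function(s_obs, q1, q2, m, variant, small_sample = FALSE) {
  k <- if (small_sample && m > 0) (m - 1) / m else 1
  correction <- if (q1 == 0) {
    0
  } else if (variant == "classic" && q2 > 0) {
    q1^2 / (2 * q2)
  } else {
    q1 * (q1 - 1) / (2 * (q2 + 1))
  }
  tibble::tibble(s_obs = as.integer(s_obs), q1 = as.integer(q1),
                 q2 = as.integer(q2), estimate = s_obs + k * correction,
                 variant = variant, m = as.integer(m))
}

#' Per-host-species richness summaries
#'
#' For every host species in a harmonized dataset, estimates parasite richness
#' from individual-level incidence with [chao2()] and attaches the covariate
#' and factor columns used by the ordered ecosystem test: host group,
#' ecosystem, number of dissected individuals, and mean host length over
#' individuals with a measured length.
#'
#' @param x A harmonized `dissection_data` object.
#' @param variant Chao2 variant, see [chao2()].
#' @param small_sample See [chao2()].
#' @return A tibble with one row per host species: `host_species`,
#'   `host_group`, `ecosystem`, `n_individuals`, `s_obs`, `q1`, `q2`,
#'   `chao2_estimate`, `mean_length`.
#' @export
host_species_summaries <- function(x, variant = c("bias_corrected", "classic"),
                                   small_sample = FALSE) {
  stopifnot(inherits(x, "dissection_data"))
  variant <- match.arg(variant)
  base <- x$hosts |>
    dplyr::group_by(.data$host_species, .data$host_group, .data$ecosystem) |>
    dplyr::summarise(n_individuals = dplyr::n(),
                     mean_length = mean(.data$host_length_mm, na.rm = TRUE),
                     .groups = "drop") |>
    dplyr::mutate(mean_length = ifelse(is.nan(.data$mean_length), NA_real_,
                                       .data$mean_length))
  # incidence frequency of each morphogroup within each host species
  freq <- x$observations |>
    dplyr::inner_join(dplyr::select(x$hosts, "host_individual_id", "host_species"),
                      by = "host_individual_id") |>
    dplyr::distinct(.data$host_species, .data$host_individual_id, .data$morphogroup_id) |>
    dplyr::count(.data$host_species, .data$morphogroup_id, name = "incidence")
  est <- freq |>
    dplyr::group_by(.data$host_species) |>
    dplyr::summarise(s_obs = dplyr::n(),
                     q1 = sum(.data$incidence == 1L),
                     q2 = sum(.data$incidence == 2L), .groups = "drop")
  out <- base |>
    dplyr::left_join(est, by = "host_species") |>
    tidyr::replace_na(list(s_obs = 0L, q1 = 0L, q2 = 0L))
  # vectorized form of chao2_from_freq (equivalence asserted in tests)
  k <- if (small_sample) (out$n_individuals - 1) / out$n_individuals else 1
  corr <- ifelse(out$q1 == 0, 0,
                 ifelse(variant == "classic" & out$q2 > 0,
                        out$q1^2 / (2 * out$q2),
                        out$q1 * (out$q1 - 1) / (2 * (out$q2 + 1))))
  out |>
    dplyr::mutate(chao2_estimate = .data$s_obs + k * corr) |>
    dplyr::select("host_species", "host_group", "ecosystem", "n_individuals",
                  "s_obs", "q1", "q2", "chao2_estimate", "mean_length") |>
    dplyr::arrange(.data$ecosystem, .data$host_group, .data$host_species)
}

#' Analytic species-accumulation curve
#'
#' Expected parasite richness in a random subset of k sampling units, in
#' closed form: with H units in total and morphogroup i present in `h_i` of
#' them, `E[S(k)] = sum_i (1 - choose(H - h_i, k) / choose(H, k))` — the
#' hypergeometric probability that a random k-subset contains morphogroup i,
#' summed over morphogroups. Used with host species as the sampling unit to
#' relate parasite richness to host richness. Binomial ratios are evaluated
#' through log-gamma differences, so curves are stable for H well past 10^3.
#'
#' An optional Monte-Carlo variance (resampled k-subsets) can be attached;
#' it is a simulation-based companion to the analytic mean, labelled as such
#' in the output.
#'
#' @param x An `incidence_matrix`, normally at `host_species` level.
#' @param k Integer vector of subset sizes, all in `1..H`. Default `1:H`.
#' @param mc_variance If `TRUE`, attach a Monte-Carlo variance column.
#' @param mc_reps Number of resampled subsets per k for the variance.
#' @param seed Seed for the Monte-Carlo variance resampling.
#' @return A tibble of class `accumulation_curve`: `k`, `expected`, and when
#'   requested `variance` (Monte-Carlo, `variance_method = "monte_carlo"`
#'   attribute).
#' @export
accumulation_curve <- function(x, k = NULL, mc_variance = FALSE,
                               mc_reps = 200L, seed = 1L) {
  inc <- if (inherits(x, "incidence_matrix")) x$incidence else as.matrix(x)
  H <- nrow(inc)
  if (H < 1L) abort("need at least one sampling unit", class = "paradiv_empty_error")
  h <- colSums(inc > 0)
  h <- h[h > 0]
  if (is.null(k)) k <- seq_len(H)
  k <- as.integer(k)
  if (any(k < 1L | k > H)) {
    abort(paste0("k must lie in 1..", H), class = "paradiv_argument_error")
  }
  expected <- vapply(k, function(kk) {
    sum(1 - exp(lchoose(H - h, kk) - lchoose(H, kk)))
  }, numeric(1))
  out <- tibble::tibble(k = k, expected = expected)
  if (mc_variance) {
    rng <- local_rng(seed)
    present <- inc[, colSums(inc > 0) > 0, drop = FALSE]
    out$variance <- vapply(k, function(kk) {
      s <- vapply(seq_len(mc_reps), function(i) {
        idx <- sample.int(H, kk)
        sum(colSums(present[idx, , drop = FALSE]) > 0)
      }, numeric(1))
      stats::var(s)
    }, numeric(1))
    attr(out, "variance_method") <- "monte_carlo"
  }
  class(out) <- c("accumulation_curve", class(out))
  out
}

#' Exhaustive-enumeration oracle for the accumulation curve
#'
#' Computes the mean richness over every k-subset of sampling units by brute
#' force. Exists purely as an independent check on [accumulation_curve()];
#' refuses instances with more than 10^5 subsets.
#'
#' @param x An `incidence_matrix` or binary matrix.
#' @param k Subset size.
#' @return The exact mean richness over all `choose(H, k)` subsets.
#' @export
accumulation_oracle <- function(x, k) {
  inc <- if (inherits(x, "incidence_matrix")) x$incidence else as.matrix(x)
  H <- nrow(inc)
  k <- as.integer(k)
  if (k < 1L || k > H) {
    abort(paste0("k must lie in 1..", H), class = "paradiv_argument_error")
  }
  if (choose(H, k) > 1e5) {
    abort("refusing to enumerate more than 1e5 subsets",
          class = "paradiv_argument_error")
  }
  subsets <- combn(H, k)
  mean(apply(subsets, 2, function(idx) {
    sum(colSums(inc[idx, , drop = FALSE]) > 0)
  }))
}

# Run code under a private RNG state so package randomness is reproducible
# from an explicit seed and never disturbs the caller's stream.
local_rng <- function(seed, env = parent.frame()) {
  withr::local_seed(as.integer(seed), .local_envir = env)
}
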