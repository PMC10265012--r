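# Synthetic dissection-data generator. Emulates the structure of multi-
# ecosystem host-dissection deposits: three ecosystems, four host groups,
# per-host-species sample sizes, per-individual parasite incidences by
# morphogroup with taxon/life-cycle/life-stage annotations, a host-size
# covariate, and an optional ordered ecosystem effect on parasite richness.

#' Simulation configuration
#'
#' Describes a synthetic multi-ecosystem dissection study. The defaults
#' emulate the comparative study the pipeline targets: ecosystems `vent`,
#' `atoll` and `kelp` (ordered by hypothesized increasing richness), host
#' species and individual counts per host group matching the published
#' per-ecosystem sampling margins (28, 44 and 28 host species; 2134, 2637 and
#' 678 individuals), a per-ecosystem parasite pool spanning the eight focal
#' taxa, and a moderate ordered ecosystem effect.
#'
#' @param ecosystems Ecosystem labels from hypothesized lowest to highest
#'   richness.
#' @param hosts Tibble with columns `ecosystem`, `host_group`, `n_species`,
#'   `n_individuals` (total dissected individuals for the group, distributed
#'   deterministically across its species). Default
#'   [default_host_structure()].
#' @param pool Tibble with columns `parasite_taxon`, `life_cycle`,
#'   `life_stage`, `n_morphogroups`: the per-ecosystem parasite pool before
#'   the ecosystem effect is applied. Default [default_parasite_pool()].
#' @param detection_prob Baseline per-individual detection probability of a
#'   compatible morphogroup (default 0.08, a typical dissection prevalence).
#' @param pool_model `"fixed"` (default): each ecosystem's pool has exactly
#'   the configured number of morphogroups per taxon/stage row; `"poisson"`:
#'   the number is drawn as Poisson with that mean. The Poisson pool with
#'   `specificity_breadth = 1` makes per-host-species richness independent
#'   draws, the regime in which permutation calibration is exact.
#' @param specificity_breadth Number of compatible host species per
#'   morphogroup (sampled uniformly among species of the stage's plausible
#'   host groups; default 2 — most metazoan parasites are host-specific).
#' @param effect Ordered ecosystem effect size (>= 0). Pool sizes and
#'   detection probabilities are multiplied by `(1 + effect)^(s - s_mid)`
#'   where `s` is the ecosystem's position in `ecosystems`; 0 means no
#'   ecosystem effect. Default 0.4.
#' @param redundancy_clusters Number of trematode species represented by
#'   linked adult + metacercaria morphogroups sharing a `redundancy_group`
#'   (the first cluster also includes the sporocyst stage when present).
#' @param length_meanlog Named numeric: per-host-group log-mean of species
#'   mean length (mm).
#' @param length_sdlog Log-sd of species mean length around the group mean.
#' @param length_richness_coef Optional linkage between log host species
#'   length and detection probability (0 = none): detection is scaled by
#'   `exp(coef * (log(length) - meanlog))`.
#' @param aggregation Host-level infection aggregation (>= 0): each host
#'   individual gets a gamma-distributed susceptibility multiplier with mean
#'   1 and variance `aggregation`, correlating infections within hosts
#'   (0 = independent, the default).
#' @param seed Default seed used by [simulate_dataset()].
#' @return A `sim_config` object.
#' @export
sim_config <- function(ecosystems = c("vent", "atoll", "kelp"),
                       hosts = default_host_structure(),
                       pool = default_parasite_pool(),
                       detection_prob = 0.08,
                       pool_model = c("fixed", "poisson"),
                       specificity_breadth = 2L,
                       effect = 0.4,
                       redundancy_clusters = 2L,
                       length_meanlog = c(crustacean = log(40), fish = log(150),
                                          mollusk = log(30), polychaete = log(25)),
                       length_sdlog = 0.5,
                       length_richness_coef = 0,
                       aggregation = 0,
                       seed = 1L) {
  pool_model <- match.arg(pool_model)
  cfg <- structure(list(ecosystems = ecosystems,
                        hosts = tibble::as_tibble(hosts),
                        pool = tibble::as_tibble(pool),
                        detection_prob = detection_prob,
                        pool_model = pool_model,
                        specificity_breadth = as.integer(specificity_breadth),
                        effect = effect,
                        redundancy_clusters = as.integer(redundancy_clusters),
                        length_meanlog = length_meanlog,
                        length_sdlog = length_sdlog,
                        length_richness_coef = length_richness_coef,
                        aggregation = aggregation,
                        seed = as.integer(seed)),
                   class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  bad <- function(field, why) {
    abort(paste0("invalid sim_config field '", field, "': ", why),
          class = "paradiv_config_error")
  }
  if (!length(cfg$ecosystems) || anyDuplicated(cfg$ecosystems)) {
    bad("ecosystems", "must be a non-empty set of distinct labels")
  }
  need_h <- c("ecosystem", "host_group", "n_species", "n_individuals")
  if (!all(need_h %in% names(cfg$hosts))) bad("hosts", "missing columns")
  if (!all(cfg$hosts$ecosystem %in% cfg$ecosystems)) {
    bad("hosts", "ecosystem labels outside the ecosystems field")
  }
  if (!all(cfg$hosts$host_group %in% host_groups())) bad("hosts", "unknown host group")
  if (any(cfg$hosts$n_species < 0) || any(cfg$hosts$n_individuals < 0)) {
    bad("hosts", "negative counts")
  }
  need_p <- c("parasite_taxon", "life_cycle", "life_stage", "n_morphogroups")
  if (!all(need_p %in% names(cfg$pool))) bad("pool", "missing columns")
  if (!all(cfg$pool$parasite_taxon %in% parasite_taxa())) bad("pool", "unknown taxon")
  if (!all(cfg$pool$life_cycle %in% life_cycles())) bad("pool", "unknown life cycle")
  if (!all(cfg$pool$life_stage %in% life_stages())) bad("pool", "unknown life stage")
  if (any(cfg$pool$n_morphogroups < 0)) bad("pool", "negative morphogroup counts")
  if (any(cfg$pool$life_cycle == "DLC" & cfg$pool$life_stage != "adult")) {
    bad("pool", "DLC entries must have life_stage 'adult'")
  }
  if (cfg$detection_prob < 0 || cfg$detection_prob > 1) {
    bad("detection_prob", "must lie in [0, 1]")
  }
  if (cfg$specificity_breadth < 1) bad("specificity_breadth", "must be >= 1")
  if (cfg$effect < 0) bad("effect", "must be >= 0")
  if (cfg$aggregation < 0) bad("aggregation", "must be >= 0")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat("  ecosystems (low -> high richness):", paste(x$ecosystems, collapse = " < "), "\n")
  cat(sprintf("  hosts: %d species, %d individuals; pool: %d morphogroups/ecosystem\n",
              sum(x$hosts$n_species), sum(x$hosts$n_individuals),
              sum(x$pool$n_morphogroups)))
  cat(sprintf("  detection_prob = %g, breadth = %d, effect = %g, seed = %d\n",
              x$detection_prob, x$specificity_breadth, x$effect, x$seed))
  invisible(x)
}

#' @rdname sim_config
#' @export
default_host_structure <- function() {
  tibble::tribble(
    ~ecosystem, ~host_group,  ~n_species, ~n_individuals,
    "kelp",     "crustacean",  2L,   25L,
    "kelp",     "fish",       12L,  195L,
    "kelp",     "mollusk",    12L,  379L,
    "kelp",     "polychaete",  2L,   79L,
    "atoll",    "crustacean",  5L,  200L,
    "atoll",    "fish",       23L,  574L,
    "atoll",    "mollusk",    12L, 1578L,
    "atoll",    "polychaete",  4L,  285L,
    "vent",     "crustacean",  6L,  712L,
    "vent",     "fish",        2L,   35L,
    "vent",     "mollusk",    10L,  880L,
    "vent",     "polychaete", 10L,  507L
  )
}

#' @rdname sim_config
#' @export
default_parasite_pool <- function() {
  tibble::tribble(
    ~parasite_taxon,  ~life_cycle, ~life_stage,       ~n_morphogroups,
    "Trematoda",      "ILC",       "adult",            7L,
    "Trematoda",      "ILC",       "metacercaria",     6L,
    "Trematoda",      "ILC",       "sporocyst",        1L,
    "Copepoda",       "DLC",       "adult",            4L,
    "Monogenea",      "DLC",       "adult",            3L,
    "Nematoda",       "ILC",       "adult",            2L,
    "Nematoda",       "ILC",       "larval_nematode",  2L,
    "Acanthocephala", "ILC",       "adult",            2L,
    "Acanthocephala", "ILC",       "cystacanth",       1L,
    "Cestoda",        "ILC",       "adult",            1L,
    "Cestoda",        "ILC",       "metacestode",      2L,
    "Isopoda",        "DLC",       "adult",            1L,
    "Rhizocephala",   "DLC",       "adult",            1L
  )
}

# Host groups a morphogroup can plausibly occupy, by taxon and stage: adult
# ILC helminths and monogeneans mature in fish; encysted intermediate stages
# (cystacanths, metacestodes, larval nematodes, metacercariae) sit in prey —
# invertebrates or smaller fish serving as intermediate hosts; sporocysts are
# in gastropods; copepods are catholic; rhizocephalans parasitize
# crustaceans.
stage_host_groups <- function(taxon, stage) {
  inverts <- c("crustacean", "mollusk", "polychaete")
  if (taxon == "Copepoda") return(c("fish", inverts))
  if (taxon == "Rhizocephala") return("crustacean")
  if (taxon == "Isopoda") return(c("fish", "crustacean"))
  if (stage == "adult") return("fish")
  if (stage == "sporocyst") return("mollusk")
  c("fish", inverts)
}

distribute_counts <- function(total, k) {
  if (k == 0L) return(integer())
  base <- total %/% k
  base + as.integer(seq_len(k) <= total %% k)
}

ecosystem_multipliers <- function(ecosystems, effect) {
  s <- seq_along(ecosystems)
  (1 + effect)^(s - (length(s) + 1) / 2)
}

#' Simulate a dissection dataset
#'
#' Draws a complete synthetic dissection dataset from a [sim_config()]:
#' host species (with deterministic allocation of the group's individuals
#' across its species and a lognormal species mean length), a per-ecosystem
#' parasite pool with host-specific compatible species, and independent
#' per-individual Bernoulli detections at the configured probability, with
#' counts `1 + Poisson(1)` given detection (only presence is used
#' downstream). The output always passes [validate_dissection()] and is
#' bit-reproducible given the seed.
#'
#' @param config A [sim_config()].
#' @param seed Integer seed; defaults to `config$seed`.
#' @return A `dissection_data` object.
#' @export
simulate_dataset <- function(config, seed = config$seed) {
  validate_sim_config(config)
  local_rng(seed)
  mult <- ecosystem_multipliers(config$ecosystems, config$effect)
  names(mult) <- config$ecosystems

  hosts_l <- list(); ann_l <- list(); obs_l <- list()
  for (eco in config$ecosystems) {
    hs <- config$hosts[config$hosts$ecosystem == eco, ]
    if (!nrow(hs)) next
    sp_group <- rep(hs$host_group, hs$n_species)
    sp_idx <- unlist(lapply(hs$n_species, seq_len), use.names = FALSE)
    species <- data.frame(
      host_group = sp_group,
      host_species = sprintf("%s_%s_sp%02d", eco, sp_group, sp_idx),
      n_ind = unlist(Map(distribute_counts, hs$n_individuals, hs$n_species),
                     use.names = FALSE))
    if (!nrow(species)) next
    species$mean_len <- rlnorm(nrow(species),
                               meanlog = config$length_meanlog[species$host_group],
                               sdlog = config$length_sdlog)

    ind_species <- rep(species$host_species, species$n_ind)
    ind_idx <- unlist(lapply(species$n_ind, seq_len), use.names = FALSE)
    host_tbl <- data.frame(
      host_individual_id = sprintf("%s_i%04d", ind_species, ind_idx),
      host_species = ind_species,
      host_group = rep(species$host_group, species$n_ind),
      ecosystem = eco, site = paste0(eco, "_site1"),
      collection_date = NA_character_,
      host_length_mm = round(rep(species$mean_len, species$n_ind) *
                               exp(stats::rnorm(length(ind_species), 0, 0.15)), 1))
    hosts_l[[eco]] <- host_tbl

    # ecosystem-specific pool, scaled by the ordered effect
    pool <- config$pool
    pool$n <- if (config$pool_model == "poisson") {
      rpois(nrow(pool), pool$n_morphogroups * mult[eco])
    } else {
      round(pool$n_morphogroups * mult[eco])
    }
    pool <- pool[pool$n > 0, ]
    mg_row <- rep(seq_len(nrow(pool)), pool$n)
    ann <- data.frame(
      morphogroup_id = sprintf("%s_%s_%s_%02d", eco,
                               tolower(pool$parasite_taxon[mg_row]),
                               pool$life_stage[mg_row],
                               unlist(lapply(pool$n, seq_len), use.names = FALSE)),
      parasite_taxon = pool$parasite_taxon[mg_row],
      life_cycle = pool$life_cycle[mg_row],
      life_stage = pool$life_stage[mg_row])
    ann$redundancy_group <- NA_character_
    # link adult trematodes with their intermediate stages
    if (config$redundancy_clusters > 0) {
      ad <- which(ann$parasite_taxon == "Trematoda" & ann$life_stage == "adult")
      mc <- which(ann$parasite_taxon == "Trematoda" & ann$life_stage == "metacercaria")
      sp <- which(ann$parasite_taxon == "Trematoda" & ann$life_stage == "sporocyst")
      nclus <- min(config$redundancy_clusters, length(ad), length(mc))
      for (r in seq_len(nclus)) {
        grp <- sprintf("%s_trem_sp%02d", eco, r)
        ann$redundancy_group[ad[r]] <- grp
        ann$redundancy_group[mc[r]] <- grp
        if (r == 1L && length(sp)) ann$redundancy_group[sp[1]] <- grp
      }
    }
    ann_l[[eco]] <- ann

    # compatible host species per morphogroup, then Bernoulli detections
    sus <- if (config$aggregation > 0) {
      setNames(stats::rgamma(nrow(host_tbl), shape = 1 / config$aggregation,
                             scale = config$aggregation),
               host_tbl$host_individual_id)
    } else NULL
    p_eco <- min(0.95, config$detection_prob * mult[eco])
    meanlog <- config$length_meanlog
    rows_by_species <- split(seq_len(nrow(host_tbl)), host_tbl$host_species)
    obs_id <- list(); obs_mg <- list()
    for (j in seq_len(nrow(ann))) {
      groups_ok <- stage_host_groups(ann$parasite_taxon[j], ann$life_stage[j])
      cand <- species$host_species[species$host_group %in% groups_ok]
      if (!length(cand)) next
      compat <- sample(cand, min(config$specificity_breadth, length(cand)))
      ridx <- unlist(rows_by_species[compat], use.names = FALSE)
      if (!length(ridx)) next
      p <- rep(p_eco, length(ridx))
      if (config$length_richness_coef != 0) {
        p <- p * exp(config$length_richness_coef *
                       (log(host_tbl$host_length_mm[ridx]) -
                          meanlog[host_tbl$host_group[ridx]]))
      }
      if (!is.null(sus)) p <- p * sus[host_tbl$host_individual_id[ridx]]
      p <- pmin(p, 1)
      hit <- runif(length(ridx)) < p
      if (!any(hit)) next
      obs_id[[length(obs_id) + 1]] <- host_tbl$host_individual_id[ridx[hit]]
      obs_mg[[length(obs_mg) + 1]] <- rep(ann$morphogroup_id[j], sum(hit))
    }
    ids <- unlist(obs_id, use.names = FALSE)
    obs_l[[eco]] <- data.frame(
      host_individual_id = ids %||% character(),
      morphogroup_id = unlist(obs_mg, use.names = FALSE) %||% character(),
      count = 1L + rpois(length(ids), 1))
  }

  hosts <- dplyr::bind_rows(hosts_l)[, host_cols]
  ann <- dplyr::bind_rows(ann_l)[, ann_cols]
  obs <- dplyr::bind_rows(obs_l)
  if (!nrow(obs)) {
    obs <- tibble::tibble(host_individual_id = character(),
                          morphogroup_id = character(), count = integer())
  }
  dissection_data(hosts, obs, ann,
                  provenance = sprintf("simulated dataset (effect = %g, seed = %d)",
                                       config$effect, as.integer(seed)))
}

#' Null and ordered-effect scenarios
#'
#' `null_scenario()` neutralizes every between-ecosystem difference: the
#' ordered effect is set to 0 and every ecosystem receives the first
#' ecosystem's host structure, so simulated ecosystems are exchangeable up to
#' labels — the reference condition for calibration of the permutation test
#' and the chi-square composition tests. `ordered_effect_scenario()` sets the
#' ordered effect to `effect`, scaling pool sizes and detection probabilities
#' monotonically along the configured ecosystem ordering; `effect = 0`
#' coincides with the null (apart from host structure, which it leaves
#' untouched).
#'
#' @param base A [sim_config()].
#' @param effect Positive ordered effect size.
#' @return A modified `sim_config`.
#' @export
null_scenario <- function(base) {
  validate_sim_config(base)
  first <- base$ecosystems[1]
  template <- base$hosts |>
    dplyr::filter(.data$ecosystem == first) |>
    dplyr::select(-"ecosystem")
  base$hosts <- purrr::map_dfr(base$ecosystems, function(eco) {
    dplyr::mutate(template, ecosystem = eco, .before = 1)
  })
  base$effect <- 0
  base
}

#' @rdname null_scenario
#' @export
ordered_effect_scenario <- function(base, effect) {
  validate_sim_config(base)
  if (effect < 0) abort("effect must be >= 0", class = "paradiv_config_error")
  base$effect <- effect
  base
}

#' Compact simulation configuration for simulation studies
#'
#' A reduced configuration used for replicated simulation studies
#' (calibration and power): three ecosystems, two host groups (fish and
#' mollusk) with 5 species x 12 individuals per group and ecosystem, and the
#' default parasite pool sizes drawn as Poisson with single-host parasite
#' specificity. In that regime each host species' parasite assemblage is an
#' independent thinned-Poisson draw, so under the null the stratified
#' permutation test is exact — the reference condition for calibration.
#' (With a fixed, shared pool, species compete for a fixed number of
#' morphogroup-host slots; the induced negative dependence makes the
#' permutation test conservative.) Small enough that a thousand replicate
#' generate-and-test cycles run in about a minute.
#'
#' @param effect Ordered ecosystem effect (default 0).
#' @param seed Default seed.
#' @return A `sim_config`.
#' @export
compact_sim_config <- function(effect = 0, seed = 1L) {
  hosts <- tidyr::expand_grid(ecosystem = c("vent", "atoll", "kelp"),
                              host_group = c("fish", "mollusk")) |>
    dplyr::mutate(n_species = 5L, n_individuals = 60L)
  sim_config(hosts = hosts, effect = effect, seed = seed,
             pool_model = "poisson", specificity_breadth = 1L,
             redundancy_clusters = 0L)
}

#' @rdname compact_sim_config
#' @details `composition_calibration_config()` is the analogous reference
#' condition for the chi-square composition tests: one invertebrate host
#' group (8 mollusk species x 12 individuals per ecosystem) and a two-row
#' pool (adult copepods, DLC; trematode metacercariae, ILC) with Poisson
#' pool sizes of mean 120 and 180 and detection probability 0.012, so each
#' life-cycle x ecosystem cell count is an independent Poisson draw with
#' expectation well above 5 — the sampling model under which the Pearson
#' chi-square p-value is asymptotically uniform under the null.
#' @export
composition_calibration_config <- function(seed = 1L) {
  hosts <- tidyr::expand_grid(ecosystem = c("vent", "atoll", "kelp"),
                              host_group = "mollusk") |>
    dplyr::mutate(n_species = 8L, n_individuals = 96L)
  pool <- tibble::tribble(
    ~parasite_taxon, ~life_cycle, ~life_stage,    ~n_morphogroups,
    "Copepoda",      "DLC",       "adult",         120L,
    "Trematoda",     "ILC",       "metacercaria",  180L)
  sim_config(hosts = hosts, pool = pool, detection_prob = 0.012,
             effect = 0, pool_model = "poisson", specificity_breadth = 1L,
             redundancy_clusters = 0L, seed = seed)
}
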