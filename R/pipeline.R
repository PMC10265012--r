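# End-to-end pipeline: harmonize -> partition -> richness/ordered test ->
# composition tests, with machine-readable reports and a manifest that makes
# a run re-executable bit-identically.

#' Run the full comparative pipeline
#'
#' Sequences every analysis stage on a multi-ecosystem dissection dataset:
#' applies the inclusion filters; computes per-host-species richness
#' summaries and the stratified-permutation rank ANCOVA of the ordered
#' ecosystem hypothesis; and, per host partition (fish / invertebrate),
#' species-accumulation curves per ecosystem and the life-cycle and
#' life-stage chi-square comparisons. The life-cycle analysis runs on the
#' redundancy-filtered partition; the life-stage analysis deliberately keeps
#' all stages. Any stage failure aborts with the stage name.
#'
#' When `out_dir` is given, reports are written as TSV/JSON together with a
#' `manifest.json` (argument hash, seed, package version) so the run can be
#' reproduced exactly.
#'
#' @param data A `dissection_data` spanning the ecosystems to compare (e.g.
#'   from [read_dissection_table()] or [simulate_dataset()]).
#' @param out_dir Optional output directory for the report bundle.
#' @param spec Inclusion [filter_spec()].
#' @param scores Ordered ecosystem scores, see [ordered_scores()].
#' @param b Number of randomizations for the permutation test.
#' @param seed Integer seed for all stochastic stages (mandatory).
#' @param variant Chao2 variant, see [chao2()].
#' @param categories Named list with elements `fish` and `invertebrate`
#'   giving the life-stage category sets, default [stage_categories()].
#' @return A list of results: `harmonized`, `summaries`, `ancova`,
#'   `accumulation` (tibble over partitions and ecosystems), `life_cycle` and
#'   `life_stage` (per-partition chi-square results), `manifest`.
#' @export
run_full_pipeline <- function(data, out_dir = NULL, spec = filter_spec(),
                              scores = ordered_scores(), b = 9999L, seed,
                              variant = c("bias_corrected", "classic"),
                              categories = list(
                                fish = stage_categories("fish"),
                                invertebrate = stage_categories("invertebrate"))) {
  stopifnot(inherits(data, "dissection_data"))
  if (missing(seed)) abort("seed is required", class = "paradiv_config_error")
  variant <- match.arg(variant)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(paste0("pipeline stage '", name, "' failed: ", conditionMessage(e)),
            class = "paradiv_pipeline_error")
    })
  }

  harmonized <- stage("harmonize", apply_inclusion_filters(data, spec))
  summaries <- stage("richness", host_species_summaries(harmonized, variant = variant))
  ancova <- stage("ordered_test",
                  permutation_test(summaries, scores = scores, b = b, seed = seed))

  parts <- stage("partition", partition_hosts(harmonized))
  accum <- list(); lc <- list(); ls_ <- list()
  lc_tab <- list(); ls_tab <- list()
  for (pn in names(parts)) {
    part <- parts[[pn]]
    if (!nrow(part$hosts)) next
    dedup <- stage(paste0("drop_redundant_stages[", pn, "]"),
                   drop_redundant_stages(part))
    ecos <- sort(unique(part$hosts$ecosystem))
    accum[[pn]] <- stage(paste0("accumulation[", pn, "]"),
      purrr::map_dfr(ecos, function(e) {
        sub <- replace_hosts(dedup, dplyr::filter(dedup$hosts, .data$ecosystem == e))
        if (!nrow(sub$hosts)) return(NULL)
        inc <- build_incidence(sub, level = "host_species")
        curve <- accumulation_curve(inc)
        dplyr::mutate(tibble::as_tibble(curve), ecosystem = e, partition = pn)
      }))
    lc_tab[[pn]] <- stage(paste0("life_cycle[", pn, "]"),
                          life_cycle_table(dedup, ecosystems = ecos))
    lc[[pn]] <- stage(paste0("life_cycle[", pn, "]"),
                      chisq_test(drop_empty_categories(lc_tab[[pn]])))
    ls_tab[[pn]] <- stage(paste0("life_stage[", pn, "]"),
                          life_stage_table(part, categories = categories[[pn]],
                                           ecosystems = ecos))
    ls_[[pn]] <- stage(paste0("life_stage[", pn, "]"),
                       chisq_test(drop_empty_categories(ls_tab[[pn]])))
  }

  manifest <- list(
    package = "paradiv",
    version = as.character(utils::packageVersion("paradiv")),
    seed = as.integer(seed), b = as.integer(b),
    scores = as.list(scores),
    filter = list(min_individuals = spec$min_individuals,
                  host_groups = spec$host_groups,
                  parasite_taxa = spec$parasite_taxa),
    chao2_variant = variant,
    input_hash = rlang::hash(data),
    provenance = harmonized$provenance
  )
  res <- list(harmonized = harmonized, summaries = summaries, ancova = ancova,
              accumulation = dplyr::bind_rows(accum),
              life_cycle = lc, life_stage = ls_,
              life_cycle_tables = lc_tab, life_stage_tables = ls_tab,
              manifest = manifest)
  if (!is.null(out_dir)) write_report_bundle(res, out_dir)
  res
}

# Categories unobserved in every ecosystem carry no information for the
# homogeneity test; drop them (the chi-square contract refuses all-zero
# rows/columns outright).
drop_empty_categories <- function(tab) {
  keep_r <- rowSums(tab) > 0
  keep_c <- colSums(tab) > 0
  if (sum(keep_r) < 2 || sum(keep_c) < 2) {
    abort("fewer than two non-empty categories/ecosystems to compare",
          class = "paradiv_argument_error")
  }
  tab[keep_r, keep_c, drop = FALSE]
}

write_report_bundle <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(out_dir, ...)
  readr::write_tsv(res$summaries, p("host_species_summaries.tsv"), progress = FALSE)
  readr::write_tsv(res$accumulation, p("accumulation_curves.tsv"), progress = FALSE)
  jsonlite::write_json(glance(res$ancova), p("ancova.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  for (pn in names(res$life_cycle)) {
    jsonlite::write_json(tidy(res$life_cycle[[pn]]),
                         p(paste0("life_cycle_", pn, ".json")),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  for (pn in names(res$life_stage)) {
    jsonlite::write_json(tidy(res$life_stage[[pn]]),
                         p(paste0("life_stage_", pn, ".json")),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  jsonlite::write_json(res$manifest, p("manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(res)
}
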