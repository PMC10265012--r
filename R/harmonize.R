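# Harmonization: the inclusion protocol that makes dissection datasets from
# different ecosystems comparable, plus the fish/invertebrate split and the
# removal of potentially redundant life stages.

#' Inclusion filter specification
#'
#' The protocol applied to every source dataset before any comparison:
#' restrict to the four focal host groups and eight focal metazoan parasite
#' taxa, then keep only host species with at least `min_individuals` dissected
#' individuals (infected or not). Filters are applied in that fixed order.
#'
#' @param min_individuals Minimum number of dissected individuals a host
#'   species needs to be retained (default 10).
#' @param host_groups Host groups to keep; default all of [host_groups()].
#' @param parasite_taxa Parasite taxa to keep; default all of
#'   [parasite_taxa()].
#' @return A `filter_spec` object.
#' @export
filter_spec <- function(min_individuals = 10L,
                        host_groups = paradiv::host_groups(),
                        parasite_taxa = paradiv::parasite_taxa()) {
  min_individuals <- as.integer(min_individuals)
  if (is.na(min_individuals) || min_individuals < 1L) {
    abort("min_individuals must be a positive integer", class = "paradiv_config_error")
  }
  if (!length(host_groups) || !length(parasite_taxa)) {
    abort("host_groups and parasite_taxa must be non-empty", class = "paradiv_config_error")
  }
  structure(list(min_individuals = min_individuals,
                 host_groups = host_groups,
                 parasite_taxa = parasite_taxa),
            class = "filter_spec")
}

#' @export
print.filter_spec <- function(x, ...) {
  cat("<filter_spec> min_individuals =", x$min_individuals, "\n")
  cat("  host groups:   ", paste(x$host_groups, collapse = ", "), "\n")
  cat("  parasite taxa: ", paste(x$parasite_taxa, collapse = ", "), "\n")
  invisible(x)
}

#' Apply the inclusion protocol to a dissection dataset
#'
#' Applies, in order: the host-group filter, the parasite-taxon filter (which
#' removes observations and annotations of excluded taxa, e.g. non-parasitic
#' symbionts outside the focal eight), and the minimum-sample-size filter
#' keeping only host species with at least `spec$min_individuals` dissected
#' individuals. Idempotent: re-applying the same spec changes nothing but
#' provenance.
#'
#' @param x A `dissection_data` object.
#' @param spec A [filter_spec()].
#' @return The filtered `dissection_data`, with one provenance entry per
#'   filter applied.
#' @export
apply_inclusion_filters <- function(x, spec = filter_spec()) {
  stopifnot(inherits(x, "dissection_data"), inherits(spec, "filter_spec"))

  h <- dplyr::filter(x$hosts, .data$host_group %in% spec$host_groups)
  x <- replace_hosts(x, h)
  x <- add_provenance(x, paste0("host-group filter [",
                                paste(spec$host_groups, collapse = ","),
                                "]: ", nrow(h), " hosts retained"))

  keep_mg <- x$annotations$morphogroup_id[x$annotations$parasite_taxon %in% spec$parasite_taxa]
  x$observations <- dplyr::filter(x$observations, .data$morphogroup_id %in% keep_mg)
  x$annotations <- dplyr::filter(x$annotations, .data$morphogroup_id %in% keep_mg)
  x <- add_provenance(x, paste0("parasite-taxon filter: ",
                                length(keep_mg), " morphogroups retained"))

  keep_sp <- x$hosts |>
    dplyr::count(.data$host_species) |>
    dplyr::filter(.data$n >= spec$min_individuals) |>
    dplyr::pull(.data$host_species)
  h <- dplyr::filter(x$hosts, .data$host_species %in% keep_sp)
  x <- replace_hosts(x, h)
  x <- add_provenance(x, paste0("min-individuals filter (>= ",
                                spec$min_individuals, "): ",
                                length(keep_sp), " host species retained"))

  if (!nrow(x$hosts)) {
    abort("inclusion filters removed every host record", class = "paradiv_empty_error")
  }
  x
}

replace_hosts <- function(x, hosts) {
  x$hosts <- hosts
  x$observations <- dplyr::filter(x$observations,
                                  .data$host_individual_id %in% hosts$host_individual_id)
  x
}

#' Split a dataset into fish and invertebrate host partitions
#'
#' Comparative analyses across host species are run separately for fish and
#' invertebrate hosts, so that larval stages in invertebrate prey and adult
#' stages in fish predators of the same parasite are never pooled. The
#' invertebrate partition holds crustaceans, mollusks and polychaetes.
#'
#' @param x A `dissection_data` object.
#' @return A named list with elements `fish` and `invertebrate`, each a
#'   `dissection_data`; their host records partition the input exactly.
#' @export
partition_hosts <- function(x) {
  stopifnot(inherits(x, "dissection_data"))
  split_one <- function(groups, label) {
    h <- dplyr::filter(x$hosts, .data$host_group %in% groups)
    add_provenance(replace_hosts(x, h),
                   paste0("partition: ", label, " hosts (", nrow(h), " individuals)"))
  }
  list(fish = split_one("fish", "fish"),
       invertebrate = split_one(c("crustacean", "mollusk", "polychaete"),
                                "invertebrate"))
}

#' Drop potentially redundant life stages within a partition
#'
#' When different life stages of what may be one biological species carry
#' separate morphogroup ids (an adult trematode and its metacercaria, say),
#' counting both within the same host partition would overestimate richness.
#' Annotations link such stages through a shared `redundancy_group`; within a
#' partition this function keeps exactly one morphogroup per redundancy group
#' present — the adult stage if one is present, otherwise the
#' lexicographically first morphogroup id (a deterministic tie-break) — and
#' removes the others' observations and annotations.
#'
#' Only applied before across-host-species richness and life-cycle analyses;
#' life-stage composition analyses deliberately keep all stages.
#'
#' @param x A `dissection_data` partition (see [partition_hosts()]).
#' @return The reduced `dissection_data`, removals logged in provenance.
#' @export
drop_redundant_stages <- function(x) {
  stopifnot(inherits(x, "dissection_data"))
  present <- unique(x$observations$morphogroup_id)
  ann <- dplyr::filter(x$annotations, .data$morphogroup_id %in% present,
                       !is.na(.data$redundancy_group))
  drop <- ann |>
    dplyr::group_by(.data$redundancy_group) |>
    dplyr::filter(dplyr::n() > 1) |>
    dplyr::arrange(dplyr::desc(.data$life_stage == "adult"),
                   .data$morphogroup_id, .by_group = TRUE) |>
    dplyr::slice(-1) |>
    dplyr::ungroup() |>
    dplyr::pull(.data$morphogroup_id)
  x$observations <- dplyr::filter(x$observations, !.data$morphogroup_id %in% drop)
  x$annotations <- dplyr::filter(x$annotations, !.data$morphogroup_id %in% drop)
  add_provenance(x, paste0("redundant-stage removal: dropped ",
                           length(drop), " morphogroup(s)",
                           if (length(drop)) paste0(" [", paste(sort(drop), collapse = ", "), "]")
                           else ""))
}
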