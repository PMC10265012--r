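# Core container: a dissection dataset is three linked tibbles (host
# individuals, parasite observations, morphogroup annotations) plus an ordered
# provenance log of every transformation applied.

host_cols <- c("host_individual_id", "host_species", "host_group", "ecosystem",
               "site", "collection_date", "host_length_mm")
obs_cols <- c("host_individual_id", "morphogroup_id", "count")
ann_cols <- c("morphogroup_id", "parasite_taxon", "life_cycle", "life_stage",
              "redundancy_group")

#' Construct a dissection dataset
#'
#' Bundles host-individual records, per-host parasite observations, and
#' morphogroup annotations into a validated `dissection_data` object, the
#' universal input of the pipeline. Absence of a parasite in a host is encoded
#' by the absence of an observation row; dissected-but-uninfected hosts are
#' ordinary host rows with no observations and carry real information (they
#' count toward the number of sampling units in richness estimation).
#'
#' @param hosts Data frame with one row per dissected host individual:
#'   `host_individual_id` (unique), `host_species`, `host_group` (one of
#'   [host_groups()]), `ecosystem`, and optionally `site`, `collection_date`
#'   (ISO-8601), `host_length_mm` (positive, millimetres; `NA` when not
#'   measured).
#' @param observations Data frame with one row per (host, morphogroup)
#'   detection: `host_individual_id`, `morphogroup_id`, `count` (>= 1).
#' @param annotations Data frame with one row per morphogroup:
#'   `morphogroup_id`, `parasite_taxon` (one of [parasite_taxa()]),
#'   `life_cycle` (`"DLC"`/`"ILC"`), `life_stage` (one of [life_stages()]),
#'   and optional `redundancy_group` linking life stages that may belong to a
#'   single biological species.
#' @param provenance Character vector describing the dataset's source and the
#'   filters already applied, in order.
#' @param check If `TRUE` (default), referential-integrity violations raise an
#'   error; soft invariants are still reported by [validate_dissection()].
#'
#' @return A `dissection_data` object: a list of tibbles `hosts`,
#'   `observations`, `annotations` and a character `provenance`.
#' @seealso [read_dissection_table()], [validate_dissection()]
#' @export
#' @examples
#' hosts <- tibble::tibble(
#'   host_individual_id = c("h1", "h2"), host_species = "Alvinocaris lusca",
#'   host_group = "crustacean", ecosystem = "vent"
#' )
#' obs <- tibble::tibble(host_individual_id = "h1",
#'                       morphogroup_id = "trem1", count = 3L)
#' ann <- tibble::tibble(morphogroup_id = "trem1",
#'                       parasite_taxon = "Trematoda", life_cycle = "ILC",
#'                       life_stage = "metacercaria")
#' dissection_data(hosts, obs, ann)
dissection_data <- function(hosts, observations = NULL, annotations = NULL,
                            provenance = character(), check = TRUE) {
  hosts <- as_host_tbl(hosts)
  observations <- as_obs_tbl(observations)
  annotations <- as_ann_tbl(annotations)
  x <- structure(
    list(hosts = hosts, observations = observations,
         annotations = annotations, provenance = as.character(provenance)),
    class = "dissection_data"
  )
  if (check) {
    if (anyDuplicated(hosts$host_individual_id)) {
      dup <- unique(hosts$host_individual_id[duplicated(hosts$host_individual_id)])
      abort(paste0("duplicate host_individual_id: ",
                   paste(head(dup, 5), collapse = ", ")),
            class = "paradiv_integrity_error")
    }
    bad_host <- setdiff(observations$host_individual_id, hosts$host_individual_id)
    if (length(bad_host)) {
      abort(paste0("observations reference unknown host_individual_id: ",
                   paste(head(bad_host, 5), collapse = ", ")),
            class = "paradiv_integrity_error")
    }
    if (nrow(annotations)) {
      bad_mg <- setdiff(observations$morphogroup_id, annotations$morphogroup_id)
      if (length(bad_mg)) {
        abort(paste0("observations reference morphogroup_id absent from ",
                     "annotations: ", paste(head(bad_mg, 5), collapse = ", ")),
              class = "paradiv_integrity_error")
      }
    }
  }
  x
}

as_host_tbl <- function(hosts) {
  hosts <- tibble::as_tibble(hosts)
  need <- c("host_individual_id", "host_species", "host_group", "ecosystem")
  miss <- setdiff(need, names(hosts))
  if (length(miss)) {
    abort(paste0("hosts table is missing required column(s): ",
                 paste(miss, collapse = ", ")),
          class = "paradiv_format_error")
  }
  if (!"site" %in% names(hosts)) hosts$site <- NA_character_
  if (!"collection_date" %in% names(hosts)) hosts$collection_date <- NA_character_
  if (!"host_length_mm" %in% names(hosts)) hosts$host_length_mm <- NA_real_
  hosts$host_individual_id <- as.character(hosts$host_individual_id)
  hosts$collection_date <- as.character(hosts$collection_date)
  hosts$host_length_mm <- as.numeric(hosts$host_length_mm)
  hosts[host_cols]
}

as_obs_tbl <- function(observations) {
  if (is.null(observations)) {
    return(tibble::tibble(host_individual_id = character(),
                          morphogroup_id = character(), count = integer()))
  }
  observations <- tibble::as_tibble(observations)
  miss <- setdiff(obs_cols, names(observations))
  if (length(miss)) {
    abort(paste0("observations table is missing required column(s): ",
                 paste(miss, collapse = ", ")),
          class = "paradiv_format_error")
  }
  observations$host_individual_id <- as.character(observations$host_individual_id)
  observations$count <- as.integer(observations$count)
  observations[obs_cols]
}

as_ann_tbl <- function(annotations) {
  if (is.null(annotations)) {
    return(tibble::tibble(morphogroup_id = character(),
                          parasite_taxon = character(),
                          life_cycle = character(), life_stage = character(),
                          redundancy_group = character()))
  }
  annotations <- tibble::as_tibble(annotations)
  miss <- setdiff(setdiff(ann_cols, "redundancy_group"), names(annotations))
  if (length(miss)) {
    abort(paste0("annotations table is missing required column(s): ",
                 paste(miss, collapse = ", ")),
          class = "paradiv_format_error")
  }
  if (!"redundancy_group" %in% names(annotations)) {
    annotations$redundancy_group <- NA_character_
  }
  annotations[ann_cols]
}

#' @export
print.dissection_data <- function(x, ...) {
  cat("<dissection_data>\n")
  cat(sprintf("  hosts:        %d individuals, %d species, %d ecosystem(s)\n",
              nrow(x$hosts), dplyr::n_distinct(x$hosts$host_species),
              dplyr::n_distinct(x$hosts$ecosystem)))
  cat(sprintf("  observations: %d rows, %d morphogroup(s)\n",
              nrow(x$observations),
              dplyr::n_distinct(x$observations$morphogroup_id)))
  cat(sprintf("  annotations:  %d morphogroup(s)\n", nrow(x$annotations)))
  if (length(x$provenance)) {
    cat("  provenance:\n")
    for (p in x$provenance) cat("    - ", p, "\n", sep = "")
  }
  invisible(x)
}

add_provenance <- function(x, msg) {
  x$provenance <- c(x$provenance, msg)
  x
}

#' Validate a dissection dataset
#'
#' Checks every domain invariant and returns the violations as a tibble
#' rather than raising, so a dataset can be audited in one pass. An empty
#' result means the dataset is clean. `validate_dissection()` is side-effect
#' free and idempotent.
#'
#' Checked invariants: unique host ids; host groups drawn from
#' [host_groups()]; positive host lengths where present; observation counts
#' >= 1; observations resolving to known hosts and annotated morphogroups;
#' parasite taxon / life-cycle / life-stage levels; direct-life-cycle (DLC)
#' morphogroups annotated as adults (a one-host parasite has no intermediate
#' stage); and unanimous host-group membership within each host species.
#'
#' @param x A `dissection_data` object.
#' @return A tibble with columns `field` and `message`, one row per violation;
#'   zero rows when all invariants hold.
#' @export
validate_dissection <- function(x) {
  stopifnot(inherits(x, "dissection_data"))
  v <- list()
  add <- function(field, message) {
    v[[length(v) + 1]] <<- tibble::tibble(field = field, message = message)
  }
  h <- x$hosts; o <- x$observations; a <- x$annotations

  dup <- unique(h$host_individual_id[duplicated(h$host_individual_id)])
  for (d in dup) add("host_individual_id", paste0("duplicate id: ", d))

  bad_grp <- unique(h$host_group[!h$host_group %in% host_groups()])
  for (g in bad_grp) add("host_group", paste0("unknown host group: ", g))

  bad_len <- h$host_individual_id[!is.na(h$host_length_mm) & h$host_length_mm <= 0]
  for (id in bad_len) add("host_length_mm", paste0("non-positive host_length_mm for host ", id))

  mixed <- h |>
    dplyr::distinct(.data$host_species, .data$host_group) |>
    dplyr::count(.data$host_species) |>
    dplyr::filter(.data$n > 1)
  for (s in mixed$host_species) {
    add("host_group", paste0("host species '", s, "' has conflicting host_group labels"))
  }

  bad_count <- which(is.na(o$count) | o$count < 1L)
  for (i in bad_count) {
    add("count", paste0("observation of ", o$morphogroup_id[i], " in host ",
                        o$host_individual_id[i], " has count < 1"))
  }
  for (id in setdiff(o$host_individual_id, h$host_individual_id)) {
    add("host_individual_id", paste0("observation references unknown host: ", id))
  }
  if (nrow(a)) {
    for (m in setdiff(o$morphogroup_id, a$morphogroup_id)) {
      add("morphogroup_id", paste0("observation references unannotated morphogroup: ", m))
    }
  }

  for (m in unique(a$morphogroup_id[duplicated(a$morphogroup_id)])) {
    add("morphogroup_id", paste0("duplicate annotation for morphogroup: ", m))
  }
  bad_tax <- a$morphogroup_id[!a$parasite_taxon %in% parasite_taxa()]
  for (m in bad_tax) add("parasite_taxon", paste0("unknown parasite_taxon for ", m))
  bad_lc <- a$morphogroup_id[!a$life_cycle %in% life_cycles()]
  for (m in bad_lc) add("life_cycle", paste0("unknown life_cycle for ", m))
  bad_st <- a$morphogroup_id[!a$life_stage %in% life_stages()]
  for (m in bad_st) add("life_stage", paste0("unknown life_stage for ", m))
  dlc_larval <- a$morphogroup_id[a$life_cycle == "DLC" & a$life_stage != "adult" &
                                   a$life_stage %in% life_stages()]
  for (m in dlc_larval) {
    add("life_stage", paste0("DLC morphogroup ", m, " must have life_stage 'adult'"))
  }

  if (length(v)) dplyr::bind_rows(v) else
    tibble::tibble(field = character(), message = character())
}
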