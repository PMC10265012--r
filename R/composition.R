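# Composition analyses: counts of distinct parasite morphogroups by
# life-cycle category (direct vs indirect) and by life-stage category, per
# ecosystem, compared with Pearson chi-square tests of homogeneity.

new_contingency_table <- function(counts, row_labels, col_labels) {
  counts <- matrix(as.integer(counts), nrow = length(row_labels),
                   dimnames = list(row_labels, col_labels))
  structure(counts, class = c("contingency_table", "matrix", "array"))
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("<contingency_table>\n")
  print(unclass(x))
  invisible(x)
}

#' Life-cycle composition table
#'
#' Counts distinct parasite morphogroups by life-cycle category (DLC: direct,
#' one-host; ILC: indirect, multi-host) in each ecosystem. A morphogroup is
#' counted once per ecosystem in which it is observed, regardless of how many
#' hosts carry it. The input partition should already be redundancy-filtered
#' ([drop_redundant_stages()]) so that two life stages of one biological
#' species are not counted as two species.
#'
#' @param x A `dissection_data` partition.
#' @param ecosystems Ordered ecosystem labels for the table columns; all must
#'   occur in the data. Defaults to the sorted ecosystems present.
#' @return A 2 x E `contingency_table` with rows `DLC`, `ILC`.
#' @export
life_cycle_table <- function(x, ecosystems = NULL) {
  stopifnot(inherits(x, "dissection_data"))
  ecosystems <- check_ecosystems(x, ecosystems)
  tallies <- observed_morphogroups(x) |>
    dplyr::count(.data$ecosystem, .data$life_cycle)
  counts <- vapply(ecosystems, function(e) {
    vapply(life_cycles(), function(lc) {
      n <- tallies$n[tallies$ecosystem == e & tallies$life_cycle == lc]
      if (length(n)) n else 0L
    }, integer(1))
  }, integer(2))
  new_contingency_table(counts, life_cycles(), ecosystems)
}

#' Life-stage composition table
#'
#' Counts distinct parasite morphogroups by life-stage category in each
#' ecosystem. Unlike the life-cycle analysis, *all* intermediate-stage
#' morphotypes are kept — the point is precisely which stages an ecosystem's
#' hosts harbour — so no redundancy filtering is applied. Stage categories
#' are configuration: each table row is a named category mapping onto one or
#' more [life_stages()] levels (see [stage_categories()]); a morphogroup whose
#' stage falls outside every category is an error.
#'
#' @param x A `dissection_data` partition (not redundancy-filtered).
#' @param categories Named list mapping category labels to character vectors
#'   of life-stage levels, e.g. `stage_categories("fish")`.
#' @param ecosystems Ordered ecosystem labels for the table columns.
#' @return A `contingency_table` with one row per category.
#' @export
life_stage_table <- function(x, categories = stage_categories("fish"),
                             ecosystems = NULL) {
  stopifnot(inherits(x, "dissection_data"))
  if (!length(categories)) {
    abort("categories must be a non-empty named list", class = "paradiv_config_error")
  }
  ecosystems <- check_ecosystems(x, ecosystems)
  obs <- observed_morphogroups(x)
  covered <- unlist(categories, use.names = FALSE)
  missing_stage <- unique(obs$morphogroup_id[!obs$life_stage %in% covered])
  if (length(missing_stage)) {
    abort(paste0("morphogroup(s) with a life stage outside the category set: ",
                 paste(missing_stage, collapse = ", ")),
          class = "paradiv_config_error")
  }
  counts <- vapply(ecosystems, function(e) {
    vapply(categories, function(stages) {
      sum(obs$ecosystem == e & obs$life_stage %in% stages)
    }, integer(1))
  }, integer(length(categories)))
  new_contingency_table(counts, names(categories), ecosystems)
}

#' Default life-stage category sets
#'
#' Five categories per host partition, chosen so that a three-ecosystem
#' comparison has 8 degrees of freedom. For fish hosts the intermediate
#' stages that pass up food chains are kept separate (cystacanth, larval
#' nematode, metacestode, metacercaria). For invertebrate hosts, trematode
#' metacercariae and sporocysts are pooled into one trematode-intermediate
#' category by default; this grouping is a configurable assumption, not a
#' fact of the data.
#'
#' @param partition `"fish"` or `"invertebrate"`.
#' @return Named list mapping category labels to [life_stages()] levels.
#' @export
stage_categories <- function(partition = c("fish", "invertebrate")) {
  partition <- match.arg(partition)
  if (partition == "fish") {
    list(adult = "adult", cystacanth = "cystacanth",
         larval_nematode = "larval_nematode", metacestode = "metacestode",
         metacercaria = "metacercaria")
  } else {
    list(adult = "adult", cystacanth = "cystacanth",
         larval_nematode = "larval_nematode", metacestode = "metacestode",
         trematode_intermediate = c("metacercaria", "sporocyst"))
  }
}

# Distinct (ecosystem, morphogroup) pairs observed in the partition, with
# their annotations.
observed_morphogroups <- function(x) {
  x$observations |>
    dplyr::inner_join(dplyr::select(x$hosts, "host_individual_id", "ecosystem"),
                      by = "host_individual_id") |>
    dplyr::distinct(.data$ecosystem, .data$morphogroup_id) |>
    dplyr::inner_join(x$annotations, by = "morphogroup_id")
}

check_ecosystems <- function(x, ecosystems) {
  present <- unique(x$hosts$ecosystem)
  if (is.null(ecosystems)) return(sort(present))
  missing <- setdiff(ecosystems, present)
  if (length(missing)) {
    abort(paste0("ecosystem label(s) absent from the data: ",
                 paste(missing, collapse = ", ")),
          class = "paradiv_argument_error")
  }
  ecosystems
}

#' Pearson chi-square test on a composition table
#'
#' The standard Pearson chi-square test of homogeneity, without continuity
#' correction and without an exact-test fallback: the statistic is
#' `sum((O - E)^2 / E)` with `df = (rows - 1) (cols - 1)` and an upper-tail
#' chi-square p-value. When any expected cell is below 5 the result flags
#' `low_expected_warning` instead of switching method.
#'
#' @param x A `contingency_table` (or plain count matrix).
#' @return A `chisq_result`: `chi2`, `df`, `p_value`, `expected`,
#'   `low_expected_warning`, `observed`. Has [tidy()] and [glance()] methods.
#' @export
#' @examples
#' chisq_test(matrix(c(10, 20, 20, 10), nrow = 2))
chisq_test <- function(x) {
  counts <- unclass(as.matrix(x))
  if (any(counts < 0) || any(counts != round(counts))) {
    abort("counts must be non-negative integers", class = "paradiv_format_error")
  }
  if (sum(counts) == 0) {
    abort("contingency table is empty", class = "paradiv_empty_error")
  }
  zero_rows <- rowSums(counts) == 0
  zero_cols <- colSums(counts) == 0
  if (any(zero_rows) || any(zero_cols)) {
    offenders <- c(rownames(counts)[zero_rows], colnames(counts)[zero_cols])
    abort(paste0("all-zero row/column (", paste(offenders, collapse = ", "),
                 "): collapse or drop the category before testing"),
          class = "paradiv_argument_error")
  }
  ct <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
  structure(list(chi2 = unname(ct$statistic), df = unname(ct$parameter),
                 p_value = unname(ct$p.value), expected = ct$expected,
                 low_expected_warning = any(ct$expected < 5),
                 observed = counts),
            class = "chisq_result")
}

#' @export
print.chisq_result <- function(x, ...) {
  cat(sprintf("<chisq_result> chi2 = %.3f, df = %d, p = %.4g%s\n",
              x$chi2, x$df, x$p_value,
              if (x$low_expected_warning) "  [expected cell < 5]" else ""))
  invisible(x)
}

#' @method tidy chisq_result
#' @export
tidy.chisq_result <- function(x, ...) {
  tibble::tibble(statistic = x$chi2, df = x$df, p.value = x$p_value,
                 low_expected_warning = x$low_expected_warning)
}

#' @method glance chisq_result
#' @export
glance.chisq_result <- function(x, ...) tidy(x)
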