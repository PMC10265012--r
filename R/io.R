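# CSV readers/writers. Canonical on-disk form is a pair of UTF-8 CSVs:
# a long dissection table (one row per parasite observation; uninfected hosts
# appear once with empty morphogroup_id and count) and an annotation table.
# A dialect maps differing source headers onto the canonical columns.

dissection_csv_cols <- c(host_cols, "morphogroup_id", "count")

#' Read a dissection table
#'
#' Reads a long-format dissection CSV (one row per parasite observation, plus
#' one row with empty `morphogroup_id` for every dissected-but-uninfected
#' host) and optional morphogroup annotations into a validated
#' [dissection_data()] object. Source files whose headers differ from the
#' canonical column names are handled through a dialect mapping.
#'
#' @param path Path to the dissection CSV. Canonical columns:
#'   `host_individual_id`, `host_species`, `host_group`, `ecosystem`, `site`,
#'   `collection_date`, `host_length_mm`, `morphogroup_id`, `count`.
#' @param annotations Optional annotation table: a path to a CSV with columns
#'   `morphogroup_id`, `parasite_taxon`, `life_cycle`, `life_stage`,
#'   `redundancy_group`, or a data frame with those columns.
#' @param dialect Optional column mapping, either a named list/vector
#'   (`canonical_name = "source header"`) or a path to a YAML/JSON file with
#'   optional blocks `dissections:` and `annotations:` of such pairs. See
#'   [read_dialect()].
#' @return A `dissection_data` object with provenance recording the source
#'   path.
#' @export
read_dissection_table <- function(path, annotations = NULL, dialect = NULL) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "paradiv_io_error")
  }
  dialect <- read_dialect(dialect)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  raw <- apply_dialect(raw, dialect$dissections)
  need <- c("host_individual_id", "host_species", "host_group", "ecosystem")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    abort(paste0("dissection table ", path, " is missing required column(s): ",
                 paste(miss, collapse = ", ")),
          class = "paradiv_format_error")
  }
  for (col in setdiff(dissection_csv_cols, names(raw))) raw[[col]] <- NA_character_
  raw$host_length_mm <- as.numeric(raw$host_length_mm)
  raw$count <- as.integer(raw$count)

  hosts <- raw |>
    dplyr::distinct(dplyr::across(dplyr::all_of(host_cols)))
  dup <- hosts |>
    dplyr::count(.data$host_individual_id) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup)) {
    abort(paste0("host_individual_id with conflicting host attributes: ",
                 paste(head(dup$host_individual_id, 5), collapse = ", ")),
          class = "paradiv_integrity_error")
  }
  obs <- raw |>
    dplyr::filter(!is.na(.data$morphogroup_id) & .data$morphogroup_id != "") |>
    dplyr::select(dplyr::all_of(obs_cols))

  ann <- NULL
  if (!is.null(annotations)) {
    ann <- if (is.character(annotations) && length(annotations) == 1) {
      read_annotation_table(annotations, dialect = dialect)
    } else {
      as_ann_tbl(annotations)
    }
  }
  dissection_data(hosts, obs, ann,
                  provenance = paste0("read ", nrow(hosts), " hosts, ",
                                      nrow(obs), " observations from ", path))
}

#' @rdname read_dissection_table
#' @export
read_annotation_table <- function(path, dialect = NULL) {
  if (!file.exists(path)) {
    abort(paste0("no such file: ", path), class = "paradiv_io_error")
  }
  dialect <- read_dialect(dialect)
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  raw <- apply_dialect(raw, dialect$annotations)
  raw$redundancy_group[!is.na(raw$redundancy_group) & raw$redundancy_group == ""] <- NA_character_
  as_ann_tbl(raw)
}

#' Read a column-mapping dialect
#'
#' A dialect renames a source file's columns onto the canonical schema. On
#' disk it is a YAML or JSON document with optional `dissections` and
#' `annotations` blocks, each a mapping `canonical_name: source header`.
#' Passing a bare named list/vector applies it to both tables.
#'
#' @param x Path to a YAML/JSON dialect file, a named list/vector, or `NULL`
#'   (identity mapping).
#' @return A list with elements `dissections` and `annotations`, each a named
#'   character vector (`canonical = source`).
#' @export
read_dialect <- function(x) {
  if (is.null(x)) return(list(dissections = character(), annotations = character()))
  if (is.list(x) && any(c("dissections", "annotations") %in% names(x))) {
    return(list(dissections = unlist(x$dissections),
                annotations = unlist(x$annotations)))
  }
  if (is.character(x) && length(x) == 1 && is.null(names(x)) && file.exists(x)) {
    parsed <- if (grepl("\\.json$", x, ignore.case = TRUE)) {
      jsonlite::read_json(x, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(x)
    }
    return(list(dissections = unlist(parsed$dissections),
                annotations = unlist(parsed$annotations)))
  }
  m <- unlist(x)
  list(dissections = m, annotations = m)
}

apply_dialect <- function(df, mapping) {
  if (!length(mapping)) return(df)
  for (canonical in names(mapping)) {
    src <- mapping[[canonical]]
    if (!src %in% names(df)) {
      abort(paste0("dialect maps '", canonical, "' to column '", src,
                   "', which is absent from the file"),
            class = "paradiv_format_error")
    }
    names(df)[names(df) == src] <- canonical
  }
  df
}

#' Write a dissection dataset to CSV
#'
#' Writes the long-format dissection CSV (and optionally the annotation CSV)
#' that [read_dissection_table()] inverts exactly. Rows are sorted by host and
#' morphogroup id so that a write-read-write cycle is byte-stable. Absent
#' values (e.g. unmeasured host length) are written as empty cells, never 0.
#'
#' @param x A `dissection_data` object.
#' @param path Output path for the dissection CSV.
#' @param annotations_path Optional output path for the annotation CSV.
#' @return `x`, invisibly.
#' @export
write_dissection_table <- function(x, path, annotations_path = NULL) {
  stopifnot(inherits(x, "dissection_data"))
  long <- x$hosts |>
    dplyr::left_join(x$observations, by = "host_individual_id") |>
    dplyr::arrange(.data$host_individual_id, .data$morphogroup_id)
  readr::write_csv(long[dissection_csv_cols], path, na = "", progress = FALSE)
  if (!is.null(annotations_path)) {
    ann <- dplyr::arrange(x$annotations, .data$morphogroup_id)
    readr::write_csv(ann, annotations_path, na = "", progress = FALSE)
  }
  invisible(x)
}
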