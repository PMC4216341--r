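#' @keywords internal
"_PACKAGE"

#' @importFrom rlang .data
#' @importFrom stats rgamma rpois runif setNames cor
#' @importFrom utils head
NULL

REQUIRED_COLUMNS <- c("informant_id", "species_id", "ailment",
                      "plant_part", "preparation", "route")
ROUTE_LEVELS <- c("oral", "topical")

# ---- attribute-set helpers -------------------------------------------------

# Composite cells ("infusion, brewing") are attribute SETS on one report,
# never extra reports. They are stored as canonical sorted comma-joined
# strings so the tibble stays plain and CSV round trips are byte-stable.

attr_split <- function(x) {
  strsplit(as.character(x), ",", fixed = TRUE) |>
    lapply(function(v) sort(unique(trimws(v[nzchar(trimws(v))]))))
}

attr_join <- function(parts) {
  vapply(parts, paste, character(1), collapse = ", ")
}

canonical_attr <- function(x) {
  out <- attr_join(attr_split(x))
  out[is.na(x)] <- NA_character_
  out
}

#' Construct a use-report table
#'
#' A use report is the atomic unit of ethnobotanical counting: one
#' informant's statement that one plant species treats one ailment (a "use
#' citation"). Attributes that can be multi-valued for a single citation
#' (plant part, preparation mode) are stored as canonical comma-separated
#' sets; duplicated `(informant, species, ailment)` triples are merged by
#' attribute-set union so index denominators are never inflated.
#'
#' @param df A data frame with columns `informant_id`, `species_id`,
#'   `ailment`, `plant_part`, `preparation`, `route` (and optionally
#'   `category`).
#' @param dedup Merge duplicate `(informant, species, ailment)` triples
#'   (default `TRUE`). A warning reports how many rows were merged.
#' @return A tibble of unique use reports with a `category` column
#'   (`NA` until [resolve_categories()] is applied) and an attribute
#'   `raw_rows` giving the pre-deduplication row count.
#' @export
as_use_reports <- function(df, dedup = TRUE) {
  missing_cols <- setdiff(REQUIRED_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop("use-report table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df <- tibble::as_tibble(df)
  for (col in c("informant_id", "species_id", "ailment")) {
    bad <- which(is.na(df[[col]]) | !nzchar(trimws(df[[col]])))
    if (length(bad) > 0) {
      stop("empty ", col, " in row(s): ",
           paste(head(bad, 5L), collapse = ", "), call. = FALSE)
    }
  }
  route <- tolower(trimws(df$route))
  bad_route <- which(!route %in% ROUTE_LEVELS)
  if (length(bad_route) > 0) {
    stop("invalid route value(s) ",
         paste(unique(df$route[bad_route]), collapse = ", "),
         " in row(s): ", paste(head(bad_route, 5L), collapse = ", "),
         "; route must be one of: ", paste(ROUTE_LEVELS, collapse = ", "),
         call. = FALSE)
  }
  out <- df |>
    dplyr::mutate(
      informant_id = as.character(.data$informant_id),
      species_id = as.character(.data$species_id),
      ailment = trimws(as.character(.data$ailment)),
      plant_part = canonical_attr(.data$plant_part),
      preparation = canonical_attr(.data$preparation),
      route = route
    )
  if (!"category" %in% names(out)) out$category <- NA_character_
  raw_rows <- nrow(out)
  if (dedup) {
    n_triples <- nrow(dplyr::distinct(
      out, .data$informant_id, .data$species_id, .data$ailment))
    if (n_triples < raw_rows) {
      warning(raw_rows - n_triples,
              " duplicate (informant, species, ailment) row(s) merged by ",
              "attribute-set union", call. = FALSE)
      out <- out |>
        dplyr::group_by(.data$informant_id, .data$species_id,
                        .data$ailment) |>
        dplyr::summarise(
          plant_part = canonical_attr(paste(.data$plant_part,
                                            collapse = ", ")),
          preparation = canonical_attr(paste(.data$preparation,
                                             collapse = ", ")),
          route = paste(sort(unique(.data$route)), collapse = ", "),
          category = dplyr::first(.data$category),
          .groups = "drop"
        )
      # a triple reported via both routes keeps both as a set
    }
  }
  out <- out |>
    dplyr::select(dplyr::all_of(c(REQUIRED_COLUMNS, "category"))) |>
    dplyr::arrange(.data$informant_id, .data$species_id, .data$ailment)
  attr(out, "raw_rows") <- raw_rows
  out
}

#' Read use reports from a CSV file
#'
#' @param path Path to a UTF-8 CSV file.
#' @param col_map Optional named character vector mapping the canonical
#'   column names to the file's header names, e.g.
#'   `c(informant_id = "informant", route = "administration")`.
#' @inheritParams as_use_reports
#' @return A use-report tibble (see [as_use_reports()]).
#' @export
read_use_reports <- function(path, col_map = NULL, dedup = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()))
  if (!is.null(col_map)) {
    present <- col_map[col_map %in% names(df)]
    names(df)[match(present, names(df))] <- names(present)
  }
  missing_cols <- setdiff(REQUIRED_COLUMNS, names(df))
  if (length(missing_cols) > 0) {
    stop("input file ", path, " is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  as_use_reports(df, dedup = dedup)
}

#' Write use reports to CSV
#'
#' The writer emits the canonical column order with attribute sets as
#' sorted comma-joined cells, so `write_use_reports()` followed by
#' [read_use_reports()] is the identity on the record set.
#'
#' @param reports A use-report tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_use_reports <- function(reports, path) {
  cols <- intersect(c(REQUIRED_COLUMNS, "category"), names(reports))
  readr::write_csv(reports[, cols], path, na = "")
  invisible(path)
}

#' Read a species table
#'
#' Expected columns: `species_id`, `scientific_name`, `family`, and
#' optionally `local_name` and `voucher`. Scientific names are stored
#' verbatim, authorities included.
#'
#' @param path Path to a UTF-8 CSV file.
#' @return A tibble, one row per species.
#' @export
read_species_table <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()))
  needed <- c("species_id", "scientific_name", "family")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0) {
    stop("species table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(df$species_id)) {
    stop("species table has duplicated species_id(s): ",
         paste(unique(df$species_id[duplicated(df$species_id)]),
               collapse = ", "), call. = FALSE)
  }
  if (any(is.na(df$family) | !nzchar(trimws(df$family)))) {
    stop("species table has empty family entries", call. = FALSE)
  }
  df
}

#' Read an ailment-to-category map
#'
#' @param path Path to a CSV file with columns `ailment` and `category`.
#' @return A named character vector: `map[ailment] == category`.
#' @export
read_category_map <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    .default = readr::col_character()))
  if (!all(c("ailment", "category") %in% names(df))) {
    stop("category map must have columns 'ailment' and 'category'",
         call. = FALSE)
  }
  dup <- df$ailment[duplicated(df$ailment)]
  if (length(dup) > 0) {
    stop("ailment(s) mapped to more than one category: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  setNames(df$category, df$ailment)
}

#' Canonical ailment-category labels
#'
#' The sixteen Heinrich-style symptom and ailment categories used to bin
#' free-text ailment labels for consensus analysis.
#'
#' @return A character vector of 16 category labels.
#' @export
default_categories <- function() {
  c("Muscular-skeletal disorders", "Pains",
    "Respiratory system disorders", "Liver complaints",
    "Cuts and wounds", "Inflammation",
    "Genitourinary system disorders", "Circulatory system disorders",
    "Skin diseases and disorders", "Gastrointestinal disorders",
    "Diabetes", "Nervous system disorders", "Veterinary ailments",
    "Poisonings", "Others", "Birth-related disorders")
}

#' Resolve ailment categories on a use-report table
#'
#' Fills the `category` column by looking each free-text ailment up in the
#' map. The map must be total over the ailments present; unmapped labels
#' are an error (use [validate_dataset()] for a non-throwing check).
#' Idempotent: re-resolving with the same map is a no-op.
#'
#' @param reports A use-report tibble.
#' @param map A named character vector (`ailment -> category`) or a data
#'   frame with columns `ailment`, `category`.
#' @return The reports with `category` filled; row count unchanged.
#' @export
resolve_categories <- function(reports, map) {
  if (is.data.frame(map)) map <- setNames(map$category, map$ailment)
  if (nrow(reports) == 0) return(reports)
  unmapped <- sort(unique(reports$ailment[!reports$ailment %in% names(map)]))
  if (length(unmapped) > 0) {
    stop("unmapped ailment label(s): ", paste(unmapped, collapse = ", "),
         call. = FALSE)
  }
  reports$category <- unname(map[reports$ailment])
  reports
}

#' Validate a survey dataset
#'
#' Reports content problems without raising: unknown species ids, ailments
#' absent from the category map, invalid administration routes, and
#' duplicated `(informant, species, ailment)` triples. A clean dataset
#' yields a zero-row tibble.
#'
#' @param reports A use-report tibble (deduplication may be disabled on
#'   read to surface duplicate triples here).
#' @param species_table A species tibble (see [read_species_table()]),
#'   or `NULL` to skip the species check.
#' @param map An ailment-to-category map, or `NULL` to skip that check.
#' @return A tibble with columns `issue`, `value`, `n` listing each
#'   distinct problem and how many rows it affects.
#' @export
validate_dataset <- function(reports, species_table = NULL, map = NULL) {
  issues <- list()
  if (!is.null(species_table)) {
    unknown <- setdiff(unique(reports$species_id), species_table$species_id)
    if (length(unknown) > 0) {
      issues[[length(issues) + 1L]] <- tibble::tibble(
        issue = "unknown_species", value = sort(unknown),
        n = unname(vapply(sort(unknown),
                          function(s) sum(reports$species_id == s),
                          integer(1))))
    }
  }
  if (!is.null(map)) {
    if (is.data.frame(map)) map <- setNames(map$category, map$ailment)
    unmapped <- setdiff(unique(reports$ailment), names(map))
    if (length(unmapped) > 0) {
      issues[[length(issues) + 1L]] <- tibble::tibble(
        issue = "unmapped_ailment", value = sort(unmapped),
        n = unname(vapply(sort(unmapped),
                          function(a) sum(reports$ailment == a),
                          integer(1))))
    }
  }
  route_ok <- vapply(attr_split(reports$route),
                     function(r) all(r %in% ROUTE_LEVELS), logical(1))
  if (any(!route_ok)) {
    bad <- sort(unique(reports$route[!route_ok]))
    issues[[length(issues) + 1L]] <- tibble::tibble(
      issue = "invalid_route", value = bad,
      n = unname(vapply(bad, function(r) sum(reports$route == r),
                        integer(1))))
  }
  key <- paste(reports$informant_id, reports$species_id, reports$ailment,
               sep = "\r")
  dup <- unique(key[duplicated(key)])
  if (length(dup) > 0) {
    issues[[length(issues) + 1L]] <- tibble::tibble(
      issue = "duplicate_triple",
      value = gsub("\r", " / ", sort(dup), fixed = TRUE),
      n = unname(vapply(sort(dup), function(k) sum(key == k),
                        integer(1))))
  }
  if (length(issues) == 0) {
    return(tibble::tibble(issue = character(), value = character(),
                          n = integer()))
  }
  dplyr::bind_rows(issues)
}
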