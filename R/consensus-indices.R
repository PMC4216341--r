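# Consensus statistics over deduplicated use reports: the informant
# consensus factor (ICF) per ailment category, the fidelity level (FL) per
# species-ailment pair, and the descriptive frequency tables.

#' Round half away from zero
#'
#' Printed ethnobotanical tables round half-up (0.945 -> 0.95), whereas
#' base [round()] rounds half to even. All presentation rounding in this
#' package goes through this helper; computation keeps full precision.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Informant consensus factor
#'
#' ICF = (nur - nt) / (nur - 1), where `nur` is the number of use reports
#' in an ailment category and `nt` the number of distinct species cited in
#' it. ICF is 1 when all informants converge on a single species and 0
#' when every citation names a different species. A category with a single
#' citation (`nur == 1`) makes the formula 0/0; by convention it returns 0
#' (one citation carries no consensus evidence) and is flagged as
#' degenerate by [category_consensus_table()].
#'
#' @param nur Use-report count(s) per category, `>= 1`.
#' @param nt Distinct-species count(s) per category, `1 <= nt <= nur`.
#' @return ICF value(s) in `[0, 1]`, full precision.
#' @examples
#' compute_icf(2142, 49) # ~0.98
#' compute_icf(100, 1)   # perfect consensus
#' @export
compute_icf <- function(nur, nt) {
  if (length(nur) != length(nt)) {
    stop("nur and nt must have equal length", call. = FALSE)
  }
  if (any(nur < 1)) stop("nur must be >= 1", call. = FALSE)
  if (any(nt < 1 | nt > nur)) {
    stop("nt must satisfy 1 <= nt <= nur", call. = FALSE)
  }
  ifelse(nur == 1, 0, (nur - nt) / (nur - 1))
}

#' Per-category consensus table
#'
#' Tallies each ailment category present in the reports: `nt` (distinct
#' species cited), `nur` (use-report count) and the ICF, sorted by ICF
#' descending with ties broken by `nur` descending then label.
#'
#' @param reports A categorised use-report tibble (see
#'   [resolve_categories()]).
#' @return A tibble with columns `category`, `nt`, `nur`, `icf`,
#'   `icf_2dp`, `degenerate`.
#' @export
category_consensus_table <- function(reports) {
  if (nrow(reports) > 0 && anyNA(reports$category)) {
    stop("reports must be categorised first; see resolve_categories()",
         call. = FALSE)
  }
  out <- reports |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(
      nt = dplyr::n_distinct(.data$species_id),
      nur = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      icf = compute_icf(.data$nur, .data$nt),
      icf_2dp = round_half_up(.data$icf, 2),
      degenerate = .data$nur == 1L
    ) |>
    dplyr::arrange(dplyr::desc(.data$icf), dplyr::desc(.data$nur),
                   .data$category)
  out
}

#' Fidelity level
#'
#' FL = 100 * Np / N: the share of a species' use reports devoted to one
#' specific ailment, where `Np` counts reports for the (species, ailment)
#' pair and `N` all reports for the species. FL = 100 means the species is
#' cited for a single ailment only.
#'
#' @param np Report count(s) for the species-ailment pair, `>= 1`.
#' @param n Total report count(s) for the species, `np <= n`.
#' @return Percentage(s) in `(0, 100]`, full precision.
#' @examples
#' compute_fl(1, 2) # 50
#' @export
compute_fl <- function(np, n) {
  if (any(np < 1)) stop("np must be >= 1", call. = FALSE)
  if (any(np > n)) stop("np must be <= n", call. = FALSE)
  100 * np / n
}

#' Fidelity table over all species-ailment pairs
#'
#' One record per observed (species, ailment) pair. Both numerator and
#' denominator count deduplicated use reports, so within each species the
#' FL values partition: they sum to exactly 100 at full precision.
#'
#' @param reports A use-report tibble.
#' @return A tibble with columns `species_id`, `ailment`, `np`, `n`,
#'   `fl`, `fl_2dp`, sorted by species then FL descending (ties by `np`
#'   descending then ailment).
#' @export
fidelity_table <- function(reports) {
  if (nrow(reports) == 0) {
    return(tibble::tibble(species_id = character(), ailment = character(),
                          np = integer(), n = integer(),
                          fl = numeric(), fl_2dp = numeric()))
  }
  reports |>
    dplyr::count(.data$species_id, .data$ailment, name = "np") |>
    dplyr::group_by(.data$species_id) |>
    dplyr::mutate(n = sum(.data$np)) |>
    dplyr::ungroup() |>
    dplyr::mutate(fl = compute_fl(.data$np, .data$n),
                  fl_2dp = round_half_up(.data$fl, 2)) |>
    dplyr::arrange(.data$species_id, dplyr::desc(.data$fl),
                   dplyr::desc(.data$np), .data$ailment)
}

#' Species with 100% fidelity
#'
#' Species whose every use report names the same single ailment, excluding
#' rarely-cited species below `min_reports` total reports. The default of
#' 2 drops species mentioned only once, for which FL = 100 is vacuous.
#'
#' @param fidelity A fidelity tibble from [fidelity_table()].
#' @param min_reports Minimum total report count `n` (default 2).
#' @return A sorted character vector of species ids.
#' @export
fl100_species <- function(fidelity, min_reports = 2) {
  if (min_reports < 1) stop("min_reports must be >= 1", call. = FALSE)
  fidelity |>
    dplyr::group_by(.data$species_id) |>
    dplyr::filter(dplyr::n() == 1L, .data$fl == 100,
                  .data$n >= min_reports) |>
    dplyr::ungroup() |>
    dplyr::pull(.data$species_id) |>
    sort()
}

#' Family representation summary
#'
#' For each botanical family: the distinct-species count with its share of
#' all cited species, and the use-report count with its share of all
#' reports. Both bases are emitted because field studies quote the two
#' interchangeably; the `basis` column labels them.
#'
#' @param reports A use-report tibble.
#' @param species_table A species tibble with `species_id` and `family`.
#' @return A tibble with columns `family`, `basis`
#'   (`"species"`/`"reports"`), `count`, `pct`, `denominator`, sorted by
#'   basis then count descending then family.
#' @export
family_summary <- function(reports, species_table) {
  unknown <- setdiff(unique(reports$species_id), species_table$species_id)
  if (length(unknown) > 0) {
    stop("species id(s) absent from species table: ",
         paste(sort(unknown), collapse = ", "), call. = FALSE)
  }
  joined <- dplyr::left_join(
    reports, species_table[, c("species_id", "family")], by = "species_id")
  by_species <- joined |>
    dplyr::distinct(.data$species_id, .data$family) |>
    dplyr::count(.data$family, name = "count") |>
    dplyr::mutate(basis = "species")
  by_reports <- joined |>
    dplyr::count(.data$family, name = "count") |>
    dplyr::mutate(basis = "reports")
  dplyr::bind_rows(by_species, by_reports) |>
    dplyr::group_by(.data$basis) |>
    dplyr::mutate(denominator = sum(.data$count),
                  pct = round_half_up(100 * .data$count /
                                        .data$denominator, 1)) |>
    dplyr::ungroup() |>
    dplyr::select(dplyr::all_of(
      c("family", "basis", "count", "pct", "denominator"))) |>
    dplyr::arrange(.data$basis, dplyr::desc(.data$count), .data$family)
}

#' Usage frequency summary along one attribute axis
#'
#' Tallies attribute occurrences along `plant_part`, `preparation` or
#' `route`. Each member of a report's attribute set counts once for that
#' report, and the denominator is the total number of attribute
#' occurrences on the axis, so percentages sum to 100.
#'
#' @param reports A use-report tibble.
#' @param axis One of `"plant_part"`, `"preparation"`, `"route"`.
#' @return A tibble with columns `key`, `count`, `pct`, `denominator`,
#'   sorted by count descending then key, with attribute `n_labels`
#'   giving the number of distinct labels on the axis.
#' @export
usage_summary <- function(reports,
                          axis = c("plant_part", "preparation", "route")) {
  axis <- match.arg(axis)
  labels <- unlist(attr_split(reports[[axis]]))
  if (length(labels) == 0) {
    out <- tibble::tibble(key = character(), count = integer(),
                          pct = numeric(), denominator = integer())
    attr(out, "n_labels") <- 0L
    return(out)
  }
  tab <- sort(table(labels), decreasing = TRUE)
  out <- tibble::tibble(
    key = names(tab),
    count = as.integer(tab),
    denominator = length(labels)
  ) |>
    dplyr::mutate(pct = round_half_up(100 * .data$count /
                                        .data$denominator, 1)) |>
    dplyr::arrange(dplyr::desc(.data$count), .data$key) |>
    dplyr::select(dplyr::all_of(c("key", "count", "pct", "denominator")))
  attr(out, "n_labels") <- nrow(out)
  out
}

#' Per-species ailment breadth
#'
#' Number of distinct ailments each species is cited for, sorted
#' descending with ties broken by species label.
#'
#' @param reports A use-report tibble.
#' @return A tibble with columns `species_id`, `n_ailments`.
#' @export
ailment_breadth <- function(reports) {
  if (nrow(reports) == 0) {
    return(tibble::tibble(species_id = character(), n_ailments = integer()))
  }
  reports |>
    dplyr::group_by(.data$species_id) |>
    dplyr::summarise(n_ailments = dplyr::n_distinct(.data$ailment),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$n_ailments), .data$species_id)
}

#' Medicinal share of the local flora
#'
#' Percentage of the study area's flora used medicinally, rounded half-up
#' to one decimal for presentation.
#'
#' @param n_medicinal Number of medicinal species, `0 <= n_medicinal <=
#'   n_flora`.
#' @param n_flora Total species count of the flora, `>= 1`.
#' @return A percentage.
#' @examples
#' flora_coverage(200, 542) # 36.9
#' @export
flora_coverage <- function(n_medicinal, n_flora) {
  if (n_flora < 1) stop("n_flora must be >= 1", call. = FALSE)
  if (n_medicinal < 0 || n_medicinal > n_flora) {
    stop("n_medicinal must be in [0, n_flora]", call. = FALSE)
  }
  round_half_up(100 * n_medicinal / n_flora, 1)
}
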