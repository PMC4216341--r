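# End-to-end orchestration: validate -> consensus indices -> network ->
# report, with deterministic file outputs and a manifest.

#' ICF table from published category counts
#'
#' Field studies publish per-category `(nt, nur)` counts rather than raw
#' reports. This shortcut computes the ICF column directly from such a
#' counts table so published tables can be reproduced and checked without
#' the underlying survey.
#'
#' @param counts A data frame with columns `category`, `nt`, `nur`.
#' @return A tibble with `icf` (full precision) and `icf_2dp` appended,
#'   input row order preserved.
#' @export
icf_from_counts <- function(counts) {
  stopifnot(all(c("category", "nt", "nur") %in% names(counts)))
  tibble::as_tibble(counts) |>
    dplyr::mutate(icf = compute_icf(.data$nur, .data$nt),
                  icf_2dp = round_half_up(.data$icf, 2))
}

md_table <- function(df) {
  fmt <- function(x) {
    if (is.numeric(x) && !is.integer(x)) sprintf("%.4f", x)
    else as.character(x)
  }
  cells <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1) cells <- matrix(cells, nrow = 1)
  c(paste0("| ", paste(names(df), collapse = " | "), " |"),
    paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|"),
    apply(cells, 1, function(r) paste0("| ", paste(r, collapse = " | "),
                                       " |")))
}

#' Run the full survey analysis pipeline
#'
#' Validates the dataset, computes the consensus indices and frequency
#' summaries, builds and analyses the two-mode network, and writes every
#' artifact plus a markdown report and a JSON manifest to `out_dir`.
#' All outputs are byte-deterministic for fixed inputs and seed.
#'
#' @param reports A use-report tibble or path to a use-reports CSV.
#' @param species A species tibble or path to a species CSV.
#' @param category_map A map (named vector / data frame) or path to a
#'   category-map CSV.
#' @param out_dir Output directory (created if absent).
#' @param seed Integer seed for the stochastic stages (layout, grouping).
#' @param network_mode `"category"` or `"ailment"` row nodes.
#' @param min_reports_fl100 Threshold for [fl100_species()].
#' @param layout_iterations Force-directed layout iterations.
#' @param force Continue despite validation issues (default FALSE).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(reports, species, category_map, out_dir,
                         seed = 1L, network_mode = "category",
                         min_reports_fl100 = 2, layout_iterations = 500,
                         force = FALSE) {
  if (is.character(reports)) reports <- read_use_reports(reports)
  if (is.character(species)) species <- read_species_table(species)
  if (is.character(category_map)) {
    category_map <- read_category_map(category_map)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "summaries"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "network"), showWarnings = FALSE)

  issues <- validate_dataset(reports, species, category_map)
  jsonl <- file.path(out_dir, "validation.jsonl")
  con <- file(jsonl, open = "wb")
  if (nrow(issues) > 0) {
    writeLines(vapply(seq_len(nrow(issues)), function(i) {
      jsonlite::toJSON(as.list(issues[i, ]), auto_unbox = TRUE)
    }, character(1)), con, sep = "\n")
  }
  close(con)
  if (nrow(issues) > 0) {
    if (!force) {
      stop("dataset failed validation with ", nrow(issues),
           " issue(s); see ", jsonl, " or rerun with force = TRUE",
           call. = FALSE)
    }
    if (is.data.frame(category_map)) {
      category_map <- setNames(category_map$category,
                               category_map$ailment)
    }
    keep <- reports$species_id %in% species$species_id &
      reports$ailment %in% names(category_map)
    if (any(!keep)) {
      warning("force = TRUE: dropping ", sum(!keep),
              " report(s) with unknown species or unmapped ailments",
              call. = FALSE)
      reports <- reports[keep, ]
    }
  }

  reports <- resolve_categories(reports, category_map)
  write_use_reports(reports, file.path(out_dir, "use_reports.csv"))

  icf_tab <- category_consensus_table(reports)
  readr::write_csv(icf_tab, file.path(out_dir, "icf_by_category.csv"))
  fid <- fidelity_table(reports)
  readr::write_csv(fid, file.path(out_dir, "fidelity.csv"))
  fl100 <- fl100_species(fid, min_reports = min_reports_fl100)
  breadth <- ailment_breadth(reports)
  readr::write_csv(breadth, file.path(out_dir, "ailment_breadth.csv"))
  fam <- family_summary(reports, species)
  readr::write_csv(fam, file.path(out_dir, "summaries", "family.csv"))
  for (axis in c("plant_part", "preparation", "route")) {
    readr::write_csv(usage_summary(reports, axis),
                     file.path(out_dir, "summaries",
                               paste0(axis, ".csv")))
  }

  inc <- build_incidence(reports, mode = network_mode)
  write_ucinet_dl(inc, file.path(out_dir, "network", "incidence.dl"))
  write_network_graphml(inc, file.path(out_dir, "network",
                                       "network.graphml"))
  write_edge_list(inc, file.path(out_dir, "network", "edges.tsv"))
  proj <- project_categories(inc)
  groups <- detect_groups(proj, seed = seed)
  readr::write_csv(groups$membership,
                   file.path(out_dir, "network", "groups.csv"))
  layout <- layout_spring(inc, seed = seed,
                          iterations = layout_iterations)
  readr::write_csv(layout, file.path(out_dir, "network", "layout.csv"))

  report_lines <- c(
    "# Survey analysis report", "",
    sprintf("Use reports: %d; species: %d; categories: %d; seed: %d.",
            nrow(reports), dplyr::n_distinct(reports$species_id),
            dplyr::n_distinct(reports$category), seed), "",
    "## Informant consensus by ailment category", "",
    md_table(icf_tab[, c("category", "nt", "nur", "icf_2dp")]), "",
    sprintf("## Species with 100%% fidelity (n >= %d): %d",
            min_reports_fl100, length(fl100)), "",
    if (length(fl100) > 0) c(paste0("- ", fl100), "") else NULL,
    "## Category groups (greedy modularity)", "",
    md_table(groups$membership),
    sprintf("\nModularity: %.4f (%d groups)",
            groups$modularity, groups$n_groups))
  con <- file(file.path(out_dir, "report.md"), open = "wb")
  writeLines(report_lines, con, sep = "\n")
  close(con)

  artifacts <- c("use_reports.csv", "validation.jsonl",
                 "icf_by_category.csv", "fidelity.csv",
                 "ailment_breadth.csv", "summaries/family.csv",
                 "summaries/plant_part.csv", "summaries/preparation.csv",
                 "summaries/route.csv", "network/incidence.dl",
                 "network/network.graphml", "network/edges.tsv",
                 "network/groups.csv", "network/layout.csv", "report.md")
  manifest <- list(
    package = "ethnoconsensus",
    version = as.character(utils::packageVersion("ethnoconsensus")),
    seed = seed,
    network_mode = network_mode,
    n_reports = nrow(reports),
    n_species = dplyr::n_distinct(reports$species_id),
    n_issues = nrow(issues),
    input_digest = unname(tools::md5sum(
      file.path(out_dir, "use_reports.csv"))),
    artifacts = artifacts
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
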