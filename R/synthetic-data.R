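# Seeded generator of synthetic informant surveys with controlled
# consensus. Per category a species-preference distribution is drawn from
# a symmetric Dirichlet(alpha / S_c); each informant makes Poisson(lambda_c)
# citation attempts from it and duplicate attempts collapse, so the emitted
# citations are DISTINCT within informant and category -- the deduplicated
# (informant, species, ailment) counting unit holds by construction, and a
# fully concentrated preference distribution yields one species per
# category. A with-replacement oracle mode keeps the duplicates so the
# closed-form occupancy expectation applies exactly.

DEFAULT_PARTS <- c("Stem", "Root", "Fruit", "Whole part", "Seed", "Leaf",
                   "Flower", "Bark", "Sap", "Aerial part")
DEFAULT_PREPARATIONS <- c(
  "Infusion", "A sweet drink made from fermented rice", "Brewing",
  "Maceration", "Juice", "Decoction", "Dried", "Pill", "Raw",
  "Grain syrup", "Simmer", "Tea")

#' Configure a synthetic informant survey
#'
#' Defaults emulate a field survey of 208 informants citing about 200
#' vascular-plant species over the 16 canonical ailment categories, with
#' a citation intensity calibrated so the total use-report count lands
#' near fourteen thousand (the order of magnitude a survey of that size
#' yields at roughly four citations per informant per category).
#'
#' @param n_informants Number of informants (default 208).
#' @param categories Character vector of ailment-category labels.
#' @param n_species Size of the species universe pools are drawn from
#'   (ignored when `species_pools` is given).
#' @param pool_size Per-category species-pool size `S_c`; recycled over
#'   categories. Pools are sampled from the common species universe, so
#'   categories share species at random.
#' @param lambda Mean citation attempts per informant per category
#'   (scalar or per-category vector), the Poisson intensity; duplicate
#'   attempts collapse, so emitted citations per informant-category
#'   average at most `lambda`.
#' @param alpha Dirichlet concentration `>= 0` controlling within-category
#'   consensus: small `alpha` concentrates citations on few species (high
#'   ICF), large `alpha` approaches uniform use of the pool (low ICF).
#' @param ailments_per_category Distinct free-text ailment labels per
#'   category.
#' @param p_oral Probability a report is administered orally (vs
#'   topically).
#' @param parts,preparations Attribute label pools, sampled with
#'   Zipf-decaying probabilities (frequency of label r proportional to
#'   1/r), mimicking the heavy-tailed usage of parts and preparation
#'   modes in real surveys.
#' @param n_families Number of synthetic botanical families, assigned to
#'   species with Zipf-decaying probabilities.
#' @param species_pools Optional named list `category -> character vector
#'   of species ids`, overriding random pool construction (e.g. from
#'   [make_blocked_pools()]).
#' @param fl100_species Number of extra species forced to be
#'   single-ailment with at least two citations (for fidelity bookkeeping
#'   tests); default 0.
#' @param replace Oracle mode: informants draw species with replacement
#'   and duplicate rows are kept, so the uniform-case occupancy formula
#'   [expected_distinct_species()] applies exactly. Default `FALSE`.
#' @param uniform Use fixed uniform species weights instead of a
#'   Dirichlet draw (the infinite-concentration limit). Default `FALSE`.
#' @param seed Integer seed (mandatory).
#' @return A `survey_config` list.
#' @export
survey_config <- function(n_informants = 208,
                          categories = default_categories(),
                          n_species = 200,
                          pool_size = 60,
                          lambda = 4.2,
                          alpha = 5,
                          ailments_per_category = 3,
                          p_oral = 0.848,
                          parts = DEFAULT_PARTS,
                          preparations = DEFAULT_PREPARATIONS,
                          n_families = 25,
                          species_pools = NULL,
                          fl100_species = 0,
                          replace = FALSE,
                          uniform = FALSE,
                          seed) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  n_cat <- length(categories)
  lambda <- rep_len(lambda, n_cat)
  pool_size <- rep_len(pool_size, n_cat)
  if (any(lambda < 0)) stop("lambda must be >= 0", call. = FALSE)
  if (alpha < 0) stop("alpha must be >= 0", call. = FALSE)
  if (p_oral < 0 || p_oral > 1) stop("p_oral must be in [0, 1]",
                                     call. = FALSE)
  if (is.null(species_pools) && any(pool_size < 1)) {
    stop("pool_size must be >= 1", call. = FALSE)
  }
  if (!is.null(species_pools) &&
      !setequal(names(species_pools), categories)) {
    stop("species_pools must be named by the configured categories",
         call. = FALSE)
  }
  structure(list(
    n_informants = n_informants, categories = categories,
    n_species = n_species, pool_size = pool_size, lambda = lambda,
    alpha = alpha, ailments_per_category = ailments_per_category,
    p_oral = p_oral, parts = parts, preparations = preparations,
    n_families = n_families, species_pools = species_pools,
    fl100_species = fl100_species, replace = replace, uniform = uniform,
    seed = as.integer(seed)
  ), class = "survey_config")
}

# log-weights of a symmetric Dirichlet(a) draw of length S, numerically
# robust for tiny a via Gamma(a) = Gamma(a + 1) * U^(1/a)
dirichlet_log_weights <- function(S, a) {
  if (a <= 0) stop("Dirichlet shape must be > 0", call. = FALSE)
  log(rgamma(S, shape = a + 1)) + log(runif(S)) / a
}

#' Generate a synthetic survey
#'
#' Runs the generative model of [survey_config()] under a single seeded
#' pseudo-random stream and returns the three survey tables plus a ledger
#' of ground truth recorded during generation. The ledger's marginals
#' (per-category `nur`/`nt`, per-species counts, attribute tallies) equal
#' exact recounts of the emitted dataset, which is what makes generated
#' surveys usable as oracles.
#'
#' @param config A `survey_config`.
#' @return A list with elements `reports` (use-report tibble), `species`
#'   (species tibble), `category_map` (ailment/category tibble) and
#'   `ledger` (list; see Details).
#' @details The ledger contains `categories` (tibble: `category`, `pool`,
#'   `nur`, `nt`), `species_counts` (tibble: `species_id`, `n`,
#'   `n_ailments`), `attribute_tallies`, `truncated` (number of
#'   informant-category draws truncated to the pool size),
#'   `forced_fl100` (ids of species forced to single-ailment use) and
#'   the seed.
#' @export
generate_survey <- function(config) {
  stopifnot(inherits(config, "survey_config"))
  withr::with_seed(config$seed, generate_survey_impl(config))
}

generate_survey_impl <- function(cfg) {
  n_cat <- length(cfg$categories)
  if (is.null(cfg$species_pools)) {
    universe <- sprintf("S%d", seq_len(cfg$n_species))
    pools <- lapply(seq_len(n_cat), function(i) {
      sort(sample(universe, min(cfg$pool_size[i], cfg$n_species)))
    })
    names(pools) <- cfg$categories
  } else {
    pools <- cfg$species_pools[cfg$categories]
    universe <- sort(unique(unlist(pools)))
  }

  rows <- vector("list", n_cat)
  cat_stats <- vector("list", n_cat)
  truncated <- 0L
  for (ci in seq_len(n_cat)) {
    pool <- pools[[ci]]
    S <- length(pool)
    if (isTRUE(cfg$uniform)) {
      logw <- rep(0, S)
      w <- rep(1 / S, S)
    } else {
      logw <- dirichlet_log_weights(S, max(cfg$alpha, 1e-12) / S)
      w <- exp(logw - max(logw))
      if (!any(w > 0)) w[which.max(logw)] <- 1
      w <- w / sum(w)
    }
    k <- rpois(cfg$n_informants, cfg$lambda[ci])
    if (!cfg$replace) {
      over <- k > S
      truncated <- truncated + sum(over)
      k[over] <- S
    }
    active <- which(k > 0)
    if (length(active) == 0) {
      cat_stats[[ci]] <- tibble::tibble(
        category = cfg$categories[ci], pool = S, nur = 0L, nt = 0L)
      next
    }
    attempts <- sample.int(S, sum(k[active]), replace = TRUE, prob = w)
    informant_att <- rep(active, k[active])
    if (cfg$replace) {
      draws <- attempts
      informant <- informant_att
    } else {
      # collapse duplicate draws within each informant so the citation
      # set is distinct; under a degenerate preference distribution each
      # informant then cites exactly one species
      keep <- !duplicated(cbind(informant_att, attempts))
      draws <- attempts[keep]
      informant <- informant_att[keep]
    }
    n_rows <- length(draws)
    ailment_pool <- paste0(cfg$categories[ci], " ailment ",
                           seq_len(cfg$ailments_per_category))
    rows[[ci]] <- tibble::tibble(
      informant_id = sprintf("I%03d", informant),
      species_id = pool[draws],
      ailment = sample(ailment_pool, n_rows, replace = TRUE),
      category = cfg$categories[ci]
    )
    cat_stats[[ci]] <- tibble::tibble(
      category = cfg$categories[ci], pool = S,
      nur = n_rows, nt = length(unique(draws)))
  }
  reports <- dplyr::bind_rows(rows)

  forced <- character(0)
  if (cfg$fl100_species > 0) {
    forced <- sprintf("F%d", seq_len(cfg$fl100_species))
    fr <- tibble::tibble(
      informant_id = rep(sprintf("I%03d",
                                 seq_len(min(3, cfg$n_informants))),
                         times = cfg$fl100_species),
      species_id = rep(forced, each = min(3, cfg$n_informants)),
      ailment = rep(paste0("Dedicated ailment ",
                           seq_len(cfg$fl100_species)),
                    each = min(3, cfg$n_informants)),
      category = cfg$categories[1]
    )
    reports <- dplyr::bind_rows(reports, fr)
  }

  n_rows <- nrow(reports)
  zipf <- function(n) (1 / seq_len(n)) / sum(1 / seq_len(n))
  if (n_rows > 0) {
    reports$plant_part <- sample(cfg$parts, n_rows, replace = TRUE,
                                 prob = zipf(length(cfg$parts)))
    reports$preparation <- sample(cfg$preparations, n_rows, replace = TRUE,
                                  prob = zipf(length(cfg$preparations)))
    reports$route <- ifelse(runif(n_rows) < cfg$p_oral, "oral", "topical")
    reports <- reports[, c(REQUIRED_COLUMNS, "category")]
  } else {
    reports <- tibble::tibble(
      informant_id = character(), species_id = character(),
      ailment = character(), plant_part = character(),
      preparation = character(), route = character(),
      category = character())
  }

  all_species <- sort(unique(c(universe, forced)))
  families <- paste0("Family ", sprintf("%02d", seq_len(cfg$n_families)))
  species <- tibble::tibble(
    species_id = all_species,
    scientific_name = paste("Synthetica", tolower(all_species)),
    family = sample(families, length(all_species), replace = TRUE,
                    prob = zipf(cfg$n_families)),
    local_name = paste("local", tolower(all_species)),
    voucher = paste0("SYN", seq_along(all_species))
  )

  category_map <- dplyr::bind_rows(
    tidyr::expand_grid(category = cfg$categories,
                       idx = seq_len(cfg$ailments_per_category)) |>
      dplyr::mutate(ailment = paste0(.data$category, " ailment ",
                                     .data$idx)) |>
      dplyr::select(dplyr::all_of(c("ailment", "category"))),
    if (cfg$fl100_species > 0) {
      tibble::tibble(ailment = paste0("Dedicated ailment ",
                                      seq_len(cfg$fl100_species)),
                     category = cfg$categories[1])
    }
  )

  forced_stats <- if (cfg$fl100_species > 0) {
    tibble::tibble(category = cfg$categories[1], pool = NA_integer_,
                   nur = as.integer(cfg$fl100_species *
                                      min(3, cfg$n_informants)),
                   nt = as.integer(cfg$fl100_species))
  }
  cat_ledger <- dplyr::bind_rows(cat_stats, forced_stats) |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(pool = sum(.data$pool, na.rm = TRUE),
                     nur = sum(.data$nur), nt = sum(.data$nt),
                     .groups = "drop")

  species_counts <- if (n_rows > 0) {
    reports |>
      dplyr::group_by(.data$species_id) |>
      dplyr::summarise(n = dplyr::n(),
                       n_ailments = dplyr::n_distinct(.data$ailment),
                       .groups = "drop")
  } else {
    tibble::tibble(species_id = character(), n = integer(),
                   n_ailments = integer())
  }
  ledger <- list(
    categories = cat_ledger,
    species_counts = species_counts,
    attribute_tallies = list(
      plant_part = table(reports$plant_part),
      preparation = table(reports$preparation),
      route = table(reports$route)),
    truncated = truncated,
    forced_fl100 = forced,
    seed = cfg$seed
  )
  list(reports = reports, species = species, category_map = category_map,
       ledger = ledger)
}

#' Expected number of distinct species under uniform sampling
#'
#' Closed-form occupancy expectation for `nur` independent uniform draws
#' from a pool of `S` species: `S * (1 - (1 - 1/S)^nur)`. This is the
#' oracle for the generator's with-replacement uniform mode.
#'
#' @param S Pool size, `>= 1`.
#' @param nur Number of draws, `>= 0`.
#' @return Expected distinct-species count.
#' @examples
#' expected_distinct_species(20, 40)
#' @export
expected_distinct_species <- function(S, nur) {
  if (any(S < 1)) stop("S must be >= 1", call. = FALSE)
  if (any(nur < 0)) stop("nur must be >= 0", call. = FALSE)
  S * (1 - (1 - 1 / S)^nur)
}

#' Build species pools with planted block structure
#'
#' Assigns categories to blocks in order and gives every category in a
#' block the same block-specific species pool, optionally plus a small
#' globally shared pool. With low between-block sharing the category
#' projection of a survey generated from these pools has planted
#' community structure, which [detect_groups()] should recover.
#'
#' @param categories Category labels (length divisible by `n_blocks`).
#' @param n_blocks Number of planted groups.
#' @param species_per_block Species in each block pool.
#' @param shared_species Number of extra species shared by all blocks
#'   (default 0).
#' @return A named list `category -> species ids`, with attribute
#'   `block` giving each category's planted block id.
#' @export
make_blocked_pools <- function(categories, n_blocks = 4,
                               species_per_block = 25,
                               shared_species = 0) {
  n_cat <- length(categories)
  if (n_cat %% n_blocks != 0) {
    stop("length(categories) must be divisible by n_blocks", call. = FALSE)
  }
  block <- rep(seq_len(n_blocks), each = n_cat / n_blocks)
  shared <- if (shared_species > 0) {
    sprintf("SHARED%d", seq_len(shared_species))
  } else character(0)
  pools <- lapply(seq_len(n_cat), function(i) {
    c(sprintf("B%d_S%d", block[i], seq_len(species_per_block)), shared)
  })
  names(pools) <- categories
  attr(pools, "block") <- setNames(block, categories)
  pools
}
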