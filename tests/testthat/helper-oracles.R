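# Shared fixtures and independent brute-force oracles. The oracles are
# deliberately written as plain loops over rows/cells so they share no
# code path with the implementation they check.

make_reports <- function(informant, species, ailment,
                         plant_part = "Stem", preparation = "Infusion",
                         route = "oral", category = NA_character_) {
  tibble::tibble(
    informant_id = informant, species_id = species, ailment = ailment,
    plant_part = plant_part, preparation = preparation, route = route,
    category = category
  )
}

# random categorised use-report table with unique triples
random_reports <- function(seed, n = 60, n_informants = 15, n_species = 12,
                           n_categories = 4) {
  withr::with_seed(seed, {
    cats <- paste0("Cat", seq_len(n_categories))
    pool <- expand.grid(
      informant_id = sprintf("I%02d", seq_len(n_informants)),
      species_id = sprintf("S%02d", seq_len(n_species)),
      ailment_idx = 1:2, stringsAsFactors = FALSE)
    pick <- pool[sample(nrow(pool), min(n, nrow(pool))), ]
    cat_of_ailment <- sample(cats, n_species * 2, replace = TRUE)
    ailment <- paste0("A", pick$species_id, "_", pick$ailment_idx)
    # ailment labels tied to species so the category map stays total
    idx <- (match(pick$species_id,
                  sprintf("S%02d", seq_len(n_species))) - 1) * 2 +
      pick$ailment_idx
    make_reports(pick$informant_id, pick$species_id, ailment,
                 plant_part = sample(c("Stem", "Root", "Leaf"),
                                     nrow(pick), replace = TRUE),
                 preparation = sample(c("Infusion", "Juice", "Pill"),
                                      nrow(pick), replace = TRUE),
                 route = sample(c("oral", "topical"), nrow(pick),
                                replace = TRUE),
                 category = cat_of_ailment[idx])
  })
}

# single-pass tally of (nt, nur, icf) per category using environments
brute_consensus <- function(reports) {
  nur <- new.env(); sp <- new.env()
  for (i in seq_len(nrow(reports))) {
    cat <- reports$category[i]
    nur[[cat]] <- (if (is.null(nur[[cat]])) 0L else nur[[cat]]) + 1L
    sp[[cat]] <- unique(c(sp[[cat]], reports$species_id[i]))
  }
  cats <- sort(ls(nur))
  out <- data.frame(category = cats,
                    nt = vapply(cats, function(c) length(sp[[c]]),
                                integer(1)),
                    nur = vapply(cats, function(c) nur[[c]], integer(1)))
  out$icf <- ifelse(out$nur == 1, 0,
                    (out$nur - out$nt) / (out$nur - 1))
  out[order(-out$icf, -out$nur, out$category), ]
}

brute_degree <- function(m, weighted = FALSE) {
  deg <- function(v) if (weighted) sum(v) else sum(v > 0)
  data.frame(
    node = c(rownames(m), colnames(m)),
    degree = c(vapply(seq_len(nrow(m)), function(i) deg(m[i, ]),
                      numeric(1)),
               vapply(seq_len(ncol(m)), function(j) deg(m[, j]),
                      numeric(1))))
}

brute_projection <- function(m) {
  p <- matrix(0L, nrow(m), nrow(m), dimnames = list(rownames(m),
                                                    rownames(m)))
  for (a in seq_len(nrow(m))) {
    for (b in seq_len(nrow(m))) {
      p[a, b] <- length(intersect(colnames(m)[m[a, ] > 0],
                                  colnames(m)[m[b, ] > 0]))
    }
  }
  p
}

random_matrix <- function(seed, nr = 6, nc = 10, max_count = 4) {
  withr::with_seed(seed, {
    m <- matrix(rpois(nr * nc, 0.8), nr,
                dimnames = list(paste0("cat", seq_len(nr)),
                                paste0("sp", seq_len(nc))))
    m[m > max_count] <- max_count
    storage.mode(m) <- "integer"
    m
  })
}
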