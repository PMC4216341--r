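test_that("compute_icf matches published category values and closed forms", {
  expect_equal(round_half_up(compute_icf(2142, 49), 2), 0.98)
  expect_equal(round_half_up(compute_icf(138, 14), 2), 0.91)
  for (k in c(2, 5, 100)) expect_equal(compute_icf(k, k), 0)
  expect_equal(compute_icf(100, 1), 1)
  expect_equal(compute_icf(1, 1), 0)
  expect_error(compute_icf(5, 6), "nt")
  expect_error(compute_icf(5, 0), "nt")
  expect_error(compute_icf(0, 0), "nur")
})

test_that("all sixteen published category ICF values reproduce at 2 dp", {
  counts <- readr::read_csv(
    system.file("extdata", "gayasan_icf_counts.csv",
                package = "ethnoconsensus"),
    show_col_types = FALSE)
  out <- icf_from_counts(counts)
  expect_equal(out$icf_2dp, out$icf_printed)
})

test_that("presentation rounding is half-up, not banker's", {
  expect_equal(round_half_up(0.945, 2), 0.95)
  expect_equal(round_half_up(155 / 164, 2), 0.95)
  expect_equal(round_half_up(0.944999, 2), 0.94)
  expect_equal(round_half_up(-0.945, 2), -0.95)
  expect_equal(round_half_up(36.90036, 1), 36.9)
})

test_that("category consensus table tallies and sorts correctly", {
  reports <- make_reports(c("i1", "i2", "i3"), c("sA", "sA", "sB"),
                          c("cough", "cough", "asthma"),
                          category = "Respiratory system disorders")
  tab <- category_consensus_table(reports)
  expect_equal(tab$nt, 2L)
  expect_equal(tab$nur, 3L)
  expect_equal(tab$icf, 0.5)
  expect_false(tab$degenerate)

  single <- category_consensus_table(
    make_reports("i1", "sA", "cough", category = "Pains"))
  expect_equal(single$icf, 0)
  expect_true(single$degenerate)

  expect_error(category_consensus_table(
    make_reports("i1", "sA", "cough")), "categorised")
})

test_that("near-degenerate Dirichlet concentration drives ICF to 1", {
  sim <- generate_survey(survey_config(
    n_informants = 100, categories = "Pains", n_species = 50,
    pool_size = 50, lambda = 2, alpha = 1e-6, seed = 3))
  tab <- category_consensus_table(sim$reports)
  expect_equal(tab$nt, 1L)
  expect_equal(tab$icf, 1)
})

test_that("ICF is monotone under replication and new-species reports", {
  for (seed in 1:20) {
    reports <- random_reports(seed, n = 40)
    tab <- category_consensus_table(reports)
    r <- 3
    rep_icf <- compute_icf(r * tab$nur, tab$nt)
    strict <- tab$nur > 1 & tab$nt > 1  # icf < 1 and defined
    expect_true(all(rep_icf[strict] > tab$icf[strict]))
    expect_true(all(rep_icf >= tab$icf))
    new_icf <- compute_icf(tab$nur + 1, tab$nt + 1)
    expect_true(all(new_icf <= tab$icf))
    expect_true(all(tab$icf >= 0 & tab$icf <= 1))
    expect_true(all((tab$icf == 1) == (tab$nt == 1 & tab$nur >= 2)))
    expect_true(all((tab$icf == 0) == (tab$nt == tab$nur)))
  }
})

test_that("compute_fl matches published and closed-form cases", {
  expect_equal(compute_fl(1, 1), 100)
  expect_equal(compute_fl(1, 2), 50)   # the printed equal two-way split
  expect_equal(compute_fl(3, 4), 75)
  expect_error(compute_fl(0, 1), "np")
  expect_error(compute_fl(3, 2), "np")
})

test_that("fidelity values partition each species' reports", {
  reports <- make_reports(
    c("i1", "i2", "i3", "i4"), "sA",
    c("cough", "cough", "cough", "fever"))
  fid <- fidelity_table(reports)
  expect_equal(fid$fl, c(75, 25))
  expect_equal(fid$np, c(3L, 1L))
  expect_equal(fid$n, c(4L, 4L))

  one <- fidelity_table(make_reports("i1", "sA", "cough"))
  expect_equal(one$fl, 100)

  expect_equal(nrow(fidelity_table(make_reports(
    character(), character(), character()))), 0)

  for (seed in 1:20) {
    fid <- fidelity_table(random_reports(seed))
    sums <- tapply(fid$fl, fid$species_id, sum)
    expect_equal(as.vector(sums), rep(100, length(sums)))
    sums2 <- tapply(fid$fl_2dp, fid$species_id, sum)
    expect_true(all(abs(sums2 - 100) <= 0.05))
    expect_equal(unname(tapply(fid$np, fid$species_id, sum)),
                 unname(tapply(fid$n, fid$species_id, function(x) x[1])))
  }
})

test_that("fl100_species applies the single-ailment and report thresholds", {
  fid <- fidelity_table(make_reports(
    c("i1", "i2", "i3", "i4", "i5", "i6"),
    c("sA", "sA", "sA", "sA", "sA", "sB"),
    c("cough", "cough", "cough", "cough", "cough", "fever")))
  expect_equal(fl100_species(fid, min_reports = 2), "sA")
  expect_equal(fl100_species(fid, min_reports = 1), c("sA", "sB"))
  expect_error(fl100_species(fid, min_reports = 0), "min_reports")

  sim <- generate_survey(survey_config(
    n_informants = 30, categories = paste0("C", 1:3), n_species = 40,
    pool_size = 15, lambda = 2, alpha = 50, ailments_per_category = 1,
    fl100_species = 4, seed = 9))
  fid <- fidelity_table(sim$reports)
  got <- fl100_species(fid, min_reports = 2)
  expect_true(all(sim$ledger$forced_fl100 %in% got))
})

test_that("family summary emits both species and citation bases", {
  species <- tibble::tibble(
    species_id = sprintf("S%d", 1:200),
    scientific_name = sprintf("Sp %d", 1:200),
    family = c(rep("Rosaceae", 13), rep("Other", 187)))
  reports <- make_reports(
    rep("i1", 200), sprintf("S%d", 1:200), sprintf("a%d", 1:200))
  fam <- family_summary(reports, species)
  ros <- fam[fam$family == "Rosaceae" & fam$basis == "species", ]
  expect_equal(ros$count, 13L)
  expect_equal(ros$pct, 6.5)
  expect_equal(ros$denominator, 200L)

  solo <- family_summary(
    make_reports("i1", "S1", "a"),
    species[1, ])
  expect_equal(solo$pct, c(100, 100))

  expect_error(family_summary(
    make_reports("i1", "SX", "a"), species), "SX")
})

test_that("family tallies equal the generator's family assignment", {
  sim <- generate_survey(survey_config(
    n_informants = 20, categories = paste0("C", 1:4), n_species = 30,
    pool_size = 12, lambda = 1, alpha = 5, seed = 21))
  fam <- family_summary(sim$reports, sim$species)
  cited <- unique(sim$reports$species_id)
  truth <- table(sim$species$family[sim$species$species_id %in% cited])
  got <- fam[fam$basis == "species", ]
  expect_equal(setNames(got$count, got$family)[names(truth)],
               setNames(as.integer(truth), names(truth)))
})

test_that("usage summary counts attribute occurrences per axis", {
  reports <- make_reports(c("i1", "i2", "i3"), c("sA", "sB", "sC"),
                          c("a", "b", "c"),
                          plant_part = c("stem", "stem", "root"))
  parts <- usage_summary(reports, "plant_part")
  expect_equal(parts$key, c("stem", "root"))
  expect_equal(parts$pct, c(66.7, 33.3))
  expect_equal(attr(parts, "n_labels"), 2L)

  routes <- usage_summary(make_reports(
    sprintf("i%d", 1:10), sprintf("s%d", 1:10), letters[1:10],
    route = rep(c("oral", "topical"), 5)), "route")
  expect_equal(routes$pct, c(50, 50))

  # each member of an attribute set counts once per report
  set_reports <- make_reports("i1", "sA", "a",
                              preparation = "infusion, brewing")
  preps <- usage_summary(set_reports, "preparation")
  expect_equal(sort(preps$key), c("brewing", "infusion"))
  expect_equal(preps$denominator, c(2L, 2L))

  expect_error(usage_summary(reports, "voucher"))
})

test_that("usage label pools match the generator's", {
  sim <- generate_survey(survey_config(
    n_informants = 40, categories = paste0("C", 1:4), n_species = 30,
    pool_size = 15, lambda = 2, alpha = 5, seed = 5))
  parts <- usage_summary(sim$reports, "plant_part")
  truth <- sim$ledger$attribute_tallies$plant_part
  expect_equal(setNames(parts$count, parts$key)[names(truth)],
               setNames(as.integer(truth), names(truth)))
  expect_equal(sum(parts$count), parts$denominator[1])
  # full-precision shares partition exactly; 1-dp rounding can drift by
  # at most half a unit in the last place per label
  expect_true(abs(sum(parts$pct) - 100) <= 0.05 * nrow(parts))
})

test_that("ailment breadth counts distinct ailments per species", {
  breadth <- ailment_breadth(make_reports(
    c("i1", "i2", "i3"), "sA", c("a", "b", "a")))
  expect_equal(breadth$n_ailments, 2L)
  expect_equal(nrow(ailment_breadth(make_reports(
    character(), character(), character()))), 0)

  hordeum <- readr::read_csv(
    system.file("extdata", "gayasan_hordeum_ailments.csv",
                package = "ethnoconsensus"),
    show_col_types = FALSE)
  reports <- make_reports(sprintf("i%d", seq_len(nrow(hordeum))),
                          hordeum$species, hordeum$ailment)
  expect_equal(ailment_breadth(reports)$n_ailments, 36L)
})

test_that("flora coverage reproduces the published share", {
  expect_equal(flora_coverage(200, 542), 36.9)
  expect_equal(flora_coverage(0, 542), 0)
  expect_equal(flora_coverage(542, 542), 100)
  expect_error(flora_coverage(543, 542), "n_medicinal")
  expect_error(flora_coverage(1, 0), "n_flora")
})
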