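# evidence table, rank rules, and pipeline orchestration

test_that("the evidence table applies the shared Bonferroni correction", {
  rows <- data.frame(pair = c("x-y", "x-z"),
                     p_niche = c(1.0, 0.005), p_efa = c(0.837, 0.02),
                     p_ldi = c(0.5, NA), p_geo = c(0.005, 0.2))
  ev <- build_evidence_table(rows, m = 6, alpha = 0.05)
  expect_equal(ev$p_niche_corr[1], 6.00)
  expect_equal(ev$p_niche_capped[1], 1.00)
  expect_equal(ev$p_niche_corr[2], 0.03)
  expect_equal(ev$p_efa_corr[1], 5.022)
  expect_equal(ev$p_efa_capped[1], 1.0)
  expect_true(ev$p_ldi_missing[2])
  expect_false(ev$p_ldi_sig[2])
  expect_true(ev$p_geo_sig[1])
  ident <- build_evidence_table(rows, m = 1)
  expect_equal(ident$p_efa_corr, rows$p_efa)
  expect_error(build_evidence_table(rbind(rows, rows[1, ]), m = 2),
               "duplicate")
})

test_that("the rank rule table is total and matches the published profiles", {
  combos <- expand.grid(gen = c(TRUE, FALSE), sym = c(TRUE, FALSE),
                        eco = c(TRUE, FALSE), mor = c(TRUE, FALSE))
  verdicts <- apply(combos, 1, function(r) {
    rank_decision("p", r[["gen"]], r[["sym"]], r[["eco"]], r[["mor"]])$verdict
  })
  expect_true(all(verdicts %in% c("species", "cryptic-species", "subspecies",
                                  "ecotype-of", "merge")))
  # genealogically distinct, sympatric, morphologically distinct -> species
  expect_identical(rank_decision("gau-vul", TRUE, TRUE, FALSE, TRUE)$verdict,
                   "species")
  # no genealogical independence, eco distinct, sympatric -> ecotype/subspecies
  expect_identical(rank_decision("pyr-vul", FALSE, TRUE, TRUE, FALSE)$verdict,
                   "ecotype-of")
  # no genealogical independence, allopatric, eco distinct -> not species rank
  expect_identical(rank_decision("plu-group", FALSE, FALSE, TRUE, TRUE)$verdict,
                   "ecotype-of")
  # allopatric + genealogically + ecologically distinct -> species
  expect_identical(rank_decision("p", TRUE, FALSE, TRUE, FALSE)$verdict,
                   "species")
  expect_identical(rank_decision("p", TRUE, FALSE, FALSE, FALSE)$verdict,
                   "subspecies")
  expect_identical(rank_decision("p", FALSE, TRUE, FALSE, FALSE)$verdict,
                   "merge")
})

test_that("unknown flags yield undecided with the gaps listed", {
  d <- rank_decision("p", TRUE, NA, TRUE, TRUE)
  expect_identical(d$verdict, "undecided")
  expect_match(d$rationale, "sympatric")
  d2 <- rank_decision("p", NA, TRUE, TRUE, TRUE)
  expect_match(d2$rationale, "genealogical")
  # morphology only decides between cryptic and plain species, so an
  # unknown morphology flag does not block an allopatric decision
  d3 <- rank_decision("p", TRUE, FALSE, TRUE, NA)
  expect_identical(d3$verdict, "species")
})

cheap_config <- function(seed, outdir = NULL,
                         stages = c("genetics", "morphology", "ecology",
                                    "geography")) {
  pipeline_config(seed = seed, outdir = outdir,
                  n_individuals = 5L, n_sites = 400L,
                  ckm_replicates = 120L, leaves_per_taxon = 5L,
                  contour_points = 96L, straighten_leaves = FALSE,
                  shape_permutations = 199L, geo_permutations = 49L,
                  niche_permutations = 49L, landscape_size = 25L,
                  n_occurrences = 35L, stages = stages)
}

test_that("pipeline reports are byte-identical across reruns", {
  d1 <- file.path(tempdir(), "rep1"); d2 <- file.path(tempdir(), "rep2")
  run_pipeline(cheap_config(5, outdir = d1))
  run_pipeline(cheap_config(5, outdir = d2))
  expect_identical(readLines(file.path(d1, "evidence_table.csv")),
                   readLines(file.path(d2, "evidence_table.csv")))
  expect_identical(readLines(file.path(d1, "decisions.json")),
                   readLines(file.path(d2, "decisions.json")))
})

test_that("disabling a stage leaves explicit gaps and undecided verdicts", {
  res <- run_pipeline(cheap_config(7, stages = c("genetics", "ecology",
                                                 "geography")))
  expect_true(all(res$evidence$p_efa_missing))
  expect_true(all(res$evidence$p_ldi_missing))
  verdicts <- vapply(res$decisions, `[[`, "", "verdict")
  # morphology is pivotal only for the sympatric genetically distinct pair
  expect_identical(verdicts[1], "undecided")
  expect_match(res$decisions[[1]]$rationale, "morpho")
})
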