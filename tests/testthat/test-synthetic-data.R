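# Generators: transcriptome, footprints, quant tables.

test_that("generated transcriptomes respect structural constraints", {
  tx <- generate_transcriptome(1, c(20, 20), "uniform", seed = 1)
  expect_equal(unname(n_codons(tx)), 20L)
  cods <- cds_codons(tx)[[1]]
  expect_identical(cods[1], "ATG")
  expect_true(cods[20] %in% stop_codons())
  expect_false(any(cods[2:19] %in% stop_codons()))

  # UTRs long enough that edge footprints stay mappable
  expect_true(all(tx$cds_start >= 34))
  expect_true(all(nchar(tx$sequence) - tx$cds_end >= 34))
})

test_that("codon usage is honored", {
  # uniform usage: internal-codon frequencies within 3 SE of 1/61
  tx <- generate_transcriptome(50, c(100, 300), "uniform", seed = 7)
  internal <- unlist(lapply(cds_codons(tx), function(x) x[-c(1, length(x))]))
  p0 <- 1 / 61
  freq <- table(factor(internal, levels = sense_codons())) / length(internal)
  se <- sqrt(p0 * (1 - p0) / length(internal))
  expect_true(all(abs(freq - p0) <= 3 * se))

  # zero-probability codon never appears
  usage <- setNames(rep(1 / 60, 61), sense_codons())
  usage["CGA"] <- 0
  usage <- usage / sum(usage)
  tx0 <- generate_transcriptome(5, c(50, 50), usage, seed = 2)
  expect_false(any(unlist(cds_codons(tx0)) == "CGA"))

  # malformed usage vectors are rejected before any work
  bad <- setNames(rep(1 / 61, 61), sense_codons())
  expect_error(generate_transcriptome(2, c(30, 30), bad * 2, seed = 1),
               "sum to 1")
  bad2 <- bad; bad2["AAA"] <- -bad2["AAA"]
  expect_error(generate_transcriptome(2, c(30, 30), bad2, seed = 1),
               "negative|sum to 1")
})

test_that("footprint simulation places reads per the truth model", {
  tx <- generate_transcriptome(1, c(200, 200), seed = 4)
  # uniform dwell, no initiation peak: per-codon counts Poisson-homogeneous
  truth <- simulation_truth(tx, start_peak = 1, seed = 9)
  sim <- simulate_footprints(tx, truth, 20000)
  counts <- sim$truth_counts[[1]][1:199]   # P-site positions 0..n-2
  disp <- sum((counts - mean(counts))^2) / mean(counts)
  p <- stats::pchisq(disp, df = length(counts) - 1, lower.tail = FALSE)
  expect_gt(min(p, 1 - p), 0.01)

  # a single strong injected pause holds the maximum count
  ip <- data.frame(transcript_id = tx$id[1], codon_index = 40L, fold = 50)
  simp <- simulate_footprints(tx, simulation_truth(tx, injected_pauses = ip,
                                                   start_peak = 1, seed = 3),
                              2000)
  expect_equal(which.max(simp$truth_counts[[1]]) - 1L, 40L)

  # degenerate length distribution
  tr28 <- simulation_truth(tx, offset_by_length = c("28" = 12),
                           length_distribution = c("28" = 1), seed = 5)
  sim28 <- simulate_footprints(tx, tr28, 500)
  expect_true(all(sim28$alignments$length == 28L))

  # no truncated reads, ever
  expect_true(all(sim$alignments$start >= 0))
  expect_true(all(sim$alignments$start + sim$alignments$length <=
                    nchar(tx$sequence[1])))

  expect_error(simulate_footprints(tx[0, ], truth, 100), "empty")
})

test_that("total read count and seeding behave as contracted", {
  tx <- generate_transcriptome(5, c(50, 80), seed = 1)
  totals <- vapply(1:20, function(s) {
    nrow(simulate_footprints(tx, simulation_truth(tx, seed = s), 2000)$alignments)
  }, numeric(1))
  # mean of 20 Poisson(2000) totals: SE = sqrt(2000/20)
  expect_lt(abs(mean(totals) - 2000), 3 * sqrt(2000 / 20))

  a <- simulate_footprints(tx, simulation_truth(tx, seed = 11), 1000)
  b <- simulate_footprints(tx, simulation_truth(tx, seed = 11), 1000)
  c2 <- simulate_footprints(tx, simulation_truth(tx, seed = 12), 1000)
  expect_identical(a$alignments, b$alignments)
  expect_false(identical(a$alignments, c2$alignments))
})

test_that("truth records survive a serialization round trip", {
  tx <- generate_transcriptome(3, c(40, 60), seed = 2)
  truth <- simulation_truth(
    tx,
    injected_pauses = data.frame(transcript_id = tx$id[1],
                                 codon_index = 10L, fold = 20),
    offset_by_length = c("28" = 12, "31" = 13),
    length_distribution = c("28" = 0.5, "31" = 0.5),
    seed = 42)
  sim <- simulate_footprints(tx, truth, 300)
  path <- withr::local_tempfile(fileext = ".json")
  write_truth_json(sim, path)
  back <- read_truth_json(path)
  expect_equal(back$transcript_abundances, truth$transcript_abundances)
  expect_equal(back$dwell_weights, truth$dwell_weights)
  expect_equal(back$offset_by_length, truth$offset_by_length)
  expect_equal(back$length_distribution, truth$length_distribution)
  expect_equal(as.data.frame(back$injected_pauses), truth$injected_pauses)
  expect_identical(back$seed, truth$seed)
  expect_equal(attr(back, "truth_counts"), sim$truth_counts)
})

test_that("simulation truth validates its invariants", {
  tx <- generate_transcriptome(2, c(30, 30), seed = 1)
  expect_error(simulation_truth(tx, dwell_weights = setNames(rep(0, 61),
                                                             sense_codons())),
               "strictly positive")
  expect_error(simulation_truth(
    tx, injected_pauses = data.frame(transcript_id = tx$id[1],
                                     codon_index = 5L, fold = 0.5)),
    "> 1")
  expect_error(simulation_truth(
    tx, injected_pauses = data.frame(transcript_id = tx$id[1],
                                     codon_index = 30L, fold = 5)),
    "outside")
  expect_error(simulation_truth(tx, length_distribution = c("28" = 0.7)),
               "sum to 1")
})

test_that("quant simulation produces the advertised structure", {
  # no dropout -> complete table
  tr <- quant_sim_truth(n_enriched = 3, dropout = NULL, seed = 1)
  sim <- simulate_quant_table(tr, 50)
  vals <- as.matrix(sim$table[names(sim$groups)])
  expect_false(anyNA(vals))
  expect_true(all(vals > 0))

  # flagged fraction lands on background rows only, at the stated rate
  trf <- quant_sim_truth(n_enriched = 5, dropout = NULL,
                         flagged_fraction = 0.2, seed = 2)
  simf <- simulate_quant_table(trf, 500)
  flagged <- simf$table$contaminant | simf$table$reverse |
    simf$table$only_identified_by_site
  expect_equal(sum(flagged), round(0.2 * 500))
  expect_false(any(flagged[simf$table$protein_id %in% trf$enriched_proteins]))

  # power: 10 proteins at effect 4, sigma 0.3, 3v3 -> all recovered
  trp <- quant_sim_truth(n_enriched = 10, effect_log2 = 4, sigma = 0.3,
                         n_replicates_per_group = 3, dropout = NULL, seed = 3)
  simp <- simulate_quant_table(trp, 200)
  res <- run_enrichment(simp$table, simp$groups, seed = 4)
  hits <- res[res$protein_id %in% trp$enriched_proteins, ]
  expect_true(all(hits$p_value < 0.01))
  expect_true(all(hits$log2_difference > 0))

  expect_error(quant_sim_truth(n_replicates_per_group = 1), ">= 2")
  # dropout probability is non-increasing in intensity
  dm <- dropout_model(20, 1)
  x <- seq(10, 30, 0.5)
  expect_true(all(diff(ribopause:::.dropout_prob(x, dm)) <= 0))
})
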