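# Density profiles, the pause z-score, calls, rankings, condition shares.

test_that("the density filter is inclusive at 0.5 reads/codon", {
  tx <- tiny_transcripts(list(t1 = c("ATG", rep("GGA", 98), "TAA")))  # 100 codons
  off <- fixed_offset_table()
  # 49 P-site reads on a 100-codon CDS: 0.49 < 0.5, excluded
  a49 <- aln_at_codons(tx, "t1", rep(10:19, length.out = 49))
  expect_length(build_profiles(a49, off, tx, 0.5), 0L)
  # 50 reads: exactly 0.5, included
  a50 <- aln_at_codons(tx, "t1", rep(10:19, length.out = 50))
  prof <- build_profiles(a50, off, tx, 0.5)
  expect_length(prof, 1L)
  expect_equal(prof$t1$mean_density, 0.5)
  expect_equal(sum(prof$t1$counts), 50L)

  expect_warning(p0 <- build_profiles(a50[0, ], off, tx, 0.5), "empty")
  expect_length(p0, 0L)
})

test_that("pause z-score matches the formula and its naive oracle", {
  # worked case: d = 30, max(background) = 10 -> z = 4
  counts <- rep(0L, 51); counts[26] <- 30L
  counts[c(10, 40)] <- 10L
  sc <- pause_scores(profile_from_counts(counts), window = 25)
  expect_equal(sc$z[26], 4)
  expect_equal(sc$background_max[26], 10)

  # zero point: count equal to the background max
  counts2 <- rep(2L, 21)
  sc2 <- pause_scores(profile_from_counts(counts2), window = 5)
  expect_true(all(sc2$z == 0))

  # all-zero flanks: not scorable, never infinite
  counts3 <- c(5L, rep(0L, 60))
  sc3 <- pause_scores(profile_from_counts(counts3), window = 10)
  expect_false(sc3$scorable[1])
  expect_true(is.na(sc3$z[1]))
  # ...but a zero-count codon with a live flank is scorable via the floor
  expect_true(sc3$scorable[2])

  # brute-force oracle agreement on 100 random profiles
  set.seed(77)
  for (k in 1:100) {
    n <- sample(30:120, 1)
    w <- sample(3:30, 1)
    counts <- rpois(n, lambda = stats::runif(1, 0.2, 4))
    got <- pause_scores(profile_from_counts(counts), window = w)
    want <- naive_pause_z(counts, window = w)
    expect_equal(got$z, want$z)
    expect_equal(got$background_max, want$bg_max)
  }
})

test_that("z-score monotonicity and scaling properties", {
  set.seed(5)
  counts <- rpois(80, 2)
  base <- pause_scores(profile_from_counts(counts), window = 10)
  # strictly increasing in the focal count, background fixed
  for (d in c(1L, 5L, 20L)) {
    bumped <- counts; bumped[40] <- bumped[40] + d
    zb <- pause_scores(profile_from_counts(bumped), window = 10)$z[40]
    expect_gt(zb, base$z[40])
  }
  # the ratio form is invariant to scaling counts and background by the
  # same factor, wherever the floor is not engaged (verified numerically)
  k <- 7L
  scaled <- pause_scores(profile_from_counts(counts * k), window = 10)
  live <- base$scorable & base$background_max > 1
  expect_equal(scaled$z[live], base$z[live])
})

test_that("calls use an inclusive threshold and rankings normalize", {
  sc <- data.frame(transcript_id = "t", codon_index = 0:2,
                   codon = c("CGA", "CAA", "AAA"),
                   count = 1L, background_max = 1,
                   z = c(9.99, 10.0, 10.1),
                   scorable = TRUE, is_edge = FALSE)
  expect_equal(nrow(call_pauses(sc, 10)), 2L)
  expect_equal(nrow(call_pauses(sc[0, ], 10)), 0L)

  calls <- data.frame(codon = rep("CGA", 4))
  rk <- rank_paused_codons(calls)
  expect_equal(nrow(rk), 61L)
  expect_equal(rk$fraction[rk$codon == "CGA"], 1)
  expect_equal(sum(rk$fraction), 1)
  expect_equal(rk$codon[1], "CGA")
  # ties broken alphabetically among the zero-count codons
  expect_identical(rk$codon[-1], sort(rk$codon[-1]))

  expect_warning(rank_paused_codons(data.frame(codon = character(0))),
                 "no pause calls")
})

test_that("condition-wise group fractions are plain call shares", {
  mk_rank <- function(codons) rank_paused_codons(data.frame(codon = codons))
  r1 <- mk_rank(c("CGA", "CGA", "CAA", "AAA"))
  out <- compare_pause_fractions(list(wt = r1, mut = r1))
  expect_equal(out$fraction[out$group == "Arg"], c(0.5, 0.5))
  expect_equal(out$fraction[out$group == "Gln"], c(0.25, 0.25))
  # identical call sets -> identical fractions, by construction
  expect_equal(out$fraction[out$condition == "wt"],
               out$fraction[out$condition == "mut"])

  expect_error(compare_pause_fractions(list(a = r1), codon_groups_default()),
               ">= 2 conditions")
  expect_error(compare_pause_fractions(list(a = r1, b = r1),
                                       list(bad = c("TAA"))),
               "unknown codon")

  # two conditions drawn from the same truth: difference within binomial error
  tx <- generate_transcriptome(30, c(100, 200), seed = 40)
  pos <- lapply(cds_codons(tx), function(x) which(x %in% c("AGA", "AGG")))
  ip <- do.call(rbind, lapply(names(pos), function(id) {
    p <- pos[[id]]; p <- p[p > 3 & p < length(cds_codons(tx)[[id]]) - 3]
    if (!length(p)) return(NULL)
    data.frame(transcript_id = id, codon_index = p[1] - 1L, fold = 50)
  }))
  run_cond <- function(seed) {
    truth <- simulation_truth(tx, injected_pauses = ip, start_peak = 1,
                              seed = seed)
    sim <- simulate_footprints(tx, truth, 5 * sum(n_codons(tx)))
    prof <- build_profiles(sim$alignments, fixed_offset_table(), tx, 0.5)
    rank_paused_codons(call_pauses(pause_scores_all(prof), 10))
  }
  r41 <- run_cond(41); r42 <- run_cond(42)
  cmp <- compare_pause_fractions(list(c1 = r41, c2 = r42))
  arg <- cmp[cmp$group == "Arg", ]
  totals <- c(sum(r41$n_pauses), sum(r42$n_pauses))
  p_hat <- sum(arg$n_pauses) / sum(totals)
  se <- sqrt(p_hat * (1 - p_hat) * sum(1 / totals))
  expect_lte(abs(arg$fraction[1] - arg$fraction[2]), 3 * se)
})
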