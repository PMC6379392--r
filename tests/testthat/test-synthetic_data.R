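test_that("error profile respects its invariants and is seed-deterministic", {
  p1 <- draw_error_profile(seed = 1, reference = REF)
  p2 <- draw_error_profile(seed = 1, reference = REF)
  p3 <- draw_error_profile(seed = 2, reference = REF)
  expect_identical(p1, p2)
  expect_false(identical(p1$rate, p3$rate))
  expect_true(all(p1$rate >= 0 & p1$rate <= 0.05))
  per_pos <- tapply(p1$rate, p1$pos, sum)
  expect_true(all(per_pos < 0.15))
  expect_equal(nrow(p1), 3L * 477L)
  # drawn-rate median within a factor 2 of the configured location
  big <- draw_error_profile(seed = 7, location = 1e-3, reference = REF)
  m <- median(big$rate)
  expect_gt(m, 5e-4)
  expect_lt(m, 2e-3)
})

test_that("simulated pileups conserve depth and obey the mixing law", {
  profile <- draw_error_profile(seed = 3, reference = REF)
  s <- simulated_sample("s1", depth = 5000, seed = 5)
  pl <- simulate_pileup(s, profile, REF)
  expect_equal(pl$A + pl$C + pl$G + pl$T + pl$other, pl$depth)
  expect_true(all(pl$depth == 5000))
  expect_identical(pl, simulate_pileup(s, profile, REF))  # determinism

  # spike at the F1245 anchor, pure tumour: VAF 0.53 within 3 binomial SDs
  sub <- mutation_to_substitution("F1245I", REF)
  st <- simulated_sample("t", spikes = data.frame(pos = sub$pos,
                                                  alt = sub$alt_fwd,
                                                  vaf = 0.53),
                         depth = 10000, seed = 11)
  plt <- simulate_pileup(st, profile, REF)
  row <- plt[plt$pos == sub$pos, ]
  obs <- row[[sub$alt_fwd]] / row$depth
  expect_lt(abs(obs - 0.53), 3 * sqrt(0.53 * 0.47 / 10000))

  # purity scales somatic spikes multiplicatively: 0.60 x 0.5 -> 0.30
  sp <- simulated_sample("p", purity = 0.5,
                         spikes = data.frame(pos = sub$pos,
                                             alt = sub$alt_fwd, vaf = 0.60),
                         depth = 20000, seed = 12)
  plp <- simulate_pileup(sp, profile, REF)
  rowp <- plp[plp$pos == sub$pos, ]
  expect_lt(abs(rowp[[sub$alt_fwd]] / rowp$depth - 0.30),
            3 * sqrt(0.30 * 0.70 / 20000))

  # germline (constitutional) spikes are not purity-scaled
  sg <- simulated_sample("g", purity = 0.5,
                         spikes = data.frame(pos = sub$pos,
                                             alt = sub$alt_fwd, vaf = 0.5,
                                             germline = TRUE),
                         depth = 20000, seed = 13)
  plg <- simulate_pileup(sg, profile, REF)
  rowg <- plg[plg$pos == sub$pos, ]
  expect_lt(abs(rowg[[sub$alt_fwd]] / rowg$depth - 0.5),
            3 * sqrt(0.5 * 0.5 / 20000))
})

test_that("zero error rates and no spikes give an all-reference pileup", {
  profile <- draw_error_profile(seed = 1, reference = REF)
  profile$rate <- 0
  s <- simulated_sample("null", depth = 1000, seed = 2,
                        noise_jitter_log10_sd = 0)
  pl <- simulate_pileup(s, profile, REF)
  bases <- c("A", "C", "G", "T")
  ref_count <- as.matrix(pl[, bases])[cbind(seq_len(nrow(pl)),
                                            match(pl$ref, bases))]
  expect_true(all(ref_count == pl$depth))
})

test_that("an over-full probability configuration is rejected", {
  profile <- draw_error_profile(seed = 1, reference = REF)
  sub <- mutation_to_substitution("F1174L", REF)
  s <- simulated_sample("bad",
                        spikes = data.frame(pos = rep(sub$pos, 2),
                                            alt = c("G", "T"),
                                            vaf = c(0.6, 0.6)),
                        depth = 1000, seed = 1)
  expect_error(simulate_pileup(s, profile, REF), "invalid configuration")
})

test_that("control cohorts have the study's size and depth floor", {
  profile <- draw_error_profile(seed = 4, reference = REF)
  ctrls <- simulate_control_cohort(8, profile, seed = 9, reference = REF)
  expect_length(ctrls, 8)
  for (p in ctrls) expect_true(all(p$depth >= 5000 & p$depth <= 65000))
  expect_error(simulate_control_cohort(1, profile, reference = REF),
               "at least 2 controls")
  # germline constructor refuses somatic spikes
  expect_error(simulated_sample("c", role = "germline",
                                spikes = data.frame(pos = 29443697,
                                                    alt = "G", vaf = 0.1)),
               "no somatic spike-ins")
})

test_that("with zero jitter the between-control spread is binomial-scale", {
  profile <- draw_error_profile(seed = 5, reference = REF)
  ctrls <- simulate_control_cohort(8, profile, depth = 20000, seed = 21,
                                   jitter_log10_sd = 0, reference = REF)
  model <- estimate_background(ctrls)
  i <- match(paste(model$pos, model$alt), paste(profile$pos, profile$alt))
  binom_sd <- sqrt(profile$rate[i] * (1 - profile$rate[i]) / 20000)
  # mean observed SD across entries tracks the mean binomial SD
  ratio <- mean(model$sd) / mean(binom_sd)
  expect_gt(ratio, 0.8)
  expect_lt(ratio, 1.2)
})

test_that("dilution series scales expected VAF as VAF0/(1+d), monotonically", {
  sub <- mutation_to_substitution("F1174L", REF)
  base <- simulated_sample("dil",
                           spikes = data.frame(pos = sub$pos,
                                               alt = sub$alt_fwd, vaf = 0.5),
                           depth = 10000, seed = 31)
  series <- simulate_dilution_series(base, c(0, 10, 40))
  ev <- attr(series, "expected_vaf")
  expect_equal(ev, c(0.5, 0.5 / 11, 0.5 / 41))
  expect_true(all(diff(ev) < 0))
  expect_error(simulate_dilution_series(base, c(0, -1)), "non-negative")
  no_spike <- simulated_sample("ns", depth = 1000, seed = 1)
  expect_error(simulate_dilution_series(no_spike), "at least one spike-in")
})

test_that("simulate_cohort mirrors the cohort table composition", {
  tab <- read_cohort()
  sim <- simulate_cohort(tab, seed = 7, depth = 5000)
  expect_length(sim$pileups, 105)
  muts <- alkdeep:::parse_deepseq(tab$deepseq)
  n_spiked <- sum(vapply(muts, function(m) any(!m$synonymous), logical(1)))
  expect_equal(n_spiked, 16L)

  # the dual-clone case carries both alternate bases in its pileup
  dual <- sim$pileups[["case40"]]
  s_sub <- mutation_to_substitution("F1174S", REF)
  i_sub <- mutation_to_substitution("F1174I", REF)
  expect_gt(dual[dual$pos == s_sub$pos, s_sub$alt_fwd] /
              dual$depth[dual$pos == s_sub$pos], 0.5)
  expect_gt(dual[dual$pos == i_sub$pos, i_sub$alt_fwd] /
              dual$depth[dual$pos == i_sub$pos], 0.05)

  empty <- simulate_cohort(tab[0, ], seed = 1)
  expect_length(empty$pileups, 0)
})

test_that("emit_reads decomposes a pileup exactly and respects read length", {
  # single position, depth 100, read length 1 -> 100 records
  one <- data.frame(chrom = "chr2", pos = 29443697, ref = "A",
                    A = 80L, C = 0L, G = 20L, T = 0L, other = 0L,
                    depth = 100L)
  reads <- emit_reads(one, read_length = 1, seed = 2)
  expect_equal(nrow(reads), 100)
  expect_true(all(reads$cigar == "1M"))
  expect_equal(sum(unlist(strsplit(reads$seq, "")) == "G"), 20)

  # multi-position round trip at quality threshold 0
  profile <- draw_error_profile(seed = 6, reference = REF)
  s <- simulated_sample("rt", depth = 60, seed = 41)
  pl <- simulate_pileup(s, profile, REF)
  pl <- pl[pl$pos >= 29436850 & pl$pos <= 29436899, ]
  reads <- emit_reads(pl, read_length = 25, seed = 3)
  expect_true(all(nchar(reads$seq) <= 25))
  rebuilt <- build_pileup(reads, REGIONS, min_base_quality = 0,
                          reference = REF)
  expect_equal(rebuilt[, c("pos", "A", "C", "G", "T", "other", "depth")],
               pl[, c("pos", "A", "C", "G", "T", "other", "depth")],
               ignore_attr = TRUE)
})

test_that("low-quality base assignment thins the filtered pileup as expected", {
  one <- data.frame(chrom = "chr2", pos = 29443650, ref = ref_base(29443650, REF),
                    A = 0L, C = 0L, G = 0L, T = 0L, other = 0L, depth = 0L)
  one[[one$ref]] <- 2000L
  one$depth <- 2000L
  reads <- emit_reads(one, read_length = 1, seed = 5,
                      low_quality_frac = 0.1, low_quality_phred = 10)
  filtered <- build_pileup(reads, REGIONS, min_base_quality = 30,
                           reference = REF, lowq_in_depth = FALSE)
  expect_lt(abs(filtered$depth / 2000 - 0.9), 0.03)
  kept <- build_pileup(reads, REGIONS, min_base_quality = 30,
                       reference = REF)
  expect_equal(kept$depth, 2000L)  # low-quality bases moved to "other"
  expect_equal(kept$other, 2000L - filtered$depth)
})
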