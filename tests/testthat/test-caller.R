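test_that("a clonal hotspot spike is called, quantified and annotated", {
  rig <- make_noise_rig(seed = 14, depth = 5000)
  tum <- make_tumour_pileup(list(F1174L = 0.247), rig$profile,
                            depth = 5000, seed = 15)
  calls <- call_variants(tum$pileup, rig$model, REF)
  hit <- calls[calls$pos == tum$spikes$pos[1] &
                 calls$alt == tum$spikes$alt[1], ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$aa_change, "F1174L")
  expect_equal(hit$hotspot, "F1174")
  expect_equal(hit$vaf, hit$alt_count / hit$depth)
  expect_lt(abs(hit$vaf - 0.247), 3 * sqrt(0.247 * 0.753 / 5000))
  expect_gt(hit$z, 5)
  expect_equal(hit$clonality, "clonal")
  expect_true(hit$sanger_detectable)
  expect_equal(attr(calls, "n_tests"), 3L * 477L)
})

test_that("two alternate bases at one position give two separate calls", {
  rig <- make_noise_rig(seed = 16, depth = 10000)
  p <- mutation_to_substitution("F1174S", REF)$pos  # forward ref A
  s <- simulated_sample("dual",
                        spikes = data.frame(pos = c(p, p), alt = c("G", "T"),
                                            vaf = c(0.587, 0.077)),
                        depth = 10000, seed = 17)
  pl <- simulate_pileup(s, rig$profile, REF)
  calls <- call_variants(pl, rig$model, REF)
  dual <- calls[calls$pos == p, ]
  expect_equal(nrow(dual), 2)
  expect_setequal(dual$alt, c("G", "T"))
  expect_true(all(dual$residue == 1174))
  expect_equal(dual$clonality[order(dual$vaf)], c("subclonal", "clonal"))
})

test_that("raising k can only shrink the call set", {
  rig <- make_noise_rig(seed = 18, depth = 5000)
  tum <- make_tumour_pileup(list(F1174L = 0.03, F1245I = 0.25), rig$profile,
                            depth = 5000, seed = 19)
  n_prev <- Inf
  for (k in c(2, 5, 10, 50, 2000)) {
    n <- nrow(call_variants(tum$pileup, rig$model, REF, k = k))
    expect_lte(n, n_prev)
    n_prev <- n
  }
  # a clonal 25% spike over an SD of ~5e-4 reaches z of several hundred,
  # so only a threshold beyond that silences everything
  expect_equal(n_prev, 0)
})

test_that("positions under the depth floor are not assessable, not no-calls", {
  rig <- make_noise_rig(seed = 20, depth = 5000)
  tum <- make_tumour_pileup(list(F1174L = 0.3), rig$profile,
                            depth = 5000, seed = 21)
  shallow <- tum$pileup
  idx <- shallow$pos == tum$spikes$pos[1]
  shallow[idx, c("A", "C", "G", "T", "other")] <-
    round(shallow[idx, c("A", "C", "G", "T", "other")] / 2)
  shallow$depth[idx] <- sum(shallow[idx, c("A", "C", "G", "T", "other")])
  calls <- call_variants(shallow, rig$model, REF, min_depth = 5000)
  expect_false(tum$spikes$pos[1] %in% calls$pos)
  expect_true(tum$spikes$pos[1] %in% attr(calls, "not_assessable"))
})

test_that("pileup positions missing from the model are reported, not skipped silently", {
  rig <- make_noise_rig(seed = 22, depth = 5000)
  model <- rig$model[rig$model$pos != 29443697, ]
  attr(model, "floor") <- attr(rig$model, "floor")
  tum <- make_tumour_pileup(list(F1174L = 0.3), rig$profile,
                            depth = 5000, seed = 23)
  expect_message(
    calls <- call_variants(tum$pileup, model, REF),
    "does not cover")
  expect_true(29443697 %in% attr(calls, "uncovered"))
})

test_that("clonality and detectability use strict threshold inequalities", {
  expect_equal(classify_clonality(c(0.027, 0.247, 0.20, 0.1999)),
               c("subclonal", "clonal", "clonal", "subclonal"))
  expect_equal(flag_sanger_detectable(c(0.22, 0.14, 0.15, 0.1501)),
               c(TRUE, FALSE, FALSE, TRUE))
})

test_that("dilution series evaluation finds the detection limit", {
  rig <- make_noise_rig(seed = 24, depth = 10000)
  sub <- mutation_to_substitution("F1245I", REF)
  base <- simulated_sample("dil",
                           spikes = data.frame(pos = sub$pos,
                                               alt = sub$alt_fwd, vaf = 0.5),
                           depth = 10000, seed = 25)
  series <- simulate_dilution_series(base, c(0, 10, 40))
  calls <- lapply(series, function(s)
    call_variants(simulate_pileup(s, rig$profile, REF), rig$model, REF))
  rep <- evaluate_dilution_series(calls, attr(series, "expected_vaf"),
                                  sub$pos, sub$alt_fwd)
  expect_true(all(rep$detected))
  expect_equal(attr(rep, "detection_limit"), 0.5 / 41)
  expect_true(all(abs(rep$relative_error) < 0.5))

  # inflate the background SD at the spiked site: the 1:40 point drops out
  noisy <- rig$model
  i <- noisy$pos == sub$pos & noisy$alt == sub$alt_fwd
  noisy$sd[i] <- 0.005  # 5*SD between the 1:10 and 1:40 expected fractions
  calls2 <- lapply(series, function(s)
    call_variants(simulate_pileup(s, rig$profile, REF), noisy, REF))
  rep2 <- evaluate_dilution_series(calls2, attr(series, "expected_vaf"),
                                   sub$pos, sub$alt_fwd)
  expect_false(rep2$detected[3])
  expect_equal(attr(rep2, "detection_limit"), 0.5 / 11)

  empty <- evaluate_dilution_series(list(), numeric(0), sub$pos, "T")
  expect_equal(nrow(empty), 0)
  expect_true(is.na(attr(empty, "detection_limit")))
})

test_that("calls round-trip through VCF 4.2", {
  rig <- make_noise_rig(seed = 26, depth = 5000)
  tum <- make_tumour_pileup(list(F1174L = 0.247, I1171T = 0.05),
                            rig$profile, depth = 5000, seed = 27)
  calls <- call_variants(tum$pileup, rig$model, REF, sample_id = "case12")
  path <- withr::local_tempfile(fileext = ".vcf")
  write_calls_vcf(calls, path)
  head <- readLines(path, n = 1)
  expect_equal(head, "##fileformat=VCFv4.2")
  back <- read_calls_vcf(path)
  for (col in names(back)) {
    expect_equal(back[[col]], calls[[col]], tolerance = 1e-9, label = col)
  }
  # empty call set still yields a valid, readable file
  path2 <- withr::local_tempfile(fileext = ".vcf")
  write_calls_vcf(calls[0, ], path2)
  expect_equal(nrow(read_calls_vcf(path2)), 0)
})
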