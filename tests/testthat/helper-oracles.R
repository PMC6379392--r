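# Independent oracles and shared fixtures for the test suite.

# One reference for the whole run; construction is deterministic.
REF <- build_mini_reference()
REGIONS <- alk_target_regions()

# Brute-force translation of a forward-strand genomic codon: reverse
# complement by hand, then standard genetic code.  Independent of the
# package's frame/annotation path.
oracle_revcomp <- function(s) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
}
oracle_translate_fwd_codon <- function(fwd_codon) {
  Biostrings::GENETIC_CODE[[oracle_revcomp(fwd_codon)]]
}

# Exhaustive hypergeometric enumeration for a 2x2 table [a b; c d]:
# probability of each table with the observed margins via binomial
# coefficients, two-sided p = sum of probabilities <= observed.
oracle_fisher <- function(a, b, c, d) {
  m <- a + b; n2 <- c + d; k <- a + c
  support <- max(0, k - n2):min(k, m)
  probs <- choose(m, support) * choose(n2, k - support) / choose(m + n2, k)
  min(1, sum(probs[probs <= probs[support == a] * (1 + 1e-7)]))
}

# Empirical survival function (no censoring): fraction still alive after t.
oracle_empirical_surv <- function(times, t) {
  vapply(t, function(x) mean(times > x), numeric(1))
}

# Small standard rig: profile + 8 controls + fitted noise model.
make_noise_rig <- function(seed = 1L, depth = 5000L, n_controls = 8L,
                           jitter = 0.1) {
  profile <- draw_error_profile(seed = seed, reference = REF)
  controls <- simulate_control_cohort(n_controls, profile, depth = depth,
                                      seed = seed + 1000L,
                                      jitter_log10_sd = jitter,
                                      reference = REF)
  list(profile = profile, controls = controls,
       model = estimate_background(controls))
}

# Tumour pileup with the given named spikes (mutation name -> VAF fraction).
make_tumour_pileup <- function(spikes_named, profile, depth = 5000L,
                               seed = 99L, purity = 1) {
  subs <- lapply(names(spikes_named), mutation_to_substitution,
                 reference = REF)
  spikes <- data.frame(
    pos = vapply(subs, `[[`, numeric(1), "pos"),
    alt = vapply(subs, `[[`, character(1), "alt_fwd"),
    vaf = unname(unlist(spikes_named)))
  s <- simulated_sample("tumour", role = "tumour", purity = purity,
                        spikes = spikes, depth = depth, seed = seed)
  list(pileup = simulate_pileup(s, profile, REF), spikes = spikes)
}
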