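# Synthetic pileup and read generator.
#
# Emulates the study conditions the downstream statistics assume: per-position
# substitution error around 0.1%, sample-to-sample spread of error rates,
# depths of 5000x and above, spike-in variants at allele fractions between
# 1% and 60%, tumour purity >= 50%, and serial dilutions.  All randomness is
# driven by explicit seeds; no global RNG state leaks.

#' Draw a background error profile
#'
#' Per (position, alternate base) substitution error rates for every targeted
#' position, drawn log-normally: `log10(rate) ~ N(log10(location), log10_sd)`,
#' truncated to `[0, max_rate]`.  The default location of 1e-3 puts the noise
#' floor well below the smallest allele fraction the assay is expected to
#' resolve (about 1%), while keeping non-zero spread at every site.
#'
#' @param regions Target regions data.frame.
#' @param seed Integer seed.
#' @param location Median error rate (fraction of reads).
#' @param log10_sd Spread of `log10(rate)` across sites.
#' @param max_rate Truncation bound for a single (position, alt) rate.
#' @param reference A `mini_reference`; defaults to the bundled one.
#' @return An `error_profile`: data.frame with columns `chrom`, `pos`, `ref`,
#'   `alt`, `rate`, three alternates per position.
#' @export
draw_error_profile <- function(regions = alk_target_regions(), seed = 1L,
                               location = 1e-3, log10_sd = 0.3,
                               max_rate = 0.05,
                               reference = build_mini_reference(regions)) {
  stopifnot(location > 0, log10_sd >= 0, max_rate > 0)
  ladder <- reference$ladder
  ref <- unname(reference$bases[as.character(ladder$pos)])
  bases <- c("A", "C", "G", "T")
  alt <- unlist(lapply(ref, function(r) setdiff(bases, r)), use.names = FALSE)
  n <- length(alt)
  rate <- withr::with_seed(seed, {
    10^(log10(location) + stats::rnorm(n, 0, log10_sd))
  })
  rate <- pmin(rate, max_rate)
  structure(
    data.frame(chrom = "chr2", pos = rep(ladder$pos, each = 3L),
               ref = rep(ref, each = 3L), alt = alt, rate = rate,
               stringsAsFactors = FALSE),
    class = c("error_profile", "data.frame"),
    location = location, log10_sd = log10_sd, max_rate = max_rate
  )
}

#' Describe a simulated sample
#'
#' Light-weight constructor for the unit the generator simulates: a germline
#' control or a tumour with optional spike-in variants.
#'
#' @param id Sample identifier.
#' @param role `"tumour"` or `"germline"`.
#' @param purity Tumour-cell fraction; somatic spike-in fractions are scaled
#'   by it (germline/constitutional spike-ins are not).
#' @param spikes `NULL` or data.frame with columns `pos`, `alt`, `vaf`
#'   (fraction of *tumour-cell* reads in `(0, 1]`) and optionally `germline`
#'   (logical, default `FALSE`).
#' @param depth Per-position sequencing depth: scalar (recycled) or one value
#'   per targeted position, or `NULL` (default) to draw per-position depths
#'   uniformly over `depth_range`, emulating the study's coverage spread.
#' @param depth_range Depth range used when `depth` is `NULL`; the assay
#'   achieved 5000-65000x per position.
#' @param seed Integer seed used when this sample's pileup is drawn.
#' @param noise_jitter_log10_sd Sample-level multiplicative jitter of all
#'   background rates (`rate * 10^N(0, sd)`), creating the between-sample
#'   error variance the 5-SD rule measures.  Set to 0 for pure binomial noise.
#' @return A `simulated_sample` list.
#' @export
simulated_sample <- function(id, role = c("tumour", "germline"), purity = 1,
                             spikes = NULL, depth = NULL,
                             depth_range = c(5000L, 65000L), seed = 1L,
                             noise_jitter_log10_sd = 0.1) {
  role <- match.arg(role)
  stopifnot(purity > 0, purity <= 1, is.null(depth) || all(depth >= 1),
            length(depth_range) == 2L, depth_range[1] <= depth_range[2])
  if (role == "germline" && !is.null(spikes) && nrow(spikes) > 0) {
    has_germline <- if (is.null(spikes$germline)) FALSE else all(spikes$germline)
    if (!has_germline) stop("germline controls carry no somatic spike-ins")
  }
  if (!is.null(spikes) && nrow(spikes) > 0) {
    stopifnot(all(c("pos", "alt", "vaf") %in% names(spikes)))
    if (is.null(spikes$germline)) spikes$germline <- FALSE
    if (any(spikes$vaf <= 0 | spikes$vaf > 1)) stop("spike VAFs must be in (0, 1]")
    if (any(is.na(locate_position(spikes$pos)))) {
      stop("spike-in position(s) outside the target regions")
    }
  }
  structure(list(id = id, role = role, purity = purity, spikes = spikes,
                 depth = depth, depth_range = depth_range,
                 seed = as.integer(seed),
                 noise_jitter_log10_sd = noise_jitter_log10_sd),
            class = "simulated_sample")
}

#' @export
print.simulated_sample <- function(x, ...) {
  cat("<simulated_sample> ", x$id, " (", x$role, ", purity ", x$purity,
      ", ", if (is.null(x$spikes)) 0L else nrow(x$spikes),
      " spike-in(s), seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

# Exact multinomial sampling across positions via the binomial chain rule:
# column k of `prob` is drawn as Binomial(remaining, p_k / remaining mass).
.multinomial_counts <- function(depth, prob) {
  n_pos <- nrow(prob)
  n_cat <- ncol(prob)
  remaining <- depth
  mass_left <- rep(1, n_pos)
  counts <- matrix(0L, n_pos, n_cat, dimnames = dimnames(prob))
  for (k in seq_len(n_cat - 1L)) {
    p <- ifelse(mass_left > 0, pmin(prob[, k] / mass_left, 1), 0)
    counts[, k] <- stats::rbinom(n_pos, remaining, p)
    remaining <- remaining - counts[, k]
    mass_left <- mass_left - prob[, k]
  }
  counts[, n_cat] <- remaining
  counts
}

#' Simulate a per-position pileup for one sample
#'
#' At every targeted position the four base counts are drawn from a
#' multinomial over the sample's depth, with alternate-base probability
#' `background rate + purity * spike VAF` for a spiked alternate (purity is
#' not applied to germline spike-ins, and never to the background), and the
#' reference base taking the remaining mass.  Background rates are first
#' scaled by one sample-level log-normal jitter factor.
#'
#' @param sample A [simulated_sample()].
#' @param profile An [draw_error_profile()] profile.
#' @param reference A `mini_reference`.
#' @return A pileup data.frame (`chrom`, `pos`, `ref`, `A`, `C`, `G`, `T`,
#'   `other`, `depth`).
#' @export
simulate_pileup <- function(sample, profile,
                            reference = build_mini_reference()) {
  stopifnot(inherits(sample, "simulated_sample"))
  ladder <- reference$ladder
  pos <- ladder$pos
  n_pos <- length(pos)
  ref <- unname(reference$bases[as.character(pos)])
  bases <- c("A", "C", "G", "T")

  withr::with_seed(sample$seed, {
    depth <- if (is.null(sample$depth)) {
      as.integer(round(stats::runif(n_pos, sample$depth_range[1],
                                    sample$depth_range[2])))
    } else {
      as.integer(round(rep_len(sample$depth, n_pos)))
    }
    jitter <- 10^stats::rnorm(1, 0, sample$noise_jitter_log10_sd)
    prob <- matrix(0, n_pos, 4L, dimnames = list(NULL, bases))
    idx <- cbind(match(profile$pos, pos), match(profile$alt, bases))
    keep <- !is.na(idx[, 1])
    prob[idx[keep, , drop = FALSE]] <- profile$rate[keep] * jitter
    if (!is.null(sample$spikes) && nrow(sample$spikes) > 0) {
      sp <- sample$spikes
      scale <- ifelse(sp$germline, 1, sample$purity)
      si <- cbind(match(sp$pos, pos), match(sp$alt, bases))
      if (anyNA(si)) stop("spike-in outside targets or invalid alt base")
      prob[si] <- prob[si] + sp$vaf * scale
    }
    alt_mass <- rowSums(prob) - prob[cbind(seq_len(n_pos), match(ref, bases))]
    if (any(alt_mass > 1)) {
      stop("invalid configuration: alternate-base probabilities exceed 1")
    }
    prob[cbind(seq_len(n_pos), match(ref, bases))] <- 1 - alt_mass
    counts <- .multinomial_counts(depth, prob)
    out <- data.frame(chrom = "chr2", pos = pos, ref = ref,
                      A = counts[, "A"], C = counts[, "C"], G = counts[, "G"],
                      T = counts[, "T"], other = 0L, depth = depth,
                      stringsAsFactors = FALSE)
    out <- out[order(out$pos), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Simulate a cohort of germline control pileups
#'
#' Independent control samples sharing one error profile, each with its own
#' sample-level rate jitter.  The study design uses eight healthy-donor
#' germline DNAs for background quantification.
#'
#' @param n_controls Number of controls (>= 2; fewer leaves the background SD
#'   undefined).
#' @param profile Error profile.
#' @param depth Per-position depth (scalar or vector), or `NULL` to draw
#'   per-position depths over the study's 5000-65000x range.
#' @param seed Integer seed.
#' @param jitter_log10_sd Sample-level rate jitter; 0 gives pure binomial
#'   between-sample variance.
#' @param reference A `mini_reference`.
#' @return Named list of pileup data.frames (`control1`, ...).
#' @export
simulate_control_cohort <- function(n_controls = 8L, profile,
                                    depth = NULL, seed = 1L,
                                    jitter_log10_sd = 0.1,
                                    reference = build_mini_reference()) {
  if (n_controls < 2L) {
    stop("at least 2 controls are required to estimate a background SD")
  }
  seeds <- withr::with_seed(seed,
    sample.int(.Machine$integer.max, n_controls))
  out <- lapply(seq_len(n_controls), function(i) {
    s <- simulated_sample(id = paste0("control", i), role = "germline",
                          depth = depth, seed = seeds[i],
                          noise_jitter_log10_sd = jitter_log10_sd)
    simulate_pileup(s, profile, reference)
  })
  names(out) <- paste0("control", seq_len(n_controls))
  out
}

#' Derive a serial dilution series from a sample
#'
#' For a mutant:wild-type DNA mass ratio of `1:d` the expected allele
#' fraction of every spike-in becomes `VAF0 / (1 + d)`; `d = 0` is the
#' undiluted sample.  The assay's validation series uses d = 0, 10, 40.
#'
#' @param base A [simulated_sample()] with at least one spike-in.
#' @param ratios Numeric vector of wild-type parts `d` (0 = undiluted).
#' @return List of `simulated_sample`s, one per ratio, with scaled spike
#'   fractions and derived seeds; expected VAFs attached as attribute
#'   `expected_vaf` (per sample, for its first spike-in).
#' @export
simulate_dilution_series <- function(base, ratios = c(0, 10, 40)) {
  stopifnot(inherits(base, "simulated_sample"))
  if (is.null(base$spikes) || nrow(base$spikes) == 0) {
    stop("dilution series needs a sample with at least one spike-in")
  }
  if (any(ratios < 0)) stop("dilution ratios must be non-negative")
  out <- lapply(seq_along(ratios), function(i) {
    d <- ratios[i]
    s <- base
    s$spikes$vaf <- base$spikes$vaf / (1 + d)
    s$id <- sprintf("%s_1to%g", base$id, d)
    s$seed <- base$seed + i
    s
  })
  attr(out, "expected_vaf") <-
    vapply(out, function(s) s$spikes$vaf[1], numeric(1))
  attr(out, "ratios") <- ratios
  out
}

# Split a deep-seq annotation string ("F1174L (24.7%)", "F1174S (58.7%) +
# F1174I (7.7%)", "D1160D", "Neg", "Amp.") into mutation names and VAF
# percentages.  Shared with cohort_stats.
parse_deepseq <- function(x) {
  lapply(x, function(s) {
    s <- trimws(s)
    if (s %in% c("Neg", "Amp.", "")) {
      return(data.frame(name = character(0), vaf_pct = numeric(0),
                        synonymous = logical(0)))
    }
    toks <- trimws(strsplit(s, "+", fixed = TRUE)[[1]])
    m <- regmatches(toks,
      regexec("^([A-Z][0-9]+[A-Z])\\s*(\\(([0-9.]+)%?\\))?$", toks))
    if (any(lengths(m) == 0L)) stop("unparseable deep-seq entry: ", s)
    name <- vapply(m, `[`, "", 2)
    vaf <- suppressWarnings(as.numeric(vapply(m, `[`, "", 4)))
    data.frame(name = name, vaf_pct = vaf,
               synonymous = substr(name, 1, 1) ==
                 substr(name, nchar(name), nchar(name)),
               stringsAsFactors = FALSE)
  })
}

#' Simulate pileups for a whole cohort
#'
#' Takes a cohort table in the packaged schema (see [read_cohort()]) and
#' simulates one tumour pileup per case, spiking each non-negative deep-seq
#' entry at its tabulated allele fraction via [mutation_to_substitution()].
#' Tabulated fractions are treated as the *observed* allele fractions, so
#' purity is left at 1 here (the dilution of signal by normal cells is
#' already inside the printed numbers).
#'
#' @param spec Cohort data.frame (columns `case`, `deepseq`, ... as in the
#'   packaged fixture), or a subset of it.
#' @param seed Integer seed.
#' @param profile Error profile (default drawn from `seed`).
#' @param depth Per-position depth.
#' @param reference A `mini_reference`.
#' @return List with `cohort` (the input table) and `pileups` (named list,
#'   one pileup per case).
#' @export
simulate_cohort <- function(spec, seed = 1L,
                            profile = draw_error_profile(seed = seed),
                            depth = NULL,
                            reference = build_mini_reference()) {
  if (nrow(spec) == 0) return(list(cohort = spec, pileups = list()))
  muts <- parse_deepseq(spec$deepseq)
  seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max, nrow(spec)))
  pileups <- lapply(seq_len(nrow(spec)), function(i) {
    mm <- muts[[i]]
    spikes <- NULL
    if (nrow(mm) > 0) {
      const <- grepl("const", spec$sanger[i], fixed = TRUE)
      sub <- lapply(mm$name, mutation_to_substitution, reference = reference)
      spikes <- data.frame(
        pos = vapply(sub, `[[`, numeric(1), "pos"),
        alt = vapply(sub, `[[`, character(1), "alt_fwd"),
        vaf = ifelse(is.na(mm$vaf_pct), 0.5, mm$vaf_pct / 100),
        germline = const
      )
    }
    s <- simulated_sample(id = paste0("case", spec$case[i]), role = "tumour",
                          purity = 1, spikes = spikes, depth = depth,
                          seed = seeds[i])
    simulate_pileup(s, profile, reference)
  })
  names(pileups) <- paste0("case", spec$case)
  list(cohort = spec, pileups = pileups)
}

#' Emit aligned-read records consistent with a pileup
#'
#' Decomposes a pileup into aligned single-end read records such that
#' rebuilding the pileup at base-quality threshold 0 recovers the counts
#' exactly: per coverage layer, runs of consecutive covered positions are cut
#' into chunks of at most `read_length` bases, and each position contributes
#' the bases of its count column in a seed-shuffled order.
#'
#' @param pileup Pileup data.frame.
#' @param read_length Maximum read length (>= 1).
#' @param seed Integer seed (shuffles base order within positions and picks
#'   which bases receive low quality).
#' @param base_quality Phred quality assigned to bases.
#' @param low_quality_frac Fraction of bases downgraded to `low_quality_phred`.
#' @param low_quality_phred Phred value for downgraded bases.
#' @return data.frame of read records (`qname`, `flag`, `rname`, `pos`,
#'   `mapq`, `cigar`, `seq`, `qual`).
#' @export
emit_reads <- function(pileup, read_length = 100L, seed = 1L,
                       base_quality = 40L, low_quality_frac = 0,
                       low_quality_phred = 10L) {
  stopifnot(read_length >= 1)
  if (nrow(pileup) == 0) {
    return(data.frame(qname = character(0), flag = integer(0),
                      rname = character(0), pos = integer(0),
                      mapq = integer(0), cigar = character(0),
                      seq = character(0), qual = character(0)))
  }
  withr::with_seed(seed, {
    base_cols <- c("A", "C", "G", "T")
    # per position: shuffled vector of depth bases ("N" for "other")
    stacks <- lapply(seq_len(nrow(pileup)), function(i) {
      b <- rep(c(base_cols, "N"),
               times = c(unlist(pileup[i, base_cols], use.names = FALSE),
                         pileup$other[i]))
      sample(b)
    })
    depth <- pileup$depth
    pos <- pileup$pos
    ord <- order(pos)
    pos <- pos[ord]; depth <- depth[ord]; stacks <- stacks[ord]
    reads <- list()
    for (layer in seq_len(max(depth))) {
      covered <- which(depth >= layer)
      if (length(covered) == 0) next
      # runs of consecutive genomic positions within this layer
      brk <- c(0L, which(diff(pos[covered]) != 1L), length(covered))
      for (r in seq_len(length(brk) - 1L)) {
        run <- covered[(brk[r] + 1L):brk[r + 1L]]
        starts <- seq(1L, length(run), by = read_length)
        for (s0 in starts) {
          chunk <- run[s0:min(s0 + read_length - 1L, length(run))]
          reads[[length(reads) + 1L]] <- list(
            pos = pos[chunk[1]],
            seq = paste(vapply(seq_along(chunk), function(j)
              stacks[[chunk[j]]][layer], character(1)), collapse = "")
          )
        }
      }
    }
    n <- length(reads)
    seqs <- vapply(reads, `[[`, character(1), "seq")
    lens <- nchar(seqs)
    qual <- vapply(seq_len(n), function(i) {
      q <- rep(base_quality, lens[i])
      if (low_quality_frac > 0) {
        low <- stats::runif(lens[i]) < low_quality_frac
        q[low] <- low_quality_phred
      }
      intToUtf8(q + 33L)
    }, character(1))
    data.frame(
      qname = sprintf("read%06d", seq_len(n)), flag = 0L,
      rname = pileup$chrom[1], pos = vapply(reads, `[[`, numeric(1), "pos"),
      mapq = 60L, cigar = paste0(lens, "M"), seq = seqs, qual = qual,
      stringsAsFactors = FALSE
    )
  })
}
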