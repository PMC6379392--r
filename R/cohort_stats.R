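# Cohort-level statistics over the packaged 105-case neuroblastoma table
# (or a simulated cohort in the same schema): hotspot spectrum, clonality
# split, Sanger comparison, genomic-subgroup associations and overall
# survival.

.COHORT_COLS <- c("case", "sanger", "deepseq", "effect", "outcome",
                  "profile", "aad_months", "inrg")
.OUTCOMES <- c("NED>5y", "NED<5y", "DOD", "AWD")
.INRG <- c("L", "M", "MS")
.PROFILE_TOKENS <- c("NMA", "11q-del", "17q-gain", "Num only",
                     "Other segm.", "ALK-amp", "chrom.tr")

#' Path of the packaged cohort table
#'
#' TSV transcription of the study's 105-case table: per case the Sanger
#' result, the deep-sequencing result with allele fraction, predicted effect,
#' outcome, SNP-array genomic profile, age at diagnosis (months) and INRG
#' stage.
#'
#' @return File path.
#' @export
cohort_fixture_path <- function() {
  system.file("extdata", "cohort_table1.tsv", package = "alkdeep",
              mustWork = TRUE)
}

#' Read a cohort table
#'
#' Reads and validates a cohort TSV in the packaged schema (columns `case`,
#' `sanger`, `deepseq`, `effect`, `outcome`, `profile`, `aad_months`,
#' `inrg`).  Deep-seq entries must parse to mutation names with allele
#' fractions in (0, 100], `Neg`, or `Amp.`; outcome, INRG and genomic-profile
#' labels are checked against the fixed vocabulary.
#'
#' @param path TSV path; defaults to the packaged table.
#' @return Cohort data.frame.
#' @export
read_cohort <- function(path = cohort_fixture_path()) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE,
                         na.strings = character(0))
  missing <- setdiff(.COHORT_COLS, names(x))
  if (length(missing)) {
    stop("cohort table lacks column(s): ", paste(missing, collapse = ", "))
  }
  bad_out <- setdiff(unique(x$outcome), .OUTCOMES)
  if (length(bad_out)) stop("unknown outcome label(s): ",
                            paste(bad_out, collapse = ", "))
  bad_inrg <- setdiff(unique(x$inrg), .INRG)
  if (length(bad_inrg)) stop("unknown INRG label(s): ",
                             paste(bad_inrg, collapse = ", "))
  prof <- unique(x$profile)
  known <- vapply(prof, function(p) {
    rest <- p
    for (tok in .PROFILE_TOKENS) rest <- gsub(tok, "", rest, fixed = TRUE)
    grepl("^[\\s()+]*$", rest, perl = TRUE)
  }, logical(1))
  if (any(!known)) stop("unknown genomic-profile label(s): ",
                        paste(prof[!known], collapse = ", "))
  muts <- parse_deepseq(x$deepseq)  # errors on unparseable entries
  vaf <- unlist(lapply(muts, function(m) m$vaf_pct[!is.na(m$vaf_pct)]))
  if (any(vaf <= 0 | vaf > 100)) {
    stop("allele fractions must lie in (0, 100]")
  }
  x
}

#' Write a cohort table as TSV
#'
#' @param table Cohort data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(table, path) {
  utils::write.table(table[, .COHORT_COLS], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

# Per-case view of the deep-seq column: mutation names, residues, max VAF.
.case_mutations <- function(table) {
  muts <- parse_deepseq(table$deepseq)
  lapply(muts, function(m) {
    m$residue <- as.integer(gsub("[A-Z]", "", m$name))
    m
  })
}

#' Summarise the mutation spectrum of a cohort
#'
#' Case-level tallies: point-mutation-positive cases (synonymous changes and
#' amplification-only cases tallied separately), counts per hotspot residue
#' and per substitution, the clonal/subclonal split at 20% allele fraction
#' (a case is subclonal when its *largest* mutant fraction is below 20%),
#' mutations missed by Sanger sequencing (Sanger-negative but deep-seq
#' positive), amplification cases, total ALK events, and the allele-fraction
#' range.
#'
#' @param table Cohort data.frame.
#' @param clonal_threshold_pct Clonality threshold in percent.
#' @return Named list of counts and percentages.
#' @export
summarize_mutations <- function(table, clonal_threshold_pct = 20) {
  n <- nrow(table)
  if (n == 0) {
    return(list(n_cases = 0L, n_mutation_positive = 0L,
                pct_mutation_positive = NaN, n_synonymous_only = 0L,
                n_amplification = 0L, n_alk_events = 0L,
                pct_alk_events = NaN, by_residue = integer(0),
                by_substitution = integer(0), n_clonal = 0L,
                n_subclonal = 0L, n_sanger_missed = 0L,
                vaf_min_pct = NA_real_, vaf_max_pct = NA_real_))
  }
  cm <- .case_mutations(table)
  nonsyn <- lapply(cm, function(m) m[!m$synonymous, , drop = FALSE])
  positive <- vapply(nonsyn, nrow, integer(1)) > 0
  syn_only <- !positive & vapply(cm, nrow, integer(1)) > 0
  amp <- trimws(table$deepseq) == "Amp."
  max_vaf <- vapply(nonsyn, function(m)
    if (nrow(m)) max(m$vaf_pct, na.rm = TRUE) else NA_real_, numeric(1))
  subclonal <- positive & max_vaf < clonal_threshold_pct
  clonal <- positive & !subclonal
  sanger_missed <- positive & trimws(table$sanger) == "Neg"
  by_residue <- sort(table(unlist(lapply(nonsyn, function(m)
    unique(m$residue)))), decreasing = TRUE)
  by_substitution <- sort(table(unlist(lapply(nonsyn, function(m)
    unique(m$name)))), decreasing = TRUE)
  all_vaf <- unlist(lapply(nonsyn, function(m) m$vaf_pct))
  list(
    n_cases = n,
    n_mutation_positive = sum(positive),
    pct_mutation_positive = 100 * sum(positive) / n,
    n_synonymous_only = sum(syn_only),
    n_amplification = sum(amp),
    n_alk_events = sum(positive | amp),
    pct_alk_events = 100 * sum(positive | amp) / n,
    by_residue = by_residue,
    by_substitution = by_substitution,
    n_clonal = sum(clonal),
    n_subclonal = sum(subclonal),
    n_sanger_missed = sum(sanger_missed),
    vaf_min_pct = if (length(all_vaf)) min(all_vaf, na.rm = TRUE) else NA_real_,
    vaf_max_pct = if (length(all_vaf)) max(all_vaf, na.rm = TRUE) else NA_real_
  )
}

#' Per-case stratification factors
#'
#' Computes the row factors used by the cohort cross-tabulations:
#' `mutated` (non-synonymous deep-seq mutation), `alk_amp`, `alk_event`
#' (mutation or amplification), `11q_del` (profile contains the 11q-del
#' token, combinations included), `mycn_amp` (profile contains the NMA
#' token), `subclonal` (`NA` for unmutated cases), `sanger_missed`,
#' `outcome`, `inrg`, `died` (outcome is DOD).
#'
#' @param table Cohort data.frame.
#' @param name Factor name.
#' @param clonal_threshold_pct Clonality threshold in percent.
#' @return Vector of per-case values.
#' @export
cohort_factor <- function(table, name, clonal_threshold_pct = 20) {
  cm <- .case_mutations(table)
  nonsyn <- lapply(cm, function(m) m[!m$synonymous, , drop = FALSE])
  positive <- vapply(nonsyn, nrow, integer(1)) > 0
  max_vaf <- vapply(nonsyn, function(m)
    if (nrow(m)) max(m$vaf_pct, na.rm = TRUE) else NA_real_, numeric(1))
  amp <- trimws(table$deepseq) == "Amp."
  switch(name,
    mutated = positive,
    alk_amp = amp,
    alk_event = positive | amp,
    "11q_del" = grepl("11q-del", table$profile, fixed = TRUE),
    mycn_amp = grepl("NMA", table$profile, fixed = TRUE),
    subclonal = ifelse(positive, max_vaf < clonal_threshold_pct, NA),
    sanger_missed = positive & trimws(table$sanger) == "Neg",
    outcome = table$outcome,
    inrg = table$inrg,
    died = table$outcome == "DOD",
    stop("unknown cohort factor: ", name)
  )
}

#' Cross-tabulate two cohort factors
#'
#' @param table Cohort data.frame.
#' @param row_factor,col_factor Factor names understood by
#'   [cohort_factor()].
#' @return A contingency `table`; cells sum to the number of rows where both
#'   factors are defined.
#' @export
crosstab <- function(table, row_factor, col_factor) {
  r <- cohort_factor(table, row_factor)
  c_ <- cohort_factor(table, col_factor)
  base::table(r, c_, dnn = c(row_factor, col_factor))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided exact p-value for the table `[a b; c d]` (rows = groups,
#' columns = outcome), computed by summing the hypergeometric probabilities
#' of all tables with the observed margins whose probability does not exceed
#' that of the observed table (with the conventional `1 + 1e-7` relative
#' slack against floating-point ties).
#'
#' @param a,b,c,d Non-negative integer cell counts.
#' @return Two-sided p-value.
#' @examples
#' fisher_exact(0, 27, 16, 62)
#' @export
fisher_exact <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("cells must be non-negative integers")
  }
  if (sum(cells) == 0) stop("all-zero table: test undefined")
  m <- a + b          # row-1 margin
  n2 <- c + d         # row-2 margin
  k <- a + c          # column-1 margin
  support <- max(0, k - n2):min(k, m)
  probs <- stats::dhyper(support, m, n2, k)
  p_obs <- stats::dhyper(a, m, n2, k)
  min(1, sum(probs[probs <= p_obs * (1 + 1e-7)]))
}

#' Kaplan-Meier estimate of overall survival
#'
#' Product-limit estimator with right censoring, via the `survival` package.
#'
#' @param time Follow-up time (months); must be non-negative.
#' @param event Event indicator (1 = death, 0 = censored).
#' @return A `km_fit`: list with `time`, `n_risk`, `n_event`, `surv` (the
#'   step function values after each distinct time) and the underlying
#'   `survfit` object.
#' @export
km_estimate <- function(time, event) {
  if (length(time) < 1) stop("at least one record is required")
  if (any(time < 0)) stop("negative survival times")
  stopifnot(length(time) == length(event))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  structure(list(time = fit$time, n_risk = fit$n.risk,
                 n_event = fit$n.event, surv = fit$surv, fit = fit),
            class = "km_fit")
}

#' Evaluate a Kaplan-Meier curve
#'
#' Right-continuous step-function evaluation: `S(t) = 1` before the first
#' event time.
#'
#' @param km A `km_fit`.
#' @param t Time(s) at which to evaluate.
#' @return Survival probabilities.
#' @export
km_surv_at <- function(km, t) {
  if (length(km$time) == 0) return(rep(1, length(t)))
  stats::approx(km$time, km$surv, xout = t, method = "constant",
                f = 0, yleft = 1, rule = 2)$y
}

#' @export
print.km_fit <- function(x, ...) {
  cat("<km_fit> ", length(x$time), " distinct times, ", sum(x$n_event),
      " events\n", sep = "")
  invisible(x)
}

#' Log-rank test between two survival groups
#'
#' Chi-square statistic (1 df) and p-value, via `survival::survdiff`;
#' invariant under swapping the group labels.
#'
#' @param time Follow-up times.
#' @param event Event indicators (1 = death).
#' @param group Two-level group labels.
#' @return list with `statistic`, `p_value`, `df`.
#' @export
logrank <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2) {
    stop("both groups must be non-empty")
  }
  if (sum(event) == 0) stop("no events in either group: test undefined")
  fit <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(fit$n) - 1L
  list(statistic = unname(fit$chisq),
       p_value = stats::pchisq(fit$chisq, df, lower.tail = FALSE),
       df = df)
}

#' Simulate an exponential-survival cohort
#'
#' Two-arm cohort with exponential event times (baseline rate and hazard
#' ratio) and administrative censoring, for exercising the survival
#' operations: per-case follow-up times are not published for the real
#' cohort, so survival analyses run on simulated or user-supplied times.
#'
#' @param n_per_group Cases per arm.
#' @param hazard_ratio Hazard ratio of group B vs A.
#' @param baseline_rate Events per month in group A.
#' @param censor_time Administrative censoring horizon (months).
#' @param seed Integer seed.
#' @return data.frame (`time`, `event`, `group`).
#' @export
simulate_survival_cohort <- function(n_per_group = 100L, hazard_ratio = 1,
                                     baseline_rate = 0.02,
                                     censor_time = 120, seed = 1L) {
  withr::with_seed(seed, {
    t_a <- stats::rexp(n_per_group, baseline_rate)
    t_b <- stats::rexp(n_per_group, baseline_rate * hazard_ratio)
    raw <- c(t_a, t_b)
    data.frame(time = pmin(raw, censor_time),
               event = as.integer(raw <= censor_time),
               group = rep(c("A", "B"), each = n_per_group))
  })
}
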