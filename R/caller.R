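# The classification rule at the heart of the pipeline: a nucleotide
# frequency is called a mutation when it lies more than k = 5 standard
# deviations above the control-derived background at that (position,
# alternate base).  Each alternate allele is tested separately, so two
# subclones hitting the same codon yield two calls.  No multiple-testing
# correction is applied (k = 5 is itself stringent); the number of tests
# performed is attached so users can post-correct if they wish.

#' Call variants from a sample pileup
#'
#' Applies the k-SD rule per (position, alternate base) at every in-target
#' position with sufficient depth, annotates each call to an amino-acid
#' change (minus-strand codon translation), and classifies clonality and
#' Sanger detectability from the allele fraction.
#'
#' @param pileup Sample pileup data.frame.
#' @param model A `noise_model` from [estimate_background()].
#' @param reference A `mini_reference`.
#' @param k SD multiplier; calls require `z > k` (strict).
#' @param min_depth Positions below this depth are "not assessable" and are
#'   reported in the `not_assessable` attribute, distinct from a no-call.
#' @param clonal_threshold Calls with VAF strictly below this are subclonal.
#' @param sanger_threshold Calls with VAF strictly above this are flagged
#'   detectable by capillary (Sanger) sequencing.
#' @param sample_id Sample identifier carried into the calls.
#' @return data.frame of calls (`sample`, `chrom`, `pos`, `ref`, `alt`,
#'   `alt_count`, `depth`, `vaf`, `z`, `aa_change`, `residue`, `synonymous`,
#'   `hotspot`, `clonality`, `sanger_detectable`), with attributes
#'   `n_tests`, `not_assessable` (positions failing `min_depth`) and
#'   `uncovered` (tested pileup positions absent from the noise model, also
#'   reported via a message rather than silently skipped).
#' @export
call_variants <- function(pileup, model, reference = build_mini_reference(),
                          k = 5, min_depth = 5000L,
                          clonal_threshold = 0.20, sanger_threshold = 0.15,
                          sample_id = "sample") {
  stopifnot(k > 0)
  bases <- c("A", "C", "G", "T")
  assessable <- pileup$depth >= min_depth
  not_assessable <- pileup$pos[!assessable]
  p <- pileup[assessable, , drop = FALSE]
  empty <- data.frame(
    sample = character(0), chrom = character(0), pos = integer(0),
    ref = character(0), alt = character(0), alt_count = integer(0),
    depth = integer(0), vaf = numeric(0), z = numeric(0),
    aa_change = character(0), residue = integer(0), synonymous = logical(0),
    hotspot = character(0), clonality = character(0),
    sanger_detectable = logical(0), stringsAsFactors = FALSE)
  finish <- function(calls, n_tests, uncovered) {
    attr(calls, "n_tests") <- n_tests
    attr(calls, "not_assessable") <- not_assessable
    attr(calls, "uncovered") <- uncovered
    calls
  }
  if (nrow(p) == 0) return(finish(empty, 0L, integer(0)))

  # long table: one row per (position, alternate base)
  long <- data.frame(
    chrom = rep(p$chrom, each = 3L),
    pos = rep(p$pos, each = 3L),
    ref = rep(p$ref, each = 3L),
    depth = rep(p$depth, each = 3L),
    alt = unlist(lapply(p$ref, function(r) setdiff(bases, r)),
                 use.names = FALSE),
    stringsAsFactors = FALSE)
  long$alt_count <- as.matrix(p[, bases])[
    cbind(rep(seq_len(nrow(p)), each = 3L), match(long$alt, bases))]
  key <- paste(long$pos, long$alt)
  mi <- match(key, paste(model$pos, model$alt))
  uncovered <- sort(unique(long$pos[is.na(mi)]))
  if (length(uncovered)) {
    message("noise model does not cover ", length(uncovered),
            " pileup position(s); they were not tested")
  }
  tested <- !is.na(mi)
  long <- long[tested, , drop = FALSE]
  mi <- mi[tested]
  long$vaf <- long$alt_count / long$depth
  long$z <- (long$vaf - model$mean[mi]) /
    pmax(model$sd[mi], attr(model, "floor"))
  hits <- long[long$z > k & long$alt_count > 0L, , drop = FALSE]
  if (nrow(hits) == 0) return(finish(empty, nrow(long), uncovered))

  ann <- lapply(seq_len(nrow(hits)), function(i) {
    tryCatch(annotate_substitution(hits$pos[i], hits$ref[i], hits$alt[i],
                                   reference),
             error = function(e) list(residue = NA_integer_,
                                      label = NA_character_,
                                      synonymous = NA))
  })
  residue <- vapply(ann, function(a) as.integer(a$residue), integer(1))
  hs <- hotspot_codons(reference)
  hi <- match(residue, hs$residue)
  calls <- data.frame(
    sample = sample_id, chrom = hits$chrom, pos = hits$pos, ref = hits$ref,
    alt = hits$alt, alt_count = hits$alt_count, depth = hits$depth,
    vaf = hits$vaf, z = hits$z,
    aa_change = vapply(ann, function(a) as.character(a$label), character(1)),
    residue = residue,
    synonymous = vapply(ann, function(a) as.logical(a$synonymous),
                        logical(1)),
    hotspot = ifelse(is.na(hi), "non-hotspot",
                     paste0(hs$ref_aa[hi], hs$residue[hi])),
    clonality = classify_clonality(hits$vaf, clonal_threshold),
    sanger_detectable = flag_sanger_detectable(hits$vaf, sanger_threshold),
    stringsAsFactors = FALSE)
  calls <- calls[order(calls$pos, calls$alt), , drop = FALSE]
  rownames(calls) <- NULL
  finish(calls, nrow(long), uncovered)
}

#' Clonality classification
#'
#' A call is subclonal when its allele fraction is strictly below the
#' threshold (default 20%), clonal otherwise.
#'
#' @param vaf Allele fraction(s).
#' @param clonal_threshold Threshold fraction.
#' @return Character vector, `"clonal"` or `"subclonal"`.
#' @export
classify_clonality <- function(vaf, clonal_threshold = 0.20) {
  ifelse(vaf < clonal_threshold, "subclonal", "clonal")
}

#' Sanger detectability flag
#'
#' In the validation data, capillary sequencing confirmed every mutation with
#' allele fraction strictly above 15%; this predicate encodes that empirical
#' detection limit.
#'
#' @param vaf Allele fraction(s).
#' @param sanger_threshold Threshold fraction.
#' @return Logical vector.
#' @export
flag_sanger_detectable <- function(vaf, sanger_threshold = 0.15) {
  vaf > sanger_threshold
}

#' Evaluate a dilution series
#'
#' Summarises detection of a known spike-in across a dilution series: per
#' dilution, whether the expected variant was called, the observed versus
#' expected allele fraction and the relative error; plus the overall
#' detection limit (smallest expected fraction still detected).
#'
#' @param calls_list List of call data.frames, one per dilution (in series
#'   order), as returned by [call_variants()].
#' @param expected_vafs Expected allele fraction per dilution.
#' @param pos,alt Genomic position and alternate base of the spiked variant.
#' @return data.frame (`dilution`, `expected_vaf`, `detected`,
#'   `observed_vaf`, `relative_error`) with attribute `detection_limit`
#'   (`NA` if nothing was detected).
#' @export
evaluate_dilution_series <- function(calls_list, expected_vafs, pos, alt) {
  stopifnot(length(calls_list) == length(expected_vafs))
  if (length(calls_list) == 0) {
    out <- data.frame(dilution = integer(0), expected_vaf = numeric(0),
                      detected = logical(0), observed_vaf = numeric(0),
                      relative_error = numeric(0))
    attr(out, "detection_limit") <- NA_real_
    return(out)
  }
  rows <- lapply(seq_along(calls_list), function(i) {
    calls <- calls_list[[i]]
    hit <- calls[calls$pos == pos & calls$alt == alt, , drop = FALSE]
    detected <- nrow(hit) > 0
    obs <- if (detected) hit$vaf[1] else NA_real_
    data.frame(dilution = i, expected_vaf = expected_vafs[i],
               detected = detected, observed_vaf = obs,
               relative_error = (obs - expected_vafs[i]) / expected_vafs[i])
  })
  out <- do.call(rbind, rows)
  attr(out, "detection_limit") <-
    if (any(out$detected)) min(out$expected_vaf[out$detected]) else NA_real_
  out
}

# ---- VCF 4.2 round-trip (single sample, INFO-only records) ----

.VCF_INFO <- c(
  "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
  "##INFO=<ID=AC,Number=1,Type=Integer,Description=\"Alternate allele read count\">",
  "##INFO=<ID=AF,Number=1,Type=Float,Description=\"Variant allele fraction\">",
  "##INFO=<ID=Z,Number=1,Type=Float,Description=\"Standardised excess over background noise\">",
  "##INFO=<ID=AAC,Number=1,Type=String,Description=\"Amino-acid change (minus-strand codon)\">",
  "##INFO=<ID=RES,Number=1,Type=Integer,Description=\"Protein residue number\">",
  "##INFO=<ID=SYN,Number=1,Type=String,Description=\"Synonymous flag\">",
  "##INFO=<ID=HOT,Number=1,Type=String,Description=\"Hotspot codon label or non-hotspot\">",
  "##INFO=<ID=CLON,Number=1,Type=String,Description=\"Clonality classification\">",
  "##INFO=<ID=SANG,Number=1,Type=String,Description=\"Detectable by Sanger sequencing\">")

#' Write calls as VCF 4.2
#'
#' One sample per file; depth, allele count, fraction, z-score, amino-acid
#' annotation, hotspot, clonality and detectability go into INFO fields.
#'
#' @param calls Calls data.frame from [call_variants()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls_vcf <- function(calls, path) {
  con <- file(path, "w")
  on.exit(close(con))
  sample_id <- if (nrow(calls) > 0) calls$sample[1] else "sample"
  writeLines(c("##fileformat=VCFv4.2",
               "##source=alkdeep",
               paste0("##sample=", sample_id),
               "##contig=<ID=chr2,length=243199373,assembly=hg19>",
               .VCF_INFO,
               paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", sep = "\t")), con)
  if (nrow(calls) > 0) {
    info <- sprintf(
      "DP=%d;AC=%d;AF=%.10g;Z=%.10g;AAC=%s;RES=%s;SYN=%s;HOT=%s;CLON=%s;SANG=%s",
      calls$depth, calls$alt_count, calls$vaf, calls$z,
      ifelse(is.na(calls$aa_change), ".", calls$aa_change),
      ifelse(is.na(calls$residue), ".", calls$residue),
      ifelse(is.na(calls$synonymous), ".",
             ifelse(calls$synonymous, "yes", "no")),
      calls$hotspot, calls$clonality,
      ifelse(calls$sanger_detectable, "yes", "no"))
    writeLines(paste(calls$chrom, calls$pos, ".", calls$ref, calls$alt, ".",
                     "PASS", info, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a VCF written by [write_calls_vcf()]
#'
#' @param path VCF path.
#' @return Calls data.frame with the same columns as [call_variants()].
#' @export
read_calls_vcf <- function(path) {
  lines <- readLines(path)
  sample_id <- sub("^##sample=", "",
                   c(grep("^##sample=", lines, value = TRUE), "sample")[1])
  body <- lines[!startsWith(lines, "#")]
  empty <- data.frame(
    sample = character(0), chrom = character(0), pos = integer(0),
    ref = character(0), alt = character(0), alt_count = integer(0),
    depth = integer(0), vaf = numeric(0), z = numeric(0),
    aa_change = character(0), residue = integer(0), synonymous = logical(0),
    hotspot = character(0), clonality = character(0),
    sanger_detectable = logical(0), stringsAsFactors = FALSE)
  if (length(body) == 0) return(empty)
  fields <- strsplit(body, "\t", fixed = TRUE)
  info_get <- function(info, key) {
    m <- regmatches(info, regexec(paste0("(^|;)", key, "=([^;]*)"), info))
    vapply(m, function(x) if (length(x)) x[3] else NA_character_,
           character(1))
  }
  info <- vapply(fields, `[`, character(1), 8)
  syn <- info_get(info, "SYN")
  aac <- info_get(info, "AAC")
  res <- info_get(info, "RES")
  data.frame(
    sample = sample_id,
    chrom = vapply(fields, `[`, character(1), 1),
    pos = as.integer(vapply(fields, `[`, character(1), 2)),
    ref = vapply(fields, `[`, character(1), 4),
    alt = vapply(fields, `[`, character(1), 5),
    alt_count = as.integer(info_get(info, "AC")),
    depth = as.integer(info_get(info, "DP")),
    vaf = as.numeric(info_get(info, "AF")),
    z = as.numeric(info_get(info, "Z")),
    aa_change = ifelse(aac == ".", NA_character_, aac),
    residue = suppressWarnings(as.integer(ifelse(res == ".", NA, res))),
    synonymous = ifelse(syn == ".", NA, syn == "yes"),
    hotspot = info_get(info, "HOT"),
    clonality = info_get(info, "CLON"),
    sanger_detectable = info_get(info, "SANG") == "yes",
    stringsAsFactors = FALSE)
}
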