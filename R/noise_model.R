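# Background-noise model: per-position, per-alternate mean and SD of the
# apparent allele fraction across mutation-free control samples.  This is the
# yardstick of the classification rule: an observed nucleotide frequency is
# called a mutation when it exceeds the background mean by more than k
# (default 5) standard deviations.

#' Estimate background noise from control pileups
#'
#' For every (position, alternate base) covered by the controls, computes the
#' mean and unbiased (n-1) sample SD of the alternate-allele fraction across
#' controls.  Positions absent from some controls are estimated from those
#' present and flagged `partial`.  A global noise floor guards positions
#' whose sampled SD is (near) zero: downstream z-scores always divide by
#' `max(sd, floor)`.
#'
#' @param control_pileups List of >= 2 pileup data.frames from mutation-free
#'   controls.
#' @param floor Global noise-floor SD (fraction units).
#' @param regions Target regions; controls are intersected with them.
#' @return A `noise_model`: data.frame (`chrom`, `pos`, `ref`, `alt`,
#'   `mean`, `sd`, `n`, `partial`) with attribute `floor`.
#' @export
estimate_background <- function(control_pileups, floor = 2e-4,
                                regions = alk_target_regions()) {
  if (length(control_pileups) < 2L) {
    stop("at least 2 control samples are required (background SD undefined)")
  }
  bases <- c("A", "C", "G", "T")
  frac_tabs <- lapply(control_pileups, function(p) {
    p <- p[!is.na(locate_position_fast(p$pos, regions)) & p$depth > 0, ,
           drop = FALSE]
    f <- as.matrix(p[, bases]) / p$depth
    rownames(f) <- p$pos
    attr(f, "ref") <- stats::setNames(p$ref, p$pos)
    f
  })
  all_pos <- sort(unique(unlist(lapply(frac_tabs, rownames))))
  if (length(all_pos) == 0) {
    stop("controls have no overlap with the target regions")
  }
  ref_map <- character(0)
  for (f in frac_tabs) ref_map[names(attr(f, "ref"))] <- attr(f, "ref")
  n_pos <- length(all_pos)
  acc_n <- matrix(0L, n_pos, 4L, dimnames = list(all_pos, bases))
  acc_sum <- matrix(0, n_pos, 4L, dimnames = list(all_pos, bases))
  acc_sq <- matrix(0, n_pos, 4L, dimnames = list(all_pos, bases))
  for (f in frac_tabs) {
    i <- match(rownames(f), all_pos)
    acc_n[i, ] <- acc_n[i, ] + 1L
    acc_sum[i, ] <- acc_sum[i, ] + f
    acc_sq[i, ] <- acc_sq[i, ] + f^2
  }
  mean_m <- acc_sum / acc_n
  var_m <- (acc_sq - acc_n * mean_m^2) / (acc_n - 1L)
  var_m[acc_n < 2L] <- NA_real_
  sd_m <- sqrt(pmax(var_m, 0))
  ref <- ref_map[all_pos]
  alt_of <- lapply(ref, function(r) setdiff(bases, r))
  rows <- data.frame(
    chrom = "chr2",
    pos = rep(as.integer(all_pos), each = 3L),
    ref = rep(unname(ref), each = 3L),
    alt = unlist(alt_of, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  idx <- cbind(match(as.character(rows$pos), all_pos), match(rows$alt, bases))
  rows$mean <- mean_m[idx]
  rows$sd <- sd_m[idx]
  rows$n <- acc_n[idx]
  rows$partial <- rows$n < length(control_pileups)
  if (any(rows$n < 2L)) {
    stop("position(s) covered by fewer than 2 controls: ",
         paste(unique(rows$pos[rows$n < 2L]), collapse = ", "))
  }
  structure(rows, class = c("noise_model", "data.frame"), floor = floor)
}

#' Effective SD of a noise model
#'
#' `max(sd, floor)` as used by every downstream z-score.
#'
#' @param model A `noise_model`.
#' @return Numeric vector, one value per model row.
#' @export
effective_sd <- function(model) {
  pmax(model$sd, attr(model, "floor"))
}

#' Standardised excess over background
#'
#' `z = (observed - mean) / max(sd, floor)` for the given (position,
#' alternate) entries of the model.
#'
#' @param observed Observed alternate-allele fraction(s).
#' @param pos Genomic position(s).
#' @param alt Alternate base(s).
#' @param model A `noise_model`.
#' @return Numeric z-score vector.
#' @export
zscore <- function(observed, pos, alt, model) {
  i <- match(paste(pos, alt), paste(model$pos, model$alt))
  if (anyNA(i)) {
    stop("noise model does not cover (position, alt): ",
         paste(paste0(pos, ">", alt)[is.na(i)], collapse = ", "))
  }
  (observed - model$mean[i]) / pmax(model$sd[i], attr(model, "floor"))
}

#' Write a noise model as TSV
#'
#' Tab-separated `chrom, pos, ref, alt, mean, sd, n` preceded by a single
#' comment line carrying the noise floor.
#'
#' @param model A `noise_model`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_noise_tsv <- function(model, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#floor=%.10g", attr(model, "floor")), con)
  utils::write.table(
    model[, c("chrom", "pos", "ref", "alt", "mean", "sd", "n")],
    con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a noise model TSV
#'
#' @param path Path written by [write_noise_tsv()].
#' @return A `noise_model`.
#' @export
read_noise_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  if (!grepl("^#floor=", first)) {
    stop("noise TSV ", path, " lacks the #floor= header line")
  }
  floor <- as.numeric(sub("^#floor=", "", first))
  x <- utils::read.delim(path, skip = 1L, stringsAsFactors = FALSE)
  x$partial <- FALSE
  structure(x, class = c("noise_model", "data.frame"), floor = floor)
}

#' @export
print.noise_model <- function(x, ...) {
  cat("<noise_model> ", nrow(x), " (position, alt) entries over ",
      length(unique(x$pos)), " positions; n = ",
      paste(range(x$n), collapse = "-"), " controls; floor = ",
      format(attr(x, "floor")), "\n", sep = "")
  invisible(x)
}
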