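# Per-position allele counting with base-quality filtering.

.PILEUP_TSV_COLS <- c("chrom", "pos", "ref", "countA", "countC", "countG",
                      "countT", "countOther", "depth")

#' Build a pileup from aligned-read records
#'
#' Tallies per-position base counts over the target regions.  Bases with
#' phred quality below `min_base_quality`, and non-ACGT bases, are counted in
#' the `other` column; by default they still contribute to depth, so allele
#' fractions are taken over total coverage (set `lowq_in_depth = FALSE` to
#' drop them from the denominator instead).  Positions outside the target
#' regions are discarded.  Only ungapped alignments (CIGAR `<n>M`) are
#' supported.
#'
#' @param reads data.frame of read records as produced by [emit_reads()] or
#'   [read_sam()] (`rname`, `pos`, `cigar`, `seq`, `qual`).
#' @param regions Target regions data.frame.
#' @param min_base_quality Phred threshold; the assay's QC motivates the
#'   default of 30.
#' @param reference A `mini_reference` supplying reference bases.
#' @param lowq_in_depth Keep filtered bases in the depth denominator?
#' @return Pileup data.frame (`chrom`, `pos`, `ref`, `A`, `C`, `G`, `T`,
#'   `other`, `depth`), covered in-target positions only.
#' @export
build_pileup <- function(reads, regions = alk_target_regions(),
                         min_base_quality = 30L,
                         reference = build_mini_reference(regions),
                         lowq_in_depth = TRUE) {
  empty <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), A = integer(0), C = integer(0),
                      G = integer(0), T = integer(0), other = integer(0),
                      depth = integer(0))
  if (nrow(reads) == 0) return(empty)
  lens <- nchar(reads$seq)
  ok <- grepl("^[0-9]+M$", reads$cigar) &
    as.integer(sub("M$", "", reads$cigar)) == lens &
    nchar(reads$qual) == lens
  if (any(!ok)) {
    stop("malformed read record(s) at index: ",
         paste(utils::head(which(!ok), 10), collapse = ", "))
  }
  row <- rep.int(seq_len(nrow(reads)), lens)
  offset <- sequence(lens) - 1L
  pos <- reads$pos[row] + offset
  base <- toupper(unlist(strsplit(reads$seq, ""), use.names = FALSE))
  qual <- unlist(lapply(reads$qual, function(q) utf8ToInt(q) - 33L),
                 use.names = FALSE)
  in_target <- !is.na(locate_position_fast(pos, regions))
  if (!any(in_target)) return(empty)
  pos <- pos[in_target]; base <- base[in_target]; qual <- qual[in_target]
  good <- base %in% c("A", "C", "G", "T") & qual >= min_base_quality
  cls <- ifelse(good, base, "other")
  if (!lowq_in_depth) {
    pos <- pos[good]; cls <- cls[good]
    if (length(pos) == 0) return(empty)
  }
  tab <- table(factor(pos, levels = sort(unique(pos))),
               factor(cls, levels = c("A", "C", "G", "T", "other")))
  upos <- as.integer(rownames(tab))
  counts <- as.data.frame.matrix(tab)
  data.frame(chrom = regions$chrom[1], pos = upos,
             ref = ref_base(upos, reference),
             A = counts$A, C = counts$C, G = counts$G, T = counts$T,
             other = counts$other,
             depth = counts$A + counts$C + counts$G + counts$T + counts$other,
             stringsAsFactors = FALSE)
}

# Vectorised in/out-of-target test (no per-element lookup of region name).
locate_position_fast <- function(pos, regions = alk_target_regions()) {
  hit <- rep(NA_character_, length(pos))
  for (i in seq_len(nrow(regions))) {
    inside <- pos >= regions$start[i] & pos <= regions$end[i]
    hit[inside] <- regions$name[i]
  }
  hit
}

#' Nucleotide frequencies at a position
#'
#' Exact per-base fractions of depth for one or more pileup rows.
#'
#' @param pc Pileup data.frame (one or more rows).
#' @return data.frame with columns `pos`, `A`, `C`, `G`, `T`, `other`, each a
#'   fraction of depth.
#' @export
frequencies <- function(pc) {
  if (any(pc$depth == 0)) {
    stop("frequencies undefined at zero depth (pos ",
         paste(pc$pos[pc$depth == 0], collapse = ", "), ")")
  }
  data.frame(pos = pc$pos,
             A = pc$A / pc$depth, C = pc$C / pc$depth,
             G = pc$G / pc$depth, T = pc$T / pc$depth,
             other = pc$other / pc$depth)
}

#' Coverage validation report
#'
#' Flags pileup positions below the minimum assessable depth (the assay is
#' designed for at least 5000x per position).
#'
#' @param pileup Pileup data.frame.
#' @param min_depth Minimum required depth.
#' @return data.frame (`chrom`, `pos`, `depth`, `pass`); attribute
#'   `callable` holds the passing positions.
#' @export
validate_coverage <- function(pileup, min_depth = 5000L) {
  rep <- data.frame(chrom = pileup$chrom, pos = pileup$pos,
                    depth = pileup$depth, pass = pileup$depth >= min_depth)
  attr(rep, "callable") <- rep$pos[rep$pass]
  rep
}

#' Write a pileup as TSV
#'
#' Columns `chrom, pos, ref, countA, countC, countG, countT, countOther,
#' depth`; round-trips bit-exactly with [read_pileup_tsv()].
#'
#' @param pileup Pileup data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pileup_tsv <- function(pileup, path) {
  out <- data.frame(chrom = pileup$chrom, pos = pileup$pos, ref = pileup$ref,
                    countA = pileup$A, countC = pileup$C, countG = pileup$G,
                    countT = pileup$T, countOther = pileup$other,
                    depth = pileup$depth)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a pileup TSV
#'
#' @param path TSV path written by [write_pileup_tsv()].
#' @return Pileup data.frame.
#' @export
read_pileup_tsv <- function(path) {
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(.PILEUP_TSV_COLS, names(x))
  if (length(missing)) {
    stop("pileup TSV ", path, " lacks column(s): ",
         paste(missing, collapse = ", "))
  }
  out <- data.frame(chrom = x$chrom, pos = as.integer(x$pos), ref = x$ref,
                    A = as.integer(x$countA), C = as.integer(x$countC),
                    G = as.integer(x$countG), T = as.integer(x$countT),
                    other = as.integer(x$countOther),
                    depth = as.integer(x$depth), stringsAsFactors = FALSE)
  bad <- with(out, A + C + G + T + other != depth)
  if (any(bad)) {
    stop("pileup TSV ", path, ": counts do not sum to depth at pos ",
         paste(out$pos[bad], collapse = ", "))
  }
  out
}

#' Write read records as minimal SAM
#'
#' Single-reference SAM with a `chr2` header; mapped, ungapped records only.
#'
#' @param reads Read records data.frame.
#' @param path Output path.
#' @param reference_length Length stated in the `@SQ` line.
#' @return `path`, invisibly.
#' @export
write_sam <- function(reads, path, reference_length = 243199373L) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               paste0("@SQ\tSN:chr2\tLN:", reference_length)), con)
  if (nrow(reads) > 0) {
    writeLines(paste(reads$qname, reads$flag, reads$rname, reads$pos,
                     reads$mapq, reads$cigar, "*", 0L, 0L, reads$seq,
                     reads$qual, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a minimal SAM file
#'
#' Parses mapped, ungapped (`<n>M`) records; anything else is rejected with
#' the offending record index.
#'
#' @param path SAM path.
#' @return Read records data.frame (`qname`, `flag`, `rname`, `pos`, `mapq`,
#'   `cigar`, `seq`, `qual`).
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "@")]
  if (length(body) == 0) {
    return(data.frame(qname = character(0), flag = integer(0),
                      rname = character(0), pos = integer(0),
                      mapq = integer(0), cigar = character(0),
                      seq = character(0), qual = character(0)))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 11L)
  if (length(short)) {
    stop("malformed SAM record(s) at line index: ",
         paste(utils::head(short, 10), collapse = ", "))
  }
  get <- function(i) vapply(fields, `[`, character(1), i)
  out <- data.frame(qname = get(1), flag = as.integer(get(2)),
                    rname = get(3), pos = as.integer(get(4)),
                    mapq = as.integer(get(5)), cigar = get(6),
                    seq = get(10), qual = get(11), stringsAsFactors = FALSE)
  bad <- which(!grepl("^[0-9]+M$", out$cigar))
  if (length(bad)) {
    stop("unsupported CIGAR (only ungapped matches handled) at record(s): ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  out
}
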