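# Target geometry of the ALK tyrosine-kinase domain (hg19, minus strand).
#
# ALK is transcribed from the minus strand of chr2, so the coding sequence
# walks the five target exons in order of *decreasing* forward-strand
# coordinate.  All positions handled by the package are 1-based forward-strand
# genomic coordinates; annotation reverse-complements at the codon level.

#' ALK kinase-domain target regions (hg19)
#'
#' The five exon intervals of the ALK tyrosine-kinase domain targeted by the
#' assay, as 1-based inclusive forward-strand coordinates on chr2 (hg19).
#'
#' @return A data.frame with columns `name`, `chrom`, `start`, `end`,
#'   one row per exon (21-25), ordered by exon number.
#' @examples
#' alk_target_regions()
#' @export
alk_target_regions <- function() {
  data.frame(
    name  = paste0("exon", 21:25),
    chrom = "chr2",
    start = c(29445383L, 29445210L, 29443572L, 29436850L, 29432652L),
    end   = c(29445473L, 29445274L, 29443701L, 29436947L, 29432744L),
    stringsAsFactors = FALSE
  )
}

# Number of coding bases upstream (5', i.e. at higher forward coordinate) of
# the first base of exon 21.  Anchored simultaneously by the published codon
# coordinates of I1171, F1174, L1240 and F1245; any one anchor yields the same
# offset, which is what makes the frame model self-consistent.
.CDS_OFFSET <- 3359L

#' Coding-position ladder over the target regions
#'
#' Maps every targeted genomic position to its coding-sequence (CDS)
#' coordinate, walking exons 5' to 3' on the minus strand (decreasing forward
#' coordinate).  Internal workhorse for all codon arithmetic.
#'
#' @param regions Target regions, as from [alk_target_regions()].
#' @return data.frame with columns `pos` (forward genomic), `exon`, `cds`
#'   (1-based coding coordinate), `residue`, `codon_offset` (1-3, in coding
#'   orientation).
#' @keywords internal
coding_ladder <- function(regions = alk_target_regions()) {
  ord <- order(regions$start, decreasing = TRUE)
  pos <- unlist(lapply(ord, function(i) seq(regions$end[i], regions$start[i])),
                use.names = FALSE)
  exon <- rep(regions$name[ord], regions$end[ord] - regions$start[ord] + 1L)
  cds <- .CDS_OFFSET + seq_along(pos)
  data.frame(
    pos = pos, exon = exon, cds = cds,
    residue = (cds + 2L) %/% 3L,
    codon_offset = cds - 3L * ((cds + 2L) %/% 3L - 1L),
    stringsAsFactors = FALSE
  )
}

#' Locate a genomic position within the target regions
#'
#' @param pos Forward-strand genomic position(s), 1-based.
#' @param regions Target regions data.frame.
#' @return Character vector of region names, `NA` where the position falls
#'   outside every target region.
#' @examples
#' locate_position(29445213)  # exon22 (the I1171 site)
#' locate_position(1)         # NA: off target
#' @export
locate_position <- function(pos, regions = alk_target_regions()) {
  stopifnot(is.numeric(pos), all(pos > 0))
  vapply(pos, function(p) {
    hit <- which(regions$start <= p & p <= regions$end)
    if (length(hit) == 1L) regions$name[hit] else NA_character_
  }, character(1))
}

#' Protein coordinate of a genomic position
#'
#' Converts a forward-strand genomic position inside the target regions into
#' the ALK protein residue number and the position within the codon (1-3 in
#' coding orientation; because the gene lies on the minus strand, codon
#' position 1 is the *highest* forward coordinate of the codon, and residue
#' numbers increase as the forward coordinate decreases).
#'
#' @param pos Forward-strand genomic position(s).
#' @param regions Target regions data.frame.
#' @return data.frame with columns `pos`, `residue`, `codon_offset`, `exon`.
#' @examples
#' codon_for_position(29436858)  # residue 1245
#' codon_for_position(29443695)  # residue 1174
#' @export
codon_for_position <- function(pos, regions = alk_target_regions()) {
  ladder <- coding_ladder(regions)
  idx <- match(pos, ladder$pos)
  if (anyNA(idx)) {
    stop("position(s) outside the coding frame of the target regions: ",
         paste(pos[is.na(idx)], collapse = ", "))
  }
  ladder[idx, c("pos", "residue", "codon_offset", "exon")]
}

# Fixed coding-strand codons for the residues the assay interrogates.  The
# bundled reference is synthetic: published sources give residue letters, not
# nucleotides, so codons are chosen to be consistent with the reference amino
# acids and to make every reported variant (F1174L/I/C/S, F1245I/C, L1240V,
# I1171T, D1160D, R1275Q/L) reachable by a single-base substitution.
.HOTSPOT_CODING_CODONS <- c(
  "1160" = "GAC",  # D
  "1170" = "ATC",  # I
  "1171" = "ATC",  # I
  "1174" = "TTC",  # F
  "1240" = "CTG",  # L
  "1245" = "TTC",  # F
  "1275" = "CGA"   # R
)

# Filler codons for all other residues: cycled deterministically, no stops.
.FILLER_CODONS <- c("GCT", "GAA", "AAG", "CTT", "GAT",
                    "ATG", "CCA", "TCT", "GTG", "TAC")

.complement <- function(x) chartr("ACGTacgt", "TGCAtgca", x)

.translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[toupper(codon)]]
  if (is.null(aa)) stop("not a DNA codon: ", codon)
  aa
}

#' Synthetic forward-strand reference over the target regions
#'
#' Builds the bundled mini-reference: a forward-strand base for every targeted
#' position, synthesised residue-by-residue on the coding strand (hotspot
#' codons fixed, filler codons cycled from a fixed non-stop set) and
#' complemented onto the forward strand.  It is a synthetic stand-in for the
#' hg19 sequence -- consistent with the reference amino acids at every
#' interrogated residue, but not the true ALK nucleotide sequence.
#'
#' @param regions Target regions data.frame.
#' @return A `mini_reference` object: list with `bases` (named character
#'   vector, names are genomic positions), `regions`, and `ladder`.
#' @export
build_mini_reference <- function(regions = alk_target_regions()) {
  ladder <- coding_ladder(regions)
  residues <- sort(unique(ladder$residue))
  codons <- .FILLER_CODONS[(residues %% length(.FILLER_CODONS)) + 1L]
  names(codons) <- residues
  fixed <- intersect(names(.HOTSPOT_CODING_CODONS), names(codons))
  codons[fixed] <- .HOTSPOT_CODING_CODONS[fixed]
  coding_base <- substr(codons[as.character(ladder$residue)],
                        ladder$codon_offset, ladder$codon_offset)
  bases <- .complement(coding_base)
  names(bases) <- ladder$pos
  structure(list(bases = bases, regions = regions, ladder = ladder),
            class = "mini_reference")
}

#' @export
print.mini_reference <- function(x, ...) {
  cat("<mini_reference> ", length(x$bases), " positions over ",
      nrow(x$regions), " regions (synthetic ALK kinase-domain reference)\n",
      sep = "")
  invisible(x)
}

#' Reference base lookup
#'
#' @param pos Forward-strand genomic position(s).
#' @param reference A `mini_reference`.
#' @return Character vector of forward-strand reference bases.
#' @export
ref_base <- function(pos, reference = build_mini_reference()) {
  b <- reference$bases[as.character(pos)]
  if (anyNA(b)) stop("position(s) not covered by the reference: ",
                     paste(pos[is.na(b)], collapse = ", "))
  unname(b)
}

# Genomic positions of a residue's codon, in coding order (offset 1, 2, 3).
.codon_positions <- function(residue, ladder) {
  rows <- ladder[ladder$residue == residue, , drop = FALSE]
  rows <- rows[order(rows$codon_offset), , drop = FALSE]
  if (nrow(rows) != 3L) {
    stop("codon for residue ", residue,
         " is only partially covered by the target regions")
  }
  rows$pos
}

#' Coding-strand codon of a residue
#' @keywords internal
.coding_codon <- function(residue, reference) {
  pos <- .codon_positions(residue, reference$ladder)
  paste(.complement(reference$bases[as.character(pos)]), collapse = "")
}

#' Known hotspot codon anchors
#'
#' Table of the interrogated ALK residues with their forward-strand genomic
#' codon spans and reference codons/amino acids.  R1275 has no published
#' genomic anchor; its exon-25 placement follows from the coding frame walked
#' across the exon 24/25 junction and is flagged `inferred`.
#'
#' @param reference A `mini_reference`.
#' @return data.frame with columns `residue`, `ref_aa`, `codon_start`,
#'   `codon_end` (forward-strand genomic span), `ref_codon_coding`,
#'   `ref_codon_fwd`, `exon`, `inferred`.
#' @export
hotspot_codons <- function(reference = build_mini_reference()) {
  res <- as.integer(names(.HOTSPOT_CODING_CODONS))
  rows <- lapply(res, function(r) {
    p <- .codon_positions(r, reference$ladder)
    coding <- .coding_codon(r, reference)
    data.frame(
      residue = r,
      ref_aa = .translate_codon(coding),
      codon_start = min(p),
      codon_end = max(p),
      ref_codon_coding = coding,
      ref_codon_fwd = paste(reference$bases[as.character(sort(p))],
                            collapse = ""),
      exon = reference$ladder$exon[match(p[1], reference$ladder$pos)],
      inferred = r == 1275L,
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Annotate a single-base substitution
#'
#' Translates a forward-strand substitution into an amino-acid change.  The
#' codon is assembled from the reference in coding orientation (reverse
#' complement of the forward strand, gene on the minus strand), the alternate
#' base is substituted at the affected codon position, and both codons are
#' translated under the standard genetic code.
#'
#' @param pos Forward-strand genomic position.
#' @param ref_fwd Forward-strand reference base; must match the reference.
#' @param alt_fwd Forward-strand alternate base.
#' @param reference A `mini_reference`.
#' @return A list with `residue`, `ref_aa`, `alt_aa`, `label` (e.g.
#'   `"F1174L"`), and `synonymous`.
#' @examples
#' ref <- build_mini_reference()
#' annotate_substitution(29443697, "A", "G", ref)  # F1174L
#' @export
annotate_substitution <- function(pos, ref_fwd, alt_fwd,
                                  reference = build_mini_reference()) {
  stopifnot(length(pos) == 1L)
  ref_fwd <- toupper(ref_fwd); alt_fwd <- toupper(alt_fwd)
  if (!all(c(ref_fwd, alt_fwd) %in% c("A", "C", "G", "T"))) {
    stop("ref and alt must be A/C/G/T")
  }
  stored <- ref_base(pos, reference)
  if (stored != ref_fwd) {
    stop("reference inconsistency at ", pos, ": reference has ", stored,
         ", caller supplied ", ref_fwd)
  }
  cp <- codon_for_position(pos, reference$regions)
  codon_pos <- .codon_positions(cp$residue, reference$ladder)
  coding <- strsplit(.coding_codon(cp$residue, reference), "")[[1]]
  ref_aa <- .translate_codon(paste(coding, collapse = ""))
  alt_coding <- coding
  alt_coding[cp$codon_offset] <- .complement(alt_fwd)
  alt_aa <- .translate_codon(paste(alt_coding, collapse = ""))
  list(
    residue = cp$residue,
    ref_aa = ref_aa,
    alt_aa = alt_aa,
    label = paste0(ref_aa, cp$residue, alt_aa),
    synonymous = identical(ref_aa, alt_aa)
  )
}

#' Genomic substitution realising a named protein change
#'
#' Inverse of [annotate_substitution()]: given a protein-level mutation name
#' such as `"F1174L"`, finds a single-base forward-strand substitution in the
#' bundled reference that produces it.  When several single-base edits yield
#' the same amino-acid change, the one at the lowest codon position (then
#' alphabetically first alternate) is chosen, which reproduces the published
#' nucleotide changes for the dual-clone case (F1174S by A>G, F1174I by A>T).
#'
#' @param name Mutation name, `<refAA><residue><altAA>`.
#' @param reference A `mini_reference`.
#' @return list with `pos`, `ref_fwd`, `alt_fwd`, `label`.
#' @export
mutation_to_substitution <- function(name, reference = build_mini_reference()) {
  m <- regmatches(name, regexec("^([A-Z])([0-9]+)([A-Z])$", name))[[1]]
  if (length(m) != 4L) stop("cannot parse mutation name: ", name)
  ref_aa <- m[2]; residue <- as.integer(m[3]); alt_aa <- m[4]
  codon_pos <- .codon_positions(residue, reference$ladder)
  coding <- strsplit(.coding_codon(residue, reference), "")[[1]]
  if (.translate_codon(paste(coding, collapse = "")) != ref_aa) {
    stop("reference amino acid at residue ", residue, " is not ", ref_aa)
  }
  for (off in 1:3) {
    for (b in c("A", "C", "G", "T")) {
      if (b == coding[off]) next
      cand <- coding
      cand[off] <- b
      if (.translate_codon(paste(cand, collapse = "")) == alt_aa) {
        p <- codon_pos[off]
        return(list(pos = p,
                    ref_fwd = .complement(coding[off]),
                    alt_fwd = .complement(b),
                    label = name))
      }
    }
  }
  stop("no single-base substitution yields ", name,
       " from codon ", paste(coding, collapse = ""))
}

#' Export target regions as BED
#'
#' Writes the (1-based inclusive) target regions as BED, converting to the
#' format's 0-based half-open convention.
#'
#' @param regions Target regions data.frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  bed <- data.frame(chrom = regions$chrom,
                    start = regions$start - 1L,
                    end = regions$end,
                    name = regions$name)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read target regions from BED
#'
#' @param path BED file path (first four columns used).
#' @return Target regions data.frame (1-based inclusive coordinates).
#' @export
read_regions_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  data.frame(name = bed[[4]], chrom = bed[[1]],
             start = as.integer(bed[[2]]) + 1L, end = as.integer(bed[[3]]),
             stringsAsFactors = FALSE)
}

#' Write the mini-reference as FASTA
#'
#' One record per exon, forward-strand sequence in ascending coordinate
#' order, headers `chr2:start-end:exonNN`.
#'
#' @param reference A `mini_reference`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_reference_fasta <- function(reference, path) {
  regions <- reference$regions
  seqs <- vapply(seq_len(nrow(regions)), function(i) {
    pos <- seq(regions$start[i], regions$end[i])
    paste(reference$bases[as.character(pos)], collapse = "")
  }, character(1))
  xs <- Biostrings::DNAStringSet(seqs)
  names(xs) <- sprintf("%s:%d-%d:%s", regions$chrom, regions$start,
                       regions$end, regions$name)
  Biostrings::writeXStringSet(xs, path)
  invisible(path)
}

#' Read a mini-reference from FASTA
#'
#' Inverse of [write_reference_fasta()]; headers must follow the
#' `chrom:start-end:name` convention.
#'
#' @param path FASTA path.
#' @return A `mini_reference`.
#' @export
read_reference_fasta <- function(path) {
  xs <- Biostrings::readDNAStringSet(path)
  parts <- regmatches(names(xs),
                      regexec("^([^:]+):([0-9]+)-([0-9]+):(.+)$", names(xs)))
  if (any(lengths(parts) != 5L)) stop("malformed FASTA header(s) in ", path)
  regions <- do.call(rbind, lapply(parts, function(p) {
    data.frame(name = p[5], chrom = p[2], start = as.integer(p[3]),
               end = as.integer(p[4]), stringsAsFactors = FALSE)
  }))
  regions <- regions[order(regions$start), , drop = FALSE]
  rownames(regions) <- NULL
  ladder <- coding_ladder(regions)
  bases <- unlist(lapply(seq_len(nrow(regions)), function(i) {
    s <- strsplit(as.character(xs[[which(vapply(parts, `[`, "", 5) ==
                                           regions$name[i])]]), "")[[1]]
    names(s) <- seq(regions$start[i], regions$end[i])
    s
  }))
  bases <- bases[as.character(ladder$pos)]
  structure(list(bases = bases, regions = regions, ladder = ladder),
            class = "mini_reference")
}
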