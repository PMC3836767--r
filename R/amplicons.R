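# Amplicon references, deletion templates, and substitution-type enumeration.
#
# Coordinates are 1-based inclusive throughout. Each amplicon carries a
# linear map from cDNA (NM_005228, position 1 = A of the ATG start codon)
# to GRCh37 chr7 genomic coordinates; conversion to 0-based half-open
# intervals happens only in the format writers (BED/VCF).

#' Construct an amplicon reference
#'
#' An amplicon reference ties a sequence to the coordinate systems the
#' caller reports in: cDNA positions of the transcript and genomic
#' positions on GRCh37 chr7. Only positions inside `target_window` are
#' scored for errors and mutations; the flanks exist so that simulated or
#' real reads overlap the window with realistic margins.
#'
#' @param amplicon_id Identifier, e.g. `"exon19"`.
#' @param exon Exon label (19, 20 or 21 for the EGFR design).
#' @param sequence Reference base string (A/C/G/T).
#' @param cdna_start cDNA coordinate of the first base of `sequence`.
#' @param genomic_offset Constant such that `genomic = cdna + genomic_offset`
#'   for every base of this amplicon.
#' @param target_window Length-2 integer vector, cDNA interval (inclusive)
#'   of positions scored for errors/mutations.
#' @return An object of class `amplicon_ref`.
#' @export
amplicon_reference <- function(amplicon_id, exon, sequence, cdna_start,
                               genomic_offset, target_window) {
  sequence <- toupper(as.character(sequence))
  stopifnot(nchar(sequence) > 0L,
            grepl("^[ACGT]+$", sequence),
            length(target_window) == 2L,
            target_window[1] <= target_window[2])
  cdna_end <- cdna_start + nchar(sequence) - 1L
  if (target_window[1] < cdna_start || target_window[2] > cdna_end)
    stop("target_window must lie within the amplicon sequence", call. = FALSE)
  structure(
    list(amplicon_id = amplicon_id,
         exon = exon,
         sequence = sequence,
         cdna_start = as.integer(cdna_start),
         cdna_end = as.integer(cdna_end),
         genomic_offset = as.integer(genomic_offset),
         target_window = as.integer(target_window)),
    class = "amplicon_ref")
}

#' @export
print.amplicon_ref <- function(x, ...) {
  cat(sprintf("<amplicon_ref> %s (exon %s), %d bp, cDNA %d-%d, window %d-%d\n",
              x$amplicon_id, x$exon, nchar(x$sequence), x$cdna_start,
              x$cdna_end, x$target_window[1], x$target_window[2]))
  invisible(x)
}

#' Reference base at a cDNA position
#' @param amp An `amplicon_ref`.
#' @param position cDNA position(s) inside the amplicon.
#' @return Character vector of reference bases.
#' @export
ref_base_at <- function(amp, position) {
  i <- position - amp$cdna_start + 1L
  if (any(i < 1L | i > nchar(amp$sequence)))
    stop("position outside amplicon", call. = FALSE)
  substring(amp$sequence, i, i)
}

#' Synthetic EGFR target-region amplicon set
#'
#' Three amplicons covering a 169-base scoring window across EGFR exons
#' 19, 20 and 21, the region interrogated for the exon 19 deletion,
#' T790M (c.2369C>T), L858R (c.2573T>G) and L861Q (c.2582T>A). The
#' coordinate maps (cDNA and GRCh37 chr7) and the reference bases at the
#' modeled loci -- including the G at c.2361, the site of a frequent
#' synonymous SNP excluded from error modeling -- are the real ones; the
#' remaining sequence is synthetic filler so the package ships no
#' licensed reference data. All alignment, counting and calling logic is
#' exercised identically on a user-supplied real reference.
#'
#' @return Named list of three `amplicon_ref` objects
#'   (`exon19`, `exon20`, `exon21`); windows of 55 + 57 + 57 = 169 bases.
#' @export
egfr_amplicons <- function() {
  list(
    exon19 = amplicon_reference(
      "exon19", 19,
      paste0("ACCTGAGAACCGGTCCCAGCTACTCATGATCTACTTTACTGTGGTTATTACAATT",
             "ATGACCTTCAGTACCAGTTATCGCACCTTGGTTCCCCGAGCTAAGAGTCTCTCCTAACCT"),
      cdna_start = 2185L, genomic_offset = 55240230L,
      target_window = c(2215L, 2269L)),
    exon20 = amplicon_reference(
      "exon20", 20,
      paste0("AAACGAGCAGCACAGGGTTAGTCAATCGGCACCGCGTATACTGGAACCTTGGTGTGTCT",
             "CCCTCTCAACTTGACCAGCATATGAGCGTTTTAACGAAGAATCTCCAGAGGGCTCATC"),
      cdna_start = 2310L, genomic_offset = 55246702L,
      target_window = c(2340L, 2396L)),
    exon21 = amplicon_reference(
      "exon21", 21,
      paste0("ACCTGGTGAGAACCCACTACCGGAAAGATGAATAATTGATCCGCAGCAACTTTTTAATT",
             "AAGCGCACTCCCTTAATGGCCACGCCTGGCTCCCGTAAAGCGTGTCTGGCCCGCATGG"),
      cdna_start = 2515L, genomic_offset = 55256942L,
      target_window = c(2545L, 2601L))
  )
}

#' Target locus definitions
#'
#' The four loci called by default: the exon 19 deletion (screened by
#' template matching) and the three point mutations. Substitutions carry
#' their cDNA position and ref/alt bases.
#'
#' @return data.frame with columns locus, amplicon, kind, position, ref, alt.
#' @export
target_loci <- function() {
  data.frame(
    locus    = c("exon19del", "T790M", "L858R", "L861Q"),
    amplicon = c("exon19", "exon20", "exon21", "exon21"),
    kind     = c("deletion", "substitution", "substitution", "substitution"),
    position = c(NA_integer_, 2369L, 2573L, 2582L),
    ref      = c(NA_character_, "C", "T", "T"),
    alt      = c(NA_character_, "T", "G", "A"),
    stringsAsFactors = FALSE)
}

# The eight representative exon 19 deletion intervals (cDNA, 1-based
# inclusive). Genomic GRCh37 chr7 intervals follow from the exon 19
# coordinate map (+55240230).
DELETION_INTERVALS <- data.frame(
  cdna_start = c(2233L, 2235L, 2235L, 2236L, 2236L, 2238L, 2239L, 2239L),
  cdna_end   = c(2247L, 2246L, 2249L, 2250L, 2256L, 2252L, 2247L, 2256L))

#' Exon 19 deletion templates
#'
#' Builds the eight template sequences used to screen exon 19 deletion
#' reads: each is the intact exon 19 amplicon with one representative
#' deletion interval removed. Reads are later assigned to the
#' best-scoring sequence among the intact reference and these templates,
#' which screens out scattered indel read errors that never match a
#' template over its full deleted span.
#'
#' @param amp The exon 19 `amplicon_ref` (default from [egfr_amplicons()]).
#' @return data.frame with columns template_id, cdna_start, cdna_end,
#'   genomic_start, genomic_end, length, sequence.
#' @export
deletion_templates <- function(amp = egfr_amplicons()$exon19) {
  iv <- DELETION_INTERVALS
  if (any(iv$cdna_start < amp$cdna_start | iv$cdna_end > amp$cdna_end))
    stop("deletion intervals outside the exon 19 amplicon", call. = FALSE)
  seqs <- vapply(seq_len(nrow(iv)), function(i) {
    a <- iv$cdna_start[i] - amp$cdna_start + 1L
    b <- iv$cdna_end[i]   - amp$cdna_start + 1L
    paste0(substr(amp$sequence, 1L, a - 1L),
           substr(amp$sequence, b + 1L, nchar(amp$sequence)))
  }, character(1))
  data.frame(
    template_id   = sprintf("del%d-%d", iv$cdna_start, iv$cdna_end),
    cdna_start    = iv$cdna_start,
    cdna_end      = iv$cdna_end,
    genomic_start = iv$cdna_start + amp$genomic_offset,
    genomic_end   = iv$cdna_end + amp$genomic_offset,
    length        = iv$cdna_end - iv$cdna_start + 1L,
    sequence      = seqs,
    stringsAsFactors = FALSE)
}

#' Enumerate substitution types over the target windows
#'
#' Every scored position contributes exactly three substitution types
#' (conversion of the reference base to each of the other three bases);
#' a 169-base window therefore yields 507 types. One pooled indel
#' pseudo-type per position (alt `"*"`) can be appended for modeling
#' insertion/deletion error rates, which are tallied without
#' distinguishing insertions from deletions.
#'
#' @param amplicons List of `amplicon_ref` objects.
#' @param indels Append one indel pseudo-type per position?
#' @return data.frame with columns amplicon, position (cDNA), ref, alt.
#' @export
substitution_types <- function(amplicons = egfr_amplicons(), indels = FALSE) {
  bases <- c("A", "C", "G", "T")
  out <- lapply(amplicons, function(amp) {
    pos <- seq.int(amp$target_window[1], amp$target_window[2])
    ref <- ref_base_at(amp, pos)
    alt <- lapply(ref, function(r) setdiff(bases, r))
    d <- data.frame(amplicon = amp$amplicon_id,
                    position = rep(pos, each = 3L),
                    ref = rep(ref, each = 3L),
                    alt = unlist(alt),
                    stringsAsFactors = FALSE)
    if (indels)
      d <- rbind(d, data.frame(amplicon = amp$amplicon_id, position = pos,
                               ref = ref, alt = "*", stringsAsFactors = FALSE))
    d
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Key for a substitution type
#'
#' Canonical string identifier `amplicon:position:ref>alt` used to index
#' fitted models and panel rows.
#' @param amplicon,position,ref,alt Vectors describing the types.
#' @return Character vector of keys.
#' @export
type_key <- function(amplicon, position, ref, alt) {
  sprintf("%s:%d:%s>%s", amplicon, as.integer(position), ref, alt)
}

#' Export target windows as BED
#'
#' Writes the scored windows as a BED file on GRCh37 chr7 coordinates
#' (BED is 0-based half-open; conversion happens here).
#' @param amplicons List of `amplicon_ref`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_target_bed <- function(amplicons, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = "chr7",
    ranges = IRanges::IRanges(
      start = vapply(amplicons, function(a) a$target_window[1] + a$genomic_offset, 0),
      end   = vapply(amplicons, function(a) a$target_window[2] + a$genomic_offset, 0)),
    name = vapply(amplicons, function(a) a$amplicon_id, ""))
  rtracklayer::export.bed(gr, path)
  invisible(path)
}
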