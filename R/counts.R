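# From raw reads to per-position base counts and exon 19 deletion
# template assignments for one sample.
#
# Reads are single-end amplicon reads carrying a 5-nt sample index at
# their 5' end. After demultiplexing and a length filter, each read is
# aligned glocally (read global, reference local) to its amplicon;
# identical reads are collapsed before alignment, which makes deep
# amplicon data cheap to process. Alignment is delegated to
# Biostrings::pairwiseAlignment with affine gap scoring.

ALIGN_MATCH <- 1
ALIGN_MISMATCH <- -3
ALIGN_GAP_OPEN <- 5
ALIGN_GAP_EXTEND <- 2
MIN_SCORE_FRAC <- 0.3

# match +1 / mismatch -3; any pairing involving N scores 0, so ambiguity
# bases neither support nor veto an alignment and are later excluded
# from pileup depth.
align_submat <- function() {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(ALIGN_MISMATCH, 5, 5, dimnames = list(b, b))
  diag(m) <- ALIGN_MATCH
  m["N", ] <- m[, "N"] <- 0
  m
}

#' Read amplicon reads from FASTQ
#'
#' @param path FASTQ path (uncompressed or gzip).
#' @return Named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  stats::setNames(as.character(x), names(x))
}

#' Demultiplex reads by 5-nt inline index
#'
#' A read is assigned to a sample iff its first five bases exactly match
#' one of the index table's keys; the index prefix is stripped before
#' alignment. Unmatched reads are discarded (counted). The result does
#' not depend on the order of the input reads beyond preserving it
#' within each sample.
#'
#' @param reads Character vector of read sequences.
#' @param index_table Named character vector: names are distinct 5-mers,
#'   values are sample identifiers.
#' @return List with `samples` (named list of stripped read vectors, one
#'   per sample in the table, possibly empty) and `discarded` (count).
#' @export
demultiplex <- function(reads, index_table) {
  idx <- names(index_table)
  if (is.null(idx) || any(nchar(idx) != 5L))
    stop("index table keys must be 5-mers", call. = FALSE)
  if (anyDuplicated(idx))
    stop("duplicate index in table", call. = FALSE)
  out <- lapply(stats::setNames(nm = unique(unname(index_table))),
                function(s) character(0))
  if (length(reads)) {
    prefix <- substr(reads, 1L, 5L)
    hit <- match(prefix, idx)
    keep <- !is.na(hit)
    stripped <- substring(reads[keep], 6L)
    by_sample <- split(stripped, index_table[hit[keep]])
    out[names(by_sample)] <- by_sample
    discarded <- sum(!keep)
  } else discarded <- 0L
  list(samples = out, discarded = discarded)
}

#' Discard short reads
#'
#' Reads shorter than `min_length` bases (after index stripping) are
#' dropped; input order is preserved.
#'
#' @param reads Character vector of read sequences.
#' @param min_length Minimum retained length (default 70).
#' @return The retained reads.
#' @export
filter_short <- function(reads, min_length = 70L) {
  reads[nchar(reads) >= min_length]
}

#' Align reads to an amplicon reference
#'
#' Glocal alignment (read global, reference local) with affine gaps
#' (match +1, mismatch -3, gap open 5, gap extend 2), computed by
#' Biostrings::pairwiseAlignment. Identical reads are collapsed and
#' aligned once. Reads whose score falls below `min_score_frac` times
#' their length are marked unaligned; for those, the reverse complement
#' is tried and used if it clears the floor (logged in the result).
#'
#' @param reads Character vector of read sequences.
#' @param amp An `amplicon_ref`.
#' @param min_score_frac Score floor as a fraction of read length.
#' @return data.frame of class `amplicon_alignments`: one row per unique
#'   read with columns read, weight, aligned, start (1-based position in
#'   the amplicon), pattern (gapped read), subject (gapped reference),
#'   score, rc. Attribute `amplicon_id` records the reference.
#' @export
align_reads <- function(reads, amp, min_score_frac = MIN_SCORE_FRAC) {
  stopifnot(inherits(amp, "amplicon_ref"))
  tab <- table(reads)
  uniq <- names(tab)
  n <- length(uniq)
  res <- data.frame(read = uniq, weight = as.integer(tab),
                    aligned = logical(n), start = rep(NA_integer_, n),
                    pattern = rep(NA_character_, n),
                    subject = rep(NA_character_, n),
                    score = rep(NA_real_, n), rc = logical(n),
                    stringsAsFactors = FALSE)
  if (length(uniq)) {
    a <- glocal_align(uniq, amp$sequence)
    floor_score <- min_score_frac * nchar(uniq)
    ok <- a$score >= floor_score
    if (any(!ok)) {
      rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAStringSet(uniq[!ok])))
      a2 <- glocal_align(rc, amp$sequence)
      better <- a2$score >= floor_score[!ok] & a2$score > a$score[!ok]
      if (any(better)) {
        i <- which(!ok)[better]
        a$score[i] <- a2$score[better]
        a$start[i] <- a2$start[better]
        a$pattern[i] <- a2$pattern[better]
        a$subject[i] <- a2$subject[better]
        res$rc[i] <- TRUE
        ok[i] <- TRUE
      }
    }
    res$aligned <- ok
    res$start[ok] <- a$start[ok]
    res$pattern[ok] <- a$pattern[ok]
    res$subject[ok] <- a$subject[ok]
    res$score <- a$score
  }
  structure(res, amplicon_id = amp$amplicon_id,
            class = c("amplicon_alignments", "data.frame"))
}

glocal_align <- function(patterns, subject) {
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(patterns), Biostrings::DNAString(subject),
    type = "global-local", substitutionMatrix = align_submat(),
    gapOpening = ALIGN_GAP_OPEN, gapExtension = ALIGN_GAP_EXTEND)
  list(score = Biostrings::score(pa),
       start = BiocGenerics::start(Biostrings::subject(pa)),
       pattern = as.character(Biostrings::alignedPattern(pa)),
       subject = as.character(Biostrings::alignedSubject(pa)))
}

#' Align one read
#'
#' Convenience wrapper around [align_reads()] for a single read.
#' @param read One read sequence.
#' @inheritParams align_reads
#' @return One-row `amplicon_alignments`.
#' @export
align_read <- function(read, amp, min_score_frac = MIN_SCORE_FRAC) {
  align_reads(read, amp, min_score_frac)
}

#' Build per-position base counts from alignments
#'
#' Tallies A/C/G/T, deletion and insertion events at every amplicon
#' position covered by the aligned reads. Bases aligned as N are
#' excluded from all counts including depth. Insertions are attached to
#' the reference base they follow. `depth` is the number of scored
#' events per position (A + C + G + T + del); the pooled `indel` count
#' (del + ins) is what enters indel error-rate summaries, which do not
#' distinguish insertions from deletions.
#'
#' @param alignments An `amplicon_alignments` object.
#' @param amp The matching `amplicon_ref`.
#' @return data.frame of class `pileup`: position (cDNA), ref, A, C, G,
#'   T, del, ins, depth, in_window.
#' @export
build_pileup <- function(alignments, amp) {
  stopifnot(inherits(alignments, "amplicon_alignments"))
  if (!identical(attr(alignments, "amplicon_id"), amp$amplicon_id))
    stop("alignments were computed against a different amplicon", call. = FALSE)
  L <- nchar(amp$sequence)
  counts <- matrix(0, nrow = L, ncol = 6,
                   dimnames = list(NULL, c("A", "C", "G", "T", "del", "ins")))
  al <- alignments[alignments$aligned, , drop = FALSE]
  for (i in seq_len(nrow(al))) {
    w <- al$weight[i]
    p <- strsplit(al$pattern[i], "")[[1]]
    s <- strsplit(al$subject[i], "")[[1]]
    pos <- al$start[i] - 1L
    for (j in seq_along(p)) {
      if (s[j] == "-") {                       # insertion in the read
        counts[max(pos, 1L), "ins"] <- counts[max(pos, 1L), "ins"] + w
      } else {
        pos <- pos + 1L
        if (p[j] == "-") {
          counts[pos, "del"] <- counts[pos, "del"] + w
        } else if (p[j] %in% c("A", "C", "G", "T")) {
          counts[pos, p[j]] <- counts[pos, p[j]] + w
        }                                       # N: excluded entirely
      }
    }
  }
  position <- seq.int(amp$cdna_start, amp$cdna_end)
  out <- data.frame(position = position,
                    ref = ref_base_at(amp, position),
                    counts,
                    stringsAsFactors = FALSE)
  out$depth <- out$A + out$C + out$G + out$T + out$del
  out$indel <- out$del + out$ins
  out$in_window <- position >= amp$target_window[1] &
    position <= amp$target_window[2]
  structure(out, amplicon_id = amp$amplicon_id,
            n_reads = sum(al$weight),
            class = c("pileup", "data.frame"))
}

#' Substitution rate at a position
#'
#' Fraction of scored bases at the type's position that show the
#' alternate base: `count(alt) / depth`.
#'
#' @param pileup A `pileup`.
#' @param type One-row data.frame (or list) with position, ref, alt.
#' @return The observed fraction.
#' @export
substitution_rate <- function(pileup, type) {
  i <- match(type$position, pileup$position)
  if (is.na(i)) stop("position not covered by pileup", call. = FALSE)
  if (pileup$depth[i] == 0)
    stop("undefined rate: zero depth at position ", type$position,
         call. = FALSE)
  pileup[[type$alt]][i] / pileup$depth[i]
}

#' Screen reads against exon 19 deletion templates
#'
#' Each read is assigned to the best-scoring sequence among the intact
#' exon 19 reference and the eight deletion templates (exact sequence
#' matches shortcut the alignment). A scattered indel read error rarely
#' beats the intact reference over a full template's deleted span, so
#' this screen suppresses the high indel error rate of the platform.
#' Ties between intact and a template go to the intact reference; ties
#' among templates go to the first (smallest) template id. The chosen
#' template is the one with the maximum read count.
#'
#' @param reads Character vector of (index-stripped) reads.
#' @param amp The intact exon 19 `amplicon_ref`.
#' @param templates data.frame from [deletion_templates()].
#' @param min_score_frac Score floor as fraction of read length.
#' @return List of class `deletion_screen`: `template_counts` (named
#'   integer), `intact_count`, `unassigned`, `chosen_template` (id or
#'   NA), `chosen_count`, `exon19_total` (all assigned reads, with or
#'   without a deletion).
#' @export
match_deletion_templates <- function(reads, amp,
                                     templates = deletion_templates(amp),
                                     min_score_frac = MIN_SCORE_FRAC) {
  stopifnot(nrow(templates) > 0)
  refs <- c(intact = amp$sequence,
            stats::setNames(templates$sequence, templates$template_id))
  tab <- table(reads)
  uniq <- names(tab)
  w <- as.integer(tab)
  assign <- integer(length(uniq))            # 0 = unassigned, else index in refs
  if (length(uniq)) {
    # fast path: reads that are exact substrings of one reference
    pending <- rep(TRUE, length(uniq))
    for (k in seq_along(refs)) {
      hit <- pending & vapply(uniq, function(r) {
        nchar(r) <= nchar(refs[k]) && grepl(r, refs[k], fixed = TRUE)
      }, logical(1))
      # exact hits on the intact sequence win outright; an exact hit on a
      # template is only provisional when the read could also sit in the
      # intact sequence (checked because intact comes first)
      assign[hit] <- k
      pending[hit] <- FALSE
    }
    if (any(pending)) {
      scores <- vapply(seq_along(refs), function(k) {
        glocal_align(uniq[pending], refs[[k]])$score
      }, numeric(sum(pending)))
      scores <- matrix(scores, ncol = length(refs))
      best <- apply(scores, 1L, which.max)   # ties -> lowest index: intact,
      floor_score <- min_score_frac * nchar(uniq[pending])   # then template order
      best[scores[cbind(seq_len(nrow(scores)), best)] < floor_score] <- 0L
      assign[pending] <- best
    }
  }
  counts <- vapply(seq_along(refs), function(k) sum(w[assign == k]), integer(1))
  names(counts) <- names(refs)
  template_counts <- counts[-1L]
  chosen <- if (any(template_counts > 0)) which.max(template_counts) else NA
  structure(
    list(template_counts = template_counts,
         intact_count = counts[[1L]],
         unassigned = sum(w[assign == 0L]),
         chosen_template = if (is.na(chosen[1])) NA_character_
                           else names(template_counts)[chosen],
         chosen_count = if (is.na(chosen[1])) 0L
                        else as.integer(template_counts[chosen]),
         exon19_total = as.integer(sum(counts))),
    class = "deletion_screen")
}

#' @export
print.deletion_screen <- function(x, ...) {
  cat(sprintf("<deletion_screen> %d exon 19 reads: intact %d, deletion %d, unassigned %d\n",
              x$exon19_total + x$unassigned, x$intact_count,
              sum(x$template_counts), x$unassigned))
  if (!is.na(x$chosen_template))
    cat(sprintf("  chosen template: %s (%d reads)\n",
                x$chosen_template, x$chosen_count))
  invisible(x)
}

#' Deletion mutant fraction
#'
#' Fraction of exon 19 reads carrying the deletion: reads of the chosen
#' (maximum-count) template divided by all reads assigned to exon 19
#' sequences with or without a deletion. `numerator = "all"` instead
#' sums reads over every template.
#'
#' @param screen A `deletion_screen`.
#' @param numerator `"chosen"` (default) or `"all"`.
#' @return Fraction in `[0, 1]`.
#' @export
deletion_fraction <- function(screen, numerator = c("chosen", "all")) {
  numerator <- match.arg(numerator)
  if (screen$exon19_total == 0)
    stop("undefined rate: no reads aligned to exon 19 sequences", call. = FALSE)
  num <- if (numerator == "chosen") screen$chosen_count
         else sum(screen$template_counts)
  num / screen$exon19_total
}

# ---- SAM interoperability ----------------------------------------------

#' Write alignments as SAM
#'
#' Emits a SAM file (with @SQ header lines naming the amplicons) so that
#' externally produced alignments and this package's internal aligner
#' can be compared on equal footing.
#'
#' @param alignments An `amplicon_alignments` object.
#' @param amp The matching `amplicon_ref`.
#' @param path Output path.
#' @return Invisibly, the path.
#' @export
write_sam <- function(alignments, amp, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("@HD\tVN:1.6\tSO:unknown",
               sprintf("@SQ\tSN:%s\tLN:%d", amp$amplicon_id,
                       nchar(amp$sequence))), con)
  al <- alignments[alignments$aligned, , drop = FALSE]
  n <- 0L
  for (i in seq_len(nrow(al))) {
    cigar <- cigar_from_gapped(al$pattern[i], al$subject[i])
    for (k in seq_len(al$weight[i])) {
      n <- n + 1L
      writeLines(sprintf("r%06d\t0\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
                         n, amp$amplicon_id, al$start[i], cigar,
                         gsub("-", "", al$pattern[i])), con)
    }
  }
  invisible(path)
}

cigar_from_gapped <- function(pattern, subject) {
  p <- strsplit(pattern, "")[[1]]
  s <- strsplit(subject, "")[[1]]
  op <- ifelse(p == "-", "D", ifelse(s == "-", "I", "M"))
  r <- rle(op)
  paste0(r$lengths, r$values, collapse = "")
}

#' Import alignments from SAM
#'
#' Reads a SAM file (via Rsamtools) and converts its records to the same
#' alignment representation produced by [align_reads()], so pileups can
#' be built from externally aligned data. Records mapped to a reference
#' name other than the given amplicon raise an error.
#'
#' @param path SAM file path.
#' @param amp The `amplicon_ref` the records should refer to.
#' @return An `amplicon_alignments` object.
#' @export
import_sam <- function(path, amp) {
  bam <- Rsamtools::asBam(path,
                          destination = tempfile(fileext = ""),
                          overwrite = TRUE, indexDestination = FALSE)
  rec <- Rsamtools::scanBam(
    bam, param = Rsamtools::ScanBamParam(
      what = c("qname", "rname", "pos", "cigar", "seq")))[[1]]
  keep <- !is.na(rec$pos)
  rname <- as.character(rec$rname[keep])
  if (length(rname) && any(rname != amp$amplicon_id))
    stop("SAM records reference unknown amplicon: ",
         paste(unique(setdiff(rname, amp$amplicon_id)), collapse = ", "),
         call. = FALSE)
  seqs <- as.character(rec$seq[keep])
  pos <- rec$pos[keep]
  cig <- rec$cigar[keep]
  n <- length(seqs)
  pat <- sub <- character(n)
  if (n) {
    ops <- GenomicAlignments::explodeCigarOps(cig)
    lens <- GenomicAlignments::explodeCigarOpLengths(cig)
    for (i in seq_len(n)) {
      g <- gapped_from_cigar(seqs[i], amp$sequence, pos[i], ops[[i]], lens[[i]])
      pat[i] <- g$pattern; sub[i] <- g$subject
    }
  }
  key <- paste(seqs, pos, cig)
  first <- !duplicated(key)
  nk <- sum(first)
  res <- data.frame(read = seqs[first],
                    weight = if (nk) as.integer(table(key)[key[first]])
                             else integer(0),
                    aligned = rep(TRUE, nk), start = pos[first],
                    pattern = pat[first], subject = sub[first],
                    score = rep(NA_real_, nk), rc = logical(nk),
                    stringsAsFactors = FALSE)
  structure(res, amplicon_id = amp$amplicon_id,
            class = c("amplicon_alignments", "data.frame"))
}

gapped_from_cigar <- function(seq, refseq, pos, ops, lens) {
  p <- character(0); s <- character(0)
  qi <- 1L; ri <- pos
  for (k in seq_along(ops)) {
    len <- lens[k]
    switch(ops[k],
           M = , `=` = , X = {
             p <- c(p, substr(seq, qi, qi + len - 1L))
             s <- c(s, substr(refseq, ri, ri + len - 1L))
             qi <- qi + len; ri <- ri + len
           },
           I = {
             p <- c(p, substr(seq, qi, qi + len - 1L))
             s <- c(s, strrep("-", len))
             qi <- qi + len
           },
           D = , N = {
             p <- c(p, strrep("-", len))
             s <- c(s, substr(refseq, ri, ri + len - 1L))
             ri <- ri + len
           },
           S = { qi <- qi + len },
           H = NULL,
           stop("unsupported CIGAR op: ", ops[k], call. = FALSE))
  }
  list(pattern = paste(p, collapse = ""), subject = paste(s, collapse = ""))
}
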