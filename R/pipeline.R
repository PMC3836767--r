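# End-to-end processing of one sample's reads: amplicon assignment,
# exon 19 template screen, pileups, target calls, whole-region scan.

#' Process one sample's reads into a report
#'
#' The computational half of the assay: reads (already demultiplexed)
#' are length-filtered, assigned to the best-scoring amplicon, and piled
#' up; exon 19 reads additionally pass the deletion-template screen.
#' Target loci are then called against their fitted models and the
#' remaining modeled substitution types are scanned.
#'
#' @param reads Character vector of index-stripped reads.
#' @param model_set An `error_model_set`.
#' @param amplicons Amplicon set (default [egfr_amplicons()]).
#' @param sample_id Sample identifier.
#' @param min_length Length filter (default 70).
#' @param scan Run the whole-region scan?
#' @return A `sample_report`.
#' @export
process_sample <- function(reads, model_set, amplicons = egfr_amplicons(),
                           sample_id = "sample", min_length = 70L,
                           scan = TRUE) {
  reads <- filter_short(reads, min_length)
  # assign each unique read to its best-scoring amplicon
  tab <- table(reads)
  uniq <- names(tab)
  scores <- vapply(amplicons,
                   function(amp) glocal_align(uniq, amp$sequence)$score,
                   numeric(length(uniq)))
  scores <- matrix(scores, ncol = length(amplicons),
                   dimnames = list(NULL, names(amplicons)))
  best <- names(amplicons)[apply(scores, 1L, which.max)]
  by_amp <- lapply(stats::setNames(nm = names(amplicons)), function(a) {
    rep(uniq[best == a], times = tab[best == a])
  })

  pileups <- list()
  for (a in names(amplicons)) {
    al <- align_reads(by_amp[[a]], amplicons[[a]])
    pileups[[a]] <- build_pileup(al, amplicons[[a]])
  }
  screen <- match_deletion_templates(by_amp$exon19, amplicons$exon19)

  loci <- target_loci()
  calls <- list()
  for (i in seq_len(nrow(loci))) {
    row <- as.list(loci[i, ])
    if (row$kind == "deletion") {
      model <- exon19del_model(model_set)
      calls[[row$locus]] <- if (screen$exon19_total > 0)
        call_exon19_deletion(screen, model)
      else uncovered_call(row, model)
    } else {
      key <- type_key(row$amplicon, row$position, row$ref, row$alt)
      model <- model_set$models[[key]]
      if (is.null(model))
        stop("no fitted model for target locus ", row$locus, call. = FALSE)
      pu <- pileups[[row$amplicon]]
      calls[[row$locus]] <- if (pu$depth[match(row$position, pu$position)] > 0)
        call_substitution(pu, model, row)
      else uncovered_call(row, model)
    }
  }
  calls <- do.call(rbind, calls)
  scan_out <- NULL
  if (scan) {
    scan_out <- do.call(rbind, lapply(pileups, scan_region,
                                      model_set = model_set))
    rownames(scan_out) <- NULL
  }
  sample_report(sample_id, calls, scan_out, model_set)
}

# placeholder row for a target locus with no read coverage, so every
# target appears exactly once in the report
uncovered_call <- function(row, model) {
  data.frame(locus = row$locus, amplicon = row$amplicon,
             position = if (is.na(row$position)) NA_integer_ else row$position,
             ref = row$ref, alt = row$alt,
             count = NA_integer_, depth = 0L,
             events_per_100k = NA_real_, threshold = model$threshold,
             tail_prob = NA_real_, called = FALSE,
             fraction_percent = NA_real_, below_quantitation = NA,
             stringsAsFactors = FALSE)
}
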