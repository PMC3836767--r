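# Applying fitted error models to one sample's counts: target-locus
# calls, whole-region scanning, quantitation, and temporal reports.
#
# The decision rule is uniform: a base change is judged a mutation when
# its events per 100,000 reads (a real number; no rounding before the
# comparison) reach the integer threshold of its fitted null model.
# Alongside the binary call, the realized upper-tail probability
# P(X >= observed) is reported so the per-test size at the threshold is
# visible.

QUANTITATION_LIMIT_PCT <- 0.3

new_mutation_call <- function(locus, amplicon, position, ref, alt,
                              count, depth, model) {
  ev <- normalize_to_per100k(count, depth)
  called <- ev >= model$threshold
  data.frame(
    locus = locus, amplicon = amplicon,
    position = if (is.null(position)) NA_integer_ else position,
    ref = if (is.null(ref)) NA_character_ else ref,
    alt = if (is.null(alt)) NA_character_ else alt,
    count = count, depth = depth,
    events_per_100k = ev,
    threshold = model$threshold,
    tail_prob = upper_tail_prob(model, ceiling(ev) - 1L),
    called = called,
    fraction_percent = 100 * count / depth,
    stringsAsFactors = FALSE)
}

#' Call a substitution mutation at one locus
#'
#' Looks up the alternate-base count at the type's position, converts it
#' to events per 100,000 reads, and compares against the type's fitted
#' threshold. `called` is TRUE iff the normalized events reach the
#' threshold, at any depth.
#'
#' @param pileup A `pileup` for the type's amplicon.
#' @param model The `error_model` fitted for this substitution type.
#' @param type One-row data.frame/list with locus (optional), amplicon,
#'   position, ref, alt.
#' @return One-row `mutation_call` data.frame (see [quantify()] for the
#'   quantitation flag).
#' @export
call_substitution <- function(pileup, model, type) {
  if (is.null(model)) stop("no fitted model for this substitution type",
                           call. = FALSE)
  i <- match(type$position, pileup$position)
  if (is.na(i)) stop("position not covered by pileup", call. = FALSE)
  depth <- pileup$depth[i]
  if (depth == 0) stop("zero depth at position ", type$position, call. = FALSE)
  quantify(new_mutation_call(
    locus = if (!is.null(type$locus)) type$locus
            else type_key(type$amplicon, type$position, type$ref, type$alt),
    amplicon = type$amplicon, position = type$position,
    ref = type$ref, alt = type$alt,
    count = pileup[[type$alt]][i], depth = depth, model = model))
}

#' Call the exon 19 deletion
#'
#' Events per 100,000 reads are computed from the chosen (maximum-count)
#' deletion template's reads over all exon-19-assigned reads; the call
#' compares them to the threshold of the deletion's fitted model (the
#' conservative Poisson floor in the default configuration, threshold
#' 7). The mutant fraction is the [deletion_fraction()].
#'
#' @param screen A `deletion_screen` from [match_deletion_templates()].
#' @param model The `error_model` for the exon 19 deletion.
#' @param numerator Passed to [deletion_fraction()].
#' @return One-row `mutation_call` data.frame.
#' @export
call_exon19_deletion <- function(screen, model,
                                 numerator = c("chosen", "all")) {
  numerator <- match.arg(numerator)
  if (screen$exon19_total == 0)
    stop("undefined rate: no reads aligned to exon 19 sequences", call. = FALSE)
  count <- if (numerator == "chosen") screen$chosen_count
           else sum(screen$template_counts)
  call <- new_mutation_call(
    locus = "exon19del", amplicon = "exon19",
    position = NULL, ref = NULL, alt = NULL,
    count = count, depth = screen$exon19_total, model = model)
  call$alt <- if (!is.na(screen$chosen_template)) screen$chosen_template
              else NA_character_
  quantify(call)
}

#' Flag calls below the quantitation limit
#'
#' The estimated fraction of a called mutation is reproducible only down
#' to about 0.3% of alleles; below that, the template-molecule
#' bottleneck (roughly 5,000 molecules per plasma assay, so 15 or fewer
#' mutant copies) makes replicate estimates unstable. Calls below the
#' limit remain calls; they are flagged as unreliable in magnitude.
#'
#' @param call A `mutation_call` data.frame (any number of rows).
#' @param limit_percent Quantitation limit (default 0.3).
#' @return The calls with a logical `below_quantitation` column
#'   (TRUE iff called and fraction < limit; NA when not called).
#' @export
quantify <- function(call, limit_percent = QUANTITATION_LIMIT_PCT) {
  call$below_quantitation <- ifelse(
    call$called, call$fraction_percent < limit_percent, NA)
  call
}

#' Scan every modeled substitution type in the target region
#'
#' Applies the fitted models across all positions of the pileup's
#' amplicon, excluding named target loci (they are called separately).
#' By default only called types are returned; `called_only = FALSE`
#' returns one row per modeled type. Per-sample and per-type summary
#' histograms can be computed directly from the full output.
#'
#' @param pileup A `pileup`.
#' @param model_set An `error_model_set` from [build_models()].
#' @param exclude data.frame of loci to exclude (default the named
#'   substitution targets from [target_loci()]).
#' @param called_only Return only called types?
#' @return `mutation_call` data.frame, zero or more rows.
#' @export
scan_region <- function(pileup, model_set,
                        exclude = target_loci(), called_only = TRUE) {
  amp_id <- attr(pileup, "amplicon_id")
  info <- model_set$types
  info <- info[info$amplicon == amp_id & info$alt %in% c("A", "C", "G", "T"), ,
               drop = FALSE]
  if (!is.null(exclude) && nrow(exclude)) {
    ex <- exclude[!is.na(exclude$position), , drop = FALSE]
    ex_keys <- type_key(ex$amplicon, ex$position, ex$ref, ex$alt)
    info <- info[!(type_key(info$amplicon, info$position, info$ref, info$alt)
                   %in% ex_keys), , drop = FALSE]
  }
  i <- match(info$position, pileup$position)
  depth <- pileup$depth[i]
  count <- mapply(function(row, alt) pileup[[alt]][row], i, info$alt)
  ok <- depth > 0
  info <- info[ok, , drop = FALSE]
  count <- count[ok]; depth <- depth[ok]
  keys <- type_key(info$amplicon, info$position, info$ref, info$alt)
  ev <- normalize_to_per100k(count, depth)
  thr <- info$threshold
  tailp <- vapply(seq_along(keys), function(j)
    upper_tail_prob(model_set$models[[keys[j]]], ceiling(ev[j]) - 1L),
    numeric(1))
  out <- data.frame(locus = keys, amplicon = info$amplicon,
                    position = info$position, ref = info$ref, alt = info$alt,
                    count = count, depth = depth,
                    events_per_100k = ev, threshold = thr,
                    tail_prob = tailp, called = ev >= thr,
                    fraction_percent = 100 * count / depth,
                    stringsAsFactors = FALSE)
  out <- quantify(out)
  rownames(out) <- NULL
  if (called_only) out[out$called, , drop = FALSE] else out
}

#' Assemble a per-sample report
#'
#' One row per target locus (each exactly once) plus the whole-region
#' scan, with depths and the model provenance hash.
#'
#' @param sample_id Sample identifier.
#' @param calls `mutation_call` rows for the target loci.
#' @param scan Scan output from [scan_region()] (optional).
#' @param model_set The `error_model_set` used.
#' @return List of class `sample_report`.
#' @export
sample_report <- function(sample_id, calls, scan = NULL, model_set = NULL) {
  if (anyDuplicated(calls$locus))
    stop("each target locus must appear exactly once", call. = FALSE)
  structure(list(sample_id = sample_id, calls = calls, scan = scan,
                 model_version = if (!is.null(model_set))
                   model_set_version(model_set) else NA_character_),
            class = "sample_report")
}

model_set_version <- function(model_set) {
  paste0("raremut-", as.character(utils::packageVersion("raremut")), "-",
         substr(rlang::hash(model_set$types), 1, 8))
}

#' @export
print.sample_report <- function(x, ...) {
  cat(sprintf("<sample_report> %s (models %s)\n", x$sample_id,
              x$model_version))
  print(x$calls[, c("locus", "count", "depth", "events_per_100k",
                    "threshold", "called", "fraction_percent")])
  if (!is.null(x$scan) && nrow(x$scan))
    cat(sprintf("  scan: %d substitution type(s) called\n", sum(x$scan$called)))
  invisible(x)
}

#' Temporal series of called mutations
#'
#' Collects the called mutations of time-ordered sample reports for one
#' patient, scaled to events per 10,000 reads (the scale used for
#' longitudinal displays; all internal math stays per 100,000).
#' Timepoints with no calls are retained as empty entries so the
#' sampling course stays visible. Input order is preserved.
#'
#' @param reports List of `sample_report`, ordered by time.
#' @param patient_id Patient identifier.
#' @return data.frame of class `temporal_series`: patient, timepoint
#'   (1..n, input order), sample_id, locus, events_per_10k,
#'   fraction_percent; loci are NA for call-free timepoints.
#' @export
temporal_report <- function(reports, patient_id = "patient") {
  if (!length(reports)) stop("at least one timepoint is required", call. = FALSE)
  rows <- lapply(seq_along(reports), function(t) {
    rep <- reports[[t]]
    called <- rep$calls[rep$calls$called, , drop = FALSE]
    if (nrow(called) == 0)
      data.frame(patient = patient_id, timepoint = t,
                 sample_id = rep$sample_id, locus = NA_character_,
                 events_per_10k = NA_real_, fraction_percent = NA_real_,
                 stringsAsFactors = FALSE)
    else
      data.frame(patient = patient_id, timepoint = t,
                 sample_id = rep$sample_id, locus = called$locus,
                 events_per_10k = called$events_per_100k / 10,
                 fraction_percent = called$fraction_percent,
                 stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, class = c("temporal_series", "data.frame"))
}

#' Plot a temporal mutation series
#'
#' Longitudinal display of called mutation levels (events per 10,000
#' reads, log scale) across sampling timepoints, one line per locus.
#' Requires ggplot2.
#'
#' @param series A `temporal_series`.
#' @return A ggplot object.
#' @export
plot_temporal_series <- function(series) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
  d <- series[!is.na(series$locus), , drop = FALSE]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$timepoint,
                                  y = .data$events_per_10k,
                                  colour = .data$locus)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "sampling timepoint",
                  y = "mutant events per 10,000 reads",
                  colour = "mutation") +
    ggplot2::theme_minimal()
}
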