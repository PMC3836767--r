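# Standard-format I/O: panel TSV, fitted-model JSON, report TSV, VCF,
# temporal-series JSON, and run configuration (JSON or YAML).

#' Read a normal-panel count table
#'
#' Long-format TSV with columns amplicon, position, ref, alt, sample,
#' count, depth (one row per substitution type per sample). Malformed
#' rows are reported with their line number.
#'
#' @param path TSV path.
#' @param excluded_types Keys excluded from fitting.
#' @return An `error_panel`.
#' @export
read_panel_tsv <- function(path, excluded_types = default_excluded_types()) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("amplicon", "position", "ref", "alt", "sample", "count", "depth")
  if (!all(need %in% names(d)))
    stop("panel TSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  bad <- which(is.na(d$count) | is.na(d$depth) | d$count < 0 | d$depth <= 0)
  if (length(bad))
    stop("malformed panel TSV at line ", bad[1] + 1L,
         ": counts must be >= 0 and depths > 0", call. = FALSE)
  key <- type_key(d$amplicon, d$position, d$ref, d$alt)
  samples <- unique(d$sample)
  ukey <- unique(key)
  counts <- matrix(NA_integer_, length(ukey), length(samples),
                   dimnames = list(ukey, samples))
  depths <- counts
  counts[cbind(match(key, ukey), match(d$sample, samples))] <- d$count
  depths[cbind(match(key, ukey), match(d$sample, samples))] <- d$depth
  if (anyNA(counts))
    stop("panel TSV is not complete: every type needs a row for every sample",
         call. = FALSE)
  first <- !duplicated(key)
  types <- data.frame(amplicon = d$amplicon[first],
                      position = as.integer(d$position[first]),
                      ref = d$ref[first], alt = d$alt[first],
                      stringsAsFactors = FALSE)
  error_panel(types, counts, depths, samples = samples,
              excluded_types = excluded_types)
}

#' Write a normal-panel count table
#'
#' @param panel An `error_panel`.
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
write_panel_tsv <- function(panel, path) {
  stopifnot(inherits(panel, "error_panel"))
  n_types <- nrow(panel$types)
  n_samp <- length(panel$samples)
  d <- data.frame(amplicon = rep(panel$types$amplicon, n_samp),
                  position = rep(panel$types$position, n_samp),
                  ref = rep(panel$types$ref, n_samp),
                  alt = rep(panel$types$alt, n_samp),
                  sample = rep(panel$samples, each = n_types),
                  count = as.vector(panel$counts),
                  depth = as.vector(panel$depths))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export fitted models as JSON
#'
#' One record per fitted type: type key, model kind, parameters
#' (lambda, or r and p), alpha, threshold, realized per-test size, and
#' the panel moments.
#'
#' @param model_set An `error_model_set`.
#' @param path Output JSON path.
#' @return Invisibly, the path.
#' @export
write_models_json <- function(model_set, path) {
  recs <- lapply(names(model_set$models), function(key) {
    m <- model_set$models[[key]]
    list(type = key, kind = m$kind,
         lambda = m$lambda, r = m$r, p = m$p,
         alpha = m$alpha, threshold = m$threshold,
         realized_size = m$realized_size,
         mean = m$moments$mean, variance = m$moments$variance,
         ratio = m$moments$ratio)
  })
  jsonlite::write_json(
    list(version = model_set_version(model_set),
         alpha = model_set$alpha, ratio_cutoff = model_set$ratio_cutoff,
         denominator = model_set$denominator,
         excluded = as.list(model_set$excluded),
         category_counts = as.list(model_set$category_counts),
         models = recs),
    path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read fitted models from JSON
#'
#' Reconstructs an `error_model_set` written by [write_models_json()];
#' thresholds are recomputed from the stored parameters and must agree
#' with the stored values.
#'
#' @param path JSON path.
#' @return An `error_model_set`.
#' @export
read_models_json <- function(path) {
  j <- jsonlite::read_json(path)
  models <- list()
  rows <- list()
  for (rec in j$models) {
    ms <- structure(list(mean = rec$mean, variance = rec$variance,
                         ratio = if (is.null(rec$ratio)) NA_real_ else rec$ratio,
                         n = NA_integer_),
                    class = "moment_summary")
    m <- if (rec$kind == "negative_binomial")
      new_error_model("negative_binomial", r = as.integer(rec$r), p = rec$p,
                      alpha = rec$alpha, moments = ms)
    else
      new_error_model(rec$kind, lambda = as.integer(rec$lambda),
                      alpha = rec$alpha, moments = ms)
    if (m$threshold != rec$threshold)
      stop("stored threshold disagrees with recomputation for ", rec$type,
           call. = FALSE)
    models[[rec$type]] <- m
    key <- strsplit(rec$type, "[:>]")[[1]]
    rows[[rec$type]] <- data.frame(
      amplicon = key[1], position = as.integer(key[2]),
      ref = key[3], alt = key[4],
      mean = rec$mean, variance = rec$variance,
      ratio = if (is.null(rec$ratio)) NA_real_ else rec$ratio,
      kind = rec$kind, threshold = rec$threshold,
      stringsAsFactors = FALSE)
  }
  info <- do.call(rbind, rows)
  rownames(info) <- NULL
  counts <- table(factor(info$kind, levels = c("poisson_floor", "poisson",
                                               "negative_binomial")))
  structure(list(models = models, types = info,
                 excluded = unlist(j$excluded),
                 alpha = j$alpha, ratio_cutoff = j$ratio_cutoff,
                 denominator = j$denominator,
                 category_counts = counts),
            class = "error_model_set")
}

#' Write a sample report as TSV
#'
#' One row per locus (targets first, then any called scan types).
#'
#' @param report A `sample_report`.
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
write_report_tsv <- function(report, path) {
  d <- report$calls
  if (!is.null(report$scan) && nrow(report$scan))
    d <- rbind(d[, intersect(names(d), names(report$scan))],
               report$scan[, intersect(names(d), names(report$scan))])
  d <- cbind(sample = report$sample_id, d)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write called mutations as VCF
#'
#' Called substitutions and deletions on GRCh37 chr7 coordinates
#' (1-based in VCF; deletions use the base preceding the deleted
#' interval as the left anchor). Uses VariantAnnotation's writer.
#'
#' @param report A `sample_report`.
#' @param amplicons The amplicon set used for calling.
#' @param path Output VCF path.
#' @return Invisibly, the path.
#' @export
write_vcf_calls <- function(report, amplicons, path) {
  calls <- report$calls
  if (!is.null(report$scan) && nrow(report$scan)) {
    keep <- intersect(names(calls), names(report$scan))
    calls <- rbind(calls[, keep], report$scan[, keep])
  }
  calls <- calls[calls$called, , drop = FALSE]
  pos <- integer(0); end <- integer(0)
  ref <- character(0); alt <- character(0)
  dp <- integer(0); ad <- integer(0)
  for (i in seq_len(nrow(calls))) {
    row <- calls[i, ]
    if (row$locus == "exon19del" || is.na(row$position)) {
      amp <- amplicons$exon19
      tmpl <- deletion_templates(amp)
      tv <- tmpl[tmpl$template_id == row$alt, , drop = FALSE]
      if (nrow(tv) != 1L) next
      anchor_cdna <- tv$cdna_start - 1L
      anchor <- ref_base_at(amp, anchor_cdna)
      delseq <- substr(amp$sequence,
                       tv$cdna_start - amp$cdna_start + 1L,
                       tv$cdna_end - amp$cdna_start + 1L)
      pos <- c(pos, anchor_cdna + amp$genomic_offset)
      end <- c(end, tv$genomic_end)
      ref <- c(ref, paste0(anchor, delseq))
      alt <- c(alt, anchor)
    } else {
      amp <- amplicons[[row$amplicon]]
      pos <- c(pos, row$position + amp$genomic_offset)
      end <- c(end, row$position + amp$genomic_offset)
      ref <- c(ref, row$ref)
      alt <- c(alt, row$alt)
    }
    dp <- c(dp, row$depth)
    ad <- c(ad, row$count)
  }
  if (!length(pos)) {
    writeLines(c("##fileformat=VCFv4.1",
                 "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), path)
    return(invisible(path))
  }
  vr <- VariantAnnotation::VRanges(
    seqnames = "chr7",
    ranges = IRanges::IRanges(start = pos, end = end),
    ref = ref, alt = alt,
    sampleNames = report$sample_id,
    totalDepth = as.integer(dp), altDepth = as.integer(ad))
  VariantAnnotation::writeVcf(vr, path)
  invisible(path)
}

#' Write a temporal series as JSON
#'
#' @param series A `temporal_series`.
#' @param path Output JSON path.
#' @return Invisibly, the path.
#' @export
write_temporal_json <- function(series, path) {
  jsonlite::write_json(as.data.frame(series), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' Read a run configuration
#'
#' JSON or YAML (by file extension). Recognized keys: alpha,
#' ratio_cutoff, denominator, excluded_types, seed, plus file paths used
#' by the command-line entry points. Unknown keys are retained.
#'
#' @param path Config path (`.json`, `.yaml` or `.yml`).
#' @return Named list with defaults filled in.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  defaults <- list(alpha = DEFAULT_ALPHA, ratio_cutoff = RATIO_CUTOFF,
                   denominator = "n",
                   excluded_types = default_excluded_types(),
                   seed = 1L)
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  if (cfg$alpha <= 0 || cfg$alpha >= 1)
    stop("alpha must be in (0, 1)", call. = FALSE)
  cfg
}
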