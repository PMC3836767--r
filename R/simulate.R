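# Synthetic normal panels, assays, and reads with the statistical
# structure the caller assumes: position-specific error intensities with
# one dominant substitution pattern per position, gamma-distributed
# intensity fluctuation across samples (overdispersion), plasma-like
# read depths, and a template-molecule bottleneck ahead of sequencing.
#
# All randomness is drawn under the spec's seed through
# withr::with_seed, so identical specs give identical outputs without
# touching the caller's RNG state.

#' Specification of a simulated normal panel
#'
#' Defaults describe the study conditions the error models are meant
#' for: 48 normal samples, read depths log-uniform between 44,400 and
#' 373,000 (mean about 162,000), per-position error intensities with a
#' dominant alternate base carrying 80% of the position's error mass,
#' and gamma intensity fluctuation giving overdispersed types a
#' variance/mean ratio of about 3.
#'
#' @param n_samples Number of panel samples (>= 2).
#' @param amplicons Amplicon set defining the substitution types.
#' @param process Optional per-type generating process: data.frame with
#'   columns amplicon, position, ref, alt, mean (per-100k intensity) and
#'   shape (gamma shape of the intensity mixture; `Inf` = pure Poisson).
#'   When NULL a default process is drawn under the seed.
#' @param depth_range Read-depth range (log-uniform sampling).
#' @param dominant_share Error-mass share of the dominant alternate base.
#' @param meanlog,sdlog Log-normal parameters of the per-position total
#'   error intensity (events per 100,000 reads).
#' @param overdispersed_prob Probability a type's intensity fluctuates
#'   (gamma-mixed) rather than being fixed.
#' @param dispersion_ratio Target variance/mean ratio of overdispersed
#'   types (the gamma shape is `mean / (dispersion_ratio - 1)`).
#' @param seed Integer seed.
#' @return List of class `panel_spec`.
#' @export
panel_spec <- function(n_samples = 48L, amplicons = egfr_amplicons(),
                       process = NULL, depth_range = c(44400L, 373000L),
                       dominant_share = 0.8, meanlog = log(6), sdlog = 1.3,
                       overdispersed_prob = 0.95, dispersion_ratio = 3,
                       seed = 1L) {
  if (n_samples < 2L) stop("n_samples must be at least 2", call. = FALSE)
  stopifnot(depth_range[1] > 0, depth_range[2] >= depth_range[1],
            dominant_share > 0, dominant_share <= 1,
            dispersion_ratio > 1)
  structure(list(n_samples = as.integer(n_samples), amplicons = amplicons,
                 process = process, depth_range = depth_range,
                 dominant_share = dominant_share, meanlog = meanlog,
                 sdlog = sdlog, overdispersed_prob = overdispersed_prob,
                 dispersion_ratio = dispersion_ratio,
                 seed = as.integer(seed)),
            class = "panel_spec")
}

#' Default per-type error process
#'
#' Draws the generating process behind a panel: per position a total
#' error intensity from a log-normal, split so one (random) alternate
#' base dominates; each type is gamma-overdispersed with probability
#' `overdispersed_prob`. Deterministic for a fixed spec (derives its
#' RNG stream from `spec$seed`).
#'
#' @param spec A `panel_spec`.
#' @return data.frame with columns amplicon, position, ref, alt, mean,
#'   shape.
#' @export
default_panel_process <- function(spec) {
  types <- substitution_types(spec$amplicons)
  withr::with_seed(spec$seed + 1000L, {
    pos_key <- paste(types$amplicon, types$position)
    upos <- unique(pos_key)
    total <- stats::rlnorm(length(upos), spec$meanlog, spec$sdlog)
    dominant <- sample.int(3L, length(upos), replace = TRUE)
    i <- match(pos_key, upos)
    rank_in_pos <- stats::ave(seq_len(nrow(types)), pos_key,
                              FUN = seq_along)
    share <- ifelse(rank_in_pos == dominant[i],
                    spec$dominant_share,
                    (1 - spec$dominant_share) / 2)
    types$mean <- total[i] * share
    od <- stats::runif(nrow(types)) < spec$overdispersed_prob
    types$shape <- ifelse(od, types$mean / (spec$dispersion_ratio - 1), Inf)
  })
  # the named target loci mirror their reported error regimes: the
  # activating-mutation sites are quiet (sub-1-per-100k, the Poisson
  # floor), L861Q sits in the plain-Poisson band, and T790M is a
  # high-error overdispersed position
  pin <- function(d, amplicon, position, alt, mean, shape) {
    i <- d$amplicon == amplicon & d$position == position & d$alt == alt
    d$mean[i] <- mean; d$shape[i] <- shape
    d
  }
  types <- pin(types, "exon21", 2573L, "G", 0.2, Inf)        # L858R site
  types <- pin(types, "exon21", 2582L, "A", 2.5, Inf)        # L861Q site
  types <- pin(types, "exon20", 2369L, "T", 20,
               20 / (spec$dispersion_ratio - 1))             # T790M site
  types
}

sample_depths <- function(n, depth_range) {
  as.integer(round(exp(stats::runif(n, log(depth_range[1]),
                                    log(depth_range[2])))))
}

#' Simulate a normal panel
#'
#' For each substitution type and sample: draw the intensity (fixed, or
#' gamma with the type's shape and mean), then a Poisson count at the
#' sample's depth, and record the per-100k rate. Identical spec and seed
#' give identical panels.
#'
#' @param spec A `panel_spec`.
#' @return An `error_panel` (see [error_panel()]); the generating
#'   process is attached as attribute `"process"` for
#'   parameter-recovery checks.
#' @export
simulate_normal_panel <- function(spec) {
  stopifnot(inherits(spec, "panel_spec"))
  process <- if (is.null(spec$process)) default_panel_process(spec)
             else spec$process
  if (any(process$mean < 0) || any(process$shape <= 0))
    stop("process means must be >= 0 and shapes > 0", call. = FALSE)
  n_types <- nrow(process)
  n <- spec$n_samples
  withr::with_seed(spec$seed, {
    depths <- sample_depths(n, spec$depth_range)
    counts <- matrix(0L, n_types, n)
    for (j in seq_len(n)) {
      lam <- ifelse(is.finite(process$shape),
                    stats::rgamma(n_types, shape = process$shape,
                                  scale = ifelse(process$shape > 0,
                                                 process$mean / process$shape, 0)),
                    process$mean)
      counts[, j] <- stats::rpois(n_types, lam * depths[j] / 1e5)
    }
  })
  colnames(counts) <- sprintf("s%02d", seq_len(n))
  panel <- error_panel(process[, c("amplicon", "position", "ref", "alt")],
                       counts, depths)
  attr(panel, "process") <- process
  panel
}

#' Specification of one simulated assay
#'
#' Defaults describe a plasma assay: 100,000 reads sequenced from a
#' bottleneck of about 5,000 template molecules. `template_molecules =
#' Inf` disables the bottleneck (appropriate for abundant-template
#' inputs such as PCR-product mixtures). The mutation is one of the
#' named target loci or an arbitrary substitution type.
#'
#' @param depth Number of sequenced reads.
#' @param template_molecules Molecules entering amplification (finite
#'   positive, or `Inf`).
#' @param fraction Mutant-allele fraction in `[0, 1]`.
#' @param mutation Target locus name (`"L858R"`, `"L861Q"`, `"T790M"`,
#'   `"exon19del"`) or a list with amplicon, position, ref, alt.
#' @param template_id Deletion template realized when
#'   `mutation = "exon19del"` (default `"del2235-2249"`, the common
#'   15-bp deletion).
#' @param amplicons Amplicon set.
#' @param process Per-type error process (as in [panel_spec()]); NULL
#'   means error-free.
#' @param seed Integer seed.
#' @return List of class `assay_spec`.
#' @export
assay_spec <- function(depth = 100000L, template_molecules = 5000,
                       fraction = 0, mutation = "L858R",
                       template_id = "del2235-2249",
                       amplicons = egfr_amplicons(), process = NULL,
                       seed = 1L) {
  if (fraction < 0 || fraction > 1)
    stop("fraction must be in [0, 1]", call. = FALSE)
  if (depth <= 0) stop("depth must be positive", call. = FALSE)
  if (!is.infinite(template_molecules) && template_molecules <= 0)
    stop("template_molecules must be positive", call. = FALSE)
  if (is.character(mutation)) {
    loci <- target_loci()
    row <- loci[loci$locus == mutation, , drop = FALSE]
    if (nrow(row) != 1L) stop("unknown target locus: ", mutation, call. = FALSE)
    mutation <- as.list(row)
  }
  if (is.null(mutation$kind)) mutation$kind <- "substitution"
  if (is.null(mutation$locus))
    mutation$locus <- type_key(mutation$amplicon, mutation$position,
                               mutation$ref, mutation$alt)
  structure(list(depth = as.integer(depth),
                 template_molecules = template_molecules,
                 fraction = fraction, mutation = mutation,
                 template_id = template_id, amplicons = amplicons,
                 process = process, seed = as.integer(seed)),
            class = "assay_spec")
}

# turn a base-count matrix (positions x A,C,G,T,del,ins) into the same
# shape build_pileup() produces, so counts-level simulations flow
# through the calling functions unchanged
pileup_from_counts <- function(amp, counts, n_reads = NA_integer_) {
  position <- seq.int(amp$cdna_start, amp$cdna_end)
  out <- data.frame(position = position, ref = ref_base_at(amp, position),
                    counts, stringsAsFactors = FALSE)
  out$depth <- out$A + out$C + out$G + out$T + out$del
  out$indel <- out$del + out$ins
  out$in_window <- position >= amp$target_window[1] &
    position <= amp$target_window[2]
  structure(out, amplicon_id = amp$amplicon_id, n_reads = n_reads,
            class = c("pileup", "data.frame"))
}

draw_error_counts <- function(process, depth) {
  if (is.null(process) || !nrow(process)) return(integer(0))
  lam <- ifelse(is.finite(process$shape),
                stats::rgamma(nrow(process), shape = process$shape,
                              scale = ifelse(process$shape > 0,
                                             process$mean / process$shape, 0)),
                process$mean)
  stats::rpois(nrow(process), lam * depth / 1e5)
}

#' Simulate one assay at the count level
#'
#' Two-stage sampling: the number of mutant template molecules is
#' binomial in the bottleneck size and the true fraction; sequencing
#' reads are then allocated to mutant vs normal in proportion to the
#' sampled molecules. Per-position substitution errors are drawn from
#' the error process and moved from the reference base to the alternate
#' base; a deletion mutation is realized as reads assigned to the
#' specified template.
#'
#' @param spec An `assay_spec`.
#' @return List of class `assay_counts`: `pileups` (one `pileup` per
#'   amplicon), `screen` (a `deletion_screen` for exon 19), and `truth`
#'   (fraction, realized mutant templates and reads).
#' @export
simulate_assay <- function(spec) {
  stopifnot(inherits(spec, "assay_spec"))
  mut <- spec$mutation
  withr::with_seed(spec$seed, {
    if (is.finite(spec$template_molecules)) {
      mt <- stats::rbinom(1L, as.integer(spec$template_molecules),
                          spec$fraction)
      f_real <- mt / spec$template_molecules
    } else {
      mt <- NA_integer_
      f_real <- spec$fraction
    }
    mutant_reads <- stats::rbinom(1L, spec$depth, f_real)

    pileups <- list()
    del_error_reads <- 0L
    for (amp in spec$amplicons) {
      L <- nchar(amp$sequence)
      m <- matrix(0L, L, 6,
                  dimnames = list(NULL, c("A", "C", "G", "T", "del", "ins")))
      refb <- ref_base_at(amp, seq.int(amp$cdna_start, amp$cdna_end))
      m[cbind(seq_len(L), match(refb, c("A", "C", "G", "T")))] <- spec$depth
      proc <- spec$process
      if (!is.null(proc)) {
        proc_amp <- proc[proc$amplicon == amp$amplicon_id, , drop = FALSE]
        err <- draw_error_counts(proc_amp, spec$depth)
        for (k in seq_along(err)) {
          if (err[k] == 0L) next
          i <- proc_amp$position[k] - amp$cdna_start + 1L
          e <- min(err[k], m[i, proc_amp$ref[k]])
          if (proc_amp$alt[k] %in% c("A", "C", "G", "T")) {
            m[i, proc_amp$alt[k]] <- m[i, proc_amp$alt[k]] + e
            m[i, proc_amp$ref[k]] <- m[i, proc_amp$ref[k]] - e
          } else {                              # pooled indel pseudo-type
            m[i, "del"] <- m[i, "del"] + e
            m[i, proc_amp$ref[k]] <- m[i, proc_amp$ref[k]] - e
          }
        }
      }
      if (mut$kind == "substitution" && mut$amplicon == amp$amplicon_id &&
          mutant_reads > 0L) {
        i <- mut$position - amp$cdna_start + 1L
        e <- min(mutant_reads, m[i, mut$ref])
        m[i, mut$alt] <- m[i, mut$alt] + e
        m[i, mut$ref] <- m[i, mut$ref] - e
      }
      if (mut$kind == "deletion" && amp$amplicon_id == "exon19" &&
          mutant_reads > 0L) {
        tmpl <- deletion_templates(amp)
        iv <- tmpl[tmpl$template_id == spec$template_id, , drop = FALSE]
        if (nrow(iv) != 1L)
          stop("unknown deletion template: ", spec$template_id, call. = FALSE)
        ii <- seq.int(iv$cdna_start - amp$cdna_start + 1L,
                      iv$cdna_end - amp$cdna_start + 1L)
        for (i in ii) {
          e <- min(mutant_reads, m[i, refb[i]])
          m[i, "del"] <- m[i, "del"] + e
          m[i, refb[i]] <- m[i, refb[i]] - e
        }
      }
      pileups[[amp$amplicon_id]] <- pileup_from_counts(amp, m, spec$depth)
    }

    # template screen for exon 19
    tmpl <- deletion_templates(spec$amplicons$exon19)
    template_counts <- stats::setNames(integer(nrow(tmpl)), tmpl$template_id)
    del_reads <- if (mut$kind == "deletion") mutant_reads else 0L
    if (del_reads > 0L) template_counts[spec$template_id] <- del_reads
    chosen <- if (any(template_counts > 0)) which.max(template_counts) else NA
    screen <- structure(
      list(template_counts = template_counts,
           intact_count = spec$depth - del_reads,
           unassigned = 0L,
           chosen_template = if (is.na(chosen[1])) NA_character_
                             else names(template_counts)[chosen],
           chosen_count = if (is.na(chosen[1])) 0L
                          else as.integer(template_counts[chosen]),
           exon19_total = spec$depth),
      class = "deletion_screen")
  })
  structure(list(pileups = pileups, screen = screen,
                 truth = list(fraction = spec$fraction,
                              mutant_templates = mt,
                              realized_fraction = f_real,
                              mutant_reads = mutant_reads,
                              mutation = mut)),
            class = "assay_counts")
}

#' Estimate the mutant fraction of a simulated assay
#'
#' Runs the calling pipeline on an assay's counts: template screen and
#' [call_exon19_deletion()] for a deletion, [call_substitution()]
#' otherwise.
#'
#' @param assay An `assay_counts`.
#' @param model_set An `error_model_set` covering the mutation's type.
#' @return One-row `mutation_call` data.frame.
#' @export
call_assay <- function(assay, model_set) {
  mut <- assay$truth$mutation
  if (mut$kind == "deletion") {
    model <- exon19del_model(model_set)
    call_exon19_deletion(assay$screen, model)
  } else {
    key <- type_key(mut$amplicon, mut$position, mut$ref, mut$alt)
    call_substitution(assay$pileups[[mut$amplicon]],
                      model_set$models[[key]], mut)
  }
}

#' Null model for the exon 19 deletion
#'
#' The deletion is screened by template matching, under which deletion
#' read errors essentially never survive; its null model is the
#' conservative Poisson floor (lambda = 1).
#'
#' @param model_set An `error_model_set` (for its alpha).
#' @return An `error_model`.
#' @export
exon19del_model <- function(model_set = NULL) {
  alpha <- if (is.null(model_set)) DEFAULT_ALPHA else model_set$alpha
  new_error_model(kind = "poisson_floor", lambda = 1L, alpha = alpha)
}

#' Simulate a dilution series through the full pipeline
#'
#' For each true fraction, `replicates` assays are simulated and pushed
#' through the counting-and-quantitation pipeline; per-point replicate
#' means are emitted alongside every individual estimate.
#'
#' @param fractions True mutant fractions (proportions in `[0, 1]`).
#' @param replicates Assays per fraction (default 3).
#' @param spec Base `assay_spec`; its fraction and seed are overridden
#'   per assay (seed offset deterministically from `spec$seed`).
#' @param model_set An `error_model_set`.
#' @return data.frame of class `dilution_series` with columns
#'   true_percent, replicate, estimated_percent, called; replicate means
#'   in attribute `"means"` and the Pearson correlation of true vs mean
#'   estimated fraction in attribute `"correlation"`.
#' @export
simulate_dilution_series <- function(fractions, replicates = 3L,
                                     spec = assay_spec(),
                                     model_set) {
  if (!length(fractions)) stop("fractions must be non-empty", call. = FALSE)
  rows <- list()
  k <- 0L
  for (i in seq_along(fractions)) {
    for (r in seq_len(replicates)) {
      k <- k + 1L
      s <- spec
      s$fraction <- fractions[i]
      s$seed <- spec$seed + 7919L * i + r
      call <- call_assay(simulate_assay(s), model_set)
      rows[[k]] <- data.frame(true_percent = 100 * fractions[i],
                              replicate = r,
                              estimated_percent = call$fraction_percent,
                              called = call$called)
    }
  }
  out <- do.call(rbind, rows)
  means <- stats::aggregate(estimated_percent ~ true_percent, out, mean)
  r <- if (nrow(means) >= 3L)
    stats::cor(means$true_percent, means$estimated_percent) else NA_real_
  structure(out, means = means, correlation = r,
            class = c("dilution_series", "data.frame"))
}

#' Simulate duplicate assays of the same samples
#'
#' Reproducibility mode: each sample (true fraction) is assayed twice
#' with independent template-bottleneck and sequencing draws, and both
#' estimates come from the calling pipeline. The Pearson correlation
#' between the two replicate vectors is attached; below about a 0.3%
#' fraction the roughly 5,000-molecule bottleneck (15 or fewer mutant
#' copies) makes the two trials visibly disagree.
#'
#' @param fractions True mutant fractions, one per sample.
#' @param spec Base `assay_spec` (fraction and seed overridden per
#'   assay).
#' @param model_set An `error_model_set`.
#' @return data.frame with true_percent, est1_percent, est2_percent;
#'   Pearson correlation of the two estimate vectors in attribute
#'   `"correlation"`.
#' @export
simulate_duplicate_assays <- function(fractions, spec = assay_spec(),
                                      model_set) {
  est <- matrix(NA_real_, length(fractions), 2L)
  for (i in seq_along(fractions)) {
    for (r in 1:2) {
      s <- spec
      s$fraction <- fractions[i]
      s$seed <- spec$seed + 104729L * i + r
      est[i, r] <- call_assay(simulate_assay(s), model_set)$fraction_percent
    }
  }
  out <- data.frame(true_percent = 100 * fractions,
                    est1_percent = est[, 1], est2_percent = est[, 2])
  structure(out,
            correlation = if (nrow(out) >= 3L)
              stats::cor(out$est1_percent, out$est2_percent) else NA_real_,
            class = c("duplicate_assays", "data.frame"))
}

#' Simulate reads for one assay
#'
#' Emits index-prefixed reads for the mutation's amplicon: normal reads
#' are the intact amplicon sequence, mutant reads carry the substitution
#' (or are the deletion-template sequence), and per-position errors from
#' the error process are planted into individual reads. A ground-truth
#' manifest accompanies the reads.
#'
#' @param spec An `assay_spec` (use modest depths; reads are
#'   materialized individually).
#' @param index 5-nt index sequence prefixed to every read.
#' @return List: `reads` (named character vector) and `manifest`
#'   (planted mutant reads, per-type error counts, spec echoes).
#' @export
simulate_reads <- function(spec, index = "ACGTC") {
  stopifnot(inherits(spec, "assay_spec"), nchar(index) == 5L)
  mut <- spec$mutation
  amp <- spec$amplicons[[if (mut$kind == "deletion") "exon19" else mut$amplicon]]
  withr::with_seed(spec$seed, {
    if (is.finite(spec$template_molecules)) {
      mt <- stats::rbinom(1L, as.integer(spec$template_molecules),
                          spec$fraction)
      f_real <- mt / spec$template_molecules
    } else f_real <- spec$fraction
    n_mut <- stats::rbinom(1L, spec$depth, f_real)
    mut_seq <- if (mut$kind == "deletion") {
      tmpl <- deletion_templates(amp)
      tmpl$sequence[tmpl$template_id == spec$template_id]
    } else {
      i <- mut$position - amp$cdna_start + 1L
      s <- amp$sequence
      substr(s, i, i) <- mut$alt
      s
    }
    reads <- c(rep(amp$sequence, spec$depth - n_mut), rep(mut_seq, n_mut))
    err_manifest <- data.frame()
    proc <- spec$process
    if (!is.null(proc)) {
      proc_amp <- proc[proc$amplicon == amp$amplicon_id &
                         proc$alt %in% c("A", "C", "G", "T"), , drop = FALSE]
      err <- draw_error_counts(proc_amp, spec$depth)
      normal_idx <- seq_len(spec$depth - n_mut)   # plant errors in normal reads
      for (k in which(err > 0L)) {
        e <- min(err[k], length(normal_idx))
        if (e == 0L) next
        pick <- sample(normal_idx, e)
        i <- proc_amp$position[k] - amp$cdna_start + 1L
        for (ri in pick) substr(reads[ri], i, i) <- proc_amp$alt[k]
      }
      err_manifest <- cbind(proc_amp, planted = pmin(err, spec$depth - n_mut))
    }
    reads <- paste0(index, reads)
    ord <- sample.int(length(reads))
    reads <- stats::setNames(reads[ord],
                             sprintf("sim%06d", seq_along(reads)))
  })
  list(reads = reads,
       manifest = list(depth = spec$depth, mutant_reads = n_mut,
                       fraction = spec$fraction, mutation = mut,
                       template_id = if (mut$kind == "deletion")
                         spec$template_id else NA_character_,
                       index = index, errors = err_manifest))
}

#' Write simulated reads as FASTQ
#'
#' @param reads Named character vector of read sequences.
#' @param path Output FASTQ path.
#' @return Invisibly, the path.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads)
  q <- Biostrings::BStringSet(vapply(nchar(reads), strrep, "", x = "I"))
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
  invisible(path)
}
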