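# Null error-rate models and anomaly thresholds.
#
# The unit of modeling is the substitution type: one (position, ref ->
# alt) conversion. For each type, event counts in the normal panel are
# expressed per 100,000 reads and a null distribution is fitted by the
# method of moments:
#
#   1. mean < 1            -> Poisson with a conservative floor lambda = 1
#   2. mean >= 1, v/m <= 1.2 -> Poisson, lambda = ceiling(mean)
#   3. mean >= 1, v/m > 1.2  -> negative binomial (gamma-mixed Poisson),
#                               r = ceiling(mean^2 / (variance - mean)),
#                               p re-solved as r / (r + mean)
#
# A base change is judged a mutation when its events per 100,000 reads
# reach the threshold T = min{ k : P(X > k) <= alpha }, alpha = 2e-5 per
# test by default. The equality boundary at ratio 1.2 goes to the
# simpler Poisson model.

DEFAULT_ALPHA <- 2e-5
RATIO_CUTOFF <- 1.2
NB_SIZE_CAP <- 1e6

#' Convert a raw event count to events per 100,000 reads
#'
#' All model fitting and threshold comparison operate on this scale, so
#' that samples sequenced at different depths are directly comparable.
#'
#' @param count Non-negative event count(s).
#' @param depth Positive read depth(s) at the position.
#' @return `count * 1e5 / depth`, a real number.
#' @export
#' @examples
#' normalize_to_per100k(10, 100000)  # 10
#' normalize_to_per100k(5, 50000)    # 10
normalize_to_per100k <- function(count, depth) {
  if (any(depth <= 0)) stop("depth must be positive", call. = FALSE)
  if (any(count < 0)) stop("count must be non-negative", call. = FALSE)
  count * 1e5 / depth
}

#' Method-of-moments summary of panel rates
#'
#' Mean and variance of the per-100k event rates of one substitution
#' type across the normal panel. The variance uses the n denominator
#' (the plain second central moment, as the method of moments
#' prescribes); set `denominator = "n-1"` for the unbiased sample
#' variance instead.
#'
#' @param rates Numeric vector of per-100k rates, one per panel sample.
#' @param denominator `"n"` (default) or `"n-1"`.
#' @return List of class `moment_summary`: mean, variance, ratio
#'   (variance/mean; `NA` when the mean is 0), n.
#' @export
compute_moments <- function(rates, denominator = c("n", "n-1")) {
  denominator <- match.arg(denominator)
  n <- length(rates)
  if (n < 2L)
    stop("insufficient panel: at least 2 samples are required", call. = FALSE)
  if (any(rates < 0)) stop("rates must be non-negative", call. = FALSE)
  m <- mean(rates)
  v <- sum((rates - m)^2) / if (denominator == "n") n else (n - 1L)
  structure(list(mean = m, variance = v,
                 ratio = if (m > 0) v / m else NA_real_, n = n),
            class = "moment_summary")
}

#' @export
print.moment_summary <- function(x, ...) {
  cat(sprintf("<moment_summary> mean %.4g, variance %.4g, ratio %s (n = %d)\n",
              x$mean, x$variance,
              if (is.na(x$ratio)) "NA" else sprintf("%.4g", x$ratio), x$n))
  invisible(x)
}

#' Select the null model family for a substitution type
#'
#' Applies the three-way criteria on the moment summary: a Poisson floor
#' for types averaging fewer than 1 event per 100,000 reads, plain
#' Poisson when the variance/mean ratio stays at or below the cutoff,
#' and negative binomial for overdispersed types. Ties at the cutoff go
#' to the simpler Poisson model.
#'
#' @param ms A `moment_summary`.
#' @param ratio_cutoff Overdispersion cutoff on variance/mean (default 1.2).
#' @return One of `"poisson_floor"`, `"poisson"`, `"negative_binomial"`.
#' @export
select_model <- function(ms, ratio_cutoff = RATIO_CUTOFF) {
  if (ms$mean < 1) return("poisson_floor")
  if (is.na(ms$ratio) || ms$ratio <= ratio_cutoff) return("poisson")
  "negative_binomial"
}

#' Fit a Poisson null model
#'
#' With `floor = TRUE` the intensity is pinned at 1 event per 100,000
#' reads, the conservative floor used for types whose observed mean is
#' below 1. Otherwise lambda is the mean rounded up to an integer
#' (never below 1).
#'
#' @param ms A `moment_summary`.
#' @param floor Apply the lambda = 1 floor?
#' @param alpha Per-test significance level.
#' @return An `error_model`.
#' @export
fit_poisson <- function(ms, floor = FALSE, alpha = DEFAULT_ALPHA) {
  lambda <- if (floor) 1L else max(1L, as.integer(ceiling(ms$mean)))
  new_error_model(kind = if (floor) "poisson_floor" else "poisson",
                  lambda = lambda, alpha = alpha, moments = ms)
}

#' Fit a negative binomial null model
#'
#' Method-of-moments fit for an overdispersed type: the number of events
#' X per 100,000 reads is modeled as a gamma-mixed Poisson, i.e.
#' negative binomial with dispersion `r = ceiling(mean^2 / (variance -
#' mean))` and success probability re-solved after the integer round-up
#' as `p = r / (r + mean)`, which preserves the empirical mean
#' (`E[X] = r (1 - p) / p = mean`). If the excess variance is so small
#' that r would exceed 1e6 the fit falls back to a Poisson model with a
#' warning; at that dispersion the two are numerically indistinguishable.
#'
#' @param ms A `moment_summary` with variance > mean.
#' @param alpha Per-test significance level.
#' @return An `error_model`.
#' @export
fit_negative_binomial <- function(ms, alpha = DEFAULT_ALPHA) {
  if (ms$variance <= ms$mean)
    stop("dispersion error: variance must exceed mean for a negative binomial fit",
         call. = FALSE)
  r <- ceiling(ms$mean^2 / (ms$variance - ms$mean))
  if (r > NB_SIZE_CAP) {
    warning("dispersion parameter r exceeds cap; falling back to Poisson",
            call. = FALSE)
    return(fit_poisson(ms, floor = FALSE, alpha = alpha))
  }
  r <- as.integer(r)
  new_error_model(kind = "negative_binomial", r = r, p = r / (r + ms$mean),
                  alpha = alpha, moments = ms)
}

new_error_model <- function(kind, lambda = NULL, r = NULL, p = NULL,
                            alpha = DEFAULT_ALPHA, moments = NULL) {
  m <- structure(list(kind = kind, lambda = lambda, r = r, p = p,
                      alpha = alpha, moments = moments, threshold = NA_integer_),
                 class = "error_model")
  m$threshold <- compute_threshold(m, alpha)
  # realized per-test size of the calling rule "events >= T"
  m$realized_size <- upper_tail_prob(m, m$threshold - 1L)
  m
}

#' @export
print.error_model <- function(x, ...) {
  par <- switch(x$kind,
                poisson_floor = ,
                poisson = sprintf("lambda = %d", x$lambda),
                negative_binomial = sprintf("r = %d, p = %.4g", x$r, x$p))
  cat(sprintf("<error_model> %s (%s), alpha = %g, threshold = %d, P(X >= T) = %.3g\n",
              x$kind, par, x$alpha, x$threshold, x$realized_size))
  invisible(x)
}

#' Exact upper-tail probability P(X > k)
#'
#' Survival function of the fitted null distribution, evaluated exactly
#' (no normal approximation); monotone non-increasing in k.
#'
#' @param model An `error_model`.
#' @param k Non-negative integer(s); `-1` is accepted so that
#'   `P(X > T - 1) = P(X >= T)` can be asked for at T = 0.
#' @return P(X > k).
#' @export
upper_tail_prob <- function(model, k) {
  if (any(k < -1L)) stop("k must be >= 0 (or -1 for P(X >= 0))", call. = FALSE)
  switch(model$kind,
         poisson_floor = ,
         poisson = stats::ppois(k, lambda = model$lambda, lower.tail = FALSE),
         negative_binomial = stats::pnbinom(k, size = model$r, prob = model$p,
                                            lower.tail = FALSE),
         stop("unknown model kind: ", model$kind, call. = FALSE))
}

#' Anomaly-detection threshold
#'
#' The minimum number of events per 100,000 reads at which a base change
#' is judged a mutation: `T = min{ k >= 0 : P(X > k) <= alpha }`. The
#' calling rule is "events >= T", so the realized per-test size is
#' `P(X >= T)`, which may slightly exceed alpha; both numbers are kept on
#' the fitted model. With `bonferroni = n`, alpha is divided by n before
#' the threshold is taken (off by default: per-test alpha is used without
#' a multiplicity correction).
#'
#' @param model An `error_model`.
#' @param alpha Per-test significance level in (0, 1).
#' @param bonferroni Optional number of tests for a Bonferroni correction.
#' @return Integer threshold T.
#' @export
#' @examples
#' m <- fit_poisson(compute_moments(c(0, 0, 1)), floor = TRUE)
#' compute_threshold(m, 2e-5)  # 7
compute_threshold <- function(model, alpha = model$alpha, bonferroni = NULL) {
  if (!is.null(bonferroni)) alpha <- alpha / bonferroni
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  q <- switch(model$kind,
              poisson_floor = ,
              poisson = stats::qpois(alpha, lambda = model$lambda,
                                     lower.tail = FALSE),
              negative_binomial = stats::qnbinom(alpha, size = model$r,
                                                 prob = model$p,
                                                 lower.tail = FALSE),
              stop("unknown model kind: ", model$kind, call. = FALSE))
  # guard the quantile against boundary rounding: enforce the sandwich
  # P(X > T) <= alpha < P(X > T - 1)
  while (upper_tail_prob(model, q) > alpha) q <- q + 1L
  while (q > 0L && upper_tail_prob(model, q - 1L) <= alpha) q <- q - 1L
  as.integer(q)
}

#' Detection limit at a given read depth
#'
#' The smallest mutant-allele fraction callable at a depth: the
#' threshold is recomputed for the null intensity scaled to the depth
#' (real-valued intensity, used only inside this curve computation;
#' fitted models always carry integer parameters) and expressed as a
#' percentage of the depth. Non-increasing in depth.
#'
#' @param model An `error_model`.
#' @param depth Positive read depth(s).
#' @param alpha Significance level.
#' @return Detection limit(s) in percent.
#' @export
#' @examples
#' m <- fit_poisson(compute_moments(c(0, 0.5)), floor = TRUE)
#' detection_limit(m, 1e5)  # 0.007
detection_limit <- function(model, depth, alpha = model$alpha) {
  if (any(depth <= 0)) stop("depth must be positive", call. = FALSE)
  scale <- depth / 1e5
  t_depth <- switch(model$kind,
                    poisson_floor = ,
                    poisson = stats::qpois(alpha, lambda = model$lambda * scale,
                                           lower.tail = FALSE),
                    negative_binomial = stats::qnbinom(
                      alpha, size = model$r,
                      mu = model$r * (1 - model$p) / model$p * scale,
                      lower.tail = FALSE))
  100 * t_depth / depth
}

#' Fit null models for every substitution type in a panel
#'
#' For each non-excluded type: moment summary, model-family selection,
#' method-of-moments fit, and threshold. Types listed in
#' `panel$excluded_types` (known SNP positions; by default the G>A
#' conversion at cDNA position 2361) never enter model fitting.
#'
#' @param panel An `error_panel` (see [error_panel()]).
#' @param alpha Per-test significance level.
#' @param ratio_cutoff Overdispersion cutoff (default 1.2).
#' @param denominator Variance denominator passed to [compute_moments()].
#' @return An `error_model_set`: list with `models` (named list of
#'   `error_model`, keyed by [type_key()]), `types` (the fitted types
#'   with per-type mean/variance/ratio/kind/threshold columns),
#'   `excluded` (keys left unfitted), and `category_counts`.
#' @export
build_models <- function(panel, alpha = DEFAULT_ALPHA,
                         ratio_cutoff = RATIO_CUTOFF,
                         denominator = c("n", "n-1")) {
  denominator <- match.arg(denominator)
  stopifnot(inherits(panel, "error_panel"))
  keys <- rownames(panel$rates)
  excluded <- intersect(panel$excluded_types, keys)
  fit_keys <- setdiff(keys, excluded)

  models <- vector("list", length(fit_keys))
  names(models) <- fit_keys
  info <- panel$types[match(fit_keys, keys), , drop = FALSE]
  info$mean <- info$variance <- info$ratio <- NA_real_
  info$kind <- NA_character_
  info$threshold <- NA_integer_

  for (i in seq_along(fit_keys)) {
    ms <- compute_moments(panel$rates[fit_keys[i], ], denominator = denominator)
    kind <- select_model(ms, ratio_cutoff)
    m <- switch(kind,
                poisson_floor = fit_poisson(ms, floor = TRUE, alpha = alpha),
                poisson = fit_poisson(ms, floor = FALSE, alpha = alpha),
                negative_binomial = fit_negative_binomial(ms, alpha = alpha))
    models[[i]] <- m
    info$mean[i] <- ms$mean; info$variance[i] <- ms$variance
    info$ratio[i] <- ms$ratio
    info$kind[i] <- m$kind
    info$threshold[i] <- m$threshold
  }
  counts <- table(factor(info$kind,
                         levels = c("poisson_floor", "poisson",
                                    "negative_binomial")))
  structure(list(models = models, types = info, excluded = excluded,
                 alpha = alpha, ratio_cutoff = ratio_cutoff,
                 denominator = denominator,
                 category_counts = counts),
            class = "error_model_set")
}

#' @export
print.error_model_set <- function(x, ...) {
  cat(sprintf("<error_model_set> %d types fitted (%d excluded), alpha = %g\n",
              length(x$models), length(x$excluded), x$alpha))
  print(x$category_counts)
  invisible(x)
}

#' Default excluded substitution types
#'
#' Known constitutional SNPs that would otherwise masquerade as
#' recurrent errors: by default the G-to-A conversion at cDNA position
#' 2361 in exon 20 (a frequent synonymous SNP).
#' @return Character vector of [type_key()] strings.
#' @export
default_excluded_types <- function() {
  type_key("exon20", 2361L, "G", "A")
}

#' Construct an error panel
#'
#' Per-(type, sample) event rates per 100,000 reads from a panel of
#' normal samples, the input to [build_models()]. Rates are recomputed
#' from raw counts and depths (`rate = count * 1e5 / depth`), making the
#' object invariant to a joint rescaling of counts and depths.
#'
#' @param types data.frame of substitution types (amplicon, position,
#'   ref, alt), as from [substitution_types()].
#' @param counts Matrix of raw event counts, types x samples.
#' @param depths Matrix (types x samples) or vector (per sample) of read
#'   depths, positive.
#' @param samples Sample identifiers (default from `colnames(counts)`).
#' @param excluded_types Keys excluded from fitting
#'   (default [default_excluded_types()]).
#' @return An object of class `error_panel` with a `rates` matrix keyed
#'   by [type_key()].
#' @export
error_panel <- function(types, counts, depths, samples = colnames(counts),
                        excluded_types = default_excluded_types()) {
  counts <- as.matrix(counts)
  n_types <- nrow(types)
  if (nrow(counts) != n_types)
    stop("counts must have one row per substitution type", call. = FALSE)
  if (is.null(samples)) samples <- sprintf("s%02d", seq_len(ncol(counts)))
  if (is.vector(depths) && !is.matrix(depths))
    depths <- matrix(depths, nrow = n_types, ncol = ncol(counts), byrow = TRUE)
  if (any(depths <= 0)) stop("depths must be positive", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  keys <- type_key(types$amplicon, types$position, types$ref, types$alt)
  if (anyDuplicated(keys)) stop("duplicate substitution types", call. = FALSE)
  rates <- counts * 1e5 / depths
  dimnames(rates) <- dimnames(counts) <- dimnames(depths) <- list(keys, samples)
  structure(list(types = types, samples = samples, counts = counts,
                 depths = depths, rates = rates,
                 excluded_types = excluded_types),
            class = "error_panel")
}

#' @export
print.error_panel <- function(x, ...) {
  cat(sprintf("<error_panel> %d substitution types x %d samples (%d excluded)\n",
              nrow(x$rates), length(x$samples), length(x$excluded_types)))
  invisible(x)
}
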