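# Generator properties: reproducibility, moment structure, bottleneck.

test_that("identical spec and seed reproduce panels and reads exactly", {
  sp <- panel_spec(n_samples = 8L, seed = 5L)
  p1 <- simulate_normal_panel(sp)
  p2 <- simulate_normal_panel(sp)
  expect_identical(p1$counts, p2$counts)
  expect_identical(p1$depths, p2$depths)
  rs <- assay_spec(depth = 200L, fraction = 0.05, template_molecules = Inf,
                   seed = 9L)
  expect_identical(simulate_reads(rs)$reads, simulate_reads(rs)$reads)
})

test_that("zero intensity gives all-zero rates", {
  types <- substitution_types()[1:12, ]
  proc <- cbind(types, mean = 0, shape = Inf)
  p <- simulate_normal_panel(panel_spec(n_samples = 6L, process = proc,
                                        seed = 2L))
  expect_true(all(p$rates == 0))
})

test_that("panel depths stay within the configured range", {
  p <- simulate_normal_panel(panel_spec(n_samples = 48L, seed = 3L))
  d <- p$depths[1, ]
  expect_true(all(d >= 44400 & d <= 373000))
})

test_that("pure-Poisson types show variance/mean near 1, gamma-mixed above 1.2", {
  types <- substitution_types()
  pois_proc <- cbind(types[1:300, ], mean = 5, shape = Inf)
  # fixed reference depth: at other depths the per-100k rescaling
  # multiplies the variance/mean ratio by 1e5/depth
  p <- simulate_normal_panel(panel_spec(n_samples = 48L, process = pois_proc,
                                        depth_range = c(1e5L, 1e5L),
                                        seed = 6L))
  ratios <- apply(p$rates, 1, function(r) {
    ms <- compute_moments(r); ms$ratio
  })
  expect_lt(abs(mean(ratios) - 1), 0.1)
  gam_proc <- cbind(types[1:300, ], mean = 5, shape = 5 / 2)  # var/mean = 3
  g <- simulate_normal_panel(panel_spec(n_samples = 48L, process = gam_proc,
                                        depth_range = c(1e5L, 1e5L),
                                        seed = 6L))
  gratios <- apply(g$rates, 1, function(r) compute_moments(r)$ratio)
  expect_gte(mean(gratios > 1.2), 0.95)
})

test_that("model selection recovers the generating category for >= 90% of types", {
  types <- substitution_types()
  n_half <- 150L
  proc <- rbind(cbind(types[1:n_half, ], mean = 5, shape = Inf),
                cbind(types[(n_half + 1):(2 * n_half), ], mean = 5,
                      shape = 5 / 2))
  p <- simulate_normal_panel(panel_spec(n_samples = 48L, process = proc,
                                        seed = 8L))
  ms <- build_models(p)
  truth_all <- rep(c("poisson", "negative_binomial"), each = n_half)
  keys_fit <- type_key(ms$types$amplicon, ms$types$position,
                       ms$types$ref, ms$types$alt)
  keys_proc <- type_key(proc$amplicon, proc$position, proc$ref, proc$alt)
  truth <- truth_all[match(keys_fit, keys_proc)]
  expect_gte(mean(ms$types$kind == truth), 0.90)
})

test_that("fitted lambda recovers the planted intensity for Poisson types", {
  types <- substitution_types()
  proc <- cbind(types[1:100, ], mean = 4.5, shape = Inf)
  p <- simulate_normal_panel(panel_spec(n_samples = 48L, process = proc,
                                        depth_range = c(2e5L, 2e5L),
                                        seed = 10L))
  ms <- build_models(p)
  lam <- vapply(ms$models, function(m)
    if (m$kind == "negative_binomial") NA_integer_ else m$lambda, integer(1))
  expect_gte(mean(lam == 5L, na.rm = TRUE), 0.95)
})

test_that("the template bottleneck drives replicate dispersion at low fractions", {
  # at 0.3% about 15 of 5,000 molecules are mutant: the squared
  # coefficient of variation of the estimate scales as 1/(fraction x
  # molecules), about 10x higher than at 3%
  rel_spread <- function(fraction, n = 200L) {
    est <- vapply(seq_len(n), function(i) {
      a <- simulate_assay(assay_spec(depth = 2e4L, fraction = fraction,
                                     template_molecules = 5000,
                                     seed = 1000L + i))
      a$truth$mutant_reads / 2e4
    }, numeric(1))
    stats::var(est) / mean(est)^2
  }
  ratio <- rel_spread(0.003) / rel_spread(0.03)
  expect_gt(ratio, 5)
  expect_lt(ratio, 20)
})

test_that("expected mutant templates at 0.3% match the binomial closed form", {
  mt <- vapply(1:400, function(i) {
    simulate_assay(assay_spec(depth = 100L, fraction = 0.003,
                              template_molecules = 5000,
                              seed = 5000L + i))$truth$mutant_templates
  }, numeric(1))
  expect_lt(abs(mean(mt) - 15) / 15, 0.1)           # E = 15 copies
  expect_lt(abs(sd(mt) / mean(mt) - 1 / sqrt(15)), 0.05)  # CV ~ 26%
})

test_that("fraction endpoints behave: 0 gives error-only counts, 1 all-mutant", {
  f0 <- simulate_assay(assay_spec(fraction = 0, depth = 1000L, seed = 1L))
  expect_equal(f0$truth$mutant_reads, 0L)
  i <- 2573L - 2515L + 1L
  expect_equal(f0$pileups$exon21$G[i], 0L)
  f1 <- simulate_assay(assay_spec(fraction = 1, depth = 1000L, seed = 1L))
  expect_equal(f1$truth$mutant_reads, 1000L)
  expect_equal(f1$pileups$exon21$G[i], 1000L)
})

test_that("error-free simulated reads are exact reference or template sequences", {
  amps <- egfr_amplicons()
  sp <- assay_spec(depth = 150L, fraction = 0.2, mutation = "exon19del",
                   template_molecules = Inf, seed = 14L)
  sim <- simulate_reads(sp, index = "GATTC")
  expect_true(all(substr(sim$reads, 1, 5) == "GATTC"))
  tmpl <- deletion_templates(amps$exon19)
  body <- substring(sim$reads, 6)
  ok <- body == amps$exon19$sequence |
    body == tmpl$sequence[tmpl$template_id == "del2235-2249"]
  expect_true(all(ok))
  # manifest conservation
  expect_equal(sum(body != amps$exon19$sequence), sim$manifest$mutant_reads)
  expect_equal(length(sim$reads), sim$manifest$depth)
})

test_that("deletion screening stays silent on indel-error-only normal samples", {
  # normal samples whose reads carry scattered single-base indel errors
  # but no true deletion allele: the chosen-template rate per 100,000
  # reads must stay below the exon 19 threshold of 7
  amp <- egfr_amplicons()$exon19
  set.seed(31)
  n_samples <- 6L
  for (s in seq_len(n_samples)) {
    n <- 2000L
    reads <- rep(amp$sequence, n)
    n_err <- rbinom(1, n, 0.01)          # 1% of reads get one indel error
    if (n_err > 0) {
      idx <- sample(n, n_err)
      for (i in idx) {
        pos <- sample(20:90, 1)
        reads[i] <- if (runif(1) < 0.5)
          paste0(substr(reads[i], 1, pos - 1),
                 substr(reads[i], pos + 1, nchar(reads[i])))
        else
          paste0(substr(reads[i], 1, pos), "A",
                 substr(reads[i], pos + 1, nchar(reads[i])))
      }
    }
    screen <- match_deletion_templates(reads, amp)
    per100k <- normalize_to_per100k(screen$chosen_count, screen$exon19_total)
    expect_lt(per100k, 7)
  }
})

test_that("dilution series emit per-point means and a correlation", {
  ms <- fixture_models()
  ds <- simulate_dilution_series(c(0.01, 0.1, 0.3), replicates = 2L,
                                 spec = assay_spec(depth = 2e4L,
                                                   template_molecules = Inf,
                                                   seed = 17L),
                                 model_set = ms)
  expect_equal(nrow(ds), 6L)
  expect_equal(nrow(attr(ds, "means")), 3L)
  expect_gt(attr(ds, "correlation"), 0.99)
  one <- simulate_dilution_series(0.01, replicates = 2L,
                                  spec = assay_spec(depth = 2e4L,
                                                    template_molecules = Inf,
                                                    seed = 18L),
                                  model_set = ms)
  expect_true(is.na(attr(one, "correlation")))
  expect_equal(nrow(one), 2L)
})

test_that("the full pipeline recovers a planted mutation from FASTQ", {
  ms <- fixture_models()
  sp <- assay_spec(depth = 1500L, fraction = 0.02, mutation = "L858R",
                   template_molecules = Inf, process = fixture_process(),
                   seed = 19L)
  sim <- simulate_reads(sp, index = "ACGTC")
  fq <- tempfile(fileext = ".fastq")
  write_fastq(sim$reads, fq)
  reads <- read_fastq(fq)
  dm <- demultiplex(unname(reads), c(ACGTC = "s1"))
  expect_equal(dm$discarded, 0L)
  rep <- process_sample(dm$samples$s1, ms, sample_id = "s1")
  call <- rep$calls[rep$calls$locus == "L858R", ]
  expect_true(call$called)
  expect_equal(call$count, sim$manifest$mutant_reads)
  # binomial tolerance around the planted fraction
  expect_lt(abs(call$fraction_percent / 100 - 0.02),
            4 * sqrt(0.02 * 0.98 / 1500))
})
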