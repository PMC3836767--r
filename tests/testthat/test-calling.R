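# Decision rule, scanning, quantitation, temporal reports.

l858r <- list(locus = "L858R", amplicon = "exon21", position = 2573L,
              ref = "T", alt = "G", kind = "substitution")

pileup_with <- function(amp, position, alt, count, depth) {
  counts <- matrix(0L, nchar(amp$sequence), 6,
                   dimnames = list(NULL, c("A", "C", "G", "T", "del", "ins")))
  refb <- ref_base_at(amp, seq.int(amp$cdna_start, amp$cdna_end))
  counts[cbind(seq_along(refb), match(refb, c("A", "C", "G", "T")))] <- depth
  i <- position - amp$cdna_start + 1L
  counts[i, alt] <- count
  counts[i, refb[i]] <- depth - count
  raremut:::pileup_from_counts(amp, counts, depth)
}

test_that("calls fire exactly at the threshold on the per-100k scale", {
  amp <- egfr_amplicons()$exon21
  m <- new_model_pois(1L)          # threshold 7
  at <- call_substitution(pileup_with(amp, 2573L, "G", 7L, 100000L), m, l858r)
  expect_true(at$called)
  expect_equal(at$events_per_100k, 7)
  below <- call_substitution(pileup_with(amp, 2573L, "G", 6L, 100000L), m, l858r)
  expect_false(below$called)
  # same raw count at twice the depth normalizes to 3.5 per 100k: no call
  deep <- call_substitution(pileup_with(amp, 2573L, "G", 7L, 200000L), m, l858r)
  expect_equal(deep$events_per_100k, 3.5)
  expect_false(deep$called)
  expect_error(call_substitution(pileup_with(amp, 2573L, "G", 0L, 10L), NULL,
                                 l858r), "no fitted model")
})

test_that("the realized tail probability accompanies every call", {
  amp <- egfr_amplicons()$exon21
  m <- new_model_pois(1L)
  call <- call_substitution(pileup_with(amp, 2573L, "G", 7L, 100000L), m, l858r)
  expect_equal(call$tail_prob, oracle_tail_pois(1, 6))   # P(X >= 7)
  expect_gt(call$tail_prob, m$alpha)   # realized size exceeds alpha at T
})

test_that("exon 19 deletion calls use template counts over exon 19 totals", {
  m <- exon19del_model()
  expect_equal(m$threshold, 7L)
  screen <- structure(list(
    template_counts = c(`del2235-2249` = 700L), intact_count = 99300L,
    unassigned = 0L, chosen_template = "del2235-2249", chosen_count = 700L,
    exon19_total = 100000L), class = "deletion_screen")
  call <- call_exon19_deletion(screen, m)
  expect_true(call$called)
  expect_equal(call$fraction_percent, 0.7)
  expect_equal(call$alt, "del2235-2249")
  screen$chosen_count <- 6L; screen$template_counts[1] <- 6L
  expect_false(call_exon19_deletion(screen, m)$called)
  screen$chosen_count <- 0L; screen$template_counts[1] <- 0L
  screen$chosen_template <- NA_character_
  none <- call_exon19_deletion(screen, m)
  expect_false(none$called)
  expect_equal(none$fraction_percent, 0)
})

test_that("decision consistency holds across depths and counts", {
  amp <- egfr_amplicons()$exon21
  ms <- fixture_models()
  model <- ms$models[[type_key("exon21", 2573L, "T", "G")]]
  set.seed(11)
  for (i in 1:40) {
    depth <- sample(c(4e4, 1e5, 3.7e5), 1)
    count <- rpois(1, runif(1, 0, 3 * model$threshold) * depth / 1e5)
    call <- call_substitution(pileup_with(amp, 2573L, "G", count, depth),
                              model, l858r)
    expect_identical(call$called,
                     normalize_to_per100k(count, depth) >= model$threshold)
  }
})

test_that("an error-free sample scans clean and a planted 1% variant is found", {
  ms <- fixture_models()
  clean <- simulate_assay(assay_spec(depth = 100000L, fraction = 0,
                                     template_molecules = Inf, seed = 2L))
  for (pu in clean$pileups)
    expect_equal(nrow(scan_region(pu, ms)), 0L)
  planted <- simulate_assay(assay_spec(
    depth = 100000L, fraction = 0.01, template_molecules = Inf,
    mutation = list(amplicon = "exon20", position = 2350L,
                    ref = ref_base_at(egfr_amplicons()$exon20, 2350L),
                    alt = "T", kind = "substitution"),
    seed = 3L))
  hits <- scan_region(planted$pileups$exon20, ms)
  expect_true(type_key("exon20", 2350L,
                       ref_base_at(egfr_amplicons()$exon20, 2350L), "T")
              %in% hits$locus)
})

test_that("named target loci are excluded from the scan", {
  ms <- fixture_models()
  assay <- simulate_assay(assay_spec(depth = 100000L, fraction = 0.05,
                                     template_molecules = Inf,
                                     mutation = "L858R", seed = 4L))
  full <- scan_region(assay$pileups$exon21, ms, called_only = FALSE)
  expect_false(type_key("exon21", 2573L, "T", "G") %in% full$locus)
  # 3 types per position minus L858R, L861Q (and nothing else on exon 21)
  expect_equal(nrow(full), 57L * 3L - 2L)
})

test_that("null simulation reproduces the per-test size of each model family", {
  ms <- fixture_models()
  kinds <- vapply(ms$models, function(m) m$kind, "")
  picks <- c(which(kinds == "poisson_floor")[1], which(kinds == "poisson")[1],
             which(kinds == "negative_binomial")[1])
  n <- 1e6L
  set.seed(7)
  for (i in picks) {
    m <- ms$models[[i]]
    x <- switch(m$kind,
                poisson_floor = , poisson = rpois(n, m$lambda),
                negative_binomial = rnbinom(n, size = m$r, prob = m$p))
    emp <- mean(x >= m$threshold)
    p <- m$realized_size          # P(X >= T)
    mcse <- sqrt(p * (1 - p) / n)
    expect_lt(abs(emp - p), 3 * mcse + 1e-12)
  }
})

test_that("activating-mutation call rate at 1 mutant in 10,000 alleles exceeds 85%", {
  m <- new_model_pois(1L)
  n <- 10000L
  set.seed(13)
  # depth 100,000; mutant reads binomial at fraction 1e-4 on top of
  # lambda = 1 background error events
  events <- rbinom(n, 100000L, 1e-4) + rpois(n, m$lambda)
  expect_gt(mean(events >= m$threshold), 0.85)
})

test_that("fraction estimates are unbiased above the quantitation limit", {
  ms <- fixture_models()
  est <- vapply(1:300, function(i) {
    a <- simulate_assay(assay_spec(depth = 1e5L, fraction = 0.01,
                                   template_molecules = 5000, seed = 100L + i))
    call_assay(a, ms)$fraction_percent
  }, numeric(1))
  expect_lt(abs(mean(est) - 1) / 1, 0.02)
})

test_that("quantitation flag marks called fractions below 0.3%", {
  call <- data.frame(called = c(TRUE, TRUE, FALSE),
                     fraction_percent = c(0.25, 0.5, 0.1))
  q <- quantify(call)
  expect_identical(q$below_quantitation, c(TRUE, FALSE, NA))
})

test_that("temporal reports keep order, scale per 10,000, and emit calls only", {
  amp <- egfr_amplicons()$exon21
  ms <- fixture_models()
  model <- ms$models[[type_key("exon21", 2573L, "T", "G")]]
  mk_report <- function(id, count, depth) {
    call <- call_substitution(pileup_with(amp, 2573L, "G", count, depth),
                              model, l858r)
    sample_report(id, call, model_set = ms)
  }
  reports <- list(mk_report("t1", 5000L, 10000L),   # 50%
                  mk_report("t2", 0L, 100000L),     # no call
                  mk_report("t3", 70L, 100000L))    # 70 per 100k
  series <- temporal_report(reports, patient_id = "p1")
  expect_equal(series$timepoint, 1:3)
  expect_equal(series$sample_id, c("t1", "t2", "t3"))
  expect_true(is.na(series$locus[2]))               # empty entry retained
  expect_equal(series$events_per_10k[3], 7)         # 70 per 100k -> 7 per 10k
  expect_equal(series$events_per_10k[1], 5000)
  expect_error(temporal_report(list()), "at least one")
})

test_that("co-occurring mutations are reported independently", {
  ms <- fixture_models()
  sub <- simulate_assay(assay_spec(depth = 5e4L, fraction = 0.05,
                                   template_molecules = Inf, seed = 21L))
  del <- simulate_assay(assay_spec(depth = 5e4L, fraction = 0.02,
                                   mutation = "exon19del",
                                   template_molecules = Inf, seed = 22L))
  calls <- rbind(call_assay(sub, ms), call_assay(del, ms))
  rep <- sample_report("double", calls, model_set = ms)
  expect_true(all(rep$calls$called))
  expect_equal(nrow(rep$calls), 2L)
})
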