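# Per-allele quantification, depth inclusion, the exact 2x2 test, control
# comparison and the plasma CoQ10 flag.

test_that("per-allele fractions reproduce the biallelic skip proportions", {
  r <- replicate_coq5_family11(seed = 1L)
  q <- r$quant
  frac <- function(al, ev) q$fraction[q$allele_id == al & q$event_id == ev]
  expect_equal(frac("G", "exon5_skip"), 0.56)
  expect_equal(frac("T", "exon5_skip"), 0.04)
  expect_equal(frac("G", "exon4_5_skip"), 0.03)
  # fractions per allele sum to 1 over classified reads
  expect_equal(as.numeric(tapply(q$fraction, q$allele_id, sum)), c(1, 1))
})

test_that("an all-canonical read set quantifies as 100% canonical", {
  loc <- toy_coq5_locus()
  al <- allele_spec("x", c(canonical = 1),
                    tag_snvs = data.frame(cds_pos = 150L, ref = "C",
                                          alt = "T", carries = "ref"))
  sim <- simulate_reads(loc$model, loc$events, list(al), 50L,
                        err = error_model(0, 0, 0), seed = 1L)
  cat5 <- event_catalogue(loc$model, loc$events, frame = "transcript")
  q <- per_allele_fractions(classify_reads(sim, cat5),
                            call_alleles(sim, loc$tags$primary$transcript))
  expect_equal(q$fraction[q$event_id == "canonical"], 1)
})

test_that("fractions are invariant to read order", {
  r <- replicate_coq5_family11(n_per_allele = 50L, seed = 3L)
  set.seed(1)
  perm <- sample(nrow(r$event_calls))
  q1 <- per_allele_fractions(r$event_calls, r$allele_calls)
  q2 <- per_allele_fractions(r$event_calls[perm, ], r$allele_calls)
  expect_equal(as.data.frame(q1), as.data.frame(q2))
})

test_that("depth inclusion matches a hand-computed pileup", {
  # 7 anchor-only reads, 3 reads spanning both regions: inclusion 0.3
  reads <- data.frame(
    read_id = sprintf("r%02d", 1:10),
    pos = 1L,
    cigar = c(rep("10M", 7L), rep("10M90N10M", 3L)))
  res <- depth_inclusion(reads, alt_region = c(101L, 110L),
                         anchor_region = c(1L, 10L))
  expect_equal(res$inclusion, 0.3)
  comp <- depth_inclusion(reads, c(101L, 110L), c(1L, 10L),
                          convention = "competing")
  expect_equal(comp$inclusion, 3 / 13)
  expect_error(depth_inclusion(reads, c(5L, 15L), c(1L, 10L)), "overlap")
  none <- reads[8:10, ]
  expect_error(depth_inclusion(none, c(1L, 10L), c(50L, 60L)), "zero anchor")
})

test_that("allele-resolved inclusion reproduces 90.25% and matches counting", {
  r <- replicate_pdss1_family5(seed = 1L)
  expect_equal(round(100 * r$inclusion$A$inclusion, 2), 90.25)
  # depth route equals the read-proportion route for full-length amplicons
  frac <- r$quant$fraction[r$quant$allele_id == "A" &
                             r$quant$event_id == "alt_exon"]
  expect_equal(r$inclusion$A$inclusion, frac)
  expect_equal(r$inclusion$A$mean_alt_depth, 361)
  expect_equal(r$inclusion$A$mean_anchor_depth, 400)
})

test_that("exact test reproduces the case/population association", {
  f <- fisher_exact_2x2(3L, 19L, 411L, 282353L)
  expect_equal(f$p_two_sided, 4.699e-6, tolerance = 1e-3)
  expect_equal(f$or_cmle, 108.34, tolerance = 0.01)
  expect_equal(f$ci_low, 20.47, tolerance = 0.02)
  expect_equal(f$ci_high, 374.14, tolerance = 0.02)
  expect_lte(f$ci_low, f$or_cmle)
  expect_gte(f$ci_high, f$or_cmle)
})

test_that("exact test agrees with brute-force enumeration on all small tables", {
  for (a in 0:3) for (b in 0:3) for (cc in 0:3) for (d in 0:3) {
    tab <- rbind(c(a, b), c(cc, d))
    if (sum(tab[1, ]) > 6 || sum(tab[2, ]) > 6) next
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
      expect_equal(fisher_exact_2x2(tab)$p_two_sided, 1)
      next
    }
    got <- fisher_exact_2x2(tab)
    want <- oracle_fisher(tab)
    expect_equal(got$p_two_sided, want$p, tolerance = 1e-9,
                 info = paste(a, b, cc, d))
    if (is.finite(want$cmle) && want$cmle > 0)
      expect_equal(got$or_cmle, want$cmle, tolerance = 1e-7,
                   info = paste(a, b, cc, d))
    else
      expect_equal(got$or_cmle, want$cmle, info = paste(a, b, cc, d))
  }
})

test_that("exact test matches the standard conditional-MLE convention", {
  set.seed(99)
  for (i in 1:20) {
    tab <- matrix(rpois(4L, lambda = sample(c(5, 20, 80), 1L)) + 1L, 2L)
    got <- fisher_exact_2x2(tab)
    ref <- stats::fisher.test(tab)
    expect_equal(got$p_two_sided, ref$p.value, tolerance = 1e-10)
    # fisher.test solves the same score equation at a looser root tolerance
    expect_equal(got$or_cmle, unname(ref$estimate), tolerance = 5e-3)
    expect_equal(got$ci_low, ref$conf.int[1L], tolerance = 2e-2)
    expect_equal(got$ci_high, ref$conf.int[2L], tolerance = 2e-2)
  }
})

test_that("symmetric and degenerate tables behave as prescribed", {
  f <- fisher_exact_2x2(1L, 1L, 1L, 1L)
  expect_equal(f$or_cmle, 1)
  expect_equal(f$p_two_sided, 1)
  d <- fisher_exact_2x2(0L, 0L, 3L, 5L)
  expect_equal(d$p_two_sided, 1)
  expect_true(is.na(d$or_cmle))
  expect_error(fisher_exact_2x2(-1L, 1L, 1L, 1L), "input error")
})

test_that("confidence intervals widen with the confidence level", {
  tab <- rbind(c(8L, 12L), c(3L, 17L))
  cis <- lapply(c(0.8, 0.9, 0.95, 0.99), function(cl)
    fisher_exact_2x2(tab, conf = cl))
  for (i in 2:4) {
    expect_lte(cis[[i]]$ci_low, cis[[i - 1L]]$ci_low)
    expect_gte(cis[[i]]$ci_high, cis[[i - 1L]]$ci_high)
  }
})

test_that("exact intervals achieve near-nominal coverage at known odds ratio", {
  # conditional draws at psi = 3 with fixed margins
  psi <- 3
  m1 <- 15L; m2 <- 15L; n1 <- 12L
  lo <- max(0L, n1 - m2); hi <- min(m1, n1)
  support <- lo:hi
  w <- lchoose(m1, support) + lchoose(m2, n1 - support) + support * log(psi)
  p <- exp(w - max(w)); p <- p / sum(p)
  set.seed(2024)
  xs <- sample(support, 1000L, replace = TRUE, prob = p)
  covered <- vapply(xs, function(x) {
    f <- fisher_exact_2x2(x, m1 - x, n1 - x, m2 - (n1 - x))
    f$ci_low <= psi && psi <= f$ci_high
  }, logical(1))
  expect_gte(mean(covered), 0.95 - 0.03)
})

test_that("case inclusion is flagged against the control range", {
  expect_true(compare_to_controls(0.9025, c(0.065, 0.08, 0.1014))$flagged)
  expect_false(compare_to_controls(0.08, c(0.065, 0.08, 0.1014))$flagged)
  expect_false(compare_to_controls(0.1014, c(0.065, 0.1014))$flagged)
  expect_error(compare_to_controls(0.5, numeric(0)), "control")
})

test_that("plasma CoQ10 levels classify against the reference range", {
  expect_equal(flag_plasma_coq10(39.33), "below")
  expect_equal(flag_plasma_coq10(195.45), "below")
  expect_equal(flag_plasma_coq10(227), "within")
  expect_equal(flag_plasma_coq10(1432), "within")
  expect_equal(flag_plasma_coq10(1500), "above")
  expect_error(flag_plasma_coq10(-1), "nonnegative")
})
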