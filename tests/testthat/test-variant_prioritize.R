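# Panel restriction, frequency annotation, the rarity filter and biallelic
# genotype detection.

test_that("panel restriction keeps exactly the CoQ10 pathway genes", {
  fx <- cohort_fixture()
  kept <- panel_restrict(fx$variants)
  expect_true("COQ5" %in% kept$gene_id)
  expect_false("USH2A" %in% kept$gene_id)
  expect_equal(nrow(panel_restrict(fx$variants[0, ])), 0L)
  expect_length(coq10_panel(), 13L)
})

test_that("frequency annotation computes MAF, popmax and display values", {
  fx <- cohort_fixture()
  ann <- annotate_frequency(panel_restrict(fx$variants), fx$freq)
  rec <- ann[ann$hgvs_c == "c.589A>G", ]
  expect_equal(rec$maf, 411 / 282764)
  expect_equal(rec$maf_display, "0.001454")
  expect_equal(rec$popmax, 0.003499)
  absent <- ann[ann$hgvs_c == "c.18G>A", ]
  expect_true(is.na(absent$maf))
  expect_equal(absent$maf_display, "-")
  # tiny populations fall below the allele-number floor and never set popmax
  tiny <- annotate_frequency(
    data.frame(gene_id = "COQ2", chrom = "chr4", pos = 1L, ref = "A",
               alt = "G"),
    data.frame(chrom = "chr4", pos = 1L, ref = "A", alt = "G",
               population = "XX", allele_count = 1L, allele_number = 2L))
  expect_true(is.na(tiny$popmax))
})

test_that("rarity filter gates on popmax, class and the whitelist", {
  fx <- cohort_fixture()
  ann <- annotate_frequency(panel_restrict(fx$variants), fx$freq)
  no_wl <- filter_rare(ann)
  expect_false("c.589A>G" %in% no_wl$hgvs_c)   # popmax 0.003499 over threshold
  wl <- filter_rare(ann, whitelist = fx$whitelist)
  rec <- wl[wl$hgvs_c == "c.589A>G", ]
  expect_equal(nrow(rec), 1L)
  expect_true(rec$frequency_exceptional)
  expect_true("c.18G>A" %in% wl$hgvs_c)        # absent stop gain retained
  expect_false(any(wl$frequency_exceptional[wl$hgvs_c == "c.18G>A"]))
  expect_false("c.600C>T" %in% wl$hgvs_c)      # synonymous, class-gated
  expect_false("c.999G>A" %in% wl$hgvs_c)      # MAF 0.01, frequency-gated
  # deep intronic variants need a splice-predictor flag to survive
  deep <- data.frame(gene_id = "PDSS1", chrom = "chr10", pos = 7L, ref = "A",
                     alt = "G", hgvs_c = "c.100-80A>G",
                     consequence = "splice_region_intronic",
                     intron_distance = -80L, splice_pred_flag = FALSE,
                     maf = NA_real_, popmax = NA_real_)
  expect_equal(nrow(filter_rare(deep)), 0L)
  deep$splice_pred_flag <- TRUE
  expect_equal(nrow(filter_rare(deep)), 1L)
})

test_that("threshold and panel monotonicity hold across the cascade", {
  fx <- cohort_fixture()
  ann <- annotate_frequency(panel_restrict(fx$variants), fx$freq)
  kept <- lapply(c(0.01, 0.001, 0.0001, 0.00001), function(thr)
    filter_rare(ann, maf_threshold = thr)$hgvs_c)
  for (i in 2:4) expect_true(all(kept[[i]] %in% kept[[i - 1L]]))
  res <- prioritize_variants(fx$variants, fx$freq, fx$genotypes,
                             whitelist = fx$whitelist,
                             panel = c("COQ5", "COQ2"))
  expect_true(all(res$gene_id %in% c("COQ5", "COQ2")))
})

test_that("pedigree phasing separates trans, cis and unknown pairs", {
  vars <- data.frame(gene_id = "PDSS1", chrom = "chr10", pos = c(10L, 20L),
                     ref = "A", alt = "G", consequence = c("lof", "missense"),
                     stringsAsFactors = FALSE)
  key <- paste("chr10", c(10L, 20L), "A", "G", sep = ":")
  ped <- data.frame(sample = "kid", father = "dad", mother = "mum")
  gt <- function(kid2, dad1, dad2, mum1, mum2) {
    data.frame(sample = c("kid", "kid", "dad", "dad", "mum", "mum"),
               var_id = rep(key, 3L),
               gt = c("het", kid2, dad1, dad2, mum1, mum2))
  }
  # one variant from each parent: trans candidate
  trans <- detect_biallelic(vars, gt("het", "het", "hom_ref",
                                     "hom_ref", "het"), ped)
  expect_equal(trans$phase, "trans")
  expect_equal(trans$zygosity, "compound_het")
  # both from the father: demoted cis
  cis <- detect_biallelic(vars, gt("het", "het", "het",
                                   "hom_ref", "hom_ref"), ped)
  expect_equal(nrow(cis), 0L)
  expect_equal(attr(cis, "demoted")$phase, "cis")
  # no parental genotypes: phase unknown but still a candidate
  solo <- detect_biallelic(vars, data.frame(sample = "kid", var_id = key,
                                            gt = "het"), NULL)
  expect_equal(solo$phase, "unknown")
  # homozygous variant: hom candidate
  hom <- detect_biallelic(vars[1L, ],
                          data.frame(sample = "kid", var_id = key[1L],
                                     gt = "hom_alt"), ped)
  expect_equal(hom$zygosity, "hom")
  # child allele absent from both genotyped parents: flagged, kept
  denovo <- detect_biallelic(vars, gt("het", "hom_ref", "hom_ref",
                                      "hom_ref", "het"), ped)
  expect_equal(nrow(denovo), 1L)
  expect_match(denovo$notes, "mendelian_inconsistency")
})

test_that("the cohort replica yields exactly the twelve family genotypes", {
  fx <- cohort_fixture()
  res <- prioritize_variants(fx$variants, fx$freq, fx$genotypes,
                             whitelist = fx$whitelist)
  expect_equal(nrow(res), 12L)
  expect_setequal(unique(res$sample), sprintf("F%d", 1:12))
  expect_equal(sum(res$zygosity == "hom"), 2L)                 # F4 and F9
  expect_equal(sum(res$zygosity == "compound_het"), 10L)
  expect_setequal(res$sample[res$zygosity == "hom"], c("F4", "F9"))
  counts <- table(res$gene_id)
  expect_equal(unname(counts[c("PDSS1", "COQ2", "COQ4", "COQ5")]),
               c(6L, 3L, 1L, 2L), ignore_attr = TRUE)
})

test_that("variant tables load from VCF with genotype classes", {
  tmp <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=GENE,Number=1,Type=String,Description=\"g\">",
    "##INFO=<ID=CSQCLASS,Number=1,Type=String,Description=\"c\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"gt\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "S1", "S2"), collapse = "\t"),
    paste(c("chr10", "100", ".", "A", "G", ".", "PASS",
            "GENE=PDSS1;CSQCLASS=missense", "GT", "0|1", "1|1"),
          collapse = "\t"),
    paste(c("chr10", "200", ".", "C", "T", ".", "PASS",
            "GENE=PDSS1;CSQCLASS=lof", "GT", "0/0", "./."),
          collapse = "\t")), tmp)
  got <- read_variants_vcf(tmp)
  expect_equal(got$variants$gene_id, c("PDSS1", "PDSS1"))
  expect_equal(got$variants$consequence, c("missense", "lof"))
  g <- got$genotypes
  expect_equal(g$gt[g$sample == "S1"], c("het", "hom_ref"))
  expect_equal(g$gt[g$sample == "S2"], c("hom_alt", "missing"))
})
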