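# Fixtures built in code: small custom gene models, an independent
# translation oracle, a brute-force conditional-distribution oracle for the
# exact test, and the cohort-replica variant/genotype tables.

# --- small gene models ------------------------------------------------------

# three plus-strand exons of given lengths separated by fixed introns,
# with an optional designed transcript sequence written into the exons
make_toy_model <- function(exon_len, intron = 50L, cds_start = NA,
                           cds_end = NA, tx_seq = NULL, seed = 99L,
                           gene_id = "toy", chrom = "chrT") {
  n <- length(exon_len)
  starts <- integer(n); starts[1L] <- 101L
  if (n > 1L) for (i in 2:n) starts[i] <- starts[i - 1L] + exon_len[i - 1L] + intron
  ex <- data.frame(start = starts, end = starts + exon_len - 1L)
  locus <- withr::with_seed(seed,
    paste(sample(c("A", "C", "G", "T"), ex$end[n] + 100L, replace = TRUE),
          collapse = ""))
  if (!is.null(tx_seq)) {
    stopifnot(nchar(tx_seq) == sum(exon_len))
    off <- 0L
    for (i in seq_len(n)) {
      substr(locus, ex$start[i], ex$end[i]) <-
        substr(tx_seq, off + 1L, off + exon_len[i])
      off <- off + exon_len[i]
    }
  }
  gene_model(gene_id, chrom, "+", ex, cds_start, cds_end,
             sequence = locus, locus_start = 1L)
}

# deterministic CDS built from non-stop codons
make_cds <- function(n_codons, seed = 7L) {
  b <- c("A", "C", "G", "T")
  all_codons <- as.vector(outer(outer(b, b, paste0), b, paste0))
  ok <- setdiff(all_codons, c("TAA", "TAG", "TGA"))
  withr::with_seed(seed, paste0(
    "ATG", paste(sample(ok, n_codons - 2L, replace = TRUE), collapse = ""),
    "TAA"))
}

# --- independent translation oracle ----------------------------------------

oracle_translate <- function(dna) {
  aa <- seqinr::translate(strsplit(dna, "")[[1L]])
  stop_at <- which(aa == "*")
  list(aa = if (length(stop_at)) aa[seq_len(stop_at[1L] - 1L)] else aa,
       terminated = length(stop_at) > 0L,
       stop_index = if (length(stop_at)) stop_at[1L] else NA_integer_)
}

# --- brute-force conditional-distribution oracle for the exact test ---------

# exact conditional pmf at odds ratio 1 via the central hypergeometric,
# and a high-precision CMLE by direct likelihood maximisation
oracle_fisher <- function(tab) {
  x <- tab[1, 1]; m1 <- sum(tab[1, ]); m2 <- sum(tab[2, ]); n1 <- sum(tab[, 1])
  lo <- max(0, n1 - m2); hi <- min(m1, n1)
  support <- lo:hi
  d1 <- stats::dhyper(support, m1, m2, n1)
  p <- sum(d1[d1 <= d1[x - lo + 1] * (1 + 1e-7)])
  loglik <- function(lp) {
    w <- lchoose(m1, support) + lchoose(m2, n1 - support) + support * lp
    (lchoose(m1, x) + lchoose(m2, n1 - x) + x * lp) -
      (max(w) + log(sum(exp(w - max(w)))))
  }
  cmle <- if (x == lo) 0 else if (x == hi) Inf else
    exp(stats::optimize(loglik, c(-40, 40), maximum = TRUE,
                        tol = 1e-12)$maximum)
  list(p = p, cmle = cmle)
}

# --- cohort-replica prioritisation fixture ----------------------------------

# variant, frequency and genotype tables replicating the 12-family cohort
# genotype table (printed popmax frequencies; "-" entries absent from the
# reference), plus decoys that each stage of the cascade must remove
cohort_fixture <- function() {
  v <- function(gene, chrom, pos, hgvs, csq, popmax, intron_dist = NA) {
    data.frame(gene_id = gene, chrom = chrom, pos = pos, ref = "A", alt = "G",
               hgvs_c = hgvs, consequence = csq, popmax_printed = popmax,
               intron_distance = intron_dist, stringsAsFactors = FALSE)
  }
  variants <- rbind(
    v("PDSS1", "chr10", 1368, "c.368A>G", "missense", NA),
    v("PDSS1", "chr10", 1018, "c.18G>A", "lof", NA),
    v("PDSS1", "chr10", 1232, "c.232C>A", "missense", NA),
    v("PDSS1", "chr10", 1886, "c.886G>A", "missense", 0.00009239),
    v("PDSS1", "chr10", 1722, "c.722-2A>G", "splice_canonical", 0.000008799),
    v("PDSS1", "chr10", 1589, "c.589A>G", "missense", 0.003499),
    v("PDSS1", "chr10", 2118, "c.1118_1120dup", "inframe_indel", NA),
    v("PDSS1", "chr10", 1468, "c.468-25A>G", "splice_region_intronic",
      0.00002641, -25),
    v("PDSS1", "chr10", 1893, "c.893dup", "lof", NA),
    v("COQ2", "chr4", 3735, "c.735C>G", "lof", NA),
    v("COQ2", "chr4", 3683, "c.683A>G", "missense", 0.0002813),
    v("COQ2", "chr4", 3338, "c.338_341delinsG", "inframe_indel", NA),
    v("COQ4", "chr9", 4692, "c.692G>A", "missense", 0.0001148),
    v("COQ4", "chr9", 4376, "c.376G>A", "missense", 0.0003508),
    v("COQ5", "chr12", 5933, "c.933delC", "lof", 0.0000176),
    v("COQ5", "chr12", 5682, "c.682-7T>G", "splice_region_intronic",
      0.001434, -7),
    v("COQ5", "chr12", 5367, "c.367C>T", "missense", 0.00003266),
    # decoys: off-panel, class-gated, frequency-gated
    v("USH2A", "chr1", 9001, "c.100A>G", "missense", NA),
    v("PDSS1", "chr10", 1600, "c.600C>T", "synonymous", 0.000001),
    v("COQ4", "chr9", 4999, "c.999G>A", "missense", 0.01))
  freq <- do.call(rbind, lapply(which(!is.na(variants$popmax_printed)),
    function(i) {
      data.frame(chrom = variants$chrom[i], pos = variants$pos[i],
                 ref = "A", alt = "G", population = "POPMAX",
                 allele_count = round(variants$popmax_printed[i] * 1e6),
                 allele_number = 1e6, stringsAsFactors = FALSE)
    }))
  # the overall gnomAD row for the recurrent missense: 411/282764
  freq <- rbind(freq, data.frame(chrom = "chr10", pos = 1589, ref = "A",
                                 alt = "G", population = "ALL",
                                 allele_count = 411, allele_number = 282764))
  key <- function(chrom, pos) paste(chrom, pos, "A", "G", sep = ":")
  gts <- function(sample, poss, chroms, gt) {
    data.frame(sample = sample, var_id = key(chroms, poss), gt = gt,
               stringsAsFactors = FALSE)
  }
  genotypes <- rbind(
    gts("F1", c(1368, 1018), "chr10", "het"),
    gts("F2", c(1232, 1886), "chr10", "het"),
    gts("F3", c(1722, 1589), "chr10", "het"),
    gts("F4", 2118, "chr10", "hom_alt"),
    gts("F5", c(1468, 1589), "chr10", "het"),
    gts("F6", c(1893, 1589), "chr10", "het"),
    gts("F7", c(3735, 3683), "chr4", "het"),
    gts("F8", c(3683, 3338), "chr4", "het"),
    gts("F9", 3683, "chr4", "hom_alt"),
    gts("F10", c(4692, 4376), "chr9", "het"),
    gts("F11", c(5933, 5682), "chr12", "het"),
    gts("F12", c(5367, 5682), "chr12", "het"),
    # decoy genotypes
    gts("F1", 9001, "chr1", "het"),
    gts("F2", 1600, "chr10", "het"),
    gts("F10", 4999, "chr9", "het"))
  list(variants = variants, freq = freq, genotypes = genotypes,
       whitelist = c("PDSS1:c.589A>G", "COQ5:c.682-7T>G"))
}
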