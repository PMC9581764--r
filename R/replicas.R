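# End-to-end replica pipelines. Each helper wires the synthetic generator
# to the classifier and quantifier under the study conditions (per-allele
# isoform mixtures, read counts, alignment frame) and returns every
# intermediate, so tests and reports can inspect any stage.

#' Allele-resolved alternate-exon inclusion replica
#'
#' Simulates the two-allele amplicon experiment in which the variant-linked
#' allele (tagged `A` at coding position 589) carries the alternate
#' noncanonical exon in 90.25% of its transcripts while the trans allele
#' shows only basal inclusion (159/1619). Reads are aligned in genome
#' frame, grouped by the allele call at the tagging SNV, and the
#' read-depth inclusion of the alternate exon is computed per allele.
#'
#' @param n_a,n_g Reads for the variant-linked (A) and trans (G) alleles.
#' @param a_inclusion,g_inclusion Per-allele alternate-exon fractions.
#' @param err [error_model()]; zero rates replicate counts exactly.
#' @param mode Count realization mode.
#' @param seed Simulation seed.
#' @return List with `sim`, `event_calls`, `allele_calls`, `inclusion`
#'   (named `inclusion_result`s per allele), `quant` (per-allele event
#'   fractions).
#' @export
replicate_pdss1_family5 <- function(n_a = 400L, n_g = 1619L,
                                    a_inclusion = 0.9025,
                                    g_inclusion = 159 / 1619,
                                    err = error_model(0, 0, 0, seed = seed),
                                    mode = "exact", seed = 1L) {
  loc <- toy_pdss1_locus()
  n_tot <- n_a + n_g
  tags_a <- data.frame(cds_pos = loc$tag$cds_pos, ref = loc$tag$ref,
                       alt = loc$tag$alt, carries = "ref")
  tags_g <- transform(tags_a, carries = "alt")
  alleles <- list(
    allele_spec("A", c(alt_exon = a_inclusion, canonical = 1 - a_inclusion),
                tag_snvs = tags_a, copy_fraction = n_a / n_tot),
    allele_spec("G", c(alt_exon = g_inclusion, canonical = 1 - g_inclusion),
                tag_snvs = tags_g, copy_fraction = n_g / n_tot))
  sim <- simulate_reads(loc$model, loc$events, alleles, n_tot, err = err,
                        frame = "genome", mode = mode, seed = seed)
  catalogue <- event_catalogue(loc$model, loc$events, frame = "genome")
  event_calls <- classify_reads(sim, catalogue)
  allele_calls <- call_alleles(sim, loc$tag$genome)
  labels <- c(ref = "A", alt = "G")
  inclusion <- allele_inclusion(sim, allele_calls, loc$regions$alt,
                                loc$regions$anchor, allele_labels = labels)
  quant <- per_allele_fractions(event_calls, allele_calls,
                                allele_labels = labels)
  list(locus = loc, sim = sim, event_calls = event_calls,
       allele_calls = allele_calls, inclusion = inclusion, quant = quant)
}

#' Per-allele exon-skip fraction replica
#'
#' Simulates the biallelic amplicon experiment in which the splice-variant
#' allele (tagged by two linked SNVs in cis) shows exon-5 skipping in 56%
#' and exon-4-5 skipping in 3% of its reads, against a trans allele with
#' 4% basal exon-5 skipping. Reads align in transcript frame; events are
#' classified against the three-chain catalogue, alleles called at the
#' primary tag, and the two linked sites phased from read co-occurrence.
#'
#' @param n_per_allele Reads per allele.
#' @param variant_mixture,trans_mixture Named isoform mixtures.
#' @param err,mode,seed See [replicate_pdss1_family5()].
#' @return List with `sim`, `event_calls`, `allele_calls`, `quant`,
#'   `phasing` (the [phase_by_linked_snv()] result).
#' @export
replicate_coq5_family11 <- function(n_per_allele = 100L,
                                    variant_mixture = c(exon5_skip = 0.56,
                                                        exon4_5_skip = 0.03,
                                                        canonical = 0.41),
                                    trans_mixture = c(exon5_skip = 0.04,
                                                      canonical = 0.96),
                                    err = error_model(0, 0, 0, seed = seed),
                                    mode = "exact", seed = 1L) {
  loc <- toy_coq5_locus()
  mk_tags <- function(carries) data.frame(
    cds_pos = c(loc$tags$primary$cds_pos, loc$tags$linked$cds_pos),
    ref = c(loc$tags$primary$ref, loc$tags$linked$ref),
    alt = c(loc$tags$primary$alt, loc$tags$linked$alt),
    carries = carries)
  alleles <- list(
    allele_spec("G", variant_mixture, tag_snvs = mk_tags("alt"),
                copy_fraction = 0.5),
    allele_spec("T", trans_mixture, tag_snvs = mk_tags("ref"),
                copy_fraction = 0.5))
  sim <- simulate_reads(loc$model, loc$events, alleles, 2L * n_per_allele,
                        err = err, frame = "transcript", mode = mode,
                        seed = seed)
  catalogue <- event_catalogue(loc$model, loc$events, frame = "transcript")
  event_calls <- classify_reads(sim, catalogue)
  allele_calls <- call_alleles(sim, loc$tags$primary$transcript)
  linked_calls <- call_alleles(sim, loc$tags$linked$transcript)
  labels <- c(ref = "T", alt = "G")
  quant <- per_allele_fractions(event_calls, allele_calls,
                                allele_labels = labels)
  phasing <- phase_by_linked_snv(allele_calls, linked_calls)
  list(locus = loc, sim = sim, event_calls = event_calls,
       allele_calls = allele_calls, linked_calls = linked_calls,
       quant = quant, phasing = phasing)
}

#' Shared ancestral-haplotype replica
#'
#' Simulates carrier families whose haplotypes share rare-marker alleles
#' across configured intervals around a target missense variant, then runs
#' marker selection, per-family cis sets and the shared-segment
#' intersection.
#'
#' @param seed RNG seed.
#' @param shared_intervals One interval (all families) or a per-family
#'   list; defaults to the three-family fully-shared segment bounded at
#'   26,535,625 and 26,933,928.
#' @param n_families Number of carrier families.
#' @param marker_spacing,maf_range Marker panel parameters.
#' @param carrier_background Carrier-haplotype background outside the
#'   shared interval (see [simulate_family_genotypes()]); the replica
#'   defaults to the controlled `"none"` background because it asserts the
#'   exact printed boundary markers.
#' @return List with `sim`, `markers` (informative set), `cis_sets`,
#'   `segment` (the [shared_segment()] result).
#' @export
replicate_shared_haplotype <- function(seed = 1L,
                                       shared_intervals = c(26535625L, 26933928L),
                                       n_families = 3L,
                                       marker_spacing = 7000L,
                                       maf_range = c(0.005, 0.08),
                                       carrier_background = "none") {
  target <- list(chrom = "chr10", pos = 26740001L, ref = "A", alt = "G")
  region <- c(26700000L, 26760000L) + c(-250000L, 250000L)
  sim <- simulate_family_genotypes(n_families, target, region,
                                   shared_intervals,
                                   marker_spacing = marker_spacing,
                                   maf_range = maf_range,
                                   carrier_background = carrier_background,
                                   seed = seed)
  markers <- informative_snvs(sim, maf_max = 0.1, window = 250000L)
  sets <- lapply(seq_len(n_families), function(i) cis_set(sim, i, markers))
  seg <- shared_segment(sets, markers)
  list(sim = sim, markers = markers, cis_sets = sets, segment = seg)
}
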