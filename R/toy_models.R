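# Bundled synthetic loci. These are deterministic toy gene models patterned
# on the splice defects under study (exon sizes chosen so the catalogued
# events reproduce the published gap widths: a 222 bp exon 7-8 skip and a
# 14 bp alternate acceptor on one locus; 89 bp exon-5 and 196 bp exon-4-5
# skips on the other). Sequences are random DNA with a valid CDS written
# into the exons; contig names are neutral. Everything here is synthetic.

NON_STOP_CODONS <- local({
  b <- c("A", "C", "G", "T")
  all_codons <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all_codons, c("TAA", "TAG", "TGA"))
})

#' @noRd
random_cds <- function(n_codons) {
  paste0("ATG",
         paste(sample(NON_STOP_CODONS, n_codons - 2L, replace = TRUE),
               collapse = ""),
         "TAA")
}

#' Synthetic locus replicating the PDSS1-style splice defects
#'
#' An 11-exon plus-strand toy gene with a 941 bp spliced transcript,
#' CDS at transcript 27..926 (300 codons), and a catalogue of four events:
#' canonical; inclusion of a 225 bp alternate noncanonical exon in
#' intron 5 (carrying a premature stop); complete exon 7-8 skipping
#' (222 bp, in-frame, first deleted codon 204); and a 14 bp downstream
#' alternate acceptor on exon 8 (frameshift). A tagging SNV at coding
#' position 589 (A>G) sits in exon 6, exonic in every isoform.
#'
#' @return List with `model`, `events` (named [splice_event()] list),
#'   `tag` (tagging-SNV definitions for the genome and transcript frames),
#'   `regions` (genome-frame `alt` and `anchor` depth regions).
#' @export
toy_pdss1_locus <- function() {
  exon_len <- c(100L, 80L, 90L, 70L, 85L, 210L, 120L, 102L, 30L, 24L, 30L)
  intron <- 400L
  starts <- integer(11L); starts[1L] <- 501L
  for (i in 2:11) starts[i] <- starts[i - 1L] + exon_len[i - 1L] + intron
  ex <- data.frame(start = starts, end = starts + exon_len - 1L)
  alt_iv <- c(ex$end[5L] + 66L, ex$end[5L] + 66L + 224L)  # 2591..2815
  locus_len <- ex$end[11L] + 500L
  with_local_seed(20260401L, {
    locus <- random_dna(locus_len)
    tx_seq <- paste0(random_dna(26L), random_cds(300L), random_dna(15L))
    substr(tx_seq, 615L, 615L) <- "A"   # tag site: c.589, tx 615 (exon 6)
    off <- 0L
    for (i in seq_len(11L)) {
      substr(locus, ex$start[i], ex$end[i]) <-
        substr(tx_seq, off + 1L, off + exon_len[i])
      off <- off + exon_len[i]
    }
    # alternate exon: random with an in-frame premature stop near its start
    alt_seq <- random_dna(225L)
    substr(alt_seq, 4L, 6L) <- "TAA"
    substr(locus, alt_iv[1L], alt_iv[2L]) <- alt_seq
  })
  model <- gene_model("PDSS1_toy", "chrT_pdss1", "+", ex,
                      cds_start = 27L, cds_end = 926L,
                      sequence = locus, locus_start = 1L)
  events <- list(
    canonical = splice_event("canonical", "canonical"),
    alt_exon = splice_event("alt_exon", "alt_exon_inclusion",
                            alt_interval = alt_iv),
    skip_ex7_8 = splice_event("skip_ex7_8", "exon_skip", exons = c(7L, 8L)),
    alt_acceptor_ex8 = splice_event("alt_acceptor_ex8", "alt_acceptor",
                                    exons = 8L, offset = 14L))
  tag_genomic <- ex$start[6L] + (615L - (sum(exon_len[1:5]) + 1L))  # 3115
  list(model = model, events = events,
       tag = list(cds_pos = 589L, ref = "A", alt = "G",
                  genome = list(pos = tag_genomic, ref = "A", alt = "G"),
                  transcript = list(pos = 615L, ref = "A", alt = "G")),
       regions = list(alt = alt_iv, anchor = c(ex$start[6L], ex$end[6L])))
}

#' Synthetic locus replicating the COQ5-style splice defects
#'
#' A 7-exon plus-strand toy gene (746 bp transcript, CDS 31..735) with
#' events: canonical, exon-5 skipping (89 bp, frameshift) and exon-4-5
#' skipping (196 bp). Two linked tagging SNVs in cis mark the variant
#' allele: coding positions 150 (exon 2) and 600 (exon 7), both exonic in
#' every isoform.
#'
#' @return List with `model`, `events`, `tags` (two linked SNVs with
#'   transcript-frame site definitions), and `tag_cds` positions.
#' @export
toy_coq5_locus <- function() {
  exon_len <- c(120L, 90L, 100L, 107L, 89L, 110L, 130L)
  intron <- 350L
  starts <- integer(7L); starts[1L] <- 301L
  for (i in 2:7) starts[i] <- starts[i - 1L] + exon_len[i - 1L] + intron
  ex <- data.frame(start = starts, end = starts + exon_len - 1L)
  locus_len <- ex$end[7L] + 300L
  with_local_seed(20260402L, {
    locus <- random_dna(locus_len)
    tx_seq <- paste0(random_dna(30L), random_cds(235L), random_dna(11L))
    substr(tx_seq, 180L, 180L) <- "C"  # c.150 tag (exon 2)
    substr(tx_seq, 630L, 630L) <- "C"  # c.600 linked tag (exon 7)
    off <- 0L
    for (i in seq_len(7L)) {
      substr(locus, ex$start[i], ex$end[i]) <-
        substr(tx_seq, off + 1L, off + exon_len[i])
      off <- off + exon_len[i]
    }
  })
  model <- gene_model("COQ5_toy", "chrT_coq5", "+", ex,
                      cds_start = 31L, cds_end = 735L,
                      sequence = locus, locus_start = 1L)
  events <- list(
    canonical = splice_event("canonical", "canonical"),
    exon5_skip = splice_event("exon5_skip", "exon_skip", exons = 5L),
    exon4_5_skip = splice_event("exon4_5_skip", "exon_skip", exons = c(4L, 5L)))
  list(model = model, events = events,
       tags = list(
         primary = list(cds_pos = 150L, ref = "C", alt = "T",
                        transcript = list(pos = 180L, ref = "C", alt = "T")),
         linked = list(cds_pos = 600L, ref = "C", alt = "T",
                       transcript = list(pos = 630L, ref = "C", alt = "T"))))
}
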