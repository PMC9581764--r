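# File-format interfaces. Gene models travel as a 6-column TSV (gene_id,
# chrom, strand, exon_index, start, end; genomic coordinates 1-based
# inclusive) plus an optional locus FASTA; BED12 exon structures are also
# accepted. Reads travel as FASTQ or SAM.

#' Write a gene model as TSV (plus optional locus FASTA)
#'
#' @param model A [gene_model()].
#' @param path TSV output path.
#' @param fasta_path Optional FASTA path for the locus sequence.
#' @return `path`, invisibly.
#' @export
write_gene_model_tsv <- function(model, path, fasta_path = NULL) {
  df <- data.frame(gene_id = model$gene_id, chrom = model$chrom,
                   strand = model$strand,
                   exon_index = seq_len(nrow(model$exons)),
                   start = model$exons$start, end = model$exons$end,
                   cds_start = model$cds_start, cds_end = model$cds_end,
                   locus_start = model$locus_start)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(fasta_path) && !is.null(model$sequence)) {
    ss <- Biostrings::DNAStringSet(model$sequence)
    names(ss) <- model$chrom
    Biostrings::writeXStringSet(ss, fasta_path)
  }
  invisible(path)
}

#' Read a gene model from TSV (plus optional locus FASTA)
#'
#' @param path TSV written by [write_gene_model_tsv()] (or any table with
#'   gene_id, chrom, strand, exon_index, start, end and optionally
#'   cds_start, cds_end, locus_start columns).
#' @param fasta_path Optional FASTA with the locus sequence.
#' @return A [gene_model()].
#' @export
read_gene_model_tsv <- function(path, fasta_path = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df <- df[order(df$exon_index), ]
  seq <- NULL
  if (!is.null(fasta_path)) {
    ss <- Biostrings::readDNAStringSet(fasta_path)
    seq <- as.character(ss[[1L]])
  }
  gene_model(df$gene_id[1L], df$chrom[1L], df$strand[1L],
             df[, c("start", "end")],
             cds_start = if ("cds_start" %in% names(df)) df$cds_start[1L] else NA,
             cds_end = if ("cds_end" %in% names(df)) df$cds_end[1L] else NA,
             sequence = seq,
             locus_start = if ("locus_start" %in% names(df)) df$locus_start[1L] else 1L)
}

#' Read exon structure from a BED12 record
#'
#' Accepts a BED12 file (one transcript per line) and converts the block
#' structure to a [gene_model()] exon table. CDS coordinates are left
#' undefined (BED thickStart/thickEnd are genomic, not transcript-space,
#' and are ignored here).
#'
#' @param path BED12 file.
#' @param line Which record to take (default first).
#' @return A [gene_model()] without sequence or CDS.
#' @export
read_gene_model_bed12 <- function(path, line = 1L) {
  df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 12L) stop("not a BED12 file")
  r <- df[line, ]
  chrom_start <- as.integer(r[[2L]])
  sizes <- as.integer(strsplit(sub(",$", "", r[[11L]]), ",")[[1L]])
  starts <- as.integer(strsplit(sub(",$", "", r[[12L]]), ",")[[1L]])
  ex <- data.frame(start = chrom_start + starts + 1L,
                   end = chrom_start + starts + sizes)
  strand <- as.character(r[[6L]])
  if (strand == "-") ex <- ex[rev(seq_len(nrow(ex))), ]
  gene_model(as.character(r[[4L]]), as.character(r[[1L]]), strand, ex,
             cds_start = NA, cds_end = NA)
}

#' Write simulated reads as FASTQ
#'
#' @param sim An `amplicon_sim` or a `data.frame` with `read_id`, `seq`,
#'   `qual`.
#' @param path Output FASTQ path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(sim, path) {
  reads <- if (inherits(sim, "amplicon_sim")) sim$reads else sim
  ss <- Biostrings::DNAStringSet(reads$seq)
  names(ss) <- reads$read_id
  q <- Biostrings::BStringSet(reads$qual)
  qs <- Biostrings::QualityScaledDNAStringSet(
    ss, Biostrings::PhredQuality(q))
  Biostrings::writeQualityScaledXStringSet(qs, path)
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path FASTQ path.
#' @return `data.frame` with `read_id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  qs <- Biostrings::readQualityScaledDNAStringSet(path)
  data.frame(read_id = names(qs), seq = as.character(qs),
             qual = as.character(Biostrings::quality(qs)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write simulated reads as SAM
#'
#' Minimal single-reference SAM text output of the truth alignments (no
#' installed package writes SAM text; BAM writers cannot produce a
#' text-only fixture).
#'
#' @param sim An `amplicon_sim`.
#' @param path Output SAM path.
#' @return `path`, invisibly.
#' @export
write_sam <- function(sim, path) {
  stopifnot(inherits(sim, "amplicon_sim"))
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", sim$ref_name, nchar(sim$ref_seq)))
  r <- sim$reads
  body <- sprintf("%s\t0\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t%s",
                  r$read_id, sim$ref_name, r$pos, r$cigar, r$seq, r$qual)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read alignments from SAM or BAM
#'
#' Uses Rsamtools; SAM text is converted to BAM on the fly. Secondary and
#' supplementary alignments are dropped (one vote per molecule), as are
#' unmapped reads.
#'
#' @param path `.sam` or `.bam` file.
#' @return `data.frame` with `read_id`, `pos`, `cigar`, `seq`, `qual`.
#' @export
read_alignments <- function(path) {
  if (!requireNamespace("Rsamtools", quietly = TRUE))
    stop("Rsamtools is required to read SAM/BAM input")
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                            indexDestination = FALSE)
  }
  flt <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                isSecondaryAlignment = FALSE,
                                isSupplementaryAlignment = FALSE)
  p <- Rsamtools::ScanBamParam(flag = flt,
                               what = c("qname", "pos", "cigar", "seq", "qual"))
  b <- Rsamtools::scanBam(bam, param = p)[[1L]]
  data.frame(read_id = b$qname, pos = b$pos, cigar = b$cigar,
             seq = as.character(b$seq), qual = as.character(b$qual),
             stringsAsFactors = FALSE)
}

#' Read a variant table from VCF
#'
#' Parses a (multi-sample, optionally phased) VCF into the flat variant and
#' genotype tables used by the prioritisation cascade. Consequence class
#' and gene are taken from `GENE=`/`CSQCLASS=` INFO keys when present.
#'
#' @param path VCF path (plain or gzipped).
#' @return List with `variants` (`chrom`, `pos`, `ref`, `alt`, `gene_id`,
#'   `consequence`) and `genotypes` (`sample`, `var_id`, `gt`).
#' @export
read_variants_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  info <- vcfR::getINFO(v)
  grab <- function(key) {
    m <- regmatches(info, regexpr(paste0(key, "=[^;]+"), info))
    out <- rep(NA_character_, length(info))
    hit <- grepl(paste0(key, "="), info)
    out[hit] <- sub(paste0("^", key, "="), "", m)
    out
  }
  variants <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                         ref = fix$REF, alt = fix$ALT,
                         gene_id = grab("GENE"), consequence = grab("CSQCLASS"),
                         stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v)
  keys <- variant_key(variants)
  gt_class <- function(g) {
    if (is.na(g)) return("missing")
    al <- strsplit(g, "[|/]")[[1L]]
    n_alt <- sum(al == "1")
    if (any(al == ".")) "missing"
    else if (n_alt == 0L) "hom_ref"
    else if (n_alt == length(al)) "hom_alt"
    else "het"
  }
  genotypes <- do.call(rbind, lapply(colnames(gt), function(s) {
    data.frame(sample = s, var_id = keys,
               gt = vapply(gt[, s], gt_class, character(1)),
               stringsAsFactors = FALSE)
  }))
  rownames(genotypes) <- NULL
  list(variants = variants, genotypes = genotypes)
}
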