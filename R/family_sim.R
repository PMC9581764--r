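# Multi-family phased genotype simulator around a target variant: carrier
# haplotypes carry identical rare-marker alleles across a configured shared
# interval (an ancestral segment) and independent population draws outside;
# the second haplotype is drawn independently throughout.

#' Simulate phased family genotypes around a target variant
#'
#' A common marker panel is laid across `region` at `marker_spacing`, with
#' every shared-interval endpoint pinned as a marker so truth boundaries are
#' recoverable exactly. Each family contributes one carrier sample,
#' heterozygous and phased for the target variant (alt on haplotype 1). On
#' haplotype 1 the carrier holds the rare allele at every marker inside the
#' family's shared interval and independent Bernoulli(MAF) draws outside;
#' haplotype 2 is Bernoulli(MAF) throughout.
#'
#' @param n_families Number of families.
#' @param target List with `chrom`, `pos`, `ref`, `alt` for the target
#'   variant.
#' @param region `c(start, end)` genomic span covered by the marker panel
#'   (typically gene span widened by the phasing window).
#' @param shared_intervals Either one `c(start, end)` interval shared by all
#'   carriers, or a list of per-family intervals (possibly differing, as
#'   when families share only telomeric or centromeric parts).
#' @param marker_spacing Distance between panel markers in bp.
#' @param maf_range Range for marker minor-allele frequencies.
#' @param carrier_background `"population"` (default): outside its shared
#'   interval the carrier haplotype carries rare alleles at population
#'   frequency, so coincidental identity-by-state sharing can occur, as in
#'   real data. `"none"`: the carrier haplotype carries ancestral rare
#'   alleles only, giving a controlled fixture whose shared segment equals
#'   the truth interval exactly.
#' @param seed RNG seed.
#' @return Object of class `family_sim`: `markers` (`chrom`, `pos`, `id`,
#'   `ref`, `alt`, `maf`), `families` (per family: `family_id`, `sample`,
#'   `hap1`, `hap2` 0/1 rare-allele indicators, `target_gt`), `target`,
#'   `truth_intervals`.
#' @export
simulate_family_genotypes <- function(n_families, target, region,
                                      shared_intervals,
                                      marker_spacing = 7000L,
                                      maf_range = c(0.005, 0.08),
                                      carrier_background = c("population",
                                                             "none"),
                                      seed = 1L) {
  carrier_background <- match.arg(carrier_background)
  if (region[1L] >= region[2L]) stop("interval nonempty required")
  if (marker_spacing <= 0L) stop("density <= 0")
  if (!is.list(shared_intervals))
    shared_intervals <- rep(list(shared_intervals), n_families)
  if (length(shared_intervals) != n_families)
    stop("one shared interval per family required")
  pos <- seq(as.integer(region[1L]), as.integer(region[2L]),
             by = as.integer(marker_spacing))
  pos <- sort(unique(c(pos, unlist(shared_intervals))))
  pos <- pos[pos != target$pos]
  n_mark <- length(pos)
  with_local_seed(seed, {
    maf <- stats::runif(n_mark, maf_range[1L], maf_range[2L])
    refalt <- t(vapply(seq_len(n_mark), function(i)
      sample(c("A", "C", "G", "T"), 2L), character(2)))
    markers <- data.frame(chrom = target$chrom, pos = pos,
                          id = sprintf("rs%07d", seq_len(n_mark) + 1000000L),
                          ref = refalt[, 1L], alt = refalt[, 2L],
                          maf = maf, stringsAsFactors = FALSE)
    # one draw of the ancestral haplotype state is shared across carriers
    families <- lapply(seq_len(n_families), function(f) {
      iv <- shared_intervals[[f]]
      inside <- pos >= iv[1L] & pos <= iv[2L]
      background <- if (carrier_background == "population")
        stats::rbinom(n_mark, 1L, maf) else integer(n_mark)
      hap1 <- ifelse(inside, 1L, background)
      hap2 <- stats::rbinom(n_mark, 1L, maf)
      list(family_id = sprintf("family%d", f),
           sample = sprintf("family%d_II1", f),
           hap1 = as.integer(hap1), hap2 = as.integer(hap2),
           target_gt = "1|0")
    })
    structure(list(markers = markers, families = families, target = target,
                   truth_intervals = shared_intervals),
              class = "family_sim")
  })
}

#' @export
print.family_sim <- function(x, ...) {
  cat(sprintf("<family_sim> %d families, %d markers on %s\n",
              length(x$families), nrow(x$markers), x$target$chrom))
  invisible(x)
}

#' Write one family's phased genotypes as VCF
#'
#' Emits a VCF 4.2 file (gzipped, vcfR convention) with pipe-separated
#' phased GT fields: the target variant plus every panel marker.
#'
#' @param sim A [simulate_family_genotypes()] result.
#' @param family_index Which family to write.
#' @param path Output path ending in `.vcf.gz`.
#' @return `path`, invisibly.
#' @export
write_phased_vcf <- function(sim, family_index, path) {
  fam <- sim$families[[family_index]]
  mk <- sim$markers
  all_pos <- c(sim$target$pos, mk$pos)
  ord <- order(all_pos)
  fix <- cbind(
    CHROM = rep(sim$target$chrom, length(all_pos)),
    POS = as.character(all_pos),
    ID = c(".", mk$id),
    REF = c(sim$target$ref, mk$ref),
    ALT = c(sim$target$alt, mk$alt),
    QUAL = ".", FILTER = "PASS",
    INFO = c("TARGET=1", sprintf("MAF=%.6f", mk$maf)))[ord, ]
  gt_str <- c(fam$target_gt, paste(fam$hap1, fam$hap2, sep = "|"))[ord]
  gt <- cbind(FORMAT = "GT", gt_str)
  colnames(gt) <- c("FORMAT", fam$sample)
  meta <- c("##fileformat=VCFv4.2",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Phased genotype\">",
            "##INFO=<ID=MAF,Number=1,Type=Float,Description=\"Population MAF\">",
            "##INFO=<ID=TARGET,Number=0,Type=Flag,Description=\"Target variant\">")
  v <- methods::new(methods::getClass("vcfR", where = asNamespace("vcfR")),
                    meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}

#' Read a phased family VCF back into the simulator representation
#'
#' Counterpart of [write_phased_vcf()]; the rare allele is taken to be ALT.
#'
#' @param path VCF path (plain or gzipped).
#' @param target_pos Genomic position of the target variant row.
#' @return List with `markers`, `hap1`, `hap2`, `sample`, `target_gt`.
#' @export
read_phased_vcf <- function(path, target_pos) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  fix$POS <- as.integer(fix$POS)
  gt <- vcfR::extract.gt(v)
  sample <- colnames(gt)[1L]
  maf <- suppressWarnings(as.numeric(sub("^.*MAF=([0-9.eE+-]+).*$", "\\1",
                                         vcfR::getINFO(v))))
  is_target <- fix$POS == target_pos
  haps <- do.call(rbind, strsplit(gt[, 1L], "|", fixed = TRUE))
  mk <- data.frame(chrom = fix$CHROM[!is_target], pos = fix$POS[!is_target],
                   id = fix$ID[!is_target], ref = fix$REF[!is_target],
                   alt = fix$ALT[!is_target], maf = maf[!is_target],
                   stringsAsFactors = FALSE)
  list(markers = mk,
       hap1 = as.integer(haps[!is_target, 1L]),
       hap2 = as.integer(haps[!is_target, 2L]),
       sample = sample,
       target_gt = gt[is_target, 1L][1L])
}
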