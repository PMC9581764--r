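# Rare-biallelic candidate prioritisation over the CoQ10 biosynthesis gene
# panel: panel restriction, population-frequency annotation (overall + popmax),
# the rarity/consequence-class filter with a recurrence whitelist, and
# pedigree-aware biallelic genotype detection.

CONSEQUENCE_CLASSES <- c("lof", "missense", "inframe_indel", "splice_canonical",
                         "splice_region_intronic", "synonymous", "other")

DEFAULT_KEEP_CLASSES <- c("lof", "missense", "inframe_indel",
                          "splice_canonical", "splice_region_intronic")

#' The CoQ10 biosynthesis pathway gene panel
#'
#' The 13 genes screened for candidate biallelic genotypes.
#' @return Character vector of gene symbols.
#' @export
coq10_panel <- function() {
  c("PDSS1", "PDSS2", "COQ2", "COQ3", "COQ4", "COQ5", "COQ6", "COQ7",
    "COQ8A", "COQ8B", "COQ9", "COQ10A", "COQ10B")
}

#' @noRd
variant_key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")

#' Restrict a variant table to a gene panel
#'
#' @param variants `data.frame` with at least a `gene_id` column.
#' @param panel Gene symbols to retain (default [coq10_panel()]).
#' @return The in-panel subset, order preserved.
#' @export
panel_restrict <- function(variants, panel = coq10_panel()) {
  variants[variants$gene_id %in% panel, , drop = FALSE]
}

#' Annotate population frequency (overall MAF and popmax)
#'
#' @param variants `data.frame` with `chrom`, `pos`, `ref`, `alt`.
#' @param freq_table `data.frame` with `chrom`, `pos`, `ref`, `alt`,
#'   `population` (`"ALL"` for the overall row), `allele_count`,
#'   `allele_number`.
#' @param an_floor Minimum population allele number for a population to
#'   enter the popmax (default 2000); tiny populations are excluded.
#' @return `variants` with added columns `maf` (overall), `popmax`,
#'   `popmax_population`, and `maf_display` (4 significant figures, `"-"`
#'   when absent). Variants absent from the table get `NA` frequencies and
#'   sort as rarest.
#' @export
annotate_frequency <- function(variants, freq_table, an_floor = 2000L) {
  vkey <- variant_key(variants)
  fkey <- variant_key(freq_table)
  maf <- popmax <- rep(NA_real_, nrow(variants))
  popmax_pop <- rep(NA_character_, nrow(variants))
  for (i in seq_along(vkey)) {
    rows <- freq_table[fkey == vkey[i] & freq_table$allele_number > 0L, ,
                       drop = FALSE]
    if (!nrow(rows)) next
    f <- rows$allele_count / rows$allele_number
    all_row <- rows$population == "ALL"
    if (any(all_row)) maf[i] <- f[all_row][1L]
    pops <- !all_row & rows$allele_number >= an_floor
    if (any(pops)) {
      j <- which(pops)[which.max(f[pops])]
      popmax[i] <- f[j]
      popmax_pop[i] <- rows$population[j]
    }
  }
  variants$maf <- maf
  variants$popmax <- popmax
  variants$popmax_population <- popmax_pop
  variants$maf_display <- ifelse(is.na(maf), "-",
                                 format(signif(maf, 4), scientific = FALSE))
  variants
}

#' Filter to rare protein-altering / splice-region variants
#'
#' A variant survives iff its frequency gate passes AND its consequence
#' class is in `keep_classes`. The frequency gate uses popmax when
#' population-resolved counts exist (stricter, matching how the study
#' tabulates "population maximum allele frequency"), otherwise the overall
#' MAF; variants absent from the reference are treated as rarest and kept.
#' Whitelisted recurrent variants bypass the frequency gate and are tagged
#' `frequency_exceptional`. Deep-intronic variants (beyond
#' `intron_window` bp from an exon boundary, per the `intron_distance`
#' column when present) additionally require `splice_pred_flag == TRUE`.
#'
#' @param variants Frequency-annotated variant table
#'   ([annotate_frequency()]) with a `consequence` column.
#' @param maf_threshold Rarity threshold (default 0.001).
#' @param keep_classes Consequence classes retained.
#' @param whitelist Character vector of `gene_id:hgvs_c` labels (or variant
#'   keys) exempt from the frequency gate.
#' @param intron_window Splice-region window in bp (default 25).
#' @return Surviving variants with a logical `frequency_exceptional` column.
#' @export
filter_rare <- function(variants, maf_threshold = 0.001,
                        keep_classes = DEFAULT_KEEP_CLASSES,
                        whitelist = NULL, intron_window = 25L) {
  if (!nrow(variants)) {
    variants$frequency_exceptional <- logical(0)
    return(variants)
  }
  gate_freq <- ifelse(is.na(variants$popmax), variants$maf, variants$popmax)
  rare <- is.na(gate_freq) | gate_freq < maf_threshold
  label <- if (!is.null(variants$hgvs_c))
    paste(variants$gene_id, variants$hgvs_c, sep = ":") else variant_key(variants)
  listed <- label %in% whitelist | variant_key(variants) %in% whitelist
  class_ok <- variants$consequence %in% keep_classes
  deep_ok <- rep(TRUE, nrow(variants))
  if (!is.null(variants$intron_distance)) {
    deep <- variants$consequence == "splice_region_intronic" &
      !is.na(variants$intron_distance) &
      abs(variants$intron_distance) > intron_window
    pred <- if (!is.null(variants$splice_pred_flag))
      variants$splice_pred_flag %in% TRUE else rep(FALSE, nrow(variants))
    deep_ok <- !deep | pred
  }
  keep <- (rare | listed) & class_ok & deep_ok
  out <- variants[keep, , drop = FALSE]
  out$frequency_exceptional <- (!rare & listed)[keep]
  out
}

#' @noRd
parental_origin <- function(var_key, genotypes, father, mother) {
  gt_of <- function(sample) {
    if (is.na(sample) || !nzchar(sample)) return(NA_character_)
    g <- genotypes$gt[genotypes$sample == sample & genotypes$var_id == var_key]
    if (length(g)) g[1L] else NA_character_
  }
  fg <- gt_of(father); mg <- gt_of(mother)
  carrier <- function(g) !is.na(g) && g %in% c("het", "hom_alt")
  f_has <- carrier(fg); m_has <- carrier(mg)
  if (f_has && !m_has && !is.na(mg)) "paternal"
  else if (m_has && !f_has && !is.na(fg)) "maternal"
  else if (!is.na(fg) && !is.na(mg) && !f_has && !m_has) "de_novo"
  else "unknown"
}

#' Detect biallelic candidate genotypes
#'
#' For each sample and gene among the supplied (already filtered) variants:
#' a rare homozygous variant yields a `hom` candidate; two or more
#' heterozygous variants yield `compound_het` candidates per variant pair,
#' with phase `trans` when parental genotypes place one variant on each
#' parental haplotype, `cis` when both come from one parent (such pairs are
#' demoted, not candidates), `unknown` when unphasable. Mendelian
#' inconsistency (a child allele absent from both genotyped parents) keeps
#' the candidate with a warning note.
#'
#' @param variants Filtered variant table with `gene_id` and key columns
#'   (`chrom`, `pos`, `ref`, `alt`).
#' @param genotypes `data.frame` with `sample`, `var_id` (matching
#'   `variant_key`, i.e. `chrom:pos:ref:alt`), `gt` in
#'   `c("hom_ref", "het", "hom_alt", "missing")`.
#' @param pedigree Optional `data.frame` with `sample`, `father`, `mother`
#'   (empty/NA for founders or singletons).
#' @return `data.frame` of candidates (`sample`, `gene_id`, `zygosity`,
#'   `phase`, `variants`, `notes`), with demoted cis pairs in attribute
#'   `demoted`.
#' @export
detect_biallelic <- function(variants, genotypes, pedigree = NULL) {
  vk <- variant_key(variants)
  out <- list(); demoted <- list()
  samples <- unique(genotypes$sample)
  if (!is.null(pedigree)) {
    parents <- unique(stats::na.omit(c(pedigree$father, pedigree$mother)))
    samples <- setdiff(samples, parents[nzchar(parents)])
  }
  for (s in samples) {
    gs <- genotypes[genotypes$sample == s & genotypes$var_id %in% vk, ,
                    drop = FALSE]
    if (!nrow(gs)) next
    ped <- if (!is.null(pedigree)) pedigree[pedigree$sample == s, , drop = FALSE]
    father <- if (!is.null(ped) && nrow(ped)) ped$father[1L] else NA_character_
    mother <- if (!is.null(ped) && nrow(ped)) ped$mother[1L] else NA_character_
    for (g in unique(variants$gene_id[vk %in% gs$var_id])) {
      keys <- vk[variants$gene_id == g]
      gg <- gs[gs$var_id %in% keys, , drop = FALSE]
      homs <- gg$var_id[gg$gt == "hom_alt"]
      hets <- gg$var_id[gg$gt == "het"]
      for (h in homs) {
        out[[length(out) + 1L]] <- data.frame(
          sample = s, gene_id = g, zygosity = "hom", phase = "trans",
          variants = h, notes = "", stringsAsFactors = FALSE)
      }
      if (length(hets) >= 2L) {
        prs <- utils::combn(sort(hets), 2L)
        for (k in seq_len(ncol(prs))) {
          v1 <- prs[1L, k]; v2 <- prs[2L, k]
          o1 <- parental_origin(v1, genotypes, father, mother)
          o2 <- parental_origin(v2, genotypes, father, mother)
          notes <- character(0)
          if ("de_novo" %in% c(o1, o2))
            notes <- c(notes, "mendelian_inconsistency")
          phase <-
            if (all(c(o1, o2) %in% c("paternal", "maternal")) && o1 != o2)
              "trans"
            else if (o1 %in% c("paternal", "maternal") && identical(o1, o2))
              "cis"
            else "unknown"
          row <- data.frame(sample = s, gene_id = g, zygosity = "compound_het",
                            phase = phase, variants = paste(v1, v2, sep = ";"),
                            notes = paste(notes, collapse = ";"),
                            stringsAsFactors = FALSE)
          if (phase == "cis") {
            row$notes <- paste0(row$notes, ";both variants on one parental haplotype")
            demoted[[length(demoted) + 1L]] <- row
          } else {
            out[[length(out) + 1L]] <- row
          }
        }
      }
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(sample = character(0), gene_id = character(0),
               zygosity = character(0), phase = character(0),
               variants = character(0), notes = character(0))
  attr(res, "demoted") <- if (length(demoted)) do.call(rbind, demoted) else NULL
  res
}

#' Run the full prioritisation cascade
#'
#' Panel restriction, frequency annotation, rarity/class filtering and
#' biallelic genotype detection in one call.
#'
#' @inheritParams annotate_frequency
#' @inheritParams filter_rare
#' @inheritParams detect_biallelic
#' @return See [detect_biallelic()]; the filtered variant table is attached
#'   as attribute `variants`.
#' @export
prioritize_variants <- function(variants, freq_table, genotypes,
                                pedigree = NULL, panel = coq10_panel(),
                                maf_threshold = 0.001,
                                keep_classes = DEFAULT_KEEP_CLASSES,
                                whitelist = NULL) {
  v <- panel_restrict(variants, panel)
  v <- annotate_frequency(v, freq_table)
  v <- filter_rare(v, maf_threshold, keep_classes, whitelist)
  res <- detect_biallelic(v, genotypes, pedigree)
  attr(res, "variants") <- v
  res
}
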