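# Cross-family ancestral-haplotype detection by identity-by-state of rare
# marker alleles: informative-marker selection, per-family cis sets, and
# the shared segment (global and pairwise) with boundary markers and span.

#' Select informative phasing markers
#'
#' Markers are informative when their population MAF is below `maf_max`
#' (rare enough to suggest shared ancestry), they lie within `window` bp of
#' the target position, and at least one carrier haplotype in the supplied
#' families bears the rare allele.
#'
#' @param sim A [simulate_family_genotypes()] object (or a list with the
#'   same `markers`/`families` shape built from VCF input).
#' @param maf_max Informative-marker MAF ceiling (default 0.1).
#' @param window Flanking window in bp each side of `target_pos`
#'   (default 250 kb).
#' @param target_pos Centre of the window; defaults to the target variant.
#' @return The informative subset of the marker table, position-sorted.
#' @export
informative_snvs <- function(sim, maf_max = 0.1, window = 250000L,
                             target_pos = sim$target$pos) {
  mk <- sim$markers
  keep <- mk$maf < maf_max &
    mk$pos >= target_pos - window & mk$pos <= target_pos + window
  carried <- vapply(seq_len(nrow(mk)), function(i)
    any(vapply(sim$families, function(f)
      f$hap1[i] == 1L || f$hap2[i] == 1L, logical(1))), logical(1))
  out <- mk[keep & carried, , drop = FALSE]
  out[order(out$pos), , drop = FALSE]
}

#' Markers in cis with the target variant in one family
#'
#' The carrier's target variant must be heterozygous and phased; the cis
#' set is the informative markers whose rare allele lies on the same
#' haplotype as the target's alt allele.
#'
#' @param sim A `family_sim` (or compatible) object.
#' @param family_index Which family.
#' @param markers Informative marker table from [informative_snvs()].
#' @return Object of class `cis_set`: `data.frame` with `family_id`, `pos`,
#'   `id`, `allele`.
#' @export
cis_set <- function(sim, family_index, markers) {
  fam <- sim$families[[family_index]]
  gt <- fam$target_gt
  if (!grepl("|", gt, fixed = TRUE) || !gt %in% c("0|1", "1|0"))
    stop("target unphased or not heterozygous: phase by trio or read-backed phasing first")
  target_hap <- if (gt == "1|0") fam$hap1 else fam$hap2
  idx <- match(markers$pos, sim$markers$pos)
  on_hap <- target_hap[idx] == 1L
  out <- data.frame(family_id = rep(fam$family_id, sum(on_hap)),
                    pos = markers$pos[on_hap],
                    id = markers$id[on_hap],
                    allele = markers$alt[on_hap],
                    stringsAsFactors = FALSE)
  class(out) <- c("cis_set", "data.frame")
  out
}

#' @noRd
longest_shared_run <- function(present_mat, markers) {
  shared <- rowSums(present_mat) == ncol(present_mat)
  if (!any(shared)) {
    return(list(start_pos = NA_integer_, start_id = NA_character_,
                end_pos = NA_integer_, end_id = NA_character_,
                span_bp = 0L, span_kb = 0L, n_markers = 0L))
  }
  r <- rle(shared)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- which(r$values)
  best <- runs[which.max(r$lengths[runs])]
  i1 <- starts[best]; i2 <- ends[best]
  span <- markers$pos[i2] - markers$pos[i1]
  list(start_pos = markers$pos[i1], start_id = markers$id[i1],
       end_pos = markers$pos[i2], end_id = markers$id[i2],
       span_bp = as.integer(span), span_kb = as.integer(round(span / 1000)),
       n_markers = i2 - i1 + 1L)
}

#' Shared ancestral-haplotype segment across families
#'
#' The global segment is the maximal run of consecutive informative markers
#' whose rare allele is present in every family's cis set, reported by its
#' outermost markers; the span is the distance between those boundary
#' marker positions (`span_bp = end - start`, `span_kb` rounded to integer).
#' A pairwise report gives the analogous segment for every family pair. An
#' empty intersection yields an empty segment; the pairwise report is still
#' emitted.
#'
#' @param cis_sets List of >= 1 [cis_set()] results.
#' @param markers The informative marker table the cis sets were drawn from
#'   (defines marker adjacency).
#' @return Object of class `haplotype_segment`: `segment` (boundary
#'   markers, `span_bp`, `span_kb`, `n_markers`), `pairwise` (`data.frame`
#'   per family pair), `families`, `note`.
#' @export
shared_segment <- function(cis_sets, markers) {
  if (!length(cis_sets)) stop("at least one cis set required")
  fam_ids <- vapply(cis_sets, function(s) s$family_id[1L], character(1))
  present <- vapply(cis_sets, function(s) markers$pos %in% s$pos,
                    logical(nrow(markers)))
  present <- matrix(present, nrow = nrow(markers))
  note <- NULL
  if (length(cis_sets) == 1L)
    note <- "single family: segment is its own cis set"
  seg <- longest_shared_run(present, markers)
  pairwise <- NULL
  if (length(cis_sets) >= 2L) {
    prs <- utils::combn(seq_along(cis_sets), 2L)
    pairwise <- do.call(rbind, lapply(seq_len(ncol(prs)), function(k) {
      i <- prs[1L, k]; j <- prs[2L, k]
      ps <- longest_shared_run(present[, c(i, j), drop = FALSE], markers)
      data.frame(family_a = fam_ids[i], family_b = fam_ids[j],
                 start_pos = ps$start_pos, start_id = ps$start_id,
                 end_pos = ps$end_pos, end_id = ps$end_id,
                 span_bp = ps$span_bp, span_kb = ps$span_kb,
                 n_markers = ps$n_markers, stringsAsFactors = FALSE)
    }))
  }
  structure(list(segment = seg, pairwise = pairwise, families = fam_ids,
                 note = note),
            class = "haplotype_segment")
}

#' @export
print.haplotype_segment <- function(x, ...) {
  s <- x$segment
  if (is.na(s$start_pos)) {
    cat("<haplotype_segment> empty shared segment\n")
  } else {
    cat(sprintf("<haplotype_segment> %s (%d) .. %s (%d): %d bp (~%d kb), %d markers, %d families\n",
                s$start_id, s$start_pos, s$end_id, s$end_pos, s$span_bp,
                s$span_kb, s$n_markers, length(x$families)))
  }
  invisible(x)
}
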