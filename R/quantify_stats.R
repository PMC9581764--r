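# Allele-resolved quantification: per-allele splice-event fractions, the
# read-depth inclusion metric, comparison against a control cohort, and the
# plasma CoQ10 reference-range flag.

#' Per-allele splice-event fractions
#'
#' Joins event calls and allele calls on read id and tabulates, per allele,
#' the fraction of classified reads assigned to each event. Reads with a
#' missing/other allele call or an unclassified event are tallied separately
#' and excluded from the denominators (the unassigned remainder gets
#' explicit bookkeeping rather than being forced to sum to 100%).
#'
#' @param event_calls [classify_reads()] output.
#' @param allele_calls [call_alleles()] output.
#' @param allele_labels Optional named vector mapping the call statuses
#'   `c(ref = ..., alt = ...)` to display allele ids.
#' @return `data.frame` of class `quant_table` with columns `allele_id`,
#'   `event_id`, `read_count`, `fraction`; attributes `totals` (classified
#'   reads per allele) and `unassigned` (counts of reads excluded and why).
#' @export
per_allele_fractions <- function(event_calls, allele_calls,
                                 allele_labels = c(ref = "ref", alt = "alt")) {
  m <- merge(event_calls[, c("read_id", "event_id")],
             allele_calls[, c("read_id", "status")], by = "read_id")
  usable <- m$status %in% c("ref", "alt") & m$event_id != "unclassified"
  unassigned <- c(
    allele_missing = sum(!m$status %in% c("ref", "alt")),
    event_unclassified = sum(m$status %in% c("ref", "alt") &
                               m$event_id == "unclassified"))
  mu <- m[usable, ]
  mu$allele_id <- unname(allele_labels[mu$status])
  if (!nrow(mu))
    stop("zero classified reads: per-allele fractions undefined")
  tab <- as.data.frame(table(allele_id = mu$allele_id, event_id = mu$event_id),
                       stringsAsFactors = FALSE)
  names(tab)[3L] <- "read_count"
  totals <- tapply(tab$read_count, tab$allele_id, sum)
  if (any(totals == 0))
    warning("allele with zero classified reads: fraction undefined for ",
            paste(names(totals)[totals == 0], collapse = ", "))
  tab$fraction <- tab$read_count / as.numeric(totals[tab$allele_id])
  tab <- tab[order(tab$allele_id, tab$event_id), ]
  rownames(tab) <- NULL
  structure(tab, totals = totals, unassigned = unassigned,
            class = c("quant_table", "data.frame"))
}

#' @export
print.quant_table <- function(x, ...) {
  y <- as.data.frame(x)
  y$fraction <- sprintf("%.2f%%", 100 * y$fraction)
  print(y, row.names = FALSE)
  un <- attr(x, "unassigned")
  cat(sprintf("unassigned: %d allele-missing, %d unclassified\n",
              un[["allele_missing"]], un[["event_unclassified"]]))
  invisible(x)
}

#' @noRd
region_depth <- function(reads, region) {
  lo <- as.integer(region[1L]); hi <- as.integer(region[2L])
  cov <- numeric(hi - lo + 1L)
  for (i in seq_len(nrow(reads))) {
    ops <- parse_cigar(reads$cigar[i])
    cur <- as.integer(reads$pos[i])
    for (j in seq_len(nrow(ops))) {
      op <- ops$op[j]; len <- ops$len[j]
      if (op %in% c("M", "=", "X")) {
        a <- max(cur, lo); b <- min(cur + len - 1L, hi)
        if (a <= b) cov[(a - lo + 1L):(b - lo + 1L)] <-
            cov[(a - lo + 1L):(b - lo + 1L)] + 1
        cur <- cur + len
      } else if (op %in% c("D", "N")) {
        cur <- cur + len
      }
    }
  }
  cov
}

#' Read-depth inclusion of an alternate region
#'
#' Computes per-base depth from aligned blocks (gaps contribute zero) and
#' the inclusion fraction of the alternate region. Under the default
#' `"anchor"` convention this is `mean(depth(alt)) / mean(depth(anchor))`
#' where the anchor is a canonical region covered by every full-length
#' amplicon; under `"competing"` it is
#' `mean(alt) / (mean(alt) + mean(anchor))`.
#'
#' @param reads `data.frame` with `pos` and `cigar` (e.g. one allele's
#'   reads), or an `amplicon_sim`.
#' @param alt_region,anchor_region `c(start, end)` reference intervals
#'   (1-based inclusive) in the alignment frame in use; must not overlap.
#' @param convention `"anchor"` or `"competing"`.
#' @return List of class `inclusion_result`: `inclusion`, `mean_alt_depth`,
#'   `mean_anchor_depth`, `convention`, `alt_region`, `anchor_region`.
#' @export
depth_inclusion <- function(reads, alt_region, anchor_region,
                            convention = c("anchor", "competing")) {
  convention <- match.arg(convention)
  if (inherits(reads, "amplicon_sim")) reads <- reads$reads
  if (alt_region[1L] > alt_region[2L] || anchor_region[1L] > anchor_region[2L])
    stop("regions must be nonempty")
  if (max(alt_region[1L], anchor_region[1L]) <=
      min(alt_region[2L], anchor_region[2L]))
    stop("alt and anchor regions must not overlap")
  d_alt <- mean(region_depth(reads, alt_region))
  d_anchor <- mean(region_depth(reads, anchor_region))
  if (d_anchor == 0 && convention == "anchor")
    stop("zero anchor depth: inclusion undefined")
  incl <- switch(convention,
    anchor = d_alt / d_anchor,
    competing = if (d_alt + d_anchor == 0) NA_real_
                else d_alt / (d_alt + d_anchor))
  structure(list(inclusion = incl, mean_alt_depth = d_alt,
                 mean_anchor_depth = d_anchor, convention = convention,
                 alt_region = alt_region, anchor_region = anchor_region),
            class = "inclusion_result")
}

#' @export
print.inclusion_result <- function(x, ...) {
  cat(sprintf("<inclusion_result> %.2f%% (%s convention; alt %.1fx / anchor %.1fx)\n",
              100 * x$inclusion, x$convention, x$mean_alt_depth,
              x$mean_anchor_depth))
  invisible(x)
}

#' Allele-grouped inclusion
#'
#' Groups reads by their allele call at a phasing SNV and computes
#' [depth_inclusion()] per allele group.
#'
#' @param reads Read set (`data.frame` or `amplicon_sim`).
#' @param allele_calls [call_alleles()] output.
#' @param alt_region,anchor_region,convention See [depth_inclusion()].
#' @param allele_labels Names for the ref/alt groups.
#' @return Named list of `inclusion_result`, one per allele.
#' @export
allele_inclusion <- function(reads, allele_calls, alt_region, anchor_region,
                             convention = "anchor",
                             allele_labels = c(ref = "ref", alt = "alt")) {
  if (inherits(reads, "amplicon_sim")) reads <- reads$reads
  out <- list()
  for (st in c("ref", "alt")) {
    ids <- allele_calls$read_id[allele_calls$status == st]
    grp <- reads[reads$read_id %in% ids, , drop = FALSE]
    if (!nrow(grp)) next
    out[[unname(allele_labels[st])]] <-
      depth_inclusion(grp, alt_region, anchor_region, convention)
  }
  out
}

#' Compare a case inclusion value to a control cohort
#'
#' @param case_fraction Case inclusion fraction (0-1 scale).
#' @param control_fractions Control inclusion fractions (>= 1 value).
#' @return List with `case`, `control_min`, `control_max`, `control_mean`,
#'   and `flagged` (`TRUE` iff the case lies strictly outside the control
#'   min-max range; boundaries inclusive).
#' @export
compare_to_controls <- function(case_fraction, control_fractions) {
  if (!length(control_fractions)) stop("at least one control required")
  lo <- min(control_fractions); hi <- max(control_fractions)
  list(case = case_fraction, control_min = lo, control_max = hi,
       control_mean = mean(control_fractions),
       flagged = case_fraction < lo || case_fraction > hi)
}

#' Flag a plasma CoQ10 concentration against the reference range
#'
#' @param value Concentration in nmol/L (>= 0).
#' @param range Reference range `c(low, high)`, boundaries inclusive.
#' @return `"below"`, `"within"` or `"above"`.
#' @export
flag_plasma_coq10 <- function(value, range = c(227, 1432)) {
  if (value < 0) stop("concentration must be nonnegative")
  if (value < range[1L]) "below"
  else if (value > range[2L]) "above"
  else "within"
}
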