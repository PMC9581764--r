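# Per-read splice classification: junction-chain extraction from CIGAR
# strings, catalogue matching with coordinate tolerance, allele calling at a
# phasing SNV, and cis/trans phasing via linked SNVs. The classifier is
# frame-agnostic: transcript-frame gaps are D operations, genome-frame gaps
# are N operations, and both become the same JunctionChain representation.

#' @noRd
parse_cigar <- function(cigar) {
  if (is.na(cigar) || cigar == "" || cigar == "*")
    return(data.frame(op = character(0), len = integer(0)))
  m <- gregexpr("\\d+[MIDNSHP=X]", cigar)[[1L]]
  toks <- regmatches(cigar, list(m))[[1L]]
  data.frame(op = substring(toks, nchar(toks), nchar(toks)),
             len = as.integer(substring(toks, 1L, nchar(toks) - 1L)))
}

#' Extract the junction chain of one aligned read
#'
#' Every D or N CIGAR operation of length >= `min_gap` becomes a gap;
#' shorter deletions are treated as alignment noise and absorbed. Gap
#' coordinates are reference-space: `donor` is the first gapped base,
#' `acceptor` the first aligned base after the gap, so
#' `acceptor - donor` is the gap width.
#'
#' @param cigar CIGAR string.
#' @param pos 1-based reference start of the alignment.
#' @param min_gap Minimum deletion length treated as a splice gap.
#' @return A `data.frame` (class `junction_chain`) with columns `donor`,
#'   `acceptor`, `width`, plus attribute `gapped_length`.
#' @export
extract_junction_chain <- function(cigar, pos, min_gap = 20L) {
  ops <- parse_cigar(cigar)
  cur <- as.integer(pos)
  donors <- integer(0); acceptors <- integer(0)
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; len <- ops$len[i]
    if (op %in% c("M", "=", "X")) {
      cur <- cur + len
    } else if (op %in% c("D", "N")) {
      if (len >= min_gap) {
        donors <- c(donors, cur)
        acceptors <- c(acceptors, cur + len)
      }
      cur <- cur + len
    }
    # I, S, H, P consume no reference
  }
  out <- data.frame(donor = donors, acceptor = acceptors,
                    width = acceptors - donors)
  attr(out, "gapped_length") <- sum(out$width)
  class(out) <- c("junction_chain", "data.frame")
  out
}

#' Expected junction chains for an event catalogue
#'
#' Derives, for each catalogued event, the junction chain a perfectly
#' aligned full-length amplicon read of that isoform would show in the
#' given alignment frame.
#'
#' @param model A [gene_model()].
#' @param events Named list of [splice_event()]s including a canonical entry.
#' @param frame `"transcript"` or `"genome"`.
#' @param min_gap Gap threshold, matching the one used at read level.
#' @return Named list of `junction_chain` objects, in catalogue order.
#' @export
event_catalogue <- function(model, events, frame = c("transcript", "genome"),
                            min_gap = 20L) {
  frame <- match.arg(frame)
  if (!length(events)) stop("configuration error: empty event catalogue")
  canonical <- build_transcript(model)
  out <- lapply(events, function(ev) {
    tx <- apply_splice_event(canonical, ev)$transcript
    al <- template_alignment(canonical, tx, frame)
    extract_junction_chain(ops_to_cigar(al$ops), al$pos, min_gap = min_gap)
  })
  if (!any(vapply(events, function(e) e$kind == "canonical", logical(1))))
    stop("configuration error: catalogue lacks a canonical chain")
  out
}

#' Classify one junction chain against the catalogue
#'
#' A read matches an event when the chains have the same number of gaps and
#' every donor/acceptor boundary agrees within `tol` bp. Among multiple
#' matches the smallest total boundary deviation wins; remaining ties go to
#' catalogue order. No match yields `"unclassified"`.
#'
#' @param chain A [extract_junction_chain()] result.
#' @param catalogue An [event_catalogue()].
#' @param tol Per-boundary tolerance in bp.
#' @return List with `event_id` and `deviation` (total boundary deviation in
#'   bp, `NA` for unclassified).
#' @export
classify_chain <- function(chain, catalogue, tol = 5L) {
  if (!length(catalogue)) stop("configuration error: empty event catalogue")
  best <- NULL; best_dev <- Inf
  for (ev_id in names(catalogue)) {
    exp <- catalogue[[ev_id]]
    if (nrow(exp) != nrow(chain)) next
    if (nrow(exp) == 0L) {
      dev <- 0L
    } else {
      dd <- abs(chain$donor - exp$donor)
      da <- abs(chain$acceptor - exp$acceptor)
      if (any(dd > tol) || any(da > tol)) next
      dev <- sum(dd) + sum(da)
    }
    if (dev < best_dev) { best <- ev_id; best_dev <- dev }
  }
  if (is.null(best)) list(event_id = "unclassified", deviation = NA_integer_)
  else list(event_id = best, deviation = as.integer(best_dev))
}

#' Classify every read of a simulated or imported read set
#'
#' @param reads A `data.frame` with `read_id`, `pos`, `cigar` columns, or an
#'   `amplicon_sim` object.
#' @param catalogue An [event_catalogue()].
#' @param min_gap,tol See [extract_junction_chain()] and [classify_chain()].
#' @return `data.frame` with `read_id`, `event_id`, `deviation`.
#' @export
classify_reads <- function(reads, catalogue, min_gap = 20L, tol = 5L) {
  if (inherits(reads, "amplicon_sim")) reads <- reads$reads
  res <- lapply(seq_len(nrow(reads)), function(i) {
    ch <- extract_junction_chain(reads$cigar[i], reads$pos[i], min_gap)
    classify_chain(ch, catalogue, tol)
  })
  data.frame(read_id = reads$read_id,
             event_id = vapply(res, `[[`, character(1), "event_id"),
             deviation = vapply(res, `[[`, integer(1), "deviation"),
             stringsAsFactors = FALSE)
}

#' Call the allele of one read at a phasing SNV
#'
#' Walks the CIGAR to the query base aligned to the site. Insertions at the
#' site do not shift the call; a deleted or soft-clipped site, a site
#' outside the alignment, or a base below `min_baseq` yields `"missing"`.
#'
#' @param pos,cigar,seq,qual Alignment fields of one read.
#' @param site List or data.frame row with `pos` (reference coordinate in
#'   the alignment frame), `ref`, `alt`.
#' @param min_baseq Minimum base quality (Phred) for a usable call.
#' @return List with `status` (`"ref"`, `"alt"`, `"other"`, `"missing"`),
#'   `base`, `baseq`, and `reason` for missing calls.
#' @export
call_allele <- function(pos, cigar, seq, qual, site, min_baseq = 7L) {
  target <- as.integer(site$pos)
  ops <- parse_cigar(cigar)
  ref_cur <- as.integer(pos)
  q_cur <- 1L
  for (i in seq_len(nrow(ops))) {
    op <- ops$op[i]; len <- ops$len[i]
    if (op %in% c("M", "=", "X")) {
      if (target >= ref_cur && target < ref_cur + len) {
        qi <- q_cur + (target - ref_cur)
        base <- substr(seq, qi, qi)
        bq <- utf8ToInt(substr(qual, qi, qi)) - 33L
        if (bq < min_baseq)
          return(list(status = "missing", base = base, baseq = bq,
                      reason = "low_quality"))
        status <- if (base == site$ref) "ref"
                  else if (base == site$alt) "alt" else "other"
        return(list(status = status, base = base, baseq = bq, reason = NA))
      }
      ref_cur <- ref_cur + len; q_cur <- q_cur + len
    } else if (op %in% c("D", "N")) {
      if (target >= ref_cur && target < ref_cur + len)
        return(list(status = "missing", base = NA_character_,
                    baseq = NA_integer_, reason = "deleted"))
      ref_cur <- ref_cur + len
    } else if (op %in% c("I", "S")) {
      q_cur <- q_cur + len
    }
  }
  list(status = "missing", base = NA_character_, baseq = NA_integer_,
       reason = "outside_alignment")
}

#' Call alleles for a whole read set
#'
#' @param reads `data.frame` with `read_id`, `pos`, `cigar`, `seq`, `qual`,
#'   or an `amplicon_sim`.
#' @param site Site definition, see [call_allele()].
#' @param min_baseq Minimum base quality.
#' @return `data.frame` with `read_id`, `status`, `base`, `baseq`.
#' @export
call_alleles <- function(reads, site, min_baseq = 7L) {
  if (inherits(reads, "amplicon_sim")) reads <- reads$reads
  res <- lapply(seq_len(nrow(reads)), function(i)
    call_allele(reads$pos[i], reads$cigar[i], reads$seq[i], reads$qual[i],
                site, min_baseq))
  data.frame(read_id = reads$read_id,
             status = vapply(res, `[[`, character(1), "status"),
             base = vapply(res, function(r) as.character(r$base), character(1)),
             baseq = vapply(res, function(r) as.integer(r$baseq %||% NA_integer_),
                            integer(1)),
             stringsAsFactors = FALSE)
}

#' Cis/trans verdict from a 2x2 co-occurrence table
#'
#' @param tab 2x2 matrix of allele co-occurrence counts, rows = site A
#'   (ref, alt), columns = site B (ref, alt).
#' @param odds_threshold Concordant:discordant odds required for a verdict.
#' @return `"cis"`, `"trans"` or `"ambiguous"`.
#' @export
phase_verdict <- function(tab, odds_threshold = 4) {
  conc <- tab[1L, 1L] + tab[2L, 2L]
  disc <- tab[1L, 2L] + tab[2L, 1L]
  if (conc >= odds_threshold * disc && conc > disc) "cis"
  else if (disc >= odds_threshold * conc && disc > conc) "trans"
  else "ambiguous"
}

#' Phase two SNV sites from read-backed co-occurrence
#'
#' Builds the 2x2 co-occurrence table of allele calls at two sites over
#' reads informative at both, and returns a cis/trans verdict: cis when
#' concordant pairs (ref-ref + alt-alt) exceed discordant pairs by
#' `odds_threshold`, trans for the reverse, ambiguous otherwise or when
#' fewer than `min_reads` doubly-informative reads exist.
#'
#' @param calls_a,calls_b [call_alleles()] results for the two sites.
#' @param min_reads Minimum doubly-informative reads for a verdict.
#' @param odds_threshold Concordant:discordant odds required (default 4).
#' @return List with `table` (2x2 matrix), `verdict`, `n_informative`,
#'   `n_excluded`, and `haplotypes` (per-read labels `"ref_hap"`/`"alt_hap"`
#'   in the site-A frame; verdict-discordant or uncallable molecules are
#'   `NA`).
#' @export
phase_by_linked_snv <- function(calls_a, calls_b, min_reads = 20L,
                                odds_threshold = 4) {
  m <- merge(calls_a[, c("read_id", "status")],
             calls_b[, c("read_id", "status")],
             by = "read_id", suffixes = c("_a", "_b"))
  inf <- m$status_a %in% c("ref", "alt") & m$status_b %in% c("ref", "alt")
  tab <- matrix(0L, 2L, 2L,
                dimnames = list(a = c("ref", "alt"), b = c("ref", "alt")))
  mi <- m[inf, ]
  for (va in c("ref", "alt")) for (vb in c("ref", "alt"))
    tab[va, vb] <- sum(mi$status_a == va & mi$status_b == vb)
  n_inf <- sum(inf)
  if (n_inf < min_reads) {
    warning("fewer than min_reads doubly-informative reads; verdict ambiguous")
    verdict <- "ambiguous"
  } else {
    verdict <- phase_verdict(tab, odds_threshold)
  }
  # per-read haplotype labels in the site-A frame: doubly-informative reads
  # must agree with the verdict (discordant molecules stay unresolved);
  # singly-informative reads use the one callable site, mapping site B
  # through the verdict
  a_inf <- m$status_a %in% c("ref", "alt")
  b_inf <- m$status_b %in% c("ref", "alt")
  b_as_a <- if (verdict == "trans")
    ifelse(m$status_b == "ref", "alt", "ref") else m$status_b
  hap <- rep(NA_character_, nrow(m))
  both <- a_inf & b_inf
  agree <- both & m$status_a == b_as_a
  hap[agree] <- paste0(m$status_a[agree], "_hap")
  hap[a_inf & !b_inf] <- paste0(m$status_a[a_inf & !b_inf], "_hap")
  if (verdict != "ambiguous")
    hap[!a_inf & b_inf] <- paste0(b_as_a[!a_inf & b_inf], "_hap")
  list(table = tab, verdict = verdict, n_informative = n_inf,
       n_excluded = nrow(m) - n_inf,
       haplotypes = data.frame(read_id = m$read_id, haplotype = hap,
                               stringsAsFactors = FALSE))
}
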