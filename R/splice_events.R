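# Splice-event specifications, their application to a transcript, and
# protein-level consequence annotation (HGVS-p-lite).

SPLICE_EVENT_KINDS <- c("canonical", "exon_skip", "alt_acceptor", "alt_donor",
                        "alt_exon_inclusion", "intron_retention")

#' Describe a catalogued mis-splicing event
#'
#' @param event_id Identifier used throughout classification and truth tables.
#' @param kind One of `"canonical"`, `"exon_skip"`, `"alt_acceptor"`,
#'   `"alt_donor"`, `"alt_exon_inclusion"`, `"intron_retention"`.
#' @param exons Exon indices removed (`exon_skip`) or the single exon whose
#'   acceptor/donor moves (`alt_acceptor`/`alt_donor`).
#' @param offset Signed base-pair shift of the splice site along the
#'   transcription direction. A positive acceptor offset moves the acceptor
#'   into the exon (trimming it, as in "alternate splice acceptor site 14 bp
#'   downstream"); a positive donor offset extends the exon into the intron.
#' @param alt_interval Genomic `c(start, end)` of an alternate noncanonical
#'   exon (`alt_exon_inclusion`); must fall inside one intron.
#' @param intron Intron index retained (`intron_retention`); intron `i` lies
#'   between exons `i` and `i + 1`.
#' @return An object of class `splice_event`.
#' @export
splice_event <- function(event_id, kind, exons = NULL, offset = NULL,
                         alt_interval = NULL, intron = NULL) {
  kind <- match.arg(kind, SPLICE_EVENT_KINDS)
  if (kind %in% c("alt_acceptor", "alt_donor")) {
    if (is.null(offset) || offset == 0L)
      stop("event-spec error: alt splice-site offset must be a nonzero integer")
  }
  if (kind == "alt_exon_inclusion" && (is.null(alt_interval) ||
      length(alt_interval) != 2L))
    stop("event-spec error: alt_exon_inclusion requires a genomic interval")
  structure(list(event_id = event_id, kind = kind,
                 exons = if (!is.null(exons)) as.integer(exons),
                 offset = if (!is.null(offset)) as.integer(offset),
                 alt_interval = if (!is.null(alt_interval)) as.integer(alt_interval),
                 intron = if (!is.null(intron)) as.integer(intron)),
            class = "splice_event")
}

#' @noRd
modified_exon_table <- function(model, event) {
  ex <- model$exons
  n <- nrow(ex)
  plus <- model$strand == "+"
  switch(event$kind,
    canonical = ex,
    exon_skip = {
      idx <- event$exons
      if (is.null(idx) || any(idx < 1L | idx > n))
        stop("event-spec error: skip references absent exon")
      ex[-idx, , drop = FALSE]
    },
    alt_acceptor = {
      i <- event$exons
      if (is.null(i) || length(i) != 1L || i < 1L || i > n)
        stop("event-spec error: alt_acceptor references absent exon")
      o <- event$offset
      if (plus) ex$start[i] <- ex$start[i] + o else ex$end[i] <- ex$end[i] - o
      if (ex$end[i] < ex$start[i])
        stop("event-spec error: acceptor offset consumes the whole exon")
      ex
    },
    alt_donor = {
      i <- event$exons
      if (is.null(i) || length(i) != 1L || i < 1L || i > n)
        stop("event-spec error: alt_donor references absent exon")
      o <- event$offset
      if (plus) ex$end[i] <- ex$end[i] + o else ex$start[i] <- ex$start[i] - o
      if (ex$end[i] < ex$start[i])
        stop("event-spec error: donor offset consumes the whole exon")
      ex
    },
    alt_exon_inclusion = {
      ai <- sort(event$alt_interval)
      # must sit inside one intron (transcription order)
      place <- NA_integer_
      for (i in seq_len(n - 1L)) {
        intron <- if (plus) c(ex$end[i] + 1L, ex$start[i + 1L] - 1L)
                  else c(ex$end[i + 1L] + 1L, ex$start[i] - 1L)
        if (ai[1L] >= intron[1L] && ai[2L] <= intron[2L]) { place <- i; break }
      }
      if (is.na(place))
        stop("event-spec error: alternate exon overlaps catalogued exons or lies outside introns")
      newrow <- data.frame(start = ai[1L], end = ai[2L])
      rbind(ex[seq_len(place), , drop = FALSE], newrow,
            ex[seq(place + 1L, n), , drop = FALSE])
    },
    intron_retention = {
      i <- event$intron
      if (is.null(i) || i < 1L || i >= n)
        stop("event-spec error: retained intron index absent")
      merged <- data.frame(start = min(ex$start[i], ex$start[i + 1L]),
                           end = max(ex$end[i], ex$end[i + 1L]))
      rbind(if (i > 1L) ex[seq_len(i - 1L), , drop = FALSE],
            merged,
            if (i + 1L < n) ex[seq(i + 2L, n), , drop = FALSE])
    }
  )
}

#' Apply a splice event to a transcript
#'
#' Rewrites the exon chain according to the event, rebuilds the spliced
#' transcript and reports the net length change. The CDS start of the
#' modified transcript is re-anchored at the genomic base that carried the
#' original CDS start; if that base is spliced out the modified transcript
#' has `cds_start = NA` and consequence annotation will refuse it.
#'
#' @param transcript A `transcript_model`.
#' @param event A [splice_event()].
#' @return A list with `transcript` (modified `transcript_model`), `delta`
#'   (net spliced-length change in bp) and `event`.
#' @export
apply_splice_event <- function(transcript, event) {
  stopifnot(inherits(transcript, "transcript_model"),
            inherits(event, "splice_event"))
  model <- transcript$model
  new_ex <- modified_exon_table(model, event)
  new_model <- gene_model(model$gene_id, model$chrom, model$strand, new_ex,
                          cds_start = NA_integer_, cds_end = NA_integer_,
                          sequence = model$sequence,
                          locus_start = model$locus_start)
  mod <- build_transcript(new_model)
  delta <- mod$spliced_length - transcript$spliced_length
  # re-anchor CDS start
  cds_start <- NA_integer_
  if (!is.na(transcript$cds_start)) {
    g <- tx_to_genomic(transcript, transcript$cds_start)
    hit <- tryCatch(map_coordinate(mod, g), error = function(e) NULL)
    if (!is.null(hit) && hit$status == "exonic") cds_start <- hit$tx_pos
  }
  mod$cds_start <- cds_start
  mod$cds_end <- if (is.na(cds_start)) NA_integer_ else mod$spliced_length
  mod$model$cds_start <- mod$cds_start
  mod$model$cds_end <- mod$cds_end
  list(transcript = mod, delta = as.integer(delta), event = event)
}

#' @noRd
exon_iranges <- function(transcript) {
  et <- transcript$exon_table
  IRanges::IRanges(start = pmin(et$start, et$end),
                   end = pmax(et$start, et$end))
}

#' Annotate the protein-level consequence of a splice change
#'
#' Compares an original and a modified transcript sharing the same CDS
#' anchor and classifies the coding outcome: `no_change`,
#' `inframe_deletion`, `inframe_insertion`, `frameshift` or `stop_gain`.
#' HGVS-p output is a constrained subset ("HGVS-p-lite"):
#' `p.(XaaN_XaaMdel)`, `p.(XaaN*)`, `p.(XaaNYyyfs*K)`; deletions are not
#' repositioned by the HGVS 3'-rule. The first affected codon is derived
#' from the structural (coordinate-level) difference between the two exon
#' chains, so codon-aligned deletions report their true genomic bounds.
#'
#' @param original,modified `transcript_model` objects with sequences; the
#'   modified transcript normally comes from [apply_splice_event()].
#' @return An object of class `protein_consequence` with fields `category`,
#'   `first_affected_codon`, `hgvs_p`, `deleted_codons`, `fs_stop_offset`.
#' @export
annotate_consequence <- function(original, modified) {
  stopifnot(inherits(original, "transcript_model"),
            inherits(modified, "transcript_model"))
  if (is.null(original$seq) || is.null(modified$seq))
    stop("consequence-unavailable error: transcript has no sequence")
  if (is.na(original$cds_start) || is.na(modified$cds_start))
    stop("consequence-unavailable error: CDS anchor lost by the splice change")

  orig_cds <- substr(original$seq, original$cds_start, original$spliced_length)
  mod_cds <- substr(modified$seq, modified$cds_start, modified$spliced_length)
  p_o <- translate_to_stop(orig_cds)
  p_m <- translate_to_stop(mod_cds, require_atg = FALSE)

  delta <- modified$spliced_length - original$spliced_length
  if (delta == 0L && identical(original$seq, modified$seq)) {
    return(structure(list(category = "no_change", first_affected_codon = NA_integer_,
                          hgvs_p = "", deleted_codons = NA_integer_,
                          fs_stop_offset = NA_integer_),
                     class = "protein_consequence"))
  }

  # structural diff in the original's transcript frame
  ir_o <- exon_iranges(original)
  ir_m <- exon_iranges(modified)
  deleted <- IRanges::setdiff(ir_o, ir_m)    # genomic bases lost
  inserted <- IRanges::setdiff(ir_m, ir_o)   # genomic bases gained
  change_tx <- integer(0)
  if (length(deleted)) {
    bounds <- cbind(IRanges::start(deleted), IRanges::end(deleted))
    change_tx <- c(change_tx, apply(bounds, 1L, function(b) {
      min(map_coordinate(original, b[1L])$tx_pos,
          map_coordinate(original, b[2L])$tx_pos)
    }))
  }
  if (length(inserted)) {
    # impact point: the first original base at/after the insertion site
    bounds <- cbind(IRanges::start(inserted), IRanges::end(inserted))
    change_tx <- c(change_tx, apply(bounds, 1L, function(b) {
      m1 <- map_coordinate(modified, b[1L])
      m2 <- map_coordinate(modified, b[2L])
      first_mod_tx <- min(m1$tx_pos, m2$tx_pos)
      # next canonical base after the inserted block in modified coords
      nxt <- first_mod_tx + (abs(b[2L] - b[1L]) + 1L)
      if (nxt > modified$spliced_length) return(original$spliced_length)
      g <- tx_to_genomic(modified, nxt)
      hit <- tryCatch(map_coordinate(original, g), error = function(e) NULL)
      if (!is.null(hit) && hit$status == "exonic") hit$tx_pos
      else original$spliced_length
    }))
  }
  if (!length(change_tx)) {
    return(structure(list(category = "no_change", first_affected_codon = NA_integer_,
                          hgvs_p = "", deleted_codons = NA_integer_,
                          fs_stop_offset = NA_integer_),
                     class = "protein_consequence"))
  }
  first_change_tx <- min(change_tx)
  if (first_change_tx < original$cds_start) {
    # change confined to the 5' UTR leaves the protein alone
    if (identical(p_o$aa, p_m$aa)) {
      return(structure(list(category = "no_change",
                            first_affected_codon = NA_integer_, hgvs_p = "",
                            deleted_codons = NA_integer_,
                            fs_stop_offset = NA_integer_),
                       class = "protein_consequence"))
    }
    first_change_tx <- original$cds_start
  }
  fa <- (first_change_tx - original$cds_start) %/% 3L + 1L

  res_orig <- function(i) if (i <= length(p_o$aa)) p_o$aa[i] else "?"
  mod_codon_start <- modified$cds_start + 3L * (fa - 1L)
  mod_codon <- substr(modified$seq, mod_codon_start, mod_codon_start + 2L)
  mod_codon_is_stop <- nchar(mod_codon) == 3L &&
    !is.na(Biostrings::GENETIC_CODE[mod_codon]) &&
    Biostrings::GENETIC_CODE[mod_codon] == "*"

  if (mod_codon_is_stop) {
    hg <- sprintf("p.(%s%d*)", aa3(res_orig(fa)), fa)
    return(structure(list(category = "stop_gain", first_affected_codon = fa,
                          hgvs_p = hg, deleted_codons = NA_integer_,
                          fs_stop_offset = NA_integer_),
                     class = "protein_consequence"))
  }

  if (delta %% 3L == 0L) {
    expected_len <- length(p_o$aa) + delta %/% 3L
    premature <- !p_m$terminated || length(p_m$aa) != expected_len
    if (!premature) {
      if (delta < 0L) {
        k <- (-delta) %/% 3L
        hg <- sprintf("p.(%s%d_%s%ddel)", aa3(res_orig(fa)), fa,
                      aa3(res_orig(fa + k - 1L)), fa + k - 1L)
        return(structure(list(category = "inframe_deletion",
                              first_affected_codon = fa, hgvs_p = hg,
                              deleted_codons = k, fs_stop_offset = NA_integer_),
                         class = "protein_consequence"))
      } else {
        k <- delta %/% 3L
        hg <- sprintf("p.(%s%d_%s%dins%d)", aa3(res_orig(fa - 1L)), fa - 1L,
                      aa3(res_orig(fa)), fa, k)
        return(structure(list(category = "inframe_insertion",
                              first_affected_codon = fa, hgvs_p = hg,
                              deleted_codons = NA_integer_,
                              fs_stop_offset = NA_integer_),
                         class = "protein_consequence"))
      }
    }
    # in-frame length change but a new stop appeared downstream
    stop_codon <- length(p_m$aa) + 1L
    hg <- sprintf("p.(%s%d*)", aa3(res_orig(stop_codon)), stop_codon)
    return(structure(list(category = "stop_gain",
                          first_affected_codon = stop_codon, hgvs_p = hg,
                          deleted_codons = NA_integer_,
                          fs_stop_offset = NA_integer_),
                     class = "protein_consequence"))
  }

  # frameshift
  new_res <- if (fa <= length(p_m$aa)) p_m$aa[fa] else "?"
  fs_off <- if (p_m$terminated) p_m$stop_index - fa + 1L else NA_integer_
  hg <- sprintf("p.(%s%d%sfs*%s)", aa3(res_orig(fa)), fa, aa3(new_res),
                if (is.na(fs_off)) "?" else fs_off)
  structure(list(category = "frameshift", first_affected_codon = fa,
                 hgvs_p = hg, deleted_codons = NA_integer_,
                 fs_stop_offset = fs_off),
            class = "protein_consequence")
}

#' @export
print.protein_consequence <- function(x, ...) {
  cat(sprintf("<protein_consequence> %s %s\n", x$category, x$hgvs_p))
  invisible(x)
}
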