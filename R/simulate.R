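# Synthetic amplicon read generator: per-allele mixtures of canonical and
# mis-spliced full-length RT-PCR amplicons, allele-tagging SNVs, and a
# nanopore-flavoured substitution/indel error model. Every read carries a
# truth label so each downstream stage can be scored exactly.

#' Nanopore-like per-base error model
#'
#' Default rates (substitution 0.03, insertion 0.01, deletion 0.02) are a
#' nanopore-flavoured stand-in, not calibrated to any basecaller. All rates
#' zero reproduces templates exactly.
#'
#' @param substitution_rate,insertion_rate,deletion_rate Per-base
#'   probabilities, each in `[0, 0.2]`.
#' @param quality_mean Constant Phred quality written to FASTQ output.
#' @param seed Integer seed used by simulation functions that take this model.
#' @return An object of class `error_model`.
#' @export
error_model <- function(substitution_rate = 0.03, insertion_rate = 0.01,
                        deletion_rate = 0.02, quality_mean = 12L, seed = 1L) {
  rates <- c(substitution_rate, insertion_rate, deletion_rate)
  if (any(rates < 0) || any(rates > 0.2))
    stop("error-model rates must lie in [0, 0.2]")
  structure(list(substitution_rate = substitution_rate,
                 insertion_rate = insertion_rate,
                 deletion_rate = deletion_rate,
                 quality_mean = as.integer(quality_mean),
                 seed = as.integer(seed)),
            class = "error_model")
}

#' Per-allele amplicon specification
#'
#' @param allele_id Allele label (e.g. `"A"`/`"G"` for a tagging SNV).
#' @param isoform_mixture Named numeric vector of event fractions; must be
#'   nonnegative and sum to 1 (tolerance 1e-9).
#' @param tag_snvs `data.frame` with columns `cds_pos` (coding coordinate of
#'   the tagging SNV on the canonical transcript), `ref`, `alt`, `carries`
#'   (`"ref"` or `"alt"`: the base this allele writes into its reads).
#' @param copy_fraction Fraction of total reads drawn from this allele.
#' @return An object of class `allele_spec`.
#' @export
allele_spec <- function(allele_id, isoform_mixture, tag_snvs = NULL,
                        copy_fraction = 1) {
  if (is.null(names(isoform_mixture)) || any(!nzchar(names(isoform_mixture))))
    stop("isoform_mixture must be a named vector of event fractions")
  if (any(isoform_mixture < 0))
    stop("isoform_mixture fractions must be nonnegative")
  if (abs(sum(isoform_mixture) - 1) > 1e-9)
    stop("isoform_mixture fractions must sum to 1")
  if (!is.null(tag_snvs))
    stopifnot(all(c("cds_pos", "ref", "alt", "carries") %in% names(tag_snvs)))
  structure(list(allele_id = allele_id,
                 isoform_mixture = isoform_mixture[order(names(isoform_mixture))],
                 tag_snvs = tag_snvs,
                 copy_fraction = copy_fraction),
            class = "allele_spec")
}

#' Largest-remainder apportionment of n among named fractions
#'
#' Ties in the fractional remainders are broken by lexical order of the
#' names, so printed study percentages are representable exactly.
#' @noRd
largest_remainder <- function(n, fracs) {
  fracs <- fracs[order(names(fracs))]
  raw <- n * fracs
  base <- floor(raw + 1e-9)
  rem <- raw - base
  short <- n - sum(base)
  if (short > 0L) {
    take <- order(-rem, names(fracs))[seq_len(short)]
    base[take] <- base[take] + 1L
  }
  stats::setNames(as.integer(base), names(fracs))
}

#' Realize per-event read counts for one allele
#'
#' @param n_reads Total reads for the allele (> 0).
#' @param mixture Named event fractions summing to 1.
#' @param mode `"exact"` (largest-remainder rounding, deterministic) or
#'   `"multinomial"` (random draw under the current RNG state).
#' @return Named integer vector of counts summing to `n_reads`.
#' @export
realize_counts <- function(n_reads, mixture, mode = c("exact", "multinomial")) {
  mode <- match.arg(mode)
  if (n_reads <= 0L) stop("n_reads must be > 0")
  if (abs(sum(mixture) - 1) > 1e-9) stop("mixture must sum to 1")
  mixture <- mixture[order(names(mixture))]
  if (mode == "exact") {
    largest_remainder(n_reads, mixture)
  } else {
    stats::setNames(as.integer(stats::rmultinom(1L, n_reads, mixture)),
                    names(mixture))
  }
}

# --- template machinery -----------------------------------------------------

#' Alignment of a modified transcript against a reference frame
#'
#' Genome frame: the read aligns to the locus; exon blocks are M operations
#' separated by N gaps (spliced introns). Transcript frame: the read aligns
#' to the canonical spliced transcript; spliced-out canonical bases are D
#' operations and novel bases (alternate exon, retained intron) are I.
#' @noRd
template_alignment <- function(canonical, modified, frame) {
  if (frame == "genome") {
    if (canonical$model$strand != "+")
      stop("genome-frame simulation supports plus-strand models only")
    et <- modified$exon_table
    n <- nrow(et)
    ops <- data.frame(op = "M", len = et$end - et$start + 1L)
    if (n > 1L) {
      gaps <- data.frame(op = "N", len = et$start[-1L] - et$end[-n] - 1L)
      ord <- integer(2L * n - 1L)
      ord[seq(1L, 2L * n - 1L, by = 2L)] <- seq_len(n)
      out <- ops[0L, ]
      for (i in seq_len(n)) {
        out <- rbind(out, ops[i, ])
        if (i < n && gaps$len[i] > 0L) out <- rbind(out, gaps[i, ])
      }
      ops <- out
    }
    return(list(pos = et$start[1L], ops = ops))
  }
  # transcript frame
  ir_c <- exon_iranges(canonical)
  ir_m <- exon_iranges(modified)
  segs <- IRanges::disjoin(c(ir_c, ir_m))
  in_c <- IRanges::overlapsAny(segs, ir_c)
  in_m <- IRanges::overlapsAny(segs, ir_m)
  ord <- order(IRanges::start(segs),
               decreasing = canonical$model$strand == "-")
  segs <- segs[ord]; in_c <- in_c[ord]; in_m <- in_m[ord]
  op <- ifelse(in_c & in_m, "M", ifelse(in_c, "D", "I"))
  len <- IRanges::width(segs)
  # strip leading/trailing deletions (an aligner reports none) and soft-clip
  # any leading/trailing insertions
  while (length(op) && op[1L] == "D") { op <- op[-1L]; len <- len[-1L]; segs <- segs[-1L] }
  while (length(op) && op[length(op)] == "D") {
    keep <- seq_len(length(op) - 1L); op <- op[keep]; len <- len[keep]; segs <- segs[keep]
  }
  if (length(op) && op[1L] == "I") op[1L] <- "S"
  if (length(op) && op[length(op)] == "I") op[length(op)] <- "S"
  first_m <- which(op == "M")[1L]
  if (is.na(first_m)) stop("event leaves no aligned bases in transcript frame")
  gfirst <- if (canonical$model$strand == "+") IRanges::start(segs)[first_m]
            else IRanges::end(segs)[first_m]
  pos <- map_coordinate(canonical, gfirst)$tx_pos
  # merge adjacent identical ops
  r <- rle(op)
  len_m <- vapply(seq_along(r$values), function(i) {
    sum(len[cumsum(c(0L, r$lengths))[i] + seq_len(r$lengths[i])])
  }, integer(1))
  list(pos = pos, ops = data.frame(op = r$values, len = len_m))
}

#' @noRd
ops_to_cigar <- function(ops) paste0(ops$len, ops$op, collapse = "")

#' @noRd
other_base <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L)

#' Apply the error model to one template read
#' @noRd
mutate_read <- function(qchars, opu, err) {
  qpos <- which(opu %in% c("M", "I", "S"))
  nq <- length(qpos)
  qchar_unit <- rep(NA_character_, length(opu))
  qchar_unit[qpos] <- qchars
  keep <- rep(TRUE, length(opu))
  opu2 <- opu
  del <- stats::runif(nq) < err$deletion_rate
  is_m <- opu[qpos] == "M"
  opu2[qpos[del & is_m]] <- "D"
  qchar_unit[qpos[del & is_m]] <- NA_character_
  keep[qpos[del & !is_m]] <- FALSE
  surv <- !del
  sub <- surv & (stats::runif(nq) < err$substitution_rate)
  if (any(sub))
    qchar_unit[qpos[sub]] <- vapply(qchar_unit[qpos[sub]], other_base,
                                    character(1))
  ins <- surv & (stats::runif(nq) < err$insertion_rate)
  ids <- c(seq_along(opu)[keep], qpos[ins] + 0.5)
  ops_all <- c(opu2[keep], rep("I", sum(ins)))
  chars_all <- c(qchar_unit[keep],
                 if (sum(ins)) vapply(seq_len(sum(ins)), function(i)
                   sample(c("A", "C", "G", "T"), 1L), character(1)))
  o <- order(ids)
  ops_f <- ops_all[o]
  chars_f <- chars_all[o]
  r <- rle(ops_f)
  list(seq = paste(chars_f[!is.na(chars_f)], collapse = ""),
       cigar = paste0(r$lengths, r$values, collapse = ""))
}

#' Simulate a full-length amplicon read set
#'
#' Every read is a primer-to-primer amplicon of one isoform template with
#' the allele's tagging bases substituted, then passed through the error
#' model. The output carries both the reads (with their truth alignments in
#' the requested frame) and a complete truth table.
#'
#' @param model A [gene_model()] with sequence.
#' @param events Named list of [splice_event()]s; names are event ids and
#'   must cover every id used in the allele mixtures. A `"canonical"` entry
#'   is conventional.
#' @param alleles List of [allele_spec()]s.
#' @param n_reads Total number of reads across alleles (> 0); apportioned to
#'   alleles by largest-remainder on their `copy_fraction`s.
#' @param err An [error_model()].
#' @param frame `"transcript"` (reads align to the canonical spliced
#'   transcript; gaps are D) or `"genome"` (reads align to the locus; gaps
#'   are N).
#' @param mode Count realization mode, see [realize_counts()].
#' @param seed Seed for all randomness in this call; defaults to the error
#'   model's seed.
#' @return A list of class `amplicon_sim`: `reads` (data.frame with
#'   `read_id`, `pos`, `cigar`, `seq`, `qual`), `truth` (`read_id`,
#'   `allele_id`, `event_id`, `strand`), `frame`, `ref_name`, `ref_seq`,
#'   `transcript` (canonical `transcript_model`), `counts`.
#' @export
simulate_reads <- function(model, events, alleles, n_reads,
                           err = error_model(),
                           frame = c("transcript", "genome"),
                           mode = c("exact", "multinomial"),
                           seed = err$seed) {
  frame <- match.arg(frame)
  mode <- match.arg(mode)
  if (n_reads <= 0L) stop("n_reads must be > 0")
  stopifnot(length(alleles) >= 1L)
  canonical <- build_transcript(model)

  # per-isoform modified transcripts and truth alignments
  iso_ids <- sort(unique(unlist(lapply(alleles, function(a)
    names(a$isoform_mixture)))))
  missing_ev <- setdiff(iso_ids, names(events))
  if (length(missing_ev))
    stop("event-spec error: mixture references uncatalogued events: ",
         paste(missing_ev, collapse = ", "))
  iso <- lapply(events[iso_ids], function(ev)
    apply_splice_event(canonical, ev)$transcript)
  aln <- lapply(iso, template_alignment, canonical = canonical, frame = frame)

  # allele-tagged template sequences; untaggable isoforms are rejected
  templates <- list()
  for (a in alleles) {
    for (ev_id in names(a$isoform_mixture)) {
      tx <- iso[[ev_id]]
      s <- tx$seq
      if (!is.null(a$tag_snvs) && nrow(a$tag_snvs)) {
        for (k in seq_len(nrow(a$tag_snvs))) {
          site_tx <- a$tag_snvs$cds_pos[k] + canonical$cds_start - 1L
          g <- tx_to_genomic(canonical, site_tx)
          hit <- tryCatch(map_coordinate(tx, g), error = function(e) NULL)
          if (is.null(hit) || hit$status != "exonic")
            stop(sprintf(
              "untaggable isoform: tag SNV c.%d is not exonic in event '%s'",
              a$tag_snvs$cds_pos[k], ev_id))
          base <- if (a$tag_snvs$carries[k] == "alt") a$tag_snvs$alt[k]
                  else a$tag_snvs$ref[k]
          substr(s, hit$tx_pos, hit$tx_pos) <- base
        }
      }
      templates[[paste(a$allele_id, ev_id, sep = "\r")]] <- s
    }
  }

  copy_fracs <- vapply(alleles, function(a) a$copy_fraction, numeric(1))
  names(copy_fracs) <- vapply(alleles, function(a) a$allele_id, character(1))
  copy_fracs <- copy_fracs / sum(copy_fracs)

  with_local_seed(seed, {
    n_allele <- largest_remainder(n_reads, copy_fracs)
    rows <- list()
    counts_tab <- list()
    ridx <- 0L
    noiseless <- err$substitution_rate == 0 && err$insertion_rate == 0 &&
      err$deletion_rate == 0
    for (a in alleles) {
      counts <- realize_counts(n_allele[[a$allele_id]], a$isoform_mixture, mode)
      counts_tab[[a$allele_id]] <- counts
      for (ev_id in names(counts)) {
        cnt <- counts[[ev_id]]
        if (cnt == 0L) next
        tmpl_seq <- templates[[paste(a$allele_id, ev_id, sep = "\r")]]
        al <- aln[[ev_id]]
        tmpl_cigar <- ops_to_cigar(al$ops)
        opu <- rep(al$ops$op, al$ops$len)
        qchars <- strsplit(tmpl_seq, "")[[1L]]
        for (j in seq_len(cnt)) {
          ridx <- ridx + 1L
          if (noiseless) {
            sq <- tmpl_seq; cg <- tmpl_cigar
          } else {
            m <- mutate_read(qchars, opu, err)
            sq <- m$seq; cg <- m$cigar
          }
          rows[[ridx]] <- data.frame(
            read_id = sprintf("read%06d", ridx),
            allele_id = a$allele_id, event_id = ev_id,
            pos = al$pos, cigar = cg, seq = sq,
            qual = strrep(intToUtf8(err$quality_mean + 33L), nchar(sq)),
            stringsAsFactors = FALSE)
        }
      }
    }
    reads <- do.call(rbind, rows)
    rownames(reads) <- NULL
    truth <- data.frame(read_id = reads$read_id, allele_id = reads$allele_id,
                        event_id = reads$event_id, strand = "+",
                        stringsAsFactors = FALSE)
    structure(list(reads = reads[, c("read_id", "pos", "cigar", "seq", "qual")],
                   truth = truth, frame = frame,
                   ref_name = if (frame == "genome") model$chrom
                              else paste0(model$gene_id, "_tx"),
                   ref_seq = if (frame == "genome") model$sequence
                             else canonical$seq,
                   transcript = canonical,
                   counts = counts_tab),
              class = "amplicon_sim")
  })
}

#' @export
print.amplicon_sim <- function(x, ...) {
  cat(sprintf("<amplicon_sim> %d reads, %s frame, ref %s\n",
              nrow(x$reads), x$frame, x$ref_name))
  invisible(x)
}

#' Simulate a control cohort with basal alternate-exon inclusion
#'
#' Each control sample draws its inclusion fraction uniformly from `band`
#' (default 0.065-0.1014, the basal mis-splicing range observed in control
#' RNA) and then emits reads like [simulate_reads()].
#'
#' @param model,events,err,frame,mode See [simulate_reads()].
#' @param alt_event_id Event id of the basal mis-splicing isoform.
#' @param band Two-element inclusion band, `band[1] <= band[2]`.
#' @param k_samples Number of control samples (> 0).
#' @param n_reads Reads per control sample.
#' @param seed Master seed; sample `i` uses `seed + i`.
#' @return List with `samples` (list of `amplicon_sim`) and `inclusion`
#'   (the truth inclusion fraction drawn for each control).
#' @export
simulate_control_cohort <- function(model, events, alt_event_id,
                                    band = c(0.065, 0.1014), k_samples = 6L,
                                    n_reads = 2000L, err = error_model(),
                                    frame = "genome", mode = "exact",
                                    seed = err$seed) {
  if (length(band) != 2L || band[1L] > band[2L])
    stop("empty inclusion band")
  if (k_samples <= 0L) stop("k_samples must be > 0")
  incl <- with_local_seed(seed, stats::runif(k_samples, band[1L], band[2L]))
  samples <- lapply(seq_len(k_samples), function(i) {
    mix <- c(incl[i], 1 - incl[i])
    names(mix) <- c(alt_event_id, "canonical")
    ctrl <- allele_spec(sprintf("control%02d", i), mix)
    simulate_reads(model, events, list(ctrl), n_reads, err = err,
                   frame = frame, mode = mode, seed = seed + i)
  })
  list(samples = samples, inclusion = incl)
}
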