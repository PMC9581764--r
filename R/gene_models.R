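# Gene and transcript models: ordered exon structures with CDS anchoring,
# genomic <-> transcript coordinate mapping, and spliced sequence assembly.
#
# Conventions (documented once, used everywhere):
#   * genomic coordinates are 1-based inclusive (VCF/HGVS style);
#   * transcript coordinates are 1-based from the transcription start;
#   * exons are stored in transcription order (for minus-strand genes that
#     means decreasing genomic coordinates).

#' Construct a gene model
#'
#' @param gene_id Gene identifier.
#' @param chrom Contig name.
#' @param strand `"+"` or `"-"`.
#' @param exons `data.frame` with columns `start`, `end` (genomic, 1-based
#'   inclusive, `start <= end` within each row), rows in transcription order.
#' @param cds_start,cds_end CDS boundaries in transcript coordinates
#'   (1-based offsets into the spliced transcript).
#' @param sequence Optional reference sequence for the locus. Genomic
#'   position `p` corresponds to `substr(sequence, p - locus_start + 1, ...)`.
#' @param locus_start Genomic position of the first base of `sequence`.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, chrom, strand, exons, cds_start, cds_end,
                       sequence = NULL, locus_start = 1L) {
  stopifnot(is.data.frame(exons), all(c("start", "end") %in% names(exons)))
  strand <- match.arg(strand, c("+", "-"))
  exons <- data.frame(start = as.integer(exons$start),
                      end = as.integer(exons$end))
  if (any(exons$end < exons$start))
    stop("structural-model error: exon end < start")
  n <- nrow(exons)
  if (n == 0L) stop("structural-model error: no exons")
  if (n > 1L) {
    if (strand == "+") {
      ok <- all(exons$start[-1L] > exons$end[-n])
    } else {
      ok <- all(exons$end[-1L] < exons$start[-n])
    }
    if (!ok)
      stop("structural-model error: exons overlap or are not in transcription order")
  }
  spliced <- sum(exons$end - exons$start + 1L)
  cds_start <- as.integer(cds_start); cds_end <- as.integer(cds_end)
  if (!is.na(cds_start) && !is.na(cds_end)) {
    if (cds_start < 1L || cds_start > cds_end || cds_end > spliced)
      stop("structural-model error: CDS outside spliced transcript")
  }
  if (!is.null(sequence)) {
    locus_end <- locus_start + nchar(sequence) - 1L
    if (min(exons$start) < locus_start || max(exons$end) > locus_end)
      stop("structural-model error: exons outside provided sequence")
  }
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 exons = exons, cds_start = cds_start, cds_end = cds_end,
                 sequence = sequence, locus_start = as.integer(locus_start)),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s%s) %d exon(s), spliced length %d\n",
              x$gene_id, x$chrom, x$strand, nrow(x$exons),
              sum(x$exons$end - x$exons$start + 1L)))
  invisible(x)
}

#' @noRd
locus_subseq <- function(model, start, end) {
  if (is.null(model$sequence)) return(NULL)
  substr(model$sequence, start - model$locus_start + 1L,
         end - model$locus_start + 1L)
}

#' Build a spliced transcript from a gene model
#'
#' Produces the spliced sequence (reverse-complemented for minus-strand
#' genes), the cumulative exon-offset table and the junction chain: one
#' (donor, acceptor) genomic coordinate pair per intron, in transcription
#' order. Donor is the last exonic base of the upstream exon, acceptor the
#' first exonic base of the downstream exon.
#'
#' @param model A [gene_model()].
#' @return An object of class `transcript_model`.
#' @export
build_transcript <- function(model) {
  stopifnot(inherits(model, "gene_model"))
  ex <- model$exons
  len <- ex$end - ex$start + 1L
  tx_end <- cumsum(len)
  tx_start <- tx_end - len + 1L
  n <- nrow(ex)
  if (n > 1L) {
    if (model$strand == "+") {
      junctions <- data.frame(donor = ex$end[-n], acceptor = ex$start[-1L])
    } else {
      junctions <- data.frame(donor = ex$start[-n], acceptor = ex$end[-1L])
    }
  } else {
    junctions <- data.frame(donor = integer(0), acceptor = integer(0))
  }
  seq <- NULL
  if (!is.null(model$sequence)) {
    pieces <- vapply(seq_len(n), function(i) {
      s <- locus_subseq(model, ex$start[i], ex$end[i])
      if (model$strand == "-") revcomp(s) else s
    }, character(1))
    seq <- paste(pieces, collapse = "")
  }
  structure(list(model = model,
                 exon_table = cbind(ex, tx_start = tx_start, tx_end = tx_end),
                 junctions = junctions,
                 seq = seq,
                 cds_start = model$cds_start,
                 cds_end = model$cds_end,
                 spliced_length = sum(len)),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s: %d bp spliced, %d junction(s)\n",
              x$model$gene_id, x$spliced_length, nrow(x$junctions)))
  invisible(x)
}

#' Map a genomic position onto a transcript
#'
#' Exonic positions return their 1-based transcript coordinate (plus the CDS
#' offset when a CDS is defined). Intronic positions return the signed
#' HGVS-style offset to the nearest exon boundary: positive counted from the
#' upstream donor (`c.N+k`), negative counted back from the downstream
#' acceptor (`c.N-k`). Ties go to the donor side.
#'
#' @param transcript A [build_transcript()] result.
#' @param pos Genomic position (1-based).
#' @return A list with `status` (`"exonic"`/`"intronic"`), `tx_pos`
#'   (exonic), and for intronic positions `offset` and `anchor_tx_pos`.
#' @export
map_coordinate <- function(transcript, pos) {
  stopifnot(inherits(transcript, "transcript_model"))
  et <- transcript$exon_table
  strand <- transcript$model$strand
  dirsign <- if (strand == "+") 1L else -1L
  span <- range(c(et$start, et$end))
  if (pos < span[1L] || pos > span[2L])
    stop("out-of-range error: position outside locus span")
  hit <- which(pos >= et$start & pos <= et$end)
  if (length(hit) == 1L) {
    i <- hit
    tx_pos <- if (strand == "+") et$tx_start[i] + (pos - et$start[i])
              else et$tx_start[i] + (et$end[i] - pos)
    out <- list(status = "exonic", tx_pos = as.integer(tx_pos))
    if (!is.na(transcript$cds_start))
      out$cds_pos <- as.integer(tx_pos - transcript$cds_start + 1L)
    return(out)
  }
  # intronic: locate flanking exons in transcription order
  n <- nrow(et)
  for (i in seq_len(n - 1L)) {
    donor <- if (strand == "+") et$end[i] else et$start[i]
    acceptor <- if (strand == "+") et$start[i + 1L] else et$end[i + 1L]
    d_donor <- (pos - donor) * dirsign
    d_acceptor <- (acceptor - pos) * dirsign
    if (d_donor > 0L && d_acceptor > 0L) {
      if (d_donor <= d_acceptor) {
        return(list(status = "intronic", offset = as.integer(d_donor),
                    anchor_tx_pos = as.integer(et$tx_end[i])))
      } else {
        return(list(status = "intronic", offset = -as.integer(d_acceptor),
                    anchor_tx_pos = as.integer(et$tx_start[i + 1L])))
      }
    }
  }
  stop("out-of-range error: position not mappable")  # nocov
}

#' Map a transcript coordinate back to genomic space
#'
#' Inverse of [map_coordinate()] on exonic positions.
#' @param transcript A `transcript_model`.
#' @param tx_pos Transcript coordinate (1-based).
#' @return Genomic position (integer).
#' @export
tx_to_genomic <- function(transcript, tx_pos) {
  et <- transcript$exon_table
  i <- which(tx_pos >= et$tx_start & tx_pos <= et$tx_end)
  if (length(i) != 1L)
    stop("out-of-range error: transcript position outside spliced transcript")
  if (transcript$model$strand == "+")
    as.integer(et$start[i] + (tx_pos - et$tx_start[i]))
  else
    as.integer(et$end[i] - (tx_pos - et$tx_start[i]))
}
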