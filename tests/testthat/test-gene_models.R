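# Transcript assembly, coordinate mapping, splice-event application and
# protein-consequence annotation.

test_that("spliced transcript length, junctions and strand handling", {
  m <- make_toy_model(c(10L, 20L, 30L))
  tx <- build_transcript(m)
  expect_equal(tx$spliced_length, 60L)
  expect_equal(nrow(tx$junctions), 2L)
  expect_equal(tx$junctions$donor, m$exons$end[1:2])
  expect_equal(tx$junctions$acceptor, m$exons$start[2:3])

  single <- make_toy_model(40L)
  expect_equal(nrow(build_transcript(single)$junctions), 0L)

  # minus strand: genomic exon sequences AAA then CCC splice to GGGTTT
  locus <- "AAAGCGCCC"
  minus <- gene_model("mini", "chrT", "-",
                      data.frame(start = c(7L, 1L), end = c(9L, 3L)),
                      NA, NA, sequence = locus)
  expect_equal(build_transcript(minus)$seq, "GGGTTT")

  expect_error(gene_model("bad", "chrT", "+",
                          data.frame(start = c(1, 5), end = c(10, 20)),
                          NA, NA),
               "structural-model")
})

test_that("coordinate mapping round-trips and reports HGVS-style intron offsets", {
  m <- make_toy_model(c(50L, 60L, 70L), cds_start = 10L, cds_end = 160L)
  tx <- build_transcript(m)
  expect_equal(map_coordinate(tx, m$exons$start[1L])$tx_pos, 1L)
  # position 7 bp upstream of the exon-2 acceptor: intronic, offset -7
  hit <- map_coordinate(tx, m$exons$start[2L] - 7L)
  expect_equal(hit$status, "intronic")
  expect_equal(hit$offset, -7L)
  expect_equal(hit$anchor_tx_pos, 51L)
  # round-trip identity on random exonic positions
  set.seed(11)
  for (p in sample(tx$spliced_length, 20L)) {
    expect_equal(map_coordinate(tx, tx_to_genomic(tx, p))$tx_pos, p)
  }
  expect_error(map_coordinate(tx, m$exons$start[1L] - 5L), "out-of-range")
})

test_that("splice events change length by their delta and rewire junctions", {
  m <- make_toy_model(c(100L, 90L, 89L, 80L, 70L))
  tx <- build_transcript(m)
  sk <- apply_splice_event(tx, splice_event("skip3", "exon_skip", exons = 3L))
  expect_equal(sk$delta, -89L)
  # junction chain now joins exon-2 donor to exon-4 acceptor
  expect_true(any(sk$transcript$junctions$donor == m$exons$end[2L] &
                  sk$transcript$junctions$acceptor == m$exons$start[4L]))

  aa <- apply_splice_event(tx, splice_event("aa", "alt_acceptor",
                                            exons = 4L, offset = 14L))
  expect_equal(aa$delta, -14L)

  can <- apply_splice_event(tx, splice_event("canonical", "canonical"))
  expect_equal(can$delta, 0L)
  expect_equal(can$transcript$exon_table, tx$exon_table)

  expect_error(apply_splice_event(tx, splice_event("bad", "exon_skip",
                                                   exons = 9L)),
               "event-spec")
})

test_that("spliced-length conservation holds for every event kind", {
  loc <- toy_pdss1_locus()
  tx <- build_transcript(loc$model)
  evs <- c(loc$events,
           list(ret = splice_event("ret", "intron_retention", intron = 3L),
                don = splice_event("don", "alt_donor", exons = 2L,
                                   offset = 9L)))
  for (ev in evs) {
    ap <- apply_splice_event(tx, ev)
    expect_equal(ap$transcript$spliced_length, tx$spliced_length + ap$delta,
                 info = ev$event_id)
  }
})

test_that("in-frame deletions report the deleted codon count", {
  cds <- make_cds(20L)                      # 60 nt across two 30 nt exons
  m <- make_toy_model(c(30L, 30L), cds_start = 1L, cds_end = 60L,
                      tx_seq = cds)
  tx <- build_transcript(m)
  ap <- apply_splice_event(tx, splice_event("aa6", "alt_acceptor",
                                            exons = 2L, offset = 6L))
  cq <- annotate_consequence(tx, ap$transcript)
  expect_equal(cq$category, "inframe_deletion")
  expect_equal(cq$deleted_codons, 2L)
  expect_equal(cq$first_affected_codon, 11L)
  expect_match(cq$hgvs_p, "^p\\.\\([A-Z][a-z]{2}11_[A-Z][a-z]{2}12del\\)$")
})

test_that("frameshift stop offset matches an independent translation", {
  skip_if_not_installed("seqinr")
  loc <- toy_pdss1_locus()
  tx <- build_transcript(loc$model)
  ap <- apply_splice_event(tx, loc$events$alt_acceptor_ex8)   # -14 bp
  cq <- annotate_consequence(tx, ap$transcript)
  expect_equal(cq$category, "frameshift")
  mod <- ap$transcript
  orc <- oracle_translate(substr(mod$seq, mod$cds_start, mod$spliced_length))
  expect_equal(cq$fs_stop_offset, orc$stop_index - cq$first_affected_codon + 1L)
})

test_that("a skip fusing codons into a stop is a stop gain", {
  # exon1 ends mid-codon on T, exon3 starts with AA: skipping exon2 fuses TAA
  e1 <- paste0(make_cds(11L) |> substr(1L, 30L), "T")          # 31 nt
  e2 <- substr(make_cds(12L, seed = 8L), 4L, 33L)              # 30 nt
  e3 <- paste0("AA", substr(make_cds(12L, seed = 9L), 4L, 27L), "TAA")  # 29 nt
  m <- make_toy_model(c(31L, 30L, 29L), cds_start = 1L, cds_end = 90L,
                      tx_seq = paste0(e1, e2, e3))
  tx <- build_transcript(m)
  ap <- apply_splice_event(tx, splice_event("skip2", "exon_skip", exons = 2L))
  cq <- annotate_consequence(tx, ap$transcript)
  expect_equal(cq$category, "stop_gain")
  expect_equal(cq$first_affected_codon, 11L)
  expect_match(cq$hgvs_p, "^p\\.\\([A-Z][a-z]{2}11\\*\\)$")
})

test_that("consequence trichotomy agrees with translation on random events", {
  skip_if_not_installed("seqinr")
  loc <- toy_pdss1_locus()
  tx <- build_transcript(loc$model)
  set.seed(42)
  n_checked <- 0L
  for (rep in seq_len(100L)) {
    kind <- sample(c("exon_skip", "alt_acceptor", "alt_donor",
                     "intron_retention"), 1L)
    ev <- switch(kind,
      exon_skip = {
        i <- sample(2:10, 1L)
        splice_event("e", "exon_skip", exons = i:min(i + sample(0:1, 1L), 10L))
      },
      alt_acceptor = splice_event("e", "alt_acceptor", exons = sample(2:11, 1L),
                                  offset = sample(c(-30:-1, 1:20), 1L)),
      alt_donor = splice_event("e", "alt_donor", exons = sample(1:10, 1L),
                               offset = sample(c(-20:-1, 1:30), 1L)),
      intron_retention = splice_event("e", "intron_retention",
                                      intron = sample(1:10, 1L)))
    ap <- apply_splice_event(tx, ev)
    cq <- annotate_consequence(tx, ap$transcript)
    expect_true(cq$category %in% c("no_change", "inframe_deletion",
                                   "inframe_insertion", "frameshift",
                                   "stop_gain"))
    mod <- ap$transcript
    orc <- oracle_translate(substr(mod$seq, mod$cds_start, mod$spliced_length))
    ref <- oracle_translate(substr(tx$seq, tx$cds_start, tx$spliced_length))
    if (cq$category == "inframe_deletion") {
      expect_equal(ap$delta %% 3L, 0L)
      expect_equal(length(orc$aa), length(ref$aa) - cq$deleted_codons)
    }
    if (cq$category == "inframe_insertion") {
      expect_equal(ap$delta %% 3L, 0L)
      expect_equal(length(orc$aa), length(ref$aa) + ap$delta %/% 3L)
    }
    if (cq$category == "frameshift") {
      expect_true(ap$delta %% 3L != 0L)
      if (!is.na(cq$fs_stop_offset))
        expect_equal(cq$fs_stop_offset,
                     orc$stop_index - cq$first_affected_codon + 1L)
    }
    if (cq$category == "stop_gain") {
      expect_true(orc$terminated)
      expect_equal(orc$stop_index, cq$first_affected_codon)
    }
    n_checked <- n_checked + 1L
  }
  expect_equal(n_checked, 100L)
})

test_that("consequence annotation refuses coordinate-only models", {
  m <- gene_model("bare", "chrT", "+",
                  data.frame(start = c(1L, 100L), end = c(50L, 150L)),
                  NA, NA)
  tx <- build_transcript(m)
  ap <- apply_splice_event(tx, splice_event("sk", "exon_skip", exons = 2L))
  expect_error(annotate_consequence(tx, ap$transcript),
               "consequence-unavailable")
})

test_that("gene models round-trip through TSV and BED12 exon structures load", {
  loc <- toy_pdss1_locus()
  tsv <- tempfile(fileext = ".tsv"); fa <- tempfile(fileext = ".fa")
  write_gene_model_tsv(loc$model, tsv, fa)
  back <- read_gene_model_tsv(tsv, fa)
  expect_equal(back$exons, loc$model$exons)
  expect_equal(build_transcript(back)$seq, build_transcript(loc$model)$seq)

  bed <- tempfile(fileext = ".bed")
  ex <- loc$model$exons
  writeLines(paste(c("chrT_pdss1", ex$start[1L] - 1L, ex$end[nrow(ex)],
                     "PDSS1_toy", 0, "+", ex$start[1L] - 1L,
                     ex$end[nrow(ex)], 0, nrow(ex),
                     paste0(paste(ex$end - ex$start + 1L, collapse = ","), ","),
                     paste0(paste(ex$start - ex$start[1L], collapse = ","), ",")),
                   collapse = "\t"), bed)
  b12 <- read_gene_model_bed12(bed)
  expect_equal(b12$exons, loc$model$exons)
})
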