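---
title: "Allele-resolved quantification of cryptic splicing from long-read amplicon sequencing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-resolved quantification of cryptic splicing from long-read amplicon sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coqsplice)
```

## The problem

Intronic variants outside canonical splice sites are an important but
easily missed cause of recessive disease. When such a variant is suspected
in a coenzyme Q10 biosynthesis gene, RT-PCR of the patient transcript
followed by long-read (nanopore-style) sequencing yields one read per
amplified cDNA molecule. Because each read is a full primer-to-primer
amplicon, two questions become answerable at the single-molecule level:

1. *What mis-splicing does each molecule show?* Each read's alignment
   implies a **junction chain** — the ordered reference-coordinate gaps
   spliced out of that molecule — which can be matched against a catalogue
   of candidate events (exon skip, alternate acceptor/donor, alternate
   noncanonical exon, intron retention).
2. *Which allele produced each molecule?* A heterozygous exonic SNV inside
   the amplicon tags every read with its haplotype of origin, so the
   mis-splicing fraction can be computed **per allele**: a cryptic splice
   variant should distort splicing on its own haplotype while the trans
   allele stays at the basal level seen in controls.

Around this core, the package implements the companion analyses a
rare-disease splicing study needs: an exact 2x2 association test for a
recurrent missense allele, a rare-biallelic-variant prioritisation cascade
over the 13-gene CoQ10 pathway panel, and cross-family detection of a
shared ancestral haplotype from phased genotypes.

Patient sequence data cannot be redistributed, so the package ships a
synthetic data generator as a first-class, tested module; every
downstream stage is validated against generated truth.

## Gene models and consequence annotation

A `gene_model()` is an ordered exon table (genomic coordinates, 1-based
inclusive; exons in transcription order) with transcript-space CDS
anchors. `build_transcript()` produces the spliced sequence, offset table
and junction chain; `map_coordinate()` maps genomic positions to
transcript coordinates and reports intronic positions with signed
HGVS-style offsets (`-7` = 7 bp before an acceptor).

`apply_splice_event()` rewrites the exon chain for each event kind and
reports the net length delta; `annotate_consequence()` compares the
original and modified transcript. Categories follow the delta and the
translation of the modified CDS:

* delta divisible by 3, no new stop: in-frame deletion (or insertion —
  the enum is extended with `inframe_insertion` because alternate-exon
  inclusion and intron retention can add length in frame);
* a stop codon at the first affected position: stop gain;
* frame-disrupting delta: frameshift, with `fs*K` counted from the first
  altered residue to the new termination codon.

HGVS-p output is a deliberately constrained subset ("HGVS-p-lite"):
`p.(XaaN_XaaMdel)`, `p.(XaaN*)`, `p.(XaaNYyyfs*K)`. Deletions are *not*
repositioned by the HGVS 3'-rule; the first affected codon is derived
from the coordinate-level difference between the exon chains, which makes
codon-aligned deletions report their true bounds deterministically.
Translation uses the standard codon table only; selenocysteine and
non-ATG starts are refused. The test suite cross-checks every consequence
against an independent translation routine (seqinr).

## The synthetic amplicon generator

`simulate_reads()` draws full-length amplicon reads from per-allele
isoform mixtures:

* **Counts.** In `exact` mode, per-(allele, event) counts are the
  largest-remainder rounding of `n * fraction` (ties broken by event id),
  so printed study percentages such as 361/400 = 90.25% are representable
  exactly. `multinomial` mode draws randomly under the seed.
* **Tags.** Each allele's tagging SNVs are substituted into every isoform
  template; an isoform in which a tag position is spliced out is rejected
  as untaggable rather than silently emitted.
* **Errors.** The error model applies independent per-base substitutions,
  insertions and deletions and records their effect in the read's CIGAR,
  exactly as an aligner would see it. The default profile (substitution
  0.03, insertion 0.01, deletion 0.02, constant quality) is a
  nanopore-flavoured invention, not calibrated to any basecaller; zero
  rates reproduce templates byte-identically.
* **Frames.** Reads can be emitted as transcript-frame alignments (the
  reference is the canonical spliced transcript; splice gaps are D
  operations) or genome-frame alignments (the locus is the reference;
  gaps are N operations). Genome-frame emission is restricted to
  plus-strand models; both bundled toy loci are forward-strand so tests
  stay readable, though the transcript machinery supports both strands.

Reads are always full-length primer-to-primer molecules — matching the
RT-PCR design — with no fragmentation or truncation model. What passing
tests therefore show is that the classifier recovers the truth for
full-length single-molecule amplicons under independent per-base noise;
they say nothing about degraded RNA, PCR chimeras, homopolymer-biased
nanopore error or reverse-transcription artefacts, none of which are
modelled.

`simulate_control_cohort()` draws each control sample's basal
alternate-exon inclusion uniformly from a band (default 6.5%–10.14%, the
range observed in control RNA). Control read depth is not stated in the
source material; the default of 2000 reads per control is an invention
and configurable.

## Classification, allele calling and phasing

`extract_junction_chain()` turns every D or N CIGAR operation of length
at least `min_gap` into a gap; shorter deletions are treated as alignment
noise. `classify_chain()` matches a read's chain against the catalogue
gap-for-gap: every boundary must agree within `tol` bp, the smallest
total deviation wins, remaining ties go to catalogue order, and a read
matching nothing is `unclassified` (never forced into the nearest
category). The defaults `min_gap = 20` and `tol = 5` are invented values
sized to absorb nanopore junction wobble; both are explicit parameters,
and a sweep test confirms the decision flips exactly at `tol`. Note the
consequence of `min_gap`: a transcript-frame catalogue containing a 14 bp
alternate-acceptor event needs `min_gap` below 14, whereas in genome
frame the same event moves an intron-gap boundary by 14 bp and is
distinguished by `tol` without lowering `min_gap`.

`call_allele()` walks the CIGAR to the base aligned at the tagging site.
Insertions do not shift the call; a deleted, soft-clipped or low-quality
site (below `min_baseq`, default 7) is `missing`, and a base matching
neither ref nor alt is `other`. Both categories are bookkept separately
and excluded from allele denominators — the explicit unassigned remainder
is deliberate, because per-allele read fractions from real data do not
sum to 100%.

`phase_by_linked_snv()` tabulates co-occurrence of calls at two sites
over doubly-informative reads and declares cis when concordant molecules
outnumber discordant ones by 4:1 (trans for the reverse, ambiguous
otherwise or below `min_reads`). Per-read haplotype labels use the
concordant pair when both sites are callable — a discordant molecule
stays unresolved rather than guessing — and the single informative site
otherwise.

## Quantification and the exact test

`per_allele_fractions()` reports, per allele, each event's fraction of
classified reads. `depth_inclusion()` computes per-base depth from
aligned blocks (gaps contribute zero) and reports
`mean(depth over alternate region) / mean(depth over anchor region)`
under the default `"anchor"` convention (the anchor being the canonical
exon given alongside the alternate region); a `"competing"` convention
(`alt / (alt + anchor)`) is available as an explicit parameter. For
full-length amplicons and whole-exon regions the depth route equals
simple read counting, and a test pins that consistency.

`fisher_exact_2x2()` implements the exact conditional analysis of a 2x2
table: the two-sided p-value sums noncentral-hypergeometric point
probabilities (at odds ratio 1) not exceeding the observed table's
probability — the common exact-test convention, chosen because the
sidedness convention is otherwise unstated; the odds ratio is the
conditional MLE, found as the bracketed root of the conditional score
equation to tolerance 1e-10 (the sample cross-product ratio is also
reported for transparency); and the confidence interval inverts
one-sided tail tests at `(1 - conf)/2` per side. Degenerate margins give
p = 1 with an undefined odds ratio. Tests verify the implementation
against full enumeration of the conditional distribution on all tables
with margins up to 6 (agreement to 1e-9) and against the standard
conditional-MLE convention on published-style tables; an empirical check
at a known odds ratio confirms at-least-nominal interval coverage. On
the reconstructed case/population allele table `[[3, 19], [411, 282353]]`
the test yields OR 108.4, 95% CI (20.5, 370), p = 4.699e-06; printed
reference values for this table derive from a root solved at a much
looser tolerance, which accounts for a ~1% difference in the upper bound.

## Prioritisation cascade

`prioritize_variants()` chains panel restriction (13 CoQ10 pathway
genes), frequency annotation, the rarity filter and biallelic detection.
Design choices made where the procedure was genuinely open:

* The frequency gate uses the **population-maximum** MAF when
  population-resolved counts exist (stricter, and matching how such
  cohorts tabulate frequency), falling back to the overall MAF;
  populations below 2000 alleles never set the popmax. A variant absent
  from the reference sorts as rarest and survives.
* Recurrent study alleles above the 0.001 threshold pass only via an
  explicit whitelist and are tagged `frequency_exceptional`, never
  silently admitted.
* Intronic variants within 25 bp of an exon boundary count as
  splice-region; deeper intronic variants need an external
  splice-predictor flag to survive. The window is a package choice — the
  filter description ("potential cryptic splice altering intronic")
  names no number — sized to cover the -25 and -7 acceptor-region
  variants it must retain.
* Compound heterozygotes are phased through parental genotypes: one
  variant per parent is trans (a candidate), both from one parent is cis
  (demoted with a note), unphasable is unknown (kept). Mendelian
  inconsistencies annotate rather than drop a candidate.

## Haplotype sharing

`informative_snvs()` keeps markers with MAF below 0.1 within 250 kb of
the target (both values are the study's stated choices); `cis_set()`
takes the markers whose rare allele sits on the carrier's
target-bearing haplotype; `shared_segment()` reports the maximal run of
consecutive informative markers present in every family's cis set,
bounded by its outermost markers, with `span_bp = end - start` (matching
26,933,928 - 26,535,625 = 398,303 ≈ 398 kb) and a per-pair table.
Comparison is identity-by-state of rare alleles — no probabilistic IBD
model — so the global and pairwise reports are emitted separately and no
claim of common ancestry is adjudicated.

The family generator pins every shared-interval endpoint as a panel
marker so truth boundaries are recoverable, and offers two carrier
backgrounds. With the realistic `"population"` background (the
generator default), the carrier haplotype outside its ancestral interval
carries rare alleles at population frequency, so a boundary-adjacent
marker is coincidentally shared with probability roughly its MAF — real
IBS noise; a property test requires boundary recovery within one marker
spacing there. The `"none"` background gives a controlled fixture whose
cis sets equal the truth exactly; the exact-span replicas use it because
they assert the printed boundary markers to the base pair.

## Problem sizes and numerical conventions

The bundled analyses run at the study's scale: 2019 reads for the
two-allele inclusion replica (400 + 1619), 100 reads per allele for the
skip-fraction replica, six controls, a ~80-marker panel over 560 kb for
three families, and 500-read sets for the noisy-accuracy properties.
Percentages print to 2 decimal places; machine output keeps full
precision. Fractions denominate over classified, allele-assigned reads
only. Accuracy under the default error model is measured over
informative calls (non-`unclassified` events; `ref`/`alt` allele calls),
mirroring how the quantification denominators are defined. All
randomness flows through explicit seeds; fixture builders restore the
caller's RNG state.

## Known limitations

* No de-novo isoform discovery: a read matching no catalogued chain is
  counted `unclassified`, so an unanticipated event shows up as an
  unclassified excess, not as a new category.
* The error model is independent per base; homopolymer and
  quality-correlated errors are not emulated, so real nanopore data may
  need a wider `tol`.
* NMD is never predicted; premature-termination outcomes are annotated
  structurally only.
* Structural variants pass the parsers but have no dedicated logic.
* The exact test addresses the single recurrent-allele association;
  no multiple-testing machinery is included.
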