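---
title: "Designing and screening ssODN knock-ins with kistat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing and screening ssODN knock-ins with kistat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kistat)
```

## The problem

Targeted knock-in by homology-directed repair (HDR) with single-stranded
oligodeoxynucleotide (ssODN) donors is inefficient in zebrafish: most
alleles at a Cas9 cut carry NHEJ indels, a minority carry the donor, and
injected F0 animals are mosaics of all of them. Because small tags and point
mutations offer no visual readout, screening hinges on fragment sizing:
fluorescent PCR read on a capillary sequencer resolves single base pairs, so
an epitope-tag insertion announces itself as a peak at a known offset above
the wild-type product, and a point mutation - invisible by size - can be made
visible by engineering a restriction site into the donor and digesting the
product before sizing (RFLP). kistat implements that entire design and
screening logic in silico: donor design, fragment-size prediction, peak
classification, and a mosaic-embryo simulator that exercises all of it
without laboratory data.

## The design model

### Geometry and conventions

All coordinates are 0-based, half-open, on the stored (+) strand of the
locus; strand-aware accessors convert to gene orientation. A cut site is a
bond coordinate: SpCas9 cuts bluntly between protospacer positions 17 and
18, i.e. 3 nt 5' of the NGG PAM. Staggered cuts are not modelled; all size
arithmetic assumes a single cut coordinate.

### Tag insertion

For a 3'-end tag the donor cassette is

    spacer + tag + stop

where the *spacer* duplicates the genomic sequence from the cut bond to the
base before the stop codon. Inserted at the cut, the cassette extends the
native reading frame seamlessly into the tag and a fresh stop; the original
spacer and stop remain downstream of the cassette and become 3'
non-coding sequence. That duplication model is the only one consistent with
the size-shift law the package enforces:

    shift = len(spacer) + len(tag) + 3

so a FLAG tag (24 nt) at a site cut 16 nt upstream of the stop shifts the
product by +43 bp, and an HA tag (27 nt) at a 6-nt site by +36 bp:

```{r tag-design}
sl <- synth_tag_locus(16, guide_strand = "-", seed = 1)
design <- design_tag_ssodn(sl$locus, sl$guide, "FLAG")
design
```

(Whether a *silent* PAM change exists is partly a question of reading
frame: with the cut 16 nt upstream of the stop, a + strand guide places
both PAM Gs at codon positions 1-2, which are essentially never
degenerate, so those designs take the flagged seed fallback; a - strand
guide puts a PAM G at a codon third position, where synonymous changes
abound.)

### Blocking re-cutting

An integrated allele that still matches the guide gets cut again, so every
design carries a CRISPR/Cas-blocking substitution. The re-cut model is
exact-match: the allele is cleavable iff the full 20-nt protospacer followed
by NGG occurs on either strand, so a single change at a PAM G (or anywhere
in the protospacer) abolishes cutting. Mismatch-tolerant activity scoring is
deliberately out of scope - it would need data the fragment assay does not
provide.

The blocking change must not alter the protein. Positions that stay coding
after integration require a synonymous change; positions at or past the
stop codon (which become non-coding in the knock-in allele) are
unconstrained. When no admissible PAM change exists the designer falls back
to a silent protospacer-seed change within 10 nt of the PAM and flags it -
an extension beyond the PAM-only rule, clearly marked in the output.

A subtlety worth spelling out: in tag mode the spacer exists twice in the
knock-in allele (once in the cassette, once at the start of the downstream
homology arm). Only the cassette copy can reconstitute a cleavable
protospacer + PAM across the arm/cassette junction, so candidate blocking
substitutions are applied to whichever copy actually abolishes re-cutting -
verified by rebuilding the full knock-in allele and scanning both strands,
never assumed from geometry.

### Point mutations

A point-mutation donor is substitution-only (size shift 0). Its
substitution set is the union of

1. the desired edits (the only changes allowed to alter the protein),
2. cohort-SNP reversions (the donor is designed against the sequenced
   injection cohort, not the reference; reversions must be silent),
3. the silent PAM block, and
4. silent restriction-site engineering, *only if* none of the above already
   creates a knock-in-specific site inside the homology-arm window.

Site engineering searches exhaustively over silent single changes, then
pairs of nearby silent changes, preferring fewest substitutions, then
proximity to the cut, then alphabetical enzyme name - a deterministic
tie-break, since the underlying choice is genuinely open. The design records
the diagnostic enzyme and the position of the new site.

Edits far from the cut are risky: conversion tracts can resolve before
reaching a distal edit, transmitting the restriction site without the
mutation. The designer warns (not errors) beyond a configurable 15-nt
cut-to-edit distance.

```{r point-design}
sp <- synth_point_locus(seed = 7)
pd <- suppressWarnings(
  design_point_ssodn(sp$locus, sp$guide, sp$desired_edits,
                     sp$snp_reversions))
pd
```

### Homology arms and oligo orientation

Arms are asymmetric: 36 nt on the PAM-distal side of the cut and 91 nt on
the PAM-proximal side, and the oligo is written against the non-target
(protospacer-bearing) strand - the annealing geometry reported to favour
HDR with asymmetric donors. The arm rule is kept PAM-relative regardless of
how the guide lies against the gene; both lengths are configurable and are
echoed in every report. Whether the asymmetry should flip when the guide
strand flips relative to the gene is not settled; the PAM-relative rule is
applied uniformly and logged per design so users can override it.

## The screening model

### In-silico PCR and digestion

Amplicons are built by exact-match, convergent, unique-hit priming; an
allele that lost a primer site yields "no product", not an error. Screening
primers must bind outside the homology-arm window (`validate_primers()`
enforces this), so imprecise integrations cannot template a false-positive
product. The three-primer fluorescent system (gene-specific forward primer
with an M13F tail, tailed reverse primer, labelled universal M13F primer) is
modelled as a constant 18-nt tail on the forward primer carrying the label
at position 0.

Digestion cuts at every site occurrence on either strand; fragment bounds
are top-strand cut positions, and only the fragment containing the 5'
forward label is detected. The shipped reverse-primer tail
(`SALI_CONTROL_TAIL`) plants a SalI site that trims exactly 10 bp off every
product - the internal control that distinguishes "digest failed" from
"no knock-in": a digested sample without the trimmed WT peak is called
`invalid`, never `negative`.

### Peak classification

A sample is positive when a peak within `size_tol` (default 1.0 bp, the
resolution of capillary electrophoresis) of the expected knock-in size rises
above `background_frac` (default 0.05) of the tallest peak in the trace.
The source assay states only that peaks "above the background threshold"
count; the 5% default is a declared constant, exposed in configuration and
reported in output, not an inferred value.

The method's known failure mode is reproduced faithfully rather than hidden:
an allele carrying the engineered site but not the desired edit digests
exactly like a true knock-in and classifies positive.
`audit_knockin_allele()` is the sequence-level companion that flags such
site-only false positives, mirroring the recommendation to
sequence-confirm every founder.

## The simulator: what it emulates, and what it does not

`simulate_mosaic()` draws a finite pool of genome copies (default 200) from
a target mixture of WT, HDR and indel alleles, so observed fractions
scatter binomially around their targets. Indel sizes follow a signed
geometric mixture - 70% deletions, magnitude `rgeom(p = 0.3) + 1` capped at
30 nt, never 0. Real F0 indel spectra are locus- and guide-specific and are
shown but never parameterized in fragment-assay data, so these defaults are
declared configuration, not estimates; the defaults (20% HDR, 60% indels,
4 indel alleles) describe a moderately active guide.

`render_peaks()` converts a mixture to a peak table by actually amplifying
and digesting each allele sequence, with peak height proportional to allele
fraction times a lognormal multiplier (CV 0.2, mean 1) and Gaussian size
jitter (SD 0.15 bp, small against the 1-bp matching tolerance).

`simulate_founder_screen()` models germline screening in pools of 3 embryos
(up to 24 pools per founder): each embryo carries the knock-in with the
founder's transmission rate r, heterozygous carriers contribute a 50%
allele fraction, and pooled DNA is averaged. The analytic pool-positivity
1-(1-r)^k is returned alongside the simulation. Indel transmission by
founders is not modelled in pools, and no biophysical electrophoresis
(stutter, adenylation, dye shifts) is attempted anywhere.

Passing tests on this simulator therefore demonstrate the *logic* of the
pipeline - size arithmetic, digestion bookkeeping, thresholding, pooling -
under a noise model chosen to be realistic for capillary data. They do not
demonstrate performance on real traces, where baseline noise, stutter
products and locus-specific artifacts can push marginal peaks across the
background threshold in either direction. The sensitivity claim the
simulator supports is deliberately qualitative: recall approaches 1 for
HDR fractions at or above 20% and degrades below 5%.

## Numerical choices and degenerate inputs

* Coordinates are validated at construction; CDS intervals must be
  stop-terminated multiples of 3 with no internal stop, and ambiguity codes
  are rejected outright.
* A guide absent from (or ambiguous on) its locus is an error; re-cut
  checks scan both strands exhaustively.
* A + strand guide cutting 2-5 nt upstream of the stop would need its PAM
  GG inside the stop codon; the synthetic generator refuses the geometry
  with an explanatory error rather than emitting an impossible locus.
* An empty spacer (cut bond immediately before the stop) is legal and gives
  shift = tag + 3.
* Tie-breaks everywhere are deterministic (candidate order for blocking
  substitutions, fewest/closest/alphabetical for site engineering), so
  identical inputs and seeds reproduce identical designs bit-for-bit.
* Simulation problem sizes used in the shipped tests (hundreds of embryos,
  10,000 pools, 1,000 random digests) were chosen to put Monte-Carlo error
  well inside the asserted bounds on a single CPU.

## Limitations

* Exact-match priming and re-cutting: no mismatch-tolerant PCR or guide
  activity model.
* Single-interval CDS only; multi-exon loci must be supplied as a
  coordinates table covering the relevant exon.
* No raw trace (.fsa) parsing; peak tables are expected as CSV exports.
* The simulator is a test harness for the screening logic, not a
  biological claim about HDR rates or F0 allele-count distributions.
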