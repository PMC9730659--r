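# kistat

Design and fragment-analysis screening of CRISPR ssODN knock-ins.

Knock-in of epitope tags and point mutations with single-stranded
oligodeoxynucleotide (ssODN) donors is bottlenecked by screening: HDR is
rare, injected F0 animals (the package's conventions come from zebrafish
work, but nothing is species-specific) are mosaics of wild-type, indel and
knock-in alleles, and small edits offer no visual readout. Fluorescent PCR
sized on a capillary sequencer solves this at single-base-pair resolution:

* **Tag insertions** shift the PCR product by a known amount. The donor
  cassette is `spacer + tag + stop`, where the spacer duplicates the
  genomic sequence from the blunt Cas9 cut (3 nt 5' of the NGG PAM) to the
  stop codon, keeping the tag in frame. The shift is
  `len(spacer) + len(tag) + 3` - e.g. **+43 bp** for FLAG (24 nt) at a site
  cut 16 nt upstream of the stop, **+36 bp** for HA (27 nt) at a 6-nt site.
* **Point mutations** do not change product size, so the donor additionally
  engineers a knock-in-specific restriction site (often the silent
  PAM-blocking change itself creates one); digesting the labeled product
  (RFLP) then separates knock-in from wild-type fragments. A restriction
  site in the reverse-primer tail trims 10 bp off every product as an
  internal control that the digest worked.

kistat implements the full in-silico workflow: ssODN design with asymmetric
36/91-nt homology arms written against the non-target strand, silent
CRISPR/Cas-blocking substitutions verified to abolish re-cutting,
restriction-site engineering, allele-specific amplicon and digest
prediction, classification of electropherogram peak tables, and a
mosaic-embryo / pooled-founder simulator that makes every stage testable
without laboratory data.

## Worked example

Design a FLAG knock-in at a synthetic locus whose cut lies 16 nt upstream
of the stop codon, predict the screening peaks, and classify a simulated
mosaic embryo:

```r
library(kistat)

sl <- synth_tag_locus(16, guide_strand = "-", seed = 1)
design <- design_tag_ssodn(sl$locus, sl$guide, "FLAG")
design
#> <ssodn_design> mode: tag  locus: synthetic_tag_locus
#>   cut bond at 197 ; arms 36 / 91 nt (distal/proximal)
#>   insert: 43 nt (spacer 16 + tag 24 + stop 3); size shift + 43 bp
#>   substitutions:
#>     191 : C > T (pam_block, silent)
#>   oligo: 170 nt

primers <- pick_screening_primers(sl$locus, design)
exp <- expected_peaks(design, sl$locus, primers, "undigested")
c(exp$wt_size, exp$ki_size)
#> [1] 195 238

embryo <- simulate_mosaic(hdr_frac = 0.3, indel_rate = 0.5,
                          n_indel_alleles = 3, seed = 2)
trace <- render_peaks(embryo, design, sl$locus, primers, seed = 3)
round(as.data.frame(trace), 1)
#>   size_bp height
#> 1   189.0   77.0
#> 2   193.0   92.5
#> 3   194.2  350.9
#> 4   194.8   97.6
#> 5   238.2  346.6

classify_sample(trace, exp)$call
#> [1] "positive"
```

Reading the numbers: the wild-type product is 195 bp (including the 18-nt
labeled M13F tail) and the knock-in allele appears 43 bp above it at
238 bp. The simulated mosaic shows indel peaks scattered around the
wild-type size (189-195 bp) and the knock-in peak at 238.2 bp, within the
1-bp matching tolerance and well above the 5% background threshold, so the
embryo is called positive. Point-mutation designs work the same way through
`design_point_ssodn()` and `expected_peaks(..., "digested")`; see the
vignette (`vignettes/knockin-design.Rmd`) for the full model, parameter
meanings and limitations.

Input formats: loci as GenBank flat files or FASTA plus a coordinates TSV
(`name`, `cds_start`, `cds_end` 0-based half-open, `gene_strand`); guides
as TSV (`name`, `protospacer`, `pam`, `strand`); primers as TSV
(`forward`, `reverse`, optional `forward_tail`, `reverse_tail`); enzymes as
TSV (`name`, `site`, `cut_top`, `cut_bottom`, offsets from the site's 5'
end); peak tables as CSV (`sample_id`, `size_bp`, `height`, `digested`).
A command-line wrapper (`inst/scripts/kistat`, subcommands `design-tag`,
`design-point`, `predict`, `digest`, `classify`, `simulate`) exposes the
same functions with exit codes 0/1/2.

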