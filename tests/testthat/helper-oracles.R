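# Independent oracles used to cross-check the implementation. These
# deliberately avoid the package's own string machinery: translation goes
# through seqinr, everything else is plain base-R string slicing.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

# codon-by-codon lookup through seqinr (standard code, '*' for stops)
oracle_translate <- function(dna, frame = 0) {
  aa <- seqinr::translate(seqinr::s2c(dna), frame = frame, numcode = 1)
  paste(aa, collapse = "")
}

oracle_is_silent <- function(sequence, cds_start, cds_end, gene_strand,
                             position, to_base) {
  if (position < cds_start || position >= cds_end) return(TRUE)
  mut <- sequence
  substr(mut, position + 1, position + 1) <- to_base
  get_cds <- function(s) {
    x <- substr(s, cds_start + 1, cds_end)
    if (gene_strand == "-") oracle_revcomp(x) else x
  }
  oracle_translate(get_cds(sequence)) == oracle_translate(get_cds(mut))
}

# naive linear site scan: all top-strand cut positions for an enzyme
oracle_digest_fragments <- function(seq, site, cut_top, cut_bottom) {
  n <- nchar(seq)
  L <- nchar(site)
  rc <- oracle_revcomp(site)
  cuts <- integer(0)
  if (n >= L) {
    for (i in seq_len(n - L + 1)) {
      win <- substr(seq, i, i + L - 1)
      if (win == site) cuts <- c(cuts, i - 1 + cut_top)
      if (win == rc && rc != site) cuts <- c(cuts, i - 1 + L - cut_bottom)
    }
  }
  cuts <- sort(unique(cuts[cuts > 0 & cuts < n]))
  diff(c(0, cuts, n))
}

# exhaustive scan for an exact protospacer + NGG on either strand
oracle_recut <- function(seq, proto) {
  scan <- function(s) {
    n <- nchar(s)
    if (n < 23) return(FALSE)
    for (i in seq_len(n - 22)) {
      if (substr(s, i, i + 19) == proto &&
          substr(s, i + 21, i + 22) == "GG") return(TRUE)
    }
    FALSE
  }
  scan(seq) || scan(oracle_revcomp(seq))
}

intervals_overlap <- function(a, b) !(a[2] <= b[1] || a[1] >= b[2])

# shared fixtures: a fixed tag locus/design/primers for screening tests
tag_fixture <- function(spacer_len = 16, seed = 101, tag = "FLAG") {
  sl <- synth_tag_locus(spacer_len, seed = seed)
  d <- suppressWarnings(design_tag_ssodn(sl$locus, sl$guide, tag))
  pp <- pick_screening_primers(sl$locus, d)
  list(locus = sl$locus, guide = sl$guide, design = d, primers = pp,
       expected = expected_peaks(d, sl$locus, pp, "undigested"))
}

point_fixture <- function(seed = 202) {
  sp <- synth_point_locus(seed = seed)
  d <- suppressWarnings(
    design_point_ssodn(sp$locus, sp$guide, sp$desired_edits,
                       sp$snp_reversions))
  pp <- pick_screening_primers(sp$locus, d,
                               reverse_tail = SALI_CONTROL_TAIL)
  list(locus = sp$locus, guide = sp$guide, design = d, primers = pp,
       motif_start = sp$motif_start,
       desired_edits = sp$desired_edits, snp_reversions = sp$snp_reversions)
}

# simple valid locus with a guide placed at a chosen protospacer start
simple_locus_with_guide <- function(proto_start0, strand = "+",
                                    total = 160, seed = 1) {
  set.seed(seed)
  repeat {
    seq <- rand_dna(total)
    cds_start <- total - 50
    body <- paste0("ATG", paste(rep("GCT", 14), collapse = ""), "TAA")
    substr(seq, cds_start + 1, cds_start + nchar(body)) <- body
    if (strand == "+") {
      proto <- substr(seq, proto_start0 + 1, proto_start0 + 20)
      substr(seq, proto_start0 + 22, proto_start0 + 23) <- "GG"
      pam <- substr(seq, proto_start0 + 21, proto_start0 + 23)
    } else {
      # on '-': PAM sits left of the protospacer on the + strand
      substr(seq, proto_start0 - 2, proto_start0 - 1) <- "CC"
      pam <- oracle_revcomp(substr(seq, proto_start0 - 2, proto_start0))
      proto <- oracle_revcomp(substr(seq, proto_start0 + 1,
                                     proto_start0 + 20))
    }
    loc <- try(locus("simple", seq, cds_start, cds_start + 48),
               silent = TRUE)
    if (inherits(loc, "try-error")) next
    g <- try(guide(proto, pam, strand), silent = TRUE)
    if (inherits(g, "try-error")) next
    cs <- try(find_cut_site(loc, g), silent = TRUE)
    if (!inherits(cs, "try-error")) return(list(locus = loc, guide = g))
  }
}
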