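# Guide location, blunt Cas9 cut geometry, and re-cut checks.

#' Construct an sgRNA guide
#'
#' @param protospacer 20-nt protospacer (the genomic sequence matched by the
#'   guide, on the guide strand).
#' @param pam 3-nt PAM immediately 3' of the protospacer; must match NGG.
#' @param strand `"+"` or `"-"`: strand of the locus carrying the
#'   protospacer.
#' @param name optional identifier.
#' @return Object of class `"guide"`.
#' @export
guide <- function(protospacer, pam, strand = "+", name = NULL) {
  protospacer <- .check_dna(protospacer, "protospacer")
  pam <- .check_dna(pam, "pam")
  if (nchar(protospacer) != 20L) stop("protospacer must be 20 nt", call. = FALSE)
  if (nchar(pam) != 3L || substr(pam, 2L, 3L) != "GG") {
    stop("PAM must be 3 nt matching NGG", call. = FALSE)
  }
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'", call. = FALSE)
  structure(list(name = if (is.null(name)) "guide" else as.character(name),
                 protospacer = protospacer, pam = pam, strand = strand),
            class = "guide")
}

#' @export
print.guide <- function(x, ...) {
  cat("<guide>", x$name, " ", x$protospacer, "|", x$pam,
      " (", x$strand, " strand)\n", sep = "")
  invisible(x)
}

#' Locate a guide on a locus and compute the blunt Cas9 cut position
#'
#' SpCas9 cuts bluntly between protospacer positions 17 and 18 (1-based
#' within the 20-mer), i.e. 3 nt 5' of the PAM on the protospacer strand.
#' The protospacer + PAM must occur exactly once on the stated strand.
#'
#' @param locus a [locus()].
#' @param guide a [guide()].
#' @return Object of class `"cut_site"` with `position` (0-based bond
#'   coordinate on the + strand: the cut falls between `position - 1` and
#'   `position`), and the + strand `protospacer_interval` / `pam_interval`.
#' @export
find_cut_site <- function(locus, guide) {
  stopifnot(inherits(locus, "locus"), inherits(guide, "guide"))
  target <- paste0(guide$protospacer, guide$pam)
  if (guide$strand == "+") {
    hits <- .find_all(locus$sequence, target)
    if (length(hits) != 1L) {
      stop("protospacer+PAM found ", length(hits),
           " times on the + strand (need exactly 1)", call. = FALSE)
    }
    s <- hits
    pos <- s + 17L
    proto <- c(s, s + 20L)
    pam <- c(s + 20L, s + 23L)
  } else {
    hits <- .find_all(locus$sequence, revcomp(target))
    if (length(hits) != 1L) {
      stop("protospacer+PAM found ", length(hits),
           " times on the - strand (need exactly 1)", call. = FALSE)
    }
    s <- hits  # + strand start of revcomp(protospacer+PAM); PAM is leftmost
    pos <- s + 6L
    pam <- c(s, s + 3L)
    proto <- c(s + 3L, s + 23L)
  }
  structure(list(position = pos, guide = guide,
                 protospacer_interval = proto, pam_interval = pam),
            class = "cut_site")
}

#' @export
print.cut_site <- function(x, ...) {
  cat("<cut_site> bond at", x$position, "( guide:", x$guide$name,
      "on", x$guide$strand, "strand; PAM [", x$pam_interval[1], ",",
      x$pam_interval[2], ") )\n")
  invisible(x)
}

#' Signed distance from a cut to an anchor interval in gene orientation
#'
#' Counts the nucleotides between the cut bond and the gene-strand-proximal
#' edge of the anchor (by default the stop codon). Negative values mean the
#' cut lies upstream of the anchor in gene orientation; a cut bond exactly at
#' the anchor edge gives 0.
#'
#' @param cut a `cut_site`.
#' @param locus the locus it was computed on.
#' @param anchor_interval 0-based half-open interval on the + strand;
#'   defaults to the locus stop codon.
#' @return Signed integer distance in nt.
#' @export
distance_to_anchor <- function(cut, locus, anchor_interval = NULL) {
  stopifnot(inherits(cut, "cut_site"), inherits(locus, "locus"))
  if (is.null(anchor_interval)) anchor_interval <- locus$stop_codon_interval
  if (anchor_interval[1] < 0 || anchor_interval[2] > nchar(locus$sequence)) {
    stop("anchor outside locus bounds", call. = FALSE)
  }
  if (locus$gene_strand == "+") {
    cut$position - anchor_interval[1]
  } else {
    anchor_interval[2] - cut$position
  }
}

#' Can the guide still cut an (edited) allele?
#'
#' Exact-match re-cut model: the allele is cleavable iff the full 20-nt
#' protospacer immediately followed by an NGG PAM occurs on either strand.
#' Any single mismatch, in the protospacer or the PAM GG, abolishes cutting
#' under this model.
#'
#' @param allele_sequence DNA string of the allele to test.
#' @param guide a [guide()].
#' @return `TRUE` if a cleavable site exists.
#' @export
is_recut_possible <- function(allele_sequence, guide) {
  allele_sequence <- .check_dna(allele_sequence, "allele_sequence")
  stopifnot(inherits(guide, "guide"))
  has_site <- function(seq) {
    n <- nchar(seq)
    for (s in .find_all(seq, guide$protospacer)) {
      if (s + 23L <= n &&
          substr(seq, s + 22L, s + 23L) == "GG") {
        return(TRUE)
      }
    }
    FALSE
  }
  has_site(allele_sequence) || has_site(revcomp(allele_sequence))
}
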