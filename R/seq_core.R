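# Sequence/locus data model shared by all other modules.
#
# Coordinate convention throughout the package: 0-based, half-open intervals
# on the stored (+) strand of the locus. Cut sites are phosphodiester-bond
# coordinates: a cut at position p separates bases p-1 and p.

DNA_BASES <- c("A", "C", "G", "T")

#' M13 forward universal tail
#'
#' The 18-nt M13F sequence used as a 5' tail on forward screening primers in
#' the three-primer fluorescent PCR system (the 6FAM label rides on a
#' separate universal M13F primer; the net effect on amplicon length is the
#' tail itself).
#' @export
M13F_TAIL <- "TGTAAAACGACGGCCAGT"

#' Reverse-primer tail carrying a SalI site
#'
#' Default 11-nt 5' tail for reverse screening primers in RFLP mode. It
#' plants a SalI site so that digestion trims exactly 10 bp off the 3' end of
#' every amplicon, serving as an internal control that the digest worked.
#' @export
SALI_CONTROL_TAIL <- "AATTCGTCGAC"

.check_dna <- function(x, what = "sequence") {
  if (length(x) != 1L || !is.character(x)) {
    stop(what, " must be a single character string", call. = FALSE)
  }
  x <- toupper(x)
  if (!grepl("^[ACGT]*$", x)) {
    stop("non-ACGT character in ", what,
         " (ambiguity codes are not supported)", call. = FALSE)
  }
  x
}

.base_at <- function(seq, pos) substr(seq, pos + 1L, pos + 1L)

.comp <- function(x) chartr("ACGT", "TGCA", x)

# All 0-based start positions of `pat` in `seq`, overlapping matches included.
.find_all <- function(seq, pat) {
  n <- nchar(seq)
  m <- nchar(pat)
  if (m == 0L || m > n) return(integer(0))
  out <- integer(0)
  i <- 1L
  while (i <= n - m + 1L) {
    j <- regexpr(pat, substr(seq, i, n), fixed = TRUE)
    if (j < 0L) break
    out <- c(out, i + j - 1L)
    i <- i + j  # step one past the match start: overlaps are found
  }
  out - 1L
}

#' Reverse complement of a DNA string
#'
#' @param x DNA string (A/C/G/T only).
#' @return The reverse complement as a character string.
#' @examples
#' revcomp("GTCGAC")  # palindromic SalI site
#' @export
revcomp <- function(x) {
  x <- .check_dna(x)
  if (nchar(x) == 0L) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Translate a DNA string with the standard genetic code
#'
#' Stops are rendered as `*`; translation is truncated at the last complete
#' codon. The first codon is never treated as an alternative initiator.
#'
#' @param dna DNA string, length at least `frame + 3`.
#' @param frame reading-frame offset, 0, 1 or 2.
#' @return Amino-acid string.
#' @examples
#' translate_dna("GATTACAAGGATGACGATGACAAG")  # FLAG -> "DYKDDDDK"
#' @export
translate_dna <- function(dna, frame = 0) {
  dna <- .check_dna(dna, "dna")
  if (!frame %in% 0:2) stop("frame must be 0, 1 or 2", call. = FALSE)
  if (nchar(dna) < frame + 3) {
    stop("sequence shorter than one codon in the requested frame",
         call. = FALSE)
  }
  body <- substr(dna, frame + 1L, nchar(dna))
  body <- substr(body, 1L, 3L * (nchar(body) %/% 3L))
  as.character(Biostrings::translate(Biostrings::DNAString(body),
                                     no.init.codon = TRUE))
}

#' Construct an annotated locus
#'
#' The design substrate: a genomic sequence (conventionally the sequenced
#' cohort of the injection strain, not necessarily the reference assembly)
#' with its CDS interval, gene strand, and any known cohort SNPs relative to
#' the reference.
#'
#' @param name locus identifier.
#' @param sequence DNA string (uppercased on ingest; ambiguity codes
#'   rejected).
#' @param cds_start,cds_end 0-based half-open CDS interval on the stored (+)
#'   strand. The CDS must end (in gene orientation) with a stop codon and
#'   contain no internal stop.
#' @param gene_strand `"+"` or `"-"`: orientation of the gene relative to the
#'   stored sequence.
#' @param cohort_snps optional `data.frame` with columns `position` (0-based,
#'   on the + strand), `ref_base`, `cohort_base`. The stored sequence must
#'   carry the cohort base.
#' @param reference optional reference DNA string of identical length used to
#'   validate `ref_base` entries.
#' @return An object of class `"locus"`.
#' @export
locus <- function(name, sequence, cds_start, cds_end, gene_strand = "+",
                  cohort_snps = NULL, reference = NULL) {
  sequence <- .check_dna(sequence)
  n <- nchar(sequence)
  if (!gene_strand %in% c("+", "-")) stop("gene_strand must be '+' or '-'")
  cds_start <- as.integer(cds_start)
  cds_end <- as.integer(cds_end)
  if (cds_start < 0L || cds_end > n || cds_end <= cds_start) {
    stop("CDS interval out of sequence bounds", call. = FALSE)
  }
  len <- cds_end - cds_start
  if (len %% 3L != 0L || len < 6L) {
    stop("CDS length must be a positive multiple of 3 (>= 6 nt)",
         call. = FALSE)
  }
  obj <- structure(
    list(name = as.character(name), sequence = sequence,
         cds_interval = c(cds_start, cds_end), gene_strand = gene_strand,
         stop_codon_interval = if (gene_strand == "+") {
           c(cds_end - 3L, cds_end)
         } else {
           c(cds_start, cds_start + 3L)
         },
         cohort_snps = cohort_snps),
    class = "locus")
  aa <- translate_dna(cds_sequence(obj))
  if (substr(aa, nchar(aa), nchar(aa)) != "*") {
    stop("CDS does not end in a stop codon", call. = FALSE)
  }
  if (grepl("\\*", substr(aa, 1L, nchar(aa) - 1L))) {
    stop("CDS contains an internal stop codon", call. = FALSE)
  }
  if (!is.null(cohort_snps)) {
    need <- c("position", "ref_base", "cohort_base")
    if (!all(need %in% names(cohort_snps))) {
      stop("cohort_snps needs columns position, ref_base, cohort_base",
           call. = FALSE)
    }
    cohort_snps$position <- as.integer(cohort_snps$position)
    if (any(cohort_snps$position < 0L | cohort_snps$position >= n)) {
      stop("cohort SNP position out of sequence bounds", call. = FALSE)
    }
    here <- vapply(cohort_snps$position, function(p) .base_at(sequence, p), "")
    if (!all(here == toupper(cohort_snps$cohort_base))) {
      stop("stored sequence does not carry the declared cohort base",
           call. = FALSE)
    }
    if (!is.null(reference)) {
      reference <- .check_dna(reference, "reference")
      refb <- vapply(cohort_snps$position,
                     function(p) .base_at(reference, p), "")
      if (!all(refb == toupper(cohort_snps$ref_base))) {
        stop("ref_base does not match the supplied reference sequence",
             call. = FALSE)
      }
    }
    obj$cohort_snps <- cohort_snps
  }
  obj
}

#' CDS sequence of a locus in gene orientation
#'
#' @param x a `locus`.
#' @return DNA string of the coding sequence read 5' to 3' on the gene
#'   strand (ends with the stop codon).
#' @export
cds_sequence <- function(x) {
  stopifnot(inherits(x, "locus"))
  s <- substr(x$sequence, x$cds_interval[1] + 1L, x$cds_interval[2])
  if (x$gene_strand == "-") revcomp(s) else s
}

#' @export
print.locus <- function(x, ...) {
  cat("<locus>", x$name, "\n")
  cat("  length:", nchar(x$sequence), "nt; gene strand:", x$gene_strand, "\n")
  cat("  CDS [", x$cds_interval[1], ",", x$cds_interval[2],
      "); stop codon [", x$stop_codon_interval[1], ",",
      x$stop_codon_interval[2], ")\n", sep = "")
  if (!is.null(x$cohort_snps)) {
    cat("  cohort SNPs:", nrow(x$cohort_snps), "\n")
  }
  invisible(x)
}

# --- readers / writers ------------------------------------------------------

.parse_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  loc <- grep("^LOCUS", lines, value = TRUE)
  name <- if (length(loc)) strsplit(trimws(loc[1]), "\\s+")[[1]][2] else "locus"
  cds_line <- grep("^\\s{2,}CDS\\s+\\S", lines, value = TRUE)
  if (!length(cds_line)) stop("GenBank record has no CDS feature", call. = FALSE)
  spec <- trimws(sub("^\\s*CDS\\s+", "", cds_line[1]))
  strand <- "+"
  if (grepl("^complement\\(", spec)) {
    strand <- "-"
    spec <- sub("^complement\\((.*)\\)$", "\\1", spec)
  }
  if (grepl("join|order", spec)) {
    stop("multi-interval CDS features are not supported; supply a ",
         "coordinates table instead", call. = FALSE)
  }
  m <- regmatches(spec, regexec("^<?(\\d+)\\.\\.>?(\\d+)$", spec))[[1]]
  if (length(m) != 3L) stop("cannot parse CDS location '", spec, "'",
                            call. = FALSE)
  start1 <- as.integer(m[2]); end1 <- as.integer(m[3])
  ori <- grep("^ORIGIN", lines)
  if (!length(ori)) stop("GenBank record has no ORIGIN block", call. = FALSE)
  term <- grep("^//", lines)
  term <- term[term > ori[1]]
  stopi <- if (length(term)) term[1] - 1L else length(lines)
  seq <- paste(lines[(ori[1] + 1L):stopi], collapse = "")
  seq <- toupper(gsub("[^A-Za-z]", "", seq))
  list(name = name, sequence = seq,
       cds_start = start1 - 1L, cds_end = end1, gene_strand = strand)
}

.read_coords <- function(coords) {
  if (is.character(coords) && length(coords) == 1L) {
    coords <- utils::read.delim(coords, stringsAsFactors = FALSE)
  }
  coords <- as.list(as.data.frame(coords, stringsAsFactors = FALSE)[1, ])
  if (is.null(coords$gene_strand)) coords$gene_strand <- "+"
  coords
}

#' Read a locus from FASTA (+ coordinates table) or GenBank
#'
#' GenBank records supply the CDS via their feature table (1-based inclusive
#' coordinates, converted on ingest; `complement(..)` sets the gene strand).
#' FASTA input requires a coordinates table with 0-based half-open
#' `cds_start`/`cds_end` columns and an optional `gene_strand` column, either
#' as a data frame or as the path to a TSV.
#'
#' @param path FASTA or GenBank flat file.
#' @param coords coordinates table (data frame, single-row list, or TSV
#'   path); required for FASTA input, ignored for GenBank.
#' @param name optional name override.
#' @return A validated [locus()].
#' @export
read_locus <- function(path, coords = NULL, name = NULL) {
  first <- readLines(path, n = 1L, warn = FALSE)
  if (grepl("^LOCUS", first)) {
    gb <- .parse_genbank(path)
    return(locus(if (is.null(name)) gb$name else name, gb$sequence,
                 gb$cds_start, gb$cds_end, gb$gene_strand))
  }
  set <- Biostrings::readDNAStringSet(path)
  if (length(set) < 1L) stop("no sequence in FASTA file", call. = FALSE)
  seqname <- sub("\\s.*$", "", names(set)[1])
  if (is.null(coords)) {
    stop("FASTA input requires a coordinates table (cds_start, cds_end)",
         call. = FALSE)
  }
  co <- .read_coords(coords)
  locus(if (is.null(name)) seqname else name, as.character(set[[1]]),
        co$cds_start, co$cds_end, co$gene_strand)
}

#' Write a locus as FASTA plus a coordinates TSV
#'
#' The pair of files round-trips exactly through [read_locus()].
#'
#' @param x a `locus`.
#' @param fasta_path,coords_path output paths.
#' @return `x`, invisibly.
#' @export
write_locus <- function(x, fasta_path, coords_path) {
  stopifnot(inherits(x, "locus"))
  set <- Biostrings::DNAStringSet(x$sequence)
  names(set) <- x$name
  Biostrings::writeXStringSet(set, fasta_path)
  utils::write.table(
    data.frame(name = x$name, cds_start = x$cds_interval[1],
               cds_end = x$cds_interval[2], gene_strand = x$gene_strand),
    coords_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(x)
}

# --- restriction enzymes ----------------------------------------------------

#' Load a restriction-enzyme table
#'
#' The packaged table ships SalI plus a panel of common 6- and 8-cutters.
#' Cut offsets are measured from the 5' end of the recognition site on the
#' top strand: `cut_top` is the top-strand cut, `cut_bottom` the bottom-strand
#' cut expressed in top-strand coordinates (SalI G^TCGAC is `1`/`5`).
#'
#' @param path optional TSV with columns `name`, `site`, `cut_top`,
#'   `cut_bottom`; defaults to the packaged table.
#' @return A `data.frame` of class `"enzyme_db"`.
#' @export
restriction_enzymes <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "restriction_enzymes.tsv",
                        package = "kistat", mustWork = TRUE)
  }
  db <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "site", "cut_top", "cut_bottom")
  if (!all(need %in% names(db))) {
    stop("enzyme table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  db$site <- toupper(db$site)
  ok <- grepl("^[ACGT]+$", db$site) &
    db$cut_top >= 0 & db$cut_top <= nchar(db$site) &
    db$cut_bottom >= 0 & db$cut_bottom <= nchar(db$site)
  if (!all(ok)) stop("inconsistent enzyme definitions", call. = FALSE)
  db <- db[order(db$name), , drop = FALSE]
  rownames(db) <- NULL
  class(db) <- c("enzyme_db", "data.frame")
  db
}

#' Look up one enzyme from an enzyme table
#'
#' @param name enzyme name, e.g. `"SalI"`.
#' @param db table from [restriction_enzymes()].
#' @return A one-row list with `name`, `site`, `cut_top`, `cut_bottom`.
#' @export
enzyme <- function(name, db = restriction_enzymes()) {
  i <- match(name, db$name)
  if (is.na(i)) stop("unknown enzyme '", name, "'", call. = FALSE)
  as.list(db[i, c("name", "site", "cut_top", "cut_bottom")])
}

# --- epitope tags -----------------------------------------------------------

#' Shipped epitope-tag table
#'
#' FLAG (8 aa, 24 nt) and HA (9 aa, 27 nt) with standard codon choices. The
#' nucleotide lengths are what drive the expected knock-in size shifts
#' (spacer + tag + stop).
#'
#' @return `data.frame` with columns `name`, `peptide`, `coding_nt`.
#' @export
epitope_tags <- function() {
  data.frame(
    name = c("FLAG", "HA"),
    peptide = c("DYKDDDDK", "YPYDVPDYA"),
    coding_nt = c("GATTACAAGGATGACGATGACAAG",
                  "TACCCATACGATGTTCCAGATTACGCT"),
    stringsAsFactors = FALSE)
}

#' Construct or look up an epitope tag
#'
#' @param name tag name. If it matches the shipped table and no sequences
#'   are supplied, the shipped entry is returned.
#' @param peptide,coding_nt custom tag definition; `coding_nt` must translate
#'   exactly to `peptide` and contain no stop codon.
#' @return Object of class `"epitope_tag"`.
#' @examples
#' epitope_tag("FLAG")
#' @export
epitope_tag <- function(name, peptide = NULL, coding_nt = NULL) {
  if (is.null(peptide) && is.null(coding_nt)) {
    tab <- epitope_tags()
    i <- match(name, tab$name)
    if (is.na(i)) stop("unknown tag '", name, "'; supply peptide + coding_nt",
                       call. = FALSE)
    peptide <- tab$peptide[i]
    coding_nt <- tab$coding_nt[i]
  }
  coding_nt <- .check_dna(coding_nt, "coding_nt")
  if (nchar(coding_nt) != 3L * nchar(peptide)) {
    stop("coding_nt must be exactly 3 nt per residue", call. = FALSE)
  }
  aa <- translate_dna(coding_nt)
  if (grepl("\\*", aa)) stop("tag coding sequence contains a stop codon",
                             call. = FALSE)
  if (aa != toupper(peptide)) {
    stop("coding_nt does not translate to the stated peptide", call. = FALSE)
  }
  structure(list(name = name, peptide = toupper(peptide),
                 coding_nt = coding_nt),
            class = "epitope_tag")
}

# --- codon bookkeeping ------------------------------------------------------

# Codon containing a + strand position, or NULL outside the CDS.
# positions come back in gene order; phase is 0-based within the codon.
.codon_at <- function(locus, pos) {
  cs <- locus$cds_interval[1]; ce <- locus$cds_interval[2]
  if (pos < cs || pos >= ce) return(NULL)
  if (locus$gene_strand == "+") {
    off <- pos - cs
    list(positions = cs + (off %/% 3L) * 3L + 0:2, phase = off %% 3L)
  } else {
    off <- (ce - 1L) - pos
    list(positions = (ce - 1L) - ((off %/% 3L) * 3L + 0:2), phase = off %% 3L)
  }
}

#' Is a single-base substitution silent?
#'
#' A substitution outside the CDS is unconstrained and reported as silent.
#' Inside the CDS the affected codon is re-translated (gene-strand aware;
#' `to_base` is given on the + strand of the locus).
#'
#' @param locus a [locus()].
#' @param position 0-based + strand coordinate.
#' @param to_base replacement base on the + strand.
#' @return `TRUE` if the encoded amino acid is unchanged (or the position is
#'   non-coding).
#' @export
is_silent_substitution <- function(locus, position, to_base) {
  info <- .codon_at(locus, position)
  if (is.null(info)) return(TRUE)
  bases <- vapply(info$positions, function(p) .base_at(locus$sequence, p), "")
  nb <- toupper(to_base)
  if (locus$gene_strand == "-") {
    bases <- .comp(bases)
    nb <- .comp(nb)
  }
  before <- paste(bases, collapse = "")
  bases[info$phase + 1L] <- nb
  after <- paste(bases, collapse = "")
  translate_dna(before) == translate_dna(after)
}
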