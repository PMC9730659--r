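# Synthetic-data generator: mosaic F0 allele mixtures, rendered
# electropherograms, and pooled-embryo founder screening. This is the test
# harness that makes every screening operation exercisable end-to-end; it is
# not a biological model of HDR.

.random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

.STOP_CODONS <- c("TAA", "TAG", "TGA")

.random_codons <- function(n) {
  all <- as.vector(outer(outer(DNA_BASES, DNA_BASES, paste0),
                         DNA_BASES, paste0))
  ok <- setdiff(all, .STOP_CODONS)
  paste(sample(ok, n, replace = TRUE), collapse = "")
}

#' Reverse-complement a locus in place
#'
#' Returns the same physical locus stored on the opposite strand (sequence
#' reverse-complemented, CDS interval mirrored, gene strand flipped, cohort
#' SNPs mirrored and complemented). A guide defined on the original stored
#' strand must have its `strand` flipped by the caller to refer to the same
#' physical site.
#'
#' @param x a [locus()].
#' @return A `locus`.
#' @export
flip_locus <- function(x) {
  stopifnot(inherits(x, "locus"))
  n <- nchar(x$sequence)
  snps <- x$cohort_snps
  if (!is.null(snps)) {
    snps <- data.frame(position = n - 1L - snps$position,
                       ref_base = .comp(toupper(snps$ref_base)),
                       cohort_base = .comp(toupper(snps$cohort_base)),
                       stringsAsFactors = FALSE)
  }
  locus(x$name, revcomp(x$sequence),
        n - x$cds_interval[2], n - x$cds_interval[1],
        if (x$gene_strand == "+") "-" else "+",
        cohort_snps = snps)
}

#' Synthesize a tag-knock-in test locus
#'
#' Random single-CDS locus with an sgRNA placed so that the blunt Cas9 cut
#' bond falls exactly `spacer_len` nt upstream of the stop codon - the
#' geometry that fixes the knock-in size shift (`spacer + tag + 3`).
#' Generation retries until the guide is unique on the locus and a full tag
#' design (including a blocking substitution that abolishes re-cutting)
#' succeeds.
#'
#' @param spacer_len nt between the cut bond and the stop codon.
#' @param guide_strand strand of the protospacer relative to the stored
#'   sequence (the gene is on `+`).
#' @param n_codons CDS length in codons (excluding stop).
#' @param utr5,utr3 flank lengths in nt.
#' @param seed RNG seed; generation is deterministic given the seed.
#' @return List with `locus` and `guide`.
#' @export
synth_tag_locus <- function(spacer_len, guide_strand = "+", n_codons = 60,
                            utr5 = 30, utr3 = 120, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  spacer_len <- as.integer(spacer_len)
  stopifnot(spacer_len >= 0L)
  for (attempt in 1:300) {
    seq <- paste0(.random_dna(utr5), "ATG", .random_codons(n_codons), "TAA",
                  .random_dna(utr3))
    cds_start <- utr5
    cds_end <- utr5 + 3L + 3L * n_codons + 3L
    a <- cds_end - 3L                       # stop codon start
    cut <- a - spacer_len
    if (guide_strand == "+") {
      if (spacer_len >= 2L && spacer_len <= 5L) {
        stop("a + strand guide cutting ", spacer_len, " nt upstream of the ",
             "stop would need its PAM GG inside the stop codon; use a - ",
             "strand guide for this geometry", call. = FALSE)
      }
      if (cut - 17L < 0L || cut + 6L > nchar(seq)) {
        stop("locus too short for the requested geometry", call. = FALSE)
      }
      # force the PAM GG 4-5 nt downstream of the cut bond
      substr(seq, cut + 5L, cut + 6L) <- "GG"
      proto <- substr(seq, cut - 16L, cut + 3L)
      pam <- substr(seq, cut + 4L, cut + 6L)
    } else {
      if (cut - 6L < 0L || cut + 17L > nchar(seq)) {
        stop("locus too short for the requested geometry", call. = FALSE)
      }
      substr(seq, cut - 5L, cut - 4L) <- "CC"   # PAM GG on the - strand
      proto <- revcomp(substr(seq, cut - 2L, cut + 17L))
      pam <- revcomp(substr(seq, cut - 5L, cut - 3L))
    }
    loc <- try(locus("synthetic_tag_locus", seq, cds_start, cds_end),
               silent = TRUE)
    if (inherits(loc, "try-error")) next
    g <- try(guide(proto, pam, guide_strand, "synth_guide"), silent = TRUE)
    if (inherits(g, "try-error")) next
    cutsite <- try(find_cut_site(loc, g), silent = TRUE)
    if (inherits(cutsite, "try-error")) next
    if (cutsite$position != cut) next
    d <- try(suppressWarnings(design_tag_ssodn(loc, g, "FLAG")),
             silent = TRUE)
    if (inherits(d, "try-error")) next
    return(list(locus = loc, guide = g))
  }
  stop("failed to synthesize a tag locus after 300 attempts", call. = FALSE)
}

#' Synthesize a point-mutation test locus
#'
#' Random single-CDS locus that reproduces the geometry of a
#' Gaucher-disease-style point knock-in: the desired edit (A>C in an AAT
#' codon, Asn -> His) lies 17 nt downstream of the cut bond; a silent cohort
#' SNP sits in the proximal arm (stored sequence carries the cohort base,
#' reversion to the reference is silent); and the PAM contains a G whose
#' silent G>C change creates a SalI site (GTGGAC -> GTCGAC).
#'
#' @param seed RNG seed.
#' @return List with `locus`, `guide`, `desired_edits` and `snp_reversions`
#'   (data frames ready for [design_point_ssodn()]), and `motif_start` (the
#'   + strand position of the SalI precursor).
#' @export
synth_point_locus <- function(seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  utr5 <- 40L; utr3 <- 80L
  for (attempt in 1:300) {
    cds <- paste0("ATG", .random_codons(10), "GTGGAC", .random_codons(3),
                  "AAT", "CTG", .random_codons(8), "TAA")
    seq <- paste0(.random_dna(utr5), cds, .random_dna(utr3))
    m <- utr5 + 3L + 30L                       # motif start, 0-based
    cds_start <- utr5
    cds_end <- utr5 + nchar(cds)
    if (length(.find_all(seq, "GTCGAC")) > 0L) next
    proto <- substr(seq, m - 18L, m + 1L)      # 0-based [m-19, m+1)
    pam <- substr(seq, m + 2L, m + 4L)         # "TGG"
    loc <- try(locus("synthetic_point_locus", seq, cds_start, cds_end,
                     cohort_snps = data.frame(position = m + 20L,
                                              ref_base = "A",
                                              cohort_base = "G")),
               silent = TRUE)
    if (inherits(loc, "try-error")) next
    g <- try(guide(proto, pam, "+", "synth_point_guide"), silent = TRUE)
    if (inherits(g, "try-error")) next
    cutsite <- try(find_cut_site(loc, g), silent = TRUE)
    if (inherits(cutsite, "try-error")) next
    if (cutsite$position != m - 2L) next
    edits <- data.frame(position = m + 15L, to_base = "C")
    revs <- data.frame(position = m + 20L, to_base = "A")
    d <- try(suppressWarnings(design_point_ssodn(loc, g, edits, revs)),
             silent = TRUE)
    if (inherits(d, "try-error")) next
    return(list(locus = loc, guide = g, desired_edits = edits,
                snp_reversions = revs, motif_start = m))
  }
  stop("failed to synthesize a point locus after 300 attempts", call. = FALSE)
}

#' Build an indel allele at the cut site
#'
#' Deletions remove bases centered on the cut bond; insertions add random
#' bases at the bond (drawn from the current RNG stream).
#'
#' @param locus a [locus()].
#' @param cut_position 0-based bond coordinate.
#' @param size signed indel size in nt (negative = deletion); must be
#'   non-zero.
#' @return The allele DNA string.
#' @export
indel_allele <- function(locus, cut_position, size) {
  stopifnot(inherits(locus, "locus"), size != 0)
  seq <- locus$sequence
  p <- as.integer(cut_position)
  if (size < 0) {
    k <- -as.integer(size)
    left <- (k + 1L) %/% 2L
    right <- k - left
    if (p - left < 0L || p + right > nchar(seq)) {
      stop("deletion extends past the locus", call. = FALSE)
    }
    paste0(substr(seq, 1L, p - left), substr(seq, p + right + 1L, nchar(seq)))
  } else {
    paste0(substr(seq, 1L, p), .random_dna(size),
           substr(seq, p + 1L, nchar(seq)))
  }
}

#' Construct a mosaic sample from explicit allele fractions
#'
#' @param alleles data frame with columns `allele` (unique labels; `"WT"`
#'   and `"HDR"` are recognized by downstream tools), `indel_size` (0 for
#'   WT/HDR) and `fraction` (in `[0, 1]`, summing to 1 within 1e-9).
#' @param provenance `"embryo"`, `"fin"` or `"pool"`.
#' @param seed seed recorded on the object (metadata only).
#' @return Object of class `"mosaic_sample"`.
#' @export
mosaic_sample <- function(alleles, provenance = "embryo", seed = NULL) {
  alleles <- as.data.frame(alleles)
  stopifnot(all(c("allele", "indel_size", "fraction") %in% names(alleles)))
  if (anyDuplicated(alleles$allele)) stop("allele labels must be unique",
                                          call. = FALSE)
  if (any(alleles$fraction < 0 | alleles$fraction > 1) ||
      abs(sum(alleles$fraction) - 1) > 1e-9) {
    stop("fractions must lie in [0,1] and sum to 1", call. = FALSE)
  }
  hdr <- alleles$fraction[alleles$allele == "HDR"]
  structure(list(alleles = alleles,
                 hdr_fraction = if (length(hdr)) hdr else 0,
                 provenance = provenance, seed = seed),
            class = "mosaic_sample")
}

#' @export
print.mosaic_sample <- function(x, ...) {
  cat("<mosaic_sample>", x$provenance, "- HDR fraction",
      signif(x$hdr_fraction, 3), "\n")
  print(x$alleles, row.names = FALSE)
  invisible(x)
}

#' Simulate a mosaic F0 sample
#'
#' Draws a finite pool of `n_cells` genome copies from the target allele
#' mixture (multinomial), so observed fractions scatter around the targets.
#' Indel sizes follow a signed geometric mixture: deletions with probability
#' `indel_del_prob`, magnitudes `rgeom(p = indel_geom_p) + 1` redrawn above
#' `indel_max`, never 0.
#'
#' @param hdr_frac target HDR (knock-in) allele fraction.
#' @param indel_rate total target fraction of CRISPR indel alleles.
#' @param n_indel_alleles number of distinct indel alleles.
#' @param n_cells genome copies sampled per embryo.
#' @param indel_del_prob,indel_geom_p,indel_max indel size distribution.
#' @param seed RNG seed (determinism contract: identical seeds give
#'   identical samples).
#' @param provenance sample provenance label.
#' @return A [mosaic_sample()].
#' @export
simulate_mosaic <- function(hdr_frac = 0.2, indel_rate = 0.6,
                            n_indel_alleles = 4, n_cells = 200,
                            indel_del_prob = 0.7, indel_geom_p = 0.3,
                            indel_max = 30, seed = NULL,
                            provenance = "embryo") {
  if (!is.null(seed)) set.seed(seed)
  if (hdr_frac < 0 || indel_rate < 0 || hdr_frac + indel_rate > 1) {
    stop("hdr_frac + indel_rate must lie in [0, 1]", call. = FALSE)
  }
  n_indel_alleles <- as.integer(n_indel_alleles)
  if (indel_rate > 0 && n_indel_alleles < 1L) {
    stop("indel_rate > 0 needs at least one indel allele", call. = FALSE)
  }
  sizes <- integer(0)
  probs <- c(WT = 1 - hdr_frac - indel_rate, HDR = hdr_frac)
  if (n_indel_alleles > 0L && indel_rate > 0) {
    mag <- integer(n_indel_alleles)
    for (i in seq_len(n_indel_alleles)) {
      repeat {
        k <- stats::rgeom(1, indel_geom_p) + 1L
        if (k <= indel_max) { mag[i] <- k; break }
      }
    }
    sign <- ifelse(stats::runif(n_indel_alleles) < indel_del_prob, -1L, 1L)
    sizes <- sign * mag
    w <- stats::rgamma(n_indel_alleles, 1)
    probs <- c(probs, indel_rate * w / sum(w))
  }
  counts <- stats::rmultinom(1, n_cells, probs)[, 1]
  alleles <- data.frame(
    allele = c("WT", "HDR",
               if (length(sizes)) paste0("indel", seq_along(sizes), "_",
                                         sizes)),
    indel_size = c(0L, 0L, sizes),
    fraction = counts / n_cells,
    stringsAsFactors = FALSE)
  mosaic_sample(alleles, provenance = provenance, seed = seed)
}

#' Render a mosaic sample as an electropherogram
#'
#' Each allele is amplified in silico (alleles that lost a primer site drop
#' out), digested when requested, and contributes a peak at its detected
#' fragment size with height proportional to its allele fraction. Noise:
#' lognormal height multiplier with coefficient of variation `height_cv`
#' (mean 1) and Gaussian size jitter with SD `size_jitter_sd` bp, chosen to
#' respect the 1-bp matching tolerance of capillary electrophoresis.
#'
#' @param sample a [mosaic_sample()].
#' @param design an `ssodn_design` (supplies the knock-in allele and, in
#'   digested mode, the diagnostic enzyme).
#' @param locus the locus.
#' @param primers a [primer_pair()].
#' @param mode `"undigested"` or `"digested"`.
#' @param enz enzyme for digested mode (default: design diagnostic).
#' @param height_cv,size_jitter_sd noise parameters.
#' @param scale height of a fraction-1 allele in arbitrary fluorescence
#'   units.
#' @param sample_id identifier stored on the trace.
#' @param seed RNG seed.
#' @return An [electropherogram()].
#' @export
render_peaks <- function(sample, design, locus, primers,
                         mode = c("undigested", "digested"), enz = NULL,
                         height_cv = 0.2, size_jitter_sd = 0.15,
                         scale = 1000, sample_id = NULL, seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(sample, "mosaic_sample"))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(sample_id)) sample_id <- paste0(sample$provenance, "_sample")
  digested <- mode == "digested"
  if (digested && is.null(enz)) {
    if (is.null(design$diagnostic)) {
      stop("digested mode requires an enzyme", call. = FALSE)
    }
    enz <- design$diagnostic$enzyme
  }
  if (is.character(enz)) enz <- enzyme(enz)
  cutpos <- design$cut_site$position
  sizes <- numeric(0)
  fracs <- numeric(0)
  for (i in seq_len(nrow(sample$alleles))) {
    row <- sample$alleles[i, ]
    if (row$fraction <= 0) next
    aseq <- if (row$allele == "WT") locus$sequence
      else if (row$allele == "HDR") design$ki_allele
      else indel_allele(locus, cutpos, row$indel_size)
    amp <- build_amplicon(aseq, primers, row$allele)
    if (!amp$found) next
    sz <- if (digested) digest_amplicon(amp, enz)$detected_length
          else amp$length
    sizes <- c(sizes, sz)
    fracs <- c(fracs, row$fraction)
  }
  if (!length(sizes)) {
    return(electropherogram(data.frame(size_bp = numeric(0),
                                       height = numeric(0)),
                            sample_id, digested))
  }
  agg <- tapply(fracs, sizes, sum)
  sz <- as.numeric(names(agg))
  frac <- as.numeric(agg)
  sdlog <- sqrt(log(1 + height_cv^2))
  mult <- exp(stats::rnorm(length(frac), -sdlog^2 / 2, sdlog))
  heights <- frac * scale * mult
  sz_obs <- sz + stats::rnorm(length(sz), 0, size_jitter_sd)
  electropherogram(data.frame(size_bp = sz_obs, height = heights),
                   sample_id, digested)
}

#' Simulate a pooled-embryo founder screen
#'
#' Each of `n_pools` pools holds `pool_size` embryos; every embryo carries
#' the knock-in allele independently with the founder's germline
#' transmission rate `r`. On the fast path a pool is detectable-positive iff
#' at least one embryo is a carrier; with `render = TRUE` the pooled allele
#' mixture (carriers heterozygous, equal DNA contribution per embryo) is
#' rendered and classified, so pool dilution and noise can suppress
#' detection. The analytic expectation `1 - (1 - r)^pool_size` is returned
#' alongside.
#'
#' @param r germline transmission rate in `[0, 1]`.
#' @param pool_size embryos per pool (default 3).
#' @param n_pools number of pools (default 24 per founder).
#' @param seed RNG seed.
#' @param render classify rendered pooled electropherograms instead of using
#'   carrier counts directly.
#' @param design,locus,primers,mode,... rendering/classification arguments
#'   (required when `render = TRUE`), passed to [render_peaks()] and
#'   [classify_sample()].
#' @param size_tol,background_frac classifier settings for rendered pools.
#' @return List with `pool_positive`, `carriers_per_pool`, `n_positive`,
#'   `observed_rate`, `expected_rate`.
#' @export
simulate_founder_screen <- function(r, pool_size = 3, n_pools = 24,
                                    seed = NULL, render = FALSE,
                                    design = NULL, locus = NULL,
                                    primers = NULL, mode = "undigested",
                                    size_tol = 1.0, background_frac = 0.05,
                                    ...) {
  if (r < 0 || r > 1) stop("r must lie in [0, 1]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  carriers <- matrix(stats::runif(n_pools * pool_size) < r,
                     nrow = n_pools)
  npos <- rowSums(carriers)
  if (!render) {
    calls <- npos > 0L
  } else {
    if (is.null(design) || is.null(locus) || is.null(primers)) {
      stop("render = TRUE needs design, locus and primers", call. = FALSE)
    }
    exp_sizes <- expected_peaks(design, locus, primers, mode)
    calls <- vapply(seq_len(n_pools), function(i) {
      ki <- 0.5 * npos[i] / pool_size   # heterozygous carriers, equal DNA
      s <- mosaic_sample(data.frame(allele = c("WT", "HDR"),
                                    indel_size = c(0L, 0L),
                                    fraction = c(1 - ki, ki)),
                         provenance = "pool")
      eph <- render_peaks(s, design, locus, primers, mode, ...)
      classify_sample(eph, exp_sizes, size_tol, background_frac)$call ==
        "positive"
    }, logical(1))
  }
  list(pool_positive = calls,
       carriers_per_pool = npos,
       n_positive = sum(calls),
       observed_rate = mean(calls),
       expected_rate = 1 - (1 - r)^pool_size,
       r = r, pool_size = pool_size, n_pools = n_pools)
}
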