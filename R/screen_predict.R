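# Allele-specific amplicons, fluorescent-PCR size prediction, restriction
# digests with 5'-label detection, and peak classification.

#' Construct a screening primer pair
#'
#' In-silico PCR is exact-match, convergent and unique-hit. The forward
#' primer carries the labeled universal tail (three-primer M13 system,
#' modelled as a constant tail length); the reverse primer may carry a
#' restriction-site tail used as an internal digestion control.
#'
#' @param forward,reverse genome-binding primer parts; `forward` matches the
#'   + strand, `reverse` the - strand of the locus.
#' @param forward_tail 5' tail on the forward primer (default [M13F_TAIL]).
#' @param reverse_tail 5' tail on the reverse primer (e.g.
#'   [SALI_CONTROL_TAIL]; default none).
#' @param name optional identifier.
#' @return Object of class `"primer_pair"`.
#' @export
primer_pair <- function(forward, reverse, forward_tail = M13F_TAIL,
                        reverse_tail = "", name = "primers") {
  structure(list(name = name,
                 forward = .check_dna(forward, "forward"),
                 reverse = .check_dna(reverse, "reverse"),
                 forward_tail = .check_dna(forward_tail, "forward_tail"),
                 reverse_tail = .check_dna(reverse_tail, "reverse_tail")),
            class = "primer_pair")
}

# Unique binding interval of a primer part, or NULL.
.bind_interval <- function(seq, part, strand) {
  pat <- if (strand == "+") part else revcomp(part)
  hits <- .find_all(seq, pat)
  if (length(hits) != 1L) return(NULL)
  c(hits, hits + nchar(pat))
}

#' Pick screening primers outside the homology arms
#'
#' Convenience generator for simulations and examples: chooses the closest
#' unique exact-match 20-mers flanking the homology-arm window with a small
#' gap, as the screening-primer rule requires binding sites disjoint from the
#' arms.
#'
#' @param locus a [locus()].
#' @param design an `ssodn_design` on that locus.
#' @param len primer length.
#' @param gap nt between each arm edge and the near primer end.
#' @param forward_tail,reverse_tail tails passed to [primer_pair()].
#' @return A `primer_pair`.
#' @export
pick_screening_primers <- function(locus, design, len = 20, gap = 5,
                                   forward_tail = M13F_TAIL,
                                   reverse_tail = "") {
  w <- design$arm_window
  f_end <- w[1] - gap
  if (f_end - len < 0) stop("no room for a forward primer upstream of the ",
                            "homology arms", call. = FALSE)
  fwd <- substr(locus$sequence, f_end - len + 1L, f_end)
  r_start <- w[2] + gap
  if (r_start + len > nchar(locus$sequence)) {
    stop("no room for a reverse primer downstream of the homology arms",
         call. = FALSE)
  }
  rev <- revcomp(substr(locus$sequence, r_start + 1L, r_start + len))
  pp <- primer_pair(fwd, rev, forward_tail, reverse_tail)
  rep <- validate_primers(pp, design, locus)
  if (!rep$pass) stop("generated primers failed validation", call. = FALSE)
  pp
}

#' Validate primer placement against a design
#'
#' Screening primers must bind the genomic regions outside the homology-arm
#' window, so that imprecise integration of the repair template cannot
#' produce a false-positive product.
#'
#' @param primers a [primer_pair()].
#' @param design an `ssodn_design`.
#' @param locus the locus both refer to.
#' @return List with `pass`, per-primer intervals, distances from the arm
#'   window, and `failures` naming any offending primer.
#' @export
validate_primers <- function(primers, design, locus) {
  stopifnot(inherits(primers, "primer_pair"),
            inherits(design, "ssodn_design"), inherits(locus, "locus"))
  w <- design$arm_window
  f <- .bind_interval(locus$sequence, primers$forward, "+")
  r <- .bind_interval(locus$sequence, primers$reverse, "-")
  failures <- character(0)
  if (is.null(f)) failures <- c(failures, "forward primer does not map uniquely")
  if (is.null(r)) failures <- c(failures, "reverse primer does not map uniquely")
  overlaps <- function(iv) !(iv[2] <= w[1] || iv[1] >= w[2])
  if (!is.null(f) && overlaps(f)) {
    failures <- c(failures, "forward primer overlaps the homology-arm window")
  }
  if (!is.null(r) && overlaps(r)) {
    failures <- c(failures, "reverse primer overlaps the homology-arm window")
  }
  if (!is.null(f) && !is.null(r) && f[1] >= r[2]) {
    failures <- c(failures, "primers are not convergent around the arms")
  }
  list(pass = length(failures) == 0L,
       forward_interval = f, reverse_interval = r,
       forward_distance = if (is.null(f)) NA_integer_ else w[1] - f[2],
       reverse_distance = if (is.null(r)) NA_integer_ else r[1] - w[2],
       failures = failures)
}

#' Build an allele-specific amplicon by in-silico PCR
#'
#' Both genome-binding primer parts must match the allele exactly once in
#' convergent orientation; otherwise a no-product result is returned (not an
#' error - an indel through a binding site simply gives no peak). The
#' amplicon runs from the forward 5' tail through the reverse-complemented
#' reverse 5' tail; the fluorescent label sits at position 0 (forward 5').
#'
#' @param allele_sequence DNA string of the allele (WT locus sequence,
#'   `design$ki_allele`, or an explicit indel allele).
#' @param primers a [primer_pair()].
#' @param allele label stored on the product (e.g. `"WT"`, `"KI"`).
#' @return Object of class `"amplicon"` with `found`, `sequence`, `length`.
#' @export
build_amplicon <- function(allele_sequence, primers, allele = "allele") {
  allele_sequence <- .check_dna(allele_sequence, "allele_sequence")
  stopifnot(inherits(primers, "primer_pair"))
  f <- .bind_interval(allele_sequence, primers$forward, "+")
  r <- .bind_interval(allele_sequence, primers$reverse, "-")
  if (is.null(f) || is.null(r) || f[2] > r[1]) {
    return(structure(list(allele = allele, found = FALSE,
                          sequence = NA_character_, length = NA_integer_),
                     class = "amplicon"))
  }
  seq <- paste0(primers$forward_tail,
                substr(allele_sequence, f[1] + 1L, r[2]),
                revcomp(primers$reverse_tail))
  structure(list(allele = allele, found = TRUE, sequence = seq,
                 length = nchar(seq), labeled_position = 0L),
            class = "amplicon")
}

#' @export
print.amplicon <- function(x, ...) {
  if (!x$found) cat("<amplicon>", x$allele, "- no product\n")
  else cat("<amplicon>", x$allele, "-", x$length, "bp (5' label)\n")
  invisible(x)
}

#' Digest an amplicon and report the labeled fragment
#'
#' Cuts at every occurrence of the recognition site on either strand
#' (palindromic sites are found once). Fragment boundaries are the top-strand
#' cut positions, matching how capillary electrophoresis sizes the labeled
#' strand. Only the fragment carrying the 5' forward label (position 0) is
#' detected; an uncut amplicon is detected at full length.
#'
#' @param amplicon an [build_amplicon()] product with `found = TRUE`.
#' @param enz enzyme list from [enzyme()] (or an enzyme name).
#' @return Object of class `"digest_result"`: `fragments` data frame
#'   (`start`, `end`, `length`) and `detected_length`.
#' @export
digest_amplicon <- function(amplicon, enz) {
  stopifnot(inherits(amplicon, "amplicon"))
  if (!amplicon$found) stop("cannot digest a no-product amplicon",
                            call. = FALSE)
  if (is.character(enz)) enz <- enzyme(enz)
  seq <- amplicon$sequence
  n <- nchar(seq)
  site <- enz$site
  len <- nchar(site)
  cuts <- .find_all(seq, site) + enz$cut_top
  rc <- revcomp(site)
  if (!identical(rc, site)) {
    cuts <- c(cuts, .find_all(seq, rc) + (len - enz$cut_bottom))
  }
  cuts <- sort(unique(cuts[cuts > 0L & cuts < n]))
  bounds <- c(0L, cuts, n)
  frags <- data.frame(start = bounds[-length(bounds)], end = bounds[-1])
  frags$length <- frags$end - frags$start
  structure(list(fragments = frags,
                 detected_length = frags$length[1],
                 enzyme = enz$name, amplicon_length = n),
            class = "digest_result")
}

#' Expected diagnostic peak sizes for a design
#'
#' Builds the WT and knock-in amplicons and, in digested mode, digests both
#' with the diagnostic enzyme; returns the two sizes the classifier will
#' match against. In tag mode (undigested) the knock-in peak sits
#' `predicted_size_shift` bp above the WT peak; in point mode the undigested
#' sizes coincide and digestion separates the alleles.
#'
#' @param design an `ssodn_design`.
#' @param locus the locus.
#' @param primers a validated [primer_pair()].
#' @param mode `"undigested"` or `"digested"`.
#' @param enz enzyme for digested mode; defaults to the design's diagnostic
#'   enzyme.
#' @return List with `wt_size`, `ki_size`, `mode`, `digested`.
#' @export
expected_peaks <- function(design, locus, primers,
                           mode = c("undigested", "digested"), enz = NULL) {
  mode <- match.arg(mode)
  wt <- build_amplicon(locus$sequence, primers, "WT")
  ki <- build_amplicon(design$ki_allele, primers, "KI")
  if (!wt$found || !ki$found) {
    stop("primers do not amplify the WT or knock-in allele", call. = FALSE)
  }
  if (mode == "undigested") {
    return(list(wt_size = wt$length, ki_size = ki$length,
                mode = mode, digested = FALSE))
  }
  if (is.null(enz)) {
    if (is.null(design$diagnostic)) {
      stop("digested mode requires a diagnostic enzyme in the design",
           call. = FALSE)
    }
    enz <- design$diagnostic$enzyme
  }
  if (is.character(enz)) enz <- enzyme(enz)
  list(wt_size = digest_amplicon(wt, enz)$detected_length,
       ki_size = digest_amplicon(ki, enz)$detected_length,
       mode = mode, digested = TRUE, enzyme = enz$name)
}

#' Construct an electropherogram peak table
#'
#' @param peaks data frame with numeric columns `size_bp` (> 0) and `height`
#'   (>= 0).
#' @param sample_id sample identifier.
#' @param digested was the sample digested before fragment analysis?
#' @return `data.frame` of class `"electropherogram"` with attributes
#'   `sample_id` and `digested`.
#' @export
electropherogram <- function(peaks, sample_id = "sample", digested = FALSE) {
  peaks <- as.data.frame(peaks)
  if (nrow(peaks)) {
    if (!all(c("size_bp", "height") %in% names(peaks))) {
      stop("peaks need columns size_bp and height", call. = FALSE)
    }
    if (any(peaks$size_bp <= 0) || any(peaks$height < 0)) {
      stop("peak sizes must be positive and heights non-negative",
           call. = FALSE)
    }
    peaks <- peaks[order(peaks$size_bp), c("size_bp", "height"),
                   drop = FALSE]
    rownames(peaks) <- NULL
  } else {
    peaks <- data.frame(size_bp = numeric(0), height = numeric(0))
  }
  structure(peaks, sample_id = sample_id, digested = digested,
            class = c("electropherogram", "data.frame"))
}

#' Classify a sample as knock-in positive or negative
#'
#' A sample is positive when some peak within `size_tol` bp of the expected
#' knock-in size rises above the background threshold (a fraction of the
#' tallest peak in the trace). In digested mode the trimmed WT peak must be
#' present as the internal digestion control; when it is missing the call is
#' `"invalid"`, as is an empty trace.
#'
#' @param eph an [electropherogram()] (or plain peak data frame).
#' @param expected list with `wt_size` and `ki_size` (see
#'   [expected_peaks()]).
#' @param size_tol matching tolerance in bp (capillary electrophoresis
#'   resolves single base pairs; default 1.0).
#' @param background_frac background threshold as a fraction of the tallest
#'   peak (default 0.05).
#' @param digested override the electropherogram's digested flag.
#' @return List with `call` (`"positive"`, `"negative"` or `"invalid"`),
#'   `matched_peaks`, `control_ok`, and the thresholds used.
#' @export
classify_sample <- function(eph, expected, size_tol = 1.0,
                            background_frac = 0.05, digested = NULL) {
  if (!inherits(eph, "electropherogram")) eph <- electropherogram(eph)
  if (is.null(digested)) digested <- isTRUE(attr(eph, "digested"))
  base <- list(size_tol = size_tol, background_frac = background_frac,
               digested = digested)
  if (nrow(eph) == 0L) {
    return(c(list(call = "invalid", matched_peaks = eph[0, ],
                  control_ok = FALSE), base))
  }
  thresh <- background_frac * max(eph$height)
  near <- function(target) {
    abs(eph$size_bp - target) <= size_tol & eph$height >= thresh
  }
  control_ok <- TRUE
  if (digested) {
    control_ok <- any(near(expected$wt_size))
    if (!control_ok) {
      return(c(list(call = "invalid", matched_peaks = eph[0, ],
                    control_ok = FALSE), base))
    }
  }
  hit <- near(expected$ki_size)
  c(list(call = if (any(hit)) "positive" else "negative",
         matched_peaks = eph[hit, , drop = FALSE],
         control_ok = control_ok), base)
}

#' Audit an allele sequence against a design
#'
#' Sequence-level comparison that exposes the stated limitation of
#' site-based RFLP screening: an allele carrying the engineered/PAM site but
#' not the desired edit still digests like a knock-in and classifies
#' positive. For substitution-only (point) designs on an allele of unchanged
#' length, reports which intended substitutions are present.
#'
#' @param design an `ssodn_design`.
#' @param allele_sequence observed allele sequence (same length as the locus
#'   for point designs).
#' @return List with a per-substitution `table`, `precise` (all intended
#'   changes present), and `site_only_false_positive` (blocking/engineering
#'   changes present but at least one desired edit absent).
#' @export
audit_knockin_allele <- function(design, allele_sequence) {
  stopifnot(inherits(design, "ssodn_design"))
  allele_sequence <- .check_dna(allele_sequence, "allele_sequence")
  if (design$mode == "point" &&
      nchar(allele_sequence) != nchar(design$locus$sequence)) {
    stop("allele length differs from the locus; audit assumes a ",
         "substitution-only allele", call. = FALSE)
  }
  st <- substitution_table(design)
  st$observed <- vapply(st$position, function(p)
    .base_at(allele_sequence, p), "")
  st$present <- st$observed == st$to_base
  desired <- st$purpose == "desired_edit"
  marker <- st$purpose %in% c("pam_block", "site_engineering")
  list(table = st,
       precise = all(st$present),
       site_only_false_positive =
         any(marker) && all(st$present[marker]) &&
         any(desired) && !all(st$present[desired]))
}

#' Read / write peak tables as CSV
#'
#' The CSV layout (`sample_id`, `size_bp`, `height`, `digested`) matches
#' what fragment-analysis software exports.
#'
#' @param path CSV path.
#' @return A list of [electropherogram()] objects, one per sample.
#' @export
read_peaks_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "size_bp", "height")
  if (!all(need %in% names(df))) {
    stop("peaks CSV needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(df$digested)) df$digested <- FALSE
  lapply(split(df, df$sample_id), function(d) {
    electropherogram(d[, c("size_bp", "height")], sample_id = d$sample_id[1],
                     digested = isTRUE(as.logical(d$digested[1])))
  })
}

#' @rdname read_peaks_csv
#' @param ephs list of electropherograms.
#' @export
write_peaks_csv <- function(ephs, path) {
  if (inherits(ephs, "electropherogram")) ephs <- list(ephs)
  rows <- lapply(ephs, function(e) {
    if (nrow(e) == 0L) {
      return(data.frame(sample_id = attr(e, "sample_id"),
                        size_bp = NA_real_, height = NA_real_,
                        digested = isTRUE(attr(e, "digested"))))
    }
    data.frame(sample_id = attr(e, "sample_id"), size_bp = e$size_bp,
               height = e$height, digested = isTRUE(attr(e, "digested")))
  })
  df <- do.call(rbind, rows)
  df <- df[!is.na(df$size_bp), , drop = FALSE]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
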