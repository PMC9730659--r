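# ssODN repair-template design: epitope-tag insertion and point-mutation
# knock-in with asymmetric homology arms, silent PAM-blocking mutations and
# engineered diagnostic restriction sites.

.substitution <- function(position, from_base, to_base, purpose,
                          silent = NA, copy = "genomic",
                          cassette_offset = NA_integer_, fallback = FALSE) {
  list(position = as.integer(position), from_base = from_base,
       to_base = to_base, purpose = purpose, silent = silent, copy = copy,
       cassette_offset = cassette_offset, fallback = fallback)
}

#' Substitution list of a design as a data frame
#'
#' @param design an `ssodn_design`.
#' @return `data.frame` with one row per substitution (+ strand coordinates
#'   and bases).
#' @export
substitution_table <- function(design) {
  stopifnot(inherits(design, "ssodn_design"))
  do.call(rbind, lapply(design$substitutions, function(s) {
    data.frame(position = s$position, from_base = s$from_base,
               to_base = s$to_base, purpose = s$purpose, silent = s$silent,
               copy = s$copy, stringsAsFactors = FALSE)
  }))
}

# Apply genomic-copy substitutions to a + strand sequence.
.apply_genomic_subs <- function(seq, subs) {
  for (s in subs) {
    if (!identical(s$copy, "genomic")) next
    if (.base_at(seq, s$position) != s$from_base) {
      stop("substitution from_base does not match the sequence at position ",
           s$position, call. = FALSE)
    }
    substr(seq, s$position + 1L, s$position + 1L) <- s$to_base
  }
  seq
}

# Apply cassette-copy substitutions to the gene-orientation cassette string.
.apply_cassette_subs <- function(cassette, subs, gene_strand) {
  for (s in subs) {
    if (!identical(s$copy, "cassette")) next
    i <- s$cassette_offset + 1L
    from <- s$from_base; to <- s$to_base
    if (gene_strand == "-") { from <- .comp(from); to <- .comp(to) }
    if (substr(cassette, i, i) != from) {
      stop("cassette substitution does not match the cassette sequence",
           call. = FALSE)
    }
    substr(cassette, i, i) <- to
  }
  cassette
}

#' Spacer between the cut bond and the stop codon
#'
#' Tag-mode designs duplicate the genomic sequence from the Cas9 cut bond up
#' to (but not including) the stop codon into the repair template, in front
#' of the tag, so that the reading frame runs straight into the tag. This
#' returns that sequence in gene orientation.
#'
#' @param locus a [locus()].
#' @param cut a `cut_site` on that locus.
#' @return DNA string (possibly empty when the cut bond sits immediately
#'   before the stop codon).
#' @export
compute_spacer <- function(locus, cut) {
  stopifnot(inherits(locus, "locus"), inherits(cut, "cut_site"))
  d <- distance_to_anchor(cut, locus)
  if (d > 0) {
    stop("cut lies downstream of the stop codon; tag mode needs a cut ",
         "at or upstream of the stop", call. = FALSE)
  }
  if (locus$gene_strand == "+") {
    a <- locus$stop_codon_interval[1]
    if (cut$position < locus$cds_interval[1]) {
      stop("cut lies upstream of the CDS", call. = FALSE)
    }
    substr(locus$sequence, cut$position + 1L, a)
  } else {
    b <- locus$stop_codon_interval[2]
    if (cut$position > locus$cds_interval[2]) {
      stop("cut lies upstream of the CDS", call. = FALSE)
    }
    if (cut$position == b) "" else
      revcomp(substr(locus$sequence, b + 1L, cut$position))
  }
}

# Is `pos` (with replacement `to`, + strand) admissible as a blocking or
# engineering substitution? Tag mode: positions at/past the stop codon in
# gene orientation become non-coding after integration and are unconstrained;
# everything else must be silent. Point mode: standard CDS silence.
.silence_ok <- function(locus, pos, to, mode) {
  if (mode == "tag") {
    noncoding <- if (locus$gene_strand == "+") {
      pos >= locus$stop_codon_interval[1]
    } else {
      pos < locus$stop_codon_interval[2]
    }
    if (noncoding) return(TRUE)
  }
  is_silent_substitution(locus, pos, to)
}

# Ordered candidate PAM-blocking / seed-fallback substitutions.
.pam_block_candidates <- function(locus, guide, cut, mode) {
  seq <- locus$sequence
  out <- list()
  if (guide$strand == "+") {
    gpos <- cut$pam_interval[1] + 1:2            # PAM positions 2, 3
    alts_plus <- c("C", "A", "T")                # guide-strand G -> C/A/T
  } else {
    gpos <- c(cut$pam_interval[1] + 1L, cut$pam_interval[1])
    alts_plus <- c("G", "T", "A")                # complement of C/A/T
  }
  for (p in gpos) {
    from <- .base_at(seq, p)
    for (to in alts_plus) {
      if (to == from) next
      if (!.silence_ok(locus, p, to, mode)) next
      out[[length(out) + 1L]] <-
        .substitution(p, from, to, "pam_block",
                      silent = is_silent_substitution(locus, p, to))
    }
  }
  # Seed fallback: silent change within 10 nt of the PAM in the protospacer.
  if (guide$strand == "+") {
    seed <- (cut$protospacer_interval[2] - 1L):(cut$protospacer_interval[2] - 10L)
  } else {
    seed <- cut$protospacer_interval[1]:(cut$protospacer_interval[1] + 9L)
  }
  for (p in seed) {
    from <- .base_at(seq, p)
    for (to in setdiff(DNA_BASES, from)) {
      if (!.silence_ok(locus, p, to, mode)) next
      out[[length(out) + 1L]] <-
        .substitution(p, from, to, "pam_block",
                      silent = is_silent_substitution(locus, p, to),
                      fallback = TRUE)
    }
  }
  out
}

#' Find a silent CRISPR/Cas-blocking substitution
#'
#' Prefers a single change at a PAM G (abolishing NGG); the change must be
#' silent where it remains coding after integration and is unconstrained in
#' non-coding positions. When no admissible PAM change exists, falls back to
#' a silent protospacer-seed change within 10 nt of the PAM (flagged, with a
#' warning), which abolishes cutting under the exact-match re-cut model.
#'
#' @param locus a [locus()].
#' @param guide a [guide()].
#' @param mode `"point"` (silence judged against the CDS as-is) or `"tag"`
#'   (positions at/past the stop codon become non-coding after integration).
#' @param cut optional precomputed `cut_site`.
#' @return A substitution record (list with `position`, `from_base`,
#'   `to_base`, `purpose`, `silent`, `fallback`).
#' @export
find_silent_pam_block <- function(locus, guide, mode = c("point", "tag"),
                                  cut = NULL) {
  mode <- match.arg(mode)
  if (is.null(cut)) cut <- find_cut_site(locus, guide)
  cand <- .pam_block_candidates(locus, guide, cut, mode)
  if (!length(cand)) {
    stop("no admissible CRISPR/Cas-blocking substitution (PAM or seed); ",
         "redesign the guide", call. = FALSE)
  }
  pick <- cand[[1]]
  if (isTRUE(pick$fallback)) {
    warning("no silent PAM change available; using a protospacer-seed ",
            "blocking substitution instead", call. = FALSE)
  }
  pick
}

# Arm lengths on the left/right of the cut on the + strand. The 36-nt arm
# sits PAM-distal, the 91-nt arm PAM-proximal; the PAM side follows the
# guide strand.
.arm_spans <- function(cut, arms) {
  distal <- arms[1]; proximal <- arms[2]
  pam_right <- cut$pam_interval[1] >= cut$position
  if (pam_right) c(left = distal, right = proximal)
  else c(left = proximal, right = distal)
}

.check_arm_bounds <- function(locus, cut, spans) {
  if (cut$position - spans["left"] < 0 ||
      cut$position + spans["right"] > nchar(locus$sequence)) {
    stop("locus too short for the requested homology arms around the cut",
         call. = FALSE)
  }
}

# Build the knock-in allele: substituted genome with the (substituted)
# cassette inserted at the cut bond. `cassette` is in gene orientation.
.build_ki_allele <- function(locus, cut, cassette, subs) {
  seq <- .apply_genomic_subs(locus$sequence, subs)
  cassette <- .apply_cassette_subs(cassette, subs, locus$gene_strand)
  ins <- if (locus$gene_strand == "-" && nchar(cassette)) revcomp(cassette)
         else cassette
  p <- cut$position
  paste0(substr(seq, 1L, p), ins, substr(seq, p + 1L, nchar(seq)))
}

# Locus + strand coordinate corresponding to gene-orientation cassette
# spacer offset handling for tag mode: a + strand position q in the
# duplicated spacer region maps to a cassette offset.
.cassette_offset_for <- function(locus, cut, q) {
  if (locus$gene_strand == "+") q - cut$position else cut$position - 1L - q
}

.in_spacer_region <- function(locus, cut, q) {
  if (locus$gene_strand == "+") {
    q >= cut$position && q < locus$stop_codon_interval[1]
  } else {
    q < cut$position && q >= locus$stop_codon_interval[2]
  }
}

#' Design a tag-insertion ssODN
#'
#' Builds the repair template for in-frame insertion of an epitope tag just
#' before the stop codon: the insert cassette is `spacer + tag + stop`, where
#' the spacer duplicates the genomic sequence between the Cas9 cut bond and
#' the stop codon so that the reading frame runs from the native CDS through
#' the tag to a fresh stop. The original spacer and stop remain downstream of
#' the cassette and become non-coding. A CRISPR/Cas-blocking substitution is
#' always included and verified to abolish re-cutting of the knock-in allele.
#'
#' @param locus a [locus()].
#' @param guide a [guide()].
#' @param tag an [epitope_tag()] (or a tag name).
#' @param arms `c(distal, proximal)` homology-arm lengths in nt; the distal
#'   arm sits on the PAM-distal side of the cut, the proximal arm on the PAM
#'   side. Defaults to the asymmetric 36/91 design.
#' @param stop_codon stop codon appended after the tag.
#' @return Object of class `"ssodn_design"` (mode `"tag"`), including the
#'   oriented oligo (written against the non-target strand), the arm
#'   sequences, the substitution list, the predicted size shift and the full
#'   knock-in allele sequence.
#' @export
design_tag_ssodn <- function(locus, guide, tag, arms = c(36, 91),
                             stop_codon = "TGA") {
  stopifnot(inherits(locus, "locus"), inherits(guide, "guide"))
  if (is.character(tag)) tag <- epitope_tag(tag)
  stopifnot(inherits(tag, "epitope_tag"))
  stop_codon <- .check_dna(stop_codon, "stop_codon")
  if (nchar(stop_codon) != 3L || translate_dna(stop_codon) != "*") {
    stop("stop_codon must be a 3-nt stop codon", call. = FALSE)
  }
  arms <- as.integer(arms)
  cut <- find_cut_site(locus, guide)
  spacer <- compute_spacer(locus, cut)
  cassette <- paste0(spacer, tag$coding_nt, stop_codon)
  spans <- .arm_spans(cut, arms)
  .check_arm_bounds(locus, cut, spans)

  # Pick the first blocking substitution that actually abolishes re-cutting
  # of the rebuilt knock-in allele. Candidates whose position falls in the
  # duplicated spacer region are applied to the cassette copy (the copy that
  # reconstitutes the cleavable site across the arm/cassette junction).
  cands <- .pam_block_candidates(locus, guide, cut, "tag")
  if (!length(cands)) {
    stop("no admissible CRISPR/Cas-blocking substitution; redesign the guide",
         call. = FALSE)
  }
  chosen <- NULL
  allele <- NULL
  for (cand in cands) {
    if (.in_spacer_region(locus, cut, cand$position)) {
      cand$copy <- "cassette"
      cand$cassette_offset <- .cassette_offset_for(locus, cut, cand$position)
    }
    a <- .build_ki_allele(locus, cut, cassette, list(cand))
    if (!is_recut_possible(a, guide)) {
      chosen <- cand
      allele <- a
      break
    }
  }
  if (is.null(chosen)) {
    stop("no blocking substitution abolishes re-cutting of the knock-in ",
         "allele; redesign the guide", call. = FALSE)
  }
  if (isTRUE(chosen$fallback)) {
    warning("no silent PAM change available; using a protospacer-seed ",
            "blocking substitution instead", call. = FALSE)
  }
  subs <- list(chosen)

  # Frame-preservation contract: KI protein == WT protein + tag peptide.
  wt_aa <- translate_dna(cds_sequence(locus))
  wt_body <- substr(wt_aa, 1L, nchar(wt_aa) - 1L)
  ins_len <- nchar(cassette)
  ki_cds <- if (locus$gene_strand == "+") {
    substr(allele, locus$cds_interval[1] + 1L, cut$position + ins_len)
  } else {
    revcomp(substr(allele, cut$position + 1L, locus$cds_interval[2] + ins_len))
  }
  ki_aa <- translate_dna(ki_cds)
  if (ki_aa != paste0(wt_body, tag$peptide, "*")) {
    stop("internal error: knock-in translation does not equal WT protein ",
         "plus tag", call. = FALSE)
  }

  .finish_design(locus, guide, cut, mode = "tag", cassette = cassette,
                 subs = subs, spans = spans, arms = arms, allele = allele,
                 extra = list(tag = tag, spacer = spacer,
                              stop_codon = stop_codon,
                              wt_protein = wt_aa, ki_protein = ki_aa))
}

# Shared tail: arms, oriented oligo, bookkeeping.
.finish_design <- function(locus, guide, cut, mode, cassette, subs, spans,
                           arms, allele, extra = list(),
                           diagnostic = NULL) {
  seq_sub <- .apply_genomic_subs(locus$sequence, subs)
  cassette_sub <- .apply_cassette_subs(cassette, subs, locus$gene_strand)
  ins_plus <- if (locus$gene_strand == "-" && nchar(cassette_sub)) {
    revcomp(cassette_sub)
  } else cassette_sub
  p <- cut$position
  left <- substr(seq_sub, p - spans["left"] + 1L, p)
  right <- substr(seq_sub, p + 1L, p + spans["right"])
  window_plus <- paste0(left, ins_plus, right)
  oriented <- if (guide$strand == "+") revcomp(window_plus) else window_plus
  # Arm strings in oligo orientation, tagged distal (short) / proximal (long).
  if (guide$strand == "+") {
    first <- revcomp(right); last <- revcomp(left)
    first_len <- spans["right"]; last_len <- spans["left"]
  } else {
    first <- left; last <- right
    first_len <- spans["left"]; last_len <- spans["right"]
  }
  if (first_len == arms[1]) {
    distal_arm <- first; proximal_arm <- last
  } else {
    distal_arm <- last; proximal_arm <- first
  }
  structure(c(list(
    mode = mode, locus = locus, guide = guide, cut_site = cut,
    insert = cassette_sub,
    predicted_size_shift = nchar(cassette_sub),
    substitutions = subs,
    arm_lengths = c(distal = arms[1], proximal = arms[2]),
    arm_window = c(p - spans[["left"]], p + spans[["right"]]),
    distal_arm = distal_arm, proximal_arm = proximal_arm,
    oriented_sequence = oriented,
    ki_allele = allele,
    diagnostic = diagnostic), extra),
    class = "ssodn_design")
}

#' @export
print.ssodn_design <- function(x, ...) {
  cat("<ssodn_design> mode:", x$mode, " locus:", x$locus$name, "\n")
  cat("  cut bond at", x$cut_site$position, "; arms",
      x$arm_lengths[1], "/", x$arm_lengths[2], "nt (distal/proximal)\n")
  if (x$mode == "tag") {
    cat("  insert:", nchar(x$insert), "nt (spacer", nchar(x$spacer),
        "+ tag", nchar(x$tag$coding_nt), "+ stop 3); size shift +",
        x$predicted_size_shift, "bp\n")
  } else {
    cat("  substitution-only design (size shift 0)\n")
    if (!is.null(x$diagnostic)) {
      cat("  diagnostic enzyme:", x$diagnostic$enzyme$name, "site at",
          x$diagnostic$site_position, "\n")
    }
  }
  st <- substitution_table(x)
  cat("  substitutions:\n")
  for (i in seq_len(nrow(st))) {
    cat("   ", st$position[i], ":", st$from_base[i], ">", st$to_base[i],
        paste0("(", st$purpose[i],
               if (isTRUE(st$silent[i])) ", silent" else "", ")"), "\n")
  }
  cat("  oligo:", nchar(x$oriented_sequence), "nt\n")
  invisible(x)
}

# --- point-mutation designs -------------------------------------------------

.coerce_edit_list <- function(locus, edits, purpose) {
  if (is.null(edits)) return(list())
  if (is.data.frame(edits)) {
    edits <- lapply(seq_len(nrow(edits)), function(i) as.list(edits[i, ]))
  }
  lapply(edits, function(e) {
    pos <- as.integer(e$position)
    from <- .base_at(locus$sequence, pos)
    if (!is.null(e$from_base) && toupper(e$from_base) != from) {
      stop("edit at position ", pos, ": from_base does not match the locus",
           call. = FALSE)
    }
    to <- toupper(e$to_base)
    if (!to %in% DNA_BASES || to == from) {
      stop("edit at position ", pos, ": invalid to_base", call. = FALSE)
    }
    .substitution(pos, from, to, purpose,
                  silent = is_silent_substitution(locus, pos, to))
  })
}

# Sites (enzyme recognition occurrences, either strand) present in `ki` and
# absent at the same + strand position in `wt`, fully inside `window`.
.new_sites <- function(wt, ki, db, window) {
  res <- list()
  for (i in seq_len(nrow(db))) {
    site <- db$site[i]
    pats <- unique(c(site, revcomp(site)))
    for (pat in pats) {
      for (s in .find_all(ki, pat)) {
        if (s < window[1] || s + nchar(pat) > window[2]) next
        if (substr(wt, s + 1L, s + nchar(pat)) == pat) next
        res[[length(res) + 1L]] <- list(enzyme = db$name[i],
                                        site_position = s,
                                        pattern = pat)
      }
    }
  }
  res
}

.pick_site <- function(sites, cutpos) {
  if (!length(sites)) return(NULL)
  d <- vapply(sites, function(s) abs(s$site_position - cutpos), 0)
  nm <- vapply(sites, function(s) s$enzyme, "")
  sites[[order(d, nm)[1]]]
}

# Enumerate admissible single-base engineering substitutions in the window:
# any base at non-coding positions, synonymous-only inside the CDS.
.engineering_singles <- function(locus, window, taken) {
  out <- list()
  for (p in seq(window[1], window[2] - 1L)) {
    if (p %in% taken) next
    from <- .base_at(locus$sequence, p)
    for (to in setdiff(DNA_BASES, from)) {
      if (!is_silent_substitution(locus, p, to)) next
      out[[length(out) + 1L]] <-
        .substitution(p, from, to, "site_engineering", silent = TRUE)
    }
  }
  out
}

#' Design a point-mutation ssODN
#'
#' Substitution-only repair template (size shift 0). The substitution set is
#' the union of the desired edits, any cohort-SNP reversions, a silent
#' CRISPR/Cas-blocking substitution, and - only when none of those already
#' creates a knock-in-specific restriction site inside the homology-arm
#' window - additional silent site-engineering substitutions found by
#' exhaustive search (fewest substitutions first, then closest to the cut,
#' then alphabetical enzyme name). The resulting allele must differ from the
#' wild-type protein only at the intended residues, and the design records
#' the diagnostic enzyme for RFLP screening.
#'
#' @param locus a [locus()].
#' @param guide a [guide()].
#' @param desired_edits data frame (or list) with `position`, `to_base`
#'   (+ strand) and optional `from_base`.
#' @param snp_reversions same format; must be silent.
#' @param enzyme_db table from [restriction_enzymes()].
#' @param arms `c(distal, proximal)` homology-arm lengths.
#' @param max_cut_edit_dist warn when a desired edit lies farther than this
#'   many nt from the cut bond (long conversion tracts are increasingly
#'   likely to be resolved without the distal edit).
#' @return Object of class `"ssodn_design"` (mode `"point"`).
#' @export
design_point_ssodn <- function(locus, guide, desired_edits,
                               snp_reversions = NULL,
                               enzyme_db = restriction_enzymes(),
                               arms = c(36, 91), max_cut_edit_dist = 15) {
  stopifnot(inherits(locus, "locus"), inherits(guide, "guide"))
  arms <- as.integer(arms)
  cut <- find_cut_site(locus, guide)
  spans <- .arm_spans(cut, arms)
  .check_arm_bounds(locus, cut, spans)
  window <- c(cut$position - spans[["left"]], cut$position + spans[["right"]])

  desired <- .coerce_edit_list(locus, desired_edits, "desired_edit")
  if (!length(desired)) stop("at least one desired edit is required",
                             call. = FALSE)
  revs <- .coerce_edit_list(locus, snp_reversions, "snp_reversion")
  for (s in c(desired, revs)) {
    if (s$position < window[1] || s$position >= window[2]) {
      stop("edit at position ", s$position,
           " lies outside the homology-arm window [", window[1], ",",
           window[2], ")", call. = FALSE)
    }
  }
  for (s in revs) {
    if (!isTRUE(s$silent)) {
      stop("SNP reversion at position ", s$position, " is not silent; ",
           "only the desired edits may change the protein", call. = FALSE)
    }
  }
  for (s in desired) {
    d <- abs(s$position - cut$position)
    if (d > max_cut_edit_dist) {
      warning("desired edit at ", s$position, " lies ", d,
              " nt from the cut (> ", max_cut_edit_dist,
              " nt): integration may resolve without it", call. = FALSE)
    }
  }

  base_subs <- c(desired, revs)
  taken <- vapply(base_subs, function(s) s$position, 0L)

  pb_cands <- .pam_block_candidates(locus, guide, cut, "point")
  pb_cands <- Filter(function(s) !(s$position %in% taken), pb_cands)
  if (!length(pb_cands)) {
    stop("no admissible CRISPR/Cas-blocking substitution; redesign the guide",
         call. = FALSE)
  }
  pam_block <- NULL
  for (cand in pb_cands) {
    a <- .apply_genomic_subs(locus$sequence, c(base_subs, list(cand)))
    if (!is_recut_possible(a, guide)) { pam_block <- cand; break }
  }
  if (is.null(pam_block)) {
    stop("no blocking substitution abolishes re-cutting; redesign the guide",
         call. = FALSE)
  }
  if (isTRUE(pam_block$fallback)) {
    warning("no silent PAM change available; using a protospacer-seed ",
            "blocking substitution instead", call. = FALSE)
  }
  subs <- c(base_subs, list(pam_block))
  allele0 <- .apply_genomic_subs(locus$sequence, subs)

  # Diagnostic site: reuse one created by the existing substitutions if any;
  # otherwise engineer silently (1 then 2 extra substitutions).
  sites <- .new_sites(locus$sequence, allele0, enzyme_db, window)
  diag <- .pick_site(sites, cut$position)
  if (is.null(diag)) {
    taken2 <- vapply(subs, function(s) s$position, 0L)
    singles <- .engineering_singles(locus, window, taken2)
    if (length(singles)) {
      d1 <- vapply(singles, function(s) abs(s$position - cut$position), 0)
      p1 <- vapply(singles, function(s) s$position, 0L)
      b1 <- vapply(singles, function(s) s$to_base, "")
      singles <- singles[order(d1, p1, b1)]
    }
    found <- NULL
    for (s1 in singles) {
      a <- .apply_genomic_subs(allele0, list(s1))
      ns <- .new_sites(locus$sequence, a, enzyme_db, window)
      ns <- Filter(function(x) {
        s1$position >= x$site_position &&
          s1$position < x$site_position + nchar(x$pattern)
      }, ns)
      pick <- .pick_site(ns, cut$position)
      if (!is.null(pick)) { found <- list(subs = list(s1), site = pick); break }
    }
    if (is.null(found) && length(singles) > 1L) {
      n1 <- length(singles)
      for (i in seq_len(n1 - 1L)) {
        if (!is.null(found)) break
        for (j in seq((i + 1L), n1)) {
          si <- singles[[i]]; sj <- singles[[j]]
          if (si$position == sj$position) next
          if (abs(si$position - sj$position) > 8L) next
          a <- try(.apply_genomic_subs(allele0, list(si, sj)), silent = TRUE)
          if (inherits(a, "try-error")) next
          ns <- .new_sites(locus$sequence, a, enzyme_db, window)
          ns <- Filter(function(x) {
            hi <- x$site_position + nchar(x$pattern)
            (si$position >= x$site_position && si$position < hi) ||
              (sj$position >= x$site_position && sj$position < hi)
          }, ns)
          pick <- .pick_site(ns, cut$position)
          if (!is.null(pick)) {
            found <- list(subs = list(si, sj), site = pick)
            break
          }
        }
      }
    }
    if (is.null(found)) {
      stop("no knock-in-specific restriction site achievable with up to two ",
           "silent substitutions in the homology-arm window", call. = FALSE)
    }
    subs <- c(subs, found$subs)
    diag <- found$site
  }

  allele <- .apply_genomic_subs(locus$sequence, subs)
  if (is_recut_possible(allele, guide)) {
    stop("engineered substitutions re-created a cleavable site; redesign",
         call. = FALSE)
  }

  # Amino-acid-diff contract: only the desired edits may change the protein.
  wt_aa <- translate_dna(cds_sequence(locus))
  ki_loc <- locus; ki_loc$sequence <- allele
  ki_aa <- translate_dna(cds_sequence(ki_loc))
  diff_idx <- which(strsplit(wt_aa, "")[[1]] != strsplit(ki_aa, "")[[1]])
  want_idx <- sort(unique(stats::na.omit(vapply(desired, function(s) {
    info <- .codon_at(locus, s$position)
    if (is.null(info)) return(NA_integer_)
    if (isTRUE(s$silent)) return(NA_integer_)
    cs <- locus$cds_interval[1]; ce <- locus$cds_interval[2]
    off <- if (locus$gene_strand == "+") s$position - cs else (ce - 1L) - s$position
    as.integer(off %/% 3L + 1L)
  }, 0L))))
  if (!identical(sort(diff_idx), want_idx)) {
    stop("internal error: protein differences do not match the desired edits",
         call. = FALSE)
  }

  diag_full <- list(enzyme = enzyme(diag$enzyme, enzyme_db),
                    site_position = diag$site_position)
  .finish_design(locus, guide, cut, mode = "point", cassette = "",
                 subs = subs, spans = spans, arms = arms, allele = allele,
                 extra = list(wt_protein = wt_aa, ki_protein = ki_aa),
                 diagnostic = diag_full)
}

#' Final oligo orientation
#'
#' The ssODN is written against the non-target strand: the oligo is the
#' complement of the protospacer-bearing strand. For a + strand guide the
#' oligo is therefore reported on the - strand of the designed allele window,
#' and vice versa.
#'
#' @param design an `ssodn_design`.
#' @return The oriented oligo string (identical to
#'   `design$oriented_sequence`; recomputed from the orientation rule).
#' @export
orient_ssodn <- function(design) {
  stopifnot(inherits(design, "ssodn_design"))
  w <- design$arm_window
  ins_len <- nchar(design$insert)
  window_plus <- substr(design$ki_allele, w[1] + 1L, w[2] + ins_len)
  if (design$guide$strand == "+") revcomp(window_plus) else window_plus
}

# --- serialization ----------------------------------------------------------

.locus_as_list <- function(x) {
  list(name = x$name, sequence = x$sequence,
       cds_start = x$cds_interval[1], cds_end = x$cds_interval[2],
       gene_strand = x$gene_strand,
       cohort_snps = if (is.null(x$cohort_snps)) NULL else x$cohort_snps)
}

#' Write a design to JSON
#'
#' Serializes every field needed to reconstruct the design (locus, guide,
#' substitutions, oligo) so that [read_design()] round-trips the oligo
#' byte-for-byte.
#'
#' @param design an `ssodn_design`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_design <- function(design, path) {
  stopifnot(inherits(design, "ssodn_design"))
  out <- list(
    mode = design$mode,
    locus = .locus_as_list(design$locus),
    guide = design$guide[c("name", "protospacer", "pam", "strand")],
    cut_position = design$cut_site$position,
    insert = design$insert,
    predicted_size_shift = design$predicted_size_shift,
    substitutions = lapply(design$substitutions, function(s) {
      s <- s[c("position", "from_base", "to_base", "purpose", "silent",
               "copy", "cassette_offset", "fallback")]
      if (is.na(s$cassette_offset)) s$cassette_offset <- NULL
      s
    }),
    arm_lengths = as.list(design$arm_lengths),
    arm_window = design$arm_window,
    distal_arm = design$distal_arm,
    proximal_arm = design$proximal_arm,
    oriented_sequence = design$oriented_sequence,
    ki_allele = design$ki_allele,
    diagnostic = if (is.null(design$diagnostic)) NULL else list(
      enzyme = design$diagnostic$enzyme$name,
      site = design$diagnostic$enzyme$site,
      cut_top = design$diagnostic$enzyme$cut_top,
      cut_bottom = design$diagnostic$enzyme$cut_bottom,
      site_position = design$diagnostic$site_position),
    tag = if (is.null(design$tag)) NULL else
      design$tag[c("name", "peptide", "coding_nt")],
    spacer = design$spacer,
    stop_codon = design$stop_codon)
  jsonlite::write_json(out, path, auto_unbox = TRUE, null = "null",
                       digits = NA)
  invisible(path)
}

#' Read a design back from JSON
#'
#' @param path JSON written by [write_design()].
#' @return An `ssodn_design`.
#' @export
read_design <- function(path) {
  j <- jsonlite::read_json(path)
  snps <- j$locus$cohort_snps
  if (!is.null(snps)) {
    snps <- do.call(rbind, lapply(snps, function(r) {
      data.frame(position = r$position, ref_base = r$ref_base,
                 cohort_base = r$cohort_base, stringsAsFactors = FALSE)
    }))
  }
  loc <- locus(j$locus$name, j$locus$sequence, j$locus$cds_start,
               j$locus$cds_end, j$locus$gene_strand, cohort_snps = snps)
  g <- guide(j$guide$protospacer, j$guide$pam, j$guide$strand, j$guide$name)
  cut <- find_cut_site(loc, g)
  subs <- lapply(j$substitutions, function(s) {
    .substitution(s$position, s$from_base, s$to_base, s$purpose,
                  silent = s$silent, copy = s$copy,
                  cassette_offset = if (is.null(s$cassette_offset))
                    NA_integer_ else as.integer(s$cassette_offset),
                  fallback = isTRUE(s$fallback))
  })
  diag <- NULL
  if (!is.null(j$diagnostic)) {
    diag <- list(enzyme = list(name = j$diagnostic$enzyme,
                               site = j$diagnostic$site,
                               cut_top = j$diagnostic$cut_top,
                               cut_bottom = j$diagnostic$cut_bottom),
                 site_position = j$diagnostic$site_position)
  }
  extra <- list()
  if (!is.null(j$tag)) {
    extra$tag <- epitope_tag(j$tag$name, j$tag$peptide, j$tag$coding_nt)
  }
  if (!is.null(j$spacer)) extra$spacer <- j$spacer
  if (!is.null(j$stop_codon)) extra$stop_codon <- j$stop_codon
  spans <- c(left = cut$position - j$arm_window[[1]],
             right = j$arm_window[[2]] - cut$position)
  cassette <- if (identical(j$mode, "tag")) {
    # reconstruct the unsubstituted cassette, then .finish_design re-applies
    paste0(extra$spacer, extra$tag$coding_nt, extra$stop_codon)
  } else ""
  d <- .finish_design(loc, g, cut, mode = j$mode, cassette = cassette,
                      subs = subs,
                      spans = spans,
                      arms = c(j$arm_lengths$distal, j$arm_lengths$proximal),
                      allele = j$ki_allele, extra = extra, diagnostic = diag)
  if (!identical(d$oriented_sequence, j$oriented_sequence)) {
    stop("design JSON is inconsistent: reconstructed oligo differs",
         call. = FALSE)
  }
  d
}

#' Write the oriented oligo as synthesis-ready FASTA
#'
#' @param design an `ssodn_design`.
#' @param path output FASTA path.
#' @return `path`, invisibly.
#' @export
write_oligo_fasta <- function(design, path) {
  stopifnot(inherits(design, "ssodn_design"))
  set <- Biostrings::DNAStringSet(design$oriented_sequence)
  names(set) <- paste0(design$locus$name, "_ssODN_", design$mode)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Plain-text design report
#'
#' Human-readable alignment-style report: the genomic window around the cut,
#' the designed allele window, the oriented oligo and the substitution list.
#'
#' @param design an `ssodn_design`.
#' @param path optional output path; when `NULL` the lines are returned.
#' @return Character vector of report lines (invisibly when written).
#' @export
design_report <- function(design, path = NULL) {
  stopifnot(inherits(design, "ssodn_design"))
  w <- design$arm_window
  wt_win <- substr(design$locus$sequence, w[1] + 1L, w[2])
  ki_win <- substr(design$ki_allele, w[1] + 1L, w[2] + nchar(design$insert))
  st <- substitution_table(design)
  lines <- c(
    paste0("ssODN design report - ", design$locus$name, " (", design$mode,
           " mode)"),
    paste0("guide ", design$guide$name, ": ", design$guide$protospacer, "|",
           design$guide$pam, " on ", design$guide$strand, " strand"),
    paste0("cut bond at ", design$cut_site$position,
           " (0-based, + strand); homology arms ",
           design$arm_lengths[["distal"]], " nt distal / ",
           design$arm_lengths[["proximal"]], " nt proximal"),
    paste0("predicted size shift: +", design$predicted_size_shift, " bp"),
    "",
    paste0("genomic window  [", w[1], ",", w[2], "): ", wt_win),
    paste0("knock-in window           : ", ki_win),
    paste0("oriented oligo (", nchar(design$oriented_sequence), " nt): ",
           design$oriented_sequence),
    "",
    "substitutions (+ strand, 0-based):",
    vapply(seq_len(nrow(st)), function(i) {
      paste0("  ", st$position[i], " ", st$from_base[i], ">", st$to_base[i],
             "  ", st$purpose[i], if (isTRUE(st$silent[i])) " (silent)" else "")
    }, ""))
  if (!is.null(design$diagnostic)) {
    lines <- c(lines, "",
               paste0("diagnostic enzyme: ", design$diagnostic$enzyme$name,
                      " (", design$diagnostic$enzyme$site, "), new site at ",
                      design$diagnostic$site_position))
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
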