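# IMGT unique numbering for V-DOMAINs, feature extraction and
# functionality calls. The numbering is implemented as an anchored layout:
# framework regions have fixed IMGT position counts (FR1 positions 1-26,
# FR2 39-55, FR3 66-104) and the CDR loops absorb all length variation,
# with gaps placed at the top of each loop. The four anchors are 1st-CYS
# 23, CONSERVED-TRP 41, a hydrophobic residue (canonically Leu) at 89 and
# 2nd-CYS 104. Residues encoded beyond 104, up to the V recombination
# signal, form the germline contribution to CDR3 (positions 105 onwards).

IMGT_HYDRO89 <- c("L", "I", "V", "M", "F", "A")
CDR1_SLOTS <- c(27L, 38L)
CDR2_SLOTS <- c(56L, 65L)

# IMGT position labels for a loop of n residues numbered over slots
# p1..p2: the first ceiling(n/2) slots are filled from the start and the
# last floor(n/2) from the end, leaving the gap at the top of the loop.
# When n exceeds the slot count, extra positions are inserted at the top
# and labelled "<top>.1", "<top>.2", ...
loop_labels <- function(p1, p2, n) {
  m <- p2 - p1 + 1L
  if (n == 0L) return(character(0))
  if (n <= m) {
    k1 <- ceiling(n / 2)
    k2 <- n - k1
    c(as.character(seq(p1, length.out = k1)),
      if (k2 > 0L) as.character(seq(p2 - k2 + 1L, p2)) else character(0))
  } else {
    top <- p1 + ceiling(m / 2) - 1L
    c(as.character(p1:top),
      paste0(top, ".", seq_len(n - m)),
      as.character((top + 1L):p2))
  }
}

# Labels for the germline CDR3 contribution (positions 105..117, then
# inserted positions 117.1, 117.2, ... for unusually long extensions).
ext_labels <- function(n) {
  if (n == 0L) return(character(0))
  base <- as.character(seq(105L, length.out = min(n, 13L)))
  if (n > 13L) c(base, paste0("117.", seq_len(n - 13L))) else base
}

build_numbering <- function(aa, layout, a, b, c104) {
  L <- length(aa)
  deleted <- layout == "deleted"
  fr2_labels <- if (deleted) as.character(39:54) else as.character(39:55)
  fr3_labels <- if (deleted) as.character(71:104) else as.character(66:104)
  labels <- c(as.character(1:26),
              loop_labels(CDR1_SLOTS[1], CDR1_SLOTS[2], a),
              fr2_labels,
              if (deleted) character(0) else loop_labels(CDR2_SLOTS[1], CDR2_SLOTS[2], b),
              fr3_labels,
              ext_labels(L - c104))
  stopifnot(length(labels) == L)
  pm <- stats::setNames(aa, labels)
  anchors <- c(
    cys23 = unname(aa[23L] == "C"),
    trp41 = unname(aa[29L + a] == "W"),
    hydro89 = unname(aa[c104 - 15L] %in% IMGT_HYDRO89),
    cys104 = unname(aa[c104] == "C"))
  fr_spans <- list(FR1 = c(1L, 26L),
                   FR2 = if (deleted) c(39L, 54L) else c(39L, 55L),
                   FR3 = if (deleted) c(71L, 104L) else c(66L, 104L))
  cdr_spans <- list(CDR1 = CDR1_SLOTS, CDR2 = if (deleted) NULL else CDR2_SLOTS,
                    CDR3 = c(105L, 117L))
  structure(
    list(success = TRUE, layout = layout,
         position_map = pm, anchors = anchors,
         cdr_lengths = c(cdr1 = a, cdr2 = if (deleted) 0L else b,
                         cdr3 = L - c104),
         fr_spans = fr_spans, cdr_spans = cdr_spans,
         cdr2_deleted = deleted, c104_index = c104,
         aa_seq = paste(aa, collapse = "")),
    class = "v_numbering")
}

numbering_failure <- function(aa, reason, on_fail) {
  partial <- stats::setNames(aa[seq_len(min(length(aa), 26L))],
                             as.character(seq_len(min(length(aa), 26L))))
  obj <- structure(
    list(success = FALSE, reason = reason, position_map = partial,
         anchors = c(cys23 = isTRUE(aa[23L] == "C"), trp41 = FALSE,
                     hydro89 = FALSE, cys104 = FALSE),
         cdr_lengths = c(cdr1 = NA_integer_, cdr2 = NA_integer_,
                         cdr3 = NA_integer_),
         cdr2_deleted = FALSE, c104_index = NA_integer_,
         aa_seq = paste(aa, collapse = "")),
    class = "v_numbering")
  if (on_fail == "return") return(obj)
  cond <- structure(
    class = c("trd_numbering_failure", "error", "condition"),
    list(message = paste0("IMGT numbering failed: ", reason),
         call = sys.call(-1L), numbering = obj))
  stop(cond)
}

#' Map a V amino-acid sequence onto IMGT unique numbering
#'
#' Searches for the anchored layout (fixed framework lengths, variable CDR
#' loops) that places cysteines at positions 23 and 104, tryptophan at 41
#' and a hydrophobic residue at 89. When no standard layout fits, a layout
#' carrying the deletion that spans the last FR2 position through the
#' fifth FR3 position (positions 55-70, i.e. a missing CDR2) is tried, and
#' finally a relaxed layout that fixes only the two cysteines, so that the
#' loss of a non-cysteine anchor is reported through the anchor flags
#' rather than as a failure.
#'
#' Among competing standard layouts the one with the most C-terminal
#' 2nd-CYS is preferred (smallest germline CDR3 extension), then a CDR2 of
#' three residues, then the shortest CDR1.
#'
#' @param aa_seq Translated V-REGION (leader excluded), 70-130 residues,
#'   running from IMGT position 1 through 2nd-CYS 104 plus any germline
#'   residues encoded beyond 104 before the V recombination signal.
#' @param on_fail `"error"` to raise a numbering-failure condition (class
#'   `trd_numbering_failure`, carrying the best partial map), or
#'   `"return"` to return the failed object.
#' @param max_cdr1,max_cdr2 Upper bounds on loop lengths considered. No
#'   biological upper bound is enforced on CDR1 beyond `max_cdr1` (an
#'   18-residue CDR1 is admissible).
#' @return An object of class `v_numbering` with elements `success`,
#'   `position_map` (IMGT position label -> residue), `anchors` (named
#'   logical: `cys23`, `trp41`, `hydro89`, `cys104`), `cdr_lengths`
#'   (CDR1, CDR2 and germline CDR3 contribution), `fr_spans`, `cdr_spans`,
#'   `cdr2_deleted`, `c104_index`.
#' @export
number_v_domain <- function(aa_seq, on_fail = c("error", "return"),
                            max_cdr1 = 30L, max_cdr2 = 10L) {
  on_fail <- match.arg(on_fail)
  aa <- strsplit(toupper(aa_seq), "")[[1L]]
  L <- length(aa)
  if (L < 70L || L > 130L) {
    stop("V-REGION length ", L, " outside the supported 70-130 residues")
  }
  if (aa[23L] != "C") {
    return(numbering_failure(aa, "no cysteine at position 23", on_fail))
  }

  # Standard layout: FR1 26 + CDR1 a + FR2 17 + CDR2 b + FR3 39; the
  # 2nd-CYS index is then 82 + a + b and position 89 is always 15 residues
  # before it.
  cands <- list()
  for (a in 0:min(max_cdr1, L - 82L)) {
    if (29L + a > L || aa[29L + a] != "W") next
    for (b in 0:min(max_cdr2, L - 82L - a)) {
      c104 <- 82L + a + b
      if (aa[c104] == "C" && aa[c104 - 15L] %in% IMGT_HYDRO89) {
        cands[[length(cands) + 1L]] <- c(a = a, b = b, c104 = c104)
      }
    }
  }
  if (length(cands)) {
    ord <- order(vapply(cands, function(x) -x["c104"], 0),
                 vapply(cands, function(x) abs(x["b"] - 3L), 0),
                 vapply(cands, function(x) x["a"], 0))
    pick <- cands[[ord[1L]]]
    return(build_numbering(aa, "standard", pick[["a"]], pick[["b"]],
                           pick[["c104"]]))
  }

  # CDR2-deleted layout: the deletion removes IMGT 55-70, leaving FR2 with
  # 16 positions (39-54) and FR3 with 34 (71-104).
  dels <- list()
  for (a in 0:min(max_cdr1, L - 76L)) {
    if (29L + a > L || aa[29L + a] != "W") next
    c104 <- 76L + a
    if (aa[c104] == "C" && aa[c104 - 15L] %in% IMGT_HYDRO89) {
      dels[[length(dels) + 1L]] <- c(a = a, c104 = c104)
    }
  }
  if (length(dels)) {
    ord <- order(vapply(dels, function(x) -x["c104"], 0),
                 vapply(dels, function(x) x["a"], 0))
    pick <- dels[[ord[1L]]]
    return(build_numbering(aa, "deleted", pick[["a"]], 0L, pick[["c104"]]))
  }

  # Relaxed layout: anchor only the cysteine pair so that templates with a
  # mutated 41 or 89 still obtain CDR lengths; the anchor flags record the
  # loss. CDR2 is assumed to be 3 residues when the loop budget allows.
  cys <- which(aa == "C")
  cys <- cys[cys >= 82L & cys <= L & (L - cys) <= 25L]
  if (length(cys)) {
    c104 <- max(cys)
    ab <- c104 - 82L
    b <- min(3L, ab)
    a <- ab - b
    return(build_numbering(aa, "standard", a, b, c104))
  }
  numbering_failure(aa, "no cysteine in the admissible 2nd-CYS window",
                    on_fail)
}

#' Extract classification features from a numbered V domain
#'
#' @param numbering A successful `v_numbering`.
#' @param leader_aa Leader length in amino acids, when known (`NA`
#'   otherwise); reported as `leader_length`.
#' @return A list of class `v_features`: `cdr1_length`, `residue_57`
#'   (`NA` when the CDR2 is missing), `trp_107` (`"present"`, `"absent"`
#'   or `"not-applicable"` when fewer than three germline residues extend
#'   beyond 104), `qxs_motif` (CDR2 contains Q-x-S), `yfc_motif` (FR3 ends
#'   Y-F-C at 102-104), `leader_length`, `cdr2_deleted`,
#'   `post104_extension`.
#' @export
extract_features <- function(numbering, leader_aa = NA_integer_) {
  stopifnot(inherits(numbering, "v_numbering"), isTRUE(numbering$success))
  pm <- numbering$position_map
  labs <- names(pm)
  ext <- numbering$cdr_lengths[["cdr3"]]
  cdr2_res <- if (numbering$cdr2_deleted) character(0) else {
    idx <- which(vapply(labs, function(x) {
      v <- suppressWarnings(as.numeric(x))
      !is.na(v) && v >= CDR2_SLOTS[1] && v <= CDR2_SLOTS[2]
    }, TRUE))
    unname(pm[idx])
  }
  qxs <- FALSE
  if (length(cdr2_res) >= 3L) {
    for (i in seq_len(length(cdr2_res) - 2L)) {
      if (cdr2_res[i] == "Q" && cdr2_res[i + 2L] == "S") { qxs <- TRUE; break }
    }
  }
  res57 <- if (numbering$cdr2_deleted || !"57" %in% labs) NA_character_
           else unname(pm["57"])
  trp107 <- if (ext < 3L) "not-applicable"
            else if (identical(unname(pm["107"]), "W")) "present"
            else "absent"
  yfc <- identical(unname(pm["102"]), "Y") &&
         identical(unname(pm["103"]), "F") &&
         identical(unname(pm["104"]), "C")
  structure(
    list(cdr1_length = numbering$cdr_lengths[["cdr1"]],
         residue_57 = res57, trp_107 = trp107, qxs_motif = qxs,
         yfc_motif = yfc, leader_length = as.integer(leader_aa),
         cdr2_deleted = numbering$cdr2_deleted,
         post104_extension = as.integer(ext)),
    class = "v_features")
}

# Splice the coding sequence of a gene from its (coding-strand) genomic
# slice using the annotated exons. Exon coordinates are genomic; for "-"
# genes the gene sequence is already reverse-complemented, so genomic
# coordinates are mapped from the gene's 3' end.
splice_coding <- function(gene) {
  stopifnot(inherits(gene, "trd_gene"), !is.null(gene$sequence),
            !is.null(gene$exons))
  pieces <- character(nrow(gene$exons))
  for (k in seq_len(nrow(gene$exons))) {
    if (gene$orientation == "+") {
      ls <- gene$exons$start[k] - gene$start + 1L
      le <- gene$exons$end[k] - gene$start + 1L
    } else {
      ls <- gene$end - gene$exons$end[k] + 1L
      le <- gene$end - gene$exons$start[k] + 1L
    }
    if (ls < 1L || le > nchar(gene$sequence)) {
      stop("gene '", gene$name, "': exon outside the gene span")
    }
    pieces[k] <- substr(gene$sequence, ls, le)
  }
  paste(pieces, collapse = "")
}

#' Call gene functionality (functional / ORF / pseudogene)
#'
#' A gene is a pseudogene when its spliced coding region carries a
#' frameshift (length not a multiple of three) or a premature stop codon;
#' such genes are excluded from downstream analyses. A gene with an open
#' reading frame whose structure deviates from canonical V domains — a
#' missing CDR2, a germline extension beyond 2nd-CYS 104 longer than
#' `orf_extension_max` residues, loss of a non-cysteine anchor, or a
#' V domain that cannot be numbered at all — is labelled ORF. Everything
#' else is functional.
#'
#' @param gene A `trd_gene` with sequence and exon structure, or a
#'   character string holding the spliced coding nucleotide sequence.
#' @param numbering,features Optional precomputed results; computed from
#'   the coding sequence when omitted.
#' @param leader_aa Leader length in amino acids removed before numbering
#'   (20 for the canonical 49-bp L-PART1 plus 11-bp L-PART2).
#' @param orf_extension_max Largest post-104 extension still regarded as
#'   canonical (3-4 residues are typical; 12-15 are anomalous).
#' @return A list of class `functionality_call` with `label`
#'   (`"functional"`, `"ORF"` or `"pseudogene"`) and `reasons` (character
#'   vector of triggered rule ids).
#' @export
classify_functionality <- function(gene, numbering = NULL, features = NULL,
                                   leader_aa = 20L, orf_extension_max = 4L) {
  coding <- if (is.character(gene)) gene else splice_coding(gene)
  reasons <- character(0)
  if (nchar(coding) %% 3L != 0L) {
    return(structure(list(label = "pseudogene", reasons = "frameshift"),
                     class = "functionality_call"))
  }
  aa_full <- translate_dna(coding)
  if (grepl("\\*", aa_full)) {
    return(structure(list(label = "pseudogene", reasons = "premature_stop"),
                     class = "functionality_call"))
  }
  if (is.null(numbering)) {
    vreg <- substring(aa_full, leader_aa + 1L)
    numbering <- number_v_domain(vreg, on_fail = "return")
  }
  if (!isTRUE(numbering$success)) {
    return(structure(list(label = "ORF", reasons = "numbering_failure"),
                     class = "functionality_call"))
  }
  if (is.null(features)) features <- extract_features(numbering, leader_aa)
  if (features$cdr2_deleted) reasons <- c(reasons, "cdr2_deleted")
  if (features$post104_extension > orf_extension_max) {
    reasons <- c(reasons, "post104_extension")
  }
  if (!numbering$anchors[["trp41"]] || !numbering$anchors[["hydro89"]]) {
    reasons <- c(reasons, "anchor_loss")
  }
  label <- if (length(reasons)) "ORF" else "functional"
  structure(list(label = label, reasons = reasons),
            class = "functionality_call")
}
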