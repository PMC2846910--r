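# Recombination signal sequence (RSS) detection and scoring. An RSS is a
# conserved heptamer and nonamer separated by a 12-bp spacer (5' of D and J
# genes) or a 23-bp spacer (3' of V and D genes). All matching is performed
# on the coding strand reading away from the coding end, so a single
# consensus (CACAGTG ... ACAAAAACC) serves both orientations; the genomic
# "3' GTG" appearance of 5'D/J signals is handled by strand normalization.

#' RSS consensus model
#'
#' @return A list with the heptamer and nonamer consensus (read away from
#'   the coding end), the mandatory `CAC` heptamer prefix, the two spacer
#'   classes and the default spacer tolerance.
#' @export
rss_consensus <- function() {
  list(heptamer = "CACAGTG", nonamer = "ACAAAAACC",
       mandatory_prefix = "CAC", spacer_classes = c(12L, 23L),
       spacer_tolerance = 1L)
}

#' Score a candidate RSS window
#'
#' The window must consist of heptamer + spacer + nonamer read away from
#' the coding end. A match is accepted when the first three heptamer
#' positions are exactly `CAC`, at most `max_heptamer_mm` of the remaining
#' four heptamer positions mismatch, and at most `max_nonamer_mm` nonamer
#' positions mismatch. The spacer length is inferred from the window length
#' and must lie within `spacer_tolerance` of the spacer class.
#'
#' @param window Nucleotide string of length `7 + spacer + 9`.
#' @param spacer_class 12 or 23.
#' @param max_heptamer_mm Maximum mismatches in heptamer positions 4-7.
#' @param max_nonamer_mm Maximum mismatches in the nonamer.
#' @param spacer_tolerance Allowed deviation from the spacer class, in bp.
#' @return A list of class `rss_match` (fields `spacer_class`,
#'   `observed_spacer_len`, `heptamer_seq`, `nonamer_seq`,
#'   `heptamer_mismatches`, `nonamer_mismatches`), or `NULL` when the
#'   window is rejected.
#' @export
score_rss_window <- function(window, spacer_class,
                             max_heptamer_mm = 2L, max_nonamer_mm = 3L,
                             spacer_tolerance = 1L) {
  stopifnot(spacer_class %in% c(12L, 23L))
  window <- toupper(window)
  spacer <- nchar(window) - 16L
  if (abs(spacer - spacer_class) > spacer_tolerance) {
    stop(sprintf("window of impossible length %d for spacer class %d",
                 nchar(window), spacer_class))
  }
  cons <- rss_consensus()
  hept <- substr(window, 1L, 7L)
  nona <- substr(window, 8L + spacer, nchar(window))
  if (substr(hept, 1L, 3L) != cons$mandatory_prefix) return(invisible(NULL))
  h_mm <- hamming(substr(hept, 4L, 7L), substr(cons$heptamer, 4L, 7L))
  n_mm <- hamming(nona, cons$nonamer)
  if (h_mm > max_heptamer_mm || n_mm > max_nonamer_mm) return(invisible(NULL))
  structure(
    list(spacer_class = as.integer(spacer_class),
         observed_spacer_len = as.integer(spacer),
         heptamer_seq = hept, nonamer_seq = nona,
         heptamer_mismatches = as.integer(h_mm),
         nonamer_mismatches = as.integer(n_mm)),
    class = "rss_match")
}

#' Scan a sequence for RSS matches
#'
#' Slides a heptamer + spacer + nonamer window over every position of the
#' coding-strand sequence, for every spacer length within tolerance of the
#' spacer class, and reports all accepted matches. When several spacer
#' lengths are accepted at the same heptamer position, the one with the
#' fewest total mismatches (ties: spacer length closest to the class) is
#' kept.
#'
#' @inheritParams score_rss_window
#' @param sequence Nucleotide string.
#' @return A data frame with one row per accepted heptamer position:
#'   `position` (1-based heptamer start), `spacer_class`,
#'   `observed_spacer_len`, `heptamer_seq`, `nonamer_seq`,
#'   `heptamer_mismatches`, `nonamer_mismatches`, `total_mismatches`.
#' @export
scan_rss <- function(sequence, spacer_class,
                     max_heptamer_mm = 2L, max_nonamer_mm = 3L,
                     spacer_tolerance = 1L) {
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  spacers <- (spacer_class - spacer_tolerance):(spacer_class + spacer_tolerance)
  rows <- list()
  for (pos in seq_len(max(0L, L - (16L + min(spacers)) + 1L))) {
    best <- NULL
    for (sp in spacers) {
      wlen <- 16L + sp
      if (pos + wlen - 1L > L) next
      m <- score_rss_window(substr(sequence, pos, pos + wlen - 1L),
                            spacer_class, max_heptamer_mm, max_nonamer_mm,
                            spacer_tolerance)
      if (is.null(m)) next
      tot <- m$heptamer_mismatches + m$nonamer_mismatches
      if (is.null(best) || tot < best$tot ||
          (tot == best$tot &&
           abs(sp - spacer_class) < abs(best$sp - spacer_class))) {
        best <- list(m = m, tot = tot, sp = sp)
      }
    }
    if (!is.null(best)) {
      m <- best$m
      rows[[length(rows) + 1L]] <- data.frame(
        position = pos, spacer_class = m$spacer_class,
        observed_spacer_len = m$observed_spacer_len,
        heptamer_seq = m$heptamer_seq, nonamer_seq = m$nonamer_seq,
        heptamer_mismatches = m$heptamer_mismatches,
        nonamer_mismatches = m$nonamer_mismatches,
        total_mismatches = best$tot, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(position = integer(), spacer_class = integer(),
                      observed_spacer_len = integer(),
                      heptamer_seq = character(), nonamer_seq = character(),
                      heptamer_mismatches = integer(),
                      nonamer_mismatches = integer(),
                      total_mismatches = integer(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# Sides mandated by gene type: V genes carry a 23-spacer RSS 3' of the
# coding region, D genes a 12-spacer RSS 5' and a 23-spacer RSS 3',
# J genes a 12-spacer RSS 5'.
rss_sides_for <- function(gene_type) {
  switch(gene_type,
         V = list(list(side = "3'V", at = "3'", spacer = 23L)),
         D = list(list(side = "5'D", at = "5'", spacer = 12L),
                  list(side = "3'D", at = "3'", spacer = 23L)),
         J = list(list(side = "5'J", at = "5'", spacer = 12L)),
         list())
}

#' Find the recombination signals flanking a gene
#'
#' Searches only the sides mandated by the gene type (V: 3' with 23-bp
#' spacer; D: 5' with 12-bp and 3' with 23-bp; J: 5' with 12-bp) and
#' requires the heptamer to abut the coding end. The flanking context is
#' normalized to the coding strand reading away from the coding end before
#' scoring, so one consensus serves both genomic orientations.
#'
#' @inheritParams score_rss_window
#' @param gene A `trd_gene` (or one-row gene-table slice) with coordinates
#'   and orientation on `context`.
#' @param context The scaffold sequence (character string) the gene
#'   coordinates refer to; must extend at least ~40 bp beyond the gene on
#'   each mandated side.
#' @return A data frame of accepted matches with columns `gene_name`,
#'   `side`, `spacer_class`, `observed_spacer_len`, `heptamer_seq`,
#'   `nonamer_seq`, `heptamer_mismatches`, `nonamer_mismatches`,
#'   `position` (genomic coordinate of the heptamer base abutting the
#'   coding end). A mandated side with no accepted match is absent from
#'   the result and raises a warning.
#' @export
find_flanking_rss <- function(gene, context,
                              max_heptamer_mm = 2L, max_nonamer_mm = 3L,
                              spacer_tolerance = 1L) {
  if (inherits(gene, "data.frame")) {
    stopifnot(nrow(gene) == 1L)
    gene <- trd_gene(name = gene$name, gene_type = gene$gene_type,
                     scaffold = gene$scaffold, start = gene$start,
                     end = gene$end, orientation = gene$orientation)
  }
  context <- toupper(as.character(context))
  L <- nchar(context)
  flank <- 16L + 23L + spacer_tolerance + 1L
  rows <- list()
  for (side in rss_sides_for(gene$gene_type)) {
    if (gene$orientation == "+") {
      if (side$at == "3'") {
        away <- substr(context, gene$end + 1L, min(L, gene$end + flank))
        gpos <- gene$end + 1L
      } else {
        away <- revcomp(substr(context, max(1L, gene$start - flank),
                               gene$start - 1L))
        gpos <- gene$start - 1L
      }
    } else {
      if (side$at == "3'") {
        away <- revcomp(substr(context, max(1L, gene$start - flank),
                               gene$start - 1L))
        gpos <- gene$start - 1L
      } else {
        away <- substr(context, gene$end + 1L, min(L, gene$end + flank))
        gpos <- gene$end + 1L
      }
    }
    best <- NULL
    for (sp in (side$spacer - spacer_tolerance):(side$spacer + spacer_tolerance)) {
      wlen <- 16L + sp
      if (nchar(away) < wlen) next
      m <- score_rss_window(substr(away, 1L, wlen), side$spacer,
                            max_heptamer_mm, max_nonamer_mm, spacer_tolerance)
      if (is.null(m)) next
      tot <- m$heptamer_mismatches + m$nonamer_mismatches
      if (is.null(best) || tot < best$tot ||
          (tot == best$tot &&
           abs(sp - side$spacer) < abs(best$sp - side$spacer))) {
        best <- list(m = m, tot = tot, sp = sp)
      }
    }
    if (is.null(best)) {
      warning(sprintf("no RS accepted on side %s of gene %s",
                      side$side, gene$name))
      next
    }
    m <- best$m
    rows[[length(rows) + 1L]] <- data.frame(
      gene_name = gene$name, side = side$side,
      spacer_class = m$spacer_class,
      observed_spacer_len = m$observed_spacer_len,
      heptamer_seq = m$heptamer_seq, nonamer_seq = m$nonamer_seq,
      heptamer_mismatches = m$heptamer_mismatches,
      nonamer_mismatches = m$nonamer_mismatches,
      position = gpos, stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    return(data.frame(gene_name = character(), side = character(),
                      spacer_class = integer(), observed_spacer_len = integer(),
                      heptamer_seq = character(), nonamer_seq = character(),
                      heptamer_mismatches = integer(),
                      nonamer_mismatches = integer(), position = integer(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

#' Per-position conservation of aligned sequences
#'
#' Computes symbol counts, frequencies and information content per
#' alignment column for equal-length DNA sequences, as used for sequence
#' logos. Information content is `2 - H` bits with Shannon entropy `H`
#' over a uniform background; no small-sample correction is applied.
#'
#' @param seqs Character vector of equal-length sequences over ACGT.
#' @return A list of class `conservation_matrix` with elements `alphabet`,
#'   `counts` (4 x L), `frequencies` (4 x L) and `information` (length-L
#'   vector of bits in `[0, 2]`).
#' @export
conservation_matrix <- function(seqs) {
  if (length(seqs) < 1L) stop("at least one sequence is required")
  seqs <- toupper(seqs)
  L <- nchar(seqs[1L])
  if (any(nchar(seqs) != L)) stop("sequences differ in length")
  m <- do.call(rbind, strsplit(seqs, ""))
  if (!all(m %in% c("A", "C", "G", "T"))) {
    stop("sequences must contain only A, C, G, T (no gaps)")
  }
  counts <- vapply(seq_len(L), function(j) {
    tabulate(factor(m[, j], levels = c("A", "C", "G", "T")), nbins = 4L)
  }, integer(4L))
  rownames(counts) <- c("A", "C", "G", "T")
  freqs <- counts / length(seqs)
  info <- vapply(seq_len(L), function(j) {
    p <- freqs[, j][freqs[, j] > 0]
    2 + sum(p * log2(p))
  }, 0)
  structure(list(alphabet = c("A", "C", "G", "T"), counts = counts,
                 frequencies = freqs, information = info),
            class = "conservation_matrix")
}
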