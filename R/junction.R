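# CDR3 junction analysis of rearranged transcripts: germline V assignment,
# CDR3 extraction between 2nd-CYS 104 and J-PHE 118 of the F/W-G-X-G
# motif, ordered multi-TRDD calling under the >= 6-nt evidence rule, and
# P/N-region annotation.

#' Junction-analysis configuration
#'
#' @param min_d_match Minimum contiguous nucleotides of a D gene required
#'   to claim usage of that gene (default 6).
#' @param max_v_mismatch Maximum nucleotide differences for a cDNA to be
#'   assigned to a germline V gene (default 6).
#' @param max_p_len Maximum P-nucleotide length per untrimmed end
#'   (default 2).
#' @param d_order D gene names in genomic order; calls must follow this
#'   order strictly.
#' @return A list of class `junction_config`.
#' @export
junction_config <- function(min_d_match = 6L, max_v_mismatch = 6L,
                            max_p_len = 2L,
                            d_order = paste0("TRDD", 1:5)) {
  stopifnot(min_d_match >= 1L, max_v_mismatch >= 0L, max_p_len >= 0L)
  structure(list(min_d_match = as.integer(min_d_match),
                 max_v_mismatch = as.integer(max_v_mismatch),
                 max_p_len = as.integer(max_p_len), d_order = d_order),
            class = "junction_config")
}

#' Assign a rearranged cDNA to its closest germline V gene
#'
#' Ungapped comparison of the cDNA 5' end against each germline V-REGION;
#' the best gene is reported with its mismatch count. More than
#' `max_v_mismatch` differences, or a tie between equally close genes,
#' leaves the cDNA unassigned (with diagnostics).
#'
#' @param cdna Nucleotide string covering the V-REGION through position
#'   104 (>= 150 nt).
#' @param v_regions Named character vector of germline V-REGION
#'   nucleotide sequences.
#' @param config A [junction_config()].
#' @param query Optional query name carried through to the result.
#' @return A list of class `v_assignment`: `query`, `gene` (`NA` when
#'   unassigned), `mismatches`, `ties`, `assigned`.
#' @export
assign_germline_v <- function(cdna, v_regions, config = junction_config(),
                              query = NA_character_) {
  if (nchar(cdna) < 150L) stop("cDNA shorter than 150 nt")
  stopifnot(length(v_regions) >= 1L, !is.null(names(v_regions)))
  mm <- vapply(v_regions, function(v) {
    n <- min(nchar(cdna), nchar(v))
    hamming(substr(cdna, 1L, n), substr(v, 1L, n))
  }, integer(1L))
  best <- min(mm)
  cand <- names(mm)[mm == best]
  assigned <- best <= config$max_v_mismatch && length(cand) == 1L
  structure(
    list(query = query,
         gene = if (assigned) cand else NA_character_,
         mismatches = as.integer(best),
         ties = if (length(cand) > 1L) cand else character(0),
         assigned = assigned),
    class = "v_assignment")
}

# Locate the F/W-G-X-G motif in a germline J sequence: returns the
# 1-based nt offset of the F codon and the reading frame, or NULL.
j_motif_offset <- function(jseq) {
  for (frame in 0:2) {
    aa <- translate_dna(substring(jseq, frame + 1L))
    m <- regexpr("[FW]G.G", aa)
    if (m > 0L) return(list(fpos = frame + 1L + 3L * (as.integer(m) - 1L),
                            frame = frame))
  }
  NULL
}

#' Extract the CDR3 of a rearranged transcript
#'
#' The CDR3 spans IMGT codons 105-117, i.e. the nucleotides between the
#' 2nd-CYS 104 codon (located by numbering the germline V translation)
#' and the J-PHE 118 codon of the F/W-G-X-G motif of the best
#' suffix-matching germline J gene.
#'
#' @param cdna Rearranged transcript starting at V-REGION position 1.
#' @param v_region Germline V-REGION nucleotide sequence of the assigned
#'   V gene (may include the germline extension beyond codon 104).
#' @param j_genes Named character vector of germline J gene sequences
#'   (5' end at the recombination signal, 3' end at the splice site).
#' @param query Optional transcript name carried through.
#' @param v_gene Optional V gene name carried through.
#' @return A list of class `junction`: `query`, `v_gene`, `j_gene`,
#'   `cdr3_nt`, `cdr3_aa_length`, `cdr3_start` (position within `cdna`),
#'   `j5_germline` (germline J nucleotides preceding the F codon),
#'   `segments` and `d_calls` unset until [call_trdd_usage()] /
#'   [annotate_np_regions()] run.
#' @export
extract_cdr3 <- function(cdna, v_region, j_genes, query = NA_character_,
                         v_gene = NA_character_) {
  stopifnot(length(j_genes) >= 1L, !is.null(names(j_genes)))
  num <- number_v_domain(translate_dna(v_region))
  cdr3_start <- 3L * num$c104_index + 1L
  if (cdr3_start > nchar(cdna)) stop("junction boundary not found: ",
                                     "transcript ends before codon 104")
  suf <- vapply(j_genes, function(j) common_suffix_len(cdna, j), integer(1L))
  jg <- names(suf)[which.max(suf)]
  j <- j_genes[[jg]]
  mot <- j_motif_offset(j)
  if (is.null(mot)) stop("junction boundary not found: germline J '", jg,
                         "' lacks an F/W-G-X-G motif")
  need <- nchar(j) - mot$fpos + 1L
  if (suf[jg] < need) stop("junction boundary not found: no F/W-G-X-G ",
                           "bearing J match in transcript")
  f_cdna <- nchar(cdna) - (nchar(j) - mot$fpos)
  if (f_cdna <= cdr3_start || (f_cdna - cdr3_start) %% 3L != 0L) {
    stop("junction boundary not found: J-PHE 118 out of frame with 2nd-CYS")
  }
  motif_aa <- translate_dna(substr(cdna, f_cdna,
                                   min(nchar(cdna), f_cdna + 11L)))
  if (!grepl("^[FW]G.G", motif_aa)) {
    stop("junction boundary not found: F/W-G-X-G motif absent at J-PHE 118")
  }
  cdr3 <- substr(cdna, cdr3_start, f_cdna - 1L)
  structure(
    list(query = query, v_gene = v_gene, j_gene = jg, cdr3_nt = cdr3,
         cdr3_aa_length = nchar(cdr3) %/% 3L, cdr3_start = cdr3_start,
         j5_germline = substr(j, 1L, mot$fpos - 1L),
         segments = NULL, d_calls = character(0)),
    class = "junction")
}

# All maximal exact matches between the junction and each D gene:
# rows (d index, cstart, cend, dstart, dend, len).
maximal_d_matches <- function(cdr3, d_seqs, min_len) {
  cs <- strsplit(cdr3, "")[[1L]]
  L <- length(cs)
  out <- list()
  for (di in seq_along(d_seqs)) {
    ds <- strsplit(d_seqs[[di]], "")[[1L]]
    M <- length(ds)
    for (i in seq_len(L)) {
      for (j in seq_len(M)) {
        if (cs[i] != ds[j]) next
        if (i > 1L && j > 1L && cs[i - 1L] == ds[j - 1L]) next  # not maximal
        k <- 0L
        while (i + k <= L && j + k <= M && cs[i + k] == ds[j + k]) k <- k + 1L
        if (k >= min_len) {
          out[[length(out) + 1L]] <- c(d = di, cstart = i, cend = i + k - 1L,
                                       dstart = j, dend = j + k - 1L, len = k)
        }
      }
    }
  }
  out
}

# Compare two candidate solutions: more matched nucleotides, then fewer
# segments, then leftmost segment starts, then lowest genomic D indices.
# Returns +1 when a is better, -1 when b is better, 0 when equivalent.
compare_d_solutions <- function(a, b) {
  if (a$total != b$total) return(sign(a$total - b$total))
  if (a$nsegs != b$nsegs) return(sign(b$nsegs - a$nsegs))
  sa <- a$starts; sb <- b$starts
  for (k in seq_len(min(length(sa), length(sb)))) {
    if (sa[k] != sb[k]) return(sign(sb[k] - sa[k]))
  }
  da <- a$ds; db <- b$ds
  for (k in seq_len(min(length(da), length(db)))) {
    if (da[k] != db[k]) return(sign(db[k] - da[k]))
  }
  0L
}

#' Call ordered TRDD usage within a CDR3
#'
#' Finds exact contiguous matches of at least `min_d_match` nucleotides
#' between the junction and the five germline D genes, and selects the
#' non-overlapping set of fragments whose genomic order is strictly
#' increasing (each D used at most once) that maximizes the total number
#' of matched nucleotides; ties prefer fewer segments, then the leftmost
#' arrangement, then the lowest genomic indices. Between one and five D
#' calls are possible; junctions without a qualifying fragment yield an
#' empty call list. Positions not covered by a D fragment are provisional
#' N nucleotides until [annotate_np_regions()] refines them.
#'
#' @param cdr3_nt CDR3 nucleotide string, or a `junction` from
#'   [extract_cdr3()].
#' @param d_genes Named character vector of the germline D gene sequences
#'   in genomic order.
#' @param config A [junction_config()].
#' @return A `junction` object with `d_calls` (ordered character vector),
#'   `segments` (data frame `kind`, `source`, `start`, `end`,
#'   `matched_len`, `ambiguous`) tiling the junction.
#' @export
call_trdd_usage <- function(cdr3_nt, d_genes, config = junction_config()) {
  jx <- NULL
  if (inherits(cdr3_nt, "junction")) {
    jx <- cdr3_nt
    cdr3_nt <- jx$cdr3_nt
  }
  stopifnot(!is.null(names(d_genes)))
  cdr3_nt <- toupper(cdr3_nt)
  L <- nchar(cdr3_nt)
  if (L == 0L) stop("empty CDR3")
  min_len <- config$min_d_match
  mm <- maximal_d_matches(cdr3_nt, d_genes, min_len)

  nd <- length(d_genes)
  empty_sol <- list(total = 0L, nsegs = 0L, starts = integer(0),
                    ds = integer(0), segs = list())
  # dp[[i]][[dmin]]: best solution using positions i..L with all D
  # indices >= dmin. i runs L+1 .. 1.
  dp <- vector("list", L + 2L)
  dp[[L + 1L]] <- rep(list(empty_sol), nd + 1L)
  # segments starting at each position, from sub-intervals of maximal runs
  starts_at <- vector("list", L)
  for (m in mm) {
    for (i in m[["cstart"]]:(m[["cend"]] - min_len + 1L)) {
      for (e in (i + min_len - 1L):m[["cend"]]) {
        key <- paste(m[["d"]], i, e, sep = ":")
        cur <- starts_at[[i]]
        if (!is.null(cur) && key %in% names(cur)) next
        seg <- list(d = m[["d"]], start = i, end = e,
                    dstart = m[["dstart"]] + (i - m[["cstart"]]),
                    dend = m[["dstart"]] + (e - m[["cstart"]]))
        cur[[key]] <- seg
        starts_at[[i]] <- cur
      }
    }
  }
  for (i in L:1L) {
    row <- vector("list", nd + 1L)
    for (dmin in seq_len(nd + 1L)) {
      best <- dp[[i + 1L]][[dmin]]   # skip position i
      for (seg in starts_at[[i]]) {
        if (seg$d < dmin) next
        nxt <- if (seg$end + 1L > L) dp[[L + 1L]][[min(seg$d + 1L, nd + 1L)]]
               else dp[[seg$end + 1L]][[min(seg$d + 1L, nd + 1L)]]
        cand <- list(total = seg$end - seg$start + 1L + nxt$total,
                     nsegs = 1L + nxt$nsegs,
                     starts = c(seg$start, nxt$starts),
                     ds = c(seg$d, nxt$ds),
                     segs = c(list(seg), nxt$segs))
        if (compare_d_solutions(cand, best) > 0L) best <- cand
      }
      row[[dmin]] <- best
    }
    dp[[i]] <- row
  }
  sol <- dp[[1L]][[1L]]

  d_names <- names(d_genes)
  segs <- sol$segs
  rows <- list()
  cursor <- 1L
  for (seg in segs) {
    if (seg$start > cursor) {
      rows[[length(rows) + 1L]] <- data.frame(
        kind = "N", source = NA_character_, start = cursor,
        end = seg$start - 1L, matched_len = 0L, ambiguous = FALSE,
        stringsAsFactors = FALSE)
    }
    frag <- substr(cdr3_nt, seg$start, seg$end)
    amb <- any(vapply(seq_along(d_genes)[-seg$d], function(k) {
      grepl(frag, d_genes[[k]], fixed = TRUE)
    }, TRUE))
    rows[[length(rows) + 1L]] <- data.frame(
      kind = "D", source = d_names[seg$d], start = seg$start, end = seg$end,
      matched_len = seg$end - seg$start + 1L, ambiguous = amb,
      d_start = seg$dstart, d_end = seg$dend, stringsAsFactors = FALSE)
    cursor <- seg$end + 1L
  }
  if (cursor <= L) {
    rows[[length(rows) + 1L]] <- data.frame(
      kind = "N", source = NA_character_, start = cursor, end = L,
      matched_len = 0L, ambiguous = FALSE, d_start = NA_integer_,
      d_end = NA_integer_, stringsAsFactors = FALSE)
  }
  if (length(rows)) {
    for (k in seq_along(rows)) {
      if (!"d_start" %in% names(rows[[k]])) {
        rows[[k]]$d_start <- NA_integer_
        rows[[k]]$d_end <- NA_integer_
      }
    }
  }
  segments <- if (length(rows)) do.call(rbind, rows) else
    data.frame(kind = character(), source = character(), start = integer(),
               end = integer(), matched_len = integer(),
               ambiguous = logical(), d_start = integer(),
               d_end = integer(), stringsAsFactors = FALSE)

  if (is.null(jx)) {
    jx <- structure(list(query = NA_character_, v_gene = NA_character_,
                         j_gene = NA_character_, cdr3_nt = cdr3_nt,
                         cdr3_aa_length = nchar(cdr3_nt) %/% 3L,
                         cdr3_start = NA_integer_, j5_germline = NULL,
                         segments = NULL, d_calls = character(0)),
                    class = "junction")
  }
  jx$d_calls <- d_names[sol$ds]
  jx$segments <- segments
  jx
}

# Assign a label to unclaimed positions; helper for annotate_np_regions.
mark_p <- function(lab, cdr3, at, dir, source_end, max_p) {
  # dir +1: P follows an untrimmed 3' end at position `at` (germline end
  # nucleotides `source_end`, 5'->3'); dir -1: P precedes an untrimmed 5'
  # end. P nucleotides are the reverse complement of the adjacent germline
  # terminal nucleotides.
  for (plen in rev(seq_len(max_p))) {
    if (nchar(source_end) < plen) next
    if (dir > 0L) {
      pos <- at:(at + plen - 1L)
      want <- revcomp(substr(source_end, nchar(source_end) - plen + 1L,
                             nchar(source_end)))
    } else {
      pos <- (at - plen):(at - 1L)
      want <- revcomp(substr(source_end, 1L, plen))
    }
    if (any(pos < 1L) || any(pos > nchar(cdr3))) next
    if (!all(lab[pos] == "N")) next
    if (substr(cdr3, pos[1L], pos[plen]) == want) {
      lab[pos] <- "P"
      break
    }
  }
  lab
}

#' Annotate P and N regions of a called junction
#'
#' V-3' and J-5' germline contributions are identified as the longest
#' junction prefix/suffix matching the germline V extension beyond codon
#' 104 and the germline J nucleotides before J-PHE 118. At every untrimmed
#' germline end (a fragment reaching the germline terminus), up to
#' `max_p_len` adjacent unassigned nucleotides equal to the reverse
#' complement of the terminal germline nucleotides are labelled P
#' (ambiguous P-versus-N calls resolve in favour of P); all remaining
#' unassigned nucleotides are N.
#'
#' @param junction A `junction` with `d_calls`/`segments` from
#'   [call_trdd_usage()].
#' @param d_genes Named character vector of germline D sequences.
#' @param v_post104 Germline V nucleotides beyond codon 104 up to the V
#'   recombination signal (`""` when none).
#' @param j5 Germline J nucleotides before the F codon; defaults to the
#'   `j5_germline` recorded by [extract_cdr3()].
#' @param config A [junction_config()].
#' @return The `junction` with refined `segments` (kinds `V3'`, `P`, `N`,
#'   `D`, `J5'`) that tile `cdr3_nt` exactly.
#' @export
annotate_np_regions <- function(junction, d_genes, v_post104 = "",
                                j5 = NULL, config = junction_config()) {
  stopifnot(inherits(junction, "junction"), !is.null(junction$segments))
  cdr3 <- junction$cdr3_nt
  L <- nchar(cdr3)
  if (is.null(j5)) j5 <- junction$j5_germline
  if (is.null(j5)) j5 <- ""
  segs <- junction$segments
  dsegs <- segs[segs$kind == "D", , drop = FALSE]

  lab <- rep("N", L)
  src <- rep(NA_character_, L)
  mlen <- rep(0L, L)
  for (k in seq_len(nrow(dsegs))) {
    lab[dsegs$start[k]:dsegs$end[k]] <- "D"
    src[dsegs$start[k]:dsegs$end[k]] <- dsegs$source[k]
  }

  # V 3' germline contribution: longest prefix match, confined to the gap
  # before the first D segment.
  cap_v <- if (nrow(dsegs)) dsegs$start[1L] - 1L else L
  vlen <- min(common_prefix_len(cdr3, v_post104), cap_v)
  if (vlen > 0L) lab[seq_len(vlen)] <- "V"
  # J 5' germline contribution, confined to the gap after the last D.
  cap_j <- if (nrow(dsegs)) L - dsegs$end[nrow(dsegs)] else L
  jlen <- min(common_suffix_len(cdr3, j5), cap_j)
  if (jlen > 0L) lab[(L - jlen + 1L):L] <- "J"

  # P nucleotides at untrimmed germline ends.
  if (vlen > 0L && vlen == nchar(v_post104)) {
    lab <- mark_p(lab, cdr3, vlen + 1L, +1L, v_post104, config$max_p_len)
  }
  for (k in seq_len(nrow(dsegs))) {
    dseq <- d_genes[[dsegs$source[k]]]
    dstart_untrimmed <- !is.na(dsegs$d_start[k]) && dsegs$d_start[k] == 1L
    dend_untrimmed <- !is.na(dsegs$d_end[k]) && dsegs$d_end[k] == nchar(dseq)
    if (dstart_untrimmed) {
      lab <- mark_p(lab, cdr3, dsegs$start[k], -1L, dseq, config$max_p_len)
    }
    if (dend_untrimmed) {
      lab <- mark_p(lab, cdr3, dsegs$end[k] + 1L, +1L, dseq, config$max_p_len)
    }
  }
  if (jlen > 0L && jlen == nchar(j5) && nchar(j5) > 0L) {
    lab <- mark_p(lab, cdr3, L - jlen + 1L, -1L, j5, config$max_p_len)
  }

  # collapse runs into segments
  rows <- list()
  i <- 1L
  while (i <= L) {
    j <- i
    while (j < L && lab[j + 1L] == lab[i] &&
           identical(src[j + 1L], src[i])) j <- j + 1L
    kind <- switch(lab[i], V = "V3'", J = "J5'", D = "D", P = "P", N = "N")
    rows[[length(rows) + 1L]] <- data.frame(
      kind = kind,
      source = if (lab[i] == "D") src[i] else
        if (lab[i] == "V") junction$v_gene else
        if (lab[i] == "J") junction$j_gene else NA_character_,
      start = i, end = j,
      matched_len = if (lab[i] %in% c("D", "V", "J")) j - i + 1L else 0L,
      ambiguous = FALSE, stringsAsFactors = FALSE)
    i <- j + 1L
  }
  segments <- do.call(rbind, rows)
  # carry the ambiguity flags of the D calls forward
  for (k in seq_len(nrow(dsegs))) {
    hit <- which(segments$kind == "D" & segments$start == dsegs$start[k])
    segments$ambiguous[hit] <- dsegs$ambiguous[k]
  }
  junction$segments <- segments
  junction
}

#' Compact segment string of a junction
#'
#' @param junction An annotated `junction`.
#' @return A string such as `"V3'|P|N|TRDD2|N|J5'"`.
#' @export
segment_string <- function(junction) {
  stopifnot(inherits(junction, "junction"), !is.null(junction$segments))
  s <- junction$segments
  paste(ifelse(s$kind == "D", s$source, s$kind), collapse = "|")
}

#' Summarize D gene usage by V subgroup
#'
#' Counts every D occurrence across junctions and reports, per V
#' subgroup, the percentage of all D occurrences contributed by each D
#' gene, rounded to one decimal (half-up by default; truncation is
#' offered because printed tables sometimes truncate).
#'
#' @param x Either a list of annotated `junction` objects each carrying a
#'   `subgroup` element, or a numeric matrix / data frame of counts with
#'   one row per subgroup (rownames) and one column per D gene.
#' @param d_names D gene names used for list input.
#' @param n_sequences Optional named vector of sequences evaluated per
#'   subgroup (derived from list input automatically).
#' @param rounding `"half-up"` (default) or `"truncate"`.
#' @return A data frame of class `d_usage_summary` with columns
#'   `subgroup`, `n_sequences`, `d_gene`, `count`, `percent`.
#' @export
summarize_d_usage <- function(x, d_names = paste0("TRDD", 1:5),
                              n_sequences = NULL,
                              rounding = c("half-up", "truncate")) {
  rounding <- match.arg(rounding)
  if (is.list(x) && !is.data.frame(x) && !is.matrix(x)) {
    if (length(x) == 0L) {
      return(structure(data.frame(subgroup = character(),
                                  n_sequences = integer(),
                                  d_gene = character(), count = integer(),
                                  percent = numeric(),
                                  stringsAsFactors = FALSE),
                       class = c("d_usage_summary", "data.frame")))
    }
    subs <- vapply(x, function(j) {
      s <- j$subgroup
      if (is.null(s)) NA_character_ else s
    }, "")
    usub <- sort(unique(subs))
    counts <- matrix(0L, length(usub), length(d_names),
                     dimnames = list(usub, d_names))
    nseq <- stats::setNames(integer(length(usub)), usub)
    for (k in seq_along(x)) {
      nseq[subs[k]] <- nseq[subs[k]] + 1L
      for (d in x[[k]]$d_calls) {
        counts[subs[k], d] <- counts[subs[k], d] + 1L
      }
    }
    x <- counts
    n_sequences <- nseq
  }
  m <- as.matrix(x)
  if (is.null(rownames(m))) rownames(m) <- paste0("group", seq_len(nrow(m)))
  rows <- list()
  for (i in seq_len(nrow(m))) {
    tot <- sum(m[i, ])
    pct <- if (tot > 0) 100 * m[i, ] / tot else rep(NA_real_, ncol(m))
    pct <- if (rounding == "half-up") round_half_up(pct, 1L)
           else floor(pct * 10 + 1e-9) / 10
    rows[[i]] <- data.frame(
      subgroup = rownames(m)[i],
      n_sequences = if (!is.null(n_sequences) &&
                        rownames(m)[i] %in% names(n_sequences))
        n_sequences[[rownames(m)[i]]] else NA_integer_,
      d_gene = colnames(m), count = as.integer(m[i, ]), percent = pct,
      stringsAsFactors = FALSE, row.names = NULL)
  }
  structure(do.call(rbind, rows), class = c("d_usage_summary", "data.frame"))
}
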