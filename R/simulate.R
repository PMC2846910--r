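# Synthetic TRD locus and repertoire generator. Emits germline V, D, J
# and C genes with canonical recombination signals and the two-exon V /
# three-exon C structures, then simulates V-D-J rearranged transcripts
# with exonuclease trimming, N insertions and P nucleotides, carrying full
# recombination ground truth. Every stage of the analysis pipeline is
# testable against this truth channel without external sequence data.

AA_SAFE <- setdiff(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]], c("C", "W"))

codon_table <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

encode_aa <- function(aa_vec, codons = codon_table()) {
  paste(vapply(aa_vec, function(a) {
    cs <- codons[[a]]
    cs[sample.int(length(cs), 1L)]
  }, ""), collapse = "")
}

random_aa <- function(n) sample(AA_SAFE, n, replace = TRUE)

#' Configuration of a synthetic germline TRD locus
#'
#' Defaults mirror the structures of the real bovine locus: a 49-bp
#' L-PART1 (leader) exon and a V-EXON of 271-335 bp for TRDV1-like genes,
#' five D genes whose lengths (13, 15, 13, 9, 11 nt) are the real span
#' lengths implied by the annotated coordinates, three J genes, and a
#' single C gene with a 1282-bp coding region over three exons.
#'
#' @param n_v Number of V genes.
#' @param v_lpart1_len L-PART1 exon length in bp.
#' @param v_exon_len_range Admissible V-EXON length range (checked).
#' @param cdr1_range Range CDR1 lengths are drawn from (amino acids).
#' @param cdr2_len CDR2 length in amino acids.
#' @param post104_aa Germline residues encoded beyond 2nd-CYS 104.
#' @param intron_len_range V gene intron length range.
#' @param n_d,d_lens Number and lengths of D genes.
#' @param n_j Number of J genes.
#' @param c_exon_lens C exon lengths (coding; must total 1282 by default).
#' @param include_inverted_v Also place one V gene downstream of C in
#'   inverted transcriptional orientation.
#' @param intergenic_range Intergenic spacer length range.
#' @param seed Integer seed; the locus is deterministic per seed.
#' @return A list of class `locus_config`.
#' @export
locus_config <- function(n_v = 8L, v_lpart1_len = 49L,
                         v_exon_len_range = c(271L, 335L),
                         cdr1_range = c(5L, 10L), cdr2_len = 3L,
                         post104_aa = 4L, intron_len_range = c(80L, 160L),
                         n_d = 5L, d_lens = c(13L, 15L, 13L, 9L, 11L),
                         n_j = 3L, c_exon_lens = c(288L, 546L, 448L),
                         include_inverted_v = FALSE,
                         intergenic_range = c(150L, 300L), seed = 1L) {
  stopifnot(n_v >= 1L, n_d == length(d_lens), all(d_lens >= 8L),
            all(d_lens <= 20L), n_j >= 1L, all(c_exon_lens > 0L),
            v_lpart1_len > 0L, post104_aa >= 0L)
  structure(as.list(environment()), class = "locus_config")
}

# Random DNA that shares no k-mer with any of the given sequences.
random_dna_avoiding <- function(n, avoid_kmers, k = 6L, max_tries = 200L) {
  if (n <= 0L) return("")
  for (t in seq_len(max_tries)) {
    s <- random_dna(n)
    if (n < k || !any(kmers(s, k) %in% avoid_kmers)) return(s)
  }
  stop("could not sample sequence avoiding the forbidden k-mers; ",
       "relax the configuration")
}

build_v_template <- function(cdr1_len, cdr2_len, post104_aa, w107) {
  fr1 <- random_aa(26L); fr1[23L] <- "C"
  cdr1 <- random_aa(cdr1_len)
  fr2 <- random_aa(17L); fr2[3L] <- "W"
  cdr2 <- if (cdr2_len >= 3L) {
    c("Q", random_aa(cdr2_len - 2L), "S")
  } else random_aa(cdr2_len)
  fr3 <- random_aa(39L); fr3[24L] <- "L"
  fr3[37:39] <- c("Y", "F", "C")
  ext <- random_aa(post104_aa)
  if (w107 && post104_aa >= 3L) ext[3L] <- "W"
  list(v_region = c(fr1, cdr1, fr2, cdr2, fr3), ext = ext)
}

#' Generate a synthetic germline TRD locus
#'
#' Builds a single scaffold containing V genes (L-PART1 + intron + V-EXON
#' followed by a canonical 23-spacer RSS), D genes (12-spacer RSS 5',
#' 23-spacer RSS 3'), J genes (12-spacer RSS 5', F/W-G-X-G-bearing body)
#' and one three-exon C gene, with full ground truth. Optionally one V
#' gene is placed downstream of C in inverted orientation. D genes are
#' built with pairwise disjoint 6-mer sets, and the V germline extensions
#' and J bodies avoid D 6-mers, so junction evidence is unambiguous by
#' construction. Deterministic per seed.
#'
#' @param config A [locus_config()].
#' @return A list of class `trd_locus`: `scaffold` (named character
#'   vector of length 1), `genes` (a `trd_gene_table` with an `exons`
#'   list-column), `truth` (per-gene construction details: declared CDR
#'   lengths, V-REGION and extension nucleotides, D/J sequences, J motif
#'   offsets), `config`.
#' @export
generate_germline_locus <- function(config = locus_config()) {
  stopifnot(inherits(config, "locus_config"))
  set.seed(config$seed)
  codons <- codon_table()
  cons <- rss_consensus()
  rs23 <- function() paste0(cons$heptamer, random_dna(23L), cons$nonamer)
  rs12_upstream <- function() revcomp(paste0(cons$heptamer, random_dna(12L),
                                             cons$nonamer))

  # --- D genes: pairwise disjoint 6-mer sets
  d_names <- paste0("TRDD", seq_len(config$n_d))
  repeat {
    d_seqs <- vapply(config$d_lens, random_dna, "")
    all_k <- unlist(lapply(d_seqs, kmers, 6L))
    if (!anyDuplicated(all_k)) break
  }
  names(d_seqs) <- d_names
  d_kmers <- unlist(lapply(d_seqs, kmers, 6L))

  # --- J genes: 5' region, F-G-X-G motif, tail; no D 6-mers
  j_names <- paste0("TRDJ", seq_len(config$n_j))
  j_list <- list()
  for (jn in j_names) {
    repeat {
      j5_len <- sample(6:12, 1L)
      j5 <- random_dna_avoiding(j5_len, d_kmers)
      motif <- paste0(sample(c("TTT", "TTC"), 1L), "GG",
                      sample(c("A", "C", "G", "T"), 1L),
                      encode_aa(random_aa(1L), codons), "GG",
                      sample(c("A", "C", "G", "T"), 1L))
      tail <- encode_aa(random_aa(8L), codons)
      jseq <- paste0(j5, motif, tail)
      if (any(kmers(jseq, 6L) %in% d_kmers)) next
      mot <- j_motif_offset(jseq)
      if (!is.null(mot) && mot$fpos == j5_len + 1L) break
    }
    j_list[[jn]] <- list(seq = jseq, j5_len = j5_len, fpos = j5_len + 1L)
  }

  # --- V genes
  v_truth <- list()
  v_bodies <- list()
  n_v_total <- config$n_v + as.integer(config$include_inverted_v)
  for (i in seq_len(n_v_total)) {
    inverted <- config$include_inverted_v && i == n_v_total
    vname <- if (inverted) "TRDV4" else
      sprintf("TRDV1s%02d", i)
    repeat {
      cdr1_len <- sample(config$cdr1_range[1]:config$cdr1_range[2], 1L)
      w107 <- runif(1L) < 0.5
      tpl <- build_v_template(cdr1_len, config$cdr2_len,
                              config$post104_aa, w107)
      leader <- c("M", random_aa(19L))
      leader_nt <- encode_aa(leader, codons)
      v_region_nt <- encode_aa(tpl$v_region, codons)
      ext_nt <- encode_aa(tpl$ext, codons)
      if (nchar(ext_nt) >= 6L && any(kmers(ext_nt, 6L) %in% d_kmers)) next
      lpart2 <- substr(leader_nt, config$v_lpart1_len + 1L, 60L)
      v_exon <- paste0(lpart2, v_region_nt, ext_nt)
      if (nchar(v_exon) >= config$v_exon_len_range[1] &&
          nchar(v_exon) <= config$v_exon_len_range[2]) break
    }
    intron <- random_dna(sample(config$intron_len_range[1]:
                                config$intron_len_range[2], 1L))
    lpart1 <- substr(leader_nt, 1L, config$v_lpart1_len)
    body <- paste0(lpart1, intron, v_exon)
    v_bodies[[vname]] <- list(
      body = body, lpart1_len = config$v_lpart1_len,
      intron_len = nchar(intron), v_exon_len = nchar(v_exon),
      inverted = inverted)
    v_truth[[vname]] <- data.frame(
      name = vname, subgroup = if (inverted) "TRDV4" else "TRDV1",
      cdr1_len = cdr1_len, cdr2_len = config$cdr2_len,
      post104_len = config$post104_aa,
      res57 = if (config$cdr2_len >= 3L) tpl$v_region[26L + cdr1_len + 17L + 2L]
              else NA_character_,
      w107 = w107 && config$post104_aa >= 3L,
      v_region_nt = v_region_nt, post104_nt = ext_nt,
      leader_aa = 20L, stringsAsFactors = FALSE)
  }

  # --- assemble scaffold
  pieces <- character(0)
  pos <- 0L
  rows <- list()
  exons_col <- list()
  pad <- function() random_dna(sample(config$intergenic_range[1]:
                                      config$intergenic_range[2], 1L))
  push <- function(s) {
    pieces[[length(pieces) + 1L]] <<- s
    pos <<- pos + nchar(s)
  }
  add_gene <- function(name, gene_type, subgroup, start, end, orientation,
                       exons) {
    rows[[length(rows) + 1L]] <<- data.frame(
      name = name, gene_type = gene_type, subgroup = subgroup,
      scaffold = "locus1", start = start, end = end,
      orientation = orientation, group = "", functionality = "unset",
      members = name, stringsAsFactors = FALSE)
    exons_col <<- c(exons_col, list(exons))   # list(NULL) keeps the slot
  }

  for (vname in names(v_bodies)) {
    vb <- v_bodies[[vname]]
    if (vb$inverted) next
    push(pad())
    gstart <- pos + 1L
    push(vb$body)
    gend <- pos
    push(rs23())
    ex <- data.frame(
      label = c("L-PART1", "V-EXON"),
      start = c(gstart, gstart + vb$lpart1_len + vb$intron_len),
      end = c(gstart + vb$lpart1_len - 1L, gend), stringsAsFactors = FALSE)
    add_gene(vname, "V", v_truth[[vname]]$subgroup, gstart, gend, "+", ex)
  }
  for (dn in d_names) {
    push(pad())
    push(rs12_upstream())
    gstart <- pos + 1L
    push(d_seqs[[dn]])
    gend <- pos
    push(rs23())
    add_gene(dn, "D", "", gstart, gend, "+", NULL)
  }
  for (jn in j_names) {
    push(pad())
    push(rs12_upstream())
    gstart <- pos + 1L
    push(j_list[[jn]]$seq)
    gend <- pos
    add_gene(jn, "J", "", gstart, gend, "+", NULL)
  }
  # C gene: three exons separated by introns
  push(pad())
  gstart <- pos + 1L
  c_ex <- list()
  for (k in seq_along(config$c_exon_lens)) {
    if (k > 1L) push(random_dna(90L))
    es <- pos + 1L
    exon_aa <- random_aa(config$c_exon_lens[k] %/% 3L)
    exon_nt <- encode_aa(exon_aa, codons)
    exon_nt <- paste0(exon_nt, random_dna(config$c_exon_lens[k] %% 3L))
    push(exon_nt)
    c_ex[[k]] <- data.frame(label = paste0("EX", k), start = es, end = pos,
                            stringsAsFactors = FALSE)
  }
  gend <- pos
  add_gene("TRDC", "C", "", gstart, gend, "+", do.call(rbind, c_ex))

  # inverted V downstream of C
  if (config$include_inverted_v) {
    vb <- v_bodies[["TRDV4"]]
    push(pad())
    cassette <- revcomp(paste0(vb$body, rs23()))
    rs_len <- 16L + 23L
    cas_start <- pos + 1L
    push(cassette)
    gstart <- cas_start + rs_len
    gend <- pos
    # genomic coordinates of the exons on the minus strand
    loc <- list(lpart1 = c(1L, vb$lpart1_len),
                vexon = c(vb$lpart1_len + vb$intron_len + 1L,
                          nchar(vb$body)))
    g <- function(local) c(gend - local[2L] + 1L, gend - local[1L] + 1L)
    l1 <- g(loc$lpart1); vx <- g(loc$vexon)
    ex <- data.frame(label = c("L-PART1", "V-EXON"),
                     start = c(l1[1L], vx[1L]), end = c(l1[2L], vx[2L]),
                     stringsAsFactors = FALSE)
    add_gene("TRDV4", "V", "TRDV4", gstart, gend, "-", ex)
  }
  push(pad())

  scaffold <- paste(pieces, collapse = "")
  genes <- do.call(rbind, rows)
  genes$exons <- I(exons_col)
  genes <- new_gene_table(genes, source = "synthetic")

  structure(
    list(scaffold = c(locus1 = scaffold), genes = genes,
         truth = list(v = do.call(rbind, v_truth), d = d_seqs,
                      j = j_list),
         config = config),
    class = "trd_locus")
}

#' Configuration of a simulated rearranged repertoire
#'
#' @param n_transcripts Number of transcripts to emit.
#' @param d_count_weights Sampling weights for the number of D genes
#'   incorporated per junction (1 to 5).
#' @param trim_max Maximum exonuclease trim per germline end; trims are
#'   drawn from a truncated geometric distribution with mean 2.
#' @param n_mean Mean length of N regions (Poisson).
#' @param p_prob Probability of P-nucleotide addition at each untrimmed
#'   germline end (at most [junction_config()]`$max_p_len` nt, reverse
#'   complement of the terminal germline nucleotides).
#' @param clean Rejection-sample N regions so the assembled junction
#'   contains no 6-mer of any D gene outside the planted fragments, and
#'   cap trims so every planted fragment retains at least 6 nt — the
#'   caller-recovery benchmark conditions.
#' @param enforce_frame Pad the final N region so the junction length is
#'   a codon multiple (keeps J-PHE 118 in frame); skipped when
#'   `n_mean = 0`, where the junction must equal the exact concatenation
#'   of germline segments.
#' @param seed Integer seed. One sub-seed per transcript is derived from
#'   it, so extending a run does not perturb earlier transcripts.
#' @return A list of class `rearrangement_config`.
#' @export
rearrangement_config <- function(n_transcripts = 100L,
                                 d_count_weights = rep(0.2, 5L),
                                 trim_max = 4L, n_mean = 4,
                                 p_prob = 0.5, clean = FALSE,
                                 enforce_frame = TRUE, seed = 1L) {
  stopifnot(n_transcripts >= 0L, length(d_count_weights) <= 5L,
            all(d_count_weights >= 0), sum(d_count_weights) > 0,
            trim_max >= 0L, n_mean >= 0, p_prob >= 0, p_prob <= 1)
  structure(as.list(environment()), class = "rearrangement_config")
}

rgeom_trunc <- function(n, mean = 2, max) {
  if (max <= 0L) return(rep(0L, n))
  pmin(stats::rgeom(n, prob = 1 / (mean + 1)), max)
}

# TRUE when every 6-mer of the junction lies fully inside a planted D
# fragment or matches no D gene.
junction_is_clean <- function(cdr3, d_intervals, d_kmer_set) {
  L <- nchar(cdr3)
  if (L < 6L) return(TRUE)
  for (i in seq_len(L - 5L)) {
    inside <- FALSE
    for (iv in d_intervals) {
      if (i >= iv[1L] && i + 5L <= iv[2L]) { inside <- TRUE; break }
    }
    if (inside) next
    if (substr(cdr3, i, i + 5L) %in% d_kmer_set) return(FALSE)
  }
  TRUE
}

#' Simulate rearranged TRD transcripts with ground truth
#'
#' Per transcript: a V, an ordered subset of D genes (size drawn from
#' `d_count_weights`) and a J are sampled; germline ends are trimmed; P
#' nucleotides are added at untrimmed ends with probability `p_prob`;
#' N regions are inserted between segments; and the full transcript
#' (V-REGION, CDR3, J) is emitted together with a
#' recombination-truth record.
#'
#' @param locus A `trd_locus` from [generate_germline_locus()].
#' @param config A [rearrangement_config()].
#' @return A list of class `trd_repertoire`: `transcripts` (named
#'   character vector), `truth` (data frame with per-transcript `v_name`,
#'   `j_name`, `d_names` (comma-joined, genomic order), `v_trim`,
#'   `j_trim`, `d_trim5`/`d_trim3` (comma-joined), `n_total`, `p_total`,
#'   `cdr3_nt`), `config`.
#' @export
simulate_rearrangements <- function(locus, config = rearrangement_config()) {
  stopifnot(inherits(locus, "trd_locus"),
            inherits(config, "rearrangement_config"))
  d_seqs <- locus$truth$d
  if (length(d_seqs) < length(config$d_count_weights)) {
    stop("d_count exceeds the number of available D genes")
  }
  v_truth <- locus$truth$v
  j_list <- locus$truth$j
  d_kmer_set <- unique(unlist(lapply(d_seqs, kmers, 6L)))

  set.seed(config$seed)
  n <- config$n_transcripts
  subseeds <- if (n > 0L) sample.int(.Machine$integer.max, n) else integer(0)

  transcripts <- character(n)
  truth_rows <- vector("list", n)
  for (t in seq_len(n)) {
    set.seed(subseeds[t])
    vi <- sample.int(nrow(v_truth), 1L)
    v <- v_truth[vi, ]
    k <- sample.int(length(config$d_count_weights), 1L,
                    prob = config$d_count_weights)
    dis <- sort(sample.int(length(d_seqs), k))
    ji <- sample.int(length(j_list), 1L)
    j <- j_list[[ji]]

    min_keep <- if (config$clean) 6L else 1L
    v_post <- v$post104_nt
    v_trim <- min(rgeom_trunc(1L, 2, config$trim_max), nchar(v_post))
    v3 <- substr(v_post, 1L, nchar(v_post) - v_trim)
    frags <- character(k); t5 <- integer(k); t3 <- integer(k)
    for (q in seq_len(k)) {
      dlen <- nchar(d_seqs[[dis[q]]])
      t5[q] <- min(rgeom_trunc(1L, 2, config$trim_max),
                   max(0L, dlen - min_keep))
      t3[q] <- min(rgeom_trunc(1L, 2, config$trim_max),
                   max(0L, dlen - min_keep - t5[q]))
      frags[q] <- substr(d_seqs[[dis[q]]], t5[q] + 1L, dlen - t3[q])
    }
    j_trim <- min(rgeom_trunc(1L, 2, config$trim_max), j$j5_len)
    j5 <- substr(j_list[[ji]]$seq, j_trim + 1L, j$fpos - 1L)

    p_v <- ""; p_j <- ""
    p5 <- character(k); p3 <- character(k); p5[] <- ""; p3[] <- ""
    if (config$p_prob > 0) {
      if (v_trim == 0L && nchar(v_post) > 0L && runif(1L) < config$p_prob) {
        plen <- sample(1:2, 1L)
        p_v <- revcomp(substr(v_post, nchar(v_post) - plen + 1L,
                              nchar(v_post)))
      }
      for (q in seq_len(k)) {
        dseq <- d_seqs[[dis[q]]]
        if (t5[q] == 0L && runif(1L) < config$p_prob) {
          plen <- sample(1:2, 1L)
          p5[q] <- revcomp(substr(dseq, 1L, plen))
        }
        if (t3[q] == 0L && runif(1L) < config$p_prob) {
          plen <- sample(1:2, 1L)
          p3[q] <- revcomp(substr(dseq, nchar(dseq) - plen + 1L,
                                  nchar(dseq)))
        }
      }
      if (j_trim == 0L && j$j5_len > 0L && runif(1L) < config$p_prob) {
        plen <- sample(1:2, 1L)
        p_j <- revcomp(substr(j_list[[ji]]$seq, 1L, plen))
      }
    }

    assemble <- function(n_lens, pad = 0L) {
      ns <- vapply(n_lens, random_dna, "")
      if (pad > 0L) ns[length(ns)] <- paste0(ns[length(ns)], random_dna(pad))
      mid <- character(0)
      for (q in seq_len(k)) {
        mid <- c(mid, ns[q], p5[q], frags[q], p3[q])
      }
      paste0(v3, p_v, paste(mid, collapse = ""), ns[k + 1L], p_j, j5)
    }
    attempt <- 0L
    repeat {
      attempt <- attempt + 1L
      n_lens <- stats::rpois(k + 1L, config$n_mean)
      cdr3 <- assemble(n_lens)
      if (config$enforce_frame && config$n_mean > 0) {
        pad <- (3L - nchar(cdr3) %% 3L) %% 3L
        if (pad > 0L) cdr3 <- assemble(n_lens, pad = pad)
      }
      if (!config$clean) break
      # locate planted fragments to validate cleanliness
      offs <- nchar(v3) + nchar(p_v)
      ivs <- list()
      pos0 <- offs
      for (q in seq_len(k)) {
        pos0 <- pos0 + n_lens[q] + nchar(p5[q])
        ivs[[q]] <- c(pos0 + 1L, pos0 + nchar(frags[q]))
        pos0 <- pos0 + nchar(frags[q]) + nchar(p3[q])
      }
      if (junction_is_clean(cdr3, ivs, d_kmer_set)) break
      if (attempt >= 200L) {
        stop("clean-benchmark rejection sampling failed after 200 ",
             "attempts; adjust the configuration")
      }
    }

    tx <- paste0(v$v_region_nt, cdr3,
                 substr(j_list[[ji]]$seq, j$fpos, nchar(j_list[[ji]]$seq)))
    name <- sprintf("tx%05d", t)
    transcripts[t] <- tx
    names(transcripts)[t] <- name
    truth_rows[[t]] <- data.frame(
      name = name, v_name = v$name, subgroup = v$subgroup,
      j_name = names(j_list)[ji],
      d_names = paste(names(d_seqs)[dis], collapse = ","),
      d_count = k, v_trim = v_trim, j_trim = j_trim,
      d_trim5 = paste(t5, collapse = ","),
      d_trim3 = paste(t3, collapse = ","),
      n_total = sum(n_lens) + (nchar(cdr3) -
        (nchar(v3) + nchar(p_v) + sum(nchar(frags)) + sum(nchar(p5)) +
         sum(nchar(p3)) + sum(n_lens) + nchar(p_j) + nchar(j5))),
      p_total = nchar(p_v) + nchar(p_j) + sum(nchar(p5)) + sum(nchar(p3)),
      cdr3_nt = cdr3, stringsAsFactors = FALSE)
  }
  truth <- if (n > 0L) do.call(rbind, truth_rows) else
    data.frame(name = character(), v_name = character(),
               subgroup = character(), j_name = character(),
               d_names = character(), d_count = integer(),
               v_trim = integer(), j_trim = integer(),
               d_trim5 = character(), d_trim3 = character(),
               n_total = integer(), p_total = integer(),
               cdr3_nt = character(), stringsAsFactors = FALSE)
  structure(list(transcripts = transcripts, truth = truth, config = config),
            class = "trd_repertoire")
}

#' Clean caller-recovery benchmark
#'
#' A labelled junction set under benchmark conditions: no P nucleotides,
#' every planted D fragment retains at least 6 nt after trimming, and N
#' regions are rejection-sampled so the junction contains no spurious D
#' 6-mer outside the planted fragments. Every junction's planted ordered
#' D list is therefore recoverable.
#'
#' @param locus A `trd_locus`.
#' @param n Number of junctions.
#' @param seed Integer seed.
#' @return A `trd_repertoire` (see [simulate_rearrangements()]).
#' @export
make_clean_benchmark <- function(locus, n, seed) {
  simulate_rearrangements(
    locus,
    rearrangement_config(n_transcripts = n, p_prob = 0, clean = TRUE,
                         trim_max = 3L, n_mean = 4, seed = seed))
}
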