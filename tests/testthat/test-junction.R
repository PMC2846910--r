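# Germline V assignment, CDR3 extraction, ordered multi-D calling against
# the exhaustive oracle, P/N annotation and usage summaries.

junction_fixtures <- function() {
  loc <- shared_locus()
  list(loc = loc,
       v_regions = setNames(loc$truth$v$v_region_nt, loc$truth$v$name),
       v_post = setNames(loc$truth$v$post104_nt, loc$truth$v$name),
       j_genes = vapply(loc$truth$j, `[[`, "", "seq"),
       d_genes = loc$truth$d)
}

test_that("cDNAs are assigned to the closest germline V under the 6-mismatch rule", {
  fx <- junction_fixtures()
  v1 <- names(fx$v_regions)[1L]
  cdna <- paste0(fx$v_regions[[v1]], random_dna_str(40))
  a0 <- assign_germline_v(cdna, fx$v_regions, query = "q0")
  expect_true(a0$assigned)
  expect_equal(a0$gene, v1)
  expect_equal(a0$mismatches, 0L)

  # 7 mismatches -> unassigned
  s <- strsplit(cdna, "")[[1L]]
  set.seed(8)
  idx <- sample(seq_len(nchar(fx$v_regions[[v1]]) - 10L), 7L)
  s[idx] <- vapply(s[idx], function(b) setdiff(c("A", "C", "G", "T"), b)[1L], "")
  a7 <- assign_germline_v(paste(s, collapse = ""), fx$v_regions)
  expect_false(a7$assigned)
  expect_gte(a7$mismatches, 7L)

  # forced tie -> unassigned with both candidates listed
  two <- c(g1 = "ACGTACGT", g2 = "ACGTACGA")
  two <- vapply(two, function(x) paste0(x, substr(fx$v_regions[[v1]], 9,
                                                  nchar(fx$v_regions[[v1]]))), "")
  q <- paste0("ACGTACGC", substr(fx$v_regions[[v1]], 9,
                                 nchar(fx$v_regions[[v1]])))
  at <- assign_germline_v(q, two)
  expect_false(at$assigned)
  expect_setequal(at$ties, c("g1", "g2"))

  expect_error(assign_germline_v(random_dna_str(100), fx$v_regions),
               "150")
})

test_that("CDR3 extraction reproduces the simulator truth", {
  fx <- junction_fixtures()
  rep <- simulate_rearrangements(
    fx$loc, rearrangement_config(n_transcripts = 25L, seed = 17L))
  for (i in seq_len(nrow(rep$truth))) {
    tr <- rep$truth[i, ]
    jx <- extract_cdr3(rep$transcripts[[tr$name]],
                       fx$v_regions[[tr$v_name]], fx$j_genes,
                       query = tr$name, v_gene = tr$v_name)
    expect_identical(jx$cdr3_nt, tr$cdr3_nt)
    expect_equal(jx$j_gene, tr$j_name)
    expect_equal(jx$cdr3_aa_length, nchar(tr$cdr3_nt) %/% 3L)
  }
})

test_that("a mutated J motif breaks the junction boundary", {
  fx <- junction_fixtures()
  rep <- simulate_rearrangements(
    fx$loc, rearrangement_config(n_transcripts = 1L, seed = 19L))
  tr <- rep$truth[1L, ]
  tx <- rep$transcripts[[1L]]
  j <- fx$j_genes[[tr$j_name]]
  fpos <- fx$loc$truth$j[[tr$j_name]]$fpos
  # mutate the final G codon of F-G-X-G (position fpos+9..11 in J) to A
  gpos <- nchar(tx) - (nchar(j) - (fpos + 9L))
  substr(tx, gpos, gpos + 2L) <- "GCA"
  expect_error(extract_cdr3(tx, fx$v_regions[[tr$v_name]], fx$j_genes),
               "junction boundary not found")
})

test_that("D calls follow the >=6-nt rule, genomic order and scoring", {
  fx <- junction_fixtures()
  d <- fx$d_genes
  cfg <- junction_config(d_order = names(d))
  set.seed(23)
  # full TRDD2 flanked by clean random N
  repeat {
    n1 <- random_dna_str(5); n2 <- random_dna_str(5)
    cdr3 <- paste0(n1, d[["TRDD2"]], n2)
    if (length(oracle_d_segments(cdr3, d)) ==
        length(oracle_d_segments(d[["TRDD2"]], d))) break
  }
  jx <- call_trdd_usage(cdr3, d, cfg)
  expect_equal(jx$d_calls, "TRDD2")

  # a 5-nt fragment is not enough
  frag5 <- substr(d[["TRDD1"]], 1, 5)
  repeat {
    cdr3b <- paste0(random_dna_str(6), frag5, random_dna_str(6))
    if (length(oracle_d_segments(cdr3b, d)) == 0L) break
  }
  expect_equal(call_trdd_usage(cdr3b, d, cfg)$d_calls, character(0))

  # 8-nt TRDD1 + 4-nt N + 7-nt TRDD4
  repeat {
    cdr3c <- paste0(substr(d[["TRDD1"]], 1, 8), random_dna_str(4),
                    substr(d[["TRDD4"]], 1, 7))
    segs <- oracle_d_segments(cdr3c, d)
    ds <- sort(unique(vapply(segs, `[`, 0, "d")))
    if (identical(ds, c(1, 4))) break
  }
  expect_equal(call_trdd_usage(cdr3c, d, cfg)$d_calls, c("TRDD1", "TRDD4"))

  # planted in anti-genomic order: never called as TRDD3 then TRDD1
  repeat {
    cdr3d <- paste0(substr(d[["TRDD3"]], 1, 9), random_dna_str(3),
                    substr(d[["TRDD1"]], 1, 8))
    segs <- oracle_d_segments(cdr3d, d)
    ds <- sort(unique(vapply(segs, `[`, 0, "d")))
    if (identical(ds, c(1, 3))) break
  }
  jd <- call_trdd_usage(cdr3d, d, cfg)
  expect_lte(length(jd$d_calls), 1L)
  or <- oracle_call_trdd(cdr3d, d)
  expect_equal(jd$d_calls, names(d)[or$ds])
})

test_that("the dynamic-programming caller equals the exhaustive oracle", {
  fx <- junction_fixtures()
  d <- fx$d_genes
  cfg <- junction_config(d_order = names(d))
  set.seed(29)
  for (case in 1:60) {
    L <- sample(15:60, 1L)
    cdr3 <- random_dna_str(L)
    # plant up to three random fragments at random positions
    for (p in seq_len(sample(0:3, 1L))) {
      di <- sample(5L, 1L)
      dl <- nchar(d[[di]])
      a <- sort(sample(dl, 2L))
      frag <- substr(d[[di]], a[1L], a[2L])
      pos <- sample(max(1L, L - nchar(frag) + 1L), 1L)
      substr(cdr3, pos, min(L, pos + nchar(frag) - 1L)) <- frag
    }
    got <- call_trdd_usage(cdr3, d, cfg)
    want <- oracle_call_trdd(cdr3, d)
    expect_identical(got$d_calls, names(d)[want$ds])
    dsegs <- got$segments[got$segments$kind == "D", , drop = FALSE]
    expect_identical(as.integer(dsegs$start), as.integer(want$starts))
    expect_identical(sum(dsegs$matched_len), as.integer(want$total))
  }
})

test_that("P nucleotides flank untrimmed ends and leftovers become N", {
  fx <- junction_fixtures()
  d <- fx$d_genes
  cfg <- junction_config(d_order = names(d))
  d2 <- d[["TRDD2"]]
  # untrimmed 5' end preceded by its 2-nt reverse-complement P
  p5 <- revcomp(substr(d2, 1, 2))
  set.seed(31)
  repeat {
    nn <- random_dna_str(4)
    cdr3 <- paste0(nn, p5, d2, "A")
    segs <- oracle_d_segments(cdr3, d)
    if (length(segs) == length(oracle_d_segments(d2, d))) break
  }
  jx <- annotate_np_regions(call_trdd_usage(cdr3, d, cfg), d,
                            v_post104 = "", j5 = "", config = cfg)
  s <- jx$segments
  pseg <- s[s$kind == "P", , drop = FALSE]
  expect_equal(nrow(pseg), 1L)
  expect_equal(pseg$end - pseg$start + 1L, 2L)
  expect_equal(substr(cdr3, pseg$start, pseg$end), p5)
  # tiling invariant
  expect_equal(paste(substring(cdr3, s$start, s$end), collapse = ""), cdr3)

  # trimmed 5' end: the same adjacent nucleotides stay N
  trimmed <- substr(d2, 2, nchar(d2))
  repeat {
    nn <- random_dna_str(4)
    cdr3t <- paste0(nn, p5, trimmed, "A")
    segs <- oracle_d_segments(cdr3t, d)
    ok <- all(vapply(segs, function(x) x[["d"]] == 2L, TRUE)) &&
      !grepl(substr(d2, 1, 6), cdr3t, fixed = TRUE)
    if (ok) break
  }
  jt <- annotate_np_regions(call_trdd_usage(cdr3t, d, cfg), d,
                            v_post104 = "", j5 = "", config = cfg)
  expect_equal(nrow(jt$segments[jt$segments$kind == "P", ]), 0L)

  # fully tiled junction: V3' + untrimmed D + J5' leaves no N and no P
  vp <- fx$v_post[[1L]]
  j5 <- substr(fx$j_genes[[1L]], 1, fx$loc$truth$j[[1L]]$j5_len)
  cdr3f <- paste0(vp, d2, j5)
  jf <- annotate_np_regions(call_trdd_usage(cdr3f, d, cfg), d,
                            v_post104 = vp, j5 = j5, config = cfg)
  expect_setequal(jf$segments$kind, c("V3'", "D", "J5'"))
  expect_equal(segment_string(jf), "V3'|TRDD2|J5'")
})

test_that("usage summaries reproduce printed-table arithmetic", {
  counts <- rbind(TRDV1 = c(33, 33, 18, 23, 29))
  colnames(counts) <- paste0("TRDD", 1:5)
  s <- summarize_d_usage(counts)
  expect_equal(s$percent, c(24.3, 24.3, 13.2, 16.9, 21.3))

  counts2 <- rbind(TRDV2 = c(6, 9, 7, 9, 6))
  colnames(counts2) <- paste0("TRDD", 1:5)
  expect_equal(summarize_d_usage(counts2)$percent,
               c(16.2, 24.3, 18.9, 24.3, 16.2))

  one <- list(structure(list(subgroup = "TRDV1", d_calls = "TRDD3"),
                        class = "junction"))
  s1 <- summarize_d_usage(one)
  expect_equal(s1$percent[s1$d_gene == "TRDD3"], 100)
  expect_equal(s1$n_sequences[1L], 1L)

  # per-subgroup percentages sum to 100 within rounding slack
  set.seed(37)
  for (i in 1:10) {
    cnt <- rbind(g = sample(0:40, 5L))
    if (sum(cnt) == 0) next
    colnames(cnt) <- paste0("TRDD", 1:5)
    expect_lt(abs(sum(summarize_d_usage(cnt)$percent) - 100), 0.3)
  }
  expect_equal(nrow(summarize_d_usage(list())), 0L)
})
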