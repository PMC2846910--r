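# IMGT numbering against construction oracles, feature extraction and
# functionality calls.

test_that("numbering recovers anchors and CDR lengths known by construction", {
  cases <- expand.grid(cdr1 = c(2L, 5L, 7L, 9L, 10L), ext = c(0L, 3L, 4L),
                       w107 = c(TRUE, FALSE))
  for (k in seq_len(nrow(cases))) {
    cs <- cases[k, ]
    aa <- template_v_aa(cdr1 = cs$cdr1, cdr2 = 3L, ext = cs$ext,
                        w107 = cs$w107, seed = 400L + k)
    num <- number_v_domain(aa)
    expect_true(num$success)
    expect_true(all(num$anchors))
    expect_equal(unname(num$cdr_lengths),
                 c(cs$cdr1, 3L, cs$ext))
    expect_equal(unname(num$position_map["23"]), "C")
    expect_equal(unname(num$position_map["104"]), "C")
    expect_equal(unname(num$position_map["41"]), "W")
    expect_equal(unname(num$position_map["89"]), "L")
  }
})

test_that("an 18-residue CDR1 is numbered with inserted positions", {
  aa <- template_v_aa(cdr1 = 18L, cdr2 = 0L, cdr2_deleted = TRUE,
                      ext = 4L, seed = 77L)
  num <- number_v_domain(aa)
  expect_true(num$success)
  expect_equal(unname(num$cdr_lengths[["cdr1"]]), 18L)
  expect_true(num$cdr2_deleted)
  expect_true("32.1" %in% names(num$position_map))
})

test_that("numbering fails with a diagnostic when no 2nd-CYS window exists", {
  aa <- template_v_aa(seed = 9L)
  aa <- gsub("C", "S", aa)   # removes both cysteines
  expect_error(number_v_domain(aa), class = "trd_numbering_failure")
  got <- tryCatch(number_v_domain(aa), trd_numbering_failure = function(e) e)
  expect_false(got$numbering$success)
  expect_type(got$numbering$position_map, "character")
  # mutate only 104: partial map via on_fail = "return"
  aa2 <- template_v_aa(ext = 0L, seed = 10L)
  substr(aa2, nchar(aa2), nchar(aa2)) <- "S"
  num2 <- number_v_domain(aa2, on_fail = "return")
  expect_false(num2$success)
})

test_that("numbering is idempotent on the gap-stripped sequence", {
  for (seed in 1:10) {
    aa <- template_v_aa(cdr1 = sample(5:10, 1L), ext = 4L, seed = seed)
    n1 <- number_v_domain(aa)
    n2 <- number_v_domain(n1$aa_seq)
    expect_identical(n1$position_map, n2$position_map)
    expect_identical(n1$cdr_lengths, n2$cdr_lengths)
  }
})

test_that("feature extraction reads the declared template properties", {
  aa <- template_v_aa(cdr1 = 7L, cdr2 = 3L, ext = 4L, res57 = "S",
                      w107 = FALSE, seed = 55L)
  f <- extract_features(number_v_domain(aa))
  expect_equal(f$cdr1_length, 7L)
  expect_equal(f$residue_57, "S")
  expect_true(f$qxs_motif)       # CDR2 built as Q, res57, S
  expect_true(f$yfc_motif)
  expect_equal(f$trp_107, "absent")
  expect_equal(f$post104_extension, 4L)
  expect_false(f$cdr2_deleted)

  aw <- template_v_aa(cdr1 = 9L, ext = 4L, w107 = TRUE, seed = 56L)
  expect_equal(extract_features(number_v_domain(aw))$trp_107, "present")

  a0 <- template_v_aa(cdr1 = 9L, ext = 0L, seed = 57L)
  expect_equal(extract_features(number_v_domain(a0))$trp_107,
               "not-applicable")
})

test_that("the FR2-last to FR3-fifth deletion is recognised as missing CDR2", {
  aa <- template_v_aa(cdr1 = 7L, cdr2_deleted = TRUE, ext = 4L, seed = 58L)
  num <- number_v_domain(aa)
  expect_true(num$success)
  expect_true(num$cdr2_deleted)
  f <- extract_features(num)
  expect_true(f$cdr2_deleted)
  expect_true(is.na(f$residue_57))
  expect_equal(unname(num$cdr_lengths[["cdr2"]]), 0L)
})

test_that("long post-104 extensions are measured", {
  aa <- template_v_aa(cdr1 = 9L, ext = 15L, seed = 59L)
  f <- extract_features(number_v_domain(aa))
  expect_equal(f$post104_extension, 15L)
})

test_that("functionality calls follow the stop/structure rules", {
  aa <- paste0("M", paste(rep("G", 19), collapse = ""),
               template_v_aa(cdr1 = 7L, ext = 4L, seed = 61L))
  nt <- aa_to_nt(aa)
  expect_equal(classify_functionality(nt)$label, "functional")

  # internal stop codon -> pseudogene
  nt_stop <- paste0(substr(nt, 1, 150), "TAA", substr(nt, 154, nchar(nt)))
  expect_equal(classify_functionality(nt_stop)$label, "pseudogene")
  # frameshift -> pseudogene
  nt_fs <- paste0(substr(nt, 1, 150), substr(nt, 152, nchar(nt)))
  expect_equal(classify_functionality(nt_fs)$label, "pseudogene")

  # CDR2 deletion with intact frame -> ORF
  aa_del <- paste0("M", paste(rep("G", 19), collapse = ""),
                   template_v_aa(cdr1 = 7L, cdr2_deleted = TRUE, ext = 4L,
                                 seed = 62L))
  call_del <- classify_functionality(aa_to_nt(aa_del))
  expect_equal(call_del$label, "ORF")
  expect_true("cdr2_deleted" %in% call_del$reasons)

  # 15-residue extension beyond 104 -> ORF
  aa_ext <- paste0("M", paste(rep("G", 19), collapse = ""),
                   template_v_aa(cdr1 = 9L, ext = 15L, seed = 63L))
  call_ext <- classify_functionality(aa_to_nt(aa_ext))
  expect_equal(call_ext$label, "ORF")
  expect_true("post104_extension" %in% call_ext$reasons)

  # loss of a non-cysteine anchor -> ORF
  aa_w <- template_v_aa(cdr1 = 7L, ext = 4L, seed = 64L)
  aa_w <- sub("W", "G", aa_w)
  call_w <- classify_functionality(
    aa_to_nt(paste0("M", paste(rep("G", 19), collapse = ""), aa_w)))
  expect_equal(call_w$label, "ORF")
  expect_true("anchor_loss" %in% call_w$reasons)
})

test_that("synonymous mutations never turn a functional gene into a pseudogene", {
  aa <- paste0("M", paste(rep("G", 19), collapse = ""),
               template_v_aa(cdr1 = 7L, ext = 4L, seed = 70L))
  gc <- Biostrings::GENETIC_CODE
  set.seed(71)
  for (rep_i in 1:20) {
    nt <- aa_to_nt(aa)
    codons <- substring(nt, seq(1, nchar(nt), 3), seq(3, nchar(nt), 3))
    # resample a random subset of codons synonymously
    for (pos in sample(seq_along(codons), 30L)) {
      alt <- names(gc)[gc == gc[[codons[pos]]]]
      codons[pos] <- sample(alt, 1L)
    }
    out <- classify_functionality(paste(codons, collapse = ""))
    expect_equal(out$label, "functional")
  }
})

test_that("every simulated germline V passes numbering with all anchors", {
  loc <- shared_locus()
  g <- loc$genes
  for (i in which(g$gene_type == "V")) {
    gene <- extract_gene_sequence(loc$scaffold, g[i, , drop = FALSE])
    gene$exons <- g$exons[[i]]
    coding <- trdrep:::splice_coding(gene)
    num <- number_v_domain(substring(translate_dna(coding), 21L))
    expect_true(num$success)
    expect_true(all(num$anchors))
    truth <- loc$truth$v[loc$truth$v$name == g$name[i], ]
    expect_equal(unname(num$cdr_lengths[["cdr1"]]), truth$cdr1_len)
  }
})
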