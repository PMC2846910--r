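# Deterministic construction of synthetic V amino-acid templates with
# declared CDR lengths and anchors; the expected numbering is known by
# construction. Random filler avoids C and W so the declared anchors are
# the only candidates.

aa_filler <- setdiff(strsplit("ADEFGHIKLMNPQRSTVY", "")[[1L]], character(0))

template_v_aa <- function(cdr1 = 7L, cdr2 = 3L, ext = 4L, res57 = "S",
                          w107 = FALSE, cdr2_deleted = FALSE, seed = 1L) {
  set.seed(seed)
  r <- function(n) sample(aa_filler, n, replace = TRUE)
  fr1 <- r(26L); fr1[23L] <- "C"
  cdr1aa <- r(cdr1)
  if (cdr2_deleted) {
    fr2 <- r(16L); fr2[3L] <- "W"        # last FR2 residue (55) deleted
    cdr2aa <- character(0)
    fr3 <- r(34L)                        # FR3 starts at 71
    fr3[89L - 71L + 1L] <- "L"
    fr3[(102:104) - 71L + 1L] <- c("Y", "F", "C")
  } else {
    fr2 <- r(17L); fr2[3L] <- "W"
    cdr2aa <- if (cdr2 >= 3L) c("Q", res57, rep("S", cdr2 - 2L)) else r(cdr2)
    fr3 <- r(39L); fr3[24L] <- "L"; fr3[37:39] <- c("Y", "F", "C")
  }
  extaa <- r(ext)
  if (w107 && ext >= 3L) extaa[3L] <- "W"
  paste(c(fr1, cdr1aa, fr2, cdr2aa, fr3, extaa), collapse = "")
}

# Reverse-translate an amino-acid string with fixed (first-listed) codons;
# deterministic, no stop codons for stop-free input.
aa_to_nt <- function(aa) {
  gc <- Biostrings::GENETIC_CODE
  first <- vapply(unique(gc), function(a) names(gc)[gc == a][1L], "")
  paste(first[strsplit(aa, "")[[1L]]], collapse = "")
}

random_dna_str <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# A small shared synthetic locus (built once per test run).
shared_locus <- function() {
  if (is.null(.trd_test_env$locus)) {
    .trd_test_env$locus <- generate_germline_locus(
      locus_config(n_v = 4L, seed = 101L))
  }
  .trd_test_env$locus
}
.trd_test_env <- new.env(parent = emptyenv())
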