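# Distance-based phylogeny: p-distances with complete deletion,
# neighbor-joining with deterministic tie-breaking, site-resampling branch
# support, and the TRDV1 set classifier (feature rules plus tree clades).
# Trees are represented as ape "phylo" objects.

as_char_alignment <- function(aln) {
  if (inherits(aln, "DNAStringSet") || inherits(aln, "AAStringSet")) {
    aln <- stats::setNames(as.character(aln), names(aln))
  }
  if (is.matrix(aln)) {
    if (is.null(rownames(aln))) rownames(aln) <- paste0("seq", seq_len(nrow(aln)))
    return(aln)
  }
  if (is.character(aln)) {
    if (is.null(names(aln))) names(aln) <- paste0("seq", seq_along(aln))
    if (length(unique(nchar(aln))) != 1L) {
      stop("alignment sequences differ in length")
    }
    m <- do.call(rbind, strsplit(toupper(aln), ""))
    rownames(m) <- names(aln)
    return(m)
  }
  stop("unsupported alignment representation")
}

#' p-distance matrix with complete deletion
#'
#' The p-distance between two aligned sequences is the proportion of
#' differing sites. With complete deletion, every alignment column
#' containing a gap (`-` or `.`) in any sequence is removed before
#' distances are computed.
#'
#' @param aln Named character vector of aligned sequences, a character
#'   matrix (rows = taxa), or a `DNAStringSet`.
#' @param complete_deletion Remove gapped columns first (default `TRUE`).
#' @return A list of class `p_dist`: `labels`, `d` (symmetric matrix with
#'   zero diagonal, entries in `[0, 1]`), `positions_used`.
#' @export
p_distance_matrix <- function(aln, complete_deletion = TRUE) {
  m <- as_char_alignment(aln)
  if (nrow(m) < 2L) stop("at least two sequences are required")
  if (complete_deletion) {
    gap <- m == "-" | m == "."
    keep <- colSums(gap) == 0L
    if (!any(keep)) stop("complete deletion removed all alignment columns")
    m <- m[, keep, drop = FALSE]
  }
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- mean(m[i, ] != m[j, ])
    }
  }
  structure(list(labels = rownames(m), d = d, positions_used = ncol(m)),
            class = "p_dist")
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining agglomeration with deterministic
#' tie-breaking: when several pairs minimize the Q criterion, the pair
#' whose (sorted) label pair is lexicographically smallest is joined, with
#' each internal node labelled by the smallest tip label it contains.
#' Negative branch lengths are retained unless `clamp_negative` is set.
#' The result is deterministic given the matrix.
#'
#' @param x A `p_dist` object or a symmetric numeric matrix with zero
#'   diagonal and dimnames.
#' @param clamp_negative Clamp negative branch lengths at 0.
#' @return An unrooted `phylo` tree (trifurcating root node).
#' @export
neighbor_joining <- function(x, clamp_negative = FALSE) {
  D <- if (inherits(x, "p_dist")) x$d else as.matrix(x)
  if (nrow(D) != ncol(D) || !isTRUE(all.equal(D, t(D), tolerance = 1e-8))) {
    stop("distance matrix must be symmetric")
  }
  if (is.null(rownames(D))) {
    rownames(D) <- colnames(D) <- paste0("t", seq_len(nrow(D)))
  }
  n0 <- nrow(D)
  if (n0 < 3L) stop("at least three taxa are required")

  labs <- rownames(D)        # tie-break key per active node
  sub <- as.list(labs)       # newick fragment per active node
  fmt <- function(v) sprintf("%.15g", v)
  cl <- function(v) if (clamp_negative) max(0, v) else v

  while (length(labs) > 3L) {
    n <- length(labs)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    idx <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    keys <- apply(idx, 1L, function(p) {
      pr <- sort(c(labs[p[1]], labs[p[2]]))
      paste(pr, collapse = "\r")
    })
    best <- idx[order(keys)[1L], ]
    i <- best[1L]; j <- best[2L]
    bi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    bj <- D[i, j] - bi
    newsub <- sprintf("(%s:%s,%s:%s)", sub[[i]], fmt(cl(bi)),
                      sub[[j]], fmt(cl(bj)))
    dnew <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    labs <- c(labs[keep], min(labs[c(i, j)]))
    rownames(D2) <- colnames(D2) <- labs
    sub <- c(sub[keep], newsub)
    D <- D2
  }

  # three nodes left: closed form for the terminal branches
  a <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  b <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  c <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  newick <- sprintf("(%s:%s,%s:%s,%s:%s);",
                    sub[[1]], fmt(cl(a)), sub[[2]], fmt(cl(b)),
                    sub[[3]], fmt(cl(c)))
  ape::read.tree(text = newick)
}

#' Branch support by site resampling
#'
#' Resamples alignment columns with replacement, rebuilds the
#' neighbor-joining tree per replicate, and scores every internal branch
#' of the original tree by the percentage of replicates whose tree
#' contains the same bipartition. Both support flavours
#' (`"interior-branch"` and `"bootstrap"`) use this site-resampling
#' partition frequency; the parametric t-statistic form of the interior
#' branch test is not implemented. Taxa are ordered canonically (sorted
#' labels) before resampling, so support values do not depend on the
#' input order of sequences.
#'
#' @inheritParams p_distance_matrix
#' @param replicates Number of resampling replicates (>= 1).
#' @param seed Optional integer seed; the same seed reproduces the same
#'   support values.
#' @param method Support flavour label, stored on the result.
#' @param clamp_negative Passed to [neighbor_joining()].
#' @return The neighbor-joining tree (a `phylo`) with `node.label` holding
#'   support percentages on internal nodes (`NA` on the root) and
#'   attributes `replicates` and `method`.
#' @export
branch_support <- function(aln, replicates = 1000L, seed = NULL,
                           method = c("interior-branch", "bootstrap"),
                           complete_deletion = TRUE, clamp_negative = FALSE) {
  method <- match.arg(method)
  if (replicates < 1L) stop("replicates must be >= 1")
  m <- as_char_alignment(aln)
  m <- m[order(rownames(m)), , drop = FALSE]
  if (complete_deletion) {
    gap <- m == "-" | m == "."
    keep <- colSums(gap) == 0L
    if (!any(keep)) stop("complete deletion removed all alignment columns")
    m <- m[, keep, drop = FALSE]
  }
  main <- neighbor_joining(p_distance_matrix(m, complete_deletion = FALSE),
                           clamp_negative = clamp_negative)
  if (!is.null(seed)) set.seed(seed)
  S <- ncol(m)
  boots <- vector("list", replicates)
  for (bb in seq_len(replicates)) {
    idx <- sample.int(S, S, replace = TRUE)
    boots[[bb]] <- neighbor_joining(
      p_distance_matrix(m[, idx, drop = FALSE], complete_deletion = FALSE),
      clamp_negative = clamp_negative)
  }
  counts <- ape::prop.clades(main, boots, rooted = FALSE)
  supp <- 100 * counts / replicates
  supp[1L] <- NA_real_   # root node: trivial partition
  main$node.label <- supp
  attr(main, "replicates") <- as.integer(replicates)
  attr(main, "method") <- method
  main
}

match_set_rules <- function(features, rules) {
  cdr1 <- features$cdr1_length
  res57 <- features$residue_57
  w107 <- features$trp_107
  hits <- integer(0)
  for (i in seq_len(nrow(rules))) {
    r <- rules[i, ]
    if (!cdr1 %in% r$cdr1_lengths[[1L]]) next
    if (identical(r$residue_57[[1L]], "lacks")) {
      if (!isTRUE(features$cdr2_deleted)) next
    } else {
      if (isTRUE(features$cdr2_deleted)) next
      if (is.na(res57) || !res57 %in% r$residue_57[[1L]]) next
    }
    ok_w <- switch(r$w107,
                   "+" = w107 %in% c("present", "not-applicable"),
                   "-" = w107 %in% c("absent", "not-applicable"),
                   TRUE)
    if (!ok_w) next
    hits <- c(hits, r$set)
  }
  hits
}

#' Assign a TRDV1 gene to a phylogenetic set
#'
#' Matches the gene's CDR features (CDR1 length, residue at IMGT 57,
#' presence of Trp at IMGT 107, missing CDR2) against the set rule table.
#' Named per-gene exceptions (a CDR1 of 8 in set 2, a CDR1 of 18 in set 9,
#' Gln at 107 in set 5) are honored before the rules. When several sets
#' match — the rule table cannot separate sets 5/8 or 4/6 on features
#' alone — and a tree containing the gene is supplied, the candidate whose
#' reference members share the smallest clade with the gene wins;
#' otherwise the assignment is flagged ambiguous.
#'
#' @param features A `v_features` object.
#' @param tree Optional `phylo` tree (rooted for clade logic) whose tips
#'   include `gene` and reference set members.
#' @param gene Optional gene name (tip label; also used for exceptions).
#' @param rules Set rule table, as returned by [trdv1_set_rules()].
#' @param members Named list mapping set id to reference member gene
#'   names, as returned by [trdv1_set_members()].
#' @return A list of class `set_assignment`: `gene`, `set_id` (integer or
#'   `NA`), `evidence` (`"features-only"`, `"tree-resolved"`,
#'   `"ambiguous"` or `"unassigned"`), `candidate_sets`.
#' @export
assign_trdv1_set <- function(features, tree = NULL, gene = NA_character_,
                             rules = trdv1_set_rules(),
                             members = trdv1_set_members()) {
  stopifnot(inherits(features, "v_features"))
  mk <- function(set_id, evidence, cands) {
    structure(list(gene = gene, set_id = set_id, evidence = evidence,
                   candidate_sets = cands), class = "set_assignment")
  }
  exc <- attr(rules, "exceptions")
  if (!is.na(gene) && gene %in% names(exc)) {
    return(mk(exc[[gene]], "features-only", exc[[gene]]))
  }
  cands <- match_set_rules(features, rules)
  if (length(cands) == 0L) return(mk(NA_integer_, "unassigned", integer(0)))
  if (length(cands) == 1L) return(mk(cands, "features-only", cands))
  if (!is.null(tree) && !is.na(gene) && gene %in% tree$tip.label) {
    sizes <- vapply(cands, function(s) {
      refs <- setdiff(intersect(members[[as.character(s)]], tree$tip.label),
                      gene)
      if (length(refs) == 0L) return(NA_integer_)
      node <- ape::getMRCA(tree, c(gene, refs))
      length(ape::extract.clade(tree, node)$tip.label)
    }, integer(1L))
    if (any(!is.na(sizes))) {
      smin <- min(sizes, na.rm = TRUE)
      winners <- cands[!is.na(sizes) & sizes == smin]
      if (length(winners) == 1L) return(mk(winners, "tree-resolved", cands))
    }
  }
  mk(NA_integer_, "ambiguous", cands)
}
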