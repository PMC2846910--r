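# Independent oracles used by the test suite. These are deliberately
# written as brute-force implementations that share no code with the
# package internals.

# --- exhaustive RSS window scan ------------------------------------------
# Direct enumeration of every window of every admissible length, with
# mismatch counting written out longhand.
oracle_scan_rss <- function(seq, spacer_class, tol = 1L) {
  hept_cons <- c("C", "A", "C", "A", "G", "T", "G")
  nona_cons <- c("A", "C", "A", "A", "A", "A", "A", "C", "C")
  s <- strsplit(seq, "")[[1L]]
  hits <- integer(0)
  for (pos in seq_along(s)) {
    for (sp in (spacer_class - tol):(spacer_class + tol)) {
      last <- pos + 16L + sp - 1L
      if (last > length(s)) next
      w <- s[pos:last]
      if (!(w[1] == "C" && w[2] == "A" && w[3] == "C")) next
      hmm <- sum(w[4:7] != hept_cons[4:7])
      nmm <- sum(w[(8L + sp):(16L + sp)] != nona_cons)
      if (hmm <= 2L && nmm <= 3L) { hits <- c(hits, pos); break }
    }
  }
  unique(hits)
}

# --- exhaustive ordered-subset D caller ----------------------------------
# Enumerates every fragment (d, start, end) whose junction substring is a
# contiguous substring of the D gene, then searches all non-overlapping,
# strictly-D-ordered selections by depth-first enumeration.
oracle_d_segments <- function(cdr3, d_seqs, min_len = 6L) {
  L <- nchar(cdr3)
  segs <- list()
  for (di in seq_along(d_seqs)) {
    dmax <- nchar(d_seqs[[di]])
    for (i in seq_len(L)) {
      e_max <- min(L, i + dmax - 1L)
      e_min <- i + min_len - 1L
      if (e_min > e_max) next
      for (e in e_min:e_max) {
        if (grepl(substr(cdr3, i, e), d_seqs[[di]], fixed = TRUE)) {
          segs[[length(segs) + 1L]] <- c(d = di, start = i, end = e)
        }
      }
    }
  }
  segs
}

oracle_better <- function(a, b) {
  # TRUE when a strictly beats b: more matched nt, fewer segments,
  # leftmost starts, lowest genomic D indices.
  if (a$total != b$total) return(a$total > b$total)
  if (a$nsegs != b$nsegs) return(a$nsegs < b$nsegs)
  k <- seq_len(min(length(a$starts), length(b$starts)))
  for (i in k) {
    if (a$starts[i] != b$starts[i]) return(a$starts[i] < b$starts[i])
  }
  for (i in k) {
    if (a$ds[i] != b$ds[i]) return(a$ds[i] < b$ds[i])
  }
  FALSE
}

oracle_call_trdd <- function(cdr3, d_seqs, min_len = 6L) {
  segs <- oracle_d_segments(cdr3, d_seqs, min_len)
  ord <- order(vapply(segs, `[`, 0, "start"))
  segs <- segs[ord]
  best <- list(total = 0L, nsegs = 0L, starts = integer(0), ds = integer(0))
  dfs <- function(idx, last_end, last_d, cur) {
    if (oracle_better(cur, best)) best <<- cur
    if (idx > length(segs)) return()
    for (k in idx:length(segs)) {
      sg <- segs[[k]]
      if (sg["start"] <= last_end || sg["d"] <= last_d) next
      dfs(k + 1L, sg["end"], sg["d"],
          list(total = cur$total + sg["end"] - sg["start"] + 1L,
               nsegs = cur$nsegs + 1L,
               starts = c(cur$starts, sg["start"]),
               ds = c(cur$ds, sg["d"])))
    }
  }
  dfs(1L, 0L, 0L, best)
  best
}

# --- least-squares tree fitting over all topologies ----------------------
ls_fit_topology <- function(topo, D) {
  labs <- rownames(D)
  pairs <- t(utils::combn(length(labs), 2L))
  E <- nrow(topo$edge)
  A <- matrix(0, nrow(pairs), E)
  for (r in seq_len(nrow(pairs))) {
    i <- match(labs[pairs[r, 1L]], topo$tip.label)
    j <- match(labs[pairs[r, 2L]], topo$tip.label)
    np <- ape::nodepath(topo, i, j)
    for (k in seq_len(length(np) - 1L)) {
      e <- which((topo$edge[, 1L] == np[k] & topo$edge[, 2L] == np[k + 1L]) |
                 (topo$edge[, 1L] == np[k + 1L] & topo$edge[, 2L] == np[k]))
      A[r, e] <- 1
    }
  }
  y <- D[cbind(pairs[, 1L], pairs[, 2L])]
  fit <- stats::lm.fit(A, y)
  list(rss = sum(fit$residuals^2), lengths = fit$coefficients)
}

# Best topology by exhaustive enumeration + least squares.
oracle_best_topology <- function(D) {
  topos <- phangorn::allTrees(nrow(D), rooted = FALSE,
                              tip.label = rownames(D))
  fits <- lapply(topos, ls_fit_topology, D = D)
  rss <- vapply(fits, `[[`, 0, "rss")
  list(tree = topos[[which.min(rss)]], rss = min(rss))
}

# Random unrooted tree with positive branch lengths and its additive
# path-distance matrix.
random_additive_matrix <- function(n, seed) {
  set.seed(seed)
  tr <- ape::rtree(n, rooted = FALSE)
  tr$edge.length <- stats::runif(nrow(tr$edge), 0.05, 0.5)
  D <- ape::cophenetic.phylo(tr)
  D <- D[order(rownames(D)), order(colnames(D))]
  list(tree = tr, D = D)
}
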