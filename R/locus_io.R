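# Germline gene data model and external formats: the gene-coordinate table
# (TSV, one row per annotated gene model), genome/locus FASTA, and GFF3
# annotation output. Coordinates are 1-based inclusive throughout, matching
# the printed start/end convention of the source gene table; GFF3 uses the
# same convention natively.

GENE_TYPES <- c("V", "D", "J", "C")

#' Construct a germline gene record
#'
#' @param name Gene symbol (e.g. `"TRDV1a"`, `"TRDD2"`).
#' @param gene_type One of `"V"`, `"D"`, `"J"`, `"C"`; inferred from the
#'   name when missing.
#' @param scaffold Sequence-region name.
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @param orientation `"+"` or `"-"`. For `"-"` the `sequence` slot holds
#'   the reverse complement of the genome slice (the coding strand).
#' @param sequence Coding-strand nucleotide string, or `NULL`.
#' @param exons `NULL` or a data frame with columns `label`, `start`, `end`
#'   (genomic coordinates), ordered 5' to 3' along the transcript. V genes
#'   carry exactly two exons (L-PART1, V-EXON) and C genes exactly three
#'   (EX1..EX3).
#' @param subgroup Subgroup label (e.g. `"TRDV1"`) or `""`.
#' @param redundancy_group Marker shared by gene models representing the
#'   same gene, or `""`.
#' @param functionality `"functional"`, `"ORF"`, `"pseudogene"` or `"unset"`.
#' @return An object of class `trd_gene`.
#' @export
trd_gene <- function(name, gene_type = NULL, scaffold = NA_character_,
                     start = NA_integer_, end = NA_integer_,
                     orientation = "+", sequence = NULL, exons = NULL,
                     subgroup = "", redundancy_group = "",
                     functionality = "unset") {
  if (is.null(gene_type)) gene_type <- infer_gene_type(name)
  stopifnot(gene_type %in% GENE_TYPES)
  if (!orientation %in% c("+", "-")) {
    stop("gene '", name, "': orientation must be '+' or '-'")
  }
  if (!is.na(start) && !is.na(end) && start > end) {
    stop("gene '", name, "': start > end")
  }
  if (!is.null(exons)) {
    exons <- as.data.frame(exons)
    stopifnot(all(c("label", "start", "end") %in% names(exons)))
    if (gene_type == "V" && nrow(exons) != 2L) {
      stop("gene '", name, "': V genes carry exactly two exons")
    }
    if (gene_type == "C" && nrow(exons) != 3L) {
      stop("gene '", name, "': C genes carry exactly three exons")
    }
  }
  if (!is.null(sequence)) {
    sequence <- toupper(as.character(sequence))
    if (!is.na(start) && !is.na(end) && nchar(sequence) != end - start + 1L) {
      stop("gene '", name, "': sequence length does not match coordinates")
    }
  }
  structure(
    list(name = name, gene_type = gene_type, subgroup = subgroup,
         scaffold = scaffold, start = as.integer(start), end = as.integer(end),
         orientation = orientation, sequence = sequence, exons = exons,
         redundancy_group = redundancy_group, functionality = functionality),
    class = "trd_gene"
  )
}

#' @export
print.trd_gene <- function(x, ...) {
  cat(sprintf("<trd_gene> %s (%s) %s:%d-%d (%s)%s\n",
              x$name, x$gene_type, x$scaffold, x$start, x$end, x$orientation,
              if (is.null(x$sequence)) "" else sprintf(" [%d nt]", nchar(x$sequence))))
  invisible(x)
}

infer_gene_type <- function(name) {
  m <- regmatches(name, regexpr("^TRD([VDJC])", name))
  if (length(m) == 1L && nzchar(m)) return(substr(m, 4L, 4L))
  stop("cannot infer gene type from name '", name, "'; supply gene_type")
}

infer_subgroup <- function(name, gene_type) {
  if (gene_type != "V") return("")
  m <- regmatches(name, regexpr("^TRDV[0-9]+", name))
  if (length(m) == 1L && nzchar(m)) m else ""
}

new_gene_table <- function(df, source = NA_character_) {
  rownames(df) <- NULL
  structure(df, class = c("trd_gene_table", "data.frame"), source = source)
}

#' Parse a gene-coordinate table
#'
#' Reads a tab-separated table of annotated gene models with header columns
#' `name`, `scaffold`, `start`, `end`, `orientation` and, optionally,
#' `gene_type` (or `type`), `subgroup` and `group` (the redundancy-group
#' marker). Coordinates are 1-based inclusive.
#'
#' @param path Path to the TSV file.
#' @return A `trd_gene_table` (a data frame with one row per gene model,
#'   columns `name`, `gene_type`, `subgroup`, `scaffold`, `start`, `end`,
#'   `orientation`, `group`, `functionality`, `members`).
#' @export
parse_gene_table <- function(path) {
  if (!file.exists(path)) stop("gene table not found: ", path)
  nf <- utils::count.fields(path, sep = "\t", quote = "", comment.char = "")
  if (length(nf) == 0L) stop("gene table is empty (no header): ", path)
  if (any(nf != nf[1L])) {
    bad <- which(nf != nf[1L])[1L]
    stop(sprintf("malformed row in %s at line %d: expected %d fields, found %d",
                 path, bad, nf[1L], nf[bad]))
  }
  raw <- utils::read.delim(path, sep = "\t", header = TRUE, quote = "",
                           colClasses = "character", check.names = TRUE,
                           stringsAsFactors = FALSE)
  names(raw) <- tolower(names(raw))
  if ("type" %in% names(raw) && !"gene_type" %in% names(raw)) {
    names(raw)[names(raw) == "type"] <- "gene_type"
  }
  required <- c("name", "scaffold", "start", "end", "orientation")
  miss <- setdiff(required, names(raw))
  if (length(miss)) stop("gene table missing column(s): ", paste(miss, collapse = ", "))

  n <- nrow(raw)
  parse_int <- function(col) {
    v <- raw[[col]]
    bad <- !grepl("^[0-9]+$", v)
    if (any(bad)) {
      stop(sprintf("non-integer %s at line %d: '%s'",
                   col, which(bad)[1L] + 1L, v[which(bad)[1L]]))
    }
    as.integer(v)
  }
  if (n == 0L) {
    df <- data.frame(name = character(), gene_type = character(),
                     subgroup = character(), scaffold = character(),
                     start = integer(), end = integer(),
                     orientation = character(), group = character(),
                     functionality = character(), members = character(),
                     stringsAsFactors = FALSE)
    return(new_gene_table(df, source = path))
  }

  start <- parse_int("start")
  end <- parse_int("end")
  bad_ori <- !raw$orientation %in% c("+", "-")
  if (any(bad_ori)) {
    stop(sprintf("invalid orientation at line %d: '%s'",
                 which(bad_ori)[1L] + 1L, raw$orientation[which(bad_ori)[1L]]))
  }
  if (any(start > end)) {
    i <- which(start > end)[1L]
    stop(sprintf("start > end for gene '%s' (line %d)", raw$name[i], i + 1L))
  }
  if (anyDuplicated(raw$name)) {
    stop("duplicate gene name in table: ",
         raw$name[duplicated(raw$name)][1L])
  }

  gene_type <- if ("gene_type" %in% names(raw)) raw$gene_type else
    vapply(raw$name, infer_gene_type, "")
  subgroup <- if ("subgroup" %in% names(raw)) raw$subgroup else
    mapply(infer_subgroup, raw$name, gene_type, USE.NAMES = FALSE)
  group <- if ("group" %in% names(raw)) raw$group else rep("", n)
  group[is.na(group)] <- ""

  df <- data.frame(name = raw$name, gene_type = gene_type,
                   subgroup = subgroup, scaffold = raw$scaffold,
                   start = start, end = end, orientation = raw$orientation,
                   group = group, functionality = rep("unset", n),
                   members = raw$name, stringsAsFactors = FALSE)
  new_gene_table(df, source = path)
}

#' Collapse redundant gene models
#'
#' Gene models sharing a non-empty redundancy-group marker are merged into a
#' single record: the first-named (first-listed) model is kept as
#' representative and the member names are recorded in the `members` column.
#' Records without a marker pass through unchanged. A marker carried by a
#' single record is treated as no group, with a warning.
#'
#' @param table A `trd_gene_table`.
#' @return A `trd_gene_table` with redundant models merged.
#' @export
collapse_redundant_models <- function(table) {
  stopifnot(inherits(table, "trd_gene_table"))
  if (nrow(table) == 0L) return(table)
  grp <- table$group
  has <- !is.na(grp) & nzchar(grp)
  sizes <- table(grp[has])
  singletons <- names(sizes)[sizes < 2L]
  if (length(singletons)) {
    warning("redundancy group(s) with a single member treated as no group: ",
            paste(singletons, collapse = ", "))
    has[grp %in% singletons] <- FALSE
  }
  keep <- rep(TRUE, nrow(table))
  members <- table$members
  for (g in unique(grp[has])) {
    idx <- which(has & grp == g)
    rep_i <- idx[1L]
    members[rep_i] <- paste(table$name[idx], collapse = ",")
    keep[idx[-1L]] <- FALSE
  }
  out <- table[keep, , drop = FALSE]
  out$members <- members[keep]
  new_gene_table(as.data.frame(out), source = attr(table, "source"))
}

#' Extract a gene's coding-strand sequence from a genome
#'
#' @param genome A named `DNAStringSet` (or named character vector) of
#'   scaffold sequences, or a path to a FASTA file.
#' @param gene A `trd_gene` stub or a one-row slice of a `trd_gene_table`.
#' @return A `trd_gene` with the `sequence` slot filled
#'   (reverse-complemented when orientation is `"-"`).
#' @export
extract_gene_sequence <- function(genome, gene) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (inherits(gene, "data.frame")) {
    stopifnot(nrow(gene) == 1L)
    gene <- trd_gene(name = gene$name, gene_type = gene$gene_type,
                     scaffold = gene$scaffold, start = gene$start,
                     end = gene$end, orientation = gene$orientation,
                     subgroup = gene$subgroup,
                     redundancy_group = gene$group,
                     functionality = gene$functionality)
  }
  stopifnot(inherits(gene, "trd_gene"))
  seqs <- if (inherits(genome, "DNAStringSet")) {
    stats::setNames(as.character(genome), names(genome))
  } else genome
  if (!gene$scaffold %in% names(seqs)) {
    stop("gene '", gene$name, "': scaffold '", gene$scaffold,
         "' not present in genome")
  }
  scaf <- seqs[[gene$scaffold]]
  if (is.na(gene$start) || is.na(gene$end) ||
      gene$start < 1L || gene$end > nchar(scaf)) {
    stop("gene '", gene$name, "': coordinates out of range for scaffold '",
         gene$scaffold, "'")
  }
  s <- substr(scaf, gene$start, gene$end)
  if (gene$orientation == "-") s <- revcomp(s)
  gene$sequence <- s
  gene
}

#' Write gene annotation as GFF3
#'
#' Emits one `gene` feature per record plus `exon` sub-features where exon
#' structure is available. Coordinates are written 1-based inclusive (the
#' native GFF3 convention) and the strand column mirrors the orientation.
#'
#' @param genes A `trd_gene_table` (optionally with an `exons` list-column)
#'   or a list of `trd_gene` objects.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_annotation <- function(genes, path) {
  if (inherits(genes, "trd_gene_table")) {
    glist <- lapply(seq_len(nrow(genes)), function(i) {
      ex <- if ("exons" %in% names(genes)) genes$exons[[i]] else NULL
      trd_gene(name = genes$name[i], gene_type = genes$gene_type[i],
               scaffold = genes$scaffold[i], start = genes$start[i],
               end = genes$end[i], orientation = genes$orientation[i],
               exons = ex, subgroup = genes$subgroup[i],
               functionality = genes$functionality[i])
    })
  } else {
    glist <- genes
    stopifnot(all(vapply(glist, inherits, TRUE, "trd_gene")))
  }
  if (length(glist) == 0L) stop("no genes to write")

  rows <- list()
  for (g in glist) {
    if (is.na(g$start) || is.na(g$end)) {
      stop("gene '", g$name, "' lacks coordinates")
    }
    rows[[length(rows) + 1L]] <- data.frame(
      seqnames = g$scaffold, start = g$start, end = g$end,
      strand = g$orientation, type = "gene", ID = g$name, Name = g$name,
      Parent = NA_character_, stringsAsFactors = FALSE)
    if (!is.null(g$exons)) {
      for (k in seq_len(nrow(g$exons))) {
        rows[[length(rows) + 1L]] <- data.frame(
          seqnames = g$scaffold, start = g$exons$start[k],
          end = g$exons$end[k], strand = g$orientation, type = "exon",
          ID = paste0(g$name, ":", g$exons$label[k]),
          Name = g$exons$label[k], Parent = g$name, stringsAsFactors = FALSE)
      }
    }
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(
    seqnames = df$seqnames,
    ranges = IRanges::IRanges(start = df$start, end = df$end),
    strand = df$strand)
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$Name <- df$Name
  plist <- lapply(df$Parent, function(p) if (is.na(p)) character(0) else p)
  S4Vectors::mcols(gr)$Parent <- methods::as(plist, "CharacterList")
  tryCatch(
    rtracklayer::export(gr, path, format = "gff3"),
    error = function(e) stop("cannot write annotation to '", path, "': ",
                             conditionMessage(e))
  )
  invisible(path)
}

#' Read a GFF3 annotation back into a gene table
#'
#' Inverse of [write_annotation()]: `gene` features become table rows and
#' `exon` features are attached through the `exons` list-column.
#'
#' @param path GFF3 file path.
#' @return A `trd_gene_table` with an `exons` list-column.
#' @export
read_annotation <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  genes <- df[df$type == "gene", , drop = FALSE]
  exons <- df[df$type == "exon", , drop = FALSE]
  n <- nrow(genes)
  gene_type <- vapply(genes$ID, infer_gene_type, "")
  out <- data.frame(
    name = genes$ID, gene_type = gene_type,
    subgroup = mapply(infer_subgroup, genes$ID, gene_type, USE.NAMES = FALSE),
    scaffold = as.character(genes$seqnames),
    start = genes$start, end = genes$end,
    orientation = as.character(genes$strand),
    group = rep("", n), functionality = rep("unset", n),
    members = genes$ID, stringsAsFactors = FALSE)
  ex_list <- lapply(genes$ID, function(id) {
    parents <- vapply(exons$Parent, function(p) {
      if (length(p)) as.character(p)[1L] else NA_character_
    }, "")
    sel <- exons[!is.na(parents) & parents == id, , drop = FALSE]
    if (nrow(sel) == 0L) return(NULL)
    data.frame(label = sel$Name, start = sel$start, end = sel$end,
               stringsAsFactors = FALSE)
  })
  out$exons <- I(ex_list)
  new_gene_table(out, source = path)
}

#' Write a gene table as TSV
#'
#' @param table A `trd_gene_table`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_gene_table <- function(table, path) {
  cols <- intersect(
    c("name", "gene_type", "subgroup", "scaffold", "start", "end",
      "orientation", "group", "functionality", "members"),
    names(table))
  utils::write.table(as.data.frame(table)[, cols, drop = FALSE], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
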