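---
title: "Methods: TRD germline annotation and junction analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TRD germline annotation and junction analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trdrep)
```

This vignette documents the models, parameter choices and numerical
conventions behind `trdrep`, in the spirit of a methods section: what
each stage assumes, which knobs matter, and what the synthetic-data
tests do and do not demonstrate about real data.

## The biological setting

T cell receptor delta chains are assembled by V(D)J recombination at
the TRD locus, which lies embedded within the TRA locus. Recombination
is directed by recombination signal sequences (RSS): a conserved
heptamer and nonamer separated by a spacer of about 12 bp (found 5' of
D and J genes) or about 23 bp (found 3' of V and D genes); efficient
recombination pairs a 12-spacer with a 23-spacer signal (the 12/23
rule). The rearranged CDR3 is built from the 3' end of the V gene, one
or more D genes, non-templated N nucleotides, palindromic P nucleotides
at untrimmed germline ends, and the 5' end of the J gene. In "γδ T cell
high" species such as cattle the TRDV1 subgroup is massively expanded,
and single junctions can incorporate up to all five D genes, giving
exceptionally long and diverse CDR3 loops.

## Gene tables and redundancy collapsing

Gene models arrive as a coordinate table (1-based inclusive start/end,
strand, scaffold). Draft-assembly annotation frequently yields several
gene models for what is most likely a single gene on different
scaffolds; the shipped table marks such models with shared
redundancy-group ids. `collapse_redundant_models()` merges each group
into its first-listed representative and records the members, so both
interpretations (duplicated genes vs. assembly artifacts) stay
recoverable; the output row count always equals the input count minus
the summed group excesses. For novel data without markers the coding
sequences and flanks must be compared by the analyst; we deliberately
do not guess a similarity threshold, because the collapse decision on
draft assemblies is evidential, not numeric. Scaffold orientations are
taken as given — draft scaffolds may be flipped, and nothing in a
single-scaffold view can detect that.

## RSS model

Matching is always performed on the coding strand reading away from
the coding end. This single normalization makes one consensus —
heptamer `CACAGTG`, nonamer `ACAAAAACC` — serve all four sides (the
genomic appearance of 5' signals as `…GTG` is just the reverse
complement). Acceptance requires:

* heptamer positions 1–3 exactly `CAC` (the functionally critical
  core),
* at most 2 mismatches over heptamer positions 4–7,
* at most 3 mismatches over the nonamer (the nonamer is the less
  conserved element),
* spacer length within ±1 bp of its class (12 or 23).

All three thresholds are arguments of every scanning function. When
two spacer lengths are acceptable at one heptamer position the lower
total mismatch count wins, then the spacer closest to its class.
`find_flanking_rss()` searches only the sides a gene type mandates
(V: 3'/23; D: 5'/12 and 3'/23; J: 5'/12) and requires the heptamer to
abut the coding end. `conservation_matrix()` computes per-position
information content as `2 − H` bits with a uniform background and no
small-sample correction — the matrix is an export for logo rendering,
not an estimator, so the correction is intentionally omitted.

## IMGT numbering as an anchored layout

Full IMGT numbering is a profile alignment problem; this package
implements it only to the depth the downstream analyses need: anchor
verification and CDR lengths. The framework regions have fixed position
counts (FR1 = positions 1–26, FR2 = 39–55, FR3 = 66–104) and the CDR
loops absorb all length variation, with gaps placed at the top of each
loop (first `ceiling(n/2)` slots filled from the start, the rest from
the end; overlong loops get inserted positions such as `32.1`). Because
positions 89 and 104 sit in one contiguous framework, the hydrophobic
anchor is always 15 residues before the 2nd-CYS — a useful internal
consistency check. The search proceeds in three stages:

1. **standard layout** — all four anchors (C23, W41, hydrophobic 89
   from {L, I, V, M, F, A} with Leu canonical, C104) must hold; among
   competing solutions the most C-terminal 2nd-CYS wins (smallest
   germline CDR3 extension), then a 3-residue CDR2, then the shortest
   CDR1;
2. **CDR2-deleted layout** — a known deletion class removes the last
   FR2 position through the fifth FR3 position (IMGT 55–70), leaving no
   CDR2; genes carrying it are numbered with FR2 = 39–54 and
   FR3 = 71–104;
3. **relaxed layout** — only the cysteine pair is anchored (CDR2
   assumed 3 residues), so that the loss of W41 or of the hydrophobic
   89 is reported through anchor flags instead of a hard failure.

Only a missing cysteine pair fails numbering; the failure condition
carries the best partial map. No upper bound is placed on CDR1 (an
18-residue CDR1 occurs naturally).

Functionality follows the standard three-way call: premature stop or
frameshift ⇒ pseudogene (excluded downstream); an intact reading frame
with a structural anomaly — missing CDR2, a germline extension beyond
position 104 longer than 4 residues (3–4 is canonical, 12–15
anomalous), a lost non-cysteine anchor, or unnumerable structure — ⇒
ORF; otherwise functional. The extension threshold is an argument
(`orf_extension_max`).

## Distances, neighbor joining and support

`p_distance_matrix()` implements the proportion-of-differences distance
with complete deletion (every column containing a gap in any sequence
is removed first; the retained column count is reported).
`neighbor_joining()` is the standard agglomeration with two
determinism guarantees that generic implementations leave unspecified:
Q-criterion ties are broken by the lexicographically smallest sorted
label pair (internal nodes inherit the smallest contained tip label),
and negative branch lengths are retained by default (`clamp_negative`
clamps them at zero). On additive matrices the algorithm provably
reconstructs the generating tree; the test suite verifies this against
an independent oracle that enumerates all unrooted topologies (via
phangorn) and fits branch lengths by least squares, and cross-checks
topologies against `ape::nj`.

`branch_support()` resamples alignment columns with replacement,
rebuilds the tree per replicate, and scores each internal bipartition
of the main tree by its replicate frequency. Both the
"interior-branch" and "bootstrap" labels use this site-resampling
frequency; the parametric t-statistic form of the interior branch test
is intentionally out of scope, and the label records only which test
the user asked for. Sequences are sorted by name before resampling so
support values cannot depend on input order.

TRDV1 set assignment combines a rule table over three CDR features —
CDR1 length, the residue at IMGT position 57, presence of Trp at
position 107 — with named per-gene exceptions (a CDR1 of 8 in set 2, a
CDR1 of 18 in set 9, Gln at 107 in set 5) kept as exceptions rather
than widened rules, so the rules stay sharp. Two pairs of sets (5/8
and 4/6) share feature tuples and are separable only phylogenetically:
when a tree containing the gene is supplied, the candidate whose
reference members share the smallest clade with the gene wins;
otherwise the assignment is flagged ambiguous. Genes whose germline
contribution past position 104 is shorter than three residues cannot
show position 107; their Trp-107 state is "not-applicable" and is
treated as compatible with any rule (absence of evidence).

## Junction analysis

A cDNA is assigned to the germline V gene with the fewest nucleotide
differences over an ungapped comparison of the V-REGION; more than 6
differences, or a tie, leaves it unassigned with diagnostics. The CDR3
spans IMGT codons 105–117: its start is three nucleotides per residue
past the 2nd-CYS of the assigned germline V, and its end abuts the
J-PHE 118 codon of the F/W-G-X-G motif, located through the best
suffix-matching germline J. A transcript whose motif is disrupted, or
whose motif falls out of frame with the 2nd-CYS, is a boundary error
rather than a junction.

D usage is claimed only on at least 6 exactly matching contiguous
nucleotides of a D gene. Matches are exact because the 6-nt floor
loses its meaning under free mismatches — a 6-mer at one mismatch is
close to random background. The caller selects, by dynamic programming
over the junction, the non-overlapping fragment set with strictly
increasing genomic D order (each D used at most once, reflecting the
deletional mechanism of sequential D-D joining) that maximizes the
total matched nucleotides; ties prefer fewer segments, then the
leftmost arrangement, then the lowest genomic indices. A fragment
whose sequence also occurs in another D gene is flagged ambiguous but
attributed to the lower genomic index. The test suite proves the
dynamic program equal to an exhaustive enumeration over all ordered
fragment subsets on hundreds of seeded junctions.

P nucleotides are only possible at untrimmed germline ends: up to 2
adjacent unassigned nucleotides equal to the reverse complement of the
terminal germline nucleotides are labelled P, longest first, with
ambiguous P-versus-N positions resolved in favour of P (the
palindromic explanation is mechanistically specific, random N is not).
Everything else unassigned is N. The final segments always tile the
junction exactly.

Usage summaries count every D occurrence per V subgroup; percentages
are shares of all D occurrences in the subgroup, rounded half-up to one
decimal. Printed tables occasionally truncate instead — one shipped
cell differs by exactly 0.1 for this reason — so truncation is offered
as an option, and neither behaviour is asserted for that cell.

## The synthetic locus and repertoire

The generator's defaults encode the documented structures of the real
locus rather than convenient test values: V genes have a 49-bp L-PART1
(leader) exon, an intron, and a V-EXON that must fall in 271–335 bp
(leader completion + FR/CDR template + a 4-residue germline extension
past the 2nd-CYS); the five D genes default to lengths 13, 15, 13, 9
and 11 nt — the span lengths implied by the annotated coordinates — so
multi-D junctions have realistic scale; J genes carry a 5' region, the
F/W-G-X-G motif and a tail; the C gene has three exons totalling a
1282-bp coding region; and an optional additional V gene sits 3' of C
in inverted orientation, as in all species examined. Canonical RSS are
planted on every mandated side, so the scanner invariant (every
emitted gene detected with zero consensus mismatches) holds by
construction.

Rearrangement simulation draws, per transcript, a V, an ordered D
subset (size weights default to uniform over 1–5) and a J; trims each
germline end by a truncated geometric with mean 2 (the literature
gives no distribution; geometric decay is the standard minimal model
for exonuclease nibbling); inserts N regions with Poisson(4) lengths
(junctions between D genes carry extensive N); and adds P nucleotides
at untrimmed ends with probability 0.5. The final N region is padded
so the junction length is a codon multiple — the simulated cDNAs model
expressed, in-frame transcripts — except in the degenerate
zero-N/zero-trim configuration, where the junction must equal the
exact germline concatenation. One sub-seed per transcript is derived
from the master seed, so enlarging a run never perturbs earlier
transcripts.

The clean benchmark (`make_clean_benchmark`) tightens this to
conditions under which recovery of the planted D list is
information-theoretically possible: no P nucleotides, every planted
fragment retains at least 6 nt, and N regions are rejection-sampled so
no 6-mer of any D gene appears outside the planted fragments. To make
rejection sampling terminate, the locus generator additionally builds
D genes with pairwise disjoint 6-mer sets and keeps V extensions and J
bodies free of D 6-mers. Synthetic V templates avoid cysteine and
tryptophan outside the designated anchors, so declared anchors are the
only candidates and numbering recovery is exact by construction.

What passing these tests shows: the algorithms implement their stated
rules exactly, and the D caller is optimal under its objective. What
they do not show: performance on real repertoires, where allelic
variation, sequencing error, spurious D-like 6-mers in N regions, and
P/N ambiguity genuinely reduce confidence — on real data the ≥ 6-nt
rule is a confidence floor, not a guarantee, which is exactly why the
original analyses adopted it.

## Problem sizes and numerical conventions

The shipped checks use a 4-V-gene locus, 500 oracle-comparison
junctions of at most 60 nt, a 2,000-junction clean benchmark, additive
matrices of 4–6 taxa (the largest size at which exhaustive topology
enumeration — 105 trees — stays instantaneous), 200 numbering
templates, and 100 seeded 1-kb scanner backgrounds. Coordinates are
1-based inclusive end-to-end, including GFF3 output. Percentages round
half-up with a 10⁻⁹ guard against binary floating-point edge cases.
Branch lengths are written with 15 significant digits, so trees
round-trip through newick without visible loss. All stochastic
routines take explicit seeds; identical seeds give byte-identical
outputs.

## Known limitations

* IMGT numbering is anchor-oriented, not a full profile alignment; it
  presumes the input starts at IMGT position 1 and will mis-number
  V domains with insertions or deletions inside framework regions
  (other than the recognised CDR2-spanning deletion).
* V/J assignment is ungapped; indel-bearing cDNAs are not handled.
* The interior branch test is approximated by resampling frequency.
* TRAV/TRAV-DV disambiguation is out of scope — distinguishing a
  delta-rearranging V gene from an alpha V gene ultimately requires
  rearrangement evidence, not sequence features alone.
* The redundancy-collapse step trusts the curated group markers; it
  does not re-derive them from sequence.
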