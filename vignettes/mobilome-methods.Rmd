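---
title: "Models and methods for mobile-element delineation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for mobile-element delineation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the science behind each
stage: the models and rules, why the defaults are what they are, what the
synthetic-data generator does and does not emulate, and the numerical
choices made where the design was genuinely open.

# The biological model

Integrative and conjugative elements (ICEs) are chromosomally integrated
mobile elements that excise into a circular form and self-transfer through
a type IV secretion system (T4SS). Integration is catalysed by a
site-specific recombinase between a short identical *core* sequence shared
by the element's *attP* site and a chromosomal *attB* site; in rhizobia the
attB cores typically overlap the 3' end of a tRNA gene or of *guaA*,
*radC* or *dusA*. The integrated element is therefore flanked by a direct
repeat of the core (*attL* and *attR*). Integrative mobilizable elements
(IMEs) integrate the same way but lack a complete T4SS; they carry a
relaxase (often a Ti-plasmid-like divergent *traACD* locus) and hijack
another element's machinery. Tripartite ICEs exist in the chromosome as
three separated regions (alpha, beta, gamma) delimited by three att-site
pairs of distinct core families whose sequential recombination assembles
one circular element.

The package's delineation logic is built directly on this model: find
repeated cores at integration anchors, demand mobility genes between the
repeats, and reconstruct the circular form with one core copy per join.

# Homology engine

All similarity calls run through one primitive: the best local alignment
(Smith–Waterman as implemented in Biostrings), BLOSUM62 with gap open 11 /
extend 1 for proteins, +1/−1 with linear gap −2 for nucleotide. Reported
identity is matches divided by alignment columns, gaps included — the
quantity BLAST prints for an HSP. Raw scores are converted to bits with
Karlin–Altschul-style parameters and an e-value *proxy*
(`m·n·2^−bits`) is attached; the proxy ranks alignments and gates edges, it
is not a database e-value.

Tunable thresholds:

* `min_identity` (percent, default 30) and `min_coverage` (query fraction,
  default 0.6) for panel hits — conservative defaults for protein panels;
  the nucleotide searches mirroring the published *trbB*/*traA* screens use
  a 50% identity cutoff over the aligned region (coverage 0.5), reading
  "pairwise identity" as local-alignment identity. Note that under
  +1/−1 scoring a reported nucleotide alignment essentially always has
  identity above ~50%, so sub-threshold homologs simply stop producing
  qualifying alignments; the cutoff is a strict floor on reported identity.
* Relaxase calling uses a bit-score floor of 33 (the hmmscan `-T 33`
  convention) on either panel hits or a user-supplied hmmscan domain table;
  a locus gets exactly one MOB family, ambiguity resolved by best
  full-sequence e-value, then score, then lexicographic id. Panel roles are
  gene names (`rlxS`, `traA`, ...) carrying their family as metadata
  (MOB_P subtype P1 and MOB_F respectively), so one exemplar serves both
  cluster typing and family calling.
* Conjugation clusters group colocated hits with inter-member gaps at most
  `locus_window` (default 10 kb — an operon-scale window; there is no
  standard colocation distance, and 10 kb comfortably spans a conjugation
  operon with a few interruptions). A trb-type T4SS needs at least 6 of the 9 core
  *trb* roles, a vir-type at least 6 vir roles; a *traACD* call needs
  divergently oriented *traA*/*traC* (an adjacent RDF gene is recorded);
  otherwise a lone coupling protein is reported as `T4CP_only`
  (potentially mobilizable).

A shared-4-mer prefilter (at least 2 distinct shared 4-mers) skips clearly
unrelated pairs when the number of alignments exceeds 20,000. It is
lossless above roughly 50% identity and can be disabled; the exhaustive
oracle tests run with it off.

# att-site delineation

Coordinates are 0-based half-open internally; GFF3 output is 1-based
inclusive.

For each anchor the strand-aware 3' end is computed (interval end on the
plus strand, start on the minus strand), and a window of ±`max_span`
(default 900 kb, chosen to exceed the largest observed monopartite
fragment, ~767 kb, with margin) is scanned on both flanks — anchors on
either strand are handled identically — for a second same-strand occurrence
of a substring of at least `min_core` bp (default 15, exact match;
an interior-mismatch budget is available but off by default) abutting or
overlapping the anchor 3' end within `slack` bp (default 10). Repeats are
extended to maximal length. A pair is retained only if the enclosed
interval contains at least one *seed* — a relaxase, conjugation-gene or
integrase locus — and per anchor the pair maximizing (core length, enclosed
seed count, shortest span) wins. Candidate elements are then accepted
greedily by (core length, span), dropping weaker candidates that overlap an
accepted one; this resolves the case where a long spurious repeat spans a
real element.

**Monopartite convention.** The fragment runs from attL start to attR end,
both cores included; the excised circle retains exactly one core (the
attP), so circle length = fragment length − core length. Excision is pure
string algebra: scar = sequence up to and including the attL core plus the
sequence after attR; re-integration inserts the circle back at the core.
Both directions are byte-exact inverses, which the tests verify against a
literal molecule-level recombination oracle.

**Tripartite resolution.** Pairs whose spans interleave on one replicon are
grouped; their sorted core copies are tiled into fragments (1st–2nd core,
3rd–4th, 5th–6th), and fragments join when one's right core pair equals the
next's left core pair. The join graph must form a single cycle, otherwise
`resolve_multipartite()` raises "unresolvable multipartite structure" (a
missing pair leaves an un-joinable set). The circle concatenates fragments
along the cycle starting at the largest (alpha) fragment, collapsing each
shared core to one copy: total length = sum of fragment lengths − 3 cores.
Published fragment sums for the largest tripartite ICE exceed its stated
total by 8 bp, implying some unstated core-overlap accounting; this
package's convention is pinned by the splice oracle rather than assumed.
Sequential excision swaps the order of the two inter-fragment chromosomal
gaps in the scar — a property of site-specific recombination that the
closed-form excision reproduces and the round-trip tests cover. The scar
formula assumes the conservative interleaved arrangement (the one produced
by integration); other arrangements excise chromosomal gaps into separate
circles and are rejected.

Candidate regions whose machinery is found but whose att sites are not
(`att_status = "att_not_found"`) are clustered from uncovered seeds (gap at
most 20 kb, extended over flanking panel-hit loci such as replication
genes); a candidate carrying repABC replication genes *and* lacking att
sites is flagged as a plasmid artificially joined to the chromosome during
assembly and excluded from element counts. att evidence always wins over
the artifact rule.

# Element typing

Classification applies rules in order: integrated + att + integrase +
relaxase + T4SS → ICE; the same without a T4SS (traACD or a lone MOB gene)
→ IME; a plasmid replicon with relaxase + T4SS → conjugative plasmid; with
relaxase and/or coupling protein only → mobilizable plasmid; otherwise
unclassified. Elements with full machinery but undetected att sites are
classified with the att-not-found override, mirroring the handful of
published ICEs whose att sites were never located.

The symbiosis (ICESym) flag is operationalized as a conjunction — all of
nodABC and nodIJ, plus at least one nitrogenase (*nif*) and one *fix* role
— because the literature identifies which elements are symbiosis ICEs
without committing to a defining gene set; the conjunction is configurable
for stricter notions of a "complete" symbiosis complement. Entry
exclusion (*trbK*) and Rep_3/DUF2840 presence are recorded because their
absence is a stable signature of the symbiosis-ICE lineage.

Quorum-sensing profiling assigns each traR/traI/qseM/qseC/fseA copy to its
paralogue class by best exemplar (the classes sit at ~54% and ~65%
amino-acid identity, far enough apart for best-hit assignment) and calls
each copy intact, pseudogene or remnant. The thresholds — frameshift when
the CDS length is not a multiple of 3, internal stop codons, truncation
below 80% of the exemplar length, remnant below 40% exemplar coverage —
have no standard published values; they were chosen so that the
characteristic decay states seen in these loci (a ~100 bp 3' remnant of
*traR1*; frame-shifting deletions in *traI2*) are called as remnant and
pseudogene respectively, and they are configurable.

Redundancy collapse groups elements sharing an identical accessory
ortholog-cluster set after removing IS transposase clusters: gene content,
not SNPs, defines redundancy. The longest member represents each group.

Nod-box motifs use a plain position-weight matrix: position probabilities
with +0.5 pseudocount over at least two aligned equal-length training
sequences, log2-odds against the background, default threshold the minimum
training-sequence self-score (so every training sequence is recovered by
construction); scanning covers both strands and skips windows containing
non-ACGT bases.

# Pangenome and mobilome

One clustering engine with presets replaces the two published tools: single
linkage over pairs passing identity (40% "Roary-like" or 25%
"Proteinortho-like"), mutual coverage 0.5, and an alignment-significance
gate (e-value proxy at most 1e−6). The gate exists because at permissive
identity thresholds single linkage is otherwise bridged by chance short
local alignments between unrelated proteins (measured on random proteins:
proxies of 1e−3 and worse, versus 1e−7 and better for true 30%-identity
homologs). Multi-copy membership within one unit is allowed (paralogs are
not split), singletons are kept, and cluster ids derive from each cluster's
lexicographically smallest member so results are input-order invariant.

Backbone clusters are those present in at least 95% of the non-redundant
elements — the margin absorbs sporadic deletions, so with 20 elements a
single deletion (19/20 = 0.95) still counts. The single-copy subset is
flagged for concatenated-alignment export to external aligners. Accessory
(non-backbone) presence/absence feeds a neighbor-joining tree (ape::nj)
on Manhattan distances — the count of clusters differing between two
elements — which is exact on additive matrices.

Mobilome accounting assigns a cluster to the mobilome if *any* member locus
lies on an element (the conflict with chromosome-resident members is
logged), reports the mobilome fraction of all clusters, the ICE share of
the mobilome, the ICESym share of ICE clusters, and per-category shares
under the priority ICE > plasmid > IME > phage so shares sum to one.

ANI is fragment-based: non-overlapping 1020 bp fragments, each matched in
the other genome (either strand) by exact 16-mer seeding plus banded
global-local alignment; fragments below 80% identity or without seeds are
excluded, as in standard whole-genome ANI practice. The reported ANI
averages the two directional means and is symmetric by construction.
`max_fragments` subsamples fragments evenly for large genomes (the
five-genome benchmark uses 200 per direction). Genospecies are
single-linkage components at ANI ≥ 95, with 95.0 counting as the same
species. Simulated 3% divergence recovers ANI ≈ 97 because alignment
identity equals one minus the substitution rate when indels are absent.

Cargo–trait association is a per-cluster two-sided Fisher exact test with
Bonferroni correction over all tested clusters; a unit exclusion list is
supported (e.g. one of a duplicated element pair). The published workflow's
population-structure-aware pairwise comparisons are out of scope and this
is labelled plain Fisher + Bonferroni. Note that under the two-sided test
a perfectly separating 10 vs 10 table has p = 2/C(20,10): both
perfectly-separating tables are equally extreme.

# Recombination detection

For each ordered element pair, the per-position profile holds the longest
exact match starting at that query position anywhere in the subject or its
reverse complement (both strands are always indexed), computed by a suffix
automaton in C++ and identical to a naive scan. The query is tiled into
1000 bp windows; each window's mean match length receives a p-value under
a null in which the subject is an i.i.d. sequence of its own length and
composition. The default null is a seeded subject-shuffle permutation
(99 shuffles; p = (1 + exceedances)/(n+1)), which is exactly calibrated by
exchangeability — the measured false-positive window rate on unrelated
sequences is ≈ 0.03–0.04 at alpha 0.05. An analytic alternative
approximates per-position match lengths as independent draws from the
geometric-tail law P(L ≥ l) = 1 − (1 − q^l)^m with an effective sample size
of window/(mean+1); it is fast but approximate, and the permutation null is
the reference.

Windows with p < 0.05 merge into maximal segments. Because isolated
significant windows arise at the null rate by construction, a network
*edge* additionally requires at least one segment of two or more
consecutive significant windows; single-window segments remain visible in
the segment table. Edges are directed (query → subject) and weighted by the
additive homologous length and its fraction of the query, reproducing the
arrow-width convention of gene-flux figures. Backbone masking drops (or
restricts to) windows overlapping the backbone intervals, which collapses
backbone-driven connectivity to genuine cargo exchange. Chimaera painting
tiles a query into windows, assigns each the donor of highest local
identity (exact ties broken lexicographically and flagged), and reports
breakpoints where the best donor switches; planted 3 kb alternating blocks
are recovered within half a window.

# The simulator: what it does and does not emulate

`simulate_mobilome()` builds genomes bottom-up so the truth is exact by
construction: background i.i.d. sequence at 62% GC (rhizobial genomes);
shared background gene families mutated per genome; 16 integration-anchor
classes (13 tRNA isotypes plus guaA/radC/dusA); elements emplaced in the
integrated att arrangement with the conservative interleave for
tripartites; cargo genes as mutated copies of the bundled synthetic
exemplar panel, back-translated with random synonymous codons. Substitution
counts are exact (`round(d·(L−1))` non-initial sites), so identity targets
are analytic; indels are used only for pseudogenization (a 1 bp deletion
two-thirds through the gene, so the annotated CDS has a frameshift but
still covers more than 40% of the exemplar). The bases flanking each
planted core copy are set so the two copies' flanks differ, keeping maximal
repeat extension exactly at the planted core and boundary recovery
base-pair exact. Recombination events overwrite a segment of one element
with the homologous offsets of another and move the covered annotations.

The default benchmark scenario plants, across five ~2 Mb genomes: four
monopartite ICEs (one sized at the 65,889 bp lower end of the observed ICE
range; other elements are desk-scaled to tens of kilobases so the full
pipeline runs in a few minutes on one CPU, with the tripartite at
36/9/5 kb fragments), one tripartite symbiosis ICE, two IMEs (one with a
serine integrase), one conjugative and one mobilizable plasmid, one
repABC-without-att artifact region, two 5 kb recombination events, a traR1
remnant and a frameshifted traI2. The 17 planted backbone families are the
conserved transfer genes (the trb cluster, rlxS, rdfS, traF, traG, msi107,
msi110); conjugative plasmids carry them too, as their published
counterparts do.

The exemplar panel is synthetic (random proteins, not real gene sequences)
so no external databases are bundled; real panels or profile-HMM tables
plug in through `read_reference_panel()` / `classify_relaxases()`. One
consequence of the synthetic fixture is worth noting: the panel's RNG seed
is a large constant so that user-level simulation seeds (small integers)
can never replay the panel's random stream and accidentally regenerate
exemplar-like sequences.

What the simulator does **not** emulate — and what passing tests therefore
do not show about real data: phylogenetically structured divergence (every
copy mutates independently from one exemplar), codon bias and GC skew,
repeat-rich intergenic DNA (random background makes spurious ≥15 bp repeats
essentially absent, so real genomes may need longer `min_core` or the
mismatch budget), nested or tandem element insertions, partial assemblies,
and annotation errors. Results on real genomes depend on annotation quality
and a domain-appropriate reference panel.

# Numerical choices and degenerate inputs

* Window tails shorter than half a window merge into the previous window;
  a window longer than the query becomes a single whole-query window with a
  warning.
* Linear replicons truncate the att scan window with a warning; circular
  replicons are scanned without wraparound (elements spanning the origin
  are not modelled).
* Ties: best att pair by (core length, seeds, span, position); best hit by
  (bit score, exemplar id); chimaera donors lexicographically with a tie
  flag; cluster ids by smallest member.
* Unknown residues are kept as N/X with a warning; N never matches in the
  profile engine beyond literal N–N, and motif/ANI windows containing N are
  skipped.
* Empty inputs return empty tables, not errors; degenerate traits
  (single-class) and sub-10-fragment genomes for ANI are errors.

# Problem sizes used by the tests

The suite runs module oracles on small instances (proteins of 20–220
residues, replicons of 3–300 kb) and the acceptance checks on the full
benchmark (five ~2 Mb genomes), 200 splice round-trips, 50 profile-oracle
pairs, 200 null-calibration trials, all 7,812 non-degenerate 2×2 tables
with margins up to 12, and 60 kb ANI pairs — about five minutes in total on
one CPU, sizes chosen so every oracle is exhaustive at its scale.

# Known limitations

Gene prediction, assembly, multiple sequence alignment, maximum-likelihood
phylogenies, neighbor-nets and ClonalFrameML-style analyses are out of
scope; the package exports sequence sets, distance matrices and trees for
external tools. The e-value proxy is a ranking device, not a calibrated
significance; profile-HMM scoring is delegated to hmmscan via its table
output. Plasmid topology and class are taken from input metadata tags, not
inferred. The att scanner assumes direct repeats on the same strand;
inverted att arrangements are not modelled.
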