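---
title: "Surveying the oxidizable CaMKII residue pair: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Surveying the oxidizable CaMKII residue pair: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oxpair)
```

## The biological question

Ca^2+^/calmodulin-dependent protein kinase II (CaMKII) can be locked in an
active state by oxidation of a residue pair in its regulatory domain at
positions 281/282 (numbered on the CaMKII-gamma isoform): methionine-
methionine (MM) in the gamma, delta and beta isoforms, cysteine-methionine
(CM) in alpha. Oxidation of this pair by reactive oxygen species (ROS)
sustains kinase activity after the initial Ca^2+^/calmodulin trigger, making
the pair a concise molecular ROS sensor. Most invertebrate CaMKII instead
carries an oxidation-resistant pair (valine-valine in *Drosophila*). Whether
a CaMKII sequence carries an oxidizable pair is therefore a binary,
alignable character whose distribution over animal phylogeny dates the
origin of ROS-activated CaMKII, and whose conservation pattern speaks to the
selective forces maintaining it.

oxpair implements the computational side of such a survey: classify the
281/282 pair in any set of CaMKII-like protein sequences, aggregate
conservation by clade and species, reconstruct the character's history on a
user-supplied dated taxonomy, and verify knock-in edit designs that move a
genotype between the two character states. A sequence-evolution simulator
with a planted character history makes every stage testable offline.

## Reference-anchored numbering

Absolute residue numbers such as "M281" are only meaningful relative to a
reference isoform. Rather than building a multiple sequence alignment (whose
column coordinates depend on the full input set and on program defaults),
each query is **pairwise-anchored**: globally aligned to a short reference
frame carrying the landmark coordinates, so that every query position
inherits a reference number through the alignment. Pairwise anchoring is
deterministic, order-independent, and directly checkable against a
dynamic-programming oracle; the only alignment product consumed downstream
is the position map, which is exactly what it produces.

The default frame (`camkii_frame()`) is a reconstruction of the mouse
CaMKII-gamma regulatory-domain fragment,

```
QRSTVAS MM HRQETVDCLKKFNARRKLKGAILTTM
        ^^
offset 274; S280, pair 281/282, T287
```

with the coordinate offset calibrated by declaring the methionine pair to be
281/282 — this is the only calibration the numbering convention fixes, and
it places S280 on a serine (the O-GlcNAcylation site) and 287 on a threonine
(the autophosphorylation site), as required. The companion fly fragments in
`camkii_fragments()` are reconstructed from the published 176-nt HDR
template for the fly VV-to-MM knock-in: its reverse-complement (coding)
strand translates to `...RERVAS MM HRQETVDCLKKFNARRKLKGAILTTM`, and the
wild-type fragment restores VV at the pair. They are labelled as
reconstructions throughout.

### Alignment algorithm

`global_align()` is an end-to-end Needleman-Wunsch/Gotoh alignment with
affine gap penalties; end gaps are penalized. A gap of length $L$ costs
$g_o + L\,g_e$ (defaults $g_o = 11$, $g_e = 1$, BLOSUM62). The `X` row and
column of the substitution matrix are set to zero so unknown residues are
neutral: they neither attract nor repel the aligner, and any landmark that
lands on an `X` is classified *undetermined* rather than guessed. Traceback
ties are broken deterministically — substitution, then gap-in-query, then
gap-in-reference — so the position map is a pure function of its inputs.
The implementation is row-vectorized (the gap-in-query recursion within a
row is solved with a running cumulative maximum), which keeps a 300-residue
query against the 35-residue frame near a millisecond.

### Inclusion filter and the identity threshold

The survey's inclusion criterion ("recognizably CaMKII at the regulatory
domain") is operationalized by `coverage_filter()`: reference coverage
$\geq$ 0.80 and alignment identity $\geq$ 0.60 at the defaults. The
identity default deserves explanation, because 25-30% identity is the
customary "twilight zone" boundary for full-length protein alignments. That
heuristic is wrong for a 35-residue window: a global alignment against a
short reference is free to choose the best-matching stretch of a long
query, and uniformly random 300-mers reach a *median* identity of about
0.34 against this frame (maximum observed over 100 draws: 0.54). Genuine
regulatory-domain sequences sit at or above 0.85 (the fly fragment scores
0.88 against the mouse frame). The default of 0.60 therefore separates the
two populations with a wide margin on both sides; both thresholds remain
configurable per run, and every rejected record is reported with the
criterion it failed.

## Character classification

`classify_pair()` calls the pair **oxidizable** when both residues are
redox-labile (methionine or cysteine), covering the canonical MM and CM
motifs; the rarer MC and CC combinations are also flagged oxidizable but
keep their verbatim motif so they can be tallied separately. A pair with a
gap or `X` at either position is **undetermined**; everything else is
**non-oxidizable**. Undetermined records are excluded from percentage
denominators and reported as a separate count — silently counting them as
negatives would bias prevalence downward, and excluding them is visible in
the output. The auxiliary sites follow the same logic: position 280 is
O-GlcNAc-capable if serine; 287 is phosphorylation-capable if threonine or
serine.

Percentages are rounded half-up to two decimals in reports (matching the
print precision of survey percentages in this literature); counts are
always carried alongside so full precision is recoverable.

## Ancestral-state reconstruction

`fitch_history()` reconstructs the binary presence/absence character by
parsimony. The downpass is Hartigan's generalization of Fitch, which is
exact on multifurcating nodes — taxonomy-shaped guide trees are routinely
non-binary, and collapsing polytomies arbitrarily would manufacture false
resolution. Tips with unknown state (`?`) contribute the full state set
`{0, 1}` and are assigned their parent's resolved state in the output.

The top-down resolution takes the parent's state wherever the downpass set
allows it, and resolves an ambiguous root to 0 (absence). This is a
Dollo-flavored choice: it never invents an ancestral presence and pushes
gains as tipward as parsimony allows, which is the conservative reading
when the derived state is a rare innovation. Nodes whose downpass set was
ambiguous are reported (`ambiguous_nodes`), so equally parsimonious
placements are visible rather than silently resolved. The guide tree is an
input: the package maps states onto an accepted taxonomy and does not
estimate phylogeny from the sequences, and no probabilistic (likelihood or
Bayesian) reconstruction is attempted — with essentially fixed states
within vertebrates and very sparse gains outside, a parsimony statement is
what the data support.

`date_gains()` brackets each gain by the ages of its branch's endpoints:
node ages are inputs (branch lengths of a chronogram, or an explicit
node-age table), never estimated. `bracket_infer()` grades ancestral
inference for a focal node by the extant phylogenetic bracket: level I when
at least two child lineages contain the trait, II when one does, III when
none does.

## The synthetic-data generator

Two generators provide ground truth. `simulate_clade()` evolves a root
sequence down a tree with independent per-site substitutions, uniform over
the 19 alternative residues; the probability compounds over branch length
as $1-(1-p)^{\ell}$. The landmark pair is held at VV on state-0 lineages
and switches to MM (or CM) on and below a designated gain branch; a halo of
three positions around every landmark never mutates, mimicking the strong
local conservation of the motif context. Species can contribute several
copies, which diversify independently along the terminal branch — a
deliberately simple stand-in for paralogy. `make_benchmark()` builds a
two-group prevalence benchmark whose defaults are the survey conditions
this package models: 300 vertebrate-like and 150 invertebrate-like
sequences with per-sequence carrier probabilities 0.9794 and 0.0223, species
assembled from 1-3 copies.

The generator is intentionally not an empirical model of protein evolution:
no substitution-rate matrix (WAG/LG), no indels, no rate heterogeneity, no
codon structure. What passing tests demonstrate is that the pipeline's
logic — anchoring, classification, aggregation, reconstruction — is
correct when its assumptions hold, and that recovery degrades gracefully
under point-substitution noise. They do not demonstrate robustness to
alignment-breaking indels, compositional bias, or annotation errors in real
survey data.

Seeds are mandatory arguments everywhere; regenerating with the same seed
reproduces byte-identical FASTA output, and there is no hidden global
randomness (`withr::with_seed` isolates the generator state).

## Edit-design verification

`verify_hdr_design()` checks a CRISPR HDR knock-in design the way a bench
scientist genotypes one: translate the declared coding strand of the
single-stranded template in the declared frame and look for the expected
post-edit residue pair, and scan both strands for the diagnostic
restriction motif (palindromic sites counted once per locus). Because the
reading frame of a genomic oligo is rarely stated, the report also lists
every frame in which the expected pair occurs. Printed-strand site
coordinates necessarily flip when the template is reported on the other
strand, so the report carries coding-strand coordinates as the
strand-invariant quantity. The published fly reagents (`ssodn_1r()`,
`crispr_guide_1()`) ship as worked-example inputs: the 176-nt template
contains a single NsiI site (ATGCAT) starting at printed position 78, and
its coding strand encodes the MM pair.

## Numerical and degenerate-input choices

* Alignment scores are compared exactly (integer matrices and penalties);
  the traceback recomputes cell decisions with the same arithmetic, so no
  tolerance is needed.
* A group whose records are all undetermined reports `NA` percentages
  rather than 0 or 100; contrasts propagate the `NA`.
* Zero-length branches give degenerate (point) age intervals.
* An ambiguity-free invariant: every input record appears exactly once in
  the classification table or the rejected list.
* Percent rounding is half-up (`floor(x*100 + 0.5)/100`), not banker's.

## Problem sizes in the shipped checks

The test-suite and the acceptance script exercise: 500 random string pairs
(lengths 2-12) against an independently written affine-gap recursion, plus
exhaustive alignment enumeration on tiny strings to validate that oracle
itself; every rooted binary tree with 4-6 tips under every tip-state
assignment (64,080 cases) and 200 random trees of up to 8 tips against a
brute-force labeling enumeration; 20 planted-gain recoveries on 50-tip
clades at substitution probabilities 0 and 0.02; and 30 replicates of the
300/150 prevalence benchmark. These sizes keep the full run in a few
minutes on one core while leaving the statistical margins wide (the
benchmark's standard error of the mean prevalence is about 0.15 percentage
points over 30 replicates).

## Known limitations

* The reference frame is a reconstruction calibrated from the pair
  position, not a verbatim published figure; users with a preferred
  reference fragment should construct their own `reference_frame()`.
* Pairwise anchoring to a 35-residue frame cannot detect domain
  architecture (kinase or association domains); the identity/coverage
  filter is a proxy, and profile-HMM domain calling is out of scope.
* Parsimony reconstruction reports one most-parsimonious labeling (with
  ambiguous nodes flagged), not the full MPR set enumeration.
* The species key is the verbatim species string (case-normalized by the
  caller if needed); no taxonomic-identifier resolution is attempted.
* No remote data retrieval: accession sets, sequences and trees are
  resolved by the user.

## A minimal end-to-end run

```{r example}
frags <- camkii_fragments()[1:2, ]
scr <- screen_dataset(frags)
tidy(scr)[, c("accession", "motif", "state", "site280", "site287")]

summarize_clades(tidy(scr))
```

```{r ancestry}
tree <- read_guide_tree(system.file("extdata", "demo_taxonomy.nwk",
                                    package = "oxpair"))
states <- c(Homo_sapiens = 1, Danio_rerio = 1, Petromyzon_marinus = 1,
            Ciona_intestinalis = 0, Strongylocentrotus_purpuratus = 0,
            Drosophila_melanogaster = 0, Caenorhabditis_elegans = 0,
            Nematostella_vectensis = 0)
h <- fitch_history(tree, states)
h
date_gains(h)
```

The single reconstructed gain sits on the vertebrate stem branch, bracketed
by the demonstration tree's calibrations at 615-676 million years ago.
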