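# oxpair

Phylogenomic survey of the oxidizable CaMKII regulatory residue pair.

CaMKII (Ca²⁺/calmodulin-dependent protein kinase II) can be trapped in an
active state when a residue pair at regulatory-domain positions **281/282**
(CaMKIIγ numbering) is oxidized by reactive oxygen species: Met-Met (MM) in
the γ/δ/β isoforms, Cys-Met (CM) in α. Most invertebrate CaMKII carries an
oxidation-resistant pair instead (Val-Val in *Drosophila*). Presence or
absence of an oxidizable pair is a binary character on animal phylogeny;
its distribution dates the origin of ROS-activated CaMKII and measures how
strongly the character is conserved.

oxpair is for molecular evolution researchers who want to run or audit such
a survey. It provides:

* **Reference-anchored classification** — each protein is globally aligned
  (Needleman–Wunsch/Gotoh, affine gaps, BLOSUM62, end gaps penalized) to a
  regulatory-domain reference frame so its residues inherit CaMKIIγ
  numbering; the 281/282 pair is then classified *oxidizable* (both
  residues ∈ {M, C}), *non-oxidizable*, or *undetermined* (gap/X), along
  with the PTM sites S280 (O-GlcNAc) and T287 (autophosphorylation).
* **Conservation statistics** — per-clade and per-species tallies, where a
  species counts as positive if at least one of its CaMKII copies carries
  the pair; undetermined records are excluded from denominators and
  reported separately.
* **Ancestral reconstruction** — Fitch/Hartigan parsimony of the binary
  character on a rooted, optionally dated guide tree (polytomies handled
  exactly), gain/loss branches, gain-age intervals from input node ages,
  and extant-phylogenetic-bracket inference levels (I/II/III).
* **Edit-design verification** — does a CRISPR HDR template introduce the
  intended pair, in which frames, and does it carry the diagnostic
  restriction site? The published fly VV→MM reagents ship as a worked
  example.
* **Synthetic data with ground truth** — sequence evolution on a tree with
  a planted gain branch, and a two-group prevalence benchmark, so the whole
  pipeline is testable without downloads.

Tabular results are tibbles; fitted objects have `tidy()`, `glance()` and
`autoplot()` methods.

## Worked example

Classify the mouse CaMKIIγ and wild-type fly regulatory-domain fragments,
then reconstruct the character's origin on a dated demonstration taxonomy:

```r
library(oxpair)

scr <- screen_dataset(camkii_fragments()[1:2, ])
tidy(scr)[, c("accession", "species", "motif", "state")]
#> # A tibble: 2 × 4
#>   accession         species                 motif state
#> 1 CAMK2G_MOUSE_FRAG Mus musculus            MM    oxidizable
#> 2 CAMKII_DROME_FRAG Drosophila melanogaster VV    non_oxidizable
```

The mouse fragment carries the oxidizable MM pair at anchored positions
281/282; the fly carries VV — and both retain S280 and T287
(`site280 = glcnac_capable`, `site287 = phospho_capable`). Mapping
presence/absence onto a dated tree:

```r
tree <- read_guide_tree(system.file("extdata", "demo_taxonomy.nwk",
                                    package = "oxpair"))
states <- c(Homo_sapiens = 1, Danio_rerio = 1, Petromyzon_marinus = 1,
            Ciona_intestinalis = 0, Strongylocentrotus_purpuratus = 0,
            Drosophila_melanogaster = 0, Caenorhabditis_elegans = 0,
            Nematostella_vectensis = 0)
h <- fitch_history(tree, states)
h
#> <character_history> 8 tips, min changes 1 (1 gain(s), 0 loss(es))
#>   gains on: Olfactores->Vertebrata
date_gains(h)
#> # A tibble: 1 × 4
#>   parent_label child_label age_older age_younger
#> 1 Olfactores   Vertebrata        676         615
```

A single gain on the vertebrate stem branch, bracketed at 615–676 million
years ago by the tree's input calibrations. Checking the published fly
knock-in template:

```r
verify_hdr_design(edit_design(crispr_guide_1(), ssodn_1r(),
                              codon_strand = "reverse"))
#> <hdr_report>
#>   introduces expected pair: TRUE (codon 31)
#>   coding strand: reverse; frames with pair: 0
#>   diagnostic sites (printed strand): 78
```

The 176-nt template encodes the MM pair on its coding strand and carries
exactly one NsiI site (ATGCAT, printed position 78) for genotyping by
restriction digest.

For a complete run over your own files (FASTA + taxonomy TSV + Newick),
`run_survey(run_config(...))` writes a report bundle — classification TSV,
clade summary, gains table, state-annotated Newick and a JSON summary — and
`inst/scripts/survey.R` wraps it for the shell. The methods vignette
(`vignettes/oxpair-methods.Rmd`) documents the model, parameter choices and
limitations.

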