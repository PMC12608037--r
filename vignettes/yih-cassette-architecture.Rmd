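---
title: "Detecting and comparing yih sulfoquinovose-catabolism cassettes"
author: "yihscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and comparing yih sulfoquinovose-catabolism cassettes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(yihscan)
```

## The problem

*Escherichia coli* can use sulfoquinovose (SQ), the sulfonated sugar head
group of the plant sulfolipid SQDG, as a carbon source via the sulfo-EMP
pathway. The pathway is encoded by a cluster of up to ten genes — the *yih*
cassette (*ompL*, *yihO*–*yihW*) — that occurs in two architectures across
*E. coli* and *Shigella* strains: a **long** form carrying all ten families
and a **short** form reduced to *yihTUVW*, sitting at the same chromosomal
locus but in reversed orientation. Across a strain panel one wants to know,
for every genome: does it carry the cassette, in which variant, where
relative to conserved marker genes, and in which orientation? And across the
panel: is the short variant associated with pathogenicity, and are the two
variants phylogenetically clustered or interspersed?

`yihscan` implements that screen end to end, plus a synthetic strain-panel
generator with complete ground-truth bookkeeping so every stage can be
tested without downloading genomes.

## The procedure

1. **Homology search** (`find_family_hits`). Each annotated protein is
   aligned locally (Smith–Waterman, affine gaps, BLOSUM62, gap open 11 /
   extend 1) against the ten family queries. A gene becomes a hit when
   identity ≥ 40% and query coverage ≥ 70%, and is assigned to its single
   best family by score. The identity threshold sits just above the 37%
   ceiling observed for SQ-enzyme look-alikes that do *not* form cassettes,
   so borderline paralogs are excluded by construction; both thresholds are
   arguments. Externally computed hit tables in BLAST tabular layout can be
   imported with `read_blast_tab()` to bypass the internal aligner; no
   claim of bit-compatibility with any particular search engine is made.
2. **Co-localization clustering** (`cluster_colocalized`). Two hits on the
   same contig are co-localized when the distance between their gene
   midpoints is *strictly less than* 5000 bp; clusters are the
   single-linkage closure of that relation. Single linkage is the weakest
   closure consistent with the pairwise rule and matches contiguous operon
   structure; complete linkage is available (`linkage = "complete"`) for
   sensitivity analysis. Distances are circular-aware.
3. **Variant classification** (`classify_variant`). LONG iff all ten
   families are present, SHORT iff the set is exactly
   {*yihT*, *yihU*, *yihV*, *yihW*}, PARTIAL for any other non-empty set,
   NONE for strains without a cluster. PARTIAL is reported, never coerced:
   the published dichotomy covers only LONG/SHORT, and downstream
   association analysis excludes PARTIAL/NONE strains explicitly.
4. **Span and synteny anchoring** (`cassette_span`, `flanking_uogs`). The
   span runs from the first member's start to the last member's end. The
   nearest universal single-copy orthologous group (UOG) genes strictly
   up- and downstream of the span anchor the locus; in the canonical
   configuration these are UOG217 and UOG236.
5. **Orientation and inversion** (`call_orientation`). Members are read
   along ascending coordinates; `forward` requires the reference family
   order (restricted to present families) with majority `+` strand,
   `reverse` the reversed order with majority `-`, anything else is
   `mixed`. The long configuration anchored by its upstream flank defines
   "forward", which operationalizes the observed reversal of the short
   variant; if the flank pair itself is swapped relative to the reference,
   the inversion call flips accordingly.
6. **Association** (`associate`). The 2×2 table (short/long ×
   pathogenic/non-pathogenic) is summarized by the sample odds ratio, with
   the Haldane–Anscombe +0.5 correction when a cell is zero, and Fisher's
   exact test computed from first principles.
7. **Phylogenetic mapping** (`fitch_transitions`, `interspersion_test`,
   `phylogroup_summary`, `export_itol`). The minimum number of LONG↔SHORT
   changes on the strain tree (Fitch small parsimony; exact on
   multifurcations via the intersection/union generalization) quantifies
   interspersion, which the published analysis asserts only qualitatively.
   The count is compared with a permutation null of shuffled tip states;
   the reported percentile is the add-one estimate of
   P(null count ≤ observed). PARTIAL/NONE tips are pruned first rather
   than treated as extra states, because the claim concerns the two
   cassette types.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `max_gap` | 5000 | bp | strict midpoint co-localization threshold |
| `min_identity` | 40 | % | just above the 37% non-cassette ceiling |
| `min_coverage` | 70 | % of query | rejects fragment matches |
| gap open / extend | 11 / 1 | score units | BLOSUM62 community default |
| `linkage` | single | — | weakest closure of the pairwise rule |
| `alternative` | two.sided | — | sidedness of the exact test |
| `n_perm` | 1000 | — | permutation-null resolution |

## Numerical choices

* **Alignment tie-breaking.** Among co-optimal local alignments the DP
  optimizes lexicographically: score, then number of identical pairs, then
  fewest columns. Identity (matches / alignment columns) is therefore
  well-defined, deterministic, and symmetric under swapping the sequences —
  without this rule, "the" identity of an alignment with score ties depends
  on traceback order. Gap states open from the match state only, which is
  score-lossless for BLOSUM62 with 11/1 because adjacent insertion/deletion
  columns always lose to a substitution column.
* **Exact test.** Point probabilities are computed with `lchoose` in log
  space, so tables with totals of 10,000+ stay exact to double precision.
  A table counts as "at least as extreme" when its point probability is
  ≤ observed × (1 + 1e−7); the relative tolerance guards floating-point
  ties in the two-sided sum. Degenerate margins give p = 1 with a flag.
* **Strict thresholds.** "Less than 5000 bp" is implemented by cutting the
  single-linkage dendrogram at 5000 − 1e−6; midpoint distances are
  multiples of 0.5, so the epsilon can never cross a real merge height.
* **Circular contigs.** Origin-spanning genes are represented with
  end < start and unwrapped internally; midpoints reduce modulo the contig
  length into (0, length]. A cluster whose locus crosses the origin
  (detected as the complement of the largest inter-member gap on the
  circle) is reported on unwrapped coordinates with an `origin_spanning`
  flag, since the original screen's circular handling is not documented —
  the flag makes the choice visible in output.
* **Best-hit ties.** Family assignment breaks score ties by identity then
  family id; reciprocal-best-hit pairing instead *disqualifies* genes whose
  best hit is tied exactly (score and identity), since a tied best hit is
  not a unique ortholog candidate.

## The synthetic panel: what it emulates and what it does not

`simulate_panel()` generates, per strain: a single circular chromosome with
an identical UOG backbone (default 238 markers, 90-residue proteins,
200 bp intergenic gaps), a cassette locus strictly between two designated
flanking UOGs (labeled UOG217/UOG236 when the backbone is large enough),
and protein sequences derived from fixed reference queries by i.i.d.
per-site substitution (uniform over the other 19 residues, no indels by
default). The cassette state evolves along a Yule tree from a LONG root by
a per-branch Markov process (switch probability 0.05 by default — a
placeholder, as the real switch rate is unknown — and optional loss).
Short cassettes are written in reversed gene order on the minus strand.
Pathotype is sampled conditionally on cassette state with conditional
probabilities that split a target odds ratio (default 2.67) symmetrically
around a baseline pathogenic fraction (default 0.5) on the odds scale;
conditioning on state rather than phylogeny makes the association module's
target well-defined. Phylogroups are the k = 8 deepest clades.

Deliberate departures from realism, and their consequences:

* Reference and backbone proteins are random sequences of ~85–150 residues
  (real bacterial proteins average ~300). This scales the full-pipeline
  tests to the stated CPU budgets; it does not change identities,
  thresholds, or any biological default. A green structural-recovery test
  establishes that the *logic* of detection, anchoring and inversion
  calling is correct, not that the thresholds are well-calibrated for real
  proteomes.
* No indels, no domain structure, no paralogs outside the planted locus:
  the generator cannot probe chaining errors caused by tandem paralogs or
  alignment breakdown under indel-rich divergence.
* Pathotype has no phylogenetic confounding by default, so OR-recovery
  tests measure estimator behaviour under the model's own assumptions,
  not robustness to lineage effects.
* `founder_clade_short = TRUE` forces exactly one switch on the branch to
  the larger root-child clade. This realizes the "perfect clade structure"
  limit (transition count exactly 1): with a switch probability of
  literally zero and no forced event, every tip would inherit the root
  state and the count would be 0 with the statistic undefined in spirit.

One scaling decision in the acceptance suite: the odds-ratio recovery check
(20 panels of 413 strains) estimates the OR from the generated variant
calls via `build_contingency()` + `odds_ratio()` rather than re-running the
alignment pipeline twenty times. At zero divergence the detection step is
proven exact by the structural-recovery criterion, so the estimator
measured is identical and the check fits its runtime budget.

## Known limitations

* No phylogenetic correction for strain non-independence in the
  association test (the original analysis applied none either); the
  interspersion statistic is reported alongside precisely because
  relatedness can confound the 2×2 test.
* No profile/HMM search, no E-values, no pseudogene calling, no detection
  of novel non-query cassettes, no breakpoint-resolution inversion mapping.
* The GenBank reader covers the minimal flat-file subset the pipeline
  needs (single-interval CDS features with locus_tag/product/translation);
  compound `join()` locations are rejected rather than mis-parsed.
* Tree inference is out of scope: the strain phylogeny is an input.

## A small worked example

```{r example}
cfg <- synthetic_panel_config(n_strains = 12, seed = 42, n_uogs = 12,
                              divergence = 0.05, switch_prob = 0.2)
panel <- simulate_panel(cfg)
res <- detect_panel(panel)
table(res$variants)

assoc <- associate(res$variants,
                   setNames(panel$metadata$pathotype,
                            panel$metadata$strain_id))
assoc

fitch_transitions(panel$tree, res$variants)
```
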