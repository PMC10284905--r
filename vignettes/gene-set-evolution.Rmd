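---
title: "Reconstructing gene-set gain and loss histories with gleam"
author: "gleam authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing gene-set gain and loss histories with gleam}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gleam)
```

# The problem

Trait modules such as flagellar motility or peptidoglycan biosynthesis are
encoded by tens of genes that are gained and lost together only
approximately: individual members flicker in and out of genomes through
deletion, annotation failure, and assembly incompleteness, especially in
metagenome-assembled genomes (MAGs). Asking "where on the phylogeny was
this *trait* gained or lost?" therefore needs three layers:

1. a per-gene ancestral character state reconstruction (ACR) on the genome
   tree,
2. a rule lifting per-gene states to a set-level present / partial /
   absent call at every node, and
3. an event caller that places gains and losses on branches only where the
   individual gene reconstructions *agree*.

`gleam` implements exactly this stack, plus the genomic-architecture
(synteny) summary and a simulator that generates data with known truth so
every stage can be validated end to end.

# Data model

* **Tree** — a rooted `ape::phylo`. Rooting is required and never
  inferred: ancestral reconstruction is root-dependent, and a basal
  polytomy (the unrooted newick convention) is rejected rather than
  silently resolved. Internal node labels are treated as *names* by
  default; interpreting numeric labels as support values is opt-in
  (`supportValues = TRUE`), because clade-identifier labels that happen to
  be numeric would otherwise be destroyed. Trees without branch lengths
  are first-class "cladograms": Fitch parsimony runs on them natively,
  while Mk-model code refuses them unless a unit-branch-length
  substitution is explicitly requested (`unitLengths = TRUE`) — a
  deliberate speed bump, since rates per "branch" of a cladogram are not
  rates per unit time.
* **TraitMatrix** — genome × gene copy counts with an explicit missing
  state (`?` on disk, `NA` in memory), stored as a
  `SummarizedExperiment`. All analysis uses the binarized view
  (count ≥ 1). Missing means *unknowable* (incomplete assembly), not
  absent; it is excluded from denominators and never imputed. The paper's
  source-data setting restricts genomes to high completeness, but the
  package degrades gracefully when completeness varies.
* **GeneSetCatalog** — named sets with member roles
  (core / regulatory / intermittent) and the two classification
  thresholds.

# Per-gene reconstruction

## Fitch parsimony (default)

The default method is parsimony because the canonical substrate for this
analysis is a cladogram, and because consensus event calling is defined
over discrete per-gene predictions. The bottom-up pass generalizes
intersection/union to polytomies: each node keeps the states carried by
the maximal number of child state sets and adds (number of children whose
sets miss that state) to the score; for binary nodes this is exactly
Fitch's rule. Missing tips carry the uninformative set {0,1}.

The top-down resolution is change-delaying: an ambiguous node adopts its
parent's resolved state whenever that state is in its own set, so changes
are pushed tipward and no change is invented near the root. A root tie is
broken by the majority observed tip state; an exact tie stays
`ambiguous`, which downstream weighs as 0.5 presence. Tips observed as
missing are reported `unknown` — reconstruction never overwrites
observation.

Correctness is checked against an independent exhaustive oracle
(`enumFitchScore`, direct enumeration of all internal labelings) on 200
random trees of up to 7 tips, and against `phangorn`'s Fitch
implementation on binary complete-data cases.

## Two-state Mk maximum likelihood

The alternative models each gene as a continuous-time two-state Markov
chain with gain rate $\alpha$ and loss rate $\beta$ per unit branch
length; transition probabilities have the standard closed form, the
likelihood is computed by Felsenstein pruning (vectorized across genes,
with per-node rescaling against underflow), and node posteriors come from
the up–down algorithm, so each node's posterior integrates over all other
nodes. Tip posteriors are degenerate on observed states; observed-missing
tips get a genuine posterior but remain tagged `unknown` for set-level
fractions.

Rates are fitted by maximizing the log-likelihood summed over the genes of
a set ("pooled"): single-gene phyletic patterns rarely identify two rates,
while a 25-gene module shares its retention regime. The optimizer is a
derivative-free Nelder–Mead simplex on $(\log\alpha, \log\beta)$ from two
fixed starting points — symmetric $(0.5, 0.5)$ and loss-biased
$(0.1, 1.0)$ — keeping the better optimum; bounds are $[10^{-6}, 10^3]$
and relative tolerance $10^{-8}$, so the fit is deterministic. All-constant
data legitimately drive a rate to the lower bound; this is flagged
(`boundary` slot, warning), not hidden.

Root prior default is the stationary distribution
$(\beta, \alpha)/(\alpha+\beta)$ — the standard Mk convention — with
`flat` available; which one the original analyses of this kind used is
generally unstated, so the choice is explicit, echoed in `summary.json`,
and easy to flip.

Numerical validation: pruning equals brute-force enumeration within
$10^{-10}$ relative error on 100 random ≤ 6-tip trees with rates in
$[0.05, 2]$; posteriors sum to 1 within $10^{-12}$ at every node;
transition matrices are row-stochastic and satisfy the semigroup property
$P(t+s) = P(t)P(s)$.

# Set states and consensus events

The presence fraction of a set at a node counts resolved-present genes
plus 0.5 per ambiguous gene, over all members except tip-missing ones —
the exact analogue of the observed-genome rule, where `?` cells leave the
denominator. Classification uses `present` ⇔ fraction ≥ 0.9 and `absent`
⇔ fraction ≤ 0.1. The 0.9 bound encodes the field's ">90% of members"
core-set rule as a closed threshold; for realistic set sizes (25 genes:
23/25 = 0.92, 22/25 = 0.88) no attainable fraction distinguishes the two
readings. The absent bound is chosen symmetric; "partial" has no standard
numeric definition, so both are configurable and echoed in output.

Events live on branches: wherever the parent and child classifications
differ, the mapping present→absent: `loss`, present→partial:
`partial_loss`, partial→absent: `loss` (the set *completes* its
disappearance; configurable to `partial_loss`), absent→present: `gain`,
absent→partial: `partial_gain`, partial→present: `gain` applies. Branches
touching `unknown` states yield no call but are logged. The consensus
rule quantifies "individual gene predictions agree" as an agreement
fraction: among member genes resolved 0/1 at both branch ends, the share
whose own state change matches the event direction. Ambiguous genes are
excluded from both numerator and denominator — ambiguity should neither
support nor veto a call. The default threshold θ = 0.9 mirrors the
core-set rule (unanimity is one flag away, θ = 1); since the consensus
criterion of the analyses this mirrors is not quantified anywhere we know
of, θ is a documented choice, recorded in every output. Raising θ can
only remove calls — a property tested over seeded simulations. Events are
reported as parent → child id pairs, so readings that attribute the event
to the child node are equally served.

# Synteny clusters

Clusters are runs of set genes on one contig whose intergenic gaps
(end-to-start distance minus one) stay within `maxGap`; overlapping genes
always co-cluster, singletons are kept and flagged, and foreign genes
nested inside a cluster's span are counted as insertions rather than
splitting it — distance, not annotation context, is the only splitting
criterion, because no published distance threshold exists for these
operon-scale clusters. The 10 kb default is comfortably above intra-operon
spacing and below the 50 kb-plus separations of distinct clusters in the
fixture. Architecture comparison first puts each cluster into a canonical
orientation — reversed if most members lie on the minus strand (a
reverse-complemented cluster equals its forward twin), with a
deterministic lexicographic tie-break when strands are uninformative —
and then scores the fraction of ordered adjacent gene pairs of one
cluster found, in order, in the other. Orientation is normalized globally
per cluster rather than per pair: locally flipping a single adjacency
(e.g. `fliC,fliD,fliS` vs `fliC,fliS,fliD`) is a genuine rearrangement
and scores 0.

# The synthetic-data generator

The generator defines the study conditions for all validation:

* **Trees**: Yule pure-birth, exponential waiting times, uniformly chosen
  splitting lineage, rescaled to mean root-to-tip height 1 so rates read
  "per tree height". Determinism comes from R's Mersenne-Twister RNG
  under an explicit seed; tip labels and node numbering are fixed by
  construction.
* **Gene histories**: independent two-state Markov evolution per gene
  down the tree; root states stationary or fixed. Forced losses are
  absorbing (no re-gain below the forced branch) to create unambiguous
  truth; spontaneous transitions elsewhere remain possible and are
  recorded. Missingness is applied at tips only, after truth is recorded:
  incompleteness affects observed genomes, not history.
* **The headline fixture** (`makePaperFixture`): a 25-leaf order-level
  cladogram — a basal caterpillar of orders 1–9 and a balanced derived
  clade of orders 10–25 — carrying a 25-gene flagellar-style set and a
  14-gene peptidoglycan-style set, both present throughout the basal
  grade and fully absent in the derived clade, so the truth is exactly
  one full loss per set on the branch into the derived clade's MRCA.
  Tip noise is capped at one absent gene per basal genome (≤ 4% of a
  25-gene set, keeping every genome ≥ 0.96, safely `present`) and drawn
  from the intermittently-present members `fliE`/`fliM` so the
  filament cluster (`fliC`,`fliD`,`fliS`) stays intact for the synteny
  check; one genome carries a foreign insertion in that cluster and a
  second `fliC` copy, exercising the insertion counter and binarization.
  Fixture missingness defaults to 0 — it emulates a completeness-filtered
  genome panel; a missingness argument exists for robustness studies.
  Optional `partialLossOrders` adds heavier (40%) basal losses for
  experiments beyond the headline scenario.

What the simulator does *not* emulate: correlated loss across genes
(each gene evolves independently outside forced events), rate variation
across lineages or genes, horizontal transfer, and annotation false
positives. Passing the validation suite therefore demonstrates the
correctness of the algorithms under the stated model, not robustness to
every process shaping real phyletic patterns.

## Chosen study scales

The validation suite (and `scripts/acceptance.R`) uses problem sizes
chosen so each check is exhaustive or statistically comfortable while the
whole suite stays desk-scale: 200 random ≤ 7-tip trees for the parsimony
oracle and 100 ≤ 6-tip trees for the likelihood oracle (small enough for
full enumeration); a 64-tip, 500-gene simulation at $\alpha = 0.1,
\beta = 0.5$ for rate recovery, which pilots place within a few percent
of truth (tolerance 25%); and 100 replicates of a 32-tip, 25-gene forced
clade-loss scenario with background rates $\alpha = \beta = 0.01$ per
unit height for event recovery. The background rate was fixed from the
stationary argument that the expected number of spontaneous flips per
replicate is roughly `nGenes × total tree length × rate` ≈ 0.4, making a
spontaneous *set-level* transition (≥ 3 concurrent gene changes at one
node) rare, so truth almost always contains exactly the forced loss; the
target branch is the internal clade whose size is closest to 8 tips,
chosen deterministically per replicate.

# Degenerate inputs and numerical choices

* Zero-length branches are legal; data impossible under them return
  log-likelihood $-\infty$ with an `impossible` flag rather than an
  error.
* Likelihood scaling is per-node, per-gene (division by the row maximum,
  log accumulated), so 500-gene pruning stays in double range.
* Posterior ties (|p1 − p0| ≤ 10⁻⁹) resolve to `ambiguous`, mirroring the
  parsimony vocabulary.
* All-missing genes, all-missing tips, empty gene sets, unbalanced
  newick, duplicate ids, negative counts, end < start coordinates and
  unknown strands are rejected with messages naming the offender.
* Every pipeline default, including ones the user never touched, is
  echoed in `summary.json`; dropped off-tree genomes are warned about and
  logged, missing tree tips are an error naming the tips.

# Known limitations

Binary characters only (no multi-state or covarion models); no stochastic
character mapping or joint ML reconstruction; no dating of events; no
correlated-evolution test between sets; cluster-level event calling is
available only by supplying clusters as pseudo-genes. The CLI is a thin
wrapper over the documented functions; programmatic use is the primary
interface.
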