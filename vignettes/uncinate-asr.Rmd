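---
title: "Reconstructing uncinate-process evolution on a fossil supertree: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing uncinate-process evolution on a fossil supertree: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(paleoasr)
```

## Scope

`paleoasr` infers the evolutionary history of a single three-state
osteological character — uncinate processes on vertebral ribs, coded as
0 = absent, 1 = cartilaginous, 2 = ossified — across an archosaur
phylogeny assembled from published trees and dated from stratigraphy.
This vignette is the package's own account of the science inside each
stage: the models, the defaults and why they were chosen, what the
synthetic-data generator does and does not emulate, and where the
inferences should not be over-read.

## Supertree assembly by landmark grafting

Composite "informal" cladograms are common in comparative paleobiology:
no single published analysis spans all taxa of interest, so source trees
are grafted onto a backbone. The rule implemented by `graft()` is
deliberately minimal and auditable:

* the caller names one *landmark* taxon shared by backbone and source;
* the smallest source clade containing the landmark plus all
  source-only taxa replaces the landmark tip, in place;
* the backbone topology restricted to its own taxa is always preserved
  (this is asserted by a property test over random backbones).

If the grafted source clade contains *other* taxa shared with the
backbone, their source placement conflicts with their backbone placement.
Because an informal supertree has no principled conflict-resolution
criterion, the package logs a topology-conflict warning, keeps the
backbone position, and prunes the duplicates from the grafted subtree.
Grafting order can matter when sources overlap, so the order is an
explicit, user-supplied part of the study configuration
(`read_study_config()`), not something the package chooses silently.
Internal node labels in Newick input are read but ignored; clades are
addressed only as the most recent common ancestor of named tip sets
(`mrca_node()`), which is robust to unlabeled consensus nodes. All trees
are treated as rooted, with the outermost Newick node as the root:
ancestral state reconstruction is meaningless on unrooted trees, and the
study design fixes the root via an outgroup.

## Timescaling from stratigraphic ranges

Branch lengths come from first and last appearance data (FAD/LAD, in Ma).
`assign_node_ages()` implements the basic paleontological dating rule:
each tip takes an age given by the tip-age policy, and each internal node
is as old as the oldest FAD among its descendant tips — a node cannot
postdate the first appearance of a lineage it subtends. Three decisions
here were genuinely open and are therefore configuration, with the
defaults reported in every output:

* **Tip-age policy** (default FAD): fossil taxa known from single
  horizons are conventionally terminated at first appearance; LAD and
  range midpoint are available for sensitivity analyses.
* **Minimum branch length** `mbl` (default 1 Myr): max-FAD dating
  produces zero-length branches wherever a tip's FAD equals its clade's
  age, and zero branches make the Mk likelihood degenerate.
  `apply_branch_lengths()` repairs them by shifting ancestors rootward by
  the *minimum* amount restoring all floors (postorder propagation; a
  brute-force perturbation test confirms minimality). Tip ages are never
  moved.
* **Extant taxa** are ordinary ranges with LAD = 0.

The trees are *not* forced ultrametric — fossil tips end at their own
ages — and the "without branch length estimates" arm of the study design
is implemented literally as `unit_branch_lengths()`: every branch set to
1, which is the conventional reading of excluding branch lengths from
ASR.

## From specimens to character states

The observational basis is a specimen-evidence table: per taxon, how many
dorsal or posterior-cervical vertebral ribs were examined, how many bear
uncinate scars, and whether a process is preserved (and in what tissue
grade). Two coding rules convert this to state sets:

* **Preferred** (`code_preferred()`): any positive evidence — at least
  one scar or preserved process in at least one specimen — yields that
  single state; otherwise the taxon is fully uncertain `{0,1,2}`.
* **Alternate** (`code_alternate()`): additionally, a taxon with no
  positive evidence but at least `min_ribs = 5` examined ribs
  (regardless of preservation) is coded absent `{0}`. The alternate
  coding always refines the preferred one (a tested invariant), and
  converges to it as `min_ribs` grows.

Scar-only evidence maps to state 1: scars mark the attachment of
removable — hence unossified, cartilaginous-grade — processes in extant
analogues. Calcified plates are likewise grouped with state 1 by default.
Both mappings live in a small configuration table
(`default_process_map()`, `scar_state`), because a case could be made for
coding some scar-bearing taxa as `{1,2}`; the data structures and all
three inference methods accept such partial ambiguity even though the
packaged codings use only singletons and `?`. Multiple specimen rows per
taxon are aggregated by summing rib counts and keeping the strongest
process class ("at least one specimen" semantics), and expert overrides
(used for the outgroup, whose 13 well-preserved scar-free ribs justify
coding absence outright) take precedence and are carried in the table
itself rather than in code.

## Ancestral state inference

**Parsimony.** `sankoff_asr()` runs the Sankoff recursion with a unit
cost matrix (the character is unordered) and, via a second up-pass,
computes for every node the full MPR set — the states realized in at
least one most-parsimonious reconstruction. Reporting the whole set
avoids the false confidence of arbitrary ACCTRAN/DELTRAN choices.
Parsimony ignores branch lengths; the analysis grid therefore computes it
once per coding and marks the rows as branch-length invariant rather than
pretending four independent analyses.

**Maximum likelihood.** The Mk model with equal rates (ER) is the
default: with roughly twenty informative taxa a symmetric or all-rates
different generator is not identifiable, and richer models can be
requested (`parameterization = "SYM"`/`"ARD"`, using the matrix
exponential) when the data warrant. The pruning likelihood is log-scaled
per node, so small rates on deep trees do not underflow. The single ER
rate is optimized on log q over [1e-8, 1e3] events/Myr by bracketed 1-D
search; estimates at the bounds are flagged (`at_bound`) because they
indicate a frozen or saturated character rather than a meaningful rate.
Node probabilities are *marginal* reconstructions — P(node = s | all tip
data, q̂) — computed exactly by a down-pass/up-pass message scheme
algebraically equivalent to re-rooting at every node but linear-time.
The root prior is flat by default (equal to the ER stationary
distribution) and configurable; it is echoed in the output metadata.

**Bayesian inference.** `bayes_asr()` samples the ER rate by random-walk
Metropolis–Hastings on log q. The prior is exponential on q with mean
100/depth (one expected change per 100 Myr of root-to-tip depth) — a
weakly informative scale that adapts automatically between timescaled
(depth in Myr) and unit-length (depth in edge counts) trees; the prior
mean is overridable and always recorded. The proposal standard deviation
adapts during burn-in towards 20–40% acceptance and is then frozen, so
retained samples come from a valid fixed-kernel chain. Node posteriors
are Rao-Blackwellized: the exact conditional marginal reconstruction is
computed at every retained rate sample and averaged, which converges far
faster than counting sampled node states and makes the uninformative
limit exact. Defaults are 100,000 iterations, 20% burn-in, thinning 50;
the result carries the effective sample size of the rate chain (flagged
below 100), the post-burn-in acceptance rate and the seed, and a fixed
seed gives bit-identical output.

**Numerical conventions.** Probability vectors are normalized per node
and tested to sum to 1 within 1e-9; best-state ties within 1e-6 are
reported as ties (e.g. `0/1/2`), never broken; human-readable reports
round to two decimals while JSON exports keep full precision.

## The analysis grid

`run_grid()` executes the full design — two codings × three methods × two
branch-length modes — and summarizes every configured clade at its MRCA.
Cells fail independently (a failed cell is recorded with its error, the
rest still run), Bayesian cell seeds derive deterministically from the
study seed, and rewriting the report from the same configuration is
byte-identical, which the tests assert. This makes the key scientific
readout — how sensitive each clade's reconstruction is to coding rule and
branch-length treatment — a single table.

## The synthetic-data generator and the study fixture

The generator mirrors the assumed forward process: a birth–death tree
conditioned on the number of extant lineages (`simulate_tree()`; for a
pure-birth process the crown age matches the closed-form expectation
`sum(1/(birth * i))`, a tested oracle), an ER Mk character evolved along
it (`simulate_mk_character()`), and an observation layer
(`simulate_evidence()`) in which each rib of a process-bearing taxon
shows a scar with a detection probability, and ossified processes
additionally preserve directly. Defaults — 40 tips, birth 0.01/Myr
(crown depth ≈ 230 Myr), q = 0.005/Myr (about one expected change per
path), Poisson(4) examinable ribs, per-rib scar detection 0.5, ossified
preservation 0.9 — were chosen once as a realistic Mesozoic-archosaur
regime.

What the generator does *not* emulate: preservation biases correlated
with age or body size, among-lineage rate variation, correlated
characters, non-independent rib preservation within specimens, and
taxonomic misassignment. Passing the end-to-end recovery tests therefore
shows the pipeline is internally consistent under its own assumptions —
not that those assumptions hold for any particular real dataset.

The packaged study fixture (`make_study_fixture()`) is fully
hand-specified (no RNG), hence byte-stable: 40 tips, a backbone plus
seven source trees whose grafting reproduces the reference supertree
exactly, Triassic–Cretaceous ranges, one outgroup overridden to absent,
20 taxa with positive evidence (scar evidence at basal positions of each
major clade; ossified evidence confined to a nested pennaraptoran-like
clade), 9 taxa codeable absent under the alternate rule (placed as
terminal sister pairs, i.e. localized losses), and 10 poorly sampled
uncertain taxa. The placement is part of the fixture's design: the
cartilaginous signal is meant to bracket the deep nodes strongly enough
to survive all four ML cells, giving the regression tests a stable
qualitative target (state 1 ancestral for the deep clades, state 2 for
the nested clade). A fixture with interleaved absences would instead
reproduce the known instability of absence-heavy codings under
unit branch lengths — scientifically interesting, but wrong for a
regression anchor.

## Validation problem sizes

The test suite checks the pruning likelihood and the Sankoff cost/MPR
sets against exhaustive enumeration on 200 random trees of up to 6 tips
(tolerance 1e-10 for log-likelihoods, exact for parsimony); marginal
reconstructions against the brute-force joint posterior and against an
independent re-rooting implementation; the ER kernel against the matrix
exponential; rate recovery over 100 simulated 200-tip datasets (mean
relative bias within 25%, profile-likelihood 95% coverage at least 90%);
and the Monte-Carlo no-signal limit at 50,000 iterations (all posteriors
within 0.02 of 1/3). These sizes were chosen to make the whole suite run
in a couple of minutes while keeping each check statistically meaningful.

## Known limitations

* The supertree stage resolves nothing: conflicts among sources are
  logged and pruned in favor of the backbone, and the grafting order is
  the user's responsibility.
* Max-FAD dating is downward-biased for nodes without a directly
  subtending tip, and the mbl repair is a floor, not an uncertainty
  model; no stochastic timescaling or tip-dating is attempted.
* With few informative taxa the Bayesian node posteriors are sensitive
  to the rate prior — the flat ~1/3 posteriors that weak data produce are
  a feature of honest uncertainty, not a bug — and ER is an assumption,
  not an inference.
* Single-character analysis only: no correlated evolution, hidden rates,
  or stochastic character mapping.
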