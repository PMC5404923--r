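---
title: "Methods: modeling evolution by gene loss"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: modeling evolution by gene loss}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genedecay)
```

# The problem

When a bacterium's environment reliably supplies a metabolite, the
pathway that synthesizes it stops contributing to fitness, purifying
selection on its genes relaxes, and the genes decay and disappear.
`genedecay` models this process end to end: from genome annotations to
stoichiometric models, from models to predicted nutrient requirements
and reaction classes, from cross-genome comparison to lineage core
metabolisms, and from codon sequences to per-clade dN/dS. Because real
decay unfolds over millions of years, the package pairs each analysis
with a seeded simulator whose ground truth the analyses must recover;
this vignette describes both sides and the choices behind them.

# Flux balance analysis

A model is a stoichiometric matrix $S$ (metabolites $\times$ reactions)
with flux bounds $lb \le v \le ub$ and the steady-state constraint
$S v = 0$. Exchange reactions connect extracellular metabolites to the
environment with the standard sign convention: negative flux is uptake,
positive is secretion. A medium is the set of nutrients whose exchanges
are opened for uptake, each capped at `uptake_limit` (default 10 flux
units; all fluxes in the package share one arbitrary unit, and default
reaction bounds are 0/1000 for irreversible and ±1000 for reversible
reactions, wide enough never to bind before an uptake cap does).

Each model passes through six steps: (i) a growth requirement — the
*growth floor*, by default `growth_floor_frac = 0.1` times the maximum
biomass on the complete medium, a scale-free reading of "biomass must be
nonzero" that is robust to rescaling of the biomass equation; (ii)
minimization of the number of active exchanges, giving the minimal
medium; (iii) restriction of exchanges to that medium; (iv) per-reaction
flux minimization and maximization (FVA); (v) biomass maximization and
fixation; (vi) total-flux minimization (parsimonious FBA, via the usual
split of each flux into nonnegative forward and reverse parts, which
zeroes futile cycles because they add cost without enabling biomass).
Classification uses the FVA ranges with zero-flux tolerance
`epsilon = 1e-6` flux units: strictly signed ranges are *essential*,
ranges within ±epsilon of zero are *nonfunctional*, everything else is
*functional*.

One reading had to be fixed for step (iv): during variability scanning
the biomass flux is constrained to at least the growth floor
(`biomass_at = "floor"`, the default) rather than pinned at its maximum.
Pinning at the maximum (`biomass_at = "max"`) is also supported; the
floor default classifies fewer reactions as essential and is the more
conservative reading of "classify each reaction during growth".

## The linear-programming engine

All steps reduce to linear programs over $S v = 0$. The package carries
its own dense bounded-variable two-phase revised simplex, written for
the structure these problems actually have: every mass-balance row has
zero right-hand side, so phase 1 starts fully degenerate, and
stoichiometric matrices are routinely rank-deficient. Artificial
variables are kept in the basis pinned at zero through phase 2 (so
redundant rows never require basis repair), and the pivot rule falls
back from Dantzig to Bland after a run of degenerate pivots, which
guarantees termination. Feasibility residuals of returned optima are
below $10^{-7}$, and the test suite checks the engine against
brute-force vertex enumeration on hundreds of random bounded LPs and
against an independent simplex implementation where that implementation
is numerically able to solve the instance.

## Minimal media and gapfilling as exact searches

Both problems minimize the cardinality of a selected subset (active
exchanges; added database reactions) subject to growth, and both
feasibility structures are monotone: enlarging a medium or an addition
set never destroys growth. The package exploits this with an exact
combinatorial branch-and-bound: candidates are explored in lexicographic
order at increasing cardinality, a subtree is pruned when even the
entire remaining candidate tail cannot restore feasibility (one LP per
probe, cached), and the first subset found is therefore *both* of
provably minimum cardinality *and* the lexicographically smallest such
set — the deterministic tie-break the pipeline needs. A greedy
alternative (strip nutrients from the complete medium, largest id
first) is available behind `method = "greedy"` but is never the
default, because only the exact search can be compared against
exhaustive subset enumeration in the tests.

Gapfilling adds a second stage mirroring automated reconstruction
practice: among all cardinality-optimal addition sets (enumerated with
the same pruned search), it keeps the one that lets the most
gene-associated model reactions carry flux, measured by FVA on the
augmented model at the growth floor. "Able to carry flux" is a
per-reaction variability property, so this stage is an enumeration over
the optimal face rather than a single optimization; candidate sets at
desk scale number in the tens, and a guard (`max_enumerate`) skips the
refinement if enumeration would explode. Addition costs are uniform
(one per reaction); no direction or pathway weighting is applied.

# Comparative layer

Core membership uses the inclusive boundary: a reaction gene-associated
in exactly 3 of 4 models qualifies at threshold 0.75. The comparison is
done on counts (`count >= threshold * n` with a $10^{-9}$ guard) so
float representation can never flip a boundary case. Lineage core
models instantiate core reactions from the database templates with the
union of gene associations seen in the lineage, then pass through the
same gapfilling and six-step analysis as genome models. The global
conserved core is the intersection of gene-associated reaction sets
across all models; containment of each lineage core in it is reported
per lineage together with both the mean over lineages and the pooled
fraction, since either summary is a defensible aggregate.

# Occurrence, coevolution, auxotrophies

A pathway is called complete in a genome when at least
`completeness_threshold = 0.9` of its expected functional roles are
annotated (inclusive). The threshold deliberately tolerates one missing
enzyme in a ten-role pathway — mirroring the common situation where one
family member (e.g. a phosphatase) is systematically hard to annotate —
and the bifunctional focal role counts toward the completeness of
*both* convergent pathways, configurable through `shared_roles`.

The coevolution concordance score is this package's own
quantification (the qualitative observation it formalizes is that a
retained bifunctional gene "tracks" its dependent pathways): the
fraction of genomes where focal-gene presence equals the presence of at
least one complete dependent pathway, with per-genome discordance
flags. Auxotrophy prediction is purely metabolic: a pathway is called
lost when its end product appears in the predicted minimal medium.

# dN/dS by counting

The estimator is a counting method with Jukes–Cantor correction,
chosen over maximum-likelihood codon models because it is closed-form,
fast, and verifiable against an independent enumeration oracle to
machine precision. Conventions, fixed once and applied consistently:

* synonymous site fractions are counted per codon position out of the
  three possible changes; mutations creating a stop codon count as
  nonsynonymous (sites per codon always sum to 3);
* sites are averaged over the two sequences; codon columns containing a
  gap or ambiguous base in either sequence are dropped pairwise;
  internal stops are an error;
* codons differing at 2–3 positions average their synonymous /
  nonsynonymous step counts over all minimal mutational pathways;
  pathways passing through a stop codon are discarded unless every
  pathway does;
* $d = -\tfrac{3}{4}\ln(1 - \tfrac{4}{3}p)$ for both proportions;
  $p \ge 3/4$ is reported as undefined (saturation);
* clade omega is the ratio of mean dN to mean dS over within-clade
  pairs — not the mean of ratios — so near-zero-dS pairs cannot
  dominate; saturated pairs are dropped and the usable pair count is
  reported.

The production path uses precomputed 61×61 codon-pair tables built at
first use; the test oracle (`ng86_reference`) recomputes everything by
explicit recursion, and the two agree to $10^{-9}$ on random
300-codon pairs.

# The synthetic generator

`generate_universe()` builds linear biosynthesis chains from
transportable precursors (`pre_*_e`) to amino-acid biomass precursors,
with every end product also transportable as a supplement (`sup_*_e`) —
the salvage route that makes pathway loss survivable. The default
universe has 4 pathways of 10, 7, 5 and 4 roles; the first two converge
on the bifunctional role `r_pri`, which catalyzes one mid-chain step of
each (positions 4 and 3), giving 10- and 7-role pathways that share one
gene. Transporter roles are housekeeping and never decay. Precursor ids
sort before supplement ids on purpose: for an intact pathway the
precursor and the supplement are interchangeable single-nutrient
sources, and the lexicographic tie-break then selects the precursor, so
a supplement in a minimal medium is always a loss signal.

`simulate_decay()` erodes genomes along a tree. A pathway is deletable
on a branch only when its product is supplied in the environments of
all lineages below that branch; each of its exclusive roles is then
lost with probability $1 - e^{-\lambda\,t}$ (exponential waiting times,
so per-branch loss frequencies can be checked against the closed form).
Loss is irreversible — no regain or horizontal transfer — matching the
decay framing. The focal gene is removed deterministically at the
moment both of its host pathways are broken by exclusive-role losses;
a stochastic focal loss would leave transient genomes whose focal gene
outlives both pathways, and focal presence would then no longer track
pathway retention exactly. Planted discordances for testing the
concordance statistic re-add the focal gene in genomes where at least
two exclusive roles of the longer pathway are missing, which guarantees
neither pathway crosses the 0.9 completeness threshold. Every emitted
genome is verified to grow in its lineage environment (the environment
construction makes a nonviable genome impossible, so the check is an
invariant assertion rather than a retry loop).

`simulate_codon_evolution()` proposes point mutations as a Poisson
process (`mutation_rate` proposals per nucleotide site per unit branch
length), rejects stops, accepts synonymous changes always and
nonsynonymous changes with the governing clade's omega — a
Gillespie-style acceptance scheme whose realized nonsynonymous/
synonymous acceptance ratio is bookkept per branch and checked against
omega in the tests. No indels are generated, so leaf sequences form a
true alignment.

What the generator does *not* emulate — and what passing tests
therefore do not establish about real data: promiscuous or redundant
enzymes (one role, one reaction), branched or cyclic pathway
topologies, transporter loss, regulatory effects, horizontal gene
transfer and recombination, annotation error, codon usage bias, indels
and alignment uncertainty, and rate variation within a clade. The
recovery results certify the *internal consistency* of the chain
(simulator → models → predictions → truth), not the error rates of any
step on genuine genomes.

# Study conditions and problem sizes

The shipped analyses run at desk scale, chosen so exhaustive oracles
remain feasible: the oracle battery uses 50 random networks of at most
8 reactions (vertex enumeration is exhaustive there); the decay
scenario uses 20 genomes in 4 lineages over a 4-pathway universe, with
loss rate 1.2 per gene per unit branch length and within-lineage branch
lengths U(0.3, 0.8) — deep enough that lineages allowed to lose
pathways usually do, shallow enough that protected lineages stay
intact; discordance tests plant k = 2 of 20.

The selection-regime study simulates three clades at omega 0.06, 0.09
and 0.15 — the regime spanned by conserved versus decaying deep clades
— with 6 leaves per clade, branch lengths U(0.8, 1.6) and proposal rate
0.35, giving mean within-clade dS around 1.75: divergence comparable to
deep inter-species clades while staying below counting-method
saturation. These conditions were fixed after a small pilot of the
estimator's variance (the 0.06 vs 0.09 contrast is the statistically
tight one) and are not tuned per seed; across 50 seeds the rank order
is recovered in well over 95 % of replicates.

# Numerical choices

* LP pivot tolerance $10^{-9}$; feasibility residual bound $10^{-7}$;
  infinite user bounds truncated at $10^6$, and a flux pinned at that
  internal cap raises an "unbounded" error pointing at a missing
  exchange constraint.
* Zero-flux tolerance for classification $10^{-6}$ flux units.
* Biomass fixation (steps v–vi, FVA at `"max"`) applies a relative
  slack of $10^{-7}$ to avoid infeasibility at the LP tolerance edge.
* Degenerate inputs: empty media are legal (a model with a spontaneous
  biomass source has an empty minimal medium); models that cannot grow
  on the complete medium raise an explicit auxotrophy error and are
  gapfilling candidates; reversible futile loops are legal and carry
  zero flux in parsimonious solutions.
* All ids are compared case-sensitively; canonical order is
  lexicographic by id; writers emit canonical order so serialization
  round-trips byte-identically.

# Known limitations

The universal database defines its own biomass composition (one unit of
each pathway end product); no attempt is made to mirror any particular
reconstruction template. The LP engine is dense and single-threaded —
appropriate for networks up to a few hundred reactions, not for
genome-scale reconstructions with thousands. Gapfilling weights are
uniform, media-specific multi-condition gapfilling is out of scope, and
the dN/dS estimator deliberately omits likelihood-based branch and site
models; ratios from published per-clade rates can be reproduced
exactly, but re-deriving such rates from real alignments with a
specific ML model is outside what a counting estimator can promise.
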