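---
title: "Detecting adaptive sequence convergence: models, tests and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting adaptive sequence convergence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(adaptconv)
```

## The scientific problem

Several small-bodied mammals — the naked mole-rat and a handful of
vespertilionid microbats — live three to six times longer than the
mammalian mass–longevity allometry `tmax = 4.88 M^0.153` (M in grams)
predicts. If shared selection for delayed senescence repeatedly targeted
the same genes, those genes should carry *convergent substitutions*:
sites at which the naked-mole-rat lineage and the ancestral-microbat
lineage independently acquired the same derived amino acid. `adaptconv`
implements the analysis chain for finding and testing such signals:

1. a gene-tree *monophyly screen* that flags genes in which the long-lived
   taxa group together against the accepted species tree;
2. *marginal ancestral reconstruction* and per-branch substitution mapping
   to identify the convergent sites in a flagged gene;
3. a *divergence-versus-convergence* empirical null and a *Zhang–Kumar*
   significance test to distinguish adaptive convergence from high overall
   substitution rate;
4. a *physicochemical-property selection scan* and an *AU topology test*
   restricted to positively selected sites, asking whether those sites
   specifically support the convergent topology.

## Models and algorithms

**Substitution models.** Reversible CTMCs `Q = R diag(pi)` with symmetric
exchangeabilities `R`, normalised to one expected substitution per site per
unit branch length. Built-ins: equal-rates (Jukes–Cantor type), GTR, and
the WAG empirical amino-acid matrix; any exchangeability matrix can be
plugged into `substitution_model()`. Rate heterogeneity uses the
discrete-gamma approximation with `k = 4` equal-weight, mean-one categories
(the field default). Transition kernels come from the
pi-symmetrised eigendecomposition, which is numerically stable and exact
for reversible models.

**Likelihoods.** Felsenstein pruning with per-node rescaling of partial
likelihoods (log-space scale accumulators), so long trees and alignments
cannot underflow. Gaps and unknown residues (`-`, `X`/`N`) are missing
data: all-ones partial likelihoods. Per-site likelihoods are averaged over
gamma categories; posterior quantities are averaged with *per-site
posterior* category weights. The suite checks the engine against exhaustive
enumeration over all node-state assignments on small instances (to 1e-6 and
better).

**Ancestral states.** Marginal reconstruction: at every internal node the
posterior over states combines the below-node (pruning) and above-node
messages; the above-node message at the root is the stationary
distribution. MAP ties (within 1e-9) break toward the parent's MAP state —
a conservative choice that avoids inventing substitutions — and otherwise
toward the lowest state index. Joint reconstruction and stochastic mapping
are out of scope: the downstream counting consumes per-node states
independently.

**Substitution mapping and convergence counting.** A branch carries a
substitution at a site when the parent MAP state and the child state
(observed at leaves, MAP at internal nodes) are both defined (non-missing)
and differ. For an independent branch pair — neither branch on the other's
root path; sister pairs allowed — a doubly-substituted site is *convergent*
if the derived states match (with *parallel*, equal ancestral states,
reported as a flagged subset) and *divergent* otherwise.

**Posterior-expected counts.** For the all-pairs scan, the per-branch
posterior probability of "substitution ending in state j" is computed
exactly per branch from the endpoint joint posterior; the two branches are
then combined as if independent conditional on the data. This
factorisation is an approximation (states on two branches remain weakly
dependent given the data, most visibly for sister pairs); the package
defines its expected counts by this rule and the enumeration oracle in the
test suite applies the same combination rule to exhaustively computed
per-branch posteriors.

**The Zhang–Kumar test.** Observed count: MAP-based convergent sites for
the focal pair. Null: keep the reconstruction (ancestral states, branch
lengths, per-site posterior rate weights) and randomise what happens on the
two focal branches under the model. Two conditionings are provided:

* *destination-conditional* (default): condition on the set of sites where
  both branches carry an inferred substitution; only the destinations are
  random. Each such site contributes
  `sum_j P'_a(i -> j) P'_b(k -> j)` (destination distributions restricted
  to actual changes), scaled by the derived-endpoint MAP posteriors —
  a coincidence can only be *scored* convergent if both derived states are
  correctly reconstructed. Because the observed count and the null refer to
  the same inferred double-substitution events, detection biases cancel and
  the test calibrates close to nominal (the suite verifies the rejection
  rate over 1000 null replicates under the study conditions below).
* *occurrence-conditional*: both occurrence and destination random given
  the ancestral states — the classical unconditional form, noticeably
  conservative because the model's and the reconstruction's substitution
  counts need not match site by site.

The p-value is the exact Poisson-binomial tail `P(X >= c_obs)` by direct
convolution (up to 5000 sites; Poisson approximation with the same mean
beyond, a documented switch).

**Empirical null scan.** Expected convergent counts are regressed on
expected divergent counts across all independent pairs by ordinary least
squares with intercept ("trendline"), and pairs are ranked by raw vertical
residual. Note a known property of this raw ranking: pairs with long
branches have the largest counts *and* the largest residual variance, so
under the null they appear at both extremes of the ranking more often than
uniformly — the ranking is a detection heuristic, not a calibrated
statistic; calibrated inference is the Zhang–Kumar test's job.

**Property selection scan.** For each inferred amino-acid substitution on
the focal branch, the magnitude of change under each shipped property scale
(Kyte–Doolittle hydropathy, Grantham polarity, Zamyatnin volume, Zimmerman
isoelectric point; any named scale list can be supplied) is binned into 8
equal-width categories spanning the range of all single-nucleotide
amino-acid replacements, weighted by codon multiplicity under the standard
code. Category counts per scan window are z-scored against that null;
sites in radical categories (6–8) with `z > 3.09` (strict; one-tailed
p about 0.001) are "positively selected". The default window is one codon,
under which a single substitution is selected exactly when its radical
category has null probability below `1/(1 + 3.09^2)`. The original
sliding-window width is not published; the window is a parameter.

**AU test.** Multiscale RELL bootstrap: per-site log-likelihood vectors are
resampled at 10 scale factors (0.5–1.4), 10,000 replicates each (seeded);
bootstrap win proportions are mapped to z-values and the weighted
regression `z ~ d sqrt(r) + c / sqrt(r)` gives `p_AU = 1 - Phi(d - c)`.
Scales with saturated proportions are dropped; if a tree wins (loses)
every replicate at every scale its p is 1 (0). Exact ties between trees
split the win and give p = 0.5 with a warning. Branch lengths are
re-optimised per candidate topology on the restricted alignment before
site-wise likelihoods, so each tree is compared at its own best fit.

**Trees.** Newick I/O via ape; branches are identified by their child
clade's sorted leaf labels, stable across round-trips. Neighbor joining is
implemented with a documented lowest-index tie-break so results are fully
deterministic; on additive matrices it is exact. Tree search is NJ
(optionally on maximum-likelihood pairwise distances, which correct for
rate heterogeneity that plain JC distances miss) plus an optional NNI hill
climb; SPR/TBR are out of scope. Monophyly is evaluated on the unrooted
tree as a bipartition query, avoiding arbitrary rooting.

## The synthetic study conditions

The simulation studies all use the accepted 15-taxon species topology with
a fixed, synthetic set of branch lengths (`load_fixture("sim_tree")`;
the published figures print none). Terminal branches are 0.06–0.55
expected substitutions per site; the ordinal-level internodes separating
the naked mole-rat from the microbats are short (0.02), reflecting the
rapid mammalian radiation; and the two focal branches are long (0.55 for
the naked-mole-rat terminal, 0.25 for the microbat stem), as their real
counterparts are. The focal lengths were set so that the null expectation
of convergent events is a handful (about 4–5 per 500 amino-acid sites):
much lower and the discrete Poisson-binomial test becomes over-conservative
at alpha = 0.05; much higher and 15 planted sites no longer stand out at
alpha = 0.001. This is the joint design point at which a calibration band
and a power requirement can both hold, and it is fixed once for all
studies.

Two default models: `default_aa_model()` (WAG+G, shape 0.8) for the
convergence statistics — convergence analysis is an amino-acid method;
nucleotide states make chance destination coincidence (about 0.4 under a
transition-rich GTR) too likely for any powerful test — and
`default_sim_model()` (GTR+G, transition-rich, shape 0.8) for the
nucleotide gene-tree screen.

The simulator draws root states from the stationary distribution, evolves
them down each branch per rate category, and records full truth: states at
every node, per-site rates, per-branch realised substitution counts.
`plant_convergence()` rewrites both focal clades at chosen sites to a
common derived state differing from both parents' states (pure
convergence), with `parallel` (equal parent states required) and `radical`
(maximal hydropathy jump, guaranteeing the property scan can see the site)
policies. The screen's positive control is a gene simulated on the
convergent gene-tree topology itself — a gene whose entire evolutionary
history follows the convergent grouping, the cleanest analogue of the one
flagged gene in the real screen.

What these simulations do *not* emulate: alignment error (the real pipeline
consumes curated alignments), indels (no indel simulation), codon-level
selection, lineage-specific rate shifts, or model misspecification beyond
the gamma mixture. Passing tests therefore certify the statistical
machinery under its own model class, not robustness to alignment artefacts.

## Numerical and degenerate-input conventions

Branch lengths are optimised on the log scale with L-BFGS-B (bounds
1e-7–50, convergence flag surfaced, never silent); ties in NJ's Q
criterion join the lowest-index pair; MAP ties go to the parent state;
zero-likelihood columns are guarded before normalisation; the two
root-adjacent branch lengths of a rooted tree are only jointly
identifiable, which the recovery tests respect by comparing patristic
distances. The identity filter retains the boundary (exactly 60% is kept;
"below 60%" is removed). Degenerate inputs are flagged rather than
guessed: all-equal scan inputs give no ranking, identical site-likelihood
vectors give AU p = 0.5 with a warning, empty focal branches give empty
scan results.

## The published character matrix

The 15×21 convergent-site matrix ships as a fixture with gaps and unknowns
preserved and original column positions (54…1933) attached. The analysis
fits branch lengths by maximum likelihood on the accepted topology under
WAG before reconstructing — the same procedure the original
reconstruction software applies — and then recovers all 21 columns as
convergent between the naked-mole-rat and ancestral-microbat branches.
Reconstructing instead with all branch lengths fixed at 1 leaves the
posteriors saturated (each leaf dominates its parent node) and recovers
only a fraction of the sites; fitted lengths are therefore the package's
default procedure for fixture analyses. The amino-acid model used by the
original ancestral reconstruction is unpublished; WAG is the package
default and any reversible exchangeability matrix can be substituted.

## Known limitations

* The cross-branch factorisation of expected counts is approximate for
  sister pairs (documented above).
* The raw-residual outlier ranking is a heuristic with heteroscedastic
  behaviour under the null (documented above).
* The property scan reconstructs amino-acid substitutions from the protein
  alignment; synonymous structure of the actual codons is used only
  through the code-wide replacement null, not per-gene codon usage.
* Desk-scale study sizes (500–1000 sites, 51 genes, 200–1000 replicates)
  are the package's fixed defaults for its reproducible studies; the
  machinery itself has no such limits.
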