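---
title: "Joint clonal deconvolution of SNVs, CNAs and SVs: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint clonal deconvolution of SNVs, CNAs and SVs: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Bulk tumor samples are mixtures of clones. For `m` samples over a variant
universe of `l` SV breakpoints, `g` SNVs and `r` genome segments (two
alleles each), the observed matrix `F` (m × (l+g+2r)) holds mean copy
numbers per variant and per allele-specific segment. The package infers an
integer clone-profile matrix `C` (N × (l+g+2r)) and clone fractions `U`
(m × N, rows on the simplex) minimizing

```
| F − U C |  +  λ₁ R  +  λ₂ S
```

over all rooted binary trees on `N = 2n − 1` clones whose root is the
diploid normal population (no variants, one copy of each allele per
segment). The three terms:

* **Data term.** Element-wise L1 distance between the observed bulk and
  the reconstructed mixture. L1 is preferred to least squares because it
  linearizes exactly inside an ILP.
* **R** (minimum evolution). For every edge and segment, auxiliary
  variables capture the absolute allele-specific copy change; their sum
  penalizes evolutionarily long trees, implicitly assuming single-copy
  gains and losses at uniform rate.
* **S** (VAF consistency). For every sample and variant, the discrepancy
  between the observed VAF (variant copy over total segment copy, clamped
  to [0, 1]) and the VAF implied by `(U, C)`, linearized through auxiliary
  variables. Entries whose mixed segment copy is zero carry no VAF
  information and are skipped.

**Dollo parsimony.** Each breakpoint or SNV is introduced on at most one
edge (tensor `W`), must be absent from the parent and present in the child
of that edge, and can never reappear after a loss; losses happen only
through copy-number loss of the carrying allele. Breakpoint mate pairs
share one introduction edge and one allele. SNV homoplasy is thereby
excluded by construction — an assumption that is safer for base-resolution
SV breakpoints than for SNVs, and a known limitation.

**Allele phasing.** Each variant is assigned to allele 1 or 2 (`D`); the
model fixes "allele 1 carries the larger copy number" per segment during
preprocessing (majority vote across samples, ties keep input order, the
swap applied cohort-wide so the allele identity stays common). Coupling
constraints tie each variant's copy change along an edge to its allele's
segment copy change.

### The `phasing` option

As written, the coupling constraints bind on every active edge whose
allele matches `d_b`, for every variant not introduced there — including
variants absent from both endpoints. That forces segments to stay
copy-neutral at loci of variants residing elsewhere in the tree, which is
well-defined but stricter than the generative model: a simulated CNA may
overlap the locus of a variant introduced on a different branch.
`phasing = "strict"` (default) implements exactly that reading;
`phasing = "gated"` adds the parent-presence indicator to the big-M so the
coupling only binds for variants the parent clone actually carries. Under
the simulator's event semantics (below), every simulated trajectory is a
feasible point of the gated model — this is provable from the event rules,
so ground-truth recovery experiments use `phasing = "gated"`.

### Choice of λ₁ and λ₂

Defaults normalize the penalties to the expected scale of the data term:
`λ₁ = (l+g+2r)/(2 r m N)` and `λ₂ = (l+g+2r)/(2 (l+g))`. Results are not
very sensitive to these weights; both are overridable in
`solver_config()`.

### Coordinate descent

`U` is initialized uniformly at random on the simplex per sample (per
restart); then the profile ILP (`solve_c_step()`) and the frequency LP
(`solve_u_step()`) alternate until the relative objective improvement
falls below `tol` (default 1e−4) on two consecutive iterations (single
plateaus are common in the alternation and often resume) or `max_iters`
(default 10) is reached. The frequency step optimizes only the data term,
as the penalty `S` is treated as part of the profile step; consequently
the full objective is guaranteed non-increasing only while both
subproblems solve to proven optimality, which the per-iteration trace
records. Five random restarts (default) guard against local optima; the
best final objective wins, and restarts stop early once a zero-objective
solution is found (it cannot be improved). Restart seeds derive from one
master seed and are recorded.

The descent is sensitive to variant scarcity: with only a handful of
variants the data term gives random initial frequencies little to latch
onto, and the alternation can stall in conservative fixed points (the
profile step given the *true* frequencies still recovers the truth
exactly on such instances). Cohorts with an SNV excess over the SV count
— the regime the generator's default `snv_count_param = 100 ×` total SV
rate emulates — are markedly better behaved.

### ILP formulation notes

* Clone labels are canonicalized: leaves `1..n`, internal nodes
  `n+1..N−1` with every internal child labeled below its parent, root
  `N`. Any binary tree admits such a labeling, so no solutions are lost,
  and the labeling removes most tree-symmetry from the search. Leaf labels
  are additionally ordered by parent index (leaves are exchangeable).
* Ancestry `A` is constrained to the exact transitive closure of `E`
  (lower bounds via transitivity, upper bounds via the unique-parent
  property), with anti-cycle conditions `a_ij + a_ji ≤ 1`, `a_ii = 0`
  implied structurally.
* Binarized presence uses `c̄ ≤ c ≤ c_max · c̄`; a redundant-but-tight cut
  `c̄_kb ≤ Σ_edges w_b` links presence to introduction and helps the LP
  relaxation.
* Big-M constants follow the printed formulation: `2c_max+1` and
  `2c_max+2` in the phasing constraints, `c_max` elsewhere.
* The backend is the HiGHS solver called through a bundled SciPy helper
  (`inst/python/milp_solve.py`); models are serialized as JSON sparse
  triplets. Determinism holds for fixed seeds because HiGHS runs
  single-threaded here; MILP tie-breaking among equally optimal trees is
  the backend's.
* The all-normal solution (diploid segments, no variants, any canonical
  tree) is feasible for every instance, so a reported infeasibility is
  treated as a modeling bug, not a data property.

### Estimating the clone number

With `max_nodes = N` (default 9) the tree is deliberately oversized;
`collapse_tree()` then iteratively (i) splices out zero-frequency nodes
with a single child and (ii) merges children joined by zero-length,
variant-free branches, summing frequencies. The number of surviving nodes
estimates the clone count. The same rule applied to a simulated truth
defines the *true* clone number: a branch that carries no event produces a
child indistinguishable from its parent, which no method can (or should)
count as a separate clone.

### Subsampling and post-hoc assignment

For large cohorts, `subsample_variants()` keeps all segments, up to
`max_breakpoints` breakpoints (mate pairs kept or dropped together) and
SNVs up to `max_total`. After solving on the subsample,
`assign_unsampled()` maps each held-out variant to the edge, allele and
timing scenario minimizing the L1 distance across samples between its
observed mean copy number and the model-implied value: scenario 1 (variant
precedes the edge's copy change; copy equals the allele's segment copy)
is admissible when the assigned clone's allele copy is 1 or the edge gain
exceeds 1, scenario 2 (variant follows the change; one copy in the
assigned clone, the expectation `chat_k / chat_i` in descendants) whenever
the allele survives. The printed admissibility rule for scenario 1 is the
default; `admissibility = "gain1"` relaxes it to `chat ≥ 1`. The distance
is L1 because that matches the objective's loss; mate pairs are assigned
jointly (summed distance) to honor their common-edge constraint.
`merge_assignment()` rounds scenario-2 descendant expectations half-up
when extending `C` (pre-rounding values are kept), which is why a merged
solution may violate the integer allele-cap check by the rounding margin
while all Dollo and tree invariants still hold exactly.

## The simulator

`simulate_cohort()` draws a uniformly random rooted binary tree topology
on `n` labeled leaves (sequential uniform edge insertion with an auxiliary
root leaf — uniform over the `(2n−3)!!` labeled topologies), places SV and
SNV events on uniformly random edges and alleles, and realizes per-clone
genomes.

* **Rates.** Either a total SV count `~ Poisson(sv_rate_total)` with
  uniform edge assignment, or per-branch `Poisson(sv_rate_branch)`; both
  modes exist because different experiments fix one or the other. The SNV
  count is `Poisson(snv_count_param)`; its default of 100 × the total SV
  rate follows the stated protocol, but the printed source for that factor
  is ambiguous, so the knob is explicit.
* **Event mix.** duplication : deletion : translocation : inversion at
  2:2:1:1; spans `~ Poisson(sv_length_mean)` (default 5,745,000 bp, an
  empirical whole-genome mean for breast tumors); duplication multiplicity
  uniform on 2..6; CNAs arise only as consequences of duplications and
  deletions.
* **Semantics (in reference coordinates).** A duplication of multiplicity
  `k` adds `k−1` copies over its span on the chosen allele and multiplies
  resident variants along; its junction breakpoint pair gets copy `k−1`.
  A deletion removes one copy (floor 0), removing a variant-bearing copy
  first, and its flanking junction pair gets copy 1. Inversions and
  translocations are copy-neutral and contribute one junction pair each
  (a reciprocal translocation's second junction is not tracked
  separately). Each event must find at least one surviving copy of its
  footprint; placements are redrawn up to `max_retries` (then error).
  These mechanics are this package's choices — the protocol fixes types
  and rates, not placement or junction bookkeeping.
* **Copy cap.** Realized copy numbers are capped at `c_max` (default 10);
  cap events are counted.
* **Mixing and noise.** Clone fractions per sample are uniform on the
  simplex (Dirichlet(1, …, 1)); the noiseless bulk is `F = U C`. Read
  noise: per sample and segment `rc ~ Poisson(read_depth)` (default 100),
  per variant `alt ~ Binomial(rc, VAF)` giving noisy copy
  `(alt/rc)·ψ`, and per segment a `Binomial(rc, BAF)` redraw of the
  allele split of the theoretical total; `rc = 0` falls back to the
  theoretical value. The read count is not scaled by segment copy number
  (the protocol leaves this unstated), and the allele-split noise mirrors
  the variant mechanism because the protocol is silent on segment-copy
  noise mechanics.
* **Allele ordering.** The canonical "allele 1 is larger" orientation is
  decided once per segment on the *noiseless* mixture and applied to the
  truth and the noisy data alike, so a cohort's ground truth does not
  depend on the noise draw.
* The default genome is 2 × 50 Mb — compact enough for desk-scale method
  studies; event statistics (types, spans, multiplicities, depths) follow
  the full-scale defaults regardless of genome size.

**What passing simulated tests does not show.** The generator emulates the
statistical structure of the protocol, not real data: breakpoint calls are
noiseless in position, segmentation is exact, the variant universe is
shared across samples by construction, and clone genotypes follow the same
Dollo assumptions the solver makes. Good recovery here demonstrates
correctness of the optimization and identifiability under the model, not
robustness to caller errors or model misspecification.

## Problem sizes used in the shipped tests

The test suite runs desk-scale instances chosen to exercise every code
path: cohorts of 2–4 leaves with 2–8 SVs and a 3–20-fold SNV excess on
the 2 × 50 Mb genome (span mean scaled to ~0.3–0.5 Mb so events fit),
oracle comparisons on N = 3 instances with `c_max = 2` against exhaustive
enumeration, exact recovery on five noiseless n = 2, m = 5 cohorts with
2 expected SVs and 20 expected SNVs (scarcer cohorts are either
non-identifiable — an event-free branch duplicates a clone, leaving `U`
undetermined — or stall the descent as described above), and pooled event
logs of ≥ 50,000 SVs for the distributional checks. The clone-number
check solves those same cohorts with `max_nodes = 9` keeping all
variants: small subsamples can admit alternative exact integer
decompositions of the mixture, in which case the clone number is not
identified by the retained data; the subsample-then-assign workflow is
validated separately against its brute-force oracle. These sizes are the
package's reproducible defaults for its own validation; the solver
itself accepts anything the time limit tolerates (clone numbers up to
about 9 are practical).

## Known limitations

* No SNV homoplasy; one introduction per variant (Dollo).
* Binary trees only; the collapse heuristic recovers multifurcations as
  zero-length chains only post hoc.
* The frequency step ignores `S`, so descent can stall in mildly
  suboptimal fixed points; restarts mitigate this.
* MILP scaling limits the variant count per solve; subsampling plus
  assignment is the intended workflow beyond ~100 variants.
* The strict phasing reading can render generative truths infeasible (see
  `phasing` above); choose the reading that matches your assumptions.
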