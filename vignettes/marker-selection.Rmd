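---
title: "Selecting minimal SNP panels for paternity exclusion in half-sib populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selecting minimal SNP panels for paternity exclusion in half-sib populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

In many breeding and ecological settings a seed (maternal) parent is known —
offspring were sampled from it — while the pollen (paternal) parent must be
inferred from a closed, fully genotyped candidate population. Genotyping costs
scale per locus, so out of thousands of genome-wide SNPs one wants the
*smallest* marker subset that still identifies every candidate father, even
when the candidates include close relatives (full sibs, parent–offspring
lines), as is typical of clonally propagated fruit-tree germplasm where a few
elite cultivars recur throughout the pedigree.

`snppick` formulates this selection as a binary integer program, provides an
exact branch-and-bound solver and fast heuristics (greedy construction plus a
one/two-flip neighborhood search), and closes the loop with a Mendelian
offspring simulator and an exclusion-based assigner so that a chosen panel can
be stress-tested before any wet-lab work.

## Model

All genotypes are biallelic SNP dosages oriented against the mother: the
mother must be homozygous at every retained locus (heterozygous or missing
maternal loci are dropped at load), and dosages count the allele she does
*not* carry, so she is 0 everywhere and an offspring's dosage equals its
paternal gamete.

**Discriminatory power.** For candidate fathers $i, j$ and marker $k$ with
dosages $a_{ik}, a_{jk} \in \{0, 1, 2\}$,

$$
p_{ijk} =
\begin{cases}
1 & |a_{ik} - a_{jk}| = 1 \\
h & |a_{ik} - a_{jk}| = 2 \\
h^{-1} & a_{ik} = a_{jk} = 1 \\
0 & \text{otherwise, including missing.}
\end{cases}
$$

Opposing homozygotes always transmit distinguishable gametes (deterministic
exclusion), hence the large weight $h$; a shared heterozygote carries only a
faint, frequency-like signal, hence $h^{-1}$. The *heterozygosity weight* $h$
is also the per-pair requirement: a marker set $x \in \{0,1\}^m$ is feasible
iff $\sum_k p_{ijk} x_k \ge h$ for every unordered candidate pair. Larger $h$
forces redundancy and is what makes panels work for close relatives, which
never show opposing homozygotes (a parent and its offspring share an allele
at *every* locus).

**Marker-count objective.** $f(x) = \sum_k x_k$, minimized subject to the
pair constraints — a weighted set-cover.

**Adjacency objective.** Parentage inference assumes linkage equilibrium, so
physically close markers should not be co-selected. With marker $k$ on
chromosome $c_k$ at position $B_k$, and $D_k$ the physical length of $c_k$,
the strictly lower-triangular weight matrix $Q = [q_{kl}]$ has

$$
q_{kl} =
\begin{cases}
1 & c_k \ne c_l \\
\left( |B_k - B_l| / D_k \right)^{-1} & c_k = c_l \\
0 & k \le l,
\end{cases}
$$

and the alternative objective is $g(x) = x^\top Q x$: every cross-chromosome
pair costs 1, same-chromosome pairs cost more the closer they sit (the weight
is unbounded as markers approach; we deliberately do not cap it, since the
optimizers only compare sums). For the exact solver $g$ is linearized with
dummy binaries $y_{kl} = x_k x_l$ and the standard linking rows
$x_k + x_l - y_{kl} \le 1$, $x_k - y_{kl} \ge 0$, $x_l - y_{kl} \ge 0$;
$y$ variables are only created where $q_{kl} > 0$.

**Depth.** $\mathrm{depth}(x)$ is the median over candidate pairs of
$\sum_k p_{ijk} x_k$ — the redundancy buffer above the requirement $h$, and a
predictor of tolerance to missing genotypes. For even pair counts the median
is the midpoint of the two central values (the convention is ours; the
choice has no effect on any comparison the optimizers make).

## Optimizers

**Exact.** No MILP library is a dependency; the package ships its own
depth-first branch-and-bound over the marker binaries, specialized to the two
model shapes. Markers are branched in descending order of initial greedy
effect; pruning uses (a) a covering lower bound
$\max_{ij} \lceil r_{ij} / \max_{k \in \text{remaining}} p_{ijk} \rceil$ for
the count objective, (b) the already-accumulated $g$ for the adjacency
objective (admissible because every $q_{kl} > 0$ for $k > l$, so $g$ only
grows), and (c) suffix power sums for infeasibility detection. The
greedy/neighborhood solution primes the incumbent. Optimality is exact; a
`time_limit` (default 3600 s) degrades the status to `feasible-not-proven`
with the best incumbent. Worst-case cost is exponential: the exact solvers
are intended for panels up to a few dozen markers (the test suite proves them
against exhaustive enumeration at $m \le 15$), while genome-scale inputs go
to the heuristics. The returned adjacency objective is recomputed
independently as $x^\top Q x$ and asserted equal to the linearized
$\sum q_{kl} y_{kl}$ within $10^{-6}$.

**Greedy.** A residual matrix $r_{ij}$ starts at $h$. Marker $k$'s gain is
$z_k(r) = \sum_{ij} \min(p_{ijk}, r_{ij})$ — power a pair no longer needs is
not re-counted — and its effect is $e_k(r) = z_k(r) / \mathrm{denom}(k)$ with

$$\mathrm{denom}(k) = 1 + \sum_{l \in M} [\, q_{kl} > 1 \,],$$

a *static* same-chromosome marker-density penalty: markers sitting in
crowded regions are discounted throughout the run. (The indicator sum can be
zero for isolated markers, hence the $+1$.) We evaluated a
selection-dependent denominator — discounting only proximity to the markers
already chosen — and rejected it: it steers greedy so strongly away from
clustering that the subsequent neighborhood search has nothing left to
improve, which contradicts the observable division of labour between the two
stages (greedy covers cheaply, the search then repairs localization). After
adding the argmax marker, $r_{ij} \leftarrow r_{ij} - \min(p_{ijk}, r_{ij})$;
the loop ends at $r = 0$. Ties break to the lowest marker index, so the
whole pipeline is deterministic. Pairs whose total available power over all
markers is below $h$ (clones, duplicated accessions) would make the loop
diverge; they are removed up front by `drop_infeasible_pairs()` and reported,
and every downstream guarantee is relative to the reduced pair set.

**Neighborhood search.** Each round first tries all 1-flips (drop a selected
marker if feasibility survives; $f$ falls and $g$ cannot rise), then 2-flips:
for each selected $s$, the top $\lceil v \cdot \#\text{non-selected} \rceil$
non-selected markers ranked by $|$Pearson correlation$|$ of dosage vectors
with $s$ are tried as replacements (a highly correlated marker is the most
plausible substitute). A swap is accepted when feasible and either $g$
strictly decreases, or $g$ ties (within $10^{-9}$) and the depth increases —
depth acts only as a tie-breaker, never overriding a $g$ improvement, and
exists to avoid early convergence. Acceptance is first-improvement within a
pass, orders are by marker index, and the candidate list never falls below
one entry even at $v = 0$ (the ceiling rule as the examples exercise it).
Rounds repeat until a full round changes nothing or `max_rounds` (default
50; convergence is typically well under 10). The flip fraction defaults to
$v = 0.2$, the upper end of the 5–20 % range that works well in practice;
zero-variance or incomplete correlations are treated as 0.

## Synthetic data: what it emulates and what it does not

`generate_panel()` draws founder dosages from Hardy–Weinberg proportions at
per-marker allele frequencies sampled uniformly on $[0.05, 0.5]$ (the
frequency refers to the non-maternal allele; 0.05 mirrors the usual
minor-allele-frequency floor applied before selection), assigns markers
round-robin to 17 chromosomes of 40 Mb (a typical diploid fruit-tree
karyotype and genome size) at distinct uniform positions, and adds
family blocks by per-marker Mendelian transmission: full-sib families
(children of two founders) and parent–offspring chains (each member a child
of the previous one and a founder). The mother is homozygous-reference
everywhere by construction. `simulate_offspring()` transmits one paternal
gamete per marker (0, 1, or Bernoulli(½) for dosages 0, 2, 1), independent
across markers and offspring, with 5 offspring per candidate father as the
default evaluation harness; `mask_genotypes()` hides each cell independently
with the given probability.

The generator deliberately omits linkage between loci (the downstream model
assumes linkage equilibrium, and the adjacency objective exists precisely to
make that assumption defensible for the *selected* set), genotyping *errors*
(wrong calls, as opposed to missing calls), null alleles, and polyploidy.
Passing tests therefore demonstrate correctness of the optimization and the
exclusion logic under the model's own assumptions — not robustness to
miscalls or to LD structure in a real germplasm, which must be assessed on
real data.

## The exclusion assigner and its honest limits

`assign_paternity()` retains, per offspring, the candidates with at most
`max_mismatch` impossible-gamete loci (offspring gamete 1 against a dosage-0
father, or 0 against a dosage-2 father; missing loci skipped) and assigns
only a *unique* survivor — ties and empty sets are withheld, never guessed.
With clean genotypes the true father can never be excluded, so false
positives are structurally zero; this invariant is asserted across the test
suite.

The conservatism has a measurable cost. A wrong candidate $j$ is excluded by
an offspring of true father $i$ only through loci where $i$ is heterozygous
and $j$ opposing-homozygous (probability ½ each) or through opposing
homozygotes (certain). Loci with $p_{ijk} = 1$ split their power between the
two directions of the pair, and shared-heterozygous loci ($h^{-1}$) have *no*
exclusion ability at all. Parent–offspring candidate pairs never admit
opposing homozygotes, so their coverage is all of the coin-flip kind: at the
feasibility minimum $\sum p \approx h$, the wrong member survives with
probability near $2^{-h/2}$, and offspring facing many such relatives
accumulate ties. On the package's canonical synthetic study (below) this
yields ~78 % unique-assignment at $h = 8$ rising to ~98 % at $h = 16$ —
likelihood-based software (e.g. Cervus, for which `export_cervus()` writes
input files) resolves most of these withheld calls by ranking survivors,
which is exactly the machinery this package intentionally does not
reimplement.

Because masking only *removes* loci, it can never create a mismatch against
the true father; `max_mismatch = 0` therefore remains correct under pure
missingness and is the default. Raising it to $\lceil \text{rate} \times f
\rceil$ is recommended once masking exceeds ~1 % *and* genotyping errors are
suspected; note that any increase also retains near-miss wrong candidates
and so trades false negatives for ties.

## Numerical and degenerate-input choices

* Feasibility comparisons use an absolute tolerance of $10^{-9}$ (powers are
  sums of $1$, $h$, $h^{-1}$; $h$ may be any positive real, not only an
  integer).
* Same-chromosome markers at identical positions make $q$ undefined
  (division by zero) and are fatal in `build_adjacency()`; unmapped markers
  are placed on private pseudo-chromosomes (weight 1 against everything,
  i.e. no distance claim) with a prominent warning.
* LD pruning is a single deterministic pass per chromosome in (position,
  marker id) order: a marker is dropped if it is within `min_bp` of the last
  *kept* marker or if its squared correlation with any of the previous
  `window − 1` kept markers exceeds `r2_max`; defining the window over kept
  markers makes the operation idempotent. This is a simplified PLINK-style
  pass, not a PLINK replica.
* Median with even counts: midpoint. Greedy and search tie-breaks: lowest
  marker index. Pair enumeration: lexicographic $(i, j)$, $i < j$.
* All randomness flows through explicit integer seeds; fixed seeds give
  bit-identical panels, offspring, masks, and therefore solutions.

## Study sizes used by the shipped checks

The end-to-end suite uses a 65-candidate population (40 founders, a
20-member full-sib family, a 5-deep parent–offspring chain) typed at 1,000
markers with 5 offspring per father, and exact-solver verification uses
exhaustive enumeration over all $2^m$ subsets at $m \le 15$, $n \le 6$ —
sizes chosen so an exhaustive oracle is still computable and the whole suite
completes in well under a minute on one core. The neighborhood-search
improvement suite uses 20 founder-only instances at $n = 40$, $m = 500$,
$h = 8$; at that scale greedy covers are exactly tight, so the search
improves localization ($g$, in 18 of 20 instances) but has no slack to
shrink $f$ — shrinking appears once family structure forces over-coverage,
as in the canonical study.

## Known limitations

* Physical distance proxies genetic distance in $Q$; a genetic-map-based
  weight would be the natural refinement where maps exist.
* The exact solvers do not scale to genome-wide marker pools; they exist to
  certify the heuristics and to solve small panels to proven optimality.
* Diploid, biallelic markers only; no imputation, no phasing, no error
  model.
* The assigner is exclusion-only by design; confidence-calibrated
  likelihood inference is delegated to external software via the Cervus
  export.
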