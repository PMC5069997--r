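---
title: "The dual partition function: model, algorithms and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The dual partition function: model, algorithms and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dualpf)
```

## The problem

RNA inverse folding asks for sequences whose minimum free energy (MFE)
structure is a prescribed target `s0`.  Instead of searching that space
heuristically, this package works with the *dual partition function*

$$Z^*(s_0) \;=\; \sum_{a \,\in\, \mathbb{A}(s_0)} e^{-E(a,\,s_0)/RT},$$

the sum of Boltzmann factors of **all** sequences `a` compatible with
`s0` (Watson–Crick or GU wobble nucleotides at every base pair).  It is
the sequence-space mirror of the McCaskill structure-space partition
function: where McCaskill sums structures of one sequence, `Z*` sums
sequences of one structure.  From `Z*` we obtain

* exact Boltzmann-weighted *sequence sampling*, `p*(a) ∝ exp(-E(a,s0)/RT)`,
  by stochastic backtracking, optionally conditioned on an exact
  GC-content and restricted by per-position IUPAC constraints;
* *dual thermodynamics*: the dual ensemble free energy
  `G* = -RT ln Z*`, the dual expected energy `⟨E*⟩`, the dual entropy
  `S* = (⟨E*⟩ - G*)/T` and a dual heat capacity;
* inputs for mutational robustness and plasticity analyses, where
  sampled sequences serve as GC-matched controls for a wild-type
  sequence.

Because the target structure is fixed, the loop decomposition is known in
advance and the computation is a product over loops rather than a cubic
dynamic programme: one pass over the base pairs in inner-to-outer order
suffices (linear in the number of loops for the d0 dangle model).

## Energy model

The free energy `E(a, s0)` is the additive Turner nearest-neighbour loop
model evaluated on the fixed loop decomposition of `s0`: stacking
energies, hairpin/bulge/interior initiation by loop size (with the
Jacobson–Stockmayer `1.75·RT·ln(size/30)` extrapolation beyond 30),
terminal mismatches for hairpins and interior loops, interior-loop
asymmetry `min(asym·|r1-r2|, maxAsym)`, the multiloop affine penalty
`a + b·(branches) + c·(unpaired)`, terminal AU/GU penalties
(0.5 kcal/mol), and — in the d2 dangle model — 5' and 3' dangle energies
on both flanks of every multiloop/external-loop helix.  The Turner 2004
tables (37 °C) ship with the package in a documented plain-text grammar
(`inst/extdata/turner2004.txt`; see `?load_parameters`), including the
dedicated 1×1, 1×2 and 2×2 interior-loop tables and the special
tri-/tetra-/hexaloop bonuses.  Special-loop energies are stored as
*bonuses relative to the generic hairpin term* of their size, which is
the form the recursions consume; they were converted from the customary
replacement-style totals at transcription time.

Two conventions are deliberately switchable, because the published
equations and the published worked example disagree and the example is
the ground truth we validate against:

* **Size-1 bulges** (`bulge_convention`): the default `"stack"` retains
  the stacking energy across the bulge and applies no terminal penalty
  (terminal penalties on both closing pairs appear only for larger
  bulges); `"literal"` uses initiation plus the outer terminal penalty at
  every size.  Only `"stack"` reproduces the worked example's bulge row.
* **Small interior loops** (`small_internal`): the default `"tables"`
  scores 1×1, 1×2, 2×1 and 2×2 loops from the lookup tables;
  `"generic"` applies the size-based formula everywhere.  Only
  `"tables"` reproduces the worked example's interior-loop row.  In the
  generic pathway, flank positions shared between the two closing pairs
  of a 1×N loop are enumerated once (exact sharing), the same treatment
  the sampling conditionals use.

Terminal AU/GU penalties are applied in two distinct roles: a plain
penalty on pairs closing a triloop, a (size >1) bulge, an interior loop,
or a multiloop; and an indicator-gated penalty on every pair that closes
a component of a multiloop or of the external loop (the outermost pair of
a stem).  A pair can legitimately incur both, once per role.

## The recursions and the group decomposition

`Z*(i,j;X,Y)` — the dual partition function of the substructure enclosed
by pair `(i,j)` with its closing nucleotides fixed to `X,Y` — is computed
for all six canonical pairs of every base pair, in the total order that
ranks a pair after every pair it encloses and after left siblings.  Each
loop type contributes a closed-form sum over its energy-relevant
positions; positions with no energy contribution contribute a bare count
(a product of allowed-set sizes under IUPAC constraints).

For d2 multiloops and external loops, helices whose dangle positions
overlap (gap of at most 2 between consecutive helix ends; a multiloop
closing pair within 2 of a component) are merged into maximal *adjacency
groups*, closed transitively.  Within a group, all base pairs and their
distinct dangle positions are enumerated jointly: a dangle position that
coincides with a paired position is forced to that pair's nucleotide, and
a position shared by two dangle roles is a single summation variable
entering both energy terms.  The implementation compiles each loop into
such *group tables* — one Boltzmann weight per joint instantiation,
conditioned on the closing pair where needed — and the same tables drive
the forward computation, the GC-resolved computation and the sampler.  A
group of `h` helices stores at most `6^h · 4^(h+1)` rows; a guard refuses
groups beyond 10⁷ rows (run time of the d2 model is exponential in the
branching of the largest multiloop, which is never a limit for natural
targets).

**Scaling.**  `Z*` grows geometrically in `n`, so the scaled quantities
`Z†(i,j;X,Y) = Z*(i,j;X,Y)/C^(j-i+1)` are propagated instead and
`ln Z* = ln Z† + n·ln C` is recovered exactly.  The default
`C = exp(-⟨stack⟩/2RT)` (geometric mean of stacking Boltzmann weights per
nucleotide) keeps intermediate values near 1; any positive constant gives
the same results, and the sampler is invariant to `C` because every
roulette uses ratios in which the scale cancels row-wise.

## GC-resolved computation

Every quantity can be resolved by exact GC content: the per-pair values
become vectors `Z*(i,j;X,Y;α)` over the GC count `α` of positions
`i..j` (including `X`, `Y`), group sums become convolutions over the GC
budgets of components, and blocks of energy-free positions contribute the
combinatorial count of assignments with a prescribed number of G/C —
`choose(m,k)·2^m` unconstrained, and a position-by-position convolution
under IUPAC constraints (`count_constrained_assignments()`).  The
top-level vector `Z*(s0,k)`, `k = 0..n`, marginalises to `Z*(s0)`
exactly, and its support equals the feasible GC range implied by the
constraints.  The cost is a factor `O(α²)` over the plain computation,
which is accepted as is; no truncation heuristics are used.

## Sampling

Sampling backtracks outer-to-inner: the external loop first, then base
pairs in descending order.  At each step the roulette wheel draws a joint
instantiation of one group table with probability proportional to its
stored mass times the (already computed) `Z*` factors of inner
components, so every decision is an exact conditional partition function
ratio and the sampled sequences are i.i.d. from `p*`.  Positions with no
energy contribution are filled uniformly over their allowed sets — except
the interiors of tri-, tetra- and hexaloops, which are drawn from the
bonus-aware conditional since special loops perturb the distribution.
With a GC target, the loop-level GC budgets `(α_1..α_k, β)` are first
drawn by roulette over the GC-resolved masses (sequentially, against
suffix convolutions of the remaining components), then nucleotides are
instantiated; G/C placements among energy-free positions are drawn
uniformly over the count-weighted arrangements by a sequential
conditional derived from the counting convolution.  Roulette outcomes
are scanned in a fixed canonical order (pairs AU, CG, GC, UA, GU, UG;
nucleotides A, C, G, U; budgets ascending), so a seed reproduces the
identical sample stream, bit for bit, across scaling constants.

An optional rejection step (`filter_mfe`) retains only sequences whose
MFE structure (per a folding backend) equals the target; this is a
post-processing convenience, not part of the distribution contract.

## Dual thermodynamics: table vs formal temperature

The energy tables are free energies at the table temperature
`T0 = 310.15 K`; no enthalpy tables are used.  The *formal* temperature
`T` appears only in the Boltzmann exponent `RT`.  The dual expected
energy is the derivative of `ln Z*(s0, T0, T)` in the formal temperature
at `T = T0`, computed by a central finite difference with default step
`h = 0.01 K`:

$$\langle E^* \rangle = R\,T_0^2\,
  \frac{\partial}{\partial T}\ln Z^*(s_0, T_0, T)\Big|_{T=T_0}.$$

`G* = -RT ln Z*` and `S* = (⟨E*⟩ - G*)/T` are then definitional
identities (held to machine precision by construction).  The central
difference converges quadratically in `h`; `h` much below ~10⁻⁴ K loses
precision to cancellation, and an error suggests enlarging it.  The dual
heat capacity is exposed as `C*_p = ∂⟨E*⟩/∂T` by a further central
difference — the quantity has no validated application and the formula is
this package's documented choice.

## Ensemble metrics and folding backends

The metric layer works on base-pair probability matrices `p_ij`:
ensemble diversity `d0 = 2·Σ_{i<j} p_ij(1-p_ij)` (the expected base-pair
distance of two independent draws from the ensemble), plasticity
`P = d0/(n/2)`, the asymmetric `d1(a,b)` (expected cross distance minus
`d0(a)`), and the ensemble distance
`D_V(a,b) = sqrt(Σ (p_ij(a)-p_ij(b))²)`, a true metric.  Mutational
robustness averages `D_V` (default) or `d1` over all `3n` single-point
mutants; neutrality averages the base-pair distance between mutant MFE
structures and the wild-type MFE structure.  The positional entropy uses
pairing states `{unpaired} ∪ {paired with j}` and natural logarithms.

Folding is pluggable.  The reference backend enumerates the complete
structure space of a sequence (θ = 3) and scores it with this package's
own evaluator, giving exact MFE structures and pairing probabilities with
no external dependency; it is exponential and intended for sequences up
to roughly 25–30 nt.  An adapter to the ViennaRNA `RNAfold` executable
covers realistic lengths, and a stub backend wraps user functions for
testing the formulas.  Note the external engine's energy model differs in
detail (coaxial stacking treatment, 1×N mismatches), so cross-backend
numbers agree closely but not bitwise.

## Validation strategy, problem sizes, and what it does not show

The worked 28-nt example (two-stem multiloop, triloop, constrained
tetraloop) has externally known per-pair values; the package reproduces
all eight rows and the total to the printed three decimals, which pins
down the stack orientation, the AU-penalty placement, both convention
switches, and the d0 external-loop assembly.  Everything else is tested
against *enumeration oracles*: randomized well-nested targets of length
12–14 with random IUPAC constraints (kept under ~10⁵ compatible
sequences) are summed exhaustively through the standalone energy
evaluator and compared with the dynamic programme at 10⁻⁹ relative
tolerance, in both dangle models, plain and GC-resolved.  The sampler is
validated by chi-square goodness of fit against the exact distribution on
fully enumerable targets (plain, constrained, and GC-conditioned).  At
200,000 draws over a support of ~6000 sequences an *exact* sampler has an
expected total-variation distance of ≈0.05 from the target distribution
(multinomial noise), so small TV values per se are not evidence of
exactness and the goodness-of-fit test is the decisive check.

These fixtures exercise every loop type, but they are short: they do not
probe numerical behaviour at natural RNA lengths (hundreds of
nucleotides; covered by the scaling machinery but not by enumeration),
nor do they say anything about how well sampled sequences *fold back*
into long targets — the MFE-identity rate of sampled sequences against a
folding engine is a property of the energy model and the target, not of
the sampling algorithm's correctness.  Pseudoknots, multi-strand
complexes, coaxial stacking and enthalpy-based temperature rescaling are
out of scope.

## Worked example

```{r}
db <- "(((.((...)).)).(((....)).))."
iu <- paste(replace(replace(rep("N", 28), 18, "G"), 23, "C"), collapse = "")
tgt <- parse_target(db, iu)
st <- dual_pf(tgt, turner_params(), mode = "d0", scale = 1)
bp_table(st)
log_dual_partition(st)
rec <- sample_sequences(st, 5, seed = 1)
rec
```
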