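---
title: "Methods: assessing quaternary-structure functionality in homodimers"
author: "quatfun authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: assessing quaternary-structure functionality in homodimers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(quatfun)
```

## The question and the model

A homodimer interface can be maintained by purifying selection without
contributing to biochemical function: hydrophobic-biased missense
mutations create sticky surface patches, and once two protomers associate,
exposing the patch again is deleterious. `quatfun` operationalises the
question "does this interface do anything?" as three independent,
per-complex statistics, each contrasting a *focus* set of residue pairs or
residues against a *reference* set from the same protein, so that
protein-specific baselines cancel:

1. **Interface coevolution Z.** Focus: evolutionary coupling scores of
   residue pairs in direct contact across the interface. Reference:
   couplings of interface residues with the non-interface residues they
   contact. `z = (mean_f − mean_r) / sd_r`, with the sample SD (ddof 1).
   Both distributions are Yeo–Johnson transformed, with λ chosen to
   maximise the Gaussian profile log-likelihood of the *reference*
   distribution (Brent search on [−5, 5]); raw coupling scores are
   right-skewed, and the transform makes the Z scale comparable across
   proteins. Significance is a two-sided Wilcoxon rank-sum test (normal
   approximation with tie and continuity correction) — note the rank-sum
   p-value is invariant under any monotone transform, so the transform
   affects `z`, never `p`.
2. **Ligand–interface coevolution Z.** Focus: couplings between
   ligand-binding residues (LBRs) and interface residues. Reference:
   couplings between LBRs and solvent-accessible surface residues. Not
   transformed (these distributions are close to normal). A positive,
   significant value says the binding site is evolutionarily tied to the
   interface specifically, not just broadly conserved.
3. **Coupling–dynamics R².** For each interface residue `i`,
   `x_i` = mean coupling of `i` to the LBRs and `y_i` = mean dynamic
   cross-correlation of `i` with the LBRs in an elastic-network
   normal-mode model; R² is the squared Pearson correlation of `(x, y)`
   with the correlation-test p-value. A positive association says the
   residues that coevolve with the binding site are also the ones
   mechanically coupled to it — the capacity to transmit information from
   the ligand across the interface.

A fourth statistic, the **conservation delta**
`Δ = mean(surface score) − mean(interface score)` (ConSurf convention,
lower = more conserved; positive Δ = interface more conserved), captures
selection on the interface independent of any ligand assumption, with a
rank-sum test between the two residue-score samples.

### Residue annotation

Interface residues form inter-chain atom contacts under
`d ≤ r_i + r_j + 2 × 0.25 Å` with a fixed element-keyed van der Waals
table (C 1.7, N 1.55, O 1.52, S 1.8, P 1.8, H 1.2, default 1.8 Å);
residues contacting only a ligand are not interface. Interface size is the
two-chain sum. LBRs are residues whose Shrake–Rupley solvent-accessible
area changes by more than 1e-3 Å² (quadrature-noise floor) when the ligand
is removed, at a 0.21 Å probe — the probe size that best reproduces
curated binding-site annotations in the source analysis. Surface residues
have RSA > 0.2 in the full complex (residue SASA over its extended
Gly-X-Gly reference area, Tien et al. 2013 values) and carry no other
annotation; RSA itself uses the standard 1.4 Å water probe. A binding site
is multichain (MBS) iff its LBRs span ≥ 2 chains; a complex is MBS iff any
relevant non-metal ligand is MBS; metal-only ligands never enter any
statistic. The ligand–interface distance is the mean over interface
residues of the distance to the nearest LBR (minimum heavy-atom distance);
the alternative all-pairs average is available via
`ligand_interface_distance(policy = "all_pairs")` because the source text
is ambiguous between the two readings.

### Classification

Per complex, the best ligand is selected by the statistic at hand (largest
Z for coevolution, largest R² for dynamics; in MBS complexes only MBS
ligands are candidates; ties break lexicographically by ligand id).
Complexes with < 40 interface residues (≈ 1000 Å², the crystallographic
artifact regime) or Neff/L < 1 are excluded. Among complexes passing the
gate — LBRs coevolve significantly more with each other than with the
surface, Benjamini–Hochberg corrected — a method flags a complex
*putatively non-functional* when its statistic is ≤ 0 or not significant
after BH (for R², when the correlation is not significantly positive;
R² ≥ 0 by construction, so the sign criterion moves to the underlying
correlation). Complexes are stratified at 100 interface residues. Venn
overlaps of the three flag sets are compared against a simulated random
expectation: subsets of the observed sizes drawn uniformly without
replacement, 1000 replicates by default (10,000 in the acceptance report),
mean ± SD reported, with the analytic check
`E[triple %] = 100 · Π(size_k / N)`.

The MBS-vs-SBS class effect on any statistic is tested by type-III ANCOVA
(OLS with marginal F tests) on log-transformed covariates — structure
size, interface size, ligand distance, LBR coevolution, Neff — with
backwards elimination of covariates at p > 0.05; the class factor is never
eliminated.

## Tunable parameters

| parameter | default | unit | why |
|---|---|---|---|
| contact probe | 0.25 | Å | interaction criterion of the residue-network tool the interface definition follows |
| LBR probe | 0.21 | Å | maximises agreement with curated binding-site residues |
| RSA probe | 1.4 | Å | standard water probe |
| RSA cutoff | 0.2 | — | conventional surface threshold |
| LBR SASA tolerance | 1e-3 | Å² | absorbs quadrature noise at 960 sphere points |
| interface minimum | 40 | residues | below ≈ 1000 Å² most interfaces are crystallographic |
| stratum boundary | 100 | residues | small/large interface split |
| ENM cutoff | 15 | Å | standard anisotropic-network cutoff at Cα resolution |
| zero-mode threshold | 1e-8 | relative | separates rigid-body modes |
| α | 0.05 | — | BH FDR level throughout |
| overlap replicates | 1000 | — | SE of the expectation ≈ 0.04 % |
| FVA affected threshold | 0.5 | fraction | flux reduced by more than 50 % |
| FVA blocked threshold | 1e-6 | mol/day | numerically zero flux |

All of these live in `default_config()` and are serialized (with a hash
and the seed) into every pipeline report.

## The synthetic world

`generate_dimer()` emits a pseudo-homodimer: two chains of 98 residues
(one Cα and one sidechain pseudo-atom each), each serpentine-folded into
7 stacked rows of 14 columns, the two slabs facing in y. The central
6 columns of rows 2–6 bend inward so that facing residues sit at 3.5 Å
(in contact at any probe ≥ 0.05 Å) while every non-planted inter-chain
pair is ≥ 4.88 Å (no contact at any probe ≤ 0.5 Å) — interface recovery
is therefore *exact*, not approximate. The back rows touch the interface
columns from behind, providing the interface/non-interface contacting
pairs that form the reference class. Ligands are placed in pockets whose
occlusion sets are known by construction: MBS ligands bridge the two
chains in the interface groove (two symmetric sites by default), SBS
ligands sit on the outer face of one chain at a controllable offset from
the interface edge, so MBS ligands are nearer the interface by
construction, mirroring the covariate structure of real complexes.

`generate_couplings()` draws i.i.d. lognormal baselines (meanlog −2,
sdlog 0.5 — right-skewed, so the Yeo–Johnson machinery is exercised
non-trivially) for all residue pairs and adds effects in units of the
analytic baseline SD: cross-interface pairs (+2 SD), LBR–interface pairs
(+3 SD), LBR–LBR pairs (+3 SD), and a motion–coupling *alignment* term —
`4 SD × exp(−d/10 Å)` on LBR–interface pairs, `d` the within-protomer Cα
distance. The alignment term is the one planted quantity with no stated
counterpart; it encodes "high-coupling interface residues sit in the
binding site's elastic neighbourhood" without ever touching the DCCM, so
the dynamics module remains an honest, independent measurement. The decay
length matches the elastic correlation lengthscale of the toy fold, and
the strength is of the same order as the other planted effects.
Conservation scores are N(0, 1) with the interface shifted by −1 (more
conserved); variants draw alternate alleles from a spectrum with
cysteine at `4/20` and the rest uniform, planting the ~4× cysteine excess
of human missense variation.

`generate_cohort()` labels complexes *functional* (all effects planted)
or *gratuitous* (interface-related effects zero) — but the gratuitous
profile keeps LBR–LBR coevolution, because a neutral interface does not
imply a dead binding site, and the flagging gate requires it.

### What a green test does and does not establish

The generator emulates the *statistical* structure the analysis assumes —
pair-class contrasts, effect sizes, alignment quality — on an idealised
geometry. It does not emulate: real packing or energetics, alignment
noise correlated with phylogeny, heterogeneous per-site conservation
rates, asymmetric interfaces, or crystallographic artifacts. Green
acceptance tests therefore establish that the pipeline *recovers planted
truth at the stated rates and is calibrated under its null*, not that it
reproduces the published cohort percentages on real PDB data (which
require the external datasets and are out of scope). Two cohort-level
published numbers *are* reproduced because they are pure arithmetic or
desk-scale simulation: the flagged-by-all-three fractions (24/222 =
10.8 %, 6/135 = 4.4 %) and the random-expectation overlaps
(5.5 ± 1.3 % triple, 32.5 ± 1.7 % at-least-two, for sizes 93/86/75 in a
universe of 222).

## Numerical choices and degenerate inputs

- **SASA** uses a deterministic golden-angle lattice (960 points);
  doubling the density moves per-atom values by ≪ 0.5 Å², far below the
  1e-3 Å² LBR criterion's role (the criterion compares the same lattice
  with and without the ligand, so quadrature error cancels except through
  occlusion changes).
- **Elastic network**: connectivity is checked by BFS and disconnection
  is an error naming component sizes. The rigid-body null space must be
  exactly six-dimensional; collinear node sets (five rigid modes) are
  recognised so the two-node stretch case works. Sparsely sprung
  quasi-1D chains possess internal floppy mechanisms (> 6 near-zero
  modes); `compute_dccm()` refuses them rather than silently inverting a
  near-singular Hessian.
- **R² in a homodimer**: coupling scores are sequence-level, so the two
  protomers contribute identical x-values. Using both chains' interface
  residues would double the apparent sample size and inflate the
  correlation test (~25 % type-I error measured under the null). The
  pipeline therefore restricts the point set to one protomer by default
  (`dccm_chains = "first"`; `"all"` available), matching how per-chain
  correlation maps are usually presented. Interface residues that are
  themselves LBRs stay in the point set (their self-pairs are dropped
  from the coupling mean); `exclude_direct = TRUE` removes them together
  with all interface residues in direct contact with the site — the
  exclusion variant that isolates the contribution of direct site–
  interface interactions.
- **Yeo–Johnson λ**: profile log-likelihood with the Jacobian term,
  Brent search on [−5, 5]. With very small reference samples the optimum
  can sit at the boundary; the fitted λ is always reported in the result.
  One subtlety: λ = 0 linearises `log1p` only on the non-negative branch,
  so "log recovers normality" holds only for predominantly positive
  samples — `exp(N(0,1)) − 1` has MLE λ ≈ −0.26, not 0.
- **Simplex FVA**: two-phase dense simplex, Bland's rule (no cycling),
  bounds handled by variable shifting plus slack rows; LP tolerance
  1e-9, results clamped to zero below it. Adequate and exactly
  reproducible for the toy models in scope; not intended for
  genome-scale networks.
- **Knockouts**: a knockout closes reactions whose gene–protein–reaction
  rule evaluates false; those directly-disabled reactions are excluded
  from the *affected* set (otherwise every knockout would trivially
  "affect" its own reactions and redundancy would be undetectable).
  `knockout()` takes a vector for combined knockouts, since GPRs
  re-evaluate against the full knocked set.
- **Ties and determinism**: ligand selection ties break lexicographically;
  every simulation takes an explicit seed; pipeline reports embed config
  hash and seed; all generators are byte-identical under a fixed seed.

## Design choices where the design was open

- The interface-Z reference class uses *contacting*
  interface/non-interface pairs (matching the interaction-network
  reading); `coupling_pair_classes(reference_policy = "all_pairs")`
  provides the all-pairs alternative.
- The per-structure conservation significance test is a Wilcoxon rank-sum
  on residue scores (two-sided by default, one-sided available), chosen
  for consistency with the other tests; the multiple-testing correction
  across structures is BH at 0.05.
- The FVA "reduced by more than 50 %" criterion compares the maximum
  absolute feasible flux (`quantity = "max_abs"`); `"min_abs"` and
  `"span"` are flag-selectable since the source is silent on which FVA
  quantity was compared.
- The variant-composition regression defaults to variants on x and region
  frequencies on y; both axes are caller-controlled in
  `slope_vs_one_test()`.

## Known limitations

- The Cα elastic network is a coarse stand-in for all-atom normal modes;
  absolute DCCM values differ from all-atom results, and only
  transform-invariant conclusions (signs, correlations, mode counts)
  should be compared across methods.
- Gratuitous MBS complexes are hard to flag by the coevolution methods by
  construction: their binding-site pairs lie inside the interface, so
  site coevolution leaks into the ligand-interface contrast. This mirrors
  the confounding acknowledged for multichain sites in the source
  analysis; the end-to-end separation guarantee is for SBS dimers.
- The single-chain R² signal is intrinsically weaker than the multichain
  one (the site sits off-interface, and motional contrast across the
  interface block is limited); in cohort flagging this manifests as low
  R²-method sensitivity for SBS complexes — consistent with the method's
  behaviour on real data, where the R² flag set is the noisiest of the
  three.
- The synthetic surface truth is the set of geometry-exposed residues;
  a minority of interior slab residues fall below RSA 0.2 and drop out of
  the computed surface. All planted statistics are unaffected (surface
  scores are exchangeable), and tests compare computed sets against the
  designed supersets accordingly.
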