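---
title: "Validating and dissecting NMR conformational ensembles with ensdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating and dissecting NMR conformational ensembles with ensdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ensdyn)
```

## The problem

Restrained molecular-dynamics protocols produce *conformational
ensembles* — ordered sets of all-atom models sharing one topology — that
are meant to represent both the structure and the fast internal dynamics
of a protein in solution. A classic application is the intracellular
lipid-binding protein family: a ten-stranded antiparallel β-barrel capped
by two helices, whose internal binding cavity is only accessible through
transient openings of the barrel. Whether such an ensemble is *consistent*
with solution NMR data, which collective motions it contains, and whether
any of its conformers resemble a sparsely populated "invisible" state seen
only by relaxation-dispersion NMR, are questions that recur across such
studies. `ensdyn` implements that post-simulation analysis chain as
composable, tested R functions.

The pipeline has six analysis stages, plus a synthetic-data generator that
makes each stage testable end to end without any external downloads:

1. **NOE restraint evaluation** — preprocessing (removal of
   stereospecificity, integer-Å binning) and per-ensemble violation
   statistics under r⁻⁶ averaging;
2. **S² order parameters** — back-calculation from amide N–H bond vectors
   and plain / outlier-corrected correlation with experiment;
3. **chemical shifts** — ensemble-averaged predictions from a pluggable
   structure→shift map, correlated with experimental tables;
4. **collective modes** — iterative superposition, pooled PCA,
   per-residue square fluctuations, pairwise backbone RMSD, and the
   correlation of every Cα–Cα distance with each mode;
5. **hydrogen-bond networks** — distance–angle detection, per-ensemble
   occupancies, and apo/holo occupancy differencing;
6. **invisible-state selection** — scoring pool conformers against
   CPMG-derived |Δω|(¹⁵N) profiles via predicted shift differences.

## Models and conventions

### NOE restraints and r⁻⁶ averaging

A distance restraint couples two (possibly ambiguous) proton groups with
an upper bound in Å. Preprocessing follows the convention of
ensemble-restrained simulations:

* **Removal of stereospecificity** (`destereo()`): any stereospecific
  proton name is replaced by its full stereo-equivalent set resolved
  against the topology — methylene HB2/HB3 pairs, the six protons of a
  Val/Leu isopropyl group, symmetric aromatic ring positions, and freely
  rotating methyl and amine groups.
* **Binning** (`bin_upper_bound()`): bounds are rounded *up* to the next
  integer Å, forming 1 Å bins on 4–10 Å. Reading "rounding up" as the
  ceiling makes integers their own bin; bounds below 4 Å clamp to the
  4 Å bin, and bounds above 10 Å are rejected as outside the declared
  range.

Evaluation (`effective_distance()`) applies r⁻⁶ averaging at both levels:
within a restraint, the inverse sixth powers of all cross-pair distances
are **summed** (the standard pseudo-atom convention; a mean-combination
variant is exposed via `combine = "mean"`), and the per-member sums are
averaged uniformly over the ensemble before the −1/6 power. A binned
restraint is *violated* when its effective distance strictly exceeds
`bin + tolerance`, with tolerance 0.5 Å by default. `filter_unviolated()`
implements restraint-list transfer between ligation states: keep only
restraints unviolated in a reference ensemble, which by construction
re-evaluate to 0.00 % on that reference.

Uniform member weights are assumed throughout; the upstream replica
structure is not reweighted.

### S² order parameters

For each residue with an observable amide, the unit N–H vectors over
members enter the symmetric second-moment form

$$S^2 = \tfrac{3}{2}\left(\langle x^2\rangle^2 + \langle y^2\rangle^2 +
\langle z^2\rangle^2 + 2\langle xy\rangle^2 + 2\langle xz\rangle^2 +
2\langle yz\rangle^2\right) - \tfrac12,$$

clipped to [0, 1] within 1e-9 (values outside that tolerance are treated
as bugs and raise an error rather than being silently clipped). Prolines
and residues lacking an amide hydrogen are skipped, matching NMR
observability. No vibrational correction factor is applied.
`s2_compare()` reports the Pearson correlation over shared residues and a
*corrected* correlation that excludes residues with |experimental −
calculated| > 0.2; with an infinite cutoff the two are identical by
construction.

### Chemical shifts

Real applications use an external empirical predictor; `ensdyn`
integrates predictors by reading their output tables
(`read_shiftx_table()`), never by invoking binaries from library code. A
deterministic **surrogate predictor** ships for testing and synthetic
benchmarks: a fixed linear map from local backbone geometry (φ/ψ
dihedrals and two Cα neighbor distances) to amide ¹⁵N and ¹H shifts, with
frozen coefficients spanning realistic amide ranges. It is a sensitivity
probe with the right contract (deterministic, conformation-dependent),
not an empirical predictor; correlations computed with it say nothing
about real shift-prediction accuracy. Ensemble correlations use the
ensemble-averaged predicted shifts by default; averaging per-model
correlations instead is available via a flag, since which convention a
given external tool uses is not always documented.

### Collective modes

`superpose()` iterates least-squares fitting (quaternion-free Kabsch via
SVD, determinant forced to +1, so mirror images are never matched) onto
the running mean until the mean moves < 1e-6 Å. `pca_modes()` pools all
supplied ensembles — apo and holo conformers share one PC plane, so
state separation appears along the components — and eigen-decomposes the
3n×3n Cα covariance about the pooled mean. Mode signs are fixed by making
each mode's largest-magnitude component positive, so plots and
projections are reproducible. Per-residue square fluctuations of mode *k*
are λₖ times the summed squared residue components and therefore sum to
λₖ exactly.

`ensemble_rmsd()` follows the deposited-ensemble convention: every member
pair is fitted independently on backbone N/Cα/C′ and the within-group
mean pairwise RMSDs are summarized as mean ± sd *across* sub-ensembles
(replicas). A deposited PDB entry forms a single sub-ensemble, which
forces the "± 0" form of its reported RMSD. The exact backbone atom set
behind published RMSD tables is rarely stated; N/Cα/C′ is this package's
choice and is exposed through `selection`.

`distance_mode_correlation()` computes, for every residue pair, the
Pearson correlation between the member-wise Cα–Cα distance and the
member-wise projection on a chosen mode. Pairs with zero distance
variance are flagged `NA` rather than 0 — absence of evidence is not a
zero correlation.

### Hydrogen bonds

Donors are N/O heavy atoms with a covalently attached hydrogen (≤ 1.2 Å);
acceptors any other N/O. A bond requires H···A ≤ 2.5 Å, D–H···A ≥ 120°,
and D···A ≤ 3.5 Å. These three thresholds are package defaults chosen
from common practice (the numeric criteria in the literature this
pipeline follows are cited there only by reference); all three are
arguments of `hbond_criteria()` and pinned by tests. Occupancy is the
fraction of members where *any* hydrogen of a donor satisfies the
criteria, keyed by the donor-heavy-atom/acceptor pair; never-formed pairs
are absent from the table rather than stored as zeros.
`state_difference()` lists bonds whose occupancy changes by ≥ 0.5 between
states, labelling them by the state with the higher occupancy; "mostly"
prefixes mark margins below 0.75. The 0.75 boundary between the plain and
"mostly" labels is a package convention.

### Secondary structure

`assign_ss()` is a deliberately discrete three-state assignment built on
the classic electrostatic backbone hydrogen-bond energy
E = 0.084·332·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN) kcal/mol with the usual
−0.5 kcal/mol cutoff: helices from two consecutive i→i+4 turns (so the
minimal helix spans 4 residues; 3₁₀/π variants fold into H), strands from
DSSP-style parallel/antiparallel bridges kept only in ladders of ≥ 2
consecutive residues (isolated bridges fold into C), chains split at
Cα–Cα breaks > 4.5 Å. Continuous multi-threshold assignment programs will
disagree at element boundaries; per-residue agreement at boundaries is
not a goal of this implementation.

### Invisible-state selection

For each pool conformer, `predicted_delta()` computes the per-residue
|Δδ(¹⁵N)| relative to *each* ground-state reference conformer and
aggregates over references by the arithmetic mean (median and
per-reference minimum are exposed as alternatives). `score_candidates()`
then, per temperature, restricts both the predicted profile and the
experimental |Δω| set to their shared residues — per-temperature residue
coverage is honored, never unioned or imputed — min-max normalizes both
to [0, 1], and computes the Pearson correlation and the RMS difference of
the normalized vectors; scores are plain means over temperatures.
Normalization makes both scores invariant to positive affine rescaling of
either side; the default RMSD selection threshold 0.00603 is meaningful
*only* on the normalized scale, which is why the selection result records
it alongside the convention. Correlation is affine-invariant anyway, so
normalizing before correlating is immaterial for that score but pins the
RMSD scale. When both vectors share fewer than 3 residues at some
temperature the scoring stops with an error; a degenerate (constant)
vector skips that temperature and the skip is recorded.

Selection applies the two criteria *independently* (mean correlation
> 0.35; mean normalized RMSD < 0.00603) and returns both lists without
inventing a merged ranking, since candidates are typically inspected per
criterion.

## The synthetic-data generator

`generator_spec()` + `generate_ensemble()` produce ensembles with planted
ground truth:

* **Topology** (`make_topology()`): an idealized backbone (N, H, Cα, C′,
  O per residue) at canonical bond lengths and angles — an antiparallel
  β-hairpin closed by a tight turn, a two-residue linker, and one
  α-helix. Strand torsions are (−139°, 135°); the turn torsions
  (45°, 49°)/(131°, −47°) were frozen after a one-time optimization of
  the inter-strand hydrogen-bond energies so that the hairpin registers
  as an antiparallel ladder under the package's own bridge definition.
* **Modes** (`make_mode_vectors()`): smooth sinusoidal per-residue
  envelopes along fixed axes, explicitly orthogonalized against the six
  rigid-body motions (so superposition cannot absorb them) and against
  each other, scaled to a common norm with a 1 Å peak atom displacement
  per unit coefficient. Smooth envelopes localize each mode on part of
  the chain, giving specific residue pairs the role of distance
  reporters — the synthetic analog of turn-opening reporter distances.
* **Members**: topology + Σₖ aₘₖ·modeₖ + ε, with aₘₖ ~ N(offsetₖ, sdₖ²)
  and isotropic ε ~ N(0, noise_sd²). One seeded stream per generator
  call, consumed in a documented order (coefficients, then noise);
  coordinates are rounded to 0.001 Å — the PDB precision — making output
  bit-stable across platforms.
* **Observables** (`synth_observables()`): S² = back-calculated values +
  truncated Gaussian observation noise; NOE restraints = all
  inter-residue H–H pairs with ensemble-mean distance < 5 Å, upper bound
  = that mean distance, binned; shifts = the surrogate predictor on the
  mean structure.
* **States** (`generate_state_ensembles()`): apo and holo means separated
  by `state_displacement` along mode 1, plus planted hydrogen-bond
  switches. A switch points the donor amide hydrogen straight at the
  acceptor in the "on" state (whenever the N···O distance permits a bond)
  and swings it away in the "off" state; switch pairs are auto-selected
  among backbone pairs whose N···O distance stays bondable in ≥ 70 % of
  the members of both states, so the planted contrast is guaranteed to
  survive the mode displacement.
* **Hidden state** (`plant_hidden_state()`): a decoy pool plus one
  conformer displaced along a chosen mode (mode 2 by default, the
  "second opening" of the two-mode model); the emitted |Δω| profile is
  the planted conformer's own predicted-Δδ profile — computed with the
  same mean-over-references aggregation the scorer uses, so the
  zero-noise benchmark scores exactly (1, 0) — replicated over
  283/287/291 K with independent multiplicative noise and an independent
  80 % residue subset per temperature, emulating the partial residue
  coverage of relaxation-dispersion data.

### Default conditions, with units

| parameter | default | meaning |
|---|---|---|
| `n_residues` | 40 | chain length (hairpin + helix) |
| `n_members` | 168 | ensemble size, a typical replica-pooled restrained-MD ensemble |
| `n_replicas` | 8 | sub-ensemble tags for the RMSD ± sd convention |
| `mode_sds` | (2, 1) Å | coefficient sd of the two planted modes (4:1 variance) |
| `noise_sd` | 0.1 Å | isotropic per-coordinate noise |
| `state_displacement` | 6 Å | apo↔holo separation along mode 1 |
| `hidden_displacement` | 6 Å | hidden conformer displacement along mode 2 |
| `n_decoys` | 200 | decoy pool size |
| `dw_noise` | 0.1 | multiplicative noise on emitted |Δω| |
| `dw_temperatures` | 283, 287, 291 K | |Δω| temperatures |
| `dw_residue_fraction` | 0.8 | residue coverage per temperature |

With these defaults the apo/holo clusters *overlap slightly* in PC1 —
deliberately: real apo/holo ensembles of a breathing barrel nearly touch
in the PC plane. The clean-separation regime used by the separability
test (`mode_sds = (0.5, 1)`, displacement 6 Å, i.e. displacement far
above both the isotropic noise and the within-state mode spread) is the
one where zero misassignment can be demanded.

### What the generator does *not* emulate

No sterics or force field: large mode amplitudes can produce locally
unphysical geometry (the switch-pair selection guards against the one
case where this matters for an analysis contract). No side chains beyond
backbone carbonyls/amides, so side-chain hydrogen bonds and methyl-group
NOEs appear only in the parsing/destereo fixtures, not in generated
ensembles. No temperature dependence, no exchange kinetics — the |Δω|
tables are profiles, not dispersion curves. Passing tests therefore
demonstrate the correctness of the *computations* under a controlled
statistical model, not the physical realism of any simulation protocol.

## Numerical choices

* Superposition: SVD-based optimal rotation with determinant correction;
  iteration tolerance 1e-6 Å on the mean, 50 rounds maximum.
* PCA: `eigen()` on the symmetric covariance; eigenvalues floored at 0;
  deterministic mode signs (largest-magnitude component positive); ties
  in `top_correlated_pairs()` broken by (lower first residue, then
  second).
* Degenerate inputs: zero-variance pools, constant vectors under min-max
  normalization, zero-variance distance series, fewer than 3 shared
  residues, sub-ensembles of size 1 — each is flagged or raised
  explicitly, never silently coerced to 0.
* Violation and selection thresholds use strict inequalities
  (`> bin + tol`, `> 0.35`, `< 0.00603`).
* Problem sizes in the test suite: oracle-equivalence checks on ≤ 5
  members × ≤ 20 residues; eigenvalue-ratio and reporter recovery at 500
  members; the hidden-state benchmark at 200 decoys × 100 seeded
  repetitions; the isotropic S² limit at n = 10⁴ orientations. These
  sizes make every statistical check stable at fixed seeds while keeping
  the full suite fast.

## Known limitations

* The restraint dialects cover pipe-separated group lists and CYANA-style
  `.upl`; NMR-STAR restraint blocks need external conversion.
* Hydrogens must be present in the input structures; no hydrogen building
  is performed, and stages that need protons fail with an explicit
  message.
* `ensemble_rmsd()`'s atom set (N/Cα/C′) is a convention choice; published
  tables computed with O or Cα-only sets will differ slightly.
* The three-state secondary structure assignment disagrees with
  continuous assignment programs at element boundaries by design.
* Scores of the invisible-state search depend on the predictor plugged
  in; the surrogate is for benchmarks only.
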