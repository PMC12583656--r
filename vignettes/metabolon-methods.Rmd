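---
title: "Methods: permutation statistics, interface overlap and patchy-particle flux simulation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: permutation statistics, interface overlap and patchy-particle flux simulation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabolon)
```

# Scope

`metabolon` provides the computational toolkit for studying transient
multi-enzyme assemblies ("metabolons") of the kind probed in bacterial
one-carbon metabolism:

1. **Interaction-matrix statistics** — building a symmetric
   protein–protein interaction (PPI) matrix from two-orientation
   split-fluorophore (BiFC) measurements and testing candidate enzyme
   clusters against a permutation null.
2. **Interface-overlap statistics** — quantifying whether a protein re-uses
   one surface region to bind several partners, via a mean inter-surface
   contact statistic with a random-surface null.
3. **Degenerate-codon arithmetic** — sizing site-saturation mutagenesis
   libraries.
4. **A coarse-grained patchy-particle reaction–diffusion simulator** — a
   ten-enzyme sequential pathway whose pairwise interaction energetics derive
   from the measured fluorescence matrix, used to ask how enzyme clustering
   changes metabolic flux.
5. **Synthetic-data generators** for every input, so the full pipeline is
   testable without any external download.

# Interaction-matrix statistics

## From wells to a symmetric matrix

Each protein pair X/Y is assayed in two fusion orientations (N-terminal
fluorophore half on X with the C-terminal half on Y, and the reverse),
because a fusion that is sterically unfavourable in one orientation can
abolish reconstitution even when the proteins interact.
`symmetrize_measurements()` therefore takes the **maximum** mean fluorescence
intensity (MFI) over the orientations that passed quality control.  Wells
with fewer than `min_cells = 10000` analysed cells are discarded; a pair with
no surviving orientation is recorded as missing, not as zero.  Duplicated
(pair, orientation) records are rejected outright with the offending rows
listed, since silently aggregating them would hide plate-layout errors.

Interaction strengths are banded by `classify_mfi()` with thresholds 750
(none/weak), 900 (weak/moderate) and 1100 (moderate/strong) MFI.  Such
bands are conventionally quoted with strict inequalities on both ends,
leaving values exactly on a threshold unassigned; we adopt half-open
intervals
`[750, 900)`, `[900, 1100)`, `[1100, Inf)` so that classification partitions
the whole non-negative axis.  This is a labelling convention only — no
statistic in the package depends on it.

## The permutation null

`cluster_permutation_test()` scores a stated set of pairs (a candidate
cluster) by the median (or mean) of its MFI values and compares it with the
same statistic over sets of equally many pairs drawn uniformly from the
matrix.  The empirical one-sided p-value is

$$p = \frac{\#(S_\mathrm{null} \ge S_\mathrm{obs}) + 1}{N + 1},$$

which is exact for a discrete permutation null, needs no normality
assumption, handles ties conservatively through the `>=` comparison, and is
bounded in `[1/(N+1), 1]`.  Conventions, all configurable:

* **Null pool**: unique unordered, non-missing, *off-diagonal* pairs.
  Diagonal entries measure homo-oligomerisation, a different quantity from
  the heteromeric pairs the clusters are made of, so they are excluded by
  default (`include_diagonal = FALSE`).
* Within one null draw, pairs are sampled **without replacement** (a draw is
  a set of pairs, like the observed cluster); draws are independent.
* `N = 10000` draws by default; every result records its seed.

Note that the observed pairs remain part of the null pool (the null asks
"how would an arbitrary same-sized set score on this matrix"), so the
theoretical floor `1/(N+1)` is attainable only when the observed statistic
exceeds anything the pool can produce — e.g. for dominant diagonal
(homomer) entries, which sit outside the off-diagonal pool.

`conditional_cross_test()` selects pairs by a predicate on one matrix (e.g.
structural similarity, TM score > 0.5) and evaluates the statistic on a
second matrix (e.g. MFI), drawing the null from the second matrix.  The null
pool stays whole-matrix even when the selection is restricted to a pathway
subset; this follows the figure-level descriptions and is configurable
through the `subset` argument, which restricts only the selection.
`protein_propensity_test()` is the same machinery applied to all pairs
involving one protein.  Two-group comparisons (e.g. the MFI distributions of
structurally similar vs dissimilar pairs) use `welch_two_sample()`, a thin
wrapper over the Welch unequal-variance t test with a `p = 1` convention for
two degenerate equal-mean samples.

`interaction_graph()` thresholds the matrix (default 1100, the strong band)
into an undirected simple graph and reports connected components and "core"
nodes, defined as members of at least one triangle.

## Concordance with binding free-energy predictions

`prediction_concordance()` consumes a table of precomputed binding free
energies (ΔG, kcal/mol) for protein pairs — typically produced upstream by
metadynamics on predicted dimer structures, which this package deliberately
does not re-run — and scores how often predicted binders
(ΔG ≤ −3 kcal/mol by default) also show fluorescence above 670 MFI.  The
null relabels predicted-binder status uniformly over the evaluated pairs
while keeping the number of predicted binders fixed, which preserves both
margins of the 2×2 table and formalises the informal idea of pairing
binding surfaces at random.  The threshold is stored as −3 kcal/mol:
binding free energies are negative for stable binders.

# Interface-overlap statistics

For a protein with $n \ge 2$ partner-specific interaction surfaces
$S_1, \dots, S_n$ (residue sets with Cα coordinates), the normalised contact
count between two surfaces is

$$C(S_i, S_j) = \frac{1}{m_i m_j} \sum_{s \in S_i} \sum_{p \in S_j}
  \mathbf{1}\left[\,\lVert r_s - r_p \rVert \le 7\,\text{Å}\,\right],$$

and the mean inter-surface contact statistic is the average of $C$ over all
$\binom{n}{2}$ surface pairs (`misc_observed()`).  Shared residues count as
contacts at distance zero, so $n$ identical compact surfaces give exactly 1;
disjoint distant surfaces give 0.  Normalising by $m_i m_j$ removes the
dependence on surface size, which varies with the irregularity of real
protein surfaces.

The null model asks how large the statistic would be if interaction surfaces
were placed at random on the solvent-exposed part of the protein
(`misc_null()`): residues with relative solvent accessibility (RSA) > 0.25
are "exposed"; a random surface is the set of exposed residues within a
probe radius of a uniformly drawn exposed seed residue.  The probe radius
defaults to the mean radius of gyration of the observed surfaces, so random
surfaces match the observed ones in spatial extent — without this, a
difference in surface *size* would masquerade as non-random overlap.  Each
of `n_sets = 10000` null sets contains `n_r = 50` random surfaces (descriptions of this
procedure vary between 50 and 100 surfaces per set; we default to 50, and
both knobs are configuration).

`overlap_significance()` reports

$$Z = \frac{\mathrm{MISC}^{O} - \overline{\mathrm{MISC}^{R}}}{\sigma/\sqrt{n}}$$

with the one-sided upper-tail normal p-value, the form in which this
statistic is conventionally defined (a t reference distribution is
indistinguishable from the normal at
$n = 10^4$, so we use the normal for determinacy).  A caveat documented here
on purpose: the denominator is the standard error of the **null mean**,
while the numerator contains a **single** set-level observation, so under
the null $Z \sim \sqrt{n}\,\mathcal{N}(0,1)$ and the normal-theory p-value
overstates significance, which is why this convention characteristically
produces extreme p-values in the $10^{-5}$–$10^{-7}$ range.  The result
therefore also carries
`p_empirical = (#(null ≥ MISC^O) + 1)/(n_sets + 1)`, the calibrated
empirical tail probability, which we recommend for accept/reject decisions
and which our calibration tests target.  Degenerate nulls (zero spread, e.g.
a protein whose exposed residues all fit in one contact ball) are flagged
and fall back to the empirical tail.

Supporting operations: `extract_interface()` (residues of one chain with any
partner-chain Cα within 7 Å — deliberately the same cutoff convention as
the contact function, so interface and overlap statistics share one length
scale),
`residue_frequency()` (per-residue participation across surfaces, for
structure colouring), `exposed_residues()`, and `read_ca_pdb()` /
`attach_rsa()` for PDB input with an RSA sidecar (computed RSA from a DSSP
run can be supplied as raw areas, normalised with the Tien et al. (2013)
theoretical maxima).

## Degenerate-codon arithmetic

`expand_degenerate_codon()` enumerates an IUPAC degenerate triplet and
translates it with the standard genetic code.  The triplet used for the
mutagenesis library, VDS = [ACG][AGT][GC], encodes 18 codons covering 13
distinct amino acids with no stop codons — it samples all chemistries while
excluding the large hydrophobics (F/W/Y) and proline.  Placed at 85 surface
positions it yields 85 × 18 = 1530 codon variants and an 85 × 13 = 1105
member amino-acid library.

# The patchy-particle reaction–diffusion simulator

## Model

Each of the 10 enzyme types is a rigid body: a core sphere of diameter 20 Å
with two rigid antipodal patch sites — one **interaction patch** carrying
the enzyme's identity and one **active-site patch** carrying the identity of
its cognate substrate state.  Ligands are 8 Å spheres in chemical states
$S_0 \to S_1 \to \dots \to S_9 \to P$; enzyme $k$ converts $S_{k-1}$ to
$S_k$, with $P$ absorbing.

Interactions:

* All non-specific pairs (core–core, core–ligand, ligand–ligand, non-cognate
  patch–ligand) use a Lennard-Jones potential with well depth 0.8 k~B~T,
  contact distance equal to the sum of the radii, truncated and shifted at
  2.5 σ.
* Interaction patches of two enzymes attract via a Morse potential
  (α = 2.2 Å⁻¹, r₀ = 17.056 Å, cutoff 20 Å, shifted at the cutoff) whose
  depth derives from the measured fluorescence through a step map
  (`kd_from_mfi()`): MFI > 1000 → K~D~ = 10 µM, 800–1000 → 200 µM, 650–800 →
  500 µM, below 650 → 100 mM; then `de_from_kd()` sets
  $D_e = |\ln(K_D/1\,\mathrm{M})|\,k_BT$, i.e. ≈ 11.5 k~B~T for the
  strongest band.  The depth is a magnitude because the Morse form already
  carries the attractive sign; the entropic part of binding is neglected,
  a standard simplification at this level of coarse-graining.
* A ligand whose state matches an enzyme's active site binds cognately
  (Morse, depth 5 k~B~T, α = 1 Å⁻¹, r₀ = 12.7 Å, capture range 2.5 Å).
  Cognate binding is exclusive — one ligand per site, one site per ligand —
  because the reaction rule is defined per bound ligand.  Each timestep,
  every bound ligand advances one state with probability
  $P_\mathrm{react}$ and is released.

Reaction probabilities derive from catalytic efficiencies:
$\log_{10}(k_\mathrm{cat}/K_M) \sim \mathcal{N}(5, 1)$, normalised by the
diffusion limit $10^8\,\mathrm{M^{-1}s^{-1}}$, so a typical enzyme reacts on
roughly one encounter in a thousand (`reaction_scheme()`).  A uniform
rescale (`p_scale`, recorded in the scheme and in outputs) is available for
reduced-scale runs in which only flux *ratios* are interpreted.

Geometry choices that the model class leaves open, fixed here and
configurable:
patch sites sit 2.697 Å (interaction) and 3.01 Å (active site) from the core
centre, chosen so that a bonded pair sits exactly at its core–core
Lennard-Jones minimum when the patches are at their Morse minimum — the
specific and non-specific minima then cooperate instead of fighting.  The
interaction-patch Morse acts on **every** patch pair within its 20 Å cutoff;
no explicit valence bookkeeping is imposed.  The short 2.8 Å capture range
together with core excluded volume is what limits multivalent engagement,
and the simulator records the worst-case number of
capture-range partners per patch as a diagnostic (`max_bond_valence`).  In a
dilute system this stays at ≤ 1; inside dense clusters a patch does engage
several partners, which is precisely what lets assemblies grow beyond dimers
— with a single interaction patch per enzyme, strictly single-valent
specific binding could never produce clusters larger than two, contradicting
the observed cluster-size distributions.

## Dynamics

The equation of motion is Langevin: conservative forces, Stokes drag
$\gamma = 6\pi\eta a$ and a fluctuation–dissipation-consistent random force
$\langle F_r(t) F_r(t')\rangle = 2\gamma k_BT\,\delta(t - t')$.  (This
model class is sometimes written with a damping constant $k_BT/6\pi\eta a$,
which is dimensionally a diffusion coefficient; Stokes drag is what the
equation of motion requires.)
Two integrators:

* `integrator = "langevin"` — inertial BAOAB splitting for rigid bodies
  (translation + quaternion rotation with isotropic sphere inertia).  With
  the drag set to zero it reduces exactly to velocity Verlet, which is how
  the microcanonical energy-drift check is run.
* `integrator = "brownian"` — the overdamped limit, position-only updates
  with rotation as a rotation-vector diffusion.  Faster and the right tool
  for reduced-scale reaction runs where momentum relaxation (≈ 2.6 ps for a
  30 kDa enzyme) is irrelevant.

Units are Å / amu / k~B~T, with the timestep supplied in femtoseconds
(default 30 fs).  Steeply repulsive pair forces are clamped at
`force_cap = 100` k~B~T/Å so that a pair created deep inside its repulsive
wall relaxes smoothly instead of producing an integration blow-up; the cap is
far above forces reached in equilibrated states and the microcanonical drift
check passes untouched by it.  A displacement of more than one patch
diameter in a single step aborts the run with advice to reduce the timestep.

Validation behind the defaults (all in the test suite and the acceptance
script): free tracers reproduce the Stokes–Einstein mean-squared
displacement within 10%; thermostatted interacting runs hold the
translational kinetic energy at 3/2 k~B~T per particle within 5%; with the
thermostat off, total energy drifts by < 1% over 10⁴ steps of 30 fs; and
identical seeds give bit-identical trajectories and reaction counters.

## Study conditions and the reduced flux demonstration

The simulator defaults describe the full-scale study conditions: 300 copies
of each of
10 enzyme types at an effective 50 µM per type (box side ≈ 1000 Å derived
from copy number and concentration via Avogadro arithmetic), water viscosity
10⁻³ Pa·s, 300 K, enzymes confined in a 400 Å sphere for the first part of
the run, five independent replicas.  "Effective concentration" is interpreted per enzyme type;
total-concentration bookkeeping is one flag away.  The ligand pool defaults
to 3× the enzyme count, all initialised to $S_0$.

Those conditions need days of CPU time.  The packaged demonstration
(`flux_demo_config()`) keeps every interaction parameter and shrinks the
transport problem: 6 copies per type at 1 mM per type (215 Å box), viscosity
10⁻⁴ Pa·s, Brownian integrator, 3×10⁵ steps of 30 fs with the first 10%
confined in a 60 Å sphere, equal reaction efficiencies rescaled to
$P_\mathrm{react} = 1$.  The dilute regime is chosen deliberately: there the
monomeric control is diffusion-starved for the late pathway steps (an
intermediate must find the next enzyme by bulk diffusion), while clustered
enzymes process intermediates locally — the phenomenon under study.  The
headline readout is directional:
with reaction counts aggregated over 5 paired replicas and
continuity-corrected ratios $(n_\mathrm{on}+\tfrac12)/(n_\mathrm{off}+\tfrac12)$,
the geometric-mean flux ratio of the last three reactions exceeds that of
the first three (early reactions lose a little to sequestration; late ones
gain).  The magnitude of the gain at full scale — which grows by orders of
magnitude with system size and run length — is *not* asserted at this
problem size.

`cluster_analysis()` defines clusters by interaction-patch distance ≤ the
20 Å Morse cutoff and reports sizes, per-cluster enzyme-type composition and
the time-averaged type-pair contact matrix; `flux_ratio()` forms the
per-reaction on/off count ratios with explicit `Inf`/`NaN` flagging.

# Synthetic data

The generators emulate the *structure* of the real inputs, not their exact
distributions (the raw MFI distributions live in external supplementary
data and are not reproduced here):

* `synth_mfi()` — a full two-orientation table: background MFI
  ~ Normal(600, 60) truncated at 0 (keeping the background fraction at
  ≥ 750 MFI below 5%, the "vast majority weak" regime), planted clusters
  ~ Normal(1150, 80), homodimer diagonal ~ Normal(900, 300), one orientation
  attenuated by Uniform(0.5, 1), and a 3% missing fraction realised as
  wells with sub-threshold cell counts — so missingness flows through the
  same QC path as real data.
* `synth_tm()` — a TM-score-like similarity matrix in [0, 1] with a planted
  structurally similar subgroup at tunable coupling to the MFI clusters.
* `synth_structure()` — compact self-avoiding virtual-Cα chains (3.8 Å
  bonds) or ideal helices with assigned RSA and planted surfaces whose
  pairwise shared fraction is controlled exactly; `synth_dimer()` — two
  chains placed at an exact minimal inter-chain distance.

All generators are seed-deterministic and attach their spec and seed as
provenance.  What passing tests on these fixtures do **not** show: anything
about fluorophore photophysics, expression-level confounds, or the true MFI
distribution of a real screen; the statistics are validated for calibration
(uniform p under the null) and power (planted-signal recovery), which are
properties of the procedures, not of the biology.

# Orchestration and reproducibility

`run_pipeline()` ties the stages into three recipes (cluster analysis,
overlap analysis, flux analysis) driven by a validated config list; unknown
keys fail before any compute.  Every run derives all stage seeds from one
root seed and writes a manifest (package version, config digest, seeds,
timestamps, outputs) next to its results, so identical config + seed
reproduce byte-identical result files.  `validate_ppi_matrix_file()` checks
matrix files (squareness, label agreement, NA coding, value ranges,
claimed symmetry) and reports all problems at once.  The package is used
from R; the exported functions are the interface.

# Known limitations

* The interaction-matrix statistics treat the matrix entries as
  exchangeable under the null; plate, expression or fusion-tag effects that
  correlate entries are not modelled.
* The overlap statistic works at Cα resolution with a hard 7 Å contact;
  side-chain-level definitions would shift absolute MISC values (the null
  comparison is designed to absorb this).
* The simulator is a transport model: no explicit substrate channeling,
  no hydrodynamic interactions, hard-sphere enzymes with isotropic inertia,
  and reaction probabilities applied once per timestep per bound ligand.
  Flux conclusions at the packaged problem size are directional only.
* The normal-theory overlap Z uses the σ/√n convention and is
  anticonservative; use `p_empirical` for decisions.
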