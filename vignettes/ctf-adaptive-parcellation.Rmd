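---
title: "Cross-talk-informed cortical parcellation and simulated connectomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cross-talk-informed cortical parcellation and simulated connectomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctfparc)
```

## The problem

Linear EEG/MEG source estimation is severely underdetermined: tens of
thousands of cortical sources are estimated from at most a few hundred
channels. For a gain (leadfield) matrix $G$ ($N_{ch} \times N_s$) and the L2
minimum-norm inverse operator

$$W = G^\top (G G^\top + \lambda^2 C)^{-1},$$

the *resolution matrix* $R = W G$ relates true to estimated sources. Row $i$
of $R$ is the *cross-talk function* (CTF) of source $i$: it quantifies how
activity everywhere in the brain contaminates the estimate at source $i$.
Ideally $R = I$; in practice $R$ is low-rank and heavily blurred, so
estimated activity *leaks* between locations. For network analyses this
leakage creates spurious connectivity: two parcels whose CTFs overlap will
appear coherent regardless of true coupling.

Anatomical atlases ignore this. Some parcels are essentially invisible to
the sensors (the sensitivity problem), some are too large to be represented
by a single time course, and some neighbouring parcels are mutually
indistinguishable (the specificity problem). This package derives
*adaptive* parcellations whose parcels are matched to the spatial
resolution of the measurement: a non-iterative split-and-merge (SaM)
modification of an initial atlas, and an atlas-free region-growing (RG)
segmentation. It also provides a full simulation bench — synthetic
multi-subject forward models, event-related source-space networks with
controlled connectivity and SNR, spectral reconstruction, and permutation
scoring — to quantify what a parcellation does to network reconstruction
accuracy.

## Parcel resolution matrices

All parcellation decisions are based on absolute CTFs: only the amount of
leakage matters. For a parcel $p$ the rows of $|R|$ belonging to its
vertices form $M^p$; the parcel's *representative CTF* is the first right
singular vector of $M^p$ (uncentered SVD, sign-fixed non-negative, unit
norm). For a parcellation with $N$ parcels the *parcel resolution matrix*
is

$$\mathrm{PRmat}_{ij} = \frac{1}{|K_j|} \sum_{k \in K_j}
  \frac{\mathrm{CTF}^i(k)}{\sum_{l=1}^{N} \mathrm{CTF}^l(k)},$$

the mean, over vertices $k$ of the receiving parcel $j$, of parcel $i$'s
share of the total representative-CTF mass at $k$. We adopted this reading
of the normalisation — averaging per-vertex leakage *shares* — because it
is the unique one that guarantees entries in $[0, 1]$, columns that sum to
one, and an identity PRmat in the fully resolved case; the alternative that
normalises by the sending parcel's total CTF mass is available as
`normalization = "per-source-mass"`. Vertices where every representative
CTF is exactly zero carry no information and are excluded from the means
(and counted).

Two summary indices grade a parcellation: the **sensitivity index**
$S_{ind}$ (mean PRmat diagonal; 1 is ideal) and the **distinguishability
index** $D_{ind}$ (Pearson correlation between the PRmat and the identity;
1 is ideal). The PRmat rank is computed with a heuristic singular-value
tolerance of 0.05 — appropriate for a matrix scaled to $[0,1]$, and far
above floating-point rank tolerance — together with the 2-norm condition
number of the full matrix and the coverage (number of vertices in the
parcellation).

Group-level PRmats average each parcel's per-subject representative CTF in
the common average space before Eq. above is applied, mirroring how
multi-subject analyses morph individual results to an average brain.

## The split-and-merge algorithm

Starting from a bilateral atlas:

1. **Split.** Per subject and parcel, count the principal components needed
   to explain more than 90% of the CTF variance of the parcel's vertices
   ($N_{PC}$, from squared singular values of the uncentered $M^p$; a
   centered variant is available via `center`). $N_{PC}$ is harmonized to
   the minimum over the contralateral pair within a subject (under-splitting
   is preferred to over-splitting) and the mode over subjects (minimum among
   tied modes). A parcel with $N_{PC} = k > 1$ is split into $k$ contiguous
   sub-parcels by projecting its registered-sphere coordinates onto the
   parcel's principal eigen-axis and cutting the projection into $k$
   equal-length intervals; empty intervals collapse with a warning. The
   left-hemisphere split is mirrored to the right so sub-parcel boundaries
   agree across hemispheres.
2. **Homogeneity.** Every vertex is re-assigned by *sensitivity* (a vertex
   counts as sensitive to a parcel if the parcel's representative CTF there
   reaches half of that CTF's global maximum) and *specificity*: the
   z-score of parcel $i$'s CTF at vertex $v$ across all parcels,
   $Z_{iv} = (\mathrm{CTF}^i_v - \overline{\mathrm{CTF}}_v)/
   \sigma_{\mathrm{CTF}_v}$ (population standard deviation). A vertex is
   *assigned* to the winner if its z-score exceeds 3 and leads the
   runner-up by at least 1; it is a *merge candidate* for the top pair when
   both exceed 3 but differ by less than 1; otherwise it is *declined*.
   Tie-breaking is strict `>` for the threshold and `>=` for the margin;
   three-way near-ties are declined (merge candidates are defined for pairs
   only). Merge candidacy additionally requires sensitivity to both pair
   members, assignment to the winner.
3. **Merge.** Merge-candidate vertices are clustered per unordered
   split-parcel pair; clusters at least as large as the smallest
   split-parcel survive as merged parcels (labels concatenate the pair's
   labels). Merged vertices are not left in their source parcels, keeping
   parcels disjoint.
4. **Final evaluation.** The homogeneity step is repeated on the modified
   parcel list's own CTFs; parcels winning fewer than 10 vertices are
   dropped; a PRmat is computed and any parcel whose row has an
   off-diagonal element above its diagonal is removed (row-wise reading:
   a parcel's row is its CTF distribution over parcels). Finally, bilateral
   symmetry is enforced: parcels surviving in only one hemisphere are
   removed, and for each surviving pair the hemisphere with more coverage is
   kept and mirrored through the mirror map; overlaps introduced by
   mirroring are resolved by sequential claim in parcel order, which is
   symmetric on mirror-symmetric fixtures.

## The region-growing algorithm

RG needs no initial atlas. Every vertex is treated as a single-vertex
parcel and the same sensitivity/specificity rules are applied to the rows
of the subject-averaged $|R|$ — raw rows, not unit-normalized ones. This
choice matters: normalizing each row cancels overall sensitivity
differences between vertices, after which no vertex can beat its
neighbours' z-scores by the required margin and no seeds exist; with raw
rows, strongly seen vertices dominate their weakly seen neighbourhoods,
and a realistic ~1–2% of vertices emerge as seeds (the same order as in
group studies at full cortical resolution). Vertices that win at least one
vertex besides themselves are *seeds*, ordered by self z-score (ties broken
by vertex index). Parcels are grown in that order: parcel $k$ takes the
still-unassigned vertices of the growing hemisphere (the one with more
winner seeds) whose cross-talk in seed $k$'s CTF reaches half of that CTF's
global maximum; grown parcels are then mirrored to the other hemisphere.
The SaM modification steps (minus splitting) finish the job. Vertex-level
z-scoring is done in fixed-size column blocks so memory stays bounded;
results are block-size invariant.

## The synthetic study fixture

Everything is testable without real recordings through a synthetic
multi-subject forward-model generator. Its defaults were chosen once to
put the *initial* anatomical stand-in atlas in the operating regime that
real anatomical atlases occupy (sensitivity index well below 0.5,
distinguishability 0.6–0.8, PRmat rank far below the parcel count), and
were not revisited afterwards:

- **Source space**: two ellipsoidal lobes (one per hemisphere) with exact
  x-mirror symmetry, so the mirror map is an involution with zero error and
  the bilateral-symmetry logic is testable without nearest-neighbour
  ambiguity. A 10 mm medial margin keeps homologous sources at least 20 mm
  apart, as in real source spaces where the medial wall is excluded;
  without it, midline mirror twins are so mutually ambiguous that their
  cross-talk dominates every leakage analysis.
- **Orientations**: vertex normals are perturbed by a smooth random field
  (amplitude 1.2, correlation length 10 mm), a proxy for cortical folding:
  neighbouring vertices share their local fold while orientation
  decorrelates across the surface. This orientation structure is what lets
  the inverse distinguish nearby patches — with smooth normals, seed
  finding degenerates.
- **Leadfield**: quasi-static dipole potentials oriented along the vertex
  normals (default), so gains inherit the orientation roughness; a purely
  distance-based Gaussian profile is available (`"gaussian-spread"`) but is
  too smooth for region growing. Depth sensitivity falls off naturally with
  sensor distance.
- **Sensors**: a 64-channel helmet (2π/3 cap) built exactly x-mirror
  symmetric; inferior regions are poorly covered, reproducing the
  sensitivity problem.
- **Subjects**: each subject's leadfield is the base gains under a smooth
  multiplicative field (scale 0.1) plus per-channel gain factors, with a
  mirror-consistent random vertex permutation standing in for morphing;
  zero perturbation gives bitwise-identical subjects and identity
  mappings. Noise covariances are empirical covariances of white baseline
  noise with 5% diagonal loading.
- **Inverse**: `lambda2 = 1/9` (the conventional `1/SNR^2` with an assumed
  SNR of 3). The noise covariance is symmetrized and trace-normalized to
  `trace(GG')` so `lambda2` is dimensionless and the PRmat is invariant to
  a global rescaling of the gains; the literal unscaled formula is
  available via `scale = "none"`.

Parcellation experiments in the tests use 700–1000 vertices per hemisphere
with 8–10 atlas parcels per hemisphere and 5–12 subjects; these sizes keep
parcel sizes proportionate to the 10-vertex survival rule at a desk scale
(the reference analyses use ~20,000 vertices, 68–148 parcels and 17
subjects). What the synthetic fixture does *not* emulate: realistic BEM
electromagnetics, spatially coloured noise, cortical geometry beyond the
two-lobe caricature, and inter-subject anatomical variability beyond smooth
gain perturbations. Passing tests therefore demonstrate the algorithms'
internal logic and their qualitative behaviour under leakage, not
quantitative agreement with any real dataset.

## Simulated connectomes

Networks are simulated the way event-related source studies are built:

- `make_basis()` creates one sinusoidal basis function per active node at
  frequencies equally spaced over 10–40 Hz (inclusive endpoints; a single
  basis sits at the lower endpoint), with phases redrawn uniformly per
  epoch so distinct basis functions are incoherent (expected squared
  coherence `1/N_e`). Epochs are 725 ms at 250 Hz — 182 samples, 31 of them
  pre-stimulus baseline. The sample rate is not dictated by the method; 250
  Hz comfortably covers the 8–55 Hz analysis band.
- `make_A()` draws a binary mixing matrix with unit diagonal whose
  *effective* connection set — node pairs sharing at least one basis
  function, which deliberately includes indirect connectivity through a
  common third source — hits `round(pct/100 * n(n-1)/2)` exactly
  (rejection sampling with bounded retries).
- `make_network()` places nodes on parcels drawn from a functional seed
  atlas that is independent of any parcellation under test, and draws one
  phase shift per node, constant over epochs, applied as a phase offset of
  every contributing sinusoid — so connected nodes are coupled at non-zero
  lag. Unit weights are used when several basis functions sum into one
  node.
- `synthesize()` copies each node's time course to all its vertices in the
  post-stimulus window and fills everything else (and the baseline) with
  white Gaussian noise, scaled per vertex so that RMS(post-stimulus
  signal)/SD(noise) equals the requested SNR. One dataset is a single
  realization in average space shared by all subjects — the design in which
  an average-brain simulation is morphed to each individual — so that
  across-subject consistency reflects the head models, not fresh noise;
  independent per-subject noise is available via `share_noise = FALSE`.
- `project_leakage()` maps each subject's data to their space, applies
  their resolution matrix (forward then inverse; optional sensor noise
  through `W`), and maps back: the no-leakage dataset is the ground-truth
  reference, the projected one the realistic scenario. `make_null()`
  generates noise-only datasets whose every significant edge downstream is
  leakage-induced.

Reconstruction mirrors standard practice: mean-flip parcel time courses
(vertex signs from the dot product with the parcel's dominant normal
direction), DPSS multitaper cross-spectra (time-bandwidth 4, 7 tapers,
Thomson adaptive weights) over the post-stimulus 0–600 ms window, and
magnitude-squared coherence or the imaginary part of coherency aggregated
over 8–55 Hz by the unweighted mean across bins (`aggregate = "max"` is
available). DPSS tapers are computed from the tridiagonal formulation and
their concentration values against the band-limiting kernel; no external
spectral library is involved.

Scoring: per-subject connectivity matrices are baseline-corrected (the
mean absolute off-diagonal value is subtracted from all absolute values),
then a one-tailed max-statistic sign-flip permutation test across subjects
controls the family-wise error over edges. The statistic is the plain mean
across subjects (a t-statistic is available); corrected p-values use the
add-one convention `p = (1 + #{max-null >= obs}) / (1 + n_perm)`, which
keeps the realized family-wise error at the nominal level in calibration
runs. Ground truth for each parcellation is whatever the *same* pipeline
finds significant on the no-leakage data; active nodes with no vertex
overlap with a sparse parcellation are counted as missed, and their
incident effective connections enter the true-positive denominator:
`TPR = |detected ∩ true| / (|true| + missed)`,
`FPR = |detected \ true| / (n(n-1)/2 - |true|)`.

## Numerical choices and degenerate inputs

- Matrix identities are validated at a relative tolerance of `1e-8` in
  double precision.
- A numerically singular system with `lambda2 = 0` is an error; with
  regularization a pseudo-inverse fallback is used and flagged.
- Zero-variance vertices (all parcels equal) are declined in specificity
  scoring; zero-denominator vertices are excluded from PRmat means; a
  constant PRmat has an undefined distinguishability index (`NA`); the
  zero matrix has rank 0 and infinite condition number.
- All generators are pure functions of (configuration, seed), and restore
  the caller's RNG state.
- An empty final parcellation (every parcel eliminated) is an explicit
  error rather than a silent empty object.

## Known limitations

- Sign-flip permutation assumes the corrected values are symmetric about
  zero under the null; baseline-corrected absolute coherences are mildly
  right-skewed, so the realized family-wise error of the mean statistic
  sits slightly above the nominal level in large calibrations (about
  0.05-0.07 at alpha 0.05), while the t-statistic variant
  (`stat = "t"`) is conservative (about 0.01). The mean statistic is the
  default; calibration runs in the test suite verify it stays within the
  binomial confidence band of the nominal level.
- The two-lobe geometry has no gyral geometry; contiguity of grown parcels
  relies on CTF unimodality rather than explicit surface constraints.
- Exact mirror symmetry plus a symmetric sensor array makes homologous
  cross-talk stronger than in real heads; the medial margin bounds but does
  not remove it. Interhemispheric edges should be interpreted with that in
  mind.
- The RG seed criterion is sensitive to the overall leakage level: a
  resolution matrix too close to identity (no vertex wins others) or too
  blurred (no margins) yields an explicit "no seeds" error.
- Only fixed (normal) source orientations are implemented; loose
  orientations would enter at the leadfield and time-course extraction
  stages and are a natural extension.
- Leakage correction by inverting the PRmat is deliberately out of scope;
  the condition number is reported exactly so that users can judge whether
  such an inversion would be stable.
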