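# ctfparc

Cross-talk-informed cortical parcellation and simulated connectomes for
EEG/MEG source-space network analysis.

## The problem

Linear EEG/MEG source estimates are heavily blurred: with a gain matrix
`G` (channels x sources) and an L2 minimum-norm inverse operator

    W = G' (G G' + λ² C)⁻¹,

the resolution matrix `R = W G` should ideally be the identity but is
low-rank in practice. Its rows — the cross-talk functions (CTFs) — describe
how activity everywhere in the brain leaks into the estimate at each
source. When source space is divided into the parcels of an anatomical
atlas and parcel time courses are correlated, this leakage manufactures
spurious network edges: anatomical boundaries have nothing to do with what
the sensor array can actually resolve.

`ctfparc` is for researchers who analyse source-space connectivity and
want parcellations matched to the resolution of their measurement. It
provides:

- **Resolution analysis**: minimum-norm operators, resolution matrices and
  CTFs (`mne_operator()`, `resolution_matrix()`, `ctf()`), and the parcel
  resolution matrix `PRmat` — normalised between-parcel leakage with its
  sensitivity index `S_ind` (mean diagonal), distinguishability index
  `D_ind` (correlation with the identity), rank and condition number
  (`parcellation_prmat()`).
- **Adaptive parcellation**: a non-iterative split-and-merge modification
  of an initial atlas (`run_sam()`) — split parcels whose CTFs need more
  than one component for 90% variance, reassign vertices by CTF
  sensitivity and winner-takes-all specificity (z > 3, margin 1), merge
  indistinguishable pairs, and keep only parcels that win at least 10
  vertices, dominate their PRmat row, and survive bilaterally — and an
  atlas-free region-growing segmentation seeded at high-specificity
  vertices (`run_rg()`). Both return a classed fit with `print()`,
  `summary()`, `coef()` and `plot()` methods.
- **A simulation bench**: synthetic multi-subject forward models
  (`make_source_space()`, `make_leadfield()`, `make_subject_set()`,
  `make_atlas()`), event-related networks with controlled effective
  connectivity and SNR (`make_basis()`, `make_A()`, `make_network()`,
  `synthesize()`), leakage projection through per-subject operators
  (`project_leakage()`, `make_null()`), multitaper coherence / imaginary
  coherency reconstruction (`extract_timecourses()`,
  `spectral_connectivity()`), and max-statistic permutation scoring with
  missed-node accounting (`baseline_correct()`, `permutation_test()`,
  `ground_truth_edges()`, `score_edges()`, `plan_experiment()`,
  `run_pipeline()`).

## Worked example

Derive an adaptive parcellation on a synthetic five-subject study and
compare it with its initial atlas:

```r
library(ctfparc)

space    <- make_source_space(700, "two-lobe", seed = 3)
sensors  <- make_sensors(64)
subjects <- make_subject_set(5, space, sensors,
                             perturbation_scale = 0.1, seed = 7)
atlas    <- make_atlas(space, 8, "anatomical-stand-in", seed = 2)

parcellation_prmat(atlas, subjects)
#> Parcel resolution matrix: 16 parcels
#>   S_ind = 0.254, D_ind = 0.802, rank = 13, cond = 41.13, coverage = 1400

fit <- run_sam(atlas, subjects)
fit
#> CTF-adaptive parcellation (split-and-merge)
#>   final parcels: 20, coverage 260/1400 vertices
#>   S_ind = 0.446 (initial 0.254), D_ind = 0.923 (initial 0.802)
```

The initial 16-parcel atlas recovers only a quarter of its own leakage
(`S_ind` 0.25): most parcels receive more cross-talk from elsewhere than
from themselves. The split-and-merge fit keeps 20 bilaterally symmetric
parcels covering the well-resolved fifth of the surface, nearly doubling
the sensitivity index and raising the distinguishability index — the same
qualitative behaviour reported for adaptive parcellations of real
20,000-vertex source spaces, where modified atlases improve the indices by
tens of percent while covering a fraction of the cortex.

`coef(fit)` returns the metrics as a vector, `summary(fit)` adds parcel
sizes and the per-stage parcel counts, and `plot(fit)` draws the final
PRmat. `run_rg(subjects)` produces the atlas-free counterpart.

A thin command-line wrapper over these functions is installed at
`inst/cli/ctfparc.R` (subcommands `synth`, `resolution`, `prmat`,
`parcellate-sam`, `parcellate-rg`, `simulate`).

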