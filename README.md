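# memanchor

Quantifying how small molecules anchor to the surface of a lipid bilayer is
a recurring task in computational membrane biophysics: for drugs whose side
effects begin with adsorption to a cell membrane (the classic example being
anthracycline chemotherapeutics and the myocardial membrane), the strength
and geometry of surface anchorage is the first quantitative handle on their
membrane-mediated toxicity potential. `memanchor` computes the standard
anchorage metrics from molecular dynamics trajectories and turns per-drug
metric bundles into a categorical, rubric-based ranking. Because real
drug–membrane MD datasets are rarely redistributable, the package ships a
Brownian-dynamics generator of synthetic adsorption trajectories with known
ground truth, so every estimator is validated end-to-end without any
download.

## The metrics

For a drug molecule and an asymmetric two-leaflet membrane (upper = outer
leaflet), with coordinates in nm and times in ps:

* **Residence time** — the percentage of analyzed frames in which the
  shortest minimum-image atom-pair distance between the molecule and a
  leaflet's atoms is ≤ 0.3 nm (the average length of a biological salt
  bridge), computed per leaflet. A molecule within cutoff for 0.6 µs of a
  1 µs window scores 0.6/1 × 100 = 60 %.
* **Hydrogen bonds** — the per-frame count of donor–hydrogen–acceptor
  triples with donor–acceptor distance r(Do,A) ≤ 0.35 nm and
  hydrogen–donor–acceptor angle ≤ 30°, averaged over frames, with a
  per-phospholipid-class attribution table.
* **Diffusion / surface immobilization** — the diffusion coefficient from
  the Einstein relation, D = slope[MSD(τ)] / (2·dim), fitted to the
  time-origin-averaged mean square displacement, and the immobilization
  ratio D_membrane / D_bulk × 100 %.
* **Mid-plane proximity** — the mean |z| distance of the molecule from the
  bilayer mid-plane (the mass-weighted lipid z centroid), reported
  separately for frames above the upper leaflet and below the lower one.

Every scalar carries a block-averaged standard deviation (the spread of the
metric recomputed on 4 consecutive blocks of the analysis window).
Supporting profiles: 1-D mass density in kg/m³ versus z, and free-energy
profiles by Boltzmann inversion, F(z) = −kT ln[p(z)/max p(z)].

## The ranking rubric

Each drug is scored on four criteria; first (`*`) and second (`x`)
category bands, with layer tags U/L/B for leaflet-resolved criteria:

| criterion                | 1st category | 2nd category  |
|--------------------------|--------------|---------------|
| residence time           | > 20 %       | 12–20 %       |
| hydrogen bonds           | > 0.1 /frame | 0.05–0.1      |
| distance from mid-plane  | < 2.6 nm     | 2.6–4.16 nm   |
| diffusivity ratio        | < 25 %       | 25–35 %       |

Drugs are ordered by number of first-category marks, then second-category
marks, then layer breadth on residence (both layers beat one), then a
documented criterion-priority tie-break. The output is an anchorage-based
potential ranking — not a clinical claim.

## Worked example

```r
library(memanchor)

# the residence-time arithmetic on a fixture with a known contact fraction
tr <- make_residence_fixture(0.6, 1000)
residence_time(tr, drug_atoms(tr$topology),
               leaflet_atoms(tr$topology, "lower"),
               selection = "lower leaflet")
#> lower leaflet : 60 +/- 48.98979 (block sd, 4 blocks) %

# an end-to-end synthetic pipeline: three drugs with increasing
# adsorption well depth (0, 1.5 and 5 kT)
res <- run_pipeline(quickstart_config("quickstart-out", seed = 1))
res$table
#>      residence hbonds midplane diffusion_ratio
#> DRG1 ""        ""     "Ux"     ""
#> DRG2 "Ux"      ""     "Ux"     ""
#> DRG3 "U*"      ""     "U*"     ""
res$ranking
#>   rank drug n_first n_second tie_group  tied
#> 1    1 DRG3       2        0         1 FALSE
#> 2    2 DRG2       0        2         2 FALSE
#> 3    3 DRG1       0        1         3 FALSE
```

The deepest well (DRG3) anchors hardest: first category on residence
(> 20 % of frames within 0.3 nm of the upper leaflet) and on mid-plane
proximity (< 2.6 nm), so it tops the ranking; the 1.5 kT drug collects two
second-category marks; the non-adsorbing drug only drifts near the
mid-plane band occasionally. `quickstart-out/` contains the tidy
`metrics.csv`, the category table, the ranking, a human-readable report
and a manifest with the seed and config hash.

A command-line interface wrapping the same functions lives at
`inst/cli/memanchor.R` (subcommands `generate`, `residence`, `hbonds`,
`diffusion`, `density`, `midplane`, `rank`, `run`).

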