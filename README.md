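# fractalmet

Fractal and multifractal quantification of metastatic lesion dispersion in
3D tracer images, with a kinetic Monte Carlo model of metastatic spread on
a fractal vascular lattice.

## The problem

In whole-body FDG emission tomography, disseminated malignant lesions light
up wherever the tracer accumulates. How *spread out* those lesions are —
homogeneously through the body versus hierarchically clustered along the
branching networks that transported the malignant cells — is prognostic
information that visual reading does not quantify. `fractalmet` measures it
with three operator-independent statistics:

- **Box-counting fractal dimension** `d_f`: cover the body with cubic boxes
  of edge `s` and count the boxes `N(s)` containing tracer; the scaling law
  `N(s) = C·s^(−d_f)` is fitted by least squares in log-log coordinates.
  Space-filling uptake gives `d_f → 3`; a single focal lesion gives
  `d_f → 0`; lesions scattered along a vascular tree give the tree's
  dimension (≈ 2.6–2.7 for human vasculature).
- **Generalized (Rényi) dimension spectrum** `D_q`: weights each box by its
  normalized tracer content `p_i` (`Σ p_i = 1`) and evaluates, at the
  finest box scale,
  `D_q = ln(Σ p_i^q) / ((q−1)·ln ε)` for `q ≠ 1` and
  `D_1 = Σ p_i ln p_i / ln ε`, with `ε` the box edge relative to the body
  extent. Negative `q` probes faint boxes, positive `q` bright ones.
- **Averaged multifractal index** `D_MF`: for two serial studies,
  `D_MF = (2L+1)^(−1) Σ_{q=−L}^{L} (D_q(I) − D_q(II))` summarizes the shift
  of the whole spectrum in one signed scalar (computed for the early
  I→II, late II→III and final I→III study pairs).

The package also implements the mechanistic model behind these statistics:
a **kinetic Monte Carlo** simulation in which a few malignant cells perform
random walks confined to a deterministic fractal vascular lattice (an
18-of-27 recursive generator, dimension `log₃18 ≈ 2.631`) and colonize an
adjacent tissue site with a small probability `p` per step. The number of
colonized sites follows `N_m(t) = A·t^α·exp(−βt)`, which the package fits
by Levenberg–Marquardt least squares.

Who it is for: image scientists and modellers who want reproducible,
whole-volume dispersion statistics for serial studies, and anyone studying
spreading processes on fractal substrates.

## Worked example

```r
library(fractalmet)

# a phantom: point lesions placed on a depth-2 fractal vascular lattice
net <- build_network(2)                       # 18² = 324 sites on a 9³ lattice
spec <- phantom_spec(extent_mm = c(36, 36, 36), spacing = c(4, 4, 4),
                     lesions = lesions_from_network(net), seed = 1)
vol <- generate_phantom(spec)

ana <- analyze_scan(vol)                      # regrid -> threshold -> count -> fit
ana$fit
#> <fractal_fit> d_f = 2.6309, C = 12431, R^2 = 1, s in [4, 36]

spec_q <- mf_spectrum(compute_measure(vol), q_max = 10)
head(spec_q, 3)
#> # A tibble: 3 × 2
#>       q   d_q
#>   <int> <dbl>
#> 1   -10  2.63
#> 2    -9  2.63
#> 3    -8  2.63

# the spreading model at the reference conditions
sim <- simulate_kmc(kmc_config(seed = 1), build_network(4))
boxcount_lesions(sim)$fit
#> <fractal_fit> d_f = 2.714, C = 188070, R^2 = 0.991018, s in [1, 20]
fit_growth(sim$series)
#> <growth_fit> N_m(t) = A t^alpha exp(-beta t)
#>   A = 8753.9, alpha = 0.75111, beta = 0.010076, corr(obs, fit) = 0.997065
```

The phantom's lesions sit exactly on a self-similar set, so the fitted
`d_f` equals the lattice dimension `log₃18 = 2.6309` and the spectrum is
flat at that value. The simulated lesion set ends slightly *above* the
network dimension (2.71 vs 2.63) because colonized tissue wraps around the
vasculature; the growth fit shows the sub-linear colonization regime
(`α ≈ 0.75`) levelling off (`β > 0`) as the tissue adjacent to the network
saturates.

A shell front end with `analyze`, `compare`, `simulate` and `phantom`
subcommands is installed at `inst/cli/fractalmet`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "fractalmet", package = "fractalmet"))')" \
  analyze --volume scan.nii.gz --out-dir out/
```

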