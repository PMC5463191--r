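# octqc

Quantitative image-quality analysis of frame-averaged OCT B-scans, in
clear versus opaque (cataract-like) ocular media.

Spectral-domain OCT devices suppress speckle noise by averaging M
eye-tracked B-scans of the same retinal line. More averaging means
longer acquisitions and, with imperfect tracking, smoother images — so
how many frames are enough, and does the answer change when a cataract
sits in the optical path? `octqc` answers this with three objective
measures computed per scan against manual layer annotations (five
retinal layers delimited by six boundary curves):

* **SNR** per layer, `SNR_l = mu_l / sigma_l` (mean over standard
  deviation of the layer's grey values), expected to grow as `sqrt(M)`
  while the frame noise is uncorrelated;
* **Cohen's d** between neighbouring layers,
  `d = |mu_1 - mu_2| / s_pooled` with the `(n-1)`-weighted pooled
  standard deviation, averaged over each layer's upper and lower
  neighbour;
* **segmentation Dice**: per layer, three-component Gaussian mixtures
  are fitted to the layer and its two neighbours, pixels are classified
  by maximum likelihood, and the result is scored against the manual
  region with `Dice = 2|A∩B| / (|A|+|B|)`.

Image-level values are unweighted means over the five layers. A
synthetic B-scan generator provides the study conditions: a layered
retina phantom, per-frame uncorrelated noise, a frame-correlated noise
floor drawn once per stack (the mechanism that saturates SNR), a
media-opacity condition (signal attenuation plus noise inflation), and
the 7-setting (2–96 frames) x 2-visit x 13-eye acquisition design with
shared per-eye geometry.

## Worked example

```r
library(octqc)
design <- study_design(n_eyes = 3)          # 3 eyes for a quick look
ds     <- simulate_study(design, scene_config(width = 96, depth = 160),
                         seed = 1)
study  <- run_study(ds, seed = 1, verbose = FALSE)

design_counts(study_design())
#> per patient: 14 scans, 70 layers, 84 boundaries; total annotations: 1092

summarize_curves(study, "snr")
#>  condition  M    value n_eyes
#>       post  2 1.000000      3
#>       post  4 1.169417      3
#>       post  8 1.339335      3
#>       post 16 1.454926      3
#>       post 32 1.496828      3
#>       post 48 1.526477      3
#>       post 96 1.533907      3
#>        pre  2 1.000000      3
#>        pre  4 1.345821      3
#>        pre  8 1.768488      3
#>        pre 16 2.170634      3
#>        pre 32 2.548521      3
#>        pre 48 2.737469      3
#>        pre 96 2.936697      3

matching_analysis(study, "dice")
#>  eye measure    target m_matched matched
#>    1    dice 0.9082750        NA   FALSE
#>    2    dice 0.9083425        NA   FALSE
#>    3    dice 0.8957946        NA   FALSE
```

The curves show the study's signature: in clear media (`post`) relative
SNR rises until 16 frames and then flattens (under 10% change from 16
to 96 frames), while with opaque media (`pre`) it is still climbing at
96 frames. The matching table asks, per eye, which opaque-media setting
reaches the clear-media 16-frame value; `NA` means even 96 frames did
not — every eye needs at least the 16-frame reference, usually far
more.

`write_dataset()` / `read_dataset()` give the on-disk form (8-bit TIFF
scans, per-eye boundary CSVs, a JSON manifest), and
`inst/cli/octqc.R` wraps the pipeline for shell use
(`simulate --config cfg.yaml --out dir`, `analyze --data dir --out
results.csv`, `report --results results.csv --out dir`).

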