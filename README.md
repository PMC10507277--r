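# shellmorph

Morphometrics and 3D architecture of scale-built protist shells from
segmented (labeled) image volumes.

Testate amoebae such as *Paulinella micropora* construct an egg-shaped
extracellular shell from ~50 curved rectangular silica scales, stacked in
five left-handed helical columns by a specialized thick pseudopodium.
Volume electron microscopy (FIB-SEM) of such cells produces 3D label
volumes — integer images in which every scale (and optionally the
pseudopodial cytoplasm) carries its own label.  `shellmorph` analyses these
volumes:

* **I/O and geometry** — multi-page TIFF label stacks in and out, per-label
  trilinear resampling of anisotropic acquisitions to isotropic voxels,
  binary STL export of exact voxel-boundary surface meshes.
* **Morphometrics** — per-scale volume, centroid, surface area and
  cytoplasm contact area by exact 6-neighbor face counting, with
  `none`/`partial`/`full` contact classification
  (ratio = min(contact/surface, 1), full at ratio ≥ 0.99).
* **Alignment** — the cell long axis is rotated onto +Z by iterated 2D
  projection and image-moment ellipse fitting
  (angle = ½·atan2(2·m₁₁, m₂₀ − m₀₂)), with an independent principal-axis
  oracle and an aperture-up normalization.
* **Architecture** — cylindrical centroid coordinates; radius-weighted
  angular spectra S(m) = |Σ rₖ·exp(i·m·θₖ)| / Σ rₖ and their
  rate-compensated form maxᵦ |Σ rₖ·exp(i(m·θₖ − β·zₖ))| / Σ rₖ for counting
  helical columns ("petals") under twist; per-column least-squares twist
  and handedness; Gaussian volume-versus-Z profile fit with robust (MAD)
  outlier detection.
* **Symmetry** — mother/daughter two-fold symmetry via homologous centroid
  midpoints, a total-least-squares symmetry axis, and the RMS overlap after
  rotating the daughter 180° about that axis.
* **Phantoms** — a parametric egg-shell generator with full ground truth
  (column count, twist, contact plan, symmetry axis, planted volume
  outliers) standing in for non-deposited raw image stacks.

See the methods vignette (`vignettes/shell-architecture.Rmd`) for the
models, conventions and design decisions.

## Worked example

Generate the study-scale phantom (52 scales in 5 left-handed columns, one
revolution of twist, 192³ voxels at 0.08 µm) and run the full pipeline:

```r
library(shellmorph)

spec <- paulinella_shell_spec(seed = 0)
gen  <- generate_shell(spec)
gen2 <- add_cytoplasm(gen$volume, gen$truth, spec)
res  <- run_pipeline(gen2$volume,
                     pipeline_config(cytoplasm_label = spec$cytoplasm_label))
print(res)
#> shell-architecture report
#> =========================
#> scales analysed: 52
#> alignment: residual 0.477 deg after 2 iteration(s)
#> petal count (helical columns): 5  [rate-compensated angular spectrum]
#> twist: -1.008 +/- 0.015 revolutions, handedness left  [per-column angular fits]
#> volume-profile outliers (gaussian fit): none
#> cytoplasm contact: 0 of 52 scales (0 partial, 0 full; largest partial 0.000 um^2 on -)
```

The report reads: the long axis was already within half a degree of +Z
after two projection/fit passes; the centroids form five helical columns
(the "five-petal" pattern of the XY plot); each column twists one full
revolution in the left-handed sense; no scale volume falls outside the
bell-shaped volume-versus-Z profile; and no scale touches the cytoplasm
(the default phantom adds only a free cytoplasm blob).

The packaged reference table of 25 daughter-shell scales (surface and
cytoplasm contact areas in µm² measured on a cell caught mid-construction)
summarizes to:

```r
summarize_contacts(table1_scales())
#> 25 scales: 17 in contact with the cytoplasm (15 partial, 2 full)
#> largest partial contact: D22, 9.542 um^2
```

i.e. 17 of the 25 scales touch the pseudopodial cytoplasm, two of them
(D23, D24) over their entire surface, and the largest partial contact is
scale D22 with 9.5 µm² of its 27.6 µm² surface — about a third — covered.

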