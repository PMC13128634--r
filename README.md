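# splatphen

Extraction of individual plant instances from multi-plant 3D Gaussian
Splatting (3DGS) scenes, and measurement of phenotypic traits from the
extracted instances.

A 3DGS reconstruction of a greenhouse row mixes the plant of interest with
its neighbours, soil, pots, trellis structure and floating reconstruction
artifacts. `splatphen` isolates one target plant from such a scene using
only a handful of 2D instance masks in seeded views, then measures six
phenotypic traits on the result:

1. **Lift** — each Gaussian is projected into every seeded view; the
   mask-coverage fraction of its footprint, weighted by opacity, viewing
   angle and view sharpness, gives a per-splat support score
   `S(g) ∈ [0, 1]`, thresholded at a support quantile (`support_scores()`,
   `foreground_select()`).
2. **Cluster** — the foreground is consolidated by OPTICS density
   clustering in a robust-standardized 4D space (position + mean camera
   distance); the cluster with the largest background-corrected support
   mass is selected, nearby fragments are merged back under a
   spatial-extent and camera-depth gate, and a single-pass
   nearest-neighbour retain step recovers thin foliage
   (`optics_cluster_merge()`, `nn_retain()`).
3. **Refine** — splat colours are modelled in CIELAB with a BIC-selected
   Gaussian mixture; splats outside the Mahalanobis window of the dominant
   (foliage) component are removed (`refine_subset()`).

`extract_plant()` runs the three stages end to end. Downstream,
`group_instances()` / `remap_to_splats()` turn externally supplied
stem/leaf point semantics into organ instances on the splats, and the trait
layer measures plant height, leaf surface area, leaf area index, leaf
count, node count and internode lengths in a metric frame estimated from a
reference object of known length (`metric_scale_align()`,
`plant_height()`, `leaf_area_lai()`, `leaf_count()`, `stem_skeleton()`,
`internode_stats()`).

The package also ships bit-stable 3DGS PLY input/output, video
frame-selection policies for reconstruction (`select_frames()`), a
synthetic greenhouse scene generator with full ground truth
(`make_scene()`), evaluation metrics (`extraction_metrics()`,
`pr_sweep()`, `instance_ap()`), and a command-line interface.

The methods vignette (`vignette("plant-extraction")`) documents the model
and the rationale behind each default.

## Worked example

A synthetic three-plant greenhouse scene with noisy cue masks (3 px mask
dilation plus two clutter rectangles):

```r
library(splatphen)

b <- make_scene(seed = 0)
cues <- render_cue_masks(b, noise = list(dilate_px = 3, clutter_boxes = 2,
                                         dropout = 0), seed = 0)
res <- extract_plant(b$scene, b$cameras, cues, rng_seed = 0)
str(res[c("foreground", "kept", "retained", "refined")], vec.len = 2)
#> List of 4
#>  $ foreground: int [1:412] 54 55 56 57 58 ...
#>  $ kept      : int [1:287] 444 445 446 447 448 ...
#>  $ retained  : int [1:287] 444 445 446 447 448 ...
#>  $ refined   : int [1:229] 444 445 446 447 448 ...

m <- extraction_metrics(res$refined, b$gt$plant_label)
round(c(precision = m$precision, recall = m$recall, miou = m$miou), 3)
#> precision    recall      miou
#>     0.865     1.000     0.928
```

Height of the extracted plant, measured in the metric frame fixed by the
scene's reference pair:

```r
ref <- b$scene$positions[b$gt$ref_ids + 1L, ]
frame <- metric_scale_align(b$scene$positions, ref, b$gt$ref_length_m)$frame
plant <- subset_splats(b$scene, res$refined)
tpos <- apply_metric_frame(frame, plant$positions)
round(c(height_m = plant_height(tpos),
        gt_height_m = b$gt$gt_height_m[b$gt$target_plant]), 4)
#>    height_m gt_height_m
#>      0.2295      0.2249
```

Across the five-seed synthetic suite with the same mask noise, the full
pipeline at its defaults (`q = 0.88`, `xi = 0.1`, `beta = 2`,
`zeta = 0.80`) reaches mean precision 0.932, recall 0.956 and mIoU 0.939
against generator ground truth.

## Command-line interface

A thin `Rscript` dispatcher wraps the package for file-based use:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "splatphen.R", package = "splatphen"))')
Rscript "$CLI" synth   --seed 0 --out scene/
Rscript "$CLI" extract --scene scene/scene.ply --cameras scene/cameras.json \
                       --cues scene/cues --out plant.ply
Rscript "$CLI" eval    --extracted plant.ply.json --gt scene/gt.json \
                       --out metrics.json
#> precision 0.865 recall 1.000 mIoU 0.928
```

Commands: `synth`, `select-frames`, `lift`, `cluster`, `refine`,
`extract`, `group`, `remap`, `traits`, `eval`. Flags can be collected in a
YAML file passed as `--config`; every run writes its resolved configuration
next to its outputs. Exit codes: `0` success, `2` input/format error, `3`
degenerate data.

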