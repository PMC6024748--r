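# stalkfield

Individual-plant segmentation of young maize fields scanned by
terrestrial LiDAR (TLS), in R.

High-throughput phenotyping needs per-plant traits, but a TLS point cloud
of a maize field is one undifferentiated set of millions of points, and
interleaving leaves defeat top-down (canopy-height) segmentation. The
stem, however, is a narrow, isolated, near-vertical structure that is
easy to find in thin side views. `stalkfield` therefore:

1. removes ground points lying within 0.1 m of the local (0.25 m cell)
   minimum elevation;
2. rotates the cloud into 32 azimuthal viewing directions and tiles each
   into 3D windows (1.024 m x 1.024 m field, 0.016 m depth);
3. compresses every window into a 256 x 256 depth image
   (pixel intensity `1 - (y_nearest - y0)/depth`);
4. detects stems on the images with a confidence-scored box detector
   (deterministic geometric baseline included; anchor/IoU utilities for a
   learned backend provided), keeping detections with confidence > 0.9;
5. maps surviving boxes back to 3D *seed points* and fuses the 32
   directions, keeping the best detection per plant (single-linkage
   grouping within 0.1 m);
6. grows each plant bottom-up by **comparative shortest paths**: on a
   k-nearest-neighbour graph (k = 10, 0.05 m edge cap), every point
   joins the seed minimizing the diameter-scaled transport distance

   DvN = Dv / DBH^(2/3),

   where `Dv` is the multi-source graph shortest-path distance to the
   seed's points and DBH the seed's estimated stem diameter;
7. extracts plant heights and, when reference labels exist, reports
   plant-level recall / precision / F-score
   (`r = TP/(TP+FN)`, `p = TP/(TP+FP)`, `F = 2rp/(r+p)`) and a height
   regression (R-squared, RMSE, mean bias).

A synthetic-field generator (`field_spec()`, `generate_field()`) emulates
ridge-planted elongation-stage maize at the sparse / moderate / dense /
training densities of the reference trial (2.69-8.96 plants/m^2), so the
whole pipeline is testable without a scanner. Point clouds are read and
written as ASCII XYZ, PLY (ASCII or binary) and LAS 1.2, with per-point
plant labels.

## Worked example

```r
library(stalkfield)

spec  <- field_spec("sparse", area = 4, rng_seed = 1L)  # small demo field
field <- generate_field(spec)
print(field$cloud)
#> <stalk_cloud> 59152 points, frame 'world', 11 labelled plants
#>   extent x [-0.250, 1.750]  y [-0.127, 1.922]  z [-0.015, 0.566] m

result <- run_pipeline(field$cloud, pipeline_config(), truths = field$truths)
print(result)
#> <pipeline_result> 11 plants from 21985 points (11.9 s)
#> <eval_report> TP 11  FP 0  FN 0
#>   r 1.00  p 1.00  F 1.00
#>   height: R2 1.00  RMSE 0.002 m  bias -0.011 m (n = 11)

head(seeds_table(result$seeds), 3)
#>   seed_id           x          y         z confidence   diameter n_points
#> 1       1 0.001579429 0.99679563 0.1242810  0.9044118 0.01573823      198
#> 2       2 0.003591919 1.60254005 0.1703513  0.9829268 0.01884205      465
#> 3       3 0.019841933 0.02354543 0.1880652  0.9774306 0.02421943      571
```

All 11 plants are recovered (TP 11, no false positives or negatives).
The height bias of -0.011 m is the expected signature of the 0.1 m
ground cut removing a little of each stem base; the regression RMSE of
0.002 m says heights are otherwise recovered to millimeters. Seed
diameters (1.6-2.4 cm here) feed the DvN scaling during region growth.

A command-line interface wraps the same functions:

```sh
Rscript inst/cli/stalkfield.R simulate --preset sparse --seed 1 \
    --out cloud.ply --truth truth.csv
Rscript inst/cli/stalkfield.R run --in cloud.ply --out results/
```

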