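# h2axprofiler

Texture-based profiling of DNA damage in thick 3D fluorescence histology
volumes.

## The problem

In cleared ~125 µm tumor sections imaged by confocal microscopy, the
γH2AX channel reports DNA double-strand-break signaling: discrete nuclear
foci during active repair, near-uniform pan-nuclear staining in heavily
damaged or apoptotic cells. Classical quantification counts foci or
positive cells. This package instead profiles the *staining texture* of
each γH2AX⁺ nucleus and the composition of its local cell neighborhood,
for researchers comparing control and treated tumor tissue regions —
including how close cytotoxic (CD8⁺) T cells sit to damaged cells.

Starting from a nuclei instance segmentation (produced externally, e.g.
by a pre-trained Cellpose model on the DAPI channel) plus the marker
channels, the pipeline:

1. **identifies marker-positive cells** by thresholding a marker channel
   and superimposing it on the (optionally dilated) instance map: a cell
   is positive when |instance ∩ mask| / |instance| reaches a threshold
   (γH2AX: no dilation, threshold 0.5; CD8, a membrane marker: 2-voxel
   ball dilation, threshold 0.15);
2. **represents each γH2AX⁺ nucleus** as a centered 64×64 patch, by
   gray-level co-occurrence matrix (GLCM) features — energy Σp²,
   contrast Σ(i−j)²p, cluster prominence Σ(i+j−μᵢ−μⱼ)⁴p, correlation
   Σ(i−μᵢ)(j−μⱼ)p/σᵢσⱼ — and by 16-dimensional latent means from a
   VAE-GAN (3-conv-layer encoder, mirrored transposed-conv generator,
   5-conv-layer discriminator whose 4th-layer feature maps define a
   learned similarity metric; Adam, lr 10⁻⁴);
3. **clusters representations** into k pseudo texture classes (seeded
   k-means, k = 5 default, PCA 2D projection for inspection);
4. **profiles spherical neighborhoods** around γH2AX⁺ cells: per-class
   neighbor counts (class × class co-occurrence heatmaps, per-center
   means) and CD8⁺ counts at radii 32/64/128 px (10.28/20.56/41.12 µm at
   the default 0.32125 µm/px lateral pitch), and compares conditions by
   region-label permutation tests.

A seedable synthetic-data generator (ellipsoidal nuclei, planted focal
vs pan-nuclear γH2AX textures, membrane CD8 shells, full ground truth)
makes every stage testable without external data. The VAE-GAN runs on a
compact, fully deterministic conv/batch-norm/Adam layer library built on
base BLAS matrix products and verified against finite-difference
gradients.

## Worked example

```r
library(h2axprofiler)

# 1. synthesize an annotated region (stand-in for a segmented acquisition)
spec <- synth_spec(shape = c(32L, 128L, 128L), n_nuclei = 60L,
                   frac_gh2ax_pos = 0.4, n_cd8 = 6L, rng_seed = 42L)
region <- generate_region(spec)

# 2. identify marker-positive cells
cells <- build_cell_table(region$labels,
                          threshold_channel(region$channels$GH2AX, "otsu"),
                          threshold_channel(region$channels$CD8, "otsu"),
                          region_id = "demo")
#> region demo: 60 instances, 24 gamma-H2AX+, 6 CD8+

# 3. GLCM texture features for each gamma-H2AX+ nucleus
patches  <- extract_patches(region$channels$GH2AX, cells, region$labels)
features <- glcm_table(patches)
head(features, 3)
#>   cell_id energy contrast prominence correlation
#> 1       1  0.906     4.55     120150       0.884
#> 2       5  0.925     4.31     130080       0.881
#> 3      10  0.863     2.39      52949       0.906

# 4. pseudo texture classes and neighborhood co-occurrence
classes  <- cluster_representations(features, k = 2, seed = 42)
profiles <- neighborhood_counts(cells, classes, radius_px = 48)
cooccurrence_heatmap(profiles, condition = "CONTROL")$H
#>          neigh_0 neigh_1
#> center_0    3.54    3.77
#> center_1    4.45    3.09

# 5. CD8 proximity at the standard radii
cd8_proximity_report(cells)$summary
#>   radius_px radius_um n_cd8 total_gh2ax_near mean_gh2ax_near
#> 1        32      10.3     6               14            2.33
#> 2        64      20.6     6               57            9.50
#> 3       128      41.1     6              141           23.50
```

The example reads: of 60 synthetic nuclei, 24 are γH2AX⁺ and 6 CD8⁺;
texture features separate into two pseudo classes; within 48 px a
class-0 cell sees on average 3.5 class-0 and 3.8 class-1 neighbors; each
CD8⁺ cell has on average 9.5 γH2AX⁺ cells within 64 px (20.56 µm). The
`run_pipeline()` orchestrator chains the same stages (synth → segment →
glcm → vaegan → cluster → profile → compare) with YAML config, JSON
provenance and config-hash caching; `inst/cli/h2axprofiler.R` exposes it
from the shell. The VAE-GAN branch is trained with
`train_vaegan(build_vaegan(), patches, train_config())` and encoded with
`encode_table()`; `reference_train_config()` carries the full 500-epoch
schedule.

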