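# fscc — few-shot subtomogram classification

`fscc` classifies cryo-electron tomography subtomograms from **very few
labeled examples**. It is aimed at cryo-ET practitioners who can label a
handful of particles of a new macromolecule but not the hundreds to
thousands that retraining a supervised 3D CNN would need.

The method is a two-stage pipeline:

1. **Contrastive pre-training** on abundant *base* classes: a six-block 3D
   convolutional feature extractor f<sub>θ</sub> plus linear head, trained
   with the weighted loss

   L = L<sub>CE</sub> + λ·L<sub>SCL</sub>,  λ = 0.05,

   where L<sub>SCL</sub> is the supervised contrastive loss (temperature
   τ = 0.07) that tightens within-class feature clusters.

2. **Distribution calibration** for *novel* classes (disjoint from the base
   classes): with the extractor frozen, each support feature v is
   Tukey-transformed (ṽ = v^0.5), the k = 2 nearest base classes (by
   ‖μ<sub>i</sub> − ṽ‖₂) donate their feature statistics,

   μ′ = (Σ<sub>i∈S</sub> μ<sub>i</sub> + ṽ)/(k+1),  Σ′ = Σ<sub>i∈S</sub> Σ<sub>i</sub>/k,

   and 150 synthetic features per support example drawn from
   N(μ′, Σ′ + εI) augment the support before a ridge multinomial head is
   retrained. Accuracy and macro F1 are reported over randomly sampled
   N-way-K-shot episodes.

The package also ships everything needed to exercise the method without
external data: a synthetic subtomogram simulator (geometric density maps,
uniform random 3D orientations, Gaussian noise at an exact variance-ratio
SNR, optional missing wedge), a feature-space Gaussian benchmark for
testing calibration in isolation, MRC volume I/O with CSV manifests, a
fine-tuning baseline comparator, and a small CLI.

## Worked example

```r
library(fscc)

# synthetic dataset: 7 shape classes, 16^3 voxels, SNR 0.5
ds <- build_synthetic_dataset(simulator_config(
  7, grid_size = 16, samples_per_class = 60, target_snr = 0.5, seed = 17))
split <- make_split(0:6, n_novel = 3, seed = 17)
base <- which(ds$labels %in% split$base_classes)
novel <- which(ds$labels %in% split$novel_classes)

# stage 1: contrastive pre-training on the base classes
bb <- fscc_pretrain(ds$volumes[base], ds$labels[base],
                    backbone_config(channel_widths = rep(16L, 6), input_edge = 16),
                    pretrain_config(batch_size = 32, epochs = 20,
                                    learning_rate = 1e-3, seed = 17),
                    loss_config(lambda_scl = 0.05))

# stage 2: calibrated episodic evaluation on the novel classes
report <- evaluate_from_volumes(bb, ds$volumes[base], ds$labels[base],
                                ds$volumes[novel], ds$labels[novel],
                                method = "fscc", n_way = 3, k_shot = 1,
                                n_tasks = 30, master_seed = 17)
report
#> 3-way-1-shot evaluation, 30 tasks, method: fscc
#>   mean accuracy 83.85% (sd over tasks 10.29%, 95% half-width 3.84%)
#>   macro F1 0.839
```

The mean accuracy is averaged over 30 random 3-way-1-shot episodes (15
queries per class); the dispersion lines quantify episode-to-episode
variability; macro F1 pools one-vs-rest confusion counts across tasks.
Chance level here is 33.3%. Swapping `method = "baseline"` evaluates the
plain fine-tuning head on the same episodes, and
`calibration_config(n_sampled_per_support = 0)` gives the no-calibration
ablation. On this clean synthetic regime the baseline is strong —
calibration's benefit depends on the base catalogue containing classes
similar to the novel ones; see the methods vignette for when each arm
wins.

A command-line interface over the same functions:

```sh
FSCC=$(Rscript -e 'cat(system.file("cli", "fscc.R", package = "fscc"))')
Rscript $FSCC simulate --config sim.yaml --out data/
Rscript $FSCC pretrain --manifest data/manifest.csv --config pretrain.yaml --out ckpt.rds
Rscript $FSCC calibrate-eval --ckpt ckpt.rds --manifest data/manifest.csv \
    --nway 5 --kshot 1 --tasks 100 --seed 7 --out report.json
```

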