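# surgraph

Instrument–tissue interaction detection in surgical scenes with a
visual–semantic graph attention network, and *incremental domain
generalization*: extending a source-domain model to a shifted target domain
with novel instruments while retaining source performance.

## Who this is for

Researchers working on surgical scene understanding (or structurally similar
human–object interaction problems) who want a complete, CPU-scale, fully
reproducible implementation of:

* **Scene-graph interaction detection** — entities (one tissue, 1–3
  instruments, given as bounding boxes) become nodes of parallel visual and
  semantic graphs; after one round of graph attention the combined graph's
  tissue→instrument edges are read out into 13 interaction classes
  (idle, grasping, retraction, tissue manipulation, tool manipulation,
  cutting, cauterization, suction, looping, suturing, clipping, staple,
  ultrasound sensing).
* **E-CBS** (enhanced curriculum by smoothing) — fixed Laplacian-of-Gaussian
  and Gaussian convolutions, `LoG(x,y) = -(1/πσ⁴)(1-(x²+y²)/2σ²)e^{-(x²+y²)/2σ²}`,
  whose bandwidth decays as `σ(e) = σ₀·d^⌊e/p⌋` during training.
* **T-Norm** — logits divided by a fixed temperature (graph: 1.5, feature
  extractor: 3.0) at training *and* inference; calibration is quantified
  with reliability diagrams and expected calibration error.
* **Incremental learning** — the crop classifier is widened from 9 to 11
  entity classes with a 50-crop exemplar memory, old-model distillation and
  balanced fine-tuning.
* **KD-based domain generalization** — a frozen source-trained teacher and a
  student trained with `L_DG = L_TD + L_nSD`, where `L_TD` is the
  multi-label soft-margin loss on the full target set and
  `L_nSD = L_MSL + 0.5·L_KD` on a sample of n source scenes, followed by
  balanced fine-tuning.

Real surgical datasets are not required: a seeded generator synthesizes
two-domain scene fixtures with the relevant structure (long-tailed classes,
visual domain shift, novel target instruments, deterministic geometry-based
interaction labels).

## Worked example

```r
library(surgraph)

cfg <- experiment_config("desk_scale", seed = 1)
run <- run_protocol(cfg, out_dir = "run1", compare = TRUE)
print(run$metrics)
```

which prints (desk scale: 200 source / 50 target scenes, about two minutes
on one CPU):

```
              model domain      acc       map    recall        ece n_edges
1           teacher source 90.68010 0.9753051 0.9420481 0.02014426     397
2           teacher target 32.25806 0.5866243 0.2271102 0.45014642      93
3    incremental_dg source 85.64232 0.9471475 0.8282951 0.07537394     397
4    incremental_dg target 94.62366 0.9807420 0.9377218 0.05076934      93
5 domain_adaptation source 69.77330 0.8517970 0.7136831 0.20392646     397
6 domain_adaptation target 96.77419 0.9931579 0.9625117 0.04027388      93
7          naive_dg source 74.05542 0.8789052 0.7342351 0.17065314     397
8          naive_dg target 96.77419 0.9943687 0.9550420 0.03660600      93
```

Reading it: the teacher masters the source domain (90.7% edge accuracy) but
not the shifted target (32.3%). All three phase-2 regimes fix the target
domain (95–97%), but they differ sharply in what they *keep*: naive
adaptation forgets the source (69.8%), naive DG recovers some of it through
balanced fine-tuning (74.1%), and distillation-based incremental DG retains
almost all of it (85.6%) — the headline retention ordering, which
`retention_experiment()` reproduces as a mean over independent training
seeds. (Your exact values depend on the seed.)

A shell front end with the same stages ships under `inst/cli/surgraph`
(after installation: `system.file("cli", "surgraph", package = "surgraph")`),
with subcommands `simulate`, `train-fen`, `extend-fen`, `train-graph`, `dg`,
`evaluate` and `run-all`.

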