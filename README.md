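# surgtcn

Joint online recognition of coarse **surgical phases** and fine-grained
**steps** in procedure videos with a multi-task multi-stage causal temporal
convolutional network (MTMS-TCN), in base R.

## The problem

Surgical workflow recognition assigns every video frame of a procedure two
nested labels: a coarse *phase* (e.g. "gastrojejunal anastomosis") and a
fine-grained *step* inside it (e.g. "stay suture placement"). The reference
annotation scheme for laparoscopic gastric bypass uses 11 phases and 44
steps, each step belonging to exactly one parent phase. Recognition must be
**online**: the prediction at frame *t* may only use frames up to *t*, so the
model can run during surgery. Step recognition is much harder than phase
recognition — steps are short, visually similar, and strongly imbalanced —
and the central claim of the modelled study is that learning both levels
*jointly* lets the fine-grained task benefit from the coarse one.

## The model

`surgtcn` implements the full pipeline of that study:

1. **Backbone contract** — a frame-level multi-task CNN (shared trunk, one
   softmax head per task) trained with median-frequency-balanced weighted
   cross-entropy, `L_total = L_phase + L_step`; its penultimate layer yields
   one feature vector per frame (`N_f = 2048` in the reference setup). A
   compact, CPU-trainable trunk ships with the package
   (`train_backbone()` / `extract_features()`); ResNet-50-class features plug
   in through the same feature-container files.
2. **MTMS-TCN** — `mtms_tcn()` fits the temporal model: `S` stages of `L`
   dilated **causal** residual layers (dilation doubling per layer; receptive
   field `1 + (k-1)(2^L - 1)` frames, ≈ 34 min at 1 fps for `L = 10`,
   `k = 3`), each stage ending in a phase head and a step head. Stage
   `s + 1` consumes the concatenated per-frame class probabilities of stage
   `s` and refines them. All stages are supervised with unweighted frame-mean
   cross-entropy summed over stages and tasks. Training, backpropagation and
   Adam are implemented in base R matrix operations — no deep-learning
   framework is required.
3. **Streaming inference** — `tcn_stream()` / `stream_step()` /
   `online_predict()` run the identical model frame by frame with
   receptive-field-bounded ring buffers; emitted predictions match the batch
   forward pass and never change when more frames arrive.
4. **Evaluation protocol** — frame accuracy, class-wise precision / recall /
   F1 with macro averaging (`classwise_prf()`), joint phase+step accuracy,
   video-level cross-validation (`make_folds()`: 40 videos → 4 folds of
   test 10 / train 24 / val 6) and mean ± sd aggregation
   (`aggregate_folds()`), plus ribbon-plot visualization (`ribbon_plot()`).
5. **Synthetic data** — the study's dataset is private, so the package ships
   a semi-Markov hierarchical workflow generator (`workflow_model()`,
   `sample_workflow()`) with truncated negative-binomial dwell times, optional
   steps, phase skips, and class-conditional Gaussian feature emission
   (`emission_model()`, `emit_features()`). `default_model()` emulates the
   study's scale: ~110-minute videos at 1 fps with two-decade long-tailed
   step durations.

## Worked example

Define a small ontology, simulate a corpus, fit the model, and evaluate on
held-out videos:

```r
library(surgtcn)

h <- hierarchy(
  phases = data.frame(phase_id = 0:2,
                      name = c("preparation", "dissection", "closure")),
  steps  = data.frame(step_id = 0:5, name = paste0("step_", 0:5),
                      parent_phase_id = c(0, 0, 1, 1, 1, 2)))

sp <- data.frame(step_id = 0:5, incl_prob = c(1, 0.8, 1, 0.9, 1, 1),
                 mean_dur = c(40, 20, 60, 30, 50, 25), size = 5,
                 min_dur = 3, max_dur = 300)
wf <- workflow_model(h, sp)
em <- emission_model(n_steps = 6, dim = 16, noise_sd = 0.5, seed = 1)

timelines <- lapply(1:8, function(i)
  sample_workflow(wf, seed = i, video_id = paste0("v", i)))
features  <- lapply(1:8, function(i)
  emit_features(timelines[[i]], em, seed = 100 + i))

cfg <- tcn_config(input_dim = 16, n_phases = 3, n_steps = 6,
                  n_stages = 2, n_layers = 6, n_channels = 16, seed = 1)
fit <- mtms_tcn(features[1:6], timelines[1:6], cfg, val = 6,
                epochs = 120, learning_rate = 3e-4, seed = 1)
fit
#> MTMS-TCN: 2 stage(s) x 6 layers, 16 channels, kernel 3 (receptive field 127 frames)
#> tasks: both; input N_f = 16; trained 120 epochs on 5 videos
#> best validation epoch 120: phase acc 0.897, step acc 0.798

pred <- predict(fit, features[7:8])          # held-out videos
print(evaluate_predictions(timelines[7:8], pred), digits = 3)
#>    task    metric value
#> 1 phase  accuracy 0.947
#> 2 phase precision 0.908
#> 3 phase    recall 0.962
#> 4 phase        f1 0.930
#> 5  step  accuracy 0.883
#> 6  step precision 0.789
#> 7  step    recall 0.805
#> 8  step        f1 0.789
#> 9 joint  accuracy 0.877

# online inference gives frame-identical output
os <- online_predict(features[[7]], fit)
identical(os$phase, pred[[1]]$phase)
#> [1] TRUE
```

The fitted object supports the usual surface: `print()`, `summary()`,
`coef()`, `predict(type = "class" | "prob", stage = ...)` and `plot()` (training
curves).

## Command line

A thin CLI over the same functions is installed at
`system.file("scripts", "surgtcn", package = "surgtcn")`:

```sh
surgtcn simulate        --out corpus --seed 1 --n-videos 40
surgtcn train-backbone  --corpus corpus --out backbone
surgtcn extract-features --corpus corpus --backbone backbone/backbone.rds --out feats
surgtcn train-tcn       --corpus feats --out tcn --folds 4 --stages 2
surgtcn evaluate        --corpus feats --pred tcn --out tcn
surgtcn visualize       --corpus feats --pred tcn --out plots
```

Flags can come from a YAML file (`--config run.yaml`), with command-line
flags taking precedence; every subcommand writes a machine-readable run
record.

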