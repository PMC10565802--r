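# snnxattr

Gradient-based feature attribution for spiking neural networks (SNNs).

Spiking networks communicate through binary spikes over discrete time, so
the standard saliency toolbox for deep networks does not transfer directly:
there is no logit, the decision is the most-spiking output neuron, the
spike function is non-differentiable, and an input is a 3D volume of
spike cells `(y, x, t)` rather than a pixel grid. `snnxattr` implements
the full explanation loop for such models, end to end and without any
external data:

- **A differentiable LIF substrate.** Leaky integrate-and-fire layers
  (convolutional, pooling, fully connected) with discrete-time dynamics
  `U(t) = λ·U_reset(t−1) + a(t)`, spike `s(t) = [U(t) ≥ θ]`, soft
  (subtract) or hard (zero) reset, and surrogate-gradient backpropagation
  through time using `ρ(u) = (α/2)·exp(−α|u − θ|)` (or a fast sigmoid) in
  place of the threshold derivative. Forward simulation, input gradients
  and toy-scale training (`simulate_forward()`, `input_gradient()`,
  `train_snn()`).
- **Neural encoders** from 8-bit grayscale images to spike tensors:
  time-to-first-spike (one spike at `t = v`, black earliest), Poisson
  rate (`p = v/255`), phase (binary expansion over oscillation cycles)
  and burst coding (count + inter-spike interval).
- **Attribution methods.** The class score is the output spike count
  `S_C = Σ_t s_C(t)`; `snn_grad3d()` backpropagates `∂S_C/∂input` to every
  spike cell. `snn_ig2d()` integrates gradients along an image path from a
  black baseline (each path image re-encoded into spikes); `snn_ig3d()`
  integrates along a temporal-subsampling path from the empty stream for
  native event data. `sam()`/`isam()` provide the forward-only spike
  activation map baseline and its negation. `collapse_time()` maps 3D
  attribution boxes to pixel maps (sum/max/avg) and `normalize_map()`
  applies `H' = |(H − H_min)/(H_max − H_min)|` for heatmaps.
- **Quantitative evaluation.** Deletion/insertion perturbation curves
  against a seeded random-ranking control (`run_perturbation_experiment()`,
  `curve_auc()`), and jitter / spike-deletion noise-robustness sweeps at
  the input or inside the network (`run_noise_sweep()`).
- **Synthetic fixtures**: class-separable oriented-bar images and
  moving-dot event streams (`make_toy_images()`,
  `make_toy_event_streams()`), plus plain-text event CSV and PNG IO.

Results come back as tibbles and plot via `autoplot()`; fitted networks
support `tidy()`/`glance()`.

## Worked example

```r
library(snnxattr)

# 1. a toy dataset of oriented bars, TTFS-encoded (T = 256)
cfg  <- toy_dataset_config(seed = 7)                 # 3 classes x 10 images
data <- encode_dataset(make_toy_images(cfg), encoder_config("ttfs"))

# 2. train a small spiking classifier on spike-count targets
net <- build_network(toy_network_spec(), seed = 1)
net <- train_snn(net, data, train_config(epochs = 15, learning_rate = 2e-4,
                                         target_high = 10, target_low = 1,
                                         seed = 5))
glance(net)
#> # A tibble: 1 x 5
#>   n_layers n_weights n_classes final_loss final_accuracy
#>      <int>     <int>     <int>      <dbl>          <dbl>
#> 1        2      1072         3       6.43              1

# 3. explain one decision at spike level, then map it to pixels
x   <- data$input[[1]]
map <- snn_grad3d(net, x)          # gradient of the winning class score
map
#> <attribution_map3d> snn-grad3d, class 1, dims 1x8x8x256, range [-2.115, 2.183]
heat <- normalize_map(collapse_time(map, "sum"))
autoplot(heat)                     # pixel-level heatmap

# 4. is the map faithful? deletion curve vs a random control
samples <- purrr::map2(data$input, data$label, ~list(input = .x, label = .y))
cur  <- run_perturbation_experiment(net, samples, function(n, i) snn_grad3d(n, i),
                                    level = "spike", direction = "delete",
                                    fractions = c(0, .05, .1, .2, .4, .6, .8, 1))
rand <- run_perturbation_experiment(net, samples, "random",
                                    level = "spike", direction = "delete",
                                    fractions = c(0, .05, .1, .2, .4, .6, .8, 1),
                                    seed = 1)
c(grad = curve_auc(cur), random = curve_auc(rand))
#>   grad random
#> 0.3875 0.6725
```

The deletion curve starts at accuracy 1 (the evaluation subset is the
correctly classified samples) and the gradient-guided curve falls much
faster than the random control — deleting the cells the map calls
important destroys the decision sooner, which is the operational test of
a faithful attribution map. The insertion direction reads the other way
round: higher AUC is better.

A command-line front end wraps the same pipeline:

```sh
snnxattr train     --config run.yaml --seed 1 --out run/
snnxattr attribute --config attr.yaml --out attr/
snnxattr evaluate  --config eval.yaml --out eval/
```

(the script is installed under `exec/` in the package directory; configs
are YAML, and every output directory receives a frozen copy of the
resolved config).

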