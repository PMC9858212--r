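# nisr — learning coarse-grained dynamics and detecting causal emergence

`nisr` addresses a question that comes up across systems biology, network
science and complex-systems modelling: given only a fine-grained stochastic
time series, is there a coarser description of the system whose dynamics
are *more causally informative per dimension* than the original one — and
if so, at which scale? The package learns the answer end to end from data:
it trains an encoder–dynamics–decoder model (an *information squeezer*)
whose encoder is an exactly invertible neural network composed with a
projection, then scans the macro dimension `q` and scores every scale by
dimension-averaged effective information.

## The model and statistic

The coarse-graining map is factored as

    phi_q = chi_q ∘ psi,        phi_q^+(y) = psi^{-1}(y ⊕ z),  z ~ N(0, I_{p-q})

where `psi` is an affine coupling flow (RealNVP-style: exact inverse,
closed-form log-Jacobian) and `chi_q` keeps the first `q` coordinates. The
macro dynamics are residual, `y_{t+1} = y_t + f(y_t) + xi`, with diagonal
noise `sigma`. Stage 1 trains the whole pipeline by minimising the mean
l-norm of the micro prediction error (the Gaussian/Laplacian likelihood);
stage 2 retrains for every `q` and compares scales by

    dEI(f)  = EI(f) / n
    dCE     = dEI(macro) − dEI(micro)
    EI      = n ln(2L) + E_{X~U([−L,L]^n)} ln|det ∂μ(X)| − Σ_i ln(σ_i √(2πe))

with the micro reference a full-dimensional (`q = p`) model trained the
same way. The scale with maximal dCE is the emergent one. Exact discrete
EI (`ei_discrete`) and a k-nearest-neighbour mutual-information estimator
(`mi_estimate`, C++ backend) support validation and the channel-theorem
diagnostics. See `vignettes/nisr-methods.Rmd` for assumptions, parameter
choices and limitations.

## Worked example

The 8-state Markov chain benchmark: seven states that shuffle uniformly
among themselves plus one absorbing state, observed as one-hot vectors in
R^8. The causally compact description is one-dimensional ("communicating
or absorbed"), which the scan recovers:

```r
library(nisr)
data <- simulate_markov(8000, seed = 1)
cfg  <- train_config(q = 1, epochs = 1000, batch_size = 128,
                     learning_rate = 3e-3, lr_decay = 0.03,
                     seed = 0, n_mc = 300)
rep  <- scan_q(data, cfg, qs = c(1, 2, 3), epsilon = 0.5,
               keep_models = TRUE)
print(rep)
#> Causal-emergence scan (reference dEI_micro = -0.09627 nats/dim)
#>  q train_loss  val_loss        dEI        dCE effectiveness error
#>  1  0.8082556 0.8245368 -0.6510583 -0.5547883      0.123625  <NA>
#>  2  0.8079305 0.8275771 -3.4842326 -3.3879626      0.123625  <NA>
#>  3  0.8137690 0.8247754 -1.4155754 -1.3193054      0.123625  <NA>
#> selected q* = 1

cl <- count_macro_clusters(rep$models[["q1"]], diag(8))
cl$n_clusters
#> [1] 2
cl$assignment
#> [1] 2 2 2 2 2 2 2 1
```

Reading the output: for each scanned scale the report shows the training
and validation prediction losses, the dimension-averaged effective
information of the learned macro dynamics (`dEI`, nats per dimension),
its excess over the full-dimensional reference model (`dCE`), and the
fraction of transitions predicted within `epsilon`. dCE peaks at `q* = 1`:
among all scales, the one-dimensional description is the causally
strongest per dimension (at this deliberately small budget its absolute
dCE is still negative; the full-scale run in `scripts/acceptance.R`, with
20,000 pairs and 2,000 steps, drives dCE(1) positive). The cluster
readout of the trained `q = 1` encoder then shows exactly two macro
states — the seven communicating
states share one code, the absorbing state sits alone — which is the
ground-truth partition.

The other two benchmarks work the same way: `simulate_spring()` (noisy
two-sensor oscillator, emergence at `q = 2`) and `simulate_boolean()`
(4-node probabilistic Boolean network). All simulators, training runs and
scans are deterministic given their seeds.

## Command line

```sh
Rscript inst/cli/nis.R simulate --system spring --n-pairs 5000 --seed 1 --out data.csv
Rscript inst/cli/nis.R train    --data data.csv --q 2 --epochs 2000 --seed 1 --out model.json
Rscript inst/cli/nis.R scan     --data data.csv --seed 1 --report report.json
Rscript inst/cli/nis.R run      --preset markov --seed 1 --out-dir results/
```

Every run writes a JSON manifest (config snapshot, seeds, input digests)
next to its outputs; reruns with identical config and seed reproduce
outputs bit for bit.

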