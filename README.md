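# crowdcaps

Capsule networks with recurrent routing-by-agreement as models of visual
crowding and uncrowding, together with the psychophysical machinery used to
measure the same phenomena in human observers — implemented entirely in base
R linear algebra (no deep-learning framework required).

## The scientific problem

A *vernier* — two vertical bars with a small horizontal offset — is easy to
judge (left/right) in isolation. Surround it with a flanking shape and
performance collapses (*crowding*); surround it with a *group* of identical
flankers and performance recovers (*uncrowding*), because the visual system
segments the coherent group away from the target. This global, configuration-
dependent effect is a hard, well-controlled challenge for vision models:
feedforward networks fail it.

`crowdcaps` implements the capsule-network account: early convolutions
extract features, primary capsules detect individual shapes, and an
iterative *routing-by-agreement* loop — couplings are the softmax over
parents of agreement logits, parent outputs are squashed coupling-weighted
vote sums — groups shapes into secondary capsules (one per stimulus class).
Networks are trained on isolated verniers and isolated shape groups only
(margin loss on capsule norms for shape type; cross-entropy decoders for
vernier offset, repetition count and location; a reconstruction decoder;
total loss weights 0.5 / 1 / 0.4 / 0.0005 / 0.1; Adam, batch 48, learning
rate 4e-4 with cosine warm restarts) and then tested on (un)crowding
compositions they have never seen. Matched controls replace the capsule
layers with feedforward, laterally recurrent, or top-down recurrent fully
connected layers of the same neuron count. The psychophysics module
implements the PEST adaptive staircase (start 16.66 arcmin, cap 33.3
arcmin, 2 x 80 trials) with maximum-likelihood cumulative-Gaussian
threshold estimation, validated on simulated 2AFC observers.

## Worked example

Estimate a vernier threshold for a simulated observer with the experiment's
staircase, exactly as the acceptance report does:

```r
library(crowdcaps)
set.seed(1)
obs <- make_simulated_observer(true_threshold = 8, spread = 4) # arcmin
trials <- run_pest(obs, staircase_config())
nrow(trials)
#> [1] 160
fit <- fit_psychometric(trials, guess = 0.5, target = 0.75)
fit
#> <psychometric_fit mu=7.864 sigma=4.212 threshold(75%)=7.864>
obs(fit$threshold)   # true accuracy at the estimated threshold
#> [1] 0.743232
```

The observer's true accuracy at the estimated threshold is ~0.75: the
staircase-plus-probit stack recovers the 75%-correct point. Averaged over
150 replicate staircases (`scripts/acceptance.R`), this is 74.4%.

Render and inspect stimuli, train a small network, and score (un)crowding:

```r
stim <- stim_config_small(1)
v <- render_vernier("right", stim)
cond <- test_condition("square_5same", rep("square", 5), "inside", "square_1")
frame <- compose_test_stimulus(v, cond, stim)

cfg <- caps_config_small(stim)
net <- init_caps_model(cfg, seed = 1)
ds <- build_training_set(1, 2000, stim, aug = NULL, seed = 2)
trained <- train_one(net, ds, train_config(batch_size = 16, steps = 2000))

sc <- uncrowding_score(trained$model, cond,
                       test_condition("square_1", "square", "inside", "square_1"),
                       stim, n_trials = 500)
sc$delta   # %correct(5 squares) - %correct(1 square)
```

A full pipeline (stimuli -> ensemble training -> battery evaluation ->
CSV + manifest) is `run_experiment()`, or from the command line:

```sh
Rscript -e 'crowdcaps::crowdcaps_cli()' run --experiment 1 \
    --arch capsnet,ffcnn --n-networks 3 --seed 1 --out runs/exp1
Rscript -e 'crowdcaps::crowdcaps_cli()' figures --out runs/exp1
```

## Scope and honesty notes

The published (un)crowding effects emerge in networks trained at GPU scale
(orders of magnitude more optimisation than a CPU test run). This package
reproduces the full protocol and verifies every mechanical component
exactly; the emergent-phenomenon criteria are executed at the largest scale
that fits an automated CPU budget and reported as observed. Design
decisions and deviations are documented in the methods vignette.
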