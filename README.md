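# cdllc — deep dictionary learning with a locality constraint

`cdllc` is an R package for multi-class classification of grayscale images
(its motivating application is brain tumor MR slices) or precomputed feature
matrices, using **convolutional/multi-layer dictionary learning with a local
constraint**: a chain of dictionaries with interleaved nonlinearities, a
supervised k-nearest-neighbor graph over the last-layer atoms whose Laplacian
regularizes the codes, and a softmax classifier trained jointly with the
dictionaries.

Training solves

```
min  ||X - D1 phi(D2 phi(... phi(DM AM)))||_F^2
     + lambda1 ||AM - S H||_F^2
     + lambda2 Tr(AM' L AM)
     - (lambda3/N) sum_{i,c} p_ci log softmax_c(theta' a_i)
s.t. ||d_j||^2 <= 1 for every atom
```

where `AM` are the last-layer sparse codes (earlier codes are activations),
`S H` is a rank-`C` factorization of the codes, `L` is the Laplacian of the
supervised atom graph (`w_ij = exp(-||d_i - d_j||^2/sigma)` for same-class
k-NN atom pairs, 0 across classes), and `theta` holds one weight column per
class. Optimization alternates backpropagated projected-gradient steps on the
dictionaries, a backtracking gradient step on the codes, closed-form
pseudoinverse updates of `S` and `H`, classifier gradient steps, and a graph
rebuild. A test sample is encoded by minimizing the same reconstruction
objective plus the projection-residual penalty onto `span(S)`, then
classified by the softmax head.

The package also provides the supporting toolchain: orthogonal matching
pursuit and K-SVD (per-class, layer-wise initialization), the ten classical
first-/second-order GLCM texture features for grayscale images, seeded
synthetic-data generators (deep sparse feature matrices with class-block
codes; toy labeled blob/texture images), stratified cross-validation with an
inner 70/30 split and a lambda grid search over `{0.001, 0.01, 0.1, 1, 10}`,
and a command-line interface.

## Worked example

```r
library(cdllc)

## 150 training samples from a known 2-layer generative chain, 3 classes
ds <- make_deep_sparse_dataset(d = 20, layer_sizes = c(24, 12), n_classes = 3,
                               n_per_class = 50, sparsity = 3,
                               noise_sigma = 0.05, seed = 1)
fit <- cdllc_fit(ds$X, ds$labels, layer_sizes = c(24, 12), k = 3,
                 control = cdllc_control(max_outer_iter = 200), seed = 1)
print(fit$model)
#> Deep dictionary model: 2 layer(s) [20x24 -> 24x12], 3 classes, activation 'relu'

## the objective decreases from 3523.2 to 471.0 over 200 outer iterations
## (fit$trace holds the per-iteration parts J1, rank, J2, J3)

## held-out samples from the SAME generating dictionaries, new seed
held <- make_deep_sparse_dataset(20, c(24, 12), 3, 25, 3, 0.05, seed = 99,
                                 dictionaries = ds$true_dictionaries)
pred <- predict(fit$model, held$X)
cm <- confusion(held$labels, pred$label, 3)
cm$counts
#>      [,1] [,2] [,3]
#> [1,]   24    1    0
#> [2,]    1   24    0
#> [3,]    0    0   25
classification_metrics(cm)$accuracy
#> 0.973
```

73 of 75 held-out samples are classified correctly (accuracy, macro recall,
macro precision, macro F1 and balanced accuracy all 0.973 on this draw): the
trained chain separates the three class-specific code subspaces and the
encoding of unseen samples lands in the right one.

For images, `make_toy_tumor_images()` + `texture_feature_matrix()` produce a
10-feature matrix in the same column-per-sample layout, and
`cross_validate()` runs the full repeated stratified-CV protocol with
grid-searched regularization weights.

## Command line

```sh
Rscript inst/cli/cdllc.R synth    --out data/ --d 20 --layers 24,12 --classes 3 \
                                  --n-per-class 50 --noise 0.05 --seed 1
Rscript inst/cli/cdllc.R train    --features data/features.csv --layers 24,12 \
                                  --knn 3 --out model.json --seed 1
Rscript inst/cli/cdllc.R predict  --model model.json --features data/features.csv \
                                  --out predictions.csv
Rscript inst/cli/cdllc.R cv       --features data/features.csv --layers 24,12 \
                                  --knn 3 --folds 5 --repeats 10 --out report
```

Subcommands `features` (GLCM features from an image folder) and `evaluate`
(metrics + confusion matrix for a labeled feature file) complete the set.
Every run writes its resolved configuration next to its outputs; fixed seeds
give byte-identical outputs.

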