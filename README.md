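# ergcn

Cancer subtype classification from gene-expression profiles with a residual
graph convolutional network (ERGCN) on a patient similarity network.

## The problem and the method

Assigning a tumor to a molecular subtype (e.g. Basal / LumA / LumB / Her2 in
breast cancer) from a bulk expression profile is a small-cohort,
high-dimensional classification problem. `ergcn` treats the *patients* as
nodes of a graph: two patients are connected when the absolute Pearson
correlation of their expression profiles exceeds a threshold,

```
A_ij = 1  iff  |r(x_i, x_j)| > θ     (self-loops: A_ii = 1),
```

and classifies the nodes with a two-layer graph convolutional network whose
first layer is augmented by a residual skip connection from the raw
features:

```
H1 = ReLU(S X W1)                 S = D^{-1/2} A D^{-1/2}
Hp = H1 + ReLU(X Ws + bs)         (residual skip against over-smoothing)
P  = softmax(S Hp W2)
```

Training is transductive full-batch: the graph spans all samples, the
masked cross-entropy loss `L = -Σ_{d∈T} ln P[d, y_d]` counts training
samples only, and Adam (learning rate 0.001) updates the weights via
analytically derived backpropagation. The package also ships:

* external metrics (accuracy, macro precision/recall/F1, multiclass MCC,
  pair-counting adjusted Rand index) and internal clustering-validity
  metrics (silhouette width, Davies–Bouldin index), each with a brute-force
  oracle twin in the tests;
* repeated stratified 5-fold transductive cross-validation, a θ sweep,
  leave-one-out new-sample evaluation via network augmentation, and an
  MLP / plain-GCN ablation;
* Gini-importance key-gene ranking via random forests;
* a synthetic expression generator with planted subtype structure, so the
  whole pipeline is testable without any download.

See the methods vignette (`vignettes/ergcn-methods.Rmd`) for the model,
the generator's correlation structure, and every default's rationale.

## Worked example

```r
library(ergcn)

bench <- default_benchmark()          # 120 samples x 400 genes, 4 subtypes
net <- build_network(bench$x, theta = 0.5)
net
#> Patient similarity network: 120 samples, theta = 0.5
#>   edges: 1740  isolated samples (self-loop only): 0
#>   mean degree (incl. self-loop): 30.00

fit <- ergcn(bench$x, bench$y, theta = 0.5, network = net, seed = 1)
fit
#> ERGCN fit (variant 'ergcn'): 120 samples, 400 genes, 4 subtypes
#>   theta = 0.5, hidden = 64, lr = 0.001, epochs = 200, dropout = 0.5, seed = 1
#>   training loss: 504.1243 -> 0.0081
#>   training-set accuracy: 1.0000 (120 labeled samples)

cv <- cross_validate(bench$x, bench$y, theta = 0.5, repeats = 2, seed = 1)
cv
#> 5-fold cross-validation x 2 repeats (variant 'ergcn', theta = 0.5)
#>   10 fold-runs; internal metrics on embeddings
#>      precision recall f1 accuracy ari mcc silhouette    dbi
#> mean         1      1  1        1   1   1     0.5731 0.5947
#> sd           0      0  0        0   0   0     0.0221 0.0355

rk <- rank_genes(bench$x, fitted(fit), n_trees = 500, seed = 1)
head(top_k(rk, 50), 8)
#> [1] "gene0103" "gene0100" "gene0025" "gene0049" "gene0003" "gene0021"
#> [7] "gene0041" "gene0155"
```

Reading the output: the thresholded network is dense enough to propagate
(mean degree 30) with no isolated samples; held-out fold accuracy is 1.0
because the benchmark's planted effect (3 noise SDs on 40 signature genes
per subtype) makes subtypes cleanly separable; the silhouette of the
learned embeddings (≈ 0.57) far exceeds that of the raw profiles (≈ 0.26,
see `feature_space = "raw"`), showing the network actually reshapes the
feature space; and the top-ranked genes fall inside the planted signature
blocks (genes 1–160).

Real cohorts load through `read_expression()` / `read_labels()` /
`align_samples()`; a thin command-line front end for the same operations
lives at `inst/cli/ergcn.R`.

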