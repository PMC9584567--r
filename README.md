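# mfda

Multitype drug-drug interaction (DDI) event prediction with a multiview,
dual-level-attention graph neural network, implemented entirely in base R.

## The problem

Co-administered drugs interact, and the *type* of interaction — weakened
metabolism, raised serum concentration, potentiated CNS depression — is
what matters clinically. Given binary descriptor tables for a set of drugs
(chemical substructures, targets, enzymes) and a list of drug pairs
labeled with one of C reaction event types, `mfda` predicts the event type
of unobserved pairs, including the cold-start regimes where one or both
drugs have no known interactions. The package is aimed at computational
pharmacology researchers who want a self-contained, inspectable
implementation of this model family with honest evaluation machinery.

## The model

Drugs are first re-expressed by Jaccard similarity profiles per feature
category, concatenated into the unified feature matrix
*X<sub>i</sub> = X<sup>s</sup><sub>i</sub> ⊕ X<sup>t</sup><sub>i</sub> ⊕
X<sup>e</sup><sub>i</sub>*. Three relational views are built over the drug
set:

* **adjacency** A<sub>adj</sub> — 1 where any labeled pair exists;
* **diffusion** A<sub>diff</sub> = α(I − (1−α) D<sup>−1/2</sup> Ã
  D<sup>−1/2</sup>)<sup>−1</sup> — Personalized PageRank, multi-hop
  proximity;
* **knn** A<sub>knn</sub> — mutual-union k-nearest-neighbour graph under
  cosine similarity of the rows of X.

Per view, a dual-channel cross-fusion encoder combines a shared
autoencoder (feature channel, H<sup>(l)</sup>) with a graph attention
network (topology channel, Z<sup>(l)</sup>), exchanging information each
layer through the convey operation Z̃ = (1−ε)Z + εH. Node-level attention
weighs neighbours; view-level attention weighs the three view embeddings
into the unified drug embedding Z = ε<sub>a</sub>Z<sub>adj</sub> +
ε<sub>d</sub>Z<sub>diff</sub> + ε<sub>k</sub>Z<sub>knn</sub>. Drug pairs
are combined (average by default) and classified; training minimizes
cross-entropy plus a reconstruction penalty λ<sub>re</sub>·Σ<sub>i</sub>
‖X<sub>i</sub> − X̂<sub>i</sub>‖ with full-batch Adam, early-stopped on
validation macro-F1. The network, its gradients (reverse-mode autodiff)
and the optimizer are implemented in base R and verified against
numerical differentiation in the tests.

## Worked example

The package ships a synthetic data generator whose drugs fall into latent
groups with group-pair-determined event labels (Bayes accuracy
1 − label_noise, here 0.95):

```r
library(mfda)

sim <- simulate_ddi(sim_config())      # 120 drugs, 8 event types, seed 7
X   <- unified_features(sim$tables)
chance_level(sim$dataset)
#> [1] 0.2472222

cv <- mfda_cv(sim$dataset, X, task = "A", n_folds = 5, seed = 1)
print(cv)
#> MFDA 5-fold cross-validation, Task A
#>   mean ACC 0.883  AUPR_micro 0.892  AUC_micro 0.970
#>   mean F1_macro 0.831  Pre_macro 0.868  Recall_macro 0.820
```

Mean accuracy 0.883 against a 0.247 majority-class baseline and a 0.95
Bayes ceiling: the model recovers most of the planted group-pair
structure. A single fitted model exposes its attention:

```r
fit <- cv$models[["1"]]
emb <- mfda_embeddings(fit)
round(colMeans(emb$view_weights), 3)   # (adj, diff, knn)
#> [1] 0 0 1
```

The feature-similarity (KNN) view dominates — on this generator the
interaction graph is uninformative by construction, and the view-level
attention finds that out. Cold-start evaluation uses the same interface
(`task = "B"` or `"C"`); accuracy degrades gracefully from Task A to C.

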