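# emrcnn

Diagnosis prediction from electronic medical record (EMR) text with a
multi-kernel convolutional neural network, implemented end to end in R.

Clinical decision support from free text is usually rule-based: a
hand-built knowledge base matched against each record. `emrcnn` takes the
learning route instead — the three most diagnostic free-text fields of a
record (chief complaint, history of present illness, physical examination)
are concatenated into one passage, and a convolutional text encoder learns
to map that passage to a probability distribution over diseases, with no
hand-crafted features or rules. The package is aimed at clinical-NLP
researchers and methods developers who want a fully inspectable,
dependency-light implementation: every stage, including backpropagation,
is plain R code under test.

## The model

A passage of $N = 130$ tokens (zero-padded or head-truncated to that
length) is embedded into $X \in \mathbb{R}^{N \times D}$ with $D = 300$
learned word vectors. Convolution kernels $W^k \in \mathbb{R}^{H \times D}$
of heights $H \in \{4,5,6\}$ (128 kernels per height, stride 1) slide over
the passage:

$$c^k_t = \mathrm{ReLU}\Big(\textstyle\sum_{i=1}^{H}\sum_{j=1}^{D}
  W^k_{ij}\, X_{t+i-1,\,j} + b^k\Big),$$

and each kernel's response is globally max-pooled to one value, giving a
$3 \times 128 = 384$-dimensional feature vector $F$ per record. A dense
layer plus softmax converts $F$ into disease probabilities
$P_i = e^{y_i}/\sum_j e^{y_j}$, $y = W_F^\top F + b_f$, over $L = 6$
diseases. Training minimizes the batch sum of squared errors between $P$
and the one-hot diagnosis plus an L2 penalty on $W_F$, by mini-batch SGD
with momentum 0.9, with inverted dropout on $F$. Evaluation reports
one-vs-rest precision, recall, F1 and accuracy per disease with macro
aggregation, and the learned feature space can be scored (silhouette) and
visualized (t-SNE) as training progresses.

A seeded synthetic EMR corpus generator (opaque tokens, disease-specific
keyword pools, ~130-token documents, a small fraction of identical-text
records carrying different diagnoses) makes the whole pipeline testable at
desk scale. See the methods vignette (`vignettes/emrcnn-methods.Rmd`) for
the full account of the model, the design decisions and what the synthetic
corpus does and does not demonstrate.

## Worked example

```r
library(emrcnn)

corpus <- synth_emr_corpus(seed = 1)              # 6 diseases, ~615 records
splits <- split_corpus(corpus, train_fraction = 0.9, seed = 1)

fit <- fit_emrcnn(splits$train, splits$test,
                  embedding_dim = 32, kernels_per_height = 16,  # desk scale
                  epochs = 30, seed = 1)
fit
#> <emrcnn> convolutional diagnosis model
#>   vocabulary: 920 tokens + unk
#>   input: 130 tokens x 32-dim embeddings
#>   kernels: heights {4, 5, 6} x 16 -> 48-dim feature (max pooling)
#>   classes: disease_1, disease_2, disease_3, disease_4, disease_5, disease_6
#>   trained 30 epochs; final train acc 0.975, test acc 1.000

evaluate_model(fit, splits$test)
#> <emrcnn_metrics> 62 records, 6 classes (macro average)
#> # A tibble: 6 × 5
#>   class     precision recall    f1 support
#>   <chr>         <dbl>  <dbl> <dbl>   <int>
#> 1 disease_1         1      1     1      11
#> 2 disease_2         1      1     1      11
#> 3 disease_3         1      1     1      10
#> 4 disease_4         1      1     1      10
#> 5 disease_5         1      1     1      10
#> 6 disease_6         1      1     1      10
#> overall accuracy 1.0000 | macro P 1.0000 R 1.0000 F1 1.0000

feats <- extract_features(fit, splits$test)       # 48-dim rows here
separation_score(feats)
#> [1] 0.839
autoplot(project_2d(feats, seed = 1))             # t-SNE, colored by disease
```

Final training accuracy sits at 0.975, not 1: by design 2.4% of generated
records are verbatim clones carrying a different diagnosis (multi-disease
patients), so one record of each clone pair is necessarily misclassified.
`tidy(fit)` returns the per-epoch history (loss, train/test accuracy) and
`autoplot(fit)` draws the training curves.

The same pipeline is scriptable from a shell via the thin CLI in
`inst/cli/emrcnn` (subcommands `synth`, `train`, `predict`, `evaluate`,
`visualize`), which reads and writes JSON-lines datasets — records with
keys `record_id`, `chief_complaint`, `present_illness_history`,
`physical_exam`, `label` — or delimited files adapted through a column
mapping (`read_emr_records(path, col_map = ...)`).

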