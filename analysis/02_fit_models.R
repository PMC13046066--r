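#!/usr/bin/env Rscript
# Step 2 — fit both predictors on the seed-0 datasets and export models
# and scatter data.
#
# For each of the six datasets: a per-element ordinary least squares
# model (closed form) and the single-layer softmax network (MSE loss,
# Adam, lr 0.001, batch 16, 80 epochs). Writes model JSONs and long-form
# (true, predicted) scatter CSVs under results/models/, and prints
# test-set RMSE per element (x1e3).
#
# What to expect: noise-free, the linear model is the more accurate of
# the two on most elements; the network's softmax keeps every prediction
# on the unit simplex (non-negative) where the linear model can stray
# outside [0, 1].

suppressPackageStartupMessages(library(dectmix))

out_dir <- "results/models"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

datasets <- build_all_datasets(seed = 0, n = 10000)

for (nm in names(datasets)) {
  ds <- datasets[[nm]]
  category <- attr(ds, "category")
  snr <- attr(ds, "snr")
  tag <- paste0(tolower(nm), "_", category, "_snr",
                ifelse(is.finite(snr), snr, "inf"))
  xtr <- dataset_features(ds, "train")
  ytr <- dataset_targets(ds, "train")
  xte <- dataset_features(ds, "test")
  yte <- dataset_targets(ds, "test")

  fit <- fit_linear_ols(xtr, ytr)
  write_model(fit, file.path(out_dir, paste0(tag, "_lm.json")))

  seed_cell <- derive_seed(0, "init",
                           (category == "bone") * 100L +
                             ifelse(is.finite(snr), as.integer(snr), 0L))
  net <- init_net(ncol(ytr), seed = seed_cell, elements = colnames(ytr))
  net <- train_net(net, xtr, ytr,
                   xval = dataset_features(ds, "val"),
                   yval = dataset_targets(ds, "val"),
                   config = train_config(), seed = seed_cell)
  write_model(net, file.path(out_dir, paste0(tag, "_nn.json")))

  sc <- rbind(scatter_export(fit, ds, "test"), scatter_export(net, ds, "test"))
  readr::write_csv(sc, file.path(out_dir, paste0("scatter_", tag, ".csv")),
                   progress = FALSE)

  r_lm <- rmse(predict_linear(fit, xte), yte)
  r_nn <- rmse(predict_net(net, xte), yte)
  cat(sprintf("\n%s (%s, SNR = %s) test RMSE x1e3:\n", nm, category,
              format(snr)))
  print(round(rbind(lm = r_lm, nn = r_nn) * 1e3, 2))
  cat(sprintf("  nn predictions in [0,1]: %s;  lm range: [%.3f, %.3f]\n",
              all(predict_net(net, xte) >= 0),
              min(predict_linear(fit, xte)), max(predict_linear(fit, xte))))
}
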