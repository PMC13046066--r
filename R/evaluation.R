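#' Root mean squared error per element
#'
#' `RMSE = sqrt(mean((w_hat - w)^2))`, computed per column when given
#' matrices.
#'
#' @param predictions,truths Numeric vectors or n x K matrices of equal
#'   shape.
#' @return Named numeric vector of per-element RMSE (scalar for vectors).
#' @export
rmse <- function(predictions, truths) {
  p <- as.matrix(predictions)
  t_ <- as.matrix(truths)
  if (!all(dim(p) == dim(t_))) stop("predictions and truths differ in shape")
  if (nrow(p) == 0) stop("RMSE of zero samples is undefined")
  out <- sqrt(colMeans((p - t_)^2))
  if (is.null(dim(predictions))) unname(out) else out
}

#' Adjusted R-squared of the linear model, per element
#'
#' `R2_adj = 1 - (1 - R2) (n - 1) / (n - 3)` with two predictors, where
#' `R2` is the per-element coefficient of determination of the fitted
#' model on the supplied data. Reported as a fit-quality measure on the
#' training partition by default in [run_replicated_experiment()].
#'
#' @param model A `dect_lm`.
#' @param x n x 2 matrix of standardized features (n > 3).
#' @param y n x K matrix of true mass fractions.
#' @return Named numeric vector of per-element adjusted R-squared.
#' @export
adjusted_r2 <- function(model, x, y) {
  stopifnot(inherits(model, "dect_lm"))
  x <- as.matrix(x)
  y <- as.matrix(y)
  n <- nrow(y)
  if (n <= 3) stop("adjusted R-squared with two predictors requires n > 3")
  pred <- predict_linear(model, x)
  ss_res <- colSums((y - pred)^2)
  ss_tot <- colSums(sweep(y, 2, colMeans(y))^2)
  if (any(ss_tot == 0)) stop("degenerate targets: zero variance")
  r2 <- 1 - ss_res / ss_tot
  out <- 1 - (1 - r2) * (n - 1) / (n - 3)
  names(out) <- colnames(y)
  out
}

#' Replicated decomposition experiment
#'
#' Runs the full study protocol: for each replicate seed, regenerate the
#' requested datasets, fit the requested models on the training partition,
#' score per-element RMSE on the test partition (and adjusted R-squared
#' for the linear model), then aggregate across seeds as mean and sample
#' standard deviation (Type A uncertainty of the replicate estimates).
#'
#' @param categories Tissue categories to run (default both).
#' @param snrs Noise levels (default `c(Inf, 10, 5)`).
#' @param models Model families, subset of `c("lm", "nn")`.
#' @param seeds Replicate master seeds (study default `0:9`).
#' @param n Samples per dataset (study default 10 000).
#' @param config Network [train_config()].
#' @param adj_r2_partition Partition on which adjusted R-squared is
#'   evaluated (`"train"` default, or `"test"`/`"all"`).
#' @param cells Optional data frame with columns `category`, `snr`,
#'   `model` selecting an explicit subset of experiment cells instead of
#'   the full crossing.
#' @param stats_scope Standardization scope passed to [build_dataset()].
#' @param table,atten Reference tables.
#' @param keep_history Keep each trained network's loss history
#'   (`$histories`, keyed by `category_snr_seed`).
#' @return A `dect_eval_report`: list with `per_seed` (tibble: seed,
#'   category, snr, model, element, rmse, adj_r2), `summary` (per-cell
#'   mean/SD over seeds), `n_seeds`, `n_test`, and optionally `histories`.
#' @export
run_replicated_experiment <- function(categories = c("soft", "bone"),
                                      snrs = c(Inf, 10, 5),
                                      models = c("lm", "nn"),
                                      seeds = 0:9,
                                      n = 10000L,
                                      config = train_config(),
                                      adj_r2_partition = "train",
                                      cells = NULL,
                                      stats_scope = "train",
                                      table = tissue_table(),
                                      atten = attenuation_table(),
                                      keep_history = FALSE) {
  models <- match.arg(models, c("lm", "nn"), several.ok = TRUE)
  if (is.null(cells)) {
    cells <- expand.grid(category = categories, snr = snrs, model = models,
                         stringsAsFactors = FALSE)
  }
  stopifnot(all(c("category", "snr", "model") %in% names(cells)))
  ds_grid <- unique(cells[, c("category", "snr")])

  rows <- list()
  histories <- list()
  for (seed in seeds) {
    for (g in seq_len(nrow(ds_grid))) {
      category <- ds_grid$category[g]
      snr <- ds_grid$snr[g]
      ds <- build_dataset(category, snr, n = n, seed = seed,
                          stats_scope = stats_scope,
                          table = table, atten = atten)
      x_tr <- dataset_features(ds, "train")
      y_tr <- dataset_targets(ds, "train")
      x_te <- dataset_features(ds, "test")
      y_te <- dataset_targets(ds, "test")
      cell_models <- cells$model[cells$category == category &
                                 cells$snr == snr]
      salt <- (category == "bone") * 100L +
        ifelse(is.finite(snr), as.integer(snr), 0L)

      if ("lm" %in% cell_models) {
        fit <- fit_linear_ols(x_tr, y_tr)
        r <- rmse(predict_linear(fit, x_te), y_te)
        ar2 <- adjusted_r2(fit,
                           dataset_features(ds, adj_r2_partition),
                           dataset_targets(ds, adj_r2_partition))
        rows[[length(rows) + 1L]] <- tibble::tibble(
          seed = seed, category = category, snr = snr, model = "lm",
          element = names(r), rmse = unname(r), adj_r2 = unname(ar2)
        )
      }
      if ("nn" %in% cell_models) {
        model_seed <- derive_seed(seed, "init", salt)
        net <- init_net(ncol(y_tr), seed = model_seed,
                        elements = colnames(y_tr))
        net <- train_net(net, x_tr, y_tr,
                         xval = dataset_features(ds, "val"),
                         yval = dataset_targets(ds, "val"),
                         config = config, seed = model_seed)
        r <- rmse(predict_net(net, x_te), y_te)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          seed = seed, category = category, snr = snr, model = "nn",
          element = names(r), rmse = unname(r), adj_r2 = NA_real_
        )
        if (keep_history) {
          histories[[paste(category, format(snr), seed, sep = "_")]] <-
            net$history
        }
      }
    }
  }
  per_seed <- dplyr::bind_rows(rows)
  summary <- per_seed |>
    dplyr::group_by(.data$category, .data$snr, .data$model, .data$element) |>
    dplyr::summarise(
      rmse_mean = mean(.data$rmse), rmse_sd = sd(.data$rmse),
      adj_r2_mean = mean(.data$adj_r2), adj_r2_sd = sd(.data$adj_r2),
      n_seeds = dplyr::n(), .groups = "drop"
    )
  structure(
    list(per_seed = per_seed, summary = summary,
         n_seeds = length(seeds), n_test = round(0.1 * n),
         histories = if (keep_history) histories else NULL),
    class = "dect_eval_report"
  )
}

#' @export
print.dect_eval_report <- function(x, ...) {
  cat(sprintf("<dect_eval_report> %d replicate seeds, %d test samples\n",
              x$n_seeds, x$n_test))
  print(x$summary, n = Inf)
  invisible(x)
}

snr_label <- function(snr) ifelse(is.finite(snr), as.character(snr), "inf")

#' Export result tables
#'
#' Writes machine-readable analogues of the study's result tables to
#' `dir`: per-element RMSE for soft tissue (`table2_soft_rmse.csv`) and
#' bone (`table3_bone_rmse.csv`), and linear-model adjusted R-squared
#' (`table4_adjusted_r2.csv`). All values are scaled by 10^3 for
#' readability, with separate mean and SD columns per noise level (and
#' model, for RMSE).
#'
#' @param report A `dect_eval_report` covering the needed cells.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
export_tables <- function(report, dir) {
  stopifnot(inherits(report, "dect_eval_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  s <- report$summary
  paths <- character(0)

  rmse_table <- function(category) {
    sub <- s[s$category == category, ]
    if (nrow(sub) == 0) return(NULL)
    elems <- element_set(category)
    combos <- unique(sub[, c("snr", "model")])
    if (nrow(sub) != nrow(combos) * length(elems)) {
      stop("incomplete report for category '", category, "'")
    }
    wide <- sub |>
      dplyr::mutate(
        key = paste0("snr_", snr_label(.data$snr), "_", .data$model),
        rmse_mean = 1e3 * .data$rmse_mean, rmse_sd = 1e3 * .data$rmse_sd
      ) |>
      dplyr::select("element", "key", "rmse_mean", "rmse_sd") |>
      tidyr::pivot_wider(names_from = "key",
                         values_from = c("rmse_mean", "rmse_sd"))
    wide[match(elems, wide$element), ]
  }

  for (cc in c("soft", "bone")) {
    tab <- rmse_table(cc)
    if (!is.null(tab)) {
      p <- file.path(dir, if (cc == "soft") "table2_soft_rmse.csv"
                          else "table3_bone_rmse.csv")
      readr::write_csv(tab, p, progress = FALSE)
      paths <- c(paths, p)
    }
  }

  lm_rows <- s[s$model == "lm", ]
  if (nrow(lm_rows) > 0) {
    wide <- lm_rows |>
      dplyr::mutate(
        key = paste0(.data$category, "_snr_", snr_label(.data$snr)),
        adj_r2_mean = 1e3 * .data$adj_r2_mean,
        adj_r2_sd = 1e3 * .data$adj_r2_sd
      ) |>
      dplyr::select("element", "key", "adj_r2_mean", "adj_r2_sd") |>
      tidyr::pivot_wider(names_from = "key",
                         values_from = c("adj_r2_mean", "adj_r2_sd"))
    wide <- wide[match(BONE_ELEMENTS[BONE_ELEMENTS %in% wide$element],
                       wide$element), ]
    p <- file.path(dir, "table4_adjusted_r2.csv")
    readr::write_csv(wide, p, progress = FALSE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Export (true, predicted) scatter pairs
#'
#' Long-format per-element prediction pairs on one partition, suitable
#' for predicted-versus-true scatter plots against the identity diagonal.
#'
#' @param model A fitted `dect_lm` or `dect_net`.
#' @param ds The `dect_dataset` the model was fitted on.
#' @param partition Partition to export (default `"test"`).
#' @return Tibble with columns `element`, `w_true`, `w_pred`, `model`,
#'   `category`, `snr`.
#' @export
scatter_export <- function(model, ds, partition = "test") {
  x <- dataset_features(ds, partition)
  y <- dataset_targets(ds, partition)
  pred <- if (inherits(model, "dect_lm")) predict_linear(model, x)
          else forward_net(model, x)
  tibble::tibble(
    element = rep(colnames(y), each = nrow(y)),
    w_true = as.vector(y),
    w_pred = as.vector(pred),
    model = if (inherits(model, "dect_lm")) "lm" else "nn",
    category = attr(ds, "category"),
    snr = attr(ds, "snr")
  )
}

#' Predicted-versus-true scatter plot
#'
#' @param scatter Tibble from [scatter_export()] (rows from several
#'   models/datasets may be combined).
#' @return A ggplot object, faceted by element, with the identity
#'   diagonal.
#' @export
plot_scatter <- function(scatter) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_scatter requires the ggplot2 package")
  }
  ggplot2::ggplot(scatter,
                  ggplot2::aes(x = .data$w_true, y = .data$w_pred,
                               colour = .data$model)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.4) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::facet_wrap(~element, scales = "free") +
    ggplot2::labs(x = "true mass fraction", y = "predicted mass fraction")
}
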