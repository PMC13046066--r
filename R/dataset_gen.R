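#' @title Synthetic tissue-sample generation
#' @name dataset_gen
#' @description
#' The generator draws voxel compositions from the per-tissue sampling
#' specifications, blends two-component mixtures with a uniform mixing
#' ratio, computes the 50/88 keV attenuation pair for every sample, injects
#' Gaussian noise at a prescribed SNR, standardizes features with
#' training-set statistics and partitions each dataset 72/18/10 into
#' train/validation/test.
NULL

DATASET_COLUMNS <- c(
  "sample_id", "category", "component_label", "mixing_ratio", "rho",
  "wH", "wC", "wN", "wO", "wCa",
  "mu50_raw", "mu88_raw", "mu50_noisy", "mu88_noisy",
  "x1", "x2", "split"
)

# Assemble sampled fractions into the canonical sample table, filling
# unmodelled elements (soft-tissue Ca) with exact zeros.
as_sample_tbl <- function(W, rho, label, mixing_ratio) {
  out <- tibble::tibble(.rows = length(rho))
  for (e in BONE_ELEMENTS) {
    col <- paste0("w", e)
    out[[col]] <- if (col %in% colnames(W)) W[, col] else 0
  }
  out$rho <- rho
  out$component_label <- label
  out$mixing_ratio <- mixing_ratio
  out
}

draw_component <- function(spec, n) {
  elems <- names(spec$elements)
  W <- matrix(NA_real_, n, length(elems),
              dimnames = list(NULL, paste0("w", elems)))
  for (k in seq_along(elems)) W[, k] <- rdist(spec$elements[[k]], n)
  list(W = W, rho = rdist(spec$density, n))
}

#' Draw pure-tissue samples
#'
#' Each element's mass fraction and the density are drawn independently
#' from the component's distribution specifications. Whole samples
#' containing any negative mass fraction are discarded and redrawn
#' (rejection sampling), imposing a non-negativity cut-off on the
#' underlying distributions.
#'
#' @param spec A `tissue_component_spec` from [build_component_specs()].
#' @param n Number of samples.
#' @param max_redraws Cap on rejection rounds; exceeding it signals a
#'   malformed specification (well-formed specs reject well under 1% of
#'   draws, except the red-marrow Ca range which straddles zero).
#' @param renormalize Rescale each accepted composition to sum to one over
#'   the modelled element set (default). The reference rows sum to
#'   slightly less than one because trace elements are omitted;
#'   renormalization redistributes that mass so compositions live on the
#'   simplex, matching the unit-sum convention of the mixture rule and of
#'   the softmax predictor's output space. Set `FALSE` to keep the raw
#'   sampled fractions.
#' @return Tibble with columns `wH ... wCa` (fractions; unmodelled elements
#'   exactly 0), `rho`, `component_label`, `mixing_ratio`.
#' @export
sample_pure <- function(spec, n = 1L, max_redraws = 1000L,
                        renormalize = TRUE) {
  stopifnot(inherits(spec, "tissue_component_spec"), n >= 1L)
  d <- draw_component(spec, n)
  bad <- which(rowSums(d$W < 0) > 0)
  rounds <- 0L
  while (length(bad) > 0) {
    rounds <- rounds + 1L
    if (rounds > max_redraws) {
      stop("rejection sampling exceeded ", max_redraws,
           " redraw rounds for component '", spec$name, "'")
    }
    redo <- draw_component(spec, length(bad))
    d$W[bad, ] <- redo$W
    d$rho[bad] <- redo$rho
    bad <- bad[rowSums(d$W[bad, , drop = FALSE] < 0) > 0]
  }
  if (renormalize) d$W <- d$W / rowSums(d$W)
  as_sample_tbl(d$W, d$rho, spec$name, NA_real_)
}

#' Draw two-component mixture samples
#'
#' For each sample a mixing ratio `w1 ~ Uniform(0, 1)` is drawn, a pure
#' sample is drawn from each component, fractions are blended elementwise
#' as `w1 * wA + (1 - w1) * wB`, and the density is the harmonic mean
#' [mixture_density()] of the two component densities.
#'
#' @inheritParams sample_pure
#' @param specA,specB Component specifications from the same category.
#' @param w1 Optional fixed mixing ratio(s) in `[0, 1]`, recycled to `n`;
#'   default draws `Uniform(0, 1)`.
#' @return Tibble as [sample_pure()], with `component_label = "mixture"`
#'   and `mixing_ratio = w1` (fraction of `specA`).
#' @export
sample_mixture <- function(specA, specB, n = 1L, w1 = NULL,
                           max_redraws = 1000L, renormalize = TRUE) {
  stopifnot(identical(names(specA$elements), names(specB$elements)))
  if (is.null(w1)) w1 <- runif(n) else w1 <- rep_len(w1, n)
  if (any(w1 < 0 | w1 > 1)) stop("mixing ratio w1 must lie in [0, 1]")
  a <- sample_pure(specA, n, max_redraws, renormalize)
  b <- sample_pure(specB, n, max_redraws, renormalize)
  cols <- paste0("w", BONE_ELEMENTS)
  W <- w1 * as.matrix(a[, cols]) + (1 - w1) * as.matrix(b[, cols])
  rho <- mixture_density(w1, a$rho, b$rho)
  as_sample_tbl(W, rho, "mixture", w1)
}

#' Generate the sample population of one tissue category
#'
#' The population is one-third samples of each pure component and
#' one-third mixtures (the first component absorbing any integer
#' remainder first), concatenated and randomly shuffled. Pure samples
#' carry `mixing_ratio` 1 (component A) or 0 (component B).
#'
#' @param category `"soft"` or `"bone"`.
#' @param n Total sample count, at least 3.
#' @param seed Optional replicate master seed; when given, sampling and
#'   shuffling use the derived `"sampling"` and `"shuffle"` streams,
#'   otherwise the ambient RNG state is used.
#' @param table Reference composition table.
#' @inheritParams sample_pure
#' @return Tibble of `n` shuffled samples with a `category` column.
#' @export
generate_category <- function(category, n, seed = NULL,
                              table = tissue_table(),
                              renormalize = TRUE) {
  category <- match.arg(category, c("soft", "bone"))
  if (n < 3) stop("n must be at least 3 (one sample per component)")
  specs <- build_component_specs(category, table)
  base <- n %/% 3L
  rem <- n - 3L * base
  counts <- base + c(as.integer(rem >= 1L), as.integer(rem >= 2L), 0L)

  samples <- with_stream(seed, "sampling", expr = {
    a <- sample_pure(specs[[1]], counts[1], renormalize = renormalize)
    a$mixing_ratio <- 1
    b <- sample_pure(specs[[2]], counts[2], renormalize = renormalize)
    b$mixing_ratio <- 0
    m <- sample_mixture(specs[[1]], specs[[2]], counts[3],
                        renormalize = renormalize)
    dplyr::bind_rows(a, b, m)
  })
  samples <- with_stream(seed, "shuffle", expr = {
    samples[sample.int(nrow(samples)), ]
  })
  samples$category <- category
  samples
}

#' Inject Gaussian attenuation noise at a fixed signal-to-noise ratio
#'
#' The SNR is defined as `mu / sigma_mu`, so each attenuation value
#' receives independent zero-mean Gaussian noise with standard deviation
#' `mu / snr`. `snr = Inf` returns the input unchanged (noise-free).
#'
#' @param mu Vector of positive linear attenuation coefficients (m^-1).
#' @param snr Positive scalar SNR, possibly `Inf`.
#' @return Noisy attenuation values.
#' @export
add_noise <- function(mu, snr) {
  if (length(snr) != 1L || is.na(snr) || snr <= 0) stop("snr must be a positive scalar")
  if (any(mu <= 0)) stop("attenuation values must be positive")
  if (is.infinite(snr)) return(mu)
  mu + rnorm(length(mu), mean = 0, sd = mu / snr)
}

#' Z-score standardization statistics and application
#'
#' `compute_stats()` returns per-feature means and standard deviations
#' (sample SD); `standardize()` applies `(x - mean) / sd` columnwise.
#' Statistics are computed on the training partition and applied to all
#' partitions, so standardization is not idempotent and validation/test
#' features have mean/SD only approximately 0/1.
#'
#' @param x Numeric matrix (or data frame) of features, one column per
#'   feature.
#' @return `compute_stats()`: list with `mean` and `sd` vectors;
#'   `standardize()`: matrix of standardized features.
#' @export
compute_stats <- function(x) {
  x <- as.matrix(x)
  s <- apply(x, 2, sd)
  if (any(s == 0)) stop("constant feature: zero standard deviation")
  list(mean = colMeans(x), sd = s)
}

#' @rdname compute_stats
#' @param stats Statistics from [compute_stats()].
#' @export
standardize <- function(x, stats) {
  x <- as.matrix(x)
  if (ncol(x) != length(stats$mean)) stop("feature count mismatch")
  sweep(sweep(x, 2, stats$mean, "-"), 2, stats$sd, "/")
}

#' Random train/validation/test partition
#'
#' Splits `n` samples 9:1 into training and test, with 20% of the
#' training portion reserved for validation: `|test| = round(0.1 n)`,
#' `|val| = round(0.2 * 0.9 * n)`, `|train|` the remainder
#' (7200/1800/1000 at n = 10 000).
#'
#' @param n Number of samples, at least 10.
#' @param seed Optional replicate master seed (uses the `"split"` stream).
#' @return List of sorted disjoint integer index vectors `train`, `val`,
#'   `test` covering `1:n`.
#' @export
split_dataset <- function(n, seed = NULL) {
  if (n < 10) stop("n must be at least 10")
  n_test <- round(0.1 * n)
  n_val <- round(0.2 * 0.9 * n)
  n_train <- n - n_test - n_val
  perm <- with_stream(seed, "split", expr = sample.int(n))
  list(
    train = sort(perm[seq_len(n_train)]),
    val   = sort(perm[n_train + seq_len(n_val)]),
    test  = sort(perm[n_train + n_val + seq_len(n_test)])
  )
}

#' Build one complete dataset
#'
#' Runs the full generation pipeline for one tissue category and noise
#' level: sample compositions, compute raw 50/88 keV attenuation pairs,
#' inject noise into all partitions, split, and standardize using the
#' training-partition statistics (switchable to whole-dataset statistics
#' via `stats_scope`).
#'
#' @param category `"soft"` or `"bone"`.
#' @param snr Positive SNR or `Inf` (noise-free).
#' @param n Samples per dataset (study default 10 000).
#' @param seed Replicate master seed driving all stage streams.
#' @param stats_scope `"train"` (default) computes standardization
#'   statistics on the training partition only; `"all"` uses every sample.
#' @param table Reference composition table.
#' @param atten Attenuation constants table.
#' @inheritParams sample_pure
#' @return A `dect_dataset`: tibble with the canonical columns
#'   (`sample_id ... split`) and attributes `category`, `snr`, `seed`,
#'   `elements`, `stats`, `stats_scope`.
#' @export
#' @examples
#' d <- build_dataset("soft", snr = Inf, n = 300, seed = 0)
#' table(d$split)
build_dataset <- function(category, snr = Inf, n = 10000L, seed = 0L,
                          stats_scope = c("train", "all"),
                          table = tissue_table(),
                          atten = attenuation_table(),
                          renormalize = TRUE) {
  category <- match.arg(category, c("soft", "bone"))
  stats_scope <- match.arg(stats_scope)
  elems <- element_set(category)

  samples <- generate_category(category, n, seed = seed, table = table,
                               renormalize = renormalize)
  samples$mu50_raw <- linear_attenuation(samples, 50, elems, atten)
  samples$mu88_raw <- linear_attenuation(samples, 88, elems, atten)

  salt <- (category == "bone") * 100L + ifelse(is.finite(snr), as.integer(snr), 0L)
  noisy <- with_stream(seed, "noise", salt, expr = {
    cbind(add_noise(samples$mu50_raw, snr), add_noise(samples$mu88_raw, snr))
  })
  samples$mu50_noisy <- noisy[, 1]
  samples$mu88_noisy <- noisy[, 2]

  idx <- split_dataset(n, seed = seed)
  split <- character(n)
  split[idx$train] <- "train"
  split[idx$val] <- "val"
  split[idx$test] <- "test"
  samples$split <- split

  scope_rows <- if (stats_scope == "train") idx$train else seq_len(n)
  stats <- compute_stats(noisy[scope_rows, , drop = FALSE])
  xs <- standardize(noisy, stats)
  samples$x1 <- xs[, 1]
  samples$x2 <- xs[, 2]
  samples$sample_id <- seq_len(n)

  out <- samples[, DATASET_COLUMNS]
  structure(out,
    class = c("dect_dataset", class(out)),
    category = category, snr = snr, seed = seed, elements = elems,
    stats = stats, stats_scope = stats_scope
  )
}

#' Build the six study datasets for one replicate seed
#'
#' D1-D3: soft tissue at SNR infinity, 10, 5; D4-D6: bone tissue at the
#' same noise levels.
#'
#' @inheritParams build_dataset
#' @return Named list `D1 ... D6` of `dect_dataset` objects.
#' @export
build_all_datasets <- function(seed = 0L, n = 10000L,
                               stats_scope = c("train", "all"),
                               table = tissue_table(),
                               atten = attenuation_table(),
                               renormalize = TRUE) {
  grid <- list(
    D1 = list("soft", Inf), D2 = list("soft", 10), D3 = list("soft", 5),
    D4 = list("bone", Inf), D5 = list("bone", 10), D6 = list("bone", 5)
  )
  lapply(grid, function(g) {
    build_dataset(g[[1]], g[[2]], n = n, seed = seed,
                  stats_scope = stats_scope, table = table, atten = atten,
                  renormalize = renormalize)
  })
}

#' Extract model matrices from a dataset
#'
#' @param ds A `dect_dataset`.
#' @param partition `"train"`, `"val"`, `"test"` or `"all"`.
#' @return `dataset_features()`: n x 2 matrix of standardized features;
#'   `dataset_targets()`: n x K matrix of true mass fractions for the
#'   category's element set (columns named by element).
#' @export
dataset_features <- function(ds, partition = "train") {
  rows <- partition_rows(ds, partition)
  unname(as.matrix(ds[rows, c("x1", "x2")]))
}

#' @rdname dataset_features
#' @export
dataset_targets <- function(ds, partition = "train") {
  rows <- partition_rows(ds, partition)
  elems <- attr(ds, "elements")
  m <- as.matrix(ds[rows, paste0("w", elems)])
  colnames(m) <- elems
  m
}

partition_rows <- function(ds, partition) {
  partition <- match.arg(partition, c("train", "val", "test", "all"))
  if (partition == "all") seq_len(nrow(ds)) else which(ds$split == partition)
}

#' @export
print.dect_dataset <- function(x, ...) {
  cat(sprintf("<dect_dataset> %s tissue, SNR = %s, n = %d, seed = %d\n",
              attr(x, "category"), format(attr(x, "snr")), nrow(x),
              attr(x, "seed")))
  cat("  partitions:", paste(names(table(x$split)), table(x$split),
                             sep = "=", collapse = " "), "\n")
  NextMethod()
}

#' Dataset serialization
#'
#' `write_dataset()` writes the sample table as CSV plus a JSON sidecar
#' (`<path>.json`) holding seed, SNR, category, element order,
#' standardization statistics and scope; `read_dataset()` reverses it
#' exactly (feature values round-trip bit-identically through the
#' shortest-roundtrip decimal representation).
#'
#' @param ds A `dect_dataset`.
#' @param path CSV file path.
#' @return `read_dataset()` returns the reconstructed `dect_dataset`;
#'   `write_dataset()` returns `path` invisibly.
#' @export
write_dataset <- function(ds, path) {
  readr::write_csv(tibble::as_tibble(ds), path, progress = FALSE)
  meta <- list(
    category = attr(ds, "category"),
    snr = format(attr(ds, "snr")),
    seed = attr(ds, "seed"),
    elements = attr(ds, "elements"),
    stats = attr(ds, "stats"),
    stats_scope = attr(ds, "stats_scope")
  )
  jsonlite::write_json(meta, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0) stop("empty dataset file: ", path)
  tab <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!identical(names(tab), DATASET_COLUMNS)) {
    stop("dataset header mismatch; expected columns: ",
         paste(DATASET_COLUMNS, collapse = ", "))
  }
  meta_path <- paste0(path, ".json")
  if (!file.exists(meta_path)) stop("missing dataset sidecar: ", meta_path)
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  structure(tab,
    class = c("dect_dataset", class(tab)),
    category = meta$category, snr = as.numeric(meta$snr),
    seed = as.integer(meta$seed), elements = meta$elements,
    stats = list(mean = unlist(meta$stats$mean), sd = unlist(meta$stats$sd)),
    stats_scope = meta$stats_scope
  )
}
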