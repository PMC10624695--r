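#' Experiment configuration
#'
#' Bundles the pipeline settings: filter-bank parameters, classifier rank,
#' split policy, seed and feature options. `J = NULL` derives the invariant
#' scale from the data at run time as
#' `floor(log2(min(H, W))) - 1`, i.e. \eqn{2^J} is half the minimum image
#' dimension rounded down to a power of two.
#'
#' @param sigma Gaussian width (default 0.85).
#' @param r number of orientations (default 12).
#' @param J number of scales, or `NULL` to derive from the image size.
#' @param d classifier subspace rank (default 30).
#' @param train_fraction hold-out training fraction (default 0.8).
#' @param k_folds `NULL` for a hold-out split, or a fold count (10 for the
#'   usual cross-validated variant).
#' @param seed integer seed driving splits (default 1).
#' @param resize `NULL` or target `c(H, W)` passed to the loader.
#' @param log_features apply `log(1 + x)` to scattering features
#'   (off by default; the transform is used raw).
#' @param include_equal_scales include `j2 == j1` second-order paths
#'   (off by default).
#' @return An object of class `"wst_config"`.
#' @export
experiment_config <- function(sigma = 0.85, r = 12L, J = NULL, d = 30L,
                              train_fraction = 0.8, k_folds = NULL,
                              seed = 1L, resize = NULL,
                              log_features = FALSE,
                              include_equal_scales = FALSE) {
  if (!is.null(k_folds) && k_folds < 2) stop("'k_folds' must be >= 2")
  structure(
    list(sigma = sigma, r = as.integer(r), J = if (is.null(J)) NULL else as.integer(J),
         d = as.integer(d), train_fraction = train_fraction,
         k_folds = if (is.null(k_folds)) NULL else as.integer(k_folds),
         seed = as.integer(seed), resize = resize,
         log_features = isTRUE(log_features),
         include_equal_scales = isTRUE(include_equal_scales)),
    class = "wst_config"
  )
}

default_J <- function(shape) max(1L, as.integer(floor(log2(min(shape)))) - 1L)

#' Run the full scattering-classification experiment
#'
#' Executes the pipeline on a loaded dataset: build the Morlet filter bank
#' (on the padded image shape), extract scattering features for every
#' image, split (stratified hold-out, or k-fold when `config$k_folds` is
#' set), fit the affine PCA classifier, predict, and evaluate. Per-class
#' counts, the derived `J`, the feature count `N_J`, per-stage timings and
#' the seed are recorded, so splits and results are auditable and
#' reproducible.
#'
#' @param config an [experiment_config()].
#' @param dataset a list with `images` and `labels`, as produced by
#'   [load_dataset()] or [generate_dataset()].
#' @return An object of class `"wst_experiment"`: list with `report` (the
#'   pooled [evaluate_predictions()] report), `folds` (per-fold reports,
#'   k-fold only), `model` (fitted [affine_pca()]; on the training split
#'   for hold-out, on the full data after k-fold), `config` (with the
#'   resolved `J`), `n_features`, `split`, `timings` (seconds per stage),
#'   and `package_version`.
#' @export
run_experiment <- function(config, dataset) {
  stopifnot(inherits(config, "wst_config"))
  images <- dataset$images
  labels <- as.character(dataset$labels)
  if (length(images) != length(labels)) stop("images and labels differ in length")
  counts <- table(labels)
  message(paste(sprintf("%s: %d", names(counts), counts), collapse = ", "))
  shape <- dim(if (inherits(images[[1]], "oct_image")) images[[1]]$pixels
               else images[[1]])
  J <- if (is.null(config$J)) default_J(shape) else config$J
  timings <- c()
  tic <- function() proc.time()[["elapsed"]]
  t0 <- tic()
  bank <- build_filter_bank(filter_params(
    shape = scattering_shape(shape, J), J = J, r = config$r,
    sigma = config$sigma))
  timings["filter_bank"] <- tic() - t0

  t0 <- tic()
  fs <- extract_features(images, bank, config$include_equal_scales)
  x <- fs$features
  if (config$log_features) x <- log1p(x)
  timings["features"] <- tic() - t0

  t0 <- tic()
  if (is.null(config$k_folds)) {
    split <- split_holdout(labels, config$train_fraction, config$seed)
    model <- affine_pca(x[split$train, , drop = FALSE], labels[split$train],
                        config$d)
    pred <- predict(model, x[split$test, , drop = FALSE])
    report <- evaluate_predictions(labels[split$test], pred$labels,
                                   pred$scores, classes = model$classes)
    folds <- NULL
  } else {
    split <- kfold(labels, config$k_folds, config$seed)
    classes <- sort(unique(labels))
    all_pred <- character(length(labels))
    all_scores <- matrix(NA_real_, length(labels), length(classes),
                         dimnames = list(NULL, classes))
    folds <- vector("list", length(split))
    for (f in seq_along(split)) {
      m <- affine_pca(x[split[[f]]$train, , drop = FALSE],
                      labels[split[[f]]$train], config$d)
      pr <- predict(m, x[split[[f]]$test, , drop = FALSE])
      all_pred[split[[f]]$test] <- pr$labels
      all_scores[split[[f]]$test, m$classes] <- pr$scores
      folds[[f]] <- evaluate_predictions(labels[split[[f]]$test], pr$labels,
                                         pr$scores, classes = m$classes)
    }
    report <- evaluate_predictions(labels, all_pred, all_scores,
                                   classes = classes)
    model <- affine_pca(x, labels, config$d)
  }
  timings["classify"] <- tic() - t0

  cfg <- config
  cfg$J <- J
  message(sprintf("J = %d, N_J = %d features", J, ncol(x)))
  structure(
    list(report = report, folds = folds, model = model, config = cfg,
         n_features = ncol(x), split = split, timings = timings,
         class_counts = counts,
         package_version = as.character(utils::packageVersion("octscatter"))),
    class = "wst_experiment"
  )
}

#' @export
print.wst_experiment <- function(x, ...) {
  cat(sprintf("Scattering experiment (octscatter %s)\n", x$package_version))
  cat(sprintf("  J = %d, r = %d, sigma = %g, d = %d, seed = %d; N_J = %d\n",
              x$config$J, x$config$r, x$config$sigma, x$config$d,
              x$config$seed, x$n_features))
  if (!is.null(x$folds))
    cat(sprintf("  %d-fold cross-validation, pooled results:\n",
                length(x$folds)))
  print(x$report)
  invisible(x)
}

#' Write experiment outputs to a directory
#'
#' Writes `report.json` / `report_confusion.csv` (see [write_report()];
#' the JSON additionally embeds the full configuration and package
#' version) and `model.bin` (the [wst_save()] classifier archive).
#'
#' @param experiment a `"wst_experiment"`.
#' @param dir output directory (created if needed).
#' @export
write_experiment <- function(experiment, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_report(experiment$report, file.path(dir, "report"))
  full <- jsonlite::read_json(file.path(dir, "report.json"))
  full$config <- experiment$config[!vapply(experiment$config, is.null, TRUE)]
  full$n_features <- experiment$n_features
  full$package_version <- experiment$package_version
  full$timings <- as.list(experiment$timings)
  if (!is.null(experiment$folds))
    full$fold_accuracies <- vapply(experiment$folds, `[[`, 0, "accuracy")
  jsonlite::write_json(full, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  wst_save(experiment$model, file.path(dir, "model.bin"))
  invisible(dir)
}
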