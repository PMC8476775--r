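#' Expected exact-match ratio of prevalence-level guessing
#'
#' Chance baseline for the exact-match ratio: the probability that a
#' predictor sampling each label independently at its training prevalence
#' reproduces a test row, averaged over the test rows.
#'
#' @param Y_test `n x C` binary truth matrix.
#' @param prevalence Length-C per-label positive fractions (training set).
#' @return Scalar in `[0, 1]`.
#' @export
chance_exact_match <- function(Y_test, prevalence) {
  P <- matrix(rep(prevalence, each = nrow(Y_test)), nrow(Y_test))
  mean(apply(P^Y_test * (1 - P)^(1 - Y_test), 1, prod))
}

#' Extract handcrafted features, standardise, and reduce with PCA
#'
#' Fits the scaler and PCA on the training rows only, then transforms all
#' images. The requested dimensionality is clamped to what the training set
#' admits.
#'
#' @param images Named list of image arrays.
#' @param train_ids Ids used for fitting.
#' @param pca_dim Requested reduced dimensionality.
#' @return List: `reduced` (n x k matrix), `scaler`, `pca`.
#' @export
reduce_handcrafted <- function(images, train_ids, pca_dim = 3732L) {
  X <- handcrafted_matrix(images)
  scaler <- fit_scaler(X[train_ids, , drop = FALSE])
  Xs <- apply_scaler(scaler, X)
  k <- clamp_pca_dim(pca_dim, Xs[train_ids, , drop = FALSE])
  pca <- fit_pca(Xs[train_ids, , drop = FALSE], k)
  reduced <- apply_pca(pca, Xs)
  rownames(reduced) <- rownames(X)
  list(reduced = reduced, scaler = scaler, pca = pca)
}

#' Run the full synthetic desk-scale study
#'
#' The complete workflow on generated data: simulate labelled tubule images,
#' split them into train/validation/test, extract and reduce handcrafted
#' features, train the hybrid Drop-Weights network, run Monte-Carlo
#' inference, score uncertainty, pick MCC-optimal probability thresholds and
#' DHC cutoffs on the validation set, and evaluate plain and DHC-triaged
#' performance on the test set.
#'
#' @param n_train,n_validation,n_test Split sizes.
#' @param config A [hbnet_config()]; default the desk profile.
#' @param image_spec Optional [synthetic_image_spec()] override (its
#'   `n_images`/`seed` are set from the other arguments).
#' @param T_mc Monte-Carlo passes per image.
#' @param pca_dim Requested handcrafted dimensionality after PCA.
#' @param target_accuracy,min_retained_fraction DHC cutoff selection
#'   settings; the default targets the high retained accuracy regime the
#'   triage is designed for.
#' @param seed Master seed.
#' @param verbose Print training progress.
#' @return A list with class `"ihc_study"` collecting the trained model,
#'   records, thresholds, cutoffs, evaluation and triage results.
#' @export
run_synthetic_study <- function(n_train = 400L, n_validation = 100L, n_test = 100L,
                                config = NULL, image_spec = NULL,
                                T_mc = 100L, pca_dim = 3732L,
                                target_accuracy = 0.99,
                                min_retained_fraction = 0.5,
                                seed = 1L, verbose = FALSE) {
  n_total <- n_train + n_validation + n_test
  spec <- image_spec %||% synthetic_image_spec()
  spec$n_images <- as.integer(n_total)
  spec$seed <- as.integer(seed)
  config <- config %||% hbnet_profile("desk", input_side = spec$image_side, seed = seed)
  gen <- generate_images(spec)
  cts <- colnames(gen$labels)
  set.seed(seed)
  ord <- sample(names(gen$images))
  ids <- list(
    train = ord[seq_len(n_train)],
    validation = ord[n_train + seq_len(n_validation)],
    test = ord[n_train + n_validation + seq_len(n_test)]
  )
  ann <- gen$annotations
  ann$split <- dplyr::case_when(
    ann$image_id %in% ids$train ~ "train",
    ann$image_id %in% ids$validation ~ "validation",
    TRUE ~ "test"
  )
  feats <- reduce_handcrafted(gen$images, ids$train, pca_dim = pca_dim)
  data_of <- function(which_ids) {
    hbnet_data(
      gen$images[which_ids],
      gen$labels[which_ids, , drop = FALSE],
      feats$reduced[which_ids, , drop = FALSE]
    )
  }
  model <- build_hbnet(config, handcrafted_dim = ncol(feats$reduced))
  model <- hbnet_train(model, data_of(ids$train), data_of(ids$validation),
    verbose = verbose
  )
  set.seed(seed + 1L)
  mc_val <- mc_predict_many(model, gen$images[ids$validation],
    feats$reduced[ids$validation, , drop = FALSE],
    T_mc = T_mc
  )
  mc_test <- mc_predict_many(model, gen$images[ids$test],
    feats$reduced[ids$test, , drop = FALSE],
    T_mc = T_mc
  )
  mu_val <- t(vapply(mc_val, function(m) colMeans(m$samples), numeric(length(cts))))
  thresholds <- grid_search_thresholds(
    gen$labels[ids$validation, , drop = FALSE], mu_val
  )
  rec_val <- uncertainty_records(mc_val,
    cell_types = cts,
    truth = gen$labels[ids$validation, , drop = FALSE],
    prob_thresholds = thresholds$prob_threshold
  )
  rec_test <- uncertainty_records(mc_test,
    cell_types = cts,
    truth = gen$labels[ids$test, , drop = FALSE],
    prob_thresholds = thresholds$prob_threshold
  )
  cutoffs <- select_cutoffs(rec_val,
    labels = cts,
    target_accuracy = target_accuracy,
    min_retained_fraction = min_retained_fraction
  )
  triage <- apply_cutoffs(rec_test, cutoffs)
  mu_test <- t(vapply(mc_test, function(m) colMeans(m$samples), numeric(length(cts))))
  calls <- sweep(mu_test, 2, thresholds$prob_threshold, ">=") * 1L
  dimnames(calls) <- dimnames(mu_test) <- list(ids$test, cts)
  evaluation <- evaluate_multilabel(
    gen$labels[ids$test, , drop = FALSE], calls,
    scores = mu_test
  )
  structure(
    list(
      config = config, image_spec = spec, split_ids = ids,
      annotations = ann, labels = gen$labels,
      model = model, thresholds = thresholds, cutoffs = cutoffs,
      records_validation = rec_val, records_test = rec_test,
      evaluation = evaluation, triage = triage,
      chance_exact_match = chance_exact_match(
        gen$labels[ids$test, , drop = FALSE],
        colMeans(gen$labels[ids$train, , drop = FALSE])
      ),
      seed = seed
    ),
    class = "ihc_study"
  )
}

#' @export
print.ihc_study <- function(x, ...) {
  cat("Synthetic IHC study (seed", x$seed, ")\n\n")
  print(x$evaluation)
  cat("\n")
  print(x$triage)
  invisible(x)
}

#' Write a provenance record for a pipeline run
#'
#' Snapshot of the configuration, seed and package version from which every
#' output of a run can be regenerated.
#'
#' @param path Output YAML path.
#' @param config An `ihc_config` or `hbnet_config`.
#' @param seed The master seed used.
#' @param extra Optional named list appended verbatim.
#' @return `path` invisibly.
#' @export
write_provenance <- function(path, config, seed, extra = list()) {
  rec <- c(
    list(
      package = "ihctriage",
      version = as.character(utils::packageVersion("ihctriage")),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
      seed = as.integer(seed),
      config = unclass_deep(config)
    ),
    extra
  )
  yaml::write_yaml(rec, path)
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.list(x)) lapply(unclass(x), unclass_deep) else x
}
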