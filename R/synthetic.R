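#' Specification for the synthetic testis-IHC image generator
#'
#' The generator emulates the geometry a manual observer scores: circular
#' seminiferous-tubule cross-sections whose concentric germ-cell rings run
#' outer to inner (spermatogonia, preleptotene, pachytene, round/early,
#' elongated/late spermatids), radial Sertoli wisps threading the germ
#' layers, interstitial Leydig blobs, and a thin peritubular perimeter ring.
#' Compartments of label-positive cell types are painted DAB-brown scaled by
#' staining intensity; everything else keeps the hematoxylin-blue
#' counterstain (which, as in real sections, is distinctly lighter than the
#' DAB precipitate); Gaussian pixel noise is added.
#'
#' Default label marginals follow the real collection qualitatively (Leydig
#' most frequent at 0.66, peritubular rarest at 0.10) and labels are
#' correlated within the three biological clusters (premeiotic, meiotic /
#' postmeiotic, somatic) through a Gaussian copula.
#'
#' @param n_images Number of images.
#' @param image_side Image side in pixels (>= 48 for the ring geometry).
#' @param label_model List with `prevalence` (length-C marginals), `clusters`
#'   (list of label-index vectors) and `rho` (within-cluster latent
#'   correlation).
#' @param intensity_distribution Probabilities of intensity 1, 2, 3 given a
#'   positive label.
#' @param stain_brown,counter_blue RGB triples of the DAB and hematoxylin
#'   palette.
#' @param noise_sd Gaussian pixel noise standard deviation (8-bit units).
#' @param seed Seed; generation is bitwise reproducible.
#' @return A list with class `"synthetic_image_spec"`.
#' @export
synthetic_image_spec <- function(n_images = 100L,
                                 image_side = 64L,
                                 label_model = default_label_model(),
                                 intensity_distribution = c(0.25, 0.40, 0.35),
                                 stain_brown = c(110, 70, 40),
                                 counter_blue = c(130, 140, 200),
                                 noise_sd = 8,
                                 seed = 1L) {
  if (image_side < 48L) stop("image_side must be >= 48 to fit the ring geometry", call. = FALSE)
  stopifnot(
    length(intensity_distribution) == 3L,
    abs(sum(intensity_distribution) - 1) < 1e-8,
    all(stain_brown >= 0 & stain_brown <= 255),
    all(counter_blue >= 0 & counter_blue <= 255),
    all(label_model$prevalence >= 0 & label_model$prevalence <= 1)
  )
  structure(
    list(
      n_images = as.integer(n_images), image_side = as.integer(image_side),
      label_model = label_model,
      intensity_distribution = intensity_distribution,
      stain_brown = stain_brown, counter_blue = counter_blue,
      noise_sd = noise_sd, seed = as.integer(seed)
    ),
    class = "synthetic_image_spec"
  )
}

#' Default correlated multilabel model
#'
#' @return A list with `prevalence`, `clusters`, `rho`.
#' @export
default_label_model <- function() {
  list(
    prevalence = stats::setNames(
      c(0.35, 0.35, 0.45, 0.40, 0.40, 0.20, 0.66, 0.10),
      cell_type_vocabulary()
    ),
    clusters = list(
      premeiotic = 1:2, meiotic = 3:5, somatic = 6:8
    ),
    rho = 0.6
  )
}

#' Sample a correlated binary label matrix
#'
#' Gaussian-copula sampler: each image draws one latent normal per cluster;
#' label c is positive when `rho * u_cluster + sqrt(1 - rho^2) * eps_c`
#' falls below the quantile of its marginal prevalence. Marginals equal
#' `prevalence`; labels within a cluster co-occur more than across clusters.
#'
#' @param n Number of images.
#' @param label_model See [default_label_model()].
#' @param seed Optional seed.
#' @return `n x C` integer matrix.
#' @export
sample_label_matrix <- function(n, label_model = default_label_model(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- label_model$prevalence
  C <- length(p)
  rho <- label_model$rho
  cluster_of <- integer(C)
  for (k in seq_along(label_model$clusters)) {
    cluster_of[label_model$clusters[[k]]] <- k
  }
  U <- matrix(stats::rnorm(n * length(label_model$clusters)), n)
  E <- matrix(stats::rnorm(n * C), n)
  Z <- rho * U[, cluster_of, drop = FALSE] + sqrt(1 - rho^2) * E
  Y <- sweep(Z, 2, stats::qnorm(p), "<") * 1L
  colnames(Y) <- names(p) %||% paste0("label_", seq_len(C))
  Y
}

# Compartment masks for one image: a list of logical matrices, one per cell
# type, plus the lumen/background. Masks are disjoint; Sertoli wisps carve
# through the germ-cell rings.
tubule_masks <- function(side, centers, radii, rng_angles) {
  x <- matrix(rep(seq_len(side), each = side), side)
  y <- matrix(rep(seq_len(side), times = side), side)
  C <- 8L
  masks <- replicate(C, matrix(FALSE, side, side), simplify = FALSE)
  ring_breaks <- c(0.12, 0.34, 0.52, 0.68, 0.82, 0.95, 1.06)
  germ_order <- 5:1 # inner ring -> elongated/late ... outer -> spermatogonia
  for (t in seq_along(radii)) {
    dx <- x - centers[[t]][1]
    dy <- y - centers[[t]][2]
    r <- sqrt(dx^2 + dy^2) / radii[t]
    theta <- atan2(dy, dx)
    wisp <- (abs(sin(3 * (theta - rng_angles[t]))) > 0.975) & r > ring_breaks[2] & r <= ring_breaks[6]
    for (g in seq_len(5)) {
      ring <- r > ring_breaks[g] & r <= ring_breaks[g + 1] & !wisp
      masks[[germ_order[g]]] <- masks[[germ_order[g]]] | ring
    }
    masks[[6]] <- masks[[6]] | wisp # sertoli
    masks[[8]] <- masks[[8]] | (r > ring_breaks[6] & r <= ring_breaks[7]) # peritubular
  }
  # interstitial Leydig blobs: seeded in the tissue between/around tubules,
  # which always exists because tubules never cover the whole crop
  interstitium <- matrix(TRUE, side, side)
  for (t in seq_along(radii)) {
    dx <- x - centers[[t]][1]
    dy <- y - centers[[t]][2]
    interstitium <- interstitium & (sqrt(dx^2 + dy^2) / radii[t] > ring_breaks[7])
  }
  free <- which(interstitium)
  seeds <- free[sample.int(length(free), min(3L, length(free)))]
  for (s in seeds) {
    blob <- (x - x[s])^2 + (y - y[s])^2 <= 3.2^2
    masks[[7]] <- masks[[7]] | (blob & interstitium)
  }
  masks
}

location_profiles <- list(
  spermatogonia = c("nucleus", "cytoplasm", "nucleus+cytoplasm"),
  preleptotene_spermatocytes = c("nucleus", "cytoplasm"),
  pachytene_spermatocytes = c("cytoplasm", "nucleus", "cytoplasm+membrane"),
  round_early_spermatids = c("cytoplasm", "nucleus"),
  elongated_late_spermatids = c("cytoplasm", "cytoplasm+membrane"),
  sertoli = c("membrane", "nucleus+membrane", "cytoplasm"),
  leydig = c("cytoplasm", "cytoplasm+membrane"),
  peritubular = c("cytoplasm", "membrane")
)

#' Generate a synthetic labelled IHC image set
#'
#' @param spec A [synthetic_image_spec()].
#' @param keep_masks Also return the per-image compartment masks (used by the
#'   colour-rule label oracle).
#' @return A list with `images` (named list of `side x side x 3` integer
#'   arrays), `annotations` (an `"ihc_annotations"` tibble with intensities,
#'   locations and splits), `labels` (`n x C` matrix) and optionally `masks`.
#' @export
generate_images <- function(spec, keep_masks = FALSE) {
  stopifnot(inherits(spec, "synthetic_image_spec"))
  set.seed(spec$seed)
  side <- spec$image_side
  cts <- names(spec$label_model$prevalence) %||% cell_type_vocabulary()
  n <- spec$n_images
  Y <- sample_label_matrix(n, spec$label_model)
  intensity <- matrix(0L, n, ncol(Y))
  intensity[Y == 1L] <- sample(1:3,
    sum(Y), replace = TRUE,
    prob = spec$intensity_distribution
  )
  # staining mix toward DAB brown per intensity grade: weak positives sit
  # deliberately close to the counterstain, as weak staining does in practice
  mixw <- c(0.35, 0.70, 1.00)
  images <- vector("list", n)
  masks_out <- if (keep_masks) vector("list", n)
  ids <- sprintf("syn_%04d", seq_len(n))
  for (i in seq_len(n)) {
    two <- stats::runif(1) < 0.3
    if (two) {
      radii <- stats::runif(2, 0.17, 0.21) * side
      centers <- list(
        c(side * 0.30 + stats::runif(1, -2, 2), side * 0.5 + stats::runif(1, -3, 3)),
        c(side * 0.72 + stats::runif(1, -2, 2), side * 0.5 + stats::runif(1, -3, 3))
      )
    } else {
      radii <- stats::runif(1, 0.34, 0.42) * side
      centers <- list(c(
        side / 2 + stats::runif(1, -3, 3),
        side / 2 + stats::runif(1, -3, 3)
      ))
    }
    angles <- stats::runif(length(radii), 0, 2 * pi)
    masks <- tubule_masks(side, centers, radii, angles)
    base <- array(rep(c(232, 228, 234), each = side * side), c(side, side, 3))
    for (c in seq_along(masks)) {
      w <- if (intensity[i, c] > 0L) mixw[intensity[i, c]] else 0
      col <- (1 - w) * spec$counter_blue + w * spec$stain_brown
      for (ch in 1:3) {
        plane <- base[, , ch]
        plane[masks[[c]]] <- col[ch]
        base[, , ch] <- plane
      }
    }
    noisy <- base + stats::rnorm(length(base), 0, spec$noise_sd)
    img <- pmax(pmin(round(noisy), 255), 0)
    storage.mode(img) <- "integer"
    images[[i]] <- img
    if (keep_masks) masks_out[[i]] <- masks
  }
  names(images) <- ids
  rownames(Y) <- ids
  ann <- tibble::tibble(image_id = ids, split = "train")
  for (c in seq_along(cts)) {
    ann[[paste0(cts[c], "_intensity")]] <- intensity[, c]
    locs <- character(n)
    pos <- which(intensity[, c] > 0L)
    if (length(pos)) {
      locs[pos] <- sample(location_profiles[[cts[c]]], length(pos), replace = TRUE)
    }
    ann[[paste0(cts[c], "_location")]] <- locs
  }
  out <- list(
    images = images,
    annotations = validate_annotations(ann, cts),
    labels = Y
  )
  if (keep_masks) {
    names(masks_out) <- ids
    out$masks <- masks_out
  }
  out
}

#' Colour-rule label oracle for synthetic images
#'
#' Recovers the label vector of a generated image from its compartment
#' masks: a cell type is called positive when the mean brown index
#' (R channel minus B channel) over its compartment exceeds `threshold`,
#' sitting between the counterstain (about -80) and the weakest staining
#' grade. Guarantees the synthetic classification task is learnable.
#'
#' @param pixels Generated image array.
#' @param masks The image's compartment masks (from
#'   `generate_images(keep_masks = TRUE)`).
#' @param threshold Brown-index decision threshold.
#' @return Integer label vector (length C).
#' @export
oracle_labels <- function(pixels, masks, threshold = -55) {
  vapply(masks, function(m) {
    if (!any(m)) return(0L)
    as.integer(mean(pixels[, , 1][m] - pixels[, , 3][m]) > threshold)
  }, integer(1))
}

#' Specification for synthetic Monte-Carlo prediction sets
#'
#' Stands in for the stochastic forward passes of a trained network, with
#' controlled calibration: item difficulty pulls the Beta sampling mean from
#' the true label toward 0.5 and lowers the Beta concentration, so harder
#' items are both less accurate and more dispersed — the regime in which
#' DHC triage is informative.
#'
#' @param true_labels `n x C` binary matrix.
#' @param T_mc Samples per item and label.
#' @param difficulty Per-item difficulty in `[0, 1]` (recycled). Difficulty
#'   moves the target sampling mean from the true label toward 0.5 and
#'   widens both the item-level spread of realised means and the
#'   pass-to-pass dispersion, so errors arise exactly where predictions are
#'   indifferent.
#' @param miscalibration Extra shrink of the sampling mean toward 0.5 that
#'   the difficulty does not account for (0 = calibrated).
#' @param concentration_range Pass-level Beta concentration at difficulty 0
#'   and 1.
#' @param item_concentration_range Item-level Beta concentration (spread of
#'   the realised per-item mean around the difficulty target) at difficulty
#'   0 and 1.
#' @param seed Seed.
#' @return A list with class `"synthetic_mc_spec"`.
#' @export
synthetic_mc_spec <- function(true_labels, T_mc = 100L, difficulty = 0.5,
                              miscalibration = 0,
                              concentration_range = c(50, 4),
                              item_concentration_range = c(4000, 25),
                              seed = 1L) {
  true_labels <- as.matrix(true_labels)
  difficulty <- rep_len(difficulty, nrow(true_labels))
  stopifnot(all(difficulty >= 0 & difficulty <= 1), T_mc >= 2L)
  structure(
    list(
      true_labels = true_labels, T_mc = as.integer(T_mc),
      difficulty = difficulty, miscalibration = miscalibration,
      concentration_range = concentration_range,
      item_concentration_range = item_concentration_range,
      seed = as.integer(seed)
    ),
    class = "synthetic_mc_spec"
  )
}

#' Generate synthetic Monte-Carlo prediction sets
#'
#' @param spec A [synthetic_mc_spec()].
#' @return A list with `mc_sets` (list of `"mc_prediction_set"`), `truth`
#'   (the label matrix with image-id rownames) and `correct` (`n x C`
#'   matrix: does thresholding the predictive mean at 0.5 match truth).
#' @export
generate_mc_samples <- function(spec) {
  stopifnot(inherits(spec, "synthetic_mc_spec"))
  set.seed(spec$seed)
  Y <- spec$true_labels
  n <- nrow(Y)
  C <- ncol(Y)
  ids <- sprintf("mc_%05d", seq_len(n))
  rownames(Y) <- ids
  colnames(Y) <- colnames(Y) %||% paste0("label_", seq_len(C))
  interp <- function(range, d) exp(log(range[1]) * (1 - d) + log(range[2]) * d)
  kap_mc <- interp(spec$concentration_range, spec$difficulty)
  kap_item <- interp(spec$item_concentration_range, spec$difficulty)
  mc_sets <- vector("list", n)
  correct <- matrix(FALSE, n, C, dimnames = list(ids, colnames(Y)))
  for (i in seq_len(n)) {
    mu <- Y[i, ] + (1 - 2 * Y[i, ]) * 0.5 * spec$difficulty[i]
    mu <- mu + spec$miscalibration * (0.5 - mu)
    mu <- pmin(pmax(mu, 0.02), 0.98)
    # realised per-item mean: how well the model actually does on this item
    m_i <- stats::rbeta(C, mu * kap_item[i], (1 - mu) * kap_item[i])
    m_i <- pmin(pmax(m_i, 0.02), 0.98)
    S <- matrix(0, spec$T_mc, C)
    for (c in seq_len(C)) {
      S[, c] <- stats::rbeta(spec$T_mc, m_i[c] * kap_mc[i], (1 - m_i[c]) * kap_mc[i])
    }
    colnames(S) <- colnames(Y)
    mc_sets[[i]] <- structure(
      list(image_id = ids[i], samples = S),
      class = "mc_prediction_set"
    )
    correct[i, ] <- (colMeans(S) >= 0.5) == (Y[i, ] == 1)
  }
  names(mc_sets) <- ids
  list(mc_sets = mc_sets, truth = Y, correct = correct)
}
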