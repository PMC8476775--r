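#' Hybrid Bayesian network configuration
#'
#' Hyperparameters of the hybrid network: a convolutional trunk whose final
#' (flattened) feature map is projected to a `cnn_feature_dim`-long
#' learned feature vector, concatenated with the PCA-reduced handcrafted
#' block and fed to a fully connected Drop-Weights head ending in one sigmoid
#' per label. Defaults follow the reference workflow (Adam with the AMSGrad
#' maximum-of-past-variance correction, base learning rate 1e-6, minibatch
#' 32, 250 epochs, weight decay 0.2, Drop-Weights rate 0.3, He-uniform
#' initialisation); [hbnet_profile()] provides a desk-scale preset.
#'
#' @param backbone `"small_cnn"` (3 conv blocks, desk-scale) or
#'   `"vgg19_like"` (16 conv layers at 1024 px input, the reference scale).
#' @param input_side Input image side in pixels.
#' @param cnn_feature_dim Length of the learned CNN feature vector.
#' @param fc_layer_sizes Widths of the fully connected hidden layers.
#' @param drop_weight_rate Per-weight Bernoulli drop probability in `[0, 1)`,
#'   active in both training and inference.
#' @param n_labels Number of sigmoid outputs.
#' @param learning_rate,batch_size,epochs,weight_decay Optimisation settings;
#'   `weight_decay` is an L2 penalty coefficient on all weight matrices.
#' @param train_trunk Backpropagate through the convolutional trunk (TRUE) or
#'   freeze it and train only the fully connected layers.
#' @param seed Master seed for initialisation, shuffling and mask sampling.
#' @return A list with class `"hbnet_config"`.
#' @export
hbnet_config <- function(backbone = c("small_cnn", "vgg19_like"),
                         input_side = NULL,
                         cnn_feature_dim = 256L,
                         fc_layer_sizes = c(512L, 512L),
                         drop_weight_rate = 0.3,
                         n_labels = 8L,
                         learning_rate = 1e-6,
                         batch_size = 32L,
                         epochs = 250L,
                         weight_decay = 0.2,
                         train_trunk = TRUE,
                         seed = 1L) {
  backbone <- match.arg(backbone)
  if (drop_weight_rate < 0 || drop_weight_rate >= 1) {
    stop("drop_weight_rate must lie in [0, 1)", call. = FALSE)
  }
  if (n_labels < 1L) stop("n_labels must be >= 1", call. = FALSE)
  input_side <- input_side %||% if (backbone == "small_cnn") 64L else 1024L
  structure(
    list(
      backbone = backbone, input_side = as.integer(input_side),
      cnn_feature_dim = as.integer(cnn_feature_dim),
      fc_layer_sizes = as.integer(fc_layer_sizes),
      drop_weight_rate = drop_weight_rate, n_labels = as.integer(n_labels),
      learning_rate = learning_rate, batch_size = as.integer(batch_size),
      epochs = as.integer(epochs), weight_decay = weight_decay,
      optimizer = "amsgrad", init = "he-uniform",
      train_trunk = isTRUE(train_trunk), seed = as.integer(seed)
    ),
    class = "hbnet_config"
  )
}

#' Desk-scale and reference-scale configuration profiles
#'
#' `"desk"` is the out-of-the-box profile (64 px input, small trunk, 64-d CNN
#' feature, two 64-wide hidden layers, learning rate 1e-3, 30 epochs, light
#' weight decay) sized so the whole workflow runs in minutes on one CPU.
#' `"paper_scale"` reproduces the reference hyperparameters for users with
#' the real image collections.
#'
#' @param profile `"desk"` or `"paper_scale"`.
#' @param ... Overrides passed to [hbnet_config()].
#' @return A `"hbnet_config"`.
#' @export
hbnet_profile <- function(profile = c("desk", "paper_scale"), ...) {
  profile <- match.arg(profile)
  defaults <- if (profile == "desk") {
    list(
      backbone = "small_cnn", input_side = 64L, cnn_feature_dim = 64L,
      fc_layer_sizes = c(64L, 64L), learning_rate = 3e-4, batch_size = 16L,
      epochs = 60L, weight_decay = 1e-4
    )
  } else {
    list(backbone = "vgg19_like", input_side = 1024L)
  }
  overrides <- list(...)
  do.call(hbnet_config, utils::modifyList(defaults, overrides))
}

trunk_channels <- function(backbone) {
  switch(backbone,
    small_cnn = list(8L, 16L, 32L),
    vgg19_like = list(
      c(64L, 64L), c(128L, 128L), c(256L, 256L, 256L, 256L),
      c(512L, 512L, 512L, 512L), c(512L, 512L, 512L, 512L)
    )
  )
}

#' Build a hybrid Bayesian network
#'
#' Allocates He-uniform initialised weights for the convolutional trunk
#' (3x3 same-padded convolutions + ReLU, a 2x2 max pool closing each block),
#' the flattened-map projection producing the CNN feature vector, and
#' the Drop-Weights fully connected head operating on the hybrid
#' (CNN + handcrafted) vector. Drop-Weights masks are applied to the fully
#' connected weights only.
#'
#' @param config A [hbnet_config()].
#' @param handcrafted_dim Length of the reduced handcrafted block appended to
#'   the CNN feature (0 for a CNN-only ablation).
#' @return A list with class `"hbnet"`.
#' @export
build_hbnet <- function(config, handcrafted_dim = 0L) {
  stopifnot(inherits(config, "hbnet_config"))
  set.seed(config$seed)
  blocks <- trunk_channels(config$backbone)
  side <- config$input_side
  n_pools <- length(blocks)
  if (side %% 2L^n_pools != 0L) {
    stop("input_side must be divisible by ", 2L^n_pools, " for this backbone", call. = FALSE)
  }
  trunk <- list()
  cin <- 3L
  for (bl in blocks) {
    for (cout in bl) {
      fan_in <- 9L * cin
      trunk[[length(trunk) + 1L]] <- list(
        W = he_uniform(fan_in, cout, fan_in), b = numeric(cout),
        side = side,
        idx = if (side <= 128L) im2col_index(side, cin)
      )
      cin <- cout
    }
    trunk[[length(trunk)]]$pool_after <- TRUE
    side <- side %/% 2L
  }
  # the final conv map feeds the projection to the learned CNN feature
  # vector: flattened (spatial layout preserved) for the desk backbone,
  # globally average-pooled at the vgg19_like scale where a flatten would
  # be enormous
  pool_mode <- if (config$backbone == "small_cnn") "flatten" else "gap"
  proj_in <- if (pool_mode == "flatten") side * side * cin else cin
  proj <- list(
    W = he_uniform(proj_in, config$cnn_feature_dim, proj_in),
    b = numeric(config$cnn_feature_dim)
  )
  hybrid_dim <- config$cnn_feature_dim + as.integer(handcrafted_dim)
  head <- list()
  din <- hybrid_dim
  for (width in config$fc_layer_sizes) {
    head[[length(head) + 1L]] <- list(W = he_uniform(din, width, din), b = numeric(width))
    din <- width
  }
  head[[length(head) + 1L]] <- list(
    W = he_uniform(din, config$n_labels, din),
    b = numeric(config$n_labels), output = TRUE
  )
  structure(
    list(
      config = config, trunk = trunk, proj = proj, head = head,
      pool_mode = pool_mode,
      handcrafted_dim = as.integer(handcrafted_dim), trained = FALSE
    ),
    class = "hbnet"
  )
}

# Normalise raw 0..255 pixels to the network input range.
prep_input <- function(pixels) {
  x <- pixels / 255 - 0.5
  storage.mode(x) <- "double"
  x
}

trunk_forward <- function(model, x, keep_cache = FALSE) {
  caches <- if (keep_cache) vector("list", length(model$trunk) * 2L)
  k <- 0L
  for (layer in model$trunk) {
    cf <- conv_forward(x, layer)
    x <- cf$out
    if (keep_cache) caches[[k <- k + 1L]] <- list(type = "conv", cache = cf$cache)
    if (isTRUE(layer$pool_after)) {
      pf <- maxpool_forward(x)
      x <- pf$out
      if (keep_cache) caches[[k <- k + 1L]] <- list(type = "pool", cache = pf$cache)
    }
  }
  pooled <- if (identical(model$pool_mode, "gap")) {
    matrix(colMeans(matrix(x, ncol = dim(x)[3])), 1)
  } else {
    matrix(as.vector(x), 1)
  }
  df <- dense_forward(pooled, model$proj$W, model$proj$b, relu = TRUE)
  list(
    cnn = drop(df$out),
    cache = if (keep_cache) list(layers = caches[seq_len(k)], map_dim = dim(x), proj = df$cache)
  )
}

trunk_backward <- function(model, dcnn, cache) {
  grads <- list(trunk = vector("list", length(model$trunk)), proj = NULL)
  dp <- dense_backward(matrix(dcnn, 1), model$proj$W, cache$proj)
  grads$proj <- list(dW = dp$dW, db = dp$db)
  md <- cache$map_dim
  dx <- if (identical(model$pool_mode, "gap")) {
    array(rep(drop(dp$dx) / (md[1] * md[2]), each = md[1] * md[2]), md)
  } else {
    array(dp$dx, md)
  }
  li <- length(model$trunk)
  for (k in rev(seq_along(cache$layers))) {
    entry <- cache$layers[[k]]
    if (entry$type == "pool") {
      dx <- maxpool_backward(dx, entry$cache)
    } else {
      cb <- conv_backward(dx, model$trunk[[li]], entry$cache)
      grads$trunk[[li]] <- list(dW = cb$dW, db = cb$db)
      dx <- cb$dx
      li <- li - 1L
    }
  }
  grads
}

head_forward <- function(model, H, masks = NULL, keep_cache = FALSE) {
  caches <- if (keep_cache) vector("list", length(model$head))
  x <- H
  for (k in seq_along(model$head)) {
    layer <- model$head[[k]]
    df <- dense_forward(x, layer$W, layer$b,
      mask = if (!is.null(masks)) masks[[k]],
      relu = !isTRUE(layer$output)
    )
    x <- df$out
    if (keep_cache) caches[[k]] <- df$cache
  }
  list(probs = sigmoid(x), logits = x, cache = caches)
}

head_backward <- function(model, dZ, cache) {
  grads <- vector("list", length(model$head))
  dx <- dZ
  for (k in rev(seq_along(model$head))) {
    db <- dense_backward(dx, model$head[[k]]$W, cache[[k]])
    grads[[k]] <- list(dW = db$dW, db = db$db)
    dx <- db$dx
  }
  list(head = grads, dhybrid = dx)
}

sample_head_masks <- function(model) {
  rate <- model$config$drop_weight_rate
  lapply(model$head, function(layer) {
    if (rate == 0) NULL else sample_drop_weights_mask(dim(layer$W), rate)
  })
}

#' Forward pass of the hybrid network
#'
#' @param model A built `"hbnet"`.
#' @param pixels `H x W x 3` image array (0..255), side matching
#'   `config$input_side`.
#' @param handcrafted Reduced handcrafted vector (length
#'   `model$handcrafted_dim`).
#' @param stochastic Sample a fresh Drop-Weights mask for the fully connected
#'   head (TRUE) or use the deterministic expected network (FALSE).
#' @return Named numeric vector of per-label sigmoid probabilities.
#' @export
hbnet_forward <- function(model, pixels, handcrafted = numeric(0), stochastic = FALSE) {
  stopifnot(inherits(model, "hbnet"))
  if (length(handcrafted) != model$handcrafted_dim) {
    stop("expected a handcrafted vector of length ", model$handcrafted_dim, call. = FALSE)
  }
  tf <- trunk_forward(model, prep_input(pixels))
  H <- matrix(assemble_hybrid(tf$cnn, handcrafted), 1)
  masks <- if (stochastic) sample_head_masks(model)
  drop(head_forward(model, H, masks = masks)$probs)
}

#' Monte-Carlo Drop-Weights prediction set
#'
#' Runs `T` stochastic forward passes for one image, each with a freshly
#' sampled Drop-Weights mask on the fully connected head (the deterministic
#' trunk and handcrafted features are computed once). The rows of the result
#' approximate draws from the Bayesian posterior predictive distribution.
#'
#' @inheritParams hbnet_forward
#' @param T_mc Number of stochastic passes (the reference workflow uses 1000;
#'   the desk profile 100).
#' @param image_id Identifier stored in the result.
#' @param seed Optional seed for the mask stream.
#' @return An object of class `"mc_prediction_set"`: a list with `image_id`
#'   and `samples` (`T x C` matrix of probabilities).
#' @export
mc_predict <- function(model, pixels, handcrafted = numeric(0), T_mc = 100L,
                       image_id = "image", seed = NULL) {
  stopifnot(inherits(model, "hbnet"), T_mc >= 1L)
  if (!is.null(seed)) set.seed(seed)
  tf <- trunk_forward(model, prep_input(pixels))
  H <- matrix(assemble_hybrid(tf$cnn, handcrafted), 1)
  S <- matrix(0, T_mc, model$config$n_labels)
  for (t in seq_len(T_mc)) {
    S[t, ] <- head_forward(model, H, masks = sample_head_masks(model))$probs
  }
  colnames(S) <- paste0("label_", seq_len(model$config$n_labels))
  structure(list(image_id = image_id, samples = S), class = "mc_prediction_set")
}

#' Monte-Carlo prediction sets for many images
#'
#' @param model A trained `"hbnet"`.
#' @param images Named list of image arrays.
#' @param handcrafted `n x d` matrix of reduced handcrafted features, rows
#'   aligned with `images`.
#' @param T_mc Number of stochastic passes per image.
#' @param seed Seed for the mask stream (one stream across all images).
#' @return Named list of `"mc_prediction_set"` objects.
#' @export
mc_predict_many <- function(model, images, handcrafted = NULL, T_mc = 100L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- names(images) %||% as.character(seq_along(images))
  out <- vector("list", length(images))
  for (i in seq_along(images)) {
    hv <- if (is.null(handcrafted)) numeric(0) else handcrafted[i, ]
    out[[i]] <- mc_predict(model, images[[i]], hv, T_mc = T_mc, image_id = ids[i])
  }
  names(out) <- ids
  out
}

l2_penalty_grads <- function(model, grads, wd) {
  if (wd == 0) return(grads)
  if (model$config$train_trunk) {
    for (k in seq_along(grads$trunk)) {
      if (!is.null(grads$trunk[[k]])) {
        grads$trunk[[k]]$dW <- grads$trunk[[k]]$dW + wd * model$trunk[[k]]$W
      }
    }
    grads$proj$dW <- grads$proj$dW + wd * model$proj$W
  }
  for (k in seq_along(grads$head)) {
    grads$head[[k]]$dW <- grads$head[[k]]$dW + wd * model$head[[k]]$W
  }
  grads
}

#' Train a hybrid Bayesian network
#'
#' Minimises mean per-label binary cross-entropy (no class weighting) with
#' AMSGrad, resampling a Drop-Weights mask for the fully connected head once
#' per minibatch. After every epoch the mean per-label validation accuracy at
#' threshold 0.5 is computed with the deterministic (expected) network, and
#' the best-on-validation weights are returned.
#'
#' @param model A built `"hbnet"`.
#' @param train,validation Datasets from [hbnet_data()], with disjoint image
#'   ids.
#' @param epochs,learning_rate,batch_size,weight_decay Optional overrides of
#'   the model configuration.
#' @param verbose Print per-epoch progress.
#' @return The trained model, with a `log` tibble (epoch, loss,
#'   val_accuracy) and `best_epoch` attached.
#' @export
hbnet_train <- function(model, train, validation,
                        epochs = NULL, learning_rate = NULL,
                        batch_size = NULL, weight_decay = NULL,
                        verbose = FALSE) {
  stopifnot(inherits(model, "hbnet"))
  cfg <- model$config
  epochs <- epochs %||% cfg$epochs
  lr <- learning_rate %||% cfg$learning_rate
  bs <- batch_size %||% cfg$batch_size
  wd <- weight_decay %||% cfg$weight_decay
  if (length(train$images) == 0L || length(validation$images) == 0L) {
    stop("empty training or validation split", call. = FALSE)
  }
  if (length(intersect(names(train$images), names(validation$images)))) {
    stop("train and validation image ids overlap", call. = FALSE)
  }
  set.seed(cfg$seed)
  n <- length(train$images)
  inputs <- lapply(train$images, prep_input)
  # start the output layer at the training prevalence (logit bias init):
  # the first epochs then refine features instead of relearning base rates
  prev <- pmin(pmax(colMeans(train$labels), 0.02), 0.98)
  model$head[[length(model$head)]]$b <- log(prev / (1 - prev))
  opt <- list(
    trunk = lapply(model$trunk, function(l) list(W = amsgrad_init(l$W), b = amsgrad_init(l$b))),
    proj = list(W = amsgrad_init(model$proj$W), b = amsgrad_init(model$proj$b)),
    head = lapply(model$head, function(l) list(W = amsgrad_init(l$W), b = amsgrad_init(l$b)))
  )
  log <- vector("list", epochs)
  best <- list(acc = -Inf, weights = NULL, epoch = NA_integer_)
  for (ep in seq_len(epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    n_batches <- 0L
    for (start in seq(1L, n, by = bs)) {
      batch <- ord[start:min(start + bs - 1L, n)]
      B <- length(batch)
      masks <- sample_head_masks(model)
      cnn_feats <- matrix(0, B, cfg$cnn_feature_dim)
      trunk_caches <- if (cfg$train_trunk) vector("list", B)
      for (bi in seq_len(B)) {
        tf <- trunk_forward(model, inputs[[batch[bi]]], keep_cache = cfg$train_trunk)
        cnn_feats[bi, ] <- tf$cnn
        if (cfg$train_trunk) trunk_caches[[bi]] <- tf$cache
      }
      H <- cbind(cnn_feats, train$handcrafted[batch, , drop = FALSE])
      hf <- head_forward(model, H, masks = masks, keep_cache = TRUE)
      lb <- bce_loss(hf$probs, train$labels[batch, , drop = FALSE])
      if (!is.finite(lb$loss)) {
        stop("training aborted: non-finite loss at epoch ", ep, call. = FALSE)
      }
      ep_loss <- ep_loss + lb$loss
      n_batches <- n_batches + 1L
      hb <- head_backward(model, lb$dZ, hf$cache)
      grads <- list(head = hb$head, trunk = NULL, proj = NULL)
      if (cfg$train_trunk) {
        dcnn <- hb$dhybrid[, seq_len(cfg$cnn_feature_dim), drop = FALSE]
        acc_tr <- NULL
        for (bi in seq_len(B)) {
          g <- trunk_backward(model, dcnn[bi, ], trunk_caches[[bi]])
          if (is.null(acc_tr)) {
            acc_tr <- g
          } else {
            for (k in seq_along(g$trunk)) {
              acc_tr$trunk[[k]]$dW <- acc_tr$trunk[[k]]$dW + g$trunk[[k]]$dW
              acc_tr$trunk[[k]]$db <- acc_tr$trunk[[k]]$db + g$trunk[[k]]$db
            }
            acc_tr$proj$dW <- acc_tr$proj$dW + g$proj$dW
            acc_tr$proj$db <- acc_tr$proj$db + g$proj$db
          }
        }
        grads$trunk <- acc_tr$trunk
        grads$proj <- acc_tr$proj
      }
      grads <- l2_penalty_grads(model, grads, wd)
      if (cfg$train_trunk) {
        for (k in seq_along(model$trunk)) {
          up <- amsgrad_step(model$trunk[[k]]$W, grads$trunk[[k]]$dW, opt$trunk[[k]]$W, lr)
          model$trunk[[k]]$W <- up$param
          opt$trunk[[k]]$W <- up$state
          up <- amsgrad_step(model$trunk[[k]]$b, grads$trunk[[k]]$db, opt$trunk[[k]]$b, lr)
          model$trunk[[k]]$b <- up$param
          opt$trunk[[k]]$b <- up$state
        }
        up <- amsgrad_step(model$proj$W, grads$proj$dW, opt$proj$W, lr)
        model$proj$W <- up$param
        opt$proj$W <- up$state
        up <- amsgrad_step(model$proj$b, grads$proj$db, opt$proj$b, lr)
        model$proj$b <- up$param
        opt$proj$b <- up$state
      }
      for (k in seq_along(model$head)) {
        up <- amsgrad_step(model$head[[k]]$W, grads$head[[k]]$dW, opt$head[[k]]$W, lr)
        model$head[[k]]$W <- up$param
        opt$head[[k]]$W <- up$state
        up <- amsgrad_step(model$head[[k]]$b, grads$head[[k]]$db, opt$head[[k]]$b, lr)
        model$head[[k]]$b <- up$param
        opt$head[[k]]$b <- up$state
      }
    }
    val_probs <- hbnet_predict_probs(model, validation$images, validation$handcrafted)
    val_acc <- mean((val_probs >= 0.5) == (validation$labels > 0))
    log[[ep]] <- tibble::tibble(
      epoch = ep, loss = ep_loss / n_batches, val_accuracy = val_acc
    )
    if (val_acc > best$acc) {
      best <- list(
        acc = val_acc, epoch = ep,
        weights = list(trunk = model$trunk, proj = model$proj, head = model$head)
      )
    }
    if (verbose) {
      message(sprintf(
        "epoch %3d  loss %.4f  val_acc %.4f", ep, ep_loss / n_batches, val_acc
      ))
    }
  }
  model$trunk <- best$weights$trunk
  model$proj <- best$weights$proj
  model$head <- best$weights$head
  model$log <- dplyr::bind_rows(log)
  model$best_epoch <- best$epoch
  model$best_val_accuracy <- best$acc
  model$trained <- TRUE
  model
}

#' Deterministic per-image probabilities for a set of images
#'
#' Expected-network forward pass (no Drop-Weights sampling).
#'
#' @inheritParams mc_predict_many
#' @return `n x C` matrix of probabilities.
#' @export
hbnet_predict_probs <- function(model, images, handcrafted = NULL) {
  P <- matrix(0, length(images), model$config$n_labels)
  for (i in seq_along(images)) {
    hv <- if (is.null(handcrafted)) numeric(0) else handcrafted[i, ]
    P[i, ] <- hbnet_forward(model, images[[i]], hv, stochastic = FALSE)
  }
  rownames(P) <- names(images)
  P
}

#' Bundle images, labels and handcrafted features for training
#'
#' @param images Named list of `H x W x 3` arrays.
#' @param labels `n x C` binary matrix with matching rownames.
#' @param handcrafted `n x d` matrix of reduced handcrafted features (or NULL
#'   for a CNN-only model).
#' @return A list with class `"hbnet_data"`.
#' @export
hbnet_data <- function(images, labels, handcrafted = NULL) {
  ids <- names(images)
  stopifnot(!is.null(ids), all(ids == rownames(labels)))
  if (is.null(handcrafted)) {
    handcrafted <- matrix(0, length(images), 0L, dimnames = list(ids, NULL))
  }
  stopifnot(nrow(handcrafted) == length(images))
  structure(
    list(images = images, labels = labels, handcrafted = as.matrix(handcrafted)),
    class = "hbnet_data"
  )
}
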