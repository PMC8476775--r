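#' Testicular cell-type vocabulary
#'
#' The eight cell types scored in testis IHC images, in the fixed order that
#' defines label-vector index 1..8 throughout the package: five germ cell
#' stages ordered from the tubule periphery inward (spermatogonia,
#' preleptotene spermatocytes, pachytene spermatocytes, round/early
#' spermatids, elongated/late spermatids) followed by the three somatic types
#' (Sertoli, Leydig, peritubular).
#'
#' @return Character vector of length 8.
#' @export
#' @examples
#' cell_type_vocabulary()
cell_type_vocabulary <- function() {
  c(
    "spermatogonia",
    "preleptotene_spermatocytes",
    "pachytene_spermatocytes",
    "round_early_spermatids",
    "elongated_late_spermatids",
    "sertoli",
    "leydig",
    "peritubular"
  )
}

#' Subcellular locations recognised in annotations
#' @return Character vector.
#' @export
subcellular_locations <- function() c("cytoplasm", "nucleus", "membrane")

#' Staining intensity scale
#'
#' 0 = negative, 1 = weak, 2 = moderate, 3 = strong.
#' @return Integer vector `0:3`.
#' @export
intensity_scale <- function() 0:3

#' Package run configuration
#'
#' A declarative, nestable key/value configuration controlling the cell-type
#' list, image size, model and DHC parameters. Values not supplied fall back
#' to package defaults.
#'
#' @param cell_types Character vector defining the label vocabulary and order.
#' @param image_side Side (pixels) images are resized to before feature
#'   extraction and the CNN. The reference workflow uses 1024; the desk-scale
#'   profile uses 64.
#' @param pca_dim Target dimensionality of the PCA-reduced handcrafted block
#'   (reference value 3732; clamped to the admissible maximum for small runs).
#' @param model A model configuration from [hbnet_config()].
#' @param T_mc Number of Monte-Carlo forward passes at inference.
#' @param cppd_mode `"per_label"` (default) treats each sigmoid output as a
#'   Bernoulli so CPPD = |2*mu - 1|; `"across_labels"` takes the gap between
#'   the two largest per-label means of an image.
#' @param dhc_epsilon Floor for the jackknife-entropy denominator of the DHC
#'   ratio.
#' @param dhc_cap Cap applied to the raw DHC ratio so tables stay finite.
#' @param seed Master seed fanned out to all stochastic stages.
#' @param ... Further fields stored verbatim.
#' @return A list with class `"ihc_config"`.
#' @export
ihc_config <- function(cell_types = cell_type_vocabulary(),
                       image_side = 64L,
                       pca_dim = 3732L,
                       model = hbnet_config(n_labels = length(cell_types)),
                       T_mc = 100L,
                       cppd_mode = c("per_label", "across_labels"),
                       dhc_epsilon = 1e-10,
                       dhc_cap = 1e6,
                       seed = 1L,
                       ...) {
  cppd_mode <- match.arg(cppd_mode)
  cfg <- list(
    cell_types = cell_types, image_side = as.integer(image_side),
    pca_dim = as.integer(pca_dim), model = model, T_mc = as.integer(T_mc),
    cppd_mode = cppd_mode, dhc_epsilon = dhc_epsilon, dhc_cap = dhc_cap,
    seed = as.integer(seed), ...
  )
  structure(cfg, class = "ihc_config")
}

#' Read / write a configuration file
#'
#' Configurations are stored as YAML (nestable key/value).
#'
#' @param path File path.
#' @return `read_config()` returns an `ihc_config`; `write_config()` returns
#'   `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  margs <- raw$model %||% list()
  margs <- margs[intersect(names(margs), names(formals(hbnet_config)))]
  model <- do.call(hbnet_config, margs)
  raw$model <- NULL
  do.call(ihc_config, c(raw, list(model = model)))
}

#' @rdname read_config
#' @param config An `ihc_config`.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "ihc_config"))
  out <- unclass(config)
  out$model <- unclass(out$model)
  yaml::write_yaml(out, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
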