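# Synthetic aligned multi-omics generator: class-dependent Gaussian
# mean shifts on a planted set of informative features, low-rank
# factors shared across layers (the cross-omics correlation structure
# the fusion module targets), and i.i.d. Gaussian noise elsewhere.

#' Simulation configuration
#'
#' Defaults define the package's standard validation fixture
#' ("mini-BRCA"): 300 samples, 3 imbalanced classes, three omics layers
#' of 200/200/100 features with 20 planted informative features each,
#' a moderate effect size and 5 shared cross-omics factors.
#'
#' @param n_samples Total sample count N.
#' @param n_classes Class count Q.
#' @param n_features Integer vector, features per omics layer.
#' @param n_informative Informative features per layer (single value or
#'   one per layer).
#' @param effect_size Class-mean separation in units of `noise_sd`
#'   (adjacent class levels of an informative feature differ by
#'   `effect_size * noise_sd / (Q - 1)`; the extreme classes by the
#'   full `effect_size * noise_sd`).
#' @param noise_sd Standard deviation of the i.i.d. Gaussian noise.
#' @param shared_factor_dim Number of latent factors shared across
#'   layers (loadings live on the informative features).
#' @param factor_sd Loading scale of the shared factors.
#' @param class_proportions Length-Q sampling proportions (sum to 1).
#' @param omics_names Layer names.
#' @param seed RNG seed; fixed seed reproduces the dataset bitwise.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_samples = 300L,
                       n_classes = 3L,
                       n_features = c(200L, 200L, 100L),
                       n_informative = 20L,
                       effect_size = 1.5,
                       noise_sd = 1,
                       shared_factor_dim = 5L,
                       factor_sd = 0.5,
                       class_proportions = c(0.5, 0.3, 0.2),
                       omics_names = NULL,
                       seed = 1L) {
  n_informative <- rep_len(n_informative, length(n_features))
  if (any(n_informative > n_features)) {
    stop("n_informative exceeds n_features", call. = FALSE)
  }
  stopifnot(effect_size >= 0, noise_sd > 0,
            length(class_proportions) == n_classes,
            abs(sum(class_proportions) - 1) < 1e-8)
  if (is.null(omics_names)) {
    omics_names <- c("mrna", "meth", "mirna",
                     paste0("omics", seq_along(n_features)))[
                       seq_along(n_features)]
  }
  structure(list(n_samples = as.integer(n_samples),
                 n_classes = as.integer(n_classes),
                 n_features = as.integer(n_features),
                 n_informative = as.integer(n_informative),
                 effect_size = effect_size, noise_sd = noise_sd,
                 shared_factor_dim = as.integer(shared_factor_dim),
                 factor_sd = factor_sd,
                 class_proportions = class_proportions,
                 omics_names = omics_names, seed = as.integer(seed)),
            class = "sim_config")
}

#' Simulate an aligned multi-omics dataset with known ground truth
#'
#' For each layer, the planted informative features carry
#' class-dependent mean shifts: each informative feature assigns the Q
#' classes a random permutation of Q equally spaced levels spanning
#' `effect_size * noise_sd`. Shared low-rank factors (loadings on
#' informative features only) induce cross-omics correlation; all other
#' variation is i.i.d. Gaussian noise. Non-informative features are
#' pure noise.
#'
#' @param cfg A `sim_config`.
#' @return List with `dataset` (a `multiomics_dataset`) and `truth`
#'   (per-layer logical `informative_mask`, the class assignment, the
#'   factor scores/loadings, and the config echo).
#' @export
simulate_multiomics <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  n <- cfg$n_samples
  q <- cfg$n_classes
  y <- sample(seq_len(q) - 1L, n, replace = TRUE,
              prob = cfg$class_proportions)
  # guarantee every class is represented (tiny-N edge case)
  missing <- setdiff(seq_len(q) - 1L, unique(y))
  if (length(missing) > 0L) {
    y[sample(n, length(missing))] <- missing
  }
  sample_ids <- sprintf("s%03d", seq_len(n))
  r <- cfg$shared_factor_dim
  Fscores <- if (r > 0L) matrix(stats::rnorm(n * r), n, r)
  levels_q <- if (q > 1L) seq(-0.5, 0.5, length.out = q) else 0

  mats <- vector("list", length(cfg$n_features))
  masks <- vector("list", length(cfg$n_features))
  loadings <- vector("list", length(cfg$n_features))
  for (m in seq_along(cfg$n_features)) {
    d <- cfg$n_features[m]
    ni <- cfg$n_informative[m]
    mask <- rep(FALSE, d)
    mask[seq_len(ni)] <- TRUE
    mask <- mask[sample.int(d)]
    mu <- matrix(0, q, d)
    for (j in which(mask)) {
      mu[, j] <- cfg$effect_size * cfg$noise_sd * sample(levels_q)
    }
    L <- matrix(0, max(r, 0L), d)
    if (r > 0L && ni > 0L) {
      L[, mask] <- stats::rnorm(r * ni, sd = cfg$factor_sd)
    }
    X <- mu[y + 1L, , drop = FALSE] +
      matrix(stats::rnorm(n * d, sd = cfg$noise_sd), n, d)
    if (r > 0L) X <- X + Fscores %*% L
    feature_ids <- sprintf("%s_f%04d", cfg$omics_names[m], seq_len(d))
    dimnames(X) <- list(sample_ids, feature_ids)
    mats[[m]] <- omics_matrix(X, cfg$omics_names[m])
    names(mask) <- feature_ids
    masks[[m]] <- mask
    loadings[[m]] <- L
  }
  names(masks) <- cfg$omics_names
  labels <- label_vector(sample_ids, sprintf("class%d", y + 1L))
  list(dataset = assemble_dataset(mats, labels),
       truth = list(informative_mask = masks, y = y,
                    factor_scores = Fscores, loadings = loadings,
                    config = cfg))
}

#' Write a simulated dataset to a directory
#'
#' Writes the standard dataset layout plus `truth.json` (informative
#' masks, class assignment, config echo).
#'
#' @param sim Output of [simulate_multiomics()].
#' @param dir Target directory.
#' @export
write_simulation <- function(sim, dir) {
  write_dataset_dir(sim$dataset, dir)
  truth <- list(informative_mask = lapply(sim$truth$informative_mask,
                                          function(m) names(m)[m]),
                y = sim$truth$y,
                config = unclass(sim$truth$config))
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
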