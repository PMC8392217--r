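#' Model and training configuration
#'
#' Collects every tunable of the three-pathway network in one validated
#' list. Defaults follow the published architecture where it is stated
#' (grid of 30 voxels per axis with 8 channels, sequence length 1000
#' with a 128-dimensional embedding, first sequence block of 64 kernels
#' of size 5, 3D channel progression 8-32-64-128, 73-dimensional atom
#' features) and this package's documented choices where it is not
#' (deeper-block widths, pooling widths, head size, optimizer).
#'
#' @param profile `"default"` for the full-size architecture or
#'   `"small"` for a reduced configuration suitable for desk-scale
#'   synthetic experiments and tests. Explicit arguments override the
#'   profile in either case.
#' @param ... named overrides of any configuration field; unknown names
#'   are an error.
#'
#' @return A list of class `"cpi_config"` with fields:
#' \describe{
#'   \item{grid_edge, grid_resolution, grid_channels}{binding-site box
#'     edge length (\ifelse{html}{\out{&Aring;}}{A}), voxel size, and
#'     number of pharmacophoric channels (30, 1, 8).}
#'   \item{site_kernel, site_channels, site_pool}{3D kernel extent per
#'     axis, output channels of the three 3D blocks, max-pool width.}
#'   \item{seq_max_len, seq_embed_dim, seq_kernel, seq_filters,
#'     seq_pool}{sequence pathway: tokenized length, embedding
#'     dimension, 1D kernel size, filters of the three blocks, pooling
#'     width.}
#'   \item{gcn_widths, gcn_feat_pool}{graph pathway: widths of the
#'     three graph-convolution weight matrices and the feature-space
#'     max-pooling width applied after each.}
#'   \item{site_readout, seq_readout}{how the final convolutional map
#'     of the site / sequence pathway becomes a vector: `"flatten"`
#'     (position-preserving, the default architecture), `"max"`, or
#'     `"mean"` (global max / average per filter: position-free, one
#'     feature per final filter, useful at small scale where
#'     positional features invite target memorization).}
#'   \item{head_hidden}{hidden units of the fully connected head.}
#'   \item{dropout}{dropout probability on the fused feature vector
#'     during training (0 disables).}
#'   \item{modality_dropout}{probability, per training batch, of
#'     zeroing one whole pathway segment of the fused vector, so each
#'     pathway must be independently predictive (0 disables).}
#'   \item{augment_seq_rotate, augment_site_jitter}{training-time
#'     augmentation: circularly rotate each protein sequence by a
#'     random offset per epoch, and re-voxelize each site with the box
#'     center jittered uniformly within the given radius
#'     (\ifelse{html}{\out{&Aring;}}{A}) per epoch. Both break
#'     position-specific target fingerprints while preserving
#'     presence-type structure; prediction never augments.}
#'   \item{leaky_slope}{negative slope of every LeakyReLU.}
#'   \item{gamma, loss_eps}{focal-loss focusing exponent and the
#'     probability clamp used inside the logarithms.}
#'   \item{lr, batch_size, epochs}{Adam learning rate, minibatch size,
#'     training epochs.}
#'   \item{avg_tail}{average the weights of the last `avg_tail` epochs
#'     into the final model (stochastic weight averaging; 0 keeps the
#'     last-epoch weights). Stabilizes small, noisy runs.}
#' }
#' @examples
#' cfg <- cpi_config()
#' cfg$site_channels
#' small <- cpi_config("small", epochs = 5)
#' @export
cpi_config <- function(profile = c("default", "small"), ...) {
  profile <- match.arg(profile)
  cfg <- list(
    grid_edge = 30, grid_resolution = 1, grid_channels = 8L,
    site_kernel = 3L, site_channels = c(32L, 64L, 128L), site_pool = 2L,
    seq_max_len = 1000L, seq_embed_dim = 128L, seq_kernel = 5L,
    seq_filters = c(64L, 96L, 128L), seq_pool = 2L,
    gcn_widths = c(64L, 96L, 128L), gcn_feat_pool = 2L,
    site_readout = "flatten", seq_readout = "flatten",
    head_hidden = 256L, dropout = 0, modality_dropout = 0,
    augment_seq_rotate = FALSE, augment_site_jitter = 0,
    leaky_slope = 0.01,
    gamma = 2, loss_eps = 1e-7,
    lr = 1e-4, weight_decay = 0, batch_size = 16L, epochs = 20L,
    avg_tail = 0L
  )
  if (profile == "small") {
    cfg$site_channels <- c(4L, 8L, 8L)
    cfg$seq_embed_dim <- 8L
    cfg$seq_filters <- c(8L, 8L, 8L)
    cfg$gcn_widths <- c(16L, 16L, 16L)
    cfg$head_hidden <- 32L
    cfg$dropout <- 0.3
    cfg$weight_decay <- 1e-4
    cfg$site_readout <- "mean"
    cfg$seq_readout <- "mean"
    cfg$augment_seq_rotate <- TRUE
    cfg$augment_site_jitter <- 2
    cfg$avg_tail <- 10L
    cfg$lr <- 1e-3
    cfg$batch_size <- 16L
    cfg$epochs <- 30L
  }
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(cfg))
    if (length(bad) || is.null(names(dots)) || any(names(dots) == ""))
      stop("unknown configuration field(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    cfg[names(dots)] <- dots
  }
  validate_config(cfg)
  structure(cfg, class = "cpi_config")
}

validate_config <- function(cfg) {
  stopifnot(
    cfg$grid_edge > 0, cfg$grid_resolution > 0,
    cfg$grid_edge %% cfg$grid_resolution == 0,
    cfg$grid_channels >= 1,
    cfg$site_kernel >= 1, length(cfg$site_channels) >= 1,
    all(cfg$site_channels >= 1), cfg$site_pool >= 1,
    cfg$seq_max_len >= 1, cfg$seq_embed_dim >= 1, cfg$seq_kernel >= 1,
    all(cfg$seq_filters >= 1), cfg$seq_pool >= 1,
    all(cfg$gcn_widths >= 1), cfg$gcn_feat_pool >= 1,
    cfg$head_hidden >= 1, cfg$dropout >= 0, cfg$dropout < 1,
    cfg$modality_dropout >= 0, cfg$modality_dropout < 1,
    cfg$site_readout %in% c("flatten", "max", "mean"),
    cfg$seq_readout %in% c("flatten", "max", "mean"),
    is.logical(cfg$augment_seq_rotate), cfg$augment_site_jitter >= 0,
    cfg$gamma >= 0, cfg$loss_eps > 0, cfg$loss_eps < 0.5,
    cfg$lr > 0, cfg$weight_decay >= 0, cfg$batch_size >= 1,
    cfg$epochs >= 0, cfg$avg_tail >= 0
  )
  invisible(cfg)
}

#' @export
print.cpi_config <- function(x, ...) {
  nvox <- as.integer(x$grid_edge / x$grid_resolution)
  cat("<cpi_config>\n")
  cat(sprintf("  site grid: %d channels, %d^3 voxels (%g A at %g A)\n",
              x$grid_channels, nvox, x$grid_edge, x$grid_resolution))
  cat(sprintf("  3D conv:   k=%d, channels %s, pool %d\n", x$site_kernel,
              paste(x$site_channels, collapse = "-"), x$site_pool))
  cat(sprintf("  sequence:  len %d, embed %d, k=%d, filters %s, pool %d\n",
              x$seq_max_len, x$seq_embed_dim, x$seq_kernel,
              paste(x$seq_filters, collapse = "-"), x$seq_pool))
  cat(sprintf("  graph:     widths %s, feature pool %d\n",
              paste(x$gcn_widths, collapse = "-"), x$gcn_feat_pool))
  cat(sprintf("  head:      %d hidden -> sigmoid; LeakyReLU slope %g\n",
              x$head_hidden, x$leaky_slope))
  cat(sprintf("  loss:      focal gamma=%g; train: Adam lr=%g, batch=%d, epochs=%d\n",
              x$gamma, x$lr, x$batch_size, x$epochs))
  invisible(x)
}

# seeded evaluation without touching the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}
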