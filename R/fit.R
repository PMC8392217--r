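#' Featurize targets for the network
#'
#' Converts raw target descriptions (site atoms + sequence) into the
#' tensors the network consumes: the 8-channel occupancy grid,
#' flattened to a voxels-by-channels matrix, and the tokenized
#' sequence.
#'
#' @param targets named list; each element is a list with `site` (a
#'   site-atom data frame, see [build_site_grid()]) and `sequence`
#'   (one-letter amino-acid string). An optional `center` element fixes
#'   the box center (e.g. the bound ligand's centroid).
#' @param config a [cpi_config()].
#' @return Named list of per-target feature caches (`V`: voxel matrix,
#'   `tokens`: integer vector, `grid_dim`: grid shape).
#' @export
featurize_targets <- function(targets, config = cpi_config()) {
  stopifnot(is.list(targets), !is.null(names(targets)))
  lapply(targets, function(t) {
    g <- build_site_grid(t$site, center = t$center,
                         edge = config$grid_edge,
                         resolution = config$grid_resolution)
    d <- dim(g)
    V <- t(matrix(g, d[1], prod(d[2:4])))
    list(V = V, grid_dim = d,
         tokens = suppressWarnings(
           tokenize_sequence(t$sequence, config$seq_max_len)))
  })
}

#' Featurize molecules for the network
#'
#' Parses SMILES (batched through openbabel) into molecular graphs.
#'
#' @param smiles named character vector of SMILES (names = ligand
#'   ids), or a list of ready-made [mol_graph()] objects (returned
#'   unchanged).
#' @return Named list of `"mol_graph"` objects.
#' @export
featurize_molecules <- function(smiles) {
  if (is.list(smiles) && all(vapply(smiles, inherits, TRUE, "mol_graph")))
    return(smiles)
  stopifnot(is.character(smiles), !is.null(names(smiles)))
  parsed <- parse_smiles(smiles, names(smiles))
  lapply(parsed, mol_graph_from_parsed)
}

check_pairs <- function(pairs) {
  need <- c("target_id", "ligand_id", "label")
  miss <- setdiff(need, names(pairs))
  if (length(miss))
    stop("pairs lack column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(pairs$label %in% c(0, 1)))
    stop("labels must be 0/1", call. = FALSE)
  key <- paste(pairs$target_id, pairs$ligand_id)
  if (anyDuplicated(key))
    stop("duplicated (target_id, ligand_id) pairs", call. = FALSE)
  pairs$target_id <- as.character(pairs$target_id)
  pairs$ligand_id <- as.character(pairs$ligand_id)
  pairs
}

#' Fit the multiscale convolutional interaction model
#'
#' Trains the three-pathway network end to end on labeled
#' compound-protein pairs: the voxelized binding site through three 3D
#' convolutional blocks, the tokenized sequence through an embedding
#' and three 1D convolutional blocks, the molecular graph through
#' three normalized graph convolutions with feature pooling and a
#' global max readout; the concatenated features feed a two-layer
#' sigmoid head. The loss is the focal loss with class-balance
#' coefficients N/(P+N) (positive term) and P/(P+N) (negative term)
#' taken from the training labels, minimized with Adam.
#'
#' @param pairs data frame with columns `target_id`, `ligand_id`,
#'   `label` (1 = interacting/docking, 0 = decoy).
#' @param targets named list of target descriptions (see
#'   [featurize_targets()]) or an already-featurized cache from it.
#' @param molecules named character vector of SMILES or featurized
#'   graphs (see [featurize_molecules()]).
#' @param config a [cpi_config()].
#' @param validation optional data frame of held-out pairs over the
#'   same `targets`/`molecules`; its AUC is logged per epoch.
#' @param ablate drop one pathway (`"site"`, `"sequence"`,
#'   `"molecule"`) from the fusion; default `"none"`.
#' @param seed integer seed driving initialization and shuffling.
#' @param cache_site_patches keep the unrolled first-layer site
#'   patches per target between epochs (faster, more memory).
#' @param verbose print one line per epoch.
#' @return An object of class `"cpi_fit"` with components `params`
#'   (trained weights), `config`, `geometry`, `history` (per-epoch
#'   loss and validation AUC), `class_counts` (P, N), `ablate`,
#'   `seed`, and the featurization caches. Methods: [predict.cpi_fit()],
#'   `print`, `summary`, `plot`, `coef`.
#' @examples
#' \donttest{
#' sim <- generate_targets(4, seed = 1)
#' dat <- generate_pairs(sim, molecules_per_target = 8, seed = 2)
#' cfg <- cpi_config("small", epochs = 1)
#' fit <- cpi_fit(dat$pairs, sim, dat$molecules, cfg, seed = 3,
#'                verbose = FALSE)
#' head(predict(fit, dat$pairs))
#' }
#' @export
cpi_fit <- function(pairs, targets, molecules, config = cpi_config(),
                    validation = NULL,
                    ablate = c("none", "site", "sequence", "molecule"),
                    seed = 1L, cache_site_patches = TRUE,
                    verbose = TRUE) {
  ablate <- match.arg(ablate)
  validate_config(config)
  pairs <- check_pairs(pairs)
  geom <- model_geometry(config)
  tcache <- if (is_tcache(targets)) targets
            else featurize_targets(targets, config)
  mcache <- featurize_molecules(molecules)
  missing_t <- setdiff(unique(pairs$target_id), names(tcache))
  missing_m <- setdiff(unique(pairs$ligand_id), names(mcache))
  if (length(missing_t) || length(missing_m))
    stop("pairs reference unknown ids: ",
         paste(c(missing_t, missing_m), collapse = ", "), call. = FALSE)
  if (!is.null(validation)) validation <- check_pairs(validation)

  if (cache_site_patches && ablate != "site") {
    k <- config$site_kernel
    for (t in unique(c(pairs$target_id, validation$target_id)))
      tcache[[t]]$patches1 <- gather_patches(
        tcache[[t]]$V, conv3d_indices(geom$grid_n, k))
  }

  P <- sum(pairs$label == 1); N <- sum(pairs$label == 0)
  if (P + N == 0) stop("no training pairs", call. = FALSE)
  nb <- ceiling(nrow(pairs) / config$batch_size)
  history <- data.frame(epoch = integer(0), loss = numeric(0),
                        val_auc = numeric(0))

  augment <- isTRUE(config$augment_seq_rotate) ||
    config$augment_site_jitter > 0
  raw_targets <- if (!is_tcache(targets)) targets
  if (augment && is.null(raw_targets))
    stop("training-time augmentation needs raw targets, not a ",
         "pre-featurized cache", call. = FALSE)
  train_ids <- unique(pairs$target_id)

  params <- NULL
  with_seed(seed, {
    params <- init_params(config, geom, ablate)
    opt <- adam_init(params)
    tc_work <- tcache
    avg <- NULL; n_avg <- 0L
    avg_from <- config$epochs - min(config$avg_tail, config$epochs) + 1L
    for (ep in seq_len(config$epochs)) {
      if (augment)
        for (t in train_ids)
          tc_work[[t]] <- augment_target(raw_targets[[t]], tcache[[t]],
                                         config, geom, ablate,
                                         cache_site_patches)
      perm <- sample.int(nrow(pairs))
      ep_loss <- 0
      for (b in seq_len(nb)) {
        rows <- perm[(((b - 1L) * config$batch_size + 1L):
                        min(b * config$batch_size, nrow(pairs)))]
        tid <- pairs$target_id[rows]
        mid <- pairs$ligand_id[rows]
        y <- pairs$label[rows]
        fw <- batch_forward(params, config, tc_work, mcache, tid, mid,
                            ablate, need_cache = TRUE, train = TRUE)
        l <- focal_loss(fw$p, y, config$gamma, P, N, config$loss_eps)
        if (!is.finite(l))
          stop("non-finite loss at epoch ", ep, ", batch ", b,
               " (diverged; lower lr?)", call. = FALSE)
        ep_loss <- ep_loss + l * length(rows)
        dz <- focal_loss_grad_logit(fw$p, y, config$gamma, P, N,
                                    config$loss_eps)
        grads <- batch_backward(fw, dz, params, config, tid, mid, ablate)
        st <- adam_step(params, grads, opt, config$lr,
                        weight_decay = config$weight_decay)
        params <- st$params
        opt <- st$state
      }
      if (config$avg_tail > 0 && ep >= avg_from) {
        # running mean of the weight trajectory tail
        n_avg <- n_avg + 1L
        avg <- if (is.null(avg)) params
               else mapply_params(avg, params, function(a, b)
                 a + (b - a) / n_avg)
      }
      ep_loss <- ep_loss / nrow(pairs)
      va <- NA_real_
      if (!is.null(validation)) {
        pv <- predict_pairs(params, config, tcache, mcache,
                            validation, ablate)
        va <- tryCatch(roc_auc(pv, validation$label),
                       error = function(e) NA_real_)
      }
      history[ep, ] <- list(ep, ep_loss, va)
      if (verbose)
        message(sprintf("epoch %3d  loss %.5f%s", ep, ep_loss,
                        if (is.na(va)) "" else sprintf("  val AUC %.3f", va)))
    }
    if (!is.null(avg)) params <- avg
  })
  for (t in names(tcache)) tcache[[t]]$patches1 <- NULL

  structure(list(params = params, config = config, geometry = geom,
                 ablate = ablate, history = history,
                 class_counts = c(P = P, N = N), seed = seed,
                 tcache = tcache, mcache = mcache,
                 call = match.call()),
            class = "cpi_fit")
}

# one augmented featurization of a raw target: random circular
# rotation of the sequence and/or a jittered box center
augment_target <- function(raw, tc, config, geom, ablate,
                           cache_site_patches) {
  out <- tc
  if (isTRUE(config$augment_seq_rotate)) {
    s <- raw$sequence
    L <- nchar(s)
    k <- sample.int(L, 1L) - 1L
    if (k > 0)
      s <- paste0(substr(s, k + 1L, L), substr(s, 1L, k))
    out$tokens <- suppressWarnings(
      tokenize_sequence(s, config$seq_max_len))
  }
  if (config$augment_site_jitter > 0 && ablate != "site") {
    ctr <- raw$center
    if (is.null(ctr)) ctr <- site_center(raw$site[, c("x", "y", "z")])
    ctr <- ctr + runif(3, -config$augment_site_jitter,
                       config$augment_site_jitter)
    g <- build_site_grid(raw$site, center = ctr,
                         edge = config$grid_edge,
                         resolution = config$grid_resolution)
    out$V <- t(matrix(g, dim(g)[1], prod(dim(g)[2:4])))
    out$patches1 <- if (cache_site_patches)
      gather_patches(out$V, conv3d_indices(geom$grid_n,
                                           config$site_kernel))
  }
  out
}

is_tcache <- function(x) {
  is.list(x) && length(x) > 0 &&
    all(vapply(x, function(t) is.list(t) && !is.null(t$V) &&
                 !is.null(t$tokens), TRUE))
}

predict_pairs <- function(params, config, tcache, mcache, pairs,
                          ablate) {
  p <- numeric(nrow(pairs))
  bs <- max(config$batch_size, 64L)
  nb <- ceiling(nrow(pairs) / bs)
  for (b in seq_len(nb)) {
    rows <- (((b - 1L) * bs + 1L):min(b * bs, nrow(pairs)))
    fw <- batch_forward(params, config, tcache, mcache,
                        pairs$target_id[rows], pairs$ligand_id[rows],
                        ablate)
    p[rows] <- fw$p
  }
  p
}

#' Predict interaction probabilities
#'
#' @param object a fitted `"cpi_fit"`.
#' @param pairs data frame with `target_id` and `ligand_id` columns
#'   (a `label` column, if present, is ignored).
#' @param targets,molecules descriptions for ids not seen at fit time
#'   (same formats as in [cpi_fit()]).
#' @param type `"response"` for probabilities (default) or `"class"`
#'   for 0/1 at `threshold`.
#' @param threshold classification cut-point for `type = "class"`.
#' @param ... unused.
#' @return Numeric vector of probabilities in (0, 1), or integer 0/1
#'   labels for `type = "class"`, in the row order of `pairs`.
#' @export
predict.cpi_fit <- function(object, pairs, targets = NULL,
                            molecules = NULL,
                            type = c("response", "class"),
                            threshold = 0.5, ...) {
  type <- match.arg(type)
  pairs$label <- NULL
  pairs$label <- 0
  pairs <- check_pairs(pairs)
  tcache <- object$tcache
  if (!is.null(targets)) {
    extra <- if (is_tcache(targets)) targets
             else featurize_targets(targets, object$config)
    tcache[names(extra)] <- extra
  }
  mcache <- object$mcache
  if (!is.null(molecules)) {
    extra <- featurize_molecules(molecules)
    mcache[names(extra)] <- extra
  }
  missing_t <- setdiff(unique(pairs$target_id), names(tcache))
  missing_m <- setdiff(unique(pairs$ligand_id), names(mcache))
  if (length(missing_t) || length(missing_m))
    stop("no featurization for id(s): ",
         paste(c(missing_t, missing_m), collapse = ", "), call. = FALSE)
  p <- predict_pairs(object$params, object$config, tcache, mcache,
                     pairs, object$ablate)
  if (type == "class") as.integer(p >= threshold) else p
}

#' @export
print.cpi_fit <- function(x, ...) {
  cat("Multiscale convolutional compound-protein interaction model\n")
  cat(sprintf("  pathways: %s (feature lengths %s)\n",
              if (x$ablate == "none") "site + sequence + molecule"
              else paste("ablated:", x$ablate),
              paste(x$geometry$lens, collapse = " + ")))
  cat(sprintf("  training: %d positive / %d negative pairs, %d epochs\n",
              x$class_counts["P"], x$class_counts["N"],
              nrow(x$history)))
  if (nrow(x$history)) {
    last <- x$history[nrow(x$history), ]
    cat(sprintf("  final loss %.5f%s\n", last$loss,
                if (is.na(last$val_auc)) ""
                else sprintf(", validation AUC %.3f", last$val_auc)))
  }
  invisible(x)
}

#' @export
summary.cpi_fit <- function(object, ...) {
  npar <- sum(rapply(object$params, length, how = "unlist"))
  out <- list(fit = object, n_parameters = npar)
  class(out) <- "summary.cpi_fit"
  out
}

#' @export
print.summary.cpi_fit <- function(x, ...) {
  print(x$fit)
  cfg <- x$fit$config
  cat(sprintf("  parameters: %s\n", format(x$n_parameters, big.mark = ",")))
  cat(sprintf("  focal loss: gamma=%g, coefficients N/(P+N)=%.3f, P/(P+N)=%.3f\n",
              cfg$gamma,
              x$fit$class_counts["N"] / sum(x$fit$class_counts),
              x$fit$class_counts["P"] / sum(x$fit$class_counts)))
  cat(sprintf("  optimizer: Adam lr=%g, batch %d, seed %d\n",
              cfg$lr, cfg$batch_size, x$fit$seed))
  invisible(x)
}

#' @export
coef.cpi_fit <- function(object, ...) object$params

#' @export
plot.cpi_fit <- function(x, ...) {
  h <- x$history
  if (!nrow(h)) {
    warning("no training history to plot")
    return(invisible(x))
  }
  has_va <- any(!is.na(h$val_auc))
  graphics::plot(h$epoch, h$loss, type = "l", xlab = "epoch",
                 ylab = "training loss", ...)
  if (has_va) {
    op <- graphics::par(new = TRUE)
    on.exit(graphics::par(op))
    graphics::plot(h$epoch, h$val_auc, type = "l", lty = 2, col = 2,
                   axes = FALSE, xlab = "", ylab = "", ylim = c(0, 1))
    graphics::axis(4, col.axis = 2)
    graphics::legend("right", c("loss", "val AUC"), lty = 1:2,
                     col = 1:2, bty = "n")
  }
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' Writes the trained weights as a flat binary vector of doubles next
#' to a JSON manifest (`<path>.json`) recording the architecture
#' configuration, its MD5 hash, the parameter shapes, the class counts
#' and the training seed, so a checkpoint fully determines the model.
#'
#' @param fit a `"cpi_fit"`.
#' @param path checkpoint path.
#' @return `path` invisibly (`save_checkpoint`); a `"cpi_fit"` without
#'   featurization caches (`load_checkpoint` -- supply `targets` /
#'   `molecules` to `predict()`).
#' @export
save_checkpoint <- function(fit, path) {
  stopifnot(inherits(fit, "cpi_fit"))
  flat <- rapply(fit$params, as.vector, how = "unlist")
  con <- file(path, "wb")
  writeBin(as.numeric(flat), con, size = 8, endian = "little")
  close(con)
  shapes <- rapply(fit$params, function(x)
    if (is.matrix(x)) dim(x) else length(x), how = "list")
  cfg_json <- jsonlite::toJSON(unclass(fit$config), auto_unbox = TRUE,
                               digits = NA)
  tf <- tempfile(); writeLines(cfg_json, tf)
  manifest <- list(config = unclass(fit$config),
                   config_md5 = unname(tools::md5sum(tf)),
                   shapes = shapes, ablate = fit$ablate,
                   class_counts = as.list(fit$class_counts),
                   seed = fit$seed, history = fit$history)
  unlink(tf)
  jsonlite::write_json(manifest, paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  man <- jsonlite::read_json(paste0(path, ".json"),
                             simplifyVector = TRUE)
  cfg <- man$config
  class(cfg) <- "cpi_config"
  validate_config(cfg)
  geom <- model_geometry(cfg)
  con <- file(path, "rb")
  flat <- readBin(con, "double", n = file.info(path)$size / 8,
                  size = 8, endian = "little")
  close(con)
  pos <- 0L
  build <- function(sh) {
    if (is.list(sh)) return(lapply(sh, build))
    n <- prod(sh)
    v <- flat[(pos + 1L):(pos + n)]
    pos <<- pos + n
    if (length(sh) == 2L) matrix(v, sh[1], sh[2]) else v
  }
  params <- build(man$shapes)
  structure(list(params = params, config = cfg, geometry = geom,
                 ablate = man$ablate,
                 history = as.data.frame(man$history),
                 class_counts = unlist(man$class_counts),
                 seed = man$seed, tcache = list(), mcache = list()),
            class = "cpi_fit")
}
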