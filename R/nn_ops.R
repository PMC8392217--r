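#' @name network-ops
#' @title Convolutional building blocks
#' @description Plain-R implementations of the network's primitive
#' operations. The 3D and 1D convolutions are computed by unrolling
#' local patches into a matrix ("im2col") and multiplying by the
#' unrolled kernel, so the heavy lifting is a BLAS matrix product; the
#' brute-force definitions are kept in the test suite as independent
#' oracles.
#' @keywords internal
NULL

leaky_relu <- function(x, slope = 0.01) {
  neg <- x < 0
  x[neg] <- x[neg] * slope
  x
}

leaky_relu_grad <- function(x, slope = 0.01) {
  ifelse(x < 0, slope, 1)
}

# ---------------------------------------------------------------------
# im2col index matrices, cached per geometry. Spatial fields are stored
# flattened as (n^3) x channels matrices, x fastest, then y, then z.

.idx_cache <- new.env(parent = emptyenv())

# valid-convolution gather indices: (n_out^3) x (k^3) of linear voxel
# positions
conv3d_indices <- function(n, k) {
  key <- paste0("c3_", n, "_", k)
  if (!is.null(.idx_cache[[key]])) return(.idx_cache[[key]])
  no <- n - k + 1L
  if (no < 1L) stop("kernel larger than input extent", call. = FALSE)
  pos <- as.matrix(expand.grid(x = 1:no, y = 1:no, z = 1:no))
  off <- as.matrix(expand.grid(i = 0:(k - 1L), j = 0:(k - 1L),
                               l = 0:(k - 1L)))
  idx <- matrix(0L, nrow(pos), nrow(off))
  for (m in seq_len(nrow(off)))
    idx[, m] <- (pos[, 1] + off[m, 1]) +
      (pos[, 2] + off[m, 2] - 1L) * n +
      (pos[, 3] + off[m, 3] - 1L) * n * n
  .idx_cache[[key]] <- idx
  idx
}

# non-overlapping max-pool groups: (n_out^3) x (w^3)
pool3d_indices <- function(n, w) {
  key <- paste0("p3_", n, "_", w)
  if (!is.null(.idx_cache[[key]])) return(.idx_cache[[key]])
  no <- n %/% w
  if (no < 1L) stop("pooling width larger than input", call. = FALSE)
  pos <- as.matrix(expand.grid(x = 1:no, y = 1:no, z = 1:no))
  off <- as.matrix(expand.grid(i = 0:(w - 1L), j = 0:(w - 1L),
                               l = 0:(w - 1L)))
  idx <- matrix(0L, nrow(pos), nrow(off))
  for (m in seq_len(nrow(off)))
    idx[, m] <- ((pos[, 1] - 1L) * w + 1L + off[m, 1]) +
      ((pos[, 2] - 1L) * w + off[m, 2]) * n +
      ((pos[, 3] - 1L) * w + off[m, 3]) * n * n
  .idx_cache[[key]] <- idx
  idx
}

# gather im2col patches from a flattened field V ((n^d) x C) given an
# index matrix: returns (n_out) x (k_vol * C), position fastest within
# each offset, offsets grouped by channel? No: columns ordered
# (offset within channel): col (c-1)*kvol + m = V[idx[, m], c].
gather_patches <- function(V, idx) {
  P <- V[as.vector(idx), , drop = FALSE]        # (n_out*kvol) x C
  matrix(P, nrow(idx), ncol(idx) * ncol(V))
}

# scatter-add patch gradients back onto the field; within one kernel
# offset every output position touches a distinct input position, so
# plain indexed addition is exact
scatter_patches <- function(dP, idx, nfield, C) {
  kvol <- ncol(idx)
  dV <- matrix(0, nfield, C)
  for (m in seq_len(kvol)) {
    cols <- (seq_len(C) - 1L) * kvol + m
    i <- idx[, m]
    dV[i, ] <- dV[i, ] + dP[, cols, drop = FALSE]
  }
  dV
}

# max over pooling groups with argmax bookkeeping.
# V: (n^d) x C; gidx: n_out x w_vol. Returns list(out, argmax) where
# argmax holds linear positions into V rows.
pool_max <- function(V, gidx) {
  C <- ncol(V)
  cur <- V[gidx[, 1], , drop = FALSE]
  amax <- matrix(gidx[, 1], nrow(gidx), C)
  if (ncol(gidx) < 2L) return(list(out = cur, argmax = amax))
  for (m in seq.int(2L, ncol(gidx))) {
    cand <- V[gidx[, m], , drop = FALSE]
    sel <- cand > cur
    cur[sel] <- cand[sel]
    pos <- matrix(gidx[, m], nrow(gidx), C)
    amax[sel] <- pos[sel]
  }
  list(out = cur, argmax = amax)
}

# pooling groups are disjoint, so argmax positions are unique within a
# channel and indexed addition is exact
pool_max_backward <- function(dOut, argmax, nfield) {
  C <- ncol(dOut)
  dV <- matrix(0, nfield, C)
  for (c in seq_len(C)) {
    i <- argmax[, c]
    dV[i, c] <- dV[i, c] + dOut[, c]
  }
  dV
}

# ---------------------------------------------------------------------

#' 3D convolution over a multi-channel cube
#'
#' One pre-activation 3D convolutional layer of the binding-site
#' pathway. For a kernel of extent (P, Q, R), the output at (x, y, z)
#' of filter f is
#' \deqn{v^{(l+1)}_{xyz} = \sum_m \sum_{i=0}^{P-1} \sum_{j=0}^{Q-1}
#'  \sum_{k=0}^{R-1} w_{ijk}^{(m,f)}\, v^{(l),m}_{(x+i)(y+j)(z+k)} +
#'  b_f,} a valid cross-correlation summed over input channels m.
#'
#' @param cube numeric array `(C, nx, ny, nz)` (channel-first, as
#'   produced by [build_site_grid()]).
#' @param kernel numeric array `(P, Q, R, C, F)`; cubic kernels with
#'   `P = Q = R` are the default architecture but any extent not
#'   exceeding the input is accepted.
#' @param bias numeric vector of length `F` (default zeros).
#' @return Array `(F, nx-P+1, ny-Q+1, nz-R+1)`.
#' @export
conv3d <- function(cube, kernel, bias = NULL) {
  d <- dim(cube)
  stopifnot(length(d) == 4, length(dim(kernel)) == 5)
  C <- d[1]; kd <- dim(kernel)
  if (kd[4] != C)
    stop("kernel input channels ", kd[4], " != cube channels ", C,
         call. = FALSE)
  if (any(kd[1:3] > d[2:4]))
    stop("kernel extent exceeds input extent", call. = FALSE)
  Fk <- kd[5]
  if (is.null(bias)) bias <- numeric(Fk)
  stopifnot(length(bias) == Fk)
  if (d[2] == d[3] && d[3] == d[4] && kd[1] == kd[2] && kd[2] == kd[3]) {
    n <- d[2]; k <- kd[1]
    V <- t(matrix(cube, C, n^3))                 # (n^3) x C
    idx <- conv3d_indices(n, k)
    P <- gather_patches(V, idx)
    # unroll kernel to (k^3*C) x F with channel-major column blocks
    W <- matrix(aperm(kernel, c(1, 2, 3, 4, 5)), k^3 * C, Fk)
    out <- P %*% W
    out <- sweep(out, 2, bias, "+")
    no <- n - k + 1L
    return(array(t(out), dim = c(Fk, no, no, no)))
  }
  conv3d_loop(cube, kernel, bias)                # general extents
}

# straightforward vectorized fallback for non-cubic extents
conv3d_loop <- function(cube, kernel, bias) {
  d <- dim(cube); kd <- dim(kernel)
  no <- d[2:4] - kd[1:3] + 1L
  Fk <- kd[5]
  out <- array(0, c(Fk, no))
  for (f in seq_len(Fk)) {
    acc <- array(0, no)
    for (m in seq_len(d[1]))
      for (i in seq_len(kd[1]))
        for (j in seq_len(kd[2]))
          for (k in seq_len(kd[3]))
            acc <- acc + kernel[i, j, k, m, f] *
              cube[m, i:(i + no[1] - 1L), j:(j + no[2] - 1L),
                   k:(k + no[3] - 1L)]
    out[f, , , ] <- acc + bias[f]
  }
  out
}

#' Fuse the three pathway features
#'
#' Concatenates the local site feature, the global sequence feature and
#' the molecular feature, in that order, into the joint descriptor fed
#' to the classifier head. All three segments must be present unless an
#' ablation is requested explicitly, in which case the named pathway is
#' dropped from the concatenation.
#'
#' @param XL,XG,XM numeric vectors: site, sequence and molecule
#'   pathway outputs.
#' @param ablate `"none"` (default), `"site"`, `"sequence"` or
#'   `"molecule"`: pathway to leave out.
#' @return Numeric vector of length `|XL| + |XG| + |XM|` (minus the
#'   ablated segment).
#' @examples
#' fuse_features(1, 2, 3)
#' fuse_features(1, 2, 3, ablate = "sequence")
#' @export
fuse_features <- function(XL, XG, XM,
                          ablate = c("none", "site", "sequence",
                                     "molecule")) {
  ablate <- match.arg(ablate)
  need <- c(site = !identical(ablate, "site"),
            sequence = !identical(ablate, "sequence"),
            molecule = !identical(ablate, "molecule"))
  seg <- list(site = XL, sequence = XG, molecule = XM)
  for (nm in names(seg))
    if (need[[nm]] && (is.null(seg[[nm]]) || !length(seg[[nm]])))
      stop("missing ", nm, " feature (request an ablation explicitly ",
           "to drop a pathway)", call. = FALSE)
  unlist(seg[need], use.names = FALSE)
}

#' Class-balance-weighted focal loss
#'
#' Per-sample loss of the interaction classifier. With P positive and N
#' negative training samples,
#' \deqn{L = -\frac{N}{P+N}(1-y')^{\gamma}\log y' \quad (y = 1),
#' \qquad L = -\frac{P}{P+N}(y')^{\gamma}\log(1-y') \quad (y = 0),}
#' so the minority class receives the larger coefficient and the
#' \eqn{\gamma} exponent down-weights easy samples. Predicted
#' probabilities are clamped to `[eps, 1-eps]` before the logarithm.
#'
#' @param y_hat predicted probabilities.
#' @param y true 0/1 labels (recycled against `y_hat`).
#' @param gamma focusing exponent, `>= 0` (default 2).
#' @param P,N positive and negative sample counts of the training set
#'   (default 1 and 1: plain focal loss).
#' @param eps probability clamp (default 1e-7).
#' @param reduce return the mean over samples (default) or the
#'   per-sample vector.
#' @return Non-negative loss value(s).
#' @examples
#' focal_loss(0.5, 1, gamma = 2, P = 1, N = 1)   # 0.0866...
#' @export
focal_loss <- function(y_hat, y, gamma = 2, P = 1, N = 1, eps = 1e-7,
                       reduce = TRUE) {
  stopifnot(gamma >= 0, P >= 0, N >= 0, P + N > 0,
            all(y %in% c(0, 1)))
  p <- pmin(pmax(y_hat, eps), 1 - eps)
  wp <- N / (P + N)
  wn <- P / (P + N)
  l <- ifelse(y == 1,
              -wp * (1 - p)^gamma * log(p),
              -wn * p^gamma * log(1 - p))
  if (reduce) mean(l) else l
}

# d loss / d logit for a sigmoid output p = plogis(z), vectorized over
# a batch; returns the mean-reduced gradient (divided by batch size)
focal_loss_grad_logit <- function(p, y, gamma, P, N, eps = 1e-7) {
  pc <- pmin(pmax(p, eps), 1 - eps)
  wp <- N / (P + N); wn <- P / (P + N)
  # dL/dp, then chain through dp/dz = p(1-p)
  dldp <- ifelse(y == 1,
                 wp * (gamma * (1 - pc)^(gamma - 1) * log(pc) -
                         (1 - pc)^gamma / pc),
                 wn * (gamma * pc^(gamma - 1) * log(1 - pc) * (-1) +
                         pc^gamma / (1 - pc)))
  # note: for y=0, dL/dp = -wn * d/dp [p^g log(1-p)]
  #      = -wn (g p^(g-1) log(1-p) - p^g/(1-p)); sign handled above
  dldp * pc * (1 - pc) / length(p)
}
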