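# Internal network machinery: geometry bookkeeping, parameter
# initialization, forward/backward passes and the Adam step. Fields are
# kept flattened ((positions) x channels matrices); convolutions run
# through the im2col helpers in nn_ops.R. Backpropagation is written by
# hand; tests check every convolution against brute-force oracles and
# the full gradient against finite differences.

model_geometry <- function(cfg) {
  k <- cfg$site_kernel; w <- cfg$site_pool
  n <- as.integer(cfg$grid_edge / cfg$grid_resolution)
  site_n <- integer(0)
  nn <- n
  for (l in seq_along(cfg$site_channels)) {
    nc <- nn - k + 1L
    if (nc < 1L) stop("site grid too small for kernel at layer ", l,
                      call. = FALSE)
    np <- nc %/% min(w, nc)
    site_n <- c(site_n, nc, np)
    nn <- np
  }
  kq <- cfg$seq_kernel; wq <- cfg$seq_pool
  LL <- cfg$seq_max_len
  seq_L <- integer(0)
  for (l in seq_along(cfg$seq_filters)) {
    Lc <- LL - kq + 1L
    if (Lc < 1L) stop("sequence too short for kernel at layer ", l,
                      call. = FALSE)
    Lp <- Lc %/% min(wq, Lc)
    seq_L <- c(seq_L, Lc, Lp)
    LL <- Lp
  }
  fp <- cfg$gcn_feat_pool
  gw <- cfg$gcn_widths
  gp <- gw %/% pmin(fp, gw)
  len_site <- if (cfg$site_readout == "flatten")
    site_n[length(site_n)]^3 * tail1(cfg$site_channels)
  else tail1(cfg$site_channels)
  len_seq <- if (cfg$seq_readout == "flatten")
    seq_L[length(seq_L)] * tail1(cfg$seq_filters)
  else tail1(cfg$seq_filters)
  len_mol <- tail1(gp)
  list(grid_n = n, site_n = site_n, seq_L = seq_L,
       gcn_pooled = gp,
       lens = c(site = len_site, sequence = len_seq, molecule = len_mol))
}

tail1 <- function(x) x[length(x)]

fusion_length <- function(geom, ablate = "none") {
  keep <- setdiff(names(geom$lens), ablate)
  sum(geom$lens[keep])
}

# He-style initialization; the RNG state of the caller drives it
init_params <- function(cfg, geom, ablate = "none") {
  he <- function(nin, nout) matrix(rnorm(nin * nout, sd = sqrt(2 / nin)),
                                   nin, nout)
  k3 <- cfg$site_kernel^3
  sc <- c(cfg$grid_channels, cfg$site_channels)
  site <- list()
  for (l in seq_along(cfg$site_channels)) {
    site[[paste0("W", l)]] <- he(k3 * sc[l], sc[l + 1])
    site[[paste0("b", l)]] <- numeric(sc[l + 1])
  }
  kq <- cfg$seq_kernel
  sf <- c(cfg$seq_embed_dim, cfg$seq_filters)
  # unit-scale embedding rows (standard for learned embeddings);
  # padding row pinned at zero
  sq <- list(E = rbind(0, matrix(rnorm(20 * cfg$seq_embed_dim),
                                 20, cfg$seq_embed_dim)))
  for (l in seq_along(cfg$seq_filters)) {
    sq[[paste0("K", l)]] <- he(kq * sf[l], sf[l + 1])
    sq[[paste0("c", l)]] <- numeric(sf[l + 1])
  }
  gin <- c(ATOM_FEATURE_DIM, geom$gcn_pooled)
  mol <- list()
  for (l in seq_along(cfg$gcn_widths))
    mol[[paste0("G", l)]] <- he(gin[l], cfg$gcn_widths[l])
  nf <- fusion_length(geom, ablate)
  head <- list(Wh = he(nf, cfg$head_hidden), bh = numeric(cfg$head_hidden),
               wo = he(cfg$head_hidden, 1L), bo = 0)
  list(site = site, seq = sq, mol = mol, head = head)
}

zero_like <- function(p) rapply(p, function(x) x * 0, how = "replace")

# elementwise combination of two identically shaped parameter trees
mapply_params <- function(a, b, f) {
  if (is.list(a)) {
    for (nm in names(a)) a[[nm]] <- mapply_params(a[[nm]], b[[nm]], f)
    return(a)
  }
  f(a, b)
}

# ---------------------------------------------------------------------
# site pathway

conv1d_indices <- function(L, k) {
  key <- paste0("c1_", L, "_", k)
  if (!is.null(.idx_cache[[key]])) return(.idx_cache[[key]])
  Lout <- L - k + 1L
  idx <- outer(seq_len(Lout), k - seq_len(k) + 1L, "+") - 1L
  # idx[t, m] = t + k - m  (offset j = m-1 reads position k - j + t - 1)
  storage.mode(idx) <- "integer"
  .idx_cache[[key]] <- idx
  idx
}

pool1d_indices <- function(L, w) {
  key <- paste0("p1_", L, "_", w)
  if (!is.null(.idx_cache[[key]])) return(.idx_cache[[key]])
  Lo <- max(L %/% w, 1L)
  idx <- outer((seq_len(Lo) - 1L) * w, seq_len(w), "+")
  storage.mode(idx) <- "integer"
  .idx_cache[[key]] <- idx
  idx
}

site_forward <- function(V, params, cfg, patches1 = NULL) {
  k <- cfg$site_kernel; w <- cfg$site_pool
  nL <- length(cfg$site_channels)
  n <- as.integer(round(nrow(V)^(1 / 3)))
  cache <- list(n = integer(0))
  H <- V
  for (l in seq_len(nL)) {
    P <- if (l == 1L && !is.null(patches1)) patches1
         else gather_patches(H, conv3d_indices(n, k))
    Z <- sweep(P %*% params[[paste0("W", l)]], 2,
               params[[paste0("b", l)]], "+")
    A <- leaky_relu(Z, cfg$leaky_slope)
    nc <- n - k + 1L
    we <- min(w, nc)
    pl <- pool_max(A, pool3d_indices(nc, we))
    np <- nc %/% we
    cache[[paste0("P", l)]] <- P
    cache[[paste0("Z", l)]] <- Z
    cache[[paste0("amax", l)]] <- pl$argmax
    cache$n <- c(cache$n, n, nc, np)
    H <- pl$out
    n <- np
  }
  ro <- readout_forward(H, cfg$site_readout)
  cache$ro <- ro$cache
  list(XL = ro$x, cache = cache)
}

# collapse a (positions x filters) map to a vector: position-preserving
# flatten, or position-free global max / mean per filter
readout_forward <- function(H, mode) {
  switch(mode,
         flatten = list(x = as.vector(H),
                        cache = list(mode = mode, n = nrow(H),
                                     d = ncol(H))),
         max = {
           ro <- apply(H, 2, which.max)
           list(x = H[cbind(ro, seq_len(ncol(H)))],
                cache = list(mode = mode, n = nrow(H), rows = ro))
         },
         mean = list(x = colMeans(H),
                     cache = list(mode = mode, n = nrow(H))))
}

readout_backward <- function(dx, cache) {
  switch(cache$mode,
         flatten = matrix(dx, cache$n, cache$d),
         max = {
           d <- matrix(0, cache$n, length(dx))
           d[cbind(cache$rows, seq_along(dx))] <- dx
           d
         },
         mean = matrix(rep(dx / cache$n, each = cache$n), cache$n))
}

site_backward <- function(dXL, cache, params, cfg) {
  k <- cfg$site_kernel
  nL <- length(cfg$site_channels)
  g <- list()
  d <- readout_backward(dXL, cache$ro)
  for (l in rev(seq_len(nL))) {
    nc <- cache$n[3 * l - 1L]
    dA <- pool_max_backward(d, cache[[paste0("amax", l)]], nc^3)
    dZ <- dA * leaky_relu_grad(cache[[paste0("Z", l)]], cfg$leaky_slope)
    g[[paste0("W", l)]] <- crossprod(cache[[paste0("P", l)]], dZ)
    g[[paste0("b", l)]] <- colSums(dZ)
    if (l > 1L) {
      nin <- cache$n[3 * l - 2L]
      dP <- dZ %*% t(params[[paste0("W", l)]])
      Cin <- ncol(params[[paste0("W", l - 1L)]])
      d <- scatter_patches(dP, conv3d_indices(nin, k), nin^3, Cin)
    }
  }
  g
}

# ---------------------------------------------------------------------
# sequence pathway

seq_forward <- function(tokens, params, cfg) {
  kq <- cfg$seq_kernel; wq <- cfg$seq_pool
  nL <- length(cfg$seq_filters)
  X <- params$E[tokens + 1L, , drop = FALSE]      # positions x embed
  cache <- list(tokens = tokens, L = integer(0))
  H <- X
  L <- nrow(X)
  for (l in seq_len(nL)) {
    P <- gather_patches(H, conv1d_indices(L, kq))
    Z <- sweep(P %*% params[[paste0("K", l)]], 2,
               params[[paste0("c", l)]], "+")
    A <- leaky_relu(Z, cfg$leaky_slope)
    Lc <- L - kq + 1L
    we <- min(wq, Lc)
    pl <- pool_max(A, pool1d_indices(Lc, we))
    cache[[paste0("P", l)]] <- P
    cache[[paste0("Z", l)]] <- Z
    cache[[paste0("amax", l)]] <- pl$argmax
    cache$L <- c(cache$L, L, Lc, Lc %/% we)
    H <- pl$out
    L <- Lc %/% we
  }
  ro <- readout_forward(H, cfg$seq_readout)
  cache$ro <- ro$cache
  list(XG = ro$x, cache = cache)
}

seq_backward <- function(dXG, cache, params, cfg) {
  kq <- cfg$seq_kernel
  nL <- length(cfg$seq_filters)
  g <- list()
  d <- readout_backward(dXG, cache$ro)
  for (l in rev(seq_len(nL))) {
    Lc <- cache$L[3 * l - 1L]
    dA <- pool_max_backward(d, cache[[paste0("amax", l)]], Lc)
    dZ <- dA * leaky_relu_grad(cache[[paste0("Z", l)]], cfg$leaky_slope)
    g[[paste0("K", l)]] <- crossprod(cache[[paste0("P", l)]], dZ)
    g[[paste0("c", l)]] <- colSums(dZ)
    Lin <- cache$L[3 * l - 2L]
    dP <- dZ %*% t(params[[paste0("K", l)]])
    Cin <- if (l > 1L) ncol(params[[paste0("K", l - 1L)]])
           else cfg$seq_embed_dim
    d <- scatter_patches(dP, conv1d_indices(Lin, kq), Lin, Cin)
  }
  # d is now dX (positions x embed); accumulate into embedding rows,
  # keeping the padding row pinned at zero
  dE <- matrix(0, nrow(params$E), ncol(params$E))
  s <- rowsum(d, cache$tokens)
  rows <- as.integer(rownames(s)) + 1L
  dE[rows, ] <- dE[rows, ] + s
  dE[1L, ] <- 0
  g$E <- dE
  g
}

# ---------------------------------------------------------------------
# molecule pathway (feature-space max pooling after each layer, global
# max readout over nodes)

pool_feat <- function(M, fp) {
  fp <- min(fp, ncol(M))
  if (fp <= 1L) return(list(out = M, argmax = NULL))
  no <- ncol(M) %/% fp
  cur <- M[, (seq_len(no) - 1L) * fp + 1L, drop = FALSE]
  amax <- matrix(rep((seq_len(no) - 1L) * fp + 1L, each = nrow(M)),
                 nrow(M), no)
  for (m in seq.int(2L, fp)) {
    cols <- (seq_len(no) - 1L) * fp + m
    cand <- M[, cols, drop = FALSE]
    sel <- cand > cur
    cur[sel] <- cand[sel]
    idxm <- matrix(rep(cols, each = nrow(M)), nrow(M), no)
    amax[sel] <- idxm[sel]
  }
  list(out = cur, argmax = amax)
}

pool_feat_backward <- function(dOut, argmax, ncol_in) {
  if (is.null(argmax)) return(dOut)
  dM <- matrix(0, nrow(dOut), ncol_in)
  for (t in seq_len(ncol(dOut))) {
    tgt <- argmax[, t]
    for (u in unique(tgt)) {
      rows <- tgt == u
      dM[rows, u] <- dM[rows, u] + dOut[rows, t]
    }
  }
  dM
}

mol_forward <- function(graph, params, cfg) {
  nL <- length(cfg$gcn_widths)
  fp <- cfg$gcn_feat_pool
  H <- graph$X
  cache <- list(graph = graph)
  for (l in seq_len(nL)) {
    M <- graph$S %*% H
    Z <- M %*% params[[paste0("G", l)]]
    A <- leaky_relu(Z, cfg$leaky_slope)
    pl <- pool_feat(A, fp)
    cache[[paste0("M", l)]] <- M
    cache[[paste0("Z", l)]] <- Z
    cache[[paste0("famax", l)]] <- pl$argmax
    H <- pl$out
  }
  ro <- apply(H, 2, which.max)
  cache$ro_rows <- ro
  cache$Hfinal_ncol <- ncol(H)
  list(XM = H[cbind(ro, seq_len(ncol(H)))], cache = cache)
}

mol_backward <- function(dXM, cache, params, cfg) {
  nL <- length(cfg$gcn_widths)
  fp <- cfg$gcn_feat_pool
  graph <- cache$graph
  g <- list()
  d <- matrix(0, graph$n, cache$Hfinal_ncol)
  d[cbind(cache$ro_rows, seq_len(cache$Hfinal_ncol))] <- dXM
  for (l in rev(seq_len(nL))) {
    dA <- pool_feat_backward(d, cache[[paste0("famax", l)]],
                             ncol(cache[[paste0("Z", l)]]))
    dZ <- dA * leaky_relu_grad(cache[[paste0("Z", l)]], cfg$leaky_slope)
    g[[paste0("G", l)]] <- crossprod(cache[[paste0("M", l)]], dZ)
    if (l > 1L)
      d <- graph$S %*% (dZ %*% t(params[[paste0("G", l)]]))
  }
  g
}

# ---------------------------------------------------------------------
# head + batched forward/backward over sample pairs

# inverted dropout on the fused feature vector (training only)
head_forward <- function(X, params, cfg, dropout = 0) {
  mask <- NULL
  if (dropout > 0) {
    mask <- matrix(rbinom(length(X), 1, 1 - dropout) / (1 - dropout),
                   nrow(X), ncol(X))
    X <- X * mask
  }
  Zh <- sweep(X %*% params$Wh, 2, params$bh, "+")
  Hh <- leaky_relu(Zh, cfg$leaky_slope)
  z <- drop(Hh %*% params$wo) + params$bo
  list(p = plogis(z), Zh = Zh, Hh = Hh, mask = mask, Xd = X)
}

head_backward <- function(dz, X, cache, params, cfg) {
  dz <- matrix(dz, ncol = 1)
  g <- list(wo = crossprod(cache$Hh, dz), bo = sum(dz))
  dH <- dz %*% t(params$wo)
  dZh <- dH * leaky_relu_grad(cache$Zh, cfg$leaky_slope)
  g$Wh <- crossprod(cache$Xd, dZh)
  g$bh <- colSums(dZh)
  dX <- dZh %*% t(params$Wh)
  if (!is.null(cache$mask)) dX <- dX * cache$mask
  list(grads = g, dX = dX)
}

# featurized caches: tcache[[target_id]] = list(V, tokens, patches1);
# mcache[[ligand_id]] = mol_graph
batch_forward <- function(params, cfg, tcache, mcache, tid, mid,
                          ablate = "none", need_cache = FALSE,
                          train = FALSE) {
  ut <- unique(tid); um <- unique(mid)
  use_site <- ablate != "site"
  use_seq <- ablate != "sequence"
  use_mol <- ablate != "molecule"
  tfeat <- lapply(stats::setNames(ut, ut), function(t) {
    tc <- tcache[[t]]
    out <- list()
    if (use_site)
      out$site <- site_forward(tc$V, params$site, cfg, tc$patches1)
    if (use_seq)
      out$seq <- seq_forward(tc$tokens, params$seq, cfg)
    out
  })
  mfeat <- if (use_mol)
    lapply(stats::setNames(um, um), function(m)
      mol_forward(mcache[[m]], params$mol, cfg))
  X <- do.call(rbind, lapply(seq_along(tid), function(i) {
    fuse_features(
      if (use_site) tfeat[[tid[i]]]$site$XL,
      if (use_seq) tfeat[[tid[i]]]$seq$XG,
      if (use_mol) mfeat[[mid[i]]]$XM,
      ablate = ablate)
  }))
  lens <- c(site = if (use_site) length(tfeat[[1]]$site$XL) else 0L,
            sequence = if (use_seq) length(tfeat[[1]]$seq$XG) else 0L,
            molecule = if (use_mol) length(mfeat[[1]]$XM) else 0L)
  seg_dropped <- NULL
  if (train && cfg$modality_dropout > 0 &&
      runif(1) < cfg$modality_dropout) {
    # modality dropout: zero one whole pathway segment for this batch,
    # so no pathway can only work in combination with the others
    present <- names(lens)[lens > 0]
    seg_dropped <- sample(present, 1)
    X[, seg_cols(lens, seg_dropped)] <- 0
  }
  hf <- head_forward(X, params$head, cfg,
                     dropout = if (train) cfg$dropout else 0)
  out <- list(p = hf$p, X = X, head = hf, lens = lens,
              seg_dropped = seg_dropped)
  if (need_cache) { out$tfeat <- tfeat; out$mfeat <- mfeat }
  out
}

seg_cols <- function(lens, what) {
  ends <- cumsum(lens)
  (ends[[what]] - lens[[what]] + 1L):ends[[what]]
}

batch_backward <- function(fw, dz, params, cfg, tid, mid,
                           ablate = "none") {
  hb <- head_backward(dz, fw$X, fw$head, params$head, cfg)
  grads <- list(head = hb$grads,
                site = zero_like(params$site),
                seq = zero_like(params$seq),
                mol = zero_like(params$mol))
  lens <- fw$lens
  if (!is.null(fw$seg_dropped))
    hb$dX[, seg_cols(lens, fw$seg_dropped)] <- 0
  ends <- cumsum(lens)
  seg <- function(i, what) {
    if (lens[[what]] == 0L) return(NULL)
    hb$dX[i, (ends[[what]] - lens[[what]] + 1L):ends[[what]]]
  }
  add_grads <- function(a, b) {
    for (nm in names(b)) a[[nm]] <- a[[nm]] + b[[nm]]
    a
  }
  for (t in names(fw$tfeat)) {
    rows <- which(tid == t)
    if (ablate != "site") {
      dXL <- Reduce(`+`, lapply(rows, seg, "site"))
      grads$site <- add_grads(
        grads$site,
        site_backward(dXL, fw$tfeat[[t]]$site$cache, params$site, cfg))
    }
    if (ablate != "sequence") {
      dXG <- Reduce(`+`, lapply(rows, seg, "sequence"))
      grads$seq <- add_grads(
        grads$seq,
        seq_backward(dXG, fw$tfeat[[t]]$seq$cache, params$seq, cfg))
    }
  }
  if (ablate != "molecule") {
    for (m in names(fw$mfeat)) {
      rows <- which(mid == m)
      dXM <- Reduce(`+`, lapply(rows, seg, "molecule"))
      grads$mol <- add_grads(
        grads$mol,
        mol_backward(dXM, fw$mfeat[[m]]$cache, params$mol, cfg))
    }
  }
  grads
}

# ---------------------------------------------------------------------
# Adam

adam_init <- function(params) {
  list(m = zero_like(params), v = zero_like(params), t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  walk <- function(p, g, m, v) {
    if (is.list(p)) {
      for (nm in names(p)) {
        r <- walk(p[[nm]], g[[nm]], m[[nm]], v[[nm]])
        p[[nm]] <- r$p; m[[nm]] <- r$m; v[[nm]] <- r$v
      }
      return(list(p = p, m = m, v = v))
    }
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mh <- m / (1 - beta1^state$t)
    vh <- v / (1 - beta2^state$t)
    # decoupled (AdamW-style) weight decay
    list(p = p - lr * (mh / (sqrt(vh) + eps) + weight_decay * p),
         m = m, v = v)
  }
  r <- walk(params, grads, state$m, state$v)
  list(params = r$p, state = list(m = r$m, v = r$v, t = state$t))
}
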