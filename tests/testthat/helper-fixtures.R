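# shared fixtures, built in code at test time

# a small deterministic site-atom table covering several channels
fixture_site_atoms <- function() {
  at <- rbind(
    data.frame(element = "Zn", x = 0.5, y = 0.5, z = 0.5),
    data.frame(element = "C", x = -3, y = 2, z = 1),
    data.frame(element = "O", x = 4, y = -2, z = 0),
    data.frame(element = "N", x = 1, y = 6, z = -5)
  )
  at$vdw <- vdw_radius(at$element)
  fl <- rbind(
    assign_channels("Zn"),
    assign_channels("C", polar_neighbors = 0),
    assign_channels("O", bonded_h = 0),
    assign_channels("N", bonded_h = 2, lone_pair = FALSE)
  )
  cbind(at, as.data.frame(fl + 0L))
}

# brute-force grid oracle: independent of build_site_grid's internals
oracle_grid <- function(atoms, center, edge = 30, resolution = 1) {
  n <- edge / resolution
  ax <- lapply(1:3, function(d)
    center[d] + ((0:(n - 1)) + 0.5 - n / 2) * resolution)
  flags <- as.matrix(atoms[, channel_names()]) != 0
  g <- array(0, c(8, n, n, n))
  for (a in seq_len(nrow(atoms))) {
    for (ix in 1:n) for (iy in 1:n) for (iz in 1:n) {
      r <- sqrt((ax[[1]][ix] - atoms$x[a])^2 +
                  (ax[[2]][iy] - atoms$y[a])^2 +
                  (ax[[3]][iz] - atoms$z[a])^2)
      o <- 1 - exp(-(atoms$vdw[a] / max(r, 1e-12))^12)
      if (r == 0) o <- 1
      for (cc in which(flags[a, ]))
        g[cc, ix, iy, iz] <- max(g[cc, ix, iy, iz], o)
    }
  }
  g
}

# brute-force 1D convolution per the flipped-kernel update
oracle_conv1d <- function(s, kernel, bias) {
  d <- nrow(s); L <- ncol(s); N <- dim(kernel)[2]; Fk <- dim(kernel)[3]
  out <- matrix(0, Fk, L - N + 1)
  for (f in seq_len(Fk))
    for (k in N:L) {
      acc <- bias[f]
      for (j in 0:(N - 1))
        for (cc in seq_len(d))
          acc <- acc + s[cc, k - j] * kernel[cc, j + 1, f]
      out[f, k - N + 1] <- acc
    }
  out
}

# brute-force 3D convolution: six nested loops over Eq-style offsets
oracle_conv3d <- function(cube, kernel, bias) {
  d <- dim(cube); kd <- dim(kernel)
  no <- d[2:4] - kd[1:3] + 1
  out <- array(0, c(kd[5], no))
  for (f in seq_len(kd[5]))
    for (x in seq_len(no[1])) for (y in seq_len(no[2]))
      for (z in seq_len(no[3])) {
        acc <- bias[f]
        for (m in seq_len(d[1]))
          for (i in 0:(kd[1] - 1))
            for (j in 0:(kd[2] - 1))
              for (k in 0:(kd[3] - 1))
                acc <- acc + kernel[i + 1, j + 1, k + 1, m, f] *
                  cube[m, x + i, y + j, z + k]
        out[f, x, y, z] <- acc
      }
  out
}

# dense-matrix oracle for the normalized graph convolution
oracle_gcn <- function(A, H, W) {
  n <- nrow(A)
  At <- A + diag(n)
  D <- diag(rowSums(At))
  Dn <- diag(1 / sqrt(diag(D)))
  Dn %*% At %*% Dn %*% H %*% W
}

# brute-force AUC: concordant-pair counting with half ties
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  s <- 0
  for (p in pos) for (q in neg)
    s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}
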