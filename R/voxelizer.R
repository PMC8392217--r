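#' Occupancy of a single atom at distance r
#'
#' Soft occupancy used to paint atoms into the voxel grid:
#' \deqn{n(r) = 1 - \exp(-(r_{vdw}/r)^{12})}
#' where \eqn{r_{vdw}} is the Van der Waals radius. The value is 1 at
#' r = 0 (continuity limit), strictly decreasing in r, and falls below
#' 1e-7 beyond roughly \eqn{r_{vdw} + 5} \ifelse{html}{\out{&Aring;}}{A}.
#'
#' @param r distance in \ifelse{html}{\out{&Aring;}}{A}; non-negative,
#'   recycled against `rvdw`.
#' @param rvdw Van der Waals radius in \ifelse{html}{\out{&Aring;}}{A};
#'   strictly positive.
#' @return Occupancy values in `[0, 1]`.
#' @examples
#' occupancy(1.7, 1.7)      # 1 - exp(-1)
#' occupancy(0, 1.5)        # 1
#' @export
occupancy <- function(r, rvdw) {
  if (any(!is.finite(r)) || any(r < 0))
    stop("r must be finite and non-negative", call. = FALSE)
  if (any(!is.finite(rvdw)) || any(rvdw <= 0))
    stop("rvdw must be finite and positive", call. = FALSE)
  out <- 1 - exp(-(rvdw / r)^12)
  out[r == 0] <- 1
  out
}

#' Geometric center of a point set
#'
#' Arithmetic centroid used to place the binding-site box: the centroid
#' of the bound ligand's atoms when available, otherwise of the site
#' atoms themselves.
#'
#' @param points numeric matrix or data frame with columns x, y, z (or
#'   three unnamed columns), one row per point.
#' @return Numeric vector `c(x, y, z)`.
#' @examples
#' site_center(rbind(c(0, 0, 0), c(2, 0, 0)))
#' @export
site_center <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) == 0) stop("empty point list", call. = FALSE)
  if (ncol(points) != 3) {
    cn <- colnames(points)
    if (all(c("x", "y", "z") %in% cn)) points <- points[, c("x", "y", "z")]
    else stop("points must have 3 coordinate columns", call. = FALSE)
  }
  storage.mode(points) <- "double"
  colMeans(points)
}

#' Grid geometry of the binding-site box
#'
#' An axis-aligned cubic box centered on `center`. Voxel centers lie at
#' `center + (i + 0.5 - n/2) * resolution` per axis for
#' `i = 0, ..., n-1` with `n = edge / resolution`.
#'
#' @param center box center `c(x, y, z)` in
#'   \ifelse{html}{\out{&Aring;}}{A}.
#' @param edge edge length (default 30).
#' @param resolution voxel size (default 1).
#' @return List of class `"grid_spec"` with `center`, `edge`,
#'   `resolution`, `n` (voxels per axis) and `axis` (a function giving
#'   voxel-center coordinates along one axis).
#' @export
grid_spec <- function(center = c(0, 0, 0), edge = 30, resolution = 1) {
  stopifnot(length(center) == 3, all(is.finite(center)),
            edge > 0, resolution > 0)
  n <- edge / resolution
  if (abs(n - round(n)) > 1e-9)
    stop("edge must be an integer multiple of resolution", call. = FALSE)
  n <- as.integer(round(n))
  spec <- list(center = as.numeric(center), edge = edge,
               resolution = resolution, n = n)
  spec$axis <- function(d) spec$center[d] +
    ((0:(n - 1L)) + 0.5 - n / 2) * resolution
  class(spec) <- "grid_spec"
  spec
}

#' Voxelize binding-site atoms into the 8-channel occupancy grid
#'
#' Builds the local binding-site descriptor: a cubic box (default 30 x
#' 30 x 30 \ifelse{html}{\out{&Aring;}}{A} at 1
#' \ifelse{html}{\out{&Aring;}}{A} resolution) around the site, with
#' one occupancy layer per pharmacophoric channel. For each channel,
#' each voxel holds the maximum over that channel's atoms of
#' [occupancy()] evaluated at the atom-to-voxel-center distance. Atoms
#' outside the box still contribute to voxels inside it. Atoms farther
#' than `rvdw * occ_tol^(-1/12)` from a voxel center contribute 0:
#' their occupancy is below `occ_tol`, so truncation is numerically
#' invisible at the default tolerance.
#'
#' @param atoms data frame of site atoms with columns `element`, `x`,
#'   `y`, `z`, optionally `vdw` (radius; filled from [vdw_radius()]
#'   when absent) and the eight 0/1 channel columns named as
#'   [channel_names()]. When channel columns are absent they are
#'   derived from the element alone via [assign_channels()].
#' @param center box center; default the centroid of the atoms
#'   ([site_center()]). Pass the bound ligand's centroid when known.
#' @param spec a [grid_spec()]; overrides `center`/`edge`/`resolution`.
#' @param edge,resolution box geometry when `spec` is not given.
#' @param occ_tol occupancy values below this are treated as zero,
#'   bounding each atom's reach (default 1e-12).
#' @return Numeric array of shape `(channels, n, n, n)` with values in
#'   `[0, 1]` and attributes `spec` (the [grid_spec()]) and `channels`
#'   (channel names). Empty `atoms` gives an all-zero grid.
#' @examples
#' at <- data.frame(element = "Zn", x = 0, y = 0, z = 0)
#' g <- build_site_grid(at, center = c(0, 0, 0))
#' dim(g)
#' @export
build_site_grid <- function(atoms, center = NULL, spec = NULL,
                            edge = 30, resolution = 1,
                            occ_tol = 1e-12) {
  if (is.null(spec)) {
    if (is.null(center)) {
      if (nrow(atoms) == 0) center <- c(0, 0, 0)
      else center <- site_center(atoms[, c("x", "y", "z")])
    }
    spec <- grid_spec(center, edge, resolution)
  }
  n <- spec$n
  nch <- length(CHANNEL_NAMES)
  grid <- array(0, dim = c(nch, n, n, n),
                dimnames = list(CHANNEL_NAMES, NULL, NULL, NULL))
  attr(grid, "spec") <- spec[c("center", "edge", "resolution", "n")]
  attr(grid, "channels") <- CHANNEL_NAMES
  if (is.null(atoms) || nrow(atoms) == 0) return(grid)
  stopifnot(all(c("element", "x", "y", "z") %in% names(atoms)))
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  storage.mode(xyz) <- "double"
  if (any(!is.finite(xyz))) stop("non-finite atom coordinates", call. = FALSE)
  rv <- if ("vdw" %in% names(atoms)) as.numeric(atoms$vdw)
        else vdw_radius(atoms$element)
  if (any(!is.finite(rv)) || any(rv <= 0))
    stop("vdw radii must be positive", call. = FALSE)
  flags <- site_atom_flags(atoms)
  ax <- lapply(1:3, spec$axis)
  for (a in seq_len(nrow(atoms))) {
    ch <- which(flags[a, ])
    if (!length(ch)) next
    reach <- rv[a] * occ_tol^(-1 / 12)
    sub <- lapply(1:3, function(d) {
      which(abs(ax[[d]] - xyz[a, d]) <= reach)
    })
    if (any(lengths(sub) == 0)) next
    dx2 <- (ax[[1]][sub[[1]]] - xyz[a, 1])^2
    dy2 <- (ax[[2]][sub[[2]]] - xyz[a, 2])^2
    dz2 <- (ax[[3]][sub[[3]]] - xyz[a, 3])^2
    d2 <- outer(outer(dx2, dy2, "+"), dz2, "+")   # |sub1| x |sub2| x |sub3|
    occ <- occupancy(sqrt(as.vector(d2)), rv[a])
    for (cc in ch) {
      cur <- grid[cc, sub[[1]], sub[[2]], sub[[3]]]
      grid[cc, sub[[1]], sub[[2]], sub[[3]]] <- pmax(as.vector(cur), occ)
    }
  }
  grid
}

# channel flag matrix (atoms x 8) from explicit columns or element-only
# typing
site_atom_flags <- function(atoms) {
  have <- all(CHANNEL_NAMES %in% names(atoms))
  if (have) {
    m <- as.matrix(atoms[, CHANNEL_NAMES]) != 0
  } else {
    m <- t(vapply(atoms$element, function(e)
      suppressWarnings(assign_channels(e)), logical(8L)))
  }
  colnames(m) <- CHANNEL_NAMES
  m
}

#' Read a site-atom table
#'
#' Plain TSV with columns `element`, `x`, `y`, `z` and optionally
#' `vdw` plus the eight 0/1 channel columns ([channel_names()]).
#'
#' @param path file path.
#' @return Data frame of site atoms suitable for [build_site_grid()].
#' @export
read_site_atoms <- function(path) {
  at <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("element", "x", "y", "z")
  miss <- setdiff(need, names(at))
  if (length(miss))
    stop("site-atom table ", path, " lacks column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  at
}

#' Write a site-atom table
#'
#' @param atoms data frame of site atoms.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_site_atoms <- function(atoms, path) {
  utils::write.table(atoms, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Extract binding-site atoms from a PDB file
#'
#' Reads ATOM/HETATM records with \pkg{bio3d} restricted to a residue
#' selection, types each protein heavy atom with the bundled
#' residue/atom-name rule table, and flags HETATM metals. Hydrogens are
#' dropped (their contribution is carried by the donor flags of their
#' heavy-atom partners).
#'
#' @param path PDB file.
#' @param resno optional integer vector of residue numbers to keep
#'   (the binding-site selection); default keeps everything.
#' @param chain optional chain identifier(s) to keep.
#' @return Site-atom data frame with channel flag columns.
#' @export
read_site_pdb <- function(path, resno = NULL, chain = NULL) {
  pdb <- bio3d::read.pdb(path)
  at <- pdb$atom
  keep <- rep(TRUE, nrow(at))
  if (!is.null(resno)) keep <- keep & at$resno %in% resno
  if (!is.null(chain)) keep <- keep & at$chain %in% chain
  at <- at[keep, , drop = FALSE]
  el <- at$elesy
  if (is.null(el) || all(is.na(el)) || all(el == ""))
    el <- substr(gsub("[^A-Za-z].*$", "", at$elety), 1, 2)
  el <- paste0(toupper(substr(el, 1, 1)), tolower(substr(el, 2, 2)))
  el <- trimws(el)
  at <- at[el != "H", , drop = FALSE]
  el <- el[el != "H"]
  n <- nrow(at)
  fl <- matrix(FALSE, n, 8L, dimnames = list(NULL, CHANNEL_NAMES))
  for (i in seq_len(n)) {
    if (el[i] %in% METAL_ELEMENTS) {
      fl[i, ] <- assign_channels(el[i])
    } else if (at$resid[i] %in% names(AA3_TO_1)) {
      ctx <- protein_atom_context(at$resid[i], at$elety[i])
      fl[i, ] <- suppressWarnings(assign_channels(
        ctx$element, aromatic = ctx$aromatic,
        polar_neighbors = ctx$polar_neighbors, bonded_h = ctx$bonded_h,
        lone_pair = ctx$lone_pair, ionizable = ctx$ionizable))
    } else {
      fl[i, ] <- suppressWarnings(assign_channels(el[i]))
    }
  }
  out <- data.frame(element = el, x = at$x, y = at$y, z = at$z,
                    vdw = vdw_radius(el), stringsAsFactors = FALSE)
  cbind(out, as.data.frame(fl + 0L))
}

#' Write / read a grid container
#'
#' Grids are stored as a chunked binary file of doubles (one chunk per
#' grid, channel-major, in the array's native order) with a JSON
#' sidecar (`<path>.json`) holding the grid geometry, the channel
#' names and the grid ids.
#'
#' @param grids named list of grids from [build_site_grid()].
#' @param path output path of the binary container.
#' @return `path`, invisibly (`write_grids`); named list of grids
#'   (`read_grids`).
#' @export
write_grids <- function(grids, path) {
  stopifnot(length(grids) > 0, !is.null(names(grids)))
  d <- dim(grids[[1]])
  con <- file(path, "wb")
  on.exit(close(con))
  for (g in grids) {
    stopifnot(identical(dim(g), d))
    writeBin(as.vector(g), con, size = 8, endian = "little")
  }
  spec <- attr(grids[[1]], "spec")
  sidecar <- list(ids = names(grids), dim = d,
                  channels = attr(grids[[1]], "channels"),
                  spec = spec)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_grids
#' @export
read_grids <- function(path) {
  sidecar <- jsonlite::read_json(paste0(path, ".json"),
                                 simplifyVector = TRUE)
  d <- as.integer(sidecar$dim)
  nval <- prod(d)
  con <- file(path, "rb")
  on.exit(close(con))
  out <- lapply(sidecar$ids, function(id) {
    v <- readBin(con, "double", n = nval, size = 8, endian = "little")
    g <- array(v, dim = d)
    dimnames(g) <- list(sidecar$channels, NULL, NULL, NULL)
    attr(g, "spec") <- sidecar$spec
    attr(g, "channels") <- sidecar$channels
    g
  })
  names(out) <- sidecar$ids
  out
}
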