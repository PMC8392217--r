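#' @name molgraph
#' @title Molecular graph pathway
#' @description A molecule is a graph G = (V, E): one node per heavy
#' atom, one edge per chemical bond. Each node carries a 73-dimensional
#' binary feature vector made of five one-hot blocks (atom type over 44
#' symbols ending in a catch-all X, degree 0-5, hydrogen count 0-10,
#' implicit hydrogen count 0-10, and an aromatic flag). Propagation
#' uses the symmetric-normalized adjacency with self-loops,
#' \deqn{H^{(l+1)} = \sigma(\tilde D^{-1/2} \tilde A \tilde D^{-1/2}
#' H^{(l)} W^{(l)}),} followed by feature-space max pooling per layer
#' and a global max readout over nodes.
#' @keywords internal
NULL

ATOM_TYPES <- c("C", "N", "O", "S", "F", "Si", "P", "Cl", "Br", "Mg",
                "Na", "Ca", "Fe", "As", "Al", "I", "B", "V", "K", "Tl",
                "Yb", "Sb", "Sn", "Ag", "Pd", "Co", "Se", "Ti", "Zn",
                "H", "Li", "Ge", "Cu", "Au", "Ni", "Cd", "In", "Mn",
                "Zr", "Cr", "Pt", "Hg", "Pb", "X")

ATOM_FEATURE_DIM <- 44L + 6L + 11L + 11L + 1L   # = 73

#' One-hot atom feature vector
#'
#' Encodes one heavy atom as the concatenation of five one-hot blocks:
#' atom type (44 symbols, unknown elements map to the terminal X),
#' heavy-atom degree (0-5), hydrogen count (0-10), implicit hydrogen
#' count (0-10) and an aromatic flag -- 73 dimensions in total.
#' Degrees above 5 and hydrogen counts above 10 are clamped to the last
#' bucket with a warning.
#'
#' @param element element symbol.
#' @param degree number of heavy-atom neighbors.
#' @param n_h number of hydrogens on the atom.
#' @param n_implicit_h number of implicit hydrogens on the atom.
#' @param aromatic is the atom aromatic?
#' @return Binary numeric vector of length 73.
#' @examples
#' f <- featurize_atom("C", degree = 0, n_h = 4, n_implicit_h = 4)
#' sum(f)   # 4 ones: atom type, degree, H count, implicit H count
#' @export
featurize_atom <- function(element, degree, n_h, n_implicit_h,
                           aromatic = FALSE) {
  one_hot <- function(i, n) { v <- numeric(n); v[i] <- 1; v }
  ti <- match(element, ATOM_TYPES)
  if (is.na(ti)) ti <- length(ATOM_TYPES)       # catch-all X
  clamp <- function(v, hi, what) {
    if (v > hi) {
      warning(what, " ", v, " clamped to ", hi, call. = FALSE)
      v <- hi
    }
    if (v < 0) stop(what, " must be non-negative", call. = FALSE)
    v
  }
  degree <- clamp(degree, 5L, "degree")
  n_h <- clamp(n_h, 10L, "H count")
  n_implicit_h <- clamp(n_implicit_h, 10L, "implicit H count")
  c(one_hot(ti, 44L),
    one_hot(degree + 1L, 6L),
    one_hot(n_h + 1L, 11L),
    one_hot(n_implicit_h + 1L, 11L),
    as.numeric(isTRUE(aromatic)))
}

# ---------------------------------------------------------------------
# SMILES -> atom/bond tables via openbabel (ChemmineOB), MOL2 output
# with hydrogens added so per-atom H counts are explicit and aromatic
# atoms carry the .ar type suffix. Batched: one conversion for many
# molecules, matched back by title.
parse_smiles <- function(smiles, ids = names(smiles)) {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  if (is.null(ids)) ids <- paste0("mol", seq_along(smiles))
  src <- paste0(paste(smiles, ids, sep = "\t"), "\n", collapse = "")
  out <- tryCatch(
    ChemmineOB::convertFormat(
      "SMI", "MOL2", source = src,
      options = data.frame(names = "h", args = "",
                           stringsAsFactors = FALSE)),
    error = function(e) stop("SMILES conversion failed: ",
                             conditionMessage(e), call. = FALSE))
  blocks <- strsplit(out, "@<TRIPOS>MOLECULE", fixed = TRUE)[[1]]
  blocks <- blocks[nzchar(trimws(blocks))]
  parsed <- lapply(blocks, parse_mol2_block)
  names(parsed) <- vapply(parsed, `[[`, "", "id")
  missing <- setdiff(ids, names(parsed))
  if (length(missing))
    stop("unparseable SMILES for id(s): ",
         paste(missing, collapse = ", "), " (input: ",
         paste(smiles[match(missing, ids)], collapse = " ; "), ")",
         call. = FALSE)
  parsed[ids]
}

parse_mol2_block <- function(block) {
  lines <- strsplit(block, "\n", fixed = TRUE)[[1]]
  id <- trimws(lines[2])
  ai <- grep("^@<TRIPOS>ATOM", lines)
  bi <- grep("^@<TRIPOS>BOND", lines)
  sect_end <- function(start) {
    nxt <- grep("^@<TRIPOS>", lines)
    nxt <- nxt[nxt > start]
    if (length(nxt)) nxt[1] - 1L else length(lines)
  }
  atom_lines <- lines[(ai + 1L):sect_end(ai)]
  atom_lines <- atom_lines[nzchar(trimws(atom_lines))]
  af <- strsplit(trimws(atom_lines), "[[:space:]]+")
  elem <- vapply(af, `[[`, "", 2)
  type <- vapply(af, `[[`, "", 6)
  elem <- sub("[0-9]+$", "", elem)
  aromatic <- grepl("\\.ar$", type)
  bonds <- matrix(integer(0), 0, 2)
  if (length(bi)) {
    bl <- lines[(bi + 1L):sect_end(bi)]
    bl <- bl[nzchar(trimws(bl))]
    if (length(bl)) {
      bf <- strsplit(trimws(bl), "[[:space:]]+")
      bonds <- cbind(as.integer(vapply(bf, `[[`, "", 2)),
                     as.integer(vapply(bf, `[[`, "", 3)))
    }
  }
  list(id = id, element = elem, aromatic = aromatic, bonds = bonds)
}

#' Build a molecular graph from SMILES
#'
#' Parses the SMILES with openbabel, drops hydrogens (the heavy-atom
#' graph; hydrogen counts become node attributes), and assembles the
#' Table-style node feature matrix together with the adjacency matrix,
#' its self-loop form and the symmetric-normalized propagation
#' operator.
#'
#' @param smiles SMILES string (one molecule).
#' @param id optional molecule identifier.
#' @return Object of class `"mol_graph"`: a list with `n` (heavy
#'   atoms), `atoms` (data frame: element, degree, n_h, aromatic), `X`
#'   (`n x 73` feature matrix), `A` (symmetric 0/1 adjacency, zero
#'   diagonal), `A_tilde` (`A + I`), `deg` (self-loop degrees
#'   \eqn{\tilde D_{ii}}) and `S` (the normalized operator
#'   \eqn{\tilde D^{-1/2}\tilde A\tilde D^{-1/2}}).
#' @examples
#' \dontrun{
#' g <- mol_graph("c1ccccc1")   # benzene: 6 nodes, ring degrees 2
#' g$deg                        # all 3 with the self-loop
#' }
#' @export
mol_graph <- function(smiles, id = "mol") {
  p <- parse_smiles(smiles, id)[[1]]
  mol_graph_from_parsed(p)
}

mol_graph_from_parsed <- function(p) {
  heavy <- which(p$element != "H")
  n <- length(heavy)
  if (n == 0) stop("molecule has no heavy atoms", call. = FALSE)
  idx <- match(seq_along(p$element), heavy)   # old -> new index or NA
  A <- matrix(0, n, n)
  n_h <- integer(n)
  if (nrow(p$bonds)) for (b in seq_len(nrow(p$bonds))) {
    i <- p$bonds[b, 1]; j <- p$bonds[b, 2]
    hi <- p$element[i] == "H"; hj <- p$element[j] == "H"
    if (hi && hj) next
    if (hi) n_h[idx[j]] <- n_h[idx[j]] + 1L
    else if (hj) n_h[idx[i]] <- n_h[idx[i]] + 1L
    else { A[idx[i], idx[j]] <- 1; A[idx[j], idx[i]] <- 1 }
  }
  degree <- as.integer(rowSums(A))
  atoms <- data.frame(element = p$element[heavy], degree = degree,
                      n_h = n_h, aromatic = p$aromatic[heavy],
                      stringsAsFactors = FALSE)
  X <- t(mapply(featurize_atom, atoms$element, atoms$degree,
                atoms$n_h, atoms$n_h, atoms$aromatic))
  dimnames(X) <- NULL
  X <- matrix(as.numeric(X), n, ATOM_FEATURE_DIM)
  At <- A + diag(n)
  dg <- rowSums(At)
  S <- At * tcrossprod(1 / sqrt(dg))
  structure(list(id = p$id, n = n, atoms = atoms, X = X, A = A,
                 A_tilde = At, deg = dg, S = S),
            class = "mol_graph")
}

#' @export
print.mol_graph <- function(x, ...) {
  cat(sprintf("<mol_graph '%s': %d heavy atoms, %d bonds, %d aromatic>\n",
              x$id, x$n, sum(x$A) / 2, sum(x$atoms$aromatic)))
  invisible(x)
}

#' One graph-convolution layer
#'
#' Applies \eqn{\sigma(\tilde D^{-1/2}\tilde A\tilde D^{-1/2} H W)} for
#' a graph built by [mol_graph()].
#'
#' @param H node features, `n x d` matrix.
#' @param graph a `"mol_graph"`.
#' @param W weight matrix `d x d_out`.
#' @param act activation function applied elementwise (default
#'   identity).
#' @return Matrix `n x d_out`.
#' @export
gcn_layer <- function(H, graph, W, act = identity) {
  stopifnot(inherits(graph, "mol_graph"))
  H <- as.matrix(H)
  if (nrow(H) != graph$n)
    stop("H has ", nrow(H), " rows but the graph has ", graph$n,
         " nodes", call. = FALSE)
  if (ncol(H) != nrow(W))
    stop("feature dimension ", ncol(H), " does not match weight rows ",
         nrow(W), call. = FALSE)
  act(graph$S %*% H %*% W)
}

#' Global max readout over nodes
#'
#' Collapses node features to a fixed-length molecular feature by
#' taking the maximum over nodes per feature dimension; invariant to
#' node order and to duplicated nodes.
#'
#' @param H node features, `n x d` matrix with `n >= 1`.
#' @return Numeric vector of length `d`.
#' @export
mol_readout <- function(H) {
  H <- as.matrix(H)
  if (nrow(H) == 0) stop("empty graph: nothing to read out", call. = FALSE)
  apply(H, 2, max)
}

#' Read a SMILES list file
#'
#' One molecule per line: identifier, whitespace, SMILES. Lines
#' starting with `#` are ignored.
#'
#' @param path file path.
#' @return Named character vector of SMILES (names = ids).
#' @export
read_smiles_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "[[:space:]]+")
  bad <- which(lengths(parts) < 2)
  if (length(bad))
    stop("malformed SMILES line(s) in ", path, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  stats::setNames(vapply(parts, `[[`, "", 2),
                  vapply(parts, `[[`, "", 1))
}

#' Write a SMILES list file
#'
#' @param smiles named character vector (names = ids).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_smiles_file <- function(smiles, path) {
  writeLines(paste(names(smiles), smiles, sep = "\t"), path)
  invisible(path)
}
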