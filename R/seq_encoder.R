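#' @name seq-encoder
#' @title Global protein feature from the amino-acid sequence
#' @description The global pathway treats the protein's primary
#' structure like text: the sequence is tokenized over the 20 standard
#' amino acids (padding index 0), fixed to 1000 positions by zero-fill
#' or truncation, embedded into a 128 x 1000 matrix, and passed through
#' three 1D convolutional blocks (convolution, LeakyReLU, max pooling)
#' whose flattened output is the global feature vector.
#' @keywords internal
NULL

AA_LETTERS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA3_TO_1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
              GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
              LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
              SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")

#' Amino-acid vocabulary
#'
#' @return Character vector of the 20 standard one-letter codes, in
#'   token-index order (token i is `aa_vocabulary()[i]`; 0 is padding).
#' @export
aa_vocabulary <- function() AA_LETTERS

#' Tokenize an amino-acid sequence
#'
#' Maps each residue to its index in [aa_vocabulary()] (1-20), pads
#' with 0 up to `max_len` and truncates beyond it, so every protein is
#' represented by exactly `max_len` tokens. Letters outside the
#' 20-letter alphabet (B, J, O, U, X, Z, ...) map to the padding index
#' with a warning.
#'
#' @param sequence character scalar of one-letter residue codes.
#' @param max_len fixed token length (default 1000).
#' @return Integer vector of length `max_len` with values in 0..20.
#' @examples
#' head(tokenize_sequence("MKVLA"), 8)
#' @export
tokenize_sequence <- function(sequence, max_len = 1000L) {
  stopifnot(is.character(sequence), length(sequence) == 1, max_len >= 1)
  chars <- strsplit(toupper(sequence), "")[[1]]
  if (length(chars) > max_len) chars <- chars[seq_len(max_len)]
  tok <- match(chars, AA_LETTERS)
  if (anyNA(tok) && length(chars)) {
    bad <- unique(chars[is.na(tok)])
    warning("unknown residue letter(s) mapped to padding: ",
            paste(bad, collapse = ", "), call. = FALSE)
    tok[is.na(tok)] <- 0L
  }
  out <- integer(max_len)
  out[seq_along(tok)] <- tok
  out
}

#' Embed a tokenized sequence
#'
#' Looks up each token in an embedding table; column i of the result
#' depends only on token i. Row 1 of the table corresponds to the
#' padding token, rows 2..21 to amino acids 1..20.
#'
#' @param tokens integer vector from [tokenize_sequence()].
#' @param table numeric matrix `(vocab + 1) x embed_dim`, row 1 =
#'   padding.
#' @return Matrix `embed_dim x length(tokens)` (embedding dimension by
#'   position).
#' @export
embed_sequence <- function(tokens, table) {
  stopifnot(is.numeric(tokens), all(tokens >= 0),
            all(tokens <= nrow(table) - 1))
  t(table[tokens + 1L, , drop = FALSE])
}

#' 1D convolution over a feature sequence
#'
#' One pre-activation convolutional layer of the sequence pathway. The
#' update at output position k is
#' \deqn{s^{(l+1)}_k = \sum_{j=0}^{N-1} s^{(l)}(k-j) \cdot w_j + b,}
#' i.e. a true (flipped-kernel) convolution over the valid positions
#' `k = N, ..., L`; output length is `L - N + 1`.
#'
#' @param s input features, matrix `d x L` (feature dimension by
#'   position) or a numeric vector (treated as `1 x L`).
#' @param kernel numeric array `d x N x F` (input dim, kernel size,
#'   filters); a matrix is treated as a single filter; a vector as a
#'   `1 x N x 1` kernel.
#' @param bias numeric vector of length `F` (default zeros).
#' @return Matrix `F x (L - N + 1)` of pre-activation outputs.
#' @examples
#' conv1d(c(1, 2, 3, 4), c(1, 0, 0))   # delta kernel: identity, shifted
#' @export
conv1d <- function(s, kernel, bias = NULL) {
  if (is.vector(s)) s <- matrix(s, nrow = 1)
  if (is.vector(kernel)) kernel <- array(kernel, c(1, length(kernel), 1))
  if (is.matrix(kernel)) kernel <- array(kernel, c(dim(kernel), 1))
  d <- nrow(s); L <- ncol(s)
  stopifnot(dim(kernel)[1] == d)
  N <- dim(kernel)[2]; Fk <- dim(kernel)[3]
  if (is.null(bias)) bias <- numeric(Fk)
  stopifnot(length(bias) == Fk)
  if (L < N)
    stop("input length ", L, " shorter than kernel size ", N,
         call. = FALSE)
  # patches: (L-N+1) x (d*N); offset j uses input position k-j
  Lout <- L - N + 1L
  P <- matrix(0, Lout, d * N)
  for (j in 0:(N - 1L)) {
    cols <- j * d + seq_len(d)
    P[, cols] <- t(s[, (N - j):(L - j), drop = FALSE])
  }
  W <- matrix(kernel, d * N, Fk)     # (d, N) unrolled: d fastest
  out <- P %*% W
  out <- sweep(out, 2, bias, "+")
  t(out)
}
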