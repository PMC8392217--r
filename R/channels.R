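#' @name channels
#' @title Pharmacophoric channel typing
#'
#' @description The binding-site descriptor separates atoms into eight
#' property channels: hydrophobic, aromatic, hydrogen-bond acceptor,
#' hydrogen-bond donor, positive ionizable, negative ionizable, metal
#' and excluded volume. The typing rule used here is an explicit table
#' keyed on the element plus a little bonded context, so grids are
#' reproducible without any external typing software:
#'
#' \itemize{
#'   \item metal: element in the metal list (Zn, Mg, Ca, Fe, Mn, Cu,
#'     Ni, Co, Na, K, Li, Cd, Hg) -- metal + excluded volume only;
#'   \item hydrophobic: C or S with no polar (N/O) neighbor;
#'   \item aromatic: member of an aromatic ring;
#'   \item h-bond acceptor: N or O carrying a lone pair;
#'   \item h-bond donor: N or O bonded to at least one hydrogen;
#'   \item positive/negative ionizable: atoms of standard protonatable
#'     (amine, guanidinium, imidazolium) or deprotonatable (carboxylate,
#'     phosphate, sulfonate) groups, supplied as context;
#'   \item excluded volume: every heavy atom.
#' }
#' @keywords internal
NULL

CHANNEL_NAMES <- c("hydrophobic", "aromatic", "acceptor", "donor",
                   "positive", "negative", "metal", "excluded")

METAL_ELEMENTS <- c("Zn", "Mg", "Ca", "Fe", "Mn", "Cu", "Ni", "Co",
                    "Na", "K", "Li", "Cd", "Hg")

#' Channel names of the site descriptor
#'
#' @return Character vector of the eight channel names, in grid order.
#' @export
channel_names <- function() CHANNEL_NAMES

#' Van der Waals radii
#'
#' Bundled per-element radius table (Bondi-style values, in
#' \ifelse{html}{\out{&Aring;}}{A}) used by the occupancy computation.
#'
#' @param element character vector of element symbols.
#' @param table optional named numeric vector overriding the bundled
#'   radii.
#' @param default radius used for elements absent from the table.
#' @return Numeric vector of radii.
#' @examples
#' vdw_radius(c("C", "N", "Zn"))
#' @export
vdw_radius <- function(element, table = NULL, default = 1.7) {
  tab <- c(
    H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
    F = 1.47, Cl = 1.75, Br = 1.85, I = 1.98, B = 1.92, Se = 1.90,
    Si = 2.10, Zn = 1.39, Mg = 1.73, Ca = 2.31, Fe = 2.05, Mn = 2.05,
    Cu = 1.40, Ni = 1.63, Co = 2.00, Na = 2.27, K = 2.75, Li = 1.82,
    Cd = 1.58, Hg = 1.55
  )
  if (!is.null(table)) tab[names(table)] <- table
  r <- unname(tab[element])
  r[is.na(r)] <- default
  r
}

#' Assign pharmacophoric channel flags to a site atom
#'
#' Deterministic rule table mapping an element plus simple bonded
#' context onto the eight binding-site channels (see
#' \link{channels}). Metals carry only the metal and excluded-volume
#' flags; every recognized heavy atom carries excluded volume.
#'
#' @param element element symbol ("C", "N", "O", "S", "Zn", ...).
#' @param aromatic is the atom part of an aromatic ring?
#' @param polar_neighbors number of N/O atoms bonded to it (controls
#'   the hydrophobic rule for C/S).
#' @param bonded_h number of hydrogens bonded to it (donor rule).
#' @param lone_pair does an N/O atom carry a lone pair (acceptor rule)?
#'   Defaults to `TRUE` for O and N, the common case.
#' @param ionizable `"none"`, `"positive"` or `"negative"` for atoms of
#'   standard protonatable/deprotonatable groups.
#' @return Named logical vector of length 8, one flag per channel.
#' @examples
#' assign_channels("Zn")
#' assign_channels("C", polar_neighbors = 0)
#' assign_channels("O", bonded_h = 0)     # carbonyl-type acceptor
#' @export
assign_channels <- function(element, aromatic = FALSE,
                            polar_neighbors = 0L, bonded_h = 0L,
                            lone_pair = element %in% c("N", "O"),
                            ionizable = c("none", "positive", "negative")) {
  ionizable <- match.arg(ionizable)
  fl <- stats::setNames(rep(FALSE, 8L), CHANNEL_NAMES)
  known <- element %in% c(METAL_ELEMENTS, "C", "N", "O", "S", "P", "F",
                          "Cl", "Br", "I", "B", "Se", "Si")
  fl["excluded"] <- TRUE               # every heavy atom
  if (!known) {
    warning("unrecognized element '", element,
            "': excluded-volume flags only", call. = FALSE)
    return(fl)
  }
  if (element %in% METAL_ELEMENTS) {
    fl["metal"] <- TRUE
    return(fl)                         # metals get no organic flags
  }
  if (element %in% c("C", "S") && polar_neighbors == 0L)
    fl["hydrophobic"] <- TRUE
  if (aromatic) fl["aromatic"] <- TRUE
  if (element %in% c("N", "O")) {
    if (isTRUE(lone_pair)) fl["acceptor"] <- TRUE
    if (bonded_h > 0L) fl["donor"] <- TRUE
  }
  if (ionizable == "positive") fl["positive"] <- TRUE
  if (ionizable == "negative") fl["negative"] <- TRUE
  fl
}

# ---------------------------------------------------------------------
# Residue/atom-name typing for standard amino acids, used by the PDB
# reader. Returns the context arguments of assign_channels() for one
# protein heavy atom. Backbone: N is a donor (except proline), O an
# acceptor. Side chains follow standard pharmacophore assignments.
protein_atom_context <- function(resid, atom_name) {
  resid <- toupper(resid); a <- toupper(atom_name)
  ctx <- list(aromatic = FALSE, polar_neighbors = 0L, bonded_h = 0L,
              lone_pair = FALSE, ionizable = "none")
  aromatic_atoms <- list(
    PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
    TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
    TRP = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2"),
    HIS = c("CG", "ND1", "CD2", "CE1", "NE2")
  )
  if (!is.null(aromatic_atoms[[resid]]) && a %in% aromatic_atoms[[resid]])
    ctx$aromatic <- TRUE
  if (a == "N") {                      # backbone amide N
    ctx$bonded_h <- if (resid == "PRO") 0L else 1L
    ctx$lone_pair <- FALSE             # amide N: donor only
  } else if (a == "O" || a == "OXT") { # backbone carbonyl / terminus
    ctx$lone_pair <- TRUE
    if (a == "OXT") ctx$ionizable <- "negative"
  } else if (a %in% c("CA", "C")) {
    ctx$polar_neighbors <- 1L          # bonded to backbone N / O
  } else switch(
    resid,
    SER = if (a == "OG") { ctx$lone_pair <- TRUE; ctx$bonded_h <- 1L },
    THR = if (a == "OG1") { ctx$lone_pair <- TRUE; ctx$bonded_h <- 1L },
    TYR = if (a == "OH") { ctx$lone_pair <- TRUE; ctx$bonded_h <- 1L },
    CYS = if (a == "SG") ctx$bonded_h <- 1L,
    ASN = { if (a == "OD1") ctx$lone_pair <- TRUE
            if (a == "ND2") ctx$bonded_h <- 2L
            if (a == "CG") ctx$polar_neighbors <- 2L },
    GLN = { if (a == "OE1") ctx$lone_pair <- TRUE
            if (a == "NE2") ctx$bonded_h <- 2L
            if (a == "CD") ctx$polar_neighbors <- 2L },
    ASP = { if (a %in% c("OD1", "OD2")) {
              ctx$lone_pair <- TRUE; ctx$ionizable <- "negative" }
            if (a == "CG") ctx$polar_neighbors <- 2L },
    GLU = { if (a %in% c("OE1", "OE2")) {
              ctx$lone_pair <- TRUE; ctx$ionizable <- "negative" }
            if (a == "CD") ctx$polar_neighbors <- 2L },
    LYS = if (a == "NZ") { ctx$bonded_h <- 3L; ctx$ionizable <- "positive" },
    ARG = { if (a %in% c("NE", "NH1", "NH2")) {
              ctx$bonded_h <- if (a == "NE") 1L else 2L
              ctx$ionizable <- "positive" }
            if (a == "CZ") ctx$polar_neighbors <- 3L },
    HIS = { if (a == "ND1") { ctx$lone_pair <- TRUE; ctx$bonded_h <- 0L }
            if (a == "NE2") { ctx$bonded_h <- 1L
              ctx$ionizable <- "positive" } },
    TRP = if (a == "NE1") ctx$bonded_h <- 1L,
    MET = if (a %in% c("CG", "CE")) ctx$polar_neighbors <- 0L,
    NULL
  )
  # element from the atom name: leading letters, standard AA elements
  el <- sub("[0-9].*$", "", a)
  el <- substr(el, 1, 1)
  ctx$element <- c(C = "C", N = "N", O = "O", S = "S")[el]
  if (is.na(ctx$element)) ctx$element <- "X"
  ctx
}
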