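#' @name synthetic-data
#' @title Desk-scale synthetic CPI data with a planted rule
#' @description Generates synthetic protein targets (binding-site atom
#' clouds with controlled pharmacophoric composition plus random
#' amino-acid sequences) and pairs them with molecules from the
#' bundled SMILES library under a planted, learnable interaction rule:
#' a pair is labeled interacting when the target satisfies a site
#' predicate AND the molecule satisfies a molecular predicate, with an
#' optional label-flip noise. This gives an end-to-end testbed for
#' featurization, training and evaluation without any external
#' dataset. It emulates the per-target active/decoy structure of
#' screening benchmarks, not binding physics.
#' @keywords internal
NULL

#' Generate synthetic protein targets
#'
#' Each target gets a binding-site atom cloud (30-80 heavy atoms in a
#' 12 \ifelse{html}{\out{&Aring;}}{A}-radius sphere) whose channel
#' composition varies across targets, and a random amino-acid sequence
#' of length 50-1200. Alternate targets (odd indices) carry 2-4 metal
#' atoms, so any contiguous block of targets contains both
#' site-classes; metal-bearing targets also draw histidine- and
#' cysteine-enriched sequences, mimicking metal-coordinating proteins,
#' so the sequence pathway carries the same target-level signal as the
#' site pathway. Channel flags are produced through
#' [assign_channels()], never set freehand. Every target is
#' reproducible from (seed, index) alone.
#'
#' @param n number of targets.
#' @param seed integer seed.
#' @param n_atoms_range,seq_len_range,radius cloud and sequence
#'   geometry.
#' @return Named list (ids `T001`...) of targets, each a list with
#'   `site` (atom data frame with channel flags), `sequence`, and
#'   `metal` (does the site predicate "metal" hold). Attribute
#'   `manifest` records the generation parameters.
#' @examples
#' tg <- generate_targets(2, seed = 1)
#' names(tg)
#' @export
generate_targets <- function(n, seed = 1L, n_atoms_range = c(30L, 80L),
                             seq_len_range = c(50L, 1200L),
                             radius = 12) {
  stopifnot(n >= 0)
  if (n == 0) return(stats::setNames(list(), character(0)))
  out <- lapply(seq_len(n), function(i) {
    with_seed(target_seed(seed, i), make_target(
      i, n_atoms_range, seq_len_range, radius,
      metal = (i %% 2L == 1L)))
  })
  names(out) <- vapply(out, `[[`, "", "target_id")
  attr(out, "manifest") <- list(
    generator = "cpiconv::generate_targets", seed = seed, n = n,
    n_atoms_range = n_atoms_range, seq_len_range = seq_len_range,
    radius = radius)
  out
}

target_seed <- function(seed, i) (seed * 1009L + i * 7919L) %% 2147483629L

make_target <- function(i, n_atoms_range, seq_len_range, radius,
                        metal) {
  n_at <- sample(n_atoms_range[1]:n_atoms_range[2], 1L)
  # per-target channel composition: jittered proportions over the six
  # organic pools
  base <- c(hydrophobic = 0.35, aromatic = 0.15, acceptor = 0.15,
            donor = 0.15, positive = 0.1, negative = 0.1)
  pr <- base * runif(6, 0.5, 1.5)
  pr <- pr / sum(pr)
  pool <- sample(names(base), n_at, replace = TRUE, prob = pr)
  if (metal) pool <- c(pool, rep("metal", sample(2:4, 1L)))
  atoms <- do.call(rbind, lapply(pool, site_atom_from_pool))
  # uniform positions in a sphere
  m <- nrow(atoms)
  u <- matrix(rnorm(3 * m), m, 3)
  u <- u / sqrt(rowSums(u^2))
  xyz <- u * radius * runif(m)^(1 / 3)
  atoms$x <- xyz[, 1]; atoms$y <- xyz[, 2]; atoms$z <- xyz[, 3]
  len <- sample(seq_len_range[1]:seq_len_range[2], 1L)
  w <- rep(1, 20)
  names(w) <- AA_LETTERS
  if (metal) w[c("H", "C")] <- 5     # His/Cys enrichment
  chars <- sample(AA_LETTERS, len, replace = TRUE, prob = w / sum(w))
  if (metal) {
    # metal-coordinating proteins share a conserved His/Cys
    # coordination motif, inserted a few times per sequence
    motif <- strsplit("HCHHCHHAHH", "")[[1]]
    n_motif <- sample(3:6, 1L)
    for (s in seq_len(n_motif)) {
      at <- sample(max(len - length(motif), 1L), 1L)
      chars[at:(at + length(motif) - 1L)] <- motif
    }
  }
  sequence <- paste(chars, collapse = "")
  list(target_id = sprintf("T%03d", i), site = atoms,
       sequence = sequence, metal = metal)
}

# one site atom of a given pharmacophoric pool: element + bonded
# context chosen so the channel-typing rules fire as intended
site_atom_from_pool <- function(pool) {
  a <- switch(
    pool,
    hydrophobic = list(el = "C", ar = FALSE, pn = 0L, bh = 0L,
                       lp = FALSE, io = "none"),
    aromatic = list(el = "C", ar = TRUE, pn = 1L, bh = 0L,
                    lp = FALSE, io = "none"),
    acceptor = list(el = "O", ar = FALSE, pn = 0L, bh = 0L,
                    lp = TRUE, io = "none"),
    donor = list(el = "N", ar = FALSE, pn = 0L, bh = 1L,
                 lp = FALSE, io = "none"),
    positive = list(el = "N", ar = FALSE, pn = 0L, bh = 3L,
                    lp = FALSE, io = "positive"),
    negative = list(el = "O", ar = FALSE, pn = 0L, bh = 0L,
                    lp = TRUE, io = "negative"),
    metal = list(el = sample(c("Zn", "Mg", "Fe"), 1L), ar = FALSE,
                 pn = 0L, bh = 0L, lp = FALSE, io = "none")
  )
  fl <- assign_channels(a$el, aromatic = a$ar, polar_neighbors = a$pn,
                        bonded_h = a$bh, lone_pair = a$lp,
                        ionizable = a$io)
  cbind(data.frame(element = a$el, x = 0, y = 0, z = 0,
                   vdw = vdw_radius(a$el), stringsAsFactors = FALSE),
        as.data.frame(t(fl + 0L)))
}

#' Planted interaction rule
#'
#' Defines when a synthetic pair is labeled interacting: the target
#' must satisfy the site predicate AND the molecule the molecular
#' predicate; the result is XOR-ed with Bernoulli(`noise`) label
#' flips. Predicates are named (not free functions) so a dataset
#' manifest fully records the rule.
#'
#' @param site_rule `"metal"` (a metal-channel atom is present) or
#'   `"aromatic_rich"` (aromatic-channel fraction above
#'   `aromatic_cutoff`).
#' @param mol_rule `"nitrogen"` (molecule contains N) or
#'   `"nitrogen_aromatic"` (contains N and at least one aromatic
#'   atom).
#' @param noise label-flip probability in `[0, 0.5)`; 0.5 is allowed
#'   as the degenerate no-signal control (labels independent of
#'   features).
#' @param aromatic_cutoff cutoff for `"aromatic_rich"`.
#' @return List of class `"planted_rule"`.
#' @export
planted_rule <- function(site_rule = c("metal", "aromatic_rich"),
                         mol_rule = c("nitrogen", "nitrogen_aromatic"),
                         noise = 0, aromatic_cutoff = 0.2) {
  site_rule <- match.arg(site_rule)
  mol_rule <- match.arg(mol_rule)
  stopifnot(noise >= 0, noise <= 0.5)
  structure(list(site_rule = site_rule, mol_rule = mol_rule,
                 noise = noise, aromatic_cutoff = aromatic_cutoff),
            class = "planted_rule")
}

rule_site_pred <- function(rule, target) {
  switch(rule$site_rule,
         metal = any(target$site$metal == 1),
         aromatic_rich = mean(target$site$aromatic == 1) >
           rule$aromatic_cutoff)
}

rule_mol_pred <- function(rule, graph) {
  has_n <- any(graph$atoms$element == "N")
  switch(rule$mol_rule,
         nitrogen = has_n,
         nitrogen_aromatic = has_n && any(graph$atoms$aromatic))
}

#' Generate labeled sample pairs under a planted rule
#'
#' Pairs every synthetic target with molecules drawn from the bundled
#' library: per target, `molecules_per_target / (ratio + 1)` molecules
#' satisfying the rule's molecular predicate and `ratio` times as many
#' that do not, so the predicate-positive fraction matches the
#' requested active:decoy ratio. Labels follow the planted rule
#' (site predicate AND molecule predicate, XOR noise); for targets
#' failing the site predicate every pair is negative, which is what
#' makes the site pathway informative.
#'
#' @param targets from [generate_targets()].
#' @param molecules_per_target pairs per target (default 40).
#' @param ratio predicate-negative molecules per predicate-positive
#'   one (default 1).
#' @param rule a [planted_rule()].
#' @param seed integer seed (independent of the target seed).
#' @return List with `pairs` (data frame: target_id, ligand_id,
#'   label), `molecules` (named SMILES actually used), `graphs`
#'   (their parsed [mol_graph()]s) and `manifest` (seed, rule, counts
#'   -- enough to regenerate the dataset exactly).
#' @export
generate_pairs <- function(targets, molecules_per_target = 40L,
                           ratio = 1L, rule = planted_rule(),
                           seed = 1L) {
  stopifnot(inherits(rule, "planted_rule"), ratio >= 1,
            molecules_per_target >= ratio + 1)
  lib <- cpi_smiles_library()
  graphs <- featurize_molecules(lib)
  mpred <- vapply(graphs, function(g) rule_mol_pred(rule, g), TRUE)
  pos_pool <- names(lib)[mpred]
  neg_pool <- names(lib)[!mpred]
  n_act <- molecules_per_target %/% (ratio + 1L)
  n_dec <- n_act * ratio
  if (n_act > length(pos_pool) || n_dec > length(neg_pool))
    stop("molecule library exhausted: need ", n_act, "/", n_dec,
         " predicate-positive/negative molecules, have ",
         length(pos_pool), "/", length(neg_pool), call. = FALSE)
  pairs <- with_seed(seed, {
    do.call(rbind, lapply(names(targets), function(t) {
      mols <- c(sample(pos_pool, n_act), sample(neg_pool, n_dec))
      site_ok <- rule_site_pred(rule, targets[[t]])
      y <- as.integer(site_ok & mpred[mols])
      if (rule$noise > 0)
        y <- as.integer(xor(y, rbinom(length(y), 1, rule$noise)))
      data.frame(target_id = t, ligand_id = mols, label = y,
                 stringsAsFactors = FALSE, row.names = NULL)
    }))
  })
  used <- unique(pairs$ligand_id)
  list(pairs = pairs, molecules = lib[used], graphs = graphs[used],
       manifest = list(generator = "cpiconv::generate_pairs",
                       seed = seed, rule = unclass(rule),
                       molecules_per_target = molecules_per_target,
                       ratio = ratio, n_targets = length(targets),
                       n_pairs = nrow(pairs),
                       n_positive = sum(pairs$label == 1)))
}

#' Write / read a synthetic dataset in the real input formats
#'
#' Emits exactly what the real-data path consumes: one site-atom TSV
#' per target, a multi-record FASTA of sequences, a SMILES list file,
#' a pairs TSV and a JSON manifest recording both generator manifests
#' (so the dataset can be regenerated and compared byte for byte).
#'
#' @param targets from [generate_targets()].
#' @param pairset from [generate_pairs()].
#' @param dir output directory.
#' @return `dir` invisibly (`write_synthetic_dataset`); a list with
#'   `targets`, `pairs`, `molecules`, `manifest`
#'   (`read_synthetic_dataset`).
#' @export
write_synthetic_dataset <- function(targets, pairset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (t in names(targets))
    write_site_atoms(targets[[t]]$site,
                     file.path(dir, paste0("site_", t, ".tsv")))
  seqs <- Biostrings::AAStringSet(
    vapply(targets, `[[`, "", "sequence"))
  names(seqs) <- names(targets)
  Biostrings::writeXStringSet(seqs, file.path(dir, "sequences.fasta"))
  write_smiles_file(pairset$molecules, file.path(dir, "molecules.smi"))
  utils::write.table(pairset$pairs, file.path(dir, "pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(targets = attr(targets, "manifest"), pairs = pairset$manifest),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_synthetic_dataset
#' @export
read_synthetic_dataset <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  seqs <- Biostrings::readAAStringSet(file.path(dir, "sequences.fasta"))
  ids <- names(seqs)
  targets <- lapply(ids, function(t) {
    list(target_id = t,
         site = read_site_atoms(file.path(dir, paste0("site_", t, ".tsv"))),
         sequence = as.character(seqs[[t]]))
  })
  names(targets) <- ids
  pairs <- utils::read.delim(file.path(dir, "pairs.tsv"),
                             stringsAsFactors = FALSE)
  molecules <- read_smiles_file(file.path(dir, "molecules.smi"))
  list(targets = targets, pairs = check_pairs(pairs),
       molecules = molecules, manifest = manifest)
}
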