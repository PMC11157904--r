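# Nine-channel atom featurization.
#
# Channel order (fixed contract used throughout the package):
#   1 hybridization (1 = sp, 2 = sp2, 3 = sp3, 0 = unknown)
#   2 heavy_degree   (number of bonded heavy atoms)
#   3 hetero_degree  (number of bonded N/O/S/P atoms)
#   4 hydrophobic    (0/1: carbon bonded only to carbons)
#   5 aromatic       (0/1)
#   6 partial_charge (elementary charge, coarse per-atom-class values)
#   7 acceptor       (0/1: hydrogen-bond acceptor)
#   8 donor          (0/1: hydrogen-bond donor)
#   9 ring           (0/1: ring member)

FEATURE_CHANNELS <- c("hybridization", "heavy_degree", "hetero_degree",
                      "hydrophobic", "aromatic", "partial_charge",
                      "acceptor", "donor", "ring")

# Per-atom perception table for the 20 standard amino acids: hybridization,
# degree counts and flags follow standard residue topology (peptide backbone
# N-CA-C=O, proline N has no H, histidine/tryptophan ring nitrogens both
# donate and accept, hydroxyls donate and accept). Partial charges are coarse
# class values (amide-style backbone, +/-1 formal charges smeared onto the
# terminal heteroatoms), not a toolkit's Gasteiger charges.
#
# Format per line: RES ATOM hyb heavy hetero phob arom charge acc don ring
.residue_atom_table_raw <- "
ALL N   2 2 0 0 0 -0.35 0 1 0
ALL CA  3 3 1 0 0  0.10 0 0 0
ALL C   2 3 2 0 0  0.55 0 0 0
ALL O   2 1 0 0 0 -0.55 1 0 0
ALL OXT 2 1 0 0 0 -0.60 1 0 0
GLY CA  3 2 1 0 0  0.10 0 0 0
PRO N   2 3 0 0 0 -0.25 0 0 1
PRO CA  3 3 1 0 0  0.10 0 0 1
ALA CB  3 1 0 1 0  0.00 0 0 0
ARG CB  3 2 0 1 0  0.00 0 0 0
ARG CG  3 2 0 1 0  0.00 0 0 0
ARG CD  3 2 1 0 0  0.10 0 0 0
ARG NE  2 2 0 0 0 -0.30 0 1 0
ARG CZ  2 3 3 0 0  0.50 0 0 0
ARG NH1 2 1 0 0 0  0.25 0 1 0
ARG NH2 2 1 0 0 0  0.25 0 1 0
ASN CB  3 2 0 1 0  0.00 0 0 0
ASN CG  2 3 2 0 0  0.55 0 0 0
ASN OD1 2 1 0 0 0 -0.55 1 0 0
ASN ND2 2 1 0 0 0 -0.60 0 1 0
ASP CB  3 2 0 1 0  0.00 0 0 0
ASP CG  2 3 2 0 0  0.50 0 0 0
ASP OD1 2 1 0 0 0 -0.60 1 0 0
ASP OD2 2 1 0 0 0 -0.60 1 0 0
CYS CB  3 2 1 0 0  0.05 0 0 0
CYS SG  3 1 0 0 0 -0.20 0 1 0
GLN CB  3 2 0 1 0  0.00 0 0 0
GLN CG  3 2 0 1 0  0.00 0 0 0
GLN CD  2 3 2 0 0  0.55 0 0 0
GLN OE1 2 1 0 0 0 -0.55 1 0 0
GLN NE2 2 1 0 0 0 -0.60 0 1 0
GLU CB  3 2 0 1 0  0.00 0 0 0
GLU CG  3 2 0 1 0  0.00 0 0 0
GLU CD  2 3 2 0 0  0.50 0 0 0
GLU OE1 2 1 0 0 0 -0.60 1 0 0
GLU OE2 2 1 0 0 0 -0.60 1 0 0
HIS CB  3 2 0 1 0  0.00 0 0 0
HIS CG  2 3 1 0 1  0.05 0 0 1
HIS ND1 2 2 0 0 1 -0.30 1 1 1
HIS CD2 2 2 1 0 1  0.05 0 0 1
HIS CE1 2 2 2 0 1  0.20 0 0 1
HIS NE2 2 2 0 0 1 -0.30 1 1 1
ILE CB  3 3 0 1 0  0.00 0 0 0
ILE CG1 3 2 0 1 0  0.00 0 0 0
ILE CG2 3 1 0 1 0  0.00 0 0 0
ILE CD1 3 1 0 1 0  0.00 0 0 0
LEU CB  3 2 0 1 0  0.00 0 0 0
LEU CG  3 3 0 1 0  0.00 0 0 0
LEU CD1 3 1 0 1 0  0.00 0 0 0
LEU CD2 3 1 0 1 0  0.00 0 0 0
LYS CB  3 2 0 1 0  0.00 0 0 0
LYS CG  3 2 0 1 0  0.00 0 0 0
LYS CD  3 2 0 1 0  0.00 0 0 0
LYS CE  3 2 1 0 0  0.10 0 0 0
LYS NZ  3 1 0 0 0  0.80 0 1 0
MET CB  3 2 0 1 0  0.00 0 0 0
MET CG  3 2 1 0 0  0.05 0 0 0
MET SD  3 2 0 0 0 -0.10 0 0 0
MET CE  3 1 1 0 0  0.05 0 0 0
PHE CB  3 2 0 1 0  0.00 0 0 0
PHE CG  2 3 0 1 1  0.00 0 0 1
PHE CD1 2 2 0 1 1  0.00 0 0 1
PHE CD2 2 2 0 1 1  0.00 0 0 1
PHE CE1 2 2 0 1 1  0.00 0 0 1
PHE CE2 2 2 0 1 1  0.00 0 0 1
PHE CZ  2 2 0 1 1  0.00 0 0 1
PRO CB  3 2 0 1 0  0.00 0 0 1
PRO CG  3 2 0 1 0  0.00 0 0 1
PRO CD  3 2 1 0 0  0.10 0 0 1
SER CB  3 2 1 0 0  0.05 0 0 0
SER OG  3 1 0 0 0 -0.65 1 1 0
THR CB  3 3 1 0 0  0.05 0 0 0
THR OG1 3 1 0 0 0 -0.65 1 1 0
THR CG2 3 1 0 1 0  0.00 0 0 0
TRP CB  3 2 0 1 0  0.00 0 0 0
TRP CG  2 3 0 1 1  0.00 0 0 1
TRP CD1 2 2 1 0 1  0.05 0 0 1
TRP CD2 2 3 0 1 1  0.00 0 0 1
TRP NE1 2 2 0 0 1 -0.35 0 1 1
TRP CE2 2 3 1 0 1  0.05 0 0 1
TRP CE3 2 2 0 1 1  0.00 0 0 1
TRP CZ2 2 2 0 1 1  0.00 0 0 1
TRP CZ3 2 2 0 1 1  0.00 0 0 1
TRP CH2 2 2 0 1 1  0.00 0 0 1
TYR CB  3 2 0 1 0  0.00 0 0 0
TYR CG  2 3 0 1 1  0.00 0 0 1
TYR CD1 2 2 0 1 1  0.00 0 0 1
TYR CD2 2 2 0 1 1  0.00 0 0 1
TYR CE1 2 2 0 1 1  0.00 0 0 1
TYR CE2 2 2 0 1 1  0.00 0 0 1
TYR CZ  2 3 1 0 1  0.10 0 0 1
TYR OH  3 1 0 0 0 -0.50 1 1 0
VAL CB  3 3 0 1 0  0.00 0 0 0
VAL CG1 3 1 0 1 0  0.00 0 0 0
VAL CG2 3 1 0 1 0  0.00 0 0 0
"

.residue_atom_table <- local({
  d <- utils::read.table(text = .residue_atom_table_raw,
                         col.names = c("res", "atom", "hyb", "heavy", "hetero",
                                       "phob", "arom", "charge", "acc", "don",
                                       "ring"),
                         stringsAsFactors = FALSE)
  rownames(d) <- paste(d$res, d$atom)
  d
})

.rule_feature_row <- function(res_name, atom_name, element) {
  tab <- .residue_atom_table
  key <- paste(res_name, atom_name)
  if (!(key %in% rownames(tab))) key <- paste("ALL", atom_name)
  if (key %in% rownames(tab)) {
    r <- tab[key, ]
    return(c(r$hyb, r$heavy, r$hetero, r$phob, r$arom, r$charge,
             r$acc, r$don, r$ring))
  }
  if (element == "H" || element %in% .two_letter_elements) {
    # hydrogens and isolated metal ions: no heavy bonds, all channels zero
    return(c(0, 0, 0, 0, 0, 0, 0, 0, 0))
  }
  # generic fallback by element for non-tabulated heavy atoms
  switch(element,
         "C" = c(3, 2, 0, 1, 0, 0, 0, 0, 0),
         "N" = c(3, 2, 0, 0, 0, -0.3, 1, 1, 0),
         "O" = c(3, 1, 0, 0, 0, -0.5, 1, 1, 0),
         "S" = c(3, 2, 0, 0, 0, -0.1, 0, 0, 0),
         "P" = c(3, 4, 0, 0, 0, 0.4, 0, 0, 0),
         NULL)
}

#' Rule-based atom perception backend
#'
#' Assigns the nine feature channels from a residue/atom-name lookup table of
#' standard amino-acid topology. Serves as the default, dependency-free
#' perception strategy; a full chemistry toolkit backend can be substituted
#' via the `backend` argument of [featurize_atoms()].
#'
#' @param atoms Data frame of atom records (see [parse_pdb()]).
#' @return N x 9 numeric matrix, one row per atom.
#' @export
rule_perception_backend <- function(atoms) {
  out <- matrix(0, nrow = nrow(atoms), ncol = 9L,
                dimnames = list(NULL, FEATURE_CHANNELS))
  unknown <- character(0L)
  for (i in seq_len(nrow(atoms))) {
    row <- .rule_feature_row(atoms$res_name[i], atoms$atom_name[i],
                             atoms$element[i])
    if (is.null(row)) {
      unknown <- c(unknown, paste0(atoms$res_name[i], ":", atoms$atom_name[i],
                                   "(", atoms$element[i], ")"))
    } else {
      out[i, ] <- row
    }
  }
  if (length(unknown) > 0L) {
    warning("unknown element for ", length(unknown),
            " atom(s), features set to zero: ",
            paste(utils::head(unique(unknown), 5L), collapse = ", "))
  }
  out
}

#' Featurize the atoms of a protein structure
#'
#' Computes the nine-channel chemical descriptor for every retained
#' (non-HETATM) atom: hybridization, heavy-atom degree, heteroatom degree,
#' hydrophobicity, aromaticity, partial charge, acceptor, donor, and ring
#' membership.
#'
#' @param structure A `protein_structure`.
#' @param backend Perception strategy: a function mapping an atom data frame
#'   to an N x 9 matrix. Defaults to [rule_perception_backend()].
#' @return N x 9 numeric matrix aligned with `retained_atoms(structure)`.
#' @export
featurize_atoms <- function(structure, backend = rule_perception_backend) {
  atoms <- retained_atoms(structure)
  if (nrow(atoms) == 0L) stop("structure has no retained atoms to featurize")
  feats <- backend(atoms)
  stopifnot(is.matrix(feats), nrow(feats) == nrow(atoms), ncol(feats) == 9L)
  colnames(feats) <- FEATURE_CHANNELS
  feats
}
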