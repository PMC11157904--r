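# PDB structure input/output: fixed-column wwPDB parsing, curation filters,
# chain grouping, and pocket output.

# Two-letter element symbols that occur in protein/ligand PDB files. Used
# when the element column (77-78) is blank and the symbol must be inferred
# from the atom name.
.two_letter_elements <- c(
  "FE", "ZN", "MG", "MN", "CU", "NA", "CL", "BR", "SE", "CA", "CO", "NI",
  "CD", "HG", "MO", "AS", "AL", "SI", "LI", "BE"
)

#' Parse a PDB-format string into a protein structure
#'
#' Reads ATOM/HETATM records at their fixed wwPDB v3.3 column positions,
#' together with MODEL/ENDMDL bookkeeping and the REMARK 2 resolution line.
#' Only the first MODEL's atoms are retained (atom counts of every model are
#' recorded so the curation filter can detect model mismatches), and only the
#' first alternate location per atom (altLoc blank or "A") is kept.
#'
#' @param text Character scalar (or vector of lines) holding PDB-format text.
#' @param structure_id Identifier attached to the parsed structure.
#' @return An object of class `protein_structure`: a list with `structure_id`,
#'   `atoms` (data frame with one row per atom: `serial`, `atom_name`,
#'   `alt_loc`, `res_name`, `chain_id`, `res_seq`, `i_code`, `x`, `y`, `z`,
#'   `element`, `is_het`), `model_atom_counts`, `resolution` (Angstrom or
#'   `NA`), and `chain_ids` (distinct chains among non-HETATM atoms).
#' @export
parse_pdb <- function(text, structure_id = "structure") {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  } else {
    lines <- text
  }
  if (length(lines) == 0L || all(!nzchar(trimws(lines)))) {
    stop("empty PDB input for '", structure_id, "'")
  }
  rec <- substr(lines, 1L, 6L)
  is_atom <- rec == "ATOM  " | rec == "HETATM"
  n_models <- sum(rec == "MODEL ")
  resolution <- NA_real_

  remark2 <- grep("^REMARK   2 RESOLUTION", lines, value = TRUE)
  if (length(remark2) > 0L) {
    m <- regmatches(remark2[1L],
                    regexpr("[0-9]+\\.?[0-9]*(?=[[:space:]]*ANGSTROM)",
                            remark2[1L], perl = TRUE))
    if (length(m) == 1L) resolution <- as.numeric(m)
  }

  # model membership of every atom line
  model_idx <- cumsum(rec == "MODEL ")
  if (n_models == 0L) model_idx <- rep(1L, length(lines))
  atom_lines <- which(is_atom)
  if (length(atom_lines) == 0L) {
    stop("no ATOM/HETATM records in '", structure_id, "'")
  }
  atom_model <- pmax(model_idx[atom_lines], 1L)
  model_atom_counts <- as.integer(table(factor(atom_model,
                                               levels = seq_len(max(atom_model)))))

  keep <- atom_lines[atom_model == 1L]
  ln <- lines[keep]
  ln <- formatC(ln, width = 80L, flag = "-")  # pad short lines

  fx <- function(a, b) substr(ln, a, b)
  x <- suppressWarnings(as.numeric(fx(31L, 38L)))
  y <- suppressWarnings(as.numeric(fx(39L, 46L)))
  z <- suppressWarnings(as.numeric(fx(47L, 54L)))
  bad <- which(!is.finite(x) | !is.finite(y) | !is.finite(z))
  if (length(bad) > 0L) {
    stop("malformed atomic record at line ", keep[bad[1L]],
         " of '", structure_id, "': cannot read coordinates")
  }
  serial <- suppressWarnings(as.integer(fx(7L, 11L)))
  atom_name <- trimws(fx(13L, 16L))
  alt_loc <- fx(17L, 17L)
  res_name <- trimws(fx(18L, 20L))
  chain_id <- fx(22L, 22L)
  res_seq <- suppressWarnings(as.integer(fx(23L, 26L)))
  if (anyNA(res_seq)) {
    stop("malformed atomic record at line ", keep[which(is.na(res_seq))[1L]],
         " of '", structure_id, "': cannot read residue number")
  }
  i_code <- fx(27L, 27L)
  element <- trimws(fx(77L, 78L))
  element <- toupper(element)
  blank <- !nzchar(element)
  if (any(blank)) {
    element[blank] <- .infer_element(atom_name[blank],
                                     fx(13L, 13L)[blank] != " ")
  }
  is_het <- rec[keep] == "HETATM"

  atoms <- data.frame(
    serial = serial, atom_name = atom_name, alt_loc = alt_loc,
    res_name = res_name, chain_id = chain_id, res_seq = res_seq,
    i_code = i_code, x = x, y = y, z = z, element = element,
    is_het = is_het, stringsAsFactors = FALSE
  )
  # keep first alternate location only
  atoms <- atoms[atoms$alt_loc %in% c(" ", "", "A"), , drop = FALSE]
  rownames(atoms) <- NULL

  structure(
    list(structure_id = structure_id,
         atoms = atoms,
         model_atom_counts = model_atom_counts,
         resolution = resolution,
         chain_ids = unique(atoms$chain_id[!atoms$is_het])),
    class = "protein_structure"
  )
}

# Element inference when columns 77-78 are blank. `starts_col13` flags names
# that begin in column 13, where two-letter elements are left-justified.
.infer_element <- function(atom_name, starts_col13) {
  out <- character(length(atom_name))
  for (i in seq_along(atom_name)) {
    nm <- gsub("[^A-Za-z]", "", atom_name[i])
    two <- toupper(substr(nm, 1L, 2L))
    if (starts_col13[i] && two %in% .two_letter_elements) {
      out[i] <- two
    } else {
      out[i] <- toupper(substr(nm, 1L, 1L))
    }
  }
  out
}

#' Read and parse a PDB file
#' @param path Path to a PDB file.
#' @param structure_id Identifier; defaults to the file name without extension.
#' @return A `protein_structure`, see [parse_pdb()].
#' @export
read_pdb <- function(path, structure_id = NULL) {
  if (is.null(structure_id)) {
    structure_id <- sub("\\.(pdb|ent)$", "", basename(path), ignore.case = TRUE)
  }
  parse_pdb(readLines(path, warn = FALSE), structure_id = structure_id)
}

#' @export
print.protein_structure <- function(x, ...) {
  n_prot <- sum(!x$atoms$is_het)
  n_het <- sum(x$atoms$is_het)
  cat("protein_structure '", x$structure_id, "': ", n_prot,
      " protein atoms, ", n_het, " HETATM atoms, chains {",
      paste(x$chain_ids, collapse = ","), "}, resolution ",
      ifelse(is.na(x$resolution), "n/a", paste0(x$resolution, " A")),
      "\n", sep = "")
  invisible(x)
}

# Non-HETATM atoms: the atoms used for featurization, labeling and tensors.
retained_atoms <- function(structure) {
  structure$atoms[!structure$atoms$is_het, , drop = FALSE]
}

.nucleotide_names <- c("DA", "DT", "DG", "DC", "DU", "A", "U", "G", "C")

#' Apply dataset curation filters to a parsed structure
#'
#' A structure is rejected when its crystallographic resolution is worse than
#' `max_resolution` (strictly above; exactly 2.0 Angstrom passes), when its
#' MODEL blocks disagree on atom counts, or when it contains standard DNA/RNA
#' nucleotide residues. Structures without a REMARK 2 resolution (e.g.
#' predicted models) are accepted on the resolution criterion with a warning,
#' since that filter targets crystallographic database curation.
#'
#' @param structure A `protein_structure`.
#' @param max_resolution Resolution cutoff in Angstrom (default 2.0).
#' @return A list with `accept` (logical), `reason` (string, `""` when
#'   accepted; otherwise the first criterion that tripped) and `structure_id`.
#' @export
apply_curation_filters <- function(structure, max_resolution = 2.0) {
  decision <- function(accept, reason = "") {
    list(structure_id = structure$structure_id,
         accept = accept, reason = reason)
  }
  if (is.na(structure$resolution)) {
    warning("structure '", structure$structure_id,
            "' has no REMARK 2 resolution; accepting on that criterion")
  } else if (structure$resolution > max_resolution) {
    return(decision(FALSE, "resolution"))
  }
  if (length(unique(structure$model_atom_counts)) > 1L) {
    return(decision(FALSE, "model mismatch"))
  }
  res <- unique(retained_atoms(structure)$res_name)
  if (any(res %in% .nucleotide_names)) {
    return(decision(FALSE, "nucleic acid"))
  }
  decision(TRUE)
}

#' Group chains of a structure into prediction units
#'
#' Mirrors the three preprocessing modes of the prediction service: the whole
#' structure as one complex, every chain as its own complex, or a named
#' subset of chains as one complex.
#'
#' @param structure A `protein_structure`.
#' @param mode One of `"single_complex"`, `"per_chain"`, `"chain_subset"`.
#' @param chains Character vector of chain identifiers (for `chain_subset`).
#' @return A list of `protein_structure` prediction units; atom order within
#'   each unit follows the original file order.
#' @export
group_chains <- function(structure,
                         mode = c("single_complex", "per_chain", "chain_subset"),
                         chains = NULL) {
  mode <- match.arg(mode)
  unit <- function(atoms, id) {
    structure(
      list(structure_id = id, atoms = atoms,
           model_atom_counts = structure$model_atom_counts,
           resolution = structure$resolution,
           chain_ids = unique(atoms$chain_id[!atoms$is_het])),
      class = "protein_structure"
    )
  }
  if (mode == "single_complex") {
    return(list(structure))
  }
  if (mode == "per_chain") {
    return(lapply(structure$chain_ids, function(ch) {
      unit(structure$atoms[structure$atoms$chain_id == ch, , drop = FALSE],
           paste0(structure$structure_id, "_", ch))
    }))
  }
  if (is.null(chains) || length(chains) == 0L) {
    stop("chain_subset mode requires a non-empty 'chains' vector")
  }
  unknown <- setdiff(chains, structure$chain_ids)
  if (length(unknown) > 0L) {
    stop("unknown chain identifier(s): ", paste(unknown, collapse = ", "))
  }
  list(unit(structure$atoms[structure$atoms$chain_id %in% chains, , drop = FALSE],
            paste0(structure$structure_id, "_", paste(chains, collapse = ""))))
}

#' Extract ligand coordinates from HETATM records
#'
#' @param structure A `protein_structure` whose HETATM records include the
#'   ligand.
#' @param res_name Ligand residue name (e.g. `"HEM"`).
#' @param chain_id Optional chain filter.
#' @param res_seq Optional residue-number filter.
#' @return A `ligand_coordinates` object: list with `ligand_id` and
#'   `atom_coords` (matrix with columns x, y, z).
#' @export
extract_ligand <- function(structure, res_name, chain_id = NULL, res_seq = NULL) {
  a <- structure$atoms
  sel <- a$is_het & a$res_name == res_name
  if (!is.null(chain_id)) sel <- sel & a$chain_id == chain_id
  if (!is.null(res_seq)) sel <- sel & a$res_seq == res_seq
  if (!any(sel)) {
    stop("no HETATM atoms match ligand selector '", res_name, "'")
  }
  ligand_coordinates(
    as.matrix(a[sel, c("x", "y", "z")]),
    ligand_id = paste0(res_name,
                       if (!is.null(chain_id)) paste0("_", chain_id) else "",
                       if (!is.null(res_seq)) paste0("_", res_seq) else "")
  )
}

#' Construct a ligand coordinate set
#' @param atom_coords Numeric matrix (or data frame) with columns x, y, z.
#' @param ligand_id Identifier string.
#' @return A `ligand_coordinates` object.
#' @export
ligand_coordinates <- function(atom_coords, ligand_id = "ligand") {
  m <- as.matrix(atom_coords)
  if (nrow(m) == 0L) stop("ligand must contain at least one atom")
  if (ncol(m) != 3L) stop("ligand coordinates need exactly 3 columns")
  storage.mode(m) <- "double"
  dimnames(m) <- list(NULL, c("x", "y", "z"))
  structure(list(ligand_id = ligand_id, atom_coords = m),
            class = "ligand_coordinates")
}

#' Read ligand coordinates from a CSV file (columns x, y, z)
#' @param path CSV file path.
#' @param ligand_id Identifier; defaults to the file name.
#' @return A `ligand_coordinates` object.
#' @export
read_ligand_csv <- function(path, ligand_id = NULL) {
  if (is.null(ligand_id)) ligand_id <- sub("\\.csv$", "", basename(path))
  d <- utils::read.csv(path)
  ligand_coordinates(d[, c("x", "y", "z")], ligand_id = ligand_id)
}

.format_atom_line <- function(record, serial, atom_name, res_name, chain_id,
                              res_seq, i_code, x, y, z, element) {
  # wwPDB name convention: 1-letter elements start in column 14
  nm <- if (nchar(atom_name) < 4L && nchar(element) == 1L) {
    formatC(paste0(" ", atom_name), width = -4L)
  } else {
    formatC(atom_name, width = -4L)
  }
  sprintf("%-6s%5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial %% 100000L, nm, " ", res_name, chain_id,
          res_seq %% 10000L, i_code, x, y, z, 1, 0, element)
}

#' Write predicted pockets as a PDB-format string
#'
#' Emits one ATOM block per pocket, blocks separated by TER records, using
#' the source structure's atom records. Coordinates round-trip through
#' [parse_pdb()] at 3-decimal precision.
#'
#' @param structure The `protein_structure` the pockets refer to.
#' @param pockets List of `pocket` objects (see [extract_pockets()]).
#' @return A single PDB-format string.
#' @export
write_pocket_pdb <- function(structure, pockets) {
  atoms <- retained_atoms(structure)
  out <- c(sprintf("HEADER    PREDICTED BINDING POCKETS FOR %s",
                   toupper(structure$structure_id)))
  for (p in pockets) {
    if (any(p$member_atoms < 1L | p$member_atoms > nrow(atoms))) {
      stop("pocket ", p$pocket_id, " references atom indices outside the structure")
    }
    out <- c(out, sprintf("REMARK 900 POCKET %d CENTER %8.3f%8.3f%8.3f",
                          p$pocket_id, p$center[1], p$center[2], p$center[3]))
    a <- atoms[p$member_atoms, , drop = FALSE]
    out <- c(out,
             vapply(seq_len(nrow(a)), function(i) {
               .format_atom_line("ATOM", a$serial[i], a$atom_name[i],
                                 a$res_name[i], a$chain_id[i], a$res_seq[i],
                                 a$i_code[i], a$x[i], a$y[i], a$z[i],
                                 a$element[i])
             }, character(1L)),
             "TER")
  }
  paste(c(out, "END", ""), collapse = "\n")
}

#' Write a full structure (protein + HETATM ligands) as PDB text
#' @param structure A `protein_structure`.
#' @return A PDB-format string.
#' @export
write_pdb <- function(structure) {
  a <- structure$atoms
  body <- vapply(seq_len(nrow(a)), function(i) {
    .format_atom_line(if (a$is_het[i]) "HETATM" else "ATOM",
                      a$serial[i], a$atom_name[i], a$res_name[i],
                      a$chain_id[i], a$res_seq[i], a$i_code[i],
                      a$x[i], a$y[i], a$z[i], a$element[i])
  }, character(1L))
  head <- sprintf("HEADER    %s", toupper(structure$structure_id))
  if (!is.na(structure$resolution)) {
    head <- c(head, sprintf("REMARK   2 RESOLUTION.%9.2f ANGSTROMS.",
                            structure$resolution))
  }
  paste(c(head, body, "END", ""), collapse = "\n")
}
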