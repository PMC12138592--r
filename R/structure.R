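# Coordinate I/O and the structure model.
#
# A `xtal_structure` is a list with:
#   atoms       tibble: chain, resno, resid, elety, elesy, alt, x, y, z,
#               o, b, is_polymer (ATOM record vs HETATM)
#   cell        numeric(6) a,b,c,alpha,beta,gamma or NULL
#   space_group Hermann-Mauguin symbol or NA
# Chains and residues keep file order; atom tables are the unit of work for
# all downstream selection and distance logic.

ATOM_COLS <- c("chain", "resno", "resid", "elety", "elesy", "alt",
               "x", "y", "z", "o", "b", "is_polymer")

new_structure <- function(atoms, cell = NULL, space_group = NA_character_) {
  atoms <- tibble::as_tibble(atoms)
  stopifnot(all(ATOM_COLS %in% names(atoms)))
  if (!is.null(cell)) {
    stopifnot(length(cell) == 6)
    if (!is.na(space_group) &&
        (any(cell[1:3] <= 0) || any(cell[4:6] <= 0) || any(cell[4:6] >= 180))) {
      stop("invalid unit cell for space group ", space_group)
    }
  }
  structure(list(atoms = atoms, cell = cell, space_group = space_group),
            class = "xtal_structure")
}

#' @export
print.xtal_structure <- function(x, ...) {
  ch <- unique(x$atoms$chain)
  cat("<xtal_structure> ", nrow(x$atoms), " atoms, ",
      length(ch), " chain(s): ", paste(ch, collapse = " "), "\n", sep = "")
  if (!is.null(x$cell)) {
    cat("  cell: ", paste(format(x$cell, digits = 6), collapse = " "),
        "  space group: ", x$space_group, "\n", sep = "")
  }
  invisible(x)
}

#' Atom records of a structure as a tibble
#'
#' @param x A `xtal_structure`.
#' @param ... Unused.
#' @return The atom tibble (one row per atom).
#' @method tidy xtal_structure
#' @export
tidy.xtal_structure <- function(x, ...) x$atoms

coords <- function(s) {
  as.matrix(s$atoms[, c("x", "y", "z")])
}

n_atoms <- function(s) nrow(s$atoms)

#' Load a coordinate file
#'
#' Reads a PDB or mmCIF file (detected by extension, `.cif`/`.mmcif` vs
#' anything else) into a `xtal_structure`.  Only the first model of
#' multi-model files is kept.  Alternate locations are reduced to the
#' highest-occupancy conformer (ties: first encountered).  Waters and other
#' heteroatoms are retained, flagged non-polymer.  The unit cell and space
#' group are taken from `CRYST1` (PDB) or the `_cell`/`_symmetry` items
#' (mmCIF) when present.
#'
#' @param path Path to a PDB or mmCIF file.
#' @return A `xtal_structure`.
#' @export
load_structure <- function(path) {
  if (!file.exists(path)) stop("cannot read coordinate file: ", path)
  ext <- tolower(sub(".*\\.", "", path))
  is_cif <- ext %in% c("cif", "mmcif")
  pdb <- if (is_cif) {
    bio3d::read.cif(path, rm.alt = FALSE, verbose = FALSE)
  } else {
    bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  }
  at <- pdb$atom
  if (nrow(at) == 0) stop("no atoms found in ", path)
  atoms <- tibble::tibble(
    chain = ifelse(is.na(at$chain), "A", at$chain),
    resno = as.integer(at$resno),
    resid = at$resid,
    elety = at$elety,
    elesy = ifelse(is.na(at$elesy) | !nzchar(at$elesy),
                   toupper(substr(gsub("[^A-Za-z].*", "", at$elety), 1, 1)),
                   at$elesy),
    alt = at$alt,
    x = at$x, y = at$y, z = at$z,
    o = ifelse(is.na(at$o), 1, at$o),
    b = ifelse(is.na(at$b), 0, at$b),
    is_polymer = at$type == "ATOM"
  )
  if (any(!is.finite(as.matrix(atoms[, c("x", "y", "z")])))) {
    stop("non-finite coordinates in ", path)
  }
  atoms <- collapse_altlocs(atoms)
  cellinfo <- if (is_cif) read_cif_cell(path) else read_cryst1(path)
  new_structure(atoms, cell = cellinfo$cell, space_group = cellinfo$space_group)
}

# keep the highest-occupancy altloc per atom site; tie -> first encountered
collapse_altlocs <- function(atoms) {
  if (all(is.na(atoms$alt))) return(atoms)
  atoms$.ord <- seq_len(nrow(atoms))
  atoms <- atoms |>
    dplyr::group_by(.data$chain, .data$resno, .data$resid, .data$elety) |>
    dplyr::slice_max(.data$o, n = 1, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.ord)
  atoms$.ord <- NULL
  atoms$alt <- NA_character_
  atoms
}

read_cryst1 <- function(path) {
  lines <- readLines(path, warn = FALSE)
  cl <- grep("^CRYST1", lines, value = TRUE)
  if (length(cl) == 0) return(list(cell = NULL, space_group = NA_character_))
  cl <- cl[[1]]
  cell <- as.numeric(c(substr(cl, 7, 15), substr(cl, 16, 24), substr(cl, 25, 33),
                       substr(cl, 34, 40), substr(cl, 41, 47), substr(cl, 48, 54)))
  sg <- trimws(substr(cl, 56, 66))
  if (!nzchar(sg)) sg <- NA_character_
  list(cell = cell, space_group = sg)
}

read_cif_cell <- function(path) {
  lines <- readLines(path, warn = FALSE)
  grab <- function(tag) {
    ln <- grep(paste0("^", tag, "[[:space:]]"), lines, value = TRUE)
    if (length(ln) == 0) return(NA)
    val <- trimws(sub(paste0("^", tag), "", ln[[1]]))
    gsub("^['\"]|['\"]$", "", val)
  }
  cell <- suppressWarnings(as.numeric(c(
    grab("_cell.length_a"), grab("_cell.length_b"), grab("_cell.length_c"),
    grab("_cell.angle_alpha"), grab("_cell.angle_beta"), grab("_cell.angle_gamma")
  )))
  sg <- grab("_symmetry.space_group_name_H-M")
  if (is.na(sg)) sg <- grab("_space_group.name_H-M_alt")
  if (any(is.na(cell))) cell <- NULL
  list(cell = cell, space_group = if (is.character(sg)) sg else NA_character_)
}

#' Select one chain of a structure
#'
#' @param s A `xtal_structure`.
#' @param chain_id Chain identifier; when `NULL`, the first chain in file
#'   order is selected.
#' @return A `xtal_structure` restricted to that chain.
#' @export
select_chain <- function(s, chain_id = NULL) {
  stopifnot(inherits(s, "xtal_structure"), nrow(s$atoms) > 0)
  avail <- unique(s$atoms$chain)
  if (is.null(chain_id) || is.na(chain_id)) chain_id <- avail[[1]]
  if (!chain_id %in% avail) {
    stop("chain '", chain_id, "' not found; available chains: ",
         paste(avail, collapse = ", "))
  }
  new_structure(s$atoms[s$atoms$chain == chain_id, ],
                cell = s$cell, space_group = s$space_group)
}

#' Select a residue range on a chain
#'
#' Returns the ligand (or any residue-of-interest) selection: all residues
#' of `chain_id` with sequence number in `[res_lo, res_hi]`, in file order.
#' An empty result is an error, since it almost always signals a typo in the
#' input card.
#'
#' @param s A `xtal_structure`.
#' @param chain_id Chain identifier.
#' @param res_lo,res_hi Inclusive residue-number range.
#' @return A `xtal_structure` restricted to the selection.
#' @export
select_residues <- function(s, chain_id, res_lo, res_hi = res_lo) {
  stopifnot(inherits(s, "xtal_structure"))
  keep <- s$atoms$chain == chain_id &
    s$atoms$resno >= res_lo & s$atoms$resno <= res_hi
  if (!any(keep)) {
    stop("ligand not found: chain ", chain_id, " residues ",
         res_lo, "-", res_hi)
  }
  new_structure(s$atoms[keep, ], cell = s$cell, space_group = s$space_group)
}

#' Write a structure to PDB or mmCIF
#'
#' Round-trips through [load_structure()]: chains, residues, atom names,
#' occupancies, B-factors and coordinates are preserved to format precision
#' (1e-3 Angstrom for PDB).  A `CRYST1` record (or `_cell` items) is written
#' when the structure has a unit cell.
#'
#' @param s A `xtal_structure` with at least one atom.
#' @param path Output path.
#' @param format `"pdb"` or `"mmcif"`.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path, format = c("pdb", "mmcif")) {
  format <- match.arg(format)
  stopifnot(inherits(s, "xtal_structure"))
  if (nrow(s$atoms) == 0) stop("refusing to write an empty structure")
  if (format == "pdb") write_pdb_file(s, path) else write_mmcif_file(s, path)
  invisible(path)
}

write_pdb_file <- function(s, path) {
  a <- s$atoms
  # PDB atom-name column convention: names of 1-3 chars for 1-2 char element
  # symbols start in column 14
  fmt_name <- function(elety, elesy) {
    ifelse(nchar(elety) >= 4 | nchar(elesy) >= 2,
           sprintf("%-4s", elety), sprintf(" %-3s", elety))
  }
  lines <- character()
  if (!is.null(s$cell)) {
    sg <- if (is.na(s$space_group)) "P 1" else s$space_group
    lines <- c(lines, sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f %-11s",
      s$cell[1], s$cell[2], s$cell[3], s$cell[4], s$cell[5], s$cell[6], sg))
  }
  rec <- ifelse(a$is_polymer, "ATOM  ", "HETATM")
  serial <- seq_len(nrow(a)) %% 100000
  body <- sprintf(
    "%s%5d %s%1s%-3s%2s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    rec, serial, fmt_name(a$elety, a$elesy), " ",
    substr(a$resid, 1, 3), substr(a$chain, 1, 2), a$resno %% 10000, " ",
    a$x, a$y, a$z, a$o, a$b, substr(a$elesy, 1, 2))
  writeLines(c(lines, body, "END"), path)
}

write_mmcif_file <- function(s, path) {
  a <- s$atoms
  lines <- c("data_structure", "#")
  if (!is.null(s$cell)) {
    lines <- c(lines,
      sprintf("_cell.length_a    %.4f", s$cell[1]),
      sprintf("_cell.length_b    %.4f", s$cell[2]),
      sprintf("_cell.length_c    %.4f", s$cell[3]),
      sprintf("_cell.angle_alpha %.4f", s$cell[4]),
      sprintf("_cell.angle_beta  %.4f", s$cell[5]),
      sprintf("_cell.angle_gamma %.4f", s$cell[6]),
      if (!is.na(s$space_group))
        sprintf("_symmetry.space_group_name_H-M '%s'", s$space_group),
      "#")
  }
  # canonical wwPDB _atom_site column order
  lines <- c(lines,
    "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x", "_atom_site.Cartn_y", "_atom_site.Cartn_z",
    "_atom_site.occupancy", "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    sprintf("%s %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f %.2f %.2f ? %d %s %s %s 1",
            ifelse(a$is_polymer, "ATOM", "HETATM"), seq_len(nrow(a)),
            a$elesy, a$elety, a$resid, a$chain, a$resno,
            a$x, a$y, a$z, a$o, a$b, a$resno, a$resid, a$chain, a$elety),
    "#")
  writeLines(lines, path)
}

# split an atom tibble into per-residue groups, preserving file order
residue_groups <- function(atoms) {
  key <- paste(atoms$chain, atoms$resno, sep = "|")
  split(seq_len(nrow(atoms)), factor(key, levels = unique(key)))
}
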