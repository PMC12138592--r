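# Crystallographic symmetry: unit-cell frames, space-group operators,
# symmetry mates contacting the ligand, and binding-site truncation.
#
# Operators come from a bundled table of the Sohncke space groups (the 65
# chiral-compatible groups, plus alternative axis settings), keyed by the
# Hermann-Mauguin symbol as printed on CRYST1 records.  Only Sohncke groups
# are relevant: chiral macromolecules cannot crystallize in centrosymmetric
# groups.

#' Unit-cell frame
#'
#' Builds the fractional-to-Cartesian orthogonalization matrix (PDB
#' convention: a along x, b in the xy plane) and its inverse for a unit
#' cell.
#'
#' @param cell Numeric(6): a, b, c (Angstrom), alpha, beta, gamma (degrees).
#' @return List with `orth` (3x3, fractional -> Cartesian), `frac` (its
#'   inverse) and `volume` (Angstrom^3).
#' @export
cell_frame <- function(cell) {
  stopifnot(length(cell) == 6, all(cell[1:3] > 0),
            all(cell[4:6] > 0), all(cell[4:6] < 180))
  a <- cell[1]; b <- cell[2]; c <- cell[3]
  al <- cell[4] * pi / 180; be <- cell[5] * pi / 180; ga <- cell[6] * pi / 180
  cosal <- cos(al); cosbe <- cos(be); cosga <- cos(ga); singa <- sin(ga)
  v <- sqrt(1 - cosal^2 - cosbe^2 - cosga^2 + 2 * cosal * cosbe * cosga)
  orth <- matrix(c(
    a, b * cosga, c * cosbe,
    0, b * singa, c * (cosal - cosbe * cosga) / singa,
    0, 0, c * v / singa
  ), nrow = 3, byrow = TRUE)
  list(orth = orth, frac = solve(orth), volume = a * b * c * v)
}

# --- space-group operator table ------------------------------------------

normalize_sg_symbol <- function(symbol) {
  toupper(gsub("[[:space:]]+", "", symbol))
}

sohncke_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "sohncke_ops.tsv", package = "ligalign")
      tab <- utils::read.delim(path, stringsAsFactors = FALSE)
      tab$key <- normalize_sg_symbol(tab$hm)
      cache <<- tab
    }
    cache
  }
})

# parse one coordinate expression like "-x+1/2" or "x-y" into
# (row of rotation, translation fraction)
parse_triplet_term <- function(expr) {
  expr <- gsub("[[:space:]]", "", tolower(expr))
  row <- c(0, 0, 0); trans <- 0
  # tokenize into signed terms
  terms <- regmatches(expr, gregexpr("[+-]?[^+-]+", expr))[[1]]
  for (term in terms) {
    sgn <- if (startsWith(term, "-")) -1 else 1
    body <- sub("^[+-]", "", term)
    if (body %in% c("x", "y", "z")) {
      row[match(body, c("x", "y", "z"))] <- row[match(body, c("x", "y", "z"))] + sgn
    } else if (grepl("^[0-9]+/[0-9]+$", body)) {
      parts <- as.numeric(strsplit(body, "/", fixed = TRUE)[[1]])
      trans <- trans + sgn * parts[1] / parts[2]
    } else if (grepl("^[0-9.]+$", body)) {
      trans <- trans + sgn * as.numeric(body)
    } else {
      stop("cannot parse symmetry term '", term, "'")
    }
  }
  list(row = row, trans = trans %% 1)
}

parse_triplet <- function(triplet) {
  parts <- strsplit(triplet, ",", fixed = TRUE)[[1]]
  stopifnot(length(parts) == 3)
  parsed <- lapply(parts, parse_triplet_term)
  list(
    rotation_frac = do.call(rbind, lapply(parsed, `[[`, "row")),
    translation_frac = vapply(parsed, `[[`, numeric(1), "trans")
  )
}

#' Space-group operators
#'
#' Looks up a Hermann-Mauguin symbol in the bundled Sohncke-group table and
#' returns all coset representatives (including the identity and any
#' centering translations) as fractional-coordinate operators.
#'
#' @param symbol Hermann-Mauguin symbol, e.g. `"P 21 21 21"`; spacing and
#'   case are ignored.
#' @return List of operators, each a list with `rotation_frac` (3x3 integer
#'   matrix) and `translation_frac` (length-3, components in `[0,1)`).
#' @export
space_group_ops <- function(symbol) {
  tab <- sohncke_table()
  hit <- which(tab$key == normalize_sg_symbol(symbol))
  if (length(hit) == 0) {
    stop("unknown or non-Sohncke space group symbol '", symbol,
         "'; supply a real-space map instead of MTZ coefficients, ",
         "or fix the CRYST1 record")
  }
  triplets <- strsplit(tab$ops[hit[[1]]], ";", fixed = TRUE)[[1]]
  lapply(triplets, parse_triplet)
}

apply_symop_frac <- function(frac_xyz, op, shift = c(0, 0, 0)) {
  sweep(frac_xyz %*% t(op$rotation_frac), 2,
        op$translation_frac + shift, "+")
}

#' Symmetry mates contacting a ligand
#'
#' Enumerates every non-identity image of the structure's residues under
#' the space-group operators combined with lattice translations in -2..2
#' per axis, and keeps the residue copies having at least one atom within
#' `radius` of any ligand atom.  The identity operator with zero shift (the
#' asymmetric unit itself) is excluded.
#'
#' Structures without a unit cell or space group (e.g. cryoEM models)
#' return an empty result with a warning rather than an error.
#'
#' @param s A `xtal_structure` with cell and space group.
#' @param ligand A `xtal_structure` holding the ligand selection (same
#'   crystal frame).
#' @param radius Contact radius in Angstrom; defaults to the binding-site
#'   truncation radius.
#' @param shift_range Lattice translation range per axis.
#' @return A tibble of atom records of contacting residue copies, with
#'   extra columns `op` (operator index), `s1`,`s2`,`s3` (lattice shift)
#'   and `src_chain` (chain id in the asymmetric unit).
#' @export
symmetry_mates_near <- function(s, ligand, radius = 4.5, shift_range = -2:2) {
  stopifnot(inherits(s, "xtal_structure"), nrow(ligand$atoms) > 0)
  empty <- s$atoms[0, ]
  empty$op <- integer(0); empty$s1 <- integer(0)
  empty$s2 <- integer(0); empty$s3 <- integer(0)
  empty$src_chain <- character(0)
  if (is.null(s$cell) || is.na(s$space_group)) {
    warning("no cell/space group: skipping symmetry-mate search ",
            "(non-crystallographic input)")
    return(empty)
  }
  frame <- cell_frame(s$cell)
  ops <- space_group_ops(s$space_group)
  lig_xyz <- coords(ligand)
  frac <- coords(s) %*% t(frame$frac)
  res_idx <- residue_groups(s$atoms)

  id_op <- vapply(ops, function(o) {
    all(o$rotation_frac == diag(3)) && all(o$translation_frac %% 1 == 0)
  }, logical(1))

  out <- list(empty)
  for (k in seq_along(ops)) {
    moved <- frac %*% t(ops[[k]]$rotation_frac)
    moved <- sweep(moved, 2, ops[[k]]$translation_frac, "+")
    for (u in shift_range) for (v in shift_range) for (w in shift_range) {
      if (id_op[k] && u == 0 && v == 0 && w == 0) next
      cart <- sweep(moved, 2, c(u, v, w), "+") %*% t(frame$orth)
      # fast reject: bounding-box distance between mate copy and ligand
      if (bbox_min_gap(cart, lig_xyz) > radius) next
      dmin <- min_dist_to_set(cart, lig_xyz)
      close_atoms <- dmin <= radius
      if (!any(close_atoms)) next
      keep_res <- vapply(res_idx, function(ii) any(close_atoms[ii]), logical(1))
      for (ri in which(keep_res)) {
        ii <- res_idx[[ri]]
        at <- s$atoms[ii, ]
        at$x <- cart[ii, 1]; at$y <- cart[ii, 2]; at$z <- cart[ii, 3]
        at$op <- k; at$s1 <- u; at$s2 <- v; at$s3 <- w
        at$src_chain <- at$chain
        out[[length(out) + 1]] <- at
      }
    }
  }
  dplyr::bind_rows(out)
}

bbox_min_gap <- function(a, b) {
  lo <- pmax(apply(b, 2, min) - apply(a, 2, max), 0)
  hi <- pmax(apply(a, 2, min) - apply(b, 2, max), 0)
  sqrt(sum(pmax(lo, hi)^2))
}

# per-row minimum distance from points `a` (Nx3) to point set `b` (Mx3)
min_dist_to_set <- function(a, b) {
  d2 <- outer(rowSums(a^2), rep(1, nrow(b))) +
    outer(rep(1, nrow(a)), rowSums(b^2)) - 2 * a %*% t(b)
  sqrt(pmax(apply(d2, 1, min), 0))
}

#' Append symmetry mates to a structure with fresh chain ids
#'
#' Mates found by [symmetry_mates_near()] are appended as new chains named
#' from a deterministic pool (lowercase letters, then digits), skipping ids
#' already present.  Each distinct (operator, lattice shift, source chain)
#' combination gets one fresh chain id.
#'
#' @inheritParams symmetry_mates_near
#' @return A `xtal_structure` containing the asymmetric unit plus mates.
#' @export
add_symmetry_mates <- function(s, ligand, radius = 4.5) {
  mates <- symmetry_mates_near(s, ligand, radius)
  if (nrow(mates) == 0) return(s)
  pool <- setdiff(c(letters, as.character(0:9)), unique(s$atoms$chain))
  key <- paste(mates$op, mates$s1, mates$s2, mates$s3, mates$src_chain)
  ukey <- unique(key)
  if (length(ukey) > length(pool)) {
    stop("too many symmetry-mate chains for the chain-id pool")
  }
  mates$chain <- pool[match(key, ukey)]
  mates <- mates[, ATOM_COLS]
  new_structure(dplyr::bind_rows(s$atoms, mates),
                cell = s$cell, space_group = s$space_group)
}

#' Truncate a structure to the ligand environment
#'
#' Keeps the ligand residues plus every residue (protein, waters, other
#' heteroatoms, symmetry-mate chains) having at least one atom within
#' `radius` of at least one ligand atom.  Residues are kept or dropped
#' whole, never split.  Truncation is idempotent.
#'
#' @param s A `xtal_structure` (possibly already containing symmetry
#'   mates).
#' @param ligand Ligand selection as a `xtal_structure` in the same frame.
#' @param radius Environment radius in Angstrom (default 4.5).
#' @return The truncated `xtal_structure` (ligand plus environment).
#' @export
truncate_environment <- function(s, ligand, radius = 4.5) {
  stopifnot(inherits(s, "xtal_structure"), nrow(ligand$atoms) > 0)
  lig_xyz <- coords(ligand)
  lig_key <- unique(paste(ligand$atoms$chain, ligand$atoms$resno))
  dmin <- min_dist_to_set(coords(s), lig_xyz)
  res_idx <- residue_groups(s$atoms)
  keep <- vapply(res_idx, function(ii) {
    key <- paste(s$atoms$chain[ii[[1]]], s$atoms$resno[ii[[1]]])
    key %in% lig_key || any(dmin[ii] <= radius)
  }, logical(1))
  rows <- sort(unlist(res_idx[keep], use.names = FALSE))
  new_structure(s$atoms[rows, ], cell = s$cell, space_group = s$space_group)
}
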