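# Synthetic fixtures: toy protein-ligand crystals, rigid-motion copies,
# Gaussian-atom map coefficients and maps.  Everything is generated in
# code, seed-deterministically, so the whole pipeline is testable with no
# external data.

# run code with a private, seeded RNG stream, restoring the caller's state
with_fixture_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

ELEMENT_Z <- c(H = 1, C = 6, N = 7, O = 8, P = 15, S = 16)

#' Build a toy protein-ligand complex in a crystal cell
#'
#' An ideal-geometry polyalanine helix (5 atoms per residue: N, CA, C, O,
#' CB) in chain A plus a single 5-atom `LIG` heteroresidue in chain L at
#' `ligand_offset`, inside the stated unit cell.  Optional seeded
#' coordinate jitter emulates experimental noise; an optional rigid
#' `motion` produces a "mobile" copy superposable back onto the original.
#'
#' @param n_residues Number of helix residues (>= 3).
#' @param space_group Hermann-Mauguin symbol for the crystal.
#' @param cell Unit-cell parameters; must contain the model.
#' @param ligand_offset Cartesian position of the ligand centroid.
#' @param motion Optional `rigid_transform` applied to all coordinates.
#' @param noise_sigma Coordinate jitter standard deviation (Angstrom).
#' @param seed RNG seed for the jitter.
#' @return List with `structure` (a `xtal_structure`) and `ligand` (its
#'   chain-L selection).
#' @export
make_complex <- function(n_residues = 8, space_group = "P 21 21 21",
                         cell = c(30, 34, 38, 90, 90, 90),
                         ligand_offset = c(14, 12, 12),
                         motion = NULL, noise_sigma = 0, seed = 1) {
  stopifnot(n_residues >= 3)
  space_group_ops(space_group)             # validate the symbol early
  base <- c(9, 9, 8)                       # helix start, inside the cell
  rows <- list()
  for (i in seq_len(n_residues) - 1) {
    th <- i * 100 * pi / 180
    at <- function(r, dth, dz) base +
      c(r * cos(th + dth), r * sin(th + dth), 1.5 * i + dz)
    pos <- rbind(at(1.6, -0.45, -0.6),   # N
                 at(2.3, 0.00, 0.0),     # CA
                 at(2.0, 0.50, 0.55),    # C
                 at(2.2, 0.60, 1.70),    # O
                 at(3.6, 0.00, 0.0))     # CB
    rows[[i + 1]] <- tibble::tibble(
      chain = "A", resno = i + 1L, resid = "ALA",
      elety = c("N", "CA", "C", "O", "CB"),
      elesy = c("N", "C", "C", "O", "C"),
      alt = NA_character_,
      x = pos[, 1], y = pos[, 2], z = pos[, 3],
      o = 1, b = 15, is_polymer = TRUE
    )
  }
  ring <- 72 * (0:3) * pi / 180
  lig_pos <- rbind(
    cbind(1.3 * cos(ring), 1.3 * sin(ring), 0),
    c(0, 0, 1.3))
  lig_pos <- sweep(lig_pos, 2, ligand_offset, "+")
  rows[[length(rows) + 1]] <- tibble::tibble(
    chain = "L", resno = 1L, resid = "LIG",
    elety = c("C1", "C2", "C3", "O4", "N5"),
    elesy = c("C", "C", "C", "O", "N"),
    alt = NA_character_,
    x = lig_pos[, 1], y = lig_pos[, 2], z = lig_pos[, 3],
    o = 1, b = 20, is_polymer = FALSE
  )
  atoms <- dplyr::bind_rows(rows)
  if (noise_sigma > 0) {
    with_fixture_seed(seed, {
      jit <- matrix(stats::rnorm(3 * nrow(atoms), sd = noise_sigma), ncol = 3)
      atoms$x <- atoms$x + jit[, 1]
      atoms$y <- atoms$y + jit[, 2]
      atoms$z <- atoms$z + jit[, 3]
    })
  }
  if (normalize_sg_symbol(space_group) != "P1") {
    frac <- sweep(lig_pos, 2, c(0, 0, 0)) %*% t(cell_frame(cell)$frac)
    if (any(frac < 0) || any(frac >= 1)) {
      stop("ligand placed outside the unit cell in space group ", space_group)
    }
  }
  s <- new_structure(atoms, cell = cell, space_group = space_group)
  if (!is.null(motion)) s <- apply_transform(s, motion)
  list(structure = s, ligand = select_residues(s, "L", 1L, 1L))
}

#' Draw a random proper rigid motion
#'
#' Uniformly random rotation (via quaternion) and a uniform translation,
#' for building "mobile" fixture copies and recovery tests.
#'
#' @param seed RNG seed.
#' @param max_shift Translation components are uniform in
#'   `[-max_shift, max_shift]`.
#' @return A `rigid_transform`.
#' @export
random_motion <- function(seed = 1, max_shift = 10) {
  with_fixture_seed(seed, {
    q <- stats::rnorm(4)
    q <- q / sqrt(sum(q^2))
    r <- matrix(c(
      1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] - q[1] * q[4]), 2 * (q[2] * q[4] + q[1] * q[3]),
      2 * (q[2] * q[3] + q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2), 2 * (q[3] * q[4] - q[1] * q[2]),
      2 * (q[2] * q[4] - q[1] * q[3]), 2 * (q[3] * q[4] + q[1] * q[2]), 1 - 2 * (q[2]^2 + q[3]^2)
    ), nrow = 3, byrow = TRUE)
    rigid_transform(r, stats::runif(3, -max_shift, max_shift))
  })
}

#' Gaussian-atom structure factors for a toy crystal
#'
#' Computes F(h) = sum_atoms Z exp(-B |s|^2 / 4) exp(2 pi i h.x_frac) over
#' the full symmetry-expanded cell content, for all reflections in a
#' hemisphere to `d_min` (including F(000) = total electron count).  This
#' is a deliberately simplified scattering model - single-Gaussian atoms,
#' no bulk solvent - that produces maps peaking at atom positions, which
#' is what synthesis/extraction/carving tests need.
#'
#' @param s A `xtal_structure` with cell and space group.
#' @param d_min Resolution limit (Angstrom).
#' @param b_iso Isotropic B-factor applied to every atom (Angstrom^2).
#' @return A `map_coefficients` object (labels FWT/PHWT).
#' @export
make_coefficients <- function(s, d_min = 4.0, b_iso = 15) {
  stopifnot(inherits(s, "xtal_structure"))
  if (is.null(s$cell) || is.na(s$space_group)) {
    stop("structure needs a cell and space group for structure factors")
  }
  if (d_min <= 0) stop("d_min must be positive")
  frame <- cell_frame(s$cell)
  ops <- space_group_ops(s$space_group)
  frac <- coords(s) %*% t(frame$frac)
  frac_all <- do.call(rbind, lapply(ops, function(op) {
    apply_symop_frac(frac, op) %% 1
  }))
  z <- rep(ELEMENT_Z[match(toupper(s$atoms$elesy), names(ELEMENT_Z))],
           times = length(ops))
  z[is.na(z)] <- 6

  hmax <- floor(s$cell[1:3] / d_min) + 1
  hkl <- as.matrix(expand.grid(h = -hmax[1]:hmax[1], k = -hmax[2]:hmax[2],
                               l = 0:hmax[3]))
  hemi <- hkl[, 3] > 0 | (hkl[, 3] == 0 & hkl[, 2] > 0) |
    (hkl[, 3] == 0 & hkl[, 2] == 0 & hkl[, 1] >= 0)
  s2 <- rowSums((hkl %*% frame$frac)^2)
  keep <- hemi & s2 <= 1 / d_min^2
  hkl <- hkl[keep, , drop = FALSE]
  s2 <- s2[keep]
  # reduce to one canonical representative per symmetry orbit
  canon <- vapply(seq_len(nrow(hkl)), function(i) {
    eq <- do.call(rbind, lapply(ops, function(op) {
      hh <- as.integer(hkl[i, ] %*% op$rotation_frac)
      rbind(hh, -hh)
    }))
    paste(eq[order(eq[, 1], eq[, 2], eq[, 3])[1], ], collapse = ",")
  }, character(1))
  first <- !duplicated(canon)
  hkl <- hkl[first, , drop = FALSE]
  s2 <- s2[first]

  phase <- exp(2i * pi * (hkl %*% t(frac_all)))     # nref x natoms
  fvec <- (phase %*% z) * exp(-b_iso * s2 / 4)
  new_map_coefficients(hkl = hkl, f = Mod(fvec),
                       phi = Arg(fvec) * 180 / pi,
                       cell = s$cell, space_group = s$space_group)
}

#' Write a complete runnable fixture set
#'
#' Builds a reference complex, one identical entry with FWT/PHWT map
#' coefficients, one rigidly moved copy, and one copy in a different
#' space group / crystal form, writes all files into `dir`, and emits an
#' example input card (`example.card`: one `#REF` line and two `#G`
#' groups) referencing them by relative path.
#'
#' @param dir Output directory (created if absent).
#' @param seed RNG seed controlling the rigid motions.
#' @param d_min Resolution for the fixture map coefficients.
#' @return Path of the example card, invisibly.
#' @export
make_fixture_set <- function(dir, seed = 1, d_min = 4.0) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref <- make_complex(seed = seed)
  write_structure(ref$structure, file.path(dir, "ref.pdb"))

  # entry 1: same crystal, with map coefficients
  write_structure(ref$structure, file.path(dir, "e1.pdb"))
  coef <- make_coefficients(ref$structure, d_min = d_min)
  write_mtz(coef, file.path(dir, "e1.mtz"))

  # entry 2: rigidly moved copy (e.g. re-deposited in a different frame)
  m2 <- random_motion(seed = seed + 101, max_shift = 8)
  e2 <- make_complex(seed = seed, motion = m2, space_group = "P 1",
                     cell = c(60, 60, 60, 90, 90, 90))
  write_structure(e2$structure, file.path(dir, "e2.pdb"))

  # entry 3: different crystal form (monoclinic cell, P 1 21 1)
  e3 <- make_complex(seed = seed, space_group = "P 1 21 1",
                     cell = c(34, 30, 36, 90, 100, 90))
  write_structure(e3$structure, file.path(dir, "e3.pdb"))

  card <- c(
    "# synthetic fixture card",
    "#REF ref.pdb A",
    "#G siteA",
    "e1.pdb e1.mtz L 1 lig_mapped A",
    "e2.pdb L 1 lig_moved A",
    "#G siteB",
    "e3.pdb L 1 lig_altform A"
  )
  card_path <- file.path(dir, "example.card")
  writeLines(card, card_path)
  invisible(card_path)
}
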