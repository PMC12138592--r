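# Shared fixtures and independent brute-force oracles.  Oracles here are
# written as plain loops, separately from the package's vectorized code
# paths, so tests compare two genuinely different computations.

# --- tiny structure builders ---------------------------------------------

toy_atoms <- function(xyz, chain = "A", resno = NULL, resid = "ALA",
                      elety = NULL, is_polymer = TRUE) {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  tibble::tibble(
    chain = rep_len(chain, n),
    resno = if (is.null(resno)) seq_len(n) else as.integer(rep_len(resno, n)),
    resid = rep_len(resid, n),
    elety = if (is.null(elety)) rep("CA", n) else rep_len(elety, n),
    elesy = "C", alt = NA_character_,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    o = 1, b = 10, is_polymer = rep_len(is_polymer, n)
  )
}

toy_structure <- function(atoms, cell = NULL, space_group = NA_character_) {
  ligalign:::new_structure(atoms, cell = cell, space_group = space_group)
}

# a random toy crystal: short helix + ligand, random cell within limits
random_toy_crystal <- function(seed, space_group) {
  set.seed(seed)
  cell <- switch(space_group,
    "P 1" = c(runif(1, 16, 22), runif(1, 16, 22), runif(1, 16, 22), 90, 90, 90),
    "P 1 21 1" = c(runif(1, 16, 22), runif(1, 16, 22), runif(1, 16, 22),
                   90, runif(1, 92, 108), 90),
    "C 1 2 1" = c(runif(1, 20, 26), runif(1, 16, 20), runif(1, 16, 20),
                  90, runif(1, 92, 105), 90),
    "P 21 21 21" = c(runif(1, 16, 22), runif(1, 16, 22), runif(1, 16, 22),
                     90, 90, 90),
    "P 41" = {a <- runif(1, 16, 22); c(a, a, runif(1, 18, 26), 90, 90, 90)},
    stop("no toy recipe for ", space_group)
  )
  frame <- cell_frame(cell)
  lig_frac <- runif(3, 0.15, 0.85)
  lig <- as.numeric(frame$orth %*% lig_frac)
  make_complex(n_residues = 3, space_group = space_group, cell = cell,
               ligand_offset = lig, seed = seed)
}

# --- brute-force oracles --------------------------------------------------

# symmetry mates: loop over every op, shift, residue, atom pair
brute_mates <- function(s, ligand, radius, shift_range = -2:2) {
  frame <- cell_frame(s$cell)
  ops <- space_group_ops(s$space_group)
  lig <- as.matrix(ligand$atoms[, c("x", "y", "z")])
  res_idx <- ligalign:::residue_groups(s$atoms)
  found <- character()
  for (k in seq_along(ops)) {
    op <- ops[[k]]
    is_id <- all(op$rotation_frac == diag(3)) &&
      all(op$translation_frac %% 1 == 0)
    for (u in shift_range) for (v in shift_range) for (w in shift_range) {
      if (is_id && u == 0 && v == 0 && w == 0) next
      for (ri in seq_along(res_idx)) {
        hit <- FALSE
        for (ai in res_idx[[ri]]) {
          p <- c(s$atoms$x[ai], s$atoms$y[ai], s$atoms$z[ai])
          fr <- as.numeric(frame$frac %*% p)
          fr2 <- as.numeric(op$rotation_frac %*% fr) + op$translation_frac +
            c(u, v, w)
          q <- as.numeric(frame$orth %*% fr2)
          for (li in seq_len(nrow(lig))) {
            if (sqrt(sum((q - lig[li, ])^2)) <= radius) { hit <- TRUE; break }
          }
          if (hit) break
        }
        if (hit) {
          a1 <- res_idx[[ri]][1]
          found <- c(found, paste(k, u, v, w,
                                  paste(s$atoms$chain[a1], s$atoms$resno[a1])))
        }
      }
    }
  }
  sort(found)
}

# environment truncation: all-pairs residue scan
brute_truncate_keys <- function(s, ligand, radius) {
  lig <- as.matrix(ligand$atoms[, c("x", "y", "z")])
  lig_keys <- unique(paste(ligand$atoms$chain, ligand$atoms$resno))
  res_idx <- ligalign:::residue_groups(s$atoms)
  keep <- character()
  for (ri in seq_along(res_idx)) {
    key <- names(res_idx)[ri]
    key_sp <- paste(s$atoms$chain[res_idx[[ri]][1]],
                    s$atoms$resno[res_idx[[ri]][1]])
    hit <- key_sp %in% lig_keys
    if (!hit) {
      for (ai in res_idx[[ri]]) {
        p <- c(s$atoms$x[ai], s$atoms$y[ai], s$atoms$z[ai])
        for (li in seq_len(nrow(lig))) {
          if (sqrt(sum((p - lig[li, ])^2)) <= radius) { hit <- TRUE; break }
        }
        if (hit) break
      }
    }
    if (hit) keep <- c(keep, key_sp)
  }
  sort(keep)
}

# direct Fourier summation of map coefficients at fractional points;
# plain loops over operators and reflections, deduplicating expanded
# indices exactly like a structure-factor program would
direct_density <- function(coef, frac_points) {
  ops <- space_group_ops(coef$space_group)
  fc <- coef$f * exp(1i * coef$phi * pi / 180)
  seen <- character()
  hs <- list(); fs <- list()
  for (op in ops) {
    for (i in seq_len(nrow(coef$hkl))) {
      h <- as.numeric(coef$hkl[i, ])
      h2 <- as.numeric(h %*% op$rotation_frac)
      f2 <- fc[i] * exp(-2i * pi * sum(h * op$translation_frac))
      for (sgn in c(1, -1)) {
        hh <- sgn * h2
        ff <- if (sgn == 1) f2 else Conj(f2)
        key <- paste(hh, collapse = ",")
        if (!key %in% seen) {
          seen <- c(seen, key)
          hs[[length(hs) + 1]] <- hh
          fs[[length(fs) + 1]] <- ff
        }
      }
    }
  }
  hmat <- do.call(rbind, hs)
  fvec <- unlist(fs)
  vol <- cell_frame(coef$cell)$volume
  apply(matrix(frac_points, ncol = 3), 1, function(x) {
    Re(sum(fvec * exp(-2i * pi * as.numeric(hmat %*% x)))) / vol
  })
}

# exhaustive global alignment score by recursion (tiny sequences only)
exhaustive_align_score <- function(a, b, match = 1, mismatch = -1, gap = -2) {
  memo <- new.env(hash = TRUE, parent = emptyenv())
  rec <- function(i, j) {
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    v <- if (i > length(a) && j > length(b)) {
      0
    } else if (i > length(a)) {
      gap * (length(b) - j + 1)
    } else if (j > length(b)) {
      gap * (length(a) - i + 1)
    } else {
      max(rec(i + 1, j + 1) + if (a[i] == b[j]) match else mismatch,
          rec(i + 1, j) + gap,
          rec(i, j + 1) + gap)
    }
    memo[[key]] <- v
    v
  }
  rec(1, 1)
}

# score of a pairing under the alignment objective
pairing_score <- function(a, b, pairs, match = 1, mismatch = -1, gap = -2) {
  sub <- sum(ifelse(a[pairs[, 1]] == b[pairs[, 2]], match, mismatch))
  # count gap positions implied by the monotone pairing
  gaps <- (length(a) - nrow(pairs)) + (length(b) - nrow(pairs))
  sub + gap * gaps
}

run_python <- function(code) {
  res <- suppressWarnings(
    system2("python", c("-c", shQuote(code)), stdout = TRUE, stderr = TRUE)
  )
  attr(res, "status") <- attr(res, "status") %||% 0L
  res
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# randomized valid card text for round-trip properties
random_card <- function(seed) {
  set.seed(seed)
  ngroups <- sample(1:3, 1)
  lines <- character()
  if (runif(1) < 0.5) {
    lines <- c(lines, paste(c("#REF", "ref.pdb",
                              if (runif(1) < 0.5) "A"), collapse = " "))
  }
  oid <- 0
  for (g in seq_len(ngroups)) {
    lines <- c(lines, paste("#G", paste0("grp", g)))
    for (e in seq_len(sample(0:3, 1))) {
      oid <- oid + 1
      lo <- sample(1:400, 1); hi <- lo + sample(0:3, 1)
      rng <- if (lo == hi) as.character(lo) else paste0(lo, "-", hi)
      tokens <- c(sprintf("m%d.pdb", oid),
                  if (runif(1) < 0.5) sprintf("m%d.mtz", oid),
                  sample(LETTERS, 1), rng, sprintf("obj%d", oid),
                  if (runif(1) < 0.5) sample(LETTERS, 1))
      lines <- c(lines, paste(tokens, collapse = " "))
    }
  }
  paste(lines, collapse = "\n")
}
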