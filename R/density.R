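# Map synthesis, fragment extraction, rigid resampling and sigma scaling.

# Expand a coefficient set to P1: apply every space-group operator to the
# Miller indices (F(h R) = F(h) exp(-2 pi i h.t)) and complete the Friedel
# mates.  Returns a data frame of unique (h,k,l) with complex F.
expand_to_p1 <- function(coef) {
  ops <- space_group_ops(coef$space_group)
  fc <- coef$f * exp(1i * coef$phi * pi / 180)
  env <- new.env(hash = TRUE, parent = emptyenv())
  put <- function(h, val) {
    key <- paste(h, collapse = ",")
    if (is.null(env[[key]])) env[[key]] <- c(h, Re(val), Im(val))
  }
  for (op in ops) {
    hs <- coef$hkl %*% op$rotation_frac       # row vector h times R
    phase <- exp(-2i * pi * as.numeric(coef$hkl %*% op$translation_frac))
    fs <- fc * phase
    for (i in seq_along(fs)) {
      put(hs[i, ], fs[i])
      put(-hs[i, ], Conj(fs[i]))
    }
  }
  rows <- do.call(rbind, as.list(env, sorted = FALSE))
  list(hkl = unname(rows[, 1:3, drop = FALSE]),
       f = complex(real = rows[, 4], imaginary = rows[, 5]))
}

#' Synthesize a real-space map from map coefficients
#'
#' Inverse Fourier synthesis rho(x) = (1/V) sum_h F(h) exp(-2 pi i h.x)
#' over the symmetry-expanded, Hermitian-completed reflection set,
#' evaluated by FFT on a full-unit-cell grid with spacing at most
#' `d_min / sample_rate` per axis (and fine enough that no reflection
#' aliases).  The mean and RMS of the full cell map are stored with the
#' grid and travel with every fragment cut from it.
#'
#' @param coef A `map_coefficients` object.
#' @param sample_rate Grid oversampling relative to `d_min` (default 3);
#'   values below 2 would undersample the map and are an error.
#' @return A periodic cell-aligned `density_grid`.
#' @export
synthesize_map <- function(coef, sample_rate = 3.0) {
  stopifnot(inherits(coef, "map_coefficients"))
  if (sample_rate < 2) stop("sample_rate below 2 undersamples the map")
  if (nrow(coef$hkl) == 0) stop("empty coefficient set")
  p1 <- expand_to_p1(coef)
  hmax <- apply(abs(p1$hkl), 2, max)
  frame <- cell_frame(coef$cell)
  n <- pmax(ceiling(coef$cell[1:3] * sample_rate /
                      min(coef$d_min, coef$cell[1:3])),
            2 * hmax + 1, 4)
  amp <- array(0i, dim = n)
  idx <- sweep(p1$hkl, 2, n, "%%") + 1
  amp[cbind(idx[, 1], idx[, 2], idx[, 3])] <- p1$f
  rho <- Re(stats::fft(amp)) / frame$volume
  new_density_grid(rho, cell = coef$cell, start = c(0L, 0L, 0L), msize = n,
                   periodic = TRUE, space_group = coef$space_group)
}

#' Extract a map fragment around an atom selection
#'
#' Cuts the minimal axis-aligned subgrid (same spacing and orientation as
#' the parent) containing every point within `radius` of any selected
#' atom.  When the parent covers a full periodic cell the fragment wraps
#' across cell boundaries as needed.  The parent's mean/sigma are carried
#' over, so the fragment contours identically to the full map.
#'
#' @param g A `density_grid`.
#' @param atoms A `xtal_structure` (or anything with x/y/z columns in
#'   `$atoms`) giving the selection, in the same frame as the map.
#' @param radius Extraction radius in Angstrom (pipeline default 3,
#'   standalone extraction default 9).
#' @return A `density_grid` fragment.
#' @export
extract_fragment <- function(g, atoms, radius = 3.0) {
  stopifnot(inherits(g, "density_grid"))
  xyz <- if (inherits(atoms, "xtal_structure")) coords(atoms) else as.matrix(atoms)
  if (nrow(xyz) == 0) stop("empty selection")
  sinv <- solve(g$step)
  u <- sweep(xyz, 2, g$origin) %*% t(sinv)    # continuous 0-based indices
  pad <- radius * sqrt(rowSums(sinv^2))       # index change per Angstrom
  lo <- floor(apply(sweep(u, 2, pad), 2, min))
  hi <- ceiling(apply(sweep(u, 2, pad, "+"), 2, max))
  d <- dim(g$values)
  if (g$periodic) {
    n_keep <- pmin(hi - lo + 1, d)
    hi <- lo + n_keep - 1
    ii <- lapply(1:3, function(a) ((lo[a]:hi[a]) %% d[a]) + 1)
    vals <- g$values[ii[[1]], ii[[2]], ii[[3]], drop = FALSE]
    new_density_grid(vals, cell = g$cell, start = as.integer(g$start + lo),
                     msize = g$msize, sigma = g$sigma, mean = g$mean,
                     space_group = g$space_group)
  } else {
    atom_inside <- rowSums(u >= -0.5 & sweep(u, 2, d - 0.5) <= 0) == 3
    lo2 <- pmax(lo, 0); hi2 <- pmin(hi, d - 1)
    if (!any(atom_inside) || any(lo2 > hi2)) {
      stop("selection not covered by map")
    }
    vals <- g$values[(lo2[1]:hi2[1]) + 1, (lo2[2]:hi2[2]) + 1,
                     (lo2[3]:hi2[3]) + 1, drop = FALSE]
    if (!is.null(g$cell)) {
      new_density_grid(vals, cell = g$cell,
                       start = as.integer(g$start + lo2), msize = g$msize,
                       sigma = g$sigma, mean = g$mean,
                       space_group = g$space_group)
    } else {
      new_density_grid(vals, origin = g$origin + as.numeric(g$step %*% lo2),
                       step = g$step, sigma = g$sigma, mean = g$mean)
    }
  }
}

#' Resample a density grid under a rigid transform
#'
#' Produces an axis-aligned Cartesian grid in the target (reference) frame
#' covering the transformed bounding box of `g`, at spacing comparable to
#' the source grid.  Each output node takes the trilinearly interpolated
#' value of `g` at the pre-image position; nodes falling outside a
#' non-periodic source get value 0 and reduce the reported `coverage`
#' fraction.  Exact cases stay exact: the identity on an axis-aligned
#' orthogonal grid and rotations mapping grid nodes onto grid nodes
#' reproduce node values to machine precision.
#'
#' @param g A `density_grid`.
#' @param t A `rigid_transform` (mobile-to-reference, as produced by
#'   [superpose_chains()]).
#' @return A Cartesian `density_grid` with the parent's sigma/mean.
#' @export
transform_map <- function(g, t) {
  stopifnot(inherits(g, "density_grid"), inherits(t, "rigid_transform"))
  d <- dim(g$values)
  m <- t$rotation %*% g$step                 # transformed step vectors
  # output spacing: per Cartesian axis, the dominant transformed step
  sp <- apply(abs(m), 1, max)
  corners0 <- as.matrix(expand.grid(c(0, d[1] - 1), c(0, d[2] - 1),
                                    c(0, d[3] - 1)))
  corners <- transform_points(grid_positions(g, corners0), t)
  lo <- apply(corners, 2, min); hi <- apply(corners, 2, max)
  n <- pmax(floor((hi - lo) / sp + 1e-9) + 1, 2)

  idx0 <- as.matrix(expand.grid(0:(n[1] - 1), 0:(n[2] - 1), 0:(n[3] - 1)))
  y <- sweep(idx0 %*% diag(sp), 2, lo, "+")
  tinv <- invert_transform(t)
  u <- sweep(transform_points(y, tinv), 2, g$origin) %*% t(solve(g$step))
  vals_cov <- interp_trilinear(g, u)
  arr <- array(vals_cov$values, dim = n)
  new_density_grid(arr, origin = lo, step = diag(sp),
                   sigma = g$sigma, mean = g$mean,
                   coverage = vals_cov$coverage)
}

# trilinear interpolation of grid g at continuous 0-based indices u (Nx3);
# periodic grids wrap, others zero-fill outside
interp_trilinear <- function(g, u) {
  d <- dim(g$values)
  # snap near-integer indices so node-coincident sampling is exact
  u <- ifelse(abs(u - round(u)) < 1e-9, round(u), u)
  f0 <- floor(u)
  w <- u - f0
  vals <- numeric(nrow(u))
  covered <- rep(TRUE, nrow(u))
  fetch <- function(ijk) {
    if (g$periodic) {
      ijk <- sweep(ijk, 2, d, "%%")
      ok <- rep(TRUE, nrow(ijk))
    } else {
      ok <- ijk[, 1] >= 0 & ijk[, 1] < d[1] &
        ijk[, 2] >= 0 & ijk[, 2] < d[2] &
        ijk[, 3] >= 0 & ijk[, 3] < d[3]
      ijk[!ok, ] <- 0
    }
    v <- g$values[cbind(ijk[, 1], ijk[, 2], ijk[, 3]) + 1]
    v[!ok] <- 0
    list(v = v, ok = ok)
  }
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    wt <- (if (dx) w[, 1] else 1 - w[, 1]) *
          (if (dy) w[, 2] else 1 - w[, 2]) *
          (if (dz) w[, 3] else 1 - w[, 3])
    active <- wt > 0
    if (!any(active)) next
    got <- fetch(sweep(f0, 2, c(dx, dy, dz), "+"))
    vals <- vals + wt * got$v
    covered <- covered & (got$ok | wt == 0)
  }
  list(values = vals, coverage = base::mean(covered))
}

#' Sigma-scale a density grid
#'
#' Rescales values to `(v - mean) / sigma` using the parent full-map mean
#' and RMS, so contouring the result at 1.0 shows the surface a viewer
#' would draw at the conventional "1 sigma" level of the parent map.
#' Idempotent on already-scaled grids (stored mean 0, sigma 1).
#'
#' @param g A `density_grid` with positive parent sigma.
#' @return The scaled `density_grid` (stored mean 0, sigma 1).
#' @export
sigma_scale <- function(g) {
  stopifnot(inherits(g, "density_grid"))
  if (!is.finite(g$sigma) || g$sigma <= 0) {
    stop("flat map: sigma is zero, cannot sigma-scale")
  }
  g$values <- (g$values - g$mean) / g$sigma
  g$mean <- 0
  g$sigma <- 1
  g
}
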