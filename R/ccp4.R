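# Real-space density grids and CCP4/MRC map I/O.
#
# A `density_grid` stores values on a regular 3D lattice plus the geometry
# needed to place it in Cartesian space, and the mean/RMS of the parent
# full map (so a fragment contours exactly like the map it was cut from).
#
# Two geometries occur:
#  * cell-aligned: axes follow the crystal axes; the grid is `start` +
#    dim nodes out of a full-cell sampling `msize`, possibly periodic
#    (covering the whole cell).  Written with the start-index convention.
#  * Cartesian: axis-aligned orthogonal grid with an arbitrary origin
#    (e.g. after rigid transformation).  Written with the ORIGIN vector
#    convention, as cryoEM maps use.

new_density_grid <- function(values, cell = NULL, start = NULL, msize = NULL,
                             origin = NULL, step = NULL,
                             sigma = NULL, mean = NULL, periodic = FALSE,
                             space_group = NA_character_,
                             coverage = 1.0) {
  values <- unname(values)
  stopifnot(length(dim(values)) == 3, all(dim(values) >= 2))
  if (!is.null(cell)) {
    frame <- cell_frame(cell)
    stopifnot(length(msize) == 3, length(start) == 3)
    step <- frame$orth %*% diag(1 / msize)
    origin <- as.numeric(frame$orth %*% (start / msize))
    periodic <- periodic && all(dim(values) == msize) && all(start == 0)
  } else {
    stopifnot(length(origin) == 3, all(dim(step) == c(3, 3)))
    periodic <- FALSE
  }
  if (abs(det(step)) < 1e-12) stop("grid step vectors are not independent")
  if (is.null(mean)) mean <- base::mean(values)
  if (is.null(sigma)) sigma <- stats::sd(as.numeric(values)) *
      sqrt((length(values) - 1) / length(values))
  structure(list(values = values, cell = cell, start = start, msize = msize,
                 origin = as.numeric(origin), step = unname(step),
                 sigma = sigma, mean = mean, periodic = periodic,
                 space_group = space_group, coverage = coverage),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<density_grid> %d x %d x %d voxels%s, sigma %.4g, mean %.4g\n",
              d[1], d[2], d[3], if (x$periodic) " (full periodic cell)" else "",
              x$sigma, x$mean))
  invisible(x)
}

#' Summary statistics of a density grid
#' @param x A `density_grid`.
#' @param ... Unused.
#' @return One-row tibble: dimensions, voxel volume, parent mean/sigma,
#'   value range, coverage fraction.
#' @method glance density_grid
#' @export
glance.density_grid <- function(x, ...) {
  d <- dim(x$values)
  tibble::tibble(nx = d[1], ny = d[2], nz = d[3],
                 voxel_volume = abs(det(x$step)),
                 parent_mean = x$mean, parent_sigma = x$sigma,
                 min = min(x$values), max = max(x$values),
                 periodic = x$periodic, coverage = x$coverage)
}

# Cartesian positions of grid nodes for 0-based index triples (Nx3)
grid_positions <- function(g, idx0) {
  sweep(as.matrix(idx0) %*% t(g$step), 2, g$origin, "+")
}

#' Write a density grid as a CCP4/MRC map
#'
#' Mode-2 (float32) maps.  Cell-aligned grids are written with the
#' start-index convention against the full crystal cell; Cartesian grids
#' are written as orthogonal pseudo-cells with the MRC ORIGIN vector.
#'
#' @param g A `density_grid`.
#' @param path Output path.
#' @param label Text stored in the map's label field.
#' @return `path`, invisibly.
#' @export
write_map <- function(g, path, label = "density fragment") {
  stopifnot(inherits(g, "density_grid"))
  d <- dim(g$values)
  if (any(d < 2)) stop("refusing to write a degenerate map")
  if (!is.null(g$cell)) {
    cell <- g$cell; msize <- g$msize; start <- g$start; origin <- c(0, 0, 0)
  } else {
    if (max(abs(g$step - diag(diag(g$step)))) > 1e-6) {
      stop("only axis-aligned Cartesian grids can be written")
    }
    sp <- diag(g$step)
    cell <- c(d * sp, 90, 90, 90); msize <- d; start <- c(0L, 0L, 0L)
    origin <- g$origin
  }
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(d)                      # NX NY NZ
  wi(2)                      # MODE 2: float32
  wi(start)                  # NXSTART..
  wi(msize)                  # MX MY MZ
  wf(cell)                   # CELL
  wi(c(1, 2, 3))             # MAPC MAPR MAPS
  wf(c(min(g$values), max(g$values), g$mean))
  sgnum <- if (!is.na(g$space_group)) {
    tab <- sohncke_table()
    n <- tab$number[tab$key == normalize_sg_symbol(g$space_group)][1]
    if (is.na(n)) 1L else n
  } else 1L
  wi(sgnum)                  # ISPG
  wi(0)                      # NSYMBT
  wi(rep(0L, 25))            # words 25-49 (extra)
  wf(origin)                 # words 50-52 ORIGIN
  writeBin(charToRaw("MAP "), con)
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)
  wf(g$sigma)                # word 55 RMS
  wi(1)                      # NLABL
  lab <- sprintf("%-80s", substr(label, 1, 80))
  writeBin(charToRaw(paste0(lab, strrep(" ", 80 * 9))), con)
  wf(as.numeric(g$values))   # column-major == column fastest
  invisible(path)
}

#' Read a CCP4/MRC density map
#'
#' Honors both origin conventions (start indices and the MRC ORIGIN
#' vector) and non-default axis orders.  The stored mean/RMS are
#' recomputed over all voxels.
#'
#' @param path Map file path.
#' @return A `density_grid`.
#' @export
read_direct_map <- function(path) {
  if (!file.exists(path)) stop("cannot read map file: ", path)
  sz <- file.info(path)$size
  if (sz < 1024 + 4) stop("corrupt map header (file too small): ", path)
  raw <- readBin(path, "raw", n = sz)
  endian <- "little"
  mode <- readBin(raw[13:16], "integer", size = 4, endian = endian)
  if (mode < 0 || mode > 6) endian <- "big"
  ri <- function(w, n = 1) readBin(raw[((w - 1) * 4 + 1):((w - 1 + n) * 4)],
                                   "integer", n = n, size = 4, endian = endian)
  rf <- function(w, n = 1) readBin(raw[((w - 1) * 4 + 1):((w - 1 + n) * 4)],
                                   "numeric", n = n, size = 4, endian = endian)
  d <- ri(1, 3); mode <- ri(4); start <- ri(5, 3); msize <- ri(8, 3)
  cell <- rf(11, 6); axmap <- ri(17, 3); nsymbt <- ri(24)
  origin_vec <- rf(50, 3)
  if (mode != 2) stop("unsupported map mode ", mode, " (only float32): ", path)
  if (any(d <= 0) || any(msize <= 0) || any(cell[1:3] <= 0)) {
    stop("corrupt map header: ", path)
  }
  nvox <- prod(d)
  data_off <- 1024 + nsymbt
  if (sz < data_off + 4 * nvox) stop("map data truncated: ", path)
  vals <- readBin(raw[(data_off + 1):(data_off + 4 * nvox)], "numeric",
                  n = nvox, size = 4, endian = endian)
  arr <- array(vals, dim = d)
  # permute so that array axes follow crystal axes a,b,c
  if (!all(axmap == c(1, 2, 3))) {
    perm <- order(axmap)
    arr <- aperm(arr, perm)
    start <- start[perm]
    d <- dim(arr)
  }
  is_ortho <- all(abs(cell[4:6] - 90) < 1e-4)
  if (any(abs(origin_vec) > 1e-6) && is_ortho) {
    # MRC convention: Cartesian origin vector, orthogonal axes
    sp <- cell[1:3] / msize
    new_density_grid(arr, origin = origin_vec + start * sp,
                     step = diag(sp))
  } else {
    periodic <- all(d == msize) && all(start == 0)
    new_density_grid(arr, cell = cell, start = start, msize = msize,
                     periodic = periodic)
  }
}
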