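# Density machinery: MTZ coefficients, Fourier synthesis vs direct
# summation, CCP4 round-trips, fragment extraction, rigid resampling,
# sigma scaling.

fixture_coef <- function(d_min = 4.0) {
  fx <- make_complex()
  make_coefficients(fx$structure, d_min = d_min)
}

test_that("MTZ write/read round-trips coefficients and metadata", {
  coef <- fixture_coef()
  f <- withr::local_tempfile(fileext = ".mtz")
  write_mtz(coef, f)
  back <- read_map_coefficients(f)
  expect_equal(nrow(back$hkl), nrow(coef$hkl))
  expect_equal(back$labels, c("FWT", "PHWT"))
  expect_equal(back$space_group, coef$space_group)
  expect_equal(back$cell, coef$cell, tolerance = 1e-4)
  ord0 <- order(coef$hkl[, 1], coef$hkl[, 2], coef$hkl[, 3])
  ord1 <- order(back$hkl[, 1], back$hkl[, 2], back$hkl[, 3])
  expect_equal(back$hkl[ord1, ], coef$hkl[ord0, ], ignore_attr = TRUE)
  expect_lt(max(abs(back$f[ord1] - coef$f[ord0])), 1e-3)
  expect_lt(max(abs(back$phi[ord1] - coef$phi[ord0])), 1e-3)
})

test_that("the Phenix-style label pair is used as fallback", {
  coef <- fixture_coef()
  alt <- ligalign:::new_map_coefficients(coef$hkl, coef$f, coef$phi,
                                         coef$cell, coef$space_group,
                                         labels = c("2FOFCWT", "PH2FOFCWT"))
  f <- withr::local_tempfile(fileext = ".mtz")
  write_mtz(alt, f)
  back <- read_map_coefficients(f)
  expect_equal(back$labels, c("2FOFCWT", "PH2FOFCWT"))
  expect_equal(nrow(back$hkl), nrow(coef$hkl))
})

test_that("an MTZ without map coefficients is rejected with its columns", {
  coef <- fixture_coef()
  fp <- ligalign:::new_map_coefficients(coef$hkl, coef$f, coef$phi,
                                        coef$cell, coef$space_group,
                                        labels = c("FP", "SIGFP"))
  f <- withr::local_tempfile(fileext = ".mtz")
  write_mtz(fp, f)
  expect_error(read_map_coefficients(f), "FP.*SIGFP|columns found")
  expect_error(read_map_coefficients(tempfile(fileext = ".mtz")),
               "cannot read")
})

test_that("a DC-only coefficient set synthesizes a constant map", {
  cell <- c(20, 24, 28, 90, 90, 90)
  vol <- cell_frame(cell)$volume
  dc <- ligalign:::new_map_coefficients(matrix(c(0, 0, 0), 1), vol, 0,
                                        cell, "P 1")
  g <- synthesize_map(dc)
  expect_equal(max(abs(g$values - 1)), 0, tolerance = 1e-10)
})

test_that("a single reflection gives the analytic cosine wave", {
  cell <- c(20, 20, 20, 90, 90, 90)
  vol <- cell_frame(cell)$volume
  one <- ligalign:::new_map_coefficients(matrix(c(1, 0, 0), 1), 1, 0,
                                         cell, "P 1")
  g <- synthesize_map(one)
  n <- dim(g$values)
  set.seed(6)
  for (i in 1:20) {
    ijk <- c(sample(n[1], 1), sample(n[2], 1), sample(n[3], 1))
    x <- (ijk - 1) / n
    expected <- 2 * cos(2 * pi * x[1]) / vol     # reflection + Friedel mate
    expect_equal(g$values[ijk[1], ijk[2], ijk[3]], expected,
                 tolerance = 1e-8)
  }
})

test_that("synthesis matches direct summation on the full fixture set", {
  coef <- fixture_coef()
  g <- synthesize_map(coef)
  n <- dim(g$values)
  set.seed(7)
  pts <- cbind(sample(n[1], 25, TRUE), sample(n[2], 25, TRUE),
               sample(n[3], 25, TRUE))
  frac <- sweep(pts - 1, 2, n, "/")
  expected <- direct_density(coef, frac)
  got <- g$values[pts]
  expect_lt(max(abs(got - expected)), 1e-6 * g$sigma)
})

test_that("map variance obeys the Parseval identity", {
  coef <- fixture_coef()
  g <- synthesize_map(coef, sample_rate = 3)
  p1 <- ligalign:::expand_to_p1(coef)
  vol <- cell_frame(coef$cell)$volume
  nondc <- rowSums(abs(p1$hkl)) > 0
  expected_var <- sum(Mod(p1$f[nondc])^2) / vol^2
  got_var <- mean((g$values - mean(g$values))^2)
  expect_equal(got_var, expected_var, tolerance = 0.01 * expected_var)
})

test_that("sub-Nyquist sampling rates are refused", {
  expect_error(synthesize_map(fixture_coef(), sample_rate = 1.5),
               "sample_rate")
})

test_that("CCP4 maps round-trip through write/read", {
  coef <- fixture_coef()
  g <- synthesize_map(coef)
  f <- withr::local_tempfile(fileext = ".ccp4")
  write_map(g, f)
  back <- read_direct_map(f)
  expect_equal(dim(back$values), dim(g$values))
  expect_lt(max(abs(back$values - g$values)), 1e-6 * max(abs(g$values)))
  expect_true(back$periodic)
  expect_equal(back$cell, g$cell, tolerance = 1e-4)
  expect_equal(back$origin, g$origin)
})

test_that("nonzero start indices shift the origin against a landmark", {
  fx <- make_complex()
  g <- synthesize_map(make_coefficients(fx$structure, d_min = 4))
  frag <- extract_fragment(g, fx$ligand, radius = 3)
  expect_true(any(frag$start != 0))
  f <- withr::local_tempfile(fileext = ".ccp4")
  write_map(frag, f)
  back <- read_direct_map(f)
  expect_equal(back$start, frag$start)
  expect_equal(back$origin, frag$origin, tolerance = 1e-5)
  # landmark: the global fragment maximum sits at the same Cartesian spot
  i0 <- which(frag$values == max(frag$values), arr.ind = TRUE)[1, ]
  i1 <- which(back$values == max(back$values), arr.ind = TRUE)[1, ]
  p0 <- ligalign:::grid_positions(frag, matrix(i0 - 1, 1))
  p1 <- ligalign:::grid_positions(back, matrix(i1 - 1, 1))
  expect_lt(max(abs(p0 - p1)), 1e-4)
})

test_that("corrupt and degenerate map files are rejected", {
  f <- withr::local_tempfile(fileext = ".ccp4")
  writeBin(raw(100), f)
  expect_error(read_direct_map(f), "corrupt|too small")
  g0 <- ligalign:::new_density_grid(array(0, dim = c(2, 2, 2)) + 1:8,
                                    origin = c(0, 0, 0), step = diag(3))
  g0$values <- array(g0$values[1], dim = c(1, 1, 1))
  expect_error(write_map(g0, tempfile()), "degenerate")
})

test_that("fragments contain every point within the radius", {
  fx <- make_complex()
  g <- synthesize_map(make_coefficients(fx$structure, d_min = 4))
  for (radius in c(3, 9)) {
    frag <- extract_fragment(g, fx$ligand, radius = radius)
    # exhaustive scan: walk a fine lattice of offsets around each atom
    xyz <- as.matrix(fx$ligand$atoms[, c("x", "y", "z")])
    offs <- as.matrix(expand.grid(o1 = c(-1, 0, 1), o2 = c(-1, 0, 1),
                                  o3 = c(-1, 0, 1)))
    offs <- offs / sqrt(pmax(rowSums(offs^2), 1)) * radius * 0.999
    pts <- do.call(rbind, lapply(seq_len(nrow(xyz)),
                                 function(i) sweep(offs, 2, xyz[i, ], "+")))
    u <- sweep(pts, 2, frag$origin) %*% t(solve(frag$step))
    d <- dim(frag$values)
    expect_true(all(u >= -1e-9 & sweep(u, 2, d - 1) <= 1e-9),
                info = paste("radius", radius))
  }
  # a radius spanning the whole periodic cell returns the full cell
  whole <- extract_fragment(g, fx$ligand, radius = 100)
  expect_equal(dim(whole$values), dim(g$values))
  expect_equal(sum(whole$values), sum(g$values), tolerance = 1e-9)
})

test_that("selections outside a non-periodic map are rejected", {
  g <- ligalign:::new_density_grid(array(stats::rnorm(1000), c(10, 10, 10)),
                                   origin = c(0, 0, 0), step = diag(3))
  far <- toy_structure(toy_atoms(rbind(c(50, 50, 50))))
  expect_error(extract_fragment(g, far, radius = 0.5), "not covered")
})

test_that("transform_map is exact for identity, shifts and rotations", {
  set.seed(11)
  cube <- ligalign:::new_density_grid(array(stats::rnorm(12^3), c(12, 12, 12)),
                                      origin = c(2, -1, 4), step = diag(3) * 0.8)
  tid <- transform_map(cube, rigid_transform())
  expect_identical(dim(tid$values), dim(cube$values))
  expect_equal(max(abs(tid$values - cube$values)), 0)

  sh <- transform_map(cube, rigid_transform(diag(3), c(2, 1, 3) * 0.8))
  expect_equal(max(abs(sh$values - cube$values)), 0)
  expect_equal(sh$origin, cube$origin + c(2, 1, 3) * 0.8)

  rz <- rigid_transform(matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, byrow = TRUE))
  rot <- transform_map(cube, rz)
  oracle <- aperm(cube$values[, 12:1, ], c(2, 1, 3))
  expect_lt(max(abs(rot$values - oracle)), 1e-10)
})

test_that("transforming there and back reproduces interior values", {
  fx <- make_complex()
  g <- synthesize_map(make_coefficients(fx$structure, d_min = 4))
  frag <- extract_fragment(g, fx$ligand, radius = 4)
  m <- random_motion(19, max_shift = 5)
  back <- transform_map(transform_map(frag, m), invert_transform(m))
  # compare on the interior region of the original fragment
  d <- dim(frag$values)
  u <- ligalign:::grid_positions(frag,
        as.matrix(expand.grid(1:(d[1] - 2), 1:(d[2] - 2), 1:(d[3] - 2))))
  ui <- sweep(u, 2, back$origin) %*% t(solve(back$step))
  got <- ligalign:::interp_trilinear(back, ui)$values
  ref <- as.numeric(frag$values[2:(d[1] - 1), 2:(d[2] - 1), 2:(d[3] - 1)])
  # double trilinear resampling smooths; bound the error against the
  # fragment's value scale rather than expecting exactness
  expect_lt(stats::median(abs(got - ref)), 0.2 * g$sigma)
  expect_gt(stats::cor(got, ref), 0.95)
})

test_that("sigma scaling normalizes and is idempotent; flat maps error", {
  set.seed(13)
  g <- ligalign:::new_density_grid(array(stats::rnorm(20^3, 5, 2), c(20, 20, 20)),
                                   origin = c(0, 0, 0), step = diag(3))
  sc <- sigma_scale(g)
  expect_lt(abs(mean(sc$values)), 1e-6)
  expect_equal(sqrt(mean((sc$values - mean(sc$values))^2)), 1,
               tolerance = 1e-6)
  sc2 <- sigma_scale(sc)
  expect_equal(sc2$values, sc$values)

  flat <- ligalign:::new_density_grid(array(7, c(4, 4, 4)),
                                      origin = c(0, 0, 0), step = diag(3))
  expect_error(sigma_scale(flat), "flat map")
})
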