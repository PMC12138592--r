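# Minimal MTZ (CCP4 reflection file) reader and writer.
#
# Only what the pipeline needs: the CELL, SYMINF and COLUMN header records
# and the float32 reflection block.  The reader pulls one amplitude/phase
# column pair for map synthesis; the writer emits fixture files carrying
# weighted 2Fo-Fc coefficients under the conventional FWT/PHWT labels.

# Preferred map-coefficient column pairs, in order: Refmac-style first,
# then the Phenix/Buster labels.
MAP_LABEL_PAIRS <- list(c("FWT", "PHWT"), c("2FOFCWT", "PH2FOFCWT"))

new_map_coefficients <- function(hkl, f, phi, cell, space_group,
                                 labels = c("FWT", "PHWT")) {
  hkl <- as.matrix(hkl)
  stopifnot(ncol(hkl) == 3, nrow(hkl) == length(f), length(f) == length(phi))
  if (anyDuplicated(paste(hkl[, 1], hkl[, 2], hkl[, 3]))) {
    stop("duplicate Miller indices in coefficient set")
  }
  frame <- cell_frame(cell)
  s2 <- rowSums((hkl %*% frame$frac)^2)
  d_min <- if (any(s2 > 0)) 1 / sqrt(max(s2)) else Inf
  structure(list(hkl = hkl, f = as.numeric(f), phi = as.numeric(phi),
                 cell = cell, space_group = space_group,
                 d_min = d_min, labels = labels),
            class = "map_coefficients")
}

#' @export
print.map_coefficients <- function(x, ...) {
  cat(sprintf("<map_coefficients> %d reflections to %.2f A (%s/%s), %s\n",
              nrow(x$hkl), x$d_min, x$labels[1], x$labels[2], x$space_group))
  invisible(x)
}

#' Map coefficients as a tibble
#' @param x A `map_coefficients` object.
#' @param ... Unused.
#' @return Tibble with columns h, k, l, f, phi.
#' @method tidy map_coefficients
#' @export
tidy.map_coefficients <- function(x, ...) {
  tibble::tibble(h = x$hkl[, 1], k = x$hkl[, 2], l = x$hkl[, 3],
                 f = x$f, phi = x$phi)
}

#' Read weighted 2Fo-Fc map coefficients from an MTZ file
#'
#' Looks for the column pair `FWT`/`PHWT` (Refmac) and falls back to
#' `2FOFCWT`/`PH2FOFCWT` (Phenix, Buster).  Reflections with missing
#' values in either column are dropped.  Other refinement outputs are
#' rejected with a message listing the columns that were found.
#'
#' @param path MTZ file path.
#' @return A `map_coefficients` object.
#' @export
read_map_coefficients <- function(path) {
  mtz <- read_mtz_raw(path)
  labels <- NULL
  for (pair in MAP_LABEL_PAIRS) {
    if (all(pair %in% mtz$columns$label)) { labels <- pair; break }
  }
  if (is.null(labels)) {
    stop("no 2Fo-Fc map coefficients (FWT/PHWT or 2FOFCWT/PH2FOFCWT) in ",
         path, "; columns found: ", paste(mtz$columns$label, collapse = ", "))
  }
  need <- c("H", "K", "L", labels)
  ci <- match(need, mtz$columns$label)
  if (any(is.na(ci))) stop("MTZ lacks H,K,L index columns: ", path)
  dat <- mtz$data[, ci, drop = FALSE]
  ok <- stats::complete.cases(dat) & is.finite(dat[, 4]) & is.finite(dat[, 5])
  dat <- dat[ok, , drop = FALSE]
  new_map_coefficients(hkl = round(dat[, 1:3]), f = dat[, 4], phi = dat[, 5],
                       cell = mtz$cell, space_group = mtz$space_group,
                       labels = labels)
}

read_mtz_raw <- function(path) {
  if (!file.exists(path)) stop("cannot read MTZ file: ", path)
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 84 || rawToChar(raw[1:4]) != "MTZ ") {
    stop("not an MTZ file: ", path)
  }
  endian <- "little"
  hdr_pos <- readBin(raw[5:8], "integer", size = 4, endian = endian)
  if (hdr_pos <= 20 || hdr_pos * 4 > length(raw) + 4) {
    endian <- "big"
    hdr_pos <- readBin(raw[5:8], "integer", size = 4, endian = endian)
  }
  if (hdr_pos <= 20 || (hdr_pos - 1) * 4 > length(raw)) {
    stop("corrupt MTZ header pointer in ", path)
  }
  hdr_start <- (hdr_pos - 1) * 4
  nrec <- (length(raw) - hdr_start) %/% 80
  recs <- vapply(seq_len(nrec), function(i) {
    rawToChar(raw[(hdr_start + (i - 1) * 80 + 1):(hdr_start + i * 80)])
  }, character(1))

  get_rec <- function(tag) {
    hit <- recs[startsWith(recs, tag)]
    if (length(hit) == 0) return(NULL)
    trimws(sub(paste0("^", tag), "", hit[[1]]))
  }
  ncol_rec <- strsplit(get_rec("NCOL"), "[[:space:]]+")[[1]]
  ncol <- as.integer(ncol_rec[1]); nref <- as.integer(ncol_rec[2])
  cell <- as.numeric(strsplit(get_rec("CELL"), "[[:space:]]+")[[1]])[1:6]
  syminf <- get_rec("SYMINF")
  sg <- if (!is.null(syminf)) {
    m <- regmatches(syminf, regexec("'([^']+)'", syminf))[[1]]
    if (length(m) == 2) m[2] else NA_character_
  } else NA_character_

  col_recs <- recs[startsWith(recs, "COLUMN")]
  cols <- do.call(rbind, lapply(col_recs, function(r) {
    tk <- strsplit(trimws(sub("^COLUMN", "", r)), "[[:space:]]+")[[1]]
    data.frame(label = tk[1], type = tk[2], stringsAsFactors = FALSE)
  }))
  if (is.null(cols) || nrow(cols) != ncol) {
    stop("inconsistent COLUMN records in ", path)
  }
  data <- readBin(raw[81:(80 + 4 * ncol * nref)], "numeric",
                  n = ncol * nref, size = 4, endian = endian)
  data <- matrix(data, nrow = nref, ncol = ncol, byrow = TRUE)
  # MTZ missing-number flag is NaN by default (VALM NAN)
  list(cell = cell, space_group = sg, columns = cols, data = data)
}

#' Write map coefficients to an MTZ file
#'
#' Emits a minimal standard MTZ with columns H, K, L and the coefficient
#' pair under the object's labels (FWT/PHWT by default), readable by
#' crystallographic software.
#'
#' @param coef A `map_coefficients` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mtz <- function(coef, path) {
  stopifnot(inherits(coef, "map_coefficients"))
  nref <- nrow(coef$hkl)
  if (nref == 0) stop("refusing to write an empty reflection set")
  ops <- space_group_ops(coef$space_group)
  tab <- sohncke_table()
  sg_number <- tab$number[tab$key == normalize_sg_symbol(coef$space_group)][1]
  n_prim <- sum(vapply(ops, function(o) all(o$translation_frac %% 1 == 0) ||
                         !all(o$rotation_frac == diag(3)), logical(1)))
  # primitive ops = total / centering multiplicity
  n_cent <- sum(vapply(ops, function(o) all(o$rotation_frac == diag(3)),
                       logical(1)))
  n_prim <- length(ops) %/% n_cent
  lattice <- substr(gsub(" ", "", coef$space_group), 1, 1)

  frame <- cell_frame(coef$cell)
  s2 <- rowSums((coef$hkl %*% frame$frac)^2)
  dat <- cbind(coef$hkl, coef$f, coef$phi)
  labels <- c("H", "K", "L", coef$labels)
  types <- c("H", "H", "H", "F", "P")

  pad80 <- function(s) sprintf("%-80s", substr(s, 1, 80))
  hdr <- c(
    "VERS MTZ:V1.1",
    sprintf("TITLE synthetic fixture coefficients"),
    sprintf("NCOL %8d %12d %8d", length(labels), nref, 0L),
    sprintf("CELL  %9.4f %9.4f %9.4f %9.4f %9.4f %9.4f",
            coef$cell[1], coef$cell[2], coef$cell[3],
            coef$cell[4], coef$cell[5], coef$cell[6]),
    "SORT    1   2   3   0   0",
    sprintf("SYMINF %3d %2d %s %5d '%s' PG1", length(ops), n_prim,
            lattice, sg_number, coef$space_group),
    vapply(ops, function(o) paste0("SYMM ", toupper(op_triplet(o))),
           character(1)),
    sprintf("RESO %12.6f %12.6f", min(s2), max(s2)),
    "VALM NAN",
    sprintf("COLUMN %-30s %s %17.4f %17.4f     1",
            labels, types, apply(dat, 2, min), apply(dat, 2, max)),
    "NDIF        1",
    "PROJECT       1 fixture",
    "CRYSTAL       1 fixture",
    "DATASET       1 fixture",
    sprintf("DCELL         1 %9.4f %9.4f %9.4f %9.4f %9.4f %9.4f",
            coef$cell[1], coef$cell[2], coef$cell[3],
            coef$cell[4], coef$cell[5], coef$cell[6]),
    "DWAVEL        1    1.00000",
    "END",
    "MTZENDOFHEADERS"
  )

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("MTZ "), con)
  hdr_word <- 21L + length(dat)  # 1-based word index of first header record
  writeBin(hdr_word, con, size = 4, endian = "little")
  writeBin(as.raw(c(0x44, 0x41, 0x00, 0x00)), con)  # little-endian stamp
  writeBin(raw(80 - 12), con)                       # pad to data start
  writeBin(as.numeric(t(dat)), con, size = 4, endian = "little")
  writeBin(charToRaw(paste(vapply(hdr, pad80, character(1)), collapse = "")),
           con)
  invisible(path)
}

# fractional symmetry operator back to a triplet string like "-x+1/2,y,z"
op_triplet <- function(op) {
  axis_names <- c("x", "y", "z")
  frac_str <- function(t) {
    if (abs(t) < 1e-9) return("")
    for (den in c(2, 3, 4, 6)) {
      num <- round(t * den)
      if (abs(t - num / den) < 1e-9) {
        return(paste0(if (num > 0) "+" else "-", abs(num), "/", den))
      }
    }
    stop("cannot render translation ", t, " as a fraction")
  }
  parts <- vapply(1:3, function(i) {
    terms <- ""
    for (j in 1:3) {
      cij <- op$rotation_frac[i, j]
      if (cij == 0) next
      sgn <- if (cij > 0) (if (nzchar(terms)) "+" else "") else "-"
      terms <- paste0(terms, sgn, axis_names[j])
    }
    paste0(terms, frac_str(op$translation_frac[i]))
  }, character(1))
  paste(parts, collapse = ",")
}
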