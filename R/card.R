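# Input-card parsing and serialization.
#
# A card is a plain-text file describing a series of ligand-bound structures:
#   #REF <coords> [<chain>]          optional, first non-comment line only
#   #G <groupname>                   opens a display group
#   <coords> [<map>] <ligand chain> <resno|lo-hi> <object name> [<align chain>]
# Tokens are whitespace-separated; any other line starting with "#" is a
# comment.  Residue ranges accept both a hyphen and an en-dash.

MAP_EXTENSIONS <- c("mtz", "ccp4", "mrc", "map")

#' Construct a card entry
#'
#' One row of an input card: which coordinate file to load, where the ligand
#' is, what to call the resulting object, and (optionally) which map to carve
#' and which chain to align on.
#'
#' @param coord_path Path to a PDB or mmCIF coordinate file.
#' @param ligand_chain Chain identifier of the ligand/residue of interest.
#' @param res_lo,res_hi Inclusive residue-number range of the ligand.
#' @param object_name Display name for the resulting object (no whitespace).
#' @param map_path Optional MTZ (map coefficients) or CCP4/MRC (direct map)
#'   file.
#' @param align_chain Optional chain used for superposition onto the
#'   reference; defaults to the first chain of the file.
#' @param group Group name the entry belongs to.
#' @return A one-row tibble with the entry fields.
#' @export
card_entry <- function(coord_path, ligand_chain, res_lo, res_hi = res_lo,
                       object_name, map_path = NA_character_,
                       align_chain = NA_character_, group = NA_character_) {
  if (res_lo > res_hi) {
    stop("invalid residue range: lo (", res_lo, ") > hi (", res_hi, ")")
  }
  if (!nzchar(object_name) || grepl("\\s", object_name)) {
    stop("object_name must be nonempty and contain no whitespace")
  }
  tibble::tibble(
    group = as.character(group),
    coord_path = as.character(coord_path),
    map_path = as.character(map_path),
    ligand_chain = as.character(ligand_chain),
    res_lo = as.integer(res_lo),
    res_hi = as.integer(res_hi),
    object_name = as.character(object_name),
    align_chain = as.character(align_chain)
  )
}

new_input_card <- function(reference_path = NULL, reference_chain = NULL,
                           groups = character(), entries = NULL) {
  if (is.null(entries)) {
    entries <- card_entry("x", "A", 1L, 1L, "placeholder")[0, ]
  }
  structure(
    list(
      reference_path = reference_path,
      reference_chain = reference_chain,
      groups = groups,
      entries = entries
    ),
    class = "input_card"
  )
}

#' @export
print.input_card <- function(x, ...) {
  cat("<input_card>\n")
  if (!is.null(x$reference_path)) {
    cat("  reference:", x$reference_path,
        if (!is.null(x$reference_chain)) paste0("(chain ", x$reference_chain, ")"),
        "\n")
  }
  cat("  groups:", if (length(x$groups)) paste(x$groups, collapse = ", ") else "(none)", "\n")
  cat("  entries:", nrow(x$entries), "\n")
  invisible(x)
}

parse_resrange <- function(token, line_no) {
  # single integer, or lo-hi with ASCII hyphen or en-dash
  token <- gsub("–", "-", token)
  if (grepl("^[0-9]+$", token)) {
    v <- as.integer(token)
    return(c(v, v))
  }
  m <- regmatches(token, regexec("^([0-9]+)-([0-9]+)$", token))[[1]]
  if (length(m) != 3) {
    stop("line ", line_no, ": malformed residue range '", token, "'")
  }
  lo <- as.integer(m[2]); hi <- as.integer(m[3])
  if (lo > hi) stop("line ", line_no, ": residue range '", token, "' has lo > hi")
  c(lo, hi)
}

has_map_extension <- function(token) {
  ext <- tolower(sub(".*\\.", "", basename(token)))
  grepl("\\.", basename(token)) && ext %in% MAP_EXTENSIONS
}

#' Parse an input card
#'
#' Parses the card text format into an `input_card` object holding the
#' optional reference specification, the ordered group list, and one tibble
#' row per entry.  Lines whose first token starts with `#` but is neither
#' `#REF` nor `#G` are comments; blank lines and repeated whitespace are
#' ignored.  `#REF` is honored only as the first non-comment line.
#'
#' @param text Card content as a single string or character vector of lines.
#' @return An `input_card`: list with `reference_path`, `reference_chain`,
#'   `groups` (character, file order) and `entries` (tibble with one row per
#'   entry, carrying its `group` and source `line` number).
#' @export
parse_card <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  card <- new_input_card()
  entries <- list()
  current_group <- NULL
  seen_content <- FALSE   # any #REF/#G/entry line yet?

  for (i in seq_along(lines)) {
    tokens <- strsplit(trimws(lines[[i]]), "[ \t]+")[[1]]
    tokens <- tokens[nzchar(tokens)]
    if (length(tokens) == 0) next
    first <- tokens[[1]]

    if (identical(first, "#REF")) {
      if (seen_content) {
        stop("line ", i, ": #REF must be the first non-comment line")
      }
      if (length(tokens) < 2) stop("line ", i, ": #REF needs a file path")
      card$reference_path <- tokens[[2]]
      if (length(tokens) >= 3) card$reference_chain <- tokens[[3]]
      seen_content <- TRUE
    } else if (identical(first, "#G")) {
      if (length(tokens) < 2) stop("line ", i, ": #G needs a group name")
      gname <- tokens[[2]]
      if (gname %in% card$groups) {
        stop("line ", i, ": duplicate group name '", gname, "'")
      }
      card$groups <- c(card$groups, gname)
      current_group <- gname
      seen_content <- TRUE
    } else if (startsWith(first, "#")) {
      next  # comment
    } else {
      if (is.null(current_group)) {
        stop("line ", i, ": entry outside group (no #G seen yet)")
      }
      entries[[length(entries) + 1]] <- parse_entry_line(tokens, i, current_group)
      seen_content <- TRUE
    }
  }

  if (length(entries) > 0) {
    card$entries <- dplyr::bind_rows(entries)
    dup <- duplicated(card$entries$object_name)
    if (any(dup)) {
      stop("duplicate object name(s) in card: ",
           paste(unique(card$entries$object_name[dup]), collapse = ", "))
    }
  }
  card
}

parse_entry_line <- function(tokens, line_no, group) {
  # <coords> [<map>] <ligand chain> <resrange> <object name> [<align chain>]
  if (length(tokens) < 4) {
    stop("line ", line_no, ": entry needs at least ",
         "<coords> <chain> <resrange> <object name>")
  }
  coord_path <- tokens[[1]]
  rest <- tokens[-1]
  map_path <- NA_character_
  if (has_map_extension(rest[[1]])) {
    map_path <- rest[[1]]
    rest <- rest[-1]
  }
  if (length(rest) < 3) {
    stop("line ", line_no, ": entry is missing tokens after the map file")
  }
  rng <- parse_resrange(rest[[2]], line_no)
  align_chain <- if (length(rest) >= 4) rest[[4]] else NA_character_
  entry <- card_entry(
    coord_path = coord_path, map_path = map_path,
    ligand_chain = rest[[1]], res_lo = rng[1], res_hi = rng[2],
    object_name = rest[[3]], align_chain = align_chain, group = group
  )
  entry$line <- line_no
  entry
}

#' Serialize an input card
#'
#' Writes an `input_card` back to the card text format, such that
#' `parse_card(serialize_card(card))` reproduces the card field-for-field.
#'
#' @param card An `input_card`.
#' @return A single string in card format.
#' @export
serialize_card <- function(card) {
  stopifnot(inherits(card, "input_card"))
  out <- character()
  if (!is.null(card$reference_path)) {
    out <- c(out, paste(c("#REF", card$reference_path, card$reference_chain),
                        collapse = " "))
  }
  for (g in card$groups) {
    out <- c(out, paste("#G", g))
    rows <- card$entries[!is.na(card$entries$group) & card$entries$group == g, ]
    for (k in seq_len(nrow(rows))) {
      e <- rows[k, ]
      rng <- if (e$res_lo == e$res_hi) as.character(e$res_lo) else
        paste0(e$res_lo, "-", e$res_hi)
      tokens <- c(e$coord_path,
                  if (!is.na(e$map_path)) e$map_path,
                  e$ligand_chain, rng, e$object_name,
                  if (!is.na(e$align_chain)) e$align_chain)
      out <- c(out, paste(tokens, collapse = " "))
    }
  }
  paste0(paste(out, collapse = "\n"), if (length(out)) "\n" else "")
}

#' Read an input card from disk
#'
#' Relative coordinate/map paths in a card resolve against the card file's
#' directory (cards are shared between machines), not the working directory.
#'
#' @param path Card file path.
#' @return An `input_card` with paths resolved.
#' @export
read_card <- function(path) {
  if (!file.exists(path)) stop("card file not found: ", path)
  card <- parse_card(readLines(path, warn = FALSE))
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    ifelse(is.na(p) | grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  }
  if (!is.null(card$reference_path)) {
    card$reference_path <- resolve(card$reference_path)
  }
  if (nrow(card$entries)) {
    card$entries$coord_path <- resolve(card$entries$coord_path)
    card$entries$map_path <- resolve(card$entries$map_path)
  }
  card
}
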