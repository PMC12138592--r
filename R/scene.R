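# Scene assembly: run card entries through the pipeline, manage groups,
# names and colors, and emit a viewer script plus a machine-readable
# run report.
#
# A scene holds one single-chain reference (the frame every entry is
# aligned into), an ordered list of scene objects in named groups, and the
# accumulated per-entry report.  Persisted map fragments live in the
# reserved group "map_objects"; "reference" and "map_objects" can never be
# user object names.

RESERVED_NAMES <- c("reference", "map_objects")

# fixed ordered palette of distinguishable viewer color names
SCENE_PALETTE <- c(
  "green", "cyan", "magenta", "yellow", "salmon", "white", "slate",
  "orange", "purple", "teal", "pink", "wheat", "lime", "marine", "olive",
  "firebrick", "deepteal", "hotpink", "yellowgreen", "lightblue"
)

#' Create an empty scene around a reference structure
#'
#' @param reference A single-chain `xtal_structure` (see
#'   [resolve_reference()]).
#' @return A `ligand_scene`.
#' @export
new_scene <- function(reference) {
  stopifnot(inherits(reference, "xtal_structure"))
  if (length(unique(reference$atoms$chain)) != 1) {
    stop("the reference must consist of a single chain")
  }
  structure(list(reference = reference, objects = list(),
                 groups = character(), report = NULL),
            class = "ligand_scene")
}

#' @export
print.ligand_scene <- function(x, ...) {
  cat("<ligand_scene> ", length(x$objects), " object(s) in ",
      length(x$groups), " group(s)\n", sep = "")
  for (g in x$groups) {
    nm <- vapply(x$objects, function(o) o$object_name, character(1))
    gs <- vapply(x$objects, function(o) o$group, character(1))
    cat("  ", g, ": ", paste(nm[gs == g], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

scene_object_names <- function(scene) {
  vapply(scene$objects, function(o) o$object_name, character(1))
}

#' Per-entry report of a scene as a tibble
#' @param x A `ligand_scene`.
#' @param ... Unused.
#' @return Tibble with one row per processed entry (status, rmsd, pair
#'   counts, symmetry mates, residues kept, map statistics).
#' @method tidy ligand_scene
#' @export
tidy.ligand_scene <- function(x, ...) {
  if (is.null(x$report)) report_row()[0, ] else x$report
}

#' One-row summary of a scene
#' @param x A `ligand_scene`.
#' @param ... Unused.
#' @return Tibble: object/group counts and how many objects carry maps.
#' @method glance ligand_scene
#' @export
glance.ligand_scene <- function(x, ...) {
  tibble::tibble(
    n_objects = length(x$objects),
    n_groups = length(x$groups),
    n_mapped = sum(vapply(x$objects, function(o) isTRUE(o$has_map), logical(1)))
  )
}

#' Resolve the reference structure for a run
#'
#' Precedence: (1) an existing scene's reference; (2) the card's `#REF`
#' path and optional chain; (3) the first entry's structure with the
#' usual chain rule (its align chain if given, else the first chain).
#' The result is reduced to a single chain.
#'
#' @param card An `input_card`.
#' @param existing Optional `ligand_scene` from a previous run.
#' @return A single-chain `xtal_structure`.
#' @export
resolve_reference <- function(card, existing = NULL) {
  if (!is.null(existing) && inherits(existing, "ligand_scene")) {
    return(existing$reference)
  }
  if (!is.null(card$reference_path)) {
    s <- load_structure(card$reference_path)
    return(select_chain(s, card$reference_chain))
  }
  if (nrow(card$entries) > 0) {
    e <- card$entries[1, ]
    s <- load_structure(e$coord_path)
    ch <- if (!is.na(e$align_chain)) e$align_chain else NULL
    return(select_chain(s, ch))
  }
  stop("no reference available: card has no #REF line and no entries")
}

report_row <- function(object_name = NA_character_, group = NA_character_,
                       status = NA_character_, message = NA_character_,
                       coord_path = NA_character_, map_path = NA_character_,
                       ligand_chain = NA_character_, res_lo = NA_integer_,
                       res_hi = NA_integer_, align_chain = NA_character_,
                       color = NA_character_, rmsd = NA_real_,
                       n_pairs_initial = NA_integer_,
                       n_pairs_final = NA_integer_, n_mates = NA_integer_,
                       n_residues = NA_integer_, has_map = FALSE,
                       map_labels = NA_character_, map_sigma = NA_real_,
                       map_mean = NA_real_, mesh_scope = NA_character_,
                       contour_level = NA_real_, carve_radius = NA_real_,
                       transform = list(NULL)) {
  tibble::tibble(
    object_name = object_name, group = group, status = status,
    message = message, coord_path = coord_path, map_path = map_path,
    ligand_chain = ligand_chain, res_lo = res_lo, res_hi = res_hi,
    align_chain = align_chain, color = color, rmsd = rmsd,
    n_pairs_initial = n_pairs_initial, n_pairs_final = n_pairs_final,
    n_mates = n_mates, n_residues = n_residues, has_map = has_map,
    map_labels = map_labels, map_sigma = map_sigma, map_mean = map_mean,
    mesh_scope = mesh_scope, contour_level = contour_level,
    carve_radius = carve_radius, transform = transform
  )
}

#' Run one card entry through the pipeline
#'
#' Load, pick the alignment chain (the one specified or the first),
#' superpose onto the reference, add symmetry mates contacting the
#' ligand, carry everything into the reference frame, truncate to the
#' binding-site environment; when a map is given, synthesize (MTZ) or
#' read it, cut the fragment around the ligand, transform it with the
#' superposition matrix, and sigma-scale.
#'
#' @param entry One-row tibble from an `input_card`'s `entries`.
#' @param reference Single-chain reference `xtal_structure`.
#' @param params Pipeline parameters; see [run_params()].
#' @return A `scene_object`.
#' @export
build_entry <- function(entry, reference, params = run_params()) {
  s <- load_structure(entry$coord_path)
  ligand <- select_residues(s, entry$ligand_chain, entry$res_lo, entry$res_hi)
  align_id <- if (!is.na(entry$align_chain)) entry$align_chain else NULL
  mobile <- select_chain(s, align_id)
  sup <- superpose_chains(mobile, reference)

  with_mates <- add_symmetry_mates(s, ligand,
                                   radius = params$truncation_radius)
  n_mates <- length(setdiff(unique(with_mates$atoms$chain),
                            unique(s$atoms$chain)))
  aligned <- apply_transform(with_mates, sup$transform)
  ligand_aligned <- apply_transform(ligand, sup$transform)
  trimmed <- truncate_environment(aligned, ligand_aligned,
                                  radius = params$truncation_radius)

  map_fragment <- NULL; map_labels <- NA_character_
  map_sigma <- NA_real_; map_mean <- NA_real_
  if (!is.na(entry$map_path)) {
    ext <- tolower(sub(".*\\.", "", entry$map_path))
    full <- if (ext == "mtz") {
      coef <- read_map_coefficients(entry$map_path)
      map_labels <- paste(coef$labels, collapse = "/")
      synthesize_map(coef, sample_rate = params$sample_rate)
    } else {
      map_labels <- "direct"
      read_direct_map(entry$map_path)
    }
    map_sigma <- full$sigma; map_mean <- full$mean
    frag <- extract_fragment(full, ligand, radius = params$ligand_map_radius)
    frag <- transform_map(frag, sup$transform)
    map_fragment <- sigma_scale(frag)
  }

  structure(list(
    object_name = entry$object_name, group = entry$group,
    color = NA_character_, structure = trimmed,
    map_fragment = map_fragment, has_map = !is.null(map_fragment),
    mesh_name = paste0(entry$object_name, "_mesh"),
    mesh_scope = params$mesh_scope,
    contour_level = params$contour, carve_radius = params$carve,
    ligand_chain = entry$ligand_chain, res_lo = entry$res_lo,
    res_hi = entry$res_hi,
    coord_path = entry$coord_path, map_path = entry$map_path,
    align_chain = if (is.null(align_id)) unique(mobile$atoms$chain)[1] else align_id,
    superposition = sup, n_mates = n_mates,
    map_labels = map_labels, map_sigma = map_sigma, map_mean = map_mean,
    stub = FALSE
  ), class = "scene_object")
}

#' Default pipeline parameters
#'
#' The numeric defaults are the pipeline's fixed conventions: binding-site
#' truncation 4.5 A around the ligand, map-fragment extraction 3 A in
#' pipeline mode (9 A in standalone extraction), mesh contour at 1 sigma
#' carved within 1.8 A of the ligand.
#'
#' @param truncation_radius Environment/symmetry-contact radius (A).
#' @param ligand_map_radius Map-fragment radius around the ligand (A).
#' @param extract_radius Standalone map-extraction radius (A).
#' @param contour Mesh contour level (sigma units).
#' @param carve Mesh carve radius (A).
#' @param mesh_scope `"ligand_only"` or `"ligand_plus_environment"`.
#' @param sample_rate Map synthesis oversampling.
#' @return Named list of parameters.
#' @export
run_params <- function(truncation_radius = 4.5, ligand_map_radius = 3.0,
                       extract_radius = 9.0, contour = 1.0, carve = 1.8,
                       mesh_scope = c("ligand_only", "ligand_plus_environment"),
                       sample_rate = 3.0) {
  mesh_scope <- match.arg(mesh_scope)
  stopifnot(truncation_radius > 0, ligand_map_radius > 0, extract_radius > 0,
            contour > 0, carve > 0)
  list(truncation_radius = truncation_radius,
       ligand_map_radius = ligand_map_radius,
       extract_radius = extract_radius, contour = contour, carve = carve,
       mesh_scope = mesh_scope, sample_rate = sample_rate)
}

#' Add card entries to a scene
#'
#' Entries whose object name is already present in the scene are skipped
#' (reported with status `"skipped_duplicate"`); the reserved names
#' `"reference"` and `"map_objects"` are rejected.  One failing entry is
#' logged in the report and does not abort the run.  Colors are drawn
#' without replacement from the bundled palette by a generator seeded
#' with `seed` (recycling when the palette is exhausted), and each mesh
#' inherits its object's color.
#'
#' @param scene A `ligand_scene`.
#' @param card An `input_card`.
#' @param seed Integer seed for color assignment.
#' @param params Pipeline parameters; see [run_params()].
#' @return The updated `ligand_scene`.
#' @export
add_entries <- function(scene, card, seed = 0, params = run_params()) {
  stopifnot(inherits(scene, "ligand_scene"), inherits(card, "input_card"))
  color_order <- with_fixture_seed(seed, sample(SCENE_PALETTE))
  n_used <- length(scene$objects)
  rows <- list()
  for (i in seq_len(nrow(card$entries))) {
    e <- card$entries[i, ]
    if (e$object_name %in% RESERVED_NAMES) {
      rows[[i]] <- report_row(e$object_name, e$group, "error",
                              paste0("'", e$object_name,
                                     "' is a reserved object name"),
                              coord_path = e$coord_path)
      next
    }
    if (e$object_name %in% scene_object_names(scene)) {
      message("skipping '", e$object_name, "': object already present")
      rows[[i]] <- report_row(e$object_name, e$group, "skipped_duplicate",
                              coord_path = e$coord_path)
      next
    }
    obj <- tryCatch(build_entry(e, scene$reference, params),
                    error = function(err) err)
    if (inherits(obj, "error")) {
      msg <- conditionMessage(obj)
      line <- if ("line" %in% names(e)) e$line else NA
      message("entry '", e$object_name, "' (card line ", line,
              ") failed: ", msg)
      rows[[i]] <- report_row(e$object_name, e$group, "error",
                              paste0("card line ", line, ": ", msg),
                              coord_path = e$coord_path,
                              map_path = e$map_path)
      next
    }
    obj$color <- color_order[(n_used %% length(color_order)) + 1]
    n_used <- n_used + 1
    scene$objects[[length(scene$objects) + 1]] <- obj
    if (!obj$group %in% scene$groups) {
      scene$groups <- c(scene$groups, obj$group)
    }
    rows[[i]] <- report_row(
      obj$object_name, obj$group, "ok",
      coord_path = obj$coord_path, map_path = obj$map_path,
      ligand_chain = obj$ligand_chain, res_lo = obj$res_lo,
      res_hi = obj$res_hi, align_chain = obj$align_chain,
      color = obj$color, rmsd = obj$superposition$rmsd,
      n_pairs_initial = obj$superposition$n_pairs_initial,
      n_pairs_final = obj$superposition$n_pairs_final,
      n_mates = obj$n_mates,
      n_residues = length(residue_groups(obj$structure$atoms)),
      has_map = obj$has_map, map_labels = obj$map_labels,
      map_sigma = obj$map_sigma, map_mean = obj$map_mean,
      mesh_scope = obj$mesh_scope, contour_level = obj$contour_level,
      carve_radius = obj$carve_radius,
      transform = list(as.numeric(t(transform_matrix(obj$superposition$transform))))
    )
  }
  scene$report <- dplyr::bind_rows(scene$report, rows)
  scene
}

#' Emit the viewer script and scene files
#'
#' Writes each object's trimmed coordinates (PDB) and map fragment
#' (CCP4), the reference (PDB), and a plain-text molecular-viewer script
#' that reconstructs the grouped scene: loads every file, builds the
#' groups, applies the stored colors, and draws one mesh per mapped
#' object at its contour level, carved around the ligand (or the whole
#' object when the mesh scope says ligand plus environment), named
#' `<object>_mesh`.  Map fragments are grouped under `map_objects`.
#'
#' @param scene A nonempty `ligand_scene`.
#' @param out_dir Output directory (created if absent).
#' @return Path of the script, invisibly.
#' @export
emit_viewer_script <- function(scene, out_dir) {
  stopifnot(inherits(scene, "ligand_scene"))
  if (length(scene$objects) == 0) stop("refusing to emit an empty scene")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_structure(scene$reference, file.path(out_dir, "reference.pdb"))
  lines <- c("# scene reconstruction script (molecular-viewer commands)",
             "load reference.pdb, reference",
             "hide everything, reference",
             "show cartoon, reference",
             "color gray80, reference")
  map_names <- character()
  for (obj in scene$objects) {
    pdb_file <- paste0(obj$object_name, ".pdb")
    pdb_path <- file.path(out_dir, pdb_file)
    if (!isTRUE(obj$stub)) {
      write_structure(obj$structure, pdb_path)
    } else if (!file.exists(pdb_path)) {
      stop("missing file for persisted object '", obj$object_name, "': ",
           pdb_path)
    }
    lines <- c(lines,
               sprintf("load %s, %s", pdb_file, obj$object_name),
               sprintf("show sticks, %s", obj$object_name),
               sprintf("color %s, %s and elem C", obj$color, obj$object_name))
    if (isTRUE(obj$has_map)) {
      map_obj <- paste0(obj$object_name, "_map")
      map_file <- paste0(map_obj, ".ccp4")
      map_path <- file.path(out_dir, map_file)
      if (!isTRUE(obj$stub)) {
        write_map(obj$map_fragment, map_path)
      } else if (!file.exists(map_path)) {
        stop("missing map for persisted object '", obj$object_name, "': ",
             map_path)
      }
      sel <- if (obj$mesh_scope == "ligand_plus_environment") {
        obj$object_name
      } else {
        rng <- if (obj$res_lo == obj$res_hi) obj$res_lo else
          paste0(obj$res_lo, "-", obj$res_hi)
        sprintf("(%s and chain %s and resi %s)", obj$object_name,
                obj$ligand_chain, rng)
      }
      lines <- c(lines,
                 sprintf("load %s, %s", map_file, map_obj),
                 sprintf("isomesh %s, %s, %.1f, %s, carve=%.1f",
                         obj$mesh_name, map_obj, obj$contour_level, sel,
                         obj$carve_radius),
                 sprintf("color %s, %s", obj$color, obj$mesh_name))
      map_names <- c(map_names, map_obj)
    }
  }
  for (g in scene$groups) {
    members <- vapply(scene$objects, function(o) o$object_name, character(1))
    ingroup <- vapply(scene$objects, function(o) o$group == g, logical(1))
    meshes <- vapply(scene$objects[ingroup], function(o) {
      if (isTRUE(o$has_map)) o$mesh_name else NA_character_
    }, character(1))
    lines <- c(lines, sprintf("group %s, %s", g,
                              paste(c(members[ingroup],
                                      meshes[!is.na(meshes)]),
                                    collapse = " ")))
  }
  if (length(map_names)) {
    lines <- c(lines, sprintf("group map_objects, %s",
                              paste(map_names, collapse = " ")))
  }
  script <- file.path(out_dir, "scene.pml")
  writeLines(lines, script)
  invisible(script)
}

#' Write the machine-readable run report
#'
#' JSON report with one record per processed entry: input paths, align
#' chain, 4x4 transform (row-major), rmsd and pair counts, symmetry
#' mates, residues retained, map labels and statistics, and the
#' skipped/error status.  Deterministic for a given card and seed.
#'
#' @param scene A `ligand_scene`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_report <- function(scene, path) {
  stopifnot(inherits(scene, "ligand_scene"))
  rep <- tidy(scene)
  entries <- lapply(seq_len(nrow(rep)), function(i) {
    row <- as.list(rep[i, ])
    row$transform <- if (is.null(rep$transform[[i]])) NULL else
      rep$transform[[i]]
    lapply(row, function(v) if (is.list(v)) unlist(v) else v)
  })
  out <- list(
    tool = "ligalign",
    reference_chain = unique(scene$reference$atoms$chain)[1],
    groups = as.list(scene$groups),
    n_objects = length(scene$objects),
    entries = entries
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Reload a persisted scene from a run directory
#'
#' Reconstructs a scene from `report.json` and `reference.pdb` written by
#' a previous [cmd_run()], so that re-running a card skips objects that
#' are already present, exactly like feeding a new card into an existing
#' viewer session.  Objects are restored as lightweight stubs pointing at
#' their already-written files.
#'
#' @param out_dir Run directory.
#' @return A `ligand_scene`, or `NULL` when no previous run is found.
#' @export
load_scene <- function(out_dir) {
  report_path <- file.path(out_dir, "report.json")
  ref_path <- file.path(out_dir, "reference.pdb")
  if (!file.exists(report_path) || !file.exists(ref_path)) return(NULL)
  rep <- jsonlite::read_json(report_path)
  scene <- new_scene(load_structure(ref_path))
  for (e in rep$entries) {
    if (!identical(e$status, "ok")) next
    obj <- structure(list(
      object_name = e$object_name, group = e$group, color = e$color,
      structure = NULL, map_fragment = NULL,
      has_map = isTRUE(e$has_map),
      mesh_name = paste0(e$object_name, "_mesh"),
      mesh_scope = e$mesh_scope, contour_level = e$contour_level,
      carve_radius = e$carve_radius, ligand_chain = e$ligand_chain,
      res_lo = e$res_lo, res_hi = e$res_hi,
      coord_path = e$coord_path, map_path = e$map_path,
      align_chain = e$align_chain, superposition = NULL,
      n_mates = e$n_mates, map_labels = e$map_labels,
      map_sigma = e$map_sigma, map_mean = e$map_mean, stub = TRUE
    ), class = "scene_object")
    scene$objects[[length(scene$objects) + 1]] <- obj
    if (!obj$group %in% scene$groups) scene$groups <- c(scene$groups, obj$group)
  }
  scene
}
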