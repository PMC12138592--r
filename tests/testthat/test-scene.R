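# Scene semantics: reference resolution, duplicate skipping, colors,
# naming discipline, script emission, reporting.

local_fixture_run <- function(env = parent.frame(), seed = 3) {
  dir <- withr::local_tempdir(.local_envir = env)
  card_path <- make_fixture_set(dir, seed = seed)
  list(dir = dir, card_path = card_path, card = read_card(card_path))
}

test_that("reference resolution follows its precedence order", {
  fxr <- local_fixture_run()
  card <- fxr$card
  # card #REF wins on a fresh scene
  ref <- resolve_reference(card)
  expect_equal(unique(ref$atoms$chain), "A")
  # an existing scene's reference wins over the card
  other <- make_complex(n_residues = 4)
  prior <- new_scene(select_chain(other$structure, "A"))
  expect_identical(resolve_reference(card, existing = prior),
                   prior$reference)
  # without #REF, the first entry's structure is used
  card2 <- card
  card2$reference_path <- NULL
  ref2 <- resolve_reference(card2)
  expect_equal(unique(ref2$atoms$chain), "A")
  # empty card, fresh scene: error
  expect_error(resolve_reference(parse_card("")), "no reference")
})

test_that("build_entry on a reference-identical entry is a near-identity", {
  fxr <- local_fixture_run()
  ref <- resolve_reference(fxr$card)
  obj <- build_entry(fxr$card$entries[1, ], ref)
  expect_lt(obj$superposition$rmsd, 1e-3)
  expect_lt(ligalign:::rotation_angle(obj$superposition$transform$rotation),
            1e-3)
  # trimmed object = ligand + 4.5 A shell, verified by direct scan
  lig <- obj$structure$atoms[obj$structure$atoms$chain == "L", ]
  env <- obj$structure$atoms[obj$structure$atoms$chain != "L", ]
  lxyz <- as.matrix(lig[, c("x", "y", "z")])
  for (key in unique(paste(env$chain, env$resno))) {
    at <- env[paste(env$chain, env$resno) == key, ]
    dmin <- min(ligalign:::min_dist_to_set(as.matrix(at[, c("x", "y", "z")]),
                                           lxyz))
    expect_lte(dmin, 4.5)
  }
  # mapped entry: sigma-scaled fragment covering ligand + 3 A
  expect_true(obj$has_map)
  expect_equal(obj$map_fragment$sigma, 1)
  expect_equal(obj$map_fragment$mean, 0)
  # unmapped entry: no fragment
  obj2 <- build_entry(fxr$card$entries[2, ], ref)
  expect_false(obj2$has_map)
  expect_null(obj2$map_fragment)
})

test_that("duplicates are skipped and reserved names rejected", {
  fxr <- local_fixture_run()
  ref <- resolve_reference(fxr$card)
  scene <- add_entries(new_scene(ref), fxr$card, seed = 1)
  n1 <- glance(scene)$n_objects
  expect_equal(n1, 3)
  scene2 <- suppressMessages(add_entries(scene, fxr$card, seed = 1))
  expect_equal(glance(scene2)$n_objects, n1)
  expect_equal(sum(tidy(scene2)$status == "skipped_duplicate"), 3)
  # object-set equality under repetition (idempotence)
  expect_identical(ligalign:::scene_object_names(scene2),
                   ligalign:::scene_object_names(scene))

  bad <- fxr$card
  bad$entries$object_name[1] <- "reference"
  bad$entries$object_name[2] <- "map_objects"
  scene3 <- suppressMessages(add_entries(new_scene(ref), bad, seed = 1))
  rep3 <- tidy(scene3)
  expect_equal(rep3$status[1:2], c("error", "error"))
  expect_match(rep3$message[1], "reserved")
})

test_that("colors are seeded, distinct, and shared with meshes", {
  fxr <- local_fixture_run()
  ref <- resolve_reference(fxr$card)
  s1 <- add_entries(new_scene(ref), fxr$card, seed = 42)
  s2 <- add_entries(new_scene(ref), fxr$card, seed = 42)
  c1 <- vapply(s1$objects, function(o) o$color, character(1))
  c2 <- vapply(s2$objects, function(o) o$color, character(1))
  expect_identical(c1, c2)
  expect_equal(anyDuplicated(c1), 0)
  expect_true(all(c1 %in% ligalign:::SCENE_PALETTE))
  s3 <- add_entries(new_scene(ref), fxr$card, seed = 43)
  c3 <- vapply(s3$objects, function(o) o$color, character(1))
  expect_false(identical(c1, c3))   # different seed, different draw

  out <- withr::local_tempdir()
  script <- readLines(emit_viewer_script(s1, out))
  for (o in s1$objects) {
    if (o$has_map) {
      expect_true(any(grepl(sprintf("^color %s, %s_mesh$", o$color,
                                    o$object_name), script)))
    }
  }
})

test_that("mesh names, groups and map_objects follow the naming rules", {
  fxr <- local_fixture_run()
  ref <- resolve_reference(fxr$card)
  scene <- add_entries(new_scene(ref), fxr$card, seed = 7)
  for (o in scene$objects) {
    expect_equal(o$mesh_name, paste0(o$object_name, "_mesh"))
  }
  expect_equal(scene$groups, c("siteA", "siteB"))

  out <- withr::local_tempdir()
  script <- readLines(emit_viewer_script(scene, out))
  expect_equal(sum(grepl("^group map_objects, ", script)), 1)
  expect_match(script[grepl("^group map_objects, ", script)],
               "lig_mapped_map")
  # exactly one mesh directive, at 1 sigma carved at 1.8
  mesh_lines <- script[grepl("^isomesh ", script)]
  expect_equal(length(mesh_lines), 1)
  expect_match(mesh_lines, "lig_mapped_mesh, lig_mapped_map, 1.0, ")
  expect_match(mesh_lines, "carve=1.8")
})

test_that("the emitted script references only files that exist", {
  fxr <- local_fixture_run()
  ref <- resolve_reference(fxr$card)
  scene <- add_entries(new_scene(ref), fxr$card, seed = 7)
  out <- withr::local_tempdir()
  script <- readLines(emit_viewer_script(scene, out))
  loads <- sub("^load ([^,]+),.*$", "\\1", script[grepl("^load ", script)])
  expect_gt(length(loads), 0)
  for (f in loads) expect_true(file.exists(file.path(out, f)), info = f)
  expect_error(emit_viewer_script(new_scene(ref), out), "empty scene")
})

test_that("one failing entry does not abort the run", {
  fxr <- local_fixture_run()
  card <- fxr$card
  card$entries$coord_path[2] <- file.path(fxr$dir, "missing.pdb")
  ref <- resolve_reference(card)
  scene <- suppressMessages(add_entries(new_scene(ref), card, seed = 1))
  rep <- tidy(scene)
  expect_equal(sum(rep$status == "ok"), 2)
  expect_equal(sum(rep$status == "error"), 1)
  expect_match(rep$message[rep$status == "error"], "card line")
})

test_that("the JSON report is valid and complete", {
  fxr <- local_fixture_run()
  ref <- resolve_reference(fxr$card)
  scene <- add_entries(new_scene(ref), fxr$card, seed = 7)
  f <- withr::local_tempfile(fileext = ".json")
  write_report(scene, f)
  rep <- jsonlite::read_json(f)
  expect_equal(rep$n_objects, 3)
  expect_equal(length(rep$entries), 3)
  rmsds <- vapply(rep$entries, function(e) e$rmsd, numeric(1))
  expect_true(all(is.finite(rmsds)))
  tm <- rep$entries[[1]]$transform
  expect_equal(length(unlist(tm)), 16)
})

test_that("scenes reload from a run directory as stubs", {
  fxr <- local_fixture_run()
  out <- withr::local_tempdir()
  st <- cmd_run(fxr$card_path, out, seed = 2)
  expect_equal(as.integer(st), 0L)
  re <- load_scene(out)
  expect_s3_class(re, "ligand_scene")
  expect_equal(glance(re)$n_objects, 3)
  expect_true(all(vapply(re$objects, function(o) isTRUE(o$stub), logical(1))))
  # re-emitting from stubs keeps referencing the files already on disk
  script <- readLines(emit_viewer_script(re, out))
  loads <- sub("^load ([^,]+),.*$", "\\1", script[grepl("^load ", script)])
  for (f in loads) expect_true(file.exists(file.path(out, f)), info = f)
})
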