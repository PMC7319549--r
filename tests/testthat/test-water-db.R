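test_that("circular variance matches its closed forms", {
  expect_equal(circular_variance(c(0, 0, 0), rbind(c(3, 0, 0))), 0)
  oct <- rbind(c(3, 0, 0), c(-3, 0, 0), c(0, 3, 0),
               c(0, -3, 0), c(0, 0, 3), c(0, 0, -3))
  expect_equal(circular_variance(c(0, 0, 0), oct), 1, tolerance = 1e-12)
  expect_equal(circular_variance(c(0, 0, 0), rbind(c(5, 0, 0), c(0, 5, 0))),
               1 - sqrt(2) / 2, tolerance = 1e-12)
})

test_that("circular variance handles empty neighbourhoods and coincident atoms", {
  expect_warning(cv0 <- circular_variance(c(0, 0, 0), rbind(c(50, 0, 0))),
                 "no neighbour")
  expect_equal(cv0, 0)
  # coincident atom skipped: same as single neighbour
  expect_equal(suppressWarnings(
    circular_variance(c(1, 1, 1), rbind(c(1, 1, 1), c(4, 1, 1)))), 0)
})

test_that("circular variance is rigid-motion invariant", {
  set.seed(42)
  for (rep in 1:25) {
    o <- runif(3, -5, 5)
    nb <- matrix(runif(30, -8, 8), ncol = 3)
    mo <- random_motion()
    cv1 <- suppressWarnings(circular_variance(o, nb))
    o2 <- as.numeric(mo$R %*% o + mo$t)
    nb2 <- sweep(nb %*% t(mo$R), 2, mo$t, "+")
    cv2 <- suppressWarnings(circular_variance(o2, nb2))
    expect_equal(cv1, cv2, tolerance = 1e-9)
  }
})

test_that("circular variance decreases from surrounded to one-sided", {
  oct <- rbind(c(3, 0, 0), c(-3, 0, 0), c(0, 3, 0),
               c(0, -3, 0), c(0, 0, 3), c(0, 0, -3))
  hemi <- rbind(c(3, 0, 0), c(0, 3, 0), c(0, 0, 3), c(2, 2, 1))
  cv_oct <- circular_variance(c(0, 0, 0), oct)
  cv_hemi <- circular_variance(c(0, 0, 0), hemi)
  cv_one <- circular_variance(c(0, 0, 0), rbind(c(3, 0, 0)))
  expect_gt(cv_oct, cv_hemi)
  expect_gt(cv_hemi, cv_one)
})

test_that("circular variance agrees with a brute-force oracle on fixtures", {
  spec <- fixture_spec(seed = 21, n_helices = 5, helix_length = 16,
                       n_cavity_waters = 3, n_surface_waters = 2)
  m <- plant_waters(generate_bundle(spec), spec)
  p <- as.matrix(protein_atoms(m)[, c("x", "y", "z")])
  truth <- m$metadata$water_truth
  for (i in seq_len(nrow(truth))) {
    o <- as.numeric(truth[i, c("x", "y", "z")])
    cv_pkg <- suppressWarnings(circular_variance(o, p, 10))
    expect_equal(cv_pkg, cv_oracle(o, p, 10), tolerance = 1e-12)
    expect_equal(as.character(classify_water(o, p)),
                 truth$label[i])
  }
})

test_that("waters with no neighbours classify external", {
  p <- matrix(c(0, 0, 0), ncol = 3)
  expect_equal(as.character(classify_water(c(50, 0, 0), p)), "external")
})

test_that("the B-factor filter discards strictly above 45", {
  spec <- fixture_spec(seed = 31, n_helices = 5, helix_length = 20,
                       n_cavity_waters = 5, n_conserved = 5,
                       n_surface_waters = 0)
  m <- plant_waters(generate_bundle(spec), spec)
  wsel <- m$atoms$resid == "HOH"
  m$atoms$b[wsel] <- c(10, 44.9, 45.0, 45.1, 80)
  entry <- build_template_entry(m, receptor_name = "T", resolution = 2.0)
  expect_equal(sort(entry$waters$b), c(10, 44.9, 45.0))
})

test_that("only internal waters are stored in a template entry", {
  spec <- fixture_spec(seed = 32, n_helices = 6, helix_length = 20,
                       n_cavity_waters = 3, n_surface_waters = 2)
  m <- plant_waters(generate_bundle(spec), spec)
  entry <- build_template_entry(m, receptor_name = "T", resolution = 2.0)
  expect_equal(nrow(entry$waters), 3)
  expect_true(all(entry$waters$cv >= 0.6))
  expect_true(all(entry$waters$b <= 45))
})

test_that("a model without waters yields an empty water list, not an error", {
  spec <- fixture_spec(seed = 33, n_helices = 4, helix_length = 12,
                       n_cavity_waters = 0, n_surface_waters = 0)
  m <- generate_bundle(spec)
  entry <- build_template_entry(m, receptor_name = "T", resolution = 2.0)
  expect_equal(nrow(entry$waters), 0)
})

test_that("every stored water in a built DB satisfies both filters", {
  fam <- generate_family(fixture_spec(seed = 34, family_size = 3,
                                      n_helices = 5, helix_length = 16,
                                      n_cavity_waters = 3, n_conserved = 3,
                                      n_surface_waters = 2,
                                      bfactor_range = c(20, 70)))
  db <- family_reference_db(fam)
  for (e in db$entries) {
    expect_true(all(e$waters$b <= 45))
    expect_true(all(e$waters$cv >= 0.6))
  }
})

test_that("save/load round-trips the database losslessly", {
  fam <- generate_family(fixture_spec(seed = 35, family_size = 3,
                                      n_helices = 5, helix_length = 16,
                                      n_cavity_waters = 3, n_conserved = 3,
                                      n_surface_waters = 2))
  db <- family_reference_db(fam)
  path <- tempfile(fileext = ".jsonl")
  save_water_db(db, path)
  db2 <- load_water_db(path)
  expect_equal(length(db2$entries), length(db$entries))
  for (k in seq_along(db$entries)) {
    expect_equal(db2$entries[[k]]$waters$x, db$entries[[k]]$waters$x,
                 tolerance = 1e-6)
    expect_identical(db2$entries[[k]]$sequence, db$entries[[k]]$sequence)
    expect_equal(db2$entries[[k]]$backbone, db$entries[[k]]$backbone,
                 tolerance = 1e-9)
    expect_equal(db2$entries[[k]]$ions$near_250, db$entries[[k]]$ions$near_250)
  }
  expect_equal(db2$provenance$cv_threshold, 0.6)
})

test_that("an unknown schema version is rejected by name", {
  path <- tempfile(fileext = ".jsonl")
  writeLines('{"schema_version":99,"provenance":{}}', path)
  expect_error(load_water_db(path), "schema_version 99")
})

test_that("an empty database round-trips", {
  db <- reference_db(list())
  path <- tempfile(fileext = ".jsonl")
  save_water_db(db, path)
  expect_length(load_water_db(path)$entries, 0)
})

test_that("duplicate (entry, chain) pairs are refused", {
  fam <- generate_family(fixture_spec(seed = 36, family_size = 2,
                                      n_helices = 4, helix_length = 12,
                                      n_cavity_waters = 2, n_conserved = 2,
                                      n_surface_waters = 1))
  db <- family_reference_db(fam)
  expect_error(reference_db(c(db$entries, db$entries[1])), "duplicate")
})
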