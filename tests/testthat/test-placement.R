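test_that("the clash boundary is strict at the cutoff", {
  occ <- matrix(c(2.39, 0, 0), ncol = 3)
  expect_true(check_clash(c(0, 0, 0), occ, 2.4))
  occ[1] <- 2.41
  expect_false(check_clash(c(0, 0, 0), occ, 2.4))
  occ[1] <- 2.40
  expect_false(check_clash(c(0, 0, 0), occ, 2.4))  # exactly at cutoff: free
  expect_false(check_clash(c(0, 0, 0), matrix(numeric(0), ncol = 3), 2.4))
})

local({
  fam <- generate_family(fixture_spec(seed = 61, family_size = 4,
                                      n_helices = 6, helix_length = 20,
                                      n_cavity_waters = 5, n_conserved = 5,
                                      n_surface_waters = 2))
  db <- family_reference_db(fam)
  query1 <- strip_waters_ions(fam$members[[1]]$model)

  test_that("hydrating against the structure's own entry restores every water", {
    db1 <- reference_db(db$entries[1])
    res <- place_waters(query1, db1, placement_config())
    expect_equal(nrow(res$report$placed), nrow(db$entries[[1]]$waters))
    rec <- water_recovery(as.matrix(db$entries[[1]]$waters[, c("x", "y", "z")]),
                          as.matrix(res$report$placed[, c("x", "y", "z")]))
    expect_equal(rec$pct_recovery, 100)
    expect_lt(rec$mean_distance, 1e-6)
  })

  test_that("a duplicate template contributes no additional waters", {
    e2 <- db$entries[[1]]
    e2$entry_id <- "ZDUP1"   # sorts after the original at equal score
    db2 <- reference_db(list(db$entries[[1]], e2))
    res <- place_waters(query1, db2, placement_config())
    tpl <- res$report$templates_used
    expect_equal(tpl$n_placed[tpl$entry_id == "ZDUP1"], 0L)
    expect_equal(sum(res$report$candidates$reason == "clash_water"),
                 nrow(e2$waters))
  })

  test_that("waters are assessed in increasing source B-factor within a template", {
    db1 <- reference_db(db$entries[1])
    res <- place_waters(query1, db1, placement_config())
    b <- res$report$candidates$source_bfactor
    expect_true(all(diff(b) >= 0))
    expect_equal(res$report$placed$order_index,
                 seq_len(nrow(res$report$placed)))
  })

  test_that("placed sets respect all minimum distances (post-condition sweep)", {
    res <- place_waters(query1, db, placement_config())
    placed <- as.matrix(res$report$placed[, c("x", "y", "z")])
    expect_gt(nrow(placed), 0)
    if (nrow(placed) > 1)
      expect_gte(min(dist(placed)), 2.4)
    qxyz <- heavy_atom_coords(query1)
    for (i in seq_len(nrow(placed)))
      expect_gte(min(sqrt(rowSums(sweep(qxyz, 2, placed[i, ])^2))), 2.4)
  })

  test_that("the report partitions every candidate from admitted templates", {
    res <- place_waters(query1, db, placement_config())
    n_cand <- sum(sapply(db$entries, function(e) nrow(e$waters)))
    expect_equal(nrow(res$report$candidates), n_cand)
    expect_equal(nrow(res$report$placed) +
                   sum(res$report$candidates$status == "rejected"), n_cand)
    expect_true(all(res$report$candidates$status %in% c("placed", "rejected")))
  })

  test_that("provenance of every placed water round-trips to a DB record", {
    res <- place_waters(query1, db, placement_config())
    ids <- sapply(db$entries, function(e) e$entry_id)
    for (i in seq_len(nrow(res$report$placed))) {
      row <- res$report$placed[i, ]
      e <- db$entries[[match(row$source_entry, ids)]]
      expect_true(any(abs(e$waters$b - row$source_bfactor) < 1e-9))
    }
  })

  test_that("hydration output and report are deterministic", {
    p1 <- tempfile(fileext = ".pdb"); p2 <- tempfile(fileext = ".pdb")
    r1 <- tempfile(fileext = ".tsv"); r2 <- tempfile(fileext = ".tsv")
    res1 <- place_waters(query1, db, placement_config())
    res2 <- place_waters(query1, db, placement_config())
    write_pdb(res1$model, p1); write_pdb(res2$model, p2)
    write_placement_report(res1$report, r1)
    write_placement_report(res2$report, r2)
    expect_identical(readLines(p1), readLines(p2))
    expect_identical(readLines(r1), readLines(r2))
  })

  test_that("re-hydrating an already hydrated model adds nothing", {
    res <- place_waters(query1, db, placement_config())
    res2 <- place_waters(res$model, db, placement_config())
    expect_equal(nrow(res2$report$placed), 0)
  })

  test_that("raised thresholds silence excluded templates entirely", {
    all_res <- place_waters(query1, db, placement_config())
    bits <- all_res$report$templates_used$score_bits
    cfg <- placement_config(score_min = sort(bits, decreasing = TRUE)[1])
    res <- place_waters(query1, db, cfg)
    expect_lte(length(unique(res$report$candidates$source_entry)), 1)
    expect_lte(nrow(res$report$placed), nrow(all_res$report$placed))
  })

  test_that("no templates above threshold returns the query unchanged", {
    res <- place_waters(query1, db, placement_config(score_min = 1e6))
    expect_identical(res$model$atoms, query1$atoms)
    expect_equal(nrow(res$report$candidates), 0)
    expect_match(res$report$note, "no templates")
  })

  test_that("pre-existing query waters are preserved and occupy space", {
    qw <- query1
    w1 <- as.numeric(db$entries[[1]]$waters[1, c("x", "y", "z")])
    qw$atoms <- rbind(qw$atoms, data.frame(
      type = "HETATM", eleno = max(qw$atoms$eleno) + 1L, elety = "O",
      resid = "HOH", chain = "A", resno = 3001L, insert = "",
      x = w1[1], y = w1[2], z = w1[3], o = 1, b = 20, elesy = "O"))
    res <- place_waters(qw, db, placement_config())
    expect_true(3001 %in% water_oxygens(res$model)$resno)
    # the coincident template water now clashes with the pre-existing one
    own <- res$report$candidates[res$report$candidates$source_entry == "SYN01", ]
    expect_true(any(own$status == "rejected" & own$reason == "clash_water"))
  })
})

local({
  fam <- generate_family(fixture_spec(seed = 62, family_size = 3,
                                      n_helices = 6, helix_length = 20,
                                      n_cavity_waters = 5, n_conserved = 5,
                                      n_surface_waters = 2))
  db <- family_reference_db(fam)
  query <- strip_waters_ions(fam$members[[1]]$model)
  qseq <- extract_sequence(query, "A")
  ranked <- rank_templates(db, qseq)

  test_that("sodium is placed in an open pocket and reported with provenance", {
    res <- place_waters(query, db, placement_config(add_sodium = TRUE))
    expect_true(res$report$sodium$placed)
    expect_equal(res$report$sodium$source_entry, "SYN01")  # 100% identity
    ions <- res$model$atoms[res$model$atoms$resid == "NA", ]
    expect_equal(nrow(ions), 1)
    # exclusion rules hold in the output
    pos <- as.numeric(ions[c("x", "y", "z")])
    prot <- .coords_of(protein_atoms(res$model))
    expect_gte(min(sqrt(rowSums(sweep(prot, 2, pos)^2))), 1.8)
    wats <- .coords_of(water_oxygens(res$model))
    expect_gte(min(sqrt(rowSums(sweep(wats, 2, pos)^2))), 2.1)
  })

  test_that("a protein atom within 1.8 A of the candidate blocks the sodium", {
    srcpos <- as.numeric(db$entries[[1]]$ions[1, c("x", "y", "z")])
    # the template is the query's own entry: candidate maps onto srcpos
    blocker <- query
    blocker$atoms <- rbind(blocker$atoms, within(blocker$atoms[1, ], {
      eleno <- max(query$atoms$eleno) + 1L; elety <- "CB"; resid <- "ALA"
      resno <- 1L; x <- srcpos[1] + 1.5; y <- srcpos[2]; z <- srcpos[3]
    }))
    out <- place_sodium(blocker, ranked, placement_config(add_sodium = TRUE))
    expect_false(out$placed)
    expect_equal(out$reason, "protein_within_1.8")
  })

  test_that("an existing water within 2.1 A blocks the sodium", {
    srcpos <- as.numeric(db$entries[[1]]$ions[1, c("x", "y", "z")])
    wet <- query
    wet$atoms <- rbind(wet$atoms, data.frame(
      type = "HETATM", eleno = max(wet$atoms$eleno) + 1L, elety = "O",
      resid = "HOH", chain = "A", resno = 3001L, insert = "",
      x = srcpos[1] + 2.0, y = srcpos[2], z = srcpos[3], o = 1, b = 10,
      elesy = "O"))
    out <- place_sodium(wet, ranked, placement_config(add_sodium = TRUE))
    expect_false(out$placed)
    expect_equal(out$reason, "water_within_2.1")
  })

  test_that("no near-2.50 ion in any template yields a logged non-placement", {
    db0 <- db
    db0$entries <- lapply(db0$entries, function(e) {
      e$ions <- e$ions[0, ]; e
    })
    res <- place_waters(query, db0, placement_config(add_sodium = TRUE))
    expect_false(res$report$sodium$placed)
    expect_equal(res$report$sodium$reason, "no_near_250_ion_in_templates")
  })
})

test_that("external predictions merge only where they do not overlap", {
  fam <- generate_family(fixture_spec(seed = 63, family_size = 2,
                                      n_helices = 5, helix_length = 16,
                                      n_cavity_waters = 3, n_conserved = 3,
                                      n_surface_waters = 2))
  db <- family_reference_db(fam)
  query <- strip_waters_ions(fam$members[[1]]$model)
  res <- place_waters(query, db, placement_config())
  placed1 <- as.numeric(res$report$placed[1, c("x", "y", "z")])
  far <- placed1 + c(40, 0, 0)
  pred <- rbind(placed1 + c(2.0, 0, 0),   # overlaps a homologous water
                far,                       # clear
                far + c(1.0, 0, 0))        # duplicates an accepted prediction
  mg <- merge_external_predictions(res$model, pred, cutoff = 2.4)
  expect_equal(mg$n_added, 1)
  expect_equal(mg$n_rejected, 2)
  expect_equal(mg$added[1, ], far, ignore_attr = TRUE)
  # empty prediction set leaves the model unchanged
  mg0 <- merge_external_predictions(res$model, matrix(numeric(0), ncol = 3))
  expect_identical(mg0$model$atoms, res$model$atoms)
})
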