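test_that("identical sequences align at 100% identity", {
  set.seed(1)
  s <- paste(sample(c("A", "C", "G", "T", "L", "K", "W", "F"), 100,
                    replace = TRUE), collapse = "")
  al <- align_pair(s, s)
  expect_equal(al$pct_identity, 100)
  expect_equal(al$n_aligned, 100)
  expect_equal(al$correspondence$qpos, al$correspondence$tpos)
})

test_that("the textbook BLOSUM50 pair scores as the DP oracle dictates", {
  m50 <- scoring_matrix("BLOSUM50")
  # affine 10/1 (gap of length L costs 10 + L): oracle-verified optimum 25
  al <- align_pair("HEAGAWGHEE", "PAWHEAE", scoring = "BLOSUM50",
                   gap_open = 10, gap_extend = 1)
  expect_equal(al$score_raw, 25)
  expect_equal(al$score_raw,
               sw_score_oracle("HEAGAWGHEE", "PAWHEAE", m50, 10, 1))
  # the classic linear d = 8 penalty reproduces the textbook AWGHE/AW-HE = 28
  al8 <- align_pair("HEAGAWGHEE", "PAWHEAE", scoring = "BLOSUM50",
                    gap_open = 0, gap_extend = 8)
  expect_equal(al8$score_raw, 28)
  expect_equal(al8$score_raw,
               sw_score_oracle("HEAGAWGHEE", "PAWHEAE", m50, 0, 8))
})

test_that("self-alignment beats alignment to the reversed sequence", {
  set.seed(7)
  s <- paste(sample(c("A", "R", "N", "D", "W", "K", "M", "F"), 60,
                    replace = TRUE), collapse = "")
  rev_s <- paste(rev(strsplit(s, "")[[1]]), collapse = "")
  expect_gt(align_pair(s, s)$score_raw, align_pair(s, rev_s)$score_raw)
})

test_that("correspondence pairs are strictly increasing in both sequences", {
  set.seed(9)
  for (rep in 1:10) {
    a <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), 35, replace = TRUE), collapse = "")
    co <- align_pair(a, b)$correspondence
    if (nrow(co) > 1) {
      expect_true(all(diff(co$qpos) >= 1))
      expect_true(all(diff(co$tpos) >= 1))
    }
  }
})

test_that("engine scores equal exhaustive DP on random short pairs", {
  m62 <- scoring_matrix("BLOSUM62")
  set.seed(11)
  for (rep in 1:60) {
    n1 <- sample(3:12, 1); n2 <- sample(3:12, 1)
    a <- paste(sample(c("A", "C", "G", "T"), n1, replace = TRUE), collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), n2, replace = TRUE), collapse = "")
    expect_equal(align_pair(a, b)$score_raw,
                 sw_score_oracle(a, b, m62, 11, 1),
                 info = paste(a, b))
  }
})

test_that("engine scores equal an independent aligner on longer pairs", {
  skip_if_not_installed("Biostrings")
  suppressPackageStartupMessages(requireNamespace("Biostrings"))
  e <- new.env(); data("BLOSUM62", package = "Biostrings", envir = e)
  set.seed(12)
  for (rep in 1:10) {
    a <- paste(sample(c("A","R","N","D","C","Q","E","G","H","I","L","K"),
                      sample(20:60, 1), replace = TRUE), collapse = "")
    b <- paste(sample(c("A","R","N","D","C","Q","E","G","H","I","L","K"),
                      sample(20:60, 1), replace = TRUE), collapse = "")
    ref <- Biostrings::pairwiseAlignment(Biostrings::AAString(a),
                                         Biostrings::AAString(b),
                                         substitutionMatrix = e$BLOSUM62,
                                         gapOpening = 11, gapExtension = 1,
                                         type = "local")
    expect_equal(align_pair(a, b)$score_raw, Biostrings::score(ref))
  }
})

test_that("bit scores follow the Karlin-Altschul conversion", {
  al <- align_pair("AAAAAAAAAA", "AAAAAAAAAA")
  expect_equal(al$score_bits, (0.267 * al$score_raw - log(0.041)) / log(2))
})

local({
  fam <- generate_family(fixture_spec(seed = 41, family_size = 4,
                                      n_helices = 5, helix_length = 16,
                                      n_cavity_waters = 3, n_conserved = 3,
                                      n_surface_waters = 2))
  db <- family_reference_db(fam)
  qseq <- db$entries[[1]]$sequence

  test_that("the bit-score threshold excludes weaker templates monotonically", {
    all_r <- rank_templates(db, qseq, score_min = 0)
    bits <- sapply(all_r, function(r) r$alignment$score_bits)
    thr <- sort(bits)[2]  # admits all but the weakest
    some_r <- rank_templates(db, qseq, score_min = thr)
    expect_equal(length(some_r), length(all_r) - 1)
    none <- rank_templates(db, qseq, score_min = max(bits) + 1)
    expect_length(none, 0)
    expect_match(attr(none, "reason"), "no templates above threshold")
    # monotone: raising the threshold never adds templates
    for (t in c(0, thr, max(bits))) {
      expect_lte(length(rank_templates(db, qseq, score_min = t + 1)),
                 length(rank_templates(db, qseq, score_min = t)))
    }
  })

  test_that("ranking is by state match, then bits, then resolution", {
    r <- rank_templates(db, qseq, query_state = "inactive")
    sm <- sapply(r, function(x) x$state_match)
    expect_true(all(diff(as.integer(!sm)) >= 0))  # matches first
    bits <- sapply(r, function(x) x$alignment$score_bits)
    expect_true(all(diff(bits[sm]) <= 1e-9))
    expect_equal(sapply(r, function(x) x$rank), seq_along(r))
    # score-only ordering when state is unknown
    r2 <- rank_templates(db, qseq, query_state = "unknown")
    expect_true(all(diff(sapply(r2, function(x) x$alignment$score_bits)) <= 1e-9))
  })

  test_that("equal-score templates order by resolution then id", {
    e1 <- db$entries[[1]]; e2 <- db$entries[[1]]
    e1$entry_id <- "ZZZ1"; e1$resolution <- 3.1
    e2$entry_id <- "ZZZ2"; e2$resolution <- 2.0
    db2 <- reference_db(list(e1, e2))
    r <- rank_templates(db2, qseq)
    expect_equal(r[[1]]$template$entry_id, "ZZZ2")  # 2.0 A first
    # exact ties break lexicographically by entry id
    e2$resolution <- 3.1
    r2 <- rank_templates(reference_db(list(e2, e1)), qseq)
    expect_equal(r2[[1]]$template$entry_id, "ZZZ1")
  })

  test_that("ranking is invariant to database entry order", {
    set.seed(5)
    ref <- rank_templates(db, qseq, query_state = "active")
    ids <- sapply(ref, function(x) x$template$entry_id)
    for (rep in 1:5) {
      perm <- sample(length(db$entries))
      dbp <- reference_db(db$entries[perm])
      rp <- rank_templates(dbp, qseq, query_state = "active")
      expect_equal(sapply(rp, function(x) x$template$entry_id), ids)
    }
  })

  test_that("state can be demoted to a tie-break", {
    r <- rank_templates(db, qseq, query_state = "active",
                        state_priority = "tiebreak")
    bits <- sapply(r, function(x) x$alignment$score_bits)
    expect_true(all(diff(bits) <= 1e-9))
  })
})
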