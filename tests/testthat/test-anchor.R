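test_that("reference frame validates landmark placement and identity", {
  fr <- camkii_frame()
  expect_equal(substr(fr$residues, fr$landmarks[["S280"]] - fr$offset + 1,
                      fr$landmarks[["S280"]] - fr$offset + 1), "S")
  expect_equal(substr(fr$residues, fr$landmarks[["T287"]] - fr$offset + 1,
                      fr$landmarks[["T287"]] - fr$offset + 1), "T")
  expect_equal(
    substr(fr$residues, fr$landmarks[["pair_first"]] - fr$offset + 1,
           fr$landmarks[["pair_second"]] - fr$offset + 1), "MM")
  expect_error(reference_frame("AAAA", 280), "landmark")
  expect_error(
    reference_frame("ATAAAAAAT", 279,
                    landmarks = c(S280 = 280, T287 = 287)),
    "S280"
  )
})

test_that("self-alignment is gapless with the matrix-diagonal score", {
  fr <- camkii_frame()
  sc <- scoring_scheme()
  aln <- global_align(fr$residues, fr, sc)
  expect_false(grepl("-", aln$aligned_ref, fixed = TRUE))
  expect_false(grepl("-", aln$aligned_query, fixed = TRUE))
  rv <- strsplit(fr$residues, "")[[1]]
  expect_equal(aln$score, sum(diag(sc$matrix[rv, rv])))
  expect_equal(unname(aln$ref_to_query),
               seq_len(nchar(fr$residues)))
  expect_equal(as.integer(names(aln$ref_to_query)[1]), fr$offset)
})

test_that("deleting one reference position maps it to a gap and shifts the rest", {
  fr <- camkii_frame()
  drop <- 10 # interior position
  q <- paste0(substr(fr$residues, 1, drop - 1),
              substr(fr$residues, drop + 1, nchar(fr$residues)))
  aln <- global_align(q, fr)
  map <- aln$ref_to_query
  expect_true(is.na(map[drop]))
  expect_equal(unname(map[seq_len(drop - 1)]), seq_len(drop - 1))
  expect_equal(unname(map[(drop + 1):length(map)]),
               seq(drop, nchar(q)))
})

test_that("alignment score matches the exhaustive enumeration oracle on tiny strings", {
  sc <- toy_scoring()
  fr0 <- function(r) structure(
    list(residues = r, offset = 1L, landmarks = c(p = 1L)),
    class = "reference_frame"
  )
  withr::with_seed(11, {
    for (k in 1:40) {
      q <- random_protein(sample(2:6, 1))
      r <- random_protein(sample(2:6, 1))
      expect_equal(
        global_align(q, fr0(r), sc)$score,
        oracle_align_enum(q, r, sc$matrix, 3, 1),
        info = paste(q, r)
      )
    }
  })
})

test_that("recursive oracle agrees with enumeration, and the aligner with both", {
  sc <- toy_scoring()
  fr0 <- function(r) structure(
    list(residues = r, offset = 1L, landmarks = c(p = 1L)),
    class = "reference_frame"
  )
  withr::with_seed(12, {
    for (k in 1:25) {
      q <- random_protein(sample(2:5, 1))
      r <- random_protein(sample(2:5, 1))
      o1 <- oracle_align_enum(q, r, sc$matrix, 3, 1)
      o2 <- oracle_align_rec(q, r, sc$matrix, 3, 1)
      expect_equal(o1, o2, info = paste(q, r))
      expect_equal(global_align(q, fr0(r), sc)$score, o2)
    }
    # longer strings against the recursive oracle, BLOSUM62 penalties too
    sc62 <- scoring_scheme()
    for (k in 1:25) {
      q <- random_protein(sample(8:12, 1))
      r <- random_protein(sample(8:12, 1))
      expect_equal(global_align(q, fr0(r), sc)$score,
                   oracle_align_rec(q, r, sc$matrix, 3, 1))
      expect_equal(global_align(q, fr0(r), sc62)$score,
                   oracle_align_rec(q, r, sc62$matrix, 11, 1))
    }
  })
})

test_that("gap removal recovers inputs and ref_to_query is strictly increasing", {
  fr <- camkii_frame()
  withr::with_seed(13, {
    for (k in 1:20) {
      q <- random_protein(sample(20:80, 1))
      aln <- global_align(q, fr)
      expect_equal(gsub("-", "", aln$aligned_query, fixed = TRUE), q)
      expect_equal(gsub("-", "", aln$aligned_ref, fixed = TRUE), fr$residues)
      expect_equal(nchar(aln$aligned_ref), nchar(aln$aligned_query))
      mm <- aln$ref_to_query[!is.na(aln$ref_to_query)]
      if (length(mm) > 1) expect_true(all(diff(mm) > 0))
    }
  })
})

test_that("landmark mapping recovers the printed fragment residues", {
  fr <- camkii_frame()
  frags <- camkii_fragments()
  mouse <- global_align(frags$residues[frags$accession == "CAMK2G_MOUSE_FRAG"], fr)
  expect_equal(unname(map_landmarks(mouse)), c("S", "M", "M", "T"))
  fly <- global_align(frags$residues[frags$accession == "CAMKII_DROME_FRAG"], fr)
  lm <- map_landmarks(fly)
  expect_equal(unname(lm[c("pair_first", "pair_second")]), c("V", "V"))
  expect_equal(unname(lm[c("S280", "T287")]), c("S", "T"))
  # pair region deleted -> GAP at both pair landmarks
  res <- fr$residues
  cut <- paste0(substr(res, 1, 6), substr(res, 11, nchar(res)))
  lm2 <- map_landmarks(global_align(cut, fr))
  expect_true(is.na(lm2[["pair_first"]]) || is.na(lm2[["pair_second"]]))
})

test_that("coverage filter passes self-alignment and rejects random queries", {
  fr <- camkii_frame()
  self <- coverage_filter(global_align(fr$residues, fr))
  expect_true(self$pass)
  expect_equal(self$identity, 1.0)
  expect_equal(self$coverage, 1.0)
  expect_error(coverage_filter(global_align(fr$residues, fr),
                               min_identity = 1.5), "0, 1")
  withr::with_seed(14, {
    fails <- vapply(1:100, function(k) {
      q <- random_protein(300)
      !coverage_filter(global_align(q, fr))$pass
    }, logical(1))
    expect_true(all(fails))
  })
})
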