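test_that("uniform tips need no changes; the four-tip split needs one gain", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  all1 <- fitch_history(tr, c(A = 1, B = 1, C = 1, D = 1))
  expect_equal(all1$min_changes, 0)
  expect_equal(unname(all1$resolved_states[["node5"]]), 1L)
  expect_equal(nrow(all1$gains), 0)
  expect_equal(nrow(all1$losses), 0)

  h <- fitch_history(tr, c(A = 1, B = 1, C = 0, D = 0))
  # brute force over the 2^3 internal labelings confirms the minimum
  expect_equal(oracle_parsimony(tr, c(A = "1", B = "1", C = "0", D = "0")), 1)
  expect_equal(h$min_changes, 1)
  expect_equal(nrow(h$gains), 1)
  expect_equal(nrow(h$losses), 0)
  # under root-preference-0 the gain subtends {A,B}
  gain_tips <- tr$tip.label[oxpair:::descendant_tips(tr, h$gains$child)]
  expect_setequal(gain_tips, c("A", "B"))
})

test_that("a clade-wide gain plus isolated convergent tips are all recovered", {
  # a 'Vertebrata' clade all in state 1 among 0-state outgroups, plus three
  # distant isolated tips in state 1 (independent origins)
  tr <- ape::read.tree(text = paste0(
    "(((((V1,V2),(V3,V4)),O1),((O2,I1),(O3,(O4,I2)))),(O5,(I3,O6)));"
  ))
  st <- c(V1 = 1, V2 = 1, V3 = 1, V4 = 1, I1 = 1, I2 = 1, I3 = 1,
          O1 = 0, O2 = 0, O3 = 0, O4 = 0, O5 = 0, O6 = 0)
  h <- fitch_history(tr, st)
  expect_equal(h$min_changes,
               oracle_parsimony(tr, stats::setNames(as.character(st), names(st))))
  expect_equal(h$min_changes, 4)
  expect_equal(nrow(h$gains), 4)
  expect_equal(nrow(h$losses), 0)
  # one gain is the clade stem; the other three are the isolated terminals
  gain_clades <- lapply(h$gains$child, function(v) {
    tr$tip.label[oxpair:::descendant_tips(tr, v)]
  })
  sizes <- sort(vapply(gain_clades, length, integer(1)))
  expect_equal(sizes, c(1, 1, 1, 4))
  expect_setequal(unlist(gain_clades), c("V1", "V2", "V3", "V4",
                                         "I1", "I2", "I3"))
})

test_that("min_changes matches brute force on random binary and multifurcating trees", {
  withr::with_seed(41, {
    for (k in 1:60) {
      n <- sample(4:8, 1)
      tr <- ape::rtree(n, rooted = TRUE)
      st <- stats::setNames(sample(c("0", "1", "?"), n, TRUE,
                                   prob = c(0.45, 0.45, 0.1)),
                            tr$tip.label)
      if (all(st == "?")) st[1] <- "1"
      h <- fitch_history(tr, st)
      expect_equal(h$min_changes, oracle_parsimony(tr, st), info = k)
      # resolved labeling realizes the minimum: flips along edges == min
      flips <- sum(h$resolved_states[h$tree$edge[, 1]] !=
                     h$resolved_states[h$tree$edge[, 2]])
      expect_equal(flips, h$min_changes)
      expect_equal(nrow(h$gains) + nrow(h$losses), h$min_changes)
    }
    # polytomies via random splits collapse
    for (k in 1:20) {
      tr <- ape::di2multi(ape::rtree(7, rooted = TRUE), tol = 0.4)
      st <- stats::setNames(sample(c("0", "1"), 7, TRUE), tr$tip.label)
      h <- fitch_history(tr, st)
      expect_equal(h$min_changes, oracle_parsimony(tr, st), info = k)
    }
  })
})

test_that("consistent tip relabeling leaves the change count invariant", {
  withr::with_seed(42, {
    for (k in 1:10) {
      tr <- ape::rtree(6, rooted = TRUE)
      st <- stats::setNames(sample(c("0", "1"), 6, TRUE), tr$tip.label)
      perm <- sample(6)
      tr2 <- tr
      tr2$tip.label <- paste0("N", perm)[match(tr$tip.label, tr$tip.label)]
      # same shape, renamed tips with states carried along
      st2 <- stats::setNames(unname(st), tr2$tip.label)
      expect_equal(fitch_history(tr2, st2)$min_changes,
                   fitch_history(tr, st)$min_changes)
    }
  })
})

test_that("states validate and degenerate inputs error", {
  tr <- ape::read.tree(text = "((A,B),C);")
  expect_error(fitch_history(tr, c(A = 1, B = 0, Z = 1)), "not in tree")
  expect_error(fitch_history(tr, c(A = 1, B = 0)), "no state for tip")
  expect_error(fitch_history(tr, c(A = "?", B = "?", C = "?")), "all tips")
  expect_error(fitch_history(tr, c(A = 2, B = 0, C = 0)), "0, 1 or")
})

test_that("gain dating brackets the change by the branch endpoint ages", {
  tr <- ape::read.tree(text = "((A:600,B:600)V:50,C:650)R;")
  h <- fitch_history(tr, c(A = 1, B = 1, C = 0))
  expect_equal(nrow(h$gains), 1)
  d <- date_gains(h)
  expect_equal(d$age_older, 650)
  expect_equal(d$age_younger, 600)
  # explicit age table keyed by labels
  d2 <- date_gains(h, ages = c(R = 650, V = 600, A = 0, B = 0, C = 0))
  expect_equal(d2$age_older, 650)
  expect_equal(d2$age_younger, 600)
  expect_error(date_gains(h, ages = c(R = 650)), "no age")
  # zero-length branch -> degenerate interval
  tr0 <- ape::read.tree(text = "((A:600,B:600)V:0,C:600)R;")
  h0 <- fitch_history(tr0, c(A = 1, B = 1, C = 0))
  d0 <- date_gains(h0)
  expect_equal(d0$age_older, d0$age_younger)
})

test_that("phangorn agrees with the reconstruction score on random trees", {
  skip_if_not_installed("phangorn")
  withr::with_seed(43, {
    for (k in 1:20) {
      n <- sample(4:10, 1)
      tr <- ape::rtree(n, rooted = TRUE)
      st <- sample(c("0", "1"), n, TRUE)
      pd <- phangorn::phyDat(matrix(st, ncol = 1,
                                    dimnames = list(tr$tip.label, NULL)),
                             type = "USER", levels = c("0", "1"))
      expect_equal(
        fitch_history(tr, stats::setNames(st, tr$tip.label))$min_changes,
        as.integer(phangorn::parsimony(tr, pd))
      )
    }
  })
})

test_that("bracket inference grades both-sides/one-side/no-side support", {
  tr <- ape::read.tree(text = "((Mouse,Rat)Mam,(Fly,Bee)Ins)Bil;")
  # both child lineages of the bilaterian root contain a state-1 tip
  st <- c(Mouse = 1, Rat = 0, Fly = 1, Bee = 0)
  expect_equal(bracket_infer(tr, "Bil", st), "I")
  expect_equal(bracket_infer(tr, "Bil", c(Mouse = 1, Rat = 1, Fly = 0, Bee = 0)), "II")
  expect_equal(bracket_infer(tr, "Bil", c(Mouse = 0, Rat = 0, Fly = 0, Bee = 0)), "III")
  expect_error(bracket_infer(tr, "Mouse", st), "tip")
})

test_that("tidy/glance/autoplot summarize a history", {
  tr <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
  h <- fitch_history(tr, c(A = 1, B = 1, C = 0, D = 0))
  td <- tidy(h)
  expect_equal(nrow(td), 7)
  expect_equal(sum(td$is_tip), 4)
  expect_true(all(td$state %in% 0:1))
  g <- glance(h)
  expect_equal(g$min_changes, 1)
  p <- autoplot(h)
  expect_s3_class(p, "ggplot")
})
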