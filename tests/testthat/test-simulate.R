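sim_tree <- function(n, seed = 1) {
  withr::with_seed(seed, {
    tr <- ape::rtree(n, rooted = TRUE)
    tr$tip.label <- sprintf("Species %02d", seq_len(n))
    tr
  })
}

test_that("zero substitution probability gives exact sequences off the landmarks", {
  tr <- sim_tree(8)
  # gain on the stem of some internal clade
  gain <- ape::Ntip(tr) + 3L
  sim <- simulate_clade(tr, gain_branch = gain, sub_prob = 0, seed = 7)
  fr <- camkii_frame()
  root_vv <- sub("MM", "VV", fr$residues, fixed = TRUE)
  root_mm <- fr$residues
  for (i in seq_len(nrow(sim$records))) {
    sp <- sim$records$species[i]
    want <- if (sim$truth$tip_states[[sp]] == 1) root_mm else root_vv
    expect_equal(sim$records$residues[i], want)
  }
  # tips below the gain branch are exactly the state-1 tips
  below <- tr$tip.label[oxpair:::descendant_tips(tr, gain)]
  expect_setequal(names(which(sim$truth$tip_states == 1)), below)
})

test_that("the same seed reproduces byte-identical FASTA output", {
  tr <- sim_tree(10)
  a <- simulate_clade(tr, gain_branch = 12L, sub_prob = 0.05,
                      copies_per_species = 1:2, seed = 99)
  b <- simulate_clade(tr, gain_branch = 12L, sub_prob = 0.05,
                      copies_per_species = 1:2, seed = 99)
  fa <- withr::local_tempfile(fileext = ".fa")
  fb <- withr::local_tempfile(fileext = ".fa")
  write_fasta(a$records, fa); write_fasta(b$records, fb)
  expect_identical(readLines(fa), readLines(fb))
  c <- simulate_clade(tr, gain_branch = 12L, sub_prob = 0.05,
                      copies_per_species = 1:2, seed = 100)
  expect_false(identical(a$records$residues, c$records$residues))
})

test_that("copy counts add up and outputs round-trip through seqio", {
  tr <- sim_tree(6)
  sim <- simulate_clade(tr, gain_branch = 8L, sub_prob = 0.02,
                        copies_per_species = 2:3, seed = 3)
  copies <- table(sim$records$species)
  expect_true(all(copies >= 2 & copies <= 3))
  expect_equal(nrow(sim$records), sum(copies))
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(sim$records, f)
  back <- read_fasta(f)
  expect_equal(back$residues, sim$records$residues)
  expect_equal(back$species, sim$records$species)
})

test_that("simulation parameters are validated", {
  tr <- sim_tree(5)
  expect_error(simulate_clade(tr, gain_branch = 99L), "no node")
  expect_error(simulate_clade(tr, gain_branch = "nope"), "not in tree")
  expect_error(simulate_clade(tr, gain_branch = 7L, sub_prob = 1.5), "0, 1")
  expect_error(simulate_clade(tr, gain_branch = ape::Ntip(tr) + 1L), "root")
})

test_that("screen -> fitch recovers the planted gain exactly when noise-free", {
  tr <- sim_tree(12, seed = 2)
  gain <- ape::Ntip(tr) + 5L
  sim <- simulate_clade(tr, gain_branch = gain, sub_prob = 0, seed = 11)
  scr <- screen_dataset(sim$records)
  expect_equal(nrow(scr$rejected), 0)
  per_species <- tapply(scr$table$state, scr$table$species,
                        function(s) if (any(s == "oxidizable")) "1" else "0")
  h <- fitch_history(tr, per_species[tr$tip.label])
  expect_equal(nrow(h$gains), 1)
  expect_equal(h$gains$child, unname(sim$truth$gain_branch[["child"]]))
  expect_equal(nrow(h$losses), 0)
})

test_that("motif recovery is exact when landmarks are conserved, despite noise", {
  tr <- sim_tree(10, seed = 4)
  sim <- simulate_clade(tr, gain_branch = 14L, sub_prob = 0.04, seed = 12)
  scr <- screen_dataset(sim$records)
  joined <- merge(scr$table, data.frame(
    species = names(sim$truth$tip_states),
    truth = ifelse(sim$truth$tip_states == 1, "MM", "VV")
  ))
  expect_equal(joined$motif, joined$truth)
})

test_that("benchmark groups honor prevalences, copies and determinism", {
  sim <- make_benchmark(n_vert = 40, n_invert = 20, p_vert = 1, p_invert = 0,
                        seed = 8)
  scr <- screen_dataset(sim$records)
  s <- summarize_clades(scr$table)
  expect_equal(s$pct_sequences[s$group == "Vertebrata"], 100.00)
  expect_equal(s$pct_sequences[s$group == "Invertebrata"], 0.00)
  expect_equal(s$pct_species[s$group == "Vertebrata"], 100.00)

  sim2 <- make_benchmark(n_vert = 40, n_invert = 20, p_vert = 1, p_invert = 0,
                         seed = 8)
  expect_identical(sim$records, sim2$records)
  expect_error(make_benchmark(n_vert = 0), "at least one")
  expect_error(make_benchmark(p_vert = 2), "0, 1")

  copies <- table(sim$records$species)
  expect_true(all(copies >= 1 & copies <= 3))
  expect_equal(length(sim$truth$states), 60)
})

test_that("generated data satisfy every downstream module contract", {
  sim <- make_benchmark(n_vert = 15, n_invert = 10, seed = 6)
  # seqio round-trip
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(sim$records, f)
  expect_equal(read_fasta(f)$accession, sim$records$accession)
  # screening + aggregation accept the records
  smry <- summarize_clades(screen_dataset(sim$records)$table)
  expect_setequal(smry$group, c("Vertebrata", "Invertebrata"))
  expect_equal(sum(smry$n_sequences), 25)
})
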