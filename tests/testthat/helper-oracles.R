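# Independent oracles used across the suite. They recompute expected values
# from first principles and never call the code paths they check.

# Exhaustive alignment oracle: enumerate every global alignment (as an op
# string over M/D/E) and score it by scanning substitutions and maximal gap
# runs. Only feasible for short strings; used to validate the recursive
# oracle below and the aligner on tiny cases.
oracle_align_enum <- function(q, r, sm, go, ge) {
  qv <- strsplit(q, "")[[1]]; rv <- strsplit(r, "")[[1]]
  best <- -Inf
  score_ops <- function(ops) {
    i <- 0; j <- 0; s <- 0
    run <- "" # current gap-run type
    run_len <- 0
    for (op in ops) {
      if (op == "M") {
        if (run_len > 0) s <- s - (go + ge * run_len)
        run <- ""; run_len <- 0
        i <- i + 1; j <- j + 1
        s <- s + sm[qv[i], rv[j]]
      } else {
        if (op != run) {
          if (run_len > 0) s <- s - (go + ge * run_len)
          run <- op; run_len <- 0
        }
        run_len <- run_len + 1
        if (op == "D") i <- i + 1 else j <- j + 1
      }
    }
    if (run_len > 0) s <- s - (go + ge * run_len)
    s
  }
  rec <- function(i, j, ops) {
    if (i == length(qv) && j == length(rv)) {
      sc <- score_ops(ops)
      if (sc > best) best <<- sc
      return(invisible())
    }
    if (i < length(qv) && j < length(rv)) rec(i + 1, j + 1, c(ops, "M"))
    if (i < length(qv)) rec(i + 1, j, c(ops, "D"))
    if (j < length(rv)) rec(i, j + 1, c(ops, "E"))
  }
  rec(0, 0, character(0))
  best
}

# Recursive memoized oracle for the affine-gap recursion: top-down over
# (i, j, last-op). Independent implementation style from the package's
# iterative row-vectorized DP.
oracle_align_rec <- function(q, r, sm, go, ge) {
  qv <- strsplit(q, "")[[1]]; rv <- strsplit(r, "")[[1]]
  nq <- length(qv); nr <- length(rv)
  NEG <- -1e15
  memo <- array(NA_real_, dim = c(nq + 1, nr + 1, 3)) # states M/D/E
  f <- function(i, j, s) {
    v <- memo[i + 1, j + 1, s]
    if (!is.na(v)) return(v)
    v <- if (s == 1) { # M: q_i ~ r_j
      if (i == 0 && j == 0) 0
      else if (i == 0 || j == 0) NEG
      else sm[qv[i], rv[j]] + max(f(i - 1, j - 1, 1), f(i - 1, j - 1, 2),
                                  f(i - 1, j - 1, 3))
    } else if (s == 2) { # D: q_i ~ gap
      if (i == 0) NEG
      else max(f(i - 1, j, 1) - go - ge, f(i - 1, j, 3) - go - ge,
               f(i - 1, j, 2) - ge)
    } else { # E: r_j ~ gap
      if (j == 0) NEG
      else max(f(i, j - 1, 1) - go - ge, f(i, j - 1, 2) - go - ge,
               f(i, j - 1, 3) - ge)
    }
    memo[i + 1, j + 1, s] <<- v
    v
  }
  max(f(nq, nr, 1), f(nq, nr, 2), f(nq, nr, 3))
}

# Brute-force parsimony oracle: minimum number of edges with differing end
# states over every labeling of internal nodes (and of '?' tips).
oracle_parsimony <- function(tree, tip_states) {
  ntip <- ape::Ntip(tree)
  n_node <- ntip + ape::Nnode(tree)
  fixed <- rep(NA_integer_, n_node)
  for (t in seq_len(ntip)) {
    s <- tip_states[[tree$tip.label[t]]]
    if (s != "?") fixed[t] <- as.integer(s)
  }
  free <- which(is.na(fixed))
  edges <- tree$edge
  best <- Inf
  for (mask in 0:(2^length(free) - 1)) {
    lab <- fixed
    lab[free] <- bitwAnd(bitwShiftR(mask, seq_along(free) - 1), 1L)
    cost <- sum(lab[edges[, 1]] != lab[edges[, 2]])
    if (cost < best) best <- cost
  }
  best
}

random_protein <- function(n, alphabet = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

toy_scoring <- function(match = 2, mismatch = -1, go = 3, ge = 1) {
  ab <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  m <- matrix(mismatch, length(ab), length(ab), dimnames = list(ab, ab))
  diag(m) <- match
  scoring_scheme(matrix = m, gap_open = go, gap_extend = ge)
}
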