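# Reference-anchored residue numbering. Each query protein is globally
# aligned (affine gaps, end gaps penalized) to a short regulatory-domain
# reference fragment carrying landmark coordinates in CaMKII-gamma numbering;
# the alignment yields a map from reference positions to query positions.

#' Build a reference frame
#'
#' A reference frame is a reference fragment plus its absolute coordinate
#' system: `offset` is the CaMKII-gamma position number of the fragment's
#' first residue, and `landmarks` are named absolute positions. The standard
#' landmarks are the O-GlcNAcylation site S280, the oxidizable pair 281/282
#' and the autophosphorylation site T287.
#'
#' @param residues Amino-acid string of the reference fragment.
#' @param offset Absolute position number of the first residue.
#' @param landmarks Named integer vector of absolute positions. Defaults to
#'   `c(S280 = 280, pair_first = 281, pair_second = 282, T287 = 287)`.
#' @return An object of class `reference_frame`.
#' @export
reference_frame <- function(residues, offset,
                            landmarks = c(S280 = 280, pair_first = 281,
                                          pair_second = 282, T287 = 287)) {
  residues <- toupper(residues)
  n <- nchar(residues)
  bad <- which(!strsplit(residues, "")[[1]] %in% AA_ALPHABET)
  if (length(bad) > 0) abort(paste0("illegal residue at position ", bad[1]))
  if (any(landmarks < offset | landmarks > offset + n - 1)) {
    abort("every landmark must lie within the fragment")
  }
  at <- function(pos) substr(residues, pos - offset + 1, pos - offset + 1)
  if ("S280" %in% names(landmarks) && at(landmarks[["S280"]]) != "S") {
    abort("residue at landmark S280 must be 'S'")
  }
  if ("T287" %in% names(landmarks) && at(landmarks[["T287"]]) != "T") {
    abort("residue at landmark T287 must be 'T'")
  }
  structure(
    list(residues = residues, offset = as.integer(offset),
         landmarks = vapply(landmarks, as.integer, integer(1))),
    class = "reference_frame"
  )
}

#' @export
print.reference_frame <- function(x, ...) {
  cat("<reference_frame> ", nchar(x$residues), " aa, positions ",
      x$offset, "-", x$offset + nchar(x$residues) - 1, "\n", sep = "")
  cat("  ", x$residues, "\n", sep = "")
  cat("  landmarks: ",
      paste(names(x$landmarks), x$landmarks, sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

# Reconstructed regulatory-domain fragments. The mouse gamma fragment is the
# canonical CaMKII autoinhibitory segment with the MM pair; its absolute
# coordinates are calibrated by declaring the pair to be 281/282 (gamma
# numbering), which places S280 and T287 on the expected serine/threonine.
# The fly fragments are reconstructed from the coding strand of the published
# HDR template for the fly VV->MM knock-in: "fly" is wild type (VV),
# "fly_mm" the edited allele.
CAMKII_FRAGMENTS <- c(
  mouse_gamma = "QRSTVASMMHRQETVDCLKKFNARRKLKGAILTTM",
  fly         = "RERVASVVHRQETVDCLKKFNARRKLKGAILTTM",
  fly_mm      = "RERVASMMHRQETVDCLKKFNARRKLKGAILTTM"
)

#' The default CaMKII regulatory-domain reference frame
#'
#' A reconstruction of the mouse CaMKII-gamma regulatory-domain fragment
#' (QRSTVAS-MM-HRQET...), with `offset = 274` so that the methionine pair
#' receives positions 281/282, S280 falls on a serine and T287 on a
#' threonine. The fragment's absolute start is calibrated from the pair, as
#' only relative coordinates of the landmarks are fixed by the numbering
#' convention.
#'
#' @return A `reference_frame`.
#' @examples
#' camkii_frame()
#' @export
camkii_frame <- function() {
  reference_frame(CAMKII_FRAGMENTS[["mouse_gamma"]], offset = 274L)
}

#' Reconstructed CaMKII regulatory-domain fragments
#'
#' Mouse CaMKII-gamma (MM pair), wild-type fly CaMKII (VV pair) and the
#' MM-edited fly allele, as annotated sequence records. The fly fragments are
#' synthetic reconstructions derived from the published single-stranded HDR
#' template for the fly knock-in (see [ssodn_1r()]): the template's coding
#' strand translates to the edited fragment, and the wild type restores VV at
#' the pair.
#'
#' @return Tibble in [read_fasta()] record shape.
#' @export
camkii_fragments <- function() {
  tibble::tibble(
    accession = c("CAMK2G_MOUSE_FRAG", "CAMKII_DROME_FRAG", "CAMKII_DROME_MM_FRAG"),
    species = c("Mus musculus", "Drosophila melanogaster",
                "Drosophila melanogaster"),
    clade_labels = list(c("Vertebrata", "Mammalia"),
                        c("Invertebrata", "Arthropoda"),
                        c("Invertebrata", "Arthropoda")),
    residues = unname(CAMKII_FRAGMENTS),
    source = c("reconstructed mouse gamma regulatory-domain fragment",
               "reconstructed wild-type fly fragment (synthetic, from HDR template)",
               "reconstructed MM-edited fly fragment (synthetic, from HDR template)")
  )
}

# -- scoring -----------------------------------------------------------------

#' Alignment scoring scheme
#'
#' Substitution matrix plus affine gap penalties. A gap of length L costs
#' `gap_open + L * gap_extend`. The default matrix is BLOSUM62 with the `X`
#' row and column set to 0, so unknown residues are neutral for
#' classification purposes.
#'
#' @param matrix `"BLOSUM62"`, a square numeric matrix with one-letter
#'   dimnames, or a path to a whitespace-separated matrix file with
#'   one-letter row/column headers.
#' @param gap_open Non-negative gap opening penalty (default 11).
#' @param gap_extend Non-negative per-residue gap extension penalty
#'   (default 1).
#' @return An object of class `scoring_scheme`.
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 11, gap_extend = 1) {
  if (is.character(matrix) && length(matrix) == 1) {
    if (identical(matrix, "BLOSUM62")) {
      env <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = env)
      m <- env$BLOSUM62
    } else {
      m <- read_score_matrix(matrix)
    }
  } else {
    m <- as.matrix(matrix)
  }
  keep <- intersect(rownames(m), AA_ALPHABET)
  m <- m[keep, keep, drop = FALSE]
  if (!"X" %in% rownames(m)) {
    m <- rbind(cbind(m, X = 0), X = 0)
  }
  m["X", ] <- 0
  m[, "X"] <- 0
  if (gap_open < 0 || gap_extend < 0) abort("gap penalties must be >= 0")
  structure(
    list(matrix = m, gap_open = gap_open, gap_extend = gap_extend),
    class = "scoring_scheme"
  )
}

#' Read a substitution matrix from a whitespace-separated table
#'
#' Expected format: a header row of one-letter residue codes, then one row
#' per residue starting with its code. Lines starting with `#` are ignored.
#'
#' @param file Path to the matrix file.
#' @return Square numeric matrix with residue dimnames.
#' @export
read_score_matrix <- function(file) {
  lines <- readLines(file)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  header <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  rows <- strsplit(trimws(lines[-1]), "\\s+")
  m <- do.call(rbind, lapply(rows, function(r) as.numeric(r[-1])))
  rownames(m) <- vapply(rows, `[[`, character(1), 1)
  colnames(m) <- header
  m
}

# -- global alignment (Gotoh, end gaps penalized) ----------------------------

# Row-vectorized affine-gap DP. States per cell (i over query, j over ref):
#   M[i,j]  best score ending in query_i aligned to ref_j
#   D[i,j]  best score ending in query_i aligned to a gap (gap in reference)
#   E[i,j]  best score ending in ref_j aligned to a gap (gap in query)
# D depends on the previous row only; E's same-row recursion is solved with a
# running cummax of max(M, D) + ge * j.
align_dp <- function(q, r, submat, go, ge) {
  nq <- length(q); nr <- length(r)
  NEG <- -1e15
  open <- go + ge
  # row 0: leading gap in query (ref consumed)
  M_prev <- c(0, rep(NEG, nr)) # M_prev[j+1] = score at (i-1, j)
  D_prev <- rep(NEG, nr + 1)
  E_prev <- c(NEG, -(go + ge * seq_len(nr)))
  H_prev <- pmax(M_prev, D_prev, E_prev)
  M_rows <- matrix(NEG, nq + 1, nr + 1)
  D_rows <- matrix(NEG, nq + 1, nr + 1)
  E_rows <- matrix(NEG, nq + 1, nr + 1)
  M_rows[1, ] <- M_prev; D_rows[1, ] <- D_prev; E_rows[1, ] <- E_prev
  for (i in seq_len(nq)) {
    s <- submat[q[i], r] # substitution scores vs all ref positions
    M_cur <- c(NEG, H_prev[seq_len(nr)] + s)
    D_cur <- pmax(pmax(M_prev, E_prev) - open, D_prev - ge)
    # E along the row: E[j] = max_{k<j} max(M_cur,D_cur)[k] - go - ge*(j-k)
    MD <- pmax(M_cur, D_cur)
    run <- cummax(MD[seq_len(nr)] + ge * (0:(nr - 1)))
    E_cur <- c(NEG, run - go - ge * seq_len(nr))
    H_prev <- pmax(M_cur, D_cur, E_cur)
    M_prev <- M_cur; D_prev <- D_cur; E_prev <- E_cur
    M_rows[i + 1, ] <- M_cur; D_rows[i + 1, ] <- D_cur; E_rows[i + 1, ] <- E_cur
  }
  list(M = M_rows, D = D_rows, E = E_rows)
}

# Deterministic traceback. Tie-break order when scores tie: substitution,
# then gap-in-query (consume reference), then gap-in-reference (consume
# query).
align_traceback <- function(dp, q, r, submat, go, ge) {
  nq <- length(q); nr <- length(r)
  open <- go + ge
  i <- nq; j <- nr
  last <- pmax(dp$M[i + 1, j + 1], dp$D[i + 1, j + 1], dp$E[i + 1, j + 1])
  state <- if (dp$M[i + 1, j + 1] == last) "M"
           else if (dp$E[i + 1, j + 1] == last) "E"
           else "D"
  ops <- character(0)
  while (i > 0 || j > 0) {
    if (i == 0) { ops <- c(ops, rep("E", j)); break }
    if (j == 0) { ops <- c(ops, rep("D", i)); break }
    if (state == "M") {
      ops <- c(ops, "M")
      prev <- dp$M[i + 1, j + 1] - submat[q[i], r[j]]
      i <- i - 1; j <- j - 1
      state <- if (dp$M[i + 1, j + 1] == prev) "M"
               else if (dp$E[i + 1, j + 1] == prev) "E"
               else "D"
    } else if (state == "E") { # ref j vs gap
      ops <- c(ops, "E")
      v <- dp$E[i + 1, j + 1]
      j <- j - 1
      state <- if (j >= 0 && dp$M[i + 1, j + 1] - open == v) "M"
               else if (dp$E[i + 1, j + 1] - ge == v) "E"
               else "D"
    } else { # D: query i vs gap
      ops <- c(ops, "D")
      v <- dp$D[i + 1, j + 1]
      i <- i - 1
      state <- if (dp$M[i + 1, j + 1] - open == v) "M"
               else if (dp$E[i + 1, j + 1] - open == v) "E"
               else "D"
    }
  }
  rev(ops)
}

#' Anchor a query protein to a reference frame by global alignment
#'
#' End-to-end (Needleman-Wunsch/Gotoh) alignment with affine gap penalties;
#' end gaps are penalized. The traceback is deterministic: at score ties a
#' substitution is preferred, then a gap in the query, then a gap in the
#' reference.
#'
#' @param query Amino-acid string (20 letters plus X).
#' @param frame A [reference_frame()].
#' @param scoring A [scoring_scheme()].
#' @return An object of class `anchored_alignment`: `aligned_ref`,
#'   `aligned_query` (gap character `-`), `score`, and `ref_to_query`, a
#'   named integer vector mapping each absolute reference position to the
#'   1-based query position aligned under it (`NA` at reference positions
#'   aligned to a gap).
#' @export
global_align <- function(query, frame, scoring = scoring_scheme()) {
  query <- toupper(query)
  if (!nzchar(query)) abort("query is empty")
  qv <- strsplit(query, "")[[1]]
  bad <- which(!qv %in% AA_ALPHABET)
  if (length(bad) > 0) {
    abort(paste0("query has illegal residue '", qv[bad[1]],
                 "' at position ", bad[1]))
  }
  rv <- strsplit(frame$residues, "")[[1]]
  sm <- scoring$matrix
  dp <- align_dp(qv, rv, sm, scoring$gap_open, scoring$gap_extend)
  nq <- length(qv); nr <- length(rv)
  score <- max(dp$M[nq + 1, nr + 1], dp$D[nq + 1, nr + 1], dp$E[nq + 1, nr + 1])
  ops <- align_traceback(dp, qv, rv, sm, scoring$gap_open, scoring$gap_extend)
  aq <- character(length(ops)); ar <- character(length(ops))
  i <- 0; j <- 0
  r2q <- rep(NA_integer_, nr)
  for (k in seq_along(ops)) {
    op <- ops[k]
    if (op == "M") {
      i <- i + 1; j <- j + 1
      aq[k] <- qv[i]; ar[k] <- rv[j]; r2q[j] <- i
    } else if (op == "D") {
      i <- i + 1; aq[k] <- qv[i]; ar[k] <- "-"
    } else {
      j <- j + 1; aq[k] <- "-"; ar[k] <- rv[j]
    }
  }
  names(r2q) <- frame$offset + seq_len(nr) - 1
  structure(
    list(aligned_ref = paste(ar, collapse = ""),
         aligned_query = paste(aq, collapse = ""),
         score = score, ref_to_query = r2q,
         query = query, frame = frame),
    class = "anchored_alignment"
  )
}

#' @export
print.anchored_alignment <- function(x, ...) {
  cat("<anchored_alignment> score ", x$score, "\n", sep = "")
  cat("  ref:   ", x$aligned_ref, "\n", sep = "")
  cat("  query: ", x$aligned_query, "\n", sep = "")
  invisible(x)
}

#' Residues under the reference landmarks
#'
#' @param aln An [global_align()] result for `query` against `frame`.
#' @param frame The [reference_frame()] used.
#' @param query The query string used.
#' @return Named character vector, one entry per landmark: the query residue
#'   aligned under that reference position, or `NA` where the landmark
#'   aligns to a gap.
#' @export
map_landmarks <- function(aln, frame = aln$frame, query = aln$query) {
  pos <- aln$ref_to_query[as.character(frame$landmarks)]
  out <- ifelse(is.na(pos), NA_character_,
                substring(query, pos, pos))
  names(out) <- names(frame$landmarks)
  out
}

#' Identity/coverage filter against the reference frame
#'
#' Operationalizes the survey's inclusion criteria: a sequence passes when
#' the fraction of reference positions aligned to a non-gap residue is at
#' least `min_ref_coverage` and the identity over aligned (both non-gap)
#' columns is at least `min_identity`.
#'
#' @param aln An `anchored_alignment`.
#' @param min_identity Identity threshold in \[0, 1\] (default 0.60;
#'   identity is measured over a short window, so random sequences reach
#'   far higher identities than they would over full-length alignments).
#' @param min_ref_coverage Reference coverage threshold in \[0, 1\]
#'   (default 0.80).
#' @return List with `pass` (logical), `identity`, `coverage` and `reasons`
#'   (character vector of failed criteria, empty when passing).
#' @export
coverage_filter <- function(aln, min_identity = 0.60, min_ref_coverage = 0.80) {
  if (min_identity < 0 || min_identity > 1 ||
      min_ref_coverage < 0 || min_ref_coverage > 1) {
    abort("thresholds must lie in [0, 1]")
  }
  rv <- strsplit(aln$aligned_ref, "")[[1]]
  qv <- strsplit(aln$aligned_query, "")[[1]]
  both <- rv != "-" & qv != "-"
  coverage <- sum(!is.na(aln$ref_to_query)) / length(aln$ref_to_query)
  identity <- if (sum(both) == 0) 0 else sum(rv[both] == qv[both]) / sum(both)
  reasons <- character(0)
  if (coverage < min_ref_coverage) {
    reasons <- c(reasons, "coverage below threshold")
  }
  if (identity < min_identity) {
    reasons <- c(reasons, "identity below threshold")
  }
  list(pass = length(reasons) == 0, identity = identity,
       coverage = coverage, reasons = reasons)
}
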