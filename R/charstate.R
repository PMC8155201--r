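# Classification of the 281/282 residue pair (oxidizable vs not) and of the
# auxiliary PTM sites S280/T287, plus whole-dataset screening.

GAP <- "-"

check_letter <- function(x, arg) {
  if (length(x) != 1) abort(paste0(arg, " must be a single letter"))
  if (is.na(x)) return(GAP)
  x <- toupper(x)
  if (nchar(x) != 1) abort(paste0(arg, " must be a single letter, got '", x, "'"))
  x
}

#' Classify the 281/282 residue pair
#'
#' The pair is *oxidizable* when both residues are redox-labile (methionine
#' or cysteine) - the canonical motifs are MM (gamma/delta/beta-type) and CM
#' (alpha-type); MC and CC are also flagged oxidizable and can be tallied
#' separately by motif. The state is *undetermined* when either residue is a
#' gap or X, otherwise *non_oxidizable*.
#'
#' @param res281,res282 Single residue letters, `"-"`/`NA` for a gap, or
#'   `"X"`.
#' @return Tibble with one row: `residue281`, `residue282`, `motif`
#'   (`"--"`-style for gaps) and `state`.
#' @examples
#' classify_pair("M", "M")  # oxidizable, motif MM
#' classify_pair("V", "V")  # non_oxidizable
#' @export
classify_pair <- function(res281, res282) {
  a <- check_letter(res281, "res281")
  b <- check_letter(res282, "res282")
  state <- if (a %in% c(GAP, "X") || b %in% c(GAP, "X")) {
    "undetermined"
  } else if (a %in% c("M", "C") && b %in% c("M", "C")) {
    "oxidizable"
  } else {
    "non_oxidizable"
  }
  tibble::tibble(residue281 = a, residue282 = b,
                 motif = paste0(a, b), state = state)
}

#' Classify the auxiliary PTM sites S280 and T287
#'
#' Position 280 supports O-GlcNAcylation when it is a serine; position 287
#' supports activating autophosphorylation when it is a phosphorylatable
#' threonine or serine. Gap/X yields `undetermined`.
#'
#' @param pos280,pos287 Single residue letters, `"-"`/`NA`, or `"X"`.
#' @return Tibble with one row: `site280` (`glcnac_capable` / `negative` /
#'   `undetermined`) and `site287` (`phospho_capable` / `negative` /
#'   `undetermined`).
#' @export
classify_sites <- function(pos280, pos287) {
  a <- check_letter(pos280, "pos280")
  b <- check_letter(pos287, "pos287")
  site280 <- if (a %in% c(GAP, "X")) "undetermined"
             else if (a == "S") "glcnac_capable" else "negative"
  site287 <- if (b %in% c(GAP, "X")) "undetermined"
             else if (b %in% c("T", "S")) "phospho_capable" else "negative"
  tibble::tibble(site280 = site280, site287 = site287)
}

#' Screen a sequence dataset for the oxidizable pair
#'
#' Anchors every record to the reference frame, applies the
#' identity/coverage inclusion filter, and classifies the landmark residues
#' of each passing sequence. Every input record lands either in the
#' classification table or in the rejected list, never both.
#'
#' @param records Tibble of sequence records ([read_fasta()] shape).
#' @param frame A [reference_frame()]; defaults to [camkii_frame()].
#' @param scoring A [scoring_scheme()].
#' @param min_identity,min_ref_coverage Filter thresholds, see
#'   [coverage_filter()].
#' @return Object of class `pair_screen`: a list with `table` (one row per
#'   passing sequence: `accession`, `species`, `clade`, `clade_labels`,
#'   `residue281`, `residue282`, `motif`, `state`, `site280`, `site287`,
#'   `identity`, `coverage`) and `rejected` (`accession`, `reason`).
#'   `tidy()` returns the table.
#' @export
screen_dataset <- function(records, frame = camkii_frame(),
                           scoring = scoring_scheme(),
                           min_identity = 0.60, min_ref_coverage = 0.80) {
  if (nrow(records) == 0) abort("empty dataset")
  rows <- vector("list", nrow(records))
  rej <- vector("list", nrow(records))
  for (k in seq_len(nrow(records))) {
    aln <- global_align(records$residues[k], frame, scoring)
    filt <- coverage_filter(aln, min_identity, min_ref_coverage)
    if (!filt$pass) {
      rej[[k]] <- tibble::tibble(
        accession = records$accession[k],
        reason = paste(filt$reasons, collapse = "; ")
      )
      next
    }
    lm <- map_landmarks(aln, frame, records$residues[k])
    pair <- classify_pair(lm[["pair_first"]], lm[["pair_second"]])
    sites <- classify_sites(lm[["S280"]], lm[["T287"]])
    cl <- records$clade_labels[[k]]
    rows[[k]] <- dplyr::bind_cols(
      tibble::tibble(
        accession = records$accession[k],
        species = records$species[k],
        clade = if (length(cl) > 0) cl[1] else NA_character_,
        clade_labels = list(cl)
      ),
      pair, sites,
      tibble::tibble(identity = filt$identity, coverage = filt$coverage)
    )
  }
  structure(
    list(table = dplyr::bind_rows(rows), rejected = dplyr::bind_rows(rej)),
    class = "pair_screen"
  )
}

#' @export
print.pair_screen <- function(x, ...) {
  cat("<pair_screen> ", nrow(x$table), " classified, ",
      nrow(x$rejected), " rejected\n", sep = "")
  if (nrow(x$table) > 0) {
    tab <- table(x$table$state)
    cat("  states: ", paste(names(tab), tab, sep = "=", collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' @rdname screen_dataset
#' @param x A `pair_screen` object.
#' @param ... Unused.
#' @method tidy pair_screen
#' @export
tidy.pair_screen <- function(x, ...) x$table

#' @rdname screen_dataset
#' @method glance pair_screen
#' @export
glance.pair_screen <- function(x, ...) {
  tibble::tibble(
    n_input = nrow(x$table) + nrow(x$rejected),
    n_classified = nrow(x$table),
    n_rejected = nrow(x$rejected),
    n_oxidizable = sum(x$table$state == "oxidizable"),
    n_undetermined = sum(x$table$state == "undetermined")
  )
}
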