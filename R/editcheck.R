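# Verification of CRISPR HDR knock-in designs: does the single-stranded
# repair template introduce the intended residue-pair change, and does it
# carry the diagnostic restriction site used for genotyping?

#' Describe an HDR knock-in design
#'
#' @param guide Guide (protospacer) sequence, DNA.
#' @param template Single-stranded HDR oligo sequence as ordered/printed.
#' @param codon_strand Which strand of the template carries the coding
#'   sequence: `"forward"` (the printed strand) or `"reverse"` (its reverse
#'   complement).
#' @param frame_offset Reading-frame offset (0/1/2) on the coding strand.
#' @param expected_before,expected_after The residue pair before and after
#'   editing, two amino-acid letters each (e.g. `"VV"` to `"MM"`).
#' @param diagnostic_motif Restriction site introduced for genotyping
#'   (default `"ATGCAT"`, NsiI).
#' @return Object of class `edit_design`.
#' @export
edit_design <- function(guide, template, codon_strand = c("reverse", "forward"),
                        frame_offset = 0, expected_before = "VV",
                        expected_after = "MM", diagnostic_motif = "ATGCAT") {
  codon_strand <- match.arg(codon_strand)
  guide <- validate_nt(guide, "guide")
  template <- validate_nt(template, "template")
  if (nchar(template) < nchar(guide)) {
    abort("template must be at least as long as the guide")
  }
  check_pair <- function(x, arg) {
    x <- toupper(x)
    if (nchar(x) != 2 || !all(strsplit(x, "")[[1]] %in% AA_STANDARD)) {
      abort(paste0(arg, " must be a 2-letter amino-acid string"))
    }
    x
  }
  structure(
    list(guide = guide, template = template, codon_strand = codon_strand,
         frame_offset = as.integer(frame_offset),
         expected_before = check_pair(expected_before, "expected_before"),
         expected_after = check_pair(expected_after, "expected_after"),
         diagnostic_motif = validate_nt(diagnostic_motif, "diagnostic_motif")),
    class = "edit_design"
  )
}

#' Verify an HDR knock-in design
#'
#' Translates the declared coding strand of the template in the declared
#' frame and searches the translation for the expected post-edit residue
#' pair; scans both strands of the printed template for the diagnostic
#' restriction motif (palindromic motifs are counted once per locus). As the
#' reading frame within a genomic oligo is rarely printed, the report also
#' lists every frame of the coding strand in which the expected pair occurs.
#'
#' @param design An [edit_design()].
#' @return List of class `hdr_report`: `introduces_expected_pair` (logical,
#'   for the declared strand/frame), `pair_position` (1-based codon index of
#'   the pair's first residue in the declared-frame translation, `NA` if
#'   absent), `frames_with_pair` (integer vector of frame offsets on the
#'   coding strand containing the pair), `diagnostic_sites` (1-based starts
#'   on the printed strand), `coding_strand_used`.
#' @examples
#' d <- edit_design(crispr_guide_1(), ssodn_1r(), codon_strand = "reverse")
#' verify_hdr_design(d)
#' @export
verify_hdr_design <- function(design) {
  coding <- if (design$codon_strand == "reverse") {
    revcomp(design$template)
  } else {
    design$template
  }
  pair_in_frame <- function(off) {
    aa <- tryCatch(translate_nt(coding, off), error = function(e) "")
    as.integer(regexpr(design$expected_after, aa, fixed = TRUE))
  }
  pos_declared <- pair_in_frame(design$frame_offset)
  frames <- Filter(function(off) pair_in_frame(off) > 0, 0:2)
  sites <- find_sites(design$diagnostic_motif, design$template,
                      both_strands = TRUE)
  # coding-strand coordinates are invariant under flipping the printed strand
  sites_coding <- if (design$codon_strand == "reverse") {
    sort(nchar(design$template) - sites - nchar(design$diagnostic_motif) + 2L)
  } else {
    sites
  }
  structure(
    list(
      introduces_expected_pair = pos_declared > 0,
      pair_position = if (pos_declared > 0) pos_declared else NA_integer_,
      frames_with_pair = as.integer(unlist(frames)),
      diagnostic_sites = sites,
      diagnostic_sites_coding = as.integer(sites_coding),
      coding_strand_used = design$codon_strand
    ),
    class = "hdr_report"
  )
}

#' @export
print.hdr_report <- function(x, ...) {
  cat("<hdr_report>\n")
  cat("  introduces expected pair: ", x$introduces_expected_pair,
      if (!is.na(x$pair_position)) paste0(" (codon ", x$pair_position, ")"),
      "\n", sep = "")
  cat("  coding strand: ", x$coding_strand_used,
      "; frames with pair: ",
      if (length(x$frames_with_pair)) paste(x$frames_with_pair, collapse = ",")
      else "none", "\n", sep = "")
  cat("  diagnostic sites (printed strand): ",
      if (length(x$diagnostic_sites)) paste(x$diagnostic_sites, collapse = ", ")
      else "none", "\n", sep = "")
  invisible(x)
}

#' Published fly knock-in reagents
#'
#' The 176-nt single-stranded HDR template (ssODN-1R) and the 20-nt CRISPR
#' guide used to replace the VV pair of *Drosophila melanogaster* CaMKII
#' with MM. The template's reverse complement carries the coding sequence
#' with the edited ATG-ATG codons and a silent NsiI site (ATGCAT) for
#' genotyping by restriction digest.
#'
#' @return A character string.
#' @export
ssodn_1r <- function() {
  paste0(
    "AACATTGTCGTAAGTATGGCTCCCTTTAGCTTGCGCCGCGCATTAAATTTCTTGAGACAG",
    "TCTACGGTTTCTTGGCGATGCATCATGGAAGCGACTCGTTCGCGTTGCTGTAACAATGTT",
    "TTTTCATTATCTTTATGTAAACCTAAGAGAAAAATTAGTCTGCACTTACACAAATC"
  )
}

#' @rdname ssodn_1r
#' @export
crispr_guide_1 <- function() "GTTACAGCAACGCGAACGTG"
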