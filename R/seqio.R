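# Readers/writers for FASTA, taxonomy TSV and Newick, plus the nucleotide
# utilities used by the edit-design checker. File parsing is delegated to
# Biostrings/ape; this layer adds the header schema, validation and the
# tibble record shape used by the rest of the package.

#' Read annotated protein sequences from FASTA
#'
#' Headers are split on `|` into the fields named by `header_schema`
#' (default `accession|species|clade`); the clade field may itself be a
#' `;`-separated path of higher-taxon labels, coarsest first. Sequences are
#' uppercased and a single terminal `*` (stop) is stripped. Residues must be
#' drawn from the 20 standard amino-acid letters plus `X`.
#'
#' @param file Path to a FASTA file, or a character string of FASTA text.
#' @param header_schema Character vector naming the `|`-separated header
#'   fields in order. Must contain `"accession"`; `"species"` and `"clade"`
#'   are recognized; any other field names are ignored.
#' @return A tibble with one row per record: `accession`, `species`,
#'   `clade_labels` (list column of character vectors), `residues`, `source`.
#' @examples
#' fa <- ">ACC1|Mus musculus|Vertebrata\nQRSTVASMMHRQET\n"
#' read_fasta(fa)
#' @export
read_fasta <- function(file, header_schema = c("accession", "species", "clade")) {
  if (!("accession" %in% header_schema)) {
    abort("header_schema must include 'accession'")
  }
  src <- if (length(file) == 1 && !grepl("\n", file) && file.exists(file)) {
    file
  } else {
    tmp <- tempfile(fileext = ".fasta")
    writeLines(sub("\n$", "", paste(file, collapse = "\n")), tmp)
    tmp
  }
  if (!any(grepl("^>", readLines(src, warn = FALSE)))) {
    abort("no records in FASTA input")
  }
  set <- Biostrings::readBStringSet(src)
  if (length(set) == 0) abort("no records in FASTA input")
  headers <- names(set)
  seqs <- toupper(as.character(set))
  seqs <- sub("\\*$", "", seqs)

  recs <- purrr::map2(headers, seqs, function(h, s) {
    fields <- strsplit(h, "|", fixed = TRUE)[[1]]
    fields <- trimws(fields)
    named <- stats::setNames(
      as.list(fields[seq_along(header_schema)]),
      header_schema
    )
    acc <- named[["accession"]]
    if (is.null(acc) || is.na(acc) || !nzchar(acc)) {
      abort(paste0("record with header '", h, "' is missing an accession"))
    }
    species <- named[["species"]] %||% NA_character_
    if (is.na(species)) species <- ""
    clade <- named[["clade"]] %||% NA_character_
    clade_labels <- if (is.na(clade) || !nzchar(clade)) {
      character(0)
    } else {
      trimws(strsplit(clade, ";", fixed = TRUE)[[1]])
    }
    if (!nzchar(s)) abort(paste0("record '", acc, "' has an empty sequence"))
    bad <- which(!strsplit(s, "")[[1]] %in% AA_ALPHABET)
    if (length(bad) > 0) {
      abort(paste0(
        "record '", acc, "' has illegal residue '",
        substr(s, bad[1], bad[1]), "' at position ", bad[1]
      ))
    }
    tibble::tibble(
      accession = acc, species = species,
      clade_labels = list(clade_labels), residues = s, source = h
    )
  })
  out <- dplyr::bind_rows(recs)
  dup <- out$accession[duplicated(out$accession)]
  if (length(dup) > 0) {
    abort(paste0("duplicate accession(s): ", paste(unique(dup), collapse = ", ")))
  }
  out
}

#' Write annotated protein sequences to FASTA
#'
#' Headers are rebuilt as `accession|species|clade;path`; lines wrap at
#' `width` columns (default 60). `read_fasta(write_fasta(x))` recovers the
#' records exactly.
#'
#' @param records Tibble as produced by [read_fasta()].
#' @param file Output path.
#' @param width Line-wrap column, default 60.
#' @return `file`, invisibly.
#' @export
write_fasta <- function(records, file, width = 60) {
  headers <- purrr::pmap_chr(
    list(records$accession, records$species, records$clade_labels),
    function(acc, sp, cl) {
      paste(acc, sp, paste(cl, collapse = ";"), sep = "|")
    }
  )
  set <- Biostrings::BStringSet(records$residues)
  names(set) <- headers
  Biostrings::writeXStringSet(set, file, width = width)
  invisible(file)
}

#' Read a taxonomy table
#'
#' Tab-separated with columns `accession`, `species`, `clade_path`
#' (`;`-separated, coarsest first). Used to override or augment
#' header-derived annotations via [apply_taxonomy()].
#'
#' @param file Path to the TSV, or TSV text.
#' @return Tibble with `accession`, `species`, `clade_labels` (list column).
#' @export
read_taxonomy <- function(file) {
  src <- if (length(file) == 1 && !grepl("\n", file) && file.exists(file)) {
    file
  } else {
    textConnection(paste(file, collapse = "\n"))
  }
  df <- utils::read.delim(src, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("accession", "species", "clade_path")
  missing_cols <- setdiff(need, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("taxonomy table missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  dup <- df$accession[duplicated(df$accession)]
  if (length(dup) > 0) {
    abort(paste0("duplicate accession(s) in taxonomy table: ",
                 paste(unique(dup), collapse = ", ")))
  }
  tibble::tibble(
    accession = as.character(df$accession),
    species = as.character(df$species),
    clade_labels = purrr::map(
      as.character(df$clade_path),
      function(p) trimws(strsplit(p, ";", fixed = TRUE)[[1]])
    )
  )
}

#' Override record annotations from a taxonomy table
#'
#' @param records Tibble from [read_fasta()].
#' @param taxonomy Tibble from [read_taxonomy()].
#' @return `records` with `species` and `clade_labels` replaced for every
#'   accession listed in `taxonomy`.
#' @export
apply_taxonomy <- function(records, taxonomy) {
  idx <- match(records$accession, taxonomy$accession)
  hit <- !is.na(idx)
  records$species[hit] <- taxonomy$species[idx[hit]]
  records$clade_labels[hit] <- taxonomy$clade_labels[idx[hit]]
  records
}

#' Read a rooted guide tree from Newick
#'
#' The tree must be rooted, with unique tip labels. Node ages in millions of
#' years can be carried as branch lengths (an ultrametric or near-ultrametric
#' chronogram; see [node_ages()]) or supplied later as a node-age table to
#' [date_gains()].
#'
#' @param file Path to a Newick file, or a Newick string.
#' @return An `ape` `phylo` object.
#' @export
read_guide_tree <- function(file) {
  is_text <- grepl("\\(", file[1])
  tree <- tryCatch(
    suppressWarnings(
      if (is_text) ape::read.tree(text = file) else ape::read.tree(file)
    ),
    error = function(e) NULL
  )
  if (is.null(tree)) abort("could not parse Newick input")
  if (!inherits(tree, "phylo")) abort("input must contain a single tree")
  if (any(duplicated(tree$tip.label))) {
    abort(paste0("duplicate tip label(s): ",
                 paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
                       collapse = ", ")))
  }
  if (!ape::is.rooted(tree)) abort("tree must be rooted")
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0)) {
    abort("negative branch lengths: a child would be older than its parent")
  }
  tree
}

# -- nucleotide utilities ----------------------------------------------------

validate_nt <- function(bases, what = "sequence") {
  bases <- toupper(bases)
  if (!nzchar(bases)) abort(paste0(what, " is empty"))
  bad <- which(!strsplit(bases, "")[[1]] %in% c("A", "C", "G", "T"))
  if (length(bad) > 0) {
    abort(paste0(what, " has non-ACGT character '",
                 substr(bases, bad[1], bad[1]), "' at position ", bad[1]))
  }
  bases
}

#' Reverse complement of a DNA sequence
#'
#' @param bases DNA string over A/C/G/T (case-insensitive).
#' @return The reverse-complement string, uppercase.
#' @examples
#' revcomp("ATGC")     # "GCAT"
#' revcomp("ATGCAT")   # palindromic NsiI site
#' @export
revcomp <- function(bases) {
  bases <- validate_nt(bases)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(bases)))
}

#' Translate a DNA sequence in a given frame
#'
#' Standard genetic code; stops render as `*`; a trailing partial codon is
#' dropped.
#'
#' @param bases DNA string.
#' @param frame_offset 0, 1 or 2: number of bases skipped before the first
#'   codon.
#' @return Amino-acid string.
#' @examples
#' translate_nt("ATGATGA")  # "MM", trailing A dropped
#' @export
translate_nt <- function(bases, frame_offset = 0) {
  if (!frame_offset %in% 0:2) abort("frame_offset must be 0, 1 or 2")
  bases <- validate_nt(bases)
  sub <- substr(bases, frame_offset + 1, nchar(bases))
  n <- nchar(sub) - nchar(sub) %% 3
  if (n < 3) abort("sequence shorter than one codon after frame offset")
  sub <- substr(sub, 1, n)
  as.character(Biostrings::translate(
    Biostrings::DNAString(sub),
    no.init.codon = TRUE
  ))
}

#' Find occurrences of a nucleotide motif
#'
#' Returns 1-based start positions on the forward strand of `target`. With
#' `both_strands = TRUE`, occurrences of the motif's reverse complement are
#' mapped back to forward-strand starts; loci found on both strands (as every
#' palindromic site is) are reported once.
#'
#' @param motif Motif string (e.g. a restriction site).
#' @param target Target DNA string, longer than `motif`.
#' @param both_strands Scan the reverse strand too?
#' @return Sorted integer vector of 1-based start positions.
#' @examples
#' find_sites("ATGCAT", "AAATGCATAA")  # 3
#' @export
find_sites <- function(motif, target, both_strands = FALSE) {
  motif <- validate_nt(motif, "motif")
  target <- validate_nt(target, "target")
  if (nchar(motif) > nchar(target)) {
    abort("motif must not be longer than target")
  }
  hits <- Biostrings::start(Biostrings::matchPattern(
    Biostrings::DNAString(motif), Biostrings::DNAString(target)
  ))
  if (both_strands) {
    rc <- revcomp(motif)
    hits2 <- Biostrings::start(Biostrings::matchPattern(
      Biostrings::DNAString(rc), Biostrings::DNAString(target)
    ))
    hits <- union(hits, hits2)
  }
  sort(as.integer(hits))
}
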