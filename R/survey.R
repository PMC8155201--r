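# One-shot orchestration of the survey: read inputs, screen, aggregate,
# reconstruct ancestry, write a report bundle (TSV/JSON/Newick). Everything
# is deterministic given the config and inputs.

#' Build or read a survey run configuration
#'
#' @param fasta Path to the protein FASTA.
#' @param out_dir Output directory (created if absent).
#' @param taxonomy Optional path to a taxonomy TSV overriding headers.
#' @param tree Optional path to a rooted Newick guide tree whose tips are
#'   species names; enables the ancestry stage.
#' @param group_by Grouping column for the clade summary (default "clade").
#' @param min_identity,min_ref_coverage Screening thresholds.
#' @param gap_open,gap_extend Alignment gap penalties.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(fasta, out_dir, taxonomy = NULL, tree = NULL,
                       group_by = "clade", min_identity = 0.60,
                       min_ref_coverage = 0.80, gap_open = 11,
                       gap_extend = 1) {
  for (p in c(fasta, taxonomy, tree)) {
    if (!is.null(p) && !file.exists(p)) {
      abort(paste0("input path does not exist: ", p))
    }
  }
  structure(
    list(fasta = fasta, out_dir = out_dir, taxonomy = taxonomy, tree = tree,
         group_by = group_by, min_identity = min_identity,
         min_ref_coverage = min_ref_coverage, gap_open = gap_open,
         gap_extend = gap_extend),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param file Path to a YAML file whose keys match the arguments of
#'   `run_config()`.
#' @export
read_run_config <- function(file) {
  if (!file.exists(file)) abort(paste0("config file not found: ", file))
  y <- yaml::read_yaml(file)
  do.call(run_config, y)
}

write_tsv_plain <- function(df, path) {
  for (nm in names(df)) {
    if (is.list(df[[nm]])) {
      df[[nm]] <- vapply(df[[nm]], function(v) paste(v, collapse = ";"),
                         character(1))
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full survey pipeline
#'
#' scan -> aggregate -> (optional) ancestry, writing a report bundle to the
#' configured output directory: `classification.tsv`, `rejected.tsv`,
#' `clade_summary.tsv`, `gains.tsv` and `annotated_tree.nwk` (when a guide
#' tree is supplied), and `summary.json` with per-stage counts and a config
#' hash. Species-level tip states for the ancestry stage are derived from
#' the classification: a species is state 1 if at least one of its copies is
#' oxidizable, 0 if all determined copies are not, `?` if it has no
#' determined copy or is absent from the dataset.
#'
#' @param config A [run_config()] (or path to a YAML config).
#' @return Invisibly, a list with `screen`, `summary`, `history` (or `NULL`)
#'   and `paths` of the written files.
#' @export
run_survey <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  records <- read_fasta(config$fasta)
  if (!is.null(config$taxonomy)) {
    records <- apply_taxonomy(records, read_taxonomy(config$taxonomy))
  }
  scoring <- scoring_scheme(gap_open = config$gap_open,
                            gap_extend = config$gap_extend)
  scr <- screen_dataset(records, scoring = scoring,
                        min_identity = config$min_identity,
                        min_ref_coverage = config$min_ref_coverage)
  summary_tab <- summarize_clades(scr$table, group_by = config$group_by)

  paths <- list(
    classification = file.path(config$out_dir, "classification.tsv"),
    rejected = file.path(config$out_dir, "rejected.tsv"),
    summary = file.path(config$out_dir, "clade_summary.tsv"),
    json = file.path(config$out_dir, "summary.json")
  )
  write_tsv_plain(scr$table, paths$classification)
  write_tsv_plain(scr$rejected, paths$rejected)
  write_tsv_plain(summary_tab, paths$summary)

  history <- NULL
  gains_dated <- NULL
  if (!is.null(config$tree)) {
    tree <- read_guide_tree(config$tree)
    per_species <- scr$table %>%
      dplyr::group_by(.data$species) %>%
      dplyr::summarise(
        state = if (any(.data$state == "oxidizable")) "1"
                else if (any(.data$state == "non_oxidizable")) "0"
                else "?",
        .groups = "drop"
      )
    # Newick writers commonly store spaces as underscores; match either way
    norm <- function(x) gsub("_", " ", x, fixed = TRUE)
    tip_states <- stats::setNames(rep("?", ape::Ntip(tree)), tree$tip.label)
    idx <- match(norm(tree$tip.label), norm(per_species$species))
    tip_states[!is.na(idx)] <- per_species$state[idx[!is.na(idx)]]
    if (!all(tip_states == "?")) {
      history <- fitch_history(tree, tip_states)
      gains <- history$gains
      if (!is.null(tree$edge.length)) {
        gains_dated <- date_gains(history)
        gains <- dplyr::bind_cols(
          gains, gains_dated[, c("age_older", "age_younger")]
        )
      }
      paths$gains <- file.path(config$out_dir, "gains.tsv")
      write_tsv_plain(gains, paths$gains)
      annotated <- tree
      annotated$node.label <- paste0(
        "state", history$resolved_states[(ape::Ntip(tree) + 1):
                                           (ape::Ntip(tree) + ape::Nnode(tree))]
      )
      paths$tree <- file.path(config$out_dir, "annotated_tree.nwk")
      ape::write.tree(annotated, paths$tree)
    }
  }

  summary_json <- list(
    schema_version = "1.0",
    config_hash = rlang::hash(config[sort(names(unclass(config)))]),
    n_input = nrow(records),
    n_classified = nrow(scr$table),
    n_rejected = nrow(scr$rejected),
    groups = summary_tab,
    n_gains = if (!is.null(history)) nrow(history$gains) else NA,
    n_losses = if (!is.null(history)) nrow(history$losses) else NA,
    min_changes = if (!is.null(history)) history$min_changes else NA
  )
  jsonlite::write_json(summary_json, paths$json, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(screen = scr, summary = summary_tab, history = history,
                 gains_dated = gains_dated, paths = paths))
}
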