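# Clade- and species-level conservation statistics over a classification
# table. Percentages exclude undetermined records from the denominator and
# are rounded half-up to two decimals for reporting.

round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Clade-level conservation summary
#'
#' One row per group: sequence counts, oxidizable counts and percentages,
#' and species-level tallies where a species counts as positive when at
#' least one of its copies carries an oxidizable pair. Undetermined records
#' are excluded from percentage denominators but reported in
#' `n_undetermined`; a species whose copies are all undetermined is likewise
#' excluded from the species denominator.
#'
#' @param table Classification tibble (the `table` element of a
#'   [screen_dataset()] result, or `tidy()` of one).
#' @param group_by Name of the grouping column, default `"clade"`.
#' @return Tibble with columns `group`, `n_sequences`, `n_oxidizable`,
#'   `n_undetermined`, `pct_sequences`, `n_species`, `n_species_ge1`,
#'   `pct_species`, sorted by `group`. Percentages are `NA` when the
#'   denominator is zero.
#' @examples
#' scr <- screen_dataset(camkii_fragments())
#' summarize_clades(tidy(scr))
#' @export
summarize_clades <- function(table, group_by = "clade") {
  if (inherits(table, "pair_screen")) table <- table$table
  if (!group_by %in% names(table)) {
    abort(paste0("no grouping column '", group_by, "' in table"))
  }
  g <- table[[group_by]]
  bad <- is.na(g) | !nzchar(g)
  if (any(bad)) {
    abort(paste0("rows missing the grouping label: ",
                 paste(table$accession[bad], collapse = ", ")))
  }
  table %>%
    dplyr::group_by(group = .data[[group_by]]) %>%
    dplyr::summarise(
      n_sequences = dplyr::n(),
      n_oxidizable = sum(.data$state == "oxidizable"),
      n_undetermined = sum(.data$state == "undetermined"),
      n_species = dplyr::n_distinct(.data$species),
      n_species_ge1 = dplyr::n_distinct(
        .data$species[.data$state == "oxidizable"]
      ),
      n_species_det = dplyr::n_distinct(
        .data$species[.data$state != "undetermined"]
      ),
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      pct_sequences = dplyr::if_else(
        .data$n_sequences - .data$n_undetermined > 0,
        round_half_up(100 * .data$n_oxidizable /
                        pmax(.data$n_sequences - .data$n_undetermined, 1)),
        NA_real_
      ),
      pct_species = dplyr::if_else(
        .data$n_species_det > 0,
        round_half_up(100 * .data$n_species_ge1 /
                        pmax(.data$n_species_det, 1)),
        NA_real_
      )
    ) %>%
    dplyr::select("group", "n_sequences", "n_oxidizable", "n_undetermined",
                  "pct_sequences", "n_species", "n_species_ge1",
                  "pct_species") %>%
    dplyr::arrange(.data$group)
}

#' Contrast two clade summaries
#'
#' Pure arithmetic on two rows of a [summarize_clades()] result: the
#' difference in per-sequence prevalence of the oxidizable pair.
#'
#' @param summaries A [summarize_clades()] tibble.
#' @param group_a,group_b Group labels to contrast.
#' @return One-row tibble: `group_a`, `group_b`, `pct_a`, `pct_b`,
#'   `diff_pct` (a minus b, `NA` if either percentage is `NA`), `n_a`, `n_b`.
#' @export
compare_groups <- function(summaries, group_a, group_b) {
  pick <- function(g) {
    row <- summaries[summaries$group == g, ]
    if (nrow(row) != 1) abort(paste0("unknown group '", g, "'"))
    row
  }
  a <- pick(group_a); b <- pick(group_b)
  tibble::tibble(
    group_a = group_a, group_b = group_b,
    pct_a = a$pct_sequences, pct_b = b$pct_sequences,
    diff_pct = a$pct_sequences - b$pct_sequences,
    n_a = a$n_sequences, n_b = b$n_sequences
  )
}

#' Bar chart of oxidizable-pair prevalence by group
#'
#' @param summaries A [summarize_clades()] tibble.
#' @return A ggplot object: per-sequence prevalence by group, with the
#'   species-level prevalence overlaid as points.
#' @export
plot_clade_summary <- function(summaries) {
  ggplot2::ggplot(summaries, ggplot2::aes(x = .data$group)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$pct_sequences),
                      fill = "grey35", width = 0.6) +
    ggplot2::geom_point(ggplot2::aes(y = .data$pct_species),
                        colour = "firebrick", size = 3) +
    ggplot2::labs(
      x = NULL, y = "% with oxidizable 281/282 pair",
      title = "Oxidizable-pair prevalence by clade",
      subtitle = "bars: sequences; points: species with >= 1 positive copy"
    ) +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' @importFrom dplyr %>%
#' @export
dplyr::`%>%`
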