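# Synthetic-data generators: (i) sequence evolution on a tree with a planted
# gain of the oxidizable pair, (ii) a two-group prevalence benchmark shaped
# like the vertebrate/invertebrate survey. Both return record tibbles that
# are valid inputs for every other module, plus a ground-truth object.

mutate_seq <- function(chars, p_per_unit, branch_len, mutable) {
  # per-site substitution probability compounds over branch length
  q <- 1 - (1 - p_per_unit)^branch_len
  if (q <= 0) return(chars)
  hit <- which(mutable & stats::runif(length(chars)) < q)
  for (i in hit) {
    alt <- AA_STANDARD[AA_STANDARD != chars[i]]
    chars[i] <- sample(alt, 1)
  }
  chars
}

#' Simulate protein evolution on a tree with a planted gain
#'
#' Evolves a root sequence tip-ward with independent per-site substitutions
#' (uniform over the 19 alternative residues). The landmark pair positions
#' are held at `ancestral_motif` (default VV) on state-0 lineages and switch
#' to `gain_motif` (default MM) on and below the gain branch; positions in
#' the conserved set (default: landmarks plus/minus 3) never mutate. Each
#' species (tip) contributes one or more copies, which diversify
#' independently along the terminal branch.
#'
#' @param tree Rooted `phylo` with branch lengths. Tip labels are used as
#'   species names.
#' @param gain_branch Child node of the branch on which the pair is gained:
#'   a node id, or a tip/node label.
#' @param root_seq Root amino-acid sequence; must contain the frame's
#'   residues with the pair replaced by `ancestral_motif` as an exact
#'   substring. Default: exactly that fragment.
#' @param frame A [reference_frame()].
#' @param sub_prob Per-site substitution probability per unit branch length,
#'   in \[0, 1\].
#' @param conserved_halo Number of positions on each side of every landmark
#'   that are additionally held invariant (default 3).
#' @param copies_per_species Integer vector; each tip's copy number is drawn
#'   uniformly from it (a scalar gives a fixed count).
#' @param extra_gain_branches Optional additional child nodes with
#'   independent (convergent) gains.
#' @param gain_motif,ancestral_motif Two-letter motifs for the derived and
#'   ancestral pair (defaults MM and VV).
#' @param clade_label Clade label stamped on every record.
#' @param seed Integer seed; the run is byte-reproducible given it.
#' @return List with `records` (tibble in [read_fasta()] shape), `taxonomy`
#'   (tibble in [read_taxonomy()] shape) and `truth`, an object of class
#'   `sim_truth` holding the tree, the gain branch(es), per-tip states, the
#'   seed and the parameters.
#' @export
simulate_clade <- function(tree, gain_branch, root_seq = NULL,
                           frame = camkii_frame(), sub_prob = 0.02,
                           conserved_halo = 3, copies_per_species = 1L,
                           extra_gain_branches = integer(0),
                           gain_motif = "MM", ancestral_motif = "VV",
                           clade_label = "Metazoa", seed = 1L) {
  if (sub_prob < 0 || sub_prob > 1) abort("sub_prob must lie in [0, 1]")
  if (is.null(tree$edge.length)) abort("tree must have branch lengths")
  ntip <- ape::Ntip(tree)
  n_node <- ntip + ape::Nnode(tree)
  resolve_node <- function(x) {
    if (is.numeric(x)) {
      if (!x %in% seq_len(n_node)) abort(paste0("no node ", x, " in tree"))
      return(as.integer(x))
    }
    labs <- vapply(seq_len(n_node), function(v) node_label(tree, v),
                   character(1))
    idx <- which(labs == x)
    if (length(idx) != 1) abort(paste0("gain branch '", x, "' not in tree"))
    idx
  }
  gain_node <- resolve_node(gain_branch)
  extra_nodes <- vapply(extra_gain_branches, resolve_node, integer(1))
  root <- ntip + 1L
  if (gain_node == root) abort("gain branch must be below the root")

  pair_idx_frame <- frame$landmarks[c("pair_first", "pair_second")] -
    frame$offset + 1
  frag_anc <- strsplit(frame$residues, "")[[1]]
  frag_anc[pair_idx_frame] <- strsplit(ancestral_motif, "")[[1]]
  frag_anc <- paste(frag_anc, collapse = "")
  if (is.null(root_seq)) root_seq <- frag_anc
  at <- as.integer(regexpr(frag_anc, root_seq, fixed = TRUE))
  if (at < 1) {
    abort("root_seq must contain the frame fragment with the ancestral motif")
  }
  land_idx <- at - 1 + (frame$landmarks - frame$offset + 1)
  pair_idx <- land_idx[c("pair_first", "pair_second")]
  halo <- unique(unlist(lapply(land_idx, function(i) {
    seq(i - conserved_halo, i + conserved_halo)
  })))
  halo <- halo[halo >= 1 & halo <= nchar(root_seq)]
  mutable <- !(seq_len(nchar(root_seq)) %in% halo)

  withr::with_seed(seed, {
    kids <- node_children(tree)
    # branch lengths by child node
    bl <- numeric(n_node)
    bl[tree$edge[, 2]] <- tree$edge.length
    node_seq <- vector("list", n_node)
    node_state <- integer(n_node)
    node_seq[[root]] <- strsplit(toupper(root_seq), "")[[1]]
    node_state[root] <- 0L
    # preorder over edges
    pre <- rev(seq_len(nrow(ape::reorder.phylo(tree, "postorder")$edge)))
    edges <- ape::reorder.phylo(tree, "postorder")$edge
    gain_set <- c(gain_node, extra_nodes)
    records <- list()
    taxonomy <- list()
    tip_states <- stats::setNames(integer(ntip), tree$tip.label)
    for (e in pre) {
      p <- edges[e, 1]; v <- edges[e, 2]
      st <- node_state[p]
      if (v %in% gain_set) st <- 1L
      node_state[v] <- st
      stamp_pair <- function(chars) {
        motif <- if (st == 1L) gain_motif else ancestral_motif
        chars[pair_idx] <- strsplit(motif, "")[[1]]
        chars
      }
      if (v > ntip) {
        node_seq[[v]] <- stamp_pair(
          mutate_seq(node_seq[[p]], sub_prob, bl[v], mutable)
        )
      } else {
        species <- tree$tip.label[v]
        tip_states[species] <- st
        n_copies <- if (length(copies_per_species) == 1) {
          as.integer(copies_per_species)
        } else {
          sample(copies_per_species, 1)
        }
        for (cp in seq_len(n_copies)) {
          s <- stamp_pair(mutate_seq(node_seq[[p]], sub_prob, bl[v], mutable))
          records[[length(records) + 1]] <- tibble::tibble(
            accession = sprintf("%s_c%d", gsub("[^A-Za-z0-9]", "_", species), cp),
            species = species,
            clade_labels = list(clade_label),
            residues = paste(s, collapse = ""),
            source = "simulated"
          )
          taxonomy[[length(taxonomy) + 1]] <- tibble::tibble(
            accession = records[[length(records)]]$accession,
            species = species,
            clade_labels = list(clade_label)
          )
        }
      }
    }
    truth <- structure(
      list(tree = tree,
           gain_branch = c(parent = unname(tree$edge[tree$edge[, 2] == gain_node, 1]),
                           child = gain_node),
           extra_gain_branches = extra_nodes,
           tip_states = tip_states, seed = seed,
           params = list(sub_prob = sub_prob, conserved_halo = conserved_halo,
                         copies_per_species = copies_per_species,
                         gain_motif = gain_motif,
                         ancestral_motif = ancestral_motif)),
      class = "sim_truth"
    )
    list(records = dplyr::bind_rows(records),
         taxonomy = dplyr::bind_rows(taxonomy),
         truth = truth)
  })
}

#' @export
print.sim_truth <- function(x, ...) {
  if (!is.null(x$gain_branch)) {
    cat("<sim_truth> gain on branch ", x$gain_branch[["parent"]], "->",
        x$gain_branch[["child"]], "; ", sum(x$tip_states == 1),
        "/", length(x$tip_states), " tips in state 1; seed ", x$seed,
        "\n", sep = "")
  } else {
    cat("<sim_truth> benchmark, ", length(x$states), " sequences, ",
        sum(x$states == 1), " carriers; seed ", x$seed, "\n", sep = "")
  }
  invisible(x)
}

#' Two-group prevalence benchmark
#'
#' Builds a vertebrate-like and an invertebrate-like group of sequence
#' records in which each sequence independently carries the oxidizable pair
#' with its group's prevalence. Defaults mirror the survey conditions this
#' package models: per-sequence prevalences 0.9794 and 0.0223 at 300 and 150
#' sequences. Species are assembled from consecutive sequences with copy
#' numbers drawn from `copies_per_species`.
#'
#' @param n_vert,n_invert Number of sequences per group (both must be > 0).
#' @param p_vert,p_invert Per-sequence prevalence of the oxidizable pair in
#'   each group, in \[0, 1\].
#' @param copies_per_species Integer vector of possible copy numbers per
#'   species.
#' @param sub_prob Per-site substitution probability applied once per
#'   sequence away from the conserved landmarks (background divergence).
#' @param frame A [reference_frame()].
#' @param gain_motif,ancestral_motif Pair motifs for carriers/non-carriers.
#' @param seed Integer seed.
#' @return List with `records`, `taxonomy` and `truth` (class `sim_truth`
#'   without a tree; `truth$states` maps accession to 0/1,
#'   `truth$species_ge1` maps species to whether it holds a carrier).
#' @export
make_benchmark <- function(n_vert = 300, n_invert = 150,
                           p_vert = 0.9794, p_invert = 0.0223,
                           copies_per_species = 1:3, sub_prob = 0.05,
                           frame = camkii_frame(),
                           gain_motif = "MM", ancestral_motif = "VV",
                           seed = 1L) {
  if (n_vert < 1 || n_invert < 1) abort("each group needs at least one sequence")
  if (any(c(p_vert, p_invert) < 0 | c(p_vert, p_invert) > 1)) {
    abort("prevalences must lie in [0, 1]")
  }
  pair_idx <- frame$landmarks[c("pair_first", "pair_second")] -
    frame$offset + 1
  halo <- unique(unlist(lapply(
    frame$landmarks - frame$offset + 1,
    function(i) seq(i - 3, i + 3)
  )))
  halo <- halo[halo >= 1 & halo <= nchar(frame$residues)]
  mutable <- !(seq_len(nchar(frame$residues)) %in% halo)
  base <- strsplit(frame$residues, "")[[1]]

  withr::with_seed(seed, {
    build_group <- function(n, p, group, prefix) {
      states <- as.integer(stats::runif(n) < p)
      # carve n sequences into species of 1..k copies
      sp_sizes <- integer(0)
      left <- n
      while (left > 0) {
        k <- min(sample(rep(copies_per_species, 2), 1), left)
        sp_sizes <- c(sp_sizes, k)
        left <- left - k
      }
      sp_id <- rep(seq_along(sp_sizes), sp_sizes)
      species <- sprintf("%s species %03d", group, sp_id)
      residues <- vapply(seq_len(n), function(i) {
        chars <- mutate_seq(base, sub_prob, 1, mutable)
        motif <- if (states[i] == 1) gain_motif else ancestral_motif
        chars[pair_idx] <- strsplit(motif, "")[[1]]
        paste(chars, collapse = "")
      }, character(1))
      copy_no <- stats::ave(sp_id, sp_id, FUN = seq_along)
      tibble::tibble(
        accession = sprintf("%s%04d", prefix, seq_len(n)),
        species = species,
        clade_labels = purrr::map(species, ~group),
        residues = residues,
        source = "benchmark",
        state_truth = states,
        copy = copy_no
      )
    }
    vert <- build_group(n_vert, p_vert, "Vertebrata", "VRT")
    invert <- build_group(n_invert, p_invert, "Invertebrata", "INV")
    all <- dplyr::bind_rows(vert, invert)
    records <- dplyr::select(all, "accession", "species", "clade_labels",
                             "residues", "source")
    taxonomy <- tibble::tibble(
      accession = all$accession, species = all$species,
      clade_labels = all$clade_labels
    )
    ge1 <- all %>%
      dplyr::group_by(.data$species) %>%
      dplyr::summarise(ge1 = any(.data$state_truth == 1), .groups = "drop")
    truth <- structure(
      list(states = stats::setNames(all$state_truth, all$accession),
           species_ge1 = stats::setNames(ge1$ge1, ge1$species),
           seed = seed,
           params = list(n_vert = n_vert, n_invert = n_invert,
                         p_vert = p_vert, p_invert = p_invert,
                         copies_per_species = copies_per_species,
                         sub_prob = sub_prob)),
      class = "sim_truth"
    )
    list(records = records, taxonomy = taxonomy, truth = truth)
  })
}
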