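# Parsimony reconstruction of the binary presence/absence character for the
# oxidizable pair on a rooted (optionally dated) tree. The downpass is
# Hartigan's generalization of Fitch, exact for multifurcating nodes; the
# top-down resolution prefers state 0 (absence) wherever the choice is free,
# which pushes gains tipward and never invents an ancestral presence.

# postorder/preorder of internal+tip node ids for an ape phylo
node_children <- function(tree) {
  n_node <- ape::Nnode(tree) + ape::Ntip(tree)
  kids <- vector("list", n_node)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; c <- tree$edge[e, 2]
    kids[[p]] <- c(kids[[p]], c)
  }
  kids
}

node_label <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(tree$tip.label[node])
  lab <- tree$node.label[node - ntip]
  if (is.null(lab) || is.na(lab) || !nzchar(lab)) {
    paste0("node", node)
  } else {
    lab
  }
}

#' Fitch/Hartigan parsimony reconstruction of a binary character
#'
#' Computes the minimum number of state changes of a binary (0/1) character
#' on a rooted tree, a most-parsimonious labeling of every node, and the
#' branches on which gains (0 to 1) and losses (1 to 0) occur under that
#' labeling. Tips with state `"?"` are treated as `{0, 1}` during the
#' downpass and take their parent's resolved state in the output.
#' Multifurcations are handled exactly (Hartigan's algorithm). At the root,
#' and wherever the downpass state set is ambiguous and the parent state
#' belongs to it, resolution prefers the parent state; an ambiguous root
#' resolves to 0 (absence), a Dollo-flavored choice that places gains as
#' tipward as parsimony allows.
#'
#' @param tree Rooted `phylo` object.
#' @param tip_states Named vector (names = tip labels) with values
#'   0, 1 or `"?"`.
#' @return Object of class `character_history`: `tree`, `tip_states`,
#'   `node_sets` (downpass state sets per node), `resolved_states` (named by
#'   node id), `min_changes`, `gains` and `losses` (tibbles with `parent`,
#'   `child`, `parent_label`, `child_label`), and `ambiguous_nodes` (ids of
#'   internal nodes whose downpass set was `{0,1}`, i.e. where equally
#'   parsimonious placements exist).
#' @examples
#' tr <- ape::read.tree(text = "((A,B),(C,D));")
#' h <- fitch_history(tr, c(A = 1, B = 1, C = 0, D = 0))
#' h$min_changes
#' @export
fitch_history <- function(tree, tip_states) {
  ntip <- ape::Ntip(tree)
  states <- as.character(tip_states)
  names(states) <- names(tip_states)
  unknown <- setdiff(names(states), tree$tip.label)
  if (length(unknown) > 0) {
    abort(paste0("tip(s) not in tree: ", paste(unknown, collapse = ", ")))
  }
  missing_tips <- setdiff(tree$tip.label, names(states))
  if (length(missing_tips) > 0) {
    abort(paste0("no state for tip(s): ",
                 paste(missing_tips, collapse = ", ")))
  }
  if (!all(states %in% c("0", "1", "?"))) {
    abort("tip states must be 0, 1 or '?'")
  }
  if (all(states == "?")) abort("all tips are '?'")

  kids <- node_children(tree)
  n_node <- ntip + ape::Nnode(tree)
  root <- ntip + 1L
  # downpass: state sets as logical pairs c(has0, has1)
  sets <- matrix(FALSE, n_node, 2)
  changes <- 0L
  for (t in seq_len(ntip)) {
    s <- states[tree$tip.label[t]]
    sets[t, ] <- if (s == "?") c(TRUE, TRUE) else c(s == "0", s == "1")
  }
  poe <- ape::reorder.phylo(tree, "postorder")$edge
  internal_po <- unique(poe[, 1]) # children visited before their parents
  for (v in internal_po) {
    ch <- kids[[v]]
    k0 <- sum(vapply(ch, function(c) sets[c, 1], logical(1)))
    k1 <- sum(vapply(ch, function(c) sets[c, 2], logical(1)))
    kmax <- max(k0, k1)
    sets[v, ] <- c(k0 == kmax, k1 == kmax)
    changes <- changes + length(ch) - kmax
  }

  # top-down resolution
  resolved <- integer(n_node)
  pick <- function(set, prefer) {
    # prefer is 0 or 1; fall back to state 0 when free
    if (set[prefer + 1]) return(prefer)
    if (set[1]) 0L else 1L
  }
  resolved[root] <- pick(sets[root, ], prefer = 0L)
  for (e in rev(seq_len(nrow(poe)))) {
    p <- poe[e, 1]; c <- poe[e, 2]
    resolved[c] <- pick(sets[c, ], prefer = resolved[p])
  }
  labels <- vapply(seq_len(n_node), function(v) node_label(tree, v),
                   character(1))
  names(resolved) <- labels

  from <- resolved[tree$edge[, 1]]
  to <- resolved[tree$edge[, 2]]
  branch_tbl <- function(idx) {
    tibble::new_tibble(list(
      parent = tree$edge[idx, 1], child = tree$edge[idx, 2],
      parent_label = labels[tree$edge[idx, 1]],
      child_label = labels[tree$edge[idx, 2]]
    ), nrow = length(idx))
  }
  gains <- branch_tbl(which(from == 0L & to == 1L))
  losses <- branch_tbl(which(from == 1L & to == 0L))

  structure(
    list(tree = tree, tip_states = states,
         node_sets = sets, resolved_states = resolved,
         min_changes = as.integer(changes),
         gains = gains, losses = losses,
         ambiguous_nodes = which(sets[, 1] & sets[, 2] &
                                   seq_len(n_node) > ntip)),
    class = "character_history"
  )
}

#' @export
print.character_history <- function(x, ...) {
  cat("<character_history> ", ape::Ntip(x$tree), " tips, min changes ",
      x$min_changes, " (", nrow(x$gains), " gain(s), ", nrow(x$losses),
      " loss(es))\n", sep = "")
  if (nrow(x$gains) > 0) {
    cat("  gains on: ",
        paste(x$gains$parent_label, x$gains$child_label, sep = "->",
              collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @rdname fitch_history
#' @param x A `character_history`.
#' @param ... Unused.
#' @method tidy character_history
#' @export
tidy.character_history <- function(x, ...) {
  ntip <- ape::Ntip(x$tree)
  n_node <- ntip + ape::Nnode(x$tree)
  tibble::tibble(
    node = seq_len(n_node),
    label = names(x$resolved_states),
    is_tip = seq_len(n_node) <= ntip,
    state = unname(x$resolved_states),
    set = purrr::map_chr(seq_len(n_node), function(v) {
      paste(c("0", "1")[x$node_sets[v, ]], collapse = "/")
    })
  )
}

#' @rdname fitch_history
#' @method glance character_history
#' @export
glance.character_history <- function(x, ...) {
  tibble::tibble(
    n_tips = ape::Ntip(x$tree),
    n_tips_present = sum(x$tip_states == "1"),
    n_tips_unknown = sum(x$tip_states == "?"),
    min_changes = x$min_changes,
    n_gains = nrow(x$gains),
    n_losses = nrow(x$losses),
    n_ambiguous_nodes = length(x$ambiguous_nodes)
  )
}

#' Node ages of a dated tree
#'
#' Ages in the tree's time unit (here: millions of years), measured from the
#' present. Requires branch lengths; the deepest tip is placed at age 0, so
#' ultrametric chronograms get their natural ages.
#'
#' @param tree `phylo` with branch lengths.
#' @return Named numeric vector of ages, one per node id.
#' @export
node_ages <- function(tree) {
  if (is.null(tree$edge.length)) abort("tree has no branch lengths")
  depth <- ape::node.depth.edgelength(tree)
  ages <- max(depth) - depth
  names(ages) <- vapply(seq_along(ages), function(v) node_label(tree, v),
                        character(1))
  ages
}

#' Date the gain branches of a character history
#'
#' Each gain is bracketed by the ages of the branch's endpoints: the change
#' happened somewhere in `[child age, parent age]` million years ago.
#'
#' @param history A [fitch_history()] result.
#' @param ages Named numeric vector of node ages. Default: computed from the
#'   tree's branch lengths via [node_ages()]. Names may be node ids
#'   (as character) or node/tip labels.
#' @return Tibble with one row per gain branch: `parent_label`,
#'   `child_label`, `age_older`, `age_younger`.
#' @export
date_gains <- function(history, ages = NULL) {
  tree <- history$tree
  if (is.null(ages)) ages <- node_ages(tree)
  get_age <- function(node, label) {
    a <- if (as.character(node) %in% names(ages)) {
      ages[[as.character(node)]]
    } else if (label %in% names(ages)) {
      ages[[label]]
    } else {
      NA_real_
    }
    if (is.na(a)) abort(paste0("no age for node '", label, "'"))
    a
  }
  purrr::pmap_dfr(history$gains, function(parent, child, parent_label,
                                          child_label) {
    older <- get_age(parent, parent_label)
    younger <- get_age(child, child_label)
    if (younger > older) abort(paste0("node '", child_label,
                                      "' is older than its parent"))
    tibble::tibble(parent_label = parent_label, child_label = child_label,
                   age_older = older, age_younger = younger)
  })
}

#' Extant phylogenetic bracket inference level
#'
#' Classifies the support for inferring the character in the ancestor at
#' `focal_node` from its living descendants: level I when at least two of
#' the node's child lineages contain a state-1 tip (the trait is on both
#' sides of the bracket), level II when exactly one does, level III when
#' none does.
#'
#' @param tree Rooted `phylo`.
#' @param focal_node Internal node id, or a node label.
#' @param tip_states Named 0/1/`"?"` vector as for [fitch_history()].
#' @return `"I"`, `"II"` or `"III"`.
#' @export
bracket_infer <- function(tree, focal_node, tip_states) {
  ntip <- ape::Ntip(tree)
  if (is.character(focal_node)) {
    n_node <- ntip + ape::Nnode(tree)
    labs <- vapply(seq_len(n_node), function(v) node_label(tree, v),
                   character(1))
    idx <- which(labs == focal_node)
    if (length(idx) != 1) abort(paste0("unknown node '", focal_node, "'"))
    focal_node <- idx
  }
  if (focal_node <= ntip) abort("focal node is a tip, not an ancestor")
  kids <- node_children(tree)[[focal_node]]
  has_state1 <- vapply(kids, function(child) {
    tips <- tree$tip.label[descendant_tips(tree, child)]
    any(tip_states[tips] == "1", na.rm = TRUE)
  }, logical(1))
  n_sides <- sum(has_state1)
  if (n_sides >= 2) "I" else if (n_sides == 1) "II" else "III"
}

descendant_tips <- function(tree, node) {
  ntip <- ape::Ntip(tree)
  if (node <= ntip) return(node)
  kids <- node_children(tree)
  out <- integer(0)
  stack <- node
  while (length(stack) > 0) {
    v <- stack[1]; stack <- stack[-1]
    if (v <= ntip) out <- c(out, v) else stack <- c(stack, kids[[v]])
  }
  out
}

#' Plot a character history
#'
#' Simple rectangular cladogram with tips ordered as in the tree, nodes
#' colored by resolved state and gain branches highlighted.
#'
#' @param object A `character_history`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot character_history
#' @export
autoplot.character_history <- function(object, ...) {
  tree <- object$tree
  ntip <- ape::Ntip(tree)
  n_node <- ntip + ape::Nnode(tree)
  depth <- if (is.null(tree$edge.length)) {
    ape::node.depth.edgelength(ape::compute.brlen(tree, 1))
  } else {
    ape::node.depth.edgelength(tree)
  }
  y <- rep(NA_real_, n_node)
  y[seq_len(ntip)] <- seq_len(ntip)
  po <- unique(ape::reorder.phylo(tree, "postorder")$edge[, 1])
  kids <- node_children(tree)
  for (v in po) y[v] <- mean(y[kids[[v]]])
  nodes <- tibble::tibble(
    node = seq_len(n_node), x = depth, y = y,
    state = factor(unname(object$resolved_states)),
    label = names(object$resolved_states),
    is_tip = seq_len(n_node) <= ntip
  )
  edges <- tibble::tibble(
    x = depth[tree$edge[, 1]], xend = depth[tree$edge[, 2]],
    y = y[tree$edge[, 1]], yend = y[tree$edge[, 2]],
    gain = paste(tree$edge[, 1], tree$edge[, 2]) %in%
      paste(object$gains$parent, object$gains$child)
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x, xend = .data$xend, y = .data$y,
                   yend = .data$yend, colour = .data$gain)
    ) +
    ggplot2::scale_colour_manual(
      values = c(`FALSE` = "grey40", `TRUE` = "firebrick"),
      labels = c(`FALSE` = "no change", `TRUE` = "gain"), name = NULL
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, fill = .data$state),
      shape = 21, size = 2.5
    ) +
    ggplot2::geom_text(
      data = nodes[nodes$is_tip, ],
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$label),
      hjust = -0.2, size = 3
    ) +
    ggplot2::scale_fill_manual(
      values = c(`0` = "white", `1` = "black"),
      name = "pair present"
    ) +
    ggplot2::labs(x = "depth", y = NULL,
                  title = "Oxidizable-pair character history") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}
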