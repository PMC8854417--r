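#' @keywords internal
# Tip states as a character vector named by tip label, validated against the
# tree. Accepts a regime_assignment data frame or a named vector.
tip_states <- function(tree, states) {
  if (is.data.frame(states)) {
    states <- stats::setNames(as.character(states$regime), states$species_id)
  }
  labs <- normalize_species_id(tree$tip.label)
  names(states) <- normalize_species_id(names(states))
  miss <- setdiff(labs, names(states))
  if (length(miss) > 0) {
    stop("tip without state: ", paste(miss, collapse = ", "))
  }
  out <- states[labs]
  if (anyNA(out)) stop("tip without state")
  out
}

# Unit-cost Sankoff dynamic program over the binary character.
# Returns a (Ntip+Nnode) x 2 cost matrix; row minimum at the root is the
# parsimony score.
sankoff_costs <- function(tree, obs, levels) {
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  cost <- matrix(0, ntip + nnode, 2)
  cost[seq_len(ntip), ] <- Inf
  cost[cbind(seq_len(ntip), match(obs, levels))] <- 0
  edges <- ape::reorder.phylo(tree, "postorder")$edge
  for (i in seq_len(nrow(edges))) {             # children before parents
    p <- edges[i, 1]; k <- edges[i, 2]
    for (s in 1:2) {
      cost[p, s] <- cost[p, s] + min(cost[k, s], cost[k, 3 - s] + 1)
    }
  }
  cost
}

#' Fitch parsimony score of a binary character
#'
#' Minimal number of state changes needed to explain the observed tip
#' states on the tree (small parsimony, unordered binary character).
#'
#' @param tree A rooted, bifurcating [ape::phylo] tree.
#' @param states A [regime_assignment] data frame or a vector of states
#'   named by tip label.
#' @return Integer parsimony score.
#' @examples
#' tree <- ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")
#' fitch_score(tree, c(A = "SAT", B = "SAT", C = "NON_SAT", D = "NON_SAT"))
#' @export
fitch_score <- function(tree, states) {
  obs <- tip_states(tree, states)
  levels <- sort(unique(obs))
  if (length(levels) == 1) return(0L)
  if (length(levels) > 2) stop("only binary characters are supported")
  cost <- sankoff_costs(tree, obs, levels)
  as.integer(min(cost[ape::Ntip(tree) + 1, ]))
}

#' Enumerate all maximum-parsimony reconstructions
#'
#' Backtracks through the Sankoff dynamic program to produce every internal
#' node labelling that achieves the minimal change count, each converted to
#' a regime painting in which a branch carries the state of its child node
#' and the root's own state supplies the ancestral regime. Output order is
#' deterministic: reconstructions are sorted lexicographically by their node
#' label sequence.
#'
#' @inheritParams fitch_score
#' @return A list of `regime_painting` objects, each with elements
#'   `node_state` (state per node, tips first), `edge_regime` (state per
#'   edge, in `tree$edge` row order), `root_regime`, `n_changes` and
#'   `reconstruction_index`.
#' @export
enumerate_mp_reconstructions <- function(tree, states) {
  obs <- tip_states(tree, states)
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  levels <- sort(unique(obs))
  if (length(levels) > 2) stop("only binary characters are supported")
  if (length(levels) == 1) {
    node_state <- rep(levels, ntip + nnode)
    return(list(new_painting(tree, node_state, 1L)))
  }
  cost <- sankoff_costs(tree, obs, levels)
  children <- split(tree$edge[, 2], tree$edge[, 1])
  root <- ntip + 1
  # Depth-first expansion of partial labelings; states assigned in node
  # index order via recursion from the root keeps branching local.
  expand <- function(node, s) {
    # all minimal-cost labelings of node's strict descendants, given that
    # node itself is in state s
    if (node <= ntip) return(list(stats::setNames(integer(0), character(0))))
    acc <- list(stats::setNames(integer(0), character(0)))
    for (k in children[[as.character(node)]]) {
      best <- min(cost[k, 1] + (1 != s), cost[k, 2] + (2 != s))
      opts <- which(c(cost[k, 1] + (1 != s), cost[k, 2] + (2 != s)) == best)
      kid_sets <- list()
      for (t in opts) {
        for (sub in expand(k, t)) {
          entry <- c(stats::setNames(t, as.character(k)), sub)
          kid_sets[[length(kid_sets) + 1]] <- entry
        }
      }
      acc <- unlist(lapply(acc, function(a) {
        lapply(kid_sets, function(b) c(a, b))
      }), recursive = FALSE)
    }
    acc
  }
  score <- min(cost[root, ])
  labelings <- list()
  for (s in which(cost[root, ] == score)) {
    for (sub in expand(root, s)) {
      lab <- c(stats::setNames(s, as.character(root)), sub)
      labelings[[length(labelings) + 1]] <- lab
    }
  }
  paintings <- lapply(labelings, function(lab) {
    node_state <- character(ntip + nnode)
    node_state[seq_len(ntip)] <- obs
    node_state[as.integer(names(lab))] <- levels[lab]
    node_state
  })
  keys <- vapply(paintings, paste, character(1), collapse = "")
  paintings <- paintings[order(keys)]
  out <- lapply(seq_along(paintings), function(i) {
    new_painting(tree, paintings[[i]], i)
  })
  stopifnot(all(vapply(out, `[[`, 0L, "n_changes") == score))
  out
}

new_painting <- function(tree, node_state, index) {
  edge_regime <- node_state[tree$edge[, 2]]
  parent_regime <- node_state[tree$edge[, 1]]
  structure(
    list(
      node_state = node_state,
      edge_regime = edge_regime,
      root_regime = node_state[ape::Ntip(tree) + 1],
      n_changes = as.integer(sum(edge_regime != parent_regime)),
      reconstruction_index = as.integer(index)
    ),
    class = "regime_painting"
  )
}

#' @export
print.regime_painting <- function(x, ...) {
  cat("Regime painting #", x$reconstruction_index, ": root ", x$root_regime,
      ", ", x$n_changes, " change(s), ", length(x$edge_regime),
      " branches\n", sep = "")
  invisible(x)
}

#' Summarise ancestral states across MP reconstructions
#'
#' For each node, collects the set of states it takes across the supplied
#' maximum-parsimony reconstructions. A singleton set at the root supports
#' statements about the ancestral strategy; multi-state sets mark nodes that
#' are ambiguous under parsimony.
#'
#' @param paintings A non-empty list of `regime_painting` objects from
#'   [enumerate_mp_reconstructions()].
#' @return A list (one element per node, in node index order) of character
#'   vectors of states.
#' @export
ancestral_state_summary <- function(paintings) {
  if (length(paintings) == 0) stop("no paintings supplied")
  n_nodes <- length(paintings[[1]]$node_state)
  lapply(seq_len(n_nodes), function(i) {
    sort(unique(vapply(paintings, function(p) p$node_state[i], character(1))))
  })
}
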