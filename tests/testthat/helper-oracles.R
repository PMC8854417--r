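# Brute-force small-parsimony oracle: enumerate every internal-node
# labelling of a binary character and count state changes directly.
brute_force_parsimony <- function(tree, states) {
  obs <- states[tree$tip.label]
  ntip <- ape::Ntip(tree)
  nnode <- tree$Nnode
  levels <- sort(unique(obs))
  if (length(levels) == 1) {
    lab <- rep(levels, ntip + nnode)
    return(list(score = 0L, labelings = list(lab)))
  }
  best <- Inf
  keep <- list()
  for (mask in 0:(2^nnode - 1)) {
    internal <- levels[bitwAnd(bitwShiftR(mask, seq_len(nnode) - 1), 1L) + 1L]
    lab <- c(obs, internal)
    changes <- sum(lab[tree$edge[, 1]] != lab[tree$edge[, 2]])
    if (changes < best) {
      best <- changes
      keep <- list(unname(lab))
    } else if (changes == best) {
      keep[[length(keep) + 1]] <- unname(lab)
    }
  }
  list(score = as.integer(best), labelings = keep)
}

random_binary_states <- function(tree) {
  repeat {
    s <- sample(c("NON_SAT", "SAT"), ape::Ntip(tree), replace = TRUE)
    if (length(unique(s)) == 2) break
  }
  stats::setNames(s, tree$tip.label)
}

# Minimal stand-in with the fields compare_models() reads, for tests that
# only exercise the AICc bookkeeping.
fake_fit <- function(aicc, response = "E_area", predictors = "none") {
  list(response = response, predictors = predictors, t_half = 0.1,
       support_region = c(0, 1), v_y = 0.1, optimal_slope = NA_real_,
       optimal_slope_se = NA_real_, evolutionary_slope = NA_real_,
       evolutionary_slope_se = NA_real_, R2_phylo = 0.5, logL = -aicc / 2,
       AICc = aicc)
}

# A small fixed study-shaped dataset used by several OU tests.
ou_test_data <- function(n_tips = 18, seed = 42) {
  tree <- simulate_tree(n_tips, seed = seed)
  sim <- simulate_regimes(tree, "clade_paint", seed = seed + 1)
  traits <- simulate_ou_traits(tree, sim$painting,
                               sim_config(seed = seed + 2))
  list(tree = tree, painting = sim$painting, assignment = sim$assignment,
       traits = traits)
}
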