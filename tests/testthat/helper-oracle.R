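# Independent brute-force oracle: builds the full joint table of a network
# by looping over state-label assignments and looking CPT entries up by
# label, sharing no code with the package's vectorized enumeration path.

oracle_joint_table <- function(net) {
  state_sets <- lapply(net$nodes, function(nd) nd$states)
  names(state_sets) <- names(net$nodes)
  grid <- do.call(expand.grid,
                  c(state_sets, KEEP.OUT.ATTRS = FALSE,
                    stringsAsFactors = FALSE))
  grid$prob <- vapply(seq_len(nrow(grid)), function(i) {
    p <- 1
    for (nd in net$nodes) {
      cpt <- net$cpts[[nd$name]]
      child <- grid[i, nd$name]
      if (!length(nd$parents)) {
        p <- p * cpt[[child]]
      } else {
        entry <- do.call(`[`, c(list(cpt), as.list(
          c(child, unlist(grid[i, nd$parents, drop = FALSE])))))
        p <- p * entry
      }
    }
    p
  }, numeric(1))
  grid
}

# Conditional distribution of `query` given label evidence, from a
# precomputed oracle joint table.
oracle_marginal <- function(joint, net, query, evidence = NULL) {
  keep <- rep(TRUE, nrow(joint))
  for (nm in names(evidence)) keep <- keep & joint[[nm]] == evidence[[nm]]
  sub <- joint[keep, , drop = FALSE]
  total <- sum(sub$prob)
  states <- net$nodes[[query]]$states
  p <- vapply(states, function(s) sum(sub$prob[sub[[query]] == s]),
              numeric(1))
  setNames(p / total, states)
}

# Small hand-checkable fixture: rain -> sprinkler-free wet-grass chain.
tiny_net <- function() {
  bn_network(
    list(bn_node("rain", c("yes", "no")),
         bn_node("wet", c("yes", "no"), parents = "rain")),
    list(rain = c(0.3, 0.7),
         wet = array(c(0.9, 0.1, 0.2, 0.8), dim = c(2, 2)))
  )
}

# Hand-built ensemble whose mean trajectory is fully controlled: trial t
# has constant posterior p_true[t] on the true state except that all
# trials jump to `late` from case `jump_at` onwards.
toy_ensemble <- function(p_true, n = 10, true_state = "strong",
                         jump_at = NULL, late = NULL) {
  states <- c("none", "medium", "strong")
  n_trials <- length(p_true)
  traj <- array(NA_real_, dim = c(n, 3, n_trials),
                dimnames = list(NULL, states, NULL))
  for (t in seq_len(n_trials)) {
    p <- rep(p_true[t], n)
    if (!is.null(jump_at)) p[seq_len(n) >= jump_at] <- late[t]
    rest <- (1 - p) / 2
    for (s in states) {
      traj[, s, t] <- if (s == true_state) p else rest
    }
  }
  structure(list(trajectories = traj,
                 scenario = list(id = NA, r_true = true_state,
                                 acem = "perfect", acrm = "perfect"),
                 seeds = seq_len(n_trials), mode = "exact",
                 prior = c(none = 0.5, medium = 0.25, strong = 0.25)),
            class = "er_ensemble")
}
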