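#' Replicate-trial simulation for one scenario
#'
#' Runs `n_trials` independent synthetic studies of size `n_max` under one
#' scenario and fits the sequential posterior to each, giving the ensemble
#' of posterior trajectories from which convergence, trial-to-trial
#' variability and required sample size are read off. Trial `t` uses seed
#' `base_seed + t`, recorded in the result.
#'
#' @param net The network.
#' @param scenario Scenario id 1-9 or explicit specification (see
#'   [scenario_catalog()]).
#' @param n_max Study size per trial (default 1000).
#' @param n_trials Number of replicate trials (default 10).
#' @param base_seed Base seed; trial `t` uses `base_seed + t`.
#' @param mode Updating mode, `"exact"` or `"fixed-bf"` (see [er_fit()]).
#' @param fix_te Optional clamped true-exposure level.
#' @return An object of class `"er_ensemble"`: list with `trajectories`
#'   (array `n_max x 3 x n_trials`), `scenario`, `seeds`, `mode`, `prior`.
#' @seealso [mean_trajectory()], [required_sample_size()], [power_table()]
#' @export
#' @examples
#' ens <- run_trials(er_network(), scenario = 9, n_max = 100, n_trials = 3,
#'                   base_seed = 1)
#' required_sample_size(ens)
run_trials <- function(net = er_network(), scenario, n_max = 1000,
                       n_trials = 10, base_seed = 20190322,
                       mode = c("exact", "fixed-bf"), fix_te = NULL) {
  mode <- match.arg(mode)
  stopifnot(n_max >= 1, n_trials >= 1)
  sc <- as_scenario(scenario)
  r_states <- net$nodes[["R"]]$states
  seeds <- as.integer(base_seed) + seq_len(n_trials)
  traj <- array(NA_real_, dim = c(n_max, length(r_states), n_trials),
                dimnames = list(NULL, r_states, NULL))
  prior <- infer_marginal(net, "R")
  for (t in seq_len(n_trials)) {
    d <- generate_dataset(net, sc, n = n_max, seed = seeds[t],
                          fix_te = fix_te)
    traj[, , t] <- er_fit(d, net, prior = prior, mode = mode)$posterior
  }
  structure(list(trajectories = traj, scenario = sc, seeds = seeds,
                 mode = mode, prior = prior),
            class = "er_ensemble")
}

#' Mean posterior trajectory across trials
#'
#' Arithmetic mean of the per-trial posteriors at each case index (the
#' black line of the trajectory plots). A mean of normalized distributions
#' is itself normalized.
#'
#' @param ens An `"er_ensemble"`.
#' @return An `n_max x 3` matrix of mean posterior probabilities.
#' @export
mean_trajectory <- function(ens) {
  apply(ens$trajectories, c(1, 2), mean)
}

#' Required sample size to identify the true strength
#'
#' The smallest study size at which the across-trial mean posterior
#' probability of the scenario's true strength state first reaches
#' `threshold`. First crossing, not sustained crossing: the mean
#' trajectory may in principle dip below the threshold again afterwards.
#' If the threshold is never reached within `n_max` cases the value is
#' censored and reported as `Inf` (rendered `">n_max"`, e.g. `">1000"`).
#'
#' @param ens An `"er_ensemble"`.
#' @param threshold Posterior probability to reach (default 0.9).
#' @return Integer sample size, or `Inf` if censored.
#' @export
required_sample_size <- function(ens, threshold = 0.9) {
  stopifnot(threshold > 0, threshold < 1)
  true_state <- ens$scenario$r_true
  m <- mean_trajectory(ens)
  hit <- which(m[, true_state] >= threshold)
  if (!length(hit)) Inf else as.integer(hit[1])
}

#' Fraction of misleading trials
#'
#' A trial is misleading at study size `n` if its posterior probability on
#' the true strength state is at or below `bound`: the study has
#' accumulated "convincing" evidence for a wrong conclusion.
#'
#' @param ens An `"er_ensemble"`.
#' @param n Study size at which to evaluate (<= `n_max`).
#' @param bound Posterior probability at or below which a trial counts as
#'   misleading (default 0.1).
#' @return Fraction of trials in `[0, 1]`.
#' @export
misleading_trial_fraction <- function(ens, n, bound = 0.1) {
  stopifnot(n >= 1, n <= dim(ens$trajectories)[1])
  true_state <- ens$scenario$r_true
  mean(ens$trajectories[n, true_state, ] <= bound)
}

#' Required-sample-size table over the scenario grid
#'
#' Runs all nine scenarios and assembles the 3 x 3 table of required
#' sample sizes: rows the accuracy levels, columns the true strength
#' states. Censored cells (threshold not reached within `n_max`) are
#' `Inf`, printed and serialized as `">n_max"`.
#'
#' @inheritParams run_trials
#' @param threshold Posterior probability to reach (default 0.9).
#' @param keep_ensembles Keep the nine trial ensembles in the result
#'   (default `TRUE`; set `FALSE` to save memory).
#' @return An object of class `"er_power_table"`: list with `required_n`
#'   (3 x 3 numeric matrix, `Inf` = censored), `threshold`, `n_max`,
#'   `n_trials`, `base_seed`, `mode`, `grid_n` (the reporting sample
#'   sizes), `mean_at_grid` (mean posterior of the true state at the
#'   reporting sizes, one row per scenario) and optionally `ensembles`.
#' @export
#' @examples
#' \donttest{
#' pt <- power_table(er_network())
#' pt
#' }
power_table <- function(net = er_network(), base_seed = 20190322,
                        mode = c("exact", "fixed-bf"), n_max = 1000,
                        n_trials = 10, threshold = 0.9,
                        keep_ensembles = TRUE) {
  mode <- match.arg(mode)
  cat_df <- scenario_catalog()
  acc_levels <- unique(cat_df$acem)
  r_levels <- unique(cat_df$r_true)
  required_n <- matrix(NA_real_, length(acc_levels), length(r_levels),
                       dimnames = list(acc_levels, r_levels))
  grid_n <- c(20, 50, 100, 1000)
  grid_n <- grid_n[grid_n <= n_max]
  mean_at_grid <- matrix(NA_real_, nrow(cat_df), length(grid_n),
                         dimnames = list(paste0("scenario", cat_df$id),
                                         paste0("n", grid_n)))
  ensembles <- vector("list", nrow(cat_df))
  for (i in seq_len(nrow(cat_df))) {
    ens <- run_trials(net, cat_df$id[i], n_max = n_max,
                      n_trials = n_trials, base_seed = base_seed,
                      mode = mode)
    required_n[cat_df$acem[i], cat_df$r_true[i]] <-
      required_sample_size(ens, threshold)
    m <- mean_trajectory(ens)
    mean_at_grid[i, ] <- m[grid_n, cat_df$r_true[i]]
    if (keep_ensembles) ensembles[[i]] <- ens
  }
  structure(list(required_n = required_n, threshold = threshold,
                 n_max = n_max, n_trials = n_trials,
                 base_seed = as.integer(base_seed), mode = mode,
                 grid_n = grid_n, mean_at_grid = mean_at_grid,
                 ensembles = if (keep_ensembles) ensembles),
            class = "er_power_table")
}

# ">1000"-style rendering of a required-N value.
format_required_n <- function(x, n_max) {
  out <- character(length(x))
  fin <- is.finite(x)
  out[fin] <- as.character(as.integer(x[fin]))
  out[!fin] <- paste0(">", n_max)
  out
}

#' @export
print.er_power_table <- function(x, ...) {
  cat(sprintf(
    "Required sample size to reach %.0f%% posterior on the true strength\n",
    100 * x$threshold))
  cat(sprintf("(%d trials of up to %d cases per scenario, %s mode, base seed %d)\n\n",
              x$n_trials, x$n_max, x$mode, x$base_seed))
  disp <- matrix(format_required_n(x$required_n, x$n_max),
                 nrow(x$required_n), dimnames = dimnames(x$required_n))
  print(as.data.frame(disp), quote = FALSE)
  invisible(x)
}

#' Plot a trial ensemble
#'
#' One panel per strength state: the posterior probability of that state
#' against study size for each replicate trial (gray) and their mean
#' (black).
#'
#' @param x An `"er_ensemble"`.
#' @param states Strength states to plot (default: all).
#' @param ... Ignored.
#' @export
plot.er_ensemble <- function(x, states = colnames(x$trajectories[, , 1]),
                             ...) {
  old <- graphics::par(mfrow = c(1, length(states)),
                       mar = c(4, 4, 2.5, 0.5))
  on.exit(graphics::par(old))
  m <- mean_trajectory(x)
  n <- dim(x$trajectories)[1]
  for (s in states) {
    graphics::matplot(seq_len(n), x$trajectories[, s, ], type = "l",
                      lty = 1, col = "gray70", ylim = c(0, 1),
                      xlab = "sample size N", ylab = paste0("P(R = ", s, ")"),
                      main = sprintf("true R = %s, accuracy %s-%s",
                                     x$scenario$r_true, x$scenario$acem,
                                     x$scenario$acrm))
    graphics::lines(seq_len(n), m[, s], col = "black", lwd = 2)
  }
  invisible(x)
}
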