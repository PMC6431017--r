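#' Sample one case by ancestral sampling
#'
#' Draws a single full assignment from the network: nodes are visited in
#' topological order and each unclamped node is sampled from its CPT row
#' given the already-drawn (or clamped) parent states, by inverse-CDF over
#' the declared state order. Uses the current R random number stream
#' (Mersenne-Twister); seed management for whole datasets is done by
#' [generate_dataset()].
#'
#' @param net A `"bn"` object.
#' @param clamped Named character vector of nodes held fixed (the scenario
#'   truth, e.g. `R`, `AcEM`, `AcRM`).
#' @return Named character vector: one state per node.
#' @export
sample_case <- function(net, clamped = NULL) {
  draw_cases(net, clamped, 1L)[1L, ]
}

# Vectorized ancestral sampler: returns an n x n_nodes character matrix.
# One runif(n) block per unclamped node, consumed in topological order, so
# the draw is fully determined by the RNG state on entry.
draw_cases <- function(net, clamped, n) {
  ev <- check_evidence(net, clamped)
  nms <- names(net$nodes)
  idx <- matrix(NA_integer_, nrow = n, ncol = length(nms),
                dimnames = list(NULL, nms))
  for (nd in net$nodes) {
    k <- length(nd$states)
    if (nd$name %in% names(ev)) {
      idx[, nd$name] <- match(ev[[nd$name]], nd$states)
      next
    }
    cpt <- net$cpts[[nd$name]]
    if (!length(nd$parents)) {
      cum <- matrix(cumsum(cpt), nrow = n, ncol = k, byrow = TRUE)
    } else {
      flat <- matrix(cpt, nrow = k)           # columns = parent combos
      cum <- apply(flat, 2, cumsum)           # k x combos
      pdims <- vapply(nd$parents,
                      function(p) length(net$nodes[[p]]$states), integer(1))
      mult <- cumprod(c(1L, pdims[-length(pdims)]))
      combo <- 1L + as.integer(
        (idx[, nd$parents, drop = FALSE] - 1L) %*% mult)
      cum <- t(cum[, combo, drop = FALSE])    # n x k
    }
    u <- stats::runif(n)
    idx[, nd$name] <- pmin.int(1L + rowSums(cum < u), k)
  }
  out <- matrix(NA_character_, nrow = n, ncol = length(nms),
                dimnames = list(NULL, nms))
  for (nd in net$nodes) out[, nd$name] <- nd$states[idx[, nd$name]]
  out
}

#' Generate a synthetic exposure-response study
#'
#' Simulates `n` independent subjects under a scenario: the strength of
#' relationship `R` and the measurement accuracies `AcEM`/`AcRM` are clamped
#' to the scenario truth, true exposure is drawn from its uniform prior
#' (or clamped via `fix_te`), and true/measured states follow the network's
#' CPTs. The seed fully determines the dataset, so any run can be
#' reproduced from its metadata.
#'
#' @param net The network, typically [er_network()].
#' @param scenario Scenario id 1-9 or a list/row with `r_true`, `acem`,
#'   `acrm` (see [scenario_catalog()]).
#' @param n Number of subjects (>= 1, or 0 for an empty dataset).
#' @param seed Integer seed.
#' @param fix_te Optional true-exposure state (`"low"`, `"medium"`,
#'   `"high"`) to clamp `TE` instead of sampling it, emulating a design
#'   with controlled exposure levels.
#' @return An object of class `"er_dataset"`: a data frame with columns
#'   `case_index`, `te`, `tr`, `me`, `mr`, `match`, and attributes
#'   `scenario`, `clamps`, `seed`, `n`.
#' @seealso [outcome_frequencies()], [er_fit()], [write_dataset()]
#' @export
#' @examples
#' d <- generate_dataset(er_network(), scenario = 9, n = 5, seed = 1)
#' d
generate_dataset <- function(net = er_network(), scenario, n, seed,
                             fix_te = NULL) {
  if (!is.numeric(n) || length(n) != 1L || n < 0 || n != round(n)) {
    stop("invalid sample size n: must be a non-negative integer")
  }
  sc <- as_scenario(scenario)
  clamps <- c(R = sc$r_true, AcEM = sc$acem, AcRM = sc$acrm)
  if (!is.null(fix_te)) clamps <- c(clamps, TE = fix_te)
  check_evidence(net, clamps)
  n <- as.integer(n)
  if (n > 0L) {
    cases <- with_preserved_rng({
      set.seed(as.integer(seed), kind = "Mersenne-Twister")
      draw_cases(net, clamps, n)
    })
    d <- data.frame(
      case_index = seq_len(n),
      te = cases[, "TE"], tr = cases[, "TR"],
      me = cases[, "ME"], mr = cases[, "MR"],
      match = er_match_state(cases[, "ME"], cases[, "MR"]),
      stringsAsFactors = FALSE
    )
  } else {
    d <- data.frame(case_index = integer(), te = character(),
                    tr = character(), me = character(), mr = character(),
                    match = character(), stringsAsFactors = FALSE)
  }
  structure(d, scenario = sc, clamps = clamps, seed = as.integer(seed),
            class = c("er_dataset", "data.frame"))
}

# Run code under its own RNG without disturbing the caller's stream.
with_preserved_rng <- function(expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  expr
}

#' Simulate method for exposure-response networks
#'
#' Convenience wrapper around [generate_dataset()] following the base-R
#' `simulate()` idiom.
#'
#' @param object An `"er_bn"` network.
#' @param nsim Number of subjects.
#' @param seed Integer seed (required, for reproducibility).
#' @param scenario,fix_te Passed to [generate_dataset()].
#' @param ... Ignored.
#' @return An `"er_dataset"`.
#' @export
simulate.er_bn <- function(object, nsim = 1, seed = NULL, scenario,
                           fix_te = NULL, ...) {
  if (is.null(seed)) stop("simulate() needs an explicit integer seed")
  generate_dataset(object, scenario = scenario, n = nsim, seed = seed,
                   fix_te = fix_te)
}

#' Tabulate study outcomes
#'
#' Counts the nine `ERMatch` outcomes in a dataset. A sufficient statistic
#' for the strength-of-relationship posterior once the accuracies are known
#' (cases are conditionally independent given `R` and the clamped
#' accuracies).
#'
#' @param d An `"er_dataset"` (or any data frame with a `match` column).
#' @return Named integer vector over the nine outcome states, summing to
#'   the number of cases.
#' @export
#' @examples
#' d <- generate_dataset(er_network(), scenario = 9, n = 100, seed = 1)
#' outcome_frequencies(d)
outcome_frequencies <- function(d) {
  counts <- table(factor(d$match, levels = er_match_states()))
  stats::setNames(as.integer(counts), er_match_states())
}

#' @export
print.er_dataset <- function(x, ...) {
  sc <- attr(x, "scenario")
  if (is.null(sc)) {
    cat(sprintf("Exposure-response study: %d cases (no scenario metadata)\n",
                nrow(x)))
  } else {
    cat(sprintf(
      "Synthetic exposure-response study: %d cases (R = %s, accuracy %s-%s, seed %s)\n",
      nrow(x), sc$r_true, sc$acem, sc$acrm, format(attr(x, "seed"))))
  }
  print.data.frame(utils::head(as.data.frame(x), 10), row.names = FALSE)
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more cases\n")
  invisible(x)
}
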