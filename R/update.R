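#' Outcome likelihoods given the strength of relationship
#'
#' Computes `P(ERMatch = o | R = r, AcEM, AcRM)` for all nine outcomes and
#' all three strength states by exact inference, with the measurement
#' accuracies clamped as evidence. The analyst is assumed to know the
#' accuracies of their instruments; only the strength of relationship is
#' learned from the data.
#'
#' @param net The network.
#' @param acem,acrm Accuracy states for the exposure and response
#'   measurements.
#' @return A 9 x 3 matrix (class `"er_likelihoods"`), rows the outcome
#'   states, columns the `R` states; each column sums to 1. The accuracies
#'   are stored as attributes.
#' @seealso [bayes_factor()], [update_posterior()], [er_fit()]
#' @export
#' @examples
#' L <- outcome_likelihoods(er_network(), "perfect", "perfect")
#' L["ll", ]   # 1/9 under none, 0.20 under medium, 0.30 under strong
outcome_likelihoods <- function(net, acem, acrm) {
  r_states <- net$nodes[["R"]]$states
  L <- vapply(r_states, function(r) {
    infer_marginal(net, "ERMatch",
                   c(AcEM = acem, AcRM = acrm, R = r))
  }, numeric(length(er_match_states())))
  structure(L, acem = acem, acrm = acrm,
            class = c("er_likelihoods", class(L)))
}

#' Bayes factor for one strength state against its complement
#'
#' The Bayes factor compares the likelihood of an observed outcome under
#' one strength state `Ri` with its likelihood under the complement
#' "not-`Ri`", a mixture of the remaining states weighted by their
#' (renormalized) probabilities in `reference_prior`:
#' \deqn{BF(o, R_i) = \frac{P(o \mid R_i)}
#'   {\sum_{j \ne i} w_j \, P(o \mid R_j)}, \quad
#'   w_j = \frac{P(R_j)}{\sum_{k \ne i} P(R_k)}.}
#'
#' With more than two hypotheses the complement weights shift as data
#' accrue, which is why the default updating mode recomputes them (see
#' [update_posterior()]).
#'
#' @param likelihoods An [outcome_likelihoods()] matrix.
#' @param outcome One of the nine outcome labels.
#' @param r_state The strength state `Ri`.
#' @param reference_prior Named probability vector over the `R` states
#'   supplying the complement-mixture weights.
#' @return A positive Bayes factor.
#' @export
#' @examples
#' L <- outcome_likelihoods(er_network(), "perfect", "perfect")
#' bayes_factor(L, "ll", "strong", c(none = 0.5, medium = 0.25, strong = 0.25))
bayes_factor <- function(likelihoods, outcome, r_state, reference_prior) {
  states <- colnames(likelihoods)
  stopifnot(outcome %in% rownames(likelihoods), r_state %in% states)
  prior <- reference_prior[states]
  others <- setdiff(states, r_state)
  w <- prior[others] / sum(prior[others])
  denom <- sum(w * likelihoods[outcome, others])
  if (denom <= 0) {
    stop("outcome '", outcome, "' is impossible under every state other ",
         "than ", r_state, " (zero complement likelihood)")
  }
  unname(likelihoods[outcome, r_state] / denom)
}

#' Table of Bayes factors for all outcomes and strength states
#'
#' @inheritParams bayes_factor
#' @return A 9 x 3 matrix of Bayes factors.
#' @export
bayes_factor_table <- function(likelihoods, reference_prior) {
  states <- colnames(likelihoods)
  out <- vapply(states, function(r) {
    vapply(rownames(likelihoods), function(o) {
      bayes_factor(likelihoods, o, r, reference_prior)
    }, numeric(1))
  }, numeric(nrow(likelihoods)))
  dimnames(out) <- dimnames(likelihoods)
  out
}

#' One sequential posterior update
#'
#' Updates the posterior over the strength of relationship after observing
#' one study outcome. Two modes:
#'
#' * `"exact"` (default): `posterior(r)` proportional to
#'   `prior(r) * P(outcome | r)` — plain Bayes' rule, the coherent
#'   generalization of odds updating to three hypotheses.
#' * `"fixed-bf"`: per-state odds updating, `posterior odds(Ri) = BF *
#'   prior odds(Ri)`, with the Bayes factors frozen at a reference prior's
#'   complement weights (pass them via `bf`); the three updated
#'   probabilities are renormalized. This replicates a literal reuse of a
#'   precomputed Bayes-factor table and is an approximation once the
#'   complement weights have drifted from the reference prior.
#'
#' @param prior Named probability vector over the `R` states.
#' @param likelihoods An [outcome_likelihoods()] matrix.
#' @param outcome Observed outcome label.
#' @param mode `"exact"` or `"fixed-bf"`.
#' @param bf Bayes-factor table for `"fixed-bf"` mode; defaults to the
#'   table computed at `prior`.
#' @return Named posterior probability vector over the `R` states.
#' @export
#' @examples
#' L <- outcome_likelihoods(er_network(), "perfect", "perfect")
#' update_posterior(c(none = 0.5, medium = 0.25, strong = 0.25), L, "ll")
update_posterior <- function(prior, likelihoods, outcome,
                             mode = c("exact", "fixed-bf"), bf = NULL) {
  mode <- match.arg(mode)
  states <- colnames(likelihoods)
  prior <- prior[states]
  stopifnot(outcome %in% rownames(likelihoods))
  if (mode == "exact") {
    post <- prior * likelihoods[outcome, ]
  } else {
    if (is.null(bf)) bf <- bayes_factor_table(likelihoods, prior)
    odds <- prior / (1 - prior)
    post_odds <- bf[outcome, ] * odds
    post <- post_odds / (1 + post_odds)
    post[is.infinite(post_odds)] <- 1
  }
  total <- sum(post)
  if (!is.finite(total) || total <= 0) {
    stop("outcome '", outcome, "' has zero likelihood under every strength ",
         "state consistent with the prior")
  }
  post / total
}

#' Fit the strength-of-relationship posterior to a study
#'
#' The package's central fitting function: folds [update_posterior()] over
#' the cases of a study in order, starting from `prior`, with the
#' measurement accuracies clamped to the dataset's scenario truth. Records
#' the full posterior trajectory — the posterior after case *i* is the
#' prior for case *i + 1* — so convergence (or mislearning) can be examined
#' as a function of sample size.
#'
#' In `"exact"` mode the trajectory is computed by accumulating
#' log-likelihoods (safe for studies of any length) and equals
#' [batch_posterior()] applied to any prefix; in `"fixed-bf"` mode the
#' Bayes factors are frozen at the initial prior (see
#' [update_posterior()]).
#'
#' @param data An `"er_dataset"` from [generate_dataset()].
#' @param net The network the data were generated from (defaults to
#'   [er_network()]).
#' @param prior Initial probability vector over the `R` states; defaults to
#'   the network's `R` prior (0.50/0.25/0.25).
#' @param mode `"exact"` (default) or `"fixed-bf"`.
#' @return An object of class `"er_fit"` with elements `posterior` (an
#'   `n x 3` matrix, row *i* the posterior after case *i*), `prior`,
#'   `mode`, `likelihoods`, `outcomes`, `scenario`, `seed`.
#'   Methods: `print`, `summary`, `coef` (final posterior), `fitted`
#'   (trajectory), `plot`, `predict` (posterior predictive over the next
#'   outcome).
#' @seealso [run_trials()] for replicate studies, [batch_posterior()] for
#'   the one-shot oracle.
#' @export
#' @examples
#' net <- er_network()
#' d <- generate_dataset(net, scenario = 9, n = 50, seed = 1)
#' fit <- er_fit(d, net)
#' coef(fit)
er_fit <- function(data, net = er_network(), prior = NULL,
                   mode = c("exact", "fixed-bf")) {
  mode <- match.arg(mode)
  sc <- attr(data, "scenario")
  if (is.null(sc)) stop("data must be an er_dataset (or carry a scenario ",
                        "attribute naming the clamped accuracies)")
  r_states <- net$nodes[["R"]]$states
  if (is.null(prior)) prior <- infer_marginal(net, "R")
  prior <- prior[r_states]
  if (abs(sum(prior) - 1) > 1e-9) stop("prior must sum to 1")
  L <- outcome_likelihoods(net, sc$acem, sc$acrm)
  outcomes <- data$match
  n <- length(outcomes)
  oi <- match(outcomes, rownames(L))
  if (anyNA(oi)) stop("dataset contains unknown outcome labels: ",
                      paste(unique(outcomes[is.na(oi)]), collapse = ", "))
  if (mode == "exact") {
    if (n > 0L) {
      ll <- apply(log(L)[oi, , drop = FALSE], 2, cumsum)
      ll <- matrix(ll, nrow = n) +
        matrix(log(prior), n, length(r_states), byrow = TRUE)
      ll <- ll - apply(ll, 1, max)
      post <- exp(ll) / rowSums(exp(ll))
      if (any(!is.finite(post))) {
        stop("some prefix of the data has zero likelihood under every ",
             "strength state (inconsistent outcomes)")
      }
    } else {
      post <- matrix(numeric(), 0, length(r_states))
    }
  } else {
    bf <- bayes_factor_table(L, prior)
    post <- matrix(NA_real_, n, length(r_states))
    p <- prior
    for (i in seq_len(n)) {
      p <- update_posterior(p, L, outcomes[i], mode = "fixed-bf", bf = bf)
      post[i, ] <- p
    }
  }
  colnames(post) <- r_states
  structure(list(posterior = post, prior = prior, mode = mode,
                 likelihoods = L, outcomes = outcomes, scenario = sc,
                 seed = attr(data, "seed")),
            class = "er_fit")
}

#' Batch posterior from outcome counts
#'
#' One-shot conjugate-style posterior over the strength of relationship
#' from the outcome frequency table, accumulated in log space:
#' `posterior(r)` proportional to
#' `prior(r) * prod_o P(o | r)^count(o)`. Because cases are conditionally
#' independent given `R` and the clamped accuracies, this equals the final
#' posterior of an exact-mode sequential [er_fit()] on the same data; the
#' two code paths serve as mutual oracles.
#'
#' @param net The network.
#' @param counts Named outcome counts, as from [outcome_frequencies()].
#' @param prior Probability vector over the `R` states (default: the
#'   network's `R` prior).
#' @param acem,acrm Clamped accuracy states.
#' @param likelihoods Optional precomputed [outcome_likelihoods()] matrix.
#' @return Named posterior probability vector.
#' @export
#' @examples
#' net <- er_network()
#' d <- generate_dataset(net, scenario = 9, n = 50, seed = 1)
#' batch_posterior(net, outcome_frequencies(d),
#'                 acem = "perfect", acrm = "perfect")
batch_posterior <- function(net, counts, prior = NULL, acem, acrm,
                            likelihoods = NULL) {
  if (is.null(likelihoods)) {
    likelihoods <- outcome_likelihoods(net, acem, acrm)
  }
  r_states <- colnames(likelihoods)
  if (is.null(prior)) prior <- infer_marginal(net, "R")
  prior <- prior[r_states]
  counts <- counts[rownames(likelihoods)]
  counts[is.na(counts)] <- 0
  seen <- counts > 0  # skip unobserved outcomes so 0 * log(0) cannot NaN
  ll <- log(prior) +
    as.vector(counts[seen] %*% log(likelihoods[seen, , drop = FALSE]))
  if (all(!is.finite(ll))) {
    stop("observed outcomes have zero likelihood under every strength state")
  }
  ll <- ll - max(ll)
  stats::setNames(exp(ll) / sum(exp(ll)), r_states)
}

#' @export
print.er_fit <- function(x, ...) {
  sc <- x$scenario
  cat(sprintf(
    "Sequential strength-of-relationship fit (%s mode): %d cases, accuracy %s-%s\n",
    x$mode, length(x$outcomes), sc$acem, sc$acrm))
  cat("Final posterior over R:\n")
  print(round(coef(x), 4))
  invisible(x)
}

#' @export
coef.er_fit <- function(object, ...) {
  n <- nrow(object$posterior)
  if (n == 0L) return(object$prior)
  object$posterior[n, ]
}

#' @export
fitted.er_fit <- function(object, ...) object$posterior

#' @export
summary.er_fit <- function(object, ...) {
  final <- coef(object)
  map <- names(final)[which.max(final)]
  structure(list(fit = object, final = final, map_state = map,
                 true_state = object$scenario$r_true),
            class = "summary.er_fit")
}

#' @export
print.summary.er_fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("Most probable strength: %s (true: %s)\n",
              x$map_state,
              if (is.null(x$true_state)) "unknown" else x$true_state))
  invisible(x)
}

#' Posterior predictive distribution of the next outcome
#'
#' @param object An `"er_fit"`.
#' @param ... Ignored.
#' @return Named probability vector over the nine outcome states:
#'   `sum_r P(r | data) P(outcome | r)`.
#' @export
predict.er_fit <- function(object, ...) {
  p <- coef(object)
  stats::setNames(as.vector(object$likelihoods %*% p),
                  rownames(object$likelihoods))
}

#' Plot a posterior trajectory
#'
#' @param x An `"er_fit"`.
#' @param ... Passed to [graphics::matplot()].
#' @export
plot.er_fit <- function(x, ...) {
  graphics::matplot(seq_len(nrow(x$posterior)), x$posterior, type = "l",
                    lty = 1, lwd = 2, col = c("#555555", "#1b7837", "#c51b7d"),
                    xlab = "cases assimilated", ylab = "posterior probability",
                    ylim = c(0, 1), ...)
  graphics::legend("topleft", legend = colnames(x$posterior), lty = 1,
                   lwd = 2, col = c("#555555", "#1b7837", "#c51b7d"),
                   bty = "n")
  invisible(x)
}
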