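#' The default exposure-response network
#'
#' Builds the eight-node discrete Bayesian network used throughout the
#' package to study how measurement error and sample size limit what an
#' exposure-response study can learn. The nodes are:
#'
#' * `AcEM`, `AcRM` — latent accuracy of the exposure and response
#'   measurements (`low`, `high`, `perfect`), uniform 1/3 priors.
#' * `TE` — true exposure class (`low`, `medium`, `high`), uniform prior.
#' * `R` — strength of the exposure-response relationship (`none`,
#'   `medium`, `strong`), prior 0.50/0.25/0.25: half the mass on "no
#'   relationship", the rest split equally between the two positive
#'   strengths.
#' * `TR` — true response class, driven by `TE` and `R`: independent of
#'   exposure when `R = none`, nearly aligned with it when `R = strong`.
#' * `ME`, `MR` — measured exposure and response, each a noisy copy of the
#'   truth whose fidelity is set by the corresponding accuracy node
#'   (`perfect` is the identity map).
#' * `ERMatch` — the deterministic study outcome for one subject: the pair
#'   (measured exposure class, measured response class), one of nine states
#'   `ll, lm, lh, ml, mm, mh, hl, hm, hh`.
#'
#' The exposure and response measurement CPTs are the same table
#' (symmetric under the `low`/`high` swap), so accuracy acts identically on
#' both arms of the study. The default tables are representative values
#' chosen to express the qualitative regime of interest — see the package
#' vignette; every entry can be overridden through a network definition
#' file ([read_network()]).
#'
#' @return A validated `"bn"` object (subclass `"er_bn"`).
#' @seealso [scenario_catalog()], [generate_dataset()], [er_fit()]
#' @export
#' @examples
#' net <- er_network()
#' infer_marginal(net, "R")
er_network <- function() {
  lmh <- c("low", "medium", "high")
  acc <- c("low", "high", "perfect")
  rs <- c("none", "medium", "strong")
  nodes <- list(
    bn_node("AcEM", acc),
    bn_node("AcRM", acc),
    bn_node("TE", lmh),
    bn_node("R", rs),
    bn_node("TR", lmh, parents = c("R", "TE")),
    bn_node("ME", lmh, parents = c("AcEM", "TE")),
    bn_node("MR", lmh, parents = c("AcRM", "TR")),
    bn_node("ERMatch", er_match_states(), parents = c("ME", "MR"))
  )
  cpts <- list(
    AcEM = rep(1 / 3, 3),
    AcRM = rep(1 / 3, 3),
    TE = rep(1 / 3, 3),
    R = c(0.50, 0.25, 0.25),
    TR = response_cpt(),
    ME = measurement_cpt(),
    MR = measurement_cpt(),
    ERMatch = er_match_cpt()
  )
  net <- bn_network(nodes, cpts)
  class(net) <- c("er_bn", class(net))
  net
}

# P(measured | accuracy, truth): dim (measured, accuracy, truth).
# One table serves both ME and MR. Each accuracy slice is symmetric under
# the low<->high swap; "perfect" is the identity.
measurement_cpt <- function() {
  slice <- function(m) t(m)  # rows of m are truth; array wants measured first
  lowacc <- rbind(c(0.50, 0.30, 0.20),
                  c(0.25, 0.50, 0.25),
                  c(0.20, 0.30, 0.50))
  highacc <- rbind(c(0.80, 0.15, 0.05),
                   c(0.10, 0.80, 0.10),
                   c(0.05, 0.15, 0.80))
  perfect <- diag(3)
  cpt <- array(0, dim = c(3, 3, 3))
  cpt[, 1, ] <- slice(lowacc)
  cpt[, 2, ] <- slice(highacc)
  cpt[, 3, ] <- slice(perfect)
  cpt
}

# P(TR | R, TE): dim (TR, R, TE). "none" makes response independent of
# exposure; "strong" puts >= 0.9 on the aligned response class.
response_cpt <- function() {
  none <- matrix(1 / 3, 3, 3)
  medium <- rbind(c(0.60, 0.30, 0.10),
                  c(0.20, 0.60, 0.20),
                  c(0.10, 0.30, 0.60))
  strong <- rbind(c(0.90, 0.08, 0.02),
                  c(0.05, 0.90, 0.05),
                  c(0.02, 0.08, 0.90))
  cpt <- array(0, dim = c(3, 3, 3))
  for (te in 1:3) {
    cpt[, 1, te] <- none[te, ]
    cpt[, 2, te] <- medium[te, ]
    cpt[, 3, te] <- strong[te, ]
  }
  cpt
}

# Deterministic ERMatch CPT: dim (9, ME, MR), a point mass per parent pair.
er_match_cpt <- function() {
  lmh <- c("low", "medium", "high")
  cpt <- array(0, dim = c(9, 3, 3))
  for (me in 1:3) for (mr in 1:3) {
    state <- er_match_state(lmh[me], lmh[mr])
    cpt[match(state, er_match_states()), me, mr] <- 1
  }
  cpt
}

#' The nine study outcome states
#'
#' @return Character vector of the nine `ERMatch` labels, in canonical
#'   order: measured exposure varying slowest.
#' @export
er_match_states <- function() {
  as.vector(t(outer(c("l", "m", "h"), c("l", "m", "h"), paste0)))
}

#' Compile a subject's study outcome
#'
#' Maps a (measured exposure, measured response) pair to its two-letter
#' outcome label; the map is a bijection over the nine pairs.
#'
#' @param me,mr Measured exposure / response state (`low`, `medium`,
#'   `high`); vectorized.
#' @return Character vector of outcome labels (`ll`, `lm`, ..., `hh`).
#' @export
#' @examples
#' er_match_state("low", "low")     # "ll"
#' er_match_state("high", "medium") # "hm"
er_match_state <- function(me, mr) {
  lmh <- c("low", "medium", "high")
  i <- match(me, lmh)
  j <- match(mr, lmh)
  if (anyNA(i)) stop("unknown measured exposure state: ",
                     paste(unique(me[is.na(i)]), collapse = ", "))
  if (anyNA(j)) stop("unknown measured response state: ",
                     paste(unique(mr[is.na(j)]), collapse = ", "))
  paste0(c("l", "m", "h")[i], c("l", "m", "h")[j])
}

#' The nine simulation scenarios
#'
#' Enumerates the 3 x 3 grid of true strength of relationship (`none`,
#' `medium`, `strong`) against measurement accuracy (`low`, `high`,
#' `perfect`). Exposure- and response-measurement accuracy are varied
#' together, so each scenario clamps `AcEM` and `AcRM` to the same level.
#'
#' @return A data frame with columns `id` (1-9), `r_true`, `acem`, `acrm`.
#' @export
#' @examples
#' scenario_catalog()
scenario_catalog <- function() {
  rs <- c("none", "medium", "strong")
  acc <- c("low", "high", "perfect")
  data.frame(
    id = 1:9,
    r_true = rep(rs, each = 3),
    acem = rep(acc, times = 3),
    acrm = rep(acc, times = 3),
    stringsAsFactors = FALSE
  )
}

# Resolve a scenario argument: an id 1-9, a row of scenario_catalog(), or a
# list with r_true/acem/acrm.
as_scenario <- function(scenario) {
  if (is.numeric(scenario) && length(scenario) == 1L) {
    if (!scenario %in% 1:9) {
      stop("scenario id must be an integer in 1-9, got ", scenario)
    }
    return(as.list(scenario_catalog()[scenario, ]))
  }
  sc <- as.list(scenario)
  need <- c("r_true", "acem", "acrm")
  if (!all(need %in% names(sc))) {
    stop("a scenario needs fields r_true, acem and acrm (or an id in 1-9)")
  }
  if (is.null(sc$id)) sc$id <- NA_integer_
  sc[c("id", need)]
}
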