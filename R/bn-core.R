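#' Define a node of a discrete Bayesian network
#'
#' A node has a name, an ordered set of categorical state labels and an
#' ordered list of parent node names. State order is canonical: it fixes the
#' row/column layout of the node's conditional probability table (CPT) and
#' the order of all serialized output.
#'
#' @param name Node name (single string).
#' @param states Character vector of at least two unique state labels.
#'   Labels are case-sensitive.
#' @param parents Character vector of parent node names (possibly empty).
#' @return A list of class `"bn_node"`.
#' @seealso [bn_network()]
#' @export
#' @examples
#' bn_node("R", c("none", "medium", "strong"))
bn_node <- function(name, states, parents = character()) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  states <- as.character(states)
  parents <- as.character(parents)
  structure(list(name = name, states = states, parents = parents),
            class = "bn_node")
}

#' Assemble a discrete Bayesian network
#'
#' Combines node definitions and conditional probability tables into a
#' network object. CPTs are stored as arrays whose first dimension runs over
#' the child's states and whose remaining dimensions run over the parents'
#' states in the declared parent order; a root node's CPT is a plain
#' probability vector. The joint distribution factorizes as the product of
#' the CPT entries, one per node.
#'
#' @param nodes List of [bn_node()] definitions. They may be given in any
#'   order; the constructor sorts them topologically (parents before
#'   children) and this order is used for enumeration and sampling.
#' @param cpts Named list, one entry per node: a numeric vector for a root
#'   node, or an array with `dim = c(n_child_states, n_parent1_states, ...)`.
#' @param validate If `TRUE` (default), stop on any violation reported by
#'   [validate_network()].
#' @return An object of class `"bn"`: a list with elements `nodes` (in
#'   topological order) and `cpts`.
#' @export
#' @examples
#' coin <- bn_network(list(bn_node("X", c("heads", "tails"))),
#'                    list(X = c(0.5, 0.5)))
#' infer_marginal(coin, "X")
bn_network <- function(nodes, cpts, validate = TRUE) {
  stopifnot(is.list(nodes), is.list(cpts))
  names(nodes) <- vapply(nodes, function(nd) nd$name, character(1))
  ord <- topo_order(nodes)
  if (!is.null(ord)) nodes <- nodes[ord]
  net <- structure(list(nodes = nodes, cpts = cpts[names(nodes)]),
                   class = "bn")
  net$cpts <- lapply(names(net$nodes), function(nm) {
    label_cpt(net$cpts[[nm]], net$nodes[[nm]], net$nodes)
  })
  names(net$cpts) <- names(net$nodes)
  if (validate) {
    bad <- validate_network(net)
    if (length(bad)) {
      stop("invalid network:\n", paste0("- ", bad, collapse = "\n"))
    }
  }
  net
}

# Stable Kahn topological sort; NULL if the parent graph has a cycle.
topo_order <- function(nodes) {
  nms <- names(nodes)
  remaining <- nms
  placed <- character()
  repeat {
    ready <- remaining[vapply(remaining, function(nm) {
      all(nodes[[nm]]$parents %in% placed |
            !(nodes[[nm]]$parents %in% nms))
    }, logical(1))]
    if (!length(ready)) break
    placed <- c(placed, ready)
    remaining <- setdiff(remaining, ready)
  }
  if (length(remaining)) NULL else placed
}

# Attach dimnames (child states first, then parent states) so CPT entries
# can be addressed by label as well as by index.
label_cpt <- function(cpt, node, nodes) {
  if (is.null(cpt)) return(NULL)
  k <- length(node$states)
  if (!length(node$parents)) {
    cpt <- as.numeric(cpt)
    if (length(cpt) == k) names(cpt) <- node$states
    return(cpt)
  }
  pdims <- vapply(node$parents, function(p) {
    if (is.null(nodes[[p]])) NA_integer_ else length(nodes[[p]]$states)
  }, integer(1))
  if (anyNA(pdims)) return(cpt)
  want <- c(k, pdims)
  if (!is.array(cpt)) {
    if (length(cpt) == prod(want)) cpt <- array(as.numeric(cpt), dim = want)
    else return(cpt)
  }
  if (identical(dim(cpt), as.integer(want))) {
    dimnames(cpt) <- c(list(node$states),
                       lapply(node$parents, function(p) nodes[[p]]$states))
  }
  cpt
}

#' Validate a network definition
#'
#' Checks the structural and probabilistic invariants of a network: unique
#' node names, at least two unique states per node, parent references that
#' exist, an acyclic graph, complete CPTs (one distribution per combination
#' of parent states) and rows that are proper distributions (entries in
#' \eqn{[0, 1]}, summing to 1 within `1e-12`).
#'
#' Violations are returned, not raised, so a partially built or deliberately
#' broken definition can be inspected.
#'
#' @param net A `"bn"` object (or an unvalidated list with the same shape).
#' @return Character vector of human-readable violations; empty if the
#'   network is valid.
#' @export
validate_network <- function(net) {
  bad <- character()
  nodes <- net$nodes
  nms <- vapply(nodes, function(nd) nd$name, character(1))
  if (anyDuplicated(nms)) {
    bad <- c(bad, paste0("duplicate node name: ",
                         paste(unique(nms[duplicated(nms)]), collapse = ", ")))
  }
  names(nodes) <- nms
  for (nd in nodes) {
    if (length(nd$states) < 2L) {
      bad <- c(bad, paste0("node ", nd$name, ": fewer than 2 states"))
    }
    if (anyDuplicated(nd$states)) {
      bad <- c(bad, paste0("node ", nd$name, ": duplicate state labels"))
    }
    missing_par <- setdiff(nd$parents, nms)
    if (length(missing_par)) {
      bad <- c(bad, paste0("node ", nd$name, ": unknown parent ",
                           paste(missing_par, collapse = ", ")))
    }
  }
  if (is.null(topo_order(nodes))) {
    bad <- c(bad, "graph has a directed cycle")
  }
  for (nd in nodes) {
    cpt <- net$cpts[[nd$name]]
    if (is.null(cpt)) {
      bad <- c(bad, paste0("node ", nd$name, ": missing CPT"))
      next
    }
    k <- length(nd$states)
    pdims <- vapply(nd$parents, function(p) {
      if (is.null(nodes[[p]])) 0L else length(nodes[[p]]$states)
    }, integer(1))
    want <- c(k, pdims)
    have <- if (is.array(cpt)) dim(cpt) else length(cpt)
    if (!identical(as.integer(have), as.integer(want))) {
      bad <- c(bad, paste0("node ", nd$name, ": CPT is incomplete (dim ",
                           paste(have, collapse = "x"), ", expected ",
                           paste(want, collapse = "x"), ")"))
      next
    }
    if (any(cpt < 0) || any(cpt > 1)) {
      bad <- c(bad, paste0("node ", nd$name,
                           ": CPT entries outside [0, 1]"))
    }
    sums <- apply(array(cpt, dim = c(k, prod(pdims), 1))[, , 1, drop = FALSE],
                  2, sum)
    off <- which(abs(sums - 1) > 1e-12)
    if (length(off)) {
      bad <- c(bad, paste0("node ", nd$name, ": ", length(off),
                           " CPT row(s) not normalized (e.g. sum = ",
                           format(sums[off[1]], digits = 15), ")"))
    }
  }
  bad
}

#' @export
print.bn <- function(x, ...) {
  cat("Discrete Bayesian network:", length(x$nodes), "nodes\n")
  for (nd in x$nodes) {
    cat(sprintf("  %-8s {%s}%s\n", nd$name,
                paste(nd$states, collapse = ", "),
                if (length(nd$parents)) {
                  paste0("  <- ", paste(nd$parents, collapse = ", "))
                } else ""))
  }
  invisible(x)
}

# Check an evidence specification (named character vector / list mapping
# node -> observed state) against the network; returns a named character
# vector.
check_evidence <- function(net, evidence) {
  if (is.null(evidence) || !length(evidence)) {
    return(stats::setNames(character(), character()))
  }
  ev <- vapply(evidence, as.character, character(1))
  if (is.null(names(ev)) || any(!nzchar(names(ev)))) {
    stop("evidence must be a named mapping node -> state")
  }
  for (nm in names(ev)) {
    nd <- net$nodes[[nm]]
    if (is.null(nd)) stop("evidence refers to unknown node: ", nm)
    if (!ev[[nm]] %in% nd$states) {
      stop("evidence state '", ev[[nm]], "' is not a state of node ", nm)
    }
  }
  ev
}

# All assignments (as state indices) consistent with the evidence, one row
# per assignment, one column per node in topological order.
assignment_grid <- function(net, evidence = NULL) {
  ev <- check_evidence(net, evidence)
  idx <- lapply(net$nodes, function(nd) {
    if (nd$name %in% names(ev)) match(ev[[nd$name]], nd$states)
    else seq_along(nd$states)
  })
  names(idx) <- names(net$nodes)
  do.call(expand.grid, c(idx, KEEP.OUT.ATTRS = FALSE))
}

# Chain-rule probability of every assignment row in a grid.
grid_probability <- function(net, grid) {
  p <- rep(1, nrow(grid))
  for (nd in net$nodes) {
    cpt <- net$cpts[[nd$name]]
    if (!length(nd$parents)) {
      p <- p * cpt[grid[[nd$name]]]
    } else {
      p <- p * cpt[as.matrix(grid[c(nd$name, nd$parents)])]
    }
  }
  p
}

#' Joint probability of a full assignment
#'
#' Evaluates the chain-rule product \eqn{\prod_v P(v \mid pa(v))} for one
#' complete assignment of states to all nodes.
#'
#' @param net A `"bn"` object.
#' @param assignment Named character vector or list assigning exactly one
#'   state to every node of the network.
#' @return A single probability in \eqn{[0, 1]}.
#' @export
#' @examples
#' net <- er_network()
#' joint_probability(net, c(AcEM = "perfect", AcRM = "perfect", TE = "low",
#'                          R = "none", TR = "low", ME = "low", MR = "low",
#'                          ERMatch = "ll"))
joint_probability <- function(net, assignment) {
  ev <- check_evidence(net, assignment)
  missing_nodes <- setdiff(names(net$nodes), names(ev))
  if (length(missing_nodes)) {
    stop("assignment must cover every node; missing: ",
         paste(missing_nodes, collapse = ", "))
  }
  grid <- assignment_grid(net, ev)
  unname(grid_probability(net, grid))
}

#' Exact marginal inference by enumeration
#'
#' Computes the exact conditional distribution of a query node given
#' evidence by summing the joint probability over all completions of the
#' evidence and normalizing. At the sizes this package targets (tens of
#' thousands of joint assignments) exact enumeration is cheap and leaves no
#' approximation error to confound downstream power results.
#'
#' @param net A `"bn"` object.
#' @param query Name of the node whose distribution is required.
#' @param evidence Optional named character vector or list of observed
#'   states; `NULL` for the unconditional marginal.
#' @return Named numeric vector over the query node's states (in declared
#'   order), summing to 1.
#' @export
#' @examples
#' net <- er_network()
#' infer_marginal(net, "R")                     # the 0.50/0.25/0.25 prior
#' infer_marginal(net, "ME", c(AcEM = "low", TE = "low"))
infer_marginal <- function(net, query, evidence = NULL) {
  if (is.null(net$nodes[[query]])) stop("unknown query node: ", query)
  grid <- assignment_grid(net, evidence)
  p <- grid_probability(net, grid)
  total <- sum(p)
  if (!is.finite(total) || total < 1e-300) {
    stop("evidence has zero probability under the network (inconsistent ",
         "evidence)")
  }
  states <- net$nodes[[query]]$states
  out <- vapply(seq_along(states),
                function(s) sum(p[grid[[query]] == s]), numeric(1))
  stats::setNames(out / total, states)
}
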