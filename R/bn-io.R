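#' Read a network definition file
#'
#' Networks are stored as YAML: a `nodes` list in which each entry gives
#' `name`, `states`, `parents` and a `cpt` block. A root node's `cpt` is a
#' single probability list; a child node's `cpt` is a list of rows, each
#' with `given` (one state per parent, in parent order) and `p` (the
#' distribution over the child's states). Probabilities may be written as
#' numbers or as exact rational strings such as `"1/3"`, which are parsed to
#' full double precision — the shipped default file reproduces
#' [er_network()] bit-exactly.
#'
#' @param file Path to a YAML network definition, or `"default"` for the
#'   file shipped with the package (the exposure-response network).
#' @return A validated `"bn"` object.
#' @seealso [write_network()], [er_network()]
#' @export
read_network <- function(file) {
  if (identical(file, "default")) {
    file <- system.file("extdata", "er_network.yaml", package = "bnpower",
                        mustWork = TRUE)
  }
  doc <- yaml::read_yaml(file)
  if (is.null(doc$nodes)) stop("network file has no 'nodes' block: ", file)
  nodes <- list()
  cpts <- list()
  for (blk in doc$nodes) {
    nd <- bn_node(blk$name, unlist(blk$states),
                  as.character(unlist(blk$parents)))
    nodes[[nd$name]] <- nd
    cpts[[nd$name]] <- parse_cpt_block(blk, nd, nodes)
  }
  bn_network(nodes, cpts)
}

parse_cpt_block <- function(blk, node, nodes) {
  k <- length(node$states)
  if (!length(node$parents)) {
    return(parse_probs(blk$cpt, k, node$name))
  }
  pstates <- lapply(node$parents, function(p) nodes[[p]]$states)
  pdims <- lengths(pstates)
  cpt <- array(NA_real_, dim = c(k, pdims))
  seen <- 0L
  for (row in blk$cpt) {
    given <- as.character(unlist(row$given))
    if (length(given) != length(node$parents)) {
      stop("node ", node$name, ": CPT row 'given' must list one state per ",
           "parent")
    }
    pidx <- mapply(match, given, pstates)
    if (anyNA(pidx)) {
      stop("node ", node$name, ": unknown parent state in 'given' (",
           paste(given, collapse = ", "), ")")
    }
    cpt[cbind(seq_len(k),
              matrix(rep(as.integer(pidx), each = k), nrow = k))] <-
      parse_probs(row$p, k, node$name)
    seen <- seen + 1L
  }
  if (anyNA(cpt)) {
    stop("node ", node$name, ": CPT incomplete (", seen, " of ",
         prod(pdims), " parent combinations given)")
  }
  cpt
}

# Probabilities written either as numbers or exact rational strings "a/b".
parse_probs <- function(x, k, node_name) {
  x <- unlist(x, use.names = FALSE)
  if (length(x) != k) {
    stop("node ", node_name, ": expected ", k, " probabilities, got ",
         length(x))
  }
  vapply(x, function(v) {
    if (is.numeric(v)) return(as.numeric(v))
    v <- trimws(as.character(v))
    if (grepl("^-?[0-9]+/[0-9]+$", v)) {
      parts <- as.numeric(strsplit(v, "/", fixed = TRUE)[[1]])
      return(parts[1] / parts[2])
    }
    out <- suppressWarnings(as.numeric(v))
    if (is.na(out)) stop("node ", node_name, ": unparseable probability '",
                         v, "'")
    out
  }, numeric(1))
}

#' Write a network definition file
#'
#' Serializes a network to the YAML layout read by [read_network()].
#' Probabilities that are exact small rationals (e.g. `1/3`, `0.15`) are
#' written as rational strings so the file round-trips bit-exactly; anything
#' else is written with 17 significant digits.
#'
#' @param net A `"bn"` object.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_network <- function(net, file) {
  blocks <- lapply(net$nodes, function(nd) {
    cpt <- net$cpts[[nd$name]]
    blk <- list(name = nd$name, states = as.list(nd$states),
                parents = as.list(nd$parents))
    if (!length(nd$parents)) {
      blk$cpt <- lapply(as.numeric(cpt), prob_string)
    } else {
      pstates <- lapply(nd$parents, function(p) net$nodes[[p]]$states)
      combos <- do.call(expand.grid,
                        c(pstates, KEEP.OUT.ATTRS = FALSE,
                          stringsAsFactors = FALSE))
      blk$cpt <- lapply(seq_len(nrow(combos)), function(i) {
        pidx <- mapply(match, as.character(combos[i, ]), pstates)
        dist <- cpt[cbind(seq_along(nd$states),
                          matrix(rep(as.integer(pidx),
                                     each = length(nd$states)),
                                 nrow = length(nd$states)))]
        list(given = as.list(as.character(combos[i, ])),
             p = lapply(dist, prob_string))
      })
    }
    blk
  })
  yaml::write_yaml(list(nodes = unname(blocks)), file,
                   indent.mapping.sequence = TRUE)
  invisible(file)
}

# Exact textual form of a probability: integer, small rational "a/b" when it
# reproduces the double bit-exactly, else 17 significant digits.
prob_string <- function(p) {
  if (p == round(p)) return(format(as.integer(p)))
  for (den in 2:1000) {
    num <- round(p * den)
    if (num / den == p) return(paste0(num, "/", den))
  }
  format(p, digits = 17)
}
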