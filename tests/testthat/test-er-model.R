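test_that("the default network has the declared structure", {
  net <- er_network()
  expect_setequal(names(net$nodes),
                  c("AcEM", "AcRM", "TE", "TR", "ME", "MR", "R", "ERMatch"))
  expect_identical(net$nodes$AcEM$states, c("low", "high", "perfect"))
  expect_identical(net$nodes$R$states, c("none", "medium", "strong"))
  expect_identical(net$nodes$TR$parents, c("R", "TE"))
  expect_identical(net$nodes$ME$parents, c("AcEM", "TE"))
  expect_identical(net$nodes$MR$parents, c("AcRM", "TR"))
  expect_identical(net$nodes$ERMatch$parents, c("ME", "MR"))
  expect_length(net$nodes$ERMatch$states, 9L)
})

test_that("the study outcome is a deterministic bijection of (ME, MR)", {
  expect_identical(er_match_state("low", "low"), "ll")
  expect_identical(er_match_state("high", "medium"), "hm")
  lmh <- c("low", "medium", "high")
  pairs <- expand.grid(me = lmh, mr = lmh, stringsAsFactors = FALSE)
  labels <- er_match_state(pairs$me, pairs$mr)
  expect_setequal(labels, er_match_states())
  expect_false(anyDuplicated(labels) > 0)
  expect_error(er_match_state("huge", "low"), "unknown measured exposure")

  # the ERMatch CPT is a point mass for every parent combination
  cpt <- er_network()$cpts$ERMatch
  for (me in 1:3) for (mr in 1:3) {
    col <- cpt[, me, mr]
    expect_identical(unname(sort(col, decreasing = TRUE)[1:2]), c(1, 0))
    expect_identical(names(which(col == 1)),
                     er_match_state(lmh[me], lmh[mr]))
  }
})

test_that("the scenario catalog enumerates the 3x3 grid in order", {
  cat_df <- scenario_catalog()
  expect_identical(nrow(cat_df), 9L)
  expect_identical(cat_df$id, 1:9)
  expect_identical(cat_df$r_true, rep(c("none", "medium", "strong"),
                                      each = 3))
  expect_identical(cat_df$acem, rep(c("low", "high", "perfect"), times = 3))
  expect_identical(cat_df$acem, cat_df$acrm)
  expect_identical(unlist(as_scenario(1)[c("r_true", "acem", "acrm")],
                          use.names = FALSE),
                   c("none", "low", "low"))
  expect_identical(unlist(as_scenario(9)[c("r_true", "acem", "acrm")],
                          use.names = FALSE),
                   c("strong", "perfect", "perfect"))
  expect_error(as_scenario(10), "1-9")
})

test_that("measurement model is shared, symmetric and anchored", {
  net <- er_network()
  # identical measurement model for the exposure and response arms
  expect_identical(net$cpts$ME, array(net$cpts$MR, dim = dim(net$cpts$ME),
                                      dimnames = dimnames(net$cpts$ME)))
  # each accuracy slice is symmetric under the low<->high swap
  for (a in 1:3) {
    slice <- net$cpts$ME[, a, ]
    expect_equal(unname(slice), unname(slice[3:1, 3:1]))
  }
  # the single quoted anchor entry
  expect_equal(net$cpts$ME["high", "low", "low"], 0.2)
  # perfect accuracy is the identity map
  expect_equal(unname(net$cpts$ME[, "perfect", ]), diag(3))
})

test_that("strength states mean what they say", {
  net <- er_network()
  # R = none: response CPT rows identical for all TE states, and the
  # inferred TR distribution ignores the exposure
  expect_identical(net$cpts$TR[, "none", "low"], net$cpts$TR[, "none", "high"])
  expect_identical(net$cpts$TR[, "none", "low"], net$cpts$TR[, "none", "medium"])
  expect_equal(infer_marginal(net, "TR", c(R = "none", TE = "low")),
               infer_marginal(net, "TR", c(R = "none", TE = "high")))
  # R = strong: aligned response almost always
  for (x in c("low", "medium", "high")) {
    expect_gte(net$cpts$TR[x, "strong", x], 0.9)
  }
})

test_that("the shipped definition file reproduces the defaults bit-exactly", {
  net <- er_network()
  shipped <- read_network("default")
  expect_identical(shipped$cpts, net$cpts)
  expect_identical(lapply(shipped$nodes, unclass),
                   lapply(net$nodes, unclass))

  # round trip through a fresh file is also bit-exact
  tmp <- withr::local_tempfile(fileext = ".yaml")
  write_network(net, tmp)
  again <- read_network(tmp)
  expect_identical(again$cpts, net$cpts)

  # users can override CPTs through the file
  doc <- yaml::read_yaml(tmp)
  stopifnot(doc$nodes[[4]]$name == "R")
  doc$nodes[[4]]$cpt <- list("0.8", "0.1", "0.1")
  yaml::write_yaml(doc, tmp)
  tweaked <- read_network(tmp)
  expect_equal(infer_marginal(tweaked, "R"),
               c(none = 0.8, medium = 0.1, strong = 0.1))
})
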