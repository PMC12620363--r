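# convenience: screen the branching fixture once per file
local_fixture_screen <- function(n = 25, seed = 6) {
  fx <- make_figure4_fixture(n, seed = seed)
  proj <- fit_projection(fx$dataset, c("l0", "l5"))
  list(fx = fx, proj = proj, subs = screen_suborders(proj, 1))
}

test_that("thresholds_equivalent matches the interval worked example", {
  # anchor [0,1], branch a [2,5], branch b [2,3], theta 0 -> region (1, 2]
  pj <- projected_from_values(c(0, 1, 2, 5, 2, 3, 6, 7),
                              c("ll", "ll", "la", "la", "lb", "lb",
                                "lr", "lr"))
  eq <- thresholds_equivalent(NULL, NULL,
                              list(anchor = "ll", branch_a = "la",
                                   branch_b = "lb", side = "left"),
                              pj, theta = 0)
  expect_s3_class(eq, "shared_threshold")
  expect_equal(eq$feasible$lower, 1)
  expect_equal(eq$feasible$upper, 2)
  expect_identical(eq$kind, "left_shared")
  # right-shared mirror: anchor [6,7] above both branches -> (5, 6]
  eqr <- thresholds_equivalent(NULL, NULL,
                               list(anchor = "lr", branch_a = "la",
                                    branch_b = "lb", side = "right"),
                               pj, theta = 0)
  expect_s3_class(eqr, "shared_threshold")
  expect_equal(eqr$feasible$lower, 5)
  expect_equal(eqr$feasible$upper, 6)
  expect_identical(eqr$kind, "right_shared")
  # empty region returns NULL: branches on opposite sides of the anchor
  none <- thresholds_equivalent(NULL, NULL,
                                list(anchor = "la", branch_a = "ll",
                                     branch_b = "lb", side = "left"),
                                pj, theta = 0)
  expect_null(none)
})

test_that("identical transitions are trivially self-equivalent", {
  pj <- projected_from_values(c(0, 1, 3, 4), c("a", "a", "b", "b"))
  d <- fit_dtc(c(0, 1), c(3, 4), 0, "a", "b")
  eq <- thresholds_equivalent(d, d,
                              list(anchor = "a", branch_a = "b",
                                   branch_b = "b", side = "left"),
                              pj, theta = 0)
  expect_s3_class(eq, "shared_threshold")
  expect_equal(eq$feasible$lower, d$interval$lower)
  expect_equal(eq$feasible$upper, d$interval$upper)
})

test_that("shared region equals the brute-force budget sweep", {
  for (seed in 1:10) {
    set.seed(seed)
    anchor <- runif(10, 0, 3)
    a <- runif(10, 2, 7)
    b <- runif(10, 2.5, 6)
    pj <- projected_from_values(c(anchor, a, b),
                                rep(c("ll", "la", "lb"), each = 10))
    theta <- 0.2
    eq <- thresholds_equivalent(NULL, NULL,
                                list(anchor = "ll", branch_a = "la",
                                     branch_b = "lb", side = "left"),
                                pj, theta = theta)
    grid <- dtc_candidate_grid(c(anchor, a), b)
    feas <- vapply(grid, function(tau)
      dtc_feasible_at(tau, anchor, a, theta) &&
        dtc_feasible_at(tau, anchor, b, theta), logical(1))
    if (is.null(eq)) {
      expect_false(any(feas))
    } else {
      inside <- grid > eq$feasible$lower & grid <= eq$feasible$upper
      expect_identical(feas, inside)
    }
  }
})

test_that("equivalence is symmetric in its two suborders", {
  pj <- projected_from_values(c(0, 1, 2, 5, 2, 3),
                              c("ll", "ll", "la", "la", "lb", "lb"))
  ab <- thresholds_equivalent(NULL, NULL,
                              list(anchor = "ll", branch_a = "la",
                                   branch_b = "lb", side = "left"),
                              pj, 0)
  ba <- thresholds_equivalent(NULL, NULL,
                              list(anchor = "ll", branch_a = "lb",
                                   branch_b = "la", side = "left"),
                              pj, 0)
  expect_equal(ab$feasible, ba$feasible)
})

test_that("membership preconditions are enforced", {
  pj <- projected_from_values(c(0, 1, 2, 5, 2, 3),
                              c("ll", "ll", "la", "la", "lb", "lb"))
  expect_error(thresholds_equivalent(NULL, NULL,
                                     list(anchor = "ll", branch_a = "la",
                                          branch_b = "lb", side = "left",
                                          suborder_a = c("ll", "lb"),
                                          suborder_b = c("ll", "lb")),
                                     pj, 0),
               "first suborder only")
  expect_error(thresholds_equivalent(NULL, NULL,
                                     list(anchor = "la", branch_a = "la",
                                          branch_b = "la", side = "left"),
                                     pj, 0),
               "anchor must differ")
})

test_that("fixture suborders aggregate into the expected layered graph", {
  sc <- local_fixture_screen()
  subs12 <- Filter(function(s) length(s$sequence) >= 5L, sc$subs)
  expect_length(subs12, 12L)
  g <- aggregate_alternatives(subs12, sc$proj, theta = 0)
  expect_length(g$components, 1L)
  expect_identical(layer_signature(g$components[[1]]),
                   c("l0<l1|l6", "l2|l7", "l3|l8", "l4<l5|l9"))
  for (s in subs12) expect_true(graph_contains_path(g, s$sequence))
  # parallel soundness: classes in different units of one layer never
  # co-occur in a contributing suborder
  for (layer in g$components[[1]]$layers) {
    if (length(layer) < 2L) next
    for (i in seq_along(layer)) for (j in seq_along(layer)) {
      if (i >= j) next
      for (s in subs12)
        expect_false(any(layer[[i]] %in% s$sequence) &&
                       any(layer[[j]] %in% s$sequence))
    }
  }
})

test_that("a single suborder aggregates to a path of singleton layers", {
  pj <- projected_from_values(c(0, 1, 3, 4, 6, 7),
                              c("a", "a", "b", "b", "c", "c"),
                              pair = c("a", "c"))
  s <- suborders:::.new_suborder(c("a", "b", "c"),
                                 fit_cascade(pj, c("a", "b", "c"), 0),
                                 c("a", "c"), TRUE)
  g <- aggregate_alternatives(list(s), pj, 0)
  expect_length(g$components, 1L)
  expect_identical(layer_signature(g$components[[1]]), c("a", "b", "c"))
  expect_true(graph_contains_path(g, c("a", "b", "c")))
})

test_that("suborders over disjoint class sets stay disconnected", {
  pj <- projected_from_values(c(0, 1, 3, 4, 0.2, 1.1, 3.2, 4.2),
                              c("a", "a", "b", "b", "x", "x", "y", "y"),
                              pair = c("a", "b"))
  s1 <- suborders:::.new_suborder(c("a", "b"), fit_cascade(pj, c("a", "b"), 0),
                                  c("a", "b"), TRUE)
  s2 <- suborders:::.new_suborder(c("x", "y"), fit_cascade(pj, c("x", "y"), 0),
                                  c("a", "b"), TRUE)
  g <- aggregate_alternatives(list(s1, s2), pj, 0)
  expect_length(g$components, 2L)
})

test_that("aggregation rejects mixed projections", {
  pj <- projected_from_values(c(0, 1, 3, 4), c("a", "a", "b", "b"),
                              pair = c("a", "b"))
  s1 <- suborders:::.new_suborder(c("a", "b"), fit_cascade(pj, c("a", "b"), 0),
                                  c("a", "b"), TRUE)
  s2 <- s1; s2$source_pair <- c("b", "a")
  expect_error(aggregate_alternatives(list(s1, s2), pj),
               "different projections")
})

test_that("DOT output encodes the layer clusters", {
  sc <- local_fixture_screen(n = 10, seed = 91)
  subs12 <- Filter(function(s) length(s$sequence) >= 5L, sc$subs)
  g <- aggregate_alternatives(subs12, sc$proj, 0)
  dot <- as_dot(g)
  lines <- strsplit(dot, "\n")[[1]]
  cl <- grep("subgraph cluster_comp1_layer", lines)
  expect_length(cl, 4L)
  # nodes listed in cluster j match the graph's layer j
  for (j in seq_along(cl)) {
    nodes <- regmatches(lines[cl[j] + 2L],
                        gregexpr('"[^"]+"', lines[cl[j] + 2L]))[[1]]
    nodes <- gsub('"', "", nodes)
    expect_setequal(nodes, unlist(g$components[[1]]$layers[[j]]))
  }
  td <- withr::local_tempdir()
  write_results(subs12, g, td)
  expect_true(file.exists(file.path(td, "graph.dot")))
  gj <- jsonlite::read_json(file.path(td, "graph.json"))
  expect_length(gj$components[[1]]$layers, 4L)
})
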