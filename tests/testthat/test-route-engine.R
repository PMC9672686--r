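test_that("GeoJSON networks load, snap endpoints, and round-trip", {
  g <- table4_chain_graph()
  tmp <- withr::local_tempfile(fileext = ".geojson")
  save_network(g, tmp)
  g2 <- load_network(tmp)
  expect_equal(nrow(g2$nodes), 8)
  expect_equal(nrow(g2$edges), 7)
  expect_equal(g2$entrances, "a")
  expect_equal(g2$edges[order(g2$edges$edge_id), ],
               g$edges[order(g$edges$edge_id), ], ignore_attr = TRUE)
  # snapping: endpoints within tolerance merge to one node
  gj <- jsonlite::read_json(tmp, simplifyVector = FALSE)
  gj$features <- Filter(function(f) f$geometry$type == "LineString",
                        gj$features)
  for (i in seq_along(gj$features)) {
    cc <- gj$features[[i]]$geometry$coordinates
    cc[[1]][[1]] <- cc[[1]][[1]] + 0.2  # jitter below the 0.5 m tolerance
    gj$features[[i]]$geometry$coordinates <- cc
  }
  tmp2 <- withr::local_tempfile(fileext = ".geojson")
  jsonlite::write_json(gj, tmp2, auto_unbox = TRUE, digits = NA)
  g3 <- load_network(tmp2)
  expect_equal(nrow(g3$nodes), 8)
})

test_that("schema problems are reported by feature", {
  tmp <- withr::local_tempfile(fileext = ".geojson")
  jsonlite::write_json(list(type = "FeatureCollection", features = list()),
                       tmp, auto_unbox = TRUE)
  expect_error(load_network(tmp), "empty")
  bad <- list(type = "FeatureCollection", features = list(list(
    type = "Feature",
    geometry = list(type = "LineString",
                    coordinates = list(c(0, 0), c(100, 0))),
    properties = list(edge_id = "ab"))))
  jsonlite::write_json(bad, tmp, auto_unbox = TRUE, digits = NA)
  expect_error(load_network(tmp), "'ab' lacks utci")
  g <- table4_chain_graph()
  tmp2 <- withr::local_tempfile(fileext = ".geojson")
  save_network(g, tmp2)
  expect_error(load_network(tmp2, entrances = "zz"), "zz")
})

test_that("the chain walk is found with its published terminal tolerance", {
  g <- table4_chain_graph()
  r <- best_tolerance_route(g, "a", "h", budget_m = 900)
  expect_true(r$feasible)
  expect_equal(r$path, letters[1:8])
  expect_equal(r$r_t, 20.9)
  expect_equal(r$distance_m, 899.9)
  # same budget expressed in minutes at 1 m/s
  r2 <- best_tolerance_route(g, "a", "h", budget_min = 15)
  expect_equal(r2$r_t, 20.9)
})

test_that("dominance prefers the cooler of two parallel edges", {
  nodes <- data.frame(node_id = c("a", "b"), x = c(0, 100), y = 0)
  edges <- data.frame(edge_id = c("hot", "cool"), from = "a", to = "b",
                      length_m = 100,
                      utci_min = c(39, 20), utci_max = c(40, 22))
  g <- street_graph(nodes, edges)
  r <- best_tolerance_route(g, "a", "b", budget_m = 900)
  expect_equal(r$edge_ids, "cool")
  expect_equal(r$r_t, 60)
})

test_that("degenerate queries: same node, disconnected, over budget", {
  g <- table4_chain_graph()
  r <- best_tolerance_route(g, "a", "a")
  expect_true(r$feasible)
  expect_equal(r$r_t, 60)
  expect_equal(r$distance_m, 0)
  r2 <- best_tolerance_route(g, "a", "h", budget_m = 500)
  expect_false(r2$feasible)
  # disconnected component
  nodes <- rbind(g$nodes, data.frame(node_id = "z", x = 9000, y = 9000))
  g2 <- street_graph(nodes, g$edges, g$entrances)
  expect_false(best_tolerance_route(g2, "a", "z")$feasible)
})

test_that("equal-stress ties break by distance then lexicographic order", {
  # two parallel two-hop routes with identical stress and length
  nodes <- data.frame(node_id = c("a", "b", "c", "d"),
                      x = c(0, 100, 100, 200), y = c(0, 50, -50, 0))
  edges <- data.frame(edge_id = c("ab", "ac", "bd", "cd"),
                      from = c("a", "a", "b", "c"),
                      to = c("b", "c", "d", "d"),
                      length_m = 100, utci_min = 33, utci_max = 35)
  g <- street_graph(nodes, edges)
  r <- best_tolerance_route(g, "a", "d", budget_m = 900)
  expect_equal(r$path, c("a", "b", "d"))
  # shorter distance wins before lexicographic order
  edges2 <- edges
  edges2$length_m <- c(100, 100, 100, 80)
  g2 <- street_graph(nodes, edges2)
  r2 <- best_tolerance_route(g2, "a", "d", budget_m = 900)
  expect_equal(r2$path, c("a", "c", "d"))
})

test_that("label-setting equals exhaustive enumeration on random graphs", {
  withr::with_seed(101, {
    for (i in 1:60) {
      g <- random_street_graph(8)
      ids <- g$nodes$node_id
      od <- sample(ids, 2)
      budget <- runif(1, 300, 1200)
      got <- best_tolerance_route(g, od[1], od[2], budget_m = budget)
      want <- oracle_best_route(g, od[1], od[2], budget)
      if (is.null(want)) {
        expect_false(got$feasible)
      } else {
        expect_true(got$feasible)
        expect_equal(got$r_t, 60 - want$s, tolerance = 1e-9)
        expect_equal(got$distance_m, want$d, tolerance = 1e-9)
      }
    }
  })
})

test_that("terminal tolerance never improves when the budget shrinks", {
  withr::with_seed(23, {
    g <- random_street_graph(9)
    ids <- g$nodes$node_id
    budgets <- c(400, 600, 800, 1000, 1500)
    rts <- vapply(budgets, function(b) {
      r <- best_tolerance_route(g, ids[1], ids[length(ids)], budget_m = b)
      if (r$feasible) r$r_t else -Inf
    }, numeric(1))
    expect_true(all(diff(rts) >= -1e-9))
    expect_true(all(rts[is.finite(rts)] <= 60))
  })
})

test_that("uniform-stress graphs reduce to shortest paths", {
  skip_if_not_installed("igraph")
  withr::with_seed(31, {
    for (i in 1:10) {
      g <- random_street_graph(9)
      g$edges$utci_min <- 39
      g$edges$utci_max <- 40  # every edge level 3
      ids <- g$nodes$node_id
      ig <- igraph::graph_from_data_frame(
        g$edges[, c("from", "to")], directed = FALSE,
        vertices = g$nodes$node_id)
      sp <- igraph::distances(ig, v = ids[1], to = ids[2],
                              weights = g$edges$length_m)[1, 1]
      # with a vanishing quantum, stress is proportional to distance and
      # the stress-optimal route is exactly a shortest path
      p <- tolerance_params(time_quantum = 1e-9)
      r <- best_tolerance_route(g, ids[1], ids[2], params = p,
                                budget_m = 1e6)
      expect_equal(r$distance_m, sp, tolerance = 1e-9)
      expect_equal(60 - r$r_t, 3 * sp / 60, tolerance = 1e-6)
    }
  })
})

test_that("walkability maps match the published chain and the oracle", {
  g <- table4_chain_graph()
  m <- walkability_map(g, "a", budget_m = 900)
  expect_equal(m$edges$r_t, c(57.6, 48.9, 47.3, 44.6, 29.9, 29.5, 20.9))
  expect_true(all(m$edges$reachable))
  withr::with_seed(53, {
    for (i in 1:25) {
      gr <- random_street_graph(8)
      origin <- sample(gr$nodes$node_id, 1)
      budget <- runif(1, 300, 1000)
      got <- walkability_map(gr, origin, budget_m = budget)
      want <- oracle_walkability(gr, origin, budget)
      expect_equal(got$edges$r_t, want, tolerance = 1e-9)
      expect_equal(got$edges$reachable, !is.na(want))
    }
  })
})

test_that("identical spokes of a star score identically", {
  g <- gen_network("radial", dims = c(5, 1), edge_length_m = 200)
  g$edges$utci_min <- 34
  g$edges$utci_max <- 36
  m <- walkability_map(g, g$nodes$node_id[1], budget_m = 900)
  expect_equal(length(unique(round(m$edges$r_t, 9))), 1L)
})

test_that("tolerance bins mirror the walkability coloring", {
  expect_equal(as.character(bin_rt(57.6)), "45-60")
  expect_equal(as.character(bin_rt(20.9)), "15-30")
  expect_equal(as.character(bin_rt(45.0)), "45-60")  # boundary to upper bin
  expect_equal(as.character(bin_rt(c(30, 15, 0, -0.1))),
               c("30-45", "15-30", "0-15", "exhausted"))
  expect_true(is.na(bin_rt(NA)))
  expect_error(bin_rt(61), "exceed")
  # cut points are configurable
  expect_equal(as.character(bin_rt(35, cutpoints = c(40, 20, 10))),
               "20-40")
})

test_that("walkability maps round-trip through GeoJSON", {
  g <- table4_chain_graph()
  m <- walkability_map(g, "a", budget_m = 900)
  tmp <- withr::local_tempfile(fileext = ".geojson")
  save_map(m, tmp)
  back <- load_map(tmp)
  expect_equal(back$edge_id, m$edges$edge_id)
  expect_equal(back$r_t, m$edges$r_t)
  expect_equal(back$bin, as.character(m$edges$bin))
  expect_equal(attr(back, "origin"), "a")
  expect_equal(attr(back, "budget_m"), 900)
})
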