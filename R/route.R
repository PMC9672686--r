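#' @keywords internal
#' @noRd
edge_costs <- function(graph, scale, params) {
  e <- graph$edges
  if (anyNA(e$utci_min) || anyNA(e$utci_max)) {
    stop("graph has edges without UTCI attributes; sample a field first",
         call. = FALSE)
  }
  level <- segment_level(e$utci_min, e$utci_max, scale)
  dur <- walk_duration(e$length_m, params)
  list(level = level, duration = dur, stress = level * dur,
       length = e$length_m)
}

# Pareto label-setting from `origin` over walks within the distance budget.
# A label is (stress s, distance d, path); at each node only labels not
# dominated in (s, d) are kept (ties in both coordinates keep the
# lexicographically smaller node sequence). Because every edge has positive
# length and non-negative stress, deleting a cycle from a walk never worsens
# either coordinate, so the frontier found over walks equals the frontier
# over simple paths and dominance pruning is exact.
pareto_labels <- function(graph, origin, cost, budget_m) {
  nid <- graph$nodes$node_id
  if (!origin %in% nid) stop("origin '", origin, "' not in graph",
                             call. = FALSE)
  adj <- graph_adjacency(graph)
  labels <- stats::setNames(vector("list", length(nid)), nid)
  labels[[origin]] <- list(list(s = 0, d = 0, path = origin,
                                edges = integer(0)))
  queue <- list(list(node = origin, s = 0, d = 0, path = origin,
                     edges = integer(0)))
  path_lt <- function(a, b) {
    # lexicographic comparison of node-id sequences
    n <- min(length(a), length(b))
    for (i in seq_len(n)) {
      if (a[i] != b[i]) return(a[i] < b[i])
    }
    length(a) < length(b)
  }
  while (length(queue)) {
    # pop the label minimizing (s, d): label-setting order
    key_s <- vapply(queue, `[[`, numeric(1), "s")
    key_d <- vapply(queue, `[[`, numeric(1), "d")
    j <- order(key_s, key_d)[1L]
    cur <- queue[[j]]
    queue[[j]] <- NULL
    # stale check: still present at its node?
    cur_set <- labels[[cur$node]]
    alive <- any(vapply(cur_set, function(l) {
      l$s == cur$s && l$d == cur$d && identical(l$path, cur$path)
    }, logical(1)))
    if (!alive) next
    nb <- adj[[cur$node]]
    if (is.null(nb)) next
    for (k in seq_len(nrow(nb))) {
      ei <- nb$edge[k]
      nn <- nb$node[k]
      nd <- cur$d + cost$length[ei]
      if (nd > budget_m + 1e-9) next
      ns <- cur$s + cost$stress[ei]
      npath <- c(cur$path, nn)
      nedges <- c(cur$edges, ei)
      set <- labels[[nn]]
      dominated <- FALSE
      keep <- logical(length(set))
      replace_equal <- FALSE
      for (m in seq_along(set)) {
        l <- set[[m]]
        if (l$s <= ns + 1e-9 && l$d <= nd + 1e-9 &&
            (l$s < ns - 1e-9 || l$d < nd - 1e-9)) {
          dominated <- TRUE
          keep[m] <- TRUE
        } else if (abs(l$s - ns) <= 1e-9 && abs(l$d - nd) <= 1e-9) {
          # equal state: keep lexicographically smaller path
          if (path_lt(l$path, npath)) dominated <- TRUE else
            replace_equal <- TRUE
          keep[m] <- !replace_equal
        } else {
          # keep unless dominated by the new label
          keep[m] <- !(ns <= l$s + 1e-9 && nd <= l$d + 1e-9)
        }
        if (dominated) break
      }
      if (dominated) next
      set <- set[keep[seq_along(set)]]
      set[[length(set) + 1L]] <- list(s = ns, d = nd, path = npath,
                                      edges = nedges)
      labels[[nn]] <- set
      queue[[length(queue) + 1L]] <- list(node = nn, s = ns, d = nd,
                                          path = npath, edges = nedges)
    }
  }
  labels
}

best_label <- function(set) {
  if (is.null(set) || !length(set)) return(NULL)
  s <- vapply(set, `[[`, numeric(1), "s")
  d <- vapply(set, `[[`, numeric(1), "d")
  cand <- which(s <= min(s) + 1e-9)
  cand <- cand[d[cand] <= min(d[cand]) + 1e-9]
  if (length(cand) > 1L) {
    # lexicographic path tie-break
    paths <- lapply(set[cand], `[[`, "path")
    key <- vapply(paths, paste, character(1), collapse = "")
    cand <- cand[order(key)[1L]]
  }
  set[[cand[1L]]]
}

#' Best walkable route under a distance budget
#'
#' Finds, among simple paths from `origin` to `dest` whose total length fits
#' the budget, one that maximizes the terminal remaining tolerant heat
#' discomfort (equivalently, minimizes cumulative heat stress). Search is
#' Pareto label-setting over (stress, distance) states with dominance
#' pruning; ties in terminal R_t are broken by shorter distance, then by
#' lexicographic node order, so results are deterministic.
#'
#' @param graph A [street_graph()] whose edges carry UTCI attributes.
#' @param origin,dest Node ids. `origin == dest` yields a zero-length walk
#'   with `r_t = H`.
#' @param scale A [heat_stress_scale()].
#' @param params A [tolerance_params()]. A positive `recovery_rate` is
#'   ignored during the search (stress is accumulated additively) and only
#'   applied when the selected route is evaluated.
#' @param budget_m Maximum route length in meters. The default 900 m is the
#'   15-minute walkshed at 1 m/s; pass `budget_min` instead to specify it in
#'   minutes.
#' @param budget_min Optional duration budget in minutes, converted via the
#'   walking speed; overrides `budget_m`.
#' @return An object of class `tolerance_route`: list with `feasible`,
#'   `path` (node ids), `edge_ids`, `distance_m`, `trajectory` (a
#'   [evaluate_route()] result, `NULL` for a zero-length walk), `r_t`, and
#'   `budget_m`. Infeasible origin/destination pairs return
#'   `feasible = FALSE`.
#' @export
best_tolerance_route <- function(graph, origin, dest,
                                 scale = heat_stress_scale(),
                                 params = tolerance_params(),
                                 budget_m = 900, budget_min = NULL) {
  stopifnot(inherits(graph, "street_graph"))
  if (!is.null(budget_min)) budget_m <- budget_min * 60 * params$walking_speed
  nid <- graph$nodes$node_id
  if (!origin %in% nid || !dest %in% nid) {
    stop("origin/dest must be node ids of the graph", call. = FALSE)
  }
  empty <- structure(list(feasible = FALSE, path = character(0),
                          edge_ids = character(0), distance_m = NA_real_,
                          trajectory = NULL, r_t = NA_real_,
                          budget_m = budget_m, origin = origin, dest = dest),
                     class = "tolerance_route")
  if (origin == dest) {
    out <- empty
    out$feasible <- TRUE
    out$path <- origin
    out$distance_m <- 0
    out$r_t <- params$H
    return(out)
  }
  cost <- edge_costs(graph, scale, params)
  labels <- pareto_labels(graph, origin, cost, budget_m)
  lab <- best_label(labels[[dest]])
  if (is.null(lab)) return(empty)
  seg <- graph$edges[lab$edges, ]
  traj <- evaluate_route(
    data.frame(segment_id = seg$edge_id, utci_min = seg$utci_min,
               utci_max = seg$utci_max, length_m = seg$length_m,
               stringsAsFactors = FALSE),
    scale = scale, params = params)
  out <- empty
  out$feasible <- TRUE
  out$path <- lab$path
  out$edge_ids <- seg$edge_id
  out$distance_m <- lab$d
  out$trajectory <- traj
  out$r_t <- traj$r_t[nrow(traj)]
  out
}

#' @export
print.tolerance_route <- function(x, ...) {
  if (!x$feasible) {
    cat(sprintf("No route from %s to %s within %g m\n", x$origin, x$dest,
                x$budget_m))
    return(invisible(x))
  }
  cat(sprintf("Best route %s -> %s (budget %g m): %s\n", x$origin, x$dest,
              x$budget_m, paste(x$path, collapse = " - ")))
  cat(sprintf("  distance %.1f m, terminal R_t = %.1f stress-min\n",
              x$distance_m, x$r_t))
  invisible(x)
}

#' Bin a remaining-tolerance value into display categories
#'
#' The categories mirror the standard walkability coloring: `[45, H]`,
#' `[30, 45)`, `[15, 30)`, `[0, 15)`, and `exhausted` for negative values.
#' A value exactly on a cut point goes to the upper bin, mirroring the
#' heat-stress classifier convention.
#'
#' @param r_t Numeric vector of remaining-tolerance values (stress-minutes),
#'   each at most `H`. `NA` passes through.
#' @param cutpoints Decreasing cut points, default `c(45, 30, 15)`.
#' @param H Budget used for the top bin's label.
#' @return Ordered factor with levels from best to worst.
#' @examples
#' bin_rt(c(57.6, 20.9, 45, -1))
#' @export
bin_rt <- function(r_t, cutpoints = c(45, 30, 15), H = 60) {
  if (any(!is.na(r_t) & r_t > H + 1e-9)) {
    stop("`r_t` values must not exceed H", call. = FALSE)
  }
  cp <- sort(cutpoints, decreasing = TRUE)
  bounds <- c(H, cp, 0)
  labs <- c(vapply(seq_along(cp), function(i) {
    sprintf("%g-%g", bounds[i + 1L], bounds[i])
  }, character(1)), sprintf("0-%g", cp[length(cp)]), "exhausted")
  idx <- vapply(r_t, function(r) {
    if (is.na(r)) return(NA_integer_)
    if (r < -1e-9) return(length(labs))
    # a value exactly on a cut point belongs to the upper bin
    1L + sum(cp > r + 1e-9)
  }, integer(1))
  factor(labs[idx], levels = labs, ordered = TRUE)
}

#' Per-edge walkability from one origin
#'
#' For every edge of the network, the best remaining tolerant heat
#' discomfort attainable at the edge's far end over feasible routes from
#' `origin` that end by traversing that edge within the distance budget.
#' Edges not reachable that way are flagged. `rule = "max"` (default) scores
#' an edge by the better of its two traversal directions; `rule = "min"`
#' takes the worse direction (each direction still via its best route).
#'
#' @inheritParams best_tolerance_route
#' @param rule `"max"` or `"min"` over the two traversal directions.
#' @return An object of class `walkability_map`: list with `edges` (data
#'   frame `edge_id`, `r_t`, `bin`, `reachable`), `origin`, `budget_m`,
#'   `params`, and the `graph`.
#' @export
walkability_map <- function(graph, origin, scale = heat_stress_scale(),
                            params = tolerance_params(), budget_m = 900,
                            budget_min = NULL, rule = c("max", "min")) {
  stopifnot(inherits(graph, "street_graph"))
  rule <- match.arg(rule)
  if (!is.null(budget_min)) budget_m <- budget_min * 60 * params$walking_speed
  cost <- edge_costs(graph, scale, params)
  labels <- pareto_labels(graph, origin, cost, budget_m)
  ne <- nrow(graph$edges)
  r_t <- rep(NA_real_, ne)
  for (i in seq_len(ne)) {
    e <- graph$edges[i, ]
    dir_r <- c(NA_real_, NA_real_)
    ends <- list(c(e$from, e$to), c(e$to, e$from))
    for (k in 1:2) {
      u <- ends[[k]][1L]
      set <- labels[[u]]
      if (is.null(set) || !length(set)) next
      s_u <- vapply(set, `[[`, numeric(1), "s")
      d_u <- vapply(set, `[[`, numeric(1), "d")
      ok <- d_u + cost$length[i] <= budget_m + 1e-9
      if (!any(ok)) next
      dir_r[k] <- params$H - (min(s_u[ok]) + cost$stress[i])
    }
    if (!all(is.na(dir_r))) {
      r_t[i] <- if (rule == "max") max(dir_r, na.rm = TRUE) else
        min(dir_r, na.rm = TRUE)
    }
  }
  edges <- data.frame(edge_id = graph$edges$edge_id, r_t = r_t,
                      bin = bin_rt(r_t, H = params$H),
                      reachable = !is.na(r_t),
                      stringsAsFactors = FALSE)
  structure(list(edges = edges, origin = origin, budget_m = budget_m,
                 params = params, graph = graph),
            class = "walkability_map")
}

#' @export
print.walkability_map <- function(x, ...) {
  cat(sprintf("Walkability map from '%s' (budget %g m): %d/%d edges reachable\n",
              x$origin, x$budget_m, sum(x$edges$reachable),
              nrow(x$edges)))
  print(table(x$edges$bin, useNA = "ifany"))
  invisible(x)
}

map_feature_collection <- function(edges_df, graph, extra_members = list()) {
  xy <- stats::setNames(split(as.matrix(graph$nodes[, c("x", "y")]),
                              seq_len(nrow(graph$nodes))),
                        graph$nodes$node_id)
  ge <- graph$edges
  feats <- lapply(seq_len(nrow(edges_df)), function(i) {
    ei <- match(edges_df$edge_id[i], ge$edge_id)
    props <- as.list(edges_df[i, , drop = FALSE])
    props <- lapply(props, function(v) {
      if (is.factor(v)) as.character(v) else v
    })
    list(type = "Feature",
         geometry = list(type = "LineString",
                         coordinates = list(as.numeric(xy[[ge$from[ei]]]),
                                            as.numeric(xy[[ge$to[ei]]]))),
         properties = props)
  })
  c(list(type = "FeatureCollection", features = feats), extra_members)
}

#' Write a walkability map to GeoJSON
#'
#' Each edge is emitted as a LineString with `edge_id`, `r_t`, `bin` and
#' `reachable` properties for GIS display; origin and budget are stored as
#' top-level members.
#'
#' @param map A [walkability_map()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_map <- function(map, path) {
  stopifnot(inherits(map, "walkability_map"))
  gj <- map_feature_collection(map$edges, map$graph,
                               list(origin = map$origin,
                                    budget_m = map$budget_m,
                                    H = map$params$H))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = FALSE)
  invisible(path)
}

#' Read back a saved walkability map
#'
#' @param path GeoJSON path written by [save_map()].
#' @return A data frame of per-edge `edge_id`, `r_t`, `bin`, `reachable`,
#'   with attributes `origin`, `budget_m`, `H`.
#' @export
load_map <- function(path) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  rows <- lapply(gj$features, function(f) {
    p <- f$properties
    data.frame(edge_id = as.character(p$edge_id),
               r_t = if (is.null(p$r_t)) NA_real_ else as.numeric(p$r_t),
               bin = if (is.null(p$bin)) NA_character_ else
                 as.character(p$bin),
               reachable = isTRUE(p$reachable),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "origin") <- gj$origin
  attr(out, "budget_m") <- gj$budget_m
  attr(out, "H") <- gj$H
  out
}
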