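#' Street network graph
#'
#' An undirected street network: nodes with planar meter coordinates, edges
#' with lengths and per-edge UTCI summaries, and a set of entrance nodes
#' (neighborhood starting points for walks). Edges are traversable in both
#' directions with identical attributes.
#'
#' @param nodes Data frame with columns `node_id`, `x`, `y` (meters, planar).
#' @param edges Data frame with columns `edge_id`, `from`, `to`, `length_m`
#'   (> 0) and optionally `utci_min`, `utci_max` (may be `NA` until sampled
#'   from a field).
#' @param entrances Character vector of node ids marking walk origins.
#' @return An object of class `street_graph`.
#' @export
street_graph <- function(nodes, edges, entrances = character(0)) {
  stopifnot(is.data.frame(nodes), is.data.frame(edges))
  need_n <- c("node_id", "x", "y")
  need_e <- c("edge_id", "from", "to", "length_m")
  if (!all(need_n %in% names(nodes))) {
    stop("`nodes` needs columns node_id, x, y", call. = FALSE)
  }
  if (!all(need_e %in% names(edges))) {
    stop("`edges` needs columns edge_id, from, to, length_m", call. = FALSE)
  }
  nodes$node_id <- as.character(nodes$node_id)
  edges$edge_id <- as.character(edges$edge_id)
  edges$from <- as.character(edges$from)
  edges$to <- as.character(edges$to)
  if (anyDuplicated(nodes$node_id)) {
    stop("node ids must be unique", call. = FALSE)
  }
  if (nrow(edges)) {
    if (anyDuplicated(edges$edge_id)) {
      stop("edge ids must be unique", call. = FALSE)
    }
    dangling <- setdiff(c(edges$from, edges$to), nodes$node_id)
    if (length(dangling)) {
      stop("edge endpoint(s) not in node table: ",
           paste(dangling, collapse = ", "), call. = FALSE)
    }
    if (any(!is.finite(edges$length_m)) || any(edges$length_m <= 0)) {
      stop("edge lengths must be positive", call. = FALSE)
    }
    if (!"utci_min" %in% names(edges)) edges$utci_min <- NA_real_
    if (!"utci_max" %in% names(edges)) edges$utci_max <- NA_real_
    bad <- !is.na(edges$utci_min) & !is.na(edges$utci_max) &
      edges$utci_min > edges$utci_max
    if (any(bad)) {
      stop("utci_min > utci_max on edge(s): ",
           paste(edges$edge_id[bad], collapse = ", "), call. = FALSE)
    }
  } else {
    if (!"utci_min" %in% names(edges)) edges$utci_min <- numeric(0)
    if (!"utci_max" %in% names(edges)) edges$utci_max <- numeric(0)
  }
  entrances <- as.character(entrances)
  missing_ent <- setdiff(entrances, nodes$node_id)
  if (length(missing_ent)) {
    stop("entrance id(s) not in graph: ",
         paste(missing_ent, collapse = ", "), call. = FALSE)
  }
  structure(list(nodes = nodes[, need_n],
                 edges = edges[, c(need_e, "utci_min", "utci_max")],
                 entrances = entrances),
            class = "street_graph")
}

#' @export
print.street_graph <- function(x, ...) {
  cat(sprintf("Street graph: %d nodes, %d edges, %d entrance(s)\n",
              nrow(x$nodes), nrow(x$edges), length(x$entrances)))
  if (length(x$entrances)) {
    cat("  entrances:", paste(x$entrances, collapse = ", "), "\n")
  }
  invisible(x)
}

# adjacency list: for each node id, data frame of (neighbor, edge row index)
graph_adjacency <- function(graph) {
  adj <- stats::setNames(vector("list", nrow(graph$nodes)),
                         graph$nodes$node_id)
  for (i in seq_len(nrow(graph$edges))) {
    e <- graph$edges[i, ]
    adj[[e$from]] <- rbind(adj[[e$from]],
                           data.frame(node = e$to, edge = i,
                                      stringsAsFactors = FALSE))
    adj[[e$to]] <- rbind(adj[[e$to]],
                         data.frame(node = e$from, edge = i,
                                    stringsAsFactors = FALSE))
  }
  adj
}

polyline_length <- function(coords) {
  # coords: matrix with columns x, y
  if (nrow(coords) < 2L) return(0)
  sum(sqrt(rowSums(diff(coords)^2)))
}

#' Load a street network from GeoJSON
#'
#' Reads an RFC 7946 FeatureCollection with planar (meter) coordinates.
#' LineString features are edges and must carry `utci_min` and `utci_max`
#' properties (`length_m` is computed from the geometry when absent;
#' `edge_id` is auto-assigned when absent). Shared endpoints are snapped
#' within a tolerance to form nodes. Point features may label nodes (property
#' `node_id`) and flag entrances (property `entrance` true); entrances can
#' also be given as node ids via the `entrances` argument.
#'
#' @param path Path to a GeoJSON file.
#' @param snap_tolerance Endpoint snapping distance in meters.
#' @param entrances Optional character vector of additional entrance node
#'   ids; unknown ids are an error.
#' @return A [street_graph()].
#' @export
load_network <- function(path, snap_tolerance = 0.5,
                         entrances = character(0)) {
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(gj$type) || gj$type != "FeatureCollection") {
    stop("expected a GeoJSON FeatureCollection", call. = FALSE)
  }
  feats <- gj$features
  lines <- Filter(function(f) identical(f$geometry$type, "LineString"), feats)
  points <- Filter(function(f) identical(f$geometry$type, "Point"), feats)
  if (length(lines) == 0L) {
    stop("FeatureCollection contains no LineString features (empty graph)",
         call. = FALSE)
  }

  # snap endpoints to shared nodes
  node_xy <- matrix(numeric(0), ncol = 2)
  snap <- function(pt) {
    if (nrow(node_xy)) {
      d2 <- (node_xy[, 1] - pt[1])^2 + (node_xy[, 2] - pt[2])^2
      j <- which.min(d2)
      if (d2[j] <= snap_tolerance^2) return(j)
    }
    node_xy <<- rbind(node_xy, pt)
    nrow(node_xy)
  }

  edges <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    f <- lines[[i]]
    props <- f$properties
    fid <- if (!is.null(props$edge_id)) as.character(props$edge_id) else
      sprintf("e%d", i)
    if (is.null(props$utci_min) || is.null(props$utci_max)) {
      stop(sprintf("feature '%s' lacks utci_min/utci_max properties", fid),
           call. = FALSE)
    }
    coords <- do.call(rbind, lapply(f$geometry$coordinates,
                                    function(c) c(c[[1]], c[[2]])))
    if (nrow(coords) < 2L) {
      stop(sprintf("feature '%s' has fewer than two coordinates", fid),
           call. = FALSE)
    }
    len <- if (!is.null(props$length_m)) as.numeric(props$length_m) else
      polyline_length(coords)
    edges[[i]] <- data.frame(
      edge_id = fid,
      from_i = snap(coords[1, ]),
      to_i = snap(coords[nrow(coords), ]),
      length_m = len,
      utci_min = as.numeric(props$utci_min),
      utci_max = as.numeric(props$utci_max),
      stringsAsFactors = FALSE)
  }
  edges <- do.call(rbind, edges)

  node_id <- sprintf("n%d", seq_len(nrow(node_xy)))
  ent_pts <- character(0)
  for (p in points) {
    pt <- c(p$geometry$coordinates[[1]], p$geometry$coordinates[[2]])
    d2 <- (node_xy[, 1] - pt[1])^2 + (node_xy[, 2] - pt[2])^2
    j <- which.min(d2)
    if (d2[j] <= snap_tolerance^2) {
      if (!is.null(p$properties$node_id)) {
        node_id[j] <- as.character(p$properties$node_id)
      }
      if (isTRUE(p$properties$entrance)) ent_pts <- c(ent_pts, node_id[j])
    }
  }
  nodes <- data.frame(node_id = node_id, x = node_xy[, 1], y = node_xy[, 2],
                      stringsAsFactors = FALSE)
  edges$from <- node_id[edges$from_i]
  edges$to <- node_id[edges$to_i]
  street_graph(nodes, edges[, c("edge_id", "from", "to", "length_m",
                                "utci_min", "utci_max")],
               entrances = union(ent_pts, entrances))
}

#' Write a street network to GeoJSON
#'
#' Edges are emitted as two-point LineStrings carrying `edge_id`,
#' `length_m`, `utci_min`, `utci_max`; nodes as Points carrying `node_id`
#' and an `entrance` flag, so a written network reloads to an identical
#' graph. Intermediate polyline vertices of loaded geometries are not kept.
#'
#' @param graph A [street_graph()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_network <- function(graph, path) {
  stopifnot(inherits(graph, "street_graph"))
  xy <- stats::setNames(split(as.matrix(graph$nodes[, c("x", "y")]),
                              seq_len(nrow(graph$nodes))),
                        graph$nodes$node_id)
  efeat <- lapply(seq_len(nrow(graph$edges)), function(i) {
    e <- graph$edges[i, ]
    list(type = "Feature",
         geometry = list(type = "LineString",
                         coordinates = list(as.numeric(xy[[e$from]]),
                                            as.numeric(xy[[e$to]]))),
         properties = list(edge_id = e$edge_id, length_m = e$length_m,
                           utci_min = e$utci_min, utci_max = e$utci_max))
  })
  nfeat <- lapply(seq_len(nrow(graph$nodes)), function(i) {
    n <- graph$nodes[i, ]
    list(type = "Feature",
         geometry = list(type = "Point",
                         coordinates = c(n$x, n$y)),
         properties = list(node_id = n$node_id,
                           entrance = n$node_id %in% graph$entrances))
  })
  gj <- list(type = "FeatureCollection", features = c(efeat, nfeat))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = FALSE)
  invisible(path)
}
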