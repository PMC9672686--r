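# Separable Gaussian smoothing of a matrix, edge-padded by replication.
smooth_matrix <- function(m, sigma_cells) {
  if (sigma_cells <= 0) return(m)
  half <- max(1L, ceiling(3 * sigma_cells))
  kern <- stats::dnorm(seq(-half, half), sd = sigma_cells)
  kern <- kern / sum(kern)
  pad_conv <- function(v) {
    vp <- c(rep(v[1L], half), v, rep(v[length(v)], half))
    stats::convolve(vp, rev(kern), type = "filter")
  }
  m <- t(apply(m, 1L, pad_conv))
  t(apply(t(m), 1L, pad_conv)) |> t()
}

#' Generate a synthetic spatially correlated UTCI field
#'
#' Stand-in for a microclimate-model UTCI raster: a smooth (kernel-filtered
#' Gaussian noise) field around a base temperature, with additive feature
#' effects on structured masks — tree-shade blobs and a riverside band cool
#' the field, east-west street canyons warm it — clipped to a plausible
#' band. The statistical structure (range of roughly 31-41 degrees C on hot
#' afternoons, cooler water-adjacent and shaded corridors, warmer east-west
#' canyons) emulates typical simulated street-level output; it is not a
#' physical model. Deterministic under a fixed seed.
#'
#' @param rows,cols Grid dimensions (positive).
#' @param cell_size Cell edge length in meters.
#' @param base Base UTCI in degrees C.
#' @param amplitude Standard deviation of the smooth random component, in
#'   degrees C; 0 gives a deterministic field.
#' @param correlation_length Smoothing length in meters (Gaussian kernel
#'   sigma).
#' @param effects Named numeric vector of additive effects in degrees C for
#'   masks `tree`, `water`, `canyon`.
#' @param band Plausibility band `c(lo, hi)` to clip to, in degrees C.
#' @param seed Integer seed; same seed, same raster.
#' @return Object of class `utci_field`: list with `values` (rows x cols
#'   matrix), `cell_size`, `masks` (logical matrices `tree`, `water`,
#'   `canyon`), `band`, `base`, `seed`. The raster origin is at (0, 0);
#'   cell `[i, j]` covers `x` in `[(j-1), j) * cell_size` and `y` in
#'   `[(i-1), i) * cell_size`.
#' @examples
#' f <- gen_utci_field(rows = 20, cols = 20, seed = 1)
#' range(f$values)
#' @export
gen_utci_field <- function(rows = 60, cols = 50, cell_size = 8, base = 36,
                           amplitude = 2, correlation_length = 40,
                           effects = c(tree = -2, water = -3, canyon = 3),
                           band = c(28, 44), seed = 1) {
  if (rows < 1 || cols < 1) stop("grid must be non-empty", call. = FALSE)
  if (anyNA(effects) || !all(is.finite(effects))) {
    stop("`effects` must be finite", call. = FALSE)
  }
  eff <- c(tree = 0, water = 0, canyon = 0)
  eff[names(effects)] <- effects
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)

  sigma <- correlation_length / cell_size
  noise <- matrix(stats::rnorm(rows * cols), rows, cols)
  sm <- smooth_matrix(noise, sigma)
  s <- stats::sd(as.vector(sm))
  # center before rescaling: smoothing shrinks the sd far below the mean's
  # sampling error, so an uncentered rescale would inflate the field mean
  sm <- if (s > 0) (sm - mean(sm)) / s * amplitude else
    matrix(0, rows, cols)

  # masks: riverside band along the west edge, east-west canyons as periodic
  # row bands, tree-shade blobs from thresholded smoothed noise
  water <- matrix(FALSE, rows, cols)
  water[, seq_len(min(3L, cols))] <- TRUE
  canyon <- matrix(FALSE, rows, cols)
  canyon_rows <- which(seq_len(rows) %% 8L %in% c(0L, 1L))
  canyon[canyon_rows, ] <- TRUE
  tree_noise <- smooth_matrix(matrix(stats::rnorm(rows * cols), rows, cols),
                              sigma)
  tree <- tree_noise >= stats::quantile(tree_noise, 0.8)
  tree <- tree & !water

  values <- base + sm + eff["tree"] * tree + eff["water"] * water +
    eff["canyon"] * (canyon & !water & !tree)
  values <- pmin(pmax(values, band[1L]), band[2L])
  structure(list(values = values, cell_size = cell_size,
                 masks = list(tree = tree, water = water, canyon = canyon),
                 band = band, base = base, seed = seed),
            class = "utci_field")
}

# save/restore the global RNG state so generators are pure in (spec, seed)
.Random.seed_get <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_set <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.utci_field <- function(x, ...) {
  cat(sprintf("UTCI field: %d x %d cells of %g m, range %.2f-%.2f deg C\n",
              nrow(x$values), ncol(x$values), x$cell_size,
              min(x$values), max(x$values)))
  invisible(x)
}

#' Plot a UTCI field
#'
#' @param x A `utci_field`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.utci_field <- function(x, ...) {
  cs <- x$cell_size
  graphics::image(x = (seq_len(ncol(x$values)) - 0.5) * cs,
                  y = (seq_len(nrow(x$values)) - 0.5) * cs,
                  z = t(x$values), xlab = "x (m)", ylab = "y (m)",
                  col = grDevices::hcl.colors(24, "YlOrRd", rev = TRUE), ...)
  invisible(x)
}

field_value_at <- function(field, x, y) {
  cs <- field$cell_size
  nr <- nrow(field$values)
  nc <- ncol(field$values)
  col <- floor(x / cs) + 1L
  row <- floor(y / cs) + 1L
  # points exactly on the east/north extent boundary belong to the last cell
  col[x >= nc * cs - 1e-9 & x <= nc * cs + 1e-9] <- nc
  row[y >= nr * cs - 1e-9 & y <= nr * cs + 1e-9] <- nr
  if (any(col < 1L | col > nc | row < 1L | row > nr)) return(NULL)
  field$values[cbind(row, col)]
}

#' Sample per-edge UTCI summaries from a field
#'
#' Walks each edge's straight segment between its endpoint coordinates,
#' samples the field at the given step (endpoints always included), and
#' records the min and max UTCI on the edge.
#'
#' @param field A [gen_utci_field()] raster.
#' @param graph A [street_graph()] whose nodes lie within the raster extent.
#' @param step Sampling step in meters; defaults to the cell size.
#' @return The graph with `utci_min`/`utci_max` filled in on every edge.
#' @export
sample_edge_utci <- function(field, graph, step = field$cell_size) {
  stopifnot(inherits(field, "utci_field"), inherits(graph, "street_graph"))
  nodes <- graph$nodes
  for (i in seq_len(nrow(graph$edges))) {
    e <- graph$edges[i, ]
    a <- nodes[nodes$node_id == e$from, c("x", "y")]
    b <- nodes[nodes$node_id == e$to, c("x", "y")]
    seg_len <- sqrt((b$x - a$x)^2 + (b$y - a$y)^2)
    npts <- max(2L, ceiling(seg_len / step) + 1L)
    tt <- seq(0, 1, length.out = npts)
    vals <- field_value_at(field, a$x + tt * (b$x - a$x),
                           a$y + tt * (b$y - a$y))
    if (is.null(vals)) {
      stop(sprintf("edge '%s' lies outside the raster extent", e$edge_id),
           call. = FALSE)
    }
    graph$edges$utci_min[i] <- min(vals)
    graph$edges$utci_max[i] <- max(vals)
  }
  graph
}

#' Generate a synthetic street network
#'
#' `kind = "grid"` builds a rectangular lattice of `dims = c(rows, cols)`
#' street blocks — `(rows+1) * (cols+1)` nodes; one dimension may be zero to
#' produce a chain. `kind = "radial"` builds `dims = c(spokes, rings)`
#' chains radiating from a center node. Edge lengths are `edge_length_m`
#' plus optional Gaussian jitter. Nodes are labelled `a`, `b`, ... when 26
#' or fewer, else `n001`, `n002`, .... The first node is the default
#' entrance.
#'
#' @param kind `"grid"` or `"radial"`.
#' @param dims Integer pair (see above), each >= 0 with at least one > 0.
#' @param edge_length_m Nominal edge length in meters.
#' @param length_jitter_sd Standard deviation of edge-length jitter in
#'   meters (lengths are kept positive).
#' @param seed Integer seed for the jitter.
#' @return A [street_graph()] with UTCI attributes unset (`NA`) until
#'   sampled via [sample_edge_utci()].
#' @examples
#' g <- gen_network("grid", dims = c(0, 7), edge_length_m = 128.6)
#' g$nodes$node_id  # a ... h chain
#' @export
gen_network <- function(kind = c("grid", "radial"), dims = c(2, 2),
                        edge_length_m = 100, length_jitter_sd = 0,
                        seed = 1) {
  kind <- match.arg(kind)
  stopifnot(length(dims) == 2L, all(dims >= 0), any(dims > 0),
            edge_length_m > 0, length_jitter_sd >= 0)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  el <- edge_length_m
  if (kind == "grid") {
    r <- dims[1L]; c <- dims[2L]
    nodes <- expand.grid(col = 0:c, row = 0:r)
    nodes <- data.frame(x = nodes$col * el, y = nodes$row * el)
    idx <- function(row, col) row * (c + 1L) + col + 1L
    ed <- list()
    for (row in 0:r) for (col in 0:c) {
      if (col < c) ed[[length(ed) + 1L]] <- c(idx(row, col), idx(row, col + 1L))
      if (row < r) ed[[length(ed) + 1L]] <- c(idx(row, col), idx(row + 1L, col))
    }
  } else {
    s <- dims[1L]; g <- dims[2L]
    stopifnot(s >= 1, g >= 1)
    ang <- 2 * pi * (seq_len(s) - 1L) / s
    nodes <- data.frame(x = 0, y = 0)
    ed <- list()
    for (k in seq_len(s)) {
      prev <- 1L
      for (ring in seq_len(g)) {
        nodes <- rbind(nodes, data.frame(x = ring * el * cos(ang[k]),
                                         y = ring * el * sin(ang[k])))
        cur <- nrow(nodes)
        ed[[length(ed) + 1L]] <- c(prev, cur)
        prev <- cur
      }
    }
  }
  n <- nrow(nodes)
  ids <- if (n <= 26L) letters[seq_len(n)] else sprintf("n%03d", seq_len(n))
  em <- do.call(rbind, ed)
  lens <- rep(el, nrow(em))
  if (length_jitter_sd > 0) {
    lens <- pmax(1, lens + stats::rnorm(nrow(em), 0, length_jitter_sd))
  }
  edges <- data.frame(edge_id = paste0(ids[em[, 1L]], ids[em[, 2L]]),
                      from = ids[em[, 1L]], to = ids[em[, 2L]],
                      length_m = lens, stringsAsFactors = FALSE)
  # offset grid coordinates so the network sits inside a raster placed at
  # the origin with a half-edge margin
  nodes$x <- nodes$x - min(nodes$x) + el / 2
  nodes$y <- nodes$y - min(nodes$y) + el / 2
  street_graph(data.frame(node_id = ids, x = nodes$x, y = nodes$y,
                          stringsAsFactors = FALSE),
               edges, entrances = ids[1L])
}

#' Default survey-generator onset matrix
#'
#' True discomfort-onset minutes per heat-stress level (rows, levels 1-4)
#' and discomfort category (columns, 1 slightly to 4 extremely); `NA` means
#' the category is never reached within the 15-minute walk. The defaults
#' encode the observed pattern: only slight discomfort under moderate heat,
#' discomfort from minute 9 under strong heat, very uncomfortable from
#' minute 12 under very strong heat, and extreme discomfort from minute 13
#' under extreme heat.
#'
#' @return 4 x 4 integer matrix of onset minutes.
#' @export
default_onsets <- function() {
  matrix(c(1L, NA, NA, NA,
           1L, 9L, NA, NA,
           1L, 6L, 12L, NA,
           1L, 5L, 8L, 13L),
         nrow = 4L, byrow = TRUE,
         dimnames = list(paste0("level", 1:4),
                         c("slightly", "uncomfortable", "very",
                           "extremely")))
}

check_onsets <- function(onsets) {
  stopifnot(is.matrix(onsets), nrow(onsets) == 4L, ncol(onsets) == 4L)
  v <- onsets[!is.na(onsets)]
  if (any(v < 1 | v > 15)) {
    stop("onset minutes must be within 1-15", call. = FALSE)
  }
  if (any(is.na(onsets[, 1L]) | onsets[, 1L] != 1L)) {
    stop("category-1 onset must be minute 1 at every level", call. = FALSE)
  }
  inf <- ifelse(is.na(onsets), Inf, onsets)
  for (l in 1:4) {
    d <- diff(inf[l, ])
    d <- d[!is.nan(d)]  # Inf - Inf between two never-reached categories
    if (any(d < 0)) {
      stop("onsets must be nondecreasing across categories within a level",
           call. = FALSE)
    }
  }
  for (l in 1:3) {
    if (any(inf[l + 1L, ] > inf[l, ])) {
      stop("higher heat levels must have onsets no later than lower levels",
           call. = FALSE)
    }
  }
  invisible(onsets)
}

#' Generate a synthetic ordinal survey panel
#'
#' Each of `n` respondents walks 15 minutes at each heat-stress level 1-4
#' and reports an ordinal discomfort category each minute. The true category
#' at (level, minute) is the highest category whose onset has been reached;
#' with probability `noise` a response is flipped by one category (symmetric
#' direction, clamped to 1-4). Deterministic under a fixed seed.
#'
#' @param n Number of respondents.
#' @param onsets 4 x 4 onset matrix as in [default_onsets()].
#' @param noise Per-response flip probability in `[0, 1]`.
#' @param seed Integer seed.
#' @return A survey panel data frame (`respondent_id`, `heat_level`,
#'   `minute`, `discomfort`) with `n * 4 * 15` rows.
#' @examples
#' panel <- gen_survey(n = 8, noise = 0, seed = 1)
#' discomfort_timeline(panel, 4)$onsets
#' @export
gen_survey <- function(n = 128, onsets = default_onsets(), noise = 0.1,
                       seed = 1) {
  stopifnot(n >= 1, noise >= 0, noise <= 1)
  check_onsets(onsets)
  old <- .Random.seed_get()
  on.exit(.Random.seed_set(old))
  set.seed(seed)
  grid <- expand.grid(minute = 1:15, heat_level = 1:4,
                      respondent_id = sprintf("r%03d", seq_len(n)),
                      stringsAsFactors = FALSE)
  truth <- mapply(function(l, m) {
    sum(!is.na(onsets[l, ]) & onsets[l, ] <= m)
  }, grid$heat_level, grid$minute)
  flip <- stats::runif(nrow(grid)) < noise
  dir <- sample(c(-1L, 1L), nrow(grid), replace = TRUE)
  resp <- truth + ifelse(flip, dir, 0L)
  resp <- pmin(pmax(resp, 1L), 4L)
  out <- data.frame(respondent_id = grid$respondent_id,
                    heat_level = grid$heat_level,
                    minute = grid$minute,
                    discomfort = as.integer(resp),
                    stringsAsFactors = FALSE)
  validate_panel(out)
}

#' Write a UTCI field as a plain-text ESRI ASCII grid
#'
#' @param field A [gen_utci_field()] raster.
#' @param path Output path (`.asc`).
#' @return `path`, invisibly.
#' @export
write_utci_grid <- function(field, path) {
  stopifnot(inherits(field, "utci_field"))
  v <- field$values
  hdr <- c(sprintf("ncols %d", ncol(v)),
           sprintf("nrows %d", nrow(v)),
           "xllcorner 0", "yllcorner 0",
           sprintf("cellsize %g", field$cell_size),
           "NODATA_value -9999")
  rows <- apply(v[rev(seq_len(nrow(v))), , drop = FALSE], 1L,
                paste, collapse = " ")
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a plain-text ESRI ASCII grid as a UTCI field
#'
#' @param path Path written by [write_utci_grid()] (or any ASCII grid).
#' @return A `utci_field` (with empty feature masks).
#' @export
read_utci_grid <- function(path) {
  ln <- readLines(path)
  hdr <- ln[1:6]
  val <- function(key) {
    row <- grep(paste0("^", key, " "), hdr, value = TRUE)
    as.numeric(strsplit(row, " +")[[1L]][2L])
  }
  nc <- val("ncols"); nr <- val("nrows"); cs <- val("cellsize")
  m <- do.call(rbind, lapply(ln[-(1:6)], function(r) {
    as.numeric(strsplit(trimws(r), " +")[[1L]])
  }))
  stopifnot(nrow(m) == nr, ncol(m) == nc)
  values <- m[rev(seq_len(nr)), , drop = FALSE]
  structure(list(values = values, cell_size = cs,
                 masks = list(), band = range(values),
                 base = mean(values), seed = NA_integer_),
            class = "utci_field")
}
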