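#' Population weights for neighborhoods
#'
#' Each neighborhood's weight is its share of the total population,
#' `k_i = P_i / sum(P)`. Only ratios matter, so populations may be given in
#' raw persons or thousands. Exact weights sum to one; a two-decimal rounded
#' view matching tabular presentation is attached for display (and need not
#' sum to one).
#'
#' @param populations Non-negative numeric vector, at least one entry, with
#'   a positive total. Names (or `ids`) label the neighborhoods.
#' @param ids Optional character vector of neighborhood ids; defaults to
#'   names of `populations` or `LETTERS`.
#' @return Object of class `neighborhood_weights`: data frame with columns
#'   `neighborhood_id`, `population`, `weight`, `weight_rounded`.
#' @examples
#' population_weights(c(A = 3.0, B = 2.7, C = 2.2))
#' @export
population_weights <- function(populations, ids = NULL) {
  if (!is.numeric(populations) || length(populations) < 1L ||
      anyNA(populations) || any(populations < 0)) {
    stop("`populations` must be non-negative numbers", call. = FALSE)
  }
  if (sum(populations) <= 0) {
    stop("total population must be positive", call. = FALSE)
  }
  if (is.null(ids)) {
    ids <- names(populations)
    if (is.null(ids)) {
      ids <- if (length(populations) <= 26L)
        LETTERS[seq_along(populations)] else
          sprintf("N%02d", seq_along(populations))
    }
  }
  stopifnot(length(ids) == length(populations))
  w <- populations / sum(populations)
  out <- data.frame(neighborhood_id = as.character(ids),
                    population = as.numeric(populations),
                    weight = as.numeric(w),
                    weight_rounded = round(as.numeric(w), 2),
                    stringsAsFactors = FALSE)
  class(out) <- c("neighborhood_weights", "data.frame")
  out
}

#' @export
print.neighborhood_weights <- function(x, ...) {
  cat(sprintf("Population weights for %d neighborhoods (sum of exact weights = %g):\n",
              nrow(x), sum(x$weight)))
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Population-weighted walkability across neighborhoods
#'
#' Combines per-neighborhood walkability maps (all on one shared street
#' graph) into a city-wide score: for each edge, the convex combination
#' `W(e) = sum_i k_i R_t,i(e)` over the neighborhoods whose walkshed reaches
#' the edge. By default weights are renormalized over that contributing
#' subset; `unreachable = "zero"` instead keeps full weights and scores an
#' unreached edge as `R_t = 0` for that neighborhood. Edges reached by no
#' neighborhood are left unscored.
#'
#' @param maps Named list of [walkability_map()] results, one per
#'   neighborhood; names are neighborhood ids and must be covered by
#'   `weights`.
#' @param weights A [population_weights()] table (or a named numeric vector
#'   of weights).
#' @param unreachable `"renormalize"` (default) or `"zero"`.
#' @return Object of class `fmc_walkability`: list with `edges` (data frame
#'   `edge_id`, `W`, `n_contrib`, `scored`), the shared `graph`, `weights`,
#'   and `H`.
#' @export
aggregate_walkability <- function(maps, weights,
                                  unreachable = c("renormalize", "zero")) {
  unreachable <- match.arg(unreachable)
  stopifnot(is.list(maps), length(maps) >= 1L)
  if (is.null(names(maps)) || any(names(maps) == "")) {
    stop("`maps` must be a named list keyed by neighborhood id",
         call. = FALSE)
  }
  if (inherits(weights, "neighborhood_weights")) {
    w <- stats::setNames(weights$weight, weights$neighborhood_id)
  } else if (is.numeric(weights) && !is.null(names(weights))) {
    w <- weights / sum(weights)
  } else {
    stop("`weights` must be a population_weights table or named numeric",
         call. = FALSE)
  }
  missing_w <- setdiff(names(maps), names(w))
  if (length(missing_w)) {
    stop("no weight for neighborhood(s): ",
         paste(missing_w, collapse = ", "), call. = FALSE)
  }
  eids <- maps[[1L]]$edges$edge_id
  for (m in maps) {
    stopifnot(inherits(m, "walkability_map"))
    if (!identical(sort(m$edges$edge_id), sort(eids))) {
      stop("all maps must share one street graph (edge sets differ)",
           call. = FALSE)
    }
  }
  H <- maps[[1L]]$params$H
  rt <- sapply(maps, function(m) {
    m$edges$r_t[match(eids, m$edges$edge_id)]
  })
  rt <- matrix(rt, nrow = length(eids),
               dimnames = list(eids, names(maps)))
  kv <- w[names(maps)]
  W <- numeric(length(eids))
  n_contrib <- integer(length(eids))
  for (i in seq_along(eids)) {
    reach <- !is.na(rt[i, ])
    n_contrib[i] <- sum(reach)
    if (!any(reach)) {
      W[i] <- NA_real_
    } else if (unreachable == "renormalize") {
      W[i] <- sum(kv[reach] * rt[i, reach]) / sum(kv[reach])
    } else {
      vals <- ifelse(reach, rt[i, ], 0)
      W[i] <- sum(kv * vals) / sum(kv)
    }
  }
  edges <- data.frame(edge_id = eids, W = W, n_contrib = n_contrib,
                      scored = !is.na(W), stringsAsFactors = FALSE)
  structure(list(edges = edges, graph = maps[[1L]]$graph,
                 weights = kv, H = H, unreachable = unreachable),
            class = "fmc_walkability")
}

#' @export
print.fmc_walkability <- function(x, ...) {
  cat(sprintf("City-wide walkability: %d edges, %d scored, %d neighborhoods\n",
              nrow(x$edges), sum(x$edges$scored), length(x$weights)))
  if (any(x$edges$scored)) {
    cat(sprintf("  W range: %.1f to %.1f stress-min\n",
                min(x$edges$W, na.rm = TRUE), max(x$edges$W, na.rm = TRUE)))
  }
  invisible(x)
}

#' Public-service siting classes from city-wide walkability
#'
#' Streets with the most remaining tolerance are where frequently-used
#' services belong; streets below the lowest cut (or unscored) are
#' unsuitable. Classes are a pure function of the score and the cut points:
#' changing cut points reclassifies without recomputing scores.
#'
#' @param fmc_map An [aggregate_walkability()] result.
#' @param cutpoints Decreasing cut points, default `c(45, 30, 15)`.
#' @return `fmc_map` with a `service_class` column added to its `edges`
#'   (factor: frequently-used, often-used, occasionally-used, unsuitable).
#' @export
service_siting <- function(fmc_map, cutpoints = c(45, 30, 15)) {
  stopifnot(inherits(fmc_map, "fmc_walkability"))
  cp <- sort(cutpoints, decreasing = TRUE)
  stopifnot(length(cp) == 3L)
  labs <- c("frequently-used", "often-used", "occasionally-used",
            "unsuitable")
  W <- fmc_map$edges$W
  cls <- vapply(W, function(w) {
    if (is.na(w) || w < cp[3L]) return(labs[4L])
    labs[1L + sum(cp > w + 1e-9)]
  }, character(1))
  fmc_map$edges$service_class <- factor(cls, levels = labs)
  fmc_map
}

#' Write a city-wide walkability map to GeoJSON
#'
#' @param fmc_map An [aggregate_walkability()] (optionally
#'   [service_siting()]-classified) result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_fmc_map <- function(fmc_map, path) {
  stopifnot(inherits(fmc_map, "fmc_walkability"))
  gj <- map_feature_collection(fmc_map$edges, fmc_map$graph,
                               list(H = fmc_map$H))
  jsonlite::write_json(gj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = FALSE)
  invisible(path)
}

#' Read a populations CSV
#'
#' Expects columns `neighborhood_id` and `population`.
#'
#' @param path CSV path.
#' @return A [population_weights()] table.
#' @export
read_populations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("neighborhood_id", "population") %in% names(df))) {
    stop("populations CSV needs columns neighborhood_id, population",
         call. = FALSE)
  }
  population_weights(df$population, ids = df$neighborhood_id)
}
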