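# Independent brute-force oracles. These re-derive the model arithmetic
# from first principles (breakpoint counting, explicit rounding, plain
# sums) and enumerate simple paths exhaustively; they share no code with
# the package internals they check.

oracle_level <- function(utci, bp = c(26, 32, 38, 46)) {
  vapply(utci, function(u) sum(u >= bp), numeric(1))
}

oracle_duration <- function(len, speed = 1, q = 0.1) {
  vapply(len, function(l) ceiling(l / speed / 60 / q - 1e-9) * q, numeric(1))
}

# straight-line re-implementation of the dose model on a segment table
oracle_trajectory <- function(seg, H = 60, speed = 1, q = 0.1) {
  lvl <- oracle_level(seg$utci_max)
  dur <- oracle_duration(seg$length_m, speed, q)
  s <- cumsum(lvl * dur)
  list(level = lvl, duration = dur, s_t = s, r_t = H - s)
}

oracle_edge_stress <- function(graph, H = 60, speed = 1, q = 0.1) {
  oracle_level(graph$edges$utci_max) *
    oracle_duration(graph$edges$length_m, speed, q)
}

# all simple paths origin -> dest with total length <= budget; returns the
# best (min stress, then min distance, then lexicographic node order)
oracle_best_route <- function(graph, origin, dest, budget_m,
                              H = 60, speed = 1, q = 0.1) {
  es <- oracle_edge_stress(graph, H, speed, q)
  e <- graph$edges
  nbr <- function(v) {
    i <- which(e$from == v | e$to == v)
    data.frame(i = i, w = ifelse(e$from[i] == v, e$to[i], e$from[i]))
  }
  best <- NULL
  walk <- function(v, visited, s, d, path) {
    if (v == dest) {
      cand <- list(s = s, d = d, path = path)
      if (is.null(best) || s < best$s - 1e-9 ||
          (abs(s - best$s) <= 1e-9 &&
           (d < best$d - 1e-9 ||
            (abs(d - best$d) <= 1e-9 &&
             paste(path, collapse = "") < paste(best$path, collapse = ""))))) {
        best <<- cand
      }
      return(invisible())
    }
    nb <- nbr(v)
    for (k in seq_len(nrow(nb))) {
      w <- nb$w[k]
      if (w %in% visited) next
      nd <- d + e$length_m[nb$i[k]]
      if (nd > budget_m + 1e-9) next
      walk(w, c(visited, w), s + es[nb$i[k]], nd, c(path, w))
    }
  }
  walk(origin, origin, 0, 0, origin)
  best
}

# per-edge oracle: best terminal R_t over simple paths from origin ending
# by traversing each edge, within the budget
oracle_walkability <- function(graph, origin, budget_m,
                               H = 60, speed = 1, q = 0.1) {
  es <- oracle_edge_stress(graph, H, speed, q)
  e <- graph$edges
  best <- rep(NA_real_, nrow(e))
  walk <- function(v, visited, s, d, path_edges_idx) {
    if (length(path_edges_idx)) {
      last <- path_edges_idx[length(path_edges_idx)]
      r <- H - s
      if (is.na(best[last]) || r > best[last]) best[last] <<- r
    }
    i <- which(e$from == v | e$to == v)
    for (k in i) {
      w <- if (e$from[k] == v) e$to[k] else e$from[k]
      if (w %in% visited) next
      nd <- d + e$length_m[k]
      if (nd > budget_m + 1e-9) next
      walk(w, c(visited, w), s + es[k], nd, c(path_edges_idx, k))
    }
  }
  walk(origin, origin, 0, 0, integer(0))
  best
}

# closed-form Cronbach alpha written out long-hand
oracle_alpha <- function(m) {
  k <- ncol(m)
  item_var <- numeric(k)
  for (j in seq_len(k)) {
    x <- m[, j]
    item_var[j] <- sum((x - mean(x))^2) / (length(x) - 1)
  }
  tot <- rowSums(m)
  tot_var <- sum((tot - mean(tot))^2) / (length(tot) - 1)
  k / (k - 1) * (1 - sum(item_var) / tot_var)
}
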