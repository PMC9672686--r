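# Shared fixtures built in code.

# the published seven-segment neighborhood walk (sections ab..gh)
table4_segments <- function() {
  data.frame(
    segment_id = c("ab", "bc", "cd", "de", "ef", "fg", "gh"),
    utci_min = c(34, 38, 33, 38, 37, 33, 32),
    utci_max = c(36, 40, 34, 40, 40, 36, 36),
    length_m = c(71.1, 171.7, 44.8, 51.0, 292.0, 12.0, 257.3),
    stringsAsFactors = FALSE)
}

# the same walk as a chain street graph a--h
table4_chain_graph <- function() {
  seg <- table4_segments()
  ids <- letters[1:8]
  x <- c(0, cumsum(seg$length_m))
  nodes <- data.frame(node_id = ids, x = x, y = 0,
                      stringsAsFactors = FALSE)
  edges <- data.frame(edge_id = seg$segment_id,
                      from = ids[1:7], to = ids[2:8],
                      length_m = seg$length_m,
                      utci_min = seg$utci_min, utci_max = seg$utci_max,
                      stringsAsFactors = FALSE)
  street_graph(nodes, edges, entrances = "a")
}

# random connected street graph with <= n_max nodes and UTCI'd edges
random_street_graph <- function(n_max = 10, extra_edge_prob = 0.35) {
  n <- sample(4:n_max, 1L)
  ids <- letters[seq_len(n)]
  nodes <- data.frame(node_id = ids,
                      x = runif(n, 0, 1000), y = runif(n, 0, 1000),
                      stringsAsFactors = FALSE)
  # random spanning tree, then extra edges
  pairs <- cbind(2:n, vapply(2:n, function(i) sample.int(i - 1L, 1L),
                             integer(1)))
  all_pairs <- t(combn(n, 2L))
  in_tree <- paste(pmin(pairs[, 1], pairs[, 2]),
                   pmax(pairs[, 1], pairs[, 2]))
  rest <- all_pairs[!paste(all_pairs[, 1], all_pairs[, 2]) %in% in_tree, ,
                    drop = FALSE]
  if (nrow(rest)) {
    take <- runif(nrow(rest)) < extra_edge_prob
    pairs <- rbind(pairs, rest[take, , drop = FALSE])
  }
  umin <- runif(nrow(pairs), 28, 42)
  edges <- data.frame(edge_id = sprintf("e%02d", seq_len(nrow(pairs))),
                      from = ids[pairs[, 1]], to = ids[pairs[, 2]],
                      length_m = runif(nrow(pairs), 50, 300),
                      utci_min = umin,
                      utci_max = umin + runif(nrow(pairs), 0, 3),
                      stringsAsFactors = FALSE)
  street_graph(nodes, edges)
}

# random loose segment table for trajectory fuzzing
random_segments <- function(n) {
  umin <- runif(n, 15, 45)
  data.frame(segment_id = sprintf("s%d", seq_len(n)),
             utci_min = umin, utci_max = umin + runif(n, 0, 5),
             length_m = runif(n, 0, 400), stringsAsFactors = FALSE)
}
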