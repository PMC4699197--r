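# Independent brute-force oracle for the minimum-weight path: enumerates
# every column-monotone path and applies the same deterministic
# tie-breaking (cost, then total row sum, then lexicographically smallest
# row sequence).  Tractable only for tiny instances, which is the point.

enumerate_paths <- function(min_row, max_row, max_step) {
  ncols <- length(min_row)
  paths <- matrix(seq.int(min_row[1], max_row[1]), ncol = 1)
  for (x in seq_len(ncols - 1L)) {
    grown <- list()
    for (i in seq_len(nrow(paths))) {
      r <- paths[i, x]
      nxt <- seq.int(max(min_row[x + 1], r - max_step),
                     min(max_row[x + 1], r + max_step))
      nxt <- nxt[nxt >= min_row[x + 1] & nxt <= max_row[x + 1]]
      if (length(nxt) == 0) next
      grown[[length(grown) + 1L]] <-
        cbind(matrix(paths[i, ], length(nxt), x, byrow = TRUE), nxt)
    }
    if (length(grown) == 0) return(NULL)
    paths <- do.call(rbind, grown)
  }
  paths
}

path_cost <- function(path, g, w_min) {
  if (length(path) < 2) return(0)
  x <- seq_len(length(path) - 1L)
  sum(2 - g[cbind(path[x], x)] - g[cbind(path[x + 1L], x + 1L)] + w_min)
}

brute_force_path <- function(g, min_row, max_row, max_step, w_min = 1e-5) {
  paths <- enumerate_paths(min_row, max_row, max_step)
  if (is.null(paths)) stop("no feasible path")
  costs <- apply(paths, 1L, path_cost, g = g, w_min = w_min)
  rowsums <- rowSums(paths)
  ord <- do.call(order, c(list(costs, rowsums),
                          lapply(seq_len(ncol(paths)), function(j) paths[, j])))
  list(path = paths[ord[1], ], cost = costs[ord[1]])
}
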