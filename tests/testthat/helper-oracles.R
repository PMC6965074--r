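# Independent brute-force oracles and shared fixtures for the test suite.
# The oracles deliberately use naive algorithms (path tracing, relaxation,
# exhaustive enumeration) so they share no code path with the kernels they
# check.

DR8 <- c(0, -1, -1, -1, 0, 1, 1, 1)     # E NE N NW W SW S SE
DC8 <- c(1, 1, 0, -1, -1, -1, 0, 1)
DIST8 <- c(1, sqrt(2), 1, sqrt(2), 1, sqrt(2), 1, sqrt(2))

# count of valid non-border cells with no strictly lower valid neighbour
undrained_count <- function(z) {
  nr <- nrow(z); nc <- ncol(z); n <- 0L
  for (r in 2:(nr - 1)) for (c in 2:(nc - 1)) {
    if (is.na(z[r, c])) next
    nb <- c(z[r - 1, (c - 1):(c + 1)], z[r, c - 1], z[r, c + 1],
            z[r + 1, (c - 1):(c + 1)])
    if (any(is.na(nb))) next        # nodata-adjacent cells count as border
    if (!any(nb < z[r, c])) n <- n + 1L
  }
  n
}

# D8 accumulation by tracing the pointer path from every cell and counting
# visits (O(n^2)); independent of the topological-order kernel
acc_path_oracle <- function(ptr) {
  nr <- nrow(ptr); nc <- ncol(ptr)
  acc <- matrix(0, nr, nc)
  for (r0 in 1:nr) for (c0 in 1:nc) {
    if (is.na(ptr[r0, c0])) { acc[r0, c0] <- NA; next }
    r <- r0; c <- c0
    repeat {
      acc[r, c] <- acc[r, c] + 1
      k <- ptr[r, c]
      if (is.na(k) || k == 0) break
      r <- r + DR8[k]; c <- c + DC8[k]
    }
  }
  acc
}

# least-cost DTW by repeated relaxation until a fixed point (Bellman-Ford
# style); exact for the non-negative step costs used here
dtw_relax_oracle <- function(slope, src, cell_size) {
  nr <- nrow(slope); nc <- ncol(slope)
  d <- matrix(Inf, nr, nc)
  d[src] <- 0
  repeat {
    changed <- FALSE
    for (r in 1:nr) for (c in 1:nc) {
      if (!is.finite(d[r, c])) next
      for (k in 1:8) {
        r2 <- r + DR8[k]; c2 <- c + DC8[k]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        if (is.na(slope[r2, c2])) next
        nd <- d[r, c] + slope[r2, c2] * DIST8[k] * cell_size
        if (nd < d[r2, c2] - 1e-15) { d[r2, c2] <- nd; changed <- TRUE }
      }
    }
    if (!changed) break
  }
  d[is.na(slope)] <- NA
  d
}

# exhaustive enumeration of all simple paths from every cell to any source,
# summing the entered-cell costs; feasible only on tiny grids
dtw_enumerate_oracle <- function(slope, src, cell_size) {
  nr <- nrow(slope); nc <- ncol(slope)
  best <- matrix(Inf, nr, nc)
  best[src] <- 0
  # depth-first over simple paths starting at each non-source cell,
  # branch-and-bound pruned (prunes only paths that cannot win).  Walking
  # from the cell to water, each step costs the slope of the cell being
  # left: the cell itself is charged, the water cell never is — the same
  # cost model as the outward expansion it checks, reached by an
  # independent route.
  for (r0 in 1:nr) for (c0 in 1:nc) {
    if (src[r0, c0]) next
    visited <- matrix(FALSE, nr, nc)
    rec <- function(r, c, cost) {
      if (cost >= best[r0, c0]) return()
      visited[r, c] <<- TRUE
      for (k in 1:8) {
        r2 <- r + DR8[k]; c2 <- c + DC8[k]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        if (visited[r2, c2]) next
        step <- slope[r, c] * DIST8[k] * cell_size
        if (src[r2, c2]) {
          if (cost + step < best[r0, c0]) best[r0, c0] <<- cost + step
        } else {
          rec(r2, c2, cost + step)
        }
      }
      visited[r, c] <<- FALSE
    }
    rec(r0, c0, 0)
  }
  best
}

# D8 steepest-descent code for one cell by literal comparison of 8 drops
d8_brute_cell <- function(z, r, c) {
  best <- 0; code <- NA_integer_
  for (k in 1:8) {
    r2 <- r + DR8[k]; c2 <- c + DC8[k]
    if (r2 < 1 || r2 > nrow(z) || c2 < 1 || c2 > ncol(z)) next
    g <- (z[r, c] - z[r2, c2]) / DIST8[k]
    if (g > best) { best <- g; code <- k }
  }
  code
}

# confusion matrix from per-class accuracies at given prevalence (counts
# scaled to N), rows observed dry/wet, cols predicted dry/wet
confusion_from_accuracies <- function(acc_wet, acc_dry, prev_wet, N = 1e6) {
  n_wet <- N * prev_wet; n_dry <- N - n_wet
  m <- matrix(c(n_dry * acc_dry, n_dry * (1 - acc_dry),
                n_wet * (1 - acc_wet), n_wet * acc_wet),
              2, 2, byrow = TRUE,
              dimnames = list(observed = c("dry", "wet"),
                              predicted = c("dry", "wet")))
  m
}

# ---- cached heavy fixtures (built once per test session) -------------------

.demo_cache <- new.env(parent = emptyenv())

demo_run <- function() {
  if (is.null(.demo_cache$run)) {
    dem <- demo_landscape(42)
    cfg <- pipeline_config(dem, NULL, learners = "random_forest", seed = 7)
    layers <- compute_index_stack(dem, NULL, cfg)
    cfg$plots <- make_plots(plot_spec(5000, seed = 11), layers$DTW_0_5)
    .demo_cache$run <- suppressMessages(run_pipeline(cfg))
  }
  .demo_cache$run
}

# a small conditioned valley grid reused by several flow tests
valley_fixture <- function(n = 41) {
  dem <- make_dem(fixture_spec("v_valley", n, n, cell_size = 2))
  cond <- condition_dem(dem)
  list(dem = dem, cond = cond, ptr = d8_pointer(cond),
       acc = d8_accumulation(d8_pointer(cond), units = "cells"))
}
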