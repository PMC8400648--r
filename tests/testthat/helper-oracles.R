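# Independent oracles used across the suite.  These deliberately avoid the
# package's own code paths: plain formulas, exhaustive enumeration, or
# brute-force loops at small n.

# Exhaustive knot-grid hinge fit: weighted least squares of the continuous
# two-segment model evaluated at every knot on a fixed-resolution grid.
# O(knots x n) via lm.wfit per knot -- slow but unambiguous.
brute_force_hinge <- function(x, y, w = rep(1, length(x)), step = 0.1,
                              min_points_per_side = 3) {
  o <- order(x)
  x <- x[o]; y <- y[o]; w <- w[o]
  n <- length(x)
  lo <- x[min_points_per_side]
  hi <- x[n - min_points_per_side + 1]
  knots <- seq(lo + step, hi - step, by = step)
  sse <- vapply(knots, function(t) {
    X <- cbind(1, pmin(x - t, 0), pmax(x - t, 0))
    f <- stats::lm.wfit(X, y, w)
    sum(w * f$residuals^2)
  }, numeric(1))
  best <- which.min(sse)        # which.min takes the first (lowest-x) tie
  list(breakpoint = knots[best], sse = sse[best])
}

# Brute-force hydrogen-bond contact count: double loop over donor and
# acceptor atoms, minimum image by explicit shifts, intramolecular excluded.
brute_force_hbonds <- function(coords, box, mol_id, donor, acceptor, cutoff) {
  don <- which(donor)
  acc <- which(acceptor)
  count <- 0L
  for (i in don) {
    for (j in acc) {
      if (mol_id[i] == mol_id[j]) next
      d <- coords[i, ] - coords[j, ]
      d <- d - round(d / box) * box
      if (sqrt(sum(d^2)) <= cutoff) count <- count + 1L
    }
  }
  count
}

# Single-species topology for point-particle test systems.
point_topology <- function(n, name = "tracer") {
  topology(seq_len(n), rep("P", n), mass = rep(1, n),
           molecule_id = seq_len(n), molecule_name = rep(name, n))
}

# Trajectory with one particle following a prescribed path (n_frames x 3).
path_trajectory <- function(path, box = 100, dt = 1, wrapped = FALSE) {
  nf <- nrow(path)
  co <- array(0, c(nf, 1, 3))
  co[, 1, ] <- path
  trajectory(co, box = rep(box, 3), times = (seq_len(nf) - 1) * dt,
             topology = point_topology(1), wrapped = wrapped)
}
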