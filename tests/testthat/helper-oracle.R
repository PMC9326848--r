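# Independent naive implementations used as oracles. Deliberately written
# with different algorithms than the package: double loops in R, and the
# isotropic edge weight computed by intersecting angle intervals on the
# circle rather than a closed-form corner formula.

# Arc (as a set of [lo, hi] intervals in [0, 2*pi]) where sin/cos constraints
# hold; all wrap-around arcs are split at 0/2*pi.
oracle_circle_fraction <- function(x, y, d, window) {
  clamp <- function(v) pmin(1, pmax(-1, v))
  two_pi <- 2 * pi
  # each constraint yields an allowed set of arcs
  arcs_cos_le <- function(c) { # cos(theta) <= c
    b <- acos(clamp(c))
    if (c >= 1) list(c(0, two_pi)) else list(c(b, two_pi - b))
  }
  arcs_cos_ge <- function(c) { # cos(theta) >= c
    b <- acos(clamp(c))
    if (c <= -1) list(c(0, two_pi)) else list(c(0, b), c(two_pi - b, two_pi))
  }
  arcs_sin_le <- function(c) { # sin(theta) <= c
    a <- asin(clamp(c))
    if (c >= 1) list(c(0, two_pi)) else list(c(pi - a, two_pi + a))
  }
  arcs_sin_ge <- function(c) { # sin(theta) >= c
    a <- asin(clamp(c))
    if (c <= -1) list(c(0, two_pi)) else list(c(a, pi - a))
  }
  normalize <- function(arcs) {
    out <- list()
    for (iv in arcs) {
      lo <- iv[1] %% two_pi
      hi <- lo + (iv[2] - iv[1])
      if (hi <= two_pi + 1e-15) {
        out <- c(out, list(c(lo, min(hi, two_pi))))
      } else {
        out <- c(out, list(c(lo, two_pi), c(0, hi - two_pi)))
      }
    }
    out
  }
  intersect_arcs <- function(a, b) {
    out <- list()
    for (i in a) for (j in b) {
      lo <- max(i[1], j[1]); hi <- min(i[2], j[2])
      if (hi > lo) out <- c(out, list(c(lo, hi)))
    }
    out
  }
  allowed <- list(c(0, two_pi))
  constraints <- list(
    normalize(arcs_cos_le((window[2] - x) / d)),  # x + d cos <= x_max
    normalize(arcs_cos_ge((window[1] - x) / d)),  # x + d cos >= x_min
    normalize(arcs_sin_le((window[4] - y) / d)),  # y + d sin <= y_max
    normalize(arcs_sin_ge((window[3] - y) / d))   # y + d sin >= y_min
  )
  for (cons in constraints) allowed <- intersect_arcs(allowed, cons)
  sum(vapply(allowed, function(iv) iv[2] - iv[1], numeric(1))) / two_pi
}

oracle_kcross <- function(xi, yi, xj, yj, radii, window, correction,
                          self = FALSE) {
  area <- (window[2] - window[1]) * (window[4] - window[3])
  n_i <- length(xi); n_j <- length(xj)
  denom <- if (self) n_i * (n_i - 1) else n_i * n_j
  vapply(radii, function(r) {
    tot <- 0
    for (a in seq_len(n_i)) {
      for (b in seq_len(n_j)) {
        if (self && a == b) next
        dx <- xj[b] - xi[a]; dy <- yj[b] - yi[a]
        d <- sqrt(dx^2 + dy^2)
        if (d > r) next
        w <- switch(correction,
          none = 1,
          translation = area /
            ((window[2] - window[1] - abs(dx)) *
               (window[4] - window[3] - abs(dy))),
          isotropic = if (d == 0) 1 else {
            1 / oracle_circle_fraction(xi[a], yi[a], d, window)
          }
        )
        tot <- tot + w
      }
    }
    area * tot / denom
  }, numeric(1))
}

# exhaustive pairwise AUC oracle
oracle_auc <- function(null_p, diff_p) {
  tot <- 0
  for (d in diff_p) for (n in null_p) {
    tot <- tot + (d < n) + 0.5 * (d == n)
  }
  tot / (length(null_p) * length(diff_p))
}

# uniform pattern in a window
csr_points <- function(n, window) {
  data.frame(x = runif(n, window[1], window[2]),
             y = runif(n, window[3], window[4]))
}

# small labelled two-type pattern for unit tests
random_two_type <- function(n_a, n_b, window, seed) {
  set.seed(seed)
  data.frame(
    x = runif(n_a + n_b, window[1], window[2]),
    y = runif(n_a + n_b, window[3], window[4]),
    cell_type = rep(c("A", "B"), c(n_a, n_b))
  )
}
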