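# Independent brute-force oracles used across test files. These deliberately
# share no code with the implementation paths they check.

# Exhaustive box count: loop over every box of the grid (strict rule: boxes
# fully inside only) and test each for foreground.
brute_box_count <- function(cells, e, or, oc) {
  nr <- nrow(cells)
  nc <- ncol(cells)
  n <- 0L
  r0 <- or + 1L
  while (r0 + e - 1L <= nr) {
    c0 <- oc + 1L
    while (c0 + e - 1L <= nc) {
      if (any(cells[r0:(r0 + e - 1L), c0:(c0 + e - 1L)] == 1L)) n <- n + 1L
      c0 <- c0 + e
    }
    r0 <- r0 + e
  }
  n
}

# Exhaustive 8-neighbour TRI.
brute_tri <- function(z) {
  nr <- nrow(z)
  nc <- ncol(z)
  vals <- c()
  for (i in 2:(nr - 1)) for (j in 2:(nc - 1)) {
    nb <- c(z[i - 1, j - 1], z[i - 1, j], z[i - 1, j + 1],
            z[i, j - 1], z[i, j + 1],
            z[i + 1, j - 1], z[i + 1, j], z[i + 1, j + 1])
    vals <- c(vals, sqrt(mean((z[i, j] - nb)^2)))
  }
  mean(vals)
}

# Pooled increment-variance Hurst estimate between row lags l1 < l2.
increment_hurst <- function(gen, n_seeds, l1 = 2L, l2 = 8L) {
  v <- vapply(seq_len(n_seeds), function(s) {
    z <- gen(s)
    n <- nrow(z)
    c(stats::var(as.vector(z[-(1:l1), ] - z[-((n - l1 + 1):n), ])),
      stats::var(as.vector(z[-(1:l2), ] - z[-((n - l2 + 1):n), ])))
  }, numeric(2))
  log(mean(v[2, ]) / mean(v[1, ])) / (2 * log(l2 / l1))
}

# Radially averaged log-periodogram slope with a Hann window (the window
# suppresses leakage from the non-periodic crop).
radial_spectrum_slope <- function(hm) {
  z <- hm$heights
  n <- nrow(z)
  w <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
  p <- Mod(stats::fft(z * outer(w, w)))^2
  f <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1)) / n
  fr <- sqrt(outer(f^2, f^2, "+"))
  sel <- fr > 4 / n & fr < 0.25
  b <- cut(log(fr[sel]), 20)
  lp <- tapply(log(p[sel]), b, mean)
  lf <- tapply(log(fr[sel]), b, mean)
  unname(stats::coef(stats::lm(lp ~ lf))[2])
}

# Quick simulated surfaces for fixtures.
mpd_map <- function(H, level, seed) {
  midpoint_displacement(sim_params(H, level, seed = seed))
}
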