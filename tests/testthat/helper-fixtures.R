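# Shared fixture builders used across test files.

# a flat-topped spectrum with known values at and around the 476 nm readout
spec_from_values <- function(wavelengths, intensities) {
  emission_spectrum(wavelengths, intensities, excitation = 425)
}

# a treatment series whose 476 nm readouts are exactly (f0, fdm, fsds)
series_from_readouts <- function(f0, fdm, fsds, ad = 1, id = "s") {
  grid <- c(470, 476, 482)
  mk <- function(v) emission_spectrum(grid, rep(v, 3))
  treatment_series(mk(f0), mk(fdm), mk(fsds), acceptor_donor_ratio = ad,
                   sample_id = id)
}

# noiseless efficiency points on a hyperbola
hyperbola_points <- function(emax, ec50, x = c(0.25, 0.5, 1, 2, 4, 8)) {
  data.frame(acceptor_donor_ratio = x, efficiency = emax * x / (ec50 + x))
}

# brute-force residual oracle for the specificity F test: 1-D and 2-D
# grid/refine minimization of the residual sum of squares, independent of
# the Levenberg-Marquardt fitting path
brute_force_specificity_f <- function(x, y, ceiling_emax) {
  sse_full <- function(p) sum((y - p[1] * x / (p[2] + x))^2)
  sse_null <- function(ec50) sum((y - ceiling_emax * x / (ec50 + x))^2)
  ec50_grid <- exp(seq(log(1e-4), log(1e4), length.out = 400))
  emax_grid <- seq(0, 1, length.out = 201)
  # full model: coarse grid then Nelder-Mead polish
  grid_ss <- outer(emax_grid, ec50_grid,
                   Vectorize(function(a, b) sse_full(c(a, b))))
  i <- which(grid_ss == min(grid_ss), arr.ind = TRUE)[1, ]
  opt <- stats::optim(c(emax_grid[i[1]], ec50_grid[i[2]]), sse_full,
                      method = "L-BFGS-B", lower = c(0, 1e-9), upper = c(1, Inf))
  ss1 <- opt$value
  # null model: 1-D golden-section over each bracket of the grid minimum
  j <- which.min(vapply(ec50_grid, sse_null, numeric(1)))
  lo <- ec50_grid[max(j - 1, 1)]; hi <- ec50_grid[min(j + 1, length(ec50_grid))]
  ss0 <- stats::optimize(sse_null, c(lo, hi))$objective
  n <- length(x)
  list(f = ((ss0 - ss1) / 1) / (ss1 / (n - 2)), ss0 = ss0, ss1 = ss1)
}

# binary matrix with disjoint square "particles" of given edge lengths at
# deterministic positions (10 px spacing grid)
square_particle_grid <- function(edges, size = 64, spacing = 12) {
  m <- matrix(FALSE, size, size)
  per_row <- floor((size - spacing) / spacing)
  for (i in seq_along(edges)) {
    r0 <- 2 + spacing * ((i - 1) %/% per_row)
    c0 <- 2 + spacing * ((i - 1) %% per_row)
    e <- edges[i]
    m[r0:(r0 + e - 1), c0:(c0 + e - 1)] <- TRUE
  }
  m
}
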