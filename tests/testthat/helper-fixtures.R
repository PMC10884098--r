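# Small builders shared across test files.

toy_counts <- function() {
  m <- matrix(c(0L, 1L, 5L,
                2L, 0L, 0L,
                1L, 1L, 1L), nrow = 3, byrow = TRUE,
              dimnames = list(c("gA", "gB", "gC"), paste0("c", 1:3)))
  count_matrix(m)
}

# straight-line tracks under a constant (vx, vy) um/h field
constant_tracks <- function(v = c(60, 0), n_cells = 4, n_frames = 5,
                            dt_min = 10, noise_sd = 0, origin_spread = 200,
                            group = "SC", seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  do.call(rbind, lapply(seq_len(n_cells), function(i) {
    start <- rnorm(2, 0, origin_spread)
    f <- seq_len(n_frames) - 1L
    x <- start[1] + v[1] * f * dt_min / 60
    y <- start[2] + v[2] * f * dt_min / 60
    if (noise_sd > 0) {
      x <- x + rnorm(n_frames, 0, noise_sd)
      y <- y + rnorm(n_frames, 0, noise_sd)
    }
    data.frame(cell_id = sprintf("%s_%03d", group, i), group = group,
               frame = f, t_min = f * dt_min, x_um = x, y_um = y,
               stringsAsFactors = FALSE)
  }))
}

# brute-force grid averaging oracle: direct loop over cells per grid point
brute_force_field <- function(vel, grid, radius) {
  out <- t(apply(grid, 1L, function(gp) {
    acc <- c(0, 0); n <- 0L
    for (i in seq_len(nrow(vel))) {
      if (is.na(vel$vx[i]) || is.na(vel$x_um[i])) next
      if ((vel$x_um[i] - gp[1])^2 + (vel$y_um[i] - gp[2])^2 <= radius^2) {
        acc <- acc + c(vel$vx[i], vel$vy[i]); n <- n + 1L
      }
    }
    if (n == 0L) c(NA, NA, 0) else c(acc / n, n)
  }))
  dimnames(out) <- NULL
  out
}

# brute-force through-origin least squares by golden-section-free grid
# refinement of the SSE over the slope
brute_force_slope <- function(x, y, lo = -10, hi = 10, iters = 60) {
  sse <- function(b) sum((y - b * x)^2)
  for (it in seq_len(iters)) {
    bs <- seq(lo, hi, length.out = 201)
    errs <- vapply(bs, sse, numeric(1))
    i <- which.min(errs)
    lo <- bs[max(1L, i - 1L)]; hi <- bs[min(length(bs), i + 1L)]
  }
  (lo + hi) / 2
}

# closed-form marginal detection probability under the capture model:
# p * E_d[1 - exp(-d * m)] with d log-normal(0, sigma)
expected_detection <- function(p, m, sigma) {
  if (sigma == 0) return(p * (1 - exp(-m)))
  f <- function(d) (1 - exp(-d * m)) * stats::dlnorm(d, 0, sigma)
  p * stats::integrate(f, 0, Inf, rel.tol = 1e-10)$value
}
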