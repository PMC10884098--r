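test_that("parameter validation rejects degenerate simulator inputs", {
  expect_error(sc_sim_params(10, character(0), 0.5), "non-empty")
  expect_error(sc_sim_params(10, "g1", 1.5), "\\[0, 1\\]")
  expect_error(sc_sim_params(10, "g1", 0.5, mean_capture = 0), "positive")
  expect_error(field_spec(n_frames = 2), "three consecutive frames")
  expect_error(field_spec(frame_interval_min = 0), "positive")
  code <- matrix("weird", 1, 1, dimnames = list("s", "g"))
  expect_error(bulk_sim_params(code), "unknown tier")
})

test_that("impossible and saturated expression give all-zero / all-detected matrices", {
  genes <- paste0("g", 1:3)
  off <- simulate_sc_counts(sc_sim_params(200, genes, 0, seed = 1))
  expect_true(all(off$counts == 0))
  sat <- simulate_sc_counts(sc_sim_params(
    200, genes, 1, mean_capture = 1e4, depth_sigma = 0, seed = 1))
  expect_true(all(sat$counts >= 1))
})

test_that("empirical detection fraction matches the closed-form capture expectation", {
  n <- 50000
  sim <- simulate_sc_counts(sc_sim_params(
    n, "g1", expr_prob = 0.5, mean_capture = 2, depth_sigma = 0, seed = 1))
  f_hat <- mean(sim$counts >= 1)
  f_true <- expected_detection(0.5, 2, 0)      # 0.5 * (1 - exp(-2)) = 0.43233
  expect_equal(f_true, 0.4323324, tolerance = 1e-6)
  se <- sqrt(f_true * (1 - f_true) / n)
  expect_lt(abs(f_hat - f_true), 3 * se)
})

test_that("detection under heterogeneous depth matches the numeric-integration oracle", {
  n <- 50000
  for (prm in list(c(p = 0.3, m = 1.5), c(p = 0.6, m = 0.8))) {
    sim <- simulate_sc_counts(sc_sim_params(
      n, "g1", prm[["p"]], mean_capture = prm[["m"]],
      depth_sigma = 0.8, seed = 7))
    f_hat <- mean(sim$counts >= 1)
    f_true <- expected_detection(prm[["p"]], prm[["m"]], 0.8)
    se <- sqrt(f_true * (1 - f_true) / n)
    expect_lt(abs(f_hat - f_true), 3 * se)
  }
})

test_that("constant-depth detection events of two genes are independent; shared depth associates them", {
  n <- 30000
  base <- function(sigma, seed)
    simulate_sc_counts(sc_sim_params(n, c("a", "b"), c(0.4, 0.4),
                                     depth_sigma = sigma, seed = seed))
  det <- detect(base(0, 3))
  gap0 <- mean(det["a", ] & det["b", ]) - mean(det["a", ]) * mean(det["b", ])
  expect_lt(abs(gap0), 3 / sqrt(n))           # ~n^(-1/2) shrinkage
  det8 <- detect(base(0.8, 3))
  gap8 <- mean(det8["a", ] & det8["b", ]) - mean(det8["a", ]) * mean(det8["b", ])
  expect_gt(gap8, 0)
})

test_that("same seed reproduces bit-identical simulator output", {
  pars <- function() sc_sim_params(100, paste0("g", 1:4), 0.3, seed = 11)
  expect_identical(simulate_sc_counts(pars()), simulate_sc_counts(pars()))
  sp <- function() field_spec(noise_sd = 4, seed = 11)
  expect_identical(simulate_tracks(sp()), simulate_tracks(sp()))
  code <- nsc_line_code()
  bp <- function() bulk_sim_params(code, noise_sd = 0.1, seed = 11)
  expect_identical(simulate_bulk_profiles(bp()),
                   simulate_bulk_profiles(bp()))
})

test_that("noise-free tracks displace exactly velocity x frame interval", {
  sp <- field_spec(groups = list(
    g = list(velocity = c(60, 0), n_cells = 3,
             origin = list(center = c(0, 0), spread = 50))),
    frame_interval_min = 10, n_frames = 5, noise_sd = 0, seed = 2)
  tr <- simulate_tracks(sp)
  one <- tr[tr$cell_id == tr$cell_id[1], ]
  expect_equal(diff(one$x_um), rep(10, 4))     # 60 um/h * 1/6 h
  expect_equal(diff(one$y_um), rep(0, 4))
})

test_that("zero field with zero noise keeps every cell stationary", {
  sp <- field_spec(groups = list(
    g = list(velocity = c(0, 0), n_cells = 4,
             origin = list(center = c(100, -50), spread = 80))),
    noise_sd = 0, n_frames = 4, seed = 5)
  tr <- simulate_tracks(sp)
  spread <- tapply(tr$x_um, tr$cell_id, function(v) diff(range(v)))
  expect_true(all(spread == 0))
})

test_that("mean displacement under positional noise recovers the field within 3 SE", {
  n <- 10000
  sp <- field_spec(groups = list(
    g = list(velocity = c(60, 0), n_cells = n,
             origin = list(center = c(0, 0), spread = 100))),
    frame_interval_min = 10, n_frames = 3, noise_sd = 5, seed = 9)
  tr <- simulate_tracks(sp)
  d <- tr[tr$frame == 1, c("x_um", "y_um")] - tr[tr$frame == 0, c("x_um", "y_um")]
  se <- 5 * sqrt(2) / sqrt(n)                  # displacement noise sd / sqrt(n)
  expect_lt(abs(mean(d$x_um) - 10), 3 * se)
  expect_lt(abs(mean(d$y_um) - 0), 3 * se)
})

test_that("bulk profiles reproduce tier means exactly without noise", {
  code <- matrix(c("off", "low", "high", "high"), nrow = 2, byrow = TRUE,
                 dimnames = list(c("s1", "s2"), c("gX", "gY")))
  tab <- simulate_bulk_profiles(bulk_sim_params(
    code, tier_means = c(off = 0, low = 0.2, high = 1), noise_sd = 0))
  expect_equal(unname(tab["gX", c("s1_1", "s1_2")]), c(0, 0))
  expect_equal(unname(tab["gY", c("s1_1", "s2_2")]), c(0.2, 1))
})

test_that("the bundled line code carries the published Hoxc9/Hoxc10 distinction", {
  tab <- simulate_bulk_profiles(bulk_sim_params(nsc_line_code(), noise_sd = 0))
  expect_equal(unname(tab["Hoxc9", "CN4_1"]), 1)
  expect_equal(unname(tab["Hoxc10", "CN4_1"]), 0)
  expect_equal(unname(tab["Hoxa9", "KN1_1"]), 0)
})

test_that("replicate means converge to tier means under multiplicative noise", {
  genes <- paste0("g", seq_len(1000))
  code <- matrix("high", nrow = 1, ncol = length(genes),
                 dimnames = list("s1", genes))
  tab <- simulate_bulk_profiles(bulk_sim_params(
    code, replicates = 2, noise_sd = 0.1, seed = 3))
  means <- rowMeans(tab)
  # multiplicative log-normal noise is mean-unbiased; average over
  # 2 replicates x 1000 genes should sit within ~3 SE of the tier mean
  expect_lt(abs(mean(means) - 1), 3 * 0.1 / sqrt(2 * length(genes)))
  expect_lt(max(abs(means - 1)), 1 * 0.5)      # no wild per-gene outliers
})
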