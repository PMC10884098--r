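test_that("detection thresholding behaves at the count boundary", {
  m <- matrix(0L, 2, 2, dimnames = list(c("a", "b"), c("c1", "c2")))
  expect_false(any(detect(m)))
  m["a", "c1"] <- 1L
  expect_true(detect(m, min_count = 1)["a", "c1"])
  expect_false(detect(m, min_count = 2)["a", "c1"])
  expect_error(detect(m, min_count = 0), ">= 1")
})

test_that("detection fractions match hand enumeration on the toy matrix", {
  f <- detection_fractions(detect(toy_counts()))
  expect_equal(as.vector(f), c(2 / 3, 1 / 3, 1))
  expect_equal(attr(f, "n_cells"), 3L)
  expect_error(detection_fractions(matrix(logical(0), 2, 0)), "no cells")
})

test_that("venn partition enumerates disjoint regions and sums to one", {
  det <- rbind(A = c(TRUE, TRUE, FALSE, FALSE),
               B = c(FALSE, TRUE, FALSE, TRUE))
  colnames(det) <- paste0("c", 1:4)
  vp <- venn_partition(det, c("A", "B"))
  expect_equal(vp$fractions[["A"]], 0.25)
  expect_equal(vp$fractions[["B"]], 0.25)
  expect_equal(vp$fractions[["A&B"]], 0.25)
  expect_equal(vp$fractions[["none"]], 0.25)
  # single gene detected in half the cells, partner never detected
  det2 <- rbind(A = c(TRUE, TRUE, FALSE, FALSE), B = rep(FALSE, 4))
  colnames(det2) <- paste0("c", 1:4)
  vp2 <- venn_partition(det2, c("A", "B"))
  expect_equal(vp2$fractions[["A"]], 0.5)
  expect_equal(vp2$fractions[["none"]], 0.5)
  expect_error(venn_partition(det, c("A", "missing")), "not in matrix")
})

test_that("venn fractions sum to 1 for random detection matrices (partition law)", {
  set.seed(42)
  for (k in c(2, 3)) {
    for (rep in 1:20) {
      det <- matrix(runif(k * 37) < runif(1), nrow = k,
                    dimnames = list(letters[1:k], paste0("c", 1:37)))
      vp <- venn_partition(det, letters[1:k])
      expect_lt(abs(sum(vp$fractions) - 1), 1e-12)
      expect_true(all(vp$fractions >= 0))
      expect_equal(sum(vp$counts), 37L)
    }
  }
})

test_that("independence prediction is the product of marginals", {
  prof <- c(a = 0.3, b = 0.2, c = 0.1, d = 0.05, e = 0.453)
  expect_equal(predicted_coexpression(prof, c("a", "b")), 0.06)
  expect_equal(predicted_coexpression(prof, c("a", "b")) * 0, 0)
  expect_equal(predicted_coexpression(prof, c("e", "c", "d")), 0.0022650)
  expect_error(predicted_coexpression(prof, c("a", "zz")), "not in profile")
})

test_that("through-origin fit reproduces hand-evaluated slope and R-squared", {
  perfect <- fit_through_origin(c(1, 2, 3), c(2, 4, 6))
  expect_equal(perfect$slope, 2)
  expect_equal(perfect$r.squared, 1)
  f <- fit_through_origin(c(1, 2), c(2, 3))
  expect_equal(f$slope, 8 / 5)
  expect_equal(f$r.squared, 1 - 0.2 / 13)
  ident <- fit_through_origin(c(0.1, 0.4, 0.7), c(0.1, 0.4, 0.7))
  expect_equal(ident$slope, 1)
  expect_equal(ident$r.squared, 1)
  expect_error(fit_through_origin(c(0, 0), c(1, 2)), "identically zero")
})

test_that("through-origin fit agrees with brute-force SSE search and lm(y ~ 0 + x)", {
  set.seed(7)
  for (rep in 1:10) {
    x <- runif(15, 0, 1)
    y <- 1.3 * x + rnorm(15, 0, 0.1)
    f <- fit_through_origin(x, y)
    expect_lt(abs(f$slope - brute_force_slope(x, y)), 1e-6)
    lmfit <- lm(y ~ 0 + x)
    expect_equal(f$slope, unname(coef(lmfit)), tolerance = 1e-12)
    expect_equal(f$r.squared, summary(lmfit)$r.squared, tolerance = 1e-12)
  }
})

test_that("observed and predicted coexpression are bounded by the marginals", {
  set.seed(8)
  sim <- simulate_sc_counts(sc_sim_params(
    3000, paste0("g", 1:6), runif(6, 0.05, 0.6), depth_sigma = 0.8, seed = 8))
  fit <- coexpr_independence(sim)
  marg_min <- pmin(fit$profile[fit$pairs$gene1], fit$profile[fit$pairs$gene2])
  expect_true(all(fit$pairs$predicted <= marg_min + 1e-12))
  expect_true(all(fit$pairs$observed <= marg_min + 1e-12))
  expect_true(all(fit$pairs$predicted >= 0))
})

test_that("coexpr_fit methods are mutually consistent", {
  sim <- simulate_sc_counts(sc_sim_params(
    2000, paste0("g", 1:5), seq(0.1, 0.5, 0.1), depth_sigma = 0, seed = 4))
  fit <- coexpr_independence(sim)
  expect_s3_class(fit, "coexpr_fit")
  expect_named(coef(fit), "slope")
  expect_equal(unname(predict(fit)), fit$pairs$predicted * coef(fit)[[1]])
  expect_equal(unname(residuals(fit)), fit$pairs$observed - predict(fit))
  newp <- data.frame(gene1 = "g1", gene2 = "g5")
  expect_equal(predict(fit, newp),
               coef(fit)[[1]] * fit$profile["g1"] * fit$profile["g5"],
               ignore_attr = TRUE)
  expect_output(print(fit), "through origin")
  expect_output(print(summary(fit)), "Detection fractions")
  # panels given as a list are de-duplicated into one pair set
  fit2 <- coexpr_independence(sim, genes = list(c("g1", "g2", "g3"),
                                                c("g2", "g3", "g4")))
  expect_equal(nrow(fit2$pairs), 5L)  # 3 + 3 pairs with g2:g3 shared
})

test_that("simulated null detection matrices recalibrate the slope near 1", {
  sim <- simulate_sc_counts(sc_sim_params(
    5000, paste0("g", 1:8), runif(8, 0.1, 0.5), depth_sigma = 0.8, seed = 5))
  fit <- coexpr_independence(sim)
  dets <- simulate(fit, nsim = 3, seed = 99)
  slopes <- vapply(dets, function(d) {
    p <- rowMeans(d)
    pairs <- t(combn(rownames(d), 2))
    obs <- apply(pairs, 1, function(g) mean(d[g[1], ] & d[g[2], ]))
    fit_through_origin(p[pairs[, 1]] * p[pairs[, 2]], obs)$slope
  }, numeric(1))
  expect_true(all(abs(slopes - 1) < 0.1))
})

test_that("depth stratification localises the inflation mechanism", {
  # constant depth: stratified slopes all near 1
  sim0 <- simulate_sc_counts(sc_sim_params(
    20000, paste0("g", 1:8), runif(8, 0.1, 0.5), depth_sigma = 0, seed = 6))
  # constant-depth strata are arbitrary splits of exchangeable cells
  di0 <- depth_inflation(count_matrix(sim0$counts, depth = rep(1, 20000)))
  expect_true(all(abs(di0$slopes - 1) < 0.1))
  # heterogeneous depth: pooled slope exceeds 1, per-pair top >= bottom
  set.seed(6)
  sim8 <- simulate_sc_counts(sc_sim_params(
    20000, paste0("g", 1:8), runif(8, 0.1, 0.5), depth_sigma = 0.8, seed = 6))
  di8 <- depth_inflation(sim8)
  expect_gt(di8$pooled_slope, 1.02)
  # conditioning on depth removes most of the inflation where the
  # within-stratum depth spread is small (the upper quartiles; the bottom
  # quartile of a log-normal keeps a wide relative spread)
  expect_true(all(abs(di8$slopes[-1] - 1) < (di8$pooled_slope - 1) / 2))
  expect_true(all(di8$top_ge_bottom))
  expect_error(depth_inflation(toy_counts(), strata = 10), "fewer cells")
})
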