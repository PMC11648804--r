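test_that("identical genotypes give a zero centered matrix", {
  m <- matrix(rep(c(4, 5, 6, 7), each = 5), 5, 4)
  rownames(m) <- paste0("G", 1:5); colnames(m) <- paste0("C", 1:4)
  fit <- suppressWarnings(gge(m))
  expect_equal(max(fit$singular_values), 0, tolerance = 1e-12)
})

test_that("variance proportions match the eigen oracle and sum to 100", {
  spec <- random_spec(10, 2, 3, 2, K = 2, seed = 51, noise_sd = 0,
                      rep_effect_sd = 0, trait = "Y")
  tab <- simulate_trial(spec)
  fit <- gge(tab, "Y")
  m <- cell_means(tab, "Y")
  Z <- sweep(unclass(m), 2, colMeans(m))
  lam <- oracle_singular_values(Z)
  expect_equal(fit$singular_values, lam[seq_len(fit$rmax)], tolerance = 1e-8)
  expect_equal(fit$var_prop,
               100 * lam[seq_len(fit$rmax)]^2 / sum(lam^2), tolerance = 1e-8)
  expect_equal(sum(fit$var_prop), 100, tolerance = 1e-8)
})

test_that("singular value partitioning splits scale between the score sets", {
  tab <- make_table(6, 2, 3, 2, seed = 53)
  fit <- gge(tab, "Y")
  for (svp in list("symmetric", "genotype", "environment", 0.3)) {
    gs <- scores(fit, "genotype", svp, K = 2)
    es <- scores(fit, "environment", svp, K = 2)
    # product of scores reconstructs the rank-2 part regardless of svp
    expect_equal(gs %*% t(es),
                 fit$u[, 1:2] %*% diag(fit$singular_values[1:2]) %*%
                   t(fit$v[, 1:2]),
                 ignore_attr = TRUE, tolerance = 1e-10)
  }
})

test_that("environment metrics match a direct trigonometric recomputation", {
  tab <- make_table(8, 2, 3, 3, seed = 57)
  fit <- gge(tab, "Y")
  em <- discriminativeness_representativeness(fit)
  es <- scores(fit, "environment", "environment", 2)
  aea <- colMeans(es) / sqrt(sum(colMeans(es)^2))
  for (i in seq_len(nrow(es))) {
    v <- es[i, ]
    expect_equal(em$vector_length[i], sqrt(sum(v^2)), tolerance = 1e-12)
    expect_equal(em$angle_to_AEA[i],
                 acos(sum(v * aea) / sqrt(sum(v^2))) * 180 / pi,
                 tolerance = 1e-10)
  }
  expect_true(all(em$angle_to_AEA >= 0 & em$angle_to_AEA <= 180))
  expect_true(all(em$type %in% c("I", "II", "III")))
  # type rules on synthetic coordinates
  lenr <- em$vector_length / max(em$vector_length)
  expect_equal(em$type[lenr < 0.5], rep("I", sum(lenr < 0.5)))
})

test_that("environment at the origin has zero length, NA angle, type I", {
  # hand-built decomposition: environment rows of v chosen so that one
  # environment sits exactly at the origin and two coincide at (2, 0)
  fit <- structure(list(
    model = "GGE", means = matrix(0, 4, 3, dimnames = list(
      paste0("G", 1:4), paste0("C", 1:3))),
    singular_values = c(1, 1), rmax = 2L, K = 2L,
    u = matrix(0, 4, 2), v = rbind(c(0, 0), c(2, 0), c(2, 0))),
    class = c("gge", "biplot_decomp"))
  em <- discriminativeness_representativeness(fit, svp = "environment")
  expect_equal(em$vector_length, c(0, 2, 2))
  expect_true(is.na(em$angle_to_AEA[1]))
  expect_equal(em$type[1], "I")
  # coincident environments lie exactly on the AEA: angle 0, long vectors
  expect_equal(em$angle_to_AEA[2:3], c(0, 0), tolerance = 1e-10)
  expect_equal(em$type[2:3], c("II", "II"))
})

test_that("mean vs stability: projection orders genotypes like their means", {
  # no interaction: ranking by AEA projection equals ranking by trait mean
  spec <- random_spec(8, 2, 3, 2, K = 0, seed = 61, noise_sd = 0,
                      rep_effect_sd = 0, trait = "Y")
  tab <- simulate_trial(spec)
  fit <- suppressWarnings(gge(tab, "Y"))
  ms <- mean_vs_stability(fit)
  m <- cell_means(tab, "Y")
  expect_equal(order(-ms$mean_projection), order(-rowMeans(m)))
  expect_equal(max(ms$stability_distance), 0, tolerance = 1e-8)

  # geometry: AEA = (1,0), genotype at (3,4) -> projection 3, distance 4
  aea <- c(1, 0)
  gsc <- c(3, 4)
  expect_equal(sum(gsc * aea), 3)
  expect_equal(abs(gsc[1] * aea[2] - gsc[2] * aea[1]), 4)

  # above-average flag agrees with the sign of mean - grand mean
  tab2 <- make_table(10, 2, 3, 2, seed = 63)
  fit2 <- gge(tab2, "Y")
  ms2 <- mean_vs_stability(fit2)
  above <- rowMeans(cell_means(tab2, "Y")) > mean(cell_means(tab2, "Y"))
  expect_gt(mean(ms2$above_average == above), 0.85)
})

test_that("symmetric triangle: the near-axis environment is won by (1,0)", {
  gs <- rbind(A = c(1, 0), B = c(-0.5, 0.866), C = c(-0.5, -0.866))
  es <- rbind(E1 = c(1, 0.1))
  w <- which_won_where(gs, env_scores = es)
  expect_equal(nrow(w$sectors), 3)
  expect_equal(w$environments$winner, "A")
})

test_that("sector winners equal the exhaustive projection oracle", {
  set.seed(202)
  agree <- 0; total <- 0
  for (i in 1:100) {
    g <- sample(5:12, 1); e <- sample(3:8, 1)
    gs <- matrix(rnorm(2 * g), g, 2, dimnames = list(paste0("G", 1:g), NULL))
    gs <- sweep(gs, 2, colMeans(gs))   # centered scores, origin interior
    es <- matrix(rnorm(2 * e), e, 2)
    w <- which_won_where(gs, env_scores = es)
    oracle <- rownames(gs)[apply(es %*% t(gs), 1, which.max)]
    agree <- agree + sum(w$environments$winner == oracle)
    total <- total + e
  }
  expect_gte(agree / total, 0.99)
})

test_that("sector membership is invariant under global rotation", {
  set.seed(77)
  gs <- matrix(rnorm(16), 8, 2); gs <- sweep(gs, 2, colMeans(gs))
  es <- matrix(rnorm(10), 5, 2)
  w0 <- which_won_where(gs, env_scores = es)
  for (theta in c(0.3, 1.2, 2.9, 4.5)) {
    R <- matrix(c(cos(theta), sin(theta), -sin(theta), cos(theta)), 2, 2)
    wr <- which_won_where(gs %*% R, env_scores = es %*% R)
    expect_equal(wr$environments$winner, w0$environments$winner,
                 info = paste("theta =", theta))
  }
})

test_that("collinear genotype scores raise a degenerate-hull error", {
  gs <- cbind(1:5, 2 * (1:5))
  expect_error(which_won_where(gs, env_scores = matrix(1, 2, 2)),
               "degenerate hull|collinear")
})

test_that("boundary environments go to the counter-clockwise sector", {
  # square of genotypes; boundary rays along the diagonals
  gs <- rbind(A = c(1, 1), B = c(-1, 1), C = c(-1, -1), D = c(1, -1))
  # edge normals point along +y (edge A-B), -x (B-C), -y (C-D), +x (D-A);
  # an environment exactly on the +y ray (boundary between sectors of A
  # and B) must belong to B, the counter-clockwise neighbour
  es <- rbind(Eb = c(0, 2))
  w <- which_won_where(gs, env_scores = es)
  expect_equal(w$environments$winner, "B")
})

test_that("mega-environments group sectors with more than one environment", {
  gs <- rbind(A = c(2, 0), B = c(-1, 1.8), C = c(-1, -1.8))
  es <- rbind(E1 = c(1, 0.2), E2 = c(1, -0.2), E3 = c(-0.6, 1))
  w <- which_won_where(gs, env_scores = es)
  me <- w$mega_environments
  expect_equal(me$vertex[me$mega], "A")
  expect_equal(me$environments[me$mega], "E1,E2")
})
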