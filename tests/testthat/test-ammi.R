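test_that("purely additive means give all-zero singular values", {
  spec <- random_spec(5, 2, 3, 2, K = 0, seed = 1, noise_sd = 0,
                      rep_effect_sd = 0, trait = "Y")
  fit <- ammi(simulate_trial(spec), "Y")
  expect_lt(max(fit$singular_values), 1e-10)
  # every genotype sits at the biplot origin (scores carry a sqrt(lambda)
  # factor, so numerically-zero components bound them at sqrt precision)
  expect_lt(max(abs(scores(fit, "genotype"))), 1e-5)
})

test_that("noise-free rank-1 structure recovers the planted singular value", {
  spec <- random_spec(24, 2, 3, 3, K = 1, seed = 8, noise_sd = 0,
                      rep_effect_sd = 0, gei_singular_values = 5,
                      grand_mean = 20, trait = "Y")
  fit <- ammi(simulate_trial(spec), "Y")
  planted <- spec$gei_genotype_scores %*% diag(5, 1) %*%
    t(spec$gei_environment_scores)
  lam_oracle <- oracle_singular_values(double_center(planted))
  expect_equal(fit$singular_values[1], lam_oracle[1], tolerance = 1e-8)
  expect_lt(max(fit$singular_values[-1]), 1e-8)
})

test_that("parameter recovery across 50 random noise-free specs", {
  for (i in 1:50) {
    g <- sample(4:10, 1); s <- sample(2:3, 1); cc <- sample(2:3, 1)
    K <- min(g - 1, s * cc - 1, 3)
    spec <- random_spec(g, s, cc, 2, K = K, seed = 5000 + i, noise_sd = 0,
                        rep_effect_sd = 0, grand_mean = 20,
                        gei_singular_values = c(4, 2.5, 1.2)[seq_len(K)],
                        trait = "Y")
    fit <- ammi(simulate_trial(spec), "Y")
    planted <- spec$gei_genotype_scores %*%
      diag(spec$gei_singular_values, K) %*% t(spec$gei_environment_scores)
    lam_oracle <- oracle_singular_values(double_center(planted))
    # leading (planted-rank) components match to 1e-8 relative; the rest of
    # both spectra are numerically zero
    expect_equal(fit$singular_values[1:K], lam_oracle[1:K],
                 tolerance = 1e-8)
    expect_lt(max(fit$singular_values[-(1:K)], 0), 1e-6)
    expect_lt(max(lam_oracle[-(1:K)], 0), 1e-6)
  }
})

test_that("reconstruction at K = max is exact and interaction SS is conserved", {
  tab <- make_table(6, 2, 3, 2, seed = 13)
  fit <- ammi(tab, "Y")
  expect_equal(fitted(fit, K = fit$rmax), unclass(fit$means),
               ignore_attr = TRUE, tolerance = 1e-10)
  expect_equal(sum(fit$singular_values^2), sum(fit$interaction^2),
               tolerance = 1e-10)
  expect_equal(sum(fit$var_prop), 100, tolerance = 1e-8)
  # residuals at full rank vanish
  expect_equal(max(abs(residuals(fit, K = fit$rmax))), 0, tolerance = 1e-10)
})

test_that("symmetric 3x3 interaction pattern splits variance 50/50", {
  D <- matrix(c(2, -1, -1, -1, 2, -1, -1, -1, 2), 3, 3) * 0.7
  m <- D + 5  # grand shift; double-centering recovers D
  expect_warning(fit <- ammi(m, K = "max"), "near-tied")
  expect_equal(fit$singular_values[1], fit$singular_values[2],
               tolerance = 1e-10)
  expect_equal(fit$var_prop[1:2], c(50, 50), tolerance = 1e-8)
})

test_that("ASV follows its closed form and flags degenerate spectra", {
  tab <- make_table(6, 2, 3, 2, seed = 17)
  fit <- ammi(tab, "Y")
  a <- asv(fit)
  w <- attr(a, "weight")
  expect_equal(w, fit$singular_values[1]^2 / fit$singular_values[2]^2)
  expect_equal(a$ASV, sqrt((w * a$IPCA1)^2 + a$IPCA2^2))
  expect_true(all(a$ASV >= 0))

  # closed-form checks: w = 1 with scores (3,4) -> 5; w = 2, (1,1) -> sqrt(5)
  expect_equal(sqrt((1 * 3)^2 + 4^2), 5)
  fake <- fit
  fake$singular_values[1:2] <- c(1, 1)  # w = 1
  fake$u[, 1] <- 0; fake$u[1, 1] <- 3
  fake$u[, 2] <- 0; fake$u[2, 2] <- 4
  av <- suppressWarnings(asv(fake))
  expect_equal(av$ASV[1], 3)            # scores (3, 0)
  expect_equal(av$ASV[2], 4)            # scores (0, 4)

  # zero interaction -> degenerate
  spec0 <- random_spec(4, 2, 2, 2, K = 0, seed = 1, noise_sd = 0,
                       rep_effect_sd = 0, trait = "Y")
  fit0 <- ammi(simulate_trial(spec0), "Y")
  expect_error(asv(fit0), "degenerate")
})

test_that("ASV ranking is invariant to component sign flips", {
  tab <- make_table(8, 2, 3, 2, seed = 19)
  fit <- ammi(tab, "Y")
  flipped <- fit
  flipped$u[, 1] <- -flipped$u[, 1]
  flipped$v[, 1] <- -flipped$v[, 1]
  expect_equal(asv(flipped)$ASV, asv(fit)$ASV, tolerance = 1e-12)
})

test_that("argument and degeneracy errors", {
  tab <- make_table(4, 2, 2, 2, seed = 23)
  expect_error(ammi(tab, "Y", K = 99), "K must be")
  expect_error(ammi(matrix(1, 2, 5)), "at least 3")
})

test_that("AMMI coordinate export supports both classic layouts", {
  tab <- make_table(5, 2, 3, 2, seed = 29)
  fit <- ammi(tab, "Y")
  a2 <- ammi_coordinates(fit, "AMMI2")
  a1 <- ammi_coordinates(fit, "AMMI1")
  expect_setequal(a2$label, c(rownames(fit$means), colnames(fit$means)))
  # AMMI1 x-axis is the trait mean; genotype rows match row means
  gm <- a1[a1$entity == "genotype", ]
  expect_equal(gm$x[match(rownames(fit$means), gm$label)],
               unname(rowMeans(fit$means)))
  # AMMI2 y is IPCA2, AMMI1 y is IPCA1
  gs <- scores(fit, "genotype", "symmetric", 2)
  g2 <- a2[a2$entity == "genotype", ]
  expect_equal(g2$y[match(rownames(gs), g2$label)], unname(gs[, 2]))
})
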