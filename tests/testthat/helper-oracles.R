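# Independent oracles used across tests. These deliberately avoid the code
# paths of the package: sums of squares by full enumeration of marginal
# means, singular values via the eigendecomposition of the crossproduct.

# brute-force combined ANOVA on a balanced genotype x season x system x rep
# table: every SS from marginal means, nothing shared with combined_anova()
oracle_anova <- function(tab, trait) {
  y <- tab[[trait]]
  G <- tab$genotype; S <- tab$season; C <- tab$system; R <- tab$rep
  grand <- mean(y)
  g <- length(unique(G)); s <- length(unique(S))
  cc <- length(unique(C)); r <- length(unique(R))
  m_s <- tapply(y, S, mean); m_c <- tapply(y, C, mean); m_g <- tapply(y, G, mean)
  m_sc <- tapply(y, list(S, C), mean)
  m_gs <- tapply(y, list(G, S), mean)
  m_gc <- tapply(y, list(G, C), mean)
  m_gsc <- tapply(y, list(G, S, C), mean)
  m_sck <- tapply(y, list(S, C, R), mean)

  ss_s <- cc * g * r * sum((m_s - grand)^2)
  ss_c <- s * g * r * sum((m_c - grand)^2)
  ss_sc <- g * r * sum((m_sc - outer(m_s, rep(1, cc)) -
                          outer(rep(1, s), m_c) + grand)^2)
  ss_g <- s * cc * r * sum((m_g - grand)^2)
  ss_gs <- cc * r * sum((m_gs - outer(m_g, rep(1, s)) -
                           outer(rep(1, g), m_s) + grand)^2)
  ss_gc <- s * r * sum((m_gc - outer(m_g, rep(1, cc)) -
                          outer(rep(1, g), m_c) + grand)^2)
  ss_gsc <- 0
  for (i in seq_len(g)) for (j in seq_len(s)) for (k in seq_len(cc)) {
    ss_gsc <- ss_gsc + r * (m_gsc[i, j, k] - m_gs[i, j] - m_gc[i, k] -
                              m_sc[j, k] + m_g[i] + m_s[j] + m_c[k] - grand)^2
  }
  ss_rep <- 0
  for (j in seq_len(s)) for (k in seq_len(cc)) for (l in seq_len(r)) {
    ss_rep <- ss_rep + g * (m_sck[j, k, l] - m_sc[j, k])^2
  }
  ss_tot <- sum((y - grand)^2)
  ss_err <- ss_tot - (ss_s + ss_c + ss_sc + ss_g + ss_gs + ss_gc +
                        ss_gsc + ss_rep)
  c(Rep = ss_rep, S = ss_s, C = ss_c, SC = ss_sc, G = ss_g,
    GS = ss_gs, GC = ss_gc, GSC = ss_gsc, Error = ss_err, Total = ss_tot)
}

# singular values of a matrix via eigen on the crossproduct
oracle_singular_values <- function(m) {
  ev <- eigen(crossprod(m), symmetric = TRUE, only.values = TRUE)$values
  sqrt(pmax(ev, 0))
}

double_center <- function(m) {
  sweep(sweep(m, 1, rowMeans(m)), 2, colMeans(m)) + mean(m)
}

# small balanced trial table with explicit values
make_table <- function(g = 3, s = 2, cc = 2, r = 2, seed = 1,
                       noise_sd = 1, trait = "Y") {
  spec <- random_spec(n_genotypes = g, n_seasons = s, n_systems = cc,
                      n_reps = r, K = min(g - 1, s * cc - 1, 2),
                      seed = seed, grand_mean = 10, genotype_sd = 1,
                      env_sd = 1, gei_singular_values = c(2, 1)[
                        seq_len(min(g - 1, s * cc - 1, 2))],
                      rep_effect_sd = 0.3, noise_sd = noise_sd, trait = trait)
  simulate_trial(spec)
}
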