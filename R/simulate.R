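#' Specification of a synthetic multi-environment trial
#'
#' Defines the generative model for a balanced trial:
#' \deqn{Y_{ijk} = \mu + G_i + E_j + \sum_t \lambda_t \alpha_{it} \gamma_{jt}
#'   + r_{k(j)} + \varepsilon_{ijk}}
#' with genotype effects \eqn{G_i} and environment effects \eqn{E_j} summing
#' to zero, a rank-K multiplicative genotype-by-environment interaction with
#' non-increasing singular values \eqn{\lambda} and orthonormal score
#' matrices, Gaussian replicate-within-environment effects
#' \eqn{r \sim N(0, \code{rep_effect_sd}^2)} and i.i.d. Gaussian plot noise
#' \eqn{\varepsilon \sim N(0, \code{noise_sd}^2)}.
#'
#' Defaults mirror a maize hybrid trial of 24 genotypes evaluated in
#' 2 seasons x 3 cropping systems with 3 replicates, at a grain-yield-like
#' scale; see the package vignette for the calibration.
#'
#' @param n_genotypes,n_seasons,n_systems,n_reps Design dimensions.
#' @param grand_mean Grand mean in t/ha.
#' @param genotype_effects Numeric vector of length `n_genotypes`, sums to 0.
#' @param environment_effects Numeric vector of length
#'   `n_seasons * n_systems`, ordered by season then system, sums to 0.
#' @param gei_singular_values Non-increasing vector of K singular values.
#' @param gei_genotype_scores g x K matrix with orthonormal columns.
#' @param gei_environment_scores e x K matrix with orthonormal columns.
#' @param rep_effect_sd,noise_sd Standard deviations of replicate effects and
#'   plot noise (t/ha).
#' @param seed Integer seed; the same spec always simulates the same table.
#' @param trait Name for the simulated trait column.
#' @param genotypes,seasons,systems Optional level names.
#' @return An object of class `"simulation_spec"`.
#' @seealso [random_spec()], [simulate_trial()]
#' @export
simulation_spec <- function(n_genotypes = 24, n_seasons = 2, n_systems = 3,
                            n_reps = 3, grand_mean = 4.36,
                            genotype_effects = NULL,
                            environment_effects = NULL,
                            gei_singular_values = numeric(0),
                            gei_genotype_scores = NULL,
                            gei_environment_scores = NULL,
                            rep_effect_sd = 0.2, noise_sd = 0.65,
                            seed = 1L, trait = "GY",
                            genotypes = NULL, seasons = NULL, systems = NULL) {
  g <- as.integer(n_genotypes); e <- as.integer(n_seasons * n_systems)
  if (g < 2L) stop("spec error: n_genotypes must be >= 2")
  if (e < 2L) stop("spec error: need at least 2 environments")
  if (n_reps < 1L) stop("spec error: n_reps must be >= 1")
  if (!is.finite(grand_mean)) stop("spec error: grand_mean must be finite")
  if (rep_effect_sd < 0) stop("spec error: rep_effect_sd must be >= 0")
  if (noise_sd < 0) stop("spec error: noise_sd must be >= 0")

  if (is.null(genotype_effects)) genotype_effects <- numeric(g)
  if (is.null(environment_effects)) environment_effects <- numeric(e)
  if (length(genotype_effects) != g)
    stop("spec error: genotype_effects must have length n_genotypes")
  if (length(environment_effects) != e)
    stop("spec error: environment_effects must have length n_seasons * n_systems")
  tol <- 1e-8
  if (abs(sum(genotype_effects)) > tol * max(1, max(abs(genotype_effects))))
    stop("spec error: genotype_effects must sum to zero")
  if (abs(sum(environment_effects)) > tol * max(1, max(abs(environment_effects))))
    stop("spec error: environment_effects must sum to zero")

  K <- length(gei_singular_values)
  if (K > min(g - 1L, e - 1L))
    stop("spec error: gei_singular_values implies K > min(g-1, e-1)")
  if (K > 0) {
    if (any(gei_singular_values < 0) || is.unsorted(rev(gei_singular_values)))
      stop("spec error: gei_singular_values must be non-increasing and >= 0")
    if (is.null(gei_genotype_scores) || is.null(gei_environment_scores))
      stop("spec error: K > 0 requires gei_genotype_scores and gei_environment_scores")
    a <- as.matrix(gei_genotype_scores); cg <- as.matrix(gei_environment_scores)
    if (!all(dim(a) == c(g, K)))
      stop("spec error: gei_genotype_scores must be n_genotypes x K")
    if (!all(dim(cg) == c(e, K)))
      stop("spec error: gei_environment_scores must be e x K")
    if (max(abs(crossprod(a) - diag(K))) > 1e-6)
      stop("spec error: gei_genotype_scores columns must be orthonormal")
    if (max(abs(crossprod(cg) - diag(K))) > 1e-6)
      stop("spec error: gei_environment_scores columns must be orthonormal")
    gei_genotype_scores <- a; gei_environment_scores <- cg
  }

  if (is.null(genotypes)) genotypes <- sprintf("G%02d", seq_len(g))
  if (is.null(seasons)) seasons <- sprintf("S%d", seq_len(n_seasons))
  if (is.null(systems))
    systems <- if (n_systems == 3L) c("sole", "soybean", "sweetpotato")
               else sprintf("sys%d", seq_len(n_systems))

  structure(list(n_genotypes = g, n_seasons = as.integer(n_seasons),
                 n_systems = as.integer(n_systems), n_reps = as.integer(n_reps),
                 grand_mean = grand_mean,
                 genotype_effects = as.numeric(genotype_effects),
                 environment_effects = as.numeric(environment_effects),
                 gei_singular_values = as.numeric(gei_singular_values),
                 gei_genotype_scores = gei_genotype_scores,
                 gei_environment_scores = gei_environment_scores,
                 rep_effect_sd = rep_effect_sd, noise_sd = noise_sd,
                 seed = as.integer(seed), trait = trait,
                 genotypes = genotypes, seasons = seasons, systems = systems),
            class = "simulation_spec")
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat(sprintf("Simulation spec: %d genotypes x (%d seasons x %d systems) x %d reps\n",
              x$n_genotypes, x$n_seasons, x$n_systems, x$n_reps))
  cat(sprintf("  trait %s, grand mean %.3g t/ha, GEI rank %d, rep sd %.3g, noise sd %.3g, seed %d\n",
              x$trait, x$grand_mean, length(x$gei_singular_values),
              x$rep_effect_sd, x$noise_sd, x$seed))
  invisible(x)
}

# run code with a private RNG stream, restoring the caller's state
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  code
}

#' Draw a random, internally consistent simulation spec
#'
#' Effects are drawn from centered Gaussians; score matrices are drawn from
#' i.i.d. normals and orthonormalized by QR, so the spec invariants hold by
#' construction. Reproducible by `seed`.
#'
#' Default effect scales are calibrated to a grain-yield-like maize trial
#' (grand mean 4.36 t/ha, genotype effect sd 0.30, environment effect sd
#' 2.10, GEI singular values 8, 5, plot noise sd 0.65); see the vignette.
#'
#' @inheritParams simulation_spec
#' @param K Rank of the planted multiplicative interaction,
#'   `K <= min(g-1, e-1)`.
#' @param genotype_sd,env_sd Standard deviations of the drawn main effects.
#' @param gei_singular_values Planted singular values (length K).
#' @return A [simulation_spec()].
#' @export
random_spec <- function(n_genotypes = 24, n_seasons = 2, n_systems = 3,
                        n_reps = 3, K = 2, seed = 1L,
                        grand_mean = 4.36, genotype_sd = 0.30, env_sd = 2.10,
                        gei_singular_values = c(8, 5, 3, 2, 1)[seq_len(K)],
                        rep_effect_sd = 0.2, noise_sd = 0.65, trait = "GY") {
  g <- as.integer(n_genotypes); e <- as.integer(n_seasons * n_systems)
  if (K > min(g - 1L, e - 1L))
    stop("spec error: K must be <= min(g-1, e-1) = ", min(g - 1L, e - 1L))
  if (K > 0 && (length(gei_singular_values) != K || anyNA(gei_singular_values)))
    stop("spec error: gei_singular_values must have length K")
  with_seed(seed, {
    ge <- stats::rnorm(g, 0, genotype_sd); ge <- ge - mean(ge)
    ee <- stats::rnorm(e, 0, env_sd); ee <- ee - mean(ee)
    if (K > 0) {
      a <- qr.Q(qr(matrix(stats::rnorm(g * K), g, K)))
      cg <- qr.Q(qr(matrix(stats::rnorm(e * K), e, K)))
      lam <- sort(abs(gei_singular_values), decreasing = TRUE)
    } else {
      a <- NULL; cg <- NULL; lam <- numeric(0)
    }
    simulation_spec(n_genotypes = g, n_seasons = n_seasons,
                    n_systems = n_systems, n_reps = n_reps,
                    grand_mean = grand_mean,
                    genotype_effects = ge, environment_effects = ee,
                    gei_singular_values = lam,
                    gei_genotype_scores = a, gei_environment_scores = cg,
                    rep_effect_sd = rep_effect_sd, noise_sd = noise_sd,
                    seed = seed, trait = trait)
  })
}

#' Structural cell means implied by a simulation spec
#'
#' The noise-free part \eqn{\mu + G_i + E_j + \sum_t \lambda_t \alpha_{it}
#' \gamma_{jt}} as a g x e matrix (environments ordered season-major, i.e.
#' season 1 systems first).
#'
#' @param spec A [simulation_spec()].
#' @return Numeric g x e matrix.
#' @export
structural_means <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  g <- spec$n_genotypes; e <- spec$n_seasons * spec$n_systems
  m <- spec$grand_mean +
    outer(spec$genotype_effects, rep(0, e), "+") +
    outer(rep(0, g), spec$environment_effects, "+")
  K <- length(spec$gei_singular_values)
  if (K > 0)
    m <- m + spec$gei_genotype_scores %*%
      diag(spec$gei_singular_values, K) %*% t(spec$gei_environment_scores)
  dimnames(m) <- list(spec$genotypes, paste0("C", seq_len(e)))
  m
}

#' Simulate a balanced multi-environment trial
#'
#' Generates one plot record per genotype x season x system x replicate
#' according to the spec's generative model. Identical specs (including
#' `seed`) produce byte-identical tables.
#'
#' @param spec A [simulation_spec()].
#' @return A [trial_table()] with one trait column.
#' @export
simulate_trial <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  g <- spec$n_genotypes; ns <- spec$n_seasons; nc <- spec$n_systems
  r <- spec$n_reps; e <- ns * nc
  mu_cell <- structural_means(spec)

  with_seed(spec$seed, {
    rep_eff <- matrix(stats::rnorm(e * r, 0, spec$rep_effect_sd), e, r)
    # grid ordered genotype-major, then season, system, rep (deterministic)
    d <- expand.grid(rep = seq_len(r), system = spec$systems,
                     season = spec$seasons, genotype = spec$genotypes,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    d <- d[, c("genotype", "season", "system", "rep")]
    gi <- match(d$genotype, spec$genotypes)
    ji <- (match(d$season, spec$seasons) - 1L) * nc + match(d$system, spec$systems)
    y <- mu_cell[cbind(gi, ji)] + rep_eff[cbind(ji, d$rep)] +
      stats::rnorm(nrow(d), 0, spec$noise_sd)
    # yields are physically non-negative: left-censor at zero (rare under
    # the default calibration; exact zero-noise tables are unaffected as
    # long as the structural means are non-negative)
    d[[spec$trait]] <- pmax(y, 0)
    trial_table(d, traits = spec$trait)
  })
}

#' Simulate a two-trait maize-style study
#'
#' Convenience wrapper generating one balanced 24 x (2 x 3) x 3 trial with a
#' biomass-like trait (CWH, cob weight with husk) and a grain-yield-like
#' trait (GY), each from its own calibrated [random_spec()]; the two traits
#' share the design but not their effects.
#'
#' @param seed Integer seed.
#' @param n_genotypes,n_seasons,n_systems,n_reps Design dimensions.
#' @return A [trial_table()] with traits `CWH` and `GY`.
#' @export
simulate_study <- function(seed = 1L, n_genotypes = 24, n_seasons = 2,
                           n_systems = 3, n_reps = 3) {
  cwh <- random_spec(n_genotypes, n_seasons, n_systems, n_reps, K = 2,
                     seed = seed, grand_mean = 7.43, genotype_sd = 0.83,
                     env_sd = 3.13, gei_singular_values = c(12, 9),
                     noise_sd = 1.48, trait = "CWH")
  gy <- random_spec(n_genotypes, n_seasons, n_systems, n_reps, K = 2,
                    seed = seed + 1000L, grand_mean = 4.36,
                    genotype_sd = 0.30, env_sd = 2.10,
                    gei_singular_values = c(8, 5), noise_sd = 0.65,
                    trait = "GY")
  t1 <- simulate_trial(cwh)
  t2 <- simulate_trial(gy)
  t1$GY <- t2$GY[match(paste(t1$genotype, t1$season, t1$system, t1$rep),
                       paste(t2$genotype, t2$season, t2$system, t2$rep))]
  trial_table(as.data.frame(t1), traits = c("CWH", "GY"))
}

#' Serialize / deserialize a simulation spec as flat YAML
#'
#' @param spec A [simulation_spec()].
#' @param path File path.
#' @return `read_spec` returns a [simulation_spec()]; `write_spec` returns
#'   `path` invisibly.
#' @export
write_spec <- function(spec, path) {
  stopifnot(inherits(spec, "simulation_spec"))
  x <- unclass(spec)
  x$gei_genotype_scores <- as.numeric(x$gei_genotype_scores)
  x$gei_environment_scores <- as.numeric(x$gei_environment_scores)
  yaml::write_yaml(x, path, precision = 17)
  invisible(path)
}

#' @rdname write_spec
#' @export
read_spec <- function(path) {
  x <- yaml::read_yaml(path)
  K <- length(x$gei_singular_values)
  if (K > 0) {
    x$gei_genotype_scores <- matrix(x$gei_genotype_scores,
                                    x$n_genotypes, K)
    x$gei_environment_scores <- matrix(x$gei_environment_scores,
                                       x$n_seasons * x$n_systems, K)
  } else {
    x$gei_genotype_scores <- NULL
    x$gei_environment_scores <- NULL
  }
  do.call(simulation_spec, x[setdiff(names(x), character(0))])
}
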