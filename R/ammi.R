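# Shared helpers for the two bilinear decompositions (AMMI and GGE).
# Both take a g x e means matrix, subtract a centering, run an SVD and fix
# the sign indeterminacy so outputs are reproducible: each component is
# flipped so that the genotype score of largest absolute value is positive.
fix_svd_signs <- function(sv) {
  for (k in seq_len(ncol(sv$u))) {
    u <- sv$u[, k]
    if (u[which.max(abs(u))] < 0) {
      sv$u[, k] <- -sv$u[, k]
      sv$v[, k] <- -sv$v[, k]
    }
  }
  sv
}

# ties among the non-null part of the spectrum make component order and
# rotation arbitrary; trailing (numerically) zero components are fine
has_tied_spectrum <- function(d, tol = 1e-10) {
  scale <- max(d, 1)
  nz <- d[d > tol * scale]
  length(nz) >= 2 && any(abs(diff(nz)) < tol * scale)
}

#' AMMI decomposition of a genotype x environment means table
#'
#' Fits the additive main effects and multiplicative interaction model
#' \deqn{Y_{ij} = \mu + G_i + E_j + \sum_k \lambda_k \alpha_{ik} \gamma_{jk}
#'   + \rho_{ij}:}
#' the means table is double-centered (row mean, column mean and grand mean
#' removed) and the residual interaction matrix is decomposed by SVD. The
#' singular vectors are the interaction principal component axis (IPCA)
#' scores; \eqn{100 \lambda_k^2 / \sum \lambda^2} is the share of
#' interaction variation on axis k.
#'
#' @param x A [trial_table()], a `means_matrix` from [cell_means()], or a
#'   plain numeric g x e matrix (g, e >= 3).
#' @param trait Trait name, required when `x` is a multi-trait table.
#' @param K Number of multiplicative components to retain, or `"max"` for
#'   `min(g-1, e-1)`.
#' @return Object of class `c("ammi", "biplot_decomp")`: a list with the
#'   means, grand mean, genotype/environment main effects, singular values
#'   (all `min(g-1, e-1)` of them), orthonormal score matrices `u` (g x rmax)
#'   and `v` (e x rmax), variance proportions (%), retained `K`, and a
#'   `degenerate` flag marking (near-)tied singular values.
#' @examples
#' tab <- simulate_study(seed = 1)
#' fit <- ammi(tab, "GY")
#' fit
#' head(scores(fit, "genotype"))
#' @export
ammi <- function(x, trait = NULL, K = "max") {
  m <- as_means_matrix(x, trait)
  g <- nrow(m); e <- ncol(m)
  if (g < 3L || e < 3L)
    stop("AMMI needs at least 3 genotypes and 3 environments")
  rmax <- min(g - 1L, e - 1L)
  if (identical(K, "max")) K <- rmax
  if (!is.numeric(K) || K < 0 || K > rmax)
    stop("argument error: K must be in 0..min(g-1, e-1) = ", rmax)
  K <- as.integer(K)

  gm <- mean(m)
  geff <- rowMeans(m) - gm
  eeff <- colMeans(m) - gm
  D <- sweep(sweep(m, 1, rowMeans(m)), 2, colMeans(m)) + gm

  sv <- fix_svd_signs(svd(unclass(D), nu = rmax, nv = rmax))
  d <- sv$d[seq_len(rmax)]
  ss <- sum(d^2)
  var_prop <- if (ss > 0) 100 * d^2 / ss else rep(0, rmax)
  degenerate <- has_tied_spectrum(d)
  if (degenerate)
    warning("near-tied singular values: component order/rotation is arbitrary")

  structure(list(model = "AMMI", means = m, grand_mean = gm,
                 genotype_effects = geff, environment_effects = eeff,
                 interaction = unclass(D),
                 singular_values = d, u = sv$u, v = sv$v,
                 var_prop = var_prop, K = K, rmax = rmax,
                 degenerate = degenerate,
                 trait = attr(m, "trait"),
                 centering = "double (grand + genotype + environment means removed)"),
            class = c("ammi", "biplot_decomp"))
}

#' Scaled biplot scores of an AMMI or GGE decomposition
#'
#' Scores are the orthonormal singular vectors scaled by a power of the
#' singular values (singular value partitioning). For an exponent `f`,
#' genotype scores are \eqn{u_k \lambda_k^f} and environment scores
#' \eqn{v_k \lambda_k^{1-f}}; `f = 0.5` is the symmetric scaling used for
#' AMMI IPCA scores and which-won-where views, `f = 1` genotype-focused,
#' `f = 0` environment-focused.
#'
#' @param object A `biplot_decomp` ([ammi()] or [gge()]).
#' @param entity `"genotype"` or `"environment"`.
#' @param svp `"symmetric"`, `"genotype"`, `"environment"`, or a numeric
#'   exponent f in \[0, 1\].
#' @param K Number of columns to return (default: the fit's `K`, at least 2).
#' @return Numeric matrix of scores (entities x components).
#' @export
scores <- function(object, entity = c("genotype", "environment"),
                   svp = "symmetric", K = NULL) {
  stopifnot(inherits(object, "biplot_decomp"))
  entity <- match.arg(entity)
  f <- svp_exponent(svp)
  K <- as.integer(K %||% max(object$K, 2L))
  K <- min(K, object$rmax)
  lam <- object$singular_values[seq_len(K)]
  if (entity == "genotype")
    sc <- object$u[, seq_len(K), drop = FALSE] %*% diag(lam^f, K)
  else
    sc <- object$v[, seq_len(K), drop = FALSE] %*% diag(lam^(1 - f), K)
  rownames(sc) <- if (entity == "genotype") rownames(object$means)
                  else colnames(object$means)
  colnames(sc) <- paste0(if (inherits(object, "ammi")) "IPCA" else "PC",
                         seq_len(K))
  sc
}

svp_exponent <- function(svp) {
  if (is.numeric(svp)) {
    if (svp < 0 || svp > 1) stop("svp exponent must be in [0, 1]")
    return(svp)
  }
  switch(match.arg(svp, c("symmetric", "genotype", "environment")),
         symmetric = 0.5, genotype = 1, environment = 0)
}

#' @export
print.biplot_decomp <- function(x, ...) {
  cat(sprintf("%s decomposition of %d x %d means (trait %s)\n", x$model,
              nrow(x$means), ncol(x$means), x$trait))
  cat("Centering:", x$centering, "\n")
  k <- min(x$rmax, 5L)
  cat(sprintf("Singular values: %s\n",
              paste(signif(x$singular_values[1:k], 4), collapse = ", ")))
  cat(sprintf("Variance explained (%%): %s\n",
              paste(sprintf("%.2f", x$var_prop[1:k]), collapse = ", ")))
  invisible(x)
}

#' @export
summary.biplot_decomp <- function(object, ...) {
  print(object)
  cat("\nGenotype scores (symmetric scaling, first 2 components):\n")
  print(round(scores(object, "genotype", "symmetric", 2), 4))
  cat("\nEnvironment scores:\n")
  print(round(scores(object, "environment", "symmetric", 2), 4))
  invisible(object)
}

#' Fitted means under the retained AMMI components
#'
#' @param object An [ammi()] fit.
#' @param K Components to use (default the fit's `K`).
#' @param ... Unused.
#' @return g x e matrix of fitted cell means.
#' @export
fitted.ammi <- function(object, K = NULL, ...) {
  K <- as.integer(K %||% object$K)
  m <- object$grand_mean +
    outer(object$genotype_effects, object$environment_effects, "+")
  if (K > 0) {
    lam <- object$singular_values[seq_len(K)]
    m <- m + object$u[, seq_len(K), drop = FALSE] %*% diag(lam, K) %*%
      t(object$v[, seq_len(K), drop = FALSE])
  }
  dimnames(m) <- dimnames(object$means)
  m
}

#' @export
residuals.ammi <- function(object, K = NULL, ...) {
  unclass(object$means) - fitted(object, K)
}

#' AMMI biplot coordinates
#'
#' Coordinate export for the two standard layouts: `"AMMI1"` (trait mean vs
#' IPCA1) and `"AMMI2"` (IPCA1 vs IPCA2, symmetric scaling).
#'
#' @param object An [ammi()] fit.
#' @param type `"AMMI1"` or `"AMMI2"`.
#' @return Data frame with columns `entity` ("genotype"/"environment"),
#'   `label`, `x`, `y`.
#' @export
ammi_coordinates <- function(object, type = c("AMMI2", "AMMI1")) {
  stopifnot(inherits(object, "ammi"))
  type <- match.arg(type)
  gs <- scores(object, "genotype", "symmetric", 2)
  es <- scores(object, "environment", "symmetric", 2)
  if (type == "AMMI2") {
    data.frame(entity = rep(c("genotype", "environment"),
                            c(nrow(gs), nrow(es))),
               label = c(rownames(gs), rownames(es)),
               x = c(gs[, 1], es[, 1]), y = c(gs[, 2], es[, 2]),
               stringsAsFactors = FALSE)
  } else {
    gmean <- rowMeans(object$means)
    emean <- colMeans(object$means)
    data.frame(entity = rep(c("genotype", "environment"),
                            c(nrow(gs), nrow(es))),
               label = c(rownames(gs), rownames(es)),
               x = c(gmean, emean), y = c(gs[, 1], es[, 1]),
               stringsAsFactors = FALSE)
  }
}

#' @export
plot.ammi <- function(x, type = c("AMMI2", "AMMI1"), ...) {
  type <- match.arg(type)
  co <- ammi_coordinates(x, type)
  xlab <- if (type == "AMMI2") sprintf("IPCA1 (%.1f%%)", x$var_prop[1])
          else sprintf("%s mean (t/ha)", x$trait)
  ylab <- if (type == "AMMI2") sprintf("IPCA2 (%.1f%%)", x$var_prop[2])
          else sprintf("IPCA1 (%.1f%%)", x$var_prop[1])
  plot(co$x, co$y, type = "n", xlab = xlab, ylab = ylab,
       main = paste(type, "biplot,", x$trait), ...)
  graphics::abline(h = 0, v = 0, col = "grey70", lty = 2)
  env <- co$entity == "environment"
  graphics::text(co$x[!env], co$y[!env], co$label[!env], col = "black", cex = 0.7)
  graphics::text(co$x[env], co$y[env], co$label[env], col = "red3", cex = 0.8)
  invisible(co)
}

#' AMMI Stability Value
#'
#' For each genotype, the weighted distance of its first two IPCA scores
#' from the biplot origin:
#' \deqn{ASV_i = \sqrt{\left(\frac{SS_{IPCA1}}{SS_{IPCA2}}
#'   IPCA1_i\right)^2 + IPCA2_i^2},}
#' where \eqn{SS_{IPCA1}/SS_{IPCA2} = \lambda_1^2/\lambda_2^2} weights the
#' first axis by its share of interaction variation. Lower ASV = more
#' stable. IPCA scores use the symmetric scaling
#' \eqn{u_k \sqrt{\lambda_k}} by default (`scaling = "sqrt"`); `"lambda"`
#' uses \eqn{u_k \lambda_k}.
#'
#' @param object An [ammi()] fit with at least 2 non-zero components.
#' @param scaling `"sqrt"` (symmetric, default) or `"lambda"`
#'   (genotype-focused) IPCA score scaling.
#' @return Data frame of class `"asv_table"`: `genotype`, `IPCA1`, `IPCA2`,
#'   `ASV`; attribute `weight` = \eqn{\lambda_1^2/\lambda_2^2}.
#' @export
asv <- function(object, scaling = c("sqrt", "lambda")) {
  stopifnot(inherits(object, "ammi"))
  scaling <- match.arg(scaling)
  if (object$rmax < 2L)
    stop("degenerate decomposition: ASV needs at least 2 components")
  lam <- object$singular_values
  if (lam[2] <= 0)
    stop("degenerate decomposition: lambda_2 = 0 (interaction rank < 2)")
  f <- if (scaling == "sqrt") 0.5 else 1
  sc <- object$u[, 1:2] %*% diag(lam[1:2]^f, 2)
  w <- lam[1]^2 / lam[2]^2
  out <- data.frame(genotype = rownames(object$means),
                    IPCA1 = sc[, 1], IPCA2 = sc[, 2],
                    ASV = sqrt((w * sc[, 1])^2 + sc[, 2]^2),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, weight = w, scaling = scaling,
            class = c("asv_table", "data.frame"))
}
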