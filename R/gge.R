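#' GGE decomposition of a genotype x environment means table
#'
#' Fits the genotype + genotype-by-environment (GGE) model: each column
#' (environment) of the means table is centered on its environment mean,
#' \deqn{Z_{ij} = \bar{Y}_{ij} - \bar{Y}_{.j},}
#' so genotype main effects and interaction are retained together, and Z is
#' decomposed by SVD. By default the environment-centered matrix is not
#' scaled; `scale = TRUE` additionally divides each column by its
#' within-environment standard deviation.
#'
#' @inheritParams ammi
#' @param svp Default singular value partitioning stored with the fit:
#'   `"symmetric"`, `"genotype"`, or `"environment"` (view functions override
#'   this with the conventional choice for each view).
#' @param scale Scale columns by environment standard deviation.
#' @return Object of class `c("gge", "biplot_decomp")`, fields as in
#'   [ammi()] plus `svp`.
#' @examples
#' tab <- simulate_study(seed = 1)
#' fit <- gge(tab, "GY")
#' fit
#' which_won_where(fit)$mega_environments
#' @export
gge <- function(x, trait = NULL, svp = c("symmetric", "genotype", "environment"),
                K = "max", scale = FALSE) {
  svp <- match.arg(svp)
  m <- as_means_matrix(x, trait)
  g <- nrow(m); e <- ncol(m)
  if (g < 3L || e < 3L)
    stop("GGE needs at least 3 genotypes and 3 environments")
  rmax <- min(g - 1L, e - 1L)
  if (identical(K, "max")) K <- rmax
  if (!is.numeric(K) || K < 0 || K > rmax)
    stop("argument error: K must be in 0..min(g-1, e-1) = ", rmax)

  Z <- sweep(unclass(m), 2, colMeans(m))
  if (scale) {
    s <- apply(unclass(m), 2, stats::sd)
    if (any(s == 0)) stop("cannot scale: zero within-environment SD")
    Z <- sweep(Z, 2, s, "/")
  }
  sv <- fix_svd_signs(svd(Z, nu = rmax, nv = rmax))
  d <- sv$d[seq_len(rmax)]
  ss <- sum(d^2)
  var_prop <- if (ss > 0) 100 * d^2 / ss else rep(0, rmax)
  degenerate <- has_tied_spectrum(d)
  if (degenerate)
    warning("near-tied singular values: component order/rotation is arbitrary")

  structure(list(model = "GGE", means = m, grand_mean = mean(m),
                 environment_means = colMeans(m),
                 centered = Z,
                 singular_values = d, u = sv$u, v = sv$v,
                 var_prop = var_prop, K = as.integer(K), rmax = rmax,
                 degenerate = degenerate, svp = svp, scaled = scale,
                 trait = attr(m, "trait"),
                 centering = if (scale)
                   "environment-centered, environment-scaled"
                 else "environment-centered (G + GE retained)"),
            class = c("gge", "biplot_decomp"))
}

# average-environment axis: unit vector along the mean of the 2-D
# environment score vectors
aea_direction <- function(es) {
  a <- colMeans(es)
  n <- sqrt(sum(a^2))
  if (n < 1e-12)
    stop("degenerate configuration: average environment axis has zero length")
  a / n
}

#' Discriminativeness vs representativeness of test environments
#'
#' For each environment: the biplot vector length (discriminating power),
#' the angle to the average-environment axis AEA (representativeness; the
#' AEA is the unit vector along the mean of the environment score vectors),
#' and a conventional type classification: type I for short vectors
#' (length < half the longest), type II for long vectors at a small angle
#' (< 45 degrees; good test environments), type III for long vectors at a
#' large angle (useful only for culling or specific adaptation). The raw
#' length and angle are reported so other cutoffs can be applied.
#'
#' @param object A [gge()] fit.
#' @param svp Singular value partitioning; environment-focused by
#'   convention for this view.
#' @return Data frame of class `"gge_env_metrics"`: `environment`, `PC1`,
#'   `PC2`, `vector_length`, `angle_to_AEA` (degrees, 0-180, NA at the
#'   origin), `type`.
#' @export
discriminativeness_representativeness <- function(object, svp = "environment") {
  stopifnot(inherits(object, "gge"))
  es <- scores(object, "environment", svp, 2)
  aea <- aea_direction(es)
  len <- sqrt(rowSums(es^2))
  cosang <- ifelse(len > 0, (es %*% aea) / pmax(len, 1e-300), NA_real_)
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  ang[len == 0] <- NA_real_
  type <- ifelse(len < 0.5 * max(len), "I",
                 ifelse(ang < 45, "II", "III"))
  type[len == 0] <- "I"
  out <- data.frame(environment = rownames(es), PC1 = es[, 1], PC2 = es[, 2],
                    vector_length = len, angle_to_AEA = as.numeric(ang),
                    type = type, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, aea = aea, class = c("gge_env_metrics", "data.frame"))
}

#' Mean performance vs stability of genotypes
#'
#' Projects each genotype's PC1-PC2 score onto the average-environment axis:
#' the signed projection orders genotypes by mean performance across
#' environments (positive = above average), and the perpendicular distance
#' to the AEA line measures instability (contribution to interaction).
#'
#' @param object A [gge()] fit.
#' @param svp Singular value partitioning; genotype-focused by convention.
#' @return Data frame of class `"gge_genotype_metrics"`: `genotype`, `PC1`,
#'   `PC2`, `mean_projection`, `stability_distance`, `above_average`.
#' @export
mean_vs_stability <- function(object, svp = "genotype") {
  stopifnot(inherits(object, "gge"))
  gs <- scores(object, "genotype", svp, 2)
  es <- scores(object, "environment", svp, 2)
  aea <- aea_direction(es)
  proj <- as.numeric(gs %*% aea)
  dist <- abs(gs[, 1] * aea[2] - gs[, 2] * aea[1])
  out <- data.frame(genotype = rownames(gs), PC1 = gs[, 1], PC2 = gs[, 2],
                    mean_projection = proj, stability_distance = dist,
                    above_average = proj > 0, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, aea = aea, class = c("gge_genotype_metrics", "data.frame"))
}

# angle in [0, 2*pi)
angle2 <- function(x, y) (atan2(y, x) + 2 * pi) %% (2 * pi)

# is angle theta in the counter-clockwise half-open arc [a, b)?
in_arc <- function(theta, a, b) {
  w <- (b - a) %% (2 * pi)
  t <- (theta - a) %% (2 * pi)
  t < w
}

#' Which-won-where sectors and mega-environments
#'
#' Partitions the PC1-PC2 biplot into sectors: the convex hull of the
#' genotype scores is traversed counter-clockwise and the outward normal of
#' each hull edge defines a ray from the origin; the sector between the
#' normals of the two edges meeting at a hull vertex is the set of
#' directions in which that vertex genotype has the largest projection (its
#' normal cone), so the vertex "wins" every environment whose score
#' direction falls in its sector. Environments exactly on a boundary ray are
#' assigned to the counter-clockwise sector. Sectors holding at least one
#' environment are reported as (mega-)environments; `mega = TRUE` marks
#' those with two or more.
#'
#' @param object A [gge()] fit, or a g x 2 matrix of genotype scores (then
#'   `env_scores` must be given).
#' @param svp Singular value partitioning; symmetric by convention.
#' @param env_scores e x 2 matrix when `object` is a plain score matrix.
#' @return List of class `"gge_www"` with `sectors` (vertex genotype and
#'   angular bounds in degrees), `environments` (angle, sector, winner), and
#'   `mega_environments` (one row per occupied sector, member environments
#'   comma-separated).
#' @export
which_won_where <- function(object, svp = "symmetric", env_scores = NULL) {
  if (inherits(object, "gge")) {
    gs <- scores(object, "genotype", svp, 2)
    es <- scores(object, "environment", svp, 2)
  } else {
    gs <- as.matrix(object); es <- as.matrix(env_scores)
    if (is.null(rownames(gs))) rownames(gs) <- paste0("G", seq_len(nrow(gs)))
    if (is.null(rownames(es))) rownames(es) <- paste0("C", seq_len(nrow(es)))
  }
  if (ncol(gs) != 2L || ncol(es) != 2L)
    stop("which_won_where needs 2-D scores")

  hull <- grDevices::chull(gs)           # clockwise
  hull <- rev(hull)                      # counter-clockwise
  h <- length(hull)
  if (h < 3L)
    stop("degenerate hull: genotype scores are collinear")

  # outward normal angle of each CCW edge (v_i -> v_{i+1})
  nxt <- c(hull[-1], hull[1])
  ex <- gs[nxt, 1] - gs[hull, 1]
  ey <- gs[nxt, 2] - gs[hull, 2]
  phi <- angle2(ey, -ex)                 # right-hand normal of CCW edge

  # vertex v_i owns the arc from the normal of its incoming edge
  # (v_{i-1} -> v_i) to the normal of its outgoing edge (v_i -> v_{i+1})
  prev_phi <- c(phi[h], phi[-h])
  sectors <- data.frame(sector = seq_len(h),
                        vertex = rownames(gs)[hull],
                        start_deg = prev_phi * 180 / pi,
                        end_deg = phi * 180 / pi,
                        stringsAsFactors = FALSE)

  etheta <- angle2(es[, 1], es[, 2])
  sec_of <- vapply(seq_along(etheta), function(i) {
    hit <- which(in_arc(etheta[i], prev_phi, phi))
    if (length(hit)) return(hit[1L])
    # numerical corner case (angle exactly between closed arcs):
    # fall back to the hull vertex with the largest projection
    which.max(as.numeric(gs[hull, , drop = FALSE] %*% es[i, ]))
  }, integer(1))
  environments <- data.frame(environment = rownames(es),
                             angle_deg = etheta * 180 / pi,
                             sector = sec_of,
                             winner = sectors$vertex[sec_of],
                             stringsAsFactors = FALSE)
  # zero-length environment vectors have no direction: no winner
  zero <- sqrt(rowSums(es^2)) < 1e-12
  environments$winner[zero] <- NA_character_
  environments$sector[zero] <- NA_integer_

  occ <- environments[!is.na(environments$sector), , drop = FALSE]
  mega <- if (nrow(occ)) {
    sp <- split(occ$environment, occ$sector)
    data.frame(sector = as.integer(names(sp)),
               vertex = sectors$vertex[as.integer(names(sp))],
               environments = vapply(sp, paste, "", collapse = ","),
               n_environments = lengths(sp),
               mega = lengths(sp) > 1L,
               row.names = NULL, stringsAsFactors = FALSE)
  } else {
    data.frame(sector = integer(), vertex = character(),
               environments = character(), n_environments = integer(),
               mega = logical())
  }
  structure(list(sectors = sectors, environments = environments,
                 mega_environments = mega,
                 genotype_scores = gs, environment_scores = es),
            class = "gge_www")
}

#' @export
print.gge_www <- function(x, ...) {
  cat(sprintf("Which-won-where: %d sectors from %d hull vertices, %d environments\n",
              nrow(x$sectors), nrow(x$sectors), nrow(x$environments)))
  print(x$mega_environments, row.names = FALSE)
  invisible(x)
}

#' @export
plot.gge <- function(x, type = c("www", "mean_stability", "discrim"), ...) {
  type <- match.arg(type)
  svp <- switch(type, www = "symmetric", mean_stability = "genotype",
                discrim = "environment")
  gs <- scores(x, "genotype", svp, 2)
  es <- scores(x, "environment", svp, 2)
  lim <- range(c(gs, es)) * 1.1
  plot(NA, xlim = lim, ylim = lim, asp = 1,
       xlab = sprintf("PC1 (%.1f%%)", x$var_prop[1]),
       ylab = sprintf("PC2 (%.1f%%)", x$var_prop[2]),
       main = paste("GGE biplot:", type, "-", x$trait), ...)
  graphics::abline(h = 0, v = 0, col = "grey80")
  if (type == "www") {
    w <- which_won_where(x, svp)
    hull <- match(w$sectors$vertex, rownames(gs))
    graphics::polygon(gs[hull, 1], gs[hull, 2], border = "grey50")
    r <- max(abs(lim))
    for (a in w$sectors$end_deg * pi / 180)
      graphics::segments(0, 0, r * cos(a), r * sin(a), col = "grey50", lty = 3)
  } else {
    aea <- aea_direction(es)
    r <- max(abs(lim))
    graphics::segments(-r * aea[1], -r * aea[2], r * aea[1], r * aea[2],
                       col = "steelblue")
  }
  graphics::arrows(0, 0, es[, 1], es[, 2], length = 0.08, col = "red3")
  graphics::text(es, rownames(es), pos = 3, col = "red3", cex = 0.8)
  graphics::text(gs, rownames(gs), cex = 0.7)
  invisible(x)
}
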