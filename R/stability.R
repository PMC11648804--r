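#' Competition (min) ranks of a numeric vector
#'
#' Ties share the minimum rank of their tie group and the next distinct
#' value skips the tied positions ("1224" style), matching how rank columns
#' are reported in stability tables.
#'
#' @param values Finite numeric vector.
#' @param direction `"descending"` ranks the largest value 1 (performance
#'   ranks); `"ascending"` ranks the smallest value 1 (stability ranks).
#' @return Integer ranks in `1..length(values)`.
#' @export
rank_values <- function(values, direction = c("descending", "ascending")) {
  direction <- match.arg(direction)
  if (!is.numeric(values) || anyNA(values) || any(!is.finite(values)))
    stop("validation error: values must be finite and non-missing")
  v <- if (direction == "descending") -values else values
  as.integer(rank(v, ties.method = "min"))
}

#' Genotype Stability Index
#'
#' Combines performance and stability into a single rank sum:
#' \deqn{GSI_i = rASV_i + rX_i,} where \eqn{rX} ranks the genotype trait
#' means in descending order (rank 1 = highest mean) and \eqn{rASV} ranks
#' the AMMI Stability Values in ascending order (rank 1 = most stable).
#' A low GSI identifies genotypes that are both high-performing and stable.
#' All ranks use the competition (min) tie rule.
#'
#' @param means Named numeric vector of per-genotype trait means, or a data
#'   frame with columns `genotype` and a mean column.
#' @param asv_table An [asv()] table, or a data frame with columns
#'   `genotype` and `ASV`.
#' @return Data frame of class `"stability_table"`, sorted by genotype:
#'   `genotype`, `mean`, `rX`, `ASV`, `rASV`, `GSI`, `rGSI`.
#' @examples
#' tab <- simulate_study(seed = 1)
#' fit <- ammi(tab, "GY")
#' gsi(rowMeans(cell_means(tab, "GY")), asv(fit))
#' @export
gsi <- function(means, asv_table) {
  if (is.data.frame(means)) {
    mcol <- setdiff(names(means), "genotype")[1]
    means <- stats::setNames(means[[mcol]], means$genotype)
  }
  if (is.null(names(means))) stop("means must be named by genotype")
  stopifnot(is.data.frame(asv_table),
            all(c("genotype", "ASV") %in% names(asv_table)))
  extra_m <- setdiff(names(means), asv_table$genotype)
  extra_a <- setdiff(asv_table$genotype, names(means))
  if (length(extra_m) || length(extra_a))
    stop("join error: genotype sets differ; only in means: {",
         paste(extra_m, collapse = ", "), "}; only in ASV table: {",
         paste(extra_a, collapse = ", "), "}")

  gens <- sort(names(means))
  m <- means[gens]
  a <- asv_table$ASV[match(gens, asv_table$genotype)]
  rX <- rank_values(as.numeric(m), "descending")
  rA <- rank_values(a, "ascending")
  g <- rX + rA
  out <- data.frame(genotype = gens, mean = as.numeric(m), rX = rX,
                    ASV = a, rASV = rA, GSI = g,
                    rGSI = rank_values(as.numeric(g), "ascending"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, class = c("stability_table", "data.frame"))
}

#' @export
print.stability_table <- function(x, ...) {
  cat("Genotype stability index (lower GSI = high-yielding and stable)\n")
  ord <- order(x$rGSI, x$genotype)
  print.data.frame(data.frame(x[ord, ], row.names = NULL), ...)
  invisible(x)
}
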