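#' Land Equivalent Ratio
#'
#' For each genotype x season x intercropping system, sums the relative
#' yields of the component crops:
#' \deqn{LER = \sum_i IC_i / C_i,}
#' where \eqn{IC_i} is the mean yield of crop i grown intercropped and
#' \eqn{C_i} its mean yield grown as a sole crop. LER > 1 (strictly) marks
#' the intercrop as favorable: it needs less land than growing the
#' components separately.
#'
#' @param input Data frame with one row per component crop: columns
#'   `genotype`, `season`, `system`, `crop`, `intercrop_mean`, `sole_mean`
#'   (t/ha). An optional `trait` column is carried through and LER is then
#'   computed per trait.
#' @return Data frame of class `"ler_table"`: `genotype`, (`trait`,)
#'   `season`, `system`, `LER`, `n_crops`, `favorable`.
#' @export
ler <- function(input) {
  stopifnot(is.data.frame(input))
  need <- c("genotype", "season", "system", "crop",
            "intercrop_mean", "sole_mean")
  miss <- setdiff(need, names(input))
  if (length(miss))
    stop("schema error: missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(input) == 0L) stop("empty LER input")
  if (anyNA(input$intercrop_mean) || anyNA(input$sole_mean))
    stop("incomplete LER input: missing component means")
  bad <- input$sole_mean <= 0
  if (any(bad))
    stop("division-domain error: sole_mean <= 0 for crop '",
         input$crop[which(bad)[1]], "'")
  if (any(input$intercrop_mean < 0))
    stop("validation error: negative intercrop_mean")

  has_trait <- "trait" %in% names(input)
  keys <- c("genotype", if (has_trait) "trait", "season", "system")
  kf <- interaction(input[keys], drop = TRUE, lex.order = TRUE)
  ratio <- input$intercrop_mean / input$sole_mean
  agg <- rowsum(ratio, kf)
  n <- as.integer(table(kf)[rownames(agg)])
  first <- !duplicated(kf)
  keydf <- input[first, keys, drop = FALSE]
  keydf <- keydf[match(rownames(agg), as.character(kf[first])), , drop = FALSE]
  out <- data.frame(keydf, LER = as.numeric(agg), n_crops = n,
                    row.names = NULL, stringsAsFactors = FALSE)
  out$favorable <- out$LER > 1
  out <- out[do.call(order, out[keys]), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("ler_table", "data.frame"))
}

#' Wrap precomputed LER values as an LER table
#'
#' For working with already-computed LER values (e.g. published tables):
#' validates and attaches the favorability flag (`LER > 1`, strictly).
#'
#' @param df Data frame with columns `genotype`, `season`, `system`, `LER`
#'   and optionally `trait`.
#' @return A `"ler_table"`.
#' @export
ler_table <- function(df) {
  stopifnot(is.data.frame(df))
  miss <- setdiff(c("genotype", "season", "system", "LER"), names(df))
  if (length(miss))
    stop("schema error: missing column(s): ", paste(miss, collapse = ", "))
  if (anyNA(df$LER) || any(df$LER < 0))
    stop("validation error: LER must be >= 0 and non-missing")
  df$favorable <- df$LER > 1
  structure(as.data.frame(df), class = c("ler_table", "data.frame"))
}

#' Count favorable genotypes in one stratum
#'
#' @param table A `"ler_table"`.
#' @param season,system Stratum selectors.
#' @param trait Optional trait selector when the table carries one.
#' @return Integer count of genotypes with LER > 1.
#' @export
favorability_count <- function(table, season, system, trait = NULL) {
  stopifnot(inherits(table, "ler_table"))
  sel <- table$season == season & table$system == system
  if (!is.null(trait)) {
    if (!"trait" %in% names(table)) stop("table has no trait column")
    sel <- sel & table$trait == trait
  }
  if (!any(sel))
    stop("lookup error: no rows for season '", season, "', system '",
         system, "'", if (!is.null(trait)) paste0(", trait '", trait, "'"))
  sum(table$favorable[sel])
}

#' Rank genotypes by LER within each stratum
#'
#' Descending LER with competition (min) tie ranks, computed within each
#' (trait x) season x system stratum.
#'
#' @param table A `"ler_table"`.
#' @return The table with an added integer `rank` column.
#' @export
ler_ranks <- function(table) {
  stopifnot(inherits(table, "ler_table"))
  keys <- c(if ("trait" %in% names(table)) "trait", "season", "system")
  kf <- interaction(table[keys], drop = TRUE)
  table$rank <- stats::ave(table$LER, kf,
                           FUN = function(v) rank(-v, ties.method = "min"))
  table$rank <- as.integer(table$rank)
  table
}

#' Maize-side partial LER components from a trial table
#'
#' Builds the maize component rows of an LER input from the trial data
#' itself: for each genotype x season x intercropping system, the intercrop
#' mean is the cell mean under that system and the sole mean is the cell
#' mean of the same genotype and season under the sole-cropping system.
#' Companion-crop rows (soybean, sweet potato), which the trial table does
#' not contain, can be supplied separately and row-bound before calling
#' [ler()].
#'
#' Strata whose sole-crop mean is zero (a failed sole crop) have no defined
#' relative yield; they are dropped with a warning rather than poisoning the
#' whole analysis.
#'
#' @param x A [trial_table()].
#' @param trait Trait column name.
#' @param sole_system Name of the sole-cropping level of `system`.
#' @return Data frame in [ler()] input format with `crop = "maize"` and a
#'   `trait` column.
#' @export
partial_ler_input <- function(x, trait, sole_system = "sole") {
  stopifnot(inherits(x, "trial_table"))
  if (!trait %in% attr(x, "traits"))
    stop("schema error: unknown trait '", trait, "'")
  if (!sole_system %in% x$system)
    stop("sole-cropping system '", sole_system, "' not present in the data")
  cellm <- stats::aggregate(x[[trait]],
                            list(genotype = x$genotype, season = x$season,
                                 system = x$system), mean)
  names(cellm)[4] <- "mean"
  ic <- cellm[cellm$system != sole_system, , drop = FALSE]
  sole <- cellm[cellm$system == sole_system, , drop = FALSE]
  i <- match(paste(ic$genotype, ic$season),
             paste(sole$genotype, sole$season))
  if (anyNA(i))
    stop("incomplete table: missing sole-crop cell for ",
         paste(unique(paste0("(", ic$genotype[is.na(i)], ", ",
                             ic$season[is.na(i)], ")")), collapse = ", "))
  out <- data.frame(genotype = ic$genotype, trait = trait,
                    season = ic$season, system = ic$system, crop = "maize",
                    intercrop_mean = ic$mean, sole_mean = sole$mean[i],
                    stringsAsFactors = FALSE)
  zero <- out$sole_mean <= 0
  if (any(zero)) {
    warning(sum(zero), " stratum/strata dropped: sole-crop mean is zero, ",
            "relative yield undefined")
    out <- out[!zero, , drop = FALSE]
  }
  out <- out[order(out$genotype, out$season, out$system), , drop = FALSE]
  rownames(out) <- NULL
  out
}
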