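#' Combined analysis of variance for a balanced multi-environment trial
#'
#' Partitions the plot-level variation of one trait in a balanced
#' genotype x season x cropping-system x replicate trial into the classical
#' sources: replicates within environment, season (S), cropping system (C),
#' S x C, genotype (G), G x S, G x C, G x S x C, and a single pooled error
#' stratum, with percentage sums of squares and descriptive statistics
#' (grand mean, min, max, SD, CV).
#'
#' Sums of squares are the sequential (balanced, hence orthogonal) sums from
#' [stats::lm()]/[stats::anova()]; replicates are treated as nested within
#' the season x system environment (df = s*c*(r-1)). By default every
#' non-replicate effect is tested against the pooled error mean square;
#' `rep_error = TRUE` switches the tests of S, C and S x C to the
#' replicate-within-environment mean square (the stricter convention when
#' environments are randomized over blocks).
#'
#' @param x A balanced [trial_table()].
#' @param trait Trait column name.
#' @param rep_error Logical; test S, C, S x C against MS of
#'   replicates-within-environment instead of the pooled error.
#' @return A data frame of class `"met_anova"` with columns `source`, `df`,
#'   `SS`, `MS`, `F`, `p`, `pct_SS` and rows Rep, Season (S),
#'   Cropping System (C), S x C, Genotype (G), G x S, G x C, G x S x C,
#'   Error, Total; attributes `grand_mean`, `min`, `max`, `SD`, `CV_percent`,
#'   `trait`.
#' @examples
#' tab <- simulate_study(seed = 1)
#' combined_anova(tab, "GY")
#' @export
combined_anova <- function(x, trait, rep_error = FALSE) {
  stopifnot(inherits(x, "trial_table"))
  if (!trait %in% attr(x, "traits"))
    stop("schema error: unknown trait '", trait, "'")
  if (!attr(x, "balanced"))
    stop("unbalanced table: combined_anova requires a balanced design; ",
         "see cell_means(impute = TRUE) for means-level imputation")

  if (max(x$rep) < 2L)
    stop("combined_anova needs at least 2 replicates per cell")
  d <- data.frame(y = x[[trait]],
                  genotype = factor(x$genotype),
                  season = factor(x$season),
                  system = factor(x$system),
                  repf = factor(x$rep))
  # balanced => effect subspaces orthogonal => sequential SS are the
  # classical marginal-means sums of squares regardless of term order
  fit <- stats::lm(y ~ season * system * genotype + season:system:repf,
                   data = d)
  a <- stats::anova(fit)
  ss <- stats::setNames(a$`Sum Sq`, rownames(a))
  df <- stats::setNames(a$Df, rownames(a))

  pick <- c(Rep = "season:system:repf",
            `Season (S)` = "season",
            `Cropping System (C)` = "system",
            `S x C` = "season:system",
            `Genotype (G)` = "genotype",
            `G x S` = "season:genotype",
            `G x C` = "system:genotype",
            `G x S x C` = "season:system:genotype",
            Error = "Residuals")
  if (!all(pick %in% names(ss)))
    stop("internal error: unexpected ANOVA terms: ",
         paste(setdiff(pick, names(ss)), collapse = ", "))

  out <- data.frame(source = names(pick),
                    df = as.integer(df[pick]),
                    SS = as.numeric(ss[pick]),
                    stringsAsFactors = FALSE)
  out$MS <- out$SS / out$df
  ms_err <- out$MS[out$source == "Error"]
  df_err <- out$df[out$source == "Error"]
  ms_rep <- out$MS[out$source == "Rep"]
  df_rep <- out$df[out$source == "Rep"]

  out$F <- NA_real_; out$p <- NA_real_
  testable <- !(out$source %in% c("Rep", "Error"))
  out$F[testable] <- out$MS[testable] / ms_err
  out$p[testable] <- stats::pf(out$F[testable], out$df[testable], df_err,
                               lower.tail = FALSE)
  if (rep_error) {
    env_terms <- out$source %in% c("Season (S)", "Cropping System (C)", "S x C")
    out$F[env_terms] <- out$MS[env_terms] / ms_rep
    out$p[env_terms] <- stats::pf(out$F[env_terms], out$df[env_terms], df_rep,
                                  lower.tail = FALSE)
  }

  total <- data.frame(source = "Total", df = sum(out$df), SS = sum(out$SS),
                      MS = NA_real_, F = NA_real_, p = NA_real_,
                      stringsAsFactors = FALSE)
  out <- rbind(out, total)
  out$pct_SS <- 100 * out$SS / total$SS

  y <- d$y
  gm <- mean(y)
  structure(out,
            grand_mean = gm, min = min(y), max = max(y),
            SD = stats::sd(y),
            CV_percent = 100 * sqrt(ms_err) / gm,
            trait = trait, rep_error = rep_error,
            class = c("met_anova", "data.frame"))
}

#' @export
print.met_anova <- function(x, digits = 4, ...) {
  cat("Combined ANOVA, trait", attr(x, "trait"), "\n\n")
  disp <- x
  disp$SS <- signif(disp$SS, digits + 2)
  disp$MS <- signif(disp$MS, digits)
  disp$F <- signif(disp$F, digits)
  disp$pct_SS <- sprintf("%.2f %%", disp$pct_SS)
  stars <- ifelse(is.na(x$p), "", ifelse(x$p < 0.01, "**",
                  ifelse(x$p < 0.05, "*", "")))
  disp$p <- ifelse(is.na(x$p), "", sprintf("%.4g%s", x$p, stars))
  print.data.frame(disp, row.names = FALSE)
  cat(sprintf("\nMean %.2f  Min %.2f  Max %.2f  SD %.2f  CV %.2f %% (t/ha)\n",
              attr(x, "grand_mean"), attr(x, "min"), attr(x, "max"),
              attr(x, "SD"), attr(x, "CV_percent")))
  invisible(x)
}

#' Percentage of total sum of squares for one source
#'
#' @param anova A `"met_anova"` table (or any data frame with `source`, `SS`
#'   columns including a Total row).
#' @param source Source row name, e.g. `"Genotype (G)"`.
#' @return Percentage (0-100), rounded to 2 decimals.
#' @export
pct_ss <- function(anova, source) {
  i <- match(source, anova$source)
  if (is.na(i)) stop("unknown source '", source, "'; available: ",
                     paste(anova$source, collapse = ", "))
  tot <- anova$SS[match("Total", anova$source)]
  round(100 * anova$SS[i] / tot, 2)
}

#' Coefficient of variation from an error stratum
#'
#' \eqn{CV = 100 \sqrt{SS_{error}/df_{error}} / \bar{Y}}, the residual
#' standard deviation as a percentage of the grand mean.
#'
#' @param ss_error Error sum of squares.
#' @param df_error Error degrees of freedom (> 0).
#' @param grand_mean Trait grand mean (> 0).
#' @return CV in percent.
#' @export
cv_percent <- function(ss_error, df_error, grand_mean) {
  if (df_error <= 0) stop("domain error: df_error must be > 0")
  if (grand_mean <= 0) stop("domain error: grand_mean must be > 0")
  if (ss_error < 0) stop("domain error: ss_error must be >= 0")
  100 * sqrt(ss_error / df_error) / grand_mean
}

#' Write a combined ANOVA table to CSV
#'
#' Columns source, df, SS, MS, F, p, pct_SS plus footer rows carrying the
#' descriptive statistics; floats at 6 significant digits.
#'
#' @param x A `"met_anova"` object.
#' @param path Output path.
#' @export
write_anova_csv <- function(x, path) {
  stopifnot(inherits(x, "met_anova"))
  df <- as.data.frame(x)
  footer <- data.frame(source = c("Mean", "Min", "Max", "SD", "CV_percent"),
                       df = NA_integer_,
                       SS = c(attr(x, "grand_mean"), attr(x, "min"),
                              attr(x, "max"), attr(x, "SD"),
                              attr(x, "CV_percent")),
                       MS = NA_real_, F = NA_real_, p = NA_real_,
                       pct_SS = NA_real_)
  write_derived_csv(rbind(df, footer), path)
}
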