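#' Column schema for long-format trial CSV files
#'
#' Maps the column names used in a CSV file onto the roles the package
#' expects: genotype identifier, season, cropping system, replicate number,
#' and one or more numeric trait columns (yields in t/ha).
#'
#' @param genotype,season,system,rep Column names holding the factors.
#' @param traits Character vector of trait column names (e.g. `c("CWH","GY")`
#'   for cob weight with husk and grain yield).
#' @return A named list of class `"trial_schema"`.
#' @export
trial_schema <- function(genotype = "genotype", season = "season",
                         system = "system", rep = "rep",
                         traits = c("CWH", "GY")) {
  if (length(traits) < 1L) stop("schema error: 'traits' must name at least one column")
  structure(list(genotype = genotype, season = season, system = system,
                 rep = rep, traits = traits),
            class = "trial_schema")
}

#' Construct and validate a trial table
#'
#' A trial table is a long-format data frame with one row per plot:
#' columns `genotype`, `season`, `system`, `rep` plus one numeric column per
#' trait (t/ha). Validation enforces uniqueness of the
#' (genotype, season, system, rep) key, finite non-negative trait values,
#' and records whether the design is balanced (identical replicate sets in
#' every genotype x environment cell).
#'
#' @param data A data frame with the columns above.
#' @param traits Character vector naming the trait columns in `data`.
#' @return `data` with class `"trial_table"`, attributes `traits` and
#'   `balanced`.
#' @export
trial_table <- function(data, traits) {
  stopifnot(is.data.frame(data))
  need <- c("genotype", "season", "system", "rep")
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("schema error: missing column(s): ", paste(miss, collapse = ", "))
  miss_tr <- setdiff(traits, names(data))
  if (length(miss_tr))
    stop("schema error: missing trait column(s): ", paste(miss_tr, collapse = ", "))
  if (nrow(data) == 0L) stop("schema error: table has no rows")

  data$genotype <- as.character(data$genotype)
  data$season   <- as.character(data$season)
  data$system   <- as.character(data$system)
  rep_num <- suppressWarnings(as.numeric(data$rep))
  if (anyNA(rep_num) || any(rep_num < 1) || any(rep_num != round(rep_num)))
    stop("validation error: 'rep' must be integer >= 1")
  data$rep <- as.integer(rep_num)

  for (tr in traits) {
    v <- suppressWarnings(as.numeric(data[[tr]]))
    bad <- which(!is.finite(v) | v < 0)
    if (length(bad))
      stop(sprintf("validation error: trait '%s' is non-numeric, non-finite or negative at row %d",
                   tr, bad[1L]))
    data[[tr]] <- v
  }

  key <- paste(data$genotype, data$season, data$system, data$rep, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop(sprintf("validation error: duplicated (genotype, season, system, rep) key at row %d: %s",
                 dup[1L], gsub("\r", " / ", key[dup[1L]])))

  # balance: every genotype x environment cell has the same replicate set
  env <- paste(data$season, data$system, sep = "\r")
  cell <- split(data$rep, paste(data$genotype, env, sep = "\r"))
  rep_sets <- unique(lapply(cell, function(r) sort(r)))
  n_cells <- length(unique(data$genotype)) * length(unique(env))
  balanced <- length(rep_sets) == 1L && length(cell) == n_cells

  rownames(data) <- NULL
  structure(data,
            traits = traits,
            balanced = balanced,
            class = c("trial_table", "data.frame"))
}

#' @export
print.trial_table <- function(x, ...) {
  ek <- environment_keys(x)
  cat(sprintf("Multi-environment trial: %d genotypes x %d environments (%d seasons x %d systems), %s\n",
              length(unique(x$genotype)), nrow(ek),
              length(unique(x$season)), length(unique(x$system)),
              if (attr(x, "balanced")) sprintf("%d reps (balanced)", max(x$rep))
              else "unbalanced"))
  cat("Traits:", paste(attr(x, "traits"), collapse = ", "), "\n")
  cat(nrow(x), "plot records\n")
  invisible(x)
}

#' Deterministic environment labels for a trial table
#'
#' An environment is one season x cropping-system combination. Labels
#' `C1..Ce` are assigned in a fixed order: seasons sorted, then systems
#' sorted within season (so the common sole / soybean / sweet-potato naming
#' yields sole cropping first within each season).
#'
#' @param x A `trial_table` or a data frame with `season` and `system`.
#' @return Data frame with columns `season`, `system`, `label`.
#' @export
environment_keys <- function(x) {
  seasons <- sort(unique(as.character(x$season)))
  systems <- sort(unique(as.character(x$system)))
  ek <- expand.grid(system = systems, season = seasons,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  ek <- ek[, c("season", "system")]
  # drop combinations absent from the data (non-crossed designs)
  present <- unique(paste(x$season, x$system, sep = "\r"))
  ek <- ek[paste(ek$season, ek$system, sep = "\r") %in% present, , drop = FALSE]
  ek$label <- paste0("C", seq_len(nrow(ek)))
  rownames(ek) <- NULL
  ek
}

#' Read a long-format trial CSV
#'
#' @param path Path to a CSV file with a header row, decimal point '.',
#'   UTF-8 encoding.
#' @param schema A [trial_schema()] mapping file columns to roles.
#' @return A validated [trial_table()].
#' @export
read_trial_csv <- function(path, schema = trial_schema()) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  if (nrow(raw) == 0L) stop("schema error: file has no data rows: ", path)
  need <- c(schema$genotype, schema$season, schema$system, schema$rep, schema$traits)
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("schema error: missing column(s): ", paste(miss, collapse = ", "))
  d <- data.frame(genotype = raw[[schema$genotype]],
                  season   = raw[[schema$season]],
                  system   = raw[[schema$system]],
                  rep      = raw[[schema$rep]],
                  stringsAsFactors = FALSE, check.names = FALSE)
  for (tr in schema$traits) d[[tr]] <- raw[[tr]]
  trial_table(d, traits = schema$traits)
}

#' Write a trial table to CSV
#'
#' Columns are written in the normalized order genotype, season, system, rep,
#' then traits, with full double precision so that
#' `read_trial_csv(write_trial_csv(x))` round-trips exactly.
#'
#' @param x A `trial_table`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trial_csv <- function(x, path) {
  stopifnot(inherits(x, "trial_table"))
  traits <- attr(x, "traits")
  out <- x[, c("genotype", "season", "system", "rep", traits), drop = FALSE]
  for (tr in traits) out[[tr]] <- sprintf("%.17g", out[[tr]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Genotype x environment cell means for one trait
#'
#' Averages plot values over replicates within each genotype x environment
#' cell, producing the complete two-way means table that AMMI and GGE
#' decompositions operate on. With a balanced table the grand mean of the
#' result equals the grand mean of the plot data.
#'
#' @param x A `trial_table`.
#' @param trait Trait column name.
#' @param impute If `TRUE`, missing cells are filled with
#'   genotype mean + environment mean - grand mean (computed from observed
#'   cells); if `FALSE` (default) missing cells are an error.
#' @return A g x e numeric matrix of class `"means_matrix"` with genotypes as
#'   rows (sorted), environments as columns (labelled per
#'   [environment_keys()]); attributes `env_keys`, `n_reps`, `trait`.
#' @export
cell_means <- function(x, trait, impute = FALSE) {
  stopifnot(inherits(x, "trial_table"))
  if (!trait %in% attr(x, "traits"))
    stop("schema error: unknown trait '", trait, "'")
  ek <- environment_keys(x)
  gens <- sort(unique(x$genotype))
  env_of <- function(season, system)
    ek$label[match(paste(season, system), paste(ek$season, ek$system))]
  env <- env_of(x$season, x$system)

  m <- matrix(NA_real_, nrow = length(gens), ncol = nrow(ek),
              dimnames = list(gens, ek$label))
  agg <- tapply(x[[trait]], list(factor(x$genotype, gens),
                                 factor(env, ek$label)), mean)
  m[] <- agg

  if (anyNA(m)) {
    missing_cells <- which(is.na(m), arr.ind = TRUE)
    pairs <- paste0("(", gens[missing_cells[, 1]], ", ",
                    ek$label[missing_cells[, 2]], ")")
    if (!impute)
      stop("incomplete table: missing cell(s) ",
           paste(pairs, collapse = ", "),
           "; use impute = TRUE for additive cell-mean imputation")
    gm <- mean(m, na.rm = TRUE)
    rm_ <- rowMeans(m, na.rm = TRUE)
    cm_ <- colMeans(m, na.rm = TRUE)
    m[is.na(m)] <- outer(rm_, cm_, "+")[is.na(m)] - gm
  }

  reps <- tapply(x[[trait]], list(factor(x$genotype, gens),
                                  factor(env, ek$label)), length)
  structure(m,
            env_keys = ek,
            n_reps = as.integer(max(reps, na.rm = TRUE)),
            trait = trait,
            class = c("means_matrix", "matrix", "array"))
}

#' @export
print.means_matrix <- function(x, ...) {
  cat(sprintf("Cell-means matrix for trait %s: %d genotypes x %d environments (means over up to %d reps)\n",
              attr(x, "trait"), nrow(x), ncol(x), attr(x, "n_reps")))
  print(round(unclass(x)[, , drop = FALSE], 3))
  invisible(x)
}

# internal: coerce trial_table / matrix input into a means matrix
as_means_matrix <- function(x, trait = NULL) {
  if (inherits(x, "means_matrix")) return(x)
  if (inherits(x, "trial_table")) {
    if (is.null(trait)) {
      traits <- attr(x, "traits")
      if (length(traits) != 1L)
        stop("specify 'trait': table holds ", paste(traits, collapse = ", "))
      trait <- traits
    }
    return(cell_means(x, trait))
  }
  if (is.matrix(x) && is.numeric(x)) {
    if (is.null(rownames(x))) rownames(x) <- paste0("G", seq_len(nrow(x)))
    if (is.null(colnames(x))) colnames(x) <- paste0("C", seq_len(ncol(x)))
    return(structure(x,
                     env_keys = data.frame(season = NA, system = NA,
                                           label = colnames(x)),
                     n_reps = 1L, trait = trait %||% "trait",
                     class = c("means_matrix", "matrix", "array")))
  }
  stop("expected a trial_table, means_matrix, or numeric matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# internal: 6-significant-digit formatting for derived CSV output
fmt6 <- function(x) {
  if (is.numeric(x) && !is.integer(x)) formatC(x, digits = 6, format = "g")
  else x
}

write_derived_csv <- function(df, path) {
  out <- as.data.frame(lapply(df, fmt6), stringsAsFactors = FALSE,
                       check.names = FALSE)
  names(out) <- names(df)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
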