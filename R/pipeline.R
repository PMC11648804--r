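#' Run the full stability-analysis pipeline
#'
#' Sequences ANOVA, AMMI + ASV, the three GGE views, GSI and (when
#' companion-crop data is supplied) LER for each trait, writing one CSV per
#' stage plus a plain-text summary and the resolved configuration. Outputs
#' are deterministic: two runs with the same configuration produce
#' byte-identical files.
#'
#' @param config A named list or path to a YAML config file. Recognized
#'   keys: `input` (trial CSV path; omitted when `simulate = TRUE`),
#'   `simulate` (logical; generate the default synthetic study), `seed`
#'   (used for simulation), `traits` (character vector), `schema` (named
#'   list passed to [trial_schema()]), `svp`, `K`, `companion` (path to a
#'   companion-crop CSV with columns genotype, trait, season, system, crop,
#'   intercrop_mean, sole_mean), `sole_system`, `out_dir`.
#' @param quiet Suppress per-stage log lines on stderr.
#' @return Invisibly, a named list of the written file paths.
#' @examples
#' \donttest{
#' out <- run_pipeline(list(simulate = TRUE, seed = 1,
#'                          traits = c("CWH", "GY"),
#'                          out_dir = tempfile("metstab_")))
#' }
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  cfg <- utils::modifyList(
    list(input = NULL, simulate = FALSE, seed = 1L,
         traits = c("CWH", "GY"), schema = NULL, svp = "symmetric",
         K = "max", companion = NULL, sole_system = "sole",
         out_dir = "metstab_out"),
    config)
  if (!length(cfg$traits)) stop("config error: 'traits' must be non-empty")

  log_stage <- function(...) if (!quiet) message(sprintf(...))
  t0 <- proc.time()[["elapsed"]]

  if (isTRUE(cfg$simulate)) {
    tab <- simulate_study(seed = as.integer(cfg$seed))
    log_stage("[simulate] seed %d -> %d plot records", cfg$seed, nrow(tab))
  } else {
    if (is.null(cfg$input)) stop("config error: need 'input' or simulate = TRUE")
    schema <- if (is.null(cfg$schema)) trial_schema(traits = cfg$traits)
              else do.call(trial_schema, cfg$schema)
    tab <- read_trial_csv(cfg$input, schema)
    log_stage("[read] %s -> %d plot records", cfg$input, nrow(tab))
  }
  missing_tr <- setdiff(cfg$traits, attr(tab, "traits"))
  if (length(missing_tr))
    stop("config error: trait(s) not in data: ",
         paste(missing_tr, collapse = ", "))

  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(cfg$out_dir))
    stop("config error: cannot create output directory ", cfg$out_dir)
  paths <- list()
  emit <- function(df, name) {
    p <- file.path(cfg$out_dir, name)
    write_derived_csv(df, p)
    paths[[name]] <<- p
    p
  }

  comp <- NULL
  if (!is.null(cfg$companion)) {
    comp <- utils::read.csv(cfg$companion, stringsAsFactors = FALSE)
    log_stage("[companion] %s -> %d component rows", cfg$companion, nrow(comp))
  }

  summary_lines <- character(0)
  for (tr in cfg$traits) {
    an <- combined_anova(tab, tr)
    p <- file.path(cfg$out_dir, sprintf("anova_%s.csv", tr))
    write_anova_csv(an, p); paths[[basename(p)]] <- p
    log_stage("[anova %s] %d rows, CV %.2f%%", tr, nrow(an),
              attr(an, "CV_percent"))

    am <- ammi(tab, tr)
    emit(ammi_coordinates(am, "AMMI2"), sprintf("ammi_scores_%s.csv", tr))
    at <- asv(am)
    emit(as.data.frame(at), sprintf("asv_%s.csv", tr))
    log_stage("[ammi %s] %d components, IPCA1 %.1f%%", tr, am$rmax,
              am$var_prop[1])

    gg <- gge(tab, tr, svp = cfg$svp)
    emit(discriminativeness_representativeness(gg),
         sprintf("gge_env_metrics_%s.csv", tr))
    emit(mean_vs_stability(gg), sprintf("gge_genotype_metrics_%s.csv", tr))
    www <- which_won_where(gg)
    emit(www$sectors, sprintf("gge_sectors_%s.csv", tr))
    emit(www$environments, sprintf("gge_environments_%s.csv", tr))
    log_stage("[gge %s] PC1+PC2 %.1f%%, %d sectors", tr,
              sum(gg$var_prop[1:2]), nrow(www$sectors))

    st <- gsi(rowMeans(cell_means(tab, tr)), at)
    emit(as.data.frame(st), sprintf("gsi_%s.csv", tr))

    if (!is.null(comp) || length(unique(tab$system)) > 1) {
      lin <- partial_ler_input(tab, tr, cfg$sole_system)
      if (!is.null(comp)) {
        ctr <- if ("trait" %in% names(comp))
          comp[comp$trait == tr, , drop = FALSE] else comp
        if (!"trait" %in% names(ctr)) ctr$trait <- tr
        lin <- rbind(lin, ctr[, names(lin), drop = FALSE])
      }
      lt <- ler_ranks(ler(lin))
      emit(as.data.frame(lt), sprintf("ler_%s.csv", tr))
      log_stage("[ler %s] %d strata rows", tr, nrow(lt))
    }

    top5 <- function(r) paste(st$genotype[order(r, st$genotype)][1:5],
                              collapse = ", ")
    summary_lines <- c(summary_lines,
      sprintf("Trait %s:", tr),
      sprintf("  top 5 by mean (rX):     %s", top5(st$rX)),
      sprintf("  top 5 by ASV (rASV):    %s", top5(st$rASV)),
      sprintf("  top 5 by GSI (rGSI):    %s", top5(st$rGSI)), "")
  }

  writeLines(summary_lines, file.path(cfg$out_dir, "summary.txt"))
  paths[["summary.txt"]] <- file.path(cfg$out_dir, "summary.txt")
  cfg_out <- cfg[!vapply(cfg, is.null, TRUE)]
  yaml::write_yaml(cfg_out, file.path(cfg$out_dir, "resolved_config.yml"))
  paths[["resolved_config.yml"]] <- file.path(cfg$out_dir, "resolved_config.yml")
  log_stage("[done] %d files in %s (%.2fs)", length(paths), cfg$out_dir,
            proc.time()[["elapsed"]] - t0)
  invisible(paths)
}
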