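#' Pipeline run configuration
#'
#' Assembles and validates the configuration for a full analysis run, either
#' simulating a multi-study collaboration (`mode = "simulate"`) or loading
#' user-supplied tables (`mode = "load"`). In load mode, either per-study
#' cohort tables (`cohort_paths`) or a pre-made association-result table
#' (`assoc_path`, e.g. the packaged worked example) must be given.
#'
#' @param mode `"simulate"` or `"load"`.
#' @param seed Integer seed; mandatory in simulate mode.
#' @param out_dir Output directory for TSV/JSON artefacts (`NULL` = do not
#'   write files).
#' @param alpha_q Heterogeneity threshold for the fixed/random rule.
#' @param n_studies,n_per_study Simulated collaboration size.
#' @param sim Named list of overrides passed to [sim_config()].
#' @param cohort_paths Character vector of cohort TSV paths (load mode).
#' @param assoc_path Path to a pre-made association table (load mode).
#' @param consortium Named list of per-SNP summary-statistic TSV paths,
#'   keyed by outcome (`sbp`, `dbp`, `hypertension`), to be combined with
#'   the cohort meta-analyses. Overlapping studies must already be excluded.
#' @param instrument Optional named list (`r2` and `n`, or `f_stat`) giving
#'   instrument diagnostics when individual-level data are not available.
#' @param keep_palindromic Passed to [harmonise_summary_stats()] for
#'   consortium files whose strand is known to match the panel.
#' @param lipid_adjust Add lipid covariates in the association battery.
#' @param panel SNP panel.
#' @return An object of class `vitdmr_run_config`.
#' @export
run_config <- function(mode = c("simulate", "load"),
                       seed = NULL,
                       out_dir = NULL,
                       alpha_q = 0.05,
                       n_studies = 20,
                       n_per_study = 2000,
                       sim = list(),
                       cohort_paths = NULL,
                       assoc_path = NULL,
                       consortium = list(),
                       instrument = NULL,
                       keep_palindromic = FALSE,
                       lipid_adjust = FALSE,
                       panel = default_snp_panel()) {
  mode <- match.arg(mode)
  if (mode == "simulate" && is.null(seed)) {
    abort("A seed is mandatory in simulate mode.")
  }
  if (mode == "load") {
    paths <- c(cohort_paths, assoc_path, unlist(consortium))
    if (is.null(cohort_paths) && is.null(assoc_path)) {
      abort("Load mode needs cohort_paths or assoc_path.")
    }
    missing_files <- paths[!file.exists(paths)]
    if (length(missing_files) > 0) {
      abort(paste0("Referenced file(s) do not exist: ",
                   toString(missing_files)))
    }
  }
  structure(
    list(mode = mode, seed = if (is.null(seed)) NULL else as.integer(seed),
         out_dir = out_dir, alpha_q = alpha_q,
         n_studies = n_studies, n_per_study = n_per_study, sim = sim,
         cohort_paths = cohort_paths, assoc_path = assoc_path,
         consortium = consortium, instrument = instrument,
         keep_palindromic = keep_palindromic,
         lipid_adjust = lipid_adjust,
         panel = validate_snp_panel(panel)),
    class = "vitdmr_run_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose keys mirror the arguments of [run_config()].
#' @return A `vitdmr_run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  known <- setdiff(names(formals(run_config)), "panel")
  unknown <- setdiff(names(cfg), known)
  if (length(unknown) > 0) {
    abort(paste0("Unknown configuration key(s): ", toString(unknown)))
  }
  do.call(run_config, cfg)
}

#' Run the full Mendelian-randomisation pipeline
#'
#' Orchestrates every stage: simulate or load per-study data; apply
#' phenotype definitions and allele scores; run the per-study association
#' battery; pool per-study results with the fixed/random-effects rule
#' (logging every model-selection decision); optionally harmonise external
#' per-SNP summary statistics, approximate the allele-score effect and
#' combine it with the cohort meta-analysis; compute instrument diagnostics
#' and the instrumental-variable estimates; and emit the triangulation
#' report. Deterministic given the configuration's seed.
#'
#' @param config A [run_config()] (or a YAML path understood by
#'   [read_run_config()]).
#' @return A report bundle (list) with elements `associations` (per-study
#'   rows), `meta` (pooled rows incl. heterogeneity), `triangulation`,
#'   `diagnostics`, `decisions` (model selections and exclusions), and in
#'   simulate mode `cohorts`. Written as TSV/JSON under `out_dir` when set.
#' @examples
#' \donttest{
#' bundle <- run_pipeline(run_config(mode = "simulate", seed = 1,
#'                                   n_studies = 3, n_per_study = 300))
#' bundle$triangulation
#' }
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "vitdmr_run_config"))
  decisions <- list()
  cohorts <- NULL
  assoc <- NULL

  if (config$mode == "simulate") {
    base <- do.call(sim_config, c(
      list(n = config$n_per_study, seed = config$seed, snps = config$panel),
      config$sim
    ))
    cfgs <- replicate_config(base, config$n_studies)
    cohorts <- simulate_studies(cfgs)
  } else if (!is.null(config$cohort_paths)) {
    cohorts <- purrr::map(config$cohort_paths, read_cohort_tsv) |>
      purrr::list_rbind()
  } else {
    assoc <- read_assoc_tsv(config$assoc_path)
  }

  if (!is.null(cohorts)) {
    cohorts <- add_allele_scores(prepare_phenotypes(cohorts), config$panel)
    assoc <- cohorts |>
      dplyr::group_split(.data$study_id) |>
      purrr::map(~ study_association_battery(
        .x, panel = config$panel, lipid_adjust = config$lipid_adjust)) |>
      purrr::list_rbind()
  }

  # Pool per-study rows when more than one study contributed.
  if ("study_id" %in% names(assoc) && dplyr::n_distinct(assoc$study_id) > 1) {
    groups <- dplyr::group_split(assoc, .data$exposure, .data$outcome)
    pooled <- purrr::map(groups, function(g) {
      m <- run_meta(g[c("study_id", "beta", "se")], alpha_q = config$alpha_q)
      tibble::tibble(
        exposure = g$exposure[1], outcome = g$outcome[1],
        beta = m$beta, se = m$se, n = sum(g$n),
        scale = g$scale[1], model = m$model,
        q = m$q, df = m$df, p_q = m$p_q, i2 = m$i2, tau2 = m$tau2, k = m$k
      )
    }) |> purrr::list_rbind()
    decisions$model_selection <- pooled[
      c("exposure", "outcome", "k", "q", "p_q", "model")
    ]
  } else {
    pooled <- dplyr::mutate(assoc, model = "single_study",
                            q = NA_real_, df = NA_integer_, p_q = NA_real_,
                            i2 = NA_real_, tau2 = NA_real_, k = 1L)
  }

  # Fold in consortium summary statistics where provided.
  for (oc in names(config$consortium)) {
    ss <- read_summary_stats(config$consortium[[oc]])
    harmonised <- harmonise_summary_stats(
      ss, config$panel, keep_palindromic = config$keep_palindromic)
    approx <- approximate_score_effect(harmonised, config$panel, "synthesis")
    key <- map_outcome_key(pooled, oc)
    idx <- which(pooled$exposure == "score_synthesis" & pooled$outcome == key)
    if (length(idx) == 1) {
      cohort_est <- pooled[idx, c("beta", "se")]
      cohort_est$study_id <- "cohorts"
      combined <- combine_with_consortium(
        meta_fixed(cohort_est), approx)
      pooled$beta[idx] <- combined$beta
      pooled$se[idx] <- combined$se
      pooled$model[idx] <- paste0(pooled$model[idx], "+consortium")
      decisions$consortium <- c(
        decisions$consortium,
        setNames(list(list(outcome = oc,
                           n_snps = nrow(harmonised),
                           excluded = nrow(ss) - nrow(harmonised))), oc))
    }
  }

  # Instrument diagnostics.
  diagnostics <- NULL
  if (!is.null(cohorts)) {
    fit <- lm(ln25ohd ~ score_synthesis, data = cohorts)
    diagnostics <- f_statistic(summary(fit)$r.squared, nrow(cohorts))
  } else if (!is.null(config$instrument)) {
    inst <- config$instrument
    if (!is.null(inst$r2) && !is.null(inst$n)) {
      diagnostics <- f_statistic(inst$r2, inst$n)
    } else if (!is.null(inst$f_stat)) {
      diagnostics <- structure(
        list(r2 = NA_real_, n = NA_integer_, f_stat = inst$f_stat,
             relative_bias = 1 / inst$f_stat),
        class = "vitdmr_instrument")
    }
  }

  triangulation <- triangulate(prepare_triangulation_rows(pooled))

  bundle <- list(
    associations = assoc,
    meta = pooled,
    triangulation = triangulation,
    diagnostics = diagnostics,
    decisions = decisions,
    cohorts = cohorts,
    config = config
  )
  if (!is.null(config$out_dir)) write_bundle(bundle, config$out_dir)
  bundle
}

# Convert pooled rows to the exposure/outcome/scale layout triangulate()
# expects: phenotypic ln-unit betas are rescaled to the per-10% convention.
prepare_triangulation_rows <- function(pooled) {
  rows <- pooled[c("exposure", "outcome", "beta", "se", "scale")]
  pheno <- rows$exposure == "ln25ohd" & grepl("per_ln_unit", rows$scale)
  rows$beta[pheno] <- rows$beta[pheno] * log(1.1)
  rows$se[pheno] <- rows$se[pheno] * log(1.1)
  rows$scale[pheno] <- sub("per_ln_unit", "per_10pct", rows$scale[pheno])
  rows
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_assoc_tsv(bundle$associations, file.path(out_dir, "associations.tsv"))
  readr::write_tsv(bundle$meta, file.path(out_dir, "meta.tsv"))
  readr::write_tsv(bundle$triangulation,
                   file.path(out_dir, "triangulation.tsv"))
  if (!is.null(bundle$diagnostics)) {
    jsonlite::write_json(unclass(bundle$diagnostics),
                         file.path(out_dir, "diagnostics.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  jsonlite::write_json(bundle$decisions, file.path(out_dir, "decisions.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(out_dir)
}

#' Path to the packaged worked-example association table
#'
#' A small association-result table on the published scale (per-allele
#' synthesis-score coefficients for each blood-pressure outcome, the
#' score-25(OH)D association in percent per allele, and phenotypic per-10%
#' estimates) that lets the triangulation stage run end-to-end without any
#' individual-level data. Standard errors are back-calculated from the
#' 95% confidence intervals.
#'
#' @return Path to the TSV file.
#' @examples
#' read_assoc_tsv(worked_example_path())
#' @export
worked_example_path <- function() {
  system.file("extdata", "worked_example_associations.tsv",
              package = "vitdmr", mustWork = TRUE)
}
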