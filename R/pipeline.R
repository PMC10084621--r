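#' Configuration for an end-to-end pipeline run
#'
#' Bundles every tunable of the discovery pipeline.  Inputs can be on-disk
#' paths (`phenotypes`, `counts`, `ontology`, `annotation`, `reference`) or,
#' when `synthetic = TRUE`, generated in memory from the design/truth
#' settings.
#'
#' @param synthetic generate inputs with the built-in simulator.
#' @param phenotypes,counts paths to CSV/TSV inputs (ignored when
#'   `synthetic`).
#' @param drop_chromosomes chromosome labels to exclude before DE (e.g. the
#'   sex chromosome); no default is assumed — set it explicitly for real
#'   annotations.
#' @param planted_rho planted canonical correlations for the synthetic mode;
#'   `NULL` to simulate from the trait effect model instead.
#' @param effects trait effect models for the synthetic mode (ignored when
#'   `planted_rho` is given); default [default_trait_effects()], use
#'   [null_trait_effects()] for a fully null run.
#' @param truth an [expression_truth()] for the synthetic mode; `NULL` for a
#'   default null expression model.
#' @param n_tail individuals per score tail, default 10.
#' @param fdr DE and enrichment FDR threshold, default 0.05.
#' @param loading_threshold |loading| flag threshold, default 0.30.
#' @param gate_p Wilks-ladder p-value below which an axis is carried into
#'   the expression stage, default 0.05.
#' @param max_axes cap on the number of axes taken to the expression stage
#'   (`NULL` = all significant axes).
#' @param min_cpm,prior_df DE settings.
#' @param spearman_threshold collinearity screen threshold, default 0.9.
#' @param seed root seed; every stage derives its own substream.
#' @return list of class `run_config`.
#' @export
run_config <- function(synthetic = TRUE, phenotypes = NULL, counts = NULL,
                       drop_chromosomes = character(0),
                       planted_rho = NULL, truth = NULL,
                       effects = default_trait_effects(),
                       n_tail = 10, fdr = 0.05, loading_threshold = 0.30,
                       gate_p = 0.05, max_axes = NULL,
                       min_cpm = 1, prior_df = 10,
                       spearman_threshold = 0.9, seed = 1L) {
  stopifnot(fdr > 0, fdr < 1, gate_p > 0, gate_p <= 1,
            loading_threshold >= 0, n_tail >= 1,
            spearman_threshold > 0, spearman_threshold <= 1)
  structure(as.list(environment()), class = "run_config")
}

#' Run the candidate-gene discovery pipeline
#'
#' Stages: (load | simulate) phenotypes and counts; derive growth rates,
#' transform and screen traits; fit the canonical correlation model and its
#' Wilks ladder; for each axis whose ladder p-value is below `gate_p`,
#' select the score tails of both variates (CCp and CCe), run the paired
#' NB exact-test DE analyses, and intersect the DEG lists directionally into
#' candidate genes.  Rerunning with the same config is fully deterministic.
#'
#' @param cfg a [run_config()].
#' @param out optional directory for on-disk artifacts (scores, DE tables,
#'   candidate tables, `report.json`); `NULL` keeps everything in memory.
#' @return list of class `run_report`: effective parameters, per-stage
#'   dimensions, `wilks` table, per-axis `candidates`, and the fitted
#'   objects in `$objects`.
#' @export
run_pipeline <- function(cfg = run_config(), out = NULL) {
  stopifnot(inherits(cfg, "run_config"))
  log_stage <- function(stage, fmt, ...)
    message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  report <- list(parameters = cfg[setdiff(names(cfg), c("truth", "effects"))],
                 package_version = as.character(utils::packageVersion("ccadeg")),
                 stages = list())

  # -- inputs ---------------------------------------------------------------
  if (cfg$synthetic) {
    design <- generate_design(design_config(seed = stage_seed(cfg$seed, "design")))
    pheno <- if (is.null(cfg$planted_rho)) {
      simulate_phenotypes(design, effects = cfg$effects,
                          seed = stage_seed(cfg$seed, "phenotypes"))
    } else {
      simulate_planted_phenotypes(design, rho = cfg$planted_rho,
                                  seed = stage_seed(cfg$seed, "phenotypes"))
    }
    truth <- cfg$truth %||%
      expression_truth(planted_per_axis = 0, lib_meanlog = log(1e4),
                       seed = stage_seed(cfg$seed, "truth"))
    counts <- simulate_counts(pheno, truth,
                              seed = stage_seed(cfg$seed, "counts"))
  } else {
    pheno <- read_phenotypes(cfg$phenotypes)
    counts <- read_counts(cfg$counts)
  }
  counts <- exclude_chromosomes(counts, cfg$drop_chromosomes)
  miss <- setdiff(pheno$individual_id, colnames(counts))
  if (length(miss))
    stopf("stage counts: individual '%s' has no count column", miss[1])
  report$stages$input <- list(n_individuals = nrow(pheno),
                              n_genes = nrow(counts))
  log_stage("input", "%d individuals, %d genes", nrow(pheno), nrow(counts))

  # -- traits ---------------------------------------------------------------
  if (!all(.derived_cols %in% names(pheno))) pheno <- derive_growth_rates(pheno)
  tm <- transform_traits(pheno)
  screen <- collinearity_screen(tm, cfg$spearman_threshold)
  report$stages$traits <- list(n_traits_in = ncol(tm),
                               dropped = screen$dropped)
  log_stage("traits", "%d traits, dropped: %s", ncol(screen$retained),
            if (length(screen$dropped)) paste(screen$dropped, collapse = ", ")
            else "none")

  # -- canonical ------------------------------------------------------------
  env <- code_environment(pheno)
  fit <- fit_cca(screen$retained, env)
  report$wilks <- as.data.frame(fit$wilks)
  scores <- canonical_scores(fit)
  sig_axes <- fit$wilks$k[fit$wilks$p_value < cfg$gate_p]
  if (!is.null(cfg$max_axes)) sig_axes <- utils::head(sig_axes, cfg$max_axes)
  report$stages$canonical <- list(rho = unname(fit$rho),
                                  significant_axes = sig_axes)
  log_stage("cca", "rho = %s; axes carried to expression: %s",
            paste(sprintf("%.2f", fit$rho), collapse = ", "),
            if (length(sig_axes)) paste(sig_axes, collapse = ", ") else "none")

  # -- expression stages per significant axis -------------------------------
  candidates <- list()
  de_tables <- list()
  for (k in sig_axes) {
    des <- lapply(c("CCp", "CCe"), function(basis) {
      contrast <- select_extremes(scores, axis = k, basis = basis,
                                  n_tail = cfg$n_tail)
      de_analysis(counts, contrast, min_cpm = cfg$min_cpm,
                  prior_df = cfg$prior_df)
    })
    # intersect on the common tested universe
    shared <- intersect(des[[1]]$gene, des[[2]]$gene)
    d1 <- des[[1]][des[[1]]$gene %in% shared, ]
    attr(d1, "axis") <- k
    d2 <- des[[2]][des[[2]]$gene %in% shared, ]
    cand <- directional_overlap(d1, d2, fdr = cfg$fdr)
    candidates[[paste0("axis", k)]] <- cand
    de_tables[[paste0("axis", k)]] <- list(ccp = des[[1]], cce = des[[2]])
    log_stage("overlap", "axis %d: %d up + %d down candidates", k,
              length(cand$up), length(cand$down))
  }
  report$candidates <- lapply(candidates, function(cc)
    list(up = cc$up, down = cc$down, discordant = cc$discordant))
  report$stages$expression <- list(
    axes_run = sig_axes,
    n_candidates = vapply(candidates, function(cc)
      length(cc$up) + length(cc$down), integer(1)))

  report$objects <- list(pheno = pheno, trait_matrix = screen$retained,
                         fit = fit, scores = scores, de = de_tables,
                         candidates = candidates)
  class(report) <- "run_report"

  if (!is.null(out)) {
    dir.create(out, recursive = TRUE, showWarnings = FALSE)
    utils::write.csv(scores, file.path(out, "scores.csv"), row.names = FALSE)
    utils::write.csv(report$wilks, file.path(out, "wilks.csv"),
                     row.names = FALSE)
    for (nm in names(candidates))
      utils::write.csv(candidates[[nm]]$table,
                       file.path(out, sprintf("candidates_%s.csv", nm)),
                       row.names = FALSE)
    jsonlite::write_json(report[c("parameters", "package_version", "stages",
                                  "wilks", "candidates")],
                         file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
  }
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("pipeline run\n")
  cat(sprintf("  individuals: %d, genes: %d\n",
              x$stages$input$n_individuals, x$stages$input$n_genes))
  cat(sprintf("  canonical correlations: %s\n",
              paste(sprintf("%.2f", x$stages$canonical$rho), collapse = ", ")))
  if (length(x$candidates))
    for (nm in names(x$candidates))
      cat(sprintf("  %s: %d up, %d down candidates\n", nm,
                  length(x$candidates[[nm]]$up),
                  length(x$candidates[[nm]]$down)))
  else cat("  no axis passed the significance gate\n")
  invisible(x)
}
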