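#' Subset a genotype matrix by individual rows
#' @param geno a \code{geno_matrix}.
#' @param rows integer row indices.
#' @return a \code{geno_matrix} over the selected individuals.
#' @export
geno_subset <- function(geno, rows) {
  structure(list(dosages = geno$dosages[rows, , drop = FALSE],
                 variants = geno$variants),
            class = "geno_matrix")
}

#' Configuration for the end-to-end synthetic study pipeline
#'
#' Bundles the synthetic-cohort configuration with every analysis knob:
#' QC thresholds, the clumping-and-thresholding grid, the forward
#' selection stopping rule, the clinical risk threshold and horizon, the
#' grouping of GWAS source cohorts for meta-analysis, and bootstrap
#' settings. The single \code{seed} fans out to per-stage seeds via
#' [stage_seed()], so any stage reproduces in isolation.
#'
#' @param sim a [sim_config()].
#' @param qc a [qc_thresholds()].
#' @param p_thresholds,r2_thresholds,window_kb C+T grid.
#' @param min_delta forward-selection AUC stopping increment.
#' @param risk_threshold clinical decision threshold (default 7.5\%).
#' @param horizon risk horizon in years (default 10).
#' @param meta_groups named list mapping a pooled label to the GWAS
#'   cohort labels meta-analyzed together; NULL pools cohorts with zero
#'   ancestry shift and keeps shifted cohorts separate.
#' @param boot_B bootstrap resamples for CIs in the report.
#' @param seed global pipeline seed.
#' @return a \code{pipeline_config}.
#' @export
pipeline_config <- function(sim = sim_config(),
                            qc = qc_thresholds(),
                            p_thresholds = c(5e-8, 1e-6, 1e-4, 1e-3,
                                             0.01, 0.05, 0.1, 0.5, 1),
                            r2_thresholds = c(0.1, 0.2, 0.5),
                            window_kb = 250,
                            min_delta = 1e-4,
                            risk_threshold = 0.075,
                            horizon = 10,
                            meta_groups = NULL,
                            boot_B = 200,
                            seed = sim$seed) {
  stopf(inherits(sim, "sim_config"), "sim must be a sim_config")
  if (is.null(meta_groups)) {
    labels <- vapply(seq_along(sim$gwas_cohorts), function(i)
      sim$gwas_cohorts[[i]]$label %||% paste0("gwas", i), character(1))
    shift <- vapply(sim$gwas_cohorts, function(g)
      (g$ancestry_shift %||% 0) > 0, logical(1))
    meta_groups <- list()
    if (any(!shift)) meta_groups$pooled <- labels[!shift]
    for (l in labels[shift]) meta_groups[[l]] <- l
  }
  structure(list(sim = sim, qc = qc,
                 p_thresholds = p_thresholds,
                 r2_thresholds = r2_thresholds,
                 window_kb = check_number(window_kb, "window_kb", 0, Inf,
                                          open_lo = TRUE),
                 min_delta = check_number(min_delta, "min_delta", 0, 1),
                 risk_threshold = check_number(risk_threshold,
                                               "risk_threshold", 0, 1),
                 horizon = check_number(horizon, "horizon", 0, Inf,
                                        open_lo = TRUE),
                 meta_groups = meta_groups,
                 boot_B = check_number(boot_B, "boot_B", 0, Inf),
                 seed = check_count(seed, "seed")),
            class = "pipeline_config")
}

#' Run the integrated-PRS study end to end on a synthetic cohort
#'
#' Executes the full study design: simulate genotypes, effects,
#' covariates and outcomes; split into a prevalent case-control tuning
#' set and a prospective testing cohort; emulate per-source GWAS summary
#' statistics; align, QC and meta-analyze them; build
#' clumping-and-thresholding PRS candidates per source; tune by AUC on
#' the tuning set (adjusted for the clinical risk score); forward-select
#' and integrate components; then evaluate the clinical model, the
#' integrated PRS, and their combination on the testing cohort by
#' discrimination, calibration and reclassification.
#'
#' @param cfg a [pipeline_config()].
#' @param risk_eq optional [risk_equation()]; defaults to the equation
#'   implied by the generator's clinical model ([sim_risk_equation()]),
#'   playing the role of externally published coefficients.
#' @param external_weights optional named list of \code{prs_weights}
#'   imported from weight files; they enter tuning as additional
#'   candidates.
#' @return a \code{pipeline_result} list with the simulated data, all
#'   intermediate artifacts, and the \code{evaluation} report.
#' @export
run_pipeline <- function(cfg = pipeline_config(), risk_eq = NULL,
                         external_weights = NULL) {
  stopf(inherits(cfg, "pipeline_config"), "cfg must be a pipeline_config")
  sim <- cfg$sim

  # -- simulate ------------------------------------------------------
  geno <- sim_genotypes(sim)
  truth <- sim_effects_and_liability(geno, sim)
  cohort <- sim_survival(geno, truth, sim)
  split <- split_tuning_testing(cohort, seed = stage_seed(sim$seed, 5))
  tuning <- split$tuning
  testing <- split$testing
  geno_tune <- geno_subset(geno, tuning$geno_row)
  geno_test <- geno_subset(geno, testing$geno_row)

  # -- per-source summary statistics, alignment, QC ------------------
  ref <- data.frame(chr = geno$variants$chr, pos = geno$variants$pos,
                    ref_allele = geno$variants$ref,
                    alt_allele = geno$variants$alt)
  gstats <- geno_variant_stats(geno)
  sumstats <- list()
  for (i in seq_along(sim$gwas_cohorts)) {
    co <- sim$gwas_cohorts[[i]]
    label <- co$label %||% paste0("gwas", i)
    ss <- sim_sumstats(geno, truth, co, seed = stage_seed(sim$seed, 10 + i))
    ss <- align_alleles(ss, ref)
    ss <- qc_filter(ss, gstats, cfg$qc)
    sumstats[[label]] <- ss
  }

  # -- meta-analysis within configured source groups -----------------
  pooled <- lapply(cfg$meta_groups, function(labels) {
    fixed_effect_meta(sumstats[labels])
  })

  # -- clinical risk on both sets ------------------------------------
  if (is.null(risk_eq)) risk_eq <- sim_risk_equation(sim)
  pce_tune <- equation_risk(tuning, risk_eq, cfg$risk_threshold)
  pce_test <- equation_risk(testing, risk_eq, cfg$risk_threshold)

  # -- C+T candidates and AUC tuning ---------------------------------
  candidates <- list()
  for (label in names(pooled)) {
    candidates <- c(candidates,
                    ct_grid(pooled[[label]], geno_tune,
                            p_thresholds = cfg$p_thresholds,
                            r2_thresholds = cfg$r2_thresholds,
                            window_kb = cfg$window_kb, label = label))
  }
  stopf(length(candidates) > 0, "no PRS candidates survived the grid")
  tune_cov <- data.frame(pce_lp = pce_tune$lp)
  components <- tune_grid(candidates, geno_tune, tuning$case, tune_cov)
  if (!is.null(external_weights)) {
    for (nm in names(external_weights)) {
      w <- external_weights[[nm]]
      sc <- prs_score(geno_tune, w)
      fit <- fit_logistic(cbind(data.frame(score = sc), tune_cov),
                          tuning$case)
      components[[length(components) + 1L]] <- structure(
        list(name = nm, weights = w, score = as.numeric(sc),
             tuning_auc = auc_rank(fit$fitted, tuning$case),
             ridged = fit$ridged),
        class = "prs_component")
    }
  }

  # -- integrate -----------------------------------------------------
  iprs <- forward_select_and_integrate(components, tuning$case, tune_cov,
                                       min_delta = cfg$min_delta)
  prs_test <- predict_integrated(iprs, geno_test)

  # -- testing-cohort models and evaluation --------------------------
  time <- testing$follow_up_time
  event <- testing$event
  comb_fit <- cox_fit(time, event,
                      data.frame(pce_lp = pce_test$lp, prs = prs_test),
                      horizon = cfg$horizon)
  comb_lp <- drop(cbind(pce_test$lp, prs_test) %*% comb_fit$coef)

  models <- list(
    prs = evaluate_model(prs_test, time, event, cfg$horizon),
    pce = evaluate_model(pce_test$lp, time, event, cfg$horizon),
    pce_prs = evaluate_model(comb_lp, time, event, cfg$horizon)
  )
  delta_c <- c_difference(time, event, pce_test$lp, comb_lp,
                          B = max(cfg$boot_B, 1),
                          seed = stage_seed(sim$seed, 20))
  reclass <- reclass_report(models$pce$risk, models$pce_prs$risk,
                            cfg$risk_threshold, time, event, cfg$horizon,
                            boot_B = cfg$boot_B,
                            seed = stage_seed(sim$seed, 21))

  structure(list(
    config = cfg,
    geno = geno, truth = truth,
    tuning = tuning, testing = testing,
    sumstats = sumstats, pooled = pooled,
    risk_eq = risk_eq,
    components = components, integrated = iprs,
    scores = list(pce_test = pce_test$lp, prs_test = prs_test,
                  combined_test = comb_lp),
    evaluation = list(models = models, delta_c = delta_c,
                      reclassification = reclass)
  ), class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  ev <- x$evaluation
  cat("Integrated-PRS synthetic study\n")
  cat(sprintf("  tuning: %d cases / %d controls; testing: %d (%d events)\n",
              sum(x$tuning$case), sum(1 - x$tuning$case),
              nrow(x$testing), sum(x$testing$event)))
  cat(sprintf("  integrated PRS: %d component(s), tuning AUC %.3f\n",
              length(x$integrated$components), x$integrated$auc))
  for (nm in names(ev$models)) {
    cs <- ev$models[[nm]]$c_statistic
    cat(sprintf("  C(%s) = %.3f (95%% CI %.3f-%.3f)\n", nm, cs$c,
                cs$ci[1], cs$ci[2]))
  }
  cat(sprintf("  delta C (PCE+PRS vs PCE) = %.4f, one-sided bootstrap p = %.4f\n",
              ev$delta_c$delta, ev$delta_c$p_one_sided))
  print(ev$reclassification$nri_categorical)
  invisible(x)
}

#' Write the evaluation report as JSON and a text summary
#'
#' Serializes the model comparison (C-statistics, HRs per SD,
#' calibration, quintile folds, reclassification) plus the full pipeline
#' configuration and seed, so any report can be traced to the exact run
#' that produced it.
#'
#' @param result a [run_pipeline()] result.
#' @param path output JSON path; a plain-text table is written alongside
#'   as \code{<path>.txt}.
#' @return the JSON path, invisibly.
#' @export
write_report <- function(result, path) {
  ev <- result$evaluation
  models <- lapply(ev$models, function(m) {
    list(c_statistic = m$c_statistic$c, c_ci = m$c_statistic$ci,
         hr_per_sd = m$hr_per_sd$hr, hr_ci = m$hr_per_sd$ci,
         calibration_slope = m$recalibration$slope,
         gnd_chisq = m$calibration$chisq, gnd_p = m$calibration$p,
         fold_top_bottom = m$quintiles$fold_top_bottom)
  })
  rc <- ev$reclassification
  payload <- list(
    seed = result$config$seed,
    config = list(
      n_individuals = result$config$sim$n_individuals,
      n_variants = result$config$sim$n_variants,
      risk_threshold = result$config$risk_threshold,
      horizon = result$config$horizon
    ),
    models = models,
    delta_c = list(delta = ev$delta_c$delta, ci = ev$delta_c$ci,
                   p_one_sided = ev$delta_c$p_one_sided),
    reclassification = list(
      table = unclass(rc$table),
      nri_categorical = unclass(rc$nri_categorical)[1:3],
      nri_km = unclass(rc$nri_km)[1:3],
      nri_continuous = unclass(rc$nri_continuous)[1:3],
      idi = rc$idi$idi
    )
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  txt <- paste0(path, ".txt")
  sink(txt)
  print(result)
  sink()
  invisible(path)
}
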