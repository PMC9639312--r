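#' Configuration for the synthetic cohort generator
#'
#' Bundles and validates every knob of the simulated study: cohort and
#' marker dimensions, block-LD structure, the genetic architecture on the
#' liability scale, the prevalence that defines prevalent (baseline) cases,
#' the GWAS source cohorts whose summary statistics are emulated, the
#' Weibull baseline hazard and clinical log hazard ratios that drive
#' incident events, and administrative censoring.
#'
#' The liability-scale variance budget is: genetic variance
#' \code{h2_liability}, a clinical component \code{clinical_liability_var},
#' and independent environmental noise making the total variance 1.
#' Prevalent disease is the indicator that this latent liability exceeds
#' its empirical \code{1 - prevalence} quantile.
#'
#' @param n_individuals number of individuals in the full study population.
#' @param n_variants number of genetic variants.
#' @param n_blocks number of LD blocks; variants are split into contiguous
#'   blocks of near-equal size, independent across blocks.
#' @param block_rho latent Gaussian correlation within a block, in [0, 1).
#' @param maf_range length-2 vector; per-variant minor allele frequencies
#'   are drawn uniformly from this interval, each endpoint in (0, 0.5].
#' @param prop_causal fraction of variants with nonzero liability effects.
#' @param h2_liability variance of the genetic component on the liability
#'   scale, in [0, 1).
#' @param clinical_liability_var variance share of the clinical component
#'   on the liability scale (prevalent disease risk carried by the same
#'   covariates that drive incident risk).
#' @param prevalence fraction of the population with prevalent disease at
#'   baseline, in (0, 1).
#' @param gwas_cohorts list of GWAS source-cohort specs; each element is a
#'   list with \code{n_gwas} (sample size), and optionally
#'   \code{ancestry_shift} (attenuation of true effects in [0,1], default 0),
#'   \code{flip_frac} (fraction of variants reported on the opposite
#'   allele, default 0), and \code{label}.
#' @param baseline_shape,baseline_scale Weibull shape and scale (years) of
#'   the baseline incident-event hazard.
#' @param true_hr_per_sd hazard ratio per standard deviation of the genetic
#'   score for incident events.
#' @param clinical_log_hrs named numeric vector of log hazard ratios for
#'   the clinical covariates (applied to standardized continuous covariates
#'   and raw 0/1 binaries).
#' @param censor_time administrative censoring time in years.
#' @param seed integer seed; identical configurations give bit-identical
#'   simulated data.
#' @return an object of class \code{sim_config}.
#' @export
sim_config <- function(n_individuals = 20000,
                       n_variants = 600,
                       n_blocks = 30,
                       block_rho = 0.6,
                       maf_range = c(0.05, 0.5),
                       prop_causal = 0.1,
                       h2_liability = 0.3,
                       clinical_liability_var = 0.1,
                       prevalence = 0.065,
                       gwas_cohorts = list(
                         list(n_gwas = 180000, label = "eur1"),
                         list(n_gwas = 120000, label = "eur2"),
                         list(n_gwas = 160000, label = "eas",
                              ancestry_shift = 0.3)
                       ),
                       baseline_shape = 1.3,
                       baseline_scale = 90,
                       true_hr_per_sd = 1.6,
                       clinical_log_hrs = c(age = 0.55, sex_male = 0.45,
                                            smoking = 0.5, sbp = 0.25,
                                            total_chol = 0.2,
                                            hdl_chol = -0.25,
                                            diabetes = 0.6),
                       censor_time = 12,
                       seed = 1L) {
  cfg <- list(
    n_individuals = check_count(n_individuals, "n_individuals"),
    n_variants = check_count(n_variants, "n_variants"),
    n_blocks = check_count(n_blocks, "n_blocks"),
    block_rho = check_number(block_rho, "block_rho", 0, 1, open_hi = TRUE),
    maf_range = maf_range,
    prop_causal = check_number(prop_causal, "prop_causal", 0, 1,
                               open_lo = TRUE),
    h2_liability = check_number(h2_liability, "h2_liability", 0, 1,
                                open_hi = TRUE),
    clinical_liability_var = check_number(clinical_liability_var,
                                          "clinical_liability_var", 0, 1,
                                          open_hi = TRUE),
    prevalence = check_number(prevalence, "prevalence", 0, 1,
                              open_lo = TRUE, open_hi = TRUE),
    gwas_cohorts = gwas_cohorts,
    baseline_shape = check_number(baseline_shape, "baseline_shape", 0, Inf,
                                  open_lo = TRUE),
    baseline_scale = check_number(baseline_scale, "baseline_scale", 0, Inf,
                                  open_lo = TRUE),
    true_hr_per_sd = check_number(true_hr_per_sd, "true_hr_per_sd", 0, Inf,
                                  open_lo = TRUE),
    clinical_log_hrs = clinical_log_hrs,
    censor_time = check_number(censor_time, "censor_time", 0, Inf),
    seed = check_count(seed, "seed")
  )
  stopf(length(maf_range) == 2L && all(is.finite(maf_range)) &&
          maf_range[1] > 0 && maf_range[2] <= 0.5 &&
          maf_range[1] <= maf_range[2],
        "'maf_range' must be an increasing pair in (0, 0.5]")
  stopf(cfg$n_blocks <= cfg$n_variants,
        "'n_blocks' cannot exceed 'n_variants'")
  stopf(cfg$h2_liability + cfg$clinical_liability_var < 1,
        "h2_liability + clinical_liability_var must be < 1")
  stopf(cfg$prop_causal * cfg$n_variants >= 1,
        "prop_causal * n_variants must be at least 1")
  stopf(length(gwas_cohorts) >= 1 &&
          all(vapply(gwas_cohorts, function(g)
            is.list(g) && !is.null(g$n_gwas) && g$n_gwas > 0, logical(1))),
        "each gwas_cohorts entry needs a positive n_gwas")
  stopf(is.numeric(cfg$clinical_log_hrs) &&
          !is.null(names(cfg$clinical_log_hrs)) &&
          all(is.finite(cfg$clinical_log_hrs)),
        "'clinical_log_hrs' must be a named finite numeric vector")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic cohort configuration\n")
  cat(sprintf("  individuals: %d, variants: %d in %d blocks (rho = %.2f)\n",
              x$n_individuals, x$n_variants, x$n_blocks, x$block_rho))
  cat(sprintf("  h2 (liability): %.2f, causal fraction: %.2f, prevalence: %.3f\n",
              x$h2_liability, x$prop_causal, x$prevalence))
  cat(sprintf("  GWAS cohorts: %d; HR per SD: %.2f; censoring at %.1f y\n",
              length(x$gwas_cohorts), x$true_hr_per_sd, x$censor_time))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
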