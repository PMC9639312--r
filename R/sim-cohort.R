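# Marginal distributions used for the simulated clinical covariates.
# Continuous covariates are standardized with these generating constants
# when clinical log hazard ratios are applied, so a log HR of x is "per SD".
COVARIATE_MARGINALS <- list(
  age        = list(type = "uniform", min = 40, max = 69),
  sex_male   = list(type = "bernoulli", p = 0.46),
  smoking    = list(type = "bernoulli", p = 0.10),
  sbp        = list(type = "normal", mean = 138, sd = 18),
  total_chol = list(type = "normal", mean = 220, sd = 42),
  hdl_chol   = list(type = "normal", mean = 55, sd = 15),
  diabetes   = list(type = "bernoulli", p = 0.05),
  bp_treatment    = list(type = "bernoulli", p = 0.20),
  lipid_treatment = list(type = "bernoulli", p = 0.15),
  race_black = list(type = "bernoulli", p = 0.0)
)

# Non-complementary base pairs: strand-ambiguous A/T and C/G pairs are not
# generated by default so the simulated markers survive QC.
UNAMBIGUOUS_PAIRS <- matrix(c(
  "A", "C", "A", "G", "C", "A", "C", "T",
  "G", "A", "G", "T", "T", "C", "T", "G"
), ncol = 2, byrow = TRUE)

#' Simulate block-LD genotype dosages
#'
#' Genotypes are built from a latent Gaussian threshold model: each
#' haplotype draws a latent normal that is equicorrelated (correlation
#' \code{block_rho}) within an LD block and independent across blocks; the
#' alternate allele is carried when the latent value falls below the
#' quantile of the variant's drawn minor allele frequency. Dosage is the
#' sum over two haplotypes, so values lie in \{0, 1, 2\}. Realized dosage
#' correlations are attenuated relative to the latent correlation
#' (tetrachoric-style), which is why downstream LD is always measured on
#' the dosages themselves.
#'
#' @param cfg a [sim_config()].
#' @param seed optional integer seed; defaults to a stage seed derived
#'   from \code{cfg$seed}.
#' @return an object of class \code{geno_matrix}: a list with
#'   \code{dosages} (individuals x variants integer matrix) and
#'   \code{variants} (data.frame with id, chr, pos, ref, alt, maf).
#' @export
sim_genotypes <- function(cfg, seed = stage_seed(cfg$seed, 1)) {
  stopf(inherits(cfg, "sim_config"), "cfg must be a sim_config")
  set.seed(seed)
  n <- cfg$n_individuals
  m <- cfg$n_variants
  block_of <- sort(rep_len(seq_len(cfg$n_blocks), m))
  maf <- runif(m, cfg$maf_range[1], cfg$maf_range[2])
  thr <- qnorm(maf)
  rho <- cfg$block_rho

  dos <- matrix(0L, n, m)
  for (b in seq_len(cfg$n_blocks)) {
    idx <- which(block_of == b)
    k <- length(idx)
    for (h in 1:2) {
      u <- rnorm(n)
      z <- sqrt(rho) * u + sqrt(1 - rho) * matrix(rnorm(n * k), n, k)
      dos[, idx] <- dos[, idx] + (z < rep(thr[idx], each = n))
    }
  }

  # Blocks cycle over autosomes; block starts are 2 Mb apart on a
  # chromosome so cross-block pairs always exceed usual clumping windows.
  chr <- ((block_of - 1L) %% 22L) + 1L
  block_on_chr <- (block_of - 1L) %/% 22L
  within <- stats::ave(seq_len(m), block_of, FUN = seq_along)
  pos <- 1e6L + block_on_chr * 2000000L + (within - 1L) * 2000L
  pair <- UNAMBIGUOUS_PAIRS[sample.int(nrow(UNAMBIGUOUS_PAIRS), m,
                                       replace = TRUE), , drop = FALSE]
  variants <- data.frame(
    id = sprintf("rs%d_%d", chr, pos),
    chr = chr, pos = as.integer(pos),
    ref = pair[, 1], alt = pair[, 2],
    maf = maf, block = block_of,
    stringsAsFactors = FALSE
  )
  colnames(dos) <- variants$id
  structure(list(dosages = dos, variants = variants),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("Genotype dosage matrix: %d individuals x %d variants (%d blocks)\n",
              nrow(x$dosages), ncol(x$dosages), length(unique(x$variants$block))))
  invisible(x)
}

sim_covariates <- function(n) {
  out <- lapply(COVARIATE_MARGINALS, function(mg) {
    switch(mg$type,
           uniform = runif(n, mg$min, mg$max),
           normal = rnorm(n, mg$mean, mg$sd),
           bernoulli = rbinom(n, 1L, mg$p))
  })
  as.data.frame(out)
}

# Standardize a covariate with its generating constants (continuous) or
# leave it raw (binary), so configured log HRs are per-SD / per-category.
standardize_covariate <- function(x, name) {
  mg <- COVARIATE_MARGINALS[[name]]
  stopf(!is.null(mg), "no marginal distribution for covariate '%s'", name)
  switch(mg$type,
         uniform = (x - (mg$min + mg$max) / 2) / ((mg$max - mg$min) / sqrt(12)),
         normal = (x - mg$mean) / mg$sd,
         bernoulli = x)
}

clinical_linear_predictor <- function(covariates, log_hrs) {
  missing <- setdiff(names(log_hrs), names(covariates))
  stopf(length(missing) == 0, "covariates missing: %s",
        paste(missing, collapse = ", "))
  lp <- numeric(nrow(covariates))
  for (nm in names(log_hrs)) {
    lp <- lp + log_hrs[[nm]] * standardize_covariate(covariates[[nm]], nm)
  }
  lp - mean(lp)
}

#' Simulate liability-scale effects, prevalent disease, and covariates
#'
#' A point-normal genetic architecture: a fraction \code{prop_causal} of
#' variants receive i.i.d. normal liability effects, rescaled so the
#' genetic score variance equals \code{h2_liability}. Clinical covariates
#' are drawn from fixed marginals; their configured log hazard ratios also
#' contribute a liability component with variance
#' \code{clinical_liability_var}. Independent Gaussian noise tops the
#' liability variance up to 1, and prevalent disease is the indicator that
#' the liability exceeds its empirical \code{1 - prevalence} quantile.
#'
#' @param geno a [sim_genotypes()] result.
#' @param cfg the [sim_config()] used to build it.
#' @param seed optional integer seed.
#' @return a list of class \code{sim_truth} with elements \code{true_betas}
#'   (per-variant liability effects, zero for non-causal variants),
#'   \code{true_clinical_lp} (per-individual clinical log-hazard linear
#'   predictor), \code{true_hr_per_sd}, \code{genetic_score},
#'   \code{liability}, \code{prevalent} (0/1) and \code{covariates}.
#'   Consumed only by downstream simulators and by tests — pipeline stages
#'   never read it.
#' @export
sim_effects_and_liability <- function(geno, cfg,
                                      seed = stage_seed(cfg$seed, 2)) {
  stopf(inherits(geno, "geno_matrix"), "geno must be a geno_matrix")
  set.seed(seed)
  n <- nrow(geno$dosages)
  m <- ncol(geno$dosages)
  n_causal <- max(1L, round(cfg$prop_causal * m))
  causal <- sort(sample.int(m, n_causal))
  beta <- numeric(m)

  if (cfg$h2_liability > 0) {
    raw <- rnorm(n_causal)
    Xc <- scale(geno$dosages[, causal, drop = FALSE],
                center = TRUE, scale = FALSE)
    g_raw <- drop(Xc %*% raw)
    s <- sqrt(cfg$h2_liability / var(g_raw))
    beta[causal] <- raw * s
    g <- g_raw * s
  } else {
    g <- numeric(n)
  }

  covariates <- sim_covariates(n)
  clin_lp <- clinical_linear_predictor(covariates, cfg$clinical_log_hrs)
  clin_sd <- sd(clin_lp)
  clin_liab <- if (clin_sd > 0) {
    sqrt(cfg$clinical_liability_var) * clin_lp / clin_sd
  } else numeric(n)

  env_var <- 1 - cfg$h2_liability - cfg$clinical_liability_var
  liability <- g + clin_liab + rnorm(n, sd = sqrt(env_var))
  cut <- quantile(liability, 1 - cfg$prevalence, names = FALSE)
  prevalent <- as.integer(liability > cut)

  structure(list(
    true_betas = beta,
    causal_index = causal,
    true_clinical_lp = clin_lp,
    true_hr_per_sd = cfg$true_hr_per_sd,
    genetic_score = g,
    liability = liability,
    prevalent = prevalent,
    covariates = covariates
  ), class = "sim_truth")
}

#' Simulate GWAS summary statistics for one source cohort
#'
#' Emulates a well-powered association scan of the liability on each
#' variant: the true marginal effect is the LD-weighted sum of causal
#' effects within the variant's block (GWAS effects are marginal, not
#' joint), the reported effect adds Gaussian sampling noise with standard
#' error \code{1 / (sd(dosage) * sqrt(n_gwas))} (unit-variance phenotype),
#' and the p-value is the two-sided Wald test of beta / se. An
#' \code{ancestry_shift} in the cohort spec attenuates true effects
#' multiplicatively, emulating imperfect cross-ancestry transfer; a
#' \code{flip_frac} reports that fraction of variants on the opposite
#' allele (labels swapped, beta negated, frequency complemented) to
#' exercise allele alignment.
#'
#' @param geno a [sim_genotypes()] result (the LD source).
#' @param truth a [sim_effects_and_liability()] result.
#' @param cohort a list with \code{n_gwas} and optional
#'   \code{ancestry_shift}, \code{flip_frac}, \code{label}.
#' @param seed optional integer seed.
#' @return a \code{data.frame} of class \code{summary_stats}.
#' @export
sim_sumstats <- function(geno, truth, cohort, seed = 1L) {
  stopf(is.list(cohort) && !is.null(cohort$n_gwas) && cohort$n_gwas > 0,
        "cohort needs a positive n_gwas")
  set.seed(seed)
  n_gwas <- cohort$n_gwas
  shift <- cohort$ancestry_shift %||% 0
  flip_frac <- cohort$flip_frac %||% 0
  v <- geno$variants
  m <- nrow(v)

  # True marginal effect: b_j = sum_k beta_k Cov(x_j, x_k) / Var(x_j),
  # with dosage covariances taken within blocks (zero across blocks).
  marg <- numeric(m)
  sdx <- numeric(m)
  for (b in unique(v$block)) {
    idx <- which(v$block == b)
    X <- geno$dosages[, idx, drop = FALSE]
    V <- stats::cov(X)
    marg[idx] <- drop(V %*% truth$true_betas[idx]) / diag(V)
    sdx[idx] <- sqrt(diag(V))
  }
  marg <- marg * (1 - shift)

  se <- 1 / (sdx * sqrt(n_gwas))
  beta <- rnorm(m, marg, se)
  z <- beta / se
  p <- 2 * pnorm(-abs(z))
  eaf_true <- colMeans(geno$dosages) / 2
  eaf <- pmin(pmax(
    eaf_true + rnorm(m, 0, sqrt(eaf_true * (1 - eaf_true) / (2 * n_gwas))),
    1e-4), 1 - 1e-4)

  ss <- data.frame(
    id = v$id, chr = v$chr, pos = v$pos,
    effect_allele = v$alt, other_allele = v$ref,
    eaf = eaf, beta = beta, se = se, p = p,
    n = rep(as.integer(n_gwas), m),
    info = runif(m, 0.6, 1),
    stringsAsFactors = FALSE
  )
  if (flip_frac > 0) {
    fl <- sample.int(m, round(flip_frac * m))
    ss[fl, c("effect_allele", "other_allele")] <-
      ss[fl, c("other_allele", "effect_allele")]
    ss$beta[fl] <- -ss$beta[fl]
    ss$eaf[fl] <- 1 - ss$eaf[fl]
  }
  attr(ss, "true_marginal") <- marg
  attr(ss, "label") <- cohort$label %||% "gwas"
  class(ss) <- c("summary_stats", "data.frame")
  ss
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate incident survival outcomes under a Weibull PH model
#'
#' Event times follow a Weibull proportional-hazards model with cumulative
#' hazard \eqn{H(t \mid x) = (t/\lambda)^k \exp(\mathrm{lp})}, where the
#' linear predictor is \code{log(true_hr_per_sd)} times the standardized
#' genetic score plus the clinical linear predictor. Follow-up is
#' administratively censored at \code{censor_time} years (no competing
#' risks; competing deaths are treated as censoring). Every individual gets
#' survival fields; prevalent cases keep their flag and are later diverted
#' to the tuning set by [split_tuning_testing()], never into testing.
#'
#' @param geno a [sim_genotypes()] result.
#' @param truth a [sim_effects_and_liability()] result.
#' @param cfg the [sim_config()].
#' @param seed optional integer seed.
#' @return a \code{data.frame} of class \code{cohort_table}: id,
#'   follow_up_time (years), event (0/1), prevalent (0/1), clinical
#'   covariate columns and \code{geno_row} linking back to the dosage
#'   matrix. A degenerate all-event or all-censored outcome among
#'   non-prevalent individuals sets the \code{"degenerate"} attribute and
#'   raises a warning.
#' @export
sim_survival <- function(geno, truth, cfg, seed = stage_seed(cfg$seed, 4)) {
  stopf(inherits(truth, "sim_truth"), "truth must come from sim_effects_and_liability")
  set.seed(seed)
  n <- nrow(geno$dosages)
  g <- truth$genetic_score
  g_std <- if (sd(g) > 0) (g - mean(g)) / sd(g) else g
  lp <- log(cfg$true_hr_per_sd) * g_std + truth$true_clinical_lp

  u <- runif(n)
  t_event <- cfg$baseline_scale *
    (-log(u) / exp(lp))^(1 / cfg$baseline_shape)
  event <- as.integer(t_event <= cfg$censor_time)
  time <- pmin(t_event, cfg$censor_time)

  cohort <- data.frame(
    id = sprintf("ind%06d", seq_len(n)),
    follow_up_time = time,
    event = event,
    prevalent = truth$prevalent,
    truth$covariates,
    geno_row = seq_len(n),
    stringsAsFactors = FALSE
  )
  incident <- cohort$event[cohort$prevalent == 0]
  degenerate <- length(incident) > 0 &&
    (all(incident == 1L) || all(incident == 0L))
  if (degenerate) {
    warning("degenerate survival outcome: all incident follow-up is ",
            if (all(incident == 1L)) "events" else "censored")
  }
  attr(cohort, "degenerate") <- degenerate
  class(cohort) <- c("cohort_table", "data.frame")
  cohort
}

#' Split a cohort into a prevalent case-control tuning set and a testing cohort
#'
#' The tuning set holds prevalent cases (all of them, or a subsample of
#' \code{n_cases_tune}) plus an equal number of controls drawn by simple
#' random sampling from individuals free of prevalent disease. The testing
#' cohort is every remaining individual with no prevalent disease; the two
#' sets never overlap.
#'
#' @param cohort a \code{cohort_table}.
#' @param n_cases_tune optional cap on tuning cases; default uses all
#'   prevalent cases.
#' @param seed integer seed for control sampling.
#' @return a list with \code{tuning} (with a \code{case} 0/1 column) and
#'   \code{testing}, both \code{cohort_table}s.
#' @export
split_tuning_testing <- function(cohort, n_cases_tune = NULL, seed = 5L) {
  set.seed(seed)
  case_rows <- which(cohort$prevalent == 1L)
  stopf(length(case_rows) > 0, "no prevalent cases: tuning set would be empty")
  if (!is.null(n_cases_tune)) {
    n_cases_tune <- check_count(n_cases_tune, "n_cases_tune")
    stopf(n_cases_tune <= length(case_rows),
          "asked for %d tuning cases but only %d prevalent cases exist",
          n_cases_tune, length(case_rows))
    case_rows <- sort(sample(case_rows, n_cases_tune))
  }
  pool <- which(cohort$prevalent == 0L)
  stopf(length(pool) >= length(case_rows),
        "not enough controls: %d needed, %d available",
        length(case_rows), length(pool))
  control_rows <- sort(sample(pool, length(case_rows)))

  tuning <- cohort[c(case_rows, control_rows), , drop = FALSE]
  tuning$case <- as.integer(tuning$prevalent == 1L)
  testing <- cohort[setdiff(pool, control_rows), , drop = FALSE]
  rownames(tuning) <- rownames(testing) <- NULL
  class(tuning) <- class(testing) <- c("cohort_table", "data.frame")
  list(tuning = tuning, testing = testing)
}
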