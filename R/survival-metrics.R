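#' Cox proportional-hazards fit with baseline survival at a horizon
#'
#' Thin wrapper around \code{survival::coxph} (Efron tie handling) that
#' also evaluates the Breslow-type baseline survival at the requested
#' horizon for the covariate-zero individual. Exact collinearity among
#' predictors (an NA coefficient) is an error; non-convergence and
#' monotone likelihood are surfaced as warnings with the final gradient
#' norm.
#'
#' @param time follow-up times.
#' @param event 0/1 event indicators.
#' @param predictors data.frame (or vector) of predictors.
#' @param horizon years at which baseline survival is evaluated.
#' @return list with \code{coef}, \code{se}, \code{s0_horizon},
#'   \code{loglik}, and the underlying \code{fit}.
#' @export
cox_fit <- function(time, event, predictors, horizon = 10) {
  if (!is.data.frame(predictors)) {
    predictors <- data.frame(x = predictors)
  }
  stopf(sum(event) >= 1, "need at least one event")
  constant <- vapply(predictors, function(x) var(as.numeric(x)) == 0,
                     logical(1))
  stopf(!any(constant), "constant predictor(s): %s",
        paste(names(predictors)[constant], collapse = ", "))
  dat <- cbind(data.frame(.time = time, .event = event), predictors)
  fml <- stats::as.formula(paste(
    "survival::Surv(.time, .event) ~",
    paste(sprintf("`%s`", names(predictors)), collapse = " + ")))
  fit <- survival::coxph(fml, data = dat, ties = "efron", x = TRUE)
  if (anyNA(coef(fit))) {
    stop("collinear predictors: ",
         paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "),
         call. = FALSE)
  }
  if (!is.null(fit$info) && grepl("did not converge", fit$info %||% "")) {
    warning("Cox fit did not converge")
  }

  # Breslow-type baseline cumulative hazard for covariates at zero
  bh <- survival::basehaz(fit, centered = FALSE)
  h0 <- if (any(bh$time <= horizon)) max(bh$hazard[bh$time <= horizon]) else 0
  list(coef = coef(fit),
       se = sqrt(diag(fit$var)),
       s0_horizon = exp(-h0),
       loglik = fit$loglik[2],
       fit = fit)
}

#' Hazard ratio per standard deviation of a score
#'
#' Standardizes the score to unit variance on the evaluation cohort,
#' optionally adjusts for covariates, and reports the Cox hazard ratio
#' per SD with its Wald 95\% confidence interval. Rescaling the score by
#' any positive constant leaves the result unchanged.
#'
#' @param time,event survival outcome.
#' @param score numeric score with positive variance.
#' @param covariates optional adjustment data.frame.
#' @return list with \code{hr}, \code{ci} (length 2), \code{log_hr},
#'   \code{se}, \code{p}.
#' @export
hr_per_sd <- function(time, event, score, covariates = NULL) {
  stopf(sd(score) > 0, "score has zero variance")
  z <- (score - mean(score)) / sd(score)
  X <- data.frame(score_sd = z)
  if (!is.null(covariates)) X <- cbind(X, covariates)
  f <- cox_fit(time, event, X)
  b <- f$coef[["score_sd"]]
  se <- f$se[[which(names(f$coef) == "score_sd")]]
  list(hr = exp(b), ci = exp(b + c(-1, 1) * 1.96 * se),
       log_hr = b, se = se, p = 2 * pnorm(-abs(b / se)))
}

#' Harrell's C-statistic for censored survival data
#'
#' Concordance over comparable pairs (the shorter follow-up time belongs
#' to an event), counting tied scores as half-concordant, with the
#' asymptotic (infinitesimal-jackknife) standard error as computed by
#' \code{survival::concordance}. Higher scores are taken to mean higher
#' risk (earlier events).
#'
#' @param time,event survival outcome.
#' @param score risk score.
#' @return list with \code{c}, \code{se}, \code{ci}, and pair counts.
#' @export
harrell_c <- function(time, event, score) {
  fit <- survival::concordance(survival::Surv(time, event) ~ score,
                               reverse = TRUE)
  counts <- fit$count
  comparable <- sum(counts[c("concordant", "discordant", "tied.x")])
  stopf(comparable > 0, "no comparable pairs")
  se <- sqrt(fit$var)
  list(c = unname(fit$concordance), se = unname(se),
       ci = unname(fit$concordance + c(-1, 1) * 1.96 * se),
       n_comparable = unname(comparable))
}

#' Bootstrap test for a difference in C-statistics
#'
#' Resamples individuals with replacement and recomputes the two
#' C-statistics on each resample; reports the difference, its percentile
#' CI, and a one-sided bootstrap p-value for "new is no better than old"
#' (the fraction of resamples with a non-positive difference).
#'
#' @param time,event survival outcome.
#' @param score_old,score_new the two risk scores.
#' @param B bootstrap resamples.
#' @param seed integer seed.
#' @return list with \code{delta}, \code{ci}, \code{p_one_sided}.
#' @export
c_difference <- function(time, event, score_old, score_new,
                         B = 200, seed = 1L) {
  set.seed(seed)
  n <- length(time)
  delta <- harrell_c(time, event, score_new)$c -
    harrell_c(time, event, score_old)$c
  boots <- vapply(seq_len(B), function(b) {
    i <- sample.int(n, n, replace = TRUE)
    harrell_c(time[i], event[i], score_new[i])$c -
      harrell_c(time[i], event[i], score_old[i])$c
  }, numeric(1))
  list(delta = delta,
       ci = unname(quantile(boots, c(0.025, 0.975))),
       p_one_sided = (sum(boots <= 0) + 1) / (B + 1))
}

#' Recalibrate model risks to a target cohort
#'
#' Fits a Cox model of the target-cohort outcomes on the fixed linear
#' predictor (giving a calibration slope), estimates the Breslow
#' baseline survival at the horizon in the target cohort, and returns
#' recalibrated absolute risks
#' \eqn{1 - S_0^{\exp(\mathrm{slope} \cdot (\mathrm{LP} - \bar{\mathrm{LP}}))}}.
#'
#' @param lp linear predictor (e.g. log relative hazard) on the target
#'   cohort.
#' @param time,event target-cohort outcome.
#' @param horizon years.
#' @return list with \code{risk} (per individual), \code{slope},
#'   \code{slope_se}, \code{s0}.
#' @export
recalibrate <- function(lp, time, event, horizon = 10) {
  stopf(sd(lp) > 0, "linear predictor has zero variance")
  lp_c <- lp - mean(lp)
  f <- cox_fit(time, event, data.frame(lp = lp_c), horizon = horizon)
  slope <- f$coef[["lp"]]
  risk <- 1 - f$s0_horizon^exp(slope * lp_c)
  list(risk = risk, slope = slope,
       slope_se = f$se[[1]], s0 = f$s0_horizon)
}

km_event_prob <- function(time, event, horizon) {
  sf <- survival::survfit(survival::Surv(time, event) ~ 1)
  sm <- summary(sf, times = horizon, extend = TRUE)
  list(prob = 1 - sm$surv, var = sm$std.err^2)
}

#' Decile calibration table and Greenwood-Nam-D'Agostino test
#'
#' Groups individuals into deciles (by default) of predicted risk,
#' compares the mean predicted risk per group with the Kaplan-Meier
#' observed event probability at the horizon, and forms the chi-square
#' statistic \eqn{\sum_d (\mathrm{KM}_d - \bar p_d)^2 /
#' \mathrm{Var}_{\mathrm{Greenwood}}(\mathrm{KM}_d)} with degrees of
#' freedom equal to the number of groups used. Groups with fewer than
#' \code{min_events} events are merged with their neighbor before
#' testing.
#'
#' @param predicted predicted event probabilities at the horizon.
#' @param time,event survival outcome.
#' @param horizon years.
#' @param groups number of risk groups (default 10).
#' @param min_events minimum events per group before merging.
#' @return list with \code{table} (per-group n, events, mean predicted,
#'   KM observed, Greenwood variance), \code{chisq}, \code{df}, \code{p}.
#' @export
gnd_test <- function(predicted, time, event, horizon = 10, groups = 10,
                     min_events = 5) {
  stopf(all(predicted >= 0 & predicted <= 1), "predicted risks must be in [0,1]")
  br <- unique(quantile(predicted, seq(0, 1, length.out = groups + 1)))
  g <- cut(predicted, breaks = br, include.lowest = TRUE, labels = FALSE)

  # merge small-event groups upward into their neighbor
  repeat {
    ev <- tapply(event * (time <= horizon), g, sum)
    ids <- as.integer(names(ev))
    if (length(ids) < 2 || all(ev >= min_events)) break
    k <- ids[which(ev < min_events)[1]]
    nbr <- if (k == max(ids)) max(ids[ids < k]) else min(ids[ids > k])
    g[g == k] <- nbr
  }
  ids <- sort(unique(g))
  stopf(length(ids) >= 2, "fewer than 2 usable risk groups")

  tab <- do.call(rbind, lapply(ids, function(k) {
    i <- g == k
    km <- km_event_prob(time[i], event[i], horizon)
    data.frame(group = k, n = sum(i),
               events = sum(event[i] * (time[i] <= horizon)),
               mean_predicted = mean(predicted[i]),
               km_observed = km$prob, km_var = km$var)
  }))
  usable <- tab$km_var > 0
  chisq <- sum((tab$km_observed[usable] - tab$mean_predicted[usable])^2 /
                 tab$km_var[usable])
  df <- sum(usable)
  list(table = tab, chisq = chisq, df = df,
       p = pchisq(chisq, df, lower.tail = FALSE))
}

#' Calibration slope and decile table for predicted risks
#'
#' Convenience wrapper: the slope is from [recalibrate()] applied to the
#' complementary-log-log of the predicted risks (the linear-predictor
#' scale of a proportional-hazards model), and the decile table from
#' [gnd_test()].
#'
#' @inheritParams gnd_test
#' @return list with \code{slope}, \code{gnd} (the [gnd_test()] result).
#' @export
calibration_deciles <- function(predicted, time, event, horizon = 10,
                                groups = 10) {
  eps <- 1e-12
  lp <- log(-log(pmin(pmax(1 - predicted, eps), 1 - eps)))
  rec <- recalibrate(lp, time, event, horizon)
  list(slope = rec$slope, slope_se = rec$slope_se,
       gnd = gnd_test(predicted, time, event, horizon, groups))
}

#' Kaplan-Meier cumulative incidence by score quintile
#'
#' Splits the cohort into quintiles of the score, computes each
#' quintile's KM cumulative incidence curve, and reports the
#' top-to-bottom fold ratio of cumulative incidence at the horizon.
#' Quintiles emptied by massive ties are merged with their neighbor and
#' flagged.
#'
#' @param score risk score.
#' @param time,event survival outcome.
#' @param horizon years.
#' @param n_groups number of score groups (default 5).
#' @return list with \code{curves} (per-group data.frame of time,
#'   cuminc), \code{incidence_at_horizon}, \code{fold_top_bottom},
#'   \code{merged} flag.
#' @export
quintile_cumulative_risk <- function(score, time, event, horizon = 10,
                                     n_groups = 5) {
  stopf(length(score) >= n_groups, "need at least one individual per group")
  br <- unique(quantile(score, seq(0, 1, length.out = n_groups + 1)))
  merged <- length(br) < n_groups + 1
  if (merged) warning("tied scores collapsed ", n_groups + 1 - length(br),
                      " group boundary(ies); groups merged")
  g <- cut(score, breaks = br, include.lowest = TRUE, labels = FALSE)
  ids <- sort(unique(g))
  curves <- lapply(ids, function(k) {
    i <- g == k
    sf <- survival::survfit(survival::Surv(time[i], event[i]) ~ 1)
    data.frame(time = sf$time, cuminc = 1 - sf$surv)
  })
  names(curves) <- paste0("q", ids)
  inc <- vapply(ids, function(k) {
    i <- g == k
    km_event_prob(time[i], event[i], horizon)$prob
  }, numeric(1))
  top <- inc[length(inc)]
  fold <- if (inc[1] > 0) top / inc[1] else if (top == 0) NaN else Inf
  list(curves = curves, incidence_at_horizon = inc,
       fold_top_bottom = fold, merged = merged)
}

#' Full evaluation of one model on a testing cohort
#'
#' Bundles discrimination (Harrell's C, HR per SD), recalibration, decile
#' calibration with the GND test, and quintile cumulative incidence into
#' one report entry.
#'
#' @param score the model's risk score or linear predictor.
#' @param time,event testing-cohort outcome.
#' @param horizon years.
#' @return an \code{eval_model} list.
#' @export
evaluate_model <- function(score, time, event, horizon = 10) {
  rec <- recalibrate(score, time, event, horizon)
  structure(list(
    c_statistic = harrell_c(time, event, score),
    hr_per_sd = hr_per_sd(time, event, score),
    recalibration = rec[c("slope", "slope_se", "s0")],
    risk = rec$risk,
    calibration = gnd_test(rec$risk, time, event, horizon),
    quintiles = quintile_cumulative_risk(score, time, event, horizon)
  ), class = "eval_model")
}

#' @export
print.eval_model <- function(x, ...) {
  cs <- x$c_statistic
  hr <- x$hr_per_sd
  cat(sprintf("C-statistic %.3f (95%% CI %.3f-%.3f)\n",
              cs$c, cs$ci[1], cs$ci[2]))
  cat(sprintf("HR per SD %.3f (95%% CI %.3f-%.3f)\n",
              hr$hr, hr$ci[1], hr$ci[2]))
  cat(sprintf("Calibration slope %.3f; GND chi-sq %.2f (df %d), p = %.3g\n",
              x$recalibration$slope, x$calibration$chisq,
              x$calibration$df, x$calibration$p))
  cat(sprintf("Top/bottom quintile incidence fold: %.2f\n",
              x$quintiles$fold_top_bottom))
  invisible(x)
}
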