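horizon_status <- function(time, event, horizon) {
  check_number(horizon, "horizon", 0, Inf, open_lo = TRUE)
  case <- event == 1 & time <= horizon
  noncase <- time >= horizon & !case
  censored <- !case & !noncase   # event-free, lost before the horizon
  list(case = case, noncase = noncase, censored = censored)
}

#' Build a reclassification table at a risk threshold
#'
#' Cross-classifies individuals by movement of their predicted risk
#' across the threshold from the old to the new model, separately for
#' cases (event by the horizon) and noncases (event-free follow-up
#' through the horizon). Individuals censored event-free before the
#' horizon are excluded from the count-based table and tallied. The
#' boundary convention matches [classify_risk()]: risk at or above the
#' threshold is high.
#'
#' @param old_risk,new_risk predicted probabilities in [0, 1].
#' @param threshold risk threshold (default 0.075).
#' @param time,event survival outcome.
#' @param horizon years.
#' @return a \code{reclass_table} list of counts: case_up, case_down,
#'   case_same, noncase_up, noncase_down, noncase_same, n_cases,
#'   n_noncases, n_censored_before_horizon.
#' @export
build_reclass_table <- function(old_risk, new_risk, threshold = 0.075,
                                time, event, horizon = 10) {
  stopf(all(old_risk >= 0 & old_risk <= 1) &&
          all(new_risk >= 0 & new_risk <= 1),
        "risks must be in [0, 1]")
  st <- horizon_status(time, event, horizon)
  old_high <- old_risk >= threshold
  new_high <- new_risk >= threshold
  up <- !old_high & new_high
  down <- old_high & !new_high

  cnt <- function(who) c(up = sum(up & who), down = sum(down & who),
                         same = sum(!up & !down & who))
  ca <- cnt(st$case)
  nc <- cnt(st$noncase)
  structure(list(
    case_up = unname(ca["up"]), case_down = unname(ca["down"]),
    case_same = unname(ca["same"]),
    noncase_up = unname(nc["up"]), noncase_down = unname(nc["down"]),
    noncase_same = unname(nc["same"]),
    n_cases = sum(st$case), n_noncases = sum(st$noncase),
    n_censored_before_horizon = sum(st$censored),
    threshold = threshold, horizon = horizon
  ), class = "reclass_table")
}

#' @export
print.reclass_table <- function(x, ...) {
  cat(sprintf("Reclassification at %.1f%% threshold, %g-year horizon\n",
              100 * x$threshold, x$horizon))
  cat(sprintf("  cases    (n = %d): up %d (%.1f%%) [+], down %d (%.1f%%) [-], same %d\n",
              x$n_cases, x$case_up, 100 * x$case_up / x$n_cases,
              x$case_down, 100 * x$case_down / x$n_cases, x$case_same))
  cat(sprintf("  noncases (n = %d): down %d (%.1f%%) [+], up %d (%.1f%%) [-], same %d\n",
              x$n_noncases, x$noncase_down,
              100 * x$noncase_down / x$n_noncases,
              x$noncase_up, 100 * x$noncase_up / x$n_noncases,
              x$noncase_same))
  cat(sprintf("  censored event-free before horizon: %d\n",
              x$n_censored_before_horizon))
  invisible(x)
}

#' Categorical net reclassification improvement from a table
#'
#' The standard decomposition
#' \deqn{\mathrm{NRI} = P(\mathrm{up} \mid \mathrm{case}) -
#'   P(\mathrm{down} \mid \mathrm{case}) -
#'   P(\mathrm{up} \mid \mathrm{noncase}) +
#'   P(\mathrm{down} \mid \mathrm{noncase})}
#' on the count-based table proportions; the overall NRI is exactly the
#' sum of the case and noncase components.
#'
#' @param table a [build_reclass_table()] result.
#' @return an \code{nri_result} list with \code{nri_cases},
#'   \code{nri_noncases}, \code{nri_overall}.
#' @export
categorical_nri <- function(table) {
  stopf(table$n_cases > 0 && table$n_noncases > 0,
        "both cases and noncases are required")
  nri_cases <- (table$case_up - table$case_down) / table$n_cases
  nri_noncases <- (table$noncase_down - table$noncase_up) / table$n_noncases
  structure(list(nri_cases = nri_cases, nri_noncases = nri_noncases,
                 nri_overall = nri_cases + nri_noncases,
                 estimator = "count-based"),
            class = "nri_result")
}

movement_cells <- function(old_risk, new_risk, threshold = NULL) {
  if (is.null(threshold)) {
    up <- new_risk > old_risk
    down <- new_risk < old_risk
  } else {
    old_high <- old_risk >= threshold
    new_high <- new_risk >= threshold
    up <- !old_high & new_high
    down <- old_high & !new_high
  }
  list(up = up, down = down, same = !up & !down)
}

#' Kaplan-Meier-adjusted net reclassification improvement
#'
#' The censoring-aware NRI estimator: within each movement cell (up,
#' down, same) the probability of being a case by the horizon is
#' estimated by Kaplan-Meier, so event-free individuals censored before
#' the horizon contribute risk time instead of being excluded. With
#' \eqn{\hat{p}} the overall KM event probability and \eqn{\hat{p}_c}
#' the cell-specific one,
#' \eqn{P(\mathrm{up} \mid \mathrm{case}) = \hat{p}_{up} \,
#' P(\mathrm{up}) / \hat{p}} (Bayes), and similarly for the other
#' components. Reduces exactly to [categorical_nri()] when no one is
#' censored before the horizon.
#'
#' @inheritParams build_reclass_table
#' @return an \code{nri_result}.
#' @export
km_adjusted_nri <- function(old_risk, new_risk, threshold = 0.075,
                            time, event, horizon = 10) {
  mv <- movement_cells(old_risk, new_risk, threshold)
  p_all <- km_event_prob(time, event, horizon)$prob
  stopf(p_all > 0 && p_all < 1, "overall KM event probability degenerate")

  cell_p <- function(sel) {
    if (!any(sel)) return(0)
    km_event_prob(time[sel], event[sel], horizon)$prob
  }
  pr <- vapply(mv, mean, numeric(1))              # P(cell)
  pc <- vapply(mv, cell_p, numeric(1))            # P(case | cell)

  p_up_case <- pc["up"] * pr["up"] / p_all
  p_down_case <- pc["down"] * pr["down"] / p_all
  p_up_non <- (1 - pc["up"]) * pr["up"] / (1 - p_all)
  p_down_non <- (1 - pc["down"]) * pr["down"] / (1 - p_all)

  nri_cases <- unname(p_up_case - p_down_case)
  nri_noncases <- unname(p_down_non - p_up_non)
  structure(list(nri_cases = nri_cases, nri_noncases = nri_noncases,
                 nri_overall = nri_cases + nri_noncases,
                 estimator = "km-adjusted"),
            class = "nri_result")
}

#' Continuous (category-free) net reclassification improvement
#'
#' Movement is any increase (up) or decrease (down) in predicted risk;
#' the same case/noncase combination as the categorical NRI applies.
#' Case status is taken at the horizon; individuals censored event-free
#' before the horizon are excluded.
#'
#' @inheritParams build_reclass_table
#' @return an \code{nri_result}.
#' @export
continuous_nri <- function(old_risk, new_risk, time, event, horizon = 10) {
  st <- horizon_status(time, event, horizon)
  stopf(any(st$case) && any(st$noncase),
        "both cases and noncases are required")
  mv <- movement_cells(old_risk, new_risk, threshold = NULL)
  nri_cases <- (sum(mv$up & st$case) - sum(mv$down & st$case)) /
    sum(st$case)
  nri_noncases <- (sum(mv$down & st$noncase) - sum(mv$up & st$noncase)) /
    sum(st$noncase)
  structure(list(nri_cases = nri_cases, nri_noncases = nri_noncases,
                 nri_overall = nri_cases + nri_noncases,
                 estimator = "continuous"),
            class = "nri_result")
}

#' Integrated discrimination improvement
#'
#' The change, new model minus old, in discrimination slope: the
#' difference of mean predicted risk between cases and noncases,
#' \deqn{\mathrm{IDI} = (\bar{p}_{new,case} - \bar{p}_{new,noncase}) -
#'   (\bar{p}_{old,case} - \bar{p}_{old,noncase}).}
#'
#' @inheritParams build_reclass_table
#' @return an \code{idi_result} list with \code{idi} and the four cell
#'   means.
#' @export
idi <- function(old_risk, new_risk, time, event, horizon = 10) {
  st <- horizon_status(time, event, horizon)
  stopf(any(st$case) && any(st$noncase),
        "both cases and noncases are required")
  means <- c(old_case = mean(old_risk[st$case]),
             old_noncase = mean(old_risk[st$noncase]),
             new_case = mean(new_risk[st$case]),
             new_noncase = mean(new_risk[st$noncase]))
  structure(list(
    idi = unname((means["new_case"] - means["new_noncase"]) -
                   (means["old_case"] - means["old_noncase"])),
    means = means
  ), class = "idi_result")
}

#' @export
print.nri_result <- function(x, ...) {
  cat(sprintf("NRI (%s): cases %+.4f, noncases %+.4f, overall %+.4f\n",
              x$estimator, x$nri_cases, x$nri_noncases, x$nri_overall))
  invisible(x)
}

#' Bootstrap confidence intervals for reclassification metrics
#'
#' Nonparametric bootstrap over individuals: resamples the cohort with
#' replacement and recomputes the statistic, returning the percentile
#' 95\% interval.
#'
#' @param stat_fn function(index) -> numeric scalar, evaluated on a
#'   resample index vector into the cohort.
#' @param n cohort size.
#' @param B resamples (default 1000).
#' @param seed integer seed.
#' @return list with \code{ci} and the bootstrap \code{replicates}.
#' @export
bootstrap_ci <- function(stat_fn, n, B = 1000, seed = 1L) {
  set.seed(seed)
  reps <- vapply(seq_len(B),
                 function(b) stat_fn(sample.int(n, n, replace = TRUE)),
                 numeric(1))
  list(ci = unname(quantile(reps, c(0.025, 0.975), na.rm = TRUE)),
       replicates = reps)
}

#' Reclassification report comparing two risk models
#'
#' Computes the count-based table and NRI, the KM-adjusted NRI, the
#' continuous NRI, and the IDI, with optional bootstrap CIs for the
#' categorical case/noncase/overall NRI and IDI.
#'
#' @inheritParams build_reclass_table
#' @param boot_B bootstrap resamples (0 disables CIs).
#' @param seed bootstrap seed.
#' @return a \code{reclass_report} list.
#' @export
reclass_report <- function(old_risk, new_risk, threshold = 0.075,
                           time, event, horizon = 10, boot_B = 0,
                           seed = 1L) {
  tab <- build_reclass_table(old_risk, new_risk, threshold, time, event,
                             horizon)
  out <- list(
    table = tab,
    nri_categorical = categorical_nri(tab),
    nri_km = km_adjusted_nri(old_risk, new_risk, threshold, time, event,
                             horizon),
    nri_continuous = continuous_nri(old_risk, new_risk, time, event,
                                    horizon),
    idi = idi(old_risk, new_risk, time, event, horizon)
  )
  if (boot_B > 0) {
    n <- length(time)
    out$ci <- list(
      nri_overall = bootstrap_ci(function(i) {
        categorical_nri(build_reclass_table(
          old_risk[i], new_risk[i], threshold, time[i], event[i],
          horizon))$nri_overall
      }, n, boot_B, seed)$ci,
      idi = bootstrap_ci(function(i) {
        idi(old_risk[i], new_risk[i], time[i], event[i], horizon)$idi
      }, n, boot_B, stage_seed(seed, 1))$ci
    )
  }
  class(out) <- "reclass_report"
  out
}

#' @export
print.reclass_report <- function(x, ...) {
  print(x$table)
  print(x$nri_categorical)
  print(x$nri_km)
  print(x$nri_continuous)
  cat(sprintf("IDI: %+.4f\n", x$idi$idi))
  if (!is.null(x$ci)) {
    cat(sprintf("  95%% CI overall NRI [%.4f, %.4f], IDI [%.4f, %.4f]\n",
                x$ci$nri_overall[1], x$ci$nri_overall[2],
                x$ci$idi[1], x$ci$idi[2]))
  }
  invisible(x)
}
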