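#' Greedy LD clumping of summary statistics
#'
#' The standard clumping-and-thresholding index-variant scan: variants are
#' visited by ascending p-value (ties broken by ascending chromosome then
#' position, so results are reproducible); a variant is kept iff no
#' already-kept variant on the same chromosome within \code{window_kb}
#' kilobases has squared dosage correlation above \code{r2_threshold}
#' with it. LD is measured as squared Pearson correlation of dosages on
#' the supplied panel.
#'
#' @param ss a \code{summary_stats} data.frame (aligned).
#' @param ld a \code{geno_matrix} LD panel containing the ss variants, or
#'   a variant-by-variant correlation matrix with dimnames = variant ids.
#' @param r2_threshold squared-correlation threshold in [0, 1].
#' @param window_kb window in kilobases.
#' @return character vector of kept (index) variant ids, in the order
#'   they were kept.
#' @export
ld_clump <- function(ss, ld, r2_threshold = 0.1, window_kb = 250) {
  check_number(r2_threshold, "r2_threshold", 0, 1)
  check_number(window_kb, "window_kb", 0, Inf, open_lo = TRUE)
  if (nrow(ss) == 0) return(character(0))

  if (inherits(ld, "geno_matrix")) {
    present <- ss$id %in% ld$variants$id
    stopf(all(present), "%d ss variant(s) absent from the LD panel",
          sum(!present))
    R <- cor(ld$dosages[, match(ss$id, ld$variants$id), drop = FALSE])
    dimnames(R) <- list(ss$id, ss$id)
  } else {
    R <- as.matrix(ld)
    stopf(all(ss$id %in% rownames(R)), "LD matrix lacks some ss variants")
    R <- R[ss$id, ss$id, drop = FALSE]
  }
  R2 <- R^2
  R2[is.na(R2)] <- 0  # zero-variance variants cannot clump anything

  ord <- order(ss$p, ss$chr, ss$pos)
  kept <- integer(0)
  window <- window_kb * 1000
  for (i in ord) {
    if (length(kept)) {
      near <- kept[ss$chr[kept] == ss$chr[i] &
                     abs(ss$pos[kept] - ss$pos[i]) <= window]
      if (length(near) && any(R2[i, near] > r2_threshold)) next
    }
    kept <- c(kept, i)
  }
  ss$id[kept]
}

#' Clumping-and-thresholding weight sets over a parameter grid
#'
#' Runs [ld_clump()] once per r-squared threshold, then derives one
#' weight set per (p-threshold, r2) pair by restricting the index
#' variants to those with p <= the p-threshold; weights are the GWAS
#' betas. Candidates whose variant set is empty are dropped.
#'
#' @param ss aligned, QC'd \code{summary_stats}.
#' @param ld LD panel as in [ld_clump()].
#' @param p_thresholds vector of p-value cutoffs (inclusive).
#' @param r2_thresholds vector of clumping r-squared cutoffs.
#' @param window_kb clumping window.
#' @param label tag recorded in each candidate's provenance.
#' @return list of \code{prs_weights}, each with provenance
#'   \code{list(method = "C+T", source, p_threshold, r2_threshold,
#'   window_kb)}.
#' @export
ct_grid <- function(ss, ld,
                    p_thresholds = c(5e-8, 1e-6, 1e-4, 1e-3, 0.01,
                                     0.05, 0.1, 0.5, 1),
                    r2_thresholds = c(0.1, 0.2, 0.5),
                    window_kb = 250, label = "gwas") {
  out <- list()
  for (r2 in r2_thresholds) {
    kept <- ld_clump(ss, ld, r2_threshold = r2, window_kb = window_kb)
    idx <- ss[ss$id %in% kept, , drop = FALSE]
    for (pt in p_thresholds) {
      sel <- idx[idx$p <= pt, , drop = FALSE]
      if (nrow(sel) == 0) next
      w <- structure(
        data.frame(id = sel$id, effect_allele = sel$effect_allele,
                   weight = sel$beta, stringsAsFactors = FALSE),
        provenance = list(method = "C+T", source = label,
                          p_threshold = pt, r2_threshold = r2,
                          window_kb = window_kb),
        class = c("prs_weights", "data.frame"))
      out[[sprintf("%s_CT_p%g_r2%g", label, pt, r2)]] <- w
    }
  }
  out
}

#' Score individuals with a PRS weight set
#'
#' \eqn{\mathrm{score}_i = \sum_v w_v \, \mathrm{dosage}_{iv}} over the
#' weight variants found in the genotype matrix. Weight effect alleles
#' must match the genotype alternate alleles (alignment is upstream);
#' a mismatch is an error. Weight variants absent from the genotypes are
#' dropped and tallied in the \code{"n_missing"} attribute.
#'
#' @param geno a \code{geno_matrix}.
#' @param w a \code{prs_weights} data.frame.
#' @return numeric per-individual score vector.
#' @export
prs_score <- function(geno, w) {
  idx <- match(w$id, geno$variants$id)
  found <- !is.na(idx)
  if (any(found)) {
    mism <- w$effect_allele[found] != geno$variants$alt[idx[found]]
    stopf(!any(mism),
          "effect-allele mismatch with genotype metadata at %d variant(s), e.g. %s",
          sum(mism), w$id[found][which(mism)[1]])
  }
  score <- if (any(found)) {
    drop(geno$dosages[, idx[found], drop = FALSE] %*% w$weight[found])
  } else {
    numeric(nrow(geno$dosages))
  }
  attr(score, "n_missing") <- sum(!found)
  score
}

#' Tune candidate PRS weight sets by AUC on the tuning case-control set
#'
#' For every candidate, scores the tuning genotypes, fits a logistic
#' regression of case status on the score plus the baseline covariates,
#' and records the AUC of the fitted probabilities. The best candidate
#' per method/source pair (from provenance) is returned; ties are broken
#' toward the simpler model: larger p-threshold, then larger r-squared
#' threshold. Complete separation triggers a ridge-stabilized refit,
#' flagged in the result.
#'
#' @param candidates list of \code{prs_weights}.
#' @param geno_tuning tuning-set \code{geno_matrix}.
#' @param case 0/1 case-status vector.
#' @param covariates optional data.frame of baseline covariates (e.g. the
#'   clinical risk linear predictor, principal components, batch).
#' @return list of \code{prs_component} objects (weights, score,
#'   tuning_auc, ridged flag), one per method/source, sorted by
#'   decreasing AUC. The full grid table is in attribute \code{"grid"}.
#' @export
tune_grid <- function(candidates, geno_tuning, case, covariates = NULL) {
  stopf(length(candidates) >= 1, "no candidates to tune")
  stopf(any(case == 1) && any(case == 0),
        "tuning set needs both cases and controls")
  rows <- lapply(names(candidates), function(nm) {
    w <- candidates[[nm]]
    sc <- prs_score(geno_tuning, w)
    X <- data.frame(score = sc)
    if (!is.null(covariates)) X <- cbind(X, covariates)
    fit <- fit_logistic(X, case)
    prov <- attr(w, "provenance") %||% list()
    data.frame(name = nm,
               method = prov$method %||% "external",
               source = prov$source %||% "unknown",
               p_threshold = prov$p_threshold %||% NA_real_,
               r2_threshold = prov$r2_threshold %||% NA_real_,
               n_variants = nrow(w),
               auc = auc_rank(fit$fitted, case),
               ridged = fit$ridged,
               stringsAsFactors = FALSE)
  })
  grid <- do.call(rbind, rows)

  key <- paste(grid$method, grid$source)
  best <- lapply(split(seq_len(nrow(grid)), key), function(i) {
    g <- grid[i, , drop = FALSE]
    # max AUC; ties toward larger p-threshold, then larger r2
    ord <- order(-g$auc, -ifelse(is.na(g$p_threshold), 0, g$p_threshold),
                 -ifelse(is.na(g$r2_threshold), 0, g$r2_threshold))
    g$name[ord[1]]
  })
  comps <- lapply(best, function(nm) {
    w <- candidates[[nm]]
    structure(list(
      name = nm,
      weights = w,
      score = as.numeric(prs_score(geno_tuning, w)),
      tuning_auc = grid$auc[grid$name == nm],
      ridged = grid$ridged[grid$name == nm]
    ), class = "prs_component")
  })
  comps <- comps[order(-vapply(comps, `[[`, numeric(1), "tuning_auc"))]
  attr(comps, "grid") <- grid[order(-grid$auc), ]
  comps
}

#' @export
print.prs_component <- function(x, ...) {
  cat(sprintf("PRS component '%s': %d variants, tuning AUC %.3f%s\n",
              x$name, nrow(x$weights), x$tuning_auc,
              if (isTRUE(x$ridged)) " (ridge-stabilized)" else ""))
  invisible(x)
}

#' Forward-select PRS components and fit the integrated PRS
#'
#' Greedy forward selection on tuning-set AUC: start from the single best
#' component (logistic AUC with baseline covariates); at each step add the
#' component with the largest AUC increase; stop when the best increase is
#' \code{min_delta} or less. The final component coefficients come from
#' one joint logistic fit of case status on all selected component scores
#' plus covariates, and the integrated score is
#' \eqn{\sum_j \hat\beta_j \mathrm{PRS}_j}.
#'
#' @param components list of \code{prs_component} (e.g. from
#'   [tune_grid()], possibly plus imported external components).
#' @param case 0/1 case status on the tuning set.
#' @param covariates optional baseline covariate data.frame.
#' @param min_delta minimum AUC improvement to keep adding components.
#' @return an \code{integrated_prs}: selected components, \code{beta_hat},
#'   \code{intercept}, tuning \code{score}, \code{auc} and the selection
#'   \code{trace}.
#' @export
forward_select_and_integrate <- function(components, case,
                                         covariates = NULL,
                                         min_delta = 1e-4) {
  stopf(length(components) >= 1, "need at least one component")
  scores <- vapply(components, `[[`, numeric(length(case)), "score")
  colnames(scores) <- vapply(components, `[[`, character(1), "name")

  auc_of <- function(sel) {
    X <- data.frame(scores[, sel, drop = FALSE])
    if (!is.null(covariates)) X <- cbind(X, covariates)
    fit <- fit_logistic(X, case)
    auc_rank(fit$fitted, case)
  }

  selected <- integer(0)
  remaining <- seq_along(components)
  trace <- data.frame(step = integer(0), added = character(0),
                      auc = numeric(0))
  current_auc <- -Inf
  repeat {
    if (!length(remaining)) break
    trial <- vapply(remaining, function(j) auc_of(c(selected, j)),
                    numeric(1))
    j_best <- remaining[which.max(trial)]
    gain <- max(trial) - if (length(selected)) current_auc else -Inf
    if (length(selected) && gain <= min_delta) break
    selected <- c(selected, j_best)
    remaining <- setdiff(remaining, j_best)
    current_auc <- max(trial)
    trace <- rbind(trace, data.frame(
      step = length(selected), added = colnames(scores)[j_best],
      auc = current_auc, stringsAsFactors = FALSE))
  }

  X <- data.frame(scores[, selected, drop = FALSE])
  if (!is.null(covariates)) X <- cbind(X, covariates)
  fit <- fit_logistic(X, case)
  beta_hat <- fit$coef[colnames(scores)[selected]]
  # guard against name mangling by data.frame()
  if (anyNA(beta_hat)) {
    beta_hat <- fit$coef[make.names(colnames(scores)[selected])]
    names(beta_hat) <- colnames(scores)[selected]
  }
  integrated <- drop(scores[, selected, drop = FALSE] %*% beta_hat)

  structure(list(
    components = components[selected],
    beta_hat = beta_hat,
    intercept = unname(fit$coef[1]),
    score = integrated,
    auc = current_auc,
    trace = trace,
    ridged = fit$ridged
  ), class = "integrated_prs")
}

#' Apply an integrated PRS to a new genotype matrix
#'
#' Recomputes each selected component's score on the new genotypes and
#' combines them with the fitted coefficients.
#'
#' @param iprs an \code{integrated_prs}.
#' @param geno a \code{geno_matrix}.
#' @return per-individual integrated score.
#' @export
predict_integrated <- function(iprs, geno) {
  comp_scores <- vapply(iprs$components,
                        function(cp) as.numeric(prs_score(geno, cp$weights)),
                        numeric(nrow(geno$dosages)))
  drop(as.matrix(comp_scores) %*% iprs$beta_hat)
}

#' @export
print.integrated_prs <- function(x, ...) {
  cat(sprintf("Integrated PRS: %d component(s), tuning AUC %.3f\n",
              length(x$components), x$auc))
  for (i in seq_along(x$components)) {
    cat(sprintf("  %-30s beta_hat = %+.4f\n",
                x$components[[i]]$name, x$beta_hat[i]))
  }
  invisible(x)
}
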