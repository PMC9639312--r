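#' Define a term of a clinical risk equation
#'
#' One additive term of the linear predictor: a coefficient times a
#' transformed covariate (or product of covariates for interactions).
#' Supported transforms: \code{"identity"}, \code{"log"},
#' \code{"square"}; for multi-covariate terms the transform applies to
#' each covariate before the product is taken.
#'
#' @param coef numeric coefficient.
#' @param vars character vector of covariate names entering the term.
#' @param transform transform name.
#' @return a \code{risk_term} list.
#' @export
risk_term <- function(coef, vars, transform = "identity") {
  stopf(is.numeric(coef) && length(coef) == 1 && is.finite(coef),
        "term coefficient must be a finite number")
  stopf(transform %in% c("identity", "log", "square"),
        "unknown transform '%s'", transform)
  structure(list(coef = coef, vars = as.character(vars),
                 transform = transform), class = "risk_term")
}

apply_transform <- function(x, transform) {
  switch(transform, identity = x, log = log(x), square = x^2)
}

#' Build a pooled-cohort-equation-style risk equation
#'
#' A generic proportional-hazards absolute-risk engine: each stratum
#' (typically sex by race group) carries its own term list, the mean
#' linear predictor used for centering, and the 10-year baseline survival
#' probability. Coefficient values are supplied by the caller or a config
#' file — none are embedded, since published equation coefficients come
#' from external sources.
#'
#' @param strata named list; each element is a list with \code{terms}
#'   (list of [risk_term()]), \code{mean_lp}, and
#'   \code{baseline_survival_10y} in (0, 1). Stratum names are
#'   \code{"<sex>_<race_black>"} (e.g. \code{"female_0"}), or the single
#'   name \code{"all"} for an unstratified equation.
#' @return a \code{risk_equation}.
#' @export
risk_equation <- function(strata) {
  stopf(is.list(strata) && length(strata) >= 1 && !is.null(names(strata)),
        "strata must be a named list")
  for (nm in names(strata)) {
    s <- strata[[nm]]
    stopf(is.list(s$terms) && length(s$terms) >= 1,
          "stratum '%s' has no terms", nm)
    check_number(s$mean_lp, paste0(nm, "$mean_lp"))
    check_number(s$baseline_survival_10y,
                 paste0(nm, "$baseline_survival_10y"), 0, 1,
                 open_lo = TRUE, open_hi = TRUE)
  }
  structure(list(strata = strata), class = "risk_equation")
}

pick_stratum <- function(row, eq) {
  if (length(eq$strata) == 1L && names(eq$strata) == "all") {
    return(eq$strata[["all"]])
  }
  sex <- if (!is.null(row[["sex"]])) as.character(row[["sex"]]) else {
    if (isTRUE(row[["sex_male"]] == 1)) "male" else "female"
  }
  key <- sprintf("%s_%d", sex, as.integer(row[["race_black"]] %||% 0))
  s <- eq$strata[[key]]
  stopf(!is.null(s), "no stratum '%s' in the risk equation", key)
  s
}

#' Linear predictor of a clinical risk equation
#'
#' Sums coefficient times transformed covariate (products for
#' interaction terms) over the stratum's terms. Physiological range
#' violations (age outside 18-120, SBP outside 60-250, cholesterol
#' outside 50-500) warn but do not stop; a missing covariate is an error
#' naming the field, matching the convention of excluding individuals
#' with missing predictors upstream.
#'
#' @param row one-row data.frame or named list of covariates.
#' @param eq a [risk_equation()].
#' @return the linear predictor (numeric scalar).
#' @export
linear_predictor <- function(row, eq) {
  s <- pick_stratum(row, eq)
  warn_range <- function(nm, x, lo, hi) {
    if (!is.na(x) && (x < lo || x > hi)) {
      warning(sprintf("%s = %g outside physiological range [%g, %g]",
                      nm, x, lo, hi))
    }
  }
  if (!is.null(row[["age"]])) warn_range("age", row[["age"]], 18, 120)
  if (!is.null(row[["sbp"]])) warn_range("sbp", row[["sbp"]], 60, 250)
  for (nm in intersect(c("total_chol", "hdl_chol"), names(row))) {
    warn_range(nm, row[[nm]], 50, 500)
  }
  lp <- 0
  for (term in s$terms) {
    val <- 1
    for (v in term$vars) {
      x <- row[[v]]
      stopf(!is.null(x) && !is.na(x),
            "missing covariate '%s' required by the risk equation", v)
      val <- val * apply_transform(x, term$transform)
    }
    lp <- lp + term$coef * val
  }
  lp
}

#' Ten-year absolute risk from a risk equation
#'
#' The proportional-hazards identity
#' \eqn{\mathrm{risk} = 1 - S_0^{\exp(\mathrm{LP} - \bar{\mathrm{LP}})}}
#' with the stratum's 10-year baseline survival and mean linear
#' predictor.
#'
#' @param row covariate row (or data.frame of rows).
#' @param eq a [risk_equation()].
#' @return 10-year event probability in [0, 1] (vector if \code{row} has
#'   several rows).
#' @export
ten_year_risk <- function(row, eq) {
  if (is.data.frame(row) && nrow(row) > 1) {
    return(vapply(seq_len(nrow(row)),
                  function(i) ten_year_risk(row[i, , drop = FALSE], eq),
                  numeric(1)))
  }
  s <- pick_stratum(row, eq)
  lp <- linear_predictor(row, eq)
  1 - s$baseline_survival_10y^exp(lp - s$mean_lp)
}

#' Classify an absolute risk against a treatment threshold
#'
#' @param risk probabilities in [0, 1].
#' @param threshold decision threshold; risk at or above it is
#'   \code{"high"} (the boundary belongs to the high-risk category).
#' @return factor with levels \code{low}, \code{high}.
#' @export
classify_risk <- function(risk, threshold = 0.075) {
  stopf(all(risk >= 0 & risk <= 1, na.rm = TRUE), "risks must be in [0, 1]")
  factor(ifelse(risk >= threshold, "high", "low"),
         levels = c("low", "high"))
}

#' Apply a risk equation to a whole covariate table
#'
#' Vectorized counterpart of [linear_predictor()] and [ten_year_risk()]:
#' computes the linear predictor, 10-year risk, and risk class for every
#' row of a covariate data.frame.
#'
#' @param covariates data.frame of covariate rows.
#' @param eq a [risk_equation()].
#' @param threshold classification threshold passed to [classify_risk()].
#' @return data.frame with columns \code{lp}, \code{risk10y},
#'   \code{class}.
#' @export
equation_risk <- function(covariates, eq, threshold = 0.075) {
  n <- nrow(covariates)
  lp <- numeric(n)
  risk <- numeric(n)
  stratum_key <- if (length(eq$strata) == 1L &&
                       names(eq$strata) == "all") {
    rep("all", n)
  } else {
    sex <- if (!is.null(covariates[["sex"]])) {
      as.character(covariates[["sex"]])
    } else {
      ifelse(covariates[["sex_male"]] == 1, "male", "female")
    }
    race <- as.integer(covariates[["race_black"]] %||% rep(0L, n))
    sprintf("%s_%d", sex, race)
  }
  for (key in unique(stratum_key)) {
    s <- eq$strata[[key]]
    stopf(!is.null(s), "no stratum '%s' in the risk equation", key)
    rows <- which(stratum_key == key)
    lp_s <- numeric(length(rows))
    for (term in s$terms) {
      val <- rep(1, length(rows))
      for (v in term$vars) {
        x <- covariates[[v]]
        stopf(!is.null(x), "missing covariate '%s' required by the risk equation", v)
        stopf(!anyNA(x[rows]), "missing covariate '%s' required by the risk equation", v)
        val <- val * apply_transform(x[rows], term$transform)
      }
      lp_s <- lp_s + term$coef * val
    }
    lp[rows] <- lp_s
    risk[rows] <- 1 - s$baseline_survival_10y^exp(lp_s - s$mean_lp)
  }
  data.frame(lp = lp, risk10y = risk,
             class = classify_risk(risk, threshold))
}

#' Read a risk equation from a JSON config file
#'
#' The config mirrors [risk_equation()]: a \code{strata} object whose
#' entries carry \code{terms} (each with \code{coef}, \code{vars},
#' \code{transform}), \code{mean_lp}, and
#' \code{baseline_survival_10y}. A template with empty slots ships in
#' \code{inst/extdata/risk_equation_template.json}.
#'
#' @param path JSON path.
#' @return a \code{risk_equation}.
#' @export
read_risk_equation <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  stopf(!is.null(cfg$strata), "config %s has no 'strata' object", path)
  strata <- lapply(cfg$strata, function(s) {
    list(
      terms = lapply(s$terms, function(t) {
        risk_term(coef = as.numeric(t$coef),
                  vars = unlist(t$vars),
                  transform = t$transform %||% "identity")
      }),
      mean_lp = as.numeric(s$mean_lp),
      baseline_survival_10y = as.numeric(s$baseline_survival_10y)
    )
  })
  risk_equation(strata)
}

#' Risk equation matching the synthetic generator's clinical model
#'
#' Builds the "published" clinical equation for a synthetic study: one
#' unstratified stratum whose terms are the generator's clinical log
#' hazard ratios applied to generating-constant-standardized covariates,
#' with the 10-year baseline survival taken from the configured Weibull
#' baseline. In the synthetic world this plays the role of externally
#' published pooled-cohort coefficients.
#'
#' @param cfg a [sim_config()].
#' @return a \code{risk_equation}.
#' @export
sim_risk_equation <- function(cfg) {
  terms <- list()
  for (nm in names(cfg$clinical_log_hrs)) {
    mg <- COVARIATE_MARGINALS[[nm]]
    stopf(!is.null(mg), "no marginal distribution for covariate '%s'", nm)
    coef <- cfg$clinical_log_hrs[[nm]]
    # expand coef * (x - mu)/sigma into coef/sigma * x, constant absorbed
    # into mean_lp (binaries enter raw)
    scale <- switch(mg$type,
                    uniform = (mg$max - mg$min) / sqrt(12),
                    normal = mg$sd,
                    bernoulli = 1)
    terms[[nm]] <- risk_term(coef / scale, nm)
    shift <- switch(mg$type,
                    uniform = (mg$min + mg$max) / 2,
                    normal = mg$mean,
                    bernoulli = mg$p)
    attr(terms[[nm]], "shift") <- coef * shift / scale
  }
  mean_lp <- sum(vapply(terms, function(t) attr(t, "shift"), numeric(1)))
  s0 <- exp(-(10 / cfg$baseline_scale)^cfg$baseline_shape)
  risk_equation(list(all = list(terms = terms, mean_lp = mean_lp,
                                baseline_survival_10y = s0)))
}
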