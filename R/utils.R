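#' @keywords internal
"_PACKAGE"

#' @importFrom stats rnorm runif rbinom qnorm pnorm pchisq quantile sd var cor
#'   glm binomial coef fitted predict setNames complete.cases ks.test
#'   plogis ave as.formula cov
#' @importFrom utils read.delim write.table head
NULL

# Single check helper: stop with the caller's message if cond is not TRUE.
stopf <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
}

check_number <- function(x, name, lo = -Inf, hi = Inf,
                         open_lo = FALSE, open_hi = FALSE) {
  stopf(is.numeric(x) && length(x) == 1L && is.finite(x),
        "'%s' must be a single finite number", name)
  ok_lo <- if (open_lo) x > lo else x >= lo
  ok_hi <- if (open_hi) x < hi else x <= hi
  stopf(ok_lo && ok_hi, "'%s' = %g outside its legal range", name, x)
  invisible(x)
}

check_count <- function(x, name) {
  check_number(x, name, lo = 1)
  stopf(x == round(x), "'%s' must be a whole number", name)
  invisible(as.integer(x))
}

#' Derive a per-stage seed from a global seed
#'
#' A single pipeline seed fans out to per-stage seeds through a fixed
#' counter offset, so any stage can be re-run in isolation and reproduce
#' its output exactly. Offsets are small primes times the counter to keep
#' derived seeds distinct and below the 32-bit integer limit.
#'
#' @param seed global integer seed
#' @param stage integer stage counter (>= 0)
#' @return an integer seed
#' @export
stage_seed <- function(seed, stage) {
  seed <- check_count(seed, "seed")
  stage <- check_number(stage, "stage", lo = 0)
  as.integer((as.numeric(seed) + 104729 * stage) %% 2147483647L)
}

# Mann-Whitney / rank form of the AUC of a score against a binary label.
# Exact (handles ties by midranks); cross-checked against pROC in tests.
auc_rank <- function(score, y) {
  y <- as.integer(y)
  stopf(all(y %in% c(0L, 1L)), "labels must be 0/1")
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  stopf(n1 > 0 && n0 > 0, "AUC needs both cases and controls")
  r <- rank(score)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Ridge-stabilized logistic IRLS, used only as a fallback when glm reports
# separation (fitted probabilities of 0/1). Small fixed penalty; intercept
# unpenalized.
logistic_ridge <- function(X, y, lambda = 1e-3, maxit = 50L, tol = 1e-10) {
  X <- cbind(`(Intercept)` = 1, as.matrix(X))
  p <- ncol(X)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  b <- numeric(p)
  for (i in seq_len(maxit)) {
    eta <- drop(X %*% b)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-10)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    b_new <- solve(XtW %*% X + pen, XtW %*% z)
    if (max(abs(b_new - b)) < tol) {
      b <- b_new
      break
    }
    b <- b_new
  }
  fitted <- plogis(drop(X %*% b))
  list(coef = drop(b), fitted = fitted)
}

# Fit logistic regression of y on columns of X; fall back to the ridge
# fit when glm warns about separation or fails to converge.
fit_logistic <- function(X, y) {
  X <- as.data.frame(X)
  dat <- cbind(.y = y, X)
  separated <- FALSE
  fit <- withCallingHandlers(
    glm(.y ~ ., data = dat, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities|did not converge", conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  if (separated) {
    rf <- logistic_ridge(as.matrix(X), y)
    return(list(coef = rf$coef, fitted = rf$fitted, ridged = TRUE))
  }
  list(coef = coef(fit), fitted = fitted(fit), ridged = FALSE)
}
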