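# Independent naive reference implementations used as oracles. These stay
# deliberately dumb (explicit loops, no shared code with the package).

# Greedy clumping, re-derived from the definition: visit by ascending p
# (ties: chr then pos), keep unless some kept variant on the same
# chromosome within the window exceeds the r2 threshold.
oracle_clump <- function(ss, R2, r2_threshold, window_kb) {
  ord <- order(ss$p, ss$chr, ss$pos)
  kept <- c()
  for (i in ord) {
    ok <- TRUE
    for (k in kept) {
      if (ss$chr[k] == ss$chr[i] &&
            abs(ss$pos[k] - ss$pos[i]) <= window_kb * 1000 &&
            R2[ss$id[i], ss$id[k]] > r2_threshold) {
        ok <- FALSE
        break
      }
    }
    if (ok) kept <- c(kept, i)
  }
  ss$id[kept]
}

# PRS scoring by explicit double loop.
oracle_score <- function(dosages, variant_ids, weights, weight_ids) {
  n <- nrow(dosages)
  out <- numeric(n)
  for (i in seq_len(n)) {
    s <- 0
    for (k in seq_along(weight_ids)) {
      j <- which(variant_ids == weight_ids[k])
      if (length(j) == 1) s <- s + weights[k] * dosages[i, j]
    }
    out[i] <- s
  }
  out
}

# Harrell's C by exhaustive pair enumeration: a pair is comparable iff the
# shorter time belongs to an event; tied scores count half.
oracle_cindex <- function(time, event, score) {
  n <- length(time)
  conc <- 0
  comp <- 0
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (time[i] == time[j]) next
      short <- if (time[i] < time[j]) i else j
      long <- if (time[i] < time[j]) j else i
      if (event[short] != 1) next
      comp <- comp + 1
      if (score[short] > score[long]) conc <- conc + 1
      else if (score[short] == score[long]) conc <- conc + 0.5
    }
  }
  conc / comp
}

# Random small summary-stat instance over one LD block for clumping tests.
random_clump_instance <- function(n_var, seed) {
  set.seed(seed)
  n <- 400
  z <- matrix(rnorm(n * n_var), n, n_var)
  shared <- rnorm(n)
  lam <- runif(1, 0, 0.95)
  X <- sqrt(lam) * shared + sqrt(1 - lam) * z
  dos <- (X < 0) + (matrix(rnorm(n * n_var), n, n_var) < 0)
  ids <- sprintf("v%03d", seq_len(n_var))
  colnames(dos) <- ids
  ss <- data.frame(
    id = ids, chr = 1L,
    pos = as.integer(sort(sample.int(400000, n_var))),
    effect_allele = "A", other_allele = "G",
    eaf = runif(n_var, 0.05, 0.95),
    beta = rnorm(n_var, 0, 0.05),
    se = runif(n_var, 0.01, 0.05),
    stringsAsFactors = FALSE
  )
  ss$p <- 2 * pnorm(-abs(ss$beta / ss$se))
  ss$n <- 10000L
  ss$info <- 1
  R <- cor(dos)
  R[is.na(R)] <- 0
  diag(R) <- 1
  list(ss = ss, R = R, R2 = R^2)
}

# Weibull PH survival data with known log HR for a standard-normal score.
sim_ph_data <- function(n, log_hr, shape = 1.3, scale = 60,
                        censor = 12, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  u <- runif(n)
  t <- scale * (-log(u) / exp(log_hr * x))^(1 / shape)
  list(time = pmin(t, censor), event = as.integer(t <= censor),
       score = x, true_time = t)
}
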