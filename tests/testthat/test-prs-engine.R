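test_that("clumping keeps the stronger of a perfect-LD pair and all independent variants", {
  ss <- data.frame(id = c("a", "b"), chr = 1L, pos = c(100000L, 110000L),
                   effect_allele = "A", other_allele = "G",
                   eaf = 0.3, beta = c(0.1, 0.05), se = 0.01,
                   p = c(1e-8, 1e-4), n = 1000L, info = 1,
                   stringsAsFactors = FALSE)
  R <- matrix(1, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_identical(ld_clump(ss, R, r2_threshold = 0.1, window_kb = 250),
                   "a")

  R0 <- diag(2)
  dimnames(R0) <- dimnames(R)
  expect_setequal(ld_clump(ss, R0, r2_threshold = 0.1, window_kb = 250),
                  c("a", "b"))

  expect_identical(ld_clump(ss[0, ], R, 0.1, 250), character(0))
  expect_error(ld_clump(ss, R, r2_threshold = 1.5), "r2_threshold")
})

test_that("clumping equals the brute-force greedy oracle on random instances", {
  for (seed in 1:100) {
    inst <- random_clump_instance(n_var = sample(10:50, 1), seed = seed)
    r2 <- sample(c(0.05, 0.1, 0.3, 0.6), 1)
    win <- sample(c(50, 150, 400), 1)
    got <- ld_clump(inst$ss, inst$R, r2_threshold = r2, window_kb = win)
    want <- oracle_clump(inst$ss, inst$R2, r2_threshold = r2,
                         window_kb = win)
    expect_identical(got, want, label = sprintf("instance seed %d", seed))
  }
})

test_that("clumped selection is invariant to input row order", {
  inst <- random_clump_instance(30, seed = 202)
  shuf <- inst$ss[sample(nrow(inst$ss)), ]
  expect_setequal(ld_clump(inst$ss, inst$R, 0.2, 250),
                  ld_clump(shuf, inst$R, 0.2, 250))
})

test_that("scoring is exact, linear, and guards allele metadata", {
  geno <- structure(list(
    dosages = matrix(c(0, 1, 2), 3, 1, dimnames = list(NULL, "v1")),
    variants = data.frame(id = "v1", chr = 1L, pos = 100L, ref = "A",
                          alt = "G", stringsAsFactors = FALSE)
  ), class = "geno_matrix")
  w <- data.frame(id = "v1", effect_allele = "G", weight = 0.5)
  expect_equal(as.numeric(prs_score(geno, w)), c(0, 0.5, 1.0))

  w0 <- w; w0$weight <- 0
  expect_equal(as.numeric(prs_score(geno, w0)), c(0, 0, 0))

  wbad <- w; wbad$effect_allele <- "A"
  expect_error(prs_score(geno, wbad), "mismatch")

  wmiss <- rbind(w, data.frame(id = "nope", effect_allele = "G",
                               weight = 1))
  sc <- prs_score(geno, wmiss)
  expect_equal(attr(sc, "n_missing"), 1L)
  expect_equal(as.numeric(sc), c(0, 0.5, 1.0))
})

test_that("scoring matches the naive double-loop oracle on a random instance", {
  set.seed(55)
  n <- 20; m <- 30
  dos <- matrix(sample(0:2, n * m, replace = TRUE), n, m)
  ids <- sprintf("v%02d", 1:m)
  colnames(dos) <- ids
  geno <- structure(list(
    dosages = dos,
    variants = data.frame(id = ids, chr = 1L, pos = seq_len(m) * 1000L,
                          ref = "A", alt = "G", stringsAsFactors = FALSE)
  ), class = "geno_matrix")
  pick <- sample(ids, 18)
  w <- data.frame(id = pick, effect_allele = "G",
                  weight = rnorm(18), stringsAsFactors = FALSE)
  got <- as.numeric(prs_score(geno, w))
  want <- oracle_score(dos, ids, w$weight, w$id)
  expect_equal(got, want, tolerance = 1e-12)

  # linearity: score(w1 + w2) = score(w1) + score(w2)
  w1 <- w; w2 <- w
  w2$weight <- rnorm(18)
  wsum <- w; wsum$weight <- w1$weight + w2$weight
  expect_equal(as.numeric(prs_score(geno, wsum)),
               as.numeric(prs_score(geno, w1)) +
                 as.numeric(prs_score(geno, w2)),
               tolerance = 1e-10)
})

# A tiny genotype world reused by the tuning tests: the liability is
# driven by the first 40 variants; the last 40 are independent of it, so
# weight sets confined to them are genuine pure-noise scores.
tuning_world <- function(n, seed) {
  set.seed(seed)
  m <- 80
  m_causal <- 40
  dos <- matrix(rbinom(n * m, 2, 0.3), n, m)
  ids <- sprintf("v%02d", 1:m)
  colnames(dos) <- ids
  geno <- structure(list(
    dosages = dos,
    variants = data.frame(id = ids, chr = 1L, pos = seq_len(m) * 1e5L,
                          ref = "A", alt = "G", stringsAsFactors = FALSE)
  ), class = "geno_matrix")
  beta <- c(rnorm(m_causal, 0, 0.3), rep(0, m - m_causal))
  liab <- scale(dos %*% beta) * sqrt(0.5) + rnorm(n, 0, sqrt(0.5))
  case <- as.integer(liab > quantile(liab, 0.5))
  weights <- function(wvec, tag) {
    structure(data.frame(id = ids, effect_allele = "G", weight = wvec,
                         stringsAsFactors = FALSE),
              provenance = list(method = "C+T", source = tag,
                                p_threshold = 1, r2_threshold = 0.1),
              class = c("prs_weights", "data.frame"))
  }
  list(geno = geno, beta = beta, m_causal = m_causal, case = case,
       weights = weights)
}

test_that("tuning selects the informative candidate over pure noise", {
  correct <- 0
  for (seed in 1:12) {
    tw <- tuning_world(4000, seed)
    noise_w <- c(rep(0, tw$m_causal), rnorm(40, 0, 0.3))
    cands <- list(true = tw$weights(tw$beta, "true"),
                  noise = tw$weights(noise_w, "noise"))
    comps <- tune_grid(cands, tw$geno, tw$case)
    best <- comps[[1]]
    if (grepl("true", best$name)) correct <- correct + 1
    grid <- attr(comps, "grid")
    noise_auc <- grid$auc[grepl("noise", grid$name)]
    expect_gte(noise_auc, 0.45)
    expect_lte(noise_auc, 0.55)
  }
  expect_equal(correct, 12)
})

test_that("a single tuning candidate is returned regardless of AUC, with ties broken simple", {
  tw <- tuning_world(500, 3)
  one <- tune_grid(list(only = tw$weights(rnorm(40), "x")), tw$geno,
                   tw$case)
  expect_length(one, 1)
  expect_identical(one[[1]]$name, "only")

  # identical weight sets differing only in declared p-threshold: the
  # larger (simpler) threshold wins the tie
  wA <- tw$weights(tw$beta, "same")
  attr(wA, "provenance")$p_threshold <- 0.01
  wB <- tw$weights(tw$beta, "same")
  attr(wB, "provenance")$p_threshold <- 0.5
  comps <- tune_grid(list(strict = wA, loose = wB), tw$geno, tw$case)
  expect_identical(comps[[1]]$name, "loose")
})

test_that("forward selection drops duplicates and integration satisfies the nested-deviance property", {
  tw <- tuning_world(3000, 17)
  comp <- function(name, wvec) {
    w <- tw$weights(wvec, name)
    structure(list(name = name, weights = w,
                   score = as.numeric(prs_score(tw$geno, w)),
                   tuning_auc = NA_real_, ridged = FALSE),
              class = "prs_component")
  }
  dup <- comp("dup1", tw$beta)
  dups <- list(dup, comp("dup2", tw$beta), comp("dup3", tw$beta))
  sel <- forward_select_and_integrate(dups, tw$case)
  expect_length(sel$components, 1)

  # single component: integrated score preserves the ranking exactly
  single <- forward_select_and_integrate(list(dup), tw$case)
  expect_equal(rank(single$score), rank(sign(single$beta_hat[1]) * dup$score))
  expect_equal(single$score,
               as.numeric(single$beta_hat[1] * dup$score),
               tolerance = 1e-10)
})

test_that("two independent informative components both enter and lower the deviance", {
  dev_of <- function(fitted, y) {
    -2 * sum(y * log(fitted) + (1 - y) * log(1 - fitted))
  }
  for (seed in 1:5) {
    set.seed(seed * 100)
    n <- 6000
    s1 <- rnorm(n); s2 <- rnorm(n)
    liab <- 0.6 * s1 + 0.6 * s2 + rnorm(n)
    case <- as.integer(liab > median(liab))
    mk <- function(name, sc) structure(
      list(name = name, weights = NULL, score = sc, tuning_auc = NA_real_,
           ridged = FALSE), class = "prs_component")
    sel <- forward_select_and_integrate(list(mk("c1", s1), mk("c2", s2)),
                                        case)
    expect_length(sel$components, 2)

    fit12 <- glm(case ~ s1 + s2, family = binomial())
    fit1 <- glm(case ~ s1, family = binomial())
    fit2 <- glm(case ~ s2, family = binomial())
    expect_lt(dev_of(fitted(fit12), case), dev_of(fitted(fit1), case))
    expect_lt(dev_of(fitted(fit12), case), dev_of(fitted(fit2), case))
    # the integrated score is the joint-fit linear combination
    expect_equal(sel$score,
                 as.numeric(cbind(s1, s2) %*% coef(fit12)[c("s1", "s2")]),
                 tolerance = 1e-6)
  }
})

test_that("C+T grid candidates carry provenance and respect the p cutoffs", {
  inst <- random_clump_instance(40, seed = 77)
  cands <- ct_grid(inst$ss, inst$R, p_thresholds = c(1e-3, 0.1, 1),
                   r2_thresholds = c(0.2), label = "demo")
  expect_gt(length(cands), 0)
  for (w in cands) {
    prov <- attr(w, "provenance")
    expect_identical(prov$method, "C+T")
    p_of <- inst$ss$p[match(w$id, inst$ss$id)]
    expect_true(all(p_of <= prov$p_threshold))
  }
  # the p = 1 candidate holds exactly the clumped index set
  full <- cands[[grep("p1_", names(cands))]]
  expect_setequal(full$id, ld_clump(inst$ss, inst$R, 0.2, 250))
})

test_that("weight files round-trip through the scoring format", {
  w <- structure(data.frame(id = c("v1", "v2"), effect_allele = c("G", "C"),
                            weight = c(0.12, -0.05),
                            stringsAsFactors = FALSE),
                 provenance = list(method = "external", source = "demo"),
                 class = c("prs_weights", "data.frame"))
  tmp <- tempfile(fileext = ".tsv")
  write_weights(w, tmp)
  back <- read_weights(tmp)
  expect_equal(as.data.frame(back), as.data.frame(w), ignore_attr = TRUE)
  expect_identical(attr(back, "provenance")$method, "external")
})
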