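make_ss <- function(...) {
  base <- data.frame(
    id = c("v1", "v2", "v3", "v4"),
    chr = c(1L, 1L, 2L, 2L),
    pos = c(100L, 5000L, 100L, 9000L),
    effect_allele = c("G", "C", "A", "T"),
    other_allele = c("A", "T", "G", "C"),
    eaf = c(0.3, 0.12, 0.45, 0.2),
    beta = c(0.05, -0.03, 0.02, 0.08),
    se = c(0.01, 0.012, 0.009, 0.02),
    n = 50000L, info = c(0.95, 0.88, 0.97, 0.99),
    stringsAsFactors = FALSE
  )
  base$p <- 2 * pnorm(-abs(base$beta / base$se))
  mods <- list(...)
  for (nm in names(mods)) base[[nm]] <- mods[[nm]]
  base
}

test_that("QC removes low-MAF, low-INFO and strand-ambiguous variants, strictly", {
  ss <- make_ss(eaf = c(0.005, 0.12, 0.45, 0.2),
                info = c(0.95, 0.25, 0.97, 0.99),
                effect_allele = c("G", "C", "A", "T"),
                other_allele = c("A", "T", "T", "C"))
  # v1 fails MAF (0.005), v2 fails INFO (0.25), v3 is A/T ambiguous
  out <- qc_filter(ss)
  expect_identical(out$id, "v4")
  tally <- attr(out, "qc_tally")
  expect_equal(unname(tally[c("maf", "info", "ambiguous")]), c(1L, 1L, 1L))

  # boundary values fail under strict inequality
  at_bound <- make_ss(eaf = c(0.01, 0.3, 0.3, 0.3),
                      info = c(0.9, 0.3, 0.9, 0.9))
  out2 <- qc_filter(at_bound)
  expect_false(any(c("v1", "v2") %in% out2$id))
})

test_that("QC at loosest legal thresholds is the identity and is idempotent", {
  ss <- make_ss()
  loose <- qc_thresholds(min_info = 0, min_maf = 0, min_hwe_p = 0,
                         max_missing = 1, drop_ambiguous = FALSE)
  out <- qc_filter(ss, th = loose)
  expect_equal(as.data.frame(out), as.data.frame(ss), ignore_attr = TRUE)

  once <- qc_filter(ss)
  twice <- qc_filter(once)
  expect_equal(as.data.frame(twice), as.data.frame(once),
               ignore_attr = TRUE)
  expect_equal(sum(attr(twice, "qc_tally")), 0)
})

test_that("genotype-panel statistics drive HWE and missingness filters", {
  set.seed(3)
  n <- 2000
  # v_ok in HWE; v_bad grossly violates it (only homozygotes); v_miss
  # has 30% missing dosages
  p_ok <- 0.3
  g_ok <- rbinom(n, 2, p_ok)
  g_bad <- sample(c(0, 2), n, replace = TRUE, prob = c(0.7, 0.3))
  g_miss <- rbinom(n, 2, 0.4)
  g_miss[seq_len(0.3 * n)] <- NA
  geno <- structure(list(
    dosages = cbind(v1 = g_ok, v2 = g_bad, v3 = g_miss),
    variants = data.frame(id = c("v1", "v2", "v3"), chr = 1L,
                          pos = c(100L, 200L, 300L),
                          ref = "A", alt = "G",
                          stringsAsFactors = FALSE)
  ), class = "geno_matrix")
  gs <- geno_variant_stats(geno)
  expect_gt(gs$hwe_p[1], 1e-10)
  expect_lt(gs$hwe_p[2], 1e-10)
  expect_equal(gs$missing[3], 0.3)

  ss <- make_ss()[1:3, ]
  ss$id <- c("v1", "v2", "v3")
  ss$chr <- 1L
  ss$pos <- c(100L, 200L, 300L)
  out <- qc_filter(ss, gs)
  expect_identical(out$id, "v1")
  expect_equal(unname(attr(out, "qc_tally")[c("hwe", "missing")]),
               c(1L, 1L))
})

test_that("allele alignment follows the reference alternate-allele convention", {
  ref <- data.frame(chr = c(1L, 1L, 2L), pos = c(100L, 5000L, 100L),
                    ref_allele = c("A", "T", "A"),
                    alt_allele = c("G", "C", "T"))
  ss <- make_ss()[1:3, ]
  ss$effect_allele <- c("G", "T", "G")  # aligned, swapped, mismatched
  ss$other_allele <- c("A", "C", "C")
  ss$beta <- c(0.05, 0.2, 0.02)
  ss$eaf <- c(0.3, 0.3, 0.45)
  out <- align_alleles(ss, ref)

  expect_identical(out$id, c("v1", "v2"))
  expect_equal(out$beta, c(0.05, -0.2))
  expect_equal(out$eaf, c(0.3, 0.7))
  expect_equal(unname(attr(out, "align_tally")),
               c(1L, 1L, 1L))
  # aligning twice equals aligning once (normal form)
  again <- align_alleles(out, ref)
  expect_equal(as.data.frame(again), as.data.frame(out),
               ignore_attr = TRUE)
})

test_that("alignment decisions match the exhaustive allele match table", {
  # oracle: enumerate every (effect, other) pair against a ref A/G site;
  # kept iff {effect,other} == {alt,ref} in either orientation
  bases <- c("A", "C", "G", "T")
  ref <- data.frame(chr = 1L, pos = 100L, ref_allele = "A",
                    alt_allele = "G")
  for (ea in bases) for (oa in setdiff(bases, ea)) {
    ss <- make_ss()[1, ]
    ss$effect_allele <- ea
    ss$other_allele <- oa
    out <- align_alleles(ss, ref)
    should_keep <- (ea == "G" && oa == "A") || (ea == "A" && oa == "G")
    expect_equal(nrow(out) == 1, should_keep,
                 label = sprintf("%s/%s vs ref A>G", ea, oa))
    if (should_keep) expect_identical(out$effect_allele, "G")
  }
  # G/C at a ref A/T site is dropped
  ss <- make_ss()[1, ]
  ss$effect_allele <- "G"; ss$other_allele <- "C"
  out <- align_alleles(ss, data.frame(chr = 1L, pos = 100L,
                                      ref_allele = "A", alt_allele = "T"))
  expect_equal(nrow(out), 0)
})

test_that("multi-allelic reference rows are rejected with a clear message", {
  ref <- data.frame(chr = c(1L, 1L), pos = c(100L, 100L),
                    ref_allele = c("A", "A"), alt_allele = c("G", "C"))
  expect_error(align_alleles(make_ss(), ref), "multi-allelic")
})

test_that("fixed-effect meta matches hand inverse-variance arithmetic", {
  s1 <- make_ss()[1, ]
  s2 <- s1
  s1$beta <- 0.1; s1$se <- 0.1; s1$p <- 2 * pnorm(-1)
  s2$beta <- 0.3; s2$se <- 0.2; s2$p <- 2 * pnorm(-1.5)
  meta <- fixed_effect_meta(list(s1, s2))
  # w = (100, 25): beta* = (100*0.1 + 25*0.3)/125, se* = 1/sqrt(125)
  expect_equal(meta$beta, 0.14, tolerance = 1e-12)
  expect_equal(meta$se, 1 / sqrt(125), tolerance = 1e-12)
  expect_equal(meta$n, s1$n + s2$n)

  # single study is the identity
  one <- fixed_effect_meta(list(make_ss()))
  expect_equal(as.data.frame(one), as.data.frame(make_ss()),
               ignore_attr = TRUE)

  # k identical studies: beta unchanged, se/sqrt(k)
  k <- 4
  same <- fixed_effect_meta(rep(list(make_ss()), k))
  expect_equal(same$beta, make_ss()$beta, tolerance = 1e-12)
  expect_equal(same$se, make_ss()$se / sqrt(k), tolerance = 1e-12)
})

test_that("meta handles study subsets, guards alleles, and beats every input SE", {
  s1 <- make_ss()
  s2 <- make_ss()[1:2, ]
  s2$beta <- s2$beta + 0.01
  meta <- fixed_effect_meta(list(s1, s2))
  expect_equal(nrow(meta), 4)
  expect_equal(attr(meta, "meta_n_studies"), c(2L, 2L, 1L, 1L))
  only1 <- meta[meta$id %in% c("v3", "v4"), ]
  expect_equal(only1$beta, s1$beta[3:4])
  for (i in seq_len(nrow(meta))) {
    ses <- c(s1$se[s1$id == meta$id[i]], s2$se[s2$id == meta$id[i]])
    expect_lte(meta$se[i], min(ses) + 1e-12)
  }

  s_flip <- make_ss()
  s_flip$effect_allele[1] <- "T"
  s_flip$other_allele[1] <- "G"
  expect_error(fixed_effect_meta(list(s1, s_flip)), "allele mismatch")
})

test_that("vectorized meta agrees with metafor's fixed-effect model", {
  set.seed(8)
  k <- 5
  studies <- lapply(1:k, function(i) {
    s <- make_ss()[1, ]
    s$beta <- rnorm(1, 0.1, 0.05)
    s$se <- runif(1, 0.02, 0.2)
    s$p <- 2 * pnorm(-abs(s$beta / s$se))
    s
  })
  meta <- fixed_effect_meta(studies)
  rma <- metafor::rma(yi = vapply(studies, `[[`, numeric(1), "beta"),
                      sei = vapply(studies, `[[`, numeric(1), "se"),
                      method = "FE")
  expect_equal(meta$beta, as.numeric(rma$beta), tolerance = 1e-10)
  expect_equal(meta$se, rma$se, tolerance = 1e-10)
})

test_that("summary-stat reader maps header synonyms and QC tallies the fixture", {
  path <- system.file("extdata", "sumstats_fixture.tsv", package = "iprs")
  ss <- read_sumstats(path)
  expect_s3_class(ss, "summary_stats")
  expect_named(ss, c("id", "chr", "pos", "effect_allele", "other_allele",
                     "eaf", "beta", "se", "p", "n", "info"),
               ignore.order = TRUE)
  expect_true(all(abs(ss$p - 2 * pnorm(-abs(ss$beta / ss$se))) < 1e-6))

  out <- qc_filter(ss)
  tally <- attr(out, "qc_tally")
  expect_equal(unname(tally["ambiguous"]), 1L)  # rs1003 is A/T
  expect_equal(unname(tally["info"]), 0L)       # rs1004 INFO 0.41 > 0.3 passes
  expect_false("rs1003" %in% out$id)

  tmp <- tempfile(fileext = ".tsv")
  write_sumstats(ss, tmp)
  back <- read_sumstats(tmp)
  expect_equal(as.data.frame(back), as.data.frame(ss), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("unknown allele codes are rejected", {
  ss <- make_ss()
  ss$effect_allele[2] <- "N"
  expect_error(qc_filter(ss), "allele codes")
})
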