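VALID_ALLELES <- c("A", "C", "G", "T")
COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

validate_sumstats <- function(ss) {
  required <- c("id", "chr", "pos", "effect_allele", "other_allele",
                "eaf", "beta", "se", "p", "n")
  missing <- setdiff(required, names(ss))
  stopf(length(missing) == 0, "summary stats lack columns: %s",
        paste(missing, collapse = ", "))
  bad <- !(ss$effect_allele %in% VALID_ALLELES &
             ss$other_allele %in% VALID_ALLELES)
  stopf(!any(bad), "unknown allele codes at %d variant(s), e.g. %s/%s",
        sum(bad), ss$effect_allele[which(bad)[1]],
        ss$other_allele[which(bad)[1]])
  stopf(all(ss$se > 0), "non-positive standard errors present")
  key <- paste(ss$chr, ss$pos, ss$effect_allele, ss$other_allele)
  stopf(!anyDuplicated(key), "duplicate (chr,pos,allele) records present")
  if (!inherits(ss, "summary_stats")) {
    class(ss) <- c("summary_stats", class(ss))
  }
  ss
}

is_ambiguous <- function(a1, a2) COMPLEMENT[a1] == a2

#' Quality-control thresholds for summary statistics
#'
#' Defaults follow common GWAS practice for imputed data: imputation INFO
#' > 0.3, minor allele frequency > 1\%, Hardy-Weinberg equilibrium p >
#' 1e-10, genotype missing rate < 10\%, and removal of strand-ambiguous
#' (A/T, C/G) variants. All comparisons are strict inequalities.
#'
#' @param min_info minimum imputation INFO score (exclusive).
#' @param min_maf minimum minor allele frequency (exclusive).
#' @param min_hwe_p minimum Hardy-Weinberg p-value (exclusive).
#' @param max_missing maximum genotype missing rate (exclusive).
#' @param drop_ambiguous drop strand-ambiguous variants?
#' @return a \code{qc_thresholds} list.
#' @export
qc_thresholds <- function(min_info = 0.3, min_maf = 0.01,
                          min_hwe_p = 1e-10, max_missing = 0.10,
                          drop_ambiguous = TRUE) {
  structure(list(
    min_info = check_number(min_info, "min_info", 0, 1),
    min_maf = check_number(min_maf, "min_maf", 0, 0.5),
    min_hwe_p = check_number(min_hwe_p, "min_hwe_p", 0, 1),
    max_missing = check_number(max_missing, "max_missing", 0, 1),
    drop_ambiguous = isTRUE(drop_ambiguous)
  ), class = "qc_thresholds")
}

#' Per-variant genotype-panel statistics for QC
#'
#' Computes, from the target genotype panel, the per-variant minor allele
#' frequency, missing rate, and a Hardy-Weinberg equilibrium p-value.
#' Dosages carry no genotype counts, so HWE uses hard calls obtained by
#' deterministic rounding, followed by the 1-df chi-square test of
#' observed versus expected genotype counts.
#'
#' @param geno a \code{geno_matrix} (dosages may contain NA).
#' @return data.frame with id, maf, missing, hwe_p.
#' @export
geno_variant_stats <- function(geno) {
  dos <- geno$dosages
  miss <- colMeans(is.na(dos))
  af <- colMeans(dos, na.rm = TRUE) / 2
  maf <- pmin(af, 1 - af)
  hwe_p <- vapply(seq_len(ncol(dos)), function(j) {
    g <- round(dos[, j])
    g <- g[!is.na(g)]
    n <- length(g)
    if (n == 0) return(NA_real_)
    p <- mean(g) / 2
    if (p <= 0 || p >= 1) return(1)
    obs <- tabulate(g + 1L, nbins = 3L)
    expn <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
    stat <- sum((obs - expn)^2 / expn)
    pchisq(stat, df = 1, lower.tail = FALSE)
  }, numeric(1))
  data.frame(id = geno$variants$id, maf = maf, missing = miss,
             hwe_p = hwe_p, stringsAsFactors = FALSE)
}

#' Quality-filter GWAS summary statistics
#'
#' Applies, in a fixed order whose outcome is order-independent (each
#' filter is a per-variant predicate): INFO > \code{min_info}; minor
#' allele frequency (from the summary-stat EAF) > \code{min_maf};
#' genotype-panel HWE p > \code{min_hwe_p}; genotype-panel missing rate <
#' \code{max_missing}; removal of strand-ambiguous A/T and C/G variants.
#' Panel-side filters are skipped (with a note in the tally) when
#' \code{geno_stats} is NULL. Variants with missing INFO pass the INFO
#' filter. The per-filter removal tally is attached as the
#' \code{"qc_tally"} attribute; the same variant can appear in several
#' tallies.
#'
#' @param ss a \code{summary_stats} data.frame.
#' @param geno_stats optional [geno_variant_stats()] output matched by id.
#' @param th a [qc_thresholds()] object.
#' @return the filtered \code{summary_stats}, with attribute
#'   \code{qc_tally} (named integer vector of removals per filter).
#' @export
qc_filter <- function(ss, geno_stats = NULL, th = qc_thresholds()) {
  ss <- validate_sumstats(ss)
  n0 <- nrow(ss)
  keep <- rep(TRUE, n0)
  tally <- c(info = 0L, maf = 0L, hwe = 0L, missing = 0L, ambiguous = 0L)

  fail_info <- !is.na(ss$info) & !(ss$info > th$min_info)
  tally["info"] <- sum(fail_info)
  keep <- keep & !fail_info

  maf <- pmin(ss$eaf, 1 - ss$eaf)
  fail_maf <- !(maf > th$min_maf)
  tally["maf"] <- sum(fail_maf)
  keep <- keep & !fail_maf

  if (!is.null(geno_stats)) {
    gs <- geno_stats[match(ss$id, geno_stats$id), ]
    fail_hwe <- !is.na(gs$hwe_p) & !(gs$hwe_p > th$min_hwe_p)
    fail_mis <- !is.na(gs$missing) & !(gs$missing < th$max_missing)
    tally["hwe"] <- sum(fail_hwe)
    tally["missing"] <- sum(fail_mis)
    keep <- keep & !fail_hwe & !fail_mis
  }

  if (th$drop_ambiguous) {
    amb <- is_ambiguous(ss$effect_allele, ss$other_allele)
    tally["ambiguous"] <- sum(amb)
    keep <- keep & !amb
  }

  out <- ss[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "qc_tally") <- tally
  attr(out, "n_input") <- n0
  out
}

#' Align summary statistics to a reference allele convention
#'
#' Forces every record's effect allele to equal the reference alternate
#' allele at its (chr, pos). Records already reported on the alternate
#' allele pass through; records reported on the reference allele have
#' their beta negated, EAF complemented, and allele labels swapped;
#' records matching neither orientation (allele set differs from the
#' reference site) are dropped and tallied. Aligning an already-aligned
#' file is a no-op.
#'
#' @param ss a \code{summary_stats} data.frame.
#' @param ref data.frame with chr, pos, ref_allele, alt_allele (one row
#'   per site; multi-allelic duplicates are an error).
#' @return aligned \code{summary_stats} with attribute
#'   \code{align_tally} = c(kept, flipped, dropped).
#' @export
align_alleles <- function(ss, ref) {
  ss <- validate_sumstats(ss)
  stopf(all(c("chr", "pos", "ref_allele", "alt_allele") %in% names(ref)),
        "ref needs chr, pos, ref_allele, alt_allele")
  key <- paste(ref$chr, ref$pos)
  dup <- unique(key[duplicated(key)])
  stopf(length(dup) == 0,
        "multi-allelic reference rows at %d site(s) (e.g. %s); split them first",
        length(dup), dup[1])
  idx <- match(paste(ss$chr, ss$pos), key)
  ra <- toupper(ref$ref_allele[idx])
  aa <- toupper(ref$alt_allele[idx])

  already <- !is.na(idx) & ss$effect_allele == aa & ss$other_allele == ra
  swapped <- !is.na(idx) & ss$effect_allele == ra & ss$other_allele == aa
  keep <- already | swapped

  out <- ss[keep, , drop = FALSE]
  fl <- swapped[keep]
  out$beta[fl] <- -out$beta[fl]
  out$eaf[fl] <- 1 - out$eaf[fl]
  out[fl, c("effect_allele", "other_allele")] <-
    out[fl, c("other_allele", "effect_allele")]
  rownames(out) <- NULL
  attr(out, "align_tally") <- c(kept = sum(already), flipped = sum(swapped),
                                dropped = sum(!keep))
  out
}

#' Fixed-effect inverse-variance meta-analysis of summary statistics
#'
#' METAL-style per-variant meta-analysis: with weights \eqn{w_i = 1/se_i^2},
#' the pooled effect is \eqn{\sum w_i \beta_i / \sum w_i}, its standard
#' error \eqn{(\sum w_i)^{-1/2}}, and the p-value the two-sided Wald test.
#' Variants present in only a subset of studies are meta-analyzed over
#' that subset; sample sizes are summed and the pooled EAF is the
#' n-weighted mean. All studies must already share one allele convention
#' (run [align_alleles()] first); an allele mismatch across studies for
#' the same site is an error.
#'
#' @param studies list of \code{summary_stats} data.frames.
#' @return pooled \code{summary_stats}; the \code{info} column is the
#'   n-weighted mean INFO. Attribute \code{meta_n_studies} gives the
#'   per-variant study count.
#' @export
fixed_effect_meta <- function(studies) {
  stopf(is.list(studies) && length(studies) >= 1,
        "need at least one study")
  studies <- lapply(studies, validate_sumstats)
  if (length(studies) == 1L) return(studies[[1]])

  all_ss <- do.call(rbind, lapply(studies, as.data.frame))
  key <- paste(all_ss$chr, all_ss$pos)
  alleles <- paste(all_ss$effect_allele, all_ss$other_allele)
  mismatch <- tapply(alleles, key, function(a) length(unique(a)) > 1)
  stopf(!any(mismatch),
        "allele mismatch across studies at %d site(s); align alleles first",
        sum(mismatch))

  grp <- factor(key, levels = unique(key))
  w <- 1 / all_ss$se^2
  sw <- tapply(w, grp, sum)
  beta <- tapply(w * all_ss$beta, grp, sum) / sw
  se <- 1 / sqrt(sw)
  n <- tapply(all_ss$n, grp, sum)
  eaf <- tapply(all_ss$eaf * all_ss$n, grp, sum) / n
  info <- tapply(ifelse(is.na(all_ss$info), 1, all_ss$info) * all_ss$n,
                 grp, sum) / n
  first <- !duplicated(key)
  out <- data.frame(
    id = all_ss$id[first], chr = all_ss$chr[first], pos = all_ss$pos[first],
    effect_allele = all_ss$effect_allele[first],
    other_allele = all_ss$other_allele[first],
    eaf = as.numeric(eaf), beta = as.numeric(beta), se = as.numeric(se),
    p = 2 * pnorm(-abs(as.numeric(beta) / as.numeric(se))),
    n = as.integer(n), info = as.numeric(info),
    stringsAsFactors = FALSE
  )
  attr(out, "meta_n_studies") <- as.integer(table(grp))
  validate_sumstats(out)
}
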