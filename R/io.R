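# Column-name synonyms accepted when reading GWAS summary statistics.
# Header matching is case-insensitive; the first synonym hit wins.
SUMSTAT_SYNONYMS <- list(
  id = c("id", "snp", "rsid", "variant_id", "markername"),
  chr = c("chr", "chromosome", "chrom"),
  pos = c("pos", "bp", "position", "base_pair_location"),
  effect_allele = c("effect_allele", "a1", "allele1", "ea", "alt"),
  other_allele = c("other_allele", "a2", "allele2", "oa", "nea", "ref"),
  eaf = c("eaf", "freq", "af", "effect_allele_frequency", "maf"),
  beta = c("beta", "b", "effect", "effect_size"),
  se = c("se", "stderr", "standard_error"),
  p = c("p", "pval", "p_value", "pvalue"),
  n = c("n", "samplesize", "n_total"),
  info = c("info", "imputation_info", "info_score")
)

#' Read GWAS summary statistics from a tab-delimited file
#'
#' Headers are mapped to the canonical schema (id, chr, pos,
#' effect_allele, other_allele, eaf, beta, se, p, n, info) through a
#' case-insensitive synonym table; extra synonyms can be supplied per
#' field via \code{col_map}. The \code{info} column is optional.
#'
#' @param path TSV path.
#' @param col_map optional named list of extra column synonyms.
#' @return a \code{summary_stats} data.frame.
#' @export
read_sumstats <- function(path, col_map = NULL) {
  raw <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  syn <- SUMSTAT_SYNONYMS
  for (nm in names(col_map)) syn[[nm]] <- c(col_map[[nm]], syn[[nm]])
  lower <- tolower(names(raw))
  out <- list()
  for (field in names(syn)) {
    hit <- which(lower %in% tolower(syn[[field]]))
    if (length(hit)) out[[field]] <- raw[[hit[1]]]
  }
  required <- c("id", "chr", "pos", "effect_allele", "other_allele",
                "eaf", "beta", "se", "p", "n")
  missing <- setdiff(required, names(out))
  stopf(length(missing) == 0, "summary-stat file %s lacks columns: %s",
        path, paste(missing, collapse = ", "))
  if (is.null(out$info)) out$info <- NA_real_
  ss <- as.data.frame(out, stringsAsFactors = FALSE)
  ss$effect_allele <- toupper(ss$effect_allele)
  ss$other_allele <- toupper(ss$other_allele)
  validate_sumstats(ss)
}

#' Write summary statistics as TSV
#' @param ss a \code{summary_stats} data.frame.
#' @param path output path.
#' @export
write_sumstats <- function(ss, path) {
  write.table(as.data.frame(ss), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write genotype dosages as a minimal VCF with a DS FORMAT field
#'
#' One sample column per individual; genotype calls are emitted as hard
#' calls (GT) with the dosage in DS, the de-facto convention for imputed
#' data.
#'
#' @param geno a \code{geno_matrix}.
#' @param path output path (plain text .vcf).
#' @export
write_dosage_vcf <- function(geno, path) {
  v <- geno$variants
  n <- nrow(geno$dosages)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Dosage of ALT allele\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sprintf("ind%06d", seq_len(n))), collapse = "\t")
  ), con)
  gt_of <- c("0/0", "0/1", "1/1")
  for (j in seq_len(nrow(v))) {
    ds <- geno$dosages[, j]
    cells <- paste0(gt_of[pmin(pmax(round(ds), 0), 2) + 1L], ":",
                    format(ds, trim = TRUE))
    writeLines(paste(c(v$chr[j], v$pos[j], v$id[j], v$ref[j], v$alt[j],
                       ".", "PASS", ".", "GT:DS", cells), collapse = "\t"),
               con)
  }
  invisible(path)
}

#' Write genotype dosages as a plain TSV (variants in columns)
#' @param geno a \code{geno_matrix}.
#' @param path output path.
#' @export
write_dosage_tsv <- function(geno, path) {
  df <- data.frame(id = sprintf("ind%06d", seq_len(nrow(geno$dosages))),
                   geno$dosages, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a cohort table as CSV and its simulation truth as sidecar JSON
#' @param cohort a \code{cohort_table}.
#' @param truth optional \code{sim_truth}; written next to the CSV as
#'   \code{<path>.truth.json}.
#' @param path CSV path.
#' @export
write_cohort <- function(cohort, path, truth = NULL) {
  utils::write.csv(as.data.frame(cohort), path, row.names = FALSE)
  if (!is.null(truth)) {
    jsonlite::write_json(
      list(true_betas = truth$true_betas,
           true_clinical_lp = truth$true_clinical_lp,
           true_hr_per_sd = truth$true_hr_per_sd),
      paste0(path, ".truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read PRS variant weights from a scoring-format TSV
#'
#' Expects at least three columns: variant id, effect allele, weight
#' (header names flexible: id/snp/rsid, effect_allele/a1/ea,
#' weight/beta/effect). Provenance, if present, is read from a
#' \code{<path>.json} sidecar.
#'
#' @param path TSV path.
#' @return a \code{prs_weights} data.frame with attributes
#'   \code{provenance}.
#' @export
read_weights <- function(path) {
  raw <- read.delim(path, stringsAsFactors = FALSE)
  lower <- tolower(names(raw))
  pick <- function(cands) {
    hit <- which(lower %in% cands)
    if (length(hit)) raw[[hit[1]]] else NULL
  }
  w <- data.frame(
    id = pick(c("id", "snp", "rsid", "variant_id")),
    effect_allele = toupper(pick(c("effect_allele", "a1", "ea", "allele"))),
    weight = pick(c("weight", "beta", "effect", "score")),
    stringsAsFactors = FALSE
  )
  stopf(!any(vapply(w, is.null, logical(1))) && nrow(w) > 0,
        "weight file %s needs id, effect allele and weight columns", path)
  stopf(!anyDuplicated(w$id), "duplicate variant ids in weight file %s", path)
  side <- paste0(path, ".json")
  prov <- if (file.exists(side)) jsonlite::read_json(side) else list()
  structure(w, provenance = prov, class = c("prs_weights", "data.frame"))
}

#' Write PRS weights with a provenance sidecar
#' @param w a \code{prs_weights} data.frame.
#' @param path TSV path; provenance goes to \code{<path>.json}.
#' @export
write_weights <- function(w, path) {
  write.table(as.data.frame(w)[c("id", "effect_allele", "weight")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  prov <- attr(w, "provenance")
  if (!is.null(prov) && length(prov)) {
    jsonlite::write_json(prov, paste0(path, ".json"), auto_unbox = TRUE)
  }
  invisible(path)
}
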