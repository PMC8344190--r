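#' Genotype matrix container
#'
#' Holds an individuals-by-SNPs dosage matrix together with per-SNP minor
#' allele frequency and missingness. Dosages are allele counts coded
#' `0/1/2` (or the centered `-1/0/1` convention); missing entries are `NA`.
#'
#' @param dosages numeric matrix, individuals in rows, SNPs in columns.
#' @param sample_ids,snp_ids character vectors of unique identifiers; taken
#'   from `dimnames(dosages)` when omitted.
#' @param check_codes if `TRUE` (default) dosages must be integer allele
#'   counts; mean imputation yields fractional dosages, which are accepted
#'   with `check_codes = FALSE`.
#' @return An object of class `genotype_matrix` with elements `dosages`,
#'   `snp_ids`, `sample_ids`, `maf` and `missing_rate`. The minor allele
#'   frequency is computed on observed (non-missing) genotypes only.
#' @export
genotype_matrix <- function(dosages, sample_ids = rownames(dosages),
                            snp_ids = colnames(dosages), check_codes = TRUE) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(sample_ids)) sample_ids <- paste0("ind", seq_len(nrow(dosages)))
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(dosages)))
  if (anyDuplicated(sample_ids)) stop("sample_ids must be unique")
  if (anyDuplicated(snp_ids)) stop("snp_ids must be unique")
  if (check_codes) {
    ok <- dosages %in% c(-1, 0, 1, 2) | is.na(dosages)
    if (!all(ok)) {
      bad <- unique(dosages[!ok])
      stop("unknown genotype code(s): ", paste(utils::head(bad, 5), collapse = ", "))
    }
  }
  dimnames(dosages) <- list(sample_ids, snp_ids)
  g <- structure(
    list(dosages = dosages, snp_ids = snp_ids, sample_ids = sample_ids),
    class = "genotype_matrix"
  )
  g$maf <- .compute_maf(dosages)
  g$missing_rate <- colMeans(is.na(dosages))
  g
}

# MAF from observed dosages; works for 0/1/2 and centered -1/0/1 coding.
.compute_maf <- function(d) {
  shift <- if (min(d, na.rm = TRUE) < 0) 1 else 0
  f <- colMeans(d + shift, na.rm = TRUE) / 2
  pmin(f, 1 - f)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d individuals x %d SNPs (mean MAF %.3f, mean missing %.4f)\n",
              nrow(x$dosages), ncol(x$dosages), mean(x$maf), mean(x$missing_rate)))
  invisible(x)
}

#' Taxon abundance container
#'
#' Holds a raw non-negative individuals-by-taxa abundance matrix and its
#' log total-sum-scaled view (see [tss_log_transform()]).
#'
#' @param raw non-negative numeric matrix (counts or proportions).
#' @param sample_ids,taxon_ids identifiers; default to `dimnames(raw)`.
#' @param logtss optional pre-computed log-TSS matrix of the same shape.
#' @return An object of class `abundance_matrix`.
#' @export
abundance_matrix <- function(raw, sample_ids = rownames(raw),
                             taxon_ids = colnames(raw), logtss = NULL) {
  raw <- as.matrix(raw)
  storage.mode(raw) <- "double"
  if (anyNA(raw)) stop("raw abundances must not contain missing values")
  if (any(raw < 0)) stop("raw abundances must be non-negative")
  if (is.null(sample_ids)) sample_ids <- paste0("ind", seq_len(nrow(raw)))
  if (is.null(taxon_ids)) taxon_ids <- paste0("otu", seq_len(ncol(raw)))
  dimnames(raw) <- list(sample_ids, taxon_ids)
  if (!is.null(logtss)) {
    logtss <- as.matrix(logtss)
    stopifnot(identical(dim(logtss), dim(raw)))
    dimnames(logtss) <- dimnames(raw)
  }
  structure(list(raw = raw, logtss = logtss, taxon_ids = taxon_ids,
                 sample_ids = sample_ids),
            class = "abundance_matrix")
}

#' @export
print.abundance_matrix <- function(x, ...) {
  cat(sprintf("abundance_matrix: %d individuals x %d taxa (zero fraction %.3f%s)\n",
              nrow(x$raw), ncol(x$raw), mean(x$raw == 0),
              if (is.null(x$logtss)) ", no log-TSS view" else ""))
  invisible(x)
}

#' Read a genotype table
#'
#' Reads an individuals-by-SNPs dosage table. Delimited input has feature ids
#' in the first row and sample ids in the first column; dosage codes are
#' `0/1/2` or `-1/0/1`, with a configurable missing sentinel. VCF input
#' (biallelic sites) is converted to a 0/1/2 dosage table; half-calls are
#' treated as missing.
#'
#' @param path file path.
#' @param format `"delimited"` or `"vcf"`.
#' @param missing missing-value sentinels (default `"NA"` and `-9`).
#' @param sep field separator; guessed from the header for delimited input.
#' @return A [genotype_matrix()], unfiltered and unimputed.
#' @export
load_genotypes <- function(path, format = c("delimited", "vcf"),
                           missing = c("NA", "-9"), sep = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "vcf") return(.load_vcf_dosage(path))
  lines <- readLines(path)
  if (length(lines) < 2L) stop("parse error: need a header and at least one row")
  if (is.null(sep)) sep <- if (grepl("\t", lines[[1L]])) "\t" else ","
  header <- strsplit(lines[[1L]], sep, fixed = TRUE)[[1L]]
  snp_ids <- header[-1L]
  p <- length(snp_ids)
  rows <- strsplit(lines[-1L], sep, fixed = TRUE)
  len <- lengths(rows)
  if (any(len != p + 1L)) {
    stop(sprintf("parse error at line %d: expected %d fields, found %d",
                 which(len != p + 1L)[1L] + 1L, p + 1L, len[len != p + 1L][1L]))
  }
  m <- do.call(rbind, rows)
  sample_ids <- m[, 1L]
  vals <- m[, -1L, drop = FALSE]
  vals[vals %in% as.character(missing)] <- NA
  d <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- !is.na(vals) & is.na(d)
  if (any(bad)) stop("unknown genotype code: ", vals[bad][1L])
  genotype_matrix(d, sample_ids = sample_ids, snp_ids = snp_ids)
}

.load_vcf_dosage <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    stop("VCF input requires the 'vcfR' package")
  }
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  alt <- vcfR::getALT(v)
  if (any(grepl(",", alt))) stop("only biallelic sites are supported")
  gt <- gsub("|", "/", gt, fixed = TRUE)
  dose <- matrix(NA_real_, nrow = nrow(gt), ncol = ncol(gt))
  dose[gt == "0/0"] <- 0
  dose[gt %in% c("0/1", "1/0")] <- 1
  dose[gt == "1/1"] <- 2
  # anything else (half-calls "./1", missing "./.") stays NA
  ids <- vcfR::getID(v)
  if (anyNA(ids) || anyDuplicated(ids)) {
    ids <- paste0(vcfR::getCHROM(v), ":", vcfR::getPOS(v))
  }
  genotype_matrix(t(dose), sample_ids = colnames(gt), snp_ids = ids)
}

#' Read a taxon abundance table
#'
#' Delimited layout as in [load_genotypes()]: taxa in the first row, sample
#' ids in the first column, non-negative counts or proportions.
#'
#' @param path file path.
#' @param sep field separator; guessed from the header when `NULL`.
#' @return An [abundance_matrix()] without a log-TSS view.
#' @export
load_abundances <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  line1 <- readLines(path, n = 1L)
  if (is.null(sep)) sep <- if (grepl("\t", line1)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE)
  abundance_matrix(as.matrix(df))
}

#' Write a genotype or abundance table
#'
#' Writes the delimited layout that [load_genotypes()] and
#' [load_abundances()] read back (feature ids in the first row, sample ids in
#' the first column).
#'
#' @param x a `genotype_matrix` or `abundance_matrix`.
#' @param path output file path.
#' @param sep field separator (default tab).
#' @export
write_table <- function(x, path, sep = "\t") {
  m <- if (inherits(x, "genotype_matrix")) x$dosages else x$raw
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter SNPs on allele frequency and missingness
#'
#' Retains SNPs with minor allele frequency at or above `maf_min` and
#' missing-genotype fraction at or below `miss_max`, preserving order.
#'
#' @param g a [genotype_matrix()].
#' @param maf_min minimum minor allele frequency (default 0.01).
#' @param miss_max maximum per-SNP missing fraction (default 0.01).
#' @return The filtered `genotype_matrix`.
#' @export
filter_snps <- function(g, maf_min = 0.01, miss_max = 0.01) {
  stopifnot(inherits(g, "genotype_matrix"),
            maf_min >= 0, maf_min <= 0.5, miss_max >= 0, miss_max <= 1)
  keep <- g$maf >= maf_min & g$missing_rate <= miss_max
  if (!any(keep)) stop("no SNPs pass the filters")
  genotype_matrix(g$dosages[, keep, drop = FALSE],
                  sample_ids = g$sample_ids, snp_ids = g$snp_ids[keep],
                  check_codes = FALSE)
}

#' Mean-impute missing genotypes
#'
#' Replaces each missing dosage by the per-SNP mean of the observed dosages;
#' observed entries are unchanged.
#'
#' @param g a [genotype_matrix()].
#' @return The imputed `genotype_matrix` (no missing entries).
#' @export
impute_mean <- function(g) {
  stopifnot(inherits(g, "genotype_matrix"))
  d <- g$dosages
  nmiss <- colSums(is.na(d))
  if (any(nmiss == nrow(d))) {
    stop("SNP(s) with all genotypes missing: ",
         paste(utils::head(g$snp_ids[nmiss == nrow(d)], 3), collapse = ", "))
  }
  if (any(nmiss > 0)) {
    mu <- colMeans(d, na.rm = TRUE)
    idx <- which(is.na(d), arr.ind = TRUE)
    d[idx] <- mu[idx[, 2L]]
  }
  genotype_matrix(d, sample_ids = g$sample_ids, snp_ids = g$snp_ids,
                  check_codes = FALSE)
}

#' Total-sum scaling and log transform of abundances
#'
#' Adds a pseudo-count to zero cells (or, optionally, to all cells), divides
#' each row by its post-pseudo-count total, and takes logs. Raw taxon
#' abundances are typically zero-inflated and highly leptokurtic; the
#' log-TSS view is much closer to symmetric.
#'
#' @param a an [abundance_matrix()].
#' @param pseudocount positive value added to zero cells (default 1).
#' @param zeros_only if `TRUE` (default) the pseudo-count is added to zero
#'   cells only; if `FALSE` it is added to every cell.
#' @return The `abundance_matrix` with its `logtss` element filled in.
#' @export
tss_log_transform <- function(a, pseudocount = 1, zeros_only = TRUE) {
  stopifnot(inherits(a, "abundance_matrix"), pseudocount >= 0)
  raw <- a$raw
  shifted <- if (zeros_only) raw + pseudocount * (raw == 0) else raw + pseudocount
  rs <- rowSums(shifted)
  if (any(rs == 0)) stop("row(s) with zero total after pseudo-count; use pseudocount > 0")
  lt <- log(shifted / rs)
  abundance_matrix(raw, sample_ids = a$sample_ids, taxon_ids = a$taxon_ids,
                   logtss = lt)
}

#' Column standardization
#'
#' Centers each column to mean zero and scales to unit sample standard
#' deviation (denominator `n - 1`).
#'
#' @param m numeric matrix.
#' @return The standardized matrix.
#' @export
standardize_columns <- function(m) {
  m <- as.matrix(m)
  s <- apply(m, 2L, stats::sd)
  if (any(s == 0 | !is.finite(s))) {
    bad <- which(s == 0 | !is.finite(s))[1L]
    nm <- if (!is.null(colnames(m))) colnames(m)[bad] else as.character(bad)
    stop("zero-variance column: ", nm)
  }
  scale(m, center = TRUE, scale = s)[, , drop = FALSE]
}
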