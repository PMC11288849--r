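#' Genotype matrix container
#'
#' Holds biallelic SNP genotypes as alt-allele dosages (0, 1, 2) for a set of
#' individuals, with optional progeny (full-sib family) and population labels.
#' Missing calls are stored as `NA`. Dosage 2 corresponds to the homozygote
#' for the counted (alternate) allele; this orientation is fixed throughout
#' the package.
#'
#' @param dosage numeric matrix, individuals in rows and markers in columns,
#'   with row and column names giving sample and marker ids. Values must be
#'   0, 1, 2 or `NA`.
#' @param family optional character vector of progeny labels, one per sample.
#' @param population optional character vector of population labels.
#' @param fractional allow fractional dosages in `[0, 2]` (e.g. after mean
#'   imputation); default `FALSE` admits only 0, 1, 2.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, family = NULL, population = NULL,
                            fractional = FALSE) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "double"
  if (is.null(rownames(dosage)))
    rownames(dosage) <- paste0("S", seq_len(nrow(dosage)))
  if (is.null(colnames(dosage)))
    colnames(dosage) <- paste0("M", seq_len(ncol(dosage)))
  .check_unique(rownames(dosage), "sample")
  .check_unique(colnames(dosage), "marker")
  bad <- !is.na(dosage) & (dosage < 0 | dosage > 2)
  if (any(bad))
    stop("non-missing dosages must lie in [0, 2]; first offender at [",
         which(bad)[1], "]")
  if (!fractional) {
    nonint <- !is.na(dosage) & dosage != round(dosage)
    if (any(nonint))
      stop("non-integer dosage found; use fractional = TRUE for imputed data")
  }
  if (!is.null(family)) {
    stopifnot(length(family) == nrow(dosage))
    family <- as.character(family)
  }
  if (!is.null(population)) {
    stopifnot(length(population) == nrow(dosage))
    population <- as.character(population)
  }
  structure(list(dosage = dosage, family = family, population = population),
            class = "genotype_matrix")
}

.check_unique <- function(ids, what) {
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate ", what, " id(s): ", paste(dup, collapse = ", "))
  invisible(TRUE)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", nrow(x$dosage), "individuals x",
      ncol(x$dosage), "markers\n")
  nm <- sum(is.na(x$dosage))
  cat("  missing calls:", nm,
      sprintf("(%.2f%%)\n", 100 * nm / length(x$dosage)))
  if (!is.null(x$family))
    cat("  families:", length(unique(x$family)), "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Sample ids of a genotype matrix
#' @param g a `genotype_matrix`.
#' @return character vector of sample ids.
#' @export
sample_ids <- function(g) rownames(g$dosage)

#' Marker ids of a genotype matrix
#' @param g a `genotype_matrix`.
#' @return character vector of marker ids.
#' @export
marker_ids <- function(g) colnames(g$dosage)

#' Subset a genotype matrix by samples and/or markers
#' @param x a `genotype_matrix`.
#' @param i sample index (ids, logical or integer).
#' @param j marker index.
#' @param ... unused.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dosage))
  if (missing(j)) j <- seq_len(ncol(x$dosage))
  if (is.character(i)) i <- match(i, rownames(x$dosage))
  genotype_matrix(x$dosage[i, j, drop = FALSE],
                  family = x$family[i], population = x$population[i],
                  fractional = TRUE)
}

# ---- readers / writers ------------------------------------------------------

.MISSING_CODES <- c("NA", "", "-9")

#' Read a genotype dosage table from CSV
#'
#' Expected dialect: comma-separated UTF-8, header `id,<marker1>,...`, one row
#' per individual. Optional `family` and `population` columns may follow `id`.
#' The strings `"NA"`, `""` and the value `-9` are read as missing; any other
#' unparseable cell also becomes missing.
#'
#' @param path path to the CSV file.
#' @return a [genotype_matrix()].
#' @export
read_genotype_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(raw) == 0 || ncol(raw) == 0) stop("empty genotype file: ", path)
  if (names(raw)[1] != "id")
    stop("first column of a genotype CSV must be 'id'")
  ids <- raw[["id"]]
  .check_unique(ids, "sample")
  fam <- if ("family" %in% names(raw)) raw[["family"]] else NULL
  pop <- if ("population" %in% names(raw)) raw[["population"]] else NULL
  keep <- setdiff(names(raw), c("id", "family", "population"))
  if (!length(keep)) stop("genotype CSV has no marker columns")
  .check_unique(keep, "marker")
  mat <- sapply(raw[keep], function(col) {
    col[col %in% .MISSING_CODES] <- NA
    suppressWarnings(as.numeric(col))
  })
  mat <- matrix(mat, nrow = length(ids),
                dimnames = list(ids, keep))
  mat[!is.na(mat) & mat == -9] <- NA
  mat[!is.na(mat) & !(mat %in% c(0, 1, 2))] <- NA
  genotype_matrix(mat, family = fam, population = pop)
}

#' Write a genotype matrix to CSV
#'
#' Inverse of [read_genotype_csv()]; missing dosages are written as `NA`.
#'
#' @param g a `genotype_matrix`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genotype_csv <- function(g, path) {
  df <- data.frame(id = sample_ids(g), check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (!is.null(g$family)) df$family <- g$family
  if (!is.null(g$population)) df$population <- g$population
  df <- cbind(df, as.data.frame(g$dosage, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' Read biallelic SNP genotypes from a VCF file
#'
#' Dosage is the count of ALT alleles in the GT field; phased and unphased
#' calls are treated alike and `./.` becomes missing. Multiallelic records
#' are skipped with a warning; the number skipped is attached as attribute
#' `"skipped_multiallelic"`.
#'
#' @param path path to a VCF (v4.x) file, plain or bgzipped.
#' @return a [genotype_matrix()].
#' @export
read_genotype_vcf <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (ncol(v@gt) < 2) stop("VCF has no sample columns")
  alt <- vcfR::getALT(v)
  multi <- grepl(",", alt)
  n_skip <- sum(multi)
  if (n_skip > 0) {
    warning("skipped ", n_skip, " multiallelic record(s)")
    v <- v[!multi, ]
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  ids <- paste(vcfR::getCHROM(v), vcfR::getPOS(v), sep = "_")
  vid <- vcfR::getID(v)
  use <- !is.na(vid) & vid != "."
  ids[use] <- vid[use]
  dos <- apply(gt, 2, function(col) {
    a <- strsplit(col, "[/|]")
    vapply(a, function(x) {
      if (length(x) == 0 || any(x == ".") || any(is.na(x))) return(NA_real_)
      sum(as.numeric(x) > 0)
    }, numeric(1))
  })
  dos <- matrix(dos, ncol = ncol(gt), dimnames = list(ids, colnames(gt)))
  out <- genotype_matrix(t(dos))
  attr(out, "skipped_multiallelic") <- n_skip
  out
}

# ---- QC ---------------------------------------------------------------------

#' SNP quality control by call rate and minor allele frequency
#'
#' Keeps markers whose genotypic call rate is at least `min_call_rate` and
#' whose minor allele frequency (computed on non-missing dosages) is at least
#' `min_maf`. The sample set is never changed.
#'
#' @param g a `genotype_matrix`.
#' @param min_call_rate minimum fraction of non-missing calls (default 0.90).
#' @param min_maf minimum minor allele frequency (default 0.05).
#' @return a list with elements `genotypes` (the filtered `genotype_matrix`)
#'   and `report` (a `qc_report` with counts and thresholds).
#' @export
qc_filter <- function(g, min_call_rate = 0.90, min_maf = 0.05) {
  stopifnot(min_call_rate >= 0, min_call_rate <= 1,
            min_maf >= 0, min_maf <= 1)
  d <- g$dosage
  n <- nrow(d)
  cr <- colMeans(!is.na(d))
  p <- colMeans(d, na.rm = TRUE) / 2
  p[is.nan(p)] <- 0
  maf <- pmin(p, 1 - p)
  fail_cr <- cr < min_call_rate
  fail_maf <- !fail_cr & maf < min_maf
  keep <- !fail_cr & !fail_maf
  if (!any(keep))
    stop("QC removed every marker; relax min_call_rate/min_maf")
  report <- structure(list(
    markers_in = ncol(d),
    markers_kept = sum(keep),
    removed_call_rate = sum(fail_cr),
    removed_maf = sum(fail_maf),
    min_call_rate = min_call_rate,
    min_maf = min_maf), class = "qc_report")
  list(genotypes = g[, keep], report = report)
}

#' @export
print.qc_report <- function(x, ...) {
  cat("SNP QC:", x$markers_in, "markers in,", x$markers_kept, "kept\n")
  cat("  removed for call rate <", x$min_call_rate, ":",
      x$removed_call_rate, "\n")
  cat("  removed for MAF <", x$min_maf, ":", x$removed_maf, "\n")
  invisible(x)
}

#' Mean imputation of missing dosages
#'
#' Replaces each missing dosage at marker j with twice the observed alt-allele
#' frequency of that marker (the marker mean). Every downstream learner
#' requires a complete matrix; this simple policy is deliberately replaceable
#' by any external imputation done before loading.
#'
#' @param g a `genotype_matrix`.
#' @return a complete `genotype_matrix` (no missing values). Imputed values
#'   are generally fractional.
#' @export
impute_missing <- function(g) {
  d <- g$dosage
  if (!anyNA(d)) return(g)
  full_miss <- colSums(!is.na(d)) == 0
  if (any(full_miss))
    stop("marker(s) with no observed calls (run qc_filter first): ",
         paste(colnames(d)[full_miss][1:min(3, sum(full_miss))], collapse = ", "))
  mu <- colMeans(d, na.rm = TRUE)
  idx <- which(is.na(d), arr.ind = TRUE)
  d[idx] <- mu[idx[, 2]]
  out <- g
  out$dosage <- d
  # bypass constructor: imputed dosages are fractional by design
  out
}

# ---- phenotypes -------------------------------------------------------------

#' Validate long-format phenotype records
#'
#' Records carry one row per (individual, year, trait) observation with the
#' classification columns used by the progeny-trial mixed model:
#' `id`, `progeny`, `population`, `year`, `plot`, `trait`, `value`.
#'
#' @param df a data.frame with the columns above (`population` and `plot` may
#'   be absent, in which case a single level is filled in).
#' @return the validated data.frame with class `pheno_records`.
#' @export
pheno_records <- function(df) {
  need <- c("id", "progeny", "year", "trait", "value")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("phenotype records missing column(s): ",
                         paste(miss, collapse = ", "))
  if (!"population" %in% names(df)) df$population <- "P1"
  if (!"plot" %in% names(df)) df$plot <- "plot1"
  df$value <- as.numeric(df$value)
  if (any(!is.finite(df$value))) stop("non-finite phenotype value(s)")
  for (col in c("id", "progeny", "population", "year", "plot", "trait"))
    df[[col]] <- as.character(df[[col]])
  df <- df[, c("id", "progeny", "population", "year", "plot", "trait", "value")]
  class(df) <- c("pheno_records", "data.frame")
  df
}

#' Read phenotype records from CSV
#' @param path CSV with columns `id,progeny,population,year,plot,trait,value`.
#' @return a [pheno_records()] data.frame.
#' @export
read_phenotype_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  pheno_records(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' Write phenotype records to CSV
#' @param records a [pheno_records()] data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_phenotype_csv <- function(records, path) {
  utils::write.csv(as.data.frame(records), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
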