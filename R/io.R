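#' Read a genotype dosage table
#'
#' Supports the PLINK "raw" additive dosage dialect (header `FID IID PAT MAT
#' SEX PHENOTYPE` followed by one `<snp>_<allele>` column per SNP, values
#' 0/1/2/NA) and VCF (biallelic records; GT converted to alternate-allele
#' dosage, half-calls treated as missing, multi-allelic records rejected
#' with a count).
#'
#' @param path input file.
#' @param format `"plink_raw"` or `"vcf"`.
#' @return An object of class `dosage_table`: `dosages` (animals x SNPs
#'   numeric matrix with dimnames), `map` (data.frame chrom/id/pos, NA for
#'   plink_raw without a map), and `missing_rate`.
#' @export
read_dosage <- function(path, format = c("plink_raw", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(format,
         plink_raw = read_dosage_plink_raw(path),
         vcf = read_dosage_vcf(path))
}

read_dosage_plink_raw <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1L) stop("empty file: ", path)
  header <- strsplit(lines[1L], "[ \t]+")[[1L]]
  fixed <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (length(header) < 6L || !identical(header[1:6], fixed))
    stop("line 1: not a PLINK raw header (expected 'FID IID PAT MAT SEX PHENOTYPE ...')")
  nf <- length(header)
  snp_cols <- header[-(1:6)]
  rows <- vector("list", length(lines) - 1L)
  for (k in seq_along(rows)) {
    f <- strsplit(lines[k + 1L], "[ \t]+")[[1L]]
    if (length(f) != nf)
      stop(sprintf("line %d: expected %d fields, found %d", k + 1L, nf,
                   length(f)))
    rows[[k]] <- f
  }
  ids <- vapply(rows, `[`, character(1), 2L)
  geno <- if (length(snp_cols) > 0L) {
    vals <- vapply(rows, function(f) {
      v <- suppressWarnings(as.numeric(f[-(1:6)]))
      v[f[-(1:6)] == "NA"] <- NA_real_
      v
    }, numeric(length(snp_cols)))
    t(matrix(vals, nrow = length(snp_cols)))
  } else {
    matrix(numeric(0), length(ids), 0L)
  }
  bad <- which(!is.na(geno) & !(geno %in% c(0, 1, 2)), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("line %d: dosage value outside {0,1,2,NA}", bad[1L, 1L] + 1L))
  snp_ids <- sub("_[ACGT0-9]+$", "", snp_cols)
  dimnames(geno) <- list(ids, snp_ids)
  new_dosage_table(geno, map = NULL)
}

read_dosage_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("the 'vcfR' package is required for VCF input")
  v <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  multi <- grepl(",", fix$ALT)
  if (any(multi)) {
    warning(sum(multi), " multi-allelic record(s) dropped")
    v <- v[!multi, ]
    fix <- fix[!multi, , drop = FALSE]
  }
  if (nrow(fix) == 0L) stop("no biallelic records in ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  dose <- function(g) {
    if (is.na(g) || g %in% c(".", "./.", ".|.")) return(NA_real_)
    al <- strsplit(g, "[/|]")[[1L]]
    if (any(al == ".")) return(NA_real_)  # half-calls are missing
    sum(al == "1")
  }
  geno <- t(apply(gt, c(1L, 2L), dose)[, , drop = FALSE])
  snp_ids <- ifelse(is.na(fix$ID) | fix$ID == ".",
                    paste0(fix$CHROM, "_", fix$POS), fix$ID)
  colnames(geno) <- snp_ids
  map <- data.frame(chrom = fix$CHROM, id = snp_ids,
                    pos = as.numeric(fix$POS))
  new_dosage_table(geno, map)
}

new_dosage_table <- function(dosages, map = NULL) {
  if (anyDuplicated(rownames(dosages))) stop("duplicate animal ids")
  if (!is.null(colnames(dosages)) && anyDuplicated(colnames(dosages)))
    stop("duplicate SNP ids")
  structure(list(dosages = dosages, map = map,
                 missing_rate = mean(is.na(dosages))),
            class = "dosage_table")
}

#' @export
print.dosage_table <- function(x, ...) {
  cat(sprintf("<dosage_table> %d animals x %d SNPs (%.2f%% missing)%s\n",
              nrow(x$dosages), ncol(x$dosages), 100 * x$missing_rate,
              if (is.null(x$map)) "" else ", with map"))
  invisible(x)
}

#' Write a genotype dosage table
#'
#' @param x a `dosage_table` or a plain dosage matrix with dimnames.
#' @param path output file.
#' @param format `"plink_raw"` or `"vcf"` (VCF 4.2, unphased GT; dosage 1 is
#'   written as 0/1).
#' @param map data.frame (chrom, id, pos) required for VCF when `x` carries
#'   none.
#' @return the path, invisibly.
#' @export
write_dosage <- function(x, path, format = c("plink_raw", "vcf"),
                         map = NULL) {
  format <- match.arg(format)
  if (inherits(x, "dosage_table")) {
    map <- map %||% x$map
    x <- x$dosages
  }
  stopifnot(is.matrix(x))
  ids <- rownames(x) %||% as.character(seq_len(nrow(x)))
  snps <- colnames(x) %||% sprintf("snp%d", seq_len(ncol(x)))
  if (format == "plink_raw") {
    df <- data.frame(FID = ids, IID = ids, PAT = 0L, MAT = 0L, SEX = 0L,
                     PHENOTYPE = -9L, check.names = FALSE)
    geno <- as.data.frame(x)
    names(geno) <- paste0(snps, "_A")
    data.table::fwrite(cbind(df, geno), path, sep = "\t", na = "NA",
                       quote = FALSE)
  } else {
    if (is.null(map))
      map <- data.frame(chrom = 1L, id = snps, pos = seq_len(ncol(x)))
    gt <- c("0/0", "0/1", "1/1")
    body <- vapply(seq_len(ncol(x)), function(j) {
      calls <- ifelse(is.na(x[, j]), "./.", gt[x[, j] + 1L])
      paste(c(as.character(map$chrom[j]), as.integer(map$pos[j]),
              snps[j], "A", "B", ".", "PASS", ".", "GT", calls),
            collapse = "\t")
    }, character(1))
    writeLines(c(
      "##fileformat=VCFv4.2",
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
              "INFO", "FORMAT", ids), collapse = "\t"),
      body), path)
  }
  invisible(path)
}

#' Mean-impute missing dosages per locus
#'
#' Loci with missingness above `max_missing` are dropped (with a message);
#' remaining NAs are replaced by the locus mean dosage.
#'
#' @param genotypes dosage matrix.
#' @param max_missing per-locus missingness ceiling.
#' @return imputed matrix (possibly fewer columns).
#' @export
impute_dosages <- function(genotypes, max_missing = 0.1) {
  miss <- colMeans(is.na(genotypes))
  drop <- miss > max_missing
  if (any(drop)) {
    message(sum(drop), " loci dropped for missingness > ", max_missing)
    genotypes <- genotypes[, !drop, drop = FALSE]
    miss <- miss[!drop]
  }
  if (any(miss > 0)) {
    mu <- colMeans(genotypes, na.rm = TRUE)
    idx <- which(is.na(genotypes), arr.ind = TRUE)
    genotypes[idx] <- mu[idx[, 2L]]
  }
  genotypes
}

#' Write a JSON run manifest
#'
#' Records the configuration echo, seeds, package and R versions and md5
#' hashes of any input files, so a run can be reproduced bit-identically.
#'
#' @param path output JSON file.
#' @param config configuration list to echo.
#' @param seeds named seed list/vector.
#' @param inputs character vector of input file paths to hash.
#' @param extra extra named entries.
#' @return the manifest list, invisibly.
#' @export
write_manifest <- function(path, config = NULL, seeds = NULL,
                           inputs = character(), extra = list()) {
  hashes <- if (length(inputs) > 0L) as.list(tools::md5sum(inputs)) else NULL
  manifest <- c(list(
    package = "fstprior",
    version = as.character(utils::packageVersion("fstprior")),
    r_version = as.character(getRversion()),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config, seeds = as.list(seeds), input_md5 = hashes
  ), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, null = "null")
  invisible(manifest)
}
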