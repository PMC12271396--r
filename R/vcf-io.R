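#' @include accessors.R utils.R
#' @importClassesFrom vcfR vcfR
NULL

#' Write a GenotypeCohort as VCFv4.2
#'
#' Emits a minimal VCF with a GT-only FORMAT field, unphased genotypes
#' (`0/0`, `0/1`, `1/1`) and `./.` for missing, with the variant key in the
#' ID column and 1-based positions. Files ending in `.gz` are written
#' gzip-compressed.
#'
#' @param cohort a [GenotypeCohort-class].
#' @param path output file path (`.vcf` or `.vcf.gz`).
#' @return `path`, invisibly.
#' @export
writeCohortVcf <- function(cohort, path) {
  rd <- rowData(cohort)
  gt <- genotypes(cohort)
  fix <- cbind(CHROM = as.character(rd$chrom), POS = as.character(rd$pos),
               ID = rownames(cohort), REF = rd$ref, ALT = rd$alt,
               QUAL = ".", FILTER = "PASS", INFO = ".")
  code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  gtc <- matrix("./.", nrow = nrow(gt), ncol = ncol(gt))
  ok <- !is.na(gt)
  gtc[ok] <- code[as.character(gt[ok])]
  colnames(gtc) <- colnames(gt)
  gtm <- cbind(FORMAT = "GT", gtc)
  meta <- c("##fileformat=VCFv4.2",
            "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  obj <- new("vcfR", meta = meta, fix = fix, gt = gtm)
  if (grepl("\\.gz$", path)) {
    vcfR::write.vcf(obj, file = path)
  } else {
    tmp <- paste0(path, ".gz")
    vcfR::write.vcf(obj, file = tmp)
    con <- gzfile(tmp, "rt")
    writeLines(readLines(con), path)
    close(con)
    unlink(tmp)
  }
  invisible(path)
}

#' Read a VCF into a GenotypeCohort
#'
#' Parses the GT field into alternate-allele dosages. Non-biallelic records
#' (multiple ALT alleles or symbolic alleles) are rejected with a logged
#' count; variant identities are normalized through [variantKey()].
#'
#' @param path VCF file (`.vcf` or `.vcf.gz`).
#' @param dataset dataset code stored in `colData`.
#' @param platform platform label (WGG/WES/WGS).
#' @return A [GenotypeCohort-class]; the number of rejected non-biallelic
#'   records is attached as attribute `"n_rejected"`.
#' @export
readCohortVcf <- function(path, dataset = "COHORT", platform = "WGS") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  biallelic <- !grepl(",", fix[, "ALT"], fixed = TRUE) &
    fix[, "ALT"] %in% c("A", "C", "G", "T") &
    fix[, "REF"] %in% c("A", "C", "G", "T")
  nRejected <- sum(!biallelic)
  if (nRejected > 0)
    message("readCohortVcf: rejected ", nRejected, " non-biallelic record(s)")
  gtChar <- vcfR::extract.gt(v, element = "GT")[biallelic, , drop = FALSE]
  dosage <- matrix(NA_integer_, nrow = nrow(gtChar), ncol = ncol(gtChar))
  clean <- gsub("|", "/", gtChar, fixed = TRUE)
  dosage[clean %in% c("0/0")] <- 0L
  dosage[clean %in% c("0/1", "1/0")] <- 1L
  dosage[clean %in% c("1/1")] <- 2L
  colnames(dosage) <- colnames(gtChar)
  variants <- data.frame(chrom = fix[biallelic, "CHROM"],
                         pos = as.integer(fix[biallelic, "POS"]),
                         ref = fix[biallelic, "REF"],
                         alt = fix[biallelic, "ALT"])
  out <- GenotypeCohort(dosage, variants,
                        data.frame(sample_id = colnames(gtChar),
                                   dataset = dataset, platform = platform))
  attr(out, "n_rejected") <- nRejected
  out
}

#' Write ancestry fractions as TSV
#'
#' Columns: sample, one column per ancestry component, cluster index and
#' cluster name when available.
#'
#' @param q a [QMatrix-class].
#' @param path output path.
#' @param clusters optional [AncestryClusters-class] supplying assignments
#'   and names.
#' @export
writeQMatrixTsv <- function(q, path, clusters = NULL) {
  df <- data.frame(sample = rownames(q@Q), q@Q, check.names = FALSE)
  if (!is.null(clusters)) {
    df$cluster <- clusters@assignment
    if (length(clusters@clusterNames))
      df$cluster_name <- clusters@clusterNames[clusters@assignment]
  } else if (!all(is.na(q@cluster))) {
    df$cluster <- q@cluster
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the annotation catalog as TSV
#' @param catalog annotation data.frame (`key`, `clinvar_class`,
#'   `pharm_level`, `label`).
#' @param path file path.
#' @rdname catalogTsv
#' @export
writeCatalogTsv <- function(catalog, path) {
  utils::write.table(catalog, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname catalogTsv
#' @export
readCatalogTsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("key", "clinvar_class", "pharm_level")
  if (!all(need %in% colnames(df)))
    stop("catalog must contain columns: ", paste(need, collapse = ", "))
  if (!all(df$clinvar_class %in% .CLINVAR_CLASSES))
    stop("unknown clinvar_class value(s)")
  if (!all(df$pharm_level %in% .PHARM_LEVELS))
    stop("unknown pharm_level value(s)")
  if (anyDuplicated(df$key)) stop("catalog keys must be unique")
  if (is.null(df$label)) df$label <- ""
  df
}
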