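#' Canonical variant key
#'
#' Builds the normalized `chrom:pos:ref:alt` string used to match variants
#' across datasets. Chromosome labels are stripped of any `chr` prefix and
#' alleles are upper-cased, so the mapping is idempotent.
#'
#' @param chrom,pos,ref,alt vectors of chromosome label, 1-based position,
#'   reference allele and alternate allele.
#' @return character vector of keys.
#' @export
variantKey <- function(chrom, pos, ref, alt) {
  chrom <- sub("^chr", "", as.character(chrom), ignore.case = TRUE)
  paste(chrom, as.integer(pos), toupper(as.character(ref)),
        toupper(as.character(alt)), sep = ":")
}

#' Parse variant keys back into their fields
#' @param keys character vector of `chrom:pos:ref:alt` keys.
#' @return data.frame with chrom, pos, ref, alt.
#' @export
parseVariantKey <- function(keys) {
  parts <- strsplit(keys, ":", fixed = TRUE)
  bad <- lengths(parts) != 4L
  if (any(bad)) stop("malformed variant key(s): ",
                     paste(utils::head(keys[bad], 3), collapse = ", "))
  m <- matrix(unlist(parts), ncol = 4L, byrow = TRUE)
  data.frame(chrom = m[, 1], pos = as.integer(m[, 2]),
             ref = m[, 3], alt = m[, 4], stringsAsFactors = FALSE)
}

# Deterministic child seeds so each pipeline stage has its own stream while
# the whole run is reproducible from one integer. Kept below 2^31 - 1.
.childSeed <- function(seed, offset) {
  as.integer((as.double(seed) * 48271 + offset * 16807) %% 2147483647)
}

# Dirichlet sampler via normalized gamma draws; alpha entries of 0 give
# exact zeros (degenerate components).
.rdirichlet <- function(n, alpha) {
  k <- length(alpha)
  x <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  sums <- rowSums(x)
  sums[sums == 0] <- 1
  x / sums
}

# Ordering of chromosome labels: numeric ascending, then X, Y, MT, others.
.chromOrder <- function(chrom) {
  num <- suppressWarnings(as.integer(chrom))
  rank <- ifelse(!is.na(num), num,
                 ifelse(chrom == "X", 23L,
                        ifelse(chrom == "Y", 24L,
                               ifelse(chrom %in% c("MT", "M"), 25L, 26L))))
  rank
}

# One record of the structured filter log carried through the pipeline.
.filterLog <- function(step, unit, nIn, nOut, detail = "") {
  data.frame(step = step, unit = unit, n_in = nIn, n_out = nOut,
             n_removed = nIn - nOut, detail = detail,
             stringsAsFactors = FALSE)
}
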