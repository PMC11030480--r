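#' Construct a population variant table
#'
#' Observed variants over a large sequenced population, with allele counts.
#' Duplicate (chromosome, position, ref, alt) records are rejected;
#' `allele_count` must be at least 1 and no greater than `allele_number`.
#'
#' @param variants data.frame with columns `chromosome`, `position`, `ref`,
#'   `alt`, `allele_count`, `allele_number` (extra columns are kept).
#' @param cohort_size Number of sequenced individuals the table derives
#'   from (stored as an attribute; used for allele-frequency reporting).
#' @return data.frame of class `population_variants`.
#' @export
population_variants <- function(variants, cohort_size = NA_integer_) {
  req <- c("chromosome", "position", "ref", "alt", "allele_count",
           "allele_number")
  miss <- setdiff(req, names(variants))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "))
  v <- as.data.frame(variants, stringsAsFactors = FALSE)
  v$position <- as.integer(v$position)
  v$ref <- toupper(v$ref); v$alt <- toupper(v$alt)
  v$allele_count <- as.integer(v$allele_count)
  v$allele_number <- as.integer(v$allele_number)
  if (any(v$allele_count < 1L))
    stop("allele_count must be >= 1 for observed variants")
  if (any(v$allele_count > v$allele_number))
    stop("allele_count exceeds allele_number")
  key <- variant_key(v$chromosome, v$position, v$ref, v$alt)
  if (anyDuplicated(key))
    stop("duplicate variant records: ",
         paste(utils::head(key[duplicated(key)], 3), collapse = ", "))
  attr(v, "cohort_size") <- as.integer(cohort_size)
  class(v) <- c("population_variants", "data.frame")
  v
}

#' Read population variants from VCF or TSV
#'
#' VCF input (via \pkg{vcfR}) takes AC/AN from INFO; multi-allelic records
#' must be decomposed into one ALT per row upstream (`bcftools norm -m-`).
#' TSV input expects the [population_variants()] column set.
#'
#' @param path File path; format inferred from the extension
#'   (`.vcf`/`.vcf.gz` versus anything else = TSV) unless `format` is given.
#' @param format `"vcf"`, `"tsv"` or `NULL` (infer).
#' @param cohort_size Passed to [population_variants()].
#' @return A `population_variants` table.
#' @export
read_population_variants <- function(path, format = NULL,
                                     cohort_size = NA_integer_) {
  if (is.null(format))
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tsv"
  if (format == "vcf") {
    vcf <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
    ac <- suppressWarnings(as.integer(vcfR::extract.info(vcf, "AC")))
    an <- suppressWarnings(as.integer(vcfR::extract.info(vcf, "AN")))
    if (anyNA(ac) || anyNA(an))
      stop("VCF records lack integer AC/AN INFO fields: ", path)
    v <- data.frame(chromosome = fix$CHROM,
                    position = as.integer(fix$POS),
                    ref = fix$REF, alt = fix$ALT,
                    allele_count = ac, allele_number = an,
                    stringsAsFactors = FALSE)
  } else {
    v <- utils::read.delim(path, stringsAsFactors = FALSE)
  }
  population_variants(v, cohort_size = cohort_size)
}

#' Write population variants as TSV or minimal VCF
#'
#' @param pop A `population_variants` table.
#' @param path Output path; `.vcf` extension selects VCF, else TSV.
#' @return `path`, invisibly.
#' @export
write_population_variants <- function(pop, path) {
  if (grepl("\\.vcf$", path)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
      "##fileformat=VCFv4.2",
      "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"Allele count\">",
      "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Allele number\">",
      "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
    writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t.\tAC=%d;AN=%d",
                       pop$chromosome, pop$position, pop$ref, pop$alt,
                       pop$allele_count, pop$allele_number), con)
  } else {
    utils::write.table(as.data.frame(pop), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

# Distinct observed SNVs per genomic position over [start, end]; returns an
# integer vector indexed by offset 1..(end-start+1). Indels are ignored and
# each distinct alternate allele counts once (capped at 3 per site by the
# duplicate-record invariant).
.snv_counts_by_position <- function(pop, chromosome, start, end) {
  is_snv <- nchar(pop$ref) == 1L & nchar(pop$alt) == 1L
  sel <- is_snv & pop$chromosome == chromosome &
    pop$position >= start & pop$position <= end
  counts <- integer(end - start + 1L)
  if (any(sel)) {
    tb <- table(pop$position[sel])
    counts[as.integer(names(tb)) - start + 1L] <- as.integer(tb)
  }
  counts
}
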