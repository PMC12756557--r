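#' Read one sample's variant records from a VCF
#'
#' Parses a VCF (via vcfR), pulls total depth `DP` and alternate observation
#' count `AO` for each record, and keeps only records with quality strictly
#' greater than `min_qual` — a record at exactly `min_qual` is excluded.
#' Multi-allelic records are collapsed to a single alternate count by summing
#' `AO` over the alternates; the ALT string is kept as written. When `AO` is
#' absent from INFO the per-sample FORMAT `AD` field is used as a fallback
#' (sum of non-reference allele depths).
#'
#' @param vcf_path path to a VCF (v4.x) file.
#' @param min_qual quality cutoff; records must satisfy `qual > min_qual`.
#' @return data frame with columns `chrom`, `pos`, `ref`, `alt`, `qual`,
#'   `depth`, `alt_obs`, in file order.
#' @export
read_sample_variants <- function(vcf_path, min_qual = 25) {
  if (!file.exists(vcf_path)) stopf("cannot read VCF: %s", vcf_path)
  v <- tryCatch(vcfR::read.vcfR(vcf_path, verbose = FALSE),
                error = function(e) stopf("failed to parse VCF %s: %s",
                                          vcf_path, conditionMessage(e)))
  fx <- vcfR::getFIX(v)
  if (is.null(dim(fx))) fx <- matrix(fx, nrow = 1L, dimnames = list(NULL, names(fx)))
  if (nrow(fx) == 0L) {
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      qual = numeric(0), depth = integer(0),
                      alt_obs = integer(0), stringsAsFactors = FALSE))
  }
  chrom <- fx[, "CHROM"]
  pos <- as.integer(fx[, "POS"])
  qual <- suppressWarnings(as.numeric(fx[, "QUAL"]))
  coord <- site_key(chrom, pos)
  if (anyNA(qual))
    stopf("record without a numeric QUAL at %s",
          paste(coord[is.na(qual)], collapse = ", "))

  dp <- suppressWarnings(as.integer(vcfR::extract.info(v, "DP")))
  ao_raw <- vcfR::extract.info(v, "AO")
  ao <- vapply(ao_raw, function(x) {
    if (is.na(x)) return(NA_integer_)
    sum(as.integer(strsplit(x, ",", fixed = TRUE)[[1]]))
  }, integer(1), USE.NAMES = FALSE)

  if (anyNA(ao)) {
    ad <- tryCatch(vcfR::extract.gt(v, "AD"), error = function(e) NULL)
    if (!is.null(ad) && ncol(ad) >= 1L) {
      fill <- vapply(ad[, 1L], function(x) {
        if (is.na(x)) return(NA_integer_)
        parts <- as.integer(strsplit(x, ",", fixed = TRUE)[[1]])
        sum(parts[-1L])
      }, integer(1), USE.NAMES = FALSE)
      ao[is.na(ao)] <- fill[is.na(ao)]
    }
  }
  if (anyNA(dp))
    stopf("record missing DP at %s", paste(coord[is.na(dp)], collapse = ", "))
  if (anyNA(ao))
    stopf("record missing AO (and no AD fallback) at %s",
          paste(coord[is.na(ao)], collapse = ", "))
  if (any(ao < 0L | ao > dp))
    stopf("alternate count outside [0, DP] at %s",
          paste(coord[ao < 0L | ao > dp], collapse = ", "))

  keep <- qual > min_qual
  data.frame(chrom = chrom[keep], pos = pos[keep],
             ref = fx[keep, "REF"], alt = fx[keep, "ALT"],
             qual = qual[keep], depth = dp[keep], alt_obs = ao[keep],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Apply caller-level inclusion thresholds to variant records
#'
#' Keeps records with `alt_obs >= min_alt`, `depth >= min_depth` and
#' `alt_obs/depth >= min_vaf`. These are minima, so boundary values pass.
#'
#' @param records data frame as returned by [read_sample_variants()].
#' @param min_alt minimum alternate observation count.
#' @param min_depth minimum total depth.
#' @param min_vaf minimum variant allele frequency.
#' @return the surviving rows, order preserved; may be empty.
#' @export
apply_caller_thresholds <- function(records, min_alt = 4L, min_depth = 5L,
                                    min_vaf = 0.2) {
  vaf_ok <- ifelse(records$depth > 0L,
                   records$alt_obs / records$depth >= min_vaf,
                   min_vaf <= 0)
  keep <- records$alt_obs >= min_alt & records$depth >= min_depth & vaf_ok
  records[keep, , drop = FALSE]
}

#' Union of variant sites across samples
#'
#' @param records_list list of per-sample record data frames.
#' @return data frame of unique `(chrom, pos, ref, alt)` keys sorted by
#'   `(chrom, pos, ref, alt)`.
#' @export
site_union <- function(records_list) {
  all <- do.call(rbind, lapply(records_list, function(r)
    r[, c("chrom", "pos", "ref", "alt"), drop = FALSE]))
  if (is.null(all) || nrow(all) == 0L)
    return(data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0)))
  all <- unique(all)
  all <- all[order(all$chrom, all$pos, all$ref, all$alt), , drop = FALSE]
  rownames(all) <- NULL
  all
}
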