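#' Build the samples-by-sites VAF matrix with its depth mask
#'
#' For each sample and union site, the VAF is `alt_obs / depth` taken from
#' the sample's own variant record when one survives the filters. A site
#' with adequate table depth but no surviving record is reference-homozygous
#' under the default `uncalled = "reference"` and gets VAF 0; under
#' `uncalled = "missing"` it is masked instead, so only sites where both
#' samples carry a call can enter a pairwise distance. Sites with missing
#' depth are always masked.
#'
#' @param records_list named list of per-sample (already filtered) record
#'   data frames; names are sample ids.
#' @param depth samples x sites depth matrix aligned to `sites` (e.g. from
#'   [read_depth_table()]); `NA` marks unknown depth.
#' @param sites union site table (`chrom`, `pos`, `ref`, `alt`); a record at
#'   a site outside this set is an error.
#' @param uncalled how to treat a covered site with no variant record.
#' @return object of class `VAFMatrix`: list with `vaf` and `depth`
#'   (samples x sites), `samples`, `sites`.
#' @export
build_vaf_matrix <- function(records_list, depth, sites,
                             uncalled = c("reference", "missing")) {
  uncalled <- match.arg(uncalled)
  samples <- names(records_list)
  if (is.null(samples) || any(!nzchar(samples)))
    stopf("records_list must be a named list (sample ids as names)")
  keys <- site_key(sites$chrom, sites$pos)
  if (anyDuplicated(keys))
    stopf("duplicate CHROM:POS in site set")
  if (!identical(dim(depth), c(length(samples), length(keys)))) {
    if (is.null(rownames(depth)) || is.null(colnames(depth)))
      stopf("depth matrix must be samples x sites with dimnames")
    miss_s <- setdiff(samples, rownames(depth))
    if (length(miss_s)) stopf("depth matrix lacks sample(s): %s",
                              paste(miss_s, collapse = ", "))
    miss_k <- setdiff(keys, colnames(depth))
    if (length(miss_k)) stopf("depth matrix lacks site(s): %s",
                              paste(utils::head(miss_k, 5), collapse = ", "))
    depth <- depth[samples, keys, drop = FALSE]
  } else {
    dimnames(depth) <- list(samples, keys)
  }

  base <- if (uncalled == "reference") 0 else NA_real_
  vaf <- matrix(base, length(samples), length(keys),
                dimnames = list(samples, keys))
  vaf[is.na(depth)] <- NA_real_
  for (i in seq_along(samples)) {
    r <- records_list[[i]]
    if (nrow(r) == 0L) next
    rk <- site_key(r$chrom, r$pos)
    j <- match(rk, keys)
    if (anyNA(j))
      stopf("sample %s has record(s) outside the site set: %s",
            samples[i], paste(rk[is.na(j)], collapse = ", "))
    if (any(r$depth <= 0L))
      stopf("sample %s has a record with non-positive depth", samples[i])
    vaf[i, j] <- r$alt_obs / r$depth
  }

  structure(list(vaf = vaf, depth = depth, samples = samples, sites = sites),
            class = "VAFMatrix")
}

#' @export
print.VAFMatrix <- function(x, ...) {
  n_masked <- sum(is.na(x$depth))
  cat(sprintf("VAF matrix: %d samples x %d sites (%.1f%% cells with unknown depth)\n",
              length(x$samples), nrow(x$sites),
              100 * n_masked / length(x$depth)))
  invisible(x)
}

#' Subset a VAF matrix by site indices
#'
#' Used by the position bootstrap: resampled site columns carry their depth
#' mask with them. Duplicate indices are allowed.
#' @param m a `VAFMatrix`.
#' @param idx integer site indices (may repeat).
#' @return a `VAFMatrix` over the selected columns.
#' @export
subset_sites <- function(m, idx) {
  structure(list(
    vaf = m$vaf[, idx, drop = FALSE],
    depth = m$depth[, idx, drop = FALSE],
    samples = m$samples,
    sites = m$sites[idx, , drop = FALSE]
  ), class = "VAFMatrix")
}
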