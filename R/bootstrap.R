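#' Position-bootstrap clade support for the Ward.D2 tree
#'
#' Resamples variant positions (columns of the VAF matrix) with replacement,
#' keeping each resampled position's depth mask, then recomputes the masked
#' pairwise distances and the Ward.D2 tree. The support of a clade of the
#' reference tree is the fraction of replicate trees containing a clade with
#' exactly the same leaf set. Positions are resampled first and the per-pair
#' coverage mask re-applied on the resampled set.
#'
#' A replicate in which some sample pair ends with no usable positions is
#' dropped (and counted); if more than 10% of replicates are dropped the run
#' aborts, since supports over so few effective replicates would be
#' misleading.
#'
#' @param m a `VAFMatrix`.
#' @param B number of bootstrap replicates.
#' @param min_pair_depth per-pair coverage mask threshold.
#' @param seed integer seed; one stream is seeded once and each replicate
#'   draws from a sub-seed keyed by its index, so results are reproducible
#'   and independent of evaluation order.
#' @param tree optional reference tree (defaults to clustering `m` itself).
#' @return object of class `vaf_boot`: data frame `support_table` (clade
#'   members semicolon-joined, clade size, support), `clades` (list of leaf
#'   sets), `support` (numeric vector aligned to `clades`), `n_replicates`
#'   (retained), `n_dropped`, `tree`.
#' @export
bootstrap_support <- function(m, B = 1000L, min_pair_depth = 8L, seed = 1L,
                              tree = NULL) {
  if (!inherits(m, "VAFMatrix")) stopf("m must be a VAFMatrix")
  if (!is_num1(B) || B < 1L) stopf("B must be >= 1")
  p <- nrow(m$sites)
  if (is.null(tree))
    tree <- ward_cluster(pairwise_distance(m, min_pair_depth = min_pair_depth))

  ref_clades <- tree_clades(tree, trivial = FALSE)
  keys <- vapply(ref_clades, paste, character(1), collapse = ";")
  hits <- stats::setNames(numeric(length(keys)), keys)

  sub_seeds <- with_seed(seed, sample.int(.Machine$integer.max, B))
  dropped <- 0L
  for (r in seq_len(B)) {
    idx <- with_seed(sub_seeds[r], sample.int(p, p, replace = TRUE))
    mb <- subset_sites(m, idx)
    db <- tryCatch(pairwise_distance(mb, min_pair_depth = min_pair_depth),
                   error = function(e) NULL)
    if (is.null(db) || any(db$flagged[upper.tri(db$flagged)])) {
      dropped <- dropped + 1L
      next
    }
    tb <- ward_cluster(db)
    bk <- vapply(tree_clades(tb, trivial = FALSE), paste, character(1),
                 collapse = ";")
    found <- keys %in% bk
    hits[found] <- hits[found] + 1
  }
  if (dropped > 0.1 * B)
    stopf("%d of %d bootstrap replicates had a sample pair with no usable positions; supports would be unreliable (raise coverage or lower min_pair_depth)",
          dropped, B)
  n_eff <- B - dropped
  support <- hits / n_eff
  structure(list(
    support_table = data.frame(
      clade = keys,
      size = vapply(ref_clades, length, integer(1)),
      support = as.numeric(support),
      stringsAsFactors = FALSE),
    clades = ref_clades,
    support = as.numeric(support),
    n_replicates = n_eff,
    n_dropped = dropped,
    tree = tree
  ), class = "vaf_boot")
}

#' @export
print.vaf_boot <- function(x, ...) {
  cat(sprintf("Bootstrap clade support: %d clades over %d replicates%s\n",
              length(x$clades), x$n_replicates,
              if (x$n_dropped) sprintf(" (%d dropped)", x$n_dropped) else ""))
  cat(sprintf("  support range [%.2f, %.2f]; %d clade(s) >= 0.95\n",
              min(x$support), max(x$support), sum(x$support >= 0.95)))
  invisible(x)
}

#' Support of the clade exactly matching a given leaf set
#'
#' @param boot a `vaf_boot`.
#' @param leaves character vector of leaf labels.
#' @return the support fraction, or `NA` if no reference clade has exactly
#'   this leaf set.
#' @export
clade_support <- function(boot, leaves) {
  key <- paste(sort(leaves), collapse = ";")
  i <- match(key, boot$support_table$clade)
  if (is.na(i)) NA_real_ else boot$support_table$support[i]
}

#' Write the support table as TSV
#' @param boot a `vaf_boot`.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_support_tsv <- function(boot, path) {
  tab <- boot$support_table
  tab$n_replicates <- boot$n_replicates
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
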