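#' Fit the VAF relatedness model: masked distances, Ward tree, support
#'
#' One-stop analysis of a VAF matrix: computes the pairwise-complete
#' normalized Euclidean distances under the per-pair coverage mask, builds
#' the Ward.D2 dendrogram, and (optionally) attaches position-bootstrap
#' clade supports.
#'
#' @param m a `VAFMatrix` from [build_vaf_matrix()].
#' @param min_pair_depth coverage each sample must have at a position for it
#'   to count for a pair (reads).
#' @param boot number of bootstrap replicates; 0 skips the bootstrap.
#' @param seed seed for the bootstrap resampling.
#' @return object of class `vafclust`: list with `dist` (`vaf_dist`),
#'   `tree` ([stats::hclust]), `boot` (`vaf_boot` or `NULL`), `n_samples`,
#'   `n_sites`, `call`.
#' @examples
#' ch <- simulate_cohort(cohort_config(n_species = 3, samples_per_species = 3,
#'                                     n_sites = 500, seed = 11))
#' vm <- build_vaf_matrix(ch$records, ch$depth, ch$sites)
#' fit <- vafclust(vm, boot = 25, seed = 1)
#' print(fit)
#' @export
vafclust <- function(m, min_pair_depth = 8L, boot = 0L, seed = 1L) {
  d <- pairwise_distance(m, min_pair_depth = min_pair_depth)
  tree <- ward_cluster(d)
  bt <- if (boot >= 1L)
    bootstrap_support(m, B = boot, min_pair_depth = min_pair_depth,
                      seed = seed, tree = tree)
  else NULL
  structure(list(dist = d, tree = tree, boot = bt,
                 n_samples = length(m$samples), n_sites = nrow(m$sites),
                 min_pair_depth = as.integer(min_pair_depth),
                 call = match.call()),
            class = "vafclust")
}

#' @export
print.vafclust <- function(x, ...) {
  cat("VAF distance clustering (ward.D2)\n")
  cat(sprintf("  %d samples, %d variant sites, pair mask depth >= %d\n",
              x$n_samples, x$n_sites, x$min_pair_depth))
  off <- upper.tri(x$dist$d)
  cat(sprintf("  distances in [%.4f, %.4f]\n",
              min(x$dist$d[off]), max(x$dist$d[off])))
  if (!is.null(x$boot))
    cat(sprintf("  bootstrap: %d replicates, %d/%d clades with support >= 0.95\n",
                x$boot$n_replicates, sum(x$boot$support >= 0.95),
                length(x$boot$support)))
  invisible(x)
}

#' @export
summary.vafclust <- function(object, ...) {
  off <- upper.tri(object$dist$d)
  out <- list(
    n_samples = object$n_samples,
    n_sites = object$n_sites,
    min_pair_depth = object$min_pair_depth,
    distance_range = range(object$dist$d[off]),
    n_sites_used_range = range(object$dist$n_sites_used[off]),
    merge_heights = object$tree$height,
    support = if (is.null(object$boot)) NULL else object$boot$support
  )
  class(out) <- "summary.vafclust"
  out
}

#' @export
print.summary.vafclust <- function(x, ...) {
  cat(sprintf("%d samples x %d sites; pair mask depth >= %d\n",
              x$n_samples, x$n_sites, x$min_pair_depth))
  cat(sprintf("pairwise distances: [%.4f, %.4f]; usable positions per pair: %d-%d\n",
              x$distance_range[1], x$distance_range[2],
              x$n_sites_used_range[1], x$n_sites_used_range[2]))
  cat(sprintf("merge heights: %.4f .. %.4f over %d merges\n",
              min(x$merge_heights), max(x$merge_heights),
              length(x$merge_heights)))
  if (!is.null(x$support))
    cat(sprintf("clade support: median %.2f, min %.2f\n",
                stats::median(x$support), min(x$support)))
  invisible(x)
}

#' Plot the fitted dendrogram
#'
#' Draws the Ward.D2 tree; if bootstrap supports are attached, non-trivial
#' clades are annotated with their support percentage.
#'
#' @param x a `vafclust` fit.
#' @param support_cex size of support labels.
#' @param ... passed to [graphics::plot()] for the dendrogram.
#' @export
plot.vafclust <- function(x, support_cex = 0.7, ...) {
  graphics::plot(x$tree, hang = -1,
                 ylab = "normalized VAF distance", ...)
  if (!is.null(x$boot)) {
    n_merge <- nrow(x$tree$merge)
    # x position of each internal node in the standard hclust layout
    leaf_x <- stats::setNames(seq_len(n_merge + 1L), x$tree$order)
    node_x <- numeric(n_merge)
    for (k in seq_len(n_merge)) {
      xs <- vapply(x$tree$merge[k, ], function(v)
        if (v < 0L) leaf_x[[as.character(-v)]] else node_x[v], numeric(1))
      node_x[k] <- mean(xs)
    }
    sup <- c(x$boot$support, NA)  # root (last merge) is a trivial clade
    lab <- ifelse(is.na(sup), "", sprintf("%d", round(100 * sup)))
    graphics::text(node_x, x$tree$height, lab, pos = 3, cex = support_cex,
                   col = "grey30")
  }
  invisible(x)
}

#' @rdname to_newick
#' @export
to_newick.vafclust <- function(tree, digits = 10L) to_newick(tree$tree, digits)
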