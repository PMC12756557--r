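#' Ward.D2 agglomerative clustering of a VAF distance matrix
#'
#' Runs Ward's minimum-variance clustering in its ward.D2 form, i.e. the
#' Lance–Williams update on squared dissimilarities
#' \deqn{d(k, i \cup j) = \sqrt{ \frac{(n_i+n_k) d^2(k,i) + (n_j+n_k) d^2(k,j)
#'       - n_k d^2(i,j)}{n_i+n_j+n_k} }}
#' with merge heights equal to the merging distance. Matrices with flagged
#' (undefined) pairs are refused — the method does not impute.
#'
#' @param d a `vaf_dist` from [pairwise_distance()], or a `dist` /
#'   symmetric matrix.
#' @return an [stats::hclust] tree with sample ids as labels.
#' @export
ward_cluster <- function(d) {
  dd <- if (inherits(d, "vaf_dist")) {
    if (any(d$flagged[upper.tri(d$flagged)]))
      stopf("%d sample pair(s) have no co-covered positions; refusing to cluster an undefined distance matrix",
            sum(d$flagged[upper.tri(d$flagged)]))
    stats::as.dist(d$d)
  } else if (inherits(d, "dist")) d else stats::as.dist(d)
  if (attr(dd, "Size") < 2L) stopf("need at least 2 samples to cluster")
  if (anyNA(dd)) stopf("distance matrix contains undefined entries")
  stats::hclust(dd, method = "ward.D2")
}

#' Serialize an hclust tree as ultrametric Newick
#'
#' Leaves sit at height 0 and each internal node at its merge height, so a
#' branch length is the parent's merge height minus the child's (the leaf
#' branch below a height-h merge has length h). Labels containing Newick
#' metacharacters (whitespace, `():;,'"[]`) are single-quoted with internal
#' quotes doubled.
#'
#' @param tree an [stats::hclust] object or a `vafclust` fit.
#' @param digits significant digits for branch lengths.
#' @return a single Newick string terminated by `;`.
#' @export
to_newick <- function(tree, digits = 10L) UseMethod("to_newick")

#' @rdname to_newick
#' @export
to_newick.hclust <- function(tree, digits = 10L) {
  labs <- tree$labels
  if (is.null(labs)) labs <- as.character(seq_len(nrow(tree$merge) + 1L))
  quote_label <- function(x) {
    if (grepl("[][():;,'\"[:space:]]", x))
      paste0("'", gsub("'", "''", x, fixed = TRUE), "'")
    else x
  }
  blen <- function(h) sprintf("%.*g", as.integer(digits), h)
  node_str <- function(k, parent_h) {
    # k < 0: leaf -k ; k > 0: internal merge row k
    if (k < 0L)
      return(paste0(quote_label(labs[-k]), ":", blen(parent_h)))
    h <- tree$height[k]
    paste0("(", node_str(tree$merge[k, 1], h), ",",
           node_str(tree$merge[k, 2], h), "):", blen(parent_h - h))
  }
  root <- nrow(tree$merge)
  h <- tree$height[root]
  paste0("(", node_str(tree$merge[root, 1], h), ",",
         node_str(tree$merge[root, 2], h), ");")
}

#' Leaf sets of all internal nodes of an hclust tree
#'
#' @param tree an [stats::hclust] object.
#' @param trivial keep the root clade (all leaves)? Single leaves are never
#'   included.
#' @return list of character vectors of sorted leaf labels, one per internal
#'   node (in merge order).
#' @export
tree_clades <- function(tree, trivial = FALSE) {
  labs <- tree$labels
  if (is.null(labs)) labs <- as.character(seq_len(nrow(tree$merge) + 1L))
  n_merge <- nrow(tree$merge)
  sets <- vector("list", n_merge)
  for (k in seq_len(n_merge)) {
    mem <- unlist(lapply(tree$merge[k, ], function(x)
      if (x < 0L) labs[-x] else sets[[x]]))
    sets[[k]] <- sort(mem)
  }
  if (!trivial) sets <- sets[-n_merge]
  sets
}

#' Cut a tree into k clusters and score recovery against truth labels
#'
#' Cuts the dendrogram with [stats::cutree()] and computes the adjusted
#' Rand index (chance-corrected partition agreement; 1 = identical,
#' 0 = what random assignment achieves on average) against known labels.
#'
#' @param tree an [stats::hclust] object.
#' @param k number of clusters, `1 <= k <=` number of leaves.
#' @param truth labels; if named, aligned to tree labels by name, otherwise
#'   taken in leaf-index order.
#' @return list with `partition` (named cluster ids) and `ari`.
#' @export
cut_and_score <- function(tree, k, truth) {
  n <- nrow(tree$merge) + 1L
  if (k < 1L || k > n) stopf("k must be in 1..%d", n)
  part <- stats::cutree(tree, k = k)
  tl <- if (!is.null(names(truth))) {
    miss <- setdiff(names(part), names(truth))
    if (length(miss)) stopf("truth labels missing for: %s", paste(miss, collapse = ", "))
    truth[names(part)]
  } else {
    if (length(truth) != n) stopf("truth must have one label per leaf")
    truth
  }
  list(partition = part, ari = mclust::adjustedRandIndex(part, tl))
}

#' Do hybrids sit between their parent species?
#'
#' For each hybrid sample, compares its mean distance to each parent
#' species' samples with the mean distance between the two parent species.
#' An F1 hybrid carries one allele from each parent at every locus, so at
#' parental fixed differences its VAF is centered at 0.5 and both
#' hybrid-to-parent distances fall near half the parent-parent distance.
#'
#' @param d a `vaf_dist`.
#' @param labels named taxon labels for every sample in `d`.
#' @param hybrid_parents named list: hybrid taxon -> character pair of
#'   parent taxa.
#' @return data frame with one row per hybrid sample: mean distance to each
#'   parent group, parent-parent mean distance, and whether the sample is
#'   intermediate (both hybrid-parent distances strictly below the
#'   parent-parent distance).
#' @export
hybrid_placement <- function(d, labels, hybrid_parents) {
  dm <- d$d
  labels <- labels[d$samples]
  rows <- list()
  for (htax in names(hybrid_parents)) {
    pp <- hybrid_parents[[htax]]
    hs <- d$samples[labels == htax]
    pa <- d$samples[labels == pp[1]]
    pb <- d$samples[labels == pp[2]]
    if (!length(hs) || !length(pa) || !length(pb))
      stopf("hybrid %s or its parents have no samples", htax)
    d_ab <- mean(dm[pa, pb, drop = FALSE])
    for (h in hs) {
      d_a <- mean(dm[h, pa]); d_b <- mean(dm[h, pb])
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = h, hybrid = htax,
        parent_a = pp[1], parent_b = pp[2],
        d_to_a = d_a, d_to_b = d_b, d_parents = d_ab,
        intermediate = d_a < d_ab && d_b < d_ab,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
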