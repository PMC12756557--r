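# Independent oracles and small builders shared across the suite.
# These deliberately use the slowest, most literal formulation of each
# quantity so they share no code path with the package internals.

# Root-mean-square VAF distance by an explicit double loop over pairs/sites.
naive_pairwise_distance <- function(vaf, depth, min_pair_depth = 8) {
  n <- nrow(vaf)
  d <- matrix(0, n, n, dimnames = list(rownames(vaf), rownames(vaf)))
  N <- matrix(0L, n, n, dimnames = dimnames(d))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    ss <- 0; cnt <- 0L
    for (p in seq_len(ncol(vaf))) {
      di <- depth[i, p]; dj <- depth[j, p]
      if (is.na(di) || is.na(dj)) next
      if (is.na(vaf[i, p]) || is.na(vaf[j, p])) next
      if (di >= min_pair_depth && dj >= min_pair_depth) {
        ss <- ss + (vaf[i, p] - vaf[j, p])^2
        cnt <- cnt + 1L
      }
    }
    d[i, j] <- if (cnt > 0L) sqrt(ss / cnt) else NA_real_
    N[i, j] <- cnt
  }
  list(d = d, n = N)
}

# Ward.D2 by per-step recomputation of every cluster-pair cost from the
# original dissimilarities, using the minimum-variance closed form
#   D^2(A,B) = 2 |A||B|/(|A|+|B|) *
#              ( E(A,B)/(|A||B|) - E(A,A)/(2|A|^2) - E(B,B)/(2|B|^2) )
# with E(X,Y) = sum of squared input dissimilarities across X x Y.
naive_ward <- function(d) {
  d2 <- as.matrix(d)^2
  n <- nrow(d2)
  clusters <- lapply(seq_len(n), identity)
  heights <- numeric(n - 1L)
  merges <- vector("list", n - 1L)
  esum <- function(A, B) sum(d2[A, B, drop = FALSE])
  cost <- function(A, B) {
    na <- length(A); nb <- length(B)
    v <- esum(A, B) / (na * nb) - esum(A, A) / (2 * na^2) - esum(B, B) / (2 * nb^2)
    sqrt(max(2 * na * nb / (na + nb) * v, 0))
  }
  for (step in seq_len(n - 1L)) {
    best <- c(NA, NA); best_cost <- Inf
    for (i in seq_len(length(clusters) - 1L)) for (j in (i + 1L):length(clusters)) {
      cc <- cost(clusters[[i]], clusters[[j]])
      if (cc < best_cost) { best_cost <- cc; best <- c(i, j) }
    }
    heights[step] <- best_cost
    merges[[step]] <- sort(unlist(clusters[best]))
    clusters[[best[1]]] <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters <- clusters[-best[2]]
  }
  list(heights = heights, merges = merges)
}

# Leaf index sets per merge of an hclust tree (for topology comparison
# against naive_ward, which works in leaf indices).
hclust_merge_sets <- function(h) {
  sets <- vector("list", nrow(h$merge))
  for (k in seq_len(nrow(h$merge))) {
    sets[[k]] <- sort(unlist(lapply(h$merge[k, ], function(x)
      if (x < 0L) -x else sets[[x]])))
  }
  sets
}

# A random VAFMatrix with a random depth mask; depths straddle the default
# pair-mask threshold so masking is actually exercised.
random_vaf_matrix <- function(n = 6, p = 200, seed = 1) {
  set.seed(seed)
  vaf <- matrix(runif(n * p), n, p)
  depth <- matrix(rpois(n * p, 12), n, p)
  depth[matrix(runif(n * p) < 0.05, n, p)] <- NA_integer_
  ids <- sprintf("s%02d", seq_len(n))
  sites <- data.frame(chrom = "ctg1", pos = seq_len(p), ref = "A", alt = "C")
  dimnames(vaf) <- dimnames(depth) <- list(ids, site_keys(sites))
  structure(list(vaf = vaf, depth = depth, samples = ids, sites = sites),
            class = "VAFMatrix")
}

site_keys <- function(sites) paste0(sites$chrom, ":", sites$pos)

# Build a VAFMatrix directly from given vaf/depth matrices.
vm_from_matrices <- function(vaf, depth) {
  ids <- rownames(vaf)
  sites <- data.frame(chrom = "ctg1", pos = seq_len(ncol(vaf)),
                      ref = "A", alt = "C")
  dimnames(vaf) <- dimnames(depth) <- list(ids, site_keys(sites))
  structure(list(vaf = vaf, depth = depth, samples = ids, sites = sites),
            class = "VAFMatrix")
}

# Minimal Newick tokenizer used only to check quoted-label output: returns
# the leaf labels of a Newick string, honouring single-quote escaping.
newick_leaf_labels <- function(s) {
  chars <- strsplit(s, "")[[1]]
  labels <- character(0); buf <- ""; in_q <- FALSE; after_struct <- TRUE
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (in_q) {
      if (ch == "'") {
        if (i < length(chars) && chars[i + 1L] == "'") { buf <- paste0(buf, "'"); i <- i + 1L }
        else { labels <- c(labels, buf); buf <- ""; in_q <- FALSE }
      } else buf <- paste0(buf, ch)
    } else if (ch == "'") {
      in_q <- TRUE; buf <- ""
    } else if (ch %in% c("(", ",")) {
      after_struct <- TRUE
    } else if (ch == ")" || ch == ";") {
      after_struct <- FALSE
    } else if (ch == ":") {
      if (nzchar(buf)) { labels <- c(labels, buf); buf <- "" }
      after_struct <- FALSE
    } else if (after_struct) {
      buf <- paste0(buf, ch)
    }
    i <- i + 1L
  }
  labels
}

default_cohort <- function(seed = 7, hybrids = list(c(1, 2, 2)), F = 0.3,
                           n_species = 3, samples_per_species = 4,
                           n_sites = 2000, mean_depth = 30, error_rate = 0.005) {
  simulate_cohort(cohort_config(
    n_species = n_species, samples_per_species = samples_per_species,
    hybrids = hybrids, n_sites = n_sites, divergence_F = F,
    mean_depth = mean_depth, error_rate = error_rate, seed = seed))
}
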