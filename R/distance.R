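#' Pairwise-complete normalized Euclidean VAF distance
#'
#' For each sample pair (i, j) only positions covered by at least
#' `min_pair_depth` reads in *both* samples (and unmasked in both) enter the
#' distance; the set of usable positions therefore differs from pair to
#' pair. The distance is the root-mean-square VAF difference over that set:
#'
#' \deqn{d_{ij} = \sqrt{ \frac{1}{|P_{ij}|} \sum_{p \in P_{ij}}
#'       (v_i(p) - v_j(p))^2 }}
#'
#' The normalization by the per-pair position count sits *inside* the square
#' root, making distances comparable across pairs with different coverage
#' and bounding them in \[0, 1\] since VAFs lie in \[0, 1\]. Pairs with
#' fewer than `min_pair_sites` usable positions are flagged undefined
#' (distance `NA`); downstream clustering refuses flagged matrices rather
#' than imputing.
#'
#' @param m a `VAFMatrix` from [build_vaf_matrix()].
#' @param min_pair_depth minimum read depth required in both samples for a
#'   position to count for that pair.
#' @param min_pair_sites pairs with fewer usable positions are flagged.
#' @return object of class `vaf_dist`: list with `d` (symmetric distance
#'   matrix, zero diagonal, `NA` where undefined), `n_sites_used` (symmetric
#'   integer matrix of per-pair position counts), `flagged` (logical
#'   matrix), `min_pair_depth`, `samples`.
#' @export
pairwise_distance <- function(m, min_pair_depth = 8L, min_pair_sites = 1L) {
  if (!inherits(m, "VAFMatrix")) stopf("m must be a VAFMatrix")
  n <- length(m$samples)
  if (n < 2L) stopf("need at least 2 samples for pairwise distances")

  ok <- !is.na(m$depth) & !is.na(m$vaf) & m$depth >= min_pair_depth
  C <- matrix(as.numeric(ok), n, dimnames = dimnames(m$vaf))
  V <- ifelse(ok, m$vaf, 0)

  # sum_{p} c_ip c_jp (v_ip - v_jp)^2 expanded into three cross-products
  W <- C * V
  W2 <- C * V * V
  S <- tcrossprod(W2, C) + tcrossprod(C, W2) - 2 * tcrossprod(W)
  S <- pmax(S, 0)  # guard fp negatives
  N <- tcrossprod(C)
  storage.mode(N) <- "integer"
  diag(N) <- 0L  # counts are a per-pair notion; the diagonal is not a pair

  d <- sqrt(S / ifelse(N > 0L, N, 1L))
  d[N == 0L] <- NA_real_
  diag(d) <- 0
  d <- (d + t(d)) / 2  # exact symmetry

  flagged <- N < min_pair_sites
  diag(flagged) <- FALSE
  d[flagged] <- NA_real_
  off <- upper.tri(flagged)
  if (all(flagged[off]))
    stopf("no co-covered positions: every sample pair is undefined at min_pair_depth=%d",
          as.integer(min_pair_depth))

  dimnames(d) <- dimnames(N) <- dimnames(flagged) <- list(m$samples, m$samples)
  structure(list(d = d, n_sites_used = N, flagged = flagged,
                 min_pair_depth = as.integer(min_pair_depth),
                 samples = m$samples),
            class = "vaf_dist")
}

#' @export
print.vaf_dist <- function(x, ...) {
  off <- upper.tri(x$d)
  cat(sprintf("Pairwise VAF distances: %d samples, pair mask depth >= %d\n",
              length(x$samples), x$min_pair_depth))
  cat(sprintf("  d range [%.4g, %.4g]; usable positions per pair: %d-%d (median %d)\n",
              min(x$d[off], na.rm = TRUE), max(x$d[off], na.rm = TRUE),
              min(x$n_sites_used[off]), max(x$n_sites_used[off]),
              as.integer(stats::median(x$n_sites_used[off]))))
  if (any(x$flagged[off]))
    cat(sprintf("  %d pair(s) flagged undefined\n", sum(x$flagged[off])))
  invisible(x)
}

#' @export
as.matrix.vaf_dist <- function(x, ...) x$d

#' @importFrom stats as.dist
#' @export
as.dist.vaf_dist <- function(m, diag = FALSE, upper = FALSE) {
  if (any(m$flagged[upper.tri(m$flagged)]))
    stopf("distance matrix has undefined pairs; cannot coerce to dist")
  stats::as.dist(m$d, diag = diag, upper = upper)
}

#' Export a distance matrix as TSV
#'
#' Writes the square matrix rounded to 6 decimals at `path`, the lossless
#' full-precision form at `<path>.full`, and the per-pair usable-position
#' counts at `<path>.nsites`.
#'
#' @param x a `vaf_dist`.
#' @param path main TSV path.
#' @return invisibly, the three paths.
#' @export
write_distance_tsv <- function(x, path) {
  wr <- function(mat, p, fmt = NULL) {
    chr <- if (is.null(fmt)) mat else
      matrix(sprintf(fmt, mat), nrow(mat), dimnames = dimnames(mat))
    tab <- data.frame(sample = rownames(mat), chr,
                      check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(tab, p, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wr(round(x$d, 6), path)
  wr(x$d, paste0(path, ".full"), fmt = "%.17g")
  wr(x$n_sites_used, paste0(path, ".nsites"))
  invisible(c(path, paste0(path, ".full"), paste0(path, ".nsites")))
}

#' Read a distance matrix written by [write_distance_tsv()]
#'
#' Prefers the lossless `<path>.full` sidecar when present so a re-clustered
#' tree is bit-identical to the original run.
#'
#' @param path main TSV path.
#' @return a `vaf_dist` (with `n_sites_used` if the sidecar exists, else 0s
#'   and no flags).
#' @export
read_distance_tsv <- function(path) {
  src <- if (file.exists(paste0(path, ".full"))) paste0(path, ".full") else path
  tab <- utils::read.delim(src, check.names = FALSE, stringsAsFactors = FALSE)
  samples <- as.character(tab[[1]])
  d <- as.matrix(tab[, -1L, drop = FALSE])
  dimnames(d) <- list(samples, samples)
  npath <- paste0(path, ".nsites")
  N <- if (file.exists(npath)) {
    nt <- utils::read.delim(npath, check.names = FALSE, stringsAsFactors = FALSE)
    nm <- as.matrix(nt[, -1L, drop = FALSE]); dimnames(nm) <- list(samples, samples)
    storage.mode(nm) <- "integer"; nm
  } else {
    matrix(0L, nrow(d), ncol(d), dimnames = dimnames(d))
  }
  flagged <- is.na(d); diag(flagged) <- FALSE
  structure(list(d = d, n_sites_used = N, flagged = flagged,
                 min_pair_depth = NA_integer_, samples = samples),
            class = "vaf_dist")
}
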