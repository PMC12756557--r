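#' Read a BED3 file of intervals
#'
#' BED coordinates are 0-based half-open. Lines beyond the first three
#' columns are allowed (extra columns ignored); `track`/`browser`/comment
#' lines are skipped. A malformed line stops with its line number.
#'
#' @param path BED file.
#' @return data frame `chrom`, `start`, `end` (0-based half-open).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stopf("cannot read BED: %s", path)
  lines <- readLines(path)
  rows <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (!nzchar(trimws(ln)) || grepl("^(#|track\\b|browser\\b)", ln)) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stopf("malformed BED line %d: fewer than 3 tab-separated fields", i)
    start <- suppressWarnings(as.numeric(f[2]))
    end <- suppressWarnings(as.numeric(f[3]))
    if (is.na(start) || is.na(end) || start < 0 || end < start)
      stopf("malformed BED line %d: bad interval [%s, %s)", i, f[2], f[3])
    rows[[i]] <- data.frame(chrom = f[1], start = start, end = end,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
  rownames(out) <- NULL
  out
}

#' Restrict a site set to BED intervals
#'
#' Keeps sites whose 1-based position falls inside some interval of the same
#' contig (`start < pos <= end` in BED's 0-based half-open coordinates).
#' Site order is preserved; the operation is idempotent.
#'
#' @param sites data frame with `chrom` and `pos` columns (e.g. from
#'   [site_union()]).
#' @param intervals BED data frame from [read_bed()], or a path to a BED file.
#' @return the retained rows of `sites`.
#' @export
restrict_to_intervals <- function(sites, intervals) {
  if (is.character(intervals)) intervals <- read_bed(intervals)
  keep <- logical(nrow(sites))
  for (ch in unique(sites$chrom)) {
    si <- which(sites$chrom == ch)
    iv <- intervals[intervals$chrom == ch, , drop = FALSE]
    if (nrow(iv) == 0L) next
    for (k in seq_len(nrow(iv))) {
      keep[si] <- keep[si] | bed_covers_pos(sites$pos[si], iv$start[k], iv$end[k])
    }
  }
  out <- sites[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a per-site depth table
#'
#' The table has one row per site keyed `CHROM:POS` (first column) and one
#' column per sample. Sites in `sites` that are absent from the table are
#' treated as *missing* depth for all samples — not zero — so they are
#' excluded by the coverage mask rather than counted as uncovered reference.
#'
#' @param path TSV file.
#' @param sites optional site table (`chrom`, `pos`) to align rows to.
#' @param sample_ids optional sample ids to select/ order columns; an id
#'   missing from the table is an error.
#' @return integer matrix, samples x sites, `NA` where depth is unknown;
#'   column names are `CHROM:POS` keys.
#' @export
read_depth_table <- function(path, sites = NULL, sample_ids = NULL) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stopf("depth table needs a site column plus >= 1 sample column")
  keys <- as.character(tab[[1]])
  if (anyDuplicated(keys))
    stopf("duplicate site row(s) in depth table: %s",
          paste(unique(keys[duplicated(keys)]), collapse = ", "))
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "integer"
  if (any(m < 0L, na.rm = TRUE)) stopf("negative depth in depth table")
  rownames(m) <- keys
  depth <- t(m)  # samples x sites

  if (!is.null(sample_ids)) {
    missing <- setdiff(sample_ids, rownames(depth))
    if (length(missing))
      stopf("depth table lacks sample column(s): %s", paste(missing, collapse = ", "))
    depth <- depth[sample_ids, , drop = FALSE]
  }
  if (!is.null(sites)) {
    want <- site_key(sites$chrom, sites$pos)
    out <- matrix(NA_integer_, nrow(depth), length(want),
                  dimnames = list(rownames(depth), want))
    have <- intersect(want, colnames(depth))
    out[, have] <- depth[, have]
    depth <- out
  }
  depth
}

#' Write a depth matrix as a depth TSV
#'
#' Inverse of [read_depth_table()]: rows are `CHROM:POS` sites, columns are
#' samples.
#'
#' @param depth samples x sites integer matrix with `CHROM:POS` column names.
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_depth_table <- function(depth, path) {
  tab <- data.frame(site = colnames(depth), t(depth),
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample manifest
#'
#' @param path TSV with columns `sample_id`, `taxon`, `section`, `source`.
#' @return the manifest data frame.
#' @export
read_manifest <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("sample_id", "taxon", "section", "source")
  miss <- setdiff(need, names(m))
  if (length(miss))
    stopf("manifest lacks column(s): %s", paste(miss, collapse = ", "))
  m
}

#' Validate a manifest and summarize its composition
#'
#' @param manifest a manifest data frame or a path to one.
#' @return a list of class `manifest_summary`: `n_samples`, `n_taxa`,
#'   `per_section` (named counts), `per_taxon` (named counts).
#' @export
validate_manifest <- function(manifest) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  need <- c("sample_id", "taxon", "section", "source")
  miss <- setdiff(need, names(manifest))
  if (length(miss))
    stopf("manifest lacks column(s): %s", paste(miss, collapse = ", "))
  if (nrow(manifest) == 0L) stopf("manifest is empty")
  dup <- unique(manifest$sample_id[duplicated(manifest$sample_id)])
  if (length(dup))
    stopf("duplicated sample id(s) in manifest: %s", paste(dup, collapse = ", "))
  structure(list(
    n_samples = nrow(manifest),
    n_taxa = length(unique(manifest$taxon)),
    per_section = table(manifest$section),
    per_taxon = table(manifest$taxon)
  ), class = "manifest_summary")
}

#' @export
print.manifest_summary <- function(x, ...) {
  cat(sprintf("Manifest: %d samples, %d distinct taxa\n", x$n_samples, x$n_taxa))
  cat("Per section:\n")
  print(x$per_section)
  invisible(x)
}
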