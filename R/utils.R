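#' @keywords internal
"_PACKAGE"

# Coordinate conventions used throughout:
#   * variant positions and depth-table keys are 1-based (VCF convention);
#   * BED intervals are 0-based half-open [start, end).
# All conversions between the two live in `bed_covers_pos()` so the off-by-one
# logic exists in exactly one place.

#' Site keys of the form "CHROM:POS"
#' @noRd
site_key <- function(chrom, pos) paste0(chrom, ":", pos)

#' Does a 1-based position fall in a 0-based half-open interval?
#'
#' A 1-based position p covers the 0-based bases [p-1, p), so p lies in
#' [start, end) iff start < p <= end.
#' @noRd
bed_covers_pos <- function(pos, start, end) start < pos & pos <= end

#' Run an expression under a local RNG state
#'
#' Seeds the session RNG, evaluates `expr`, and restores the caller's
#' `.Random.seed` so simulation and bootstrap calls do not perturb the
#' surrounding analysis.
#' @noRd
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv()),
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

#' Stop with a formatted message, no call in the condition
#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' Check a scalar is a single finite number
#' @noRd
is_num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
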