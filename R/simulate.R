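#' Configuration for a synthetic multi-species cohort
#'
#' Defines a cohort of diploid individuals drawn from `n_species` diverged
#' species plus optional F1 inter-species hybrids, genotyped at `n_sites`
#' unlinked biallelic sites with Poisson sequencing depth and a per-read
#' error rate. Species allele frequencies follow the Balding–Nichols model:
#' an ancestral frequency p is drawn uniformly from `ancestral_freq_range`
#' for each site and each species' frequency is
#' Beta(p(1-F)/F, (1-p)(1-F)/F), so `divergence_F` in (0,1) controls drift —
#' F near 1 gives fixed differences between species, F near 0 gives
#' near-identical species.
#'
#' @param n_species number of pure species.
#' @param samples_per_species diploid individuals sequenced per species.
#' @param hybrids list of F1 hybrid groups, each `c(parent_a, parent_b, n)`
#'   with parent indices in `1:n_species` and `n` individuals.
#' @param n_sites number of biallelic sites, placed at positions
#'   `1:n_sites` on one synthetic contig.
#' @param divergence_F drift parameter in (0,1).
#' @param ancestral_freq_range range of the ancestral allele frequency.
#' @param mean_depth Poisson mean of per-site sequencing depth.
#' @param error_rate per-read miscall rate in \[0, 0.05\].
#' @param seed integer seed; identical config + seed gives bit-identical
#'   cohorts.
#' @return an object of class `cohort_config`.
#' @seealso [simulate_cohort()]
#' @export
cohort_config <- function(n_species = 3L, samples_per_species = 4L,
                          hybrids = list(), n_sites = 2000L,
                          divergence_F = 0.3,
                          ancestral_freq_range = c(0.1, 0.9),
                          mean_depth = 30, error_rate = 0.005,
                          seed = 1L) {
  if (!is_num1(n_species) || n_species < 1)
    stopf("n_species must be a positive integer (got %s)", format(n_species))
  if (!is_num1(samples_per_species) || samples_per_species < 1)
    stopf("samples_per_species must be a positive integer")
  if (!is_num1(n_sites) || n_sites < 1)
    stopf("n_sites must be >= 1 (degenerate cohorts are refused, not emitted empty)")
  if (!is_num1(divergence_F) || divergence_F <= 0 || divergence_F >= 1)
    stopf("divergence_F must lie strictly in (0,1), got %s", format(divergence_F))
  if (length(ancestral_freq_range) != 2L ||
      any(ancestral_freq_range <= 0) || any(ancestral_freq_range >= 1) ||
      ancestral_freq_range[1] > ancestral_freq_range[2])
    stopf("ancestral_freq_range must be an increasing pair inside (0,1)")
  if (!is_num1(mean_depth) || mean_depth <= 0)
    stopf("mean_depth must be positive")
  if (!is_num1(error_rate) || error_rate < 0 || error_rate > 0.05)
    stopf("error_rate must lie in [0, 0.05]")
  if (!is_num1(seed)) stopf("seed must be a single integer")
  if (!is.list(hybrids)) stopf("hybrids must be a list of c(parent_a, parent_b, n)")
  for (h in hybrids) {
    if (length(h) != 3L || any(h[1:2] < 1) || any(h[1:2] > n_species) ||
        h[1] == h[2] || h[3] < 1)
      stopf("each hybrid spec must be c(parent_a, parent_b, n) with distinct parents in 1:%d",
            as.integer(n_species))
  }
  structure(list(
    n_species = as.integer(n_species),
    samples_per_species = as.integer(samples_per_species),
    hybrids = lapply(hybrids, as.integer),
    n_sites = as.integer(n_sites),
    divergence_F = divergence_F,
    ancestral_freq_range = as.numeric(ancestral_freq_range),
    mean_depth = mean_depth,
    error_rate = error_rate,
    seed = as.integer(seed)
  ), class = "cohort_config")
}

# Caller-emulation thresholds: a variant record is emitted for a sample/site
# iff alt reads >= 4, depth >= 5 and alt/depth >= 0.2, mirroring the
# Freebayes settings the pipeline's filters assume upstream.
.sim_min_alt <- 4L
.sim_min_depth <- 5L
.sim_min_vaf <- 0.2
.sim_qual <- 60

#' Simulate a read-level cohort with known population structure
#'
#' Draws species allele frequencies, diploid genotypes (F1 hybrids take one
#' allele from each parent species), Poisson depths and binomial alternate
#' read counts with error, then emits per-sample variant records exactly as
#' a caller with thresholds (alt reads >= 4, depth >= 5, VAF >= 0.2) would.
#' The depth table reports depth for *every* sample at the union of emitted
#' sites — including samples with no variant record there — which is what
#' makes the downstream per-pair coverage mask computable.
#'
#' Draws are made from one stream seeded once, in a fixed documented order
#' (ancestral frequencies, then species frequencies species-by-species, then
#' per sample in manifest order: genotypes, depths, alt reads). Changing any
#' dimension of the config changes all subsequent draws; prefix stability
#' when adding samples is not guaranteed.
#'
#' @param config a [cohort_config()].
#' @return an object of class `vaf_cohort`: a list with `config`, `manifest`
#'   (sample_id, taxon, section, source), `truth` (`sample_labels`,
#'   `species_site_freqs`, `genotypes`), `records` (named list of per-sample
#'   variant record data frames), `sites` (union site table), `depth`
#'   (samples x union-sites depth matrix) and `raw` (full depth and alt-read
#'   matrices over all simulated sites, kept so emission can be audited
#'   against the raw draws).
#' @examples
#' cfg <- cohort_config(n_species = 2, samples_per_species = 2,
#'                      n_sites = 200, seed = 42)
#' ch <- simulate_cohort(cfg)
#' ch$manifest
#' @export
simulate_cohort <- function(config) {
  if (!inherits(config, "cohort_config"))
    stopf("config must be built by cohort_config()")
  K <- config$n_species
  p <- config$n_sites
  F <- config$divergence_F

  manifest <- .sim_manifest(config)
  n <- nrow(manifest)

  with_seed(config$seed, {
    p_anc <- stats::runif(p, config$ancestral_freq_range[1],
                          config$ancestral_freq_range[2])
    q <- matrix(NA_real_, K, p,
                dimnames = list(paste0("species_", seq_len(K)), NULL))
    shape_scale <- (1 - F) / F
    for (s in seq_len(K)) {
      qs <- stats::rbeta(p, p_anc * shape_scale, (1 - p_anc) * shape_scale)
      # rbeta can return NaN when both shapes underflow at extreme F;
      # resolve those sites as a Bernoulli(p_anc) fixation
      bad <- !is.finite(qs)
      if (any(bad)) qs[bad] <- as.numeric(stats::runif(sum(bad)) < p_anc[bad])
      q[s, ] <- pmin(pmax(qs, 0), 1)
    }

    G <- matrix(NA_integer_, n, p, dimnames = list(manifest$sample_id, NULL))
    for (i in seq_len(n)) {
      a <- manifest$.parent_a[i]; b <- manifest$.parent_b[i]
      G[i, ] <- if (is.na(b)) {
        stats::rbinom(p, 2L, q[a, ])
      } else {
        stats::rbinom(p, 1L, q[a, ]) + stats::rbinom(p, 1L, q[b, ])
      }
    }

    D <- matrix(NA_integer_, n, p, dimnames = dimnames(G))
    A <- matrix(NA_integer_, n, p, dimnames = dimnames(G))
    e <- config$error_rate
    for (i in seq_len(n)) {
      D[i, ] <- stats::rpois(p, config$mean_depth)
      palt <- (G[i, ] / 2) * (1 - e) + (1 - G[i, ] / 2) * e
      A[i, ] <- stats::rbinom(p, D[i, ], palt)
    }
  })

  emitted <- A >= .sim_min_alt & D >= .sim_min_depth &
    D > 0L & A / pmax(D, 1L) >= .sim_min_vaf
  union_sites <- which(colSums(emitted) > 0L)
  if (length(union_sites) == 0L)
    stopf("simulation produced no variant records; raise depth or divergence")

  sites <- data.frame(chrom = "ctg1", pos = union_sites,
                      ref = "A", alt = "C", stringsAsFactors = FALSE)
  keys <- site_key(sites$chrom, sites$pos)

  records <- vector("list", n)
  names(records) <- manifest$sample_id
  for (i in seq_len(n)) {
    j <- which(emitted[i, ])
    records[[i]] <- data.frame(
      chrom = rep("ctg1", length(j)), pos = j,
      ref = rep("A", length(j)), alt = rep("C", length(j)),
      qual = rep(.sim_qual, length(j)),
      depth = D[i, j], alt_obs = A[i, j],
      stringsAsFactors = FALSE
    )
  }

  depth <- D[, union_sites, drop = FALSE]
  colnames(depth) <- keys

  truth <- list(
    sample_labels = stats::setNames(manifest$taxon, manifest$sample_id),
    species_site_freqs = q,
    genotypes = G
  )

  manifest$.parent_a <- NULL
  manifest$.parent_b <- NULL

  structure(list(
    config = config, manifest = manifest, truth = truth,
    records = records, sites = sites, depth = depth,
    raw = list(depth = D, alt = A)
  ), class = "vaf_cohort")
}

#' @noRd
.sim_manifest <- function(config) {
  K <- config$n_species
  rows <- list()
  for (s in seq_len(K)) {
    for (i in seq_len(config$samples_per_species)) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf("sp%d_s%d", s, i),
        taxon = paste0("species_", s),
        section = paste0("section_", s),
        source = "simulated",
        .parent_a = s, .parent_b = NA_integer_,
        stringsAsFactors = FALSE
      )
    }
  }
  for (h in seq_along(config$hybrids)) {
    hb <- config$hybrids[[h]]
    for (i in seq_len(hb[3])) {
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = sprintf("hyb%dx%d_s%d", hb[1], hb[2], i),
        taxon = sprintf("hybrid_%dx%d", hb[1], hb[2]),
        section = "hybrid",
        source = "simulated",
        .parent_a = hb[1], .parent_b = hb[2],
        stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, rows)
}

#' @export
print.vaf_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d samples (%d species%s), %d simulated sites\n",
              nrow(x$manifest), x$config$n_species,
              if (length(x$config$hybrids))
                sprintf(" + %d hybrid group(s)", length(x$config$hybrids)) else "",
              x$config$n_sites))
  cat(sprintf("  %d sites carry at least one variant record; mean depth %.1f; error rate %.3g\n",
              nrow(x$sites), x$config$mean_depth, x$config$error_rate))
  invisible(x)
}

#' Write a cohort to disk in the pipeline's input formats
#'
#' Serializes one VCF per sample (INFO fields `DP=` and `AO=`), a depth TSV
#' (rows CHROM:POS over the union of emitted sites, one column per sample),
#' a manifest TSV and a ground-truth JSON.
#'
#' @param cohort a `vaf_cohort` from [simulate_cohort()].
#' @param dir output directory, created if needed.
#' @return invisibly, a named list of written paths.
#' @export
write_cohort <- function(cohort, dir) {
  if (!inherits(cohort, "vaf_cohort")) stopf("cohort must be a vaf_cohort")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  vcfs <- character(0)
  for (sid in names(cohort$records)) {
    path <- file.path(dir, paste0(sid, ".vcf"))
    write_variants_vcf(cohort$records[[sid]], path, sample_id = sid)
    vcfs[sid] <- path
  }
  depth_path <- file.path(dir, "depth.tsv")
  write_depth_table(cohort$depth, depth_path)
  manifest_path <- file.path(dir, "manifest.tsv")
  utils::write.table(cohort$manifest, manifest_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth_path <- file.path(dir, "truth.json")
  jsonlite::write_json(list(
    sample_labels = as.list(cohort$truth$sample_labels),
    species_site_freqs = cohort$truth$species_site_freqs,
    genotypes = cohort$truth$genotypes
  ), truth_path, auto_unbox = TRUE, digits = NA)
  invisible(list(vcf = vcfs, depth = depth_path,
                 manifest = manifest_path, truth = truth_path))
}

#' Write variant records as a minimal VCF
#'
#' @param records data frame with columns chrom, pos, ref, alt, qual, depth,
#'   alt_obs (the layout produced by [simulate_cohort()] and
#'   [read_sample_variants()]).
#' @param path output file.
#' @param sample_id recorded in the header for provenance.
#' @return invisibly, `path`.
#' @export
write_variants_vcf <- function(records, path, sample_id = "sample") {
  header <- c(
    "##fileformat=VCFv4.2",
    sprintf("##source=vafclust;sample=%s", sample_id),
    "##contig=<ID=ctg1>",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total read depth\">",
    "##INFO=<ID=AO,Number=A,Type=Integer,Description=\"Alternate allele observation count\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO"),
          collapse = "\t")
  )
  body <- if (nrow(records) == 0L) character(0) else
    paste(records$chrom, records$pos, ".", records$ref, records$alt,
          format(records$qual, trim = TRUE), ".",
          sprintf("DP=%d;AO=%d", records$depth, records$alt_obs),
          sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
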