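#' Pipeline configuration
#'
#' Exactly one of `simulation` (a [cohort_config()]; the cohort is generated
#' in memory) or `inputs` (paths to on-disk data) must be given. `inputs` is
#' a list with `vcf` (named character vector of per-sample VCF paths; names
#' are sample ids), `depth` (depth TSV), `manifest` (manifest TSV) and
#' optionally `bed` (CDS intervals, BED3).
#'
#' The mapping/base-quality settings applied by upstream read processing are
#' not parameters here: the pipeline starts from called variant records.
#'
#' @param simulation optional [cohort_config()].
#' @param inputs optional input path list (see above).
#' @param min_qual variant quality cutoff (strict: `qual > min_qual`).
#' @param min_alt,min_depth,min_vaf caller-level inclusion minima.
#' @param min_pair_depth per-pair coverage mask (reads in both samples).
#' @param uncalled covered-but-uncalled sites: `"reference"` (VAF 0) or
#'   `"missing"`.
#' @param bootstrap number of position-bootstrap replicates (0 to skip).
#' @param seed seed for simulation and bootstrap.
#' @param outdir output directory.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(simulation = NULL, inputs = NULL,
                            min_qual = 25, min_alt = 4L, min_depth = 5L,
                            min_vaf = 0.2, min_pair_depth = 8L,
                            uncalled = "reference",
                            bootstrap = 1000L, seed = 1L,
                            outdir = "vafclust_out") {
  if (is.null(simulation) == is.null(inputs))
    stopf("exactly one of `simulation` or `inputs` must be set")
  if (!is.null(simulation) && !inherits(simulation, "cohort_config"))
    stopf("simulation must be a cohort_config()")
  if (!is.null(inputs)) {
    need <- c("vcf", "depth", "manifest")
    miss <- setdiff(need, names(inputs))
    if (length(miss)) stopf("inputs lacks: %s", paste(miss, collapse = ", "))
    if (is.null(names(inputs$vcf)) || any(!nzchar(names(inputs$vcf))))
      stopf("inputs$vcf must be a named vector (names = sample ids)")
  }
  for (v in c(min_qual, min_alt, min_depth, min_vaf, min_pair_depth, bootstrap))
    if (!is_num1(v) || v < 0) stopf("thresholds and bootstrap count must be >= 0")
  structure(list(simulation = simulation, inputs = inputs,
                 min_qual = min_qual, min_alt = as.integer(min_alt),
                 min_depth = as.integer(min_depth), min_vaf = min_vaf,
                 min_pair_depth = as.integer(min_pair_depth),
                 uncalled = match.arg(uncalled, c("reference", "missing")),
                 bootstrap = as.integer(bootstrap), seed = as.integer(seed),
                 outdir = outdir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages: load (or simulate) per-sample variant records; quality filter;
#' caller-threshold filter; optional CDS restriction; union site set; VAF
#' matrix with depth mask; pairwise-complete distances; Ward.D2 tree;
#' position bootstrap. Writes `distance.tsv` (plus `.full` and `.nsites`
#' sidecars), `tree.nwk`, `support.tsv` (if bootstrapping) and
#' `run_report.json` with per-stage record/site counts and every threshold
#' actually applied.
#'
#' @param config a [pipeline_config()].
#' @return invisibly, a list with `fit` (the [vafclust] object), `report`,
#'   and `paths` of written artifacts.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) stopf("config must be a pipeline_config()")
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  report <- list(thresholds = config[c("min_qual", "min_alt", "min_depth",
                                       "min_vaf", "min_pair_depth",
                                       "uncalled", "bootstrap", "seed")])
  stage <- function(fmt, ...) message(sprintf(paste0("[vafclust] ", fmt), ...))

  if (!is.null(config$simulation)) {
    sim <- config$simulation
    sim$seed <- config$seed
    cohort <- simulate_cohort(sim)
    stage("simulated cohort: %d samples, %d sites with records",
          nrow(cohort$manifest), nrow(cohort$sites))
    records <- cohort$records
    depth_raw <- cohort$depth
    manifest <- cohort$manifest
    bed <- NULL
  } else {
    manifest <- read_manifest(config$inputs$manifest)
    records <- lapply(config$inputs$vcf, read_sample_variants,
                      min_qual = config$min_qual)
    bed <- config$inputs$bed
    depth_raw <- NULL
  }
  msum <- validate_manifest(manifest)
  report$manifest <- list(n_samples = msum$n_samples, n_taxa = msum$n_taxa)
  stage("manifest: %d samples, %d taxa", msum$n_samples, msum$n_taxa)

  report$records_read <- sum(vapply(records, nrow, integer(1)))
  # simulated records are emitted at qual 60, so the qual filter is a no-op
  # there; file inputs were already qual-filtered at read time
  records <- lapply(records, apply_caller_thresholds,
                    min_alt = config$min_alt, min_depth = config$min_depth,
                    min_vaf = config$min_vaf)
  report$records_after_thresholds <- sum(vapply(records, nrow, integer(1)))
  stage("records: %d read, %d after AO/DP/VAF thresholds",
        report$records_read, report$records_after_thresholds)

  sites <- site_union(records)
  report$sites_union <- nrow(sites)
  if (!is.null(bed)) {
    sites <- restrict_to_intervals(sites, bed)
    report$sites_after_cds <- nrow(sites)
    stage("sites: %d in union, %d inside CDS intervals",
          report$sites_union, nrow(sites))
    records <- lapply(records, function(r) {
      keep <- site_key(r$chrom, r$pos) %in% site_key(sites$chrom, sites$pos)
      r[keep, , drop = FALSE]
    })
  } else {
    stage("sites: %d in union", report$sites_union)
  }
  if (nrow(sites) == 0L) stopf("no variant sites survive the filters")

  depth <- if (is.null(depth_raw))
    read_depth_table(config$inputs$depth, sites = sites,
                     sample_ids = manifest$sample_id)
  else {
    keys <- site_key(sites$chrom, sites$pos)
    depth_raw[, keys, drop = FALSE]
  }

  m <- build_vaf_matrix(records, depth, sites, uncalled = config$uncalled)
  fit <- vafclust(m, min_pair_depth = config$min_pair_depth,
                  boot = config$bootstrap, seed = config$seed)
  off <- upper.tri(fit$dist$n_sites_used)
  report$n_sites_used <- list(min = min(fit$dist$n_sites_used[off]),
                              median = stats::median(fit$dist$n_sites_used[off]),
                              max = max(fit$dist$n_sites_used[off]))
  stage("distances: usable positions per pair %d-%d",
        report$n_sites_used$min, report$n_sites_used$max)

  paths <- list(distance = file.path(config$outdir, "distance.tsv"),
                newick = file.path(config$outdir, "tree.nwk"),
                report = file.path(config$outdir, "run_report.json"))
  write_distance_tsv(fit$dist, paths$distance)
  writeLines(to_newick(fit$tree), paths$newick)
  if (!is.null(fit$boot)) {
    paths$support <- file.path(config$outdir, "support.tsv")
    write_support_tsv(fit$boot, paths$support)
    report$bootstrap <- list(n_replicates = fit$boot$n_replicates,
                             n_dropped = fit$boot$n_dropped,
                             min_support = min(fit$boot$support))
  }
  jsonlite::write_json(report, paths$report, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  stage("wrote %s", paste(unlist(paths), collapse = ", "))
  invisible(list(fit = fit, report = report, paths = paths))
}
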