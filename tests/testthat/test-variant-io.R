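fixture <- function(f) system.file("extdata", f, package = "vafclust")

test_that("quality filter is strictly greater-than and collapses multi-allelics", {
  recs <- read_sample_variants(fixture("lowq_synthetic.vcf"), min_qual = 25)
  expect_identical(nrow(recs), 7L)            # 3 of 10 records at qual <= 25
  expect_false(25 %in% recs$qual)             # qual == 25.0 excluded
  expect_false(any(recs$qual <= 25))
  multi <- recs[recs$alt == "G,T", ]
  expect_identical(nrow(multi), 1L)
  expect_identical(multi$alt_obs, 8L)         # AO=5,3 summed
  expect_identical(multi$depth, 30L)
  # a lenient cutoff admits everything in the file
  expect_identical(nrow(read_sample_variants(fixture("lowq_synthetic.vcf"),
                                             min_qual = 0)), 10L)
})

test_that("caller thresholds keep boundary values and drop below-minimum records", {
  recs <- data.frame(chrom = "c", pos = 1:4, ref = "A", alt = "C", qual = 60,
                     depth = c(5L, 30L, 21L, 20L),
                     alt_obs = c(4L, 3L, 4L, 8L))
  kept <- apply_caller_thresholds(recs)
  # AO=4,DP=5,VAF=0.8 kept; AO=3 dropped; AO=4,DP=21 (VAF ~0.190) dropped
  expect_identical(kept$pos, c(1L, 4L))
})

test_that("qual filter and caller thresholds commute", {
  path <- fixture("lowq_synthetic.vcf")
  a <- apply_caller_thresholds(read_sample_variants(path, min_qual = 25))
  all_recs <- read_sample_variants(path, min_qual = 0)
  b <- apply_caller_thresholds(all_recs)
  b <- b[b$qual > 25, , drop = FALSE]
  rownames(a) <- rownames(b) <- NULL
  expect_identical(a, b)
})

test_that("BED restriction converts coordinates correctly at both boundaries", {
  sites <- data.frame(chrom = "ctg1", pos = 100L, ref = "A", alt = "C")
  iv <- function(s, e) data.frame(chrom = "ctg1", start = s, end = e)
  expect_identical(nrow(restrict_to_intervals(sites, iv(99, 100))), 1L)
  expect_identical(nrow(restrict_to_intervals(sites, iv(0, 99))), 0L)
  # a 1-based position equal to the 0-based start is just outside
  expect_identical(nrow(restrict_to_intervals(sites, iv(100, 101))), 0L)
  # wrong contig never matches
  expect_identical(nrow(restrict_to_intervals(
    sites, data.frame(chrom = "ctg2", start = 0, end = 1000))), 0L)
})

test_that("fixture sites restricted to CDS intervals match a brute-force scan", {
  sites <- read.delim(fixture("sites50.tsv"))
  bed <- read_bed(fixture("cds3.bed"))
  got <- restrict_to_intervals(sites, bed)
  # literal oracle: test every site against every interval
  keep <- vapply(seq_len(nrow(sites)), function(i) {
    any(bed$chrom == sites$chrom[i] &
          bed$start < sites$pos[i] & sites$pos[i] <= bed$end)
  }, logical(1))
  expect_identical(got$pos, sites$pos[keep])
  expect_identical(nrow(got), 21L)  # frozen count for this fixture
  # idempotence and order preservation
  again <- restrict_to_intervals(got, bed)
  expect_identical(again, got)
  expect_false(is.unsorted(got$pos))
})

test_that("malformed BED lines fail with their line number", {
  p <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("ctg1\t0\t10", "ctg1\t5", "ctg1\t20\t30"), p)
  expect_error(read_bed(p), "line 2")
  writeLines(c("ctg1\t0\t10", "ctg1\t50\t30"), p)
  expect_error(read_bed(p), "line 2")
})

test_that("depth table round-trips and distinguishes absent from zero", {
  ch <- default_cohort(seed = 41, n_sites = 300)
  p <- withr::local_tempfile(fileext = ".tsv")
  write_depth_table(ch$depth, p)
  back <- read_depth_table(p, sites = ch$sites,
                           sample_ids = ch$manifest$sample_id)
  expect_identical(back, ch$depth)

  # a site missing from the table is NA for all samples, not zero
  sites2 <- rbind(ch$sites,
                  data.frame(chrom = "ctg1", pos = max(ch$sites$pos) + 1L,
                             ref = "A", alt = "C"))
  back2 <- read_depth_table(p, sites = sites2,
                            sample_ids = ch$manifest$sample_id)
  expect_true(all(is.na(back2[, ncol(back2)])))
  expect_false(any(back2[, ncol(back2)] %in% 0L))
})

test_that("depth table rejects negative depths and duplicate site rows", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("site\ts1\ts2", "ctg1:1\t5\t-2"), p)
  expect_error(read_depth_table(p), "negative")
  writeLines(c("site\ts1\ts2", "ctg1:1\t5\t2", "ctg1:1\t3\t4"), p)
  expect_error(read_depth_table(p), "duplicate")
  writeLines(c("site\ts1\ts2", "ctg1:1\t5\t2"), p)
  expect_error(read_depth_table(p, sample_ids = c("s1", "s3")), "s3")
})

test_that("union of sites is invariant to sample input order", {
  ch <- default_cohort(seed = 17, n_sites = 200)
  u1 <- site_union(ch$records)
  u2 <- site_union(rev(ch$records))
  expect_identical(u1, u2)
  expect_false(anyDuplicated(paste(u1$chrom, u1$pos, u1$ref, u1$alt)) > 0)
})

test_that("simulator VCFs read back identical to the in-memory records", {
  ch <- default_cohort(seed = 23, n_sites = 250)
  d <- withr::local_tempdir()
  paths <- write_cohort(ch, d)
  for (sid in ch$manifest$sample_id) {
    back <- read_sample_variants(paths$vcf[[sid]], min_qual = 25)
    orig <- ch$records[[sid]]
    rownames(back) <- rownames(orig) <- NULL
    expect_identical(back$pos, orig$pos)
    expect_identical(back$depth, orig$depth)
    expect_identical(back$alt_obs, orig$alt_obs)
  }
})
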