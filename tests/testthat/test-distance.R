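test_that("closed forms: identity, full difference, hybrid triangle", {
  set.seed(1)
  # identical rows -> 0 under any mask
  vaf <- rbind(a = runif(50), b = 0)
  vaf["b", ] <- vaf["a", ]
  depth <- matrix(sample(c(3L, 9L, 30L), 100, TRUE), 2, 50,
                  dimnames = list(c("a", "b"), NULL))
  d <- pairwise_distance(vm_from_matrices(vaf, depth))
  expect_equal(d$d["a", "b"], 0, tolerance = 1e-12)

  # all-0 vs all-1 rows -> 1 regardless of how many sites are co-covered
  for (ncov in c(1L, 7L, 40L)) {
    vaf <- rbind(a = rep(0, 40), b = rep(1, 40))
    depth <- matrix(30L, 2, 40, dimnames = list(c("a", "b"), NULL))
    if (ncov < 40L) depth[1, (ncov + 1L):40] <- 2L
    d <- pairwise_distance(vm_from_matrices(vaf, depth))
    expect_equal(unname(d$d["a", "b"]), 1, tolerance = 1e-12)
    expect_identical(unname(d$n_sites_used["a", "b"]), ncov)
  }

  # F1 hybrid at M fixed differences: d(A,B)=1, d(H,A)=d(H,B)=0.5
  M <- 64
  vaf <- rbind(A = rep(0, M), B = rep(1, M), H = rep(0.5, M))
  depth <- matrix(20L, 3, M, dimnames = list(c("A", "B", "H"), NULL))
  d <- pairwise_distance(vm_from_matrices(vaf, depth))
  expect_equal(unname(d$d["A", "B"]), 1, tolerance = 1e-12)
  expect_equal(unname(d$d["H", "A"]), 0.5, tolerance = 1e-12)
  expect_equal(unname(d$d["H", "B"]), 0.5, tolerance = 1e-12)
})

test_that("matrix-algebra distances match the naive double loop to 1e-12", {
  for (seed in 1:8) {
    m <- random_vaf_matrix(n = 6, p = 200, seed = seed)
    got <- pairwise_distance(m)
    want <- naive_pairwise_distance(m$vaf, m$depth)
    expect_equal(got$d, want$d, tolerance = 1e-12)
    expect_identical(unname(got$n_sites_used), unname(want$n))
  }
})

test_that("distances are symmetric, zero-diagonal and bounded by [0, 1]", {
  for (seed in 11:14) {
    d <- pairwise_distance(random_vaf_matrix(n = 7, p = 150, seed = seed))
    expect_identical(d$d, t(d$d))
    expect_identical(unname(diag(d$d)), rep(0, 7))
    expect_true(all(d$d >= 0 & d$d <= 1, na.rm = TRUE))
    expect_identical(d$n_sites_used, t(d$n_sites_used))
  }
})

test_that("raising the pair-depth threshold never increases usable positions", {
  m <- random_vaf_matrix(n = 6, p = 300, seed = 5)
  n_prev <- pairwise_distance(m, min_pair_depth = 0)$n_sites_used
  for (t in c(5L, 8L, 12L, 20L)) {
    n_t <- pairwise_distance(m, min_pair_depth = t)$n_sites_used
    expect_true(all(n_t <= n_prev))
    n_prev <- n_t
  }
})

test_that("sites below the coverage mask in either sample do not move the distance", {
  m <- random_vaf_matrix(n = 4, p = 100, seed = 9)
  set.seed(10)
  d0 <- pairwise_distance(m)
  # append a site deeply covered in sample 1 only
  vaf2 <- cbind(m$vaf, extra = runif(4))
  depth2 <- cbind(m$depth, extra = c(50L, 3L, 3L, 3L))
  d1 <- pairwise_distance(vm_from_matrices(vaf2, depth2))
  expect_equal(unname(d1$d), unname(d0$d), tolerance = 1e-15)
  expect_identical(unname(d1$n_sites_used), unname(d0$n_sites_used))
})

test_that("permuting samples permutes the distance matrix consistently", {
  m <- random_vaf_matrix(n = 6, p = 120, seed = 3)
  d <- pairwise_distance(m)$d
  perm <- c(4, 1, 6, 2, 5, 3)
  mp <- vm_from_matrices(m$vaf[perm, ], m$depth[perm, ])
  dp <- pairwise_distance(mp)$d
  expect_equal(dp, d[perm, perm], tolerance = 1e-15)
})

test_that("pairs with no co-covered positions are flagged; all-undefined errors", {
  vaf <- rbind(a = rep(0.5, 10), b = rep(0.2, 10), c = rep(0.9, 10))
  depth <- rbind(a = rep(30L, 10), b = rep(30L, 10), c = rep(2L, 10))
  d <- pairwise_distance(vm_from_matrices(vaf, depth))
  expect_true(d$flagged["a", "c"] && d$flagged["b", "c"])
  expect_true(is.na(d$d["a", "c"]))
  expect_false(d$flagged["a", "b"])
  expect_error(ward_cluster(d), "no co-covered")

  depth_all_low <- matrix(2L, 3, 10, dimnames = dimnames(depth))
  expect_error(pairwise_distance(vm_from_matrices(vaf, depth_all_low)),
               "no co-covered positions")
})

test_that("distance TSV round-trip via the lossless sidecar is exact", {
  m <- random_vaf_matrix(n = 5, p = 80, seed = 2)
  d <- pairwise_distance(m)
  p <- file.path(withr::local_tempdir(), "distance.tsv")
  write_distance_tsv(d, p)
  back <- read_distance_tsv(p)
  expect_equal(back$d, d$d, tolerance = 0)
  expect_identical(back$n_sites_used, d$n_sites_used)
  # the rounded main file is within rounding error
  main <- as.matrix(read.delim(p, row.names = 1))
  expect_lt(max(abs(main - d$d)), 5e-7)
})

test_that("between-species distances exceed within-species distances on strong signal", {
  ch <- simulate_cohort(cohort_config(n_species = 2, samples_per_species = 3,
                                      n_sites = 1500, divergence_F = 0.9,
                                      mean_depth = 60, error_rate = 0, seed = 3))
  m <- build_vaf_matrix(ch$records, ch$depth, ch$sites)
  d <- pairwise_distance(m)
  lab <- ch$truth$sample_labels[d$samples]
  same <- outer(lab, lab, "==") & upper.tri(d$d)
  diff <- outer(lab, lab, "!=") & upper.tri(d$d)
  expect_lt(max(d$d[same]), min(d$d[diff]))
})
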