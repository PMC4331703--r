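# Simulators: fixed four-allele design, haplotype pool, assignment, counts.

test_that("sim1 dataset follows the 12-sample protocol with the fixed allele panel", {
  sim <- sim1_dataset(seed = 31)
  expect_true("ATTGCGATATTGCGAT" %in% sim$truth$alleles$sequence)
  expect_true("CGATTGAACGTCGTAC" %in% sim$truth$alleles$sequence)
  expect_equal(nrow(sim$truth$alleles), 4)
  expect_equal(length(unique(sim$counts$sample)), 12)
  expect_equal(sort(unique(sim$counts$site)), 1:16)
  expect_true(all(as.matrix(sim$counts[, CNV_BASES]) >= 0))
  units <- dplyr::count(sim$truth$assignment, sample)
  expect_equal(sort(units$n), rep(c(2L, 3L, 4L), each = 4))
})

test_that("theta_true rows sum to one", {
  sim <- sim1_dataset(seed = 32)
  sums <- tapply(sim$truth$theta$theta, sim$truth$theta$sample, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})

test_that("haplotype pool honors size, distinctness and site-variability constraints", {
  pool <- haplotype_pool(seed = 33)
  expect_equal(nrow(pool), 45)
  seqs <- unique(pool$sequence)
  expect_equal(length(seqs), 9)
  expect_true(all(nchar(seqs) == 21))
  mat <- do.call(rbind, strsplit(seqs, ""))
  n_bases <- apply(mat, 2, function(col) length(unique(col)))
  expect_true(all(n_bases == 2))  # biallelic
  minor <- apply(mat, 2, function(col) sort(table(col), decreasing = TRUE)[2])
  expect_true(all(minor >= 2))
})

test_that("haplotype pool is deterministic under seed and degenerates gracefully", {
  p1 <- haplotype_pool(seed = 34)
  p2 <- haplotype_pool(seed = 34)
  expect_identical(p1, p2)
  p3 <- haplotype_pool(seed = 35)
  expect_false(identical(p1$sequence, p3$sequence))
  expect_warning(p4 <- haplotype_pool(n_distinct = 1, seed = 34), "identical")
  expect_equal(length(unique(p4$sequence)), 1)
  expect_error(haplotype_pool(n_distinct = 50, pool_size = 45), "n_distinct")
})

test_that("table2 presets each total 45 copy units", {
  for (ds in c("a", "b", "c")) {
    cfg <- table2_config(ds)
    expect_equal(sum(cfg$copy_number * cfg$n_samples), 45)
  }
  expect_equal(sum(table2_config("a")$n_samples), 22)
  expect_equal(sum(table2_config("c")$n_samples), 9)
})

test_that("assign_alleles deals tokens without replacement and errors on excess demand", {
  pool <- haplotype_pool(seed = 36)
  asg <- assign_alleles(pool, table2_config("c"), seed = 36)
  expect_equal(nrow(asg), 45)
  expect_false(any(duplicated(asg$token)))
  expect_equal(length(unique(asg$sample)), 9)
  counts_per_sample <- sort(dplyr::count(asg, sample)$n)
  expect_equal(counts_per_sample, sort(rep(3:7, times = c(1, 2, 3, 2, 1))))
  big <- tibble::tibble(copy_number = 10, n_samples = 5)
  expect_error(assign_alleles(pool, big), "pool has 45")
})

test_that("different assignment seeds give different deals", {
  pool <- haplotype_pool(seed = 37)
  a1 <- assign_alleles(pool, table2_config("a"), seed = 1)
  a2 <- assign_alleles(pool, table2_config("a"), seed = 2)
  expect_false(identical(a1$token, a2$token))
})

test_that("error-free counts contain only bases carried by the sample's own copy units", {
  set.seed(38)
  pool <- haplotype_pool(seed = 38)
  asg <- assign_alleles(pool, table2_config("b"), seed = 38)
  counts <- simulate_counts(asg, mean_depth = 10, error_rate = 0)
  for (s in unique(asg$sample)[1:4]) {
    seqs <- asg$sequence[asg$sample == s]
    own <- do.call(rbind, strsplit(seqs, ""))
    sub <- counts[counts$sample == s, ]
    for (x in seq_len(nrow(sub))) {
      present <- CNV_BASES[which(as.numeric(sub[x, CNV_BASES]) > 0)]
      expect_true(all(present %in% own[, sub$site[x]]))
    }
  }
})

test_that("total depth matches the Poisson mixture mean", {
  # 3 copy units at mean depth 15: expected per-site total 45
  set.seed(39)
  asg <- tibble::tibble(sample = "s1", unit = 1:3, label = paste0("h", 1:3),
                        sequence = rep("ACGT", 3))
  tots <- replicate(300, {
    cnt <- simulate_counts(asg, mean_depth = 15, error_rate = 0.01)
    sum(cnt[, CNV_BASES]) / 4
  })
  se <- sd(tots) / sqrt(length(tots))
  expect_lt(abs(mean(tots) - 45), 3 * se + 1e-9)
})

test_that("the error model corrupts at the configured rate, uniformly", {
  set.seed(40)
  asg <- tibble::tibble(sample = "s1", unit = 1, label = "h1", sequence = "A")
  cnt <- simulate_counts(asg, mean_depth = 1e5, error_rate = 0.01)
  tot <- sum(cnt[, CNV_BASES])
  err <- tot - cnt$A
  expect_equal(err / tot, 0.01, tolerance = 0.15)
  spill <- as.numeric(cnt[, c("C", "G", "T")])
  expect_true(all(abs(spill / err - 1 / 3) < 0.1))
})

test_that("sim2 datasets are reproducible under seed and exhaust the pool", {
  s1 <- sim2_dataset("b", mean_depth = 5, seed = 41)
  s2 <- sim2_dataset("b", mean_depth = 5, seed = 41)
  expect_identical(s1$counts, s2$counts)
  expect_equal(nrow(s1$truth$assignment), 45)
  sums <- tapply(s1$truth$theta$theta, s1$truth$theta$sample, sum)
  expect_true(all(abs(sums - 1) < 1e-12))
})
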