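# Unit tests for the variational updates against trivial closed forms and
# independent brute-force oracles (helper-oracles.R).

simple_counts <- function() {
  count_tbl(
    sample = rep(c("s1", "s2"), each = 2),
    site = rep(1:2, 2),
    A = c(5, 0, 2, 1), C = c(0, 3, 1, 0), G = c(1, 0, 4, 2), T = c(0, 2, 0, 3)
  )
}

test_that("e_step with a single allele gives unit responsibilities and r = depth + alpha", {
  counts <- simple_counts()
  phi <- random_phi(1, 2)
  es <- e_step(counts, phi)
  expect_true(all(abs(es$w - 1) < 1e-12))
  depths <- c(s1 = 5 + 1 + 3 + 2, s2 = 2 + 1 + 4 + 1 + 2 + 3)
  expect_equal(as.numeric(es$r[, 1]), as.numeric(depths + 1), tolerance = 1e-12)
})

test_that("uniform phi and symmetric r give uniform responsibilities", {
  counts <- simple_counts()
  K <- 3
  phi <- array(0.25, dim = c(K, 2, 4))
  # equal r across alleles is a fixed point by symmetry: w = 1/K everywhere
  es <- e_step(counts, phi)
  expect_true(all(abs(es$w - 1 / K) < 1e-9))
})

test_that("e_step matches the brute-force fixed-point oracle", {
  set.seed(11)
  counts <- count_tbl(sample = "s1", site = 1, A = 3, C = 1, G = 0, T = 0)
  phi <- array(0, dim = c(2, 1, 4))
  phi[1, 1, ] <- c(0.9, 0.0333, 0.0333, 0.0334)
  phi[2, 1, ] <- c(0.25, 0.25, 0.25, 0.25)
  es <- e_step(counts, phi, tol = 1e-13, max_iter = 100000)
  orc <- oracle_e_step(counts_to_array(counts), phi,
                       r0 = matrix(1 + 4 / 2, 1, 2), alpha = c(1, 1))
  expect_equal(as.numeric(es$r), as.numeric(orc$r), tolerance = 1e-8)
  expect_equal(as.vector(es$w), as.vector(orc$w), tolerance = 1e-8)

  # and on a larger random instance
  counts <- random_counts(3, 3, max_depth = 5)
  phi <- random_phi(3, 3)
  es <- e_step(counts, phi, tol = 1e-13, max_iter = 100000)
  r0 <- matrix(1, 3, 3) + rowSums(counts_to_array(counts)) / 3
  orc <- oracle_e_step(counts_to_array(counts), phi, r0, alpha = rep(1, 3))
  expect_equal(as.numeric(es$r), as.numeric(orc$r), tolerance = 1e-7)
})

test_that("e_step invariants: simplex over alleles, r above alpha, depth conservation", {
  set.seed(12)
  for (rep in 1:5) {
    counts <- random_counts(3, 4, max_depth = 6)
    K <- sample(1:4, 1)
    phi <- random_phi(K, 4)
    es <- e_step(counts, phi)
    expect_true(all(abs(apply(es$w, c(1, 2, 3), sum) - 1) < 1e-9))
    expect_true(all(es$r >= 1 - 1e-12))
    d <- counts_to_array(counts)
    expect_equal(as.numeric(rowSums(es$r) - K), as.numeric(apply(d, 1, sum)),
                 tolerance = 1e-9)
  }
})

test_that("e_step leaves samples independent", {
  set.seed(13)
  counts <- random_counts(4, 3, max_depth = 5)
  phi <- random_phi(2, 3)
  full <- e_step(counts, phi)
  drop1 <- e_step(dplyr::filter(counts, sample != "s1"), phi)
  expect_equal(full$r[-1, ], drop1$r, tolerance = 1e-12)
})

test_that("e_step rejects mismatched dimensions and non-finite phi", {
  counts <- simple_counts()
  expect_error(e_step(counts, random_phi(2, 5)), "phi must be")
  phi <- random_phi(2, 2)
  phi[2, 1, 3] <- NaN
  expect_error(e_step(counts, phi), "allele 2, site index 1, base G")
})

test_that("m_step with K = 1 pools empirical base frequencies", {
  counts <- simple_counts()
  es <- e_step(counts, random_phi(1, 2))
  phi <- m_step(counts, es$w)
  d <- counts_to_array(counts)
  pooled <- apply(d, c(2, 3), sum)
  expect_equal(matrix(phi[1, , ], nrow = 2), pooled / rowSums(pooled),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("m_step matches the direct-summation oracle and normalizes", {
  set.seed(14)
  counts <- random_counts(2, 1, max_depth = 6)
  w <- array(runif(2 * 1 * 4 * 2), dim = c(2, 1, 4, 2))
  sw <- apply(w, c(1, 2, 3), sum)
  for (k in 1:2) w[, , , k] <- array(as.vector(w[, , , k]) / as.vector(sw), dim = dim(sw))
  phi <- suppressMessages(m_step(counts, w))
  orc <- oracle_m_step(counts_to_array(counts), w)
  expect_equal(as.vector(phi), as.vector(orc), tolerance = 1e-8)
  expect_true(all(abs(apply(phi, c(1, 2), sum) - 1) < 1e-9))
})

test_that("m_step falls back to uniform for unweighted cells with a message", {
  counts <- count_tbl(sample = "s1", site = 1:2, A = c(4, 0), C = 0, G = 0, T = 0)
  es <- e_step(counts, random_phi(2, 2))
  expect_message(phi <- m_step(counts, es$w), "zero weighted counts")
  expect_equal(as.numeric(phi[1, 2, ]), rep(0.25, 4), tolerance = 1e-9)
})

test_that("ELBO is zero with no data and r at the prior", {
  counts <- count_tbl(sample = c("s1", "s2"), site = 1, A = 0, C = 0, G = 0, T = 0)
  phi <- random_phi(2, 1)
  es <- e_step(counts, phi)
  expect_equal(as.vector(es$r), rep(1, 4), tolerance = 1e-12)
  expect_equal(elbo(counts, phi, es$w, es$r), 0, tolerance = 1e-10)
})

test_that("converged ELBO never exceeds the exact enumerated marginal likelihood", {
  set.seed(15)
  for (rep in 1:8) {
    N <- sample(1:2, 1)
    M <- sample(1:2, 1)
    K <- sample(2:3, 1)
    counts <- random_counts(N, M, max_depth = if (K == 3) 2 else 3)
    d <- counts_to_array(counts)
    if (max(apply(d, 1, sum)) > 6) next
    phi <- random_phi(K, M)
    es <- e_step(counts, phi, tol = 1e-12, max_iter = 100000)
    el <- elbo(counts, phi, es$w, es$r)
    exact <- oracle_log_marginal(d, phi, rep(1, K))
    expect_lte(el, exact + 1e-8)
  }
})

test_that("the e_step fixed point maximizes the ELBO over perturbed states", {
  set.seed(16)
  counts <- random_counts(1, 2, max_depth = 4)
  phi <- random_phi(2, 2)
  es <- e_step(counts, phi, tol = 1e-12, max_iter = 100000)
  best <- elbo(counts, phi, es$w, es$r)
  for (i in 1:10) {
    w2 <- es$w + array(runif(length(es$w), -0.05, 0.05), dim = dim(es$w))
    w2 <- pmax(w2, 1e-6)
    sw <- apply(w2, c(1, 2, 3), sum)
    for (k in 1:2) w2[, , , k] <- array(as.vector(w2[, , , k]) / as.vector(sw), dim = dim(sw))
    r2 <- es$r * (1 + runif(length(es$r), -0.1, 0.1))
    expect_lte(elbo(counts, phi, w2, r2), best + 1e-8)
  }
})
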