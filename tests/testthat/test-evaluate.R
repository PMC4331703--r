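# Allele calling, concordance metrics, copy-number conversion, trio check.

test_that("call_alleles takes the per-site argmax with A<C<G<T tie-breaking", {
  phi <- array(0, dim = c(1, 3, 4))
  phi[1, 1, ] <- c(0.97, 0.01, 0.01, 0.01)   # dominant A
  phi[1, 2, ] <- c(0.25, 0.25, 0.25, 0.25)   # full tie -> A
  phi[1, 3, ] <- c(0.1, 0.4, 0.4, 0.1)       # C/G tie -> C
  expect_equal(call_alleles(phi)$sequence, "AAC")
})

test_that("match_ratio counts matching positions and rejects length mismatch", {
  expect_equal(match_ratio("ATTG", "ATTG"), 1)
  expect_equal(match_ratio("ATTG", "ATTC"), 0.75)
  expect_equal(match_ratio("AAAA", "CCCC"), 0)
  expect_error(match_ratio("AT", "ATT"), "lengths differ")
})

test_that("concordance reproduces the hand-worked example", {
  cc <- allele_concordance(c("AA", "AT"), c("AA", "CC"))
  expect_equal(cc$precision, 0.75)
  expect_equal(cc$recall, 0.5)
  expect_equal(cc$f_measure, 0.6)
  expect_equal(dim(cc$r_matrix), c(2, 2))
  expect_equal(cc$r_matrix[1, 1], 1)
  expect_equal(cc$r_matrix[2, 2], 0)
})

test_that("identical sets give perfect concordance regardless of order", {
  truth <- c("ACGT", "TTTT", "AAAA")
  cc <- allele_concordance(rev(truth), truth)
  expect_equal(cc$precision, 1)
  expect_equal(cc$recall, 1)
  expect_equal(cc$f_measure, 1)
})

test_that("concordance is permutation invariant and P/R swap under transposition", {
  set.seed(51)
  rand_set <- function(k, m) {
    vapply(seq_len(k), function(i) {
      paste(sample(CNV_BASES, m, replace = TRUE), collapse = "")
    }, character(1))
  }
  for (rep in 1:100) {
    pred <- rand_set(sample(2:4, 1), 6)
    truth <- rand_set(sample(2:4, 1), 6)
    cc <- allele_concordance(pred, truth)
    cp <- allele_concordance(sample(pred), sample(truth))
    expect_equal(cc$precision, cp$precision, tolerance = 1e-12)
    expect_equal(cc$recall, cp$recall, tolerance = 1e-12)
    sw <- allele_concordance(truth, pred)
    expect_equal(cc$precision, sw$recall, tolerance = 1e-12)
    expect_equal(cc$recall, sw$precision, tolerance = 1e-12)
    # harmonic <= geometric <= arithmetic mean of (P, R)
    g <- sqrt(cc$precision * cc$recall)
    expect_lte(cc$f_measure, g + 1e-12)
    expect_lte(g, (cc$precision + cc$recall) / 2 + 1e-12)
  }
})

test_that("concordance rejects empty sets and length mismatches", {
  expect_error(allele_concordance(character(0), "ACGT"), "empty")
  expect_error(allele_concordance("ACG", c("ACGT")), "lengths differ")
})

test_that("copy numbers use largest-remainder rounding and conserve the total", {
  fit <- structure(list(
    samples = c("s1", "s2"),
    theta = matrix(c(0.5, 0.5, 0.6, 0.4), 2, 2, byrow = TRUE,
                   dimnames = list(c("s1", "s2"), c("allele1", "allele2"))),
    r = matrix(c(2, 2, 3, 2), 2, 2, byrow = TRUE,
               dimnames = list(c("s1", "s2"), c("allele1", "allele2")))
  ), class = "cnv_fit")
  calls <- copy_number_calls(fit, total_copies = 4)
  expect_equal(calls$copy_number[calls$sample == "s1"], c(2L, 2L))
  set.seed(52)
  for (rep in 1:50) {
    k <- sample(1:6, 1)
    th <- rdirichlet_test(k)
    tot <- sample(1:12, 1)
    cn <- cnvalleles:::largest_remainder(th, tot)
    expect_equal(sum(cn), tot)
    expect_true(all(cn >= 0))
  }
  # K = 1 puts everything on the single allele
  expect_equal(cnvalleles:::largest_remainder(1, 7), 7L)
})

test_that("trio consistency truth table", {
  expect_true(trio_consistency(c(2, 3), c(1, 2), c(1, 1))$consistent)
  expect_true(trio_consistency(c(0, 0, 0), c(0, 0, 0), c(0, 0, 0))$consistent)
  bad <- trio_consistency(c(3, 0), c(1, 2), c(1, 2))
  expect_false(bad$consistent)
  expect_equal(bad$violations, 1L)
  expect_error(trio_consistency(c(1, 2), c(1, 2, 3), c(1, 2)), "same alleles")
})

test_that("simulated pedigrees with inherited copy units satisfy the trio rule", {
  set.seed(53)
  # parents hold copy units; each child inherits a subset of each parent's units
  for (rep in 1:20) {
    k <- 3
    father <- as.integer(rmultinom(1, 4, rep(1 / k, k)))
    mother <- as.integer(rmultinom(1, 5, rep(1 / k, k)))
    pick <- function(cn) {
      vapply(cn, function(x) if (x == 0) 0L else sample(0:x, 1), integer(1))
    }
    child <- pick(father) + pick(mother)
    expect_true(trio_consistency(child, father, mother)$consistent)
  }
})
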