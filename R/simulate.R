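#' Benchmark allele set (four alleles, 16 variable sites)
#'
#' The fixed set of four copy-unit alleles over 16 variable sites used by the
#' first benchmark design (see [sim1_dataset()]).
#'
#' @return A tibble with columns `label` and `sequence`.
#' @export
benchmark_alleles <- function() {
  tibble::tibble(
    label = paste0("allele", 1:4),
    sequence = c(
      "ATTGCGATATTGCGAT",
      "ACGGATTTACGGATTT",
      "CTTCGGAACTTCGGAA",
      "CGATTGAACGTCGTAC"
    )
  )
}

#' Simulated dataset: fixed four-allele design
#'
#' Generates the first benchmark design: 12 samples at a 16-site locus, four
#' samples carrying two copy units, four carrying three, and four carrying
#' four. Each copy unit's allele is drawn uniformly (with replacement, so a
#' sample may hold duplicate alleles) from the four [benchmark_alleles()].
#' Read depth per copy unit and site is Poisson with mean `mean_depth`, and
#' each read base is corrupted with probability `error_rate` to one of the
#' other three bases uniformly.
#'
#' @param mean_depth mean Poisson read depth per copy unit per site.
#' @param error_rate per-base sequencing error probability in `[0, 1)`.
#' @param seed integer seed; `NULL` uses the current RNG state.
#'
#' @return A list of class `cnv_sim` with `counts` (base-count tibble, 12
#'   samples x 16 sites) and `truth` (see [sim_truth()]); the truth allele set
#'   is the full four-allele panel.
#' @export
#' @examples
#' sim <- sim1_dataset(seed = 42)
#' dplyr::count(sim$truth$assignment, sample)
sim1_dataset <- function(mean_depth = 15, error_rate = 0.01, seed = NULL) {
  stopifnot(mean_depth > 0, error_rate >= 0, error_rate < 1)
  if (!is.null(seed)) set.seed(seed)
  alleles <- benchmark_alleles()
  n_units <- rep(c(2L, 3L, 4L), each = 4L)
  samples <- sprintf("s%02d", seq_along(n_units))
  assignment <- purrr::map2_dfr(samples, n_units, function(s, u) {
    idx <- sample.int(4L, u, replace = TRUE)
    tibble::tibble(
      sample = s, unit = seq_len(u),
      label = alleles$label[idx], sequence = alleles$sequence[idx]
    )
  })
  counts <- simulate_counts(assignment, mean_depth = mean_depth,
                            error_rate = error_rate)
  structure(list(
    counts = counts,
    truth = sim_truth(assignment, alleles = alleles,
                      mean_depth = mean_depth, error_rate = error_rate,
                      seed = seed)
  ), class = "cnv_sim")
}

#' Synthetic haplotype pool
#'
#' Builds a pool of `pool_size` haplotype tokens carrying `n_distinct`
#' distinct sequences over `n_sites` variable sites, emulating the phased
#' haplotypes of a population panel at a small region. Haplotypes over a few
#' kilobases are genealogically related, so the derived-allele carriers of
#' each site are drawn from the clades of a random coalescent topology over
#' the haplotypes rather than independently; every site is biallelic with
#' the rarer base carried by at least two distinct haplotypes (where
#' `n_distinct` allows), and a minimal number of homoplastic adjustments
#' separates haplotypes that the clade mutations alone leave identical.
#' Token multiplicities come from a Dirichlet(1) split (largest-remainder
#' rounding, every haplotype at least once) so common and rare haplotypes
#' both occur. Both the multiplicities and the genealogy are a seeded
#' stand-in, not an estimate of any real population's frequencies.
#'
#' @param n_distinct number of distinct haplotype sequences.
#' @param pool_size total number of tokens (haplotype copies) in the pool.
#' @param n_sites number of variable sites (sequence length).
#' @param seed integer seed; `NULL` uses the current RNG state.
#'
#' @return A tibble with one row per token: `token`, `label` (shared by
#'   tokens of the same haplotype), `sequence`.
#' @export
haplotype_pool <- function(n_distinct = 9, pool_size = 45, n_sites = 21,
                           seed = NULL) {
  if (n_distinct < 1 || n_distinct > pool_size) {
    abort("need 1 <= n_distinct <= pool_size")
  }
  if (log(n_distinct) > n_sites * log(4)) {
    abort("n_distinct exceeds the number of distinct sequences of that length")
  }
  if (!is.null(seed)) set.seed(seed)

  if (n_distinct == 1) {
    warn("n_distinct = 1: all tokens identical, no site is variable")
    seqs <- paste(sample(CNV_BASES, n_sites, replace = TRUE), collapse = "")
  } else {
    carriers <- draw_carrier_sets(n_distinct, n_sites)
    mat <- matrix("", nrow = n_distinct, ncol = n_sites)
    for (x in seq_len(n_sites)) {
      pair <- sample(CNV_BASES, 2)
      mat[, x] <- pair[1]
      mat[carriers[[x]], x] <- pair[2]
    }
    seqs <- apply(mat, 1, paste, collapse = "")
    if (anyDuplicated(seqs)) abort("failed to draw distinct haplotypes")  # nocov
  }

  mult <- dirichlet_multiplicities(n_distinct, pool_size)
  idx <- rep(seq_len(n_distinct), times = mult)
  tibble::tibble(
    token = sprintf("t%02d", seq_len(pool_size)),
    label = sprintf("hap%d", idx),
    sequence = seqs[idx]
  )
}

# Derived-allele carrier sets for n_sites biallelic sites over n haplotypes.
# Carriers are clades of a random coalescent topology (sizes 2..n-2 so the
# minor allele is carried at least twice), then identical haplotype pairs --
# e.g. cherries, which no such clade separates -- are split by minimally
# editing one site's carrier set (drop one of the pair, or add one of the
# pair plus keep the size bounds), i.e. a homoplasy.
draw_carrier_sets <- function(n, n_sites) {
  if (n < 4) {
    # too few haplotypes for a minor count of 2: any proper nonempty subset
    return(lapply(seq_len(n_sites), function(x) {
      sample.int(n, sample.int(n - 1L, 1))
    }))
  }
  clades <- coalescent_clades(n)
  eligible <- clades[vapply(clades, length, 1L) <= n - 2L]
  carriers <- lapply(seq_len(n_sites), function(x) {
    eligible[[sample.int(length(eligible), 1)]]
  })
  for (attempt in 1:1000) {
    key <- vapply(seq_len(n), function(h) {
      paste(vapply(carriers, function(cs) h %in% cs, logical(1)), collapse = "")
    }, character(1))
    dup_pair <- NULL
    for (h in which(duplicated(key))) {
      dup_pair <- c(which(key == key[h])[1], h)
      break
    }
    if (is.null(dup_pair)) return(carriers)
    a <- dup_pair[1]; b <- dup_pair[2]
    x <- sample.int(n_sites, 1)
    cs <- carriers[[x]]
    if (all(c(a, b) %in% cs) && length(cs) > 2) {
      carriers[[x]] <- setdiff(cs, b)
    } else if (!any(c(a, b) %in% cs) && length(cs) < n - 2) {
      carriers[[x]] <- c(cs, a)
    }
  }
  abort("failed to separate all haplotypes; increase n_sites")
}

# Clades (leaf index sets) of a random topology built by successive random
# merges of lineages; the root (all leaves) is included.
coalescent_clades <- function(n) {
  groups <- as.list(seq_len(n))
  clades <- list()
  while (length(groups) > 1) {
    ij <- sample.int(length(groups), 2)
    merged <- c(groups[[ij[1]]], groups[[ij[2]]])
    clades[[length(clades) + 1]] <- merged
    groups[[ij[1]]] <- merged
    groups[[ij[2]]] <- NULL
  }
  clades
}

# Dirichlet(1)-proportional split of `total` into `n` positive integers via
# largest-remainder rounding; zeros are topped up from the largest class.
dirichlet_multiplicities <- function(n, total) {
  stopifnot(total >= n)
  p <- rdirichlet1(rep(1, n))
  m <- largest_remainder(p, total)
  while (any(m == 0)) {
    i <- which.max(m)
    j <- which(m == 0)[1]
    m[i] <- m[i] - 1L
    m[j] <- 1L
  }
  m
}

#' Copy-number configurations of the second benchmark design
#'
#' Preset sample copy-number configurations for the lower- (`"a"`),
#' middle- (`"b"`) and higher- (`"c"`) copy-number datasets. Each
#' configuration totals 45 copy units, exhausting the default
#' [haplotype_pool()].
#'
#' @param dataset one of `"a"`, `"b"`, `"c"`.
#' @return A tibble with columns `copy_number` and `n_samples`.
#' @export
#' @examples
#' sum(with(table2_config("c"), copy_number * n_samples))  # 45
table2_config <- function(dataset = c("a", "b", "c")) {
  dataset <- match.arg(dataset)
  switch(dataset,
    a = tibble::tibble(copy_number = 1:3, n_samples = c(5L, 11L, 6L)),
    b = tibble::tibble(copy_number = 2:6, n_samples = c(2L, 3L, 4L, 2L, 1L)),
    c = tibble::tibble(copy_number = 3:7, n_samples = c(1L, 2L, 3L, 2L, 1L))
  )
}

#' Assign pool haplotypes to samples
#'
#' Deals haplotype tokens to samples without replacement: a sample with copy
#' number `c` receives `c` tokens drawn uniformly from the tokens not yet
#' used. The total demand must not exceed the pool size.
#'
#' @param pool a token tibble from [haplotype_pool()].
#' @param config a tibble with columns `copy_number` and `n_samples`, e.g.
#'   from [table2_config()].
#' @param seed integer seed; `NULL` uses the current RNG state.
#'
#' @return An assignment tibble with one row per copy unit: `sample`, `unit`,
#'   `token`, `label`, `sequence`.
#' @export
assign_alleles <- function(pool, config, seed = NULL) {
  stopifnot(all(c("copy_number", "n_samples") %in% names(config)))
  demand <- sum(config$copy_number * config$n_samples)
  if (demand > nrow(pool)) {
    abort(sprintf("configuration needs %d copy units but the pool has %d tokens",
                  demand, nrow(pool)))
  }
  if (!is.null(seed)) set.seed(seed)
  copies <- rep(config$copy_number, times = config$n_samples)
  samples <- sprintf("s%02d", seq_along(copies))
  picks <- sample.int(nrow(pool), demand)  # without replacement
  offsets <- cumsum(c(0L, copies[-length(copies)]))
  purrr::map2_dfr(seq_along(samples), copies, function(i, cc) {
    rows <- picks[offsets[i] + seq_len(cc)]
    tibble::tibble(
      sample = samples[i], unit = seq_len(cc),
      token = pool$token[rows], label = pool$label[rows],
      sequence = pool$sequence[rows]
    )
  })
}

#' Simulate base counts from an allele assignment
#'
#' For every sample, site and copy unit: the number of reads is Poisson with
#' mean `mean_depth`; each read carries that unit's base at the site and is
#' independently corrupted with probability `error_rate` to one of the other
#' three bases, chosen uniformly. Counts are accumulated per base.
#'
#' @param assignment assignment tibble (`sample`, `sequence`, one row per
#'   copy unit) from [assign_alleles()] or a `cnv_sim` truth.
#' @inheritParams sim1_dataset
#'
#' @return A base-count tibble (see [count_tbl()]) with sites `1..M`.
#' @export
simulate_counts <- function(assignment, mean_depth, error_rate = 0.01,
                            seed = NULL) {
  stopifnot(mean_depth > 0, error_rate >= 0, error_rate < 1)
  if (!is.null(seed)) set.seed(seed)
  M <- unique(nchar(assignment$sequence))
  if (length(M) != 1) abort("all allele sequences must have equal length")
  samples <- unique(assignment$sample)
  base_idx <- function(s) match(strsplit(s, "")[[1]], CNV_BASES)

  purrr::map_dfr(samples, function(s) {
    seqs <- assignment$sequence[assignment$sample == s]
    cnt <- matrix(0L, nrow = M, ncol = 4L)
    for (sq in seqs) {
      bi <- base_idx(sq)
      depth <- rpois(M, mean_depth)
      err <- rbinom(M, depth, error_rate)
      for (x in seq_len(M)) {
        cnt[x, bi[x]] <- cnt[x, bi[x]] + depth[x] - err[x]
        if (err[x] > 0) {
          others <- setdiff(1:4, bi[x])
          spill <- rmultinom(1, err[x], rep(1 / 3, 3))[, 1]
          cnt[x, others] <- cnt[x, others] + spill
        }
      }
    }
    tibble::tibble(sample = s, site = seq_len(M),
                   A = cnt[, 1], C = cnt[, 2], G = cnt[, 3], T = cnt[, 4])
  })
}

#' Ground truth summary for a simulated dataset
#'
#' Collects the quantities later needed for evaluation: the allele set (by
#' default the distinct sequences actually present in the assignment), the
#' per-copy-unit assignment, and the per-sample true allele proportions
#' `theta = copy_number / total_copies`.
#'
#' @param assignment assignment tibble (one row per copy unit).
#' @param alleles optional allele tibble (`label`, `sequence`) defining the
#'   truth panel; defaults to the distinct sequences in `assignment`.
#' @param mean_depth,error_rate,seed generator settings recorded alongside.
#'
#' @return A list with `alleles`, `assignment`, `theta` (tibble: `sample`,
#'   `label`, `copy_number`, `total_copies`, `theta`), and the generator
#'   settings.
#' @export
sim_truth <- function(assignment, alleles = NULL, mean_depth = NA,
                      error_rate = NA, seed = NULL) {
  if (is.null(alleles)) {
    alleles <- dplyr::distinct(assignment, .data$label, .data$sequence)
  }
  theta <- assignment |>
    dplyr::count(.data$sample, .data$label, name = "copy_number") |>
    tidyr::complete(sample = unique(assignment$sample),
                    label = alleles$label,
                    fill = list(copy_number = 0L)) |>
    dplyr::group_by(.data$sample) |>
    dplyr::mutate(total_copies = sum(.data$copy_number),
                  theta = .data$copy_number / .data$total_copies) |>
    dplyr::ungroup()
  list(
    alleles = alleles, assignment = assignment, theta = theta,
    mean_depth = mean_depth, error_rate = error_rate,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed)
  )
}

#' Simulated dataset: pool-based copy-number designs
#'
#' Generates one replicate of the second benchmark design: build (or accept)
#' a haplotype pool, assign tokens to samples according to a preset
#' copy-number configuration (see [table2_config()]), and simulate base
#' counts. The truth allele set contains the distinct sequences actually
#' drawn, so the true number of alleles can be below the pool's 9.
#'
#' @param dataset `"a"`, `"b"` or `"c"` (lower/middle/higher copy numbers).
#' @param pool optional token tibble; a default [haplotype_pool()] is drawn
#'   when omitted.
#' @inheritParams sim1_dataset
#'
#' @return A list of class `cnv_sim` with `counts` and `truth`.
#' @export
sim2_dataset <- function(dataset = c("a", "b", "c"), mean_depth = 10,
                         error_rate = 0.01, seed = NULL, pool = NULL) {
  dataset <- match.arg(dataset)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(pool)) pool <- haplotype_pool()
  assignment <- assign_alleles(pool, table2_config(dataset))
  counts <- simulate_counts(assignment, mean_depth = mean_depth,
                            error_rate = error_rate)
  structure(list(
    counts = counts,
    truth = sim_truth(assignment, mean_depth = mean_depth,
                      error_rate = error_rate, seed = seed)
  ), class = "cnv_sim")
}
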