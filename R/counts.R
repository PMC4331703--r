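#' Build a base-count table
#'
#' Base counts are the package's primary input: one row per (sample, site)
#' pair with integer columns `A`, `C`, `G`, `T` giving how many aligned read
#' bases of each nucleotide were observed at that variable site in that
#' sample. Sites are 1-based positions; a (sample, site) pair that is absent
#' is treated as uncovered (all-zero counts).
#'
#' @param sample character vector of sample identifiers.
#' @param site integer vector of 1-based site positions.
#' @param A,C,G,T non-negative integer count vectors.
#'
#' @return A tibble with columns `sample`, `site`, `A`, `C`, `G`, `T`.
#' @export
#' @examples
#' count_tbl(sample = "s1", site = 1:2, A = c(10, 0), C = 0, G = c(0, 9), T = 0)
count_tbl <- function(sample, site, A = 0L, C = 0L, G = 0L, T = 0L) {
  out <- tibble::tibble(
    sample = as.character(sample), site = as.integer(site),
    A = as.integer(A), C = as.integer(C), G = as.integer(G), T = as.integer(T)
  )
  validate_counts(out)
  out
}

validate_counts <- function(counts) {
  need <- c("sample", "site", CNV_BASES)
  missing_cols <- setdiff(need, names(counts))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "count table must have columns sample, site, A, C, G, T; missing: ",
      paste(missing_cols, collapse = ", ")
    ))
  }
  if (nrow(counts) == 0) abort("count table is empty")
  cm <- as.matrix(counts[, CNV_BASES])
  if (anyNA(cm) || any(cm < 0)) abort("base counts must be non-negative and non-missing")
  dup <- duplicated(counts[, c("sample", "site")])
  if (any(dup)) {
    abort(paste0(
      "duplicate (sample, site) rows: ",
      paste(utils::head(paste0(counts$sample[dup], ":", counts$site[dup]), 3), collapse = ", ")
    ))
  }
  invisible(counts)
}

# Internal dense representation: counts as an N x (M*4) matrix with (site,
# base) pairs flattened base-fastest, so column (x - 1) * 4 + b holds base
# CNV_BASES[b] at the x-th site. Samples keep first-appearance order, sites
# ascending position.
counts_matrix <- function(counts) {
  validate_counts(counts)
  samples <- unique(as.character(counts$sample))
  sites <- sort(unique(as.integer(counts$site)))
  N <- length(samples)
  M <- length(sites)
  D <- matrix(0, nrow = N, ncol = M * 4L,
              dimnames = list(samples, NULL))
  ni <- match(as.character(counts$sample), samples)
  xi <- match(as.integer(counts$site), sites)
  for (b in 1:4) {
    D[cbind(ni, (xi - 1L) * 4L + b)] <- as.numeric(counts[[CNV_BASES[b]]])
  }
  list(D = D, samples = samples, sites = sites, N = N, M = M)
}

# phi: public form is a K x M x 4 array [allele, site, base]; the flat form
# used by the compiled kernel is (M*4) x K, base fastest.
phi_to_flat <- function(phi) {
  K <- dim(phi)[1]; M <- dim(phi)[2]
  out <- matrix(0, nrow = M * 4L, ncol = K)
  for (k in seq_len(K)) out[, k] <- as.vector(t(phi[k, , , drop = TRUE]))
  out
}

phi_from_flat <- function(phi_flat, sites, allele_labels = NULL) {
  K <- ncol(phi_flat); M <- length(sites)
  if (is.null(allele_labels)) allele_labels <- paste0("allele", seq_len(K))
  phi <- array(0, dim = c(K, M, 4L),
               dimnames = list(allele_labels, as.character(sites), CNV_BASES))
  for (k in seq_len(K)) phi[k, , ] <- t(matrix(phi_flat[, k], nrow = 4L))
  phi
}

# w: public form N x M x 4 x K; flat form a cube (M*4) x K x N.
w_from_cube <- function(W, samples, sites) {
  K <- dim(W)[2]; N <- dim(W)[3]; M <- length(sites)
  w <- array(0, dim = c(N, M, 4L, K),
             dimnames = list(samples, as.character(sites), CNV_BASES, NULL))
  for (n in seq_len(N)) {
    w[n, , , ] <- aperm(array(W[, , n], dim = c(4L, M, K)), c(2, 1, 3))
  }
  w
}

w_to_cube <- function(w) {
  N <- dim(w)[1]; M <- dim(w)[2]; K <- dim(w)[4]
  W <- array(0, dim = c(M * 4L, K, N))
  for (n in seq_len(N)) {
    W[, , n] <- matrix(aperm(array(w[n, , , ], dim = c(M, 4L, K)), c(2, 1, 3)),
                       nrow = M * 4L, ncol = K)
  }
  W
}

check_phi <- function(phi_flat) {
  bad <- which(!is.finite(phi_flat))
  if (length(bad) > 0) {
    j <- (bad[1] - 1L) %% nrow(phi_flat) + 1L
    k <- (bad[1] - 1L) %/% nrow(phi_flat) + 1L
    x <- (j - 1L) %/% 4L + 1L
    b <- (j - 1L) %% 4L + 1L
    abort(sprintf(
      "phi contains a non-finite value at allele %d, site index %d, base %s",
      k, x, CNV_BASES[b]
    ))
  }
  if (any(phi_flat <= 0)) abort("phi must be strictly positive (apply the floor first)")
  invisible(phi_flat)
}
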