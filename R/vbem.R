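#' Variational E-step
#'
#' One E-step of the variational Bayesian EM for the allele mixture model.
#' For each sample independently, the base-level responsibilities `w` and the
#' Dirichlet posterior parameters `r` over allele proportions are alternated
#'
#' \deqn{w_{nxbk} \propto \phi_{kxb}\,\exp[\Psi(r_{nk}) - \Psi(\textstyle\sum_k r_{nk})]}
#' \deqn{r_{nk} = \sum_x \sum_b d_{nxb}\, w_{nxbk} + \alpha_k}
#'
#' until `max |delta r| < tol`, where \eqn{\Psi} is the digamma function and
#' \eqn{d_{nxb}} the observed count of base b at site x in sample n.
#' Responsibilities are stored per observed base, not per read: the per-read
#' update depends on a read only through its base, so collapsing is exact.
#'
#' @param counts base-count table (see [count_tbl()]).
#' @param phi emission probability array `[allele, site, base]`, rows of the
#'   base dimension summing to 1 and strictly positive.
#' @param r optional starting `N x K` matrix of Dirichlet posterior
#'   parameters; defaults to `alpha + d_n / K`.
#' @param alpha Dirichlet prior on allele proportions, scalar or length-K
#'   (default 1: uniform prior).
#' @param tol inner convergence threshold on `max |delta r|`.
#' @param max_iter maximum inner iterations per sample.
#'
#' @return A list with `w` (`N x M x 4 x K` responsibility array, summing to 1
#'   over alleles), `r` (`N x K` matrix), and `iterations` per sample.
#' @seealso [m_step()], [elbo()], [fit_alleles()]
#' @export
e_step <- function(counts, phi, r = NULL, alpha = 1, tol = 1e-4, max_iter = 100) {
  cm <- counts_matrix(counts)
  if (length(dim(phi)) != 3 || dim(phi)[2] != cm$M || dim(phi)[3] != 4) {
    abort(sprintf(
      "phi must be a K x %d x 4 array matching the count table, got %s",
      cm$M, paste(dim(phi), collapse = " x ")
    ))
  }
  K <- dim(phi)[1]
  phi_flat <- phi_to_flat(phi)
  check_phi(phi_flat)
  alpha <- expand_alpha(alpha, K)
  if (is.null(r)) {
    r <- init_r(cm$D, K, alpha)
  } else {
    r <- as.matrix(r)
    if (nrow(r) != cm$N || ncol(r) != K) {
      abort(sprintf("r must be %d x %d, got %d x %d", cm$N, K, nrow(r), ncol(r)))
    }
  }
  es <- cpp_e_step(cm$D, phi_flat, r, alpha, tol, max_iter)
  rownames(es$r) <- cm$samples
  list(
    w = w_from_cube(es$w, cm$samples, cm$sites),
    r = es$r,
    iterations = es$iterations
  )
}

#' Variational M-step
#'
#' Re-estimates the emission probabilities from weighted base counts,
#' \eqn{\phi_{kxb} \propto \sum_n d_{nxb} w_{nxbk}}, normalised over bases for
#' each (allele, site). Cells where an allele receives no weighted count at a
#' site fall back to the uniform distribution (reported via a message).
#' Probabilities are floored at `eps` and renormalised so downstream logs are
#' finite.
#'
#' @param counts base-count table.
#' @param w responsibility array `[sample, site, base, allele]` from
#'   [e_step()].
#' @param eps positive floor applied to every emission probability.
#'
#' @return Emission probability array `[allele, site, base]`.
#' @export
m_step <- function(counts, w, eps = 1e-10) {
  cm <- counts_matrix(counts)
  dw <- dim(w)
  if (length(dw) != 4 || dw[1] != cm$N || dw[2] != cm$M || dw[3] != 4) {
    abort(sprintf(
      "w must be %d x %d x 4 x K, got %s",
      cm$N, cm$M, paste(dw, collapse = " x ")
    ))
  }
  ms <- cpp_m_step(cm$D, w_to_cube(w), eps)
  if (ms$n_uniform_cells > 0) {
    inform(sprintf(
      "%d (allele, site) cells had zero weighted counts; set to uniform",
      ms$n_uniform_cells
    ))
  }
  phi_from_flat(ms$phi, cm$sites)
}

#' Evidence lower bound
#'
#' The variational lower bound on the marginal log likelihood
#' \eqn{\log P(b \mid \alpha, \phi)} at the given variational state,
#' expanded in the standard mean-field form
#' \eqn{E_Q[\log P(b, z, \theta)] - E_Q[\log Q(z, \theta)]} with Dirichlet
#' expectations \eqn{E[\log\theta_{nk}] = \Psi(r_{nk}) - \Psi(\sum_k r_{nk})}.
#' With no observed bases and `r = alpha` the bound is exactly 0.
#'
#' @inheritParams m_step
#' @param phi emission probability array `[allele, site, base]`.
#' @param r Dirichlet posterior parameter matrix `N x K`.
#' @param alpha Dirichlet prior, scalar or length K.
#'
#' @return A finite scalar; never exceeds the exact marginal log likelihood.
#' @export
elbo <- function(counts, phi, w, r, alpha = 1) {
  cm <- counts_matrix(counts)
  K <- dim(phi)[1]
  phi_flat <- phi_to_flat(phi)
  check_phi(phi_flat)
  val <- cpp_elbo(cm$D, phi_flat, w_to_cube(w), as.matrix(r),
                  expand_alpha(alpha, K))
  if (!is.finite(val)) abort("ELBO is non-finite")
  val
}

#' Fit the allele mixture model
#'
#' Runs variational Bayesian EM for a fixed number of alleles `k`: each outer
#' iteration performs an E-step to an inner fixed point, an M-step, and an
#' ELBO evaluation, stopping when the relative ELBO change falls below `tol`.
#' Because the bound is multimodal under label symmetry, `n_restarts`
#' randomised initialisations are run and the restart with the highest final
#' ELBO is returned. Initial emission rows mix the pooled empirical base
#' frequencies with a symmetric Dirichlet(1) draw (equal parts), and `r`
#' starts at `alpha + d_n / k`.
#'
#' @inheritParams e_step
#' @param k number of copy-unit alleles (mixture components), `>= 1`.
#' @param n_restarts number of random restarts.
#' @param max_iter maximum outer EM iterations.
#' @param tol relative ELBO change declaring outer convergence.
#' @param inner_tol,inner_max_iter inner E-step controls (see [e_step()]).
#' @param seed integer seed making the whole fit reproducible; `NULL` uses
#'   the current RNG state.
#'
#' @return An object of class `cnv_fit` with elements `k`, `phi`, `r`, `w`,
#'   `theta` (posterior mean proportions `r / rowSums(r)`), `alpha`, `elbo`,
#'   `elbo_trace`, `restarts` (per-restart summary tibble), `converged`,
#'   `n_iterations`, `seed`, `samples`, `sites`. Supports [tidy()],
#'   [glance()], [autoplot()] and [call_alleles()].
#' @export
#' @examples
#' sim <- sim1_dataset(seed = 1)
#' fit <- fit_alleles(sim$counts, k = 4, n_restarts = 2, seed = 1)
#' glance(fit)
fit_alleles <- function(counts, k, alpha = 1, n_restarts = 10,
                        max_iter = 500, tol = 1e-6,
                        inner_tol = 1e-4, inner_max_iter = 100,
                        seed = NULL) {
  stopifnot(k >= 1, n_restarts >= 1)
  cm <- counts_matrix(counts)
  alpha <- expand_alpha(alpha, k)
  if (!is.null(seed)) set.seed(seed)
  restart_seeds <- sample.int(.Machine$integer.max, n_restarts)

  warn_if_overparameterised(cm$D, k)
  emp <- pooled_base_freq(cm$D)  # 4 x M

  best <- NULL
  restarts <- vector("list", n_restarts)
  for (i in seq_len(n_restarts)) {
    set.seed(restart_seeds[i])
    run <- vbem_run(cm, k, alpha, emp, max_iter, tol, inner_tol, inner_max_iter)
    restarts[[i]] <- tibble::tibble(
      restart = i, seed = restart_seeds[i], elbo = run$elbo,
      n_iterations = run$n_iterations, converged = run$converged
    )
    if (is.null(best) || run$elbo > best$elbo) best <- run
  }

  r <- best$r
  dimnames(r) <- list(cm$samples, paste0("allele", seq_len(k)))
  structure(list(
    k = k,
    phi = phi_from_flat(best$phi_flat, cm$sites),
    r = r,
    w = w_from_cube(best$W, cm$samples, cm$sites),
    theta = r / rowSums(r),
    alpha = alpha,
    elbo = best$elbo,
    elbo_trace = best$trace,
    restarts = dplyr::bind_rows(restarts),
    converged = best$converged,
    n_iterations = best$n_iterations,
    n_restarts = n_restarts,
    seed = if (is.null(seed)) NA_integer_ else as.integer(seed),
    samples = cm$samples,
    sites = cm$sites
  ), class = "cnv_fit")
}

#' Select the number of alleles by the evidence lower bound
#'
#' Fits the model for every `k` in `[k_min, k_max]` (each with `n_restarts`
#' restarts) and selects the `k` whose best final ELBO is highest; ELBO ties
#' within `1e-6` are broken toward the smaller `k` (parsimony).
#'
#' @inheritParams fit_alleles
#' @param k_min,k_max inclusive range of candidate allele numbers.
#' @param keep_fits keep every fitted model (in `$fits`) rather than only the
#'   selected one.
#' @param ... passed on to [fit_alleles()].
#'
#' @return An object of class `cnv_k_selection` with `k` (selected), `best`
#'   (the selected `cnv_fit`), `elbo_by_k` (tibble: `k`, `restart`, `elbo`),
#'   and optionally `fits`. [tidy()] returns the ELBO table, [autoplot()]
#'   draws the ELBO-versus-k curve.
#' @export
select_n_alleles <- function(counts, k_min = 1, k_max = 8, seed = NULL,
                             keep_fits = FALSE, ...) {
  stopifnot(k_min >= 1, k_min <= k_max)
  ks <- seq.int(k_min, k_max)
  if (!is.null(seed)) set.seed(seed)
  kseeds <- sample.int(.Machine$integer.max, length(ks))

  fits <- purrr::map2(ks, kseeds, function(k, s) {
    fit_alleles(counts, k = k, seed = s, ...)
  })
  finals <- purrr::map_dbl(fits, "elbo")
  sel <- min(ks[finals >= max(finals) - 1e-6])
  elbo_by_k <- purrr::map2_dfr(ks, fits, function(k, f) {
    dplyr::mutate(f$restarts, k = k, .before = 1)
  })
  structure(list(
    k = sel,
    best = fits[[match(sel, ks)]],
    elbo_by_k = elbo_by_k,
    final_elbo = tibble::tibble(k = ks, elbo = finals),
    fits = if (keep_fits) setNames(fits, paste0("k", ks)) else NULL
  ), class = "cnv_k_selection")
}

# ---- internals -------------------------------------------------------------

expand_alpha <- function(alpha, K) {
  if (length(alpha) == 1) alpha <- rep(alpha, K)
  if (length(alpha) != K || any(!is.finite(alpha)) || any(alpha <= 0)) {
    abort("alpha must be positive, length 1 or K")
  }
  as.numeric(alpha)
}

init_r <- function(D, K, alpha) {
  dn <- rowSums(D)
  matrix(alpha, nrow = nrow(D), ncol = K, byrow = TRUE) + dn / K
}

pooled_base_freq <- function(D) {
  M <- ncol(D) %/% 4L
  pool <- matrix(colSums(D), nrow = 4L)  # 4 x M
  tot <- colSums(pool)
  freq <- matrix(0.25, nrow = 4L, ncol = M)
  ok <- tot > 0
  freq[, ok] <- sweep(pool[, ok, drop = FALSE], 2, tot[ok], "/")
  freq
}

warn_if_overparameterised <- function(D, k) {
  M <- ncol(D) %/% 4L
  pool <- matrix(colSums(D), nrow = 4L)
  log_patterns <- sum(log(pmax(colSums(pool > 0), 1)))
  if (log(k) > log_patterns) {
    warn(paste0(
      "k = ", k, " exceeds the number of distinct base patterns observable ",
      "at the covered sites; surplus alleles will converge to duplicates"
    ))
  }
}

rdirichlet1 <- function(a) {
  g <- rgamma(length(a), shape = a)
  s <- sum(g)
  if (s <= 0) return(rep(1 / length(a), length(a)))
  g / s
}

init_phi_flat <- function(emp, K, eps = 1e-10) {
  M <- ncol(emp)
  phi <- matrix(0, nrow = M * 4L, ncol = K)
  for (k in seq_len(K)) {
    for (x in seq_len(M)) {
      p <- 0.5 * emp[, x] + 0.5 * rdirichlet1(rep(1, 4))
      phi[(x - 1L) * 4L + 1:4, k] <- p
    }
  }
  floor_phi(phi, eps)
}

floor_phi <- function(phi_flat, eps = 1e-10) {
  phi_flat <- pmax(phi_flat, eps)
  M <- nrow(phi_flat) %/% 4L
  for (k in seq_len(ncol(phi_flat))) {
    m <- matrix(phi_flat[, k], nrow = 4L)
    phi_flat[, k] <- as.vector(sweep(m, 2, colSums(m), "/"))
  }
  phi_flat
}

# One full VB-EM run from a fresh random initialisation; the outer loop
# lives in compiled code, only the initialisation uses R's RNG.
vbem_run <- function(cm, K, alpha, emp, max_iter, tol, inner_tol, inner_max_iter) {
  phi_flat <- init_phi_flat(emp, K)
  r <- init_r(cm$D, K, alpha)
  run <- cpp_vbem_run(cm$D, phi_flat, r, alpha, max_iter, tol,
                      inner_tol, inner_max_iter, 1e-10)
  list(
    phi_flat = run$phi, r = run$r, W = run$w,
    elbo = run$trace[length(run$trace)], trace = run$trace,
    n_iterations = run$n_iterations, converged = run$converged
  )
}
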