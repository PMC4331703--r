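# Independent brute-force oracles for the variational updates and the exact
# marginal likelihood. These deliberately use naive loops and a different
# code path from the package internals.

BASES <- c("A", "C", "G", "T")

# counts tibble -> dense array [n, x, b]
counts_to_array <- function(counts) {
  samples <- unique(counts$sample)
  sites <- sort(unique(counts$site))
  a <- array(0, dim = c(length(samples), length(sites), 4),
             dimnames = list(samples, sites, BASES))
  for (i in seq_len(nrow(counts))) {
    n <- match(counts$sample[i], samples)
    x <- match(counts$site[i], sites)
    for (b in 1:4) a[n, x, b] <- counts[[BASES[b]]][i]
  }
  a
}

# Alternate the two E-step updates with naive loops until max |delta r| < tol.
oracle_e_step <- function(d, phi, r0, alpha, tol = 1e-12, max_iter = 10000) {
  N <- dim(d)[1]; M <- dim(d)[2]; K <- dim(phi)[1]
  w <- array(0, dim = c(N, M, 4, K))
  r <- r0
  for (it in seq_len(max_iter)) {
    for (n in seq_len(N)) {
      for (x in seq_len(M)) {
        for (b in 1:4) {
          u <- numeric(K)
          for (k in seq_len(K)) {
            u[k] <- phi[k, x, b] * exp(digamma(r[n, k]) - digamma(sum(r[n, ])))
          }
          w[n, x, b, ] <- u / sum(u)
        }
      }
    }
    rnew <- r
    for (n in seq_len(N)) {
      for (k in seq_len(K)) {
        s <- 0
        for (x in seq_len(M)) for (b in 1:4) s <- s + d[n, x, b] * w[n, x, b, k]
        rnew[n, k] <- s + alpha[k]
      }
    }
    delta <- max(abs(rnew - r))
    r <- rnew
    if (delta < tol) break
  }
  list(w = w, r = r)
}

# Direct summation of the M-step formula.
oracle_m_step <- function(d, w) {
  N <- dim(d)[1]; M <- dim(d)[2]; K <- dim(w)[4]
  phi <- array(0, dim = c(K, M, 4))
  for (k in seq_len(K)) {
    for (x in seq_len(M)) {
      for (b in 1:4) {
        s <- 0
        for (n in seq_len(N)) s <- s + d[n, x, b] * w[n, x, b, k]
        phi[k, x, b] <- s
      }
      tot <- sum(phi[k, x, ])
      phi[k, x, ] <- if (tot > 0) phi[k, x, ] / tot else rep(0.25, 4)
    }
  }
  phi
}

# Exact log marginal likelihood by exhaustive enumeration of all K^d allele
# assignments per sample, each weighted by its Polya (Dirichlet-multinomial)
# prior mass: samples are independent, so the totals multiply.
oracle_log_marginal <- function(d, phi, alpha) {
  N <- dim(d)[1]; M <- dim(d)[2]; K <- dim(phi)[1]
  total <- 0
  for (n in seq_len(N)) {
    # expand this sample's counts into base tokens (x, b)
    toks <- list()
    for (x in seq_len(M)) for (b in 1:4) {
      if (d[n, x, b] > 0) {
        for (t in seq_len(d[n, x, b])) toks[[length(toks) + 1]] <- c(x, b)
      }
    }
    dn <- length(toks)
    if (dn == 0) next
    terms <- numeric(K^dn)
    for (code in 0:(K^dn - 1)) {
      z <- integer(dn)
      cc <- code
      for (t in seq_len(dn)) {
        z[t] <- cc %% K + 1
        cc <- cc %/% K
      }
      lp <- 0
      m <- integer(K)
      for (t in seq_len(dn)) {
        lp <- lp + log(phi[z[t], toks[[t]][1], toks[[t]][2]])
        m[z[t]] <- m[z[t]] + 1
      }
      # Dirichlet-multinomial weight of the assignment pattern
      lp <- lp + lgamma(sum(alpha)) - sum(lgamma(alpha)) +
        sum(lgamma(alpha + m)) - lgamma(sum(alpha) + dn)
      terms[code + 1] <- lp
    }
    mx <- max(terms)
    total <- total + mx + log(sum(exp(terms - mx)))
  }
  total
}

# Random small count tables for property tests.
random_counts <- function(N, M, max_depth = 3) {
  rows <- list()
  for (n in seq_len(N)) {
    for (x in seq_len(M)) {
      cnt <- as.integer(rmultinom(1, sample(0:max_depth, 1), rep(0.25, 4)))
      rows[[length(rows) + 1]] <- tibble::tibble(
        sample = paste0("s", n), site = x,
        A = cnt[1], C = cnt[2], G = cnt[3], T = cnt[4]
      )
    }
  }
  dplyr::bind_rows(rows)
}

rdirichlet_test <- function(k) {
  g <- rgamma(k, 1) + 1e-6
  g / sum(g)
}

random_phi <- function(K, M) {
  phi <- array(0, dim = c(K, M, 4))
  for (k in seq_len(K)) for (x in seq_len(M)) {
    g <- rgamma(4, 1) + 0.05
    phi[k, x, ] <- g / sum(g)
  }
  phi
}
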