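#' Call allele sequences from fitted emission probabilities
#'
#' The predicted base of allele k at site x is the argmax over bases of the
#' emission probability, \eqn{\hat b_{kx} = \arg\max_b \phi_{kxb}}. Ties are
#' broken by the fixed alphabet order A < C < G < T.
#'
#' @param x a `cnv_fit` object or an emission probability array
#'   `[allele, site, base]`.
#' @param ... unused.
#'
#' @return A tibble with columns `label` and `sequence`, one row per allele.
#' @export
call_alleles <- function(x, ...) UseMethod("call_alleles")

#' @rdname call_alleles
#' @export
call_alleles.cnv_fit <- function(x, ...) call_alleles(x$phi)

#' @rdname call_alleles
#' @export
call_alleles.default <- function(x, ...) {
  phi <- x
  if (length(dim(phi)) != 3 || dim(phi)[3] != 4) {
    abort("phi must be a K x M x 4 array")
  }
  K <- dim(phi)[1]
  seqs <- vapply(seq_len(K), function(k) {
    m <- matrix(phi[k, , ], ncol = 4L)
    paste(CNV_BASES[max.col(m, ties.method = "first")], collapse = "")
  }, character(1))
  labels <- dimnames(phi)[[1]]
  if (is.null(labels)) labels <- paste0("allele", seq_len(K))
  tibble::tibble(label = labels, sequence = seqs)
}

#' Fraction of matching bases between two sequences
#'
#' The per-pair concordance ratio: the number of positions at which the two
#' sequences carry the same base, divided by their length.
#'
#' @param pred,truth equal-length nucleotide strings.
#' @return A number in `[0, 1]`.
#' @export
#' @examples
#' match_ratio("ATTG", "ATTC")  # 0.75
match_ratio <- function(pred, truth) {
  if (nchar(pred) != nchar(truth)) {
    abort(sprintf("sequence lengths differ: %d vs %d", nchar(pred), nchar(truth)))
  }
  a <- strsplit(pred, "")[[1]]
  b <- strsplit(truth, "")[[1]]
  mean(a == b)
}

as_allele_seqs <- function(x, what) {
  if (is.character(x)) return(x)
  if (is.data.frame(x) && "sequence" %in% names(x)) return(x$sequence)
  if (inherits(x, "cnv_fit")) return(call_alleles(x)$sequence)
  abort(paste0(what, " must be a character vector, an allele tibble, or a cnv_fit"))
}

#' Concordance between predicted and true allele sets
#'
#' Precision is the mean over predicted alleles of the best match ratio
#' against any true allele; recall is the mean over true alleles of the best
#' match ratio against any predicted allele:
#' \deqn{P = \frac{1}{K}\sum_k \max_l r_{kl},\qquad
#'       R = \frac{1}{K_0}\sum_l \max_k r_{kl},}
#' with \eqn{r_{kl}} the per-pair [match_ratio()]. The F-measure is their
#' harmonic mean (0 when both are 0). Both metrics use a per-allele max, not
#' a one-to-one matching, so duplicated predictions can inflate precision.
#'
#' @param pred,truth allele sets: character vectors of equal-length
#'   sequences, tibbles with a `sequence` column, or `cnv_fit` objects.
#'
#' @return An object of class `cnv_concordance`: a list with `precision`,
#'   `recall`, `f_measure`, and the `K_pred x K_true` matrix `r_matrix`.
#'   [tidy()] returns the three metrics as a one-row tibble.
#' @export
#' @examples
#' allele_concordance(c("AA", "AT"), c("AA", "CC"))
allele_concordance <- function(pred, truth) {
  pred <- as_allele_seqs(pred, "pred")
  truth <- as_allele_seqs(truth, "truth")
  if (length(pred) == 0 || length(truth) == 0) abort("empty allele set")
  r_matrix <- outer(pred, truth, Vectorize(match_ratio))
  precision <- mean(apply(r_matrix, 1, max))
  recall <- mean(apply(r_matrix, 2, max))
  f <- if (precision + recall == 0) 0 else {
    2 * precision * recall / (precision + recall)
  }
  structure(list(
    precision = precision, recall = recall, f_measure = f, r_matrix = r_matrix
  ), class = "cnv_concordance")
}

#' @export
print.cnv_concordance <- function(x, ...) {
  cat(sprintf("Allele concordance: precision %.3f, recall %.3f, F %.3f (%d predicted vs %d true)\n",
              x$precision, x$recall, x$f_measure, nrow(x$r_matrix), ncol(x$r_matrix)))
  invisible(x)
}

#' @export
tidy.cnv_concordance <- function(x, ...) {
  tibble::tibble(precision = x$precision, recall = x$recall,
                 f_measure = x$f_measure)
}

# Largest-remainder rounding of proportions p (summing to ~1) to integers
# summing to `total`; remainder ties go to the earlier index.
largest_remainder <- function(p, total) {
  raw <- p / sum(p) * total
  base <- floor(raw)
  left <- as.integer(round(total - sum(base)))
  if (left > 0) {
    ord <- order(raw - base, decreasing = TRUE)
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

#' Integer copy-number calls from a fitted model
#'
#' Converts posterior mean allele proportions `theta = r / sum(r)` into
#' integer per-allele copy numbers given each sample's total copy number.
#' The model itself only measures proportions; the total must come from an
#' external source (e.g. depth-based total copy-number estimation). Rounding
#' uses the largest-remainder method so the per-allele integers always sum
#' to the supplied total.
#'
#' @param fit a `cnv_fit` object.
#' @param total_copies total copy units per sample: a single number recycled
#'   to all samples, or a vector named by sample.
#'
#' @return A tibble with columns `sample`, `label`, `theta`, `copy_number`,
#'   `total_copies`.
#' @export
copy_number_calls <- function(fit, total_copies) {
  stopifnot(inherits(fit, "cnv_fit"), all(total_copies >= 1))
  samples <- fit$samples
  if (length(total_copies) == 1) {
    total_copies <- setNames(rep(total_copies, length(samples)), samples)
  }
  if (is.null(names(total_copies))) {
    stopifnot(length(total_copies) == length(samples))
    names(total_copies) <- samples
  }
  purrr::map_dfr(samples, function(s) {
    th <- fit$theta[s, ]
    tot <- as.integer(total_copies[[s]])
    tibble::tibble(
      sample = s, label = colnames(fit$r), theta = as.numeric(th),
      copy_number = largest_remainder(th, tot), total_copies = tot
    )
  })
}

#' Trio heredity consistency of copy-number calls
#'
#' Checks the heredity constraint on estimated per-allele copy numbers in a
#' parent-offspring trio: for every allele, the child's copy number must not
#' exceed the sum of its parents' copy numbers.
#'
#' @param child,father,mother integer copy-number vectors over the same
#'   alleles (same length and order).
#'
#' @return A list with `consistent` (logical) and `violations` (indices of
#'   alleles where the constraint fails).
#' @export
#' @examples
#' trio_consistency(c(2, 3), c(1, 2), c(1, 1))$consistent  # TRUE
trio_consistency <- function(child, father, mother) {
  if (length(child) != length(father) || length(child) != length(mother)) {
    abort("child, father and mother must cover the same alleles")
  }
  bad <- which(child > father + mother)
  list(consistent = length(bad) == 0, violations = as.integer(bad))
}
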