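#' @export
print.cnv_fit <- function(x, ...) {
  cat(sprintf(
    "Allele mixture fit: K = %d, %d samples x %d sites\n  ELBO %.3f after %d iterations (%s), best of %d restarts\n",
    x$k, length(x$samples), length(x$sites), x$elbo, x$n_iterations,
    if (x$converged) "converged" else "not converged", x$n_restarts
  ))
  invisible(x)
}

#' Tidy a fitted allele mixture
#'
#' Returns the per-sample posterior over allele proportions: the Dirichlet
#' parameter `r` and its posterior mean `theta = r / sum(r)` for every
#' (sample, allele) pair.
#'
#' @param x a `cnv_fit` object.
#' @param ... unused.
#' @return A tibble with columns `sample`, `label`, `r`, `theta`.
#' @export
tidy.cnv_fit <- function(x, ...) {
  purrr::map_dfr(seq_along(x$samples), function(n) {
    tibble::tibble(
      sample = x$samples[n], label = colnames(x$r),
      r = as.numeric(x$r[n, ]), theta = as.numeric(x$theta[n, ])
    )
  })
}

#' @rdname tidy.cnv_fit
#' @export
glance.cnv_fit <- function(x, ...) {
  tibble::tibble(
    k = x$k, elbo = x$elbo, n_iterations = x$n_iterations,
    converged = x$converged, n_restarts = x$n_restarts,
    n_samples = length(x$samples), n_sites = length(x$sites)
  )
}

#' ELBO trace plot for a fitted allele mixture
#'
#' @param object a `cnv_fit` object.
#' @param ... unused.
#' @return A ggplot of the lower bound against outer EM iteration.
#' @export
autoplot.cnv_fit <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$elbo_trace),
                       elbo = object$elbo_trace)
  ggplot2::ggplot(df, ggplot2::aes(.data$iteration, .data$elbo)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "EM iteration", y = "evidence lower bound",
                  title = sprintf("VB-EM trace (K = %d)", object$k))
}

#' @export
print.cnv_k_selection <- function(x, ...) {
  cat(sprintf("Allele number selection: K = %d (ELBO %.3f) over K = %d..%d\n",
              x$k, x$best$elbo, min(x$final_elbo$k), max(x$final_elbo$k)))
  invisible(x)
}

#' Tidy an allele-number selection
#'
#' @param x a `cnv_k_selection` object.
#' @param ... unused.
#' @return The per-restart ELBO table: `k`, `restart`, `seed`, `elbo`,
#'   `n_iterations`, `converged`.
#' @export
tidy.cnv_k_selection <- function(x, ...) x$elbo_by_k

#' @rdname tidy.cnv_k_selection
#' @export
glance.cnv_k_selection <- function(x, ...) {
  tibble::tibble(k = x$k, elbo = x$best$elbo,
                 k_min = min(x$final_elbo$k), k_max = max(x$final_elbo$k))
}

#' ELBO-versus-K curve
#'
#' Plots the best final lower bound for each candidate number of alleles,
#' marking the selected K; the analogue of the model-selection curve used to
#' pick the number of copy-unit alleles.
#'
#' @param object a `cnv_k_selection` object.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.cnv_k_selection <- function(object, ...) {
  ggplot2::ggplot(object$final_elbo, ggplot2::aes(.data$k, .data$elbo)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k, linetype = "dashed") +
    ggplot2::labs(x = "number of alleles K", y = "evidence lower bound",
                  title = sprintf("Selected K = %d", object$k))
}

#' Per-allele copy-number profile plot
#'
#' Line plot of integer copy-number calls across alleles, one line per
#' sample; useful for eyeballing trio heredity patterns.
#'
#' @param calls tibble from [copy_number_calls()].
#' @param highlight optional sample names drawn with thick lines (e.g. the
#'   parents of a pedigree).
#' @return A ggplot object.
#' @export
plot_copy_numbers <- function(calls, highlight = NULL) {
  calls <- dplyr::mutate(calls,
                         highlighted = .data$sample %in% (highlight %||% character(0)))
  ggplot2::ggplot(calls, ggplot2::aes(.data$label, .data$copy_number,
                                      group = .data$sample,
                                      colour = .data$sample)) +
    ggplot2::geom_line(ggplot2::aes(linewidth = .data$highlighted)) +
    ggplot2::scale_linewidth_manual(values = c(`FALSE` = 0.4, `TRUE` = 1.2),
                                    guide = "none") +
    ggplot2::labs(x = "allele", y = "copy number")
}

#' @export
print.cnv_sim <- function(x, ...) {
  cat(sprintf(
    "Simulated CNV dataset: %d samples x %d sites, %d true alleles (mean depth %s, error %s)\n",
    length(unique(x$counts$sample)), length(unique(x$counts$site)),
    nrow(x$truth$alleles), format(x$truth$mean_depth), format(x$truth$error_rate)
  ))
  invisible(x)
}
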