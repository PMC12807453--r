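#' Occupancy cutoff from a fitted lower component
#'
#' The cutoff separating genes with substantial Pol II TSS signal from
#' background is the `1 - type1_error` quantile of the lower (background)
#' Gaussian component: the type-I error is the probability that a background
#' gene exceeds the cutoff.
#'
#' @param mu,sigma mean and standard deviation of the lower component on the
#'   log10-density scale.
#' @param type1_error tolerated type-I error (default 0.10).
#' @return the log10-density cutoff.
#' @export
mixture_cutoff <- function(mu, sigma, type1_error = 0.1) {
  if (!(type1_error > 0 && type1_error < 1))
    stop("type1_error must lie in (0, 1)")
  mu + stats::qnorm(1 - type1_error) * sigma
}

#' Fit a two-component Gaussian mixture to log TSS densities
#'
#' Log-transformed TSS read densities across genes are typically bimodal: an
#' upper mode of genes with real Pol II signal over a lower background mode.
#' This EM fit models them as two partially overlapping Gaussians and derives
#' the occupancy cutoff as the `1 - type1_error` quantile of the lower
#' component (see [mixture_cutoff()]).
#'
#' Initialisation is deterministic: component means at the 25th and 75th
#' percentiles, both standard deviations at half the sample SD, equal weights.
#' Convergence is declared when the log-likelihood improves by less than `tol`
#' (default 1e-8) or after `max_iter` iterations. Components are relabelled so
#' `mu_low < mu_high`. A collapsing component (weight < 1e-3 or sigma < 1e-6)
#' aborts with an error suggesting the data may be unimodal.
#'
#' @param log_densities numeric vector of log10 TSS densities (non-finite
#'   values are dropped); at least 50 values required.
#' @param type1_error tolerated type-I error for the cutoff.
#' @param max_iter,tol EM iteration cap and log-likelihood tolerance.
#' @return object of class `tss_mixture` with fields mu_low, sigma_low,
#'   weight_low, mu_high, sigma_high, weight_high, type1_error, cutoff,
#'   loglik, n_iter, converged, n.
#' @export
fit_tss_mixture <- function(log_densities, type1_error = 0.1,
                            max_iter = 1000L, tol = 1e-8) {
  x <- as.numeric(log_densities)
  x <- x[is.finite(x)]
  if (length(x) < 50)
    stop("need at least 50 finite log densities to fit the mixture")
  if (stats::sd(x) < 1e-12)
    stop("degenerate fit: all log densities identical; data look unimodal")
  mu <- unname(stats::quantile(x, c(0.25, 0.75)))
  sg <- rep(stats::sd(x) / 2, 2)
  w <- c(0.5, 0.5)
  n <- length(x)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(x, mu[1], sg[1])
    d2 <- w[2] * stats::dnorm(x, mu[2], sg[2])
    tot <- d1 + d2
    tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
    ll <- sum(log(tot))
    r2 <- d2 / tot
    r1 <- 1 - r2
    n1 <- sum(r1); n2 <- sum(r2)
    if (min(n1, n2) / n < 1e-3)
      stop("degenerate fit: a component weight collapsed below 1e-3; ",
           "data may be unimodal")
    mu <- c(sum(r1 * x) / n1, sum(r2 * x) / n2)
    sg <- sqrt(c(sum(r1 * (x - mu[1])^2) / n1, sum(r2 * (x - mu[2])^2) / n2))
    if (min(sg) < 1e-6)
      stop("degenerate fit: a component sigma collapsed below 1e-6; ",
           "data may be unimodal")
    w <- c(n1, n2) / n
    if (ll - ll_old < tol && iter > 1L) { converged <- TRUE; break }
    ll_old <- ll
  }
  if (mu[1] > mu[2]) { mu <- rev(mu); sg <- rev(sg); w <- rev(w) }
  fit <- list(mu_low = mu[1], sigma_low = sg[1], weight_low = w[1],
              mu_high = mu[2], sigma_high = sg[2], weight_high = w[2],
              type1_error = type1_error,
              cutoff = mixture_cutoff(mu[1], sg[1], type1_error),
              loglik = ll, n_iter = iter, converged = converged, n = n)
  class(fit) <- "tss_mixture"
  fit
}

#' @export
print.tss_mixture <- function(x, ...) {
  cat("Two-component Gaussian mixture on log10 TSS densities\n")
  cat(sprintf("  lower : mu=%.4f sd=%.4f weight=%.3f\n",
              x$mu_low, x$sigma_low, x$weight_low))
  cat(sprintf("  upper : mu=%.4f sd=%.4f weight=%.3f\n",
              x$mu_high, x$sigma_high, x$weight_high))
  cat(sprintf("  cutoff: %.4f (type-I error %.2f), loglik %.2f, %d iter%s\n",
              x$cutoff, x$type1_error, x$loglik, x$n_iter,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Select Pol II-occupied genes by the mixture cutoff
#'
#' The per-gene occupancy statistic is the mean TSS density across control
#' replicates, log10-transformed (genes with non-positive mean density are
#' dropped and logged). Genes strictly above the cutoff of the fitted (or
#' supplied) mixture are retained.
#'
#' @param counts long count table (from [quantify_samples()] or
#'   [simulate_counts_table()]) with columns gene_id, condition, tss_density.
#' @param control_condition label of the control condition.
#' @param type1_error tolerated type-I error for the cutoff.
#' @param fit optional pre-computed `tss_mixture`; fitted from the data when
#'   NULL.
#' @return object of class `occupancy_selection`: list with `genes` (retained
#'   gene ids), `fit`, and `report` (n_input, n_positive, n_retained, cutoff).
#' @export
select_occupied_genes <- function(counts, control_condition = "control",
                                  type1_error = 0.1, fit = NULL) {
  if (!all(c("gene_id", "condition", "tss_density") %in% names(counts)))
    stop("counts must have columns gene_id, condition, tss_density")
  ctrl <- counts[counts$condition == control_condition, ]
  if (nrow(ctrl) == 0)
    stop("no rows for control condition '", control_condition, "'")
  stat <- tapply(ctrl$tss_density, ctrl$gene_id, mean)
  pos <- stat > 0 & is.finite(stat)
  if (sum(pos) < 50)
    stop("fewer than 50 genes with positive TSS density; cannot select")
  logstat <- log10(stat[pos])
  if (is.null(fit)) fit <- fit_tss_mixture(logstat, type1_error)
  retained <- names(logstat)[logstat > fit$cutoff]
  out <- list(genes = retained, fit = fit,
              report = list(n_input = length(stat),
                            n_positive = sum(pos),
                            n_retained = length(retained),
                            cutoff = fit$cutoff))
  class(out) <- "occupancy_selection"
  out
}

#' @export
print.occupancy_selection <- function(x, ...) {
  r <- x$report
  cat(sprintf(
    "Occupancy selection: %d / %d genes retained (%d with positive density; cutoff %.4f)\n",
    r$n_retained, r$n_input, r$n_positive, r$cutoff))
  invisible(x)
}
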