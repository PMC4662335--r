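## Convergence diagnostics and posterior summaries.

#' Gelman-Rubin potential scale reduction factor
#'
#' The classic between/within-chain variance ratio: with m chains of length
#' n, `W` the mean within-chain variance and `B/n` the variance of the chain
#' means, the statistic is `sqrt(((n-1)/n * W + B/n) / W)`.  Values near 1
#' indicate the chains have mixed; values well above 1 indicate
#' non-convergence.
#'
#' @param x an `occ_fit`, a list of equal-length numeric vectors (one chain
#'   each), or a list of equal-dimension draw matrices.
#' @return named numeric vector of R-hat values (one per parameter).
#' @export
gelman_rubin <- function(x) {
  if (inherits(x, "occ_fit")) x <- x$draws
  stopifnot(is.list(x))
  if (length(x) < 2) stop("Gelman-Rubin diagnostic needs at least 2 chains")
  if (is.null(dim(x[[1]]))) x <- lapply(x, function(v) matrix(v, ncol = 1))
  dims <- vapply(x, dim, c(0L, 0L))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("chains must have identical dimensions")
  n <- nrow(x[[1]])
  rhat <- vapply(seq_len(ncol(x[[1]])), function(j) {
    ch <- vapply(x, function(m) m[, j], numeric(n))
    W <- mean(apply(ch, 2, var))
    B_over_n <- var(colMeans(ch))
    if (W == 0) return(if (B_over_n == 0) 1 else Inf)
    sqrt(((n - 1) / n * W + B_over_n) / W)
  }, 0)
  names(rhat) <- colnames(x[[1]])
  rhat
}

## effective sample size by Geyer's initial positive sequence, per chain,
## summed over chains (reported as an extra diagnostic, no pass/fail rule)
ess_chain <- function(v) {
  n <- length(v)
  if (n < 5 || var(v) == 0) return(n)
  lag_max <- min(n - 1, 2000)
  ac <- stats::acf(v, lag.max = lag_max, plot = FALSE)$acf[, 1, 1]
  s <- 0
  for (k in seq(2, lag_max, by = 2)) {
    pair <- ac[k] + ac[k + 1]
    if (is.na(pair) || pair < 0) break
    s <- s + pair
  }
  n / max(1, 1 + 2 * s)
}

effective_size <- function(fit) {
  cols <- colnames(fit$draws[[1]])
  out <- vapply(seq_along(cols), function(j)
    sum(vapply(fit$draws, function(m) ess_chain(m[, j]), 0)), 0)
  setNames(out, cols)
}

#' Posterior summaries for a fitted model
#'
#' Mean, SD, the 2.5/25/50/75/97.5 percent quantiles, the Gelman-Rubin
#' R-hat, the posterior probability of being positive, and an effective
#' sample size for each parameter.  Parameters with R-hat above 1.1 trigger
#' a convergence warning.
#'
#' @param fit an `occ_fit`.
#' @param params optional character vector of parameter names to keep.
#' @param warn_rhat R-hat threshold for the convergence warning.
#' @return data.frame with one row per parameter.
#' @export
fit_summary <- function(fit, params = NULL, warn_rhat = 1.1) {
  stopifnot(inherits(fit, "occ_fit"))
  cols <- colnames(fit$draws[[1]])
  if (!is.null(params)) {
    bad <- setdiff(params, cols)
    if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  }
  rhat <- if (length(fit$draws) >= 2) gelman_rubin(fit) else
    setNames(rep(NA_real_, length(cols)), cols)
  ess <- effective_size(fit)
  m <- pool_draws(fit)
  qs <- t(apply(m, 2, quantile, probs = c(0.025, 0.25, 0.5, 0.75, 0.975)))
  out <- data.frame(parameter = cols, mean = colMeans(m),
                    sd = apply(m, 2, sd),
                    q2.5 = qs[, 1], q25 = qs[, 2], q50 = qs[, 3],
                    q75 = qs[, 4], q97.5 = qs[, 5],
                    rhat = unname(rhat), p_gt0 = colMeans(m > 0),
                    ess = unname(ess),
                    stringsAsFactors = FALSE, row.names = NULL)
  if (!is.null(params)) out <- out[match(params, out$parameter), ]
  rownames(out) <- NULL
  high <- out$parameter[!is.na(out$rhat) & out$rhat > warn_rhat]
  if (length(high))
    warning("R-hat above ", warn_rhat, " for: ",
            paste(utils::head(high, 5), collapse = ", "),
            if (length(high) > 5) " ...")
  out
}

#' @export
summary.occ_fit <- function(object, ...) fit_summary(object, ...)
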