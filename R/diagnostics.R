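# Convergence diagnostics for the MCMC output: autocorrelation series,
# the Gelman-Rubin potential scale reduction factor, and a machine-readable
# convergence report (trace and kernel-density series included so plotting
# is an optional thin layer over exported numbers).

#' Sample autocorrelation series
#'
#' Autocorrelation of one chain/slot series at lags 0..`max_lag`, with
#' overall-mean centering and lag-0 normalization. A constant
#' (variance-zero) series is defined to have ACF 1 at lag 0 and 0 elsewhere.
#'
#' @param x Numeric series (one chain, one slot).
#' @param max_lag Largest lag; must be smaller than the series length.
#' @return An `acf_series` data frame with columns `lag`, `acf`.
#' @export
autocorrelation <- function(x, max_lag) {
  n <- length(x)
  if (max_lag >= n) stop("max_lag must be smaller than the series length", call. = FALSE)
  if (stats::var(x) == 0) {
    rho <- c(1, rep(0, max_lag))
  } else {
    rho <- drop(stats::acf(x, lag.max = max_lag, plot = FALSE, demean = TRUE)$acf)
  }
  structure(data.frame(lag = 0:max_lag, acf = rho),
            class = c("acf_series", "data.frame"))
}

as_chain_list <- function(samples) {
  if (inherits(samples, "posterior_samples")) {
    lapply(seq_len(dim(samples$draws)[3]), function(k) {
      m <- samples$draws[, , k, drop = FALSE]
      matrix(m, dim(samples$draws)[1], dim(samples$draws)[2],
             dimnames = list(NULL, samples$slots))
    })
  } else if (is.list(samples)) {
    lapply(samples, as.matrix)
  } else {
    stop("samples must be a posterior_samples object or a list of chain matrices",
         call. = FALSE)
  }
}

#' Gelman-Rubin potential scale reduction factor
#'
#' For each slot, with m chains of n stored draws: W is the mean
#' within-chain variance, B = n * var(chain means) the between-chain
#' variance, and the pooled variance estimate is V = W + B/n, giving
#' R-hat = sqrt(V / W) = sqrt(1 + B/(nW)). R-hat is exactly 1 when the chain
#' means coincide and grows with between-chain disagreement; values below a
#' threshold (conventionally 1.1) for every slot indicate convergence. The
#' diagnostic requires at least two chains.
#'
#' @param samples A `posterior_samples` or list of equal-size chain matrices.
#' @param threshold Pass threshold on R-hat (default 1.1).
#' @return A `psrf_report` data frame with columns `slot`, `W`, `B`,
#'   `v_pooled`, `psrf`; attribute `pass` is TRUE when all R-hat < threshold.
#' @export
gelman_rubin <- function(samples, threshold = 1.1) {
  chains <- as_chain_list(samples)
  m <- length(chains)
  if (m < 2) {
    stop("the Gelman-Rubin diagnostic requires at least two chains", call. = FALSE)
  }
  n <- unique(vapply(chains, nrow, 1L))
  if (length(n) != 1) stop("chains must have equal stored lengths", call. = FALSE)
  if (n < 2) stop("chains must contain at least two stored draws", call. = FALSE)
  slots <- colnames(chains[[1]])
  if (is.null(slots)) slots <- paste0("b", seq_len(ncol(chains[[1]])) - 1L)
  psrf_one <- function(j) {
    series <- vapply(chains, function(ch) ch[, j], numeric(n))
    W <- mean(apply(series, 2, stats::var))
    B <- n * stats::var(colMeans(series))
    if (W == 0) {
      r <- if (B == 0) 1 else Inf
      return(c(W = W, B = B, v_pooled = W + B / n, psrf = r))
    }
    V <- W + B / n
    c(W = W, B = B, v_pooled = V, psrf = sqrt(V / W))
  }
  vals <- t(vapply(seq_along(slots), psrf_one, numeric(4)))
  res <- data.frame(slot = slots, vals, row.names = NULL)
  attr(res, "threshold") <- threshold
  attr(res, "pass") <- all(res$psrf < threshold)
  class(res) <- c("psrf_report", "data.frame")
  res
}

#' Machine-readable convergence report
#'
#' Bundles the diagnostics used to judge chain convergence: per-slot
#' Gelman-Rubin R-hat, the lag-1 autocorrelation of the stored (thinned)
#' draws (averaged across chains, which reduces the estimator noise of the
#' short per-chain series), the trace series, and a Gaussian kernel
#' density of the pooled draws per slot (Silverman's rule bandwidth). The
#' report passes when every R-hat is below `threshold`.
#'
#' @param samples A `posterior_samples`.
#' @param threshold R-hat pass threshold (default 1.1).
#' @param max_lag Largest lag of the exported ACF series (default 20, in
#'   units of stored — i.e. thinned — draws).
#' @return A `convergence_report` list: `psrf`, `acf_lag1` (named per slot),
#'   `acf` (per-slot `acf_series` of chain 1), `density` (per-slot data
#'   frames with `x`, `y`), `trace` (the draws array), `pass`.
#' @export
convergence_report <- function(samples, threshold = 1.1, max_lag = 20) {
  chains <- as_chain_list(samples)
  psrf <- gelman_rubin(samples, threshold = threshold)
  slots <- psrf$slot
  max_lag <- min(max_lag, nrow(chains[[1]]) - 1)
  acf_lag1 <- vapply(seq_along(slots), function(j) {
    mean(vapply(chains, function(ch) autocorrelation(ch[, j], 1)$acf[2], 1))
  }, 1)
  names(acf_lag1) <- slots
  acf_series <- lapply(seq_along(slots), function(j) {
    autocorrelation(chains[[1]][, j], max_lag)
  })
  names(acf_series) <- slots
  pooled <- do.call(rbind, chains)
  density_series <- lapply(seq_along(slots), function(j) {
    x <- pooled[, j]
    if (stats::var(x) == 0) return(data.frame(x = x[1], y = Inf))
    d <- stats::density(x, bw = "nrd0")
    data.frame(x = d$x, y = d$y)
  })
  names(density_series) <- slots
  structure(list(psrf = psrf, acf_lag1 = acf_lag1, acf = acf_series,
                 density = density_series,
                 trace = if (inherits(samples, "posterior_samples")) samples$draws else chains,
                 threshold = threshold, pass = attr(psrf, "pass")),
            class = "convergence_report")
}

#' @export
print.psrf_report <- function(x, ...) {
  cat(sprintf("Gelman-Rubin diagnostic (threshold %.2f): %s\n",
              attr(x, "threshold"), if (attr(x, "pass")) "PASS" else "FAIL"))
  print.data.frame(format.data.frame(x, digits = 5), row.names = FALSE)
  invisible(x)
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf("convergence report: %s (R-hat threshold %.2f)\n",
              if (x$pass) "PASS" else "FAIL", x$threshold))
  tab <- data.frame(slot = x$psrf$slot, psrf = x$psrf$psrf,
                    acf_lag1 = unname(x$acf_lag1))
  print(format(tab, digits = 4), row.names = FALSE)
  invisible(x)
}
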