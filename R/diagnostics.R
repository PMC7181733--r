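## Convergence diagnostics: split R-hat and effective sample size, computed
## from post-warmup draws (Gelman et al., Bayesian Data Analysis, 3rd ed.).

# sequences: iterations x sequences matrix (post-warmup, chains split in half)
split_sequences <- function(x, param) {
  keep <- (x$warmup + 1L):x$n_iter
  half <- length(keep) %/% 2L
  seqs <- lapply(seq_len(x$n_chains), function(ch) {
    d <- x$draws[ch, keep, param]
    list(d[seq_len(half)], d[(length(d) - half + 1L):length(d)])
  })
  matrix(unlist(seqs), nrow = half)
}

rhat_split <- function(seqs) {
  n <- nrow(seqs)
  m <- ncol(seqs)
  mu <- colMeans(seqs)
  s2 <- apply(seqs, 2, stats::var)
  W <- mean(s2)
  B <- n * stats::var(mu)
  var_plus <- (n - 1) / n * W + B / n
  if (W <= 0) return(1)
  sqrt(var_plus / W)
}

ess_autocorr <- function(seqs) {
  n <- nrow(seqs)
  m <- ncol(seqs)
  mu <- colMeans(seqs)
  s2 <- apply(seqs, 2, stats::var)
  W <- mean(s2)
  B <- n * stats::var(mu)
  var_plus <- (n - 1) / n * W + B / n
  if (var_plus <= 0) return(n * m)
  # mean within-sequence autocovariance at each lag
  acov <- sapply(seq_len(m), function(j) {
    v <- seqs[, j] - mu[j]
    stats::convolve(v, rev(v), type = "open")[n:(2 * n - 1)] / n
  })
  rho <- 1 - (W - rowMeans(acov)) / var_plus # rho[1] is lag 0 (=~1)
  # Geyer initial monotone positive sequence over lag pairs
  tau <- 0
  last <- Inf
  t <- 2L
  while (t + 1L <= n) {
    pair <- rho[t] + rho[t + 1L]
    if (pair < 0) break
    pair <- min(pair, last)
    last <- pair
    tau <- tau + pair
    t <- t + 2L
  }
  ess <- m * n / (1 + 2 * tau)
  min(ess, m * n)
}

#' Convergence diagnostics for posterior samples
#'
#' Computes split R-hat (chains halved, between/within variance ratio) and
#' autocorrelation-based effective sample size per parameter from the
#' post-warmup draws. The run passes when every R-hat is within `tol` of 1.
#'
#' @param samples a `posterior_samples` object with at least 2 chains.
#' @param tol R-hat tolerance for the pass flag (default 0.01).
#' @return object of class `"convergence_report"`: data frame of `parameter`,
#'   `rhat`, `ess`, with attribute `pass`.
#' @export
diagnostics <- function(samples, tol = 0.01) {
  if (samples$n_chains < 2) stop("diagnostics require >= 2 chains", call. = FALSE)
  stats_df <- do.call(rbind, lapply(samples$parameters, function(p) {
    seqs <- split_sequences(samples, p)
    data.frame(parameter = p, rhat = rhat_split(seqs), ess = ess_autocorr(seqs))
  }))
  rownames(stats_df) <- NULL
  structure(stats_df,
    pass = all(abs(stats_df$rhat - 1) <= tol), tol = tol,
    class = c("convergence_report", "data.frame")
  )
}

#' @export
print.convergence_report <- function(x, ...) {
  cat(sprintf(
    "Convergence: %s (all |R-hat - 1| <= %.2g: max R-hat %.4f, min ESS %.0f)\n",
    if (attr(x, "pass")) "PASS" else "FAIL", attr(x, "tol"),
    max(x$rhat), min(x$ess)
  ))
  invisible(x)
}
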