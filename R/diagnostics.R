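#' Rank-normalized split R-hat
#'
#' Potential-scale-reduction diagnostic computed on rank-normalized,
#' split-in-half chains: draws of each chain are split into halves, all draws
#' are replaced by normal scores of their pooled ranks, and the classic
#' between/within variance ratio is computed on the resulting chains. Values
#' near 1 indicate convergence; the package flags parameters at or above
#' 1.02, the threshold used when assessing the study fits.
#'
#' @param samples A `cjs_posterior` (needs at least 2 chains with at least 10
#'   retained draws each), or a numeric matrix with one column per chain for
#'   a single parameter.
#' @param threshold Flagging threshold for the convergence report.
#' @return For a `cjs_posterior`: named numeric vector of R-hat values, with
#'   attribute `flagged` naming parameters at or above `threshold`. For a
#'   matrix: a single R-hat value.
#' @export
gelman_rubin <- function(samples, threshold = 1.02) {
  if (is.matrix(samples)) return(.rhat_rank(samples))
  stopifnot(inherits(samples, "cjs_posterior"))
  d <- samples$draws
  chains <- unique(d$chain)
  if (length(chains) < 2L)
    stop("R-hat needs at least two chains", call. = FALSE)
  per <- table(d$chain)
  if (any(per < 10L))
    stop("R-hat needs at least 10 retained draws per chain", call. = FALSE)
  pars <- setdiff(names(d), c("chain", "iteration"))
  rh <- vapply(pars, function(pn) {
    m <- vapply(chains, function(ch) d[[pn]][d$chain == ch], numeric(min(per)))
    .rhat_rank(m)
  }, numeric(1))
  attr(rh, "flagged") <- names(rh)[!is.na(rh) & rh >= threshold]
  rh
}

# split chains in half, rank-normalize jointly, classic Rhat on the result
.rhat_rank <- function(mat) {
  niter <- nrow(mat)
  if (niter < 4L) return(NA_real_)
  half <- niter %/% 2L
  split_mat <- cbind(mat[seq_len(half), , drop = FALSE],
                     mat[(niter - half + 1L):niter, , drop = FALSE])
  if (all(split_mat == split_mat[1])) return(1)  # constant parameter
  r <- rank(split_mat, ties.method = "average")
  z <- qnorm((r - 3 / 8) / (length(r) + 1 / 4))
  zmat <- matrix(z, nrow = half)
  nc <- ncol(zmat)
  means <- colMeans(zmat)
  vars <- apply(zmat, 2L, var)
  W <- mean(vars)
  B <- half * var(means)
  if (W <= 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' Convergence report
#'
#' @param samples A `cjs_posterior`.
#' @param threshold R-hat flagging threshold.
#' @return Data frame with columns `parameter`, `rhat`, `converged`.
#' @export
convergence_report <- function(samples, threshold = 1.02) {
  rh <- gelman_rubin(samples, threshold)
  data.frame(parameter = names(rh), rhat = as.numeric(rh),
             converged = as.numeric(rh) < threshold,
             row.names = NULL, stringsAsFactors = FALSE)
}
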