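# Karlin-Altschul statistics for ungapped local alignment scores under
# match/mismatch scoring. lambda solves E[exp(lambda * S)] = 1 for the
# per-column score S; K comes from the renewal-theoretic series
#   sigma = sum_k (1/k) [ P(S_k >= 0) + E(exp(lambda S_k); S_k < 0) ]
#   K = lambda * delta * exp(-2 sigma) / (H * (1 - exp(-lambda * delta)))
# with delta the lattice span of the step scores. For +1/-2 and +1/-3 at
# uniform base composition this reproduces the published ungapped DNA
# constants (lambda 1.33 / K 0.62 and lambda 1.37 / K 0.71).

.karlin_cache <- new.env(parent = emptyenv())

#' Karlin-Altschul parameters for match/mismatch scoring
#'
#' @param match,mismatch integer scores (defaults +1/-3, the scheme used
#'   for duplicate detection and marker alignment).
#' @param p_match probability that two random letters match (0.25 for
#'   uniform base composition).
#' @param kmax truncation of the renewal series.
#' @return List with `lambda`, `K`, `H`.
#' @export
karlin_parameters <- function(match = 1, mismatch = -3, p_match = 0.25,
                              kmax = 60) {
  key <- paste(match, mismatch, signif(p_match, 10), kmax, sep = "_")
  if (!is.null(.karlin_cache[[key]])) return(.karlin_cache[[key]])
  stopifnot(match > 0, mismatch < 0, p_match > 0, p_match < 1)
  f <- function(l) p_match * exp(l * match) + (1 - p_match) *
    exp(l * mismatch) - 1
  lambda <- uniroot(f, c(1e-8, 50), tol = 1e-12)$root
  H <- lambda * (p_match * match * exp(lambda * match) +
                 (1 - p_match) * mismatch * exp(lambda * mismatch))
  gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)
  delta <- gcd2(abs(match), abs(mismatch))
  d <- c("0" = 1)
  sigma <- 0
  for (k in seq_len(kmax)) {
    dn <- as.numeric(names(d))
    nv <- c(dn + match, dn + mismatch)
    np <- c(d * p_match, d * (1 - p_match))
    d <- tapply(np, nv, sum)
    s <- as.numeric(names(d))
    sigma <- sigma + (sum(d[s >= 0]) +
                      sum((d * exp(lambda * s))[s < 0])) / k
  }
  K <- lambda * delta * exp(-2 * sigma) / (H * (1 - exp(-lambda * delta)))
  out <- list(lambda = lambda, K = K, H = H)
  .karlin_cache[[key]] <- out
  out
}

#' E-value of an ungapped local alignment score
#'
#' `E = K m n exp(-lambda S)`. Values at the 1e-300 scale underflow double
#' precision, so comparisons should use `log10_evalue`.
#'
#' @param score alignment score.
#' @param m,n lengths of the two sequences searched (search space `m * n`).
#' @param params from [karlin_parameters()].
#' @export
log10_evalue <- function(score, m, n, params = karlin_parameters()) {
  (log(params$K) + log(m) + log(n) - params$lambda * score) / log(10)
}

#' @rdname log10_evalue
#' @export
evalue <- function(score, m, n, params = karlin_parameters()) {
  10^log10_evalue(score, m, n, params)
}
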