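# Negative binomial depth model and the per-allele genotype likelihood.
#
# Read depth at a site is modelled as NB(n, r) with
#   n = d^2 / (sigma^2 - d),   r = (sigma^2 - d) / sigma^2,
# pinned to the parameterisation P(k) = C(k+n-1, k) (1-r)^n r^k, the unique
# one under which the distribution has mean d and variance sigma^2.

#' Fit the genome-wide depth model
#'
#' `d` is the mean and `sigma^2` the variance of the per-site total
#' coverage.  The negative binomial requires overdispersion; when the
#' observed variance does not exceed the mean (seen only with unrealistic,
#' very even simulated depth), the variance is set to double the mean.
#'
#' @param site_depths numeric vector of per-site total coverage `c`, or a
#'   `coverage_data` object.
#' @return object of class `depth_model` with fields `d`, `var`, `n`, `r`,
#'   `p0` (probability of zero depth at a position) and `p = 1 - p0`.
#' @export
fit_depth_model <- function(site_depths) {
  if (inherits(site_depths, "coverage_data")) {
    site_depths <- vapply(site_depths$site_cov,
                          function(s) sum(s$gamma), numeric(1))
  }
  if (!length(site_depths)) stop("no sites with coverage to fit depth model")
  d <- mean(site_depths)
  if (d <= 0) stop("mean site depth is zero; cannot fit depth model")
  v <- if (length(site_depths) > 1) stats::var(site_depths) else 0
  fallback <- v <= d
  if (fallback) v <- 2 * d
  n <- d^2 / (v - d)
  r <- (v - d) / v
  p0 <- (1 - r)^n
  structure(list(d = d, var = v, n = n, r = r, p0 = p0, p = 1 - p0,
                 var_fallback = fallback),
            class = "depth_model")
}

#' @export
print.depth_model <- function(x, ...) {
  cat(sprintf(
    "depth_model: d=%.3f var=%.3f (NB n=%.3f r=%.4f)%s\n", x$d, x$var,
    x$n, x$r, if (x$var_fallback) " [variance fallback 2d]" else ""))
  invisible(x)
}

#' Negative binomial depth pmf
#'
#' @param model a `depth_model`.
#' @param k non-negative integer depth(s).
#' @param log return log probabilities.
#' @return P(depth = k) under NB(n, r) with mean `d`, variance `var`.
#' @export
nb_pmf <- function(model, k, log = FALSE) {
  stats::dnbinom(k, size = model$n, prob = 1 - model$r, log = log)
}

#' Log-likelihood of one allele at one site
#'
#' Sums the natural logs of three terms: the probability of the allele's
#' coverage under the depth model, an error term `epsilon^(c - c_a)` for
#' the reads on other alleles, and a gap penalty
#' `p^(b/l) * (1-p)^((l-b)/l)` where `p` is the probability that a
#' position has non-zero depth, `l` the allele length and `b` the number
#' of allele positions with non-zero coverage.
#'
#' @param c_a coverage of the allele.
#' @param c total site coverage (`c_a <= c`).
#' @param b number of allele positions with non-zero depth.
#' @param ell allele length (> 0).
#' @param model a `depth_model`.
#' @param epsilon per-read-base error rate (default 0.002).
#' @return log-likelihood (natural log).
#' @export
allele_log_likelihood <- function(c_a, c, b, ell, model, epsilon = 0.002) {
  if (c_a > c) stop("allele coverage exceeds site coverage (c_a > c)")
  if (ell <= 0) stop("allele length must be positive")
  if (b < 0 || b > ell) stop("covered positions b must lie in [0, ell]")
  ll <- nb_pmf(model, c_a, log = TRUE)
  if (c > c_a) ll <- ll + (c - c_a) * log(epsilon)
  fb <- b / ell
  if (fb > 0) ll <- ll + fb * log(model$p)
  if (fb < 1) ll <- ll + (1 - fb) * log1p(-model$p)
  ll
}

#' Genotype one site
#'
#' Evaluates the log-likelihood of every allele and calls the allele with
#' the greatest value (haploid call; ties broken by lowest allele index,
#' i.e. reference first).  The genotype confidence GT_CONF is the
#' difference between the best and second-best log-likelihoods.  A site
#' with zero coverage gets a null call.
#'
#' @param summary one site's coverage summary (element of
#'   [coverage_summary()]: fields `c`, `c_a`, `b`, `ell`).
#' @param model a `depth_model`.
#' @param epsilon read error rate.
#' @return list with `allele` (1-based index, 1 = reference; NA for a null
#'   call), `log_lik` (per-allele vector), `gt_conf` (>= 0), `dp` (total
#'   coverage) and `frs` (fraction of reads supporting the call).
#' @export
genotype_site <- function(summary, model, epsilon = 0.002) {
  n_alleles <- length(summary$ell)
  stopifnot(n_alleles >= 2)
  if (summary$c == 0) {
    return(list(allele = NA_integer_,
                log_lik = rep(NA_real_, n_alleles), gt_conf = 0,
                dp = 0, frs = NA_real_))
  }
  ll <- vapply(seq_len(n_alleles), function(a) {
    allele_log_likelihood(summary$c_a[[a]], summary$c, summary$b[[a]],
                          summary$ell[[a]], model, epsilon)
  }, numeric(1))
  best <- which.max(ll)           # which.max takes the first maximum
  second <- max(ll[-best])
  list(allele = best, log_lik = ll, gt_conf = ll[[best]] - second,
       dp = summary$c, frs = summary$c_a[[best]] / summary$c)
}
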