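# The four FILTER criteria: MIN_DP, MAX_DP, MIN_FRS and MIN_GCP, the last
# against a simulated genotype-confidence null matched to the run's depth
# model.

#' Filter configuration
#'
#' @param min_dp minimum site depth (default 2).
#' @param max_dp_sd depth ceiling in standard deviations above the mean
#'   (default 3).
#' @param min_frs minimum fraction of reads supporting the called allele
#'   (default 0.9).
#' @param gcp_percentile confidence-null percentile below which calls fail
#'   (default 0.5, i.e. the first 0.5%).
#' @param gcp_sims number of SNPs simulated for the null (default 10000).
#' @param epsilon read error rate (default 0.002).
#' @param seed RNG seed for the null simulation.
#' @return list of class `filter_config`.
#' @export
filter_config <- function(min_dp = 2L, max_dp_sd = 3, min_frs = 0.9,
                          gcp_percentile = 0.5, gcp_sims = 10000L,
                          epsilon = 0.002, seed = 42L) {
  stopifnot(min_frs > 0, min_frs <= 1,
            gcp_percentile > 0, gcp_percentile < 100, gcp_sims >= 1)
  structure(list(min_dp = min_dp, max_dp_sd = max_dp_sd, min_frs = min_frs,
                 gcp_percentile = gcp_percentile, gcp_sims = gcp_sims,
                 epsilon = epsilon, seed = seed),
            class = "filter_config")
}

#' Simulate the genotype-confidence null distribution
#'
#' Genotype confidence depends on read depth, so raw confidences are not
#' comparable between runs.  To normalise, biallelic SNPs are simulated:
#' the correct allele's depth is drawn from the fitted negative binomial
#' (the same distribution the genotyping model uses) and the wrong
#' allele's depth from a binomial with size equal to the drawn depth and
#' probability equal to the read error rate.  Each simulated site is
#' genotyped with the same model as real calls (SNP semantics: allele
#' length 1, covered iff depth > 0), and the sorted confidences form the
#' null.  The threshold is the order statistic at the configured
#' percentile.
#'
#' @param model a `depth_model`.
#' @param config a [filter_config()].
#' @return object of class `confidence_null` with sorted `values` and the
#'   `threshold`.
#' @export
simulate_confidence_null <- function(model, config = filter_config()) {
  n_sim <- config$gcp_sims
  confs <- withr_seed(config$seed, {
    dc <- stats::rnbinom(n_sim, size = model$n, prob = 1 - model$r)
    dw <- stats::rbinom(n_sim, size = dc, prob = config$epsilon)
    simulated_snp_conf(dc, dw, model, config$epsilon)
  })
  values <- sort(confs)
  idx <- max(1L, floor(config$gcp_percentile / 100 * n_sim))
  structure(list(values = values, threshold = values[[idx]],
                 percentile = config$gcp_percentile),
            class = "confidence_null")
}

# GT_CONF of simulated biallelic SNPs with correct/wrong depths dc, dw
# (vectorised); same likelihood as genotype_site with ell = 1.
simulated_snp_conf <- function(dc, dw, model, epsilon) {
  c_tot <- dc + dw
  ll_one <- function(ca, b) {
    ll <- stats::dnbinom(ca, size = model$n, prob = 1 - model$r,
                         log = TRUE) +
      (c_tot - ca) * log(epsilon) * as.numeric(c_tot > ca)
    ll + ifelse(b > 0, log(model$p), log1p(-model$p))
  }
  l_correct <- ll_one(dc, as.integer(dc > 0))
  l_wrong <- ll_one(dw, as.integer(dw > 0))
  conf <- abs(l_correct - l_wrong)
  conf[c_tot == 0] <- 0   # null calls carry zero confidence
  conf
}

# run code with a temporary RNG seed, restoring the caller's RNG state
withr_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  code
}

#' @export
print.confidence_null <- function(x, ...) {
  cat(sprintf("confidence_null: %d simulated SNPs, %.4g%% threshold = %.4f\n",
              length(x$values), x$percentile, x$threshold))
  invisible(x)
}

#' Apply the four call filters
#'
#' * `MIN_DP` fails when total depth `c < min_dp`.
#' * `MAX_DP` fails when `c > d + max_dp_sd * sqrt(var)`.
#' * `MIN_FRS` fails when `c_a / c < min_frs` (undefined at `c = 0`,
#'   which fails by convention).
#' * `MIN_GCP` fails when `gt_conf` is below the simulated-null threshold.
#'
#' Null genotype calls fail all four filters.
#'
#' @param call result of [genotype_site()].
#' @param model a `depth_model`.
#' @param null a `confidence_null`.
#' @param config a [filter_config()].
#' @return character vector of failed filter names (empty = PASS).
#' @export
apply_filters <- function(call, model, null, config = filter_config()) {
  if (is.na(call$allele)) {
    return(c("MIN_DP", "MAX_DP", "MIN_FRS", "MIN_GCP"))
  }
  fails <- character()
  if (call$dp < config$min_dp) fails <- c(fails, "MIN_DP")
  if (call$dp > model$d + config$max_dp_sd * sqrt(model$var)) {
    fails <- c(fails, "MAX_DP")
  }
  if (is.na(call$frs) || call$frs < config$min_frs) {
    fails <- c(fails, "MIN_FRS")
  }
  if (call$gt_conf < null$threshold) fails <- c(fails, "MIN_GCP")
  fails
}
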