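# Single-sample adjudication pipeline: merge -> cluster -> graph -> map ->
# genotype -> filter.

#' Genotype every site of a graph from mapped coverage
#'
#' @param graph a `genome_graph`.
#' @param cov a `coverage_data` from [quasimap()].
#' @param model a `depth_model`; fitted from `cov` when NULL.
#' @param config a [filter_config()].
#' @param null a `confidence_null`; simulated from `model` when NULL.
#' @return calls data.frame: one row per site with the called allele index
#'   (1 = reference, NA = null call), per-allele coverage, DP, FRS,
#'   GT_CONF and the failed-filter string (`""` = PASS).
#' @export
genotype_calls <- function(graph, cov, model = NULL,
                           config = filter_config(), null = NULL) {
  summ <- coverage_summary(cov)
  if (is.null(model)) model <- fit_depth_model(cov)
  if (is.null(null)) null <- simulate_confidence_null(model, config)
  sites <- graph$sites
  rows <- lapply(seq_len(nrow(sites)), function(i) {
    call <- genotype_site(summ[[i]], model, config$epsilon)
    fails <- apply_filters(call, model, null, config)
    data.frame(chrom = sites$chrom[i], start = sites$start[i],
               end = sites$end[i], ref_allele = sites$ref_allele[i],
               alts = I(list(sites$alts[[i]])),
               allele = call$allele,
               cov = I(list(summ[[i]]$c_a)),
               dp = call$dp, frs = call$frs, gt_conf = call$gt_conf,
               filters = paste(fails, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  calls <- do.call(rbind, rows)
  attr(calls, "model") <- model
  attr(calls, "null") <- null
  calls
}

#' Adjudicate candidate callsets for one sample
#'
#' Runs the full single-sample pipeline: load and normalise each input
#' VCF, merge and deduplicate, exclude long deletions, cluster overlapping
#' variants into multi-allelic sites, build the bubble graph, map the
#' sample's reads by exact matching, fit the depth model and genotype
#' every site, then apply the four filters.
#'
#' @param vcf_paths character vector of candidate VCF files.
#' @param reference FASTA path or named character vector.
#' @param reads reads file (FASTQ/FASTA/BAM) or character vector of read
#'   sequences.
#' @param config a [filter_config()].
#' @param max_del_len,max_alleles,dedup_window clustering knobs.
#' @param require_gt,respect_filter passed to [load_calls()].
#' @return list of class `adjudication`: `calls` (see [genotype_calls()]),
#'   `sites`, `graph`, `merged` (the merged variant set), `model`, and
#'   `counts`, a one-row data.frame of run statistics (unique variants,
#'   excluded variants, sites after clustering, genome inside sites, total
#'   alleles, SNP sites).
#' @export
adjudicate <- function(vcf_paths, reference, reads,
                       config = filter_config(), max_del_len = 50L,
                       max_alleles = 500L, dedup_window = 7L,
                       require_gt = FALSE, respect_filter = FALSE) {
  if (is.character(reference) && length(reference) == 1 &&
      file.exists(reference)) {
    reference <- read_reference(reference)
  }
  callsets <- lapply(vcf_paths, load_calls, reference = reference,
                     require_gt = require_gt,
                     respect_filter = respect_filter)
  merged <- merge_and_deduplicate(callsets)
  sites <- cluster_variants(merged, reference, max_del_len = max_del_len,
                            max_alleles = max_alleles,
                            dedup_window = dedup_window)
  graph <- build_graph(reference, sites)
  cov <- quasimap(reads, graph)
  calls <- genotype_calls(graph, cov, config = config)
  counts <- data.frame(
    unique_variants = nrow(merged),
    excluded_variants = attr(sites, "n_excluded"),
    sites_after_clustering = nrow(sites),
    genome_inside_sites = if (nrow(sites)) sum(nchar(sites$ref_allele)) else 0L,
    total_alleles = if (nrow(sites)) sum(site_allele_count(sites)) else 0L,
    snp_sites = if (nrow(sites)) {
      sum(vapply(seq_len(nrow(sites)), function(i) {
        all(nchar(c(sites$ref_allele[i], sites$alts[[i]])) == 1L)
      }, logical(1)))
    } else 0L)
  structure(list(calls = calls, sites = sites, graph = graph,
                 merged = merged, model = attr(calls, "model"),
                 counts = counts),
            class = "adjudication")
}

#' @export
print.adjudication <- function(x, ...) {
  cat("adjudication of", x$counts$unique_variants, "unique variants at",
      x$counts$sites_after_clustering, "sites\n")
  nonref <- sum(!is.na(x$calls$allele) & x$calls$allele > 1L &
                x$calls$filters == "")
  cat("  PASS non-reference calls:", nonref, "\n")
  invisible(x)
}

#' Extract the final (non-reference, optionally PASS-only) callset
#'
#' @param adj an `adjudication` object or calls data.frame.
#' @param pass_only keep only calls with no failed filter.
#' @return normalised-variant-style data.frame of the called alternate
#'   alleles (`chrom`, `pos`, `ref`, `alt`), suitable for evaluation or
#'   for [apply_calls_to_genome()].
#' @export
final_calls <- function(adj, pass_only = TRUE) {
  calls <- if (inherits(adj, "adjudication")) adj$calls else adj
  keep <- !is.na(calls$allele) & calls$allele > 1L
  if (pass_only) keep <- keep & calls$filters == ""
  rows <- which(keep)
  data.frame(chrom = calls$chrom[rows], pos = calls$start[rows],
             ref = calls$ref_allele[rows],
             alt = vapply(rows, function(i) {
               calls$alts[[i]][[calls$allele[i] - 1L]]
             }, character(1)),
             stringsAsFactors = FALSE)
}
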