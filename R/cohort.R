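# Joint genotyping of cohorts: one shared site list built from the union
# of all samples' callsets, every sample genotyped at every site, a
# multi-sample VCF and a genotype distance matrix.

#' Read a cohort manifest
#'
#' Tab-separated with header `name  vcf  reads`: one row per sample with
#' its candidate-call VCF and its reads file.
#'
#' @param path manifest TSV.
#' @return data.frame with columns `name`, `vcf`, `reads`.
#' @export
read_manifest <- function(path) {
  m <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("name", "vcf", "reads") %in% names(m)))
  if (anyDuplicated(m$name)) stop("duplicate sample names in manifest")
  missing <- !file.exists(m$vcf) | !file.exists(m$reads)
  if (any(missing)) {
    stop("manifest paths not found: ",
         paste(c(m$vcf, m$reads)[c(missing, missing)], collapse = ", "))
  }
  m
}

#' Collect and merge the cohort's candidate variants
#'
#' Loads every sample's VCF with the sample name as origin, and merges
#' into one deduplicated set; per-sample asserted variants are retained
#' for the allele-cap fallback during clustering.
#'
#' @param manifest data.frame from [read_manifest()] (or with the same
#'   columns).
#' @param reference named character vector of contig sequences.
#' @return merged normalised variant data.frame with a `sample_calls`
#'   attribute keyed by sample name.
#' @export
collect_cohort_variants <- function(manifest, reference) {
  if (anyDuplicated(manifest$name)) stop("duplicate sample names")
  sets <- lapply(seq_len(nrow(manifest)), function(i) {
    v <- load_calls(manifest$vcf[i], reference,
                    source_id = manifest$name[i])
    # key the asserted-variant list by the manifest sample name: each VCF
    # is one sample's callset regardless of its internal column name
    sc <- attr(v, "sample_calls")
    attr(v, "sample_calls") <-
      setNames(list(unique(unlist(sc))), manifest$name[i])
    v
  })
  merge_and_deduplicate(sets)
}

#' Joint genotype a cohort at a shared site list
#'
#' Builds the shared graph from the union of all samples' variants, then
#' genotypes each sample's reads independently (its own depth model and
#' confidence null), producing per-sample calls at the identical site
#' list, an N x M genotype matrix, and the pairwise genotype distance
#' matrix.  A sample whose reads file fails to load is recorded as failed
#' and skipped; the rest of the cohort is still processed.
#'
#' @param manifest manifest data.frame or TSV path.
#' @param reference named character vector or FASTA path.
#' @param config a [filter_config()].
#' @param max_del_len,max_alleles,dedup_window clustering knobs.
#' @param out_dir if not NULL, per-sample VCFs, the multi-sample VCF and
#'   the distance matrix TSV are written here.
#' @param count_null_as_diff in the distance matrix, count sites where
#'   exactly one sample is null as differences (default: skip them).
#' @return list of class `joint_genotyping`: `sites`, `calls` (named list
#'   of per-sample calls data.frames), `genotype_matrix` (samples x
#'   sites; allele index, NA = null), `distance` (symmetric matrix),
#'   `failed_samples`, `counts`.
#' @export
joint_genotype <- function(manifest, reference, config = filter_config(),
                           max_del_len = 50L, max_alleles = 500L,
                           dedup_window = 7L, out_dir = NULL,
                           count_null_as_diff = FALSE) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  if (is.character(reference) && length(reference) == 1 &&
      file.exists(reference)) {
    reference <- read_reference(reference)
  }
  merged <- collect_cohort_variants(manifest, reference)
  sites <- cluster_variants(merged, reference, max_del_len = max_del_len,
                            max_alleles = max_alleles,
                            dedup_window = dedup_window)
  graph <- build_graph(reference, sites)
  calls <- list()
  failed <- character()
  for (i in seq_len(nrow(manifest))) {
    name <- manifest$name[i]
    reads <- tryCatch(read_reads(manifest$reads[i]), error = function(e) e)
    if (inherits(reads, "error")) {
      warning("sample ", name, " failed: ", conditionMessage(reads))
      failed <- c(failed, name)
      next
    }
    cov <- quasimap(reads, graph)
    calls[[name]] <- genotype_calls(graph, cov, config = config)
  }
  gt <- t(vapply(calls, function(x) x$allele, integer(nrow(sites))))
  if (nrow(sites) == 1) gt <- matrix(gt, ncol = 1,
                                     dimnames = list(names(calls), NULL))
  dist <- distance_matrix(gt, count_null_as_diff = count_null_as_diff)
  counts <- data.frame(
    n_samples = nrow(manifest),
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
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (name in names(calls)) {
      write_calls_vcf(calls[[name]], reference,
                      file.path(out_dir, paste0(name, ".vcf")), name)
    }
    if (length(calls)) {
      write_multisample_vcf(calls, reference,
                            file.path(out_dir, "cohort.vcf"))
    }
    utils::write.table(dist, file.path(out_dir, "distance_matrix.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    utils::write.table(counts, file.path(out_dir, "run_counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  structure(list(sites = sites, calls = calls, genotype_matrix = gt,
                 distance = dist, failed_samples = failed,
                 counts = counts),
            class = "joint_genotyping")
}

#' @export
print.joint_genotyping <- function(x, ...) {
  cat(sprintf("joint_genotyping: %d sample(s) x %d site(s)\n",
              nrow(x$genotype_matrix), ncol(x$genotype_matrix)))
  invisible(x)
}

#' Pairwise genotype distance matrix
#'
#' The distance between two samples is the number of variant sites where
#' their called alleles differ.  Sites where either sample has a null
#' call are skipped unless `count_null_as_diff` (then a null vs non-null
#' pair counts as a difference).
#'
#' @param gt samples x sites matrix of allele indices (NA = null call).
#' @param count_null_as_diff see above.
#' @return symmetric integer matrix with zero diagonal, dimnames from the
#'   row names of `gt`.
#' @export
distance_matrix <- function(gt, count_null_as_diff = FALSE) {
  n <- nrow(gt)
  d <- matrix(0L, n, n, dimnames = list(rownames(gt), rownames(gt)))
  if (n < 2) return(d)
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      a <- gt[i, ]; b <- gt[j, ]
      both <- !is.na(a) & !is.na(b)
      diff <- sum(a[both] != b[both])
      if (count_null_as_diff) diff <- diff + sum(xor(is.na(a), is.na(b)))
      d[i, j] <- d[j, i] <- diff
    }
  }
  d
}
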