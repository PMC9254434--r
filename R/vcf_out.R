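# VCF writers.  Records are emitted 1-based, sorted, with the package's
# FORMAT fields (GT, DP, COV, FRS, GT_CONF).  Input VCF parsing is done by
# vcfR; output records are simple enough to format directly.

vcf_header <- function(reference, extra = character()) {
  c("##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", names(reference),
            nchar(reference)),
    extra)
}

#' Write a merged variant set as a sorted VCF
#'
#' One biallelic record per normalised variant, with an `ORIGINS` INFO tag
#' listing the callsets (and samples) the variant came from.
#'
#' @param variants normalised variant data.frame.
#' @param reference named character vector of contig sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_merged_vcf <- function(variants, reference, path) {
  hdr <- c(vcf_header(reference,
    '##INFO=<ID=ORIGINS,Number=1,Type=String,Description="Source callsets of this variant">'),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  recs <- if (nrow(variants)) {
    sprintf("%s\t%d\t.\t%s\t%s\t.\t.\tORIGINS=%s", variants$chrom,
            variants$pos, variants$ref, variants$alt,
            ifelse(variants$origins == "", ".", variants$origins))
  } else character()
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Write clustered sites as a multi-allelic VCF (the graph definition)
#'
#' @param sites site data.frame.
#' @param reference named character vector of contig sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sites_vcf <- function(sites, reference, path) {
  hdr <- c(vcf_header(reference),
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  recs <- if (nrow(sites)) {
    vapply(seq_len(nrow(sites)), function(i) {
      sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.", sites$chrom[i], sites$start[i],
              sites$ref_allele[i], paste(sites$alts[[i]], collapse = ","))
    }, character(1))
  } else character()
  writeLines(c(hdr, recs), path)
  invisible(path)
}

format_genotype_field <- function(calls, i) {
  gt <- if (is.na(calls$allele[i])) "." else
    as.character(calls$allele[i] - 1L)
  cov <- paste(calls$cov[[i]], collapse = ",")
  frs <- if (is.na(calls$frs[i])) "." else sprintf("%.4g", calls$frs[i])
  sprintf("%s:%d:%s:%s:%.4f", gt, calls$dp[i], cov, frs, calls$gt_conf[i])
}

genotype_format_header <- c(
  '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
  '##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Total read depth at the site">',
  '##FORMAT=<ID=COV,Number=.,Type=Integer,Description="Per-allele read coverage">',
  '##FORMAT=<ID=FRS,Number=1,Type=Float,Description="Fraction of reads supporting the called allele">',
  '##FORMAT=<ID=GT_CONF,Number=1,Type=Float,Description="Genotype confidence (best minus second-best log-likelihood)">',
  '##FILTER=<ID=MIN_DP,Description="Depth below minimum">',
  '##FILTER=<ID=MAX_DP,Description="Depth above mean plus k standard deviations">',
  '##FILTER=<ID=MIN_FRS,Description="Fraction of read support below minimum">',
  '##FILTER=<ID=MIN_GCP,Description="Genotype confidence below simulated-null percentile">')

#' Write per-sample genotype calls as VCF
#'
#' One multi-allelic record per site with GT, DP, COV, FRS and GT_CONF
#' FORMAT fields and the filter result in FILTER.
#'
#' @param calls calls data.frame from [genotype_calls()].
#' @param reference named character vector of contig sequences.
#' @param path output path.
#' @param sample_name genotype column name.
#' @return `path`, invisibly.
#' @export
write_calls_vcf <- function(calls, reference, path, sample_name = "sample") {
  hdr <- c(vcf_header(reference, genotype_format_header),
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                  sample_name))
  recs <- vapply(seq_len(nrow(calls)), function(i) {
    filt <- if (calls$filters[i] == "") "PASS" else
      gsub(";", ";", calls$filters[i], fixed = TRUE)
    sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t.\tGT:DP:COV:FRS:GT_CONF\t%s",
            calls$chrom[i], calls$start[i], calls$ref_allele[i],
            paste(calls$alts[[i]], collapse = ","), filt,
            format_genotype_field(calls, i))
  }, character(1))
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Merge per-sample calls into one multi-sample VCF
#'
#' All samples must have been genotyped at the identical site list; the
#' output has one record per site and one genotype column per sample, in
#' manifest order.
#'
#' @param call_list named list of calls data.frames (one per sample).
#' @param reference named character vector of contig sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_multisample_vcf <- function(call_list, reference, path) {
  stopifnot(length(call_list) >= 1)
  first <- call_list[[1]]
  site_sig <- function(x) paste(x$chrom, x$start, x$ref_allele,
                                vapply(x$alts, paste, character(1),
                                       collapse = ","))
  sig <- site_sig(first)
  for (x in call_list[-1]) {
    if (!identical(site_sig(x), sig)) {
      stop("samples were genotyped at different site lists; cannot merge")
    }
  }
  hdr <- c(vcf_header(reference, genotype_format_header),
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                  paste(names(call_list), collapse = "\t")))
  recs <- vapply(seq_len(nrow(first)), function(i) {
    cols <- vapply(call_list, function(x) {
      filt <- if (x$filters[i] == "") "PASS" else x$filters[i]
      paste0(format_genotype_field(x, i), ":", filt)
    }, character(1))
    sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.\tGT:DP:COV:FRS:GT_CONF:FT\t%s",
            first$chrom[i], first$start[i], first$ref_allele[i],
            paste(first$alts[[i]], collapse = ","),
            paste(cols, collapse = "\t"))
  }, character(1))
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Read a multi-sample VCF back into per-sample genotype calls
#'
#' Round-trip helper for [write_multisample_vcf()]: returns the genotype
#' matrix encoded in the file.
#'
#' @param path VCF path.
#' @return list with `sites` (chrom/pos/ref/alts data.frame) and `gt`
#'   (samples x sites integer matrix of called allele indices, 1 =
#'   reference, NA = null).
#' @export
read_multisample_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  idx <- suppressWarnings(apply(gt, 2, as.integer)) + 1L
  if (is.null(dim(idx))) idx <- matrix(idx, ncol = ncol(gt),
                                       dimnames = dimnames(gt))
  list(sites = data.frame(chrom = fix[, "CHROM"],
                          pos = as.integer(fix[, "POS"]),
                          ref = fix[, "REF"], alt = fix[, "ALT"],
                          stringsAsFactors = FALSE),
       gt = t(idx))
}
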