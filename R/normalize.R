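# VCF ingestion, allele extraction, decomposition into primitive SNPs and
# indels, left-normalisation, and merging into one deduplicated variant set.
#
# A normalised variant set is a data.frame with columns
#   chrom  contig name
#   pos    1-based position of the first REF base
#   ref    reference allele (upper-case ACGTN, non-empty)
#   alt    alternate allele (upper-case ACGTN, non-empty, != ref)
#   origins  semicolon-joined "source:sample" labels
# and is unique and sorted on (chrom, pos, ref, alt).

variant_columns <- c("chrom", "pos", "ref", "alt", "origins")

empty_variants <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), origins = character(),
             stringsAsFactors = FALSE)
}

# key identifying a variant within a merged set
variant_key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = "\r")

is_acgtn <- function(x) grepl("^[ACGTN]+$", x)

#' Load and normalise candidate calls from one VCF
#'
#' Reads a VCF (v4.x, plain or gzip), keeps the relevant alleles of each
#' record, splits multi-allelic records, decomposes complex alleles into
#' primitive SNPs/indels and left-normalises everything against the
#' reference.  For records that carry a genotype (GT) only the called
#' alleles are kept; records without GT contribute all their ALT alleles
#' (set `require_gt = TRUE` to drop such records instead).  Records whose
#' REF does not match the reference sequence, and symbolic/breakend/`*`
#' or non-ACGTN alleles, are dropped with a warning.
#'
#' @param vcf_path path to the VCF file.
#' @param reference named character vector from [read_reference()], or a
#'   FASTA path.
#' @param source_id label recorded as the variant origin; defaults to the
#'   file name.
#' @param require_gt if TRUE, records lacking a GT field are ignored
#'   rather than contributing all alleles.
#' @param respect_filter if TRUE, only records whose FILTER is PASS or "."
#'   are used; by default FILTER is ignored.
#' @param max_ref_len alleles with REF longer than this are not decomposed
#'   (passed through whole).
#' @return normalised variant data.frame (see above), with attribute
#'   `sample_calls`: a named list giving, per sample in the VCF, the keys
#'   of the variants that sample's genotype asserts (used later as the
#'   seen-combination fallback during clustering).
#' @export
load_calls <- function(vcf_path, reference, source_id = basename(vcf_path),
                       require_gt = FALSE, respect_filter = FALSE,
                       max_ref_len = 10000L) {
  if (is.character(reference) && length(reference) == 1 &&
      file.exists(reference)) {
    reference <- read_reference(reference)
  }
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  n_rec <- nrow(fix)
  out <- list()
  n_bad_ref <- 0L
  n_bad_allele <- 0L
  sample_calls <- list()

  has_gt_matrix <- nrow(vcf@gt) > 0 && ncol(vcf@gt) >= 2
  gt_mat <- NULL
  samples <- character()
  if (has_gt_matrix) {
    gt_mat <- vcfR::extract.gt(vcf, element = "GT")
    samples <- colnames(gt_mat)
    for (s in samples) sample_calls[[s]] <- character()
  }

  for (i in seq_len(n_rec)) {
    chrom <- fix[i, "CHROM"]
    pos <- as.integer(fix[i, "POS"])
    ref <- toupper(fix[i, "REF"])
    alt_field <- fix[i, "ALT"]
    if (respect_filter) {
      filt <- fix[i, "FILTER"]
      if (!is.na(filt) && !(filt %in% c("PASS", "."))) next
    }
    if (is.na(alt_field) || alt_field == "." || alt_field == "") next
    if (!chrom %in% names(reference)) {
      n_bad_ref <- n_bad_ref + 1L
      next
    }
    if (!is_acgtn(ref) ||
        substr(reference[[chrom]], pos, pos + nchar(ref) - 1L) != ref) {
      n_bad_ref <- n_bad_ref + 1L
      next
    }
    alts <- toupper(strsplit(alt_field, ",", fixed = TRUE)[[1]])
    bad <- !is_acgtn(alts)
    if (any(bad)) {
      n_bad_allele <- n_bad_allele + sum(bad)
    }

    # which ALT indices are asserted, per sample
    called_idx <- NULL   # NULL = no GT info for this record
    rec_sample_alt <- list()
    if (has_gt_matrix) {
      gts <- gt_mat[i, , drop = FALSE]
      if (any(!is.na(gts))) {
        called_idx <- integer()
        for (s in samples) {
          g <- gts[1L, s]
          if (is.na(g)) next
          idx <- suppressWarnings(
            as.integer(strsplit(g, "[/|]")[[1]]))
          idx <- idx[!is.na(idx) & idx > 0]
          called_idx <- c(called_idx, idx)
          if (length(idx)) rec_sample_alt[[s]] <- unique(idx)
        }
        called_idx <- unique(called_idx)
      }
    }
    if (is.null(called_idx) && require_gt) next
    use_idx <- if (is.null(called_idx)) seq_along(alts) else called_idx
    use_idx <- use_idx[use_idx <= length(alts) & !bad[use_idx]]
    if (!length(use_idx)) next

    for (j in use_idx) {
      prim <- decompose_complex(pos, ref, alts[[j]], max_ref_len = max_ref_len)
      if (!nrow(prim)) next
      norm <- do.call(rbind, lapply(seq_len(nrow(prim)), function(k) {
        left_normalize(chrom, prim$pos[k], prim$ref[k], prim$alt[k],
                       reference)
      }))
      norm$origins <- source_id
      out[[length(out) + 1L]] <- norm
      for (s in names(rec_sample_alt)) {
        if (j %in% rec_sample_alt[[s]]) {
          sample_calls[[s]] <- c(sample_calls[[s]], variant_key(norm))
        }
      }
    }
  }
  if (n_bad_ref > 0) {
    warning(sprintf("%s: %d record(s) failed reference validation and were dropped",
                    source_id, n_bad_ref))
  }
  if (n_bad_allele > 0) {
    warning(sprintf("%s: %d symbolic/non-ACGTN allele(s) dropped",
                    source_id, n_bad_allele))
  }
  res <- if (length(out)) do.call(rbind, out) else empty_variants()
  res <- dedup_variants(res)
  attr(res, "sample_calls") <- lapply(sample_calls, unique)
  attr(res, "n_bad_ref") <- n_bad_ref
  res
}

#' Split a multi-allelic VCF record into biallelic records
#'
#' @param pos,ref 1-based position and REF allele of the record.
#' @param alts character vector of ALT alleles.
#' @return data.frame with one row per ALT (`pos`, `ref`, `alt`).
#' @export
split_multiallelic <- function(pos, ref, alts) {
  stopifnot(length(alts) >= 1)
  data.frame(pos = rep(as.integer(pos), length(alts)), ref = ref,
             alt = alts, stringsAsFactors = FALSE)
}

#' Decompose a complex biallelic variant into primitive SNPs and indels
#'
#' Globally aligns REF against ALT (match +1, mismatch/gap -1; ties prefer
#' a mismatch over a gap so SNP runs stay SNPs, then gaps placed
#' deterministically) and emits one variant per mismatch column and one per
#' maximal gap run.  Indel outputs may have an empty REF or ALT; they are
#' anchored during [left_normalize()].  Applying every output to the
#' reference span reproduces the ALT haplotype exactly.  Variants whose REF
#' exceeds `max_ref_len` are passed through undecomposed.
#'
#' @param pos 1-based genomic position of the REF allele.
#' @param ref,alt allele strings.
#' @param max_ref_len decomposition length cap (default 10000).
#' @return data.frame (`pos`, `ref`, `alt`); indel rows may have an empty
#'   string on one side until normalised.
#' @export
decompose_complex <- function(pos, ref, alt, max_ref_len = 10000L) {
  pos <- as.integer(pos)
  if (ref == alt) {
    return(data.frame(pos = integer(), ref = character(), alt = character(),
                      stringsAsFactors = FALSE))
  }
  if (nchar(ref) == 1 && nchar(alt) == 1) {
    return(data.frame(pos = pos, ref = ref, alt = alt,
                      stringsAsFactors = FALSE))
  }
  if (nchar(ref) > max_ref_len) {
    return(data.frame(pos = pos, ref = ref, alt = alt,
                      stringsAsFactors = FALSE))
  }
  aln <- nw_align(ref, alt)
  ops <- aln$ops          # per column: "M" match, "X" mismatch, "D", "I"
  rpos <- aln$ref_pos     # 1-based position in ref per column (NA for I)
  a <- aln$a_char         # ref char per column ("" for I)
  b <- aln$b_char         # alt char per column ("" for D)
  res <- list()
  i <- 1L
  ncol_ <- length(ops)
  while (i <= ncol_) {
    op <- ops[[i]]
    if (op == "X") {
      res[[length(res) + 1L]] <- data.frame(
        pos = pos + rpos[[i]] - 1L, ref = a[[i]], alt = b[[i]],
        stringsAsFactors = FALSE)
      i <- i + 1L
    } else if (op == "D" || op == "I") {
      j <- i
      while (j < ncol_ && ops[[j + 1L]] == op) j <- j + 1L
      if (op == "D") {
        p <- pos + rpos[[i]] - 1L
        res[[length(res) + 1L]] <- data.frame(
          pos = p, ref = paste(a[i:j], collapse = ""), alt = "",
          stringsAsFactors = FALSE)
      } else {
        # insertion between ref columns; anchor at the next ref position
        nxt <- if (j < ncol_) rpos[[j + 1L]] else nchar(ref) + 1L
        res[[length(res) + 1L]] <- data.frame(
          pos = pos + nxt - 1L, ref = "",
          alt = paste(b[i:j], collapse = ""), stringsAsFactors = FALSE)
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  do.call(rbind, res)
}

# Needleman-Wunsch, match +1, mismatch -1, gap -1 per base.  A tiny extra
# gap-opening cost breaks the many score ties of the linear-gap problem in
# favour of contiguous indel runs (so one 4bp insertion never splits into
# two runs around an accidental interior match); remaining ties resolve
# mismatch over gap, deterministically.
nw_align <- function(ref, alt) {
  ra <- strsplit(ref, "", fixed = TRUE)[[1]]
  aa <- strsplit(alt, "", fixed = TRUE)[[1]]
  n <- length(ra); m <- length(aa)
  if (as.double(n) * m > 4e6) {
    stop("alleles too long to decompose (", n, " x ", m, ")")
  }
  open <- 1.015625   # 1 + 1/64: exact in binary, ties stay exact
  NEG <- -1e9
  M <- matrix(NEG, n + 1L, m + 1L)
  D <- matrix(NEG, n + 1L, m + 1L)   # gap in alt (deletion from ref)
  I <- matrix(NEG, n + 1L, m + 1L)   # gap in ref (insertion)
  M[1L, 1L] <- 0
  for (i in seq_len(n)) D[i + 1L, 1L] <- -open - (i - 1L)
  for (j in seq_len(m)) I[1L, j + 1L] <- -open - (j - 1L)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (ra[i] == aa[j]) 1 else -1
      M[i + 1L, j + 1L] <- max(M[i, j], D[i, j], I[i, j]) + s
      D[i + 1L, j + 1L] <- max(M[i, j + 1L] - open, D[i, j + 1L] - 1,
                               I[i, j + 1L] - open)
      I[i + 1L, j + 1L] <- max(M[i + 1L, j] - open, I[i + 1L, j] - 1,
                               D[i + 1L, j] - open)
    }
  }
  ops <- character(); rpos <- integer(); ac <- character(); bc <- character()
  i <- n; j <- m
  state <- which.max(c(M[n + 1L, m + 1L], D[n + 1L, m + 1L],
                       I[n + 1L, m + 1L]))
  state <- c("M", "D", "I")[state]
  tol <- 1e-9
  while (i > 0 || j > 0) {
    if (state == "M") {
      s <- if (ra[i] == aa[j]) 1 else -1
      ops <- c(if (ra[i] == aa[j]) "M" else "X", ops)
      rpos <- c(i, rpos); ac <- c(ra[i], ac); bc <- c(aa[j], bc)
      prev <- M[i + 1L, j + 1L] - s
      i <- i - 1L; j <- j - 1L
      state <- if (abs(M[i + 1L, j + 1L] - prev) < tol) "M"
               else if (abs(D[i + 1L, j + 1L] - prev) < tol) "D" else "I"
    } else if (state == "D") {
      ops <- c("D", ops); rpos <- c(i, rpos); ac <- c(ra[i], ac)
      bc <- c("", bc)
      here <- D[i + 1L, j + 1L]
      i <- i - 1L
      state <- if (i == 0 && j == 0) "M"
               else if (abs(D[i + 1L, j + 1L] - 1 - here) < tol) "D"
               else if (abs(M[i + 1L, j + 1L] - open - here) < tol) "M"
               else "I"
    } else {
      ops <- c("I", ops); rpos <- c(NA_integer_, rpos); ac <- c("", ac)
      bc <- c(aa[j], bc)
      here <- I[i + 1L, j + 1L]
      j <- j - 1L
      state <- if (i == 0 && j == 0) "M"
               else if (abs(I[i + 1L, j + 1L] - 1 - here) < tol) "I"
               else if (abs(M[i + 1L, j + 1L] - open - here) < tol) "M"
               else "D"
    }
  }
  list(ops = ops, ref_pos = rpos, a_char = ac, b_char = bc)
}

#' Left-normalise one variant against the reference
#'
#' Produces the parsimonious, left-aligned representation: identical
#' trailing bases are trimmed (extending left from the reference whenever
#' an allele would become empty), then identical leading bases are trimmed
#' while both alleles keep at least one base.  Empty REF or ALT on input
#' (raw indels from [decompose_complex()]) are anchored by extending left.
#' The operation is idempotent.
#'
#' @param chrom contig name.
#' @param pos 1-based position.
#' @param ref,alt allele strings (one may be empty on input).
#' @param reference named character vector of contig sequences.
#' @return one-row variant data.frame (`chrom`, `pos`, `ref`, `alt`).
#' @export
left_normalize <- function(chrom, pos, ref, alt, reference) {
  seqs <- reference[[chrom]]
  if (is.null(seqs)) stop("unknown contig: ", chrom)
  pos <- as.integer(pos)
  extend_left <- function() {
    if (pos <= 1L) stop("normalisation would move variant before contig start")
    pos <<- pos - 1L
    base <- substr(seqs, pos, pos)
    ref <<- paste0(base, ref)
    alt <<- paste0(base, alt)
  }
  if (nchar(ref) == 0 || nchar(alt) == 0) extend_left()
  repeat {
    # trim identical trailing bases
    while (nchar(ref) > 0 && nchar(alt) > 0 &&
           substr(ref, nchar(ref), nchar(ref)) ==
           substr(alt, nchar(alt), nchar(alt))) {
      ref <- substr(ref, 1L, nchar(ref) - 1L)
      alt <- substr(alt, 1L, nchar(alt) - 1L)
      if (nchar(ref) == 0 || nchar(alt) == 0) extend_left()
    }
    # trim identical leading bases
    moved <- FALSE
    while (nchar(ref) > 1 && nchar(alt) > 1 &&
           substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
      ref <- substr(ref, 2L, nchar(ref))
      alt <- substr(alt, 2L, nchar(alt))
      pos <- pos + 1L
      moved <- TRUE
    }
    if (!moved) break
  }
  if (ref == alt) stop("variant normalised to a no-op: ", chrom, ":", pos)
  data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

# collapse duplicate (chrom,pos,ref,alt) rows, unioning origins, and sort
dedup_variants <- function(v) {
  if (!nrow(v)) return(v)
  if (is.null(v$origins)) v$origins <- ""
  key <- variant_key(v)
  origin_by_key <- tapply(v$origins, key, function(o) {
    paste(sort(unique(unlist(strsplit(o, ";", fixed = TRUE)))),
          collapse = ";")
  })
  v <- v[!duplicated(key), , drop = FALSE]
  v$origins <- as.character(origin_by_key[variant_key(v)])
  v <- v[order(v$chrom, v$pos, v$ref, v$alt), , drop = FALSE]
  rownames(v) <- NULL
  v
}

#' Merge normalised variant sets into one deduplicated set
#'
#' Variants identical on (chrom, pos, ref, alt) are kept once with the
#' union of their origins.  The per-sample call lists attached by
#' [load_calls()] are merged too (used by the clustering fallback).
#'
#' @param ... normalised variant data.frames, or a single list of them.
#' @return merged, sorted, deduplicated variant data.frame with a
#'   `sample_calls` attribute.
#' @export
merge_and_deduplicate <- function(...) {
  inputs <- list(...)
  if (length(inputs) == 1 && is.list(inputs[[1]]) &&
      !is.data.frame(inputs[[1]])) {
    inputs <- inputs[[1]]
  }
  stopifnot(length(inputs) >= 1)
  merged <- dedup_variants(do.call(rbind, lapply(inputs, function(x) {
    x[, variant_columns[variant_columns %in% names(x)], drop = FALSE]
  })))
  sc <- list()
  for (x in inputs) {
    for (s in names(attr(x, "sample_calls"))) {
      sc[[s]] <- unique(c(sc[[s]], attr(x, "sample_calls")[[s]]))
    }
  }
  attr(merged, "sample_calls") <- sc
  merged
}
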