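# Clustering of merged variants into non-overlapping multi-allelic sites.
#
# A site set is a data.frame with columns
#   chrom, start, end   reference span (1-based closed)
#   ref_allele          reference substring over the span
#   alts                list column of alternate allele strings
#   members             list column of merged-variant keys folded in
# No two sites share a reference position.

ref_interval <- function(v) {
  cbind(start = v$pos, end = v$pos + nchar(v$ref) - 1L)
}

#' Exclude long deletions before graph construction
#'
#' Deletions whose net deleted length `nchar(ref) - nchar(alt)` exceeds
#' `max_del_len` are excluded from the graph (they would allow a
#' combinatorial explosion of alleles when SNPs sit beneath them).
#' Insertions of any length are kept.
#'
#' @param variants normalised variant data.frame.
#' @param max_del_len maximum deletion length retained (default 50).
#' @return list with elements `kept` and `excluded` (both variant
#'   data.frames; `nrow(kept) + nrow(excluded) == nrow(variants)`).
#' @export
filter_long_deletions <- function(variants, max_del_len = 50L) {
  if (!nrow(variants)) return(list(kept = variants, excluded = variants))
  del_len <- pmax(nchar(variants$ref) - nchar(variants$alt), 0L)
  drop <- del_len > max_del_len
  list(kept = variants[!drop, , drop = FALSE],
       excluded = variants[drop, , drop = FALSE])
}

#' Cluster variants whose reference intervals overlap
#'
#' Computes the transitive closure of reference-interval overlap (1-based
#' closed intervals; an insertion occupies its single anchor base).  Each
#' cluster becomes one multi-allelic site downstream.
#'
#' @param variants normalised variant data.frame.
#' @return integer vector of cluster ids, parallel to `variants` rows;
#'   cluster spans are pairwise disjoint within each contig.
#' @export
cluster_overlapping <- function(variants) {
  n <- nrow(variants)
  ids <- integer(n)
  next_id <- 0L
  for (chrom in unique(variants$chrom)) {
    sel <- which(variants$chrom == chrom)
    iv <- ref_interval(variants[sel, , drop = FALSE])
    ir <- IRanges::IRanges(start = iv[, "start"], end = iv[, "end"])
    red <- IRanges::reduce(ir, min.gapwidth = 0L)
    hit <- IRanges::findOverlaps(ir, red)
    ids[sel] <- next_id + S4Vectors::subjectHits(hit)
    next_id <- next_id + length(red)
  }
  ids
}

# count conflict-free subsets (incl. the empty one) of intervals sorted by
# start; conflict = interval overlap
count_conflict_free <- function(starts, ends, cap) {
  n <- length(starts)
  ord <- order(starts, ends)
  starts <- starts[ord]; ends <- ends[ord]
  # f[i] = number of conflict-free subsets of intervals i..n
  f <- numeric(n + 1L)
  f[n + 1L] <- 1
  for (i in n:1) {
    j <- i + 1L
    while (j <= n && starts[j] <= ends[i]) j <- j + 1L
    f[i] <- f[i + 1L] + f[j]
    if (f[i] > cap * 4) return(Inf)   # early out; only magnitude matters
  }
  f[1L]
}

# apply non-conflicting variants (rows of v) to the span [start,end] of seq
apply_to_span <- function(span_seq, start, v) {
  if (!nrow(v)) return(span_seq)
  ord <- order(v$pos, decreasing = TRUE)
  s <- span_seq
  for (i in ord) {
    off <- v$pos[i] - start + 1L
    s <- paste0(substr(s, 1L, off - 1L), v$alt[i],
                substr(s, off + nchar(v$ref[i]), nchar(s)))
  }
  s
}

# enumerate all conflict-free subsets of cluster rows (list of integer vecs)
conflict_free_subsets <- function(iv) {
  n <- nrow(iv)
  res <- list(integer())
  recurse <- function(i, chosen, last_end) {
    if (i > n) return()
    # subsets are built over intervals sorted by start
    if (iv[i, "start"] > last_end) {
      sel <- c(chosen, i)
      res[[length(res) + 1L]] <<- sel
      recurse(i + 1L, sel, iv[i, "end"])
    }
    recurse(i + 1L, chosen, last_end)
  }
  recurse(1L, integer(), -Inf)
  res
}

#' Build one multi-allelic site from a cluster of variants
#'
#' The site's alleles are the distinct sequences obtained by applying every
#' conflict-free subset of the cluster's variants to the reference span
#' (two variants conflict when their reference intervals overlap).  If the
#' number of conflict-free combinations would exceed `max_alleles`, only
#' allele combinations actually observed in at least one sample's input
#' genotypes are used (plus the reference); if the result still exceeds the
#' cap, alleles are kept by descending observed frequency, ties broken
#' lexicographically.
#'
#' @param cluster variant data.frame (one overlap cluster, one contig).
#' @param reference named character vector of contig sequences.
#' @param max_alleles allele cap per site (default 500).
#' @param sample_calls optional named list: per sample, the keys of
#'   variants that sample asserted (from [load_calls()]); required when
#'   the fallback engages.
#' @return one-row site data.frame (columns described at top of file).
#' @export
enumerate_site_alleles <- function(cluster, reference, max_alleles = 500L,
                                   sample_calls = NULL) {
  stopifnot(nrow(cluster) >= 1, length(unique(cluster$chrom)) == 1)
  chrom <- cluster$chrom[[1]]
  iv <- ref_interval(cluster)
  start <- min(iv[, "start"])
  end <- max(iv[, "end"])
  span_seq <- substr(reference[[chrom]], start, end)
  keys <- variant_key(cluster)

  ord <- order(iv[, "start"], iv[, "end"])
  cluster <- cluster[ord, , drop = FALSE]
  iv <- iv[ord, , drop = FALSE]

  n_comb <- count_conflict_free(iv[, "start"], iv[, "end"], max_alleles)
  if (n_comb <= max_alleles) {
    subsets <- conflict_free_subsets(iv)
    alleles <- vapply(subsets, function(sel) {
      apply_to_span(span_seq, start, cluster[sel, , drop = FALSE])
    }, character(1))
    freq <- NULL
  } else {
    if (is.null(sample_calls) || !length(sample_calls)) {
      stop(sprintf(
        "site %s:%d-%d has %s allele combinations (cap %d) and no per-sample genotypes for the seen-combination fallback",
        chrom, start, end, format(n_comb), max_alleles))
    }
    combos <- character()
    for (s in names(sample_calls)) {
      sel <- which(variant_key(cluster) %in% sample_calls[[s]])
      if (!length(sel)) next
      sub <- cluster[sel, , drop = FALSE]
      si <- iv[sel, , drop = FALSE]
      o <- order(si[, "start"])
      if (any(si[o, "start"][-1] <= cummax(si[o, "end"])[-length(sel)])) {
        warning(sprintf(
          "sample %s asserts conflicting variants in site %s:%d-%d; its combination was skipped",
          s, chrom, start, end))
        next
      }
      combos <- c(combos, apply_to_span(span_seq, start, sub))
    }
    tab <- sort(table(combos), decreasing = TRUE)
    alleles <- c(span_seq, names(tab)[order(-as.integer(tab), names(tab))])
    freq <- c(Inf, as.integer(tab)[order(-as.integer(tab), names(tab))])
  }

  keep <- !duplicated(alleles)
  alleles <- alleles[keep]
  if (!is.null(freq)) freq <- freq[keep]
  # reference allele first
  alleles <- c(span_seq, setdiff(alleles, span_seq))
  if (length(alleles) > max_alleles) {
    alleles <- alleles[seq_len(max_alleles)]
  }
  data.frame(chrom = chrom, start = start, end = end, ref_allele = span_seq,
             alts = I(list(setdiff(alleles, span_seq))),
             members = I(list(keys)), stringsAsFactors = FALSE)
}

site_allele_count <- function(sites) {
  vapply(sites$alts, length, integer(1)) + 1L
}

# all sequences spellable over the combined span of a block of sites,
# one per path (product of allele choices); NULL if too many paths
block_path_sequences <- function(block, reference, max_paths = 4096L) {
  n_paths <- prod(site_allele_count(block))
  if (n_paths > max_paths) return(NULL)
  chrom <- block$chrom[[1]]
  seqs <- ""
  cursor <- min(block$start)
  for (i in seq_len(nrow(block))) {
    gap <- substr(reference[[chrom]], cursor, block$start[i] - 1L)
    alleles <- c(block$ref_allele[i], block$alts[[i]])
    seqs <- as.vector(outer(paste0(seqs, gap), alleles, paste0))
    cursor <- block$end[i] + 1L
  }
  seqs
}

#' Merge sites that can spell duplicate sequences through different paths
#'
#' In low-complexity sequence, two alternate deletions of a repeat unit at
#' neighbouring sites can realise the identical genome sequence through
#' different graph paths, which would make read mapping ambiguous.  As each
#' site is appended, the previous `window` sites are checked: if any block
#' of consecutive sites ending at the new one realises the same sequence
#' via two different paths, the block is merged into a single site whose
#' alleles are the distinct realised sequences.
#'
#' @param sites site data.frame in genome order.
#' @param reference named character vector of contig sequences.
#' @param window how many predecessors to check (default 7).
#' @param max_alleles allele cap applied to merged sites.
#' @param max_paths blocks spelling more paths than this are not checked
#'   (duplicate spelling is a low-complexity phenomenon of small sites).
#' @return deduplicated site data.frame.
#' @export
dedup_duplicate_sites <- function(sites, reference, window = 7L,
                                  max_alleles = 500L, max_paths = 4096L) {
  out <- sites[0, , drop = FALSE]
  for (i in seq_len(nrow(sites))) {
    out <- rbind(out, sites[i, , drop = FALSE])
    repeat {
      merged <- FALSE
      last <- nrow(out)
      for (k in seq_len(min(window, last - 1L))) {
        block <- out[(last - k):last, , drop = FALSE]
        if (length(unique(block$chrom)) > 1) break
        paths <- block_path_sequences(block, reference, max_paths)
        if (is.null(paths)) next
        if (anyDuplicated(paths)) {
          chrom <- block$chrom[[1]]
          start <- min(block$start); end <- max(block$end)
          ref_allele <- substr(reference[[chrom]], start, end)
          alleles <- unique(paths)
          alleles <- c(ref_allele, setdiff(alleles, ref_allele))
          if (length(alleles) > max_alleles) {
            alleles <- alleles[seq_len(max_alleles)]
          }
          newsite <- data.frame(
            chrom = chrom, start = start, end = end,
            ref_allele = ref_allele,
            alts = I(list(setdiff(alleles, ref_allele))),
            members = I(list(unique(unlist(block$members)))),
            stringsAsFactors = FALSE)
          out <- rbind(out[seq_len(last - k - 1L), , drop = FALSE], newsite)
          merged <- TRUE
          break
        }
      }
      if (!merged) break
    }
  }
  rownames(out) <- NULL
  out
}

#' Cluster merged variants into non-overlapping multi-allelic sites
#'
#' Full clustering stage: long-deletion exclusion, overlap clustering,
#' allele enumeration with the seen-combination fallback, and duplicate
#' path merging.  The resulting sites define the bubble genome graph.
#'
#' @param variants merged, normalised variant data.frame
#'   (from [merge_and_deduplicate()]).
#' @param reference named character vector of contig sequences.
#' @param max_del_len,max_alleles,dedup_window tuning knobs; see the
#'   individual stage functions.
#' @param sample_calls per-sample asserted-variant keys for the allele-cap
#'   fallback; defaults to the `sample_calls` attribute of `variants`.
#' @return site data.frame with attributes `n_excluded` (long deletions)
#'   and `excluded` (the excluded rows).
#' @export
cluster_variants <- function(variants, reference, max_del_len = 50L,
                             max_alleles = 500L, dedup_window = 7L,
                             sample_calls = attr(variants, "sample_calls")) {
  flt <- filter_long_deletions(variants, max_del_len)
  v <- flt$kept
  if (!nrow(v)) {
    sites <- data.frame(chrom = character(), start = integer(),
                        end = integer(), ref_allele = character(),
                        alts = I(list()), members = I(list()),
                        stringsAsFactors = FALSE)
  } else {
    ids <- cluster_overlapping(v)
    sites <- do.call(rbind, lapply(split(seq_len(nrow(v)), ids), function(sel) {
      enumerate_site_alleles(v[sel, , drop = FALSE], reference,
                             max_alleles = max_alleles,
                             sample_calls = sample_calls)
    }))
    sites <- sites[order(sites$chrom, sites$start), , drop = FALSE]
    sites <- dedup_duplicate_sites(sites, reference, window = dedup_window,
                                   max_alleles = max_alleles)
  }
  rownames(sites) <- NULL
  attr(sites, "excluded") <- flt$excluded
  attr(sites, "n_excluded") <- nrow(flt$excluded)
  sites
}

#' Split sites into genome slices for low-memory mapping
#'
#' Sites are partitioned in genome order into at most `n_slices` contiguous
#' groups with approximately equal total allele counts (within one site's
#' worth).  Each slice's reference interval is extended by `read_length`
#' on both ends, so adjacent slices overlap by at least a read length and
#' mapping has no end effects.
#'
#' @param sites site data.frame (single contig per slice group).
#' @param n_slices requested number of slices.
#' @param read_length read length used for the overlap.
#' @param genome_length named vector of contig lengths.
#' @return data.frame with columns `slice`, `chrom`, `start`, `end` (the
#'   padded interval) and list column `site_idx` (row indices of `sites`).
#' @export
slice_graph <- function(sites, n_slices, read_length, genome_length) {
  stopifnot(nrow(sites) >= 1)
  if (n_slices > nrow(sites)) {
    warning("fewer sites than requested slices; returning one slice per site")
    n_slices <- nrow(sites)
  }
  out <- list()
  slice_id <- 0L
  for (chrom in unique(sites$chrom)) {
    idx <- which(sites$chrom == chrom)
    counts <- site_allele_count(sites[idx, , drop = FALSE])
    total <- sum(counts)
    # contiguous greedy partition: close a slice once its share is reached
    n_here <- max(1L, round(n_slices * length(idx) / nrow(sites)))
    target <- total / n_here
    cum <- cumsum(counts)
    grp <- pmin(n_here, floor((cum - counts / 2) / target) + 1L)
    grp <- cummax(grp)
    groups <- unique(grp)
    # core intervals tile the contig, cut midway between adjacent groups
    ends <- vapply(groups, function(g) max(sites$end[idx[grp == g]]),
                   integer(1))
    starts <- vapply(groups, function(g) min(sites$start[idx[grp == g]]),
                     integer(1))
    cuts <- as.integer(floor((utils::head(ends, -1) +
                              utils::tail(starts, -1)) / 2))
    core_start <- c(1L, cuts + 1L)
    core_end <- c(cuts, genome_length[[chrom]])
    for (k in seq_along(groups)) {
      slice_id <- slice_id + 1L
      out[[slice_id]] <- data.frame(
        slice = slice_id, chrom = chrom,
        start = max(1L, core_start[k] - read_length),
        end = min(genome_length[[chrom]], core_end[k] + read_length),
        site_idx = I(list(idx[grp == groups[k]])), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
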