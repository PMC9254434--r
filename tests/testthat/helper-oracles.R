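# Independent brute-force oracles used by the property tests.  These stay
# deliberately naive (exhaustive enumeration, quadratic scans) so they are
# easy to trust and fully independent of the implementation they check.

# write a minimal single-sample VCF for tests
write_test_vcf <- function(records, path, gt = "1",
                           contigs = c(chr1 = 1000L)) {
  hdr <- c("##fileformat=VCFv4.2",
           sprintf("##contig=<ID=%s,length=%d>", names(contigs), contigs),
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tsample")
  writeLines(c(hdr, records), path)
  path
}

vcf_record <- function(chrom, pos, ref, alt, gt = "1", filter = "PASS") {
  sprintf("%s\t%d\t.\t%s\t%s\t.\t%s\t.\tGT\t%s", chrom, pos, ref, alt,
          filter, gt)
}

# apply one variant to a contig sequence
apply_one <- function(seqs, pos, ref, alt) {
  stopifnot(substr(seqs, pos, pos + nchar(ref) - 1L) == ref)
  paste0(substr(seqs, 1L, pos - 1L), alt,
         substr(seqs, pos + nchar(ref), nchar(seqs)))
}

# exhaustive-enumeration normalisation oracle: among every (pos, ref, alt)
# representation producing the same mutated sequence, return the
# parsimonious one with the smallest position
oracle_left_normalize <- function(seqs, pos, ref, alt, max_len = 25L) {
  mutated <- apply_one(seqs, pos, ref, alt)
  g_len <- nchar(seqs)
  m_len <- nchar(mutated)
  best <- NULL
  for (p in seq_len(g_len)) {
    for (lr in 0:max_len) {
      if (p + lr - 1L > g_len) break
      suffix_len <- g_len - (p + lr - 1L)
      la <- m_len - (p - 1L) - suffix_len
      if (la < 0) next
      if (substr(mutated, 1L, p - 1L) != substr(seqs, 1L, p - 1L)) next
      if (suffix_len > 0 &&
          substr(mutated, m_len - suffix_len + 1L, m_len) !=
          substr(seqs, p + lr, g_len)) next
      r <- substr(seqs, p, p + lr - 1L)
      a <- substr(mutated, p, p + la - 1L)
      if (r == a || nchar(r) == 0 || nchar(a) == 0) next
      # parsimonious: no shared trailing base; no droppable leading base
      if (substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) next
      if (nchar(r) > 1 && nchar(a) > 1 &&
          substr(r, 1L, 1L) == substr(a, 1L, 1L)) next
      cand <- list(pos = p, ref = r, alt = a)
      if (is.null(best) || p < best$pos ||
          (p == best$pos && nchar(r) < nchar(best$ref))) {
        best <- cand
      }
    }
  }
  best
}

oracle_revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

# haplotype-enumeration mapping oracle: spell every haplotype of the graph
# (with a per-position record of site/allele membership), scan every read
# on both strands with a quadratic exact search, and accumulate gamma and
# per-base depth with the same per-read-per-site counting contract
oracle_quasimap <- function(reference, sites, reads) {
  chrom <- names(reference)[[1]]
  n_sites <- nrow(sites)
  allele_counts <- vapply(sites$alts, length, integer(1)) + 1L
  combos <- expand.grid(lapply(allele_counts, seq_len))
  per_base <- lapply(seq_len(n_sites), function(i) {
    alleles <- c(sites$ref_allele[i], sites$alts[[i]])
    lapply(nchar(alleles), function(l) integer(l))
  })
  gamma <- lapply(seq_len(n_sites), function(i) list())
  # read -> per site: set of alleles, and per allele matched positions
  read_site_alleles <- lapply(seq_along(reads), function(r) {
    lapply(seq_len(n_sites), function(i) list())
  })
  for (ci in seq_len(nrow(combos))) {
    choice <- as.integer(combos[ci, ])
    pieces <- character()
    site_of <- integer()    # per spelled position: site id or 0
    apos_of <- integer()    # per spelled position: position within allele
    cursor <- 1L
    for (i in seq_len(n_sites)) {
      gap <- substr(reference[[chrom]], cursor, sites$start[i] - 1L)
      alleles <- c(sites$ref_allele[i], sites$alts[[i]])
      al <- alleles[[choice[i]]]
      pieces <- c(pieces, gap, al)
      site_of <- c(site_of, rep(0L, nchar(gap)), rep(i, nchar(al)))
      apos_of <- c(apos_of, rep(0L, nchar(gap)), seq_len(nchar(al)))
      cursor <- sites$end[i] + 1L
    }
    tailseq <- substr(reference[[chrom]], cursor, nchar(reference[[chrom]]))
    pieces <- c(pieces, tailseq)
    site_of <- c(site_of, rep(0L, nchar(tailseq)))
    apos_of <- c(apos_of, rep(0L, nchar(tailseq)))
    hap <- paste(pieces, collapse = "")
    hlen <- nchar(hap)
    for (r in seq_along(reads)) {
      for (rseq in unique(c(reads[[r]], oracle_revcomp(reads[[r]])))) {
        rl <- nchar(rseq)
        if (rl > hlen) next
        offs <- seq_len(hlen - rl + 1L)
        hit <- offs[substring(hap, offs, offs + rl - 1L) == rseq]
        for (o in hit) {
          span <- o:(o + rl - 1L)
          for (i in unique(site_of[span])) {
            if (i == 0L) next
            a <- choice[i]
            key <- as.character(a)
            prev <- read_site_alleles[[r]][[i]][[key]]
            pos_in_allele <- apos_of[span][site_of[span] == i]
            read_site_alleles[[r]][[i]][[key]] <-
              sort(unique(c(prev, pos_in_allele)))
          }
        }
      }
    }
  }
  for (r in seq_along(reads)) {
    for (i in seq_len(n_sites)) {
      rec <- read_site_alleles[[r]][[i]]
      if (!length(rec)) next
      aset <- sort(as.integer(names(rec)))
      gkey <- paste(aset, collapse = ",")
      gamma[[i]][[gkey]] <- (gamma[[i]][[gkey]] %||% 0) + 1
      for (a in aset) {
        p <- rec[[as.character(a)]]
        per_base[[i]][[a]][p] <- per_base[[i]][[a]][p] + 1L
      }
    }
  }
  list(gamma = lapply(gamma, function(g) unlist(g)),
       per_base = per_base)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random small site set over a reference, for the mapping oracle tests
random_small_graph <- function(glen = 400L, n_sites = 3L,
                               max_alleles = 3L) {
  seqs <- paste(sample(c("A", "C", "G", "T"), glen, replace = TRUE),
                collapse = "")
  reference <- stats::setNames(seqs, "chr1")
  starts <- sort(sample(seq.int(30L, glen - 40L), n_sites))
  while (any(diff(starts) < 12L)) {
    starts <- sort(sample(seq.int(30L, glen - 40L), n_sites))
  }
  rows <- lapply(starts, function(s) {
    w <- sample(1:3, 1)
    ref_allele <- substr(seqs, s, s + w - 1L)
    n_alt <- sample(seq_len(max_alleles - 1L), 1)
    alts <- character()
    while (length(unique(alts)) < n_alt) {
      kind <- sample(c("snp", "ins", "del"), 1)
      alt <- if (kind == "snp") {
        paste(sample(c("A", "C", "G", "T"), w, replace = TRUE),
              collapse = "")
      } else if (kind == "ins") {
        paste0(ref_allele, paste(sample(c("A", "C", "G", "T"),
                                        sample(1:3, 1), replace = TRUE),
                                 collapse = ""))
      } else {
        substr(ref_allele, 1L, max(1L, w - 1L))
      }
      if (alt != ref_allele) alts <- unique(c(alts, alt))
    }
    data.frame(chrom = "chr1", start = s, end = s + w - 1L,
               ref_allele = ref_allele, alts = I(list(alts)),
               members = I(list(character())), stringsAsFactors = FALSE)
  })
  list(reference = reference, sites = do.call(rbind, rows))
}
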