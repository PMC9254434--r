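# Clustering variants into non-overlapping multi-allelic sites.

test_that("deletion length cap keeps 50bp and excludes 51bp deletions", {
  v <- data.frame(chrom = "chr1", pos = c(10L, 200L, 400L, 600L),
                  ref = c(paste(rep("A", 51), collapse = ""),   # 50bp del
                          paste(rep("A", 52), collapse = ""),   # 51bp del
                          "C",                                  # SNP
                          "G"),                                 # 200bp ins
                  alt = c("A", "A", "T",
                          paste0("G", paste(rep("T", 200), collapse = ""))),
                  origins = "x", stringsAsFactors = FALSE)
  out <- filter_long_deletions(v)
  expect_equal(out$kept$pos, c(10L, 400L, 600L))
  expect_equal(out$excluded$pos, 200L)
  expect_equal(nrow(out$kept) + nrow(out$excluded), nrow(v))
})

test_that("overlap clustering takes the transitive closure", {
  v <- data.frame(chrom = "chr1",
                  pos = c(7L, 8L, 30L, 50L, 52L, 54L),
                  ref = c("AT", "T", "G", "AAA", "AAA", "A"),
                  alt = c("A", "C", "C", "A", "A", "T"),
                  origins = "x", stringsAsFactors = FALSE)
  ids <- cluster_overlapping(v)
  # 2bp-spanning variant at 7 overlaps the SNP at 8
  expect_equal(ids[1], ids[2])
  # isolated SNP at 30 alone
  expect_false(ids[3] %in% ids[-3])
  # chained overlap 50-52, 52-54, 54: one cluster
  expect_true(all(ids[4:6] == ids[4]))
  # SNPs 10bp apart do not cluster
  v2 <- data.frame(chrom = "chr1", pos = c(10L, 20L), ref = "A", alt = "T",
                   origins = "x", stringsAsFactors = FALSE)
  expect_equal(length(unique(cluster_overlapping(v2))), 2L)
})

test_that("three overlapping biallelic SNPs expand to 2^3 alleles", {
  seqs <- c(chr1 = "TTTTTTACGTTTTTTTTTTT")
  # a 3bp-spanning variant ties the three SNP positions into one cluster
  v <- data.frame(chrom = "chr1",
                  pos = c(7L, 7L, 8L, 9L),
                  ref = c("ACG", "A", "C", "G"),
                  alt = c("TGA", "C", "G", "T"),
                  origins = "x", stringsAsFactors = FALSE)
  site <- enumerate_site_alleles(v[-1, , drop = FALSE], seqs)
  expect_equal(length(site$alts[[1]]) + 1L, 8L)
  # single SNP cluster: 2 alleles
  s2 <- enumerate_site_alleles(v[2, , drop = FALSE], seqs)
  expect_equal(length(s2$alts[[1]]), 1L)
  # every alt differs from ref and equals some conflict-free application
  expect_false(site$ref_allele %in% site$alts[[1]])
})

test_that("allele explosion beyond the cap uses seen sample combinations", {
  set.seed(11)
  base <- paste(sample(c("A", "C", "G", "T"), 40, replace = TRUE),
                collapse = "")
  seqs <- c(chr1 = base)
  # 10 biallelic SNPs chained by a spanning variant: 2^10 + 1 combinations
  pos <- 11:20
  snps <- do.call(rbind, lapply(pos, function(p) {
    ref <- substr(base, p, p)
    data.frame(chrom = "chr1", pos = p, ref = ref,
               alt = setdiff(c("A", "C", "G", "T"), ref)[1],
               origins = "x", stringsAsFactors = FALSE)
  }))
  span <- data.frame(chrom = "chr1", pos = 11L,
                     ref = substr(base, 11, 20),
                     alt = substr(base, 11, 11),
                     origins = "x", stringsAsFactors = FALSE)
  cluster <- rbind(snps, span)
  expect_error(enumerate_site_alleles(cluster, seqs, max_alleles = 500L),
               "fallback")
  # with per-sample genotypes: only seen combinations (plus reference)
  keys <- paste(cluster$chrom, cluster$pos, cluster$ref, cluster$alt,
                sep = "\r")
  sample_calls <- list(s1 = keys[1:3], s2 = keys[c(4, 6)], s3 = keys[11])
  site <- enumerate_site_alleles(cluster, seqs, max_alleles = 500L,
                                 sample_calls = sample_calls)
  expect_equal(length(site$alts[[1]]), 3L)   # three distinct seen haplotypes
  expect_lte(length(site$alts[[1]]) + 1L, 500L)
})

test_that("conflicting within-sample combinations are skipped with warning", {
  seqs <- c(chr1 = "AAAAAAAAAACCCCCCCCCC")
  cluster <- data.frame(chrom = "chr1", pos = c(5L, 5L, 6L),
                        ref = c("AA", "A", "A"),
                        alt = c("A", "T", "G"),
                        origins = "x", stringsAsFactors = FALSE)
  keys <- paste(cluster$chrom, cluster$pos, cluster$ref, cluster$alt,
                sep = "\r")
  # force fallback by a tiny cap
  expect_warning(
    site <- enumerate_site_alleles(cluster, seqs, max_alleles = 4L,
                                   sample_calls = list(bad = keys[1:2],
                                                       ok = keys[3])),
    "conflicting")
  # only the ok sample's SNP at 6 applied over the [5,6] span
  expect_equal(site$alts[[1]], "AG")
})

test_that("adjacent alternate deletions of a repeat merge into one site", {
  seqs <- c(chr1 = "TTTTTACACACATTTTTTTT")
  # deleting the first or the second AC unit gives the same mutated
  # sequence through two different paths: the graph would spell duplicates
  sites <- rbind(
    enumerate_site_alleles(
      data.frame(chrom = "chr1", pos = 5L, ref = "TAC", alt = "T",
                 origins = "x", stringsAsFactors = FALSE), seqs),
    enumerate_site_alleles(
      data.frame(chrom = "chr1", pos = 8L, ref = "ACA", alt = "A",
                 origins = "x", stringsAsFactors = FALSE), seqs))
  expect_true(all(sites$start[-1] > sites$end[-nrow(sites)]))  # disjoint
  out <- dedup_duplicate_sites(sites, seqs)
  expect_equal(nrow(out), 1L)
  expect_equal(out$start, 5L)
  expect_equal(out$end, 10L)
  # the merged site's alleles realise every distinct original spelling
  expect_setequal(c(out$ref_allele, out$alts[[1]]),
                  c("TACACA", "TACA", "TA"))
  # non-repetitive adjacent sites stay separate
  seqs2 <- c(chr1 = "AAACGTACGATCGGCTAGCA")
  sites2 <- rbind(
    enumerate_site_alleles(
      data.frame(chrom = "chr1", pos = 4L, ref = "C", alt = "T",
                 origins = "x", stringsAsFactors = FALSE), seqs2),
    enumerate_site_alleles(
      data.frame(chrom = "chr1", pos = 8L, ref = "C", alt = "A",
                 origins = "x", stringsAsFactors = FALSE), seqs2))
  expect_equal(nrow(dedup_duplicate_sites(sites2, seqs2)), 2L)
})

test_that("duplicate spellings outside the window are not merged", {
  # a long AC repeat array: equivalent unit-deletions at both ends, and 8
  # distinct SNP sites between them
  seqs <- c(chr1 = paste0("TTTT", "T",
                          paste(rep("AC", 12), collapse = ""), "ATTTT"))
  mk <- function(pos, ref, alt) {
    enumerate_site_alleles(
      data.frame(chrom = "chr1", pos = pos, ref = ref, alt = alt,
                 origins = "x", stringsAsFactors = FALSE), seqs)
  }
  del1 <- mk(5L, "TAC", "T")
  del2 <- mk(24L, "ACA", "A")
  mids <- do.call(rbind, lapply(seq(8L, 22L, by = 2L), function(p) {
    mk(p, substr(seqs[[1]], p, p), "G")
  }))
  sites <- rbind(del1, mids, del2)
  expect_true(all(sites$start[-1] > sites$end[-nrow(sites)]))
  # the duplicate pair is 9 sites apart: found with a window of 9 ...
  expect_lt(nrow(dedup_duplicate_sites(sites, seqs, window = 9L)),
            nrow(sites))
  # ... but not within the default window of 7
  expect_equal(nrow(dedup_duplicate_sites(sites, seqs, window = 7L)),
               nrow(sites))
})

test_that("clustering bookkeeping reconciles kept and excluded counts", {
  set.seed(300)
  seqs <- c(chr1 = paste(sample(c("A", "C", "G", "T"), 3000,
                                replace = TRUE), collapse = ""))
  pos <- sort(sample(100:2900, 60))
  v <- do.call(rbind, lapply(pos, function(p) {
    ref <- substr(seqs[[1]], p, p)
    data.frame(chrom = "chr1", pos = p, ref = ref,
               alt = setdiff(c("A", "C", "G", "T"), ref)[1],
               origins = "x", stringsAsFactors = FALSE)
  }))
  # add one long deletion to exercise exclusion
  v <- rbind(v, data.frame(chrom = "chr1", pos = 50L,
                           ref = substr(seqs[[1]], 50, 110),
                           alt = substr(seqs[[1]], 50, 50),
                           origins = "x", stringsAsFactors = FALSE))
  sites <- cluster_variants(v, seqs)
  expect_equal(attr(sites, "n_excluded"), 1L)
  # sites are pairwise disjoint
  o <- order(sites$start)
  expect_true(all(sites$start[o][-1] > sites$end[o][-nrow(sites)]))
  # every alt differs from its site's ref allele
  for (i in seq_len(nrow(sites))) {
    expect_false(sites$ref_allele[i] %in% sites$alts[[i]])
  }
})

test_that("graph slices balance alleles, tile the genome and overlap by a
           read length", {
  set.seed(301)
  seqs <- c(chr1 = paste(sample(c("A", "C", "G", "T"), 5000,
                                replace = TRUE), collapse = ""))
  pos <- seq(100L, 4900L, by = 48L)
  v <- do.call(rbind, lapply(pos, function(p) {
    ref <- substr(seqs[[1]], p, p)
    data.frame(chrom = "chr1", pos = p, ref = ref,
               alt = setdiff(c("A", "C", "G", "T"), ref)[1],
               origins = "x", stringsAsFactors = FALSE)
  }))
  sites <- cluster_variants(v, seqs)
  sl <- slice_graph(sites, 4L, read_length = 100L,
                    genome_length = c(chr1 = 5000L))
  expect_equal(nrow(sl), 4L)
  # uniform allele counts: equal split within one site
  per_slice <- vapply(sl$site_idx, length, integer(1))
  expect_lte(max(per_slice) - min(per_slice), 1L)
  # coverage of the genome and pairwise overlap >= read length
  expect_equal(sl$start[1], 1L)
  expect_equal(sl$end[nrow(sl)], 5000L)
  for (k in seq_len(nrow(sl) - 1L)) {
    expect_gte(sl$end[k] - sl$start[k + 1L] + 1L, 100L)
  }
  # no site split across a boundary
  for (k in seq_len(nrow(sl))) {
    idx <- sl$site_idx[[k]]
    expect_true(all(sites$start[idx] >= sl$start[k] &
                    sites$end[idx] <= sl$end[k]))
  }
  # one slice is the identity partition
  sl1 <- slice_graph(sites, 1L, 100L, c(chr1 = 5000L))
  expect_equal(nrow(sl1), 1L)
  expect_equal(length(sl1$site_idx[[1]]), nrow(sites))
  # more slices than sites: warns and degrades
  expect_warning(slice_graph(sites[1:2, ], 5L, 100L, c(chr1 = 5000L)),
                 "fewer sites")
})
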