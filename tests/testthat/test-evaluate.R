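# Probe-based truth evaluation: probes, alignment, scoring, precision,
# genome mutation and recall.

random_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

test_that("block edit distance counts an indel run of any length as one", {
  expect_equal(block_edit_distance("ACGT", "ACGT"), 0L)
  expect_equal(block_edit_distance("ACGT", "AGGT"), 1L)
  expect_equal(block_edit_distance("A", "T"), 1L)
  # one long deletion: one edit
  expect_equal(block_edit_distance("ACGTACGTACGT", "ACGT"), 1L)
  # SNP plus separated gap: two edits
  expect_equal(block_edit_distance("TACGTACGA", "TACGA"), 1L)
  expect_equal(block_edit_distance("AACGTTTTTGCA", "ATCGGCA"), 2L)
  expect_equal(block_edit_distance("", ""), 0L)
  expect_equal(block_edit_distance("", "ACGT"), 1L)
})

test_that("probes embed the allele in flanks and truncate at contig edges", {
  set.seed(61)
  genome <- c(chr1 = random_seq(1000))
  p <- make_probes("chr1", 200L, substr(genome, 200, 200), "T", genome)
  expect_equal(nchar(p$alt$seq), 201L)
  expect_equal(p$alt$allele_start, 101L)
  expect_equal(p$alt$allele_end, 101L)
  # near the contig start the left flank is truncated
  p2 <- make_probes("chr1", 10L, substr(genome, 10, 10), "T", genome)
  expect_equal(p2$alt$allele_start, 10L)
  # a deletion's ref probe is longer than its alt probe by the deleted bases
  p3 <- make_probes("chr1", 300L, substr(genome, 300, 304),
                    substr(genome, 300, 300), genome)
  expect_equal(nchar(p3$ref$seq) - nchar(p3$alt$seq), 4L)
  expect_error(make_probes("chr1", 2000L, "A", "T", genome), "outside")
})

test_that("the printed partial-credit example scores one half", {
  # a 5bp allele; truth differs from the reference by two SNPs (A->T at
  # position 2, C->G at position 4); the call reports only the first
  set.seed(62)
  left <- random_seq(150)
  right <- random_seq(150)
  ref_allele <- "GATCA"
  truth_allele <- "GTTGA"
  called_allele <- "GTTCA"
  genome <- c(chr1 = paste0(left, ref_allele, right))
  truth <- c(chr1 = paste0(left, truth_allele, right))
  calls <- data.frame(chrom = "chr1", pos = 151L, ref = ref_allele,
                      alt = called_allele, stringsAsFactors = FALSE)
  ev <- evaluate_calls(calls, genome, truth)
  expect_equal(ev$per_call$d_ta, 1L)
  expect_equal(ev$per_call$d_tr, 2L)
  expect_equal(ev$per_call$score, 0.5)
  # the called allele matches truth at 4 of its 5 positions
  expect_equal(ev$per_call$allele_match, 4L)
  expect_equal(ev$per_call$allele_len, 5L)
})

test_that("clean true positives score one and pure false positives zero", {
  set.seed(63)
  genome <- c(chr1 = random_seq(600))
  ref_base <- substr(genome, 300, 300)
  alt_base <- setdiff(c("A", "C", "G", "T"), ref_base)[1]
  truth <- c(chr1 = paste0(substr(genome, 1, 299), alt_base,
                           substr(genome, 301, 600)))
  tp <- data.frame(chrom = "chr1", pos = 300L, ref = ref_base,
                   alt = alt_base, stringsAsFactors = FALSE)
  ev_tp <- evaluate_calls(tp, genome, truth)
  expect_equal(ev_tp$per_call$score, 1)
  expect_equal(ev_tp$per_call$d_ta, 0L)
  expect_equal(ev_tp$per_call$d_tr, 1L)
  # the same call against an unmutated truth: d_tr = 0, scores zero
  ev_fp <- evaluate_calls(tp, genome, genome)
  expect_equal(ev_fp$per_call$score, 0)
  expect_equal(ev_fp$per_call$d_tr, 0L)
  # one TP and one FP: precision one half
  other <- substr(genome, 450, 450)
  fp <- data.frame(chrom = "chr1", pos = 450L, ref = other,
                   alt = setdiff(c("A", "C", "G", "T"), other)[1],
                   stringsAsFactors = FALSE)
  ev <- evaluate_calls(rbind(tp, fp), genome, truth)
  expect_equal(ev$precision, 0.5)
})

test_that("a probe matching two repeat copies is discarded as ambiguous", {
  set.seed(64)
  pad1 <- random_seq(220)
  pad2 <- random_seq(220)
  pad3 <- random_seq(220)
  unit <- random_seq(250)   # longer than probe: both copies match fully
  genome <- c(chr1 = paste0(pad1, unit, pad2, unit, pad3))
  pos <- nchar(pad1) + 125L   # probe lies fully inside the unit
  ref_base <- substr(genome, pos, pos)
  calls <- data.frame(chrom = "chr1", pos = pos, ref = ref_base,
                      alt = setdiff(c("A", "C", "G", "T"), ref_base)[1],
                      stringsAsFactors = FALSE)
  # truth containing both copies mutated: the alt probe matches twice
  mut_unit <- unit
  substr(mut_unit, 125, 125) <- calls$alt
  truth <- c(chr1 = paste0(pad1, mut_unit, pad2, mut_unit, pad3))
  ev <- evaluate_calls(calls, genome, truth)
  expect_equal(ev$per_call$classification, "no-alt-mapping")
  expect_equal(ev$per_call$score, 0)
})

test_that("reverse-complemented truth contigs still score correctly", {
  set.seed(65)
  genome <- c(chr1 = random_seq(500))
  ref_base <- substr(genome, 250, 250)
  alt_base <- setdiff(c("A", "C", "G", "T"), ref_base)[1]
  truth_fwd <- paste0(substr(genome, 1, 249), alt_base,
                      substr(genome, 251, 500))
  truth <- c(chr1 = oracle_revcomp(truth_fwd))
  calls <- data.frame(chrom = "chr1", pos = 250L, ref = ref_base,
                      alt = alt_base, stringsAsFactors = FALSE)
  ev <- evaluate_calls(calls, genome, truth)
  expect_equal(ev$per_call$score, 1)
})

test_that("masks remove calls from both numerator and denominator", {
  set.seed(66)
  genome <- c(chr1 = random_seq(800))
  b1 <- substr(genome, 200, 200)
  b2 <- substr(genome, 600, 600)
  calls <- data.frame(chrom = "chr1", pos = c(200L, 600L),
                      ref = c(b1, b2),
                      alt = c(setdiff(c("A", "C", "G", "T"), b1)[1],
                              setdiff(c("A", "C", "G", "T"), b2)[1]),
                      stringsAsFactors = FALSE)
  truth <- apply_calls_to_genome(calls[1, ], genome)  # only first is real
  ev_all <- evaluate_calls(calls, genome, unclass(truth))
  expect_equal(ev_all$precision, 0.5)
  mask <- data.frame(chrom = "chr1", start = 590L, end = 610L)
  ev_masked <- evaluate_calls(calls, genome, unclass(truth),
                              mask_ref = mask)
  expect_equal(ev_masked$n_masked, 1L)
  expect_equal(ev_masked$precision, 1)
})

test_that("applying calls mutates the genome and round-trips variants", {
  set.seed(67)
  genome <- c(chr1 = random_seq(400))
  expect_equal(apply_calls_to_genome(
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character()), genome)[["chr1"]], genome[["chr1"]])
  b <- substr(genome, 100, 100)
  snp <- data.frame(chrom = "chr1", pos = 100L, ref = b,
                    alt = setdiff(c("A", "C", "G", "T"), b)[1],
                    stringsAsFactors = FALSE)
  mut <- apply_calls_to_genome(snp, genome)
  expect_equal(substr(mut[["chr1"]], 100, 100), snp$alt)
  expect_equal(nchar(mut[["chr1"]]), nchar(genome[["chr1"]]))
  # indel cocktail: deriving the difference back recovers the haplotype
  cocktail <- rbind(
    snp,
    data.frame(chrom = "chr1", pos = 200L,
               ref = substr(genome, 200, 205),
               alt = substr(genome, 200, 200), stringsAsFactors = FALSE),
    data.frame(chrom = "chr1", pos = 300L,
               ref = substr(genome, 300, 300),
               alt = paste0(substr(genome, 300, 300), "ACGTT"),
               stringsAsFactors = FALSE))
  mut2 <- apply_calls_to_genome(cocktail, genome)
  expect_equal(nchar(mut2[["chr1"]]), nchar(genome[["chr1"]]))
  # every implanted variant is found again by probe evaluation
  ev <- evaluate_calls(cocktail, genome, unclass(mut2))
  expect_true(all(ev$per_call$score == 1))
  # overlapping conflicting calls refuse to apply
  clash <- rbind(cocktail[2, ],
                 data.frame(chrom = "chr1", pos = 203L,
                            ref = substr(genome, 203, 203), alt = "A",
                            stringsAsFactors = FALSE))
  expect_error(apply_calls_to_genome(clash, genome), "conflicting")
})

test_that("recall is the mean probe score of the truth set against the
           mutated genome", {
  set.seed(68)
  genome <- c(chr1 = random_seq(3000))
  pos <- seq(200L, 2800L, by = 200L)   # 14 well-separated truth SNPs
  truth_calls <- do.call(rbind, lapply(pos, function(p) {
    b <- substr(genome, p, p)
    data.frame(chrom = "chr1", pos = p, ref = b,
               alt = setdiff(c("A", "C", "G", "T"), b)[1],
               stringsAsFactors = FALSE)
  }))
  # calling all truth variants: recall 1
  r_all <- recall_from_truth(truth_calls, truth_calls, genome)
  expect_equal(r_all$recall, 1)
  # calling half of them: recall one half
  half <- truth_calls[seq(1, nrow(truth_calls), by = 2), ]
  r_half <- recall_from_truth(truth_calls, half, genome)
  expect_equal(r_half$recall, nrow(half) / nrow(truth_calls))
  # calling nothing: recall 0
  r_none <- recall_from_truth(
    truth_calls,
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character()), genome)
  expect_equal(r_none$recall, 0)
})

test_that("evaluating a callset against its own mutated genome is perfect", {
  set.seed(69)
  genome <- c(chr1 = random_seq(2000))
  pos <- seq(150L, 1850L, by = 170L)
  calls <- do.call(rbind, lapply(seq_along(pos), function(i) {
    p <- pos[i]
    b <- substr(genome, p, p)
    if (i %% 3 == 0) {
      data.frame(chrom = "chr1", pos = p, ref = substr(genome, p, p + 3),
                 alt = b, stringsAsFactors = FALSE)
    } else if (i %% 3 == 1) {
      data.frame(chrom = "chr1", pos = p, ref = b,
                 alt = setdiff(c("A", "C", "G", "T"), b)[1],
                 stringsAsFactors = FALSE)
    } else {
      data.frame(chrom = "chr1", pos = p, ref = b,
                 alt = paste0(b, "GATTAC"), stringsAsFactors = FALSE)
    }
  }))
  mut <- apply_calls_to_genome(calls, genome)
  ev <- evaluate_calls(calls, genome, unclass(mut))
  expect_equal(ev$precision, 1)
  expect_true(all(ev$per_call$score <= 1))
})

test_that("a truth set can be built from an assembly pair with minimap2", {
  skip_if(Sys.which("minimap2") == "", "minimap2 not on PATH")
  set.seed(70)
  genome <- c(chr1 = random_seq(20000))
  # identical genomes: empty truth set
  none <- build_truth_set(genome, genome)
  expect_equal(nrow(none), 0L)
  # a single implanted SNP is recovered exactly
  b <- substr(genome, 10000, 10000)
  snp <- data.frame(chrom = "chr1", pos = 10000L, ref = b,
                    alt = setdiff(c("A", "C", "G", "T"), b)[1],
                    stringsAsFactors = FALSE)
  truth <- apply_calls_to_genome(snp, genome)
  got <- build_truth_set(genome, unclass(truth))
  expect_equal(got$pos, snp$pos)
  expect_equal(got$alt, snp$alt)
})
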