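# Seeded synthetic fixtures: random genomes, implanted truth variants,
# reads at negative-binomially distributed depth, and pseudo-caller VCFs
# with configurable recall / false-positive behaviour.  Everything is
# deterministic under a fixed seed, so the whole pipeline is testable with
# no external data.

#' Generate a random genome
#'
#' @param length genome length in bp (>= 1).
#' @param gc GC fraction (default 0.5).
#' @param chrom contig name.
#' @return named character vector with one contig.
#' @export
random_genome <- function(length, gc = 0.5, chrom = "chr1") {
  stopifnot(length >= 1)
  bases <- sample(c("A", "T", "G", "C"), length, replace = TRUE,
                  prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
  setNames(paste(bases, collapse = ""), chrom)
}

other_bases <- c(A = "CGT", C = "AGT", G = "ACT", T = "ACG")

random_snp_alt <- function(ref_base) {
  choices <- strsplit(other_bases[[ref_base]], "")[[1]]
  sample(choices, 1)
}

#' Implant truth variants into a genome
#'
#' Draws non-conflicting SNP and indel positions by rejection sampling
#' (plus an optional dense cluster of variants packed into a small
#' window), left-normalises the truth set against the input genome, and
#' applies it to produce the truth genome.
#'
#' @param genome named character vector (one contig).
#' @param n_snps,n_ins,n_del counts of each variant type.
#' @param indel_size two-element range of indel lengths (uniform).
#' @param cluster NULL, or `list(window=, n=)`: additionally packs `n`
#'   variants into one window of `window` bp.
#' @param margin variants are kept this far from the contig ends.
#' @return list with `truth_variants` (normalised data.frame) and
#'   `truth_genome`; `apply_calls_to_genome(truth_variants, genome)`
#'   equals `truth_genome` by construction.
#' @export
implant_variants <- function(genome, n_snps = 100L, n_ins = 10L,
                             n_del = 10L, indel_size = c(1L, 10L),
                             cluster = list(window = 10L, n = 5L),
                             margin = 200L) {
  chrom <- names(genome)[[1]]
  seqs <- genome[[chrom]]
  glen <- nchar(seqs)
  n_total <- n_snps + n_ins + n_del
  if (glen < margin * 2 + 20 * n_total) {
    stop("genome too short for the requested variant density")
  }
  taken_start <- integer(); taken_end <- integer()
  reserve <- function(s, e) {
    # 1bp guard band so adjacent truth variants stay distinct sites
    ok <- !any(taken_start <= e + 1L & taken_end >= s - 1L)
    if (ok) {
      taken_start <<- c(taken_start, s)
      taken_end <<- c(taken_end, e)
    }
    ok
  }
  vars <- list()
  add_snp <- function(pos) {
    ref <- substr(seqs, pos, pos)
    vars[[length(vars) + 1L]] <<- data.frame(
      chrom = chrom, pos = pos, ref = ref, alt = random_snp_alt(ref),
      stringsAsFactors = FALSE)
  }
  add_indel <- function(pos, is_ins) {
    size <- sample(seq.int(indel_size[1], indel_size[2]), 1)
    anchor <- substr(seqs, pos, pos)
    if (is_ins) {
      ins <- paste(sample(c("A", "C", "G", "T"), size, replace = TRUE),
                   collapse = "")
      v <- left_normalize(chrom, pos, anchor, paste0(anchor, ins), genome)
    } else {
      del <- substr(seqs, pos, pos + size)
      v <- left_normalize(chrom, pos, del, anchor, genome)
    }
    vars[[length(vars) + 1L]] <<- v
  }
  draw <- function(n, width_fn, place_fn) {
    placed <- 0L
    tries <- 0L
    while (placed < n) {
      tries <- tries + 1L
      if (tries > 200L * n + 1000L) {
        stop("variant density infeasible: rejection sampling failed")
      }
      pos <- sample(seq.int(margin, glen - margin), 1)
      w <- width_fn()
      if (!reserve(pos - 1L, pos + w)) next   # pad for normalisation shift
      place_fn(pos)
      placed <- placed + 1L
    }
  }
  if (!is.null(cluster) && cluster$n > 0) {
    # a dense window: alternating SNPs / 1bp indels at adjacent offsets
    repeat {
      cpos <- sample(seq.int(margin, glen - margin - cluster$window), 1)
      if (reserve(cpos - 2L, cpos + cluster$window + 2L)) break
    }
    offs <- sort(sample(seq.int(0L, cluster$window - 1L),
                        min(cluster$n, cluster$window)))
    # SNPs at distinct offsets, at least one 1bp deletion if room
    for (k in seq_along(offs)) {
      p <- cpos + offs[k]
      if (k == length(offs) && length(offs) >= 2 &&
          offs[k] - offs[k - 1L] >= 2L) {
        del <- substr(seqs, p, p + 1L)
        vars[[length(vars) + 1L]] <- left_normalize(
          chrom, p, del, substr(seqs, p, p), genome)
      } else {
        add_snp(p)
      }
    }
  }
  draw(n_snps, function() 1L, add_snp)
  draw(n_ins, function() 2L, function(pos) add_indel(pos, TRUE))
  draw(n_del, function() indel_size[2] + 2L,
       function(pos) add_indel(pos, FALSE))
  truth <- if (length(vars)) dedup_variants(do.call(rbind, vars)) else
    empty_variants()
  truth$origins <- NULL
  list(truth_variants = truth,
       truth_genome = unclass_shift(apply_calls_to_genome(truth, genome)))
}

unclass_shift <- function(x) { attr(x, "shift") <- NULL; x }

#' Simulate reads from a genome
#'
#' Per-window read-start counts are drawn from the negative binomial the
#' genotype model assumes (windows of one read length, so the window count
#' approximates per-position depth); start positions are uniform within
#' the window, strands equiprobable, and sequencing errors are injected
#' per base at a flat rate.
#'
#' @param genome named character vector (one contig).
#' @param read_length read length (default 100).
#' @param depth mean depth `d` (default 30).
#' @param depth_var depth variance `sigma^2` (default 45; must exceed
#'   `depth` for the negative binomial).
#' @param error_rate per-base error probability (default 0).
#' @return character vector of read sequences.
#' @export
simulate_reads <- function(genome, read_length = 100L, depth = 30,
                           depth_var = 45, error_rate = 0) {
  seqs <- genome[[1]]
  glen <- nchar(seqs)
  stopifnot(read_length <= glen, depth_var > depth)
  size <- depth^2 / (depth_var - depth)
  win_starts <- seq.int(1L, glen - read_length + 1L, by = read_length)
  reads <- character()
  for (ws in win_starts) {
    n_here <- stats::rnbinom(1, size = size, mu = depth)
    if (n_here == 0) next
    starts <- ws + sample.int(read_length, n_here, replace = TRUE) - 1L
    starts <- pmin(starts, glen - read_length + 1L)
    r <- substring(seqs, starts, starts + read_length - 1L)
    reads <- c(reads, r)
  }
  if (error_rate > 0) {
    reads <- vapply(reads, function(r) {
      hit <- which(stats::runif(nchar(r)) < error_rate)
      for (h in hit) {
        substr(r, h, h) <- random_snp_alt(substr(r, h, h))
      }
      r
    }, character(1), USE.NAMES = FALSE)
  }
  flip <- stats::runif(length(reads)) < 0.5
  if (any(flip)) reads[flip] <- revcomp(reads[flip])
  reads
}

# re-encode an indel in an equivalent right-shifted (non-left-aligned,
# non-parsimonious) representation, as some callers emit: drop the shared
# anchor base and append the next reference base to both alleles
right_shift_variant <- function(v, genome, shift = 2L) {
  seqs <- genome[[v$chrom]]
  pos <- v$pos; ref <- v$ref; alt <- v$alt
  if (nchar(ref) == nchar(alt)) return(v)   # SNP: nothing to shift
  for (s in seq_len(shift)) {
    # equivalence of the shifted encoding needs a shared leading base
    if (substr(ref, 1L, 1L) != substr(alt, 1L, 1L)) break
    nxt_at <- pos + nchar(ref)
    if (nxt_at > nchar(seqs)) break
    nxt <- substr(seqs, nxt_at, nxt_at)
    pos <- pos + 1L
    ref <- paste0(substr(ref, 2L, nchar(ref)), nxt)
    alt <- paste0(substr(alt, 2L, nchar(alt)), nxt)
  }
  data.frame(chrom = v$chrom, pos = pos, ref = ref, alt = alt,
             stringsAsFactors = FALSE)
}

#' Make pseudo-caller VCFs from a truth set
#'
#' Each pseudo-caller keeps a fraction (`recall`) of the truth variants,
#' adds false calls at `fp_rate` per truth variant, and can re-encode
#' indels right-shifted to exercise normalisation.  With
#' `complementary = TRUE` and two callers, the variants missed by the two
#' callers are disjoint, so their union covers the whole truth set.
#'
#' @param truth_variants normalised truth data.frame.
#' @param genome mapping genome (named character vector).
#' @param out_dir directory for the VCF files.
#' @param recall per-caller true-positive fraction (default 0.8).
#' @param fp_rate false calls per truth variant (default 0.05).
#' @param n_callers number of pseudo-callers (default 2).
#' @param complementary make the callers' missed sets disjoint.
#' @param styles per-caller representation: "normalized" or
#'   "right_shifted".
#' @return character vector of VCF paths.
#' @export
make_caller_vcfs <- function(truth_variants, genome, out_dir,
                             recall = 0.8, fp_rate = 0.05, n_callers = 2L,
                             complementary = TRUE,
                             styles = c("normalized", "right_shifted")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  n <- nrow(truth_variants)
  n_miss <- round((1 - recall) * n)
  miss_sets <- vector("list", n_callers)
  if (complementary && n_callers * n_miss <= n) {
    pool <- sample.int(n)
    for (k in seq_len(n_callers)) {
      miss_sets[[k]] <- if (n_miss > 0) {
        pool[seq.int((k - 1L) * n_miss + 1L, k * n_miss)]
      } else integer()
    }
  } else {
    for (k in seq_len(n_callers)) {
      miss_sets[[k]] <- sample.int(n, n_miss)
    }
  }
  styles <- rep_len(styles, n_callers)
  chrom <- names(genome)[[1]]
  glen <- nchar(genome[[chrom]])
  occupied <- unlist(mapply(seq.int, truth_variants$pos,
                            truth_variants$pos +
                              nchar(truth_variants$ref) - 1L,
                            SIMPLIFY = FALSE))
  paths <- character(n_callers)
  for (k in seq_len(n_callers)) {
    tp <- truth_variants[setdiff(seq_len(n), miss_sets[[k]]), ,
                         drop = FALSE]
    if (styles[k] == "right_shifted") {
      tp <- do.call(rbind, lapply(seq_len(nrow(tp)), function(i) {
        right_shift_variant(tp[i, , drop = FALSE], genome)
      }))
    }
    n_fp <- round(fp_rate * n)
    fps <- list()
    while (length(fps) < n_fp) {
      pos <- sample(seq.int(200L, glen - 200L), 1)
      if (any(abs(pos - occupied) < 3L)) next
      ref <- substr(genome[[chrom]], pos, pos)
      if (stats::runif(1) < 0.7) {
        fps[[length(fps) + 1L]] <- data.frame(
          chrom = chrom, pos = pos, ref = ref,
          alt = random_snp_alt(ref), stringsAsFactors = FALSE)
      } else {   # small false deletion
        del <- substr(genome[[chrom]], pos, pos + 2L)
        fps[[length(fps) + 1L]] <- data.frame(
          chrom = chrom, pos = pos, ref = del, alt = ref,
          stringsAsFactors = FALSE)
      }
    }
    calls <- rbind(tp[, c("chrom", "pos", "ref", "alt")],
                   if (length(fps)) do.call(rbind, fps))
    calls <- calls[order(calls$pos), , drop = FALSE]
    path <- file.path(out_dir, sprintf("caller%d.vcf", k))
    write_caller_vcf(calls, genome, path, sample_name = sprintf("s%d", k))
    paths[k] <- path
  }
  paths
}

# minimal single-sample VCF with haploid 1 genotypes
write_caller_vcf <- function(calls, reference, path,
                             sample_name = "sample") {
  hdr <- c(vcf_header(reference,
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">'),
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
           sample_name))
  recs <- if (nrow(calls)) {
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT\t1", calls$chrom,
            calls$pos, calls$ref, calls$alt)
  } else character()
  writeLines(c(hdr, recs), path)
  invisible(path)
}

#' Generate a complete synthetic fixture bundle
#'
#' Writes a mapping genome, truth genome, truth VCF, reads FASTQ and
#' pseudo-caller VCFs to `out_dir`, plus a cohort manifest TSV, all
#' deterministic under `seed`.
#'
#' @param out_dir output directory.
#' @param seed RNG seed.
#' @param genome_length,gc genome spec.
#' @param n_snps,n_ins,n_del,indel_size,cluster variant spec
#'   (see [implant_variants()]).
#' @param read_length,depth,depth_var,error_rate read spec
#'   (see [simulate_reads()]).
#' @param recall,fp_rate,n_callers,complementary,styles callset spec
#'   (see [make_caller_vcfs()]).
#' @return list of file paths plus the in-memory `genome`,
#'   `truth_variants` and `truth_genome`.
#' @export
simulate_bundle <- function(out_dir, seed = 1L, genome_length = 100000L,
                            gc = 0.5, n_snps = 300L, n_ins = 25L,
                            n_del = 25L, indel_size = c(1L, 10L),
                            cluster = list(window = 10L, n = 5L),
                            read_length = 100L, depth = 30,
                            depth_var = 45, error_rate = 0,
                            recall = 0.8, fp_rate = 0.05, n_callers = 2L,
                            complementary = TRUE,
                            styles = c("normalized", "right_shifted")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  withr_seed(seed, {
    genome <- random_genome(genome_length, gc)
    imp <- implant_variants(genome, n_snps = n_snps, n_ins = n_ins,
                            n_del = n_del, indel_size = indel_size,
                            cluster = cluster)
    reads <- simulate_reads(imp$truth_genome, read_length = read_length,
                            depth = depth, depth_var = depth_var,
                            error_rate = error_rate)
    ref_fa <- file.path(out_dir, "ref.fa")
    truth_fa <- file.path(out_dir, "truth.fa")
    reads_fq <- file.path(out_dir, "reads.fastq")
    truth_vcf <- file.path(out_dir, "truth.vcf")
    write_fasta(genome, ref_fa)
    write_fasta(imp$truth_genome, truth_fa)
    write_fastq(reads, reads_fq)
    write_caller_vcf(imp$truth_variants, genome, truth_vcf,
                     sample_name = "truth")
    vcfs <- make_caller_vcfs(imp$truth_variants, genome, out_dir,
                             recall = recall, fp_rate = fp_rate,
                             n_callers = n_callers,
                             complementary = complementary,
                             styles = styles)
    manifest <- file.path(out_dir, "manifest.tsv")
    utils::write.table(
      data.frame(name = sprintf("caller%d", seq_along(vcfs)),
                 vcf = vcfs, reads = reads_fq),
      manifest, sep = "\t", quote = FALSE, row.names = FALSE)
    list(ref_fasta = ref_fa, truth_fasta = truth_fa, reads_fastq = reads_fq,
         truth_vcf = truth_vcf, caller_vcfs = vcfs, manifest = manifest,
         genome = genome, truth_variants = imp$truth_variants,
         truth_genome = imp$truth_genome, reads = reads)
  })
}
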