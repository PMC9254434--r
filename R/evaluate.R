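# Probe-based evaluation of a callset against a haploid truth genome.
#
# Each call becomes an "alt probe" (called allele embedded in flanking
# reference sequence) and a "ref probe" (reference allele, same flanks).
# Both are aligned to the truth genome; the truth allele observed at the
# aligned location yields edit distances d(truth, alt) and d(truth, ref),
# and the call's score is 1 - d(t,a)/d(t,r).  An insertion or deletion of
# any length counts as one edit, so long indels do not dominate.

#' Edit distance where an indel run of any length counts one
#'
#' Minimises (number of substituted positions) + (number of maximal gap
#' runs): a three-state alignment with unit mismatch cost, unit gap-open
#' cost and zero gap extension.
#'
#' @param a,b sequences.
#' @return non-negative integer distance.
#' @export
block_edit_distance <- function(a, b) {
  x <- strsplit(a, "", fixed = TRUE)[[1]]
  y <- strsplit(b, "", fixed = TRUE)[[1]]
  n <- length(x); m <- length(y)
  if (n == 0 && m == 0) return(0L)
  if (n == 0 || m == 0) return(1L)
  INF <- .Machine$integer.max %/% 2L
  M <- matrix(INF, n + 1L, m + 1L)   # last column pair aligned
  I <- matrix(INF, n + 1L, m + 1L)   # gap in a (insertion in b)
  D <- matrix(INF, n + 1L, m + 1L)   # gap in b (deletion from a)
  M[1L, 1L] <- 0L
  for (j in 2L:(m + 1L)) I[1L, j] <- 1L
  for (i in 2L:(n + 1L)) D[i, 1L] <- 1L
  for (i in 2L:(n + 1L)) {
    for (j in 2L:(m + 1L)) {
      sub <- as.integer(x[i - 1L] != y[j - 1L])
      M[i, j] <- min(M[i - 1L, j - 1L], I[i - 1L, j - 1L],
                     D[i - 1L, j - 1L]) + sub
      I[i, j] <- min(M[i, j - 1L] + 1L, I[i, j - 1L], D[i, j - 1L] + 1L)
      D[i, j] <- min(M[i - 1L, j] + 1L, D[i - 1L, j], I[i - 1L, j] + 1L)
    }
  }
  min(M[n + 1L, m + 1L], I[n + 1L, m + 1L], D[n + 1L, m + 1L])
}

# truth alleles from minus-strand alignments are reported in probe
# orientation so edit distances compare like with like
orient_allele <- function(allele, strand) {
  if (strand == "-" && nchar(allele)) revcomp(allele) else allele
}

# all (non-overlapping) occurrences of a literal pattern in subject
find_fixed <- function(pattern, subject) {
  hits <- gregexpr(pattern, subject, fixed = TRUE)[[1]]
  if (hits[1] == -1L) integer() else as.integer(hits)
}

#' Build alt and ref probes for one call
#'
#' @param chrom,pos,ref,alt the call (1-based, normalised).
#' @param mapping_genome named character vector of contig sequences.
#' @param flank flank length taken verbatim from the mapping genome
#'   (default 100); truncated at contig edges.
#' @return list of two probes (`alt`, `ref`), each a list with `seq`,
#'   `allele_start`, `allele_end` (1-based interval of the allele within
#'   the probe; `allele_end = allele_start - 1` for an empty allele).
#' @export
make_probes <- function(chrom, pos, ref, alt, mapping_genome, flank = 100L) {
  seqs <- mapping_genome[[chrom]]
  if (is.null(seqs)) stop("call on unknown contig: ", chrom)
  pos <- as.integer(pos)
  if (pos < 1 || pos + nchar(ref) - 1L > nchar(seqs)) {
    stop("call outside mapping genome: ", chrom, ":", pos)
  }
  lf <- substr(seqs, max(1L, pos - flank), pos - 1L)
  rf <- substr(seqs, pos + nchar(ref),
               min(nchar(seqs), pos + nchar(ref) + flank - 1L))
  probe <- function(allele) {
    list(seq = paste0(lf, allele, rf),
         allele_start = nchar(lf) + 1L,
         allele_end = nchar(lf) + nchar(allele))
  }
  list(alt = probe(alt), ref = probe(ref))
}

# Align pattern (probe) to a truth window with explicit scoring; returns
# NULL or list(truth_start, truth_end, pat_start, pat_end, score,
# allele_match, truth_allele) where coordinates are in truth-genome space.
align_probe_window <- function(probe, truth_seq, win_start, win_end,
                               strand) {
  window <- substr(truth_seq, win_start, win_end)
  submat <- Biostrings::nucleotideSubstitutionMatrix(match = 2,
                                                     mismatch = -2)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(probe$seq), Biostrings::DNAString(window),
    type = "local", substitutionMatrix = submat,
    gapOpening = 4, gapExtension = 2)
  pat <- Biostrings::pattern(al)
  subj <- Biostrings::subject(al)
  pstart <- Biostrings::start(pat); pend <- Biostrings::end(pat)
  sstart <- Biostrings::start(subj); send <- Biostrings::end(subj)
  pa <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
  # allele inclusion: aligned pattern region must contain the allele
  a1 <- probe$allele_start; a2 <- probe$allele_end
  included <- pstart <= a1 && pend >= max(a2, a1 - 1L) &&
    (a2 >= a1 || (pstart < a1 && pend >= a1))  # empty allele: span junction
  # walk columns: pattern position per column
  ppos <- cumsum(pa != "-") + pstart - 1L
  if (a2 >= a1) {
    core <- which(pa != "-" & ppos >= a1 & ppos <= a2)
    in_allele <- logical(length(pa))
    if (length(core)) {
      in_allele[min(core):max(core)] <- TRUE
      # subject insertions contiguous with the allele's right edge belong
      # to the allele (left-anchored VCF places variation after the anchor)
      k <- max(core) + 1L
      while (k <= length(pa) && pa[k] == "-") {
        in_allele[k] <- TRUE
        k <- k + 1L
      }
    }
  } else {
    in_allele <- pa == "-" & ppos == a1 - 1L   # empty allele: junction gaps
  }
  truth_allele <- paste(sa[in_allele & sa != "-"], collapse = "")
  allele_match <- sum(in_allele & pa != "-" & pa == sa)
  list(truth_start = win_start + sstart - 1L,
       truth_end = win_start + send - 1L,
       pat_start = pstart, pat_end = pend,
       score = Biostrings::score(al), included = included,
       allele_match = allele_match, truth_allele = truth_allele,
       strand = strand)
}

#' Align a probe to the truth genome
#'
#' Exact full-probe matches are found first (both strands); a unique exact
#' match is a perfect alignment, while two or more exact matches at
#' distinct loci are discarded as ambiguous (the zero-mapping-quality
#' analog).  Otherwise candidate loci are located with exact seed k-mers
#' and each is aligned locally; alignments that do not include the whole
#' allele are discarded, a score tie between distinct loci is discarded as
#' ambiguous, and the survivor with the greatest number of allele
#' positions matching the truth wins.
#'
#' @param probe from [make_probes()].
#' @param truth_genome named character vector (all contigs searched) or a
#'   single sequence string.
#' @param seed_k seed length for candidate location (default 18).
#' @param required_start if not NULL, only alignments whose truth start
#'   equals this are considered (used for the ref probe).
#' @return alignment list (see `align_probe_window`) or NULL.
#' @export
align_probe <- function(probe, truth_genome, seed_k = 18L,
                        required_start = NULL) {
  if (is.null(names(truth_genome))) names(truth_genome) <- "truth"
  oriented <- list("+" = probe,
                   "-" = {
                     pseq <- revcomp(probe$seq)
                     list(seq = pseq,
                          allele_start = nchar(pseq) - probe$allele_end + 1L,
                          allele_end = nchar(pseq) - probe$allele_start + 1L)
                   })
  cands <- list()
  # phase 1: exact full-probe matches anywhere
  for (contig in names(truth_genome)) {
    tseq <- truth_genome[[contig]]
    for (strand in c("+", "-")) {
      pr <- oriented[[strand]]
      hits <- find_fixed(pr$seq, tseq)
      plen <- nchar(pr$seq)
      for (h in hits) {
        cands[[length(cands) + 1L]] <- list(
          contig = contig, truth_start = h, truth_end = h + plen - 1L,
          pat_start = 1L, pat_end = plen, score = 2 * plen,
          included = TRUE,
          allele_match = max(0L, pr$allele_end - pr$allele_start + 1L),
          truth_allele = orient_allele(
            substr(tseq, h + pr$allele_start - 1L,
                   h + pr$allele_end - 1L), strand),
          strand = strand, exact = TRUE)
      }
    }
  }
  # phase 2: seeded inexact alignment, only when nothing matched exactly
  if (!length(cands)) {
    for (contig in names(truth_genome)) {
      tseq <- truth_genome[[contig]]
      for (strand in c("+", "-")) {
        pr <- oriented[[strand]]
        pseq <- pr$seq
        plen <- nchar(pseq)
        k <- min(seed_k, plen)
        seed_at <- unique(pmax(1L, pmin(plen - k + 1L,
          as.integer(round(seq(1L, plen - k + 1L, length.out = 5))))))
        starts <- integer()
        for (sp in seed_at) {
          seed <- substr(pseq, sp, sp + k - 1L)
          sh <- find_fixed(seed, tseq)
          starts <- c(starts, sh - sp + 1L)
        }
        starts <- sort(unique(starts))
        if (!length(starts)) next
        # merge nearby candidate starts
        grp <- cumsum(c(TRUE, diff(starts) > 30L))
        for (g in unique(grp)) {
          cand <- as.integer(round(mean(starts[grp == g])))
          margin <- 40L
          ws <- max(1L, cand - margin)
          we <- min(nchar(tseq), cand + plen + margin)
          aln <- align_probe_window(pr, tseq, ws, we, strand)
          aln$truth_allele <- orient_allele(aln$truth_allele, strand)
          aln$contig <- contig
          aln$exact <- FALSE
          cands[[length(cands) + 1L]] <- aln
        }
      }
    }
  }
  if (!length(cands)) return(NULL)
  if (!is.null(required_start)) {
    cands <- Filter(function(x) x$truth_start == required_start, cands)
    if (!length(cands)) return(NULL)
  }
  scores <- vapply(cands, function(x) x$score, numeric(1))
  top <- max(scores)
  top_loci <- unique(vapply(cands[scores >= top - 1e-9], function(x) {
    paste(x$contig, x$truth_start, sep = ":")
  }, character(1)))
  if (length(top_loci) >= 2) return(NULL)   # ambiguous placement
  cands <- Filter(function(x) isTRUE(x$included), cands)
  if (!length(cands)) return(NULL)
  am <- vapply(cands, function(x) x$allele_match, numeric(1))
  sc <- vapply(cands, function(x) x$score, numeric(1))
  cands[[order(-am, -sc)[1]]]
}

#' Score one call from its probe alignments
#'
#' No alt-probe alignment: false positive, score 0.  Alt aligns but the
#' ref probe has no alignment starting at the same truth position: clean
#' true positive, score 1.  Otherwise the truth allele at the aligned
#' location gives `d_ta = d(truth, alt)` and `d_tr = d(truth, ref)`
#' (indels of any length count one) and the score is `1 - d_ta/d_tr`
#' (zero when `d_tr = 0`; can be negative for very wrong calls).
#'
#' @param alt_aln,ref_aln results of [align_probe()] (either may be NULL).
#' @param alt_allele,ref_allele the call's allele sequences.
#' @return list with `classification`, `d_ta`, `d_tr`, `score`,
#'   `numerator`, `denominator` (the aggregation fractions) plus
#'   `allele_match` and `allele_len` from the alt alignment.
#' @export
score_call <- function(alt_aln, ref_aln, alt_allele, ref_allele) {
  if (is.null(alt_aln)) {
    return(list(classification = "no-alt-mapping", d_ta = NA_integer_,
                d_tr = NA_integer_, score = 0, numerator = 0,
                denominator = 1, allele_match = NA_integer_,
                allele_len = nchar(alt_allele)))
  }
  if (is.null(ref_aln)) {
    return(list(classification = "alt-only-mapping", d_ta = NA_integer_,
                d_tr = NA_integer_, score = 1, numerator = 1,
                denominator = 1, allele_match = alt_aln$allele_match,
                allele_len = nchar(alt_allele)))
  }
  # the truth allele is read off the alt probe's alignment; the ref probe
  # alignment only establishes that the locus is comparable
  truth_allele <- alt_aln$truth_allele
  d_ta <- block_edit_distance(truth_allele, alt_allele)
  d_tr <- block_edit_distance(truth_allele, ref_allele)
  if (d_tr == 0) {
    return(list(classification = "scored", d_ta = d_ta, d_tr = d_tr,
                score = 0, numerator = 0, denominator = 1,
                allele_match = alt_aln$allele_match,
                allele_len = nchar(alt_allele)))
  }
  list(classification = "scored", d_ta = d_ta, d_tr = d_tr,
       score = 1 - d_ta / d_tr, numerator = d_tr - d_ta,
       denominator = d_tr, allele_match = alt_aln$allele_match,
       allele_len = nchar(alt_allele))
}

#' Evaluate a callset against a truth genome
#'
#' Probe-maps every call, scores it, and aggregates precision as the sum
#' of numerators over the sum of denominators.  Calls intersecting a mask
#' of the mapping genome, or whose alt probe aligns inside a mask of the
#' truth genome, are excluded.
#'
#' @param calls data.frame with columns `chrom`, `pos`, `ref`, `alt`
#'   (1-based, e.g. from [final_calls()]), or a VCF path.
#' @param mapping_genome,truth_genome named character vectors or FASTA
#'   paths.
#' @param flank probe flank length (default 100).
#' @param mask_ref,mask_truth optional masks ([read_mask()] input).
#' @return list of class `call_evaluation`: `per_call` data.frame,
#'   `precision`, `numerator`, `denominator`, `n_evaluated`, `n_masked`.
#' @export
evaluate_calls <- function(calls, mapping_genome, truth_genome,
                           flank = 100L, mask_ref = NULL,
                           mask_truth = NULL) {
  mapping_genome <- as_genome(mapping_genome)
  truth_genome <- as_genome(truth_genome)
  if (is.character(calls) && length(calls) == 1 && file.exists(calls)) {
    calls <- load_calls(calls, mapping_genome, require_gt = FALSE)
  }
  mask_ref <- read_mask(mask_ref)
  mask_truth <- read_mask(mask_truth)
  rows <- list()
  n_masked <- 0L
  for (i in seq_len(nrow(calls))) {
    pos <- calls$pos[i]; ref <- calls$ref[i]; alt <- calls$alt[i]
    chrom <- calls$chrom[i]
    mp <- mask_positions(mask_ref, chrom)
    if (length(mp) && any(seq.int(pos, pos + nchar(ref) - 1L) %in% mp)) {
      n_masked <- n_masked + 1L
      next
    }
    probes <- make_probes(chrom, pos, ref, alt, mapping_genome, flank)
    alt_aln <- align_probe(probes$alt, truth_genome)
    if (!is.null(alt_aln) && nrow(mask_truth)) {
      tp <- mask_positions(mask_truth, alt_aln$contig)
      if (length(tp) &&
          any(seq.int(alt_aln$truth_start, alt_aln$truth_end) %in% tp)) {
        n_masked <- n_masked + 1L
        next
      }
    }
    ref_aln <- if (is.null(alt_aln)) NULL else {
      align_probe(probes$ref, truth_genome,
                  required_start = alt_aln$truth_start)
    }
    sc <- score_call(alt_aln, ref_aln, alt, ref)
    rows[[length(rows) + 1L]] <- data.frame(
      chrom = chrom, pos = pos, ref = ref, alt = alt,
      classification = sc$classification, d_ta = sc$d_ta, d_tr = sc$d_tr,
      score = sc$score, numerator = sc$numerator,
      denominator = sc$denominator, allele_match = sc$allele_match,
      allele_len = sc$allele_len, stringsAsFactors = FALSE)
  }
  per_call <- if (length(rows)) do.call(rbind, rows) else
    data.frame(chrom = character(), pos = integer(), ref = character(),
               alt = character(), classification = character(),
               d_ta = integer(), d_tr = integer(), score = numeric(),
               numerator = numeric(), denominator = numeric(),
               allele_match = integer(), allele_len = integer(),
               stringsAsFactors = FALSE)
  den <- sum(per_call$denominator)
  structure(list(per_call = per_call,
                 precision = if (den > 0) sum(per_call$numerator) / den
                             else NA_real_,
                 numerator = sum(per_call$numerator), denominator = den,
                 n_evaluated = nrow(per_call), n_masked = n_masked),
            class = "call_evaluation")
}

#' @export
print.call_evaluation <- function(x, ...) {
  cat(sprintf("call_evaluation: %d call(s), precision %.4f\n",
              x$n_evaluated, x$precision))
  invisible(x)
}

as_genome <- function(x) {
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    read_reference(x)
  } else {
    toupper(x)
  }
}

#' Apply calls to a genome
#'
#' Substitutes every called alternate allele into the mapping genome,
#' producing the "mutated" genome used by the recall computation.
#'
#' @param calls data.frame with `chrom`, `pos`, `ref`, `alt`.
#' @param mapping_genome named character vector or FASTA path.
#' @return named character vector of mutated contigs, with an attribute
#'   `shift` (data.frame of per-call coordinate offsets in the mutated
#'   genome).
#' @export
apply_calls_to_genome <- function(calls, mapping_genome) {
  mapping_genome <- as_genome(mapping_genome)
  out <- mapping_genome
  shifts <- list()
  for (chrom in unique(calls$chrom)) {
    v <- calls[calls$chrom == chrom, , drop = FALSE]
    v <- v[order(v$pos), , drop = FALSE]
    ends <- v$pos + nchar(v$ref) - 1L
    if (nrow(v) > 1 && any(v$pos[-1] <= cummax(ends)[-nrow(v)])) {
      bad <- which(v$pos[-1] <= cummax(ends)[-nrow(v)])[1]
      stop(sprintf("conflicting overlapping calls at %s:%d and %s:%d",
                   chrom, v$pos[bad], chrom, v$pos[bad + 1L]))
    }
    seqs <- mapping_genome[[chrom]]
    if (any(substr(rep(seqs, nrow(v)), v$pos, ends) != v$ref)) {
      stop("call REF does not match the mapping genome on ", chrom)
    }
    pieces <- character()
    cursor <- 1L
    offset <- 0L
    for (i in seq_len(nrow(v))) {
      pieces <- c(pieces, substr(seqs, cursor, v$pos[i] - 1L), v$alt[i])
      shifts[[length(shifts) + 1L]] <- data.frame(
        chrom = chrom, pos = v$pos[i], offset = offset,
        stringsAsFactors = FALSE)
      offset <- offset + nchar(v$alt[i]) - nchar(v$ref[i])
      cursor <- ends[i] + 1L
    }
    pieces <- c(pieces, substr(seqs, cursor, nchar(seqs)))
    out[[chrom]] <- paste(pieces, collapse = "")
  }
  attr(out, "shift") <- if (length(shifts)) do.call(rbind, shifts) else
    data.frame(chrom = character(), pos = integer(), offset = integer())
  out
}

#' Recall of a callset against a truth variant set
#'
#' The evaluated calls are applied to the mapping genome to make a
#' "mutated" genome; every truth variant is then probe-evaluated with the
#' mutated genome standing in for the truth.  Recall is the mean score
#' over the truth variants considered.
#'
#' @param truth_calls truth variants (data.frame `chrom`/`pos`/`ref`/`alt`
#'   or VCF path; must be expressed against the mapping genome).
#' @param calls the callset under evaluation (same formats).
#' @param mapping_genome named character vector or FASTA path.
#' @param flank probe flank length.
#' @param mask_ref optional mapping-genome mask.
#' @return list of class `recall_result`: `recall`, `per_call`,
#'   `n_considered`.
#' @export
recall_from_truth <- function(truth_calls, calls, mapping_genome,
                              flank = 100L, mask_ref = NULL) {
  mapping_genome <- as_genome(mapping_genome)
  if (is.character(calls) && length(calls) == 1 && file.exists(calls)) {
    calls <- load_calls(calls, mapping_genome, require_gt = FALSE)
  }
  if (is.character(truth_calls) && length(truth_calls) == 1 &&
      file.exists(truth_calls)) {
    truth_calls <- load_calls(truth_calls, mapping_genome,
                              require_gt = FALSE)
  }
  mutated <- apply_calls_to_genome(calls, mapping_genome)
  ev <- evaluate_calls(truth_calls, mapping_genome, unclass(mutated),
                       flank = flank, mask_ref = mask_ref)
  n <- nrow(ev$per_call)
  structure(list(recall = if (n > 0) sum(ev$per_call$score) / n
                          else NA_real_,
                 per_call = ev$per_call, n_considered = n),
            class = "recall_result")
}

#' @export
print.recall_result <- function(x, ...) {
  cat(sprintf("recall_result: %.4f over %d truth variant(s)\n",
              x$recall, x$n_considered))
  invisible(x)
}

#' Build a truth variant set from a truth assembly (external aligner)
#'
#' Calls variants between the mapping and truth genomes with minimap2
#' (`-c --cs`), parses the alignment difference strings, left-normalises,
#' and keeps only candidates whose probe evaluation against the truth
#' genome scores exactly one.  Candidates with conflicting calls at the
#' same position are dropped.  Requires `minimap2` on the PATH; if it is
#' missing, supply a truth VCF yourself instead.
#'
#' @param mapping_genome,truth_genome named character vectors or FASTA
#'   paths.
#' @param flank probe flank for the perfect-score filter.
#' @return truth variant data.frame (`chrom`, `pos`, `ref`, `alt`).
#' @export
build_truth_set <- function(mapping_genome, truth_genome, flank = 100L) {
  if (Sys.which("minimap2") == "") {
    stop("minimap2 not found on PATH; supply a truth VCF instead of ",
         "building one from the assemblies")
  }
  mapping_genome <- as_genome(mapping_genome)
  truth_genome <- as_genome(truth_genome)
  ref_fa <- tempfile(fileext = ".fa")
  qry_fa <- tempfile(fileext = ".fa")
  on.exit(unlink(c(ref_fa, qry_fa)))
  write_fasta(mapping_genome, ref_fa)
  write_fasta(truth_genome, qry_fa)
  paf <- system2("minimap2", c("-c", "--cs", "-x", "asm5", ref_fa, qry_fa),
                 stdout = TRUE, stderr = FALSE)
  cand <- parse_cs_variants(paf, mapping_genome)
  if (!nrow(cand)) return(cand)
  cand <- dedup_variants(cand)
  # drop same-position conflicts
  key_pos <- paste(cand$chrom, cand$pos)
  cand <- cand[!key_pos %in% key_pos[duplicated(key_pos)], , drop = FALSE]
  # keep only perfect-score candidates
  keep <- vapply(seq_len(nrow(cand)), function(i) {
    probes <- make_probes(cand$chrom[i], cand$pos[i], cand$ref[i],
                          cand$alt[i], mapping_genome, flank)
    alt_aln <- align_probe(probes$alt, truth_genome)
    if (is.null(alt_aln)) return(FALSE)
    ref_aln <- align_probe(probes$ref, truth_genome,
                           required_start = alt_aln$truth_start)
    sc <- score_call(alt_aln, ref_aln, cand$alt[i], cand$ref[i])
    isTRUE(all.equal(sc$score, 1))
  }, logical(1))
  res <- cand[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}

# parse minimap2 cs:Z: difference strings from PAF lines into variants on
# the reference; reverse-strand alignments are skipped (assemblies of the
# same organism align forward)
parse_cs_variants <- function(paf_lines, reference) {
  out <- list()
  for (line in paf_lines) {
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(f) < 12) next
    if (f[5] != "+") next
    chrom <- f[6]
    rpos <- as.integer(f[8]) + 1L   # PAF target start is 0-based
    cs <- sub("^cs:Z:", "", grep("^cs:Z:", f, value = TRUE)[1])
    if (is.na(cs)) next
    toks <- regmatches(cs, gregexpr(
      "(:[0-9]+)|(\\*[a-z][a-z])|(\\+[a-z]+)|(-[a-z]+)", cs))[[1]]
    for (tk in toks) {
      op <- substr(tk, 1, 1)
      body <- substr(tk, 2, nchar(tk))
      if (op == ":") {
        rpos <- rpos + as.integer(body)
      } else if (op == "*") {
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, pos = rpos,
          ref = toupper(substr(body, 1, 1)),
          alt = toupper(substr(body, 2, 2)), stringsAsFactors = FALSE)
        rpos <- rpos + 1L
      } else if (op == "-") {
        # deletion from the reference; anchor on the previous base
        out[[length(out) + 1L]] <- left_normalize(
          chrom, rpos, toupper(body), "", reference)
        rpos <- rpos + nchar(body)
      } else if (op == "+") {
        out[[length(out) + 1L]] <- left_normalize(
          chrom, rpos, "", toupper(body), reference)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(chrom = character(), pos = integer(),
                      ref = character(), alt = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res$origins <- "assembly-diff"
  res
}
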