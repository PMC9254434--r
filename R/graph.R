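# Bubble genome graph and exact-match read mapping ("quasimap").
#
# The graph is the reference backbone plus the clustered sites; every path
# chooses one allele (reference or alternate) per site.  A read maps to an
# allele when the full read, with no clipping and no mismatches, equals a
# substring of some path and that substring overlaps the allele's segment.
# For every site, gamma(X) counts the reads whose matched allele set at
# that site is exactly X, and a per-base depth counter is kept per allele.

#' Build a bubble genome graph
#'
#' @param reference named character vector of contig sequences (or FASTA
#'   path).
#' @param sites site data.frame from [cluster_variants()].
#' @return object of class `genome_graph`.
#' @export
build_graph <- function(reference, sites) {
  if (is.character(reference) && length(reference) == 1 &&
      file.exists(reference)) {
    reference <- read_reference(reference)
  }
  if (nrow(sites)) {
    stopifnot(all(sites$chrom %in% names(reference)))
    for (chrom in unique(sites$chrom)) {
      s <- sites[sites$chrom == chrom, , drop = FALSE]
      if (any(s$end > nchar(reference[[chrom]])) || any(s$start < 1)) {
        stop("site out of reference bounds on contig ", chrom)
      }
      o <- order(s$start)
      if (any(s$start[o][-1] <= s$end[o][-nrow(s)])) {
        stop("sites overlap on contig ", chrom)
      }
      if (any(s$ref_allele != substr(rep(reference[[chrom]], nrow(s)),
                                     s$start, s$end))) {
        stop("site reference allele does not match the reference sequence")
      }
    }
    sites <- sites[order(sites$chrom, sites$start), , drop = FALSE]
    rownames(sites) <- NULL
  }
  structure(list(reference = reference, sites = sites),
            class = "genome_graph")
}

#' @export
print.genome_graph <- function(x, ...) {
  cat(sprintf("genome_graph: %d contig(s), %d site(s), %d allele(s)\n",
              length(x$reference), nrow(x$sites),
              if (nrow(x$sites)) sum(site_allele_count(x$sites)) else 0L))
  invisible(x)
}

#' Spell one haplotype of the graph
#'
#' Applies the chosen allele at every site of one contig; allele index 1 is
#' the reference allele, 2.. are the alternates in site order.
#'
#' @param graph a `genome_graph`.
#' @param chrom contig name.
#' @param choice integer vector, one allele index per site on `chrom`.
#' @return single sequence string.
#' @export
spell_haplotype <- function(graph, chrom, choice) {
  s <- graph$sites[graph$sites$chrom == chrom, , drop = FALSE]
  stopifnot(length(choice) == nrow(s))
  pieces <- character(0)
  cursor <- 1L
  for (i in seq_len(nrow(s))) {
    alleles <- c(s$ref_allele[i], s$alts[[i]])
    pieces <- c(pieces,
                substr(graph$reference[[chrom]], cursor, s$start[i] - 1L),
                alleles[[choice[i]]])
    cursor <- s$end[i] + 1L
  }
  pieces <- c(pieces, substr(graph$reference[[chrom]], cursor,
                             nchar(graph$reference[[chrom]])))
  paste(pieces, collapse = "")
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# spell the local context around site i for one combination of neighbour
# alleles; returns list(seq=, allele_start=, allele_len=) per focal allele
# Helper used by quasimap below.
local_windows <- function(graph, site_row, neighbours, flank, combo_cap) {
  ref <- graph$reference[[site_row$chrom]]
  glen <- nchar(ref)
  pad <- flank + 60L  # extra backbone so deletions cannot shorten below flank
  left_from <- max(1L, site_row$start - pad)
  right_to <- min(glen, site_row$end + pad)

  nb_left <- neighbours[neighbours$end < site_row$start &
                        neighbours$end >= left_from, , drop = FALSE]
  nb_right <- neighbours[neighbours$start > site_row$end &
                         neighbours$start <= right_to, , drop = FALSE]
  trim_neighbours <- function(nb, from_far) {
    # drop farthest-first until the combination count is workable
    counts <- vapply(nb$alts, length, integer(1)) + 1L
    while (nrow(nb) && prod(counts) > combo_cap) {
      drop <- if (from_far == "left") 1L else nrow(nb)
      nb <- nb[-drop, , drop = FALSE]
      counts <- vapply(nb$alts, length, integer(1)) + 1L
    }
    nb
  }
  nb_left <- trim_neighbours(nb_left, "left")
  nb_right <- trim_neighbours(nb_right, "right")

  spell_side <- function(nb, from, to) {
    # all realisations of backbone [from,to] with neighbour alleles applied
    if (!nrow(nb)) return(substr(ref, from, to))
    seqs <- ""
    cursor <- from
    for (i in seq_len(nrow(nb))) {
      gap <- substr(ref, cursor, nb$start[i] - 1L)
      alleles <- c(nb$ref_allele[i], nb$alts[[i]])
      seqs <- as.vector(outer(paste0(seqs, gap), alleles, paste0))
      cursor <- nb$end[i] + 1L
    }
    paste0(seqs, substr(ref, cursor, to))
  }
  lefts <- spell_side(nb_left, left_from, site_row$start - 1L)
  rights <- spell_side(nb_right, site_row$end + 1L, right_to)
  # keep only the flank-proximal part
  lefts <- unique(substr(lefts, pmax(1L, nchar(lefts) - flank + 1L),
                         nchar(lefts)))
  rights <- unique(substr(rights, 1L, flank))
  list(lefts = lefts, rights = rights)
}

#' Map reads to a genome graph by exact full-length matching
#'
#' For every site, every combination of focal allele, nearby neighbour
#' alleles and flank is spelled, and reads (both strands) are matched
#' exactly against every substring position that overlaps the focal
#' allele.  Gamma counts each read once per site, keyed by the exact set
#' of alleles it matched; per-base depth of every matched allele is
#' incremented at matched positions (multi-mapping allowed).  Reads
#' containing characters other than ACGT are skipped and counted.
#'
#' @param reads character vector of read sequences (or a file path readable
#'   by [read_reads()]).
#' @param graph a `genome_graph`.
#' @param flank matching context length on each side of an allele; default
#'   `max(nchar(reads)) - 1` so any read overlapping an allele by one base
#'   is findable.
#' @param combo_cap cap on neighbour-allele combinations spelled per side
#'   of one site (graph regions denser than this are matched against the
#'   most proximal neighbour combinations only).
#' @return object of class `coverage_data`: per site a list with `gamma`
#'   (named counts; names are comma-joined allele indices, 1 = reference),
#'   `per_base` (list of integer depth vectors per allele) and
#'   `allele_len`.  Attribute `n_skipped` counts skipped reads.
#' @export
quasimap <- function(reads, graph, flank = NULL, combo_cap = 128L) {
  if (length(reads) == 1 && file.exists(reads[[1]]) &&
      !grepl("^[ACGTN]+$", reads[[1]])) {
    reads <- read_reads(reads)
  }
  reads <- toupper(reads)
  ok <- grepl("^[ACGT]+$", reads)
  n_skipped <- sum(!ok)
  reads <- reads[ok]
  sites <- graph$sites
  n_sites <- nrow(sites)
  empty_site <- function(i) {
    alleles <- c(sites$ref_allele[i], sites$alts[[i]])
    list(gamma = setNames(numeric(0), character(0)),
         per_base = lapply(nchar(alleles), function(l) integer(l)),
         allele_len = nchar(alleles))
  }
  cov <- lapply(seq_len(n_sites), empty_site)
  if (!length(reads) || n_sites == 0) {
    return(structure(list(sites = sites, site_cov = cov),
                     class = "coverage_data", n_skipped = n_skipped))
  }

  rl_max <- max(nchar(reads))
  if (is.null(flank)) flank <- rl_max - 1L
  # group identical read sequences; a read group matches via either strand
  useq <- unique(reads)
  group_count <- as.integer(table(factor(reads, levels = useq)))
  urc <- revcomp(useq)
  lookup <- c(useq, urc)
  lookup_group <- c(seq_along(useq), seq_along(useq))
  read_lens <- sort(unique(nchar(reads)))

  for (i in seq_len(n_sites)) {
    site_row <- sites[i, , drop = FALSE]
    nb <- sites[sites$chrom == site_row$chrom, , drop = FALSE]
    win <- local_windows(graph, site_row, nb, flank, combo_cap)
    alleles <- c(site_row$ref_allele, site_row$alts[[1]])
    # per group: matched allele ids, and per allele the matched positions
    group_hits <- new.env(parent = emptyenv())
    for (a in seq_along(alleles)) {
      al <- alleles[[a]]
      al_len <- nchar(al)
      for (lf in win$lefts) {
        llen <- nchar(lf)
        for (rt in win$rights) {
          w <- paste0(lf, al, rt)
          wlen <- nchar(w)
          for (rl in read_lens) {
            if (rl > wlen) next
            # offsets whose read interval overlaps the allele segment
            # allele occupies [llen+1, llen+al_len] (junction llen..llen+1
            # for zero-length alleles)
            lo <- max(1L, llen + 1L - rl + 1L)
            hi <- min(wlen - rl + 1L, llen + max(al_len, 1L))
            if (al_len == 0L) hi <- min(wlen - rl + 1L, llen + 1L)
            if (lo > hi) next
            offs <- lo:hi
            kmers <- substring(w, offs, offs + rl - 1L)
            m <- match(kmers, lookup)
            hit <- which(!is.na(m))
            for (h in hit) {
              g <- lookup_group[[m[[h]]]]
              off <- offs[[h]]
              # allele positions covered by this read
              p1 <- max(1L, off - llen)
              p2 <- min(al_len, off + rl - 1L - llen)
              key <- as.character(g)
              rec <- get0(key, envir = group_hits,
                          ifnotfound = list())
              apos <- if (p1 <= p2) p1:p2 else integer()
              rec[[as.character(a)]] <- unique(c(rec[[as.character(a)]],
                                                 apos))
              assign(key, rec, envir = group_hits)
            }
          }
        }
      }
    }
    gamma <- list()
    per_base <- lapply(nchar(alleles), function(l) integer(l))
    for (key in ls(group_hits)) {
      rec <- get(key, envir = group_hits)
      g <- as.integer(key)
      aset <- sort(as.integer(names(rec)))
      gkey <- paste(aset, collapse = ",")
      gamma[[gkey]] <- (if (is.null(gamma[[gkey]])) 0 else gamma[[gkey]]) +
        group_count[[g]]
      for (a in aset) {
        apos <- rec[[as.character(a)]]
        if (length(apos)) {
          per_base[[a]][apos] <- per_base[[a]][apos] + group_count[[g]]
        }
      }
    }
    cov[[i]] <- list(gamma = unlist(gamma) %||% setNames(numeric(0),
                                                         character(0)),
                     per_base = per_base, allele_len = nchar(alleles))
  }
  structure(list(sites = sites, site_cov = cov), class = "coverage_data",
            n_skipped = n_skipped)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.coverage_data <- function(x, ...) {
  cat(sprintf("coverage_data: %d site(s), total mapped read-site pairs %d\n",
              length(x$site_cov),
              sum(vapply(x$site_cov, function(s) sum(s$gamma), numeric(1)))))
  invisible(x)
}

#' Summarise coverage at every site
#'
#' Computes, per site, the total coverage `c = sum over subsets X of
#' gamma(X)`, per-allele coverage `c_a = sum over X containing a of
#' gamma(X)`, the number of allele positions with non-zero depth `b_a`,
#' and the allele lengths.
#'
#' @param cov a `coverage_data` object.
#' @return list of per-site lists with elements `c`, `c_a`, `b`, `ell`.
#' @export
coverage_summary <- function(cov) {
  lapply(cov$site_cov, function(s) {
    n_alleles <- length(s$allele_len)
    total <- sum(s$gamma)
    subsets <- lapply(strsplit(names(s$gamma), ",", fixed = TRUE),
                      as.integer)
    c_a <- vapply(seq_len(n_alleles), function(a) {
      sum(s$gamma[vapply(subsets, function(X) a %in% X, logical(1))])
    }, numeric(1))
    b <- vapply(s$per_base, function(p) sum(p > 0L), integer(1))
    list(c = total, c_a = c_a, b = b, ell = s$allele_len)
  })
}
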