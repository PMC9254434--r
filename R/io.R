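# File readers/writers shared across the package.  Sequences are handled as
# upper-case character strings keyed by contig name; Biostrings does the
# actual FASTA/FASTQ parsing.

#' Read a reference genome
#'
#' Loads a FASTA file into a named character vector of upper-case contig
#' sequences.  Contig names are truncated at the first whitespace, matching
#' how they appear in VCF CHROM columns.
#'
#' @param path path to a FASTA file (plain or gzip).
#' @return named character vector, one element per contig.
#' @export
read_reference <- function(path) {
  dss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(dss))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  dss <- Biostrings::DNAStringSet(unlist(seqs))
  names(dss) <- names(seqs)
  Biostrings::writeXStringSet(dss, path)
  invisible(path)
}

#' Read sequencing reads
#'
#' Accepts FASTQ or FASTA (plain or gzip; format inferred from the file
#' name), or a coordinate-sorted indexed BAM restricted to a region (used
#' when mapping genome slices; requires the Rsamtools package).
#'
#' @param path reads file.
#' @param region optional `list(chrom=, start=, end=)` restricting a BAM to
#'   one reference window (1-based closed).
#' @return character vector of upper-case read sequences.
#' @export
read_reads <- function(path, region = NULL) {
  lower <- tolower(path)
  if (grepl("\\.bam$", lower)) {
    if (!requireNamespace("Rsamtools", quietly = TRUE)) {
      stop("reading BAM requires the Rsamtools package")
    }
    param <- if (is.null(region)) {
      Rsamtools::ScanBamParam(what = "seq")
    } else {
      which <- IRanges::IRangesList(IRanges::IRanges(region$start, region$end))
      names(which) <- region$chrom
      Rsamtools::ScanBamParam(what = "seq", which = which)
    }
    res <- Rsamtools::scanBam(path, param = param)
    return(toupper(unlist(lapply(res, function(x) as.character(x$seq)),
                          use.names = FALSE)))
  }
  fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", lower)) "fastq" else "fasta"
  dss <- Biostrings::readDNAStringSet(path, format = fmt)
  toupper(as.character(dss))
}

#' Write reads to FASTQ
#'
#' All reads get a flat maximum base quality; the package's mapper and
#' genotype model are quality-unaware.
#'
#' @param reads character vector of read sequences.
#' @param path output path; `.gz` suffix triggers compression.
#' @param names read names; defaults to `read1..readN`.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, names = NULL) {
  if (is.null(names)) names <- paste0("read", seq_along(reads))
  dss <- Biostrings::DNAStringSet(reads)
  quals <- Biostrings::PhredQuality(vapply(nchar(reads), function(w) {
    paste(rep("I", w), collapse = "")
  }, character(1)))
  q <- Biostrings::QualityScaledDNAStringSet(dss, quals)
  names(q) <- names
  Biostrings::writeQualityScaledXStringSet(q, path,
                                           compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a genome mask
#'
#' Masks mark unreliable genome regions to be excluded from evaluation.
#' Accepts a BED path (parsed with rtracklayer when available, 0-based
#' half-open as per BED), or a data.frame with columns chrom/start/end
#' already in 1-based closed coordinates.
#'
#' @param mask BED file path, data.frame, or NULL.
#' @return data.frame with columns `chrom`, `start`, `end` (1-based closed),
#'   possibly with zero rows.
#' @export
read_mask <- function(mask) {
  if (is.null(mask)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer()))
  }
  if (is.data.frame(mask)) {
    stopifnot(all(c("chrom", "start", "end") %in% names(mask)))
    return(mask[, c("chrom", "start", "end")])
  }
  if (requireNamespace("rtracklayer", quietly = TRUE)) {
    gr <- as.data.frame(rtracklayer::import(mask, format = "BED"))
    return(data.frame(chrom = as.character(gr$seqnames),
                      start = gr$start, end = gr$end))
  }
  bed <- utils::read.delim(mask, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  data.frame(chrom = as.character(bed[[1]]),
             start = as.integer(bed[[2]]) + 1L,
             end = as.integer(bed[[3]]))
}

# positions (1-based) covered by a mask on one contig
mask_positions <- function(mask_df, chrom) {
  rows <- mask_df[mask_df$chrom == chrom, , drop = FALSE]
  if (nrow(rows) == 0) return(integer())
  unique(unlist(mapply(seq.int, rows$start, rows$end, SIMPLIFY = FALSE)))
}
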