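# Transcript models and genomic <-> cDNA coordinate arithmetic.

#' Construct a transcript model
#'
#' A transcript model carries the exon structure and coding sequence of one
#' panel gene and powers the genomic/cDNA mapping and codon arithmetic.
#' Exons are given 1-based inclusive in genomic coordinates, ordered 5' to 3'
#' in *transcript* orientation (so for a minus-strand transcript the first
#' exon is the genomically highest). The coding sequence is in transcript
#' orientation, must start with ATG, have length divisible by 3, and contain
#' no internal stop codon.
#'
#' @param gene gene symbol.
#' @param chrom chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exon_starts,exon_ends integer vectors of genomic exon boundaries
#'   (1-based inclusive), one entry per exon in transcript order.
#' @param cds_start_cdna 1-based cDNA offset of the A of the initiator ATG.
#' @param cds_seq coding sequence string (transcript orientation).
#' @return A `transcript_model` object.
#' @export
transcript_model <- function(gene, chrom, strand, exon_starts, exon_ends,
                             cds_start_cdna, cds_seq) {
  stopifnot(strand %in% c("+", "-"),
            length(exon_starts) == length(exon_ends),
            all(exon_starts <= exon_ends),
            cds_start_cdna >= 1)
  starts <- as.integer(exon_starts); ends <- as.integer(exon_ends)
  # non-overlap + transcript ordering
  ord_key <- if (strand == "+") starts else -starts
  if (is.unsorted(ord_key, strictly = TRUE)) {
    stop("exons must be ordered 5'->3' in transcript orientation", call. = FALSE)
  }
  gen_order <- order(starts)
  if (any(starts[gen_order][-1] <= ends[gen_order][-length(ends)])) {
    stop("exons overlap", call. = FALSE)
  }
  cds_seq <- toupper(cds_seq)
  n <- nchar(cds_seq)
  if (n %% 3L != 0L) stop("coding sequence length not divisible by 3", call. = FALSE)
  if (substr(cds_seq, 1L, 3L) != "ATG") {
    stop("coding sequence must begin with ATG", call. = FALSE)
  }
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds_seq)))
  if (grepl("\\*", substr(aa, 1L, nchar(aa) - 1L))) {
    stop("coding sequence contains an internal stop codon", call. = FALSE)
  }
  widths <- ends - starts + 1L
  cdna_len <- sum(widths)
  if (cds_start_cdna + n - 1L > cdna_len) {
    stop("coding sequence extends beyond the spliced transcript", call. = FALSE)
  }
  structure(list(gene = gene, chrom = as.character(chrom), strand = strand,
                 exon_starts = starts, exon_ends = ends,
                 widths = widths, cum_before = cumsum(c(0L, widths))[seq_along(widths)],
                 cds_start_cdna = as.integer(cds_start_cdna),
                 cds_seq = cds_seq, cds_len = n,
                 protein = substr(aa, 1L, nchar(aa) - as.integer(endsWith(aa, "*")))),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("transcript_model %s (%s%s): %d exon(s), CDS %d nt (%d codons)\n",
              x$gene, x$chrom, x$strand, length(x$exon_starts), x$cds_len,
              x$cds_len %/% 3L))
  invisible(x)
}

#' Read transcript models from a TSV
#'
#' Columns: `gene`, `chrom`, `strand`, `exon_starts`, `exon_ends`
#' (comma-separated genomic coordinates in transcript order),
#' `cds_start_cdna`, `cds_seq`.
#'
#' @param path path to the TSV.
#' @return A named list of [transcript_model()] objects, keyed by gene.
#' @export
read_transcripts <- function(path) {
  raw <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  out <- lapply(seq_len(nrow(raw)), function(i) {
    transcript_model(
      gene = raw$gene[i], chrom = raw$chrom[i], strand = raw$strand[i],
      exon_starts = as.integer(strsplit(raw$exon_starts[i], ",")[[1]]),
      exon_ends = as.integer(strsplit(raw$exon_ends[i], ",")[[1]]),
      cds_start_cdna = raw$cds_start_cdna[i], cds_seq = raw$cds_seq[i])
  })
  setNames(out, raw$gene)
}

.non_coding_error <- function(msg) {
  stop(errorCondition(msg, class = c("tp_non_coding_error", "error")))
}

#' Map a genomic position to a coding (cDNA) position
#'
#' @param pos 1-based genomic position; must fall in an exon and within the
#'   CDS of `tm`, otherwise a typed `tp_non_coding_error` is signalled.
#' @param tm a [transcript_model()].
#' @return The 1-based coding position (A of the initiator ATG = 1).
#' @seealso [cdna_to_genomic()] for the inverse.
#' @export
genomic_to_cdna <- function(pos, tm) {
  stopifnot(inherits(tm, "transcript_model"), length(pos) == 1L)
  pos <- as.integer(pos)
  ex <- which(pos >= tm$exon_starts & pos <= tm$exon_ends)
  if (!length(ex)) {
    .non_coding_error(sprintf("position %d is not exonic in %s", pos, tm$gene))
  }
  within <- if (tm$strand == "+") pos - tm$exon_starts[ex] + 1L
            else tm$exon_ends[ex] - pos + 1L
  cdna <- tm$cum_before[ex] + within
  c_pos <- cdna - tm$cds_start_cdna + 1L
  if (c_pos < 1L || c_pos > tm$cds_len) {
    .non_coding_error(sprintf("position %d lies in the UTR of %s", pos, tm$gene))
  }
  c_pos
}

#' Map a coding position back to its genomic position
#' @param c_pos 1-based coding position in `[1, CDS length]`.
#' @param tm a [transcript_model()].
#' @return The 1-based genomic position.
#' @export
cdna_to_genomic <- function(c_pos, tm) {
  stopifnot(inherits(tm, "transcript_model"), length(c_pos) == 1L)
  c_pos <- as.integer(c_pos)
  if (c_pos < 1L || c_pos > tm$cds_len) {
    stop("coding position out of CDS range", call. = FALSE)
  }
  cdna <- c_pos + tm$cds_start_cdna - 1L
  ex <- findInterval(cdna - 1L, tm$cum_before)  # exon index in transcript order
  within <- cdna - tm$cum_before[ex]
  if (tm$strand == "+") tm$exon_starts[ex] + within - 1L
  else tm$exon_ends[ex] - within + 1L
}

#' Codon index and within-codon offset of a coding position
#'
#' With the initiator ATG as codon 1: `codon_index = floor((c_pos - 1)/3) + 1`
#' and `offset = (c_pos - 1) mod 3`.
#'
#' @param c_pos 1-based coding position (scalar or vector).
#' @return A list with integer elements `codon_index` and `offset` (0, 1, 2).
#' @export
#' @examples
#' codon_of(70)  # codon 24, first codon position
codon_of <- function(c_pos) {
  c_pos <- as.integer(c_pos)
  if (any(c_pos < 1L)) stop("coding position must be >= 1", call. = FALSE)
  list(codon_index = (c_pos - 1L) %/% 3L + 1L, offset = (c_pos - 1L) %% 3L)
}

.comp <- function(x) chartr("ACGT", "TGCA", x)

#' Convert a genomic allele to transcript orientation
#' @param base allele string on the genomic plus strand.
#' @param tm a [transcript_model()]; minus-strand models complement.
#' @return The allele as read on the transcript strand.
#' @export
transcript_allele <- function(base, tm) {
  if (tm$strand == "+") toupper(base) else .comp(toupper(base))
}
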