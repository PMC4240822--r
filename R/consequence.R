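# Substitution consequences: codon translation, HGVS c./p. formatting,
# mature-protein renumbering, and alignment-column conservation.

.aa3 <- function(aa1) {
  if (aa1 == "*") return("Ter")
  unname(Biostrings::AMINO_ACID_CODE[aa1])
}

.codon_aa <- function(codon) unname(Biostrings::GENETIC_CODE[codon])

#' Translate a single-nucleotide coding substitution
#'
#' Computes the affected codon, translates reference and mutated codons with
#' the standard genetic code, classifies the substitution and formats HGVS
#' c./p. descriptions. The reference base is checked against the transcript's
#' coding sequence; a mismatch signals a typed `tp_reference_mismatch` error
#' carrying both bases.
#'
#' @param tm a [transcript_model()].
#' @param c_pos 1-based coding position.
#' @param ref_base,alt_base single bases in transcript orientation.
#' @return A `consequence_call`: list with `hgvs_c`, `hgvs_p`, `codon_index`,
#'   `within_codon_offset`, `ref_aa`, `alt_aa` (3-letter codes, `"Ter"` for
#'   stop) and `klass` (`missense`, `synonymous`, `nonsense`, `start-lost`).
#' @export
#' @examples
#' tm <- read_transcripts(tp_fixture("transcripts_synthetic.tsv"))$CRYGD
#' translate_substitution(tm, 70, "C", "A")  # p.Pro24Thr
translate_substitution <- function(tm, c_pos, ref_base, alt_base) {
  stopifnot(inherits(tm, "transcript_model"))
  c_pos <- as.integer(c_pos)
  ref_base <- toupper(ref_base); alt_base <- toupper(alt_base)
  stopifnot(c_pos >= 1L, c_pos <= tm$cds_len,
            ref_base %in% c("A", "C", "G", "T"),
            alt_base %in% c("A", "C", "G", "T"))
  have <- substr(tm$cds_seq, c_pos, c_pos)
  if (have != ref_base) {
    stop(errorCondition(
      sprintf("reference mismatch at c.%d of %s: transcript has %s, given %s",
              c_pos, tm$gene, have, ref_base),
      class = c("tp_reference_mismatch", "error"),
      expected = have, given = ref_base))
  }
  co <- codon_of(c_pos)
  idx <- co$codon_index; off <- co$offset
  ref_codon <- substr(tm$cds_seq, 3L * (idx - 1L) + 1L, 3L * idx)
  alt_codon <- ref_codon
  substr(alt_codon, off + 1L, off + 1L) <- alt_base
  ref_aa1 <- .codon_aa(ref_codon); alt_aa1 <- .codon_aa(alt_codon)
  klass <- if (ref_aa1 == alt_aa1) "synonymous"
           else if (idx == 1L && alt_codon != "ATG") "start-lost"
           else if (alt_aa1 == "*") "nonsense"
           else "missense"
  call <- structure(list(
    gene = tm$gene, c_pos = c_pos, ref_base = ref_base, alt_base = alt_base,
    codon_index = idx, within_codon_offset = off,
    ref_codon = ref_codon, alt_codon = alt_codon,
    ref_aa = .aa3(ref_aa1), alt_aa = .aa3(alt_aa1), klass = klass),
    class = "consequence_call")
  h <- format_hgvs(call)
  call$hgvs_c <- h[["hgvs_c"]]
  call$hgvs_p <- h[["hgvs_p"]]
  call
}

#' @export
print.consequence_call <- function(x, ...) {
  cat(sprintf("%s %s (%s) [%s]\n", x$gene, x$hgvs_c, x$hgvs_p, x$klass))
  invisible(x)
}

#' Format HGVS c. and p. descriptions for a substitution call
#'
#' cDNA level: `c.<pos><ref>><alt>`. Protein level: `p.<RefAa><index><AltAa>`
#' with 3-letter amino-acid codes and initiator Met = 1; a same-base
#' substitution formats as `p.(=)`, a synonymous base change as
#' `p.<RefAa><index>=`.
#'
#' @param call a `consequence_call` (or a bare list with the same fields).
#' @return Named character vector with elements `hgvs_c` and `hgvs_p`.
#' @export
format_hgvs <- function(call) {
  hgvs_c <- sprintf("c.%d%s>%s", call$c_pos, call$ref_base, call$alt_base)
  hgvs_p <- if (call$klass == "synonymous") {
    if (call$ref_base == call$alt_base) "p.(=)"
    else sprintf("p.%s%d=", call$ref_aa, call$codon_index)
  } else {
    sprintf("p.%s%d%s", call$ref_aa, call$codon_index, call$alt_aa)
  }
  c(hgvs_c = hgvs_c, hgvs_p = hgvs_p)
}

#' Parse an HGVS cDNA substitution string
#'
#' Accepts the substitution grammar `c.<int><base>><base>` only.
#'
#' @param x a string such as `"c.70C>A"`.
#' @return A list with `c_pos`, `ref`, `alt`.
#' @export
parse_hgvs_c <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  m <- regmatches(x, regexec("^c\\.([0-9]+)([ACGT])>([ACGT])$", x))[[1]]
  if (!length(m)) {
    ok <- regexpr("^c\\.[0-9]+[ACGT]?>?[ACGT]?", x)
    at <- attr(ok, "match.length")
    stop("malformed HGVS cDNA substitution '", x, "' (parse failed at ",
         "character ", max(1L, at + 1L), ")", call. = FALSE)
  }
  list(c_pos = as.integer(m[2]), ref = m[3], alt = m[4])
}

#' Mature-protein residue numbering
#'
#' Renumbers a canonical codon index (initiator Met = 1) to the mature-protein
#' convention used after N-terminal processing removes the initiator
#' methionine: residue `k` becomes `k - 1`. The initiator itself has no
#' mature number and signals a typed `tp_initiator_error`.
#'
#' @param codon_index canonical codon index, `>= 2`.
#' @return `codon_index - 1`, as integer.
#' @export
#' @examples
#' mature_numbering(24)  # 23
mature_numbering <- function(codon_index) {
  codon_index <- as.integer(codon_index)
  stopifnot(length(codon_index) == 1L, !is.na(codon_index), codon_index >= 1L)
  if (codon_index == 1L) {
    stop(errorCondition("the initiator methionine has no mature-protein number",
                        class = c("tp_initiator_error", "error")))
  }
  codon_index - 1L
}

#' Cross-species conservation of one reference residue
#'
#' Fraction of non-reference alignment rows whose residue equals the
#' reference residue at the alignment column holding the `position`-th
#' residue of the reference row (gaps in the reference row are skipped when
#' counting; gaps in other rows count as mismatches).
#'
#' @param alignment a named character vector of equal-length gapped sequences
#'   (see [read_alignment()]), or a path to an aligned FASTA file.
#' @param position 1-based residue index on the reference row.
#' @param ref_row index of the reference row (default 1).
#' @return The conservation fraction in `[0, 1]`.
#' @export
conservation_fraction <- function(alignment, position, ref_row = 1L) {
  if (is.character(alignment) && length(alignment) == 1L &&
      file.exists(alignment)) {
    alignment <- read_alignment(alignment)
  }
  seqs <- toupper(as.character(alignment))
  if (length(seqs) < 2L) stop("no comparison rows in alignment", call. = FALSE)
  if (length(unique(nchar(seqs))) != 1L) {
    stop("alignment rows differ in length", call. = FALSE)
  }
  mat <- do.call(rbind, strsplit(seqs, ""))
  res_cols <- which(mat[ref_row, ] != "-")
  position <- as.integer(position)
  if (position < 1L || position > length(res_cols)) {
    stop("position ", position, " out of range for reference row (",
         length(res_cols), " residues)", call. = FALSE)
  }
  col <- res_cols[position]
  mean(mat[-ref_row, col] == mat[ref_row, col])
}
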