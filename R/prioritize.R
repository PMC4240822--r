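# End-to-end prioritization: every input variant receives an auditable trail
# through panel -> co-segregation -> population frequency, then (for
# candidates and panel variants alike, where resources permit) consequence,
# conservation and predictor annotation. The three filters are evaluated
# independently of one another, so the candidate set does not depend on the
# stage order; the recorded exclusion reason names the first failed stage in
# the canonical order.

.as_input <- function(x, reader, ...) {
  if (is.character(x) && length(x) == 1L) reader(x, ...) else x
}

#' Prioritize variants in a family under the dominant model
#'
#' Runs the full cascade over one family's variants: candidate-panel
#' intersection, autosomal dominant co-segregation against the pedigree, and
#' population minor-allele-frequency exclusion. Variants passing all three
#' are candidates. Panel variants are additionally annotated — where a
#' transcript model, an alignment or a score row is available — with the
#' HGVS c./p. consequence, the cross-species conservation of the affected
#' residue, and per-tool predictor verdicts. Annotations never change the
#' candidate/excluded verdict.
#'
#' @param variants a `variant_table`, or a path to a VCF (read with
#'   [read_vcf()] against `pedigree`).
#' @param pedigree a `pedigree` or path to a PED file.
#' @param panel a `gene_panel` or path to a BED4 file.
#' @param frequencies a `frequency_table`, path, or `NULL` (all variants
#'   treated as novel).
#' @param transcripts named list of [transcript_model()]s (or path to a
#'   transcript TSV), keyed by gene; optional.
#' @param scores a `predictor_scores` table or path; optional.
#' @param alignments named list of alignments (or of aligned-FASTA paths),
#'   keyed by gene; optional.
#' @param config a [filter_config()].
#' @param known_mutations data frame with columns `gene`, `hgvs_c`, `hgvs_p`
#'   (or path to such a TSV) used to mark annotated candidates as
#'   `"Recurrent"` versus `"Novel"`; optional.
#' @return A `prioritization` object: list with `trails` (one row per
#'   variant), `candidates` (the candidate subset, sorted by damaging-tool
#'   count descending, then MAF ascending, then genomic coordinate),
#'   `counts` (per-stage tallies), plus the pedigree, panel size and
#'   configuration. Methods: `print`, `summary`, `as.data.frame`.
#' @export
prioritize <- function(variants, pedigree, panel, frequencies = NULL,
                       transcripts = NULL, scores = NULL, alignments = NULL,
                       config = filter_config(), known_mutations = NULL) {
  pedigree <- .as_input(pedigree, read_ped)
  variants <- .as_input(variants, read_vcf, pedigree = pedigree)
  panel <- .as_input(panel, read_panel)
  frequencies <- if (!is.null(frequencies)) .as_input(frequencies, read_frequencies)
  transcripts <- if (!is.null(transcripts)) .as_input(transcripts, read_transcripts)
  scores <- if (!is.null(scores)) .as_input(scores, read_scores)
  known_mutations <- if (!is.null(known_mutations)) {
    .as_input(known_mutations, function(p) {
      read.table(p, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
    })
  }
  stopifnot(inherits(variants, "variant_table"),
            inherits(config, "filter_config"))

  pan <- panel_status(variants, panel)
  seg <- segregation_status(variants, pedigree, config)
  frq <- frequency_status(variants, frequencies, config)

  n <- nrow(variants)
  trails <- data.frame(
    chrom = variants$chrom, pos = variants$pos, ref = variants$ref,
    alt = variants$alt, vid = variants$vid,
    gene = pan$gene, in_panel = pan$in_panel,
    segregates = seg$segregates, fail_sample = seg$fail_sample,
    maf = frq$maf, novel = frq$novel, passes_frequency = frq$passes_frequency,
    hgvs_c = NA_character_, hgvs_p = NA_character_,
    codon_index = NA_integer_, klass = NA_character_,
    conservation = NA_real_,
    damaging_count = NA_integer_, prediction = NA_character_,
    status = NA_character_,
    stringsAsFactors = FALSE)

  # annotation stages (advisory; skipped per variant when inputs are absent)
  for (i in seq_len(n)) {
    g <- trails$gene[i]
    if (is.na(g)) next
    tm <- transcripts[[g]]
    if (!is.null(tm) && identical(tm$chrom, trails$chrom[i])) {
      cc <- tryCatch({
        c_pos <- genomic_to_cdna(trails$pos[i], tm)
        translate_substitution(tm, c_pos,
                               transcript_allele(trails$ref[i], tm),
                               transcript_allele(trails$alt[i], tm))
      }, tp_non_coding_error = function(e) NULL,
         tp_reference_mismatch = function(e) NULL)
      if (!is.null(cc)) {
        trails$hgvs_c[i] <- cc$hgvs_c
        trails$hgvs_p[i] <- cc$hgvs_p
        trails$codon_index[i] <- cc$codon_index
        trails$klass[i] <- cc$klass
        aln <- alignments[[g]]
        if (!is.null(aln)) {
          trails$conservation[i] <- tryCatch(
            conservation_fraction(aln, cc$codon_index),
            error = function(e) NA_real_)
        }
        if (!is.null(known_mutations)) {
          hit <- known_mutations$gene == g &
            (known_mutations$hgvs_c == cc$hgvs_c |
             known_mutations$hgvs_p == cc$hgvs_p)
          trails$status[i] <- if (any(hit)) "Recurrent" else "Novel"
        }
      }
    }
    if (!is.null(scores)) {
      j <- which(scores$chrom == trails$chrom[i] & scores$pos == trails$pos[i] &
                 scores$ref == trails$ref[i] & scores$alt == trails$alt[i])
      if (length(j)) {
        ps <- tryCatch(classify_predictions(scores[j[1L], ]),
                       tp_no_scores = function(e) NULL)
        if (!is.null(ps)) {
          trails$damaging_count[i] <- ps$damaging_count
          trails$prediction[i] <- paste(names(ps$verdict), ps$verdict,
                                        sep = ":", collapse = "; ")
        }
      }
    }
  }

  candidate <- trails$in_panel & trails$segregates & trails$passes_frequency
  trails$final <- ifelse(candidate, "candidate", "excluded")
  trails$reason <- ifelse(candidate, NA_character_,
                   ifelse(!trails$in_panel, "not in panel",
                   ifelse(!trails$segregates, "does not co-segregate",
                          "population MAF above threshold")))

  cand <- trails[candidate, , drop = FALSE]
  if (nrow(cand)) {
    dc <- ifelse(is.na(cand$damaging_count), -1L, cand$damaging_count)
    cand <- cand[order(-dc, cand$maf, cand$chrom, cand$pos), , drop = FALSE]
    rownames(cand) <- NULL
  }

  in_panel <- trails$in_panel
  counts <- list(
    n_total = n,
    n_panel = sum(in_panel),
    n_genes_hit = length(unique(trails$gene[in_panel])),
    n_panel_genes = nrow(panel),
    n_segregating = sum(in_panel & trails$segregates),
    n_candidates = sum(candidate))

  structure(list(trails = trails, candidates = cand, counts = counts,
                 pedigree = pedigree, config = config),
            class = "prioritization")
}

#' @export
print.prioritization <- function(x, ...) {
  ct <- x$counts
  cat("Trio-based candidate-gene variant prioritization (dominant model)\n")
  cat(sprintf("  %d variants in %d of %d candidate genes\n",
              ct$n_panel, ct$n_genes_hit, ct$n_panel_genes))
  cat(sprintf("  co-segregating with disease: %d\n", ct$n_segregating))
  cat(sprintf("  surviving MAF <= %g exclusion: %d candidate(s)\n",
              x$config$maf_threshold, ct$n_candidates))
  if (nrow(x$candidates)) {
    cols <- c("chrom", "pos", "ref", "alt", "vid", "gene", "hgvs_c", "hgvs_p",
              "maf", "damaging_count", "status")
    print(x$candidates[, cols], row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.prioritization <- function(object, ...) {
  structure(object$counts, class = "summary.prioritization")
}

#' @export
print.summary.prioritization <- function(x, ...) {
  cat(sprintf(
    "%d variants; %d in %d of %d candidate genes; %d co-segregating; %d candidate(s)\n",
    x$n_total, x$n_panel, x$n_genes_hit, x$n_panel_genes,
    x$n_segregating, x$n_candidates))
  invisible(x)
}

#' @export
as.data.frame.prioritization <- function(x, ...) x$trails
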