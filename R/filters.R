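# The prioritization filters: candidate-gene panel intersection, autosomal
# dominant co-segregation, population allele-frequency exclusion, and the
# threshold classifier for external predictor scores.
#
# Each filter comes in two forms: a *_status() evaluator returning one row
# per input variant (used by prioritize() to build auditable trails) and a
# *_filter() subsetting wrapper.

#' Filtering configuration
#'
#' @param maf_threshold exclusion threshold on the folded minor-allele
#'   frequency; variants with MAF strictly greater are excluded. Default
#'   `1e-4`, i.e. the 0.01 percent rule.
#' @param model inheritance model; only `"dominant"` is implemented.
#' @param missing policy for missing genotypes in samples consulted by the
#'   segregation filter: `"strict"` (a missing genotype fails the variant)
#'   or `"lenient"` (the sample is ignored).
#' @return A `filter_config` list.
#' @export
filter_config <- function(maf_threshold = 1e-4, model = "dominant",
                          missing = c("strict", "lenient")) {
  missing <- match.arg(missing)
  model <- match.arg(model, "dominant")
  stopifnot(is.numeric(maf_threshold), length(maf_threshold) == 1L,
            maf_threshold >= 0, maf_threshold <= 1)
  structure(list(maf_threshold = maf_threshold, model = model,
                 missing = missing), class = "filter_config")
}

.panel_granges <- function(panel) {
  # BED half-open 0-based -> GRanges 1-based inclusive
  GenomicRanges::GRanges(
    seqnames = panel$chrom,
    ranges = IRanges::IRanges(start = panel$start + 1L, end = panel$end),
    gene = panel$gene)
}

#' Panel intersection status
#'
#' @param variants a `variant_table`.
#' @param panel a `gene_panel`.
#' @return A data frame with one row per variant: `in_panel` (logical) and
#'   `gene` (symbol or `NA`).
#' @export
panel_status <- function(variants, panel) {
  stopifnot(inherits(panel, "gene_panel"))
  gene <- rep(NA_character_, nrow(variants))
  if (nrow(variants)) {
    gr <- GenomicRanges::GRanges(
      seqnames = variants$chrom,
      ranges = IRanges::IRanges(start = variants$pos, width = 1L))
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(gr, .panel_granges(panel),
                                  select = "first"))
    gene <- panel$gene[hits]
  }
  data.frame(in_panel = !is.na(gene), gene = gene, stringsAsFactors = FALSE)
}

#' Restrict variants to the candidate-gene panel
#'
#' @inheritParams panel_status
#' @return The subset of `variants` falling in a panel region, with a `gene`
#'   column appended; attribute `"summary"` holds `n_variants` (distinct
#'   retained variants) and `n_genes_hit` (distinct panel genes hit).
#' @export
panel_filter <- function(variants, panel) {
  st <- panel_status(variants, panel)
  out <- variants[st$in_panel, , drop = FALSE]
  out$gene <- st$gene[st$in_panel]
  out <- new_variant_table(out, attr(variants, "samples"))
  attr(out, "summary") <- c(n_variants = nrow(out),
                            n_genes_hit = length(unique(out$gene)))
  out
}

# Per-sample carrier requirement under the dominant model.
# Returns TRUE (requirement met), FALSE (violated) or NA (missing allele
# makes the requirement undecidable).
.sample_ok <- function(gt, need_alt) {
  al <- strsplit(sub("\\|", "/", gt), "/", fixed = TRUE)
  vapply(al, function(ab) {
    has_alt <- any(ab == "1")
    has_missing <- any(ab == ".")
    if (need_alt) {
      if (has_alt) TRUE else if (has_missing) NA else FALSE
    } else {
      if (has_alt) FALSE else if (has_missing) NA else TRUE
    }
  }, NA)
}

#' Dominant co-segregation status
#'
#' A variant co-segregates when every affected sample carries at least one
#' alternate allele and every unaffected sample carries none. Samples of
#' unknown affection status are ignored. Under the `"strict"` missing-genotype
#' policy a missing genotype in any consulted sample fails the variant; under
#' `"lenient"` that sample is ignored.
#'
#' @param variants a `variant_table`.
#' @param pedigree a `pedigree` with at least one affected and one unaffected
#'   sample (hard error otherwise).
#' @param config a [filter_config()].
#' @return Data frame with one row per variant: `segregates` (logical) and
#'   `fail_sample` (id of the first sample violating the rule, or `NA`).
#' @export
segregation_status <- function(variants, pedigree, config = filter_config()) {
  stopifnot(inherits(pedigree, "pedigree"))
  affected <- pedigree$id[pedigree$affected == "affected"]
  unaffected <- pedigree$id[pedigree$affected == "unaffected"]
  if (!length(affected)) {
    stop("segregation filter undefined: pedigree has no affected samples",
         call. = FALSE)
  }
  if (!length(unaffected)) {
    stop("segregation filter undefined: pedigree has no unaffected samples",
         call. = FALSE)
  }
  n <- nrow(variants)
  seg <- rep(TRUE, n)
  fail <- rep(NA_character_, n)
  consulted <- c(affected, unaffected)
  for (s in consulted) {
    ok <- .sample_ok(variants[[s]], need_alt = s %in% affected)
    bad <- if (config$missing == "strict") is.na(ok) | !ok else !is.na(ok) & !ok
    newly <- seg & bad
    fail[newly] <- s
    seg <- seg & !bad
  }
  data.frame(segregates = seg, fail_sample = fail, stringsAsFactors = FALSE)
}

#' Retain variants co-segregating under the dominant model
#' @inheritParams segregation_status
#' @return The co-segregating subset of `variants`.
#' @export
segregation_filter <- function(variants, pedigree, config = filter_config()) {
  st <- segregation_status(variants, pedigree, config)
  new_variant_table(variants[st$segregates, , drop = FALSE],
                    attr(variants, "samples"))
}

#' Population-frequency status
#'
#' Variants are matched in the frequency table by `(chrom, pos, ref, alt)`.
#' A variant absent from the table is treated as novel (MAF 0) and retained.
#' The retention rule is `MAF <= maf_threshold` — exclusion requires a MAF
#' *strictly greater* than the threshold.
#'
#' @param variants a `variant_table`.
#' @param frequencies a `frequency_table`, or `NULL` (all variants novel).
#' @param config a [filter_config()].
#' @return Data frame with one row per variant: `maf` (folded minor-allele
#'   frequency; 0 for novel), `novel` (absent from the table) and
#'   `passes_frequency`.
#' @export
frequency_status <- function(variants, frequencies = NULL,
                             config = filter_config()) {
  key <- function(chrom, pos, ref, alt) paste(chrom, pos, ref, alt, sep = ":")
  maf <- numeric(nrow(variants))
  novel <- rep(TRUE, nrow(variants))
  if (!is.null(frequencies) && nrow(frequencies)) {
    stopifnot(inherits(frequencies, "frequency_table"))
    idx <- match(key(variants$chrom, variants$pos, variants$ref, variants$alt),
                 key(frequencies$chrom, frequencies$pos, frequencies$ref,
                     frequencies$alt))
    hit <- !is.na(idx)
    maf[hit] <- frequencies$maf[idx[hit]]
    novel <- !hit
  }
  data.frame(maf = maf, novel = novel,
             passes_frequency = maf <= config$maf_threshold)
}

#' Exclude variants by population minor-allele frequency
#' @inheritParams frequency_status
#' @return The subset of `variants` with MAF at or below the threshold
#'   (novel variants always retained).
#' @export
frequency_filter <- function(variants, frequencies = NULL,
                             config = filter_config()) {
  st <- frequency_status(variants, frequencies, config)
  new_variant_table(variants[st$passes_frequency, , drop = FALSE],
                    attr(variants, "samples"))
}

#' Threshold classification of external predictor scores
#'
#' Applies the published decision thresholds to the scores of one variant:
#' SIFT damaging iff value < 0.05; PolyPhen-2 categorized by the cutpoints
#' (`< low` benign, `< high` possibly damaging, else probably damaging);
#' PMUT pathological iff the neural-net output > 0.5; PANTHER deleterious iff
#' subPSEC < -3 (with a concordance flag against P_deleterious > 0.5);
#' MutPred deleterious iff probability > 0.5; PON-P2 pathogenic/neutral only
#' when probability +/- standard error clears 0.5, otherwise unknown.
#'
#' @param scores a named list or one-row data frame with any of `sift`,
#'   `polyphen2`, `pmut_nn`, `panther_subpsec`, `panther_pdel`, `ponp2_prob`,
#'   `ponp2_se`, `mutpred_prob`; absent scores are skipped. All absent is a
#'   typed `tp_no_scores` error.
#' @param polyphen2_cutpoints benign/probably-damaging cutpoints.
#' @return A `prediction_summary` list: `verdict` (named character, one entry
#'   per scored tool), `damaging` (named logical votes), `damaging_count`,
#'   `n_tools`, and `panther_concordant` (or `NA`).
#' @export
#' @examples
#' classify_predictions(list(sift = 0.00, polyphen2 = 0.991, pmut_nn = 0.8749,
#'                           panther_subpsec = -4.3388, panther_pdel = 0.79148,
#'                           ponp2_prob = 0.947, ponp2_se = 0.050,
#'                           mutpred_prob = 0.918))
classify_predictions <- function(scores,
                                 polyphen2_cutpoints = c(0.453, 0.957)) {
  if (is.data.frame(scores)) {
    stopifnot(nrow(scores) == 1L)
    scores <- as.list(scores)
  }
  get <- function(nm) {
    v <- scores[[nm]]
    if (is.null(v) || is.na(v)) NULL else as.numeric(v)
  }
  verdict <- character(0)
  damaging <- logical(0)
  vote <- function(tool, verd, dam) {
    verdict[[tool]] <<- verd
    damaging[[tool]] <<- dam
  }
  if (!is.null(s <- get("sift"))) {
    vote("SIFT", if (s < 0.05) "not tolerated" else "tolerated", s < 0.05)
  }
  if (!is.null(s <- get("polyphen2"))) {
    v <- if (s < polyphen2_cutpoints[1]) "benign"
         else if (s < polyphen2_cutpoints[2]) "possibly damaging"
         else "probably damaging"
    vote("PolyPhen-2", v, v != "benign")
  }
  if (!is.null(s <- get("pmut_nn"))) {
    vote("PMUT", if (s > 0.5) "pathological" else "neutral", s > 0.5)
  }
  panther_concordant <- NA
  if (!is.null(s <- get("panther_subpsec"))) {
    del <- s < -3
    vote("PANTHER", if (del) "deleterious" else "neutral", del)
    if (!is.null(p <- get("panther_pdel"))) panther_concordant <- (p > 0.5) == del
  }
  if (!is.null(p <- get("ponp2_prob"))) {
    se <- get("ponp2_se")
    if (is.null(se)) se <- 0
    v <- if (p - se > 0.5) "pathogenic" else if (p + se < 0.5) "neutral"
         else "unknown"
    vote("PON-P2", v, v == "pathogenic")
  }
  if (!is.null(s <- get("mutpred_prob"))) {
    vote("MutPred", if (s > 0.5) "deleterious" else "neutral", s > 0.5)
  }
  if (!length(verdict)) {
    stop(errorCondition("no predictor scores present",
                        class = c("tp_no_scores", "error")))
  }
  structure(list(verdict = verdict, damaging = damaging,
                 damaging_count = sum(damaging), n_tools = length(verdict),
                 panther_concordant = panther_concordant),
            class = "prediction_summary")
}

#' @export
print.prediction_summary <- function(x, ...) {
  cat(sprintf("%d of %d tools damaging\n", x$damaging_count, x$n_tools))
  for (nm in names(x$verdict)) cat(sprintf("  %-10s %s\n", nm, x$verdict[[nm]]))
  invisible(x)
}
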