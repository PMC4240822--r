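# Per-family reports: TSV trail table, full JSON trail, and a markdown
# summary mirroring the familiar published presentation (candidate summary
# rows plus a per-tool prediction grid).

#' Write a prioritization report
#'
#' `"tsv"` writes the full per-variant trail table; `"json"` the trails, the
#' stage counts and the candidate list; `"markdown"` a human-readable
#' per-family summary with the per-stage counts sentence, the candidate
#' table (physical location, cDNA/protein variant, MAF, Novel/Recurrent
#' status) and the per-tool prediction grid for annotated candidates.
#'
#' @param x a `prioritization` object.
#' @param path output path.
#' @param format one of `"tsv"`, `"json"`, `"markdown"`.
#' @return `path`, invisibly. Identical inputs and configuration produce
#'   byte-identical files.
#' @export
write_report <- function(x, path, format = c("tsv", "json", "markdown")) {
  stopifnot(inherits(x, "prioritization"))
  format <- match.arg(format)
  switch(format,
    tsv = write.table(x$trails, path, sep = "\t", quote = FALSE,
                      row.names = FALSE, na = "."),
    json = jsonlite::write_json(
      list(counts = x$counts, candidates = x$candidates, trails = x$trails),
      path, auto_unbox = TRUE, digits = NA, na = "null"),
    markdown = writeLines(.report_md(x), path))
  invisible(path)
}

.report_md <- function(x) {
  ct <- x$counts
  lines <- c(
    "# Variant prioritization report",
    "",
    sprintf("%d variants in %d of %d candidate genes.", ct$n_panel,
            ct$n_genes_hit, ct$n_panel_genes),
    sprintf("Of these, %d co-segregate with disease and %d survive the MAF <= %g exclusion.",
            ct$n_segregating, ct$n_candidates, x$config$maf_threshold),
    "")
  cand <- x$candidates
  if (nrow(cand)) {
    lines <- c(lines, "## Candidates", "",
      "| Location | Gene | cDNA variant | Protein variant | MAF | Status |",
      "|---|---|---|---|---|---|",
      sprintf("| %s:%s | %s | %s | %s | %s | %s |",
              cand$chrom, format(cand$pos, big.mark = ",", trim = TRUE),
              cand$gene,
              ifelse(is.na(cand$hgvs_c), ".", cand$hgvs_c),
              ifelse(is.na(cand$hgvs_p), ".", cand$hgvs_p),
              ifelse(cand$novel, "novel", format(cand$maf)),
              ifelse(is.na(cand$status), ".", cand$status)),
      "")
    pred <- cand[!is.na(cand$prediction), , drop = FALSE]
    if (nrow(pred)) {
      lines <- c(lines, "## In silico predictions", "",
        sprintf("- %s %s: %s (%d tool(s) damaging)",
                pred$gene, ifelse(is.na(pred$hgvs_p), pred$hgvs_c, pred$hgvs_p),
                pred$prediction, pred$damaging_count),
        "")
    }
  } else {
    lines <- c(lines, "No candidate variants.", "")
  }
  lines
}
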