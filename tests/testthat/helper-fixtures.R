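# Shared in-code fixtures: tiny pedigrees, transcripts, VCF writers, and the
# brute-force co-segregation oracle used to cross-check the filter.

# family-A-style trio: unaffected spouse, affected parent, affected child
trio_ped <- function() {
  structure(data.frame(
    id = c("I-1", "I-2", "II-1"),
    father = c(NA, NA, "I-1"), mother = c(NA, NA, "I-2"),
    sex = c(1L, 2L, 1L),
    affected = c("unaffected", "affected", "affected"),
    stringsAsFactors = FALSE), class = c("pedigree", "data.frame"))
}

make_vt <- function(chrom, pos, ref, alt, vid = "novel", gts, samples) {
  df <- data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
                   vid = vid, stringsAsFactors = FALSE)
  gts <- matrix(gts, nrow = nrow(df), ncol = length(samples))
  for (k in seq_along(samples)) df[[samples[k]]] <- gts[, k]
  trioprior:::new_variant_table(df, samples)
}

# single-exon plus-strand toy transcript: exon starts at genomic 1001,
# CDS at cDNA position 1
toy_tm <- function(cds = paste0("ATG", strrep("GGA", 30), "TAA")) {
  transcript_model("TOY", "chrT", "+", 1001L, 1000L + nchar(cds), 1L, cds)
}

write_vcf_text <- function(lines, samples = c("I-1", "I-2", "II-1")) {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    lines), path)
  path
}

# literal application of the published rule: present in every affected,
# absent from every unaffected; written independently of the implementation
seg_oracle <- function(gts, affected_idx, unaffected_idx,
                       missing = "strict") {
  alleles <- strsplit(gts, "/", fixed = TRUE)
  carrier <- function(ab) {
    if (any(ab == "1")) return(TRUE)
    if (any(ab == ".")) return(NA)
    FALSE
  }
  states <- lapply(alleles, carrier)
  ok <- TRUE
  for (i in affected_idx) {
    s <- states[[i]]
    if (is.na(s)) { if (missing == "strict") return(FALSE) }
    else if (!s) return(FALSE)
  }
  for (i in unaffected_idx) {
    s <- states[[i]]
    if (is.na(s)) { if (missing == "strict") return(FALSE) }
    else if (s) return(FALSE)
  }
  ok
}

fixture_transcripts <- function() {
  read_transcripts(tp_fixture("transcripts_synthetic.tsv"))
}

fixture_panel <- function() {
  read_panel(tp_fixture("cataract_panel_39.bed"))
}
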