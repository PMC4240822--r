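# Readers and writers for the standard input formats: multi-sample VCF,
# 6-column PED, BED4 gene panel, allele-frequency TSV, predictor-score TSV.
# All variant positions are 1-based (VCF convention); BED is converted from
# its 0-based half-open dialect at this boundary.

.gt_re <- "^([0-9]+|\\.)[/|]([0-9]+|\\.)$"

new_variant_table <- function(df, samples) {
  stopifnot(all(c("chrom", "pos", "ref", "alt", "vid") %in% names(df)))
  reserved <- c("chrom", "pos", "ref", "alt", "vid")
  if (any(samples %in% reserved)) {
    stop("sample ids clash with reserved column names: ",
         paste(intersect(samples, reserved), collapse = ", "), call. = FALSE)
  }
  if (nrow(df) > 0) {
    stopifnot(all(df$pos >= 1),
              all(grepl("^[ACGT]+$", df$ref)),
              all(grepl("^[ACGT]+$", df$alt)))
  }
  rownames(df) <- NULL
  structure(df, samples = samples, class = c("variant_table", "data.frame"))
}

#' @export
`[.variant_table` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out)) {
    attr(out, "samples") <- attr(x, "samples")
    class(out) <- c("variant_table", "data.frame")
  }
  out
}

#' Read a multi-sample VCF into a variant table
#'
#' Reads a VCF 4.x file (via \pkg{vcfR}) and normalizes it into one row per
#' (record, alt allele) pair. Multi-allelic records are split, with per-sample
#' genotypes recoded against the retained alt allele (alleles belonging to a
#' different alt are recoded as reference). Records whose FILTER is neither
#' `PASS` nor `.` are dropped, as are records with malformed genotypes (with
#' a warning) or with symbolic/non-ACGT alleles.
#'
#' @param path path to a VCF file (plain or bgzipped).
#' @param pedigree a [read_ped()] pedigree; every pedigree sample must be
#'   present in the VCF header (hard error naming the missing sample
#'   otherwise) and genotype columns are restricted to the pedigree samples.
#' @return A `variant_table`: a data frame with columns `chrom`, `pos`,
#'   `ref`, `alt`, `vid` (rs id, or `"novel"` for records without one) and one
#'   `"a/b"` genotype column per pedigree sample (alleles `0`, `1` or `.`).
#' @export
read_vcf <- function(path, pedigree) {
  stopifnot(inherits(pedigree, "pedigree"))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcf@fix
  gt <- vcf@gt
  if (is.null(gt) || ncol(gt) < 2L) {
    stop("VCF has no sample genotype columns", call. = FALSE)
  }
  vcf_samples <- colnames(gt)[-1L]
  missing <- setdiff(pedigree$id, vcf_samples)
  if (length(missing)) {
    stop("pedigree sample(s) absent from VCF header: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  samples <- pedigree$id

  keep_filter <- is.na(fix[, "FILTER"]) | fix[, "FILTER"] %in% c("PASS", ".")
  out <- vector("list", nrow(fix))
  for (i in seq_len(nrow(fix))) {
    if (!keep_filter[i]) next
    gts <- sub(":.*$", "", gt[i, samples])
    gts[is.na(gts) | gts == "."] <- "./."  # vcfR reports missing GT as NA
    if (!all(grepl(.gt_re, gts))) {
      warning("dropping ", fix[i, "CHROM"], ":", fix[i, "POS"],
              ": malformed genotype", call. = FALSE)
      next
    }
    ref <- toupper(fix[i, "REF"])
    alts <- toupper(strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]])
    if (!grepl("^[ACGT]+$", ref)) next
    al <- strsplit(sub("\\|", "/", gts), "/", fixed = TRUE)
    vid <- fix[i, "ID"]
    vid <- if (is.na(vid) || vid == ".") "novel" else vid
    rows <- lapply(seq_along(alts), function(k) {
      if (!grepl("^[ACGT]+$", alts[k])) return(NULL)
      rec <- vapply(al, function(ab) {
        paste(ifelse(ab == ".", ".", ifelse(ab == as.character(k), "1", "0")),
              collapse = "/")
      }, "")
      c(list(chrom = fix[i, "CHROM"], pos = as.integer(fix[i, "POS"]),
             ref = ref, alt = alts[k], vid = vid), as.list(rec))
    })
    out[[i]] <- rows
  }
  rows <- unlist(out, recursive = FALSE)
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    df <- data.frame(chrom = character(), pos = integer(), ref = character(),
                     alt = character(), vid = character(),
                     stringsAsFactors = FALSE)
    for (s in samples) df[[s]] <- character()
    return(new_variant_table(df, samples))
  }
  df <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  names(df) <- c("chrom", "pos", "ref", "alt", "vid", samples)
  new_variant_table(df, samples)
}

#' Write a variant table as a minimal multi-sample VCF 4.2
#'
#' Emits a GT-only VCF that [read_vcf()] reads back to the identical
#' `(chrom, pos, ref, alt, genotype)` tuples. Variant ids of `"novel"` are
#' written as `.`.
#'
#' @param variants a `variant_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path) {
  stopifnot(inherits(variants, "variant_table"))
  samples <- attr(variants, "samples")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=trioprior",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")), con)
  if (nrow(variants)) {
    ids <- ifelse(variants$vid == "novel", ".", variants$vid)
    body <- cbind(variants$chrom, variants$pos, ids, variants$ref,
                  variants$alt, ".", "PASS", ".", "GT",
                  as.matrix(variants[, samples, drop = FALSE]))
    writeLines(apply(body, 1L, paste, collapse = "\t"), con)
  }
  invisible(path)
}

#' Read a 6-column PED pedigree
#'
#' Whitespace-delimited PED: family id, sample id, father id, mother id, sex,
#' phenotype. Phenotype coding 2 = affected, 1 = unaffected, 0 or -9 =
#' unknown. Parent id 0 means founder.
#'
#' @param path path to a PED file.
#' @return A `pedigree` data frame with columns `id`, `father`, `mother`
#'   (`NA` for founders), `sex`, and `affected`
#'   (`"affected"`/`"unaffected"`/`"unknown"`).
#' @export
read_ped <- function(path) {
  raw <- tryCatch(read.table(path, header = FALSE, stringsAsFactors = FALSE),
                  error = function(e) stop("cannot read PED '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  if (ncol(raw) < 6L) stop("PED must have 6 columns", call. = FALSE)
  ids <- as.character(raw[[2]])
  if (anyDuplicated(ids)) {
    stop("duplicate sample id in PED: ", ids[duplicated(ids)][1], call. = FALSE)
  }
  fa <- as.character(raw[[3]]); mo <- as.character(raw[[4]])
  fa[fa == "0"] <- NA; mo[mo == "0"] <- NA
  bad <- setdiff(stats::na.omit(c(fa, mo)), ids)
  if (length(bad)) {
    stop("parent id not present in pedigree: ", bad[1], call. = FALSE)
  }
  ph <- as.character(raw[[6]])
  aff <- ifelse(ph == "2", "affected",
                ifelse(ph == "1", "unaffected",
                       ifelse(ph %in% c("0", "-9"), "unknown", NA)))
  if (anyNA(aff)) stop("unrecognized phenotype code in PED", call. = FALSE)
  structure(
    data.frame(id = ids, father = fa, mother = mo,
               sex = as.integer(raw[[5]]), affected = aff,
               stringsAsFactors = FALSE),
    class = c("pedigree", "data.frame"))
}

#' Write a pedigree as 6-column PED
#' @param pedigree a `pedigree`.
#' @param path output path.
#' @param family family id for column 1.
#' @return `path`, invisibly.
#' @export
write_ped <- function(pedigree, path, family = "FAM1") {
  ph <- c(affected = 2L, unaffected = 1L, unknown = 0L)[pedigree$affected]
  fa <- ifelse(is.na(pedigree$father), "0", pedigree$father)
  mo <- ifelse(is.na(pedigree$mother), "0", pedigree$mother)
  write.table(data.frame(family, pedigree$id, fa, mo, pedigree$sex, ph),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED4 candidate-gene panel
#'
#' BED intervals are 0-based half-open; they are kept that way in the panel
#' object and converted when intersecting with 1-based variant positions.
#'
#' @param path path to a BED file with at least 4 columns
#'   (chrom, start, end, gene symbol).
#' @return A `gene_panel` data frame with columns `gene`, `chrom`, `start`,
#'   `end`.
#' @export
read_panel <- function(path) {
  raw <- read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) < 4L) stop("panel BED needs 4 columns", call. = FALSE)
  start <- as.integer(raw[[2]]); end <- as.integer(raw[[3]])
  if (any(start >= end)) {
    stop("BED interval with start >= end at line ",
         which(start >= end)[1], call. = FALSE)
  }
  gene <- as.character(raw[[4]])
  if (anyDuplicated(gene)) {
    stop("duplicate gene symbol in panel: ", gene[duplicated(gene)][1],
         call. = FALSE)
  }
  structure(
    data.frame(gene = gene, chrom = as.character(raw[[1]]),
               start = start, end = end, stringsAsFactors = FALSE),
    class = c("gene_panel", "data.frame"))
}

.parse_counts <- function(x) {
  # "0/8,600" -> c(0, 8600); thousands separators accepted
  parts <- strsplit(gsub(",", "", x, fixed = TRUE), "/", fixed = TRUE)
  bad <- lengths(parts) != 2L
  if (any(bad)) stop("malformed allele-count string: ", x[bad][1], call. = FALSE)
  m <- matrix(as.numeric(unlist(parts)), ncol = 2L, byrow = TRUE)
  if (anyNA(m)) stop("non-numeric allele count", call. = FALSE)
  m
}

#' Read a population allele-frequency table
#'
#' Tab-separated with header. Either explicit `ac`/`an` integer columns or a
#' single `freq` column in the EVS report style `"alt count/total alleles"`
#' (thousands separators accepted, e.g. `"0/8,600"`), keyed by
#' `chrom`, `pos`, `ref`, `alt`.
#'
#' @param path path to the TSV.
#' @return A `frequency_table` data frame with columns `chrom`, `pos`, `ref`,
#'   `alt`, `ac`, `an` and the folded minor-allele frequency `maf`
#'   (`min(ac/an, 1 - ac/an)`).
#' @export
read_frequencies <- function(path) {
  raw <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(raw))) {
    stop("frequency table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (all(c("ac", "an") %in% names(raw))) {
    ac <- as.numeric(raw$ac); an <- as.numeric(raw$an)
  } else if ("freq" %in% names(raw)) {
    m <- .parse_counts(raw$freq)
    ac <- m[, 1]; an <- m[, 2]
  } else {
    stop("frequency table needs 'ac'+'an' or 'freq' columns", call. = FALSE)
  }
  frequency_table(raw$chrom, as.integer(raw$pos), toupper(raw$ref),
                  toupper(raw$alt), ac, an)
}

#' Construct a frequency table from allele counts
#' @param chrom,pos,ref,alt variant key vectors.
#' @param ac,an alternate-allele count and total allele number.
#' @return A `frequency_table` (see [read_frequencies()]).
#' @export
frequency_table <- function(chrom, pos, ref, alt, ac, an) {
  an <- rep_len(as.numeric(an), length(pos))
  ac <- rep_len(as.numeric(ac), length(pos))
  if (any(an <= 0)) stop("total allele number must be positive", call. = FALSE)
  if (any(ac < 0) || any(ac > an)) {
    stop("alt allele count must lie in [0, total]", call. = FALSE)
  }
  af <- ac / an
  structure(
    data.frame(chrom = as.character(chrom), pos = as.integer(pos),
               ref = ref, alt = alt, ac = ac, an = an,
               maf = pmin(af, 1 - af), stringsAsFactors = FALSE),
    class = c("frequency_table", "data.frame"))
}

.score_ranges <- list(
  sift = c(0, 1), polyphen2 = c(0, 1), pmut_nn = c(0, 1),
  pmut_reliability = c(0, 9), panther_subpsec = c(-Inf, 0),
  panther_pdel = c(0, 1), ponp2_prob = c(0, 1), ponp2_se = c(0, Inf),
  mutpred_prob = c(0, 1))

#' Read external predictor scores
#'
#' One row per variant, keyed by `chrom`, `pos`, `ref`, `alt`; recognized
#' score columns are `sift`, `polyphen2`, `pmut_nn`, `pmut_reliability`,
#' `panther_subpsec`, `panther_pdel`, `ponp2_prob`, `ponp2_se`,
#' `mutpred_prob`. Any score may be absent (`NA`); present values are
#' validated against their ranges.
#'
#' @param path path to the TSV.
#' @return A `predictor_scores` data frame.
#' @export
read_scores <- function(path) {
  raw <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(raw))) {
    stop("score table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  for (col in intersect(names(.score_ranges), names(raw))) {
    v <- raw[[col]]
    rng <- .score_ranges[[col]]
    ok <- is.na(v) | (v >= rng[1] & v <= rng[2])
    if (!all(ok)) {
      stop("score '", col, "' out of range [", rng[1], ", ", rng[2], "]: ",
           v[!ok][1], call. = FALSE)
    }
  }
  structure(raw, class = c("predictor_scores", "data.frame"))
}

#' Read a protein multiple alignment from aligned FASTA
#' @param path path to an aligned multi-FASTA file.
#' @return A named character vector of equal-length gapped sequences, first
#'   row first.
#' @export
read_alignment <- function(path) {
  aln <- Biostrings::readAAStringSet(path)
  setNames(as.character(aln), names(aln))
}
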