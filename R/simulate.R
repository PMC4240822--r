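# Synthetic family generator: Hardy-Weinberg founders, Mendelian
# transmission, one planted fully-penetrant dominant causal variant, and
# background panel variants carrying population frequencies. Emulates the
# data structure the filter cascade consumes so the whole pipeline can be
# verified without patient exomes.

.shapes <- c("trio", "family_b", "family_c")

#' Simulation configuration
#'
#' The defaults emulate one sequenced nuclear family: an affected
#' child-parent pair plus an unaffected spouse (`"trio"`), 100 background
#' panel variants with population minor-allele frequencies uniform on
#' `[0.004, 0.55]` (the range printed for the excluded family variants), a
#' 5 percent novel fraction (variants absent from the reference frequency
#' table), and a fully-penetrant dominant causal variant planted in one
#' panel gene.
#'
#' @param shape pedigree shape: `"trio"` (3 samples, 2 affected),
#'   `"family_b"` (5 samples, 4 affected) or `"family_c"` (4 samples, 2
#'   affected).
#' @param n_background number of background panel variants.
#' @param novel_fraction probability a background variant is absent from the
#'   frequency table (simulated as a private variant carried heterozygously
#'   by one random founder).
#' @param maf_range range of the uniform population allele-frequency draw
#'   for table-listed background variants.
#' @param genotype_error_rate per genotype, the probability that one
#'   randomly chosen allele is flipped after transmission.
#' @param causal optional list `(chrom, pos, ref, alt, gene)` pinning the
#'   planted variant; default: random position in `causal_gene`.
#' @param causal_gene panel gene for the planted variant; default: drawn at
#'   random.
#' @param panel a `gene_panel`; default: the packaged 39-gene cataract panel.
#' @param an total allele number reported in the simulated frequency table.
#' @param seed integer seed; identical configurations produce byte-identical
#'   outputs.
#' @return A `sim_config` list.
#' @export
sim_config <- function(shape = c("trio", "family_b", "family_c"),
                       n_background = 100L, novel_fraction = 0.05,
                       maf_range = c(0.004, 0.55), genotype_error_rate = 0,
                       causal = NULL, causal_gene = NULL, panel = NULL,
                       an = 8600L, seed = 1L) {
  shape <- match.arg(shape)
  stopifnot(n_background >= 0L,
            novel_fraction >= 0, novel_fraction <= 1,
            genotype_error_rate >= 0, genotype_error_rate <= 1,
            length(maf_range) == 2L, maf_range[1] > 0, maf_range[2] <= 1)
  if (is.null(panel)) panel <- read_panel(tp_fixture("cataract_panel_39.bed"))
  structure(list(shape = shape, n_background = as.integer(n_background),
                 novel_fraction = novel_fraction, maf_range = maf_range,
                 genotype_error_rate = genotype_error_rate,
                 causal = causal, causal_gene = causal_gene, panel = panel,
                 an = as.integer(an), seed = as.integer(seed)),
            class = "sim_config")
}

#' Pedigree for a simulation shape
#'
#' `"trio"`: unaffected father, affected mother, affected child (the
#' affected child-parent pair plus unaffected spouse). `"family_b"`:
#' affected father, unaffected mother, three affected children.
#' `"family_c"`: affected father, unaffected mother, one unaffected and one
#' affected child.
#'
#' @param shape one of `"trio"`, `"family_b"`, `"family_c"`.
#' @return A `pedigree` data frame.
#' @export
pedigree_shape <- function(shape = c("trio", "family_b", "family_c")) {
  shape <- match.arg(shape)
  df <- switch(shape,
    trio = data.frame(
      id = c("I-1", "I-2", "II-1"),
      father = c(NA, NA, "I-1"), mother = c(NA, NA, "I-2"),
      sex = c(1L, 2L, 1L),
      affected = c("unaffected", "affected", "affected")),
    family_b = data.frame(
      id = c("I-1", "I-2", "II-1", "II-2", "II-3"),
      father = c(NA, NA, "I-1", "I-1", "I-1"),
      mother = c(NA, NA, "I-2", "I-2", "I-2"),
      sex = c(1L, 2L, 1L, 2L, 1L),
      affected = c("affected", "unaffected", "affected", "affected",
                   "affected")),
    family_c = data.frame(
      id = c("I-1", "I-2", "II-1", "II-2"),
      father = c(NA, NA, "I-1", "I-1"),
      mother = c(NA, NA, "I-2", "I-2"),
      sex = c(1L, 2L, 2L, 1L),
      affected = c("affected", "unaffected", "unaffected", "affected")))
  df$id <- as.character(df$id)
  df$father <- as.character(df$father); df$mother <- as.character(df$mother)
  structure(df, class = c("pedigree", "data.frame"))
}

.bases <- c("A", "C", "G", "T")

.gt_str <- function(a1, a2) paste(a1, a2, sep = "/")

#' Simulate one family dataset
#'
#' Draws background variant positions uniformly within the panel gene
#' regions. Founder genotypes at table-frequency variants follow
#' Hardy-Weinberg at the variant's population allele frequency; novel
#' variants (absent from the frequency table) are private to one random
#' founder, carried heterozygously. Children inherit one allele per parent
#' uniformly at random. The planted causal variant is heterozygous in every
#' affected sample, absent from every unaffected sample and absent from the
#' frequency table (full penetrance, dominant, monogenic). Genotype errors
#' then flip one random allele of each genotype independently with the
#' configured rate.
#'
#' @param config a [sim_config()].
#' @param dir optional output directory; when given, writes `family.vcf`,
#'   `family.ped`, `frequencies.tsv` and `truth.json`.
#' @return A `sim_family` list: `variants` (a `variant_table`), `pedigree`,
#'   `frequencies` (a `frequency_table`), `truth` (the planted variant:
#'   chrom, pos, ref, alt, gene) and `config`; plus `paths` when `dir` is
#'   given.
#' @export
simulate_family <- function(config = sim_config(), dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (exists(".Random.seed", globalenv())) {
    old_seed <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  }
  set.seed(config$seed)

  ped <- pedigree_shape(config$shape)
  if (!any(ped$affected == "affected")) {
    stop("pedigree shape has no affected samples", call. = FALSE)
  }
  founders <- ped$id[is.na(ped$father)]
  children <- ped$id[!is.na(ped$father)]
  panel <- config$panel

  # --- positions: causal first (reserved), then background ---
  widths <- panel$end - panel$start
  pick_pos <- function(gene) {
    r <- panel[panel$gene == gene, ]
    as.integer(r$start + sample.int(r$end - r$start, 1L))  # 1-based in region
  }
  causal <- config$causal
  if (is.null(causal)) {
    gene <- if (!is.null(config$causal_gene)) config$causal_gene
            else sample(panel$gene, 1L, prob = widths)
    r <- panel[panel$gene == gene, ]
    ref <- sample(.bases, 1L)
    causal <- list(chrom = r$chrom, pos = pick_pos(gene), ref = ref,
                   alt = sample(setdiff(.bases, ref), 1L), gene = gene)
  }

  nb <- config$n_background
  bg_gene <- if (nb) sample(panel$gene, nb, replace = TRUE, prob = widths)
             else character(0)
  bg_pos <- vapply(bg_gene, pick_pos, 1L)
  bg_chrom <- panel$chrom[match(bg_gene, panel$gene)]
  # avoid duplicate sites (incl. the causal site)
  dup <- duplicated(paste(bg_chrom, bg_pos)) |
    (bg_chrom == causal$chrom & bg_pos == causal$pos)
  while (any(dup)) {
    bg_pos[dup] <- vapply(bg_gene[dup], pick_pos, 1L)
    dup <- duplicated(paste(bg_chrom, bg_pos)) |
      (bg_chrom == causal$chrom & bg_pos == causal$pos)
  }
  bg_ref <- sample(.bases, nb, replace = TRUE)
  bg_alt <- vapply(bg_ref, function(r) sample(setdiff(.bases, r), 1L), "")
  bg_p <- runif(nb, config$maf_range[1], config$maf_range[2])
  bg_novel <- runif(nb) < config$novel_fraction

  # --- founder genotypes (allele-count matrix: variants x samples) ---
  nv <- nb + 1L
  dose1 <- matrix(0L, nv, length(ped$id), dimnames = list(NULL, ped$id))
  dose2 <- dose1
  for (f in founders) {
    if (nb) {
      a1 <- as.integer(runif(nb) < bg_p)
      a2 <- as.integer(runif(nb) < bg_p)
      a1[bg_novel] <- 0L; a2[bg_novel] <- 0L
      dose1[seq_len(nb), f] <- a1
      dose2[seq_len(nb), f] <- a2
    }
  }
  if (nb && any(bg_novel)) {
    carrier <- sample(founders, sum(bg_novel), replace = TRUE)
    dose1[which(bg_novel), ] <- 0L
    for (k in seq_along(carrier)) {
      dose1[which(bg_novel)[k], carrier[k]] <- 1L
    }
  }
  # children inherit one allele per parent uniformly
  for (ch in children) {
    fa <- ped$father[ped$id == ch]; mo <- ped$mother[ped$id == ch]
    from_fa <- ifelse(runif(nv) < 0.5, dose1[, fa], dose2[, fa])
    from_mo <- ifelse(runif(nv) < 0.5, dose1[, mo], dose2[, mo])
    dose1[, ch] <- from_fa
    dose2[, ch] <- from_mo
  }
  # planted causal variant: genotype determined by affection status
  # (full penetrance; the affected founder is the transmitting parent)
  crow <- nv
  aff <- ped$affected == "affected"
  dose1[crow, ] <- as.integer(aff)
  dose2[crow, ] <- 0L

  # genotype errors: flip one random allele with the configured rate
  eps <- config$genotype_error_rate
  if (eps > 0) {
    for (s in ped$id) {
      hit <- runif(nv) < eps
      which_allele <- runif(nv) < 0.5
      flip1 <- hit & which_allele
      flip2 <- hit & !which_allele
      dose1[flip1, s] <- 1L - dose1[flip1, s]
      dose2[flip2, s] <- 1L - dose2[flip2, s]
    }
  }

  chrom <- c(bg_chrom, causal$chrom)
  pos <- c(bg_pos, causal$pos)
  ref <- c(bg_ref, causal$ref)
  alt <- c(bg_alt, causal$alt)
  vid <- c(ifelse(bg_novel, "novel", sprintf("rs9%06d", seq_len(max(nb, 0L)))),
           "novel")
  df <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt, vid = vid,
                   stringsAsFactors = FALSE)
  for (s in ped$id) df[[s]] <- .gt_str(dose1[, s], dose2[, s])
  ord <- order(match(df$chrom, unique(panel$chrom)), df$pos)
  variants <- new_variant_table(df[ord, , drop = FALSE], ped$id)

  keep <- if (nb) which(!bg_novel) else integer(0)
  freqs <- frequency_table(bg_chrom[keep], bg_pos[keep], bg_ref[keep],
                           bg_alt[keep],
                           ac = round(bg_p[keep] * config$an), an = config$an)

  out <- structure(list(variants = variants, pedigree = ped,
                        frequencies = freqs, truth = causal, config = config),
                   class = "sim_family")
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(vcf = file.path(dir, "family.vcf"),
                  ped = file.path(dir, "family.ped"),
                  frequencies = file.path(dir, "frequencies.tsv"),
                  truth = file.path(dir, "truth.json"))
    write_vcf(variants, paths$vcf)
    write_ped(ped, paths$ped)
    write.table(freqs[, c("chrom", "pos", "ref", "alt", "ac", "an")],
                paths$frequencies, sep = "\t", quote = FALSE,
                row.names = FALSE)
    jsonlite::write_json(causal, paths$truth, auto_unbox = TRUE)
    out$paths <- paths
  }
  out
}

#' @export
print.sim_family <- function(x, ...) {
  cat(sprintf(
    "simulated %s family: %d samples, %d variant(s), causal %s:%d %s>%s (%s)\n",
    x$config$shape, nrow(x$pedigree), nrow(x$variants),
    x$truth$chrom, x$truth$pos, x$truth$ref, x$truth$alt, x$truth$gene))
  invisible(x)
}

#' Planted-variant recovery under genotyping error
#'
#' For each genotyping error rate, simulates `n_reps` families, runs the
#' full cascade, and reports the fraction of replicates in which the planted
#' causal variant is among the candidates, together with the mean number of
#' false candidates (background variants surviving all filters).
#'
#' @param error_rates numeric vector of genotype error rates.
#' @param n_reps replicates per rate.
#' @param shape pedigree shape passed to [sim_config()].
#' @param n_background background variants per family.
#' @param config_filter a [filter_config()].
#' @param seed base seed; replicate `j` at rate index `i` uses
#'   `seed + 10000*i + j`.
#' @param ... further arguments to [sim_config()].
#' @return A data frame with one row per error rate: `error_rate`,
#'   `recovery`, `mean_false_candidates`, `n_reps`.
#' @export
recovery_experiment <- function(error_rates, n_reps = 50L, shape = "trio",
                                n_background = 100L,
                                config_filter = filter_config(),
                                seed = 1L, ...) {
  stopifnot(n_reps >= 1L)
  panel <- read_panel(tp_fixture("cataract_panel_39.bed"))
  rows <- lapply(seq_along(error_rates), function(i) {
    hit <- logical(n_reps)
    false_cand <- integer(n_reps)
    for (j in seq_len(n_reps)) {
      cfg <- sim_config(shape = shape, n_background = n_background,
                        genotype_error_rate = error_rates[i], panel = panel,
                        seed = seed + 10000L * i + j, ...)
      sim <- simulate_family(cfg)
      pr <- prioritize(sim$variants, sim$pedigree, panel, sim$frequencies,
                       config = config_filter)
      is_truth <- pr$candidates$chrom == sim$truth$chrom &
        pr$candidates$pos == sim$truth$pos
      hit[j] <- any(is_truth)
      false_cand[j] <- sum(!is_truth)
    }
    data.frame(error_rate = error_rates[i], recovery = mean(hit),
               mean_false_candidates = mean(false_cand), n_reps = n_reps)
  })
  do.call(rbind, rows)
}
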