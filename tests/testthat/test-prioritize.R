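# Family-A-like in-memory dataset: six co-segregating panel variants, five
# with population MAFs in the printed range, one novel coding variant.
family_a_like <- function() {
  ped <- trio_ped()
  pos <- c(208989018L, 91222287L, 31810000L, 111780000L, 73755000L, 73756000L)
  chrom <- c("chr2", "chr10", "chr11", "chr11", "chr17", "chr17")
  vt <- make_vt(chrom, pos,
                ref = c("C", "T", "A", "G", "C", "A"),
                alt = c("A", "G", "G", "A", "T", "G"),
                vid = c("rs28931605", "rs3740030", "rs101", "rs102", "rs103",
                        "rs104"),
                gts = matrix(rep(c("0/0", "0/1", "0/1"), each = 6), ncol = 3),
                samples = ped$id)
  mafs <- c(0.085, 0.20, 0.31, 0.45, 0.524)
  ft <- frequency_table(chrom = c("chr2", chrom[-1]),
                        pos = c(208989018L, pos[-1]),
                        ref = c("C", vt$ref[-1]), alt = c("A", vt$alt[-1]),
                        ac = round(c(0, mafs) * 8600), an = 8600)
  list(variants = vt, pedigree = ped, frequencies = ft)
}

test_that("the family-A-like dataset yields exactly one candidate", {
  fa <- family_a_like()
  pr <- prioritize(fa$variants, fa$pedigree, fixture_panel(),
                   fa$frequencies,
                   transcripts = fixture_transcripts(),
                   scores = tp_fixture("predictor_scores_published.tsv"),
                   alignments = list(
                     CRYGD = read_alignment(tp_fixture("CRYGD_alignment_synthetic.fa"))),
                   known_mutations = tp_fixture("known_mutations.tsv"))
  expect_equal(pr$counts$n_candidates, 1L)
  cand <- pr$candidates
  expect_equal(cand$vid, "rs28931605")
  expect_equal(cand$gene, "CRYGD")
  expect_equal(cand$hgvs_c, "c.70C>A")
  expect_equal(cand$hgvs_p, "p.Pro24Thr")
  expect_equal(cand$status, "Recurrent")
  expect_equal(cand$conservation, 0.25)
  # retained despite tolerated/benign/neutral in silico verdicts
  expect_equal(cand$damaging_count, 1L)
  excl <- pr$trails[pr$trails$final == "excluded", ]
  expect_true(all(excl$reason == "population MAF above threshold"))
})

test_that("variants outside the panel are all excluded with that reason", {
  ped <- trio_ped()
  vt <- make_vt("chr14", c(100L, 200L), "A", "C",
                gts = matrix(c("0/0", "0/1", "0/1"), 2, 3, byrow = TRUE),
                samples = ped$id)
  pr <- prioritize(vt, ped, fixture_panel())
  expect_equal(pr$counts$n_candidates, 0L)
  expect_true(all(pr$trails$final == "excluded"))
  expect_true(all(pr$trails$reason == "not in panel"))
})

test_that("the planted causal variant is the unique candidate by construction", {
  # with no novel background variants every background site carries a table
  # MAF above the threshold, so uniqueness is guaranteed, not seed-dependent
  panel <- fixture_panel()
  cfg <- sim_config(novel_fraction = 0, seed = 11)
  sim <- simulate_family(cfg)
  pr <- prioritize(sim$variants, sim$pedigree, panel, sim$frequencies)
  expect_equal(pr$counts$n_candidates, 1L)
  expect_equal(pr$candidates$pos, sim$truth$pos)
  expect_equal(pr$candidates$chrom, sim$truth$chrom)
})

test_that("under the default generator the planted variant is always recovered", {
  panel <- fixture_panel()
  for (seed in c(1, 7, 23)) {
    sim <- simulate_family(sim_config(seed = seed))
    pr <- prioritize(sim$variants, sim$pedigree, panel, sim$frequencies)
    hit <- pr$candidates$chrom == sim$truth$chrom &
      pr$candidates$pos == sim$truth$pos
    expect_true(any(hit))
    # any extra candidate must be a chance-co-segregating novel background
    expect_true(all(pr$candidates$novel))
  }
})

test_that("filter stages commute: any application order gives the same set", {
  panel <- fixture_panel()
  cfg <- filter_config()
  key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt)
  for (seed in 1:5) {
    sim <- simulate_family(sim_config(seed = seed, n_background = 40))
    filters <- list(
      p = function(v) {
        out <- panel_filter(v, panel)
        trioprior:::new_variant_table(
          out[, setdiff(names(out), "gene")], attr(out, "samples"))
      },
      s = function(v) segregation_filter(v, sim$pedigree, cfg),
      f = function(v) frequency_filter(v, sim$frequencies, cfg))
    orders <- list(c("p", "s", "f"), c("p", "f", "s"), c("s", "p", "f"),
                   c("s", "f", "p"), c("f", "p", "s"), c("f", "s", "p"))
    sets <- lapply(orders, function(ord) {
      v <- sim$variants
      for (nm in ord) v <- filters[[nm]](v)
      sort(key(v))
    })
    for (s in sets[-1]) expect_identical(s, sets[[1]])
  }
})

test_that("lowering the MAF threshold never adds candidates", {
  panel <- fixture_panel()
  sim <- simulate_family(sim_config(seed = 3))
  thresholds <- c(0.05, 0.01, 1e-3, 1e-4, 0)
  keys <- lapply(thresholds, function(th) {
    pr <- prioritize(sim$variants, sim$pedigree, panel, sim$frequencies,
                     config = filter_config(maf_threshold = th))
    paste(pr$candidates$chrom, pr$candidates$pos)
  })
  for (i in seq_along(keys)[-1]) {
    expect_true(all(keys[[i]] %in% keys[[i - 1]]))
  }
})

test_that("adding an unaffected carrier sample never adds candidates", {
  panel <- fixture_panel()
  sim <- simulate_family(sim_config(seed = 5, shape = "family_c"))
  ped <- sim$pedigree
  pr_full <- prioritize(sim$variants, ped, panel, sim$frequencies)
  # drop the unaffected child, then compare: the smaller pedigree can only
  # have a superset of candidates
  ped_small <- structure(ped[ped$id != "II-1", ],
                         class = c("pedigree", "data.frame"))
  vt_small <- trioprior:::new_variant_table(
    sim$variants[, c("chrom", "pos", "ref", "alt", "vid", ped_small$id)],
    ped_small$id)
  pr_small <- prioritize(vt_small, ped_small, panel, sim$frequencies)
  key <- function(pr) paste(pr$candidates$chrom, pr$candidates$pos)
  expect_true(all(key(pr_full) %in% key(pr_small)))
})

test_that("conservation and prediction stages annotate but never change the verdict", {
  fa <- family_a_like()
  bare <- prioritize(fa$variants, fa$pedigree, fixture_panel(),
                     fa$frequencies)
  full <- prioritize(fa$variants, fa$pedigree, fixture_panel(),
                     fa$frequencies,
                     transcripts = fixture_transcripts(),
                     scores = tp_fixture("predictor_scores_published.tsv"),
                     alignments = list(
                       CRYGD = read_alignment(tp_fixture("CRYGD_alignment_synthetic.fa"))))
  expect_identical(bare$trails$final, full$trails$final)
  expect_identical(bare$trails$reason, full$trails$reason)
})

test_that("candidates sort by damaging count, then MAF, then coordinate", {
  ped <- trio_ped()
  vt <- make_vt(c("chr1", "chr1", "chr2"),
                c(147380102L, 147380375L, 208989018L),
                ref = c("T", "A", "C"), alt = c("C", "C", "A"),
                gts = matrix(rep(c("0/0", "0/1", "0/1"), each = 3), ncol = 3),
                samples = ped$id)
  pr <- prioritize(vt, ped, fixture_panel(),
                   transcripts = fixture_transcripts(),
                   scores = tp_fixture("predictor_scores_published.tsv"))
  expect_equal(pr$counts$n_candidates, 3L)
  expect_equal(pr$candidates$damaging_count, c(6L, 5L, 1L))
  expect_equal(pr$candidates$hgvs_p,
               c("p.Leu7Pro", "p.His98Pro", "p.Pro24Thr"))
})

test_that("prioritization summary prints the per-stage counts sentence", {
  fa <- family_a_like()
  pr <- prioritize(fa$variants, fa$pedigree, fixture_panel(), fa$frequencies)
  out <- paste(capture.output(print(pr)), collapse = "\n")
  expect_match(out, "6 variants in 5 of 39 candidate genes")
  expect_match(out, "co-segregating with disease: 6")
  expect_match(out, "1 candidate")
  expect_equal(summary(pr)$n_genes_hit, 5L)
})
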