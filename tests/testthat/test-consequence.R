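tms <- fixture_transcripts()

test_that("codon arithmetic matches the published codon assignments", {
  expect_equal(codon_of(70)$codon_index, 24L)
  expect_equal(codon_of(70)$offset, 0L)
  expect_equal(codon_of(20)$codon_index, 7L)
  expect_equal(codon_of(20)$offset, 1L)
  expect_equal(codon_of(293)$codon_index, 98L)
  expect_equal(codon_of(293)$offset, 1L)
  expect_equal(codon_of(1)$codon_index, 1L)
  expect_error(codon_of(0), ">= 1")
})

test_that("codon arithmetic is a bijection over the CDS", {
  n <- tms$CRYGD$cds_len
  co <- codon_of(seq_len(n))
  expect_identical(3L * (co$codon_index - 1L) + co$offset + 1L, seq_len(n))
})

test_that("genomic/cDNA mapping anchors the published coordinate pairs", {
  expect_equal(genomic_to_cdna(208989018, tms$CRYGD), 70L)
  expect_equal(genomic_to_cdna(147380102, tms$GJA8), 20L)
  expect_equal(genomic_to_cdna(147380375, tms$GJA8), 293L)
})

test_that("a single-exon transcript maps by plain offset and c.1 is the first CDS base", {
  tm <- toy_tm()
  expect_equal(genomic_to_cdna(1070, tm), 70L)
  expect_equal(genomic_to_cdna(1001, tm), 1L)
  expect_equal(cdna_to_genomic(1L, tm), 1001L)
})

test_that("genomic_to_cdna and cdna_to_genomic compose to identity on both strands", {
  for (tm in tms) {
    for (c_pos in seq_len(tm$cds_len)) {
      g <- cdna_to_genomic(c_pos, tm)
      expect_identical(genomic_to_cdna(g, tm), c_pos)
    }
  }
  expect_equal(tms$GJA3$strand, "-")  # minus strand exercised
})

test_that("intronic and UTR positions raise the typed non-coding error", {
  expect_error(genomic_to_cdna(208988700, tms$CRYGD),
               class = "tp_non_coding_error")  # intron
  expect_error(genomic_to_cdna(147379310, tms$GJA8),
               class = "tp_non_coding_error")  # 5' UTR exon
  expect_error(genomic_to_cdna(1, tms$CRYGD),
               class = "tp_non_coding_error")  # off transcript
})

test_that("the three published substitutions translate to the printed calls", {
  cc <- translate_substitution(tms$CRYGD, 70, "C", "A")
  expect_equal(cc$hgvs_c, "c.70C>A")
  expect_equal(cc$hgvs_p, "p.Pro24Thr")
  expect_equal(cc$ref_aa, "Pro")
  expect_equal(cc$alt_aa, "Thr")
  expect_equal(cc$klass, "missense")

  cc <- translate_substitution(tms$GJA8, 20, "T", "C")
  expect_equal(cc$hgvs_p, "p.Leu7Pro")
  cc <- translate_substitution(tms$GJA8, 293, "A", "C")
  expect_equal(cc$hgvs_p, "p.His98Pro")
})

test_that("any codon synonymous with the reference amino acid yields the same protein call", {
  # the printed data fix only the amino acids; all four proline codons at
  # codon 24 must give p.Pro24Thr for the first-base C>A substitution
  for (codon in c("CCA", "CCC", "CCG", "CCT")) {
    cds <- tms$CRYGD$cds_seq
    substr(cds, 70, 72) <- codon
    tm <- transcript_model("CRYGD", "chr2", "+", tms$CRYGD$exon_starts,
                           tms$CRYGD$exon_ends, 1L, cds)
    cc <- translate_substitution(tm, 70, "C", "A")
    expect_equal(cc$hgvs_p, "p.Pro24Thr")
    expect_equal(cc$klass, "missense")
  }
})

test_that("translation agrees with an independently entered code table on all 64 codons", {
  skip_if_not_installed("seqinr")
  for (b1 in c("A", "C", "G", "T")) for (b2 in c("A", "C", "G", "T"))
    for (b3 in c("A", "C", "G", "T")) {
      codon <- paste0(b1, b2, b3)
      tm <- transcript_model("T64", "chrT", "+", 1L, 6L, 1L,
                             paste0("ATG", codon))
      cc <- translate_substitution(tm, 4L, b1, b1)
      oracle1 <- seqinr::translate(strsplit(codon, "")[[1]])
      oracle3 <- if (oracle1 == "*") "Ter" else
        unname(seqinr::aaa(oracle1))
      expect_equal(cc$ref_aa, oracle3, info = codon)
    }
})

test_that("substitution classes cover synonymous, nonsense and start-lost", {
  tm <- toy_tm()  # codons: ATG GGA GGA ... TAA
  same <- translate_substitution(tm, 5, "G", "G")
  expect_equal(same$klass, "synonymous")
  expect_equal(same$hgvs_p, "p.(=)")
  syn <- translate_substitution(tm, 6, "A", "G")  # GGA -> GGG, both Gly
  expect_equal(syn$klass, "synonymous")
  expect_equal(syn$hgvs_p, "p.Gly2=")
  non <- translate_substitution(tm, 4, "G", "T")  # GGA -> TGA stop
  expect_equal(non$klass, "nonsense")
  expect_equal(non$alt_aa, "Ter")
  sl <- translate_substitution(tm, 2, "T", "C")   # ATG -> ACG
  expect_equal(sl$klass, "start-lost")
})

test_that("substituting any base by itself is synonymous everywhere", {
  tm <- tms$GJA3
  set.seed(1)
  for (c_pos in sample.int(tm$cds_len, 40L)) {
    b <- substr(tm$cds_seq, c_pos, c_pos)
    expect_equal(translate_substitution(tm, c_pos, b, b)$klass, "synonymous")
  }
})

test_that("a reference-base mismatch raises the typed error with both bases", {
  err <- tryCatch(translate_substitution(tms$CRYGD, 70, "G", "A"),
                  tp_reference_mismatch = identity)
  expect_s3_class(err, "tp_reference_mismatch")
  expect_equal(err$expected, "C")
  expect_equal(err$given, "G")
})

test_that("HGVS formatting and parsing round trip", {
  expect_equal(parse_hgvs_c("c.70C>A"), list(c_pos = 70L, ref = "C", alt = "A"))
  expect_equal(parse_hgvs_c("c.293A>C"),
               list(c_pos = 293L, ref = "A", alt = "C"))
  set.seed(2)
  for (i in 1:30) {
    p <- sample.int(2000, 1)
    ba <- sample(c("A", "C", "G", "T"), 2)
    s <- sprintf("c.%d%s>%s", p, ba[1], ba[2])
    got <- parse_hgvs_c(s)
    expect_equal(sprintf("c.%d%s>%s", got$c_pos, got$ref, got$alt), s)
  }
  expect_error(parse_hgvs_c("c.70C>"), "malformed")
  expect_error(parse_hgvs_c("p.Pro24Thr"), "malformed")
})

test_that("mature-protein renumbering drops the initiator methionine", {
  expect_equal(mature_numbering(24), 23L)
  expect_equal(mature_numbering(2), 1L)
  expect_error(mature_numbering(1), class = "tp_initiator_error")
})

test_that("conservation counts matching non-reference rows, gaps as mismatches", {
  ident <- rep("MKLVP", 5)
  expect_equal(conservation_fraction(ident, 3), 1.0)
  aln <- c(ref = "ML", a = "ML", b = "ML", c = "MP", d = "M-")
  expect_equal(conservation_fraction(aln, 2), 0.5)
  expect_error(conservation_fraction("MKLVP", 1), "no comparison rows")
  expect_error(conservation_fraction(ident, 6), "out of range")
  expect_error(conservation_fraction(c("ML", "MLL"), 1), "length")
})

test_that("gaps in the reference row are skipped when indexing residues", {
  aln <- c(ref = "M-KL", a = "MQKL", b = "MQKP")
  expect_equal(conservation_fraction(aln, 2), 1.0)  # residue 2 of ref is K
  expect_equal(conservation_fraction(aln, 3), 0.5)  # residue 3 is L
})

test_that("fixture alignments show low conservation at CRYGD Pro24, high at GJA8 Leu7/His98", {
  crygd <- read_alignment(tp_fixture("CRYGD_alignment_synthetic.fa"))
  gja8 <- read_alignment(tp_fixture("GJA8_alignment_synthetic.fa"))
  expect_equal(conservation_fraction(crygd, 24), 0.25)
  expect_equal(conservation_fraction(gja8, 7), 1.0)
  expect_equal(conservation_fraction(gja8, 98), 1.0)
})

test_that("transcript models validate their coding sequence", {
  expect_error(transcript_model("X", "chr1", "+", 1, 7, 1, "ATGGGAA"),
               "divisible by 3")
  expect_error(transcript_model("X", "chr1", "+", 1, 6, 1, "TTGGGA"),
               "begin with ATG")
  expect_error(transcript_model("X", "chr1", "+", 1, 9, 1, "ATGTAAGGA"),
               "internal stop")
  expect_error(transcript_model("X", "chr1", "+", c(1, 5), c(10, 20), 1,
                                "ATGGGA"), "order|overlap")
})
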