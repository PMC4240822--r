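---
title: "Trio-based candidate-gene variant prioritization: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trio-based candidate-gene variant prioritization: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trioprior)
```

## The model

trioprior implements the deterministic filter cascade used to isolate causal
mutations in nuclear families segregating a monogenic, fully penetrant,
autosomal dominant trait — the setting of trio exome studies of inherited
cataract, where a curated panel of 39 candidate genes (crystallins,
connexins, lens membrane/cytoskeletal genes, and several transcription
factors) restricts the search space.

Under full penetrance and dominance, the causal allele is carried by every
affected family member and by no unaffected member. With one affected
child–parent pair plus an unaffected spouse (a "trio"), three independent
predicates on each variant suffice:

* **panel**: the position falls inside a candidate-gene interval;
* **co-segregation**: every affected sample has at least one alternate
  allele, every unaffected sample has none (zygosity is deliberately not
  constrained — the model states presence/absence only, so a homozygous
  affected carrier passes);
* **frequency**: the folded minor allele frequency
  `min(ac/an, 1 - ac/an)` in a reference population does not exceed the
  threshold. A dominant, fully penetrant disease allele cannot be common, so
  variants with MAF above 0.01 % (`1e-4`) are excluded; variants absent from
  the table are treated as novel (MAF 0) and retained. The rule is a strict
  inequality: a variant exactly at the threshold is retained. All published
  family exclusions lie between 0.4 % and 54.69 %, so the verdicts are
  insensitive to the exact reading of the threshold over several orders of
  magnitude.

The predicates are evaluated independently for every variant, so the
candidate set cannot depend on the order in which filters are applied; the
recorded exclusion reason names the first failed stage in the canonical
order (panel, segregation, frequency). Every input variant receives a full
trail — the audit record matters as much as the candidate list.

Consequence, conservation and predictor classification are *annotations*:
they inform interpretation but never change the candidate/excluded verdict.
This mirrors practice — the recurrent CRYGD p.Pro24Thr cataract mutation is
called tolerated/benign/neutral by most predictors and poorly conserved
across species, yet it is the established causal allele; a pipeline that
filtered on predictions would discard it.

## Consequence engine

Transcript models carry exon intervals (1-based, inclusive, ordered 5′→3′ in
transcript orientation), the cDNA offset of the initiator ATG, and the
coding sequence (validated: length divisible by 3, starts ATG, no internal
stop). Genomic positions map to coding positions by exon-walk; minus-strand
transcripts complement incoming alleles. Codon arithmetic is the exact
integer form: `codon_index = floor((c_pos - 1)/3) + 1`,
`offset = (c_pos - 1) mod 3`. Translation uses the standard genetic code
(`Biostrings::GENETIC_CODE`); the test suite cross-checks all 64 codons
against a second, independently maintained code table (seqinr).

Only single-nucleotide substitutions in the CDS are supported — the HGVS
subset `c.<pos><ref>><alt>` / `p.<RefAa><idx><AltAa>` — because that is the
variant class the cascade consumes; indel and splice nomenclature are out of
scope. Protein numbering sets the initiator Met = 1; the mature-protein view
(`mature_numbering()`, residue k → k−1 after initiator removal) is an
explicit separate operation rather than a default, avoiding the historical
ambiguity between p.Pro24Thr and p.Pro23Thr for the same CRYGD allele.

The packaged transcript models are *synthetic fixtures* (so named in their
file): no transcript accessions accompany the published coordinate pairs, so
the fixtures anchor exactly those pairs (chr2:208,989,018 ↔ c.70;
chr1:147,380,102 ↔ c.20; chr1:147,380,375 ↔ c.293) with otherwise random
non-stop codons. The printed allele pair C>A at the CRYGD site fixes that
fixture to the plus strand; a minus-strand fixture transcript is included so
both strands are exercised by the mapping-bijection tests. Because the
published data fix amino acids but not codons, the fixture codons are one
choice from the synonymous class (CCA, CTG, CAT), and the suite asserts that
every synonymous alternative yields the identical protein-level call.

Conservation is the fraction of non-reference alignment rows matching the
reference residue at a column, with gaps counted as mismatches —
conservative and deterministic, at the cost of penalizing legitimately
gapped orthologs. Columns are indexed by reference residue number (gaps in
the reference row are skipped), so codon indices address alignment columns
directly. The shipped alignments are synthetic illustrations reproducing the
qualitative published pattern (Pro24 poorly conserved, 0.25; Leu7 and His98
fully conserved, 1.0), not curated orthologs.

## Predictor classification

`classify_predictions()` applies the published decision thresholds: SIFT
damaging below 0.05; PolyPhen-2 categorized at 0.453/0.957 (the tool's own
HumDiv sensitivity cutpoints); PMUT pathological above 0.5; PANTHER
deleterious below subPSEC −3, with a concordance flag against
P_deleterious > 0.5; MutPred deleterious above 0.5. PON-P2 reports a
probability with a standard error, so its verdict is "unknown" whenever
probability ± SE straddles 0.5 — this reproduces the published verdicts for
all three study variants (pathogenic at 0.947 ± 0.050; unknown at
0.479 ± 0.332 and 0.444 ± 0.090). All comparisons are strict inequalities,
matching the printed threshold notation. The damaging-tool count orders
candidates but never excludes them.

## Synthetic family generator

`simulate_family()` emulates the statistical structure the cascade assumes:

* **Pedigree shapes**: `trio` (3 samples, 2 affected), `family_b`
  (5 samples, 4 affected), `family_c` (4 samples, 2 affected) — the three
  study configurations.
* **Background variants** (default 100) are placed uniformly within panel
  gene intervals, with population allele frequencies uniform on
  [0.004, 0.55], spanning the printed exclusion ranges (0.4–45.8 % and
  8.5–52.4 %). Founder genotypes are Hardy–Weinberg draws at the variant's
  frequency; children inherit one allele per parent uniformly. No linkage
  disequilibrium is modeled: every filter is single-site, so LD would not
  change any verdict.
* **Novel variants** (default fraction 0.05) are absent from the frequency
  table. A table frequency of zero with Hardy–Weinberg sampling would make
  such variants unobservable, so they are simulated as what they represent
  in real data — rare private alleles: one uniformly chosen founder carries
  the variant heterozygously. This design makes chance co-segregation of a
  novel background variant possible (in a trio, probability 1/4 per novel
  variant: the right founder, one transmission), which is precisely the
  false-candidate mode the frequency filter cannot remove and larger
  pedigrees suppress (1/16 in the 5-sample shape). The Hardy–Weinberg
  calibration checks apply to the table-frequency variants.
* **The planted causal variant** is heterozygous in every affected sample,
  absent in every unaffected sample and absent from the frequency table —
  the monogenic, fully penetrant dominant model conditioned on the observed
  affection pattern. With zero genotyping error its recovery is certain by
  construction, and the suite verifies this over 200 seeds.
* **Genotyping error** flips one uniformly chosen allele of a genotype with
  the configured rate (default 0), after transmission. Errors can break
  co-segregation of the causal variant (missed recovery) but, under the
  strict missing-genotype policy, cannot create missing calls — the error
  model is allele flips, not dropout.

Identical configurations are byte-identical (the generator seeds a private
RNG stream and restores the caller's), and `recovery_experiment()` tabulates
recovery and false-candidate rates over a seed grid.

What the generator does *not* emulate: read-level noise, coverage gaps,
population structure, de novo mutation, and locus heterogeneity. Passing
tests therefore demonstrate the correctness of the filter logic under the
stated genetic model, not robustness to the full failure modes of real
exomes.

## Numerical and policy choices

* Coordinates: VCF/variants 1-based; BED half-open 0-based, converted once
  at the reading boundary.
* Only `PASS`/`.` FILTER records enter the cascade; the pipeline consumes
  post-calling VCFs. No genotype-quality or depth thresholds are applied:
  the upstream filtering regime of the original analysis is unstated, and
  guessing one would silently change counts.
* Missing genotypes are kept at read time and resolved by the segregation
  filter's policy. The default is strict (a missing genotype in a consulted
  sample fails the variant): prioritization favors specificity, and a
  lenient mode exists for sparse data. A genotype like `./1` still decides
  an affected sample's carrier state.
* Multi-allelic records are split per alt; alleles of a different alt
  recode as reference in the split record.
* Candidate ordering: damaging-tool count (descending), then MAF
  (ascending), then genomic coordinate — fully deterministic; unscored
  candidates sort last within their MAF tier.
* Known-mutation status ("Recurrent" vs "Novel") is a lookup against an
  editable packaged table keyed by gene and HGVS c. or p. string — a
  curation artifact, not a computation.

## Problem sizes in the test suite

The suite's stochastic checks use 200 single-family simulations at the
default 100 background variants for recovery, exhaustive genotype-pattern
enumeration (3–4 states per sample, up to 5 samples) against a brute-force
oracle for the segregation rule, and ~10,000–12,000 simulated founder
genotypes for the Hardy–Weinberg calibration band (3 standard errors,
overall and within frequency thirds). These sizes give exact or
Monte-Carlo-stable answers for every assertion while keeping the suite fast.

## Known limitations

Only the dominant, fully penetrant, monogenic model is implemented —
recessive, compound-heterozygous, X-linked and de novo analyses are out of
scope, as is any statistical co-segregation evidence (the families are far
below the ~10 informative meioses linkage requires; the filter is a
deterministic sieve, not a test). The HGVS surface covers CDS SNVs only.
The packaged panel coordinates are approximate gene spans suitable for the
packaged fixtures and simulations; real analyses should supply their own
panel BED, transcript models, frequency table and alignments.
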