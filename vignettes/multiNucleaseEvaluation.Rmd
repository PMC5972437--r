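---
title: "Evaluating multiple CRISPR nucleases at matched target sites"
author: "crisprEval maintainers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating multiple CRISPR nucleases at matched target sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprEval)
```

# Scope

crisprEval supports experiments that compare several CRISPR nucleases —
SpCas9, SaCas9, NmCas9, AsCpf1 and LbCpf1 — side by side at the same
genomic locus. It covers the computational slice of such a study: finding
target sites that satisfy several PAM requirements at once, designing
single-stranded oligodeoxynucleotide (ssODN) donors around each enzyme's
cut geometry, classifying amplicon deep-sequencing reads into editing
outcomes, comparing per-site efficiencies statistically, and simulating
reads with known ground truth to validate the pipeline. Wet-lab steps
(cloning, transfection, sequencing) and genome-scale off-target search
are out of scope.

# The nuclease model

Each enzyme is a `NucleaseProfile` with six substantive attributes:

| enzyme | PAM | PAM side | cut | optimal spacer |
|--------|-----|----------|-----|----------------|
| SpCas9 | `NGG`      | 3′ | blunt, 3 bp 5′ of PAM | 17–22 nt |
| SaCas9 | `NNGRRT`   | 3′ | blunt, 3 bp 5′ of PAM | ≥ 21 nt |
| NmCas9 | `NNNNGATT` | 3′ | blunt, 3 bp 5′ of PAM | ≥ 19 nt |
| AsCpf1 | `TTTN`     | 5′ | staggered, 18/23 nt 3′ of PAM | ≥ 19 nt |
| LbCpf1 | `TTTN`     | 5′ | staggered, 18/23 nt 3′ of PAM | ≥ 19 nt |

Open-ended optimal ranges are stored with `optimalSpacerMax = NA`
(interpreted as unbounded), rather than inventing an upper limit the
evidence does not support. The seed region — the PAM-proximal ~7 nt most
critical for target recognition — is recorded as `seedLen = 7` for all
five enzymes.

Cut geometry in 0-based inter-base coordinates, for a plus-strand site
with spacer `[s, e)`:

- Cas9 blunt cut: `e - 3` (3 bp 5′ of the first PAM base).
- Cpf1 non-target-strand nick: `s + 18`; target-strand nick: `s + 23`.
  The 5-nt difference is the 5′ overhang the staggered cut leaves.
  Reported Cpf1 cleavage positions vary by a few nucleotides between
  studies; 18/23 is used as the fixed default here, and both offsets are
  profile attributes, so alternative geometries can be registered via
  `registerNuclease()` or a YAML config without code changes.

Minus-strand sites mirror all coordinates through `x -> L - x`.

# Matched target sites

`scanMatchedSites()` finds loci cleavable by several enzymes at once: a
5′ `TTTN` (Cpf1 PAM), a spacer of 17–25 nt, and a 3′ combined pattern:

- `cpf1_sp_sa`: 3′ `NGGRRT` (SpCas9 `NGG` nested in SaCas9 `NNGRRT`) —
  compatible with SpCas9, SaCas9, AsCpf1, LbCpf1.
- `cpf1_sp_nm`: 3′ `NGGNGATT` — SpCas9, NmCas9, AsCpf1, LbCpf1.
- `cpf1_nm_long`: 3′ `NNNNGATT`, spacers restricted to 24–25 nt —
  NmCas9, AsCpf1, LbCpf1.

IUPAC matching is positional; an `N` in the *subject* sequence (an
unknown base) fails every non-`N` pattern position, and windows
containing `N` are excluded entirely, so no site is ever reported on
ambiguous sequence. The scanner is validated in the test suite against an
independent regex-enumeration oracle on thousands of random sequences,
including strand-mirror invariance.

# Donor design

`designSsodn()` builds ssODN donors with exact length accounting
(`arm5 + insert + arm3`), and `strandIdentity` selects whether the oligo
carries the target-strand ("T") or non-target-strand ("NT") sequence; the
two are reverse complements with swapped arm labels. The recommended
designs encode enzyme-specific asymmetries:

- SpCas9: T-strand donor, 37 nt PAM-proximal / 77 nt PAM-distal
  (120 nt total).
- LbCpf1: NT-strand donor with the PAM-proximal arm extended (77/37).

`insertionPointBetweenCuts()` places the edit between the Cas9 blunt cut
and the Cpf1 non-target nick. When the midpoint is a half-integer it
rounds **toward the Cas9 cut** — a fixed, documented tie-break so donor
designs are deterministic. `inSilicoDigest()` predicts RFLP fragment
lengths for restriction-site knock-in readouts.

# Outcome classification

Reads are aligned to the amplicon reference with affine gap penalties
(match +2, mismatch −2, a length-*k* gap costs 6 + *k*), using
Biostrings' pairwise aligner. Numerical choices:

- **Left-alignment.** Equivalent gap placements are normalized to the
  5′-most position (VCF convention), so CIGARs and event coordinates are
  deterministic. The alignment *score* is placement-invariant; only the
  reported position is canonicalized.
- **Identity threshold 0.75 and minimum read length 30 nt.** Reads below
  either bound are labelled `Unaligned` and excluded from percentage
  denominators. The threshold is permissive enough to keep reads bearing
  a 25-nt indel plus sequencing errors, while rejecting unrelated
  sequence (random DNA aligns near 0.25–0.5 identity).
- **Window semantics.** NHEJ events count if they intersect the spacer
  extended by `windowSize` (default 40 bp) on each side: deletions by
  interval overlap, insertions by their inter-base point (edge-
  inclusive). Enlarging the window can only add events — a monotonicity
  property the tests assert.

NHEJ labels: any insertion → `Insertion`; any deletion → `Deletion`;
neither (substitutions only) → `Match`; both → the longest event wins,
ties going to `Deletion`. HDR labels are assigned against the
donor-modified reference: the recognition sequence must occur exactly in
the read segment aligned to the spacer window (anchoring the call to the
edit locus, not anywhere in the read); present with no indel →
`Correct`, present with an indel → `Wrong`, absent → `No`.
`estimateOutcomeMixture()` combines both passes into wt / indel /
hdr_correct / hdr_wrong proportions.

The aligner is cross-checked in the tests against an independently
written Gotoh dynamic-programming oracle (hundreds of random pairs,
exact score equality), so the fast path and the textbook recursion never
drift apart silently.

# Statistics

Per-site editing efficiencies are compared with the Wilcoxon rank-sum
test (exact null distribution when the combined sample size is ≤ 20 and
untied — validated against exhaustive permutation enumeration — normal
approximation with tie correction otherwise), Welch's t-test, or the
two-sample KS test. When every pooled value is identical the rank
statistic is degenerate (its tie-corrected variance is zero); the package
returns p = 1 in that case, since such data carry no evidence against the
null. Sites are grouped by expression at FPKM 25 (strictly below = low)
and filtered to each enzyme's optimal spacer lengths before comparison.
`recommendSystem()` is a pure rule engine mapping (goal, specificity,
donor type) to an enzyme/donor recommendation with explicit rationale
strings.

# The simulator

`simConfig()` / `makeLocusFixture()` / `simulateReads()` generate a
synthetic locus and reads with per-read truth labels. Defaults describe a
deep-sequenced HDR experiment: a 240-nt amplicon with one embedded
`cpf1_sp_sa` site (20-nt spacer), 10,000 reads mixing 60% wild-type,
30% indel, 7% correct and 3% wrong incorporation, geometric indel
lengths (p = 0.3, truncated at 25 nt), a 6-nt XbaI insert (`TCTAGA`),
and a 0.1% per-base substitution error rate.

Design choices and limits:

- Indel positions are drawn near the Cas9 cut (±5 nt, clipped inside the
  spacer), mimicking repair locality and keeping events inside the
  classification window. Wrong-HDR indels are placed within 25 nt of the
  insert and never disrupt the recognition sequence, so truth labels are
  unambiguous. The background is redrawn if it happens to contain the
  recognition sequence, keeping the restriction readout identifiable.
- The error model is substitution-only; sequencing indels would blur the
  truth labels and are deliberately excluded. No claim of realism is made
  for the indel-length spectrum.
- Everything derives from the integer seed (fixture stream: `seed`; read
  stream: `seed + 1`), so runs are byte-reproducible.

At zero noise, classification equals truth read for read (asserted in the
tests); at the default error rate, category estimates fall within three
binomial standard deviations of the realized truth at depth 10,000.

Problem sizes used in the validation suites (pair counts, sequence
lengths, replicate numbers) are the package's own choices, balancing
coverage against runtime on a single CPU.

# Reproducibility

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "crisprEval",
                               load_package = "installed")'
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The acceptance script recomputes the design identities, oracle agreement
rates, mixture recovery and test calibration from the installed package
and a single seed, and writes them as flat JSON.
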