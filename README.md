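# crisprEval

An R package for planning and evaluating genome-editing experiments that
compare multiple CRISPR nucleases — SpCas9, SaCas9, NmCas9 and the Cpf1
(Cas12a) enzymes AsCpf1 and LbCpf1 — at the *same* genomic locus.

Comparing nucleases fairly requires target sites that satisfy every
enzyme's PAM requirement simultaneously ("matched" sites: a 5′ `TTTN`
for Cpf1 plus a 3′ combined Cas9 PAM such as `NGGRRT`), donor templates
designed around each enzyme's distinct cut geometry, and a uniform way to
score editing outcomes from amplicon deep-sequencing reads. crisprEval
implements all of that:

- **Nuclease models** — S4 `NucleaseProfile` objects carrying PAM pattern
  (IUPAC), PAM side, blunt-cut offset (Cas9: 3 bp 5′ of the PAM) or
  staggered nick offsets (Cpf1: non-target strand 18 nt, target strand
  23 nt 3′ of the PAM, leaving 5-nt 5′ overhangs), and per-enzyme optimal
  spacer-length ranges (SpCas9 17–22 nt; SaCas9 ≥ 21 nt; NmCas9, AsCpf1,
  LbCpf1 ≥ 19 nt). Custom enzymes load from YAML.
- **Site finder** — strand-aware scanning for matched target sites
  (`scanMatchedSites`), single-enzyme scans, and detection of Cas9/Cpf1
  site pairs whose 7-nt seed regions overlap. Sites are returned as
  `GRanges`.
- **Donor designer** — ssODN construction with explicit strand identity
  (target "T" vs non-target "NT"), exact arm/insert length accounting
  (47/47 + 6 = 100 nt; 17/17 + 6 = 40 nt; 37/77 + 6 = 120 nt), enzyme-
  specific recommended designs (SpCas9: asymmetric 37/77 T donor, long
  arm PAM-distal; LbCpf1: NT donor with the PAM-proximal arm extended),
  insertion-point placement between the Cas9 cut and the Cpf1 nick, and
  in-silico restriction digests for RFLP readouts.
- **Outcome classifier** — affine-gap global alignment of amplicon reads
  (Biostrings' aligner, verified against an independent dynamic-
  programming oracle), VCF-style left-aligned indel events,
  deterministic CIGARs, NHEJ labels (Insertion / Deletion / Match within
  a ±40 bp spacer window) and HDR labels (Correct / Wrong / No by
  restriction-site incorporation), plus a four-way mixture estimator
  (wt / indel / hdr_correct / hdr_wrong).
- **Stats helpers** — expression split at FPKM 25, optimal-spacer-length
  filtering, exact Wilcoxon rank-sum / Welch t / KS comparisons, BH
  adjustment, and a deterministic rule engine that recommends an
  enzyme/donor combination from experimental goal, specificity needs and
  donor type.
- **Synthetic data** — a seeded simulator that embeds a matched site in a
  random amplicon, generates reads from a programmed outcome mixture with
  per-base substitution errors, and emits FASTQ plus a per-read truth
  table, so the whole pipeline can be validated end to end.

## Worked example

```r
library(crisprEval)

## 1. build a synthetic locus with one matched target site
locus <- makeLocusFixture(simConfig(seed = 42, nReads = 2000))
locus$site
#> GRanges object with 1 range and 9 metadata columns:
#>              seqnames    ranges strand |           spacer_seq       combo
#>                 <Rle> <IRanges>  <Rle> |          <character> <character>
#>   [1] synthetic_locus   111-130      + | AAACTCCATGTGTAACTCCG  cpf1_sp_sa
#>                     compatible    pam5_seq    pam3_seq pam5_start0 pam5_end0
#>                <CharacterList> <character> <character>   <integer> <integer>
#>   [1] SpCas9,SaCas9,AsCpf1,...        TTTA      GGGAAT         106       110
#>       pam3_start0 pam3_end0
#>         <integer> <integer>
#>   [1]         130       136

## 2. cut-site coordinates (0-based, inter-base)
cas9CutSite(locus$site)
#> [1] 127
cpf1CutSites(locus$site)
#> non_target     target
#>        128        133

## 3. the recommended SpCas9 donor for a TCTAGA (XbaI) knock-in
ref <- as.character(locus$reference[[1]])
recommendedDesign("SpCas9", locus$site, "TCTAGA", ref)
#> DonorDesign (T strand) at locus
#>   arms: 37/77 nt, insert TCTAGA (6 nt), total 120 nt
#>   insertion point (plus strand, inter-base): 127
#>   arm labels anchored to: SpCas9
#>   oligo: CAAGCGGGAGGCGTGATATGCCAGCGGTATTCCCCGGTCTAGAAGTTACACATGGAGTTT...

## 4. simulate reads and estimate the outcome mixture
sim <- simulateReads(locus)
mix <- estimateOutcomeMixture(sim$reads, locus$experiment)
round(100 * mix$proportions, 2)
#>          wt       indel hdr_correct   hdr_wrong
#>       60.55       30.30        6.35        2.80

round(100 * table(sim$truth$category) / nrow(sim$truth), 2)  # realized truth
#> hdr_correct   hdr_wrong       indel          wt
#>        6.35        2.80       30.30       60.55

## 5. which system should I use for a precise ssODN edit?
recommendSystem("precise_edit", donor = "ssODN")
#> Recommendation (goal: precise_edit, donor: ssODN)
#>   nucleases: SpCas9, LbCpf1
#>   donor for SpCas9: T strand, PAM-proximal arm 37 nt / PAM-distal arm 77 nt
#>   donor for LbCpf1: NT strand, PAM-proximal arm 77 nt / PAM-distal arm 37 nt
#>   rationale:
#>    - for ssODN-mediated HDR, SpCas9 prefers target-strand donors and is most
#>      efficient with the asymmetric 37/77 T design (long arm PAM-distal)
#>    - the Cpf1 nucleases prefer non-target-strand donors; extending the
#>      PAM-proximal arm of the NT ssODN increases LbCpf1 HDR frequency
```

At zero sequencing noise the mixture estimate equals the simulation truth
read for read; at the default 0.1% substitution error rate it matches the
realized truth to within binomial sampling error (the example above
recovers it exactly).

## Coordinate conventions

All exported coordinates are **0-based, half-open, on the forward
strand**; cut sites are inter-base integers (a cut at `k` falls between
bases `k-1` and `k`). `GRanges` objects use the usual 1-based closed
internal representation (`start0 = start - 1`, `end0 = end`). Minus-strand
sites mirror through `x -> L - x` where `L` is the sequence length.

## Vignette

`vignettes/multiNucleaseEvaluation.Rmd` documents the underlying models,
parameter defaults, numerical choices (left-alignment, identity
threshold, window semantics, midpoint rounding) and the simulator's
scope and limits.
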