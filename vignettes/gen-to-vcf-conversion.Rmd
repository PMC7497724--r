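---
title: "Converting GEN genotype probabilities to VCF with dosages"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Converting GEN genotype probabilities to VCF with dosages}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dosevcf)
```

## The conversion model

Imputation of untyped variants from a haplotype reference panel yields,
for every sample and biallelic variant with alleles A and B, a posterior
probability triple $\bigl(P(AA), P(AB), P(BB)\bigr)$. `dosevcf` maps
each triple to the three per-sample VCF FORMAT fields used downstream:

* **GP** — the triple itself, in genotype order $P(0/0), P(0/1),
  P(1/1)$, as linear probabilities (not phred-scaled, matching the
  convention of contemporary converters for imputation output);
* **DS** — the expected ALT-allele count
  $0\,P(AA) + 1\,P(AB) + 2\,P(BB)$, which for a diploid biallelic
  genotype lies in $[0, 2]$;
* **GT** — the best-guess genotype $\arg\max$ of the triple.

Allele A is written as REF and allele B as ALT, so the dosage counts
copies of the coded (B) allele. Positions are 1-based in GEN and in
VCF and pass through unchanged; GEN carries no strand, qual, or filter
information, so QUAL, FILTER and INFO are emitted as `.`.

A triple whose components sum to (numerically) zero is the GEN missing
code: GT, GP and DS are all written as missing (`./.:.:.`).

## Parameters that matter

* `precision` (decimal places for GP/DS; default **3**). IMPUTE prints
  3-decimal probabilities, so more digits would be false precision. A
  value re-parsed from the VCF is within half a unit in the last
  printed decimal of the computed value.
* `gt_threshold` (default **0**). A hard-call filter: when the maximum
  genotype probability is below the threshold, GT is blanked to `./.`.
  GP and DS are still emitted — the filter is a presentation policy and
  must not destroy information. The default always calls.
* `renormalize` (default **off**). Rounded triples need not sum to 1.
  By default the conversion uses the values as written and clamps the
  dosage into $[0, 2]$ if rounding pushed it outside (counted in the
  run statistics); with renormalization on, each triple is divided by
  its sum first, after which no clamping can ever fire. Both behaviours
  are exposed because neither is canonical for this conversion; the
  as-written default is the more transparent one.
* `missing_eps` (default **1e-6**): the threshold under which a
  component sum is treated as the missing code.
* `strict` (default **on**): malformed lines and out-of-range
  probabilities abort with the offending line number. Lenient mode
  skips malformed lines, clamps negative probabilities to 0 and values
  at most `1e-6` above 1 down to 1, and reports counts.

### Tie-breaking and numerical choices

At an exact tie the best guess is the genotype with the lowest index
(hom-ref < het < hom-alt) — a deterministic, reproducible rule for a
case the probability model itself leaves open. Probabilities up to
`1e-6` above 1 are tolerated in strict mode because 3-decimal rounding
legitimately produces them. Floating-point values are rendered in fixed
precision by the C library's correctly rounded conversion
(round-half-to-even), never in exponent notation, so output is
byte-reproducible across runs; `no_date = TRUE` (CLI `--no-date`)
additionally drops the `##fileDate` header line, making whole files
byte-identical.

## Input dialects and identifiers

GEN files occur with five leading metadata columns (varid, rsid, pos,
alleleA, alleleB) or six (chromosome first). The dialect is detected
from the first non-empty line — the token count mod 3 identifies it
uniquely — and enforced for the rest of the file, so ragged files fail
fast. Five-column input carries no chromosome and therefore requires an
explicit override (`chrom` / `--chr`), which also takes precedence over
the chromosome column when given to six-column input.

Sample identifiers come from the Oxford sample file when supplied
(default the `ID_2` column, commonly the within-family identifier;
`id_column` selects `ID_1` or the concatenation instead), and are
synthesized as `sample_1..N` otherwise, so conversion never requires
metadata the GEN file lacks. The VCF ID column defaults to the rsid,
falling back to the variant id and then to `chrom:pos_ref_alt`.

## Streaming and output

The converter holds a constant-size buffer of lines — never the file —
so peak memory is flat in the number of variants; this is what makes it
usable on whole-chromosome files and in pipelines (`--gen - --out -`,
logging strictly to stderr). Output to a `.gz` path is staged as plain
text and BGZF-compressed on completion, then tabix-indexed when the
records arrived coordinate-sorted; no sorting is ever performed (input
order is preserved), and indexing of unsorted output is refused with a
warning rather than buffering the file. Standard-output mode always
writes plain text. BGZF compression and tabix indexing use Rsamtools
(htslib); everything else — parsing, genotype derivation, rendering —
is implemented in the package.

Degenerate inputs: an empty stream yields a header-only VCF (with no
sample file the sample count is unknowable, so the header is
sites-only); blank lines are skipped and counted; duplicate positions
or IDs pass through, since VCF permits them and deduplication is a
user policy.

## The synthetic-data generator

`generate_gen_fixture()` emulates the shape of IMPUTE output: per
genotype a triple drawn from the flat (symmetric Dirichlet) distribution
on the probability simplex, rounded to 3 decimals — so written triples,
as in real files, need not sum to exactly 1 — with a configurable
fraction of `0 0 0` missing codes, strictly increasing positions, both
dialects, and an occasional `.` rsid to exercise the ID fallback. Its
truth table records the dosage and best-guess genotype implied by the
*as-written, rounded* values, since those are all a converter can see.
Identical spec and seed give byte-identical files.

What it deliberately does not emulate: linkage-disequilibrium structure,
realistic allele frequencies or imputation-quality gradients, multi-
allelic sites, chromosome X / mixed ploidy. Passing tests therefore
demonstrate format- and arithmetic-correctness of the conversion, not
anything about imputation quality on real cohorts — which is the right
scope, because the conversion is purely per-genotype and has no
statistical coupling across variants or samples.

`oracle_convert()` is a second, deliberately naive whole-file-in-memory
implementation of the same conversion — scalar loops, no shared code
with the streaming path — used in the tests as an independent reference:
the two must agree byte-for-byte.

## Verification sizes

The test suite checks the dosage range on the exhaustive 1 %-grid of
5151 triples; oracle equivalence on 20 seeded fixtures up to 1000
variants × 50 samples; round-tripping of GP/DS/GT through an
independent VCF parser (VariantAnnotation) on a 1000 × 50 fixture; the
flat-memory streaming contract on 1000- vs 20000-variant fixtures at
100 samples (R heap peaks via `gc(reset = TRUE)`); and a cohort-shaped
1000 × 1000 conversion to indexed BGZF re-read through htslib. These
sizes exercise every contract at desk scale while keeping the suite
fast.

## Known limitations

* Diploid, biallelic genotypes only; no chromosome X / haploid
  handling.
* BGEN input is out of scope — pipe an external BGEN-to-GEN converter
  into standard input instead.
* No INFO-field imputation-quality metrics (info/r²) and no
  allele-frequency computation; the conversion carries exactly what the
  GEN file contains.
* Standard-output mode does not BGZF-compress; pipe through `bgzip`
  when a compressed stream is needed.
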