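# dosevcf

Streaming conversion of Oxford/IMPUTE GEN genotype-probability files to
BGZF-compressed, tabix-indexable VCF, carrying per sample the best-guess
genotype (**GT**), the genotype posterior probabilities (**GP**) and the
imputed alternate-allele dosage (**DS**).

## The problem

Genotype imputation with IMPUTE-family tools writes GEN format: one line
per variant with a few metadata columns followed by three posterior
probabilities per diploid sample,

    P(AA)  P(AB)  P(BB)

for genotypes built from allele A (taken as the VCF REF allele) and
allele B (ALT). Association software, however, consumes VCF with
per-sample FORMAT fields — in particular the dosage

    DS = 0·P(AA) + 1·P(AB) + 2·P(BB) ∈ [0, 2],

the expected ALT-allele count, which is the standard genotype encoding
for association tests on imputed data. `dosevcf` performs the whole
conversion in one pass — read a GEN line, derive GT/GP/DS, append to the
output — with memory bounded by a constant number of lines, so it works
on arbitrarily long files and inside shell pipelines (`stdin`/`stdout`).
GT is the genotype with maximum posterior probability (ties break to the
lower genotype index; an optional hard-call threshold blanks GT while
keeping GP and DS). Missing genotypes (`0 0 0` triples) become
`./.:.:.`.

Both common GEN layouts are auto-detected from the column count: five
leading metadata columns (no chromosome — supply one with `chrom` /
`--chr`) or six (chromosome first).

## Worked example

```r
library(dosevcf)

# a seeded synthetic GEN + sample fixture with a truth table
fx <- generate_gen_fixture(n_variants = 6, n_samples = 3, seed = 7,
                           missing_rate = 0.2)
out <- tempfile(fileext = ".vcf")
gen_to_vcf(fx$gen, out, sample_file = fx$sample, no_date = TRUE)
```

The returned statistics print as:

```
GEN -> VCF conversion: 6 record(s), 3 sample(s)
  missing genotypes : 2
  clamped dosages   : 0
  clamped probs     : 0
  malformed lines   : 0
  blank lines       : 0
```

i.e. all 6 variants were written, and 2 of the 18 genotypes were the
GEN missing code `0 0 0`. The first emitted record is

```
1  1042  rs000001  T  G  .  .  .  GT:GP:DS  0/0:0.687,0.106,0.207:0.520  0/1:0.150,0.525,0.325:1.175  0/0:0.851,0.126,0.023:0.172
```

— for sample 1, the probabilities `0.687, 0.106, 0.207` give the
best-guess genotype `0/0` (hom-ref has the maximum probability) and the
dosage `0.106 + 2 × 0.207 = 0.520`.

The same conversion from the shell, in a pipeline:

```sh
zcat chr1.gen.gz | dosevcf --gen - --sample chr1.sample --out - --chr 1 | bgzip > chr1.vcf.gz
# or directly, with BGZF compression and a tabix index:
dosevcf --gen chr1.gen.gz --sample chr1.sample --out chr1.vcf.gz
```

(The installed script lives at `<library>/dosevcf/exec/dosevcf`; run it
with `Rscript` or put it on your PATH. All logging goes to stderr —
stdout carries only VCF.)

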