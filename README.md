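# cyp2c19pgx

Allele-specific PCR genotyping and pharmacogenetic dose guidance for
**CYP2C19**, aimed at labs and researchers who need a simple, equipment-light
genotyping assay for the three common functional star alleles and a curated
translation of the resulting diplotype into pediatric dosing advice.

The package covers the whole path from assay to recommendation:

1. **Assay design** — mismatch-augmented allele-specific PCR (ARMS-style).
   For a biallelic SNP with forward-strand context, two forward primers are
   designed whose 3′-terminal base is the diagnostic allele base, and an
   *artificial destabilizing mismatch* — replacement of the template base by
   its Watson–Crick complement — is written four bases 5′ of that terminus
   (the 5th base from the 3′ end). Annealing to the matched allele leaves a
   single internal mismatch (extendable); the mismatched allele adds the 3′
   diagnostic mismatch (refractory). A common reverse primer completes the
   two parallel reactions. Melting temperatures use unified
   nearest-neighbor thermodynamics, T<sub>m</sub> = ΔH/(ΔS + R ln C_T) with
   the 0.368·(N−1)·ln[Na⁺] entropy salt correction.
2. **In-silico PCR** — a binary amplification rule (no 3′-terminal mismatch
   and ≤1 total mismatch) that maps each diploid genotype to a two-lane band
   pattern; the map is injective, which is what makes the assay a complete
   genotyping test.
3. **Genotyping** — band patterns (or a VCF matched by rsID at rs4244285,
   rs4986893, rs12248560) are called and assembled into a star-allele
   diplotype, with trans phasing of multi-SNP heterozygotes flagged
   explicitly and loss-of-function precedence (*2 > *3 > *17) when
   homozygosity forces co-occurrence.
4. **Phenotype** — the diplotype is translated into a metabolizer phenotype
   (ultra-rapid … poor, indeterminate) through a data-file allele-function
   registry and a total, symmetric rule engine.
5. **Guidance** — a provenance-tracked knowledge base returns published
   pediatric voriconazole/SSRI doses, trough-window classification and
   qualitative risk flags (PPIs, clopidogrel, SSRIs), every record carrying
   its primary-source citation.

## Worked example

```r
library(cyp2c19pgx)

loci  <- table5_loci()                      # the three reconstructed CYP2C19 loci
assay <- design_assay(loci[["CYP2C19*2"]])
assay
#> allele-specific PCR assay for CYP2C19*2 (rs4244285)
#>   forward (major G): 5'-CACTATCATTGATTATTACCCG-3'
#>   forward (minor A): 5'-CACTATCATTGATTATTACCCA-3'
#>   common reverse:      5'-CTCCATTTTGATCAGGAAGC-3'
#>   product: 192 bp; cycling 94/60/72 degC x 35 cycles
```

The two forward primers differ only at the 3′ diagnostic base (G/A) and
share the artificial T→A substitution at the 5th base from the 3′ end. A
heterozygote lights up both lanes:

```r
simulate_assay(assay, diploid_genotype(assay$locus, c("major", "minor")))
#> band pattern: major reaction [band], minor reaction [band] (192 bp)
```

From three SNP calls to a recommendation:

```r
d <- assign_diplotype(c(rs4244285 = "heterozygous",
                        rs4986893 = "homozygous-major",
                        rs12248560 = "heterozygous"))
d
#> CYP2C19 diplotype *2/*17 (trans configuration assumed)
diplotype_to_phenotype(d)
#> CYP2C19 intermediate metabolizer (*2/*17: one increased function allele
#> and one no function allele)
vcz_dose("takahashi-2021", diplotype_to_phenotype(d), weight_kg = 12)
#> voriconazole [takahashi-2021]: 8-10.72 mg/kg
#>   - 33-50% below the normal-metabolizer base dose
#>   source: Takahashi et al. 2021, CYP2C19 phenotype and body weight-guided
#>   voriconazole initial dose in infants and children after hematopoietic
#>   cell transplantation
```

The dose is an *interval* because the source publishes a percent range
(33–50% below the 12 mg/kg base dose for a 12 kg normal metabolizer);
collapsing it to a midpoint would invent precision. Trough monitoring:

```r
classify_trough(0.8)$class
#> [1] subtherapeutic    # below the 1.5-5.0 mg/L target window
```

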