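---
title: "Mismatch-augmented allele-specific PCR for CYP2C19: design, simulation and guidance methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mismatch-augmented allele-specific PCR for CYP2C19}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cyp2c19pgx)
```

## The problem

CYP2C19 metabolizes voriconazole, several SSRIs, proton pump inhibitors and
clopidogrel, and its star-allele diplotype stratifies patients into
metabolizer phenotypes that matter clinically — particularly in pediatrics,
where poor and intermediate metabolizers accumulate voriconazole and
ultra-rapid metabolizers fail to reach therapeutic troughs. Three SNPs tag
the common functional alleles: rs4244285 (*2, no function), rs4986893 (*3,
no function) and rs12248560 (*17, increased function).

Allele-specific PCR (AS-PCR) genotypes a SNP with two parallel reactions
that share a common reverse primer and differ only in the forward primer,
whose 3'-terminal base matches one of the two alleles. Plain AS-PCR often
discriminates poorly because a single 3' mismatch can still be extended.
The method implemented here sharpens discrimination the ARMS way: an
*artificial destabilizing mismatch* — the simple replacement of a template
base by its Watson-Crick complement — is written into both forward primers
four bases 5' of the diagnostic base (the 5th base from the 3' terminus).
The matched allele then anneals with a single internal mismatch and
amplifies; the mismatched allele carries two mismatches (3'-terminal
diagnostic plus internal artificial) and is refractory. Two gel lanes per
sample read out the three diploid genotypes.

## Primer design rules

`design_assay()` composes, for a `snp_locus()`:

* two forward allele-specific primers: the forward-strand template ending on
  the diagnostic base of each allele, with the artificial substitution
  applied by `apply_artificial_mismatch()`. The substitution policy is
  strictly complement-of-template — not a strongest-destabilizer heuristic —
  and its offset (default 4 bases 5' of the diagnostic terminus) is a
  `design_params()` field.
* a common reverse primer: the reverse complement of a downstream
  forward-strand window, selected to minimize |Tm − annealing target|
  subject to primer length 18–25 nt, amplicon length 80–400 bp, GC fraction
  0.40–0.60, and a GC clamp (the reverse primer must end 3' on G or C — the
  conventional guard against slippery AT-rich 3' termini). Ties break toward
  the shorter primer, then the smaller amplicon, so designs are
  deterministic.

The forward-primer length is shared by both allele primers and chosen to
put their melting temperatures nearest the 60 °C annealing step of the
standard cycling program (94/60/72 °C, 30 s each, 35 cycles), over the
lengths the upstream context supports.

Melting temperatures come from the unified nearest-neighbor parameter set
(SantaLucia 1998), with the entropy salt correction
0.368·(N−1)·ln[Na⁺] at 50 mM monovalent salt and 250 nM primer in excess
over template. These concentration defaults are conventional PCR practice;
the published assay does not state them. The additive Wallace rule
(2 °C per A/T + 4 °C per G/C) is available for oligos shorter than the
8 nt the nearest-neighbor model needs. Primers whose Tm falls outside the
55–65 °C window are flagged on the primer record (`tm_within_window`)
rather than rejected, because the validated published primers themselves
sit a few degrees below that window under these conditions.

## The reconstructed CYP2C19 loci

`table5_loci()` rebuilds the three assay loci from the published
oligonucleotides themselves: the upstream context is the published forward
primer with the artificial substitution reverted to its complement, and the
downstream context embeds the reverse complement of the published common
reverse primer behind a fixed, committed 150 bp AT-only spacer. The true
intervening genomic sequence and the product sizes were not published, so
the spacer is explicitly synthetic; it is AT-only so that no spacer window
can satisfy the GC bounds or the GC clamp, which keeps reverse design on
these loci deterministic. Each upstream context is exactly one base shorter
than the published primer, so the length search recovers the published
primer lengths (22/20/20 nt). Re-designing on these loci reproduces all six
published forward primers and selects all three published reverse primers
— a permanent regression test, not a claim that the original designers used
these exact numerical criteria (their Tm objective is unstated; the printed
reverse primers are treated as regression fixtures).

## In-silico amplification model

`predict_amplification()` is deliberately binary: a reaction amplifies iff
the end-anchored mismatch profile against the template has no 3'-terminal
mismatch and at most one mismatch in total. The underlying experimental
principle is qualitative (two mismatches are much less extendable than
one), and the gel readout scored is presence/absence, so a quantitative
efficiency model would add parameters nothing in the validation could
constrain. Consequences worth knowing:

* any 3'-terminal mismatch is treated as refractory, including a
  hypothetical primer without the artificial mismatch — the conservative
  reading;
* off-target priming elsewhere in the template is not modeled;
* for every designable locus the genotype → band-pattern map is injective
  ((T,F), (T,T), (F,T) for the three genotypes; (F,F) never occurs), which
  is the assay's entire diagnostic value and is property-tested on random
  loci.

## Diplotype assembly and phasing

`assign_diplotype()` distributes the observed variant copies at the three
SNPs over two chromosomes. Homozygous variants occupy both; heterozygous
variants at different SNPs are placed in trans and the result carries
`phased = FALSE`, because an unphased two-reaction assay cannot exclude the
cis configuration — *2/*17 is the standard interpretation of a *2-het +
*17-het sample, but it is an assumption, and the flag says so. When
homozygosity forces a loss-of-function variant and *17 onto one chromosome,
the loss-of-function allele names the haplotype (*2 > *3 > *17), following
star-allele nomenclature in which the functional lesion defines the allele.
A triple heterozygote is reported as a documented ambiguity error rather
than silently phased; of the 27 three-locus genotype combinations, the
remaining 26 are recovered end-to-end by simulate → call → assign, which
stands in for the original wet-lab concordance validation (the per-sample
reference genotypes of that panel were not published, so a synthetic
equivalence property replaces them).

## Phenotype translation

The allele registry (`inst/extdata/allele_function.yaml`) assigns each star
allele one function class: *1 normal, *2/*3 none, *9 decreased, *17
increased, *12/*14 uncertain. `diplotype_to_phenotype()` is a total,
symmetric function of the unordered pair of classes: two increased →
ultra-rapid; normal+increased → rapid; two normal → normal; any decreased
with normal/increased/decreased → likely-intermediate; none with
normal/increased → intermediate; decreased+none → likely-poor; two none →
poor; any uncertain dominates → indeterminate (the published rule table
places mixed pairs such as *2/*12 under indeterminate, implying dominance).
*9, *12 and *14 are registry-resolvable for direct diplotype input but are
not callable from the three-SNP assay panel. The registry is a data file so
further alleles can be added with one line.

## The guidance knowledge base

`inst/extdata/dosing_kb.yaml` encodes, verbatim, the published outputs of
pediatric dosing studies; the module is a lookup table with a small rules
engine, never a pharmacokinetic simulator, and every record carries its
primary-source citation. Encoding decisions that were genuinely open:

* Weight bands for the Takahashi model are half-open (<15, [15, 30),
  ≥30 kg): the source prints the band edges ambiguously, and half-open
  bands make the lookup total and deterministic. Percent adjustments
  ("33–50% lower", "25–50% higher") are returned as dose *intervals*
  (multipliers 0.50–0.67 and 1.25–1.50); collapsing them to midpoints would
  invent precision.
* Tian age bands are <12 vs ≥12 years, with exactly 12 in the older band;
  rapid metabolizers are mapped to the UM/EM group with an explicit caveat
  qualifier, since the source defines doses per phenotype group and does
  not state the assignment.
* Two published trough windows exist (1.5–5.0 mg/L, and 1.0–5.5 mg/L by
  immunoassay); 1.5–5.0 is the default and the other is selectable by name.
  Window bounds are inclusive; classification is strict outside them and
  monotone in concentration.
* SSRI exposure-equivalents exist only for the phenotypes the modeling
  study printed; other phenotypes raise an error instead of interpolating.
* Drug–drug interaction effects (omeprazole raises, rifampicin lowers the
  voriconazole trough) are emitted as qualitative directional flags only —
  no quantitative effect sizes were published.

## Synthetic data: what it does and does not show

`synth_locus()` draws uniform random templates with random distinct
alleles; `synth_panel()` draws per-locus diploid genotypes independently
with uniform thirds by default. These choices are a test harness, not a
population model: there is no Hardy-Weinberg structure, no linkage
disequilibrium between the three SNPs, and no realistic allele
frequencies. Passing the 100%-recovery property therefore shows that the
design rules and the calling logic are mutually consistent under the
in-silico amplification model — it does not show that the wet assay is
robust to polymerase-specific 3'-mismatch extension, secondary structure,
or off-target priming, none of which are modeled. All generators take an
explicit seed, restore the caller's RNG state, and reproduce bit-identical
output under the same seed.

## Problem sizes and numerical choices

The shipped test-suite exercises the design sweep on 200 random loci
(1000 run cleanly; the suite uses 200), panel recovery at 21 samples (the
size of a typical reference cell-line validation panel) and 1000 samples,
and the full 27-combination genotype enumeration. Degenerate inputs are
errors with named reasons: upstream context too short for the minimum
primer length, no reverse window satisfying the constraints (the error
counts rejections per constraint), empty or non-ACGT sequences (U and
IUPAC ambiguity codes are rejected — this is a DNA-only tool), negative
trough concentrations. Lowercase sequence input is upper-cased on ingest.

## Known limitations

* The amplification rule is binary; weak cross-amplification and
  polymerase-dependent 3'-mismatch extension are out of scope.
* Product sizes for the real CYP2C19 amplicons cannot be validated — the
  sources do not print them — so the reconstructed loci carry a synthetic
  spacer and the product lengths reported for them are fixture artifacts.
* Multiplexing, probe-based (TaqMan) designs, hairpin/primer-dimer
  screening and copy-number or hybrid star alleles are not modeled.
* The guidance module reproduces printed study outputs; it is not a dose
  individualization or decision-support system.
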