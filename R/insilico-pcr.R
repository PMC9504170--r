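#' Diploid genotype at a locus
#'
#' @param locus a [snp_locus()].
#' @param alleles unordered pair from `"major"`/`"minor"` (e.g.
#'   `c("major", "minor")` for a heterozygote).
#' @return an object of class `diploid_genotype`.
#' @export
diploid_genotype <- function(locus, alleles) {
  if (length(alleles) != 2L || !all(alleles %in% c("major", "minor")))
    stop("alleles must be a pair drawn from {major, minor}", call. = FALSE)
  structure(list(locus = locus, alleles = sort(alleles)),
            class = "diploid_genotype")
}

#' Predict amplification of one allele-specific reaction
#'
#' Binary rule encoding the discrimination principle of mismatch-augmented
#' allele-specific PCR: a reaction amplifies only when the primer-template
#' duplex carries no 3'-terminal mismatch and at most one mismatch in total.
#' A primer annealing to its own allele carries only the single internal
#' artificial mismatch and amplifies; annealing to the other allele adds the
#' 3'-terminal diagnostic mismatch (two mismatches) and is refractory.
#'
#' @param primer an [asp_primer][design_allele_specific_primer()].
#' @param template_allele `"major"` or `"minor"`: the allele carried by the
#'   template chromosome.
#' @return `TRUE` if the reaction is predicted to amplify.
#' @export
predict_amplification <- function(primer, template_allele = c("major", "minor")) {
  template_allele <- match.arg(template_allele)
  window <- allele_template_window(primer$locus, template_allele,
                                   nchar(primer$sequence))
  prof <- mismatch_profile(primer$sequence, window)
  prof$total <= 1L && !(1L %in% prof$positions_from_3prime)
}

#' Band pattern of the two parallel reactions
#'
#' @param major_reaction_amplified,minor_reaction_amplified logicals.
#' @param product_length_bp expected amplicon length; required when at least
#'   one reaction amplified, `NA` otherwise.
#' @return an object of class `band_pattern`.
#' @export
band_pattern <- function(major_reaction_amplified, minor_reaction_amplified,
                         product_length_bp = NA_integer_) {
  any_band <- isTRUE(major_reaction_amplified) || isTRUE(minor_reaction_amplified)
  if (any_band && is.na(product_length_bp))
    stop("product_length_bp required when a reaction amplified", call. = FALSE)
  if (!any_band) product_length_bp <- NA_integer_
  structure(list(major_reaction_amplified = isTRUE(major_reaction_amplified),
                 minor_reaction_amplified = isTRUE(minor_reaction_amplified),
                 product_length_bp = as.integer(product_length_bp)),
            class = "band_pattern")
}

#' @export
print.band_pattern <- function(x, ...) {
  lane <- function(b) if (b) "band" else "-"
  cat("band pattern: major reaction [", lane(x$major_reaction_amplified),
      "], minor reaction [", lane(x$minor_reaction_amplified), "]", sep = "")
  if (!is.na(x$product_length_bp)) cat(" (", x$product_length_bp, " bp)", sep = "")
  cat("\n")
  invisible(x)
}

#' Simulate the two-reaction assay for one diploid genotype
#'
#' Each reaction amplifies when [predict_amplification()] is true for at
#' least one of the two allele copies, mirroring the gel readout: a band in
#' the major-specific lane, the minor-specific lane, or both.
#'
#' @param assay an [asp_assay][design_assay()].
#' @param genotype a [diploid_genotype()] at the assay's locus.
#' @return a [band_pattern()].
#' @export
simulate_assay <- function(assay, genotype) {
  if (!identical(genotype$locus$rsid, assay$locus$rsid))
    stop("genotype locus (", genotype$locus$rsid,
         ") does not match assay locus (", assay$locus$rsid, ")", call. = FALSE)
  amp <- function(primer)
    any(vapply(genotype$alleles, function(a) predict_amplification(primer, a),
               logical(1L)))
  band_pattern(amp(assay$primer_major), amp(assay$primer_minor),
               assay$product_length_bp)
}

#' Truth table of band patterns over the three diploid genotypes
#'
#' Enumerates major/major, major/minor and minor/minor through
#' [simulate_assay()]. For any assay designed by [design_assay()] the three
#' patterns are pairwise distinct, which is what makes the two-lane readout
#' a complete genotyping test.
#'
#' @param assay an [asp_assay][design_assay()].
#' @return named list of three [band_pattern()] objects
#'   (`"major/major"`, `"major/minor"`, `"minor/minor"`).
#' @export
genotype_truth_table <- function(assay) {
  genos <- list("major/major" = c("major", "major"),
                "major/minor" = c("major", "minor"),
                "minor/minor" = c("minor", "minor"))
  lapply(genos, function(g)
    simulate_assay(assay, diploid_genotype(assay$locus, g)))
}
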