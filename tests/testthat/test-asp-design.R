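test_that("apply_artificial_mismatch substitutes the complement at the 5th base from 3'", {
  expect_identical(apply_artificial_mismatch("CACTATCATTGATTATTTCCCG"),
                   "CACTATCATTGATTATTACCCG")
  expect_identical(apply_artificial_mismatch("GGATTGTAAGCACCCCCTGG"),
                   "GGATTGTAAGCACCCGCTGG")
  # complement involution makes the operation self-inverse
  set.seed(7)
  for (i in 1:20) {
    core <- paste(sample(c("A", "C", "G", "T"), sample(10:25, 1), replace = TRUE),
                  collapse = "")
    expect_identical(apply_artificial_mismatch(apply_artificial_mismatch(core)),
                     core)
  }
  expect_error(apply_artificial_mismatch("ACG"), "too short")
})

test_that("designed allele-specific primers match the published sequences", {
  loci <- table5_loci()
  expect_identical(
    design_allele_specific_primer(loci[["CYP2C19*2"]], "minor", 22)$sequence,
    "CACTATCATTGATTATTACCCA")
  expect_identical(
    design_allele_specific_primer(loci[["CYP2C19*17"]], "major", 20)$sequence,
    "GTGTCTTCTGTTCTCTAAGC")
})

test_that("designed primers carry the documented mismatch structure", {
  loci <- table5_loci()
  for (loc in loci) {
    for (allele in c("major", "minor")) {
      p <- design_allele_specific_primer(loc, allele, 20)
      own <- cyp2c19pgx:::allele_template_window(loc, allele, 20)
      other <- cyp2c19pgx:::allele_template_window(
        loc, setdiff(c("major", "minor"), allele), 20)
      expect_identical(mismatch_profile(p$sequence, own)$positions_from_3prime, 5L)
      expect_identical(mismatch_profile(p$sequence, other)$positions_from_3prime,
                       c(1L, 5L))
      # structural invariants
      expect_identical(substr(p$sequence, 20, 20), p$target_allele)
      expect_identical(p$substituted_base, complement(p$template_base))
      expect_false(p$substituted_base == p$template_base)
    }
  }
})

test_that("major and minor primers differ only at the 3' terminus", {
  loc <- synth_locus(seed = 11)
  maj <- design_allele_specific_primer(loc, "major", 20)
  mnr <- design_allele_specific_primer(loc, "minor", 20)
  prof <- mismatch_profile(maj$sequence, mnr$sequence)
  expect_identical(prof$positions_from_3prime, 1L)
})

test_that("primer-length and upstream-context bounds are enforced", {
  loc <- synth_locus(seed = 12, upstream_len = 15)
  expect_error(design_allele_specific_primer(loc, "major", 30), "outside allowed range")
  expect_error(design_allele_specific_primer(loc, "major", 20), "too short")
  expect_error(design_assay(loc), "too short")
})

test_that("reverse design errors when no window satisfies the constraints", {
  loc <- snp_locus("rsX", "synthetic", "1", upstream = strrep("ACGT", 10),
                   major_allele = "A", minor_allele = "G",
                   downstream = strrep("AT", 20))   # shorter than min product
  expect_error(design_common_reverse_primer(loc), "no reverse-primer window")
})

test_that("reverse-primer validation reports a reason on rejection", {
  loc <- table5_loci()[["CYP2C19*2"]]
  expect_true(is_valid_reverse_primer(loc, "CTCCATTTTGATCAGGAAGC"))
  bad <- is_valid_reverse_primer(loc, "GGGGGGGGGGGGGGGGGGGG")
  expect_false(as.logical(bad))
  expect_match(attr(bad, "reason"), "not found")
})

test_that("assembled assays satisfy their structural invariants", {
  for (loc in table5_loci()) {
    a <- design_assay(loc)
    L <- nchar(a$primer_major$sequence)
    expect_identical(nchar(a$primer_minor$sequence), L)
    expect_identical(substr(a$primer_major$sequence, 1, L - 1),
                     substr(a$primer_minor$sequence, 1, L - 1))
    expect_false(a$primer_major$target_allele == a$primer_minor$target_allele)
    expect_gte(a$product_length_bp, design_params()$product_length_range[1])
    expect_lte(a$product_length_bp, design_params()$product_length_range[2])
    expect_equal(a$cycling[c("denature_celsius", "anneal_celsius",
                             "extend_celsius", "cycles")],
                 list(denature_celsius = 94, anneal_celsius = 60,
                      extend_celsius = 72, cycles = 35))
  }
})

test_that("round-trip design on the reconstructed loci recovers every published string", {
  loci <- table5_loci()
  pub <- published_assays()
  for (i in seq_len(nrow(pub))) {
    loc <- loci[[pub$allele_name[i]]]
    L <- nchar(pub$forward_major[i])
    expect_identical(design_allele_specific_primer(loc, "major", L)$sequence,
                     pub$forward_major[i])
    expect_identical(design_allele_specific_primer(loc, "minor", L)$sequence,
                     pub$forward_minor[i])
    # full assay assembly also selects the published strings
    a <- design_assay(loc)
    expect_identical(a$primer_major$sequence, pub$forward_major[i])
    expect_identical(a$primer_minor$sequence, pub$forward_minor[i])
    expect_identical(a$common_reverse$sequence, pub$reverse[i])
    expect_true(is_valid_reverse_primer(loc, pub$reverse[i]))
  }
})

test_that("design parameters are validated", {
  expect_error(design_params(mismatch_offset = 1), "mismatch_offset")
  expect_error(design_params(mismatch_offset = 18), "mismatch_offset")
  expect_error(design_params(primer_length_range = c(25, 18)))
})
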