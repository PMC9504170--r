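test_that("band patterns map onto the four genotype calls", {
  bp <- function(m, n) band_pattern(m, n, if (m || n) 190L else NA_integer_)
  expect_identical(call_snp_genotype(bp(TRUE, FALSE)), "homozygous-major")
  expect_identical(call_snp_genotype(bp(TRUE, TRUE)), "heterozygous")
  expect_identical(call_snp_genotype(bp(FALSE, TRUE)), "homozygous-minor")
  expect_identical(call_snp_genotype(bp(FALSE, FALSE)), "no-call")
})

test_that("diplotype equality is order-insensitive and registry-checked", {
  expect_identical(format(diplotype("*17", "*2")), "*2/*17")
  expect_identical(format(diplotype("*2", "*17")), "*2/*17")
  expect_error(diplotype("*2", "*99"), "unknown star allele")
  expect_identical(format(parse_diplotype(" *17/*1 ")), "*1/*17")
  expect_error(parse_diplotype("*2"), "\\*X/\\*Y")
})

test_that("diplotype assembly distributes variant copies over two chromosomes", {
  calls <- function(c2, c3, c17)
    c(rs4244285 = c2, rs4986893 = c3, rs12248560 = c17)
  hm <- "homozygous-major"; ht <- "heterozygous"; hv <- "homozygous-minor"
  expect_identical(format(assign_diplotype(calls(hm, hm, hm))), "*1/*1")
  expect_identical(format(assign_diplotype(calls(ht, hm, hm))), "*1/*2")
  d <- assign_diplotype(calls(ht, hm, ht))
  expect_identical(format(d), "*2/*17")   # trans assumption
  expect_false(d$phased)
  expect_true(assign_diplotype(calls(ht, hm, hm))$phased)
  # homozygosity forcing co-occurrence: loss-of-function precedence over *17
  expect_identical(format(assign_diplotype(calls(hv, hm, ht))), "*2/*2")
  expect_identical(format(assign_diplotype(calls(ht, hm, hv))), "*2/*17")
  expect_identical(format(assign_diplotype(calls(hm, ht, hv))), "*3/*17")
})

test_that("incomplete and ambiguous panels raise documented errors", {
  ht <- "heterozygous"
  expect_error(assign_diplotype(c(rs4244285 = ht, rs4986893 = ht,
                                  rs12248560 = ht)),
               "ambiguous genotype")
  expect_error(assign_diplotype(c(rs4244285 = ht, rs4986893 = "no-call",
                                  rs12248560 = ht)),
               "incomplete panel")
  expect_error(assign_diplotype(c(rs4244285 = ht)), "incomplete panel")
})

test_that("end-to-end recovery holds for every unambiguous genotype combination", {
  loci <- table5_loci()
  assays <- lapply(loci, design_assay)
  names(assays) <- vapply(loci, `[[`, character(1), "rsid")
  combos <- all_panel_genotypes()
  alleles_of <- list("major/major" = c("major", "major"),
                     "major/minor" = c("major", "minor"),
                     "minor/minor" = c("minor", "minor"))
  n_ambiguous <- 0L
  for (i in seq_len(nrow(combos))) {
    truth_calls <- vapply(names(assays), function(rs)
      unname(genotype_to_call[combos[i, rs]]), character(1))
    expected <- tryCatch(assign_diplotype(truth_calls), error = function(e) NULL)
    # redo the calls through the full simulate -> call path
    sim_calls <- vapply(names(assays), function(rs) {
      a <- assays[[rs]]
      call_snp_genotype(simulate_assay(
        a, diploid_genotype(a$locus, alleles_of[[combos[i, rs]]])))
    }, character(1))
    if (is.null(expected)) {
      n_ambiguous <- n_ambiguous + 1L
      expect_error(assign_diplotype(sim_calls), "ambiguous genotype")
    } else {
      expect_identical(format(assign_diplotype(sim_calls)), format(expected))
    }
  }
  expect_identical(n_ambiguous, 1L)   # only the triple heterozygote
})

test_that("panel calling isolates per-sample failures and summarizes counts", {
  bands <- data.frame(
    sample = rep(c("good", "failed"), each = 3),
    rsid = rep(c("rs4244285", "rs4986893", "rs12248560"), 2),
    major_band = c(TRUE, TRUE, TRUE,  TRUE, FALSE, TRUE),
    minor_band = c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE))
  res <- call_panel(bands)
  expect_identical(res$diplotype[res$sample == "good"], "*1/*2")
  expect_true(is.na(res$diplotype[res$sample == "failed"]))
  expect_match(res$note[res$sample == "failed"], "incomplete panel")
  expect_identical(as.integer(attr(res, "summary")[["*1/*2"]]), 1L)
  empty <- call_panel(bands[0, ])
  expect_identical(nrow(empty), 0L)
})
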