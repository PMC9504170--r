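test_that("weight-banded voriconazole doses and percent adjustments are returned", {
  expect_equal(vcz_dose("takahashi-2021", "normal", weight_kg = 10)$dose_value, 16)
  expect_equal(vcz_dose("takahashi-2021", "normal", weight_kg = 20)$dose_value, 12)
  expect_equal(vcz_dose("takahashi-2021", "normal", weight_kg = 30)$dose_value, 10)
  expect_equal(vcz_dose("takahashi-2021", "normal", weight_kg = 15)$dose_value, 12)
  # percent adjustments come back as intervals, never collapsed midpoints
  pm <- vcz_dose("takahashi-2021", "poor", weight_kg = 10)
  expect_equal(pm$dose_value, 16 * c(0.50, 0.67))
  um <- vcz_dose("takahashi-2021", "ultra-rapid", weight_kg = 10)
  expect_equal(um$dose_value, 16 * c(1.25, 1.50))
  expect_error(vcz_dose("takahashi-2021", "normal"), "weight_kg")
  expect_error(vcz_dose("no-such-model", "normal", weight_kg = 10), "unknown")
})

test_that("age-banded twice-daily doses follow the phenotype group", {
  expect_equal(vcz_dose("tian-2021", "poor", age_years = 8)$dose_value, 5.75)
  expect_equal(vcz_dose("tian-2021", "intermediate", age_years = 14)$dose_value, 4.23)
  expect_equal(vcz_dose("tian-2021", "normal", age_years = 8)$dose_value, 6.53)
  expect_equal(vcz_dose("tian-2021", "ultra-rapid", age_years = 12)$dose_value, 3.95)
  rapid <- vcz_dose("tian-2021", "rapid", age_years = 8)
  expect_equal(rapid$dose_value, 6.53)
  expect_match(paste(rapid$qualifiers, collapse = " "), "UM/EM")
  expect_error(vcz_dose("tian-2021", "poor"), "age_years")
})

test_that("median daily doses carry their published ranges", {
  im <- vcz_dose("chen-2022", "intermediate")
  expect_equal(im$dose_value, 18.2)
  expect_equal(im$range, c(13.3, 21.8))
  expect_equal(vcz_dose("chen-2022", "normal")$dose_value, 20.8)
  expect_equal(vcz_dose("chen-2022", "poor")$range, c(10.7, 19.1))
})

test_that("package-insert dosing is age-banded", {
  expect_equal(vcz_dose("package-insert", "normal", age_years = 8)$dose_value, 9)
  expect_equal(vcz_dose("package-insert", "normal", age_years = 15)$dose_value, 6)
  expect_equal(vcz_dose("package-insert", "normal", age_years = 1)$dose_value, c(5, 7))
})

test_that("trough classification is strict against the window and monotone", {
  expect_identical(as.character(classify_trough(0.8)$class), "subtherapeutic")
  expect_identical(as.character(classify_trough(6.0)$class), "supratherapeutic")
  expect_identical(as.character(classify_trough(3.0)$class), "therapeutic")
  # window bounds are inclusive (strict comparison beyond them)
  expect_identical(as.character(classify_trough(1.5)$class), "therapeutic")
  expect_identical(as.character(classify_trough(5.0)$class), "therapeutic")
  expect_error(classify_trough(-1), "non-negative")
  # selectable alternative window
  gg <- trough_window("garcia-garcia")
  expect_equal(as.numeric(gg), c(1.0, 5.5))
  expect_identical(as.character(classify_trough(1.2, gg)$class), "therapeutic")
  # monotone: class index never decreases with rising concentration
  cls <- vapply(seq(0, 8, by = 0.25),
                function(x) as.integer(classify_trough(x)$class), integer(1))
  expect_true(all(diff(cls) >= 0))
})

test_that("the prophylaxis policy follows phenotype", {
  expect_equal(vcz_prophylaxis_policy("rapid")$dose_value, 300)
  expect_identical(vcz_prophylaxis_policy("ultra-rapid")$dose_value, "avoid")
  expect_equal(vcz_prophylaxis_policy("normal")$dose_value, 200)
  expect_equal(vcz_prophylaxis_policy("intermediate")$dose_value, 200)
})

test_that("SSRI exposure-equivalent doses match the published modeling", {
  expect_equal(ssri_equivalent_dose("escitalopram", "poor")$dose_value, 10)
  expect_equal(ssri_equivalent_dose("escitalopram", "normal")$dose_value, 20)
  um <- ssri_equivalent_dose("escitalopram", "ultra-rapid")
  expect_equal(um$dose_value, 30)
  expect_match(paste(um$qualifiers, collapse = " "), "twice-daily")
  expect_equal(ssri_equivalent_dose("sertraline", "poor")$dose_value, 100)
  expect_equal(ssri_equivalent_dose("sertraline", "rapid")$dose_value, 200)
  expect_equal(ssri_equivalent_dose("sertraline", "ultra-rapid")$dose_value, 200)
  expect_error(ssri_equivalent_dose("escitalopram", "intermediate"),
               "no published")
  expect_error(ssri_equivalent_dose("fluoxetine", "poor"))
})

test_that("dose ordering is monotone across phenotypes", {
  for (w in c(10, 20, 35)) {
    pm <- vcz_dose("takahashi-2021", "poor", weight_kg = w)$dose_value
    nm <- vcz_dose("takahashi-2021", "normal", weight_kg = w)$dose_value
    um <- vcz_dose("takahashi-2021", "ultra-rapid", weight_kg = w)$dose_value
    expect_lte(max(pm), nm)
    expect_lte(nm, min(um))
  }
  # normal-metabolizer base dose non-increasing in weight
  base <- vapply(c(10, 20, 35), function(w)
    vcz_dose("takahashi-2021", "normal", weight_kg = w)$dose_value, numeric(1))
  expect_true(all(diff(base) <= 0))
  for (drug in c("escitalopram", "sertraline")) {
    d <- vapply(c("poor", "normal", "ultra-rapid"), function(p)
      ssri_equivalent_dose(drug, p)$dose_value, numeric(1))
    expect_true(all(diff(d) > 0))
  }
})

test_that("risk flags fire only when their condition holds, with provenance", {
  ppi <- risk_flags("PPI", diplotype = "*1/*17")
  expect_length(ppi, 1L)
  expect_match(ppi[[1]]$citation, "Franciosi")
  expect_length(risk_flags("PPI", diplotype = "*1/*1"), 0L)
  clo <- risk_flags("clopidogrel", phenotype = "poor")
  expect_length(clo, 1L)
  expect_match(clo[[1]]$flag, "extrapolated from adult")
  expect_length(risk_flags("clopidogrel", phenotype = "normal"), 0L)
  ssri <- risk_flags("SSRI", phenotype = "poor")
  expect_length(ssri, 1L)
  expect_match(ssri[[1]]$citation, "Aldrich")
  expect_length(risk_flags("SSRI", phenotype = "ultra-rapid"), 0L)
})

test_that("co-medication flags are qualitative and directional", {
  fl <- vcz_comedication_flags(c("Omeprazole", "paracetamol", "rifampicin"))
  expect_length(fl, 2L)
  effects <- setNames(vapply(fl, `[[`, character(1), "effect"),
                      vapply(fl, `[[`, character(1), "comedication"))
  expect_identical(effects[["omeprazole"]], "raises")
  expect_identical(effects[["rifampicin"]], "lowers")
})

test_that("every recommendation carries a non-empty citation", {
  recs <- list(vcz_dose("takahashi-2021", "poor", weight_kg = 10),
               vcz_dose("tian-2021", "rapid", age_years = 5),
               vcz_dose("chen-2022", "normal"),
               vcz_dose("package-insert", "normal", age_years = 5),
               vcz_prophylaxis_policy("ultra-rapid"),
               ssri_equivalent_dose("sertraline", "normal"))
  for (r in recs) expect_true(nzchar(r$citation))
  for (f in c(risk_flags("PPI", diplotype = "*2/*17"),
              risk_flags("clopidogrel", phenotype = "intermediate")))
    expect_true(nzchar(f$citation))
})
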