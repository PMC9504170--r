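# shared helpers for the test suite

# the published assay strings, as an independent copy frozen in the tests
# (not read back from the package) so regressions in table5_primers() or the
# design path cannot mask each other
published_assays <- function() {
  data.frame(
    allele_name = c("CYP2C19*2", "CYP2C19*3", "CYP2C19*17"),
    rsid = c("rs4244285", "rs4986893", "rs12248560"),
    forward_major = c("CACTATCATTGATTATTACCCG", "GGATTGTAAGCACCCGCTGG",
                      "GTGTCTTCTGTTCTCTAAGC"),
    forward_minor = c("CACTATCATTGATTATTACCCA", "GGATTGTAAGCACCCGCTGA",
                      "GTGTCTTCTGTTCTCTAAGT"),
    reverse = c("CTCCATTTTGATCAGGAAGC", "AGAACTTTGCCATCTTTTCCAG",
                "CAAATGGGAAAAGGGAGAC"),
    stringsAsFactors = FALSE)
}

# the genotype-to-phenotype examples printed in the published rule table
published_phenotype_examples <- function() {
  data.frame(
    diplotype = c("*17/*17", "*1/*17", "*1/*1",
                  "*1/*9", "*9/*17", "*9/*9",
                  "*1/*2", "*1/*3", "*2/*17", "*3/*17",
                  "*2/*9", "*3/*9",
                  "*2/*2", "*3/*3", "*2/*3",
                  "*1/*12", "*2/*12", "*12/*14"),
    phenotype = c("ultra-rapid", "rapid", "normal",
                  rep("likely-intermediate", 3L),
                  rep("intermediate", 4L),
                  rep("likely-poor", 2L),
                  rep("poor", 3L),
                  rep("indeterminate", 3L)),
    stringsAsFactors = FALSE)
}

# enumerate all 27 three-locus diploid genotype combinations
all_panel_genotypes <- function() {
  classes <- c("major/major", "major/minor", "minor/minor")
  expand.grid(rs4244285 = classes, rs4986893 = classes, rs12248560 = classes,
              stringsAsFactors = FALSE)
}

genotype_to_call <- c("major/major" = "homozygous-major",
                      "major/minor" = "heterozygous",
                      "minor/minor" = "homozygous-minor")

# run the packaged CLI script in a child R process
run_cli <- function(args) {
  script <- system.file("cli", "cyp2c19pgx.R", package = "cyp2c19pgx")
  out <- suppressWarnings(system2(
    file.path(R.home("bin"), "Rscript"), c(script, args),
    stdout = TRUE, stderr = TRUE,
    env = paste0("R_LIBS=", paste(.libPaths(), collapse = .Platform$path.sep))))
  list(status = attr(out, "status") %||% 0L, output = paste(out, collapse = "\n"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
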