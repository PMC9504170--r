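# run code under a locally seeded RNG without disturbing global state
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# fixed AT-only spacer between the diagnostic base and the reverse-primer
# binding site of the reconstructed CYP2C19 loci (the true intervening
# genomic sequence is not part of the assay definition); committed, not
# generated, so reverse design on these loci is deterministic
TABLE5_SPACER <- strrep("AATTAT", 25L)

# printed assay strings: forward allele-specific primers (major form, with
# the artificial substitution) and common reverse primers
TABLE5_ASSAYS <- list(
  "CYP2C19*2" = list(rsid = "rs4244285", position_label = "681",
                     forward_major = "CACTATCATTGATTATTACCCG",
                     minor_base = "A",
                     reverse = "CTCCATTTTGATCAGGAAGC"),
  "CYP2C19*3" = list(rsid = "rs4986893", position_label = "636",
                     forward_major = "GGATTGTAAGCACCCGCTGG",
                     minor_base = "A",
                     reverse = "AGAACTTTGCCATCTTTTCCAG"),
  "CYP2C19*17" = list(rsid = "rs12248560", position_label = "806",
                      forward_major = "GTGTCTTCTGTTCTCTAAGC",
                      minor_base = "T",
                      reverse = "CAAATGGGAAAAGGGAGAC"))

#' The three reconstructed CYP2C19 assay loci
#'
#' Rebuilds SNP loci for CYP2C19*2 (rs4244285), *3 (rs4986893) and *17
#' (rs12248560) from the published assay oligonucleotides: the upstream
#' context is the forward allele-specific primer with the artificial
#' substitution reverted to its template complement (so re-designing on
#' these loci reproduces the published primers), and the downstream context
#' embeds the reverse complement of the published common reverse primer
#' behind a fixed 150 bp synthetic AT spacer (the true intervening genomic
#' sequence and product sizes are not part of the assay definition).
#'
#' @return named list of three [snp_locus()] objects.
#' @export
table5_loci <- function() {
  params <- design_params()
  lapply(setNames(nm = names(TABLE5_ASSAYS)), function(nm) {
    a <- TABLE5_ASSAYS[[nm]]
    fwd <- a$forward_major
    n <- nchar(fwd)
    # revert the artificial substitution to recover the template core
    core <- apply_artificial_mismatch(fwd, params)
    snp_locus(rsid = a$rsid, allele_name = nm,
              position_label = a$position_label,
              upstream = substr(core, 1L, n - 1L),
              major_allele = substr(core, n, n),
              minor_allele = a$minor_base,
              downstream = paste0(TABLE5_SPACER, reverse_complement(a$reverse)))
  })
}

#' Published assay oligonucleotides
#'
#' The forward allele-specific primer pairs (major/minor) and common reverse
#' primers of the three CYP2C19 assays, as regression fixtures.
#'
#' @return data frame with columns `allele_name`, `rsid`, `forward_major`,
#'   `forward_minor`, `reverse`.
#' @export
table5_primers <- function() {
  rows <- lapply(names(TABLE5_ASSAYS), function(nm) {
    a <- TABLE5_ASSAYS[[nm]]
    n <- nchar(a$forward_major)
    data.frame(allele_name = nm, rsid = a$rsid,
               forward_major = a$forward_major,
               forward_minor = paste0(substr(a$forward_major, 1L, n - 1L),
                                      a$minor_base),
               reverse = a$reverse, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Generate a random SNP locus
#'
#' Uniform random template with distinct random major/minor alleles;
#' reproducible under a seed and without touching global RNG state.
#'
#' @param seed integer seed (optional; uses the current RNG stream when
#'   `NULL`).
#' @param upstream_len,downstream_len context lengths in nt.
#' @param rsid identifier attached to the locus.
#' @return a [snp_locus()].
#' @export
synth_locus <- function(seed = NULL, upstream_len = 40L, downstream_len = 250L,
                        rsid = "rsSYNTH") {
  if (upstream_len < 1L || downstream_len < 1L)
    stop("context lengths must be positive", call. = FALSE)
  build <- function() {
    major <- sample(c("A", "C", "G", "T"), 1L)
    minor <- sample(setdiff(c("A", "C", "G", "T"), major), 1L)
    snp_locus(rsid = rsid, allele_name = paste0(rsid, "-synthetic"),
              position_label = as.character(upstream_len + 1L),
              upstream = random_dna(upstream_len),
              major_allele = major, minor_allele = minor,
              downstream = random_dna(downstream_len))
  }
  if (is.null(seed)) build() else with_local_seed(seed, build())
}

#' Generate a synthetic diploid sample panel with known truth
#'
#' Draws per-locus diploid genotypes for `n_samples` samples at the three
#' CYP2C19 panel loci (default [table5_loci()]), keeping the planted truth
#' for concordance scoring. Genotype classes are drawn independently per
#' locus with the stated frequencies (uniform thirds by default; this is a
#' test harness, not a population model, so no Hardy-Weinberg structure is
#' imposed).
#'
#' @param seed integer seed; the same seed reproduces the panel exactly.
#' @param n_samples number of samples (default 21, the size of a typical
#'   reference cell-line validation panel).
#' @param genotype_frequencies numeric length-3 vector of frequencies for
#'   (homozygous major, heterozygous, homozygous minor); must sum to 1.
#' @param loci named list of [snp_locus()] objects (default the three
#'   reconstructed CYP2C19 loci).
#' @return an object of class `synthetic_panel`: `loci`, `genotypes` (long
#'   data frame sample/rsid/genotype), `truth` (per-sample expected
#'   diplotype string or `NA` for the ambiguous triple heterozygote, plus
#'   phased flag) and `seed`.
#' @export
synth_panel <- function(seed = 760103L, n_samples = 21L,
                        genotype_frequencies = rep(1 / 3, 3L),
                        loci = table5_loci()) {
  if (length(genotype_frequencies) != 3L || any(genotype_frequencies < 0) ||
      abs(sum(genotype_frequencies) - 1) > 1e-8)
    stop("genotype_frequencies must be 3 non-negative values summing to 1",
         call. = FALSE)
  classes <- c("major/major", "major/minor", "minor/minor")
  rsids <- vapply(loci, `[[`, character(1L), "rsid")
  genotypes <- with_local_seed(seed, {
    do.call(rbind, lapply(seq_len(n_samples), function(i)
      data.frame(sample = sprintf("S%03d", i), rsid = unname(rsids),
                 genotype = sample(classes, length(rsids), replace = TRUE,
                                   prob = genotype_frequencies),
                 stringsAsFactors = FALSE)))
  })
  if (is.null(genotypes))
    genotypes <- data.frame(sample = character(), rsid = character(),
                            genotype = character(), stringsAsFactors = FALSE)
  geno_to_call <- c("major/major" = "homozygous-major",
                    "major/minor" = "heterozygous",
                    "minor/minor" = "homozygous-minor")
  truth <- do.call(rbind, lapply(unique(genotypes$sample), function(s) {
    sub <- genotypes[genotypes$sample == s, ]
    calls <- setNames(geno_to_call[sub$genotype], sub$rsid)
    d <- tryCatch(assign_diplotype(calls), error = function(e) NULL)
    data.frame(sample = s,
               diplotype = if (is.null(d)) NA_character_ else format(d),
               phased = if (is.null(d)) NA else d$phased,
               stringsAsFactors = FALSE)
  }))
  if (is.null(truth))
    truth <- data.frame(sample = character(), diplotype = character(),
                        phased = logical(), stringsAsFactors = FALSE)
  structure(list(loci = loci, genotypes = genotypes, truth = truth,
                 seed = seed),
            class = "synthetic_panel")
}

#' @export
print.synthetic_panel <- function(x, ...) {
  cat("synthetic panel: ", length(unique(x$genotypes$sample)), " samples x ",
      length(x$loci), " loci (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Simulate assay band patterns for a synthetic panel
#'
#' Designs an assay for every panel locus and runs [simulate_assay()] on
#' every sample/locus genotype, producing the long band-pattern table that
#' [call_panel()] consumes.
#'
#' @param panel a [synth_panel()].
#' @param params a [design_params()] object.
#' @return data frame with columns `sample`, `rsid`, `major_band`,
#'   `minor_band`.
#' @export
simulate_panel <- function(panel, params = design_params()) {
  assays <- lapply(panel$loci, design_assay, params = params)
  names(assays) <- vapply(panel$loci, `[[`, character(1L), "rsid")
  g <- panel$genotypes
  alleles_of <- list("major/major" = c("major", "major"),
                     "major/minor" = c("major", "minor"),
                     "minor/minor" = c("minor", "minor"))
  pats <- lapply(seq_len(nrow(g)), function(i) {
    assay <- assays[[g$rsid[i]]]
    simulate_assay(assay, diploid_genotype(assay$locus,
                                           alleles_of[[g$genotype[i]]]))
  })
  data.frame(sample = g$sample, rsid = g$rsid,
             major_band = vapply(pats, `[[`, logical(1L), "major_reaction_amplified"),
             minor_band = vapply(pats, `[[`, logical(1L), "minor_reaction_amplified"),
             stringsAsFactors = FALSE)
}

#' End-to-end concordance of simulate -> call on a synthetic panel
#'
#' Runs the full pipeline (assay design, in-silico amplification, genotype
#' calling, diplotype assembly) and scores recovery of the planted truth on
#' the unambiguous samples (the triple heterozygote is excluded because its
#' phase cannot be resolved by an unphased assay, which the caller reports
#' as a documented error).
#'
#' @param panel a [synth_panel()].
#' @param params a [design_params()] object.
#' @return list with `n_samples`, `n_unambiguous`, `n_concordant`,
#'   `concordance_pct` and the per-sample `calls` table.
#' @export
panel_concordance <- function(panel, params = design_params()) {
  calls <- call_panel(simulate_panel(panel, params))
  merged <- merge(calls, panel$truth, by = "sample",
                  suffixes = c("_called", "_truth"))
  ok <- !is.na(merged$diplotype_truth)
  conc <- sum(ok & !is.na(merged$diplotype_called) &
                merged$diplotype_called == merged$diplotype_truth)
  list(n_samples = nrow(merged), n_unambiguous = sum(ok),
       n_concordant = conc,
       concordance_pct = if (sum(ok)) 100 * conc / sum(ok) else NA_real_,
       calls = merged)
}
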