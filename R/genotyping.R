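# the three diagnostic SNPs of the panel and the star allele each defines
PANEL_RSIDS <- c("rs4244285", "rs4986893", "rs12248560")
RSID_TO_STAR <- c(rs4244285 = "*2", rs4986893 = "*3", rs12248560 = "*17")
GENOTYPE_CALLS <- c("homozygous-major", "heterozygous", "homozygous-minor", "no-call")
# loss-of-function alleles outrank *17 when homozygosity forces co-occurrence
STAR_PRECEDENCE <- c("*2", "*3", "*17")

#' Call a SNP genotype from a band pattern
#'
#' Major-lane band only: homozygous major. Both lanes: heterozygous.
#' Minor-lane band only: homozygous minor. No band in either lane is a
#' failed assay and yields `"no-call"` (a value, not an error).
#'
#' @param pattern a [band_pattern()].
#' @return one of `"homozygous-major"`, `"heterozygous"`,
#'   `"homozygous-minor"`, `"no-call"`.
#' @export
call_snp_genotype <- function(pattern) {
  maj <- pattern$major_reaction_amplified
  mnr <- pattern$minor_reaction_amplified
  if (maj && mnr) "heterozygous"
  else if (maj) "homozygous-major"
  else if (mnr) "homozygous-minor"
  else "no-call"
}

#' Star-allele diplotype
#'
#' An unordered pair of star alleles; equality is order-insensitive because
#' alleles are stored in registry order. `phased = FALSE` records that the
#' assignment needed a phasing assumption (variants at different SNPs placed
#' in trans).
#'
#' @param allele1,allele2 star-allele names resolvable in the allele
#'   registry (e.g. `"*2"`).
#' @param phased logical; `FALSE` when a phasing assumption was required.
#' @return an object of class `diplotype`.
#' @export
diplotype <- function(allele1, allele2, phased = TRUE) {
  reg <- names(allele_registry())
  pair <- c(allele1, allele2)
  unknown <- setdiff(pair, reg)
  if (length(unknown))
    stop("unknown star allele(s) ", paste(unknown, collapse = ", "),
         "; registry knows ", paste(reg, collapse = ", "), call. = FALSE)
  pair <- pair[order(match(pair, reg))]
  structure(list(alleles = pair, phased = isTRUE(phased)), class = "diplotype")
}

#' @export
format.diplotype <- function(x, ...) paste(x$alleles, collapse = "/")

#' @export
print.diplotype <- function(x, ...) {
  cat("CYP2C19 diplotype ", format(x),
      if (!x$phased) " (trans configuration assumed)", "\n", sep = "")
  invisible(x)
}

#' Parse a diplotype string
#'
#' @param x string of the form `"*2/*17"` (order-insensitive).
#' @param phased logical flag stored on the result.
#' @return a [diplotype()].
#' @export
parse_diplotype <- function(x, phased = TRUE) {
  parts <- strsplit(trimws(x), "/", fixed = TRUE)[[1L]]
  if (length(parts) != 2L)
    stop("diplotype must be written as \"*X/*Y\", got \"", x, "\"", call. = FALSE)
  diplotype(trimws(parts[1L]), trimws(parts[2L]), phased = phased)
}

#' Assemble a CYP2C19 diplotype from the three-SNP panel
#'
#' Takes genotype calls at rs4244285 (*2), rs4986893 (*3) and rs12248560
#' (*17) and distributes the observed variant copies over the two
#' chromosomes. Homozygous variants occupy both chromosomes; heterozygous
#' variants at different SNPs are placed in trans (on opposite chromosomes)
#' and the result is flagged `phased = FALSE`, since an unphased assay
#' cannot exclude the cis configuration. When homozygosity forces a
#' loss-of-function variant and *17 onto one chromosome, the
#' loss-of-function allele names the haplotype (*2 > *3 > *17). A
#' chromosome with no variant is *1.
#'
#' @param calls named character vector or list of genotype calls with names
#'   `rs4244285`, `rs4986893`, `rs12248560`; values as returned by
#'   [call_snp_genotype()].
#' @return a [diplotype()].
#' @export
assign_diplotype <- function(calls) {
  calls <- unlist(calls)
  missing_rs <- setdiff(PANEL_RSIDS, names(calls))
  if (length(missing_rs))
    stop("incomplete panel: missing call(s) at ",
         paste(missing_rs, collapse = ", "), call. = FALSE)
  calls <- calls[PANEL_RSIDS]
  bad <- setdiff(calls, GENOTYPE_CALLS)
  if (length(bad))
    stop("unknown genotype call(s): ", paste(bad, collapse = ", "), call. = FALSE)
  if (any(calls == "no-call"))
    stop("incomplete panel: no-call at ",
         paste(names(calls)[calls == "no-call"], collapse = ", "), call. = FALSE)
  copies <- c(`homozygous-major` = 0L, heterozygous = 1L, `homozygous-minor` = 2L)[calls]
  names(copies) <- RSID_TO_STAR[names(calls)]
  hets <- names(copies)[copies == 1L]
  homs <- names(copies)[copies == 2L]
  if (length(hets) == 3L)
    stop("ambiguous genotype: heterozygous at all three SNPs; the variant ",
         "copies cannot be distributed over two chromosomes without an ",
         "external phasing source", call. = FALSE)
  chromA <- homs
  chromB <- homs
  if (length(hets) >= 1L) chromA <- c(chromA, hets[1L])
  if (length(hets) == 2L) chromB <- c(chromB, hets[2L])
  star_of <- function(vars) {
    hit <- STAR_PRECEDENCE[STAR_PRECEDENCE %in% vars]
    if (length(hit)) hit[1L] else "*1"
  }
  diplotype(star_of(chromA), star_of(chromB), phased = length(hets) < 2L)
}

#' Call diplotypes for a panel of samples
#'
#' @param band_patterns data frame in long format with columns `sample`,
#'   `rsid`, `major_band`, `minor_band` (logical), one row per sample and
#'   panel SNP.
#' @return data frame with one row per sample: the three genotype calls, the
#'   diplotype string, the phased flag and a `note` column carrying
#'   per-sample errors (empty on success). A diplotype count table is
#'   attached as attribute `"summary"`. Per-sample failures never abort the
#'   batch.
#' @export
call_panel <- function(band_patterns) {
  cols <- c("sample", "rsid", "major_band", "minor_band")
  if (!all(cols %in% names(band_patterns)))
    stop("band_patterns needs columns ", paste(cols, collapse = ", "), call. = FALSE)
  samples <- unique(band_patterns$sample)
  rows <- lapply(samples, function(s) {
    sub <- band_patterns[band_patterns$sample == s, , drop = FALSE]
    calls <- setNames(rep("no-call", 3L), PANEL_RSIDS)
    for (rs in intersect(PANEL_RSIDS, sub$rsid)) {
      r <- sub[sub$rsid == rs, ][1L, ]
      calls[[rs]] <- call_snp_genotype(band_pattern(r$major_band, r$minor_band,
                                                    product_length_bp = 1L))
    }
    res <- tryCatch(assign_diplotype(calls), error = function(e) e)
    if (inherits(res, "error"))
      data.frame(sample = s, rs4244285 = calls[[1L]], rs4986893 = calls[[2L]],
                 rs12248560 = calls[[3L]], diplotype = NA_character_,
                 phased = NA, note = conditionMessage(res),
                 stringsAsFactors = FALSE)
    else
      data.frame(sample = s, rs4244285 = calls[[1L]], rs4986893 = calls[[2L]],
                 rs12248560 = calls[[3L]], diplotype = format(res),
                 phased = res$phased, note = "", stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sample = character(), rs4244285 = character(),
               rs4986893 = character(), rs12248560 = character(),
               diplotype = character(), phased = logical(), note = character(),
               stringsAsFactors = FALSE)
  attr(out, "summary") <- table(out$diplotype[!is.na(out$diplotype)])
  out
}
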