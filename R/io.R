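# small stable polynomial hash used to stamp outputs with a config fingerprint
config_hash <- function(x) {
  bytes <- utf8ToInt(paste(deparse(x), collapse = ""))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

output_header <- function(params = NULL, seed = NULL) {
  c(paste0("# cyp2c19pgx version=", as.character(packageVersion("cyp2c19pgx"))),
    paste0("# config_hash=", config_hash(params)),
    paste0("# seed=", if (is.null(seed)) "NA" else seed))
}

#' Read SNP loci from FASTA plus a locus configuration file
#'
#' The FASTA file holds the forward-strand context of each locus; the YAML
#' configuration cross-references records by identifier and gives the rsID,
#' the 1-based diagnostic position within the record, and the major/minor
#' alleles. The reference base at the diagnostic position must equal the
#' major allele unless `check_ref = FALSE`.
#'
#' @param fasta_path FASTA file of forward-strand locus contexts.
#' @param config_path YAML file with a top-level `loci:` list of records
#'   `id`, `rsid`, `allele_name`, `position_label`, `position`, `major`,
#'   `minor`.
#' @param check_ref strict reference-allele check (default `TRUE`).
#' @return named list of [snp_locus()] objects.
#' @export
read_locus_file <- function(fasta_path, config_path, check_ref = TRUE) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  cfg <- yaml::read_yaml(config_path)$loci
  if (is.null(cfg)) stop("locus config has no 'loci' list", call. = FALSE)
  loci <- lapply(cfg, function(rec) {
    if (!rec$id %in% names(seqs))
      stop("missing FASTA record \"", rec$id, "\"", call. = FALSE)
    s <- as.character(seqs[[rec$id]])
    pos <- as.integer(rec$position)
    if (is.na(pos) || pos < 2L || pos >= nchar(s))
      stop("diagnostic position ", rec$position, " out of range for record \"",
           rec$id, "\" (", nchar(s), " nt; need flanking context on both sides)",
           call. = FALSE)
    ref <- substr(s, pos, pos)
    if (!ref %in% c("A", "C", "G", "T"))
      stop("invalid nucleotide '", ref, "' at diagnostic position of record \"",
           rec$id, "\"", call. = FALSE)
    if (check_ref && !identical(ref, toupper(rec$major)))
      stop("reference base ", ref, " at position ", pos, " of \"", rec$id,
           "\" does not match the stated major allele ", rec$major,
           " (use check_ref = FALSE to override)", call. = FALSE)
    snp_locus(rsid = rec$rsid, allele_name = rec$allele_name,
              position_label = as.character(rec$position_label),
              upstream = substr(s, 1L, pos - 1L),
              major_allele = rec$major, minor_allele = rec$minor,
              downstream = substr(s, pos + 1L, nchar(s)))
  })
  names(loci) <- vapply(cfg, `[[`, character(1L), "allele_name")
  loci
}

#' Write SNP loci as FASTA plus locus configuration
#'
#' Emits the same two files [read_locus_file()] consumes.
#'
#' @param loci named list of [snp_locus()] objects.
#' @param fasta_path,config_path output paths.
#' @return invisibly, the two paths.
#' @export
write_locus_files <- function(loci, fasta_path, config_path) {
  ids <- vapply(loci, `[[`, character(1L), "rsid")
  seqs <- Biostrings::DNAStringSet(vapply(loci, function(l)
    paste0(l$upstream, l$major_allele, l$downstream), character(1L)))
  names(seqs) <- ids
  Biostrings::writeXStringSet(seqs, fasta_path)
  cfg <- list(loci = lapply(loci, function(l)
    list(id = l$rsid, rsid = l$rsid, allele_name = l$allele_name,
         position_label = l$position_label,
         position = nchar(l$upstream) + 1L,
         major = l$major_allele, minor = l$minor_allele)))
  names(cfg$loci) <- NULL
  yaml::write_yaml(cfg, config_path)
  invisible(c(fasta_path, config_path))
}

#' Write designed assays as a primer table (TSV)
#'
#' Tab-separated table mirroring the published assay layout (allele name,
#' rsID, forward major/minor, reverse) plus melting temperatures and product
#' length, preceded by commented header lines embedding the tool version,
#' a configuration hash and the seed.
#'
#' @param assays list of [asp_assay][design_assay()] objects.
#' @param path output path.
#' @param params the [design_params()] used (hashed into the header).
#' @param seed optional seed recorded in the header.
#' @return invisibly, `path`.
#' @export
write_primer_table <- function(assays, path, params = design_params(),
                               seed = NULL) {
  rows <- lapply(assays, function(a)
    data.frame(allele_name = a$locus$allele_name, rsid = a$locus$rsid,
               forward_major = a$primer_major$sequence,
               forward_minor = a$primer_minor$sequence,
               reverse = a$common_reverse$sequence,
               tm_forward_major = round(a$primer_major$melting_temp_celsius, 2),
               tm_forward_minor = round(a$primer_minor$melting_temp_celsius, 2),
               tm_reverse = round(a$common_reverse$melting_temp_celsius, 2),
               product_length_bp = a$product_length_bp,
               stringsAsFactors = FALSE))
  tbl <- do.call(rbind, rows)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(output_header(params, seed), con)
  suppressWarnings(write.table(tbl, con, sep = "\t", quote = FALSE,
                               row.names = FALSE))
  invisible(path)
}

#' Read a primer table written by [write_primer_table()]
#'
#' @param path TSV path.
#' @return data frame of primer records.
#' @export
read_primer_table <- function(path) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write assay primers as FASTA
#'
#' @param assays list of [asp_assay][design_assay()] objects.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_primer_fasta <- function(assays, path) {
  seqs <- character()
  for (a in assays) {
    nm <- paste0(a$locus$allele_name, "|", a$locus$rsid)
    seqs[paste0(nm, "|forward-major")] <- a$primer_major$sequence
    seqs[paste0(nm, "|forward-minor")] <- a$primer_minor$sequence
    seqs[paste0(nm, "|reverse")] <- a$common_reverse$sequence
  }
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read per-sample genotype calls at the panel SNPs from a VCF
#'
#' Records are matched by the ID column against the three panel rsIDs
#' (rs4244285, rs4986893, rs12248560); coordinates are ignored, so the input
#' is genome-build independent. GT fields map 0/0 to homozygous-major, 0/1
#' or 1/0 to heterozygous, 1/1 to homozygous-minor and ./. (or absent) to
#' no-call. Other records are ignored; a multiallelic record at a panel
#' rsID is an error.
#'
#' @param vcf_path path to a VCF v4.x file.
#' @return data frame with one row per sample and columns `sample`,
#'   `rs4244285`, `rs4986893`, `rs12248560`; attribute `"ignored_records"`
#'   counts non-panel records skipped.
#' @export
read_vcf_genotypes <- function(vcf_path) {
  v <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  ids <- vcfR::getID(v)
  hit <- ids %in% PANEL_RSIDS
  if (!any(hit))
    stop("incomplete panel: VCF contains none of ",
         paste(PANEL_RSIDS, collapse = ", "), call. = FALSE)
  alt <- vcfR::getALT(v)[hit]
  if (any(grepl(",", alt, fixed = TRUE)))
    stop("unsupported record: multiallelic ALT at ",
         paste(ids[hit][grepl(",", alt, fixed = TRUE)], collapse = ", "),
         call. = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  samples <- colnames(gt)
  map_gt <- function(g) {
    if (is.na(g)) return("no-call")
    g <- gsub("|", "/", g, fixed = TRUE)
    switch(g, "0/0" = "homozygous-major",
           "0/1" = , "1/0" = "heterozygous",
           "1/1" = "homozygous-minor",
           "./." = , "." = "no-call",
           stop("unsupported GT \"", g, "\" (biallelic diploid only)",
                call. = FALSE))
  }
  out <- data.frame(sample = samples, stringsAsFactors = FALSE)
  for (rs in PANEL_RSIDS) {
    row <- which(ids == rs)
    out[[rs]] <- if (length(row))
      vapply(gt[row[1L], samples], map_gt, character(1L), USE.NAMES = FALSE)
    else "no-call"
  }
  attr(out, "ignored_records") <- sum(!hit)
  out
}

#' Write panel genotypes as a minimal VCF
#'
#' Emits the synthetic panel's per-sample genotypes at the three panel SNPs
#' as a VCF v4.2 file consumable by [read_vcf_genotypes()].
#'
#' @param panel a [synth_panel()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_panel_vcf <- function(panel, path) {
  g <- panel$genotypes
  samples <- unique(g$sample)
  gt_of <- c("major/major" = "0/0", "major/minor" = "0/1",
             "minor/minor" = "1/1")
  lines <- c("##fileformat=VCFv4.2",
             paste0("##source=cyp2c19pgx-", packageVersion("cyp2c19pgx"),
                    " seed=", panel$seed),
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", samples), collapse = "\t"))
  for (i in seq_along(panel$loci)) {
    l <- panel$loci[[i]]
    gts <- vapply(samples, function(s) {
      sub <- g[g$sample == s & g$rsid == l$rsid, ]
      if (nrow(sub)) gt_of[[sub$genotype[1L]]] else "./."
    }, character(1L))
    lines <- c(lines, paste(c("10", l$position_label, l$rsid, l$major_allele,
                              l$minor_allele, ".", "PASS", ".", "GT", gts),
                            collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
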