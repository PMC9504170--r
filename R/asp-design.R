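#' SNP locus description
#'
#' A biallelic diagnostic site given by its forward-strand flanking sequence:
#' `upstream` ends immediately 5' of the diagnostic base, `downstream` starts
#' immediately 3' of it. The allele-specific forward primers end on the
#' diagnostic base; the common reverse primer binds within `downstream`.
#'
#' @param rsid dbSNP identifier, e.g. "rs4244285".
#' @param allele_name star-allele label, e.g. "CYP2C19*2".
#' @param position_label coordinate label used in assay reports (free text).
#' @param upstream forward-strand sequence ending just before the diagnostic
#'   base.
#' @param major_allele,minor_allele the two single-base alleles at the
#'   diagnostic position (must differ).
#' @param downstream forward-strand sequence starting just after the
#'   diagnostic base.
#' @return an object of class `snp_locus`.
#' @export
snp_locus <- function(rsid, allele_name, position_label,
                      upstream, major_allele, minor_allele, downstream) {
  major_allele <- complement(complement(toupper(major_allele))) # alphabet check
  minor_allele <- complement(complement(toupper(minor_allele)))
  if (identical(major_allele, minor_allele))
    stop("major and minor alleles must differ", call. = FALSE)
  structure(list(rsid = as.character(rsid),
                 allele_name = as.character(allele_name),
                 position_label = as.character(position_label),
                 upstream = dna(upstream),
                 major_allele = major_allele,
                 minor_allele = minor_allele,
                 downstream = dna(downstream)),
            class = "snp_locus")
}

#' @export
print.snp_locus <- function(x, ...) {
  cat("SNP locus ", x$allele_name, " (", x$rsid, ", position ",
      x$position_label, ")\n", sep = "")
  cat("  alleles: major ", x$major_allele, " / minor ", x$minor_allele, "\n", sep = "")
  cat("  context: ", nchar(x$upstream), " nt upstream, ",
      nchar(x$downstream), " nt downstream\n", sep = "")
  invisible(x)
}

#' Assay design parameters
#'
#' Defaults follow conventional PCR practice compatible with a 60 degC
#' annealing step: primer lengths 18-25 nt, target amplicons 80-400 bp,
#' acceptable primer Tm 55-65 degC, nearest-neighbor conditions 50 mM
#' monovalent salt and 250 nM primer. `mismatch_offset` is the distance, in
#' bases 5' of the 3'-terminal diagnostic base, at which the artificial
#' destabilizing substitution is written (default 4, i.e. the 5th base from
#' the 3' terminus).
#'
#' @param mismatch_offset integer >= 2 and smaller than the minimum primer
#'   length.
#' @param primer_length_range integer pair, min/max primer length.
#' @param tm_window numeric pair, acceptable primer Tm in degC (designs
#'   outside it are flagged, not rejected).
#' @param annealing_temp_celsius annealing target used to score candidates.
#' @param product_length_range integer pair, min/max amplicon length in bp.
#' @param gc_range numeric pair, acceptable GC fraction for the common
#'   reverse primer.
#' @param monovalent_mM,primer_nM nearest-neighbor model conditions.
#' @param tm_model identifier of the thermodynamic parameter set.
#' @return an object of class `design_params`.
#' @export
design_params <- function(mismatch_offset = 4L,
                          primer_length_range = c(18L, 25L),
                          tm_window = c(55, 65),
                          annealing_temp_celsius = 60,
                          product_length_range = c(80L, 400L),
                          gc_range = c(0.40, 0.60),
                          monovalent_mM = 50,
                          primer_nM = 250,
                          tm_model = "santalucia1998-unified") {
  mismatch_offset <- as.integer(mismatch_offset)
  primer_length_range <- as.integer(primer_length_range)
  stopifnot(length(primer_length_range) == 2L,
            primer_length_range[1L] <= primer_length_range[2L],
            length(product_length_range) == 2L,
            product_length_range[1L] <= product_length_range[2L],
            length(tm_window) == 2L, tm_window[1L] <= tm_window[2L],
            length(gc_range) == 2L, gc_range[1L] <= gc_range[2L],
            monovalent_mM > 0, primer_nM > 0)
  if (mismatch_offset < 2L || mismatch_offset >= primer_length_range[1L])
    stop("mismatch_offset must be >= 2 and smaller than the minimum primer length",
         call. = FALSE)
  structure(list(mismatch_offset = mismatch_offset,
                 primer_length_range = primer_length_range,
                 tm_window = as.numeric(tm_window),
                 annealing_temp_celsius = as.numeric(annealing_temp_celsius),
                 product_length_range = as.integer(product_length_range),
                 gc_range = as.numeric(gc_range),
                 monovalent_mM = as.numeric(monovalent_mM),
                 primer_nM = as.numeric(primer_nM),
                 tm_model = tm_model),
            class = "design_params")
}

#' Write the artificial destabilizing mismatch into a primer core
#'
#' Replaces the base `mismatch_offset` positions 5' of the 3'-terminal
#' diagnostic base (so the 5th base from the 3' end at the default offset 4)
#' by its Watson-Crick complement. Because complementation is an involution,
#' applying the operation twice restores the original core.
#'
#' @param core primer core sequence 5'->3', ending on the diagnostic base.
#' @param params a [design_params()] object.
#' @return the core with the artificial substitution written in.
#' @export
apply_artificial_mismatch <- function(core, params = design_params()) {
  core <- dna(core)
  n <- nchar(core)
  if (n <= params$mismatch_offset)
    stop("design error: core of ", n, " nt too short for mismatch offset ",
         params$mismatch_offset, call. = FALSE)
  idx <- n - params$mismatch_offset          # 5'-based index of the 5th base from 3'
  paste0(substr(core, 1L, idx - 1L),
         complement(substr(core, idx, idx)),
         substr(core, idx + 1L, n))
}

# forward-strand template window a forward primer of the given length covers,
# for the stated allele at the diagnostic position
allele_template_window <- function(locus, allele = c("major", "minor"), length) {
  allele <- match.arg(allele)
  up <- locus$upstream
  n_up <- nchar(up)
  if (length < 2L || n_up < length - 1L)
    stop("design error: upstream context (", n_up,
         " nt) too short for primer length ", length, call. = FALSE)
  base <- if (allele == "major") locus$major_allele else locus$minor_allele
  paste0(substr(up, n_up - (length - 2L), n_up), base)
}

#' Design one allele-specific forward primer
#'
#' The primer is the forward-strand template ending on the diagnostic base of
#' the targeted allele, with the artificial destabilizing substitution
#' written at `params$mismatch_offset` bases 5' of that terminus. Against its
#' own allele the primer therefore carries a single internal mismatch;
#' against the other allele it carries two (3'-terminal diagnostic plus
#' artificial), which is what makes the two-reaction readout discriminating.
#'
#' @param locus a [snp_locus()].
#' @param allele `"major"` or `"minor"`: which allele the primer targets.
#' @param length primer length in nt (within `params$primer_length_range`).
#' @param params a [design_params()] object.
#' @return an object of class `asp_primer` with fields `sequence`,
#'   `target_allele`, `allele` (major/minor label), `diagnostic_offset`
#'   (always 1), `artificial_mismatch_offset`, `template_base`,
#'   `substituted_base`, `melting_temp_celsius`, `tm_within_window` and the
#'   originating `locus`.
#' @export
design_allele_specific_primer <- function(locus, allele = c("major", "minor"),
                                          length, params = design_params()) {
  allele <- match.arg(allele)
  length <- as.integer(length)
  if (length < params$primer_length_range[1L] || length > params$primer_length_range[2L])
    stop("design error: primer length ", length, " outside allowed range [",
         params$primer_length_range[1L], ", ", params$primer_length_range[2L], "]",
         call. = FALSE)
  core <- allele_template_window(locus, allele, length)
  seqn <- apply_artificial_mismatch(core, params)
  idx <- nchar(core) - params$mismatch_offset
  tmpl_base <- substr(core, idx, idx)
  tm <- melting_temperature(seqn, params)
  structure(list(sequence = seqn,
                 target_allele = substr(seqn, length, length),
                 allele = allele,
                 diagnostic_offset = 1L,
                 artificial_mismatch_offset = params$mismatch_offset,
                 template_base = tmpl_base,
                 substituted_base = complement(tmpl_base),
                 melting_temp_celsius = tm,
                 tm_within_window = tm >= params$tm_window[1L] && tm <= params$tm_window[2L],
                 locus = locus),
            class = "asp_primer")
}

#' @export
print.asp_primer <- function(x, ...) {
  cat("allele-specific primer (", x$allele, " allele ", x$target_allele,
      ", ", x$locus$allele_name, ")\n", sep = "")
  cat("  5'-", x$sequence, "-3'  (", nchar(x$sequence), " nt, Tm ",
      sprintf("%.1f", x$melting_temp_celsius), " degC",
      if (!x$tm_within_window) ", outside Tm window" else "", ")\n", sep = "")
  cat("  artificial mismatch: ", x$template_base, "->", x$substituted_base,
      " at ", x$artificial_mismatch_offset, " nt 5' of the diagnostic 3' base\n",
      sep = "")
  invisible(x)
}

# enumerate candidate reverse-primer windows on the forward strand of
# `downstream`; returns a data.frame of survivors plus attrition counts
reverse_candidates <- function(locus, params, forward_length) {
  d <- locus$downstream
  nd <- nchar(d)
  lr <- params$primer_length_range
  grid <- expand.grid(len = seq.int(lr[1L], lr[2L]),
                      end = seq_len(nd), KEEP.OUT.ATTRS = FALSE)
  grid$start <- grid$end - grid$len + 1L
  grid <- grid[grid$start >= 1L, , drop = FALSE]
  dropped <- c(product = 0L, gc = 0L, clamp = 0L)
  prod_len <- forward_length + grid$end
  keep <- prod_len >= params$product_length_range[1L] &
    prod_len <= params$product_length_range[2L]
  dropped[["product"]] <- sum(!keep)
  grid <- grid[keep, , drop = FALSE]
  if (nrow(grid)) {
    win <- substr(rep(d, nrow(grid)), grid$start, grid$end)
    gc <- (nchar(win) - nchar(gsub("[GC]", "", win))) / nchar(win)
    keep <- gc >= params$gc_range[1L] & gc <= params$gc_range[2L]
    dropped[["gc"]] <- sum(!keep)
    grid <- grid[keep, , drop = FALSE]; win <- win[keep]; gc <- gc[keep]
    # GC clamp: the reverse primer's 3'-terminal base pairs with the window
    # start base, which must therefore be G or C
    if (nrow(grid)) {
      keep <- substr(win, 1L, 1L) %in% c("G", "C")
      dropped[["clamp"]] <- sum(!keep)
      grid <- grid[keep, , drop = FALSE]; win <- win[keep]; gc <- gc[keep]
    }
    if (nrow(grid)) {
      grid$window <- win
      grid$gc <- gc
    }
  }
  attr(grid, "dropped") <- dropped
  grid
}

#' Design the common reverse primer
#'
#' Scans forward-strand windows of `locus$downstream`, keeping windows whose
#' implied amplicon length and GC fraction are within bounds and whose
#' reverse primer would end 3' on a G or C (GC clamp), and returns the
#' reverse complement of the window whose Tm is closest to the annealing
#' target. Ties are broken toward the shorter primer, then the smaller
#' amplicon, so the design is deterministic.
#'
#' @param locus a [snp_locus()].
#' @param params a [design_params()] object.
#' @param forward_length forward-primer length used to compute amplicon
#'   lengths; defaults to the longest length the upstream context supports.
#' @return an object of class `reverse_primer`: `sequence` (5'->3' on the
#'   reverse strand), `strand`, `melting_temp_celsius`, `gc_fraction`,
#'   `window_start`/`window_end` (1-based in `downstream`) and
#'   `product_length_bp`.
#' @export
design_common_reverse_primer <- function(locus, params = design_params(),
                                         forward_length = NULL) {
  if (is.null(forward_length))
    forward_length <- min(params$primer_length_range[2L], nchar(locus$upstream) + 1L)
  cand <- reverse_candidates(locus, params, forward_length)
  if (!nrow(cand)) {
    drp <- attr(cand, "dropped")
    stop("design error: no reverse-primer window satisfies the constraints ",
         "(rejected by product length: ", drp[["product"]],
         ", GC bounds: ", drp[["gc"]], ", GC clamp: ", drp[["clamp"]], ")",
         call. = FALSE)
  }
  cand$tm <- vapply(cand$window, melting_temperature, numeric(1L),
                    params = params, USE.NAMES = FALSE)
  cand$score <- abs(cand$tm - params$annealing_temp_celsius)
  best <- cand[order(cand$score, cand$len, cand$end), , drop = FALSE][1L, ]
  structure(list(sequence = reverse_complement(best$window),
                 strand = "reverse",
                 melting_temp_celsius = best$tm,
                 gc_fraction = best$gc,
                 window_start = best$start,
                 window_end = best$end,
                 product_length_bp = forward_length + best$end),
            class = "reverse_primer")
}

#' Check a reverse primer against a locus
#'
#' Accepts a candidate common reverse primer if its reverse complement occurs
#' as a window of the locus downstream sequence satisfying the same length,
#' amplicon, GC and clamp constraints used by [design_common_reverse_primer()].
#'
#' @inheritParams design_common_reverse_primer
#' @param primer_seq candidate reverse primer 5'->3'.
#' @return `TRUE` or `FALSE`; when `FALSE`, attribute `"reason"` explains.
#' @export
is_valid_reverse_primer <- function(locus, primer_seq, params = design_params(),
                                    forward_length = NULL) {
  if (is.null(forward_length))
    forward_length <- min(params$primer_length_range[2L], nchar(locus$upstream) + 1L)
  primer_seq <- dna(primer_seq)
  fail <- function(why) structure(FALSE, reason = why)
  n <- nchar(primer_seq)
  if (n < params$primer_length_range[1L] || n > params$primer_length_range[2L])
    return(fail("length outside primer_length_range"))
  window <- reverse_complement(primer_seq)
  hit <- regexpr(window, locus$downstream, fixed = TRUE)
  if (hit < 0L) return(fail("binding site not found in downstream sequence"))
  end <- as.integer(hit) + n - 1L
  prod <- forward_length + end
  if (prod < params$product_length_range[1L] || prod > params$product_length_range[2L])
    return(fail("amplicon length outside product_length_range"))
  gc <- gc_fraction(window)
  if (gc < params$gc_range[1L] || gc > params$gc_range[2L])
    return(fail("GC fraction outside gc_range"))
  if (!substr(window, 1L, 1L) %in% c("G", "C"))
    return(fail("no GC clamp at the reverse primer 3' end"))
  TRUE
}

#' Design a complete two-reaction allele-specific PCR assay
#'
#' Chooses a single forward-primer length (feasible under the upstream
#' context, scored by mean closeness of both allele-specific primer Tms to
#' the annealing target), designs both allele-specific forward primers and
#' the common reverse primer, and fills in the standard cycling conditions
#' (94/60/72 degC, 30 s each, 35 cycles). The two forward primers differ
#' only at the 3'-terminal diagnostic base and share the artificial
#' substitution, so both parallel reactions yield the same product length.
#'
#' @param locus a [snp_locus()].
#' @param params a [design_params()] object.
#' @return an object of class `asp_assay` with fields `locus`,
#'   `primer_major`, `primer_minor`, `common_reverse`, `product_length_bp`
#'   and `cycling`.
#' @export
design_assay <- function(locus, params = design_params()) {
  lr <- params$primer_length_range
  max_len <- min(lr[2L], nchar(locus$upstream) + 1L)
  if (max_len < lr[1L])
    stop("design error: upstream context (", nchar(locus$upstream),
         " nt) too short for the minimum primer length ", lr[1L], call. = FALSE)
  lens <- seq.int(lr[1L], max_len)
  score <- vapply(lens, function(L) {
    tms <- c(melting_temperature(apply_artificial_mismatch(
               allele_template_window(locus, "major", L), params), params),
             melting_temperature(apply_artificial_mismatch(
               allele_template_window(locus, "minor", L), params), params))
    mean(abs(tms - params$annealing_temp_celsius))
  }, numeric(1L))
  L <- lens[order(score, lens)][1L]
  maj <- design_allele_specific_primer(locus, "major", L, params)
  mnr <- design_allele_specific_primer(locus, "minor", L, params)
  stopifnot(substr(maj$sequence, 1L, L - 1L) == substr(mnr$sequence, 1L, L - 1L),
            maj$target_allele != mnr$target_allele)
  rev <- design_common_reverse_primer(locus, params, forward_length = L)
  structure(list(locus = locus,
                 primer_major = maj,
                 primer_minor = mnr,
                 common_reverse = rev,
                 product_length_bp = rev$product_length_bp,
                 cycling = list(denature_celsius = 94, anneal_celsius = 60,
                                extend_celsius = 72, step_seconds = 30,
                                cycles = 35)),
            class = "asp_assay")
}

#' @export
print.asp_assay <- function(x, ...) {
  cat("allele-specific PCR assay for ", x$locus$allele_name, " (",
      x$locus$rsid, ")\n", sep = "")
  cat("  forward (major ", x$primer_major$target_allele, "): 5'-",
      x$primer_major$sequence, "-3'\n", sep = "")
  cat("  forward (minor ", x$primer_minor$target_allele, "): 5'-",
      x$primer_minor$sequence, "-3'\n", sep = "")
  cat("  common reverse:      5'-", x$common_reverse$sequence, "-3'\n", sep = "")
  cat("  product: ", x$product_length_bp, " bp; cycling ",
      x$cycling$denature_celsius, "/", x$cycling$anneal_celsius, "/",
      x$cycling$extend_celsius, " degC x ", x$cycling$cycles, " cycles\n", sep = "")
  invisible(x)
}
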