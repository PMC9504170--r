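#' Validate a DNA sequence
#'
#' Normalizes a nucleotide string to uppercase and checks that it is a
#' non-empty string over the strict DNA alphabet A/C/G/T. IUPAC ambiguity
#' codes and RNA (U) are rejected: every downstream design rule assumes an
#' unambiguous template strand.
#'
#' @param x character scalar, bases written 5'->3'. Lowercase accepted.
#' @return the validated uppercase sequence string.
#' @export
dna <- function(x) {
  if (!is.character(x) || length(x) != 1L || is.na(x))
    stop("sequence must be a single character string", call. = FALSE)
  x <- toupper(x)
  if (!nzchar(x)) stop("sequence must be non-empty", call. = FALSE)
  bad <- gsub("[ACGT]", "", x)
  if (nzchar(bad))
    stop("invalid nucleotide(s) '", bad,
         "': only A/C/G/T allowed (DNA only, no IUPAC ambiguity codes)",
         call. = FALSE)
  x
}

#' Watson-Crick complement of single bases
#'
#' @param base character vector of single nucleotides in A/C/G/T.
#' @return complementary base(s); involutive.
#' @export
complement <- function(base) {
  if (length(base) == 0L) stop("no base supplied", call. = FALSE)
  base <- toupper(base)
  if (any(is.na(base)) || any(nchar(base) != 1L) || any(!base %in% c("A", "C", "G", "T")))
    stop("complement() takes single nucleotides in {A,C,G,T}", call. = FALSE)
  chartr("ACGT", "TGCA", base)
}

#' Reverse complement
#'
#' Opposite strand read 5'->3'. Wraps Biostrings.
#'
#' @param seq DNA sequence string (validated with [dna()]).
#' @return reverse-complemented sequence string.
#' @export
reverse_complement <- function(seq) {
  seq <- dna(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Per-position mismatch profile between a primer and its template window
#'
#' Compares two equal-length sequences position by position, anchored at the
#' 3' end of the primer. Offsets are reported 1-based from the 3' terminus
#' (position 1 = the 3'-terminal primer base, where the diagnostic allele
#' base sits in an allele-specific primer).
#'
#' @param primer primer sequence 5'->3'.
#' @param template_window the same-strand template window the primer covers,
#'   aligned at the 3' end, equal length.
#' @return an object of class `mismatch_profile`: list with `total` (count of
#'   mismatching positions) and `positions_from_3prime` (sorted integer
#'   offsets).
#' @export
mismatch_profile <- function(primer, template_window) {
  primer <- dna(primer)
  template_window <- dna(template_window)
  n <- nchar(primer)
  if (n != nchar(template_window))
    stop("alignment error: primer (", n, " nt) and template window (",
         nchar(template_window), " nt) must have equal length", call. = FALSE)
  p <- strsplit(primer, "", fixed = TRUE)[[1L]]
  t <- strsplit(template_window, "", fixed = TRUE)[[1L]]
  mm <- which(p != t)               # 5'-based indices
  pos3 <- sort(n - mm + 1L)         # 1 = 3'-terminal base
  structure(list(total = length(pos3), positions_from_3prime = pos3),
            class = "mismatch_profile")
}

#' @export
print.mismatch_profile <- function(x, ...) {
  cat("mismatch profile:", x$total, "mismatch(es)")
  if (x$total > 0L)
    cat(" at 3'-offset(s) ", paste(x$positions_from_3prime, collapse = ", "), sep = "")
  cat("\n")
  invisible(x)
}
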