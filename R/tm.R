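# Nearest-neighbor duplex thermodynamics, unified DNA parameter set
# (SantaLucia 1998 / Allawi & SantaLucia 1997). dH in kcal/mol, dS in
# cal/(K*mol), per 5'->3' dinucleotide stack on the top strand.
.nn_dH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
            CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
            CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
            CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
.nn_dS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
            CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
            CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
            CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)
# duplex initiation, per terminus
.init_dH <- c(G = 0.1, C = 0.1, A = 2.3, T = 2.3)
.init_dS <- c(G = -2.8, C = -2.8, A = 4.1, T = 4.1)

#' Primer melting temperature
#'
#' Nearest-neighbor thermodynamic estimate of the duplex melting temperature
#' using the unified DNA parameter set, with entropy corrected for monovalent
#' salt (0.368 * (N-1) * ln\[Na+\] per SantaLucia 1998) and the primer assumed
#' in excess over template. A simple additive rule (2 degC per A/T plus
#' 4 degC per G/C, the Wallace rule) is selectable for very short
#' oligonucleotides where the nearest-neighbor model is not meaningful.
#'
#' @param seq primer sequence 5'->3'.
#' @param params a [design_params()] object supplying `monovalent_mM` and
#'   `primer_nM`; defaults used when omitted.
#' @param method `"nearest-neighbor"` (default, requires length >= 8) or
#'   `"wallace"` (any length).
#' @return melting temperature in degrees Celsius.
#' @export
melting_temperature <- function(seq, params = design_params(),
                                method = c("nearest-neighbor", "wallace")) {
  seq <- dna(seq)
  method <- match.arg(method)
  n <- nchar(seq)
  b <- strsplit(seq, "", fixed = TRUE)[[1L]]
  if (method == "wallace") {
    return(2 * sum(b %in% c("A", "T")) + 4 * sum(b %in% c("G", "C")))
  }
  if (n < 8L)
    stop("nearest-neighbor model needs length >= 8 (got ", n,
         "); use method = \"wallace\"", call. = FALSE)
  stacks <- paste0(b[-n], b[-1L])
  dH <- sum(.nn_dH[stacks]) + .init_dH[[b[1L]]] + .init_dH[[b[n]]]
  dS <- sum(.nn_dS[stacks]) + .init_dS[[b[1L]]] + .init_dS[[b[n]]]
  selfcomp <- n %% 2L == 0L &&
    identical(b, rev(chartr("ACGT", "TGCA", b)))
  if (selfcomp) dS <- dS - 1.4  # self-complementary duplex symmetry
  dS <- dS + 0.368 * (n - 1L) * log(params$monovalent_mM / 1000)
  ct <- params$primer_nM * 1e-9
  1000 * dH / (dS + 1.987 * log(ct)) - 273.15
}

gc_fraction <- function(seq) {
  seq <- dna(seq)
  (nchar(seq) - nchar(gsub("[GC]", "", seq))) / nchar(seq)
}
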