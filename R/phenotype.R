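PHENOTYPES <- c("ultra-rapid", "rapid", "normal", "likely-intermediate",
                "intermediate", "likely-poor", "poor", "indeterminate")

#' The CYP2C19 allele-function registry
#'
#' Star alleles and their function classes (normal, decreased, none,
#' increased, uncertain) are shipped as a YAML data file so additional
#' alleles can be registered without code changes. Defaults: *1 normal,
#' *2/*3 no function, *9 decreased, *17 increased, *12/*14 uncertain.
#'
#' @param path optional path to an alternative registry YAML file.
#' @return named character vector mapping star allele to function class.
#' @export
allele_registry <- function(path = NULL) {
  if (is.null(path)) {
    if (is.null(.pkg_env$registry)) {
      reg <- yaml::read_yaml(pkg_extdata("allele_function.yaml"))
      .pkg_env$registry <- unlist(reg$alleles)
    }
    return(.pkg_env$registry)
  }
  unlist(yaml::read_yaml(path)$alleles)
}

#' Function class of a star allele
#'
#' @param star_allele star-allele name, e.g. `"*17"`.
#' @return list with `star_allele` and `function_class`.
#' @export
allele_function <- function(star_allele) {
  reg <- allele_registry()
  if (!star_allele %in% names(reg))
    stop("unknown star allele \"", star_allele, "\"; registry knows ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  list(star_allele = star_allele, function_class = unname(reg[[star_allele]]))
}

# phenotype from an unordered pair of function classes; rule strings name
# the allele-function combination that fired
.phenotype_rule <- function(classes) {
  cl <- sort(classes)
  if ("uncertain" %in% cl)
    return(c("indeterminate", "one or two uncertain function alleles"))
  key <- paste(cl, collapse = "+")
  rules <- c(
    "increased+increased" = "ultra-rapid|two increased function alleles",
    "increased+normal"    = "rapid|one normal function allele and one increased function allele",
    "normal+normal"       = "normal|two normal function alleles",
    "decreased+normal"    = "likely-intermediate|one normal function allele and one decreased function allele",
    "decreased+increased" = "likely-intermediate|one increased function allele and one decreased function allele",
    "decreased+decreased" = "likely-intermediate|two decreased function alleles",
    "none+normal"         = "intermediate|one normal function allele and one no function allele",
    "increased+none"      = "intermediate|one increased function allele and one no function allele",
    "decreased+none"      = "likely-poor|one decreased function allele and one no function allele",
    "none+none"           = "poor|two no function alleles")
  if (!key %in% names(rules))
    stop("no phenotype rule for function-class pair ", key, call. = FALSE)
  strsplit(rules[[key]], "|", fixed = TRUE)[[1L]]
}

#' Translate a diplotype into a predicted metabolizer phenotype
#'
#' Applies the standard genotype-to-phenotype rules on the unordered pair of
#' allele function classes: two increased-function alleles give an
#' ultra-rapid metabolizer, two no-function alleles a poor metabolizer, and
#' so on; any uncertain-function allele makes the call indeterminate. The
#' mapping is total over the registry and symmetric in the two alleles.
#'
#' @param d a [diplotype()] or a diplotype string such as `"*2/*17"`.
#' @return an object of class `phenotype_call`: `phenotype`, the `rule` that
#'   fired, and the formatted `diplotype`.
#' @export
diplotype_to_phenotype <- function(d) {
  if (is.character(d)) d <- parse_diplotype(d)
  classes <- vapply(d$alleles, function(a) allele_function(a)$function_class,
                    character(1L))
  hit <- .phenotype_rule(classes)
  structure(list(phenotype = hit[[1L]], rule = hit[[2L]], diplotype = format(d)),
            class = "phenotype_call")
}

#' @export
print.phenotype_call <- function(x, ...) {
  cat("CYP2C19 ", x$phenotype, " metabolizer (", x$diplotype, ": ",
      x$rule, ")\n", sep = "")
  invisible(x)
}

#' Full diplotype-to-phenotype mapping over the registry
#'
#' Enumerates every unordered pair of registry alleles (n(n+1)/2 pairs; 28
#' for the default 7-allele registry) with its predicted phenotype and the
#' rule applied. Useful as a QC dump of the rule engine.
#'
#' @return data frame with columns `diplotype`, `phenotype`, `rule`.
#' @export
phenotype_table <- function() {
  reg <- names(allele_registry())
  pairs <- which(upper.tri(diag(length(reg)), diag = TRUE), arr.ind = TRUE)
  rows <- apply(pairs, 1L, function(ij) {
    d <- diplotype(reg[ij[[1L]]], reg[ij[[2L]]])
    p <- diplotype_to_phenotype(d)
    data.frame(diplotype = format(d), phenotype = p$phenotype, rule = p$rule,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$diplotype), , drop = FALSE]
}
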