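# Amino-acid vocabulary shared across the package.
#
# AAINDEX_ORDER is the canonical residue order of the AAindex flat-file
# format (A/R/N/D/C/Q/E/G/H/I/L/K/M/F/P/S/T/W/Y/V); every internal value
# vector is stored in this order.

AAINDEX_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                   "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

AA_THREE_TO_ONE <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C",
  Gln = "Q", Glu = "E", Gly = "G", His = "H", Ile = "I",
  Leu = "L", Lys = "K", Met = "M", Phe = "F", Pro = "P",
  Ser = "S", Thr = "T", Trp = "W", Tyr = "Y", Val = "V")

#' Normalize residue codes to one-letter form
#'
#' Accepts one-letter codes (any case) or three-letter codes such as
#' `"Cys"`. Codes outside the 20 standard amino acids are returned
#' uppercased but unmapped, so callers can detect and reject them.
#'
#' @param x character vector of residue codes.
#' @return character vector of uppercase one-letter codes.
#' @keywords internal
aa_one <- function(x) {
  x <- as.character(x)
  three <- AA_THREE_TO_ONE[sub("^(\\w)(\\w\\w)$", "\\U\\1\\L\\2", x, perl = TRUE)]
  out <- ifelse(nchar(x) == 3 & !is.na(three), three, toupper(x))
  unname(out)
}

is_standard_aa <- function(x) x %in% AAINDEX_ORDER

stop_nonstandard <- function(x, context) {
  bad <- unique(x[!is_standard_aa(x)])
  if (length(bad)) {
    stop(sprintf(
      "non-standard residue code(s) %s in %s; the method is defined only over the 20 standard amino acids -- filter replacements first",
      paste(sQuote(bad), collapse = ", "), context), call. = FALSE)
  }
  invisible(x)
}
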