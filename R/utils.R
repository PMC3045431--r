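#' @keywords internal
"_PACKAGE"

BASES <- c("A", "C", "G", "T")

# the 12 ordered ref->alt substitution types
SUBST_TYPES <- {
  g <- expand.grid(alt = BASES, ref = BASES, stringsAsFactors = FALSE)
  g <- g[g$ref != g$alt, c("ref", "alt")]
  rownames(g) <- NULL
  g
}

#' Round half away from zero
#'
#' Standard commercial rounding: ties go away from zero, so 7.5 -> 8 and
#' -7.5 -> -8, unlike [base::round()]'s round-half-even. Used wherever an
#' allele count is reconstructed from a frequency.
#'
#' @param x numeric vector.
#' @return integer-valued numeric vector.
#' @export
round_half_away <- function(x) {
  sign(x) * floor(abs(x) + 0.5)
}

subst_label <- function(ref, alt) paste0(ref, ">", alt)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_ps <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
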