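# Internal helpers shared across modules.

`%||%` <- function(x, y) if (is.null(x)) y else x

px_abort <- function(message, class, ...) {
  rlang::abort(message, class = c(paste0("plastex_error_", class), "plastex_error"), ...)
}

px_warn <- function(message, class) {
  rlang::warn(message, class = c(paste0("plastex_warning_", class), "plastex_warning"))
}

#' Reverse complement of a nucleotide string
#'
#' Operates on plain character vectors over the alphabet `{A,C,G,T,N}`.
#'
#' @param x Character vector of nucleotide strings.
#' @return Character vector of the same length.
#' @export
revcomp <- function(x) {
  vapply(strsplit(chartr("ACGTacgt", "TGCAtgca", x), ""),
         function(v) paste(rev(v), collapse = ""), character(1),
         USE.NAMES = FALSE)
}

# complement without reversal
comp <- function(x) {
  chartr("ACGTacgt", "TGCAtgca", x)
}

rev_string <- function(x) {
  vapply(strsplit(x, ""), function(ch) paste(rev(ch), collapse = ""), character(1))
}

# DNA -> RNA reporting alphabet
to_rna <- function(x) chartr("Tt", "Uu", x)
to_dna <- function(x) chartr("Uu", "Tt", x)

check_alphabet <- function(seq, what = "sequence") {
  if (grepl("[^ACGTN]", seq)) {
    px_abort(sprintf("%s contains letters outside {A,C,G,T,N}", what), "bad_alphabet")
  }
  invisible(seq)
}

# 1-based inclusive substring on a circular sequence; start may exceed end
# only through explicit wrap = TRUE extraction of [start, start + width - 1].
circ_substr <- function(seq, start, width) {
  n <- nchar(seq)
  stopifnot(width <= n)
  end <- start + width - 1L
  if (end <= n) {
    substr(seq, start, end)
  } else {
    paste0(substr(seq, start, n), substr(seq, 1L, end - n))
  }
}

# deterministic RNG scope; all generator entry points funnel through this
with_seed <- function(seed, code) {
  withr::with_seed(as.integer(seed), code)
}

amino_acid_3letter <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln", E = "Glu",
  G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys", M = "Met", F = "Phe",
  P = "Pro", S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val", `*` = "stop"
)

# plastid genetic code (NCBI translation table 11), keyed by DNA codon
plastid_code <- function() {
  Biostrings::getGeneticCode("11")
}

#' Translate a DNA codon under the plastid genetic code
#'
#' Uses NCBI translation table 11 (bacterial/archaeal/plant plastid). Stop
#' codons are reported as `"stop"`; codons containing N return `NA`.
#'
#' @param codon Character vector of 3-letter DNA (or RNA) codons.
#' @return Character vector of three-letter amino-acid codes or `"stop"`.
#' @export
translate_codon <- function(codon) {
  codon <- to_dna(toupper(codon))
  code <- plastid_code()
  aa1 <- unname(code[codon])
  out <- unname(amino_acid_3letter[aa1])
  out[is.na(aa1)] <- NA_character_
  out
}
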