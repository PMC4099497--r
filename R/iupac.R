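# IUPAC nucleotide alphabet: code -> base set, and helpers shared by the
# design, consensus and identity machinery.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_CODES <- names(IUPAC_SETS)

# reverse lookup: sorted base set (collapsed) -> code
IUPAC_FROM_SET <- local({
  keys <- vapply(IUPAC_SETS, function(s) paste(sort(s), collapse = ""), "")
  stats::setNames(names(IUPAC_SETS), keys)
})

iupac_code_for <- function(bases) {
  bases <- sort(unique(toupper(bases)))
  key <- paste(bases, collapse = "")
  code <- IUPAC_FROM_SET[[key]]
  if (is.null(code)) {
    stop("no IUPAC code covers base set {", paste(bases, collapse = ","), "}")
  }
  code
}

iupac_degeneracy <- function(code) {
  vapply(strsplit(code, "")[[1]], function(s) length(IUPAC_SETS[[s]]), 0L)
}

# TRUE when the base sets of two symbols overlap; gaps are compatible with
# nothing, including other gaps.
iupac_compatible <- function(a, b) {
  sa <- IUPAC_SETS[[a]]
  sb <- IUPAC_SETS[[b]]
  if (is.null(sa) || is.null(sb)) return(FALSE)
  length(intersect(sa, sb)) > 0L
}

GAP_CHARS <- c("-", ".")

#' Reverse-complement a nucleotide sequence with IUPAC ambiguity codes
#'
#' Complements every IUPAC symbol (e.g. `R` to `Y`, `N` to `N`) and reverses
#' the sequence; gap characters are preserved.
#'
#' @param x character vector of sequences.
#' @return character vector of reverse-complemented sequences.
#' @examples
#' revcomp_iupac("ACGTRN-")
#' @export
revcomp_iupac <- function(x) {
  comp <- chartr("ACGTRYSWKMBDHVNacgtryswkmbdhvn",
                 "TGCAYRSWMKVHDBNtgcayrswmkvhdbn", x)
  vapply(strsplit(comp, ""), function(s) paste(rev(s), collapse = ""), "")
}

valid_alphabet <- function(seqs) {
  bad <- grepl(paste0("[^", paste(IUPAC_CODES, collapse = ""), ".-]"),
               toupper(seqs))
  !bad
}
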