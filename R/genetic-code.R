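#' The standard genetic code as a codon table
#'
#' Returns one row per codon of the standard genetic code, with the amino acid
#' it encodes, its synonymous-family membership and the family degeneracy
#' `k`. Leucine, serine and arginine are treated as single six-fold families
#' (not split by first-base block), isoleucine is the only three-fold family,
#' and the three termination codons form a `k = 3` family labelled `"Ter"`.
#' Methionine and tryptophan are the two single-codon families.
#'
#' The 59 *informative* codons are the sense codons excluding ATG and TGG:
#' these are the codons over which RSCU, CAI and the correspondence analysis
#' are defined.
#'
#' @return A tibble with columns `codon` (DNA alphabet, alphabetical),
#'   `amino_acid` (three-letter name, `"Ter"` for stops), `aa1` (one-letter
#'   code, `"*"` for stops), `k` (family degeneracy), `third` (third-position
#'   base) and `informative` (logical).
#' @examples
#' codon_table()
#' dplyr::count(codon_table(), k)
#' @export
codon_table <- function() {
  .codonbias_env$codon_table
}

.codonbias_env <- new.env(parent = emptyenv())

.aa3 <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
  E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
  M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
  Y = "Tyr", V = "Val", `*` = "Ter"
)

.build_codon_table <- function() {
  code <- Biostrings::GENETIC_CODE
  codon <- sort(names(code))
  aa1 <- unname(code[codon])
  k <- table(aa1)[aa1]
  tibble::tibble(
    codon = codon,
    amino_acid = unname(.aa3[aa1]),
    aa1 = aa1,
    k = as.integer(k),
    third = substr(codon, 3, 3),
    informative = aa1 != "*" & !codon %in% c("ATG", "TGG")
  )
}

.onLoad <- function(libname, pkgname) {
  .codonbias_env$codon_table <- .build_codon_table()
}

# Stop codons of the standard code.
STOP_CODONS <- c("TAA", "TAG", "TGA")

# The 64 codons in alphabetical order (column order of all count tables).
all_codons <- function() codon_table()$codon

#' Informative (sense, non-ATG/TGG) codons
#'
#' @return Character vector of the 59 codons used for RSCU/CAI/COA.
#' @export
informative_codons <- function() {
  ct <- codon_table()
  ct$codon[ct$informative]
}

# Codons belonging to fourfold-degenerate third-position quartets
# (Sueoka's PR2 convention): the eight blocks CTN, GTN, TCN, CCN, ACN,
# GCN, CGN, GGN in which all four third bases encode the same amino acid.
fourfold_codons <- function() {
  ct <- codon_table()
  quartet <- substr(ct$codon, 1, 2)
  full <- vapply(
    split(ct$aa1, quartet),
    function(a) length(a) == 4L && length(unique(a)) == 1L && a[1] != "*",
    logical(1)
  )
  ct$codon[full[quartet]]
}
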