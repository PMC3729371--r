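# Wright's effective number of codons (Nc).

#' Effective number of codons (Wright's Nc)
#'
#' Estimates codon usage bias as
#' \deqn{Nc = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6}
#' where \eqn{\bar F_k} averages the codon homozygosity
#' \eqn{F = (n \sum \hat p_i^2 - 1) / (n - 1)} over the amino acids of
#' synonymous degeneracy \eqn{k} (standard genetic code).  Methionine,
#' tryptophan and stop codons are excluded; amino acids observed fewer than
#' twice, or with non-positive \eqn{F}, do not enter the class average.  If
#' the threefold class (isoleucine) is unobserved its homozygosity is
#' interpolated as the mean of \eqn{\bar F_2} and \eqn{\bar F_4}.  The
#' result is clamped to the theoretical maximum of 61 (uniform usage); the
#' minimum of 20 corresponds to exactly one codon per amino acid.
#'
#' @param cds a nucleotide sequence: single string, character vector of
#'   codons, or a \code{Biostrings::DNAString}.  Trailing bases beyond a
#'   codon multiple are trimmed; codons with ambiguous bases are skipped.
#' @return Nc in [20, 61], or \code{NA_real_} if no class is scorable.
#' @export
#' @examples
#' effectiveNumberOfCodons(strrep("TTTTTC", 30))  # 2-fold aa only
effectiveNumberOfCodons <- function(cds) {
  codons <- asCodons(cds)
  codons <- codons[grepl("^[ACGT]{3}$", codons)]
  if (!length(codons)) return(NA_real_)

  gc <- Biostrings::GENETIC_CODE
  aaOf <- gc[codons]
  keep <- !(aaOf %in% c("*", "M", "W"))
  codons <- codons[keep]; aaOf <- aaOf[keep]
  if (!length(codons)) return(NA_real_)

  degeneracy <- table(gc[gc != "*"])
  degeneracy <- degeneracy[!names(degeneracy) %in% c("M", "W")]

  Fhat <- vapply(names(degeneracy), function(aa) {
    cnt <- table(codons[aaOf == aa])
    n <- sum(cnt)
    if (n < 2L) return(NA_real_)
    p <- as.numeric(cnt) / n
    (n * sum(p^2) - 1) / (n - 1)
  }, numeric(1))

  classMean <- function(k) {
    f <- Fhat[degeneracy == k]
    f <- f[!is.na(f) & f > 0]
    if (length(f)) mean(f) else NA_real_
  }
  F2 <- classMean(2); F3 <- classMean(3); F4 <- classMean(4); F6 <- classMean(6)
  if (is.na(F3) && !is.na(F2) && !is.na(F4)) F3 <- (F2 + F4) / 2
  if (anyNA(c(F2, F3, F4, F6))) return(NA_real_)
  min(61, 2 + 9 / F2 + 1 / F3 + 5 / F4 + 3 / F6)
}

asCodons <- function(cds) {
  if (inherits(cds, "DNAString") || inherits(cds, "RNAString"))
    cds <- as.character(cds)
  if (length(cds) > 1L) {
    codons <- toupper(cds)
  } else {
    s <- toupper(gsub("\\s", "", cds))
    s <- chartr("U", "T", s)
    n <- nchar(s) %/% 3L
    if (!n) return(character(0))
    codons <- substring(s, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  }
  chartr("U", "T", codons)
}
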