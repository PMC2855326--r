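#' Reverse complement of k-mer strings
#'
#' @param x character vector of DNA words (A/C/G/T/N, case-insensitive).
#' @return character vector of reverse complements, upper case.
#' @export
revcomp_kmer <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(toupper(x))))
}

#' Canonical representative of a motif class
#'
#' On double-stranded DNA a word and its reverse complement describe the same
#' binding site, so k-mers are collapsed into classes \{word, revcomp(word)\}.
#' The canonical representative is the lexicographically smaller member.
#'
#' @param x character vector of DNA words.
#' @return character vector of canonical words (same length as `x`).
#' @examples
#' canonical_motif("TAATC")  # "GATTA"
#' @export
canonical_motif <- function(x) {
  x <- toupper(x)
  rc <- revcomp_kmer(x)
  ifelse(x <= rc, x, rc)
}

#' Both members of a motif class
#'
#' @param canonical a single canonical word.
#' @return character vector of the distinct class members (length 1 for a
#'   palindrome, 2 otherwise).
#' @export
motif_class_members <- function(canonical) {
  canonical <- toupper(canonical)
  unique(c(canonical, revcomp_kmer(canonical)))
}

.all_kmers <- function(k) {
  stopifnot(length(k) == 1L, k >= 1)
  do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), k),
                              stringsAsFactors = FALSE))
}

# memoised word -> canonical lookup used by the scanner
.canon_cache <- new.env(parent = emptyenv())
.canon_table <- function(k) {
  key <- as.character(k)
  if (is.null(.canon_cache[[key]])) {
    words <- .all_kmers(k)
    .canon_cache[[key]] <- structure(canonical_motif(words), names = words)
  }
  .canon_cache[[key]]
}

#' Enumerate all canonical k-mer classes
#'
#' Every k-mer over \{A,C,G,T\} belongs to exactly one returned class. For odd
#' k no word is its own reverse complement, so the count is 4^k / 2
#' (512 classes for pentamers).
#'
#' @param k word length (>= 1).
#' @return sorted character vector of canonical words.
#' @export
enumerate_motif_classes <- function(k) {
  stopifnot(length(k) == 1L, k >= 1)
  sort(unique(unname(.canon_table(k))))
}
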