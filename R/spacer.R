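#' Read a forbidden k-mer set
#'
#' Loads a TSV of k-mers with binding enrichment scores (e.g. per-octamer
#' protein-binding-microarray scores), keeps those above the threshold, and
#' closes the set under reverse complement so that a single forward-strand
#' window check covers both strands.
#'
#' @param path TSV with header columns `kmer`, `score`.
#' @param score_threshold keep k-mers with score strictly above this value
#'   (default 0.3).
#' @return list of class `forbidden_kmers` with `k`, `entries` (upper-case,
#'   closed under reverse complement) and `score_threshold`.
#' @export
read_forbidden_kmers <- function(path, score_threshold = 0.3) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stopifnot(all(c("kmer", "score") %in% names(df)))
  forbidden_kmers(df$kmer[df$score > score_threshold],
                  score_threshold = score_threshold)
}

#' @rdname read_forbidden_kmers
#' @param entries character vector of forbidden k-mers (all one length).
#' @export
forbidden_kmers <- function(entries, score_threshold = 0.3) {
  entries <- toupper(entries)
  if (length(entries) > 0L) {
    stopifnot(all(grepl("^[ACGT]+$", entries)),
              length(unique(nchar(entries))) == 1L)
    entries <- sort(unique(c(entries, revcomp_kmer(entries))))
  }
  structure(list(k = if (length(entries) > 0L) nchar(entries[1]) else NA_integer_,
                 entries = entries, score_threshold = score_threshold),
            class = "forbidden_kmers")
}

#' Design a spacer sequence avoiding a forbidden k-mer set
#'
#' Grows the sequence one base at a time, extending with a seeded uniform
#' shuffle of \{A,C,G,T\} at each position and backtracking one base whenever
#' the newest k-length window (on either strand; the set is closed under
#' reverse complement) is forbidden. The search gives up after `max_visits`
#' node visits.
#'
#' @param length target sequence length in bp (>= 1).
#' @param forbidden a [forbidden_kmers()] set (possibly empty).
#' @param seed RNG seed; the design is deterministic given the seed.
#' @param max_visits backtracking budget (default 1e6 node visits).
#' @return a sequence string of exactly `length` bases with no forbidden
#'   window, or an error if the constraint is unsatisfiable within budget.
#' @export
design_spacer <- function(length, forbidden = forbidden_kmers(character(0)),
                          seed = 1, max_visits = 1e6) {
  stopifnot(length >= 1, inherits(forbidden, "forbidden_kmers"))
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  k <- forbidden$k
  bad <- forbidden$entries
  seqv <- character(length)
  options <- vector("list", length)
  tried <- integer(length)
  pos <- 1L
  options[[1L]] <- sample(bases)
  tried[1L] <- 0L
  visits <- 0L
  while (pos >= 1L) {
    visits <- visits + 1L
    if (visits > max_visits)
      stop("spacer design unsatisfiable: backtracking budget exhausted")
    if (tried[pos] >= 4L) {
      pos <- pos - 1L
      if (pos == 0L)
        stop("spacer design unsatisfiable: forbidden set blocks every extension")
      next
    }
    tried[pos] <- tried[pos] + 1L
    seqv[pos] <- options[[pos]][tried[pos]]
    if (!is.na(k) && pos >= k &&
        paste(seqv[(pos - k + 1L):pos], collapse = "") %in% bad)
      next
    if (pos == length)
      return(paste(seqv, collapse = ""))
    pos <- pos + 1L
    options[[pos]] <- sample(bases)
    tried[pos] <- 0L
  }
  stop("spacer design unsatisfiable: forbidden set blocks every extension")
}
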