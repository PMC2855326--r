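# per-element window decomposition shared by the scanners
.element_windows <- function(seq, mask, k) {
  L <- nchar(seq)
  if (L < k) {
    return(list(starts = integer(0), words = character(0),
                conserved = logical(0)))
  }
  starts <- seq_len(L - k + 1L)
  words <- substring(toupper(seq), starts, starts + k - 1L)
  conserved <- if (is.null(mask)) {
    rep(TRUE, length(starts))
  } else {
    cs <- c(0, cumsum(mask))
    (cs[starts + k] - cs[starts]) == k
  }
  list(starts = starts, words = words, conserved = conserved)
}

#' Find occurrences of a motif class in CNEs
#'
#' Scans the forward strand of each element for either member of the motif
#' class (so matches on both strands are reported at their forward-strand
#' offset). Offsets are 1-based starts within the element.
#'
#' @param cnes `GRanges` of CNEs with `cne_id`, `seq`, `mask` columns.
#' @param motif a word of the class to search (canonicalised internally).
#' @param require_conserved if `TRUE` (default) an occurrence counts only when
#'   all k mask positions under it are conserved.
#' @return data.frame with columns `cne_id`, `offset`, `word` (the class
#'   member matched at that offset), `conserved`; offsets ascending per CNE.
#' @export
find_motif_occurrences <- function(cnes, motif, require_conserved = TRUE) {
  motif <- canonical_motif(motif)
  members <- motif_class_members(motif)
  k <- nchar(motif)
  ids <- S4Vectors::mcols(cnes)$cne_id
  seqs <- S4Vectors::mcols(cnes)$seq
  masks <- if ("mask" %in% names(S4Vectors::mcols(cnes)))
    as.list(S4Vectors::mcols(cnes)$mask) else vector("list", length(cnes))
  out <- vector("list", length(cnes))
  for (i in seq_along(cnes)) {
    w <- .element_windows(seqs[i], masks[[i]], k)
    hit <- w$words %in% members
    if (require_conserved) hit <- hit & w$conserved
    if (!any(hit)) next
    out[[i]] <- data.frame(cne_id = ids[i], offset = w$starts[hit],
                           word = w$words[hit], conserved = w$conserved[hit],
                           stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0L)
    return(data.frame(cne_id = character(0), offset = integer(0),
                      word = character(0), conserved = logical(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Test whether occurrence offsets contain a c-copy duplicate within a window
#'
#' Under the default start-to-start semantics the signature is present when
#' some c occurrence starts fit in a window: sorted offsets satisfy
#' `offset[i+c-1] - offset[i] <= window` for some i. The span-inclusive mode
#' additionally counts the k-1 trailing bases of the last occurrence.
#'
#' @param offsets integer occurrence start offsets within one CNE.
#' @param copies required copy count c (>= 1).
#' @param window window size W in bp.
#' @param window_mode `"start"` (start-to-start, default) or `"span"`
#'   (end-of-last minus start-of-first).
#' @param k word length, required for `window_mode = "span"`.
#' @return logical scalar.
#' @export
has_signature <- function(offsets, copies = 2, window = 125,
                          window_mode = c("start", "span"), k = NULL) {
  window_mode <- match.arg(window_mode)
  stopifnot(copies >= 1, window >= 0)
  o <- sort(unique(as.integer(offsets)))
  n <- length(o)
  if (n < copies) return(FALSE)
  d <- o[copies:n] - o[seq_len(n - copies + 1L)]
  if (window_mode == "span") {
    if (is.null(k)) stop("window_mode = 'span' needs the word length k")
    d <- d + k - 1L
  }
  any(d <= window)
}

#' Scan all motif classes for duplicate signatures across a CNE set
#'
#' For each element, every k-length window is mapped to its canonical class
#' (windows containing non-ACGT bases are skipped) and each class's offsets
#' are tested with [has_signature()]. The result is the complete incidence of
#' (CNE, class) signature presence for a fixed (copies, window).
#'
#' @inheritParams find_motif_occurrences
#' @inheritParams has_signature
#' @param k word length (default 5: pentamer classes).
#' @param classes optional character vector restricting to these canonical
#'   classes.
#' @return data.frame with columns `cne_id`, `motif` (canonical word), one row
#'   per element/class with the signature.
#' @export
scan_signatures <- function(cnes, k = 5, copies = 2, window = 125,
                            require_conserved = TRUE,
                            window_mode = c("start", "span"),
                            classes = NULL) {
  window_mode <- match.arg(window_mode)
  ct <- .canon_table(k)
  ids <- S4Vectors::mcols(cnes)$cne_id
  seqs <- S4Vectors::mcols(cnes)$seq
  masks <- if ("mask" %in% names(S4Vectors::mcols(cnes)))
    as.list(S4Vectors::mcols(cnes)$mask) else vector("list", length(cnes))
  out <- vector("list", length(cnes))
  for (i in seq_along(cnes)) {
    w <- .element_windows(seqs[i], masks[[i]], k)
    keep <- if (require_conserved) w$conserved else rep(TRUE, length(w$starts))
    canon <- unname(ct[w$words[keep]])
    starts <- w$starts[keep]
    ok <- !is.na(canon)
    canon <- canon[ok]
    starts <- starts[ok]
    if (!is.null(classes)) {
      ok <- canon %in% classes
      canon <- canon[ok]
      starts <- starts[ok]
    }
    if (length(starts) == 0L) next
    offs <- split(starts, canon)
    present <- vapply(offs, has_signature, NA, copies = copies,
                      window = window, window_mode = window_mode, k = k)
    if (!any(present)) next
    out[[i]] <- data.frame(cne_id = ids[i], motif = names(offs)[present],
                           stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0L)
    return(data.frame(cne_id = character(0), motif = character(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
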