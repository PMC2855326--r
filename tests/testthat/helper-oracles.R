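# Shared fixtures and independent oracles for the test suite.

# build a CNE GRanges directly from sequences/masks
cnes_from_seqs <- function(seqs, masks = NULL, chrom = "chr1", starts = NULL) {
  n <- length(seqs)
  if (is.null(masks)) masks <- lapply(nchar(seqs), function(L) rep(TRUE, L))
  if (is.null(starts)) starts <- cumsum(c(1L, utils::head(nchar(seqs), -1) + 50L))
  gr <- GenomicRanges::GRanges(rep(chrom, n),
    IRanges::IRanges(start = starts[seq_len(n)], width = nchar(seqs)))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    cne_id = sprintf("cne_%05d", seq_len(n)),
    seq = seqs, mask = IRanges::LogicalList(masks))
  gr
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# naive occurrence scan: compare every k-window against both class members
naive_occurrences <- function(seq, mask, motif, require_conserved = TRUE) {
  members <- motif_class_members(motif)
  k <- nchar(members[1])
  L <- nchar(seq)
  if (L < k) return(integer(0))
  off <- integer(0)
  for (s in seq_len(L - k + 1)) {
    w <- toupper(substr(seq, s, s + k - 1))
    if (!(w %in% members)) next
    if (require_conserved && !all(mask[s:(s + k - 1)])) next
    off <- c(off, s)
  }
  off
}

# brute-force duplicate test over all c-subsets of offsets
brute_has_dup <- function(offsets, copies, window) {
  offsets <- unique(offsets)
  if (length(offsets) < copies) return(FALSE)
  if (copies == 1) return(length(offsets) >= 1)
  combs <- utils::combn(offsets, copies)
  any(apply(combs, 2, function(x) max(x) - min(x) <= window))
}

# full brute-force class incidence for one element
brute_scan_element <- function(seq, mask, k = 5, copies = 2, window = 125,
                               require_conserved = TRUE) {
  classes <- enumerate_motif_classes(k)
  L <- nchar(seq)
  if (L < k) return(character(0))
  starts <- seq_len(L - k + 1)
  words <- substring(toupper(seq), starts, starts + k - 1)
  cons <- vapply(starts, function(s) all(mask[s:(s + k - 1)]), NA)
  keep <- if (require_conserved) cons else rep(TRUE, length(starts))
  present <- character(0)
  for (cl in classes) {
    off <- starts[keep & words %in% motif_class_members(cl)]
    if (brute_has_dup(off, copies, window)) present <- c(present, cl)
  }
  present
}

# exhaustive-enumeration two-tailed Fisher oracle via binomial coefficients
fisher_enum <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
  a_range <- max(0, c1 - r2):min(r1, c1)
  pp <- vapply(a_range, function(a)
    choose(r1, a) * choose(r2, c1 - a) / choose(N, c1), 0)
  p_obs <- choose(r1, tab[1, 1]) * choose(r2, tab[2, 1]) / choose(N, c1)
  sum(pp[pp <= p_obs * (1 + 1e-7)])
}

# random non-overlapping aligned blocks on one chromosome
random_blocks <- function(n_blocks = 8, chrom_len = 2000) {
  starts <- sort(sample.int(chrom_len - 100, n_blocks))
  out <- vector("list", n_blocks)
  cursor <- 1L
  made <- 0L
  for (s in starts) {
    if (s < cursor) next
    w <- sample(30:120, 1)
    if (s + w - 1 > chrom_len) break
    made <- made + 1L
    out[[made]] <- list(start = s, width = w, seq = random_seq(w),
                        mask = sample(c(TRUE, FALSE), w, replace = TRUE,
                                      prob = c(0.8, 0.2)))
    cursor <- s + w + 5L
  }
  out <- out[seq_len(made)]
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    start = vapply(out, `[[`, 0, "start"),
    width = vapply(out, `[[`, 0, "width")))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    seq = vapply(out, `[[`, "", "seq"),
    mask = IRanges::LogicalList(lapply(out, `[[`, "mask")))
  gr
}

random_exons <- function(n = 6, chrom_len = 2000) {
  starts <- sample.int(chrom_len - 60, n)
  GenomicRanges::GRanges("chr1", IRanges::IRanges(
    start = starts, width = sample(10:60, n, replace = TRUE)))
}

# per-base membership oracle: count of aligned, non-transcribed bases
per_base_kept <- function(blocks, transcribed, chrom_len = 2000,
                          min_length = 1) {
  aligned <- logical(chrom_len)
  for (i in seq_along(blocks)) {
    aligned[GenomicRanges::start(blocks)[i]:GenomicRanges::end(blocks)[i]] <- TRUE
  }
  tx <- logical(chrom_len)
  for (i in seq_along(transcribed)) {
    tx[GenomicRanges::start(transcribed)[i]:GenomicRanges::end(transcribed)[i]] <- TRUE
  }
  kept <- aligned & !tx
  r <- rle(kept)
  sum(r$lengths[r$values & r$lengths >= min_length])
}

# exhaustive two-strand window check for spacer sequences
spacer_is_clean <- function(seq, entries, k) {
  if (length(entries) == 0 || nchar(seq) < k) return(TRUE)
  for (s in seq_len(nchar(seq) - k + 1)) {
    w <- substr(seq, s, s + k - 1)
    if (w %in% entries || revcomp_kmer(w) %in% entries) return(FALSE)
  }
  TRUE
}

# small planted fixture shared across tests
small_fixture <- function(seed = 7, ...) {
  make_fixture(fixture_params(
    n_genes = 60, tissue_sizes = c(anterior_ns = 12, posterior_ns = 12,
                                   epidermis = 36),
    seed = seed, ...))
}
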