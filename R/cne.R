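#' Read pairwise alignment blocks from a MAF file
#'
#' Parses a pairwise MAF (multiple alignment format) file into a `GRanges` of
#' aligned blocks on the reference species. The first `s` row of each block is
#' the reference, the second the other species. A per-reference-base identity
#' mask is computed column-wise: a position is conserved when the two aligned
#' bases are identical (case-insensitive) and both in \{A,C,G,T\} — so a gap or
#' an N in the other species marks the position non-conserved, and columns
#' where the reference itself is gapped occupy no mask slot.
#'
#' @param path path to a MAF file.
#' @return `GRanges` on the reference assembly, sorted by (chrom, start), with
#'   metadata columns `seq` (ungapped reference sequence), `mask`
#'   (`LogicalList`, one flag per reference base), `ref_row`, `other_row`
#'   (the original gapped rows).
#' @export
read_maf <- function(path) {
  lines <- readLines(path)
  rec <- list()
  i <- 1L
  n <- length(lines)
  while (i <= n) {
    line <- lines[i]
    if (startsWith(line, "a")) {
      srows <- list()
      j <- i + 1L
      while (j <= n && nzchar(trimws(lines[j])) && !startsWith(lines[j], "a")) {
        if (startsWith(lines[j], "s")) {
          f <- strsplit(trimws(lines[j]), "[ \t]+")[[1]]
          if (length(f) < 7L)
            stop("malformed MAF 's' line at line ", j, ": ", lines[j])
          srows[[length(srows) + 1L]] <-
            list(src = f[2], start = as.numeric(f[3]), size = as.numeric(f[4]),
                 strand = f[5], src_size = as.numeric(f[6]), text = f[7],
                 lineno = j)
        }
        j <- j + 1L
      }
      if (length(srows) < 2L)
        stop("MAF block starting at line ", i, " has fewer than 2 's' rows")
      rec[[length(rec) + 1L]] <- .maf_block(srows[[1]], srows[[2]])
      i <- j
    } else {
      i <- i + 1L
    }
  }
  if (length(rec) == 0L) {
    gr <- GenomicRanges::GRanges()
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      seq = character(0), mask = IRanges::LogicalList(),
      ref_row = character(0), other_row = character(0))
    return(gr)
  }
  gr <- GenomicRanges::GRanges(
    seqnames = vapply(rec, `[[`, "", "chrom"),
    ranges = IRanges::IRanges(
      start = vapply(rec, `[[`, 0, "start0") + 1L,
      end = vapply(rec, `[[`, 0, "start0") + vapply(rec, `[[`, 0, "size")))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    seq = vapply(rec, `[[`, "", "seq"),
    mask = IRanges::LogicalList(lapply(rec, `[[`, "mask")),
    ref_row = vapply(rec, `[[`, "", "ref_row"),
    other_row = vapply(rec, `[[`, "", "other_row"))
  sort(gr, ignore.strand = TRUE)
}

.maf_block <- function(ref, oth) {
  if (nchar(ref$text) != nchar(oth$text))
    stop("inconsistent MAF row lengths at line ", oth$lineno)
  if (ref$strand != "+")
    stop("reference-strand '-' MAF rows are not supported (line ", ref$lineno, ")")
  rc <- strsplit(ref$text, "")[[1]]
  oc <- strsplit(oth$text, "")[[1]]
  keep <- rc != "-"
  if (sum(keep) != ref$size)
    stop("MAF row at line ", ref$lineno, ": ungapped length ", sum(keep),
         " != declared size ", ref$size)
  rk <- toupper(rc[keep])
  ok <- toupper(oc[keep])
  bases <- c("A", "C", "G", "T")
  mask <- rk == ok & rk %in% bases & ok %in% bases
  chrom <- sub("^[^.]*\\.", "", ref$src)
  list(chrom = chrom, start0 = ref$start, size = ref$size,
       seq = paste(rc[keep], collapse = ""), mask = unname(mask),
       ref_row = ref$text, other_row = oth$text)
}

#' Subtract transcribed intervals from aligned blocks
#'
#' Cuts every transcribed position out of the aligned blocks; the maximal
#' remaining sub-intervals of length >= `min_length` become conserved
#' non-coding elements (CNEs). Sequence and conservation mask are sliced
#' base-for-base.
#'
#' @param blocks `GRanges` from [read_maf()] (needs `seq` and `mask` columns).
#' @param transcribed `GRanges` of transcribed intervals (exons by default in
#'   the pipeline; full gene spans via its `transcribed: genes` switch).
#' @param min_length minimum element length in bp to retain (default 20; a
#'   shorter fragment cannot hold two pentamers plus context).
#' @return `GRanges` of CNEs sorted by (chrom, start) with metadata columns
#'   `cne_id`, `seq`, `mask`.
#' @export
subtract_transcribed <- function(blocks, transcribed, min_length = 20) {
  if (length(blocks) == 0L) return(.empty_cnes())
  transcribed <- GenomicRanges::reduce(transcribed, ignore.strand = TRUE)
  tx_by_chrom <- split(IRanges::ranges(transcribed),
                       as.character(GenomicRanges::seqnames(transcribed)))
  out <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    b <- blocks[i]
    chrom <- as.character(GenomicRanges::seqnames(b))
    br <- IRanges::ranges(b)
    tx <- tx_by_chrom[[chrom]]
    kept <- if (is.null(tx)) br else IRanges::setdiff(br, tx)
    kept <- kept[IRanges::width(kept) >= min_length]
    if (length(kept) == 0L) next
    off <- IRanges::start(kept) - IRanges::start(br) + 1L
    w <- IRanges::width(kept)
    seqs <- substring(S4Vectors::mcols(b)$seq, off, off + w - 1L)
    bm <- S4Vectors::mcols(b)$mask[[1]]
    masks <- lapply(seq_along(kept), function(j) bm[off[j]:(off[j] + w[j] - 1L)])
    gr <- GenomicRanges::GRanges(chrom, kept)
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
      seq = seqs, mask = IRanges::LogicalList(masks))
    out[[i]] <- gr
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0L) return(.empty_cnes())
  cnes <- sort(suppressWarnings(do.call(c, out)), ignore.strand = TRUE)
  S4Vectors::mcols(cnes)$cne_id <-
    sprintf("cne_%05d", seq_along(cnes))
  cnes[, c("cne_id", "seq", "mask")]
}

.empty_cnes <- function() {
  gr <- GenomicRanges::GRanges()
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    cne_id = character(0), seq = character(0), mask = IRanges::LogicalList())
  gr
}

#' Summary statistics of a CNE set
#'
#' @param cnes `GRanges` of CNEs.
#' @return list with `count`, `mean_length` (0 with `empty = TRUE` flag when
#'   there are no elements).
#' @export
cne_stats <- function(cnes) {
  n <- length(cnes)
  list(count = n,
       mean_length = if (n > 0L) mean(GenomicRanges::width(cnes)) else 0,
       empty = n == 0L)
}

.mask_to_rle <- function(mask) {
  r <- rle(mask)
  paste0(r$lengths, ifelse(r$values, "C", "m"), collapse = "")
}

.rle_to_mask <- function(code) {
  m <- regmatches(code, gregexpr("[0-9]+[Cm]", code))[[1]]
  lens <- as.integer(sub("[Cm]$", "", m))
  vals <- substring(m, nchar(m)) == "C"
  rep(vals, lens)
}

#' Write a CNE set to disk
#'
#' Writes `cnes.bed` (intervals, name = cne_id), `cne_masks.tsv` (cne_id plus
#' a run-length-encoded conservation mask, `C` = conserved, `m` = mismatch)
#' and `cne_seqs.fa` (element sequences).
#'
#' @param cnes `GRanges` from [subtract_transcribed()].
#' @param dir output directory (created if missing).
#' @return invisibly, the written paths.
#' @export
write_cnes <- function(cnes, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  bed <- file.path(dir, "cnes.bed")
  gr <- cnes
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(name = S4Vectors::mcols(cnes)$cne_id)
  rtracklayer::export(gr, bed, format = "BED")
  masks <- file.path(dir, "cne_masks.tsv")
  utils::write.table(
    data.frame(cne_id = S4Vectors::mcols(cnes)$cne_id,
               mask_rle = vapply(as.list(S4Vectors::mcols(cnes)$mask),
                                 .mask_to_rle, ""),
               stringsAsFactors = FALSE),
    masks, sep = "\t", quote = FALSE, row.names = FALSE)
  fa <- file.path(dir, "cne_seqs.fa")
  ss <- Biostrings::DNAStringSet(S4Vectors::mcols(cnes)$seq)
  names(ss) <- S4Vectors::mcols(cnes)$cne_id
  Biostrings::writeXStringSet(ss, fa)
  invisible(c(bed = bed, masks = masks, seqs = fa))
}

#' Read a CNE set written by [write_cnes()]
#'
#' @param dir directory containing `cnes.bed`, `cne_masks.tsv`, `cne_seqs.fa`.
#' @return `GRanges` with `cne_id`, `seq`, `mask` columns.
#' @export
read_cnes <- function(dir) {
  gr <- rtracklayer::import(file.path(dir, "cnes.bed"), format = "BED")
  ids <- S4Vectors::mcols(gr)$name
  masks <- utils::read.table(file.path(dir, "cne_masks.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE)
  ss <- Biostrings::readDNAStringSet(file.path(dir, "cne_seqs.fa"))
  stopifnot(identical(ids, masks$cne_id), identical(ids, names(ss)))
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    cne_id = ids,
    seq = unname(as.character(ss)),
    mask = IRanges::LogicalList(lapply(masks$mask_rle, .rle_to_mask)))
  GenomicRanges::strand(gr) <- "*"
  gr
}
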