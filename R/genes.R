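#' Controlled tissue vocabulary
#'
#' The base territories used for annotation, mirroring an ascidian
#' in-situ-derived gene expression atlas: anterior and posterior nervous
#' system, notochord, epidermis, muscle. The derived `_specific` categories
#' come from [derive_specific_labels()].
#'
#' @return character vector of tissue labels.
#' @export
default_tissue_vocabulary <- function() {
  c("anterior_ns", "posterior_ns", "notochord", "epidermis", "muscle")
}

.derived_labels <- function() c("anterior_ns_specific", "posterior_ns_specific")

#' Read a gene-to-tissue annotation table
#'
#' @param path TSV with header columns `gene_id`, `tissue` (one row per
#'   gene-tissue pair).
#' @param vocabulary permitted tissue labels.
#' @return data.frame with columns `gene_id`, `tissue`.
#' @export
read_gene_annotations <- function(path, vocabulary = default_tissue_vocabulary()) {
  ann <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "tissue") %in% names(ann)))
  validate_annotations(ann[, c("gene_id", "tissue")], vocabulary)
}

#' @rdname read_gene_annotations
#' @param ann annotation data.frame to validate.
#' @export
validate_annotations <- function(ann, vocabulary = default_tissue_vocabulary()) {
  bad <- setdiff(unique(ann$tissue), c(vocabulary, .derived_labels()))
  if (length(bad) > 0L)
    stop("unknown tissue label(s): ", paste(bad, collapse = ", "))
  if (anyNA(ann$gene_id) || anyNA(ann$tissue))
    stop("annotation table contains missing values")
  unique(ann)
}

#' Derive tissue-specific expression categories
#'
#' Adds `anterior_ns_specific` (expressed in the anterior and not the
#' posterior nervous system) and the symmetric `posterior_ns_specific`
#' labels; original labels are preserved.
#'
#' @param ann annotation data.frame (`gene_id`, `tissue`).
#' @return annotation data.frame with the derived labels appended.
#' @export
derive_specific_labels <- function(ann) {
  ant <- unique(ann$gene_id[ann$tissue == "anterior_ns"])
  post <- unique(ann$gene_id[ann$tissue == "posterior_ns"])
  add <- rbind(
    if (length(setdiff(ant, post)) > 0L)
      data.frame(gene_id = setdiff(ant, post), tissue = "anterior_ns_specific",
                 stringsAsFactors = FALSE),
    if (length(setdiff(post, ant)) > 0L)
      data.frame(gene_id = setdiff(post, ant), tissue = "posterior_ns_specific",
                 stringsAsFactors = FALSE))
  out <- unique(rbind(ann[, c("gene_id", "tissue")], add))
  rownames(out) <- NULL
  out
}

#' Associate CNEs with neighboring genes
#'
#' A CNE overlapping a gene span is assigned to that host gene (to all hosts
#' if gene spans overlap). An intergenic CNE is assigned to the nearest gene
#' upstream and the nearest gene downstream on the same chromosome, each
#' within `max_distance`; ties on distance break to the smaller `gene_id`.
#' Strand is ignored throughout.
#'
#' @param cnes `GRanges` of CNEs with a `cne_id` column.
#' @param genes `GRanges` of gene spans with a `gene_id` column.
#' @param max_distance maximum gap in bp to a flanking gene (default `Inf`;
#'   appropriate for compact genomes with short intergenic regions).
#' @return data.frame with columns `cne_id`, `gene_id`.
#' @export
assign_cnes_to_genes <- function(cnes, genes, max_distance = Inf) {
  stopifnot("gene_id" %in% names(S4Vectors::mcols(genes)))
  ids <- S4Vectors::mcols(cnes)$cne_id
  gid <- S4Vectors::mcols(genes)$gene_id
  hits <- GenomicRanges::findOverlaps(cnes, genes, ignore.strand = TRUE)
  res <- data.frame(cne_id = ids[S4Vectors::queryHits(hits)],
                    gene_id = gid[S4Vectors::subjectHits(hits)],
                    stringsAsFactors = FALSE)
  genic <- unique(S4Vectors::queryHits(hits))
  inter <- setdiff(seq_along(cnes), genic)
  gchrom <- as.character(GenomicRanges::seqnames(genes))
  gstart <- GenomicRanges::start(genes)
  gend <- GenomicRanges::end(genes)
  extra <- vector("list", length(inter))
  for (j in seq_along(inter)) {
    i <- inter[j]
    chrom <- as.character(GenomicRanges::seqnames(cnes)[i])
    s <- GenomicRanges::start(cnes)[i]
    e <- GenomicRanges::end(cnes)[i]
    same <- which(gchrom == chrom)
    picked <- character(0)
    up <- same[gend[same] < s]
    if (length(up) > 0L) {
      dist <- s - gend[up] - 1L
      best <- up[dist == min(dist)]
      if (min(dist) <= max_distance)
        picked <- c(picked, min(gid[best]))
    }
    down <- same[gstart[same] > e]
    if (length(down) > 0L) {
      dist <- gstart[down] - e - 1L
      best <- down[dist == min(dist)]
      if (min(dist) <= max_distance)
        picked <- c(picked, min(gid[best]))
    }
    if (length(picked) > 0L)
      extra[[j]] <- data.frame(cne_id = ids[i], gene_id = unique(picked),
                               stringsAsFactors = FALSE)
  }
  extra <- extra[!vapply(extra, is.null, TRUE)]
  res <- unique(rbind(res, do.call(rbind, extra)))
  res <- res[order(res$cne_id, res$gene_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Gene-level signature incidence
#'
#' Lifts the per-CNE signature incidence to genes: a gene carries a motif
#' class if any of its associated CNEs does.
#'
#' @param incidence data.frame (`cne_id`, `motif`) from [scan_signatures()].
#' @param assignment data.frame (`cne_id`, `gene_id`) from
#'   [assign_cnes_to_genes()].
#' @return data.frame with columns `gene_id`, `motif`.
#' @export
gene_signature_incidence <- function(incidence, assignment) {
  m <- merge(incidence, assignment, by = "cne_id")
  out <- unique(m[, c("gene_id", "motif")])
  out <- out[order(out$gene_id, out$motif), , drop = FALSE]
  rownames(out) <- NULL
  out
}
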