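#' Inclusive binomial upper tail P[X >= k]
#'
#' @param n number of trials.
#' @param k threshold count (0 <= k <= n).
#' @param p success probability.
#' @return P[X >= k] for X ~ Binomial(n, p), computed in log space by the
#'   regularised incomplete beta function underlying [stats::pbinom()].
#' @export
binomial_tail <- function(n, k, p) {
  if (any(n < 0) || any(k < 0) || any(k > n) || any(p < 0) || any(p > 1))
    stop("binomial_tail needs 0 <= k <= n and 0 <= p <= 1")
  stats::pbinom(k - 1, n, p, lower.tail = FALSE)
}

# -log_base P[X >= k] (or P[X > k] for tail = "exclusive"), capped
.log_tail_score <- function(n, k, p, log_base = 10, tail = c("inclusive", "exclusive"),
                            cap = 300) {
  tail <- match.arg(tail)
  q <- if (tail == "inclusive") k - 1 else k
  lp <- stats::pbinom(q, n, p, lower.tail = FALSE, log.p = TRUE)
  s <- -lp / log(log_base)
  s[k == 0 & tail == "inclusive"] <- 0
  pmin(s, cap)
}

#' Motif-tissue enrichment score
#'
#' Of the n annotated genes flanked by the signature, k are annotated in the
#' tissue; with background tissue fraction p (tissue genes over all annotated
#' genes) the score is S = -log10 P[X >= k], X ~ Binomial(n, p). Genes absent
#' from the annotation table are excluded from both n and the background. S
#' is capped at 300 on underflow.
#'
#' @param gene_incidence data.frame (`gene_id`, `motif`) from
#'   [gene_signature_incidence()].
#' @param annotations annotation data.frame (`gene_id`, `tissue`).
#' @param motif canonical motif class.
#' @param tissue tissue label.
#' @param log_base logarithm base for S (default 10; the base rescales but
#'   never reorders scores).
#' @param tail `"inclusive"` (P[X >= k], default) or `"exclusive"` (P[X > k]).
#' @return one-row data.frame with `motif`, `tissue`, `n`, `k`, `p`, `S`.
#' @export
motif_tissue_score <- function(gene_incidence, annotations, motif, tissue,
                               log_base = 10, tail = "inclusive") {
  motif <- canonical_motif(motif)
  annotated <- unique(annotations$gene_id)
  tg <- unique(annotations$gene_id[annotations$tissue == tissue])
  p <- length(tg) / length(annotated)
  if (p <= 0 || p >= 1)
    stop("degenerate background: tissue fraction p = ", p)
  flanked <- unique(gene_incidence$gene_id[gene_incidence$motif == motif])
  flanked <- intersect(flanked, annotated)
  n <- length(flanked)
  k <- length(intersect(flanked, tg))
  data.frame(motif = motif, tissue = tissue, n = n, k = k, p = p,
             S = .log_tail_score(n, k, p, log_base = log_base, tail = tail),
             stringsAsFactors = FALSE)
}

#' Score all motif classes against a set of tissues
#'
#' Vectorised version of [motif_tissue_score()] over motifs x tissues.
#' Classes never seen flanking an annotated gene get n = k = 0, S = 0.
#'
#' @inheritParams motif_tissue_score
#' @param tissues character vector of tissue labels.
#' @param motifs canonical classes to score (default: all classes observed in
#'   `gene_incidence`; pass [enumerate_motif_classes()] output for the full
#'   complement).
#' @return data.frame with one row per motif x tissue.
#' @export
score_all_motifs <- function(gene_incidence, annotations, tissues,
                             motifs = NULL, log_base = 10, tail = "inclusive") {
  annotated <- unique(annotations$gene_id)
  gi <- unique(gene_incidence[gene_incidence$gene_id %in% annotated,
                              c("gene_id", "motif")])
  if (is.null(motifs)) motifs <- sort(unique(gi$motif))
  n_by <- table(factor(gi$motif, levels = motifs))
  out <- vector("list", length(tissues))
  for (t in seq_along(tissues)) {
    tg <- unique(annotations$gene_id[annotations$tissue == tissues[t]])
    p <- length(tg) / length(annotated)
    if (p <= 0 || p >= 1)
      stop("degenerate background: tissue fraction p = ", p,
           " for ", tissues[t])
    k_by <- table(factor(gi$motif[gi$gene_id %in% tg], levels = motifs))
    out[[t]] <- data.frame(
      motif = motifs, tissue = tissues[t],
      n = as.integer(n_by), k = as.integer(k_by), p = p,
      S = .log_tail_score(as.integer(n_by), as.integer(k_by), p,
                          log_base = log_base, tail = tail),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-tissue signature proportion table
#'
#' For a single motif class, the number and fraction of genes in each tissue
#' category that are flanked by the signature.
#'
#' @inheritParams motif_tissue_score
#' @param tissues ordered tissue labels defining the rows.
#' @return data.frame with `tissue`, `genes_in_category`, `genes_flanked`,
#'   `fraction` (full precision), `fraction_2dp` (2-decimal rendering,
#'   truncated toward zero as proportion tables of this kind conventionally
#'   print them), `empty_category` flag.
#' @export
tissue_table <- function(gene_incidence, annotations, motif, tissues) {
  motif <- canonical_motif(motif)
  flanked <- unique(gene_incidence$gene_id[gene_incidence$motif == motif])
  rows <- lapply(tissues, function(t) {
    tg <- unique(annotations$gene_id[annotations$tissue == t])
    size <- length(tg)
    fl <- length(intersect(tg, flanked))
    data.frame(tissue = t, genes_in_category = size, genes_flanked = fl,
               fraction = if (size > 0L) fl / size else NA_real_,
               empty_category = size == 0L, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$fraction_2dp <- ifelse(out$empty_category, NA_character_,
                             sprintf("%.2f", floor(out$fraction * 100 + 1e-9) / 100))
  rownames(out) <- NULL
  out[, c("tissue", "genes_in_category", "genes_flanked", "fraction",
          "fraction_2dp", "empty_category")]
}

#' Two-tailed Fisher exact test on a 2x2 contingency table
#'
#' The two-tailed p-value sums the hypergeometric point probabilities of all
#' tables with the observed margins whose probability does not exceed that of
#' the observed table (point-probability rule, with a small relative
#' tolerance guarding floating-point ties).
#'
#' @param tab 2x2 matrix of non-negative integer counts (rows = groups,
#'   columns = flanked / not flanked).
#' @return the two-tailed p-value in (0, 1].
#' @export
fisher_two_tailed <- function(tab) {
  tab <- as.matrix(tab)
  if (!all(dim(tab) == c(2L, 2L)))
    stop("fisher_two_tailed needs a 2x2 table")
  if (any(tab < 0) || any(tab != round(tab)))
    stop("cell counts must be non-negative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("degenerate margins: every row and column sum must be positive")
  stats::fisher.test(tab)$p.value
}

#' Rank motif classes by score for one tissue
#'
#' @param scores data.frame from [score_all_motifs()], restricted to or
#'   filtered for one tissue.
#' @param tissue tissue label to rank within.
#' @param top_m number of top classes to return (default all).
#' @return data.frame sorted by descending S, ties broken by ascending
#'   canonical word, with a `rank` column.
#' @export
rank_motifs <- function(scores, tissue = NULL, top_m = Inf) {
  if (!is.null(tissue)) scores <- scores[scores$tissue == tissue, , drop = FALSE]
  ord <- order(-scores$S, scores$motif)
  out <- scores[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  utils::head(out, n = if (is.finite(top_m)) top_m else nrow(out))
}

#' Nominate candidate enhancer CNEs
#'
#' CNEs that carry the signature and are associated with at least one gene
#' annotated in the target tissue, sorted by genomic position.
#'
#' @param cnes `GRanges` of CNEs with `cne_id`.
#' @param incidence data.frame (`cne_id`, `motif`).
#' @param assignment data.frame (`cne_id`, `gene_id`).
#' @param annotations annotation data.frame.
#' @param motif canonical motif class.
#' @param tissue tissue label gating the associated genes.
#' @return `GRanges` subset of `cnes`, sorted by (chrom, start).
#' @export
select_candidate_cnes <- function(cnes, incidence, assignment, annotations,
                                  motif, tissue) {
  motif <- canonical_motif(motif)
  sig <- unique(incidence$cne_id[incidence$motif == motif])
  tg <- unique(annotations$gene_id[annotations$tissue == tissue])
  near <- unique(assignment$cne_id[assignment$gene_id %in% tg])
  ids <- intersect(sig, near)
  out <- cnes[S4Vectors::mcols(cnes)$cne_id %in% ids]
  sort(out, ignore.strand = TRUE)
}
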