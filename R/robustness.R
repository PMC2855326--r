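#' Perturb a fraction of gene annotations
#'
#' Selects `ceiling(f * G)` genes uniformly at random and, in `"rotate"` mode
#' (the default), cyclically rotates their whole label-sets among the selected
#' genes. This preserves the multiset of label-sets and therefore every tissue
#' category size, so the background fraction p is identical across replicates.
#' `"resample"` mode instead redraws each selected gene's label-set from the
#' empirical distribution of all label-sets (category sizes then fluctuate).
#'
#' @param ann annotation data.frame (`gene_id`, `tissue`).
#' @param f fraction of genes to perturb (0..1).
#' @param mode `"rotate"` (size-preserving, default) or `"resample"`.
#' @return perturbed annotation data.frame; `f = 0` returns `ann` unchanged.
#' @export
shuffle_annotations <- function(ann, f = 0.10, mode = c("rotate", "resample")) {
  mode <- match.arg(mode)
  stopifnot(f >= 0, f <= 1)
  genes <- unique(ann$gene_id)
  G <- length(genes)
  if (f == 0 || G == 0L) return(ann)
  m <- ceiling(f * G)
  if (m < 2L) {
    warning("f * G rounds below 2 genes; returning annotations unchanged")
    return(ann)
  }
  sel <- sample(genes, m)
  sets <- split(ann$tissue, factor(ann$gene_id, levels = genes))
  if (mode == "rotate") {
    sets[sel] <- sets[c(sel[-1], sel[1])]
  } else {
    sets[sel] <- sample(sets, m, replace = TRUE)
  }
  out <- data.frame(gene_id = rep(genes, lengths(sets)),
                    tissue = unlist(sets, use.names = FALSE),
                    stringsAsFactors = FALSE)
  out <- unique(out)
  rownames(out) <- NULL
  out
}

#' Annotation-shuffle confidence intervals for motif-tissue scores
#'
#' Repeats [shuffle_annotations()] `replicates` times, rescoring the signature
#' for every tissue each time, and reports the replicate mean and empirical
#' percentile confidence interval per tissue. Replicate r runs under its own
#' sub-seed drawn from `seed`, so any single replicate can be reproduced.
#'
#' @inheritParams motif_tissue_score
#' @param tissues tissue labels to score.
#' @param f fraction of annotations perturbed per replicate (default 0.10).
#' @param replicates number of replicates R (default 100).
#' @param level confidence level (default 0.95, i.e. the 2.5 and 97.5
#'   percentiles).
#' @param seed master RNG seed.
#' @param mode passed to [shuffle_annotations()].
#' @return data.frame with `tissue`, `S` (unperturbed), `mean_S`, `ci_lo`,
#'   `ci_hi`, plus the configuration columns `f` and `replicates`.
#' @export
score_confidence <- function(gene_incidence, annotations, motif, tissues,
                             f = 0.10, replicates = 100, level = 0.95,
                             seed = 1, mode = "rotate",
                             log_base = 10, tail = "inclusive") {
  stopifnot(replicates >= 1)
  motif <- canonical_motif(motif)
  set.seed(seed)
  streams <- sample.int(.Machine$integer.max, replicates)
  base <- vapply(tissues, function(t) {
    motif_tissue_score(gene_incidence, annotations, motif, t,
                       log_base = log_base, tail = tail)$S
  }, 0)
  reps <- matrix(NA_real_, nrow = replicates, ncol = length(tissues),
                 dimnames = list(NULL, tissues))
  for (r in seq_len(replicates)) {
    set.seed(streams[r])
    ann_r <- shuffle_annotations(annotations, f = f, mode = mode)
    reps[r, ] <- vapply(tissues, function(t) {
      motif_tissue_score(gene_incidence, ann_r, motif, t,
                         log_base = log_base, tail = tail)$S
    }, 0)
  }
  alpha <- (1 - level) / 2
  data.frame(
    tissue = tissues,
    S = unname(base),
    mean_S = colMeans(reps),
    ci_lo = apply(reps, 2, stats::quantile, probs = alpha, names = FALSE),
    ci_hi = apply(reps, 2, stats::quantile, probs = 1 - alpha, names = FALSE),
    f = f, replicates = replicates,
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Copy-number and window-size robustness sweep
#'
#' Rescans one motif class over a grid of copy counts and window sizes and
#' rescores each (c, W) cell for every tissue. Occurrences are located once;
#' only the duplicate test is repeated per cell.
#'
#' @param cnes `GRanges` of CNEs.
#' @param assignment data.frame (`cne_id`, `gene_id`).
#' @param annotations annotation data.frame.
#' @param motif motif class to sweep.
#' @param tissues tissue labels to score.
#' @param windows window sizes W in bp (default 25..300 as in the headline
#'   robustness analysis).
#' @param copies copy counts c (default 1..4).
#' @param require_conserved gate occurrences on the conservation mask.
#' @param window_mode see [has_signature()].
#' @inheritParams motif_tissue_score
#' @return data.frame with one row per (copies, window, tissue): `n`, `k`,
#'   `p`, `S` and the within-cell `rank` of the tissue by S.
#' @export
sweep_signature <- function(cnes, assignment, annotations, motif, tissues,
                            windows = c(25, 50, 75, 100, 125, 150, 200, 250, 300),
                            copies = 1:4, require_conserved = TRUE,
                            window_mode = "start",
                            log_base = 10, tail = "inclusive") {
  motif <- canonical_motif(motif)
  k <- nchar(motif)
  occ <- find_motif_occurrences(cnes, motif, require_conserved = require_conserved)
  offs <- split(occ$offset, occ$cne_id)
  grid <- expand.grid(copies = copies, window = windows)
  out <- vector("list", nrow(grid))
  for (g in seq_len(nrow(grid))) {
    cc <- grid$copies[g]
    W <- grid$window[g]
    present <- vapply(offs, has_signature, NA, copies = cc, window = W,
                      window_mode = window_mode, k = k)
    inc <- data.frame(cne_id = names(offs)[present],
                      motif = rep(motif, sum(present)),
                      stringsAsFactors = FALSE)
    gi <- gene_signature_incidence(inc, assignment)
    rows <- do.call(rbind, lapply(tissues, function(t) {
      motif_tissue_score(gi, annotations, motif, t,
                         log_base = log_base, tail = tail)
    }))
    rows$copies <- cc
    rows$window <- W
    rows$rank <- rank(-rows$S, ties.method = "min")
    out[[g]] <- rows
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[, c("copies", "window", "tissue", "n", "k", "p", "S", "rank")]
}
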