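#' Default pipeline configuration
#'
#' Defaults equal the headline analysis parameters: pentamer classes (k = 5),
#' two copies within a 125-bp start-to-start window, conserved occurrences
#' only, base-10 score with inclusive tail, 10% annotation shuffles with 100
#' replicates at 95% confidence, and a sweep over W in 25..300 bp and c in
#' 1..4.
#'
#' @return nested list of configuration defaults.
#' @export
default_pipeline_config <- function() {
  list(
    paths = list(maf = NULL, exons = NULL, genes = NULL, annotations = NULL,
                 outdir = NULL),
    cne = list(min_length = 20, transcribed = "exons"),
    scan = list(k = 5, copies = 2, window = 125, window_mode = "start",
                require_conserved = TRUE),
    score = list(log_base = 10, tail = "inclusive",
                 tissues = default_tissue_vocabulary(),
                 focus_motif = "GATTA", focus_tissue = "anterior_ns"),
    robustness = list(f = 0.1, replicates = 100, level = 0.95, seed = 1,
                      mode = "rotate"),
    sweep = list(windows = c(25, 50, 75, 100, 125, 150, 200, 250, 300),
                 copies = 1:4))
}

.merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      base[[nm]] <- .merge_config(base[[nm]], user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

#' Load a pipeline configuration from YAML
#'
#' @param path YAML file with any subset of the fields of
#'   [default_pipeline_config()]; unspecified fields take the defaults.
#' @return merged configuration list.
#' @export
read_pipeline_config <- function(path) {
  .merge_config(default_pipeline_config(), yaml::read_yaml(path))
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

.read_bed_named <- function(path, id_col = "gene_id") {
  gr <- rtracklayer::import(path, format = "BED")
  GenomicRanges::strand(gr) <- "*"
  if ("name" %in% names(S4Vectors::mcols(gr)))
    S4Vectors::mcols(gr)[[id_col]] <- S4Vectors::mcols(gr)$name
  gr
}

#' Run the full signature-discovery pipeline
#'
#' Stages: read alignment blocks (MAF) -> subtract transcribed intervals ->
#' scan all k-mer classes for duplicate conserved signatures -> map CNEs to
#' genes -> score motif-tissue associations -> tissue proportion table and
#' anterior/posterior Fisher test for the focus motif -> motif ranking ->
#' shuffle confidence intervals -> copy/window sweep -> candidate CNEs.
#' Writes all artifacts plus a JSON run manifest into `outdir`; a rerun with
#' the same config and inputs is byte-identical.
#'
#' @param config a configuration list (see [default_pipeline_config()]) or a
#'   path to a YAML file.
#' @return invisibly, a list with all stage outputs and artifact paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  cfg <- .merge_config(default_pipeline_config(), config)
  for (p in c("maf", "exons", "genes", "annotations")) {
    if (is.null(cfg$paths[[p]]) || !file.exists(cfg$paths[[p]]))
      stop("pipeline stage 'config': missing input path '", p, "'")
  }
  outdir <- cfg$paths$outdir
  if (is.null(outdir)) stop("pipeline stage 'config': outdir not set")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  .stage <- function(name, expr) {
    message("[tagscan] stage ", name)
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  blocks <- .stage("read-alignment", read_maf(cfg$paths$maf))
  message("[tagscan]   ", length(blocks), " aligned blocks in")
  genes <- .stage("read-genes", .read_bed_named(cfg$paths$genes, "gene_id"))
  tx <- .stage("read-transcribed", {
    if (identical(cfg$cne$transcribed, "genes")) genes
    else .read_bed_named(cfg$paths$exons, "name")
  })
  ann <- .stage("read-annotations", {
    derive_specific_labels(read_gene_annotations(cfg$paths$annotations))
  })

  cnes <- .stage("build-cnes",
                 subtract_transcribed(blocks, tx, cfg$cne$min_length))
  message("[tagscan]   ", length(cnes), " CNEs out (mean length ",
          round(cne_stats(cnes)$mean_length, 1), " bp)")
  cne_paths <- write_cnes(cnes, outdir)

  incidence <- .stage("scan", scan_signatures(
    cnes, k = cfg$scan$k, copies = cfg$scan$copies, window = cfg$scan$window,
    require_conserved = cfg$scan$require_conserved,
    window_mode = cfg$scan$window_mode))
  assignment <- .stage("assign-genes", assign_cnes_to_genes(cnes, genes))
  gi <- .stage("gene-incidence", gene_signature_incidence(incidence, assignment))

  focus <- canonical_motif(cfg$score$focus_motif)
  tissues <- cfg$score$tissues
  scores <- .stage("score", score_all_motifs(
    gi, ann, tissues, motifs = enumerate_motif_classes(cfg$scan$k),
    log_base = cfg$score$log_base, tail = cfg$score$tail))
  ttab <- .stage("tissue-table", {
    tt <- tissue_table(gi, ann, focus,
                       c("anterior_ns_specific", "posterior_ns_specific",
                         setdiff(tissues, c("anterior_ns", "posterior_ns"))))
    tt
  })
  fisher_p <- .stage("fisher", {
    a <- ttab[ttab$tissue == "anterior_ns_specific", ]
    b <- ttab[ttab$tissue == "posterior_ns_specific", ]
    if (a$genes_in_category > 0 && b$genes_in_category > 0 &&
        (a$genes_flanked + b$genes_flanked) > 0 &&
        (a$genes_in_category - a$genes_flanked +
           b$genes_in_category - b$genes_flanked) > 0) {
      fisher_two_tailed(matrix(
        c(a$genes_flanked, a$genes_in_category - a$genes_flanked,
          b$genes_flanked, b$genes_in_category - b$genes_flanked),
        nrow = 2, byrow = TRUE))
    } else NA_real_
  })
  ranks <- .stage("rank", rank_motifs(scores, tissue = cfg$score$focus_tissue))
  ci <- .stage("shuffle-ci", score_confidence(
    gi, ann, focus, tissues, f = cfg$robustness$f,
    replicates = cfg$robustness$replicates, level = cfg$robustness$level,
    seed = cfg$robustness$seed, mode = cfg$robustness$mode,
    log_base = cfg$score$log_base, tail = cfg$score$tail))
  sweep_m <- .stage("sweep", sweep_signature(
    cnes, assignment, ann, focus, tissues,
    windows = cfg$sweep$windows, copies = cfg$sweep$copies,
    require_conserved = cfg$scan$require_conserved,
    window_mode = cfg$scan$window_mode,
    log_base = cfg$score$log_base, tail = cfg$score$tail))
  candidates <- .stage("candidates", select_candidate_cnes(
    cnes, incidence, assignment, ann, focus, cfg$score$focus_tissue))

  paths <- c(
    cne_paths,
    incidence = .write_tsv(incidence, file.path(outdir, "incidence.tsv")),
    gene_incidence = .write_tsv(gi, file.path(outdir, "gene_incidence.tsv")),
    tissue_table = .write_tsv(ttab, file.path(outdir, "tissue_table.tsv")),
    scores = .write_tsv(scores, file.path(outdir, "score_table.tsv")),
    ranks = .write_tsv(ranks, file.path(outdir, "rank_table.tsv")),
    ci = .write_tsv(ci, file.path(outdir, "ci_table.tsv")),
    sweep = .write_tsv(sweep_m, file.path(outdir, "sweep_matrix.tsv")),
    candidates = local({
      p <- file.path(outdir, "candidates.bed")
      gr <- candidates
      S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        name = S4Vectors::mcols(candidates)$cne_id)
      rtracklayer::export(gr, p, format = "BED")
      p
    }))

  manifest <- list(
    package = "tagscan",
    version = as.character(utils::packageVersion("tagscan")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config = cfg[setdiff(names(cfg), "paths")],
    inputs = lapply(cfg$paths[c("maf", "exons", "genes", "annotations")],
                    function(p) list(path = p,
                                     md5 = unname(tools::md5sum(p)))),
    fisher_anterior_vs_posterior_p = fisher_p,
    n_blocks = length(blocks), n_cnes = length(cnes),
    mean_cne_length = cne_stats(cnes)$mean_length,
    n_candidates = length(candidates),
    artifacts = as.list(paths))
  manifest_path <- file.path(outdir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  invisible(list(blocks = blocks, cnes = cnes, incidence = incidence,
                 assignment = assignment, gene_incidence = gi,
                 annotations = ann, scores = scores, tissue_table = ttab,
                 fisher_p = fisher_p, ranks = ranks, ci = ci,
                 sweep = sweep_m, candidates = candidates,
                 paths = c(paths, manifest = manifest_path)))
}
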