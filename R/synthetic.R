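#' Parameters for a synthetic study fixture
#'
#' Describes a small two-chromosome genome laid out as per-gene slots: a run
#' of 5' intergenic CNEs, then the gene span, whose central intron holds one
#' further CNE. Genes are partitioned into tissue categories; for genes of
#' `planted_tissue` a duplicated copy of `planted_motif` is planted into the
#' intronic CNE with probability `enrichment_rate` (and `background_rate`
#' for every other gene), at conserved positions with a start-to-start
#' distance drawn uniformly from `planting_distance`. The intronic placement
#' mirrors the position of the study system's candidate elements (intronic
#' and 5'-proximal conserved sequence counts as a gene's flanking conserved
#' DNA) and gives the planted signal an unambiguous host gene, while the
#' intergenic CNEs exercise the two-nearest-flanks assignment rule.
#'
#' @param n_genes total number of genes.
#' @param tissue_sizes named integer vector of category sizes (must sum to at
#'   most `n_genes`; the remainder is unannotated).
#' @param planted_motif word planted as a duplicate (default GATTA, the
#'   K50-Paired homeodomain core).
#' @param planted_tissue category receiving the enrichment.
#' @param enrichment_rate q: probability a planted-tissue gene gets a planted
#'   duplicate.
#' @param background_rate b: same probability for all other genes (0 <= b <= q).
#' @param cne_per_gene flanking CNEs per gene.
#' @param cne_length_mean mean CNE length in bp (lengths drawn uniformly in
#'   +/- 30% of the mean; a CNE receiving a planted duplicate is widened to
#'   hold it if needed).
#' @param conservation_rate per-base probability of being conserved in the
#'   simulated alignment; planted motif bases are forced conserved.
#' @param planting_distance length-2 range; the start-to-start distance of a
#'   planted duplicate is drawn uniformly from it (default `c(5, 125)`,
#'   clamped below at the motif length so copies never overlap).
#' @param gene_length span of each gene in bp; two 150-bp exons frame a
#'   central intron sized to hold the intronic CNE (default `NULL`: computed
#'   from the CNE length cap).
#' @param genome_length optional total genome length; computed from the
#'   layout when `NULL`, and an error is raised if too small to fit it.
#' @param seed RNG seed; all outputs are a deterministic function of it.
#' @return validated parameter list of class `fixture_params`.
#' @export
fixture_params <- function(n_genes = 300,
                           tissue_sizes = c(anterior_ns = 60, posterior_ns = 60,
                                            epidermis = 180),
                           planted_motif = "GATTA",
                           planted_tissue = "anterior_ns",
                           enrichment_rate = 0.4,
                           background_rate = 0.05,
                           cne_per_gene = 2,
                           cne_length_mean = 150,
                           conservation_rate = 0.9,
                           planting_distance = c(5, 125),
                           gene_length = NULL,
                           genome_length = NULL,
                           seed = 1) {
  planted_motif <- toupper(planted_motif)
  stopifnot(n_genes >= 1, cne_per_gene >= 1, cne_length_mean >= 40,
            conservation_rate >= 0, conservation_rate <= 1,
            grepl("^[ACGT]+$", planted_motif),
            length(planting_distance) == 2L,
            planting_distance[1] >= 1, diff(planting_distance) >= 0)
  if (!(background_rate >= 0 && background_rate <= enrichment_rate &&
        enrichment_rate <= 1))
    stop("rates must satisfy 0 <= background_rate <= enrichment_rate <= 1")
  if (sum(tissue_sizes) > n_genes)
    stop("tissue category sizes sum to more than n_genes")
  if (!planted_tissue %in% names(tissue_sizes))
    stop("planted_tissue must be one of the tissue_sizes categories")
  gap <- 30L
  k <- nchar(planted_motif)
  planting_distance <- as.integer(pmax(planting_distance, k))
  max_cne <- max(ceiling(1.3 * cne_length_mean),
                 10L + planting_distance[2] + k)
  exon_length <- 150L
  if (is.null(gene_length)) gene_length <- 2L * exon_length + max_cne + 16L
  if (gene_length < 2L * exon_length + max_cne + 16L)
    stop("gene_length ", gene_length, " too short to hold two ", exon_length,
         "-bp exons and an intronic CNE (need >= ",
         2L * exon_length + max_cne + 16L, ")")
  slot <- cne_per_gene * (max_cne + gap) + gene_length + gap
  required <- (n_genes + 2L) * slot
  if (is.null(genome_length)) genome_length <- required
  if (genome_length < required)
    stop("genome_length ", genome_length, " too short for ", n_genes,
         " gene loci (need >= ", required, ")")
  structure(list(n_genes = as.integer(n_genes), tissue_sizes = tissue_sizes,
                 planted_motif = planted_motif, planted_tissue = planted_tissue,
                 enrichment_rate = enrichment_rate,
                 background_rate = background_rate,
                 cne_per_gene = as.integer(cne_per_gene),
                 cne_length_mean = as.integer(cne_length_mean),
                 conservation_rate = conservation_rate,
                 planting_distance = planting_distance,
                 gene_length = as.integer(gene_length),
                 exon_length = exon_length,
                 genome_length = as.integer(genome_length),
                 gap = gap, max_cne = as.integer(max_cne),
                 seed = as.integer(seed)),
            class = "fixture_params")
}

.rand_bases <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

.mutate_base <- function(b) {
  vapply(b, function(x) sample(setdiff(c("A", "C", "G", "T"), x), 1L), "")
}

#' Generate a complete synthetic fixture
#'
#' Emits a genome (FASTA), a pairwise alignment (MAF; one block per CNE whose
#' identity pattern realises the conservation mask, plus a few decoy blocks
#' straddling exon starts that the transcribed-region subtraction must trim),
#' gene spans and exons (BED), a gene-to-tissue table (TSV) and a truth record
#' (JSON) listing every planted duplicate. Chance occurrences of the planted
#' motif in background sequence are left in place; they are part of the
#' background the enrichment score must tolerate.
#'
#' @param params a [fixture_params()] object.
#' @param dir optional output directory; when given, all files are written
#'   there (byte-identical across runs with the same seed).
#' @return list with the in-memory objects (`genome` as `DNAStringSet`,
#'   `blocks`, `exons`, `genes` as `GRanges`, `annotations` data.frame,
#'   `truth` list, `params`) and, when `dir` is given, `paths`.
#' @export
make_fixture <- function(params, dir = NULL) {
  stopifnot(inherits(params, "fixture_params"))
  set.seed(params$seed)
  p <- params
  k <- nchar(p$planted_motif)
  members <- motif_class_members(p$planted_motif)

  gene_ids <- sprintf("gene_%04d", seq_len(p$n_genes))
  tissue_of <- rep(NA_character_, p$n_genes)
  tissue_of[sample.int(p$n_genes, sum(p$tissue_sizes))] <-
    rep(names(p$tissue_sizes), p$tissue_sizes)

  prob <- ifelse(!is.na(tissue_of) & tissue_of == p$planted_tissue,
                 p$enrichment_rate, p$background_rate)
  planted <- stats::runif(p$n_genes) < prob

  half <- ceiling(p$n_genes / 2)
  chrom_of <- ifelse(seq_len(p$n_genes) <= half, "chr1", "chr2")
  chrom_len <- c(chr1 = (half + 1L) * (p$cne_per_gene * (p$max_cne + p$gap) +
                                         p$gene_length + p$gap),
                 chr2 = (p$n_genes - half + 1L) *
                   (p$cne_per_gene * (p$max_cne + p$gap) +
                      p$gene_length + p$gap))
  chrom_seq <- lapply(chrom_len, .rand_bases)

  blocks <- list()
  genes <- list()
  exons <- list()
  placements <- list()
  cursor <- c(chr1 = p$gap, chr2 = p$gap)  # 0-based next free position

  lo <- max(40L, floor(0.7 * p$cne_length_mean))
  hi <- ceiling(1.3 * p$cne_length_mean)

  plant_cne <- function(i, start0, len) {
    # one duplicated motif pair at conserved positions; returns seq/mask and
    # appends the truth placement
    seq_chars <- .rand_bases(len)
    mask <- stats::runif(len) < p$conservation_rate
    o1 <- 4L
    d <- p$planting_distance[1] +
      sample.int(p$planting_distance[2] - p$planting_distance[1] + 1L, 1L) - 1L
    o2 <- o1 + d
    w1 <- sample(members, 1L)
    w2 <- sample(members, 1L)
    seq_chars[o1:(o1 + k - 1L)] <- strsplit(w1, "")[[1]]
    seq_chars[o2:(o2 + k - 1L)] <- strsplit(w2, "")[[1]]
    mask[o1:(o1 + k - 1L)] <- TRUE
    mask[o2:(o2 + k - 1L)] <- TRUE
    placements[[length(placements) + 1L]] <<- list(
      gene_id = gene_ids[i], chrom = chrom_of[i],
      cne_start0 = start0, cne_end0 = start0 + len,
      offsets = c(o1, o2), words = c(w1, w2),
      motif = canonical_motif(p$planted_motif))
    list(seq = seq_chars, mask = mask)
  }

  for (i in seq_len(p$n_genes)) {
    chrom <- chrom_of[i]
    # 5' intergenic CNEs (never planted; may flank two genes)
    for (j in seq_len(p$cne_per_gene - 1L)) {
      len <- sample(lo:hi, 1L)
      start0 <- cursor[[chrom]]
      seq_chars <- .rand_bases(len)
      mask <- stats::runif(len) < p$conservation_rate
      chrom_seq[[chrom]][(start0 + 1L):(start0 + len)] <- seq_chars
      blocks[[length(blocks) + 1L]] <- list(
        chrom = chrom, start0 = start0, seq = seq_chars, mask = mask)
      cursor[[chrom]] <- start0 + len + p$gap
    }
    gstart0 <- cursor[[chrom]]
    genes[[length(genes) + 1L]] <- list(gene_id = gene_ids[i], chrom = chrom,
                                        start0 = gstart0,
                                        end0 = gstart0 + p$gene_length)
    exons[[length(exons) + 1L]] <- list(chrom = chrom, start0 = gstart0,
                                        end0 = gstart0 + p$exon_length)
    exons[[length(exons) + 1L]] <- list(chrom = chrom,
                                        start0 = gstart0 + p$gene_length -
                                          p$exon_length,
                                        end0 = gstart0 + p$gene_length)
    # intronic CNE: hosts any planted duplicate, so the signal attributes
    # unambiguously to this gene
    ilen <- sample(lo:hi, 1L)
    if (planted[i]) ilen <- max(ilen, 10L + p$planting_distance[2] + k)
    istart0 <- gstart0 + p$exon_length + 8L
    if (planted[i]) {
      sm <- plant_cne(i, istart0, ilen)
    } else {
      sm <- list(seq = .rand_bases(ilen),
                 mask = stats::runif(ilen) < p$conservation_rate)
    }
    chrom_seq[[chrom]][(istart0 + 1L):(istart0 + ilen)] <- sm$seq
    blocks[[length(blocks) + 1L]] <- list(
      chrom = chrom, start0 = istart0, seq = sm$seq, mask = sm$mask)
    # decoy aligned block straddling the first exon start: subtraction must
    # trim it back to the 25 bp upstream of the gene
    if (i %% 50L == 1L) {
      ds0 <- gstart0 - 25L
      dlen <- 50L
      dseq <- chrom_seq[[chrom]][(ds0 + 1L):(ds0 + dlen)]
      blocks[[length(blocks) + 1L]] <- list(
        chrom = chrom, start0 = ds0, seq = dseq, mask = rep(TRUE, dlen))
    }
    cursor[[chrom]] <- gstart0 + p$gene_length + p$gap
  }

  genome <- Biostrings::DNAStringSet(vapply(chrom_seq, paste, "", collapse = ""))
  names(genome) <- names(chrom_len)

  blocks_gr <- GenomicRanges::GRanges(
    seqnames = vapply(blocks, `[[`, "", "chrom"),
    ranges = IRanges::IRanges(
      start = vapply(blocks, `[[`, 0, "start0") + 1L,
      width = lengths(lapply(blocks, `[[`, "seq"))))
  S4Vectors::mcols(blocks_gr) <- S4Vectors::DataFrame(
    seq = vapply(blocks, function(b) paste(b$seq, collapse = ""), ""),
    mask = IRanges::LogicalList(lapply(blocks, `[[`, "mask")))
  ord <- order(as.character(GenomicRanges::seqnames(blocks_gr)),
               GenomicRanges::start(blocks_gr))
  blocks_gr <- blocks_gr[ord]

  genes_gr <- GenomicRanges::GRanges(
    seqnames = vapply(genes, `[[`, "", "chrom"),
    ranges = IRanges::IRanges(start = vapply(genes, `[[`, 0, "start0") + 1L,
                              end = vapply(genes, `[[`, 0, "end0")))
  S4Vectors::mcols(genes_gr)$gene_id <- vapply(genes, `[[`, "", "gene_id")

  exons_gr <- GenomicRanges::GRanges(
    seqnames = vapply(exons, `[[`, "", "chrom"),
    ranges = IRanges::IRanges(start = vapply(exons, `[[`, 0, "start0") + 1L,
                              end = vapply(exons, `[[`, 0, "end0")))

  ann <- data.frame(gene_id = gene_ids[!is.na(tissue_of)],
                    tissue = tissue_of[!is.na(tissue_of)],
                    stringsAsFactors = FALSE)
  ann <- ann[order(ann$gene_id), , drop = FALSE]
  rownames(ann) <- NULL

  truth <- list(
    params = unclass(p)[c("n_genes", "planted_motif", "planted_tissue",
                          "enrichment_rate", "background_rate", "seed")],
    placements = placements,
    blocks = data.frame(
      chrom = as.character(GenomicRanges::seqnames(blocks_gr)),
      start0 = GenomicRanges::start(blocks_gr) - 1L,
      end0 = GenomicRanges::end(blocks_gr),
      mask_rle = vapply(as.list(S4Vectors::mcols(blocks_gr)$mask),
                        .mask_to_rle, ""),
      stringsAsFactors = FALSE))

  res <- list(genome = genome, blocks = blocks_gr, exons = exons_gr,
              genes = genes_gr, annotations = ann, truth = truth,
              params = p)
  if (!is.null(dir)) res$paths <- .write_fixture(res, dir)
  res
}

.write_fixture <- function(fx, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(genome = file.path(dir, "genome.fa"),
             maf = file.path(dir, "alignment.maf"),
             exons = file.path(dir, "exons.bed"),
             genes = file.path(dir, "genes.bed"),
             annotations = file.path(dir, "annotations.tsv"),
             truth = file.path(dir, "truth.json"))
  Biostrings::writeXStringSet(fx$genome, paths["genome"])
  .write_maf(fx$blocks, fx$genome, paths["maf"])
  .write_bed0 <- function(gr, path, names = NULL) {
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                     start = GenomicRanges::start(gr) - 1L,
                     end = GenomicRanges::end(gr),
                     stringsAsFactors = FALSE)
    if (!is.null(names)) df$name <- names
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  .write_bed0(fx$exons, paths["exons"])
  .write_bed0(fx$genes, paths["genes"], S4Vectors::mcols(fx$genes)$gene_id)
  utils::write.table(fx$annotations, paths["annotations"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(fx$truth, paths["truth"], auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  paths
}

.write_maf <- function(blocks, genome, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##maf version=1", con)
  src_size <- stats::setNames(Biostrings::width(genome), names(genome))
  for (i in seq_along(blocks)) {
    chrom <- as.character(GenomicRanges::seqnames(blocks)[i])
    s0 <- GenomicRanges::start(blocks)[i] - 1L
    seq <- S4Vectors::mcols(blocks)$seq[i]
    mask <- S4Vectors::mcols(blocks)$mask[[i]]
    oth <- strsplit(seq, "")[[1]]
    if (any(!mask)) oth[!mask] <- .mutate_base(oth[!mask])
    size <- nchar(seq)
    writeLines(c("",
                 "a score=0",
                 sprintf("s ref.%s %d %d + %d %s", chrom, s0, size,
                         src_size[[chrom]], seq),
                 sprintf("s oth.%s %d %d + %d %s", chrom, s0, size,
                         src_size[[chrom]], paste(oth, collapse = ""))),
               con)
  }
}
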