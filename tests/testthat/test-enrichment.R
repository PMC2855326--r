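# expected tail probabilities computed once with exact rational arithmetic
exact_tails <- list(
  list(n = 5,   k = 5,  p = 1 / 2,   value = 3.125000000000000e-02),
  list(n = 30,  k = 9,  p = 1 / 5,   value = 1.286507539140439e-01),
  list(n = 200, k = 50, p = 1 / 4,   value = 5.271236581202351e-01),
  list(n = 100, k = 3,  p = 3 / 100, value = 5.802249170181446e-01),
  list(n = 200, k = 190, p = 1 / 2,  value = 1.473853802148427e-44),
  list(n = 24,  k = 10, p = 1 / 5,   value = 1.262108992009734e-02))

test_that("binomial upper tail is exact against rational arithmetic and summation", {
  expect_equal(binomial_tail(10, 0, 0.3), 1.0)
  expect_equal(binomial_tail(7, 0, 0), 1.0)
  for (cs in exact_tails) {
    expect_equal(binomial_tail(cs$n, cs$k, cs$p), cs$value,
                 tolerance = 1e-10,
                 info = sprintf("n=%d k=%d", cs$n, cs$k))
  }
  # term-by-term summation oracle over a grid
  for (n in c(10, 30, 120, 200)) {
    for (p in c(0.05, 0.2, 0.5, 0.9)) {
      for (k in unique(c(0, 1, floor(n * p), n - 1, n))) {
        expect_equal(binomial_tail(n, k, p), sum(stats::dbinom(k:n, n, p)),
                     tolerance = 1e-10)
      }
    }
  }
  expect_error(binomial_tail(5, 6, 0.5), "k <= n")
  expect_error(binomial_tail(5, 2, 1.5), "k <= n")
})

test_that("motif-tissue score follows the binomial tail and its invariances", {
  ann <- data.frame(
    gene_id = sprintf("g%03d", 1:100),
    tissue = rep(c("anterior_ns", "muscle"), c(20, 80)),
    stringsAsFactors = FALSE)
  flanked <- sprintf("g%03d", c(1:10, 21:34))  # 10 anterior + 14 muscle
  gi <- data.frame(gene_id = flanked, motif = "GATTA",
                   stringsAsFactors = FALSE)
  sc <- motif_tissue_score(gi, ann, "GATTA", "anterior_ns")
  expect_equal(sc$n, 24)
  expect_equal(sc$k, 10)
  expect_equal(sc$p, 0.2)
  expect_equal(sc$S, -log10(1.262108992009734e-02), tolerance = 1e-9)
  # genes absent from the annotation table are excluded from n
  gi_extra <- rbind(gi, data.frame(gene_id = "unannotated_gene",
                                   motif = "GATTA"))
  expect_equal(motif_tissue_score(gi_extra, ann, "GATTA", "anterior_ns")$n, 24)
  # k = 0 gives S = 0
  gi0 <- data.frame(gene_id = sprintf("g%03d", 21:30), motif = "GATTA")
  expect_equal(motif_tissue_score(gi0, ann, "GATTA", "anterior_ns")$S, 0)
  # raising k at fixed n never decreases S
  s_seq <- vapply(0:20, function(k) {
    gik <- data.frame(gene_id = sprintf("g%03d", c(seq_len(k),
                                                   20 + seq_len(24 - k))),
                      motif = "GATTA")
    motif_tissue_score(gik, ann, "GATTA", "anterior_ns")$S
  }, 0)
  expect_true(all(diff(s_seq) >= 0))
  # relabeling genes outside the tissue and outside the flanked set is neutral
  ann2 <- ann
  swap <- ann2$gene_id %in% sprintf("g%03d", 60:79)
  ann2$tissue[swap] <- "muscle"  # already muscle: genuine no-op relabel
  ann2$tissue[ann2$gene_id == "g090"] <- "notochord"
  sc2 <- motif_tissue_score(gi, ann2, "GATTA", "anterior_ns")
  expect_equal(sc2[c("n", "k", "p", "S")], sc[c("n", "k", "p", "S")])
  # degenerate backgrounds are rejected
  expect_error(motif_tissue_score(gi, ann, "GATTA", "notochord"),
               "degenerate")
  # the score cap engages on extreme underflow (p^n below 1e-300)
  ann_big <- data.frame(gene_id = sprintf("h%04d", 1:2250),
                        tissue = rep(c("anterior_ns", "muscle"), c(450, 1800)))
  gi_big <- data.frame(gene_id = sprintf("h%04d", 1:450), motif = "GATTA")
  expect_equal(motif_tissue_score(gi_big, ann_big, "GATTA",
                                  "anterior_ns")$S, 300)
})

test_that("vectorised scoring matches the single-pair path across all classes", {
  fx <- small_fixture(seed = 41)
  cnes <- subtract_transcribed(fx$blocks, fx$exons, min_length = 20)
  inc <- scan_signatures(cnes)
  asn <- assign_cnes_to_genes(cnes, fx$genes)
  gi <- gene_signature_incidence(inc, asn)
  tissues <- c("anterior_ns", "posterior_ns", "epidermis")
  all_sc <- score_all_motifs(gi, fx$annotations, tissues,
                             motifs = enumerate_motif_classes(5))
  expect_equal(nrow(all_sc), 512 * 3)
  picks <- all_sc[sample.int(nrow(all_sc), 25), ]
  for (i in seq_len(nrow(picks))) {
    one <- motif_tissue_score(gi, fx$annotations, picks$motif[i],
                              picks$tissue[i])
    expect_equal(picks$n[i], one$n)
    expect_equal(picks$k[i], one$k)
    expect_equal(picks$S[i], one$S)
  }
})

test_that("tissue proportion table reproduces the printed category fractions", {
  sizes <- c(anterior_ns_specific = 100, posterior_ns_specific = 58,
             notochord = 346, epidermis = 523, muscle = 143)
  flanked_n <- c(anterior_ns_specific = 26, posterior_ns_specific = 7,
                 notochord = 18, epidermis = 26, muscle = 4)
  ann <- data.frame(gene_id = sprintf("g%04d", seq_len(sum(sizes))),
                    tissue = rep(names(sizes), sizes),
                    stringsAsFactors = FALSE)
  ids <- split(ann$gene_id, ann$tissue)
  gi <- data.frame(
    gene_id = unlist(lapply(names(sizes),
                            function(t) ids[[t]][seq_len(flanked_n[[t]])]),
                     use.names = FALSE),
    motif = "GATTA", stringsAsFactors = FALSE)
  tab <- tissue_table(gi, ann, "GATTA", names(sizes))
  expect_equal(tab$genes_in_category, unname(sizes))
  expect_equal(tab$genes_flanked, unname(flanked_n))
  expect_equal(tab$fraction_2dp, c("0.26", "0.12", "0.05", "0.04", "0.02"))
  expect_equal(tab$fraction, unname(flanked_n / sizes))
})

test_that("tissue table flags empty categories and zero flanking", {
  ann <- data.frame(gene_id = c("g1", "g2"), tissue = "muscle",
                    stringsAsFactors = FALSE)
  gi <- data.frame(gene_id = character(0), motif = character(0))
  tab <- tissue_table(gi, ann, "GATTA", c("muscle", "notochord"))
  expect_equal(tab$fraction_2dp[tab$tissue == "muscle"], "0.00")
  expect_true(tab$empty_category[tab$tissue == "notochord"])
  expect_true(is.na(tab$fraction[tab$tissue == "notochord"]))
})

test_that("two-tailed Fisher test matches enumeration and its symmetries", {
  tab <- matrix(c(26, 74, 7, 51), nrow = 2, byrow = TRUE)
  p <- fisher_two_tailed(tab)
  expect_equal(round(p, 3), 0.043)
  expect_equal(p, fisher_enum(tab), tolerance = 1e-7)
  expect_equal(fisher_two_tailed(matrix(c(5, 5, 5, 5), 2)), 1.0)
  t2 <- matrix(c(3, 1, 1, 3), nrow = 2, byrow = TRUE)
  expect_equal(fisher_two_tailed(t2), fisher_enum(t2), tolerance = 1e-9)
  withr::local_seed(29)
  for (rep in 1:25) {
    t3 <- matrix(rpois(4, 12) + 1, 2)
    p3 <- fisher_two_tailed(t3)
    expect_equal(p3, fisher_enum(t3), tolerance = 1e-7)
    expect_equal(fisher_two_tailed(t(t3)), p3, tolerance = 1e-12)
    expect_equal(fisher_two_tailed(t3[2:1, 2:1]), p3, tolerance = 1e-12)
    expect_gt(p3, 0)
    expect_lte(p3, 1)
  }
  expect_error(fisher_two_tailed(matrix(c(0, 0, 3, 4), 2, byrow = TRUE)),
               "margins")
  expect_error(fisher_two_tailed(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
})

test_that("motif ranking is deterministic with lexicographic tie-breaks", {
  sc <- data.frame(motif = c("TTACG", "AATGC", "GATTA"),
                   tissue = "anterior_ns",
                   n = c(5, 5, 9), k = c(3, 3, 7), p = 0.2,
                   S = c(2.5, 2.5, 6.1), stringsAsFactors = FALSE)
  r <- rank_motifs(sc, "anterior_ns")
  expect_equal(r$motif, c("GATTA", "AATGC", "TTACG"))
  expect_equal(r$rank, 1:3)
  expect_equal(nrow(rank_motifs(sc, "anterior_ns", top_m = 0)), 0)
  expect_equal(nrow(rank_motifs(sc, "anterior_ns", top_m = 2)), 2)
})

test_that("candidate nomination gates on both signature and tissue", {
  cnes <- cnes_from_seqs(vapply(1:4, function(i) random_seq(60), ""),
                         starts = c(100L, 300L, 500L, 700L))
  ids <- S4Vectors::mcols(cnes)$cne_id
  inc <- data.frame(cne_id = ids[c(1, 2)], motif = "GATTA")
  asn <- data.frame(cne_id = ids, gene_id = c("gA", "gM", "gA", "gM"))
  ann <- data.frame(gene_id = c("gA", "gM"),
                    tissue = c("anterior_ns", "muscle"))
  got <- select_candidate_cnes(cnes, inc, asn, ann, "GATTA", "anterior_ns")
  # cne 2 has the signature but flanks only a muscle gene; cne 3 flanks the
  # anterior gene but lacks the signature
  expect_equal(S4Vectors::mcols(got)$cne_id, ids[1])
  # brute-force set intersection on a fixture
  fx <- small_fixture(seed = 43)
  fcnes <- subtract_transcribed(fx$blocks, fx$exons, min_length = 20)
  finc <- scan_signatures(fcnes)
  fasn <- assign_cnes_to_genes(fcnes, fx$genes)
  fgot <- select_candidate_cnes(fcnes, finc, fasn, fx$annotations,
                                "GATTA", "anterior_ns")
  tg <- fx$annotations$gene_id[fx$annotations$tissue == "anterior_ns"]
  want <- intersect(finc$cne_id[finc$motif == "GATTA"],
                    fasn$cne_id[fasn$gene_id %in% tg])
  expect_setequal(S4Vectors::mcols(fgot)$cne_id, want)
  expect_false(is.unsorted(GenomicRanges::start(fgot)[
    as.character(GenomicRanges::seqnames(fgot)) == "chr1"]))
})
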