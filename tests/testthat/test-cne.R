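write_maf_text <- function(lines) {
  path <- withr::local_tempfile(fileext = ".maf",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("MAF parsing applies the identity-mask gap conventions", {
  path <- write_maf_text(c(
    "##maf version=1",
    "",
    "a score=0",
    "s ref.chr1 10 5 + 1000 GATTA",
    "s oth.chr1 10 5 + 1000 GATTA",
    "",
    "a score=0",
    "s ref.chr1 40 5 + 1000 GAT-TA",
    "s oth.chr1 40 6 + 1000 GATCTA",
    "",
    "a score=0",
    "s ref.chr1 80 5 + 1000 GANTA",
    "s oth.chr1 80 5 + 1000 GA-TA"))
  blocks <- read_maf(path)
  expect_length(blocks, 3)
  expect_equal(GenomicRanges::start(blocks), c(11, 41, 81))
  # identical rows: all conserved
  expect_equal(S4Vectors::mcols(blocks)$mask[[1]], rep(TRUE, 5))
  # reference gap column consumes no mask slot
  expect_equal(S4Vectors::mcols(blocks)$mask[[2]], rep(TRUE, 5))
  expect_equal(S4Vectors::mcols(blocks)$seq[2], "GATTA")
  # N never matches (aligned here to the other species' gap column)
  expect_equal(S4Vectors::mcols(blocks)$mask[[3]],
               c(TRUE, TRUE, FALSE, TRUE, TRUE))
})

test_that("malformed MAF input is rejected with line context", {
  bad_len <- write_maf_text(c("a score=0",
                              "s ref.chr1 0 5 + 100 GATTA",
                              "s oth.chr1 0 6 + 100 GATTAC"))
  expect_error(read_maf(bad_len), "line")
  one_row <- write_maf_text(c("a score=0", "s ref.chr1 0 5 + 100 GATTA"))
  expect_error(read_maf(one_row), "fewer than 2")
  bad_size <- write_maf_text(c("a score=0",
                               "s ref.chr1 0 6 + 100 GAT-TA",
                               "s oth.chr1 0 6 + 100 GATCTA"))
  expect_error(read_maf(bad_size), "ungapped length")
})

test_that("transcribed-region subtraction splits blocks as expected", {
  blocks <- cnes_from_seqs(random_seq(200), starts = 1L)
  exon <- GenomicRanges::GRanges("chr1", IRanges::IRanges(51, 100))
  out <- subtract_transcribed(blocks, exon, min_length = 1)
  expect_equal(GenomicRanges::start(out), c(1, 101))
  expect_equal(GenomicRanges::end(out), c(50, 200))
  expect_equal(S4Vectors::mcols(out)$seq[1],
               substr(S4Vectors::mcols(blocks)$seq[1], 1, 50))
  # full covering removes the block entirely
  all_tx <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 200))
  expect_length(subtract_transcribed(blocks, all_tx, min_length = 1), 0)
  # min_length filters short fragments
  near_all <- GenomicRanges::GRanges("chr1", IRanges::IRanges(11, 200))
  expect_length(subtract_transcribed(blocks, near_all, min_length = 20), 0)
})

test_that("subtraction conserves bases against a per-base oracle and is idempotent", {
  withr::local_seed(11)
  for (rep in 1:30) {
    blocks <- random_blocks()
    exons <- random_exons()
    cnes <- subtract_transcribed(blocks, exons, min_length = 1)
    expect_equal(sum(GenomicRanges::width(cnes)),
                 per_base_kept(blocks, exons))
    # no element overlaps any transcribed interval
    expect_length(GenomicRanges::findOverlaps(cnes, exons), 0)
    # idempotence: subtracting again changes nothing
    again <- subtract_transcribed(cnes, exons, min_length = 1)
    expect_equal(GenomicRanges::ranges(again), GenomicRanges::ranges(cnes))
    expect_equal(S4Vectors::mcols(again)$seq, S4Vectors::mcols(cnes)$seq)
    # masks are sliced base-for-base
    for (i in seq_along(cnes)) {
      src <- which(GenomicRanges::start(blocks) <= GenomicRanges::start(cnes)[i] &
                   GenomicRanges::end(blocks) >= GenomicRanges::end(cnes)[i])
      expect_length(src, 1)
      off <- GenomicRanges::start(cnes)[i] - GenomicRanges::start(blocks)[src] + 1
      w <- GenomicRanges::width(cnes)[i]
      expect_equal(S4Vectors::mcols(cnes)$mask[[i]],
                   S4Vectors::mcols(blocks)$mask[[src]][off:(off + w - 1)])
    }
  }
})

test_that("cne_stats reports count and mean length, flagging empty sets", {
  empty <- subtract_transcribed(
    cnes_from_seqs(character(0)),
    GenomicRanges::GRanges())
  s <- cne_stats(empty)
  expect_equal(s$count, 0)
  expect_equal(s$mean_length, 0)
  expect_true(s$empty)
  two <- cnes_from_seqs(c(random_seq(100), random_seq(200)))
  s2 <- cne_stats(two)
  expect_equal(s2$count, 2)
  expect_equal(s2$mean_length, 150)
  expect_false(s2$empty)
})

test_that("CNE sets round-trip through BED + mask + FASTA files", {
  withr::local_seed(3)
  blocks <- random_blocks()
  cnes <- subtract_transcribed(blocks, random_exons(), min_length = 20)
  dir <- withr::local_tempdir()
  write_cnes(cnes, dir)
  back <- read_cnes(dir)
  expect_equal(GenomicRanges::ranges(back), GenomicRanges::ranges(cnes))
  expect_equal(S4Vectors::mcols(back)$cne_id, S4Vectors::mcols(cnes)$cne_id)
  expect_equal(S4Vectors::mcols(back)$seq, S4Vectors::mcols(cnes)$seq)
  expect_equal(as.list(S4Vectors::mcols(back)$mask),
               as.list(S4Vectors::mcols(cnes)$mask))
  # stats recomputed from disk equal in-memory stats
  expect_equal(cne_stats(back)[1:2], cne_stats(cnes)[1:2])
})

test_that("fixture alignments round-trip: parsed masks equal the truth record", {
  fx <- small_fixture(seed = 21)
  dir <- withr::local_tempdir()
  paths <- tagscan:::.write_fixture(fx, dir)
  blocks <- read_maf(paths[["maf"]])
  expect_equal(length(blocks), nrow(fx$truth$blocks))
  expect_equal(GenomicRanges::start(blocks) - 1L, fx$truth$blocks$start0)
  got <- vapply(as.list(S4Vectors::mcols(blocks)$mask),
                tagscan:::.mask_to_rle, "")
  expect_equal(got, fx$truth$blocks$mask_rle)
  # sequences match the genome FASTA
  genome <- Biostrings::readDNAStringSet(paths[["genome"]])
  i <- which.max(GenomicRanges::width(blocks))
  chrom <- as.character(GenomicRanges::seqnames(blocks)[i])
  expect_equal(S4Vectors::mcols(blocks)$seq[i],
               as.character(Biostrings::subseq(
                 genome[[chrom]], GenomicRanges::start(blocks)[i],
                 GenomicRanges::end(blocks)[i])))
})
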