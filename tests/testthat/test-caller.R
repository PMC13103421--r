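test_that("pair filters require mapped, non-duplicate mates at MAPQ >= 20", {
  lines <- c(
    sam_line("ok", 97, "chrA", 500, 60, "50M", "chrB", 500),
    sam_line("ok", 145, "chrB", 500, 60, "50M", "chrA", 500),
    sam_line("lowq", 97, "chrA", 520, 60, "50M", "chrB", 520),
    sam_line("lowq", 145, "chrB", 520, 19, "50M", "chrA", 520),
    sam_line("edge", 97, "chrA", 540, 20, "50M", "chrB", 540),
    sam_line("edge", 145, "chrB", 540, 20, "50M", "chrA", 540),
    sam_line("dup", 97 + 1024, "chrA", 560, 60, "50M", "chrB", 560),
    sam_line("dup", 145 + 1024, "chrB", 560, 60, "50M", "chrA", 560))
  pairs <- fetch_pairs(read_alignments(write_test_sam(lines)), tiny_target)
  ok <- pass_filters(pairs, min_mapq = 20)
  expect_equal(sort(pairs$qname[ok]), c("edge", "ok"))
  expect_false(ok[pairs$qname == "lowq"])
  expect_false(ok[pairs$qname == "dup"])
})

test_that("mate-unmapped pairs are excluded from evidence", {
  ## 0x8 on read1: its mate is unmapped and yields no primary record
  lines <- c(
    sam_line("halfpair", 73, "chrA", 500, 60, "50M", "chrA", 500))
  aln <- read_alignments(write_test_sam(lines))
  pairs <- fetch_pairs(aln, tiny_target)
  expect_equal(nrow(pairs), 0L)
  expect_equal(attr(pairs, "unpaired"), "halfpair")
})

test_that("split and discordant classification follows the evidence definitions", {
  sa_into_B <- "chrB,750,+,40S60M,60,0;"
  lines <- c(
    ## read1 primary in gene A with SA into gene B, mate in gene B: split
    sam_line("split1", 97, "chrA", 691, 60, "60M40S", "chrB", 800,
             sa = sa_into_B),
    sam_line("split1", 145, "chrB", 800, 60, "100M", "chrA", 691),
    ## mates in different genes, no SA: discordant
    sam_line("disc1", 97, "chrA", 600, 60, "100M", "chrB", 600),
    sam_line("disc1", 145, "chrB", 600, 60, "100M", "chrA", 600),
    ## both mates in gene A, no SA: none
    sam_line("conc1", 99, "chrA", 600, 60, "100M", "chrA", 800),
    sam_line("conc1", 147, "chrA", 800, 60, "100M", "chrA", 600),
    ## split candidate whose mate sits in the same gene: strict excludes,
    ## lenient keeps
    sam_line("near1", 97, "chrA", 691, 60, "60M40S", "chrA", 500,
             sa = sa_into_B),
    sam_line("near1", 145, "chrA", 500, 60, "100M", "chrA", 691))
  pairs <- fetch_pairs(read_alignments(write_test_sam(lines)), tiny_target)

  strict <- classify_pair(pairs, tiny_target, mode = "strict")
  expect_equal(strict$class[strict$qname == "split1"], "split")
  expect_equal(strict$class[strict$qname == "disc1"], "discordant")
  expect_equal(strict$class[strict$qname == "conc1"], "none")
  expect_equal(strict$class[strict$qname == "near1"], "none")

  lenient <- classify_pair(pairs, tiny_target, mode = "lenient")
  expect_equal(lenient$class[lenient$qname == "near1"], "split")

  ## SA entries below the MAPQ threshold do not qualify
  weak <- sub("60,0;", "10,0;", sa_into_B, fixed = TRUE)
  lines2 <- c(
    sam_line("weak", 97, "chrA", 691, 60, "60M40S", "chrB", 800, sa = weak),
    sam_line("weak", 145, "chrB", 800, 60, "100M", "chrA", 691))
  p2 <- fetch_pairs(read_alignments(write_test_sam(lines2)), tiny_target)
  cls2 <- classify_pair(p2, tiny_target, mode = "strict")
  expect_equal(cls2$class, "discordant")
})

test_that("clip boundaries follow the leading/trailing soft-clip rule", {
  expect_equal(clip_boundary(1001, "50S100M"), 1001L)
  expect_equal(clip_boundary(2001, "100M50S"), 2100L)
  ## deletion consumes reference: 500 + (40 + 5 + 60) - 1
  expect_equal(clip_boundary(500, "40M5D60M10S"), 604L)
  ## hard clips count like soft clips for side determination
  expect_equal(clip_boundary(1001, "50H100M"), 1001L)
  expect_error(clip_boundary(100, "100M"), "not a split alignment")
})

test_that("breakpoints are located from primary and SA clip boundaries", {
  sa <- parse_sa_tag("chrB,750,+,60S40M,60,0;")
  bp <- locate_breakpoint("chrA", 691, "60M40S", sa, tiny_target)
  expect_equal(bp, c(posA = 750L, posB = 750L))
  ## swapped gene sides order the coordinates by gene, not by record
  sa2 <- parse_sa_tag("chrA,691,+,60M40S,60,0;")
  bp2 <- locate_breakpoint("chrB", 750, "60S40M", sa2, tiny_target)
  expect_equal(bp2, c(posA = 750L, posB = 750L))
})

test_that("call_fusion recovers the planted junction and partitions evidence", {
  cfg <- sim_config(fraction = 1, depth = 50, seed = 31)
  sim <- simulate_reads(tiny_genome, tiny_allele, cfg)
  aln <- sim_alignments(sim)
  call <- call_fusion(aln, tiny_target, mode = "lenient")

  expect_equal(call$total_count, call$split_count + call$discordant_count)
  expect_gt(call$split_count, 0)
  expect_true(call$detected)
  ## modal breakpoint is exactly the planted coordinate pair
  expect_equal(call$breakpoints$posA[1], 750)
  expect_equal(call$breakpoints$posB[1], 750)
  expect_equal(sum(call$breakpoints$support), call$split_count)

  ## symmetry: swapping gene A and gene B preserves counts and swaps
  ## breakpoint coordinates
  swapped <- target_pair(tiny_target$geneB, tiny_target$geneA)
  call_s <- call_fusion(aln, swapped, mode = "lenient")
  expect_equal(call_s$split_count, call$split_count)
  expect_equal(call_s$discordant_count, call$discordant_count)
  expect_equal(call_s$breakpoints$posA, call$breakpoints$posB)
  expect_equal(call_s$breakpoints$posB, call$breakpoints$posA)
})

test_that("fusion-free input yields an empty call, not an error", {
  cfg <- sim_config(fraction = 0, depth = 10, seed = 33)
  sim <- simulate_reads(tiny_genome, NULL, cfg)
  call <- call_fusion(sim_alignments(sim), tiny_target)
  expect_equal(call$split_count, 0L)
  expect_equal(call$discordant_count, 0L)
  expect_false(call$detected)
  expect_equal(nrow(call$breakpoints), 0L)
  ## detection threshold contract
  expect_false(call$total_count >= call$detection_min)
})

test_that("raising the MAPQ threshold never increases any count", {
  cfg <- sim_config(fraction = 1, depth = 40, seed = 37, lowmapq_rate = 0.3,
                    lowmapq_value = 10)
  sim <- simulate_reads(tiny_genome, tiny_allele, cfg)
  aln <- sim_alignments(sim)
  prev <- c(Inf, Inf, Inf)
  for (q in c(0, 20, 40, 61)) {
    call <- call_fusion(aln, tiny_target, min_mapq = q, mode = "lenient")
    now <- c(call$split_count, call$discordant_count, call$total_count)
    expect_true(all(now <= prev), info = paste("min_mapq", q))
    prev <- now
  }
  ## the low-MAPQ contamination is actually being filtered
  all_in <- call_fusion(aln, tiny_target, min_mapq = 0, mode = "lenient")
  strict <- call_fusion(aln, tiny_target, min_mapq = 20, mode = "lenient")
  expect_lt(strict$total_count, all_in$total_count)
})

test_that("duplicate-flagged pairs never contribute evidence", {
  cfg <- sim_config(fraction = 1, depth = 40, seed = 41, dup_rate = 0.3)
  sim <- simulate_reads(tiny_genome, tiny_allele, cfg)
  aln <- sim_alignments(sim)
  call <- call_fusion(aln, tiny_target, mode = "lenient")
  dup_q <- unique(aln$qname[aln$is_duplicate])
  expect_gt(length(dup_q), 0)
  expect_false(any(call$evidence$qname %in% dup_q))
})
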