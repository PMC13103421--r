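test_that("toy reference generation is reproducible and GC-calibrated", {
  g1 <- make_toy_reference(lengths = c(50000, 50000), seed = 1)
  g2 <- make_toy_reference(lengths = c(50000, 50000), seed = 1)
  expect_identical(g1$contigs, g2$contigs)
  expect_true(all(strsplit(g1$contigs[[1]], "")[[1]] %in% c("A", "C", "G", "T")))

  ## binomial oracle: observed GC within 3 s.d. of n * gc
  g <- make_toy_reference(lengths = c(50000, 50000), gc = 0.5, seed = 7)
  n <- 50000
  gc_obs <- sum(strsplit(g$contigs[[1]], "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc_obs - n * 0.5), 3 * sqrt(n * 0.25))

  pure <- make_toy_reference(lengths = c(1000, 1000), gc = 1, seed = 1)
  expect_true(grepl("^[GC]+$", pure$contigs[[1]]))

  expect_error(make_toy_reference(lengths = c(100, 100)), "1000")
})

test_that("planted fusion joins the retained sides with correct arithmetic", {
  al <- plant_fusion(tiny_genome, 750, 750)
  LA <- 750
  LB <- nchar(tiny_genome$contigs[[2]]) - 750 + 1
  expect_equal(nchar(al$sequence), LA + LB)
  expect_identical(substr(al$sequence, 1, LA),
                   substr(tiny_genome$contigs[[1]], 1, LA))
  expect_equal(al$junction_offset, 750)

  ## opposite orientation: downstream segment is the reverse complement
  ## of the gene-B slice up to the junction
  alo <- plant_fusion(tiny_genome, 750, 750, orientation = "opposite")
  down <- substr(alo$sequence, 751, nchar(alo$sequence))
  sliceB <- substr(tiny_genome$contigs[[2]], 1, 750)
  expect_identical(down, wgbsfuse:::revcomp(sliceB))

  expect_error(plant_fusion(tiny_genome, 100, 750), "outside gene")
})

test_that("fragment simulation hits the configured dilution and spanning rates", {
  cfg <- sim_config(fraction = 0, depth = 10, seed = 3)
  fr0 <- simulate_fragments(tiny_genome, NULL, cfg)
  expect_equal(sum(fr0$origin == "fusion"), 0L)
  expect_false(any(fr0$spans_junction))

  ## dilution calibration: binomial 3 s.d. around fraction
  cfg4 <- sim_config(fraction = 0.4, depth = 80, seed = 8)
  fr4 <- simulate_fragments(tiny_genome, tiny_allele, cfg4)
  n <- nrow(fr4)
  expect_lt(abs(sum(fr4$origin == "fusion") - 0.4 * n),
            3 * sqrt(n * 0.4 * 0.6))

  ## spanning-rate enumeration oracle at constant fragment length:
  ## starts 1..Lf-fl+1 are uniform and exactly fl-1 of them span
  fl <- 300
  cfg1 <- sim_config(fraction = 1, fragment_mean = fl, fragment_sd = 0,
                     depth = 100, seed = 9)
  fr1 <- simulate_fragments(tiny_genome, tiny_allele, cfg1, n = 10000)
  Lf <- nchar(tiny_allele$sequence)
  p <- (fl - 1) / (Lf - fl + 1)
  expect_lt(abs(sum(fr1$spans_junction) - 10000 * p),
            3 * sqrt(10000 * p * (1 - p)))
  expect_true(all(fr1$origin[fr1$spans_junction] == "fusion"))
  expect_true(all(is.na(fr1$bpA) == !fr1$spans_junction))

  ## determinism
  expect_identical(fr1, simulate_fragments(tiny_genome, tiny_allele, cfg1,
                                           n = 10000))
})

test_that("bisulfite conversion follows context, rate and strand rules", {
  frag <- paste(rep(c("A", "C", "G", "T"), 50), collapse = "")
  cfg_full <- sim_config(conversion_rate = 1, meth_cpg = 0, meth_chg = 0,
                         meth_chh = 0, read_length = 100)
  rp <- bisulfite_convert(frag, "top", cfg_full, seed = 1)
  expect_false(grepl("C", rp$converted))

  cfg_none <- sim_config(conversion_rate = 0, meth_cpg = 0, meth_chg = 0,
                         meth_chh = 0, read_length = 100)
  rp0 <- bisulfite_convert(frag, "top", cfg_none, seed = 1)
  expect_identical(rp0$read1, substr(frag, 1, 100))

  ## binomial oracle at 0.99 over >= 10^4 cytosines
  set.seed(11)
  long <- paste(sample(c("A", "C", "G", "T"), 48000, replace = TRUE),
                collapse = "")
  n_c <- lengths(regmatches(long, gregexpr("C", long)))
  expect_gte(n_c, 1e4)
  cfg99 <- sim_config(conversion_rate = 0.99, meth_cpg = 0, meth_chg = 0,
                      meth_chh = 0, read_length = 100)
  conv <- bisulfite_convert(long, "top", cfg99, seed = 2)$converted
  n_left <- lengths(regmatches(conv, gregexpr("C", conv)))
  obs <- (n_c - n_left) / n_c
  expect_lt(abs(obs - 0.99), 3 * sqrt(0.99 * 0.01 / n_c))

  ## bottom strand: read 1 derives from the reverse complement, so the
  ## fully converted read carries no G in source-forward orientation
  rpb <- bisulfite_convert(frag, "bottom", cfg_full, seed = 3)
  expect_false(grepl("C", rpb$converted))
  expect_identical(bisulfite_convert(frag, "bottom", cfg_none, seed = 4)$read1,
                   substr(wgbsfuse:::revcomp(frag), 1, 100))
})

test_that("FASTQ output is record-synchronized and round-trips", {
  cfg <- sim_config(fraction = 0, depth = 1, seed = 6)
  sim <- simulate_reads(tiny_genome, NULL, cfg, n = 3)
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  emit_fastq(sim, f1, f2)
  l1 <- readLines(f1); l2 <- readLines(f2)
  expect_length(l1, 12L)
  expect_length(l2, 12L)
  expect_identical(l1[seq(1, 12, 4)], l2[seq(1, 12, 4)])
  expect_identical(l1[seq(2, 12, 4)], sim$reads$read1)
  expect_identical(l2[seq(2, 12, 4)], sim$reads$read2)
})

test_that("simulation outputs are byte-identical under a fixed seed", {
  cfg <- sim_config(fraction = 0.5, depth = 15, seed = 21, dup_rate = 0.05,
                    n_chimeric = 3)
  out1 <- tempfile(); out2 <- tempfile()
  simulate_wgbs(out1, cfg, genome = tiny_genome, allele = tiny_allele)
  simulate_wgbs(out2, cfg, genome = tiny_genome, allele = tiny_allele)
  for (f in c("reads_1.fastq", "reads_2.fastq", "alignments.sam", "truth.tsv"))
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)),
                     info = f)
})

test_that("oracle SAM encodes split reads with reciprocal SA tags", {
  cfg <- sim_config(fraction = 1, depth = 60, seed = 13)
  sim <- simulate_reads(tiny_genome, tiny_allele, cfg)
  sam <- tempfile(fileext = ".sam")
  emit_oracle_sam(sim, sam, min_clip = 20)
  aln <- read_alignments(sam)
  segs <- read_segments(sim)
  rl <- cfg$read_length

  eligible <- segs[segs$crossing & pmin(segs$lenA, segs$lenB) >= 20, ]
  expect_gt(nrow(eligible), 10)

  ## oracle consistency: each eligible crossing read gives exactly one
  ## SA-tagged primary + one supplementary, cross-referencing each other
  for (k in seq_len(nrow(eligible))) {
    e <- eligible[k, ]
    mate_flag <- if (e$mate == 1) aln$is_read1 else aln$is_read2
    rec <- aln[aln$qname == e$id & mate_flag, ]
    expect_equal(nrow(rec), 2L, info = e$id)
    prim <- rec[rec$is_primary, ]; supp <- rec[!rec$is_primary, ]
    expect_equal(nrow(prim), 1L)
    expect_false(is.na(prim$sa))
    ## CIGAR lengths follow the junction arithmetic
    expect_setequal(c(cigar_ref_span(prim$cigar), cigar_ref_span(supp$cigar)),
                    c(e$lenA, e$lenB))
    ## reciprocal SA cross-reference
    sa_p <- parse_sa_tag(prim$sa)
    expect_equal(sa_p$pos, supp$pos)
    sa_s <- parse_sa_tag(supp$sa)
    expect_equal(sa_s$pos, prim$pos)
  }

  ## short-side absorption: crossing reads under min_clip get one record,
  ## a clip, and no SA tag
  short <- segs[segs$crossing & pmin(segs$lenA, segs$lenB) < 20, ]
  if (nrow(short) > 0) {
    e <- short[1, ]
    mate_flag <- if (e$mate == 1) aln$is_read1 else aln$is_read2
    rec <- aln[aln$qname == e$id & mate_flag, ]
    expect_equal(nrow(rec), 1L)
    expect_true(rec$is_primary)
    expect_true(is.na(rec$sa))
    cl <- clip_lengths(rec$cigar)
    expect_equal(max(cl), min(e$lenA, e$lenB))
  }

  ## non-spanning pairs carry no SA tag on either record
  non <- sim$fragments$id[!sim$fragments$spans_junction][1:20]
  expect_true(all(is.na(aln$sa[aln$qname %in% non])))
})

test_that("oracle read sequences match the reference where conversion is off", {
  cfg <- sim_config(fraction = 1, depth = 30, seed = 17, conversion_rate = 0,
                    meth_cpg = 0, meth_chg = 0, meth_chh = 0)
  sim <- simulate_reads(tiny_genome, tiny_allele, cfg)
  aln <- sim_alignments(sim)
  prim <- aln[aln$is_primary, ]
  ## stored SEQ, clipped portions removed, must equal the reference slice
  set.seed(1)
  for (i in sample(nrow(prim), 40)) {
    laid <- as.character(GenomicAlignments::sequenceLayer(
      Biostrings::DNAStringSet(prim$seq[i]), prim$cigar[i]))
    refsl <- substr(tiny_genome$contigs[[prim$contig[i]]], prim$pos[i],
                    prim$pos[i] + nchar(laid) - 1L)
    expect_identical(laid, refsl, info = paste(prim$qname[i], prim$cigar[i]))
  }
})

test_that("opposite-orientation junctions localize to the planted coordinates", {
  alo <- plant_fusion(tiny_genome, 750, 750, orientation = "opposite")
  cfg <- sim_config(fraction = 1, depth = 60, seed = 19)
  sim <- simulate_reads(tiny_genome, alo, cfg)
  call <- call_fusion(sim_alignments(sim), tiny_target, mode = "lenient")
  expect_gt(call$split_count, 5)
  expect_equal(call$breakpoints$posA[1], 750)
  expect_equal(call$breakpoints$posB[1], 750)
})

test_that("duplicate and low-MAPQ fragments carry the configured marks", {
  cfg <- sim_config(fraction = 0, depth = 20, seed = 23, dup_rate = 0.2,
                    lowmapq_rate = 0.3, lowmapq_value = 5)
  sim <- simulate_reads(tiny_genome, NULL, cfg)
  aln <- sim_alignments(sim)
  expect_gt(sum(aln$is_duplicate), 0)
  expect_gt(sum(aln$mapq == 5), 0)
  ## duplicates duplicate an existing fragment's coordinates
  dups <- aln[aln$is_duplicate & aln$is_read1 & aln$is_primary, ]
  orig <- aln[!aln$is_duplicate & aln$is_read1 & aln$is_primary, ]
  expect_true(all(dups$pos %in% orig$pos))
})
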