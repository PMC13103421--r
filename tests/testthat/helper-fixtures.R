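## Shared fixtures, built in code at test time.

## compact genome: 1.5 kb contigs, genes chrA:301-1200 / chrB:301-1200,
## junction planted mid-gene so junction-covering fragments are frequent
tiny_genome <- make_toy_reference(lengths = c(1500L, 1500L), seed = 5L)
tiny_allele <- plant_fusion(tiny_genome, 750L, 750L)
tiny_target <- genome_targets(tiny_genome)

## run a simulation through SAM serialization and back
sim_alignments <- function(sim, min_clip = 20L) {
  sam <- tempfile(fileext = ".sam")
  on.exit(unlink(sam))
  emit_oracle_sam(sim, sam, min_clip = min_clip)
  read_alignments(sam)
}

## write a SAM file from hand-built record lines over the tiny genome
write_test_sam <- function(lines,
                           contigs = c(chrA = 1500L, chrB = 1500L)) {
  path <- tempfile(fileext = ".sam")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", names(contigs), contigs),
               lines), path)
  path
}

## build one SAM record line; seq defaults to a run of A matching the
## query width of the CIGAR
sam_line <- function(qname, flag, contig, pos, mapq, cigar,
                     mate_contig = "=", mate_pos = 0L, sa = NULL) {
  qw <- GenomicAlignments::cigarWidthAlongQuerySpace(cigar)
  seq <- strrep("A", qw)
  line <- paste(qname, flag, contig, pos, mapq, cigar, mate_contig,
                mate_pos, 0, seq, strrep("F", qw), sep = "\t")
  if (!is.null(sa)) line <- paste0(line, "\tSA:Z:", sa)
  line
}

## independent brute-force CIGAR interpreter (character-walk oracle)
bf_cigar <- function(cigar) {
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1]])
  ops <- regmatches(cigar, gregexpr("[A-Z=]", cigar))[[1]]
  ref <- sum(lens[ops %in% c("M", "D", "N", "=", "X")])
  query <- sum(lens[ops %in% c("M", "I", "S", "=", "X")])
  clip <- ops %in% c("S", "H")
  lead <- 0L
  for (k in seq_along(ops)) { if (!clip[k]) break; lead <- lead + lens[k] }
  trail <- 0L
  for (k in rev(seq_along(ops))) { if (!clip[k]) break; trail <- trail + lens[k] }
  list(ref = ref, query = query, leading = lead, trailing = trail)
}

## random valid CIGAR: optional clips around a core of M/I/D segments
random_cigar <- function() {
  core_ops <- sample(c("M", "I", "D", "=", "X"), sample(1:5, 1),
                     replace = TRUE)
  ## ensure at least one reference-consuming, query-consuming anchor
  core_ops <- c("M", core_ops)
  core <- paste0(sample(1:80, length(core_ops), replace = TRUE), core_ops,
                 collapse = "")
  lead <- if (runif(1) < 0.5) paste0(sample(1:50, 1), "S") else ""
  trail <- if (runif(1) < 0.5) paste0(sample(1:50, 1), "S") else ""
  paste0(lead, core, trail)
}
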