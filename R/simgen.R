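## Synthetic WGBS fusion data: toy two-gene references, planted fusion
## junctions, directional bisulfite-converted paired-end reads at a
## configurable dilution, and oracle alignments with per-fragment truth.
##
## The simulator stands in for the wet-lab dilution series and for a
## bisulfite-aware split-capable aligner: junction-spanning reads receive
## a soft-clipped primary record plus a hard-clipped supplementary record
## with reciprocal SA tags, exactly as downstream fusion calling expects.

#' Generate a toy two-contig reference with one gene per contig
#'
#' Each contig carries a single annotated gene interval spanning its
#' central portion; the two genes live on distinct contigs so any read
#' pair joining them is unambiguously chimeric.
#'
#' @param lengths Integer vector of two contig lengths (>= 1000).
#' @param gc GC content in (0, 1].
#' @param seed Integer seed; the same seed reproduces the same genome.
#' @param gene_margin Fraction of each contig left gene-free on either
#'   side (default 0.2, so the gene covers the central 60%).
#' @return An object of class `"toy_genome"`: a list with `contigs`
#'   (named character vector of uppercase DNA) and `genes` (a
#'   `data.frame` with `name`, `contig`, `start`, `end`, `strand`).
#' @examples
#' g <- make_toy_reference(lengths = c(5000, 5000), seed = 1)
#' g$genes
#' @export
make_toy_reference <- function(lengths = c(50000L, 50000L), gc = 0.42,
                               seed = 1L, gene_margin = 0.2) {
  if (length(lengths) != 2L || any(lengths < 1000L))
    stop("need two contig lengths >= 1000 to host gene intervals", call. = FALSE)
  if (!is.numeric(gc) || gc <= 0 || gc > 1)
    stop("'gc' must be in (0, 1]", call. = FALSE)
  lengths <- as.integer(lengths)
  contigs <- withr::with_seed(seed, {
    vapply(lengths, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
                   prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
            collapse = "")
    }, character(1))
  })
  names(contigs) <- c("chrA", "chrB")
  genes <- data.frame(
    name = c("geneA", "geneB"),
    contig = c("chrA", "chrB"),
    start = as.integer(floor(gene_margin * lengths)) + 1L,
    end = as.integer(floor((1 - gene_margin) * lengths)),
    strand = "+",
    stringsAsFactors = FALSE)
  if (any(genes$start >= genes$end))
    stop("contigs too small to host a gene interval", call. = FALSE)
  structure(list(contigs = contigs, genes = genes), class = "toy_genome")
}

#' @export
print.toy_genome <- function(x, ...) {
  cat("Toy genome:", paste(sprintf("%s (%d bp)", names(x$contigs),
                                   nchar(x$contigs)), collapse = ", "), "\n")
  print(x$genes)
  invisible(x)
}

#' Target pair corresponding to a toy genome's gene annotation
#' @param genome A `"toy_genome"`.
#' @return A `"target_pair"` over the two annotated genes.
#' @export
genome_targets <- function(genome) {
  g <- genome$genes
  target_pair(region(g$name[1], g$contig[1], g$start[1], g$end[1]),
              region(g$name[2], g$contig[2], g$start[2], g$end[2]))
}

#' Plant a fusion junction between the two toy genes
#'
#' Constructs the fused allele joining gene A's retained left side (contig
#' start up to and including `posA`) with gene B's retained side starting
#' at `posB`.  With `orientation = "same"` the downstream segment is
#' `chrB[posB..end]` read forward; with `"opposite"` it is the reverse
#' complement of `chrB[1..posB]`, modelling a junction between opposite
#' strands.
#'
#' @param genome A `"toy_genome"`.
#' @param posA,posB 1-based junction coordinates; must fall inside the
#'   respective gene intervals.
#' @param orientation `"same"` or `"opposite"` relative strand of the
#'   joined segments.
#' @return An object of class `"fusion_allele"`: `sequence` (the fused
#'   contig), `junctionA`/`junctionB` (contig, pos, retained side),
#'   `orientation` and `junction_offset` (position of the last gene-A base
#'   within the fused contig).
#' @export
plant_fusion <- function(genome, posA, posB,
                         orientation = c("same", "opposite")) {
  orientation <- match.arg(orientation)
  g <- genome$genes
  posA <- as.integer(posA); posB <- as.integer(posB)
  if (posA < g$start[1] || posA > g$end[1])
    stop("posA (", posA, ") outside gene interval ", g$name[1], call. = FALSE)
  if (posB < g$start[2] || posB > g$end[2])
    stop("posB (", posB, ") outside gene interval ", g$name[2], call. = FALSE)
  up <- substr(genome$contigs[[1]], 1L, posA)
  down <- if (orientation == "same") {
    substr(genome$contigs[[2]], posB, nchar(genome$contigs[[2]]))
  } else {
    revcomp(substr(genome$contigs[[2]], 1L, posB))
  }
  structure(list(
    sequence = paste0(up, down),
    junctionA = list(contig = g$contig[1], pos = posA, side = "left"),
    junctionB = list(contig = g$contig[2], pos = posB,
                     side = if (orientation == "same") "right" else "left"),
    orientation = orientation,
    junction_offset = posA), class = "fusion_allele")
}

#' @export
print.fusion_allele <- function(x, ...) {
  cat(sprintf("Fusion allele: %s:%d | %s:%d (%s orientation), %d bp fused contig\n",
              x$junctionA$contig, x$junctionA$pos,
              x$junctionB$contig, x$junctionB$pos,
              x$orientation, nchar(x$sequence)))
  invisible(x)
}

#' Simulation configuration
#'
#' @param fraction Proportion of fragments drawn from the fusion allele,
#'   in \[0, 1\] (the dilution knob).
#' @param depth Target mean coverage over the two gene intervals (x).
#' @param read_length Read length in bases.
#' @param fragment_mean,fragment_sd Fragment length distribution (bases);
#'   lengths are drawn Normal and truncated below at `read_length`.
#' @param conversion_rate Probability an unmethylated cytosine reads as
#'   thymine after bisulfite conversion.
#' @param meth_cpg,meth_chg,meth_chh Methylation probabilities per
#'   cytosine context.
#' @param seq_error Per-base sequencing error probability.
#' @param seed Integer seed; identical configuration and seed give
#'   byte-identical outputs.
#' @param mapq Mapping quality assigned to uniquely placed oracle records.
#' @param lowmapq_rate Fraction of fragments whose records are assigned
#'   `lowmapq_value` instead of `mapq`, to exercise MAPQ filtering.
#' @param lowmapq_value MAPQ for contaminating low-quality fragments.
#' @param dup_rate Probability a read pair is re-emitted as an exact
#'   duplicate flagged with the SAM duplicate flag (emulating upstream
#'   duplicate marking).
#' @param n_chimeric Number of artificial chimeric read pairs injected at
#'   random non-gene positions (background noise outside the targets).
#' @return An object of class `"sim_config"` (a validated list).
#' @export
sim_config <- function(fraction = 0, depth = 30, read_length = 100L,
                       fragment_mean = 300, fragment_sd = 30,
                       conversion_rate = 0.99, meth_cpg = 0.8,
                       meth_chg = 0.02, meth_chh = 0.02, seq_error = 0,
                       seed = 1L, mapq = 60L, lowmapq_rate = 0,
                       lowmapq_value = 5L, dup_rate = 0, n_chimeric = 0L) {
  for (p in c("fraction", "conversion_rate", "meth_cpg", "meth_chg",
              "meth_chh", "seq_error", "lowmapq_rate", "dup_rate"))
    stop_if_not_prob(get(p), p)
  if (depth <= 0) stop("'depth' must be positive", call. = FALSE)
  if (read_length < 20L) stop("'read_length' must be >= 20", call. = FALSE)
  if (read_length > fragment_mean)
    warning("read_length exceeds fragment_mean; mates will overlap heavily")
  structure(list(fraction = fraction, depth = depth,
                 read_length = as.integer(read_length),
                 fragment_mean = fragment_mean, fragment_sd = fragment_sd,
                 conversion_rate = conversion_rate, meth_cpg = meth_cpg,
                 meth_chg = meth_chg, meth_chh = meth_chh,
                 seq_error = seq_error, seed = as.integer(seed),
                 mapq = as.integer(mapq), lowmapq_rate = lowmapq_rate,
                 lowmapq_value = as.integer(lowmapq_value),
                 dup_rate = dup_rate, n_chimeric = as.integer(n_chimeric)),
            class = "sim_config")
}

## --- fragment generation ---------------------------------------------------

sim_fragments_impl <- function(genome, allele, config, n = NULL) {
  genes <- genome$genes
  gene_len <- genes$end - genes$start + 1L
  rl <- config$read_length
  if (is.null(n))
    n <- ceiling(config$depth * sum(gene_len) / (2 * rl))
  n <- as.integer(n)
  if (config$fraction > 0 && is.null(allele))
    stop("a fusion allele is required when fraction > 0", call. = FALSE)

  len <- pmax(rl, as.integer(round(stats::rnorm(n, config$fragment_mean,
                                                config$fragment_sd))))
  origin <- ifelse(stats::runif(n) < config$fraction, "fusion", "wildtype")
  strand <- sample(c("top", "bottom"), n, replace = TRUE)
  start <- integer(n)
  spans <- logical(n)

  wt <- origin == "wildtype"
  if (any(wt)) {
    g <- sample(seq_len(2L), sum(wt), replace = TRUE,
                prob = gene_len / sum(gene_len))
    clen <- nchar(genome$contigs)[g]
    len[wt] <- pmin(len[wt], clen)
    lo <- pmax(1L, genes$start[g] - len[wt] + 1L)
    hi <- pmax(lo, pmin(genes$end[g], clen - len[wt] + 1L))
    start[wt] <- lo + as.integer(floor(stats::runif(sum(wt)) * (hi - lo + 1L)))
    origin_contig <- character(n)
    origin_contig[wt] <- genes$contig[g]
  } else origin_contig <- character(n)

  fu <- origin == "fusion"
  if (any(fu)) {
    Lf <- nchar(allele$sequence)
    len[fu] <- pmin(len[fu], Lf)
    start[fu] <- 1L + as.integer(floor(stats::runif(sum(fu)) * (Lf - len[fu] + 1L)))
    J <- allele$junction_offset
    spans[fu] <- start[fu] <= J & start[fu] + len[fu] - 1L >= J + 1L
    origin_contig[fu] <- "fusion"
  }

  frags <- data.frame(
    id = sprintf("frag%06d", seq_len(n)),
    origin = origin, contig = origin_contig, start = start, len = len,
    strand = strand, spans_junction = spans,
    bpA = ifelse(spans, allele$junctionA$pos %||% NA_integer_, NA_integer_),
    bpB = ifelse(spans, allele$junctionB$pos %||% NA_integer_, NA_integer_),
    contig2 = NA_character_, start2 = NA_integer_,
    stringsAsFactors = FALSE)

  if (config$n_chimeric > 0L) {
    ch <- chimeric_fragments(genome, config)
    frags <- rbind(frags, ch)
  }
  frags$mapq <- ifelse(stats::runif(nrow(frags)) < config$lowmapq_rate,
                       config$lowmapq_value, config$mapq)
  frags
}

## artificial inter-contig pairs placed outside the gene intervals,
## emulating genome-wide chimeric background noise
chimeric_fragments <- function(genome, config) {
  rl <- config$read_length
  n <- config$n_chimeric
  pick_outside <- function(ci) {
    g <- genome$genes[ci, ]
    clen <- nchar(genome$contigs[[ci]])
    lo1 <- 1L; hi1 <- g$start - 2L * rl
    lo2 <- g$end + rl; hi2 <- clen - 2L * rl
    widths <- c(max(0L, hi1 - lo1 + 1L), max(0L, hi2 - lo2 + 1L))
    if (sum(widths) == 0L)
      stop("no room outside the gene interval for chimeric injection", call. = FALSE)
    side <- sample(1:2, n, replace = TRUE, prob = widths / sum(widths))
    ifelse(side == 1L,
           lo1 + as.integer(floor(stats::runif(n) * widths[1])),
           lo2 + as.integer(floor(stats::runif(n) * widths[2])))
  }
  data.frame(
    id = sprintf("chim%06d", seq_len(n)),
    origin = "chimeric", contig = genome$genes$contig[1],
    start = pick_outside(1L), len = 2L * rl,
    strand = sample(c("top", "bottom"), n, replace = TRUE),
    spans_junction = FALSE, bpA = NA_integer_, bpB = NA_integer_,
    contig2 = genome$genes$contig[2], start2 = pick_outside(2L),
    stringsAsFactors = FALSE)
}

#' Simulate fragment coordinates and ground truth
#'
#' Draws fragments from the fusion allele with probability
#' `config$fraction` and from the wildtype gene loci otherwise; the
#' fragment count is chosen so expected coverage over the two gene
#' intervals approximates `config$depth`.  A fusion fragment is marked
#' `spans_junction` when it covers the planted junction boundary.
#'
#' @param genome A `"toy_genome"`.
#' @param allele A `"fusion_allele"`, or `NULL` when `fraction = 0`.
#' @param config A `"sim_config"`.
#' @param n Optional explicit fragment count overriding the depth-based
#'   calculation.
#' @return `data.frame` of fragments with ground-truth columns `id`,
#'   `origin`, `start`, `len`, `strand`, `spans_junction`, `bpA`, `bpB`.
#' @export
simulate_fragments <- function(genome, allele, config, n = NULL) {
  withr::with_seed(config$seed, sim_fragments_impl(genome, allele, config, n))
}

## --- bisulfite conversion --------------------------------------------------

## convert the C strand of `seq` (already oriented 5'->3' on the strand
## being converted); `f3` supplies up to 2 downstream context bases
convert_c_strand <- function(seq, f3, config) {
  b <- c(chars(seq), chars(substr(paste0(f3, "NN"), 1L, 2L)))
  n <- nchar(seq)
  idx <- which(b[seq_len(n)] == "C")
  if (length(idx)) {
    n1 <- b[idx + 1L]; n2 <- b[idx + 2L]
    ctx <- ifelse(n1 == "G", "CpG", ifelse(n2 == "G", "CHG", "CHH"))
    pm <- unname(c(CpG = config$meth_cpg, CHG = config$meth_chg,
                   CHH = config$meth_chh)[ctx])
    meth <- stats::runif(length(idx)) < pm
    conv <- !meth & (stats::runif(length(idx)) < config$conversion_rate)
    b[idx[conv]] <- "T"
  }
  paste(b[seq_len(n)], collapse = "")
}

apply_seq_error <- function(read, p) {
  if (p <= 0) return(read)
  b <- chars(read)
  hit <- which(stats::runif(length(b)) < p)
  if (length(hit)) {
    alt <- c("A", "C", "G", "T")
    b[hit] <- vapply(b[hit], function(x) sample(setdiff(alt, x), 1L),
                     character(1))
  }
  paste(b, collapse = "")
}

#' Bisulfite-convert one fragment into a directional read pair
#'
#' Models a directional (OT/OB) protocol: read 1 is sequenced from the
#' converted strand, read 2 from its complement.  Each cytosine on the
#' converted strand is first assigned methylated with its context
#' probability (CpG/CHG/CHH, context taken from the unconverted sequence
#' plus optional flanking bases), then, if unmethylated, rendered as
#' thymine with probability `conversion_rate`.
#'
#' @param fragment Fragment sequence (source-forward orientation).
#' @param strand `"top"` (forward strand converted) or `"bottom"`.
#' @param config A `"sim_config"`.
#' @param flank5,flank3 Up to two reference bases flanking the fragment,
#'   used for methylation context at the fragment edges.
#' @param seed Optional seed; without it the current RNG stream is used.
#' @return List with `read1`, `read2` (as-sequenced orientation) and
#'   `converted` (the full converted strand).
#' @export
bisulfite_convert <- function(fragment, strand = c("top", "bottom"), config,
                              flank5 = "", flank3 = "", seed = NULL) {
  strand <- match.arg(strand)
  run <- function() {
    if (strand == "bottom") {
      s <- revcomp(fragment)
      f3 <- if (nzchar(flank5)) revcomp(flank5) else ""
    } else {
      s <- fragment
      f3 <- flank3
    }
    conv <- convert_c_strand(s, f3, config)
    rl <- min(config$read_length, nchar(conv))
    r1 <- substr(conv, 1L, rl)
    r2 <- revcomp(substr(conv, nchar(conv) - rl + 1L, nchar(conv)))
    list(read1 = apply_seq_error(r1, config$seq_error),
         read2 = apply_seq_error(r2, config$seq_error),
         converted = conv)
  }
  if (!is.null(seed)) withr::with_seed(seed, run()) else run()
}

## fragment sequence (source-forward) plus 2-base flanks for context
fragment_source <- function(genome, allele, frag) {
  if (frag$origin == "fusion") {
    src <- allele$sequence
    list(seq = substr(src, frag$start, frag$start + frag$len - 1L),
         f5 = substr(src, max(1L, frag$start - 2L), frag$start - 1L),
         f3 = substr(src, frag$start + frag$len,
                     min(nchar(src), frag$start + frag$len + 1L)))
  } else if (frag$origin == "chimeric") {
    rl <- frag$len %/% 2L
    a <- genome$contigs[[frag$contig]]
    b <- genome$contigs[[frag$contig2]]
    list(seq = paste0(substr(a, frag$start, frag$start + rl - 1L),
                      substr(b, frag$start2, frag$start2 + rl - 1L)),
         f5 = substr(a, max(1L, frag$start - 2L), frag$start - 1L),
         f3 = substr(b, frag$start2 + rl,
                     min(nchar(b), frag$start2 + rl + 1L)))
  } else {
    src <- genome$contigs[[frag$contig]]
    list(seq = substr(src, frag$start, frag$start + frag$len - 1L),
         f5 = substr(src, max(1L, frag$start - 2L), frag$start - 1L),
         f3 = substr(src, frag$start + frag$len,
                     min(nchar(src), frag$start + frag$len + 1L)))
  }
}

#' Simulate a complete WGBS read set with ground truth
#'
#' Runs fragment generation, directional bisulfite conversion and
#' duplicate injection under a single seed, yielding an in-memory
#' simulation object that [emit_fastq()], [emit_oracle_sam()] and
#' [write_truth()] serialize.
#'
#' @inheritParams simulate_fragments
#' @return Object of class `"wgbs_sim"`: list with `genome`, `allele`,
#'   `config`, `fragments` (truth table) and `reads` (`id`, `read1`,
#'   `read2`, `is_dup`).
#' @export
simulate_reads <- function(genome, allele, config, n = NULL) {
  withr::with_seed(config$seed, {
    frags <- sim_fragments_impl(genome, allele, config, n)
    reads <- vector("list", nrow(frags))
    for (i in seq_len(nrow(frags))) {
      src <- fragment_source(genome, allele, frags[i, ])
      rp <- bisulfite_convert(src$seq, frags$strand[i], config,
                              flank5 = src$f5, flank3 = src$f3)
      reads[[i]] <- c(rp$read1, rp$read2)
    }
    reads <- do.call(rbind, reads)
    reads <- data.frame(id = frags$id, read1 = reads[, 1], read2 = reads[, 2],
                        is_dup = FALSE, stringsAsFactors = FALSE)
    if (config$dup_rate > 0) {
      dup <- which(stats::runif(nrow(frags)) < config$dup_rate)
      if (length(dup)) {
        dfr <- frags[dup, , drop = FALSE]
        drd <- reads[dup, , drop = FALSE]
        dfr$id <- paste0(dfr$id, "d")
        drd$id <- paste0(drd$id, "d")
        drd$is_dup <- TRUE
        frags <- rbind(frags, dfr)
        reads <- rbind(reads, drd)
      }
    }
    structure(list(genome = genome, allele = allele, config = config,
                   fragments = frags, reads = reads), class = "wgbs_sim")
  })
}

#' @export
print.wgbs_sim <- function(x, ...) {
  cat(sprintf(
    "WGBS fusion simulation: %d fragments (%d fusion-origin, %d junction-spanning), read length %d\n",
    nrow(x$fragments), sum(x$fragments$origin == "fusion"),
    sum(x$fragments$spans_junction), x$config$read_length))
  invisible(x)
}

## --- per-read truth geometry ----------------------------------------------

#' Per-read junction geometry of a simulation
#'
#' For every sequenced read, reports whether it crosses the planted
#' junction and the lengths of its gene-A and gene-B segments; the truth
#' oracle for split-read classification and breakpoint recovery.
#'
#' @param sim A `"wgbs_sim"`.
#' @return `data.frame` with `id`, `mate` (1/2), `crossing`, `lenA`,
#'   `lenB`, and `cover_start` (read start in source coordinates).
#' @export
read_segments <- function(sim) {
  fr <- sim$fragments
  rl <- sim$config$read_length
  J <- if (!is.null(sim$allele)) sim$allele$junction_offset else NA_integer_
  rows <- lapply(1:2, function(m) {
    ## read 1 is sequenced from the converted strand: for bottom-strand
    ## fragments it covers the source-forward 3' end of the fragment
    first_end <- (m == 1L) == (fr$strand == "top")
    a <- ifelse(first_end, fr$start, fr$start + fr$len - rl)
    ## chimeric fragments use virtual coordinates 1..2*read_length
    a <- ifelse(fr$origin == "chimeric", a - fr$start + 1L, a)
    b <- a + rl - 1L
    crossing <- fr$origin == "fusion" & !is.na(J) & a <= J & b >= J + 1L
    data.frame(id = fr$id, mate = m, cover_start = a,
               crossing = crossing,
               lenA = ifelse(crossing, J - a + 1L, NA_integer_),
               lenB = ifelse(crossing, b - J, NA_integer_),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$id, out$mate), , drop = FALSE]
}

## --- serialization ---------------------------------------------------------

#' Write paired FASTQ files
#'
#' @param sim A `"wgbs_sim"`.
#' @param path1,path2 Output paths for read 1 / read 2 (4-line records,
#'   record-synchronized, constant Q37 qualities).
#' @return Invisibly, `c(path1, path2)`.
#' @export
emit_fastq <- function(sim, path1, path2) {
  rd <- sim$reads
  if (nrow(rd) == 0L) stop("no reads to write", call. = FALSE)
  qual <- function(s) strrep("F", nchar(s))
  writeLines(rbind(paste0("@", rd$id), rd$read1, "+", qual(rd$read1)), path1)
  writeLines(rbind(paste0("@", rd$id), rd$read2, "+", qual(rd$read2)), path2)
  invisible(c(path1, path2))
}

#' Write the wildtype reference as FASTA
#' @param genome A `"toy_genome"`.
#' @param path Output FASTA path.
#' @export
write_reference <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome$contigs), path)
  invisible(path)
}

#' Write the per-fragment truth table as TSV
#' @param sim A `"wgbs_sim"`.
#' @param path Output TSV path.
#' @export
write_truth <- function(sim, path) {
  cols <- c("id", "origin", "spans_junction", "bpA", "bpB", "strand")
  utils::write.table(sim$fragments[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

## vectorized mapping of reads covering source-forward intervals [a, b]
## that lie entirely on one side of the junction to wildtype coordinates
map_segments_vec <- function(sim, fr, a, b) {
  al <- sim$allele
  contig <- character(nrow(fr))
  pos <- integer(nrow(fr))
  minus <- logical(nrow(fr))
  wt <- fr$origin == "wildtype"
  contig[wt] <- fr$contig[wt]; pos[wt] <- a[wt]
  ch <- fr$origin == "chimeric"
  if (any(ch)) {
    rl <- fr$len[ch] %/% 2L
    left <- b[ch] <= rl
    contig[ch] <- ifelse(left, fr$contig[ch], fr$contig2[ch])
    pos[ch] <- ifelse(left, fr$start[ch] + a[ch] - 1L,
                      fr$start2[ch] + a[ch] - rl - 1L)
  }
  fu <- fr$origin == "fusion"
  if (any(fu)) {
    J <- al$junction_offset
    sideA <- b[fu] <= J
    if (al$orientation == "same") {
      contig[fu] <- ifelse(sideA, al$junctionA$contig, al$junctionB$contig)
      pos[fu] <- ifelse(sideA, a[fu], al$junctionB$pos + a[fu] - J - 1L)
    } else {
      contig[fu] <- ifelse(sideA, al$junctionA$contig, al$junctionB$contig)
      pos[fu] <- ifelse(sideA, a[fu], al$junctionB$pos - (b[fu] - J) + 1L)
      minus[fu] <- !sideA
    }
  }
  list(contig = contig, pos = pos, minus = minus)
}

## map a read covering source-forward interval [a, b] that lies entirely on
## one side of the junction to wildtype coordinates
map_single_segment <- function(sim, frag, a, b) {
  al <- sim$allele
  if (frag$origin == "wildtype") {
    list(contig = frag$contig, pos = a, minus = FALSE, m = b - a + 1L)
  } else if (frag$origin == "chimeric") {
    rl <- frag$len %/% 2L
    if (b <= rl) list(contig = frag$contig, pos = frag$start + a - 1L,
                      minus = FALSE, m = b - a + 1L)
    else list(contig = frag$contig2, pos = frag$start2 + (a - rl - 1L),
              minus = FALSE, m = b - a + 1L)
  } else {  # fusion origin, one side of the junction
    J <- al$junction_offset
    if (b <= J) {
      list(contig = al$junctionA$contig, pos = a, minus = FALSE, m = b - a + 1L)
    } else if (al$orientation == "same") {
      list(contig = al$junctionB$contig, pos = al$junctionB$pos + (a - J - 1L),
           minus = FALSE, m = b - a + 1L)
    } else {
      list(contig = al$junctionB$contig, pos = al$junctionB$pos - (b - J) + 1L,
           minus = TRUE, m = b - a + 1L)
    }
  }
}

#' Emit oracle alignments as SAM
#'
#' Stands in for a bisulfite-aware split-capable aligner: every read is
#' placed at its true wildtype locus.  Junction-crossing reads get a
#' soft-clipped primary record for the longer segment plus a hard-clipped
#' supplementary record for the shorter one, with reciprocal SA tags
#' (`rname,pos,strand,CIGAR,mapQ,NM;`).  Segments shorter than `min_clip`
#' are absorbed into the clip without a supplementary record, mirroring
#' aligner seed-length limits.
#'
#' @param sim A `"wgbs_sim"`.
#' @param path Output SAM path.
#' @param min_clip Minimum split-segment length reported as a
#'   supplementary alignment (default 20).
#' @return Invisibly, `path`.
#' @export
emit_oracle_sam <- function(sim, path, min_clip = 20L) {
  fr <- sim$fragments
  rd <- sim$reads
  rl <- sim$config$read_length
  short <- fr$len < rl
  if (any(short))
    warning("skipping ", sum(short), " fragment(s) shorter than read_length")
  J <- if (!is.null(sim$allele)) sim$allele$junction_offset else NA_integer_
  recs <- list()
  for (m in 1:2) {
    ## read 1 of a top fragment and read 2 of a bottom fragment run along
    ## the source-forward sequence; the other mate reads its revcomp
    first_end <- (m == 1L) == (fr$strand == "top")
    a <- ifelse(first_end, fr$start, fr$start + fr$len - rl)
    a <- ifelse(fr$origin == "chimeric", a - fr$start + 1L, a)
    b <- a + rl - 1L
    read_rev <- (m == 1L) != (fr$strand == "top")
    reads <- if (m == 1L) rd$read1 else rd$read2
    crossing <- fr$origin == "fusion" & !is.na(J) & a <= J & b >= J + 1L
    idx <- which(!crossing & !short)
    if (length(idx)) {
      mp <- map_segments_vec(sim, fr[idx, , drop = FALSE], a[idx], b[idx])
      minus <- xor(read_rev[idx], mp$minus)
      recs[[length(recs) + 1L]] <- data.frame(
        id = fr$id[idx], mate = m, contig = mp$contig, pos = mp$pos,
        minus = minus,
        cigar = paste0(b[idx] - a[idx] + 1L, "M"),
        seq = ifelse(minus, revcomp(reads[idx]), reads[idx]),
        suppl = FALSE, sa = NA_character_, stringsAsFactors = FALSE)
    }
    for (i in which(crossing & !short)) {
      recs[[length(recs) + 1L]] <-
        make_read_records(sim, fr[i, ], m, reads[i], read_rev[i], a[i], b[i],
                          TRUE, min_clip)
    }
  }
  recs <- do.call(rbind, recs)
  ## mate fields from each mate's primary record
  prim <- recs[!recs$suppl, ]
  key <- paste(recs$id, 3L - recs$mate)
  pidx <- match(key, paste(prim$id, prim$mate))
  recs$mate_contig <- prim$contig[pidx]
  recs$mate_pos <- prim$pos[pidx]
  recs$mate_minus <- prim$minus[pidx]
  fr_idx <- match(recs$id, fr$id)
  dup <- rd$is_dup[match(recs$id, rd$id)]
  proper <- fr$origin[fr_idx] == "wildtype"
  flag <- 1L +
    ifelse(proper, 2L, 0L) +
    ifelse(recs$minus, 16L, 0L) +
    ifelse(recs$mate_minus, 32L, 0L) +
    ifelse(recs$mate == 1L, 64L, 128L) +
    ifelse(dup, 1024L, 0L) +
    ifelse(recs$suppl, 2048L, 0L)
  opt <- ifelse(is.na(recs$sa), "", paste0("\tSA:Z:", recs$sa))
  lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t0\t%s\t%s%s",
                   recs$id, flag, recs$contig, recs$pos,
                   fr$mapq[fr_idx], recs$cigar, recs$mate_contig,
                   recs$mate_pos, recs$seq, strrep("F", nchar(recs$seq)), opt)
  header <- c("@HD\tVN:1.6\tSO:unsorted",
              sprintf("@SQ\tSN:%s\tLN:%d", names(sim$genome$contigs),
                      nchar(sim$genome$contigs)),
              "@PG\tID:wgbsfuse\tPN:wgbsfuse")
  writeLines(c(header, lines), path)
  invisible(path)
}

## build the SAM record(s) for one read; returns a small data.frame
make_read_records <- function(sim, frag, mate, read, read_rev, a, b,
                              crossing, min_clip) {
  al <- sim$allele
  mapq <- frag$mapq
  rec <- function(contig, pos, minus, cigar, seq, suppl, sa = NA_character_) {
    data.frame(id = frag$id, mate = mate, contig = contig, pos = pos,
               minus = minus, cigar = cigar, seq = seq, suppl = suppl,
               sa = sa, stringsAsFactors = FALSE)
  }
  if (!crossing) {
    mp <- map_single_segment(sim, frag, a, b)
    minus <- xor(read_rev, mp$minus)
    stored <- if (minus) revcomp(read) else read
    return(rec(mp$contig, mp$pos, minus, paste0(mp$m, "M"), stored, FALSE))
  }
  ## junction-crossing read: A segment [a..J], B segment [J+1..b]
  J <- al$junction_offset
  lenA <- J - a + 1L
  lenB <- b - J
  ## A side always maps forward to chrA; stored orientation for the A
  ## record is the source-forward read sequence
  storedA <- if (read_rev) revcomp(read) else read
  recA <- list(contig = al$junctionA$contig, pos = a,
               minus = xor(read_rev, FALSE),
               cigar = sprintf("%dM%dS", lenA, lenB),
               stored = storedA, m_off = 0L, m_len = lenA)
  if (al$orientation == "same") {
    recB <- list(contig = al$junctionB$contig, pos = al$junctionB$pos,
                 minus = xor(read_rev, FALSE),
                 cigar = sprintf("%dS%dM", lenA, lenB),
                 stored = storedA, m_off = lenA, m_len = lenB)
  } else {
    recB <- list(contig = al$junctionB$contig,
                 pos = al$junctionB$pos - lenB + 1L,
                 minus = xor(read_rev, TRUE),
                 cigar = sprintf("%dM%dS", lenB, lenA),
                 stored = revcomp(storedA), m_off = 0L, m_len = lenB)
  }
  primary_is_A <- lenA >= lenB
  pr <- if (primary_is_A) recA else recB
  sp <- if (primary_is_A) recB else recA
  if (min(lenA, lenB) < min_clip) {
    ## short side absorbed into the clip: single primary, no SA
    return(rec(pr$contig, pr$pos, pr$minus, pr$cigar, pr$stored, FALSE))
  }
  sa_of <- function(x) sprintf("%s,%d,%s,%s,%d,0;", x$contig, x$pos,
                               if (x$minus) "-" else "+", x$cigar, mapq)
  sp_cigar_hard <- gsub("S", "H", sp$cigar, fixed = TRUE)
  sp_seq <- substr(sp$stored, sp$m_off + 1L, sp$m_off + sp$m_len)
  rbind(
    rec(pr$contig, pr$pos, pr$minus, pr$cigar, pr$stored, FALSE, sa_of(sp)),
    rec(sp$contig, sp$pos, sp$minus, sp_cigar_hard, sp_seq, TRUE, sa_of(pr)))
}

#' Run the simulator and serialize all artifacts
#'
#' Convenience wrapper: builds (or accepts) a toy genome and fusion
#' allele, simulates reads, and writes the reference FASTA, paired FASTQ,
#' oracle SAM and truth TSV into `out_dir`.
#'
#' @param out_dir Output directory (created if missing).
#' @param config A `"sim_config"`.
#' @param genome Optional `"toy_genome"`; a default 50 kb toy genome is
#'   generated from `config$seed` when omitted.
#' @param allele Optional `"fusion_allele"`; defaults to a junction at the
#'   midpoint of each gene.
#' @param n Optional explicit fragment count.
#' @param min_clip Passed to [emit_oracle_sam()].
#' @return Invisibly, a list with the simulation object and file paths.
#' @export
simulate_wgbs <- function(out_dir, config, genome = NULL, allele = NULL,
                          n = NULL, min_clip = 20L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(genome)) genome <- make_toy_reference(seed = config$seed)
  if (is.null(allele) && config$fraction > 0) {
    g <- genome$genes
    allele <- plant_fusion(genome, (g$start[1] + g$end[1]) %/% 2L,
                           (g$start[2] + g$end[2]) %/% 2L)
  }
  sim <- simulate_reads(genome, allele, config, n)
  paths <- list(
    reference = file.path(out_dir, "reference.fa"),
    fastq1 = file.path(out_dir, "reads_1.fastq"),
    fastq2 = file.path(out_dir, "reads_2.fastq"),
    sam = file.path(out_dir, "alignments.sam"),
    truth = file.path(out_dir, "truth.tsv"))
  write_reference(genome, paths$reference)
  emit_fastq(sim, paths$fastq1, paths$fastq2)
  emit_oracle_sam(sim, paths$sam, min_clip = min_clip)
  write_truth(sim, paths$truth)
  invisible(list(sim = sim, paths = paths))
}
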