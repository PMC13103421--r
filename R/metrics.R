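## Supporting metrics around the fusion call: breakpoint-flanking depth
## profiles, seeded read-pair downsampling, genome-wide chimeric-pair
## background quantification, bisulfite conversion-rate QC and replicate
## concordance.

primary_mapped <- function(aln, keep_dup = FALSE) {
  keep <- aln$is_primary & !aln$is_unmapped
  if (!keep_dup) keep <- keep & !aln$is_duplicate
  aln[keep, , drop = FALSE]
}

#' Binned depth profile over a region
#'
#' Mean aligned-base coverage per bin from primary, non-duplicate
#' records.  Only reference-consuming aligned bases count: soft- and
#' hard-clipped read portions contribute nothing, which is what produces
#' the characteristic coverage drop flanking a fusion breakpoint.
#'
#' @param alignments Alignment `data.frame` from [read_alignments()].
#' @param region A region from [region()].
#' @param bin_size Bin width in bases (>= 1).
#' @return Object of class `"depth_profile"`: the region, bin size and a
#'   `bins` table (`start`, `end`, `width`, `depth`).
#' @export
depth_profile <- function(alignments, region, bin_size = 1000L) {
  if (bin_size < 1L) stop("'bin_size' must be >= 1", call. = FALSE)
  clens <- attr(alignments, "contig_lengths")
  if (!is.null(clens) && region$contig %in% names(clens) &&
      region$end > clens[[region$contig]])
    stop("region extends beyond contig ", region$contig, call. = FALSE)
  sub <- primary_mapped(alignments)
  sub <- sub[sub$contig == region$contig, , drop = FALSE]
  starts <- seq.int(region$start, region$end, by = bin_size)
  ends <- pmin(starts + bin_size - 1L, region$end)
  if (nrow(sub) == 0L) {
    cov <- S4Vectors::Rle(0L, region$end)
  } else {
    ga <- GenomicAlignments::GAlignments(
      seqnames = S4Vectors::Rle(factor(sub$contig)),
      pos = as.integer(sub$pos), cigar = sub$cigar,
      strand = S4Vectors::Rle(factor(ifelse(sub$is_reverse, "-", "+"),
                                     levels = c("+", "-", "*"))))
    cov <- GenomicAlignments::coverage(ga, drop.D.ranges = TRUE)[[1]]
    if (length(cov) < region$end)
      cov <- c(cov, S4Vectors::Rle(0L, region$end - length(cov)))
  }
  v <- IRanges::Views(cov, start = starts, end = ends)
  structure(list(region = region, bin_size = as.integer(bin_size),
                 bins = data.frame(start = starts, end = ends,
                                   width = ends - starts + 1L,
                                   depth = IRanges::viewMeans(v))),
            class = "depth_profile")
}

#' @export
print.depth_profile <- function(x, ...) {
  cat(sprintf("Depth profile %s:%d-%d, %d bins of %d bp, mean depth %.2f\n",
              x$region$contig, x$region$start, x$region$end,
              nrow(x$bins), x$bin_size,
              stats::weighted.mean(x$bins$depth, x$bins$width)))
  invisible(x)
}

#' @export
plot.depth_profile <- function(x, ...) {
  graphics::plot((x$bins$start + x$bins$end) / 2, x$bins$depth, type = "h",
                 xlab = sprintf("%s position", x$region$contig),
                 ylab = "mean depth", ...)
  invisible(x)
}

#' Downsample read pairs by seeded qname hash
#'
#' Keeps each qname -- both mates and any supplementary records -- with
#' probability `fraction`, decided by a seeded 32-bit hash of the read
#' name so the subset is reproducible and mate consistency is preserved.
#'
#' @param alignments Alignment `data.frame`.
#' @param fraction Keep probability in (0, 1].
#' @param seed Integer hash seed.
#' @return The subset `data.frame` (attributes preserved).
#' @export
downsample_pairs <- function(alignments, fraction, seed = 1L) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("'fraction' must be in (0, 1]", call. = FALSE)
  if (fraction == 1) return(alignments)
  h <- digest::digest2int(alignments$qname, seed = as.integer(seed))
  u <- (as.numeric(h) + 2^31) / 2^32
  out <- alignments[u < fraction, , drop = FALSE]
  attr(out, "contig_lengths") <- attr(alignments, "contig_lengths")
  out
}

#' Genome-wide versus target-region chimeric pair counts
#'
#' Counts filtered primary read pairs that look fusion-like anywhere in
#' the genome: inter-contig mates, intra-contig mates separated by more
#' than `min_distance`, or a mate carrying an SA entry across such a
#' distance.  Counts are partitioned into pairs whose both ends lie
#' within the target regions versus all others, mirroring the
#' target-region/background contrast used to assess noise.
#'
#' @param alignments Alignment `data.frame`.
#' @param target A `"target_pair"`.
#' @param min_mapq MAPQ threshold for both mates.
#' @param min_distance Intra-contig separation beyond which a pair is
#'   considered chimeric (default 1 Mb).
#' @return Object of class `"background_scan"`: `inside`, `outside`,
#'   `total` counts.
#' @export
background_scan <- function(alignments, target, min_mapq = 20L,
                            min_distance = 1e6) {
  if (min_distance < 0) stop("'min_distance' must be >= 0", call. = FALSE)
  prim <- primary_mapped(alignments)
  r1 <- prim[prim$is_read1, , drop = FALSE]
  r2 <- prim[prim$is_read2, , drop = FALSE]
  qn <- intersect(r1$qname, r2$qname)
  r1 <- r1[match(qn, r1$qname), , drop = FALSE]
  r2 <- r2[match(qn, r2$qname), , drop = FALSE]
  ok <- r1$mapq >= min_mapq & r2$mapq >= min_mapq &
    !r1$mate_unmapped & !r2$mate_unmapped
  r1 <- r1[ok, , drop = FALSE]; r2 <- r2[ok, , drop = FALSE]
  sa_far <- function(rec) {
    if (is.na(rec$sa) || !nzchar(rec$sa)) return(FALSE)
    e <- parse_sa_tag(rec$sa)
    e <- e[e$mapq >= min_mapq, , drop = FALSE]
    any(e$contig != rec$contig | abs(e$pos - rec$pos) > min_distance)
  }
  n <- nrow(r1)
  chim <- logical(n)
  for (i in seq_len(n)) {
    chim[i] <- r1$contig[i] != r2$contig[i] ||
      abs(r1$pos[i] - r2$pos[i]) > min_distance ||
      sa_far(r1[i, ]) || sa_far(r2[i, ])
  }
  in_targets <- function(rec) {
    end <- rec$pos + cigar_ref_span(rec$cigar) - 1L
    overlaps_region(rec$contig, rec$pos, end, target$geneA) |
      overlaps_region(rec$contig, rec$pos, end, target$geneB)
  }
  inside <- chim & in_targets(r1) & in_targets(r2)
  structure(list(inside = sum(inside), outside = sum(chim & !inside),
                 total = sum(chim), min_distance = min_distance),
            class = "background_scan")
}

#' @export
print.background_scan <- function(x, ...) {
  cat(sprintf(
    "Chimeric read pairs: %d inside target region, %d genome-wide background (total %d)\n",
    x$inside, x$outside, x$total))
  invisible(x)
}

#' Bisulfite conversion-rate QC
#'
#' For every reference cytosine covered by a read, counts converted
#' (read T at a reference C for top-strand reads; read A at a reference G
#' for bottom-strand reads) versus retained observations, aggregated by
#' context (CpG, CHG, CHH) inferred from the reference trinucleotide.
#' The conversion strand of each record follows the directional-library
#' rule: read 1 on the forward strand (or read 2 on the reverse) observes
#' the original top strand.
#'
#' On fully unmethylated control sequence (lambda-style spike-in) the
#' all-context rate estimates the conversion efficiency; on CpG-methylated
#' control sequence (pUC19-style) use [cpg_retention()].
#'
#' @param alignments Alignment `data.frame` with `seq` populated.
#' @param reference Named character vector, `DNAStringSet` or FASTA path.
#' @param contig_filter Optional contig names to restrict to (e.g. a
#'   spike-in contig).
#' @return Object of class `"conversion_report"`: a `data.frame` with
#'   rows CpG, CHG, CHH and all; columns `context`, `converted`, `total`,
#'   `rate`.
#' @export
conversion_rate <- function(alignments, reference, contig_filter = NULL) {
  ref <- load_reference(reference)
  sub <- primary_mapped(alignments)
  if (!is.null(contig_filter))
    sub <- sub[sub$contig %in% contig_filter, , drop = FALSE]
  missing <- setdiff(unique(sub$contig), names(ref))
  if (length(missing))
    stop("reference sequence missing for contig(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  counts <- matrix(0L, nrow = 3, ncol = 2,
                   dimnames = list(c("CpG", "CHG", "CHH"),
                                   c("converted", "retained")))
  for (ct in unique(sub$contig)) {
    rows <- which(sub$contig == ct)
    refb <- chars(ref[[ct]])
    ctx <- context_codes(refb)
    ## project read bases onto reference space; S/I removed, D/N gapped
    laid <- GenomicAlignments::sequenceLayer(
      Biostrings::BStringSet(sub$seq[rows]), sub$cigar[rows])
    laid <- as.character(laid)
    for (k in seq_along(rows)) {
      i <- rows[k]
      rb <- chars(laid[k])
      p <- sub$pos[i]:(sub$pos[i] + length(rb) - 1L)
      keep <- p <= length(refb)
      rb <- rb[keep]; p <- p[keep]
      top_sense <- sub$is_read1[i] != sub$is_reverse[i]
      if (top_sense) {
        at <- refb[p] == "C"
        conv <- rb[at] == "T"; ret <- rb[at] == "C"
        cx <- ctx$top[p[at]]
      } else {
        at <- refb[p] == "G"
        conv <- rb[at] == "A"; ret <- rb[at] == "G"
        cx <- ctx$bottom[p[at]]
      }
      use <- (conv | ret) & !is.na(cx)
      if (!any(use)) next
      tc <- table(factor(cx[use], levels = rownames(counts)),
                  factor(ifelse(conv[use], "converted", "retained"),
                         levels = colnames(counts)))
      counts <- counts + tc
    }
  }
  df <- data.frame(context = c(rownames(counts), "all"),
                   converted = c(counts[, 1], sum(counts[, 1])),
                   total = c(rowSums(counts), sum(counts)),
                   stringsAsFactors = FALSE)
  df$rate <- ifelse(df$total > 0, df$converted / df$total, NA_real_)
  rownames(df) <- df$context
  structure(df, class = c("conversion_report", "data.frame"))
}

#' CpG retention rate (methylated spike-in QC)
#'
#' One minus the CpG-context conversion rate: on a fully CpG-methylated
#' control this should be near 1.
#'
#' @param report A `"conversion_report"`.
#' @return Numeric retention rate in \[0, 1\].
#' @export
cpg_retention <- function(report) 1 - report["CpG", "rate"]

## per-position cytosine context on both strands of one contig:
## top[i] is the context of a C at i (looking downstream), bottom[i] the
## context of the bottom-strand C paired with a G at i (looking upstream)
context_codes <- function(refb) {
  n <- length(refb)
  nxt1 <- c(refb[-1], "N"); nxt2 <- c(refb[-(1:2)], "N", "N")
  prv1 <- c("N", refb[-n]); prv2 <- c("N", "N", refb[-((n - 1):n)])
  top <- ifelse(nxt1 == "G", "CpG", ifelse(nxt2 == "G", "CHG", "CHH"))
  bottom <- ifelse(prv1 == "C", "CpG", ifelse(prv2 == "C", "CHG", "CHH"))
  list(top = top, bottom = bottom)
}

load_reference <- function(reference) {
  if (inherits(reference, "toy_genome")) return(as.list(reference$contigs))
  if (inherits(reference, "DNAStringSet"))
    return(as.list(as.character(reference)))
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference) && !grepl("^[ACGTN]+$", reference)) {
    x <- Biostrings::readDNAStringSet(reference)
    names(x) <- sub("\\s.*$", "", names(x))
    return(as.list(as.character(x)))
  }
  if (is.character(reference) && !is.null(names(reference)))
    return(as.list(reference))
  stop("cannot interpret 'reference'; supply a named character vector, ",
       "DNAStringSet, toy_genome or FASTA path", call. = FALSE)
}

#' @export
print.conversion_report <- function(x, ...) {
  cat("Bisulfite conversion report:\n")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Replicate concordance of per-target fusion counts
#'
#' Pearson correlation of total, split and discordant fusion read-pair
#' counts between two replicate call tables over the same target list.
#'
#' @param tables List of >= 2 call tables (as from
#'   `as.data.frame(<fusion_call>)` rbind-ed over targets), each with
#'   columns `target`, `split`, `discordant`, `total`.
#' @return `data.frame` with one row per count type and one correlation
#'   column per replicate pair.
#' @export
replicate_concordance <- function(tables) {
  if (length(tables) < 2L) stop("need at least two call tables", call. = FALSE)
  targets <- tables[[1]]$target
  if (length(targets) < 2L)
    stop("correlation undefined for fewer than two targets", call. = FALSE)
  for (t in tables[-1])
    if (!identical(sort(t$target), sort(targets)))
      stop("call tables cover different target lists", call. = FALSE)
  metrics <- c("total", "split", "discordant")
  pairs <- utils::combn(length(tables), 2)
  out <- data.frame(metric = metrics, stringsAsFactors = FALSE)
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    t1 <- tables[[i1]][match(targets, tables[[i1]]$target), ]
    t2 <- tables[[i2]][match(targets, tables[[i2]]$target), ]
    r <- vapply(metrics, function(m) {
      if (stats::sd(t1[[m]]) == 0 || stats::sd(t2[[m]]) == 0)
        stop("zero variance in '", m, "' counts: correlation undefined",
             call. = FALSE)
      stats::cor(t1[[m]], t2[[m]])
    }, numeric(1))
    out[[sprintf("r_%d_%d", i1, i2)]] <- r
  }
  out
}
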