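## Targeted fusion calling between two gene loci: pair filtering,
## split/discordant classification and soft-clip breakpoint localization.
##
## The evidence model follows the targeted WGBS fusion-detection design:
## a split read pair has one mate whose primary alignment lies in one
## target gene and carries an SA entry reaching the other gene; a
## discordant read pair has its mates' primary alignments in the two
## different target genes without qualifying SA entries.  Fusion read
## pairs are counted as split plus discordant pairs.

#' Pair-level filters
#'
#' True when both mates are mapped, neither is flagged duplicate, and
#' both reach the MAPQ threshold.
#'
#' @param pairs Pair table from [fetch_pairs()].
#' @param min_mapq Minimum mapping quality for both mates (default 20).
#' @return Logical vector along the rows of `pairs`.
#' @export
pass_filters <- function(pairs, min_mapq = 20L) {
  !pairs$is_unmapped_1 & !pairs$is_unmapped_2 &
    !pairs$mate_unmapped_1 & !pairs$mate_unmapped_2 &
    !pairs$is_duplicate_1 & !pairs$is_duplicate_2 &
    pairs$mapq_1 >= min_mapq & pairs$mapq_2 >= min_mapq
}

## which target gene ("A"/"B"/NA) does an aligned interval fall in?
gene_of <- function(contig, pos, end, target) {
  ifelse(overlaps_region(contig, pos, end, target$geneA), "A",
         ifelse(overlaps_region(contig, pos, end, target$geneB), "B",
                NA_character_))
}

## best SA entry of one record reaching `other` region (mapq >= min_mapq);
## ties broken by lowest NM then leftmost pos; NULL if none
qualifying_sa <- function(sa_text, other, min_mapq) {
  if (is.na(sa_text) || !nzchar(sa_text)) return(NULL)
  e <- parse_sa_tag(sa_text)
  if (nrow(e) == 0L) return(NULL)
  ends <- e$pos + cigar_ref_span(e$cigar) - 1L
  e <- e[overlaps_region(e$contig, e$pos, ends, other) & e$mapq >= min_mapq, ,
         drop = FALSE]
  if (nrow(e) == 0L) return(NULL)
  e <- e[order(-e$mapq, e$nm, e$pos), , drop = FALSE]
  e[1, , drop = FALSE]
}

#' Classify filtered read pairs as split, discordant or neither
#'
#' A pair is *split* when one mate's primary alignment lies in one target
#' gene and carries an SA entry into the other target gene while its mate
#' maps to that other gene (`mode = "strict"`) or to either gene
#' (`mode = "lenient"`; a junction-proximal fragment can place the mate on
#' the near side of the breakpoint).  A pair is *discordant* when the two
#' primary alignments lie in different target genes and neither carries a
#' qualifying SA entry.  A pair satisfying the split condition is never
#' also counted discordant; pairs where both mates carry qualifying SA
#' entries are classified split once.
#'
#' @param pairs Pair table from [fetch_pairs()] (already filter-passing).
#' @param target A `"target_pair"`.
#' @param mode `"strict"` (default) or `"lenient"` mate placement.
#' @param min_mapq MAPQ threshold also applied to SA entries.
#' @return `data.frame` with `qname`, `class` (`"split"`, `"discordant"`,
#'   `"none"`), `split_mate` (1, 2 or `NA`) and `ambiguous` (both mates
#'   carried qualifying SA entries).
#' @export
classify_pair <- function(pairs, target, mode = c("strict", "lenient"),
                          min_mapq = 20L) {
  mode <- match.arg(mode)
  n <- nrow(pairs)
  out <- data.frame(qname = pairs$qname,
                    class = rep("none", n),
                    split_mate = rep(NA_integer_, n),
                    ambiguous = rep(FALSE, n), stringsAsFactors = FALSE)
  if (n == 0L) return(out)
  end1 <- pairs$pos_1 + cigar_ref_span(pairs$cigar_1) - 1L
  end2 <- pairs$pos_2 + cigar_ref_span(pairs$cigar_2) - 1L
  g1 <- gene_of(pairs$contig_1, pairs$pos_1, end1, target)
  g2 <- gene_of(pairs$contig_2, pairs$pos_2, end2, target)
  for (i in seq_len(n)) {
    gg <- c(g1[i], g2[i])
    sa_hit <- c(FALSE, FALSE)
    for (m in 1:2) {
      if (is.na(gg[m])) next
      other <- if (gg[m] == "A") target$geneB else target$geneA
      sa <- qualifying_sa(pairs[[paste0("sa_", m)]][i], other, min_mapq)
      if (is.null(sa)) next
      mate_gene <- gg[3L - m]
      ok <- if (mode == "strict") {
        !is.na(mate_gene) && mate_gene == setdiff(c("A", "B"), gg[m])
      } else {
        !is.na(mate_gene)
      }
      sa_hit[m] <- ok
    }
    if (any(sa_hit)) {
      out$class[i] <- "split"
      out$split_mate[i] <- which(sa_hit)[1]
      out$ambiguous[i] <- all(sa_hit)
    } else if (!anyNA(gg) && gg[1] != gg[2]) {
      out$class[i] <- "discordant"
    }
  }
  out
}

#' Breakpoint boundary of a clipped alignment
#'
#' Applies the soft-clip boundary rule to one alignment: if the leading
#' clip is at least the trailing clip, the boundary is the first aligned
#' reference base (`pos`); otherwise the last aligned base
#' (`pos + reference span - 1`).  CIGAR coordinates are interpreted in
#' reference orientation, which is how both primary records and SA
#' entries express them, so the rule accounts for strand implicitly.
#'
#' @param pos 1-based leftmost aligned position.
#' @param cigar CIGAR string.
#' @return The boundary coordinate (integer).
#' @examples
#' clip_boundary(1001, "50S100M")   # 1001
#' clip_boundary(2001, "100M50S")   # 2100
#' @export
clip_boundary <- function(pos, cigar) {
  cl <- clip_lengths(cigar)
  if (cl[1, "leading"] == 0L && cl[1, "trailing"] == 0L)
    stop("no clipped side: not a split alignment", call. = FALSE)
  if (cl[1, "leading"] >= cl[1, "trailing"]) as.integer(pos)
  else as.integer(pos) + cigar_ref_span(cigar) - 1L
}

#' Locate the breakpoint coordinate pair of one split read
#'
#' Applies [clip_boundary()] independently to the read's primary
#' alignment and to its qualifying SA entry, then orders the two
#' boundaries as (gene-A coordinate, gene-B coordinate).
#'
#' @param contig,pos,cigar Primary alignment of the split read.
#' @param sa_entry One-row `data.frame` as selected by the classifier
#'   (the SA entry reaching the partner gene).
#' @param target A `"target_pair"`.
#' @return Named integer vector `c(posA = , posB = )`.
#' @export
locate_breakpoint <- function(contig, pos, cigar, sa_entry, target) {
  bp_prim <- clip_boundary(pos, cigar)
  bp_sa <- clip_boundary(sa_entry$pos, sa_entry$cigar)
  prim_end <- pos + cigar_ref_span(cigar) - 1L
  g_prim <- gene_of(contig, pos, prim_end, target)
  if (is.na(g_prim))
    stop("split read primary alignment overlaps neither target gene",
         call. = FALSE)
  if (g_prim == "A") c(posA = bp_prim, posB = bp_sa)
  else c(posA = bp_sa, posB = bp_prim)
}

#' Call a fusion between two target genes
#'
#' Runs the full evidence chain on an alignment set: extract mated
#' primary pairs touching the targets, filter on mapping and duplicate
#' status, classify split versus discordant pairs, localize breakpoints
#' from soft-clip boundaries, and aggregate unique breakpoint coordinate
#' pairs with their support.  Each read pair (qname) is counted at most
#' once.
#'
#' @param alignments Alignment `data.frame` from [read_alignments()], or
#'   a path to a SAM/BAM file.
#' @param target A `"target_pair"`.
#' @param min_mapq MAPQ threshold for both mates and SA entries
#'   (default 20).
#' @param mode Split mate-placement mode, see [classify_pair()].
#' @param detection_min Minimum total fusion read pairs for the sample to
#'   be flagged detected (default 1; fusion-negative controls show zero).
#' @return Object of class `"fusion_call"`: counts (`split_count`,
#'   `discordant_count`, `total_count`), `detected`, the unique
#'   `breakpoints` table (`contigA`, `posA`, `contigB`, `posB`,
#'   `support`) and the per-pair `evidence` table.
#' @export
call_fusion <- function(alignments, target, min_mapq = 20L,
                        mode = c("strict", "lenient"), detection_min = 1L) {
  mode <- match.arg(mode)
  if (is.character(alignments)) alignments <- read_alignments(alignments)
  pairs <- fetch_pairs(alignments, target)
  pairs <- pairs[pass_filters(pairs, min_mapq), , drop = FALSE]
  cls <- classify_pair(pairs, target, mode, min_mapq)
  bps <- data.frame(contigA = character(0), posA = integer(0),
                    contigB = character(0), posB = integer(0),
                    stringsAsFactors = FALSE)
  split_idx <- which(cls$class == "split")
  if (length(split_idx)) {
    bp_rows <- lapply(split_idx, function(i) {
      m <- cls$split_mate[i]
      contig <- pairs[[paste0("contig_", m)]][i]
      pos <- pairs[[paste0("pos_", m)]][i]
      cigar <- pairs[[paste0("cigar_", m)]][i]
      end <- pos + cigar_ref_span(cigar) - 1L
      g <- gene_of(contig, pos, end, target)
      other <- if (g == "A") target$geneB else target$geneA
      sa <- qualifying_sa(pairs[[paste0("sa_", m)]][i], other, min_mapq)
      bp <- locate_breakpoint(contig, pos, cigar, sa, target)
      data.frame(contigA = target$geneA$contig, posA = bp[["posA"]],
                 contigB = target$geneB$contig, posB = bp[["posB"]],
                 stringsAsFactors = FALSE)
    })
    bps <- do.call(rbind, bp_rows)
  }
  key <- paste(bps$posA, bps$posB)
  uniq <- !duplicated(key)
  breakpoints <- bps[uniq, , drop = FALSE]
  breakpoints$support <- as.integer(table(key)[key[uniq]])
  if (nrow(breakpoints))
    breakpoints <- breakpoints[order(-breakpoints$support,
                                     breakpoints$posA), , drop = FALSE]
  rownames(breakpoints) <- NULL
  split_count <- sum(cls$class == "split")
  discordant_count <- sum(cls$class == "discordant")
  structure(list(
    target = target,
    split_count = split_count,
    discordant_count = discordant_count,
    total_count = split_count + discordant_count,
    detected = split_count + discordant_count >= detection_min,
    breakpoints = breakpoints,
    evidence = cls[cls$class != "none", , drop = FALSE],
    min_mapq = min_mapq, mode = mode, detection_min = detection_min),
    class = "fusion_call")
}

#' @export
print.fusion_call <- function(x, ...) {
  cat(sprintf("Fusion call %s--%s [%s mode, MAPQ >= %d]\n",
              x$target$geneA$name, x$target$geneB$name, x$mode, x$min_mapq))
  cat(sprintf("  split read pairs:      %d\n", x$split_count))
  cat(sprintf("  discordant read pairs: %d\n", x$discordant_count))
  cat(sprintf("  total fusion pairs:    %d  (detected: %s)\n",
              x$total_count, x$detected))
  if (nrow(x$breakpoints)) {
    cat(sprintf("  unique breakpoints:    %d (modal %s:%d | %s:%d, support %d)\n",
                nrow(x$breakpoints),
                x$breakpoints$contigA[1], x$breakpoints$posA[1],
                x$breakpoints$contigB[1], x$breakpoints$posB[1],
                x$breakpoints$support[1]))
  }
  invisible(x)
}

#' @export
summary.fusion_call <- function(object, ...) {
  print(object)
  if (nrow(object$breakpoints)) {
    cat("\nBreakpoint table:\n")
    print(object$breakpoints)
  }
  invisible(object)
}

#' Flatten a fusion call to a one-row call table
#' @param x A `"fusion_call"`.
#' @param row.names,optional,... Passed for S3 compatibility; unused.
#' @return One-row `data.frame`: `target`, `split`, `discordant`, `total`,
#'   `detected`.
#' @export
as.data.frame.fusion_call <- function(x, row.names = NULL, optional = FALSE,
                                      ...) {
  data.frame(target = paste0(x$target$geneA$name, "--", x$target$geneB$name),
             split = x$split_count, discordant = x$discordant_count,
             total = x$total_count, detected = x$detected,
             stringsAsFactors = FALSE)
}
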