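## Alignment input: SAM/BAM reading, mate pairing within target regions,
## CIGAR arithmetic and SA-tag parsing.
##
## Coordinates are SAM-native throughout: 1-based, inclusive.  BED input
## (0-based, half-open) is converted at the boundary in read_targets_bed().

#' Define a named genomic region
#'
#' @param name Region (gene) name.
#' @param contig Contig/chromosome name.
#' @param start,end 1-based inclusive interval, `start <= end`.
#' @return A one-row `data.frame` with columns `name`, `contig`, `start`, `end`.
#' @examples
#' region("geneA", "chrA", 2001, 8000)
#' @export
region <- function(name, contig, start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1L || start > end)
    stop("invalid region: need 1 <= start <= end", call. = FALSE)
  data.frame(name = as.character(name), contig = as.character(contig),
             start = start, end = end, stringsAsFactors = FALSE)
}

#' Define the target gene pair of a fusion hypothesis
#'
#' @param geneA,geneB Regions created by [region()]. Must have distinct
#'   names and disjoint intervals.
#' @return A list of class `"target_pair"` with elements `geneA`, `geneB`.
#' @export
target_pair <- function(geneA, geneB) {
  stopifnot(is.data.frame(geneA), is.data.frame(geneB))
  if (identical(geneA$name, geneB$name))
    stop("target genes must have distinct names", call. = FALSE)
  if (geneA$contig == geneB$contig &&
      geneA$start <= geneB$end && geneB$start <= geneA$end)
    stop("target gene regions must be disjoint", call. = FALSE)
  structure(list(geneA = geneA, geneB = geneB), class = "target_pair")
}

#' @export
print.target_pair <- function(x, ...) {
  cat("Target gene pair:\n")
  for (g in list(x$geneA, x$geneB))
    cat(sprintf("  %s  %s:%d-%d\n", g$name, g$contig, g$start, g$end))
  invisible(x)
}

#' Read a target pair from a BED file
#'
#' Expects a 4+ column BED file (0-based half-open) with exactly two rows;
#' the name column is required and coordinates are converted to 1-based
#' inclusive on input.
#'
#' @param path Path to a BED file with two named intervals.
#' @return A `"target_pair"`.
#' @export
read_targets_bed <- function(path) {
  bed <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(bed) < 4L) stop("BED file must have a name column (>= 4 columns)")
  if (nrow(bed) != 2L) stop("expected exactly two target intervals, got ", nrow(bed))
  target_pair(region(bed[1, 4], bed[1, 1], bed[1, 2] + 1L, bed[1, 3]),
              region(bed[2, 4], bed[2, 1], bed[2, 2] + 1L, bed[2, 3]))
}

#' Parse an SA:Z auxiliary tag
#'
#' The SA tag of a chimeric read lists its other alignments as
#' semicolon-terminated `rname,pos,strand,CIGAR,mapQ,NM;` entries.
#'
#' @param text The tag value (without the `SA:Z:` prefix). `NA` or `""`
#'   yields an empty table.
#' @return `data.frame` with columns `contig`, `pos`, `strand`, `cigar`,
#'   `mapq`, `nm`, one row per entry, input order preserved.
#' @examples
#' parse_sa_tag("chrB,1000,+,50S100M,60,1;")
#' @export
parse_sa_tag <- function(text) {
  empty <- data.frame(contig = character(0), pos = integer(0),
                      strand = character(0), cigar = character(0),
                      mapq = integer(0), nm = integer(0),
                      stringsAsFactors = FALSE)
  if (length(text) != 1L) stop("parse_sa_tag() expects a single tag value")
  if (is.na(text) || !nzchar(text)) return(empty)
  entries <- strsplit(text, ";", fixed = TRUE)[[1]]
  entries <- entries[nzchar(entries)]
  if (length(entries) == 0L) return(empty)
  rows <- lapply(entries, function(e) {
    f <- strsplit(e, ",", fixed = TRUE)[[1]]
    if (length(f) != 6L)
      stop("malformed SA entry (expected 6 fields): '", e, "'", call. = FALSE)
    pos <- suppressWarnings(as.integer(f[2]))
    mapq <- suppressWarnings(as.integer(f[5]))
    nm <- suppressWarnings(as.integer(f[6]))
    if (anyNA(c(pos, mapq, nm)))
      stop("non-numeric pos/mapq/NM in SA entry: '", e, "'", call. = FALSE)
    if (!f[3] %in% c("+", "-"))
      stop("invalid strand in SA entry: '", e, "'", call. = FALSE)
    data.frame(contig = f[1], pos = pos, strand = f[3], cigar = f[4],
               mapq = mapq, nm = nm, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Serialize SA entries back to tag text
#'
#' Inverse of [parse_sa_tag()]; round-trips byte-for-byte.
#'
#' @param entries `data.frame` as returned by [parse_sa_tag()].
#' @return A single SA:Z tag value (semicolon-terminated), `""` if empty.
#' @export
format_sa_tag <- function(entries) {
  if (nrow(entries) == 0L) return("")
  paste0(paste(entries$contig, entries$pos, entries$strand, entries$cigar,
               entries$mapq, entries$nm, sep = ","), ";", collapse = "")
}

#' Reference span of a CIGAR string
#'
#' Number of reference bases consumed: the sum of lengths over operations
#' in M, D, N, =, X.
#'
#' @param cigar Character vector of CIGAR strings.
#' @return Integer vector of reference spans.
#' @examples
#' cigar_ref_span(c("100M", "51S100M", "40M10I60M2D"))
#' @export
validate_cigar <- function(cigar) {
  bad <- !grepl("^([0-9]+[MIDNSHP=X])+$", cigar)
  if (any(bad))
    stop("invalid CIGAR: '", cigar[which(bad)[1]], "'", call. = FALSE)
  invisible(cigar)
}

cigar_ref_span <- function(cigar) {
  validate_cigar(cigar)
  GenomicAlignments::cigarWidthAlongReferenceSpace(cigar)
}

#' Query span of a CIGAR string (aligned read bases, clips included)
#' @param cigar Character vector of CIGAR strings.
#' @return Integer vector of query widths including soft clips.
#' @keywords internal
cigar_query_span <- function(cigar) {
  GenomicAlignments::cigarWidthAlongQuerySpace(cigar, after.soft.clipping = FALSE)
}

#' Leading and trailing clip lengths of CIGAR strings
#'
#' Soft (S) and hard (H) clips are counted together: most aligners
#' soft-clip the primary record of a chimeric read and hard-clip the
#' supplementary, but both mark the same unaligned read portion whose
#' boundary abuts the putative breakpoint.
#'
#' @param cigar Character vector of CIGAR strings.
#' @return A two-column integer matrix with columns `leading`, `trailing`.
#' @examples
#' clip_lengths(c("50S100M", "100M50S", "10H40S100M5S"))
#' @export
clip_lengths <- function(cigar) {
  validate_cigar(cigar)
  ops <- GenomicAlignments::explodeCigarOps(cigar)
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)
  out <- t(mapply(function(op, len) {
    clip <- op %in% c("S", "H")
    if (all(clip))
      stop("degenerate alignment: CIGAR consists only of clips", call. = FALSE)
    first <- which(!clip)[1]
    last <- max(which(!clip))
    c(leading = if (first > 1L) sum(len[seq_len(first - 1L)]) else 0L,
      trailing = if (last < length(op)) sum(len[(last + 1L):length(op)]) else 0L)
  }, ops, lens))
  dimnames(out) <- list(NULL, c("leading", "trailing"))
  out
}

#' Read alignments from a SAM or BAM file
#'
#' SAM input is converted to BAM via [Rsamtools::asBam()] before parsing;
#' records are returned as a flat `data.frame` with decomposed flags. The
#' SA tag, if present, is kept as its raw tag text (see [parse_sa_tag()]).
#'
#' @param file Path to a `.sam` or `.bam` file.
#' @return `data.frame` with one row per record: `qname`, `flag`, `contig`,
#'   `pos`, `mapq`, `cigar`, `mate_contig`, `mate_pos`, `seq`, `sa`,
#'   `is_read1`, `is_read2`, `is_reverse`, `is_primary`, `is_duplicate`,
#'   `is_unmapped`, `mate_unmapped`.  The contig lengths from the header
#'   are attached as attribute `"contig_lengths"`.
#' @export
read_alignments <- function(file) {
  if (!file.exists(file)) stop("alignment file not found: ", file, call. = FALSE)
  if (grepl("\\.sam$", file, ignore.case = TRUE)) {
    file <- Rsamtools::asBam(file, tempfile(), overwrite = TRUE,
                             indexDestination = FALSE)
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "mapq", "cigar",
             "mrnm", "mpos", "seq"),
    tag = "SA")
  res <- Rsamtools::scanBam(file, param = param)[[1]]
  n <- length(res$qname)
  sa <- res$tag$SA %||% rep(NA_character_, n)
  flag <- res$flag
  df <- data.frame(
    qname = res$qname,
    flag = flag,
    contig = as.character(res$rname),
    pos = res$pos,
    mapq = res$mapq,
    cigar = res$cigar,
    mate_contig = as.character(res$mrnm),
    mate_pos = res$mpos,
    seq = as.character(res$seq),
    sa = sa,
    is_read1 = bitwAnd(flag, 0x40L) > 0L,
    is_read2 = bitwAnd(flag, 0x80L) > 0L,
    is_reverse = bitwAnd(flag, 0x10L) > 0L,
    is_primary = bitwAnd(flag, 0x100L) == 0L & bitwAnd(flag, 0x800L) == 0L,
    is_duplicate = bitwAnd(flag, 0x400L) > 0L,
    is_unmapped = bitwAnd(flag, 0x4L) > 0L,
    mate_unmapped = bitwAnd(flag, 0x8L) > 0L,
    stringsAsFactors = FALSE)
  attr(df, "contig_lengths") <- Rsamtools::scanBamHeader(file)[[1]]$targets
  df
}

## does the aligned reference interval [pos, end] of a record overlap region r?
overlaps_region <- function(contig, pos, end, r) {
  !is.na(contig) & contig == r$contig & pos <= r$end & end >= r$start
}

normalize_regions <- function(regions) {
  if (inherits(regions, "target_pair")) return(list(regions$geneA, regions$geneB))
  if (is.data.frame(regions)) return(split(regions, seq_len(nrow(regions))))
  regions
}

#' Extract mated primary-alignment pairs touching target regions
#'
#' Keeps read pairs where at least one mate's primary alignment overlaps
#' one of the regions with at least one aligned (non-clipped) reference
#' base.  Secondary and supplementary records never appear as pair
#' members; the content of supplementary alignments reaches the caller
#' only through the SA tag of primaries.
#'
#' @param alignments `data.frame` from [read_alignments()].
#' @param regions A `"target_pair"`, a `data.frame` of regions, or a list
#'   of one-row region `data.frame`s.
#' @param pad Extra bases added to each region side (default 0).
#' @return A `data.frame` with one row per pair; mate columns carry
#'   suffixes `_1` and `_2`. Qnames that overlap a region but lack a mated
#'   primary record are returned in attribute `"unpaired"`.
#' @export
fetch_pairs <- function(alignments, regions, pad = 0L) {
  regions <- normalize_regions(regions)
  prim <- alignments[alignments$is_primary & !alignments$is_unmapped, ,
                     drop = FALSE]
  if (nrow(prim) == 0L) {
    out <- merge_pairs(prim, prim)
    attr(out, "unpaired") <- character(0)
    return(out)
  }
  ref_end <- prim$pos + cigar_ref_span(prim$cigar) - 1L
  hit <- rep(FALSE, nrow(prim))
  for (r in regions) {
    rr <- r
    rr$start <- rr$start - pad; rr$end <- rr$end + pad
    hit <- hit | overlaps_region(prim$contig, prim$pos, ref_end, rr)
  }
  qn <- unique(prim$qname[hit])
  sub <- prim[prim$qname %in% qn, , drop = FALSE]
  r1 <- sub[sub$is_read1, , drop = FALSE]
  r2 <- sub[sub$is_read2, , drop = FALSE]
  if (anyDuplicated(r1$qname))
    stop("input integrity: multiple primary read-1 records for qname '",
         r1$qname[duplicated(r1$qname)][1], "'", call. = FALSE)
  if (anyDuplicated(r2$qname))
    stop("input integrity: multiple primary read-2 records for qname '",
         r2$qname[duplicated(r2$qname)][1], "'", call. = FALSE)
  paired <- intersect(r1$qname, r2$qname)
  out <- merge_pairs(r1[match(paired, r1$qname), , drop = FALSE],
                     r2[match(paired, r2$qname), , drop = FALSE])
  out <- out[order(out$qname), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unpaired") <- setdiff(qn, paired)
  out
}

merge_pairs <- function(r1, r2) {
  keep <- c("contig", "pos", "mapq", "cigar", "mate_contig", "mate_pos",
            "seq", "sa", "is_reverse", "is_duplicate", "is_unmapped",
            "mate_unmapped")
  out <- data.frame(qname = r1$qname, stringsAsFactors = FALSE)
  for (k in keep) {
    out[[paste0(k, "_1")]] <- r1[[k]]
    out[[paste0(k, "_2")]] <- r2[[k]]
  }
  out
}
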