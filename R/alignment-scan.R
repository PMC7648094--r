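#' @importFrom GenomicAlignments cigarWidthAlongReferenceSpace explodeCigarOps
#'   explodeCigarOpLengths
#' @importFrom Rsamtools scanBam ScanBamParam scanBamWhat asBam asSam
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges
NULL

## SAM flag bits used throughout
FLAG_PAIRED <- 0x1; FLAG_UNMAPPED <- 0x4; FLAG_MUNMAPPED <- 0x8
FLAG_REVERSE <- 0x10; FLAG_MREVERSE <- 0x20; FLAG_FIRST <- 0x40
FLAG_LAST <- 0x80; FLAG_SECONDARY <- 0x100; FLAG_DUP <- 0x400
FLAG_SUPPLEMENTARY <- 0x800

hasFlag <- function(flag, bit) bitwAnd(flag, bit) != 0L

## Resolve a SAM/BAM path to a BAM path, converting SAM text on the fly.
ensureBam <- function(file) {
    stopifnot(file.exists(file))
    magic <- readBin(file, "raw", n = 2L)
    ## BAM files are BGZF-compressed: gzip magic 1f 8b
    if (identical(as.integer(magic), c(0x1fL, 0x8bL))) return(file)
    asBam(file, tempfile(), overwrite = TRUE, indexDestination = FALSE)
}

## Resolve a SAM/BAM path to SAM text lines.
samLines <- function(file) {
    magic <- readBin(file, "raw", n = 2L)
    if (identical(as.integer(magic), c(0x1fL, 0x8bL)))
        file <- asSam(file, tempfile(), overwrite = TRUE)
    readLines(file)
}

#' Read mapped read pairs from a SAM or BAM file
#'
#' Loads primary, non-duplicate alignment records, pairs mates by read name,
#' and returns the pair-level mapping geometry needed for atypical-alignment
#' detection.  Secondary/supplementary and duplicate-flagged records are
#' excluded (matching a best-practice pipeline where duplicates are marked
#' before variant calling); unmapped records, singletons and cross-reference
#' pairs are excluded and tallied.
#'
#' @param file Path to a BAM file or SAM text file (detected by content).
#' @return A [S4Vectors::DataFrame] with one row per mapped same-reference
#'   pair: `read_name`, `ref_name`, `mate1_start`, `mate1_end`,
#'   `mate2_start`, `mate2_end`, `cigar1`, `cigar2`, `mapq1`, `mapq2`,
#'   `tlen` (signed, as recorded on mate 1).  The reject tally is attached
#'   as `metadata(x)$rejects`.
#' @export
readPairAlignments <- function(file) {
    bam <- ensureBam(file)
    res <- scanBam(bam, param = ScanBamParam(
        what = c("qname", "flag", "rname", "pos", "mapq", "cigar",
                 "isize")))[[1]]
    flag <- res$flag
    rejects <- c(secondary_supplementary = 0L, duplicate = 0L,
                 unmapped = 0L, singleton = 0L, cross_reference = 0L,
                 malformed_cigar = 0L)
    sec <- hasFlag(flag, FLAG_SECONDARY) | hasFlag(flag, FLAG_SUPPLEMENTARY)
    rejects["secondary_supplementary"] <- sum(sec)
    dup <- !sec & hasFlag(flag, FLAG_DUP)
    rejects["duplicate"] <- sum(dup)
    unm <- !sec & !dup & (hasFlag(flag, FLAG_UNMAPPED) | is.na(res$pos))
    rejects["unmapped"] <- sum(unm)
    keep <- !sec & !dup & !unm
    if (!any(keep))
        return(emptyPairFrame(rejects))

    qname <- res$qname[keep]; flag <- flag[keep]
    rname <- as.character(res$rname)[keep]; pos <- res$pos[keep]
    mapq <- res$mapq[keep]; cigar <- res$cigar[keep]
    isize <- res$isize[keep]

    refw <- tryCatchCigarWidth(cigar)
    bad <- is.na(refw$width) | refw$width < 1L
    if (any(bad & !refw$valid)) {
        rejects["malformed_cigar"] <- sum(bad & !refw$valid)
        warning(sum(bad & !refw$valid),
                " record(s) with unparseable CIGAR skipped")
    }
    keep2 <- !bad
    qname <- qname[keep2]; flag <- flag[keep2]; rname <- rname[keep2]
    pos <- pos[keep2]; mapq <- mapq[keep2]; cigar <- cigar[keep2]
    isize <- isize[keep2]; endp <- pos[seq_along(pos)] + refw$width[keep2] - 1L

    tab <- table(qname)
    paired_names <- names(tab)[tab == 2L]
    rejects["singleton"] <- sum(tab == 1L)
    ## >2 primary records under one name should not occur; treat as malformed
    rejects["malformed_cigar"] <- rejects["malformed_cigar"] +
        sum(tab[tab > 2L])
    sel <- qname %in% paired_names
    if (!any(sel)) return(emptyPairFrame(rejects))

    ord <- order(match(qname[sel], paired_names),
                 !hasFlag(flag[sel], FLAG_FIRST))
    idx <- which(sel)[ord]
    i1 <- idx[seq(1L, length(idx), by = 2L)]
    i2 <- idx[seq(2L, length(idx), by = 2L)]

    same_ref <- rname[i1] == rname[i2]
    rejects["cross_reference"] <- 2L * sum(!same_ref)
    i1 <- i1[same_ref]; i2 <- i2[same_ref]

    out <- DataFrame(
        read_name = qname[i1], ref_name = rname[i1],
        mate1_start = pos[i1], mate1_end = endp[i1],
        mate2_start = pos[i2], mate2_end = endp[i2],
        cigar1 = cigar[i1], cigar2 = cigar[i2],
        mapq1 = mapq[i1], mapq2 = mapq[i2],
        tlen = ifelse(is.na(isize[i1]), 0L, isize[i1]))
    metadata(out)$rejects <- rejects
    out
}

emptyPairFrame <- function(rejects) {
    out <- DataFrame(
        read_name = character(0), ref_name = character(0),
        mate1_start = integer(0), mate1_end = integer(0),
        mate2_start = integer(0), mate2_end = integer(0),
        cigar1 = character(0), cigar2 = character(0),
        mapq1 = integer(0), mapq2 = integer(0), tlen = integer(0))
    metadata(out)$rejects <- rejects
    out
}

## Reference-space CIGAR widths with per-record validity.
tryCatchCigarWidth <- function(cigar) {
    valid <- grepl("^([0-9]+[MIDNSHP=X])+$", cigar)
    width <- rep(NA_integer_, length(cigar))
    if (any(valid))
        width[valid] <- cigarWidthAlongReferenceSpace(cigar[valid])
    list(width = width, valid = valid)
}

#' Template span of a read pair
#'
#' The inclusive distance in bp between the leftmost and the rightmost
#' reference base covered by either mate:
#' `max(mate ends) - min(mate starts) + 1`.  For a pair aligned by an
#' aligner following the standard template-length convention this equals
#' `|TLEN|`; the span is recomputed from coordinates because that holds
#' regardless of aligner convention.  Atypical contaminant pairs have spans
#' of at most 30 bp, ordinary pairs a span near the library insert size.
#'
#' @param pairs A pair `DataFrame` from [readPairAlignments()] (or any
#'   data frame with `mate1_start`, `mate1_end`, `mate2_start`, `mate2_end`).
#' @return Integer vector of spans, one per pair.
#' @examples
#' p <- S4Vectors::DataFrame(mate1_start = 1000L, mate1_end = 1021L,
#'                           mate2_start = 1000L, mate2_end = 1021L)
#' templateSpan(p)  # 22
#' @export
templateSpan <- function(pairs) {
    need <- c("mate1_start", "mate1_end", "mate2_start", "mate2_end")
    stopifnot(all(need %in% colnames(pairs)))
    if (any(is.na(pairs$mate1_start) | is.na(pairs$mate2_start)))
        stop("span undefined: unmapped mate or cross-reference pair")
    pmax(pairs$mate1_end, pairs$mate2_end) -
        pmin(pairs$mate1_start, pairs$mate2_start) + 1L
}

#' Core identity region and soft-clip geometry of a pair
#'
#' For each pair, the matched ("core") reference interval of each mate is
#' the reference-consuming extent of its CIGAR; the pair's core is the union
#' of the two.  Soft-clip lengths are taken from leading/trailing `S`
#' operations.  In an atypical pair the core is the short (19--25 bp)
#' chance-identity k-mer shared by both mates and the flanks are the
#' soft-clipped contaminant sequence.
#'
#' @param pairs A pair `DataFrame` with `mate1_start`, `mate2_start`,
#'   `cigar1`, `cigar2` columns.
#' @return A `DataFrame` with per-mate cores (`core1_start`, `core1_end`,
#'   `core2_start`, `core2_end`), the union core (`core_start`, `core_end`,
#'   `core_len`) and clip lengths (`clip_left1`, `clip_right1`,
#'   `clip_left2`, `clip_right2`).
#' @export
coreIdentityRegion <- function(pairs) {
    w1 <- tryCatchCigarWidth(pairs$cigar1)
    w2 <- tryCatchCigarWidth(pairs$cigar2)
    if (any(!w1$valid | !w2$valid))
        stop("unparseable CIGAR in core computation")
    if (any(w1$width < 1L | w2$width < 1L))
        stop("no core: CIGAR without reference-consuming operation")
    c1s <- pairs$mate1_start; c1e <- c1s + w1$width - 1L
    c2s <- pairs$mate2_start; c2e <- c2s + w2$width - 1L
    cl1 <- clipLengths(pairs$cigar1)
    cl2 <- clipLengths(pairs$cigar2)
    DataFrame(
        core1_start = c1s, core1_end = c1e,
        core2_start = c2s, core2_end = c2e,
        core_start = pmin(c1s, c2s), core_end = pmax(c1e, c2e),
        core_len = pmax(c1e, c2e) - pmin(c1s, c2s) + 1L,
        clip_left1 = cl1$left, clip_right1 = cl1$right,
        clip_left2 = cl2$left, clip_right2 = cl2$right)
}

## Leading/trailing soft-clip lengths (hard clips ignored).
clipLengths <- function(cigar) {
    ops <- explodeCigarOps(cigar)
    lens <- explodeCigarOpLengths(cigar)
    one <- function(o, l, tail = FALSE) {
        keep <- o != "H"
        o <- o[keep]; l <- l[keep]
        if (!length(o)) return(0L)
        i <- if (tail) length(o) else 1L
        if (o[i] == "S") l[i] else 0L
    }
    if (!length(cigar))
        return(list(left = integer(0), right = integer(0)))
    list(left = mapply(one, ops, lens, MoreArgs = list(tail = FALSE),
                       USE.NAMES = FALSE),
         right = mapply(one, ops, lens, MoreArgs = list(tail = TRUE),
                        USE.NAMES = FALSE))
}

#' Detect atypically aligned read pairs
#'
#' Scans mapped same-reference read pairs and returns those whose template
#' span (leftmost-to-rightmost mapped extent) lies in
#' `[minSpan, maxSpan]` -- by default 1--30 bp, the signature of contaminant
#' reads pinned to the reference by a short identity core -- and whose
#' better mate has MAPQ >= `minMapq`.  The recomputed span is checked
#' against `|TLEN|` and a warning is raised when the aligner's recorded
#' template length disagrees.
#'
#' @param x A SAM/BAM path or a pair `DataFrame` from
#'   [readPairAlignments()].
#' @param minSpan,maxSpan Span window in bp (default 1 and 30).
#' @param minMapq Minimum of `max(mapq1, mapq2)` for a pair to be reported
#'   (default 0; impact assessment uses 10, the floor below which variant
#'   callers discard alignments).
#' @return An [AtypicalPairSet].
#' @export
detectAtypicalPairs <- function(x, minSpan = 1L, maxSpan = 30L,
                                minMapq = 0L) {
    if (is.character(x)) x <- readPairAlignments(x)
    rejects <- metadata(x)$rejects
    if (is.null(rejects)) rejects <- c(none = 0L)
    span <- if (nrow(x)) templateSpan(x) else integer(0)
    hit <- span >= minSpan & span <= maxSpan &
        pmax(x$mapq1, x$mapq2) >= minMapq
    sel <- x[hit, , drop = FALSE]
    span <- span[hit]
    if (nrow(sel)) {
        tl <- abs(sel$tlen)
        disagree <- tl != 0L & tl != span
        if (any(disagree))
            warning(sum(disagree), " atypical pair(s) where |TLEN| ",
                    "disagrees with the recomputed span")
        core <- coreIdentityRegion(sel)
        pairs <- cbind(sel[, c("read_name", "ref_name", "mate1_start",
                               "mate1_end", "mate2_start", "mate2_end",
                               "cigar1", "cigar2", "mapq1", "mapq2",
                               "tlen")],
                       DataFrame(span = span), core)
    } else {
        pairs <- cbind(emptyPairFrame(rejects),
                       DataFrame(span = integer(0)),
                       coreIdentityRegion(emptyPairFrame(rejects)))
    }
    new("AtypicalPairSet", pairs = pairs, rejects = rejects,
        params = list(min_span = minSpan, max_span = maxSpan,
                      min_mapq = minMapq))
}

#' Cluster atypical pairs into genomic intervals
#'
#' Single-linkage merge of the union core intervals: two cores join the
#' same cluster when the gap between them is at most `mergeGap` bp.  The
#' default of 20 bp mirrors the spacing observed between anomalous variant
#' clusters in contaminated saliva genomes.
#'
#' @param x An `AtypicalPairSet` (or a `GRanges` of core intervals with a
#'   `read_name` metadata column).
#' @param mergeGap Maximum gap in bp for two cores to be merged
#'   (default 20).
#' @return A `GRanges` of clusters sorted by (seqname, start) with metadata
#'   columns `n_pairs` and `member_read_names`
#'   (a [IRanges::CharacterList]).
#' @export
clusterAtypical <- function(x, mergeGap = 20L) {
    gr <- if (is(x, "AtypicalPairSet")) coreRanges(x) else x
    if (!length(gr)) {
        out <- GRanges()
        S4Vectors::mcols(out) <- S4Vectors::DataFrame(
            n_pairs = integer(0),
            member_read_names = IRanges::CharacterList())
        return(out)
    }
    cl <- GenomicRanges::reduce(gr, min.gapwidth = mergeGap + 1L,
                                ignore.strand = TRUE)
    ov <- GenomicRanges::findOverlaps(gr, cl, ignore.strand = TRUE)
    members <- split(S4Vectors::mcols(gr)$read_name[S4Vectors::from(ov)],
                     factor(S4Vectors::to(ov), levels = seq_along(cl)))
    S4Vectors::mcols(cl)$n_pairs <- unname(lengths(members))
    S4Vectors::mcols(cl)$member_read_names <-
        unname(IRanges::CharacterList(members))
    sort(cl, ignore.strand = TRUE)
}

#' Mapping-quality profile of an atypical pair set
#'
#' Tallies the MAPQ of every mate of every atypical pair and reports the
#' fractions at or below 10 (discarded by variant callers) and at or above
#' 40 (passing every default filter); the middle bin completes the
#' partition.  Pair-level fractions (each pair counted once at its better
#' mate's MAPQ) are reported alongside.
#'
#' @param x An `AtypicalPairSet`.
#' @return A [MapqProfile].  Fractions are `NA` ("undefined") on empty
#'   input, not 0.
#' @export
mapqProfile <- function(x) {
    stopifnot(is(x, "AtypicalPairSet"))
    p <- x@pairs
    mq <- c(p$mapq1, p$mapq2)
    if (!length(mq)) {
        return(new("MapqProfile", histogram = integer(0),
                   fracLe10 = NA_real_, fracMid = NA_real_,
                   fracGe40 = NA_real_, pairFracLe10 = NA_real_,
                   pairFracGe40 = NA_real_, nAlignments = 0L))
    }
    hist <- tabulate(mq + 1L, nbins = max(mq) + 1L)
    names(hist) <- as.character(seq_along(hist) - 1L)
    pairmq <- pmax(p$mapq1, p$mapq2)
    new("MapqProfile",
        histogram = hist,
        fracLe10 = mean(mq <= 10L), fracMid = mean(mq > 10L & mq < 40L),
        fracGe40 = mean(mq >= 40L),
        pairFracLe10 = mean(pairmq <= 10L),
        pairFracGe40 = mean(pairmq >= 40L),
        nAlignments = length(mq))
}

#' Write atypical clusters as a BED file
#'
#' Columns: chrom, start, end, n_pairs.  BED convention: 0-based
#' half-open coordinates.
#'
#' @param clusters A `GRanges` from [clusterAtypical()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeClustersBed <- function(clusters, path) {
    df <- data.frame(
        chrom = as.character(GenomicRanges::seqnames(clusters)),
        start = GenomicRanges::start(clusters) - 1L,
        end = GenomicRanges::end(clusters),
        n_pairs = S4Vectors::mcols(clusters)$n_pairs)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read an atypical-cluster BED file
#'
#' @param path BED path written by [writeClustersBed()] (chrom, start, end,
#'   optional n_pairs; 0-based half-open).
#' @return A `GRanges` (1-based internally) with an `n_pairs` column when
#'   present.
#' @export
readClustersBed <- function(path) {
    df <- utils::read.table(path, sep = "\t", header = FALSE)
    gr <- GRanges(df[[1]], IRanges(df[[2]] + 1L, df[[3]]))
    if (ncol(df) >= 4L) S4Vectors::mcols(gr)$n_pairs <- df[[4]]
    gr
}
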