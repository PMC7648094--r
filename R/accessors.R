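#' @rdname AtypicalPairSet-class
#' @param x,object An object.
#' @export
setGeneric("pairs", function(x, ...) standardGeneric("pairs"))

#' @rdname AtypicalPairSet-class
#' @param ... Ignored.
#' @export
setMethod("pairs", "AtypicalPairSet", function(x, ...) x@pairs)

#' @rdname AtypicalPairSet-class
#' @export
setGeneric("rejects", function(x) standardGeneric("rejects"))

#' @rdname AtypicalPairSet-class
#' @export
setMethod("rejects", "AtypicalPairSet", function(x) x@rejects)

#' @rdname AtypicalPairSet-class
#' @export
setMethod("length", "AtypicalPairSet", function(x) nrow(x@pairs))

#' Core identity intervals as a GRanges
#'
#' Returns the per-pair union core interval (the matched, non-clipped
#' reference region shared by the two mates) as a
#' [GenomicRanges::GRanges], with the pair's read name, span and per-mate
#' cores in the metadata columns.
#'
#' @param x An `AtypicalPairSet`.
#' @return A `GRanges`, one range per pair.
#' @export
coreRanges <- function(x) {
    stopifnot(is(x, "AtypicalPairSet"))
    p <- x@pairs
    gr <- GenomicRanges::GRanges(p$ref_name,
        IRanges::IRanges(p$core_start, p$core_end))
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
        read_name = p$read_name, span = p$span, core_len = p$core_len)
    gr
}

setMethod("show", "AtypicalPairSet", function(object) {
    cat(sprintf("AtypicalPairSet with %d pair(s)\n", length(object)))
    pr <- object@params
    if (length(pr))
        cat(sprintf("  span in [%s, %s] bp, min MAPQ %s\n",
                    pr$min_span, pr$max_span, pr$min_mapq))
    if (length(object))
        cat(sprintf("  core lengths: %d-%d bp; references: %s\n",
                    min(object@pairs$core_len), max(object@pairs$core_len),
                    paste(unique(object@pairs$ref_name), collapse = ", ")))
    rej <- object@rejects[object@rejects > 0L]
    if (length(rej))
        cat("  rejected records:",
            paste(names(rej), rej, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "MapqProfile", function(object) {
    cat(sprintf("MapqProfile over %d alignment(s)\n", object@nAlignments))
    cat(sprintf("  per mate:  MAPQ<=10: %s  11-39: %s  >=40: %s\n",
                fmtFrac(object@fracLe10), fmtFrac(object@fracMid),
                fmtFrac(object@fracGe40)))
    cat(sprintf("  per pair:  MAPQ<=10: %s  >=40: %s\n",
                fmtFrac(object@pairFracLe10), fmtFrac(object@pairFracGe40)))
})

fmtFrac <- function(x) {
    if (is.na(x)) "undefined" else sprintf("%.2f%%", 100 * x)
}

#' @rdname TaxonTally-class
#' @param x,object An object.
#' @export
setGeneric("speciesCounts", function(x) standardGeneric("speciesCounts"))

#' @rdname TaxonTally-class
#' @export
setMethod("speciesCounts", "TaxonTally", function(x) x@species)

#' @rdname TaxonTally-class
#' @export
setGeneric("genusCounts", function(x) standardGeneric("genusCounts"))

#' @rdname TaxonTally-class
#' @export
setMethod("genusCounts", "TaxonTally", function(x) x@genus)

#' @rdname TaxonTally-class
#' @export
setGeneric("categoryCounts", function(x) standardGeneric("categoryCounts"))

#' @rdname TaxonTally-class
#' @export
setMethod("categoryCounts", "TaxonTally", function(x) x@category)

setMethod("show", "TaxonTally", function(object) {
    cat(sprintf("TaxonTally over %d quer%s (%d no-hit",
                object@nQueries, if (object@nQueries == 1) "y" else "ies",
                object@nNoHit))
    if (object@nUnmappedSubject > 0L)
        cat(sprintf(", %d unmapped-subject", object@nUnmappedSubject))
    cat(")\n")
    k <- object@category
    k <- k[order(-k$count), , drop = FALSE]
    for (i in seq_len(min(nrow(k), 5L)))
        cat(sprintf("  %-16s %6d  (%.2f%% of all, %.2f%% of assigned)\n",
                    k$category[i], k$count[i], 100 * k$frac_all[i],
                    100 * k$frac_assigned[i]))
    if (nrow(k) > 5L) cat("  ...\n")
})

#' @rdname DecoySequence-class
#' @param x,object An object.
#' @export
setGeneric("decoySeq", function(x) standardGeneric("decoySeq"))

#' @rdname DecoySequence-class
#' @export
setMethod("decoySeq", "DecoySequence", function(x) x@seq)

#' @rdname DecoySequence-class
#' @export
setGeneric("components", function(x) standardGeneric("components"))

#' @rdname DecoySequence-class
#' @export
setMethod("components", "DecoySequence", function(x) x@components)

#' @rdname DecoySequence-class
#' @export
setGeneric("spacerLen", function(x) standardGeneric("spacerLen"))

#' @rdname DecoySequence-class
#' @export
setMethod("spacerLen", "DecoySequence", function(x) x@spacerLen)

#' @rdname DecoySequence-class
#' @export
setMethod("length", "DecoySequence", function(x) length(x@seq))

setMethod("show", "DecoySequence", function(object) {
    cat(sprintf("DecoySequence: %d bp, %d component(s), %d-N spacers\n",
                length(object@seq), nrow(object@components),
                object@spacerLen))
    nN <- Biostrings::countPattern("N", object@seq)
    cat(sprintf("  N bases (spacers + masks): %d (%.1f%%)\n", nN,
                100 * nN / length(object@seq)))
})

setMethod("show", "AlignmentStats", function(object) {
    cat(sprintf(paste0("AlignmentStats: %g reads, %g unaligned, ",
                       "%g atypical pair(s), %g on decoy\n"),
                object@nReadsTotal, object@nUnaligned,
                object@nAtypicalPairs, object@nMappedToDecoy))
})

#' @rdname GenotypeComparison-class
#' @param x,object An object.
#' @export
setGeneric("changes", function(x) standardGeneric("changes"))

#' @rdname GenotypeComparison-class
#' @export
setMethod("changes", "GenotypeComparison", function(x) x@changes)

#' @rdname GenotypeComparison-class
#' @export
setGeneric("changeSummary", function(x) standardGeneric("changeSummary"))

#' @rdname GenotypeComparison-class
#' @export
setMethod("changeSummary", "GenotypeComparison", function(x) x@summary)

setMethod("show", "GenotypeComparison", function(object) {
    cat(sprintf("GenotypeComparison over %d locus/loci\n",
                nrow(object@changes)))
    cnt <- object@summary$counts
    for (cl in names(cnt))
        if (cnt[[cl]] > 0L) cat(sprintf("  %-18s %d\n", cl, cnt[[cl]]))
    mq <- object@summary$median_lost_qual
    if (!is.na(mq)) cat(sprintf("  median QUAL of lost variants: %.2f\n", mq))
})
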