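#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' Set of atypically aligned read pairs
#'
#' Container for read pairs whose leftmost-to-rightmost mapped extent
#' (template span) falls inside a short window (by default 1--30 bp), the
#' alignment signature of contaminant reads stuck to the human reference by a
#' short chance identity core.  Each row records the pair's mapping geometry,
#' the per-mate matched ("core") reference intervals, their union, and the
#' soft-clipped flank lengths.
#'
#' @slot pairs A [S4Vectors::DataFrame] with one row per atypical pair:
#'   `read_name`, `ref_name`, `mate1_start`, `mate1_end`, `mate2_start`,
#'   `mate2_end`, `cigar1`, `cigar2`, `mapq1`, `mapq2`, `tlen`, `span`,
#'   `core1_start`, `core1_end`, `core2_start`, `core2_end`, `core_start`,
#'   `core_end`, `core_len`, `clip_left1`, `clip_right1`, `clip_left2`,
#'   `clip_right2`.
#' @slot rejects Named integer vector tallying records excluded from pairing
#'   (secondary/supplementary, duplicates, unmapped, singletons,
#'   cross-reference pairs, malformed CIGARs).
#' @slot params Named list of the detection parameters used
#'   (`min_span`, `max_span`, `min_mapq`).
#'
#' @seealso [detectAtypicalPairs()], [clusterAtypical()], [mapqProfile()]
#' @exportClass AtypicalPairSet
setClass("AtypicalPairSet",
    slots = c(pairs = "DataFrame", rejects = "integer", params = "list"))

setValidity("AtypicalPairSet", function(object) {
    p <- object@pairs
    need <- c("read_name", "ref_name", "span", "core_start", "core_end",
              "core_len", "mapq1", "mapq2", "tlen")
    if (!all(need %in% colnames(p)))
        return(paste("missing pair columns:",
                     paste(setdiff(need, colnames(p)), collapse = ", ")))
    if (nrow(p)) {
        if (any(p$span < 1L))
            return("template span must be >= 1")
        if (any(p$core_len > p$span))
            return("core length cannot exceed template span")
        if (any(p$core_end < p$core_start))
            return("core_end < core_start")
    }
    TRUE
})

#' Mapping-quality profile of atypical alignments
#'
#' MAPQ histogram over atypical alignments plus the two fractions that decide
#' whether a variant caller will see them: callers such as GATK
#' HaplotypeCaller drop alignments with MAPQ <= 10, while alignments with
#' MAPQ >= 40 pass every default filter.  Fractions are reported under two
#' conventions: per mate (each alignment record counted once) and per pair
#' (each pair counted once at its better mate's MAPQ).
#'
#' @slot histogram Integer vector named by MAPQ value, per-mate counts.
#' @slot fracLe10,fracMid,fracGe40 Per-mate fractions with MAPQ <= 10,
#'   in 11--39, and >= 40.  `NA` when the profile is empty.
#' @slot pairFracLe10,pairFracGe40 Same fractions per pair (MAPQ = max of the
#'   two mates).
#' @slot nAlignments Number of mate alignments profiled.
#' @exportClass MapqProfile
setClass("MapqProfile",
    slots = c(histogram = "integer", fracLe10 = "numeric", fracMid = "numeric",
              fracGe40 = "numeric", pairFracLe10 = "numeric",
              pairFracGe40 = "numeric", nAlignments = "integer"))

setValidity("MapqProfile", function(object) {
    fr <- c(object@fracLe10, object@fracMid, object@fracGe40)
    if (any(!is.na(fr) & (fr < 0 | fr > 1)))
        return("fractions must lie in [0, 1]")
    if (sum(object@histogram) != object@nAlignments)
        return("histogram counts must sum to nAlignments")
    TRUE
})

#' Taxonomic tally of BLAST-profiled reads
#'
#' Aggregated best-hit assignments of a query read set: counts per species,
#' per genus, and per category over the eleven-category scheme
#' (Archaea, Bacteria, Fungi, Invertebrate, Plant, Protozoa, Human,
#' Mammalian other, Vertebrate other, Viral, No-hit).  Category fractions are
#' reported both over all queries (No-hit included in the denominator) and
#' over assigned queries only, since published per-category tables are
#' ambiguous about the denominator.
#'
#' @slot species `DataFrame` with columns `species`, `genus`, `category`,
#'   `count`.
#' @slot genus `DataFrame` with columns `genus`, `count`.
#' @slot category `DataFrame` with columns `category`, `count`, `frac_all`,
#'   `frac_assigned`.
#' @slot nQueries Total queries tallied (assigned + no-hit + unmapped-subject).
#' @slot nNoHit Queries with no surviving BLAST hit.
#' @slot nUnmappedSubject Queries whose best hit's subject is absent from the
#'   taxon map; reported separately, outside the eleven categories.
#' @exportClass TaxonTally
setClass("TaxonTally",
    slots = c(species = "DataFrame", genus = "DataFrame",
              category = "DataFrame", nQueries = "integer",
              nNoHit = "integer", nUnmappedSubject = "integer"))

TAXON_CATEGORIES <- c("Archaea", "Bacteria", "Fungi", "Invertebrate", "Plant",
                      "Protozoa", "Human", "Mammalian other",
                      "Vertebrate other", "Viral", "No-hit")

setValidity("TaxonTally", function(object) {
    if (!all(object@category$category %in% TAXON_CATEGORIES))
        return("unknown taxon category label")
    n_assigned <- sum(object@species$count)
    if (n_assigned + object@nNoHit + object@nUnmappedSubject !=
        object@nQueries)
        return("category counts + no-hit + unmapped-subject must equal total")
    TRUE
})

#' Concatenated decoy contig
#'
#' A single decoy sequence built by concatenating selected contaminant
#' genome sequences, each pair of neighbours separated by a fixed run of `N`
#' bases (1000 by default) so that no read can align across a junction.
#' The component index maps decoy coordinates back to source sequences.
#'
#' @slot seq A [Biostrings::DNAString] over A/C/G/T/N.
#' @slot components `DataFrame` with `source_name`, `start` (1-based decoy
#'   offset of the component), `length`.
#' @slot spacerLen Spacer length in bp.
#' @seealso [concatenateDecoy()], [maskIntervals()], [decoyToSource()]
#' @exportClass DecoySequence
setClass("DecoySequence",
    slots = c(seq = "DNAString", components = "DataFrame",
              spacerLen = "integer"))

setValidity("DecoySequence", function(object) {
    cmp <- object@components
    n <- nrow(cmp)
    if (n < 1L) return("decoy must contain at least one component")
    expect_len <- sum(cmp$length) + (n - 1L) * object@spacerLen
    if (length(object@seq) != expect_len)
        return(sprintf("decoy length %d != sum(components) + spacers (%d)",
                       length(object@seq), expect_len))
    if (n > 1L && object@spacerLen > 0L) {
        sp_start <- cmp$start[-n] + cmp$length[-n]
        sp <- Biostrings::extractAt(object@seq,
            IRanges::IRanges(sp_start, width = object@spacerLen))
        if (!all(vapply(sp, function(s)
                Biostrings::countPattern("N", s) == length(s), logical(1))))
            return("inter-component spacers must be all N")
    }
    TRUE
})

#' Alignment-level summary statistics
#'
#' Counts used to quantify a decoy's effect on one sample's alignment:
#' total reads, reads left unaligned, atypical pairs at the impact-assessment
#' MAPQ floor (10, matching what variant callers retain), and reads captured
#' by the decoy contig.
#'
#' @slot nReadsTotal,nUnaligned,nAtypicalPairs,nMappedToDecoy Non-negative
#'   counts.
#' @seealso [reductionMetrics()]
#' @exportClass AlignmentStats
setClass("AlignmentStats",
    slots = c(nReadsTotal = "numeric", nUnaligned = "numeric",
              nAtypicalPairs = "numeric", nMappedToDecoy = "numeric"))

setValidity("AlignmentStats", function(object) {
    v <- c(object@nReadsTotal, object@nUnaligned, object@nAtypicalPairs,
           object@nMappedToDecoy)
    if (any(v < 0)) return("all counts must be >= 0")
    if (object@nUnaligned > object@nReadsTotal)
        return("nUnaligned cannot exceed nReadsTotal")
    TRUE
})

#' @describeIn AlignmentStats-class Constructor.
#' @param nReadsTotal,nUnaligned,nAtypicalPairs,nMappedToDecoy counts.
#' @export
AlignmentStats <- function(nReadsTotal = 0, nUnaligned = 0,
                           nAtypicalPairs = 0, nMappedToDecoy = 0) {
    new("AlignmentStats", nReadsTotal = as.numeric(nReadsTotal),
        nUnaligned = as.numeric(nUnaligned),
        nAtypicalPairs = as.numeric(nAtypicalPairs),
        nMappedToDecoy = as.numeric(nMappedToDecoy))
}

#' Pre/post-decoy genotype comparison
#'
#' Per-locus classification of genotype calls between a VCF called against
#' the plain reference (`pre`) and one called after appending the decoy
#' (`post`).  Loci are matched on (chrom, pos, ref, alt) after multi-allelic
#' decomposition.  Classes: `lost` (pre only), `new` (post only),
#' `restored_hom_alt` (0/1 pre, 1/1 post: the false-heterozygous call driven
#' by contaminant reference-supporting reads, corrected by the decoy),
#' `unchanged`, `other`.
#'
#' @slot changes `DataFrame` with `chrom`, `pos`, `ref`, `alt`, `gt_pre`,
#'   `gt_post`, `qual_pre`, `qual_post`, `change_class`.
#' @slot summary List: per-class counts, total loci, and the median QUAL of
#'   lost variants (lower median for even counts).
#' @seealso [compareVcfs()]
#' @exportClass GenotypeComparison
setClass("GenotypeComparison",
    slots = c(changes = "DataFrame", summary = "list"))

GENOTYPE_CLASSES <- c("lost", "new", "restored_hom_alt", "unchanged", "other")

setValidity("GenotypeComparison", function(object) {
    cls <- object@changes$change_class
    if (!all(cls %in% GENOTYPE_CLASSES))
        return("unknown change_class label")
    cnt <- object@summary$counts
    if (!is.null(cnt) && sum(cnt) != nrow(object@changes))
        return("summary counts must sum to number of loci")
    TRUE
})
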