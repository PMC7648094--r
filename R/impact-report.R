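#' @importFrom VariantAnnotation readVcf alt geno
#' @importFrom SummarizedExperiment rowRanges
#' @importFrom GenomicRanges seqnames start end
NULL

## Parse a VCF (path or VCF object) into one row per (chrom,pos,ref,alt)
## after multi-allelic decomposition.  Genotypes are recoded relative to
## each alternate allele: the alt -> 1, the reference -> 0, any other
## allele -> 2; the pair is sorted, so "1/0" becomes "0/1".
parseVcfRecords <- function(x) {
    if (is.character(x)) x <- readVcf(x, genome = "unknown")
    rr <- rowRanges(x)
    n <- length(rr)
    gts <- if ("GT" %in% names(geno(x))) geno(x)$GT[, 1L]
           else rep("./.", n)
    alts <- alt(x)
    if (!is(alts, "CharacterList"))
        alts <- IRanges::CharacterList(lapply(alts, as.character))
    nalt <- lengths(alts)
    i <- rep(seq_len(n), nalt)
    ai <- unlist(lapply(nalt, seq_len), use.names = FALSE)
    gt <- recodeGT(gts[i], ai)
    data.frame(
        chrom = as.character(seqnames(rr))[i],
        pos = start(rr)[i],
        ref = as.character(rr$REF)[i],
        alt = unlist(alts, use.names = FALSE),
        gt = gt,
        qual = as.numeric(rr$QUAL)[i],
        stringsAsFactors = FALSE)
}

recodeGT <- function(gt, altIndex) {
    gt <- gsub("|", "/", gt, fixed = TRUE)
    parts <- strsplit(gt, "/", fixed = TRUE)
    vapply(seq_along(parts), function(j) {
        a <- parts[[j]]
        if (any(a == ".")) return("./.")
        a <- as.integer(a)
        a <- ifelse(a == 0L, 0L, ifelse(a == altIndex[j], 1L, 2L))
        paste(sort(a), collapse = "/")
    }, character(1))
}

#' Variants within a window of atypical clusters
#'
#' Returns the variants whose POS lies inside a cluster or within
#' `window` bp of its nearest base (positional distance; a variant at
#' POS 1130 is 100 bp from a cluster ending at 1030 and is included at
#' the default window).  Indels are anchored at POS only.
#'
#' @param vcf VCF path, `VCF` object, or a parsed record data frame.
#' @param clusters `GRanges` from [clusterAtypical()] (or
#'   [readClustersBed()]).
#' @param window Distance window in bp (default 100).
#' @return The subset of parsed variant records (`chrom`, `pos`, `ref`,
#'   `alt`, `gt`, `qual`) near clusters.
#' @export
variantsNearAtypical <- function(vcf, clusters, window = 100L) {
    v <- if (is.data.frame(vcf)) vcf else parseVcfRecords(vcf)
    if (!nrow(v)) return(v)
    if (length(clusters)) {
        vc <- unique(v$chrom)
        cc <- unique(as.character(seqnames(clusters)))
        if (!length(intersect(vc, cc)))
            stop("contig names in VCF and clusters do not overlap; VCF: ",
                 paste(vc, collapse = ", "), "; clusters: ",
                 paste(cc, collapse = ", "))
    } else return(v[0L, , drop = FALSE])
    pos <- GRanges(v$chrom, IRanges(v$pos, width = 1L))
    hit <- IRanges::overlapsAny(pos, clusters,
                                      maxgap = window - 1L,
                                      ignore.strand = TRUE)
    v[hit, , drop = FALSE]
}

#' Compare pre- and post-decoy variant calls
#'
#' Matches loci on (chrom, pos, ref, alt) after multi-allelic decomposition
#' and classifies every locus present in either call set:
#' `lost` (pre only), `new` (post only), `restored_hom_alt`
#' (heterozygous 0/1 before the decoy, homozygous-alternate 1/1 after --
#' the signature correction when contaminant reference-supporting reads no
#' longer align), `unchanged` (same genotype) and `other`.  The summary
#' reports per-class counts and the median QUAL of lost variants (lower
#' median for even counts, so the value is always an observed QUAL).
#'
#' @param vcfPre,vcfPost VCF paths, `VCF` objects, or parsed record data
#'   frames from the pre-decoy and post-decoy pipelines.
#' @return A [GenotypeComparison].
#' @export
compareVcfs <- function(vcfPre, vcfPost) {
    pre <- if (is.data.frame(vcfPre)) vcfPre else parseVcfRecords(vcfPre)
    post <- if (is.data.frame(vcfPost)) vcfPost else parseVcfRecords(vcfPost)
    key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = ":")
    kpre <- key(pre); kpost <- key(post)
    allk <- union(kpre, kpost)
    mpre <- match(allk, kpre); mpost <- match(allk, kpost)

    gt_pre <- ifelse(is.na(mpre), NA_character_, pre$gt[mpre])
    gt_post <- ifelse(is.na(mpost), NA_character_, post$gt[mpost])
    src <- ifelse(is.na(mpre), mpost + nrow(pre), mpre)
    both <- rbind(pre, post)
    cls <- classifyChange(gt_pre, gt_post)

    changes <- DataFrame(
        chrom = both$chrom[src], pos = both$pos[src],
        ref = both$ref[src], alt = both$alt[src],
        gt_pre = gt_pre, gt_post = gt_post,
        qual_pre = ifelse(is.na(mpre), NA_real_, pre$qual[mpre]),
        qual_post = ifelse(is.na(mpost), NA_real_, post$qual[mpost]),
        change_class = cls)
    ord <- order(changes$chrom, changes$pos, changes$alt)
    changes <- changes[ord, , drop = FALSE]
    counts <- stats::setNames(
        vapply(GENOTYPE_CLASSES, function(k) sum(cls == k), integer(1)),
        GENOTYPE_CLASSES)
    lostq <- changes$qual_pre[changes$change_class == "lost"]
    lostq <- lostq[!is.na(lostq)]
    new("GenotypeComparison", changes = changes,
        summary = list(counts = counts, n_loci = length(allk),
                       n_pre = nrow(pre), n_post = nrow(post),
                       median_lost_qual = lowerMedian(lostq)))
}

classifyChange <- function(gt_pre, gt_post) {
    ifelse(is.na(gt_post), "lost",
    ifelse(is.na(gt_pre), "new",
    ifelse(gt_pre == gt_post, "unchanged",
    ifelse(gt_pre == "0/1" & gt_post == "1/1", "restored_hom_alt",
           "other"))))
}

## Lower median: for even n, the n/2-th order statistic (deterministic,
## always an observed value).
lowerMedian <- function(x) {
    if (!length(x)) return(NA_real_)
    sort(x)[ceiling(length(x) / 2)]
}

#' Percent-reduction metrics between pre- and post-decoy alignments
#'
#' For the unaligned-read count and the atypical-pair count,
#' `r = 100 * (1 - post / pre)`.  A zero pre-decoy count makes the metric
#' undefined (`NA`), not 0; a post count exceeding pre yields a negative
#' reduction with a warning, never clamped.
#'
#' @param statsPre,statsPost [AlignmentStats] for the same read set
#'   aligned without and with the decoy.
#' @return A list with `unaligned_reduction_pct`,
#'   `atypical_reduction_pct`, and `n_mapped_to_decoy`.
#' @export
reductionMetrics <- function(statsPre, statsPost) {
    stopifnot(is(statsPre, "AlignmentStats"), is(statsPost, "AlignmentStats"))
    red <- function(pre, post, what) {
        if (pre == 0) {
            message("pre-decoy ", what, " count is 0: reduction undefined")
            return(NA_real_)
        }
        r <- 100 * (1 - post / pre)
        if (r < 0)
            warning(what, " count increased after decoy (reduction ",
                    sprintf("%.2f", r), "%)")
        r
    }
    list(unaligned_reduction_pct =
             red(statsPre@nUnaligned, statsPost@nUnaligned, "unaligned"),
         atypical_reduction_pct =
             red(statsPre@nAtypicalPairs, statsPost@nAtypicalPairs,
                 "atypical-pair"),
         n_mapped_to_decoy = statsPost@nMappedToDecoy)
}

#' Partition allelic support at a SNV between typical and atypical reads
#'
#' Classifies every read overlapping an SNV position by (typical vs
#' atypical, membership in `atypicalReadNames`) crossed with the base the
#' read places on the position after CIGAR projection (ref vs alt vs
#' other).  At contaminant-driven loci the atypical reads all carry the
#' reference base while typical reads carry the alternate.
#'
#' @param alignments SAM/BAM path.
#' @param chrom,pos Locus (1-based).
#' @param ref,alt Reference and alternate base (single characters).
#' @param atypicalReadNames Character vector of atypical pair read names.
#' @return A list of counts: `ref_support_typical`,
#'   `alt_support_typical`, `ref_support_atypical`,
#'   `alt_support_atypical`, `other_support`, `n_not_overlapping`.
#' @export
allelicSupportPartition <- function(alignments, chrom, pos, ref, alt,
                                    atypicalReadNames) {
    stopifnot(nchar(ref) == 1L, nchar(alt) == 1L)
    bam <- ensureBam(alignments)
    res <- scanBam(bam, param = ScanBamParam(
        what = c("qname", "flag", "rname", "pos", "cigar", "seq")))[[1]]
    keep <- !hasFlag(res$flag, FLAG_SECONDARY) &
        !hasFlag(res$flag, FLAG_SUPPLEMENTARY) &
        !hasFlag(res$flag, FLAG_DUP) & !hasFlag(res$flag, FLAG_UNMAPPED) &
        as.character(res$rname) == chrom & !is.na(res$pos)
    out <- c(ref_support_typical = 0L, alt_support_typical = 0L,
             ref_support_atypical = 0L, alt_support_atypical = 0L,
             other_support = 0L, n_not_overlapping = 0L)
    seen <- character(0)
    for (i in which(keep)) {
        base <- baseAtPosition(res$cigar[i], res$pos[i],
                               as.character(res$seq[i]), pos)
        qn <- res$qname[i]
        ## count each pair's support once per mate observation
        if (is.na(base)) { out["n_not_overlapping"] <-
            out["n_not_overlapping"] + 1L; next }
        atyp <- qn %in% atypicalReadNames
        if (base == ref) {
            k <- if (atyp) "ref_support_atypical" else "ref_support_typical"
        } else if (base == alt) {
            k <- if (atyp) "alt_support_atypical" else "alt_support_typical"
        } else k <- "other_support"
        out[k] <- out[k] + 1L
        seen <- c(seen, qn)
    }
    as.list(out)
}

## Read base projected onto a reference position via the CIGAR, or NA when
## the position is not consumed by an aligned (M/=/X) block.
baseAtPosition <- function(cigar, alnStart, seq, refPos) {
    ops <- explodeCigarOps(cigar)[[1]]
    lens <- explodeCigarOpLengths(cigar)[[1]]
    rpos <- alnStart; qpos <- 1L
    for (k in seq_along(ops)) {
        op <- ops[k]; l <- lens[k]
        if (op %in% c("M", "=", "X")) {
            if (refPos >= rpos && refPos < rpos + l)
                return(substr(seq, qpos + (refPos - rpos),
                              qpos + (refPos - rpos)))
            rpos <- rpos + l; qpos <- qpos + l
        } else if (op %in% c("D", "N")) {
            if (op == "D" && refPos >= rpos && refPos < rpos + l)
                return(NA_character_)
            rpos <- rpos + l
        } else if (op %in% c("I", "S")) {
            qpos <- qpos + l
        }
    }
    NA_character_
}

#' Fraction of variants attributable to atypical alignments
#'
#' The share of pre-decoy variants that disappear once the decoy is added
#' and that lie within `window` bp of an atypical cluster:
#' `100 * n_lost_near_clusters / n_pre_variants`, in percent.  When a BED
#' of coding intervals is supplied the same fraction is also computed over
#' the coding subset.
#'
#' @param vcfPre,vcfPost VCF paths, `VCF` objects or parsed record data
#'   frames.
#' @param clusters `GRanges` of atypical clusters.
#' @param window Proximity window in bp (default 100).
#' @param codingBed Optional BED path (or `GRanges`) of coding intervals.
#' @return A list: `percent`, `n_lost_near`, `n_pre`, and when coding
#'   intervals are given, `percent_coding`, `n_lost_near_coding`,
#'   `n_pre_coding`.
#' @export
fractionVariantsAttributable <- function(vcfPre, vcfPost, clusters,
                                         window = 100L, codingBed = NULL) {
    pre <- if (is.data.frame(vcfPre)) vcfPre else parseVcfRecords(vcfPre)
    post <- if (is.data.frame(vcfPost)) vcfPost else parseVcfRecords(vcfPost)
    if (!nrow(pre)) {
        message("empty pre-decoy VCF: fraction undefined")
        return(list(percent = NA_real_, n_lost_near = 0L, n_pre = 0L))
    }
    cmp <- compareVcfs(pre, post)
    ch <- as.data.frame(changes(cmp))
    lost <- ch[ch$change_class == "lost", , drop = FALSE]
    lost_near <- if (nrow(lost) && length(clusters))
        variantsNearAtypical(
            lost[, c("chrom", "pos", "ref", "alt")],
            clusters, window)
    else lost[0L, , drop = FALSE]
    out <- list(percent = 100 * nrow(lost_near) / nrow(pre),
                n_lost_near = nrow(lost_near), n_pre = nrow(pre))
    if (!is.null(codingBed)) {
        cod <- if (is(codingBed, "GRanges")) codingBed
               else rtracklayer::import(codingBed, format = "BED")
        inCoding <- function(d) {
            if (!nrow(d)) return(d)
            g <- GRanges(d$chrom, IRanges(d$pos, width = 1L))
            d[IRanges::overlapsAny(g, cod, ignore.strand = TRUE), ,
              drop = FALSE]
        }
        pre_cod <- inCoding(pre)
        lost_cod <- inCoding(lost_near)
        out$percent_coding <- if (nrow(pre_cod))
            100 * nrow(lost_cod) / nrow(pre_cod) else NA_real_
        out$n_lost_near_coding <- nrow(lost_cod)
        out$n_pre_coding <- nrow(pre_cod)
    }
    out
}
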