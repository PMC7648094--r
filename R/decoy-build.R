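#' @importFrom Biostrings DNAString DNAStringSet readDNAStringSet
#'   writeXStringSet replaceAt extractAt pairwiseAlignment nmatch nchar
#' @importFrom IRanges IRanges reduce
NULL

#' Concatenate selected genomes into a decoy contig
#'
#' Joins the input sequences in order, separating each neighbouring pair
#' with a run of `spacerLen` `N` bases so that no read can align across a
#' junction.  Input is uppercased and IUPAC ambiguity codes are converted
#' to `N`.  The component index (name, 1-based decoy offset, length) is
#' retained for coordinate back-mapping.
#'
#' @param sequences A named [Biostrings::DNAStringSet] (or named character
#'   vector) of selected genome/contig sequences.
#' @param spacerLen Spacer length in bp (default 1000).
#' @return A [DecoySequence].
#' @export
concatenateDecoy <- function(sequences, spacerLen = 1000L) {
    if (is.character(sequences)) sequences <- DNAStringSet(sequences)
    stopifnot(length(sequences) >= 1L)
    nm <- names(sequences)
    if (is.null(nm)) nm <- paste0("component_", seq_along(sequences))
    lens <- Biostrings::width(sequences)
    if (any(lens == 0L))
        stop("empty input sequence: ", paste(nm[lens == 0L], collapse = ", "))
    ## uppercase + collapse ambiguity codes to N
    seqs <- toupper(as.character(sequences))
    seqs <- gsub("[^ACGTN]", "N", seqs)
    spacer <- strrep("N", spacerLen)
    decoy <- DNAString(paste(seqs, collapse = spacer))
    starts <- as.integer(cumsum(c(1L, utils::head(lens + spacerLen, -1L))))
    new("DecoySequence", seq = decoy,
        components = DataFrame(source_name = nm, start = starts,
                               length = lens),
        spacerLen = as.integer(spacerLen))
}

#' Map a decoy coordinate back to its source sequence
#'
#' @param decoy A [DecoySequence].
#' @param pos 1-based decoy coordinate(s).
#' @return A `data.frame` with `source_name` (`NA` inside spacers) and
#'   `source_offset` (1-based offset within the source).
#' @export
decoyToSource <- function(decoy, pos) {
    cmp <- decoy@components
    idx <- findInterval(pos, cmp$start)
    src <- rep(NA_character_, length(pos))
    off <- rep(NA_integer_, length(pos))
    inside <- idx >= 1L & pos <= cmp$start[pmax(idx, 1L)] +
        cmp$length[pmax(idx, 1L)] - 1L
    src[inside] <- cmp$source_name[idx[inside]]
    off[inside] <- pos[inside] - cmp$start[idx[inside]] + 1L
    data.frame(source_name = src, source_offset = off)
}

#' Find decoy regions highly similar to the human genome
#'
#' Decoy bases similar to human sequence would compete with the human
#' reference for genuinely human reads, so they must be masked.  The decoy
#' is scanned in fixed windows (`window` bp every `step` bp); each window
#' is seeded against a k-mer index of the human reference (`seedK`), and
#' every seeded candidate region is locally aligned to the window.  The
#' window is masked when any local alignment reaches `minIdentity` over at
#' least `window / 2` aligned columns.  Overlapping masked windows are
#' merged.
#'
#' @param decoy A [DecoySequence] (or a `DNAString`).
#' @param humanRef A [Biostrings::DNAString] / `DNAStringSet` (first
#'   sequence used) or FASTA path.
#' @param minIdentity Identity threshold (default 0.65).
#' @param window,step Window size and stride in bp (defaults 100 and 50).
#' @param seedK Seed k-mer length (default 12).
#' @return An [IRanges::IRanges] of merged masked regions (1-based), with
#'   a `reason` metadata column set to `"human_similar"`.
#' @export
findHumanSimilarRegions <- function(decoy, humanRef, minIdentity = 0.65,
                                    window = 100L, step = 50L,
                                    seedK = 12L) {
    dseq <- if (is(decoy, "DecoySequence")) decoy@seq else DNAString(decoy)
    href <- loadSingleSequence(humanRef)
    n <- length(dseq); h <- length(href)
    if (window > n) window <- n
    hstr <- as.character(href)
    idx <- kmerIndex(hstr, seedK)
    starts <- unique(c(seq(1L, max(1L, n - window + 1L), by = step),
                       max(1L, n - window + 1L)))
    dstr <- as.character(dseq)
    hit_windows <- logical(length(starts))
    for (i in seq_along(starts)) {
        s <- starts[i]
        wseq <- substr(dstr, s, s + window - 1L)
        if (grepl("N", wseq, fixed = TRUE) &&
            nchar(gsub("N", "", wseq, fixed = TRUE)) < seedK) next
        seeds <- unique(substring(wseq, seq(1L, max(1L, nchar(wseq) - seedK + 1L), by = 4L),
                                  seq(1L, max(1L, nchar(wseq) - seedK + 1L), by = 4L) + seedK - 1L))
        seeds <- seeds[nchar(seeds) == seedK & !grepl("N", seeds, fixed = TRUE)]
        cand <- unlist(idx[seeds[seeds %in% names(idx)]], use.names = FALSE)
        if (!length(cand)) next
        ## collapse candidate seed positions into candidate human regions
        reg <- reduce(IRanges(pmax(1L, cand - window),
                              pmin(h, cand + 2L * window)))
        wS <- DNAString(wseq)
        for (j in seq_along(reg)) {
            sub <- Biostrings::subseq(href, IRanges::start(reg)[j],
                                      IRanges::end(reg)[j])
            aln <- pairwiseAlignment(wS, sub, type = "local",
                                     substitutionMatrix = identityScoring(),
                                     gapOpening = 2, gapExtension = 1)
            alen <- nchar(aln)
            if (alen >= window / 2 && nmatch(aln) / alen >= minIdentity) {
                hit_windows[i] <- TRUE
                break
            }
        }
    }
    ir <- IRanges(starts[hit_windows],
                  width = pmin(window, n - starts[hit_windows] + 1L))
    out <- reduce(ir)
    S4Vectors::mcols(out)$reason <- rep("human_similar", length(out))
    out
}

## +1/-1 scoring keeps local alignments honest about identity: a segment
## extends only while matches outnumber mismatches, so the reported
## identity over the aligned columns is the quantity the 65% screen means.
identityScoring <- function() {
    Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                             baseOnly = FALSE)
}

loadSingleSequence <- function(x) {
    if (is.character(x) && length(x) == 1L && file.exists(x))
        x <- readDNAStringSet(x)
    if (is(x, "DNAStringSet")) x <- x[[1]]
    if (is.character(x)) x <- DNAString(x)
    x
}

## Hash of k-mer -> start positions (1-based), skipping k-mers with N.
kmerIndex <- function(seqstr, k) {
    n <- nchar(seqstr)
    if (n < k) return(list())
    starts <- seq_len(n - k + 1L)
    kmers <- substring(seqstr, starts, starts + k - 1L)
    keep <- !grepl("N", kmers, fixed = TRUE)
    split(starts[keep], kmers[keep])
}

#' Find short-unit tandem repeats (polynucleotide runs)
#'
#' Low-complexity runs of a repeated unit (homopolymers up to hexanucleotide
#' repeats by default) attract spurious alignments and are masked in the
#' decoy.  A position range is reported when a unit of length
#' `minUnit..maxUnit` repeats contiguously over at least `minTotalLen` bp;
#' nested and overlapping runs are merged.  Runs consisting solely of `N`
#' (e.g. the inter-component spacers, which are already masked) are not
#' reported.
#'
#' @param decoy A [DecoySequence], `DNAString` or character string.
#' @param minUnit,maxUnit Repeat-unit lengths considered (defaults 1 and 6).
#' @param minTotalLen Minimum total run length in bp (default 20).
#' @return An `IRanges` of merged repeat regions (1-based) with a `reason`
#'   column set to `"polynucleotide_repeat"`.
#' @export
findPolynucleotideRepeats <- function(decoy, minUnit = 1L, maxUnit = 6L,
                                      minTotalLen = 20L) {
    s <- decoySeqToChars(decoy)
    n <- length(s)
    hits <- IRanges()
    for (u in seq.int(minUnit, maxUnit)) {
        if (n <= u) break
        eq <- s[seq_len(n - u)] == s[seq_len(n - u) + u]
        r <- rle(eq)
        ends <- cumsum(r$lengths)
        starts <- ends - r$lengths + 1L
        good <- r$values & (r$lengths + u) >= minTotalLen
        if (any(good))
            hits <- c(hits, IRanges(starts[good], ends[good] + u))
    }
    out <- reduce(hits)
    if (length(out)) {
        ## drop pure-N runs (spacers are already masked)
        allN <- vapply(seq_along(out), function(i) {
            all(s[IRanges::start(out)[i]:IRanges::end(out)[i]] == "N")
        }, logical(1))
        out <- out[!allN]
    }
    S4Vectors::mcols(out)$reason <- rep("polynucleotide_repeat", length(out))
    out
}

decoySeqToChars <- function(decoy) {
    x <- if (is(decoy, "DecoySequence")) as.character(decoy@seq)
         else if (is(decoy, "DNAString")) as.character(decoy)
         else as.character(decoy)
    strsplit(x, "", fixed = TRUE)[[1]]
}

#' Find internally duplicated decoy regions
#'
#' Regions represented more than once in the decoy would let one read align
#' equally well to several decoy locations, so every copy after the first
#' occurrence is masked (the first is kept: masking all copies would delete
#' legitimate decoy content).  Duplicates are detected by shared-k-mer
#' chaining: every position of a k-mer seen earlier in the decoy is marked,
#' marked positions are merged, and merged intervals of at least `minLen`
#' bp are reported.
#'
#' @param decoy A [DecoySequence], `DNAString` or character string.
#' @param minLen Minimum duplicated-interval length in bp (default 100).
#' @param k Seed k-mer length (default 21).
#' @return An `IRanges` of merged later-copy regions with `reason` set to
#'   `"internal_duplicate"`.
#' @export
findInternalDuplicates <- function(decoy, minLen = 100L, k = 21L) {
    x <- if (is(decoy, "DecoySequence")) as.character(decoy@seq)
         else as.character(decoy)
    idx <- kmerIndex(x, k)
    dup <- idx[lengths(idx) >= 2L]
    if (!length(dup)) {
        out <- IRanges()
        S4Vectors::mcols(out)$reason <- character(0)
        return(out)
    }
    later <- unlist(lapply(dup, function(p) sort(p)[-1L]), use.names = FALSE)
    out <- reduce(IRanges(later, width = k))
    out <- out[IRanges::width(out) >= minLen]
    S4Vectors::mcols(out)$reason <- rep("internal_duplicate", length(out))
    out
}

#' Mask decoy intervals with N
#'
#' Every base inside any interval becomes `N`; all other bases and the
#' total length are unchanged.  Masking is idempotent and the three mask
#' passes (human-similar, polynucleotide repeat, internal duplicate)
#' commute.
#'
#' @param decoy A [DecoySequence].
#' @param intervals An `IRanges` (1-based, within bounds) or a list of
#'   such, which are combined.
#' @return The masked [DecoySequence].
#' @export
maskIntervals <- function(decoy, intervals) {
    stopifnot(is(decoy, "DecoySequence"))
    if (is.list(intervals))
        intervals <- do.call(c, lapply(intervals, function(x) {
            S4Vectors::mcols(x) <- NULL
            x
        }))
    S4Vectors::mcols(intervals) <- NULL
    if (!length(intervals)) return(decoy)
    n <- length(decoy@seq)
    if (any(IRanges::start(intervals) < 1L | IRanges::end(intervals) > n))
        stop("mask interval out of decoy bounds")
    iv <- reduce(intervals)
    masked <- replaceAt(decoy@seq, iv,
                        as.character(lapply(IRanges::width(iv),
                                            function(w) strrep("N", w))))
    new("DecoySequence", seq = masked, components = decoy@components,
        spacerLen = decoy@spacerLen)
}

#' Append the decoy contig to a reference FASTA
#'
#' Writes the reference records in their original order followed by the
#' decoy as one extra contig, 60-column wrapped.  Fails if `contigName`
#' already exists in the reference.
#'
#' @param referenceFasta Path to the reference FASTA.
#' @param decoy A [DecoySequence].
#' @param contigName Name for the decoy contig.
#' @param outFasta Output path.
#' @return `outFasta`, invisibly.
#' @export
appendDecoyToReference <- function(referenceFasta, decoy, contigName,
                                   outFasta) {
    ref <- readDNAStringSet(referenceFasta)
    refnames <- sub("\\s.*$", "", names(ref))
    if (contigName %in% refnames)
        stop("contig name already present in reference: ", contigName)
    out <- c(ref, DNAStringSet(stats::setNames(
        as.character(decoy@seq), contigName)))
    writeXStringSet(out, outFasta, width = 60L)
    invisible(outFasta)
}

#' Write mask intervals as BED
#'
#' Columns chrom, start, end, reason; BED convention (0-based half-open).
#'
#' @param intervals `IRanges` with a `reason` metadata column (or list of
#'   such from the three finders).
#' @param chrom Contig name to write (the decoy's).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeMaskBed <- function(intervals, chrom, path) {
    if (is.list(intervals)) {
        reason <- unlist(lapply(intervals,
                                function(x) S4Vectors::mcols(x)$reason))
        iv <- do.call(c, lapply(intervals, function(x) {
            S4Vectors::mcols(x) <- NULL
            x
        }))
    } else {
        reason <- S4Vectors::mcols(intervals)$reason
        iv <- intervals
    }
    if (is.null(reason)) reason <- rep(".", length(iv))
    ord <- order(IRanges::start(iv))
    df <- data.frame(chrom = chrom, start = IRanges::start(iv)[ord] - 1L,
                     end = IRanges::end(iv)[ord], reason = reason[ord])
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Write the decoy component index as TSV
#'
#' @param decoy A [DecoySequence].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeComponentIndex <- function(decoy, path) {
    utils::write.table(as.data.frame(decoy@components), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(path)
}
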