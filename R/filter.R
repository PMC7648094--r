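#' Remove or annotate atypical read pairs in a SAM/BAM file
#'
#' Record-level mitigation that needs no re-alignment: pairs whose template
#' span falls in `[minSpan, maxSpan]` are either dropped (both mates,
#' `mode = "remove"`) or tagged in place (`mode = "annotate"`, tag
#' `ZA:i:<span>` on both mates, nothing dropped).  All other records are
#' preserved byte-identically; the header is preserved and a `@PG` line is
#' appended.  Pairs are re-derived from the file with the same rules as
#' [detectAtypicalPairs()] (primary, non-duplicate, both mates mapped to the
#' same reference).  Orphan records -- mate flagged as mapped but absent
#' from the file -- whose `|TLEN|` falls in the span window are annotated
#' and never removed, with a warning.
#'
#' @param samIn Input SAM text or BAM path.
#' @param samOut Output path; written as BAM when it ends in `.bam`,
#'   SAM text otherwise.
#' @param mode `"remove"` or `"annotate"`.
#' @param minSpan,maxSpan Span window in bp (defaults 1 and 30).
#' @return Invisibly, a report list: `n_pairs_flagged`,
#'   `n_records_removed`, `n_records_tagged`, `n_orphans_annotated`,
#'   `n_records_in`, `n_records_out`, and the flagged read names.
#' @export
filterByTlen <- function(samIn, samOut, mode = c("remove", "annotate"),
                         minSpan = 1L, maxSpan = 30L) {
    mode <- match.arg(mode)
    lines <- samLines(samIn)
    is_hdr <- startsWith(lines, "@")
    header <- lines[is_hdr]
    recs <- lines[!is_hdr]

    flagged <- character(0)
    orphan_idx <- integer(0)
    span_of <- integer(0)
    if (length(recs)) {
        f <- strsplit(recs, "\t", fixed = TRUE)
        qname <- vapply(f, `[[`, "", 1L)
        flag <- as.integer(vapply(f, `[[`, "", 2L))
        rname <- vapply(f, `[[`, "", 3L)
        pos <- as.integer(vapply(f, `[[`, "", 4L))
        cigar <- vapply(f, `[[`, "", 6L)
        tlen <- as.integer(vapply(f, `[[`, "", 9L))

        eligible <- !hasFlag(flag, FLAG_SECONDARY) &
            !hasFlag(flag, FLAG_SUPPLEMENTARY) & !hasFlag(flag, FLAG_DUP) &
            !hasFlag(flag, FLAG_UNMAPPED) & rname != "*"
        refw <- tryCatchCigarWidth(cigar)
        eligible <- eligible & refw$valid & !is.na(refw$width) &
            refw$width >= 1L
        endp <- pos + refw$width - 1L

        cnt <- table(qname[eligible])
        paired <- names(cnt)[cnt == 2L]
        idx <- which(eligible & qname %in% paired)
        if (length(idx)) {
            sp <- split(idx, qname[idx])
            first <- vapply(sp, `[[`, 0L, 1L)
            second <- vapply(sp, `[[`, 0L, 2L)
            same <- rname[first] == rname[second]
            span <- pmax(endp[first], endp[second]) -
                pmin(pos[first], pos[second]) + 1L
            hit <- same & span >= minSpan & span <= maxSpan
            flagged <- names(sp)[hit]
            span_of <- stats::setNames(span[hit], flagged)
        }
        ## orphans: mate claimed mapped, |TLEN| in window, but mate absent
        lone <- eligible & !(qname %in% paired) &
            hasFlag(flag, FLAG_PAIRED) & !hasFlag(flag, FLAG_MUNMAPPED) &
            abs(tlen) >= minSpan & abs(tlen) <= maxSpan
        orphan_idx <- which(lone)
        if (length(orphan_idx))
            warning(length(orphan_idx), " orphan record(s) with in-window ",
                    "|TLEN| but missing mate: annotated, not removed")
    }

    n_in <- length(recs)
    tagged <- 0L
    if (length(recs)) {
        in_flagged <- qname %in% flagged &
            !hasFlag(flag, FLAG_SECONDARY) &
            !hasFlag(flag, FLAG_SUPPLEMENTARY) & !hasFlag(flag, FLAG_DUP)
        if (mode == "remove") {
            drop <- qname %in% flagged
            removed <- sum(drop)
            if (length(orphan_idx))
                recs[orphan_idx] <- paste0(recs[orphan_idx], "\tZA:i:",
                                           abs(tlen[orphan_idx]))
            recs <- recs[!drop]
        } else {
            removed <- 0L
            tag_idx <- which(in_flagged)
            if (length(tag_idx)) {
                recs[tag_idx] <- paste0(recs[tag_idx], "\tZA:i:",
                                        span_of[qname[tag_idx]])
                tagged <- length(tag_idx)
            }
            if (length(orphan_idx)) {
                recs[orphan_idx] <- paste0(recs[orphan_idx], "\tZA:i:",
                                           abs(tlen[orphan_idx]))
                tagged <- tagged + length(orphan_idx)
            }
        }
    } else removed <- 0L

    pg <- sprintf(
        "@PG\tID:SalivaDecoy\tPN:SalivaDecoy\tVN:%s\tCL:filterByTlen mode=%s minSpan=%d maxSpan=%d",
        as.character(utils::packageVersion("SalivaDecoy")), mode,
        as.integer(minSpan), as.integer(maxSpan))
    out_lines <- c(header, pg, recs)
    if (grepl("\\.bam$", samOut, ignore.case = TRUE)) {
        tmp <- tempfile(fileext = ".sam")
        writeLines(out_lines, tmp)
        Rsamtools::asBam(tmp, sub("\\.bam$", "", samOut, ignore.case = TRUE),
                         overwrite = TRUE, indexDestination = FALSE)
    } else {
        writeLines(out_lines, samOut)
    }
    invisible(list(
        n_pairs_flagged = length(flagged),
        n_records_removed = removed,
        n_records_tagged = tagged,
        n_orphans_annotated = length(orphan_idx),
        n_records_in = n_in,
        n_records_out = length(recs),
        flagged_read_names = flagged))
}
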