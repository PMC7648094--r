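#' Read BLAST tabular output
#'
#' Parses the standard 12-column tabular dialect
#' (`qseqid sseqid pident length mismatch gapopen qstart qend sstart send
#' evalue bitscore`), with an optional 13th `qlen` column.  Query coverage
#' is computed as `length / qlen`; when the file has no `qlen` column a
#' sidecar table of read lengths must be supplied.
#'
#' @param path Tab-separated BLAST hit file, no header.
#' @param queryLengths Optional named vector (query id -> read length in
#'   bp) used when the file lacks a `qlen` column.
#' @return A `data.frame` of hits with columns `query_id`, `subject_id`,
#'   `pct_identity`, `align_len`, `evalue`, `bitscore`, `query_len`,
#'   `query_cov`.  Malformed rows are skipped with a warning and their
#'   count stored in `attr(x, "n_skipped")`.
#' @export
readBlastTab <- function(path, queryLengths = NULL) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    empty <- data.frame(query_id = character(0), subject_id = character(0),
                        pct_identity = numeric(0), align_len = integer(0),
                        evalue = numeric(0), bitscore = numeric(0),
                        query_len = integer(0), query_cov = numeric(0))
    if (!length(lines)) { attr(empty, "n_skipped") <- 0L; return(empty) }
    f <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(f)
    ok <- nf >= 12L
    n_skipped <- sum(!ok)
    if (n_skipped) warning(n_skipped, " malformed BLAST row(s) skipped")
    f <- f[ok]
    if (!length(f)) { attr(empty, "n_skipped") <- n_skipped; return(empty) }
    col <- function(i) vapply(f, `[[`, "", i)
    out <- data.frame(
        query_id = col(1L), subject_id = col(2L),
        pct_identity = as.numeric(col(3L)),
        align_len = as.integer(col(4L)),
        evalue = as.numeric(col(11L)), bitscore = as.numeric(col(12L)),
        stringsAsFactors = FALSE)
    bad <- is.na(out$align_len) | is.na(out$evalue) | is.na(out$bitscore)
    if (any(bad)) {
        warning(sum(bad), " BLAST row(s) with non-numeric fields skipped")
        n_skipped <- n_skipped + sum(bad)
        out <- out[!bad, , drop = FALSE]
        f <- f[!bad]
        nf <- lengths(f)
    } else nf <- nf[ok]
    if (all(nf >= 13L)) {
        out$query_len <- as.integer(vapply(f, `[[`, "", 13L))
    } else if (!is.null(queryLengths)) {
        out$query_len <- as.integer(queryLengths[out$query_id])
        if (anyNA(out$query_len))
            stop("query length missing for: ",
                 paste(utils::head(unique(
                     out$query_id[is.na(out$query_len)])), collapse = ", "))
    } else {
        stop("no qlen column and no queryLengths table: ",
             "query coverage cannot be computed")
    }
    out$query_cov <- out$align_len / out$query_len
    attr(out, "n_skipped") <- n_skipped
    out
}

#' Read a taxon lookup table
#'
#' Tab-separated with header columns `subject_id`, `species`, `genus`,
#' `category`; `category` must be one of the eleven labels used by
#' [tallyTaxa()] (excluding `No-hit`, which is never a map entry).
#'
#' @param path TSV path.
#' @return A `data.frame` keyed by `subject_id`.
#' @export
readTaxonMap <- function(path) {
    tm <- utils::read.table(path, sep = "\t", header = TRUE,
                            stringsAsFactors = FALSE, quote = "",
                            comment.char = "")
    need <- c("subject_id", "species", "genus", "category")
    if (!all(need %in% colnames(tm)))
        stop("taxon map must have columns: ", paste(need, collapse = ", "))
    badcat <- setdiff(unique(tm$category),
                      setdiff(TAXON_CATEGORIES, "No-hit"))
    if (length(badcat))
        stop("unknown taxon categories: ", paste(badcat, collapse = ", "))
    tm
}

#' Filter BLAST hits on query coverage and e-value
#'
#' Keeps exactly the hits with `query_cov >= minQueryCov` and
#' `evalue <= maxEvalue`.  Defaults (80% coverage, e-value at most 1)
#' define a "positive" BLAST result for contaminant profiling.
#'
#' @param hits Data frame from [readBlastTab()].
#' @param minQueryCov Minimum fraction of the read covered by the
#'   alignment (default 0.80).
#' @param maxEvalue Maximum e-value (default 1.0).
#' @return The surviving subset, same columns.
#' @export
filterHits <- function(hits, minQueryCov = 0.80, maxEvalue = 1.0) {
    hits[hits$query_cov >= minQueryCov & hits$evalue <= maxEvalue, ,
         drop = FALSE]
}

#' Assign each query read to a taxon by best hit
#'
#' Each query takes the species of its highest-bitscore surviving hit
#' (ties broken by lowest e-value, then lexicographically smallest
#' subject id, so assignment is deterministic and order-invariant).
#' Queries in `allQueries` with no surviving hit are assigned `No-hit`;
#' queries whose best subject is absent from the taxon map are assigned
#' the out-of-band category `Unmapped-subject`.
#'
#' @param hits Filtered hits ([filterHits()]).
#' @param taxonMap Data frame from [readTaxonMap()].
#' @param allQueries Optional character vector of every queried read name;
#'   defaults to the queries present in `hits` (in which case no `No-hit`
#'   rows can be produced).
#' @return A `data.frame` with `query_id`, `subject_id`, `species`,
#'   `genus`, `category`.
#' @export
assignQueries <- function(hits, taxonMap, allQueries = NULL) {
    if (nrow(hits)) {
        ord <- order(hits$query_id, -hits$bitscore, hits$evalue,
                     hits$subject_id)
        h <- hits[ord, , drop = FALSE]
        best <- h[!duplicated(h$query_id), , drop = FALSE]
        m <- match(best$subject_id, taxonMap$subject_id)
        asg <- data.frame(
            query_id = best$query_id, subject_id = best$subject_id,
            species = taxonMap$species[m], genus = taxonMap$genus[m],
            category = taxonMap$category[m], stringsAsFactors = FALSE)
        unk <- is.na(m)
        asg$species[unk] <- NA_character_
        asg$genus[unk] <- NA_character_
        asg$category[unk] <- "Unmapped-subject"
    } else {
        asg <- data.frame(query_id = character(0), subject_id = character(0),
                          species = character(0), genus = character(0),
                          category = character(0), stringsAsFactors = FALSE)
    }
    if (!is.null(allQueries)) {
        miss <- setdiff(allQueries, asg$query_id)
        if (length(miss))
            asg <- rbind(asg, data.frame(
                query_id = miss, subject_id = NA_character_,
                species = NA_character_, genus = NA_character_,
                category = "No-hit", stringsAsFactors = FALSE))
    }
    asg[order(asg$query_id), , drop = FALSE]
}

#' Tally per-query taxon assignments
#'
#' Aggregates [assignQueries()] output into species, genus and category
#' counts.  Category fractions are reported over two denominators, since
#' published tables rarely state which one they use: all queries
#' (`frac_all`, No-hit included) and assigned queries only
#' (`frac_assigned`).
#'
#' @param assignments Data frame from [assignQueries()].
#' @return A [TaxonTally].
#' @export
tallyTaxa <- function(assignments) {
    a <- assignments
    n_total <- nrow(a)
    is_nohit <- a$category == "No-hit"
    is_unm <- a$category == "Unmapped-subject"
    asg <- a[!is_nohit & !is_unm, , drop = FALSE]
    n_assigned <- nrow(asg)

    sp <- if (n_assigned) {
        agg <- stats::aggregate(list(count = asg$query_id),
            by = list(species = asg$species, genus = asg$genus,
                      category = asg$category), FUN = length)
        DataFrame(agg[order(-agg$count, agg$species), , drop = FALSE])
    } else DataFrame(species = character(0), genus = character(0),
                     category = character(0), count = integer(0))

    ge <- if (n_assigned) {
        agg <- stats::aggregate(list(count = asg$query_id),
                                by = list(genus = asg$genus), FUN = length)
        DataFrame(agg[order(-agg$count, agg$genus), , drop = FALSE])
    } else DataFrame(genus = character(0), count = integer(0))

    cat_counts <- stats::setNames(integer(length(TAXON_CATEGORIES)),
                                  TAXON_CATEGORIES)
    if (n_assigned) {
        tb <- table(asg$category)
        cat_counts[names(tb)] <- as.integer(tb)
    }
    cat_counts["No-hit"] <- sum(is_nohit)
    denom_all <- sum(is_nohit) + n_assigned  # unmapped-subject kept apart
    ka <- DataFrame(
        category = TAXON_CATEGORIES,
        count = as.integer(cat_counts),
        frac_all = if (denom_all) cat_counts / denom_all
                   else rep(NA_real_, length(cat_counts)),
        frac_assigned = ifelse(TAXON_CATEGORIES == "No-hit", NA_real_,
            if (n_assigned) cat_counts / n_assigned else NA_real_))
    new("TaxonTally", species = sp, genus = ge, category = ka,
        nQueries = n_total, nNoHit = sum(is_nohit),
        nUnmappedSubject = sum(is_unm))
}

#' Select decoy genera by minimum read frequency
#'
#' Genera whose assigned-read count reaches `minFreq` of the total
#' unaligned-read count are selected for the decoy, sorted by descending
#' count.  The default threshold, one read in 100,000 (0.001%), is applied
#' to a tally built from BLAST results of reads that failed to align to
#' the human reference: unaligned reads sample the full microbial
#' diversity of the specimen, whereas atypical pairs alone are too few.
#'
#' @param tally A [TaxonTally] built from unaligned-read BLAST results.
#' @param nTotalReads Total number of unaligned reads queried (the
#'   frequency denominator).
#' @param minFreq Minimum frequency (default `1e-5`, i.e. 0.001%).
#' @return A `data.frame` with `genus`, `count`, `freq`, sorted by
#'   descending count.
#' @export
selectDecoyGenera <- function(tally, nTotalReads, minFreq = 1e-5) {
    stopifnot(is(tally, "TaxonTally"))
    if (nTotalReads <= 0) stop("nTotalReads must be positive")
    g <- as.data.frame(tally@genus)
    g$freq <- g$count / nTotalReads
    g <- g[g$freq >= minFreq, , drop = FALSE]
    g[order(-g$count, g$genus), , drop = FALSE]
}

#' Select additional decoy species from atypical-read hits
#'
#' Species accounting for at least `minFraction` of the positive
#' (assigned) BLAST results from the atypical-read query set are added to
#' the decoy, unless their genus is already covered by the genus
#' selection.  Default 2%.
#'
#' @param tally A [TaxonTally] built from atypical-read BLAST results.
#' @param minFraction Minimum fraction of assigned results (default 0.02).
#' @param selectedGenera Character vector of genera already selected
#'   (their species are not added again).
#' @return A `data.frame` with `species`, `genus`, `count`, `fraction`,
#'   sorted by descending count.
#' @export
selectAdditionalSpecies <- function(tally, minFraction = 0.02,
                                    selectedGenera = character(0)) {
    stopifnot(is(tally, "TaxonTally"))
    sp <- as.data.frame(tally@species)
    if (!nrow(sp))
        return(data.frame(species = character(0), genus = character(0),
                          count = integer(0), fraction = numeric(0)))
    n_assigned <- sum(sp$count)
    sp$fraction <- sp$count / n_assigned
    sp <- sp[sp$fraction >= minFraction &
             !(sp$genus %in% selectedGenera), , drop = FALSE]
    sp <- sp[order(-sp$count, sp$species),
             c("species", "genus", "count", "fraction"), drop = FALSE]
    rownames(sp) <- NULL
    sp
}

#' Write a taxon tally to TSV
#'
#' Three sections are written to separate files sharing `prefix`:
#' `<prefix>.category.tsv`, `<prefix>.genus.tsv`, `<prefix>.species.tsv`.
#'
#' @param tally A [TaxonTally].
#' @param prefix Output path prefix.
#' @return Character vector of the written paths, invisibly.
#' @export
writeTaxonTally <- function(tally, prefix) {
    paths <- paste0(prefix, c(".category.tsv", ".genus.tsv", ".species.tsv"))
    utils::write.table(as.data.frame(tally@category), paths[1],
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(tally@genus), paths[2],
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(as.data.frame(tally@species), paths[3],
                       sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(paths)
}
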