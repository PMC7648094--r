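## Independent brute-force oracles used for equivalence testing.  These are
## deliberately naive (per-element loops, all-pairs scans) and share no code
## with the package implementations.

## Random pair-geometry table in the shape readPairAlignments() returns.
randomPairTable <- function(n, refLen = 100000L, nref = 2L) {
    if (n == 0L) {
        tab <- randomPairTable(1L, refLen, nref)
        return(tab[0L, , drop = FALSE])
    }
    start1 <- sample.int(refLen - 400L, n)
    ## mixture of short-span and normal-insert geometries
    short <- runif(n) < 0.3
    w1 <- sample(19:30, n, replace = TRUE)
    end1 <- start1 + ifelse(short, w1 - 1L, 150L)
    start2 <- ifelse(short, start1,
                     start1 + sample(100:400, n, replace = TRUE))
    end2 <- start2 + ifelse(short, w1 - 1L, 150L)
    S4Vectors::DataFrame(
        read_name = sprintf("r%05d", seq_len(n)),
        ref_name = sample(paste0("chr", seq_len(nref)), n, replace = TRUE),
        mate1_start = as.integer(start1), mate1_end = as.integer(end1),
        mate2_start = as.integer(start2), mate2_end = as.integer(end2),
        cigar1 = paste0(end1 - start1 + 1L, "M"),
        cigar2 = paste0(end2 - start2 + 1L, "M"),
        mapq1 = sample(0:60, n, replace = TRUE),
        mapq2 = sample(0:60, n, replace = TRUE),
        tlen = as.integer(pmax(end1, end2) - pmin(start1, start2) + 1L))
}

## Per-pair loop oracle for atypical detection.
oracleDetect <- function(tab, minSpan = 1L, maxSpan = 30L, minMapq = 0L) {
    hits <- character(0)
    for (i in seq_len(nrow(tab))) {
        span <- max(tab$mate1_end[i], tab$mate2_end[i]) -
            min(tab$mate1_start[i], tab$mate2_start[i]) + 1L
        if (span >= minSpan && span <= maxSpan &&
            max(tab$mapq1[i], tab$mapq2[i]) >= minMapq)
            hits <- c(hits, tab$read_name[i])
    }
    hits
}

## One-line predicate oracle for BLAST-hit filtering.
oracleFilterHits <- function(hits, minCov = 0.80, maxE = 1.0) {
    keep <- logical(nrow(hits))
    for (i in seq_len(nrow(hits)))
        keep[i] <- hits$query_cov[i] >= minCov && hits$evalue[i] <= maxE
    hits[keep, , drop = FALSE]
}

## O(n^2) single-linkage interval merging oracle (same-chromosome cores).
oracleClusters <- function(starts, ends, gap) {
    n <- length(starts)
    comp <- seq_len(n)
    repeat {
        changed <- FALSE
        for (i in seq_len(n)) for (j in seq_len(n)) {
            if (comp[i] != comp[j] &&
                starts[j] <= ends[i] + gap + 1L &&
                starts[i] <= ends[j] + gap + 1L) {
                comp[comp == comp[j]] <- comp[i]
                changed <- TRUE
            }
        }
        if (!changed) break
    }
    out <- do.call(rbind, lapply(unique(comp), function(k) {
        data.frame(start = min(starts[comp == k]),
                   end = max(ends[comp == k]),
                   n = sum(comp == k))
    }))
    out[order(out$start), , drop = FALSE]
}

## All-pairs positional-distance oracle for variant/cluster proximity.
oracleNear <- function(pos, clStart, clEnd, window) {
    hit <- logical(length(pos))
    for (i in seq_along(pos)) {
        for (j in seq_along(clStart)) {
            d <- if (pos[i] >= clStart[j] && pos[i] <= clEnd[j]) 0L
                 else min(abs(pos[i] - clStart[j]), abs(pos[i] - clEnd[j]))
            if (d <= window) { hit[i] <- TRUE; break }
        }
    }
    hit
}

## Brute-force tandem-repeat position coverage: position p is covered when
## some run with unit length <= maxUnit and total length >= minLen spans it.
## Scans every (unit, start) pair by direct character comparison.
oracleRepeatCoverage <- function(s, minUnit = 1L, maxUnit = 6L,
                                 minLen = 20L) {
    ch <- strsplit(s, "")[[1]]
    n <- length(ch)
    covered <- logical(n)
    for (u in minUnit:maxUnit) {
        i <- 1L
        while (i + u <= n) {
            if (ch[i] == ch[i + u]) {
                j <- i
                while (j + u <= n && ch[j] == ch[j + u]) j <- j + 1L
                runlen <- (j - i) + u
                if (runlen >= minLen && !all(ch[i:(j + u - 1L)] == "N"))
                    covered[i:(j + u - 1L)] <- TRUE
                i <- j + 1L
            } else i <- i + 1L
        }
    }
    covered
}

## Coverage vector from an IRanges.
coverageFromRanges <- function(ir, n) {
    covered <- logical(n)
    for (k in seq_along(ir))
        covered[IRanges::start(ir)[k]:IRanges::end(ir)[k]] <- TRUE
    covered
}

randomDNA <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
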