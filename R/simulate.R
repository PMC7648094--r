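#' Simulation configuration
#'
#' Bundles the study conditions emulated by the synthetic-data generator:
#' 151 bp paired-end reads, atypical pairs with 19--25 bp identity cores
#' and symmetric soft-clipped flanks, a MAPQ mixture matching the observed
#' partition of atypical alignments (45.41% at MAPQ <= 10, 42.40% at
#' MAPQ >= 40), and a contaminant taxon table dominated by oral bacteria
#' with a 32.86% no-hit fraction for atypical-read BLAST queries.
#'
#' @param seed Integer RNG seed; every generator output is reproducible
#'   from it.
#' @param refLen Reference length in bp (default 100000).
#' @param refName Reference contig name.
#' @param nTypicalPairs,nAtypicalPairs Planted pair counts (defaults 5000
#'   and 50).
#' @param coreLenRange Atypical identity-core length range in bp
#'   (default `c(19, 25)`).
#' @param readLen Read length in bp (default 151).
#' @param insertMean,insertSd Typical-pair insert size distribution in bp
#'   (defaults 400 and 50; truncated so that inserts always exceed the
#'   read length, hence always exceed the 30 bp atypical window).
#' @param mapqMixture Weights over MAPQ bins `<=10`, `11-39`, `>=40`
#'   (default `c(0.4541, 0.1219, 0.4240)`).
#' @param noHitFrac Fraction of atypical queries with no significant
#'   BLAST similarity (default 0.3286).
#' @param contaminantTaxa Data frame `species`, `genus`, `category`,
#'   `weight` (weights over assigned queries, summing to 1).
#' @return A list of class `SimConfig`.
#' @export
simConfig <- function(seed = 1L, refLen = 100000L, refName = "chrS",
                      nTypicalPairs = 5000L, nAtypicalPairs = 50L,
                      coreLenRange = c(19L, 25L), readLen = 151L,
                      insertMean = 400, insertSd = 50,
                      mapqMixture = c(le10 = 0.4541, mid = 0.1219,
                                      ge40 = 0.4240),
                      noHitFrac = 0.3286,
                      contaminantTaxa = defaultContaminantTaxa()) {
    stopifnot(all(mapqMixture >= 0), abs(sum(mapqMixture) - 1) < 1e-8,
              coreLenRange[1] >= 1L, coreLenRange[2] < readLen,
              coreLenRange[2] <= 30L,  # planted pairs must be atypical
              abs(sum(contaminantTaxa$weight) - 1) < 1e-8)
    structure(list(seed = as.integer(seed), refLen = as.integer(refLen),
                   refName = refName,
                   nTypicalPairs = as.integer(nTypicalPairs),
                   nAtypicalPairs = as.integer(nAtypicalPairs),
                   coreLenRange = as.integer(coreLenRange),
                   readLen = as.integer(readLen),
                   insertMean = insertMean, insertSd = insertSd,
                   mapqMixture = mapqMixture, noHitFrac = noHitFrac,
                   contaminantTaxa = contaminantTaxa),
              class = "SimConfig")
}

## Oral-microbiome-dominated contaminant table: ~95% bacterial weight among
## assigned queries, with small plant / human / viral components.
defaultContaminantTaxa <- function() {
    data.frame(
        species = c("Streptococcus mitis", "Streptococcus salivarius",
                    "Rothia mucilaginosa", "Neisseria subflava",
                    "Haemophilus parainfluenzae", "Veillonella parvula",
                    "Prevotella melaninogenica", "Aegilops tauschii",
                    "Homo sapiens", "Human gammaherpesvirus 4"),
        genus = c("Streptococcus", "Streptococcus", "Rothia", "Neisseria",
                  "Haemophilus", "Veillonella", "Prevotella", "Aegilops",
                  "Homo", "Lymphocryptovirus"),
        category = c(rep("Bacteria", 7), "Plant", "Human", "Viral"),
        weight = c(0.30, 0.15, 0.15, 0.12, 0.10, 0.08, 0.05, 0.02, 0.01,
                   0.02),
        stringsAsFactors = FALSE)
}

#' Generate a uniform-random reference sequence
#'
#' @param refLen Length in bp (>= 1000).
#' @param seed Integer seed; the same seed reproduces the same sequence.
#' @param name Contig name.
#' @return A named [Biostrings::DNAStringSet] of one sequence.
#' @export
makeReference <- function(refLen, seed, name = "chrS") {
    stopifnot(refLen >= 1000L)
    set.seed(seed)
    s <- paste(sample(c("A", "C", "G", "T"), refLen, replace = TRUE),
               collapse = "")
    DNAStringSet(stats::setNames(s, name))
}

randomBases <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

samRecord <- function(qname, flag, rname, pos, mapq, cigar, pnext, tlen,
                      seq) {
    paste(qname, flag, rname, pos, mapq, cigar, "=", pnext, tlen, seq,
          strrep("I", nchar(seq)), sep = "\t")
}

#' Plant one typical read pair
#'
#' Both mates are exact reference substrings with fully-matched CIGARs,
#' proper-pair flags and `TLEN` equal to the insert.
#'
#' @param refSeq Reference sequence as a character string.
#' @param refName Reference contig name.
#' @param pos 1-based start of mate 1.
#' @param readLen Read length in bp.
#' @param insert Insert size in bp (> `readLen`).
#' @param name Read name.
#' @return List: `records` (two SAM record lines) and `truth` (one-row
#'   data frame).
#' @export
plantTypicalPair <- function(refSeq, refName, pos, readLen, insert, name) {
    stopifnot(insert > readLen, pos + insert - 1L <= nchar(refSeq))
    pos2 <- pos + insert - readLen
    cig <- paste0(readLen, "M")
    r1 <- samRecord(name, 99L, refName, pos, 60L, cig, pos2, insert,
                    substr(refSeq, pos, pos + readLen - 1L))
    r2 <- samRecord(name, 147L, refName, pos2, 60L, cig, pos, -insert,
                    substr(refSeq, pos2, pos2 + readLen - 1L))
    list(records = c(r1, r2),
         truth = data.frame(read_name = name, is_atypical = FALSE,
                            core_start = pos, core_len = NA_integer_,
                            span = insert, source_taxon = "Homo sapiens",
                            mapq1 = 60L, mapq2 = 60L,
                            stringsAsFactors = FALSE))
}

#' Plant one atypical read pair
#'
#' Both mates carry the reference k-mer `refSeq[pos, pos+coreLen)` at a
#' random internal offset, flanked by random non-reference sequence
#' (rejection-sampled so the core occurs nowhere else in either read).
#' CIGARs have the form `xS cM yS` with `c = coreLen`; both mates start at
#' `pos` and `|TLEN| = coreLen`.
#'
#' @param refSeq Reference sequence as a character string.
#' @param refName Reference contig name.
#' @param pos 1-based core start on the reference.
#' @param coreLen Core length in bp (<= `readLen`).
#' @param readLen Read length in bp.
#' @param mapq1,mapq2 Mapping qualities to record.
#' @param name Read name.
#' @return List: `records` (two SAM lines) and `truth` (one-row data
#'   frame).
#' @export
plantAtypicalPair <- function(refSeq, refName, pos, coreLen, readLen,
                              mapq1 = 20L, mapq2 = 20L, name) {
    stopifnot(coreLen <= readLen, pos + coreLen - 1L <= nchar(refSeq))
    core <- substr(refSeq, pos, pos + coreLen - 1L)
    mkread <- function() {
        left <- sample.int(readLen - coreLen + 1L, 1L) - 1L
        right <- readLen - coreLen - left
        repeat {
            read <- paste0(randomBases(left), core, randomBases(right))
            ## the core must occur exactly once
            if (length(gregexpr(core, read, fixed = TRUE)[[1]]) == 1L)
                break
        }
        list(read = read, left = left, right = right)
    }
    m1 <- mkread(); m2 <- mkread()
    cig <- function(m) {
        paste0(if (m$left) paste0(m$left, "S") else "", coreLen, "M",
               if (m$right) paste0(m$right, "S") else "")
    }
    r1 <- samRecord(name, 97L, refName, pos, mapq1, cig(m1), pos, coreLen,
                    m1$read)
    r2 <- samRecord(name, 145L, refName, pos, mapq2, cig(m2), pos,
                    -coreLen, m2$read)
    list(records = c(r1, r2),
         truth = data.frame(read_name = name, is_atypical = TRUE,
                            core_start = pos, core_len = coreLen,
                            span = coreLen, source_taxon = NA_character_,
                            mapq1 = mapq1, mapq2 = mapq2,
                            stringsAsFactors = FALSE))
}

sampleMapq <- function(n, weights) {
    bin <- sample.int(3L, n, replace = TRUE, prob = weights)
    lo <- c(0L, 11L, 40L)[bin]
    hi <- c(10L, 39L, 60L)[bin]
    lo + floor(stats::runif(n) * (hi - lo + 1L))
}

#' Simulate an alignment file with planted typical and atypical pairs
#'
#' Generates a random reference, plants `nTypicalPairs` proper pairs
#' (insert ~ Normal truncated above the read length) and
#' `nAtypicalPairs` atypical pairs (core lengths uniform over
#' `coreLenRange`, per-mate MAPQ drawn from `mapqMixture`), shuffles the
#' records, and writes SAM text plus a complete truth table.  Atypical
#' pairs are assigned a source taxon (or no-hit) for downstream BLAST
#' simulation.  Byte-identical output under a fixed seed.
#'
#' @param config A [simConfig()].
#' @param dir Output directory (created if needed).
#' @return List with `sam` (path), `ref` (path), `truth` (data frame,
#'   also written to `truth_pairs.tsv`), `refSeq` (character).
#' @export
simulateAlignments <- function(config, dir = tempfile("sim")) {
    stopifnot(inherits(config, "SimConfig"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    set.seed(config$seed)
    refset <- makeReference(config$refLen, config$seed, config$refName)
    ## makeReference reseeds; continue the stream distinctly
    set.seed(config$seed + 1L)
    refSeq <- as.character(refset[[1]])

    nAll <- config$nTypicalPairs + config$nAtypicalPairs
    recs <- vector("list", nAll)
    truth <- vector("list", nAll)
    minInsert <- config$readLen + 10L
    i <- 0L
    for (t in seq_len(config$nTypicalPairs)) {
        insert <- max(minInsert,
                      round(stats::rnorm(1, config$insertMean,
                                         config$insertSd)))
        pos <- sample.int(config$refLen - insert, 1L)
        p <- plantTypicalPair(refSeq, config$refName, pos, config$readLen,
                              insert, sprintf("typ%05d", t))
        i <- i + 1L; recs[[i]] <- p$records; truth[[i]] <- p$truth
    }
    mq <- matrix(sampleMapq(2L * config$nAtypicalPairs,
                            config$mapqMixture), ncol = 2L)
    taxa <- sampleTaxa(config$nAtypicalPairs, config)
    for (a in seq_len(config$nAtypicalPairs)) {
        coreLen <- sample(seq.int(config$coreLenRange[1],
                                  config$coreLenRange[2]), 1L)
        pos <- sample.int(config$refLen - coreLen, 1L)
        p <- plantAtypicalPair(refSeq, config$refName, pos, coreLen,
                               config$readLen, mq[a, 1L], mq[a, 2L],
                               sprintf("atyp%05d", a))
        p$truth$source_taxon <- taxa[a]
        i <- i + 1L; recs[[i]] <- p$records; truth[[i]] <- p$truth
    }
    truth <- do.call(rbind, truth)
    recs <- unlist(recs, use.names = FALSE)
    ## shuffle records: detection must be order-invariant
    recs <- recs[sample.int(length(recs))]

    samPath <- file.path(dir, "alignments.sam")
    writeSam(recs, config$refName, config$refLen, samPath)
    refPath <- file.path(dir, "reference.fa")
    writeXStringSet(refset, refPath, width = 60L)
    utils::write.table(truth, file.path(dir, "truth_pairs.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    list(sam = samPath, ref = refPath, truth = truth, refSeq = refSeq)
}

sampleTaxa <- function(n, config) {
    tax <- config$contaminantTaxa
    nohit <- stats::runif(n) < config$noHitFrac
    out <- rep("No-hit", n)
    k <- sum(!nohit)
    if (k)
        out[!nohit] <- sample(tax$species, k, replace = TRUE,
                              prob = tax$weight)
    out
}

#' Write SAM text records with a minimal header
#'
#' @param records Character vector of SAM record lines.
#' @param refName,refLen Contig name and length for the `@SQ` line.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeSam <- function(records, refName, refLen, path) {
    writeLines(c("@HD\tVN:1.6\tSO:unsorted",
                 sprintf("@SQ\tSN:%s\tLN:%d", refName, as.integer(refLen)),
                 "@PG\tID:sim\tPN:SalivaDecoy-simulate",
                 records), path)
    invisible(path)
}

#' Simulate a BLAST tabular file and taxonomy table for atypical queries
#'
#' One query per atypical pair.  Queries whose truth taxon is `No-hit`
#' receive either no row or only a sub-threshold row (coverage below 80%
#' or e-value above 1, so it cannot survive filtering); assigned queries
#' receive one passing best hit from their truth species, optionally a
#' weaker secondary hit from another species, and optionally an extra
#' sub-threshold row.  A 13th `qlen` column carries the read length.
#'
#' @param truth Truth table from [simulateAlignments()] (atypical rows
#'   used).
#' @param config The [simConfig()] used.
#' @param dir Output directory.
#' @param seed Integer seed (default `config$seed + 2`).
#' @return List: `blast` (path), `taxmap` (path), `truth` (per-query data
#'   frame with `query_id`, `true_species`, `true_category`).
#' @export
makeBlastTable <- function(truth, config, dir = tempfile("blast"),
                           seed = config$seed + 2L) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    set.seed(seed)
    tax <- config$contaminantTaxa
    tax$subject_id <- paste0("ACC_",
                             gsub("[^A-Za-z0-9]", "_", tax$species))
    at <- truth[truth$is_atypical, , drop = FALSE]
    rows <- character(0)
    qtruth <- data.frame(query_id = at$read_name,
                         true_species = at$source_taxon,
                         true_category = ifelse(at$source_taxon == "No-hit",
                             "No-hit",
                             tax$category[match(at$source_taxon,
                                                tax$species)]),
                         stringsAsFactors = FALSE)
    mkrow <- function(q, subj, cov, evalue, bitscore) {
        alen <- as.integer(round(cov * config$readLen))
        sprintf("%s\t%s\t%.2f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%.3g\t%.1f\t%d",
                q, subj, stats::runif(1, 85, 100), alen,
                sample.int(5L, 1L) - 1L, 0L, 1L, alen, 1L, alen,
                evalue, bitscore, config$readLen)
    }
    for (j in seq_len(nrow(at))) {
        q <- at$read_name[j]; sp <- at$source_taxon[j]
        if (sp == "No-hit") {
            ## half of no-hit queries get a sub-threshold decoy row
            if (stats::runif(1) < 0.5) {
                if (stats::runif(1) < 0.5)
                    rows <- c(rows, mkrow(q, sample(tax$subject_id, 1L),
                                          stats::runif(1, 0.3, 0.79),
                                          10^stats::runif(1, -3, 0), 40))
                else
                    rows <- c(rows, mkrow(q, sample(tax$subject_id, 1L),
                                          stats::runif(1, 0.8, 1.0),
                                          10^stats::runif(1, 0.05, 2), 25))
            }
            next
        }
        subj <- tax$subject_id[match(sp, tax$species)]
        best_bs <- stats::runif(1, 150, 280)
        rows <- c(rows, mkrow(q, subj, stats::runif(1, 0.8, 1.0),
                              10^stats::runif(1, -40, -5), best_bs))
        if (stats::runif(1) < 0.3)
            rows <- c(rows, mkrow(q, sample(tax$subject_id, 1L),
                                  stats::runif(1, 0.8, 1.0),
                                  10^stats::runif(1, -10, 0),
                                  best_bs - stats::runif(1, 5, 50)))
        if (stats::runif(1) < 0.2)
            rows <- c(rows, mkrow(q, sample(tax$subject_id, 1L),
                                  stats::runif(1, 0.3, 0.79),
                                  10^stats::runif(1, -5, 0), 30))
    }
    blastPath <- file.path(dir, "hits.tsv")
    writeLines(rows, blastPath)
    taxPath <- file.path(dir, "taxmap.tsv")
    utils::write.table(
        tax[, c("subject_id", "species", "genus", "category")], taxPath,
        sep = "\t", quote = FALSE, row.names = FALSE)
    list(blast = blastPath, taxmap = taxPath, truth = qtruth)
}

#' Simulate a pre/post-decoy VCF pair with a genotype-change truth table
#'
#' Plants loci of each comparison class: `restored_hom_alt` (0/1 before
#' the decoy, 1/1 after), `unchanged`, `lost` (pre only; contaminant-driven
#' calls that vanish with the decoy, QUAL drawn from a configurable
#' distribution) and `new` (post only).
#'
#' @param refSeq Reference sequence (character) supplying REF bases.
#' @param chrom Contig name.
#' @param nRestored,nUnchanged,nLost,nNew Locus counts per class.
#' @param lostQualMeanlog,lostQualSdlog Log-normal QUAL parameters for
#'   lost variants (defaults `log(40)` and 0.5: low-quality calls, as
#'   decoy-removed variants are).
#' @param seed Integer seed.
#' @param dir Output directory.
#' @return List: `pre`, `post` (VCF paths), `truth` (data frame `chrom`,
#'   `pos`, `ref`, `alt`, `class`, `qual_pre`, `qual_post`).
#' @export
makeVcfPair <- function(refSeq, chrom = "chrS", nRestored = 5L,
                        nUnchanged = 20L, nLost = 5L, nNew = 2L,
                        lostQualMeanlog = log(40), lostQualSdlog = 0.5,
                        seed = 1L, dir = tempfile("vcf")) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    set.seed(seed)
    n <- nRestored + nUnchanged + nLost + nNew
    refLen <- nchar(refSeq)
    pos <- sort(sample.int(refLen, n))
    ref <- vapply(seq_len(n), function(i) substr(refSeq, pos[i], pos[i]),
                  character(1))
    alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"),
                                                  b), 1L), character(1))
    cls <- sample(rep(c("restored_hom_alt", "unchanged", "lost", "new"),
                      c(nRestored, nUnchanged, nLost, nNew)))
    gt_unchanged <- sample(c("0/1", "1/1"), n, replace = TRUE)
    qual_gen <- round(stats::runif(n, 200, 2000), 2)
    qual_lost <- round(stats::rlnorm(n, lostQualMeanlog, lostQualSdlog), 2)

    gt_pre <- character(n); gt_post <- character(n)
    qual_pre <- numeric(n); qual_post <- numeric(n)
    for (i in seq_len(n)) {
        switch(cls[i],
            restored_hom_alt = {
                gt_pre[i] <- "0/1"; gt_post[i] <- "1/1"
                qual_pre[i] <- qual_gen[i]
                qual_post[i] <- round(qual_gen[i] * 1.1, 2)
            },
            unchanged = {
                gt_pre[i] <- gt_post[i] <- gt_unchanged[i]
                qual_pre[i] <- qual_post[i] <- qual_gen[i]
            },
            lost = {
                gt_pre[i] <- "0/1"; gt_post[i] <- NA_character_
                qual_pre[i] <- qual_lost[i]; qual_post[i] <- NA_real_
            },
            new = {
                gt_pre[i] <- NA_character_; gt_post[i] <- "0/1"
                qual_pre[i] <- NA_real_; qual_post[i] <- qual_gen[i]
            })
    }
    truth <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                        class = cls, gt_pre = gt_pre, gt_post = gt_post,
                        qual_pre = qual_pre, qual_post = qual_post,
                        stringsAsFactors = FALSE)
    prePath <- file.path(dir, "pre.vcf")
    postPath <- file.path(dir, "post.vcf")
    writeSimpleVcf(truth, "pre", chrom, refLen, prePath)
    writeSimpleVcf(truth, "post", chrom, refLen, postPath)
    list(pre = prePath, post = postPath, truth = truth)
}

#' Write a minimal single-sample VCF
#'
#' Internal writer for the simulator's pre/post VCFs (VCFv4.2, GT-only
#' FORMAT, PASS filter).
#' @noRd
writeSimpleVcf <- function(truth, side, chrom, refLen, path) {
    gt <- truth[[paste0("gt_", side)]]
    qual <- truth[[paste0("qual_", side)]]
    keep <- !is.na(gt)
    hdr <- c("##fileformat=VCFv4.2",
             sprintf("##contig=<ID=%s,length=%d>", chrom,
                     as.integer(refLen)),
             paste0("##FORMAT=<ID=GT,Number=1,Type=String,",
                    "Description=\"Genotype\">"),
             paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", "SAMPLE1", sep = "\t"))
    body <- sprintf("%s\t%d\t.\t%s\t%s\t%.2f\tPASS\t.\tGT\t%s",
                    truth$chrom[keep], truth$pos[keep], truth$ref[keep],
                    truth$alt[keep], qual[keep], gt[keep])
    writeLines(c(hdr, body), path)
    invisible(path)
}
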