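mkHits <- function(query_id, query_cov, evalue,
                   subject_id = paste0("S", seq_along(query_id)),
                   bitscore = 100) {
    data.frame(query_id = query_id, subject_id = subject_id,
               pct_identity = 95, align_len = as.integer(round(query_cov * 151)),
               evalue = evalue, bitscore = bitscore, query_len = 151L,
               query_cov = query_cov, stringsAsFactors = FALSE)
}

mkMap <- function(...) {
    rows <- list(...)
    do.call(rbind, lapply(rows, function(r)
        data.frame(subject_id = r[1], species = r[2], genus = r[3],
                   category = r[4], stringsAsFactors = FALSE)))
}

test_that("BLAST tabular parsing computes coverage and skips bad rows", {
    path <- tempfile()
    writeLines(c(
        "q1\tsub1\t98.0\t121\t2\t0\t1\t121\t5\t125\t1e-30\t220\t151",
        "q2\tsub2\t90.0\t100\t5\t1\t1\t100\t1\t100\t0.5\t80\t151",
        "broken\trow"), path)
    expect_warning(hits <- readBlastTab(path), "malformed")
    expect_identical(nrow(hits), 2L)
    expect_equal(hits$query_cov, c(121 / 151, 100 / 151))
    expect_identical(attr(hits, "n_skipped"), 1L)

    empty <- tempfile(); file.create(empty)
    expect_identical(nrow(readBlastTab(empty)), 0L)
})

test_that("12-column input requires a query-length source", {
    path <- tempfile()
    writeLines("q1\tsub1\t98.0\t121\t2\t0\t1\t121\t5\t125\t1e-30\t220",
               path)
    expect_error(readBlastTab(path), "coverage cannot be computed")
    hits <- readBlastTab(path, queryLengths = c(q1 = 151L))
    expect_equal(hits$query_cov, 121 / 151)
    expect_error(readBlastTab(path, queryLengths = c(other = 10L)),
                 "missing")
})

test_that("hit filter boundaries follow the 80% / e-value-1 rule", {
    h <- mkHits(c("a", "b", "c", "d"), c(0.79, 0.80, 0.90, 0.90),
                c(0.5, 0.5, 1.0, 1.01))
    kept <- filterHits(h)
    expect_setequal(kept$query_id, c("b", "c"))
})

test_that("hit filter matches the predicate oracle and is monotone", {
    set.seed(14)
    for (trial in 1:10) {
        h <- mkHits(sprintf("q%03d", 1:300), runif(300, 0.3, 1.0),
                    10^runif(300, -10, 1))
        expect_identical(filterHits(h)$query_id,
                         oracleFilterHits(h)$query_id)
        loose <- nrow(filterHits(h, minQueryCov = 0.7, maxEvalue = 2))
        tight <- nrow(filterHits(h, minQueryCov = 0.9, maxEvalue = 0.1))
        expect_lte(nrow(filterHits(h)), loose)
        expect_gte(nrow(filterHits(h)), tight)
    }
})

test_that("best-hit assignment follows bitscore, then e-value, then subject", {
    tm <- mkMap(c("sA", "SpecA", "GenA", "Bacteria"),
                c("sB", "SpecB", "GenB", "Bacteria"),
                c("sC", "SpecC", "GenC", "Fungi"))
    h <- data.frame(query_id = c("q1", "q1", "q2", "q2", "q3", "q3"),
                    subject_id = c("sA", "sB", "sB", "sC", "sC", "sA"),
                    pct_identity = 95, align_len = 140L,
                    evalue = c(1e-5, 1e-5, 1e-9, 1e-5, 1e-5, 1e-5),
                    bitscore = c(50, 60, 70, 70, 70, 70),
                    query_len = 151L, query_cov = 0.93,
                    stringsAsFactors = FALSE)
    asg <- assignQueries(h, tm)
    expect_identical(asg$species[asg$query_id == "q1"], "SpecB")  # bitscore
    expect_identical(asg$species[asg$query_id == "q2"], "SpecB")  # e-value
    expect_identical(asg$species[asg$query_id == "q3"], "SpecA")  # lexicographic
    ## order invariance
    asg2 <- assignQueries(h[sample(nrow(h)), ], tm)
    expect_identical(asg, asg2)
})

test_that("queries with no surviving hit become No-hit", {
    tm <- mkMap(c("sA", "SpecA", "GenA", "Bacteria"))
    h <- mkHits("q1", 0.9, 1e-5, subject_id = "sA")
    asg <- assignQueries(h, tm, allQueries = c("q1", "q2"))
    expect_identical(asg$category, c("Bacteria", "No-hit"))
    ## unknown subject reported separately
    h2 <- mkHits("q3", 0.9, 1e-5, subject_id = "mystery")
    asg2 <- assignQueries(h2, tm)
    expect_identical(asg2$category, "Unmapped-subject")
})

test_that("tally fractions use both denominators", {
    tm <- mkMap(c("sB", "Bacterium x", "Bact", "Bacteria"),
                c("sH", "Homo sapiens", "Homo", "Human"))
    asg <- data.frame(
        query_id = sprintf("q%02d", 1:10),
        subject_id = c(rep("sB", 6), rep(NA, 3), "sH"),
        species = c(rep("Bacterium x", 6), rep(NA, 3), "Homo sapiens"),
        genus = c(rep("Bact", 6), rep(NA, 3), "Homo"),
        category = c(rep("Bacteria", 6), rep("No-hit", 3), "Human"),
        stringsAsFactors = FALSE)
    tal <- tallyTaxa(asg)
    k <- as.data.frame(categoryCounts(tal))
    expect_equal(k$frac_all[k$category == "Bacteria"], 0.6)
    expect_equal(k$frac_assigned[k$category == "Bacteria"], 6 / 7,
                 tolerance = 1e-12)
    ## conservation
    expect_identical(sum(k$count), tal@nQueries)
    expect_equal(sum(k$frac_all), 1)
})

test_that("degenerate tally: one species is 100% of assigned", {
    tm <- mkMap(c("s1", "Only species", "Only", "Bacteria"))
    asg <- assignQueries(mkHits(c("a", "b"), 0.9, 0.1,
                                subject_id = c("s1", "s1")), tm)
    tal <- tallyTaxa(asg)
    sp <- as.data.frame(speciesCounts(tal))
    expect_identical(nrow(sp), 1L)
    expect_identical(sp$count, 2L)
    k <- as.data.frame(categoryCounts(tal))
    expect_equal(k$frac_assigned[k$category == "Bacteria"], 1)
})

test_that("tally matches generator truth on simulated BLAST output", {
    cfg <- simConfig(seed = 31, nTypicalPairs = 0, nAtypicalPairs = 300,
                     refLen = 150000)
    sim <- simulateAlignments(cfg)
    bl <- makeBlastTable(sim$truth, cfg)
    hits <- readBlastTab(bl$blast)
    tm <- readTaxonMap(bl$taxmap)
    asg <- assignQueries(filterHits(hits), tm,
                         allQueries = bl$truth$query_id)
    m <- merge(asg, bl$truth, by = "query_id")
    expect_identical(nrow(m), 300L)
    expect_identical(m$category, m$true_category)
    expect_identical(tallyTaxa(asg)@nNoHit,
                     sum(bl$truth$true_species == "No-hit"))
})

test_that("genus selection boundary at one read in 100000", {
    tal <- tallyTaxa(data.frame(
        query_id = sprintf("q%02d", 1:19),
        subject_id = "s",
        species = c(rep("Sp low", 9), rep("Sp high", 10)),
        genus = c(rep("GenLow", 9), rep("GenHigh", 10)),
        category = "Bacteria", stringsAsFactors = FALSE))
    sel <- selectDecoyGenera(tal, nTotalReads = 1e6)
    expect_identical(sel$genus, "GenHigh")   # 10/1e6 = 0.001% in, 9 out
    all_g <- selectDecoyGenera(tal, nTotalReads = 1e6, minFreq = 0)
    expect_setequal(all_g$genus, c("GenHigh", "GenLow"))
    expect_error(selectDecoyGenera(tal, nTotalReads = 0), "positive")
})

test_that("species addition boundary at 2% with genus dedup", {
    n <- 1000L
    counts <- c(`Species big` = 900L, `Species edge` = 20L,
                `Species under` = 19L, `Species covered` = 61L)
    asg <- data.frame(
        query_id = sprintf("q%04d", seq_len(n)),
        subject_id = "s",
        species = rep(names(counts), counts),
        genus = rep(c("GenBig", "GenEdge", "GenUnder", "GenCovered"),
                    counts),
        category = "Bacteria", stringsAsFactors = FALSE)
    tal <- tallyTaxa(asg)
    sel <- selectAdditionalSpecies(tal, selectedGenera = c("GenCovered"))
    expect_setequal(sel$species, c("Species big", "Species edge"))
    sel2 <- selectAdditionalSpecies(tal)
    expect_true("Species covered" %in% sel2$species)
    expect_identical(nrow(selectAdditionalSpecies(
        tallyTaxa(asg[0, , drop = FALSE]))), 0L)
})

test_that("typical reads profile as overwhelmingly human", {
    ## the same tally pipeline applied to a typical-read query set
    tm <- mkMap(c("sH", "Homo sapiens", "Homo", "Human"),
                c("sP", "Pan troglodytes", "Pan", "Mammalian other"))
    n <- 200L
    set.seed(8)
    subj <- sample(c("sH", "sP", NA), n, replace = TRUE,
                   prob = c(0.94, 0.03, 0.03))
    asg <- data.frame(query_id = sprintf("t%03d", seq_len(n)),
                      subject_id = subj,
                      species = tm$species[match(subj, tm$subject_id)],
                      genus = tm$genus[match(subj, tm$subject_id)],
                      category = ifelse(is.na(subj), "No-hit",
                          tm$category[match(subj, tm$subject_id)]),
                      stringsAsFactors = FALSE)
    k <- as.data.frame(categoryCounts(tallyTaxa(asg)))
    expect_gt(k$frac_all[k$category == "Human"], 0.85)
})
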