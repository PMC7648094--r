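mkClusters <- function(starts, ends, chrom = "chrS") {
    GenomicRanges::GRanges(chrom, IRanges::IRanges(starts, ends))
}

mkVariants <- function(pos, chrom = "chrS") {
    data.frame(chrom = chrom, pos = pos, ref = "A", alt = "C",
               gt = "0/1", qual = 100, stringsAsFactors = FALSE)
}

test_that("variant proximity boundary: 100 bp in, 101 bp out", {
    cl <- mkClusters(1000, 1030)
    expect_identical(variantsNearAtypical(mkVariants(1130), cl)$pos, 1130)
    expect_identical(nrow(variantsNearAtypical(mkVariants(1131), cl)), 0L)
    ## upstream side and inside
    expect_identical(variantsNearAtypical(mkVariants(900), cl)$pos, 900)
    expect_identical(nrow(variantsNearAtypical(mkVariants(899), cl)), 0L)
    expect_identical(variantsNearAtypical(mkVariants(1015), cl)$pos, 1015)
})

test_that("contig mismatch between VCF and clusters is a hard error", {
    cl <- mkClusters(1000, 1030, chrom = "chr1")
    expect_error(variantsNearAtypical(mkVariants(1005, chrom = "1"), cl),
                 "contig names")
})

test_that("proximity matches the all-pairs distance oracle", {
    set.seed(19)
    for (trial in 1:10) {
        npos <- 300L
        v <- mkVariants(sample.int(50000, npos))
        cs <- sort(sample.int(49000, 15))
        cl <- mkClusters(cs, cs + sample(10:60, 15, TRUE))
        got <- variantsNearAtypical(v, cl, window = 100)$pos
        want <- v$pos[oracleNear(v$pos, GenomicRanges::start(cl),
                                 GenomicRanges::end(cl), 100)]
        expect_setequal(got, want)
    }
})

test_that("identical VCFs compare as all unchanged", {
    ref <- as.character(makeReference(5000, 2, "chrS")[[1]])
    vp <- makeVcfPair(ref, nRestored = 0, nUnchanged = 10, nLost = 0,
                      nNew = 0, seed = 4)
    cmp <- compareVcfs(vp$pre, vp$pre)
    cnt <- changeSummary(cmp)$counts
    expect_identical(cnt[["unchanged"]], 10L)
    expect_identical(sum(cnt) - cnt[["unchanged"]], 0L)
})

test_that("heterozygous-to-hom-alt transitions classify as restored", {
    pre <- data.frame(chrom = "chrS", pos = 100, ref = "A", alt = "G",
                      gt = "0/1", qual = 50, stringsAsFactors = FALSE)
    post <- pre; post$gt <- "1/1"
    cmp <- compareVcfs(pre, post)
    expect_identical(as.character(changes(cmp)$change_class),
                     "restored_hom_alt")
    ## reverse direction is "other", not restored
    cmp2 <- compareVcfs(post, pre)
    expect_identical(as.character(changes(cmp2)$change_class), "other")
})

test_that("classification is a partition conserving totals", {
    ref <- as.character(makeReference(8000, 3, "chrS")[[1]])
    vp <- makeVcfPair(ref, nRestored = 4, nUnchanged = 12, nLost = 6,
                      nNew = 3, seed = 12)
    cmp <- compareVcfs(vp$pre, vp$post)
    s <- changeSummary(cmp)
    expect_identical(sum(s$counts), s$n_loci)
    expect_identical(s$counts[["lost"]] + s$counts[["unchanged"]] +
                     s$counts[["restored_hom_alt"]] + s$counts[["other"]],
                     s$n_pre)
    expect_identical(s$n_loci - s$counts[["lost"]], s$n_post)
})

test_that("multi-allelic records decompose to per-alt comparisons", {
    vcf <- tempfile(fileext = ".vcf")
    writeLines(c("##fileformat=VCFv4.2",
                 "##contig=<ID=chrS,length=1000>",
                 "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"G\">",
                 "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
                 "chrS\t50\t.\tA\tC,G\t99\tPASS\t.\tGT\t1/2"), vcf)
    post <- tempfile(fileext = ".vcf")
    writeLines(c("##fileformat=VCFv4.2",
                 "##contig=<ID=chrS,length=1000>",
                 "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"G\">",
                 "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\tS1",
                 "chrS\t50\t.\tA\tC\t99\tPASS\t.\tGT\t0/1"), post)
    cmp <- compareVcfs(vcf, post)
    ch <- as.data.frame(changes(cmp))
    expect_identical(nrow(ch), 2L)              # A>C and A>G rows
    expect_setequal(ch$alt, c("C", "G"))
    expect_identical(ch$change_class[ch$alt == "G"], "lost")
    ## 1/2 relative to alt C is "this alt + another alt" = 1/2
    expect_identical(ch$gt_pre[ch$alt == "C"], "1/2")
})

test_that("reduction metrics follow the percent rule and edge cases", {
    r <- reductionMetrics(AlignmentStats(1e6, 2000, 1000, 0),
                          AlignmentStats(1e6, 2000, 500, 400))
    expect_equal(r$atypical_reduction_pct, 50)
    expect_equal(r$unaligned_reduction_pct, 0)

    expect_message(
        r0 <- reductionMetrics(AlignmentStats(10, 0, 0, 0),
                               AlignmentStats(10, 0, 0, 0)),
        "undefined")
    expect_true(is.na(r0$atypical_reduction_pct))

    expect_warning(
        rn <- reductionMetrics(AlignmentStats(10, 5, 10, 0),
                               AlignmentStats(10, 5, 20, 0)),
        "increased")
    expect_equal(rn$atypical_reduction_pct, -100)

    x <- AlignmentStats(100, 10, 7, 0)
    expect_equal(reductionMetrics(x, x)$atypical_reduction_pct, 0)
})

test_that("allelic support partitions typical-alt vs atypical-ref reads", {
    set.seed(27)
    ref <- randomDNA(4000)
    locus <- 2000L
    refBase <- substr(ref, locus, locus)
    altBase <- setdiff(c("A", "C", "G", "T"), refBase)[1]
    ## individual carries hom-alt: typical reads all show the alt base
    altRef <- paste0(substr(ref, 1, locus - 1), altBase,
                     substr(ref, locus + 1, nchar(ref)))
    ## insert 400: only mate 1 overlaps the locus, so 10 pairs give 10
    ## overlapping typical reads
    recs <- character(0)
    for (i in 1:10)
        recs <- c(recs, plantTypicalPair(altRef, "chrT",
            locus - 65 - i, 151, 400, sprintf("typ%02d", i))$records)
    atyp_names <- sprintf("atyp%02d", 1:4)
    for (i in 1:4)
        recs <- c(recs, plantAtypicalPair(ref, "chrT", locus - 10, 22, 151,
                                          name = atyp_names[i])$records)
    sam <- tempfile(fileext = ".sam")
    writeSam(recs, "chrT", 4000, sam)
    sup <- allelicSupportPartition(sam, "chrT", locus, refBase, altBase,
                                   atyp_names)
    expect_identical(sup$ref_support_typical, 0L)
    expect_identical(sup$alt_support_typical, 10L)
    expect_identical(sup$ref_support_atypical, 8L)   # both mates overlap
    expect_identical(sup$alt_support_atypical, 0L)
    ## no atypical reads at the locus -> zero atypical counts
    sup2 <- allelicSupportPartition(sam, "chrT", locus, refBase, altBase,
                                    character(0))
    expect_identical(sup2$ref_support_atypical, 0L)
    expect_identical(sup2$alt_support_atypical, 0L)
})

test_that("attributable-variant fraction is lost-near-clusters over pre", {
    pre <- mkVariants(c(1000, 5000, 9000, 20000))
    post <- pre[c(1, 4), , drop = FALSE]       # 5000 and 9000 lost
    cl <- mkClusters(c(4950, 30000), c(4980, 30030))
    fa <- fractionVariantsAttributable(pre, post, cl)
    ## one lost variant (5000) within 100 bp of a cluster, of 4 pre
    expect_identical(fa$n_lost_near, 1L)
    expect_equal(fa$percent, 25)

    fa0 <- fractionVariantsAttributable(pre, pre, cl)
    expect_equal(fa0$percent, 0)

    expect_message(
        fae <- fractionVariantsAttributable(pre[0, ], post, cl),
        "undefined")
    expect_true(is.na(fae$percent))
})

test_that("coding-region subset uses the BED intervals", {
    pre <- mkVariants(c(1000, 5000, 9000, 20000))
    post <- pre[c(1, 4), , drop = FALSE]
    cl <- mkClusters(c(4950, 8990), c(4980, 9020))
    cod <- GenomicRanges::GRanges("chrS", IRanges::IRanges(4500, 5500))
    fa <- fractionVariantsAttributable(pre, post, cl, codingBed = cod)
    expect_identical(fa$n_lost_near, 2L)
    expect_identical(fa$n_pre_coding, 1L)      # only pos 5000 is coding
    expect_identical(fa$n_lost_near_coding, 1L)
    expect_equal(fa$percent_coding, 100)
})

test_that("lost-variant QUAL summary uses the lower median", {
    pre <- do.call(rbind, lapply(1:4, function(i) {
        v <- mkVariants(i * 1000); v$qual <- c(10, 30, 20, 40)[i]; v
    }))
    cmp <- compareVcfs(pre, pre[0, , drop = FALSE])
    ## even count: lower median of {10,20,30,40} is 20
    expect_identical(changeSummary(cmp)$median_lost_qual, 20)
})
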