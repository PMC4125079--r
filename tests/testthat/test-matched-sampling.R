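test_that("bin assignment follows the 25 x 2 x 10 table", {
    b <- binAssign(0.039, FALSE, 0.95)
    expect_equal(unlist(b[c("maf_bin", "imputed_bin", "b_bin")]),
                 c(maf_bin = 1L, imputed_bin = 0L, b_bin = 9L))
    ## boundary values cap into the top bins
    top <- binAssign(0.5, TRUE, 1.0)
    expect_equal(unlist(top[c("maf_bin", "imputed_bin", "b_bin")]),
                 c(maf_bin = 24L, imputed_bin = 1L, b_bin = 9L))
    zero <- binAssign(0, FALSE, 0)
    expect_equal(unlist(zero[c("maf_bin", "imputed_bin", "b_bin")]),
                 c(maf_bin = 0L, imputed_bin = 0L, b_bin = 0L))
    expect_error(binAssign(0.6, FALSE, 0.5), "MAF")
    expect_error(binAssign(0.2, FALSE, 1.5), "B value")
})

test_that("the pool index partitions every SNP exactly once", {
    pool3 <- data.frame(snp_id = c("a", "b", "c"),
                        maf = c(0.01, 0.21, 0.41),
                        imputed = FALSE, b_value = 0.5)
    idx3 <- buildPoolIndex(pool3)
    expect_equal(unname(lengths(idx3@index)), c(1L, 1L, 1L))
    empty <- buildPoolIndex(pool3[0, ])
    expect_equal(length(empty@index), 0L)
    ds <- tiny_dataset()
    idx <- buildPoolIndex(ds$pool)
    expect_equal(sum(lengths(idx@index)), nrow(ds$pool))
})

test_that("null sets match bins, are reproducible, and respect uniqueness", {
    ds <- tiny_dataset()
    idx <- buildPoolIndex(ds$pool)
    s1 <- sampleNullSets(ds$effects, idx, 50L, seed = 20)
    s2 <- sampleNullSets(ds$effects, idx, 50L, seed = 20)
    expect_identical(s1@idx, s2@idx)
    s3 <- sampleNullSets(ds$effects, idx, 50L, seed = 21)
    expect_false(identical(s1@idx, s3@idx))
    expect_equal(s1@alpha, unname(ds$effects$alpha))

    ## matching fidelity: each set reproduces the GWAS bin multiset
    ## (restricted to loci whose exact cell was occupied)
    gwas_keys <- binAssign(ds$effects$maf, ds$effects$imputed,
                           ds$effects$b_value)$key
    pool_keys <- idx@keys
    if (s1@nFallback == 0L) {
        for (j in c(1L, 25L, 50L))
            expect_equal(sort(pool_keys[s1@idx[, j]]), sort(gwas_keys))
    }

    ## two GWAS loci in one cell draw distinct pool SNPs in every set
    gwas2 <- data.frame(snp_id = c("g1", "g2"), effect_allele = "A",
                        alpha = 0.1, maf = 0.11, imputed = FALSE,
                        b_value = 0.55)
    pool_big <- data.frame(snp_id = sprintf("n%d", 1:40), maf = 0.11,
                           imputed = FALSE, b_value = 0.55)
    sets2 <- sampleNullSets(EffectTable(gwas2), buildPoolIndex(pool_big),
                            200L, seed = 22)
    expect_true(all(sets2@idx[1, ] != sets2@idx[2, ]))

    ## single-SNP cell: every set contains that SNP
    pool1 <- pool_big[1, ]
    sets1 <- sampleNullSets(EffectTable(gwas2[1, ]),
                            buildPoolIndex(pool1), 20L, seed = 23)
    expect_true(all(sets1@idx == 1L))
})

test_that("empty cells widen to neighbouring MAF bins or fail loudly", {
    gwas <- EffectTable(data.frame(
        snp_id = "g1", effect_allele = "A", alpha = 0.2, maf = 0.25,
        imputed = FALSE, b_value = 0.35))
    ## neighbour bin (maf 0.27 -> bin 13 vs gwas bin 12) at same B bin
    pool <- data.frame(snp_id = "n1", maf = 0.27, imputed = FALSE,
                       b_value = 0.35)
    sets <- sampleNullSets(gwas, buildPoolIndex(pool), 5L, seed = 1)
    expect_equal(sets@nFallback, 1L)
    expect_true(all(sets@idx == 1L))
    ## nothing within +/- 2 MAF bins -> error naming the locus
    far <- data.frame(snp_id = "n1", maf = 0.45, imputed = FALSE,
                      b_value = 0.35)
    expect_error(sampleNullSets(gwas, buildPoolIndex(far), 5L, seed = 1),
                 "g1")
})

test_that("null genetic values reproduce the defining sum", {
    ds <- tiny_dataset()
    idx <- buildPoolIndex(ds$pool)
    sets <- sampleNullSets(ds$effects, idx, 10L, seed = 24)
    Zn <- nullGeneticValues(sets, ds$pool_panel)
    expect_equal(dim(Zn), c(6L, 10L))
    P <- freqMatrix(ds$pool_panel)
    oracle <- 2 * colSums(sets@alpha * P[sets@idx[, 4], ])
    expect_equal(Zn[, 4], oracle)
    ## zero effects give zero vectors
    sets0 <- sets
    sets0@alpha <- rep(0, length(sets@alpha))
    expect_equal(unname(nullGeneticValues(sets0, ds$pool_panel)),
                 matrix(0, 6, 10))
})

test_that("null Q_X over matched neutral sets has the chi-square mean", {
    ds <- tiny_dataset()
    model <- tiny_model()
    idx <- buildPoolIndex(ds$pool)
    sets <- sampleNullSets(ds$effects, idx, 1000L, seed = 25)
    qn <- qx(nullGeneticValues(sets, ds$pool_panel), model)
    M1 <- length(populationIds(ds$pool_panel)) - 1L
    expect_lt(abs(mean(qn) - M1), 4 * sd(qn) / sqrt(length(qn)) + 0.3)
})

test_that("admixed ascertainment frequencies are folded weighted means", {
    panel <- make_panel(matrix(c(0.2, 0.6, 0.9, 0.1), 2, 2, byrow = TRUE),
                        pops = c("FR", "YRI"))
    expect_equal(unname(admixedAscertainmentFreq(panel, "FR", "YRI", 1)),
                 pmin(c(0.2, 0.9), 1 - c(0.2, 0.9)))
    expect_equal(unname(admixedAscertainmentFreq(panel, "FR", "YRI", 0.5))[1],
                 0.4)
    ## w = 0.5 is symmetric under swapping the references
    expect_equal(admixedAscertainmentFreq(panel, "FR", "YRI", 0.5),
                 admixedAscertainmentFreq(panel, "YRI", "FR", 0.5))
    expect_error(admixedAscertainmentFreq(panel, "FR", "XX", 0.5),
                 "missing")
})
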