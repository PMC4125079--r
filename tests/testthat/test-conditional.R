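test_that("re-centering matches the explicit projection construction", {
    ds <- tiny_dataset()
    pops <- populationIds(ds$pool_panel)
    part <- GroupPartition(pops[1:2], pops[3:6])
    F2 <- recenterF(ds$pool_panel, part)
    ## oracle: apply the explicit M x M projection to the standardized
    ## deviations and take the sample covariance
    sd_ <- polyadapt:::.standardized_deviations(ds$pool_panel)
    M2 <- 4L
    Tc <- diag(6)
    Tc[, 3:6] <- Tc[, 3:6] - 1 / M2
    F_oracle <- cov(sd_$D %*% t(Tc))
    expect_equal(unname(F2), unname(F_oracle), tolerance = 1e-12)
    ## the group-2 block is rank deficient by exactly one
    ev <- eigen(F2[3:6, 3:6], symmetric = TRUE, only.values = TRUE)$values
    expect_lt(abs(ev[4]), 1e-10)
    expect_gt(ev[3], 1e-6)
    ## divergence from a subgroup mean exceeds divergence from the
    ## global mean
    F_global <- estimateF(ds$pool_panel, drop = 6L)
    expect_gt(F2[1, 1], F_global[1, 1])
})

test_that("conditional operators agree with the precision-matrix oracle", {
    set.seed(30)
    for (i in seq_len(100)) {
        M <- 7L
        A <- matrix(rnorm(M * M), M)
        Sigma <- crossprod(A) + diag(M) * 0.5
        pops <- sprintf("P%d", seq_len(M))
        dimnames(Sigma) <- list(pops, pops)
        part <- GroupPartition(pops[1:2], pops[3:M])
        v2 <- rnorm(M - 2L)
        got <- conditionalDistribution(v2, Sigma, part, va = 1)
        ## independent route through the precision matrix:
        ## sigma_11|2 = Lambda_11^{-1},
        ## mu_1|2 = m1 - Lambda_11^{-1} Lambda_12 (v2 - m2)
        Lam <- solve(Sigma)
        S11inv <- solve(Lam[1:2, 1:2])
        m <- mean(v2)
        mu_oracle <- m - unname(drop(S11inv %*% Lam[1:2, 3:M] %*% (v2 - m)))
        sig_oracle <- S11inv
        expect_equal(unname(got$mu_cond), mu_oracle, tolerance = 1e-8)
        expect_equal(unname(got$sigma_cond), unname(sig_oracle),
                     tolerance = 1e-8)
    }
})

test_that("independence and duplication limits behave as expected", {
    pops <- sprintf("P%d", 1:5)
    ## block-diagonal covariance: conditioning is uninformative
    Sigma <- diag(5) * 0.3
    dimnames(Sigma) <- list(pops, pops)
    part <- GroupPartition(pops[1], pops[2:5])
    v2 <- c(1, 2, 3, 4)
    got <- conditionalDistribution(v2, Sigma, part, va = 2)
    expect_equal(unname(got$mu_cond), mean(v2))
    expect_equal(unname(got$sigma_cond), matrix(0.6))

    ## a population duplicated into both groups: the conditional pins the
    ## tested population to its duplicate, with near-zero variance
    ds <- tiny_dataset()
    f <- freqMatrix(ds$pool_panel)
    dup <- cbind(f, dup1 = f[, 1])
    colnames(dup) <- c(populationIds(ds$pool_panel), "dup1")
    panel <- FrequencyPanel(dup, 50L)
    part2 <- GroupPartition("dup1", populationIds(ds$pool_panel))
    F2 <- recenterF(panel, part2)
    z <- c(geneticValues(ds$effects, ds$gwas_panel), dup1 = 0)
    cd <- conditionalDistribution(z[1:6], F2, part2, va = 1)
    expect_lt(cd$sigma_cond[1, 1] / F2["dup1", "dup1"], 0.05)
    expect_equal(unname(cd$mu_cond), unname(z[1]), tolerance = 1e-5)
})

test_that("group Z-scores standardize the conditional discrepancy", {
    mu <- c(a = 0.3, b = 0.5)
    sig <- matrix(c(0.04, 0.01, 0.01, 0.09), 2)
    r0 <- groupZscore(c(0.3, 0.5), mu, sig)
    expect_equal(r0@z, 0)
    expect_equal(r0@pTwoSided, 1)
    ## scalar case
    r1 <- groupZscore(1.2, c(x = 1.0), matrix(0.04))
    expect_equal(r1@z, (1.2 - 1.0) / 0.2)
    expect_equal(r1@pTwoSided, 2 * pnorm(-1))
    expect_error(groupZscore(1, c(x = 1), matrix(-0.1)), "positive")
})

test_that("vectorized Z-scores agree with the per-vector path", {
    ds <- tiny_dataset()
    model <- tiny_model()
    pops <- populationIds(ds$pool_panel)
    part <- GroupPartition(pops[2], pops[-2])
    idx <- buildPoolIndex(ds$pool)
    Zn <- nullGeneticValues(sampleNullSets(ds$effects, idx, 5L, seed = 31),
                            ds$pool_panel)
    F2 <- recenterF(ds$pool_panel, part)
    zv <- conditionalZScores(Zn, ds$pool_panel, part, model@vaScale,
                             F2 = F2)
    for (j in 1:5) {
        rj <- conditionalTest(Zn[, j], ds$pool_panel, part, model@vaScale,
                              F2 = F2)
        expect_equal(zv[j], rj@z, tolerance = 1e-12)
    }
    loo <- leaveOneOutZ(Zn[, 1], ds$pool_panel, model@vaScale)
    expect_equal(nrow(loo), 6L)
    expect_equal(loo["pop02", "z"],
                 conditionalTest(Zn[, 1], ds$pool_panel, part,
                                 model@vaScale)@z)
})

test_that("shifts are easier to see in populations with close relatives", {
    ## two-clade tree: pop 1 has in-clade relatives, pop 6 is isolated by
    ## a long branch; the same frequency shift must yield a larger |z|
    ## where unaffected close relatives anchor the expectation
    spec <- fixtureSpec(M = 6L, Lgwas = 40L, Kpool = 4000L,
                        driftF = list(own = 0.06, shared = 0.05,
                                      sizes = c(5L, 1L)),
                        seed = 33L)
    ds <- makeDataset(spec)
    model <- fitMatchedModel(ds, n_cov_sets = 80L, seed = 34L)
    pops <- populationIds(ds$pool_panel)
    alpha <- unname(ds$effects$alpha)
    f0 <- freqMatrix(ds$gwas_panel)
    z_close <- z_far <- numeric(60)
    F2c <- recenterF(ds$pool_panel, GroupPartition(pops[1], pops[-1]))
    F2f <- recenterF(ds$pool_panel, GroupPartition(pops[6], pops[-6]))
    Fch <- chol(ds$F_true)
    set.seed(35)
    for (r in seq_len(60)) {
        s <- polyadapt:::.simulate_freqs(spec, spec@Lgwas, F_chol = Fch)
        shift_c <- targetedShift(s$freq, alpha, 2, pops[1])
        shift_f <- targetedShift(s$freq, alpha, 2, pops[6])
        zc <- 2 * drop(crossprod(shift_c, alpha))
        zf <- 2 * drop(crossprod(shift_f, alpha))
        z_close[r] <- conditionalZScores(
            matrix(zc), ds$pool_panel,
            GroupPartition(pops[1], pops[-1]), model@vaScale, F2 = F2c)
        z_far[r] <- conditionalZScores(
            matrix(zf), ds$pool_panel,
            GroupPartition(pops[6], pops[-6]), model@vaScale, F2 = F2f)
    }
    expect_gt(mean(abs(z_close)), mean(abs(z_far)))
})
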