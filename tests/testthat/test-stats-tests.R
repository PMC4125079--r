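test_that("Q_X equals the explicit quadratic form", {
    set.seed(10)
    A <- matrix(rnorm(25), 5)
    model <- make_model(crossprod(A) + diag(5) * 0.1, va = 1.7)
    v <- rnorm(6)
    ## dense-inverse oracle: (Tz)' (va F)^{-1} (Tz)
    tz <- drop(model@Tproj %*% v)
    oracle <- drop(t(tz) %*% solve(1.7 * model@Fmat) %*% tz)
    expect_equal(qx(v, model), oracle, tolerance = 1e-8)
    expect_equal(qx(rep(2, 6), model), 0)
    ## matrix input gives one statistic per column
    V <- matrix(rnorm(18), 6)
    expect_equal(qx(V, model), apply(V, 2, qx, model = model))
})

test_that("the decomposition is exact and trivial for one locus", {
    ds <- tiny_dataset()
    model <- tiny_model()
    one <- EffectTable(as.data.frame(ds$effects)[3, , drop = FALSE])
    dec1 <- qxDecomposition(one, ds$gwas_panel, model)
    expect_equal(dec1$ld_like, 0)
    z1 <- geneticValues(one, ds$gwas_panel)
    expect_equal(dec1$fst_like, qx(z1, model), tolerance = 1e-10)

    ## additivity against the independent genetic-value route
    dec <- qxDecomposition(ds$effects, ds$gwas_panel, model)
    z <- geneticValues(ds$effects, ds$gwas_panel)
    expect_equal(dec$fst_like + dec$ld_like, qx(z, model),
                 tolerance = 1e-8)
})

test_that("LD-like component centers on zero over neutral sets", {
    ds <- tiny_dataset()
    model <- tiny_model()
    index <- buildPoolIndex(ds$pool)
    sets <- sampleNullSets(ds$effects, index, 400L, seed = 12)
    P <- freqMatrix(ds$pool_panel)
    ld <- vapply(seq_len(400L), function(j) {
        f <- P[sets@idx[, j], , drop = FALSE]
        panel <- FrequencyPanel(f, chromCounts(ds$pool_panel))
        rownames(panel) <- snpIds(ds$effects)
        qxDecomposition(ds$effects, panel, model)$ld_like
    }, numeric(1))
    expect_lt(abs(mean(ld)), 3 * sd(ld) / sqrt(length(ld)))
})

test_that("environmental regression has its closed forms", {
    set.seed(11)
    y <- rnorm(8)
    r <- envRegression(2 * y, y)
    expect_equal(r$beta, 2)
    expect_equal(r$r2, 1)
    expect_equal(r$rho, 1)
    ## orthogonal vectors give slope zero
    x_orth <- c(1, -1, rep(0, 6)); y_orth <- c(1, 1, rep(0, 6))
    expect_equal(envRegression(x_orth, y_orth)$beta, 0)
    ## closed-form slope
    x <- rnorm(8)
    expect_equal(envRegression(x, y)$beta, sum(x * y) / sum(y^2))
    expect_error(envRegression(x, rep(1, 8)), "zero variance")
})

test_that("per-locus slopes combine into the genetic-value slope", {
    ds <- tiny_dataset()
    model <- tiny_model()
    y <- whitenEnvironment(ds$env, model)
    pl <- perLocusRegression(ds$effects, ds$gwas_panel, model, y)
    a2 <- 2 * ds$effects$alpha
    ## stacked-regression oracle: regress the stacked transformed
    ## frequencies {x_lm} on the stacked predictor {2a_l y_m}
    Xp <- transformedFrequencies(ds$gwas_panel, model)
    num <- sum(vapply(seq_along(a2),
                      function(l) a2[l] * sum(Xp[, l] * y), numeric(1)))
    oracle <- num / (sum(a2^2) * sum(y^2))
    expect_equal(pl$beta_bar, oracle, tolerance = 1e-10)
    ## proportionality with the genetic-value slope:
    ## beta_bar = slope * sqrt(2 V_A) / sum((2 alpha)^2)
    z <- geneticValues(ds$effects, ds$gwas_panel)
    slope <- envRegression(whiten(z, model), y)$beta
    expect_equal(pl$beta_bar, slope * sqrt(model@vaScale) / sum(a2^2),
                 tolerance = 1e-8)
    ## single locus: the identity reduces to one term
    one <- EffectTable(as.data.frame(ds$effects)[1, , drop = FALSE])
    pl1 <- perLocusRegression(one, ds$gwas_panel, model, y)
    z1 <- geneticValues(one, ds$gwas_panel)
    s1 <- envRegression(whiten(z1, model), y)$beta
    expect_equal(pl1$beta_bar,
                 s1 * sqrt(model@vaScale) / (2 * one$alpha)^2,
                 tolerance = 1e-8)
    ## constant frequencies transform to zero, so all slopes vanish
    cpanel <- make_panel(matrix(0.4, 25, 6),
                         ids = snpIds(ds$effects),
                         pops = populationIds(ds$gwas_panel))
    plc <- perLocusRegression(ds$effects, cpanel, model, y)
    expect_equal(unname(plc$per_locus), rep(0, 25))
})

test_that("empirical p-values follow the add-one counting rule", {
    expect_equal(empiricalPValue(10, rep(1, 999), "upper"), 1 / 1000)
    nulls <- c(-(1:10), 1:9)  # observed 0 sits at the median
    expect_equal(empiricalPValue(0, nulls, "two-sided"), 1)
    ## 19 nulls, observed ranks 5th largest
    expect_equal(empiricalPValue(15.5, c(1:15, 16:19), "upper"), 5 / 20)
    expect_error(empiricalPValue(1, numeric(0)), "at least one")
})

test_that("test wrappers assemble consistent reports", {
    ds <- tiny_dataset()
    model <- tiny_model()
    index <- buildPoolIndex(ds$pool)
    sets <- sampleNullSets(ds$effects, index, 99L, seed = 13)
    Zn <- nullGeneticValues(sets, ds$pool_panel)
    z <- geneticValues(ds$effects, ds$gwas_panel)
    qr <- qxTest(z, model, Zn, seed = 13L)
    expect_s4_class(qr, "TestReport")
    expect_equal(qr@observed, qx(z, model))
    expect_equal(qr@pEmpirical,
                 empiricalPValue(qr@observed, qr@nullDraws, "upper"))
    er <- envTest(z, ds$env, model, Zn, seed = 13L)
    expect_named(er, c("beta", "r2", "rho"))
    y <- whitenEnvironment(ds$env, model)
    expect_equal(er$beta@observed,
                 envRegression(whiten(z, model), y)$beta)
    expect_equal(er$beta@tail, "two-sided")
    expect_equal(er$r2@tail, "upper")
})
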