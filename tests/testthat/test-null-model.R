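test_that("genetic values are the doubled effect-weighted frequency sums", {
    effects <- make_effects(c(0.5))
    panel <- make_panel(matrix(0.2, 1, 4))
    expect_equal(unname(geneticValues(effects, panel)), rep(0.2, 4))

    effects0 <- make_effects(rep(0, 3))
    panel0 <- make_panel(matrix(runif(12), 3, 4))
    expect_equal(unname(geneticValues(effects0, panel0)), rep(0, 4))

    ## independent summation oracle on random inputs
    set.seed(9)
    a <- runif(3); p <- matrix(runif(15), 3, 5)
    oracle <- sapply(seq_len(5), function(m) 2 * sum(a * p[, m]))
    got <- geneticValues(make_effects(a), make_panel(p))
    expect_equal(unname(got), oracle)
})

test_that("center projection subtracts the mean and drops a coordinate", {
    P2 <- centerProjection(2)
    expect_equal(drop(P2 %*% c(3, 1)), 1)        # (a - b) / 2
    expect_equal(drop(centerProjection(4) %*% rep(7, 4)), rep(0, 3))
    set.seed(1)
    v <- rnorm(5)
    expect_equal(drop(centerProjection(5) %*% v), (v - mean(v))[1:4])
    expect_error(centerProjection(1), "2 populations")
})

test_that("F estimation recovers known structure", {
    ## no variation across populations -> zero covariance
    const <- make_panel(matrix(rep(runif(20), 4), 20, 4), chromosomes = 50L)
    expect_equal(unname(estimateF(const)), matrix(0, 3, 3))

    ## star tree recovery: large chromosome counts isolate the drift term.
    ## Centering at the sample mean projects c*I to c*(I - 11'/M), so the
    ## estimate targets that form, not c*I itself.
    spec <- fixtureSpec(M = 4L, Kpool = 8000L, driftF = 0.05,
                        chromosomes = 4000L, seed = 3L)
    sim <- simulatePanel(spec, 8000L, seed = 3L)
    F_hat <- estimateF(sim$panel)
    F_expect <- 0.05 * (diag(4) - 1 / 4)[1:3, 1:3]
    expect_lt(max(abs(F_hat - F_expect)), 0.005)

    ## duplicated populations covary like a single one
    set.seed(4)
    base <- matrix(runif(4000, 0.1, 0.9), 2000, 2)
    noise <- function() matrix(rbinom(4000, 100, base) / 100, 2000, 2)
    dup <- cbind(noise(), noise()[, 1])
    F_dup <- estimateF(make_panel(dup, chromosomes = 100L,
                                  pops = c("A", "B", "Adup")),
                       drop = 2L)
    expect_lt(abs(F_dup["A", "Adup"] - mean(diag(F_dup)[c(1, 2)])) /
              mean(diag(F_dup)[c(1, 2)]), 0.25)
})

test_that("the additive-variance scale matches its closed form", {
    effects <- make_effects(1)
    panel <- make_panel(matrix(0.5, 1, 4))
    expect_equal(vaScale(effects, panel), 1.0)   # V_A = 0.5, scale = 2 V_A

    set.seed(5)
    a <- runif(6); p <- matrix(runif(6 * 5, 0.1, 0.9), 6, 5)
    eps <- rowMeans(p)
    expect_equal(vaScale(make_effects(a), make_panel(p)),
                 4 * sum(a^2 * eps * (1 - eps)))

    ## all-zero effects make the whitening transform undefined
    ds <- tiny_dataset()
    zero <- make_effects(rep(0, 4))
    zp <- make_panel(matrix(runif(16, 0.2, 0.8), 4, 4))
    expect_error(fitDriftModel(zero, zp, zp), "zero")
})

test_that("whitening has the documented closed forms and round trip", {
    model <- make_model(diag(4), va = 1)
    expect_equal(whiten(rep(3, 5), model), rep(0, 4))
    set.seed(6)
    v <- rnorm(5)
    ## F = I, va = 1: whitening is just centering + dropping
    expect_equal(whiten(v, model), (v - mean(v))[1:4])

    ## random F: C x' sqrt(va) reconstructs the projected values
    A <- matrix(rnorm(16), 4)
    model2 <- make_model(crossprod(A) + diag(4) * 0.1, va = 2.3)
    x <- whiten(v, model2)
    expect_equal(drop(model2@cholC %*% x) * sqrt(2.3),
                 drop(model2@Tproj %*% v), tolerance = 1e-10)
})

test_that("environment whitening shares the transform minus the scale", {
    model <- make_model(diag(4), va = 4)
    env <- EnvVector(c(1, 1, 1, 1, 1), model@populationIds)
    expect_equal(whitenEnvironment(env, model), rep(0, 4))
    set.seed(7)
    v <- rnorm(5)
    env2 <- EnvVector(v, model@populationIds)
    expect_equal(whitenEnvironment(env2, model), (v - mean(v))[1:4])
    ## env equal to the genetic values: transforms proportional by sqrt(va)
    expect_equal(whitenEnvironment(env2, model) / sqrt(4),
                 whiten(v, model))
    expect_error(whitenEnvironment(EnvVector(v, letters[1:5]), model),
                 "not match")
})

test_that("whitening turns model-law genetic values into white noise", {
    ## values drawn from the model's own null, MVN(mu 1, 2 V_A F): build a
    ## length-M vector whose projection equals C x sqrt(va) with x white
    set.seed(8)
    A <- matrix(rnorm(36), 6)
    model <- make_model(crossprod(A) / 6 + diag(6) * 0.05, va = 1.8)
    M <- 7L
    draw_values <- function() {
        x <- rnorm(M - 1L)
        u <- drop(model@cholC %*% x) * sqrt(model@vaScale)
        2.5 + c(u, -sum(u))   # mean-free completion, arbitrary location
    }
    X <- vapply(seq_len(4000), function(r) whiten(draw_values(), model),
                numeric(M - 1L))
    emp <- cov(t(X))
    expect_lt(max(abs(diag(emp) - 1)), 0.12)
    expect_lt(max(abs(emp[upper.tri(emp)])), 0.08)
    expect_lt(max(abs(rowMeans(X))), 0.06)
})

test_that("the dropped population does not affect downstream statistics", {
    ds <- tiny_dataset()
    pops <- populationIds(ds$gwas_panel)
    z <- geneticValues(ds$effects, ds$gwas_panel)
    m1 <- fitDriftModel(ds$effects, ds$gwas_panel, ds$pool_panel,
                        drop = "last")
    m2 <- fitDriftModel(ds$effects, ds$gwas_panel, ds$pool_panel,
                        drop = pops[2])
    expect_equal(qx(z, m1), qx(z, m2), tolerance = 1e-8)
    ## the no-intercept slope is a ratio of invariant quadratic forms
    y1 <- whitenEnvironment(ds$env, m1)
    y2 <- whitenEnvironment(ds$env, m2)
    r1 <- envRegression(whiten(z, m1), y1)
    r2 <- envRegression(whiten(z, m2), y2)
    expect_equal(r1$beta, r2$beta, tolerance = 1e-8)
})
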