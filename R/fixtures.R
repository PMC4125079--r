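## Synthetic fixtures: datasets with the statistical structure the method
## assumes (MVN-drifted frequencies under a known F, binomial sampling,
## MAF / B-value / imputation metadata), so the whole pipeline runs without
## any external download.

#' Build a population covariance from a fixture spec
#'
#' A scalar drift parameter c gives a star-shaped tree, \eqn{F = c I}; a
#' list \code{list(own =, shared =, sizes =)} gives a balanced two-clade
#' tree with per-population drift \code{own} on the diagonal and the shared
#' branch length \code{shared} on within-clade off-diagonals; an explicit
#' matrix is validated positive semi-definite and returned as is.
#'
#' @param spec a \code{\link{FixtureSpec}}.
#' @return M x M covariance matrix.
#' @export
makeF <- function(spec) {
    d <- spec@driftF
    M <- spec@M
    if (is.matrix(d)) {
        if (!all(dim(d) == c(M, M)))
            stop("explicit F must be M x M")
        if (min(eigen(d, symmetric = TRUE, only.values = TRUE)$values) <
            -1e-10 * max(abs(d)))
            stop("explicit F must be positive semi-definite")
        return(d)
    }
    if (is.list(d)) {
        sizes <- d$sizes
        if (sum(sizes) != M) stop("clade sizes must sum to M")
        F_mat <- matrix(0, M, M)
        start <- 0L
        for (sz in sizes) {
            i <- start + seq_len(sz)
            F_mat[i, i] <- d$shared
            start <- start + sz
        }
        diag(F_mat) <- d$own
        return(F_mat)
    }
    diag(as.numeric(d), M)
}

#' Simulate a frequency panel under the drift model
#'
#' Per SNP: draw an ancestral frequency \eqn{\epsilon} from the spec's
#' uniform law; draw population frequencies from
#' \eqn{N(\epsilon 1,\; \epsilon(1-\epsilon) F)} truncated to [0, 1]; then
#' draw sample frequencies binomially with the per-population chromosome
#' counts, so the \eqn{1/n_m}-order diagonal inflation of estimated
#' covariances is present in fixtures exactly as in real data. Metadata
#' (ascertainment MAF = the folded sample frequency in the first
#' population, an independent imputation flag, and a uniform B value) is
#' emitted for both GWAS and pool SNPs so the matching machinery is
#' exercised end to end.
#'
#' @param spec a \code{\link{FixtureSpec}}.
#' @param n_snps number of SNPs to simulate.
#' @param F_mat covariance from \code{\link{makeF}} (computed from the spec
#'   when \code{NULL}).
#' @param id_prefix prefix for generated SNP ids.
#' @param seed integer seed, or \code{NULL} to continue the current RNG
#'   stream.
#' @return list with \code{panel} (a \code{\link{FrequencyPanel}}; its
#'   \code{metadata()$truncation_rate} records the fraction of MVN draws
#'   clipped into [0, 1]) and \code{metadata} (a \code{DataFrame} with
#'   \code{snp_id}, \code{maf}, \code{imputed}, \code{b_value}).
#' @export
simulatePanel <- function(spec, n_snps, F_mat = NULL, id_prefix = "snp",
                          seed = NULL) {
    sim <- .simulate_freqs(spec, n_snps, F_mat, id_prefix, seed)
    panel <- FrequencyPanel(sim$freq, spec@chromosomes)
    metadata(panel)$truncation_rate <- sim$truncation_rate
    meta <- DataFrame(snp_id = rownames(sim$freq), maf = sim$maf,
                      imputed = sim$imputed, b_value = sim$b_value,
                      row.names = rownames(sim$freq))
    list(panel = panel, metadata = meta)
}

## Bare-matrix simulator behind simulatePanel; replicate-heavy callers use
## this directly to avoid per-replicate container construction costs.
.simulate_freqs <- function(spec, n_snps, F_mat = NULL, id_prefix = "snp",
                            seed = NULL, F_chol = NULL) {
    if (!is.null(seed)) set.seed(seed)
    if (is.null(F_chol)) {
        if (is.null(F_mat)) F_mat <- makeF(spec)
        ## a zero matrix (no drift) has no Cholesky factor; frequencies
        ## then sit exactly at the ancestral value before sampling
        F_chol <- if (max(abs(F_mat)) == 0) F_mat else chol(F_mat)
    }
    M <- spec@M
    n <- as.integer(n_snps)
    eps <- stats::runif(n, spec@ancestralRange[1], spec@ancestralRange[2])
    dev <- matrix(stats::rnorm(n * M), n, M) %*% F_chol
    p <- eps + sqrt(eps * (1 - eps)) * dev
    n_trunc <- sum(p < 0 | p > 1)
    p <- pmin(pmax(p, 0), 1)
    size <- rep(spec@chromosomes, each = n)
    f <- matrix(stats::rbinom(n * M, size = size, prob = as.vector(p)) /
                size, n, M)
    dimnames(f) <- list(paste0(id_prefix, seq_len(n)),
                        sprintf("pop%02d", seq_len(M)))
    list(freq = f, maf = pmin(f[, 1], 1 - f[, 1]),
         imputed = stats::runif(n) < spec@pImputed,
         b_value = stats::runif(n), truncation_rate = n_trunc / (n * M))
}

#' Generate a complete synthetic dataset
#'
#' Draws a GWAS effect table (half-normal effect sizes, random allele
#' labels, simulated ascertainment metadata), the GWAS-locus frequency
#' panel, a genome-wide null pool with the same generative law, and a
#' latitude-like environmental vector (absolute latitudes uniform on
#' [0, 60] degrees).
#'
#' @param spec a \code{\link{FixtureSpec}}.
#' @param seed integer seed (defaults to the spec's).
#' @return list with \code{effects} (\code{EffectTable}),
#'   \code{gwas_panel} and \code{pool_panel} (\code{FrequencyPanel}s),
#'   \code{pool} (pool metadata \code{DataFrame}), \code{env}
#'   (\code{EnvVector}) and \code{F_true} (the generating covariance).
#' @export
makeDataset <- function(spec, seed = spec@seed) {
    set.seed(seed)
    F_mat <- makeF(spec)
    pool_sim <- simulatePanel(spec, spec@Kpool, F_mat, id_prefix = "null")
    gwas_sim <- simulatePanel(spec, spec@Lgwas, F_mat, id_prefix = "rs")
    L <- spec@Lgwas
    bases <- c("A", "C", "G", "T")
    ea <- sample(bases, L, replace = TRUE)
    oa <- vapply(ea, function(b) sample(setdiff(bases, b), 1L), character(1))
    effects <- EffectTable(data.frame(
        snp_id = rownames(gwas_sim$panel),
        effect_allele = ea, other_allele = oa,
        alpha = abs(stats::rnorm(L, 0, spec@effectSd)),
        maf = gwas_sim$metadata$maf,
        imputed = gwas_sim$metadata$imputed,
        b_value = gwas_sim$metadata$b_value))
    env <- EnvVector(stats::runif(spec@M, 0, 60),
                     populationIds(gwas_sim$panel))
    list(effects = effects, gwas_panel = gwas_sim$panel,
         pool = pool_sim$metadata, pool_panel = pool_sim$panel,
         env = env, F_true = F_mat)
}

#' Fit a drift model from a dataset using matched covariance SNPs
#'
#' Follows the same matching procedure for the covariance-estimation SNPs
#' as for the null statistic sets: stacks \code{n_cov_sets} matched null
#' sets drawn from the pool and estimates F from them, so F describes the
#' expected covariance structure of SNPs with the GWAS ascertainment
#' profile.
#'
#' @param dataset a list as returned by \code{\link{makeDataset}} (or with
#'   the same elements built from real files).
#' @param n_cov_sets number of matched sets stacked for F estimation
#'   (about \code{n_cov_sets * L} SNPs).
#' @param drop population to drop, or \code{"last"}.
#' @param seed integer seed for the matched draw.
#' @return a fitted \code{\link{DriftModel}}.
#' @export
fitMatchedModel <- function(dataset, n_cov_sets = 125L, drop = "last",
                            seed = 1L) {
    index <- buildPoolIndex(dataset$pool)
    sets <- sampleNullSets(dataset$effects, index, n_cov_sets, seed = seed)
    rows <- as.vector(sets@idx)
    f <- freqMatrix(dataset$pool_panel)[rows, , drop = FALSE]
    rownames(f) <- make.unique(rownames(f))
    cov_panel <- FrequencyPanel(f, chromCounts(dataset$pool_panel))
    fitDriftModel(dataset$effects, dataset$gwas_panel, cov_panel,
                  drop = drop)
}

#' Neutral calibration experiment
#'
#' The package's end-to-end type-I-error machinery: fits the drift model
#' once from the pool via matched covariance SNPs, then for each of
#' \code{n_replicates} fresh neutral GWAS datasets (same generating F, new
#' frequencies and ascertainment metadata, the same effect sizes) computes
#' empirical p-values for Q_X (upper tail), the environmental slope and
#' Spearman correlation (two-sided) and r2 (upper tail) against
#' \code{n_null_sets} matched null sets, plus the single-locus enrichment
#' comparator's binomial p-value. With \code{n_null_sets = 99}, rejecting
#' at \eqn{p \le 0.05} is an exact 5\% level test under exchangeability.
#'
#' @param spec a \code{\link{FixtureSpec}}.
#' @param n_replicates number of neutral replicates.
#' @param n_null_sets matched null sets per replicate.
#' @param n_cov_sets matched sets stacked for F estimation.
#' @param seed integer seed.
#' @return data.frame with one row per replicate: p-values \code{qx_p},
#'   \code{beta_p}, \code{rho_p}, \code{r2_p}, \code{enrich_p}, the
#'   observed \code{qx}, and the decomposition columns \code{fst_like},
#'   \code{ld_like}. The fitted model is attached as
#'   \code{attr(, "model")}.
#' @export
calibrationExperiment <- function(spec, n_replicates = 1000L,
                                  n_null_sets = 99L, n_cov_sets = 125L,
                                  seed = 1L) {
    base <- makeDataset(spec, seed = seed)
    model <- fitMatchedModel(base, n_cov_sets = n_cov_sets, seed = seed + 1L)
    index <- buildPoolIndex(base$pool)
    P <- freqMatrix(base$pool_panel)
    y_t <- whitenEnvironment(base$env, model)
    ## per-locus correlations of every pool SNP with the environment,
    ## computed once; a set's per-locus null is a lookup
    Xp_pool <- .transform_cholesky(t(P), model)
    cor_pool <- drop(suppressWarnings(stats::cor(Xp_pool, y_t)))
    cor_pool[is.na(cor_pool)] <- 0   # fixed SNPs carry no association
    alpha <- unname(base$effects$alpha)
    sy2 <- sum(y_t^2)
    out <- matrix(NA_real_, n_replicates, 8,
                  dimnames = list(NULL, c("qx_p", "beta_p", "rho_p", "r2_p",
                                          "enrich_p", "qx", "fst_like",
                                          "ld_like")))
    F_chol <- chol(base$F_true)
    eff_base <- as.data.frame(base$effects)
    for (r in seq_len(n_replicates)) {
        rep_seed <- seed + 2L * r
        rep_sim <- .simulate_freqs(spec, spec@Lgwas, id_prefix = "rs",
                                   seed = rep_seed, F_chol = F_chol)
        eff_r <- eff_base
        eff_r$maf <- rep_sim$maf
        eff_r$imputed <- rep_sim$imputed
        eff_r$b_value <- rep_sim$b_value
        freq_r <- rep_sim$freq
        z_obs <- 2 * drop(crossprod(freq_r, alpha))
        sets <- sampleNullSets(eff_r, index, n_null_sets,
                               seed = rep_seed + 1L)
        Zn <- nullGeneticValues(sets, base$pool_panel)
        x_obs <- whiten(z_obs, model)
        Xn <- whiten(Zn, model)
        qx_obs <- sum(x_obs^2)
        qx_null <- colSums(Xn^2)
        beta_obs <- sum(x_obs * y_t) / sy2
        beta_null <- drop(crossprod(Xn, y_t)) / sy2
        r_obs <- stats::cor(x_obs, y_t)
        r_null <- drop(stats::cor(Xn, y_t))
        rho_obs <- stats::cor(x_obs, y_t, method = "spearman")
        rho_null <- drop(stats::cor(Xn, y_t, method = "spearman"))
        ## decomposition of the observed replicate
        Xp <- .transform_cholesky(t(freq_r), model)
        W <- Xp * rep(2 * alpha, each = nrow(Xp))
        fst_like <- sum(W^2) / model@vaScale
        ld_like <- (sum(rowSums(W)^2) - sum(W^2)) / model@vaScale
        ## enrichment comparator
        ## per-locus null from the exact matched mixture (all pool SNPs in
        ## each locus's cell), free of set-resampling noise
        mix <- .matched_candidate_rows(eff_r, index)
        cutoffs <- .enrich_cutoffs(cor_pool[mix], 0.05)
        obs_cors <- drop(stats::cor(Xp, y_t))
        enrich_p <- .binom_tail_p(.enrich_count(obs_cors, cutoffs),
                                  length(alpha), 0.05,
                                  method = "randomized")
        out[r, ] <- c(
            empiricalPValue(qx_obs, qx_null, "upper"),
            empiricalPValue(beta_obs, beta_null, "two-sided"),
            empiricalPValue(rho_obs, rho_null, "two-sided"),
            empiricalPValue(r_obs^2, r_null^2, "upper"),
            enrich_p, qx_obs, fst_like, ld_like)
    }
    out <- as.data.frame(out)
    attr(out, "model") <- model
    out
}
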