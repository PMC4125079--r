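## Selection power simulations: perturb neutral frequency sets to mimic
## directional selection along an environmental gradient, with pleiotropy,
## locus downsampling and targeted (population/region) variants; evaluate
## power of the structure-aware statistics against naive and single-locus
## comparators.

#' Perturb frequencies to mimic selection along a gradient
#'
#' Adds a deterministic shift to each frequency,
#' \eqn{p'_{lm} = p_{lm} + s\, \alpha_l\, Y_m\, p_{lm}(1-p_{lm})}, clipped
#' to [0, 1]: shifts grow with the environmental value, the effect size,
#' and heterozygosity (so intermediate-frequency alleles move most), which
#' are the qualitative signatures of directional selection on a polygenic
#' trait. Because the input frequencies are neutral draws, drift and shared
#' history are already present and are not re-simulated. The shift function
#' is deliberately minimal; alternatives can be swapped in via
#' \code{shift_fun}.
#'
#' @param freqs L x M matrix of neutral frequencies.
#' @param alpha_acting length-L effect sizes that selection acts on (the
#'   measured effects, or pleiotropic ones from
#'   \code{\link{pleiotropicEffects}}).
#' @param env an \code{\link{EnvVector}} or numeric length-M vector; mean
#'   centered internally when \code{center_env} is \code{TRUE}.
#' @param s shift strength per unit environment (>= 0).
#' @param center_env mean-center the environment first (default); targeted
#'   shifts pass raw indicators with \code{FALSE}.
#' @param shift_fun function(p, a, y, s) returning the shifted matrix
#'   before clipping; the default implements the form above.
#' @return perturbed L x M matrix with attribute \code{n_clipped}, the
#'   number of entries clipped into [0, 1].
#' @export
applyShift <- function(freqs, alpha_acting, env, s, center_env = TRUE,
                       shift_fun = NULL) {
    y <- if (is(env, "EnvVector")) envValues(env) else as.numeric(env)
    if (length(y) != ncol(freqs))
        stop("environment length must equal the number of populations")
    if (center_env) y <- y - mean(y)
    if (is.null(shift_fun))
        shift_fun <- function(p, a, y, s)
            p + s * outer(a, y) * p * (1 - p)
    shifted <- shift_fun(freqs, alpha_acting, y, s)
    n_clipped <- sum(shifted < 0 | shifted > 1)
    out <- pmin(pmax(shifted, 0), 1)
    attr(out, "n_clipped") <- n_clipped
    out
}

#' Pleiotropic effect sizes
#'
#' Draws the effects \eqn{\gamma_l} that selection acts on from the
#' conditional of a mean-zero bivariate normal with equal marginal variance
#' and correlation \code{rho} given the measured effects \eqn{\alpha_l}:
#' \eqn{\gamma_l = \rho\,\alpha_l + \sqrt{1-\rho^2}\,e_l} with \eqn{e_l
#' \sim N(0, \sigma^2)}. \code{rho} plays the role of the genetic
#' correlation between the measured trait and the trait selection sees;
#' shifts are applied with \eqn{\gamma} while tests keep using
#' \eqn{\alpha}.
#'
#' Because the bivariate normal is centred at zero, the plug-in marginal
#' variance \eqn{\sigma^2} is the mean square of \eqn{\alpha} (its second
#' moment about zero), not the variance about the sample mean: the measured
#' effects are all non-negative only because alleles are labelled by their
#' trait-increasing direction, and the labelling must not shrink the
#' acting effects. This keeps \eqn{E[\gamma_l^2]} invariant in \code{rho},
#' so the per-locus shift magnitudes -- and with them the power of
#' sign-agnostic single-locus tests -- do not change as the correlation
#' falls.
#'
#' @param alpha measured effect sizes.
#' @param rho genetic correlation in [0, 1].
#' @param seed integer seed.
#' @return length-L vector of acting effects.
#' @export
pleiotropicEffects <- function(alpha, rho, seed = 1L) {
    if (rho < 0 || rho > 1) stop("rho must lie in [0, 1]")
    if (rho == 1) return(alpha)
    set.seed(seed)
    rho * alpha + sqrt(1 - rho^2) *
        stats::rnorm(length(alpha), 0, sqrt(mean(alpha^2)))
}

#' Downsample GWAS loci
#'
#' Uniform subsample of \code{n} loci without regard to effect size,
#' mimicking a GWAS that ascertained fewer loci. With
#' \code{rescale_va = TRUE} all effect sizes are multiplied by the scalar
#' that restores the subsample's additive variance to \code{va_target}
#' (normally the full-set value), mimicking the same variance explained
#' partitioned over fewer loci.
#'
#' @param effects the full \code{\link{EffectTable}}.
#' @param n subsample size, 2 <= n <= L.
#' @param rescale_va rescale effect sizes to hold V_A constant.
#' @param va_target target 2 V_A (required when rescaling).
#' @param panel \code{\link{FrequencyPanel}} supplying the mean frequencies
#'   that enter V_A (required when rescaling).
#' @param seed integer seed.
#' @return an \code{\link{EffectTable}} of n loci.
#' @export
downsampleLoci <- function(effects, n, rescale_va = FALSE, va_target = NULL,
                           panel = NULL, seed = 1L) {
    L <- nrow(effects)
    if (n < 2L || n > L) stop("n must lie in [2, ", L, "]")
    set.seed(seed)
    keep <- sort(sample.int(L, n))
    df <- as.data.frame(effects)[keep, , drop = FALSE]
    if (rescale_va) {
        if (is.null(va_target) || is.null(panel))
            stop("rescaling requires va_target and a frequency panel")
        va_sub <- vaScale(EffectTable(df), panel)
        if (va_sub <= 0) stop("subsample has zero additive variance")
        df$alpha <- df$alpha * sqrt(va_target / va_sub)
    }
    EffectTable(df)
}

#' Population- or region-targeted frequency shift
#'
#' Applies \code{\link{applyShift}} with an indicator environment: 1 for
#' the targeted population(s), 0 elsewhere, used raw (not mean-centered),
#' so only the targeted columns move.
#'
#' @param freqs L x M matrix of neutral frequencies (columns named by
#'   population).
#' @param alpha_acting length-L acting effect sizes.
#' @param s shift strength.
#' @param target a population id, a region label, or a character vector of
#'   population ids.
#' @param membership optional named character vector mapping population id
#'   to region label (needed for region targets).
#' @return perturbed matrix (see \code{\link{applyShift}}).
#' @export
targetedShift <- function(freqs, alpha_acting, s, target,
                          membership = NULL) {
    pops <- colnames(freqs)
    if (is.null(pops)) stop("freqs must have population column names")
    hit <- pops %in% target
    if (!any(hit) && !is.null(membership))
        hit <- membership[pops] %in% target
    if (!any(hit) && length(target) > 0L && !identical(target, character(0)))
        stop("unknown target: ", paste(target, collapse = ", "))
    applyShift(freqs, alpha_acting, as.numeric(hit), s, center_env = FALSE)
}

#' Per-locus environmental correlations
#'
#' Pearson correlation of each locus's transformed frequencies with the
#' transformed environment, the single-locus building block of the
#' enrichment comparator.
#'
#' @param freqs L x M frequency matrix (or \code{\link{FrequencyPanel}}).
#' @param model a fitted \code{\link{DriftModel}}.
#' @param y transformed environment from \code{\link{whitenEnvironment}}.
#' @return length-L vector of correlations.
#' @export
perLocusEnvCor <- function(freqs, model, y) {
    if (is(freqs, "FrequencyPanel")) freqs <- freqMatrix(freqs)
    Xp <- .transform_cholesky(t(freqs), model)
    cors <- drop(suppressWarnings(stats::cor(Xp, y)))
    cors[is.na(cors)] <- 0   # loci fixed across populations
    cors
}

#' Single-locus environmental-outlier enrichment test
#'
#' Counts GWAS loci whose per-locus transformed-frequency correlation with
#' the environment is an outlier against the per-locus empirical null --
#' beyond the null's lower \code{level/2} or upper \code{1 - level/2}
#' quantile, a sign-agnostic 5\% tail -- and tests that count against
#' Binomial(L, \code{level}) (upper tail). Unlike the genetic-value
#' statistics, this comparator ignores agreement between like-effect
#' alleles: a locus counts however its allele moves with the environment,
#' which is why its power is insensitive to the genetic correlation between
#' the measured trait and the trait selection acts on.
#'
#' By default the mid-p binomial tail, \eqn{P(X > k) + P(X = k)/2}, is
#' reported: the exact tail test is conservative by discreteness (at
#' L = 161 and a 5\% tail its attained size is about 3.2\%), and the mid-p
#' correction keeps the comparator's realized level near nominal so its
#' power is comparable with the continuous statistics.
#'
#' @param obs_cors observed per-locus correlations (length L), from
#'   \code{\link{perLocusEnvCor}}.
#' @param null_cors per-locus correlations of matched null SNPs (pooled
#'   across null sets).
#' @param level total tail level (default 0.05, split across both tails).
#' @param method \code{"midp"} (default), \code{"exact"}, or
#'   \code{"randomized"}. The exact tail \eqn{P(X \ge k)} is conservative
#'   by discreteness; the randomized p-value \eqn{P(X > k) + U P(X = k)}
#'   with \eqn{U \sim \mathrm{Unif}(0,1)} is exactly uniform under the
#'   null, and is what the power machinery uses so that the comparator is
#'   held to precisely the same level as the continuous statistics.
#' @return list with the binomial \code{p}, the tail \code{count} and the
#'   two \code{cutoffs} used.
#' @export
enrichmentTest <- function(obs_cors, null_cors, level = 0.05,
                           method = c("midp", "exact", "randomized")) {
    cutoffs <- .enrich_cutoffs(null_cors, level)
    count <- .enrich_count(obs_cors, cutoffs)
    p <- .binom_tail_p(count, length(obs_cors), level, match.arg(method))
    list(p = p, count = count, cutoffs = cutoffs)
}

.enrich_cutoffs <- function(null_cors, level = 0.05)
    stats::quantile(null_cors, c(level / 2, 1 - level / 2), names = FALSE)

.enrich_count <- function(obs_cors, cutoffs)
    sum(obs_cors < cutoffs[1] | obs_cors > cutoffs[2])

.binom_tail_p <- function(count, L, level, method = "midp") {
    over <- stats::pbinom(count, L, level, lower.tail = FALSE)  # P(X > k)
    point <- stats::dbinom(count, L, level)
    switch(method,
           exact = over + point,
           midp = over + 0.5 * point,
           randomized = over + stats::runif(length(count)) * point)
}

## ---------------------------------------------------------------------------
## Power experiment driver
## ---------------------------------------------------------------------------

## All statistics for one replicate frequency matrix. `y_t` is the
## transformed environment, `y_raw` the raw (uncentered) environment;
## naive variants skip the whitening and use raw mean-centered values.
.replicate_stats <- function(freqs, alpha, model, y_t, y_raw,
                             null_cutoff = NULL) {
    z <- 2 * drop(crossprod(freqs, alpha))
    x <- whiten(z, model)
    er <- list(beta = sum(x * y_t) / sum(y_t^2), rho = stats::cor(
        x, y_t, method = "spearman"))
    Xp <- .transform_cholesky(t(freqs), model)
    W <- Xp * rep(2 * alpha, each = nrow(Xp))
    fst_like <- sum(W^2) / model@vaScale
    tot <- rowSums(W)
    qx_val <- sum(x^2)
    ld_like <- (sum(tot^2) - sum(W^2)) / model@vaScale
    zc <- z - mean(z)
    yc <- y_raw - mean(y_raw)
    out <- c(qx = qx_val, ld_like = ld_like, fst_like = fst_like,
             beta = er$beta, rho = er$rho,
             naive_qx = sum(zc^2),
             naive_rho = stats::cor(z, y_raw, method = "spearman"))
    if (!is.null(null_cutoff)) {
        cors <- drop(stats::cor(Xp, y_t))
        out["enrich_count"] <- .enrich_count(cors, null_cutoff)
    }
    out
}

.TWO_SIDED_STATS <- c("beta", "rho", "naive_rho")

#' Power of the test statistics under simulated selection
#'
#' For each row of the scenario grid, perturbs \code{n_replicates} neutral
#' matched-null frequency sets according to the scenario (gradient
#' strength \code{s}, pleiotropy \code{rho}, locus downsampling
#' \code{n_loci} with optional V_A rescaling, or a targeted population /
#' region) and reports, per statistic, the fraction of replicates whose
#' statistic falls beyond the 5\% critical value established from the same
#' replicates left unshifted. Structure-aware statistics (Q_X, its
#' components, the environmental slope and rank correlation) use the
#' whitening transform; naive comparators use raw mean-centered values;
#' the enrichment comparator applies \code{\link{enrichmentTest}} per
#' replicate.
#'
#' @param effects GWAS \code{\link{EffectTable}} (supplies the tested
#'   effect sizes).
#' @param pool pool metadata (for matched sampling).
#' @param pool_panel pool \code{\link{FrequencyPanel}}.
#' @param gwas_panel GWAS-locus \code{\link{FrequencyPanel}} (supplies the
#'   mean frequencies for V_A rescaling when downsampling loci).
#' @param model fitted \code{\link{DriftModel}}.
#' @param env \code{\link{EnvVector}} driving both the shift and the
#'   environmental tests.
#' @param grid data.frame of scenarios; recognized columns (all optional):
#'   \code{s} (default 0), \code{rho} (default 1), \code{n_loci} (default
#'   all), \code{rescale_va} (default \code{FALSE}), \code{target}
#'   (population/region id, \code{NA} for gradient scenarios).
#' @param membership named character vector mapping population to region
#'   (for region targets).
#' @param n_replicates replicates per scenario (a warning is issued below
#'   100, where power estimates are noisy).
#' @param level test level (default 0.05).
#' @param seed integer seed.
#' @return a \code{data.frame} (\dQuote{PowerTable}): the grid columns plus
#'   one \code{power_<statistic>} rejection-fraction column per statistic.
#' @export
powerExperiment <- function(effects, pool, pool_panel, model, env, grid,
                            gwas_panel = NULL, membership = NULL,
                            n_replicates = 200L, level = 0.05, seed = 1L) {
    n_replicates <- as.integer(n_replicates)
    if (n_replicates < 100L)
        warning("fewer than 100 replicates; power estimates will be noisy")
    for (col in c("s", "rho", "n_loci", "rescale_va", "target")) {
        if (is.null(grid[[col]]))
            grid[[col]] <- switch(col, s = 0, rho = 1, n_loci = NA_integer_,
                                  rescale_va = FALSE, target = NA_character_)
    }
    index <- buildPoolIndex(pool)
    y_raw <- envValues(env)
    va_full <- model@vaScale
    ## per-locus environment correlations of every pool SNP, computed once;
    ## the enrichment comparator's null is a matched-mixture lookup
    y_t_all <- whitenEnvironment(env, model)
    cor_pool <- perLocusEnvCor(freqMatrix(pool_panel), model, y_t_all)
    results <- vector("list", nrow(grid))
    for (g in seq_len(nrow(grid))) {
        sc <- grid[g, ]
        seed_g <- seed + 1000L * g
        eff_g <- effects
        if (!is.na(sc$n_loci) && sc$n_loci < nrow(effects)) {
            if (isTRUE(sc$rescale_va) && is.null(gwas_panel))
                stop("V_A rescaling requires gwas_panel")
            eff_g <- downsampleLoci(effects, sc$n_loci,
                                    rescale_va = isTRUE(sc$rescale_va),
                                    va_target = va_full, panel = gwas_panel,
                                    seed = seed_g)
        }
        alpha <- unname(eff_g$alpha)
        sets <- sampleNullSets(eff_g, index, n_replicates, seed = seed_g + 2L)
        P <- freqMatrix(pool_panel)
        y_t <- y_t_all
        ## per-locus null cutoffs from the exact matched mixture
        mix <- .matched_candidate_rows(eff_g, index)
        cutoff <- .enrich_cutoffs(cor_pool[mix], level)
        L <- length(alpha)
        stat_null <- stat_alt <- NULL
        for (r in seq_len(n_replicates)) {
            ## a fresh pleiotropic draw per replicate, so power averages
            ## over the acting-effect distribution
            acting <- if (sc$rho < 1)
                pleiotropicEffects(alpha, sc$rho, seed = seed_g + 10L + r)
            else alpha
            f0 <- P[sets@idx[, r], , drop = FALSE]
            f1 <- if (!is.na(sc$target) && nzchar(sc$target))
                targetedShift(f0, acting, sc$s, sc$target, membership)
            else applyShift(f0, acting, y_raw, sc$s)
            s0 <- .replicate_stats(f0, alpha, model, y_t, y_raw, cutoff)
            s1 <- .replicate_stats(f1, alpha, model, y_t, y_raw, cutoff)
            if (is.null(stat_null)) {
                stat_null <- matrix(0, n_replicates, length(s0),
                                    dimnames = list(NULL, names(s0)))
                stat_alt <- stat_null
            }
            stat_null[r, ] <- s0
            stat_alt[r, ] <- s1
        }
        rej <- vapply(colnames(stat_alt), function(nm) {
            if (nm == "enrich_count") {
                p_alt <- .binom_tail_p(stat_alt[, nm], L, level,
                                       method = "randomized")
                return(mean(p_alt <= level))
            }
            if (nm %in% .TWO_SIDED_STATS) {
                lo <- stats::quantile(stat_null[, nm], level / 2,
                                      names = FALSE)
                hi <- stats::quantile(stat_null[, nm], 1 - level / 2,
                                      names = FALSE)
                mean(stat_alt[, nm] < lo | stat_alt[, nm] > hi)
            } else {
                crit <- stats::quantile(stat_null[, nm], 1 - level,
                                        names = FALSE)
                mean(stat_alt[, nm] > crit)
            }
        }, numeric(1))
        names(rej)[names(rej) == "enrich_count"] <- "enrichment"
        names(rej) <- paste0("power_", names(rej))
        results[[g]] <- c(unlist(sc[c("s", "rho", "n_loci")]), rej)
    }
    out <- as.data.frame(do.call(rbind, results))
    out$rescale_va <- grid$rescale_va
    out$target <- grid$target
    out
}
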