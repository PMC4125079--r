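## The multivariate-normal drift null: genetic values, centering projection,
## covariance estimation from null SNPs, additive-variance scaling, whitening.

.align_effects_panel <- function(effects, panel) {
    ids <- intersect(snpIds(effects), rownames(panel))
    if (length(ids) == 0L)
        stop("no shared loci between effect table and panel")
    list(alpha = effectSizes(effects)[ids],
         freq = freqMatrix(panel)[ids, , drop = FALSE])
}

#' Population mean genetic values
#'
#' The estimated mean genetic value of each population,
#' \eqn{Z_m = 2 \sum_l \alpha_l p_{lm}}: twice the effect-size-weighted sum
#' of effect-allele frequencies (diploid dosage). The effect table and panel
#' are aligned on shared SNP ids.
#'
#' @param effects an \code{\link{EffectTable}}.
#' @param panel a \code{\link{FrequencyPanel}} oriented to the effect
#'   alleles (see \code{\link{orientPanel}}).
#' @return named numeric vector of length M, in trait units.
#' @export
geneticValues <- function(effects, panel) {
    ap <- .align_effects_panel(effects, panel)
    z <- 2 * drop(crossprod(ap$freq, ap$alpha))
    stats::setNames(z, colnames(ap$freq))
}

#' Mean-centering and dropping projection
#'
#' The (M-1) x M projection that subtracts the across-population mean from a
#' length-M vector and drops the coordinate of one population (the centering
#' makes the M coordinates linearly dependent, so one is redundant; which
#' population is dropped does not affect any downstream statistic).
#'
#' @param M population count (>= 2).
#' @param drop index of the dropped population (default the last).
#' @return (M-1) x M matrix with rows summing to zero.
#' @export
centerProjection <- function(M, drop = M) {
    M <- as.integer(M)
    if (M < 2L) stop("need at least 2 populations")
    if (drop < 1L || drop > M) stop("invalid dropped population index")
    P <- diag(M) - 1 / M
    P[-drop, , drop = FALSE]
}

.standardized_deviations <- function(panel) {
    f <- freqMatrix(panel)
    eps <- rowMeans(f)
    usable <- eps > 0 & eps < 1
    n_excluded <- sum(!usable)
    if (n_excluded > 0L)
        message(n_excluded, " null SNP(s) fixed across populations were ",
                "excluded from the covariance estimate")
    f <- f[usable, , drop = FALSE]
    eps <- eps[usable]
    list(D = (f - eps) / sqrt(eps * (1 - eps)), n = sum(usable))
}

#' Estimate the drift covariance F
#'
#' For each null SNP k the per-population sample frequencies are
#' standardized as \eqn{(p_{km} - \bar\epsilon_k)/\sqrt{\bar\epsilon_k
#' (1-\bar\epsilon_k)}}, with \eqn{\bar\epsilon_k} the unweighted mean
#' frequency across the M populations; each length-M vector is passed
#' through \code{\link{centerProjection}} and the sample covariance (divisor
#' K-1) of the projected vectors is returned. SNPs fixed across all
#' populations carry no information and are excluded with a message.
#'
#' Because sample (not population) frequencies enter the estimate, binomial
#' sampling noise inflates the diagonal by terms of order
#' \eqn{1/n_m}; the GWAS loci are subject to the same sampling, so the null
#' is matched and no correction is applied.
#'
#' @param null_panel a \code{\link{FrequencyPanel}} of K >= M null SNPs.
#' @param drop index of the dropped population (default last).
#' @return (M-1) x (M-1) symmetric covariance matrix.
#' @export
estimateF <- function(null_panel, drop = ncol(null_panel)) {
    M <- ncol(null_panel)
    sd_ <- .standardized_deviations(null_panel)
    if (sd_$n < M)
        stop("fewer usable null SNPs (", sd_$n, ") than populations (", M,
             "); enlarge the null pool")
    Tproj <- centerProjection(M, drop)
    proj <- sd_$D %*% t(Tproj)
    F_mat <- stats::cov(proj)
    dimnames(F_mat) <- list(colnames(null_panel)[-drop],
                            colnames(null_panel)[-drop])
    F_mat
}

#' Additive-variance scale
#'
#' \eqn{V_A = 2 \sum_l \alpha_l^2 \bar\epsilon_l (1 - \bar\epsilon_l)}, the
#' additive genetic variance the GWAS loci would contribute in a population
#' at the grand-mean allele frequencies \eqn{\bar\epsilon_l} (the mean of
#' each locus across the M populations). The returned scale is
#' \eqn{2 V_A}, the multiplier of F in the covariance of the genetic
#' values. Loci fixed across all populations contribute zero and are
#' flagged with a message.
#'
#' @param effects an \code{\link{EffectTable}}.
#' @param panel the \code{\link{FrequencyPanel}} whose mean frequencies are
#'   used (normally the GWAS panel).
#' @return positive scalar \eqn{2 V_A} in squared trait units.
#' @export
vaScale <- function(effects, panel) {
    ap <- .align_effects_panel(effects, panel)
    eps <- rowMeans(ap$freq)
    fixed <- eps <= 0 | eps >= 1
    if (any(fixed))
        message(sum(fixed), " locus/loci fixed across populations ",
                "contribute nothing to V_A")
    va <- 2 * sum(ap$alpha[!fixed]^2 * eps[!fixed] * (1 - eps[!fixed]))
    2 * va
}

.chol_lower <- function(F_mat) {
    C <- tryCatch(t(chol(F_mat)), error = function(e) NULL)
    if (is.null(C)) {
        ridge <- 1e-10 * sum(diag(F_mat)) / nrow(F_mat)
        warning("F is not positive definite; adding a ridge of ",
                signif(ridge, 3), " (duplicate populations, or too few ",
                "null SNPs?)")
        C <- tryCatch(t(chol(F_mat + ridge * diag(nrow(F_mat)))),
                      error = function(e) NULL)
        if (is.null(C))
            stop("F is singular even after ridging; increase the number of ",
                 "null SNPs or drop duplicate populations")
    }
    C
}

#' Fit the drift null model
#'
#' Assembles a \code{\link{DriftModel}}: the centering projection, the
#' covariance F estimated from the null panel, its Cholesky factor, and the
#' additive-variance scale computed from the GWAS loci.
#'
#' @param effects GWAS \code{\link{EffectTable}}.
#' @param gwas_panel GWAS-locus \code{\link{FrequencyPanel}} (for the
#'   variance scale).
#' @param null_panel null-SNP \code{\link{FrequencyPanel}} (for F); must
#'   share the population order of \code{gwas_panel}.
#' @param drop population id to drop, or \code{"last"}.
#' @return a fitted \code{\link{DriftModel}}.
#' @export
fitDriftModel <- function(effects, gwas_panel, null_panel, drop = "last") {
    pops <- populationIds(null_panel)
    if (!identical(pops, populationIds(gwas_panel)))
        stop("GWAS and null panels must share the same population order")
    drop_idx <- if (identical(drop, "last")) length(pops)
                else match(drop, pops)
    if (is.na(drop_idx)) stop("unknown dropped population: ", drop)
    F_mat <- estimateF(null_panel, drop = drop_idx)
    va <- vaScale(effects, gwas_panel)
    if (va <= 0)
        stop("additive-variance scale is zero (all effect sizes zero?); ",
             "the whitening transform is undefined")
    new("DriftModel", populationIds = pops, dropped = pops[drop_idx],
        Tproj = centerProjection(length(pops), drop_idx), Fmat = F_mat,
        cholC = .chol_lower(F_mat), vaScale = va,
        nNullSnps = as.integer(nrow(null_panel)))
}

#' Whiten genetic values
#'
#' Transforms a length-M vector of genetic values to M-1 coordinates that
#' are independent standard normals under the drift null:
#' \eqn{x' = C^{-1} T z / \sqrt{2 V_A}}, where T is the centering
#' projection and C the lower-triangular Cholesky factor of F (solved by
#' forward substitution). A matrix of column vectors is transformed
#' column-wise.
#'
#' @param values numeric length-M vector, or M x n matrix of column vectors.
#' @param model a fitted \code{\link{DriftModel}}.
#' @return numeric vector of length M-1 (or (M-1) x n matrix).
#' @export
whiten <- function(values, model) {
    x <- .transform_cholesky(values, model)
    x / sqrt(model@vaScale)
}

## Shared projection + Cholesky solve, without the variance standardization.
## Vector in, vector out; matrix in, matrix out (even with one column).
.transform_cholesky <- function(values, model) {
    keep_matrix <- is.matrix(values)
    v <- as.matrix(values)
    if (nrow(v) != length(model@populationIds))
        stop("values must have one entry per population")
    out <- forwardsolve(model@cholC, model@Tproj %*% v)
    if (keep_matrix) out else drop(out)
}

#' Whiten an environmental variable
#'
#' Applies the same mean-centering, projection and Cholesky solve as
#' \code{\link{whiten}} but without the additive-variance standardization
#' (the environmental variable keeps its own units), placing it in the same
#' rotated frame of reference as the transformed genetic values.
#'
#' @param env an \code{\link{EnvVector}} aligned to the model's populations.
#' @param model a fitted \code{\link{DriftModel}}.
#' @return numeric vector of length M-1.
#' @export
whitenEnvironment <- function(env, model) {
    if (!identical(populationIds(env), model@populationIds))
        stop("environment populations do not match the model")
    .transform_cholesky(envValues(env), model)
}
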