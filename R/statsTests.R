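## Q_X, its decomposition, environmental-correlation statistics, per-locus
## regression, and empirical p-values.

#' The Q_X excess-variance statistic
#'
#' \eqn{Q_X = \sum_{m=1}^{M-1} x'^2_m} with \eqn{x'} the whitened genetic
#' values: a standardized measure of among-population variance in genetic
#' values beyond what drift and shared history explain. Equivalently the
#' quadratic form \eqn{(Tz)^\top (2 V_A F)^{-1} (Tz)}; approximately
#' chi-square with M-1 degrees of freedom under the null.
#'
#' @param values length-M genetic value vector, or M x n matrix (one
#'   statistic is returned per column).
#' @param model a fitted \code{\link{DriftModel}}.
#' @return non-negative scalar (or vector of length n).
#' @export
qx <- function(values, model) {
    x <- whiten(values, model)
    if (is.matrix(x)) colSums(x^2) else sum(x^2)
}

#' Transformed per-locus allele frequencies
#'
#' Passes each locus's frequency vector through the same centering
#' projection and Cholesky solve as the genetic values (without the
#' additive-variance standardization). The transformed populations are
#' uncorrelated under the null, so per-locus analyses in this frame need no
#' further structure correction.
#'
#' @param panel a \code{\link{FrequencyPanel}} (loci aligned to the model's
#'   populations).
#' @param model a fitted \code{\link{DriftModel}}.
#' @return (M-1) x L matrix; column l holds the transformed frequencies of
#'   locus l.
#' @export
transformedFrequencies <- function(panel, model) {
    if (!identical(populationIds(panel), model@populationIds))
        stop("panel populations do not match the model")
    .transform_cholesky(t(freqMatrix(panel)), model)
}

#' Decompose Q_X into F_ST-like and LD-like components
#'
#' Writing the whitened genetic values as an effect-size-weighted sum of
#' transformed per-locus frequencies, Q_X splits exactly into a sum of
#' per-locus variance terms (the F_ST-like component) and a sum of
#' cross-locus covariance terms (the LD-like component):
#' \deqn{Q_X = \frac{1}{2V_A}\sum_m \sum_l (2\alpha_l x'_{lm})^2 +
#'       \frac{1}{2V_A}\sum_m \sum_{l \ne l'} (2\alpha_l x'_{lm})
#'       (2\alpha_{l'} x'_{l'm}).}
#' Under neutrality the LD-like term has expectation zero; coordinated
#' shifts of like-effect alleles under selection drive it positive.
#'
#' @param effects an \code{\link{EffectTable}}.
#' @param panel the GWAS-locus \code{\link{FrequencyPanel}} (same loci).
#' @param model a fitted \code{\link{DriftModel}}.
#' @return named list with elements \code{fst_like} and \code{ld_like};
#'   their sum equals \code{qx(geneticValues(effects, panel), model)}.
#' @export
qxDecomposition <- function(effects, panel, model) {
    ap <- .align_effects_panel(effects, panel)
    sub <- FrequencyPanel(ap$freq, chromCounts(panel))
    Xp <- transformedFrequencies(sub, model)      # (M-1) x L
    W <- Xp * rep(2 * ap$alpha, each = nrow(Xp))  # weighted contributions
    fst_like <- sum(W^2) / model@vaScale
    tot <- rowSums(W)
    ld_like <- (sum(tot^2) - sum(W^2)) / model@vaScale
    list(fst_like = fst_like, ld_like = ld_like)
}

#' Environmental regression in the whitened frame
#'
#' Regresses transformed genetic values on a transformed environmental
#' variable. Both vectors are mean-free by construction, so the model has
#' no intercept: \eqn{\hat\beta = \sum_i x_i y_i / \sum_i y_i^2}. Also
#' returns the squared Pearson correlation (fraction of variance explained)
#' and the Spearman rank correlation, which is robust to outlying
#' populations.
#'
#' @param x transformed genetic values (length M-1), from
#'   \code{\link{whiten}}.
#' @param y transformed environmental variable (length M-1), from
#'   \code{\link{whitenEnvironment}}.
#' @return named list with \code{beta}, \code{r2}, \code{rho}.
#' @export
envRegression <- function(x, y) {
    if (length(x) != length(y))
        stop("x and y must have equal length")
    if (length(x) < 3L)
        stop("need at least 3 transformed coordinates")
    if (stats::var(y) == 0)
        stop("environmental variable has zero variance after transformation")
    list(beta = sum(x * y) / sum(y^2),
         r2 = stats::cor(x, y)^2,
         rho = stats::cor(x, y, method = "spearman"))
}

#' Per-locus environmental regression
#'
#' Fits the environmental slope locus by locus in the whitened frame and
#' combines the per-locus slopes into the maximum-likelihood stacked
#' estimate. Each locus l has slope \eqn{\beta_l = \sum_m x'_{lm} y_m /
#' \sum_m y_m^2}; under the shared-slope model \eqn{x'_{lm} = 2\alpha_l
#' \beta y_m + e_{lm}} the maximum-likelihood \eqn{\bar\beta} is the
#' regression of the stacked transformed frequencies on the stacked
#' predictor \eqn{2\alpha_l y_m},
#' \deqn{\bar\beta = \sum_l 2\alpha_l \beta_l / \sum_l (2\alpha_l)^2,}
#' an effect-size-weighted combination of the per-locus slopes that is
#' exactly proportional to the genetic-value slope of
#' \code{\link{envRegression}}: \eqn{\bar\beta = \beta_{\mathrm{GV}}
#' \sqrt{2V_A} / \sum_l (2\alpha_l)^2}.
#'
#' @param effects an \code{\link{EffectTable}}.
#' @param panel the GWAS-locus \code{\link{FrequencyPanel}}.
#' @param model a fitted \code{\link{DriftModel}}.
#' @param y transformed environmental variable (length M-1).
#' @return named list with \code{beta_bar} and the length-L vector
#'   \code{per_locus}.
#' @export
perLocusRegression <- function(effects, panel, model, y) {
    ap <- .align_effects_panel(effects, panel)
    sub <- FrequencyPanel(ap$freq, chromCounts(panel))
    Xp <- transformedFrequencies(sub, model)
    per_locus <- drop(crossprod(Xp, y)) / sum(y^2)
    a2 <- 2 * ap$alpha
    beta_bar <- sum(a2 * per_locus) / sum(a2^2)
    list(beta_bar = beta_bar,
         per_locus = stats::setNames(per_locus, names(ap$alpha)))
}

#' Empirical p-value with the add-one rule
#'
#' \code{upper}: \eqn{p = (\#\{null \ge obs\} + 1)/(K + 1)};
#' \code{two-sided}: twice the smaller of the upper and lower tails, capped
#' at 1. The add-one correction keeps p strictly positive.
#'
#' @param observed observed statistic.
#' @param null_draws numeric vector of K >= 1 null draws.
#' @param tail \code{"upper"} or \code{"two-sided"}.
#' @return empirical p-value in (0, 1].
#' @export
empiricalPValue <- function(observed, null_draws,
                            tail = c("upper", "two-sided")) {
    tail <- match.arg(tail)
    K <- length(null_draws)
    if (K < 1L) stop("at least one null draw is required")
    upper <- (sum(null_draws >= observed) + 1) / (K + 1)
    if (tail == "upper") return(upper)
    lower <- (sum(null_draws <= observed) + 1) / (K + 1)
    min(1, 2 * min(upper, lower))
}

#' Q_X test against the matched-SNP empirical null
#'
#' Computes the observed Q_X and its empirical p-value against Q_X of the
#' supplied null genetic-value draws (columns), all whitened with the same
#' model.
#'
#' @param values observed length-M genetic values.
#' @param model a fitted \code{\link{DriftModel}}.
#' @param null_values M x K matrix of null genetic-value draws, e.g. from
#'   \code{\link{nullGeneticValues}}.
#' @param tail \code{"upper"} (default) or \code{"two-sided"} (of interest
#'   when widespread stabilizing selection is a candidate).
#' @param seed seed recorded in the report.
#' @return a \code{\link{TestReport}}.
#' @export
qxTest <- function(values, model, null_values, tail = "upper", seed = NA_integer_) {
    obs <- qx(values, model)
    nulls <- qx(null_values, model)
    new("TestReport", statistic = "QX", observed = obs, nullDraws = nulls,
        pEmpirical = empiricalPValue(obs, nulls, tail), tail = tail,
        seed = as.integer(seed))
}

#' Environmental-correlation tests against the empirical null
#'
#' Computes the no-intercept slope, squared correlation and Spearman rank
#' correlation between whitened genetic values and the whitened
#' environmental variable, with empirical p-values from the same statistics
#' applied to the null genetic-value draws. The slope and rank correlation
#' are tested two-sided; r2 is unsigned, so it is tested upper-tail (the
#' direction of the association is carried by the slope's sign).
#'
#' @param values observed length-M genetic values.
#' @param env an \code{\link{EnvVector}}.
#' @param model a fitted \code{\link{DriftModel}}.
#' @param null_values M x K matrix of null genetic-value draws.
#' @param seed seed recorded in the reports.
#' @return named list of three \code{\link{TestReport}}s: \code{beta},
#'   \code{r2}, \code{rho}.
#' @export
envTest <- function(values, env, model, null_values, seed = NA_integer_) {
    y <- whitenEnvironment(env, model)
    obs <- envRegression(whiten(values, model), y)
    Xn <- whiten(null_values, model)
    null_beta <- drop(crossprod(Xn, y)) / sum(y^2)
    null_r <- drop(stats::cor(Xn, y))
    null_rho <- drop(stats::cor(Xn, y, method = "spearman"))
    mk <- function(name, o, nulls, tail)
        new("TestReport", statistic = name, observed = o, nullDraws = nulls,
            pEmpirical = empiricalPValue(o, nulls, tail), tail = tail,
            seed = as.integer(seed))
    list(beta = mk("beta", obs$beta, null_beta, "two-sided"),
         r2 = mk("r2", obs$r2, null_r^2, "upper"),
         rho = mk("rho", obs$rho, null_rho, "two-sided"))
}
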