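## Conditional multivariate-normal machinery for localizing signals:
## re-centered covariance, conditional distributions, per-group Z-scores.

.partition_indices <- function(partition, pops) {
    i1 <- match(partition@group1, pops)
    i2 <- match(partition@group2, pops)
    if (anyNA(i1) || anyNA(i2))
        stop("partition names unknown population(s): ",
             paste(c(partition@group1[is.na(i1)],
                     partition@group2[is.na(i2)]), collapse = ", "))
    if (length(c(i1, i2)) != length(pops))
        stop("partition must cover all populations exactly once")
    list(i1 = i1, i2 = i2)
}

#' Re-centered covariance for a population partition
#'
#' Re-estimates the full M x M covariance of standardized allele-frequency
#' deviations with every population expressed relative to the mean of the
#' conditioning group (group 2) instead of the global mean: divergence from
#' a subgroup mean exceeds divergence from the global mean even under
#' neutrality, and the conditional null must reflect that. The projection
#' has 1 on the diagonal (0 elsewhere) in the group-1 columns and
#' \eqn{1 - 1/M_2} on the diagonal (\eqn{-1/M_2} elsewhere) in the group-2
#' columns; the group-2 block of the result has rank \eqn{M_2 - 1} by
#' construction.
#'
#' @param null_panel null-SNP \code{\link{FrequencyPanel}}.
#' @param partition a \code{\link{GroupPartition}} over the panel's
#'   populations.
#' @return M x M re-centered covariance matrix (population order as the
#'   panel).
#' @export
recenterF <- function(null_panel, partition) {
    pops <- populationIds(null_panel)
    pi <- .partition_indices(partition, pops)
    sd_ <- .standardized_deviations(null_panel)
    if (sd_$n < length(pops))
        stop("fewer usable null SNPs than populations")
    ## subtract the group-2 mean from every population's deviation
    D2 <- sd_$D - rowMeans(sd_$D[, pi$i2, drop = FALSE])
    F2 <- stats::cov(D2)
    dimnames(F2) <- list(pops, pops)
    F2
}

#' Conditional distribution of group-1 genetic values
#'
#' Standard multivariate-normal conditioning on the re-centered covariance
#' \eqn{\Sigma = 2 V_A F^{(2)}}: with blocks \eqn{\Sigma_{11}},
#' \eqn{\Sigma_{22}}, \eqn{\Sigma_{12}} indexed by the partition,
#' \deqn{\mu_{cond} = \bar z_2 1 + \Sigma_{12} \Sigma_{22}^- (z_2 - \bar
#'   z_2 1), \qquad
#'   \Sigma_{cond} = \Sigma_{11} - \Sigma_{12} \Sigma_{22}^- \Sigma_{21},}
#' where \eqn{\bar z_2} is the mean observed genetic value of group 2 and
#' \eqn{\Sigma_{22}^-} is a pseudo-inverse restricted to the block's
#' rank-(M2-1) support (the re-centering makes the block singular by one).
#'
#' @param values2 observed genetic values of the group-2 populations
#'   (ordered as they appear in the panel).
#' @param F2 re-centered covariance from \code{\link{recenterF}}.
#' @param partition the \code{\link{GroupPartition}} used for \code{F2}.
#' @param va the additive-variance scale 2 V_A (from the global fit; the
#'   scale is a property of the loci, not the partition).
#' @return list with \code{mu_cond} (length M1) and \code{sigma_cond}
#'   (M1 x M1).
#' @export
conditionalDistribution <- function(values2, F2, partition, va) {
    pops <- rownames(F2)
    pi <- .partition_indices(partition, pops)
    if (length(values2) != length(pi$i2))
        stop("values2 must hold one value per group-2 population")
    Sigma <- va * F2
    S11 <- Sigma[pi$i1, pi$i1, drop = FALSE]
    S22 <- Sigma[pi$i2, pi$i2, drop = FALSE]
    S12 <- Sigma[pi$i1, pi$i2, drop = FALSE]
    S22inv <- MASS::ginv(S22)
    zbar <- mean(values2)
    mu_cond <- zbar + drop(S12 %*% S22inv %*% (values2 - zbar))
    sigma_cond <- S11 - S12 %*% S22inv %*% t(S12)
    list(mu_cond = stats::setNames(mu_cond, pops[pi$i1]),
         sigma_cond = sigma_cond)
}

#' Conditional Z-score for a group of populations
#'
#' Compares the mean observed genetic value of the tested group with its
#' conditional expectation: \eqn{Z = (\bar z_1 - \overline{\mu_{cond}}) /
#' \sqrt{\overline{\Sigma_{cond}}}}, where the bar over the conditional
#' covariance denotes the mean of all its elements (the variance of a mean
#' of jointly normal variables). Standard normal under the drift null;
#' reported with a two-sided Gaussian p-value, as departures in either
#' direction are of interest.
#'
#' @param values1 observed genetic values of the tested populations.
#' @param mu_cond,sigma_cond conditional mean vector and covariance matrix
#'   from \code{\link{conditionalDistribution}}.
#' @param group1 tested population ids (recorded in the report).
#' @return a \code{\link{ConditionalReport}}.
#' @export
groupZscore <- function(values1, mu_cond, sigma_cond,
                        group1 = names(mu_cond)) {
    v <- mean(sigma_cond)
    if (v <= 0) stop("conditional variance must be positive")
    z <- (mean(values1) - mean(mu_cond)) / sqrt(v)
    new("ConditionalReport", group1 = as.character(group1),
        condMean = mean(mu_cond), condVar = v, z = z,
        pTwoSided = 2 * stats::pnorm(-abs(z)))
}

#' Conditional outlier test for one partition
#'
#' Convenience wrapper: re-centers the covariance on the conditioning
#' group, forms the conditional distribution of the tested group, and
#' returns its Z-score report.
#'
#' @param values full length-M genetic value vector (named by population).
#' @param null_panel null-SNP \code{\link{FrequencyPanel}}.
#' @param partition a \code{\link{GroupPartition}}.
#' @param va additive-variance scale 2 V_A from the global fit.
#' @param F2 optionally a precomputed \code{\link{recenterF}} result.
#' @return a \code{\link{ConditionalReport}}.
#' @export
conditionalTest <- function(values, null_panel, partition, va, F2 = NULL) {
    if (is.null(F2)) F2 <- recenterF(null_panel, partition)
    pops <- rownames(F2)
    pi <- .partition_indices(partition, pops)
    cd <- conditionalDistribution(values[pi$i2], F2, partition, va)
    groupZscore(values[pi$i1], cd$mu_cond, cd$sigma_cond,
                group1 = pops[pi$i1])
}

#' Conditional Z-scores for many genetic-value draws
#'
#' Vectorized form of \code{\link{conditionalTest}} for calibration and
#' power work: the conditional operators are formed once and applied to
#' every column of \code{values}.
#'
#' @param values M x n matrix of genetic-value vectors (rows ordered as
#'   the panel's populations).
#' @param null_panel null-SNP \code{\link{FrequencyPanel}}.
#' @param partition a \code{\link{GroupPartition}}.
#' @param va additive-variance scale 2 V_A.
#' @param F2 optionally a precomputed \code{\link{recenterF}} result.
#' @return numeric vector of n Z-scores.
#' @export
conditionalZScores <- function(values, null_panel, partition, va,
                               F2 = NULL) {
    if (is.null(F2)) F2 <- recenterF(null_panel, partition)
    pops <- rownames(F2)
    pi <- .partition_indices(partition, pops)
    Sigma <- va * F2
    S22inv <- MASS::ginv(Sigma[pi$i2, pi$i2, drop = FALSE])
    S12 <- Sigma[pi$i1, pi$i2, drop = FALSE]
    sigma_cond <- Sigma[pi$i1, pi$i1, drop = FALSE] -
        S12 %*% S22inv %*% t(S12)
    denom <- sqrt(mean(sigma_cond))
    abar <- colMeans(S12 %*% S22inv)   # mean conditional loading on group 2
    V1 <- values[pi$i1, , drop = FALSE]
    V2 <- values[pi$i2, , drop = FALSE]
    zbar2 <- colMeans(V2)
    mu_bar <- zbar2 + drop(crossprod(sweep(V2, 2, zbar2), abar))
    (colMeans(V1) - mu_bar) / denom
}

#' Leave-one-out conditional Z-scores
#'
#' Iterates every population as the tested group, conditioning on all
#' others.
#'
#' @param values full length-M genetic value vector (named by population).
#' @param null_panel null-SNP \code{\link{FrequencyPanel}}.
#' @param va additive-variance scale 2 V_A from the global fit.
#' @return \code{DataFrame} with one row per population: conditional mean,
#'   conditional variance, Z and two-sided p.
#' @export
leaveOneOutZ <- function(values, null_panel, va) {
    pops <- populationIds(null_panel)
    reports <- lapply(pops, function(p) {
        part <- GroupPartition(p, setdiff(pops, p))
        conditionalTest(values, null_panel, part, va)
    })
    DataFrame(population = pops,
              cond_mean = vapply(reports, function(r) r@condMean, 0),
              cond_var = vapply(reports, function(r) r@condVar, 0),
              z = vapply(reports, function(r) r@z, 0),
              p_two_sided = vapply(reports, function(r) r@pTwoSided, 0),
              row.names = pops)
}
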