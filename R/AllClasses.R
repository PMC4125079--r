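#' @import methods
#' @importFrom S4Vectors DataFrame DFrame metadata metadata<-
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
NULL

## ---------------------------------------------------------------------------
## EffectTable
## ---------------------------------------------------------------------------

#' GWAS effect table
#'
#' Holds the L trait-associated loci: the trait-increasing (effect) allele,
#' its additive effect size \eqn{\alpha_l} (trait units per allele copy), and
#' the ascertainment metadata used for null-SNP matching: minor allele
#' frequency in the ascertainment population, imputation status, and the
#' background-selection B value.
#'
#' Rows are oriented at construction so that every effect size is
#' non-negative; a row supplied with a negative effect has its alleles
#' swapped, the effect negated, and is marked in the \code{flipped} column.
#' Downstream allele frequencies for flipped rows must be complemented, which
#' \code{\link{readFrequencyPanel}} does automatically.
#'
#' @slot .Data inherited from \code{\link[S4Vectors]{DataFrame}}; required
#'   columns are \code{snp_id}, \code{effect_allele}, \code{alpha},
#'   \code{maf}, \code{imputed}, \code{b_value}, plus the derived
#'   \code{flipped} flag.
#' @export
setClass("EffectTable", contains = "DFrame")

.ET_REQUIRED <- c("snp_id", "effect_allele", "alpha", "maf", "imputed", "b_value")

setValidity("EffectTable", function(object) {
    msg <- character()
    missing <- setdiff(c(.ET_REQUIRED, "flipped"), colnames(object))
    if (length(missing))
        return(sprintf("missing required column(s): %s",
                       paste(missing, collapse = ", ")))
    if (anyDuplicated(object$snp_id))
        msg <- c(msg, "snp_id values must be unique")
    if (any(object$alpha < 0))
        msg <- c(msg, "effect sizes must be >= 0 after orientation")
    if (any(object$maf < 0 | object$maf > 0.5))
        msg <- c(msg, "ascertainment MAF must lie in [0, 0.5]")
    if (any(object$b_value < 0 | object$b_value > 1))
        msg <- c(msg, "B values must lie in [0, 1]")
    if (!is.logical(object$imputed))
        msg <- c(msg, "imputed must be logical")
    if (length(msg)) msg else TRUE
})

#' Construct an EffectTable
#'
#' Validates the columns and resolves allele orientation: rows with a
#' negative effect size are flipped so that the stored allele is always the
#' trait-increasing one. If an \code{other_allele} column is present the two
#' allele labels are swapped on flip; otherwise the flipped allele label is
#' set to \code{"N"} with a warning, since the complementary allele is
#' unknown.
#'
#' @param x a \code{data.frame} or \code{DataFrame} with columns
#'   \code{snp_id}, \code{effect_allele}, \code{alpha}, \code{maf},
#'   \code{imputed}, \code{b_value} and optionally \code{other_allele}.
#' @return an \code{EffectTable} with an added logical \code{flipped} column.
#' @examples
#' et <- EffectTable(data.frame(
#'     snp_id = c("rs1", "rs2"), effect_allele = c("A", "C"),
#'     other_allele = c("G", "T"), alpha = c(-0.3, 0.1),
#'     maf = c(0.2, 0.4), imputed = c(FALSE, TRUE), b_value = c(0.8, 0.5)))
#' effectSizes(et)   # both non-negative; rs1 was flipped
#' @export
EffectTable <- function(x) {
    x <- as(x, "DFrame")
    missing <- setdiff(.ET_REQUIRED, colnames(x))
    if (length(missing))
        stop("effect table is missing column(s): ",
             paste(missing, collapse = ", "))
    x$snp_id <- as.character(x$snp_id)
    x$effect_allele <- as.character(x$effect_allele)
    x$alpha <- as.numeric(x$alpha)
    x$maf <- as.numeric(x$maf)
    x$imputed <- as.logical(x$imputed)
    x$b_value <- as.numeric(x$b_value)
    flip <- x$alpha < 0
    if (any(flip)) {
        if ("other_allele" %in% colnames(x)) {
            ea <- x$effect_allele
            x$effect_allele[flip] <- as.character(x$other_allele)[flip]
            x$other_allele[flip] <- ea[flip]
        } else {
            warning(sum(flip), " row(s) flipped without an other_allele ",
                    "column; flipped allele labels set to 'N'")
            x$effect_allele[flip] <- "N"
        }
        x$alpha[flip] <- -x$alpha[flip]
    }
    prior <- if ("flipped" %in% colnames(x)) x$flipped else FALSE
    x$flipped <- xor(prior, flip)
    rownames(x) <- x$snp_id
    new("EffectTable", x)
}

## ---------------------------------------------------------------------------
## FrequencyPanel
## ---------------------------------------------------------------------------

#' Loci-by-population allele frequency panel
#'
#' A \code{SummarizedExperiment} whose single assay \code{"freq"} holds
#' sample frequencies of the effect allele (rows = SNPs, columns =
#' populations), with the number of sampled chromosomes per population in
#' \code{colData()$chromosomes}. Used both for the GWAS loci and for the
#' genome-wide null SNP pool.
#'
#' @export
setClass("FrequencyPanel", contains = "SummarizedExperiment")

setValidity("FrequencyPanel", function(object) {
    msg <- character()
    if (!"freq" %in% SummarizedExperiment::assayNames(object))
        return("assay 'freq' is required")
    f <- SummarizedExperiment::assay(object, "freq")
    if (any(!is.finite(f)) || any(f < 0 | f > 1))
        msg <- c(msg, "all frequencies must be finite and in [0, 1]")
    if (!"chromosomes" %in% colnames(colData(object)))
        msg <- c(msg, "colData must contain a 'chromosomes' column")
    else if (any(colData(object)$chromosomes < 2))
        msg <- c(msg, "every population needs >= 2 sampled chromosomes")
    if (is.null(rownames(object)))
        msg <- c(msg, "SNP ids (rownames) are required")
    if (length(msg)) msg else TRUE
})

#' Construct a FrequencyPanel
#'
#' @param freq numeric L x M matrix of effect-allele sample frequencies with
#'   SNP ids as rownames and population ids as colnames.
#' @param chromosomes integer vector of sampled chromosome counts, one per
#'   population (recycled if scalar).
#' @return a \code{FrequencyPanel}.
#' @examples
#' f <- matrix(0.5, 2, 3, dimnames = list(c("rs1", "rs2"), c("P1", "P2", "P3")))
#' fp <- FrequencyPanel(f, chromosomes = 50)
#' freqMatrix(fp)
#' @export
FrequencyPanel <- function(freq, chromosomes) {
    freq <- as.matrix(freq)
    storage.mode(freq) <- "double"
    chromosomes <- rep_len(as.integer(chromosomes), ncol(freq))
    se <- SummarizedExperiment(
        assays = list(freq = freq),
        colData = DataFrame(chromosomes = chromosomes,
                            row.names = colnames(freq)))
    new("FrequencyPanel", se)
}

## ---------------------------------------------------------------------------
## EnvVector
## ---------------------------------------------------------------------------

#' Per-population environmental variable
#'
#' One real-valued measurement per population (for example absolute latitude
#' or a climate principal-component score), ordered identically to the
#' companion \code{FrequencyPanel}.
#'
#' @slot values named numeric vector, one finite value per population.
#' @export
setClass("EnvVector", representation(values = "numeric"))

setValidity("EnvVector", function(object) {
    if (any(!is.finite(object@values)))
        return("environmental values must be finite")
    if (is.null(names(object@values)))
        return("population ids (names) are required")
    TRUE
})

#' @param values numeric vector of measurements.
#' @param population_ids character vector of population labels; defaults to
#'   \code{names(values)}.
#' @rdname EnvVector-class
#' @export
EnvVector <- function(values, population_ids = names(values)) {
    population_ids <- population_ids   # force before coercion strips names
    values <- as.numeric(values)
    names(values) <- population_ids
    new("EnvVector", values = values)
}

## ---------------------------------------------------------------------------
## DriftModel
## ---------------------------------------------------------------------------

#' Fitted multivariate-normal drift null
#'
#' The fitted null model for population mean genetic values: the centering
#' projection \code{Tproj} that subtracts the across-population mean and
#' drops one population, the (M-1) x (M-1) covariance \code{Fmat} of
#' standardized allele-frequency deviations estimated from matched null
#' SNPs, its lower-triangular Cholesky factor \code{cholC}, and the
#' additive-variance scale \code{vaScale} = 2 V_A that multiplies
#' \code{Fmat} in the genetic-value covariance.
#'
#' @slot populationIds character, all M population labels in panel order.
#' @slot dropped the population whose coordinate is dropped by the projection.
#' @slot Tproj (M-1) x M centering/dropping projection (rows sum to zero).
#' @slot Fmat (M-1) x (M-1) symmetric positive-definite covariance.
#' @slot cholC lower-triangular Cholesky factor of \code{Fmat}.
#' @slot vaScale positive scalar, two times the additive genetic variance
#'   contributed by the loci at the grand-mean allele frequencies.
#' @slot nNullSnps number of null SNPs used to estimate \code{Fmat}.
#' @export
setClass("DriftModel", representation(
    populationIds = "character",
    dropped = "character",
    Tproj = "matrix",
    Fmat = "matrix",
    cholC = "matrix",
    vaScale = "numeric",
    nNullSnps = "integer"))

setValidity("DriftModel", function(object) {
    msg <- character()
    M <- length(object@populationIds)
    if (!all(dim(object@Tproj) == c(M - 1L, M)))
        msg <- c(msg, "Tproj must be (M-1) x M")
    else if (max(abs(rowSums(object@Tproj))) > 1e-8)
        msg <- c(msg, "Tproj rows must sum to zero")
    if (max(abs(object@Fmat - t(object@Fmat))) > 1e-8)
        msg <- c(msg, "Fmat must be symmetric")
    if (any(diag(object@cholC) <= 0))
        msg <- c(msg, "all Cholesky pivots must be positive")
    if (object@vaScale <= 0)
        msg <- c(msg, "vaScale must be positive")
    if (length(msg)) msg else TRUE
})

setMethod("show", "DriftModel", function(object) {
    M <- length(object@populationIds)
    cat("DriftModel:", M, "populations (dropped:", object@dropped, ")\n")
    cat("  F estimated from", object@nNullSnps, "null SNPs\n")
    cat("  mean diag(F):", signif(mean(diag(object@Fmat)), 4),
        " vaScale (2*V_A):", signif(object@vaScale, 4), "\n")
})

## ---------------------------------------------------------------------------
## TestReport
## ---------------------------------------------------------------------------

#' Empirical test report
#'
#' Observed statistic, its matched-SNP null draws, and the add-one empirical
#' p-value \eqn{(r+1)/(K+1)} under the stated tail rule.
#'
#' @slot statistic one of \code{"QX"}, \code{"beta"}, \code{"r2"},
#'   \code{"rho"}, \code{"qx_fst_like"}, \code{"qx_ld_like"}.
#' @slot observed observed value.
#' @slot nullDraws numeric vector of null statistic draws.
#' @slot pEmpirical empirical p-value in (0, 1].
#' @slot tail \code{"upper"} or \code{"two-sided"}.
#' @slot seed integer seed used to draw the null sets.
#' @export
setClass("TestReport", representation(
    statistic = "character", observed = "numeric", nullDraws = "numeric",
    pEmpirical = "numeric", tail = "character", seed = "integer"))

setValidity("TestReport", function(object) {
    if (object@pEmpirical <= 0 || object@pEmpirical > 1)
        return("empirical p-value must lie in (0, 1]")
    if (!object@tail %in% c("upper", "two-sided"))
        return("tail must be 'upper' or 'two-sided'")
    TRUE
})

setMethod("show", "TestReport", function(object) {
    cat(sprintf("TestReport: %s = %.6g  (p = %.4g, %s tail, %d null draws)\n",
                object@statistic, object@observed, object@pEmpirical,
                object@tail, length(object@nullDraws)))
})

## ---------------------------------------------------------------------------
## GroupPartition / ConditionalReport
## ---------------------------------------------------------------------------

#' Population partition for conditional analysis
#'
#' Splits the M populations into a tested group 1 and a conditioning group 2
#' (at least two populations, since the covariance is re-centered on the
#' group-2 mean).
#'
#' @slot group1 character ids of the tested populations (M1 >= 1).
#' @slot group2 character ids of the conditioning populations (M2 >= 2).
#' @export
setClass("GroupPartition",
         representation(group1 = "character", group2 = "character"))

setValidity("GroupPartition", function(object) {
    if (length(object@group1) < 1L) return("group 1 must be non-empty")
    if (length(object@group2) < 2L)
        return("group 2 needs at least 2 populations")
    if (length(intersect(object@group1, object@group2)))
        return("groups must be disjoint")
    TRUE
})

#' @param group1 character vector of tested population ids.
#' @param group2 character vector of conditioning population ids.
#' @rdname GroupPartition-class
#' @export
GroupPartition <- function(group1, group2)
    new("GroupPartition", group1 = as.character(group1),
        group2 = as.character(group2))

#' Conditional multivariate-normal outlier report
#'
#' For the tested group, the expected mean genetic value given the
#' conditioning populations, the variance of that mean, and the standardized
#' Z-score (standard normal under the drift null) with its two-sided
#' Gaussian p-value.
#'
#' @slot group1 tested population ids.
#' @slot condMean conditional expectation of the group-1 mean genetic value.
#' @slot condVar variance of that mean under the null.
#' @slot z standardized score.
#' @slot pTwoSided two-sided Gaussian p-value.
#' @export
setClass("ConditionalReport", representation(
    group1 = "character", condMean = "numeric", condVar = "numeric",
    z = "numeric", pTwoSided = "numeric"))

setValidity("ConditionalReport", function(object) {
    if (object@condVar <= 0) return("conditional variance must be positive")
    if (object@pTwoSided <= 0 || object@pTwoSided > 1)
        return("p-value must lie in (0, 1]")
    TRUE
})

setMethod("show", "ConditionalReport", function(object) {
    cat(sprintf("ConditionalReport [%s]: z = %.3f (p = %.4g)\n",
                paste(object@group1, collapse = ","), object@z,
                object@pTwoSided))
})

## ---------------------------------------------------------------------------
## PoolIndex / NullSets
## ---------------------------------------------------------------------------

#' Contingency-table index of the null SNP pool
#'
#' Maps each cell of the 25 (MAF) x 2 (imputation) x 10 (B value)
#' contingency table to the pool SNPs it contains.
#'
#' @slot index named list: bin key -> integer positions into the pool.
#' @slot keys integer bin key per pool SNP.
#' @slot snpIds character pool SNP ids.
#' @export
setClass("PoolIndex", representation(
    index = "list", keys = "integer", snpIds = "character"))

setMethod("show", "PoolIndex", function(object) {
    cat("PoolIndex:", length(object@snpIds), "pool SNPs in",
        length(object@index), "occupied bins\n")
})

#' Matched null SNP sets
#'
#' \code{n_sets} sets of L null SNPs, each matched cell-by-cell to the GWAS
#' loci in the MAF x imputation x B-value contingency table, carrying the
#' GWAS effect sizes positionally.
#'
#' @slot idx L x n_sets integer matrix of pool row positions.
#' @slot poolIds character ids of the pool SNPs.
#' @slot alpha the GWAS effect sizes carried over to each set.
#' @slot nFallback number of GWAS loci whose bin had to be widened.
#' @slot seed integer seed used for sampling.
#' @export
setClass("NullSets", representation(
    idx = "matrix", poolIds = "character", alpha = "numeric",
    nFallback = "integer", seed = "integer"))

setMethod("show", "NullSets", function(object) {
    cat("NullSets:", ncol(object@idx), "matched sets of",
        nrow(object@idx), "SNPs")
    if (object@nFallback > 0L)
        cat(" (", object@nFallback, "loci used widened MAF bins)")
    cat("\n")
})

## ---------------------------------------------------------------------------
## FixtureSpec
## ---------------------------------------------------------------------------

#' Synthetic fixture specification
#'
#' Describes a fully synthetic dataset with the statistical structure the
#' method assumes: population frequencies drifted around an ancestral
#' frequency under a known covariance \code{F}, binomially sampled with
#' \code{chromosomes} chromosomes per population, with MAF / imputation /
#' B-value metadata so the matching machinery is exercised end to end.
#'
#' Defaults emulate the HGDP-scale height analysis: 52 populations, 161 GWAS
#' loci, a 20,000-SNP genome-wide pool, a star-shaped population tree with
#' per-branch drift 0.02, ancestral frequencies uniform on [0.05, 0.95] and
#' 50 chromosomes per population.
#'
#' @slot M population count.
#' @slot driftF either a scalar star-tree drift parameter c (F = c I) or an
#'   explicit M x M positive semi-definite matrix.
#' @slot Lgwas number of GWAS loci.
#' @slot Kpool null pool size.
#' @slot chromosomes sampled chromosomes per population (scalar or length M).
#' @slot ancestralRange range of the uniform ancestral frequency law.
#' @slot effectSd scale of the half-normal effect-size law (trait units).
#' @slot pImputed marginal probability a SNP is flagged imputed.
#' @slot seed integer seed.
#' @export
setClass("FixtureSpec", representation(
    M = "integer", driftF = "ANY", Lgwas = "integer", Kpool = "integer",
    chromosomes = "integer", ancestralRange = "numeric", effectSd = "numeric",
    pImputed = "numeric", seed = "integer"))

setValidity("FixtureSpec", function(object) {
    msg <- character()
    if (object@M < 2L) msg <- c(msg, "M must be >= 2")
    if (object@Lgwas < 1L) msg <- c(msg, "Lgwas must be >= 1")
    if (object@Kpool < object@M)
        msg <- c(msg, "Kpool must be at least M")
    if (length(object@ancestralRange) != 2L ||
        object@ancestralRange[1] <= 0 || object@ancestralRange[2] >= 1)
        msg <- c(msg, "ancestralRange must lie strictly inside (0, 1)")
    if (length(msg)) msg else TRUE
})

#' @param M,driftF,Lgwas,Kpool,chromosomes,ancestralRange,effectSd,pImputed,seed
#'   see the class slots.
#' @rdname FixtureSpec-class
#' @export
fixtureSpec <- function(M = 52L, driftF = 0.02, Lgwas = 161L, Kpool = 20000L,
                        chromosomes = 50L, ancestralRange = c(0.05, 0.95),
                        effectSd = 0.1, pImputed = 0.5, seed = 1L) {
    new("FixtureSpec", M = as.integer(M), driftF = driftF,
        Lgwas = as.integer(Lgwas), Kpool = as.integer(Kpool),
        chromosomes = rep_len(as.integer(chromosomes), as.integer(M)),
        ancestralRange = as.numeric(ancestralRange),
        effectSd = as.numeric(effectSd), pImputed = as.numeric(pImputed),
        seed = as.integer(seed))
}

setMethod("show", "FixtureSpec", function(object) {
    cat("FixtureSpec:", object@M, "populations,", object@Lgwas,
        "GWAS loci, pool of", object@Kpool, "SNPs\n")
})
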