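#' Accessors for polyadapt classes
#'
#' Small accessor generics shared across the package's S4 classes:
#' \code{populationIds} returns population labels, \code{snpIds} SNP labels,
#' \code{freqMatrix} the loci-by-population frequency matrix,
#' \code{chromCounts} the per-population chromosome counts,
#' \code{effectSizes} the (non-negative) effect sizes, and \code{envValues}
#' the per-population environmental measurements.
#'
#' @param x an object.
#' @return a vector or matrix as described above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("populationIds", function(x) standardGeneric("populationIds"))

#' @rdname accessors
#' @export
setGeneric("snpIds", function(x) standardGeneric("snpIds"))

#' @rdname accessors
#' @export
setGeneric("freqMatrix", function(x) standardGeneric("freqMatrix"))

#' @rdname accessors
#' @export
setGeneric("chromCounts", function(x) standardGeneric("chromCounts"))

#' @rdname accessors
#' @export
setGeneric("effectSizes", function(x) standardGeneric("effectSizes"))

#' @rdname accessors
#' @export
setGeneric("envValues", function(x) standardGeneric("envValues"))

#' @rdname accessors
#' @export
setMethod("populationIds", "FrequencyPanel", function(x) colnames(x))

#' @rdname accessors
#' @export
setMethod("populationIds", "EnvVector", function(x) names(x@values))

#' @rdname accessors
#' @export
setMethod("populationIds", "DriftModel", function(x) x@populationIds)

#' @rdname accessors
#' @export
setMethod("snpIds", "FrequencyPanel", function(x) rownames(x))

#' @rdname accessors
#' @export
setMethod("snpIds", "EffectTable", function(x) x$snp_id)

#' @rdname accessors
#' @export
setMethod("freqMatrix", "FrequencyPanel",
          function(x) SummarizedExperiment::assay(x, "freq"))

#' @rdname accessors
#' @export
setMethod("chromCounts", "FrequencyPanel",
          function(x) stats::setNames(colData(x)$chromosomes, colnames(x)))

#' @rdname accessors
#' @export
setMethod("effectSizes", "EffectTable",
          function(x) stats::setNames(x$alpha, x$snp_id))

#' @rdname accessors
#' @export
setMethod("envValues", "EnvVector", function(x) x@values)
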