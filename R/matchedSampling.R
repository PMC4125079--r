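## Matched null SNP sampling: the 25 x 2 x 10 MAF/imputation/B-value
## contingency table, null set draws, and null genetic values.

.N_MAF_BINS <- 25L
.N_B_BINS <- 10L

#' Assign SNPs to contingency-table bins
#'
#' MAF bins have width 0.02 (25 bins over [0, 0.5], the top edge capped into
#' bin 24), imputation is binary, and B-value bins have width 0.1 (10 bins
#' over [0, 1], capped into bin 9).
#'
#' @param maf ascertainment minor allele frequency, in [0, 0.5] (vectorized).
#' @param imputed logical imputation flag.
#' @param b_value background-selection B value in [0, 1].
#' @return data.frame with columns \code{maf_bin}, \code{imputed_bin},
#'   \code{b_bin} and the combined integer \code{key}.
#' @export
binAssign <- function(maf, imputed, b_value) {
    if (any(maf < 0 | maf > 0.5))
        stop("MAF must lie in [0, 0.5]")
    if (any(b_value < 0 | b_value > 1))
        stop("B values must lie in [0, 1]")
    maf_bin <- pmin(floor(maf / 0.02), .N_MAF_BINS - 1L)
    b_bin <- pmin(floor(b_value / 0.1), .N_B_BINS - 1L)
    imputed_bin <- as.integer(imputed)
    data.frame(maf_bin = as.integer(maf_bin), imputed_bin = imputed_bin,
               b_bin = as.integer(b_bin),
               key = .bin_key(maf_bin, imputed_bin, b_bin))
}

.bin_key <- function(maf_bin, imputed_bin, b_bin)
    as.integer(maf_bin + .N_MAF_BINS * (imputed_bin + 2L * b_bin))

#' Index a null SNP pool by contingency-table cell
#'
#' @param pool pool metadata: a \code{data.frame}, \code{DataFrame} or
#'   \code{\link{EffectTable}} with columns \code{snp_id}, \code{maf},
#'   \code{imputed}, \code{b_value}.
#' @return a \code{\link{PoolIndex}}.
#' @export
buildPoolIndex <- function(pool) {
    pool <- as.data.frame(pool)
    keys <- binAssign(pool$maf, pool$imputed, pool$b_value)$key
    idx <- split(seq_len(nrow(pool)), keys)
    new("PoolIndex", index = idx, keys = keys,
        snpIds = as.character(pool$snp_id))
}

## Candidate pool positions for one bin, widening the MAF bin by +/-1 then
## +/-2 at the same imputation and B bins until at least `need` candidates
## are available (a cell shared by several GWAS loci needs that many
## distinct null SNPs per set).
.bin_candidates <- function(index, maf_bin, imputed_bin, b_bin, need = 1L) {
    cand <- integer()
    for (width in 0:2) {
        mbins <- max(0L, maf_bin - width):min(.N_MAF_BINS - 1L,
                                              maf_bin + width)
        keys <- as.character(.bin_key(mbins, imputed_bin, b_bin))
        cand <- unlist(index@index[keys], use.names = FALSE)
        if (length(cand) >= need)
            return(list(cand = cand, widened = width > 0L))
    }
    list(cand = cand, widened = TRUE)
}

## Resolve, for each GWAS locus, the pool candidate list of its
## contingency cell (with MAF-bin widening); shared by set sampling and by
## the per-locus empirical null of the enrichment comparator.
.resolve_candidates <- function(gwas, index) {
    bins <- binAssign(gwas$maf, gwas$imputed, gwas$b_value)
    key_count <- table(bins$key)
    ukey <- !duplicated(bins$key)
    cand_by_key <- lapply(which(ukey), function(i)
        .bin_candidates(index, bins$maf_bin[i], bins$imputed_bin[i],
                        bins$b_bin[i],
                        need = key_count[[as.character(bins$key[i])]]))
    names(cand_by_key) <- as.character(bins$key[ukey])
    empty <- vapply(cand_by_key, function(x) length(x$cand) == 0L,
                    logical(1))
    if (any(empty)) {
        bad <- bins$key %in% as.integer(names(cand_by_key)[empty])
        stop("no pool SNPs available (even after widening the MAF bin) ",
             "for GWAS SNP(s): ",
             paste(gwas$snp_id[bad], collapse = ", "))
    }
    list(bins = bins, cand_by_key = cand_by_key,
         n_fallback = sum(vapply(cand_by_key[as.character(bins$key)],
                                 function(x) x$widened, logical(1))))
}

## All pool SNPs of each GWAS locus's resolved cell, concatenated with one
## block per locus (loci sharing a cell repeat its SNPs): the exact matched
## mixture behind the per-locus empirical null, free of resampling noise.
.matched_candidate_rows <- function(gwas, index) {
    res <- .resolve_candidates(gwas, index)
    unlist(lapply(as.character(res$bins$key),
                  function(k) res$cand_by_key[[k]]$cand),
           use.names = FALSE)
}

#' Sample matched null SNP sets
#'
#' Draws \code{n_sets} sets of null SNPs, one per GWAS locus, each sampled
#' from the pool SNPs in the same contingency-table cell as its GWAS locus
#' and assigned that locus's effect size. Within a set, GWAS loci sharing a
#' cell receive distinct null SNPs (sampling without replacement per cell);
#' sets are independent draws. When a cell is empty, the MAF bin is widened
#' by one, then two, at the same imputation and B bins; the number of loci
#' needing widening is recorded. Deterministic given \code{seed}.
#'
#' @param gwas the GWAS \code{\link{EffectTable}}.
#' @param index a \code{\link{PoolIndex}} from \code{\link{buildPoolIndex}}.
#' @param n_sets number of null sets.
#' @param seed integer seed.
#' @return a \code{\link{NullSets}} object.
#' @export
sampleNullSets <- function(gwas, index, n_sets, seed = 1L) {
    n_sets <- as.integer(n_sets)
    if (n_sets < 1L) stop("n_sets must be >= 1")
    res <- .resolve_candidates(gwas, index)
    bins <- res$bins
    cand_by_key <- res$cand_by_key
    n_fallback <- res$n_fallback
    L <- nrow(bins)
    grp <- split(seq_len(L), bins$key)
    set.seed(seed)
    out <- matrix(0L, nrow = L, ncol = n_sets)
    for (k in names(grp)) {
        rows <- grp[[k]]
        cand <- cand_by_key[[k]]$cand
        g <- length(rows)
        n <- length(cand)
        if (g == 1L) {
            out[rows, ] <- cand[sample.int(n, n_sets, replace = TRUE)]
        } else {
            if (n < g)
                stop("contingency cell for GWAS SNP(s) ",
                     paste(gwas$snp_id[rows], collapse = ", "),
                     " holds only ", n, " pool SNPs but ", g,
                     " are needed per set")
            out[rows, ] <- vapply(seq_len(n_sets),
                                  function(i) cand[sample.int(n, g)],
                                  integer(g))
        }
    }
    new("NullSets", idx = out, poolIds = index@snpIds,
        alpha = unname(gwas$alpha), nFallback = as.integer(n_fallback),
        seed = as.integer(seed))
}

#' SNP ids of one null set
#'
#' @param sets a \code{\link{NullSets}} object.
#' @param i set index.
#' @return character vector of pool SNP ids, ordered as the GWAS loci.
#' @export
nullSetIds <- function(sets, i) sets@poolIds[sets@idx[, i]]

#' Null genetic values from matched sets
#'
#' Applies the genetic-value sum to each null set using its carried-over
#' effect sizes and the pool frequencies, producing one draw from the
#' genome-wide null distribution of the genetic values per set.
#'
#' @param sets a \code{\link{NullSets}} object.
#' @param null_panel the pool \code{\link{FrequencyPanel}} (row order must
#'   match the pool the index was built from).
#' @return M x n_sets matrix of null genetic values.
#' @export
nullGeneticValues <- function(sets, null_panel) {
    P <- freqMatrix(null_panel)
    if (nrow(P) != length(sets@poolIds))
        stop("pool panel does not match the sampled sets")
    a <- sets@alpha
    n_sets <- ncol(sets@idx)
    out <- matrix(0, nrow = ncol(P), ncol = n_sets,
                  dimnames = list(colnames(P), NULL))
    for (j in seq_len(n_sets))
        out[, j] <- 2 * colSums(a * P[sets@idx[, j], , drop = FALSE])
    out
}

#' Ascertainment-frequency proxy for an admixed GWAS population
#'
#' When the GWAS ascertainment population is admixed between two reference
#' populations, its genome-wide allele frequencies are approximated by the
#' admixture-weighted mean \eqn{w p_a + (1-w) p_b}, folded to a minor
#' allele frequency, for use in contingency-table bin assignment.
#'
#' @param panel a \code{\link{FrequencyPanel}} containing both references.
#' @param pop_a,pop_b reference population ids.
#' @param w admixture proportion of \code{pop_a}, in [0, 1].
#' @return named numeric vector of per-SNP proxy MAFs.
#' @export
admixedAscertainmentFreq <- function(panel, pop_a, pop_b, w) {
    if (w < 0 || w > 1) stop("w must lie in [0, 1]")
    pops <- populationIds(panel)
    if (!all(c(pop_a, pop_b) %in% pops))
        stop("population(s) missing from the panel: ",
             paste(setdiff(c(pop_a, pop_b), pops), collapse = ", "))
    f <- freqMatrix(panel)
    proxy <- w * f[, pop_a] + (1 - w) * f[, pop_b]
    stats::setNames(pmin(proxy, 1 - proxy), rownames(f))
}
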