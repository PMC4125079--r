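## Tabular I/O. All files are tab-separated with a header row.

.read_tsv <- function(path) {
    utils::read.delim(path, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE, check.names = FALSE)
}

#' Read a GWAS effect table
#'
#' Tab-separated with header columns \code{snp_id}, \code{effect_allele},
#' \code{alpha}, \code{maf}, \code{imputed}, \code{b_value} (and optionally
#' \code{other_allele}). Rows with negative \code{alpha} are flipped to the
#' trait-increasing orientation; see \code{\link{EffectTable}}.
#'
#' @param path file path.
#' @return an \code{\link{EffectTable}}.
#' @export
readEffectTable <- function(path) {
    df <- .read_tsv(path)
    missing <- setdiff(.ET_REQUIRED, colnames(df))
    if (length(missing))
        stop("effect table file '", path, "' is missing column(s): ",
             paste(missing, collapse = ", "))
    df$imputed <- as.logical(df$imputed)
    EffectTable(df)
}

#' Read a null-pool metadata table
#'
#' Same dialect as the effect table minus the effect size: columns
#' \code{snp_id}, \code{maf}, \code{imputed}, \code{b_value}.
#'
#' @param path file path.
#' @return a \code{DataFrame} of pool SNP metadata.
#' @export
readPoolMetadata <- function(path) {
    df <- .read_tsv(path)
    missing <- setdiff(c("snp_id", "maf", "imputed", "b_value"), colnames(df))
    if (length(missing))
        stop("pool metadata file '", path, "' is missing column(s): ",
             paste(missing, collapse = ", "))
    df$imputed <- as.logical(df$imputed)
    DataFrame(df, row.names = df$snp_id)
}

#' Read a frequency panel
#'
#' The frequency file is a tab-separated matrix whose first column is
#' \code{snp_id} and whose remaining columns are one population each; the
#' companion chromosome-count file has columns \code{population_id} and
#' \code{chromosomes}. When an \code{EffectTable} is supplied, frequencies
#' are oriented to the (trait-increasing) effect allele by complementing
#' flipped rows, the panel is restricted to the effect-table loci in effect
#' order, and loci absent from the panel are dropped with a warning; the
#' dropped count is stored in \code{metadata(panel)$n_dropped}.
#'
#' @param path frequency matrix file path.
#' @param chrom_path chromosome-count file path.
#' @param effects optional \code{\link{EffectTable}} for orientation.
#' @return a \code{\link{FrequencyPanel}}.
#' @export
readFrequencyPanel <- function(path, chrom_path, effects = NULL) {
    df <- .read_tsv(path)
    if (colnames(df)[1] != "snp_id")
        stop("first column of '", path, "' must be snp_id")
    freq <- as.matrix(df[, -1, drop = FALSE])
    rownames(freq) <- as.character(df$snp_id)
    if (any(!is.finite(freq)) || any(freq < 0 | freq > 1))
        stop("frequencies must be finite and within [0, 1]")
    ch <- .read_tsv(chrom_path)
    missing <- setdiff(c("population_id", "chromosomes"), colnames(ch))
    if (length(missing))
        stop("chromosome-count file is missing column(s): ",
             paste(missing, collapse = ", "))
    counts <- stats::setNames(as.integer(ch$chromosomes),
                              as.character(ch$population_id))
    if (!all(colnames(freq) %in% names(counts)))
        stop("chromosome counts missing for population(s): ",
             paste(setdiff(colnames(freq), names(counts)), collapse = ", "))
    panel <- FrequencyPanel(freq, counts[colnames(freq)])
    if (!is.null(effects))
        panel <- orientPanel(panel, effects)
    panel
}

#' Orient and align a frequency panel to an effect table
#'
#' Complements frequencies at loci whose effect allele was flipped during
#' effect-table orientation, restricts the panel to the effect-table loci
#' (in their order), and records the number of effect-table loci absent from
#' the panel in \code{metadata()$n_dropped}.
#'
#' @param panel a \code{\link{FrequencyPanel}}.
#' @param effects an \code{\link{EffectTable}}.
#' @return the oriented, aligned \code{FrequencyPanel}.
#' @export
orientPanel <- function(panel, effects) {
    ids <- snpIds(effects)
    present <- ids %in% rownames(panel)
    n_dropped <- sum(!present)
    if (n_dropped > 0L)
        warning(n_dropped, " effect-table loci absent from the panel were ",
                "dropped")
    keep <- ids[present]
    freq <- freqMatrix(panel)[keep, , drop = FALSE]
    flip <- effects$flipped[present]
    if (any(flip))
        freq[flip, ] <- 1 - freq[flip, ]
    out <- FrequencyPanel(freq, chromCounts(panel))
    metadata(out)$n_dropped <- n_dropped
    out
}

#' Read a per-population environmental variable
#'
#' Tab-separated with columns \code{population_id} and \code{value}. If a
#' panel is given, the vector is reordered to the panel's populations and an
#' error is raised when any are missing.
#'
#' @param path file path.
#' @param panel optional companion \code{\link{FrequencyPanel}}.
#' @return an \code{\link{EnvVector}}.
#' @export
readEnvVector <- function(path, panel = NULL) {
    df <- .read_tsv(path)
    missing <- setdiff(c("population_id", "value"), colnames(df))
    if (length(missing))
        stop("environment file is missing column(s): ",
             paste(missing, collapse = ", "))
    v <- stats::setNames(as.numeric(df$value), as.character(df$population_id))
    if (!is.null(panel)) {
        absent <- setdiff(populationIds(panel), names(v))
        if (length(absent))
            stop("environment file lacks population(s): ",
                 paste(absent, collapse = ", "))
        v <- v[populationIds(panel)]
    }
    EnvVector(v)
}

#' Write a frequency panel
#'
#' Writes the frequency matrix and the chromosome counts as two
#' tab-separated files in the dialect \code{\link{readFrequencyPanel}}
#' expects. Frequencies are written at full precision so a write/read
#' round trip is bit exact.
#'
#' @param panel a \code{\link{FrequencyPanel}}.
#' @param path frequency matrix output path.
#' @param chrom_path chromosome-count output path.
#' @export
writeFrequencyPanel <- function(panel, path, chrom_path) {
    f <- freqMatrix(panel)
    df <- data.frame(snp_id = rownames(f),
                     as.data.frame(format(f, digits = 17, trim = TRUE)),
                     check.names = FALSE)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    ch <- data.frame(population_id = populationIds(panel),
                     chromosomes = unname(chromCounts(panel)))
    utils::write.table(ch, chrom_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(NULL)
}

#' Write an effect table
#'
#' @param effects an \code{\link{EffectTable}}.
#' @param path output path.
#' @export
writeEffectTable <- function(effects, path) {
    utils::write.table(as.data.frame(effects), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    invisible(NULL)
}

#' Write an environmental vector
#'
#' @param env an \code{\link{EnvVector}}.
#' @param path output path.
#' @export
writeEnvVector <- function(env, path) {
    utils::write.table(
        data.frame(population_id = populationIds(env),
                   value = unname(envValues(env))),
        path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(NULL)
}

#' Write a test or conditional report
#'
#' Writes one tab-separated summary row per statistic (statistic name,
#' observed value, empirical p-value, number of null draws, seed for a
#' \code{TestReport}; group, conditional mean and variance, Z and p for a
#' \code{ConditionalReport}). For a \code{TestReport}, the null draws can be
#' written to a sidecar file.
#'
#' @param report a \code{\link{TestReport}}, \code{\link{ConditionalReport}},
#'   or a list of either.
#' @param path output path.
#' @param sidecar optional path receiving one null draw per line.
#' @export
writeReport <- function(report, path, sidecar = NULL) {
    if (!is.list(report)) report <- list(report)
    if (all(vapply(report, is, logical(1), class2 = "TestReport"))) {
        df <- do.call(rbind, lapply(report, function(r)
            data.frame(statistic = r@statistic, observed = r@observed,
                       p_empirical = r@pEmpirical,
                       n_null = length(r@nullDraws), tail = r@tail,
                       seed = r@seed)))
        if (!is.null(sidecar)) {
            draws <- do.call(cbind, lapply(report, function(r) r@nullDraws))
            colnames(draws) <- vapply(report, function(r) r@statistic,
                                      character(1))
            utils::write.table(draws, sidecar, sep = "\t", quote = FALSE,
                               row.names = FALSE)
        }
    } else if (all(vapply(report, is, logical(1),
                          class2 = "ConditionalReport"))) {
        df <- do.call(rbind, lapply(report, function(r)
            data.frame(group = paste(r@group1, collapse = ","),
                       cond_mean = r@condMean, cond_var = r@condVar,
                       z = r@z, p_two_sided = r@pTwoSided)))
    } else {
        stop("report must be a TestReport or ConditionalReport (or a list ",
             "of one kind)")
    }
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(NULL)
}

#' Read a run configuration
#'
#' YAML file with fields \code{n_null_sets}, \code{n_cov_snps},
#' \code{rng_seed}, \code{dropped_population} and \code{tails}; missing
#' fields take the documented defaults.
#'
#' @param path YAML file path.
#' @return a named list.
#' @export
readRunConfig <- function(path) {
    if (!requireNamespace("yaml", quietly = TRUE))
        stop("the 'yaml' package is required to read run configurations")
    cfg <- yaml::read_yaml(path)
    defaults <- list(n_null_sets = 1000L, n_cov_snps = 20000L,
                     rng_seed = 1L, dropped_population = "last",
                     tails = list(QX = "upper", beta = "two-sided",
                                  r2 = "upper", rho = "two-sided"))
    out <- utils::modifyList(defaults, cfg)
    if (out$n_null_sets < 1L) stop("n_null_sets must be >= 1")
    out
}
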