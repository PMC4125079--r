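## Shared fixtures, built once per test run and cached.

.cache <- new.env(parent = emptyenv())

## Small dataset for unit tests: 6 populations, 25 loci, 3000-SNP pool.
tiny_spec <- function(...) {
    args <- utils::modifyList(
        list(M = 6L, Lgwas = 25L, Kpool = 3000L, chromosomes = 50L,
             driftF = 0.05, seed = 42L),
        list(...))
    do.call(fixtureSpec, args)
}

tiny_dataset <- function() {
    if (is.null(.cache$tiny)) .cache$tiny <- makeDataset(tiny_spec())
    .cache$tiny
}

tiny_model <- function() {
    if (is.null(.cache$tiny_model))
        .cache$tiny_model <- fitMatchedModel(tiny_dataset(),
                                             n_cov_sets = 80L, seed = 2L)
    .cache$tiny_model
}

## Study-scale dataset for the end-to-end statistical checks: 52 populations,
## 161 loci, 20,000-SNP pool (the default fixture conditions).
study_dataset <- function() {
    if (is.null(.cache$study))
        .cache$study <- makeDataset(fixtureSpec(), seed = 5L)
    .cache$study
}

study_model <- function() {
    if (is.null(.cache$study_model))
        .cache$study_model <- fitMatchedModel(study_dataset(),
                                              n_cov_sets = 125L, seed = 6L)
    .cache$study_model
}

## Shared 1000-replicate neutral calibration at the study scale.
study_calibration <- function() {
    if (is.null(.cache$cal))
        .cache$cal <- suppressWarnings(
            calibrationExperiment(fixtureSpec(), n_replicates = 1000L,
                                  seed = 11L))
    .cache$cal
}

## A hand-buildable effect table.
make_effects <- function(alpha, maf = 0.25, imputed = FALSE, b = 0.5,
                         ids = sprintf("rs%d", seq_along(alpha))) {
    EffectTable(data.frame(
        snp_id = ids, effect_allele = "A", other_allele = "G",
        alpha = alpha, maf = maf, imputed = imputed, b_value = b))
}

## A frequency panel from a bare matrix with default ids.
make_panel <- function(freq, chromosomes = 50L,
                       ids = sprintf("rs%d", seq_len(nrow(freq))),
                       pops = sprintf("P%d", seq_len(ncol(freq)))) {
    dimnames(freq) <- list(ids, pops)
    FrequencyPanel(freq, chromosomes)
}

## A DriftModel with known F and scale, for closed-form checks.
make_model <- function(F_mat, va = 1, pops = NULL) {
    M <- nrow(F_mat) + 1L
    if (is.null(pops)) pops <- sprintf("P%d", seq_len(M))
    new("DriftModel", populationIds = pops, dropped = pops[M],
        Tproj = centerProjection(M), Fmat = F_mat, cholC = t(chol(F_mat)),
        vaScale = va, nNullSnps = 0L)
}
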