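## Shared fixtures, built in code and cached for the session.

.fixtures <- new.env(parent = emptyenv())

tinyCohort <- function() {
  if (is.null(.fixtures$tiny))
    .fixtures$tiny <- simulateCohort(defaultSimulationConfig("tiny"))
  .fixtures$tiny
}

tinyFeatureMatrix <- function() {
  if (is.null(.fixtures$tinyFm))
    .fixtures$tinyFm <- cohortFeatureMatrix(tinyCohort())
  .fixtures$tinyFm
}

deskCohort <- function() {
  if (is.null(.fixtures$desk))
    .fixtures$desk <- simulateCohort(defaultSimulationConfig("desk"))
  .fixtures$desk
}

deskFeatureMatrix <- function() {
  if (is.null(.fixtures$deskFm))
    .fixtures$deskFm <- cohortFeatureMatrix(deskCohort())
  .fixtures$deskFm
}

## Small perceptron settings for test-scale training runs.
testMlpConfig <- function(...) {
  mlpConfig(hiddenLayers = 2, unitsPerLayer = 64, learningRate = 1e-3,
            maxEpochs = 60, earlyStopPatience = 8, ...)
}

## Solver budget used for desk-scale selection runs.
deskSelectionArgs <- list(maxIter = 80, tol = 1e-5)

writeTinyMaf <- function(path,
                         classes = c("Missense_Mutation", "Silent",
                                     "Nonsense_Mutation")) {
  header <- paste("sample", "gene", "chrom", "pos", "ref", "alt",
                  "variant_type", "variant_class", sep = "\t")
  rows <- sprintf("S%d\tG%d\tchr1\t%d\tC\tT\tSNP\t%s",
                  seq_along(classes), seq_along(classes),
                  100 + seq_along(classes), classes)
  writeLines(c(header, rows), path)
  path
}

## A toy two-contig genome for context lookup.
toyGenome <- function() c(c1 = "ACGTA", c2 = "GGGCC")
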