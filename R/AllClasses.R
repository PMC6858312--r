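#' Class definitions
#'
#' Central S4 containers for the somatic-alteration classification pipeline.
#' @import methods
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData rowData
#' @name OncoVote-classes
NULL

## Fixed feature-name constants ------------------------------------------------

.BASES <- c("A", "C", "G", "T")

.RATE_NAMES <- c("snv_indel_per_mb", "mutated_gene_fraction")

## The six pyrimidine-referenced single-base substitution classes, fixed order.
.SPECTRUM_NAMES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

## 96 trinucleotide signature keys "<5'><ref><3'>.<ref>><alt>", ordered
## lexicographically by (5' base, spectrum, 3' base), e.g. "ACA.C>A".
.signatureNames <- function() {
  out <- character(0)
  for (b5 in .BASES) {
    for (sp in .SPECTRUM_NAMES) {
      ref <- substr(sp, 1L, 1L)
      for (b3 in .BASES) {
        out <- c(out, paste0(b5, ref, b3, ".", sp))
      }
    }
  }
  out
}

.SIGNATURE_NAMES <- .signatureNames()

## VariantTable ----------------------------------------------------------------

.VARIANT_COLUMNS <- c("sample_id", "gene", "chrom", "pos", "ref", "alt",
                      "variant_type", "variant_class", "context5", "context3")

#' VariantTable: filtered somatic variant records
#'
#' Holds protein-altering SNV/indel records, one row per variant, in input
#' order. Coordinates are 1-based inclusive (MAF convention). `context5` /
#' `context3` optionally carry the 5' and 3' flanking reference bases used for
#' trinucleotide signature counting (NA when unknown).
#'
#' @slot records data.frame with columns sample_id, gene, chrom, pos, ref,
#'   alt, variant_type (SNP/INS/DEL), variant_class, context5, context3.
#' @export
setClass("VariantTable", representation(records = "data.frame"))

setValidity("VariantTable", function(object) {
  df <- object@records
  missing <- setdiff(.VARIANT_COLUMNS, colnames(df))
  if (length(missing) > 0)
    return(paste("missing record columns:", paste(missing, collapse = ", ")))
  if (nrow(df) == 0) return(TRUE)
  if (!is.numeric(df$pos) || any(df$pos < 1))
    return("pos must be numeric and >= 1")
  if (!all(df$variant_type %in% c("SNP", "INS", "DEL")))
    return("variant_type must be one of SNP, INS, DEL")
  snp <- df$variant_type == "SNP"
  if (any(snp)) {
    ok <- df$ref[snp] %in% c(.BASES, "N") & df$alt[snp] %in% c(.BASES, "N") &
      df$ref[snp] != df$alt[snp]
    if (!all(ok))
      return(sprintf("%d SNP record(s) with invalid or identical ref/alt alleles",
                     sum(!ok)))
  }
  TRUE
})

## FeatureSchema ---------------------------------------------------------------

#' FeatureSchema: ordered five-group feature layout
#'
#' Defines the column layout of the feature matrix: gene-level mutation
#' profiles, the two mutation rates, the six mutation spectra, the 96
#' trinucleotide mutation signatures, and gene-level copy-number columns
#' (prefixed \code{"cnv:"} so names stay globally unique), in that order.
#'
#' @slot mutGenes ordered character vector of mutation-profile genes.
#' @slot cnvGenes ordered character vector of copy-number genes.
#' @slot territoryMb sequenced territory in megabases used as the denominator
#'   of the per-Mb mutation rate.
#' @export
setClass("FeatureSchema",
         representation(mutGenes = "character", cnvGenes = "character",
                        territoryMb = "numeric"))

setValidity("FeatureSchema", function(object) {
  if (length(object@mutGenes) < 1 || length(object@cnvGenes) < 1)
    return("gene lists must be non-empty")
  if (anyDuplicated(object@mutGenes)) return("duplicate mutation-profile gene")
  if (anyDuplicated(object@cnvGenes)) return("duplicate copy-number gene")
  if (length(object@territoryMb) != 1 || object@territoryMb <= 0)
    return("territoryMb must be a single positive number")
  TRUE
})

## FeatureMatrix ---------------------------------------------------------------

#' FeatureMatrix: samples-by-features container
#'
#' A \linkS4class{SummarizedExperiment} whose rows are features (with group
#' membership in \code{rowData()$group}) and whose columns are samples (with
#' the cancer-type label, when known, in \code{colData()$label}), plus the
#' \linkS4class{FeatureSchema} that fixes the feature order.
#' \code{featureValues()} returns the machine-learning orientation
#' (samples in rows).
#' @export
setClass("FeatureMatrix",
         contains = "SummarizedExperiment",
         representation(schema = "FeatureSchema"))

setValidity("FeatureMatrix", function(object) {
  sch <- object@schema
  want <- c(sch@mutGenes, .RATE_NAMES, .SPECTRUM_NAMES, .SIGNATURE_NAMES,
            paste0("cnv:", sch@cnvGenes))
  if (nrow(object) != length(want))
    return(sprintf("matrix has %d feature rows but schema dimension is %d",
                   nrow(object), length(want)))
  if (!identical(rownames(object), want))
    return("feature row names do not match schema order")
  TRUE
})

## SelectionProblem ------------------------------------------------------------

#' SelectionProblem: supervised selection input with scaling state
#'
#' Couples a samples-by-features matrix with class labels and the per-feature
#' standardization statistics learned from those (training) rows. Population
#' (1/n) moments are used; constant features get scale 1 so standardization is
#' always defined. Tree-based selection runs on the raw values; the L1 methods
#' run on the standardized values.
#'
#' @slot X raw samples-by-features numeric matrix.
#' @slot y factor of class labels, one per row of X.
#' @slot center,scale per-feature population mean and standard deviation.
#' @slot sampleIds sample identifiers, used by the leakage guard.
#' @export
setClass("SelectionProblem",
         representation(X = "matrix", y = "factor", center = "numeric",
                        scale = "numeric", sampleIds = "character"))

setValidity("SelectionProblem", function(object) {
  if (nrow(object@X) != length(object@y))
    return("X rows and y length differ")
  if (nlevels(droplevels(object@y)) < 2)
    return("at least 2 classes are required")
  if (anyNA(object@X)) return("X contains missing values")
  if (length(object@center) != ncol(object@X) ||
      length(object@scale) != ncol(object@X))
    return("center/scale length must equal ncol(X)")
  TRUE
})

## SelectionResult -------------------------------------------------------------

#' SelectionResult: outcome of a supervised feature-selection run
#'
#' @slot method one of "extra_trees", "lasso", "lsvc".
#' @slot selected ordered integer indices of the selected features (1-based).
#' @slot scores per-feature score: impurity importance (extra_trees) or the
#'   maximum absolute coefficient across classes (lasso/lsvc).
#' @slot regularizationUsed the regularization value the selection was made at
#'   (NA for extra_trees).
#' @slot coefficients optional classes-by-features coefficient matrix.
#' @slot intercepts per-class intercepts (length 0 when not applicable).
#' @slot featureNames feature names aligned with scores.
#' @slot path data.frame (regularization, n_selected) recording the probes of
#'   the select-to-k controller, in probe order.
#' @export
setClass("SelectionResult",
         representation(method = "character", selected = "integer",
                        scores = "numeric", regularizationUsed = "numeric",
                        coefficients = "ANY", intercepts = "numeric",
                        featureNames = "character", path = "data.frame"))

setValidity("SelectionResult", function(object) {
  d <- length(object@scores)
  if (length(object@selected) > 0 &&
      (min(object@selected) < 1 || max(object@selected) > d))
    return("selected indices out of range")
  if (!object@method %in% c("extra_trees", "lasso", "lsvc"))
    return("unknown method")
  TRUE
})

## Classifiers -----------------------------------------------------------------

#' ProbabilisticClassifier: uniform probabilistic model contract
#'
#' Wraps one of the four base classifiers (multilayer perceptron, random
#' forest, one-vs-rest linear SVM, k-nearest neighbours) behind a single
#' contract: \code{predictProba()} returns one row per sample of non-negative
#' per-class probabilities summing to 1, with columns in the class order fixed
#' at fit time.
#'
#' @slot kind "mlp", "random_forest", "ovr_svm" or "knn".
#' @slot classLevels class label order fixed at fit time.
#' @slot nFeatures number of input features the model was fitted on.
#' @slot fit kind-specific fitted state.
#' @export
setClass("ProbabilisticClassifier",
         representation(kind = "character", classLevels = "character",
                        nFeatures = "integer", fit = "list"))

setValidity("ProbabilisticClassifier", function(object) {
  if (!object@kind %in% c("mlp", "random_forest", "ovr_svm", "knn"))
    return("unknown classifier kind")
  if (length(object@classLevels) < 2) return("need >= 2 classes")
  TRUE
})

#' EnsembleModel: two-member soft-voting ensemble
#'
#' Averages the per-class probability rows of its two members (by default a
#' multilayer perceptron and a random forest) and predicts the argmax; ties
#' resolve to the lowest class index.
#' @slot memberA,memberB fitted \linkS4class{ProbabilisticClassifier} objects
#'   sharing class order and feature count.
#' @export
setClass("EnsembleModel",
         representation(memberA = "ProbabilisticClassifier",
                        memberB = "ProbabilisticClassifier"))

setValidity("EnsembleModel", function(object) {
  if (!identical(object@memberA@classLevels, object@memberB@classLevels))
    return("members disagree on class order")
  if (object@memberA@nFeatures != object@memberB@nFeatures)
    return("members disagree on feature count")
  TRUE
})

## Evaluation containers -------------------------------------------------------

#' FoldPlan: seeded stratified fold assignment
#'
#' @slot folds list of disjoint integer index vectors partitioning the samples.
#' @slot seed the seed the plan was drawn with.
#' @export
setClass("FoldPlan", representation(folds = "list", seed = "integer"))

setValidity("FoldPlan", function(object) {
  idx <- unlist(object@folds)
  if (anyDuplicated(idx)) return("folds overlap")
  TRUE
})

#' CVReport: nested cross-validation outcome
#'
#' @slot predictions data.frame with one row per sample: sample_id, fold,
#'   truth, and one prediction column per recorded model (pred_mlp, pred_rf,
#'   pred_ensemble, optionally pred_ovr_svm, pred_knn).
#' @slot foldChoices data.frame with the (selector method, k, regularization)
#'   chosen in each outer fold.
#' @slot metrics list with perClass data.frame, overall accuracy and macro
#'   averages, computed from the stored predictions.
#' @slot meta run metadata (seed, configs, fold plan).
#' @export
setClass("CVReport",
         representation(predictions = "data.frame", foldChoices = "data.frame",
                        metrics = "list", meta = "list"))

setValidity("CVReport", function(object) {
  if (anyDuplicated(object@predictions$sample_id))
    return("a sample was predicted more than once")
  TRUE
})
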