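#' @include AllClasses.R AllGenerics.R
NULL

## VariantTable ---------------------------------------------------------------

#' @describeIn VariantTable-class variant records as a data.frame.
#' @param x,object a VariantTable.
#' @aliases variantRecords
#' @export
setMethod("variantRecords", "VariantTable", function(x) x@records)

#' @describeIn VariantTable-class distinct sample identifiers, in order of
#'   first appearance.
#' @export
setMethod("sampleIds", "VariantTable", function(x) unique(x@records$sample_id))

#' @describeIn VariantTable-class distinct gene symbols, in order of first
#'   appearance.
#' @export
setMethod("geneSymbols", "VariantTable", function(x) unique(x@records$gene))

setMethod("show", "VariantTable", function(object) {
  df <- object@records
  cat(sprintf("VariantTable: %d record(s), %d sample(s), %d gene(s)\n",
              nrow(df), length(unique(df$sample_id)),
              length(unique(df$gene))))
  if (nrow(df) > 0) {
    tt <- table(df$variant_type)
    cat("  variant types:",
        paste(sprintf("%s=%d", names(tt), tt), collapse = ", "), "\n")
    cat(sprintf("  with trinucleotide context: %d\n",
                sum(!is.na(df$context5) & !is.na(df$context3))))
  }
})

## FeatureSchema --------------------------------------------------------------

#' @describeIn FeatureSchema-class all feature names in block order
#'   [profile | rates | spectra | signatures | scna].
#' @param x,object a FeatureSchema.
#' @export
setMethod("featureNames", "FeatureSchema", function(x) {
  c(x@mutGenes, .RATE_NAMES, .SPECTRUM_NAMES, .SIGNATURE_NAMES,
    paste0("cnv:", x@cnvGenes))
})

#' @describeIn FeatureSchema-class feature-group factor aligned with
#'   \code{featureNames()}, levels profile, rates, spectra, signatures, scna.
#' @export
setMethod("featureGroups", "FeatureSchema", function(x) {
  factor(rep(c("profile", "rates", "spectra", "signatures", "scna"),
             c(length(x@mutGenes), length(.RATE_NAMES),
               length(.SPECTRUM_NAMES), length(.SIGNATURE_NAMES),
               length(x@cnvGenes))),
         levels = c("profile", "rates", "spectra", "signatures", "scna"))
})

#' @describeIn FeatureSchema-class total feature dimension
#'   G_m + 2 + 6 + 96 + G_c.
#' @export
setMethod("nFeatures", "FeatureSchema", function(x) {
  length(x@mutGenes) + length(.RATE_NAMES) + length(.SPECTRUM_NAMES) +
    length(.SIGNATURE_NAMES) + length(x@cnvGenes)
})

setMethod("show", "FeatureSchema", function(object) {
  cat(sprintf(paste0("FeatureSchema: %d features ",
                     "(%d profile + 2 rates + 6 spectra + 96 signatures + %d scna), ",
                     "territory %.1f Mb\n"),
              nFeatures(object), length(object@mutGenes),
              length(object@cnvGenes), object@territoryMb))
})

## FeatureMatrix --------------------------------------------------------------

#' @describeIn FeatureMatrix-class the samples-by-features value matrix.
#' @param x,object a FeatureMatrix.
#' @export
setMethod("featureValues", "FeatureMatrix", function(x) {
  t(SummarizedExperiment::assay(x, "features"))
})

#' @describeIn FeatureMatrix-class sample identifiers (matrix row order).
#' @export
setMethod("sampleIds", "FeatureMatrix", function(x) colnames(x))

#' @describeIn FeatureMatrix-class feature names in schema order.
#' @export
setMethod("featureNames", "FeatureMatrix", function(x) rownames(x))

#' @describeIn FeatureMatrix-class feature-group factor.
#' @export
setMethod("featureGroups", "FeatureMatrix", function(x) featureGroups(x@schema))

#' @describeIn FeatureMatrix-class number of feature columns.
#' @export
setMethod("nFeatures", "FeatureMatrix", function(x) nrow(x))

#' @describeIn FeatureMatrix-class the FeatureSchema.
#' @export
setMethod("featureSchema", "FeatureMatrix", function(x) x@schema)

#' @describeIn FeatureMatrix-class per-sample cancer-type labels as a named
#'   factor (NULL when the matrix carries no labels).
#' @export
setMethod("sampleLabels", "FeatureMatrix", function(x) {
  cd <- SummarizedExperiment::colData(x)
  if (!"label" %in% colnames(cd)) return(NULL)
  stats::setNames(factor(cd$label), colnames(x))
})

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix: %d sample(s) x %d feature(s)\n",
              ncol(object), nrow(object)))
  show(object@schema)
  lab <- sampleLabels(object)
  if (!is.null(lab))
    cat("  labels:", paste(levels(lab), collapse = ", "), "\n")
})

## SelectionProblem / SelectionResult -----------------------------------------

#' @describeIn SelectionProblem-class sample identifiers.
#' @param x,object a SelectionProblem.
#' @export
setMethod("sampleIds", "SelectionProblem", function(x) x@sampleIds)

setMethod("show", "SelectionProblem", function(object) {
  cat(sprintf("SelectionProblem: %d sample(s) x %d feature(s), %d class(es)\n",
              nrow(object@X), ncol(object@X), nlevels(object@y)))
})

#' @describeIn SelectionResult-class ordered indices of selected features.
#' @param x,object a SelectionResult.
#' @export
setMethod("selectedFeatures", "SelectionResult", function(x) x@selected)

#' @describeIn SelectionResult-class per-feature scores.
#' @export
setMethod("selectionScores", "SelectionResult", function(x) {
  stats::setNames(x@scores, x@featureNames)
})

#' @describeIn SelectionResult-class names of the selected features.
#' @export
setMethod("featureNames", "SelectionResult", function(x) {
  x@featureNames[x@selected]
})

setMethod("show", "SelectionResult", function(object) {
  cat(sprintf("SelectionResult: method=%s, %d of %d feature(s) selected",
              object@method, length(object@selected), length(object@scores)))
  if (!is.na(object@regularizationUsed))
    cat(sprintf(", regularization=%.4g", object@regularizationUsed))
  cat("\n")
})

## Classifiers ----------------------------------------------------------------

#' @describeIn ProbabilisticClassifier-class fixed class order.
#' @param x,object a classifier.
#' @export
setMethod("classLevels", "ProbabilisticClassifier", function(x) x@classLevels)

#' @describeIn EnsembleModel-class shared class order of the members.
#' @export
setMethod("classLevels", "EnsembleModel", function(x) x@memberA@classLevels)

setMethod("show", "ProbabilisticClassifier", function(object) {
  cat(sprintf("ProbabilisticClassifier: kind=%s, %d class(es), %d feature(s)\n",
              object@kind, length(object@classLevels), object@nFeatures))
})

setMethod("show", "EnsembleModel", function(object) {
  cat(sprintf("EnsembleModel: %s + %s soft-voting, %d class(es)\n",
              object@memberA@kind, object@memberB@kind,
              length(classLevels(object))))
})

## FoldPlan / CVReport --------------------------------------------------------

#' @describeIn FoldPlan-class the list of fold index vectors.
#' @param x,object a FoldPlan.
#' @export
setMethod("foldIndices", "FoldPlan", function(x) x@folds)

setMethod("show", "FoldPlan", function(object) {
  cat(sprintf("FoldPlan: %d fold(s), sizes %s\n", length(object@folds),
              paste(lengths(object@folds), collapse = "/")))
})

#' @describeIn CVReport-class per-sample prediction table.
#' @param x,object a CVReport.
#' @export
setMethod("cvPredictions", "CVReport", function(x) x@predictions)

#' @describeIn CVReport-class pooled overall accuracy of a given model column
#'   (default the ensemble), as a percentage.
#' @param model prediction column to score, e.g. "ensemble", "mlp", "rf".
#' @export
setMethod("overallAccuracy", "CVReport", function(x, model = "ensemble") {
  col <- paste0("pred_", model)
  stopifnot(col %in% colnames(x@predictions))
  100 * mean(x@predictions[[col]] == x@predictions$truth)
})

#' @describeIn CVReport-class per-class precision/recall/F1/accuracy table.
#' @export
setMethod("perClassMetrics", "CVReport", function(x) x@metrics$perClass)

setMethod("show", "CVReport", function(object) {
  cat(sprintf("CVReport: %d sample(s), %d outer fold(s)\n",
              nrow(object@predictions), length(unique(object@predictions$fold))))
  for (m in intersect(c("mlp", "rf", "ensemble"),
                      sub("^pred_", "", grep("^pred_",
                                             colnames(object@predictions),
                                             value = TRUE)))) {
    cat(sprintf("  %-9s accuracy: %6.2f%%\n", m, overallAccuracy(object, m)))
  }
})
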