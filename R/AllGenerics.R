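#' @importFrom S4Vectors metadata metadata<-
NULL

#' Accessors for bidirMR classes
#'
#' Small generics giving read access to the slots of the package's S4
#' objects; user code should prefer these over \code{@}.
#'
#' @param x,object a bidirMR S4 object.
#' @param ... unused.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("traitId", function(x) standardGeneric("traitId"))
#' @rdname accessors
#' @export
setGeneric("traitType", function(x) standardGeneric("traitType"))
#' @rdname accessors
#' @export
setGeneric("snps", function(x) standardGeneric("snps"))
#' @rdname accessors
#' @export
setGeneric("nSnps", function(x) standardGeneric("nSnps"))
#' @rdname accessors
#' @export
setGeneric("instruments", function(x) standardGeneric("instruments"))
#' @rdname accessors
#' @export
setGeneric("selectionLog", function(x) standardGeneric("selectionLog"))
#' @rdname accessors
#' @export
setGeneric("harmonizedPairs", function(x) standardGeneric("harmonizedPairs"))
#' @rdname accessors
#' @export
setGeneric("dropLog", function(x) standardGeneric("dropLog"))
#' @rdname accessors
#' @export
setGeneric("mrBeta", function(x) standardGeneric("mrBeta"))
#' @rdname accessors
#' @export
setGeneric("mrSe", function(x) standardGeneric("mrSe"))
#' @rdname accessors
#' @export
setGeneric("mrPval", function(x) standardGeneric("mrPval"))
#' @rdname accessors
#' @export
setGeneric("confInt", function(x) standardGeneric("confInt"))
#' @rdname accessors
#' @export
setGeneric("outliers", function(x) standardGeneric("outliers"))
#' @rdname accessors
#' @export
setGeneric("globalPval", function(x) standardGeneric("globalPval"))

#' Pairwise LD lookup
#'
#' r-squared between one index variant and a vector of other variants,
#' computed from dosages (squared Pearson correlation) or looked up in the
#' precomputed map. Unknown pairs in a precomputed map return \code{NA};
#' \code{r2(ld, a, a)} is exactly 1.
#'
#' @param ld an \code{\link{LdReference}}.
#' @param a single rsid; @param b character vector of rsids.
#' @return numeric vector of r-squared values, one per element of \code{b}.
#' @export
setGeneric("ldR2", function(ld, a, b) standardGeneric("ldR2"))

#' @rdname ldR2
#' @param rsids character vector.
#' @return \code{hasRsid}: logical vector, whether each rsid is known.
#' @export
setGeneric("hasRsid", function(ld, rsids) standardGeneric("hasRsid"))

setMethod("traitId", "SumstatsTable", function(x) x@traitId)
setMethod("traitType", "SumstatsTable", function(x) x@traitType)
setMethod("snps", "SumstatsTable", function(x) x@snps)
setMethod("nSnps", "SumstatsTable", function(x) nrow(x@snps))

setMethod("instruments", "InstrumentSet", function(x) x@instruments)
setMethod("selectionLog", "InstrumentSet", function(x) x@selectionLog)
setMethod("nSnps", "InstrumentSet", function(x) nrow(x@instruments))

setMethod("harmonizedPairs", "HarmonizedSet", function(x) x@pairs)
setMethod("dropLog", "HarmonizedSet", function(x) x@dropLog)
setMethod("nSnps", "HarmonizedSet", function(x) nrow(x@pairs))

setMethod("mrBeta", "MrResult", function(x) x@beta)
setMethod("mrSe", "MrResult", function(x) x@se)
setMethod("mrPval", "MrResult", function(x) x@pval)
setMethod("confInt", "MrResult", function(x) c(x@ciLow, x@ciHigh))

setMethod("outliers", "PressoResult", function(x) x@outliers)
setMethod("globalPval", "PressoResult", function(x) x@globalPval)

setMethod("show", "SumstatsTable", function(object) {
  cat(sprintf("SumstatsTable '%s' (%s, %s): %d variants\n",
              object@traitId, object@traitType, object@ancestry,
              nrow(object@snps)))
  if (nrow(object@snps)) {
    cat(sprintf("  min p = %.3g; %d with missing eaf\n",
                min(object@snps$pval), sum(is.na(object@snps$eaf))))
  }
})

setMethod("show", "LdReference", function(object) {
  kind <- if (length(object@dosages)) {
    sprintf("dosage panel, %d samples", nrow(object@dosages))
  } else {
    sprintf("precomputed map, %d pairs", length(object@r2map))
  }
  cat(sprintf("LdReference (%s) over %d variants\n", kind,
              length(object@rsids)))
})

setMethod("show", "InstrumentSet", function(object) {
  cat(sprintf("InstrumentSet for '%s': %d instruments\n",
              object@exposureId, nrow(object@instruments)))
  log <- object@selectionLog
  cat("  stages:", paste(sprintf("%s=%d", names(log), log), collapse = " "),
      "\n")
})

setMethod("show", "HarmonizedSet", function(object) {
  cat(sprintf("HarmonizedSet %s -> %s: %d aligned variants, %d dropped\n",
              object@exposureId, object@outcomeId, nrow(object@pairs),
              nrow(object@dropLog)))
  if (nrow(object@dropLog)) {
    tab <- table(object@dropLog$reason)
    cat("  drops:", paste(sprintf("%s=%d", names(tab), tab),
                          collapse = " "), "\n")
  }
})

setMethod("show", "MrResult", function(object) {
  unit <- if (object@effectScale == "or") "OR" else "beta"
  model <- if (!is.na(object@ivwModel)) sprintf(" [%s]", object@ivwModel)
  else ""
  cat(sprintf("MrResult %s%s (k=%d): %s = %.4g (95%% CI %.4g, %.4g), p = %.3g\n",
              object@method, model, object@nSnp, unit, object@beta,
              object@ciLow, object@ciHigh, object@pval))
})

setMethod("show", "Diagnostics", function(object) {
  cat(sprintf("Diagnostics: Q = %.4g (df %s, p = %.3g); Egger intercept = %.4g (p = %.3g)\n",
              object@cochranQ, format(object@qDf), object@qPval,
              object@eggerIntercept, object@interceptPval))
})

setMethod("show", "PressoResult", function(object) {
  cat(sprintf("PressoResult: RSS = %.4g, global p = %.4g (%d sims), %d outlier(s)\n",
              object@rssObs, object@globalPval, object@nSim,
              length(object@outliers)))
})

setMethod("show", "PairAnalysis", function(object) {
  cat(sprintf("PairAnalysis [%s] %s -> %s: %s\n", object@direction,
              object@exposureId, object@outcomeId, object@status))
  if (!is.null(object@results[["ivw"]])) {
    show(object@results[["ivw"]])
    cat(sprintf("  significant at p < %.4g: %s\n", object@threshold,
                object@significant))
  }
})
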