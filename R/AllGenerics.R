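#' @rdname GermlineSet
#' @param x a `GermlineSet`.
#' @export
setGeneric("germlineIds", function(x) standardGeneric("germlineIds"))

#' @rdname GermlineSet
#' @export
setMethod("germlineIds", "GermlineSet", function(x) names(x@sequences))

#' Germline sequence / labels accessors
#'
#' @param x a [GermlineSet-class].
#' @param id germline identifier.
#' @return `glSequence`: the amino-acid sequence as a character scalar;
#'   `glLabels`: the per-residue Kabat-Chothia labels.
#' @export
setGeneric("glSequence", function(x, id) standardGeneric("glSequence"))

#' @rdname glSequence
#' @export
setMethod("glSequence", "GermlineSet", function(x, id) {
  if (!id %in% germlineIds(x))
    stop(sprintf("unknown germline id '%s'", id), call. = FALSE)
  as.character(x@sequences[[id]])
})

#' @rdname glSequence
#' @export
setGeneric("glLabels", function(x, id) standardGeneric("glLabels"))

#' @rdname glSequence
#' @export
setMethod("glLabels", "GermlineSet", function(x, id) {
  if (!id %in% germlineIds(x))
    stop(sprintf("unknown germline id '%s'", id), call. = FALSE)
  x@kcLabels[[id]]
})

#' ContactMap accessors
#'
#' @param x a [ContactMap-class].
#' @return `monomericPairs`/`dimericPairs`: two-column integer matrices of
#'   scheme-position pairs; `contactThreshold`: the cutoff in angstroms.
#' @export
setGeneric("monomericPairs", function(x) standardGeneric("monomericPairs"))

#' @rdname monomericPairs
#' @export
setMethod("monomericPairs", "ContactMap", function(x) x@monomeric)

#' @rdname monomericPairs
#' @export
setGeneric("dimericPairs", function(x) standardGeneric("dimericPairs"))

#' @rdname monomericPairs
#' @export
setMethod("dimericPairs", "ContactMap", function(x) x@dimeric)

#' @rdname monomericPairs
#' @export
setGeneric("contactThreshold", function(x) standardGeneric("contactThreshold"))

#' @rdname monomericPairs
#' @export
setMethod("contactThreshold", "ContactMap", function(x) x@threshold)

#' SMutExperiment accessors
#'
#' @param x a [SMutExperiment-class].
#' @return `tokens`: the positions-by-sequences character token matrix;
#'   `nSM`: named integer vector of somatic-mutation counts per sequence;
#'   `toxLabels`: named character vector of tox/nox/unknown labels;
#'   `positionUniverse`: data.frame of `position` and `kc_label`.
#' @export
setGeneric("tokens", function(x) standardGeneric("tokens"))

#' @rdname tokens
#' @export
setMethod("tokens", "SMutExperiment", function(x) assay(x, "tokens"))

#' @rdname tokens
#' @export
setGeneric("nSM", function(x) standardGeneric("nSM"))

#' @rdname tokens
#' @export
setMethod("nSM", "SMutExperiment",
          function(x) setNames(colData(x)$n_sm, colnames(x)))

#' @rdname tokens
#' @export
setGeneric("toxLabels", function(x) standardGeneric("toxLabels"))

#' @rdname tokens
#' @export
setMethod("toxLabels", "SMutExperiment",
          function(x) setNames(as.character(colData(x)$label), colnames(x)))

#' @rdname tokens
#' @export
setMethod("toxLabels", "FeatureSet",
          function(x) setNames(as.character(colData(x)$label), colnames(x)))

#' @rdname tokens
#' @export
setGeneric("positionUniverse", function(x) standardGeneric("positionUniverse"))

#' @rdname tokens
#' @export
setMethod("positionUniverse", "SMutExperiment", function(x) {
  rd <- rowData(x)
  data.frame(position = rd$position, kc_label = rd$kc_label)
})

#' FeatureSet accessors
#'
#' @param x a [FeatureSet-class].
#' @return `featureValues`: features-by-sequences character matrix;
#'   `featureInfo`: data.frame of feature family, name and positions.
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname featureValues
#' @export
setMethod("featureValues", "FeatureSet", function(x) assay(x, "values"))

#' @rdname featureValues
#' @export
setGeneric("featureInfo", function(x) standardGeneric("featureInfo"))

#' @rdname featureValues
#' @export
setMethod("featureInfo", "FeatureSet",
          function(x) as.data.frame(rowData(x)))
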