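#' Accessor generics
#'
#' Small accessor layer over the package's S4 containers, so downstream code
#' never touches slots directly.
#'
#' @param x an object of the documented class.
#' @name accessors
NULL

#' @describeIn accessors per-cell cluster labels of a [CellMatrix].
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))

#' @describeIn accessors dataset tag of a [CellMatrix].
#' @export
setGeneric("datasetTag", function(x) standardGeneric("datasetTag"))

#' @describeIn accessors named gene -> category vector of a [GeneCatalog].
#' @export
setGeneric("geneCategory", function(x) standardGeneric("geneCategory"))

#' @describeIn accessors transcription-factor gene ids.
#' @export
setGeneric("tfGenes", function(x) standardGeneric("tfGenes"))

#' @describeIn accessors effector gene ids.
#' @export
setGeneric("effectorGenes", function(x) standardGeneric("effectorGenes"))

#' @describeIn accessors RNA-binding-protein gene ids.
#' @export
setGeneric("rbpGenes", function(x) standardGeneric("rbpGenes"))

#' @describeIn accessors cluster x gene mean matrix of a [ClusterMeanMatrix].
#' @export
setGeneric("profileMatrix", function(x) standardGeneric("profileMatrix"))

#' @describeIn accessors per-cluster metadata of a [ClusterMeanMatrix].
#' @export
setGeneric("clusterMeta", function(x) standardGeneric("clusterMeta"))

#' @describeIn accessors symmetric matrix of a [PairwiseDistance].
#' @export
setGeneric("distanceMatrix", function(x) standardGeneric("distanceMatrix"))

#' @describeIn accessors gene-set tag of a distance or call object.
#' @export
setGeneric("geneSetTag", function(x) standardGeneric("geneSetTag"))

#' @describeIn accessors per-pair call table of a [SimilarityCalls].
#' @export
setGeneric("callTable", function(x) standardGeneric("callTable"))

#' @describeIn accessors per-pair pattern table of a [PatternAssignment].
#' @export
setGeneric("patternTable", function(x) standardGeneric("patternTable"))

#' @describeIn accessors provenance of a [PatternAssignment].
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @describeIn accessors planted pair table of a [SyntheticTruth].
#' @export
setGeneric("plantedPairs", function(x) standardGeneric("plantedPairs"))

#' Write an analysis result to disk
#'
#' One generic covers every result the package produces: distance matrices and
#' binary marking matrices as square TSV, dendrograms as newick, pattern
#' assignments as JSON (plus a TSV sidecar), plain tables as TSV.
#'
#' @param object the result to write.
#' @param path output file path.
#' @param ... method-specific options.
#' @return invisibly, `path`.
#' @export
setGeneric("writeResults", function(object, path, ...) standardGeneric("writeResults"))
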