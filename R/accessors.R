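#' Accessors for fitted reconstructions and synthetic tissues
#'
#' `cellEstimates()` returns the per-cell table (id, x, y, z, R) of a fit;
#' `lossTrace()` the per-iteration swarm-best loss and penalty components;
#' `penaltyBreakdown()` the [PenaltyBreakdown-class] of the returned
#' solution; `swarmConfig4Fit()` the configuration used. For a
#' [SyntheticTissue-class], `truthCells()` returns the ground-truth packing,
#' `observations()` the derived 2D nucleus table and `tissueParams()` the
#' generator settings.
#'
#' @param object a [CellDepthFit-class] or [SyntheticTissue-class]
#' @return a data.frame, list or S4 object as described above
#' @name accessors
#' @examples
#' tis <- generateTissue(nCells = 5, seed = 1)
#' head(truthCells(tis))
#' observations(tis)$r_nuc
NULL

#' @rdname accessors
#' @export
setGeneric("cellEstimates", function(object) standardGeneric("cellEstimates"))
#' @rdname accessors
#' @export
setMethod("cellEstimates", "CellDepthFit", function(object) object@cells)

#' @rdname accessors
#' @export
setGeneric("lossTrace", function(object) standardGeneric("lossTrace"))
#' @rdname accessors
#' @export
setMethod("lossTrace", "CellDepthFit", function(object) object@lossTrace)
#' @rdname accessors
#' @export
setMethod("lossTrace", "SwarmState", function(object) object@lossTrace)

#' @rdname accessors
#' @export
setGeneric("penaltyBreakdown",
           function(object) standardGeneric("penaltyBreakdown"))
#' @rdname accessors
#' @export
setMethod("penaltyBreakdown", "CellDepthFit", function(object) object@penalties)

#' @rdname accessors
#' @export
setGeneric("swarmConfig4Fit", function(object) standardGeneric("swarmConfig4Fit"))
#' @rdname accessors
#' @export
setMethod("swarmConfig4Fit", "CellDepthFit", function(object) object@config)

#' @rdname accessors
#' @export
setGeneric("truthCells", function(object) standardGeneric("truthCells"))
#' @rdname accessors
#' @export
setMethod("truthCells", "SyntheticTissue", function(object) object@truth)

#' @rdname accessors
#' @export
setGeneric("observations", function(object) standardGeneric("observations"))
#' @rdname accessors
#' @export
setMethod("observations", "SyntheticTissue",
          function(object) object@observations)
#' @rdname accessors
#' @export
setMethod("observations", "CellDepthFit", function(object) object@observations)

#' @rdname accessors
#' @export
setGeneric("tissueParams", function(object) standardGeneric("tissueParams"))
#' @rdname accessors
#' @export
setMethod("tissueParams", "SyntheticTissue", function(object) object@params)

#' Total loss and components of a PenaltyBreakdown
#'
#' @param object a [PenaltyBreakdown-class]
#' @return `totalPenalty()` the weighted total L; `penaltyComponents()` a
#'   named numeric vector (P_R, P_Z, P_O, L)
#' @export
setGeneric("totalPenalty", function(object) standardGeneric("totalPenalty"))
#' @rdname totalPenalty
#' @export
setMethod("totalPenalty", "PenaltyBreakdown", function(object) object@L)

#' @rdname totalPenalty
#' @export
setGeneric("penaltyComponents",
           function(object) standardGeneric("penaltyComponents"))
#' @rdname totalPenalty
#' @export
setMethod("penaltyComponents", "PenaltyBreakdown", function(object)
  c(P_R = object@PR, P_Z = object@PZ, P_O = object@PO, L = object@L))

#' Patches and manifest of a PatchSet
#'
#' @param object a [PatchSet-class]
#' @return `patchImages()` the list of patch arrays; `patchManifest()` the
#'   manifest data.frame
#' @export
setGeneric("patchImages", function(object) standardGeneric("patchImages"))
#' @rdname patchImages
#' @export
setMethod("patchImages", "PatchSet", function(object) object@patches)

#' @rdname patchImages
#' @export
setGeneric("patchManifest", function(object) standardGeneric("patchManifest"))
#' @rdname patchImages
#' @export
setMethod("patchManifest", "PatchSet", function(object) object@manifest)

## ---- show methods ----------------------------------------------------------

setMethod("show", "SwarmConfig", function(object) {
  cat("SwarmConfig\n")
  cat(sprintf("  ratio band [alpha, beta]: [%g, %g]\n",
              object@alpha, object@beta))
  cat(sprintf("  depth box [zMin, zMax]:   [%g, %g]\n",
              object@zMin, object@zMax))
  cat(sprintf("  weights (R, Z, O):        %g, %g, %g\n",
              object@lambdaR, object@lambdaZ, object@lambdaO))
  cat(sprintf("  inertia %g -> %g; c1 %g -> %g; c2 %g -> %g\n",
              object@wStart, object@wEnd, object@c1Start, object@c1End,
              object@c2Start, object@c2End))
  cat(sprintf("  swarm %d, iterations %d, seed %s, GA %s\n",
              object@nSwarm, object@iterations,
              ifelse(is.na(object@seed), "unset", object@seed),
              ifelse(object@gaEnabled, "on", "off")))
})

setMethod("show", "PenaltyBreakdown", function(object) {
  cat(sprintf("PenaltyBreakdown: L = %g (P_R = %g, P_Z = %g, P_O = %g)\n",
              object@L, object@PR, object@PZ, object@PO))
})

setMethod("show", "CellDepthFit", function(object) {
  cat(sprintf("CellDepthFit with %d cells\n", nrow(object@cells)))
  cat(sprintf("  final loss L = %g after %d iterations\n",
              object@penalties@L, nrow(object@lossTrace)))
  show(object@penalties)
})

setMethod("show", "SyntheticTissue", function(object) {
  p <- object@params
  cat(sprintf("SyntheticTissue: %d cells in a %g x %g x %g slab (seed %s)\n",
              nrow(object@truth), p$fieldSize, p$fieldSize, p$zMax,
              ifelse(is.null(p$seed), "unset", p$seed)))
})

setMethod("show", "PatchSet", function(object) {
  cat(sprintf("PatchSet: %d patches of %d x %d px (%s)\n",
              length(object@patches), object@size, object@size,
              paste(unique(object@manifest$provenance), collapse = ", ")))
})

setMethod("show", "SwarmState", function(object) {
  cat(sprintf("SwarmState: %d particles, iteration %d, best loss %g\n",
              nrow(object@positions), object@iteration, object@gbestLoss))
})
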