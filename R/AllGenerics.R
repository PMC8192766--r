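#' @include AllClasses.R
NULL

#' Accessors for the core containers
#'
#' Small accessor generics so downstream code never touches slots directly:
#' `chainId`, `chainSeq`, `chainLength` and `atomTable` for
#' [ChainRecord-class]; `contactKind`, `contactPairs`, `mapLength` and
#' `nContacts` for [ContactMap-class]; `predItems` and `predLength` for
#' [PredictionSet-class].
#'
#' @param x the object.
#' @return the corresponding slot content (`nContacts` and lengths return
#'   integers; `contactPairs` a two-column integer matrix).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("chainId", function(x) standardGeneric("chainId"))
#' @rdname accessors
#' @export
setGeneric("chainSeq", function(x) standardGeneric("chainSeq"))
#' @rdname accessors
#' @export
setGeneric("chainLength", function(x) standardGeneric("chainLength"))
#' @rdname accessors
#' @export
setGeneric("atomTable", function(x) standardGeneric("atomTable"))
#' @rdname accessors
#' @export
setGeneric("contactKind", function(x) standardGeneric("contactKind"))
#' @rdname accessors
#' @export
setGeneric("contactPairs", function(x) standardGeneric("contactPairs"))
#' @rdname accessors
#' @export
setGeneric("mapLength", function(x) standardGeneric("mapLength"))
#' @rdname accessors
#' @export
setGeneric("nContacts", function(x) standardGeneric("nContacts"))
#' @rdname accessors
#' @export
setGeneric("predItems", function(x) standardGeneric("predItems"))
#' @rdname accessors
#' @export
setGeneric("predLength", function(x) standardGeneric("predLength"))

#' @rdname accessors
setMethod("chainId", "ChainRecord", function(x) x@chainId)
#' @rdname accessors
setMethod("chainSeq", "ChainRecord", function(x) x@sequence)
#' @rdname accessors
setMethod("chainLength", "ChainRecord", function(x) nchar(x@sequence))
#' @rdname accessors
setMethod("atomTable", "ChainRecord", function(x) x@atoms)
#' @rdname accessors
setMethod("contactKind", "ContactMap", function(x) x@kind)
#' @rdname accessors
setMethod("contactPairs", "ContactMap", function(x) x@pairs)
#' @rdname accessors
setMethod("mapLength", "ContactMap", function(x) x@L)
#' @rdname accessors
setMethod("nContacts", "ContactMap", function(x) nrow(x@pairs))
#' @rdname accessors
setMethod("predItems", "PredictionSet", function(x) x@items)
#' @rdname accessors
setMethod("predLength", "PredictionSet", function(x) x@L)

setMethod("show", "ChainRecord", function(object) {
  cat(sprintf("ChainRecord '%s': %d residues, %d atoms\n",
              object@chainId, nchar(object@sequence), nrow(object@atoms)))
  s <- object@sequence
  if (nchar(s) > 60) s <- paste0(substr(s, 1, 57), "...")
  cat(" sequence:", s, "\n")
})

setMethod("show", "ContactMap", function(object) {
  cat(sprintf("ContactMap (%schain): L = %d, %d contacts, density %.3f\n",
              object@kind, object@L, nrow(object@pairs),
              nrow(object@pairs) / object@L))
})

setMethod("show", "PredictionSet", function(object) {
  cat(sprintf("PredictionSet: L = %d, %d scored pairs", object@L,
              nrow(object@items)))
  if (nrow(object@items) > 0)
    cat(sprintf(", score range [%.3f, %.3f]",
                min(object@items$score), max(object@items$score)))
  cat("\n")
})

setMethod("show", "RigidTransform", function(object) {
  ang <- acos(pmin(1, pmax(-1, (sum(diag(object@rotation)) - 1) / 2)))
  cat(sprintf("RigidTransform: rotation %.1f deg, translation (%.2f, %.2f, %.2f) A\n",
              ang * 180 / pi, object@translation[1], object@translation[2],
              object@translation[3]))
})

#' Convert a ContactMap to a dense logical matrix
#'
#' @param x a [ContactMap-class]. Intrachain maps are symmetrized in the
#'   dense form; interchain maps are laid out as stored (rows: first chain,
#'   columns: partner).
#' @param ... unused.
#' @return an `L x L` logical matrix.
#' @export
setMethod("as.matrix", "ContactMap", function(x, ...) {
  M <- matrix(FALSE, x@L, x@L)
  if (nrow(x@pairs) > 0) {
    M[x@pairs] <- TRUE
    if (x@kind == "intra") M[x@pairs[, 2:1, drop = FALSE]] <- TRUE
  }
  M
})
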