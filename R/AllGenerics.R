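#' Accessors for scVarLink data classes
#'
#' Slot access goes through these accessors rather than \code{@}.
#'
#' @param x a \linkS4class{GenotypeMatrix}, \linkS4class{TrioData},
#'   \linkS4class{SummaryTrack}, \linkS4class{ColocResult} or
#'   \linkS4class{CitResult}.
#' @return \code{dosages}: the numeric donor-by-variant matrix;
#'   \code{variantInfo}: the per-variant metadata \code{DataFrame};
#'   \code{donorIds}: character donor identifiers;
#'   \code{posteriors}: the named PP0..PP4 vector;
#'   \code{perVariantPosteriors}: named per-variant H4 posteriors;
#'   \code{componentPvalues}: named p1..p4 plus pCit (and q).
#'
#' @examples
#' g <- simGenotypes(simConfig(nDonors = 10, nVariants = 4, seed = 1))
#' dim(dosages(g))
#' variantInfo(g)$pos
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("dosages", function(x) standardGeneric("dosages"))
#' @rdname accessors
#' @export
setGeneric("variantInfo", function(x) standardGeneric("variantInfo"))
#' @rdname accessors
#' @export
setGeneric("donorIds", function(x) standardGeneric("donorIds"))
#' @rdname accessors
#' @export
setGeneric("posteriors", function(x) standardGeneric("posteriors"))
#' @rdname accessors
#' @export
setGeneric("perVariantPosteriors",
           function(x) standardGeneric("perVariantPosteriors"))
#' @rdname accessors
#' @export
setGeneric("componentPvalues",
           function(x) standardGeneric("componentPvalues"))

#' @rdname accessors
#' @export
setMethod("dosages", "GenotypeMatrix", function(x) x@dosage)

#' @rdname accessors
#' @export
setMethod("variantInfo", "GenotypeMatrix", function(x) x@variants)

#' @rdname accessors
#' @export
setMethod("donorIds", "GenotypeMatrix", function(x) rownames(x@dosage))

#' @rdname accessors
#' @export
setMethod("donorIds", "TrioData", function(x) x@donors)

#' @rdname accessors
#' @export
setMethod("posteriors", "ColocResult", function(x) x@pp)

#' @rdname accessors
#' @export
setMethod("perVariantPosteriors", "ColocResult", function(x) x@perVariantPP4)

#' @rdname accessors
#' @export
setMethod("componentPvalues", "CitResult", function(x)
  c(p1 = x@p1, p2 = x@p2, p3 = x@p3, p4 = x@p4, pCit = x@pCit, q = x@q))

#' Subset a GenotypeMatrix by donors and/or variants
#'
#' @param x a \linkS4class{GenotypeMatrix}.
#' @param i donor index (integer, logical or donor ids).
#' @param j variant index.
#' @param ... ignored.
#' @param drop ignored; the result is always a \code{GenotypeMatrix}.
#' @return a \code{GenotypeMatrix}.
#' @export
setMethod("[", "GenotypeMatrix", function(x, i, j, ..., drop = FALSE) {
  if (missing(i)) i <- seq_len(nrow(x@dosage))
  if (missing(j)) j <- seq_len(ncol(x@dosage))
  new("GenotypeMatrix", dosage = x@dosage[i, j, drop = FALSE],
      variants = x@variants[j, , drop = FALSE])
})

#' @describeIn accessors number of donors and variants.
#' @export
setMethod("dim", "GenotypeMatrix", function(x) dim(x@dosage))

#' Coerce a CitResult (or list of them) to a data.frame
#'
#' @param x a \linkS4class{CitResult} or a list of them.
#' @param row.names,optional,... passed through for generic compatibility.
#' @return one row per result with columns p1..p4, pCit, q, call, n.
#' @export
as.data.frame.CitResult <- function(x, row.names = NULL, optional = FALSE,
                                    ...) {
  data.frame(p1 = x@p1, p2 = x@p2, p3 = x@p3, p4 = x@p4, pCit = x@pCit,
             q = x@q, call = x@call, n = x@n, stringsAsFactors = FALSE)
}

#' @rdname as.data.frame.CitResult
#' @param results a list of \code{CitResult} objects.
#' @export
citResultTable <- function(results) {
  if (is(results, "CitResult")) results <- list(results)
  do.call(rbind, lapply(results, as.data.frame.CitResult))
}
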