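#' @name TaxonOccurrence-accessors
#' @title Accessors for TaxonOccurrence objects
#' @description Convenience accessors over the SummarizedExperiment slots:
#'   the taxonomy as a plain data.frame, the 0/1 incidence matrix, and the
#'   per-region species richness.
#' @param x a [TaxonOccurrence-class] object.
NULL

#' @rdname TaxonOccurrence-accessors
#' @export
setGeneric("taxonomyTable", function(x) standardGeneric("taxonomyTable"))

#' @rdname TaxonOccurrence-accessors
#' @export
setMethod("taxonomyTable", "TaxonOccurrence", function(x) {
  rd <- as.data.frame(SummarizedExperiment::rowData(x))
  data.frame(species = rownames(x), rd, row.names = NULL,
             check.names = FALSE, stringsAsFactors = FALSE)
})

#' @rdname TaxonOccurrence-accessors
#' @export
setGeneric("presenceMatrix", function(x) standardGeneric("presenceMatrix"))

#' @rdname TaxonOccurrence-accessors
#' @export
setMethod("presenceMatrix", "TaxonOccurrence", function(x)
  SummarizedExperiment::assay(x, "presence"))

#' @rdname TaxonOccurrence-accessors
#' @export
setGeneric("richness", function(x) standardGeneric("richness"))

#' @rdname TaxonOccurrence-accessors
#' @export
setMethod("richness", "TaxonOccurrence", function(x)
  colSums(presenceMatrix(x)))

#' @rdname TaxonOccurrence-accessors
#' @export
setGeneric("regionNames", function(x) standardGeneric("regionNames"))

#' @rdname TaxonOccurrence-accessors
#' @export
setMethod("regionNames", "TaxonOccurrence", function(x) colnames(x))

#' @rdname TaxonOccurrence-accessors
#' @param region region label; its assemblage (species marked present).
#' @export
assemblage <- function(x, region) {
  m <- presenceMatrix(x)
  if (!region %in% colnames(m)) stop("unknown region: ", region)
  rownames(m)[m[, region] == 1L]
}

setMethod("show", "TaxonOccurrence", function(object) {
  m <- presenceMatrix(object)
  tab <- taxonomyTable(object)
  cat("TaxonOccurrence:", nrow(m), "species x", ncol(m), "regions\n")
  cat("  classes:", paste(unique(tab$class), collapse = ", "), "\n")
  cat("  orders:", length(unique(tab$order)),
      " families:", length(unique(tab$family)),
      " genera:", length(unique(tab$genus)), "\n")
  r <- colSums(m)
  cat("  richness range:", min(r), "-", max(r), "\n")
})

#' Select the species of a taxonomic group
#'
#' Group membership is predicate-based over the taxonomy ranks, with an
#' optional explicit species list for groups that are not a single clade at
#' one rank (e.g. pinnipeds as a set of carnivore families). Multiple
#' predicates combine with AND within an argument's rank and OR is expressed
#' by passing several values (e.g. \code{family = c("Phocidae",
#' "Otariidae", "Odobenidae")}).
#'
#' @param x a [TaxonOccurrence-class] object or a taxonomy data.frame.
#' @param class,order,family,genus character vectors of rank values; a
#'   species is kept if its rank value is in the vector (NULL = no
#'   constraint on that rank).
#' @param species explicit species names, unioned with the rank predicate
#'   result if both given; used alone it is the whole selection.
#' @param includeExtinct keep species flagged extinct in the optional
#'   \code{extinct} taxonomy column (default TRUE; the column is ignored if
#'   absent).
#' @return character vector of selected species names, in taxonomy order.
#' @export
selectSpecies <- function(x, class = NULL, order = NULL, family = NULL,
                          genus = NULL, species = NULL, includeExtinct = TRUE) {
  tab <- if (methods::is(x, "TaxonOccurrence")) taxonomyTable(x) else
    normalizeTaxonomy(x)
  keep <- rep(TRUE, nrow(tab))
  ranked <- !is.null(class) || !is.null(order) || !is.null(family) ||
    !is.null(genus)
  if (!is.null(class))  keep <- keep & tab$class %in% class
  if (!is.null(order))  keep <- keep & tab$order %in% order
  if (!is.null(family)) keep <- keep & tab$family %in% family
  if (!is.null(genus))  keep <- keep & tab$genus %in% genus
  if (!ranked) keep <- rep(FALSE, nrow(tab))
  if (!is.null(species)) keep <- keep | tab$species %in% species
  if (!ranked && is.null(species)) keep <- rep(TRUE, nrow(tab))
  if (!includeExtinct && "extinct" %in% colnames(tab))
    keep <- keep & !isTRUE_vec(tab$extinct)
  tab$species[keep]
}

isTRUE_vec <- function(x) !is.na(x) & as.logical(x)
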