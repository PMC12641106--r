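#' @import methods
#' @importFrom stats quantile rbinom rgeom pnorm sd median setNames
#' @importFrom utils read.csv write.csv combn head
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment assay assayNames rowData
#' @importFrom S4Vectors DataFrame
NULL

#' TaxonOccurrence: species-by-region incidence with a ranked taxonomy
#'
#' An S4 container coupling a presence/absence matrix (species in rows,
#' regions in columns, assay \code{"presence"}) with the five-rank Linnaean
#' lineage of each species (genus, family, order, class stored in
#' \code{rowData}). Extends
#' \linkS4class{SummarizedExperiment}, so all the usual subsetting and
#' accessor machinery applies; the validity method additionally enforces
#' the taxonomic invariants every downstream computation relies on:
#' \itemize{
#'   \item every cell of the presence assay is exactly 0 or 1;
#'   \item species names are unique and all four higher ranks are non-empty;
#'   \item the ranks nest consistently: a genus maps to exactly one family,
#'     a family to one order, an order to one class.
#' }
#'
#' @slot ... see \linkS4class{SummarizedExperiment}.
#' @seealso [TaxonOccurrence()] for the user-facing constructor,
#'   [taxonomyTable()], [presenceMatrix()], [richness()].
#' @name TaxonOccurrence-class
#' @rdname TaxonOccurrence-class
#' @exportClass TaxonOccurrence
setClass("TaxonOccurrence", contains = "SummarizedExperiment")

.RANKS <- c("genus", "family", "order", "class")

.checkRankNesting <- function(tab) {
  ## child rank -> parent rank must be a function (one parent per child)
  msgs <- character()
  pairs <- list(c("genus", "family"), c("family", "order"), c("order", "class"))
  for (p in pairs) {
    child <- tab[[p[1]]]
    parent <- tab[[p[2]]]
    bad <- tapply(parent, child, function(v) length(unique(v)) > 1L)
    if (any(bad)) {
      offenders <- names(bad)[bad]
      msgs <- c(msgs, sprintf(
        "%s mapped to more than one %s: %s",
        p[1], p[2], paste(offenders, collapse = ", ")))
    }
  }
  msgs
}

setValidity("TaxonOccurrence", function(object) {
  msgs <- character()
  if (!"presence" %in% SummarizedExperiment::assayNames(object))
    return("assay 'presence' is missing")
  m <- SummarizedExperiment::assay(object, "presence")
  if (length(m) && !all(m %in% c(0L, 1L)))
    msgs <- c(msgs, "presence assay contains values other than 0/1")
  sp <- rownames(object)
  if (is.null(sp) || anyDuplicated(sp))
    msgs <- c(msgs, "species (row) names must be present and unique")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(.RANKS %in% colnames(rd))) {
    msgs <- c(msgs, sprintf("rowData must contain columns: %s",
                            paste(.RANKS, collapse = ", ")))
  } else {
    tab <- as.data.frame(rd[, .RANKS, drop = FALSE])
    if (any(vapply(tab, function(x) any(is.na(x) | !nzchar(x)), logical(1))))
      msgs <- c(msgs, "all rank fields must be non-empty")
    msgs <- c(msgs, .checkRankNesting(tab))
  }
  if (length(msgs)) msgs else TRUE
})

#' Construct a TaxonOccurrence object
#'
#' @param occurrence integer/numeric matrix of 0/1 presences, species in rows
#'   (rownames required), regions in columns (colnames required).
#' @param taxonomy data.frame with columns \code{species}, \code{genus},
#'   \code{family}, \code{order}, \code{class} (an optional logical
#'   \code{extinct} column is carried along). Every row of \code{occurrence}
#'   must have a matching \code{species} entry; taxonomy rows never present
#'   in the matrix are dropped with a message.
#' @return a validated [TaxonOccurrence-class] object.
#' @examples
#' fx <- paperLikeFixture()
#' fx
#' richness(fx)
#' @export
TaxonOccurrence <- function(occurrence, taxonomy) {
  occurrence <- as.matrix(occurrence)
  if (is.null(rownames(occurrence)) || is.null(colnames(occurrence)))
    stop("'occurrence' needs species rownames and region colnames")
  taxonomy <- normalizeTaxonomy(taxonomy)
  missing <- setdiff(rownames(occurrence), taxonomy$species)
  if (length(missing))
    stop("species absent from taxonomy: ", paste(missing, collapse = ", "))
  extra <- setdiff(taxonomy$species, rownames(occurrence))
  if (length(extra))
    message(length(extra), " taxonomy species not in the occurrence matrix; dropped")
  taxonomy <- taxonomy[match(rownames(occurrence), taxonomy$species), , drop = FALSE]
  storage.mode(occurrence) <- "integer"
  rd <- S4Vectors::DataFrame(taxonomy[, setdiff(colnames(taxonomy), "species"),
                                      drop = FALSE])
  rownames(rd) <- taxonomy$species
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(presence = occurrence), rowData = rd)
  methods::new("TaxonOccurrence", se)
}

#' Canonicalize a taxonomy data.frame
#'
#' Trims and collapses whitespace in all rank fields, checks the five
#' required columns, rejects duplicated species and inconsistent rank
#' nesting. Species matching throughout the package is exact-string after
#' this normalization; no synonym resolution is attempted.
#'
#' @param taxonomy data.frame with \code{species} and the four higher ranks.
#' @return the cleaned data.frame, row order preserved.
#' @export
normalizeTaxonomy <- function(taxonomy) {
  taxonomy <- as.data.frame(taxonomy)
  need <- c("species", .RANKS)
  miss <- setdiff(need, colnames(taxonomy))
  if (length(miss))
    stop("taxonomy is missing column(s): ", paste(miss, collapse = ", "))
  squeeze <- function(x) gsub("[[:space:]]+", " ", trimws(as.character(x)))
  for (cl in need) taxonomy[[cl]] <- squeeze(taxonomy[[cl]])
  dup <- unique(taxonomy$species[duplicated(taxonomy$species)])
  if (length(dup))
    stop("duplicated species in taxonomy: ", paste(dup, collapse = ", "))
  empty <- vapply(taxonomy[need], function(x) any(is.na(x) | !nzchar(x)), logical(1))
  if (any(empty))
    stop("empty values in column(s): ", paste(need[empty], collapse = ", "))
  nest <- .checkRankNesting(taxonomy)
  if (length(nest))
    stop("taxonomy rank inconsistency: ", paste(nest, collapse = "; "))
  if ("extinct" %in% colnames(taxonomy))
    taxonomy$extinct <- as.logical(taxonomy$extinct)
  taxonomy
}

#' NullEnsemble: richness-preserving randomized occurrence matrices
#'
#' Holds \code{k} randomizations of an occurrence matrix in which each
#' region keeps its observed species count but species identities are drawn
#' uniformly without replacement from a master pool, together with the
#' per-region Delta+ of every randomization and the seeds used.
#'
#' @slot matrices list of 0/1 matrices, one per randomization.
#' @slot deltaTable data.frame with columns \code{replicate}, \code{region},
#'   \code{richness}, \code{deltaPlus} (regions with fewer than 2 species
#'   are omitted: Delta+ is undefined there).
#' @slot pool character vector, the master species pool.
#' @slot seeds integer vector of child seeds, one per randomization.
#' @seealso [nullEnsemble()]
#' @exportClass NullEnsemble
setClass("NullEnsemble",
  representation(matrices = "list", deltaTable = "data.frame",
                 pool = "character", seeds = "integer"))

setValidity("NullEnsemble", function(object) {
  msgs <- character()
  if (length(object@matrices) != length(object@seeds))
    msgs <- c(msgs, "one seed per matrix required")
  cs <- lapply(object@matrices, colSums)
  if (length(cs) > 1L && !all(vapply(cs[-1], identical, logical(1), cs[[1]])))
    msgs <- c(msgs, "null matrices disagree on per-region richness")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn NullEnsemble-class number of randomized matrices.
#' @param x a NullEnsemble.
#' @export
nullCount <- function(x) length(x@matrices)

#' @describeIn NullEnsemble-class per-replicate, per-region Delta+ table.
#' @export
nullDeltaTable <- function(x) x@deltaTable

#' @describeIn NullEnsemble-class the list of randomized matrices.
#' @export
nullMatrices <- function(x) x@matrices

setMethod("show", "NullEnsemble", function(object) {
  cat("NullEnsemble with", length(object@matrices), "richness-preserving",
      "randomizations\n")
  cat("  pool size:", length(object@pool), "species\n")
  cat("  regions:", ncol(object@matrices[[1]]), " (",
      nrow(object@deltaTable), "defined Delta+ values )\n")
})
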