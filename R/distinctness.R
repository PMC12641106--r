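#' Distinctness weight conventions
#'
#' The weight w_ij of a species pair is the step value of the lowest
#' Linnaean rank the two share. Two dialects are provided:
#' \describe{
#'   \item{step1 (default)}{congeneric = 1, confamilial = 2, same order =
#'     3, same class = 4, different classes = 5. This is the convention
#'     under which all reported regional values in the marine-megafauna
#'     study are reproducible.}
#'   \item{w0}{each step one lower (congeneric = 0 ... different classes =
#'     4), i.e. the number of rank levels strictly between the pair and
#'     their lowest shared rank. Every assemblage's Delta+ under w0 is
#'     exactly the step1 value minus 1 (a uniform shift of all weights
#'     shifts their mean).}
#' }
#' Weights strictly increase with taxonomic remoteness in both dialects.
#'
#' @param dialect \code{"step1"} or \code{"w0"}.
#' @return object of class \code{WeightConvention}.
#' @examples
#' weightConvention("step1")
#' @exportClass WeightConvention
#' @export
weightConvention <- function(dialect = c("step1", "w0")) {
  dialect <- match.arg(dialect)
  steps <- c(genus = 1, family = 2, order = 3, class = 4, cross = 5)
  if (dialect == "w0") steps <- steps - 1
  methods::new("WeightConvention", dialect = dialect, steps = steps)
}

setClass("WeightConvention",
         representation(dialect = "character", steps = "numeric"))

setValidity("WeightConvention", function(object) {
  if (length(object@steps) != 5L ||
      !identical(names(object@steps),
                 c("genus", "family", "order", "class", "cross")))
    return("steps must be named genus, family, order, class, cross")
  if (any(diff(object@steps) <= 0))
    return("steps must strictly increase with remoteness")
  TRUE
})

setMethod("show", "WeightConvention", function(object) {
  cat("WeightConvention '", object@dialect, "': ", sep = "")
  cat(paste(names(object@steps), object@steps, sep = "=", collapse = ", "),
      "\n")
})

.rankTable <- function(taxonomy) {
  if (methods::is(taxonomy, "TaxonOccurrence")) taxonomyTable(taxonomy)
  else normalizeTaxonomy(taxonomy)
}

#' Distinctness weight of one species pair
#'
#' Returns the step value of the lowest rank shared by the two species:
#' congeners score the genus step, confamilials of different genera the
#' family step, and so on up to the cross-class step for species sharing no
#' rank. Symmetric in its arguments; self-pairs are rejected (they never
#' enter Delta+, whose sum runs over unordered distinct pairs).
#'
#' @param taxonomy taxonomy data.frame or [TaxonOccurrence-class].
#' @param sp1,sp2 species names present in the taxonomy.
#' @param conv a [weightConvention()].
#' @return single numeric weight.
#' @examples
#' tax <- data.frame(
#'   species = c("Hydrophis platurus", "Hydrophis cyanocinctus",
#'               "Caretta caretta"),
#'   genus = c("Hydrophis", "Hydrophis", "Caretta"),
#'   family = c("Elapidae", "Elapidae", "Cheloniidae"),
#'   order = c("Squamata", "Squamata", "Testudines"),
#'   class = "Reptilia")
#' pairWeight(tax, "Hydrophis platurus", "Hydrophis cyanocinctus",
#'            weightConvention("w0"))   # congeners: 0
#' pairWeight(tax, "Hydrophis platurus", "Caretta caretta")  # class: 4
#' @export
pairWeight <- function(taxonomy, sp1, sp2, conv = weightConvention()) {
  tab <- .rankTable(taxonomy)
  i <- match(sp1, tab$species); j <- match(sp2, tab$species)
  if (is.na(i)) stop("unknown species: ", sp1)
  if (is.na(j)) stop("unknown species: ", sp2)
  if (i == j) stop("self-pair: distinctness weight is defined for distinct species")
  s <- conv@steps
  if (tab$genus[i] == tab$genus[j]) return(s[["genus"]])
  if (tab$family[i] == tab$family[j]) return(s[["family"]])
  if (tab$order[i] == tab$order[j]) return(s[["order"]])
  if (tab$class[i] == tab$class[j]) return(s[["class"]])
  s[["cross"]]
}

#' Pairwise distinctness weight matrix
#'
#' Symmetric matrix of [pairWeight()] values over an ordered species list,
#' computed by vectorized rank comparison. The diagonal is set to 0 purely
#' as a placeholder: Delta+ sums strictly over i < j and never reads it.
#'
#' @inheritParams pairWeight
#' @param species ordered character vector, no duplicates; defaults to all
#'   species in the taxonomy.
#' @return numeric species-by-species matrix with dimnames.
#' @export
weightMatrix <- function(taxonomy, species = NULL, conv = weightConvention()) {
  tab <- .rankTable(taxonomy)
  if (is.null(species)) species <- tab$species
  if (anyDuplicated(species))
    stop("duplicated species in list: ",
         paste(unique(species[duplicated(species)]), collapse = ", "))
  idx <- match(species, tab$species)
  if (anyNA(idx))
    stop("unknown species: ", paste(species[is.na(idx)], collapse = ", "))
  s <- conv@steps
  n <- length(species)
  same <- function(v) outer(v[idx], v[idx], "==")
  w <- matrix(s[["cross"]], n, n)
  w[same(tab$class)] <- s[["class"]]
  w[same(tab$order)] <- s[["order"]]
  w[same(tab$family)] <- s[["family"]]
  w[same(tab$genus)] <- s[["genus"]]
  diag(w) <- 0
  dimnames(w) <- list(species, species)
  w
}

#' Average taxonomic distinctness of an assemblage
#'
#' Delta+ = sum over unordered pairs i < j of w_ij, divided by the number
#' of pairs s(s-1)/2 — the mean taxonomic remoteness of two randomly chosen
#' species from the assemblage. Presence/absence only; richness-independent
#' in expectation, which is what makes regional comparisons across
#' assemblages of very different sizes meaningful. Undefined for fewer than
#' two species.
#'
#' @inheritParams pairWeight
#' @param assemblage character vector of species (a set: order irrelevant,
#'   duplicates rejected), at least 2.
#' @return Delta+ as a single numeric.
#' @examples
#' tax <- data.frame(
#'   species = c("Caretta caretta", "Chelonia mydas", "Dermochelys coriacea"),
#'   genus = c("Caretta", "Chelonia", "Dermochelys"),
#'   family = c("Cheloniidae", "Cheloniidae", "Dermochelyidae"),
#'   order = "Testudines", class = "Reptilia")
#' deltaPlus(tax, tax$species)  # (2 + 3 + 3) / 3 = 2.667
#' @export
deltaPlus <- function(taxonomy, assemblage, conv = weightConvention()) {
  if (length(assemblage) < 2L)
    stop("Delta+ undefined for fewer than 2 species")
  w <- weightMatrix(taxonomy, assemblage, conv)
  sum(w[upper.tri(w)]) / (length(assemblage) * (length(assemblage) - 1) / 2)
}

## fast path used by the samplers: mean upper-triangle of a precomputed
## weight submatrix
.deltaFromW <- function(W, idx) {
  s <- length(idx)
  sub <- W[idx, idx]
  sum(sub) / (s * (s - 1))   # full sum counts each pair twice
}

#' Per-region Delta+ table for a taxonomic group
#'
#' Restricts the occurrence matrix to a group of species (see
#' [selectSpecies()]) and computes each region's richness and Delta+.
#' Regions holding fewer than two group members get flag \code{"undefined"};
#' funnel columns are NA until [classifyRegions()] fills them.
#'
#' @param x a [TaxonOccurrence-class] object.
#' @param group character vector of species names defining the group
#'   (typically from [selectSpecies()]); NULL = all species.
#' @param conv a [weightConvention()].
#' @return data.frame with columns \code{region}, \code{richness},
#'   \code{deltaPlus}, \code{funnelMean}, \code{ciLower}, \code{ciUpper},
#'   \code{flag}.
#' @export
groupDeltaTable <- function(x, group = NULL, conv = weightConvention()) {
  m <- presenceMatrix(x)
  if (is.null(group)) group <- rownames(m)
  group <- intersect(rownames(m), group)
  if (length(group) < 2L)
    stop("group must contain at least 2 species present in the matrix")
  m <- m[group, , drop = FALSE]
  W <- weightMatrix(x, group, conv)
  res <- lapply(colnames(m), function(reg) {
    idx <- which(m[, reg] == 1L)
    s <- length(idx)
    data.frame(region = reg, richness = s,
               deltaPlus = if (s >= 2) .deltaFromW(W, idx) else NA_real_,
               funnelMean = NA_real_, ciLower = NA_real_, ciUpper = NA_real_,
               flag = if (s >= 2) NA_character_ else "undefined")
  })
  do.call(rbind, res)
}

#' Per-region species richness of a group, ranked
#'
#' Column sums of the occurrence matrix restricted to the group, sorted
#' descending; ties keep the matrix's (canonical) region order.
#'
#' @inheritParams groupDeltaTable
#' @return data.frame with columns \code{region}, \code{richness}, sorted.
#' @export
richnessTable <- function(x, group = NULL) {
  m <- presenceMatrix(x)
  if (is.null(group)) group <- rownames(m)
  group <- intersect(rownames(m), group)
  counts <- colSums(m[group, , drop = FALSE])
  ord <- order(-counts)   # stable: ties keep canonical column order
  data.frame(region = colnames(m)[ord], richness = as.integer(counts[ord]),
             row.names = NULL)
}
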