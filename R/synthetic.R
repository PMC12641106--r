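#' Specification for the synthetic taxonomy/assemblage generator
#'
#' Bundles the knobs of the generator: the shape of the five-rank taxonomy
#' (counts per rank and a truncated-geometric species-per-genus
#' distribution, whose small \code{speciesGeomP} produces the heavily
#' uneven clade sizes typical of real groups, where a single family can
#' hold most of a clade's species), and the regional assemblage design
#' (number of regions, richness range, per-region assembly mode and
#' clustering intensity kappa).
#'
#' Assembly modes: \code{"random"} draws species uniformly without
#' replacement; \code{"clustered"} biases draws into one seed genus's
#' family (each draw restricted with probability kappa); \code{"overdispersed"}
#' spreads draws round-robin across orders (each draw follows the
#' round-robin with probability kappa). kappa = 0 makes all three modes
#' identical to random.
#'
#' @param nClasses,ordersPerClass,familiesPerOrder,generaPerFamily integer
#'   counts (all >= 1).
#' @param speciesGeomP geometric parameter in (0, 1]; species per genus is
#'   1 + Geometric(p), so smaller p gives more lopsided genera.
#' @param nRegions number of regions.
#' @param richnessRange two integers, per-region richness drawn uniformly
#'   from this range (clipped to the realized species total).
#' @param modes character vector recycled over regions.
#' @param kappa clustering/overdispersion intensity in [0, 1].
#' @return list of class \code{"syntheticSpec"}.
#' @export
syntheticSpec <- function(nClasses = 1L, ordersPerClass = 3L,
                          familiesPerOrder = 2L, generaPerFamily = 3L,
                          speciesGeomP = 0.25, nRegions = 6L,
                          richnessRange = c(2L, 60L),
                          modes = "random", kappa = 0) {
  stopifnot(nClasses >= 1, ordersPerClass >= 1, familiesPerOrder >= 1,
            generaPerFamily >= 1, speciesGeomP > 0, speciesGeomP <= 1,
            nRegions >= 1, length(richnessRange) == 2,
            richnessRange[1] >= 2, kappa >= 0, kappa <= 1,
            all(modes %in% c("random", "clustered", "overdispersed")))
  out <- list(nClasses = as.integer(nClasses),
              ordersPerClass = as.integer(ordersPerClass),
              familiesPerOrder = as.integer(familiesPerOrder),
              generaPerFamily = as.integer(generaPerFamily),
              speciesGeomP = speciesGeomP, nRegions = as.integer(nRegions),
              richnessRange = as.integer(richnessRange),
              modes = rep_len(modes, nRegions), kappa = kappa)
  class(out) <- "syntheticSpec"
  out
}

#' Generate a synthetic five-rank taxonomy
#'
#' Builds the nested rank structure declared in the spec and draws species
#' counts per genus from a truncated geometric (always >= 1). Names encode
#' the lineage (\code{Class_c}, \code{Order_c_o}, ..., species
#' \code{Genus_g_species_s}), so rank nesting holds by construction.
#' Deterministic given \code{seed}.
#'
#' @param spec a [syntheticSpec()].
#' @param seed integer seed.
#' @return taxonomy data.frame (species, genus, family, order, class).
#' @export
generateTaxonomy <- function(spec, seed = 1L) {
  set.seed(childSeed(seed, 1L))
  rows <- list()
  g <- 0L
  for (cl in seq_len(spec$nClasses))
    for (o in seq_len(spec$ordersPerClass))
      for (f in seq_len(spec$familiesPerOrder))
        for (gg in seq_len(spec$generaPerFamily)) {
          g <- g + 1L
          nsp <- 1L + stats::rgeom(1L, spec$speciesGeomP)
          gname <- sprintf("Genus_%d", g)
          rows[[g]] <- data.frame(
            species = sprintf("%s_species_%d", gname, seq_len(nsp)),
            genus = gname,
            family = sprintf("Family_%d_%d_%d", cl, o, f),
            order = sprintf("Order_%d_%d", cl, o),
            class = sprintf("Class_%d", cl))
        }
  do.call(rbind, rows)
}

## one assemblage of the requested size under an assembly mode
.drawAssemblage <- function(tab, s, mode, kappa) {
  species <- tab$species
  if (mode == "clustered" && kappa > 0) {
    ## seed the cluster from a uniformly chosen species, so a clade's
    ## chance of hosting the assemblage scales with its size (a draw from
    ## a radiation is overwhelmingly a radiation member)
    fam <- tab$family[sample.int(nrow(tab), 1L)]
    inFam <- species[tab$family == fam]
    chosen <- character(0)
    for (i in seq_len(s)) {
      candFam <- setdiff(inFam, chosen)
      cand <- if (stats::runif(1) < kappa && length(candFam)) candFam
              else setdiff(species, chosen)
      if (!length(cand)) cand <- setdiff(species, chosen)  # fallback, logged below
      chosen <- c(chosen, sample(cand, 1L))
    }
    if (s > length(inFam))
      message("clustered draw exceeded family size; padded uniformly")
    return(chosen)
  }
  if (mode == "overdispersed" && kappa > 0) {
    orders <- sample(unique(tab$order))
    chosen <- character(0)
    oi <- 0L
    for (i in seq_len(s)) {
      remaining <- setdiff(species, chosen)
      if (stats::runif(1) < kappa) {
        ## advance round-robin to the next order with unused species
        for (tries in seq_along(orders)) {
          oi <- oi %% length(orders) + 1L
          cand <- intersect(remaining, species[tab$order == orders[oi]])
          if (length(cand)) break
        }
        if (!length(cand)) cand <- remaining
      } else cand <- remaining
      chosen <- c(chosen, sample(cand, 1L))
    }
    return(chosen)
  }
  sample(species, s)
}

#' Generate synthetic regional assemblages
#'
#' Per region: richness is drawn uniformly from the spec's range (clipped
#' to the species total), then species are sampled under the region's
#' assembly mode (see [syntheticSpec()]). Clustered draws that exhaust the
#' focal family fall back to uniform sampling for the remainder (with a
#' message) rather than failing. Deterministic given \code{seed}.
#'
#' @param taxonomy taxonomy data.frame (typically from
#'   [generateTaxonomy()]).
#' @param spec a [syntheticSpec()].
#' @param seed integer seed.
#' @return a [TaxonOccurrence-class] object with regions
#'   \code{Region_1..n}.
#' @export
generateAssemblages <- function(taxonomy, spec, seed = 1L) {
  tab <- normalizeTaxonomy(taxonomy)
  n <- nrow(tab)
  m <- matrix(0L, n, spec$nRegions,
              dimnames = list(tab$species,
                              sprintf("Region_%d", seq_len(spec$nRegions))))
  for (r in seq_len(spec$nRegions)) {
    set.seed(childSeed(seed, 100L + r))
    lo <- min(spec$richnessRange[1], n)
    hi <- min(spec$richnessRange[2], n)
    rng <- seq.int(lo, hi)
    s <- rng[sample.int(length(rng), 1L)]
    mode <- if (spec$kappa == 0) "random" else spec$modes[r]
    m[.drawAssemblage(tab, s, mode, spec$kappa), r] <- 1L
  }
  TaxonOccurrence(m, tab)
}

#' Small frozen fixture with known funnel behaviour
#'
#' A deterministic ~26-species, 6-region dataset combining a radiation
#' clade (one family dominated by a single large genus) with taxonomically
#' dispersed clades across four orders in two classes. Regions are
#' composed so that, against the full-pool funnel, all three flags occur:
#' a region of eight congeners (phylogenetically clustered, below), a
#' five-species region spanning every order (overdispersed, above),
#' mixed regions (within), plus a single-species region (undefined).
#'
#' @return a [TaxonOccurrence-class] object.
#' @examples
#' fx <- paperLikeFixture()
#' groupDeltaTable(fx)
#' @export
paperLikeFixture <- function() {
  counts <- list(
    ## genus, family, order, class, n species
    list("Genus_1", "Family_1", "Order_1", "Class_1", 8L),
    list("Genus_2", "Family_1", "Order_1", "Class_1", 4L),
    list("Genus_3", "Family_2", "Order_1", "Class_1", 2L),
    list("Genus_4", "Family_3", "Order_2", "Class_1", 3L),
    list("Genus_5", "Family_4", "Order_2", "Class_1", 2L),
    list("Genus_6", "Family_5", "Order_2", "Class_1", 1L),
    list("Genus_7", "Family_6", "Order_3", "Class_1", 2L),
    list("Genus_8", "Family_7", "Order_3", "Class_1", 1L),
    list("Genus_9", "Family_8", "Order_4", "Class_2", 2L),
    list("Genus_10", "Family_9", "Order_4", "Class_2", 1L))
  tab <- do.call(rbind, lapply(counts, function(x)
    data.frame(species = sprintf("%s_species_%d", x[[1]], seq_len(x[[5]])),
               genus = x[[1]], family = x[[2]], order = x[[3]],
               class = x[[4]])))
  sp <- tab$species
  regions <- list(
    RadiationSea = sprintf("Genus_1_species_%d", 1:8),
    DispersedSea = c("Genus_2_species_1", "Genus_4_species_1",
                     "Genus_7_species_1", "Genus_9_species_1",
                     "Genus_10_species_1"),
    TypicalSea = c(sprintf("Genus_1_species_%d", 1:3), "Genus_2_species_2",
                   "Genus_3_species_1", "Genus_4_species_2",
                   "Genus_5_species_1", "Genus_7_species_2",
                   "Genus_8_species_1", "Genus_9_species_2"),
    BroadSea = c(sprintf("Genus_1_species_%d", 1:5),
                 sprintf("Genus_2_species_%d", 1:3), "Genus_3_species_2",
                 "Genus_4_species_3", "Genus_5_species_2",
                 "Genus_6_species_1", "Genus_7_species_1",
                 "Genus_9_species_1", "Genus_10_species_1"),
    PairSea = c("Genus_4_species_1", "Genus_5_species_1"),
    SparseSea = "Genus_8_species_1")
  m <- matrix(0L, length(sp), length(regions),
              dimnames = list(sp, names(regions)))
  for (r in names(regions)) m[regions[[r]], r] <- 1L
  TaxonOccurrence(m, tab)
}
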