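#' Canonical oceanic region vocabulary
#'
#' The fifteen oceans and seas used for the global marine-megafauna
#' assemblages, as short labels with their full names, in canonical order.
#' Custom region labels are always allowed in occurrence files; this
#' vocabulary is the default used by the synthetic generators and by
#' tie-breaking in richness rankings.
#'
#' @return named character vector: names are the short labels, values the
#'   full region names.
#' @export
canonicalRegions <- function() {
  c(NAO = "North Atlantic Ocean",  TAO = "Tropical Atlantic Ocean",
    SAO = "South Atlantic Ocean",  NPO = "North Pacific Ocean",
    TPO = "Tropical Pacific Ocean", SPO = "South Pacific Ocean",
    TIO = "Tropical Indian Ocean", SIO = "South Indian Ocean",
    AO  = "Arctic Ocean",          SO  = "Southern Ocean",
    MED = "Mediterranean Sea",     RED = "Red Sea",
    PEG = "Persian Gulf",          GOM = "Gulf of Mexico",
    CAR = "Caribbean Sea")
}

#' Latitudinal band of a coordinate
#'
#' Maps a latitude to one of the five bands used to delimit the open-ocean
#' regions: Arctic (>= 60), North (60 to 23), Tropical (23 to -23), South
#' (-23 to -60), Southern (<= -60). Band boundaries belong to the poleward
#' band ("+60 and above", "-60 and below"), so 60 is Arctic, 23 North,
#' -23 South and -60 Southern; the bands partition [-90, 90].
#'
#' @param latitude numeric vector of latitudes in degrees, in [-90, 90].
#' @return character vector of band labels.
#' @examples
#' latitudeBand(c(70, 23, 0, -23, -75))
#' @export
latitudeBand <- function(latitude) {
  if (!is.numeric(latitude) || any(is.na(latitude)))
    stop("latitude must be numeric and non-missing")
  if (any(latitude < -90 | latitude > 90))
    stop("latitude outside [-90, 90]")
  out <- character(length(latitude))
  out[latitude >= 60] <- "Arctic"
  out[latitude < 60 & latitude > 23] <- "North"
  out[latitude == 23] <- "North"
  out[latitude < 23 & latitude > -23] <- "Tropical"
  out[latitude <= -23 & latitude > -60] <- "South"
  out[latitude <= -60] <- "Southern"
  out
}

#' Read a taxonomy table from delimited text
#'
#' Expects a header row containing the five rank columns (any order);
#' \code{dialect} renames non-standard headers, e.g.
#' \code{c(species = "Species_name")} if the file calls the species column
#' \code{Species_name}. An optional \code{extinct} column (logical/0-1) is
#' preserved. Validation (unique species, non-empty ranks, consistent
#' nesting) happens on read; row order is preserved.
#'
#' @param path file path; comma-delimited unless \code{sep} says otherwise.
#' @param dialect named character vector mapping standard column names to
#'   the file's header names.
#' @param sep field separator.
#' @return validated taxonomy data.frame.
#' @export
readTaxonomy <- function(path, dialect = NULL, sep = ",") {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                         check.names = FALSE)
  if (!is.null(dialect)) {
    for (std in names(dialect)) {
      if (!dialect[[std]] %in% colnames(raw))
        stop("dialect column not in file: ", dialect[[std]])
      colnames(raw)[colnames(raw) == dialect[[std]]] <- std
    }
  }
  normalizeTaxonomy(raw)
}

#' Write a taxonomy table to CSV
#' @param taxonomy taxonomy data.frame.
#' @param path output file.
#' @export
writeTaxonomy <- function(taxonomy, path) {
  utils::write.csv(normalizeTaxonomy(taxonomy), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a presence/absence occurrence matrix
#'
#' First column species names, remaining columns one per region, cells
#' strictly 0 or 1; anything else is rejected with its row/column
#' coordinates.
#'
#' @param path file path.
#' @param sep field separator.
#' @return integer matrix, species in rows, regions in columns.
#' @export
readOccurrence <- function(path, sep = ",") {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, sep = sep, stringsAsFactors = FALSE,
                         check.names = FALSE)
  if (nrow(raw) == 0L || ncol(raw) < 2L)
    stop("occurrence file has no data")
  sp <- gsub("[[:space:]]+", " ", trimws(raw[[1]]))
  cells <- raw[, -1, drop = FALSE]
  for (j in seq_along(cells)) {
    v <- cells[[j]]
    ok <- !is.na(v) & (v == 0 | v == 1)
    if (!all(ok)) {
      i <- which(!ok)[1]
      stop(sprintf("non-0/1 cell at row %d (%s), column '%s': '%s'",
                   i, sp[i], colnames(cells)[j], as.character(v[i])))
    }
  }
  m <- as.matrix(cells)
  storage.mode(m) <- "integer"
  rownames(m) <- sp
  m
}

#' Write an occurrence matrix to CSV
#' @param occurrence 0/1 matrix with species rownames.
#' @param path output file.
#' @export
writeOccurrence <- function(occurrence, path) {
  df <- data.frame(species = rownames(occurrence), occurrence,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Cross-validate a taxonomy against an occurrence matrix
#'
#' Produces a severity-graded report rather than erroring: species present
#' in the matrix but absent from the taxonomy are fatal (weights cannot be
#' computed); taxonomy species never present anywhere are a warning; regions
#' with richness below 2 are a warning (Delta+ has denominator s(s-1)/2 and
#' is undefined there). Side-effect free and idempotent.
#'
#' @param taxonomy taxonomy data.frame.
#' @param occurrence 0/1 matrix with species rownames.
#' @return data.frame with columns \code{severity} ("fatal"/"warning"),
#'   \code{subject}, \code{message}; zero rows when everything is clean.
#'   Attribute \code{ok} is TRUE when no fatal entries exist.
#' @export
validateDataset <- function(taxonomy, occurrence) {
  taxonomy <- normalizeTaxonomy(taxonomy)
  rows <- list()
  ghost <- setdiff(rownames(occurrence), taxonomy$species)
  for (g in ghost)
    rows[[length(rows) + 1L]] <- data.frame(
      severity = "fatal", subject = g,
      message = "species in occurrence matrix but absent from taxonomy")
  unused <- setdiff(taxonomy$species, rownames(occurrence)[
    rowSums(occurrence) > 0])
  for (u in unused)
    rows[[length(rows) + 1L]] <- data.frame(
      severity = "warning", subject = u,
      message = "taxonomy species never present in any region")
  rich <- colSums(occurrence)
  for (r in names(rich)[rich < 2])
    rows[[length(rows) + 1L]] <- data.frame(
      severity = "warning", subject = r,
      message = sprintf("richness %d < 2: Delta+ undefined", rich[[r]]))
  rep <- if (length(rows)) do.call(rbind, rows) else
    data.frame(severity = character(), subject = character(),
               message = character())
  attr(rep, "ok") <- !any(rep$severity == "fatal")
  rep
}
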