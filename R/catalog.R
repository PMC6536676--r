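#' @importFrom utils read.delim write.table
NULL

.catalogColumns <- c("name", "host_strain", "family", "lifestyle",
                     "previously_described", "integration_strategy",
                     "integration_site_class", "integration_site_name",
                     "genome_size", "gc_percent", "gene_count",
                     "replicon_accession", "start", "end",
                     "accession2", "start2", "end2", "attB_core")

.families <- c("Siphoviridae", "Myoviridae", "Podoviridae", "unclassified")
.lifestyles <- c("induced_active", "insilico_prophage", "lytic")
.strategies <- c("tyr", "ser", "tnp", "unknown")
.siteClasses <- c("tRNA", "gene_disruption", "intergenic", "other_gene",
                  "not_identified")

#' Path to the packaged Paracoccus virome catalog
#'
#' A TSV transcription of the published census of the Paracoccus virome:
#' the five mitomycin C-induced active phages, 59 in-silico prophages
#' (including the six previously described prophages of P. aminophilus
#' JCM 7686) and the two lytic phages vB_PmaS_IMEP1 and vB_PmaS_Shpa --
#' 66 (pro)phages in total, with family, lifestyle, integration strategy
#' and site, genome size, GC content, gene count, replicon coordinates and
#' attB core sequences where reported.
#'
#' @return file path of the packaged TSV.
#' @export
paracoccusCatalogPath <- function() {
  system.file("extdata", "paracoccus_virome_catalog.tsv",
              package = "viromeKit", mustWork = TRUE)
}

#' Normalise an integration-site name
#'
#' tRNA sites are canonicalised to the form `tRNA-Xaa(ANT)` (case of the
#' anticodon preserved upper-case; `tRNA_Xaa_(ANT)` variants accepted);
#' other site names are trimmed and lower-cased for matching. Anticodon
#' variants of the same amino acid remain distinct sites.
#'
#' @param x character vector of site names.
#' @return normalised character vector.
#' @export
normalizeSiteName <- function(x) {
  out <- trimws(x)
  m <- grepl("^tRNA[-_]", out, ignore.case = TRUE)
  canon <- sub("^trna[-_]?([a-z]{3})[-_]?\\(?([a-z]{3})\\)?$", "\\1 \\2",
               tolower(out[m]))
  ok <- grepl("^[a-z]{3} [a-z]{3}$", canon)
  aa <- substr(canon, 1, 3)
  aa <- paste0(toupper(substr(aa, 1, 1)), substr(aa, 2, 3))
  anticodon <- toupper(substr(canon, 5, 7))
  out[m][ok] <- sprintf("tRNA-%s(%s)", aa[ok], anticodon[ok])
  out[!m] <- tolower(out[!m])
  out
}

#' Load and validate a virome catalog
#'
#' Reads a TSV in the documented catalog schema, checks row-level
#' invariants (coordinates ordered, genome size positive, GC in \[0,100\],
#' lytic entries free of integration metadata, prophages carrying a host
#' strain, closed enum vocabularies) and collects every violation into a
#' validation report instead of dropping rows. Malformed files (wrong
#' header, wrong field count, duplicated names) raise errors naming the
#' offending line.
#'
#' @param path TSV file; defaults to the packaged Paracoccus catalog.
#' @return a [ViromeCatalog-class] object.
#' @examples
#' cat66 <- loadCatalog()
#' viromeSize(cat66)
#' @export
loadCatalog <- function(path = paracoccusCatalogPath()) {
  if (!file.exists(path)) stop("catalog file not found: ", path)
  lines <- readLines(path)
  if (!length(lines)) stop("catalog file is empty (no header)")
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!identical(hdr, .catalogColumns))
    stop("catalog header does not match the documented schema; expected: ",
         paste(.catalogColumns, collapse = ", "))
  nfield <- lengths(strsplit(lines[-1], "\t", fixed = TRUE))
  bad <- which(nzchar(lines[-1]) & nfield != length(.catalogColumns))
  if (length(bad))
    stop(sprintf("malformed catalog row at line %d: expected %d fields, got %d",
                 bad[1] + 1L, length(.catalogColumns), nfield[bad[1]]))
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
  dup <- df$name[duplicated(df$name)]
  if (length(dup))
    stop("duplicate catalog entry name(s): ", paste(unique(dup), collapse = ", "))

  issues <- data.frame(name = character(), issue = character(),
                       stringsAsFactors = FALSE)
  flag <- function(name, issue)
    rbind(issues, data.frame(name = name, issue = issue,
                             stringsAsFactors = FALSE))
  for (i in seq_len(nrow(df))) {
    r <- df[i, ]
    if (!is.na(r$family) && !r$family %in% .families)
      issues <- flag(r$name, paste("unknown family:", r$family))
    if (is.na(r$lifestyle) || !r$lifestyle %in% .lifestyles)
      issues <- flag(r$name, paste("unknown lifestyle:", r$lifestyle))
    if (!is.na(r$integration_strategy) &&
        !r$integration_strategy %in% .strategies)
      issues <- flag(r$name, paste("unknown integration strategy:",
                                   r$integration_strategy))
    if (!is.na(r$integration_site_class) &&
        !r$integration_site_class %in% .siteClasses)
      issues <- flag(r$name, paste("unknown site class:",
                                   r$integration_site_class))
    if (!is.na(r$genome_size) && r$genome_size <= 0)
      issues <- flag(r$name, "genome_size must be > 0")
    if (!is.na(r$gc_percent) && (r$gc_percent < 0 || r$gc_percent > 100))
      issues <- flag(r$name, "gc_percent outside [0, 100]")
    if (!is.na(r$start) && !is.na(r$end) && r$start > r$end)
      issues <- flag(r$name, sprintf("end (%d) < start (%d)", r$end, r$start))
    if (!is.na(r$start2) && !is.na(r$end2) && r$start2 > r$end2)
      issues <- flag(r$name, "second segment end < start")
    if (identical(r$lifestyle, "lytic") &&
        (!is.na(r$integration_strategy) || !is.na(r$integration_site_class) ||
         !is.na(r$integration_site_name) || !is.na(r$attB_core)))
      issues <- flag(r$name, "lytic entry carries integration metadata")
    if (identical(r$lifestyle, "insilico_prophage") &&
        (is.na(r$host_strain) || !nzchar(r$host_strain)))
      issues <- flag(r$name, "prophage entry lacks a host strain")
  }
  df$integration_site_name <- ifelse(
    is.na(df$integration_site_name), NA_character_,
    normalizeSiteName(df$integration_site_name))
  new("ViromeCatalog", entries = S4Vectors::DataFrame(df),
      validation = issues)
}

#' Write a virome catalog back to TSV
#'
#' Inverse of [loadCatalog()]: writes the documented column schema so that
#' load -> write -> load round-trips the table.
#'
#' @param catalog a [ViromeCatalog-class].
#' @param path output TSV path.
#' @export
writeCatalog <- function(catalog, path) {
  df <- as.data.frame(catalogEntries(catalog))
  write.table(df[, .catalogColumns], path, sep = "\t", quote = FALSE,
              row.names = FALSE, na = "NA")
  invisible(path)
}

.subsetEntries <- function(catalog, lifestyle = NULL) {
  e <- catalogEntries(catalog)
  if (!is.null(lifestyle)) e <- e[e$lifestyle %in% lifestyle, , drop = FALSE]
  e
}

#' Size of the virome
#'
#' Number of unique (pro)phage names in the catalog (optionally restricted
#' to a lifestyle subset). On the packaged Paracoccus catalog this is 66;
#' restricted to mitomycin C-induced active phages it is 5.
#'
#' @param catalog a [ViromeCatalog-class].
#' @param lifestyle optional lifestyle filter (character vector).
#' @return integer count.
#' @export
viromeSize <- function(catalog, lifestyle = NULL) {
  length(unique(.subsetEntries(catalog, lifestyle)$name))
}

#' Number of lysogenic host strains
#'
#' Distinct host strains among in-silico prophage entries: 29 on the
#' packaged Paracoccus catalog.
#'
#' @param catalog a [ViromeCatalog-class].
#' @return integer count.
#' @export
countLysogens <- function(catalog) {
  e <- .subsetEntries(catalog, "insilico_prophage")
  length(unique(e$host_strain))
}

#' Prophages per host and polylysogen count
#'
#' Histogram of in-silico prophage counts per host strain; polylysogens are
#' hosts carrying two or more prophages (14 on the packaged catalog, with
#' P. aminophilus JCM 7686 carrying six).
#'
#' @param catalog a [ViromeCatalog-class].
#' @return list with `histogram` (named integer vector, host -> prophage
#'   count) and `polylysogens` (hosts with count >= 2).
#' @export
polylysogenCensus <- function(catalog) {
  e <- .subsetEntries(catalog, "insilico_prophage")
  h <- table(e$host_strain)
  hist <- stats::setNames(as.integer(h), names(h))
  list(histogram = hist, polylysogens = sum(hist >= 2L))
}

#' Family tally over a lifestyle subset
#'
#' @param catalog a [ViromeCatalog-class].
#' @param lifestyle lifestyle filter; default counts in-silico prophages
#'   (50 Siphoviridae, 8 Podoviridae, 1 Myoviridae on the packaged catalog).
#' @return named integer vector family -> count; values sum to the subset
#'   size.
#' @export
tallyByFamily <- function(catalog, lifestyle = "insilico_prophage") {
  e <- .subsetEntries(catalog, lifestyle)
  if (!nrow(e)) return(stats::setNames(integer(), character()))
  h <- table(e$family)
  stats::setNames(as.integer(h), names(h))
}

#' Integration-site usage tally
#'
#' Counts catalog entries per normalised integration-site name, excluding
#' sites that were not identified. By default only in-silico prophages are
#' counted (tRNA-Met(CAT) is used by 10 prophages on the packaged catalog);
#' with `includeActive = TRUE` the induced active phages join the tally
#' (tRNA-Pro(TGG) then reaches 4).
#'
#' @param catalog a [ViromeCatalog-class].
#' @param includeActive also count induced active phages.
#' @return named integer vector site name -> count.
#' @export
tallyIntegrationSites <- function(catalog, includeActive = FALSE) {
  lifestyles <- c("insilico_prophage", if (includeActive) "induced_active")
  e <- .subsetEntries(catalog, lifestyles)
  e <- e[!is.na(e$integration_site_class) &
           e$integration_site_class != "not_identified" &
           !is.na(e$integration_site_name), , drop = FALSE]
  if (!nrow(e)) return(stats::setNames(integer(), character()))
  h <- table(e$integration_site_name)
  stats::setNames(as.integer(h), names(h))
}

#' Integration-strategy tally
#'
#' Recombinase-class counts over in-silico prophages (table-derived: 39
#' tyrosine, 15 serine, 5 Mu-like transposase on the packaged catalog).
#'
#' @param catalog a [ViromeCatalog-class].
#' @return named integer vector strategy -> count.
#' @export
tallyIntegrationStrategies <- function(catalog) {
  e <- .subsetEntries(catalog, "insilico_prophage")
  h <- table(e$integration_strategy)
  stats::setNames(as.integer(h), names(h))
}

#' Genome size from 1-based inclusive coordinates
#'
#' `end - start + 1`; the convention under which the packaged catalog's
#' printed sizes and coordinates agree (e.g. 725,048-768,929 -> 43,882 bp).
#'
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @return size in base pairs.
#' @export
genomeSizeFromCoords <- function(start, end) {
  stopifnot(all(start >= 1), all(end >= 1))
  if (any(start > end)) stop("start > end")
  end - start + 1
}

#' Audit printed genome sizes against replicon coordinates
#'
#' For every single-contig entry with coordinates, compares the printed
#' genome size with the coordinate span. Mismatches are reported, never
#' raised: the packaged catalog is a verbatim transcription and one row
#' (vB_PamS_PD3) disagrees with its own coordinates. Two-contig entries
#' are skipped.
#'
#' @param catalog a [ViromeCatalog-class].
#' @return data.frame of mismatches: name, genome_size, coordinate_size.
#' @export
crossValidateSizes <- function(catalog) {
  e <- as.data.frame(catalogEntries(catalog))
  e <- e[!is.na(e$start) & !is.na(e$end) & !is.na(e$genome_size) &
           is.na(e$accession2), , drop = FALSE]
  span <- genomeSizeFromCoords(e$start, e$end)
  bad <- e$genome_size != span
  data.frame(name = e$name[bad], genome_size = e$genome_size[bad],
             coordinate_size = span[bad], stringsAsFactors = FALSE)
}

#' Plain-text census report over a virome catalog
#'
#' Aggregates the census statistics (virome size, lysogens, polylysogens,
#' family tallies, integration strategies and most-used integration sites)
#' into a printable data.frame, as emitted by the `catalog-stats` CLI
#' subcommand.
#'
#' @param catalog a [ViromeCatalog-class].
#' @return data.frame with `statistic` and `value` columns.
#' @export
catalogCensus <- function(catalog) {
  fam <- tallyByFamily(catalog)
  strat <- tallyIntegrationStrategies(catalog)
  sites <- tallyIntegrationSites(catalog)
  pl <- polylysogenCensus(catalog)
  stat <- c(
    virome_size = viromeSize(catalog),
    active_phages = viromeSize(catalog, "induced_active"),
    insilico_prophages = viromeSize(catalog, "insilico_prophage"),
    novel_prophages = sum(
      catalogEntries(catalog)$lifestyle == "insilico_prophage" &
        !catalogEntries(catalog)$previously_described),
    lytic_phages = viromeSize(catalog, "lytic"),
    lysogens = countLysogens(catalog),
    polylysogens = pl$polylysogens,
    stats::setNames(fam, paste0("prophage_family_", names(fam))),
    stats::setNames(strat, paste0("integration_strategy_", names(strat))),
    prophages_at_tRNA_sites = sum(
      .subsetEntries(catalog, "insilico_prophage")$integration_site_class
      %in% "tRNA"),
    stats::setNames(sites, paste0("site_", names(sites))))
  data.frame(statistic = names(stat), value = as.integer(stat),
             stringsAsFactors = FALSE)
}
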