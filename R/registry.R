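#' Construct nucleic-acid mass constants
#'
#' @param avogadro particles per mole.
#' @param mwSsPerNt average molecular weight of one ssDNA nucleotide, g/mol.
#'   The dsDNA weight per base pair is fixed at twice this value.
#' @return a [NucleicAcidConstants-class] object.
#' @examples
#' const <- nucleicAcidConstants()
#' virionDnaMass(1.8, "ssDNA", const)  # 9.9e-19 g
#' @export
nucleicAcidConstants <- function(avogadro = 6.022e23, mwSsPerNt = 331.2) {
  new("NucleicAcidConstants", avogadro = avogadro, mwSsPerNt = mwSsPerNt,
      mwDsPerBp = 2 * mwSsPerNt)
}

#' Construct a genome-size range
#'
#' @param minKb,maxKb bounds in kilobases; `maxKb` defaults to `minKb`
#'   (a point assumption).
#' @return a [GenomeSizeRange-class].
#' @export
genomeSizeRange <- function(minKb, maxKb = minKb) {
  new("GenomeSizeRange", minKb = as.numeric(minKb), maxKb = as.numeric(maxKb))
}

.normalizeTaxRows <- function(records) {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  checkHeader(records, c("name", "rank", "parent"), "taxonomy table")
  for (col in c("na_type", "genome_min_kb", "genome_max_kb"))
    if (is.null(records[[col]])) records[[col]] <- NA
  records$name <- as.character(records$name)
  records$rank <- as.character(records$rank)
  records$parent <- as.character(records$parent)
  records$parent[records$parent %in% c("", "NA")] <- NA_character_
  records$na_type <- as.character(records$na_type)
  records$na_type[records$na_type %in% c("", "NA", "unknown")] <- NA_character_
  records$genome_min_kb <- suppressWarnings(as.numeric(records$genome_min_kb))
  records$genome_max_kb <- suppressWarnings(as.numeric(records$genome_max_kb))
  # ranks outside the closed vocabulary collapse to "other"
  records$rank[!records$rank %in% .taxRanks] <- "other"
  records[c("name", "rank", "parent", "na_type",
            "genome_min_kb", "genome_max_kb")]
}

#' Build a validated viral taxonomy
#'
#' Constructs a rooted taxonomy from tabular rows (columns: name, rank,
#' parent, and optionally na_type, genome_min_kb, genome_max_kb). The root row
#' has an empty parent. Duplicate names, missing parents and parent cycles
#' each raise a distinct, classed error (`viromassDuplicateError`,
#' `viromassMissingParentError`, `viromassCycleError`).
#'
#' @param records data.frame of taxon rows.
#' @return a [ViralTaxonomy-class].
#' @export
buildTaxonomy <- function(records) {
  nd <- .normalizeTaxRows(records)
  dup <- nd$name[duplicated(nd$name)]
  vmAssert(length(dup) == 0L, "viromassDuplicateError",
           paste("duplicate taxon name(s):", paste(unique(dup), collapse = ", ")))
  roots <- which(is.na(nd$parent))
  vmAssert(length(roots) == 1L, "viromassMissingParentError",
           sprintf("exactly one root required, found %d", length(roots)))
  missing <- setdiff(nd$parent[!is.na(nd$parent)], nd$name)
  vmAssert(length(missing) == 0L, "viromassMissingParentError",
           paste("parent(s) not found:", paste(missing, collapse = ", ")))
  # cycle check: every chain must reach the root within n steps
  parent <- setNames(nd$parent, nd$name)
  n <- nrow(nd)
  for (nm in nd$name) {
    cur <- nm
    steps <- 0L
    while (!is.na(parent[[cur]])) {
      cur <- parent[[cur]]
      steps <- steps + 1L
      vmAssert(steps <= n, "viromassCycleError",
               sprintf("cycle detected in ancestry of '%s'", nm))
    }
  }
  new("ViralTaxonomy", nodes = nd)
}

#' Ancestor chain of a taxon
#'
#' @param tree a [ViralTaxonomy-class].
#' @param taxon taxon name.
#' @param includeSelf include the taxon itself as the first element.
#' @return character vector from the taxon (or its parent) up to the root.
#' @export
taxAncestors <- function(tree, taxon, includeSelf = TRUE) {
  nd <- tree@nodes
  vmAssert(taxon %in% nd$name, "viromassUnknownTaxonError",
           sprintf("unknown taxon '%s'", taxon))
  parent <- setNames(nd$parent, nd$name)
  chain <- if (includeSelf) taxon else character()
  cur <- taxon
  while (!is.na(parent[[cur]])) {
    cur <- parent[[cur]]
    chain <- c(chain, cur)
  }
  chain
}

# nearest annotated value walking up from `taxon`; NULL if none
.nearestAnnotation <- function(tree, taxon, getter) {
  for (nm in taxAncestors(tree, taxon)) {
    v <- getter(tree@nodes[tree@nodes$name == nm, , drop = FALSE])
    if (!is.null(v) && !any(is.na(v))) return(v)
  }
  NULL
}

#' Genome-size lookup with ancestor inheritance
#'
#' Returns the genome-size range annotated at the taxon itself or, if absent,
#' at its nearest annotated ancestor (e.g. a genus inherits its family's
#' range).
#'
#' @param tree a [ViralTaxonomy-class].
#' @param taxon taxon name present in the tree.
#' @return a [GenomeSizeRange-class].
#' @export
genomeSizeLookup <- function(tree, taxon) {
  v <- .nearestAnnotation(tree, taxon,
                          function(row) c(row$genome_min_kb, row$genome_max_kb))
  vmAssert(!is.null(v), "viromassNoAnnotationError",
           sprintf("no annotated ancestor with a genome-size range for '%s'",
                   taxon))
  genomeSizeRange(v[1], v[2])
}

#' Nucleic-acid-type lookup with ancestor inheritance
#'
#' @inheritParams genomeSizeLookup
#' @return "ssDNA", "dsDNA", or NA when no ancestor is annotated.
#' @export
naTypeLookup <- function(tree, taxon) {
  v <- .nearestAnnotation(tree, taxon, function(row) row$na_type)
  if (is.null(v)) NA_character_ else v
}

.taxonomyHeader <- c("name", "rank", "parent", "na_type",
                     "genome_min_kb", "genome_max_kb")

#' Read / write a taxonomy registry TSV
#'
#' The registry format is TSV with header
#' `name rank parent na_type genome_min_kb genome_max_kb` (strictly
#' validated); the root row leaves `parent` empty.
#'
#' @param file path to a TSV file.
#' @return `readTaxonomy` returns a [ViralTaxonomy-class];
#'   `writeTaxonomy` returns `file` invisibly.
#' @export
readTaxonomy <- function(file) {
  df <- read.delim(file, stringsAsFactors = FALSE, na.strings = c("NA", ""))
  vmAssert(identical(names(df), .taxonomyHeader), "viromassHeaderError",
           sprintf("taxonomy file must have header: %s",
                   paste(.taxonomyHeader, collapse = "\t")))
  buildTaxonomy(df)
}

#' @rdname readTaxonomy
#' @param tree a [ViralTaxonomy-class].
#' @export
writeTaxonomy <- function(tree, file) {
  write.table(tree@nodes, file, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(file)
}

#' Bundled default viral taxonomy registry
#'
#' A small registry covering the ssDNA families commonly reported from marine
#' sediment viromes (Circoviridae, Microviridae, Inoviridae) and the common
#' dsDNA phage and algal-virus families (Siphoviridae, Podoviridae,
#' Myoviridae under Caudovirales, plus Phycodnaviridae), annotated with
#' ViralZone-style genome-size ranges. The internal "ssDNA viruses" node
#' carries the community-level 1.8-24.9 kb envelope used for mass
#' apportioning; per-family ranges refine it.
#'
#' @return a [ViralTaxonomy-class].
#' @export
defaultTaxonomy <- function() {
  readTaxonomy(system.file("extdata", "viral_taxonomy.tsv",
                           package = "viromass", mustWork = TRUE))
}
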