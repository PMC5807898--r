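.blastCols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
                "qstart", "qend", "sstart", "send", "evalue", "bitscore")
.blastNumeric <- c("pident", "length", "mismatch", "gapopen", "qstart", "qend",
                   "sstart", "send", "evalue", "bitscore")

#' Parse BLAST 12-column tabular output
#'
#' Reads the standard tabular dialect (`-outfmt 6`: qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore). Lines
#' with the wrong column count or unparseable numeric fields are not fatal:
#' they are collected, with line numbers, in the `malformed` attribute of the
#' result.
#'
#' @param x path to a hit file, or a character vector of lines.
#' @return data.frame of hits in input order with the standard column names;
#'   attribute `malformed` is a data.frame (line, content) of rejected lines.
#' @export
parseBlastTab <- function(x) {
  lines <- if (length(x) == 1L && file.exists(x)) readLines(x) else x
  lines <- lines[nzchar(trimws(lines))]
  empty <- data.frame(matrix(ncol = 12, nrow = 0))
  names(empty) <- .blastCols
  if (length(lines) == 0L) {
    attr(empty, "malformed") <- data.frame(line = integer(),
                                           content = character())
    return(empty)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  rows <- vector("list", length(lines))
  bad <- logical(length(lines))
  for (i in seq_along(lines)) {
    if (nf[i] != 12L) { bad[i] <- TRUE; next }
    p <- parts[[i]]
    num <- suppressWarnings(as.numeric(p[3:12]))
    if (anyNA(num)) { bad[i] <- TRUE; next }
    rows[[i]] <- c(list(p[1], p[2]), as.list(num))
  }
  keep <- rows[!bad]
  df <- if (length(keep)) {
    out <- as.data.frame(do.call(rbind, lapply(keep, function(r) {
      setNames(r, .blastCols)
    })), stringsAsFactors = FALSE)
    out[] <- lapply(seq_along(out), function(j) {
      if (.blastCols[j] %in% .blastNumeric) as.numeric(unlist(out[[j]]))
      else as.character(unlist(out[[j]]))
    })
    names(out) <- .blastCols
    rownames(out) <- NULL
    out
  } else empty
  attr(df, "malformed") <- data.frame(line = which(bad),
                                      content = lines[bad],
                                      stringsAsFactors = FALSE)
  df
}

#' Filter hits by E-value
#'
#' Keeps hits with `evalue < maxEvalue` (strictly less than); input order is
#' preserved.
#'
#' @param hits data.frame from [parseBlastTab()].
#' @param maxEvalue E-value cutoff (> 0); default 1e-5.
#' @return filtered data.frame.
#' @export
filterHits <- function(hits, maxEvalue = 1e-5) {
  vmAssert(maxEvalue > 0, "viromassDomainError", "maxEvalue must be > 0")
  hits[hits$evalue < maxEvalue, , drop = FALSE]
}

#' Map subject identifiers to taxa
#'
#' Joins a two-column subject-to-taxon table onto a hit set, adding a
#' `subject_taxon` column. Subjects absent from the map get NA.
#'
#' @param hits data.frame from [parseBlastTab()].
#' @param map data.frame (or TSV path) with columns `subject`, `taxon`.
#' @return hits with a `subject_taxon` column appended.
#' @export
mapSubjects <- function(hits, map) {
  if (is.character(map) && length(map) == 1L)
    map <- read.delim(map, stringsAsFactors = FALSE)
  checkHeader(map, c("subject", "taxon"), "subject-taxon map")
  hits$subject_taxon <- map$taxon[match(hits$sseqid, map$subject)]
  hits
}

#' Lowest-common-ancestor assignment for one read
#'
#' MEGAN-style LCA: among the hits for a single read, retain those with
#' `bitscore >= minBitscore` and within `topPercent` of the best retained
#' bitscore (`bitscore >= (1 - topPercent/100) * best`); the read is assigned
#' to the deepest taxonomy node shared by every retained hit's taxon. With no
#' retained hits the read is "unassigned". Hits whose taxon is absent from
#' the tree are skipped (counted in `n_skipped`).
#'
#' @param hits data.frame of hits for one read, carrying a `subject_taxon`
#'   column (see [mapSubjects()]).
#' @param tree a [ViralTaxonomy-class].
#' @param minBitscore minimum bitscore, default 50.
#' @param topPercent retain hits within this percentage of the best bitscore,
#'   default 10.
#' @return list with `query_id`, `assigned_taxon` ("unassigned" when
#'   nothing is retained), `n_hits_used` and `n_skipped`.
#' @export
lcaAssign <- function(hits, tree, minBitscore = 50, topPercent = 10) {
  qid <- unique(hits$qseqid)
  vmAssert(length(qid) <= 1L, "viromassDomainError",
           "lcaAssign expects hits from a single read")
  if (length(qid) == 0L) qid <- NA_character_
  known <- !is.na(hits$subject_taxon) & hits$subject_taxon %in% tree@nodes$name
  nSkipped <- sum(!known)
  if (nSkipped > 0 && nrow(hits) > 0)
    warning(sprintf("%d hit(s) with taxa absent from the tree skipped",
                    nSkipped), call. = FALSE)
  hits <- hits[known, , drop = FALSE]
  hits <- hits[hits$bitscore >= minBitscore, , drop = FALSE]
  if (nrow(hits) > 0) {
    best <- max(hits$bitscore)
    hits <- hits[hits$bitscore >= (1 - topPercent / 100) * best, , drop = FALSE]
  }
  if (nrow(hits) == 0L) {
    return(list(query_id = qid, assigned_taxon = "unassigned",
                n_hits_used = 0L, n_skipped = nSkipped))
  }
  taxa <- unique(hits$subject_taxon)
  # deepest node present in every ancestor chain; chains are root-terminated,
  # so reversing aligns them from the root downwards
  chains <- lapply(taxa, function(t) rev(taxAncestors(tree, t)))
  depth <- min(lengths(chains))
  lca <- chains[[1]][1]
  for (d in seq_len(depth)) {
    level <- vapply(chains, `[`, character(1), d)
    if (all(level == level[1])) lca <- level[1] else break
  }
  list(query_id = qid, assigned_taxon = lca,
       n_hits_used = nrow(hits), n_skipped = nSkipped)
}

#' Assign every read in a hit table
#'
#' Convenience wrapper: splits a mapped hit table by read and applies
#' [lcaAssign()] to each group.
#'
#' @inheritParams lcaAssign
#' @param maxEvalue E-value cutoff applied before assignment.
#' @return data.frame with columns query_id, assigned_taxon, n_hits_used.
#' @export
assignReads <- function(hits, tree, minBitscore = 50, topPercent = 10,
                        maxEvalue = 1e-5) {
  hits <- filterHits(hits, maxEvalue)
  if (nrow(hits) == 0L)
    return(data.frame(query_id = character(), assigned_taxon = character(),
                      n_hits_used = integer(), stringsAsFactors = FALSE))
  groups <- split(hits, hits$qseqid)
  out <- lapply(groups, lcaAssign, tree = tree, minBitscore = minBitscore,
                topPercent = topPercent)
  df <- data.frame(
    query_id = vapply(out, `[[`, character(1), "query_id"),
    assigned_taxon = vapply(out, `[[`, character(1), "assigned_taxon"),
    n_hits_used = vapply(out, `[[`, integer(1), "n_hits_used"),
    stringsAsFactors = FALSE)
  rownames(df) <- NULL
  df
}

# category of one assigned taxon under a grouping scheme
.schemeCategory <- function(tree, taxon, scheme) {
  if (identical(taxon, "unassigned")) return("unassigned")
  chain <- taxAncestors(tree, taxon)
  nd <- tree@nodes
  targetRank <- switch(scheme, family = "family",
                       na_type = NA, superkingdom = "superkingdom")
  if (identical(scheme, "na_type")) {
    nt <- naTypeLookup(tree, taxon)
    return(if (is.na(nt)) "others" else paste(nt, "viruses"))
  }
  for (nm in chain) {
    if (nd$rank[nd$name == nm] == targetRank) return(nm)
  }
  # no node of the target rank on the chain: bin by nucleic-acid type
  nt <- naTypeLookup(tree, taxon)
  if (is.na(nt)) "others" else sprintf("unclassified %s viruses", nt)
}

#' Build a taxonomic profile from read assignments
#'
#' Maps each assigned read to a category by walking its ancestor chain:
#' `"family"` bins at family rank (assignments above family fall into
#' "unclassified ssDNA/dsDNA viruses" by nucleic-acid type),
#' `"na_type"` bins into "ssDNA viruses"/"dsDNA viruses", and
#' `"superkingdom"` bins at superkingdom rank. Unassigned reads are counted
#' under "unassigned". The profile total always equals the number of input
#' assignments.
#'
#' @param assignments data.frame from [assignReads()] (columns query_id,
#'   assigned_taxon).
#' @param tree a [ViralTaxonomy-class].
#' @param scheme one of "family", "na_type", "superkingdom".
#' @param libraryId label for the profile.
#' @param totalReads total reads in the library, defaulting to
#'   `nrow(assignments)` (pass the sequenced total when only hit-bearing
#'   reads were assigned).
#' @return a [TaxonomicProfile-class].
#' @export
buildProfile <- function(assignments, tree,
                         scheme = c("family", "na_type", "superkingdom"),
                         libraryId = "library", totalReads = NULL) {
  scheme <- match.arg(scheme)
  cats <- vapply(assignments$assigned_taxon, .schemeCategory,
                 character(1), tree = tree, scheme = scheme)
  counts <- table(cats)
  counts <- setNames(as.numeric(counts), names(counts))
  if (is.null(totalReads)) totalReads <- nrow(assignments)
  viralCats <- setdiff(names(counts), "unassigned")
  catNa <- vapply(viralCats, function(cat) {
    if (cat %in% tree@nodes$name) naTypeLookup(tree, cat)
    else if (grepl("ssDNA", cat)) "ssDNA"
    else if (grepl("dsDNA", cat)) "dsDNA"
    else NA_character_
  }, character(1))
  new("TaxonomicProfile", libraryId = libraryId, counts = counts,
      categoryNaType = catNa, totalReads = as.numeric(totalReads),
      viralReads = sum(counts[viralCats]))
}

#' Construct a profile directly from category counts
#'
#' @param counts named numeric vector of reads per category (may include
#'   "unassigned").
#' @param categoryNaType named character vector giving "ssDNA"/"dsDNA"/NA per
#'   viral category; missing names default to NA.
#' @param libraryId label.
#' @param totalReads total library size; defaults to `sum(counts)`.
#' @return a [TaxonomicProfile-class].
#' @export
taxonomicProfile <- function(counts, categoryNaType = NULL,
                             libraryId = "library", totalReads = NULL) {
  viralCats <- setdiff(names(counts), "unassigned")
  nt <- setNames(rep(NA_character_, length(viralCats)), viralCats)
  if (!is.null(categoryNaType))
    nt[intersect(names(categoryNaType), viralCats)] <-
      categoryNaType[intersect(names(categoryNaType), viralCats)]
  if (is.null(totalReads)) totalReads <- sum(counts)
  new("TaxonomicProfile", libraryId = libraryId,
      counts = setNames(as.numeric(counts), names(counts)),
      categoryNaType = nt, totalReads = as.numeric(totalReads),
      viralReads = sum(counts[viralCats]))
}

#' Collapse minor categories
#'
#' Viral categories holding strictly less than `thresholdPercent` of the
#' viral reads are merged into "other ssDNA viruses", "other dsDNA viruses"
#' or "others" according to their nucleic-acid type; a category at exactly
#' the threshold is retained. Totals are conserved and "unassigned" is never
#' collapsed.
#'
#' @param profile a [TaxonomicProfile-class].
#' @param thresholdPercent percent of viral reads below which a category is
#'   collapsed, in \[0, 100\]; default 2.
#' @return a collapsed [TaxonomicProfile-class].
#' @export
collapseMinor <- function(profile, thresholdPercent = 2) {
  vmAssert(thresholdPercent >= 0 && thresholdPercent <= 100,
           "viromassDomainError", "thresholdPercent must be in [0, 100]")
  counts <- profile@counts
  viralCats <- setdiff(names(counts), "unassigned")
  if (profile@viralReads == 0 || length(viralCats) == 0L) return(profile)
  pct <- 100 * counts[viralCats] / profile@viralReads
  minor <- viralCats[pct < thresholdPercent]
  keep <- counts[setdiff(names(counts), minor)]
  binOf <- function(cat) {
    nt <- profile@categoryNaType[[cat]]
    if (is.na(nt)) "others" else sprintf("other %s viruses", nt)
  }
  for (cat in minor) {
    bin <- binOf(cat)
    keep[bin] <- (if (bin %in% names(keep)) keep[[bin]] else 0) + counts[[cat]]
  }
  nt <- profile@categoryNaType[intersect(names(profile@categoryNaType),
                                         names(keep))]
  for (bin in intersect(c("other ssDNA viruses", "other dsDNA viruses"),
                        names(keep)))
    nt[bin] <- sub("^other (\\w+DNA) viruses$", "\\1", bin)
  taxonomicProfile(keep, nt, profile@libraryId, profile@totalReads)
}

#' Write profiles as TSV
#'
#' One row per (library, category) with count and percent of viral reads.
#'
#' @param profiles list of [TaxonomicProfile-class] objects.
#' @param file output path.
#' @return invisibly, the path.
#' @export
writeProfiles <- function(profiles, file) {
  rows <- do.call(rbind, lapply(profiles, function(p) {
    data.frame(library_id = p@libraryId, category = names(p@counts),
               count = as.numeric(p@counts),
               percent_of_viral = ifelse(
                 names(p@counts) == "unassigned", NA,
                 100 * as.numeric(p@counts) / max(p@viralReads, 1)),
               stringsAsFactors = FALSE)
  }))
  write.table(rows, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read profiles from TSV
#'
#' Inverse of [writeProfiles()]; nucleic-acid types are re-derived from
#' `tree` when given.
#'
#' @param file TSV path with columns library_id, category, count.
#' @param tree optional [ViralTaxonomy-class] for na_type annotation.
#' @return named list of [TaxonomicProfile-class] objects.
#' @export
readProfiles <- function(file, tree = NULL) {
  df <- read.delim(file, stringsAsFactors = FALSE)
  checkHeader(df, c("library_id", "category", "count"), "profile table")
  lapply(split(df, df$library_id), function(d) {
    counts <- setNames(d$count, d$category)
    nt <- NULL
    if (!is.null(tree)) {
      viralCats <- setdiff(names(counts), "unassigned")
      nt <- setNames(vapply(viralCats, function(cat) {
        if (cat %in% tree@nodes$name) naTypeLookup(tree, cat)
        else if (grepl("ssDNA", cat)) "ssDNA"
        else if (grepl("dsDNA", cat)) "dsDNA"
        else NA_character_
      }, character(1)), viralCats)
    }
    taxonomicProfile(counts, nt, libraryId = d$library_id[1])
  })
}
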