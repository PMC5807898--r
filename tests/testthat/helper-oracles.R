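# Independent oracles and random-instance generators used across the suite.

# Random rooted taxonomy as a plain parent table. Node i's parent is drawn
# uniformly among nodes 1..(i-1), so the result is always a tree.
randomTaxRows <- function(nNodes, pAnnotated = 0.4) {
  name <- c("root", sprintf("node%03d", seq_len(nNodes - 1)))
  parent <- c(NA, vapply(seq_len(nNodes - 1), function(i)
    name[sample.int(i, 1)], character(1)))
  annotated <- c(FALSE, runif(nNodes - 1) < pAnnotated)
  minKb <- ifelse(annotated, runif(nNodes, 1, 20), NA)
  data.frame(name = name,
             rank = c("root", sample(c("order", "family", "genus", "other"),
                                     nNodes - 1, replace = TRUE)),
             parent = parent,
             na_type = ifelse(annotated, sample(c("ssDNA", "dsDNA"), nNodes,
                                                replace = TRUE), NA),
             genome_min_kb = minKb,
             genome_max_kb = minKb * runif(nNodes, 1, 2),
             stringsAsFactors = FALSE)
}

# brute-force ancestor chain from the parent table (no package code)
oracleChain <- function(rows, taxon) {
  parent <- setNames(rows$parent, rows$name)
  chain <- taxon
  while (!is.na(parent[[chain[length(chain)]]]))
    chain <- c(chain, parent[[chain[length(chain)]]])
  chain
}

# brute-force nearest annotated genome size walking up the chain
oracleGenomeSize <- function(rows, taxon) {
  for (nm in oracleChain(rows, taxon)) {
    r <- rows[rows$name == nm, ]
    if (!is.na(r$genome_min_kb)) return(c(r$genome_min_kb, r$genome_max_kb))
  }
  NULL
}

# brute-force LCA: intersect full ancestor chains, take the deepest shared
# node (chains are self..root; depth = distance from root)
oracleLca <- function(rows, taxa) {
  chains <- lapply(taxa, function(t) rev(oracleChain(rows, t)))
  d <- min(lengths(chains))
  lca <- chains[[1]][1]
  for (i in seq_len(d)) {
    lev <- vapply(chains, `[`, character(1), i)
    if (all(lev == lev[1])) lca <- lev[1] else break
  }
  lca
}

# direct eigendecomposition PCA oracle
oraclePca <- function(m) {
  centered <- scale(m, center = TRUE, scale = FALSE)
  eig <- eigen(cov(centered), symmetric = TRUE)
  list(values = pmax(eig$values, 0), vectors = eig$vectors,
       scores = centered %*% eig$vectors)
}

# small fixture mirroring the published sediment measurements
tohokuSamples <- function() {
  readSamples(system.file("extdata", "tohoku_samples.tsv",
                          package = "viromass"))
}

tohokuLibraries <- function() {
  read.delim(system.file("extdata", "tohoku_libraries.tsv",
                         package = "viromass"), stringsAsFactors = FALSE)
}

# minimal hand-built taxonomy used by profiler unit tests
toyTree <- function() {
  buildTaxonomy(data.frame(
    name = c("Viruses", "ssDNA viruses", "dsDNA viruses",
             "Circoviridae", "Microviridae", "Siphoviridae", "CircoGenusA"),
    rank = c("root", "other", "other", "family", "family", "family", "genus"),
    parent = c(NA, "Viruses", "Viruses", "ssDNA viruses", "ssDNA viruses",
               "dsDNA viruses", "Circoviridae"),
    na_type = c(NA, "ssDNA", "dsDNA", "ssDNA", "ssDNA", "dsDNA", NA),
    genome_min_kb = c(NA, 1.8, NA, 1.8, 4.4, 22, NA),
    genome_max_kb = c(NA, 24.9, NA, 2.1, 6.1, 121, NA),
    stringsAsFactors = FALSE))
}

hitRow <- function(qid, subj, taxon, evalue = 1e-20, bitscore = 100) {
  data.frame(qseqid = qid, sseqid = subj, pident = 90, length = 100,
             mismatch = 0, gapopen = 0, qstart = 1, qend = 100, sstart = 1,
             send = 100, evalue = evalue, bitscore = bitscore,
             subject_taxon = taxon, stringsAsFactors = FALSE)
}
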