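## Readers and writers: FASTA proteomes, taxon tables, cluster/hit tables,
## ABC graph files.

#' Read one amino-acid proteome from a FASTA file
#'
#' Entry ids are the first whitespace-delimited header token, prefixed with
#' `taxonId` and a pipe to guarantee global uniqueness across pooled
#' proteomes.  Sequences are upper-cased and stop-codon asterisks stripped.
#' Residues outside the 20 standard amino acids + X are rejected.
#'
#' @param path FASTA file (plain or gzip).
#' @param taxonId Taxon key used as the id prefix.
#' @return Named character vector of sequences (names are global protein
#'   ids), preserving file order.
#' @export
#' @examples
#' f <- tempfile(fileext = ".faa")
#' writeLines(c(">p1 some description", "MKVL", ">p2", "MK*V"), f)
#' readProteomeFasta(f, "T1")
readProteomeFasta <- function(path, taxonId) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  lines <- readLines(path)
  nonblank <- which(!grepl("^[[:space:]]*$", lines))
  if (length(nonblank) && !startsWith(lines[nonblank[1L]], ">"))
    .stopf("malformed FASTA %s: sequence data before first header at line %d",
           path, nonblank[1L])
  set <- withCallingHandlers(
    readAAStringSet(path),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w)))
        .stopf("invalid residues in %s: only the 20 standard amino acids + X are accepted",
               path)
      invokeRestart("muffleWarning")
    })
  if (!length(set)) .stopf("no FASTA entries in %s", path)
  ids <- sub("[[:space:]].*$", "", names(set))
  if (anyDuplicated(ids))
    .stopf("duplicate sequence id(s) in %s: %s", path,
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- gsub("*", "", toupper(as.character(set)), fixed = TRUE)
  empty <- !nzchar(seqs)
  if (any(empty))
    .stopf("empty sequence(s) in %s: %s", path,
           paste(ids[empty], collapse = ", "))
  bad <- grepl(sprintf("[^%sX]", paste(AA20, collapse = "")), seqs)
  if (any(bad))
    .stopf("non-amino-acid residues in %s (entry %s)", path,
           paste(ids[bad], collapse = ", "))
  stats::setNames(seqs, paste0(taxonId, "|", ids))
}

#' Write a proteome subset to FASTA
#'
#' Sequence lines are wrapped at 60 columns.  The taxon prefix is kept in
#' the header so a written file read back with the same prefix would not be
#' double-prefixed; use `stripPrefix = TRUE` to emit local ids.
#'
#' @param sequences Named character vector or `AAStringSet`.
#' @param path Output file.
#' @param stripPrefix Drop the `taxonid|` prefix from ids.
#' @return Invisibly, `path`.
#' @export
writeProteomeFasta <- function(sequences, path, stripPrefix = FALSE) {
  if (!is(sequences, "AAStringSet")) sequences <- AAStringSet(sequences)
  if (stripPrefix) names(sequences) <- sub("^[^|]*\\|", "", names(sequences))
  writeXStringSet(sequences, filepath = path, width = 60L)
  invisible(path)
}

#' Read a taxon metadata table
#'
#' Tab-separated with header `taxon_id`, `name`, `domain`, `group`,
#' `genus`.  Domains must be eukaryote/bacteria/archaea; eukaryote groups
#' must be one of the six supergroups; duplicate taxon ids are rejected.
#' Loading is order-independent: the registry is canonically sorted.
#'
#' @param path TSV file.
#' @return A [TaxonRegistry-class].
#' @export
readTaxonTable <- function(path) {
  if (!file.exists(path)) .stopf("no such file: %s", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  TaxonRegistry(tab)
}

#' Write a taxon registry to TSV
#' @param registry A [TaxonRegistry-class].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
writeTaxonTable <- function(registry, path) {
  utils::write.table(taxonTable(registry), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a family clustering as TSV
#'
#' One row per member with columns `cluster_id`, `protein_id`, `taxon_id`,
#' `domain`, `group`, sorted by (cluster_id, protein_id); a write-then-read
#' round trip reproduces the membership mapping exactly.
#'
#' @param clustering A [FamilyClustering-class].
#' @param proteomes [ProteomeSet-class] used to annotate taxon and group.
#' @param path Output file.
#' @return `writeClustersTsv`: invisibly `path`; `readClustersTsv`: a
#'   [FamilyClustering-class] (unclustered proteins are not stored in the
#'   file and come back empty).
#' @export
writeClustersTsv <- function(clustering, proteomes, path) {
  m <- clusterMembership(clustering)
  ptax <- proteinTaxon(proteomes)
  reg <- proteomes@registry
  dom <- taxonField(reg, "domain")
  grp <- taxonField(reg, "group")
  tax <- unname(ptax[m$protein_id])
  out <- data.frame(cluster_id = m$cluster_id, protein_id = m$protein_id,
                    taxon_id = tax, domain = unname(dom[tax]),
                    group = unname(grp[tax]), stringsAsFactors = FALSE)
  out <- out[order(out$cluster_id, out$protein_id), , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeClustersTsv
#' @export
readClustersTsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  FamilyClustering(tab[, c("cluster_id", "protein_id")])
}

#' Write a hit table to TSV
#'
#' Fixed column order `query_id`, `subject_id`, `bit_score`, `evalue`,
#' `global_identity`, with the E-value in scientific notation.
#'
#' @param hits Hit table as returned by [searchHits()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
writeHitsTsv <- function(hits, path) {
  out <- data.frame(
    query_id = hits$query_id, subject_id = hits$subject_id,
    bit_score = format(hits$bit_score, digits = 6),
    evalue = format(hits$evalue, scientific = TRUE, digits = 4),
    global_identity = format(hits$global_identity, digits = 4),
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a similarity graph in ABC format
#'
#' Three whitespace-separated columns (node, node, weight), the label input
#' format of the original MCL implementation.
#'
#' @param graph A [SimilarityGraph-class].
#' @param path File path.
#' @return `writeAbcGraph`: invisibly `path`; `readAbcGraph`: a
#'   [SimilarityGraph-class].
#' @export
writeAbcGraph <- function(graph, path) {
  e <- graphEdges(graph)
  utils::write.table(e[, c("a", "b", "weight")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeAbcGraph
#' @export
readAbcGraph <- function(path) {
  tab <- utils::read.table(path, header = FALSE,
                           col.names = c("a", "b", "weight"),
                           colClasses = c("character", "character",
                                          "numeric"))
  .makeSimilarityGraph(tab)
}

#' Load a directory of FASTA proteomes
#'
#' Expects one `<taxon_id>.faa` (or `.fa`/`.fasta`, optionally `.gz`) per
#' taxon listed in the registry.
#'
#' @param dir Directory of FASTA files.
#' @param registry [TaxonRegistry-class] naming the taxa to load.
#' @return A [ProteomeSet-class].
#' @export
loadProteomeDir <- function(dir, registry) {
  ids <- taxonIds(registry)
  seqs <- character()
  taxa <- character()
  for (tid in ids) {
    cand <- list.files(dir, full.names = TRUE, pattern = paste0(
      "^", gsub("([][{}()+*^$.|\\\\?])", "\\\\\\1", tid),
      "\\.(faa|fa|fasta)(\\.gz)?$"))
    if (!length(cand)) .stopf("no FASTA file for taxon %s in %s", tid, dir)
    s <- readProteomeFasta(cand[1L], tid)
    seqs <- c(seqs, s)
    taxa <- c(taxa, rep(tid, length(s)))
  }
  ProteomeSet(seqs, taxa, registry)
}
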