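#' Write annotation tracks as flat files
#'
#' Serializes every track of an `AnnotationTracks` object under `dir` in
#' the plain-text formats the package reads back: tab tables for domains,
#' GERP scores, gene covariates, expression, allele frequencies and
#' ancestral alleles; BED (0-based half-open) for constrained elements and
#' segmental duplications; an edge list plus a disease-gene table for the
#' interaction network; one-gene-per-line lists for paralog/pseudogene
#' membership.
#'
#' @param tracks an `AnnotationTracks` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_tracks <- function(tracks, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, name) utils::write.table(
    x, file.path(dir, name), sep = "\t", quote = FALSE, row.names = FALSE)
  w(tracks$domains, "domains.tsv")
  gerp_df <- data.frame(
    contig = sub(":.*$", "", names(tracks$gerp)),
    pos = as.integer(sub("^.*:", "", names(tracks$gerp))),
    score = as.numeric(tracks$gerp))
  w(gerp_df, "gerp.tsv")
  bed <- function(x) data.frame(contig = x$contig, start = x$start - 1L,
                                end = x$end)
  utils::write.table(bed(tracks$constrained), file.path(dir, "constrained.bed"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(bed(tracks$segdup), file.path(dir, "segdup.bed"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  w(tracks$edges, "network_edges.tsv")
  w(data.frame(
    gene_id = c(tracks$dominant_genes, tracks$recessive_genes),
    inheritance = rep(c("dominant", "recessive"),
                      c(length(tracks$dominant_genes),
                        length(tracks$recessive_genes)))),
    "disease_genes.tsv")
  w(tracks$gene_table, "gene_table.tsv")
  w(data.frame(gene_id = rownames(tracks$expression), tracks$expression),
    "expression.tsv")
  anc_df <- data.frame(
    contig = sub(":.*$", "", names(tracks$ancestral)),
    pos = as.integer(sub("^.*:", "", names(tracks$ancestral))),
    base = as.character(tracks$ancestral))
  w(anc_df, "ancestral.tsv")
  writeLines(tracks$paralog_genes, file.path(dir, "paralog_genes.txt"))
  writeLines(tracks$pseudogene_genes, file.path(dir, "pseudogene_genes.txt"))
  w(tracks$af, "allele_freq.tsv")
  if (!is.null(tracks$gene_class))
    w(data.frame(gene_id = names(tracks$gene_class),
                 class = as.character(tracks$gene_class)), "gene_class.tsv")
  invisible(dir)
}

#' Read annotation tracks from a directory of flat files
#'
#' Inverse of [write_tracks()]; rebuilds the interaction graph from the
#' edge list (isolated genes from the gene table are kept as vertices).
#'
#' @param dir directory holding the track files.
#' @return an `AnnotationTracks` object.
#' @export
read_tracks <- function(dir) {
  r <- function(name, ...) utils::read.table(
    file.path(dir, name), sep = "\t", header = TRUE,
    stringsAsFactors = FALSE, ...)
  rbed <- function(name) {
    p <- file.path(dir, name)
    if (file.size(p) == 0)
      return(data.frame(contig = character(), start = integer(),
                        end = integer()))
    b <- utils::read.table(p, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)
    data.frame(contig = b[[1]], start = b[[2]] + 1L, end = b[[3]])
  }
  gerp_df <- r("gerp.tsv")
  anc_df <- r("ancestral.tsv", colClasses = c("character", "integer",
                                              "character"))
  edges <- r("network_edges.tsv")
  dis <- r("disease_genes.tsv")
  gene_table <- r("gene_table.tsv")
  expr_df <- r("expression.tsv")
  expression <- as.matrix(expr_df[, -1, drop = FALSE])
  rownames(expression) <- expr_df$gene_id
  vertices <- unique(c(edges$from, edges$to, gene_table$gene_id,
                       dis$gene_id))
  graph <- igraph::simplify(igraph::graph_from_data_frame(
    edges, directed = FALSE, vertices = vertices))
  gene_class <- NULL
  if (file.exists(file.path(dir, "gene_class.tsv"))) {
    gc_df <- r("gene_class.tsv")
    gene_class <- stats::setNames(gc_df$class, gc_df$gene_id)
  }
  af <- r("allele_freq.tsv", colClasses = c("character", "numeric",
                                            "numeric", "numeric"))
  structure(list(
    domains = r("domains.tsv"),
    gerp = stats::setNames(gerp_df$score,
                           paste0(gerp_df$contig, ":", gerp_df$pos)),
    constrained = rbed("constrained.bed"),
    edges = edges, graph = graph,
    dominant_genes = dis$gene_id[dis$inheritance == "dominant"],
    recessive_genes = dis$gene_id[dis$inheritance == "recessive"],
    gene_table = gene_table, expression = expression,
    ancestral = stats::setNames(anc_df$base,
                                paste0(anc_df$contig, ":", anc_df$pos)),
    segdup = rbed("segdup.bed"),
    paralog_genes = readLines(file.path(dir, "paralog_genes.txt")),
    pseudogene_genes = readLines(file.path(dir, "pseudogene_genes.txt")),
    af = af, gene_class = gene_class
  ), class = "AnnotationTracks")
}

#' @export
print.AnnotationTracks <- function(x, ...) {
  cat(sprintf(paste0("<AnnotationTracks: %d domain intervals, %d GERP bases, ",
                     "%d constrained elements, %d-node network, %d genes>\n"),
              nrow(x$domains), length(x$gerp), nrow(x$constrained),
              igraph::vcount(x$graph), nrow(x$gene_table)))
  invisible(x)
}
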