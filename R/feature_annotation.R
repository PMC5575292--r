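DOMAIN_KINDS <- c("pfam", "smart", "scop", "signal_peptide", "transmembrane",
                  "ptm_site", "disorder")
TISSUE_NAMES <- sprintf("expr_t%02d", 1:25)

#' The classifier feature registry
#'
#' A declarative table of the 108 named feature slots fed to the
#' classifier, grouped by family: `consequence` (call category, stop-codon
#' identity, frameshift phase, affected-intron length), `position`
#' (CDS/protein geometry of the truncation), `nmd` (nonsense-mediated decay
#' candidacy under the 50-nt last-junction rule), `domain` (per-kind
#' hit/lost/count features for PFAM, SMART, SCOP, signal peptide,
#' transmembrane, post-translational-modification and disorder intervals),
#' `conservation` (site GERP, conservation of the truncated region, dN/dS),
#' `network` (protein-protein-interaction proximity to disease genes and
#' centralities), `frequency` (cohort allele frequencies), `gene` (per-gene
#' variation and constraint covariates) and `expression` (25-tissue
#' expression and entropy-based tissue specificity).
#'
#' Binary slots take values in \{-1, +1\} with `NA` for missing; numeric
#' slots are real-valued with `NA` for missing.
#'
#' @return data frame with columns `name`, `type` (`"binary"`/`"numeric"`),
#'   `family`; exactly 108 rows, fixed order.
#' @export
feature_registry <- function() {
  reg <- rbind(
    data.frame(name = c("cat_premature_stop", "cat_frameshift",
                        "cat_splice_donor", "cat_splice_acceptor",
                        "stop_codon_taa", "stop_codon_tag", "stop_codon_tga",
                        "indel_shift_1", "indel_shift_2"),
               type = "binary", family = "consequence"),
    data.frame(name = "splice_intron_len", type = "numeric", family = "consequence"),
    data.frame(name = c("cds_pos", "cds_fraction", "cds_length",
                        "protein_length", "n_exons", "transcript_span",
                        "dist_last_junction", "frac_protein_truncated",
                        "removed_nt", "exon_index", "intron_min_len",
                        "intron_mean_len", "gc_content_cds"),
               type = "numeric", family = "position"),
    data.frame(name = "nmd_candidate", type = "binary", family = "nmd"),
    data.frame(name = paste0("dom_", rep(DOMAIN_KINDS, each = 2), c("_hit", "_lost")),
               type = "binary", family = "domain"),
    data.frame(name = paste0("dom_", rep(DOMAIN_KINDS, each = 2),
                             c("_n_lost", "_n_total")),
               type = "numeric", family = "domain"),
    data.frame(name = c("site_gerp", "truncation_constrained_frac",
                        "gerp_mean_removed", "dnds_macaque", "dnds_mouse"),
               type = "numeric", family = "conservation"),
    data.frame(name = c("net_dominant_neighbors", "net_recessive_neighbors",
                        "net_shortest_path_disease", "centrality_degree",
                        "centrality_betweenness", "centrality_closeness"),
               type = "numeric", family = "network"),
    data.frame(name = c("af_kg", "af_esp", "af_exac"),
               type = "numeric", family = "frequency"),
    data.frame(name = c("in_kg", "in_esp", "in_exac"),
               type = "binary", family = "frequency"),
    data.frame(name = c("gene_syn_density", "gene_nonsyn_density",
                        "gene_syn_mean_gerp", "gene_nonsyn_mean_gerp",
                        "gene_syn_constrained_pct", "gene_nonsyn_constrained_pct",
                        "gene_cds_constrained_pct", "gene_het_syn",
                        "gene_het_nonsyn", "gene_mirna_sites",
                        "gene_n_transcripts"),
               type = "numeric", family = "gene"),
    data.frame(name = c(TISSUE_NAMES, "expr_mean", "expr_max",
                        "tissue_specificity"),
               type = "numeric", family = "expression"))
  rownames(reg) <- NULL
  reg
}

#' Nonsense-mediated decay prediction
#'
#' A premature stop is an NMD candidate when its distance to the last
#' exon-exon junction, measured in spliced-transcript nucleotides at the
#' first base of the stop codon, is strictly greater than 50 nt; otherwise
#' (including every single-exon transcript) the transcript escapes NMD. For
#' frameshifts the shifted reading frame is scanned for the first novel stop
#' codon and the same rule is applied at that stop; a frameshift creating no
#' new stop (stop-loss-like) escapes. Splice calls are not applicable.
#'
#' @param call a `PLoFCall` of category `premature_stop` or `frameshift`.
#' @param tx the matching `plof_transcript`.
#' @param genome named character vector of contig sequences (needed for frameshift rescanning).
#' @param rule_nt junction-distance threshold (default 50).
#' @return list with `status` (`"nmd_candidate"`, `"nmd_escape"`, or
#'   `"not_applicable"`) and `distance` (nt to last junction at the relevant
#'   stop, `NA` when undefined).
#' @export
predict_nmd <- function(call, tx, genome, rule_nt = 50L) {
  if (!call$category %in% c("premature_stop", "frameshift"))
    return(list(status = "not_applicable", distance = NA_integer_))
  if (nrow(tx$exons) < 2L)
    return(list(status = "nmd_escape", distance = NA_integer_))
  if (call$category == "premature_stop") {
    stop_first <- 3L * ((call$cds_pos - 1L) %/% 3L) + 1L
    d <- distance_to_last_junction(tx, stop_first)
  } else {
    d <- frameshift_stop_distance(call, tx, genome)
    if (is.null(d))
      return(list(status = "nmd_escape", distance = NA_integer_))
  }
  list(status = if (d > rule_nt) "nmd_candidate" else "nmd_escape",
       distance = d)
}

# Distance (mutated spliced-transcript nt) from the first novel stop in the
# shifted frame to the last junction; NULL when no novel stop arises.
frameshift_stop_distance <- function(call, tx, genome) {
  cds <- spliced_cds(tx, genome)
  len_ref <- nchar(call$ref); len_alt <- nchar(call$alt)
  delta <- len_alt - len_ref
  if (len_ref > 1L) {
    changed <- (call$pos + 1L):(call$pos + len_ref - 1L)
    cpos <- sort(match(changed, tx$cds_map))
    ins <- substr(call$alt, 2L, len_alt)
    if (tx$strand == "-" && nchar(ins)) ins <- revcomp(ins)
    mut <- paste0(substr(cds, 1L, cpos[1L] - 1L), ins,
                  substr(cds, cpos[length(cpos)] + 1L, nchar(cds)))
    anchor <- cpos[1L]
  } else {
    ins <- substr(call$alt, 2L, len_alt)
    if (tx$strand == "-") ins <- revcomp(ins)
    anchor <- call$cds_pos                       # first altered CDS base
    mut <- paste0(substr(cds, 1L, anchor - 1L), ins,
                  substr(cds, anchor, nchar(cds)))
  }
  first_codon <- (anchor - 1L) %/% 3L + 1L
  stop_codon <- NA_integer_
  for (ci in first_codon:(nchar(mut) %/% 3L)) {
    if (substr(mut, 3L * ci - 2L, 3L * ci) %in% STOP_CODONS) {
      stop_codon <- ci; break
    }
  }
  if (is.na(stop_codon)) return(NULL)
  p_mut <- 3L * stop_codon - 2L                  # mutated-CDS pos of new stop
  # junction position in spliced-transcript coordinates, shifted if the
  # indel lies upstream of it
  ex_len <- tx$exons$end - tx$exons$start + 1L
  if (tx$strand == "-") ex_len <- rev(ex_len)
  junction <- sum(ex_len[-length(ex_len)])
  t_anchor <- match(tx$cds_map[anchor], tx$exon_map)
  j_mut <- if (t_anchor <= junction) junction + delta else junction
  t_cds1 <- match(tx$cds_map[1L], tx$exon_map)
  j_mut - (p_mut + t_cds1 - 1L)
}

#' Domain hit/loss features for a truncating call
#'
#' The truncation point is the protein position of the call,
#' `ceil(cds_pos / 3)`. For each domain kind, `hit` is +1 when the
#' truncation point falls inside an interval of that kind, and `lost` is +1
#' when any interval of that kind starts at or after the truncation point
#' (i.e. is removed by the truncated product).
#'
#' @param call a `PLoFCall` with a CDS position.
#' @param tx the matching transcript.
#' @param domains domain track: data frame `transcript_id`, `kind`,
#'   `start`, `end` (protein coordinates).
#' @return named list: per kind `_hit`, `_lost` (+1/-1), `_n_lost`,
#'   `_n_total` (counts).
#' @export
domain_features <- function(call, tx, domains) {
  p <- (call$cds_pos - 1L) %/% 3L + 1L
  d <- domains[domains$transcript_id == tx$transcript_id, , drop = FALSE]
  out <- list()
  for (k in DOMAIN_KINDS) {
    dk <- d[d$kind == k, , drop = FALSE]
    hit <- any(dk$start <= p & dk$end >= p)
    n_lost <- sum(dk$start >= p)
    out[[paste0("dom_", k, "_hit")]] <- if (hit) 1 else -1
    out[[paste0("dom_", k, "_lost")]] <- if (n_lost > 0L) 1 else -1
    out[[paste0("dom_", k, "_n_lost")]] <- n_lost
    out[[paste0("dom_", k, "_n_total")]] <- nrow(dk)
  }
  out
}

in_intervals <- function(contig, pos, iv) {
  if (!nrow(iv)) return(rep(FALSE, length(pos)))
  iv <- iv[iv$contig == contig, , drop = FALSE]
  if (!nrow(iv)) return(rep(FALSE, length(pos)))
  vapply(pos, function(p) any(iv$start <= p & iv$end >= p), logical(1))
}

#' Fraction of the truncated coding region inside constrained elements
#'
#' The truncation removes spliced-CDS bases `cds_pos .. cds_length`; the
#' returned value is the fraction of those bases (mapped to the genome)
#' overlapping GERP-constrained elements. Counted in nucleotides.
#'
#' @param call a `PLoFCall` with a CDS position.
#' @param tx the matching transcript.
#' @param constrained data frame `contig`, `start`, `end` (1-based closed).
#' @return fraction in \[0, 1\]; 0 for a zero-length removal.
#' @export
truncation_conservation <- function(call, tx, constrained) {
  if (call$cds_pos > tx$cds_length) return(0)
  removed <- tx$cds_map[call$cds_pos:tx$cds_length]
  mean(in_intervals(tx$contig, removed, constrained))
}

#' Site GERP score of a call
#'
#' SNVs return the score at the variant position; deletions the mean score
#' over the deleted reference bases; insertions the mean over the two
#' reference bases flanking the insertion point.
#'
#' @param call a `PLoFCall`.
#' @param gerp named numeric vector keyed `"contig:pos"`.
#' @return score, or `NA` when no affected base has a defined score.
#' @export
site_gerp <- function(call, gerp) {
  pos <- affected_positions(call)
  v <- gerp[paste0(call$contig, ":", pos)]
  if (all(is.na(v))) return(NA_real_)
  mean(v, na.rm = TRUE)
}

affected_positions <- function(call) {
  len_ref <- nchar(call$ref); len_alt <- nchar(call$alt)
  if (len_ref == 1L && len_alt == 1L) return(call$pos)
  if (len_ref > 1L) return((call$pos + 1L):(call$pos + len_ref - 1L))
  c(call$pos, call$pos + 1L)
}

#' Network proximity of a gene to disease genes
#'
#' @param gene gene identifier.
#' @param graph an `igraph` protein-protein interaction graph with vertex
#'   names = gene ids.
#' @param dominant_genes,recessive_genes character vectors of disease-gene
#'   labels.
#' @return list: `n_dominant_neighbors`, `n_recessive_neighbors` (direct
#'   edges), `shortest_path_to_disease_gene` (unweighted hops; 0 when the
#'   gene itself is a disease gene, `NA` when unreachable or absent from the
#'   graph).
#' @export
network_features <- function(gene, graph, dominant_genes, recessive_genes) {
  disease <- union(dominant_genes, recessive_genes)
  if (!gene %in% igraph::V(graph)$name)
    return(list(n_dominant_neighbors = NA_real_,
                n_recessive_neighbors = NA_real_,
                shortest_path_to_disease_gene = NA_real_))
  nb <- igraph::V(graph)$name[igraph::neighbors(graph, gene)]
  sp <- if (gene %in% disease) 0 else {
    reach <- intersect(disease, igraph::V(graph)$name)
    if (!length(reach)) NA_real_ else {
      d <- suppressWarnings(igraph::distances(graph, v = gene, to = reach))
      if (all(is.infinite(d))) NA_real_ else min(d)
    }
  }
  list(n_dominant_neighbors = sum(nb %in% dominant_genes),
       n_recessive_neighbors = sum(nb %in% recessive_genes),
       shortest_path_to_disease_gene = sp)
}

#' Average heterozygosity of a coding transcript
#'
#' Computed as `sum(2 p q) / l` over the transcript's SNPs, where `p` is the
#' minor allele frequency, `q` the reference allele frequency, and `l` the
#' coding-transcript length in nucleotides.
#'
#' @param snps data frame with columns `p` and `q` (one row per SNP; zero
#'   rows allowed).
#' @param cds_length positive transcript length `l`.
#' @return non-negative heterozygosity.
#' @export
heterozygosity <- function(snps, cds_length) {
  if (cds_length <= 0) stop("cds_length must be > 0")
  if (is.null(snps) || nrow(snps) == 0L) return(0)
  sum(2 * snps$p * snps$q) / cds_length
}

#' Entropy-based tissue specificity
#'
#' Expression across tissues is normalized to proportions `p_i`; Shannon
#' entropy `H = -sum(p_i log2 p_i)` is rescaled to a specificity
#' `1 - H / log2(N)`: 1 for expression confined to a single tissue, 0 for
#' perfectly uniform expression.
#'
#' @param expression non-negative expression values (one per tissue).
#' @return specificity in \[0, 1\], or `NA` for an all-zero row.
#' @export
tissue_specificity <- function(expression) {
  stopifnot(all(expression >= 0 | is.na(expression)))
  s <- sum(expression)
  if (is.na(s) || s == 0) return(NA_real_)
  p <- expression / s
  p <- p[p > 0]
  h <- -sum(p * log2(p))
  1 - h / log2(length(expression))
}

#' Assemble the full feature vector for one pLoF call
#'
#' Populates every slot of [feature_registry()] from the call, its
#' transcript, and the annotation tracks. Absent track entries are recorded
#' as `NA` (missingness is data, handled downstream by imputation); slots
#' that are structurally inapplicable to the call category (e.g. stop-codon
#' identity for a splice call) are `-1` for binary slots and 0 for
#' `splice_intron_len`.
#'
#' @param call a `PLoFCall`.
#' @param transcript_set a `TranscriptSet`.
#' @param tracks an `AnnotationTracks` object (see [read_tracks()]).
#' @return named numeric vector with exactly the 108 registry slots, in
#'   registry order.
#' @export
assemble_features <- function(call, transcript_set, tracks) {
  reg <- feature_registry()
  f <- stats::setNames(rep(NA_real_, nrow(reg)), reg$name)
  tx <- transcript_set$transcripts[[call$transcript_id]]
  genome <- transcript_set$genome
  pm <- function(b) if (isTRUE(b)) 1 else -1

  f["cat_premature_stop"] <- pm(call$category == "premature_stop")
  f["cat_frameshift"] <- pm(call$category == "frameshift")
  f["cat_splice_donor"] <- pm(call$category == "splice_donor")
  f["cat_splice_acceptor"] <- pm(call$category == "splice_acceptor")
  f["stop_codon_taa"] <- pm(identical(call$introduced_stop_codon, "TAA"))
  f["stop_codon_tag"] <- pm(identical(call$introduced_stop_codon, "TAG"))
  f["stop_codon_tga"] <- pm(identical(call$introduced_stop_codon, "TGA"))
  f["indel_shift_1"] <- pm(identical(call$indel_shift, 1L))
  f["indel_shift_2"] <- pm(identical(call$indel_shift, 2L))
  il <- intron_lengths(tx)
  f["splice_intron_len"] <-
    if (!is.na(call$intron_index)) il[call$intron_index] else 0

  cds <- spliced_cds(tx, genome)
  f["cds_length"] <- tx$cds_length
  f["protein_length"] <- tx$cds_length / 3 - 1
  f["n_exons"] <- nrow(tx$exons)
  f["transcript_span"] <- max(tx$exons$end) - min(tx$exons$start) + 1
  f["intron_min_len"] <- if (length(il)) min(il) else NA_real_
  f["intron_mean_len"] <- if (length(il)) mean(il) else NA_real_
  f["gc_content_cds"] <-
    sum(strsplit(cds, "")[[1]] %in% c("G", "C")) / nchar(cds)

  if (!is.na(call$cds_pos)) {
    f["cds_pos"] <- call$cds_pos
    f["cds_fraction"] <- call$cds_fraction
    prot_pos <- (call$cds_pos - 1) %/% 3 + 1
    f["frac_protein_truncated"] <-
      max(0, min(1, (f[["protein_length"]] - prot_pos + 1) / f[["protein_length"]]))
    f["removed_nt"] <- tx$cds_length - call$cds_pos + 1
    d <- distance_to_last_junction(tx, call$cds_pos)
    f["dist_last_junction"] <- if (is.na(d)) NA_real_ else d
    tx_pos <- match(tx$cds_map[call$cds_pos], tx$exon_map)
    ex_len <- tx$exons$end - tx$exons$start + 1L
    if (tx$strand == "-") ex_len <- rev(ex_len)
    f["exon_index"] <- findInterval(tx_pos - 1L, cumsum(ex_len)) + 1L

    nmd <- predict_nmd(call, tx, genome)
    if (nmd$status != "not_applicable")
      f["nmd_candidate"] <- pm(nmd$status == "nmd_candidate")
    dfeat <- domain_features(call, tx, tracks$domains)
    for (kv in names(dfeat)) f[kv] <- dfeat[[kv]]
    f["truncation_constrained_frac"] <-
      truncation_conservation(call, tx, tracks$constrained)
    removed <- tx$cds_map[call$cds_pos:tx$cds_length]
    g <- tracks$gerp[paste0(tx$contig, ":", removed)]
    f["gerp_mean_removed"] <- if (all(is.na(g))) NA_real_ else mean(g, na.rm = TRUE)
  }
  f["site_gerp"] <- site_gerp(call, tracks$gerp)

  gt <- tracks$gene_table[tracks$gene_table$gene_id == call$gene_id, , drop = FALSE]
  if (nrow(gt) == 1L) {
    f["dnds_macaque"] <- gt$dnds_macaque
    f["dnds_mouse"] <- gt$dnds_mouse
    f["centrality_degree"] <- gt$centrality_degree
    f["centrality_betweenness"] <- gt$centrality_betweenness
    f["centrality_closeness"] <- gt$centrality_closeness
    f["gene_syn_density"] <- gt$syn_density
    f["gene_nonsyn_density"] <- gt$nonsyn_density
    f["gene_syn_mean_gerp"] <- gt$syn_mean_gerp
    f["gene_nonsyn_mean_gerp"] <- gt$nonsyn_mean_gerp
    f["gene_syn_constrained_pct"] <- gt$syn_constrained_pct
    f["gene_nonsyn_constrained_pct"] <- gt$nonsyn_constrained_pct
    f["gene_cds_constrained_pct"] <- gt$cds_constrained_pct
    f["gene_het_syn"] <- gt$het_syn
    f["gene_het_nonsyn"] <- gt$het_nonsyn
    f["gene_mirna_sites"] <- gt$mirna_sites
  }
  f["gene_n_transcripts"] <- sum(vapply(transcript_set$transcripts,
                                        function(t) t$gene_id == call$gene_id,
                                        logical(1)))

  nf <- network_features(call$gene_id, tracks$graph,
                         tracks$dominant_genes, tracks$recessive_genes)
  f["net_dominant_neighbors"] <- nf$n_dominant_neighbors
  f["net_recessive_neighbors"] <- nf$n_recessive_neighbors
  f["net_shortest_path_disease"] <- nf$shortest_path_to_disease_gene

  key <- paste(call$contig, call$pos, call$ref, call$alt, sep = ":")
  af <- tracks$af[tracks$af$key == key, , drop = FALSE]
  for (coh in c("kg", "esp", "exac")) {
    v <- if (nrow(af) == 1L) af[[paste0("af_", coh)]] else NA_real_
    f[paste0("af_", coh)] <- if (is.na(v)) 0 else v
    f[paste0("in_", coh)] <- pm(!is.na(v))
  }

  if (call$gene_id %in% rownames(tracks$expression)) {
    e <- as.numeric(tracks$expression[call$gene_id, ])
    f[TISSUE_NAMES] <- e
    f["expr_mean"] <- mean(e)
    f["expr_max"] <- max(e)
    f["tissue_specificity"] <- tissue_specificity(e)
  }
  f
}

#' Assemble a feature matrix for a list of calls
#'
#' @param calls list of `PLoFCall`.
#' @inheritParams assemble_features
#' @return data frame: one row per call, 108 registry columns.
#' @export
assemble_corpus <- function(calls, transcript_set, tracks) {
  m <- t(vapply(calls, assemble_features, numeric(nrow(feature_registry())),
                transcript_set = transcript_set, tracks = tracks))
  as.data.frame(m)
}
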