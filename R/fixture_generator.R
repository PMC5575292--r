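SENSE_CODONS <- setdiff(
  apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                    c("A", "C", "G", "T")), 1, paste, collapse = ""),
  c("TAA", "TAG", "TGA"))

#' Configuration for the synthetic fixture world
#'
#' Defines the study conditions for the synthetic corpus: gene counts and
#' variants per gene for the three classes (~150 labeled premature-stop
#' variants per class: benign as many genes with few variants, dominant as
#' few genes with many variants, echoing the strong per-gene skew of real
#' dominant training sets), transcript geometry, the fraction of
#' noncanonical/small introns, and the class effect size. `effect_size`
#' scales every class-dependent signal (gene-level Gaussian mean shifts in
#' units of the within-class SD, network wiring rates, allele-frequency
#' presence, truncation-position bias); at `effect_size = 0` the three
#' classes are statistically indistinguishable by construction.
#'
#' @param class_genes named integer vector: genes per class.
#' @param variants_per_gene named integer vector: planted stop variants per
#'   gene and class.
#' @param exons_range,cds_codons_range,intron_len_range geometry ranges.
#' @param single_exon_fraction,multi_transcript_fraction,domain_fraction,
#'   housekeeping_fraction gene-level fractions.
#' @param small_intron_fraction,noncanonical_fraction intron-level fractions.
#' @param n_background,disease_gene_fraction interaction-network background
#'   genes and the fraction of them labeled as (dominant/recessive) disease
#'   genes.
#' @param effect_size class separation in within-class SD units (default 3,
#'   the separable regime).
#' @param missingness per-cell missing-data rate applied to the assembled
#'   feature table.
#' @param ancestral_alt_fraction fraction of covered sites whose ancestral
#'   allele differs from the reference.
#' @param holdout_fraction fraction of genes (per class) held out.
#' @param seed master seed; all generator stages derive from it.
#' @return a `FixtureConfig` list.
#' @export
fixture_config <- function(class_genes = c(benign = 50L, dominant = 15L,
                                           recessive = 50L),
                           variants_per_gene = c(benign = 3L, dominant = 10L,
                                                 recessive = 3L),
                           exons_range = c(2L, 6L),
                           cds_codons_range = c(120L, 400L),
                           intron_len_range = c(30L, 120L),
                           single_exon_fraction = 0.05,
                           multi_transcript_fraction = 0.15,
                           domain_fraction = 0.7,
                           housekeeping_fraction = 0.2,
                           small_intron_fraction = 0.05,
                           noncanonical_fraction = 0.05,
                           n_background = 40L,
                           disease_gene_fraction = 0.5,
                           effect_size = 3,
                           missingness = 0.05,
                           ancestral_alt_fraction = 0.05,
                           holdout_fraction = 0.2,
                           seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(all(cfg$class_genes >= 1L), all(cfg$variants_per_gene >= 1L),
            cfg$missingness >= 0, cfg$missingness <= 1,
            cfg$effect_size >= 0)
  structure(cfg, class = "FixtureConfig")
}

fixture_gene_ids <- function(config) {
  n <- sum(config$class_genes)
  ids <- sprintf("G%04d", seq_len(n))
  cls <- rep(names(config$class_genes), config$class_genes)
  stats::setNames(cls, ids)
}

rand_bases <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")

# CDS chunk lengths for n_ex exons, each chunk >= 8 nt
split_cds <- function(L, n_ex) {
  if (n_ex == 1L) return(L)
  for (i in 1:200) {
    cuts <- sort(sample(seq(9L, L - 8L), n_ex - 1L))
    len <- diff(c(0L, cuts, L))
    if (all(len >= 8L)) return(len)
  }
  stop("cannot split CDS of length ", L, " into ", n_ex, " exons")
}

# Build one transcript in transcript orientation, then map to the genome.
# Returns the gene-local genomic sequence plus exon/CDS intervals (1-based
# within that sequence, genomic order).
build_transcript_seq <- function(config) {
  single <- stats::runif(1) < config$single_exon_fraction
  n_ex <- if (single) 1L else
    sample(seq(config$exons_range[1], config$exons_range[2]), 1L)
  n_cod <- sample(seq(config$cds_codons_range[1], config$cds_codons_range[2]), 1L)
  cds <- paste0("ATG",
                paste(sample(SENSE_CODONS, n_cod - 2L, replace = TRUE),
                      collapse = ""),
                sample(STOP_CODONS, 1L))
  L <- nchar(cds)
  chunk <- split_cds(L, n_ex)
  u5 <- sample(0:30, 1L); u3 <- sample(0:30, 1L)
  # transcript-orientation pieces
  pieces <- character(0); exon_t <- NULL; cds_t <- NULL
  cursor <- 0L; cds_done <- 0L
  noncanon <- character(0)
  for (i in seq_len(n_ex)) {
    ex_seq <- substr(cds, cds_done + 1L, cds_done + chunk[i])
    lead <- if (i == 1L) u5 else 0L
    trail <- if (i == n_ex) u3 else 0L
    ex_seq <- paste0(if (lead) rand_bases(lead) else "", ex_seq,
                     if (trail) rand_bases(trail) else "")
    pieces <- c(pieces, ex_seq)
    exon_t <- rbind(exon_t, c(cursor + 1L, cursor + nchar(ex_seq)))
    cds_t <- rbind(cds_t, c(cursor + lead + 1L, cursor + lead + chunk[i]))
    cursor <- cursor + nchar(ex_seq)
    cds_done <- cds_done + chunk[i]
    if (i < n_ex) {
      small <- stats::runif(1) < config$small_intron_fraction
      il <- if (small) sample(8:14, 1L) else
        sample(seq(config$intron_len_range[1], config$intron_len_range[2]), 1L)
      nc <- stats::runif(1) < config$noncanonical_fraction
      dinucs <- if (nc) c("GC", "AC") else c("GT", "AG")
      if (nc) noncanon <- c(noncanon, i)
      intron <- paste0(dinucs[1], rand_bases(il - 4L), dinucs[2])
      pieces <- c(pieces, intron)
      cursor <- cursor + il
    }
  }
  seq_t <- paste(pieces, collapse = "")
  strand <- sample(c("+", "-"), 1L)
  M <- nchar(seq_t)
  flip <- function(iv) {
    g <- cbind(M - iv[, 2] + 1L, M - iv[, 1] + 1L)
    g[order(g[, 1]), , drop = FALSE]
  }
  if (strand == "-") {
    seq_g <- revcomp(seq_t)
    exon_g <- flip(exon_t); cds_g <- flip(cds_t)
  } else {
    seq_g <- seq_t; exon_g <- exon_t; cds_g <- cds_t
  }
  list(seq = seq_g, strand = strand, exons = exon_g, cds = cds_g,
       cds_length = L)
}

#' Generate the synthetic genome and gene models
#'
#' Emits a genome FASTA and an Ensembl-dialect GTF whose transcripts all
#' satisfy the loader's contract: spliced CDS starting ATG, ending in a
#' stop, no internal stop, stop codon included in the CDS, introns carrying
#' GT..AG except for a configurable noncanonical fraction. A configurable
#' fraction of genes get a second (shorter, non-overlapping) transcript.
#' Deterministic for a fixed `config$seed`.
#'
#' @param config a [fixture_config()].
#' @param dir output directory (created if needed).
#' @return list with `fasta`, `gtf` paths and the gene -> class truth map.
#' @export
make_reference <- function(config, dir) {
  set.seed(config$seed)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gene_class <- fixture_gene_ids(config)
  per_contig <- 12L
  contigs <- list(); gtf <- character(0)
  cur_contig <- 0L; cur_seq <- character(0); cur_pos <- 0L
  flush_contig <- function() {
    if (cur_pos > 0L)
      contigs[[paste0("ctg", cur_contig)]] <<- paste(cur_seq, collapse = "")
  }
  genes_on_contig <- 0L
  for (gi in seq_along(gene_class)) {
    if (genes_on_contig == 0L) {
      cur_contig <- cur_contig + 1L
      cur_seq <- character(0); cur_pos <- 0L
    }
    gid <- names(gene_class)[gi]
    n_tx <- if (stats::runif(1) < config$multi_transcript_fraction) 2L else 1L
    for (ti in seq_len(n_tx)) {
      tid <- paste0(sub("G", "T", gid), letters[ti])
      b <- build_transcript_seq(config)
      pad <- 150L + sample(0:100, 1L)
      cur_seq <- c(cur_seq, rand_bases(pad), b$seq)
      off <- cur_pos + pad
      cur_pos <- off + nchar(b$seq)
      attr_str <- sprintf('gene_id "%s"; transcript_id "%s";', gid, tid)
      ctg <- paste0("ctg", cur_contig)
      for (r in seq_len(nrow(b$exons)))
        gtf <- c(gtf, paste(ctg, "plofpred", "exon", off + b$exons[r, 1],
                            off + b$exons[r, 2], ".", b$strand, ".",
                            attr_str, sep = "\t"))
      cds_iv <- b$cds
      ord <- if (b$strand == "-") rev(seq_len(nrow(cds_iv))) else seq_len(nrow(cds_iv))
      cum <- 0L
      for (r in ord) {
        phase <- (3L - cum %% 3L) %% 3L
        gtf <- c(gtf, paste(ctg, "plofpred", "CDS", off + cds_iv[r, 1],
                            off + cds_iv[r, 2], ".", b$strand, phase,
                            attr_str, sep = "\t"))
        cum <- cum + cds_iv[r, 2] - cds_iv[r, 1] + 1L
      }
    }
    genes_on_contig <- (genes_on_contig + 1L) %% per_contig
    if (genes_on_contig == 0L || gi == length(gene_class)) {
      cur_seq <- c(cur_seq, rand_bases(150L))
      cur_pos <- cur_pos + 150L
      flush_contig()
    }
  }
  fasta <- file.path(dir, "genome.fa")
  gtf_path <- file.path(dir, "models.gtf")
  dna <- Biostrings::DNAStringSet(unlist(contigs))
  Biostrings::writeXStringSet(dna, fasta, width = 80L)
  writeLines(gtf, gtf_path)
  list(fasta = fasta, gtf = gtf_path, gene_class = gene_class)
}

shifted <- function(n, base, slope, effect, offs, sd = 1)
  base + slope * effect * offs + stats::rnorm(n, 0, sd)

CLASS_OFFS <- c(benign = -1, recessive = 0.4, dominant = 1)

#' Generate all annotation tracks for a fixture transcript set
#'
#' Builds the domain, conservation (per-base GERP + constrained elements),
#' protein-protein-interaction network (labeled disease genes live among
#' background nodes), gene-level covariate, expression (25 tissues),
#' ancestral-allele, and homology (segdup/paralog/pseudogene) tracks, plus
#' an allele-frequency table shell, with every class-dependent mean scaled
#' by `config$effect_size`. All tracks are written as flat files under
#' `dir` and returned in memory as an `AnnotationTracks` object.
#'
#' @param config a [fixture_config()].
#' @param transcript_set the loaded fixture `TranscriptSet`.
#' @param dir output directory.
#' @return an `AnnotationTracks` object (see [read_tracks()]).
#' @export
make_tracks <- function(config, transcript_set, dir) {
  set.seed(config$seed + 1L)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  gene_class <- fixture_gene_ids(config)
  genes <- names(gene_class)
  offs <- CLASS_OFFS[gene_class]
  eff <- config$effect_size
  txs <- transcript_set$transcripts
  ng <- length(genes)

  # domains (protein coordinates, per transcript)
  dom <- list()
  for (tx in txs) {
    if (stats::runif(1) > config$domain_fraction) next
    plen <- tx$cds_length %/% 3L - 1L
    for (k in DOMAIN_KINDS) {
      if (stats::runif(1) > 0.55) next
      for (j in seq_len(sample(1:2, 1L))) {
        w <- sample(5:max(6L, plen %/% 4L), 1L)
        s <- sample(seq_len(max(1L, plen - w)), 1L)
        dom[[length(dom) + 1L]] <- data.frame(
          transcript_id = tx$transcript_id, kind = k, start = s,
          end = min(plen, s + w))
      }
    }
  }
  domains <- if (length(dom)) do.call(rbind, dom) else
    data.frame(transcript_id = character(), kind = character(),
               start = integer(), end = integer())

  # per-base GERP over exons +/- 8 intronic bases; class-shifted gene mean
  gerp_list <- list()
  constrained <- list()
  for (tx in txs) {
    o <- CLASS_OFFS[[gene_class[[tx$gene_id]]]]
    mu <- 2 + 0.7 * eff * o
    lo <- max(1L, min(tx$exons$start) - 8L)
    hi <- min(nchar(transcript_set$genome[[tx$contig]]),
              max(tx$exons$end) + 8L)
    pos <- lo:hi
    gerp_list[[tx$transcript_id]] <- data.frame(
      contig = tx$contig, pos = pos, score = stats::rnorm(length(pos), mu, 1))
    # constrained elements: class-dependent fraction of the CDS span
    frac <- min(0.9, max(0.02, 0.25 + 0.08 * eff * o + stats::rnorm(1, 0, 0.05)))
    for (r in seq_len(nrow(tx$cds))) {
      w <- tx$cds$end[r] - tx$cds$start[r] + 1L
      cw <- round(frac * w)
      if (cw >= 3L) {
        s <- tx$cds$start[r] + sample(0:(w - cw), 1L)
        constrained[[length(constrained) + 1L]] <- data.frame(
          contig = tx$contig, start = s, end = s + cw - 1L)
      }
    }
  }
  gerp_df <- do.call(rbind, gerp_list)
  gerp_df <- gerp_df[!duplicated(paste0(gerp_df$contig, ":", gerp_df$pos)), ]
  constrained <- do.call(rbind, constrained)

  # network: background nodes carry the disease labels so that, at zero
  # effect size, class genes are topologically exchangeable
  bg <- sprintf("B%03d", seq_len(config$n_background))
  n_dis <- round(config$disease_gene_fraction * config$n_background)
  dominant_genes <- bg[seq_len(n_dis %/% 2)]
  recessive_genes <- bg[(n_dis %/% 2 + 1):n_dis]
  edges <- list()
  add_edge <- function(a, b) if (a != b)
    edges[[length(edges) + 1L]] <<- data.frame(from = a, to = b)
  for (b1 in bg) for (b2 in bg) if (b1 < b2 && stats::runif(1) < 0.08)
    add_edge(b1, b2)
  for (g in genes) {
    k <- gene_class[[g]]
    for (b in sample(bg, sample(1:3, 1L))) add_edge(g, b)
    n_dom <- stats::rpois(1, 0.2 + 0.4 * eff * (k == "dominant"))
    n_rec <- stats::rpois(1, 0.2 + 0.4 * eff * (k == "recessive"))
    if (n_dom) for (b in sample(dominant_genes, min(n_dom, length(dominant_genes))))
      add_edge(g, b)
    if (n_rec) for (b in sample(recessive_genes, min(n_rec, length(recessive_genes))))
      add_edge(g, b)
  }
  edges <- unique(do.call(rbind, edges))
  graph <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                         vertices = c(bg, genes))
  graph <- igraph::simplify(graph)

  deg <- igraph::degree(graph)[genes]
  btw <- igraph::betweenness(graph)[genes]
  cls <- suppressWarnings(igraph::closeness(graph))[genes]
  gene_table <- data.frame(
    gene_id = genes,
    dnds_macaque = pmax(0.01, shifted(ng, 0.5, -0.08, eff, offs, 0.08)),
    dnds_mouse = pmax(0.01, shifted(ng, 0.45, -0.08, eff, offs, 0.08)),
    centrality_degree = as.numeric(deg),
    centrality_betweenness = as.numeric(btw),
    centrality_closeness = as.numeric(cls),
    syn_density = pmax(0, shifted(ng, 8, -0.6, eff, offs, 1)),
    nonsyn_density = pmax(0, shifted(ng, 6, -0.8, eff, offs, 1)),
    syn_mean_gerp = shifted(ng, 1.5, 0.4, eff, offs, 0.5),
    nonsyn_mean_gerp = shifted(ng, 2, 0.5, eff, offs, 0.5),
    syn_constrained_pct = pmin(1, pmax(0, shifted(ng, 0.3, 0.05, eff, offs, 0.06))),
    nonsyn_constrained_pct = pmin(1, pmax(0, shifted(ng, 0.35, 0.06, eff, offs, 0.06))),
    cds_constrained_pct = pmin(1, pmax(0, shifted(ng, 0.3, 0.06, eff, offs, 0.06))),
    het_syn = pmax(0, shifted(ng, 0.004, -0.0004, eff, offs, 0.0008)),
    het_nonsyn = pmax(0, shifted(ng, 0.003, -0.0004, eff, offs, 0.0008)),
    mirna_sites = stats::rpois(ng, pmax(0.2, 3 + 0.5 * eff * offs)),
    row.names = NULL)

  # expression: disease genes broader (housekeeping-like), benign spikier
  expression <- matrix(0, ng, 25L, dimnames = list(genes, TISSUE_NAMES))
  housekeeping <- stats::runif(ng) < config$housekeeping_fraction
  for (i in seq_len(ng)) {
    expression[i, ] <- if (housekeeping[i]) stats::runif(25L, 90, 110) else
      stats::rgamma(25L, shape = 1.2 * exp(0.25 * eff * offs[i]), rate = 0.5)
  }

  # ancestral alleles over all CDS bases: reference, except a small fraction
  anc <- list()
  for (tx in txs) {
    pos <- sort(tx$cds_map)
    refb <- strsplit(genome_seq(transcript_set$genome, tx$contig,
                                min(pos), max(pos)), "")[[1]][pos - min(pos) + 1L]
    flip <- stats::runif(length(pos)) < config$ancestral_alt_fraction
    alt <- vapply(refb[flip], function(b)
      sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
    refb[flip] <- alt
    anc[[tx$transcript_id]] <- data.frame(contig = tx$contig, pos = pos,
                                          base = refb)
  }
  anc <- do.call(rbind, anc)
  anc <- anc[!duplicated(paste0(anc$contig, ":", anc$pos)), ]

  # homology tracks
  seg <- list()
  for (ctg in names(transcript_set$genome)) {
    len <- nchar(transcript_set$genome[[ctg]])
    n_seg <- max(1L, len %/% 20000L)
    for (j in seq_len(n_seg)) {
      s <- sample(seq_len(max(1L, len - 1000L)), 1L)
      seg[[length(seg) + 1L]] <- data.frame(contig = ctg, start = s,
                                            end = min(len, s + 999L))
    }
  }
  segdup <- do.call(rbind, seg)
  paralog_genes <- sample(genes, round(0.2 * ng))
  pseudogene_genes <- sample(genes, round(0.1 * ng))

  af <- data.frame(key = character(), af_kg = numeric(), af_esp = numeric(),
                   af_exac = numeric())

  tracks <- structure(list(
    domains = domains,
    gerp = stats::setNames(gerp_df$score, paste0(gerp_df$contig, ":", gerp_df$pos)),
    constrained = constrained,
    edges = edges, graph = graph,
    dominant_genes = dominant_genes, recessive_genes = recessive_genes,
    gene_table = gene_table, expression = expression,
    ancestral = stats::setNames(anc$base, paste0(anc$contig, ":", anc$pos)),
    segdup = segdup, paralog_genes = paralog_genes,
    pseudogene_genes = pseudogene_genes, af = af,
    gene_class = gene_class
  ), class = "AnnotationTracks")
  write_tracks(tracks, dir)
  tracks
}

#' Plant labeled premature-stop variants and assemble the training corpus
#'
#' For every fixture gene, stop-introducing SNVs are enumerated on the
#' gene's longest transcript and sampled with a class-dependent positional
#' bias (benign variants drift toward the 3' end of the CDS, dominant
#' toward the 5' end, scaled by `effect_size`). Benign variants are
#' preferentially entered into the cohort allele-frequency table at higher
#' frequencies. Each planted variant is re-called through the consequence
#' caller, annotated with the full feature bundle, masked with the
#' configured missingness, and split gene-wise into a training corpus and a
#' holdout set.
#'
#' @param config a [fixture_config()].
#' @param transcript_set the fixture `TranscriptSet`.
#' @param tracks the [make_tracks()] result (its allele-frequency table is
#'   filled in and rewritten under `dir`).
#' @param dir output directory (for the updated allele-frequency table and
#'   the variant VCF).
#' @return list: `corpus` and `holdout` (data frames: `label`, `gene_id`,
#'   `transcript_id`, then the 108 registry features), `variants` (the
#'   planted variant table with labels), `vcf` (path), and the updated
#'   `tracks`.
#' @export
make_labeled_variants <- function(config, transcript_set, tracks, dir) {
  set.seed(config$seed + 2L)
  gene_class <- tracks$gene_class
  eff <- config$effect_size
  af_offs <- c(benign = 1, recessive = -0.5, dominant = -1)
  rows <- list(); af_rows <- list()
  vid <- 0L
  for (g in names(gene_class)) {
    k <- gene_class[[g]]
    tx <- longest_transcript(transcript_set, g)
    if (is.null(tx)) next
    cand <- stop_candidates(tx, transcript_set$genome)
    if (!nrow(cand)) next
    a <- 1.5 + eff * if (k == "benign") 0.8 else 0
    b <- 1.5 + eff * if (k == "dominant") 0.5 else 0
    wts <- stats::dbeta(cand$cds_pos / tx$cds_length, a, b) + 1e-9
    n <- min(config$variants_per_gene[[k]], nrow(cand))
    pick <- sample(seq_len(nrow(cand)), n, prob = wts)
    for (i in pick) {
      vid <- vid + 1L
      id <- sprintf("v%05d", vid)
      rows[[vid]] <- data.frame(
        contig = tx$contig, pos = cand$g_pos[i], id = id,
        ref = cand$g_ref[i], alt = cand$g_alt[i], label = k, gene_id = g,
        transcript_id = tx$transcript_id, stringsAsFactors = FALSE)
      p_present <- min(0.95, max(0.02, 0.35 + 0.1 * eff * af_offs[[k]]))
      present <- stats::runif(3) < p_present
      if (any(present)) {
        base_af <- stats::rbeta(3, 1, 20) *
          (1 + 0.5 * eff * max(af_offs[[k]], 0))
        af_rows[[length(af_rows) + 1L]] <- data.frame(
          key = paste(tx$contig, cand$g_pos[i], cand$g_ref[i],
                      cand$g_alt[i], sep = ":"),
          af_kg = ifelse(present[1], pmin(0.5, base_af[1]), NA_real_),
          af_esp = ifelse(present[2], pmin(0.5, base_af[2]), NA_real_),
          af_exac = ifelse(present[3], pmin(0.5, base_af[3]), NA_real_))
      }
    }
  }
  variants <- do.call(rbind, rows)
  tracks$af <- if (length(af_rows)) do.call(rbind, af_rows) else tracks$af
  utils::write.table(tracks$af, file.path(dir, "allele_freq.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  vcf <- file.path(dir, "variants.vcf")
  write_variants_vcf(variants, vcf)

  # annotate: every planted variant must re-call as a premature stop on its
  # transcript
  calls <- list()
  for (i in seq_len(nrow(variants))) {
    cc <- call_consequences(variants[i, ], transcript_set)
    hit <- Filter(function(cl) cl$transcript_id == variants$transcript_id[i] &&
                    cl$category == "premature_stop", cc)
    if (!length(hit))
      stop("planted variant ", variants$id[i], " did not re-call as premature stop")
    calls[[i]] <- hit[[1L]]
  }
  feats <- assemble_corpus(calls, transcript_set, tracks)
  if (config$missingness > 0) {
    mask <- matrix(stats::runif(nrow(feats) * ncol(feats)) < config$missingness,
                   nrow(feats))
    feats[mask] <- NA
  }
  corpus <- cbind(variants[, c("label", "gene_id", "transcript_id")], feats)
  ho_genes <- unlist(lapply(split(names(gene_class), gene_class), function(gs)
    sample(gs, round(config$holdout_fraction * length(gs)))))
  ho <- corpus$gene_id %in% ho_genes
  list(corpus = corpus[!ho, , drop = FALSE],
       holdout = corpus[ho, , drop = FALSE],
       variants = variants, vcf = vcf, tracks = tracks)
}

# All single-base substitutions of a transcript that create a premature
# stop: returns spliced-CDS position plus genomic position/ref/alt.
stop_candidates <- function(tx, genome) {
  cds <- spliced_cds(tx, genome)
  L <- nchar(cds)
  codon_i <- 2:(L %/% 3L - 1L)              # skip start and annotated stop
  starts <- 3L * codon_i - 2L
  codons <- substring(cds, starts, starts + 2L)
  keep <- !codons %in% STOP_CODONS
  codon_i <- codon_i[keep]; codons <- codons[keep]
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(k = seq_along(codon_i), w = 1:3, alt = bases,
                      stringsAsFactors = FALSE)
  ref_b <- substr(codons[grid$k], grid$w, grid$w)
  mut <- codons[grid$k]
  substr(mut, grid$w, grid$w) <- grid$alt
  hit <- ref_b != grid$alt & mut %in% STOP_CODONS
  if (!any(hit))
    return(data.frame(cds_pos = integer(), g_pos = integer(),
                      g_ref = character(), g_alt = character()))
  g <- grid[hit, ]
  cds_pos <- 3L * (codon_i[g$k] - 1L) + g$w
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  minus <- tx$strand == "-"
  out <- data.frame(
    cds_pos = cds_pos, g_pos = tx$cds_map[cds_pos],
    g_ref = if (minus) comp[ref_b[hit]] else ref_b[hit],
    g_alt = if (minus) comp[g$alt] else g$alt,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(out$cds_pos), ]
}

#' Write a variant table as a minimal VCF
#'
#' @param variants data frame with `contig`, `pos`, `id`, `ref`, `alt`.
#' @param path output path.
#' @export
write_variants_vcf <- function(variants, path) {
  hdr <- c("##fileformat=VCFv4.2",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- sprintf("%s\t%d\t%s\t%s\t%s\t.\t.\t.", variants$contig,
                  variants$pos, variants$id, variants$ref, variants$alt)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Generate the complete fixture world in one call
#'
#' Convenience wrapper running [make_reference()], [load_gene_models()],
#' [make_tracks()] and [make_labeled_variants()] under one configuration.
#'
#' @param config a [fixture_config()].
#' @param dir output directory.
#' @return list: `transcript_set`, `tracks`, `corpus`, `holdout`,
#'   `variants`, `paths`.
#' @export
make_fixture_world <- function(config = fixture_config(), dir = tempfile("fixture")) {
  ref <- make_reference(config, dir)
  ts <- load_gene_models(ref$gtf, ref$fasta)
  tracks <- make_tracks(config, ts, dir)
  lv <- make_labeled_variants(config, ts, tracks, dir)
  list(transcript_set = ts, tracks = lv$tracks, corpus = lv$corpus,
       holdout = lv$holdout, variants = lv$variants,
       paths = list(dir = dir, fasta = ref$fasta, gtf = ref$gtf,
                    vcf = lv$vcf))
}
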