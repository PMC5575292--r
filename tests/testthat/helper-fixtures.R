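# Hand-built transcript fixtures and a memoized shared fixture world.

# A TranscriptSet built directly from in-memory pieces (no files).
manual_transcript_set <- function(transcripts, genome) {
  structure(list(transcripts = transcripts, genome = genome,
                 dropped = data.frame(transcript_id = character(),
                                      reason = character())),
            class = "TranscriptSet")
}

# Random sense CDS of n_codons codons: ATG + sense codons + one stop.
random_cds <- function(n_codons, stop = "TAA") {
  sense <- setdiff(apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                                     c("A","C","G","T")),
                         1, paste, collapse = ""), c("TAA","TAG","TGA"))
  paste0("ATG", paste(sample(sense, n_codons - 2, replace = TRUE),
                      collapse = ""), stop)
}

rand_seq <- function(n) paste(sample(c("A","C","G","T"), n, replace = TRUE),
                              collapse = "")

str_revcomp <- function(s)
  paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")

# Build a transcript from a CDS string split into exon chunks with given
# intron lengths; no UTRs (exon == CDS intervals). Returns the transcript,
# a one-contig genome vector, and bookkeeping.
build_tx <- function(cds, chunks, intron_lens, strand = "+",
                     contig = "chrT", tid = "tx1", gid = "g1",
                     offset = 10L, donor = "GT", acceptor = "AG") {
  stopifnot(sum(chunks) == nchar(cds),
            length(intron_lens) == length(chunks) - 1)
  pieces <- character(0); exon_t <- NULL
  cur <- 0L; done <- 0L
  for (i in seq_along(chunks)) {
    pieces <- c(pieces, substr(cds, done + 1L, done + chunks[i]))
    exon_t <- rbind(exon_t, c(cur + 1L, cur + chunks[i]))
    cur <- cur + chunks[i]; done <- done + chunks[i]
    if (i < length(chunks)) {
      il <- intron_lens[i]
      pieces <- c(pieces, paste0(donor, rand_seq(il - 4L), acceptor))
      cur <- cur + il
    }
  }
  seq_t <- paste(pieces, collapse = "")
  M <- nchar(seq_t)
  if (strand == "-") {
    seq_g <- str_revcomp(seq_t)
    exon_g <- cbind(M - exon_t[, 2] + 1L, M - exon_t[, 1] + 1L)
    exon_g <- exon_g[order(exon_g[, 1]), , drop = FALSE]
  } else {
    seq_g <- seq_t; exon_g <- exon_t
  }
  genome <- stats::setNames(paste0(rand_seq(offset), seq_g, rand_seq(10L)),
                            contig)
  iv <- data.frame(start = exon_g[, 1] + offset, end = exon_g[, 2] + offset)
  tx <- new_transcript(tid, gid, contig, strand, iv, iv)
  list(tx = tx, genome = genome, cds = cds,
       set = manual_transcript_set(stats::setNames(list(tx), tid), genome))
}

# Minimal PLoFCall for direct feature/flag tests.
make_call <- function(tx, category = "premature_stop", cds_pos = NA_integer_,
                      pos = NA_integer_, ref = "A", alt = "T",
                      introduced_stop_codon = NA_character_,
                      indel_shift = NA_integer_,
                      intron_index = NA_integer_, intron_pos = NA_integer_) {
  if (is.na(pos) && !is.na(cds_pos)) pos <- tx$cds_map[cds_pos]
  structure(list(
    contig = tx$contig, pos = pos, id = "v1", ref = ref, alt = alt,
    transcript_id = tx$transcript_id, gene_id = tx$gene_id,
    category = category, cds_pos = cds_pos,
    cds_fraction = if (is.na(cds_pos)) NA_real_ else cds_pos / tx$cds_length,
    introduced_stop_codon = introduced_stop_codon, indel_shift = indel_shift,
    intron_index = intron_index, intron_pos = intron_pos
  ), class = "PLoFCall")
}

# Empty-but-valid tracks that can be selectively filled per test.
empty_tracks <- function(genes = character(0)) {
  g <- igraph::make_empty_graph(directed = FALSE)
  structure(list(
    domains = data.frame(transcript_id = character(), kind = character(),
                         start = integer(), end = integer()),
    gerp = stats::setNames(numeric(0), character(0)),
    constrained = data.frame(contig = character(), start = integer(),
                             end = integer()),
    edges = data.frame(from = character(), to = character()),
    graph = g, dominant_genes = character(0), recessive_genes = character(0),
    gene_table = data.frame(gene_id = genes)[0, , drop = FALSE],
    expression = matrix(numeric(0), 0, 25,
                        dimnames = list(NULL, sprintf("expr_t%02d", 1:25))),
    ancestral = stats::setNames(character(0), character(0)),
    segdup = data.frame(contig = character(), start = integer(),
                        end = integer()),
    paralog_genes = character(0), pseudogene_genes = character(0),
    af = data.frame(key = character(), af_kg = numeric(),
                    af_esp = numeric(), af_exac = numeric()),
    gene_class = NULL
  ), class = "AnnotationTracks")
}

# Shared fixture world (separable regime) and a small trained ensemble,
# built once per test run.
.shared <- new.env(parent = emptyenv())

shared_world <- function() {
  if (is.null(.shared$world)) {
    dir <- file.path(tempdir(), "plofpred-shared-world")
    .shared$world <- make_fixture_world(fixture_config(seed = 101L), dir)
  }
  .shared$world
}

shared_mini_model <- function() {
  if (is.null(.shared$model)) {
    w <- shared_world()
    .shared$model <- train_ensemble(w$corpus, n_replicates = 3L,
                                    ntree = 150L, base_seed = 11L,
                                    cv = FALSE)
  }
  .shared$model
}
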