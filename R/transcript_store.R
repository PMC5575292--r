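#' @importFrom stats sd setNames rnorm runif rbinom quantile
#' @importFrom utils read.table write.table head tail
NULL

STOP_CODONS <- c("TAA", "TAG", "TGA")

#' Construct a transcript model
#'
#' A transcript is the unit of coordinate arithmetic for all downstream
#' annotation: it carries its exon and CDS intervals (1-based, closed, in
#' genomic order, per GTF convention) plus precomputed position maps between
#' the genome, the spliced transcript, and the spliced coding sequence.
#' The stop codon is expected to be included in the CDS intervals.
#'
#' @param transcript_id,gene_id identifiers.
#' @param contig contig name; must exist in the accompanying genome.
#' @param strand `"+"` or `"-"`.
#' @param exons,cds data frames with integer columns `start`, `end`
#'   (1-based closed genomic intervals).
#' @return an object of class `"plof_transcript"`.
#' @export
new_transcript <- function(transcript_id, gene_id, contig, strand, exons, cds) {
  stopifnot(strand %in% c("+", "-"), nrow(exons) >= 1L, nrow(cds) >= 1L)
  exons <- exons[order(exons$start), c("start", "end"), drop = FALSE]
  cds <- cds[order(cds$start), c("start", "end"), drop = FALSE]
  if (any(exons$end < exons$start) || any(cds$end < cds$start))
    stop("interval with end < start in transcript ", transcript_id)
  if (nrow(exons) > 1L && any(exons$start[-1L] <= exons$end[-nrow(exons)]))
    stop("overlapping exons in transcript ", transcript_id)
  # every CDS interval must sit inside one exon
  for (i in seq_len(nrow(cds))) {
    if (!any(exons$start <= cds$start[i] & exons$end >= cds$end[i]))
      stop("CDS interval outside exons in transcript ", transcript_id)
  }
  expand <- function(iv) unlist(lapply(seq_len(nrow(iv)),
                                       function(i) iv$start[i]:iv$end[i]), use.names = FALSE)
  exon_map <- expand(exons)   # genomic position of each spliced-transcript base
  cds_map <- expand(cds)      # genomic position of each spliced-CDS base
  if (strand == "-") {
    exon_map <- rev(exon_map)
    cds_map <- rev(cds_map)
  }
  structure(list(
    transcript_id = transcript_id, gene_id = gene_id,
    contig = contig, strand = strand,
    exons = exons, cds = cds,
    exon_map = exon_map, cds_map = cds_map,
    cds_length = length(cds_map)
  ), class = "plof_transcript")
}

#' @export
print.plof_transcript <- function(x, ...) {
  cat(sprintf("<transcript %s (gene %s) %s:%s %d exons, CDS %d nt>\n",
              x$transcript_id, x$gene_id, x$contig, x$strand,
              nrow(x$exons), x$cds_length))
  invisible(x)
}

#' Load genome and gene models
#'
#' Reads a genome FASTA and an Ensembl-dialect GTF (exon and CDS features,
#' `gene_id`/`transcript_id` attributes) and returns an indexed transcript
#' set. Transcripts whose CDS is malformed (outside exons, length not a
#' multiple of three, or containing an internal stop codon) are dropped with
#' a warning; a missing contig is a fatal error.
#'
#' @param gtf_path path to GTF file.
#' @param fasta_path path to genome FASTA.
#' @return an object of class `"TranscriptSet"`: a list with `transcripts`
#'   (named list of [new_transcript()] objects), `genome`
#'   (`Biostrings::DNAStringSet`), and `dropped` (data frame of discarded
#'   transcripts with reasons).
#' @export
load_gene_models <- function(gtf_path, fasta_path) {
  dss <- Biostrings::readDNAStringSet(fasta_path)
  genome <- toupper(as.character(dss))           # plain strings: fast substr
  names(genome) <- sub("\\s.*$", "", names(dss))
  gtf <- rtracklayer::import(gtf_path, format = "gtf")
  gtf <- gtf[gtf$type %in% c("exon", "CDS")]
  df <- data.frame(
    contig = as.character(GenomicRanges::seqnames(gtf)),
    start = GenomicRanges::start(gtf), end = GenomicRanges::end(gtf),
    strand = as.character(GenomicRanges::strand(gtf)),
    type = as.character(gtf$type),
    transcript_id = gtf$transcript_id, gene_id = gtf$gene_id,
    stringsAsFactors = FALSE)
  missing_contig <- setdiff(unique(df$contig), names(genome))
  if (length(missing_contig))
    stop("contig(s) absent from FASTA: ", paste(missing_contig, collapse = ", "))

  transcripts <- list()
  dropped <- data.frame(transcript_id = character(), reason = character())
  for (tid in unique(df$transcript_id)) {
    sub <- df[df$transcript_id == tid, ]
    ex <- sub[sub$type == "exon", ]
    cd <- sub[sub$type == "CDS", ]
    if (nrow(cd) == 0L) next  # non-coding: not in scope
    tx <- tryCatch(
      new_transcript(tid, sub$gene_id[1L], sub$contig[1L], sub$strand[1L],
                     ex[, c("start", "end")], cd[, c("start", "end")]),
      error = function(e) conditionMessage(e))
    if (is.character(tx)) {
      warning("dropping transcript ", tid, ": ", tx, call. = FALSE)
      dropped <- rbind(dropped, data.frame(transcript_id = tid, reason = tx))
      next
    }
    reason <- validate_cds(tx, genome)
    if (!is.null(reason)) {
      warning("dropping transcript ", tid, ": ", reason, call. = FALSE)
      dropped <- rbind(dropped, data.frame(transcript_id = tid, reason = reason))
      next
    }
    transcripts[[tid]] <- tx
  }
  structure(list(transcripts = transcripts, genome = genome, dropped = dropped),
            class = "TranscriptSet")
}

#' @export
print.TranscriptSet <- function(x, ...) {
  cat(sprintf("<TranscriptSet: %d transcripts on %d contig(s), %d dropped>\n",
              length(x$transcripts), length(x$genome), nrow(x$dropped)))
  invisible(x)
}

validate_cds <- function(tx, genome) {
  if (tx$cds_length %% 3L != 0L)
    return(sprintf("CDS length %d not divisible by 3", tx$cds_length))
  cds <- spliced_cds(tx, genome)
  n_codon <- nchar(cds) %/% 3L
  starts <- 3L * seq_len(n_codon - 1L) - 2L       # all but the final codon
  codons <- substring(cds, starts, starts + 2L)
  if (any(codons %in% STOP_CODONS))
    return("internal stop codon in spliced CDS")
  NULL
}

#' Spliced coding sequence of a transcript
#'
#' @param tx a `plof_transcript`.
#' @param genome named character vector of contig sequences (the `genome`
#'   element of a [load_gene_models()] result).
#' @return upper-case character string, 5'->3' in translation orientation.
#' @export
spliced_cds <- function(tx, genome) {
  parts <- substring(genome[[tx$contig]], tx$cds$start, tx$cds$end)
  s <- paste(parts, collapse = "")
  if (tx$strand == "-") s <- revcomp(s)
  s
}

#' Map a genomic position into spliced-CDS coordinates
#'
#' @param tx a `plof_transcript`.
#' @param genomic_pos 1-based genomic position on the transcript's contig.
#' @param contig optional contig name; an error is raised if it differs from
#'   the transcript's contig.
#' @return a list with `cds_pos` (1-based offset into the spliced CDS, in
#'   translation order) and `cds_fraction` (`cds_pos / cds_length`), or
#'   `NULL` when the position does not fall in the CDS.
#' @export
genomic_to_cds <- function(tx, genomic_pos, contig = NULL) {
  if (!is.null(contig) && contig != tx$contig)
    stop("position on contig ", contig, " but transcript is on ", tx$contig)
  i <- match(genomic_pos, tx$cds_map)
  if (is.na(i)) return(NULL)
  list(cds_pos = i, cds_fraction = i / tx$cds_length)
}

#' Map a spliced-CDS position back to the genome
#'
#' Inverse of [genomic_to_cds()].
#' @param tx a `plof_transcript`.
#' @param cds_pos 1-based position in the spliced CDS.
#' @return 1-based genomic position.
#' @export
cds_to_genomic <- function(tx, cds_pos) {
  stopifnot(cds_pos >= 1L, cds_pos <= tx$cds_length)
  tx$cds_map[cds_pos]
}

#' Distance from a CDS position to the last exon-exon junction
#'
#' Measured in spliced-transcript nucleotides: positive when the position
#' lies upstream (5') of the junction, zero when it is the last base of the
#' penultimate exon, negative inside the final exon. The premature-stop NMD
#' rule asks whether this distance, taken at the first base of the stop
#' codon, exceeds 50 nt.
#'
#' @param tx a `plof_transcript`.
#' @param cds_pos 1-based spliced-CDS position.
#' @return integer distance, or `NA` for single-exon transcripts.
#' @export
distance_to_last_junction <- function(tx, cds_pos) {
  n_ex <- nrow(tx$exons)
  if (n_ex < 2L) return(NA_integer_)
  stopifnot(cds_pos >= 1L, cds_pos <= tx$cds_length)
  ex_len <- tx$exons$end - tx$exons$start + 1L
  if (tx$strand == "-") ex_len <- rev(ex_len)      # translation order
  junction <- sum(ex_len[-n_ex])                   # spliced pos of last base before final exon
  tx_pos <- match(tx$cds_map[cds_pos], tx$exon_map)
  junction - tx_pos
}

#' Intron lengths of a transcript
#'
#' @param tx a `plof_transcript`.
#' @return integer vector of length `n_exons - 1`: gaps between consecutive
#'   exons in genomic order (empty for single-exon transcripts).
#' @export
intron_lengths <- function(tx) {
  n <- nrow(tx$exons)
  if (n < 2L) return(integer(0))
  tx$exons$start[-1L] - tx$exons$end[-n] - 1L
}

#' Select the longest transcript of a gene
#'
#' Used when constructing training sets, where a single representative
#' (longest-CDS) transcript per gene is preferred.
#'
#' @param transcript_set a `TranscriptSet`.
#' @param gene_id gene identifier.
#' @return a `plof_transcript`, or `NULL` when the gene has none.
#' @export
longest_transcript <- function(transcript_set, gene_id) {
  txs <- Filter(function(t) t$gene_id == gene_id, transcript_set$transcripts)
  if (!length(txs)) return(NULL)
  txs[[which.max(vapply(txs, function(t) t$cds_length, integer(1)))]]
}

#' Transcripts overlapping a genomic window
#'
#' @param transcript_set a `TranscriptSet`.
#' @param contig contig name.
#' @param start,end 1-based closed window.
#' @param pad extra bases added on both sides (default 2, the canonical
#'   splice positions).
#' @return list of `plof_transcript`.
#' @export
overlapping_transcripts <- function(transcript_set, contig, start, end, pad = 2L) {
  Filter(function(t) {
    t$contig == contig &&
      min(t$exons$start) - pad <= end && max(t$exons$end) + pad >= start
  }, transcript_set$transcripts)
}
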