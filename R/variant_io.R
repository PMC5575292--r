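#' Read variants from VCF or a 5-column tab-delimited file
#'
#' Multi-allelic records are decomposed into one variant per alternate
#' allele, and every variant is checked against the genome and normalized
#' (shared prefix/suffix trimmed, indels left-aligned, minimal
#' representation). Records whose reference allele does not match the genome
#' and unparseable lines are skipped with a warning.
#'
#' @param path input file.
#' @param genome a named character vector of contig sequences.
#' @param format `"vcf"`, `"tab5"` (chromosome, position, ID, ref, alt), or
#'   `"auto"` (by file extension).
#' @return data frame with columns `contig`, `pos`, `id`, `ref`, `alt`.
#' @export
read_variants <- function(path, genome, format = c("auto", "vcf", "tab5")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.vcf(\\.gz)?$", path)) "vcf" else "tab5"
  if (format == "vcf") {
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)  # stays a matrix for 1 record
    raw <- data.frame(contig = fix$CHROM, pos = as.integer(fix$POS),
                      id = ifelse(is.na(fix$ID), ".", fix$ID),
                      ref = fix$REF, alt = fix$ALT, stringsAsFactors = FALSE)
  } else {
    raw <- utils::read.table(path, sep = "\t", header = FALSE,
                             colClasses = "character", comment.char = "#")
    if (ncol(raw) < 5L) stop("tab5 input needs 5 columns, got ", ncol(raw))
    raw <- data.frame(contig = raw[[1L]], pos = suppressWarnings(as.integer(raw[[2L]])),
                      id = raw[[3L]], ref = raw[[4L]], alt = raw[[5L]],
                      stringsAsFactors = FALSE)
  }
  out <- list()
  for (i in seq_len(nrow(raw))) {
    r <- raw[i, ]
    if (is.na(r$pos) || is.na(r$alt)) {
      warning("skipping unparseable record at line ", i, call. = FALSE)
      next
    }
    for (alt in strsplit(toupper(r$alt), ",", fixed = TRUE)[[1L]]) {
      ref <- toupper(r$ref)
      if (!grepl("^[ACGT]+$", ref) || !grepl("^[ACGT]+$", alt) || ref == alt) {
        warning("skipping non-sequence allele ", ref, ">", alt,
                " at ", r$contig, ":", r$pos, call. = FALSE)
        next
      }
      if (!r$contig %in% names(genome) ||
          r$pos + nchar(ref) - 1L > nchar(genome[[r$contig]]) ||
          genome_seq(genome, r$contig, r$pos, r$pos + nchar(ref) - 1L) != ref) {
        warning("reference mismatch at ", r$contig, ":", r$pos,
                " (", ref, "); record skipped", call. = FALSE)
        next
      }
      n <- normalize_variant(r$contig, r$pos, ref, alt, genome)
      out[[length(out) + 1L]] <- data.frame(
        contig = r$contig, pos = n$pos, id = r$id, ref = n$ref, alt = n$alt,
        stringsAsFactors = FALSE)
    }
  }
  v <- if (length(out)) do.call(rbind, out) else
    data.frame(contig = character(), pos = integer(), id = character(),
               ref = character(), alt = character())
  rownames(v) <- NULL
  v
}

genome_seq <- function(genome, contig, start, end) {
  substr(genome[[contig]], start, end)
}

#' Normalize a variant to minimal left-aligned representation
#'
#' Standard variant normalization: the shared suffix is trimmed (extending
#' left through matching reference sequence for indels, i.e. left-aligning
#' them), then the shared prefix is trimmed. SNVs come back unchanged.
#'
#' @param contig,pos,ref,alt the variant (ref must match the genome at pos).
#' @param genome named character vector of contig sequences.
#' @return list with `pos`, `ref`, `alt`.
#' @export
normalize_variant <- function(contig, pos, ref, alt, genome) {
  repeat {
    nr <- nchar(ref); na <- nchar(alt)
    if (nr > 0L && na > 0L &&
        substr(ref, nr, nr) == substr(alt, na, na) && !(nr == 1L && na == 1L)) {
      ref <- substr(ref, 1L, nr - 1L)
      alt <- substr(alt, 1L, na - 1L)
    } else if (nr == 0L || na == 0L) {
      if (pos <= 1L) stop("cannot left-extend allele past contig start")
      pos <- pos - 1L
      b <- genome_seq(genome, contig, pos, pos)
      ref <- paste0(b, ref)
      alt <- paste0(b, alt)
    } else break
  }
  while (nchar(ref) > 1L && nchar(alt) > 1L &&
         substr(ref, 1L, 1L) == substr(alt, 1L, 1L)) {
    ref <- substr(ref, 2L, nchar(ref))
    alt <- substr(alt, 2L, nchar(alt))
    pos <- pos + 1L
  }
  list(pos = pos, ref = ref, alt = alt)
}

revcomp <- function(s) {
  if (nchar(s) == 1L) return(chartr("ACGTN", "TGCAN", s))
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "", fixed = TRUE)[[1L]]),
        collapse = "")
}

#' Call pLoF consequences of a variant on all overlapping transcripts
#'
#' For each transcript overlapping the variant, classifies it as one of
#' `premature_stop` (SNV whose alternate codon translates to TAA/TAG/TGA and
#' whose reference codon is not already a stop), `frameshift` (indel fully
#' inside the CDS with length change not a multiple of 3), or
#' `splice_donor`/`splice_acceptor` (SNV at one of the two canonical
#' intronic positions at either intron end, resolved in transcript
#' orientation). Anything else yields no call; indels spanning a CDS/intron
#' boundary are recorded as splice-region events in the `skipped` attribute
#' but produce no call.
#'
#' @param variant one-row data frame (or list) with `contig`, `pos`, `id`,
#'   `ref`, `alt`; must be normalized.
#' @param transcript_set a `TranscriptSet`.
#' @return list of `PLoFCall` objects (possibly empty), with attribute
#'   `skipped` describing boundary-spanning indels.
#' @export
call_consequences <- function(variant, transcript_set) {
  v <- as.list(variant)
  genome <- transcript_set$genome
  span_end <- v$pos + nchar(v$ref) - 1L
  txs <- overlapping_transcripts(transcript_set, v$contig, v$pos, span_end)
  calls <- list()
  skipped <- character()
  for (tx in txs) {
    if (nchar(v$ref) == 1L && nchar(v$alt) == 1L) {
      cl <- call_snv(v, tx, genome)
    } else {
      cl <- call_indel(v, tx, genome)
      if (is.character(cl)) { skipped <- c(skipped, cl); cl <- NULL }
    }
    if (!is.null(cl)) calls[[length(calls) + 1L]] <- cl
  }
  attr(calls, "skipped") <- skipped
  calls
}

new_plof_call <- function(v, tx, category, cds_pos = NA_integer_,
                          introduced_stop_codon = NA_character_,
                          indel_shift = NA_integer_,
                          intron_index = NA_integer_, intron_pos = NA_integer_) {
  structure(list(
    contig = v$contig, pos = v$pos, id = v$id, ref = v$ref, alt = v$alt,
    transcript_id = tx$transcript_id, gene_id = tx$gene_id,
    category = category, cds_pos = cds_pos,
    cds_fraction = if (is.na(cds_pos)) NA_real_ else cds_pos / tx$cds_length,
    introduced_stop_codon = introduced_stop_codon, indel_shift = indel_shift,
    intron_index = intron_index, intron_pos = intron_pos
  ), class = "PLoFCall")
}

call_snv <- function(v, tx, genome) {
  m <- genomic_to_cds(tx, v$pos)
  if (!is.null(m)) {
    cds <- spliced_cds(tx, genome)
    alt_tx <- if (tx$strand == "-") revcomp(v$alt) else v$alt
    codon_i <- (m$cds_pos - 1L) %/% 3L + 1L
    codon <- substr(cds, 3L * codon_i - 2L, 3L * codon_i)
    within <- m$cds_pos - (3L * codon_i - 3L)
    new_codon <- codon
    substr(new_codon, within, within) <- alt_tx
    if (codon %in% STOP_CODONS) return(NULL)    # reference stop: not a gain
    if (!new_codon %in% STOP_CODONS) return(NULL)
    return(new_plof_call(v, tx, "premature_stop", cds_pos = m$cds_pos,
                         introduced_stop_codon = new_codon))
  }
  sp <- splice_site_of(tx, v$pos)
  if (is.null(sp)) return(NULL)
  new_plof_call(v, tx, paste0("splice_", sp$end),
                intron_index = sp$intron, intron_pos = sp$intron_pos)
}

# Which canonical splice position (if any) a genomic position occupies.
# Donor = first two intron bases in transcript orientation, acceptor = last
# two; intron index is in genomic order.
splice_site_of <- function(tx, pos) {
  n <- nrow(tx$exons)
  if (n < 2L) return(NULL)
  for (i in seq_len(n - 1L)) {
    s <- tx$exons$end[i] + 1L
    e <- tx$exons$start[i + 1L] - 1L
    if (pos < s || pos > e) next
    if (tx$strand == "+") {
      donor <- c(s, s + 1L); acceptor <- c(e, e - 1L)
    } else {
      donor <- c(e, e - 1L); acceptor <- c(s, s + 1L)
    }
    if (pos %in% donor)
      return(list(end = "donor", intron = i, intron_pos = match(pos, donor)))
    if (pos %in% acceptor)
      return(list(end = "acceptor", intron = i, intron_pos = match(pos, acceptor)))
    return(NULL)
  }
  NULL
}

call_indel <- function(v, tx, genome) {
  len_ref <- nchar(v$ref); len_alt <- nchar(v$alt)
  shift <- abs(len_ref - len_alt) %% 3L
  if (len_ref > 1L) {
    # deletion (or complex): changed reference bases after the anchor
    changed <- (v$pos + 1L):(v$pos + len_ref - 1L)
    in_cds <- !is.na(match(changed, tx$cds_map))
    if (!any(in_cds)) return(NULL)
    if (!all(in_cds))
      return(sprintf("%s:%d %s>%s spans a CDS boundary in %s (splice-region, not called)",
                     v$contig, v$pos, v$ref, v$alt, tx$transcript_id))
    if (shift == 0L) return(NULL)                 # in-frame
    anchor <- min(match(changed, tx$cds_map))
  } else {
    # pure insertion between pos and pos+1
    i1 <- match(v$pos, tx$cds_map); i2 <- match(v$pos + 1L, tx$cds_map)
    if (is.na(i1) || is.na(i2)) return(NULL)
    if (abs(i1 - i2) != 1L) return(NULL)          # insertion point hits a junction
    if (shift == 0L) return(NULL)
    anchor <- min(i1, i2) + 1L
  }
  new_plof_call(v, tx, "frameshift", cds_pos = anchor, indel_shift = shift)
}

#' Tabulate a list of pLoF calls
#'
#' @param calls list of `PLoFCall` objects.
#' @return data frame with one row per call.
#' @export
calls_to_df <- function(calls) {
  cols <- c("contig", "pos", "id", "ref", "alt", "transcript_id", "gene_id",
            "category", "cds_pos", "cds_fraction", "introduced_stop_codon",
            "indel_shift", "intron_index", "intron_pos")
  if (!length(calls))
    return(stats::setNames(data.frame(matrix(nrow = 0, ncol = length(cols))), cols))
  do.call(rbind, lapply(calls, function(cl)
    as.data.frame(cl[cols], stringsAsFactors = FALSE)))
}
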