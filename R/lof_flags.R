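FLAG_VOCABULARY <- c("lof_anc", "near_start", "near_end", "alt_canonical_site",
                     "noncanonical_splice_flank", "small_intron",
                     "segdup", "paralog", "pseudogene")

# Reference donor/acceptor dinucleotides of intron i, transcript orientation.
intron_dinucs <- function(tx, genome, i) {
  s <- tx$exons$end[i] + 1L
  e <- tx$exons$start[i + 1L] - 1L
  if (e - s + 1L < 2L) return(list(donor = NA, acceptor = NA))
  if (tx$strand == "+") {
    list(donor = genome_seq(genome, tx$contig, s, s + 1L),
         acceptor = genome_seq(genome, tx$contig, e - 1L, e))
  } else {
    list(donor = revcomp(genome_seq(genome, tx$contig, e - 1L, e)),
         acceptor = revcomp(genome_seq(genome, tx$contig, s, s + 1L)))
  }
}

intron_is_canonical <- function(tx, genome, i) {
  d <- intron_dinucs(tx, genome, i)
  identical(d$donor, "GT") && identical(d$acceptor, "AG")
}

#' Annotation-artifact and mismapping flags for a pLoF call
#'
#' Emits the subset of the closed flag vocabulary that applies to a call:
#' \describe{
#'   \item{lof_anc}{the alternate allele equals the ancestral allele at the
#'     site (the "LoF" allele is the evolutionarily conserved state, so the
#'     call is likely a reference-annotation artifact); absent when no
#'     ancestral allele is known.}
#'   \item{near_start}{the variant lies in the first 5\% of the coding
#'     sequence (`cds_fraction <= 0.05`).}
#'   \item{near_end}{the variant lies in the last 5\%
#'     (`cds_fraction > 0.95`).}
#'   \item{alt_canonical_site}{a splice-site SNV whose alternate allele
#'     makes the site canonical (GT at the donor, AG at the acceptor, in
#'     transcript orientation) -- i.e. the variant restores rather than
#'     destroys the splice site.}
#'   \item{noncanonical_splice_flank}{the exon adjacent to the call is
#'     flanked by at least one non-GT..AG intron, suggesting a spurious exon
#'     model.}
#'   \item{small_intron}{the splice call's intron is shorter than 15 nt.}
#'   \item{segdup, paralog, pseudogene}{the site falls in a segmental
#'     duplication, or the gene has paralogs / pseudogenes, per the supplied
#'     homology tracks.}
#' }
#'
#' @param call a `PLoFCall`.
#' @param tx the matching `plof_transcript`.
#' @param tracks an `AnnotationTracks` object (uses `ancestral`, `segdup`,
#'   `paralog_genes`, `pseudogene_genes`).
#' @param genome named character vector of contig sequences.
#' @return character vector: a subset of
#'   `c("lof_anc", "near_start", "near_end", "alt_canonical_site",
#'   "noncanonical_splice_flank", "small_intron", "segdup", "paralog",
#'   "pseudogene")`.
#' @export
flag_call <- function(call, tx, tracks, genome) {
  flags <- character()
  if (nchar(call$ref) == 1L && nchar(call$alt) == 1L) {
    anc <- tracks$ancestral[paste0(call$contig, ":", call$pos)]
    if (!is.na(anc) && toupper(anc) == call$alt) flags <- c(flags, "lof_anc")
  }
  if (!is.na(call$cds_fraction)) {
    if (call$cds_fraction <= 0.05) flags <- c(flags, "near_start")
    if (call$cds_fraction > 0.95) flags <- c(flags, "near_end")
  }
  splice <- call$category %in% c("splice_donor", "splice_acceptor")
  if (splice) {
    i <- call$intron_index
    d <- intron_dinucs(tx, genome, i)
    site <- if (call$category == "splice_donor") d$donor else d$acceptor
    if (!all(is.na(site))) {
      # substitute the alt allele at its position within the dinucleotide;
      # intron_pos counts from the adjacent exon, so for the acceptor it
      # indexes the dinucleotide from its right end
      base_tx <- if (tx$strand == "-") revcomp(call$alt) else call$alt
      chr_i <- if (call$category == "splice_donor") call$intron_pos else
        3L - call$intron_pos
      mut <- site
      substr(mut, chr_i, chr_i) <- base_tx
      want <- if (call$category == "splice_donor") "GT" else "AG"
      if (mut == want) flags <- c(flags, "alt_canonical_site")
    }
    if (intron_lengths(tx)[i] < 15L) flags <- c(flags, "small_intron")
  }
  ex <- adjacent_exon(call, tx)
  if (!is.na(ex)) {
    flank <- intersect(c(ex - 1L, ex), seq_len(nrow(tx$exons) - 1L))
    if (length(flank) &&
        !all(vapply(flank, function(i) intron_is_canonical(tx, genome, i),
                    logical(1))))
      flags <- c(flags, "noncanonical_splice_flank")
  }
  if (any(in_intervals(call$contig, affected_positions(call), tracks$segdup)))
    flags <- c(flags, "segdup")
  if (call$gene_id %in% tracks$paralog_genes) flags <- c(flags, "paralog")
  if (call$gene_id %in% tracks$pseudogene_genes) flags <- c(flags, "pseudogene")
  flags
}

# Genomic-order index of the exon a call is in (exonic calls) or adjacent
# to (splice calls); NA when undetermined.
adjacent_exon <- function(call, tx) {
  if (!is.na(call$cds_pos)) {
    g <- tx$cds_map[call$cds_pos]
    return(which(tx$exons$start <= g & tx$exons$end >= g)[1L])
  }
  if (!is.na(call$intron_index)) {
    # donor abuts the intron's transcript-upstream exon
    upstream <- (call$category == "splice_donor") == (tx$strand == "+")
    return(if (upstream) call$intron_index else call$intron_index + 1L)
  }
  NA_integer_
}
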