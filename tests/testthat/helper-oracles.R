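# Independent brute-force oracles. These deliberately avoid the package's
# own code paths: string slicing, O(n^2) pair enumeration, naive BFS.

# Hand-spliced CDS by direct string slicing on the contig.
oracle_spliced_cds <- function(contig_seq, cds_df, strand) {
  parts <- vapply(seq_len(nrow(cds_df)), function(i)
    substr(contig_seq, cds_df$start[i], cds_df$end[i]), character(1))
  s <- paste(parts, collapse = "")
  if (strand == "-") s <- str_revcomp(s)
  s
}

# Premature-stop oracle by full re-translation of the mutated spliced CDS:
# an SNV is a premature stop iff the mutated protein gains an internal stop
# at a position where the reference protein had none. Batch form: one
# translate call over all mutated sequences.
oracle_premature_stop_batch <- function(cds, cds_pos, alt_tx) {
  muts <- vapply(seq_along(cds_pos), function(i) {
    m <- cds
    substr(m, cds_pos[i], cds_pos[i]) <- alt_tx[i]
    m
  }, character(1))
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(c(cds, muts)), if.fuzzy.codon = "X"))
  aa_ref <- strsplit(aa[1], "")[[1]]
  n <- length(aa_ref)
  internal_ref <- aa_ref[-n] == "*"
  vapply(aa[-1], function(a) {
    aa_mut <- strsplit(a, "")[[1]]
    any(aa_mut[-n] == "*" & !internal_ref)
  }, logical(1), USE.NAMES = FALSE)
}

# Minimal left-aligned representation derived from the edited sequence
# alone (never looks at the input alleles).
oracle_normalize <- function(contig_seq, pos, ref, alt) {
  R <- contig_seq
  E <- paste0(substr(R, 1, pos - 1), alt,
              substr(R, pos + nchar(ref), nchar(R)))
  nR <- nchar(R); nE <- nchar(E)
  s <- 0L
  while (s < min(nR, nE) &&
         substr(R, nR - s, nR - s) == substr(E, nE - s, nE - s)) s <- s + 1L
  if (nR - s == 0L || nE - s == 0L) s <- s - 1L   # keep alleles non-empty
  r2 <- substr(R, 1, nR - s); e2 <- substr(E, 1, nE - s)
  p <- 1L
  while (nchar(r2) > 1L && nchar(e2) > 1L &&
         substr(r2, 1, 1) == substr(e2, 1, 1)) {
    r2 <- substr(r2, 2, nchar(r2)); e2 <- substr(e2, 2, nchar(e2))
    p <- p + 1L
  }
  list(pos = p, ref = r2, alt = e2)
}

# Unweighted BFS distances from one source over an edge list.
oracle_bfs <- function(edges, from, targets) {
  adj <- split(c(edges$to, edges$from), c(edges$from, edges$to))
  if (!from %in% names(adj)) return(NA_real_)
  if (from %in% targets) return(0)
  dist <- stats::setNames(0, from)
  frontier <- from
  d <- 0
  while (length(frontier)) {
    d <- d + 1
    nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)),
                   names(dist))
    if (!length(nxt)) return(NA_real_)
    if (any(nxt %in% targets)) return(d)
    dist[nxt] <- d
    frontier <- nxt
  }
  NA_real_
}

# O(n^2) pairwise Hand-and-Till AUC.
oracle_hand_till <- function(labels, probs) {
  labels <- as.character(labels)
  classes <- intersect(colnames(probs), unique(labels))
  a_hat <- function(i, j) {
    si <- probs[labels == i, i]; sj <- probs[labels == j, i]
    tot <- 0
    for (a in si) for (b in sj)
      tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(si) * length(sj))
  }
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  mean(vapply(pairs, function(p)
    (a_hat(p[1], p[2]) + a_hat(p[2], p[1])) / 2, numeric(1)))
}

# Shannon-entropy tissue specificity, written independently.
oracle_specificity <- function(x) {
  p <- x / sum(x)
  h <- 0
  for (pi in p) if (pi > 0) h <- h - pi * log(pi, base = 2)
  1 - h / log(length(x), base = 2)
}

# Confidence label by explicit interval arithmetic.
oracle_confidence <- function(means, sds, n) {
  lo <- means - 1.96 * sds / sqrt(n)
  hi <- means + 1.96 * sds / sqrt(n)
  k <- which.max(means)
  if (any(lo[k] <= hi[-k])) "Low" else "High"
}

# Per-class precision/recall from an explicit contingency table.
oracle_precision_recall <- function(labels, predicted, class) {
  tab <- table(factor(labels, levels = unique(c(labels, predicted))),
               factor(predicted, levels = unique(c(labels, predicted))))
  tp <- tab[class, class]
  fp <- sum(tab[, class]) - tp
  fn <- sum(tab[class, ]) - tp
  c(precision = if (tp + fp == 0) NA_real_ else tp / (tp + fp),
    recall = if (tp + fn == 0) NA_real_ else tp / (tp + fn))
}
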