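# Independent oracles used across the suite. These deliberately avoid the
# package's own k-mer / MCL code paths.

# brute-force canonical k-mer set of a sequence, as strings
oracle_kmers <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(character(0))
  kms <- substring(seq, 1:(n - k + 1), k:n)
  kms <- kms[!grepl("[^ACGT]", kms)]
  rc <- vapply(kms, function(x)
    paste(rev(chartr("ACGT", "TGCA", strsplit(x, "")[[1]])), collapse = ""),
    character(1), USE.NAMES = FALSE)
  unique(pmin(kms, rc))
}

oracle_containment <- function(a, b, k) {
  ka <- oracle_kmers(a, k); kb <- oracle_kmers(b, k)
  if (length(ka) == 0 || length(kb) == 0) return(0)
  length(intersect(ka, kb)) / min(length(ka), length(kb))
}

# dense-matrix MCL reference: plain matrix arithmetic, run to convergence,
# no pruning; cluster read-out by column support of attractor rows
oracle_mcl <- function(A, inflation = 4, expansion = 2, max_iter = 200,
                       tol = 1e-10) {
  n <- nrow(A)
  mx <- apply(A, 2, max)
  diag(A) <- ifelse(mx > 0, mx, 1)
  M <- sweep(A, 2, colSums(A), "/")
  for (it in seq_len(max_iter)) {
    E <- M
    for (e in seq_len(expansion - 1)) E <- E %*% M
    Inf_ <- E^inflation
    Mn <- sweep(Inf_, 2, colSums(Inf_), "/")
    if (max(abs(Mn - M)) < tol) { M <- Mn; break }
    M <- Mn
  }
  attr_rows <- which(diag(M) > 1e-7)
  clusters <- list()
  assigned <- rep(NA_integer_, n)
  for (a in attr_rows) {
    support <- which(M[a, ] > 1e-7)
    hit <- stats::na.omit(unique(assigned[support]))
    if (length(hit)) {
      ci <- hit[1]
      clusters[[ci]] <- sort(unique(c(clusters[[ci]], support, a)))
      assigned[support] <- ci
    } else {
      clusters[[length(clusters) + 1]] <- sort(unique(c(support, a)))
      assigned[support] <- length(clusters)
    }
  }
  for (j in which(is.na(assigned))) {
    clusters[[length(clusters) + 1]] <- j
    assigned[j] <- length(clusters)
  }
  unname(lapply(clusters, sort))
}

# canonical form of a partition (list of member vectors) for comparison
canon_partition <- function(groups) {
  gs <- lapply(groups, function(g) sort(as.character(g)))
  gs[order(vapply(gs, `[`, character(1), 1))]
}

# build an alignment table row-by-row for the score unit tests
make_aln <- function(...) {
  rows <- list(...)
  base <- list(read_id = "r", contig_id = "c", pos = 0L, aligned_len = 100L,
               n_match = 100L, n_mismatch = 0L, is_primary = TRUE,
               is_mapped = TRUE, is_reverse = FALSE, is_first = TRUE,
               mate_contig_id = NA_character_, mate_pos = NA_integer_,
               mate_is_reverse = NA, template_len = NA_integer_)
  do.call(rbind, lapply(rows, function(r) {
    as.data.frame(utils::modifyList(base, r), stringsAsFactors = FALSE)
  }))
}

random_seq <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# construct a truth_set directly (for targeted read-simulation tests)
make_truth <- function(ids, seqs, tpm, genes = ids) {
  structure(list(
    transcripts = contig_set(ids, seqs, "truth"),
    tpm = stats::setNames(tpm / sum(tpm) * 1e6, ids),
    gene_of = stats::setNames(genes, ids)
  ), class = "truth_set")
}
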