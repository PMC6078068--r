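#' Bottom-s MinHash sketch of an assembly
#'
#' Keeps the `num_hashes` smallest 64-bit hash values of the assembly's
#' canonical k-mers (FNV-1a with a splitmix64 finalizer; fixed, documented,
#' and stable across platforms), supporting Jaccard distance estimation
#' between assemblies without comparing the full k-mer sets.
#'
#' @param contigs a [contig_set].
#' @param k sketch k-mer length (odd, >= 15; default 51).
#' @param num_hashes sketch size (default 5000).
#' @param label label stored in the signature (defaults to the most common
#'   origin).
#' @return A `sketch_signature`: list with `label`, `k`, `num_hashes`,
#'   `hashes` (strictly increasing numeric vector).
#' @export
sketch <- function(contigs, k = 51L, num_hashes = 5000L, label = NULL) {
  stopifnot(inherits(contigs, "contig_set"), k >= 15L)
  if (k %% 2L == 0L) stop("sketch k must be odd")
  label <- label %||% names(sort(table(contigs$origin), decreasing = TRUE))[1L]
  if (all(nchar(contigs$seq) < k)) {
    warning("no sequence of length >= k; empty signature")
    hashes <- numeric(0)
  } else {
    hashes <- cpp_bottom_sketch(contigs$seq, as.integer(k),
                                as.integer(num_hashes))
  }
  structure(list(label = label, k = as.integer(k),
                 num_hashes = as.integer(num_hashes), hashes = hashes),
            class = "sketch_signature")
}

#' @export
print.sketch_signature <- function(x, ...) {
  cat(sprintf("sketch_signature '%s': k=%d, %d/%d hashes\n",
              x$label, x$k, length(x$hashes), x$num_hashes))
  invisible(x)
}

# bottom-s merge estimator of Jaccard similarity between two signatures
sketch_jaccard <- function(a, b) {
  s <- min(a$num_hashes, b$num_hashes)
  u <- sort(unique(c(a$hashes, b$hashes)))
  x <- u[seq_len(min(s, length(u)))]
  if (length(x) == 0L) return(0)
  sum(x %in% a$hashes & x %in% b$hashes) / length(x)
}

#' Pairwise Jaccard distance matrix between sketch signatures
#'
#' Distance is `1 - estimated Jaccard`, using the bottom-s merge estimator
#' (the fraction of the union's bottom-s hashes present in both sketches).
#'
#' @param signatures list of `sketch_signature` objects (equal `k`).
#' @return A `distance_matrix`: list with `labels` and `d` (symmetric,
#'   zero-diagonal matrix with entries in `[0, 1]`).
#' @export
compare_sketches <- function(signatures) {
  stopifnot(length(signatures) >= 2L)
  ks <- vapply(signatures, `[[`, integer(1), "k")
  if (length(unique(ks)) != 1L) stop("signatures have mixed k")
  labels <- vapply(signatures, `[[`, character(1), "label")
  n <- length(signatures)
  d <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      dij <- 1 - sketch_jaccard(signatures[[i]], signatures[[j]])
      d[i, j] <- dij
      d[j, i] <- dij
    }
  }
  structure(list(labels = labels, d = d), class = "distance_matrix")
}

#' Classical MDS embedding of a distance matrix
#'
#' Torgerson metric MDS (double-centering of `-d^2/2` and
#' eigendecomposition, as implemented by [stats::cmdscale()]). The sign of
#' each axis is fixed by making its largest-magnitude coordinate positive,
#' so embeddings are orientation-stable.
#'
#' @param dm a `distance_matrix`.
#' @param dims embedding dimension (< number of labels).
#' @return matrix of coordinates (rows = labels, cols = dims).
#' @export
mds_embed <- function(dm, dims = 2L) {
  stopifnot(inherits(dm, "distance_matrix"))
  n <- length(dm$labels)
  if (dims >= n) stop("dims must be smaller than the number of labels")
  if (all(dm$d == 0)) {
    return(matrix(0, n, dims, dimnames = list(dm$labels, NULL)))
  }
  co <- stats::cmdscale(stats::as.dist(dm$d), k = dims)
  if (ncol(co) < dims) {
    co <- cbind(co, matrix(0, n, dims - ncol(co)))
  }
  for (j in seq_len(ncol(co))) {
    i <- which.max(abs(co[, j]))
    if (co[i, j] < 0) co[, j] <- -co[, j]
  }
  rownames(co) <- dm$labels
  co
}

#' Quantify contig expression from read alignments
#'
#' A fragment (read pair) is assigned to the contigs on which both mates
#' have a best-tier alignment; multi-best-hit fragments are split equally
#' among the tied contigs. Counts are normalized by effective length
#' `max(length - insert_mean + 1, 1)` and scaled to TPM (sums to 1e6).
#'
#' @param aln alignment table over `contigs`.
#' @param contigs a [contig_set].
#' @param insert_mean mean insert size for the effective length.
#' @return data.frame: `contig_id`, `count`, `tpm`.
#' @export
quantify <- function(aln, contigs, insert_mean = 250) {
  stopifnot(inherits(contigs, "contig_set"))
  dt <- data.table::as.data.table(aln)[is_mapped == TRUE]
  m1 <- unique(dt[is_first == TRUE, c("read_id", "contig_id")])
  m2 <- unique(dt[is_first == FALSE, c("read_id", "contig_id")])
  both <- merge(m1, m2, by = c("read_id", "contig_id"))
  count <- stats::setNames(rep(0, length(contigs)), contigs$id)
  if (nrow(both) > 0L) {
    both[, w := 1 / .N, by = "read_id"]
    agg <- both[, list(count = sum(w)), by = "contig_id"]
    count[agg$contig_id] <- agg$count
  }
  eff_len <- pmax(nchar(contigs$seq) - insert_mean + 1, 1)
  rate <- count / eff_len
  tpm <- if (sum(rate) > 0) rate / sum(rate) * 1e6 else rate
  data.frame(contig_id = contigs$id, count = as.numeric(count),
             tpm = as.numeric(tpm), stringsAsFactors = FALSE)
}

#' Expression distribution of merged winners, stratified by origin
#'
#' Summarizes log(TPM+1) of the merged assembly's winners per assembler of
#' origin, exposing expression-dependent assembler biases (e.g. an
#' assembler that only recovers highly expressed transcripts shows an
#' elevated median).
#'
#' @param result a `merge_result`.
#' @param expression data.frame from [quantify()] covering the winners.
#' @return data.frame per origin: `origin`, `n`, `q25`, `median`, `q75`,
#'   `mean` of log(TPM+1).
#' @export
expression_by_origin <- function(result, expression) {
  stopifnot(inherits(result, "merge_result"))
  m <- match(result$merged$id, expression$contig_id)
  if (anyNA(m)) {
    warning("winner(s) absent from expression table are omitted")
  }
  logx <- log(expression$tpm[m] + 1)
  origin <- result$merged$origin
  keep <- !is.na(m)
  df <- data.frame(origin = origin[keep], logx = logx[keep])
  out <- do.call(rbind, lapply(split(df$logx, df$origin), function(v) {
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(n = length(v), q25 = q[1], median = q[2], q75 = q[3],
               mean = mean(v))
  }))
  out$origin <- rownames(out)
  rownames(out) <- NULL
  out[, c("origin", "n", "q25", "median", "q75", "mean")]
}
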