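#' Fraction of read pairs with both mates primary-mapped
#'
#' The mapping rate is the headline representativeness metric of an
#' assembly: reads that fail to map are biology the assembly cannot speak
#' for.
#'
#' @param aln alignment table (from [builtin_map()] or [read_sam()]).
#' @param n_pairs total number of read pairs sequenced.
#' @return mapping rate in `[0, 1]`.
#' @export
mapping_rate <- function(aln, n_pairs) {
  if (n_pairs < 1L) stop("n_pairs must be >= 1")
  pm <- aln[aln$is_primary & aln$is_mapped, c("read_id", "is_first")]
  if (nrow(pm) == 0L) return(0)
  # a pair contributes when both a first and a second primary record exist
  firsts <- unique(pm$read_id[pm$is_first])
  seconds <- unique(pm$read_id[!pm$is_first])
  length(intersect(firsts, seconds)) / n_pairs
}

#' Nucleotide fidelity of one contig
#'
#' Sum of matched bases over sum of aligned bases, over primary alignments.
#'
#' @param aln alignment table rows for one contig.
#' @return value in `[0, 1]`; 0 when the contig has no primary alignments.
#' @export
s_nuc <- function(aln) {
  p <- aln[aln$is_primary & aln$is_mapped, , drop = FALSE]
  if (nrow(p) == 0L) return(0)
  sum(p$n_match) / sum(p$aligned_len)
}

# per-base coverage of one contig from primary alignments (integer vector)
contig_coverage <- function(aln, contig_length) {
  p <- aln[aln$is_primary & aln$is_mapped, , drop = FALSE]
  if (nrow(p) == 0L) return(integer(contig_length))
  ir <- IRanges::IRanges(start = p$pos + 1L, width = p$aligned_len)
  as.integer(IRanges::coverage(ir, width = contig_length))
}

#' Fraction of contig positions covered by at least one primary-aligned base
#'
#' @param aln alignment table rows for one contig.
#' @param contig_length contig length in bp.
#' @return value in `[0, 1]`.
#' @export
s_cov <- function(aln, contig_length) {
  stopifnot(contig_length >= 1L)
  mean(contig_coverage(aln, contig_length) > 0L)
}

#' Pair order/orientation agreement of one contig
#'
#' Among read pairs with at least one mate primary-mapped to this contig:
#' the fraction whose two mates are both on the contig in proper FR
#' orientation (mates on opposite strands, leftmost mate forward) with
#' `|template_len| <= insert_mean + 3*insert_sd`. A pair whose other mate
#' maps elsewhere (or nowhere) counts as improper: such bridging pairs are
#' the read-evidence signature of a fragmented transcript, and they are what
#' lets the selection stage prefer a full-length contig over its fragments.
#' Defined as 1 (neutral) when no pairs touch the contig, so short contigs
#' are not annihilated by an undefined component.
#'
#' @param aln alignment table rows for one contig.
#' @param insert_mean,insert_sd insert-size model in bp.
#' @return value in `[0, 1]`.
#' @export
s_ord <- function(aln, insert_mean = 250, insert_sd = 50) {
  p <- data.table::as.data.table(
    aln[aln$is_primary & aln$is_mapped, , drop = FALSE])
  if (nrow(p) == 0L) return(1)
  cnt <- p[, .N, by = "read_id"]
  paired <- cnt$read_id[cnt$N == 2L]
  n_touch <- nrow(cnt)
  if (n_touch == 0L) return(1)
  if (length(paired) == 0L) return(0)
  p <- p[p$read_id %in% paired, ]
  data.table::setorder(p, read_id, -is_first)
  first <- p[p$is_first == TRUE, ]
  second <- p[p$is_first == FALSE, ]
  opposite <- first$is_reverse != second$is_reverse
  left_fwd <- ifelse(first$pos <= second$pos, !first$is_reverse,
                     !second$is_reverse)
  tlen <- abs(pmax(first$pos + first$aligned_len,
                   second$pos + second$aligned_len) -
                pmin(first$pos, second$pos))
  ok <- opposite & left_fwd & (tlen <= insert_mean + 3 * insert_sd)
  sum(ok) / n_touch
}

#' Single-transcript coverage plausibility of one contig
#'
#' Compares a 1-segment against the best 2-segment piecewise-constant model
#' of `log2(coverage + 1)` under a Gaussian likelihood with shared variance;
#' the breakpoint is searched over the middle 80% of positions on a decile
#' grid. The score is the 1-segment model's BIC weight: near 1 for uniform
#' coverage, near 0 for a step profile such as a chimera junction.
#'
#' @param cov integer per-base coverage vector.
#' @return value in `[0, 1]`; 0 for all-zero coverage (unsupported contig),
#'   1 for a length-1 vector (no breakpoint possible).
#' @export
s_seg <- function(cov) {
  n <- length(cov)
  stopifnot(n >= 1L)
  if (all(cov == 0L)) return(0)
  if (n == 1L) return(1)
  y <- log2(cov + 1)
  sse <- function(v) { m <- mean(v); sum((v - m)^2) }
  sse1 <- sse(y)
  breaks <- unique(pmax(1L, pmin(n - 1L, round(n * seq(0.1, 0.9, by = 0.1)))))
  sse2 <- min(vapply(breaks, function(b)
    sse(y[seq_len(b)]) + sse(y[seq.int(b + 1L, n)]), numeric(1)))
  eps <- 1e-9
  v1 <- max(sse1 / n, eps)
  v2 <- max(sse2 / n, eps)
  ll1 <- -n / 2 * (log(2 * pi * v1) + 1)
  ll2 <- -n / 2 * (log(2 * pi * v2) + 1)
  bic1 <- -2 * ll1 + 2 * log(n)       # mean + variance
  bic2 <- -2 * ll2 + 4 * log(n)       # two means + variance + breakpoint
  d1 <- bic1 - min(bic1, bic2)
  d2 <- bic2 - min(bic1, bic2)
  w <- exp(-d1 / 2) / (exp(-d1 / 2) + exp(-d2 / 2))
  min(max(w, 0), 1)
}

#' Combine the four components into a composite contig score
#'
#' Geometric mean of the four components, each floored at `floor` first so a
#' single zero cannot annihilate the composite.
#'
#' @param s_nuc,s_cov,s_ord,s_seg component scores in `[0, 1]`.
#' @param floor component floor (default 0.01).
#' @return composite score in `(0, 1]`.
#' @export
contig_score <- function(s_nuc, s_cov, s_ord, s_seg, floor = 0.01) {
  comp <- pmax(cbind(s_nuc, s_cov, s_ord, s_seg), floor)
  unname(exp(rowMeans(log(comp))))
}

#' Score every contig of an assembly from read alignments
#'
#' @param aln alignment table over `contigs`.
#' @param contigs a [contig_set].
#' @param insert_mean,insert_sd insert-size model for the pair-order score.
#' @param floor component floor for the composite.
#' @return data.frame with one row per contig: `contig_id`, `origin`,
#'   `length`, `s_nuc`, `s_cov`, `s_ord`, `s_seg`, `composite`.
#' @export
score_contigs <- function(aln, contigs, insert_mean = 250, insert_sd = 50,
                          floor = 0.01) {
  stopifnot(inherits(contigs, "contig_set"))
  lens <- nchar(contigs$seq)
  dt <- data.table::as.data.table(aln)[is_mapped == TRUE]
  split_idx <- split(seq_len(nrow(dt)), dt$contig_id)
  out <- data.frame(contig_id = contigs$id, origin = contigs$origin,
                    length = lens, s_nuc = 0, s_cov = 0, s_ord = 1,
                    s_seg = 0, stringsAsFactors = FALSE)
  for (r in seq_len(nrow(out))) {
    cid <- out$contig_id[r]
    rows <- split_idx[[cid]]
    if (is.null(rows)) next
    sub <- dt[rows]
    cov <- contig_coverage(sub, lens[r])
    out$s_nuc[r] <- s_nuc(sub)
    out$s_cov[r] <- mean(cov > 0L)
    out$s_ord[r] <- s_ord(sub, insert_mean, insert_sd)
    out$s_seg[r] <- s_seg(cov)
  }
  out$composite <- contig_score(out$s_nuc, out$s_cov, out$s_ord, out$s_seg,
                                floor = floor)
  out
}

#' Assembly-level score
#'
#' Geometric mean of the composite contig scores multiplied by the mapping
#' rate, a synthetic quality metric in `[0, 1]`.
#'
#' @param composites composite contig scores (>= 1 value).
#' @param mapping_rate assembly mapping rate.
#' @return list with `mapping_rate`, `contig_geo_mean`, `score`.
#' @export
assembly_score <- function(composites, mapping_rate) {
  if (length(composites) == 0L) stop("empty assembly: no contig scores")
  geo <- exp(mean(log(composites)))
  list(mapping_rate = mapping_rate, contig_geo_mean = geo,
       score = geo * mapping_rate)
}

#' Map paired-end reads to contigs with the bundled exact-seed mapper
#'
#' A deliberately simple, deterministic seed-and-extend mapper for
#' benchmark-scale data: canonical-orientation seed k-mers of the contigs
#' are indexed; each read (tried forward and reverse-complement) is placed
#' ungapped at the diagonal of its seed hits, scored by full-length mismatch
#' count. The best tier is kept; the primary is the tie with the
#' lexicographically smallest contig id. Equal-best ties are reported as
#' secondary records so multi-best-hit fragments can be split during
#' quantification.
#'
#' @param r1,r2 named character vectors of mate sequences (same names), or
#'   FASTQ paths.
#' @param contigs a [contig_set].
#' @param seed_k seed k-mer size (>= 15).
#' @param seed_step offset step between seeds along the read.
#' @param max_mismatch_frac maximum mismatch fraction for a valid placement.
#' @param tie_break how the primary is chosen among equal-best contigs:
#'   `"hash"` (default) picks deterministically but pseudorandomly per
#'   (read, contig), so identical copies of a transcript share the read
#'   evidence; `"id"` always picks the lexicographically smallest contig id.
#' @param sam_path if non-NULL, also write a SAM file there.
#' @return alignment table as documented in [read_sam()], with extra columns
#'   `mate_pos` and `n_tie`.
#' @export
builtin_map <- function(r1, r2, contigs, seed_k = 31L, seed_step = 7L,
                        max_mismatch_frac = 0.2,
                        tie_break = c("hash", "id"), sam_path = NULL) {
  tie_mode <- if (match.arg(tie_break) == "hash") 1L else 0L
  stopifnot(seed_k >= 15L, inherits(contigs, "contig_set"))
  if (length(r1) == 1L && is.null(names(r1)) && file.exists(r1)) {
    r1 <- read_fastq(r1)
  }
  if (length(r2) == 1L && is.null(names(r2)) && file.exists(r2)) {
    r2 <- read_fastq(r2)
  }
  stopifnot(length(r1) == length(r2))
  ids <- names(r1) %||% sprintf("p%07d", seq_along(r1))
  rank <- match(contigs$id, sort(contigs$id))
  maxmm <- as.integer(ceiling(max_mismatch_frac * max(nchar(c(r1, r2)))))
  h1 <- cpp_map_reads(unname(toupper(r1)), contigs$seq, rank,
                      as.integer(seed_k), as.integer(seed_step), maxmm,
                      tie_mode)
  h2 <- cpp_map_reads(unname(toupper(r2)), contigs$seq, rank,
                      as.integer(seed_k), as.integer(seed_step), maxmm,
                      tie_mode)
  mk <- function(h, mate_first, seqs) {
    data.table::data.table(
      read_id = ids[h$read],
      contig_id = contigs$id[h$contig],
      pos = h$pos,
      aligned_len = nchar(unname(seqs))[h$read],
      n_mismatch = h$nm,
      is_primary = h$is_primary == 1L,
      is_mapped = TRUE,
      is_reverse = h$is_rev == 1L,
      is_first = mate_first,
      n_tie = h$n_tie
    )
  }
  a1 <- mk(h1, TRUE, r1)
  a2 <- mk(h2, FALSE, r2)
  # mate info from the other mate's primary record
  p1 <- a1[a1$is_primary, c("read_id", "contig_id", "pos", "is_reverse")]
  p2 <- a2[a2$is_primary, c("read_id", "contig_id", "pos", "is_reverse")]
  data.table::setnames(p1, c("read_id", "m_contig", "m_pos", "m_rev"))
  data.table::setnames(p2, c("read_id", "m_contig", "m_pos", "m_rev"))
  mate_of <- function(x, mate_tbl) {
    m <- mate_tbl[match(x$read_id, mate_tbl$read_id), ]
    x$mate_contig_id <- m$m_contig
    x$mate_pos <- m$m_pos
    x$mate_is_reverse <- m$m_rev
    x
  }
  aln <- rbind(mate_of(a1, p2), mate_of(a2, p1))
  aln$n_match <- aln$aligned_len - aln$n_mismatch
  same <- !is.na(aln$mate_contig_id) & aln$mate_contig_id == aln$contig_id
  lo <- pmin(aln$pos, aln$mate_pos)
  hi <- pmax(aln$pos + aln$aligned_len, aln$mate_pos + aln$aligned_len)
  span <- hi - lo
  aln$template_len <- ifelse(same,
                             ifelse(aln$pos <= aln$mate_pos, span, -span),
                             NA_integer_)
  # unmapped mates of mapped reads, for SAM completeness
  un1 <- setdiff(ids, a1$read_id)
  un2 <- setdiff(ids, a2$read_id)
  unmapped <- function(rids, mate_first, mate_tbl) {
    if (length(rids) == 0L) return(NULL)
    m <- mate_tbl[match(rids, mate_tbl$read_id), ]
    data.table::data.table(
      read_id = rids, contig_id = NA_character_, pos = NA_integer_,
      aligned_len = NA_integer_, n_mismatch = NA_integer_,
      is_primary = FALSE, is_mapped = FALSE, is_reverse = FALSE,
      is_first = mate_first, n_tie = 0L, n_match = NA_integer_,
      mate_contig_id = m$m_contig, mate_pos = m$m_pos,
      mate_is_reverse = m$m_rev, template_len = NA_integer_
    )
  }
  aln <- rbind(aln, unmapped(un1, TRUE, p2), unmapped(un2, FALSE, p1),
               use.names = TRUE)
  data.table::setorder(aln, read_id, -is_first, -is_primary)
  setcols <- c("read_id", "contig_id", "pos", "aligned_len", "n_match",
               "n_mismatch", "is_primary", "is_mapped", "is_reverse",
               "is_first", "mate_contig_id", "mate_pos", "mate_is_reverse",
               "template_len", "n_tie")
  aln <- aln[, setcols, with = FALSE]
  if (!is.null(sam_path)) write_sam(aln, contigs, sam_path)
  aln[]
}
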