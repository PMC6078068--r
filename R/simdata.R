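#' @useDynLib txmerge, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

random_dna <- function(n) {
  vapply(n, function(len)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = ""),
    character(1))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Simulate a ground-truth transcriptome
#'
#' Generates a transcriptome with log-normal transcript lengths and
#' log-normal expression normalized to TPM (summing to 1e6). Isoforms of a
#' gene are built by block replacement so that any two isoforms share at
#' least 60% of their sequence, which is the regime that stresses the
#' isoform-collapse behaviour of graph clustering.
#'
#' @param n_genes number of genes (>= 1).
#' @param isoforms_per_gene integer scalar, or a function(n_genes) returning
#'   an integer vector of isoform counts.
#' @param length_meanlog,length_sdlog log-normal length parameters
#'   (defaults give a median near 1,500 bp).
#' @param min_length minimum transcript length in bp.
#' @param expr_sdlog sdlog of the log-normal expression weights.
#' @param seed RNG seed; output is deterministic given the seed.
#' @return A `truth_set`: list with `transcripts` ([contig_set], origin
#'   `"truth"`), `tpm` (named numeric, sums to 1e6), `gene_of` (named
#'   character map transcript id -> gene id).
#' @export
simulate_transcriptome <- function(n_genes, isoforms_per_gene = 1L,
                                   length_meanlog = log(1500),
                                   length_sdlog = 0.35,
                                   min_length = 300L,
                                   expr_sdlog = 1.5,
                                   seed = 1L) {
  if (n_genes < 1L) stop("n_genes must be >= 1")
  set.seed(seed)
  n_iso <- if (is.function(isoforms_per_gene)) {
    as.integer(isoforms_per_gene(n_genes))
  } else rep(as.integer(isoforms_per_gene), n_genes)
  stopifnot(all(n_iso >= 1L))
  gene_ids <- sprintf("g%05d", seq_len(n_genes))
  gene_len <- pmax(min_length,
                   round(stats::rlnorm(n_genes, length_meanlog, length_sdlog)))
  gene_seq <- random_dna(gene_len)

  ids <- character(0); seqs <- character(0); genes <- character(0)
  for (g in seq_len(n_genes)) {
    base <- gene_seq[g]
    len <- gene_len[g]
    for (i in seq_len(n_iso[g])) {
      if (i == 1L) {
        s <- base
      } else {
        # replace a contiguous 30% block with novel sequence: isoforms share 70%
        blk <- max(1L, round(0.3 * len))
        at <- sample.int(len - blk + 1L, 1L)
        s <- paste0(substr(base, 1L, at - 1L), random_dna(blk),
                    substr(base, at + blk, len))
      }
      ids <- c(ids, sprintf("%s_t%d", gene_ids[g], i))
      seqs <- c(seqs, s)
      genes <- c(genes, gene_ids[g])
    }
  }
  w <- stats::rlnorm(length(ids), meanlog = 0, sdlog = expr_sdlog)
  tpm <- stats::setNames(w / sum(w) * 1e6, ids)
  structure(list(
    transcripts = contig_set(ids, seqs, "truth"),
    tpm = tpm,
    gene_of = stats::setNames(genes, ids)
  ), class = "truth_set")
}

#' @export
print.truth_set <- function(x, ...) {
  cat(sprintf("truth_set: %d transcripts, %d genes\n",
              length(x$transcripts), length(unique(x$gene_of))))
  invisible(x)
}

apply_substitutions <- function(seqs, error_rate) {
  if (error_rate <= 0) return(list(seqs = seqs, n_err = integer(length(seqs))))
  lens <- nchar(seqs)
  n_err <- stats::rbinom(length(seqs), lens, error_rate)
  idx <- which(n_err > 0L)
  bases <- c("A", "C", "G", "T")
  for (i in idx) {
    s <- strsplit(seqs[i], "")[[1]]
    at <- sample.int(lens[i], n_err[i])
    for (p in at) s[p] <- sample(setdiff(bases, s[p]), 1L)
    seqs[i] <- paste(s, collapse = "")
  }
  list(seqs = seqs, n_err = n_err)
}

#' Simulate paired-end reads from a truth set
#'
#' Fragments are sampled from transcripts proportional to TPM x length;
#' inserts are normal (truncated to `[read_len, transcript length]`), pairs
#' are FR-oriented, and substitution errors are i.i.d. per base. A placement
#' table records the true source and coordinates of every pair.
#'
#' @param truth a `truth_set`.
#' @param n_pairs number of read pairs.
#' @param read_len read length in bp (must be < shortest transcript).
#' @param insert_mean,insert_sd insert-size model in bp.
#' @param error_rate per-base substitution probability.
#' @param seed RNG seed.
#' @param out_prefix if non-NULL, write `<prefix>_1.fastq`, `<prefix>_2.fastq`
#'   and `<prefix>_placements.tsv`.
#' @return list with `r1`, `r2` (named character vectors of read sequences),
#'   `placements` (data.frame: `pair_id`, `transcript_id`, `frag_start`
#'   (0-based), `insert`, `n_err1`, `n_err2`), and file paths when written.
#' @export
simulate_reads <- function(truth, n_pairs, read_len = 100L,
                           insert_mean = 250L, insert_sd = 50L,
                           error_rate = 0.01, seed = 1L, out_prefix = NULL) {
  stopifnot(inherits(truth, "truth_set"), n_pairs >= 1L)
  tlen <- nchar(truth$transcripts$seq)
  if (read_len >= min(tlen)) {
    stop("read_len must be shorter than the shortest transcript (",
         min(tlen), " bp)")
  }
  set.seed(seed)
  w <- truth$tpm * tlen
  pick <- sample.int(length(tlen), n_pairs, replace = TRUE, prob = w / sum(w))
  ins <- pmin(pmax(round(stats::rnorm(n_pairs, insert_mean, insert_sd)),
                   read_len), tlen[pick])
  start <- floor(stats::runif(n_pairs) * (tlen[pick] - ins + 1L))  # 0-based
  seqs <- truth$transcripts$seq[pick]
  r1 <- substr(seqs, start + 1L, start + read_len)
  r2 <- revcomp(substr(seqs, start + ins - read_len + 1L, start + ins))
  e1 <- apply_substitutions(r1, error_rate)
  e2 <- apply_substitutions(r2, error_rate)
  ids <- sprintf("p%07d", seq_len(n_pairs))
  placements <- data.frame(
    pair_id = ids,
    transcript_id = truth$transcripts$id[pick],
    frag_start = as.integer(start),
    insert = as.integer(ins),
    n_err1 = e1$n_err, n_err2 = e2$n_err,
    stringsAsFactors = FALSE
  )
  out <- list(r1 = stats::setNames(e1$seqs, ids),
              r2 = stats::setNames(e2$seqs, ids),
              placements = placements)
  if (!is.null(out_prefix)) {
    f1 <- paste0(out_prefix, "_1.fastq")
    f2 <- paste0(out_prefix, "_2.fastq")
    fp <- paste0(out_prefix, "_placements.tsv")
    write_fastq(out$r1, ids, f1)
    write_fastq(out$r2, ids, f2)
    write_report(placements, fp)
    out$files <- c(r1 = f1, r2 = f2, placements = fp)
  }
  out
}

#' Define an assembler bias profile
#'
#' A profile describes how a hypothetical assembler corrupts the truth:
#' expression-dependent dropout (a logistic retention curve in log(TPM+1),
#' plus an optional hard drop below a TPM threshold), artificial duplication
#' with small edits, fragmentation, chimera formation, and per-base
#' substitution noise.
#'
#' @param name origin label for contigs emitted under this profile.
#' @param dropout_low_tpm TPM threshold; transcripts below it are dropped
#'   with probability `p_drop_low` (use `Inf` for expression-independent
#'   dropout of all transcripts).
#' @param p_drop_low drop probability below `dropout_low_tpm`.
#' @param retention_midpoint midpoint of the logistic retention curve on the
#'   log(TPM+1) scale (`NULL` disables the curve).
#' @param retention_slope slope of the logistic retention curve; larger
#'   values give a sharper bias toward high-expression transcripts.
#' @param frag_rate probability a retained transcript is split in two
#'   (breakpoint uniform in the middle 50%).
#' @param dup_rate probability a retained transcript is emitted twice, the
#'   copy carrying 0.5% substitutions.
#' @param chimera_rate probability a retained transcript additionally emits
#'   a concatenation with another random retained transcript.
#' @param error_rate per-base substitution rate on all emitted contigs.
#' @return A `bias_profile` object (validated named list).
#' @export
bias_profile <- function(name, dropout_low_tpm = 0, p_drop_low = 0,
                         retention_midpoint = NULL, retention_slope = 0,
                         frag_rate = 0, dup_rate = 0, chimera_rate = 0,
                         error_rate = 0) {
  rates <- c(p_drop_low = p_drop_low, frag_rate = frag_rate,
             dup_rate = dup_rate, chimera_rate = chimera_rate,
             error_rate = error_rate)
  if (any(rates < 0 | rates > 1)) {
    stop("profile rates must lie in [0,1]: ",
         paste(names(rates)[rates < 0 | rates > 1], collapse = ", "))
  }
  structure(list(name = name, dropout_low_tpm = dropout_low_tpm,
                 p_drop_low = p_drop_low,
                 retention_midpoint = retention_midpoint,
                 retention_slope = retention_slope,
                 frag_rate = frag_rate, dup_rate = dup_rate,
                 chimera_rate = chimera_rate, error_rate = error_rate),
            class = "bias_profile")
}

#' Corrupt a truth transcriptome under an assembler bias profile
#'
#' Applies, in order: expression-dependent dropout, duplication,
#' fragmentation (split point uniform in the middle 50% of the transcript),
#' chimera formation (concatenation with another random retained
#' transcript), then per-base substitution noise. Every emitted contig is
#' traceable to its source transcript(s) through the provenance table.
#'
#' @param truth a `truth_set`.
#' @param profile a [bias_profile].
#' @param seed RNG seed.
#' @return list with `contigs` ([contig_set] with origin `profile$name`) and
#'   `provenance` (data.frame: `contig_id`, `source_id`, `source2_id`,
#'   `type` in intact/duplicate/fragment/chimera).
#' @export
corrupt_assembly <- function(truth, profile, seed = 1L) {
  stopifnot(inherits(truth, "truth_set"), inherits(profile, "bias_profile"))
  set.seed(seed)
  tid <- truth$transcripts$id
  seqs <- stats::setNames(truth$transcripts$seq, tid)
  tpm <- truth$tpm[tid]
  logx <- log(tpm + 1)

  keep_p <- rep(1, length(tid))
  if (!is.null(profile$retention_midpoint) && profile$retention_slope != 0) {
    keep_p <- stats::plogis(profile$retention_slope *
                              (logx - profile$retention_midpoint))
  }
  keep <- stats::runif(length(tid)) < keep_p
  low <- tpm < profile$dropout_low_tpm
  keep[low & stats::runif(length(tid)) < profile$p_drop_low] <- FALSE
  retained <- tid[keep]

  out_id <- character(0); out_seq <- character(0)
  src1 <- character(0); src2 <- character(0); type <- character(0)
  emit <- function(id, s, a, b, ty) {
    out_id <<- c(out_id, id); out_seq <<- c(out_seq, s)
    src1 <<- c(src1, a); src2 <<- c(src2, b); type <<- c(type, ty)
  }
  dup <- stats::runif(length(retained)) < profile$dup_rate
  frag <- stats::runif(length(retained)) < profile$frag_rate
  chim <- stats::runif(length(retained)) < profile$chimera_rate
  for (i in seq_along(retained)) {
    t <- retained[i]
    s <- seqs[[t]]
    len <- nchar(s)
    if (frag[i] && len >= 4L) {
      cut <- sample(seq.int(floor(len * 0.25), ceiling(len * 0.75)), 1L)
      emit(paste0(t, "_f1"), substr(s, 1L, cut), t, NA_character_, "fragment")
      emit(paste0(t, "_f2"), substr(s, cut + 1L, len), t, NA_character_,
           "fragment")
    } else {
      emit(t, s, t, NA_character_, "intact")
    }
    if (dup[i]) {
      d <- apply_substitutions(s, 0.005)$seqs
      emit(paste0(t, "_dup"), d, t, NA_character_, "duplicate")
    }
    if (chim[i] && length(retained) > 1L) {
      other <- sample(setdiff(retained, t), 1L)
      emit(paste0(t, "_", other, "_chim"), paste0(s, seqs[[other]]),
           t, other, "chimera")
    }
  }
  noisy <- apply_substitutions(out_seq, profile$error_rate)
  list(
    contigs = contig_set(out_id, noisy$seqs, profile$name),
    provenance = data.frame(contig_id = out_id, source_id = src1,
                            source2_id = src2, type = type,
                            stringsAsFactors = FALSE)
  )
}

#' Canned bias profiles of the standard benchmark
#'
#' Four profiles emulating the qualitative biases of common assemblers:
#' `trinity` (balanced: expression-independent moderate dropout, the most
#' duplication), `spades55` (mild bias against low-abundance transcripts),
#' `spades75` (stronger retention bias toward high abundance, as expected
#' from a longer k-mer), and `shannon` (severe low-abundance dropout; emits
#' the fewest contigs). Logistic midpoints are placed at quantiles of the
#' truth's log(TPM+1) distribution.
#'
#' @param truth a `truth_set` (used only to locate expression quantiles).
#' @return named list of four [bias_profile] objects.
#' @export
benchmark_profiles <- function(truth) {
  q <- stats::quantile(log(truth$tpm + 1), c(0.05, 0.45, 0.65), names = FALSE)
  list(
    trinity = bias_profile("trinity", dropout_low_tpm = Inf, p_drop_low = 0.13,
                           dup_rate = 0.18, frag_rate = 0.06,
                           chimera_rate = 0.04, error_rate = 0.003),
    spades55 = bias_profile("spades55", retention_midpoint = q[1],
                            retention_slope = 0.9, dup_rate = 0.06,
                            frag_rate = 0.05, chimera_rate = 0.04,
                            error_rate = 0.003),
    spades75 = bias_profile("spades75", retention_midpoint = q[2],
                            retention_slope = 1.6, dup_rate = 0.06,
                            frag_rate = 0.05, chimera_rate = 0.04,
                            error_rate = 0.003),
    shannon = bias_profile("shannon", retention_midpoint = q[3],
                           retention_slope = 2.5, dup_rate = 0.03,
                           frag_rate = 0.03, chimera_rate = 0.02,
                           error_rate = 0.003)
  )
}

#' Generate the standard synthetic benchmark
#'
#' One call produces everything the pipeline consumes: a ground-truth
#' transcriptome, paired-end reads, and four corrupted assemblies under the
#' canned profiles of [benchmark_profiles()]. By construction the four
#' assemblies are complementary: their union covers nearly all truth genes
#' while each single assembly misses a sizable expression-dependent slice.
#'
#' @param seed RNG seed driving every stage.
#' @param n_genes number of truth genes.
#' @param n_pairs number of simulated read pairs.
#' @param out_dir if non-NULL, write FASTA/FASTQ/TSV artifacts there.
#' @return list with `truth`, `reads` (as from [simulate_reads()]),
#'   `assemblies` (named list of [contig_set]), `provenance` (named list of
#'   data.frames), and `files` when written.
#' @export
standard_benchmark <- function(seed = 42L, n_genes = 500L, n_pairs = 50000L,
                               out_dir = NULL) {
  truth <- simulate_transcriptome(n_genes, seed = seed)
  reads <- simulate_reads(truth, n_pairs, read_len = 100L,
                          insert_mean = 250L, insert_sd = 50L,
                          error_rate = 0.01, seed = seed + 1L)
  profiles <- benchmark_profiles(truth)
  corrupted <- lapply(seq_along(profiles), function(i)
    corrupt_assembly(truth, profiles[[i]], seed = seed + 1L + i))
  names(corrupted) <- names(profiles)
  out <- list(
    truth = truth,
    reads = reads,
    assemblies = lapply(corrupted, `[[`, "contigs"),
    provenance = lapply(corrupted, `[[`, "provenance")
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- character(0)
    for (lab in names(out$assemblies)) {
      fa <- file.path(out_dir, paste0(lab, ".fasta"))
      write_fasta(out$assemblies[[lab]], fa)
      pv <- file.path(out_dir, paste0(lab, "_provenance.tsv"))
      write_report(out$provenance[[lab]], pv)
      files <- c(files, fa, pv)
    }
    tf <- file.path(out_dir, "truth.fasta")
    write_fasta(truth$transcripts, tf)
    write_report(data.frame(transcript_id = truth$transcripts$id,
                            gene_id = unname(truth$gene_of),
                            tpm = unname(truth$tpm)),
                 file.path(out_dir, "truth_expression.tsv"))
    rf <- simulate_reads(truth, n_pairs, read_len = 100L, insert_mean = 250L,
                         insert_sd = 50L, error_rate = 0.01, seed = seed + 1L,
                         out_prefix = file.path(out_dir, "reads"))
    out$reads <- rf
    out$files <- c(files, tf, rf$files)
  }
  out
}

# gene-level recovery of a corrupted assembly, from its provenance table
gene_recovery <- function(provenance, truth) {
  src <- unique(c(provenance$source_id,
                  provenance$source2_id[!is.na(provenance$source2_id)]))
  genes <- unique(truth$gene_of[src])
  length(genes) / length(unique(truth$gene_of))
}
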