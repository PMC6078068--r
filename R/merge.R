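#' Select the best-scoring contig of each orthogroup
#'
#' The winner of a group is the member with the maximal composite score;
#' ties go to the longer contig, then to the lexicographically smallest id.
#' Singleton groups keep their only member.
#'
#' @param groups list of orthogroups (`group_id`, `members`).
#' @param scores data.frame from [score_contigs()] covering every member.
#' @param contigs the pooled [contig_set].
#' @return A `merge_result`: list with `merged` ([contig_set] of winners,
#'   original prefixed ids kept), `group_table` (data.frame: `group_id`,
#'   `member_count`, `members`, `winner_id`, `winner_origin`,
#'   `winner_score`), `contribution` (named fractions by origin, sums to 1).
#' @export
select_representatives <- function(groups, scores, contigs) {
  stopifnot(inherits(contigs, "contig_set"))
  idx <- match(scores$contig_id, scores$contig_id)
  srow <- stats::setNames(seq_len(nrow(scores)), scores$contig_id)
  missing <- setdiff(unlist(lapply(groups, `[[`, "members")),
                     scores$contig_id)
  if (length(missing)) {
    stop("no score for contig(s): ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  winners <- character(length(groups))
  wscore <- numeric(length(groups))
  for (i in seq_along(groups)) {
    m <- groups[[i]]$members
    rs <- srow[m]
    comp <- scores$composite[rs]
    len <- scores$length[rs]
    ord <- order(-comp, -len, m)
    winners[i] <- m[ord[1L]]
    wscore[i] <- comp[ord[1L]]
  }
  wi <- match(winners, contigs$id)
  merged <- contigs[wi]
  group_table <- data.frame(
    group_id = vapply(groups, `[[`, integer(1), "group_id"),
    member_count = vapply(groups, function(g) length(g$members), integer(1)),
    members = vapply(groups, function(g) paste(g$members, collapse = ","),
                     character(1)),
    winner_id = winners,
    winner_origin = merged$origin,
    winner_score = wscore,
    stringsAsFactors = FALSE
  )
  contribution <- table(merged$origin) / length(merged$origin)
  structure(list(
    merged = merged,
    group_table = group_table,
    contribution = stats::setNames(as.numeric(contribution),
                                   names(contribution))
  ), class = "merge_result")
}

#' @export
print.merge_result <- function(x, ...) {
  cat(sprintf("merge_result: %d orthogroups -> %d representative contigs\n",
              nrow(x$group_table), length(x$merged)))
  cat("contribution:",
      paste(sprintf("%s=%.1f%%", names(x$contribution),
                    100 * x$contribution), collapse = ", "), "\n")
  invisible(x)
}

#' Per-assembler contribution to the merged assembly
#'
#' @param result a `merge_result`.
#' @return named numeric: fraction of winners per origin label (sums to 1).
#' @export
contribution_report <- function(result) {
  stopifnot(inherits(result, "merge_result"))
  if (length(result$merged) == 0L) stop("empty merged assembly")
  result$contribution
}

# map pooled (prefixed) contig ids to truth gene ids via provenance tables;
# chimeras count toward both source genes
pooled_genes <- function(ids, provenance, truth) {
  parts <- data.table::tstrsplit(ids, "|", fixed = TRUE, keep = 1:2)
  labs <- parts[[1]]; orig <- parts[[2]]
  out <- vector("list", length(ids))
  for (lab in unique(labs)) {
    pv <- provenance[[lab]]
    if (is.null(pv)) stop("no provenance table for label: ", lab)
    sel <- labs == lab
    m <- match(orig[sel], pv$contig_id)
    g1 <- truth$gene_of[pv$source_id[m]]
    g2 <- truth$gene_of[pv$source2_id[m]]
    out[sel] <- Map(function(a, b) unique(stats::na.omit(c(a, b))), g1, g2)
  }
  out
}

#' Duplication rate of a contig collection against the truth
#'
#' Fraction of all truth genes represented by more than one contig; a gene
#' hit by several fragments, duplicates, or chimera arms counts once.
#'
#' @param ids pooled-style contig ids (`label|original_id`).
#' @param provenance named list of provenance tables (one per label).
#' @param truth a `truth_set`.
#' @return duplication fraction in `[0, 1]`.
#' @export
gene_duplication <- function(ids, provenance, truth) {
  genes <- unlist(pooled_genes(ids, provenance, truth), use.names = FALSE)
  tab <- table(genes)
  n_genes <- length(unique(truth$gene_of))
  sum(tab > 1L) / n_genes
}

#' Duplication report for a merged assembly
#'
#' With a truth set, reports the fraction of truth genes represented by more
#' than one merged contig. Without one, reports residual redundancy: the
#' fraction of merged contigs whose best similarity to another merged contig
#' is at least the clustering threshold.
#'
#' @param result a `merge_result`.
#' @param truth a `truth_set`, or NULL.
#' @param provenance named list of provenance tables (required with truth).
#' @param k,min_similarity clustering parameters for the reference-free mode.
#' @return list with `mode` and `duplication`.
#' @export
duplication_report <- function(result, truth = NULL, provenance = NULL,
                               k = 31L, min_similarity = 0.1) {
  stopifnot(inherits(result, "merge_result"))
  if (!is.null(truth)) {
    stopifnot(!is.null(provenance))
    list(mode = "truth",
         duplication = gene_duplication(result$merged$id, provenance, truth))
  } else {
    g <- build_graph(result$merged, k = k, min_similarity = min_similarity)
    linked <- unique(c(g$edges$from, g$edges$to))
    list(mode = "residual",
         duplication = length(linked) / length(result$merged))
  }
}

#' Run the full merge pipeline
#'
#' Pools the input assemblies, clusters the pool into orthogroups, scores
#' every contig from paired-end read evidence (mapping with the bundled
#' mapper against the pooled set, unless a SAM file is supplied), and keeps
#' the highest-scoring contig per group. Deterministic given inputs and
#' config.
#'
#' @param assemblies named list: label -> FASTA path or [contig_set].
#' @param r1,r2 FASTQ paths or named read vectors (ignored when `sam` given).
#' @param sam optional path to a SAM file of the reads aligned to the pooled
#'   set (reference names must use the `label|id` convention).
#' @param config a [run_config()] list.
#' @param out_dir if non-NULL, write `merged.fasta`, `groups.tsv`,
#'   `contigscores.tsv`, `contribution.tsv` and `manifest.json` there.
#' @return A `merge_result` (see [select_representatives()]) with extra
#'   fields `scores`, `assembly_score`, `mapping_rate`, `n_pairs`,
#'   `params_used`.
#' @export
orthofuse <- function(assemblies, r1 = NULL, r2 = NULL, sam = NULL,
                      config = run_config(), out_dir = NULL) {
  if (length(assemblies) < 2L) stop("merging requires at least two assemblies")
  asm <- lapply(names(assemblies), function(lab) {
    a <- assemblies[[lab]]
    if (inherits(a, "contig_set")) a else read_fasta(a, lab)
  })
  names(asm) <- names(assemblies)
  pooled <- pool_assemblies(asm)
  tx_log("merge", sprintf("pooled %d contigs from %d assemblies",
                          length(pooled), length(asm)))
  groups <- cluster_assemblies(pooled, k = config$k_cluster,
                               min_similarity = config$min_similarity,
                               params = mcl_params(
                                 inflation = config$inflation,
                                 expansion = config$expansion,
                                 prune_threshold = config$prune_threshold,
                                 max_iter = config$max_iter,
                                 tol = config$tol))
  if (!is.null(sam)) {
    aln <- read_sam(sam, pooled)
    n_pairs <- length(unique(aln$read_id))
  } else {
    if (is.null(r1) || is.null(r2)) stop("supply reads (r1, r2) or a SAM file")
    if (is.character(r1) && length(r1) == 1L) r1 <- read_fastq(r1)
    if (is.character(r2) && length(r2) == 1L) r2 <- read_fastq(r2)
    n_pairs <- length(r1)
    aln <- builtin_map(r1, r2, pooled, seed_k = config$seed_k,
                       seed_step = config$seed_step)
  }
  rate <- mapping_rate(aln, n_pairs)
  tx_log("merge", sprintf("mapping rate on pooled set: %.3f", rate))
  scores <- score_contigs(aln, pooled, insert_mean = config$insert_mean,
                          insert_sd = config$insert_sd,
                          floor = config$score_floor)
  result <- select_representatives(groups, scores, pooled)
  result$scores <- scores
  result$mapping_rate <- rate
  result$n_pairs <- n_pairs
  result$assembly_score <- assembly_score(
    scores$composite[match(result$merged$id, scores$contig_id)], rate)$score
  result$params_used <- config
  tx_log("merge", sprintf("%d winners selected", length(result$merged)))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(result$merged, file.path(out_dir, "merged.fasta"))
    write_report(result$group_table, file.path(out_dir, "groups.tsv"))
    write_report(scores, file.path(out_dir, "contigscores.tsv"))
    write_report(data.frame(origin = names(result$contribution),
                            fraction = as.numeric(result$contribution)),
                 file.path(out_dir, "contribution.tsv"))
    manifest <- list(
      tool = "txmerge", version = as.character(utils::packageVersion("txmerge")),
      assemblies = names(assemblies), n_pairs = n_pairs,
      config = config,
      outputs = c("merged.fasta", "groups.tsv", "contigscores.tsv",
                  "contribution.tsv")
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  }
  result
}
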