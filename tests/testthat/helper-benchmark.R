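# Shared benchmark fixtures, computed once per test run.

.bm_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .bm_cache)) {
    assign(key, force(expr), envir = .bm_cache)
  }
  get(key, envir = .bm_cache)
}

# a small benchmark for module-level tests (fast; full scale lives in the
# acceptance suite)
small_benchmark <- function() {
  cached("small_bm", standard_benchmark(seed = 42, n_genes = 80,
                                        n_pairs = 4000))
}

small_merge <- function() {
  cached("small_merge", {
    bm <- small_benchmark()
    orthofuse(bm$assemblies, r1 = bm$reads$r1, r2 = bm$reads$r2)
  })
}

# full-scale study conditions (500 genes, 50k pairs), used by the
# acceptance suite
full_benchmark <- function(seed) {
  cached(paste0("full_bm_", seed), standard_benchmark(seed = seed))
}

full_merge <- function(seed) {
  cached(paste0("full_merge_", seed), {
    bm <- full_benchmark(seed)
    orthofuse(bm$assemblies, r1 = bm$reads$r1, r2 = bm$reads$r2)
  })
}

# combined provenance with pooled-style ids
pooled_provenance <- function(bm) {
  do.call(rbind, lapply(names(bm$provenance), function(l) {
    p <- bm$provenance[[l]]
    p$pooled_id <- paste0(l, "|", p$contig_id)
    p
  }))
}

# ARI of a grouping against the true gene partition, over non-chimeric
# contigs (a chimera spans two genes and has no single true label)
gene_partition_ari <- function(group_table, bm) {
  ids <- unlist(strsplit(group_table$members, ","))
  memb <- rep(group_table$group_id,
              vapply(strsplit(group_table$members, ","), length, integer(1)))
  pv <- pooled_provenance(bm)
  m <- match(ids, pv$pooled_id)
  keep <- pv$type[m] != "chimera"
  gene <- bm$truth$gene_of[pv$source_id[m]]
  mclust::adjustedRandIndex(memb[keep], gene[keep])
}
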