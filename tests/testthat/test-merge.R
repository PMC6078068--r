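mk_scores <- function(ids, comp, len = NULL, origin = "x") {
  data.frame(contig_id = ids, origin = origin,
             length = len %||% rep(100L, length(ids)),
             s_nuc = comp, s_cov = comp, s_ord = comp, s_seg = comp,
             composite = comp, stringsAsFactors = FALSE)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("select_representatives picks the argmax with documented tie-breaks", {
  cs <- contig_set(c("A", "B"), c(strrep("AC", 250), strrep("GT", 400)), "x")
  groups <- list(list(group_id = 1L, members = c("A", "B")))
  res <- select_representatives(groups, mk_scores(c("A", "B"), c(0.9, 0.5)),
                                cs)
  expect_equal(res$merged$id, "A")
  # equal score: longer contig wins
  res2 <- select_representatives(groups,
                                 mk_scores(c("A", "B"), c(0.7, 0.7),
                                           len = c(500L, 800L)), cs)
  expect_equal(res2$merged$id, "B")
  # equal score and length: smallest id wins
  res3 <- select_representatives(groups,
                                 mk_scores(c("A", "B"), c(0.7, 0.7)), cs)
  expect_equal(res3$merged$id, "A")
  expect_error(
    select_representatives(list(list(group_id = 1L, members = c("A", "Z"))),
                           mk_scores("A", 1), cs),
    "no score for contig")
})

test_that("winners are exhaustive per-group argmaxes on the benchmark", {
  res <- small_merge()
  sc <- res$scores
  srow <- stats::setNames(seq_len(nrow(sc)), sc$contig_id)
  for (i in seq_len(nrow(res$group_table))) {
    members <- strsplit(res$group_table$members[i], ",")[[1]]
    best <- max(sc$composite[srow[members]])
    expect_equal(res$group_table$winner_score[i], best)
    expect_true(res$group_table$winner_id[i] %in% members)
  }
  # one winner per group, merged size equals group count
  expect_equal(length(res$merged), nrow(res$group_table))
  expect_equal(sum(res$contribution), 1, tolerance = 1e-9)
})

test_that("merging two identical assemblies collapses duplicates", {
  truth <- simulate_transcriptome(15, seed = 71)
  rd <- simulate_reads(truth, 600, error_rate = 0, seed = 72)
  cs <- truth$transcripts
  res <- orthofuse(list(X = contig_set(cs$id, cs$seq, "X"),
                        Y = contig_set(cs$id, cs$seq, "Y")),
                   r1 = rd$r1, r2 = rd$r2)
  expect_equal(length(res$merged), 15L)
  expect_true(all(res$group_table$member_count == 2L))
})

test_that("orthofuse keeps union content from complementary assemblies", {
  truth <- simulate_transcriptome(20, seed = 73)
  rd <- simulate_reads(truth, 800, error_rate = 0, seed = 74)
  first <- truth$transcripts$id[1:10]
  second <- truth$transcripts$id[11:20]
  res <- orthofuse(list(A = truth$transcripts[first],
                        B = truth$transcripts[second]),
                   r1 = rd$r1, r2 = rd$r2)
  expect_equal(length(res$merged), 20L)
  expect_setequal(sub("^[AB]\\|", "", res$merged$id), truth$transcripts$id)
  expect_error(orthofuse(list(A = truth$transcripts)), "at least two")
})

test_that("merging is idempotent up to relabeling", {
  truth <- simulate_transcriptome(12, seed = 75)
  rd <- simulate_reads(truth, 500, error_rate = 0.005, seed = 76)
  bmk <- list(
    A = corrupt_assembly(truth, bias_profile("A", p_drop_low = 0.3,
                                             dropout_low_tpm = Inf),
                         seed = 1)$contigs,
    B = corrupt_assembly(truth, bias_profile("B", p_drop_low = 0.3,
                                             dropout_low_tpm = Inf),
                         seed = 2)$contigs)
  res1 <- orthofuse(bmk, r1 = rd$r1, r2 = rd$r2)
  m <- res1$merged
  res2 <- orthofuse(list(M1 = contig_set(m$id, m$seq, "M1"),
                         M2 = contig_set(m$id, m$seq, "M2")),
                    r1 = rd$r1, r2 = rd$r2)
  expect_setequal(sort(res2$merged$seq), sort(m$seq))
})

test_that("contribution_report counts winner origins", {
  cs <- contig_set(sprintf("c%d", 1:8), rep(strrep("ACGT", 30), 8),
                   c(rep("trinity", 4), rep("spades55", 2), "spades75",
                     "shannon"))
  groups <- lapply(1:8, function(i) list(group_id = i,
                                         members = sprintf("c%d", i)))
  res <- select_representatives(groups, mk_scores(cs$id, rep(0.5, 8)), cs)
  expect_equal(contribution_report(res)[["trinity"]], 0.5)
  expect_equal(contribution_report(res)[["spades55"]], 0.25)
  expect_equal(contribution_report(res)[["spades75"]], 0.125)
  expect_equal(contribution_report(res)[["shannon"]], 0.125)
})

test_that("gene duplication counts genes represented by multiple contigs", {
  truth <- simulate_transcriptome(10, seed = 77)
  pv <- list(A = data.frame(
    contig_id = c(truth$transcripts$id, paste0(truth$transcripts$id[1], "_f2")),
    source_id = c(truth$transcripts$id, truth$transcripts$id[1]),
    source2_id = NA_character_, type = "intact",
    stringsAsFactors = FALSE))
  # exactly one contig per gene: zero duplication
  ids1 <- paste0("A|", truth$transcripts$id)
  expect_equal(gene_duplication(ids1, pv, truth), 0.0)
  # two fragments of one gene (even in different groups): that gene once
  ids2 <- c(ids1, paste0("A|", truth$transcripts$id[1], "_f2"))
  expect_equal(gene_duplication(ids2, pv, truth), 0.1)
})

test_that("reference-free duplication measures residual redundancy", {
  s1 <- random_seq(400, seed = 78); s2 <- random_seq(400, seed = 79)
  cs <- contig_set(c("a", "b", "c"), c(s1, s1, s2), "m")
  res <- structure(list(merged = cs), class = "merge_result")
  out <- duplication_report(res)
  expect_equal(out$mode, "residual")
  expect_equal(out$duplication, 2 / 3)
})

test_that("the {AB, A, B} chimera group resolves to a non-chimeric winner", {
  # two genes with distinct expression; the chimera AB shows a coverage step
  set.seed(80)
  A <- random_seq(900); B <- random_seq(900)
  truth <- make_truth(c("A", "B"), c(A, B), c(8, 1))
  rd <- simulate_reads(truth, 1500, error_rate = 0, seed = 81)
  asm <- list(
    good = contig_set(c("A", "B"), c(A, B), "good"),
    chim = contig_set("AB", paste0(A, B), "chim"))
  res <- orthofuse(asm, r1 = rd$r1, r2 = rd$r2)
  grp <- res$group_table[grepl("chim\\|AB", res$group_table$members), ]
  # the selection contract holds: winner is the in-group argmax
  sc <- res$scores
  members <- strsplit(grp$members[1], ",")[[1]]
  best <- members[which.max(sc$composite[match(members, sc$contig_id)])]
  expect_equal(grp$winner_id[1], best)
  # and the chimera's s_seg deficit keeps it from winning
  expect_false(any(grepl("^chim\\|", res$merged$id)))
  expect_lt(sc$s_seg[sc$contig_id == "chim|AB"], 0.5)
})

test_that("orthofuse writes the declared run artifacts", {
  dir <- withr::local_tempdir()
  truth <- simulate_transcriptome(8, seed = 82)
  rd <- simulate_reads(truth, 300, error_rate = 0, seed = 83)
  res <- orthofuse(list(X = truth$transcripts, Y = truth$transcripts),
                   r1 = rd$r1, r2 = rd$r2, out_dir = dir)
  expect_true(all(file.exists(file.path(
    dir, c("merged.fasta", "groups.tsv", "contigscores.tsv",
           "contribution.tsv", "manifest.json")))))
  man <- jsonlite::read_json(file.path(dir, "manifest.json"))
  expect_setequal(unlist(man$outputs),
                  c("merged.fasta", "groups.tsv", "contigscores.tsv",
                    "contribution.tsv"))
  back <- read_fasta(file.path(dir, "merged.fasta"), "m")
  expect_equal(sort(back$seq), sort(res$merged$seq))
})
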