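test_that("mapping_rate counts pairs with both mates primary-mapped", {
  full <- do.call(rbind, lapply(1:100, function(i) make_aln(
    list(read_id = paste0("p", i), is_first = TRUE),
    list(read_id = paste0("p", i), is_first = FALSE))))
  expect_equal(mapping_rate(full, 100), 1.0)
  expect_equal(mapping_rate(empty_aln <- full[0, ], 10), 0.0)
  # a pair with only one mapped mate does not count
  half <- make_aln(list(read_id = "p1", is_first = TRUE))
  expect_equal(mapping_rate(half, 1), 0.0)
  expect_error(mapping_rate(full, 0), "n_pairs")
})

test_that("s_nuc is the primary-alignment match fraction", {
  expect_equal(s_nuc(make_aln(list(n_match = 100L, n_mismatch = 0L))), 1.0)
  expect_equal(s_nuc(make_aln(list(n_match = 90L, n_mismatch = 10L))), 0.9)
  expect_equal(s_nuc(make_aln(list(is_mapped = FALSE, is_primary = FALSE))), 0)
  # secondary alignments are excluded
  aln <- make_aln(list(n_match = 50L, aligned_len = 100L),
                  list(n_match = 100L, is_primary = FALSE))
  expect_equal(s_nuc(aln), 0.5)
})

test_that("s_nuc equals a per-record summation oracle on simulated data", {
  truth <- simulate_transcriptome(5, seed = 51)
  rd <- simulate_reads(truth, 300, error_rate = 0.02, seed = 52)
  aln <- builtin_map(rd$r1, rd$r2, truth$transcripts)
  cid <- truth$transcripts$id[1]
  sub <- aln[aln$contig_id %in% cid & aln$is_primary & aln$is_mapped, ]
  expect_equal(s_nuc(sub), sum(sub$n_match) / sum(sub$aligned_len))
  expect_true(all(sub$n_match + sub$n_mismatch <= sub$aligned_len))
})

test_that("s_cov is the covered fraction (interval union)", {
  one <- make_aln(list(pos = 0L, aligned_len = 50L))
  expect_equal(s_cov(one, 100L), 0.5)
  two <- make_aln(list(pos = 0L, aligned_len = 60L),
                  list(read_id = "r2", pos = 40L, aligned_len = 60L))
  expect_equal(s_cov(two, 100L), 1.0)
})

test_that("coverage matches a positional counting oracle on simulated reads", {
  truth <- simulate_transcriptome(1, seed = 53)
  rd <- simulate_reads(truth, 200, error_rate = 0, seed = 54)
  aln <- builtin_map(rd$r1, rd$r2, truth$transcripts)
  len <- nchar(truth$transcripts$seq)
  prim <- aln[aln$is_primary & aln$is_mapped, ]
  counts <- integer(len)
  for (r in seq_len(nrow(prim))) {
    span <- (prim$pos[r] + 1):(prim$pos[r] + prim$aligned_len[r])
    counts[span] <- counts[span] + 1L
  }
  expect_equal(txmerge:::contig_coverage(prim, len), counts)
  expect_equal(s_cov(prim, len), mean(counts > 0))
})

test_that("s_ord scores FR pairs within the insert bound, neutral when undefined", {
  mk_pair <- function(i, proper = TRUE, tlen = 250L) {
    p2 <- if (proper) 150L else 400L
    list(make_aln(list(read_id = paste0("p", i), pos = 0L, is_first = TRUE,
                       is_reverse = FALSE, mate_contig_id = "c",
                       mate_pos = p2, mate_is_reverse = TRUE,
                       template_len = tlen)),
         make_aln(list(read_id = paste0("p", i), pos = p2, is_first = FALSE,
                       is_reverse = proper, mate_contig_id = "c",
                       mate_pos = 0L, mate_is_reverse = FALSE,
                       template_len = -tlen)))[[c(1, 2)]]
  }
  pairs4 <- do.call(rbind, unlist(lapply(1:4, function(i) list(
    make_aln(list(read_id = paste0("p", i), pos = 0L, is_first = TRUE)),
    make_aln(list(read_id = paste0("p", i), pos = 150L, is_first = FALSE,
                  is_reverse = TRUE)))), recursive = FALSE))
  expect_equal(s_ord(pairs4, 250, 50), 1.0)
  # flip one mate's strand: 3/4 proper
  bad <- pairs4
  bad$is_reverse[bad$read_id == "p4" & !bad$is_first] <- FALSE
  expect_equal(s_ord(bad, 250, 50), 0.75)
  # a pair whose mate maps elsewhere is a bridging pair: improper
  expect_equal(s_ord(make_aln(list(read_id = "x")), 250, 50), 0.0)
  # no pairs touch the contig at all: neutral
  expect_equal(s_ord(make_aln(list(read_id = "x"))[0, ], 250, 50), 1.0)
  # an FR pair beyond mean + 3 sd is improper
  far <- do.call(rbind, list(
    make_aln(list(read_id = "p9", pos = 0L, is_first = TRUE)),
    make_aln(list(read_id = "p9", pos = 900L, is_first = FALSE,
                  is_reverse = TRUE, aligned_len = 100L))))
  expect_equal(s_ord(far, 250, 50), 0.0)
})

test_that("s_ord matches per-pair enumeration on the benchmark", {
  bm <- small_benchmark()
  pooled <- pool_assemblies(bm$assemblies)
  aln <- builtin_map(bm$reads$r1[1:500], bm$reads$r2[1:500], pooled)
  cid <- names(sort(table(aln$contig_id), decreasing = TRUE))[1]
  sub <- aln[aln$contig_id %in% cid, ]
  prim <- sub[sub$is_primary & sub$is_mapped, ]
  byread <- split(seq_len(nrow(prim)), prim$read_id)
  ok <- 0; tot <- length(byread)   # every pair touching the contig counts
  for (ix in byread) {
    if (length(ix) != 2L) next     # bridging pair: stays improper
    a <- prim[ix[1], ]; b <- prim[ix[2], ]
    left <- if (a$pos <= b$pos) a else b
    proper <- (a$is_reverse != b$is_reverse) && !left$is_reverse &&
      abs(max(a$pos + a$aligned_len, b$pos + b$aligned_len) -
            min(a$pos, b$pos)) <= 250 + 3 * 50
    ok <- ok + proper
  }
  expect_equal(s_ord(prim, 250, 50), ok / tot)
})

test_that("s_seg follows the BIC arithmetic oracle", {
  bic_oracle <- function(cov) {
    n <- length(cov); y <- log2(cov + 1)
    sse <- function(v) sum((v - mean(v))^2)
    sse1 <- sse(y)
    brk <- unique(pmax(1, pmin(n - 1, round(n * seq(0.1, 0.9, 0.1)))))
    sse2 <- min(sapply(brk, function(b) sse(y[1:b]) + sse(y[(b + 1):n])))
    v1 <- max(sse1 / n, 1e-9); v2 <- max(sse2 / n, 1e-9)
    b1 <- n * (log(2 * pi * v1) + 1) + 2 * log(n)
    b2 <- n * (log(2 * pi * v2) + 1) + 4 * log(n)
    exp(-(b1 - min(b1, b2)) / 2) /
      (exp(-(b1 - min(b1, b2)) / 2) + exp(-(b2 - min(b1, b2)) / 2))
  }
  unif <- rep(20L, 500)
  expect_gt(s_seg(unif), 0.5)  # the 2-segment model pays the extra parameters
  expect_equal(s_seg(unif), bic_oracle(unif))
  step <- c(rep(50L, 500), rep(1L, 500))   # chimera-junction profile
  expect_lt(s_seg(step), 0.5)
  expect_equal(s_seg(step), bic_oracle(step))
  set.seed(9)
  noisy <- rpois(400, 30)
  expect_equal(s_seg(noisy), bic_oracle(noisy))
  expect_equal(s_seg(c(5L)), 1.0)
  expect_equal(s_seg(integer(10)), 0.0)
})

test_that("composite scoring applies the floor and geometric mean exactly", {
  expect_equal(contig_score(1, 1, 1, 1), 1.0)
  expect_equal(contig_score(1, 1, 1, 0.0625), 0.5)
  expect_equal(contig_score(0, 1, 1, 1), 0.01^(1 / 4))
  expect_equal(contig_score(c(1, 0), c(1, 1), c(1, 1), c(0.0625, 1)),
               c(0.5, 0.01^(1 / 4)))
})

test_that("assembly_score is the contig geometric mean times mapping rate", {
  expect_equal(assembly_score(rep(1, 5), 0.9)$score, 0.9)
  expect_equal(assembly_score(c(0.25, 1.0), 1.0)$score, 0.5)
  expect_error(assembly_score(numeric(0), 1), "empty")
  set.seed(10)
  comp <- runif(200, 0.05, 1)
  ref <- exp(sum(log(comp)) / length(comp)) * 0.8   # log-domain oracle
  expect_equal(assembly_score(comp, 0.8)$score, ref, tolerance = 1e-9)
  expect_equal(assembly_score(sample(comp), 0.8)$score, ref,
               tolerance = 1e-9)  # permutation invariance
})

test_that("builtin mapper places error-free reads exactly", {
  truth <- simulate_transcriptome(10, seed = 61)
  rd <- simulate_reads(truth, 500, error_rate = 0, seed = 62)
  aln <- builtin_map(rd$r1, rd$r2, truth$transcripts)
  prim <- aln[aln$is_primary & aln$is_mapped, ]
  expect_equal(mapping_rate(aln, 500), 1.0)
  expect_true(all(prim$n_mismatch == 0L))
  # placements agree with the truth table for uniquely-placed reads
  m <- match(prim$read_id[prim$is_first], rd$placements$pair_id)
  expect_equal(prim$contig_id[prim$is_first],
               rd$placements$transcript_id[m])
})

test_that("reads from an absent transcript go unmapped", {
  truth <- simulate_transcriptome(4, seed = 63)
  rd <- simulate_reads(truth, 200, error_rate = 0, seed = 64)
  present <- truth$transcripts[truth$transcripts$id[1:3]]
  aln <- builtin_map(rd$r1, rd$r2, present)
  absent <- truth$transcripts$id[4]
  from_absent <- rd$placements$pair_id[rd$placements$transcript_id == absent]
  hit <- aln$read_id[aln$is_mapped]
  expect_false(any(from_absent %in% hit))
})

test_that("reported NM matches the placement-table mismatch counts", {
  truth <- simulate_transcriptome(10, seed = 65)
  rd <- simulate_reads(truth, 2000, error_rate = 0.01, seed = 66)
  aln <- builtin_map(rd$r1, rd$r2, truth$transcripts)
  prim <- aln[aln$is_primary & aln$is_mapped & aln$is_first, ]
  m <- match(prim$read_id, rd$placements$pair_id)
  same <- prim$contig_id == rd$placements$transcript_id[m]
  agree <- prim$n_mismatch[same] == rd$placements$n_err1[m][same]
  expect_gte(mean(agree), 0.99)
})

test_that("primary ties go to the lowest contig id under tie_break = 'id'", {
  s <- random_seq(400, seed = 67)
  cs <- contig_set(c("zeta", "alpha", "mid"), rep(s, 3), "x")
  r1 <- stats::setNames(substr(s, 1, 100), "p1")
  r2 <- stats::setNames(
    as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(substr(s, 151, 250)))), "p1")
  aln <- builtin_map(r1, r2, cs, tie_break = "id")
  prim <- aln[aln$is_primary & aln$is_mapped, ]
  expect_equal(unique(prim$contig_id), "alpha")
  expect_equal(sort(unique(aln$contig_id[aln$is_mapped])),
               c("alpha", "mid", "zeta"))   # ties kept as secondaries
  expect_true(all(aln$n_tie[aln$is_mapped] == 3L))
})

test_that("an exact fully-covered truth copy attains perfect components", {
  # deterministic tiling of error-free pairs so every base is covered
  s <- random_seq(800, seed = 68)
  cs <- contig_set("t", s, "x")
  starts <- seq(0, 600, by = 20)
  ids <- sprintf("p%03d", seq_along(starts))
  r1 <- stats::setNames(substring(s, starts + 1, starts + 100), ids)
  r2 <- stats::setNames(as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(substring(s, starts + 101, starts + 200)))), ids)
  aln <- builtin_map(r1, r2, cs)
  sc <- score_contigs(aln, cs)
  expect_equal(sc$s_nuc, 1.0)
  expect_equal(sc$s_cov, 1.0)
  expect_equal(sc$s_ord, 1.0)
})

test_that("chimeric contigs score lower s_seg than their sources", {
  bm <- small_benchmark()
  res <- small_merge()
  sc <- res$scores
  pv <- do.call(rbind, lapply(names(bm$provenance), function(l) {
    p <- bm$provenance[[l]]
    p$pooled_id <- paste0(l, "|", p$contig_id)
    p
  }))
  m <- match(sc$contig_id, pv$pooled_id)
  covered <- sc$s_cov > 0          # compare only read-supported contigs
  chim <- pv$type[m] == "chimera" & covered
  intact <- pv$type[m] == "intact" & covered
  expect_gt(sum(chim), 3)
  expect_lt(mean(sc$s_seg[chim]), mean(sc$s_seg[intact]))
})
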