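#' Construct a contig set
#'
#' A contig set is the atomic container of the pipeline: an ordered collection
#' of transcript contigs, each with a unique id, a nucleotide sequence over
#' `{A,C,G,T,N}`, and an assembler-of-origin label.
#'
#' @param id character vector of unique contig ids.
#' @param seq character vector of sequences (same length as `id`).
#' @param origin character vector (or scalar, recycled) of origin labels.
#' @return An object of class `contig_set` with fields `id`, `seq`, `origin`.
#' @export
contig_set <- function(id, seq, origin) {
  id <- as.character(id)
  seq <- toupper(as.character(seq))
  if (length(seq) != length(id)) stop("id and seq lengths differ")
  if (length(origin) == 1L) origin <- rep(origin, length(id))
  if (anyDuplicated(id)) {
    stop("duplicate contig id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  n_bad <- sum(vapply(gregexpr("[^ACGTN]", seq), function(m) {
    if (m[1] == -1L) 0L else length(m)
  }, integer(1)))
  if (n_bad > 0L) {
    seq <- gsub("[^ACGTN]", "N", seq)
    tx_log("seqio", sprintf("normalized %d non-ACGTN character(s) to N", n_bad))
  }
  if (length(id) && any(nchar(seq) < 1L)) stop("zero-length sequence")
  structure(list(id = id, seq = seq, origin = as.character(origin)),
            class = "contig_set")
}

#' @export
length.contig_set <- function(x) length(x$id)

#' @export
print.contig_set <- function(x, ...) {
  cat(sprintf("contig_set: %d contigs, origins: %s\n", length(x),
              paste(sort(unique(x$origin)), collapse = ", ")))
  invisible(x)
}

#' @export
`[.contig_set` <- function(x, i) {
  if (is.character(i)) i <- match(i, x$id)
  structure(list(id = x$id[i], seq = x$seq[i], origin = x$origin[i]),
            class = "contig_set")
}

contig_lengths <- function(x) stats::setNames(nchar(x$seq), x$id)

#' Read an assembly FASTA file
#'
#' Reads a (plain or gzipped) FASTA file into a [contig_set], uppercasing
#' sequences and normalizing any character outside `{A,C,G,T,N}` to `N`.
#'
#' @param path path to a FASTA file (gzip detected by magic bytes).
#' @param label origin label to attach to every contig.
#' @return A [contig_set].
#' @export
read_fasta <- function(path, label) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb"); magic <- readBin(con, "raw", 2L); close(con)
  gz <- length(magic) == 2L && identical(as.integer(magic), c(31L, 139L))
  first <- {
    con <- if (gz) gzfile(path, "rt") else file(path, "rt")
    on.exit(close(con), add = TRUE)
    ln <- readLines(con, n = 50L)
    ln[nzchar(ln) & !startsWith(ln, ";")]
  }
  if (length(first) == 0L) stop("empty assembly: ", path)
  if (!startsWith(first[1L], ">")) {
    stop("malformed FASTA (sequence before header) at line ",
         which(nzchar(readLines(path, n = 50L)))[1L], " of ", path)
  }
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0L) stop("empty assembly: ", path)
  ids <- sub("\\s.*$", "", names(x))
  contig_set(id = ids, seq = as.character(x), origin = label)
}

#' Write a contig set to FASTA
#'
#' Sequences are emitted single-line so that write/read round-trips are
#' byte-stable.
#'
#' @param x a [contig_set].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  stopifnot(inherits(x, "contig_set"))
  dss <- Biostrings::DNAStringSet(x$seq)
  names(dss) <- x$id
  Biostrings::writeXStringSet(dss, path,
                              width = max(20001L, max(nchar(x$seq), 0L) + 1L))
  invisible(path)
}

#' Pool assemblies into one labelled contig set
#'
#' Concatenates two or more assemblies into a single set, rewriting every
#' contig id to `"<label>|<original id>"` so the assembler of origin survives
#' round-trips through FASTA/SAM consumed by external tools. `|` is reserved
#' for this purpose.
#'
#' @param assemblies named list of [contig_set] objects; names are the labels.
#' @return A pooled [contig_set].
#' @export
pool_assemblies <- function(assemblies) {
  if (length(assemblies) < 2L) stop("merging requires at least two assemblies")
  labels <- names(assemblies)
  if (is.null(labels) || any(!nzchar(labels)))
    stop("assemblies must be a named list (label = contig_set)")
  if (anyDuplicated(labels)) stop("duplicate assembly labels")
  if (any(grepl("|", labels, fixed = TRUE))) stop("'|' is reserved in labels")
  contig_set(
    id = unlist(lapply(labels, function(l)
      paste0(l, "|", assemblies[[l]]$id)), use.names = FALSE),
    seq = unlist(lapply(assemblies, `[[`, "seq"), use.names = FALSE),
    origin = rep(labels, times = vapply(assemblies, length, integer(1)))
  )
}

read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  stats::setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

write_fastq <- function(seqs, ids, path, qual_char = "I") {
  dss <- Biostrings::DNAStringSet(toupper(seqs))
  names(dss) <- ids
  quals <- Biostrings::BStringSet(strrep(qual_char, nchar(seqs)))
  Biostrings::writeXStringSet(dss, path, format = "fastq", qualities = quals)
  invisible(path)
}

# --- SAM ---------------------------------------------------------------------

sam_flag_bits <- function(flag) {
  list(
    paired     = bitwAnd(flag, 0x1L)   != 0L,
    unmapped   = bitwAnd(flag, 0x4L)   != 0L,
    mate_unmapped = bitwAnd(flag, 0x8L) != 0L,
    reverse    = bitwAnd(flag, 0x10L)  != 0L,
    mate_reverse = bitwAnd(flag, 0x20L) != 0L,
    first      = bitwAnd(flag, 0x40L)  != 0L,
    secondary  = bitwAnd(flag, 0x100L) != 0L,
    supplementary = bitwAnd(flag, 0x800L) != 0L
  )
}

# reference span and query-aligned length from CIGAR strings (vectorized)
parse_cigar <- function(cigar) {
  ops <- gregexpr("\\d+[MIDNSHP=X]", cigar)
  ref_span <- integer(length(cigar))
  qry_aln  <- integer(length(cigar))
  ins <- integer(length(cigar))
  del <- integer(length(cigar))
  for (i in seq_along(cigar)) {
    if (cigar[i] == "*") next
    m <- regmatches(cigar[i], ops[i])[[1]]
    n <- as.integer(sub("[MIDNSHP=X]$", "", m))
    op <- sub("^\\d+", "", m)
    ref_span[i] <- sum(n[op %in% c("M", "D", "N", "=", "X")])
    qry_aln[i]  <- sum(n[op %in% c("M", "=", "X")])
    ins[i] <- sum(n[op == "I"])
    del[i] <- sum(n[op %in% c("D", "N")])
  }
  list(ref_span = ref_span, qry_aln = qry_aln, ins = ins, del = del)
}

# mismatch count from an MD tag (substituted reference bases outside deletions)
md_mismatches <- function(md) {
  vapply(md, function(s) {
    if (is.na(s)) return(NA_integer_)
    s <- gsub("\\^[ACGTN]+", "", s)
    sum(strsplit(gsub("[0-9]+", "", s), "")[[1]] %in% c("A", "C", "G", "T", "N"))
  }, integer(1), USE.NAMES = FALSE)
}

#' Read a SAM file into an alignment table
#'
#' Parses SAM text (header required) into one row per alignment record.
#' Coordinates are converted from SAM's 1-based POS to 0-based starts;
#' mismatch counts are derived from `NM` (preferred) or `MD` plus the CIGAR.
#' Unmapped and secondary/supplementary records are retained with
#' `is_primary = FALSE`; only primary records enter read-evidence scoring.
#'
#' @param path path to a SAM file.
#' @param contigs the [contig_set] the reads were aligned to; reference names
#'   must be a subset of its ids.
#' @return A `data.table` with one row per record: `read_id`, `contig_id`,
#'   `pos` (0-based), `aligned_len`, `n_match`, `n_mismatch`, `is_primary`,
#'   `is_mapped`, `is_reverse`, `is_first`, `mate_contig_id`,
#'   `mate_is_reverse`, `template_len`.
#' @export
read_sam <- function(path, contigs) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "@")]
  if (length(body) == 0L) {
    return(empty_alignments())
  }
  f <- data.table::tstrsplit(body, "\t", fixed = TRUE, keep = 1:9)
  dt <- data.table::data.table(
    read_id = f[[1]], flag = as.integer(f[[2]]), rname = f[[3]],
    pos1 = as.integer(f[[4]]), cigar = f[[6]], rnext = f[[7]],
    tlen = as.integer(f[[9]])
  )
  # optional tags
  nm <- rep(NA_integer_, nrow(dt))
  md <- rep(NA_character_, nrow(dt))
  tagm <- regmatches(body, regexpr("\tNM:i:\\d+", body))
  has_nm <- grepl("\tNM:i:", body, fixed = TRUE)
  nm[has_nm] <- as.integer(sub("\tNM:i:", "", tagm))
  mdm <- regmatches(body, regexpr("\tMD:Z:[0-9ACGTN^]+", body))
  has_md <- grepl("\tMD:Z:", body, fixed = TRUE)
  md[has_md] <- sub("\tMD:Z:", "", mdm)

  bits <- sam_flag_bits(dt$flag)
  mapped <- !bits$unmapped & dt$rname != "*"
  unknown <- setdiff(unique(dt$rname[mapped]), contigs$id)
  if (length(unknown)) {
    stop("SAM reference name(s) absent from contig set: ",
         paste(unknown, collapse = ", "))
  }
  cig <- parse_cigar(dt$cigar)
  n_mismatch <- nm - cig$ins - cig$del
  use_md <- mapped & is.na(n_mismatch)
  if (any(use_md)) n_mismatch[use_md] <- md_mismatches(md[use_md])
  if (any(mapped & is.na(n_mismatch))) {
    stop("cannot derive mismatch count (no NM or MD tag) for record(s): ",
         paste(utils::head(dt$read_id[mapped & is.na(n_mismatch)], 5),
               collapse = ", "))
  }
  n_mismatch[!mapped] <- NA_integer_
  out <- data.table::data.table(
    read_id = dt$read_id,
    contig_id = ifelse(mapped, dt$rname, NA_character_),
    pos = ifelse(mapped, dt$pos1 - 1L, NA_integer_),
    aligned_len = ifelse(mapped, cig$ref_span, NA_integer_),
    n_match = ifelse(mapped, cig$qry_aln - n_mismatch, NA_integer_),
    n_mismatch = n_mismatch,
    is_primary = mapped & !bits$secondary & !bits$supplementary,
    is_mapped = mapped,
    is_reverse = bits$reverse,
    is_first = !bits$paired | bits$first,
    mate_contig_id = ifelse(bits$paired & !bits$mate_unmapped & dt$rnext != "*",
                            ifelse(dt$rnext == "=", dt$rname, dt$rnext),
                            NA_character_),
    mate_is_reverse = ifelse(bits$paired, bits$mate_reverse, NA),
    template_len = ifelse(dt$tlen == 0L, NA_integer_, dt$tlen)
  )
  len <- contig_lengths(contigs)
  bad <- out$is_mapped & (out$pos + out$aligned_len > len[out$contig_id])
  if (any(bad, na.rm = TRUE)) {
    stop("alignment(s) extend past contig end: ",
         paste(utils::head(out$read_id[which(bad)], 5), collapse = ", "))
  }
  out[]
}

empty_alignments <- function() {
  data.table::data.table(
    read_id = character(), contig_id = character(), pos = integer(),
    aligned_len = integer(), n_match = integer(), n_mismatch = integer(),
    is_primary = logical(), is_mapped = logical(), is_reverse = logical(),
    is_first = logical(), mate_contig_id = character(),
    mate_is_reverse = logical(), template_len = integer()
  )
}

# Serialize an alignment table (as produced by the builtin mapper) to SAM.
write_sam <- function(aln, contigs, path, read_seqs = NULL) {
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", contigs$id, nchar(contigs$seq)),
           "@PG\tID:txmerge\tPN:txmerge")
  flag <- rep(1L, nrow(aln))  # paired
  flag <- flag + ifelse(aln$is_mapped, 0L, 4L)
  mate_mapped <- !is.na(aln$mate_contig_id)
  flag <- flag + ifelse(mate_mapped, 0L, 8L)
  flag <- flag + ifelse(aln$is_mapped & aln$is_reverse, 16L, 0L)
  flag <- flag + ifelse(mate_mapped & !is.na(aln$mate_is_reverse) &
                          aln$mate_is_reverse, 32L, 0L)
  flag <- flag + ifelse(aln$is_first, 64L, 128L)
  flag <- flag + ifelse(aln$is_mapped & !aln$is_primary, 256L, 0L)
  seqf <- if (is.null(read_seqs)) "*" else read_seqs
  rec <- paste(
    aln$read_id, flag,
    ifelse(aln$is_mapped, aln$contig_id, "*"),
    ifelse(aln$is_mapped, aln$pos + 1L, 0L),
    ifelse(aln$is_mapped, ifelse(aln$is_primary, 60L, 0L), 0L),
    ifelse(aln$is_mapped, paste0(aln$aligned_len, "M"), "*"),
    ifelse(mate_mapped, ifelse(!is.na(aln$contig_id) &
             aln$mate_contig_id == aln$contig_id, "=", aln$mate_contig_id), "*"),
    ifelse(mate_mapped & !is.na(aln$mate_pos), aln$mate_pos + 1L, 0L),
    ifelse(is.na(aln$template_len), 0L, aln$template_len),
    seqf, "*",
    ifelse(aln$is_mapped, paste0("NM:i:", aln$n_mismatch), ""),
    sep = "\t")
  rec <- sub("\t$", "", rec)
  writeLines(c(hdr, rec), path)
  invisible(path)
}
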