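`%||%` <- function(a, b) if (is.null(a)) b else a

.datatable.aware <- TRUE

#' @importFrom utils modifyList head tail
NULL

tx_log <- function(stage, ..., verbose = getOption("txmerge.verbose", TRUE)) {
  if (isTRUE(verbose)) {
    message(sprintf("[txmerge:%s] %s", stage, paste0(...)))
  }
  invisible(NULL)
}

#' Default run configuration
#'
#' Central defaults for the pipeline: clustering k-mer size and similarity
#' threshold, MCL inflation, sketch parameters, and the insert-size model
#' used by the pair-order score.
#'
#' @param ... named overrides of any default.
#' @return A named list of parameters.
#' @export
run_config <- function(...) {
  cfg <- list(
    k_cluster      = 31L,
    min_similarity = 0.1,
    inflation      = 4,
    expansion      = 2L,
    prune_threshold = 1e-5,
    max_iter       = 100L,
    tol            = 1e-6,
    sketch_k       = 51L,
    num_hashes     = 5000L,
    insert_mean    = 250L,
    insert_sd      = 50L,
    seed_k         = 31L,
    seed_step      = 10L,
    score_floor    = 0.01,
    seed           = 1L,
    threads        = 1L
  )
  ov <- list(...)
  if (length(ov)) {
    bad <- setdiff(names(ov), names(cfg))
    if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
    cfg <- utils::modifyList(cfg, ov)
  }
  cfg
}

# write a TSV report with optional '#'-prefixed comment lines, stable layout
write_report <- function(df, path, comments = character()) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_report <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
}
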