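# Tabular per-read call importers: megalodon, nanopolish, guppy, custom.
# Everything is normalized at the boundary to 0-based coordinates and
# natural-log likelihood ratio scores.

#' Import per-read modification calls from a tabular caller output
#'
#' Supported dialects:
#' \describe{
#'   \item{`megalodon`}{per-read text with columns `read_id, chrm, strand,
#'     pos, mod_log_prob, can_log_prob, mod_base`; the score is
#'     `mod_log_prob - can_log_prob` (already an LLR), `pos` 0-based.}
#'   \item{`nanopolish`}{methylation calls with columns `chromosome, strand,
#'     start, end, read_name, log_lik_ratio, ..., num_motifs, sequence`;
#'     `start` is treated as 1-based and converted. A row grouping
#'     `num_motifs > 1` CpGs is expanded to one call per CpG (positions from
#'     scanning the row's sequence context, anchored at the first motif), all
#'     sharing the row's log likelihood ratio.}
#'   \item{`guppy`}{per-read table with columns `read_id, chrom, strand, pos,
#'     prob_mod` (`pos` 0-based, probability converted to LLR).}
#'   \item{`custom`}{any tab/comma-separated table; `column_spec` names the
#'     columns (by name or 1-based index) and the score scale.}
#' }
#'
#' @param path Input file (tab-separated unless `column_spec$sep` says else).
#' @param dialect One of `"megalodon"`, `"nanopolish"`, `"guppy"`, `"custom"`.
#' @param sample Sample label for all imported calls.
#' @param column_spec For `dialect = "custom"` (and optional overrides for
#'   `"guppy"`): list with entries `read_id`, `chrom`, `pos`, `score`,
#'   optionally `strand`, plus `score_type` (`"probability"` or `"llr"`),
#'   `one_based` (logical, default `FALSE`), `header` (default `TRUE`) and
#'   `sep`.
#' @param mod_code Modification code label stored on the calls.
#' @param cutoffs [cutoff_config()] used for classification.
#' @return A [new_callstore()]; its `meta$import_report` records accepted and
#'   skipped row counts. Zero accepted rows is an error.
#' @export
import_tabular <- function(path, dialect = c("megalodon", "nanopolish",
                                             "guppy", "custom"),
                           sample, column_spec = NULL, mod_code = "m",
                           cutoffs = cutoff_config()) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  res <- switch(dialect,
    megalodon = .read_megalodon(path),
    nanopolish = .read_nanopolish(path),
    guppy = .read_custom(path, .guppy_spec(column_spec)),
    custom = .read_custom(path, column_spec)
  )
  if (nrow(res$calls) == 0L) {
    stop("zero accepted rows imported from ", path)
  }
  calls <- res$calls
  calls[, `:=`(sample = sample, mod_code = mod_code)]
  new_callstore(calls, cutoffs,
                meta = list(importer = dialect, source = path,
                            import_report = res$report))
}

.read_megalodon <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  need <- c("read_id", "chrm", "pos", "mod_log_prob", "can_log_prob")
  if (!all(need %in% names(dt))) {
    stop("megalodon table missing columns: ",
         paste(setdiff(need, names(dt)), collapse = ", "))
  }
  n_in <- nrow(dt)
  dt <- dt[!is.na(pos) & !is.na(mod_log_prob) & !is.na(can_log_prob)]
  calls <- data.table::data.table(
    read_id = as.character(dt$read_id),
    chrom = as.character(dt$chrm),
    ref_pos = as.integer(dt$pos),                  # megalodon is 0-based
    strand = if ("strand" %in% names(dt)) as.character(dt$strand) else "+",
    score = dt$mod_log_prob - dt$can_log_prob      # ln P(mod) - ln P(can)
  )
  list(calls = calls, report = list(n_rows = n_in, n_accepted = nrow(calls),
                                    n_skipped = n_in - nrow(calls)))
}

# expand a nanopolish row covering num_motifs CpGs: positions come from
# scanning the row's sequence context, anchored so the first motif sits at
# the row's start coordinate
.expand_nanopolish_row <- function(start0, num_motifs, sequence, motif = "CG") {
  if (is.na(num_motifs) || num_motifs <= 1L || is.na(sequence) ||
      !nzchar(sequence)) {
    return(start0)
  }
  offs <- as.integer(
    Biostrings::start(Biostrings::matchPattern(motif,
                                               Biostrings::DNAString(sequence)))) - 1L
  if (length(offs) == 0L) return(start0)
  start0 + (offs - offs[1L])
}

.read_nanopolish <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE)
  need <- c("chromosome", "start", "read_name", "log_lik_ratio")
  if (!all(need %in% names(dt))) {
    stop("nanopolish table missing columns: ",
         paste(setdiff(need, names(dt)), collapse = ", "))
  }
  n_in <- nrow(dt)
  dt <- dt[!is.na(start) & !is.na(log_lik_ratio)]
  if (!"num_motifs" %in% names(dt)) dt[, num_motifs := 1L]
  if (!"sequence" %in% names(dt)) dt[, sequence := NA_character_]
  if (!"strand" %in% names(dt)) dt[, strand := "+"]
  expanded <- dt[, {
    pos <- .expand_nanopolish_row(as.integer(start) - 1L,  # 1-based at boundary
                                  as.integer(num_motifs[1L]),
                                  as.character(sequence[1L]))
    .(read_id = rep(as.character(read_name), length(pos)),
      chrom = rep(as.character(chromosome), length(pos)),
      ref_pos = pos,
      strand = rep(as.character(strand), length(pos)),
      score = rep(as.numeric(log_lik_ratio), length(pos)))
  }, by = .(.row = seq_len(nrow(dt)))][, .row := NULL][]
  list(calls = expanded,
       report = list(n_rows = n_in, n_accepted = nrow(expanded),
                     n_skipped = n_in - nrow(dt)))
}

.guppy_spec <- function(overrides = NULL) {
  spec <- list(read_id = "read_id", chrom = "chrom", pos = "pos",
               score = "prob_mod", strand = "strand",
               score_type = "probability", one_based = FALSE,
               header = TRUE, sep = "\t")
  if (!is.null(overrides)) spec[names(overrides)] <- overrides
  spec
}

.read_custom <- function(path, spec) {
  if (is.null(spec)) stop("dialect 'custom' requires a column_spec")
  need <- c("read_id", "chrom", "pos", "score")
  if (!all(need %in% names(spec))) {
    stop("column_spec must name columns: ", paste(need, collapse = ", "))
  }
  score_type <- if (is.null(spec$score_type)) "probability" else spec$score_type
  if (!score_type %in% c("probability", "llr")) {
    stop("score_type must be 'probability' or 'llr'")
  }
  one_based <- isTRUE(spec$one_based)
  header <- if (is.null(spec$header)) TRUE else isTRUE(spec$header)
  sep <- if (is.null(spec$sep)) "\t" else spec$sep
  dt <- data.table::fread(path, sep = sep, header = header)
  col <- function(key) {
    k <- spec[[key]]
    if (is.null(k)) return(NULL)
    if (is.numeric(k)) dt[[as.integer(k)]] else dt[[k]]
  }
  n_in <- nrow(dt)
  calls <- data.table::data.table(
    read_id = as.character(col("read_id")),
    chrom = as.character(col("chrom")),
    ref_pos = suppressWarnings(as.integer(col("pos"))),
    strand = if (is.null(spec$strand)) "+" else as.character(col("strand")),
    score_raw = suppressWarnings(as.numeric(col("score")))
  )
  bad <- is.na(calls$ref_pos) | is.na(calls$score_raw)
  if (score_type == "probability") {
    bad <- bad | calls$score_raw < 0 | calls$score_raw > 1
  }
  calls <- calls[!bad]
  if (one_based) calls[, ref_pos := ref_pos - 1L]
  calls[, score := if (score_type == "probability")
    probability_to_llr(score_raw) else score_raw]
  calls[, score_raw := NULL]
  list(calls = calls,
       report = list(n_rows = n_in, n_accepted = nrow(calls),
                     n_skipped = sum(bad)))
}
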