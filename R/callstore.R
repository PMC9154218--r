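#' @import data.table
NULL

# canonical column order of the calls table
.call_cols <- c("read_id", "sample", "chrom", "ref_pos", "strand", "mod_code",
                "score", "call", "haplotype", "phase_set")

.empty_calls <- function() {
  data.table::data.table(
    read_id = character(), sample = character(), chrom = character(),
    ref_pos = integer(), strand = character(), mod_code = character(),
    score = numeric(), call = character(), haplotype = integer(),
    phase_set = character()
  )
}

#' Construct a call store
#'
#' A `CallStore` holds per-read, per-site modification calls (one row per
#' read/site pair), indexed by `(sample, chrom, ref_pos)`, together with the
#' per-sample classification cutoffs and import provenance. Coordinates are
#' 0-based; scores are natural-log likelihood ratios.
#'
#' @param calls A data.frame with columns `read_id, sample, chrom, ref_pos,
#'   strand, mod_code, score` (and optionally `haplotype`, `phase_set`).
#'   The `call` column is derived from `score` and the cutoffs.
#' @param cutoffs A [cutoff_config()] applied to every sample, or a named list
#'   of configs keyed by sample.
#' @param meta List of provenance metadata (importer, source path, import log).
#' @return A `CallStore` object.
#' @export
new_callstore <- function(calls = NULL, cutoffs = cutoff_config(), meta = list()) {
  if (is.null(calls) || nrow(calls) == 0L) {
    calls <- .empty_calls()
  } else {
    calls <- data.table::as.data.table(calls)
    if (!"haplotype" %in% names(calls)) calls[, haplotype := NA_integer_]
    if (!"phase_set" %in% names(calls)) calls[, phase_set := NA_character_]
    if (!"mod_code" %in% names(calls)) calls[, mod_code := "m"]
    if (!"strand" %in% names(calls)) calls[, strand := "+"]
    calls[, ref_pos := as.integer(ref_pos)]
    calls[, haplotype := as.integer(haplotype)]
    calls[, phase_set := as.character(phase_set)]
    if (any(calls$ref_pos < 0, na.rm = TRUE)) stop("ref_pos must be >= 0")
  }
  cutoffs <- .normalize_cutoffs(cutoffs, unique(calls$sample))
  calls[, call := classify_calls(score, .cutoffs_for(cutoffs, sample[1L])),
        by = sample]
  calls <- calls[, .call_cols, with = FALSE]
  data.table::setkeyv(calls, c("sample", "chrom", "ref_pos"))
  structure(list(calls = calls, cutoffs = cutoffs, meta = meta),
            class = "CallStore")
}

.normalize_cutoffs <- function(cutoffs, samples) {
  if (inherits(cutoffs, "cutoff_config")) {
    out <- stats::setNames(rep(list(cutoffs), length(samples)), samples)
    attr(out, "default") <- cutoffs
    return(out)
  }
  stopifnot(is.list(cutoffs))
  lapply(cutoffs, function(x) stopifnot(inherits(x, "cutoff_config")))
  if (is.null(attr(cutoffs, "default"))) attr(cutoffs, "default") <- cutoff_config()
  cutoffs
}

.cutoffs_for <- function(cutoffs, sample) {
  if (!is.null(cutoffs[[sample]])) cutoffs[[sample]]
  else if (!is.null(attr(cutoffs, "default"))) attr(cutoffs, "default")
  else cutoff_config()
}

#' Cutoffs in effect for a sample
#' @param store A `CallStore`.
#' @param sample Sample label.
#' @return The sample's [cutoff_config()] (the store default if none was set).
#' @export
store_cutoffs <- function(store, sample) {
  stopifnot(inherits(store, "CallStore"))
  .cutoffs_for(store$cutoffs, sample)
}

#' @export
print.CallStore <- function(x, ...) {
  cat("CallStore:", nrow(x$calls), "calls,",
      length(unique(x$calls$sample)), "sample(s),",
      length(unique(x$calls$chrom)), "sequence(s)\n")
  for (s in unique(x$calls$sample)) {
    cc <- .cutoffs_for(x$cutoffs, s)
    tab <- table(factor(x$calls[sample == s]$call, c("MOD", "UNMOD", "AMBIG")))
    cat(sprintf("  %s [lo=%g hi=%g]: MOD=%d UNMOD=%d AMBIG=%d\n",
                s, cc$lo, cc$hi, tab["MOD"], tab["UNMOD"], tab["AMBIG"]))
  }
  invisible(x)
}

#' Samples present in a store
#' @param store A `CallStore`.
#' @return Character vector of sample labels.
#' @export
store_samples <- function(store) unique(store$calls$sample)

#' Merge call stores
#'
#' Concatenates the calls of several stores. Duplicate calls (same read, sample,
#' site and modification code) are resolved last-import-wins, with a warning.
#'
#' @param ... `CallStore` objects.
#' @return A merged `CallStore`.
#' @export
merge_callstores <- function(...) {
  stores <- list(...)
  stopifnot(length(stores) >= 1L, all(vapply(stores, inherits, TRUE, "CallStore")))
  calls <- data.table::rbindlist(lapply(stores, `[[`, "calls"))
  key <- c("read_id", "sample", "chrom", "ref_pos", "mod_code")
  dup <- duplicated(calls, by = key, fromLast = TRUE)
  if (any(dup)) {
    warning(sum(dup), " duplicate call(s) replaced (last import wins)")
    calls <- calls[!dup]
  }
  cutoffs <- list()
  for (st in stores) for (s in names(st$cutoffs)) cutoffs[[s]] <- st$cutoffs[[s]]
  attr(cutoffs, "default") <- attr(stores[[1L]]$cutoffs, "default")
  new_callstore(calls, cutoffs, meta = list(merged_from = lapply(stores, `[[`, "meta")))
}

#' Query calls overlapping a region
#'
#' Returns exactly the calls whose `ref_pos` lies in the half-open interval
#' `[start, end)` on `chrom`.
#'
#' @param store A `CallStore`.
#' @param chrom Sequence name.
#' @param start,end 0-based half-open interval bounds.
#' @param samples Optional subset of sample labels (default: all).
#' @return A data.table of calls.
#' @export
query_calls <- function(store, chrom, start = 0L, end = .Machine$integer.max,
                        samples = NULL) {
  stopifnot(inherits(store, "CallStore"), start <= end)
  qc <- chrom
  out <- store$calls[chrom == qc & ref_pos >= start & ref_pos < end]
  if (!is.null(samples)) out <- out[sample %in% samples]
  out[]
}

#' Re-classify a sample's calls under new cutoffs
#'
#' Updates the cutoff configuration for one sample (or all samples) and
#' re-derives every affected call's MOD/UNMOD/AMBIG state. The total number of
#' calls is conserved.
#'
#' @param store A `CallStore`.
#' @param sample Sample label, or `NULL` to adjust every sample.
#' @param lo,hi New cutoffs, `lo < hi`.
#' @return The updated `CallStore`.
#' @examples
#' st <- new_callstore(data.frame(read_id = "r", sample = "s", chrom = "c",
#'                                ref_pos = 0:4, score = c(-3, -1, 0, 1, 3)))
#' table(adjust_cutoffs(st, "s", -0.5, 0.5)$calls$call)
#' @export
adjust_cutoffs <- function(store, sample = NULL, lo, hi) {
  stopifnot(inherits(store, "CallStore"))
  cfg <- cutoff_config(lo, hi)  # validates lo < hi
  targets <- if (is.null(sample)) store_samples(store) else sample
  for (s in targets) store$cutoffs[[s]] <- cfg
  if (is.null(sample)) attr(store$cutoffs, "default") <- cfg
  store$calls[sample %in% targets,
              call := classify_calls(score, cfg)]
  store
}

#' Classification counts per sample
#' @param store A `CallStore`.
#' @param samples Optional sample subset.
#' @return data.table with columns `sample, n_mod, n_unmod, n_ambig, n_total`.
#' @export
call_counts <- function(store, samples = NULL) {
  stopifnot(inherits(store, "CallStore"))
  calls <- store$calls
  if (!is.null(samples)) calls <- calls[sample %in% samples]
  calls[, .(
    n_mod = sum(call == "MOD"), n_unmod = sum(call == "UNMOD"),
    n_ambig = sum(call == "AMBIG"), n_total = .N
  ), by = sample][]
}

#' Kernel density estimate of a sample's score distribution
#'
#' Useful as an import-quality check: a clean bimodal shape with modes either
#' side of the cutoffs indicates a successful import. The bandwidth follows
#' Scott's rule and the 512-point grid spans the data range plus three
#' bandwidths on each side; the trapezoidal integral of the density over the
#' grid is 1 (to 1e-3).
#'
#' @param store A `CallStore`.
#' @param sample Sample label.
#' @return A `score_distribution` object: list with `grid`, `density`,
#'   `bandwidth`, per-class `counts` and the sample's `cutoffs`.
#' @export
score_distribution <- function(store, sample) {
  stopifnot(inherits(store, "CallStore"))
  s <- sample
  x <- store$calls[sample == s & is.finite(score)]$score
  if (length(unique(x)) < 2L) {
    stop("score_distribution requires >= 2 distinct finite scores for sample '",
         s, "'")
  }
  bw <- stats::bw.nrd(x)  # Scott's rule-of-thumb bandwidth
  # nearly-constant scores give a zero IQR; fall back to a positive width
  if (!is.finite(bw) || bw <= 0) bw <- max(stats::sd(x), 1e-3)
  d <- stats::density(x, bw = bw, n = 512L, cut = 3)
  cls <- factor(store$calls[sample == s]$call, c("MOD", "UNMOD", "AMBIG"))
  structure(list(
    sample = s, grid = d$x, density = d$y, bandwidth = bw,
    counts = as.list(table(cls)),
    cutoffs = .cutoffs_for(store$cutoffs, s)
  ), class = "score_distribution")
}

#' @export
print.score_distribution <- function(x, ...) {
  cat(sprintf("score distribution for '%s': %d grid points, bw=%.3g\n",
              x$sample, length(x$grid), x$bandwidth))
  cat(sprintf("  MOD=%d UNMOD=%d AMBIG=%d\n",
              x$counts$MOD, x$counts$UNMOD, x$counts$AMBIG))
  invisible(x)
}

#' Write a call store to a tab-separated file
#'
#' Plain-text persistence: `#`-prefixed header lines carry the per-sample
#' cutoffs and provenance, followed by the calls table. [read_callstore()]
#' restores an identical store.
#'
#' @param store A `CallStore`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_callstore <- function(store, path) {
  stopifnot(inherits(store, "CallStore"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##methkit-callstore\tv1", con)
  def <- attr(store$cutoffs, "default")
  writeLines(sprintf("##default-cutoffs\t%.17g\t%.17g", def$lo, def$hi), con)
  for (s in names(store$cutoffs)) {
    cc <- store$cutoffs[[s]]
    writeLines(sprintf("##cutoffs\t%s\t%.17g\t%.17g", s, cc$lo, cc$hi), con)
  }
  if (!is.null(store$meta$importer)) {
    writeLines(sprintf("##importer\t%s", store$meta$importer), con)
  }
  if (!is.null(store$meta$source)) {
    writeLines(sprintf("##source\t%s", store$meta$source), con)
  }
  utils::write.table(store$calls, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a call store written by [write_callstore()]
#' @param path File path.
#' @return A `CallStore`.
#' @export
read_callstore <- function(path) {
  hdr <- character()
  con <- file(path, "r")
  while (length(line <- readLines(con, n = 1L)) && startsWith(line, "##")) {
    hdr <- c(hdr, line)
  }
  close(con)
  if (!length(hdr) || !startsWith(hdr[1L], "##methkit-callstore")) {
    stop("not a methkit callstore file: ", path)
  }
  cutoffs <- list()
  meta <- list()
  for (h in hdr[-1L]) {
    f <- strsplit(h, "\t", fixed = TRUE)[[1L]]
    tag <- sub("^##", "", f[1L])
    if (tag == "cutoffs") {
      cutoffs[[f[2L]]] <- cutoff_config(as.numeric(f[3L]), as.numeric(f[4L]))
    } else if (tag == "default-cutoffs") {
      attr(cutoffs, "default") <- cutoff_config(as.numeric(f[2L]), as.numeric(f[3L]))
    } else if (tag %in% c("importer", "source")) {
      meta[[tag]] <- f[2L]
    }
  }
  calls <- data.table::fread(path, skip = length(hdr), sep = "\t",
                             header = TRUE, na.strings = "NA",
                             colClasses = list(character = c("read_id", "sample",
                                                             "chrom", "strand",
                                                             "mod_code",
                                                             "phase_set")))
  new_callstore(calls, cutoffs, meta)
}
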