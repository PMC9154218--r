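# Locus/region profile computation: motif-site indexing, genome -> motif-space
# translation, per-read call matrices, phase splitting and smoothing.

.load_reference <- function(reference) {
  if (inherits(reference, "DNAStringSet")) return(reference)
  if (inherits(reference, "DNAString")) {
    out <- Biostrings::DNAStringSet(reference)
    names(out) <- "seq"
    return(out)
  }
  if (is.character(reference) && length(reference) == 1L &&
      file.exists(reference)) {
    ref <- Biostrings::readDNAStringSet(reference)
    names(ref) <- sub("\\s.*$", "", names(ref))
    return(ref)
  }
  stop("reference must be a DNAStringSet or a FASTA path")
}

#' Find motif sites in a reference region
#'
#' Scans a region for every occurrence of `motif` (IUPAC ambiguity codes
#' allowed; overlapping matches reported) and records the 0-based position of
#' the scored base (`match start + offset`) of each occurrence, in ascending
#' order. These positions define the genome-to-motif-space map used by locus
#' plots.
#'
#' @param reference `DNAStringSet` or FASTA path.
#' @param region List `(chrom, start, end)` or `chrom:start-end` string;
#'   `NULL` scans the whole first sequence.
#' @param motif Motif string, e.g. `"CG"`, `"GATC"`.
#' @param offset 0-based offset of the scored base within the motif.
#' @return A `motif_index`: list with `chrom`, `start`, `end`, `motif`,
#'   `offset` and the integer vector `positions`.
#' @examples
#' ref <- Biostrings::DNAStringSet(c(chr1 = "ACGTCGCG"))
#' find_motif_sites(ref, NULL, "CG")$positions  # 1, 4, 6
#' @export
find_motif_sites <- function(reference, region = NULL, motif, offset = 0L) {
  stopifnot(nchar(motif) >= 1L, offset >= 0L, offset < nchar(motif))
  ref <- .load_reference(reference)
  if (is.character(region)) region <- parse_region(region)
  if (is.null(region)) {
    region <- list(chrom = names(ref)[1L], start = 0L,
                   end = length(ref[[1L]]))
  }
  if (!region$chrom %in% names(ref)) {
    stop("chromosome '", region$chrom, "' not in reference")
  }
  seqlen <- length(ref[[region$chrom]])
  if (region$start < 0L || region$end > seqlen || region$start >= region$end) {
    stop("region [", region$start, ",", region$end, ") outside reference ",
         region$chrom, " (length ", seqlen, ")")
  }
  sub <- Biostrings::subseq(ref[[region$chrom]], region$start + 1L, region$end)
  hits <- Biostrings::matchPattern(motif, sub, fixed = FALSE)
  pos <- region$start + Biostrings::start(hits) - 1L + as.integer(offset)
  pos <- pos[pos < region$end]
  structure(list(chrom = region$chrom, start = region$start,
                 end = region$end, motif = motif, offset = as.integer(offset),
                 positions = as.integer(sort(pos))),
            class = "motif_index")
}

#' Translate genome coordinates to motif-space ranks
#'
#' Rank `r` (0-based) is returned iff `index$positions[r + 1] == ref_pos`;
#' positions that are not motif sites map to `NA`. The mapping is strictly
#' order-preserving.
#'
#' @param index A `motif_index` from [find_motif_sites()].
#' @param ref_pos Integer vector of 0-based genomic positions.
#' @return Integer vector of 0-based motif ranks (`NA` for non-sites).
#' @export
genome_to_motifspace <- function(index, ref_pos) {
  stopifnot(inherits(index, "motif_index"))
  match(as.integer(ref_pos), index$positions) - 1L
}

#' Pooled sliding-window smoothing of methylation fractions
#'
#' The smoothed fraction at rank `r` pools the classified calls of all ranks
#' within a centered window of `window` sites (truncated at the edges):
#' `sum(n_mod) / sum(n_mod + n_unmod)`. Ranks whose window contains no
#' classified call yield `NA`. Pooling calls (rather than averaging per-site
#' fractions) is stable at low coverage; with exactly one classified call per
#' site the two coincide.
#'
#' @param n_mod,n_unmod Integer vectors of per-rank modified / unmodified
#'   call counts (same length, rank order).
#' @param window Odd integer window width in sites (`1` = no smoothing).
#' @return Numeric vector of smoothed fractions (length of `n_mod`).
#' @examples
#' smoothed_profile(c(1, 1, 0, 0, 1), c(0, 0, 1, 1, 0), window = 3)
#' @export
smoothed_profile <- function(n_mod, n_unmod, window = 21L) {
  stopifnot(length(n_mod) == length(n_unmod))
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1")
  if (window %% 2L == 0L) stop("window must be odd, got ", window)
  n <- length(n_mod)
  if (n == 0L) return(numeric())
  half <- window %/% 2L
  cm <- cumsum(c(0, n_mod)); cu <- cumsum(c(0, n_unmod))
  lo <- pmax(seq_len(n) - half, 1L); hi <- pmin(seq_len(n) + half, n)
  wm <- cm[hi + 1L] - cm[lo]; wu <- cu[hi + 1L] - cu[lo]
  ifelse(wm + wu > 0, wm / (wm + wu), NA_real_)
}

#' Assemble the data behind a locus plot
#'
#' For a sub-megabase region: builds the motif index, restricts the store to
#' reads overlapping the region, places each read's calls at motif ranks
#' (states MOD / UNMOD / AMBIG / NOCALL — NOCALL marks motif sites the read
#' covers no call for), collects raw (rank, score) points for every call, and
#' computes one pooled smoothed profile per group. With
#' `phase_mode = "tags"`, groups are split by the reads' HP haplotype tags
#' into `sample|hap<k>` / `sample|unphased`; groups always partition the
#' reads.
#'
#' @param store A `CallStore`.
#' @param reference `DNAStringSet` or FASTA path.
#' @param region `chrom:start-end` string or list; a warning is issued above
#'   1 Mb (region mode is recommended there).
#' @param motif,motif_offset Methylation motif.
#' @param samples Optional sample subset.
#' @param phase_mode `"none"` (one group per sample) or `"tags"` (split by
#'   HP tag).
#' @param smooth_window Odd window width in motif sites for the smoothed
#'   profile.
#' @param highlights Optional data.frame/BED path of intervals to highlight.
#' @return A `locus_data` object: list with `index`, `reads` (per-read
#'   metadata incl. group), `matrix` (reads x motif sites call states),
#'   `raw` (rank, score, group), `site_counts`, `smoothed` (per group), and
#'   `highlights`.
#' @export
build_locus_data <- function(store, reference, region, motif = "CG",
                             motif_offset = 0L, samples = NULL,
                             phase_mode = c("none", "tags"),
                             smooth_window = 21L, highlights = NULL) {
  stopifnot(inherits(store, "CallStore"))
  phase_mode <- match.arg(phase_mode)
  if (is.character(region)) region <- parse_region(region)
  if (region$end - region$start > 1e6) {
    warning("region spans ", region$end - region$start,
            " bp (> 1 Mb); region mode is recommended for large windows")
  }
  index <- find_motif_sites(reference, region, motif, motif_offset)
  if (length(index$positions) == 0L) {
    stop("no '", motif, "' motif sites in ", region$chrom, ":", region$start,
         "-", region$end, "; use region mode or another motif")
  }
  calls <- query_calls(store, region$chrom, region$start, region$end, samples)
  calls <- calls[, rank := genome_to_motifspace(index, ref_pos)][!is.na(rank)]
  reads <- calls[, .(
    sample = sample[1L],
    haplotype = haplotype[1L],
    phase_set = phase_set[1L],
    first_pos = min(ref_pos), last_pos = max(ref_pos), n_calls = .N
  ), by = read_id]
  if (phase_mode == "tags") {
    reads[, group := paste0(sample, "|",
                            ifelse(is.na(haplotype), "unphased",
                                   paste0("hap", haplotype)))]
  } else {
    reads[, group := sample]
  }
  calls[reads, group := i.group, on = "read_id"]
  nsite <- length(index$positions)
  mat <- matrix("NOCALL", nrow = nrow(reads), ncol = nsite,
                dimnames = list(reads$read_id, NULL))
  if (nrow(calls)) {
    mat[cbind(match(calls$read_id, reads$read_id), calls$rank + 1L)] <-
      calls$call
  }
  site_counts <- calls[call %in% c("MOD", "UNMOD"),
                       .(n_mod = sum(call == "MOD"),
                         n_unmod = sum(call == "UNMOD")),
                       by = .(group, rank)]
  groups <- sort(unique(reads$group))
  smoothed <- data.table::rbindlist(lapply(groups, function(g) {
    nm <- nu <- integer(nsite)
    gc <- site_counts[group == g]
    nm[gc$rank + 1L] <- gc$n_mod; nu[gc$rank + 1L] <- gc$n_unmod
    data.table::data.table(group = g, rank = seq_len(nsite) - 1L,
                           fraction = smoothed_profile(nm, nu, smooth_window))
  }))
  hl <- NULL
  if (!is.null(highlights)) {
    hl <- if (is.character(highlights)) read_segments_bed(highlights) else
      data.table::as.data.table(highlights)
    hl <- hl[chrom == region$chrom & end > region$start & start < region$end]
  }
  structure(list(index = index, reads = reads[], matrix = mat,
                 raw = calls[, .(read_id, group, sample, rank, ref_pos,
                                 score, call)],
                 site_counts = site_counts[],
                 smoothed = smoothed[!is.na(fraction)][],
                 smooth_window = as.integer(smooth_window),
                 highlights = hl),
            class = "locus_data")
}

#' @export
print.locus_data <- function(x, ...) {
  cat(sprintf("locus_data: %s:%d-%d, %d motif sites, %d reads, %d groups\n",
              x$index$chrom, x$index$start, x$index$end,
              length(x$index$positions), nrow(x$reads),
              length(unique(x$reads$group))))
  invisible(x)
}

#' Assemble the data behind a region plot
#'
#' For megabase-scale windows: delegates to [wgmeth_binned()] restricted to
#' the region (bins are normalized for motif occurrences; zero-motif bins are
#' masked) and smooths the per-bin pooled counts over a window of bins.
#' Masked bins are excluded from the smoothed series; the x-axis is the bin
#' index.
#'
#' @param store A `CallStore`.
#' @param reference `DNAStringSet` or FASTA path.
#' @param region `chrom:start-end` string or list.
#' @param motif,motif_offset Methylation motif.
#' @param bin_size Bin width in bp; alternatively give `n_bins`.
#' @param n_bins Number of bins tiling the region (used when `bin_size` is
#'   `NULL`).
#' @param samples Optional sample subset.
#' @param smooth_window Odd window width in bins.
#' @return A `region_data` object: list with per-sample `bins` tables and
#'   `smoothed` series over unmasked bins.
#' @export
build_region_data <- function(store, reference, region, motif = "CG",
                              motif_offset = 0L, bin_size = NULL,
                              n_bins = 50L, samples = NULL,
                              smooth_window = 5L) {
  stopifnot(inherits(store, "CallStore"))
  if (is.character(region)) region <- parse_region(region)
  if (is.null(bin_size)) {
    bin_size <- max(1L, as.integer(ceiling((region$end - region$start) /
                                             n_bins)))
  }
  if (is.null(samples)) samples <- store_samples(store)
  bins <- lapply(samples, function(s) {
    wgmeth_binned(store, s, bin_size, reference, motif, motif_offset,
                  chrom = region$chrom, start = region$start,
                  end = region$end)
  })
  names(bins) <- samples
  smoothed <- data.table::rbindlist(lapply(samples, function(s) {
    b <- bins[[s]][masked == FALSE]
    data.table::data.table(
      sample = s, bin = b$bin, start = b$start, end = b$end,
      fraction = smoothed_profile(b$n_mod, b$n_unmod, smooth_window))
  }))
  structure(list(region = region, bin_size = as.integer(bin_size),
                 bins = bins, smoothed = smoothed[!is.na(fraction)][],
                 smooth_window = as.integer(smooth_window)),
            class = "region_data")
}
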