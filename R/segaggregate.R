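# Aggregation of classified calls over segments, genome bins and single
# sites; bedMethyl / DSS / segmeth table writers.

.as_segments <- function(segments) {
  if (inherits(segments, "GRanges")) {
    dt <- data.table::data.table(
      chrom = as.character(GenomicRanges::seqnames(segments)),
      start = GenomicRanges::start(segments) - 1L,
      end = GenomicRanges::end(segments),
      name = if (!is.null(segments$name)) as.character(segments$name)
             else NA_character_,
      group = if (!is.null(segments$group)) as.character(segments$group)
              else NA_character_)
  } else {
    dt <- data.table::as.data.table(segments)
    if (!all(c("chrom", "start", "end") %in% names(dt))) {
      stop("segments need columns chrom, start, end")
    }
    if (!"name" %in% names(dt)) dt[, name := NA_character_]
    if (!"group" %in% names(dt)) dt[, group := NA_character_]
    dt <- dt[, .(chrom = as.character(chrom), start = as.integer(start),
                 end = as.integer(end), name = as.character(name),
                 group = as.character(group))]
  }
  if (any(dt$start >= dt$end)) stop("segments must satisfy start < end")
  dt
}

#' Read segments from a BED file
#'
#' BED3/4/6 plus an optional extra column used as the `group` label; when no
#' group column is present the `name` column doubles as the group.
#'
#' @param path BED file path.
#' @return data.table with columns `chrom, start, end, name, group, strand`.
#' @export
read_segments_bed <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t", fill = TRUE)
  n <- ncol(dt)
  out <- data.table::data.table(
    chrom = as.character(dt[[1L]]),
    start = as.integer(dt[[2L]]),
    end = as.integer(dt[[3L]]),
    name = if (n >= 4L) as.character(dt[[4L]]) else NA_character_,
    strand = if (n >= 6L) as.character(dt[[6L]]) else "+"
  )
  out[, group := if (n >= 7L) as.character(dt[[7L]]) else name]
  out[]
}

#' Aggregate methylation calls over segments
#'
#' One row per (segment, sample): counts of MOD/UNMOD/AMBIG calls whose
#' position falls in the segment's half-open interval, the number of distinct
#' contributing reads, the number of motif occurrences in the segment when a
#' reference is supplied, and the methylation fraction
#' `n_mod / (n_mod + n_unmod)` (NA when no classified calls). Ambiguous calls
#' are counted but excluded from the fraction.
#'
#' @param store A `CallStore`.
#' @param segments data.frame/GRanges of segments (`chrom, start, end`,
#'   optional `name`, `group`), or a BED path.
#' @param samples Optional sample subset (default: all in the store).
#' @param reference Optional reference (`DNAStringSet` or FASTA path) used to
#'   count motif sites per segment.
#' @param motif,motif_offset Motif scanned when `reference` is given.
#' @param min_coverage Minimum classified-call coverage; fractions for
#'   segments below it are set to NA (counts kept). Default 0 (no filter).
#' @return data.table with one row per segment x sample.
#' @export
segmeth <- function(store, segments, samples = NULL, reference = NULL,
                    motif = "CG", motif_offset = 0L, min_coverage = 0L) {
  stopifnot(inherits(store, "CallStore"))
  segs <- .as_segments(segments)
  if (is.null(samples)) samples <- store_samples(store)
  missing_chroms <- setdiff(unique(segs$chrom), unique(store$calls$chrom))
  if (length(missing_chroms)) {
    warning("segment chromosome(s) absent from store: ",
            paste(missing_chroms, collapse = ", "), "; reporting zero counts")
  }
  ref <- if (!is.null(reference)) .load_reference(reference)
  grid <- data.table::CJ(seg_idx = seq_len(nrow(segs)), sample = samples)
  out <- grid[, {
    sg <- segs[seg_idx]
    calls <- query_calls(store, sg$chrom, sg$start, sg$end, samples = sample)
    nm <- sum(calls$call == "MOD"); nu <- sum(calls$call == "UNMOD")
    n_sites <- if (is.null(ref) || !sg$chrom %in% names(ref)) NA_integer_ else
      length(find_motif_sites(ref, list(chrom = sg$chrom, start = sg$start,
                                        end = sg$end),
                              motif, motif_offset)$positions)
    .(chrom = sg$chrom, start = sg$start, end = sg$end, name = sg$name,
      group = sg$group,
      n_mod = nm, n_unmod = nu, n_ambig = sum(calls$call == "AMBIG"),
      n_reads = length(unique(calls$read_id)), n_motif_sites = n_sites,
      meth_fraction = if (nm + nu > 0L && nm + nu >= min_coverage)
        nm / (nm + nu) else NA_real_)
  }, by = .(seg_idx, sample)][, seg_idx := NULL]
  data.table::setcolorder(out, c("chrom", "start", "end", "name", "group",
                                 "sample"))
  out[]
}

#' Write a segmeth table
#'
#' Tab-separated, one row per segment with per-sample column blocks
#' (`<sample>_n_mod`, `<sample>_n_unmod`, `<sample>_n_ambig`,
#' `<sample>_meth_fraction`).
#'
#' @param stats Output of [segmeth()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segmeth_table <- function(stats, path) {
  wide <- data.table::dcast(
    data.table::as.data.table(stats),
    chrom + start + end + name + group ~ sample,
    value.var = c("n_mod", "n_unmod", "n_ambig", "meth_fraction"))
  data.table::setorder(wide, chrom, start)
  utils::write.table(wide, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Per-site aggregation of classified calls
#'
#' Collapses a sample's calls to one row per (chrom, site, strand,
#' mod_code): counts, coverage (`n_mod + n_unmod`) and methylation fraction.
#'
#' @param store A `CallStore`.
#' @param sample Sample label.
#' @return data.table sorted by (chrom, ref_pos).
#' @export
aggregate_sites <- function(store, sample) {
  stopifnot(inherits(store, "CallStore"))
  s <- sample
  out <- store$calls[sample == s, .(
    n_mod = sum(call == "MOD"), n_unmod = sum(call == "UNMOD"),
    n_ambig = sum(call == "AMBIG")
  ), by = .(chrom, ref_pos, strand, mod_code)]
  out[, coverage := n_mod + n_unmod]
  out[, meth_fraction := ifelse(coverage > 0, n_mod / coverage, NA_real_)]
  data.table::setorder(out, chrom, ref_pos)
  out[]
}

#' Bin a chromosome's calls into fixed-size, motif-normalized bins
#'
#' Bins tile the chromosome (the last, possibly partial, bin is kept and
#' flagged). Each bin carries call counts, the number of motif occurrences it
#' contains, and the methylation fraction; bins with zero motif sites are
#' masked.
#'
#' @param store A `CallStore`.
#' @param sample Sample label.
#' @param bin_size Bin width in bp (> 0).
#' @param reference Reference sequences (`DNAStringSet` or FASTA path).
#' @param motif,motif_offset Methylation motif scanned per bin.
#' @param chrom Chromosome to bin (default: the store's first).
#' @param start,end Optional sub-interval to bin (defaults: whole sequence).
#' @return A `genome_bin_profile`: data.table of bins plus attributes
#'   `chrom`, `bin_size`.
#' @export
wgmeth_binned <- function(store, sample, bin_size, reference, motif = "CG",
                          motif_offset = 0L, chrom = NULL, start = NULL,
                          end = NULL) {
  stopifnot(inherits(store, "CallStore"))
  if (!is.numeric(bin_size) || bin_size <= 0) stop("bin_size must be > 0")
  bin_size <- as.integer(bin_size)
  ref <- .load_reference(reference)
  if (is.null(chrom)) chrom <- unique(store$calls$chrom)[1L]
  if (!chrom %in% names(ref)) stop("chromosome '", chrom, "' not in reference")
  if (is.null(start)) start <- 0L
  if (is.null(end)) end <- length(ref[[chrom]])
  sites <- find_motif_sites(ref, list(chrom = chrom, start = start, end = end),
                            motif, motif_offset)$positions
  calls <- query_calls(store, chrom, start, end, samples = sample)
  starts <- seq.int(start, end - 1L, by = bin_size)
  bins <- data.table::data.table(
    bin = seq_along(starts) - 1L,
    start = starts,
    end = pmin(starts + bin_size, end))
  bins[, partial := end - start < bin_size]
  bin_of <- function(pos) pmin((pos - start) %/% bin_size, nrow(bins) - 1L)
  site_tab <- if (length(sites)) table(factor(bin_of(sites), bins$bin)) else
    table(factor(integer(), bins$bin))
  bins[, n_motif_sites := as.integer(site_tab)]
  for (cls in c("MOD", "UNMOD", "AMBIG")) {
    tab <- table(factor(bin_of(calls[call == cls]$ref_pos), bins$bin))
    bins[, paste0("n_", tolower(cls)) := as.integer(tab)]
  }
  bins[, masked := n_motif_sites == 0L]
  bins[, meth_fraction := ifelse(!masked & n_mod + n_unmod > 0,
                                 n_mod / (n_mod + n_unmod), NA_real_)]
  bins[, call_density := ifelse(n_motif_sites > 0,
                                (n_mod + n_unmod) / n_motif_sites, NA_real_)]
  data.table::setattr(bins, "chrom", chrom)
  data.table::setattr(bins, "bin_size", bin_size)
  data.table::setattr(bins, "class", c("genome_bin_profile", class(bins)))
  bins[]
}

#' Write per-site aggregates as bedMethyl
#'
#' BED9+2: chrom, start, end (= start + 1), name (modification code), score
#' (coverage capped at 1000), strand, thickStart, thickEnd, color, coverage
#' (`n_mod + n_unmod`) and percent methylation (rounded to integer). Sites
#' with zero classified calls are omitted; lines are sorted by
#' (chrom, start).
#'
#' @param sites Output of [aggregate_sites()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedmethyl <- function(sites, path) {
  dt <- data.table::as.data.table(sites)[coverage > 0]
  data.table::setorder(dt, chrom, ref_pos)
  lines <- dt[, sprintf("%s\t%d\t%d\t%s\t%d\t%s\t%d\t%d\t0,0,0\t%d\t%d",
                        chrom, ref_pos, ref_pos + 1L, mod_code,
                        pmin(1000L, coverage), strand, ref_pos, ref_pos + 1L,
                        coverage, as.integer(round(100 * meth_fraction)))]
  writeLines(lines, path)
  invisible(path)
}

#' Read a bedMethyl file
#' @param path bedMethyl path.
#' @return data.table with the 11 bedMethyl columns.
#' @export
read_bedmethyl <- function(path) {
  dt <- data.table::fread(path, header = FALSE, sep = "\t",
                          col.names = c("chrom", "start", "end", "name",
                                        "score", "strand", "thick_start",
                                        "thick_end", "color", "coverage",
                                        "percent"))
  dt[]
}

#' Write a per-sample DSS input table
#'
#' Tab-separated with header `chr pos N X`; `pos` is 1-based, `N` the
#' classified coverage (`n_mod + n_unmod`) and `X` the modified count. Sites
#' with zero classified calls are omitted.
#'
#' @param sites Output of [aggregate_sites()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dss_table <- function(sites, path) {
  dt <- data.table::as.data.table(sites)[coverage > 0]
  data.table::setorder(dt, chrom, ref_pos)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("chr\tpos\tN\tX", con)
  if (nrow(dt)) {
    writeLines(dt[, sprintf("%s\t%d\t%d\t%d", chrom, ref_pos + 1L, coverage,
                            n_mod)], con)
  }
  invisible(path)
}
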