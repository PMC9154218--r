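# BAM base-modification import: MM/ML tag decoding and CIGAR lifting.
#
# MM:Z sub-tags look like "C+m?,5,2,0;": canonical base, strand of the
# modified base relative to SEQ as stored ('+' or '-'), one or more
# modification codes, an optional '.'/'?' flag, then skip counts — the number
# of unmodified canonical bases to pass over between successive modified
# calls, in the read's original (sequencing) orientation. For reads aligned to
# the reverse strand the stored SEQ is the reverse complement of the
# sequenced read, so decoding walks the reverse complement of SEQ.

.parse_mm_subtags <- function(mm) {
  mm <- sub(";$", "", mm)
  if (!nzchar(mm)) return(list())
  lapply(strsplit(mm, ";", fixed = TRUE)[[1L]], function(sub) {
    m <- regmatches(sub, regexec("^([A-Zacgtun])([-+])([a-zA-Z]+|[0-9]+)([.?]?)(,.*)?$", sub))[[1L]]
    if (length(m) == 0L) return(NULL)
    skips <- if (is.na(m[6L]) || !nzchar(m[6L])) integer() else
      as.integer(strsplit(sub("^,", "", m[6L]), ",", fixed = TRUE)[[1L]])
    list(base = m[2L], mm_strand = m[3L],
         codes = strsplit(m[4L], "")[[1L]], flag = m[5L], skips = skips)
  })
}

# query(0-based, stored orientation) -> reference position (0-based), NA for
# bases in insertions / soft clips
.query_to_ref <- function(cigar, pos0) {
  ops <- GenomicAlignments::explodeCigarOps(cigar)[[1L]]
  lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1L]]
  qlen <- sum(lens[ops %in% c("M", "=", "X", "I", "S")])
  map <- rep(NA_integer_, qlen)
  q <- 0L; r <- pos0
  for (i in seq_along(ops)) {
    op <- ops[i]; n <- lens[i]
    if (op %in% c("M", "=", "X")) {
      map[(q + 1L):(q + n)] <- r:(r + n - 1L)
      q <- q + n; r <- r + n
    } else if (op %in% c("I", "S")) {
      q <- q + n
    } else if (op %in% c("D", "N")) {
      r <- r + n
    }  # H, P consume neither
  }
  map
}

.revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Decode one read's MM/ML tags into (ref_pos, strand, probability) rows.
# seq/cigar/pos0 are as stored in the BAM; is_reverse from flag bit 0x10.
.decode_read_modcalls <- function(seq, cigar, pos0, is_reverse, mm, ml,
                                  canonical_base, mod_code) {
  subtags <- .parse_mm_subtags(mm)
  if (!length(subtags)) return(NULL)
  read_seq <- if (is_reverse) .revcomp_chr(seq) else seq
  qlen <- nchar(read_seq)
  base_pos <- which(strsplit(read_seq, "")[[1L]] == canonical_base)  # 1-based
  ml_off <- 0L
  out <- NULL
  for (st in subtags) {
    if (is.null(st)) next
    n_entries <- length(st$skips) * length(st$codes)
    if (st$base != canonical_base || !(mod_code %in% st$codes)) {
      ml_off <- ml_off + n_entries  # skip this sub-tag's ML block
      next
    }
    if (ml_off + n_entries > length(ml)) {
      warning("MM/ML length mismatch; read skipped")
      return(NULL)
    }
    occ <- cumsum(st$skips + 1L)          # occurrence index among canonical bases
    keep <- occ <= length(base_pos)
    if (!all(keep)) {
      warning("MM skip counts exceed canonical base count; excess dropped")
    }
    # per-position ML bytes are interleaved across the sub-tag's codes
    code_idx <- match(mod_code, st$codes)
    bytes <- ml[ml_off + (seq_along(st$skips) - 1L) * length(st$codes) + code_idx]
    ml_off <- ml_off + n_entries
    qpos_read <- base_pos[occ[keep]] - 1L     # 0-based, original orientation
    bytes <- bytes[keep]
    qpos_stored <- if (is_reverse) qlen - 1L - qpos_read else qpos_read
    refmap <- .query_to_ref(cigar, pos0)
    rp <- refmap[qpos_stored + 1L]
    ok <- !is.na(rp)
    if (!any(ok)) next
    out <- rbind(out, data.frame(
      ref_pos = rp[ok],
      strand = if (is_reverse) "-" else "+",
      prob = ml_byte_to_probability(bytes[ok])
    ))
  }
  out
}

#' Import modified-base calls from a BAM file with MM/ML tags
#'
#' Reads a coordinate-sorted, indexed BAM whose reads carry SAM base
#' modification tags (`MM`/`ML`, legacy `Mm`/`Ml` accepted), decodes the
#' skip-count encoding over the canonical base in read orientation, lifts each
#' modified position to reference coordinates through the CIGAR (positions in
#' insertions or soft clips are dropped), converts ML probability bytes to log
#' likelihood ratios, and classifies every call against `cutoffs`. `HP`/`PS`
#' tags, when present, populate the haplotype and phase-set fields.
#'
#' For the symmetric CpG motif, minus-strand calls are collapsed onto the
#' plus-strand C coordinate (`ref_pos - 1`) so both strands aggregate to one
#' site; asymmetric motifs keep strands separate.
#'
#' @param bam_path Path to the BAM file (index `.bai` required).
#' @param sample Sample label recorded on every call.
#' @param mod_code Single-character modification code to extract (e.g. `"m"`).
#' @param motif Modification motif, e.g. `"CG"`; its base at `motif_offset`
#'   is the canonical base the MM tag is decoded over.
#' @param motif_offset 0-based offset of the scored base within `motif`.
#' @param collapse_strands Collapse minus-strand calls onto the plus-strand
#'   motif coordinate; default `TRUE` for the palindromic `"CG"` motif.
#' @param cutoffs [cutoff_config()] used for classification.
#' @param region Optional `GRanges` or `chrom:start-end` string restricting
#'   the import.
#' @return A [new_callstore()] with one call per (read, aligned modified
#'   position).
#' @export
import_bam_modcalls <- function(bam_path, sample, mod_code = "m", motif = "CG",
                                motif_offset = 0L,
                                collapse_strands = identical(toupper(motif), "CG"),
                                cutoffs = cutoff_config(), region = NULL) {
  if (!file.exists(bam_path)) stop("BAM file not found: ", bam_path)
  if (!file.exists(paste0(bam_path, ".bai")) &&
      !file.exists(sub("\\.bam$", ".bai", bam_path))) {
    stop("BAM index (.bai) not found for ", bam_path)
  }
  canonical_base <- toupper(substr(motif, motif_offset + 1L, motif_offset + 1L))
  param_args <- list(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq"),
    tag = c("MM", "ML", "Mm", "Ml", "HP", "PS"),
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isSupplementaryAlignment = FALSE)
  )
  if (!is.null(region)) {
    if (is.character(region)) region <- parse_region(region)
    param_args$which <- GenomicRanges::GRanges(
      region$chrom, IRanges::IRanges(region$start + 1L, region$end))
  }
  res <- Rsamtools::scanBam(Rsamtools::BamFile(bam_path),
                            param = do.call(Rsamtools::ScanBamParam, param_args))
  rows <- vector("list", length(res))
  n_skipped <- 0L
  for (chunk in seq_along(res)) {
    b <- res[[chunk]]
    n <- length(b$qname)
    if (n == 0L) next
    mm_all <- if (!is.null(b$tag$MM)) b$tag$MM else rep(NA_character_, n)
    ml_all <- if (!is.null(b$tag$ML)) b$tag$ML else vector("list", n)
    if (!is.null(b$tag$Mm)) mm_all[is.na(mm_all)] <- b$tag$Mm[is.na(mm_all)]
    if (!is.null(b$tag$Ml) && is.list(ml_all)) {
      miss <- vapply(ml_all, is.null, TRUE)
      ml_all[miss] <- b$tag$Ml[miss]
    }
    hp <- if (!is.null(b$tag$HP)) b$tag$HP else rep(NA_integer_, n)
    ps <- if (!is.null(b$tag$PS)) b$tag$PS else rep(NA_integer_, n)
    chunk_rows <- vector("list", n)
    for (i in seq_len(n)) {
      mm <- mm_all[i]
      if (is.na(mm) || !nzchar(mm)) next
      ml <- ml_all[[i]]
      ml <- if (is.null(ml)) integer() else as.integer(ml)
      dec <- tryCatch(
        .decode_read_modcalls(as.character(b$seq[i]), b$cigar[i],
                              b$pos[i] - 1L, bitwAnd(b$flag[i], 16L) > 0L,
                              mm, ml, canonical_base, mod_code),
        warning = function(w) {
          warning(conditionMessage(w), " (read ", b$qname[i], ")", call. = FALSE)
          NULL
        })
      if (is.null(dec) || nrow(dec) == 0L) {
        if (is.null(dec)) n_skipped <- n_skipped + 1L
        next
      }
      chunk_rows[[i]] <- data.table::data.table(
        read_id = b$qname[i], sample = sample,
        chrom = as.character(b$rname[i]), ref_pos = dec$ref_pos,
        strand = dec$strand, mod_code = mod_code,
        score = probability_to_llr(dec$prob),
        haplotype = as.integer(hp[i]),
        phase_set = if (is.na(ps[i])) NA_character_ else as.character(ps[i])
      )
    }
    rows[[chunk]] <- data.table::rbindlist(chunk_rows)
  }
  calls <- data.table::rbindlist(rows)
  if (nrow(calls) && collapse_strands) {
    calls[strand == "-", ref_pos := ref_pos - 1L]
  }
  new_callstore(calls, cutoffs,
                meta = list(importer = "bam", source = bam_path,
                            motif = motif, mod_code = mod_code,
                            n_reads_skipped = n_skipped))
}

#' Parse a "chrom:start-end" region string
#'
#' @param x Region string; coordinates 0-based half-open. Commas allowed.
#' @return A list with `chrom`, `start`, `end` (also usable as GRanges via
#'   coercion helpers in this package).
#' @export
parse_region <- function(x) {
  if (is.list(x) && all(c("chrom", "start", "end") %in% names(x))) return(x)
  m <- regmatches(x, regexec("^(.+):([0-9,]+)-([0-9,]+)$", x))[[1L]]
  if (length(m) != 4L) stop("cannot parse region '", x,
                            "' (expected chrom:start-end)")
  list(chrom = m[2L],
       start = as.integer(gsub(",", "", m[3L])),
       end = as.integer(gsub(",", "", m[4L])))
}
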