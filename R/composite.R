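# Repeat-consensus composite profiles: pairwise alignment of each genomic
# element to a consensus, genomic -> consensus coordinate lifting, pooling.

#' Align an element sequence to a repeat consensus
#'
#' Affine-gap pairwise alignment (match +2, mismatch -3, gap open -5, gap
#' extend -2; a gap of length k costs `open + k * extend`). The whole element
#' must align, while consensus overhangs at either end are penalty-free, so
#' truncated elements align to the sub-interval of the consensus they derive
#' from. The returned map covers exactly the match/mismatch columns; element
#' bases opposite a gap are unmapped.
#'
#' @param element Element sequence (character or `DNAString`), already
#'   reverse-complemented for minus-strand elements.
#' @param consensus Consensus sequence.
#' @param match,mismatch,gap_open,gap_extend Scoring parameters.
#' @param min_identity If non-`NULL`, alignments whose identity
#'   (matches / aligned columns) falls below it return `NULL` with a message.
#' @return A `consensus_map`: list with `mapping` (integer vector, 0-based
#'   element position -> 0-based consensus position, `NA` at gaps),
#'   `identity`, `score`, `n_aligned`, `consensus_length`.
#' @export
align_to_consensus <- function(element, consensus, match = 2, mismatch = -3,
                               gap_open = 5, gap_extend = 2,
                               min_identity = NULL) {
  el <- if (inherits(element, "DNAString")) element else
    Biostrings::DNAString(toupper(as.character(element)))
  cs <- if (inherits(consensus, "DNAString")) consensus else
    Biostrings::DNAString(toupper(as.character(consensus)))
  if (length(el) == 0L || length(cs) == 0L) {
    stop("element and consensus must be non-empty")
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = FALSE)
  # element global, consensus local: consensus end overhangs are free
  pa <- Biostrings::pairwiseAlignment(el, cs, substitutionMatrix = mat,
                                      gapOpening = gap_open,
                                      gapExtension = gap_extend,
                                      type = "global-local")
  pat <- strsplit(as.character(Biostrings::pattern(pa)), "")[[1L]]
  sub <- strsplit(as.character(Biostrings::subject(pa)), "")[[1L]]
  # aligned strings exclude end gaps; start offsets give the 0-based
  # positions of their first columns in element and consensus
  mapping <- rep(NA_integer_, length(el))
  qi <- Biostrings::start(Biostrings::pattern(pa)) - 1L
  si <- Biostrings::start(Biostrings::subject(pa)) - 1L
  n_match <- 0L; n_cols <- 0L
  for (k in seq_along(pat)) {
    pgap <- pat[k] == "-"; sgap <- sub[k] == "-"
    if (!pgap && !sgap) {
      mapping[qi + 1L] <- si
      n_cols <- n_cols + 1L
      if (pat[k] == sub[k]) n_match <- n_match + 1L
      qi <- qi + 1L; si <- si + 1L
    } else if (!pgap) {
      qi <- qi + 1L
    } else if (!sgap) {
      si <- si + 1L
    }
  }
  identity <- if (n_cols > 0L) n_match / n_cols else 0
  if (!is.null(min_identity) && identity < min_identity) {
    message(sprintf("alignment identity %.3f below min_identity %.3f; excluded",
                    identity, min_identity))
    return(NULL)
  }
  structure(list(mapping = mapping, identity = identity,
                 score = Biostrings::score(pa), n_aligned = n_cols,
                 consensus_length = length(cs)),
            class = "consensus_map")
}

#' @export
print.consensus_map <- function(x, ...) {
  cat(sprintf("consensus_map: %d/%d element bases aligned, identity %.3f, score %g\n",
              x$n_aligned, length(x$mapping), x$identity, x$score))
  invisible(x)
}

# genomic position (0-based) -> consensus position for one element,
# honouring the element's strand. For strand-collapsed palindromic motifs the
# collapsed plus-strand scored base corresponds, on a minus-strand element, to
# the motif's other-strand scored base minus_shift bp downstream.
.lift_positions <- function(pos, el, cmap, minus_shift = 0L) {
  idx <- if (el$strand == "-") el$end - 1L - (pos + minus_shift) else
    pos - el$start
  ok <- idx >= 0L & idx < length(cmap$mapping)
  out <- rep(NA_integer_, length(pos))
  out[ok] <- cmap$mapping[idx[ok] + 1L]
  out
}

#' Composite methylation profile over a repeat family
#'
#' Each element of a repeat family is extracted from the reference
#' (minus-strand elements reverse-complemented), aligned to the user-supplied
#' consensus, and its classified calls are lifted through the alignment into
#' consensus coordinates; all profiles therefore share the consensus
#' orientation. Lifted calls are pooled per consensus position into
#' `n_mod` / `n_unmod` counts and a methylation fraction. Calls landing on
#' consensus columns that are not consensus motif sites are still pooled but
#' flagged (`at_motif = FALSE`). Up to `max_elements` per-element call tracks
#' are retained for display, chosen by classified-call coverage with a
#' deterministic `(chrom, start)` tie-break.
#'
#' @param store A `CallStore`.
#' @param elements Elements of the family: data.frame with `chrom, start,
#'   end, strand` (BED6 path accepted).
#' @param reference `DNAStringSet` or FASTA path.
#' @param consensus Consensus sequence (character, `DNAString`, or FASTA
#'   path).
#' @param motif,motif_offset Motif scanned on the consensus for the composite
#'   axis.
#' @param samples Optional sample subset.
#' @param max_elements Number of individual element tracks to keep.
#' @param min_identity Elements aligning below this identity are excluded.
#' @param strand_collapsed Were the store's calls collapsed onto the
#'   plus-strand scored base of a palindromic motif (the importer default for
#'   `"CG"`)? Minus-strand elements then lift calls with the corresponding
#'   within-motif shift.
#' @param align_args Extra arguments passed to [align_to_consensus()].
#' @return A `composite_profile`: list with `pooled` (per consensus position),
#'   `element_tracks`, `elements` (with identities), `motif_positions`,
#'   `n_elements`.
#' @export
composite_profile <- function(store, elements, reference, consensus,
                              motif = "CG", motif_offset = 0L,
                              samples = NULL, max_elements = 20L,
                              min_identity = 0.6,
                              strand_collapsed = identical(toupper(motif), "CG"),
                              align_args = list()) {
  minus_shift <- if (strand_collapsed)
    nchar(motif) - 1L - 2L * as.integer(motif_offset) else 0L
  stopifnot(inherits(store, "CallStore"))
  els <- if (is.character(elements) && length(elements) == 1L &&
             file.exists(elements)) read_segments_bed(elements) else
    data.table::as.data.table(elements)
  if (!"strand" %in% names(els)) stop("elements require a strand column")
  ref <- .load_reference(reference)
  cs <- if (is.character(consensus) && length(consensus) == 1L &&
            file.exists(consensus)) .load_reference(consensus)[[1L]] else
    Biostrings::DNAString(toupper(as.character(consensus)))
  cons_sites <- find_motif_sites(Biostrings::DNAStringSet(stats::setNames(
    as.character(cs), "consensus")), NULL, motif, motif_offset)$positions
  els <- els[chrom %in% names(ref)]
  if (nrow(els) == 0L) stop("no elements on chromosomes present in reference")
  lifted <- vector("list", nrow(els))
  keep <- logical(nrow(els))
  identities <- rep(NA_real_, nrow(els))
  for (i in seq_len(nrow(els))) {
    el <- as.list(els[i])
    seq_el <- Biostrings::subseq(ref[[el$chrom]], el$start + 1L, el$end)
    if (el$strand == "-") seq_el <- Biostrings::reverseComplement(seq_el)
    cmap <- do.call(align_to_consensus,
                    c(list(seq_el, cs, min_identity = min_identity),
                      align_args))
    if (is.null(cmap)) next
    identities[i] <- cmap$identity
    calls <- query_calls(store, el$chrom, el$start, el$end, samples)
    calls <- calls[call %in% c("MOD", "UNMOD", "AMBIG")]
    cpos <- .lift_positions(calls$ref_pos, el, cmap, minus_shift)
    calls[, cons_pos := cpos]
    calls <- calls[!is.na(cons_pos)]
    calls[, element := i]
    keep[i] <- TRUE
    lifted[[i]] <- calls[, .(element, read_id, sample, cons_pos, score, call)]
  }
  if (!any(keep)) stop("zero elements survived the identity filter")
  all_calls <- data.table::rbindlist(lifted[keep])
  pooled <- all_calls[call != "AMBIG",
                      .(n_mod = sum(call == "MOD"),
                        n_unmod = sum(call == "UNMOD")),
                      by = cons_pos]
  data.table::setorder(pooled, cons_pos)
  pooled[, meth_fraction := n_mod / (n_mod + n_unmod)]
  pooled[, at_motif := cons_pos %in% cons_sites]
  cov <- all_calls[call != "AMBIG", .N, by = element]
  els[, element := .I]
  els[cov, n_classified := i.N, on = "element"]
  els[is.na(n_classified), n_classified := 0L]
  els[, identity := identities]
  ranked <- els[keep][order(-n_classified, chrom, start)]
  shown <- utils::head(ranked$element, max_elements)
  structure(list(
    pooled = pooled[],
    element_tracks = all_calls[element %in% shown][],
    elements = els[],
    kept = which(keep),
    shown_elements = shown,
    motif_positions = cons_sites,
    consensus_length = length(cs),
    n_elements = sum(keep)
  ), class = "composite_profile")
}

#' @export
print.composite_profile <- function(x, ...) {
  cat(sprintf("composite_profile: %d elements pooled (consensus %d bp, %d motif sites), %d tracks shown\n",
              x$n_elements, x$consensus_length, length(x$motif_positions),
              length(x$shown_elements)))
  invisible(x)
}
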