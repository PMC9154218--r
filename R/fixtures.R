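# Synthetic fixture generator: references with planted repeat families,
# MM/ML-tagged aligned reads with known per-site modification probabilities
# and haplotype effects, plus truth tables. Everything is deterministic under
# the config seed, so the whole import -> classify -> aggregate chain can be
# validated against known ground truth.

#' Simulation configuration
#'
#' Defaults describe a small methylome-like fixture: a random reference with
#' ~0.5 GC, CpG methylation at background probability 0.8, an unmethylated
#' island (p = 0.1), and an optional phased interval where the two haplotypes
#' diverge (0.9 vs 0.1). The per-call score model draws LLRs from
#' N(+4, 1.5) for modified and N(-4, 1.5) for unmodified states, giving the
#' bimodal score distribution typical of nanopore callers; ML bytes encode
#' the logistic transform of the drawn score.
#'
#' @param seed Mandatory RNG seed (integer).
#' @param ref_length Reference length in bp.
#' @param gc GC fraction of the random reference.
#' @param chrom Reference sequence name.
#' @param motif,mod_code Methylation motif and modification code.
#' @param background_p Modification probability outside truth intervals.
#' @param intervals data.frame `(start, end, p)` of truth intervals with
#'   their own modification probability.
#' @param phased Simulate haplotypes (HP/PS tags)?
#' @param phased_interval List `(start, end, p_hap1, p_hap2)` where the
#'   haplotypes diverge (used when `phased = TRUE`).
#' @param depth Mean read depth (>= 1).
#' @param read_length Read length in bp (reads shorter than the reference).
#' @param frac_reverse Fraction of reads simulated on the reverse strand.
#' @param score_model List `(mu_mod, sd_mod, mu_unmod, sd_unmod)` of the
#'   state-conditional LLR distributions.
#' @param indel_rate Per-base probability of opening a small indel in a read
#'   (0 = perfect full-match CIGARs; > 0 exercises CIGAR lifting).
#' @param repeats Optional repeat-family spec: list
#'   `(consensus_length, n_copies, mutation_rate, min_frac_length)`; copies
#'   are planted in the reference on random strands, some 5'-truncated.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed,
                       ref_length = 20000L,
                       gc = 0.5,
                       chrom = "chrS",
                       motif = "CG",
                       mod_code = "m",
                       background_p = 0.8,
                       intervals = data.frame(start = 2000L, end = 4000L,
                                              p = 0.1),
                       phased = FALSE,
                       phased_interval = list(start = 6000L, end = 9000L,
                                              p_hap1 = 0.9, p_hap2 = 0.1),
                       depth = 20L,
                       read_length = 3000L,
                       frac_reverse = 0.5,
                       score_model = list(mu_mod = 4, sd_mod = 1.5,
                                          mu_unmod = -4, sd_unmod = 1.5),
                       indel_rate = 0,
                       repeats = NULL) {
  if (missing(seed) || is.na(seed)) stop("sim_config requires a seed")
  stopifnot(depth >= 1L, ref_length > 0L, read_length > 0L,
            background_p >= 0, background_p <= 1)
  if (!is.null(intervals) && nrow(intervals)) {
    stopifnot(all(intervals$p >= 0 & intervals$p <= 1))
  }
  structure(as.list(environment()), class = "sim_config")
}

.sample_dna <- function(n, gc) {
  sample(c("A", "T", "G", "C"), n, replace = TRUE,
         prob = c((1 - gc) / 2, (1 - gc) / 2, gc / 2, gc / 2))
}

#' Simulate a reference (optionally with planted repeat copies)
#'
#' Draws a random sequence at the configured GC fraction and, when the config
#' carries a repeat-family spec, generates a random consensus and plants
#' mutated (and partly 5'-truncated) copies at non-overlapping positions on
#' random strands, recording their coordinates. Byte-for-byte reproducible
#' under the config seed.
#'
#' @param config A [sim_config()].
#' @return A `sim_reference`: list with `reference` (`DNAStringSet`),
#'   `truth_intervals` (data.table `start, end, p`), and when repeats are
#'   configured, `consensus` (`DNAString`) and `elements`
#'   (data.table `chrom, start, end, name, strand, frac_length`).
#' @export
simulate_reference <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  base <- .sample_dna(config$ref_length, config$gc)
  elements <- NULL
  consensus <- NULL
  if (!is.null(config$repeats)) {
    rp <- config$repeats
    cons <- .sample_dna(rp$consensus_length, max(config$gc, 0.5))
    consensus <- Biostrings::DNAString(paste(cons, collapse = ""))
    min_frac <- if (is.null(rp$min_frac_length)) 0.5 else rp$min_frac_length
    # plant copies in evenly spaced slots so they never overlap
    slot <- config$ref_length %/% (rp$n_copies + 1L)
    if (slot <= rp$consensus_length) {
      stop("reference too short for ", rp$n_copies, " repeat copies")
    }
    rows <- vector("list", rp$n_copies)
    for (i in seq_len(rp$n_copies)) {
      frac <- if (i == 1L) 1 else stats::runif(1, min_frac, 1)
      len <- max(10L, as.integer(round(frac * rp$consensus_length)))
      copy <- cons[(rp$consensus_length - len + 1L):rp$consensus_length]
      mut <- stats::runif(len) < rp$mutation_rate
      copy[mut] <- .sample_dna(sum(mut), 0.5)
      strand <- sample(c("+", "-"), 1L)
      if (strand == "-") {
        copy <- strsplit(as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(paste(copy, collapse = "")))), "")[[1L]]
      }
      start <- (i - 1L) * slot + sample.int(slot - len, 1L)
      base[(start + 1L):(start + len)] <- copy
      rows[[i]] <- data.table::data.table(
        chrom = config$chrom, start = start, end = start + len,
        name = paste0("rep", i), strand = strand, frac_length = len /
          rp$consensus_length)
    }
    elements <- data.table::rbindlist(rows)
  }
  reference <- Biostrings::DNAStringSet(paste(base, collapse = ""))
  names(reference) <- config$chrom
  truth <- if (!is.null(config$intervals) && nrow(config$intervals)) {
    data.table::as.data.table(config$intervals)
  } else {
    data.table::data.table(start = integer(), end = integer(), p = numeric())
  }
  structure(list(reference = reference, truth_intervals = truth,
                 consensus = consensus, elements = elements,
                 config = config),
            class = "sim_reference")
}

# true modification probability at a site for a haplotype
.true_p <- function(config, pos, hap = NA_integer_) {
  p <- rep(config$background_p, length(pos))
  iv <- config$intervals
  if (!is.null(iv) && nrow(iv)) {
    for (i in seq_len(nrow(iv))) {
      p[pos >= iv$start[i] & pos < iv$end[i]] <- iv$p[i]
    }
  }
  if (config$phased && !is.null(config$phased_interval)) {
    pi <- config$phased_interval
    inpi <- pos >= pi$start & pos < pi$end
    p[inpi & !is.na(hap) & hap == 1L] <- pi$p_hap1
    p[inpi & !is.na(hap) & hap == 2L] <- pi$p_hap2
  }
  p
}

# read-level alignment path: returns stored-orientation read sequence, the
# per-base reference position map (NA for insertions) and a CIGAR string
.sim_alignment <- function(ref_chars, start0, len, indel_rate, gc) {
  if (indel_rate <= 0) {
    idx <- (start0 + 1L):(start0 + len)
    return(list(seq = ref_chars[idx], refmap = idx - 1L,
                cigar = paste0(len, "M")))
  }
  seq <- character(0); refmap <- integer(0)
  ops <- character(0); lens <- integer(0)
  push <- function(op, n) {
    if (length(ops) && ops[length(ops)] == op) {
      lens[length(lens)] <<- lens[length(lens)] + n
    } else {
      ops <<- c(ops, op); lens <<- c(lens, n)
    }
  }
  r <- start0
  while (length(seq) < len && r < length(ref_chars)) {
    u <- stats::runif(1)
    if (u < indel_rate / 2) {            # insertion of 1-3 random bases
      n <- sample.int(3L, 1L)
      seq <- c(seq, .sample_dna(n, gc)); refmap <- c(refmap, rep(NA_integer_, n))
      push("I", n)
    } else if (u < indel_rate) {         # deletion of 1-3 reference bases
      n <- min(sample.int(3L, 1L), length(ref_chars) - r - 1L)
      if (n > 0L) { r <- r + n; push("D", n) }
    } else {
      seq <- c(seq, ref_chars[r + 1L]); refmap <- c(refmap, r)
      r <- r + 1L
      push("M", 1L)
    }
  }
  if (length(ops) && ops[1L] == "D") { ops <- ops[-1L]; lens <- lens[-1L] }
  if (length(ops) && ops[length(ops)] == "D") {
    ops <- ops[-length(ops)]; lens <- lens[-length(lens)]
  }
  list(seq = seq, refmap = refmap,
       cigar = paste0(lens, ops, collapse = ""))
}

#' Simulate MM/ML-tagged aligned reads
#'
#' Tiles the reference with reads at the configured depth. For every CpG (or
#' configured motif) a read covers on its own strand, the modified state is a
#' Bernoulli draw at the site's true (haplotype-adjusted) probability, the
#' per-call LLR is drawn from the state-conditional score model, and the ML
#' byte encodes its logistic transform. MM skip counts are computed over the
#' canonical base in read orientation; reverse-strand reads store the reverse
#' complement, so decoding them exercises the orientation logic. Phased
#' configs add HP/PS tags. The output BAM is coordinate-sorted and indexed.
#'
#' @param config A [sim_config()].
#' @param simref Output of [simulate_reference()] for the same config.
#' @param out_dir Directory for the BAM (created if needed).
#' @param prefix File name prefix.
#' @return List with `bam` (path), `n_reads`, `truth_sites` (data.table
#'   `chrom, pos, p, p_hap1, p_hap2`), and `truth_calls` (one row per
#'   simulated call: `read_id, pos, haplotype, state`).
#' @export
simulate_reads <- function(config, simref, out_dir = tempdir(),
                           prefix = "sim") {
  stopifnot(inherits(config, "sim_config"), inherits(simref, "sim_reference"))
  set.seed(config$seed + 1L)
  ref <- simref$reference[[config$chrom]]
  ref_chars <- strsplit(as.character(ref), "")[[1L]]
  L <- min(config$read_length, length(ref))
  n_reads <- as.integer(ceiling(config$depth * length(ref) / L))
  if (n_reads < 1L) stop("configuration yields zero reads")
  motif <- toupper(config$motif)
  mlen <- nchar(motif)
  # truth table over plus-strand motif sites
  site_pos <- find_motif_sites(simref$reference, NULL, motif, 0L)$positions
  truth_sites <- data.table::data.table(
    chrom = config$chrom, pos = site_pos,
    p = .true_p(config, site_pos),
    p_hap1 = .true_p(config, site_pos, 1L),
    p_hap2 = .true_p(config, site_pos, 2L))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sam_path <- file.path(out_dir, paste0(prefix, ".sam"))
  con <- file(sam_path, "w")
  writeLines(c("@HD\tVN:1.6\tSO:unsorted",
               sprintf("@SQ\tSN:%s\tLN:%d", config$chrom, length(ref))), con)
  sm <- config$score_model
  truth_calls <- vector("list", n_reads)
  collapse_cg <- identical(motif, "CG")
  for (i in seq_len(n_reads)) {
    start0 <- sample.int(length(ref) - L + 1L, 1L) - 1L
    is_rev <- stats::runif(1) < config$frac_reverse
    hap <- if (config$phased) sample(1:2, 1L) else NA_integer_
    aln <- .sim_alignment(ref_chars, start0, L, config$indel_rate, config$gc)
    qlen <- length(aln$seq)
    read_chars <- if (is_rev) {
      strsplit(as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(paste(aln$seq, collapse = "")))), "")[[1L]]
    } else aln$seq
    # motif occurrences in read orientation whose bases are all aligned to
    # consecutive reference positions (so the motif is genuine in reference)
    canon <- substr(motif, 1L, 1L)
    canon_pos <- which(read_chars == canon)              # 1-based read coords
    is_site <- logical(length(canon_pos))
    site_ref <- integer(length(canon_pos))               # collapsed ref coord
    for (k in seq_along(canon_pos)) {
      q <- canon_pos[k]
      if (q + mlen - 1L > qlen) next
      if (paste(read_chars[q:(q + mlen - 1L)], collapse = "") != motif) next
      stored <- if (is_rev) qlen - (q:(q + mlen - 1L)) + 1L else
        q:(q + mlen - 1L)
      rp <- aln$refmap[stored]
      if (anyNA(rp)) next
      step <- if (is_rev) -1L else 1L
      if (mlen > 1L && !all(diff(rp) == step)) next
      is_site[k] <- TRUE
      # collapse to the plus-strand scored-base coordinate
      site_ref[k] <- if (is_rev && collapse_cg) rp[1L] - 1L else
        if (is_rev) rp[1L] else rp[1L]
    }
    occ_idx <- which(is_site)
    mm <- sprintf("MM:Z:%s+%s;", canon, config$mod_code)
    ml <- NULL
    if (length(occ_idx)) {
      sites <- site_ref[occ_idx]
      p_true <- .true_p(config, sites, hap)
      state <- stats::rbinom(length(sites), 1L, p_true)
      score <- stats::rnorm(length(sites),
                            ifelse(state == 1L, sm$mu_mod, sm$mu_unmod),
                            ifelse(state == 1L, sm$sd_mod, sm$sd_unmod))
      bytes <- pmin(255L, pmax(0L, as.integer(floor(llr_to_probability(score) *
                                                      256))))
      skips <- diff(c(0L, occ_idx)) - 1L
      mm <- sprintf("MM:Z:%s+%s,%s;", canon, config$mod_code,
                    paste(skips, collapse = ","))
      ml <- sprintf("ML:B:C,%s", paste(bytes, collapse = ","))
      truth_calls[[i]] <- data.table::data.table(
        read_id = sprintf("read%05d", i), pos = sites, haplotype = hap,
        state = state)
    }
    flag <- if (is_rev) 16L else 0L
    pos1 <- min(aln$refmap, na.rm = TRUE) + 1L
    tags <- c(mm, ml)
    if (config$phased) tags <- c(tags, sprintf("HP:i:%d", hap), "PS:i:1")
    writeLines(paste(c(sprintf("read%05d", i), flag, config$chrom, pos1, 60L,
                       aln$cigar, "*", 0L, 0L,
                       paste(aln$seq, collapse = ""), "*", tags),
                     collapse = "\t"), con)
  }
  close(con)
  bam_stub <- file.path(out_dir, prefix)
  bam <- Rsamtools::asBam(sam_path, bam_stub, overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam_path)
  list(bam = bam, n_reads = n_reads, truth_sites = truth_sites,
       truth_calls = data.table::rbindlist(truth_calls))
}
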