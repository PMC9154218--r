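# Independent brute-force oracles used to cross-check the package
# implementations. These deliberately use naive per-base / per-cell loops and
# share no code with the package internals.

.comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

oracle_revcomp <- function(x) {
  paste(rev(.comp[strsplit(x, "")[[1]]]), collapse = "")
}

# expand a CIGAR string into one op letter per unit
oracle_cigar_units <- function(cigar) {
  parts <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  lens <- as.integer(sub("[MIDNSHP=X]$", "", parts))
  ops <- sub("^[0-9]+", "", parts)
  rep(ops, lens)
}

# brute-force per-base decoder: walks read and reference base by base and
# returns the (ref_pos, byte) pairs an MM/ML pair encodes for one read
oracle_decode_mm <- function(seq_stored, cigar, pos0, is_rev, mm, ml,
                             canonical = "C", code = "m") {
  # per-query-base reference position (stored orientation)
  units <- oracle_cigar_units(cigar)
  qref <- integer(0)
  r <- pos0
  for (op in units) {
    if (op %in% c("M", "=", "X")) { qref <- c(qref, r); r <- r + 1 }
    else if (op %in% c("I", "S")) qref <- c(qref, NA_integer_)
    else if (op %in% c("D", "N")) r <- r + 1
  }
  read_seq <- if (is_rev) oracle_revcomp(seq_stored) else seq_stored
  chars <- strsplit(read_seq, "")[[1]]
  qlen <- length(chars)
  # find the sub-tag for this base/code; track ML offset across sub-tags
  out <- NULL
  ml_used <- 0
  for (sub in strsplit(sub(";$", "", mm), ";")[[1]]) {
    head <- sub("^([A-Z][-+][a-zA-Z0-9]+[.?]?).*$", "\\1", sub)
    skips_str <- substring(sub, nchar(head) + 1)
    skips <- if (nzchar(skips_str))
      as.integer(strsplit(sub("^,", "", skips_str), ",")[[1]]) else integer(0)
    base <- substr(head, 1, 1)
    codes <- strsplit(gsub("[.?]$", "", substring(head, 3)), "")[[1]]
    if (base != canonical || !(code %in% codes)) {
      ml_used <- ml_used + length(skips) * length(codes)
      next
    }
    ci <- which(codes == code)
    # walk the read base by base, consuming skip counts
    want <- skips
    n_seen <- 0
    hit_q <- integer(0)
    wi <- 1
    for (q in seq_len(qlen)) {
      if (chars[q] != canonical) next
      if (wi > length(want)) break
      if (n_seen == want[wi]) {
        hit_q <- c(hit_q, q)
        n_seen <- 0
        wi <- wi + 1
      } else {
        n_seen <- n_seen + 1
      }
    }
    bytes <- ml[ml_used + (seq_along(skips) - 1) * length(codes) + ci]
    ml_used <- ml_used + length(skips) * length(codes)
    for (k in seq_along(hit_q)) {
      q <- hit_q[k]
      qs <- if (is_rev) qlen - q + 1 else q   # stored-orientation, 1-based
      rp <- qref[qs]
      if (is.na(rp)) next
      out <- rbind(out, data.frame(ref_pos = rp,
                                   strand = if (is_rev) "-" else "+",
                                   byte = bytes[k]))
    }
  }
  out
}

# write reads (list of lists) to a sorted+indexed BAM; returns the BAM path
write_test_bam <- function(reads, chrom = "chrT", chrom_len = 10000,
                           dir = withr::local_tempdir(.local_envir = parent.frame())) {
  sam <- file.path(dir, "t.sam")
  lines <- c("@HD\tVN:1.6",
             sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrom_len))
  for (rd in reads) {
    tags <- rd$tags
    lines <- c(lines, paste(c(
      rd$qname, rd$flag, chrom, rd$pos1, 60, rd$cigar, "*", 0, 0,
      rd$seq, "*", tags), collapse = "\t"))
  }
  writeLines(lines, sam)
  Rsamtools::asBam(sam, file.path(dir, "t"), overwrite = TRUE,
                   indexDestination = TRUE)
}

# random read with a random CIGAR over {M,I,D,S} and a random MM/ML pair
random_mm_read <- function(qname, max_len = 50, max_mod = 8) {
  repeat {
    qlen <- sample(10:max_len, 1)
    lead_s <- sample(0:3, 1); trail_s <- sample(0:3, 1)
    core <- qlen - lead_s - trail_s
    if (core < 1) next
    # alternate M/I/D blocks consuming exactly `core` query bases
    ops <- c(); lens <- c(); q <- 0; last <- ""
    while (q < core) {
      op <- sample(c("M", "M", "M", "I", "D"), 1)
      if (op == last) next
      if (op == "D" && length(ops) == 0) next
      n <- if (op == "D") sample(1:5, 1) else min(sample(1:12, 1), core - q)
      if (op != "D") q <- q + n
      ops <- c(ops, op); lens <- c(lens, n); last <- op
    }
    if (ops[length(ops)] == "D") {
      ops <- ops[-length(ops)]; lens <- lens[-length(lens)]
    }
    if (!any(ops == "M")) next
    if (lead_s > 0) { ops <- c("S", ops); lens <- c(lead_s, lens) }
    if (trail_s > 0) { ops <- c(ops, "S"); lens <- c(lens, trail_s) }
    break
  }
  seq <- paste(sample(c("A", "C", "G", "T"), qlen, replace = TRUE,
                      prob = c(0.2, 0.35, 0.25, 0.2)), collapse = "")
  cigar <- paste0(lens, ops, collapse = "")
  is_rev <- runif(1) < 0.5
  read_seq <- if (is_rev) oracle_revcomp(seq) else seq
  ncanon <- sum(strsplit(read_seq, "")[[1]] == "C")
  nmod <- min(sample(0:max_mod, 1), ncanon)
  if (nmod > 0) {
    occ <- sort(sample(seq_len(ncanon), nmod))
    skips <- diff(c(0, occ)) - 1
    bytes <- sample(0:255, nmod, replace = TRUE)
    mm <- sprintf("MM:Z:C+m,%s;", paste(skips, collapse = ","))
    ml <- sprintf("ML:B:C,%s", paste(bytes, collapse = ","))
    tags <- c(mm, ml)
  } else {
    bytes <- integer(0)
    mm <- "MM:Z:C+m;"
    tags <- mm
  }
  list(qname = qname, flag = if (is_rev) 16 else 0,
       pos1 = sample(1:1000, 1), cigar = cigar, seq = seq,
       tags = tags, mm = mm, ml_bytes = bytes, is_rev = is_rev)
}

# ---- affine-gap alignment oracle (Gotoh; element global, consensus ends
# free). Returns the optimal score.
oracle_align_score <- function(element, consensus, match = 2, mismatch = -3,
                               open = 5, ext = 2) {
  x <- strsplit(toupper(element), "")[[1]]
  y <- strsplit(toupper(consensus), "")[[1]]
  m <- length(x); n <- length(y)
  NEG <- -1e9
  M <- matrix(NEG, m + 1, n + 1)   # best ending in any state
  Ix <- matrix(NEG, m + 1, n + 1)  # element base vs gap
  Iy <- matrix(NEG, m + 1, n + 1)  # consensus base vs gap
  M[1, ] <- 0                      # free consensus leading overhang
  for (i in 2:(m + 1)) {
    Ix[i, 1] <- -(open + (i - 1) * ext)
    M[i, 1] <- Ix[i, 1]
    for (j in 2:(n + 1)) {
      s <- if (x[i - 1] == y[j - 1]) match else mismatch
      diag <- M[i - 1, j - 1] + s
      Ix[i, j] <- max(M[i - 1, j] - open - ext, Ix[i - 1, j] - ext)
      Iy[i, j] <- max(M[i, j - 1] - open - ext, Iy[i, j - 1] - ext)
      M[i, j] <- max(diag, Ix[i, j], Iy[i, j])
    }
  }
  max(M[m + 1, ])                  # free consensus trailing overhang
}

# score the alignment a consensus_map's mapping implies, under the same
# scoring scheme (consensus overhangs outside the aligned span are free)
oracle_score_mapping <- function(element, consensus, mapping, match = 2,
                                 mismatch = -3, open = 5, ext = 2) {
  x <- strsplit(toupper(element), "")[[1]]
  y <- strsplit(toupper(consensus), "")[[1]]
  idx <- which(!is.na(mapping))
  if (length(idx) == 0) return(NA_real_)
  sc <- 0
  # leading/trailing unmapped element bases are penalized gap runs
  lead <- idx[1] - 1
  trail <- length(x) - idx[length(idx)]
  if (lead > 0) sc <- sc - open - lead * ext
  if (trail > 0) sc <- sc - open - trail * ext
  for (k in seq_along(idx)) {
    i <- idx[k]
    sc <- sc + if (x[i] == y[mapping[i] + 1]) match else mismatch
    if (k > 1) {
      gap_el <- idx[k] - idx[k - 1] - 1          # unmapped element bases
      gap_cons <- mapping[idx[k]] - mapping[idx[k - 1]] - 1
      if (gap_el > 0) sc <- sc - open - gap_el * ext
      if (gap_cons > 0) sc <- sc - open - gap_cons * ext
    }
  }
  sc
}

# tiny manual call-store builder
make_store <- function(scores, chrom = "chr1", pos = seq_along(scores) - 1L,
                       sample = "s1", read_id = paste0("r", seq_along(scores)),
                       strand = "+", haplotype = NA_integer_,
                       cutoffs = cutoff_config()) {
  new_callstore(data.frame(read_id = read_id, sample = sample, chrom = chrom,
                           ref_pos = pos, strand = strand, score = scores,
                           haplotype = haplotype),
                cutoffs = cutoffs)
}
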