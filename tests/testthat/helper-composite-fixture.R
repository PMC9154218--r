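# small fixture: 3 full-length copies of a consensus planted in a reference,
# one on the minus strand, with MOD calls at every CpG of every copy
.composite_fixture <- function(score = 8) {
  cons <- "ATTACGGATCGTTACGATTTCGATACGGTA"      # CpGs at 4, 9, 14, 20, 25
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(cons)))
  pad <- strrep("T", 20)
  refseq <- paste0(pad, cons, pad, cons, pad, rc, pad)
  ref <- Biostrings::DNAStringSet(c(chr1 = refseq))
  L <- nchar(cons)
  els <- data.frame(chrom = "chr1",
                    start = c(20, 20 + L + 20, 20 + 2 * (L + 20)),
                    end = c(20 + L, 20 + 2 * L + 20, 20 + 2 * (L + 20) + L),
                    name = paste0("e", 1:3),
                    strand = c("+", "+", "-"))
  cpg <- find_motif_sites(Biostrings::DNAStringSet(c(cons = cons)), NULL,
                          "CG")$positions
  rows <- list()
  for (i in 1:3) {
    for (j in seq_along(cpg)) {
      gpos <- if (els$strand[i] == "+") els$start[i] + cpg[j] else
        els$end[i] - 2 - cpg[j]   # collapsed plus-strand C of the rc motif
      rows[[length(rows) + 1]] <- data.frame(
        read_id = paste0("rd", i), sample = "s1", chrom = "chr1",
        ref_pos = gpos, strand = "+", score = score)
    }
  }
  list(store = new_callstore(do.call(rbind, rows)), ref = ref, cons = cons,
       els = els, cpg = cpg)
}
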