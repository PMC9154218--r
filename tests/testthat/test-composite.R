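test_that("identical sequences align with identity 1 and identity mapping", {
  cm <- align_to_consensus("ACGTACGT", "ACGTACGT")
  expect_equal(cm$identity, 1)
  expect_equal(cm$mapping, 0:7)
  expect_equal(cm$score, 16)
})

test_that("a one-base deletion maps around the missing consensus column", {
  cm <- align_to_consensus("ACGACGT", "ACGTACGT")
  expect_equal(cm$mapping, c(0L, 1L, 2L, 4L, 5L, 6L, 7L))
  expect_equal(cm$score, 7)  # 7 matches - (5 + 2) gap
})

test_that("low-identity elements are excluded by min_identity", {
  expect_message(cm <- align_to_consensus("TTTTTTTT", "ACGTACGT",
                                          min_identity = 0.5),
                 "excluded")
  expect_null(cm)
})

test_that("truncated elements align to a consensus sub-interval without penalty", {
  cons <- "ACGTACGTACGTACGT"
  cm <- align_to_consensus("ACGTACGT", cons)   # 5'-truncated copy
  expect_equal(cm$identity, 1)
  expect_equal(cm$score, 16)                   # overhang costs nothing
  expect_equal(diff(cm$mapping), rep(1L, 7))
})

test_that("alignment score equals the brute-force DP and mappings attain it", {
  set.seed(61)
  for (k in 1:120) {
    m <- sample(5:30, 1); n <- sample(5:30, 1)
    el <- paste(sample(c("A", "C", "G", "T"), m, TRUE), collapse = "")
    cs <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
    cm <- align_to_consensus(el, cs)
    best <- oracle_align_score(el, cs)
    expect_equal(cm$score, best, info = paste(el, cs))
    if (any(!is.na(cm$mapping))) {
      expect_equal(oracle_score_mapping(el, cs, cm$mapping), best,
                   info = paste(el, cs))
    }
    # mapping is injective and strictly increasing over aligned columns
    mp <- cm$mapping[!is.na(cm$mapping)]
    expect_true(all(diff(mp) >= 1))
  }
})

test_that("identical fully methylated copies pool to fraction 1 at every consensus CpG", {
  fx <- .composite_fixture()
  cp <- composite_profile(fx$store, fx$els, fx$ref, fx$cons)
  expect_equal(cp$n_elements, 3L)
  expect_setequal(cp$pooled$cons_pos, fx$cpg)
  expect_true(all(cp$pooled$meth_fraction == 1))
  expect_true(all(cp$pooled$at_motif))
  expect_equal(sum(cp$pooled$n_mod), 3L * length(fx$cpg))
})

test_that("pooled counts conserve per-element lifted classified calls", {
  fx <- .composite_fixture()
  cp <- composite_profile(fx$store, fx$els, fx$ref, fx$cons)
  per_el <- cp$element_tracks[call != "AMBIG", .N, by = element]
  expect_equal(sum(cp$pooled$n_mod + cp$pooled$n_unmod), sum(per_el$N))
})

test_that("a deletion over a consensus CpG removes that copy's contribution there", {
  fx <- .composite_fixture()
  # delete 3 bp around the consensus CpG at 14 from element 2's sequence
  refchars <- strsplit(as.character(fx$ref[[1]]), "")[[1]]
  s2 <- fx$els$start[2]
  refchars <- refchars[-((s2 + 14):(s2 + 16))]
  ref2 <- Biostrings::DNAStringSet(c(chr1 = paste(refchars, collapse = "")))
  els2 <- fx$els
  els2$end[2] <- els2$end[2] - 3          # element 2 is 3 bp shorter
  els2$start[3] <- els2$start[3] - 3; els2$end[3] <- els2$end[3] - 3
  # rebuild calls for the shifted coordinates
  cpg <- fx$cpg
  rows <- list()
  for (i in 1:3) {
    for (j in seq_along(cpg)) {
      if (i == 2 && cpg[j] == 14) next   # deleted site: no call to make
      gpos <- if (els2$strand[i] == "+") els2$start[i] + cpg[j] else
        els2$end[i] - 2 - cpg[j]
      if (i == 2 && cpg[j] > 14) gpos <- gpos - 3
      rows[[length(rows) + 1]] <- data.frame(
        read_id = paste0("rd", i), sample = "s1", chrom = "chr1",
        ref_pos = gpos, strand = "+", score = 8)
    }
  }
  st2 <- new_callstore(do.call(rbind, rows))
  cp <- composite_profile(st2, els2, ref2, fx$cons)
  at14 <- cp$pooled[cons_pos == 14]
  expect_equal(at14$n_mod + at14$n_unmod, 2L)   # copies 1 and 3 only
  expect_equal(at14$meth_fraction, 1)
})

test_that("minus-strand element lifts are monotone decreasing in genome space", {
  fx <- .composite_fixture()
  cp <- composite_profile(fx$store, fx$els, fx$ref, fx$cons)
  e3 <- cp$element_tracks[element == 3]
  calls3 <- fx$store$calls[ref_pos >= fx$els$start[3] &
                             ref_pos < fx$els$end[3]][order(ref_pos)]
  lifted <- cp$element_tracks[element == 3][order(-cons_pos)]
  expect_equal(nrow(e3), nrow(calls3))
  # ascending genome position pairs with descending consensus position
  expect_true(all(diff(lifted$cons_pos) < 0) || nrow(lifted) < 2)
})

test_that("zero surviving elements is an error", {
  fx <- .composite_fixture()
  els <- fx$els
  expect_error(
    suppressMessages(composite_profile(fx$store, els, fx$ref,
                                       strrep("A", 30),
                                       min_identity = 0.9)),
    "zero elements")
})
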