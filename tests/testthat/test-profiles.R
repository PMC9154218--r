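test_that("motif sites are enumerated in ascending order", {
  ref <- Biostrings::DNAStringSet(c(chr1 = "ACGTCGCG"))
  expect_equal(find_motif_sites(ref, NULL, "CG")$positions, c(1L, 4L, 6L))
  ref2 <- Biostrings::DNAStringSet(c(chr1 = "GGATCC"))
  expect_equal(find_motif_sites(ref2, NULL, "GATC", offset = 1)$positions, 2L)
  ref3 <- Biostrings::DNAStringSet(c(chr1 = "CCCC"))
  expect_equal(find_motif_sites(ref3, NULL, "CG")$positions, integer(0))
  expect_error(find_motif_sites(ref, list(chrom = "chr1", start = 0,
                                          end = 99), "CG"),
               "outside")
  # overlapping matches are all reported
  ref4 <- Biostrings::DNAStringSet(c(chr1 = "CGCGCG"))
  expect_equal(find_motif_sites(ref4, NULL, "CGCG")$positions, c(0L, 2L))
  # IUPAC ambiguity codes resolve (GCH = GC followed by not-G)
  ref5 <- Biostrings::DNAStringSet(c(chr1 = "GCAGCGGCT"))
  expect_equal(find_motif_sites(ref5, NULL, "GCH", offset = 1)$positions,
               c(1L, 7L))
})

test_that("genome to motif-space translation is exact and order-preserving", {
  ref <- Biostrings::DNAStringSet(c(chr1 = "ACGTCGCG"))
  idx <- find_motif_sites(ref, NULL, "CG")
  expect_equal(genome_to_motifspace(idx, 4L), 1L)
  expect_true(is.na(genome_to_motifspace(idx, 5L)))
  ranks <- genome_to_motifspace(idx, idx$positions)
  expect_equal(ranks, c(0L, 1L, 2L))
  expect_true(all(diff(ranks) > 0))
})

test_that("pooled window smoothing matches hand-rolled expectations", {
  # one classified call per site: pooling equals the rolling mean
  expect_equal(smoothed_profile(c(1, 1, 0, 0, 1), c(0, 0, 1, 1, 0), 3),
               c(1, 2 / 3, 1 / 3, 1 / 3, 0.5))
  f <- c(1, 0, 1, 1, 0)
  expect_equal(smoothed_profile(f, 1 - f, 1), f)
  expect_equal(smoothed_profile(rep(2, 7), rep(0, 7), 5), rep(1, 7))
  expect_error(smoothed_profile(1:4, 1:4, 2), "odd")
  # empty windows yield NA
  expect_equal(smoothed_profile(c(1, 0, 0), c(0, 0, 0), 1),
               c(1, NA, NA))
})

test_that("smoothing is a convex combination of window site fractions", {
  set.seed(31)
  for (rep in 1:20) {
    n <- sample(5:40, 1)
    nm <- rpois(n, 3); nu <- rpois(n, 3)
    w <- sample(c(3, 5, 7), 1)
    sm <- smoothed_profile(nm, nu, w)
    frac <- ifelse(nm + nu > 0, nm / (nm + nu), NA)
    half <- w %/% 2
    for (r in seq_len(n)) {
      win <- frac[max(1, r - half):min(n, r + half)]
      if (all(is.na(win))) next
      expect_gte(sm[r] + 1e-12, min(win, na.rm = TRUE))
      expect_lte(sm[r] - 1e-12, max(win, na.rm = TRUE))
    }
  }
})

test_that("locus data places calls at motif ranks and tracks NOCALL", {
  ref <- Biostrings::DNAStringSet(c(chr1 = "ACGTCGTTCGAA"))  # CpGs 1,4,8
  st <- new_callstore(data.frame(
    read_id = c("A", "A", "A", "B", "B"),
    sample = "s1", chrom = "chr1",
    ref_pos = c(1L, 4L, 8L, 1L, 8L),
    strand = "+",
    score = c(5, 5, 5, -5, -5)))
  ld <- build_locus_data(st, ref, list(chrom = "chr1", start = 0, end = 12),
                         smooth_window = 1)
  expect_equal(dim(ld$matrix), c(2L, 3L))
  expect_equal(unname(ld$matrix["A", ]), c("MOD", "MOD", "MOD"))
  expect_equal(unname(ld$matrix["B", ]), c("UNMOD", "NOCALL", "UNMOD"))
  expect_equal(nrow(ld$raw), 5L)
  expect_error(build_locus_data(st, Biostrings::DNAStringSet(c(chr1 = "AAAATTTTAAAA")),
                                list(chrom = "chr1", start = 0, end = 12)),
               "motif sites")
})

test_that("phase groups partition the reads", {
  ref <- Biostrings::DNAStringSet(c(chr1 = "ACGTCGTTCGAA"))
  st <- new_callstore(data.frame(
    read_id = c("A", "B", "C", "D"), sample = "s1", chrom = "chr1",
    ref_pos = 1L, strand = "+", score = 5,
    haplotype = c(1L, 2L, NA, 1L)))
  ld <- build_locus_data(st, ref, list(chrom = "chr1", start = 0, end = 12),
                         phase_mode = "tags", smooth_window = 1)
  expect_setequal(unique(ld$reads$group),
                  c("s1|hap1", "s1|hap2", "s1|unphased"))
  expect_equal(nrow(ld$reads), 4L)
  expect_equal(sum(table(ld$reads$group)), 4L)
  expect_equal(anyDuplicated(ld$reads$read_id), 0L)
  ld2 <- build_locus_data(st, ref, list(chrom = "chr1", start = 0, end = 12),
                          phase_mode = "none", smooth_window = 1)
  expect_equal(unique(ld2$reads$group), "s1")
})

test_that("whole-region locus fraction agrees with segmeth", {
  cfg <- sim_config(seed = 41, ref_length = 4000, depth = 10,
                    read_length = 800)
  simref <- simulate_reference(cfg)
  sim <- simulate_reads(cfg, simref, out_dir = withr::local_tempdir())
  st <- import_bam_modcalls(sim$bam, "s1")
  ld <- build_locus_data(st, simref$reference,
                         list(chrom = "chrS", start = 1000, end = 2000),
                         smooth_window = 1)
  lf <- ld$raw[call %in% c("MOD", "UNMOD"),
               sum(call == "MOD") / .N]
  sf <- segmeth(st, data.frame(chrom = "chrS", start = 1000,
                               end = 2000))$meth_fraction
  expect_equal(lf, sf, tolerance = 1e-12)
})

test_that("region data recovers uniform methylation and matches wgmeth_binned", {
  cfg <- sim_config(seed = 43, ref_length = 10000, depth = 15,
                    read_length = 2000, background_p = 0.7, intervals = NULL)
  simref <- simulate_reference(cfg)
  sim <- simulate_reads(cfg, simref, out_dir = withr::local_tempdir())
  st <- import_bam_modcalls(sim$bam, "s1")
  rd <- build_region_data(st, simref$reference,
                          list(chrom = "chrS", start = 0, end = 10000),
                          bin_size = 1000)
  b <- rd$bins$s1
  expect_equal(nrow(b), 10L)
  expect_equal(b$end - b$start, rep(1000L, 10))
  ok <- b[masked == FALSE & n_mod + n_unmod > 0]
  m <- ok$n_mod + ok$n_unmod
  ci <- 4 * sqrt(0.7 * 0.3 / m)
  expect_true(all(abs(ok$meth_fraction - 0.7) <= pmax(ci, 0.05)))
  # consistency with direct binning of the same chromosome
  wb <- wgmeth_binned(st, "s1", 1000, simref$reference, chrom = "chrS")
  expect_equal(as.data.frame(b), as.data.frame(wb))
})
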