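test_that("segment stats count calls by class with half-open overlap", {
  st <- make_store(c(3, 4, 5, -3, 1, 0), pos = c(10L, 20L, 30L, 40L, 50L, 60L))
  segs <- data.frame(chrom = "chr1", start = 0, end = 100)
  out <- segmeth(st, segs)
  expect_equal(out$n_mod, 3L)
  expect_equal(out$n_unmod, 1L)
  expect_equal(out$n_ambig, 2L)
  expect_equal(out$meth_fraction, 0.75)
  # only-AMBIG segment reports NA
  amb <- segmeth(make_store(c(0, 1), pos = c(5L, 6L)),
                 data.frame(chrom = "chr1", start = 0, end = 10))
  expect_true(is.na(amb$meth_fraction))
  expect_equal(amb$n_ambig, 2L)
  # a call at the boundary belongs to the right-hand segment only
  bnd <- segmeth(make_store(3, pos = 50L),
                 data.frame(chrom = "chr1", start = c(0, 50),
                            end = c(50, 100)))
  expect_equal(bnd$n_mod, c(0L, 1L))
})

test_that("segments on chromosomes absent from the store give zero rows with warning", {
  st <- make_store(c(3, -3))
  expect_warning(out <- segmeth(st, data.frame(chrom = "chrX", start = 0,
                                               end = 10)),
                 "absent")
  expect_equal(out$n_mod + out$n_unmod + out$n_ambig, 0L)
})

test_that("segment aggregation matches a brute-force per-call loop", {
  set.seed(11)
  n <- 400
  st <- new_callstore(data.frame(
    read_id = paste0("r", sample(1:60, n, TRUE)),
    sample = sample(c("a", "b"), n, TRUE),
    chrom = "chr1",
    ref_pos = sample(0:2000, n, TRUE),
    strand = "+",
    score = rnorm(n, sd = 4)))
  segs <- data.frame(chrom = "chr1",
                     start = seq(0, 1800, by = 200),
                     end = seq(200, 2000, by = 200))
  out <- segmeth(st, segs)
  for (i in seq_len(nrow(out))) {
    row <- out[i]
    brute <- st$calls[sample == row$sample & chrom == row$chrom]
    cnt <- c(MOD = 0L, UNMOD = 0L, AMBIG = 0L)
    for (j in seq_len(nrow(brute))) {
      if (brute$ref_pos[j] >= row$start && brute$ref_pos[j] < row$end) {
        cnt[brute$call[j]] <- cnt[brute$call[j]] + 1L
      }
    }
    expect_equal(unname(c(row$n_mod, row$n_unmod, row$n_ambig)),
                 unname(as.integer(cnt)))
  }
})

test_that("binned profiles tile the chromosome and conserve call counts", {
  ref <- Biostrings::DNAStringSet(c(chr1 = paste(
    rep(c("ACGT", "TTAA"), 125), collapse = "")))  # 1000 bp, CpGs only in ACGT
  set.seed(5)
  st <- make_store(rnorm(300, 2), pos = sample(0:999, 300, TRUE))
  bins <- wgmeth_binned(st, "s1", 500, ref, chrom = "chr1")
  expect_equal(nrow(bins), 2L)
  expect_equal(bins$start, c(0L, 500L))
  expect_equal(sum(bins$n_mod + bins$n_unmod + bins$n_ambig),
               nrow(st$calls))
  expect_error(wgmeth_binned(st, "s1", 0, ref), "bin_size")
  # uneven division keeps a flagged partial bin
  b2 <- wgmeth_binned(st, "s1", 300, ref, chrom = "chr1")
  expect_equal(nrow(b2), 4L)
  expect_true(b2$partial[4])
  expect_equal(b2$end[4], 1000L)
})

test_that("bins without motif sites are masked", {
  ref <- Biostrings::DNAStringSet(c(chr1 = paste0(
    paste(rep("CG", 50), collapse = ""), paste(rep("AT", 50), collapse = ""))))
  st <- make_store(c(3, 3, -3), pos = c(0L, 2L, 150L))
  bins <- wgmeth_binned(st, "s1", 100, ref)
  expect_equal(bins$masked, c(FALSE, TRUE))
  expect_equal(bins$n_motif_sites, c(50L, 0L))
  expect_true(is.na(bins$meth_fraction[2]))
  expect_equal(bins$meth_fraction[1], 1)
})

test_that("bedMethyl lines follow the 9+2 format and round-trip", {
  st <- new_callstore(data.frame(
    read_id = paste0("r", 1:4), sample = "s1", chrom = "chr1",
    ref_pos = 104L, strand = "+",
    score = c(5, 6, 7, -4)))
  sites <- aggregate_sites(st, "s1")
  path <- withr::local_tempfile(fileext = ".bed")
  write_bedmethyl(sites, path)
  expect_equal(readLines(path),
               "chr1\t104\t105\tm\t4\t+\t104\t105\t0,0,0\t4\t75")
  back <- read_bedmethyl(path)
  expect_equal(back$coverage, 4L)
  expect_equal(back$percent, 75L)
})

test_that("bedMethyl output is sorted and skips uncovered sites", {
  set.seed(13)
  pos <- sample(0:5000, 300)
  st <- make_store(rnorm(300, 3), pos = pos)
  sites <- aggregate_sites(st, "s1")
  # add an all-AMBIG site: no classified coverage, no line
  st2 <- merge_callstores(st, make_store(0.5, pos = 9999L, read_id = "amb"))
  path <- withr::local_tempfile(fileext = ".bed")
  write_bedmethyl(aggregate_sites(st2, "s1"), path)
  back <- read_bedmethyl(path)
  expect_false(9999L %in% back$start)
  expect_true(!is.unsorted(back$start))
  expect_equal(back$coverage, aggregate_sites(st2, "s1")[coverage > 0]$coverage)
})

test_that("DSS tables report 1-based positions with X <= N", {
  st <- new_callstore(data.frame(
    read_id = paste0("r", 1:4), sample = "s1", chrom = "chr1",
    ref_pos = 104L, strand = "+", score = c(5, 6, 7, -4)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_dss_table(aggregate_sites(st, "s1"), path)
  lines <- readLines(path)
  expect_equal(lines[1], "chr\tpos\tN\tX")
  expect_equal(lines[2], "chr1\t105\t4\t3")
  # random store: X <= N everywhere; empty store: header only
  set.seed(17)
  st2 <- make_store(rnorm(200, 0, 5), pos = sample(0:999, 200, TRUE))
  write_dss_table(aggregate_sites(st2, "s1"), path)
  tab <- utils::read.delim(path)
  expect_true(all(tab$X <= tab$N))
  expect_true(all(tab$N >= 1))
  write_dss_table(aggregate_sites(st2, "nosuch"), path)
  expect_equal(readLines(path), "chr\tpos\tN\tX")
})

test_that("segmeth tables round-trip through write/read", {
  set.seed(23)
  st <- new_callstore(data.frame(
    read_id = paste0("r", 1:200), sample = sample(c("a", "b"), 200, TRUE),
    chrom = "chr1", ref_pos = sample(0:999, 200, TRUE), strand = "+",
    score = rnorm(200, 0, 5)))
  segs <- data.frame(chrom = "chr1", start = c(0, 500), end = c(500, 1000),
                     name = c("x", "y"), group = c("g1", "g2"))
  out <- segmeth(st, segs)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_segmeth_table(out, path)
  back <- read_segmeth_table(path)
  m <- merge(as.data.frame(out),
             as.data.frame(back),
             by = c("chrom", "start", "end", "name", "group", "sample"))
  expect_equal(nrow(m), nrow(out))
  expect_equal(m$n_mod.x, m$n_mod.y)
  expect_equal(m$meth_fraction.x, m$meth_fraction.y, tolerance = 1e-9)
})
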