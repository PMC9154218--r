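# MM/ML BAM import: worked single-read traces plus randomized cross-checks
# against the per-base brute-force decoder in helper-oracles.R.

test_that("a hand-traced forward read decodes to the expected calls", {
  # SEQ ACGTCGTTCG, CIGAR 10M at ref 100: Cs at read 1,4,8 (0-based);
  # MM skips 1,0 select the 2nd and 3rd C -> ref 104 and 108
  bam <- write_test_bam(list(list(
    qname = "r1", flag = 0, pos1 = 101, cigar = "10M", seq = "ACGTCGTTCG",
    tags = c("MM:Z:C+m,1,0;", "ML:B:C,230,26"))),
    dir = withr::local_tempdir())
  st <- import_bam_modcalls(bam, "s1")
  calls <- st$calls[order(ref_pos)]
  expect_equal(calls$ref_pos, c(104L, 108L))
  expect_equal(calls$score,
               c(log((230.5 / 256) / (1 - 230.5 / 256)),
                 log((26.5 / 256) / (1 - 26.5 / 256))),
               tolerance = 1e-12)
  expect_equal(calls$score, c(2.202, -2.159), tolerance = 5e-4)
  expect_equal(calls$call, c("MOD", "UNMOD"))
})

test_that("an empty MM position list yields zero calls", {
  bam <- write_test_bam(list(
    list(qname = "r1", flag = 0, pos1 = 101, cigar = "10M",
         seq = "ACGTCGTTCG", tags = "MM:Z:C+m;"),
    list(qname = "r2", flag = 0, pos1 = 201, cigar = "10M",
         seq = "ACGTCGTTCG", tags = c("MM:Z:C+m,0;", "ML:B:C,250"))),
    dir = withr::local_tempdir())
  st <- import_bam_modcalls(bam, "s1")
  expect_equal(nrow(st$calls), 1L)
  expect_equal(st$calls$read_id, "r2")
})

test_that("modified bases inside insertions are dropped, others kept", {
  # CIGAR 5M2I5M; read CCGTA|CC|GGCGT: the two inserted Cs carry the 2nd and
  # 3rd modified calls and have no reference coordinate
  seq <- "CCGTACCGGCGT"  # Cs at read idx 0,1,5,6,9; idx 5,6 are the insertion
  bam <- write_test_bam(list(list(
    qname = "r1", flag = 0, pos1 = 101, cigar = "5M2I5M", seq = seq,
    tags = c("MM:Z:C+m,0,1,0,0;", "ML:B:C,240,241,242,243"))),
    dir = withr::local_tempdir())
  st <- import_bam_modcalls(bam, "s1", collapse_strands = FALSE)
  # modified C occurrences 1,3,4,5 -> read idx 0,5,6,9; 5 and 6 are inserted
  # bases with no reference coordinate, 9 lifts across the insertion to 107
  expect_equal(sort(st$calls$ref_pos), c(100L, 107L))
  expect_equal(nrow(st$calls), 2L)
})

test_that("MM/ML length mismatch skips the read with a warning", {
  bam <- write_test_bam(list(
    list(qname = "bad", flag = 0, pos1 = 101, cigar = "10M",
         seq = "ACGTCGTTCG", tags = c("MM:Z:C+m,1,0;", "ML:B:C,230")),
    list(qname = "ok", flag = 0, pos1 = 201, cigar = "10M",
         seq = "ACGTCGTTCG", tags = c("MM:Z:C+m,1;", "ML:B:C,230"))),
    dir = withr::local_tempdir())
  expect_warning(st <- import_bam_modcalls(bam, "s1"), "mismatch")
  expect_equal(st$calls$read_id, "ok")
  expect_equal(st$meta$n_reads_skipped, 1L)
})

test_that("missing index is an error", {
  dir <- withr::local_tempdir()
  bam <- write_test_bam(list(list(
    qname = "r1", flag = 0, pos1 = 101, cigar = "4M", seq = "ACGT",
    tags = "MM:Z:C+m;")), dir = dir)
  file.remove(paste0(bam, ".bai"))
  expect_error(import_bam_modcalls(bam, "s1"), "index")
})

test_that("reverse-strand CpG calls collapse onto the plus-strand C", {
  # reference ...ACGT...: read aligned 4M at ref 100 on the minus strand.
  # stored SEQ = ACGT; sequenced read = revcomp = ACGT; its C (read idx 1)
  # maps to stored idx 2 = ref 102 (the G); collapsed site is 101 (the C).
  bam <- write_test_bam(list(list(
    qname = "r1", flag = 16, pos1 = 101, cigar = "4M", seq = "ACGT",
    tags = c("MM:Z:C+m,0;", "ML:B:C,250"))),
    dir = withr::local_tempdir())
  st <- import_bam_modcalls(bam, "s1")
  expect_equal(st$calls$ref_pos, 101L)
  expect_equal(st$calls$strand, "-")
  raw <- import_bam_modcalls(bam, "s1", collapse_strands = FALSE)
  expect_equal(raw$calls$ref_pos, 102L)
})

test_that("HP/PS tags populate haplotype and phase set", {
  bam <- write_test_bam(list(
    list(qname = "r1", flag = 0, pos1 = 101, cigar = "10M",
         seq = "ACGTCGTTCG", tags = c("MM:Z:C+m,1;", "ML:B:C,230",
                                      "HP:i:2", "PS:i:77")),
    list(qname = "r2", flag = 0, pos1 = 101, cigar = "10M",
         seq = "ACGTCGTTCG", tags = c("MM:Z:C+m,1;", "ML:B:C,230"))),
    dir = withr::local_tempdir())
  st <- import_bam_modcalls(bam, "s1")
  expect_equal(st$calls[read_id == "r1"]$haplotype, 2L)
  expect_equal(st$calls[read_id == "r1"]$phase_set, "77")
  expect_true(is.na(st$calls[read_id == "r2"]$haplotype))
})

test_that("MM sub-tags for other bases or codes are ignored but keep ML in register", {
  # A+a block first (2 entries), then C+m (1 entry): the C+m byte is the 3rd
  bam <- write_test_bam(list(list(
    qname = "r1", flag = 0, pos1 = 101, cigar = "10M", seq = "AAGTCGTTCG",
    tags = c("MM:Z:A+a,0,0;C+m,0;", "ML:B:C,10,11,230"))),
    dir = withr::local_tempdir())
  st <- import_bam_modcalls(bam, "s1", mod_code = "m", motif = "CG")
  expect_equal(nrow(st$calls), 1L)
  expect_equal(st$calls$ref_pos, 104L)
  expect_equal(llr_to_probability(st$calls$score), 230.5 / 256,
               tolerance = 1e-12)
})

test_that("random reads with random CIGARs match the brute-force decoder", {
  set.seed(1234)
  n <- 150
  reads <- lapply(seq_len(n), function(i) random_mm_read(sprintf("rr%04d", i)))
  bam <- write_test_bam(reads, dir = withr::local_tempdir())
  st <- import_bam_modcalls(bam, "s1", collapse_strands = FALSE)
  got <- st$calls[, .(read_id, ref_pos,
                      byte = as.integer(round(llr_to_probability(score) * 256 - 0.5)))]
  data.table::setorder(got, read_id, ref_pos, byte)
  want <- data.table::rbindlist(lapply(reads, function(rd) {
    dec <- oracle_decode_mm(rd$seq, rd$cigar, rd$pos1 - 1, rd$is_rev,
                            sub("^MM:Z:", "", rd$mm), rd$ml_bytes)
    if (is.null(dec)) return(NULL)
    data.table::data.table(read_id = rd$qname, ref_pos = dec$ref_pos,
                           byte = dec$byte)
  }))
  data.table::setorder(want, read_id, ref_pos, byte)
  expect_equal(as.data.frame(got), as.data.frame(want))
})
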