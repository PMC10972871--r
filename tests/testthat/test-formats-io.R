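test_that("protein FASTA parsing extracts ids, uppercases and validates", {
  f <- write_lines_tmp(c(">p1 desc here", "MKV", ">p2", "acde"), ".fasta")
  ps <- read_protein_fasta(f)
  expect_equal(names(ps), c("p1", "p2"))
  expect_equal(as.character(ps), c(p1 = "MKV", p2 = "ACDE"))
  expect_equal(unname(Biostrings::width(ps)), c(3L, 4L))

  dupf <- write_lines_tmp(c(">p1", "MKV", ">p1", "ACDE"), ".fasta")
  expect_error(read_protein_fasta(dupf), "p1")

  emptyf <- write_lines_tmp(character(), ".fasta")
  expect_error(read_protein_fasta(emptyf), "no proteins")

  badf <- write_lines_tmp(c(">p1", "MK1V"), ".fasta")
  expect_error(read_protein_fasta(badf), "alphabet")
})

fastq_lines <- function(ids, seqs) {
  as.vector(rbind(paste0("@", ids), seqs, "+",
                  vapply(nchar(seqs), function(n)
                    paste(rep("I", n), collapse = ""), character(1))))
}

test_that("FASTQ reading concatenates files and sums lengths", {
  seqs <- vapply(1:3, function(i)
    paste(sample(c("A", "C", "G", "T"), 100, replace = TRUE), collapse = ""),
    character(1))
  f1 <- write_lines_tmp(fastq_lines(paste0("r", 1:3), seqs), ".fastq")
  b <- read_fastq(f1)
  expect_length(b, 3L)
  expect_equal(cumulative_length(b), 300)

  # paired files: mates counted independently, ids kept distinct
  f2 <- write_lines_tmp(fastq_lines(c("r1", "r2"), seqs[1:2]), ".fastq")
  f3 <- write_lines_tmp(fastq_lines(c("r1", "r2"), seqs[2:3]), ".fastq")
  pb <- read_fastq(c(f2, f3))
  expect_length(pb, 4L)
  expect_equal(cumulative_length(pb), 400)
  expect_false(anyDuplicated(names(pb)) > 0)

  fe <- write_lines_tmp(character(), ".fastq")
  be <- read_fastq(fe)
  expect_length(be, 0L)
  expect_equal(cumulative_length(be), 0)

  ft <- write_lines_tmp(c("@r1", "ACGT", "+"), ".fastq")
  expect_error(read_fastq(ft), "FASTQ")
})

test_that("FASTQ round trip preserves ids and sequences", {
  g <- make_genome(20000, 2, seed = 7)
  reads <- sample_reads(g, depth = 0.5, seed = 8)
  f <- tempfile(fileext = ".fastq")
  write_fastq(reads, f)
  back <- read_fastq(f)
  expect_identical(names(back), names(reads))
  expect_identical(as.character(back), as.character(reads))
})

test_that("tabular hit parsing maps fields and infers strand", {
  f <- write_lines_tmp(
    "r1\tp1\t95.0\t30\t1\t0\t1\t90\t1\t30\t1e-10\t60.0")
  h <- parse_tabular_hits(f)
  expect_equal(nrow(h), 1L)
  expect_equal(h$read_id, "r1")
  expect_equal(h$protein_id, "p1")
  expect_equal(h$evalue, 1e-10)
  expect_equal(h$bitscore, 60.0)
  expect_gt(h$frame, 0)

  frev <- write_lines_tmp(
    "r1\tp1\t95.0\t30\t1\t0\t90\t1\t1\t30\t1e-10\t60.0")
  expect_lt(parse_tabular_hits(frev)$frame, 0)

  fe <- write_lines_tmp(character())
  expect_equal(nrow(parse_tabular_hits(fe)), 0L)

  fbad <- write_lines_tmp(c("r1\tp1\t95.0", "x"))
  expect_error(parse_tabular_hits(fbad), "line 1")

  fnn <- write_lines_tmp("r1\tp1\tox\t30\t1\t0\t1\t90\t1\t30\t1e-10\t60.0")
  expect_error(parse_tabular_hits(fnn), "non-numeric")
})

test_that("tabular writer and parser are inverse on real search output", {
  g <- make_genome(60000, 3, seed = 21)
  reads <- sample_reads(g, depth = 2, seed = 22)
  hits <- search_reads(reads, g$proteins)
  expect_gt(nrow(hits), 0L)
  f <- tempfile(fileext = ".tsv")
  write_tabular_hits(hits, f)
  back <- parse_tabular_hits(f)
  tab_cols <- c("read_id", "protein_id", "pident", "align_len_aa",
                "mismatch", "gapopen", "qstart", "qend", "sstart", "send",
                "evalue", "bitscore")
  expect_equal(back[tab_cols], hits[tab_cols], ignore_attr = TRUE)
})

test_that("slope tables look up case-insensitively with a default fallback", {
  f <- write_lines_tmp(c("group\tslope", "all\t1.56"), ".tsv")
  tab <- read_slope_table(f)
  expect_equal(slope_lookup(tab, "ALL"), 1.56)
  expect_true("default" %in% tab$group)
  expect_warning(s <- slope_lookup(tab, "nonesuch"), "default")
  expect_equal(s, 1)

  fneg <- write_lines_tmp(c("group\tslope", "all\t-2"), ".tsv")
  expect_error(read_slope_table(fneg), "positive")

  fdup <- write_lines_tmp(c("group\tslope", "all\t1.5", "ALL\t1.6"), ".tsv")
  expect_error(read_slope_table(fdup), "duplicate")
})

test_that("reports carry every quantity of the estimate in TSV and JSON", {
  est <- estimate_size(L = 1e9, scp_depth = 2, beta = 1.56, group = "all",
                       n_retained = 390, n_removed = 20)
  prefix <- tempfile()
  paths <- write_report(est, prefix)
  expect_true(all(file.exists(paths)))
  js <- jsonlite::read_json(paste0(prefix, ".json"))
  expect_equal(js$L, 1e9)
  expect_equal(js$beta, 1.56)
  expect_equal(js$one_cx_bp, 1e9 / (1.56 * 2))
  expect_equal(js$one_cx_mb, js$one_cx_bp / 1e6)
  tsv <- read.table(paste0(prefix, ".tsv"), header = TRUE, sep = "\t")
  expect_setequal(tsv$field,
                  c("L", "scp_depth", "beta", "group", "n_retained",
                    "n_removed", "one_cx_bp", "one_cx_mb"))
})
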