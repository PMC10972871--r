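test_that("six-frame translation follows the standard code and conventions", {
  fr <- sixframe_translate("ATGGCCTAA")
  expect_equal(fr[["+1"]], "MA*")
  expect_equal(fr[["-1"]], "LGH")    # revcomp TTAGGCCAT
  expect_equal(fr[["+2"]], "WP")

  # a codon containing N translates to X
  frn <- sixframe_translate("ATGNAAGGG")
  expect_equal(substr(frn[["+1"]], 2, 2), "X")

  expect_true(all(sixframe_translate("AT") == ""))
})

test_that("an exact back-translated read hits its protein at 100% identity", {
  ps <- tiny_proteins()
  seg <- substr(as.character(ps[[1]]), 10, 42)     # 33 residues
  read <- Biostrings::DNAStringSet(c(r1 = back_translate(seg)))
  hits <- search_reads(read, ps)
  expect_gte(nrow(hits), 1L)
  best <- best_hit_per_read(hits)
  expect_equal(best$protein_id, names(ps)[1])
  expect_equal(best$pident, 100)
  expect_equal(best$align_len_aa, 33L)
})

test_that("reads sharing no 5-mer seed with any protein yield no hit", {
  ps <- Biostrings::AAStringSet(c(pK = strrep("K", 150)))
  read <- Biostrings::DNAStringSet(c(r1 = strrep("CCC", 33)))  # poly-proline
  expect_equal(nrow(search_reads(read, ps)), 0L)
})

test_that("seeded search equals the exhaustive Smith-Waterman oracle", {
  g <- make_genome(2e5, 3, seed = 51)
  reads <- sample_reads(g, depth = 1.2, seed = 52)
  reads <- reads[seq_len(min(250, length(reads)))]
  seeded <- search_reads(reads, g$proteins)
  oracle <- brute_force_search(reads, g$proteins)
  key <- function(d) paste(d$read_id, d$protein_id)
  expect_setequal(key(seeded), key(oracle))
  m <- match(key(seeded), key(oracle))
  expect_equal(seeded$bitscore, oracle$bitscore[m], tolerance = 1e-12)
})

test_that("best-hit selection follows bitscore, e-value, then protein id", {
  h <- data.frame(read_id = c("r1", "r1", "r2", "r2", "r3"),
                  protein_id = c("pA", "pB", "pB", "pA", "pC"),
                  bitscore = c(50, 55, 40, 40, 60),
                  evalue = c(1e-6, 1e-7, 1e-5, 1e-5, 1e-8),
                  stringsAsFactors = FALSE)
  best <- best_hit_per_read(h)
  expect_equal(nrow(best), 3L)
  expect_equal(best$protein_id[best$read_id == "r1"], "pB")  # max bitscore
  expect_equal(best$protein_id[best$read_id == "r2"], "pA")  # id tie-break
  expect_equal(best_hit_per_read(h[5, ])$protein_id, "pC")   # single hit
})

test_that("reverse-complementing reads leaves best hits unchanged", {
  g <- make_genome(1e5, 2, seed = 61)
  reads <- sample_reads(g, depth = 1, seed = 62)
  reads <- reads[seq_len(min(120, length(reads)))]
  fwd <- best_hit_per_read(search_reads(reads, g$proteins))
  rc <- Biostrings::reverseComplement(reads)
  names(rc) <- names(reads)
  rev <- best_hit_per_read(search_reads(rc, g$proteins))
  expect_setequal(paste(fwd$read_id, fwd$protein_id, round(fwd$bitscore, 9)),
                  paste(rev$read_id, rev$protein_id, round(rev$bitscore, 9)))
})

test_that("a mismatch never increases the bitscore of a perfect read", {
  ps <- tiny_proteins(n = 1L)
  seg <- substr(as.character(ps[[1]]), 5, 37)
  perfect <- back_translate(seg)
  score_of <- function(s) {
    h <- search_reads(Biostrings::DNAStringSet(c(r = s)), ps)
    if (nrow(h) == 0) -Inf else max(h$bitscore)
  }
  s0 <- score_of(perfect)
  set.seed(71)
  for (i in 1:5) {
    pos <- sample(nchar(perfect), 1)
    alt <- setdiff(c("A", "C", "G", "T"), substr(perfect, pos, pos))[1]
    mutated <- perfect
    substr(mutated, pos, pos) <- alt
    expect_lte(score_of(mutated), s0)
  }
})

test_that("the external-backend adapter reproduces a fixture hit file", {
  g <- make_genome(60000, 3, seed = 81)
  reads <- sample_reads(g, depth = 1, seed = 82)
  hits <- search_reads(reads, g$proteins)
  fixture <- tempfile(fileext = ".tsv")
  write_tabular_hits(hits, fixture)
  db <- tempfile(fileext = ".faa")
  Biostrings::writeXStringSet(g$proteins, db)

  tmpl <- paste0("test -f {query} && test -f ", db,
                 " && cp ", fixture, " {out} # {db}")
  ext <- run_external_search(reads, db, tmpl)
  expect_equal(ext, parse_tabular_hits(fixture))

  expect_error(
    run_external_search(reads, db,
                        "echo boom >&2; false # {query} {db} {out}"),
    "boom")
  expect_error(run_external_search(reads, db, "cmd-without-placeholders"),
               "placeholder")
})
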