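test_that("BED and headered-TSV gene annotations parse to the same records", {
  layout <- tiny_layout()
  bed <- withr::local_tempfile(lines = c(
    "# a comment",
    "chr1\t100\t200\tGENE_A\t0\t+",
    "chr2\t300\t450\tGENE_B\t0\t-"))
  g <- read_genes(bed, layout)
  expect_equal(g$gene_id, c("GENE_A", "GENE_B"))
  expect_equal(g$chrom, c("chr1", "chr2"))
  expect_identical(g$start, c(100, 300))
  expect_identical(g$end, c(200, 450))
  expect_equal(g$strand, c("+", "-"))

  tsv <- withr::local_tempfile(lines = c(
    "gene_id\tchrom\tstart\tend\tstrand",
    "GENE_A\tchr1\t100\t200\t+",
    "GENE_B\tchr2\t300\t450\t-"))
  expect_equal(read_genes(tsv, layout), g)

  # 1-based inclusive inputs are shifted on read
  expect_equal(read_genes(withr::local_tempfile(lines = c(
    "gene_id\tchrom\tstart\tend\tstrand",
    "GENE_A\tchr1\t101\t200\t+")), layout, one_based = TRUE)$start, 100)
})

test_that("gene reader handles empty files, off-layout rows and bad rows", {
  layout <- tiny_layout()
  empty <- withr::local_tempfile(lines = "# nothing here")
  expect_equal(nrow(read_genes(empty, layout)), 0L)

  offlayout <- withr::local_tempfile(lines = "chrZ\t10\t20\tG1\t0\t+")
  expect_message(g <- read_genes(offlayout, layout), "dropping 1 gene")
  expect_equal(nrow(g), 0L)

  bad_coord <- withr::local_tempfile(lines = "chr1\t200\t200\tG1\t0\t+")
  expect_error(read_genes(bad_coord, layout), "start < end")

  bad_field <- withr::local_tempfile(lines = c(
    "gene_id\tchrom\tstart\tend\tstrand",
    "G1\tchr1\tnot_a_number\t200\t+"))
  expect_error(read_genes(bad_field, layout), "line 2")

  short_row <- withr::local_tempfile(lines = c("chr1\t10\t20\tG1", "chr1\t30"))
  expect_error(read_genes(short_row, layout), "line 2")
})

test_that("SNP arrays sort into layout order and reject invariant violations", {
  layout <- tiny_layout()
  f <- withr::local_tempfile(lines = c(
    "snp_id\tchrom\tpos", "s1\tchr2\t5", "s2\tchr1\t9"))
  a <- read_snp_array(f, layout)
  expect_equal(a$snp_id, c("s2", "s1"))  # layout order, not file order

  one <- withr::local_tempfile(lines = c("snp_id\tchrom\tpos", "s1\tchr1\t0"))
  expect_equal(nrow(read_snp_array(one, layout)), 1L)

  dup <- withr::local_tempfile(lines = c(
    "snp_id\tchrom\tpos", "s1\tchr1\t9", "s2\tchr1\t9"))
  expect_error(read_snp_array(dup, layout), "duplicate")

  unknown <- withr::local_tempfile(lines = c(
    "snp_id\tchrom\tpos", "s1\tchrZ\t9"))
  expect_error(read_snp_array(unknown, layout), "absent from layout")

  too_far <- withr::local_tempfile(lines = c(
    "snp_id\tchrom\tpos", "s1\tchr2\t1000000"))
  expect_error(read_snp_array(too_far, layout), "outside")
})

test_that("association rows parse with probability validation", {
  f <- withr::local_tempfile(lines = c(
    "snp_id\tprior\tposterior", "rs1\t0.0004\t0.017"))
  a <- read_association(f)
  expect_identical(a$prior, 0.0004)
  expect_identical(a$posterior, 0.017)

  bad <- withr::local_tempfile(lines = c(
    "snp_id\tprior\tposterior", "rs1\t0.0004\t1.5"))
  expect_error(read_association(bad), "\\[0, 1\\]")
})

test_that("duplicate interactions aggregate by max support", {
  f <- withr::local_tempfile(lines = c(
    "mirna_id\tgene_id\tsupport",
    "miR-1\tG\t2", "miR-1\tG\t3", "miR-2\tG\t1"))
  expect_message(it <- read_interactions(f), "aggregated 1 duplicate")
  expect_equal(nrow(it), 2L)
  expect_equal(it$support[it$mirna_id == "miR-1"], 3)

  empty <- withr::local_tempfile(lines = "# none")
  expect_equal(nrow(read_interactions(empty)), 0L)

  zero <- withr::local_tempfile(lines = c(
    "mirna_id\tgene_id\tsupport", "miR-1\tG\t0"))
  expect_error(read_interactions(zero), "support")
})

test_that("every table type round-trips through write/read bit-identically", {
  layout <- tiny_layout()
  genes <- tiny_genes(layout)
  array <- tiny_array(10, layout)
  assoc <- make_assoc(array, 3, 5, 2)
  interactions <- data.frame(mirna_id = c("miR-1", "miR-2"),
                             gene_id = c("A", "A"), support = c(2, 5),
                             stringsAsFactors = FALSE)
  orthologs <- data.frame(source_mirna = "mmu-miR-134",
                          target_mirna = "hsa-miR-134",
                          stringsAsFactors = FALSE)
  d <- withr::local_tempdir()
  p <- function(x) file.path(d, x)
  write_layout(layout, p("l.tsv"))
  write_genes(genes, p("g.tsv"))
  write_snp_array(array, p("s.tsv"))
  write_association(assoc, p("a.tsv"))
  write_interactions(interactions, p("i.tsv"))
  write_orthologs(orthologs, p("o.tsv"))
  expect_equal(read_layout(p("l.tsv")), layout)
  expect_equal(read_genes(p("g.tsv"), layout), genes)
  expect_equal(read_snp_array(p("s.tsv"), layout), array,
               ignore_attr = "layout")
  expect_equal(read_association(p("a.tsv")), assoc)
  expect_equal(read_interactions(p("i.tsv")), interactions)
  expect_equal(read_orthologs(p("o.tsv")), orthologs)

  # array index is a stable bijection across re-reads
  again <- read_snp_array(p("s.tsv"), layout)
  expect_identical(again$snp_id, array$snp_id)
  expect_identical(seq_len(nrow(again)), match(again$snp_id, array$snp_id))
})

test_that("genome layout rejects duplicates and non-positive lengths", {
  expect_error(genome_layout(c("chr1", "chr1"), c(10, 20)), "unique")
  expect_error(genome_layout("chr1", 0), "positive")
  expect_error(tier_config(c(25000, 25000)), "increasing")
})
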