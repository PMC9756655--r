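test_that("domain table reader maps rows to hits and validates coordinates", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tdomain_acc\tdomain_name\tstart\tend",
               "p1\tPF00990\tGGDEF\t10\t170",
               "p2\tPF00563\tEAL\t5\t240"), path)
  hits <- read_domain_table(path)
  expect_equal(nrow(hits), 2L)
  expect_equal(hits$protein_id, c("p1", "p2"))
  expect_equal(hits$domain_acc[1], "PF00990")
  expect_equal(hits$start, c(10L, 5L))
  expect_equal(hits$end, c(170L, 240L))

  # header-only file -> empty table
  writeLines("protein_id\tdomain_acc\tdomain_name\tstart\tend", path)
  expect_equal(nrow(read_domain_table(path)), 0L)

  # 1-based invariant: start = 0 rejected with the line number
  writeLines(c("protein_id\tdomain_acc\tdomain_name\tstart\tend",
               "p1\tPF00990\tGGDEF\t0\t170"), path)
  expect_error(read_domain_table(path), "line 1")

  # start > end rejected
  writeLines(c("protein_id\tdomain_acc\tdomain_name\tstart\tend",
               "p1\tPF00990\tGGDEF\t9\t170",
               "p2\tPF00563\tEAL\t200\t100"), path)
  expect_error(read_domain_table(path), "line 2")

  # missing required column named in the error
  writeLines(c("protein_id\tdomain_acc\tstart\tend", "p1\tPF00990\t1\t9"),
             path)
  expect_error(read_domain_table(path), "domain_name")
})

test_that("optional e-value ceiling filters hits only when requested", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tdomain_acc\tdomain_name\tstart\tend\tevalue",
               "p1\tPF00990\tGGDEF\t10\t170\t1e-30",
               "p2\tPF00563\tEAL\t5\t240\t0.5"), path)
  expect_equal(nrow(read_domain_table(path)), 2L)
  expect_equal(read_domain_table(path, evalue_max = 1e-3)$protein_id, "p1")
})

test_that("GFF3 + FASTA annotation reading yields replicons and 1-based loci", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  fa <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c("##gff-version 3",
               "##sequence-region chrA 1 10000",
               "chrA\tsrc\tregion\t1\t10000\t.\t+\t.\tID=chrA",
               "chrA\tsrc\tCDS\t101\t400\t.\t+\t0\tID=c1;protein_id=p1",
               "chrA\tsrc\tCDS\t901\t1200\t.\t-\t0\tID=c2;protein_id=p2"), gff)
  writeLines(c(">chrA", paste(rep("ACGT", 2500), collapse = "")), fa)
  rec <- read_genome_annotation(gff, fa, genome_id = "G1")
  expect_s3_class(rec, "genome_record")
  expect_equal(nrow(rec$replicons), 1L)
  expect_equal(rec$replicons$length_bp, 10000)
  expect_equal(nrow(rec$proteins), 2L)
  expect_equal(rec$proteins$start, c(101, 901))
  expect_equal(rec$proteins$end, c(400, 1200))
  expect_equal(rec$proteins$strand, c("+", "-"))
})

test_that("a CDS referencing an unknown replicon is a fatal error", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "##sequence-region chrA 1 10000",
               "chrA\tsrc\tregion\t1\t10000\t.\t+\t.\tID=chrA",
               "chrB\tsrc\tCDS\t10\t90\t.\t+\t0\tID=c1;protein_id=p1"), gff)
  expect_error(suppressWarnings(read_genome_annotation(gff, genome_id = "G1")),
               "unknown replicon")
})

test_that("GenBank flat files give replicon lengths and CDS loci", {
  gb <- withr::local_tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       chrZ       10000 bp    DNA     circular BCT 01-JAN-2020",
    "FEATURES             Location/Qualifiers",
    "     source          1..10000",
    "     CDS             101..400",
    "                     /protein_id=\"p1\"",
    "     CDS             complement(901..1200)",
    "                     /protein_id=\"p2\"",
    "     CDS             500..700",
    "ORIGIN",
    "//"), gb)
  expect_warning(read_genome_annotation(gb, genome_id = "GZ"),
                 "without protein_id")
  rec <- suppressWarnings(read_genome_annotation(gb, genome_id = "GZ"))
  expect_equal(rec$replicons$length_bp, 10000)
  expect_equal(nrow(rec$proteins), 2L)  # the qualifier-less CDS is skipped
  expect_equal(rec$proteins$strand, c("+", "-"))
  expect_equal(rec$proteins$start, c(101, 901))
})

test_that("wrap-around joins are normalized to start..end+length", {
  gb <- withr::local_tempfile(fileext = ".gb")
  writeLines(c(
    "LOCUS       chrW       10000 bp    DNA     circular BCT 01-JAN-2020",
    "FEATURES             Location/Qualifiers",
    "     CDS             join(9901..10000,1..200)",
    "                     /protein_id=\"pw\"",
    "//"), gb)
  rec <- read_genome_annotation(gb, genome_id = "GW")
  expect_equal(rec$proteins$start, 9901)
  expect_equal(rec$proteins$end, 10200)  # 200 + 10000
})

test_that("write_results is deterministic and validates table names", {
  dir1 <- withr::local_tempdir(); dir2 <- withr::local_tempdir()
  tabs <- list(a = data.frame(x = c(3, 1, 2), y = c("c", "a", "b")))
  write_results(tabs, dir1, seed = 5)
  write_results(tabs, dir2, seed = 5)
  expect_identical(readLines(file.path(dir1, "a.tsv")),
                   readLines(file.path(dir2, "a.tsv")))
  # rows sorted
  expect_equal(utils::read.delim(file.path(dir1, "a.tsv"))$x, c(1, 2, 3))
  # empty table set -> manifest only
  dir3 <- withr::local_tempdir()
  write_results(list(), dir3)
  expect_identical(list.files(dir3), "manifest.json")
  expect_error(write_results(list(data.frame(x = 1)), dir3), "named")
})

test_that("classification table round-trips through write_results", {
  g <- tiny_genome(classes = c("GGDEF", "EAL", "GGDEF_EAL"))
  cls <- classify_genome(g)$classified
  dir <- withr::local_tempdir()
  write_results(list(classified_proteins = cls), dir)
  back <- utils::read.delim(file.path(dir, "classified_proteins.tsv"),
                            stringsAsFactors = FALSE,
                            colClasses = c(aux_domains = "character"))
  back <- back[order(back$protein_id), ]
  cls <- cls[order(cls$protein_id), ]
  rownames(back) <- rownames(cls) <- NULL
  expect_equal(back$class, cls$class)
  expect_equal(back$start, cls$start)
  expect_equal(back$aux_domains, cls$aux_domains)
})
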