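make_g <- function(counts, gene = "g1") {
  genotype_matrix(counts,
                  site_ids = paste0("s", seq_len(ncol(counts))),
                  site_positions = seq_len(ncol(counts)),
                  site_gene = rep(gene, ncol(counts)),
                  individual_ids = paste0("i", seq_len(nrow(counts))))
}

test_that("recoding collapses any variant-carrying genotype to 1", {
  # allele-count genotypes that share a code: homozygous-alternate carriers
  # recode identically to heterozygous carriers
  counts <- rbind(c(0L, 0L, 2L, 0L),
                  c(0L, 0L, 1L, 0L),
                  c(0L, 2L, 0L, 0L),
                  c(0L, 1L, 0L, 0L),
                  c(0L, 0L, 0L, 0L))
  b <- recode_to_bmg(make_g(counts), "g1")
  expect_identical(unname(b$codes), rbind(c(0L, 0L, 1L, 0L),
                                          c(0L, 0L, 1L, 0L),
                                          c(0L, 1L, 0L, 0L),
                                          c(0L, 1L, 0L, 0L),
                                          c(0L, 0L, 0L, 0L)))
  # idempotence: recoding an already-binary matrix changes nothing
  g2 <- make_g(b$codes)
  expect_identical(recode_to_bmg(g2, "g1")$codes, g2$genotypes)
  # conservation of individuals
  expect_identical(nrow(b$codes), nrow(counts))
})

test_that("with polarize off the bit is exactly (count != 0)", {
  set.seed(11)
  counts <- matrix(sample(0:2, 60, replace = TRUE), 10)
  b <- recode_to_bmg(make_g(counts), "g1")
  expect_identical(unname(b$codes), (unname(counts) != 0L) * 1L)
})

test_that("polarization takes the sample-major allele as common", {
  counts <- cbind(c(2L, 2L, 2L, 1L, 0L),  # alt freq 0.7: alt is common
                  c(1L, 1L, 0L, 0L, 0L),  # alt freq 0.2: ref stays common
                  c(1L, 1L, 1L, 1L, 1L))  # alt freq 0.5: tie keeps reference
  b <- recode_to_bmg(make_g(counts), "g1", polarize = TRUE)
  expect_identical(unname(b$codes), cbind(c(0L, 0L, 0L, 1L, 1L),
                                          c(1L, 1L, 0L, 0L, 0L),
                                          c(1L, 1L, 1L, 1L, 1L)))
})

test_that("missing genotypes follow the configured policy", {
  counts <- rbind(c(0L, NA, 1L), c(1L, 0L, 0L))
  g <- make_g(counts)
  expect_error(recode_to_bmg(g, "g1", missing_policy = "error"), "s2")
  expect_message(recode_to_bmg(g, "g1", missing_policy = "as_common"),
                 "missing")
  b <- suppressMessages(recode_to_bmg(g, "g1", missing_policy = "as_common"))
  expect_identical(unname(b$codes), rbind(c(0L, 0L, 1L), c(1L, 0L, 0L)))
})

test_that("the worked-example counts recode to themselves", {
  g <- example_genotype_matrix()
  expect_identical(length(g$individual_ids), 100L)
  b <- recode_to_bmg(g, "exampleGene")
  codes_str <- apply(b$codes, 1, paste, collapse = "-")
  tab <- example_genotype_counts()
  expect_identical(as.integer(table(codes_str)[tab$code]),
                   tab$controls + tab$cases)
  expect_identical(unname(b$codes), unname(g$genotypes))
})

test_that("genotype matrix validation rejects bad input", {
  expect_error(make_g(rbind(c(0L, 3L))), "0, 1, 2 or NA")
  expect_error(genotype_matrix(rbind(0L), "s1", 1L, "g", "i1",
                               population = ""), "non-empty")
  expect_error(genotype_matrix(cbind(0L, 0L), c("s1", "s1"), 1:2,
                               c("g", "g"), "i1"), "unique")
})

test_that("TSV genotypes round-trip and malformed input is rejected", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\ts1\ts2", "a\t0\t1", "b\t2\tNA"), path)
  g <- suppressMessages(read_genotype_tsv(path))
  expect_identical(unname(g$genotypes), rbind(c(0L, 1L), c(2L, NA)))
  expect_identical(g$individual_ids, c("a", "b"))

  writeLines(c("id\ts1\ts2", "a\t0\t1", "b\t2"), path)
  expect_error(suppressMessages(read_genotype_tsv(path)), "row 3")
  writeLines(c("id\ts1\ts2", "a\t0\t3", "b\t2\t1"), path)
  expect_error(suppressMessages(read_genotype_tsv(path)), "out of range")
  writeLines(c("id\ts1\ts2", "a\t0\tx", "b\t2\t1"), path)
  expect_error(suppressMessages(read_genotype_tsv(path)), "non-numeric")
})

test_that("VCF GT parsing counts any non-reference allele as alternate", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf_fixture_lines(), path)
  g <- suppressMessages(read_vcf(path))
  expect_identical(g$genotypes["indA", ], c(rs1 = 0L, rs2 = 2L))
  expect_identical(g$genotypes["indB", ], c(rs1 = 1L, rs2 = 1L))
  expect_identical(unname(g$genotypes["indC", "rs2"]), NA_integer_)
})

test_that("gene maps assign sites by id or by interval", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(vcf_fixture_lines(), path)
  map_path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tsite_id", "GENE1\trs1"), map_path)
  g <- suppressMessages(read_vcf(path, read_gene_map(map_path)))
  expect_identical(g$site_gene, "GENE1")  # rs2 unmapped, dropped

  writeLines(c("gene\tchrom\tstart\tend", "GENE2\t1\t200\t300"), map_path)
  g <- suppressMessages(read_vcf(path, read_gene_map(map_path)))
  expect_identical(g$site_ids, "rs2")
  map_path2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\tother"), map_path2)
  expect_error(read_gene_map(map_path2), "columns")
})

test_that("phenotype join aligns rows and drops incomplete individuals", {
  g <- make_g(rbind(c(0L, 1L), c(1L, 0L), c(2L, 2L)))
  ph <- data.frame(id = c("i3", "i1", "i4"), population = c("p2", "p1", "p1"),
                   Q = c(1.5, 2.5, 9))
  j <- suppressMessages(join_phenotypes(g, ph))
  expect_identical(j$genotypes$individual_ids, c("i1", "i3"))
  expect_identical(j$phenotypes$Q, c(2.5, 1.5))
  expect_identical(j$genotypes$population, c("p1", "p2"))
  ph$Q[1] <- NA
  j2 <- suppressMessages(join_phenotypes(g, ph))
  expect_identical(j2$genotypes$individual_ids, "i1")
})
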