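test_that("the 20 packaged variants reproduce the published consequence classes", {
  ann <- cached_annotation()
  got <- setNames(ann$consequence, ann$variant_id)
  expect_equal(got[["rs334"]], "missense")
  expect_equal(got[["rs33930165"]], "missense")
  expect_equal(got[["rs33912272"]], "missense")
  expect_equal(got[["rs11549407"]], "stop_gained")
  expect_equal(got[["rs281864900"]], "frameshift")
  expect_equal(got[["rs1135071"]], "splice_region&missense")
  expect_equal(got[["rs35578002"]], "splice_region&synonymous")
  expect_equal(got[["rs33943001"]], "splice_acceptor&intron")
  expect_equal(got[["rs33971440"]], "splice_donor&intron")
  pc <- setNames(ann$protein_change, ann$variant_id)
  expect_equal(pc[["rs334"]], "Glu7Val")
  expect_equal(pc[["rs281864900"]], "Phe42fs")
  expect_equal(pc[["rs11549407"]], "Gln40")
  expect_equal(pc[["rs1135071"]], "Arg31Ser")
  expect_equal(pc[["rs33950507"]], "Glu27Lys")
  expect_equal(pc[["rs36020563"]], "His144His")
  # codon-level record for the HbS substitution
  expect_equal(ann$codon_ref[ann$variant_id == "rs334"], "GAG")
  expect_equal(ann$codon_alt[ann$variant_id == "rs334"], "GTG")
})

test_that("consequence classes partition carriers as published", {
  fx <- cached_fixture()
  ann <- cached_annotation()
  cls <- vapply(ann$terms, function(t) paste(sort(t), collapse = "&"),
                character(1))
  n_of <- function(x) sum(cls == x)
  expect_equal(n_of("synonymous"), 4L)
  expect_equal(n_of("missense"), 7L)
  expect_equal(n_of("stop_gained"), 4L)
  expect_equal(n_of("frameshift"), 1L)
  expect_equal(sum(grepl("splice", cls)), 4L)
})

test_that("positions outside the gene span are intergenic", {
  fx <- cached_fixture()
  pos <- 5246050L
  v <- tibble::tibble(pos = pos,
                      ref = contig_slice(fx$reference, pos, pos),
                      alt = "A")
  if (v$ref == "A") v$alt <- "C"
  ann <- annotate_variants(v, fx$model, fx$reference)
  expect_equal(ann$consequence, "intergenic")
  expect_true(is.na(ann$protein_change))
})

test_that("a REF allele that contradicts the contig aborts annotation", {
  fx <- cached_fixture()
  base <- contig_slice(fx$reference, 5248232L, 5248232L)
  wrong <- setdiff(c("A", "C", "G", "T"), base)[1]
  v <- tibble::tibble(pos = 5248232L, ref = wrong, alt = base)
  expect_error(annotate_variants(v, fx$model, fx$reference), "REF mismatch")
})

test_that("annotator agrees with the whole-translation oracle on the fixture", {
  fx <- cached_fixture()
  ann <- cached_annotation()
  orc <- classify_by_full_translation(fx$variants, fx$model, fx$reference)
  expect_identical(ann$consequence, orc$consequence)
  expect_identical(ann$protein_change, orc$protein_change)
  expect_identical(ann$aa_pos, orc$aa_pos)
})

test_that("annotator agrees with the oracle on random gene/variant systems", {
  for (s in 1:8) {
    sys <- random_gene_system(s)
    v <- random_variants(sys$model, sys$reference, 25L, seed = 100 + s)
    ann <- annotate_variants(v, sys$model, sys$reference)
    orc <- classify_by_full_translation(v, sys$model, sys$reference)
    expect_identical(ann$consequence, orc$consequence)
    expect_identical(ann$protein_change, orc$protein_change)
  }
})

test_that("consequences are invariant under a strand mirror", {
  fx <- cached_fixture()
  ann <- cached_annotation()
  mir <- mirror_gene_system(fx$model, fx$reference, fx$variants)
  ann2 <- annotate_variants(mir$variants, mir$model, mir$reference)
  expect_identical(ann$consequence, ann2$consequence)
  expect_identical(ann$protein_change, ann2$protein_change)
  for (s in 21:24) {
    sys <- random_gene_system(s)
    v <- random_variants(sys$model, sys$reference, 20L, seed = 200 + s)
    mir <- mirror_gene_system(sys$model, sys$reference, v)
    a1 <- annotate_variants(v, sys$model, sys$reference)
    a2 <- annotate_variants(mir$variants, mir$model, mir$reference)
    expect_identical(a1$consequence, a2$consequence)
    expect_identical(a1$protein_change, a2$protein_change)
  }
})

test_that("every consequence carries exactly one anchoring term", {
  anchors <- c("synonymous", "missense", "stop_gained", "frameshift",
               "intron", "intergenic")
  check <- function(ann) {
    for (t in ann$terms) {
      expect_equal(sum(t %in% anchors), 1L)
    }
    # protein change present iff a coding term is present
    coding <- vapply(ann$terms, function(t) {
      any(t %in% c("synonymous", "missense", "stop_gained", "frameshift"))
    }, logical(1))
    expect_identical(coding, !is.na(ann$protein_change))
  }
  check(cached_annotation())
  sys <- random_gene_system(31)
  v <- random_variants(sys$model, sys$reference, 40L, seed = 301)
  check(annotate_variants(v, sys$model, sys$reference))
})

test_that("protein changes format in published and HGVS-like styles", {
  ann <- cached_annotation()
  stopg <- ann[ann$variant_id == "rs11549407", ]
  expect_equal(format_protein_change(stopg, "paper"), "Gln40")
  expect_equal(format_protein_change(stopg, "hgvs"), "Gln40Ter")
  mis <- ann[ann$variant_id == "rs334", ]
  expect_equal(format_protein_change(mis, "paper"), "Glu7Val")
  expect_equal(format_protein_change(mis, "hgvs"), "Glu7Val")
  fs <- ann[ann$variant_id == "rs281864900", ]
  expect_equal(format_protein_change(fs, "hgvs"), "Phe42fs")
  intronic <- ann[ann$variant_id == "rs33943001", ]
  expect_error(format_protein_change(intronic), "without a protein-level")
})
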