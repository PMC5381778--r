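test_that("constrained codon choice matches brute-force codon-table enumeration", {
  # minus-strand toy gene; pin genomic base T at the codon-7 second position
  # and require Glu there: enumeration of the codon table says the CDS codon
  # must be GAA or GAG (cDNA A complements the genomic T)
  gm <- gene_model("c", "-", tibble::tibble(start = 101L, end = 160L))
  pin_pos <- cds_to_genomic(gm, 19L)  # codon 7, base 2
  oracle <- names(Biostrings::GENETIC_CODE)[
    Biostrings::GENETIC_CODE == "E" &
      substr(names(Biostrings::GENETIC_CODE), 2, 2) == "A"]
  expect_setequal(oracle, c("GAA", "GAG"))
  for (s in 1:5) {
    ref <- build_reference(gm, codon_constraints = list(`7` = "E"),
                           base_constraints = tibble::tibble(pos = pin_pos,
                                                             base = "T"),
                           seed = s)
    codon7 <- substr(spliced_cds(gm, ref), 19, 21)
    expect_true(codon7 %in% oracle)
    expect_equal(contig_slice(ref, pin_pos, pin_pos), "T")
  }
})

test_that("unsatisfiable codon/base constraints raise a spec error", {
  gm <- gene_model("c", "-", tibble::tibble(start = 101L, end = 160L))
  pin_pos <- cds_to_genomic(gm, 19L)
  # Glu requires cDNA A at base 2, i.e. genomic T; pinning C is impossible
  expect_error(
    build_reference(gm, codon_constraints = list(`7` = "E"),
                    base_constraints = tibble::tibble(pos = pin_pos,
                                                      base = "C"),
                    seed = 1),
    "unsatisfiable")
})

test_that("an unconstrained build yields a valid open reading frame", {
  gm <- gene_model("c", "+", tibble::tibble(start = 101L, end = 190L))
  ref <- build_reference(gm, seed = 3)
  p <- translate_cds(spliced_cds(gm, ref))
  expect_equal(substr(p, 1, 1), "M")
  expect_equal(substr(p, nchar(p), nchar(p)), "*")
  expect_false(grepl("\\*", substr(p, 1, nchar(p) - 1L)))
})

test_that("the packaged reference carries every residue the published labels require", {
  fx <- cached_fixture()
  p <- translate_cds(spliced_cds(fx$model, fx$reference))
  want <- c(`6` = "P", `7` = "E", `16` = "W", `18` = "K", `27` = "E",
            `30` = "G", `31` = "R", `40` = "Q", `42` = "F", `82` = "L",
            `108` = "G", `109` = "N", `122` = "E", `128` = "Q", `130` = "A",
            `134` = "V", `144` = "H")
  got <- substring(p, as.integer(names(want)), as.integer(names(want)))
  expect_equal(unname(got), unname(want))
})

test_that("cohort simulation is deterministic and respects carrier counts", {
  fx1 <- hbb_fixture(seed = 7)
  fx2 <- hbb_fixture(seed = 7)
  expect_identical(fx1$cohort$dosage, fx2$cohort$dosage)
  expect_identical(fx1$reference$sequence, fx2$reference$sequence)
  # one variant per carrier, all heterozygous
  expect_true(all(fx1$cohort$dosage %in% c(0L, 1L)))
  expect_true(all(rowSums(fx1$cohort$dosage) <= 1L))
  expect_equal(sum(rowSums(fx1$cohort$dosage) > 0L), 209L)
  # per-population column sums reproduce the published carrier table
  cc <- hbb_carrier_counts()
  for (k in seq_len(nrow(cc))) {
    pop_samples <- fx1$cohort$samples$population == cc$population[k]
    expect_equal(sum(fx1$cohort$dosage[pop_samples, cc$variant_id[k]]),
                 cc$carriers[k])
  }
})

test_that("carrier demand exceeding a population size is rejected", {
  expect_error(
    cohort_spec(c(A = 3L),
                tibble::tibble(variant_id = "v1", pos = 1L, ref = "A",
                               alt = "T"),
                tibble::tibble(variant_id = "v1", population = "A",
                               carriers = 5L)),
    "exceeds population size")
})

test_that("written VCF recounts to the spec and round-trips losslessly", {
  fx <- cached_fixture()
  dir <- withr::local_tempdir()
  paths <- write_pipeline_inputs(fx$cohort, fx$reference, fx$model,
                                 fx$evidence, dir,
                                 overrides = fx$overrides)
  # independent re-parse: raw line scan, no package reader involved
  lines <- readLines(paths$vcf)
  body <- lines[!startsWith(lines, "#")]
  expect_equal(length(body), 20L)
  fields <- strsplit(body, "\t", fixed = TRUE)
  hdr <- strsplit(lines[startsWith(lines, "#CHROM")], "\t")[[1]]
  recount <- vapply(fields, function(f) sum(f[-(1:9)] == "0/1"), integer(1))
  ids <- vapply(fields, `[`, character(1), 3L)
  totals <- dplyr::count(hbb_carrier_counts(), variant_id,
                         wt = carriers, name = "carriers")
  expect_equal(recount, totals$carriers[match(ids, totals$variant_id)])
  expect_false(any(vapply(fields, function(f) any(f[-(1:9)] == "1/1"),
                          logical(1))))
  # deletion emitted VCF-style with its anchor base
  del <- fields[[which(ids == "rs281864900")]]
  expect_equal(del[4], "CAAAG")
  expect_equal(del[5], "C")
  expect_equal(as.integer(del[2]), 5247992L)
  # round trip through the package readers
  cohort2 <- read_cohort_vcf(paths$vcf, paths$pop_map)
  expect_identical(cohort2$dosage, fx$cohort$dosage)
  expect_equal(cohort2$variants, fx$cohort$variants)
  expect_equal(read_evidence(paths$evidence), fx$evidence)
  expect_equal(read_overrides(paths$overrides), fx$overrides)
  # same seed => byte-identical emitted files
  dir2 <- withr::local_tempdir()
  fxb <- hbb_fixture(seed = 42L)
  paths2 <- write_pipeline_inputs(fxb$cohort, fxb$reference, fxb$model,
                                  fxb$evidence, dir2,
                                  overrides = fxb$overrides)
  for (nm in names(paths)) {
    expect_identical(readLines(paths2[[nm]]), readLines(paths[[nm]]))
  }
})

test_that("an all-reference cohort writes a valid VCF with zero carriers", {
  spec <- cohort_spec(
    c(A = 5L, B = 4L),
    tibble::tibble(variant_id = "v1", pos = 150L, ref = "A", alt = "T"),
    tibble::tibble(variant_id = "v1", population = c("A", "B"),
                   carriers = c(0L, 0L)))
  cohort <- simulate_cohort(spec, seed = 1)
  expect_true(all(cohort$dosage == 0L))
  dir <- withr::local_tempdir()
  p <- file.path(dir, "c.vcf")
  write_cohort_vcf(cohort, p, contig = "ctg")
  cohort2 <- read_cohort_vcf(p, cohort$samples)
  expect_equal(nrow(cohort2$variants), 1L)
  expect_equal(cohort2$variants$ref, "A")
  expect_true(all(cohort2$dosage == 0L))
})
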