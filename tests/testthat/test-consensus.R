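test_that("raw labels normalize onto the four analysis classes", {
  expect_equal(normalize_label("Probably damaging"), "damaging")
  expect_equal(normalize_label("Damaging"), "damaging")
  expect_equal(normalize_label("Benign"), "benign")
  expect_equal(normalize_label("Other"), "uninformative")
  expect_equal(normalize_label("not-evaluated"), "absent")
  expect_error(normalize_label("suspicious"), "unknown evidence label")
})

test_that("class calls take a strict majority of informative labels", {
  expect_equal(class_call(c("damaging", "damaging", "benign")), "Damaging")
  expect_equal(class_call(c("benign", "benign", "damaging")), "Benign")
  expect_equal(class_call(c("damaging", "benign")), "NoCall")
  expect_equal(class_call(c("uninformative", "absent")), "NoCall")
  expect_equal(class_call(character(0)), "NoCall")
  expect_equal(class_call(c("damaging", "benign"), "unanimous"), "Conflict")
})

test_that("consensus combines database and predictor calls as specified", {
  ev <- function(db, pr) {
    tibble::tibble(
      source = c("CLINVAR", "dbSNP", "HbVar",
                 "POLYPHEN", "PROVEAN", "SIFT", "PANTHER", "MUTPRED"),
      label = c(db, pr))
  }
  D <- "Damaging"; B <- "Benign"; N <- "not-evaluated"
  # Glu27Lys: databases all damaging, predictors 4-1 damaging -> Damaging
  expect_equal(consensus_verdict(ev(c(D, D, D), c(B, D, D, D, D)))$verdict,
               "Damaging")
  # Glu122Gln: databases 2-1 damaging, predictors 3-2 benign -> Conflict
  v <- consensus_verdict(ev(c(D, D, B), c(B, B, D, B, D)))
  expect_equal(v$db_call, "Damaging")
  expect_equal(v$predictor_call, "Benign")
  expect_equal(v$verdict, "Conflict")
  # Gln40: predictors all absent; the database call stands
  expect_equal(consensus_verdict(ev(c(D, D, D), rep(N, 5)))$verdict,
               "Damaging")
  expect_equal(consensus_verdict(ev(c(B, B, B), c(B, B, B, B, B)))$verdict,
               "Benign")
  expect_equal(consensus_verdict(ev(rep(N, 3), rep(N, 5)))$verdict,
               "NotEvaluated")
})

test_that("verdicts are invariant under source permutation and uninformative padding", {
  fx <- cached_fixture()
  base <- classify_pathogenicity(fx$evidence, cached_annotation())
  withr::with_seed(9, {
    shuffled <- fx$evidence[sample(nrow(fx$evidence)), ]
  })
  expect_equal(classify_pathogenicity(shuffled, cached_annotation()), base)
  # swapping labels within a class leaves verdicts unchanged
  swapped <- fx$evidence
  i_cv <- swapped$source == "CLINVAR"; i_hb <- swapped$source == "HbVar"
  tmp <- swapped$label[i_cv]
  swapped$label[i_cv] <- swapped$label[i_hb]
  swapped$label[i_hb] <- tmp
  expect_equal(classify_pathogenicity(swapped, cached_annotation())$verdict,
               base$verdict)
  # adding uninformative or absent labels never changes a verdict
  padded <- dplyr::bind_rows(
    fx$evidence,
    tibble::tibble(variant_id = unique(fx$evidence$variant_id),
                   source = "dbSNP", label = "Other"),
    tibble::tibble(variant_id = unique(fx$evidence$variant_id),
                   source = "MUTPRED", label = "not-evaluated"))
  expect_equal(classify_pathogenicity(padded, cached_annotation())$verdict,
               base$verdict)
})

test_that("flipping a benign predictor to damaging never demotes a Damaging verdict", {
  fx <- cached_fixture()
  ann <- cached_annotation()
  base <- classify_pathogenicity(fx$evidence, ann)
  benign_pred <- which(fx$evidence$label == "Benign" &
                         fx$evidence$source %in%
                           c("POLYPHEN", "PROVEAN", "SIFT", "PANTHER",
                             "MUTPRED"))
  for (i in benign_pred) {
    ev2 <- fx$evidence
    ev2$label[i] <- "Damaging"
    after <- classify_pathogenicity(ev2, ann)
    was_damaging <- base$verdict == "Damaging"
    expect_false(any(after$verdict[was_damaging] == "Benign"))
  }
})

test_that("the default rule reproduces 15/16 published conclusions; the override completes them", {
  fx <- cached_fixture()
  ann <- cached_annotation()
  published <- c(
    rs111645889 = "Conflict", rs33971634 = "Damaging",
    rs33946267 = "Conflict", rs33958637 = "Conflict",
    rs281864900 = "Damaging", rs11549407 = "Damaging",
    rs1135071 = "Damaging", rs33943001 = "Damaging",
    rs33971440 = "Damaging", rs35578002 = "Conflict",
    rs33950507 = "Damaging", rs33986703 = "Damaging",
    rs63750783 = "Damaging", rs334 = "Damaging",
    rs33930165 = "Damaging", rs33912272 = "Conflict")
  no_ovr <- classify_pathogenicity(fx$evidence, ann)
  got <- setNames(no_ovr$verdict, no_ovr$variant_id)[names(published)]
  expect_equal(sum(got == published), 15L)
  expect_equal(unname(got["rs33912272"]), "Benign")   # the residual row
  with_ovr <- classify_pathogenicity(fx$evidence, ann,
                                     overrides = fx$overrides)
  got2 <- setNames(with_ovr$verdict, with_ovr$variant_id)[names(published)]
  expect_equal(unname(got2), unname(published))
  expect_true(with_ovr$overridden[with_ovr$variant_id == "rs33912272"])
  # 11 Damaging verdicts with or without the override
  expect_equal(sum(no_ovr$verdict == "Damaging"), 11L)
  expect_equal(sum(with_ovr$verdict == "Damaging"), 11L)
})

test_that("pure-synonymous variants are excluded from pathogenicity review", {
  fx <- cached_fixture()
  verdicts <- classify_pathogenicity(fx$evidence, cached_annotation())
  syn <- c("rs36020563", "rs113082294", "rs193922562", "rs145669504")
  expect_equal(verdicts$verdict[match(syn, verdicts$variant_id)],
               rep("NotEvaluated", 4))
  expect_false(any(verdicts$evaluated[match(syn, verdicts$variant_id)]))
  expect_equal(sum(verdicts$evaluated), 16L)
  empty <- classify_pathogenicity(fx$evidence[0, ], cached_annotation()[0, ])
  expect_equal(nrow(empty), 0L)
})
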