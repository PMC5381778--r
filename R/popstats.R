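#' Per-population alternate-allele counts
#'
#' Tallies alternate alleles by population (a heterozygote contributes 1, a
#' homozygous-alternate genotype 2) together with carrier counts.
#'
#' @param cohort A `cohort_genotypes`.
#' @param variant_id Optional character vector restricting the tally; an
#'   unknown id aborts.
#' @returns Long tibble: `variant_id`, `population`, `carriers`,
#'   `alt_alleles` (complete over populations, zeros included).
#' @export
allele_counts <- function(cohort, variant_id = NULL) {
  ids <- variant_id %||% cohort$variants$variant_id
  unknown <- setdiff(ids, cohort$variants$variant_id)
  if (length(unknown)) {
    abort(sprintf("unknown variant id(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  pops <- unique(cohort$samples$population)
  tidyr::expand_grid(variant_id = ids, population = pops) |>
    mutate(
      carriers = map2_int(.data$variant_id, .data$population, function(v, p) {
        d <- cohort$dosage[cohort$samples$population == p, v]
        sum(d > 0L)
      }),
      alt_alleles = map2_int(.data$variant_id, .data$population,
                             function(v, p) {
        sum(cohort$dosage[cohort$samples$population == p, v])
      })
    )
}

#' Allele frequency with the cohort display convention
#'
#' @param count Alternate-allele count(s).
#' @param n_diploid Number of diploid samples (so `2 * n_diploid` alleles).
#' @param display `"exact"` for the raw ratio, `"paper"` for the published
#'   table convention: truncation (flooring) at 5 decimal places.
#' @returns Numeric frequency vector.
#' @examples
#' allele_frequency(137, 2504, "paper")   # 0.02735
#' @export
allele_frequency <- function(count, n_diploid,
                             display = c("exact", "paper")) {
  display <- match.arg(display)
  if (n_diploid <= 0L) abort("n_diploid must be positive")
  if (any(count < 0L | count > 2L * n_diploid)) {
    abort("count must lie in [0, 2 * n_diploid]")
  }
  f <- count / (2 * n_diploid)
  if (display == "paper") trunc_digits(f, 5L) else f
}

#' Hardy-Weinberg projection of the affected-offspring frequency
#'
#' Under random mating, the probability that an offspring receives two
#' mutant alleles from an allele class of pooled frequency `q` — i.e. is
#' homozygous or compound heterozygous for that class — is `q^2`.
#'
#' @param q Mutant-allele frequency (or vector), in `[0, 1]`.
#' @returns `q^2`.
#' @examples
#' hw_projection(209 / 5008)
#' @export
hw_projection <- function(q) {
  if (any(is.na(q)) || any(q < 0 | q > 1)) {
    abort("q must lie in [0, 1]")
  }
  q^2
}

#' Cohort carrier-burden summary
#'
#' Joins genotype tallies with consequence annotations and pathogenicity
#' verdicts and computes the cohort-level burden statistics: the carrier
#' proportion, the non-synonymous and deleterious carrier subsets, the pooled
#' mutant-allele frequency `q` with its Hardy-Weinberg projection `q^2`, and
#' the same pair restricted to Damaging-verdict variants (`q_d`, `q_d^2`).
#'
#' @param cohort A `cohort_genotypes`.
#' @param annotations Output of [annotate_variants()] covering every cohort
#'   variant.
#' @param verdicts Output of [classify_pathogenicity()] covering every
#'   cohort variant.
#' @returns An object of class `hbb_burden` with elements `per_variant`
#'   (tibble), `per_population` (long count tibble) and `cohort` (one-row
#'   tibble of burden statistics).
#' @examples
#' fx <- hbb_fixture(seed = 1)
#' ann <- annotate_variants(fx$variants, fx$model, fx$reference)
#' ver <- classify_pathogenicity(fx$evidence, ann)
#' burden_summary(fx$cohort, ann, ver)
#' @export
burden_summary <- function(cohort, annotations, verdicts) {
  ids <- cohort$variants$variant_id
  gap <- setdiff(ids, annotations$variant_id)
  if (length(gap)) {
    abort(sprintf("annotations missing for: %s", paste(gap, collapse = ", ")))
  }
  gap <- setdiff(ids, verdicts$variant_id)
  if (length(gap)) {
    abort(sprintf("verdicts missing for: %s", paste(gap, collapse = ", ")))
  }
  n <- nrow(cohort$samples)
  counts <- allele_counts(cohort)
  per_pop <- counts |>
    left_join(dplyr::count(cohort$samples, .data$population,
                           name = "population_size"),
              by = "population")
  totals <- counts |>
    group_by(.data$variant_id) |>
    summarise(carriers = sum(.data$carriers),
              alt_alleles = sum(.data$alt_alleles), .groups = "drop")
  per_variant <- cohort$variants |>
    left_join(totals, by = "variant_id") |>
    left_join(select(annotations, "variant_id", "terms", "consequence",
                     "protein_change"),
              by = "variant_id") |>
    left_join(select(verdicts, "variant_id", "verdict", "overridden"),
              by = "variant_id") |>
    mutate(
      pure_synonymous = map_lgl(.data$terms, function(t) {
        identical(sort(t), "synonymous")
      }),
      missense_only = map_lgl(.data$terms, function(t) {
        identical(t, "missense")
      }),
      deleterious = .data$verdict == "Damaging",
      frequency = allele_frequency(.data$alt_alleles, n),
      frequency_paper = allele_frequency(.data$alt_alleles, n, "paper")
    )
  carriers <- sum(rowSums(cohort$dosage) > 0L)
  nonsyn_carriers <- sum(per_variant$carriers[!per_variant$pure_synonymous])
  q <- sum(per_variant$alt_alleles) / (2 * n)
  q_d <- sum(per_variant$alt_alleles[per_variant$deleterious]) / (2 * n)
  cohort_stats <- tibble(
    n_samples = n,
    n_variants = nrow(per_variant),
    carriers = carriers,
    carrier_proportion = carriers / n,
    pure_synonymous_carriers =
      sum(per_variant$carriers[per_variant$pure_synonymous]),
    missense_only_carriers =
      sum(per_variant$carriers[per_variant$missense_only]),
    nonsynonymous_carriers = nonsyn_carriers,
    deleterious_carriers =
      sum(per_variant$carriers[per_variant$deleterious]),
    n_damaging_variants = sum(per_variant$deleterious, na.rm = TRUE),
    q = q,
    homozygote_projection = hw_projection(q),
    q_deleterious = q_d,
    affected_projection = hw_projection(q_d),
    affected_per_10000 = hw_projection(q_d) * 1e4
  )
  structure(
    list(per_variant = per_variant, per_population = per_pop,
         cohort = cohort_stats),
    class = "hbb_burden"
  )
}

#' @export
print.hbb_burden <- function(x, ...) {
  s <- x$cohort
  cat(sprintf(
    paste0("<hbb_burden> %d variants in %d samples\n",
           "  carriers: %d (%.2f%% truncated: %s%%)\n",
           "  non-synonymous carriers: %d; deleterious carriers: %d\n",
           "  q = %.4f (projection q^2 = %.4f); ",
           "q_d = %.4f (q_d^2 x 10^4 = %.1f)\n"),
    s$n_variants, s$n_samples, s$carriers, 100 * s$carrier_proportion,
    format(trunc_digits(100 * s$carrier_proportion, 2L)),
    s$nonsynonymous_carriers, s$deleterious_carriers,
    s$q, s$homozygote_projection, s$q_deleterious, s$affected_per_10000))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-variant tidy view of a burden summary
#' @param x An `hbb_burden`.
#' @param ... Unused.
#' @returns The per-variant tibble (counts, frequencies, consequence,
#'   verdict).
#' @export
tidy.hbb_burden <- function(x, ...) {
  x$per_variant
}

#' One-row cohort view of a burden summary
#' @param x An `hbb_burden`.
#' @param ... Unused.
#' @returns One-row tibble of cohort burden statistics.
#' @export
glance.hbb_burden <- function(x, ...) {
  x$cohort
}

#' Plot carrier counts by population and consequence class
#' @param object An `hbb_burden`.
#' @param ... Unused.
#' @returns A ggplot object.
#' @export
autoplot.hbb_burden <- function(object, ...) {
  classes <- object$per_variant |>
    mutate(class = dplyr::case_when(
      .data$pure_synonymous ~ "synonymous",
      .data$deleterious ~ "deleterious",
      TRUE ~ "other non-synonymous"
    )) |>
    select("variant_id", "class")
  df <- object$per_population |>
    left_join(classes, by = "variant_id") |>
    group_by(.data$population, .data$class) |>
    summarise(carriers = sum(.data$carriers), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$population, y = .data$carriers,
                                   fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "super-population", y = "carrier individuals",
                  fill = "variant class") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
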