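#' Specify a synthetic multi-population carrier cohort
#'
#' A cohort spec pairs super-population sizes with a variant table and
#' per-population heterozygous-carrier counts.  Each carrier individual is
#' assigned exactly one variant (no double heterozygotes), matching a cohort
#' in which per-variant carrier counts sum to the number of mutated
#' individuals.
#'
#' @param population_sizes Named integer vector of diploid sample counts.
#' @param variants Tibble with columns `variant_id`, `pos`, `ref`, `alt`.
#' @param carrier_counts Long tibble (`variant_id`, `population`, `carriers`).
#' @returns An object of class `cohort_spec`.
#' @export
cohort_spec <- function(population_sizes, variants, carrier_counts) {
  variants <- as_tibble(variants)
  carrier_counts <- as_tibble(carrier_counts)
  stopifnot(!is.null(names(population_sizes)),
            all(c("variant_id", "pos", "ref", "alt") %in% names(variants)),
            all(c("variant_id", "population", "carriers") %in%
                  names(carrier_counts)))
  bad_pop <- setdiff(unique(carrier_counts$population),
                     names(population_sizes))
  if (length(bad_pop)) {
    abort(sprintf("carrier counts name unknown population(s): %s",
                  paste(bad_pop, collapse = ", ")))
  }
  demand <- carrier_counts |>
    group_by(.data$population) |>
    summarise(total = sum(.data$carriers), .groups = "drop")
  over <- demand$total > population_sizes[demand$population]
  if (any(over)) {
    abort(sprintf("carrier demand exceeds population size in: %s",
                  paste(demand$population[over], collapse = ", ")))
  }
  structure(
    list(population_sizes = population_sizes, variants = variants,
         carrier_counts = carrier_counts),
    class = "cohort_spec"
  )
}

# All codons coding a given one-letter residue ("*" = terminator).
codons_for <- function(aa) {
  names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE == aa]
}

#' Build a reference contig satisfying codon and base constraints
#'
#' Generates a seeded-random contig window whose CDS translates with the
#' required residues (initiator Met and terminal stop are always enforced, no
#' internal stops) and whose bases at constrained genomic positions — variant
#' reference alleles and any explicit pins — take the required values,
#' strand-adjusted.  Jointly unsatisfiable constraints (e.g. a pinned base
#' incompatible with a required residue) raise an error.
#'
#' @param model A [gene_model()].
#' @param variants Optional tibble (`pos`, `ref`, ...): each reference allele
#'   pins `nchar(ref)` contig bases starting at `pos`.
#' @param codon_constraints Named list: codon index (Met = 1) to required
#'   one-letter residue.
#' @param base_constraints Optional tibble (`pos`, `base`) of genomic pins.
#' @param window Length-2 integer vector, the genomic span of the contig;
#'   defaults to the gene span padded by 200 bases.
#' @param seed Integer seed for unconstrained bases and free codon choices.
#' @returns A [reference_contig()].
#' @export
build_reference <- function(model, variants = NULL, codon_constraints = NULL,
                            base_constraints = NULL, window = NULL,
                            seed = 1L) {
  span <- c(min(model$exons$start), max(model$exons$end))
  window <- as.integer(window %||% c(span[1] - 200L, span[2] + 200L))
  if (window[1] > span[1] || window[2] < span[2]) {
    abort("window does not cover the gene span")
  }
  L <- window[2] - window[1] + 1L
  withr::with_seed(seed, {
    bases <- sample(DNA_BASES, L, replace = TRUE)
    pinned <- logical(L)
    pin <- function(pos, base) {
      i <- pos - window[1] + 1L
      if (any(i < 1L | i > L)) abort("pinned base outside contig window")
      clash <- pinned[i] & bases[i] != base
      if (any(clash)) {
        abort(sprintf("conflicting base constraints at position(s) %s",
                      paste(pos[clash], collapse = ", ")))
      }
      bases[i] <<- base
      pinned[i] <<- TRUE
    }
    if (!is.null(variants)) {
      for (k in seq_len(nrow(variants))) {
        r <- strsplit(variants$ref[k], "")[[1]]
        assert_dna(variants$ref[k], "variant REF")
        pin(variants$pos[k] + seq_along(r) - 1L, r)
      }
    }
    if (!is.null(base_constraints)) {
      for (k in seq_len(nrow(base_constraints))) {
        pin(base_constraints$pos[k], base_constraints$base[k])
      }
    }
    n_codons <- cds_length(model) %/% 3L
    for (i in seq_len(n_codons)) {
      gpos <- cds_to_genomic(model, 3L * (i - 1L) + 0:2)
      idx <- gpos - window[1] + 1L
      have <- pinned[idx]
      fixed <- if (model$strand == "+") bases[idx] else
        dna_complement(bases[idx])
      aa <- if (i == 1L) "M" else if (i == n_codons) "*" else
        codon_constraints[[as.character(i)]]
      cand <- if (is.null(aa)) {
        names(Biostrings::GENETIC_CODE)[Biostrings::GENETIC_CODE != "*"]
      } else {
        codons_for(aa)
      }
      if (any(have)) {
        keep <- map_lgl(cand, function(cd) {
          all(strsplit(cd, "")[[1]][have] == fixed[have])
        })
        cand <- cand[keep]
      }
      if (!length(cand)) {
        abort(sprintf(
          "unsatisfiable constraints at codon %d (required residue %s)",
          i, aa %||% "any"))
      }
      chosen <- strsplit(sample(cand, 1L), "")[[1]]
      if (model$strand == "-") chosen <- dna_complement(chosen)
      bases[idx] <- chosen
      pinned[idx] <- TRUE
    }
    reference_contig(model$contig, paste(bases, collapse = ""),
                     offset = window[1])
  })
}

#' Simulate cohort genotypes from a spec
#'
#' Deterministically (given `seed`) assigns distinct carrier individuals to
#' variants within each population: a carrier is heterozygous (`0/1`) for
#' exactly one variant, every other genotype is `0/0`.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed for carrier-to-sample assignment.
#' @returns An object of class `cohort_genotypes`: list with `samples`
#'   (tibble `sample_id`, `population`), `variants`, and `dosage` (samples x
#'   variants integer matrix of alternate-allele counts).
#' @export
simulate_cohort <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  sizes <- spec$population_sizes
  samples <- imap(sizes, function(n, pop) {
    tibble(sample_id = sprintf("%s%04d", pop, seq_len(n)), population = pop)
  }) |> list_rbind()
  nv <- nrow(spec$variants)
  dosage <- matrix(0L, nrow = nrow(samples), ncol = nv,
                   dimnames = list(samples$sample_id,
                                   spec$variants$variant_id))
  withr::with_seed(seed, {
    for (pop in names(sizes)) {
      cc <- filter(spec$carrier_counts, .data$population == pop,
                   .data$carriers > 0L)
      if (!nrow(cc)) next
      # keep the variant-table order for reproducible partitioning
      cc <- cc[match(intersect(spec$variants$variant_id, cc$variant_id),
                     cc$variant_id), ]
      total <- sum(cc$carriers)
      pool <- samples$sample_id[samples$population == pop]
      chosen <- sample(pool, total)
      at <- 0L
      for (k in seq_len(nrow(cc))) {
        ids <- chosen[at + seq_len(cc$carriers[k])]
        dosage[ids, cc$variant_id[k]] <- 1L
        at <- at + cc$carriers[k]
      }
    }
  })
  structure(
    list(samples = samples, variants = spec$variants, dosage = dosage),
    class = "cohort_genotypes"
  )
}

#' @export
print.cohort_genotypes <- function(x, ...) {
  cat(sprintf(
    "<cohort_genotypes> %d samples in %d population(s), %d variant(s), %d carrier(s)\n",
    nrow(x$samples), dplyr::n_distinct(x$samples$population),
    nrow(x$variants), sum(rowSums(x$dosage) > 0)))
  invisible(x)
}

# ---- pipeline input files ---------------------------------------------------

dosage_to_gt <- function(d) c("0/0", "0/1", "1/1")[d + 1L]

#' Write every pipeline input to a directory
#'
#' Emits the reference FASTA, gene-model GFF3, GT-only VCF v4.2, population
#' map TSV, evidence TSV and (optionally) override TSV.  Files round-trip
#' losslessly through the package readers.
#'
#' @param cohort A `cohort_genotypes`.
#' @param reference A `reference_contig`.
#' @param model A `gene_model`.
#' @param evidence Long evidence tibble (`variant_id`, `source`, `label`).
#' @param dir Output directory (created if missing).
#' @param overrides Optional verdict override tibble (`variant_id`,
#'   `verdict`).
#' @returns Named list of the file paths written.
#' @export
write_pipeline_inputs <- function(cohort, reference, model, evidence, dir,
                                  overrides = NULL) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- list(
    reference = file.path(dir, "reference.fa"),
    gene_model = file.path(dir, "gene_model.gff3"),
    vcf = file.path(dir, "cohort.vcf"),
    pop_map = file.path(dir, "population_map.tsv"),
    evidence = file.path(dir, "evidence.tsv")
  )
  write_reference(reference, paths$reference)
  write_gene_model(model, paths$gene_model)
  write_cohort_vcf(cohort, paths$vcf)
  readr::write_tsv(cohort$samples, paths$pop_map)
  readr::write_tsv(evidence, paths$evidence)
  if (!is.null(overrides)) {
    paths$overrides <- file.path(dir, "overrides.tsv")
    readr::write_tsv(overrides, paths$overrides)
  }
  paths
}

#' Write cohort genotypes as a GT-only VCF v4.2
#'
#' @param cohort A `cohort_genotypes`.
#' @param path Output file.
#' @param contig Contig name for the header (defaults to the first variant's
#'   implied contig, `"chr11"` for the packaged fixture).
#' @returns `path`, invisibly.
#' @export
write_cohort_vcf <- function(cohort, path, contig = "chr11") {
  v <- cohort$variants
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=hbbcohort",
    sprintf("##contig=<ID=%s>", contig),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", cohort$samples$sample_id), collapse = "\t")
  )
  body <- map_chr(seq_len(nrow(v)), function(k) {
    paste(c(contig, v$pos[k], v$variant_id[k], v$ref[k], v$alt[k], ".",
            "PASS", ".", "GT", dosage_to_gt(cohort$dosage[, k])),
          collapse = "\t")
  })
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a genotyped cohort from VCF plus a population map
#'
#' @param vcf_path GT-format multi-sample VCF.
#' @param pop_map Either the path of a two-column TSV (`sample_id`,
#'   `population`) or an equivalent tibble.
#' @returns A `cohort_genotypes`.
#' @export
read_cohort_vcf <- function(vcf_path, pop_map) {
  if (is.character(pop_map)) pop_map <- read_population_map(pop_map)
  x <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(x)
  if (is.null(dim(fix))) fix <- t(fix)    # single-record VCF
  fix <- as_tibble(as.data.frame(fix, stringsAsFactors = FALSE))
  variants <- tibble(
    variant_id = fix$ID,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT
  )
  samples <- as_tibble(pop_map)
  nv <- nrow(variants)
  dosage <- matrix(0L, nrow = nrow(samples), ncol = nv,
                   dimnames = list(samples$sample_id, variants$variant_id))
  if (nv > 0L) {
    gt <- vcfR::extract.gt(x, element = "GT")   # variants x samples
    counts <- matrix(
      stringr::str_count(gt, "1"),
      nrow = nrow(gt), dimnames = dimnames(gt))
    missing <- setdiff(samples$sample_id, colnames(counts))
    if (length(missing)) {
      abort(sprintf("population map sample(s) absent from VCF: %s",
                    paste(head(missing, 3), collapse = ", ")))
    }
    dosage[, ] <- t(counts[, samples$sample_id, drop = FALSE])
    storage.mode(dosage) <- "integer"
  }
  structure(
    list(samples = samples, variants = variants, dosage = dosage),
    class = "cohort_genotypes"
  )
}

#' Read a sample-to-population map TSV
#' @param path TSV with columns `sample_id`, `population`.
#' @returns Tibble.
#' @export
read_population_map <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    population = readr::col_character()
  ))
}

#' Read a long evidence-label TSV
#' @param path TSV with columns `variant_id`, `source`, `label`.
#' @returns Tibble.
#' @export
read_evidence <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default =
                                                  readr::col_character()))
}

#' Read a verdict-override TSV
#' @param path TSV with columns `variant_id`, `verdict`.
#' @returns Tibble.
#' @export
read_overrides <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(.default =
                                                  readr::col_character()))
}
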