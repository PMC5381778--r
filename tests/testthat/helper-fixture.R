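# Shared fixtures: the packaged cohort is deterministic apart from filler
# bases and carrier placement, so one seeded build is reused across tests.

.fixture_cache <- new.env(parent = emptyenv())

cached_fixture <- function(seed = 42L) {
  key <- sprintf("fx%d", seed)
  if (is.null(.fixture_cache[[key]])) {
    .fixture_cache[[key]] <- hbb_fixture(seed = seed)
  }
  .fixture_cache[[key]]
}

cached_annotation <- function(seed = 42L) {
  key <- sprintf("ann%d", seed)
  if (is.null(.fixture_cache[[key]])) {
    fx <- cached_fixture(seed)
    .fixture_cache[[key]] <- annotate_variants(fx$variants, fx$model,
                                               fx$reference)
  }
  .fixture_cache[[key]]
}

# Random single-gene systems for property-style checks: 1-3 coding exons,
# 30-60 codons, either strand, seeded contig via build_reference().
random_gene_system <- function(seed) {
  withr::with_seed(seed, {
    n_exons <- sample(1:3, 1)
    n_codons <- sample(30:60, 1)
    len <- 3L * n_codons
    repeat {
      cuts <- if (n_exons > 1L) sort(sample(seq_len(len - 1L),
                                            n_exons - 1L)) else integer(0)
      pieces <- diff(c(0L, cuts, len))
      if (all(pieces >= 4L)) break
    }
    introns <- if (n_exons > 1L) sample(20:60, n_exons - 1L,
                                        replace = TRUE) else integer(0)
    start <- 101L
    starts <- integer(n_exons); ends <- integer(n_exons)
    at <- start
    for (j in seq_len(n_exons)) {
      starts[j] <- at
      ends[j] <- at + pieces[j] - 1L
      at <- ends[j] + 1L + (if (j < n_exons) introns[j] else 0L)
    }
    model <- gene_model("ctg", sample(c("+", "-"), 1),
                        tibble::tibble(start = starts, end = ends),
                        gene_name = sprintf("G%d", seed))
  })
  reference <- build_reference(model, window = c(41L, max(model$exons$end) + 60L),
                               seed = seed + 1000L)
  list(model = model, reference = reference)
}

# Random variants over a gene system: coding/intronic/intergenic SNVs plus
# frameshift-length anchored deletions inside single exons.  The terminal
# stop codon is left untouched (stop-loss semantics are out of scope).
random_variants <- function(model, reference, n, seed) {
  len <- cds_length(model)
  span <- c(min(model$exons$start), max(model$exons$end))
  wstart <- reference$offset
  wend <- reference$offset + nchar(reference$sequence) - 1L
  withr::with_seed(seed, {
    rows <- lapply(seq_len(n), function(i) {
      kind <- sample(c("cds_snv", "noncoding_snv", "deletion"), 1,
                     prob = c(0.55, 0.3, 0.15))
      if (kind == "cds_snv") {
        off <- sample(0:(len - 4L), 1)          # spare the stop codon
        pos <- cds_to_genomic(model, off)
      } else if (kind == "noncoding_snv") {
        repeat {
          pos <- sample(wstart:wend, 1)
          if (is.na(genomic_to_cds(model, pos))) break
        }
      } else {
        d <- sample(c(1L, 2L, 4L), 1)
        ok <- which(model$exons$end - model$exons$start + 1L >= d + 2L)
        if (!length(ok)) return(NULL)
        j <- if (length(ok) == 1L) ok else sample(ok, 1)
        s <- model$exons$start[j]; e <- model$exons$end[j]
        # deleted run strictly inside the exon, clear of the stop codon
        first <- sample(s:(e - d), 1)
        offs <- genomic_to_cds(model, first:(first + d - 1L))
        if (any(offs >= len - 3L)) return(NULL)
        pos <- first - 1L
        if (pos < wstart) return(NULL)
        ref <- contig_slice(reference, pos, pos + d)
        return(tibble::tibble(pos = pos, ref = ref,
                              alt = substr(ref, 1L, 1L)))
      }
      ref <- contig_slice(reference, pos, pos)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      tibble::tibble(pos = pos, ref = ref, alt = alt)
    })
    dplyr::bind_rows(rows)
  })
}
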