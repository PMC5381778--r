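TERM_ORDER <- c("splice_acceptor", "splice_donor", "splice_region",
                "synonymous", "missense", "stop_gained", "frameshift",
                "intron", "intergenic")

terms_to_string <- function(terms) {
  paste(terms[order(match(terms, TERM_ORDER))], collapse = "&")
}

# Genomic positions whose reference base is altered (or, for an insertion,
# the anchor base): these drive exon/intron/window membership.
touched_positions <- function(pos, ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  if (nr == na) pos + seq_len(nr) - 1L
  else if (nr > na) pos + na + seq_len(nr - na) - 1L   # anchored deletion
  else pos + nr - 1L                                   # anchored insertion
}

# Whole-protein comparison of a reference and an alternate spliced CDS;
# shared by the arithmetic annotator and the full-translation oracle (the two
# routes derive the alternate CDS independently).
classify_coding <- function(R, A) {
  net <- nchar(A) - nchar(R)
  P <- translate_prefix(R)
  if (net %% 3L != 0L) {
    p <- first_mismatch(R, A)
    if (is.na(p)) p <- min(nchar(R), nchar(A))
    cod <- p %/% 3L + 1L
    return(list(term = "frameshift", aa_pos = cod,
                aa_ref = substr(P, cod, cod), aa_alt = "fs",
                codon_ref = NA_character_, codon_alt = NA_character_))
  }
  Q <- translate_prefix(A)
  if (identical(P, Q)) {
    p <- first_mismatch(R, A)
    cod <- p %/% 3L + 1L
    aa <- substr(P, cod, cod)
    return(list(term = "synonymous", aa_pos = cod, aa_ref = aa, aa_alt = aa,
                codon_ref = substr(R, 3L * cod - 2L, 3L * cod),
                codon_alt = substr(A, 3L * cod - 2L, 3L * cod)))
  }
  i <- first_mismatch(P, Q)
  if (is.na(i)) i <- min(nchar(P), nchar(Q))
  cod <- i + 1L
  aa_r <- substr(P, cod, cod)
  aa_a <- substr(Q, cod, cod)
  term <- if (identical(aa_a, "*")) "stop_gained" else "missense"
  list(term = term, aa_pos = cod, aa_ref = aa_r, aa_alt = aa_a,
       codon_ref = if (net == 0L) substr(R, 3L * cod - 2L, 3L * cod) else
         NA_character_,
       codon_alt = if (net == 0L) substr(A, 3L * cod - 2L, 3L * cod) else
         NA_character_)
}

# Apply a VCF-style edit to the spliced CDS using offset arithmetic.
edit_spliced_cds <- function(model, R, pos, ref, alt) {
  nr <- nchar(ref); na <- nchar(alt)
  if (nr == na) {
    gpos <- pos + seq_len(nr) - 1L
    offs <- genomic_to_cds(model, gpos)
    alt_bases <- strsplit(alt, "")[[1]]
    if (model$strand == "-") alt_bases <- dna_complement(alt_bases)
    chars <- strsplit(R, "")[[1]]
    keep <- !is.na(offs)
    chars[offs[keep] + 1L] <- alt_bases[keep]
    return(paste(chars, collapse = ""))
  }
  if (nr > na) {  # anchored deletion
    del <- pos + na + seq_len(nr - na) - 1L
    offs <- genomic_to_cds(model, del)
    offs <- offs[!is.na(offs)]
    if (!length(offs)) return(R)
    chars <- strsplit(R, "")[[1]]
    return(paste(chars[-(offs + 1L)], collapse = ""))
  }
  # anchored insertion between genomic g and g+1
  g <- pos + nr - 1L
  ins <- substr(alt, nr + 1L, na)
  off_g <- genomic_to_cds(model, g)
  off_g1 <- genomic_to_cds(model, g + 1L)
  if (is.na(off_g) || is.na(off_g1)) return(R)   # outside / at exon edge
  if (model$strand == "+") {
    k <- off_g + 1L
    cdna <- ins
  } else {
    k <- off_g1 + 1L
    cdna <- dna_revcomp(ins)
  }
  paste0(substr(R, 1L, k), cdna, substr(R, k + 1L, nchar(R)))
}

empty_annotation <- function(variants) {
  bind_cols(variants, tibble(
    terms = list(), consequence = character(), aa_pos = integer(),
    aa_ref = character(), aa_alt = character(), codon_ref = character(),
    codon_alt = character(), protein_change = character()))
}

consequence_row <- function(terms, cc = NULL) {
  label <- terms_to_string(terms)
  tibble(
    terms = list(terms),
    consequence = label,
    aa_pos = if (is.null(cc)) NA_integer_ else as.integer(cc$aa_pos),
    aa_ref = if (is.null(cc)) NA_character_ else cc$aa_ref,
    aa_alt = if (is.null(cc)) NA_character_ else cc$aa_alt,
    codon_ref = if (is.null(cc)) NA_character_ else cc$codon_ref,
    codon_alt = if (is.null(cc)) NA_character_ else cc$codon_alt
  )
}

#' Annotate variant consequences against a gene model
#'
#' Classifies each variant by codon arithmetic on the spliced CDS: coding
#' SNVs become `synonymous`, `missense` or `stop_gained` by comparing the
#' reference and alternate codons (strand-adjusted); length-changing coding
#' variants whose net length difference is not a multiple of 3 become
#' `frameshift`, labeled at the first codon whose spliced-CDS base differs.
#' Positions inside splice windows add `splice_donor`, `splice_acceptor` or
#' `splice_region`; intronic positions outside any window are `intron`;
#' positions outside the gene span are `intergenic`.  Protein-level changes
#' use three-letter residue codes with the initiator Met as residue 1.
#'
#' @param variants Tibble with columns `pos`, `ref`, `alt` and optionally
#'   `variant_id`.  Reference alleles are verified against the contig; a
#'   mismatch aborts.
#' @param model A [gene_model()].
#' @param reference A [reference_contig()].
#' @param windows Splice-window table, by default [splice_windows()] of the
#'   model.
#' @returns The input tibble plus columns `terms` (list of term sets),
#'   `consequence` (canonical `&`-joined string), `aa_pos`, `aa_ref`,
#'   `aa_alt`, `codon_ref`, `codon_alt` and `protein_change`.
#' @examples
#' fx <- hbb_fixture(seed = 1)
#' ann <- annotate_variants(fx$variants, fx$model, fx$reference)
#' ann[ann$variant_id == "rs334", c("consequence", "protein_change")]
#' @export
annotate_variants <- function(variants, model, reference,
                              windows = splice_windows(model)) {
  variants <- as_tibble(variants)
  if (!"variant_id" %in% names(variants)) {
    variants$variant_id <- sprintf("var%03d", seq_len(nrow(variants)))
  }
  if (nrow(variants) == 0L) return(empty_annotation(variants))
  R <- spliced_cds(model, reference)
  span <- c(min(model$exons$start), max(model$exons$end))
  rows <- map(seq_len(nrow(variants)), function(k) {
    pos <- variants$pos[k]; ref <- variants$ref[k]; alt <- variants$alt[k]
    obs <- contig_slice(reference, pos, pos + nchar(ref) - 1L)
    if (!identical(obs, ref)) {
      abort(sprintf(
        "REF mismatch for %s at %d: VCF says %s, contig has %s",
        variants$variant_id[k], pos, ref, obs))
    }
    touched <- touched_positions(pos, ref, alt)
    offs <- genomic_to_cds(model, touched)
    splice_terms <- unique(windows$label[windows$pos %in% touched])
    if (any(!is.na(offs))) {
      A <- edit_spliced_cds(model, R, pos, ref, alt)
      cc <- classify_coding(R, A)
      consequence_row(c(splice_terms, cc$term), cc)
    } else if (any(touched >= span[1] & touched <= span[2])) {
      consequence_row(unique(c(splice_terms, "intron")))
    } else {
      consequence_row("intergenic")
    }
  })
  out <- bind_cols(variants, list_rbind(rows))
  out$protein_change <- ifelse(
    is.na(out$aa_pos), NA_character_,
    render_protein_change(out$aa_ref, out$aa_pos, out$aa_alt, "paper"))
  out
}

#' Classify variants by whole-contig mutation and re-translation
#'
#' Brute-force oracle for [annotate_variants()]: applies the edit to the full
#' contig sequence, shifts the exon coordinates accordingly, re-splices and
#' re-translates, and derives the consequence from the whole-protein diff.
#' It never uses the CDS offset arithmetic ([genomic_to_cds()] /
#' [cds_to_genomic()]) that the annotator relies on.
#'
#' @inheritParams annotate_variants
#' @returns Same shape as [annotate_variants()].
#' @export
classify_by_full_translation <- function(variants, model, reference,
                                         windows = splice_windows(model)) {
  variants <- as_tibble(variants)
  if (!"variant_id" %in% names(variants)) {
    variants$variant_id <- sprintf("var%03d", seq_len(nrow(variants)))
  }
  if (nrow(variants) == 0L) return(empty_annotation(variants))
  span <- c(min(model$exons$start), max(model$exons$end))
  R <- spliced_cds(model, reference)
  rows <- map(seq_len(nrow(variants)), function(k) {
    pos <- variants$pos[k]; ref <- variants$ref[k]; alt <- variants$alt[k]
    obs <- contig_slice(reference, pos, pos + nchar(ref) - 1L)
    if (!identical(obs, ref)) {
      abort(sprintf("REF mismatch at %d: VCF says %s, contig has %s",
                    pos, ref, obs))
    }
    touched <- touched_positions(pos, ref, alt)
    in_exon <- map_lgl(touched, function(g) {
      any(g >= model$exons$start & g <= model$exons$end)
    })
    splice_terms <- unique(windows$label[windows$pos %in% touched])
    if (any(in_exon)) {
      # mutate the whole contig
      lo <- pos - reference$offset + 1L
      seq2 <- paste0(substr(reference$sequence, 1L, lo - 1L), alt,
                     substr(reference$sequence, lo + nchar(ref),
                            nchar(reference$sequence)))
      ref2 <- reference_contig(reference$name, seq2, reference$offset)
      # coordinate shift under the edit: positions beyond a deleted run move
      # left by its length (a start boundary inside the run snaps to the
      # first surviving base, an end boundary to the last base before the
      # run); positions beyond an insertion anchor move right
      net <- nchar(alt) - nchar(ref)
      k <- abs(net)
      del_lo <- pos + nchar(alt)
      del_hi <- pos + nchar(ref) - 1L
      map_start <- function(b) {
        if (net < 0L) {
          if (b > del_hi) b - k else if (b >= del_lo) del_lo else b
        } else if (net > 0L && b > pos + nchar(ref) - 1L) b + k else b
      }
      map_end <- function(b) {
        if (net < 0L) {
          if (b > del_hi) b - k else if (b >= del_lo) del_lo - 1L else b
        } else if (net > 0L && b > pos + nchar(ref) - 1L) b + k else b
      }
      ex2 <- tibble(start = map_int(model$exons$start, map_start),
                    end = map_int(model$exons$end, map_end))
      ex2 <- filter(ex2, .data$end >= .data$start)
      # bypass the constructor: a frameshift edit legitimately yields a
      # mutated CDS whose length is not a multiple of 3
      model2 <- structure(
        list(contig = model$contig, strand = model$strand, exons = ex2,
             gene_name = model$gene_name),
        class = "gene_model")
      A <- spliced_cds(model2, ref2)
      cc <- classify_coding(R, A)
      consequence_row(c(splice_terms, cc$term), cc)
    } else if (any(touched >= span[1] & touched <= span[2])) {
      consequence_row(unique(c(splice_terms, "intron")))
    } else {
      consequence_row("intergenic")
    }
  })
  out <- bind_cols(variants, list_rbind(rows))
  out$protein_change <- ifelse(
    is.na(out$aa_pos), NA_character_,
    render_protein_change(out$aa_ref, out$aa_pos, out$aa_alt, "paper"))
  out
}

render_protein_change <- function(aa_ref, aa_pos, aa_alt, style) {
  ref3 <- aa_three(aa_ref)
  dplyr::case_when(
    aa_alt == "fs" ~ paste0(ref3, aa_pos, "fs"),
    aa_alt == "*" & style == "paper" ~ paste0(ref3, aa_pos),
    aa_alt == "*" ~ paste0(ref3, aa_pos, "Ter"),
    TRUE ~ paste0(ref3, aa_pos, aa_three(aa_alt))
  )
}

#' Format protein-level changes
#'
#' Renders the protein change of annotated coding variants.  `"paper"` style
#' writes three-letter codes with Met = 1 numbering, stop-gains as residue +
#' index with no suffix (`"Gln40"`) and frameshifts as residue + index +
#' `"fs"` (`"Phe42fs"`); `"hgvs"` style appends `"Ter"` to stop-gains.
#'
#' @param annotations Output of [annotate_variants()] (rows must carry a
#'   protein change; an annotation without one aborts).
#' @param style `"paper"` or `"hgvs"`.
#' @returns Character vector, one formatted change per row.
#' @export
format_protein_change <- function(annotations, style = c("paper", "hgvs")) {
  style <- match.arg(style)
  if (any(is.na(annotations$aa_pos))) {
    abort("annotation without a protein-level change")
  }
  render_protein_change(annotations$aa_ref, annotations$aa_pos,
                        annotations$aa_alt, style)
}

#' Mirror a gene system onto the opposite strand
#'
#' Builds the reverse-complemented contig and the mirror-image gene model and
#' variant table, preserving anchored-deletion VCF conventions.  Used to
#' check strand invariance: every consequence must be unchanged under the
#' mirror.
#'
#' @param model A `gene_model`.
#' @param reference A `reference_contig`.
#' @param variants Variant tibble (`pos`, `ref`, `alt`, ...); substitutions
#'   and anchored deletions are supported.
#' @returns List with mirrored `model`, `reference`, `variants`.
#' @export
mirror_gene_system <- function(model, reference, variants) {
  L <- nchar(reference$sequence)
  o <- reference$offset
  m <- function(g) 2L * o + L - 1L - g
  ref2 <- reference_contig(reference$name, dna_revcomp(reference$sequence), o)
  model2 <- gene_model(
    model$contig, if (model$strand == "+") "-" else "+",
    tibble(start = m(model$exons$end), end = m(model$exons$start)),
    model$gene_name
  )
  v <- as_tibble(variants)
  mirrored <- map(seq_len(nrow(v)), function(k) {
    pos <- v$pos[k]; ref <- v$ref[k]; alt <- v$alt[k]
    nr <- nchar(ref); na <- nchar(alt)
    if (nr == na) {
      tibble(pos = m(pos + nr - 1L), ref = dna_revcomp(ref),
             alt = dna_revcomp(alt))
    } else if (nr > na) {
      a2 <- m(pos + nr - 1L) - 1L   # base preceding the mirrored deleted run
      ref2_allele <- contig_slice(ref2, a2, a2 + nr - 1L)
      tibble(pos = a2, ref = ref2_allele,
             alt = substr(ref2_allele, 1L, na))
    } else {
      abort("mirroring insertions is not supported")
    }
  }) |> list_rbind()
  v$pos <- mirrored$pos; v$ref <- mirrored$ref; v$alt <- mirrored$alt
  list(model = model2, reference = ref2, variants = v)
}
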