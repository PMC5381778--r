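#' Construct a single-transcript protein-coding gene model
#'
#' A gene model holds the coding exon structure of one transcript on a named
#' contig, on either strand.  Coordinates are 1-based inclusive genomic
#' positions (VCF/GFF3 convention); offsets along the spliced CDS are 0-based
#' in transcript orientation (for a minus-strand gene, transcript order runs
#' from the highest genomic coordinate downwards).
#'
#' @param contig Contig (chromosome) name.
#' @param strand `"+"` or `"-"`.
#' @param exons Data frame with columns `start`, `end`: coding-exon intervals,
#'   1-based inclusive, non-overlapping, separated by at least one intronic
#'   base.  They are stored sorted by genomic coordinate.
#' @param gene_name Gene symbol, e.g. `"HBB"`.
#' @returns An object of class `gene_model`.
#' @examples
#' gm <- gene_model("chrT", "+", tibble::tibble(start = 11, end = 19),
#'                  gene_name = "TOY")
#' cds_length(gm)
#' @export
gene_model <- function(contig, strand, exons, gene_name = "gene") {
  strand <- match.arg(strand, c("+", "-"))
  exons <- as_tibble(exons)[, c("start", "end")]
  exons <- arrange(exons, .data$start)
  if (any(exons$end < exons$start)) {
    abort("exon end precedes start")
  }
  if (nrow(exons) > 1L) {
    gap <- exons$start[-1L] - exons$end[-nrow(exons)]
    if (any(gap < 2L)) {
      abort("exons must be non-overlapping and separated by >= 1 intronic base")
    }
  }
  len <- sum(exons$end - exons$start + 1)
  if (len %% 3L != 0L || len < 6L) {
    abort("total CDS length must be a multiple of 3 and >= 6")
  }
  structure(
    list(contig = contig, strand = strand, exons = exons,
         gene_name = gene_name),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s on %s(%s), %d coding exon(s), CDS %d nt\n",
              x$gene_name, x$contig, x$strand, nrow(x$exons), cds_length(x)))
  print(x$exons)
  invisible(x)
}

#' Total spliced CDS length of a gene model
#' @param model A `gene_model`.
#' @returns Integer number of coding bases.
#' @export
cds_length <- function(model) {
  as.integer(sum(model$exons$end - model$exons$start + 1))
}

# Exons in transcript orientation with the cumulative 0-based CDS offset at
# which each begins.
exon_frames <- function(model) {
  ex <- model$exons
  if (model$strand == "-") ex <- ex[rev(seq_len(nrow(ex))), ]
  len <- ex$end - ex$start + 1L
  ex$offset0 <- cumsum(c(0L, len))[seq_len(nrow(ex))]
  ex$length <- as.integer(len)
  ex
}

#' Map genomic positions to spliced-CDS offsets
#'
#' @param model A `gene_model`.
#' @param pos Integer vector of 1-based genomic positions.
#' @returns Integer vector of 0-based offsets along the spliced CDS in
#'   transcript orientation; `NA` for intronic or intergenic positions.
#' @examples
#' gm <- gene_model("c", "-", tibble::tibble(start = c(1, 13), end = c(6, 21)))
#' genomic_to_cds(gm, 21)   # first transcribed base -> 0
#' @export
genomic_to_cds <- function(model, pos) {
  ex <- exon_frames(model)
  out <- rep(NA_integer_, length(pos))
  for (j in seq_len(nrow(ex))) {
    hit <- !is.na(pos) & pos >= ex$start[j] & pos <= ex$end[j]
    if (!any(hit)) next
    out[hit] <- if (model$strand == "+") {
      ex$offset0[j] + (pos[hit] - ex$start[j])
    } else {
      ex$offset0[j] + (ex$end[j] - pos[hit])
    }
  }
  as.integer(out)
}

#' Map spliced-CDS offsets back to genomic positions
#'
#' Inverse of [genomic_to_cds()]; the round trip is the identity on the CDS.
#'
#' @param model A `gene_model`.
#' @param offset Integer vector of 0-based CDS offsets.
#' @returns Integer vector of 1-based genomic positions.
#' @export
cds_to_genomic <- function(model, offset) {
  len <- cds_length(model)
  if (any(is.na(offset)) || any(offset < 0L) || any(offset >= len)) {
    abort(sprintf("CDS offset out of range [0, %d)", len))
  }
  ex <- exon_frames(model)
  out <- rep(NA_integer_, length(offset))
  for (j in seq_len(nrow(ex))) {
    hit <- offset >= ex$offset0[j] & offset < ex$offset0[j] + ex$length[j]
    if (!any(hit)) next
    out[hit] <- if (model$strand == "+") {
      ex$start[j] + (offset[hit] - ex$offset0[j])
    } else {
      ex$end[j] - (offset[hit] - ex$offset0[j])
    }
  }
  as.integer(out)
}

#' Reference contig backed by a plain DNA string
#'
#' A windowed slice of a chromosome: `offset` is the genomic coordinate of the
#' first stored base, so Table-style absolute coordinates can be used without
#' materializing a whole chromosome.
#'
#' @param name Contig name (the VCF `CHROM` value).
#' @param sequence DNA string over `{A,C,G,T}`.
#' @param offset Genomic coordinate of the first base of `sequence`
#'   (default 1).
#' @returns An object of class `reference_contig`.
#' @export
reference_contig <- function(name, sequence, offset = 1L) {
  assert_dna(sequence, "reference contig")
  structure(
    list(name = name, sequence = sequence, offset = as.integer(offset)),
    class = "reference_contig"
  )
}

#' @export
print.reference_contig <- function(x, ...) {
  cat(sprintf("<reference_contig> %s: %d bp starting at genomic position %d\n",
              x$name, nchar(x$sequence), x$offset))
  invisible(x)
}

#' Extract contig bases by genomic coordinates
#' @param ref A `reference_contig`.
#' @param start,end 1-based inclusive genomic positions.
#' @returns Character scalar of bases.
#' @export
contig_slice <- function(ref, start, end) {
  lo <- start - ref$offset + 1L
  hi <- end - ref$offset + 1L
  if (lo < 1L || hi > nchar(ref$sequence) || hi < lo) {
    abort("requested slice outside contig bounds")
  }
  substr(ref$sequence, lo, hi)
}

#' Spliced coding sequence of a gene model
#'
#' Concatenates the coding exons in transcript orientation;
#' reverse-complemented for minus-strand genes.
#'
#' @param model A `gene_model`.
#' @param ref A `reference_contig` covering the gene.
#' @returns DNA string of length [cds_length()].
#' @export
spliced_cds <- function(model, ref) {
  ex <- model$exons
  pieces <- map_chr(seq_len(nrow(ex)),
                    function(j) contig_slice(ref, ex$start[j], ex$end[j]))
  plus <- paste(pieces, collapse = "")
  if (model$strand == "+") plus else dna_revcomp(plus)
}

#' Translate a coding sequence with the standard genetic code
#'
#' @param cds DNA string whose length is a multiple of 3.
#' @returns One-letter protein string; the terminator is rendered as `"*"`.
#' @examples
#' translate_cds("ATGGAGTAA")  # "ME*"
#' @export
translate_cds <- function(cds) {
  if (nchar(cds) %% 3L != 0L) {
    abort("CDS length is not a multiple of 3")
  }
  translate_prefix(cds)
}

# Translation that tolerates a trailing partial codon (dropped), used when
# comparing frameshifted alternates.
translate_prefix <- function(cds) {
  n <- nchar(cds) %/% 3L
  if (n == 0L) return("")
  starts <- 3L * (seq_len(n) - 1L) + 1L
  codons <- substring(cds, starts, starts + 2L)
  paste(unname(Biostrings::GENETIC_CODE[codons]), collapse = "")
}

# Three-letter residue name; "*" renders as "Ter".
aa_three <- function(aa) {
  ifelse(aa == "*", "Ter", unname(Biostrings::AMINO_ACID_CODE[aa]))
}

#' Classify splice-window positions of a gene model
#'
#' Positions flanking each exon/intron junction are labeled in transcript
#' orientation: `splice_donor` (intronic bases 1-2 downstream of an exon),
#' `splice_acceptor` (last 2 intronic bases upstream of an exon) and
#' `splice_region` (exonic bases 1-3, or intronic bases 3-8, from a
#' junction).  Window sizes follow the usual annotation-tool convention and
#' are configurable.
#'
#' @param model A `gene_model`.
#' @param donor,acceptor Number of intronic bases in the donor/acceptor core
#'   (default 2 each).
#' @param region_exon Number of junction-proximal exonic bases labeled
#'   `splice_region` (default 3).
#' @param region_intron Length-2 integer vector: inclusive intronic distance
#'   range labeled `splice_region` (default `c(3, 8)`).
#' @returns Tibble with columns `pos` (genomic position) and `label`.
#' @export
splice_windows <- function(model, donor = 2L, acceptor = 2L,
                           region_exon = 3L, region_intron = c(3L, 8L)) {
  ex <- exon_frames(model)
  n <- nrow(ex)
  rows <- list()
  add <- function(pos, label) {
    rows[[length(rows) + 1L]] <<- tibble(pos = as.integer(pos), label = label)
  }
  # direction of transcription in genomic coordinates
  step <- if (model$strand == "+") 1L else -1L
  for (j in seq_len(n)) {
    tx_end <- if (model$strand == "+") ex$end[j] else ex$start[j]    # donor side
    tx_start <- if (model$strand == "+") ex$start[j] else ex$end[j]  # acceptor side
    if (j < n) {  # junction to the following intron: donor
      if (donor > 0) add(tx_end + step * seq_len(donor), "splice_donor")
      add(tx_end + step * seq(region_intron[1], region_intron[2]),
          "splice_region")
      if (region_exon > 0) {
        add(tx_end - step * (seq_len(region_exon) - 1L), "splice_region")
      }
    }
    if (j > 1L) {  # junction to the preceding intron: acceptor
      if (acceptor > 0) add(tx_start - step * seq_len(acceptor),
                            "splice_acceptor")
      add(tx_start - step * seq(region_intron[1], region_intron[2]),
          "splice_region")
      if (region_exon > 0) {
        add(tx_start + step * (seq_len(region_exon) - 1L), "splice_region")
      }
    }
  }
  if (!length(rows)) {
    return(tibble(pos = integer(), label = character()))
  }
  distinct(list_rbind(rows))
}

# ---- standard-format I/O ----------------------------------------------------

#' Write a reference contig as FASTA
#'
#' The genomic offset of the windowed slice is serialized in the description
#' (`offset=N`) so absolute coordinates survive the round trip.
#'
#' @param ref A `reference_contig`.
#' @param path Output file.
#' @returns `path`, invisibly.
#' @export
write_reference <- function(ref, path) {
  x <- Biostrings::DNAStringSet(ref$sequence)
  names(x) <- sprintf("%s offset=%d", ref$name, ref$offset)
  Biostrings::writeXStringSet(x, path, width = 70L)
  invisible(path)
}

#' Read a reference contig from FASTA
#' @param path FASTA file written by [write_reference()] (an `offset=N` token
#'   in the description is honored; absent, the offset is 1).
#' @returns A `reference_contig`.
#' @export
read_reference <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) != 1L) abort("expected a single-sequence FASTA")
  header <- names(x)[1]
  name <- strsplit(header, "\\s+")[[1]][1]
  off <- stringr::str_match(header, "offset=(\\d+)")[, 2]
  reference_contig(name, as.character(x[[1]]),
                   offset = if (is.na(off)) 1L else as.integer(off))
}

#' Write a gene model as GFF3
#'
#' Emits gene, mRNA, exon and CDS features (one transcript; exons equal the
#' CDS intervals) with correct CDS phases.
#'
#' @param model A `gene_model`.
#' @param path Output file.
#' @returns `path`, invisibly.
#' @export
write_gene_model <- function(model, path) {
  ex <- model$exons
  span <- c(min(ex$start), max(ex$end))
  gid <- sprintf("gene:%s", model$gene_name)
  tid <- sprintf("transcript:%s", model$gene_name)
  fr <- exon_frames(model)
  phase <- (3L - fr$offset0 %% 3L) %% 3L      # in transcript order
  fr$phase <- phase
  fr <- arrange(fr, .data$start)              # back to genomic order for output
  lines <- c(
    "##gff-version 3",
    sprintf("%s\thbbcohort\tgene\t%d\t%d\t.\t%s\t.\tID=%s;Name=%s",
            model$contig, span[1], span[2], model$strand, gid,
            model$gene_name),
    sprintf("%s\thbbcohort\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
            model$contig, span[1], span[2], model$strand, tid, gid),
    sprintf("%s\thbbcohort\texon\t%d\t%d\t.\t%s\t.\tParent=%s",
            model$contig, fr$start, fr$end, model$strand, tid),
    sprintf("%s\thbbcohort\tCDS\t%d\t%d\t.\t%s\t%d\tID=cds:%s;Parent=%s",
            model$contig, fr$start, fr$end, model$strand, fr$phase,
            model$gene_name, tid)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene model from GFF3
#'
#' Builds the model from the CDS features of the (single) transcript.
#'
#' @param path GFF3 file.
#' @returns A `gene_model`.
#' @export
read_gene_model <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  cds <- gr[gr$type == "CDS"]
  if (length(cds) == 0L) abort("GFF3 contains no CDS features")
  gene <- gr[gr$type == "gene"]
  name <- if (length(gene) && !is.null(gene$Name)) gene$Name[1] else "gene"
  gene_model(
    contig = as.character(GenomicRanges::seqnames(cds))[1],
    strand = as.character(BiocGenerics::strand(cds))[1],
    exons = tibble(start = GenomicRanges::start(cds),
                   end = GenomicRanges::end(cds)),
    gene_name = name
  )
}
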