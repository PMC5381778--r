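#' The packaged HBB study fixture
#'
#' These functions reconstruct, exactly and in code, the study conditions of a
#' published survey of *HBB* coding variation in the 2,504-sample, five
#' super-population 1000 Genomes phase-3 cohort: 20 heterozygous variants
#' carried by 209 distinct individuals, with categorical pathogenicity labels
#' from three clinical databases and five in-silico predictors.
#'
#' The gene geometry is an HBB-like minus-strand model on chromosome 11
#' (HG19-scale coordinates): three coding exons of 92/223/126 nt (441 nt CDS,
#' 146 residues plus terminator; initiator Met counted as residue 1), introns
#' of 130 and 850 nt.  Exon boundaries are placed so that every published
#' splice-window classification (donor at 5248159, acceptor at 5248030,
#' splice-region at 5248162 and 5248029) is derivable from the model.
#'
#' @returns `hbb_gene_model()`: a [gene_model()].
#' @name hbb_fixture_tables
NULL

# Genomic window held by the fixture reference contig.
HBB_WINDOW <- c(5246001L, 5249000L)

#' @rdname hbb_fixture_tables
#' @export
hbb_gene_model <- function() {
  gene_model(
    contig = "chr11",
    strand = "-",
    exons = tibble(start = c(5246831L, 5247807L, 5248160L),
                   end   = c(5246956L, 5248029L, 5248251L)),
    gene_name = "HBB"
  )
}

#' @rdname hbb_fixture_tables
#' @returns `hbb_population_sizes()`: named integer vector of diploid sample
#'   counts per super-population (AFR, AMR, EAS, EUR, SAS), summing to 2,504.
#' @export
hbb_population_sizes <- function() {
  c(AFR = 661L, AMR = 347L, EAS = 504L, EUR = 503L, SAS = 489L)
}

#' @rdname hbb_fixture_tables
#' @returns `hbb_variants()`: tibble of the 20 fixture variants with genomic
#'   position, alleles, per-population heterozygous-carrier counts, and the
#'   published amino-acid and consequence labels (kept as metadata columns
#'   `paper_aa`, `paper_type`; the reference codon 30 is Gly, so rs35578002 is
#'   synonymous as its published consequence class states, even though its
#'   published amino-acid string reads "Glu30Gly").
#' @export
hbb_variants <- function() {
  tibble::tribble(
    ~variant_id,    ~pos,     ~ref,    ~alt, ~AFR, ~AMR, ~EAS, ~EUR, ~SAS, ~paper_aa,   ~paper_type,
    "rs36020563",   5246840L, "G",     "A",    1L,   0L,   0L,   0L,   0L, "His144His", "Synonymous",
    "rs113082294",  5246870L, "C",     "G",    0L,   2L,   0L,   7L,   0L, "Val134Val", "Synonymous",
    "rs111645889",  5246883L, "G",     "A",    1L,   0L,   0L,   0L,   0L, "Ala130Val", "Missense",
    "rs33971634",   5246890L, "G",     "A",    0L,   1L,   0L,   0L,   0L, "Gln128",    "Stop gained",
    "rs33946267",   5246908L, "C",     "G",    0L,   0L,   0L,   0L,   3L, "Glu122Gln", "Missense",
    "rs33958637",   5246947L, "T",     "G",    0L,   0L,   1L,   0L,   0L, "Asn109His", "Missense",
    "rs193922562",  5246948L, "G",     "A",    1L,   0L,   0L,   0L,   0L, "Gly108Gly", "Synonymous",
    "rs145669504",  5247876L, "G",     "T",    0L,   0L,   5L,   0L,   0L, "Leu82Leu",  "Synonymous",
    "rs281864900",  5247992L, "CAAAG", "C",    0L,   0L,   5L,   0L,   0L, "Phe42fs",   "Frameshift",
    "rs11549407",   5248004L, "G",     "A",    0L,   1L,   0L,   0L,   0L, "Gln40",     "Stop gained",
    "rs1135071",    5248029L, "C",     "A",    0L,   0L,   0L,   1L,   0L, "Arg31Ser",  "Splice region and missense",
    "rs33943001",   5248030L, "C",     "G",    0L,   0L,   0L,   0L,   1L, NA,          "Splice acceptor and intron variant",
    "rs33971440",   5248159L, "C",     "T",    0L,   1L,   0L,   0L,   0L, NA,          "Splice donor and intron variant",
    "rs35578002",   5248162L, "G",     "T",    1L,   0L,   0L,   0L,   0L, "Glu30Gly",  "Splice region and synonymous variant",
    "rs33950507",   5248173L, "C",     "T",    0L,   0L,   8L,   0L,   6L, "Glu27Lys",  "Missense",
    "rs33986703",   5248200L, "T",     "A",    0L,   0L,   6L,   0L,   0L, "Lys18",     "Stop gained",
    "rs63750783",   5248205L, "C",     "T",    0L,   0L,   0L,   0L,   2L, "Trp16",     "Stop gained",
    "rs334",        5248232L, "T",     "A",  132L,   5L,   0L,   0L,   0L, "Glu7Val",   "Missense",
    "rs33930165",   5248233L, "C",     "T",   17L,   0L,   0L,   0L,   0L, "Glu7Lys",   "Missense",
    "rs33912272",   5248236L, "G",     "A",    0L,   0L,   0L,   1L,   0L, "Pro6Ser",   "Missense"
  )
}

#' @rdname hbb_fixture_tables
#' @returns `hbb_carrier_counts()`: long tibble (`variant_id`, `population`,
#'   `carriers`) of per-population heterozygous-carrier counts; column sums
#'   give 153/10/25/9/12 carriers over AFR/AMR/EAS/EUR/SAS (209 total).
#' @export
hbb_carrier_counts <- function() {
  hbb_variants() |>
    select("variant_id", "AFR", "AMR", "EAS", "EUR", "SAS") |>
    tidyr::pivot_longer(-"variant_id", names_to = "population",
                        values_to = "carriers")
}

#' @rdname hbb_fixture_tables
#' @returns `hbb_evidence()`: long tibble (`variant_id`, `source`, `label`) of
#'   the published categorical evidence for the 16 variants submitted to
#'   pathogenicity review.  Sources CLINVAR/dbSNP/HbVar form the database
#'   class; POLYPHEN/PROVEAN/SIFT/PANTHER/MUTPRED the predictor class.
#'   Labels: `Damaging`, `Probably damaging`, `Benign`, `Other`,
#'   `not-evaluated`.
#' @export
hbb_evidence <- function() {
  D <- "Damaging"; P <- "Probably damaging"; B <- "Benign"
  O <- "Other";    N <- "not-evaluated"
  rows <- list(
    # variant_id     CLINVAR dbSNP HbVar POLYPHEN PROVEAN SIFT PANTHER MUTPRED
    c("rs111645889", O, O, B,  B, D, D, D, D),
    c("rs33971634",  D, O, D,  N, D, N, N, N),
    c("rs33946267",  D, D, B,  B, B, D, B, D),
    c("rs33958637",  O, N, B,  P, D, D, B, D),
    c("rs281864900", D, D, D,  N, D, N, N, N),
    c("rs11549407",  D, D, D,  N, N, N, N, N),
    c("rs1135071",   D, D, B,  P, D, D, D, D),
    c("rs33943001",  D, D, D,  N, N, N, N, N),
    c("rs33971440",  D, D, D,  N, N, N, N, N),
    c("rs35578002",  N, N, D,  B, B, B, B, B),
    c("rs33950507",  D, D, D,  B, D, D, D, D),
    c("rs33986703",  D, D, D,  N, D, N, N, N),
    c("rs63750783",  D, D, D,  N, D, N, N, N),
    c("rs334",       D, D, D,  B, D, D, N, D),
    c("rs33930165",  D, D, D,  B, D, D, N, D),
    c("rs33912272",  O, O, B,  B, B, B, N, D)
  )
  src <- c("CLINVAR", "dbSNP", "HbVar",
           "POLYPHEN", "PROVEAN", "SIFT", "PANTHER", "MUTPRED")
  map(rows, function(r) {
    tibble(variant_id = r[1], source = src, label = r[-1])
  }) |> list_rbind()
}

#' @rdname hbb_fixture_tables
#' @returns `hbb_overrides()`: tibble (`variant_id`, `verdict`) with the
#'   single documented override: rs33912272 (Pro6Ser) is published as
#'   Conflict although the default class-majority rule resolves it Benign
#'   (all informative labels except one predictor are benign).
#' @export
hbb_overrides <- function() {
  tibble(variant_id = "rs33912272", verdict = "Conflict")
}

#' @rdname hbb_fixture_tables
#' @returns `hbb_codon_constraints()`: named list mapping codon index (Met =
#'   1) to the required one-letter reference residue, pinning every residue
#'   the published variant labels touch.
#' @export
hbb_codon_constraints <- function() {
  list(`6` = "P", `7` = "E", `16` = "W", `18` = "K", `27` = "E",
       `30` = "G", `31` = "R", `40` = "Q", `42` = "F", `82` = "L",
       `108` = "G", `109` = "N", `122` = "E", `128` = "Q", `130` = "A",
       `134` = "V", `144` = "H")
}

#' @rdname hbb_fixture_tables
#' @returns `hbb_base_constraints()`: tibble (`pos`, `base`) of genomic base
#'   pins beyond the variant reference alleles: canonical GT/AG splice
#'   dinucleotides of both introns (strand-adjusted) and the junction-codon
#'   base that fixes codon 31 to AGG (so the published Arg31Ser substitution,
#'   not a synonymous Arg codon, results from the C>A change).
#' @export
hbb_base_constraints <- function() {
  tibble::tribble(
    ~pos,     ~base,
    5248158L, "A",   # intron 1 donor +2 (cDNA T)
    5248031L, "T",   # intron 1 acceptor -2 (cDNA A)
    5247806L, "C",   # intron 2 donor +1 (cDNA G)
    5247805L, "A",   # intron 2 donor +2 (cDNA T)
    5246958L, "T",   # intron 2 acceptor -2 (cDNA A)
    5246957L, "C",   # intron 2 acceptor -1 (cDNA G)
    5248161L, "T",   # codon 31 first base (cDNA A): AGG, not CGG
    5248231L, "C"    # codon 7 third base (cDNA G): the classic GAG Glu codon
  )
}

#' Assemble the complete packaged study fixture
#'
#' Builds every object the pipeline consumes for the packaged cohort: the
#' HBB-like gene model, a seeded reference contig satisfying all codon and
#' base constraints, the 2,504-sample genotype cohort with 209 heterozygous
#' carriers, the evidence table and the verdict override table.
#'
#' Only carrier-to-sample assignment and unconstrained reference bases are
#' random; every published quantity derived downstream is invariant to the
#' seed.
#'
#' @param seed Integer seed driving the reference filler bases and the
#'   carrier-to-sample assignment.
#' @returns List with elements `model`, `reference`, `cohort`, `variants`,
#'   `evidence`, `overrides`.
#' @examples
#' fx <- hbb_fixture(seed = 1)
#' nrow(fx$variants)   # 20
#' @export
hbb_fixture <- function(seed = 1L) {
  model <- hbb_gene_model()
  variants <- hbb_variants()
  reference <- build_reference(
    model,
    variants = variants,
    codon_constraints = hbb_codon_constraints(),
    base_constraints = hbb_base_constraints(),
    window = HBB_WINDOW,
    seed = seed
  )
  spec <- cohort_spec(
    population_sizes = hbb_population_sizes(),
    variants = select(variants, "variant_id", "pos", "ref", "alt"),
    carrier_counts = hbb_carrier_counts()
  )
  cohort <- simulate_cohort(spec, seed = seed)
  list(model = model, reference = reference, cohort = cohort,
       variants = variants, evidence = hbb_evidence(),
       overrides = hbb_overrides())
}
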