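DB_SOURCES <- c("CLINVAR", "dbSNP", "HbVar")
PREDICTOR_SOURCES <- c("POLYPHEN", "PROVEAN", "SIFT", "PANTHER", "MUTPRED")
RAW_LABELS <- c("Damaging", "Probably damaging", "Benign", "Other",
                "not-evaluated")

#' Normalize a raw pathogenicity label
#'
#' Maps the categorical vocabulary used by clinical databases and predictors
#' onto four analysis classes: `Damaging`/`Probably damaging` are
#' `damaging`; `Benign` is `benign`; `Other` is `uninformative` (an entry
#' exists but takes no side); `not-evaluated` is `absent`.
#'
#' @param raw Character vector of raw labels.
#' @returns Character vector over
#'   `{damaging, benign, uninformative, absent}`.
#' @examples
#' normalize_label(c("Probably damaging", "Other"))
#' @export
normalize_label <- function(raw) {
  bad <- setdiff(unique(raw), RAW_LABELS)
  if (length(bad)) {
    abort(sprintf("unknown evidence label(s): %s",
                  paste(bad, collapse = ", ")))
  }
  dplyr::case_match(raw,
    c("Damaging", "Probably damaging") ~ "damaging",
    "Benign" ~ "benign",
    "Other" ~ "uninformative",
    "not-evaluated" ~ "absent"
  )
}

#' Call one evidence class from its normalized labels
#'
#' The default (`"majority"`) rule takes a strict majority among the
#' informative labels (`damaging`/`benign`); a tie, or no informative label,
#' yields `NoCall`.  The stricter `"unanimous"` rule returns `Conflict` as
#' soon as the informative labels mix.
#'
#' @param labels Character vector of normalized labels.
#' @param strategy `"majority"` (default) or `"unanimous"`.
#' @returns One of `"Damaging"`, `"Benign"`, `"NoCall"` (or `"Conflict"`
#'   under `"unanimous"`).
#' @examples
#' class_call(c("damaging", "damaging", "benign"))
#' @export
class_call <- function(labels, strategy = c("majority", "unanimous")) {
  strategy <- match.arg(strategy)
  d <- sum(labels == "damaging")
  b <- sum(labels == "benign")
  if (d + b == 0L) return("NoCall")
  if (strategy == "unanimous" && d > 0L && b > 0L) return("Conflict")
  if (d > b) "Damaging" else if (b > d) "Benign" else "NoCall"
}

#' Consensus verdict for one evidence record
#'
#' Combines the database class call (CLINVAR, dbSNP, HbVar) with the
#' predictor class call (POLYPHEN, PROVEAN, SIFT, PANTHER, MUTPRED): if the
#' calls agree, or exactly one class abstains, the informative call wins;
#' both abstaining gives `NotEvaluated`; disagreement gives `Conflict`.
#'
#' @param evidence Long tibble (`source`, `label`) for a single variant.
#' @param strategy Vote rule passed to [class_call()].
#' @returns One-row tibble: `db_call`, `predictor_call`, `verdict`.
#' @examples
#' ev <- dplyr::filter(hbb_evidence(), variant_id == "rs33950507")
#' consensus_verdict(ev)
#' @export
consensus_verdict <- function(evidence, strategy = "majority") {
  norm <- normalize_label(evidence$label)
  db <- class_call(norm[evidence$source %in% DB_SOURCES], strategy)
  pr <- class_call(norm[evidence$source %in% PREDICTOR_SOURCES], strategy)
  verdict <-
    if (db == "Conflict" || pr == "Conflict") "Conflict"
    else if (db == "NoCall" && pr == "NoCall") "NotEvaluated"
    else if (db == "NoCall") pr
    else if (pr == "NoCall") db
    else if (db == pr) db
    else "Conflict"
  tibble(db_call = db, predictor_call = pr, verdict = verdict)
}

#' Classify pathogenicity for a batch of annotated variants
#'
#' Pure-synonymous variants (term set exactly `{synonymous}`) are excluded
#' from pathogenicity review and marked `NotEvaluated`; every other variant
#' is classified with [consensus_verdict()].  An optional override table
#' replaces computed verdicts for named variants (flagged in `overridden`).
#'
#' @param evidence Long tibble (`variant_id`, `source`, `label`).
#' @param annotations Output of [annotate_variants()] covering every variant
#'   to classify.
#' @param overrides Optional tibble (`variant_id`, `verdict`).
#' @param strategy Vote rule passed to [class_call()].
#' @returns Tibble: `variant_id`, `db_call`, `predictor_call`, `verdict`,
#'   `overridden`, `evaluated`.
#' @examples
#' fx <- hbb_fixture(seed = 1)
#' ann <- annotate_variants(fx$variants, fx$model, fx$reference)
#' verdicts <- classify_pathogenicity(fx$evidence, ann)
#' table(verdicts$verdict)
#' @export
classify_pathogenicity <- function(evidence, annotations, overrides = NULL,
                                   strategy = "majority") {
  annotations <- as_tibble(annotations)
  if (nrow(annotations) == 0L) {
    return(tibble(variant_id = character(), db_call = character(),
                  predictor_call = character(), verdict = character(),
                  overridden = logical(), evaluated = logical()))
  }
  missing_ann <- setdiff(unique(evidence$variant_id),
                         annotations$variant_id)
  if (length(missing_ann)) {
    abort(sprintf("evidence for unannotated variant(s): %s",
                  paste(head(missing_ann, 3), collapse = ", ")))
  }
  pure_syn <- map_lgl(annotations$terms, function(t) {
    identical(sort(t), "synonymous")
  })
  rows <- map(seq_len(nrow(annotations)), function(k) {
    vid <- annotations$variant_id[k]
    if (pure_syn[k]) {
      return(tibble(variant_id = vid, db_call = "NoCall",
                    predictor_call = "NoCall", verdict = "NotEvaluated",
                    overridden = FALSE, evaluated = FALSE))
    }
    ev <- filter(evidence, .data$variant_id == vid)
    v <- if (nrow(ev)) consensus_verdict(ev, strategy) else
      tibble(db_call = "NoCall", predictor_call = "NoCall",
             verdict = "NotEvaluated")
    bind_cols(tibble(variant_id = vid), v,
              tibble(overridden = FALSE, evaluated = TRUE))
  })
  out <- list_rbind(rows)
  if (!is.null(overrides) && nrow(overrides)) {
    hit <- match(out$variant_id, overrides$variant_id)
    use <- !is.na(hit) & out$evaluated
    out$verdict[use] <- overrides$verdict[hit[use]]
    out$overridden[use] <- TRUE
  }
  out
}
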