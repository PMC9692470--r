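#' Load the bundled drug-property and target-specification tables
#'
#' Reads the package's built-in tables of candidate small-molecule
#' compounds per drug target — perturbation-response regulation ability
#' (L1000-style signed score), cell-viability sensitivity (PRISM-style
#' log-fold change) and toxicity (LC50, log(mol/kg)) — together with the
#' target specifications: each biomarker's dysregulation direction (`+`
#' upregulated, `-` downregulated) and its disease context (MIBC:
#' muscle-invasive bladder cancer; ABC: advanced bladder cancer).
#'
#' @return List with `drugs` (drug, target, regulation, sensitivity, lc50)
#'   and `targets` (biomarker, direction, disease).
#' @export
table1_fixture <- function() {
  drugs <- utils::read.delim(
    system.file("extdata", "table1_drug_properties.tsv", package = "gwgenr"),
    stringsAsFactors = FALSE
  )
  targets <- utils::read.delim(
    system.file("extdata", "table1_target_specs.tsv", package = "gwgenr"),
    stringsAsFactors = FALSE
  )
  list(drugs = drugs, targets = targets)
}

#' Filter candidate drugs for one target by the design specifications
#'
#' Keeps the drugs whose regulation ability opposes the biomarker's
#' dysregulation direction (strictly negative regulation for an
#' upregulated target, strictly positive for a downregulated one) and
#' whose sensitivity is close to zero (`|sensitivity| <= s_max`: the cell
#' line tolerates the perturbation). Survivors are ranked by descending
#' LC50 — the higher the LC50, the lower the toxicity.
#'
#' @param drugs Drug-property data.frame (drug, target, regulation,
#'   sensitivity, lc50).
#' @param target A one-row target spec (biomarker, direction) or a list
#'   with those fields.
#' @param s_max Sensitivity bound (default 3).
#' @return Data.frame of passing drugs ranked by descending LC50, with a
#'   `passes` attribute-free structure; zero rows mean the target is
#'   uncoverable under the specification.
#' @export
filter_candidates <- function(drugs, target, s_max = 3) {
  rows <- drugs[drugs$target == target$biomarker, , drop = FALSE]
  if (nrow(rows) == 0) return(rows)
  sign_ok <- if (target$direction == "+") rows$regulation < 0 else rows$regulation > 0
  keep <- sign_ok & abs(rows$sensitivity) <= s_max
  out <- rows[keep, , drop = FALSE]
  out <- out[order(-out$lc50, out$drug), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Build the drug-by-target coverage matrix
#'
#' @param passing Named list (by biomarker) of per-target passing drug
#'   data.frames from [filter_candidates()].
#' @return Logical matrix, drugs x targets; `TRUE` where the drug passed
#'   that target's filter.
#' @export
build_coverage <- function(passing) {
  if (length(passing) == 0) stop_gw("need at least one target")
  drugs <- sort(unique(unlist(lapply(passing, function(df) df$drug))))
  cov <- matrix(FALSE, nrow = length(drugs), ncol = length(passing),
                dimnames = list(drugs, names(passing)))
  for (tg in names(passing)) cov[passing[[tg]]$drug, tg] <- TRUE
  cov
}

# ordered selection criteria for a candidate cover; larger is better on
# every component
combination_score <- function(combo, coverage, drug_props) {
  lc50 <- vapply(combo, function(d) {
    min(drug_props$lc50[drug_props$drug == d])
  }, numeric(1))
  links <- sum(coverage[combo, , drop = FALSE])
  reg_sum <- sum(vapply(colnames(coverage), function(tg) {
    covering <- combo[coverage[combo, tg]]
    if (length(covering) == 0) return(0)
    max(abs(drug_props$regulation[drug_props$drug %in% covering &
                                    drug_props$target == tg]))
  }, numeric(1)))
  c(min_lc50 = min(lc50), links = links, reg_sum = reg_sum)
}

#' Select a minimal multi-target drug combination
#'
#' Enumerates every drug subset up to the smallest size that covers all
#' targets and picks the winner by the ordered criteria: (1) fewest drugs;
#' (2) largest minimum LC50 across the selected drugs (least toxic
#' bottleneck); (3) most drug-target coverage links; (4) largest sum over
#' targets of the best absolute regulation ability among covering selected
#' drugs; (5) lexicographically earliest drug names. The full comparison
#' trace is returned so every tie-break is auditable.
#'
#' @param coverage Logical drug-by-target matrix from [build_coverage()].
#' @param drug_props Drug-property data.frame (for LC50 and regulation).
#' @return An object of class `gw_combination`: `drugs` (selected set),
#'   `coverage` (target -> covering selected drugs), `score`, `trace`
#'   (data.frame of every evaluated cover with its criteria).
#' @export
select_combination <- function(coverage, drug_props) {
  uncoverable <- colnames(coverage)[colSums(coverage) == 0]
  if (length(uncoverable) > 0) {
    stop_gw("target(s) uncoverable under the specification: %s",
            paste(uncoverable, collapse = ", "))
  }
  drugs <- rownames(coverage)
  covers <- list()
  for (size in seq_along(drugs)) {
    combos <- utils::combn(drugs, size, simplify = FALSE)
    covers <- Filter(function(cb) all(colSums(coverage[cb, , drop = FALSE]) > 0),
                     combos)
    if (length(covers) > 0) break
  }
  trace <- do.call(rbind, lapply(covers, function(cb) {
    sc <- combination_score(cb, coverage, drug_props)
    data.frame(combination = paste(cb, collapse = " + "),
               size = length(cb), min_lc50 = sc[["min_lc50"]],
               links = sc[["links"]], reg_sum = sc[["reg_sum"]],
               stringsAsFactors = FALSE)
  }))
  ord <- order(trace$size, -trace$min_lc50, -trace$links, -trace$reg_sum,
               trace$combination)
  trace <- trace[ord, , drop = FALSE]
  rownames(trace) <- NULL
  winner <- covers[[ord[1]]]
  cov_map <- lapply(stats::setNames(colnames(coverage), colnames(coverage)),
                    function(tg) winner[coverage[winner, tg]])
  structure(
    list(drugs = winner, coverage = cov_map,
         score = combination_score(winner, coverage, drug_props),
         trace = trace),
    class = "gw_combination"
  )
}

#' Design a drug combination for one disease context
#'
#' Runs the full specification pipeline: per-target candidate filtering
#' (sign rule and sensitivity bound), coverage construction, and minimal
#' combination selection with the ordered tie-break criteria.
#'
#' @param drugs Drug-property data.frame.
#' @param targets Target-spec data.frame (biomarker, direction, disease).
#' @param disease Disease context label to design for.
#' @param s_max Sensitivity bound (default 3).
#' @return A `gw_combination`, plus elements `passing` (per-target filter
#'   results) and `disease` attached.
#' @export
design_combination <- function(drugs, targets, disease, s_max = 3) {
  spec <- targets[targets$disease == disease, , drop = FALSE]
  if (nrow(spec) == 0) stop_gw("no targets defined for disease '%s'", disease)
  passing <- lapply(seq_len(nrow(spec)), function(i) {
    filter_candidates(drugs, spec[i, ], s_max = s_max)
  })
  names(passing) <- spec$biomarker
  coverage <- build_coverage(passing)
  combo <- select_combination(coverage, drugs)
  combo$passing <- passing
  combo$disease <- disease
  combo
}
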