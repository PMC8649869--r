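#' Per-shRNA depletion scoring
#'
#' For each hairpin, the log2 fold change of mean treated abundance over mean
#' reference abundance on CPM-normalized counts, with a pseudocount:
#' \deqn{\mathrm{lfc}_i = \log_2\frac{\bar{x}^{\mathrm{trt}}_i + \epsilon}
#'   {\bar{x}^{\mathrm{ref}}_i + \epsilon}.}
#' A hairpin is called depleted when `lfc < lfc_threshold` (strict) and its
#' mean reference abundance is at least `abundance_floor`, suppressing
#' low-coverage noise.
#'
#' @param cm A normalized `count_matrix` (see [cpm_normalize()]) whose
#'   features table carries a `gene` column.
#' @param treated_samples,reference_samples Sample ids of the two groups.
#' @param pseudocount Abundance pseudocount epsilon (CPM), default 0.5.
#' @param lfc_threshold Depletion call threshold on log2 fold change
#'   (default -1, i.e. at least two-fold loss).
#' @param abundance_floor Minimum mean reference abundance (CPM, default 5).
#' @return A data.frame of class `shrna_depletion` with columns `shrna_id`,
#'   `gene`, `lfc`, `ref_abundance`, `depleted`.
#' @export
shrna_depletion <- function(cm, treated_samples, reference_samples,
                            pseudocount = 0.5, lfc_threshold = -1,
                            abundance_floor = 5) {
  stopifnot(inherits(cm, "count_matrix"))
  if (!cm$normalized)
    abort_validation("shrna_depletion needs a normalized count matrix")
  if (!length(treated_samples) || !length(reference_samples))
    abort_validation("both sample groups must be non-empty")
  bad <- setdiff(c(treated_samples, reference_samples), colnames(cm$counts))
  if (length(bad))
    abort_validation(sprintf("sample id(s) not in matrix: %s",
                             paste(bad, collapse = ", ")))
  trt <- rowMeans(cm$counts[, treated_samples, drop = FALSE])
  ref <- rowMeans(cm$counts[, reference_samples, drop = FALSE])
  lfc <- log2((trt + pseudocount) / (ref + pseudocount))
  gene <- if (!is.null(cm$features) && "gene" %in% names(cm$features))
    cm$features$gene else NA_character_
  out <- data.frame(shrna_id = rownames(cm$counts), gene = gene,
                    lfc = lfc, ref_abundance = ref,
                    depleted = lfc < lfc_threshold & ref >= abundance_floor,
                    row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("shrna_depletion", "data.frame")
  out
}

#' Subtract acute-arm dropouts from resistant-arm calls
#'
#' Hairpins that also drop out in drug-naive parental cells under acute
#' treatment reflect general drug essentiality, not maintained resistance;
#' their depleted flag is cleared so they never contribute to a candidate
#' tier. Operates at the hairpin level by default; `level = "gene"` clears
#' every hairpin of any gene with at least one acute-depleted hairpin.
#'
#' @param resistant_calls,acute_calls `shrna_depletion` tables over the same
#'   hairpin universe.
#' @param level `"shrna"` (default) or `"gene"`.
#' @return The resistant calls with depleted flags cleared where subtracted;
#'   an added logical column `acute_depleted` records the reason.
#' @export
subtract_acute <- function(resistant_calls, acute_calls,
                           level = c("shrna", "gene")) {
  level <- match.arg(level)
  if (!setequal(resistant_calls$shrna_id, acute_calls$shrna_id))
    abort_validation("resistant and acute calls cover different shRNA universes")
  acute <- acute_calls[match(resistant_calls$shrna_id, acute_calls$shrna_id), ]
  drop <- if (level == "shrna") acute$depleted
          else resistant_calls$gene %in% unique(acute$gene[acute$depleted])
  out <- resistant_calls
  out$acute_depleted <- drop
  out$depleted <- out$depleted & !drop
  out
}

#' Aggregate hairpin calls to gene-level candidate tiers
#'
#' Per gene: the number of hairpins assayed, the number called depleted
#' (after any subtraction), and the median log2 fold change over all the
#' gene's hairpins. Tiers: `stringent` when `n_depleted >= min_stringent`
#' (default 4, i.e. more than three independent hairpins), `candidate` when
#' `n_depleted >= min_candidate` (default 2), else `none`. Stringent genes
#' are by construction a subset of candidate genes.
#'
#' @param calls A `shrna_depletion` table with a `gene` column.
#' @param min_candidate,min_stringent Tier thresholds
#'   (`min_stringent >= min_candidate >= 1`).
#' @return A data.frame of class `gene_depletion_summary` with columns
#'   `gene`, `n_shrnas`, `n_depleted`, `median_lfc`, `tier`.
#' @export
aggregate_genes <- function(calls, min_candidate = 2L, min_stringent = 4L) {
  if (!(min_stringent >= min_candidate && min_candidate >= 1))
    abort_parameter("need min_stringent >= min_candidate >= 1")
  if (!nrow(calls)) {
    out <- data.frame(gene = character(0), n_shrnas = integer(0),
                      n_depleted = integer(0), median_lfc = numeric(0),
                      tier = character(0), stringsAsFactors = FALSE)
    class(out) <- c("gene_depletion_summary", "data.frame")
    return(out)
  }
  genes <- sort(unique(calls$gene))
  n_shrnas <- as.integer(table(calls$gene)[genes])
  n_depleted <- vapply(split(calls$depleted, calls$gene)[genes], sum,
                       integer(1))
  median_lfc <- vapply(split(calls$lfc, calls$gene)[genes], stats::median,
                       numeric(1))
  tier <- ifelse(n_depleted >= min_stringent, "stringent",
                 ifelse(n_depleted >= min_candidate, "candidate", "none"))
  out <- data.frame(gene = genes, n_shrnas = n_shrnas,
                    n_depleted = n_depleted, median_lfc = median_lfc,
                    tier = tier, row.names = NULL, stringsAsFactors = FALSE)
  class(out) <- c("gene_depletion_summary", "data.frame")
  out
}

#' Genes at or above a tier
#'
#' @param summary A `gene_depletion_summary`.
#' @param tier `"candidate"` (includes stringent) or `"stringent"`.
#' @return Character vector of gene symbols.
#' @export
tier_genes <- function(summary, tier = c("candidate", "stringent")) {
  tier <- match.arg(tier)
  keep <- if (tier == "candidate") summary$tier %in% c("candidate", "stringent")
          else summary$tier == "stringent"
  summary$gene[keep]
}
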