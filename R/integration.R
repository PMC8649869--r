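#' Gene-set intersection with provenance
#'
#' All candidate integration in the pipeline reduces to intersections of
#' gene sets whose symbols are upper-cased and whitespace-trimmed first (no
#' alias mapping is attempted). The result carries a `provenance` attribute
#' naming both parents and their sizes.
#'
#' @param a,b Character vectors of gene symbols.
#' @param name_a,name_b Labels recorded in the provenance.
#' @return Character vector (sorted, unique) with attribute `provenance`.
#' @export
intersect_sets <- function(a, b, name_a = "a", name_b = "b") {
  a <- normalize_symbols(a)
  b <- normalize_symbols(b)
  out <- sort(intersect(a, b))
  attr(out, "provenance") <- list(parents = c(name_a, name_b),
                                  sizes = c(length(a), length(b)),
                                  n = length(out))
  out
}

#' Overlay screen candidates with differentially expressed genes
#'
#' The combinatorial step of the discovery pipeline: intersect the
#' selected-tier genes of the dropout screen with the genes differentially
#' regulated during establishment of resistance. By default the DE side is
#' the union of up- and down-regulated sets (direction is a choice of the
#' caller, not of the method).
#'
#' @param screen A `gene_depletion_summary`.
#' @param de_changed Character vector of differentially regulated genes (or
#'   a `list(up=, down=)` as returned by [filter_de()], which is unioned).
#' @param tier `"candidate"` or `"stringent"` screen tier.
#' @return Intersection gene set with provenance.
#' @export
overlay_screen_de <- function(screen, de_changed,
                              tier = c("candidate", "stringent")) {
  tier <- match.arg(tier)
  if (is.list(de_changed)) de_changed <- unique(unlist(de_changed))
  sg <- tier_genes(screen, tier)
  if (!length(sg)) warning("screen input contributes no genes at this tier")
  intersect_sets(sg, de_changed,
                 name_a = sprintf("screen_%s", tier), name_b = "de_changed")
}

#' Downstream-target candidates of a regulator
#'
#' Genes down-regulated upon knockdown of a regulator that are also
#' up-regulated in the resistant state: putative effectors through which the
#' regulator sustains resistance.
#'
#' @param down_on_knockdown,up_in_resistant Character vectors of symbols.
#' @return Intersection gene set with provenance.
#' @export
target_candidates <- function(down_on_knockdown, up_in_resistant) {
  intersect_sets(down_on_knockdown, up_in_resistant,
                 name_a = "down_on_knockdown", name_b = "up_in_resistant")
}

#' Genes co-regulated by two regulators
#'
#' Intersection of the two knockdown-down gene sets (same contrast
#' condition, e.g. under drug treatment).
#'
#' @param down_set_1,down_set_2 Character vectors of symbols.
#' @return Intersection gene set with provenance.
#' @export
coregulated <- function(down_set_1, down_set_2) {
  intersect_sets(down_set_1, down_set_2,
                 name_a = "down_set_1", name_b = "down_set_2")
}

#' Venn region cardinalities for 2 or 3 gene sets
#'
#' Counts every disjoint membership region; region names join the member set
#' names with `&` and prefix exclusive regions with `only:` semantics via
#' the name itself (e.g. `A`, `A&B`, `A&B&C`). Region counts always sum to
#' the cardinality of the union.
#'
#' @param sets Named list of 2 or 3 character vectors.
#' @return Named integer vector of region counts (3 regions for 2 sets,
#'   7 for 3).
#' @export
venn_summary <- function(sets) {
  if (!is.list(sets) || length(sets) < 2 || length(sets) > 3)
    abort_validation("venn_summary supports exactly 2 or 3 sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    abort_validation("sets must be named")
  sets <- lapply(sets, normalize_symbols)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 0)
    member <- matrix(logical(0), 0, length(sets),
                     dimnames = list(NULL, names(sets)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1,
                                              dimnames = list(NULL, names(sets)))
  k <- length(sets)
  patterns <- expand.grid(rep(list(c(TRUE, FALSE)), k))[-2^k, , drop = FALSE]
  names(patterns) <- names(sets)
  counts <- apply(patterns, 1, function(p) {
    sum(apply(member, 1, function(row) all(row == p)))
  })
  labels <- apply(patterns, 1, function(p)
    paste(names(sets)[as.logical(p)], collapse = "&"))
  stats::setNames(as.integer(counts), labels)
}
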