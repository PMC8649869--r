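#' Ground truth for a simulated dropout screen
#'
#' Records, per gene, its role in the simulated selection and, per hairpin,
#' its knockdown efficacy. Roles:
#' \describe{
#'   \item{neutral}{no fitness effect in any arm (selection coefficient 0).}
#'   \item{resistance_driver}{required to maintain drug resistance; its
#'     knockdown depletes under selection in the resistant arm only.}
#'   \item{acute_essential}{required for survival under the drug regardless
#'     of resistance status; depletes in both the resistant and the
#'     parental acute arm.}
#' }
#'
#' @param gene_role Named character vector, gene -> role.
#' @param selection_coeff Named numeric vector, gene -> per-week log2 fitness
#'   effect (<= 0 for non-neutral roles, exactly 0 for neutral genes).
#' @param efficacy Named numeric vector in `[0, 1]`, shRNA id -> knockdown
#'   efficacy (0 = inert hairpin).
#' @return A `screen_truth` object.
#' @export
screen_truth <- function(gene_role, selection_coeff, efficacy) {
  roles <- c("neutral", "resistance_driver", "acute_essential")
  if (!all(gene_role %in% roles))
    abort_validation("gene_role values must be neutral, resistance_driver or acute_essential")
  if (!setequal(names(gene_role), names(selection_coeff)))
    abort_validation("gene_role and selection_coeff must cover the same genes")
  selection_coeff <- selection_coeff[names(gene_role)]
  if (any(selection_coeff[gene_role == "neutral"] != 0))
    abort_validation("neutral genes must have selection_coeff 0")
  if (any(selection_coeff[gene_role != "neutral"] > 0))
    abort_validation("non-neutral selection coefficients must be <= 0")
  if (any(efficacy < 0 | efficacy > 1))
    abort_validation("efficacy must lie in [0, 1]")
  structure(list(gene_role = gene_role,
                 selection_coeff = selection_coeff,
                 efficacy = efficacy),
            class = "screen_truth")
}

#' Draw a random planted truth for a library
#'
#' Assigns `n_drivers` resistance drivers and `n_acute` acute-essential genes
#' at random; every other gene is neutral. Hairpin efficacies follow the
#' library model: a fraction `active_fraction` of each gene's hairpins are
#' active with efficacy drawn from Beta(5, 2); the remainder are inert
#' (efficacy 0), which is what makes multi-hairpin gene filters informative.
#'
#' @param lib A `shrna_library`.
#' @param n_drivers,n_acute Number of planted driver / acute-essential genes.
#' @param driver_s,acute_s Per-week log2 selection coefficients (<= 0).
#' @param active_fraction Fraction of hairpins per gene that are active.
#' @param seed Integer seed.
#' @return A `screen_truth` covering every gene and hairpin of `lib`.
#' @export
random_screen_truth <- function(lib, n_drivers, n_acute,
                                driver_s = -0.75, acute_s = -0.75,
                                active_fraction = 0.8, seed = 1L) {
  stopifnot(inherits(lib, "shrna_library"))
  genes <- unique(lib$gene)
  if (n_drivers + n_acute > length(genes))
    abort_parameter("more planted genes requested than genes in the library")
  with_seed(seed, {
    planted <- sample(genes, n_drivers + n_acute)
    role <- stats::setNames(rep("neutral", length(genes)), genes)
    role[planted[seq_len(n_drivers)]] <- "resistance_driver"
    if (n_acute > 0)
      role[planted[n_drivers + seq_len(n_acute)]] <- "acute_essential"
    s <- stats::setNames(numeric(length(genes)), genes)
    s[role == "resistance_driver"] <- driver_s
    s[role == "acute_essential"] <- acute_s
    eff <- stats::setNames(numeric(nrow(lib)), lib$shrna_id)
    for (g in genes) {
      idx <- which(lib$gene == g)
      k <- stats::rbinom(1, length(idx), active_fraction)
      act <- sample(idx, k)
      eff[act] <- stats::rbeta(k, 5, 2)
    }
    screen_truth(role, s, eff)
  })
}

#' Arm-structured design of a simulated screen
#'
#' Defaults mirror a genome-wide synthetic-lethality screen: a reference
#' (pre-selection) arm, a drug-selected resistant arm cultured for 4 weeks,
#' and a parental arm under acute drug treatment, all sequenced to about two
#' million barcode reads per sample with mild overdispersion.
#'
#' @param arms Character vector of arm names; must include `reference`.
#' @param weeks Named numeric vector, arm -> weeks of selection; the
#'   reference arm must be 0.
#' @param depth Expected reads per sample (> 0).
#' @param dispersion Negative-binomial dispersion phi >= 0
#'   (variance = mu + phi * mu^2).
#' @param replicates Replicates per arm (>= 1).
#' @return A `screen_design` object.
#' @export
screen_design <- function(arms = c("reference", "resistant_selected",
                                   "parental_acute"),
                          weeks = c(reference = 0, resistant_selected = 4,
                                    parental_acute = 4),
                          depth = 2e6, dispersion = 0.05, replicates = 3L) {
  if (!"reference" %in% arms)
    abort_validation("design must include a reference arm")
  if (!setequal(names(weeks), arms))
    abort_validation("weeks must be named by the arms")
  if (weeks[["reference"]] != 0)
    abort_validation("reference arm must have weeks = 0")
  if (depth <= 0) abort_parameter("depth must be > 0")
  if (dispersion < 0) abort_parameter("dispersion must be >= 0")
  if (!is_count(replicates) || replicates < 1)
    abort_parameter("replicates must be a positive integer")
  structure(list(arms = arms, weeks = weeks[arms], depth = depth,
                 dispersion = dispersion, replicates = as.integer(replicates)),
            class = "screen_design")
}

#' Simulate an arm-structured barcode dropout screen
#'
#' Each hairpin starts at a log-normal baseline abundance (sdlog 1,
#' reproducing pooled-library skew). In arm \eqn{a} its relative abundance is
#' \deqn{w_i = b_i \, 2^{\,s_g \cdot e_i \cdot \mathrm{weeks}_a}}
#' where the selection coefficient \eqn{s_g} applies in the resistant arm for
#' resistance drivers, in both resistant and parental-acute arms for
#' acute-essential genes, and nowhere for neutral genes; \eqn{e_i} is the
#' hairpin's knockdown efficacy. Observed counts are negative-binomial with
#' mean `depth` times the arm-wise abundance proportion.
#'
#' @param lib A `shrna_library`.
#' @param truth A `screen_truth` covering every gene and hairpin of `lib`.
#' @param design A `screen_design`.
#' @param seed Integer seed; the output is a pure function of the arguments.
#' @return A raw `count_matrix` with one column per (arm, replicate) and the
#'   library's gene map in `features`.
#' @export
simulate_screen <- function(lib, truth, design = screen_design(), seed = 1L) {
  stopifnot(inherits(lib, "shrna_library"), inherits(truth, "screen_truth"),
            inherits(design, "screen_design"))
  if (!all(lib$gene %in% names(truth$gene_role)))
    abort_validation("truth is missing gene roles for some library genes")
  if (!all(lib$shrna_id %in% names(truth$efficacy)))
    abort_validation("truth is missing efficacies for some hairpins")
  role <- truth$gene_role[lib$gene]
  s <- truth$selection_coeff[lib$gene]
  eff <- truth$efficacy[lib$shrna_id]
  with_seed(seed, {
    baseline <- stats::rlnorm(nrow(lib), meanlog = 0, sdlog = 1)
    cols <- list()
    samp <- list()
    for (arm in design$arms) {
      wk <- design$weeks[[arm]]
      applies <- switch(arm,
        reference = rep(FALSE, nrow(lib)),
        resistant_selected = role != "neutral",
        parental_acute = role == "acute_essential",
        rep(FALSE, nrow(lib)))
      w <- baseline * 2^(ifelse(applies, s * eff * wk, 0))
      mu <- design$depth * w / sum(w)
      for (r in seq_len(design$replicates)) {
        y <- if (design$dispersion <= 0) stats::rpois(length(mu), mu)
             else stats::rnbinom(length(mu), mu = mu,
                                 size = 1 / design$dispersion)
        id <- sprintf("%s_rep%d", arm, r)
        cols[[id]] <- y
        samp[[id]] <- data.frame(sample = id, arm = arm, replicate = r,
                                 stringsAsFactors = FALSE)
      }
    }
    m <- do.call(cbind, cols)
    rownames(m) <- lib$shrna_id
    count_matrix(m,
                 samples = do.call(rbind, samp),
                 features = data.frame(feature_id = lib$shrna_id,
                                       gene = lib$gene,
                                       stringsAsFactors = FALSE))
  })
}

#' Serialize / restore a planted screen truth as JSON
#'
#' Round-trips losslessly so that recovery experiments can be checked against
#' the recorded truth.
#'
#' @param truth A `screen_truth`.
#' @param path JSON file path.
#' @export
write_screen_truth <- function(truth, path) {
  stopifnot(inherits(truth, "screen_truth"))
  jsonlite::write_json(lapply(unclass(truth), as.list), path,
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_screen_truth
#' @export
read_screen_truth <- function(path) {
  x <- jsonlite::read_json(path)
  screen_truth(unlist(x$gene_role), unlist(x$selection_coeff),
               unlist(x$efficacy))
}
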