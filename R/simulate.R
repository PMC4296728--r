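#' Simulation configuration for case-control communities
#'
#' Bundles and validates the parameters of the Dirichlet-multinomial
#' case-control community generator. Defaults emulate a rarefied adult gut
#' 16S survey: fixed sequencing depth of 10,000 reads per sample, a
#' power-law baseline composition (a few dominant taxa, a long rare tail),
#' moderate overdispersion, and case status confounded with age (cases
#' younger, log-odds -0.04 per year, as observed for cesarean birth in
#' adult cohorts).
#'
#' @param n_cases,n_controls group sizes (`n_cases + n_controls >= 4`).
#' @param n_taxa number of OTUs.
#' @param depth reads per sample (rarefaction depth), default 10000.
#' @param effect_taxa_fraction proportion of taxa in `[0,1]` whose Dirichlet
#'   concentrations are shifted in cases.
#' @param effect_size multiplicative fold-change `>= 1` applied to the
#'   Dirichlet concentrations of affected taxa in cases; `1` is the null
#'   (exchangeable groups).
#' @param base_concentration positive scalar or length-`n_taxa` vector of
#'   Dirichlet concentrations. Default `50 * w` with `w` proportional to
#'   `1/rank`: total concentration 50 gives the overdispersion typical of
#'   stool profiles.
#' @param age_effect log-odds of case status per year of age. Implemented
#'   exactly (see Details).
#' @param missing_case_fraction fraction of samples whose case field is
#'   recorded as `"Unknown"` rather than yes/no.
#' @param seed integer RNG seed; fixes every emitted artifact.
#'
#' @details Case status must both hit the exact group sizes and follow a
#' logistic model in age. Both hold exactly under the normal-discriminant
#' duality: ages are drawn `N(46, 16)` for controls and
#' `N(46 + age_effect * 16^2, 16)` for cases, which induces
#' `logit P(case | age) = a + age_effect * age` for some intercept `a`.
#' @return An object of class `"sim_config"` (a validated list).
#' @export
sim_config <- function(n_cases = 50, n_controls = 50, n_taxa = 100,
                       depth = 10000, effect_taxa_fraction = 0.1,
                       effect_size = 1, base_concentration = NULL,
                       age_effect = -0.04, missing_case_fraction = 0,
                       seed = 1) {
  if (depth <= 0) stop("`depth` must be positive")
  if (n_cases + n_controls < 4) stop("need n_cases + n_controls >= 4")
  if (effect_taxa_fraction < 0 || effect_taxa_fraction > 1)
    stop("`effect_taxa_fraction` must lie in [0, 1]")
  if (effect_size < 1) stop("`effect_size` must be >= 1")
  if (is.null(base_concentration)) {
    w <- 1 / seq_len(n_taxa)
    base_concentration <- 50 * w / sum(w)
  } else if (length(base_concentration) == 1L) {
    base_concentration <- rep(base_concentration, n_taxa)
  }
  if (length(base_concentration) != n_taxa || any(base_concentration <= 0))
    stop("`base_concentration` must be positive, scalar or length n_taxa")
  structure(list(n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 n_taxa = as.integer(n_taxa), depth = as.integer(depth),
                 effect_taxa_fraction = effect_taxa_fraction,
                 effect_size = effect_size,
                 base_concentration = base_concentration,
                 age_effect = age_effect,
                 missing_case_fraction = missing_case_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# hierarchical greengenes-style lineages: random paths through a nested
# name tree; ~10% empty genus and ~15% empty species names, as in real
# greengenes assignments
.make_lineages <- function(n_taxa) {
  phyla <- c("Firmicutes", "Bacteroidetes", "Proteobacteria",
             "Actinobacteria", "Verrucomicrobia", "Tenericutes")
  p <- sample(phyla, n_taxa, replace = TRUE,
              prob = c(0.45, 0.3, 0.12, 0.08, 0.03, 0.02))
  cl <- paste0(substr(p, 1, 3), "cls", sample(1:2, n_taxa, TRUE))
  or <- paste0(cl, "ord", sample(1:2, n_taxa, TRUE))
  fa <- paste0(or, "fam", sample(1:2, n_taxa, TRUE))
  ge <- paste0(fa, "gen", sample(1:3, n_taxa, TRUE))
  ge[stats::runif(n_taxa) < 0.10] <- ""
  sp <- paste0("sp", seq_len(n_taxa))
  sp[stats::runif(n_taxa) < 0.15] <- ""
  paste0("k__Bacteria;p__", p, ";c__", cl, ";o__", or, ";f__", fa,
         ";g__", ge, ";s__", sp)
}

.sample_levels <- function(n, levels, counts)
  sample(levels, n, replace = TRUE, prob = counts / sum(counts))

#' Simulate a case-control microbiome dataset
#'
#' Draws a fixed-depth OTU count table from a Dirichlet-multinomial model:
#' each sample's composition is Dirichlet with the baseline concentrations,
#' multiplied by `effect_size` on the affected taxa for cases, then read
#' counts are multinomial at exactly `depth`. Sample metadata mirrors the
#' variables of an adult gut cohort (age, sex, race, BMI, region, diet,
#' alcohol, smoking, antibiotic recency, weight change, gluten/lactose/
#' asthma flags, body site, diabetes and IBD flags, cesarean and
#' appendectomy status), with category frequencies matching a large US
#' volunteer cohort and case status linked to age through a logistic model.
#'
#' @param config a [sim_config()].
#' @return A list with elements `table` (counts-mode [taxon_table()]),
#'   `metadata` (data.frame keyed by `SAMPLE_ID`), `lineages`, and
#'   `affected` (taxon ids of the ground-truth shifted set).
#' @export
simulate_dataset <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_cases + config$n_controls
  K <- config$n_taxa

  lineages <- .make_lineages(K)
  taxon_ids <- sprintf("OTU_%04d", seq_len(K))
  n_aff <- round(config$effect_taxa_fraction * K)
  affected <- sort(sample.int(K, n_aff))

  is_case <- sample(rep(c(TRUE, FALSE), c(config$n_cases, config$n_controls)))
  age_shift <- config$age_effect * 16^2
  age <- round(stats::rnorm(n, 46 + ifelse(is_case, age_shift, 0), 16))
  age <- pmax(age, 18)

  alpha0 <- config$base_concentration
  alpha1 <- alpha0
  alpha1[affected] <- alpha1[affected] * config$effect_size
  counts <- matrix(0L, n, K)
  for (i in seq_len(n)) {
    a <- if (is_case[i]) alpha1 else alpha0
    g <- stats::rgamma(K, shape = a)
    counts[i, ] <- stats::rmultinom(1, config$depth, g / sum(g))
  }
  sample_ids <- sprintf("S%04d", seq_len(n))
  dimnames(counts) <- list(sample_ids, taxon_ids)

  case_chr <- ifelse(is_case, "yes", "no")
  if (config$missing_case_fraction > 0)
    case_chr[stats::runif(n) < config$missing_case_fraction] <- "Unknown"

  md <- data.frame(
    SAMPLE_ID = sample_ids,
    HOST_SUBJECT_ID = sprintf("H%04d", seq_len(n)),
    AGE = age,
    SEX = .sample_levels(n, c("male", "female"), c(461, 579)),
    RACE = .sample_levels(n, c("Caucasian", "African American", "Hispanic",
                               "Asian or Pacific Islander", "Other"),
                          c(964, 10, 16, 34, 16)),
    BMI = round(pmax(stats::rnorm(n, 24, 5), 15), 1),
    BODY_SITE = "feces",
    DIABETES = "no",
    IBD = "no",
    ANTIBIOTIC_SELECT = .sample_levels(
      n, c("Not in the last year", "In the past 2-6 months",
           "In the past 7-12 months"), c(793, 112, 135)),
    REGION = .sample_levels(
      n, c("California", "Other western US", "Midwestern US",
           "Northeastern US", "Southern US", "Canada", "Europe", "Australia"),
      c(206, 224, 164, 196, 210, 22, 11, 6)),
    DIET_TYPE = .sample_levels(
      n, c("Omnivore", "No red meat", "Vegan", "Vegetarian", "Pescetarian"),
      c(828, 64, 29, 44, 71)),
    ALCOHOL_FREQUENCY = .sample_levels(
      n, c("Never", "Rarely", "Occasionally", "Regularly", "Daily"),
      c(221, 255, 214, 205, 142)),
    SMOKING_FREQUENCY = .sample_levels(
      n, c("Never", "Rarely", "More than rarely"), c(991, 25, 17)),
    WEIGHT_CHANGE = .sample_levels(
      n, c("Remained stable", "Decreased more than 10 pounds",
           "Increased more than 10 pounds"), c(877, 104, 53)),
    GLUTEN = .sample_levels(n, c("no", "yes"), c(840, 200)),
    LACTOSE = .sample_levels(n, c("no", "yes"), c(857, 183)),
    ASTHMA = .sample_levels(n, c("no", "yes"), c(954, 86)),
    CSECTION = case_chr,
    APPENDIX_REMOVED = .sample_levels(n, c("no", "yes", "Unknown"),
                                      c(961, 155, 21)),
    stringsAsFactors = FALSE)

  list(table = taxon_table(counts, lineages = lineages, mode = "counts"),
       metadata = md,
       lineages = lineages,
       affected = taxon_ids[affected])
}

#' Simulate a rooted phylogeny over taxa
#'
#' Random binary topology with exponential branch lengths; any positive
#' branch-length rooted tree is sufficient for phylogenetic-diversity
#' computations, so no attempt is made to mirror the lineage hierarchy.
#'
#' @param taxa character vector of unique leaf names (length >= 2).
#' @param seed integer RNG seed; the emitted tree is deterministic given it.
#' @param rate rate of the exponential branch-length distribution.
#' @return A rooted `ape::phylo` with `length(taxa)` leaves.
#' @export
simulate_tree <- function(taxa, seed = 1, rate = 1) {
  if (length(taxa) < 2) stop("need at least 2 taxa")
  if (anyDuplicated(taxa))
    stop("duplicate taxon names: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  set.seed(seed)
  tr <- ape::rtree(length(taxa), rooted = TRUE, tip.label = taxa,
                   br = function(k) stats::rexp(k, rate))
  tr
}
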