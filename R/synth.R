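# Seeded synthetic-data generators. They emulate the study design --
# ordered mono-cropping treatments crossed with two growth stages, four
# replicates -- with controllable ground truth (assembly process,
# treatment filtering strength, SIP density shift, planted allocation
# fractions) so every pipeline stage has a recovery test. Each
# generator is a pure function of its arguments and seed; ground-truth
# objects ride along for tests and are never consumed by pipeline
# stages.

#' Generate a set of valid molecular formulas
#'
#' Emulates the molecular-formula space of an FTICR-MS spectrum in two
#' steps. First, "seed" formulas are drawn from a mixture of van
#' Krevelen compound-class archetypes with weights emulating
#' rhizodeposit spectra (lignins and lipids dominant, then
#' proteins/amino sugars, smaller shares of the remaining classes): an
#' (O/C, H/C) point is placed uniformly inside the class rectangle,
#' carbon is drawn uniformly (C 6-35), H and O follow from the ratios,
#' N is enriched in protein-like formulas, and S and P are rare.
#' Second, the set is grown into homologous series by repeatedly
#' applying common biochemical element-count deltas (H2, CH2, O, NH3,
#' H2O, CO, CH2O, C2H2O, CO2) to existing formulas, as real spectra are
#' dominated by such series; this also makes the set well connected
#' under mass-difference transformation matching. Candidates violating
#' DBE >= 0, H <= 2C + 2 + N or the realistic element windows (C 4-40,
#' H 4-80, O 0-25, N 0-3, S 0-2, P 0-1) are rejected and duplicates are
#' collapsed. At n >= 200 the set is resampled (bounded retries) until
#' it covers at least 4 compound classes.
#'
#' @param n number of formulas (>= 20).
#' @param seed RNG seed (mandatory).
#' @param max_retries resampling bound for class coverage (default 20).
#' @param seed_fraction fraction of formulas drawn as archetype seeds
#'   rather than grown as series neighbours (default 0.05; smaller
#'   values give fewer, larger homologous families and a better
#'   connected transformation network).
#' @param class_weights named mixture weights over the classes of
#'   [default_class_table()].
#' @return data frame of unique formulas with characteristics and a
#'   \code{formula} id column.
#' @export
gen_formulas <- function(n, seed, max_retries = 20, seed_fraction = 0.05,
                         class_weights = c(
                           "lipids" = 0.28,
                           "proteins/amino sugars" = 0.13,
                           "carbohydrates" = 0.07,
                           "unsaturated hydrocarbons" = 0.05,
                           "lignins" = 0.35,
                           "tannins" = 0.07,
                           "condensed aromatics" = 0.05)) {
  if (missing(seed)) stop("seed is mandatory")
  if (n < 20) stop("n must be at least 20")
  set.seed(seed)
  ct <- default_class_table()
  if (!all(names(class_weights) %in% ct$class)) {
    stop("class_weights names must match the class table")
  }
  deltas <- rbind(
    H2   = c(0, 2, 0, 0, 0, 0),
    CH2  = c(1, 2, 0, 0, 0, 0),
    O    = c(0, 0, 1, 0, 0, 0),
    NH3  = c(0, 3, 0, 1, 0, 0),
    H2O  = c(0, 2, 1, 0, 0, 0),
    CO   = c(1, 0, 1, 0, 0, 0),
    CH2O = c(1, 2, 1, 0, 0, 0),
    C2H2O = c(2, 2, 1, 0, 0, 0),
    CO2  = c(1, 0, 2, 0, 0, 0))
  colnames(deltas) <- ELEMENTS
  valid <- function(f) {
    dbe <- 1 + (2 * f$C - f$H + f$N + f$P) / 2
    dbe >= 0 & f$H <= 2 * f$C + 2 + f$N &
      f$C >= 4 & f$C <= 40 & f$H >= 4 & f$H <= 80 &
      f$O >= 0 & f$O <= 25 & f$N >= 0 & f$N <= 3 &
      f$S >= 0 & f$S <= 2 & f$P >= 0 & f$P <= 1
  }
  draw_seeds <- function(m) {
    cls <- sample(names(class_weights), m, TRUE, prob = class_weights)
    row <- ct[match(cls, ct$class), ]
    oc <- stats::runif(m, row$oc_min + 0.05 * (row$oc_max - row$oc_min),
                       row$oc_max - 0.05 * (row$oc_max - row$oc_min))
    hc <- stats::runif(m, row$hc_min + 0.05 * (row$hc_max - row$hc_min),
                       row$hc_max - 0.05 * (row$hc_max - row$hc_min))
    C <- sample(6:35, m, TRUE)
    f <- data.frame(C = C, H = pmax(1, round(hc * C)), O = round(oc * C),
                    N = stats::rbinom(m, 2, ifelse(cls == "proteins/amino sugars",
                                                   0.45, 0.10)),
                    S = stats::rbinom(m, 1, 0.05),
                    P = stats::rbinom(m, 1, 0.03))
    f[valid(f), , drop = FALSE]
  }
  n_seed <- max(10, round(seed_fraction * n))
  for (attempt in seq_len(max_retries)) {
    out <- data.frame()
    guard <- 0
    while (nrow(out) < n_seed && guard < 50) {
      out <- rbind(out, draw_seeds(3 * n_seed))
      out <- out[!duplicated(formula_id(out)), , drop = FALSE]
      guard <- guard + 1
    }
    if (nrow(out) < n_seed) stop("formula generation retry bound exceeded")
    out <- out[seq_len(n_seed), , drop = FALSE]
    # grow homologous series off the seed set
    guard <- 0
    while (nrow(out) < n && guard < 500) {
      m <- min(2 * (n - nrow(out)), 4 * n)
      base <- out[sample.int(nrow(out), m, replace = TRUE),
                  ELEMENTS, drop = FALSE]
      dl <- deltas[sample.int(nrow(deltas), m, replace = TRUE), ,
                   drop = FALSE]
      sgn <- sample(c(-1L, 1L), m, replace = TRUE)
      cand <- as.data.frame(as.matrix(base) + sgn * dl)
      cand <- cand[valid(cand), , drop = FALSE]
      out <- rbind(out, cand)
      out <- out[!duplicated(formula_id(out)), , drop = FALSE]
      guard <- guard + 1
    }
    if (nrow(out) < n) stop("formula generation retry bound exceeded")
    out <- out[seq_len(n), , drop = FALSE]
    rownames(out) <- NULL
    out <- molecular_characteristics(out)
    out$formula <- formula_id(out)
    if (n < 200) return(out)
    ncl <- length(setdiff(unique(classify_compound(out)), "unclassified"))
    if (ncl >= 4) return(out)
  }
  stop("could not cover 4 compound classes within retry bound")
}

#' Generate a synthetic rhizodeposit metabolome
#'
#' Produces a binary incidence matrix over a crossed design of ordered
#' treatments (emulating increasing mono-cropping duration) and growth
#' stages. Each formula carries a latent treatment-affinity trait: its
#' score on the first principal component of the standardized
#' molecular-characteristics matrix, i.e. the dominant axis of chemical
#' variation. Treatment t filters formulas through a Gaussian niche
#'
#'   filter_t(f) = (1 - strength) + strength exp(-(trait_f - mu_t)^2 / (2 sigma^2))
#'
#' with well-separated optima mu_t at the 0.05...0.95 trait quantiles,
#' so different treatments deterministically select chemically distinct
#' formula suites (variable-selection truth). Presence probability is
#'
#'   p = detect_prob x stage multiplier x (1 - strength x decline x (t-1))
#'       x (min_t M_t / M_t) x filter_t(f)
#'
#' where M_t = sum_f filter_t(f): the density calibration (min M / M)
#' equalizes expected chemodiversity across niches of unequal trait
#' density, and the geometric \code{decline} term then makes expected
#' chemodiversity fall monotonically along the treatment order
#' (emulating the loss of effective peaks under prolonged
#' mono-cropping). At strength 0 every filter is 1 and all treatments
#' share the same expected chemodiversity.
#'
#' @param formulas formula table from [gen_formulas()] (generated
#'   internally when NULL).
#' @param n_formulas used when \code{formulas} is NULL (default 500).
#' @param treatments ordered treatment labels (default P1, P5, P10).
#' @param stages stage labels (default W6, W10); the first stage's
#'   detection is reduced by \code{stage_effect}.
#' @param n_replicates replicates per (treatment x stage), default 4.
#' @param detect_prob in-niche detection probability (default 0.4).
#' @param strength treatment filter strength in \[0, 1\] (default 0.8).
#' @param decline per-treatment-step relative chemodiversity decline
#'   (default 0.15), active only at strength > 0.
#' @param stage_effect relative detection reduction at the first stage
#'   (default 0.15).
#' @param sigma0 niche width in trait SD units (default 0.25).
#' @param seed RNG seed (mandatory).
#' @return list: \code{metabolome} (a \code{metabolome} object),
#'   \code{metadata} (sample table), \code{truth} (trait, optima,
#'   width, per-treatment detection, expected chemodiversity by
#'   treatment at the reference stage).
#' @export
gen_metabolome <- function(formulas = NULL, n_formulas = 500,
                           treatments = c("P1", "P5", "P10"),
                           stages = c("W6", "W10"), n_replicates = 4,
                           detect_prob = 0.4, strength = 0.8,
                           decline = 0.15, stage_effect = 0.15,
                           sigma0 = 0.25, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (strength < 0 || strength > 1) stop("strength must be in [0, 1]")
  if (is.null(formulas)) formulas <- gen_formulas(n_formulas, seed = seed + 1)
  set.seed(seed)
  nf <- nrow(formulas)
  chm <- as.matrix(formulas[c("C", "H", "O", "N", "S", "P", "mass", "oc",
                              "hc", "dbe", "ai_mod", "nosc")])
  sds <- apply(chm, 2, stats::sd)
  trait <- stats::prcomp(scale(chm[, sds > 0, drop = FALSE]))$x[, 1]
  k <- length(treatments)
  qs <- if (k == 1) 0.5 else seq(0.05, 0.95, length.out = k)
  mu <- stats::quantile(trait, probs = qs, names = FALSE)
  sigma <- sigma0 * stats::sd(trait)
  filt <- vapply(seq_len(k), function(t) {
    (1 - strength) + strength * exp(-(trait - mu[t])^2 / (2 * sigma^2))
  }, numeric(nf))
  M <- colSums(filt)
  dpt <- detect_prob * (1 - strength * decline * (seq_len(k) - 1)) * min(M) / M
  meta <- expand.grid(replicate = seq_len(n_replicates),
                      stage = stages, treatment = treatments,
                      stringsAsFactors = FALSE)
  meta$sample_id <- sprintf("%s_%s_r%d", meta$treatment, meta$stage,
                            meta$replicate)
  meta <- meta[, c("sample_id", "treatment", "stage", "replicate")]
  stage_mult <- stats::setNames(
    c(1 - stage_effect, rep(1, length(stages) - 1)), stages)
  inc <- matrix(0L, nrow(meta), nf,
                dimnames = list(meta$sample_id, formulas$formula))
  for (s in seq_len(nrow(meta))) {
    t_idx <- match(meta$treatment[s], treatments)
    p <- pmin(1, dpt[t_idx] * stage_mult[[meta$stage[s]]] * filt[, t_idx])
    for (try in 1:10) {
      row <- stats::rbinom(nf, 1, p)
      if (sum(row) > 0) break
    }
    if (sum(row) == 0) stop("could not generate a non-empty sample")
    inc[s, ] <- row
  }
  mm <- structure(list(incidence = inc, formulas = formulas),
                  class = "metabolome")
  list(metabolome = mm, metadata = meta,
       truth = list(trait = trait, optima = mu, width = sigma,
                    strength = strength, detection = dpt,
                    expected_chemodiversity = dpt * M))
}

#' Generate a synthetic active community with phylogeny
#'
#' A pure-birth tree (exponentially distributed waiting times) carries
#' a Brownian-motion trait. In \code{selection} mode each sample's
#' expected composition is a Gaussian kernel of (trait - treatment
#' optimum) with optima differing across treatments (variable-selection
#' truth); in \code{drift} mode all samples draw from one shared
#' lognormal metacommunity (stochastic truth). Counts are multinomial
#' at the stated sequencing depth.
#'
#' @param n_tips tree size (default 200; >= 20).
#' @param treatments treatment label per sample. In drift mode defaults
#'   to 8 exchangeable samples; in selection mode defaults to 3
#'   treatments x 3 replicates.
#' @param mode assembly truth: "drift" or "selection".
#' @param depth multinomial sequencing depth per sample (default
#'   10000; must be positive).
#' @param niche_width Gaussian kernel width in trait SD units
#'   (selection mode, default 0.25; smaller = stronger selection).
#' @param seed RNG seed (mandatory).
#' @return list: \code{counts} (tips x samples), \code{tree}
#'   (\code{phylo}), \code{metadata}, \code{truth} (mode, trait,
#'   optima).
#' @export
gen_community <- function(n_tips = 200, treatments = NULL,
                          mode = c("drift", "selection"), depth = 10000,
                          niche_width = 0.25, seed) {
  if (missing(seed)) stop("seed is mandatory")
  mode <- match.arg(mode)
  if (depth <= 0) stop("depth must be positive")
  if (n_tips < 20) stop("need at least 20 tips")
  if (is.null(treatments)) {
    treatments <- if (mode == "drift") rep("M", 8) else
      rep(c("P1", "P5", "P10"), each = 3)
  }
  set.seed(seed)
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  trait <- ape::rTraitCont(tree, model = "BM", sigma = 1)
  n_s <- length(treatments)
  ids <- sprintf("%s_s%02d", treatments, seq_len(n_s))
  counts <- matrix(0L, n_tips, n_s, dimnames = list(tree$tip.label, ids))
  optima <- NULL
  if (mode == "drift") {
    meta_p <- stats::rlnorm(n_tips, 0, 1)
    meta_p <- meta_p / sum(meta_p)
    for (s in seq_len(n_s)) {
      counts[, s] <- stats::rmultinom(1, depth, meta_p)
    }
  } else {
    lev <- unique(treatments)
    optima <- stats::setNames(
      stats::quantile(trait, probs = seq(0.15, 0.85, length.out = length(lev)),
                      names = FALSE), lev)
    w <- niche_width * stats::sd(trait)
    for (s in seq_len(n_s)) {
      p <- exp(-(trait - optima[[treatments[s]]])^2 / (2 * w^2))
      p <- p / sum(p)
      counts[, s] <- stats::rmultinom(1, depth, p)
    }
  }
  list(counts = counts, tree = tree,
       metadata = data.frame(sample_id = ids, treatment = treatments,
                             stringsAsFactors = FALSE),
       truth = list(mode = mode, trait = trait, optima = optima))
}

#' Generate paired SIP fraction profiles
#'
#' The control profile is a Gaussian over a 15-fraction buoyant-density
#' grid (1.66-1.78 g/mL); the labeled profile mixes the control shape
#' with a component shifted to higher density by \code{shift}.
#' Multiplicative lognormal qPCR noise is applied to the copies. The
#' planted heavy window -- the fractions [heavy_fractions()] selects on
#' the noiseless profiles -- is recorded as ground truth.
#'
#' @param shift density shift of the labeled component (g/mL; must be
#'   > 0 when \code{labeled = TRUE}).
#' @param labeled generate a labeled profile (FALSE gives a second
#'   unlabeled gradient, for null checks).
#' @param label_fraction fraction of the labeled profile's DNA in the
#'   shifted component (default 0.5).
#' @param n_fractions number of fractions (default 15).
#' @param density_range gradient range in g/mL (default 1.66-1.78).
#' @param center,width control Gaussian center and width (default 1.70,
#'   0.02 g/mL).
#' @param noise_cv multiplicative qPCR noise coefficient (default
#'   0.05).
#' @param total_copies total 16S copies per gradient (default 1e8).
#' @param density_min,ratio_min heavy-fraction rule parameters used to
#'   record the planted window (defaults as in [heavy_fractions()]).
#' @param seed RNG seed (mandatory).
#' @return list: \code{labeled}, \code{control} (data frames fraction,
#'   density, copies), \code{truth_window} (integer fraction indices).
#' @export
gen_sip <- function(shift = 0.03, labeled = TRUE, label_fraction = 0.5,
                    n_fractions = 15, density_range = c(1.66, 1.78),
                    center = 1.70, width = 0.02, noise_cv = 0.05,
                    total_copies = 1e8, density_min = 1.72,
                    ratio_min = 1.5, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (labeled && shift <= 0) stop("shift must be positive in labeled mode")
  set.seed(seed)
  dens <- seq(density_range[1], density_range[2], length.out = n_fractions)
  gauss <- function(mu) exp(-(dens - mu)^2 / (2 * width^2))
  ctrl_shape <- gauss(center)
  lab_shape <- if (labeled) {
    (1 - label_fraction) * ctrl_shape + label_fraction * gauss(center + shift)
  } else ctrl_shape
  make_profile <- function(shape) {
    copies <- total_copies * shape / sum(shape)
    if (noise_cv > 0) copies <- copies * exp(stats::rnorm(n_fractions, 0, noise_cv))
    data.frame(fraction = seq_len(n_fractions), density = dens,
               copies = copies)
  }
  clean <- function(shape) data.frame(fraction = seq_len(n_fractions),
                                      density = dens,
                                      copies = total_copies * shape / sum(shape))
  truth <- heavy_fractions(clean(lab_shape), clean(ctrl_shape),
                           density_min = density_min, ratio_min = ratio_min)
  attributes(truth) <- NULL
  list(labeled = make_profile(lab_shape), control = make_profile(ctrl_shape),
       truth_window = as.integer(truth))
}

#' Generate isotope pools with planted carbon allocation
#'
#' For each treatment, a planted allocation of a fixed total excess
#' 13C among shoot, root and soil compartments is converted back to
#' labeled delta-13C values (via the VPDB atom-percent map), with
#' Gaussian noise on the deltas. The planted fractions are the ground
#' truth for recovery tests.
#'
#' @param allocations named list (per treatment) of length-3 numeric
#'   vectors (shoot, root, soil) summing to 1. Defaults emulate a
#'   declining belowground allocation across P1/P5/P10.
#' @param total_excess total 13C excess per treatment in g (default
#'   0.05).
#' @param noise_sd Gaussian noise on delta-13C in permil (default 2).
#' @param seed RNG seed (mandatory).
#' @return list: \code{pools} (data frame treatment, compartment, mass,
#'   c_conc, delta_labeled, delta_control), \code{truth} (planted
#'   allocation percentages per treatment).
#' @export
gen_isotope <- function(allocations = list(
                          P1 = c(shoot = 0.16, root = 0.08, soil = 0.76),
                          P5 = c(shoot = 0.29, root = 0.15, soil = 0.56),
                          P10 = c(shoot = 0.38, root = 0.19, soil = 0.43)),
                        total_excess = 0.05, noise_sd = 2, seed) {
  if (missing(seed)) stop("seed is mandatory")
  set.seed(seed)
  base <- data.frame(
    compartment = c("shoot", "root", "soil"),
    mass = c(8, 2, 3000),
    c_conc = c(0.45, 0.45, 0.01),
    delta_control = c(-28, -28, -26),
    stringsAsFactors = FALSE)
  atom_to_delta <- function(atom) {
    R <- atom / (100 - atom)
    (R / R_VPDB - 1) * 1000
  }
  rows <- list()
  for (tr in names(allocations)) {
    al <- allocations[[tr]]
    if (abs(sum(al) - 1) > 1e-8) stop("allocations must sum to 1 for ", tr)
    b <- base
    excess <- total_excess * al[b$compartment]
    atom_ctrl <- atom_percent(b$delta_control)
    atom_lab <- atom_ctrl + 100 * excess / (b$mass * b$c_conc)
    b$delta_labeled <- atom_to_delta(atom_lab) +
      stats::rnorm(nrow(b), 0, noise_sd)
    b$treatment <- tr
    rows[[tr]] <- b
  }
  pools <- do.call(rbind, rows)
  rownames(pools) <- NULL
  truth <- lapply(allocations, function(a) 100 * a / sum(a))
  list(pools = pools[, c("treatment", "compartment", "mass", "c_conc",
                         "delta_labeled", "delta_control")],
       truth = truth)
}
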