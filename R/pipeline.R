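# Configuration handling and the end-to-end pipeline. A single config
# (YAML file or R list) with a mandatory seed drives every stage;
# identical config + seed gives byte-identical outputs. Stage outputs
# are delimited text (distance matrices as labelled square tables,
# stats tables with a "# seed=... n_perm=..." provenance comment) and
# newick dendrograms.

#' Default pipeline configuration
#'
#' Returns the demo configuration: a 3-treatment x 2-stage x 4-replicate
#' synthetic design with 200 formulas, a 120-tip phylogeny at depth
#' 10000, 999 null/permutation replicates, and the package default
#' tolerances and thresholds. Any field can be overridden.
#'
#' @param seed RNG seed (mandatory; every stochastic stage derives its
#'   stream from it).
#' @param ... overrides of default fields.
#' @return named list of class \code{run_config}.
#' @export
default_config <- function(seed, ...) {
  if (missing(seed)) stop("seed is mandatory in the configuration")
  cfg <- list(
    seed = seed,
    n_formulas = 200,
    n_tips = 120,
    depth = 2000,
    treatments = c("P1", "P5", "P10"),
    stages = c("W6", "W10"),
    n_replicates = 4,
    detect_prob = 0.4,
    strength = 0.8,
    stage_effect = 0.15,
    community_mode = "drift",
    n_null = 999,
    n_perm = 999,
    mass_tolerance = 0.005,
    transformation_tolerance = 0.001,
    betanti_threshold = 2,
    density_min = 1.72,
    ratio_min = 1.5,
    sip_shift = 0.03,
    class_table = NULL,
    transformation_reference = NULL,
    drop_flagged = FALSE
  )
  over <- list(...)
  cfg[names(over)] <- over
  class(cfg) <- "run_config"
  cfg
}

#' Read / validate a pipeline configuration
#'
#' @param x YAML file path or a list of fields (see
#'   [default_config()]).
#' @return validated \code{run_config}.
#' @export
read_config <- function(x) {
  cfg <- if (is.character(x)) yaml::read_yaml(x) else x
  if (is.null(cfg$seed)) {
    stop("configuration must set a seed (null models are stochastic)")
  }
  full <- default_config(seed = cfg$seed)
  unknown <- setdiff(names(cfg), names(full))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  full[names(cfg)] <- cfg
  for (p in c("class_table", "transformation_reference")) {
    if (!is.null(full[[p]]) && !file.exists(full[[p]])) {
      stop("config path does not exist: ", p, " = ", full[[p]])
    }
  }
  class(full) <- "run_config"
  full
}

pipe_write <- function(tb, out, name, cfg, what = "") {
  write_table_commented(tb, file.path(out, name),
                        comments = sprintf("seed=%d n_perm=%d n_null=%d %s",
                                           cfg$seed, cfg$n_perm, cfg$n_null,
                                           what))
}

#' Run the full analysis pipeline
#'
#' Generates the synthetic inputs from the config, then chains the
#' analysis stages: metabolome ecology (chemodiversity, compound
#' classes, Sorensen PCoA), transformation networks, the three
#' relational dendrograms, betaNTI null models for metabolites (on
#' MCD/TD/TWCD) and the active community (on its phylogeny), process
#' classification and betaNTI coupling, community statistics
#' (diversity, Bray-Curtis, two-way PERMANOVA, Mantel, Wilcoxon
#' enrichment), 13C allocation, and SIP heavy-fraction detection. All
#' outputs are written under \code{out_dir}; a stage failure aborts
#' with the stage name.
#'
#' @param config \code{run_config}, list, or YAML path.
#' @param out_dir output directory (created if needed).
#' @param stages character vector of stage names, or "all".
#' @return (invisibly) a list of in-memory stage results.
#' @export
run_pipeline <- function(config, out_dir, stages = "all") {
  cfg <- read_config(config)
  all_stages <- c("simulate", "metabolome", "transformations", "dendrogram",
                  "assembly", "commstats", "isotope", "sip")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  # stage dependencies
  if ("assembly" %in% stages) stages <- union(stages, "dendrogram")
  if ("dendrogram" %in% stages) stages <- union(stages, "transformations")
  stages <- union("simulate", stages)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- list(config = cfg)
  run_stage <- function(name, fun) {
    if (!(name %in% stages)) return()
    tryCatch(fun(), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # --- simulate: all synthetic inputs -------------------------------
  run_stage("simulate", function() {
    gm <- gen_metabolome(n_formulas = cfg$n_formulas,
                         treatments = cfg$treatments, stages = cfg$stages,
                         n_replicates = cfg$n_replicates,
                         detect_prob = cfg$detect_prob,
                         strength = cfg$strength,
                         stage_effect = cfg$stage_effect,
                         seed = cfg$seed + 11)
    gc_ <- gen_community(n_tips = cfg$n_tips,
                         treatments = gm$metadata$treatment,
                         mode = cfg$community_mode, depth = cfg$depth,
                         seed = cfg$seed + 22)
    gs <- gen_sip(shift = cfg$sip_shift, density_min = cfg$density_min,
                  ratio_min = cfg$ratio_min, seed = cfg$seed + 33)
    gi <- gen_isotope(seed = cfg$seed + 44)
    res$simulate <<- list(metabolome = gm, community = gc_,
                          sip = gs, isotope = gi)
    # write the generated inputs as the pipeline's on-disk input set
    inc <- gm$metabolome$incidence
    fl <- gm$metabolome$formulas
    peaks <- do.call(rbind, lapply(rownames(inc), function(s) {
      pres <- which(inc[s, ] == 1)
      data.frame(sample_id = s, mz = fl$mass[pres],
                 fl[pres, ELEMENTS], stringsAsFactors = FALSE)
    }))
    write_table_commented(peaks, file.path(out_dir, "peaks.csv"))
    write_table_commented(gm$metadata, file.path(out_dir, "metadata.csv"))
    cts <- data.frame(feature = rownames(gc_$counts), gc_$counts,
                      check.names = FALSE)
    write_table_commented(cts, file.path(out_dir, "community_counts.csv"))
    ape::write.tree(gc_$tree, file.path(out_dir, "community_tree.nwk"))
    sip_tb <- rbind(cbind(gs$labeled, sample_id = "S1", label = "labeled"),
                    cbind(gs$control, sample_id = "S1", label = "control"))
    write_table_commented(sip_tb, file.path(out_dir, "sip_fractions.csv"))
    write_table_commented(gi$pools, file.path(out_dir, "isotope_pools.csv"))
  })
  sim <- res$simulate
  if (is.null(sim)) stop("pipeline requires the 'simulate' stage")
  mm <- sim$metabolome$metabolome
  meta <- sim$metabolome$metadata

  run_stage("metabolome", function() {
    ct <- if (is.null(cfg$class_table)) default_class_table() else
      utils::read.csv(cfg$class_table, stringsAsFactors = FALSE)
    classes <- classify_compound(mm$formulas, ct)
    cd <- chemodiversity(mm)
    pipe_write(data.frame(sample_id = names(cd), chemodiversity = cd),
               out_dir, "chemodiversity.csv", cfg)
    pipe_write(data.frame(formula = mm$formulas$formula, class = classes),
               out_dir, "compound_classes.csv", cfg)
    cra <- class_relative_abundance(mm, classes = classes, class_table = ct)
    pipe_write(data.frame(sample_id = rownames(cra), cra,
                          check.names = FALSE),
               out_dir, "class_relative_abundance.csv", cfg)
    sor <- sorensen_matrix(mm)
    write_distance_matrix(sor, file.path(out_dir, "sorensen.csv"),
                          comments = "metric=sorensen")
    pc <- pcoa(sor)
    pipe_write(data.frame(sample_id = rownames(pc$coordinates),
                          pc$coordinates[, 1:min(3, ncol(pc$coordinates))]),
               out_dir, "metabolome_pcoa.csv", cfg)
    res$metabolome <<- list(classes = classes, chemodiversity = cd,
                            sorensen = sor, pcoa = pc)
  })

  run_stage("transformations", function() {
    ref <- transformation_reference(cfg$transformation_reference)
    tr <- sample_transformations(mm, reference = ref,
                                 tolerance = cfg$transformation_tolerance)
    pipe_write(data.frame(sample_id = names(tr$counts),
                          n_transformations = tr$counts),
               out_dir, "transformation_counts.csv", cfg)
    pipe_write(tr$pooled$edges, out_dir, "pooled_network_edges.csv", cfg)
    res$transformations <<- tr
  })

  run_stage("dendrogram", function() {
    if (is.null(res$transformations)) stop("requires the transformations stage")
    mcd <- build_mcd(mm$formulas)
    td <- build_td(res$transformations$pooled)
    twcd <- build_twcd(mm$formulas,
                       peak_transformation_profile(res$transformations$pooled))
    write_dendrogram(mcd, file.path(out_dir, "mcd.nwk"))
    write_dendrogram(td, file.path(out_dir, "td.nwk"))
    write_dendrogram(twcd, file.path(out_dir, "twcd.nwk"))
    res$dendrograms <<- list(MCD = mcd, TD = td, TWCD = twcd)
  })

  run_stage("assembly", function() {
    if (is.null(res$dendrograms)) stop("requires the dendrogram stage")
    bn <- list()
    for (kind in names(res$dendrograms)) {
      bn[[kind]] <- beta_nti(mm, res$dendrograms[[kind]],
                             n_null = cfg$n_null, seed = cfg$seed + 55)
      write_distance_matrix(bn[[kind]]$z,
                            file.path(out_dir, paste0("betanti_", kind, ".csv")),
                            comments = sprintf("betaNTI %s n_null=%d seed=%d",
                                               kind, cfg$n_null, cfg$seed + 55))
    }
    bn$community <- beta_nti(sim$community$counts, sim$community$tree,
                             n_null = cfg$n_null, seed = cfg$seed + 66,
                             mode = "abundance")
    write_distance_matrix(bn$community$z,
                          file.path(out_dir, "betanti_community.csv"),
                          comments = sprintf("betaNTI phylogeny n_null=%d seed=%d",
                                             cfg$n_null, cfg$seed + 66))
    cls <- lapply(bn, classify_assembly, threshold = cfg$betanti_threshold)
    pipe_write(data.frame(
      source = names(cls),
      t(vapply(cls, function(x) x$fractions, numeric(3)))),
      out_dir, "assembly_classification.csv", cfg)
    # betaNTI coupling: community vs each metabolite dendrogram betaNTI.
    # Metabolome and community samples are paired by design position;
    # samples dropped from a dendrogram betaNTI (e.g. outside the TD
    # component) are excluded from its coupling.
    coup <- list()
    for (kind in names(res$dendrograms)) {
      z1 <- bn[[kind]]$z
      pos <- match(rownames(z1), meta$sample_id)
      z2 <- bn$community$z[pos, pos, drop = FALSE]
      if (nrow(z1) >= 4) {
        dimnames(z2) <- dimnames(z1)
        coup[[kind]] <- mantel(z1, z2, n_perm = cfg$n_perm,
                               seed = cfg$seed + 77)
      }
    }
    if (length(coup)) {
      pipe_write(data.frame(
        dendrogram = names(coup),
        mantel_r = vapply(coup, function(x) x$statistic, numeric(1)),
        p_value = vapply(coup, function(x) x$p_value, numeric(1))),
        out_dir, "betanti_coupling.csv", cfg)
    }
    res$assembly <<- list(betanti = bn, classification = cls,
                          coupling = coup)
  })

  run_stage("commstats", function() {
    div <- diversity_indices(sim$community$counts)
    pipe_write(div, out_dir, "alpha_diversity.csv", cfg)
    bc <- bray_curtis(sim$community$counts)
    write_distance_matrix(bc, file.path(out_dir, "bray_curtis.csv"),
                          comments = "metric=bray-curtis")
    pc <- pcoa(bc)
    pipe_write(data.frame(sample_id = rownames(pc$coordinates),
                          pc$coordinates[, 1:min(3, ncol(pc$coordinates))]),
               out_dir, "community_pcoa.csv", cfg)
    # two-way PERMANOVA of the metabolome (stage then treatment, as for
    # a crossed growth-stage x mono-cropping design)
    sor <- sorensen_matrix(mm)
    pv <- permanova_two_way(sor, A = meta$stage, B = meta$treatment,
                            n_perm = cfg$n_perm, seed = cfg$seed + 88)
    pipe_write(as.data.frame(pv), out_dir, "permanova_metabolome.csv", cfg,
               what = "A=stage B=treatment")
    # one-way PERMANOVA of the community by treatment
    pvc <- permanova_two_way(bc, A = sim$community$metadata$treatment,
                             n_perm = cfg$n_perm, seed = cfg$seed + 89)
    pipe_write(as.data.frame(pvc), out_dir, "permanova_community.csv", cfg,
               what = "A=treatment")
    # Mantel between metabolite and community dissimilarity (paired by
    # design order when sample counts match)
    mt <- NULL
    if (nrow(as.matrix(sor)) == nrow(as.matrix(bc))) {
      m2 <- as.matrix(bc)
      dimnames(m2) <- dimnames(as.matrix(sor))
      mt <- mantel(sor, m2, n_perm = cfg$n_perm, seed = cfg$seed + 90)
      pipe_write(data.frame(mantel_r = mt$statistic, p_value = mt$p_value),
                 out_dir, "mantel_sorensen_braycurtis.csv", cfg)
    }
    # Wilcoxon enrichment between the first two treatments
    trt <- sim$community$metadata$treatment
    lev <- unique(trt)[1:2]
    keep <- trt %in% lev
    wt <- wilcoxon_enrichment(sim$community$counts[, keep, drop = FALSE],
                              trt[keep])
    pipe_write(wt, out_dir, "wilcoxon_enrichment.csv", cfg)
    res$commstats <<- list(diversity = div, bray_curtis = bc,
                           permanova = pv, permanova_community = pvc,
                           mantel = mt, wilcoxon = wt)
  })

  run_stage("isotope", function() {
    pools <- sim$isotope$pools
    out <- do.call(rbind, lapply(split(pools, pools$treatment), function(p) {
      af <- allocation_fractions(p)
      data.frame(treatment = p$treatment[1], compartment = p$compartment,
                 allocation_pct = unname(af), stringsAsFactors = FALSE)
    }))
    rownames(out) <- NULL
    pipe_write(out, out_dir, "c13_allocation.csv", cfg)
    res$isotope <<- out
  })

  run_stage("sip", function() {
    hw <- heavy_fractions(sim$sip$labeled, sim$sip$control,
                          density_min = cfg$density_min,
                          ratio_min = cfg$ratio_min)
    pipe_write(data.frame(fraction = sim$sip$labeled$fraction,
                          density = sim$sip$labeled$density,
                          ratio = as.numeric(attr(hw, "ratio")),
                          heavy = sim$sip$labeled$fraction %in% hw),
               out_dir, "sip_heavy_fractions.csv", cfg)
    res$sip <<- hw
  })

  invisible(res)
}
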