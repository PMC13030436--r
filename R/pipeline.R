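## Pipeline orchestration: one run configuration drives simulation (or
## file input), sequence diversity, phenotype statistics, correlation
## screening and multi-criteria ranking, writing a report bundle with a
## manifest.

#' Default run configuration
#'
#' A complete configuration running the whole pipeline on synthetic data
#' generated under the study conditions (31-accession ITS panel, 17
#' evaluated genotypes). All knobs mirror the analysis parameters: gap
#' policy, distance model, Shannon class count, leaf-area thresholds,
#' indicator list with directions, weighting method, alpha, and the
#' mandatory seed.
#'
#' @param seed Integer seed applied to both generators.
#' @return A nested configuration list.
#' @export
default_run_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    synthgen = list(
      haplo = list(),   # overrides for haplo_config()
      traits = list()), # overrides for trait_gen_config()
    input = NULL,       # alternatively: list(fasta =, traits =)
    gap_policy = "exclude_gap_columns",
    distance_model = "p",
    shannon_classes = 10,
    leaf_thresholds = list(large_min = 2.50, small_max = 1.80),
    stagnation_threshold = 12,
    indicators = list(
      names = c("H", "BN", "NN", "SBD", "LL", "MLW", "LA", "SC",
                "Fm", "Fv/Fm", "Y(II)", "Y(NPQ)", "qP"),
      directions = "benefit"),
    weighting = "entropy",
    alpha = 0.05)
}

#' Read a run configuration from YAML
#'
#' Loads a YAML file and validates it against the pipeline schema;
#' missing optional fields fall back to [default_run_config()] values.
#'
#' @param path YAML file path.
#' @return A validated configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_run_config(seed = cfg$seed %||% 1L)
  cfg <- utils::modifyList(base, cfg)
  validate_run_config(cfg)
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_run_config <- function(cfg) {
  if (is.null(cfg$input) && is.null(cfg$synthgen))
    stop("config error at `input`/`synthgen`: supply either input file ",
         "paths or synthetic-generator parameters")
  if (!is.null(cfg$input)) {
    for (f in c("fasta", "traits"))
      if (is.null(cfg$input[[f]]))
        stop("config error at `input$", f, "`: path missing")
    for (f in c("fasta", "traits"))
      if (!file.exists(cfg$input[[f]]))
        stop("config error at `input$", f, "`: file not found: ",
             cfg$input[[f]])
  } else if (is.null(cfg$seed)) {
    stop("config error at `seed`: a seed is mandatory when the synthetic ",
         "generator is used")
  }
  if (!cfg$gap_policy %in% c("exclude_gap_columns", "include_gaps"))
    stop("config error at `gap_policy`: unknown policy ", cfg$gap_policy)
  if (!cfg$distance_model %in% c("p", "K2P"))
    stop("config error at `distance_model`: unknown model ",
         cfg$distance_model)
  if (!cfg$weighting %in% c("entropy", "critic"))
    stop("config error at `weighting`: unknown method ", cfg$weighting)
  invisible(cfg)
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full host-screening pipeline
#'
#' Executes the requested stages — `simulate` (or file input), `seqdiv`,
#' `pheno`, `assoc`, `rank` — and writes a report bundle to `out_dir`:
#' FASTA and trait tables (when simulated), a diversity JSON plus newick
#' tree, distance matrix and network edge/node tables, trait summary /
#' growth-rate / leaf-class tables, correlation matrices and pair list,
#' weight and ranking tables, and a `manifest.json` recording the package
#' version, seed, configuration echo and every file written. Fixed seeds
#' give byte-identical outputs.
#'
#' @param config Configuration list (see [default_run_config()]) or a path
#'   to a YAML file.
#' @param out_dir Output directory (created if needed).
#' @param stages Stages to run (subset of `simulate`, `seqdiv`, `pheno`,
#'   `assoc`, `rank`; `"all"` selects everything).
#' @param quiet Suppress stage logging.
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir,
                         stages = "all", quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  validate_run_config(config)
  all_stages <- c("simulate", "seqdiv", "pheno", "assoc", "rank")
  if (identical(stages, "all")) stages <- all_stages
  if (!all(stages %in% all_stages))
    stop("unknown stage(s): ",
         paste(setdiff(stages, all_stages), collapse = ", "))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  say <- function(...) if (!quiet) message("[hostscreen] ", ...)
  emit <- function(name) { files <<- c(files, name); file.path(out_dir, name) }
  results <- list()

  ## --- inputs -----------------------------------------------------------
  if (!is.null(config$input)) {
    say("loading inputs from files")
    aln <- run_stage("input", read_alignment(config$input$fasta))
    tt <- run_stage("input", read_trait_table(config$input$traits))
  } else {
    say("simulate: seed ", config$seed)
    hcfg <- run_stage("simulate", do.call(haplo_config, utils::modifyList(
      list(seed = config$seed), config$synthgen$haplo %||% list())))
    tcfg <- run_stage("simulate", do.call(trait_gen_config, utils::modifyList(
      list(seed = config$seed), config$synthgen$traits %||% list())))
    sim <- run_stage("simulate", generate_its_alignment(hcfg))
    aln <- sim$alignment
    tt <- run_stage("simulate", generate_trait_tables(tcfg))
    if ("simulate" %in% stages) {
      write_alignment(aln, emit("its_alignment.fasta"))
      write_trait_table(tt, emit("trait_table.tsv"))
      results$simulate <- list(alignment = aln, truth = sim$assignment,
                               traits = tt)
    }
  }

  ## --- sequence diversity ----------------------------------------------
  if ("seqdiv" %in% stages) {
    say("seqdiv: ", nrow(aln), " accessions, ", ncol(aln), " columns")
    sdv <- run_stage("seqdiv",
                     seqdiv_summary(aln, config$distance_model,
                                    config$gap_policy))
    ape::write.tree(sdv$tree, emit("nj_tree.nwk"))
    utils::write.table(sdv$distance_matrix, emit("distances.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    utils::write.table(sdv$network$edges, emit("network_edges.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(sdv$network$nodes, emit("network_nodes.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(mean_gc = sdv$mean_gc,
           segregating_sites = sdv$segregating_sites,
           nucleotide_diversity = sdv$nucleotide_diversity,
           n_haplotypes = sdv$n_haplotypes,
           haplotype_diversity = sdv$haplotype_diversity,
           haplotype_counts = as.list(sdv$haplotypes$counts),
           per_genotype_polymorphic_sites =
             as.list(sdv$per_genotype_polymorphic_sites)),
      emit("diversity.json"), auto_unbox = TRUE, digits = NA)
    results$seqdiv <- sdv
  }

  ## --- phenotype statistics --------------------------------------------
  if ("pheno" %in% stages) {
    say("pheno: ", length(unique(tt$genotype)), " genotypes")
    agro <- intersect(c("H", "BN", "NN", "SBD"), unique(tt$trait))
    growth <- run_stage("pheno", do.call(rbind, lapply(agro, function(tr) {
      g <- monthly_growth_rates(tt, tr, config$stagnation_threshold)
      cbind(trait = tr, g,
            total_rate = attr(g, "total_rate"),
            rate_sum = attr(g, "rate_sum"))
    })))
    summ <- run_stage("pheno", trait_summary(
      tt, by_month = FALSE, n_classes = config$shannon_classes))
    leaf_df <- NULL
    if (all(c("LA", "SC") %in% tt$trait)) {
      la <- genotype_means(tt, "LA")
      sc <- genotype_means(tt, "SC")
      leaf_df <- data.frame(genotype = la$genotype, LA = la$mean,
                            SC = sc$mean[match(la$genotype, sc$genotype)])
    }
    leaf <- if (!is.null(leaf_df))
      run_stage("pheno", classify_leaves(
        leaf_df, config$leaf_thresholds$large_min,
        config$leaf_thresholds$small_max)) else NULL
    utils::write.table(growth, emit("growth_rates.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(summ, emit("trait_summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    if (!is.null(leaf)) {
      utils::write.table(leaf$classes, emit("leaf_classes.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(leaf$summary, emit("leaf_class_summary.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    results$pheno <- list(growth = growth, summary = summ, leaf = leaf)
  }

  ## --- correlation screening -------------------------------------------
  if ("assoc" %in% stages) {
    say("assoc: correlation screen")
    wide <- run_stage("assoc", trait_wide_table(tt))
    cs <- run_stage("assoc", pearson_matrix(wide))
    utils::write.table(cs$r, emit("correlation_r.tsv"), sep = "\t",
                       quote = FALSE, col.names = NA)
    utils::write.table(cs$p, emit("correlation_p.tsv"), sep = "\t",
                       quote = FALSE, col.names = NA)
    utils::write.table(cs$q, emit("correlation_q.tsv"), sep = "\t",
                       quote = FALSE, col.names = NA)
    utils::write.table(cs$pairs, emit("correlation_pairs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    results$assoc <- cs
  }

  ## --- multi-criteria ranking ------------------------------------------
  if ("rank" %in% stages) {
    say("rank: entropy-weighted TOPSIS with CRITIC cross-check")
    ind <- intersect(config$indicators$names, unique(tt$trait))
    dm <- run_stage("rank", decision_matrix_from_traits(
      tt, ind, directions = config$indicators$directions))
    ev <- run_stage("rank", evaluate_genotypes(dm))
    headline <- config$weighting
    utils::write.table(ev$weights$entropy, emit("weights_entropy.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(ev$weights$critic, emit("weights_critic.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(ev$rankings[[headline]], emit("ranking.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(
      list(weighting = headline,
           weights = ev$weights[[headline]],
           ranking = ev$rankings[[headline]],
           spearman_agreement = ev$agreement$spearman_rho),
      emit("ranking.json"), auto_unbox = TRUE, digits = NA,
      dataframe = "rows")
    results$rank <- ev
  }

  manifest <- list(
    package = "hostscreen",
    version = as.character(utils::packageVersion("hostscreen")),
    seed = config$seed,
    stages = stages,
    files = files,
    config = config_echo(config))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  say("wrote ", length(files) + 1L, " files to ", out_dir)
  invisible(list(results = results, manifest = manifest))
}

## Echo of the configuration with function-valued entries dropped so the
## manifest stays serialisable.
config_echo <- function(cfg) {
  rapply(cfg, function(x) if (is.function(x)) NULL else x,
         how = "replace")
}

#' Wide genotype x trait table
#'
#' Genotype-level means for every trait, one row per genotype — the input
#' format of [pearson_matrix()].
#'
#' @param tt Long trait table.
#' @param traits Traits to include (default: all).
#' @return Numeric matrix, genotypes x traits.
#' @export
trait_wide_table <- function(tt, traits = unique(tt$trait)) {
  ids <- sort(unique(tt$genotype))
  x <- vapply(traits, function(tr) {
    gm <- genotype_means(tt, tr)
    stats::setNames(gm$mean, gm$genotype)[ids]
  }, numeric(length(ids)))
  dimnames(x) <- list(ids, traits)
  x
}
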